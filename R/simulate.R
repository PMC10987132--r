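#' Generate a random genome
#'
#' I.i.d. bases at the requested GC content; deterministic for a fixed
#' seed.
#'
#' @param length genome length in bp (>= 100).
#' @param gc GC fraction in (0, 1).
#' @param seed RNG seed.
#' @param id contig id.
#' @return single-row contig data.frame.
#' @export
gen_genome <- function(length, gc = 0.5, seed = 1, id = "genome_1") {
  if (length < 100) stop("genome length must be >= 100 bp")
  if (gc <= 0 || gc >= 1) stop("gc must be inside (0,1)")
  set.seed(seed)
  bases <- sample(c("A", "C", "G", "T"), length, replace = TRUE,
                  prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  data.frame(id = id, sequence = paste0(bases, collapse = ""),
             sample_id = NA_character_, assembly_source = NA_character_,
             length = as.integer(length), stringsAsFactors = FALSE)
}

#' Mutate a genome by random substitutions
#'
#' Each base is substituted independently (to one of the three other
#' bases) with probability `divergence`. No indels, so the realized
#' identity is exactly 1 - (substitutions / length).
#'
#' @param genome single-row contig data.frame or DNA string.
#' @param divergence substitution probability in [0, 0.5].
#' @param seed RNG seed.
#' @param id id for the mutant.
#' @return single-row contig data.frame with attribute
#'   `realized_divergence`.
#' @export
mutate_genome <- function(genome, divergence, seed = 1,
                          id = "mutant_1") {
  stopifnot(divergence >= 0, divergence <= 0.5)
  seq <- as_seq(genome)
  set.seed(seed)
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(bases)) < divergence)
  alphabet <- c("A", "C", "G", "T")
  for (i in hit) {
    bases[i] <- sample(setdiff(alphabet, bases[i]), 1L)
  }
  out <- data.frame(id = id, sequence = paste0(bases, collapse = ""),
                    sample_id = NA_character_,
                    assembly_source = NA_character_,
                    length = length(bases), stringsAsFactors = FALSE)
  attr(out, "realized_divergence") <- length(hit) / length(bases)
  out
}

#' Add a terminal repeat, emulating assembly of a circular genome
#'
#' Appends the first `tr_len` bases to the end of the sequence, the
#' signature an assembler leaves when traversing a circular genome past its
#' origin.
#'
#' @param genome single-row contig data.frame or DNA string.
#' @param tr_len repeat length in bp (1 <= tr_len < length).
#' @param id id for the output contig (defaults to the input id).
#' @return single-row contig data.frame.
#' @export
make_circular <- function(genome, tr_len, id = NULL) {
  seq <- as_seq(genome)
  stopifnot(tr_len >= 1, tr_len < nchar(seq))
  out_seq <- paste0(seq, substr(seq, 1L, tr_len))
  if (is.null(id)) {
    id <- if (is.data.frame(genome)) genome$id else "circular_1"
  }
  data.frame(id = id, sequence = out_seq, sample_id = NA_character_,
             assembly_source = NA_character_, length = nchar(out_seq),
             stringsAsFactors = FALSE)
}

#' Build a mosaic genome sharing a region with a donor
#'
#' Copies one contiguous stretch covering `shared_fraction` of the donor
#' (lightly mutated, ~99\% identity) and embeds it in unrelated background
#' sequence; the output has the donor's length, so its expected ANI to the
#' donor is about `100 * shared_fraction`.
#'
#' @param donor,background single-row contig data.frames or DNA strings.
#' @param shared_fraction fraction in (0, 1).
#' @param seed RNG seed.
#' @param id id for the mosaic.
#' @return single-row contig data.frame.
#' @export
make_mosaic <- function(donor, background, shared_fraction, seed = 1,
                        id = "mosaic_1") {
  stopifnot(shared_fraction > 0, shared_fraction < 1)
  dseq <- as_seq(donor); bseq <- as_seq(background)
  n <- nchar(dseq)
  stopifnot(nchar(bseq) >= n)
  set.seed(seed)
  shared_len <- round(shared_fraction * n)
  d_start <- sample.int(n - shared_len + 1L, 1L)
  shared <- substr(dseq, d_start, d_start + shared_len - 1L)
  shared <- mutate_genome(shared, 0.01, seed = seed + 1L)$sequence
  pre_len <- sample.int(n - shared_len + 1L, 1L) - 1L
  post_len <- n - shared_len - pre_len
  out_seq <- paste0(substr(bseq, 1L, pre_len), shared,
                    substr(bseq, pre_len + 1L, pre_len + post_len))
  data.frame(id = id, sequence = out_seq, sample_id = NA_character_,
             assembly_source = NA_character_, length = nchar(out_seq),
             stringsAsFactors = FALSE)
}

#' Simulate per-sample read placements for a community
#'
#' Present genomes receive uniformly placed 150-bp reads at a
#' lognormal-abundance-driven depth comfortably above the presence
#' thresholds; absent genomes receive a few reads confined to under a third
#' of the genome, keeping breadth below the presence cut. Circular genomes
#' additionally receive `circ_min_reads` junction-spanning reads (two
#' segments each: one ending at the contig tail, one starting at the head,
#' both >= `circ_min_hit` bp, same strand).
#'
#' @param genomes contig data.frame.
#' @param n_samples number of samples (>= 1).
#' @param seed RNG seed.
#' @param circular_ids ids of genomes that should receive junction reads.
#' @param presence optional logical matrix (samples x genomes); generated
#'   at 70\% presence when `NULL`.
#' @param cfg pipeline configuration.
#' @param read_len simulated read length (bp).
#' @return list with `placements` (placement table), `presence` (logical
#'   truth matrix), `abundance` (lognormal abundance truth matrix).
#' @export
gen_community <- function(genomes, n_samples, seed = 1,
                          circular_ids = character(0), presence = NULL,
                          cfg = pipeline_config(), read_len = 150) {
  stopifnot(n_samples >= 1)
  set.seed(seed)
  n_g <- nrow(genomes)
  samples <- sprintf("S%02d", seq_len(n_samples))
  if (is.null(presence)) {
    presence <- matrix(stats::runif(n_samples * n_g) < 0.7, n_samples, n_g,
                       dimnames = list(samples, genomes$id))
    presence[1, ] <- TRUE               # anchor: everything in sample 1
  }
  abundance <- matrix(stats::rlnorm(n_samples * n_g, 0, 1), n_samples, n_g,
                      dimnames = list(samples, genomes$id))
  abundance[!presence] <- 0
  rows <- list()
  for (s in seq_len(n_samples)) {
    counter <- 0L
    for (g in seq_len(n_g)) {
      len <- genomes$length[g]
      id <- genomes$id[g]
      if (presence[s, g]) {
        depth <- cfg$presence_depth + 2 + 3 * abundance[s, g]
        n_reads <- ceiling(depth * len / read_len)
        starts <- sample.int(max(len - read_len, 1L), n_reads,
                             replace = TRUE) - 1L
        counter <- counter + n_reads
        rows[[length(rows) + 1L]] <- data.frame(
          read_id = sprintf("%s_%s_r%06d", samples[s], id,
                            seq_len(n_reads)),
          contig_id = id, start = starts,
          end = pmin(starts + read_len, len), strand = "+",
          sample_id = samples[s], stringsAsFactors = FALSE)
      } else {
        # sparse placements under a third of the genome: clearly absent
        n_reads <- sample.int(5L, 1L)
        lim <- max(floor(len / 3) - read_len, 1L)
        starts <- sample.int(lim, n_reads, replace = TRUE) - 1L
        rows[[length(rows) + 1L]] <- data.frame(
          read_id = sprintf("%s_%s_a%06d", samples[s], id,
                            seq_len(n_reads)),
          contig_id = id, start = starts, end = starts + read_len,
          strand = "+", sample_id = samples[s], stringsAsFactors = FALSE)
      }
      if (id %in% circular_ids && presence[s, g]) {
        for (r in seq_len(cfg$circ_min_reads)) {
          rid <- sprintf("%s_%s_junc%02d", samples[s], id, r)
          tail_len <- cfg$circ_min_hit + 20L
          head_len <- cfg$circ_min_hit + 10L
          rows[[length(rows) + 1L]] <- data.frame(
            read_id = rid, contig_id = id,
            start = c(len - tail_len, 5L),
            end = c(len, 5L + head_len),
            strand = "+", sample_id = samples[s],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  list(placements = do.call(rbind, rows), presence = presence,
       abundance = abundance)
}

#' Simulate detector-evidence tables with known truth
#'
#' At noise 0 every true virus scores above every detector threshold and
#' every non-virus below; with noise, each criterion flips independently
#' with the given probability. A `single_criterion_frac` of true viruses
#' receive exactly one satisfied criterion (VirSorter), exercising the
#' completeness-rescue route; `frac_hq` of true viruses get CheckV
#' completeness >= 90.
#'
#' @param genomes contig data.frame.
#' @param is_viral logical truth vector along `genomes`.
#' @param noise per-criterion flip probability in [0, 0.5].
#' @param seed RNG seed.
#' @param frac_hq fraction of viruses annotated high-quality by
#'   completeness.
#' @param single_criterion_frac fraction of viruses restricted to a single
#'   satisfied criterion.
#' @param cfg pipeline configuration.
#' @return `evidence`-schema data.frame (plus `checkv_quality`).
#' @export
gen_evidence <- function(genomes, is_viral, noise = 0, seed = 1,
                         frac_hq = 0.3, single_criterion_frac = 0,
                         cfg = pipeline_config()) {
  stopifnot(noise >= 0, noise <= 0.5, nrow(genomes) == length(is_viral))
  set.seed(seed)
  n <- nrow(genomes)
  above <- function(viral) {
    # satisfied with prob 1-noise for viruses, prob noise otherwise
    want <- ifelse(viral, 1 - noise, noise)
    stats::runif(n) < want
  }
  hi_score <- function(min, inclusive) {
    if (inclusive) min + stats::runif(n, 0.02, 0.25)
    else min + stats::runif(n, 0.02, 0.25)
  }
  lo_score <- function(min) pmax(stats::runif(n, 0, min - 0.05), 0)
  single <- is_viral & (stats::runif(n) < single_criterion_frac)

  a1 <- above(is_viral); a2 <- above(is_viral); a3 <- above(is_viral)
  a4 <- above(is_viral); a5 <- above(is_viral)
  a2[single] <- FALSE; a3[single] <- FALSE
  a4[single] <- FALSE; a5[single] <- FALSE
  a1[single] <- TRUE

  virsorter <- ifelse(a1, hi_score(cfg$virsorter_min, TRUE),
                      lo_score(cfg$virsorter_min))
  virfinder <- ifelse(a2, hi_score(cfg$virfinder_min, FALSE),
                      lo_score(cfg$virfinder_min))
  pprmeta <- ifelse(a3, hi_score(cfg$pprmeta_min, FALSE),
                    lo_score(cfg$pprmeta_min))
  ref_id <- ifelse(a4, stats::runif(n, cfg$refseq_min_identity + 10, 99),
                   stats::runif(n, 5, cfg$refseq_min_identity - 10))
  ref_cov <- ifelse(a4, stats::runif(n, cfg$refseq_min_coverage + 1, 99),
                    stats::runif(n, 5, cfg$refseq_min_coverage - 20))
  need_orfs <- pmax(cfg$pog_min_orfs,
                    ceiling(cfg$pog_min_per_10kb * genomes$length / 10000))
  pog <- ifelse(a5, need_orfs + sample.int(4L, n, replace = TRUE) - 1L, 0L)

  hq <- is_viral & (stats::runif(n) < frac_hq)
  hq[single] <- TRUE                    # rescue route must stay open
  completeness <- ifelse(hq,
                         stats::runif(n, cfg$checkv_hq_completeness, 100),
                         stats::runif(n, 5,
                                      cfg$checkv_hq_completeness - 10))
  data.frame(contig_id = genomes$id,
             virsorter_score = round(virsorter, 4),
             virfinder_score = round(virfinder, 4),
             pprmeta_score = round(pprmeta, 4),
             refseq_hit_identity = ifelse(a4 | stats::runif(n) < 0.8,
                                          round(ref_id, 2), NA_real_),
             refseq_hit_coverage = ifelse(a4 | stats::runif(n) < 0.8,
                                          round(ref_cov, 2), NA_real_),
             pog_hit_orfs = pog,
             checkv_completeness = round(completeness, 2),
             checkv_quality = ifelse(hq, "High-quality",
                                     "Medium-quality"),
             stringsAsFactors = FALSE)
}

#' Simulate bacterial hosts, CRISPR spacers, tRNAs and a taxonomy
#'
#' Each planted virus-host link copies the requested number of exact
#' spacers (25-45 bp) and/or tRNA genes (70-90 bp) from the virus into the
#' host species' records; optionally a short (< 20 bp) spacer exercising
#' the low-confidence path. Host genomes are random sequence, two of which
#' carry a planted prophage (a copy of a viral segment) with its interval
#' recorded. The taxonomy is a balanced binary-collapsing tree over all
#' seven ranks.
#'
#' @param viruses contig data.frame of viral genomes.
#' @param n_species number of bacterial species (>= 1).
#' @param seed RNG seed.
#' @param links optional data.frame (`virus_id`, `species_idx`,
#'   `n_spacers`, `n_trnas`, `short_spacer`); a default plan covering all
#'   five evidence patterns is generated when `NULL`.
#' @param cfg pipeline configuration.
#' @param host_len bacterial genome length (bp).
#' @return list: `hosts` (contig data.frame), `prophages`
#'   (`prophage_intervals` table), `spacers`, `viral_trnas`, `host_trnas`
#'   (data.frames), `taxonomy` (taxonomy table), `links` (truth table with
#'   `expected_confidence`).
#' @export
gen_hosts <- function(viruses, n_species, seed = 1, links = NULL,
                      cfg = pipeline_config(), host_len = 4000) {
  stopifnot(n_species >= 1)
  set.seed(seed)
  species <- sprintf("SP%02d", seq_len(n_species))
  hosts <- do.call(rbind, lapply(seq_len(n_species), function(k) {
    gen_genome(host_len, 0.45, seed = seed + 1000L + k, id = species[k])
  }))
  # plant prophages in the first two species (copies of viral segments)
  prophages <- data.frame(genome_id = character(), start = integer(),
                          end = integer(), stringsAsFactors = FALSE)
  for (k in seq_len(min(2L, n_species, nrow(viruses)))) {
    vseq <- viruses$sequence[k]
    frag_len <- min(1000L, nchar(vseq))
    frag <- substr(vseq, 1L, frag_len)
    pos <- 500L
    hseq <- hosts$sequence[k]
    hosts$sequence[k] <- paste0(substr(hseq, 1L, pos), frag,
                                substr(hseq, pos + 1L, nchar(hseq)))
    hosts$length[k] <- nchar(hosts$sequence[k])
    prophages <- rbind(prophages,
                       data.frame(genome_id = species[k], start = pos,
                                  end = pos + frag_len,
                                  stringsAsFactors = FALSE))
  }
  if (is.null(links)) {
    patterns <- data.frame(n_spacers = c(2L, 0L, 1L, 1L, 0L),
                           n_trnas = c(0L, 2L, 1L, 0L, 0L),
                           short_spacer = c(FALSE, FALSE, FALSE, FALSE,
                                            TRUE))
    n_links <- min(nrow(viruses), n_species)
    links <- data.frame(
      virus_id = viruses$id[seq_len(n_links)],
      species_idx = seq_len(n_links),
      patterns[rep(seq_len(5L), length.out = n_links), ],
      stringsAsFactors = FALSE)
  }
  spacers <- list(); viral_trnas <- list(); host_trnas <- list()
  sp_n <- 0L; tr_n <- 0L
  for (i in seq_len(nrow(links))) {
    v <- links$virus_id[i]
    vseq <- viruses$sequence[viruses$id == v]
    sp_id <- species[links$species_idx[i]]
    for (j in seq_len(links$n_spacers[i])) {
      sp_n <- sp_n + 1L
      len <- sample(25:45, 1L)
      # draw each spacer from its own quarter so multiple spacers of one
      # link are guaranteed distinct sequences
      quarter <- nchar(vseq) %/% 4L
      pos <- sample.int(max(quarter - len, 1L), 1L) + (j - 1L) * quarter
      spacers[[sp_n]] <- data.frame(
        id = sprintf("spacer%04d", sp_n),
        sequence = substr(vseq, pos, pos + len - 1L),
        host_species_id = sp_id, stringsAsFactors = FALSE)
    }
    if (isTRUE(links$short_spacer[i])) {
      sp_n <- sp_n + 1L
      len <- sample(16:(cfg$spacer_min_len - 1L), 1L)
      pos <- sample.int(nchar(vseq) - len, 1L)
      spacers[[sp_n]] <- data.frame(
        id = sprintf("spacer%04d", sp_n),
        sequence = substr(vseq, pos, pos + len - 1L),
        host_species_id = sp_id, stringsAsFactors = FALSE)
    }
    for (j in seq_len(links$n_trnas[i])) {
      tr_n <- tr_n + 1L
      len <- sample(70:90, 1L)
      pos <- sample.int(nchar(vseq) - len, 1L)
      gene <- substr(vseq, pos, pos + len - 1L)
      viral_trnas[[tr_n]] <- data.frame(
        id = sprintf("vtrna%04d", tr_n), virus_id = v, sequence = gene,
        stringsAsFactors = FALSE)
      host_trnas[[tr_n]] <- data.frame(
        id = sprintf("htrna%04d", tr_n), host_species_id = sp_id,
        sequence = gene, stringsAsFactors = FALSE)
    }
  }
  bindl <- function(x, proto) if (length(x)) do.call(rbind, x) else proto
  links$expected_confidence <- ifelse(
    links$n_spacers >= 2L | links$n_trnas >= 2L |
      (links$n_spacers >= 1L & links$n_trnas >= 1L), "high",
    ifelse(links$n_spacers + links$n_trnas >= 1L |
             links$short_spacer, "low", "none"))
  list(hosts = hosts, prophages = prophages,
       spacers = bindl(spacers,
                       data.frame(id = character(), sequence = character(),
                                  host_species_id = character(),
                                  stringsAsFactors = FALSE)),
       viral_trnas = bindl(viral_trnas,
                           data.frame(id = character(),
                                      virus_id = character(),
                                      sequence = character(),
                                      stringsAsFactors = FALSE)),
       host_trnas = bindl(host_trnas,
                          data.frame(id = character(),
                                     host_species_id = character(),
                                     sequence = character(),
                                     stringsAsFactors = FALSE)),
       taxonomy = balanced_taxonomy(species),
       links = links)
}

# Balanced taxonomy over all seven ranks: counts halve toward the root.
balanced_taxonomy <- function(species) {
  ranks <- c("species", "genus", "family", "order", "class", "phylum",
             "domain")
  nodes <- list()
  current <- species
  cur_rank <- "species"
  for (level in 2:7) {
    n_par <- max(1L, ceiling(length(current) / 2))
    if (level == 7L) n_par <- 1L
    prefix <- c("g", "f", "o", "c", "p", "d")[level - 1L]
    parents <- sprintf("%s%02d", prefix, seq_len(n_par))
    par_of <- parents[ceiling(seq_along(current) / 2)]
    if (level == 7L) par_of <- rep(parents[1], length(current))
    nodes[[length(nodes) + 1L]] <- data.frame(
      node_id = current, parent_id = par_of, rank = cur_rank,
      name = current, stringsAsFactors = FALSE)
    current <- parents
    cur_rank <- ranks[level]
  }
  nodes[[length(nodes) + 1L]] <- data.frame(
    node_id = current, parent_id = NA_character_, rank = "domain",
    name = current, stringsAsFactors = FALSE)
  do.call(rbind, nodes)
}
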