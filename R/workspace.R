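#' Simulate a complete pipeline workspace with known ground truth
#'
#' Builds everything the pipeline consumes — contigs (clustered viral
#' genomes with planted circularity, assembly sources, a long crAss-like
#' genome, non-viral contigs, a bacterial contaminant, sub-5-kb fragments),
#' detector evidence, read placements, novelty references, bacterial hosts
#' with spacers/tRNAs/taxonomy, lifestyle scores and a protein COG table —
#' and writes the planted truth beside it.
#'
#' Cluster founders are the longest members of their clusters, so the
#' dereplication representative of each planted cluster is its founder.
#' Founder/member assembly sources rotate through five patterns covering
#' the three source groups; every third founder has an exact or 75\%-mosaic
#' relative in the reference catalogues (novelty classes identical /
#' partial / novel).
#'
#' @param dir workspace directory (created).
#' @param n_genomes total viral genomes including cluster members
#'   (>= 6).
#' @param n_samples number of samples.
#' @param seed master RNG seed; all content derives from it.
#' @param cfg pipeline configuration.
#' @param with_crass include a >70 kb crAss-like genome.
#' @return invisibly, a list of truth tables (`truth`, `links`,
#'   `presence`).
#' @export
simulate_workspace <- function(dir, n_genomes = 60, n_samples = 5,
                               seed = 1, cfg = pipeline_config(),
                               with_crass = TRUE) {
  stopifnot(n_genomes >= 6)
  set.seed(seed)
  sub_seeds <- sample.int(2^31 - 2, 400)
  si <- 0L
  next_seed <- function() {
    si <<- si + 1L
    sub_seeds[si]
  }
  for (d in c("inputs", "inputs/references", "inputs/hosts", "truth")) {
    dir.create(file.path(dir, d), showWarnings = FALSE, recursive = TRUE)
  }
  samples <- sprintf("S%02d", seq_len(n_samples))

  n_clusters <- max(2L, round(n_genomes / 3))
  n_members <- n_genomes - n_clusters
  # five source patterns: founder source, member source, expected group
  pat_founder <- c("long", "hybrid", "short", "long", "short")
  pat_member <- c("long", "short", "short", "short", "hybrid")

  founders <- list(); members <- list(); truth_rows <- list()
  circular_ids <- character(0)
  member_of <- rep(seq_len(n_clusters),
                   length.out = n_members)       # round-robin allocation
  for (ci in seq_len(n_clusters)) {
    len <- sample(6000:12000, 1L)
    fid <- sprintf("V%03d", ci)
    base <- gen_genome(len, gc = stats::runif(1, 0.38, 0.52),
                       seed = next_seed(), id = fid)
    p <- ((ci - 1L) %% 5L) + 1L
    is_tr_circ <- ci %% 4L == 1L
    is_read_circ <- !is_tr_circ && ci %% 7L == 3L
    if (is_tr_circ) {
      base <- make_circular(base, tr_len = sample(35:80, 1L), id = fid)
    }
    if (is_tr_circ || is_read_circ) circular_ids <- c(circular_ids, fid)
    base$sample_id <- samples[((ci - 1L) %% n_samples) + 1L]
    base$assembly_source <- pat_founder[p]
    founders[[ci]] <- base
    n_mem_ci <- sum(member_of == ci)
    has_short_member <- n_mem_ci > 0L && pat_member[p] == "short"
    has_long_member <- n_mem_ci > 0L && pat_member[p] %in%
      c("long", "hybrid")
    group <- if (pat_founder[p] %in% c("long", "hybrid")) {
      if (has_short_member) "both" else "long_read"
    } else {
      if (has_long_member) "both" else "short_read"
    }
    truth_rows[[length(truth_rows) + 1L]] <- data.frame(
      genome_id = fid, is_viral = TRUE,
      is_circular = is_tr_circ || is_read_circ, source_group = group,
      cluster_id = sprintf("clust%03d", ci), divergence = 0,
      lifestyle_score = NA_real_, decontam_expected = FALSE,
      role = "founder", stringsAsFactors = FALSE)
  }
  for (mi in seq_len(n_members)) {
    ci <- member_of[mi]
    founder <- founders[[ci]]
    mid <- sprintf("V%03dm%02d", ci, sum(member_of[seq_len(mi)] == ci))
    div <- stats::runif(1, 0.01, 0.03)
    mut <- mutate_genome(founder$sequence, div, seed = next_seed(),
                         id = mid)
    # members are shorter than their founder so the founder stays the
    # dereplication representative
    cut <- 200L * sum(member_of[seq_len(mi)] == ci)
    mut$sequence <- substr(mut$sequence, 1L, mut$length - cut)
    mut$length <- nchar(mut$sequence)
    p <- ((ci - 1L) %% 5L) + 1L
    mut$sample_id <- samples[(mi %% n_samples) + 1L]
    mut$assembly_source <- pat_member[p]
    members[[mi]] <- mut
    truth_rows[[length(truth_rows) + 1L]] <- data.frame(
      genome_id = mid, is_viral = TRUE, is_circular = FALSE,
      source_group = NA_character_, cluster_id = sprintf("clust%03d", ci),
      divergence = div, lifestyle_score = NA_real_,
      decontam_expected = FALSE, role = "member",
      stringsAsFactors = FALSE)
  }
  viral <- rbind(do.call(rbind, founders), do.call(rbind, members))

  if (with_crass) {
    crass <- gen_genome(72000, gc = 0.35, seed = next_seed(),
                        id = "CRASS01")
    crass$sample_id <- samples[1]
    crass$assembly_source <- "long"
    viral <- rbind(viral, crass)
    truth_rows[[length(truth_rows) + 1L]] <- data.frame(
      genome_id = "CRASS01", is_viral = TRUE, is_circular = FALSE,
      source_group = "long_read", cluster_id = "clust_crass",
      divergence = 0, lifestyle_score = NA_real_,
      decontam_expected = FALSE, role = "founder",
      stringsAsFactors = FALSE)
  }

  # hosts, spacers, tRNAs, taxonomy (links planted on founders = reps)
  founders_df <- do.call(rbind, founders)
  hostpack <- gen_hosts(founders_df, n_species = 6, seed = next_seed(),
                        cfg = cfg, host_len = 8000)

  # non-viral contigs: random background + one bacterial contaminant that
  # detectors mistake for a virus (removed by decontamination)
  n_nonviral <- max(3L, round(n_genomes * 0.12))
  nonviral <- do.call(rbind, lapply(seq_len(n_nonviral), function(k) {
    g <- gen_genome(sample(6000:9000, 1L), 0.45, seed = next_seed(),
                    id = sprintf("NV%02d", k))
    g$sample_id <- samples[(k %% n_samples) + 1L]
    g$assembly_source <- "short"
    g
  }))
  host1 <- hostpack$hosts$sequence[3]    # species without a prophage
  contam_seq <- mutate_genome(substr(host1, 1L, 6000), 0.01,
                              seed = next_seed())$sequence
  contam <- data.frame(id = "CONTAM01", sequence = contam_seq,
                       sample_id = samples[1], assembly_source = "short",
                       length = nchar(contam_seq),
                       stringsAsFactors = FALSE)
  shorts <- do.call(rbind, lapply(1:2, function(k) {
    g <- gen_genome(3000, 0.45, seed = next_seed(),
                    id = sprintf("SHORT%02d", k))
    g$sample_id <- samples[1]
    g$assembly_source <- "short"
    g
  }))
  for (df in list(nonviral, contam, shorts)) {
    for (k in seq_len(nrow(df))) {
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        genome_id = df$id[k], is_viral = FALSE, is_circular = FALSE,
        source_group = NA_character_, cluster_id = NA_character_,
        divergence = NA_real_, lifestyle_score = NA_real_,
        decontam_expected = df$id[k] == "CONTAM01",
        role = if (grepl("^SHORT", df$id[k])) "short_fragment" else
          "nonviral", stringsAsFactors = FALSE)
    }
  }
  contigs <- rbind(viral, nonviral, contam, shorts)
  truth <- do.call(rbind, truth_rows)

  # detector evidence: noise 0; contaminant and short fragments look viral
  looks_viral <- truth$is_viral[match(contigs$id, truth$genome_id)] |
    contigs$id == "CONTAM01" | grepl("^SHORT", contigs$id)
  evidence <- gen_evidence(contigs, looks_viral, noise = 0,
                           seed = next_seed(), frac_hq = 0.3,
                           single_criterion_frac = 0.1, cfg = cfg)

  # lifestyle scores clear of the bin boundaries
  set.seed(next_seed())
  bins <- matrix(c(0.05, 0.28, 0.32, 0.48, 0.52, 0.68, 0.72, 0.95),
                 ncol = 2, byrow = TRUE)
  pick <- sample.int(4L, nrow(contigs), replace = TRUE)
  scores <- round(stats::runif(nrow(contigs), bins[pick, 1],
                               bins[pick, 2]), 4)
  truth$lifestyle_score <- scores[match(truth$genome_id, contigs$id)]

  # community placements
  comm <- gen_community(contigs, n_samples, seed = next_seed(),
                        circular_ids = circular_ids, cfg = cfg)

  # novelty references: identical / partial(0.75 mosaic) / novel by
  # founder index mod 3; split across two catalogues
  ref_rows <- list()
  for (ci in seq_len(n_clusters)) {
    f <- founders[[ci]]
    if (ci %% 3L == 1L) {
      ref_rows[[length(ref_rows) + 1L]] <- data.frame(
        id = paste0("REF_ID_", f$id), sequence = f$sequence,
        stringsAsFactors = FALSE)
    } else if (ci %% 3L == 2L) {
      bg <- gen_genome(f$length + 100L, 0.45, seed = next_seed())
      mos <- make_mosaic(f$sequence, bg$sequence, 0.75,
                         seed = next_seed(),
                         id = paste0("REF_PART_", f$id))
      ref_rows[[length(ref_rows) + 1L]] <- data.frame(
        id = mos$id, sequence = mos$sequence, stringsAsFactors = FALSE)
    }
  }
  refs <- do.call(rbind, ref_rows)
  refs$sample_id <- NA_character_; refs$assembly_source <- NA_character_
  refs$length <- nchar(refs$sequence)
  half <- seq_len(ceiling(nrow(refs) / 2))
  write_fasta(refs[half, ], file.path(dir, "inputs/references/cat1.fasta"))
  if (nrow(refs) > length(half)) {
    write_fasta(refs[-half, ],
                file.path(dir, "inputs/references/cat2.fasta"))
  }

  # protein COG table over founders (novel founders skew metabolic)
  set.seed(next_seed())
  cats <- c("Carbohydrate metabolism", "Amino acid metabolism",
            "Energy production", "Replication and repair",
            "Transcription", "Cell wall biogenesis", "Defense",
            "Function unknown")
  novel_truth <- vapply(seq_len(n_clusters), function(ci) ci %% 3L == 0L,
                        logical(1))
  cog_rows <- lapply(seq_len(n_clusters), function(ci) {
    n_prot <- sample(8:15, 1L)
    w <- if (novel_truth[ci]) c(3, 3, 3, 1, 1, 1, 1, 2) else
      c(1, 1, 1, 3, 3, 2, 2, 3)
    data.frame(contig_id = founders[[ci]]$id,
               category = sample(cats, n_prot, replace = TRUE,
                                 prob = w / sum(w)),
               stringsAsFactors = FALSE)
  })
  write_tsv(do.call(rbind, cog_rows), file.path(dir, "inputs/cog.tsv"))

  # write inputs
  write_fasta(contigs, file.path(dir, "inputs/contigs.fasta"))
  write_tsv(evidence, file.path(dir, "inputs/evidence.tsv"))
  write_tsv(comm$placements, file.path(dir, "inputs/placements.tsv"))
  write_tsv(data.frame(contig_id = contigs$id, score = scores,
                       stringsAsFactors = FALSE),
            file.path(dir, "inputs/lifestyle.tsv"))
  write_fasta(hostpack$hosts, file.path(dir, "inputs/hosts/bacteria.fasta"))
  write_tsv(hostpack$prophages,
            file.path(dir, "inputs/hosts/prophage_intervals.tsv"),
            comment = "coordinates 0-based half-open")
  sp <- hostpack$spacers
  sp_fa <- data.frame(id = paste0(sp$id, "|host=", sp$host_species_id),
                      sequence = sp$sequence, stringsAsFactors = FALSE)
  write_fasta(sp_fa, file.path(dir, "inputs/hosts/spacers.fasta"))
  vt <- hostpack$viral_trnas
  vt_fa <- data.frame(id = paste0(vt$id, "|virus=", vt$virus_id),
                      sequence = vt$sequence, stringsAsFactors = FALSE)
  write_fasta(vt_fa, file.path(dir, "inputs/hosts/viral_trnas.fasta"))
  ht <- hostpack$host_trnas
  ht_fa <- data.frame(id = paste0(ht$id, "|host=", ht$host_species_id),
                      sequence = ht$sequence, stringsAsFactors = FALSE)
  write_fasta(ht_fa, file.path(dir, "inputs/hosts/host_trnas.fasta"))
  write_tsv(hostpack$taxonomy, file.path(dir, "inputs/taxonomy.tsv"))
  if (with_crass) {
    write_tsv(data.frame(contig_id = "CRASS01", target = "terminase",
                         significant = TRUE, stringsAsFactors = FALSE),
              file.path(dir, "inputs/crass_protein_hits.tsv"))
  }

  # truth
  write_tsv(truth, file.path(dir, "truth/truth.tsv"))
  write_tsv(hostpack$links, file.path(dir, "truth/links.tsv"))
  pres_df <- data.frame(sample_id = rownames(comm$presence),
                        comm$presence * 1L, check.names = FALSE,
                        stringsAsFactors = FALSE)
  write_tsv(pres_df, file.path(dir, "truth/presence.tsv"))
  invisible(list(truth = truth, links = hostpack$links,
                 presence = comm$presence))
}
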