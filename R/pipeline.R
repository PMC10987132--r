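# Workspace layout: inputs/ (contigs, evidence, placements, references,
# hosts, lifestyle, cog), derived/ (per-stage TSVs), catalogue/ (final
# outputs), truth/ (synthetic only), manifest.json.

ws_path <- function(ws, ...) file.path(ws, ...)

config_hash <- function(cfg) {
  flat <- vapply(sort(names(cfg)), function(k) {
    paste0(k, "=", paste(format(cfg[[k]], digits = 15), collapse = ","))
  }, character(1))
  tmp <- tempfile()
  writeLines(flat, tmp)
  on.exit(unlink(tmp))
  unname(tools::md5sum(tmp))
}

read_manifest <- function(ws) {
  p <- ws_path(ws, "manifest.json")
  if (!file.exists(p)) {
    return(list(config_hash = NULL, completed = list()))
  }
  jsonlite::read_json(p)
}

write_manifest <- function(ws, manifest) {
  p <- ws_path(ws, "manifest.json")
  tmp <- paste0(p, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE)
  file.rename(tmp, p)                    # atomic per stage
  invisible(manifest)
}

# Read a FASTA whose headers carry `|key=value` labels.
read_labeled_fasta <- function(path, key) {
  stopifnot(file.exists(path))
  ss <- Biostrings::readBStringSet(path)
  headers <- names(ss)
  ids <- sub("\\|.*$", "", headers)
  pat <- paste0(".*\\|", key, "=([^|[:space:]]+).*")
  labels <- ifelse(grepl(paste0("\\|", key, "="), headers),
                   sub(pat, "\\1", headers), NA_character_)
  data.frame(id = ids, sequence = toupper(as.character(ss)),
             label = labels, stringsAsFactors = FALSE)
}

pipeline_stages <- c("identify", "derep", "novelty", "cluster", "clades",
                     "quantify", "lifestyle", "hosts", "report")

stage_prereqs <- list(
  identify = character(0),
  derep = "identify",
  novelty = "derep",
  cluster = "derep",
  clades = "cluster",
  quantify = "cluster",
  lifestyle = c("novelty", "quantify"),
  hosts = c("cluster", "lifestyle"),
  report = c("novelty", "clades", "quantify", "lifestyle", "hosts")
)

#' Run the catalogue pipeline over a workspace
#'
#' Executes, in order: identify (viral calling + circularity +
#' decontamination + length filter), derep (dereplication + source
#' groups), novelty, cluster (homology graph + MCL), clades (crAssphage /
#' labelled-reference co-clustering), quantify (coverage, presence, RPKM,
#' abundance, diversity, rarefaction), lifestyle (+ COG enrichment), hosts
#' (spacer/tRNA matching, LCA ranges, network), report. Completed stages
#' are skipped unless `force`; outputs are deterministic for fixed inputs
#' and config.
#'
#' @param ws workspace directory.
#' @param cfg pipeline configuration.
#' @param stages character vector of stages to run (`"all"` for the full
#'   ordered set; prerequisites must already be complete).
#' @param force rerun stages already recorded in the manifest, and accept a
#'   config-hash mismatch.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(ws, cfg = pipeline_config(), stages = "all",
                         force = FALSE) {
  if (identical(stages, "all")) stages <- pipeline_stages
  bad <- setdiff(stages, pipeline_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stages <- pipeline_stages[pipeline_stages %in% stages]
  manifest <- read_manifest(ws)
  h <- config_hash(cfg)
  if (!is.null(manifest$config_hash) &&
      !identical(manifest$config_hash, h)) {
    if (!force) {
      stop("config hash mismatch with manifest; use force = TRUE to rerun")
    }
    manifest$completed <- list()
  }
  manifest$config_hash <- h
  dir.create(ws_path(ws, "derived"), showWarnings = FALSE, recursive = TRUE)
  dir.create(ws_path(ws, "catalogue"), showWarnings = FALSE)
  runners <- list(identify = stage_identify, derep = stage_derep,
                  novelty = stage_novelty, cluster = stage_cluster,
                  clades = stage_clades, quantify = stage_quantify,
                  lifestyle = stage_lifestyle, hosts = stage_hosts,
                  report = stage_report)
  for (st in stages) {
    done <- names(manifest$completed)[vapply(manifest$completed, isTRUE,
                                             logical(1))]
    if (st %in% done && !force) next
    missing_pre <- setdiff(stage_prereqs[[st]], done)
    missing_pre <- missing_pre[!missing_pre %in% stages[
      seq_len(match(st, stages) - 1L)]]
    if (length(missing_pre)) {
      stop("stage '", st, "' requires completed stage(s): ",
           paste(missing_pre, collapse = ", "))
    }
    runners[[st]](ws, cfg)
    manifest$completed[[st]] <- TRUE
    write_manifest(ws, manifest)
  }
  invisible(manifest)
}

load_contigs <- function(ws) read_fasta(ws_path(ws, "inputs/contigs.fasta"))

load_placements <- function(ws) {
  p <- ws_path(ws, "inputs/placements.tsv")
  if (!file.exists(p)) return(NULL)
  read_table(p, "placements")
}

stage_identify <- function(ws, cfg) {
  contigs <- load_contigs(ws)
  evidence <- read_table(ws_path(ws, "inputs/evidence.tsv"), "evidence")
  placements <- load_placements(ws)
  circ <- do.call(rbind, lapply(seq_len(nrow(contigs)), function(i) {
    call_circularity(contigs[i, , drop = FALSE], placements, cfg)
  }))
  write_tsv(circ, ws_path(ws, "derived/circularity.tsv"))
  bacteria <- NULL; prophages <- NULL
  bp <- ws_path(ws, "inputs/hosts/bacteria.fasta")
  if (file.exists(bp)) {
    bacteria <- read_fasta(bp)
    prophages <- read_table(ws_path(ws, "inputs/hosts/prophage_intervals.tsv"),
                            "prophage_intervals")
  }
  circ_flags <- stats::setNames(circ$is_circular, circ$contig_id)
  calls <- identify_viruses(contigs, evidence, circ_flags, bacteria,
                            prophages, cfg)
  write_tsv(calls, ws_path(ws, "derived/calls.tsv"))
  invisible(NULL)
}

read_derived <- function(ws, name) {
  utils::read.delim(ws_path(ws, paste0("derived/", name, ".tsv")),
                    comment.char = "#", stringsAsFactors = FALSE)
}

candidate_contigs <- function(ws, cfg) {
  contigs <- load_contigs(ws)
  calls <- read_derived(ws, "calls")
  keep_ids <- calls$contig_id[calls$is_virus & !calls$removed_as_bacterial &
                                calls$passed_length]
  length_filter(contigs[contigs$id %in% keep_ids, , drop = FALSE], cfg)
}

stage_derep <- function(ws, cfg) {
  cand <- candidate_contigs(ws, cfg)
  derep <- dereplicate(cand, cfg)
  write_tsv(derep, ws_path(ws, "derived/derep.tsv"))
  reps <- cand[cand$id %in% unique(derep$representative_id), , drop = FALSE]
  reps <- reps[order(-reps$length, reps$id), , drop = FALSE]
  write_fasta(reps, ws_path(ws, "derived/votus.fasta"))
  groups <- do.call(rbind, lapply(seq_len(nrow(reps)), function(i) {
    others <- cand[cand$id != reps$id[i], , drop = FALSE]
    data.frame(contig_id = reps$id[i],
               source_group = assign_source_group(reps[i, , drop = FALSE],
                                                  others, cfg),
               stringsAsFactors = FALSE)
  }))
  write_tsv(groups, ws_path(ws, "derived/groups.tsv"))
  invisible(NULL)
}

load_votus <- function(ws) read_fasta(ws_path(ws, "derived/votus.fasta"))

stage_novelty <- function(ws, cfg) {
  votus <- load_votus(ws)
  ref_dir <- ws_path(ws, "inputs/references")
  ref_files <- list.files(ref_dir, pattern = "\\.fasta$",
                          full.names = TRUE)
  stopifnot(length(ref_files) > 0L)
  refs <- lapply(ref_files, read_fasta)
  names(refs) <- sub("\\.fasta$", "", basename(ref_files))
  novelty <- novelty_vs_catalogues(votus, refs, cfg)
  write_tsv(novelty, ws_path(ws, "derived/novelty.tsv"))
  invisible(NULL)
}

stage_cluster <- function(ws, cfg) {
  votus <- load_votus(ws)
  edges <- build_graph(votus, cfg)
  write_tsv(edges, ws_path(ws, "derived/edges.tsv"))
  clusters <- mcl_cluster(edges, votus$id, cfg = cfg)
  vcs <- rank_and_label(clusters)
  write_tsv(vcs, ws_path(ws, "derived/vcs.tsv"))
  invisible(NULL)
}

stage_clades <- function(ws, cfg) {
  votus <- load_votus(ws)
  hits_path <- ws_path(ws, "inputs/crass_protein_hits.tsv")
  protein_hits <- if (file.exists(hits_path)) {
    utils::read.delim(hits_path, comment.char = "#",
                      stringsAsFactors = FALSE)
  } else NULL
  p_crass_path <- ws_path(ws, "inputs/references/p_crass.fasta")
  p_crass <- if (file.exists(p_crass_path)) {
    read_fasta(p_crass_path)$sequence[1]
  } else NULL
  crass <- do.call(rbind, lapply(seq_len(nrow(votus)), function(i) {
    call_crassphage(votus[i, , drop = FALSE], protein_hits, p_crass, cfg)
  }))
  guba_path <- ws_path(ws, "inputs/clade_refs.fasta")
  crass$is_guba <- FALSE
  if (file.exists(guba_path)) {
    ss <- read_fasta(guba_path)
    headers <- names(Biostrings::readBStringSet(guba_path))
    clade <- ifelse(grepl("clade=", headers),
                    sub(".*clade=([^[:space:]]+).*", "\\1", headers),
                    "reference")
    refs <- data.frame(id = ss$id, sequence = ss$sequence,
                       length = ss$length, clade = clade,
                       stringsAsFactors = FALSE)
    labels <- co_cluster_with_references(votus, refs, cfg)
    guba_ids <- labels$contig_id[labels$clade == "Gubaphage"]
    crass$is_guba <- crass$contig_id %in% guba_ids
  }
  write_tsv(crass, ws_path(ws, "derived/clades.tsv"))
  invisible(NULL)
}

stage_quantify <- function(ws, cfg) {
  votus <- load_votus(ws)
  placements <- load_placements(ws)
  stopifnot(!is.null(placements))
  placements <- placements[placements$contig_id %in% votus$id, ,
                           drop = FALSE]
  lens <- stats::setNames(as.list(votus$length), votus$id)
  cov <- summarize_coverage(placements, lens)
  write_tsv(cov, ws_path(ws, "derived/coverage.tsv"))
  samples <- sort(unique(placements$sample_id))
  mk <- function(col, default = 0) {
    m <- matrix(default, length(samples), nrow(votus),
                dimnames = list(samples, votus$id))
    m[cbind(match(cov$sample_id, samples),
            match(cov$contig_id, votus$id))] <- cov[[col]]
    m
  }
  breadth <- mk("breadth"); depth <- mk("mean_depth")
  reads <- mk("mapped_reads")
  presence <- is_present(breadth, depth, cfg)
  rpkm_mat <- matrix(0, length(samples), nrow(votus),
                     dimnames = list(samples, votus$id))
  for (s in seq_along(samples)) {
    total <- sum(reads[s, ])
    if (total > 0) {
      rpkm_mat[s, ] <- rpkm(reads[s, ], votus$length, total)
    }
  }
  relab <- relative_abundance(rpkm_mat, presence)
  write_matrix <- function(m, name) {
    df <- data.frame(sample_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write_tsv(df, ws_path(ws, paste0("derived/", name, ".tsv")))
  }
  write_matrix(presence * 1L, "presence")
  write_matrix(rpkm_mat, "rpkm")
  write_matrix(relab, "relabund")
  vcs <- read_derived(ws, "vcs")
  vca <- vc_abundance(relab, vcs, presence)
  write_matrix(vca$abundance, "vc_relabund")
  prev <- prevalence(presence)
  write_tsv(data.frame(contig_id = names(prev), prevalence = unname(prev),
                       stringsAsFactors = FALSE),
            ws_path(ws, "derived/prevalence.tsv"))
  shan <- apply(relab, 1L, shannon_index)
  write_tsv(data.frame(sample_id = names(shan), shannon = unname(shan),
                       stringsAsFactors = FALSE),
            ws_path(ws, "derived/diversity.tsv"))
  if (length(samples) >= 2L) {
    bc <- as.matrix(vegan::vegdist(relab[rowSums(relab) > 0, ,
                                         drop = FALSE], method = "bray"))
    write_matrix(bc, "bray_curtis")
  }
  sample_sets <- lapply(samples, function(s) {
    colnames(presence)[presence[s, ]]
  })
  names(sample_sets) <- samples
  rc <- rarefaction_curve(sample_sets, n_resamples = 10, seed = 1)
  write_tsv(rc, ws_path(ws, "derived/rarefaction.tsv"))
  invisible(NULL)
}

stage_lifestyle <- function(ws, cfg) {
  votus <- load_votus(ws)
  scores <- read_table(ws_path(ws, "inputs/lifestyle.tsv"), "lifestyle")
  scores <- scores[scores$contig_id %in% votus$id, , drop = FALSE]
  calls <- data.frame(contig_id = scores$contig_id, score = scores$score,
                      category = classify_lifestyle(scores$score, cfg),
                      stringsAsFactors = FALSE)
  calls <- calls[order(calls$contig_id), , drop = FALSE]
  write_tsv(calls, ws_path(ws, "derived/lifestyle_calls.tsv"))
  cog_path <- ws_path(ws, "inputs/cog.tsv")
  if (file.exists(cog_path)) {
    cog <- read_table(cog_path, "cog")
    novelty <- read_derived(ws, "novelty")
    novel_ids <- novelty$contig_id[novelty$novelty_class == "novel"]
    nv <- table(cog$category[cog$contig_id %in% novel_ids])
    ot <- table(cog$category[!cog$contig_id %in% novel_ids])
    if (length(nv) && length(ot)) {
      enr <- suppressWarnings(
        cog_enrichment(stats::setNames(as.integer(nv), names(nv)),
                       stats::setNames(as.integer(ot), names(ot)), cfg))
      write_tsv(enr, ws_path(ws, "derived/enrichment.tsv"))
    }
  }
  invisible(NULL)
}

stage_hosts <- function(ws, cfg) {
  votus <- load_votus(ws)
  sp <- read_labeled_fasta(ws_path(ws, "inputs/hosts/spacers.fasta"),
                           "host")
  spacers <- data.frame(id = sp$id, sequence = sp$sequence,
                        host_species_id = sp$label,
                        stringsAsFactors = FALSE)
  vt <- read_labeled_fasta(ws_path(ws, "inputs/hosts/viral_trnas.fasta"),
                           "virus")
  viral_trnas <- data.frame(id = vt$id, virus_id = vt$label,
                            sequence = vt$sequence,
                            stringsAsFactors = FALSE)
  viral_trnas <- viral_trnas[viral_trnas$virus_id %in% votus$id, ,
                             drop = FALSE]
  ht <- read_labeled_fasta(ws_path(ws, "inputs/hosts/host_trnas.fasta"),
                           "host")
  host_trnas <- data.frame(id = ht$id, host_species_id = ht$label,
                           sequence = ht$sequence, stringsAsFactors = FALSE)
  taxonomy <- read_table(ws_path(ws, "inputs/taxonomy.tsv"), "taxonomy")
  sp_matches <- match_spacers(spacers, votus, cfg)
  tr_matches <- match_trnas(viral_trnas, host_trnas, cfg)
  evidence <- assign_hosts(sp_matches, tr_matches, cfg)
  write_tsv(evidence, ws_path(ws, "derived/host_evidence.tsv"))
  high <- evidence[evidence$confidence == "high", , drop = FALSE]
  if (nrow(high) > 0L) {
    hr <- host_range(high, taxonomy)
    write_tsv(hr, ws_path(ws, "derived/host_range.tsv"))
  }
  vcs <- read_derived(ws, "vcs")
  lifestyle <- read_derived(ws, "lifestyle_calls")
  net <- export_network(vcs[, c("vc_id", "member_id")], evidence, taxonomy,
                        lifestyle)
  write_tsv(net$edges, ws_path(ws, "derived/network_edges.tsv"))
  write_tsv(net$host_nodes, ws_path(ws, "derived/network_host_nodes.tsv"))
  write_tsv(net$vc_nodes, ws_path(ws, "derived/network_vc_nodes.tsv"))
  # V/T ratio per host genus over high-confidence assignments
  if (nrow(high) > 0L) {
    high$genus <- vapply(high$host_species_id, taxon_ancestor_at_rank,
                         character(1), rank = "genus", taxonomy = taxonomy)
    vt_rows <- lapply(sort(unique(high$genus)), function(g) {
      vids <- unique(high$virus_id[high$genus == g])
      cats <- lifestyle$category[lifestyle$contig_id %in% vids]
      if (length(cats) == 0L) return(NULL)
      r <- vt_ratio(cats, cfg)
      data.frame(host_genus = g, n_viruses = length(vids),
                 vt_ratio = r$ratio, undefined = r$undefined,
                 stringsAsFactors = FALSE)
    })
    vt_rows <- vt_rows[!vapply(vt_rows, is.null, logical(1))]
    if (length(vt_rows)) {
      write_tsv(do.call(rbind, vt_rows),
                ws_path(ws, "derived/vt_ratios.tsv"))
    }
  }
  invisible(NULL)
}

stage_report <- function(ws, cfg) {
  votus <- load_votus(ws)
  circ <- read_derived(ws, "circularity")
  groups <- read_derived(ws, "groups")
  novelty <- read_derived(ws, "novelty")
  vcs <- read_derived(ws, "vcs")
  clades <- read_derived(ws, "clades")
  lifestyle <- read_derived(ws, "lifestyle_calls")
  hosts_path <- ws_path(ws, "derived/host_evidence.tsv")
  host_ev <- if (file.exists(hosts_path)) {
    read_derived(ws, "host_evidence")
  } else NULL
  layers <- list(circularity = circ[circ$contig_id %in% votus$id, ,
                                    drop = FALSE],
                 group = groups, novelty = novelty,
                 vc = vcs[, c("vc_id", "member_id", "size",
                              "is_singleton")],
                 clade = clades, lifestyle = lifestyle)
  if (!is.null(host_ev)) layers$hosts <- host_ev
  names(layers$vc)[2] <- "contig_id"
  write_catalogue(votus, layers, ws_path(ws, "catalogue"))
  n <- nrow(votus)
  circ_v <- circ[circ$contig_id %in% votus$id, , drop = FALSE]
  vir_side <- mean(lifestyle$category %in%
                     c("virulent", "uncertain_virulent"))
  report <- list(
    n_votus = n,
    pct_complete = 100 * mean(circ_v$is_circular),
    pct_long_read = 100 * mean(groups$source_group == "long_read"),
    pct_short_read = 100 * mean(groups$source_group == "short_read"),
    pct_both = 100 * mean(groups$source_group == "both"),
    pct_novel = 100 * mean(novelty$novelty_class == "novel"),
    n_vcs = length(unique(vcs$vc_id)),
    n_nonsingleton_vcs = length(unique(vcs$vc_id[!vcs$is_singleton])),
    n_crass = sum(clades$is_crass),
    pct_virulent_side = 100 * vir_side,
    pct_temperate_side = 100 * (1 - vir_side),
    n_host_assignments = if (is.null(host_ev)) 0L else nrow(host_ev),
    n_high_confidence_hosts = if (is.null(host_ev)) 0L else {
      sum(host_ev$confidence == "high")
    }
  )
  jsonlite::write_json(report, ws_path(ws, "catalogue/report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}
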