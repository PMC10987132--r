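#' Pipeline configuration
#'
#' Every numeric threshold used by the catalogue pipeline, with defaults
#' matching the published gut-virome construction protocol. Override any
#' field by name.
#'
#' @param ... named overrides of individual thresholds.
#' @return A validated list of class `virocat_config`.
#' @details Key fields (units): detector score minima `virsorter_min` (0.7,
#'   inclusive), `virfinder_min` (0.6, exclusive), `pprmeta_min` (0.7,
#'   exclusive); viral RefSeq hit rule `refseq_min_identity` (50%) and
#'   `refseq_min_coverage` (90%), both exclusive; phage-orthologous-group
#'   rule `pog_min_orfs` (3) and `pog_min_per_10kb` (2); completeness rescue
#'   `checkv_hq_completeness` (90%); decontamination `decontam_identity`
#'   (90%) over `decontam_coverage` (50%) of contig length; `min_contig_len`
#'   (5000 bp, exclusive); dereplication `derep_identity` (0.95 global
#'   identity over the shorter sequence); circularity `tr_min_len` (30 bp),
#'   `circ_min_reads` (2), `circ_min_hit` (50 bp), `circ_end_window`
#'   (100 bp); novelty ANI from merged regions at `novelty_hsp_identity`
#'   (95%) and `novelty_hsp_minlen` (500 bp) with class cuts
#'   `novelty_identical` (95%) / `novelty_partial` (70%); viral-cluster
#'   graph `vc_hsp_identity` (90%), `vc_cov_large` (70%), `vc_cov_small`
#'   (90%), `mcl_inflation` (4.0); crAssphage `crass_min_len` (70000 bp),
#'   `crass_nt_identity` (95%), `crass_nt_coverage` (80%); presence
#'   `presence_breadth` (0.5) and `presence_depth` (4x), both exclusive;
#'   `lifestyle_bins` (0.3, 0.5, 0.7); host assignment `spacer_min_len`
#'   (20 bp), `trna_identity` (95%); enrichment `enrich_alpha` (0.001).
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    virsorter_min = 0.7,
    virfinder_min = 0.6,
    pprmeta_min = 0.7,
    refseq_min_identity = 50,
    refseq_min_coverage = 90,
    pog_min_orfs = 3,
    pog_min_per_10kb = 2,
    checkv_hq_completeness = 90,
    decontam_identity = 90,
    decontam_coverage = 50,
    min_contig_len = 5000,
    derep_identity = 0.95,
    tr_min_len = 30,
    circ_min_reads = 2,
    circ_min_hit = 50,
    circ_end_window = 100,
    novelty_hsp_identity = 95,
    novelty_hsp_minlen = 500,
    novelty_identical = 95,
    novelty_partial = 70,
    vc_hsp_identity = 90,
    vc_cov_large = 70,
    vc_cov_small = 90,
    mcl_inflation = 4.0,
    crass_min_len = 70000,
    crass_nt_identity = 95,
    crass_nt_coverage = 80,
    presence_breadth = 0.5,
    presence_depth = 4,
    lifestyle_bins = c(0.3, 0.5, 0.7),
    spacer_min_len = 20,
    trna_identity = 95,
    enrich_alpha = 0.001,
    # HSP engine tuning
    hsp_k = 15,
    hsp_xdrop = 20,
    hsp_match = 1,
    hsp_mismatch = -2,
    hsp_max_seed_hits = 200,
    # behaviour switches
    ani_identity_weighted = FALSE,
    vt_strict_bins = FALSE,
    spacer_max_mismatch = 0
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) {
      stop("unknown config field(s): ", paste(bad, collapse = ", "))
    }
    cfg[names(over)] <- over
  }
  validate_config(cfg)
}

#' Validate a pipeline configuration
#'
#' @param cfg a list as produced by [pipeline_config()].
#' @return The config, invisibly classed, or an error naming the bad field.
#' @export
validate_config <- function(cfg) {
  num_fields <- setdiff(names(cfg),
                        c("lifestyle_bins", "ani_identity_weighted",
                          "vt_strict_bins"))
  for (f in num_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("config field '", f, "' must be a single finite number")
    }
  }
  pos_fields <- c("virsorter_min", "virfinder_min", "pprmeta_min",
                  "refseq_min_identity", "refseq_min_coverage",
                  "pog_min_orfs", "pog_min_per_10kb",
                  "checkv_hq_completeness", "decontam_identity",
                  "decontam_coverage", "min_contig_len", "derep_identity",
                  "tr_min_len", "circ_min_reads", "circ_min_hit",
                  "circ_end_window", "novelty_hsp_identity",
                  "novelty_hsp_minlen", "novelty_identical",
                  "novelty_partial", "vc_hsp_identity", "vc_cov_large",
                  "vc_cov_small", "mcl_inflation", "crass_min_len",
                  "crass_nt_identity", "crass_nt_coverage",
                  "presence_breadth", "presence_depth", "spacer_min_len",
                  "trna_identity", "enrich_alpha")
  for (f in pos_fields) {
    if (cfg[[f]] <= 0) stop("config field '", f, "' must be positive")
  }
  pct_fields <- c("refseq_min_identity", "refseq_min_coverage",
                  "checkv_hq_completeness", "decontam_identity",
                  "decontam_coverage", "novelty_hsp_identity",
                  "novelty_identical", "novelty_partial", "vc_hsp_identity",
                  "vc_cov_large", "vc_cov_small", "crass_nt_identity",
                  "crass_nt_coverage", "trna_identity")
  for (f in pct_fields) {
    if (cfg[[f]] < 0 || cfg[[f]] > 100) {
      stop("config field '", f, "' must be a percentage in [0,100]")
    }
  }
  for (f in c("derep_identity", "presence_breadth")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) {
      stop("config field '", f, "' must be a fraction in [0,1]")
    }
  }
  b <- cfg$lifestyle_bins
  if (!is.numeric(b) || length(b) != 3L || any(!is.finite(b)) ||
      any(diff(b) <= 0)) {
    stop("config field 'lifestyle_bins' must be 3 strictly increasing scores")
  }
  class(cfg) <- "virocat_config"
  cfg
}

#' Load a configuration file
#'
#' Flat `key = value` text file; `#` starts a comment; absent keys keep their
#' defaults. `lifestyle_bins` takes three comma-separated scores.
#'
#' @param path path to the config file, or `NULL` for all defaults.
#' @return A validated `virocat_config`.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) return(pipeline_config())
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  over <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed config line: '", ln, "'")
    key <- trimws(kv[1]); val <- trimws(kv[2])
    parsed <- suppressWarnings(as.numeric(strsplit(val, ",")[[1]]))
    if (anyNA(parsed)) {
      if (val %in% c("TRUE", "FALSE")) {
        parsed <- as.logical(val)
      } else {
        stop("non-numeric value for config key '", key, "': '", val, "'")
      }
    }
    over[[key]] <- parsed
  }
  do.call(pipeline_config, over)
}
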