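#' crAssphage call for one contig
#'
#' A contig is a putative crAssphage when it is longer than 70 kb and either
#' carries a significant protein hit to the prototypical crAssphage
#' polymerase or terminase, or shows >= 95\% nucleotide identity over >=
#' 80\% of its length to the prototypical crAssphage genome. When both
#' routes fire, the protein route is recorded.
#'
#' @param contig single-row contig data.frame.
#' @param protein_hits data.frame with `contig_id`, `target` (one of
#'   `polymerase`, `terminase`) and `significant` (logical); may be `NULL`.
#' @param p_crass prototypical crAssphage genome (sequence string or
#'   single-row contig data.frame); may be `NULL` to skip the nucleotide
#'   route.
#' @param cfg pipeline configuration.
#' @return one-row data.frame: `contig_id`, `is_crass`, `crass_route`.
#' @export
call_crassphage <- function(contig, protein_hits = NULL, p_crass = NULL,
                            cfg = pipeline_config()) {
  route <- "none"
  if (contig$length > cfg$crass_min_len) {
    prot <- FALSE
    if (!is.null(protein_hits) && nrow(protein_hits) > 0L) {
      h <- protein_hits[protein_hits$contig_id == contig$id &
                          protein_hits$target %in%
                          c("polymerase", "terminase") &
                          protein_hits$significant, , drop = FALSE]
      prot <- nrow(h) > 0L
    }
    if (prot) {
      route <- "protein_hit"
    } else if (!is.null(p_crass)) {
      hsps <- find_hsps(contig$sequence, p_crass,
                        min_identity = cfg$crass_nt_identity,
                        min_len = cfg$hsp_k, cfg = cfg)
      regions <- merge_regions(hsps, cfg$crass_nt_identity, cfg$hsp_k)
      cov <- 100 * sum(regions$end - regions$start) / contig$length
      if (cov >= cfg$crass_nt_coverage) route <- "nucleotide_identity"
    }
  }
  data.frame(contig_id = contig$id, is_crass = route != "none",
             crass_route = route, stringsAsFactors = FALSE)
}

#' Six-frame translation
#'
#' Standard genetic code; frames +1..+3 on the given strand and -1..-3 on
#' the reverse complement; stop codons as `*`, codons containing `N` as `X`.
#'
#' @param seq DNA string.
#' @return named character vector of 6 peptides (`F1`,`F2`,`F3`,
#'   `R1`,`R2`,`R3`).
#' @export
six_frame_translate <- function(seq) {
  translate1 <- function(s) {
    n <- floor(nchar(s) / 3)
    if (n == 0L) return("")
    codons <- substring(s, 3 * seq_len(n) - 2, 3 * seq_len(n))
    aa <- GENETIC_CODE_TABLE[codons]
    aa[is.na(aa)] <- "X"
    paste0(aa, collapse = "")
  }
  rc <- cpp_revcomp(seq)
  out <- c(F1 = translate1(seq),
           F2 = translate1(substr(seq, 2, nchar(seq))),
           F3 = translate1(substr(seq, 3, nchar(seq))),
           R1 = translate1(rc),
           R2 = translate1(substr(rc, 2, nchar(rc))),
           R3 = translate1(substr(rc, 3, nchar(rc))))
  out
}

GENETIC_CODE_TABLE <- local({
  code <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(code), names(code))
})

#' Lifestyle category from a virulence score
#'
#' Bins: temperate (score <= 0.3), uncertain_temperate (0.3, 0.5],
#' uncertain_virulent (0.5, 0.7], virulent (> 0.7).
#'
#' @param score numeric vector of virulence scores in [0, 1].
#' @param cfg pipeline configuration (`lifestyle_bins`).
#' @return character vector of categories.
#' @export
classify_lifestyle <- function(score, cfg = pipeline_config()) {
  if (any(is.na(score)) || any(score < 0 | score > 1)) {
    stop("lifestyle score outside [0,1]")
  }
  b <- cfg$lifestyle_bins
  ifelse(score <= b[1], "temperate",
         ifelse(score <= b[2], "uncertain_temperate",
                ifelse(score <= b[3], "uncertain_virulent", "virulent")))
}

#' Virulent-to-temperate ratio
#'
#' Default pools each uncertain bin with its side:
#' (virulent + uncertain_virulent) / (temperate + uncertain_temperate).
#' With `cfg$vt_strict_bins`, only the unambiguous bins are counted.
#'
#' @param categories character vector of lifestyle categories.
#' @param cfg pipeline configuration.
#' @return list with `ratio` (numeric or `NA`) and `undefined` (logical;
#'   `TRUE` when the temperate-side count is zero).
#' @export
vt_ratio <- function(categories, cfg = pipeline_config()) {
  stopifnot(length(categories) >= 1L)
  if (cfg$vt_strict_bins) {
    v <- sum(categories == "virulent")
    t <- sum(categories == "temperate")
  } else {
    v <- sum(categories %in% c("virulent", "uncertain_virulent"))
    t <- sum(categories %in% c("temperate", "uncertain_temperate"))
  }
  if (t == 0L) list(ratio = NA_real_, undefined = TRUE)
  else list(ratio = v / t, undefined = FALSE)
}

#' COG-category enrichment of novel vOTU proteins
#'
#' Per category, a 2x2 Pearson chi-squared test (no continuity correction)
#' of in-category vs not, novel vs other. A category is enriched when p <
#' 0.001 and the novel proportion exceeds the other proportion. Categories
#' with a zero margin are skipped with a warning.
#'
#' @param novel_counts named integer vector: category -> protein count in
#'   novel vOTUs.
#' @param other_counts same, for the comparison set.
#' @param cfg pipeline configuration (`enrich_alpha`).
#' @return data.frame: `category`, `novel_in`, `novel_out`, `other_in`,
#'   `other_out`, `chi2`, `p`, `enriched`.
#' @export
cog_enrichment <- function(novel_counts, other_counts,
                           cfg = pipeline_config()) {
  cats <- union(names(novel_counts), names(other_counts))
  get <- function(v, k) if (k %in% names(v)) v[[k]] else 0
  n_tot <- sum(novel_counts); o_tot <- sum(other_counts)
  rows <- list()
  for (cat in cats) {
    a <- get(novel_counts, cat); b <- n_tot - a
    c_ <- get(other_counts, cat); d <- o_tot - c_
    tab <- matrix(c(a, b, c_, d), nrow = 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      warning("category '", cat, "' has a zero margin; skipped")
      next
    }
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    enriched <- ht$p.value < cfg$enrich_alpha && (a / n_tot) > (c_ / o_tot)
    rows[[length(rows) + 1L]] <- data.frame(
      category = cat, novel_in = a, novel_out = b, other_in = c_,
      other_out = d, chi2 = unname(ht$statistic), p = ht$p.value,
      enriched = enriched, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(category = character(), novel_in = integer(),
                      novel_out = integer(), other_in = integer(),
                      other_out = integer(), chi2 = numeric(),
                      p = numeric(), enriched = logical(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Lifestyle side percentages from category counts
#'
#' Pools the uncertain bins with their side and expresses each side as a
#' percentage of the catalogue size: the virulent side is
#' `virulent + uncertain_virulent`, the temperate side
#' `temperate + uncertain_temperate`.
#'
#' @param counts named numeric vector with entries `temperate`,
#'   `uncertain_temperate`, `uncertain_virulent`, `virulent`.
#' @param n_total catalogue size used as the denominator (defaults to the
#'   sum of the counts).
#' @return list with `virulent_side_pct` and `temperate_side_pct`.
#' @export
lifestyle_summary <- function(counts, n_total = sum(counts)) {
  need <- c("temperate", "uncertain_temperate", "uncertain_virulent",
            "virulent")
  stopifnot(all(need %in% names(counts)), n_total > 0)
  v <- counts[["virulent"]] + counts[["uncertain_virulent"]]
  t <- counts[["temperate"]] + counts[["uncertain_temperate"]]
  list(virulent_side_pct = 100 * v / n_total,
       temperate_side_pct = 100 * t / n_total)
}
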