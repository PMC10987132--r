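#' Evaluate the five viral-calling criteria for one contig
#'
#' C1: VirSorter score >= 0.7; C2: VirFinder score > 0.6; C3: PPR-Meta phage
#' score > 0.7; C4: viral RefSeq hit with > 50\% identity and > 90\%
#' coverage; C5: >= 3 ORFs hitting phage orthologous groups, at a rate of
#' >= 2 per 10 kb of contig length. A missing value never satisfies a
#' criterion.
#'
#' @param e one-row evidence data.frame (see the `evidence` table schema).
#' @param length contig length in bp.
#' @param cfg pipeline configuration.
#' @return character vector, a subset of `c("C1","C2","C3","C4","C5")`.
#' @export
evaluate_criteria <- function(e, length, cfg = pipeline_config()) {
  stopifnot(length > 0)
  ok <- function(x) !is.null(x) && length(x) == 1L && !is.na(x)
  crit <- character(0)
  if (ok(e$virsorter_score) && e$virsorter_score >= cfg$virsorter_min) {
    crit <- c(crit, "C1")
  }
  if (ok(e$virfinder_score) && e$virfinder_score > cfg$virfinder_min) {
    crit <- c(crit, "C2")
  }
  if (ok(e$pprmeta_score) && e$pprmeta_score > cfg$pprmeta_min) {
    crit <- c(crit, "C3")
  }
  if (ok(e$refseq_hit_identity) && ok(e$refseq_hit_coverage) &&
      e$refseq_hit_identity > cfg$refseq_min_identity &&
      e$refseq_hit_coverage > cfg$refseq_min_coverage) {
    crit <- c(crit, "C4")
  }
  if (ok(e$pog_hit_orfs) && e$pog_hit_orfs >= cfg$pog_min_orfs &&
      e$pog_hit_orfs / (length / 10000) >= cfg$pog_min_per_10kb) {
    crit <- c(crit, "C5")
  }
  crit
}

#' The viral-calling decision rule
#'
#' A contig is a virus if it is circular, or satisfies at least two of the
#' five criteria, or satisfies exactly one criterion while CheckV calls it
#' high quality (completeness >= 90\%).
#'
#' @param criteria output of [evaluate_criteria()].
#' @param circular logical circularity flag.
#' @param e one-row evidence data.frame (for `checkv_completeness`).
#' @param cfg pipeline configuration.
#' @return logical.
#' @export
call_virus <- function(criteria, circular, e, cfg = pipeline_config()) {
  if (isTRUE(circular)) return(TRUE)
  n <- length(criteria)
  if (n >= 2L) return(TRUE)
  comp <- e$checkv_completeness
  hq <- length(comp) == 1L && !is.na(comp) &&
    comp >= cfg$checkv_hq_completeness
  n >= 1L && hq
}

#' Excise prophage intervals from a bacterial genome
#'
#' Intervals are 0-based half-open; overlapping intervals are merged before
#' excision and the remaining sequence is concatenated.
#'
#' @param genome single-row contig data.frame or DNA string.
#' @param intervals data.frame with `start`, `end` columns.
#' @return the masked sequence (character string).
#' @export
mask_prophages <- function(genome, intervals) {
  seq <- as_seq(genome)
  n <- nchar(seq)
  if (is.null(intervals) || nrow(intervals) == 0L) return(seq)
  if (any(intervals$start < 0 | intervals$end > n |
          intervals$start >= intervals$end)) {
    stop("prophage interval out of genome bounds [0,", n, ")")
  }
  ir <- IRanges::reduce(IRanges::IRanges(start = intervals$start + 1L,
                                         end = intervals$end))
  keep_parts <- character(0)
  pos <- 1L
  for (i in seq_along(ir)) {
    s <- IRanges::start(ir)[i]; e <- IRanges::end(ir)[i]
    if (s > pos) keep_parts <- c(keep_parts, substr(seq, pos, s - 1L))
    pos <- e + 1L
  }
  if (pos <= n) keep_parts <- c(keep_parts, substr(seq, pos, n))
  paste0(keep_parts, collapse = "")
}

#' Bacterial decontamination decision for one contig
#'
#' Remove a contig when its merged hit regions at >= 90\% identity against
#' the prophage-masked bacterial set cover >= 50\% of its length. Coverage
#' is computed on merged intervals, so the decision is invariant to how a
#' region is split into HSPs.
#'
#' @param contig single-row contig data.frame.
#' @param hits HSP data.frame (query = contig) against the masked set.
#' @param cfg pipeline configuration.
#' @return logical: `TRUE` means remove.
#' @export
decontaminate <- function(contig, hits, cfg = pipeline_config()) {
  if (is.null(hits) || nrow(hits) == 0L) return(FALSE)
  regions <- merge_regions(hits, cfg$decontam_identity, 1L)
  covered <- sum(regions$end - regions$start)
  100 * covered / contig$length >= cfg$decontam_coverage
}

#' Minimum-length filter
#'
#' Keeps contigs strictly longer than `min_contig_len` (default 5 kb),
#' returned sorted by descending length with ties broken by id.
#'
#' @param contigs contig data.frame.
#' @param cfg pipeline configuration.
#' @return filtered, sorted contig data.frame.
#' @export
length_filter <- function(contigs, cfg = pipeline_config()) {
  out <- contigs[contigs$length > cfg$min_contig_len, , drop = FALSE]
  out <- out[order(-out$length, out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full viral-identification stage over a contig table
#'
#' Applies [evaluate_criteria()] and [call_virus()] per contig, the
#' decontamination rule against prophage-masked bacterial genomes, and the
#' length filter, and reports every intermediate flag.
#'
#' @param contigs contig data.frame.
#' @param evidence evidence table (`evidence` schema).
#' @param circular named logical vector of circularity flags (ids matching
#'   contigs; missing ids are treated as not circular).
#' @param bacteria optional contig data.frame of bacterial genomes.
#' @param prophages optional `prophage_intervals` table for `bacteria`.
#' @param cfg pipeline configuration.
#' @return data.frame: `contig_id`, `criteria` (comma-joined), `n_criteria`,
#'   `circular`, `hq_rescue`, `is_virus`, `removed_as_bacterial`,
#'   `passed_length`.
#' @export
identify_viruses <- function(contigs, evidence, circular = NULL,
                             bacteria = NULL, prophages = NULL,
                             cfg = pipeline_config()) {
  masked <- NULL
  if (!is.null(bacteria) && nrow(bacteria) > 0L) {
    masked <- vapply(seq_len(nrow(bacteria)), function(i) {
      iv <- prophages[prophages$genome_id == bacteria$id[i], , drop = FALSE]
      mask_prophages(bacteria$sequence[i], iv)
    }, character(1))
  }
  rows <- lapply(seq_len(nrow(contigs)), function(i) {
    id <- contigs$id[i]
    e <- evidence[evidence$contig_id == id, , drop = FALSE]
    if (nrow(e) == 0L) {
      e <- data.frame(virsorter_score = NA_real_, virfinder_score = NA_real_,
                      pprmeta_score = NA_real_,
                      refseq_hit_identity = NA_real_,
                      refseq_hit_coverage = NA_real_, pog_hit_orfs = 0,
                      checkv_completeness = NA_real_)
    }
    crit <- evaluate_criteria(e[1, , drop = FALSE], contigs$length[i], cfg)
    circ <- isTRUE(unname(circular[id]))
    comp <- e$checkv_completeness[1]
    hq <- !is.na(comp) && comp >= cfg$checkv_hq_completeness
    is_virus <- call_virus(crit, circ, e[1, , drop = FALSE], cfg)
    removed <- FALSE
    if (is_virus && !is.null(masked)) {
      hits_list <- lapply(masked, function(m) {
        find_hsps(contigs$sequence[i], m,
                  min_identity = cfg$decontam_identity,
                  min_len = cfg$hsp_k, cfg = cfg)
      })
      hits <- do.call(rbind, hits_list)
      removed <- decontaminate(contigs[i, , drop = FALSE], hits, cfg)
    }
    data.frame(contig_id = id,
               criteria = paste(crit, collapse = ","),
               n_criteria = length(crit),
               circular = circ,
               hq_rescue = hq && length(crit) == 1L && !circ,
               is_virus = is_virus,
               removed_as_bacterial = removed,
               passed_length = contigs$length[i] > cfg$min_contig_len,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
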