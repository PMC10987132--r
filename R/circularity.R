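#' Detect a terminal repeat
#'
#' A contig assembled from a circular genome carries an exact duplication of
#' its start at its end. The detector reports the maximal length L >=
#' `tr_min_len` (default 30 bp) for which the length-L prefix equals the
#' length-L suffix exactly; repeats containing `N` never match.
#'
#' @param seq DNA string or single-row contig data.frame.
#' @param cfg pipeline configuration.
#' @return list with `tr_detected` (logical) and `tr_length` (bp, 0 when
#'   absent).
#' @export
detect_terminal_repeat <- function(seq, cfg = pipeline_config()) {
  s <- as_seq(seq)
  n <- nchar(s)
  k <- cfg$tr_min_len
  if (n < 2 * k) return(list(tr_detected = FALSE, tr_length = 0L))
  prefix <- substr(s, 1L, k)
  if (grepl("N", prefix, fixed = TRUE)) {
    return(list(tr_detected = FALSE, tr_length = 0L))
  }
  # candidate suffix starts: occurrences of the length-k prefix; suffix of
  # length L starts at n - L + 1, so L = n - p + 1
  hits <- Biostrings::matchPattern(prefix, Biostrings::DNAString(s),
                                   fixed = TRUE)
  starts <- Biostrings::start(hits)
  starts <- starts[starts > 1L]          # L == n would be the whole contig
  for (p in starts) {                    # ascending p = descending L
    L <- n - p + 1L
    if (L < k) next
    cand <- substr(s, p, n)
    if (grepl("N", cand, fixed = TRUE)) next
    if (cand == substr(s, 1L, L)) {
      return(list(tr_detected = TRUE, tr_length = L))
    }
  }
  list(tr_detected = FALSE, tr_length = 0L)
}

#' Junction-spanning read support for circularity
#'
#' Counts reads that align both to the front and to the tail of a contig:
#' one segment of >= `circ_min_hit` bp (50) starting within
#' `circ_end_window` bp (100) of the contig start and another segment of >=
#' 50 bp ending within 100 bp of the contig end, on the same strand.
#'
#' @param contig_id contig identifier.
#' @param contig_len contig length in bp.
#' @param placements read-placement table (`placements` schema; `start`,
#'   `end` 0-based half-open).
#' @param cfg pipeline configuration.
#' @return integer count of supporting reads.
#' @export
read_support_circularity <- function(contig_id, contig_len, placements,
                                     cfg = pipeline_config()) {
  p <- placements[placements$contig_id == contig_id, , drop = FALSE]
  if (nrow(p) == 0L) return(0L)
  p$len <- p$end - p$start
  p <- p[p$len >= cfg$circ_min_hit, , drop = FALSE]
  if (nrow(p) == 0L) return(0L)
  front <- p$start <= cfg$circ_end_window
  tail_ <- (contig_len - p$end) <= cfg$circ_end_window
  n_support <- 0L
  for (rid in unique(p$read_id)) {
    rows <- p$read_id == rid
    for (st in c("+", "-")) {
      sel <- rows & p$strand == st
      if (any(front & sel) && any(tail_ & sel) &&
          !identical(which(front & sel), which(tail_ & sel))) {
        n_support <- n_support + 1L
        break
      }
    }
  }
  n_support
}

#' Combined circularity call
#'
#' A contig is circular when it carries a terminal repeat or when at least
#' `circ_min_reads` (2) junction-spanning reads support the junction.
#'
#' @param contig single-row contig data.frame.
#' @param placements read-placement table (may be `NULL`).
#' @param cfg pipeline configuration.
#' @return one-row data.frame: `contig_id`, `tr_detected`, `tr_length`,
#'   `read_support_count`, `is_circular`, `method` (one of
#'   `terminal_repeat`, `read_support`, `both`, `none`).
#' @export
call_circularity <- function(contig, placements = NULL,
                             cfg = pipeline_config()) {
  tr <- detect_terminal_repeat(contig$sequence, cfg)
  n_reads <- if (is.null(placements)) 0L else {
    read_support_circularity(contig$id, contig$length, placements, cfg)
  }
  by_reads <- n_reads >= cfg$circ_min_reads
  method <- if (tr$tr_detected && by_reads) "both"
  else if (tr$tr_detected) "terminal_repeat"
  else if (by_reads) "read_support"
  else "none"
  data.frame(contig_id = contig$id, tr_detected = tr$tr_detected,
             tr_length = tr$tr_length, read_support_count = n_reads,
             is_circular = tr$tr_detected || by_reads, method = method,
             stringsAsFactors = FALSE)
}
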