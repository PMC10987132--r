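#' Find local alignment segments (HSPs) between two sequences
#'
#' Seed-and-extend search: exact k-mer anchors on both strands followed by
#' ungapped X-drop extension; overlapping segments on the same diagonal are
#' merged. Coordinates are 0-based half-open. `N` never counts as a match.
#'
#' @param query,subject DNA strings (upper-case A/C/G/T/N) or single-row
#'   contig data.frames.
#' @param min_identity minimum percent identity of a reported segment.
#' @param min_len minimum segment length (bp).
#' @param cfg pipeline configuration (engine tuning: seed length `hsp_k`,
#'   X-drop `hsp_xdrop`, match/mismatch scores).
#' @return data.frame of segments sorted by `q_start`: `q_start`, `q_end`,
#'   `s_start`, `s_end`, `identity`, `aligned_len`, `strand`, `score`.
#' @export
find_hsps <- function(query, subject, min_identity = 90, min_len = 100,
                      cfg = pipeline_config()) {
  q <- as_seq(query); s <- as_seq(subject)
  stopifnot(nzchar(q), nzchar(s))
  cpp_find_hsps(q, s, min_identity, as.integer(min_len),
                as.integer(cfg$hsp_k), as.integer(cfg$hsp_xdrop),
                as.integer(cfg$hsp_match), as.integer(cfg$hsp_mismatch),
                as.integer(cfg$hsp_max_seed_hits))
}

as_seq <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    return(x$sequence)
  }
  stopifnot(is.character(x), length(x) == 1L)
  x
}

#' Merge qualifying HSPs into disjoint query intervals
#'
#' Filters segments to `identity >= min_identity` and
#' `aligned_len >= min_len`, projects them onto the query and merges
#' overlaps.
#'
#' @param hsps HSP data.frame from [find_hsps()].
#' @param min_identity,min_len filter thresholds (percent, bp).
#' @return data.frame of disjoint sorted intervals (`start`, `end`,
#'   0-based half-open).
#' @export
merge_regions <- function(hsps, min_identity, min_len) {
  keep <- hsps$identity >= min_identity & hsps$aligned_len >= min_len
  hsps <- hsps[keep, , drop = FALSE]
  if (nrow(hsps) == 0L) {
    return(data.frame(start = integer(), end = integer()))
  }
  ir <- IRanges::reduce(IRanges::IRanges(start = hsps$q_start + 1L,
                                         end = hsps$q_end))
  data.frame(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

#' Merged-region average nucleotide identity and novelty class
#'
#' ANI is the percentage of the query covered by merged alignment regions
#' with identity >= 95\% and length >= 500 bp (thresholds from `cfg`).
#' Classes: `identical` (ANI >= 95), `partial` (70 <= ANI < 95), `novel`
#' (ANI < 70). ANI is query-normalized and therefore asymmetric.
#'
#' @param query,subject sequences or single-row contig data.frames.
#' @param cfg pipeline configuration.
#' @return one-row data.frame: `ani`, `merged_coverage`, `n_regions`,
#'   `novelty_class`.
#' @export
compute_ani <- function(query, subject, cfg = pipeline_config()) {
  q <- as_seq(query)
  hsps <- find_hsps(q, subject, min_identity = cfg$novelty_hsp_identity,
                    min_len = min(cfg$novelty_hsp_minlen, nchar(q)),
                    cfg = cfg)
  regions <- merge_regions(hsps, cfg$novelty_hsp_identity,
                           min(cfg$novelty_hsp_minlen, nchar(q)))
  covered <- sum(regions$end - regions$start)
  if (cfg$ani_identity_weighted && nrow(hsps) > 0L) {
    # identity-weighted variant: mean identity of qualifying segments,
    # scaled by merged coverage
    w <- hsps$identity >= cfg$novelty_hsp_identity &
      hsps$aligned_len >= min(cfg$novelty_hsp_minlen, nchar(q))
    mid <- if (any(w)) {
      sum(hsps$identity[w] * hsps$aligned_len[w]) / sum(hsps$aligned_len[w])
    } else 0
    ani <- mid * covered / nchar(q)
  } else {
    ani <- 100 * covered / nchar(q)
  }
  ani <- min(ani, 100)
  data.frame(ani = ani, merged_coverage = covered / nchar(q),
             n_regions = nrow(regions),
             novelty_class = classify_novelty(ani, cfg),
             stringsAsFactors = FALSE)
}

classify_novelty <- function(ani, cfg = pipeline_config()) {
  ifelse(ani >= cfg$novelty_identical, "identical",
         ifelse(ani >= cfg$novelty_partial, "partial", "novel"))
}

#' Global identity between two sequences
#'
#' Matching bases of the best chain of compatible HSPs, divided by the
#' length of the shorter sequence (the CD-HIT notion of global identity).
#'
#' @param a,b sequences or single-row contig data.frames.
#' @param cfg pipeline configuration.
#' @param min_identity HSP-level identity floor used when collecting
#'   segments for the chain.
#' @return percent global identity in [0, 100].
#' @export
global_identity <- function(a, b, cfg = pipeline_config(),
                            min_identity = 80) {
  sa <- as_seq(a); sb <- as_seq(b)
  hsps <- find_hsps(sa, sb, min_identity = min_identity,
                    min_len = cfg$hsp_k, cfg = cfg)
  if (nrow(hsps) == 0L) return(0)
  # chain greedily by score, rejecting overlaps on either sequence
  hsps <- hsps[order(-hsps$score), , drop = FALSE]
  sel <- rep(FALSE, nrow(hsps))
  for (i in seq_len(nrow(hsps))) {
    ok <- TRUE
    for (j in which(sel)) {
      if (hsps$q_start[i] < hsps$q_end[j] && hsps$q_end[i] > hsps$q_start[j]) {
        ok <- FALSE; break
      }
      if (hsps$s_start[i] < hsps$s_end[j] && hsps$s_end[i] > hsps$s_start[j]) {
        ok <- FALSE; break
      }
    }
    if (ok) sel[i] <- TRUE
  }
  matches <- sum(hsps$identity[sel] * hsps$aligned_len[sel] / 100)
  100 * matches / min(nchar(sa), nchar(sb))
}

#' Greedy 95\% dereplication into vOTUs
#'
#' Contigs are visited by descending length (ties by id); each joins the
#' first existing representative to which its global identity is at least
#' `derep_identity`, otherwise it founds a new cluster. The representative
#' is always the longest member.
#'
#' @param contigs contig data.frame with unique `id`s.
#' @param cfg pipeline configuration.
#' @return data.frame with one row per member: `representative_id`,
#'   `member_id`, `identity_to_rep` (100 for the representative itself).
#' @export
dereplicate <- function(contigs, cfg = pipeline_config()) {
  stopifnot(!anyDuplicated(contigs$id))
  ord <- order(-contigs$length, contigs$id)
  contigs <- contigs[ord, , drop = FALSE]
  reps <- integer(0)           # row indices of representatives
  rows <- vector("list", nrow(contigs))
  for (i in seq_len(nrow(contigs))) {
    assigned <- FALSE
    for (r in reps) {
      gid <- global_identity(contigs$sequence[i], contigs$sequence[r],
                             cfg = cfg)
      if (gid >= 100 * cfg$derep_identity) {
        rows[[i]] <- data.frame(representative_id = contigs$id[r],
                                member_id = contigs$id[i],
                                identity_to_rep = gid,
                                stringsAsFactors = FALSE)
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      reps <- c(reps, i)
      rows[[i]] <- data.frame(representative_id = contigs$id[i],
                              member_id = contigs$id[i],
                              identity_to_rep = 100,
                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Assembly-source group of a vOTU
#'
#' A long/hybrid-assembled representative is `long_read` unless some
#' short-read contig anywhere in the workspace (cluster member or discarded)
#' shares >95\% ANI over >50\% of the vOTU length, in which case `both`;
#' symmetrically a short-read representative is `short_read` unless a
#' long/hybrid contig matches by the same rule.
#'
#' @param votu single-row contig data.frame (the representative).
#' @param others contig data.frame of all other contigs in the workspace
#'   with their `assembly_source` labels.
#' @param cfg pipeline configuration.
#' @return one of `"long_read"`, `"short_read"`, `"both"`.
#' @export
assign_source_group <- function(votu, others, cfg = pipeline_config()) {
  src <- votu$assembly_source
  if (!src %in% c("short", "long", "hybrid")) {
    stop("unknown assembly source label: '", src, "'")
  }
  opposite <- if (src == "short") c("long", "hybrid") else "short"
  cand <- others[others$assembly_source %in% opposite, , drop = FALSE]
  matched <- FALSE
  for (i in seq_len(nrow(cand))) {
    hsps <- find_hsps(votu$sequence, cand$sequence[i],
                      min_identity = cfg$novelty_identical,
                      min_len = cfg$hsp_k, cfg = cfg)
    regions <- merge_regions(hsps, cfg$novelty_identical, cfg$hsp_k)
    cov <- sum(regions$end - regions$start) / votu$length
    if (cov > 0.5) { matched <- TRUE; break }
  }
  if (src == "short") {
    if (matched) "both" else "short_read"
  } else {
    if (matched) "both" else "long_read"
  }
}

#' Novelty of vOTUs against reference catalogues
#'
#' Per vOTU, the best (maximum) merged-region ANI over every reference
#' sequence in every catalogue decides the class.
#'
#' @param votus contig data.frame of catalogue representatives.
#' @param references named list of contig data.frames (one per reference
#'   catalogue).
#' @param cfg pipeline configuration.
#' @return data.frame: `contig_id`, `best_ani`, `best_reference`,
#'   `novelty_class`.
#' @export
novelty_vs_catalogues <- function(votus, references,
                                  cfg = pipeline_config()) {
  stopifnot(length(references) > 0L)
  refs <- do.call(rbind, lapply(names(references), function(nm) {
    r <- references[[nm]]
    data.frame(id = r$id, sequence = r$sequence, catalogue = nm,
               stringsAsFactors = FALSE)
  }))
  stopifnot(nrow(refs) > 0L)
  out <- lapply(seq_len(nrow(votus)), function(i) {
    best_ani <- 0; best_ref <- NA_character_
    for (j in seq_len(nrow(refs))) {
      a <- compute_ani(votus$sequence[i], refs$sequence[j], cfg = cfg)
      if (a$ani > best_ani) {
        best_ani <- a$ani
        best_ref <- refs$id[j]
      }
    }
    data.frame(contig_id = votus$id[i], best_ani = best_ani,
               best_reference = best_ref,
               novelty_class = classify_novelty(best_ani, cfg),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
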