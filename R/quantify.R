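#' Per-sample per-contig coverage summaries from read placements
#'
#' Breadth is the fraction of positions covered by at least one read; mean
#' depth is mean per-base coverage over the whole contig; `mapped_reads`
#' counts distinct read ids.
#'
#' @param placements read-placement table (`placements` schema).
#' @param contig_lengths named integer vector (id -> bp).
#' @return `coverage`-schema data.frame, one row per (sample, contig) with
#'   any placements plus zero rows for covered samples x contigs pairs
#'   absent from `placements` are omitted.
#' @export
summarize_coverage <- function(placements, contig_lengths) {
  if (nrow(placements) == 0L) {
    return(data.frame(sample_id = character(), contig_id = character(),
                      breadth = numeric(), mean_depth = numeric(),
                      mapped_reads = integer(), stringsAsFactors = FALSE))
  }
  key <- paste(placements$sample_id, placements$contig_id, sep = "\r")
  rows <- lapply(split(seq_len(nrow(placements)), key), function(ix) {
    p <- placements[ix, , drop = FALSE]
    len <- contig_lengths[[p$contig_id[1]]]
    stopifnot(!is.null(len), all(p$start >= 0), all(p$end <= len))
    ir <- IRanges::IRanges(start = p$start + 1L, end = p$end)
    cov <- IRanges::coverage(ir, width = len)
    covered <- sum(S4Vectors::runLength(cov)[S4Vectors::runValue(cov) > 0])
    depth <- sum(as.numeric(p$end - p$start)) / len
    data.frame(sample_id = p$sample_id[1], contig_id = p$contig_id[1],
               breadth = covered / len, mean_depth = depth,
               mapped_reads = length(unique(p$read_id)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$sample_id, out$contig_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Presence rule
#'
#' A vOTU is present in a sample when more than 50\% of its length is
#' covered and mean depth exceeds 4x (both strict).
#'
#' @param breadth fraction of covered positions.
#' @param mean_depth mean per-base depth (x-fold).
#' @param cfg pipeline configuration.
#' @return logical (vectorized).
#' @export
is_present <- function(breadth, mean_depth, cfg = pipeline_config()) {
  breadth > cfg$presence_breadth & mean_depth > cfg$presence_depth
}

#' Reads per kilobase per million mapped reads
#'
#' @param mapped_reads reads mapped to the contig in the sample.
#' @param length contig length (bp), > 0.
#' @param total_mapped total mapped reads in the sample, > 0.
#' @return RPKM value (vectorized over `mapped_reads`/`length`).
#' @export
rpkm <- function(mapped_reads, length, total_mapped) {
  if (any(total_mapped <= 0)) stop("total mapped reads must be positive")
  stopifnot(all(length > 0))
  mapped_reads / (length / 1000) / (total_mapped / 1e6)
}

#' Relative abundance from an RPKM matrix and presence mask
#'
#' Absent entries are zeroed before normalization; each row with at least
#' one present vOTU then sums to 1, rows with none are all-zero.
#'
#' @param rpkm_mat samples x vOTUs RPKM matrix.
#' @param presence logical matrix of the same shape.
#' @return relative-abundance matrix of the same shape.
#' @export
relative_abundance <- function(rpkm_mat, presence) {
  stopifnot(identical(dim(rpkm_mat), dim(presence)))
  x <- rpkm_mat
  x[!presence] <- 0
  rs <- rowSums(x)
  rs[rs == 0] <- 1
  sweep(x, 1L, rs, "/")
}

#' Viral-cluster abundance
#'
#' Per sample, the abundance of a VC is the sum over its member vOTUs; a VC
#' is present when any member is present.
#'
#' @param abundance samples x vOTUs relative-abundance matrix.
#' @param clusters data.frame with `vc_id`, `member_id`.
#' @param presence optional logical matrix matching `abundance`.
#' @return list with `abundance` (samples x VCs) and `presence` (or `NULL`).
#' @export
vc_abundance <- function(abundance, clusters, presence = NULL) {
  stopifnot(all(clusters$member_id %in% colnames(abundance)))
  vcs <- unique(clusters$vc_id)
  ab <- sapply(vcs, function(vc) {
    mem <- clusters$member_id[clusters$vc_id == vc]
    rowSums(abundance[, mem, drop = FALSE])
  })
  ab <- matrix(ab, nrow = nrow(abundance),
               dimnames = list(rownames(abundance), vcs))
  pr <- NULL
  if (!is.null(presence)) {
    pr <- sapply(vcs, function(vc) {
      mem <- clusters$member_id[clusters$vc_id == vc]
      rowSums(presence[, mem, drop = FALSE]) > 0
    })
    pr <- matrix(pr, nrow = nrow(presence),
                 dimnames = list(rownames(presence), vcs))
  }
  list(abundance = ab, presence = pr)
}

#' Prevalence: fraction of samples where each vOTU is present
#'
#' @param presence samples x vOTUs logical matrix.
#' @return named numeric vector over vOTUs.
#' @export
prevalence <- function(presence) {
  stopifnot(nrow(presence) >= 1L)
  colMeans(presence)
}

#' Shannon diversity (natural log)
#'
#' @param x a vector of nonnegative (relative) abundances.
#' @return Shannon index in nats; 0 when at most one entry is positive.
#' @export
shannon_index <- function(x) {
  stopifnot(all(x >= 0))
  if (sum(x > 0) <= 1L) return(0)
  unname(vegan::diversity(x, index = "shannon"))
}

#' Bray-Curtis dissimilarity between two abundance rows
#'
#' @param a,b nonnegative vectors of equal length, not both all-zero.
#' @return dissimilarity in [0, 1].
#' @export
bray_curtis <- function(a, b) {
  stopifnot(length(a) == length(b), all(a >= 0), all(b >= 0))
  if (sum(a) + sum(b) == 0) stop("Bray-Curtis undefined for two zero rows")
  as.numeric(vegan::vegdist(rbind(a, b), method = "bray"))
}

#' Rarefaction curve of unique vOTU discovery
#'
#' The sample pool is resampled `n_resamples` times (random orderings); for
#' each subset size k the reported value is the mean (and sd) over
#' resamples of the number of unique vOTUs in the union of the first k
#' samples. Prefix unions make each resample's curve, and hence the mean
#' curve, non-decreasing in k.
#'
#' @param sample_sets named list: sample id -> character vector of vOTU ids.
#' @param n_resamples resamples of the pool (default 10).
#' @param seed RNG seed; the curve is deterministic per seed.
#' @return data.frame: `k`, `mean_unique`, `sd_unique`.
#' @export
rarefaction_curve <- function(sample_sets, n_resamples = 10, seed = 1) {
  stopifnot(length(sample_sets) >= 1L)
  n <- length(sample_sets)
  set.seed(seed)
  counts <- matrix(0, nrow = n_resamples, ncol = n)
  for (r in seq_len(n_resamples)) {
    ord <- sample(n)
    seen <- character(0)
    for (k in seq_len(n)) {
      seen <- union(seen, sample_sets[[ord[k]]])
      counts[r, k] <- length(seen)
    }
  }
  data.frame(k = seq_len(n), mean_unique = colMeans(counts),
             sd_unique = apply(counts, 2L, stats::sd))
}
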