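#' Build the filtered genome-homology graph
#'
#' All-vs-all HSP search; per pair, segments at >= 90\% identity (no length
#' floor) are merged on each genome and the pair becomes an edge when the
#' merged coverage exceeds 70\% of the larger genome and 90\% of the smaller
#' genome.
#'
#' @param votus contig data.frame.
#' @param cfg pipeline configuration.
#' @return data.frame of all evaluated pairs: `a_id`, `b_id`,
#'   `cov_on_larger`, `cov_on_smaller`, `passes`.
#' @export
build_graph <- function(votus, cfg = pipeline_config()) {
  stopifnot(nrow(votus) >= 1L)
  n <- nrow(votus)
  rows <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      hsps <- find_hsps(votus$sequence[i], votus$sequence[j],
                        min_identity = cfg$vc_hsp_identity,
                        min_len = cfg$hsp_k, cfg = cfg)
      if (nrow(hsps) == 0L) next
      cov_i <- merged_len(hsps$q_start, hsps$q_end) / votus$length[i]
      cov_j <- merged_len(hsps$s_start, hsps$s_end) / votus$length[j]
      if (votus$length[i] >= votus$length[j]) {
        cl <- 100 * cov_i; cs <- 100 * cov_j
      } else {
        cl <- 100 * cov_j; cs <- 100 * cov_i
      }
      rows[[length(rows) + 1L]] <- data.frame(
        a_id = votus$id[i], b_id = votus$id[j],
        cov_on_larger = cl, cov_on_smaller = cs,
        passes = cl > cfg$vc_cov_large && cs > cfg$vc_cov_small,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(a_id = character(), b_id = character(),
                      cov_on_larger = numeric(), cov_on_smaller = numeric(),
                      passes = logical(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

merged_len <- function(start0, end0) {
  ir <- IRanges::reduce(IRanges::IRanges(start = start0 + 1L, end = end0))
  sum(IRanges::width(ir))
}

#' Markov clustering of the homology graph
#'
#' From-scratch MCL on the undirected graph with unit edge weights and unit
#' self-loops: column-normalize, then iterate expansion (matrix square) and
#' inflation (entrywise power followed by renormalization), pruning entries
#' below 1e-6, until the maximum column change falls below 1e-8 or 200
#' iterations. Clusters are the connected components of the converged
#' matrix's nonzero structure, so every node lands in exactly one cluster.
#' Node ordering is fixed (lexicographic), making the output deterministic.
#'
#' @param edges data.frame with `a_id`, `b_id` and optionally `passes`
#'   (only passing edges are used when present).
#' @param nodes character vector of all node ids (isolated nodes become
#'   singletons).
#' @param inflation inflation exponent (> 1); default from `cfg`.
#' @param cfg pipeline configuration.
#' @param prune,tol,max_iter numeric controls of the iteration.
#' @return list of character vectors, each a cluster's member ids.
#' @export
mcl_cluster <- function(edges, nodes, inflation = NULL,
                        cfg = pipeline_config(), prune = 1e-6, tol = 1e-8,
                        max_iter = 200L) {
  if (is.null(inflation)) inflation <- cfg$mcl_inflation
  stopifnot(inflation > 1)
  nodes <- sort(unique(nodes))
  n <- length(nodes)
  if (!is.null(edges$passes)) edges <- edges[edges$passes, , drop = FALSE]
  M <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(edges) > 0L) {
    ai <- match(edges$a_id, nodes); bi <- match(edges$b_id, nodes)
    if (anyNA(ai) || anyNA(bi)) stop("edge references unknown node id")
    M[cbind(ai, bi)] <- 1
    M[cbind(bi, ai)] <- 1
  }
  diag(M) <- 1
  normalize <- function(X) sweep(X, 2L, colSums(X), "/")
  M <- normalize(M)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M                        # expansion
    M2 <- M2 ^ inflation                 # inflation
    M2[M2 < prune] <- 0
    cs <- colSums(M2)
    cs[cs == 0] <- 1
    M2 <- sweep(M2, 2L, cs, "/")
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("MCL did not converge in ", max_iter,
            " iterations; interpreting current state")
  }
  A <- (M > prune) | (t(M) > prune)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  unname(split(nodes, comp))
}

#' Rank clusters and assign VC labels
#'
#' `VC_1` is the largest cluster; ties are broken by the lexicographically
#' smallest member id. Singletons are labelled but flagged.
#'
#' @param clusters list of member-id vectors from [mcl_cluster()].
#' @return data.frame: `vc_id`, `member_id`, `size`, `is_singleton`.
#' @export
rank_and_label <- function(clusters) {
  if (length(clusters) == 0L) {
    return(data.frame(vc_id = character(), member_id = character(),
                      size = integer(), is_singleton = logical(),
                      stringsAsFactors = FALSE))
  }
  clusters <- lapply(clusters, sort)
  sizes <- lengths(clusters)
  firsts <- vapply(clusters, `[`, character(1), 1L)
  ord <- order(-sizes, firsts)
  rows <- lapply(seq_along(ord), function(k) {
    mem <- clusters[[ord[k]]]
    data.frame(vc_id = paste0("VC_", k), member_id = mem,
               size = length(mem), is_singleton = length(mem) == 1L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Label vOTUs by co-clustering with labelled reference genomes
#'
#' The union of vOTUs and references is clustered with
#' [build_graph()] + [mcl_cluster()]; a vOTU inherits the clade label of any
#' labelled reference sharing its cluster.
#'
#' @param votus contig data.frame.
#' @param refs contig data.frame with an additional `clade` column.
#' @param cfg pipeline configuration.
#' @return data.frame: `contig_id`, `clade` (only labelled vOTUs).
#' @export
co_cluster_with_references <- function(votus, refs,
                                       cfg = pipeline_config()) {
  stopifnot(!is.null(refs$clade))
  all_contigs <- rbind(votus[, c("id", "sequence", "length")],
                       refs[, c("id", "sequence", "length")])
  edges <- build_graph(all_contigs, cfg)
  clusters <- mcl_cluster(edges, all_contigs$id, cfg = cfg)
  out <- list()
  for (cl in clusters) {
    ref_in <- refs[refs$id %in% cl, , drop = FALSE]
    vot_in <- intersect(cl, votus$id)
    if (nrow(ref_in) > 0L && length(vot_in) > 0L) {
      for (clade in unique(ref_in$clade)) {
        out[[length(out) + 1L]] <- data.frame(contig_id = vot_in,
                                              clade = clade,
                                              stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(contig_id = character(), clade = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
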