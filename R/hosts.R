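#' Match CRISPR spacers against vOTU sequences
#'
#' Full-length exact substring match of each spacer or its reverse
#' complement (mismatch tolerance configurable via
#' `cfg$spacer_max_mismatch`). Matches from spacers shorter than
#' `spacer_min_len` (20 bp) are flagged and can only support low-confidence
#' assignments.
#'
#' @param spacers data.frame with `id`, `sequence`, `host_species_id`.
#' @param votus contig data.frame.
#' @param cfg pipeline configuration.
#' @return data.frame: `virus_id`, `host_species_id`, `spacer_id`,
#'   `spacer_seq`, `short_spacer`.
#' @export
match_spacers <- function(spacers, votus, cfg = pipeline_config()) {
  stopifnot(all(nchar(spacers$sequence) >= 10))
  mm <- cfg$spacer_max_mismatch
  rows <- list()
  subjects <- Biostrings::DNAStringSet(votus$sequence)
  for (i in seq_len(nrow(spacers))) {
    sp <- spacers$sequence[i]
    pat <- Biostrings::DNAString(sp)
    n_f <- Biostrings::vcountPattern(pat, subjects, max.mismatch = mm,
                                     fixed = TRUE)
    n_r <- Biostrings::vcountPattern(Biostrings::reverseComplement(pat),
                                     subjects, max.mismatch = mm,
                                     fixed = TRUE)
    hit <- which(n_f + n_r > 0)
    for (j in hit) {
      rows[[length(rows) + 1L]] <- data.frame(
        virus_id = votus$id[j],
        host_species_id = spacers$host_species_id[i],
        spacer_id = spacers$id[i], spacer_seq = sp,
        short_spacer = nchar(sp) < cfg$spacer_min_len,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(virus_id = character(),
                      host_species_id = character(),
                      spacer_id = character(), spacer_seq = character(),
                      short_spacer = logical(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Match viral tRNA genes against bacterial tRNA genes
#'
#' A pair matches when the alignment covers 100\% of the viral tRNA length
#' at >= 95\% identity (ungapped, via the homology engine).
#'
#' @param viral_trnas data.frame with `id`, `virus_id`, `sequence`.
#' @param host_trnas data.frame with `id`, `host_species_id`, `sequence`.
#' @param cfg pipeline configuration.
#' @return data.frame: `virus_id`, `host_species_id`, `viral_trna_id`,
#'   `host_trna_id`, `identity`.
#' @export
match_trnas <- function(viral_trnas, host_trnas, cfg = pipeline_config()) {
  rows <- list()
  for (i in seq_len(nrow(viral_trnas))) {
    vlen <- nchar(viral_trnas$sequence[i])
    for (j in seq_len(nrow(host_trnas))) {
      hsps <- find_hsps(viral_trnas$sequence[i], host_trnas$sequence[j],
                        min_identity = cfg$trna_identity, min_len = vlen,
                        cfg = cfg)
      full <- hsps[hsps$q_start == 0L & hsps$q_end == vlen, , drop = FALSE]
      if (nrow(full) > 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          virus_id = viral_trnas$virus_id[i],
          host_species_id = host_trnas$host_species_id[j],
          viral_trna_id = viral_trnas$id[i],
          host_trna_id = host_trnas$id[j],
          identity = max(full$identity), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(virus_id = character(),
                      host_species_id = character(),
                      viral_trna_id = character(),
                      host_trna_id = character(), identity = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Aggregate spacer and tRNA matches into tiered host assignments
#'
#' Evidence is counted per (virus, host species): distinct qualifying
#' spacer sequences (length >= 20 bp) and distinct host tRNA genes.
#' Confidence is high with >= 2 spacers, >= 2 tRNAs, or >= 1 of each;
#' otherwise low. Short spacers are reported but never qualify.
#'
#' @param spacer_matches output of [match_spacers()] (may be empty).
#' @param trna_matches output of [match_trnas()] (may be empty).
#' @param cfg pipeline configuration.
#' @return data.frame: `virus_id`, `host_species_id`, `n_spacer_matches`,
#'   `n_trna_matches`, `any_short_spacer_only`, `confidence`.
#' @export
assign_hosts <- function(spacer_matches, trna_matches,
                         cfg = pipeline_config()) {
  pairs <- unique(rbind(
    spacer_matches[, c("virus_id", "host_species_id"), drop = FALSE],
    trna_matches[, c("virus_id", "host_species_id"), drop = FALSE]))
  if (nrow(pairs) == 0L) {
    return(data.frame(virus_id = character(),
                      host_species_id = character(),
                      n_spacer_matches = integer(),
                      n_trna_matches = integer(),
                      any_short_spacer_only = logical(),
                      confidence = character(), stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    v <- pairs$virus_id[i]; h <- pairs$host_species_id[i]
    sm <- spacer_matches[spacer_matches$virus_id == v &
                           spacer_matches$host_species_id == h, ,
                         drop = FALSE]
    tm <- trna_matches[trna_matches$virus_id == v &
                         trna_matches$host_species_id == h, , drop = FALSE]
    n_sp <- length(unique(sm$spacer_seq[!sm$short_spacer]))
    n_tr <- length(unique(tm$host_trna_id))
    high <- n_sp >= 2L || n_tr >= 2L || (n_sp >= 1L && n_tr >= 1L)
    data.frame(virus_id = v, host_species_id = h, n_spacer_matches = n_sp,
               n_trna_matches = n_tr,
               any_short_spacer_only = any(sm$short_spacer) && n_sp == 0L &&
                 n_tr == 0L,
               confidence = if (high) "high" else "low",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$virus_id, out$host_species_id), , drop = FALSE]
}

# Walk ancestors of a node up to the root; returns c(node, ..., root).
taxonomy_path <- function(node_id, taxonomy) {
  path <- character(0)
  cur <- node_id
  repeat {
    i <- match(cur, taxonomy$node_id)
    if (is.na(i)) stop("unknown taxonomy node: '", cur, "'")
    path <- c(path, cur)
    parent <- taxonomy$parent_id[i]
    if (is.na(parent) || parent == "" || parent == cur) break
    cur <- parent
  }
  path
}

#' Ancestor of a taxonomy node at a given rank
#'
#' @param node_id node identifier.
#' @param rank target rank (e.g. `"genus"`).
#' @param taxonomy `taxonomy`-schema data.frame.
#' @return node id at the rank, or `NA` if the lineage lacks it.
#' @export
taxon_ancestor_at_rank <- function(node_id, rank, taxonomy) {
  path <- taxonomy_path(node_id, taxonomy)
  ranks <- taxonomy$rank[match(path, taxonomy$node_id)]
  hit <- which(ranks == rank)
  if (length(hit) == 0L) NA_character_ else path[hit[1]]
}

#' LCA host range of each virus
#'
#' For every virus in `evidence`, the last common ancestor of its host
#' species in the taxonomy, and its rank.
#'
#' @param evidence host-assignment data.frame (see [assign_hosts()]);
#'   restrict to high confidence upstream if desired.
#' @param taxonomy `taxonomy`-schema data.frame.
#' @return data.frame: `virus_id`, `lca_node`, `lca_rank`, `n_hosts`.
#' @export
host_range <- function(evidence, taxonomy) {
  viruses <- unique(evidence$virus_id)
  rows <- lapply(viruses, function(v) {
    hosts <- unique(evidence$host_species_id[evidence$virus_id == v])
    paths <- lapply(hosts, taxonomy_path, taxonomy = taxonomy)
    common <- Reduce(intersect, lapply(paths, rev))
    # paths reversed run root -> node, so the LCA is the deepest shared node
    lca <- common[length(common)]
    data.frame(virus_id = v, lca_node = lca,
               lca_rank = taxonomy$rank[match(lca, taxonomy$node_id)],
               n_hosts = length(hosts), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Export the VC-host interaction network
#'
#' Edges connect viral clusters to host genera, deduplicated from
#' high-confidence evidence of member vOTUs. Node attributes carry the host
#' phylum and each VC's majority lifestyle.
#'
#' @param clusters data.frame with `vc_id`, `member_id`.
#' @param evidence host-assignment data.frame.
#' @param taxonomy `taxonomy`-schema data.frame.
#' @param lifestyle optional data.frame with `contig_id`, `category`.
#' @return list with `edges` (`vc_id`, `host_genus`), `host_nodes`
#'   (`host_genus`, `phylum`), `vc_nodes` (`vc_id`, `majority_lifestyle`).
#' @export
export_network <- function(clusters, evidence, taxonomy,
                           lifestyle = NULL) {
  ev <- evidence[evidence$confidence == "high", , drop = FALSE]
  ev <- merge(ev, clusters, by.x = "virus_id", by.y = "member_id")
  if (nrow(ev) == 0L) {
    return(list(edges = data.frame(vc_id = character(),
                                   host_genus = character(),
                                   stringsAsFactors = FALSE),
                host_nodes = data.frame(host_genus = character(),
                                        phylum = character(),
                                        stringsAsFactors = FALSE),
                vc_nodes = data.frame(vc_id = character(),
                                      majority_lifestyle = character(),
                                      stringsAsFactors = FALSE)))
  }
  ev$host_genus <- vapply(ev$host_species_id, taxon_ancestor_at_rank,
                          character(1), rank = "genus",
                          taxonomy = taxonomy)
  edges <- unique(ev[, c("vc_id", "host_genus")])
  edges <- edges[order(edges$vc_id, edges$host_genus), , drop = FALSE]
  rownames(edges) <- NULL
  genera <- unique(edges$host_genus)
  host_nodes <- data.frame(
    host_genus = genera,
    phylum = vapply(genera, taxon_ancestor_at_rank, character(1),
                    rank = "phylum", taxonomy = taxonomy),
    stringsAsFactors = FALSE)
  vc_nodes <- data.frame(vc_id = unique(edges$vc_id),
                         majority_lifestyle = NA_character_,
                         stringsAsFactors = FALSE)
  if (!is.null(lifestyle)) {
    vc_nodes$majority_lifestyle <- vapply(vc_nodes$vc_id, function(vc) {
      mem <- clusters$member_id[clusters$vc_id == vc]
      cats <- lifestyle$category[lifestyle$contig_id %in% mem]
      if (length(cats) == 0L) return(NA_character_)
      tab <- sort(table(cats), decreasing = TRUE)
      names(tab)[1]
    }, character(1))
  }
  list(edges = edges, host_nodes = host_nodes, vc_nodes = vc_nodes)
}
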