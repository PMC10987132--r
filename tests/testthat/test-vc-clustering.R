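test_that("homology edges require coverage 70/90 on larger/smaller", {
  a <- rg(8000, 110, "a")
  # smaller genome ~95% contained, but only 57% of the larger: fails
  small_fail <- data.frame(id = "b",
                           sequence = paste0(substr(a$sequence, 1, 4560),
                                             rg(240, 111)$sequence),
                           sample_id = NA, assembly_source = NA,
                           length = 4800L, stringsAsFactors = FALSE)
  e1 <- build_graph(rbind(a, small_fail))
  expect_false(e1$passes[1])
  expect_lt(e1$cov_on_larger[1], 70)
  expect_gt(e1$cov_on_smaller[1], 90)
  # 76% of the larger, 95% of the smaller: passes
  small_pass <- data.frame(id = "c",
                           sequence = paste0(substr(a$sequence, 1, 6080),
                                             rg(320, 112)$sequence),
                           sample_id = NA, assembly_source = NA,
                           length = 6400L, stringsAsFactors = FALSE)
  e2 <- build_graph(rbind(a, small_pass))
  expect_true(e2$passes[1])
  # identical genomes: 100/100
  a2 <- a; a2$id <- "a2"
  e3 <- build_graph(rbind(a, a2))
  expect_true(e3$passes[1])
  expect_equal(e3$cov_on_larger[1], 100)
})

clique_edges <- function(groups) {
  rows <- list()
  for (g in groups) {
    if (length(g) < 2) next
    cmb <- utils::combn(g, 2)
    rows[[length(rows) + 1L]] <- data.frame(a_id = cmb[1, ],
                                            b_id = cmb[2, ],
                                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

test_that("MCL recovers planted cliques and singletons exactly", {
  groups <- split(sprintf("n%02d", 1:50), rep(1:5, each = 10))
  singles <- c("s1", "s2", "s3")
  cl <- mcl_cluster(clique_edges(groups), c(unlist(groups), singles))
  sizes <- sort(lengths(cl))
  expect_equal(sizes, c(1, 1, 1, 10, 10, 10, 10, 10))
  canon <- lapply(cl, sort)
  for (g in groups) {
    expect_true(any(vapply(canon, identical, logical(1), sort(g))))
  }
  # two disjoint 4-cliques
  g4 <- split(letters[1:8], rep(1:2, each = 4))
  cl4 <- mcl_cluster(clique_edges(g4), letters[1:8])
  expect_equal(sort(lengths(cl4)), c(4, 4))
  # a single edge clusters its two nodes
  one <- mcl_cluster(data.frame(a_id = "x", b_id = "y"), c("x", "y"))
  expect_equal(lengths(one), 2L)
})

test_that("MCL never merges disconnected components", {
  set.seed(113)
  for (rep in 1:20) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    v1 <- sprintf("L%02d", 1:n1); v2 <- sprintf("R%02d", 1:n2)
    re <- function(v) {
      cmb <- utils::combn(v, 2)
      keep <- runif(ncol(cmb)) < 0.6
      data.frame(a_id = cmb[1, keep], b_id = cmb[2, keep],
                 stringsAsFactors = FALSE)
    }
    edges <- rbind(re(v1), re(v2))
    cl <- mcl_cluster(edges, c(v1, v2))
    for (cc in cl) {
      expect_true(all(cc %in% v1) || all(cc %in% v2))
    }
    # partition property: every node in exactly one cluster
    expect_setequal(unlist(cl), c(v1, v2))
    expect_equal(anyDuplicated(unlist(cl)), 0L)
  }
})

test_that("higher inflation never coarsens a noisy two-clique graph", {
  v1 <- sprintf("A%d", 1:6); v2 <- sprintf("B%d", 1:6)
  edges <- clique_edges(list(v1, v2))
  edges <- rbind(edges, data.frame(a_id = "A1", b_id = "B1"),
                 data.frame(a_id = "A2", b_id = "B2"))
  n_low <- length(mcl_cluster(edges, c(v1, v2), inflation = 1.5))
  n_high <- length(mcl_cluster(edges, c(v1, v2), inflation = 6))
  expect_gte(n_high, n_low)
})

test_that("VC labels rank by size with documented tie-breaks", {
  clusters <- list(c("m3", "m1", "m2"), "z9", c("b1", "b2"), "a1",
                   c("a2", "a3"))
  out <- rank_and_label(clusters)
  expect_equal(out$vc_id[out$member_id == "m1"], "VC_1")
  # ties between the two pairs: smallest member id wins
  expect_equal(out$vc_id[out$member_id == "a2"], "VC_2")
  expect_equal(out$vc_id[out$member_id == "b1"], "VC_3")
  expect_equal(sum(out$is_singleton), 2L)
  nonsing <- unique(out$vc_id[!out$is_singleton])
  expect_length(nonsing, 3L)
  all_single <- rank_and_label(list("x", "y"))
  expect_true(all(all_single$is_singleton))
})

test_that("vOTUs inherit clade labels from co-clustered references", {
  v <- rg(8000, 114, "votu1")
  ref <- data.frame(id = "GUBA_REF",
                    sequence = mutate_genome(v$sequence, 0.02,
                                             seed = 115)$sequence,
                    length = 8000L, clade = "Gubaphage",
                    stringsAsFactors = FALSE)
  other <- rg(8000, 116, "votu2")
  labels <- co_cluster_with_references(rbind(v, other), ref)
  expect_equal(labels$contig_id, "votu1")
  expect_equal(labels$clade, "Gubaphage")
  # reference-free and reference-only clusters emit nothing
  none <- co_cluster_with_references(other, ref)
  expect_equal(nrow(none), 0L)
})
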