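test_that("identical sequences give one full-length perfect HSP", {
  g <- rg(600, 90)
  h <- find_hsps(g$sequence, g$sequence, min_identity = 95, min_len = 500)
  fwd <- h[h$strand == "+", ]
  expect_equal(nrow(fwd), 1L)
  expect_equal(fwd$identity, 100)
  expect_equal(fwd$aligned_len, 600L)
  expect_equal(c(fwd$q_start, fwd$q_end), c(0L, 600L))
})

test_that("planted regions match the Smith-Waterman oracle boundaries", {
  set.seed(91)
  for (i in 1:10) {
    a <- rg(280, 910 + i)$sequence
    b <- rg(280, 930 + i)$sequence
    ins <- sample(20:100, 1)
    region <- substr(a, ins + 1, ins + 150)
    region <- mutate_genome(region, 0.02, seed = 950 + i)$sequence
    pos <- sample(10:120, 1)
    b <- paste0(substr(b, 1, pos), region, substr(b, pos + 1, 130))
    hs <- find_hsps(a, b, min_identity = 95, min_len = 100)
    orc <- sw_oracle(a, b, 95, 100)
    expect_false(is.null(orc))
    expect_gte(nrow(hs), 1L)
    best <- hs[which.max(hs$score), ]
    expect_lte(abs(best$q_start - orc$q_start), 5)
    expect_lte(abs(best$q_end - orc$q_end), 5)
  }
  # random pairs: engine and oracle both silent
  for (i in 1:10) {
    a <- rg(1000, 970 + i)$sequence
    b <- rg(1000, 990 + i)$sequence
    expect_equal(nrow(find_hsps(a, b, 95, 500)), 0L)
    expect_null(sw_oracle(a, b, 95, 500))
  }
})

test_that("region merging filters then unions query intervals", {
  hs <- data.frame(q_start = c(100, 600, 2000), q_end = c(700, 1200, 2400),
                   s_start = 0, s_end = 1, identity = c(97, 96, 99),
                   aligned_len = c(600, 600, 400), strand = "+",
                   score = 1)
  out <- merge_regions(hs, 95, 500)
  expect_equal(out, data.frame(start = 100, end = 1200))  # 400 bp dropped
  expect_equal(nrow(merge_regions(hs[0, ], 95, 500)), 0L)
  expect_equal(nrow(merge_regions(hs[3, , drop = FALSE], 95, 500)), 0L)
})

test_that("ANI is 100 against self, bounded, and monotone in regions", {
  g <- rg(3000, 95)
  self <- compute_ani(g, g)
  expect_equal(self$ani, 100)
  expect_equal(self$novelty_class, "identical")
  other <- rg(3000, 96)
  expect_equal(compute_ani(g, other)$ani, 0)
  expect_equal(compute_ani(g, other)$novelty_class, "novel")
  # removing an HSP never increases the merged coverage
  hs <- data.frame(q_start = c(0, 1000), q_end = c(800, 1900),
                   s_start = 0, s_end = 1, identity = 99,
                   aligned_len = c(800, 900), strand = "+", score = 1)
  full <- sum(with(merge_regions(hs, 95, 500), end - start))
  less <- sum(with(merge_regions(hs[1, , drop = FALSE], 95, 500),
                   end - start))
  expect_lte(less, full)
})

test_that("novelty class boundaries sit exactly at 95 and 70", {
  expect_equal(classify_novelty(95.0), "identical")
  expect_equal(classify_novelty(94.999), "partial")
  expect_equal(classify_novelty(70.0), "partial")
  expect_equal(classify_novelty(69.999), "novel")
  expect_equal(classify_novelty(100), "identical")
  expect_equal(classify_novelty(0), "novel")
})

test_that("dereplication merges close mutants and splits distant ones", {
  g <- rg(8000, 97, "parent")
  near <- mutate_genome(g, 0.02, seed = 98, id = "near")
  near$sequence <- substr(near$sequence, 1, 7800)  # shorter member
  near$length <- 7800L
  far <- mutate_genome(g, 0.15, seed = 99, id = "far")
  res <- dereplicate(rbind(g, near, far))
  expect_equal(sort(unique(res$representative_id)), c("far", "parent"))
  expect_equal(res$representative_id[res$member_id == "near"], "parent")
  single <- dereplicate(g)
  expect_equal(single$representative_id, "parent")
  expect_equal(single$identity_to_rep, 100)
})

test_that("source groups follow the cross-technology 95%/50% rule", {
  rep_long <- rg(8000, 100, "repL")
  rep_long$assembly_source <- "hybrid"
  unrelated <- rg(8000, 101, "uns")
  unrelated$assembly_source <- "short"
  expect_equal(assign_source_group(rep_long, unrelated), "long_read")

  short_member <- mutate_genome(rep_long$sequence, 0.02, seed = 102,
                                id = "sm")
  short_member$assembly_source <- "short"
  expect_equal(assign_source_group(rep_long, short_member), "both")

  rep_short <- rg(8000, 103, "repS")
  rep_short$assembly_source <- "short"
  expect_equal(assign_source_group(rep_short, unrelated), "short_read")
  rep_bad <- rep_short
  rep_bad$assembly_source <- "nanopore"
  expect_error(assign_source_group(rep_bad, unrelated), "unknown")
})

test_that("catalogue novelty takes the best ANI across references", {
  v <- rg(6000, 104, "votu")
  bg <- rg(6200, 105)
  refs <- list(
    catA = rbind(make_mosaic(v$sequence, bg$sequence, 0.60, seed = 106,
                             id = "r60"),
                 make_mosaic(v$sequence, bg$sequence, 0.72, seed = 107,
                             id = "r72")),
    catB = make_mosaic(v$sequence, bg$sequence, 0.40, seed = 108,
                       id = "r40"))
  out <- novelty_vs_catalogues(v, refs)
  expect_equal(out$novelty_class, "partial")       # max ANI ~72
  expect_equal(out$best_reference, "r72")

  verbatim <- novelty_vs_catalogues(v, list(cat = v))
  expect_equal(verbatim$novelty_class, "identical")
  lonely <- novelty_vs_catalogues(v, list(cat = rg(6000, 109, "zz")))
  expect_equal(lonely$novelty_class, "novel")
})
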