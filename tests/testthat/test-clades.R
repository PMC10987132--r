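test_that("crAssphage calls need 70 kb plus protein or nucleotide proof", {
  hits <- data.frame(contig_id = c("big", "small"), target = "terminase",
                     significant = TRUE, stringsAsFactors = FALSE)
  big <- rg(80000, 120, "big")
  out <- call_crassphage(big, hits)
  expect_true(out$is_crass)
  expect_equal(out$crass_route, "protein_hit")

  small <- rg(60000, 121, "small")
  expect_false(call_crassphage(small, hits)$is_crass)

  # nucleotide route: ~99% identity over ~85% of the contig
  contig <- rg(75000, 122, "nt")
  bg <- rg(76000, 123)
  p_crass <- make_mosaic(contig$sequence, bg$sequence, 0.85, seed = 124)
  out2 <- call_crassphage(contig, NULL, p_crass$sequence)
  expect_true(out2$is_crass)
  expect_equal(out2$crass_route, "nucleotide_identity")
  # monotone in length at fixed evidence: shorter contig, same hits
  expect_false(call_crassphage(small, NULL, p_crass$sequence)$is_crass)
})

test_that("six-frame translation obeys the code and strand symmetry", {
  expect_equal(unname(six_frame_translate("ATGGCC")["F1"]), "MA")
  expect_equal(unname(six_frame_translate("TTAG")["F2"]), "*")
  g <- rg(300, 125)$sequence
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", g), "")[[1]]),
              collapse = "")
  expect_equal(unname(six_frame_translate(g)["R1"]),
               unname(six_frame_translate(rc)["F1"]))
  n <- 301
  g2 <- rg(n, 126)$sequence
  expect_equal(nchar(six_frame_translate(g2)["F2"]),
               floor((n - 1) / 3), ignore_attr = TRUE)
})

test_that("lifestyle bins partition [0,1] with inclusive boundaries", {
  expect_equal(classify_lifestyle(0.25), "temperate")
  expect_equal(classify_lifestyle(0.30), "temperate")
  expect_equal(classify_lifestyle(0.31), "uncertain_temperate")
  expect_equal(classify_lifestyle(0.50), "uncertain_temperate")
  expect_equal(classify_lifestyle(0.55), "uncertain_virulent")
  expect_equal(classify_lifestyle(0.70), "uncertain_virulent")
  expect_equal(classify_lifestyle(0.90), "virulent")
  expect_error(classify_lifestyle(1.2), "outside")
  set.seed(127)
  scores <- runif(200)
  cats <- classify_lifestyle(scores)
  expect_equal(length(cats), 200L)                # every score mapped once
  expect_equal(sum(table(cats)), 200L)
})

test_that("V/T ratios pool uncertain bins and flag zero denominators", {
  cats <- c(rep("virulent", 3), rep("uncertain_virulent", 2),
            rep("temperate", 1), rep("uncertain_temperate", 1))
  expect_equal(vt_ratio(cats)$ratio, 2.5)
  expect_equal(vt_ratio(rep("temperate", 4))$ratio, 0)
  allv <- vt_ratio(rep("virulent", 4))
  expect_true(allv$undefined)
  expect_true(is.na(allv$ratio))
  strict <- vt_ratio(cats, pipeline_config(vt_strict_bins = TRUE))
  expect_equal(strict$ratio, 3)
})

test_that("chi-squared enrichment matches the closed 2x2 formula", {
  flat <- cog_enrichment(c(X = 50, Y = 50), c(X = 50, Y = 50))
  expect_equal(flat$chi2, c(0, 0), tolerance = 1e-12)
  expect_false(any(flat$enriched))

  closed_chi2 <- function(a, b, c_, d) {
    n <- a + b + c_ + d
    n * (a * d - b * c_)^2 /
      ((a + b) * (c_ + d) * (a + c_) * (b + d))
  }
  set.seed(128)
  for (i in 1:20) {
    a <- sample(5:80, 1); b <- sample(5:80, 1)
    c_ <- sample(5:80, 1); d <- sample(5:80, 1)
    out <- cog_enrichment(c(K = a, other = b), c(K = c_, other = d))
    expect_equal(out$chi2[out$category == "K"], closed_chi2(a, b, c_, d),
                 tolerance = 1e-9)
  }
  # significant depletion is not enrichment
  dep <- cog_enrichment(c(K = 10, other = 90), c(K = 60, other = 40))
  expect_false(dep$enriched[dep$category == "K"])
  expect_lt(dep$p[dep$category == "K"], 0.001)
})

test_that("published category counts give the printed side percentages", {
  counts_file <- system.file("extdata", "published_lifestyle_counts.tsv",
                             package = "virocat")
  counts <- utils::read.delim(counts_file, comment.char = "#")
  counts <- stats::setNames(counts$count, counts$category)
  stats_file <- system.file("extdata", "published_catalogue_stats.tsv",
                            package = "virocat")
  n <- utils::read.delim(stats_file, comment.char = "#")$value[1]
  s <- lifestyle_summary(counts, n)
  expect_equal(round(s$virulent_side_pct, 2), 29.22)
})
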