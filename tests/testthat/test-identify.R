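ev_row <- function(...) {
  base <- data.frame(virsorter_score = NA_real_, virfinder_score = NA_real_,
                     pprmeta_score = NA_real_,
                     refseq_hit_identity = NA_real_,
                     refseq_hit_coverage = NA_real_, pog_hit_orfs = 0L,
                     checkv_completeness = NA_real_,
                     stringsAsFactors = FALSE)
  over <- list(...)
  base[names(over)] <- over
  base
}

test_that("the five criteria follow the printed comparators exactly", {
  cfg <- pipeline_config()
  expect_equal(evaluate_criteria(ev_row(virsorter_score = 0.8), 8000, cfg),
               "C1")
  expect_equal(evaluate_criteria(ev_row(virsorter_score = 0.7), 8000, cfg),
               "C1")                               # >= is inclusive
  expect_length(evaluate_criteria(ev_row(virfinder_score = 0.6), 8000,
                                  cfg), 0L)        # strict >
  expect_equal(evaluate_criteria(ev_row(virfinder_score = 0.61), 8000,
                                 cfg), "C2")
  expect_length(evaluate_criteria(ev_row(pprmeta_score = 0.7), 8000, cfg),
                0L)
  expect_equal(evaluate_criteria(ev_row(refseq_hit_identity = 51,
                                        refseq_hit_coverage = 91),
                                 8000, cfg), "C4")
  expect_length(evaluate_criteria(ev_row(refseq_hit_identity = 51), 8000,
                                  cfg), 0L)        # missing never satisfies
  expect_equal(evaluate_criteria(ev_row(pog_hit_orfs = 4L), 20000, cfg),
               "C5")                               # 4 >= 3 and 4/2 >= 2
  expect_length(evaluate_criteria(ev_row(pog_hit_orfs = 3L), 20000, cfg),
                0L)                                # 3/2 = 1.5 < 2
  expect_length(evaluate_criteria(ev_row(virsorter_score = 0,
                                         virfinder_score = 0,
                                         pprmeta_score = 0), 8000, cfg),
                0L)
})

test_that("the decision rule needs two criteria, circularity or rescue", {
  cfg <- pipeline_config()
  e40 <- ev_row(checkv_completeness = 40)
  expect_true(call_virus(c("C1", "C3"), FALSE, e40, cfg))
  expect_true(call_virus("C2", FALSE, ev_row(checkv_completeness = 92),
                         cfg))
  expect_true(call_virus(character(0), TRUE, e40, cfg))
  expect_false(call_virus("C1", FALSE, ev_row(checkv_completeness = 80),
                          cfg))
  expect_false(call_virus(character(0), FALSE,
                          ev_row(checkv_completeness = 99), cfg))
})

test_that("virus calls are monotone in added evidence", {
  cfg <- pipeline_config()
  set.seed(42)
  for (rep in 1:25) {
    e <- ev_row(virsorter_score = runif(1), virfinder_score = runif(1),
                pprmeta_score = runif(1),
                checkv_completeness = runif(1, 0, 100),
                pog_hit_orfs = sample(0:6, 1))
    len <- sample(6000:20000, 1)
    crit <- evaluate_criteria(e, len, cfg)
    called <- call_virus(crit, FALSE, e, cfg)
    boosted <- e
    boosted$virsorter_score <- 1
    boosted$refseq_hit_identity <- 99
    boosted$refseq_hit_coverage <- 99
    crit2 <- evaluate_criteria(boosted, len, cfg)
    expect_true(all(crit %in% crit2))
    if (called) expect_true(call_virus(crit2, FALSE, boosted, cfg))
  }
})

test_that("prophage masking excises merged intervals", {
  g <- rg(10000, 50)
  one <- mask_prophages(g, data.frame(start = 2000, end = 3000))
  expect_equal(nchar(one), 9000L)
  expect_equal(substr(one, 1, 2000), substr(g$sequence, 1, 2000))
  expect_equal(substr(one, 2001, 2100), substr(g$sequence, 3001, 3100))

  expect_equal(mask_prophages(g, NULL), g$sequence)
  expect_equal(mask_prophages(g, data.frame(start = integer(),
                                            end = integer())),
               g$sequence)

  two <- mask_prophages(g, data.frame(start = c(100, 200),
                                      end = c(300, 400)))
  expect_equal(nchar(two), 10000L - 300L)          # overlaps merged first

  expect_error(mask_prophages(g, data.frame(start = 9000, end = 11000)),
               "bounds")
})

test_that("decontamination thresholds and HSP-split invariance hold", {
  cfg <- pipeline_config()
  contig <- rg(10000, 51)
  hit <- function(qs, qe, id) {
    data.frame(q_start = qs, q_end = qe, s_start = qs, s_end = qe,
               identity = id, aligned_len = qe - qs, strand = "+",
               score = qe - qs)
  }
  expect_true(decontaminate(contig, hit(0, 6000, 92), cfg))    # 60% at 92%
  expect_false(decontaminate(contig, hit(0, 3000, 95), cfg))   # 30% only
  expect_false(decontaminate(contig, NULL, cfg))
  expect_false(decontaminate(contig, hit(0, 6000, 85), cfg))   # identity low

  whole <- hit(0, 6000, 92)
  split <- rbind(hit(0, 2500, 92), hit(2000, 4500, 92), hit(4400, 6000, 92))
  expect_equal(decontaminate(contig, whole, cfg),
               decontaminate(contig, split, cfg))
})

test_that("the length filter is strict at 5 kb and orders output", {
  contigs <- rbind(rg(5001, 60, "keep1"), rg(5000, 61, "drop1"),
                   rg(7000, 62, "keep2"), rg(7000, 63, "keep0"))
  out <- length_filter(contigs)
  expect_equal(out$id, c("keep0", "keep2", "keep1"))
  expect_equal(nrow(length_filter(contigs[0, ])), 0L)
})

test_that("noise-0 synthetic evidence yields perfect calls end to end", {
  genomes <- do.call(rbind, lapply(1:14, function(i) {
    rg(5500 + 123 * i, 70 + i, sprintf("id%02d", i))
  }))
  truth <- rep(c(TRUE, TRUE, FALSE), length.out = 14)
  ev <- gen_evidence(genomes, truth, noise = 0, seed = 8)
  calls <- identify_viruses(genomes, ev)
  expect_equal(calls$is_virus, truth)              # sensitivity = spec = 1
})
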