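test_that("genome generation is deterministic with controlled GC", {
  g1 <- gen_genome(1000, 0.5, seed = 7)
  g2 <- gen_genome(1000, 0.5, seed = 7)
  expect_identical(g1, g2)
  expect_equal(g1$length, 1000L)

  big <- gen_genome(1e5, 0.2, seed = 11)
  gc <- sum(strsplit(big$sequence, "")[[1]] %in% c("G", "C")) / 1e5
  expect_lt(abs(gc - 0.2), 0.01)       # 3-sigma binomial bound ~ 0.004

  expect_error(gen_genome(50), ">= 100")
  expect_error(gen_genome(1000, gc = 1.2), "gc")
})

test_that("mutation realizes the requested divergence, substitution-only", {
  g <- gen_genome(10000, 0.5, seed = 1)
  same <- mutate_genome(g, 0, seed = 2)
  expect_identical(same$sequence, g$sequence)

  mut <- mutate_genome(g, 0.05, seed = 3)
  expect_equal(mut$length, g$length)   # no indels
  mism <- sum(strsplit(g$sequence, "")[[1]] !=
                strsplit(mut$sequence, "")[[1]])
  expect_lt(abs(mism - 500), 70)       # 3-sigma binomial interval

  # a 2%-divergence pair lands in the "identical" novelty class downstream
  mut2 <- mutate_genome(g, 0.02, seed = 4)
  expect_equal(compute_ani(mut2, g)$novelty_class, "identical")
})

test_that("terminal-repeat construction matches its downstream detection", {
  g <- gen_genome(2000, 0.5, seed = 5)
  circ <- make_circular(g, 40)
  expect_equal(circ$length, g$length + 40L)
  expect_equal(substr(circ$sequence, 1, 40),
               substr(circ$sequence, circ$length - 39, circ$length))
  expect_true(detect_terminal_repeat(circ$sequence)$tr_detected)

  small <- make_circular(g, 29)
  expect_false(detect_terminal_repeat(small$sequence)$tr_detected)

  big <- make_circular(g, 100)
  expect_equal(detect_terminal_repeat(big$sequence)$tr_length, 100L)
})

test_that("mosaic sharing drives the novelty class as constructed", {
  donor <- gen_genome(6000, 0.5, seed = 6)
  bg <- gen_genome(6200, 0.5, seed = 7)
  m75 <- make_mosaic(donor, bg, 0.75, seed = 8)
  a75 <- compute_ani(m75, donor)
  expect_equal(a75$novelty_class, "partial")
  expect_lt(abs(a75$ani - 75), 6)

  m98 <- make_mosaic(donor, bg, 0.98, seed = 9)
  expect_equal(compute_ani(m98, donor)$novelty_class, "identical")
  expect_gt(compute_ani(m98, donor)$ani, compute_ani(m75, donor)$ani)
})

test_that("community placements respect presence truth and junctions", {
  genomes <- rbind(rg(6000, 21, "gA"), rg(7000, 22, "gB"),
                   rg(8000, 23, "gC"))
  pres <- matrix(c(TRUE, TRUE, FALSE,
                   TRUE, FALSE, TRUE), nrow = 2, byrow = TRUE,
                 dimnames = list(c("S01", "S02"), genomes$id))
  comm <- gen_community(genomes, 2, seed = 3, circular_ids = "gA",
                        presence = pres)
  lens <- stats::setNames(as.list(genomes$length), genomes$id)
  cov <- summarize_coverage(comm$placements, lens)
  for (i in seq_len(nrow(cov))) {
    expect_equal(
      is_present(cov$breadth[i], cov$mean_depth[i]),
      pres[cov$sample_id[i], cov$contig_id[i]],
      info = paste(cov$sample_id[i], cov$contig_id[i]))
  }
  # junction reads present for the circular genome in both present samples
  expect_gte(read_support_circularity("gA", 6000, comm$placements), 2L)
  # read conservation: every placement row belongs to exactly one contig
  expect_equal(nrow(comm$placements),
               sum(table(comm$placements$contig_id)))
  # determinism
  comm2 <- gen_community(genomes, 2, seed = 3, circular_ids = "gA",
                         presence = pres)
  expect_identical(comm$placements, comm2$placements)
})

test_that("evidence at noise 0 separates viruses perfectly", {
  genomes <- do.call(rbind, lapply(1:10, function(i) {
    rg(6000 + 100 * i, 30 + i, sprintf("e%02d", i))
  }))
  truth <- rep(c(TRUE, FALSE), 5)
  ev <- gen_evidence(genomes, truth, noise = 0, seed = 4)
  cfg <- pipeline_config()
  for (i in seq_len(nrow(ev))) {
    crit <- evaluate_criteria(ev[i, ], genomes$length[i], cfg)
    if (truth[i]) expect_gte(length(crit), 2L) else
      expect_length(crit, 0L)
  }
  expect_identical(ev, gen_evidence(genomes, truth, noise = 0, seed = 4))

  # single-criterion viruses survive through the completeness rescue
  ev1 <- gen_evidence(genomes, truth, noise = 0, seed = 5, frac_hq = 1,
                      single_criterion_frac = 1)
  for (i in which(truth)) {
    crit <- evaluate_criteria(ev1[i, ], genomes$length[i], cfg)
    expect_length(crit, 1L)
    expect_true(call_virus(crit, FALSE, ev1[i, ], cfg))
  }
})

test_that("host generation plants recoverable links and a valid taxonomy", {
  viruses <- do.call(rbind, lapply(1:5, function(i) {
    rg(4000, 40 + i, sprintf("hv%02d", i))
  }))
  hp <- gen_hosts(viruses, n_species = 5, seed = 6)
  tax <- hp$taxonomy
  expect_equal(sum(is.na(tax$parent_id)), 1L)       # single root
  non_root <- tax$parent_id[!is.na(tax$parent_id)]
  expect_true(all(non_root %in% tax$node_id))       # resolvable parents
  expect_setequal(unique(tax$rank),
                  c("species", "genus", "family", "order", "class",
                    "phylum", "domain"))
  # planted spacers are exact substrings of their virus
  for (i in seq_len(nrow(hp$spacers))) {
    li <- hp$links[hp$links$species_idx ==
                     match(hp$spacers$host_species_id[i],
                           sprintf("SP%02d", 1:5)), ]
    expect_true(grepl(hp$spacers$sequence[i],
                      viruses$sequence[viruses$id == li$virus_id[1]],
                      fixed = TRUE))
  }
  # no planted link, no assignment downstream at exact-match settings
  lonely <- rg(4000, 99, "lonely")
  m <- match_spacers(hp$spacers, lonely)
  expect_equal(nrow(m), 0L)
})
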