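test_that("spacer matching is exact, strand-aware, and length-flagged", {
  v <- rg(4000, 130, "virus1")
  sp32 <- substr(v$sequence, 101, 132)
  sp18 <- substr(v$sequence, 901, 918)
  rc <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }
  spacers <- data.frame(
    id = c("s1", "s2", "s3", "s4"),
    sequence = c(sp32, sp18, rc(substr(v$sequence, 2001, 2035)),
                 rg(120, 131)$sequence),   # s4: unrelated, no match
    host_species_id = c("SPA", "SPA", "SPB", "SPC"),
    stringsAsFactors = FALSE)
  m <- match_spacers(spacers, v)
  expect_setequal(m$spacer_id, c("s1", "s2", "s3"))
  expect_false(m$short_spacer[m$spacer_id == "s1"])
  expect_true(m$short_spacer[m$spacer_id == "s2"])
  expect_false(m$short_spacer[m$spacer_id == "s3"])  # revcomp matched
})

test_that("tRNA matching needs 95% identity across the full viral gene", {
  v <- rg(4000, 132, "virus2")
  gene <- substr(v$sequence, 501, 580)               # 80 bp
  vt <- data.frame(id = "vt1", virus_id = "virus2", sequence = gene,
                   stringsAsFactors = FALSE)
  exact <- data.frame(id = "ht1", host_species_id = "SPA",
                      sequence = gene, stringsAsFactors = FALSE)
  expect_equal(nrow(match_trnas(vt, exact)), 1L)
  diverged <- exact
  bases <- strsplit(gene, "")[[1]]
  swap <- seq(5, 80, by = 10)                      # exactly 90% identity
  bases[swap] <- chartr("ACGT", "TGCA", bases[swap])
  diverged$sequence <- paste0(bases, collapse = "")
  expect_equal(nrow(match_trnas(vt, diverged)), 0L)
  truncated <- exact
  truncated$sequence <- substr(gene, 1, 72)          # 90% of the length
  expect_equal(nrow(match_trnas(vt, truncated)), 0L)
})

test_that("evidence tiers count distinct qualifying pieces", {
  sp_row <- function(v, h, seq, short = FALSE, id = "sx") {
    data.frame(virus_id = v, host_species_id = h, spacer_id = id,
               spacer_seq = seq, short_spacer = short,
               stringsAsFactors = FALSE)
  }
  tr_row <- function(v, h, tid) {
    data.frame(virus_id = v, host_species_id = h, viral_trna_id = "vt",
               host_trna_id = tid, identity = 100,
               stringsAsFactors = FALSE)
  }
  no_tr <- tr_row("x", "y", "t")[0, ]
  no_sp <- sp_row("x", "y", "s")[0, ]

  two_sp <- rbind(sp_row("v", "h", "AAAA"), sp_row("v", "h", "CCCC"))
  expect_equal(assign_hosts(two_sp, no_tr)$confidence, "high")
  two_tr <- rbind(tr_row("v", "h", "t1"), tr_row("v", "h", "t2"))
  expect_equal(assign_hosts(no_sp, two_tr)$confidence, "high")
  mixed <- assign_hosts(sp_row("v", "h", "AAAA"), tr_row("v", "h", "t1"))
  expect_equal(mixed$confidence, "high")
  one_sp <- assign_hosts(sp_row("v", "h", "AAAA"), no_tr)
  expect_equal(one_sp$confidence, "low")
  # the same spacer sequence twice counts once
  dup <- rbind(sp_row("v", "h", "AAAA", id = "s1"),
               sp_row("v", "h", "AAAA", id = "s2"))
  dup_out <- assign_hosts(dup, no_tr)
  expect_equal(dup_out$n_spacer_matches, 1L)
  expect_equal(dup_out$confidence, "low")
  # short spacers never qualify for the tier rule
  shorts <- rbind(sp_row("v", "h", "AAAA", short = TRUE),
                  sp_row("v", "h", "CCCC", short = TRUE))
  short_out <- assign_hosts(shorts, no_tr)
  expect_equal(short_out$n_spacer_matches, 0L)
  expect_equal(short_out$confidence, "low")
  expect_true(short_out$any_short_spacer_only)
})

test_that("LCA host range walks the taxonomy correctly", {
  tax <- toy_taxonomy()
  ev <- function(hosts) {
    data.frame(virus_id = "v", host_species_id = hosts,
               confidence = "high", stringsAsFactors = FALSE)
  }
  single <- host_range(ev("s1"), tax)
  expect_equal(single$lca_rank, "species")
  expect_equal(single$n_hosts, 1L)
  genus <- host_range(ev(c("s1", "s2")), tax)
  expect_equal(genus$lca_rank, "genus")
  expect_equal(genus$lca_node, "g1")
  cross <- host_range(ev(c("s1", "s3")), tax)
  expect_equal(cross$lca_rank, "domain")
  # permutation-invariant and idempotent under duplication
  expect_equal(host_range(ev(c("s2", "s1")), tax)$lca_node, "g1")
  expect_equal(host_range(ev(c("s1", "s1", "s2")), tax)$lca_node, "g1")
  expect_error(host_range(ev("missing"), tax), "missing")
})

test_that("the interaction network deduplicates to genus level", {
  tax <- toy_taxonomy()
  clusters <- data.frame(vc_id = "VC_1", member_id = c("v1", "v2"),
                         stringsAsFactors = FALSE)
  ev <- data.frame(virus_id = c("v1", "v2", "v1"),
                   host_species_id = c("s1", "s2", "s3"),
                   confidence = c("high", "high", "low"),
                   stringsAsFactors = FALSE)
  net <- export_network(clusters, ev, tax)
  # s1 and s2 share genus g1; the low-confidence s3 link is excluded
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$host_genus, "g1")
  empty <- export_network(clusters, ev[ev$confidence == "low", ], tax)
  expect_equal(nrow(empty$edges), 0L)
})
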