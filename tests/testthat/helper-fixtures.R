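# Shared fixtures and independent oracles.

# Random contig shortcut.
rg <- function(len, seed, id = paste0("g", seed), gc = 0.5) {
  gen_genome(len, gc = gc, seed = seed, id = id)
}

# Independent Smith-Waterman oracle (local alignment via Biostrings) under
# the same +1/-2 scoring. Gap penalties are set prohibitively high because
# the generator is substitution-only, so the optimum is the best-scoring
# ungapped segment. Returns NULL or a list with query boundaries (0-based
# half-open), identity and length.
sw_oracle <- function(query, subject, min_identity = 95, min_len = 100) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query), Biostrings::DNAString(subject),
    type = "local", substitutionMatrix = mat,
    gapOpening = 1e5, gapExtension = 1e5)
  len <- Biostrings::nchar(al)
  pid <- Biostrings::pid(al)
  if (len >= min_len && pid >= min_identity) {
    list(q_start = Biostrings::start(Biostrings::pattern(al)) - 1L,
         q_end = Biostrings::end(Biostrings::pattern(al)),
         identity = pid, len = len)
  } else {
    NULL
  }
}

# Brute-force terminal-repeat scan over every overlap length.
brute_terminal_repeat <- function(seq, min_len = 30) {
  n <- nchar(seq)
  for (L in seq(n - 1L, min_len)) {
    p <- substr(seq, 1L, L)
    if (!grepl("N", p, fixed = TRUE) &&
        p == substr(seq, n - L + 1L, n)) {
      return(L)
    }
  }
  0L
}

# Tiny three-level toy taxonomy: 4 species, 2 genera, 1 domain root.
toy_taxonomy <- function() {
  data.frame(
    node_id = c("s1", "s2", "s3", "s4", "g1", "g2", "root"),
    parent_id = c("g1", "g1", "g2", "g2", "root", "root", NA),
    rank = c(rep("species", 4), rep("genus", 2), "domain"),
    name = c("s1", "s2", "s3", "s4", "g1", "g2", "root"),
    stringsAsFactors = FALSE)
}
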