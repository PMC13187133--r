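# Shared fixtures and independent oracles used across the suite.

# Minimal 3-ESV / 2-MOTU / 2-sample tables with consistent linkage.
tiny_tables <- function() {
  reads <- matrix(c(10, 5,
                    0, 7,
                    3, 0), nrow = 3, byrow = TRUE,
                  dimnames = list(c("e1", "e2", "e3"), c("s1", "s2")))
  esvs <- esv_table(reads, c(e1 = "m1", e2 = "m1", e3 = "m2"))
  motus <- motu_table(matrix(c(10, 12, 3, 0), nrow = 2, byrow = TRUE,
                             dimnames = list(c("m1", "m2"), c("s1", "s2"))),
                      taxonomy = c(m1 = "Arthropoda;;;;;",
                                   m2 = "Mollusca;;;;;"))
  samples <- sample_frame(data.frame(
    sample_id = c("s1", "s2"), locality = c("A", "B"),
    time_point = c("T1", "T1"), replicate = 1L,
    sample_type = "true_sample", stringsAsFactors = FALSE))
  list(esvs = esvs, motus = motus, samples = samples)
}

# Independent re-transcription of the Jost's D estimator (Nei-Chesser
# correction, harmonic-mean sample size, n = 2 subpopulations). Kept
# deliberately literal, step by step, as the oracle for jost_d_pair.
oracle_jost_d <- function(occ) {
  N1 <- sum(occ[, 1]); N2 <- sum(occ[, 2])
  p1 <- occ[, 1] / N1;  p2 <- occ[, 2] / N2
  hs <- ((1 - sum(p1^2)) + (1 - sum(p2^2))) / 2
  ntilde <- 2 / (1 / N1 + 1 / N2)
  hs_est <- ntilde / (ntilde - 1) * hs
  pbar <- (p1 + p2) / 2
  ht <- 1 - sum(pbar^2)
  ht_est <- ht + hs_est / (2 * ntilde)
  2 * (ht_est - hs_est) / (1 - hs_est)
}

# Brute-force expected rarefied richness: mean observed richness over
# many random without-replacement subsamples.
mc_rarefied_richness <- function(counts, depth, n_draws = 1000, seed = 42) {
  set.seed(seed)
  pool <- rep(seq_along(counts), counts)
  mean(vapply(seq_len(n_draws), function(i)
    length(unique(sample(pool, depth))), 0))
}

# Brute-force one-way pseudo-F (Anderson) computed from first principles,
# independent of the package internals.
oracle_pseudo_f <- function(d, g) {
  n <- length(g)
  lev <- unique(g)
  sst <- sum(d[lower.tri(d)]^2) / n
  ssw <- 0
  for (l in lev) {
    i <- which(g == l)
    ssw <- ssw + sum(d[i, i][lower.tri(d[i, i])]^2) / length(i)
  }
  ((sst - ssw) / (length(lev) - 1)) / (ssw / (n - length(lev)))
}

# All permutations of 1..n (for exhaustive permutation oracles).
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(pos)
    t(apply(sub, 1, function(p) append(p, n, after = pos - 1)))))
}

# A sequence whose in-frame translation is stop-free under the default codes
# (shared template used by several filtering tests).
clean_seq_for_tests <- function() {
  set.seed(99)
  metaport:::.make_clean_sequence()
}

metazoan_phyla <- c("Arthropoda", "Cnidaria", "Chordata", "Annelida",
                    "Mollusca", "Bryozoa", "Echinodermata", "Porifera")
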