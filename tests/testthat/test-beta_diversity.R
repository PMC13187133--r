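# Shared small design: 2 localities x 2 time points x 2 replicates.
.beta_samples <- function() {
  grid <- expand.grid(replicate = 1:2, time_point = c("T1", "T2"),
                      locality = c("A", "B"), stringsAsFactors = FALSE)
  grid$sample_id <- paste(grid$locality, grid$time_point, grid$replicate,
                          sep = "_")
  grid$sample_type <- "true_sample"
  sample_frame(grid[, c("sample_id", "locality", "time_point", "replicate",
                        "sample_type")])
}

.beta_reads <- function(seed = 31, n_taxa = 12) {
  samples <- .beta_samples()
  set.seed(seed)
  base <- matrix(rpois(n_taxa * nrow(samples), 20), n_taxa,
                 dimnames = list(paste0("m", seq_len(n_taxa)),
                                 samples$sample_id))
  # locality B enriched in the second half of the taxa: real group signal
  b_cols <- grepl("^B", colnames(base))
  base[(n_taxa / 2 + 1):n_taxa, b_cols] <-
    base[(n_taxa / 2 + 1):n_taxa, b_cols] + 60
  base
}

test_that("Bray-Curtis matches the hand formula on relative abundances", {
  reads <- cbind(s1 = c(10, 30, 60), s2 = c(50, 30, 20))
  rownames(reads) <- paste0("m", 1:3)
  dm <- bray_curtis(reads)
  rel1 <- reads[, 1] / 100; rel2 <- reads[, 2] / 100
  hand <- 1 - 2 * sum(pmin(rel1, rel2)) / (sum(rel1) + sum(rel2))
  expect_equal(dm$values["s1", "s2"], hand)
  expect_equal(hand, 0.4)                       # min = .1+.3+.2 = .6
  # identical composition at different depth: distance 0 on relatives
  reads2 <- cbind(s1 = c(10, 30, 60), s2 = c(20, 60, 120))
  expect_equal(bray_curtis(reads2)$values["s1", "s2"], 0)
  expect_error(bray_curtis(cbind(s1 = c(1, 2), s2 = c(0, 0))), "zero-sum")
})

test_that("Sorensen locality mode matches hand counts on pooled incidence", {
  samples <- .beta_samples()
  reads <- matrix(0, 4, nrow(samples),
                  dimnames = list(paste0("m", 1:4), samples$sample_id))
  # A has m1, m2, m3 (spread over its samples); B has m2, m3, m4; every
  # sample carries at least one taxon
  reads["m1", c("A_T1_1", "A_T2_2")] <- 5
  reads["m2", c("A_T1_2", "B_T1_1")] <- 5
  reads["m3", c("A_T2_1", "B_T2_1")] <- 5
  reads["m4", c("B_T1_2", "B_T2_2")] <- 5
  out <- sorensen_localities(reads, samples)
  expect_equal(out$pairs$sorensen, 2 * 2 / (3 + 3))
  expect_equal(out$mean, out$pairs$sorensen)
  # sample mode averages cross-locality sample pairs; here most sample pairs
  # share nothing, so it must be below the pooled value
  out_s <- sorensen_localities(reads, samples, mode = "sample")
  expect_lt(out_s$mean, out$mean)
})

test_that("membership patterns count subsets and fractions correctly", {
  inc <- rbind(m1 = c(TRUE, FALSE, FALSE),
               m2 = c(TRUE, TRUE, FALSE),
               m3 = c(TRUE, TRUE, TRUE),
               m4 = c(TRUE, TRUE, TRUE),
               m5 = c(FALSE, FALSE, TRUE))
  colnames(inc) <- c("A", "B", "C")
  out <- membership_patterns(inc)
  expect_equal(out$counts$count[out$counts$pattern == "A+B+C"], 2)
  expect_equal(out$counts$count[out$counts$pattern == "A"], 1)
  expect_equal(out$frac_unique, 2 / 5)
  expect_equal(out$frac_all, 2 / 5)
  expect_equal(sum(out$counts$count), 5)
})

test_that("PERMANOVA pseudo-F matches the first-principles oracle and adonis2", {
  reads <- .beta_reads()
  samples <- .beta_samples()
  dm <- bray_curtis(reads)
  g <- samples$locality[match(dm$labels, samples$sample_id)]
  res <- permanova(dm, g, n_perm = 199, seed = 4)
  expect_equal(res$f, oracle_pseudo_f(dm$values, g), tolerance = 1e-10)
  # independent route: vegan::adonis2 on the same distances
  ad <- vegan::adonis2(stats::as.dist(dm$values) ~ g, permutations = 199)
  expect_equal(res$f, ad$F[1], tolerance = 1e-8)
  expect_lt(res$p_value, 0.05)
})

test_that("exhaustive PERMANOVA p-value equals brute-force enumeration", {
  set.seed(8)
  pts <- rbind(matrix(rnorm(6, 0), 3), matrix(rnorm(6, 2), 3))
  rownames(pts) <- paste0("s", 1:6)
  d <- as.matrix(stats::dist(pts))
  dm <- dist_matrix(d, "euclidean")
  g <- rep(c("x", "y"), each = 3)
  res <- permanova(dm, g, exhaustive = TRUE)
  perms <- all_permutations(6)
  f_all <- apply(perms, 1, function(idx) oracle_pseudo_f(d, g[idx]))
  f_obs <- oracle_pseudo_f(d, g)
  expect_equal(res$f, f_obs, tolerance = 1e-10)
  expect_equal(res$p_value, mean(f_all >= f_obs - 1e-12), tolerance = 1e-12)
  expect_equal(res$n_perm, factorial(6))
})

test_that("sampled PERMANOVA p-values are seeded and use the +1 convention", {
  reads <- .beta_reads(seed = 5)
  samples <- .beta_samples()
  dm <- bray_curtis(reads)
  g <- samples$locality[match(dm$labels, samples$sample_id)]
  a <- permanova(dm, g, n_perm = 99, seed = 12)
  b <- permanova(dm, g, n_perm = 99, seed = 12)
  expect_identical(a, b)
  expect_gte(a$p_value, 1 / 100)           # +1 convention lower bound
  expect_error(permanova(dm, rep("only", length(g))), ">= 2 groups")
  expect_error(permanova(dm, c("a", rep("b", length(g) - 1))), ">= 2 members")
})

test_that("pairwise PERMANOVA covers all pairs with adjusted p-values", {
  samples <- .beta_samples()
  # add a third locality by relabelling T2 of B
  g <- samples$locality
  g[samples$locality == "B" & samples$time_point == "T2"] <- "C"
  reads <- .beta_reads(seed = 9)
  dm <- bray_curtis(reads)
  out <- pairwise_permanova(dm, g[match(dm$labels, samples$sample_id)],
                            n_perm = 99, seed = 2)
  expect_equal(nrow(out), choose(3, 2))
  expect_true(all(out$p_adj >= out$p))
})

test_that("permdisp F agrees with an ANOVA on betadisper distances", {
  reads <- .beta_reads(seed = 13)
  samples <- .beta_samples()
  dm <- bray_curtis(reads)
  g <- factor(samples$locality[match(dm$labels, samples$sample_id)])
  res <- permdisp(dm, g, n_perm = 99, seed = 6)
  bd <- vegan::betadisper(stats::as.dist(dm$values), g, type = "centroid")
  fit <- stats::anova(stats::lm(bd$distances ~ g))
  expect_equal(res$f, fit$`F value`[1], tolerance = 1e-10)
  expect_equal(as.numeric(res$group_means),
               as.numeric(tapply(bd$distances, g, mean)), tolerance = 1e-12)
})

test_that("NMDS is deterministic under a seed and reports stress", {
  reads <- .beta_reads(seed = 17)
  dm <- bray_curtis(reads)
  # 8 points embed almost perfectly in 2D; vegan warns about near-zero stress
  a <- suppressWarnings(nmds_ordination(dm, seed = 5, trymax = 5))
  b <- suppressWarnings(nmds_ordination(dm, seed = 5, trymax = 5))
  expect_equal(a$points, b$points)
  expect_true(is.finite(a$stress) && a$stress >= 0)
  expect_equal(nrow(a$points), length(dm$labels))
})

test_that("temporal turnover averages consecutive-time pairs per locality", {
  samples <- .beta_samples()
  n <- nrow(samples)
  d <- matrix(0.5, n, n, dimnames = list(samples$sample_id,
                                         samples$sample_id))
  diag(d) <- 0
  # make A's T1-vs-T2 pairs distinctive: 0.9
  a1 <- samples$sample_id[samples$locality == "A" & samples$time_point == "T1"]
  a2 <- samples$sample_id[samples$locality == "A" & samples$time_point == "T2"]
  d[a1, a2] <- 0.9; d[a2, a1] <- 0.9
  dm <- dist_matrix(d, "bray_curtis")
  out <- temporal_turnover(dm, samples)
  expect_equal(nrow(out), 1)
  expect_equal(out$from, "T1"); expect_equal(out$to, "T2")
  expect_equal(out$mean_dissimilarity, mean(c(0.9, 0.5)))  # A then B
  expect_equal(out$n_pairs, 2)
  expect_equal(out$gaps, "")

  # a locality missing a time point is reported as a gap
  samples2 <- samples[!(samples$locality == "B" &
                          samples$time_point == "T2"), , drop = FALSE]
  keep <- samples2$sample_id
  dm2 <- dist_matrix(d[keep, keep], "bray_curtis")
  out2 <- temporal_turnover(dm2, samples2)
  expect_equal(out2$gaps, "B")
  expect_equal(out2$n_pairs, 1)
})

test_that("paired matrix comparison matches a direct paired t-test", {
  reads <- .beta_reads(seed = 23)
  dm1 <- bray_curtis(reads)
  set.seed(99)
  noisy <- pmax(reads + matrix(rpois(length(reads), 8), nrow(reads)), 1)
  dm2 <- bray_curtis(noisy)
  out <- compare_mean_dissimilarity(dm1, dm2)
  tt <- stats::t.test(dm_pairs(dm1), dm_pairs(dm2), paired = TRUE)
  expect_equal(out$t, unname(tt$statistic))
  expect_equal(out$p_value, tt$p.value)
  expect_equal(out$df, length(dm_pairs(dm1)) - 1)
  # identical matrices short-circuit instead of erroring on zero variance
  same <- compare_mean_dissimilarity(dm1, dm1)
  expect_equal(same$t, 0); expect_equal(same$p_value, 1)
})

test_that("season labels split at the temperature threshold", {
  temp <- c(s1 = 14, s2 = 20, s3 = 26)
  expect_equal(unname(season_labels(temp)), c("cold", "warm", "warm"))
  expect_equal(names(season_labels(temp)), names(temp))
})
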