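test_that("Jost's D matches hand-computed reference values", {
  # complete differentiation: disjoint variants
  expect_equal(jost_d_pair(cbind(c(5, 0), c(0, 5))), 1)
  # identical frequencies: raw corrected estimate is negative, clamped to 0
  even <- cbind(c(3, 3), c(3, 3))
  expect_equal(jost_d_pair(even), 0)
  expect_equal(jost_d_pair(even, clamp = FALSE), -0.25)
  expect_equal(jost_d_pair(even, corrected = FALSE), 0)
  # intermediate case, worked by hand:
  # p1=(.8,.2), p2=(.2,.8); Hs=.32; ntilde=5; Hs^=.4; Ht=.5; Ht^=.54;
  # D = 2(.54-.4)/(1-.4) = 7/15
  expect_equal(jost_d_pair(cbind(c(4, 1), c(1, 4))), 7 / 15)
})

test_that("Jost's D agrees with the literal oracle on random matrices", {
  set.seed(61)
  for (i in 1:25) {
    k <- sample(2:6, 1)
    occ <- matrix(rpois(2 * k, 2), k, 2)
    # ensure validity: both columns nonzero, >= 2 nonzero variants
    occ[1, ] <- occ[1, ] + 1
    occ[2, ] <- occ[2, ] + 1
    expect_equal(jost_d_pair(occ, clamp = FALSE), oracle_jost_d(occ),
                 tolerance = 1e-12)
    expect_equal(jost_d_pair(occ), max(0, oracle_jost_d(occ)),
                 tolerance = 1e-12)
  }
})

test_that("Jost's D rejects degenerate occurrence matrices", {
  expect_error(jost_d_pair(cbind(c(2, 3), c(0, 0))), "all-zero")
  expect_error(jost_d_pair(cbind(c(2, 0), c(3, 0))), ">= 2 variants")
})

test_that("occurrence matrices count samples with detections per locality", {
  fx <- worked_fixture()
  occ <- occurrence_matrix(fx$esvs, fx$samples, "M01", c("A", "B"))
  # E01 is read in A1, A2, A3 and B1; E02 in A3 and B1, B2, B3
  expect_equal(occ["E01", ], c(A = 3, B = 1))
  expect_equal(occ["E02", ], c(A = 1, B = 3))
  expect_equal(jost_d_pair(occ), fx$expected$d_m01)
  expect_error(occurrence_matrix(fx$esvs, fx$samples, "M99", c("A", "B")),
               "unknown MOTU")
  expect_error(occurrence_matrix(fx$esvs, fx$samples, "M01", c("A", "Z")),
               "no samples")
})

test_that("ESV richness summaries count nonzero ESVs and conserve reads", {
  fx <- worked_fixture()
  motus <- partition_datasets(fx$motus, fx$nis_ids, fx$nat_ids)
  summ <- esv_richness_summary(fx$esvs, motus)
  expect_setequal(summ$dataset, c("NIS", "NAT"))
  m01 <- summ[summ$motu_id == "M01", ]
  expect_equal(m01$n_esvs, 2L)
  expect_equal(m01$total_reads, sum(fx$esvs$reads[c("E01", "E02"), ]))
  # scope "all" covers every MOTU with nonzero reads
  all_summ <- esv_richness_summary(fx$esvs, motus, scope = "all")
  expect_equal(sum(all_summ$total_reads), sum(fx$esvs$reads))
  expect_equal(sum(all_summ$n_esvs), sum(rowSums(fx$esvs$reads) > 0))
})

test_that("ESV richness test reproduces wilcox.test and skips empty strata", {
  summ <- data.frame(
    dataset = rep(c("NIS", "NAT"), c(6, 8)),
    n_esvs = c(9, 7, 12, 8, 10, 6, 3, 2, 4, 1, 2, 3, 5, 2),
    locality = c(rep("RO", 6), rep("RO", 4), rep("BL", 4)),
    stringsAsFactors = FALSE)
  out <- esv_richness_test(summ)
  ref <- stats::wilcox.test(summ$n_esvs[summ$dataset == "NIS"],
                            summ$n_esvs[summ$dataset == "NAT"],
                            exact = FALSE)
  expect_equal(out$w, unname(ref$statistic))
  expect_equal(out$p_value, ref$p.value)
  expect_equal(out$median_nis, 8.5)
  expect_equal(out$median_nat, 2.5)

  strat <- esv_richness_test(summ, stratify = "locality")
  expect_equal(nrow(strat), 2)
  # BL has no NIS rows: skipped with a note, not an error
  bl <- strat[strat$stratum == "BL", ]
  expect_true(is.na(bl$p_value))
  expect_match(bl$note, "skipped")
})

test_that("log-log regression matches direct lm fits and the interaction F", {
  set.seed(33)
  n <- 30
  reads_nis <- round(exp(rnorm(n, 8, 1)))
  reads_nat <- round(exp(rnorm(n, 7, 1)))
  esv_nis <- pmax(1, round(exp(0.5 * log(reads_nis) + rnorm(n, 0, .3))))
  esv_nat <- pmax(1, round(exp(0.3 * log(reads_nat) + rnorm(n, 0, .3))))
  summ <- data.frame(
    motu_id = paste0("m", 1:(2 * n)),
    dataset = rep(c("NIS", "NAT"), each = n),
    n_esvs = c(esv_nis, esv_nat),
    total_reads = c(reads_nis, reads_nat),
    stringsAsFactors = FALSE)
  out <- reads_esvs_regression(summ)
  for (ds in c("NIS", "NAT")) {
    s <- summ[summ$dataset == ds, ]
    fit <- stats::lm(log(s$n_esvs) ~ log(s$total_reads))
    row <- out$per_dataset[out$per_dataset$dataset == ds, ]
    expect_equal(row$slope, unname(stats::coef(fit)[2]), tolerance = 1e-12)
    expect_equal(row$r, stats::cor(log(s$total_reads), log(s$n_esvs)),
                 tolerance = 1e-12)
  }
  joint <- stats::anova(stats::lm(log(n_esvs) ~ log(total_reads) * dataset,
                                  data = summ))
  expect_equal(out$homogeneity$interaction_p, joint$`Pr(>F)`[3],
               tolerance = 1e-12)
  expect_error(reads_esvs_regression(summ[1:2, ]), "< 3 MOTUs")
})

test_that("MOTU-level rarefaction hits the threshold exactly", {
  bundle <- simulate_dataset(sim_config(seed = 19, n_nis_motus = 6,
                                        n_nat_motus = 10, n_other_motus = 5,
                                        n_timepoints = 3))
  thr <- 500L
  out <- rarefy_motu_reads(bundle$esvs, bundle$motus, threshold = thr,
                           seed = 2)
  expect_equal(out$threshold_used, thr)
  summ_before <- esv_richness_summary(bundle$esvs, bundle$motus)
  totals_after <- rowsum(rowSums(out$esvs$reads), group = out$esvs$motu_id)
  for (m in summ_before$motu_id) {
    before <- summ_before$total_reads[summ_before$motu_id == m]
    after <- as.numeric(totals_after[m, 1])
    if (before > thr) expect_equal(after, thr)  # subsampled to the threshold
    else expect_equal(after, before)            # untouched at/below it
  }
  # rarefied counts never exceed the originals, cell by cell
  common <- intersect(out$esvs$esv_id, bundle$esvs$esv_id)
  expect_true(all(out$esvs$reads[common, ] <=
                    bundle$esvs$reads[common, colnames(out$esvs$reads)]))
  # elimination accounting is internally consistent
  expect_equal(out$eliminated$n_esvs_before - out$eliminated$n_esvs_after,
               round(out$eliminated$pct_eliminated *
                       out$eliminated$n_esvs_before / 100))
})

test_that("the sequential hypergeometric draw is a uniform subsample", {
  # distributional check: expected per-cell share proportional to counts
  counts <- c(60, 30, 10)
  n_draws <- 3000
  set.seed(14)
  draws <- t(vapply(seq_len(n_draws),
                    function(i) metaport:::.mv_hypergeom(counts, 50),
                    numeric(3)))
  expect_true(all(rowSums(draws) == 50))
  expect_true(all(sweep(draws, 2, counts, "<=")))
  expected <- 50 * counts / sum(counts)
  se <- apply(draws, 2, stats::sd) / sqrt(n_draws)
  expect_true(all(abs(colMeans(draws) - expected) < 4 * se + 1e-9))
})

test_that("randomization balance test controls for group size", {
  set.seed(51)
  nis <- rpois(20, 9) + 1
  nat <- rpois(60, 3) + 1
  out <- randomization_balance_test(nis, nat, n_resamples = 50, seed = 3)
  expect_length(out$p_values, 50)
  expect_gte(out$fraction_significant, 0.9)  # strong true difference persists
  # identical distributions: significance near the nominal level, not forced
  null_out <- randomization_balance_test(rpois(20, 3) + 1, nat,
                                         n_resamples = 50, seed = 3)
  expect_lte(null_out$fraction_significant, 0.5)
  expect_error(randomization_balance_test(nis, nat, target_size = 100),
               "exceeds NAT size")
})

test_that("mean D eligibility modes and the NIS/NAT comparison behave", {
  bundle <- simulate_dataset(sim_config(seed = 29, n_nis_motus = 10,
                                        n_nat_motus = 20, n_other_motus = 5,
                                        n_timepoints = 4))
  d_nis <- mean_d_between_localities(bundle$esvs, bundle$motus,
                                     bundle$samples, scope = "NIS")
  d_nat <- mean_d_between_localities(bundle$esvs, bundle$motus,
                                     bundle$samples, scope = "NAT")
  expect_equal(nrow(d_nis), choose(4, 2))
  expect_true(all(d_nis$mean_d >= 0 | is.na(d_nis$mean_d)))
  # per-MOTU attribute is consistent with the reported means
  pm <- attr(d_nis, "per_motu")
  for (j in seq_len(nrow(d_nis))) {
    key <- paste(d_nis$loc1[j], d_nis$loc2[j], sep = "|")
    expect_equal(d_nis$n_motus_used[j], length(pm[[key]]))
    if (d_nis$n_motus_used[j] > 0)
      expect_equal(d_nis$mean_d[j], mean(pm[[key]]))
  }
  # per-locality eligibility is at least as strict as pooled
  strict <- mean_d_between_localities(bundle$esvs, bundle$motus,
                                      bundle$samples, scope = "NIS",
                                      eligibility = "per_locality")
  expect_true(all(strict$n_motus_used <= d_nis$n_motus_used))

  cmp <- compare_jost_d(d_nis, d_nat)
  # pairs lacking eligible MOTUs in either dataset are excluded from both
  ok <- !is.na(d_nis$mean_d) & !is.na(d_nat$mean_d)
  ref <- stats::t.test(d_nis$mean_d[ok], d_nat$mean_d[ok], paired = TRUE)
  expect_equal(cmp$t, unname(ref$statistic))
  expect_equal(cmp$p_value, ref$p.value)
  expect_equal(cmp$n_pairs, sum(ok))
  if (stats::var(d_nis$mean_d[ok]) == 0 || stats::var(d_nat$mean_d[ok]) == 0) {
    expect_true(is.na(cmp$r))   # constant vector: correlation undefined
  } else {
    expect_equal(cmp$r, unname(stats::cor.test(d_nis$mean_d[ok],
                                               d_nat$mean_d[ok])$estimate))
  }
})
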