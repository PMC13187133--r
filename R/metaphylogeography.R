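# Intra-MOTU haplotype (ESV) diversity and occurrence-based Jost's D
# differentiation between localities, comparing non-indigenous (NIS) and
# native (NAT) MOTUs with read-abundance confound control.

#' Per-MOTU genetic summaries (ESV richness, total reads)
#'
#' @param esvs an [esv_table()]
#' @param motus the companion [motu_table()] with dataset labels
#' @param scope dataset scopes to include (default NIS and NAT)
#' @return data.frame `motu_id`, `dataset`, `n_esvs`, `total_reads`
#' @export
esv_richness_summary <- function(esvs, motus, scope = c("NIS", "NAT")) {
  ids <- unlist(lapply(scope, function(s) dataset_ids(motus, s)))
  keep <- esvs$motu_id %in% ids & rowSums(esvs$reads) > 0
  n_esvs <- table(esvs$motu_id[keep])
  tot <- rowsum(rowSums(esvs$reads[keep, , drop = FALSE]),
                group = esvs$motu_id[keep])
  mids <- intersect(ids, names(n_esvs))
  data.frame(motu_id = mids,
             dataset = motus$dataset_label[mids],
             n_esvs = as.integer(n_esvs[mids]),
             total_reads = as.numeric(tot[mids, 1]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-locality ESV counts per MOTU
#'
#' ESV richness of each MOTU restricted to the samples of each locality
#' (an ESV counts when it has at least one read in the locality).
#'
#' @inheritParams esv_richness_summary
#' @param samples a [sample_frame()]
#' @return data.frame `motu_id`, `dataset`, `locality`, `n_esvs`
#' @export
esv_richness_by_locality <- function(esvs, motus, samples,
                                     scope = c("NIS", "NAT")) {
  ids <- unlist(lapply(scope, function(s) dataset_ids(motus, s)))
  true <- samples[samples$sample_type == "true_sample", , drop = FALSE]
  true <- true[true$sample_id %in% colnames(esvs$reads), , drop = FALSE]
  out <- list()
  for (loc in sort(unique(true$locality))) {
    sids <- true$sample_id[true$locality == loc]
    in_loc <- rowSums(esvs$reads[, sids, drop = FALSE]) > 0 &
      esvs$motu_id %in% ids
    if (!any(in_loc)) next
    cnt <- table(esvs$motu_id[in_loc])
    out[[loc]] <- data.frame(motu_id = names(cnt),
                             dataset = motus$dataset_label[names(cnt)],
                             locality = loc, n_esvs = as.integer(cnt),
                             stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Mann-Whitney comparison of ESV richness between NIS and NAT
#'
#' Two-sided rank test on per-MOTU ESV counts, optionally per stratum
#' (locality or phylum); empty or single-dataset strata are skipped with a
#' note.
#'
#' @param summaries data.frame with columns `dataset` and `n_esvs`, and the
#'   stratifying column when `stratify` is given
#' @param stratify optional column name to stratify by
#' @return data.frame `stratum`, `n_nis`, `n_nat`, `w`, `p_value`,
#'   `median_nis`, `median_nat`, `note`
#' @export
esv_richness_test <- function(summaries, stratify = NULL) {
  strata <- if (is.null(stratify)) list(overall = summaries)
            else split(summaries, summaries[[stratify]])
  out <- list()
  for (nm in names(strata)) {
    s <- strata[[nm]]
    x <- s$n_esvs[s$dataset == "NIS"]
    y <- s$n_esvs[s$dataset == "NAT"]
    if (length(x) == 0 || length(y) == 0) {
      out[[nm]] <- data.frame(stratum = nm, n_nis = length(x),
                              n_nat = length(y), w = NA_real_,
                              p_value = NA_real_, median_nis = NA_real_,
                              median_nat = NA_real_,
                              note = "skipped: empty group",
                              stringsAsFactors = FALSE)
      next
    }
    wt <- stats::wilcox.test(x, y, alternative = "two.sided", exact = FALSE)
    out[[nm]] <- data.frame(stratum = nm, n_nis = length(x),
                            n_nat = length(y), w = unname(wt$statistic),
                            p_value = wt$p.value,
                            median_nis = stats::median(x),
                            median_nat = stats::median(y), note = "",
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Log-log regression of ESV richness on read abundance
#'
#' Per-dataset ordinary least squares of `log(n_esvs)` on `log(total_reads)`
#' with Pearson correlation, plus a slope-homogeneity test via the
#' dataset-by-log-reads interaction term of a joint model.
#'
#' @param summaries output of [esv_richness_summary()]
#' @return list with `per_dataset` (data.frame `dataset`, `slope`,
#'   `intercept`, `r`, `n`) and `homogeneity` (list `interaction_p`,
#'   `f`)
#' @export
reads_esvs_regression <- function(summaries) {
  summaries <- summaries[summaries$total_reads > 0 & summaries$n_esvs > 0, ]
  per <- list()
  for (ds in unique(summaries$dataset)) {
    s <- summaries[summaries$dataset == ds, ]
    if (nrow(s) < 3) stop("reads_esvs_regression: < 3 MOTUs in ", ds)
    lx <- log(s$total_reads); ly <- log(s$n_esvs)
    if (stats::var(lx) == 0)
      stop("reads_esvs_regression: zero predictor variance in ", ds)
    fit <- stats::lm(ly ~ lx)
    per[[ds]] <- data.frame(dataset = ds,
                            slope = unname(stats::coef(fit)[2]),
                            intercept = unname(stats::coef(fit)[1]),
                            r = stats::cor(lx, ly), n = nrow(s),
                            stringsAsFactors = FALSE)
  }
  lx <- log(summaries$total_reads); ly <- log(summaries$n_esvs)
  ds <- factor(summaries$dataset)
  full <- stats::lm(ly ~ lx * ds)
  an <- stats::anova(full)
  irow <- grep(":", rownames(an))
  list(per_dataset = do.call(rbind, c(per, make.row.names = FALSE)),
       homogeneity = list(interaction_p = an[irow, "Pr(>F)"],
                          f = an[irow, "F value"]))
}

#' Rarefy MOTU read totals to a common threshold
#'
#' For each MOTU (in the NIS and NAT datasets) whose pooled reads exceed the
#' threshold, draws a without-replacement subsample of exactly `threshold`
#' reads from its (ESV, sample) cells via sequential hypergeometric sampling
#' (multivariate hypergeometric: expected per-cell share proportional to the
#' original counts, so per-sample proportions are preserved in expectation).
#' ESVs reduced to zero reads are eliminated; MOTUs at or below the threshold
#' are untouched.
#'
#' @param esvs an [esv_table()]
#' @param motus the companion [motu_table()]
#' @param threshold `"mean"` or `"median"` (of the NAT MOTUs' read totals),
#'   or an explicit positive integer
#' @param seed integer seed
#' @return list with `esvs` (rarefied table over the NIS+NAT scope),
#'   `threshold_used`, and `eliminated` (data.frame `dataset`, `n_esvs_before`,
#'   `n_esvs_after`, `pct_eliminated`)
#' @export
rarefy_motu_reads <- function(esvs, motus, threshold = "mean", seed = 1L) {
  summ <- esv_richness_summary(esvs, motus, scope = c("NIS", "NAT"))
  nat_tot <- summ$total_reads[summ$dataset == "NAT"]
  thr <- if (identical(threshold, "mean")) mean(nat_tot)
         else if (identical(threshold, "median")) stats::median(nat_tot)
         else as.numeric(threshold)
  if (is.na(thr) || thr < 1) stop("rarefy_motu_reads: threshold < 1")
  thr <- floor(thr)
  scope_ids <- summ$motu_id
  sub <- esv_subset(esvs, esvs$esv_id[esvs$motu_id %in% scope_ids])
  reads <- sub$reads
  set.seed(seed)
  for (m in scope_ids) {
    rows <- which(sub$motu_id == m)
    total <- sum(reads[rows, ])
    if (total <= thr) next
    cells <- reads[rows, , drop = FALSE]
    flat <- as.vector(cells)
    reads[rows, ] <- .mv_hypergeom(flat, thr)
  }
  keep <- rowSums(reads) > 0
  out <- esv_table(reads[keep, , drop = FALSE], sub$motu_id[keep],
                   if (is.null(sub$sequence)) NULL else sub$sequence[keep])
  elim <- do.call(rbind, lapply(c("NIS", "NAT"), function(ds) {
    ids <- summ$motu_id[summ$dataset == ds]
    before <- sum(sub$motu_id %in% ids)
    after <- sum(out$motu_id %in% ids)
    data.frame(dataset = ds, n_esvs_before = before, n_esvs_after = after,
               pct_eliminated = 100 * (before - after) / before,
               stringsAsFactors = FALSE)
  }))
  list(esvs = out, threshold_used = thr, eliminated = elim)
}

# Multivariate hypergeometric draw: subsample `n` items without replacement
# from cells with counts `counts`; returns the same-shape vector of draws.
.mv_hypergeom <- function(counts, n) {
  out <- numeric(length(counts))
  rem_total <- sum(counts)
  rem_draw <- n
  for (i in seq_along(counts)) {
    if (rem_draw == 0) break
    x <- stats::rhyper(1, counts[i], rem_total - counts[i], rem_draw)
    out[i] <- x
    rem_total <- rem_total - counts[i]
    rem_draw <- rem_draw - x
  }
  out
}

#' Randomization test balancing dataset sizes
#'
#' Repeatedly subsamples the NAT per-MOTU ESV counts (without replacement) to
#' `target_size` and reruns the Mann-Whitney comparison against the full NIS
#' set, reporting the fraction of resamples significant at `alpha` and the
#' p-value distribution. Controls for the different numbers of NIS and NAT
#' MOTUs entering the comparison.
#'
#' @param nis_counts integer vector of per-MOTU ESV counts, NIS
#' @param nat_counts integer vector of per-MOTU ESV counts, NAT
#' @param target_size NAT subsample size (default `length(nis_counts)`)
#' @param n_resamples number of resamples (default 100)
#' @param alpha significance level (default 0.05)
#' @param seed integer seed
#' @return list with `fraction_significant`, `p_values`
#' @export
randomization_balance_test <- function(nis_counts, nat_counts,
                                       target_size = length(nis_counts),
                                       n_resamples = 100, alpha = 0.05,
                                       seed = 1L) {
  if (target_size > length(nat_counts))
    stop("randomization_balance_test: target_size exceeds NAT size")
  set.seed(seed)
  p <- vapply(seq_len(n_resamples), function(b) {
    sub <- sample(nat_counts, target_size)
    stats::wilcox.test(nis_counts, sub, exact = FALSE)$p.value
  }, 0)
  list(fraction_significant = mean(p < alpha), p_values = p)
}

#' ESV occurrence matrix for a MOTU over a locality pair
#'
#' The abundance proxy for Jost's D: for each ESV of the MOTU, the number of
#' samples in each locality where the ESV has at least one read.
#'
#' @param esvs an [esv_table()]
#' @param samples a [sample_frame()]
#' @param motu_id the MOTU
#' @param pair character vector of two localities
#' @return integer matrix, ESV rows x 2 locality columns
#' @export
occurrence_matrix <- function(esvs, samples, motu_id, pair) {
  stopifnot(length(pair) == 2)
  rows <- which(esvs$motu_id == motu_id)
  if (length(rows) == 0) stop("occurrence_matrix: unknown MOTU: ", motu_id)
  true <- samples[samples$sample_type == "true_sample", , drop = FALSE]
  true <- true[true$sample_id %in% colnames(esvs$reads), , drop = FALSE]
  occ <- vapply(pair, function(loc) {
    sids <- true$sample_id[true$locality == loc]
    if (length(sids) == 0) stop("occurrence_matrix: locality has no samples: ",
                                loc)
    rowSums(esvs$reads[rows, sids, drop = FALSE] > 0)
  }, numeric(length(rows)))
  occ <- matrix(occ, nrow = length(rows),
                dimnames = list(esvs$esv_id[rows], pair))
  if (all(colSums(occ) == 0))
    stop("occurrence_matrix: MOTU absent from both localities: ", motu_id)
  occ
}

#' Jost's D between two subpopulations from occurrence frequencies
#'
#' Bias-corrected (Nei-Chesser-style) estimator with harmonic-mean sample
#' size. With `n = 2` subpopulations, column totals \eqn{N_j}, frequencies
#' \eqn{p_{ij} = x_{ij}/N_j} and harmonic mean \eqn{\tilde n} of the
#' \eqn{N_j}:
#' \deqn{H_s = mean_j (1 - \sum_i p_{ij}^2), \quad
#'       \hat H_s = \tilde n/(\tilde n - 1) H_s}
#' \deqn{H_t = 1 - \sum_i \bar p_i^2, \quad
#'       \hat H_t = H_t + \hat H_s/(\tilde n \cdot n)}
#' \deqn{D = \frac{n}{n-1}\,\frac{\hat H_t - \hat H_s}{1 - \hat H_s}}
#' Negative estimates are set to zero after estimation (`clamp = TRUE`).
#'
#' @param occ matrix of non-negative counts, variants x 2 localities
#'   (see [occurrence_matrix()])
#' @param clamp clamp negative estimates at zero (default TRUE)
#' @param corrected apply the bias correction (default TRUE); with FALSE the
#'   raw D from uncorrected \eqn{H_s}, \eqn{H_t} is returned
#' @return D estimate (numeric scalar)
#' @export
jost_d_pair <- function(occ, clamp = TRUE, corrected = TRUE) {
  stopifnot(is.matrix(occ), ncol(occ) == 2, all(occ >= 0))
  N <- colSums(occ)
  if (any(N == 0)) stop("jost_d_pair: locality with all-zero counts")
  if (sum(rowSums(occ) > 0) < 2)
    stop("jost_d_pair: need >= 2 variants with nonzero counts")
  n_pop <- 2
  p <- sweep(occ, 2, N, "/")
  hs <- mean(1 - colSums(p^2))
  pbar <- rowMeans(p)
  ht <- 1 - sum(pbar^2)
  if (corrected) {
    ntilde <- n_pop / sum(1 / N)
    if (ntilde <= 1)
      stop("jost_d_pair: bias correction undefined when both localities ",
           "have a single occurrence")
    hs_est <- ntilde / (ntilde - 1) * hs
    ht_est <- ht + hs_est / (ntilde * n_pop)
  } else {
    hs_est <- hs
    ht_est <- ht
  }
  if (abs(1 - hs_est) < 1e-12) stop("jost_d_pair: Hs estimate is 1; D undefined")
  d <- n_pop / (n_pop - 1) * (ht_est - hs_est) / (1 - hs_est)
  if (clamp) max(0, d) else d
}

#' Mean Jost's D between localities for a dataset
#'
#' For each locality pair: selects MOTUs of the scope present in both
#' localities with at least two ESVs showing nonzero occurrence in the pair
#' (`eligibility = "pooled"`, default) or at least two in each locality
#' (`"per_locality"`), computes [jost_d_pair()] per MOTU on occurrence
#' counts, and averages the clamped values.
#'
#' @param esvs an [esv_table()]
#' @param motus the companion [motu_table()]
#' @param samples a [sample_frame()]
#' @param scope dataset scope (`"NIS"` or `"NAT"`)
#' @param eligibility `"pooled"` or `"per_locality"`
#' @param clamp clamp negative per-MOTU values at zero (default TRUE)
#' @return data.frame `loc1`, `loc2`, `n_motus_used`, `mean_d`, plus
#'   attribute `"per_motu"` (list of per-pair named D vectors)
#' @export
mean_d_between_localities <- function(esvs, motus, samples, scope = "NIS",
                                      eligibility = c("pooled",
                                                      "per_locality"),
                                      clamp = TRUE) {
  eligibility <- match.arg(eligibility)
  ids <- dataset_ids(motus, scope)
  true <- samples[samples$sample_type == "true_sample", , drop = FALSE]
  true <- true[true$sample_id %in% colnames(esvs$reads), , drop = FALSE]
  locs <- sort(unique(true$locality))
  cmb <- utils::combn(locs, 2)
  rows <- which(esvs$motu_id %in% ids)
  out <- list(); per_motu <- list()
  for (j in seq_len(ncol(cmb))) {
    pair <- cmb[, j]
    sid1 <- true$sample_id[true$locality == pair[1]]
    sid2 <- true$sample_id[true$locality == pair[2]]
    occ1 <- rowSums(esvs$reads[rows, sid1, drop = FALSE] > 0)
    occ2 <- rowSums(esvs$reads[rows, sid2, drop = FALSE] > 0)
    mid <- esvs$motu_id[rows]
    pres1 <- tapply(occ1, mid, function(x) sum(x) > 0)
    pres2 <- tapply(occ2, mid, function(x) sum(x) > 0)
    n_var <- if (eligibility == "pooled")
      tapply(occ1 + occ2, mid, function(x) sum(x > 0))
    else pmin(tapply(occ1, mid, function(x) sum(x > 0)),
              tapply(occ2, mid, function(x) sum(x > 0)))
    eligible <- names(pres1)[pres1 & pres2 & n_var >= 2]
    dvals <- vapply(eligible, function(m) {
      sel <- mid == m
      jost_d_pair(cbind(occ1[sel], occ2[sel]), clamp = clamp)
    }, 0)
    key <- paste(pair, collapse = "|")
    per_motu[[key]] <- dvals
    out[[key]] <- data.frame(loc1 = pair[1], loc2 = pair[2],
                             n_motus_used = length(dvals),
                             mean_d = if (length(dvals)) mean(dvals)
                                      else NA_real_,
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  attr(res, "per_motu") <- per_motu
  res
}

#' Compare per-pair mean D between two datasets
#'
#' Paired-sample t-test across locality pairs (NIS vs NAT means on the same
#' pairs) and Pearson correlation of the two pair-wise mean-D vectors. Pairs
#' without eligible MOTUs in either dataset are excluded from both tests.
#'
#' @param d1,d2 outputs of [mean_d_between_localities()] for the two datasets
#' @return list with `mean1`, `mean2`, `t`, `p_value`, `r`, `r_p_value`,
#'   `n_pairs`
#' @export
compare_jost_d <- function(d1, d2) {
  key1 <- paste(d1$loc1, d1$loc2, sep = "|")
  key2 <- paste(d2$loc1, d2$loc2, sep = "|")
  if (!identical(sort(key1), sort(key2)))
    stop("compare_jost_d: locality pairs differ")
  v2 <- d2$mean_d[match(key1, key2)]
  v1 <- d1$mean_d
  ok <- !is.na(v1) & !is.na(v2)
  v1 <- v1[ok]; v2 <- v2[ok]
  if (length(v1) < 3) stop("compare_jost_d: < 3 usable pairs")
  tt <- stats::t.test(v1, v2, paired = TRUE)
  if (stats::var(v1) == 0 || stats::var(v2) == 0) {
    # a constant mean-D vector carries no correlation information
    r <- NA_real_; r_p <- NA_real_
  } else {
    ct <- stats::cor.test(v1, v2)
    r <- unname(ct$estimate); r_p <- ct$p.value
  }
  list(mean1 = mean(v1), mean2 = mean(v2), t = unname(tt$statistic),
       p_value = tt$p.value, r = r, r_p_value = r_p, n_pairs = length(v1))
}
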