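# Beta diversity: Bray-Curtis on relative read abundances, Sorensen sharing
# between localities, membership (upset) counts, NMDS, one-way PERMANOVA and
# multivariate dispersion tests, temporal turnover.

#' Symmetric distance-matrix container
#'
#' @param values symmetric numeric matrix with zero diagonal, labelled
#' @param metric metric name (e.g. "bray_curtis")
#' @param scope dataset scope the matrix was computed on
#' @return a `dist_matrix` object
#' @export
dist_matrix <- function(values, metric = "bray_curtis", scope = "all") {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (is.null(rownames(values)))
    stop("dist_matrix: values must be labelled")
  if (any(abs(values - t(values)) > 1e-12)) stop("dist_matrix: not symmetric")
  if (any(abs(diag(values)) > 1e-12)) stop("dist_matrix: nonzero diagonal")
  structure(list(labels = rownames(values), values = values,
                 metric = metric, scope = scope),
            class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat("dist_matrix:", x$metric, "on", length(x$labels), "units ( scope",
      x$scope, ")\n")
  invisible(x)
}

#' Lower-triangle values of a distance matrix, named by pair
#' @param dm a [dist_matrix()]
#' @return named numeric vector ("a|b")
#' @export
dm_pairs <- function(dm) {
  n <- length(dm$labels)
  idx <- which(lower.tri(dm$values), arr.ind = TRUE)
  stats::setNames(dm$values[idx],
                  paste(dm$labels[idx[, 2]], dm$labels[idx[, 1]], sep = "|"))
}

#' Write a distance matrix as square TSV
#' @param dm a [dist_matrix()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_dist_matrix <- function(dm, path) {
  df <- data.frame(id = dm$labels, dm$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Bray-Curtis dissimilarity on relative read abundances
#'
#' Reads are converted to per-sample relative abundances internally (no
#' rarefaction); \eqn{BC(x,y) = 1 - 2\sum_i \min(x_i,y_i) /
#' (\sum x_i + \sum y_i)}.
#'
#' @param reads taxa x samples read matrix
#' @param scope dataset scope recorded in the result
#' @return a [dist_matrix()] over samples
#' @export
bray_curtis <- function(reads, scope = "all") {
  m <- t(reads)
  tot <- rowSums(m)
  if (any(tot == 0))
    stop("bray_curtis: zero-sum sample(s): ",
         paste(rownames(m)[tot == 0], collapse = ", "))
  rel <- sweep(m, 1, tot, "/")
  d <- as.matrix(vegan::vegdist(rel, method = "bray"))
  dist_matrix(d, "bray_curtis", scope)
}

#' Locality-level presence/absence incidence
#' @param reads taxa x samples read matrix
#' @param samples a [sample_frame()]
#' @return logical matrix taxa x localities (present if any read in any
#'   sample of the locality)
#' @export
locality_incidence <- function(reads, samples) {
  true <- samples[samples$sample_type == "true_sample", , drop = FALSE]
  true <- true[true$sample_id %in% colnames(reads), , drop = FALSE]
  locs <- sort(unique(true$locality))
  inc <- vapply(locs, function(l)
    rowSums(reads[, true$sample_id[true$locality == l], drop = FALSE]) > 0,
    logical(nrow(reads)))
  colnames(inc) <- locs
  inc
}

#' Sorensen similarity between localities
#'
#' Default mode pools incidence per locality and computes
#' \eqn{S = 2|A \cap B| / (|A| + |B|)} per locality pair. Mode `"sample"`
#' computes Sorensen between every cross-locality sample pair and averages
#' within each locality pair.
#'
#' @param reads taxa x samples read matrix
#' @param samples a [sample_frame()]
#' @param mode `"locality"` (default) or `"sample"`
#' @return list with `pairs` (data.frame `loc1`, `loc2`, `sorensen`) and
#'   `mean`
#' @export
sorensen_localities <- function(reads, samples, mode = c("locality", "sample")) {
  mode <- match.arg(mode)
  inc <- locality_incidence(reads, samples)
  if (any(colSums(inc) == 0))
    stop("sorensen_localities: empty locality: ",
         paste(colnames(inc)[colSums(inc) == 0], collapse = ", "))
  locs <- colnames(inc)
  cmb <- utils::combn(locs, 2)
  val <- numeric(ncol(cmb))
  if (mode == "locality") {
    for (j in seq_len(ncol(cmb))) {
      a <- inc[, cmb[1, j]]; b <- inc[, cmb[2, j]]
      val[j] <- 2 * sum(a & b) / (sum(a) + sum(b))
    }
  } else {
    true <- samples[samples$sample_type == "true_sample", , drop = FALSE]
    true <- true[true$sample_id %in% colnames(reads), , drop = FALSE]
    pres <- reads > 0
    for (j in seq_len(ncol(cmb))) {
      sa <- true$sample_id[true$locality == cmb[1, j]]
      sb <- true$sample_id[true$locality == cmb[2, j]]
      vals <- outer(sa, sb, Vectorize(function(x, y) {
        a <- pres[, x]; b <- pres[, y]
        2 * sum(a & b) / (sum(a) + sum(b))
      }))
      val[j] <- mean(vals)
    }
  }
  list(pairs = data.frame(loc1 = cmb[1, ], loc2 = cmb[2, ], sorensen = val,
                          stringsAsFactors = FALSE),
       mean = mean(val))
}

#' Membership (upset) patterns across localities
#'
#' For each nonempty subset of localities, the number of taxa present in
#' exactly that subset, plus the fraction unique to a single locality and the
#' fraction present everywhere.
#'
#' @param incidence logical taxa x localities matrix
#'   (see [locality_incidence()])
#' @return list with `counts` (data.frame `pattern`, `n_localities`, `count`),
#'   `frac_unique`, `frac_all`
#' @export
membership_patterns <- function(incidence) {
  if (ncol(incidence) < 2) stop("membership_patterns: need >= 2 localities")
  present <- rowSums(incidence) > 0
  inc <- incidence[present, , drop = FALSE]
  pat <- apply(inc, 1, function(r)
    paste(colnames(inc)[r], collapse = "+"))
  tab <- table(pat)
  nloc <- vapply(strsplit(names(tab), "+", fixed = TRUE), length, 1L)
  counts <- data.frame(pattern = names(tab), n_localities = nloc,
                       count = as.integer(tab), stringsAsFactors = FALSE)
  counts <- counts[order(-counts$count), , drop = FALSE]
  total <- nrow(inc)
  list(counts = counts,
       frac_unique = sum(counts$count[counts$n_localities == 1]) / total,
       frac_all = sum(counts$count[counts$n_localities == ncol(inc)]) / total)
}

#' Non-metric multidimensional scaling of a distance matrix
#'
#' Seeded wrapper around [vegan::metaMDS()] (monotone-regression stress
#' minimisation, multiple random starts, best configuration retained).
#'
#' @param dm a [dist_matrix()]
#' @param k number of dimensions (default 2)
#' @param seed integer seed
#' @param trymax maximum random starts (default 20)
#' @return list with `points` (configuration), `stress`, `converged`
#' @export
nmds_ordination <- function(dm, k = 2, seed = 1L, trymax = 20) {
  set.seed(seed)
  fit <- vegan::metaMDS(stats::as.dist(dm$values), k = k, trymax = trymax,
                        trace = 0)
  list(points = fit$points, stress = fit$stress,
       converged = isTRUE(fit$converged > 0) || isTRUE(fit$converged))
}

# Anderson's one-way pseudo-F from squared inter-point distances.
.pseudo_f <- function(d2, g) {
  N <- nrow(d2)
  lev <- unique(g)
  a <- length(lev)
  ss_total <- sum(d2[lower.tri(d2)]) / N
  ss_within <- 0
  for (l in lev) {
    idx <- which(g == l)
    sub <- d2[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[lower.tri(sub)]) / length(idx)
  }
  ss_among <- ss_total - ss_within
  (ss_among / (a - 1)) / (ss_within / (N - a))
}

#' One-way PERMANOVA
#'
#' Permutational multivariate analysis of variance: pseudo-F from among- and
#' within-group sums of squared dissimilarities, with a permutation p-value
#' using the +1 convention, \eqn{p = (\#\{F^* \ge F\} + 1)/(n_{perm} + 1)}.
#' With `exhaustive = TRUE` all label permutations are enumerated and the
#' exact p-value \eqn{\#\{F^* \ge F\}/n!} is returned (tiny designs only).
#'
#' @param dm a [dist_matrix()] over samples
#' @param groups factor of group labels, aligned with `dm$labels`
#' @param n_perm number of permutations (default 999)
#' @param seed integer seed
#' @param exhaustive enumerate all permutations instead of sampling
#' @return list with `f`, `p_value`, `n_perm`, `method`
#' @export
permanova <- function(dm, groups, n_perm = 999, seed = 1L,
                      exhaustive = FALSE) {
  g <- as.character(groups)
  if (length(unique(g)) < 2) stop("permanova: need >= 2 groups")
  if (any(table(g) < 2)) stop("permanova: every group needs >= 2 members")
  d2 <- dm$values^2
  f_obs <- .pseudo_f(d2, g)
  if (exhaustive) {
    perms <- .all_perms(length(g))
    f_perm <- apply(perms, 1, function(idx) .pseudo_f(d2, g[idx]))
    p <- mean(f_perm >= f_obs - 1e-12)
    return(list(f = f_obs, p_value = p, n_perm = nrow(perms),
                method = "exhaustive"))
  }
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    f_b <- .pseudo_f(d2, sample(g))
    if (f_b >= f_obs - 1e-12) hits <- hits + 1L
  }
  list(f = f_obs, p_value = (hits + 1) / (n_perm + 1), n_perm = n_perm,
       method = "sampled")
}

.all_perms <- function(n) {
  if (n > 8) stop("exhaustive permutations limited to n <= 8")
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .all_perms(n - 1)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 1L
  for (i in seq_len(nrow(sub))) for (pos in seq_len(n)) {
    out[r, ] <- append(sub[i, ], n, after = pos - 1L)
    r <- r + 1L
  }
  out
}

#' Pairwise PERMANOVA over group pairs
#' @inheritParams permanova
#' @param p_adjust adjustment method over pairs (default "holm")
#' @return data.frame `group1`, `group2`, `f`, `p`, `p_adj`
#' @export
pairwise_permanova <- function(dm, groups, n_perm = 999, seed = 1L,
                               p_adjust = "holm") {
  g <- as.character(groups)
  lev <- sort(unique(g))
  cmb <- utils::combn(lev, 2)
  f <- p <- numeric(ncol(cmb))
  for (j in seq_len(ncol(cmb))) {
    keep <- g %in% cmb[, j]
    sub <- dist_matrix(dm$values[keep, keep, drop = FALSE], dm$metric,
                       dm$scope)
    res <- permanova(sub, g[keep], n_perm = n_perm, seed = seed + j)
    f[j] <- res$f; p[j] <- res$p_value
  }
  data.frame(group1 = cmb[1, ], group2 = cmb[2, ], f = f, p = p,
             p_adj = stats::p.adjust(p, method = p_adjust),
             stringsAsFactors = FALSE)
}

#' Multivariate dispersion test (permdisp)
#'
#' Distances to group centroids in principal-coordinate space with the
#' negative-eigenvalue correction ([vegan::betadisper()]), then a one-way
#' ANOVA F on those distances with a permutation p-value over group labels
#' (+1 convention; exhaustive enumeration available for tiny designs).
#'
#' @inheritParams permanova
#' @return list with `f`, `p_value`, `group_means` (mean distance to
#'   centroid), `n_perm`, `method`
#' @export
permdisp <- function(dm, groups, n_perm = 999, seed = 1L,
                     exhaustive = FALSE) {
  g <- factor(groups)
  if (nlevels(g) < 2) stop("permdisp: need >= 2 groups")
  if (any(table(g) < 2)) stop("permdisp: every group needs >= 2 members")
  bd <- vegan::betadisper(stats::as.dist(dm$values), g, type = "centroid")
  z <- as.numeric(bd$distances)
  f_of <- function(gg) {
    gm <- tapply(z, gg, mean)
    nn <- tapply(z, gg, length)
    ssb <- sum(nn * (gm - mean(z))^2)
    ssw <- sum((z - gm[gg])^2)
    (ssb / (length(gm) - 1)) / (ssw / (length(z) - length(gm)))
  }
  f_obs <- f_of(g)
  if (exhaustive) {
    perms <- .all_perms(length(z))
    f_perm <- apply(perms, 1, function(idx) f_of(g[idx]))
    p <- mean(f_perm >= f_obs - 1e-12)
    method <- "exhaustive"; n_used <- nrow(perms)
  } else {
    set.seed(seed)
    hits <- 0L
    for (b in seq_len(n_perm))
      if (f_of(sample(g)) >= f_obs - 1e-12) hits <- hits + 1L
    p <- (hits + 1) / (n_perm + 1)
    method <- "sampled"; n_used <- n_perm
  }
  list(f = f_obs, p_value = p,
       group_means = tapply(z, g, mean), n_perm = n_used, method = method)
}

#' Temporal turnover: mean dissimilarity between consecutive time points
#'
#' For each consecutive pair of time points, the mean Bray-Curtis value over
#' all cross-time sample pairs within each locality, averaged over
#' localities. Time points with no samples in a locality are flagged as gaps.
#'
#' @param dm a [dist_matrix()] over samples (Bray-Curtis)
#' @param samples a [sample_frame()]
#' @param time_levels optional ordered vector of time points; default the
#'   sorted unique time points
#' @return data.frame `from`, `to`, `mean_dissimilarity`, `n_pairs`, `gaps`
#' @export
temporal_turnover <- function(dm, samples, time_levels = NULL) {
  true <- samples[samples$sample_type == "true_sample", , drop = FALSE]
  true <- true[true$sample_id %in% dm$labels, , drop = FALSE]
  if (is.null(time_levels)) time_levels <- sort(unique(true$time_point))
  rownames(dm$values) <- colnames(dm$values) <- dm$labels
  out <- list()
  for (i in seq_len(length(time_levels) - 1)) {
    t1 <- time_levels[i]; t2 <- time_levels[i + 1]
    vals <- c(); gaps <- character()
    for (loc in unique(true$locality)) {
      s1 <- true$sample_id[true$locality == loc & true$time_point == t1]
      s2 <- true$sample_id[true$locality == loc & true$time_point == t2]
      if (length(s1) == 0 || length(s2) == 0) { gaps <- c(gaps, loc); next }
      vals <- c(vals, mean(dm$values[s1, s2, drop = FALSE]))
    }
    out[[i]] <- data.frame(from = t1, to = t2,
                           mean_dissimilarity = if (length(vals)) mean(vals)
                                                else NA_real_,
                           n_pairs = length(vals),
                           gaps = paste(gaps, collapse = ","),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Paired comparison of two distance matrices
#'
#' Paired-sample t-test over the sample-pair dissimilarities of two matrices
#' computed on the same sample set (pairing by sample pair).
#'
#' @param dm1,dm2 [dist_matrix()] objects with identical labels
#' @return list with `mean1`, `mean2`, `t`, `p_value`, `df`
#' @export
compare_mean_dissimilarity <- function(dm1, dm2) {
  if (!identical(dm1$labels, dm2$labels))
    stop("compare_mean_dissimilarity: label mismatch")
  v1 <- dm_pairs(dm1); v2 <- dm_pairs(dm2)
  if (isTRUE(all.equal(unname(v1), unname(v2))))
    return(list(mean1 = mean(v1), mean2 = mean(v2), t = 0, p_value = 1,
                df = length(v1) - 1))
  tt <- stats::t.test(v1, v2, paired = TRUE)
  list(mean1 = mean(v1), mean2 = mean(v2), t = unname(tt$statistic),
       p_value = tt$p.value, df = unname(tt$parameter))
}

#' Label samples as warm or cold season by a temperature threshold
#' @param temperature named numeric vector (by sample id), degrees Celsius
#' @param threshold split point (default 20)
#' @return character vector "warm"/"cold" named by sample id
#' @export
season_labels <- function(temperature, threshold = 20) {
  stats::setNames(ifelse(temperature >= threshold, "warm", "cold"),
                  names(temperature))
}
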