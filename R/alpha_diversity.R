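# Rarefied alpha diversity (expected richness, Shannon), group comparisons
# (ANOVA + Tukey for Shannon; Kruskal-Wallis + Dunn for richness), and
# taxonomic composition summaries.

#' Expected MOTU richness under rarefaction
#'
#' Analytic (hypergeometric) expected number of taxa in a without-replacement
#' subsample of `depth` reads:
#' \eqn{E[S] = \sum_i (1 - C(N - N_i, d)/C(N, d))}. Delegates to
#' [vegan::rarefy()].
#'
#' @param counts non-negative integer vector of reads per MOTU
#' @param depth subsample size; must not exceed `sum(counts)`
#' @return expected richness (numeric scalar)
#' @export
rarefied_richness <- function(counts, depth) {
  if (depth > sum(counts))
    stop("rarefied_richness: depth exceeds total reads")
  suppressWarnings(
    as.numeric(vegan::rarefy(matrix(counts, nrow = 1), sample = depth)))
}

#' Shannon diversity (natural log)
#'
#' \eqn{H' = -\sum p_i \ln p_i} over nonzero proportions.
#'
#' @param x counts or relative abundances, non-negative, not all zero
#' @return Shannon index in nats
#' @export
shannon_index <- function(x) {
  if (any(x < 0)) stop("shannon_index: negative abundances")
  if (sum(x) == 0) stop("shannon_index: all-zero input")
  as.numeric(vegan::diversity(x, index = "shannon"))
}

#' Per-sample rarefied alpha diversity
#'
#' Richness is the analytic expected richness at the common depth (the
#' minimum total reads over samples, unless `depth` is given). Shannon is
#' computed on a seeded random without-replacement subsample at that depth
#' ([vegan::rrarefy()]); set `k_draws > 1` to average over several draws.
#'
#' @param motus a [motu_table()] restricted to the scope of interest
#' @param depth rarefaction depth; default `min(colSums(reads))`
#' @param seed integer seed for the rarefied draw(s)
#' @param k_draws number of rarefied draws averaged for Shannon (default 1)
#' @return data.frame `sample_id`, `richness`, `shannon`, `depth_used`
#' @export
alpha_diversity <- function(motus, depth = NULL, seed = 1L, k_draws = 1L) {
  stopifnot(inherits(motus, "motu_table"))
  m <- t(motus$reads)                       # samples x MOTUs
  totals <- rowSums(m)
  if (any(totals == 0)) stop("alpha_diversity: sample with zero reads")
  if (is.null(depth)) depth <- min(totals)
  if (depth > min(totals))
    stop("alpha_diversity: depth exceeds the shallowest sample")
  # vegan warns that read counts are not individual counts; expected here
  rich <- suppressWarnings(as.numeric(vegan::rarefy(m, sample = depth)))
  set.seed(seed)
  sh <- matrix(0, k_draws, nrow(m))
  for (k in seq_len(k_draws)) {
    sub <- suppressWarnings(vegan::rrarefy(m, depth))
    sh[k, ] <- as.numeric(vegan::diversity(sub, index = "shannon"))
  }
  data.frame(sample_id = rownames(m), richness = rich,
             shannon = colMeans(sh), depth_used = depth,
             stringsAsFactors = FALSE)
}

#' Dunn's post-hoc test after Kruskal-Wallis
#'
#' Pairwise z statistics on mean ranks with the tie correction, p-values
#' adjusted across pairs.
#'
#' @param x numeric response
#' @param g grouping factor
#' @param p_adjust adjustment method for [stats::p.adjust()] (default "holm")
#' @return data.frame `group1`, `group2`, `z`, `p`, `p_adj`
#' @export
dunn_test <- function(x, g, p_adjust = "holm") {
  g <- factor(g)
  if (nlevels(g) < 2) stop("dunn_test: need at least two groups")
  r <- rank(x)
  N <- length(x)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  mr <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  pairs <- utils::combn(levels(g), 2)
  z <- p <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[[a]] + 1 / n[[b]]))
    z[j] <- (mr[[a]] - mr[[b]]) / se
    p[j] <- 2 * stats::pnorm(-abs(z[j]))
  }
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z, p = p,
             p_adj = stats::p.adjust(p, method = p_adjust),
             stringsAsFactors = FALSE)
}

#' Compare alpha-diversity values across groups
#'
#' Shannon values are compared with one-way ANOVA plus Tukey HSD pairwise
#' tests; richness with Kruskal-Wallis plus Dunn pairwise tests (the
#' non-parametric route, used when parametric assumptions do not hold for
#' rarefied richness).
#'
#' @param values numeric vector of per-sample alpha values
#' @param groups grouping factor (e.g. locality)
#' @param metric `"shannon"` (parametric) or `"richness"` (rank-based)
#' @return list with `method`, `statistic`, `p_value`, and `pairwise`
#'   (data.frame of pairwise comparisons)
#' @export
compare_alpha <- function(values, groups, metric = c("shannon", "richness")) {
  metric <- match.arg(metric)
  groups <- factor(groups)
  if (nlevels(groups) < 2 || any(table(groups) < 2))
    stop("compare_alpha: need >= 2 groups with >= 2 values each")
  if (metric == "shannon") {
    fit <- stats::aov(values ~ groups)
    an <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit)$groups
    pw <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                     p_adj = tk[, "p adj"], row.names = NULL,
                     stringsAsFactors = FALSE)
    list(method = "anova_tukey", statistic = an[["F value"]][1],
         p_value = an[["Pr(>F)"]][1], pairwise = pw)
  } else {
    if (stats::var(values) == 0) {
      # fully tied data carry no rank information: H is 0 by convention
      pw <- utils::combn(levels(groups), 2)
      return(list(method = "kruskal_dunn", statistic = 0, p_value = 1,
                  pairwise = data.frame(group1 = pw[1, ], group2 = pw[2, ],
                                        z = 0, p = 1, p_adj = 1,
                                        stringsAsFactors = FALSE)))
    }
    kw <- stats::kruskal.test(values, groups)
    pw <- dunn_test(values, groups)
    list(method = "kruskal_dunn", statistic = unname(kw$statistic),
         p_value = kw$p.value, pairwise = pw)
  }
}

#' Per-locality taxonomic composition summary
#'
#' For each locality, the mean over its samples of the per-sample relative
#' read proportions by phylum. Phyla below `min_prop` of a locality's reads
#' are pooled as "Others"; MOTUs with no phylum are reported as
#' "Unidentified". Proportions sum to one per locality.
#'
#' @param motus a [motu_table()] restricted to the dataset scope
#' @param samples a [sample_frame()] (true samples define localities)
#' @param min_prop pooling threshold (default 0.05)
#' @return data.frame `locality`, `phylum`, `proportion`
#' @export
composition_summary <- function(motus, samples, min_prop = 0.05) {
  stopifnot(inherits(motus, "motu_table"), inherits(samples, "sample_frame"))
  phylum <- taxon_at_rank(motus, 1)
  phylum[phylum == ""] <- "Unidentified"
  true <- samples[samples$sample_type == "true_sample", , drop = FALSE]
  true <- true[true$sample_id %in% colnames(motus$reads), , drop = FALSE]
  out <- list()
  for (loc in unique(true$locality)) {
    sids <- true$sample_id[true$locality == loc]
    sub <- motus$reads[, sids, drop = FALSE]
    rel <- sweep(sub, 2, colSums(sub), "/")
    rel[, colSums(sub) == 0] <- 0
    by_phy <- rowsum(rel, group = phylum)
    mean_prop <- rowMeans(by_phy)
    small <- mean_prop < min_prop & rownames(by_phy) != "Unidentified"
    pooled <- c(mean_prop[!small], Others = sum(mean_prop[small]))
    pooled <- pooled[pooled > 0 | names(pooled) != "Others"]
    out[[loc]] <- data.frame(locality = loc, phylum = names(pooled),
                             proportion = unname(pooled),
                             stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
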