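# End-to-end orchestration: filter -> classify -> alpha -> beta ->
# metaphylogeography, with machine-readable outputs and a run manifest.

#' Pipeline configuration
#'
#' @param simulate when TRUE, inputs come from [simulate_dataset()] with
#'   `sim` as configuration; otherwise `esv_path`, `motu_path`,
#'   `sample_path` (and optionally `fasta_path`, `hit_path`) must point to
#'   TSV/FASTA inputs
#' @param sim a [sim_config()] (used when `simulate = TRUE`)
#' @param filter a [filter_config()]
#' @param esv_path,fasta_path,motu_path,sample_path,hit_path input files
#' @param nat_exclusion character vector for [curate_nat()]
#' @param metazoa accepted phyla for [restrict_to_marine_metazoa()]; NULL
#'   skips the restriction
#' @param rarefaction_threshold `"mean"`, `"median"`, or integer, for
#'   [rarefy_motu_reads()]
#' @param n_perm permutations for PERMANOVA/permdisp (default 999)
#' @param seed master seed; per-stage seeds are derived deterministically
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(simulate = TRUE, sim = sim_config(),
                            filter = filter_config(),
                            esv_path = NULL, fasta_path = NULL,
                            motu_path = NULL, sample_path = NULL,
                            hit_path = NULL,
                            nat_exclusion = character(),
                            metazoa = c("Arthropoda", "Cnidaria", "Chordata",
                                        "Annelida", "Mollusca", "Bryozoa",
                                        "Echinodermata", "Porifera"),
                            rarefaction_threshold = "mean",
                            n_perm = 999, seed = 1L) {
  structure(list(simulate = simulate, sim = sim, filter = filter,
                 esv_path = esv_path, fasta_path = fasta_path,
                 motu_path = motu_path, sample_path = sample_path,
                 hit_path = hit_path, nat_exclusion = nat_exclusion,
                 metazoa = metazoa,
                 rarefaction_threshold = rarefaction_threshold,
                 n_perm = n_perm, seed = as.integer(seed)),
            class = "pipeline_config")
}

# per-stage seeds derived from the master seed, kept within 32-bit range
.stage_seed <- function(seed, stage) {
  (as.integer(seed) * 131L + match(stage, c("simulate", "filter", "classify",
                                            "alpha", "beta", "metaphylo"))) %%
    2147483647L
}

#' Load or simulate the pipeline inputs
#' @param cfg a [pipeline_config()]
#' @return list with `esvs`, `motus`, `samples`, `hits` (NULL when absent),
#'   `truth` (simulation only)
#' @export
stage_inputs <- function(cfg) {
  if (isTRUE(cfg$simulate)) {
    sim <- cfg$sim
    sim$seed <- .stage_seed(cfg$seed, "simulate")
    bundle <- simulate_dataset(sim)
    bundle[c("esvs", "motus", "samples", "hits", "truth")]
  } else {
    samples <- read_sample_frame(cfg$sample_path)
    list(esvs = read_esv_table(cfg$esv_path, fasta = cfg$fasta_path,
                               samples = samples),
         motus = read_motu_table(cfg$motu_path, samples = samples),
         samples = samples,
         hits = if (is.null(cfg$hit_path)) NULL
                else read_hit_table(cfg$hit_path),
         truth = NULL)
  }
}

#' Filtering stage: the full curation cascade
#' @param data list with `esvs`, `motus`, `samples`
#' @param cfg a [pipeline_config()]
#' @return filtered `data` plus `log` and `removed_samples`
#' @export
stage_filter <- function(data, cfg) {
  res <- run_filter_cascade(data$esvs, data$motus, data$samples,
                            cfg$filter, metazoa = cfg$metazoa)
  mism <- validate_linkage(res$esvs, res$motus)
  if (nrow(mism) > 0) stop("stage_filter: linkage broken after cascade")
  res
}

#' Classification stage: NIS assignment and dataset partition
#' @param data filtered data list
#' @param hits a [hit_table()] or NULL (stage skipped with a warning)
#' @param cfg a [pipeline_config()]
#' @return `data` with relabeled `motus` plus `nis` (assignment result) and
#'   `nat_ids`; when hits are missing, labels stay COMM_other
#' @export
stage_classify <- function(data, hits, cfg) {
  if (is.null(hits)) {
    warning("stage_classify: no NIS hit table; classification skipped, ",
            "NIS analyses disabled downstream")
    data$motus$dataset_label[] <- "COMM_other"
    data$nis <- NULL
    return(data)
  }
  nis <- assign_nis(hits)
  motus <- partition_datasets(data$motus, nis$nis_ids)
  sp <- nis$best_species$species[match(motus$motu_id, nis$best_species$motu_id)]
  motus$nominal_species[!is.na(sp)] <- sp[!is.na(sp)]
  nat_ids <- curate_nat(motus, cfg$nat_exclusion)
  motus <- partition_datasets(motus, nis$nis_ids, nat_ids)
  data$motus <- motus
  data$nis <- nis
  data$nat_ids <- nat_ids
  data
}

#' Alpha-diversity stage
#' @param data classified data list
#' @param cfg a [pipeline_config()]
#' @return list per dataset scope with the alpha table and locality tests
#' @export
stage_alpha <- function(data, cfg) {
  scopes <- c("COMM", if (any(data$motus$dataset_label == "NIS")) "NIS")
  seed <- .stage_seed(cfg$seed, "alpha")
  out <- list()
  for (sc in scopes) {
    m <- motu_subset(data$motus, dataset_ids(data$motus, sc))
    keep <- colSums(m$reads) > 0
    m <- motu_subset(m, sample_keep = colnames(m$reads)[keep])
    alpha <- alpha_diversity(m, seed = seed)
    loc <- data$samples$locality[match(alpha$sample_id,
                                       data$samples$sample_id)]
    out[[sc]] <- list(
      alpha = alpha,
      shannon_test = compare_alpha(alpha$shannon, loc, "shannon"),
      richness_test = compare_alpha(alpha$richness, loc, "richness"),
      composition = composition_summary(m, data$samples))
  }
  out
}

#' Beta-diversity stage
#' @param data classified data list
#' @param cfg a [pipeline_config()]
#' @return list per dataset scope (Bray-Curtis, Sorensen, membership, NMDS,
#'   PERMANOVA site/month, permdisp, turnover) plus the COMM-vs-NIS paired
#'   comparisons when NIS labels exist
#' @export
stage_beta <- function(data, cfg) {
  has_nis <- any(data$motus$dataset_label == "NIS")
  scopes <- c("COMM", if (has_nis) "NIS")
  seed <- .stage_seed(cfg$seed, "beta")
  out <- list()
  for (sc in scopes) {
    m <- motu_subset(data$motus, dataset_ids(data$motus, sc))
    keep <- colSums(m$reads) > 0
    m <- motu_subset(m, sample_keep = colnames(m$reads)[keep])
    dm <- bray_curtis(m$reads, scope = sc)
    meta <- data$samples[match(dm$labels, data$samples$sample_id), ]
    out[[sc]] <- list(
      bray_curtis = dm,
      sorensen = sorensen_localities(m$reads, data$samples),
      membership = membership_patterns(locality_incidence(m$reads,
                                                          data$samples)),
      nmds = nmds_ordination(dm, seed = seed),
      permanova_site = permanova(dm, meta$locality, cfg$n_perm, seed),
      permanova_month = permanova(dm, meta$time_point, cfg$n_perm, seed + 1L),
      permdisp_site = permdisp(dm, meta$locality, cfg$n_perm, seed + 2L),
      turnover = temporal_turnover(dm, data$samples))
  }
  if (has_nis &&
      identical(out$COMM$bray_curtis$labels, out$NIS$bray_curtis$labels)) {
    out$comparison <- list(
      mean_bc = compare_mean_dissimilarity(out$COMM$bray_curtis,
                                           out$NIS$bray_curtis),
      sorensen = {
        v1 <- out$COMM$sorensen$pairs$sorensen
        v2 <- out$NIS$sorensen$pairs$sorensen
        tt <- stats::t.test(v1, v2, paired = TRUE)
        list(mean_comm = mean(v1), mean_nis = mean(v2),
             t = unname(tt$statistic), p_value = tt$p.value)
      })
  }
  out
}

#' Metaphylogeography stage
#' @param data classified data list (needs NIS and NAT labels)
#' @param cfg a [pipeline_config()]
#' @return list with richness summaries and tests, log-log regression,
#'   read rarefaction, randomization balance test, and per-dataset mean
#'   Jost's D with the paired comparison
#' @export
stage_metaphylo <- function(data, cfg) {
  lab <- data$motus$dataset_label
  if (!any(lab == "NIS") || !any(lab == "NAT"))
    stop("stage_metaphylo: needs both NIS and NAT labels")
  seed <- .stage_seed(cfg$seed, "metaphylo")
  summ <- esv_richness_summary(data$esvs, data$motus)
  reg <- reads_esvs_regression(summ)
  rar <- rarefy_motu_reads(data$esvs, data$motus,
                           threshold = cfg$rarefaction_threshold, seed = seed)
  summ_rar <- esv_richness_summary(rar$esvs, data$motus)
  nis_counts <- summ$n_esvs[summ$dataset == "NIS"]
  nat_counts <- summ$n_esvs[summ$dataset == "NAT"]
  bal <- randomization_balance_test(
    nis_counts, nat_counts,
    target_size = min(length(nis_counts), length(nat_counts)),
    seed = seed + 1L)
  d_nis <- mean_d_between_localities(data$esvs, data$motus, data$samples,
                                     "NIS")
  d_nat <- mean_d_between_localities(data$esvs, data$motus, data$samples,
                                     "NAT")
  list(summary = summ,
       richness_test = esv_richness_test(summ),
       regression = reg,
       rarefaction = rar[c("threshold_used", "eliminated")],
       richness_test_rarefied = esv_richness_test(summ_rar),
       balance = bal,
       d_nis = d_nis, d_nat = d_nat,
       d_comparison = compare_jost_d(d_nis, d_nat))
}

#' Run the full pipeline and write results
#'
#' Executes filter, classify, alpha, beta and metaphylogeography stages in
#' order and writes every intermediate table, removal log, JSON report and a
#' run manifest (seed, thresholds, package version) under `outdir`. Any stage
#' failure aborts with the stage name and cause.
#'
#' @param cfg a [pipeline_config()], or a path to a YAML/JSON file with its
#'   fields
#' @param outdir output directory (created if absent)
#' @return invisibly, the list of in-memory stage results
#' @export
run_pipeline <- function(cfg = pipeline_config(), outdir = tempfile("run")) {
  if (is.character(cfg)) cfg <- .read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  data <- run_stage("inputs", stage_inputs(cfg))
  filt <- run_stage("filter", stage_filter(data, cfg))
  write_esv_table(filt$esvs, file.path(outdir, "esv_table_filtered.tsv"))
  write_motu_table(filt$motus, file.path(outdir, "motu_table_filtered.tsv"))
  write_sample_frame(filt$samples, file.path(outdir, "samples_retained.tsv"))
  if (!is.null(filt$log))
    write_removal_log(filt$log, file.path(outdir, "removal_log.tsv"))
  filt$hits <- data$hits
  cls <- run_stage("classify", stage_classify(filt, data$hits, cfg))
  write_motu_table(cls$motus, file.path(outdir, "motu_table_labeled.tsv"))
  alpha <- run_stage("alpha", stage_alpha(cls, cfg))
  beta <- run_stage("beta", stage_beta(cls, cfg))
  metaphylo <- if (!is.null(cls$nis) && any(cls$motus$dataset_label == "NAT"))
    run_stage("metaphylo", stage_metaphylo(cls, cfg)) else NULL
  results <- list(filter = filt[c("removed_samples")],
                  classify = cls[c("nis", "nat_ids")],
                  alpha = alpha, beta = beta, metaphylo = metaphylo)
  jsonlite::write_json(.jsonable(results),
                       file.path(outdir, "reports.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  manifest <- list(package_version = as.character(
                     utils::packageVersion("metaport")),
                   seed = cfg$seed, n_perm = cfg$n_perm,
                   rarefaction_threshold = cfg$rarefaction_threshold,
                   filter = unclass(cfg$filter), simulate = cfg$simulate)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(data = cls, alpha = alpha, beta = beta,
                 metaphylo = metaphylo, outdir = outdir))
}

# strip heavy/circular members before JSON serialisation
.jsonable <- function(x) {
  if (inherits(x, "dist_matrix"))
    return(list(metric = x$metric, scope = x$scope,
                mean = mean(dm_pairs(x))))
  if (inherits(x, c("esv_table", "motu_table"))) return(NULL)
  if (is.list(x) && !is.data.frame(x)) return(lapply(x, .jsonable))
  x
}

.read_pipeline_config <- function(path) {
  fields <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required to read YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  base <- pipeline_config()
  known <- intersect(names(fields), names(base))
  for (f in known) {
    if (f == "sim") base$sim <- do.call(sim_config, fields$sim)
    else if (f == "filter") base$filter <- do.call(filter_config,
                                                   fields$filter)
    else base[[f]] <- fields[[f]]
  }
  base$seed <- as.integer(base$seed)
  base
}
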