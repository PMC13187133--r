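# Post-denoising curation cascade: blank-based contamination filter, dual
# abundance filter, pseudogene (stop codon / conserved residue) filter,
# sample-depth filter. All thresholds use strict inequalities, matching the
# "more than" / "less than" wording of the rules they implement.

#' Filter configuration
#'
#' @param blank_fraction_threshold an ESV is treated as a contaminant when
#'   its reads in blanks + PCR negatives exceed this fraction of its reads in
#'   true samples (default 0.10)
#' @param rel_abundance_threshold per-sample relative-abundance floor; cells
#'   below `rel_abundance_threshold * sample total` are zeroed
#'   (default 5e-5, i.e. 0.005\%)
#' @param min_reads_per_esv_sample absolute per-cell floor applied after the
#'   relative one; cells with fewer reads are zeroed (default 5)
#' @param min_sample_depth true samples with fewer total reads are discarded
#'   (default 9500)
#' @param genetic_codes NCBI translation-table ids checked by the pseudogene
#'   filter; defaults to the mitochondrial tables applicable to metazoans
#'   available in Biostrings (ids 2, 4, 5, 9, 13, 14, 21, 24)
#' @param conserved_positions optional named list mapping amino-acid position
#'   within the translated fragment to the allowed residue(s), e.g.
#'   `list("20" = "H")`; empty list disables the check
#' @param reading_frame 0-based offset (bases skipped before the first codon),
#'   in 0:2; default 2, the customary frame of the Leray COI fragment
#' @param blank_denominator `"true_samples"` (default) or `"all_samples"`:
#'   what the contaminant fraction is taken over
#' @return a `filter_config` list
#' @export
filter_config <- function(blank_fraction_threshold = 0.10,
                          rel_abundance_threshold = 0.00005,
                          min_reads_per_esv_sample = 5L,
                          min_sample_depth = 9500L,
                          genetic_codes = c("2", "4", "5", "9", "13", "14",
                                            "21", "24"),
                          conserved_positions = list(),
                          reading_frame = 2L,
                          blank_denominator = c("true_samples", "all_samples")) {
  stopifnot(blank_fraction_threshold >= 0, rel_abundance_threshold >= 0,
            min_reads_per_esv_sample >= 0, min_sample_depth >= 0,
            reading_frame %in% 0:2)
  blank_denominator <- match.arg(blank_denominator)
  structure(list(blank_fraction_threshold = blank_fraction_threshold,
                 rel_abundance_threshold = rel_abundance_threshold,
                 min_reads_per_esv_sample = as.integer(min_reads_per_esv_sample),
                 min_sample_depth = as.integer(min_sample_depth),
                 genetic_codes = as.character(genetic_codes),
                 conserved_positions = conserved_positions,
                 reading_frame = as.integer(reading_frame),
                 blank_denominator = blank_denominator),
            class = "filter_config")
}

.removal_log <- function(esv_id = character(), stage = character(),
                         reason = character(), reads_removed = numeric()) {
  data.frame(esv_id = esv_id, stage = stage, reason = reason,
             reads_removed = reads_removed, stringsAsFactors = FALSE)
}

#' Blank-based contamination filter
#'
#' Deletes any ESV whose summed reads in blanks and PCR negatives exceed
#' `blank_fraction_threshold` of its summed reads in true samples (strict
#' "more than"). ESVs seen only in controls are always deleted. Surviving
#' ESVs keep their control-column reads for bookkeeping; downstream analyses
#' should drop control columns via [drop_control_samples()].
#'
#' @param esvs an [esv_table()]
#' @param samples a [sample_frame()]
#' @param cfg a [filter_config()]
#' @return list with elements `esvs` (filtered table) and `log` (removal log)
#' @export
blank_filter <- function(esvs, samples, cfg = filter_config()) {
  stopifnot(inherits(esvs, "esv_table"), inherits(samples, "sample_frame"))
  ctrl <- intersect(sample_ids(samples, "control"), colnames(esvs$reads))
  true <- intersect(sample_ids(samples, "true_sample"), colnames(esvs$reads))
  if (length(ctrl) == 0) {
    warning("blank_filter: no blank or negative samples present; no-op")
    return(list(esvs = esvs, log = .removal_log()))
  }
  in_ctrl <- rowSums(esvs$reads[, ctrl, drop = FALSE])
  in_true <- rowSums(esvs$reads[, true, drop = FALSE])
  denom <- if (cfg$blank_denominator == "true_samples") in_true
           else in_true + in_ctrl
  # zero denominator with control reads present -> contaminant by definition
  contaminated <- (in_ctrl > cfg$blank_fraction_threshold * denom) & in_ctrl > 0
  removed <- esvs$esv_id[contaminated]
  log <- .removal_log(removed, rep("blank_filter", length(removed)),
                      rep(sprintf("control reads > %g of true-sample reads",
                                  cfg$blank_fraction_threshold),
                          length(removed)),
                      (in_ctrl + in_true)[contaminated])
  list(esvs = esv_subset(esvs, esvs$esv_id[!contaminated]), log = log)
}

#' Drop control (blank and PCR negative) columns from a table
#' @param x an [esv_table()] or [motu_table()]
#' @param samples a [sample_frame()]
#' @return `x` restricted to true-sample columns
#' @export
drop_control_samples <- function(x, samples) {
  true <- sample_ids(samples, "true_sample")
  if (inherits(x, "esv_table")) esv_subset(x, sample_keep = true)
  else motu_subset(x, sample_keep = true)
}

#' Dual abundance filter
#'
#' Per sample, in order: (i) cells whose reads are less than
#' `rel_abundance_threshold` of the sample total are set to zero; (ii) cells
#' with fewer than `min_reads_per_esv_sample` reads, evaluated on the
#' post-step-(i) values, are set to zero. ESVs left with all-zero rows are
#' dropped. The step order matters and is fixed: sample totals for step (i)
#' are the pre-filter totals.
#'
#' @param esvs an [esv_table()] (control columns already excluded)
#' @param cfg a [filter_config()]
#' @return list with elements `esvs` and `log`
#' @export
dual_abundance_filter <- function(esvs, cfg = filter_config()) {
  stopifnot(inherits(esvs, "esv_table"))
  reads <- esvs$reads
  totals <- colSums(reads)
  floor_rel <- matrix(cfg$rel_abundance_threshold * totals,
                      nrow(reads), ncol(reads), byrow = TRUE)
  step1 <- reads
  step1[reads < floor_rel] <- 0                     # strict "less than"
  step2 <- step1
  step2[step1 < cfg$min_reads_per_esv_sample & step1 > 0] <- 0
  step2[step1 == 0] <- 0
  dropped <- rowSums(step2) == 0
  log <- .removal_log(esvs$esv_id[dropped],
                      rep("dual_abundance_filter", sum(dropped)),
                      rep("all cells below abundance thresholds", sum(dropped)),
                      rowSums(reads)[dropped])
  out <- esv_table(step2[!dropped, , drop = FALSE],
                   esvs$motu_id[!dropped],
                   if (is.null(esvs$sequence)) NULL else
                     esvs$sequence[!dropped])
  list(esvs = out, log = log)
}

# Translate fragments from a 0-based frame offset under one NCBI code id;
# vectorised over sequences, returns amino-acid strings.
.translate_frame <- function(seqs, frame, code_id) {
  n <- nchar(seqs)
  if (any(n - frame < 3)) stop("sequence too short for reading frame")
  sub <- substr(seqs, frame + 1, frame + 3 * ((n - frame) %/% 3))
  as.character(Biostrings::translate(
    Biostrings::DNAStringSet(sub),
    genetic.code = Biostrings::getGeneticCode(code_id),
    if.fuzzy.codon = "X"))
}

#' Pseudogene filter (stop codons and conserved residues)
#'
#' Translates each ESV's sequence in the configured reading frame under each
#' configured mitochondrial genetic code. An ESV is deleted when (a) every
#' configured code yields at least one in-frame stop (no code under which the
#' sequence is plausibly functional), or (b) a stop-free translation exists
#' but violates a configured conserved-residue constraint. Such sequences are
#' the signature of nuclear mitochondrial inserts (numts) and other
#' pseudogenes.
#'
#' @param esvs an [esv_table()] with sequences attached
#' @param cfg a [filter_config()]
#' @return list with elements `esvs` and `log`
#' @export
pseudogene_filter <- function(esvs, cfg = filter_config()) {
  stopifnot(inherits(esvs, "esv_table"))
  if (is.null(esvs$sequence))
    stop("pseudogene_filter: sequences not attached")
  bad_len <- nchar(esvs$sequence) == 0
  if (any(bad_len))
    stop("pseudogene_filter: zero-length sequence for: ",
         paste(esvs$esv_id[bad_len], collapse = ", "))
  # one vectorised translation per genetic code
  aa_by_code <- lapply(cfg$genetic_codes, function(code)
    .translate_frame(toupper(esvs$sequence), cfg$reading_frame, code))
  stop_by_code <- vapply(aa_by_code, function(a)
    grepl("*", a, fixed = TRUE), logical(length(esvs$esv_id)))
  stop_by_code <- matrix(stop_by_code, nrow = length(esvs$esv_id))
  delete <- apply(stop_by_code, 1, all)
  reason <- ifelse(delete, "in-frame stop under every configured genetic code",
                   "")
  if (length(cfg$conserved_positions) > 0) {
    for (i in which(!delete)) {
      best <- aa_by_code[[which(!stop_by_code[i, ])[1]]][i]
      for (pos in names(cfg$conserved_positions)) {
        p <- as.integer(pos)
        allowed <- cfg$conserved_positions[[pos]]
        if (p <= nchar(best) && !substr(best, p, p) %in% allowed) {
          delete[i] <- TRUE
          reason[i] <- sprintf("conserved residue violated at position %d", p)
          break
        }
      }
    }
  }
  log <- .removal_log(esvs$esv_id[delete],
                      rep("pseudogene_filter", sum(delete)),
                      reason[delete], rowSums(esvs$reads)[delete])
  list(esvs = esv_subset(esvs, esvs$esv_id[!delete]), log = log)
}

#' Sample-depth filter
#'
#' Removes true samples whose total reads are less than `min_sample_depth`
#' (strict "less than"; a sample at exactly the threshold is retained) from
#' the ESV table and the sample frame.
#'
#' @param esvs an [esv_table()]
#' @param samples a [sample_frame()]
#' @param cfg a [filter_config()]
#' @return list with elements `esvs`, `samples`, and `removed` (sample ids)
#' @export
sample_depth_filter <- function(esvs, samples, cfg = filter_config()) {
  stopifnot(inherits(esvs, "esv_table"), inherits(samples, "sample_frame"))
  true <- intersect(sample_ids(samples, "true_sample"), colnames(esvs$reads))
  depth <- colSums(esvs$reads[, true, drop = FALSE])
  shallow <- true[depth < cfg$min_sample_depth]
  keep_cols <- setdiff(colnames(esvs$reads), shallow)
  if (length(intersect(keep_cols, true)) == 0)
    stop("sample_depth_filter: all true samples removed")
  out <- esv_subset(esvs, sample_keep = keep_cols)
  # drop ESVs emptied by the column removal
  out <- esv_subset(out, out$esv_id[rowSums(out$reads) > 0])
  sf <- samples[!samples$sample_id %in% shallow, , drop = FALSE]
  class(sf) <- c("sample_frame", "data.frame")
  list(esvs = out, samples = sf, removed = shallow)
}

#' Restrict a MOTU table to marine metazoan taxa
#'
#' @param motus a [motu_table()]
#' @param esvs the companion [esv_table()]
#' @param keep either a character vector of accepted phyla (rank 1 of the
#'   lineage) or a predicate `function(taxonomy) -> logical`
#' @return list with elements `motus`, `esvs`, and `dropped` (MOTU ids)
#' @export
restrict_to_marine_metazoa <- function(motus, esvs, keep) {
  stopifnot(inherits(motus, "motu_table"))
  ok <- if (is.function(keep)) {
    vapply(motus$taxonomy, keep, TRUE, USE.NAMES = FALSE)
  } else {
    taxon_at_rank(motus, 1) %in% keep
  }
  kept_ids <- motus$motu_id[ok]
  list(motus = motu_subset(motus, kept_ids),
       esvs = esv_subset(esvs, esvs$esv_id[esvs$motu_id %in% kept_ids]),
       dropped = motus$motu_id[!ok])
}

#' Run the full curation cascade
#'
#' Applies, in order: blank filter, exclusion of control columns, dual
#' abundance filter, pseudogene filter (when sequences are attached),
#' optional metazoan restriction, and the sample-depth filter; the MOTU table
#' is rebuilt from surviving ESVs after every stage, so linkage always holds.
#'
#' @param esvs an [esv_table()]
#' @param motus a [motu_table()]
#' @param samples a [sample_frame()]
#' @param cfg a [filter_config()]
#' @param metazoa optional `keep` argument for [restrict_to_marine_metazoa()]
#' @return list with `esvs`, `motus`, `samples`, `log` (row-bound removal
#'   logs), and `removed_samples`
#' @export
run_filter_cascade <- function(esvs, motus, samples, cfg = filter_config(),
                               metazoa = NULL) {
  logs <- list()
  b <- blank_filter(esvs, samples, cfg)
  logs$blank <- b$log
  cur <- drop_control_samples(b$esvs, samples)
  d <- dual_abundance_filter(cur, cfg)
  logs$dual <- d$log
  cur <- d$esvs
  if (!is.null(cur$sequence)) {
    p <- pseudogene_filter(cur, cfg)
    logs$pseudo <- p$log
    cur <- p$esvs
  }
  motus2 <- rebuild_motu_table(cur, motus)
  if (!is.null(metazoa)) {
    m <- restrict_to_marine_metazoa(motus2, cur, metazoa)
    motus2 <- m$motus
    cur <- m$esvs
  }
  s <- sample_depth_filter(cur, samples, cfg)
  cur <- s$esvs
  motus2 <- rebuild_motu_table(cur, motus2)
  list(esvs = cur, motus = motus2, samples = s$samples,
       log = do.call(rbind, logs), removed_samples = s$removed)
}

#' Write a removal log to TSV
#' @param log removal-log data.frame from a filter stage
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_removal_log <- function(log, path) {
  utils::write.table(log, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
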