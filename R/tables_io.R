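#' @importFrom stats aov TukeyHSD kruskal.test wilcox.test t.test lm anova
#'   cor cor.test p.adjust pnorm rbinom rlnorm rmultinom rnbinom rgamma
#'   rhyper runif setNames coef as.dist cmdscale dist
#' @importFrom utils read.delim write.table combn head
NULL

# ---------------------------------------------------------------------------
# S3 containers: sample_frame, esv_table, motu_table, hit_table
# ---------------------------------------------------------------------------

SAMPLE_TYPES <- c("true_sample", "blank", "pcr_negative")

#' Sample metadata frame
#'
#' Defines the strata used for filtering and grouping: which columns of the
#' read tables are true samples and which are controls (blanks and PCR
#' negatives), and the locality / time point / replicate of each true sample.
#'
#' @param df data.frame with columns `sample_id`, `locality`, `time_point`,
#'   `replicate`, `sample_type`. `sample_type` must be one of
#'   `"true_sample"`, `"blank"`, `"pcr_negative"`. Controls may have `NA`
#'   locality and time point.
#' @return A `sample_frame` object (a validated data.frame).
#' @export
sample_frame <- function(df) {
  req <- c("sample_id", "locality", "time_point", "replicate", "sample_type")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop("sample_frame: missing columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[, req]
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("sample_frame: duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  bad <- setdiff(unique(df$sample_type), SAMPLE_TYPES)
  if (length(bad) > 0)
    stop("sample_frame: unknown sample_type: ", paste(bad, collapse = ", "))
  is_true <- df$sample_type == "true_sample"
  if (any(is_true & (is.na(df$locality) | is.na(df$time_point))))
    stop("sample_frame: every true_sample needs locality and time_point")
  df$locality <- as.character(df$locality)
  df$time_point <- as.character(df$time_point)
  class(df) <- c("sample_frame", "data.frame")
  df
}

#' @export
print.sample_frame <- function(x, ...) {
  cat("sample_frame:", nrow(x), "samples (",
      sum(x$sample_type == "true_sample"), "true,",
      sum(x$sample_type != "true_sample"), "controls )\n")
  invisible(x)
}

#' Sample ids of a given type
#' @param samples a [sample_frame()]
#' @param type one of `"true_sample"`, `"blank"`, `"pcr_negative"`, or
#'   `"control"` (blanks plus negatives)
#' @return character vector of sample ids
#' @export
sample_ids <- function(samples, type = "true_sample") {
  stopifnot(inherits(samples, "sample_frame"))
  if (type == "control")
    samples$sample_id[samples$sample_type %in% c("blank", "pcr_negative")]
  else samples$sample_id[samples$sample_type == type]
}

.check_reads <- function(reads, what) {
  if (!is.matrix(reads)) stop(what, ": reads must be a matrix")
  # a filter may legitimately empty the table: 0-row matrices carry no
  # rownames, which is fine
  if ((nrow(reads) > 0 && is.null(rownames(reads))) ||
      is.null(colnames(reads)))
    stop(what, ": reads matrix needs row and column names")
  if (any(reads < 0)) stop(what, ": negative read counts")
  if (any(reads != round(reads))) stop(what, ": non-integer read counts")
  storage.mode(reads) <- "double"  # avoid integer overflow on sums
  reads
}

#' ESV (haplotype) read table
#'
#' The haplotype-level record: reads per exact sequence variant per sample,
#' each ESV linked to its parent MOTU and optionally carrying its nucleotide
#' sequence.
#'
#' @param reads non-negative integer matrix, rows named by ESV id, columns by
#'   sample id
#' @param motu_id character vector (parallel to rows, or named by ESV id)
#'   giving the MOTU each ESV belongs to
#' @param sequence optional character vector of IUPAC DNA sequences, parallel
#'   to rows or named by ESV id
#' @return An `esv_table` object.
#' @export
esv_table <- function(reads, motu_id, sequence = NULL) {
  reads <- .check_reads(reads, "esv_table")
  ids <- if (is.null(rownames(reads))) character(0) else rownames(reads)
  if (anyDuplicated(ids))
    stop("esv_table: duplicate esv_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  motu_id <- .align_vec(motu_id, ids, "motu_id")
  if (!is.null(sequence)) {
    sequence <- .align_vec(sequence, ids, "sequence")
    if (any(!grepl("^[ACGTRYSWKMBDHVN-]*$", toupper(sequence))))
      stop("esv_table: non-IUPAC characters in sequence of: ",
           paste(ids[!grepl("^[ACGTRYSWKMBDHVN-]*$", toupper(sequence))],
                 collapse = ", "))
  }
  structure(list(esv_id = ids, motu_id = motu_id, sequence = sequence,
                 reads = reads),
            class = "esv_table")
}

.align_vec <- function(v, ids, what) {
  if (!is.null(names(v))) {
    miss <- setdiff(ids, names(v))
    if (length(miss) > 0)
      stop("esv_table: ", what, " missing for: ", paste(miss, collapse = ", "))
    v <- v[ids]
  } else if (length(v) != length(ids)) {
    stop("esv_table: ", what, " length mismatch")
  }
  stats::setNames(as.character(v), ids)
}

#' @export
print.esv_table <- function(x, ...) {
  cat("esv_table:", length(x$esv_id), "ESVs x", ncol(x$reads), "samples;",
      length(unique(x$motu_id)), "MOTUs;",
      if (is.null(x$sequence)) "no sequences" else "sequences attached", "\n")
  invisible(x)
}

#' MOTU read table
#'
#' The species-proxy record: reads per MOTU per sample, with a ranked
#' taxonomy string, an optional nominal species, and the dataset label
#' (NIS / NAT / COMM_other / excluded).
#'
#' @param reads non-negative integer matrix, rows named by MOTU id
#' @param taxonomy character vector of semicolon-delimited ranked lineages
#'   (phylum;class;order;family;genus;species — absent ranks empty)
#' @param nominal_species optional character vector (NA where unassigned)
#' @param dataset_label character vector in
#'   `c("NIS","NAT","COMM_other","excluded")`; default `"COMM_other"`
#' @return A `motu_table` object.
#' @export
motu_table <- function(reads, taxonomy = NULL, nominal_species = NULL,
                       dataset_label = NULL) {
  reads <- .check_reads(reads, "motu_table")
  ids <- if (is.null(rownames(reads))) character(0) else rownames(reads)
  if (anyDuplicated(ids))
    stop("motu_table: duplicate motu_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (is.null(taxonomy)) taxonomy <- rep("", length(ids))
  taxonomy <- .align_vec(taxonomy, ids, "taxonomy")
  if (is.null(nominal_species)) nominal_species <- rep(NA_character_, length(ids))
  nominal_species <- stats::setNames(as.character(
    if (!is.null(names(nominal_species))) nominal_species[ids] else nominal_species), ids)
  if (is.null(dataset_label)) dataset_label <- rep("COMM_other", length(ids))
  dataset_label <- .align_vec(dataset_label, ids, "dataset_label")
  bad <- setdiff(unique(dataset_label), c("NIS", "NAT", "COMM_other", "excluded"))
  if (length(bad) > 0)
    stop("motu_table: unknown dataset_label: ", paste(bad, collapse = ", "))
  structure(list(motu_id = ids, taxonomy = taxonomy,
                 nominal_species = nominal_species,
                 dataset_label = dataset_label, reads = reads),
            class = "motu_table")
}

#' @export
print.motu_table <- function(x, ...) {
  tab <- table(x$dataset_label)
  cat("motu_table:", length(x$motu_id), "MOTUs x", ncol(x$reads), "samples (",
      paste(names(tab), tab, sep = "=", collapse = ", "), ")\n")
  invisible(x)
}

#' Reference-database hit table
#'
#' Per-MOTU best matches against a curated reference (BLAST tabular style),
#' with percent identity and percent query coverage. A MOTU may have several
#' hits.
#'
#' @param df data.frame with columns `motu_id`, `subject_species`,
#'   `identity`, `coverage` (both percentages in \[0, 100\])
#' @return A `hit_table` object.
#' @export
hit_table <- function(df) {
  req <- c("motu_id", "subject_species", "identity", "coverage")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop("hit_table: missing columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[, req]
  if (any(df$identity < 0 | df$identity > 100, na.rm = TRUE) ||
      any(df$coverage < 0 | df$coverage > 100, na.rm = TRUE))
    stop("hit_table: identity/coverage outside [0, 100]")
  class(df) <- c("hit_table", "data.frame")
  df
}

# ---------------------------------------------------------------------------
# Subsetting helpers (used throughout the filter cascade)
# ---------------------------------------------------------------------------

#' Subset an ESV table by row and/or column
#' @param esvs an [esv_table()]
#' @param esv_keep character vector of ESV ids to keep (NULL = all)
#' @param sample_keep character vector of sample ids to keep (NULL = all)
#' @return the subsetted `esv_table`
#' @export
esv_subset <- function(esvs, esv_keep = NULL, sample_keep = NULL) {
  stopifnot(inherits(esvs, "esv_table"))
  if (is.null(esv_keep)) esv_keep <- esvs$esv_id
  if (is.null(sample_keep)) sample_keep <- colnames(esvs$reads)
  esv_keep <- intersect(esvs$esv_id, esv_keep)
  sample_keep <- intersect(colnames(esvs$reads), sample_keep)
  esv_table(esvs$reads[esv_keep, sample_keep, drop = FALSE],
            esvs$motu_id[esv_keep],
            if (is.null(esvs$sequence)) NULL else esvs$sequence[esv_keep])
}

#' Subset a MOTU table by row and/or column
#' @param motus a [motu_table()]
#' @param motu_keep character vector of MOTU ids to keep (NULL = all)
#' @param sample_keep character vector of sample ids to keep (NULL = all)
#' @return the subsetted `motu_table`
#' @export
motu_subset <- function(motus, motu_keep = NULL, sample_keep = NULL) {
  stopifnot(inherits(motus, "motu_table"))
  if (is.null(motu_keep)) motu_keep <- motus$motu_id
  if (is.null(sample_keep)) sample_keep <- colnames(motus$reads)
  motu_keep <- intersect(motus$motu_id, motu_keep)
  sample_keep <- intersect(colnames(motus$reads), sample_keep)
  motu_table(motus$reads[motu_keep, sample_keep, drop = FALSE],
             motus$taxonomy[motu_keep], motus$nominal_species[motu_keep],
             motus$dataset_label[motu_keep])
}

#' Rebuild MOTU read sums from an ESV table
#'
#' After any ESV-level filter, MOTU read counts must be regenerated as the
#' per-sample sums over surviving member ESVs; MOTUs with no surviving ESV
#' are dropped. Taxonomy, nominal species and dataset labels are carried over
#' from `motus`.
#'
#' @param esvs an [esv_table()]
#' @param motus the companion [motu_table()] providing annotations
#' @return an updated `motu_table`
#' @export
rebuild_motu_table <- function(esvs, motus) {
  stopifnot(inherits(esvs, "esv_table"), inherits(motus, "motu_table"))
  orphan <- setdiff(unique(esvs$motu_id), motus$motu_id)
  if (length(orphan) > 0)
    stop("rebuild_motu_table: ESVs reference unknown MOTUs: ",
         paste(orphan, collapse = ", "))
  keep <- intersect(motus$motu_id, unique(esvs$motu_id))
  agg <- rowsum(esvs$reads, group = esvs$motu_id, reorder = FALSE)
  agg <- agg[keep, , drop = FALSE]
  motu_table(agg, motus$taxonomy[keep], motus$nominal_species[keep],
             motus$dataset_label[keep])
}

#' Extract a taxonomic rank from the delimited lineage string
#' @param motus a [motu_table()]
#' @param rank 1-based rank position (1 = phylum in the default layout)
#' @return character vector named by MOTU id ("" where absent)
#' @export
taxon_at_rank <- function(motus, rank = 1) {
  parts <- strsplit(motus$taxonomy, ";", fixed = TRUE)
  out <- vapply(parts, function(p) if (length(p) >= rank) p[rank] else "", "")
  stats::setNames(out, motus$motu_id)
}

# ---------------------------------------------------------------------------
# TSV / FASTA I/O
# ---------------------------------------------------------------------------

.read_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "", comment.char = "")
}

.resolve_sample_cols <- function(df_names, id_cols, samples) {
  other <- setdiff(df_names, id_cols)
  if (is.null(samples)) return(other)
  known <- samples$sample_id
  unknown <- setdiff(other, known)
  if (length(unknown) > 0)
    stop("unknown sample columns (absent from sample_frame): ",
         paste(unknown, collapse = ", "))
  intersect(known, other)
}

#' Read an ESV table from TSV (and sequences from FASTA)
#'
#' The TSV must have one row per ESV, an id column, a MOTU membership column,
#' and one column per sample. Column names for ids are configurable via
#' `col_map` so supplementary-style layouts can be ingested directly.
#'
#' @param path TSV file path
#' @param fasta optional FASTA path; record ids must match ESV ids
#' @param samples optional [sample_frame()]; when given, sample columns are
#'   identified by membership and unknown columns are an error
#' @param col_map list with entries `esv_id` and `motu_id` naming the id
#'   columns in the file
#' @return an [esv_table()]
#' @export
read_esv_table <- function(path, fasta = NULL, samples = NULL,
                           col_map = list(esv_id = "esv_id",
                                          motu_id = "motu_id")) {
  df <- .read_tsv(path)
  for (col in c(col_map$esv_id, col_map$motu_id))
    if (!col %in% names(df)) stop("read_esv_table: missing column: ", col)
  ids <- as.character(df[[col_map$esv_id]])
  if (anyDuplicated(ids))
    stop("read_esv_table: duplicate esv_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  scols <- .resolve_sample_cols(names(df), c(col_map$esv_id, col_map$motu_id),
                                samples)
  if (length(scols) == 0) stop("read_esv_table: no sample columns found")
  reads <- as.matrix(df[, scols, drop = FALSE])
  rownames(reads) <- ids
  seqs <- NULL
  if (!is.null(fasta)) {
    ss <- Biostrings::readDNAStringSet(fasta)
    nm <- sub("\\s.*$", "", names(ss))
    miss <- setdiff(ids, nm)
    if (length(miss) > 0)
      stop("read_esv_table: FASTA missing sequences for: ",
           paste(miss, collapse = ", "))
    seqs <- stats::setNames(as.character(ss), nm)[ids]
  }
  esv_table(reads, stats::setNames(as.character(df[[col_map$motu_id]]), ids),
            seqs)
}

#' Write an ESV table to TSV (and sequences to FASTA)
#' @param esvs an [esv_table()]
#' @param path output TSV path
#' @param fasta optional output FASTA path for the sequences
#' @return `path`, invisibly
#' @export
write_esv_table <- function(esvs, path, fasta = NULL) {
  df <- data.frame(esv_id = esvs$esv_id, motu_id = unname(esvs$motu_id),
                   esvs$reads, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(fasta)) {
    if (is.null(esvs$sequence)) stop("write_esv_table: no sequences attached")
    ss <- Biostrings::DNAStringSet(esvs$sequence)
    names(ss) <- esvs$esv_id
    Biostrings::writeXStringSet(ss, fasta)
  }
  invisible(path)
}

#' Read a MOTU table from TSV
#' @param path TSV file path
#' @param samples optional [sample_frame()] (see [read_esv_table()])
#' @param col_map list naming the `motu_id`, `taxonomy`, `nominal_species`
#'   and `dataset_label` columns; annotation columns absent from the file are
#'   filled with defaults
#' @return a [motu_table()]
#' @export
read_motu_table <- function(path, samples = NULL,
                            col_map = list(motu_id = "motu_id",
                                           taxonomy = "taxonomy",
                                           nominal_species = "nominal_species",
                                           dataset_label = "dataset_label")) {
  df <- .read_tsv(path)
  if (!col_map$motu_id %in% names(df))
    stop("read_motu_table: missing column: ", col_map$motu_id)
  ids <- as.character(df[[col_map$motu_id]])
  ann_cols <- unlist(col_map[c("taxonomy", "nominal_species", "dataset_label")])
  id_cols <- c(col_map$motu_id, intersect(ann_cols, names(df)))
  scols <- .resolve_sample_cols(names(df), id_cols, samples)
  if (length(scols) == 0) stop("read_motu_table: no sample columns found")
  reads <- as.matrix(df[, scols, drop = FALSE])
  rownames(reads) <- ids
  get <- function(col, default) {
    if (!is.null(col) && col %in% names(df)) {
      v <- as.character(df[[col]]); v[is.na(v)] <- default; v
    } else rep(default, length(ids))
  }
  ns <- if (col_map$nominal_species %in% names(df))
    as.character(df[[col_map$nominal_species]]) else rep(NA_character_, length(ids))
  ns[!is.na(ns) & ns == ""] <- NA_character_
  motu_table(reads, get(col_map$taxonomy, ""), ns,
             get(col_map$dataset_label, "COMM_other"))
}

#' Write a MOTU table to TSV
#' @param motus a [motu_table()]
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_motu_table <- function(motus, path) {
  df <- data.frame(motu_id = motus$motu_id,
                   taxonomy = unname(motus$taxonomy),
                   nominal_species = unname(motus$nominal_species),
                   dataset_label = unname(motus$dataset_label),
                   motus$reads, check.names = FALSE, stringsAsFactors = FALSE)
  df$nominal_species[is.na(df$nominal_species)] <- ""
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample frame from TSV
#' @param path TSV with columns sample_id, locality, time_point, replicate,
#'   sample_type
#' @return a [sample_frame()]
#' @export
read_sample_frame <- function(path) {
  df <- .read_tsv(path)
  for (col in c("locality", "time_point"))
    if (col %in% names(df)) df[[col]][df[[col]] == ""] <- NA
  sample_frame(df)
}

#' Write a sample frame to TSV
#' @param samples a [sample_frame()]
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_sample_frame <- function(samples, path) {
  df <- as.data.frame(samples)
  df$locality[is.na(df$locality)] <- ""
  df$time_point[is.na(df$time_point)] <- ""
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a hit table from BLAST-tabular-style TSV
#' @param path TSV file path
#' @param col_map list naming the query id, subject species, percent identity
#'   and query coverage columns (defaults follow qseqid/sseqid/pident/qcovs)
#' @return a [hit_table()]
#' @export
read_hit_table <- function(path, col_map = list(motu_id = "qseqid",
                                                subject_species = "sseqid",
                                                identity = "pident",
                                                coverage = "qcovs")) {
  df <- .read_tsv(path)
  miss <- setdiff(unlist(col_map), names(df))
  if (length(miss) > 0)
    stop("read_hit_table: missing columns: ", paste(miss, collapse = ", "))
  hit_table(data.frame(motu_id = as.character(df[[col_map$motu_id]]),
                       subject_species = as.character(df[[col_map$subject_species]]),
                       identity = as.numeric(df[[col_map$identity]]),
                       coverage = as.numeric(df[[col_map$coverage]]),
                       stringsAsFactors = FALSE))
}

# ---------------------------------------------------------------------------
# Linkage validation and dataset partition
# ---------------------------------------------------------------------------

#' Validate ESV/MOTU linkage
#'
#' Checks that both tables share the same sample columns, that every ESV's
#' MOTU exists, and that each MOTU's per-sample reads equal the sum of its
#' member ESVs' reads.
#'
#' @param esvs an [esv_table()]
#' @param motus a [motu_table()]
#' @return data.frame of mismatches (`motu_id`, `sample_id`, `motu_reads`,
#'   `esv_sum`); zero rows when consistent
#' @export
validate_linkage <- function(esvs, motus) {
  stopifnot(inherits(esvs, "esv_table"), inherits(motus, "motu_table"))
  if (!setequal(colnames(esvs$reads), colnames(motus$reads)))
    stop("validate_linkage: tables do not share sample columns")
  orphan <- setdiff(unique(esvs$motu_id), motus$motu_id)
  if (length(orphan) > 0)
    stop("validate_linkage: orphan ESV MOTUs: ", paste(orphan, collapse = ", "))
  scols <- colnames(motus$reads)
  esum <- rowsum(esvs$reads[, scols, drop = FALSE], group = esvs$motu_id)
  full <- matrix(0, length(motus$motu_id), length(scols),
                 dimnames = list(motus$motu_id, scols))
  full[rownames(esum), ] <- esum
  diff_idx <- which(full != motus$reads, arr.ind = TRUE)
  data.frame(motu_id = motus$motu_id[diff_idx[, 1]],
             sample_id = scols[diff_idx[, 2]],
             motu_reads = motus$reads[diff_idx],
             esv_sum = full[diff_idx],
             stringsAsFactors = FALSE)
}

#' Partition MOTUs into NIS / NAT / COMM datasets
#'
#' Labels MOTUs as non-indigenous (NIS), curated natives (NAT), or the rest
#' of the community (COMM_other). The COMM dataset used downstream is
#' everything that is not NIS, i.e. NAT plus COMM_other. Relabeling changes
#' no read counts.
#'
#' @param motus a [motu_table()]
#' @param nis_ids MOTU ids classified as NIS
#' @param nat_ids MOTU ids classified as curated natives
#' @return the relabeled `motu_table`
#' @export
partition_datasets <- function(motus, nis_ids, nat_ids = character()) {
  stopifnot(inherits(motus, "motu_table"))
  both <- intersect(nis_ids, nat_ids)
  if (length(both) > 0)
    stop("partition_datasets: ids in both NIS and NAT: ",
         paste(both, collapse = ", "))
  lab <- rep("COMM_other", length(motus$motu_id))
  names(lab) <- motus$motu_id
  lab[intersect(nis_ids, motus$motu_id)] <- "NIS"
  lab[intersect(nat_ids, motus$motu_id)] <- "NAT"
  motus$dataset_label <- lab
  motus
}

#' MOTU ids belonging to a dataset scope
#'
#' @param motus a [motu_table()]
#' @param scope `"NIS"`, `"NAT"`, `"COMM"` (everything not NIS), or `"all"`
#' @return character vector of MOTU ids
#' @export
dataset_ids <- function(motus, scope) {
  lab <- motus$dataset_label
  switch(scope,
         NIS = motus$motu_id[lab == "NIS"],
         NAT = motus$motu_id[lab == "NAT"],
         COMM = motus$motu_id[lab != "NIS" & lab != "excluded"],
         all = motus$motu_id,
         stop("dataset_ids: unknown scope: ", scope))
}
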