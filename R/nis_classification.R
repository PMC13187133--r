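# NIS detection from curated-reference hits, native-subset curation, and
# nominal-species pooling.

#' Assign MOTUs to non-indigenous species from reference hits
#'
#' A MOTU is classified as NIS when it has at least one hit with identity and
#' coverage at or above the thresholds ("equal to or greater than"). Its
#' nominal species is the species of the best hit: highest identity, ties
#' broken by higher coverage, then lexicographic species name, so the result
#' is invariant under permutation of the hit rows.
#'
#' @param hits a [hit_table()]
#' @param min_identity percent identity threshold (default 97)
#' @param min_coverage percent coverage threshold (default 70)
#' @return list with `nis_ids` (character) and `best_species` (data.frame
#'   `motu_id`, `species`, `identity`, `coverage`)
#' @export
assign_nis <- function(hits, min_identity = 97, min_coverage = 70) {
  stopifnot(inherits(hits, "hit_table"))
  ok <- hits[hits$identity >= min_identity & hits$coverage >= min_coverage, ,
             drop = FALSE]
  if (nrow(ok) == 0)
    return(list(nis_ids = character(),
                best_species = data.frame(motu_id = character(),
                                          species = character(),
                                          identity = numeric(),
                                          coverage = numeric(),
                                          stringsAsFactors = FALSE)))
  ord <- order(ok$motu_id, -ok$identity, -ok$coverage, ok$subject_species)
  ok <- ok[ord, , drop = FALSE]
  best <- ok[!duplicated(ok$motu_id), , drop = FALSE]
  list(nis_ids = best$motu_id,
       best_species = data.frame(motu_id = best$motu_id,
                                 species = best$subject_species,
                                 identity = best$identity,
                                 coverage = best$coverage,
                                 stringsAsFactors = FALSE))
}

#' Compare NIS-reference assignments with a general-database assignment
#'
#' Classes each NIS MOTU by the agreement between the species assigned from
#' the curated NIS reference and the lineage assigned from a general
#' reference database: `coincident` (same species), `higher_rank_only` (the
#' general assignment stops above species but its lineage contains the NIS
#' species' genus), `different_species`, or `same_species_low_identity`
#' (species agree but the general assignment's identity was below the NIS
#' threshold).
#'
#' @param nis_species data.frame `motu_id`, `species` (from [assign_nis()])
#' @param general data.frame `motu_id`, `species` (NA or "" where not
#'   assigned to species), `lineage` (delimited ranked string), and optional
#'   `identity`
#' @param min_identity identity threshold defining "low identity" (default 97)
#' @return list with `classes` (named character by motu_id) and `counts`
#'   (table over the four classes)
#' @export
compare_assignments <- function(nis_species, general, min_identity = 97) {
  g <- general[match(nis_species$motu_id, general$motu_id), , drop = FALSE]
  cls <- character(nrow(nis_species))
  for (i in seq_len(nrow(nis_species))) {
    sp_nis <- nis_species$species[i]
    sp_gen <- g$species[i]
    no_sp <- is.na(sp_gen) || sp_gen == ""
    if (!no_sp && sp_gen == sp_nis) {
      low <- !is.null(g$identity) && !is.na(g$identity[i]) &&
        g$identity[i] < min_identity
      cls[i] <- if (low) "same_species_low_identity" else "coincident"
    } else if (no_sp) {
      cls[i] <- "higher_rank_only"
    } else {
      cls[i] <- "different_species"
    }
  }
  names(cls) <- nis_species$motu_id
  lv <- c("coincident", "higher_rank_only", "different_species",
          "same_species_low_identity")
  list(classes = cls, counts = table(factor(cls, levels = lv)))
}

#' Curate the native (NAT) dataset
#'
#' NAT is the set of species-level-assigned, non-NIS MOTUs minus an explicit
#' exclusion list (species complexes, dubious database matches, cryptogenic
#' species). Exclusions may be given as MOTU ids or binomial species names.
#'
#' @param motus a [motu_table()] with `nominal_species` populated for
#'   species-level assignments (NA elsewhere)
#' @param exclusion_list character vector of MOTU ids and/or species names
#' @return character vector of NAT MOTU ids
#' @export
curate_nat <- function(motus, exclusion_list = character()) {
  stopifnot(inherits(motus, "motu_table"))
  cand <- motus$motu_id[!is.na(motus$nominal_species) &
                          motus$dataset_label != "NIS"]
  known <- c(motus$motu_id, stats::na.omit(unique(motus$nominal_species)))
  unknown <- setdiff(exclusion_list, known)
  if (length(unknown) > 0)
    warning("curate_nat: exclusions not present in table: ",
            paste(unknown, collapse = ", "))
  excl_by_sp <- motus$motu_id[!is.na(motus$nominal_species) &
                                motus$nominal_species %in% exclusion_list]
  setdiff(cand, union(exclusion_list, excl_by_sp))
}

#' Pool MOTUs sharing a nominal species
#'
#' Sums the reads of MOTUs assigned to the same nominal species per sample,
#' within a dataset scope. Total reads are conserved exactly; MOTUs without a
#' nominal species are kept as their own units under their MOTU id.
#'
#' @param motus a [motu_table()]
#' @param scope `"NIS"`, `"NAT"`, `"COMM"`, or `"all"`
#' @return numeric matrix, rows named by nominal species (or MOTU id), one
#'   column per sample
#' @export
pool_nominal_species <- function(motus, scope = "NIS") {
  ids <- dataset_ids(motus, scope)
  sub <- motu_subset(motus, ids)
  key <- ifelse(is.na(sub$nominal_species), sub$motu_id, sub$nominal_species)
  rowsum(sub$reads, group = key)
}
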