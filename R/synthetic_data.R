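# Synthetic COI metabarcoding datasets with the structure the analysis
# assumes: a port monitoring design (localities x monthly time points x
# replicates plus blanks/negatives), widely-occurring read-abundant NIS
# MOTUs vs locality-restricted natives, higher haplotype (ESV) counts in
# NIS, tunable between-locality haplotype differentiation, contaminant ESVs
# concentrated in controls, and pseudogene ESVs carrying in-frame stops.

# Codons that are not stops under any of the metazoan mitochondrial codes
# checked by the default pseudogene filter (stops there: TAA, TAG, AGA, AGG).
.SAFE_CODONS <- {
  b <- c("T", "C", "A", "G")
  all <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all, c("TAA", "TAG", "AGA", "AGG"))
}

# A stop-free COI-like fragment: `offset` leading bases, then `n_codons`
# codons drawn from the safe set, then 2 trailing bases (Leray-fragment
# geometry: 313 bp = 2 + 103*3 + 2).
.make_clean_sequence <- function(n_codons = 103, offset = 2) {
  lead <- paste(sample(c("A", "C", "G", "T"), offset, replace = TRUE),
                collapse = "")
  body <- paste(sample(.SAFE_CODONS, n_codons, replace = TRUE),
                collapse = "")
  tail <- paste(sample(c("A", "C", "G", "T"), 2, replace = TRUE),
                collapse = "")
  paste0(lead, body, tail)
}

# Synonymous-style variant: substitute third codon positions, keeping every
# touched codon in the safe (never-stop) set.
.mutate_sequence <- function(seq, n_subs = 3, offset = 2) {
  n_codons <- (nchar(seq) - offset) %/% 3
  pos <- sample(seq_len(n_codons), min(n_subs, n_codons))
  for (p in pos) {
    start <- offset + (p - 1) * 3 + 1
    codon <- substr(seq, start, start + 2)
    cand <- .SAFE_CODONS[substr(.SAFE_CODONS, 1, 2) == substr(codon, 1, 2)]
    cand <- setdiff(cand, codon)
    if (length(cand) == 0) next
    substr(seq, start, start + 2) <- sample(cand, 1)
  }
  seq
}

# Replace one in-frame codon with TAG (a stop under every metazoan
# mitochondrial code table).
.pseudogenize <- function(seq, offset = 2, codon_index = 10) {
  start <- offset + (codon_index - 1) * 3 + 1
  substr(seq, start, start + 2) <- "TAG"
  seq
}

#' Simulation configuration
#'
#' Defaults encode the monitoring design the analysis targets: 4 localities
#' sampled at 10 time points with 3 replicates plus control samples; NIS
#' MOTUs occur in most localities and dominate reads, natives are
#' locality-restricted; NIS carry ~3x more haplotypes (ESVs) per MOTU; NIS
#' show weaker between-locality haplotype differentiation than natives.
#'
#' @param n_localities number of port localities (default 4, named RO, BL,
#'   VI, LR)
#' @param n_timepoints monthly sampling points (default 10)
#' @param n_replicates replicates per locality x time (default 3)
#' @param n_blanks,n_negatives control samples (default 2 each)
#' @param n_nis_motus,n_nat_motus,n_other_motus MOTU counts per class
#'   (default 25 / 60 / 90)
#' @param depth_meanlog,depth_sdlog lognormal read-depth parameters per true
#'   sample (default log(30000), 0.35)
#' @param occupancy per-class probability a MOTU occurs in a locality
#'   (default NIS 0.8, NAT 0.3, COMM_other 0.3)
#' @param esv_mean per-class mean of the zero-truncated negative-binomial ESV
#'   count (default NIS 9, NAT 3, COMM_other 3)
#' @param esv_size negative-binomial dispersion (default 2)
#' @param theta per-class differentiation in \[0, 1\]: mixing weight pulling
#'   locality haplotype frequencies away from the MOTU's shared base vector
#'   (0 = identical frequencies everywhere, 1 = locality-private dominant
#'   haplotypes; default NIS 0.15, NAT 0.35, COMM_other 0.35)
#' @param abundance_mult per-class multiplier on the lognormal MOTU abundance
#'   weight (default NIS 8, others 1: read-abundant NIS)
#' @param contamination_rate fraction of (clean) ESV count injected as
#'   contaminant ESVs concentrated in controls (default 0.02)
#' @param pseudogene_rate fraction injected as stop-bearing pseudogene ESVs
#'   (default 0.02)
#' @param n_nonmetazoan MOTUs with non-metazoan taxonomy (default 5)
#' @param time_sd lognormal SD of the per-MOTU month effect (default 0.4)
#' @param seed master seed
#' @return a `sim_config` list
#' @export
sim_config <- function(n_localities = 4, n_timepoints = 10, n_replicates = 3,
                       n_blanks = 2, n_negatives = 2,
                       n_nis_motus = 25, n_nat_motus = 60, n_other_motus = 90,
                       depth_meanlog = log(30000), depth_sdlog = 0.35,
                       occupancy = c(NIS = 0.8, NAT = 0.3, COMM_other = 0.3),
                       esv_mean = c(NIS = 9, NAT = 3, COMM_other = 3),
                       esv_size = 2,
                       theta = c(NIS = 0.15, NAT = 0.35, COMM_other = 0.35),
                       abundance_mult = c(NIS = 8, NAT = 1, COMM_other = 1),
                       contamination_rate = 0.02, pseudogene_rate = 0.02,
                       n_nonmetazoan = 5, time_sd = 0.4, seed = 1L) {
  stopifnot(n_localities >= 2, n_timepoints >= 1, n_replicates >= 1,
            all(theta >= 0 & theta <= 1),
            all(occupancy >= 0 & occupancy <= 1),
            contamination_rate >= 0, contamination_rate <= 1,
            pseudogene_rate >= 0, pseudogene_rate <= 1,
            all(esv_mean > 0))
  if (n_nis_motus + n_nat_motus + n_other_motus < 1)
    stop("sim_config: no MOTUs requested")
  structure(as.list(environment()), class = "sim_config")
}

.LOCALITY_NAMES <- c("RO", "BL", "VI", "LR")
.METAZOAN_PHYLA <- c("Arthropoda", "Cnidaria", "Chordata", "Annelida",
                     "Mollusca", "Bryozoa", "Echinodermata", "Porifera")

.rztnb <- function(n, mu, size) {
  out <- stats::rnbinom(n, mu = mu, size = size)
  while (any(out == 0))
    out[out == 0] <- stats::rnbinom(sum(out == 0), mu = mu, size = size)
  out
}

.rdirichlet <- function(k, alpha) {
  g <- stats::rgamma(k, shape = alpha)
  if (sum(g) == 0) g[sample(k, 1)] <- 1
  g / sum(g)
}

#' Simulate a complete synthetic dataset bundle
#'
#' @param cfg a [sim_config()]
#' @return list with `esvs` ([esv_table()], sequences attached), `motus`
#'   ([motu_table()] with true dataset labels), `samples` ([sample_frame()]),
#'   `hits` ([hit_table()]), and `truth` (ground-truth ledger: classes,
#'   per-MOTU theta, injected contaminant and pseudogene ESV ids, NIS/NAT id
#'   sets)
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  locs <- if (cfg$n_localities <= length(.LOCALITY_NAMES))
    .LOCALITY_NAMES[seq_len(cfg$n_localities)]
  else c(.LOCALITY_NAMES,
         paste0("L", seq_len(cfg$n_localities - length(.LOCALITY_NAMES))))
  times <- sprintf("T%02d", seq_len(cfg$n_timepoints))

  grid <- expand.grid(replicate = seq_len(cfg$n_replicates),
                      time_point = times, locality = locs,
                      stringsAsFactors = FALSE)
  true_ids <- with(grid, paste(locality, time_point,
                               paste0("R", replicate), sep = "_"))
  ctrl <- data.frame(
    sample_id = c(sprintf("BLANK%d", seq_len(cfg$n_blanks)),
                  sprintf("NEG%d", seq_len(cfg$n_negatives))),
    locality = NA_character_, time_point = NA_character_,
    replicate = 1L,
    sample_type = c(rep("blank", cfg$n_blanks),
                    rep("pcr_negative", cfg$n_negatives)),
    stringsAsFactors = FALSE)
  samples <- sample_frame(rbind(
    data.frame(sample_id = true_ids, locality = grid$locality,
               time_point = grid$time_point, replicate = grid$replicate,
               sample_type = "true_sample", stringsAsFactors = FALSE),
    ctrl))

  # --- MOTU-level structure -------------------------------------------------
  n_motu <- cfg$n_nis_motus + cfg$n_nat_motus + cfg$n_other_motus +
    cfg$n_nonmetazoan
  motu_ids <- sprintf("M%04d", seq_len(n_motu))
  cls <- c(rep("NIS", cfg$n_nis_motus), rep("NAT", cfg$n_nat_motus),
           rep("COMM_other", cfg$n_other_motus),
           rep("nonmetazoan", cfg$n_nonmetazoan))
  names(cls) <- motu_ids
  eff_cls <- ifelse(cls == "nonmetazoan", "COMM_other", cls)

  base_w <- stats::rlnorm(n_motu, 0, 1) * cfg$abundance_mult[eff_cls]
  occ <- matrix(stats::runif(n_motu * length(locs)) <
                  cfg$occupancy[eff_cls], n_motu, length(locs),
                dimnames = list(motu_ids, locs))
  none <- rowSums(occ) == 0
  occ[cbind(which(none), sample(length(locs), sum(none), replace = TRUE))] <-
    TRUE
  timefx <- matrix(stats::rlnorm(n_motu * length(times), 0, cfg$time_sd),
                   n_motu, length(times), dimnames = list(motu_ids, times))

  # --- ESVs: counts, locality-specific haplotype frequencies, sequences ----
  k <- .rztnb(n_motu, mu = cfg$esv_mean[eff_cls], size = cfg$esv_size)
  names(k) <- motu_ids
  esv_motu <- rep(motu_ids, k)
  esv_ids <- paste0(esv_motu, "_E", unlist(lapply(k, seq_len)))
  theta_m <- stats::setNames(cfg$theta[eff_cls], motu_ids)

  freq <- matrix(0, length(esv_ids), length(locs),
                 dimnames = list(esv_ids, locs))
  seqs <- character(length(esv_ids))
  names(seqs) <- esv_ids
  row0 <- 0
  for (i in seq_len(n_motu)) {
    ki <- k[i]
    base_f <- .rdirichlet(ki, 1)
    for (l in seq_along(locs)) {
      priv <- .rdirichlet(ki, 0.3)
      freq[row0 + seq_len(ki), l] <-
        (1 - theta_m[i]) * base_f + theta_m[i] * priv
    }
    tmpl <- .make_clean_sequence()
    seqs[row0 + 1] <- tmpl
    if (ki > 1)
      for (j in 2:ki) seqs[row0 + j] <- .mutate_sequence(tmpl)
    row0 <- row0 + ki
  }

  # --- reads: multinomial per sample ---------------------------------------
  reads <- matrix(0, length(esv_ids), nrow(samples),
                  dimnames = list(esv_ids, samples$sample_id))
  depth <- round(stats::rlnorm(length(true_ids), cfg$depth_meanlog,
                               cfg$depth_sdlog))
  names(depth) <- true_ids
  for (s in true_ids) {
    l <- grid$locality[true_ids == s]
    t <- grid$time_point[true_ids == s]
    w_m <- stats::setNames(base_w * occ[, l] * timefx[, t], motu_ids)
    p <- freq[, l] * w_m[esv_motu]
    if (sum(p) == 0) next
    reads[, s] <- stats::rmultinom(1, depth[s], p)
  }

  # --- contaminant spike-ins (concentrated in controls) --------------------
  n_clean <- length(esv_ids)
  n_cont <- round(cfg$contamination_rate * n_clean)
  cont_esvs <- character(0)
  if (n_cont > 0) {
    cont_motus <- sprintf("CONT%03d", seq_len(n_cont))
    cont_esvs <- paste0(cont_motus, "_E1")
    cm <- matrix(0, n_cont, ncol(reads),
                 dimnames = list(cont_esvs, colnames(reads)))
    ctrl_ids <- ctrl$sample_id
    for (i in seq_len(n_cont)) {
      cm[i, ctrl_ids] <- 100 + stats::rpois(length(ctrl_ids), 50)
      cm[i, sample(true_ids, 3)] <- 20 + stats::rpois(3, 30)
    }
    reads <- rbind(reads, cm)
    esv_motu <- c(esv_motu, cont_motus)
    seqs <- c(seqs, stats::setNames(
      vapply(seq_len(n_cont), function(i) .make_clean_sequence(), ""),
      cont_esvs))
    cls <- c(cls, stats::setNames(rep("contaminant", n_cont), cont_motus))
    motu_ids <- c(motu_ids, cont_motus)
  }

  # --- pseudogene spike-ins (in-frame TAG) ---------------------------------
  n_pseudo <- round(cfg$pseudogene_rate * n_clean)
  pseudo_esvs <- character(0)
  if (n_pseudo > 0) {
    hosts <- sample(motu_ids[cls[motu_ids] %in%
                               c("NIS", "NAT", "COMM_other")], n_pseudo,
                    replace = TRUE)
    pseudo_esvs <- sprintf("%s_P%03d", hosts, seq_len(n_pseudo))
    pm <- matrix(0, n_pseudo, ncol(reads),
                 dimnames = list(pseudo_esvs, colnames(reads)))
    for (i in seq_len(n_pseudo))
      pm[i, sample(true_ids, 2)] <- 10 + stats::rpois(2, 20)
    reads <- rbind(reads, pm)
    esv_motu <- c(esv_motu, hosts)
    host_seq <- vapply(hosts, function(h)
      seqs[which(esv_motu[seq_len(n_clean)] == h)[1]], "")
    seqs <- c(seqs, stats::setNames(
      vapply(host_seq, .pseudogenize, ""), pseudo_esvs))
  }

  names(esv_motu) <- rownames(reads)
  # drop all-zero ESVs (MOTUs that never occurred with enough weight)
  nz <- rowSums(reads) > 0
  esvs <- esv_table(reads[nz, , drop = FALSE], esv_motu[nz], seqs[nz])

  # --- taxonomy, nominal species, hit table --------------------------------
  phyla <- sample(.METAZOAN_PHYLA, length(motu_ids), replace = TRUE)
  names(phyla) <- motu_ids
  is_nonmeta <- cls[motu_ids] == "nonmetazoan"
  phyla[is_nonmeta] <- "Bacillariophyta"
  nis_ids <- motu_ids[cls[motu_ids] == "NIS"]
  nat_ids <- motu_ids[cls[motu_ids] == "NAT"]
  # species pools smaller than the MOTU sets: species complexes (several
  # MOTUs sharing a nominal species) are more common in NIS
  sp_pool <- function(ids, frac) {
    n_sp <- max(1, ceiling(frac * length(ids)))
    sp <- sprintf("Genus%03d species%03d", seq_len(n_sp), seq_len(n_sp))
    stats::setNames(sample(sp, length(ids), replace = TRUE), ids)
  }
  nominal <- rep(NA_character_, length(motu_ids))
  names(nominal) <- motu_ids
  nominal[nis_ids] <- sp_pool(nis_ids, 0.8)
  nominal[nat_ids] <- sp_pool(nat_ids, 0.95)
  lineage <- ifelse(is.na(nominal), paste0(phyla, ";;;;;"),
                    paste0(phyla, ";Class;Order;Family;Genus;", nominal))
  names(lineage) <- motu_ids

  hits <- list()
  for (m in nis_ids)
    hits[[m]] <- data.frame(motu_id = m, subject_species = nominal[m],
                            identity = stats::runif(1, 97.5, 100),
                            coverage = stats::runif(1, 75, 100),
                            stringsAsFactors = FALSE)
  decoys <- sample(setdiff(motu_ids, nis_ids),
                   max(1, round(0.1 * length(motu_ids))))
  for (m in decoys)
    hits[[m]] <- data.frame(motu_id = m, subject_species = "Decoyus decoyi",
                            identity = stats::runif(1, 90, 96.9),
                            coverage = stats::runif(1, 50, 100),
                            stringsAsFactors = FALSE)
  hits <- hit_table(do.call(rbind, c(hits, make.row.names = FALSE)))

  labels <- ifelse(cls[motu_ids] == "NIS", "NIS",
                   ifelse(cls[motu_ids] == "NAT", "NAT", "COMM_other"))
  motus <- rebuild_motu_table(
    esvs, motu_table(matrix(0, length(motu_ids), ncol(reads),
                            dimnames = list(motu_ids, colnames(reads))),
                     lineage, nominal, stats::setNames(labels, motu_ids)))

  list(esvs = esvs, motus = motus, samples = samples, hits = hits,
       truth = list(class = cls, theta = theta_m,
                    contaminant_esvs = intersect(cont_esvs, esvs$esv_id),
                    pseudogene_esvs = intersect(pseudo_esvs, esvs$esv_id),
                    nis_ids = nis_ids, nat_ids = nat_ids),
       cfg = cfg)
}

#' Miniature hand-auditable worked fixture
#'
#' A fixed 10-MOTU, 2-locality dataset (3 true samples per locality plus one
#' shallow extra, one blank, one PCR negative) where every filter and
#' statistic is computable by hand. Constructed offenders: one contaminant
#' ESV (12.5\% of its reads in controls), one boundary ESV at exactly 10\%
#' (retained), one 4-read cell (removed by the dual filter) next to a 5-read
#' cell (retained), one pseudogene ESV whose removal deletes its MOTU, one
#' non-metazoan MOTU, and one sample below the fixture's depth threshold.
#' The one polymorphic MOTU shared between the localities (M01) has
#' occurrence counts (3,1)/(1,3), giving Jost's D = 0.25 by hand.
#'
#' @return list with `esvs`, `motus`, `samples`, `hits`, `nis_ids`,
#'   `nat_ids`, `cfg` (a [filter_config()] scaled to the fixture), and
#'   `expected` (hand-computed outcomes used by the tests)
#' @export
worked_fixture <- function() {
  samples <- sample_frame(data.frame(
    sample_id = c("A1", "A2", "A3", "A4", "B1", "B2", "B3", "BLK1", "NEG1"),
    locality = c(rep("A", 4), rep("B", 3), NA, NA),
    time_point = c("T1", "T2", "T3", "T1", "T1", "T2", "T3", NA, NA),
    replicate = c(1, 1, 1, 2, 1, 1, 1, 1, 1),
    sample_type = c(rep("true_sample", 7), "blank", "pcr_negative"),
    stringsAsFactors = FALSE))

  esv_ids <- sprintf("E%02d", 1:13)
  motu_of <- c(E01 = "M01", E02 = "M01", E03 = "M02", E04 = "M03",
               E05 = "M03", E06 = "M04", E07 = "M05", E08 = "M06",
               E09 = "M07", E10 = "M08", E11 = "M09", E12 = "M10",
               E13 = "M10")
  # E13 belongs to M10 (non-metazoan, 2 ESVs) so the metazoan restriction
  # drops a whole MOTU with all its ESVs.
  reads <- matrix(0, 13, 9,
                  dimnames = list(esv_ids, samples$sample_id))
  reads["E01", c("A1", "A2", "A3", "B1")] <- c(100, 80, 120, 50)
  reads["E02", c("A3", "B1", "B2", "B3")] <- c(60, 70, 90, 40)
  reads["E03", c("A1", "B1")] <- c(500, 600)                 # M02, NIS
  reads["E04", c("A1", "A2", "A4")] <- c(200, 150, 60)       # M03, NAT
  reads["E05", c("A2", "B2")] <- c(50, 80)                   # M03, NAT
  reads["E06", c("B1", "B2", "B3")] <- c(300, 250, 200)      # M04, COMM
  reads["E07", "A1"] <- 50                                   # M05, pseudogene
  reads["E08", c("BLK1", "NEG1", "A1")] <- c(30, 20, 400)    # M06, contaminant
  reads["E09", c("BLK1", "A1")] <- c(40, 400)                # M07, 10% boundary
  reads["E10", "A1"] <- 4                                    # M08, dual filter
  reads["E11", "A2"] <- 5                                    # M09, boundary keep
  reads["E12", "B3"] <- 120                                  # M10, non-metazoan
  reads["E13", "B3"] <- 30

  set.seed(424242)
  clean <- .make_clean_sequence()
  seqs <- stats::setNames(character(13), esv_ids)
  seqs["E01"] <- clean
  for (e in setdiff(esv_ids, c("E01", "E07")))
    seqs[e] <- .mutate_sequence(clean)
  seqs["E07"] <- .pseudogenize(clean)

  esvs <- esv_table(reads, motu_of, seqs)
  motu_ids <- sprintf("M%02d", 1:10)
  lineage <- c(M01 = "Arthropoda;Class;Order;Family;Elasmopus;Elasmopus synthetica",
               M02 = "Annelida;Class;Order;Family;Hydroides;Hydroides synthetica",
               M03 = "Mollusca;Class;Order;Family;Mytilus;Mytilus fixturensis",
               M04 = "Cnidaria;;;;;",
               M05 = "Arthropoda;;;;;",
               M06 = "Chordata;;;;;",
               M07 = "Chordata;Class;Order;Family;Styela;Styela synthetica",
               M08 = "Annelida;Class;Order;Family;Platynereis;Platynereis fixturensis",
               M09 = "Bryozoa;Class;Order;Family;Bugula;Bugula fixturensis",
               M10 = "Bacillariophyta;;;;;")
  nominal <- c(M01 = "Elasmopus synthetica", M02 = "Hydroides synthetica",
               M03 = "Mytilus fixturensis", M04 = NA, M05 = NA, M06 = NA,
               M07 = "Styela synthetica", M08 = "Platynereis fixturensis",
               M09 = "Bugula fixturensis", M10 = NA)
  shell <- motu_table(matrix(0, 10, 9,
                             dimnames = list(motu_ids, samples$sample_id)),
                      lineage, nominal)
  motus <- rebuild_motu_table(esvs, shell)

  hits <- hit_table(data.frame(
    motu_id = c("M01", "M02", "M07", "M07", "M03", "M04"),
    subject_species = c("Elasmopus synthetica", "Hydroides synthetica",
                        "Styela synthetica", "Styela alterna",
                        "Mytilus dubius", "Obelia decoyi"),
    identity = c(99.1, 97.0, 99.0, 99.0, 98.0, 96.5),
    coverage = c(92, 70, 80, 75, 60, 95),
    stringsAsFactors = FALSE))

  list(esvs = esvs, motus = motus, samples = samples, hits = hits,
       nis_ids = c("M01", "M02", "M07"), nat_ids = c("M03", "M09"),
       cfg = filter_config(min_sample_depth = 100),
       expected = list(
         blank_removed = "E08",
         blank_boundary_kept = "E09",
         dual_removed = "E10",
         dual_boundary_kept = "E11",
         pseudogene_removed = "E07",
         motu_removed_by_pseudogene = "M05",
         nonmetazoan_removed = "M10",
         shallow_sample = "A4",
         final_esvs = c("E01", "E02", "E03", "E04", "E05", "E06", "E09",
                        "E11"),
         final_motus = c("M01", "M02", "M03", "M04", "M07", "M09"),
         d_m01 = 0.25))
}
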