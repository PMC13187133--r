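# Helper: one-locality frame with named true samples and one blank/negative.
.filter_samples <- function(true_ids, blanks = "BLK", negs = "NEG") {
  sample_frame(data.frame(
    sample_id = c(true_ids, blanks, negs),
    locality = c(rep("A", length(true_ids)), rep(NA, length(blanks) +
                                                   length(negs))),
    time_point = c(rep("T1", length(true_ids)), rep(NA, length(blanks) +
                                                      length(negs))),
    replicate = 1L,
    sample_type = c(rep("true_sample", length(true_ids)),
                    rep("blank", length(blanks)),
                    rep("pcr_negative", length(negs))),
    stringsAsFactors = FALSE))
}

test_that("blank filter deletes above 10% and keeps the exact-10% boundary", {
  samples <- .filter_samples(c("s1", "s2"))
  reads <- rbind(over  = c(300, 100, 30, 20),   # controls 50/400 = 12.5%
                 at    = c(300, 100, 25, 15),   # controls 40/400 = exactly 10%
                 clean = c(200, 100, 0, 0))     # no control reads
  colnames(reads) <- c("s1", "s2", "BLK", "NEG")
  esvs <- esv_table(reads, c(over = "m1", at = "m1", clean = "m2"))
  out <- blank_filter(esvs, samples)
  expect_setequal(out$esvs$esv_id, c("at", "clean"))
  expect_equal(out$log$esv_id, "over")
  expect_equal(out$log$stage, "blank_filter")
})

test_that("blank filter is a warning no-op without control samples", {
  tt <- tiny_tables()
  expect_warning(out <- blank_filter(tt$esvs, tt$samples), "no-op")
  expect_equal(out$esvs$reads, tt$esvs$reads)
})

test_that("dual abundance filter applies the relative then absolute floors", {
  # sample u: total 100000 -> 0.005% floor = 5 reads; a 4-read cell dies in
  # step (i). sample v: total 80000 -> floor = 4 reads; a 4-read cell passes
  # (i) ("less than") but dies in step (ii) (< 5 reads); a 5-read cell
  # survives both.
  reads <- rbind(filler = c(99996, 79991),
                 four   = c(4, 4),
                 five   = c(0, 5))
  colnames(reads) <- c("u", "v")
  esvs <- esv_table(reads, c(filler = "m", four = "m", five = "m"))
  out <- dual_abundance_filter(esvs, filter_config())
  expect_setequal(out$esvs$esv_id, c("filler", "five"))
  expect_equal(out$log$esv_id, "four")
  expect_equal(out$esvs$reads["five", "v"], 5)
})

test_that("the order of the dual-filter steps matters", {
  # Crafted sample: filler 100 reads, twenty 4-read cells, one 8-read
  # candidate; total 188. Enforced order -- relative floor on the original
  # total (5% of 188 = 9.4) -- zeroes the candidate. The swapped order
  # (absolute step first, relative floor recomputed on the reduced total
  # 108 -> 5.4) would keep it.
  ids <- c("filler", paste0("tiny", 1:20), "candidate")
  reads <- matrix(c(100, rep(4, 20), 8), ncol = 1,
                  dimnames = list(ids, "s"))
  esvs <- esv_table(reads, stats::setNames(rep("m", length(ids)), ids))
  cfg <- filter_config(rel_abundance_threshold = 0.05,
                       min_reads_per_esv_sample = 5)
  out <- dual_abundance_filter(esvs, cfg)
  expect_setequal(out$esvs$esv_id, "filler")

  # hand evaluation of the swapped order on the same fixture
  swapped <- reads
  swapped[swapped < 5] <- 0
  floor_swapped <- 0.05 * sum(swapped)
  swapped[swapped < floor_swapped] <- 0
  survivors_swapped <- rownames(swapped)[swapped[, 1] > 0]
  expect_setequal(survivors_swapped, c("filler", "candidate"))
  expect_false(setequal(out$esvs$esv_id, survivors_swapped))
})

test_that("pseudogene filter removes stop-bearing ESVs and spares clean COI", {
  clean <- clean_seq_for_tests()
  stopper <- metaport:::.pseudogenize(clean)          # TAG: stop in all codes
  taa <- clean
  substr(taa, 2 + 9 * 3 + 1, 2 + 9 * 3 + 3) <- "TAA"  # stop in all but code 14
  reads <- matrix(c(10, 10, 10), 3,
                  dimnames = list(c("clean", "stopper", "taa"), "s"))
  esvs <- esv_table(reads, c(clean = "m1", stopper = "m2", taa = "m3"),
                    c(clean = clean, stopper = stopper, taa = taa))

  out <- pseudogene_filter(esvs, filter_config())     # code 14 reads TAA as Y
  expect_setequal(out$esvs$esv_id, c("clean", "taa"))

  out2 <- pseudogene_filter(esvs, filter_config(genetic_codes = c("2", "5")))
  expect_setequal(out2$esvs$esv_id, "clean")
  expect_setequal(out2$log$esv_id, c("stopper", "taa"))
})

test_that("conserved-residue violations are removed under a stop-free frame", {
  clean <- clean_seq_for_tests()
  aa <- metaport:::.translate_frame(clean, 2, "5")
  pos <- 7
  res <- substr(aa, pos, pos)
  ok_cfg <- filter_config(conserved_positions =
                            stats::setNames(list(res), pos))
  bad_cfg <- filter_config(conserved_positions =
                             stats::setNames(list(setdiff(LETTERS, res)[1]),
                                             pos))
  reads <- matrix(5, 1, dimnames = list("e", "s"))
  esvs <- esv_table(reads, c(e = "m"), c(e = clean))
  expect_equal(pseudogene_filter(esvs, ok_cfg)$esvs$esv_id, "e")
  expect_equal(pseudogene_filter(esvs, bad_cfg)$log$esv_id, "e")
})

test_that("a MOTU losing its last ESV disappears from the MOTU table", {
  fx <- worked_fixture()
  out <- pseudogene_filter(fx$esvs, fx$cfg)
  expect_false(fx$expected$pseudogene_removed %in% out$esvs$esv_id)
  rebuilt <- rebuild_motu_table(out$esvs, fx$motus)
  expect_false(fx$expected$motu_removed_by_pseudogene %in% rebuilt$motu_id)
})

test_that("sample-depth filter drops strictly-shallow samples only", {
  samples <- .filter_samples(c("deep", "exact", "shallow"))
  reads <- rbind(e1 = c(10000, 9500, 9499, 0, 0))
  colnames(reads) <- c("deep", "exact", "shallow", "BLK", "NEG")
  esvs <- esv_table(reads, c(e1 = "m"))
  out <- sample_depth_filter(esvs, samples, filter_config())
  expect_equal(out$removed, "shallow")
  expect_setequal(intersect(out$samples$sample_id,
                            c("deep", "exact", "shallow")),
                  c("deep", "exact"))

  cfg_all <- filter_config(min_sample_depth = 20000)
  expect_error(sample_depth_filter(esvs, samples, cfg_all), "all true samples")
})

test_that("metazoan restriction drops MOTUs by phylum, conserving counts", {
  tt <- tiny_tables()
  out <- restrict_to_marine_metazoa(tt$motus, tt$esvs, "Arthropoda")
  expect_equal(out$motus$motu_id, "m1")
  expect_equal(out$dropped, "m2")
  expect_equal(length(out$motus$motu_id) + length(out$dropped),
               length(tt$motus$motu_id))
  all_kept <- restrict_to_marine_metazoa(tt$motus, tt$esvs, metazoan_phyla)
  expect_equal(all_kept$motus$reads, tt$motus$reads)
})

test_that("the cascade never increases reads and preserves linkage", {
  bundle <- simulate_dataset(sim_config(seed = 5, n_nis_motus = 8,
                                        n_nat_motus = 15, n_other_motus = 20,
                                        n_timepoints = 3))
  cfg <- filter_config(min_sample_depth = 1000)
  b <- blank_filter(bundle$esvs, bundle$samples, cfg)
  expect_lte(sum(b$esvs$reads), sum(bundle$esvs$reads))
  cur <- drop_control_samples(b$esvs, bundle$samples)
  d <- dual_abundance_filter(cur, cfg)
  expect_lte(sum(d$esvs$reads), sum(cur$reads))
  p <- pseudogene_filter(d$esvs, cfg)
  expect_lte(sum(p$esvs$reads), sum(d$esvs$reads))
  m1 <- rebuild_motu_table(p$esvs, bundle$motus)
  expect_equal(nrow(validate_linkage(p$esvs, m1)), 0)
  s <- sample_depth_filter(p$esvs, bundle$samples, cfg)
  m2 <- rebuild_motu_table(s$esvs, m1)
  expect_equal(nrow(validate_linkage(s$esvs, m2)), 0)
  expect_lte(sum(s$esvs$reads), sum(p$esvs$reads))
})
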