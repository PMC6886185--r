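test_that("generation is deterministic under a fixed seed", {
  a <- make_transcriptome(50, 9)
  b <- make_transcriptome(50, 9)
  expect_identical(a, b)
  c_ <- make_transcriptome(50, 10)
  expect_false(identical(a$tx$utr5, c_$tx$utr5))

  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  s1 <- simulate_dataset(dir1, "minimal", seed = 4)
  s2 <- simulate_dataset(dir2, "minimal", seed = 4)
  for (f in c("transcripts.fa", "rip_eIF4A2_counts.tsv", "rpf_reads.tsv",
              "truth.tsv", "binding_titration.tsv")) {
    expect_identical(unname(tools::md5sum(file.path(dir1, f))),
                     unname(tools::md5sum(file.path(dir2, f))),
                     info = f)
  }
})

test_that("planted sequence features are recoverable, null ones are not", {
  p <- sim_params()
  mk <- make_transcriptome(800, 14, p)
  freq <- vapply(mk$tx$utr5, motif_frequency, numeric(1),
                 USE.NAMES = FALSE)
  e2 <- mk$truth$group == "eIF4A2"
  none <- mk$truth$group == "none"
  d <- kruskal_dunn(list(eIF4A2 = freq[e2], none = freq[none]),
                    correction = "bonferroni")
  expect_lt(d$p_adjusted, 0.05)
  # planted tetramers concentrate in the last 50 nt of the 5'UTR
  long <- nchar(mk$tx$utr5) >= 50
  pp <- positional_profile(mk$tx$utr5[e2 & long], mk$tx$utr5[none & long],
                           "utr5_last50")
  pf <- positional_profile(mk$tx$utr5[e2 & long], mk$tx$utr5[none & long],
                           "utr5_first50")
  expect_gt(mean(pp$enrichment, na.rm = TRUE),
            mean(pf$enrichment, na.rm = TRUE))
  expect_gt(mean(pp$enrichment, na.rm = TRUE), 1.2)

  # eIF4A1-like 5'UTR ends carry the planted GC gradient
  gc_tail <- function(s) {
    v <- rolling_gc(s)
    mean(utils::tail(v, 45))
  }
  a1 <- mk$truth$group == "eIF4A1"
  expect_gt(mean(vapply(mk$tx$utr5[a1 & long], gc_tail, numeric(1))),
            mean(vapply(mk$tx$utr5[none & long], gc_tail, numeric(1))) +
              0.1)

  # zero planting density: no group separation (frozen-seed null run)
  pn <- sim_params(effects = FALSE)
  mkn <- make_transcriptome(800, 15, pn)
  freqn <- vapply(mkn$tx$utr5, motif_frequency, numeric(1),
                  USE.NAMES = FALSE)
  gn <- mkn$truth$group
  dn <- kruskal_dunn(list(eIF4A2 = freqn[gn == "eIF4A2"],
                          none = freqn[gn == "none"]))
  expect_gt(dn$p_adjusted, 0.05)
})

test_that("simulated footprints honour the planted read geometry", {
  p <- sim_params()
  mk <- make_transcriptome(300, 16, p)
  rpf <- simulate_rpf(mk$truth, mk$tx, 16, p)
  expect_true(all(rpf$reads$length %in% 28:30))
  expect_true(all(rpf$reads$five_prime_pos >= 0))
  # periodicity: all three lengths pass the 0.6 modal-frame threshold
  kept <- select_periodic_lengths(rpf$reads, mk$tx)
  expect_setequal(as.integer(kept), 28:30)
  expect_true(all(attr(kept, "frame_fraction") > 0.6))
  # repressed transcripts carry ~0.4x footprint density
  ds <- rpf_dataset(rpf$reads, mk$tx, rpf$total_counts)
  rep_ids <- mk$truth$transcript_id[mk$truth$group == "eIF4A2"]
  bg_ids <- mk$truth$transcript_id[mk$truth$group == "none"]
  mg_rep <- metagene_cds(ds, mk$tx, rep_ids)
  mg_bg <- metagene_cds(ds, mk$tx, bg_ids)
  ratio <- mean(mg_rep$start_profile) / mean(mg_bg$start_profile)
  expect_lt(ratio, 0.7)
  expect_gt(ratio, 0.2)
})

test_that("simulated binding data respects its stated noise model", {
  b <- simulate_binding(17, noise_titration = 0)
  one <- b$titration[b$titration$protein == "eIF4A2" &
                       b$titration$rna == "AG" & b$titration$replicate == 1, ]
  f <- fit_hill(one$conc_M, anisotropy_change(one$conc_M, one$signal))
  expect_lt(abs(f$params[["kd"]] - b$truth$kd[["eIF4A2_AG"]]) /
              b$truth$kd[["eIF4A2_AG"]], 0.01)  # sigma = 0: exact recovery
  expect_equal(nrow(b$competition),
               length(b$truth$excess) * 3 * 12)
})

test_that("generator parameter validation is enforced", {
  expect_error(make_transcriptome(5, 1), ">= 10")
  p <- sim_params(); p$group_probs <- c(a = 0.5, b = 0.2)
  expect_error(make_transcriptome(20, 1, p), "sum to 1")
  p2 <- sim_params(); p2$disp_rip <- 0
  mk <- make_transcriptome(20, 1)
  expect_error(simulate_counts(mk$truth, 1, p2), "dispersion")
  p3 <- sim_params(); p3$tis_probs <- c(annotated = 0.5, utis = 0.1,
                                        both = 0.1, none = 0.1)
  expect_error(simulate_peaks_and_families(mk$truth, mk$tx, 1, p3),
               "sum to 1")
})
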