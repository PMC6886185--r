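test_that("periodicity selection retains frame-biased lengths only", {
  tx <- make_tx(utr5_len = 30, cds_len = 600, utr3_len = 30)
  # length 29: all frame 0; length 28: frames 1/3 each
  mk_reads <- function(len, positions) {
    data.frame(transcript_id = "tx01", five_prime_pos = positions,
               length = len)
  }
  cds0 <- 30  # cds start
  periodic <- mk_reads(29, cds0 + seq(0, 297, by = 3) - 13)
  scrambled <- mk_reads(28, cds0 + 0:99 - 13)
  reads <- rbind(periodic, scrambled)
  got <- select_periodic_lengths(reads, tx)
  expect_true(29 %in% got)
  expect_false(28 %in% got)
  fr <- attr(got, "frame_fraction")
  expect_equal(unname(fr["29"]), 1.0)
  expect_lt(unname(fr["28"]), 0.6)
  expect_error(select_periodic_lengths(mk_reads(20, 1:10), tx),
               "no reads")
})

test_that("psite_assign offsets, tallies and drops out-of-bounds reads", {
  tx <- make_tx(utr5_len = 50, cds_len = 120, utr3_len = 10)
  reads <- data.frame(
    transcript_id = "tx01",
    five_prime_pos = c(100, 100, 20, 180 - 5),  # tx length 180
    length = 28)
  v <- psite_assign(reads, tx, offset = 13)
  expect_equal(attr(v, "n_dropped"), 1)  # 175 + 13 > 179
  expect_equal(v$tx01[100 + 13 + 1], 2)  # two reads at 5' pos 100
  expect_equal(v$tx01[20 + 13 + 1], 1)
  expect_equal(sum(v$tx01), 3)
  expect_equal(length(v$tx01), 180)
  expect_error(psite_assign(reads, tx, offset = -1), ">= 0")
})

test_that("tpm normalises rates to one million", {
  expect_equal(unname(tpm(c(a = 7), c(1000))), 1e6)
  got <- tpm(c(a = 10, b = 10), c(1000, 2000))
  expect_equal(unname(got), c(2 / 3, 1 / 3) * 1e6)
  expect_equal(sum(got), 1e6)
  set.seed(5)
  x <- tpm(setNames(rpois(50, 40), paste0("t", 1:50)),
           sample(200:3000, 50))
  expect_equal(sum(x), 1e6, tolerance = 1e-9)
  expect_error(tpm(c(0, 0), c(10, 10)), "all-zero")
  expect_error(tpm(c(1, 1), c(0, 10)), "positive")
})

test_that("normalized_occupancy divides by TPM and excludes zero-TPM", {
  occ <- normalized_occupancy(list(t1 = c(2, 0, 4)), c(t1 = 200))
  expect_equal(occ$t1, c(0.01, 0, 0.02))
  # homogeneity: doubling TPM halves occupancy
  occ2 <- normalized_occupancy(list(t1 = c(2, 0, 4)), c(t1 = 400))
  expect_equal(occ2$t1, occ$t1 / 2)
  expect_message(
    z <- normalized_occupancy(list(t1 = c(1, 1), t2 = c(1, 1)),
                              c(t1 = 10, t2 = 0)), "zero TPM")
  expect_equal(names(z), "t1")
  expect_equal(attr(z, "excluded"), "t2")
})

uniform_ds <- function(tx, per_nt = 2L, total_counts = NULL) {
  # deterministic uniform coverage dataset bypassing read simulation
  ids <- tx$transcript_id
  vecs <- lapply(seq_along(ids), function(i) {
    rep(per_nt, tx$utr5_len[i] + tx$cds_len[i] + tx$utr3_len[i])
  })
  names(vecs) <- ids
  rpm <- rpm_normalize(vecs)
  if (is.null(total_counts)) total_counts <- setNames(rep(100, length(ids)),
                                                      ids)
  tpms <- tpm(total_counts, tx_lengths <- tx$utr5_len + tx$cds_len +
                tx$utr3_len)
  names(tpms) <- ids
  list(occupancy = normalized_occupancy(rpm, tpms), tpm = tpms,
       raw_totals = attr(rpm, "raw_totals"), retained_lengths = 28:30)
}

test_that("metagene enforces the CDS and read-count filters", {
  tx <- make_tx(utr5_len = c(10, 10, 10), cds_len = c(600, 300, 600),
                utr3_len = 10)
  ds <- uniform_ds(tx)
  ds$raw_totals[3] <- 24  # below the >= 25 footprint filter
  mg <- metagene_cds(ds, tx, tx$transcript_id)
  expect_equal(mg$n_transcripts, 1)  # CDS 300 excluded (strict > 300), tx3 too
  expect_equal(unname(mg$filter_report["cds_too_short"]), 1)
  expect_equal(unname(mg$filter_report["too_few_rpf"]), 1)
  expect_length(mg$start_profile, 75)
  expect_length(mg$stop_profile, 75)
  # uniform coverage gives a flat per-codon profile
  expect_lt(sd(mg$start_profile) / mean(mg$start_profile), 1e-12)
  expect_error(metagene_cds(ds, tx, tx$transcript_id[2]), "filters")
})

test_that("utr5 occupancy windows honour the strict length filter", {
  tx <- make_tx(utr5_len = c(100, 150), cds_len = 300, utr3_len = 10)
  ds <- uniform_ds(tx)
  u <- utr5_occupancy(ds, tx, tx$transcript_id)
  expect_equal(u$transcript_id, "tx02")  # 100 nt is excluded (needs > 100)
  expect_equal(u$last50 / u$first50, 1)  # uniform coverage
  expect_error(utr5_occupancy(ds, tx, "tx01"), "qualifying")
})

test_that("occupancy is invariant to duplicating reads", {
  tx <- make_tx(utr5_len = 120, cds_len = 600, utr3_len = 30)
  reads <- data.frame(transcript_id = "tx01",
                      five_prime_pos = 120 + seq(0, 597, by = 3) - 13,
                      length = 29)
  tot <- c(tx01 = 80)
  ds1 <- rpf_dataset(reads, tx, tot)
  ds2 <- rpf_dataset(rbind(reads, reads), tx, tot)
  expect_equal(ds2$occupancy$tx01, ds1$occupancy$tx01)
})
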