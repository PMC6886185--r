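test_that("classify_tis covers every peak configuration", {
  st <- 90
  cases <- expand.grid(at = c(FALSE, TRUE), up = c(FALSE, TRUE),
                       down = c(FALSE, TRUE))
  for (i in seq_len(nrow(cases))) {
    peaks <- c(if (cases$at[i]) st, if (cases$up[i]) st - 30,
               if (cases$down[i]) st + 60)
    got <- classify_tis(st, peaks %||% integer(0))
    want <- if (cases$at[i] && cases$up[i]) "both"
    else if (cases$at[i]) "annotated_only"
    else if (cases$up[i]) "utis_only"
    else "none"  # downstream peaks never affect the label
    expect_equal(got$label, want, info = paste(cases[i, ], collapse = "/"))
  }
  cl <- classify_tis(90, c(45, 90))
  expect_equal(cl$utis_positions, 45)
  expect_equal(cl$in_frame, TRUE)  # 45 nt upstream is a multiple of 3
})

test_that("utis_frame agrees with a codon-walk", {
  expect_true(utis_frame(60, 90))    # delta 30
  expect_false(utis_frame(59, 90))   # delta 31
  expect_false(utis_frame(89, 90))   # delta 1
  expect_error(utis_frame(90, 90), "upstream")
  # codon-walk oracle: stepping back 3 nt at a time lands exactly on pos
  for (st in c(30, 91)) {
    for (d in 1:12) {
      walk <- seq(st, 0, by = -3)
      expect_equal(utis_frame(st - d, st), (st - d) %in% walk)
    }
  }
})

test_that("group proportions exclude 'none' and sum to one", {
  cls <- data.frame(
    transcript_id = paste0("t", 1:6),
    label = c("annotated_only", "annotated_only", "annotated_only",
              "both", "none", "utis_only"),
    stringsAsFactors = FALSE)
  part <- data.frame(transcript_id = paste0("t", 1:6),
                     label = c(rep("A", 5), "B"))
  props <- group_tis_proportions(cls, part)
  a <- props[props$group == "A", ]
  expect_equal(c(a$annotated_only, a$utis_only, a$both), c(0.75, 0, 0.25))
  expect_equal(a$n, 4)  # the 'none' transcript is out of the denominator
  expect_equal(props$annotated_only + props$utis_only + props$both,
               rep(1, nrow(props)))
  # a group whose only transcript has no detected initiation is omitted
  part2 <- data.frame(transcript_id = paste0("t", 1:6),
                      label = c(rep("A", 4), "B", "A"))
  expect_warning(group_tis_proportions(cls, part2), "omitted")
  # planted utis excess is recovered by the generator round-trip
  p <- sim_params()
  mk <- make_transcriptome(1500, 33, p)
  pk <- simulate_peaks_and_families(mk$truth, mk$tx, 33, p)
  cls2 <- classify_tis_table(pk$peaks)
  part2 <- data.frame(transcript_id = mk$truth$transcript_id,
                      label = mk$truth$group)
  pr <- group_tis_proportions(cls2, part2)
  expect_gt(pr$utis_only[pr$group == "eIF4A2"],
            1.5 * pr$utis_only[pr$group == "none"])
})

test_that("miRNA-family enrichment matches the hypergeometric oracle", {
  universe <- sprintf("g%04d", 1:2000)
  grp <- universe[1:200]
  fam <- data.frame(
    family_id = rep(c("planted", "flat", "all"), c(50, 60, 2000)),
    gene_id = c(c(grp[1:40], universe[300:309]),     # 40/50 inside group
                universe[seq(5, 2000, length.out = 60)],
                universe),
    stringsAsFactors = FALSE)
  enr <- mirna_family_enrichment(list(group1 = grp), fam, universe)
  planted <- enr[enr$family_id == "planted", ]
  expect_lt(planted$fdr, 0.05)
  expect_equal(as.character(planted$fdr_bin), "<0.05")
  expect_equal(planted$p, oracle_fisher_p(40, 200, 50, 2000))
  # a family covering the whole universe can never be enriched
  expect_equal(enr$p[enr$family_id == "all"], 1)
  # every p matches the enumeration oracle
  for (i in seq_len(nrow(enr))) {
    expect_equal(enr$p[i],
                 oracle_fisher_p(enr$k[i], enr$n[i], enr$K[i], enr$N[i]),
                 tolerance = 1e-12)
  }
  # empty-in-universe families are skipped with a message
  fam2 <- rbind(fam, data.frame(family_id = "ghost", gene_id = "absent"))
  expect_message(mirna_family_enrichment(list(g = grp), fam2, universe),
                 "skipped")
  # fdr bins partition [0, 1]
  bins <- fdr_bin <- table(cut(c(0, 0.049, 0.05, 0.099, 0.1, 0.2, 1),
                               c(-Inf, 0.05, 0.1, 0.2, Inf), right = FALSE))
  expect_equal(sum(bins), 7)
})
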