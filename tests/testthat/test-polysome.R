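grad_cm <- function(sub, poly, condition = "control",
                    library_sizes = NULL) {
  m <- cbind(as.matrix(sub), as.matrix(poly))
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
  colnames(m) <- sprintf("s%d", seq_len(ncol(m)))
  meta <- data.frame(
    sample = colnames(m),
    assay = rep(c("subpolysomal", "polysomal"),
                c(ncol(as.matrix(sub)), ncol(as.matrix(poly)))),
    condition = condition,
    replicate = c(seq_len(ncol(as.matrix(sub))),
                  seq_len(ncol(as.matrix(poly)))),
    stringsAsFactors = FALSE)
  count_matrix(m, meta, library_sizes)
}

test_that("association_score subtracts mean CPM and is antisymmetric", {
  # equal library sizes of 1e6 make counts equal CPM
  cm <- grad_cm(matrix(c(10, 5), 2), matrix(c(30, 5), 2),
                library_sizes = c(1e6, 1e6))
  sc <- association_score(cm)
  expect_equal(sc$score, c(20, 0))

  # swapping the fraction labels negates the score
  swapped <- cm
  swapped$sample_meta$assay <- rev(swapped$sample_meta$assay)
  expect_equal(association_score(swapped)$score, -sc$score)

  # linear in CPM: doubling counts at fixed library size doubles the score
  cm2 <- grad_cm(matrix(c(20, 10), 2), matrix(c(60, 10), 2),
                 library_sizes = c(1e6, 1e6))
  expect_equal(association_score(cm2)$score, 2 * sc$score)

  # FPKM variant divides by length in kb
  lens <- setNames(c(2000, 500), rownames(cm$counts))
  expect_equal(association_score(cm, unit = "fpkm", lengths = lens)$score,
               sc$score / c(2, 0.5))
  expect_error(association_score(make_cm(matrix(1:2, 1), "total")),
               "polysomal")
})

test_that("differential_shift recovers balanced planted shifts", {
  # Balanced world, as in a CNOT1 depletion: some mRNAs move into
  # polysomes (100<->40 across fractions, dispersion 0.05, n = 4), an
  # equal number move out, the rest are untouched — library sizes stay
  # comparable so CPM normalisation is not confounded compositionally.
  set.seed(42)
  n <- 300; into <- 1:75; outof <- 76:150; null <- 151:300
  mu_sub_c <- rep(70, n); mu_poly_c <- rep(70, n)
  mu_sub_c[into] <- 100; mu_poly_c[into] <- 40
  mu_sub_c[outof] <- 40; mu_poly_c[outof] <- 100
  mu_sub_k <- mu_sub_c; mu_poly_k <- mu_poly_c
  mu_sub_k[into] <- 40; mu_poly_k[into] <- 100
  mu_sub_k[outof] <- 100; mu_poly_k[outof] <- 40
  gen <- function(mu, reps = 4) {
    m <- sapply(seq_len(reps), function(r) rnbinom(n, mu = mu, size = 20))
    rownames(m) <- sprintf("g%03d", seq_len(n))
    m
  }
  ctrl <- grad_cm(gen(mu_sub_c), gen(mu_poly_c))
  kd <- grad_cm(gen(mu_sub_k), gen(mu_poly_k), "knockdown")
  sh <- differential_shift(ctrl, kd)
  expect_gte(mean(sh$shifted[into]), 0.6)
  expect_gte(mean(sh$shifted[outof]), 0.6)
  expect_true(all(sh$direction[into][sh$shifted[into]] ==
                    "into_polysomes"))
  expect_true(all(sh$direction[outof][sh$shifted[outof]] ==
                    "out_of_polysomes"))
  # unchanged genes essentially never called
  expect_lte(mean(sh$shifted[null]), 0.05)
})

test_that("a gene significant in one fraction only is not shifted", {
  # subpolysomal counts identical across conditions (zero variance, p = 1);
  # polysomal strongly changed
  sub <- matrix(50, 4, 4, dimnames = list(sprintf("g%03d", 1:4)))
  poly_c <- matrix(rep(c(40, 41, 39, 40), 4), 4, byrow = FALSE,
                   dimnames = list(sprintf("g%03d", 1:4)))
  poly_k <- poly_c * 8
  ctrl <- grad_cm(sub, poly_c)
  kd <- grad_cm(sub, poly_k, "knockdown")
  sh <- differential_shift(ctrl, kd)
  expect_true(all(!sh$shifted))
  expect_error(
    differential_shift(grad_cm(sub[, 1, drop = FALSE],
                               poly_c[, 1, drop = FALSE]), kd),
    ">= 2 replicates")
})

test_that("group_shift_comparison delegates to Dunn and drops tiny groups", {
  set.seed(7)
  scores <- setNames(rnorm(60), sprintf("g%03d", 1:60))
  part <- data.frame(gene_id = names(scores),
                     label = rep(c("A", "B", "tiny"), c(29, 29, 2)),
                     stringsAsFactors = FALSE)
  expect_warning(cmp <- group_shift_comparison(scores, part), "tiny")
  expect_equal(nrow(cmp), 1)  # only A vs B
  # identical groups give z = 0
  part2 <- data.frame(gene_id = names(scores)[1:20],
                      label = rep(c("A", "B"), 10))
  sc2 <- setNames(rep(c(1, 1), 10), names(scores)[1:20])
  cmp2 <- group_shift_comparison(sc2, part2)
  expect_equal(cmp2$z, 0)
})
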