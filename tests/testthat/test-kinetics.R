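hill_y <- function(x, kd, h, amp, base) {
  base + amp * ifelse(x > 0, x^h / (kd^h + x^h), 0)
}

test_that("anisotropy_change subtracts the zero-protein baseline", {
  conc <- c(0, 1e-7, 1e-6)
  expect_equal(anisotropy_change(conc, c(0.05, 0.05, 0.15)),
               c(0, 0, 0.10))
  expect_error(anisotropy_change(c(1e-7, 1e-6), c(0.1, 0.2)),
               "zero-protein")
  expect_warning(anisotropy_change(conc, c(0.05, 0.01, 0.15)),
                 "artifact")
})

test_that("fit_hill recovers noiseless parameters and half-saturation", {
  x <- c(0, 10^seq(-8, -4.5, length.out = 11))
  kd <- 5e-7; amp <- 0.12; base <- 0.03
  y <- hill_y(x, kd, 1, amp, base)
  f <- fit_hill(x, y)
  expect_true(f$converged)
  expect_lt(abs(f$params[["kd"]] - kd) / kd, 0.01)
  expect_lt(abs(f$params[["hill_h"]] - 1), 0.01)
  # fitted curve at the fitted KD sits at half saturation by construction
  yk <- hill_y(f$params[["kd"]], f$params[["kd"]], f$params[["hill_h"]],
               f$params[["amplitude"]], f$params[["baseline"]])
  expect_equal(yk, f$params[["baseline"]] + f$params[["amplitude"]] / 2)

  # flat data cannot converge
  flat <- fit_hill(x, rep(0.03, length(x)))
  expect_false(flat$converged)
  # non-monotone saturated data (max signal at lowest concentration)
  bad <- fit_hill(x, rev(y))
  expect_false(bad$converged)
  expect_error(fit_hill(c(0, 1e-7, 1e-7, 1e-7, 2e-7), rep(1, 5)),
               "distinct")
})

test_that("fit_hill recovers KD within 10% at 2% noise (median)", {
  x <- rep(c(0, 10^seq(-8, -4.5, length.out = 11)), 3)
  kd <- 5e-7; amp <- 0.12
  set.seed(21)
  errs <- replicate(60, {
    y <- hill_y(x, kd, 1, amp, 0.03) + rnorm(length(x), 0, 0.02 * amp)
    f <- fit_hill(x, y)
    abs(f$params[["kd"]] - kd) / kd
  })
  expect_lt(median(errs), 0.10)
})

test_that("fit_exp_decay ties half-life to the rate and spots bad input", {
  tt <- seq(0, 60, by = 5)
  y <- 0.02 + 0.1 * exp(-0.1 * tt)
  f <- fit_exp_decay(tt, y)
  expect_true(f$converged)
  expect_lt(abs(f$params[["k"]] - 0.1) / 0.1, 1e-3)
  expect_equal(f$params[["half_life"]] * f$params[["k"]], log(2))
  expect_equal(fit_exp_decay(tt, 0.05 + 0.2 * exp(-0.02 * tt))$params[["half_life"]],
               log(2) / 0.02, tolerance = 1e-3)
  inc <- fit_exp_decay(tt, 0.02 + 0.001 * tt)
  expect_false(inc$converged)
  expect_error(fit_exp_decay(tt[-1] , y[-1]), "t = 0")
})

test_that("decay rate is recovered within 10% at 3% noise (median)", {
  tt <- rep(seq(0, 60, by = 5), 3)
  k <- 0.05; amp <- 0.1
  set.seed(22)
  errs <- replicate(60, {
    y <- 0.02 + amp * exp(-k * tt) + rnorm(length(tt), 0, 0.03 * amp)
    f <- fit_exp_decay(tt, y)
    abs(f$params[["k"]] - k) / k
  })
  expect_lt(median(errs), 0.10)
})

test_that("competition equilibrium solver is exact and conserves mass", {
  # no competitor reduces to the single-site quadratic closed form
  P <- 2e-6; R <- 25e-9; kd <- 3e-7
  s <- solve_competition_equilibrium(P, R, 0, kd, 1)
  b <- (P + R + kd - sqrt((P + R + kd)^2 - 4 * P * R)) / 2
  expect_equal(s$complex_L, b, tolerance = 1e-9)

  # symmetric RNAs bind symmetrically
  sym <- solve_competition_equilibrium(1e-6, 5e-8, 5e-8, 4e-7, 4e-7)
  expect_equal(sym$fraction_bound_L, sym$fraction_bound_C)

  set.seed(23)
  for (i in 1:50) {
    P <- 10^runif(1, -8, -5); RL <- 10^runif(1, -9, -6)
    RC <- 10^runif(1, -9, -6)
    KL <- 10^runif(1, -8, -5); KC <- 10^runif(1, -8, -5)
    s <- solve_competition_equilibrium(P, RL, RC, KL, KC)
    o <- oracle_competition(P, RL, RC, KL, KC)
    expect_equal(s$P_free, o$P_free, tolerance = 1e-6)
    # mass conservation to 1e-9 relative
    expect_equal(s$P_free + s$complex_L + s$complex_C, P,
                 tolerance = 1e-9)
    free_L <- RL * (1 - s$fraction_bound_L)
    expect_equal(free_L + s$complex_L, RL, tolerance = 1e-9)
  }
  expect_equal(solve_competition_equilibrium(0, 1e-8, 0, 1e-7, 1)$P_free, 0)
  expect_error(solve_competition_equilibrium(1e-6, 1e-8, 0, -1, 1), "> 0")
})

test_that("apparent KD from competition fits behaves physically", {
  kd_l <- 3e-7; kd_c <- 3e-5; rl <- 25e-9
  conc <- c(0, 10^seq(-8.5, -5.2, length.out = 12))
  curve <- function(excess) {
    vapply(conc, function(p) {
      solve_competition_equilibrium(p, rl, excess * rl, kd_l,
                                    kd_c)$fraction_bound_L
    }, numeric(1))
  }
  f0 <- fit_competition(conc, curve(0))
  expect_true(f0$converged)
  expect_lt(abs(f0$params[["kd"]] - kd_l) / kd_l, 0.1)  # zero competitor
  # 50x excess of a 100x weaker competitor barely moves the apparent KD
  f50 <- fit_competition(conc, curve(50))
  expect_lt(abs(f50$params[["kd"]] - kd_l) / kd_l, 0.2)
  # apparent KD is non-decreasing in competitor excess
  kds <- vapply(c(0, 5, 20, 50, 200),
                function(e) fit_competition(conc, curve(e))$params[["kd"]],
                numeric(1))
  expect_true(all(diff(kds) > -0.02 * kds[-length(kds)]))
  expect_error(fit_competition(conc, rep(2, length(conc))), "tolerance")
})

test_that("fits are invariant to input row order", {
  x <- c(0, 10^seq(-8, -4.5, length.out = 11))
  set.seed(24)
  y <- hill_y(x, 5e-7, 1.2, 0.1, 0.02) + rnorm(length(x), 0, 0.002)
  perm <- sample(length(x))
  f1 <- fit_hill(x, y); f2 <- fit_hill(x[perm], y[perm])
  expect_equal(f1$params, f2$params, tolerance = 1e-6)
})
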