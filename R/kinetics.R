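# In vitro RNA-binding models: equilibrium titrations fit with the Hill
# equation, strand-release kinetics fit with a single-exponential decay,
# and an exact mass-balance solver for competition binding.

#' Convert raw anisotropy to changes in anisotropy
#'
#' Subtracts the free-RNA baseline (the zero-protein measurement). A
#' missing zero-protein point with no explicit baseline is fatal; changes
#' below -0.02 trigger a photophysics-artifact warning.
#'
#' @param conc protein concentration series (M).
#' @param raw raw anisotropy readings.
#' @param baseline optional explicit free-RNA baseline; defaults to the
#'   mean raw value at zero protein.
#' @return numeric vector of anisotropy changes.
#' @export
anisotropy_change <- function(conc, raw, baseline = NULL) {
  if (is.null(baseline)) {
    if (!any(conc == 0)) stop("no zero-protein point and no baseline given")
    baseline <- mean(raw[conc == 0])
  }
  d <- raw - baseline
  if (any(d < -0.02)) {
    warning("anisotropy change below -0.02; possible photophysics artifact")
  }
  d
}

hill_f <- function(x, kd, h, amplitude, baseline) {
  baseline + amplitude * ifelse(x > 0, x^h / (kd^h + x^h), 0)
}

num_jacobian <- function(f, theta, eps = 1e-6) {
  f0 <- f(theta)
  J <- matrix(0, length(f0), length(theta))
  for (j in seq_along(theta)) {
    d <- max(abs(theta[j]), 1) * eps
    tp <- theta; tp[j] <- tp[j] + d
    J[, j] <- (f(tp) - f0) / d
  }
  J
}

fit_se <- function(predict_fun, theta, residuals) {
  n <- length(residuals); p <- length(theta)
  if (n <= p) return(rep(NA_real_, p))
  J <- num_jacobian(predict_fun, theta)
  s2 <- sum(residuals^2) / (n - p)
  cov <- tryCatch(s2 * solve(crossprod(J)), error = function(e) NULL)
  if (is.null(cov)) rep(NA_real_, p) else sqrt(pmax(diag(cov), 0))
}

new_fit <- function(model, params, se, converged, rss, diagnostic = NULL) {
  structure(list(model = model, params = params, se = se,
                 converged = converged, rss = rss,
                 diagnostic = diagnostic),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat("binding_fit (", x$model, "), converged:", x$converged, "\n")
  print(signif(x$params, 4))
  if (!is.null(x$diagnostic)) cat("diagnostic:", x$diagnostic, "\n")
  invisible(x)
}

#' Fit the Hill equation to a titration
#'
#' Least-squares fit of y = baseline + amplitude * x^h / (KD^h + x^h) with
#' the Hill coefficient bounded to \[0.3, 4\] and multi-start from five
#' log-spaced KD guesses across the concentration range (deterministic, no
#' RNG). The convergence flag is set to FALSE when the optimiser reports
#' failure, a bound is hit, the fitted KD falls outside the titrated range
#' (the data do not span half-saturation), the fitted amplitude is not
#' positive, or the data are saturated non-monotonically (maximum signal at
#' the lowest concentration). Free-ligand conditions are assumed, as in
#' conventional Hill fitting of anisotropy titrations.
#'
#' @param x concentrations (M); at least 5 distinct values, zero allowed.
#' @param y signal (anisotropy change or fraction bound).
#' @param h_bounds bounds on the Hill coefficient.
#' @return a `binding_fit` with params `kd`, `hill_h`, `amplitude`,
#'   `baseline` and matching standard errors.
#' @export
fit_hill <- function(x, y, h_bounds = c(0.3, 4)) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(unique(x)) < 5L) stop("need >= 5 distinct concentrations")
  xp <- x[x > 0]
  if (length(xp) == 0L) stop("need positive concentrations")
  ymeans <- vapply(split(y, x), mean, numeric(1))
  xs <- as.numeric(names(ymeans))
  no_range <- diff(range(y)) == 0
  nonmono <- which.max(ymeans) == which.min(xs) && !no_range
  lo_kd <- log(min(xp) / 100); hi_kd <- log(max(xp) * 100)
  obj <- function(th) {
    sum((y - hill_f(x, exp(th[1]), th[2], th[3], th[4]))^2)
  }
  starts <- exp(seq(log(min(xp)), log(max(xp)), length.out = 5))
  amp0 <- max(y) - min(y); base0 <- min(y)
  best <- NULL
  for (kd0 in starts) {
    fit <- tryCatch(
      optim(c(log(kd0), 1, amp0, base0), obj, method = "L-BFGS-B",
            lower = c(lo_kd, h_bounds[1], -Inf, -Inf),
            upper = c(hi_kd, h_bounds[2], Inf, Inf),
            control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) {
      best <- fit
    }
  }
  if (is.null(best)) {
    return(new_fit("hill", c(kd = NA, hill_h = NA, amplitude = NA,
                             baseline = NA), rep(NA_real_, 4), FALSE, NA,
                   "optimization failed"))
  }
  th <- best$par
  kd <- exp(th[1])
  params <- c(kd = kd, hill_h = th[2], amplitude = th[3], baseline = th[4])
  pred <- function(t) hill_f(x, exp(t[1]), t[2], t[3], t[4])
  res <- y - pred(th)
  se <- fit_se(pred, th, res)
  se[1] <- se[1] * kd  # delta method: SE(KD) from SE(log KD)
  names(se) <- names(params)
  tol <- 1e-6
  at_bound <- th[1] <= lo_kd + tol || th[1] >= hi_kd - tol ||
    th[2] <= h_bounds[1] + tol || th[2] >= h_bounds[2] - tol
  spans <- kd >= min(xp) && kd <= max(xp)
  diagnostic <- if (nonmono) "non-monotone saturated data"
  else if (no_range) "no signal range"
  else if (at_bound) "parameter at bound"
  else if (!spans) "KD outside titrated range"
  else if (params["amplitude"] <= 0) "non-positive amplitude"
  else NULL
  converged <- best$convergence == 0 && is.null(diagnostic)
  new_fit("hill", params, se, converged, best$value, diagnostic)
}

#' Fit a single-exponential decay to a strand-release time course
#'
#' y = plateau + amplitude * exp(-k t); the half-life t1/2 = ln(2)/k is
#' reported alongside. Increasing signal flips the convergence flag to
#' FALSE. Multi-start over log-spaced rate guesses (deterministic).
#'
#' @param t time points (same unit as the reported rate); must include 0.
#' @param y signal.
#' @return a `binding_fit` with params `k`, `half_life`, `amplitude`,
#'   `plateau`.
#' @export
fit_exp_decay <- function(t, y) {
  if (length(t) != length(y)) stop("t and y lengths differ")
  if (length(unique(t)) < 5L) stop("need >= 5 time points")
  if (!any(t == 0)) stop("time series must include t = 0")
  increasing <- stats::cor(t, y) > 0
  tr <- diff(range(t[t >= 0]))
  obj <- function(th) sum((y - (th[3] + th[2] * exp(-exp(th[1]) * t)))^2)
  amp0 <- mean(y[t == 0]) - min(y)
  best <- NULL
  for (k0 in exp(seq(log(0.01 / tr * 10), log(10 / tr * 10),
                     length.out = 6))) {
    fit <- tryCatch(
      optim(c(log(k0), amp0, min(y)), obj, method = "BFGS",
            control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) {
      best <- fit
    }
  }
  if (is.null(best)) {
    return(new_fit("exp_decay", c(k = NA, half_life = NA, amplitude = NA,
                                  plateau = NA), rep(NA_real_, 4), FALSE,
                   NA, "optimization failed"))
  }
  th <- best$par
  k <- exp(th[1])
  params <- c(k = k, half_life = log(2) / k, amplitude = th[2],
              plateau = th[3])
  pred <- function(p) p[3] + p[2] * exp(-exp(p[1]) * t)
  se3 <- fit_se(pred, th, y - pred(th))
  se3[1] <- se3[1] * k
  se <- c(se3[1], log(2) / k^2 * se3[1], se3[2], se3[3])
  names(se) <- names(params)
  diagnostic <- if (increasing) "increasing signal" else NULL
  converged <- best$convergence == 0 && !increasing && params["amplitude"] > 0
  new_fit("exp_decay", params, se, converged, best$value, diagnostic)
}

#' Solve the competition binding equilibrium exactly
#'
#' One protein P binding two RNAs (labelled L, competitor C) with
#' independent dissociation constants. The free-protein mass balance
#' P_total = P_free (1 + RL_total/(KD_L + P_free) ... ) combined with the
#' RNA balances reduces to a single monotone equation in P_free,
#' f(P_free) = P_free + RL_total P_free/(KD_L + P_free) +
#' RC_total P_free/(KD_C + P_free) - P_total, solved by bracketed
#' root-finding and polished by Newton steps to 1e-12 relative tolerance.
#' No free-ligand approximation is made.
#'
#' @param P_total,RL_total,RC_total total concentrations (> 0 protein; RNA
#'   totals >= 0).
#' @param KD_L,KD_C dissociation constants (> 0).
#' @return list with `P_free`, `fraction_bound_L`, `fraction_bound_C`,
#'   `complex_L`, `complex_C`.
#' @export
solve_competition_equilibrium <- function(P_total, RL_total, RC_total,
                                          KD_L, KD_C) {
  if (P_total < 0 || RL_total < 0 || RC_total < 0 || KD_L <= 0 ||
      KD_C <= 0) {
    stop("concentrations must be >= 0 and dissociation constants > 0")
  }
  if (P_total == 0) {
    return(list(P_free = 0, fraction_bound_L = 0, fraction_bound_C = 0,
                complex_L = 0, complex_C = 0))
  }
  f <- function(pf) {
    pf + RL_total * pf / (KD_L + pf) + RC_total * pf / (KD_C + pf) - P_total
  }
  fp <- function(pf) {
    1 + RL_total * KD_L / (KD_L + pf)^2 + RC_total * KD_C / (KD_C + pf)^2
  }
  root <- uniroot(f, c(0, P_total), tol = 1e-12 * max(P_total, 1))$root
  for (i in 1:8) {  # Newton polish; f is smooth and increasing
    step <- f(root) / fp(root)
    root <- max(root - step, 0)
    if (abs(step) <= 1e-14 * max(root, P_total)) break
  }
  if (abs(f(root)) > 1e-12 * P_total) {
    stop("equilibrium solver did not reach 1e-12 relative tolerance")
  }
  fbL <- root / (KD_L + root)
  fbC <- root / (KD_C + root)
  list(P_free = root,
       fraction_bound_L = fbL, fraction_bound_C = fbC,
       complex_L = RL_total * fbL, complex_C = RC_total * fbC)
}

#' Fit an apparent KD to competition binding data
#'
#' At a fixed competitor excess, the fraction of labelled RNA bound versus
#' total protein concentration is fit with the Hill equation (the
#' conventional analysis of competition EMSAs); the fitted KD is the
#' *apparent* dissociation constant at that excess and is non-decreasing in
#' competitor strength/excess.
#'
#' @param conc total protein concentrations (M).
#' @param fraction_bound fraction of labelled RNA bound, within
#'   \[-0.05, 1.05\].
#' @return a `binding_fit` (see [fit_hill()]); `params["kd"]` is the
#'   apparent KD.
#' @export
fit_competition <- function(conc, fraction_bound) {
  if (any(fraction_bound < -0.05 | fraction_bound > 1.05)) {
    stop("fraction bound outside the [-0.05, 1.05] tolerance band")
  }
  fit_hill(conc, fraction_bound)
}
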