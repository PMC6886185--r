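# Statistical primitives used throughout the pipeline: multiple-testing
# corrections, the one-sided Fisher test for gene-set enrichment, and the
# Kruskal-Wallis / Dunn post hoc machinery used for group comparisons of
# scores and motif frequencies.

#' Benjamini-Hochberg step-up adjustment
#'
#' Returns FDR q-values for a vector of p-values: with order statistics
#' p_(1) <= ... <= p_(n), q_(i) = min_{j >= i} p_(j) * n / j, mapped back to
#' the input order (permutation-equivariant).
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length and order as `p`.
#' @export
benjamini_hochberg <- function(p) {
  check_pvalues(p)
  n <- length(p)
  if (n == 0L) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(n / (n:1) * p[o]))
  q[order(o)]
}

#' Bonferroni adjustment
#' @param p numeric vector of p-values in \[0, 1\].
#' @return `pmin(1, p * length(p))`.
#' @export
bonferroni <- function(p) {
  check_pvalues(p)
  pmin(1, p * length(p))
}

check_pvalues <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  invisible(p)
}

adjust_p <- function(p, method = c("benjamini_hochberg", "bonferroni")) {
  method <- match.arg(method)
  switch(method,
         benjamini_hochberg = benjamini_hochberg(p),
         bonferroni = bonferroni(p))
}

#' One-sided Fisher's exact test for gene-set enrichment
#'
#' Tests over-representation of a target set in a group drawn from a
#' universe: with `k` targets among `n` group genes, `K` targets among `N`
#' universe genes, p = P(X >= k) for X ~ hypergeometric(N, K, n). The odds
#' ratio is computed from the 2x2 table (with 0.5 added to every cell only
#' when some cell is zero; reported, never used in the p-value).
#'
#' @param k targets in the group. @param n group size.
#' @param K targets in the universe. @param N universe size.
#' @return list with `p` and `odds_ratio`.
#' @export
fisher_exact_onesided <- function(k, n, K, N) {
  if (N < 1 || n > N || K > N || k > min(n, K) || min(k, n, K) < 0) {
    stop("inconsistent 2x2 margins")
  }
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  a <- k; b <- n - k; c_ <- K - k; d <- N - K - (n - k)
  if (min(a, b, c_, d) == 0) {
    a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5
  }
  list(p = p, odds_ratio = (a * d) / (b * c_))
}

#' Kruskal-Wallis with Dunn's post hoc test
#'
#' Ranks the pooled observations with mid-ranks for ties and computes, for
#' every pair of groups, the Dunn z statistic
#' z = (Rbar_a - Rbar_b) / sqrt(S2 * (1/n_a + 1/n_b)) with the tie-corrected
#' variance S2 = N(N+1)/12 - sum(t^3 - t) / (12(N-1)), a two-sided normal
#' p-value, and the chosen multiplicity correction over all pairs. When all
#' pooled values are identical the variance collapses and every pair is
#' reported as z = 0, p = 1.
#'
#' @param groups named list of numeric vectors (>= 2 non-empty groups).
#' @param correction `"bonferroni"` (classic Dunn) or
#'   `"benjamini_hochberg"`.
#' @return data.frame with `group_a`, `group_b`, `z`, `p_raw`,
#'   `p_adjusted`, `method`; the Kruskal-Wallis statistic and its
#'   chi-squared p-value are attached as attributes `kw_statistic` and
#'   `kw_p`.
#' @export
kruskal_dunn <- function(groups,
                         correction = c("bonferroni", "benjamini_hochberg")) {
  correction <- match.arg(correction)
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop("groups must be named")
  }
  sizes <- lengths(groups)
  if (any(sizes == 0L)) {
    stop("empty group(s): ", paste(names(groups)[sizes == 0], collapse = ", "))
  }
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), sizes)
  N <- length(x)
  r <- rank(x)  # mid-ranks
  ties <- table(r)
  tie_term <- sum(ties^3 - ties)
  S2 <- if (N > 1) N * (N + 1) / 12 - tie_term / (12 * (N - 1)) else 0
  rbar <- vapply(split(r, g), mean, numeric(1))[names(groups)]
  # Kruskal-Wallis statistic with tie correction
  H <- (12 / (N * (N + 1))) * sum(sizes * (rbar - (N + 1) / 2)^2)
  tie_c <- 1 - tie_term / (N^3 - N)
  H <- if (tie_c > 0) H / tie_c else 0
  kw_p <- stats::pchisq(H, df = length(groups) - 1, lower.tail = FALSE)

  pairs <- utils::combn(names(groups), 2)
  res <- apply(pairs, 2, function(pr) {
    a <- pr[1]; b <- pr[2]
    v <- S2 * (1 / sizes[[a]] + 1 / sizes[[b]])
    z <- if (v > 0) (rbar[[a]] - rbar[[b]]) / sqrt(v) else 0
    c(z = z, p = 2 * pnorm(-abs(z)))
  })
  out <- data.frame(
    group_a = pairs[1, ], group_b = pairs[2, ],
    z = res["z", ], p_raw = res["p", ],
    p_adjusted = adjust_p(res["p", ], correction),
    method = correction,
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "kw_statistic") <- H
  attr(out, "kw_p") <- kw_p
  out
}
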