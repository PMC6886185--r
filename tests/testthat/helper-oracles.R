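# Independent oracles and tiny fixture builders shared across tests. The
# oracles deliberately use different machinery from the implementation
# (regex scans, explicit choose() sums, permutation draws, grid/bisection).

`%||%` <- function(a, b) if (is.null(a)) b else a

random_dna <- function(n, probs = c(A = 0.3, C = 0.2, G = 0.2, T = 0.25,
                                    N = 0.05)) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs),
        collapse = "")
}

# Brute-force non-overlapping motif count: regex lookahead finds every
# (overlapping) match start per motif, then greedy left-to-right selection.
oracle_count_motifs <- function(sequence, motifs) {
  starts <- sort(unique(unlist(lapply(motifs, function(m) {
    r <- gregexpr(paste0("(?=", m, ")"), sequence, perl = TRUE)[[1]]
    r[r > 0]
  }))))
  w <- nchar(motifs[1])
  cnt <- 0L; nxt <- 1L
  for (s in starts) {
    if (s >= nxt) { cnt <- cnt + 1L; nxt <- s + w }
  }
  cnt
}

# Overlapping match count (upper bound on the non-overlapping count).
oracle_count_overlapping <- function(sequence, motifs) {
  length(unique(unlist(lapply(motifs, function(m) {
    r <- gregexpr(paste0("(?=", m, ")"), sequence, perl = TRUE)[[1]]
    r[r > 0]
  }))))
}

# Exhaustive hypergeometric upper tail via explicit binomial coefficients.
oracle_fisher_p <- function(k, n, K, N) {
  js <- k:min(n, K)
  js <- js[js >= max(0, n - (N - K))]
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Monte-Carlo permutation tails of |Dunn z| for two groups: returns the
# weak (>=) and strict (>) tail estimates, bracketing the continuous tail.
oracle_dunn_perm <- function(a, b, n_perm = 1e5, seed = 42) {
  set.seed(seed)
  x <- c(a, b); na <- length(a); nb <- length(b); N <- na + nb
  r <- rank(x)
  ties <- table(r)
  S2 <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  zstat <- function(idx) {
    (mean(r[idx]) - mean(r[-idx])) / sqrt(S2 * (1 / na + 1 / nb))
  }
  z_obs <- abs(zstat(seq_len(na)))
  zs <- abs(vapply(seq_len(n_perm),
                   function(i) zstat(sample.int(N, na)), numeric(1)))
  list(z_obs = z_obs,
       p_ge = mean(zs >= z_obs - 1e-12),
       p_gt = mean(zs > z_obs + 1e-12))
}

# Grid + bisection solver for the competition equilibrium, independent of
# the package's Newton/uniroot path.
oracle_competition <- function(P_total, RL_total, RC_total, KD_L, KD_C) {
  f <- function(pf) {
    pf + RL_total * pf / (KD_L + pf) + RC_total * pf / (KD_C + pf) - P_total
  }
  lo <- 0; hi <- P_total
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  pf <- (lo + hi) / 2
  list(P_free = pf,
       fraction_bound_L = pf / (KD_L + pf),
       fraction_bound_C = pf / (KD_C + pf))
}

# Small count_matrix fixture.
make_cm <- function(counts, assay, condition = "control",
                    library_sizes = NULL) {
  m <- as.matrix(counts)
  if (is.null(rownames(m))) {
    rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
  }
  colnames(m) <- sprintf("s%d", seq_len(ncol(m)))
  meta <- data.frame(sample = colnames(m),
                     assay = rep(assay, length.out = ncol(m)),
                     condition = rep(condition, length.out = ncol(m)),
                     replicate = seq_len(ncol(m)),
                     stringsAsFactors = FALSE)
  count_matrix(m, meta, library_sizes)
}

# Minimal transcript annotation: k transcripts with given region lengths.
make_tx <- function(utr5_len, cds_len, utr3_len,
                    ids = sprintf("tx%02d", seq_along(utr5_len))) {
  mk <- function(n) {
    vapply(n, function(k) paste(rep("A", k), collapse = ""), character(1))
  }
  cds <- vapply(cds_len, function(k) {
    paste0("ATG", paste(rep("C", k - 6), collapse = ""), "TAA")
  }, character(1))
  transcript_records(ids, paste0("gene_", ids), mk(utr5_len), cds,
                     mk(utr3_len))
}
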