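# Synthetic-data generation with known ground truth. Emulates the
# statistical structure the analyses assume: negative-binomial RIP and
# gradient count matrices with planted effects, 3-nt periodic footprints
# with planted 5'UTR peaks, transcript sequences with planted purine
# tetramers and GC gradients, initiation peaks, miRNA families, and noisy
# binding curves. One gene carries one transcript.

sub_seed <- function(seed, k) as.integer((seed %% 1000000L) * 1000L + k)

#' Default generator parameters
#'
#' The stated world of the synthetic experiment: group proportions of the
#' binding partition, log-normal region-length distributions, planted
#' effect sizes (4x IP enrichment, polysome-fraction shifts under CNOT1
#' knockdown, 0.4x translation with a 3x 5'UTR-end occupancy peak for
#' repressed mRNAs, purine-tetramer planting and a GC gradient), and
#' negative-binomial dispersions (0.1 RNA-Seq-like, 0.2 RIP).
#'
#' @param effects logical; `FALSE` zeroes every planted effect (null
#'   world) while keeping the same sampling layout.
#' @return named list of parameters.
#' @export
sim_params <- function(effects = TRUE) {
  list(
    group_probs = c("eIF4A1" = 0.15, "eIF4A2" = 0.10, "DDX6" = 0.10,
                    "eIF4A1+eIF4A2" = 0.15, "none" = 0.50),
    utr5_meanlog = log(160), utr5_sdlog = 0.45, utr5_min = 12,
    cds_codons_meanlog = log(430), cds_codons_sdlog = 0.35,
    cds_codons_min = 40,
    utr3_meanlog = log(700), utr3_sdlog = 0.6, utr3_min = 30,
    base_probs = c(A = 0.28, C = 0.22, G = 0.22, T = 0.28),
    gc_end = if (effects) 0.70 else NA,   # eIF4A1-like last-50 GC target
    plant_n = if (effects) 2L else 0L,    # tetramers per eIF4A2-like 5'UTR end
    plant_window = 50L,
    expr_meanlog = log(100), expr_sdlog = 1,
    ip_fold = if (effects) 4 else 1,
    disp_rip = 0.2, disp_rnaseq = 0.1,
    # polysome fraction pi per group, control and CNOT1 knockdown
    poly_frac = c("eIF4A1" = 0.50, "eIF4A2" = 0.35, "DDX6" = 0.50,
                  "eIF4A1+eIF4A2" = 0.42, "none" = 0.50),
    poly_frac_kd = if (effects) {
      c("eIF4A1" = 0.50, "eIF4A2" = 0.62, "DDX6" = 0.32,
        "eIF4A1+eIF4A2" = 0.55, "none" = 0.50)
    } else {
      c("eIF4A1" = 0.50, "eIF4A2" = 0.35, "DDX6" = 0.50,
        "eIF4A1+eIF4A2" = 0.42, "none" = 0.50)
    },
    translation_factor = if (effects) 0.4 else 1,  # repressed groups
    utr5_peak_factor = if (effects) 3 else 1,      # eIF4A2-like last 50 nt
    rpf_depth = 0.3,        # expected RPFs/transcript ~ depth * relexpr * codons
    utr5_rpf_rate = 0.1,    # 5'UTR per-nt rate relative to CDS
    frame0_prob = 0.85,
    tis_probs = c(annotated = 0.70, utis = 0.10, both = 0.12, none = 0.08),
    tis_utis_excess = if (effects) 2 else 1,  # eIF4A2-like utis multiplier
    n_families = 40L, family_base_prob = 0.04,
    n_planted_families = if (effects) 8L else 0L,
    family_bias = 6  # relative target prob inside eIF4A2-like/both groups
  )
}

sample_seq <- function(n, probs) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

#' Generate a synthetic transcriptome with planted sequence features
#'
#' Genes are assigned to binding groups; eIF4A1-like transcripts get a GC
#' gradient rising toward the 3' end of the 5'UTR, eIF4A2-like (and
#' eIF4A1+eIF4A2) transcripts get purine tetramers planted in the last 50
#' nt of the 5'UTR. CDS starts with ATG and ends with a stop codon.
#'
#' @param n_genes number of genes (>= 10).
#' @param seed RNG seed; identical seeds give identical output.
#' @param params see [sim_params()].
#' @return list with `tx` (a `transcript_records`) and `truth`
#'   (data.frame: per-gene group, planted effects).
#' @export
make_transcriptome <- function(n_genes, seed, params = sim_params()) {
  if (n_genes < 10) stop("n_genes must be >= 10")
  p <- params
  if (abs(sum(p$group_probs) - 1) > 1e-8) stop("group_probs must sum to 1")
  set.seed(sub_seed(seed, 1L))
  wd <- max(5L, nchar(as.character(n_genes)))
  gene_id <- sprintf("g%0*d", wd, seq_len(n_genes))
  transcript_id <- sprintf("t%0*d.1", wd, seq_len(n_genes))
  group <- sample(names(p$group_probs), n_genes, replace = TRUE,
                  prob = p$group_probs)
  l5 <- pmax(p$utr5_min, round(rlnorm(n_genes, p$utr5_meanlog, p$utr5_sdlog)))
  cod <- pmax(p$cds_codons_min,
              round(rlnorm(n_genes, p$cds_codons_meanlog,
                           p$cds_codons_sdlog)))
  l3 <- pmax(p$utr3_min, round(rlnorm(n_genes, p$utr3_meanlog, p$utr3_sdlog)))
  repressed <- group %in% c("eIF4A2", "eIF4A1+eIF4A2")
  planted_motifs <- integer(n_genes)
  utr5 <- character(n_genes)
  gc_probs <- c(A = 0.15, C = 0.35, G = 0.35, T = 0.15)
  motifs <- purine_tetramers()
  for (i in seq_len(n_genes)) {
    L <- l5[i]
    s <- sample_seq(L, p$base_probs)
    w <- min(p$plant_window, L)
    if (group[i] == "eIF4A1" && !is.na(p$gc_end) && L >= 20) {
      # GC gradient: regenerate the last window with GC-rich composition
      tail_seq <- sample_seq(w, gc_probs)
      substr(s, L - w + 1L, L) <- tail_seq
    }
    if (repressed[i] && p$plant_n > 0L && L >= 20) {
      slots <- seq.int(max(1L, L - w + 1L), L - 3L, by = 4L)
      k <- min(p$plant_n, length(slots))
      at <- sort(sample(slots, k))
      for (a in at) {
        substr(s, a, a + 3L) <- sample(motifs, 1L)
      }
      planted_motifs[i] <- k
    }
    utr5[i] <- s
  }
  cds <- vapply(cod, function(nc) {
    body <- sample_seq((nc - 2L) * 3L, p$base_probs)
    paste0("ATG", body, sample(c("TAA", "TAG", "TGA"), 1L))
  }, character(1))
  utr3 <- vapply(l3, sample_seq, character(1), probs = p$base_probs)
  mu <- rlnorm(n_genes, p$expr_meanlog, p$expr_sdlog)
  truth <- data.frame(
    gene_id = gene_id, transcript_id = transcript_id, group = group,
    expr_mu = mu,
    ip_fold_eIF4A1 = ifelse(group %in% c("eIF4A1", "eIF4A1+eIF4A2"),
                            p$ip_fold, 1),
    ip_fold_eIF4A2 = ifelse(group %in% c("eIF4A2", "eIF4A1+eIF4A2"),
                            p$ip_fold, 1),
    ip_fold_DDX6 = ifelse(group == "DDX6", p$ip_fold, 1),
    poly_frac = unname(p$poly_frac[group]),
    poly_frac_kd = unname(p$poly_frac_kd[group]),
    translation_factor = ifelse(repressed, p$translation_factor, 1),
    utr5_peak_factor = ifelse(group == "eIF4A2", p$utr5_peak_factor, 1),
    planted_motifs = planted_motifs,
    stringsAsFactors = FALSE
  )
  tx <- transcript_records(transcript_id, gene_id, utr5, cds, utr3)
  list(tx = tx, truth = truth)
}

nb_matrix <- function(mu, disp, n_rep, prefix) {
  m <- vapply(seq_len(n_rep), function(r) {
    rnbinom(length(mu), mu = mu, size = 1 / disp)
  }, numeric(length(mu)))
  m <- matrix(m, ncol = n_rep)
  colnames(m) <- paste0(prefix, seq_len(n_rep))
  m
}

#' Simulate RIP, gradient and total-RNA count matrices
#'
#' RIP: per protein, 3 IP + 3 input replicates, NB with dispersion 0.2, IP
#' means multiplied by the planted fold for bound genes. Gradient: 4
#' replicates of subpolysomal and polysomal fractions for control and
#' CNOT1-knockdown conditions, NB dispersion 0.1, fraction means set by the
#' per-group polysome fraction. Total RNA: 2 replicates.
#'
#' @param truth truth table from [make_transcriptome()].
#' @param seed RNG seed.
#' @param params see [sim_params()].
#' @param n_rip,n_grad,n_total replicate numbers (defaults 3, 4, 2).
#' @return list with `rip` (named list of [count_matrix()] per protein),
#'   `gradient` (named list per condition) and `total`.
#' @export
simulate_counts <- function(truth, seed, params = sim_params(),
                            n_rip = 3L, n_grad = 4L, n_total = 2L) {
  p <- params
  if (p$disp_rip <= 0 || p$disp_rnaseq <= 0) stop("dispersion must be > 0")
  set.seed(sub_seed(seed, 2L))
  g <- truth$gene_id
  mu <- truth$expr_mu
  rip <- lapply(setNames(nm = c("eIF4A1", "eIF4A2", "DDX6")), function(pr) {
    fold <- truth[[paste0("ip_fold_", pr)]]
    # Matched IP/input libraries come from one lysate: the gene's realized
    # abundance in a replicate is shared between the two sides (Gamma
    # multiplier, Poisson counting), so marginal counts are NB with the
    # stated dispersion while IP vs input conditioning stays binomial.
    ip <- matrix(0L, length(mu), n_rip)
    inp <- matrix(0L, length(mu), n_rip)
    for (r in seq_len(n_rip)) {
      a <- mu * stats::rgamma(length(mu), shape = 1 / p$disp_rip,
                              rate = 1 / p$disp_rip)
      inp[, r] <- rpois(length(mu), a)
      ip[, r] <- rpois(length(mu), a * fold)
    }
    colnames(ip) <- paste0(pr, "_ip_", seq_len(n_rip))
    colnames(inp) <- paste0(pr, "_input_", seq_len(n_rip))
    m <- cbind(ip, inp)
    rownames(m) <- g
    meta <- data.frame(
      sample = colnames(m),
      assay = rep(c("rip_ip", "rip_input"), each = n_rip),
      condition = "control",
      replicate = rep(seq_len(n_rip), 2),
      stringsAsFactors = FALSE
    )
    count_matrix(m, meta)
  })
  gradient <- lapply(
    setNames(nm = c("control", "cnot1_kd")), function(cond) {
      pf <- if (cond == "control") truth$poly_frac else truth$poly_frac_kd
      sub <- nb_matrix(2 * mu * (1 - pf), p$disp_rnaseq, n_grad,
                       paste0(cond, "_sub_"))
      pol <- nb_matrix(2 * mu * pf, p$disp_rnaseq, n_grad,
                       paste0(cond, "_poly_"))
      m <- cbind(sub, pol)
      rownames(m) <- g
      meta <- data.frame(
        sample = colnames(m),
        assay = rep(c("subpolysomal", "polysomal"), each = n_grad),
        condition = cond,
        replicate = rep(seq_len(n_grad), 2),
        stringsAsFactors = FALSE
      )
      count_matrix(m, meta)
    })
  tot <- nb_matrix(mu, p$disp_rnaseq, n_total, "total_")
  rownames(tot) <- g
  total <- count_matrix(tot, data.frame(
    sample = colnames(tot), assay = "total", condition = "control",
    replicate = seq_len(n_total), stringsAsFactors = FALSE))
  list(rip = rip, gradient = gradient, total = total)
}

#' Simulate ribosome footprints and matched total RNA
#'
#' Per transcript, CDS footprint numbers are Poisson with mean
#' `rpf_depth * relative_expression * translation_factor * codons`,
#' placed uniformly over codons with frame-0 probability 0.85. 5'UTR
#' footprints (scanning/uORF ribosomes) are an independent Poisson
#' component at `utr5_rpf_rate` of the unrepressed CDS per-nt rate — not
#' scaled by the translation factor — whose last 50 nt are multiplied by
#' the planted peak factor. Read 5' ends are P-site - 13 and
#' lengths are drawn from 28-30 nt; reads falling off the transcript are
#' discarded. Matched total-RNA counts are NB with mean proportional to
#' expression times length (so TPM recovers expression).
#'
#' @param truth,tx from [make_transcriptome()].
#' @param seed RNG seed.
#' @param params see [sim_params()].
#' @return list with `reads` (read-position data.frame) and
#'   `total_counts` (named per-transcript counts).
#' @export
simulate_rpf <- function(truth, tx, seed, params = sim_params()) {
  p <- params
  set.seed(sub_seed(seed, 3L))
  stopifnot(identical(tx$transcript_id, truth$transcript_id))
  n <- nrow(tx)
  relexpr <- truth$expr_mu / mean(truth$expr_mu)
  # CDS footprints scale with the translation level; 5'UTR footprints
  # (scanning/uORF ribosomes) do not — initiation-repressed transcripts
  # keep their 5'UTR density while CDS density drops.
  lam_cds <- p$rpf_depth * relexpr * truth$translation_factor *
    (tx$cds_len / 3)
  rate5 <- p$utr5_rpf_rate * p$rpf_depth * relexpr / 3  # per nt
  frame_probs <- c(p$frame0_prob, (1 - p$frame0_prob) / 2,
                   (1 - p$frame0_prob) / 2)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    l5 <- tx$utr5_len[i]; lc <- tx$cds_len[i]
    w5 <- numeric(l5)
    if (l5 > 0) {
      w5[] <- rate5[i]
      pk <- min(50L, l5)
      w5[(l5 - pk + 1L):l5] <- rate5[i] * truth$utr5_peak_factor[i]
    }
    n_utr <- rpois(1L, sum(w5))
    n_cds <- rpois(1L, lam_cds[i])
    if (n_utr + n_cds == 0L) next
    psite <- integer(0)
    if (n_utr > 0L) {
      psite <- c(psite, sample.int(l5, n_utr, replace = TRUE, prob = w5) - 1L)
    }
    if (n_cds > 0L) {
      codon <- sample.int(lc %/% 3L, n_cds, replace = TRUE)
      off <- sample.int(3L, n_cds, replace = TRUE, prob = frame_probs) - 1L
      psite <- c(psite, l5 + (codon - 1L) * 3L + off)
    }
    five <- psite - 13L
    len <- sample(28:30, length(psite), replace = TRUE)
    total_len <- l5 + lc + tx$utr3_len[i]
    ok <- five >= 0L & five + len <= total_len
    if (!any(ok)) next
    out[[i]] <- data.frame(transcript_id = tx$transcript_id[i],
                           five_prime_pos = five[ok], length = len[ok],
                           stringsAsFactors = FALSE)
  }
  reads <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(reads) <- NULL
  tl <- tx_total_length(tx)
  total_counts <- rnbinom(n, mu = truth$expr_mu * tl / 1e3,
                          size = 1 / p$disp_rnaseq)
  names(total_counts) <- tx$transcript_id
  list(reads = reads, total_counts = total_counts)
}

#' Simulate initiation peaks, miRNA families and a reference target set
#'
#' Initiation labels are multinomial per gene with an excess of
#' upstream-only initiation planted in eIF4A2-like (and eIF4A1+eIF4A2)
#' groups; upstream peaks are placed 6-60 nt upstream of the annotated
#' start. miRNA families sample targets from the universe, with planted
#' families biased toward the repressed groups; the reference set emulates
#' genes upregulated on TNRC6 depletion (true family targets with noise).
#'
#' @param truth,tx from [make_transcriptome()].
#' @param seed RNG seed.
#' @param params see [sim_params()].
#' @return list with `peaks`, `families`, `reference_targets`,
#'   `tis_truth` (per-transcript planted label).
#' @export
simulate_peaks_and_families <- function(truth, tx, seed,
                                        params = sim_params()) {
  p <- params
  set.seed(sub_seed(seed, 4L))
  if (abs(sum(p$tis_probs) - 1) > 1e-8) stop("tis_probs must sum to 1")
  n <- nrow(tx)
  repressed <- truth$group %in% c("eIF4A2", "eIF4A1+eIF4A2")
  labs <- character(n)
  base <- p$tis_probs
  boosted <- base
  boosted["utis"] <- min(0.9, base["utis"] * p$tis_utis_excess)
  boosted["annotated"] <- base["annotated"] - (boosted["utis"] - base["utis"])
  for (i in seq_len(n)) {
    pr <- if (repressed[i]) boosted else base
    labs[i] <- sample(names(pr), 1L, prob = pr)
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    st <- tx$utr5_len[i]
    up_ok <- st >= 7L
    lab <- labs[i]
    if (lab %in% c("utis", "both") && !up_ok) lab <- "annotated"
    peak <- switch(lab,
      annotated = st,
      utis = st - sample(6:min(60L, st), 1L),
      both = c(st - sample(6:min(60L, st), 1L), st),
      none = NA_integer_)
    labs[i] <- lab
    rows[[i]] <- data.frame(transcript_id = tx$transcript_id[i],
                            annotated_start = st, peak_pos = peak,
                            stringsAsFactors = FALSE)
  }
  peaks <- do.call(rbind, rows)
  rownames(peaks) <- NULL

  planted <- seq_len(p$n_planted_families)
  fam_rows <- lapply(seq_len(p$n_families), function(f) {
    pr <- rep(p$family_base_prob, n)
    if (f %in% planted) {
      pr[repressed] <- pmin(0.5, p$family_base_prob * p$family_bias)
    }
    hit <- runif(n) < pr
    if (!any(hit)) hit[sample.int(n, 2L)] <- TRUE
    data.frame(family_id = sprintf("miR-fam-%02d", f),
               gene_id = truth$gene_id[hit], stringsAsFactors = FALSE)
  })
  families <- do.call(rbind, fam_rows)
  target_any <- truth$gene_id %in% families$gene_id
  ref <- truth$gene_id[(target_any & runif(n) < 0.8) |
                         (!target_any & runif(n) < 0.05)]
  list(peaks = peaks, families = families, reference_targets = ref,
       tis_truth = data.frame(transcript_id = tx$transcript_id,
                              planted_label = labs,
                              stringsAsFactors = FALSE))
}

#' Simulate binding-assay data: titrations, release kinetics, competition
#'
#' Triplicate Hill titrations (0-40 uM protein) for each protein/RNA pair,
#' single-exponential strand-release time courses, and competition curves
#' generated from the exact equilibrium solver at increasing competitor
#' excess; Gaussian noise throughout.
#'
#' @param seed RNG seed.
#' @param noise_titration,noise_decay,noise_competition Gaussian noise SDs
#'   as fractions of amplitude (defaults 0.02, 0.03, 0.02).
#' @return list with `titration`, `kinetics`, `competition` data.frames and
#'   `truth` (the generating parameters).
#' @export
simulate_binding <- function(seed, noise_titration = 0.02,
                             noise_decay = 0.03,
                             noise_competition = 0.02) {
  set.seed(sub_seed(seed, 5L))
  kd_true <- c("eIF4A1_AG" = 0.6e-6, "eIF4A1_CA" = 0.8e-6,
               "eIF4A2_AG" = 0.3e-6, "eIF4A2_CA" = 3e-6)
  amp <- 0.12; base <- 0.05
  conc <- c(0, exp(seq(log(1e-8), log(40e-6), length.out = 12)))
  titration <- do.call(rbind, lapply(names(kd_true), function(id) {
    do.call(rbind, lapply(1:3, function(rep) {
      y <- hill_f(conc, kd_true[[id]], 1, amp, base) +
        rnorm(length(conc), 0, noise_titration * amp)
      pr <- sub("_.*", "", id)
      data.frame(protein = pr, rna = sub(".*_", "", id), conc_M = conc,
                 signal = y, replicate = rep, stringsAsFactors = FALSE)
    }))
  }))
  k_true <- c("eIF4A2_AG" = 0.02, "eIF4A2_CA" = 0.3,
              "eIF4A1_AG" = 0.05, "eIF4A1_CA" = 0.08)
  tt <- seq(0, 60, by = 5)
  kinetics <- do.call(rbind, lapply(names(k_true), function(id) {
    do.call(rbind, lapply(1:3, function(rep) {
      y <- 0.02 + amp * exp(-k_true[[id]] * tt) +
        rnorm(length(tt), 0, noise_decay * amp)
      data.frame(protein = sub("_.*", "", id), rna = sub(".*_", "", id),
                 time_min = tt, signal = y, replicate = rep,
                 stringsAsFactors = FALSE)
    }))
  }))
  kd_l <- 0.3e-6; kd_c <- 30e-6; rl <- 25e-9
  pconc <- c(0, exp(seq(log(5e-9), log(7e-6), length.out = 11)))
  excess <- c(0, 1, 5, 10, 20, 50)
  competition <- do.call(rbind, lapply(excess, function(ex) {
    do.call(rbind, lapply(1:3, function(rep) {
      fb <- vapply(pconc, function(pt) {
        solve_competition_equilibrium(pt, rl, ex * rl, kd_l,
                                      kd_c)$fraction_bound_L
      }, numeric(1))
      fb <- pmin(1.05, pmax(-0.05, fb + rnorm(length(fb), 0,
                                              noise_competition)))
      data.frame(excess = ex, conc_M = pconc, fraction_bound = fb,
                 replicate = rep, stringsAsFactors = FALSE)
    }))
  }))
  list(titration = titration, kinetics = kinetics,
       competition = competition,
       truth = list(kd = kd_true, hill_h = 1, amplitude = amp,
                    baseline = base, k = k_true, kd_l = kd_l, kd_c = kd_c,
                    rl = rl, excess = excess))
}

#' Generate a complete synthetic dataset on disk
#'
#' Runs every generator and writes all pipeline input formats plus a
#' first-class truth table: FASTA + region table, RIP/gradient/total count
#' and metadata TSVs, footprint positions, initiation peaks, miRNA
#' families, reference targets, binding-assay TSVs, `truth.tsv` and a
#' `manifest.json` listing every file with its md5 checksum.
#'
#' @param out_dir output directory (created if needed).
#' @param preset `"paperlike"` (5,000 genes, all effects planted),
#'   `"null"` (2,000 genes, no effects), `"minimal"` (60 genes, effects,
#'   fast).
#' @param seed RNG seed.
#' @return (invisibly) a list with all in-memory objects and `files`.
#' @export
simulate_dataset <- function(out_dir, preset = c("paperlike", "null",
                                                 "minimal"), seed = 1) {
  preset <- match.arg(preset)
  n_genes <- switch(preset, paperlike = 5000L, null = 2000L, minimal = 60L)
  params <- sim_params(effects = preset != "null")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mk <- make_transcriptome(n_genes, seed, params)
  counts <- simulate_counts(mk$truth, seed, params)
  rpf <- simulate_rpf(mk$truth, mk$tx, seed, params)
  pk <- simulate_peaks_and_families(mk$truth, mk$tx, seed, params)
  bind <- simulate_binding(seed)

  path <- function(f) file.path(out_dir, f)
  write_transcriptome(mk$tx, path("transcripts.fa"), path("regions.tsv"))
  for (pr in names(counts$rip)) {
    write_counts(counts$rip[[pr]], path(sprintf("rip_%s_counts.tsv", pr)),
                 path(sprintf("rip_%s_meta.tsv", pr)))
  }
  for (cond in names(counts$gradient)) {
    write_counts(counts$gradient[[cond]],
                 path(sprintf("gradient_%s_counts.tsv", cond)),
                 path(sprintf("gradient_%s_meta.tsv", cond)))
  }
  write_counts(counts$total, path("total_counts.tsv"),
               path("total_meta.tsv"))
  write_tsv(rpf$reads, path("rpf_reads.tsv"))
  write_tsv(data.frame(transcript_id = names(rpf$total_counts),
                       count = unname(rpf$total_counts)),
            path("rpf_total_counts.tsv"))
  write_tsv(pk$peaks, path("initiation_peaks.tsv"))
  write_tsv(pk$families, path("mirna_families.tsv"))
  write_tsv(data.frame(gene_id = pk$reference_targets),
            path("reference_targets.tsv"))
  write_tsv(bind$titration, path("binding_titration.tsv"))
  write_tsv(bind$kinetics, path("binding_kinetics.tsv"))
  write_tsv(bind$competition, path("binding_competition.tsv"))
  truth <- merge(mk$truth, pk$tis_truth, by = "transcript_id", sort = FALSE)
  write_tsv(truth, path("truth.tsv"))

  files <- list.files(out_dir, full.names = FALSE)
  files <- setdiff(files, "manifest.json")
  manifest <- list(
    preset = preset, seed = seed, n_genes = n_genes,
    package_version = as.character(utils::packageVersion("ribofate")),
    files = lapply(setNames(nm = files), function(f) {
      list(md5 = unname(tools::md5sum(path(f))),
           bytes = file.size(path(f)))
    })
  )
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(tx = mk$tx, truth = truth, counts = counts, rpf = rpf,
                 peaks_families = pk, binding = bind,
                 files = file.path(out_dir, c(files, "manifest.json"))))
}
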