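# Polysome-association analysis from sucrose-gradient RNA-Seq of pooled
# subpolysomal and polysomal fractions: per-gene association scores,
# knockdown-induced shifts between fractions, and group-level comparisons.

#' Polysome-association score
#'
#' Score = mean abundance in the polysomal fraction minus mean abundance in
#' the subpolysomal fraction, per gene. Replicates are averaged after
#' normalisation (CPM by default; FPKM = CPM / length * 1e3 reproduces the
#' Methods-style variant and requires transcript lengths). Low scores mark
#' mRNAs repressed at initiation. The score is antisymmetric under swapping
#' the fractions.
#'
#' @param cm a [count_matrix()] holding `polysomal` and `subpolysomal`
#'   samples of one condition.
#' @param condition optional condition filter applied first.
#' @param unit `"cpm"` (default) or `"fpkm"`.
#' @param lengths named per-gene transcript lengths (nt), required for FPKM.
#' @return data.frame `gene_id`, `score`, `condition`.
#' @export
association_score <- function(cm, condition = NULL,
                              unit = c("cpm", "fpkm"), lengths = NULL) {
  unit <- match.arg(unit)
  if (!is.null(condition)) cm <- subset_samples(cm, condition = condition)
  assays <- cm$sample_meta$assay
  if (!any(assays == "polysomal") || !any(assays == "subpolysomal")) {
    stop("both polysomal and subpolysomal samples are required")
  }
  norm <- cpm(cm$counts, cm$library_sizes)
  if (unit == "fpkm") {
    if (is.null(lengths)) stop("FPKM requires transcript lengths")
    lv <- lengths[rownames(norm)]
    if (any(is.na(lv) | lv <= 0)) stop("missing or non-positive lengths")
    norm <- norm / lv * 1e3
  }
  poly <- rowMeans(norm[, assays == "polysomal", drop = FALSE])
  sub <- rowMeans(norm[, assays == "subpolysomal", drop = FALSE])
  cond <- unique(cm$sample_meta$condition)
  data.frame(
    gene_id = rownames(norm),
    score = unname(poly - sub),
    condition = if (length(cond) == 1L) cond else NA_character_,
    stringsAsFactors = FALSE
  )
}

# Vectorised Welch t-test per gene on two matrices (genes x replicates);
# returns two-sided p and the mean difference b - a.
welch_rows <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  if (na < 2L || nb < 2L) stop("need >= 2 replicates per condition")
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, stats::var); vb <- apply(b, 1, stats::var)
  se2 <- va / na + vb / nb
  tstat <- ifelse(se2 > 0, (mb - ma) / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1)),
               na + nb - 2)
  p <- ifelse(se2 > 0, 2 * stats::pt(-abs(tstat), df), 1)
  list(p = p, delta = mb - ma)
}

#' Differential polysome shift between conditions
#'
#' For each gradient fraction (subpolysomal, polysomal) the knockdown is
#' compared to control per gene with a Welch t-test on log2(CPM + 0.5)
#' (documented stand-in for the original external count model), BH-corrected
#' across genes. A gene is `shifted` only when significant in *both*
#' fractions (FDR < `fdr_threshold` each), and its direction is
#' `into_polysomes` when the polysomal fold change is positive and the
#' subpolysomal negative, `out_of_polysomes` when reversed, otherwise
#' `discordant`.
#'
#' @param control_cm,knockdown_cm [count_matrix()] objects, each with >= 2
#'   replicates of both fractions.
#' @param fdr_threshold per-fraction FDR cutoff (default 0.05).
#' @return data.frame with `gene_id`, `log2fc_polysomal`,
#'   `log2fc_subpolysomal`, `fdr_poly`, `fdr_sub`, `shifted`, `direction`.
#' @export
differential_shift <- function(control_cm, knockdown_cm,
                               fdr_threshold = 0.05) {
  if (!identical(rownames(control_cm$counts), rownames(knockdown_cm$counts))) {
    stop("control and knockdown matrices must share the gene universe")
  }
  logcpm <- function(cm, assay) {
    keep <- cm$sample_meta$assay == assay
    if (sum(keep) < 2L) stop("need >= 2 replicates of ", assay)
    log2(cpm(cm$counts[, keep, drop = FALSE], cm$library_sizes[keep]) + 0.5)
  }
  res <- lapply(c(polysomal = "polysomal", subpolysomal = "subpolysomal"),
                function(a) {
                  w <- welch_rows(logcpm(control_cm, a), logcpm(knockdown_cm, a))
                  w$fdr <- benjamini_hochberg(w$p)
                  w
                })
  lp <- res$polysomal$delta; ls_ <- res$subpolysomal$delta
  shifted <- res$polysomal$fdr < fdr_threshold &
    res$subpolysomal$fdr < fdr_threshold
  direction <- ifelse(lp > 0 & ls_ < 0, "into_polysomes",
                      ifelse(lp < 0 & ls_ > 0, "out_of_polysomes",
                             "discordant"))
  data.frame(
    gene_id = rownames(control_cm$counts),
    log2fc_polysomal = unname(lp),
    log2fc_subpolysomal = unname(ls_),
    fdr_poly = unname(res$polysomal$fdr),
    fdr_sub = unname(res$subpolysomal$fdr),
    shifted = unname(shifted),
    direction = unname(direction),
    stringsAsFactors = FALSE
  )
}

#' Compare score shifts across binding groups
#'
#' Kruskal-Wallis plus Dunn's post hoc test (BH correction by default,
#' matching the knockdown-shift comparison) over the per-group
#' distributions of a per-gene score, typically the change in
#' polysome-association score (knockdown minus control). Groups with fewer
#' than `min_size` genes are excluded with a warning.
#'
#' @param scores named numeric vector, one value per gene.
#' @param partition data.frame `gene_id`, `label` (see
#'   [assign_binding_groups()]).
#' @param correction multiplicity correction passed to [kruskal_dunn()].
#' @param min_size minimum group size (default 3).
#' @return [kruskal_dunn()] result.
#' @export
group_shift_comparison <- function(scores, partition,
                                   correction = "benjamini_hochberg",
                                   min_size = 3L) {
  if (is.null(names(scores))) stop("scores must be named by gene")
  partition <- partition[partition$gene_id %in% names(scores), , drop = FALSE]
  groups <- split(unname(scores[partition$gene_id]), partition$label)
  small <- lengths(groups) < min_size
  if (any(small)) {
    warning("excluding group(s) with < ", min_size, " genes: ",
            paste(names(groups)[small], collapse = ", "))
    groups <- groups[!small]
  }
  kruskal_dunn(groups, correction = correction)
}
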