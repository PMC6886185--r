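# Translation-initiation-site usage from initiating-ribosome peak data and
# miRNA-family target enrichment across binding groups.

#' Classify initiation usage of one transcript
#'
#' Given the annotated main-AUG coordinate and the set of
#' initiating-ribosome peak coordinates: `annotated_only` (peak exactly at
#' the start, none upstream), `utis_only` (>= 1 peak strictly upstream,
#' none at the start), `both`, or `none`. Peaks downstream of the start are
#' ignored for labelling.
#'
#' @param annotated_start 0-based transcript coordinate of the main AUG.
#' @param peaks integer coordinates of initiating-ribosome peaks (may be
#'   empty).
#' @return list with `label`, `utis_positions` (sorted upstream peaks) and
#'   `in_frame` (logical per upstream peak; in frame when the distance to
#'   the annotated start is a multiple of 3).
#' @export
classify_tis <- function(annotated_start, peaks) {
  if (annotated_start < 0) stop("annotated_start must be >= 0")
  peaks <- peaks[!is.na(peaks)]
  at <- any(peaks == annotated_start)
  up <- sort(unique(peaks[peaks < annotated_start]))
  label <- if (at && length(up)) "both"
  else if (at) "annotated_only"
  else if (length(up)) "utis_only"
  else "none"
  list(label = label, utis_positions = up,
       in_frame = if (length(up)) {
         vapply(up, utis_frame, logical(1),
                annotated_start = annotated_start)
       } else logical(0))
}

#' Is an upstream initiation site in frame with the main ORF?
#' @param utis_pos upstream peak coordinate (strictly less than
#'   `annotated_start`).
#' @param annotated_start main AUG coordinate.
#' @return TRUE when `(annotated_start - utis_pos) %% 3 == 0`.
#' @export
utis_frame <- function(utis_pos, annotated_start) {
  if (utis_pos >= annotated_start) {
    stop("utis_pos must be strictly upstream of annotated_start")
  }
  (annotated_start - utis_pos) %% 3 == 0
}

#' Classify initiation usage for a peak table
#' @param peaks data.frame from [read_initiation_peaks()].
#' @return data.frame `transcript_id`, `label`, `n_utis`, `n_utis_in_frame`.
#' @export
classify_tis_table <- function(peaks) {
  by_tx <- split(peaks, peaks$transcript_id)
  rows <- lapply(by_tx, function(d) {
    cl <- classify_tis(d$annotated_start[1], d$peak_pos)
    data.frame(transcript_id = d$transcript_id[1], label = cl$label,
               n_utis = length(cl$utis_positions),
               n_utis_in_frame = sum(cl$in_frame),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Initiation-usage proportions per binding group
#'
#' Per group, the fractions of `annotated_only`, `utis_only` and `both`
#' among transcripts with detected initiation (label `none` excluded);
#' fractions sum to 1. Groups left empty after exclusion are omitted with a
#' warning.
#'
#' @param classifications output of [classify_tis_table()].
#' @param partition data.frame `gene_id`/`transcript_id`, `label` mapping
#'   ids to groups (column `label` is the group).
#' @return data.frame `group`, `annotated_only`, `utis_only`, `both`, `n`.
#' @export
group_tis_proportions <- function(classifications, partition) {
  idcol <- intersect(c("transcript_id", "gene_id"), names(partition))[1]
  if (is.na(idcol)) stop("partition needs a transcript_id or gene_id column")
  m <- merge(classifications, partition,
             by.x = "transcript_id", by.y = idcol,
             suffixes = c("", "_group"))
  m <- m[m$label != "none", , drop = FALSE]
  rows <- lapply(split(m, m$label_group), function(d) {
    if (nrow(d) == 0L) return(NULL)
    n <- nrow(d)
    data.frame(group = d$label_group[1],
               annotated_only = mean(d$label == "annotated_only"),
               utis_only = mean(d$label == "utis_only"),
               both = mean(d$label == "both"),
               n = n, stringsAsFactors = FALSE)
  })
  empty <- setdiff(unique(partition$label), m$label_group)
  if (length(empty)) {
    warning("group(s) with no classified transcripts omitted: ",
            paste(empty, collapse = ", "))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

fdr_bin <- function(fdr) {
  cut(fdr, breaks = c(-Inf, 0.05, 0.1, 0.2, Inf), right = FALSE,
      labels = c("<0.05", "0.05-0.1", "0.1-0.2", "ns"))
}

#' miRNA-family target enrichment across binding groups
#'
#' For each group x family, a one-sided Fisher test asks whether the
#' family's targets are over-represented in the group relative to the gene
#' universe; BH correction runs across families within each group, and the
#' FDR is binned (`<0.05`, `0.05-0.1`, `0.1-0.2`, `ns`) for heatmap
#' display. Families with no targets in the universe are skipped with a
#' message. A reference gene set (e.g. genes upregulated after TNRC6
#' depletion, the operational "miRNA targets in these cells") enters as an
#' ordinary group.
#'
#' @param groups named list of gene-id sets (binding groups and any
#'   reference set).
#' @param families data.frame `family_id`, `gene_id` (see
#'   [read_mirna_families()]).
#' @param universe character vector of all considered genes.
#' @return data.frame `family_id`, `group`, `k`, `n`, `K`, `N`, `p`,
#'   `fdr`, `odds_ratio`, `fdr_bin`.
#' @export
mirna_family_enrichment <- function(groups, families, universe) {
  universe <- unique(universe)
  N <- length(universe)
  fam_targets <- lapply(split(families$gene_id, families$family_id),
                        function(g) intersect(unique(g), universe))
  empty <- lengths(fam_targets) == 0L
  if (any(empty)) {
    message(sum(empty), " family/-ies with no targets in universe skipped")
    fam_targets <- fam_targets[!empty]
  }
  out <- do.call(rbind, lapply(names(groups), function(gname) {
    gset <- intersect(unique(groups[[gname]]), universe)
    n <- length(gset)
    rows <- lapply(names(fam_targets), function(f) {
      tg <- fam_targets[[f]]
      k <- length(intersect(tg, gset))
      ft <- fisher_exact_onesided(k, n, length(tg), N)
      data.frame(family_id = f, group = gname, k = k, n = n,
                 K = length(tg), N = N, p = ft$p,
                 odds_ratio = ft$odds_ratio, stringsAsFactors = FALSE)
    })
    d <- do.call(rbind, rows)
    d$fdr <- benjamini_hochberg(d$p)
    d
  }))
  out$fdr_bin <- fdr_bin(out$fdr)
  rownames(out) <- NULL
  out[, c("family_id", "group", "k", "n", "K", "N", "p", "fdr",
          "odds_ratio", "fdr_bin")]
}
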