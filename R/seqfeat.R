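# Sequence features of UTRs and CDS: rolling GC content, non-overlapping
# purine-tetramer counting and positional enrichment, Pumilio elements, and
# group-level motif-frequency comparisons.

#' The eight purine-rich tetramers
#'
#' The purine tetramers most strongly clamped by chemically inhibited
#' eIF4A: AAGA, AGAA, GAAA, GAGA, AGAG, GGAA, AAAA, GAAG.
#' @return character vector of 8 motifs.
#' @export
purine_tetramers <- function() {
  c("AAGA", "AGAA", "GAAA", "GAGA", "AGAG", "GGAA", "AAAA", "GAAG")
}

check_motifs <- function(motifs) {
  if (length(motifs) == 0L) stop("motif set is empty")
  w <- unique(nchar(motifs))
  if (length(w) != 1L) stop("motifs must share one length")
  if (any(grepl("[^ACGT]", motifs))) stop("motifs must be over {A,C,G,T}")
  w
}

# All (overlapping) start positions, 1-based, where any motif matches.
# N never matches. Vectorised window comparison against the motif set.
motif_match_starts <- function(sequence, motifs) {
  w <- check_motifs(motifs)
  L <- nchar(sequence)
  if (L < w) return(integer(0))
  starts <- seq_len(L - w + 1L)
  windows <- substring(sequence, starts, starts + w - 1L)
  starts[windows %in% motifs]
}

greedy_nonoverlap <- function(starts, width) {
  count <- 0L
  next_free <- 1L
  for (s in starts) {
    if (s >= next_free) {
      count <- count + 1L
      next_free <- s + width
    }
  }
  count
}

#' Count non-overlapping motif occurrences
#'
#' Greedy left-to-right scan: at each position, if any motif of the set
#' matches, one occurrence is counted and the scan jumps past it (several
#' motifs matching at one position count once). `N` bases never match.
#'
#' @param sequence character scalar over {A,C,G,T,N}.
#' @param motifs equal-length motif set (default [purine_tetramers()]).
#' @return integer count.
#' @export
count_motifs_nonoverlap <- function(sequence, motifs = purine_tetramers()) {
  w <- check_motifs(motifs)
  greedy_nonoverlap(motif_match_starts(sequence, motifs), w)
}

#' Per-nucleotide motif frequency
#'
#' Non-overlapping motif count divided by sequence length, so regions of
#' different lengths are comparable.
#'
#' @inheritParams count_motifs_nonoverlap
#' @return frequency (per nt); `NA` with a message for empty sequences.
#' @export
motif_frequency <- function(sequence, motifs = purine_tetramers()) {
  L <- nchar(sequence)
  if (L == 0L) {
    message("empty sequence excluded from motif frequency")
    return(NA_real_)
  }
  count_motifs_nonoverlap(sequence, motifs) / L
}

#' Rolling GC content
#'
#' GC fraction in a sliding window (default 6 nt): value i covers
#' `sequence[i:(i+window-1)]`; output length is L - window + 1. `N` counts
#' as non-GC. Sequences shorter than the window give an empty vector with a
#' warning.
#'
#' @param sequence character scalar.
#' @param window window width (default 6).
#' @return numeric vector of window GC fractions.
#' @export
rolling_gc <- function(sequence, window = 6) {
  L <- nchar(sequence)
  if (L < window) {
    warning("sequence shorter than window; returning empty vector")
    return(numeric(0))
  }
  is_gc <- as.integer(strsplit(chartr("Uu", "Tt", toupper(sequence)),
                               "")[[1]] %in% c("G", "C"))
  cs <- c(0, cumsum(is_gc))
  (cs[(window + 1):(L + 1)] - cs[1:(L - window + 1)]) / window
}

window_seq <- function(utr5, region = c("utr5_first50", "utr5_last50"),
                       width = 50) {
  region <- match.arg(region)
  L <- nchar(utr5)
  if (region == "utr5_first50") substr(utr5, 1L, width)
  else substr(utr5, L - width + 1L, L)
}

# Per-position covered-by-a-motif indicator within a window sequence.
coverage_indicator <- function(seqs, motifs, width, mode) {
  w <- check_motifs(motifs)
  acc <- numeric(width)
  for (s in seqs) {
    st <- motif_match_starts(s, motifs)
    ind <- logical(width)
    if (mode == "covering") {
      for (p in st) ind[p:min(p + w - 1L, width)] <- TRUE
    } else {
      ind[st] <- TRUE
    }
    acc <- acc + ind
  }
  acc / length(seqs)
}

#' Positional motif profile and enrichment over a background
#'
#' For the first or last 50 nt of the 5'UTR, the per-position occurrence is
#' the fraction of sequences in which a motif occurrence covers that
#' position (corrected for group size); enrichment is the ratio of group to
#' background occurrence, `NA` where the background is zero. `mode =
#' "starts"` counts motif start positions instead of covered bases.
#'
#' @param group_seqs,background_seqs 5'UTR sequences (>= 50 nt each; shorter
#'   ones are dropped).
#' @param region `"utr5_first50"` or `"utr5_last50"`.
#' @param motifs motif set.
#' @param width window width (default 50).
#' @param mode `"covering"` (default) or `"starts"`.
#' @return data.frame `position`, `occurrence`, `background`, `enrichment`.
#' @export
positional_profile <- function(group_seqs, background_seqs,
                               region = c("utr5_first50", "utr5_last50"),
                               motifs = purine_tetramers(), width = 50,
                               mode = c("covering", "starts")) {
  region <- match.arg(region)
  mode <- match.arg(mode)
  group_seqs <- group_seqs[nchar(group_seqs) >= width]
  background_seqs <- background_seqs[nchar(background_seqs) >= width]
  if (length(group_seqs) == 0L) stop("empty group after length filter")
  if (length(background_seqs) == 0L) stop("empty background")
  gw <- vapply(group_seqs, window_seq, character(1), region = region,
               width = width, USE.NAMES = FALSE)
  bw <- vapply(background_seqs, window_seq, character(1), region = region,
               width = width, USE.NAMES = FALSE)
  occ <- coverage_indicator(gw, motifs, width, mode)
  bg <- coverage_indicator(bw, motifs, width, mode)
  data.frame(
    position = seq_len(width),
    occurrence = occ,
    background = bg,
    enrichment = ifelse(bg > 0, occ / bg, NA_real_)
  )
}

#' Count Pumilio-response elements in a 3'UTR
#'
#' Non-overlapping, left-to-right count of the 8-mer TGTANATA (N one of
#' A/C/G/T; an `N` base in the sequence never matches).
#'
#' @param utr3_sequence character scalar.
#' @return integer count.
#' @export
pumilio_sites <- function(utr3_sequence) {
  motifs <- paste0("TGTA", c("A", "C", "G", "T"), "ATA")
  if (nchar(utr3_sequence) < 8L) return(0L)
  greedy_nonoverlap(motif_match_starts(utr3_sequence, motifs), 8L)
}

#' Compare motif frequencies across groups
#'
#' Kruskal-Wallis + Dunn's test (Bonferroni by default, matching the
#' cumulative-frequency comparisons) over per-group motif-frequency
#' distributions, plus per-group empirical CDF tables for plotting.
#'
#' @param freq_by_group named list of numeric frequency vectors.
#' @param correction multiplicity correction (default `"bonferroni"`).
#' @return list with `tests` ([kruskal_dunn()] output) and `ecdf` (named
#'   list of data.frames `value`, `cumfreq`).
#' @export
group_motif_comparison <- function(freq_by_group,
                                   correction = "bonferroni") {
  freq_by_group <- lapply(freq_by_group, function(v) v[!is.na(v)])
  tests <- kruskal_dunn(freq_by_group, correction = correction)
  ecdfs <- lapply(freq_by_group, function(v) {
    s <- sort(v)
    data.frame(value = s, cumfreq = seq_along(s) / length(s))
  })
  list(tests = tests, ecdf = ecdfs)
}
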