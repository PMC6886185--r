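# Ribosome-profiling downstream analysis: periodicity-based footprint
# length selection, P-site assignment with a fixed offset, TPM
# normalisation of matched total RNA, abundance-normalised occupancy, CDS
# metagenes and 5'UTR occupancy.

tx_total_length <- function(tx) tx$utr5_len + tx$cds_len + tx$utr3_len

#' Select footprint lengths showing 3-nt periodicity
#'
#' For each candidate read length, P-sites (5' position + offset) falling
#' inside the CDS are framed relative to the annotated start; a length is
#' retained when the modal frame holds at least `threshold` of its
#' CDS-internal reads (the conventional operationalisation of "shows
#' periodicity"; threshold configurable, default 0.6).
#'
#' @param reads data.frame from [read_read_positions()].
#' @param tx `transcript_records` annotation.
#' @param lengths candidate lengths (default 28:30).
#' @param offset P-site offset (default 13).
#' @param threshold modal-frame fraction required (default 0.6).
#' @return integer vector of retained lengths; per-length frame fractions
#'   attached as attribute `frame_fraction`.
#' @export
select_periodic_lengths <- function(reads, tx, lengths = 28:30,
                                    offset = 13, threshold = 0.6) {
  reads <- reads[reads$length %in% lengths, , drop = FALSE]
  if (nrow(reads) == 0L) stop("no reads of any candidate length")
  cds_start <- setNames(tx$utr5_len, tx$transcript_id)
  cds_len <- setNames(tx$cds_len, tx$transcript_id)
  st <- cds_start[reads$transcript_id]
  cl <- cds_len[reads$transcript_id]
  psite <- reads$five_prime_pos + offset
  internal <- !is.na(st) & psite >= st & psite < st + cl
  frac <- vapply(lengths, function(L) {
    keep <- internal & reads$length == L
    if (!any(keep)) return(NA_real_)
    fr <- (psite[keep] - st[keep]) %% 3
    max(tabulate(fr + 1L, 3L)) / sum(keep)
  }, numeric(1))
  names(frac) <- lengths
  retained <- lengths[!is.na(frac) & frac >= threshold]
  structure(retained, frame_fraction = frac)
}

#' Assign P-sites and build per-transcript count vectors
#'
#' The P-site of a footprint is its 5' end plus a fixed offset (default 13
#' nt, applied uniformly to 28-30 nt fragments). Reads whose P-site falls
#' outside the transcript are dropped and counted.
#'
#' @param reads data.frame of read positions (already length-selected).
#' @param tx `transcript_records` annotation.
#' @param offset non-negative P-site offset.
#' @return named list of integer vectors (one per transcript, length =
#'   transcript length); number of dropped reads in attribute `n_dropped`.
#' @export
psite_assign <- function(reads, tx, offset = 13) {
  if (offset < 0) stop("offset must be >= 0")
  len <- setNames(tx_total_length(tx), tx$transcript_id)
  unknown <- !reads$transcript_id %in% names(len)
  if (any(unknown)) {
    stop("reads on unannotated transcripts: ",
         paste(unique(reads$transcript_id[unknown]), collapse = ", "))
  }
  psite <- reads$five_prime_pos + offset
  ok <- psite < len[reads$transcript_id] & psite >= 0
  dropped <- sum(!ok)
  reads <- reads[ok, , drop = FALSE]
  psite <- psite[ok]
  vecs <- lapply(setNames(nm = tx$transcript_id), function(id) {
    integer(len[[id]])
  })
  by_tx <- split(psite, reads$transcript_id)
  for (id in names(by_tx)) {
    vecs[[id]] <- tabulate(by_tx[[id]] + 1L, nbins = len[[id]])
  }
  structure(vecs, n_dropped = dropped)
}

#' Transcripts per million
#'
#' tpm_i = (count_i / length_i) / sum_j(count_j / length_j) * 1e6; sums to
#' 1e6 over the dataset.
#'
#' @param counts named non-negative counts per transcript.
#' @param lengths positive lengths (nt), aligned with `counts`.
#' @return named TPM vector.
#' @export
tpm <- function(counts, lengths) {
  if (any(lengths <= 0)) stop("lengths must be positive")
  if (length(counts) != length(lengths)) stop("counts/lengths mismatch")
  rate <- counts / lengths
  tot <- sum(rate)
  if (tot == 0) stop("all-zero counts")
  rate / tot * 1e6
}

#' Reads-per-million normalisation of P-site vectors
#' @param psite_vectors list from [psite_assign()].
#' @param total_reads library size; defaults to the total retained reads.
#' @return list of RPM vectors; raw per-transcript totals in attribute
#'   `raw_totals`.
#' @export
rpm_normalize <- function(psite_vectors, total_reads = NULL) {
  raw <- vapply(psite_vectors, sum, numeric(1))
  if (is.null(total_reads)) total_reads <- sum(raw)
  if (total_reads <= 0) stop("no reads to normalize")
  out <- lapply(psite_vectors, function(v) v / total_reads * 1e6)
  structure(out, raw_totals = raw)
}

#' Abundance-normalised ribosome occupancy
#'
#' Divides each position of the per-transcript RPM vector by the
#' transcript's TPM so occupancy reflects ribosome density per mRNA copy.
#' Transcripts with zero TPM are excluded and reported.
#'
#' @param psite_rpm list of RPM vectors.
#' @param tpm_values named TPM vector covering the transcripts.
#' @return list of occupancy vectors; excluded ids in attribute `excluded`.
#' @export
normalized_occupancy <- function(psite_rpm, tpm_values) {
  ids <- names(psite_rpm)
  miss <- setdiff(ids, names(tpm_values))
  if (length(miss)) stop("TPM missing for: ", paste(head(miss, 5),
                                                    collapse = ", "))
  tv <- tpm_values[ids]
  excluded <- ids[tv <= 0]
  if (length(excluded)) {
    message(length(excluded), " transcript(s) excluded with zero TPM")
  }
  keep <- ids[tv > 0]
  structure(Map(function(v, t) v / t, psite_rpm[keep], tv[keep]),
            excluded = excluded)
}

#' Build a ribosome-profiling dataset
#'
#' Convenience constructor bundling length selection, P-site assignment,
#' RPM normalisation, TPM of matched total RNA and occupancy normalisation.
#'
#' @param reads footprint positions. @param tx annotation.
#' @param total_counts named total-RNA counts per transcript.
#' @param offset,lengths,threshold see [select_periodic_lengths()].
#' @return list with `occupancy` (per-nt normalised vectors), `tpm`,
#'   `raw_totals`, `retained_lengths`.
#' @export
rpf_dataset <- function(reads, tx, total_counts, offset = 13,
                        lengths = 28:30, threshold = 0.6) {
  keep_len <- select_periodic_lengths(reads, tx, lengths, offset, threshold)
  reads <- reads[reads$length %in% keep_len, , drop = FALSE]
  vecs <- psite_assign(reads, tx, offset)
  rpm <- rpm_normalize(vecs)
  tl <- setNames(tx_total_length(tx), tx$transcript_id)
  tc <- total_counts[names(tl)]
  tc[is.na(tc)] <- 0
  tpms <- tpm(setNames(as.numeric(tc), names(tl)), tl)
  occ <- normalized_occupancy(rpm, tpms)
  list(occupancy = occ, tpm = tpms,
       raw_totals = attr(rpm, "raw_totals"),
       retained_lengths = as.integer(keep_len))
}

metagene_filter <- function(ds, tx, ids, min_rpf = 25, min_cds = 301) {
  info <- tx[match(ids, tx$transcript_id), ]
  raw <- ds$raw_totals[ids]
  keep <- !is.na(info$cds_len) & info$cds_len >= min_cds &
    raw >= min_rpf & ids %in% names(ds$occupancy)
  list(ids = ids[keep],
       report = c(input = length(ids),
                  cds_too_short = sum(info$cds_len < min_cds, na.rm = TRUE),
                  too_few_rpf = sum(raw < min_rpf, na.rm = TRUE),
                  retained = sum(keep)))
}

#' CDS metagene profile
#'
#' Per-codon occupancy (sum of the three in-frame nucleotide values) is
#' averaged with equal transcript weight over the first `n_codons` codons
#' downstream of the AUG and the last `n_codons` upstream of the STOP.
#' Transcripts need at least `min_rpf` raw footprints and CDS length
#' strictly greater than 300 nt (`min_cds = 301`).
#'
#' @param ds an [rpf_dataset()].
#' @param tx annotation.
#' @param group transcript ids to profile.
#' @param n_codons codons from each end (default 75).
#' @param min_rpf,min_cds inclusion filters.
#' @return list with `start_profile` (codons 1..n from AUG),
#'   `stop_profile` (codons -n..-1 to STOP), `n_transcripts`,
#'   `filter_report`.
#' @export
metagene_cds <- function(ds, tx, group, n_codons = 75, min_rpf = 25,
                         min_cds = 301) {
  flt <- metagene_filter(ds, tx, group, min_rpf, min_cds)
  if (length(flt$ids) == 0L) {
    stop("no transcripts pass the metagene filters: ",
         paste(names(flt$report), flt$report, sep = "=", collapse = ", "))
  }
  info <- tx[match(flt$ids, tx$transcript_id), ]
  prof <- function(id, start, len, from_start) {
    v <- ds$occupancy[[id]]
    cds <- v[(start + 1):(start + len)]
    cod <- colSums(matrix(cds, nrow = 3))
    if (from_start) cod[seq_len(min(n_codons, length(cod)))]
    else utils::tail(cod, n_codons)
  }
  take <- function(from_start) {
    m <- t(mapply(prof, flt$ids, info$utr5_len, info$cds_len,
                  MoreArgs = list(from_start = from_start)))
    colMeans(m)
  }
  start_profile <- take(TRUE)
  stop_profile <- take(FALSE)
  names(start_profile) <- seq_len(length(start_profile))
  names(stop_profile) <- seq(-length(stop_profile), -1)
  list(start_profile = start_profile, stop_profile = stop_profile,
       n_transcripts = length(flt$ids), filter_report = flt$report)
}

#' 5'UTR occupancy in the first and last 50 nt
#'
#' For transcripts whose 5'UTR is strictly longer than 100 nt, the mean
#' normalised occupancy (all frames) over the first and last `window` nt of
#' the 5'UTR. Elevated occupancy in the last window relative to all mRNAs
#' is the signature of initiation-repressed, uORF-prone messages.
#'
#' @param ds an [rpf_dataset()]. @param tx annotation.
#' @param group transcript ids.
#' @param window nt from each 5'UTR end (default 50).
#' @param min_utr5 minimum 5'UTR length, strict lower bound via default 101.
#' @return data.frame `transcript_id`, `first50`, `last50`.
#' @export
utr5_occupancy <- function(ds, tx, group, window = 50, min_utr5 = 101) {
  info <- tx[match(group, tx$transcript_id), ]
  keep <- !is.na(info$utr5_len) & info$utr5_len >= min_utr5 &
    group %in% names(ds$occupancy)
  ids <- group[keep]
  if (length(ids) == 0L) stop("no transcripts with qualifying 5'UTRs")
  l5 <- info$utr5_len[keep]
  first <- mapply(function(id, l) mean(ds$occupancy[[id]][1:window]),
                  ids, l5)
  last <- mapply(function(id, l) {
    mean(ds$occupancy[[id]][(l - window + 1):l])
  }, ids, l5)
  data.frame(transcript_id = ids, first50 = unname(first),
             last50 = unname(last), stringsAsFactors = FALSE)
}
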