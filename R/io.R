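#' @importFrom utils read.delim write.table head
#' @importFrom stats pnorm pbinom phyper rbinom rlnorm rnbinom rpois rnorm runif
#'   setNames p.adjust complete.cases sd median quantile ecdf optim uniroot
#'   aggregate
NULL

VALID_ASSAYS <- c("rip_ip", "rip_input", "total", "subpolysomal", "polysomal")
DNA_ALPHABET <- c("A", "C", "G", "T", "N")

# ---- transcript records -----------------------------------------------------

#' Construct a table of transcript records
#'
#' A transcript record holds the sense-strand 5'UTR, CDS and 3'UTR sequences
#' of one transcript together with its gene id. Sequences are stored in the
#' DNA alphabet (`U` is mapped to `T` on ingest); coordinates throughout the
#' package are 0-based, half-open and transcript-relative.
#'
#' @param transcript_id,gene_id character vectors.
#' @param utr5,cds,utr3 character vectors of region sequences (may be "").
#' @return A `data.frame` with class `transcript_records`.
#' @export
transcript_records <- function(transcript_id, gene_id, utr5, cds, utr3) {
  utr5 <- clean_seq(utr5); cds <- clean_seq(cds); utr3 <- clean_seq(utr3)
  full <- paste0(utr5, cds, utr3)
  bad <- grepl(sprintf("[^%s]", paste(DNA_ALPHABET, collapse = "")), full)
  if (any(bad)) {
    stop("sequences contain characters outside {A,C,G,T,N}: ",
         paste(transcript_id[bad], collapse = ", "))
  }
  cl <- nchar(cds)
  bad_cds <- cl > 0 & (cl %% 3L != 0L | cl < 3L)
  if (any(bad_cds)) {
    stop("CDS length not a positive multiple of 3 for: ",
         paste(transcript_id[bad_cds], collapse = ", "))
  }
  out <- data.frame(
    transcript_id = as.character(transcript_id),
    gene_id = as.character(gene_id),
    utr5 = utr5, cds = cds, utr3 = utr3,
    utr5_len = nchar(utr5), cds_len = cl, utr3_len = nchar(utr3),
    stringsAsFactors = FALSE
  )
  class(out) <- c("transcript_records", "data.frame")
  out
}

clean_seq <- function(x) {
  x[is.na(x)] <- ""
  chartr("Uu", "Tt", toupper(as.character(x)))
}

#' Read a transcriptome from FASTA plus a region table
#'
#' The FASTA file carries full transcript sequences (5'UTR + CDS + 3'UTR on
#' the sense strand); the tab-separated region table gives, per transcript,
#' `transcript_id`, `gene_id`, `utr5_len`, `cds_len`, `utr3_len`. Sequences
#' are sliced into regions, `U` is mapped to `T`, transcripts whose CDS
#' length is not a positive multiple of 3 are excluded with a warning, and
#' duplicate full sequences are collapsed to a single record (first
#' occurrence kept), mirroring feature analyses that consider only unique
#' sequences.
#'
#' @param fasta_path path to the transcript FASTA.
#' @param regions_path path to the TSV region table.
#' @return A `transcript_records` data.frame.
#' @export
read_transcriptome <- function(fasta_path, regions_path) {
  seqs <- Biostrings::readBStringSet(fasta_path)
  reg <- read.delim(regions_path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "gene_id", "utr5_len", "cds_len", "utr3_len")
  if (!all(need %in% names(reg))) {
    stop("region table must have columns: ", paste(need, collapse = ", "))
  }
  ids <- sub("\\s.*$", "", names(seqs))
  missing <- setdiff(reg$transcript_id, ids)
  if (length(missing)) {
    stop("transcripts in region table absent from FASTA: ",
         paste(head(missing, 5), collapse = ", "))
  }
  seqchar <- clean_seq(as.character(seqs))
  names(seqchar) <- ids
  s <- seqchar[reg$transcript_id]
  total <- reg$utr5_len + reg$cds_len + reg$utr3_len
  mism <- nchar(s) != total
  if (any(mism)) {
    stop("FASTA/region length mismatch for: ",
         paste(reg$transcript_id[mism], collapse = ", "))
  }
  bad_cds <- reg$cds_len > 0 & (reg$cds_len %% 3L != 0L | reg$cds_len < 3L)
  if (any(bad_cds)) {
    warning(sum(bad_cds), " transcript(s) excluded, CDS length not a ",
            "positive multiple of 3: ",
            paste(reg$transcript_id[bad_cds], collapse = ", "))
    reg <- reg[!bad_cds, , drop = FALSE]
    s <- s[!bad_cds]
  }
  # dedup on full sequence, keep first occurrence
  keep <- !duplicated(unname(s))
  reg <- reg[keep, , drop = FALSE]
  s <- s[keep]
  transcript_records(
    transcript_id = reg$transcript_id,
    gene_id = reg$gene_id,
    utr5 = substr(s, 1L, reg$utr5_len),
    cds = substr(s, reg$utr5_len + 1L, reg$utr5_len + reg$cds_len),
    utr3 = substr(s, reg$utr5_len + reg$cds_len + 1L, nchar(s))
  )
}

#' Write a transcriptome as FASTA plus region table
#'
#' Inverse of [read_transcriptome()]; round-trips exactly.
#'
#' @param tx a `transcript_records` data.frame.
#' @param fasta_path,regions_path output paths.
#' @export
write_transcriptome <- function(tx, fasta_path, regions_path) {
  full <- Biostrings::DNAStringSet(paste0(tx$utr5, tx$cds, tx$utr3))
  names(full) <- tx$transcript_id
  Biostrings::writeXStringSet(full, fasta_path)
  write_tsv(tx[, c("transcript_id", "gene_id", "utr5_len", "cds_len",
                   "utr3_len")], regions_path)
  invisible(tx)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

# ---- count matrices ---------------------------------------------------------

#' Construct a count matrix with sample metadata
#'
#' @param counts non-negative integer matrix, genes in rows (rownames are
#'   gene ids), samples in columns.
#' @param sample_meta data.frame with one row per column of `counts` and at
#'   least `sample`, `assay` (one of `rip_ip`, `rip_input`, `total`,
#'   `subpolysomal`, `polysomal`), `condition`, `replicate`.
#' @param library_sizes optional positive numeric; defaults to column sums.
#' @return object of class `count_matrix`.
#' @export
count_matrix <- function(counts, sample_meta, library_sizes = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) == 0L) stop("no genes")
  if (is.null(rownames(counts))) stop("counts must have gene ids as rownames")
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (length(counts) && max(counts) < .Machine$integer.max) {
    storage.mode(counts) <- "integer"  # bit-exact TSV round trips
  }
  if (nrow(sample_meta) != ncol(counts)) {
    stop("sample_meta rows must match count columns")
  }
  bad <- !sample_meta$assay %in% VALID_ASSAYS
  if (any(bad)) {
    stop("unknown assay label(s): ",
         paste(unique(sample_meta$assay[bad]), collapse = ", "))
  }
  if (is.null(library_sizes)) {
    library_sizes <- colSums(counts)
  } else {
    library_sizes <- as.numeric(library_sizes)
    if (length(library_sizes) != ncol(counts)) {
      stop("one library size per sample required")
    }
    off <- library_sizes != colSums(counts)
    if (any(off)) {
      message("library_sizes override column sums for ",
              sum(off), " sample(s)")
    }
  }
  if (any(library_sizes <= 0)) stop("library_sizes must be positive")
  structure(
    list(counts = counts,
         sample_meta = as.data.frame(sample_meta, stringsAsFactors = FALSE),
         library_sizes = unname(library_sizes)),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples\n")
  cat("assays:", paste(unique(x$sample_meta$assay), collapse = ", "), "\n")
  invisible(x)
}

#' Read a count matrix from a counts TSV and a metadata TSV
#'
#' The counts TSV has a `gene_id` column followed by one column per sample;
#' the metadata TSV has columns `sample`, `assay`, `condition`, `replicate`
#' and optionally `library_size` (which overrides the column sum, with the
#' discrepancy reported).
#'
#' @param tsv_path,meta_path input paths.
#' @return a `count_matrix`.
#' @export
read_counts <- function(tsv_path, meta_path) {
  tab <- read.delim(tsv_path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"gene_id" %in% names(tab)) stop("counts TSV needs a gene_id column")
  meta <- read.delim(meta_path, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, setdiff(names(tab), "gene_id"), drop = FALSE])
  rownames(m) <- tab$gene_id
  if (!all(meta$sample %in% colnames(m))) {
    stop("metadata samples missing from counts: ",
         paste(setdiff(meta$sample, colnames(m)), collapse = ", "))
  }
  m <- m[, meta$sample, drop = FALSE]
  ls <- if ("library_size" %in% names(meta)) meta$library_size else NULL
  count_matrix(m, meta, ls)
}

#' Write a count matrix to counts + metadata TSVs
#' @param cm a `count_matrix`.
#' @param tsv_path,meta_path output paths.
#' @export
write_counts <- function(cm, tsv_path, meta_path) {
  df <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, tsv_path)
  meta <- cm$sample_meta
  meta$library_size <- cm$library_sizes
  write_tsv(meta, meta_path)
  invisible(cm)
}

#' Subset a count matrix to samples matching assay/condition
#' @param cm a `count_matrix`.
#' @param assay,condition optional filters on the sample metadata.
#' @export
subset_samples <- function(cm, assay = NULL, condition = NULL) {
  keep <- rep(TRUE, ncol(cm$counts))
  if (!is.null(assay)) keep <- keep & cm$sample_meta$assay %in% assay
  if (!is.null(condition)) {
    keep <- keep & cm$sample_meta$condition %in% condition
  }
  if (!any(keep)) stop("no samples match the requested assay/condition")
  count_matrix(cm$counts[, keep, drop = FALSE],
               cm$sample_meta[keep, , drop = FALSE],
               cm$library_sizes[keep])
}

# ---- read positions, peaks, families ---------------------------------------

#' Read ribosome-footprint positions (BED-like 3-column TSV)
#'
#' Columns: `transcript_id`, `five_prime_pos` (0-based transcript
#' coordinate of the read 5' end), `length` (nt).
#' @param path input TSV.
#' @return data.frame of read positions.
#' @export
read_read_positions <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "five_prime_pos", "length")
  if (!all(need %in% names(df))) {
    stop("read-position table needs columns: ", paste(need, collapse = ", "))
  }
  if (any(df$five_prime_pos < 0) || any(df$length <= 0)) {
    stop("five_prime_pos must be >= 0 and length > 0")
  }
  df[need]
}

#' Read initiation-peak tables
#'
#' Long TSV with columns `transcript_id`, `annotated_start` (0-based
#' coordinate of the main AUG) and `peak_pos`; one row per initiating
#' ribosome peak, `peak_pos` may be NA for transcripts with no peak.
#' @param path input TSV.
#' @return data.frame.
#' @export
read_initiation_peaks <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "annotated_start", "peak_pos")
  if (!all(need %in% names(df))) {
    stop("peak table needs columns: ", paste(need, collapse = ", "))
  }
  if (any(df$annotated_start < 0)) stop("annotated_start must be >= 0")
  df[need]
}

#' Read miRNA-family target lists
#'
#' TSV with columns `family_id`, `gene_id` and optionally `pct`
#' (Targetscan-style conservation probability). When a `pct` column is
#' present, rows with `pct <= threshold` are dropped.
#' @param path input TSV.
#' @param pct_threshold keep targets with PCT strictly above this (default
#'   0.5, the conventional conserved-family cutoff).
#' @return data.frame with `family_id`, `gene_id`.
#' @export
read_mirna_families <- function(path, pct_threshold = 0.5) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("family_id", "gene_id") %in% names(df))) {
    stop("family table needs columns family_id, gene_id")
  }
  if (any(!nzchar(df$family_id))) stop("empty family_id")
  if ("pct" %in% names(df)) df <- df[df$pct > pct_threshold, , drop = FALSE]
  unique(df[c("family_id", "gene_id")])
}

#' Pick the most abundant isoform per gene
#'
#' Downstream analyses use one representative transcript per gene: the one
#' with the highest mean total-RNA count. Ties break lexicographically on
#' transcript id; genes whose transcripts are all zero get the
#' lexicographically first transcript and are flagged.
#'
#' @param counts_by_transcript numeric matrix (transcripts x samples) or
#'   named vector of per-transcript counts.
#' @param transcript_to_gene named character vector transcript -> gene.
#' @return named character vector gene -> transcript, with attribute
#'   `all_zero` listing flagged genes.
#' @export
most_abundant_isoform <- function(counts_by_transcript, transcript_to_gene) {
  if (is.matrix(counts_by_transcript)) {
    mu <- rowMeans(counts_by_transcript)
  } else {
    mu <- counts_by_transcript
  }
  if (is.null(names(mu))) stop("transcript counts must be named")
  missing <- setdiff(names(mu), names(transcript_to_gene))
  if (length(missing)) {
    stop("transcripts without gene mapping: ",
         paste(head(missing, 5), collapse = ", "))
  }
  ord <- order(names(mu))  # lexicographic tie-break
  mu <- mu[ord]
  gene <- transcript_to_gene[names(mu)]
  pick <- vapply(split(seq_along(mu), gene), function(idx) {
    idx[which.max(mu[idx])]  # first max = lexicographically smallest
  }, integer(1))
  out <- setNames(names(mu)[pick], names(pick))
  zero <- vapply(split(mu, gene), function(v) all(v == 0), logical(1))
  attr(out, "all_zero") <- names(zero)[zero]
  if (any(zero)) {
    message(sum(zero), " gene(s) with all-zero transcripts; first ",
            "transcript used")
  }
  out
}
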