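# RIP-Seq enrichment: call per-protein IP-over-input enrichment and
# partition the gene universe into binding groups (the Venn groups used to
# contrast eIF4A1-, eIF4A2- and DDX6-bound mRNAs).

#' Counts per million
#' @param counts non-negative numeric vector or matrix (genes x samples).
#' @param library_size positive scalar, or one value per column.
#' @return CPM values with the shape of `counts`.
#' @export
cpm <- function(counts, library_size) {
  if (any(library_size <= 0)) stop("library_size must be positive")
  if (is.matrix(counts)) {
    if (length(library_size) == 1L) {
      library_size <- rep(library_size, ncol(counts))
    }
    sweep(counts, 2, library_size, "/") * 1e6
  } else {
    counts / library_size * 1e6
  }
}

#' Test per-gene RIP enrichment of IP over input
#'
#' The original enrichment analysis is only described as following earlier
#' RIP-Seq studies, so this package defines a transparent exact stand-in:
#' replicates are pooled per side, and with pooled counts c_ip, c_in and
#' summed library sizes L_ip, L_in each gene is tested one-sided with
#' X ~ Binomial(c_ip + c_in, L_ip / (L_ip + L_in)), p = P(X >= c_ip).
#' `log2_enrichment` is log2((c_ip + 0.5)/L_ip) - log2((c_in + 0.5)/L_in)
#' (0.5 pseudocount for zeros); BH correction runs across genes and
#' `enriched` requires both `fdr < fdr_threshold` and a positive log2
#' enrichment. Genes with zero total count get p = 1 and enrichment 0.
#'
#' @param ip_counts,input_counts matrices (genes x replicates) or named
#'   vectors; gene ids taken from rownames/names, genes absent on one side
#'   count as zero.
#' @param ip_libsizes,input_libsizes per-replicate library sizes; default
#'   column sums.
#' @param fdr_threshold significance threshold on the BH FDR (default 0.05).
#' @return data.frame: `gene_id`, `log2_enrichment`, `p`, `fdr`, `enriched`.
#' @export
enrichment_test <- function(ip_counts, input_counts,
                            ip_libsizes = NULL, input_libsizes = NULL,
                            fdr_threshold = 0.05) {
  as_mat <- function(x) {
    if (is.matrix(x)) x else matrix(x, ncol = 1, dimnames = list(names(x)))
  }
  ip <- as_mat(ip_counts); inp <- as_mat(input_counts)
  if (is.null(rownames(ip)) || is.null(rownames(inp))) {
    stop("counts must carry gene ids")
  }
  if (is.null(ip_libsizes)) ip_libsizes <- colSums(ip)
  if (is.null(input_libsizes)) input_libsizes <- colSums(inp)
  genes <- sort(union(rownames(ip), rownames(inp)))
  fill <- function(m, genes) {
    out <- matrix(0, length(genes), ncol(m), dimnames = list(genes))
    out[rownames(m), ] <- m
    out
  }
  c_ip <- rowSums(fill(ip, genes))
  c_in <- rowSums(fill(inp, genes))
  L_ip <- sum(ip_libsizes); L_in <- sum(input_libsizes)
  if (L_ip <= 0 || L_in <= 0) stop("library sizes must be positive")
  tot <- c_ip + c_in
  pr <- L_ip / (L_ip + L_in)
  p <- ifelse(tot == 0, 1, pbinom(c_ip - 1, tot, pr, lower.tail = FALSE))
  lfc <- ifelse(tot == 0, 0,
                log2((c_ip + 0.5) / L_ip) - log2((c_in + 0.5) / L_in))
  fdr <- benjamini_hochberg(p)
  data.frame(
    gene_id = genes,
    log2_enrichment = unname(lfc),
    p = unname(p),
    fdr = unname(fdr),
    enriched = unname(fdr < fdr_threshold & lfc > 0),
    stringsAsFactors = FALSE
  )
}

#' Partition genes into binding groups from per-protein RIP results
#'
#' Each gene is labelled with the set of proteins for which it is enriched
#' (FDR below threshold with positive enrichment): e.g. `"eIF4A2"`,
#' `"eIF4A1+eIF4A2"`, or `"none"`. Labels form a partition of the shared
#' gene universe.
#'
#' @param rip_results named list of [enrichment_test()] outputs, one per
#'   protein; identical gene universes required.
#' @param fdr_threshold threshold re-applied to the stored `fdr` and
#'   `log2_enrichment` columns (default 0.05).
#' @return data.frame `gene_id`, `label`, with a `counts` attribute (table
#'   of label sizes).
#' @export
assign_binding_groups <- function(rip_results, fdr_threshold = 0.05) {
  if (is.null(names(rip_results))) stop("rip_results must be named by protein")
  universes <- lapply(rip_results, function(r) sort(r$gene_id))
  ref <- universes[[1]]
  same <- vapply(universes, identical, logical(1), y = ref)
  if (!all(same)) {
    diffs <- unique(unlist(lapply(universes, function(u) {
      c(setdiff(u, ref), setdiff(ref, u))
    })))
    stop("inconsistent gene universes across proteins; differing ids: ",
         paste(head(diffs, 5), collapse = ", "))
  }
  enr <- vapply(rip_results, function(r) {
    r <- r[order(r$gene_id), ]
    r$fdr < fdr_threshold & r$log2_enrichment > 0
  }, logical(length(ref)))
  enr <- matrix(enr, nrow = length(ref),
                dimnames = list(ref, names(rip_results)))
  label <- apply(enr, 1, function(e) {
    if (!any(e)) "none" else paste(sort(names(rip_results)[e]),
                                   collapse = "+")
  })
  out <- data.frame(gene_id = ref, label = unname(label),
                    stringsAsFactors = FALSE)
  attr(out, "counts") <- table(out$label)
  out
}
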