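# Count normalization: CPM, FPKM and their base-2 log transforms.
# FPKM uses the raw per-sample library size (column sum over all genes in the
# matrix) as the "million mapped reads" denominator.

library_sizes <- function(counts) {
  totals <- colSums(counts$counts)
  zero <- names(totals)[totals == 0]
  if (length(zero)) {
    stop("zero total count for sample(s): ", paste(zero, collapse = ", "),
         call. = FALSE)
  }
  totals
}

#' Counts per million
#'
#' `CPM(g, s) = counts(g, s) / total(s) * 1e6`; every column of the result
#' sums to one million.
#'
#' @param counts A [count_matrix()]; every sample must have a positive total.
#' @return An [expression_matrix()] with `transform = "CPM"`.
#' @export
#' @examples
#' m <- matrix(c(1L, 3L), 2, 1, dimnames = list(c("G1", "G2"), "s1"))
#' meta <- data.frame(sample_id = "s1", cell_type = "OPC",
#'                    genotype = "WT", condition = "NS")
#' compute_cpm(count_matrix(m, meta))$values
compute_cpm <- function(counts) {
  if (!inherits(counts, "count_matrix")) {
    stop("`counts` must be a count_matrix", call. = FALSE)
  }
  totals <- library_sizes(counts)
  values <- sweep(counts$counts, 2, totals, `/`) * 1e6
  expression_matrix(values, counts$samples, transform = "CPM")
}

#' Fragments per kilobase per million mapped reads
#'
#' `FPKM(g, s) = counts(g, s) * 1e9 / (length_bp(g) * total(s))`, the
#' length- and depth-normalized expression unit used throughout the
#' downstream interaction scoring.
#'
#' @param counts A [count_matrix()].
#' @param annotation A [gene_annotation()] covering every gene in `counts`.
#' @return An [expression_matrix()] with `transform = "FPKM"`.
#' @export
compute_fpkm <- function(counts, annotation) {
  if (!inherits(counts, "count_matrix")) {
    stop("`counts` must be a count_matrix", call. = FALSE)
  }
  if (!inherits(annotation, "gene_annotation")) {
    stop("`annotation` must be a gene_annotation", call. = FALSE)
  }
  genes <- rownames(counts$counts)
  idx <- match(genes, annotation$gene)
  if (anyNA(idx)) {
    stop("no length annotation for gene(s): ",
         paste(genes[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  totals <- library_sizes(counts)
  len <- annotation$length_bp[idx]
  values <- counts$counts * 1e9 / outer(len, totals)
  dimnames(values) <- dimnames(counts$counts)
  expression_matrix(values, counts$samples, transform = "FPKM")
}

#' Base-2 log transform of a linear expression matrix
#'
#' Applies `log2(value + pseudocount)` to a CPM or FPKM matrix and records
#' the transform and pseudocount. Refuses to transform an already
#' log-transformed matrix, and refuses a zero pseudocount when any entry is
#' zero (the result would not be finite).
#'
#' @param expr An [expression_matrix()] with a linear transform (CPM, FPKM).
#' @param pseudocount Non-negative value added before taking logs; default 1
#'   so zeros map to zero.
#' @return An [expression_matrix()] with transform `log2CPM` or `logFPKM`.
#' @export
log_transform <- function(expr, pseudocount = 1) {
  if (!inherits(expr, "expression_matrix")) {
    stop("`expr` must be an expression_matrix", call. = FALSE)
  }
  if (is_log_transform(expr$transform)) {
    stop("matrix is already log-transformed (", expr$transform, ")",
         call. = FALSE)
  }
  if (length(pseudocount) != 1 || !is.numeric(pseudocount) ||
      is.na(pseudocount) || pseudocount < 0) {
    stop("`pseudocount` must be a single non-negative number", call. = FALSE)
  }
  if (pseudocount == 0 && any(expr$values == 0)) {
    stop("pseudocount 0 with zero entries would give non-finite logs",
         call. = FALSE)
  }
  out_transform <- switch(expr$transform, CPM = "log2CPM", FPKM = "logFPKM")
  expression_matrix(log2(expr$values + pseudocount), expr$samples,
                    transform = out_transform, pseudocount = pseudocount)
}
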