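# Differential-expression plumbing and the threshold filters applied to
# per-comparison DE tables: significance on the adjusted p-value plus
# abundance (log2CPM) and effect-size (|log2FC|) floors, all inclusive.

#' Benjamini-Hochberg adjustment with input validation
#'
#' Step-up FDR adjustment of a vector of p-values (delegates to
#' [stats::p.adjust()] after validating the input range). Each adjusted
#' value is at least its raw p and at most 1, and adjustment is monotone in
#' the input ranks.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param method Adjustment procedure, `"BH"` (default) or `"bonferroni"`.
#' @return Numeric vector of adjusted p-values, same length and order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
bh_adjust <- function(p, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (!is.numeric(p)) stop("`p` must be numeric", call. = FALSE)
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = method)
}

#' Construct a per-comparison differential-expression table
#'
#' @param data Data frame with one row per gene and columns `gene`,
#'   `log2FC`, `log2CPM`, `p`; `p_adj` is computed by [bh_adjust()] when
#'   absent.
#' @param comparison One of the four labels in [opc_comparisons()].
#' @return A data.frame of class `de_table` carrying the comparison label
#'   as an attribute.
#' @export
de_table <- function(data, comparison) {
  if (length(comparison) != 1 || !comparison %in% opc_comparisons()) {
    stop("`comparison` must be one of: ",
         paste(opc_comparisons(), collapse = ", "), call. = FALSE)
  }
  required <- c("gene", "log2FC", "log2CPM", "p")
  if (!is.data.frame(data) || !all(required %in% names(data))) {
    stop("`data` must have columns ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(data$gene)) {
    stop("duplicate gene rows in DE table", call. = FALSE)
  }
  if (anyNA(data$p) || any(data$p < 0) || any(data$p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(data$p_adj)) data$p_adj <- bh_adjust(data$p)
  data <- data[, c("gene", "log2FC", "log2CPM", "p", "p_adj")]
  rownames(data) <- NULL
  structure(data, comparison = comparison,
            class = c("de_table", "data.frame"))
}

#' Two-group differential-expression test on log2CPM
#'
#' A deliberately simple stand-in for a full count-model fit so the pipeline
#' runs end-to-end: per gene, `log2FC` is the difference of group means of
#' `log2(CPM + 1)` (group B minus group A), `log2CPM` is the mean over both
#' groups, and the p-value comes from a two-sided Welch t-test on the
#' `log2(CPM + 1)` values. Genes with zero variance in both groups get
#' `p = 1` (never flagged), which also covers all-zero genes.
#'
#' @param counts A [count_matrix()] (library sizes are taken over all its
#'   samples).
#' @param group_a,group_b Disjoint character vectors of at least two sample
#'   ids each; the reference group is `group_a`.
#' @param comparison Label for the resulting table; see [opc_comparisons()].
#' @return A [de_table()] with BH-adjusted p-values.
#' @export
simple_de_test <- function(counts, group_a, group_b,
                           comparison = opc_comparisons()[1]) {
  if (!inherits(counts, "count_matrix")) {
    stop("`counts` must be a count_matrix", call. = FALSE)
  }
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  overlap <- intersect(group_a, group_b)
  if (length(overlap)) {
    stop("groups overlap: ", paste(overlap, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(c(group_a, group_b), colnames(counts$counts))
  if (length(unknown)) {
    stop("unknown sample(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  lcpm <- log2(compute_cpm(counts)$values + 1)
  a <- lcpm[, group_a, drop = FALSE]
  b <- lcpm[, group_b, drop = FALSE]
  mean_a <- rowMeans(a)
  mean_b <- rowMeans(b)
  var_a <- apply(a, 1, var)
  var_b <- apply(b, 1, var)
  p <- vapply(seq_len(nrow(lcpm)), function(i) {
    if (var_a[i] == 0 && var_b[i] == 0) return(1)
    t.test(b[i, ], a[i, ], var.equal = FALSE)$p.value
  }, numeric(1))
  de_table(data.frame(gene = rownames(lcpm),
                      log2FC = mean_b - mean_a,
                      log2CPM = rowMeans(cbind(a, b)),
                      p = p),
           comparison = comparison)
}

#' Differential-expression filter thresholds
#'
#' Defaults reproduce the study's inclusion rule: adjusted p-value at most
#' 0.05, average abundance `log2CPM >= 1`, and effect size
#' `|log2FC| >= 0.585` (about 1.5-fold). All three boundaries are inclusive.
#' Set the floors to 0 to count DE genes on significance alone.
#'
#' @param alpha Ceiling on the adjusted p-value, in `(0, 1]`.
#' @param min_log2cpm Abundance floor (>= 0).
#' @param min_abs_log2fc Absolute log2 fold-change floor (>= 0).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(alpha = 0.05, min_log2cpm = 1, min_abs_log2fc = 0.585) {
  if (length(alpha) != 1 || !is.numeric(alpha) || is.na(alpha) ||
      alpha <= 0 || alpha > 1) {
    stop("`alpha` must lie in (0, 1]", call. = FALSE)
  }
  if (length(min_log2cpm) != 1 || !is.numeric(min_log2cpm) ||
      is.na(min_log2cpm) || min_log2cpm < 0) {
    stop("`min_log2cpm` must be >= 0", call. = FALSE)
  }
  if (length(min_abs_log2fc) != 1 || !is.numeric(min_abs_log2fc) ||
      is.na(min_abs_log2fc) || min_abs_log2fc < 0) {
    stop("`min_abs_log2fc` must be >= 0", call. = FALSE)
  }
  structure(list(alpha = alpha, min_log2cpm = min_log2cpm,
                 min_abs_log2fc = min_abs_log2fc),
            class = "filter_spec")
}

#' Apply significance, abundance and effect filters to a DE table
#'
#' A gene is called up-regulated iff `p_adj <= alpha`, `log2CPM >=
#' min_log2cpm` and `log2FC >= min_abs_log2fc`; down-regulated symmetric
#' with `log2FC <= -min_abs_log2fc`. Boundary values pass.
#'
#' @param table A [de_table()].
#' @param spec A [filter_spec()].
#' @return An object of class `gene_set_pair`: list with character vectors
#'   `up` and `down` (disjoint) and the `comparison` label.
#' @export
apply_filters <- function(table, spec = filter_spec()) {
  if (!inherits(table, "de_table")) {
    stop("`table` must be a de_table", call. = FALSE)
  }
  if (!inherits(spec, "filter_spec")) {
    stop("`spec` must be a filter_spec", call. = FALSE)
  }
  keep <- table$p_adj <= spec$alpha & table$log2CPM >= spec$min_log2cpm
  up <- table$gene[keep & table$log2FC > 0 &
                     table$log2FC >= spec$min_abs_log2fc]
  down <- table$gene[keep & table$log2FC < 0 &
                       table$log2FC <= -spec$min_abs_log2fc]
  structure(list(up = up, down = down,
                 comparison = attr(table, "comparison")),
            class = "gene_set_pair")
}

#' @export
print.gene_set_pair <- function(x, ...) {
  cat("gene_set_pair [", x$comparison, "]: ", length(x$up), " up, ",
      length(x$down), " down\n", sep = "")
  invisible(x)
}
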