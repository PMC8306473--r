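# Core containers: count_matrix, expression_matrix, gene_annotation,
# lr_pair_table. Deliberately light S3 (list + validated data.frames) in the
# style of edgeR's DGEList.

#' Construct a count matrix with sample metadata
#'
#' @param counts Integer matrix, genes as rows and samples as columns, with
#'   unique row and column names. Values must be non-negative integers.
#' @param samples Data frame of per-sample metadata with columns
#'   `sample_id`, `cell_type`, `genotype`, `condition`, covering every
#'   column of `counts`.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (the matrix) and `samples` (metadata aligned to the matrix columns).
#' @export
#' @examples
#' m <- matrix(c(5L, 0L, 3L, 7L), 2, 2,
#'             dimnames = list(c("G1", "G2"), c("s1", "s2")))
#' meta <- data.frame(sample_id = c("s1", "s2"), cell_type = "OPC",
#'                    genotype = "WT", condition = c("NS", "St"))
#' cm <- count_matrix(m, meta)
count_matrix <- function(counts, samples) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("`counts` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` must have gene row names and sample column names",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate gene ids in `counts`", call. = FALSE)
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate sample ids in `counts`", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("`counts` must contain non-negative integers", call. = FALSE)
  }
  required <- c("sample_id", "cell_type", "genotype", "condition")
  if (!is.data.frame(samples) || !all(required %in% names(samples))) {
    stop("`samples` must be a data.frame with columns ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample ids in `samples`", call. = FALSE)
  }
  missing <- setdiff(colnames(counts), samples$sample_id)
  if (length(missing)) {
    stop("metadata missing for sample(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  samples <- samples[match(colnames(counts), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, samples = samples), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts), "samples\n")
  tab <- table(x$samples$cell_type, paste(x$samples$genotype,
                                          x$samples$condition, sep = "-"))
  print(tab)
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Construct a normalized expression matrix
#'
#' Holds normalized expression values together with a record of which
#' transform produced them (CPM, log2CPM, FPKM or logFPKM) and, for log
#' transforms, the pseudocount used, so downstream stages can refuse
#' ill-typed input (e.g. log of a log).
#'
#' @param values Numeric gene x sample matrix with unique dimnames.
#' @param samples Per-sample metadata, as for [count_matrix()].
#' @param transform One of `"CPM"`, `"log2CPM"`, `"FPKM"`, `"logFPKM"`.
#' @param pseudocount Pseudocount used by a log transform; `NA` for linear
#'   quantities.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, samples,
                              transform = c("CPM", "log2CPM", "FPKM", "logFPKM"),
                              pseudocount = NA_real_) {
  transform <- match.arg(transform)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have gene row names and sample column names",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values))) {
    stop("duplicate gene or sample ids", call. = FALSE)
  }
  if (transform %in% c("log2CPM", "logFPKM") && any(!is.finite(values))) {
    stop("log-transformed values must all be finite", call. = FALSE)
  }
  required <- c("sample_id", "cell_type", "genotype", "condition")
  if (!is.data.frame(samples) || !all(required %in% names(samples))) {
    stop("`samples` must be a data.frame with columns ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(colnames(values), samples$sample_id)
  if (length(missing)) {
    stop("metadata missing for sample(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(values = values, samples = samples, transform = transform,
                 pseudocount = pseudocount),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix (", x$transform, "): ", nrow(x$values), " genes x ",
      ncol(x$values), " samples", sep = "")
  if (!is.na(x$pseudocount)) cat(", pseudocount ", x$pseudocount, sep = "")
  cat("\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

is_log_transform <- function(transform) transform %in% c("log2CPM", "logFPKM")

#' Subset a count or expression matrix by sample
#'
#' @param x A `count_matrix` or `expression_matrix`.
#' @param sample_ids Character vector of sample ids to keep (order preserved).
#' @return An object of the same class restricted to those samples.
#' @export
subset_samples <- function(x, sample_ids) {
  UseMethod("subset_samples")
}

#' @export
subset_samples.count_matrix <- function(x, sample_ids) {
  missing <- setdiff(sample_ids, colnames(x$counts))
  if (length(missing)) {
    stop("unknown sample(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  count_matrix(x$counts[, sample_ids, drop = FALSE],
               x$samples[x$samples$sample_id %in% sample_ids, , drop = FALSE])
}

#' @export
subset_samples.expression_matrix <- function(x, sample_ids) {
  missing <- setdiff(sample_ids, colnames(x$values))
  if (length(missing)) {
    stop("unknown sample(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  expression_matrix(x$values[, sample_ids, drop = FALSE],
                    x$samples[x$samples$sample_id %in% sample_ids, , drop = FALSE],
                    transform = x$transform, pseudocount = x$pseudocount)
}

#' Select sample ids by metadata fields
#'
#' @param x A `count_matrix` or `expression_matrix`.
#' @param cell_type,genotype,condition Optional values to match; `NULL`
#'   matches everything.
#' @return Character vector of matching sample ids.
#' @export
select_samples <- function(x, cell_type = NULL, genotype = NULL,
                           condition = NULL) {
  meta <- x$samples
  keep <- rep(TRUE, nrow(meta))
  if (!is.null(cell_type)) keep <- keep & meta$cell_type %in% cell_type
  if (!is.null(genotype)) keep <- keep & meta$genotype %in% genotype
  if (!is.null(condition)) keep <- keep & meta$condition %in% condition
  meta$sample_id[keep]
}

#' Construct a gene-length annotation table
#'
#' @param gene Character vector of unique gene ids.
#' @param length_bp Positive integer transcript lengths in base pairs, the
#'   "per kilobase" divisor of FPKM.
#' @return A data.frame of class `gene_annotation` with columns `gene`,
#'   `length_bp`.
#' @export
gene_annotation <- function(gene, length_bp) {
  gene <- as.character(gene)
  if (anyDuplicated(gene)) stop("duplicate gene ids", call. = FALSE)
  if (length(gene) != length(length_bp)) {
    stop("`gene` and `length_bp` lengths differ", call. = FALSE)
  }
  if (any(length_bp < 1) || any(length_bp != round(length_bp))) {
    stop("`length_bp` must be positive integers", call. = FALSE)
  }
  structure(data.frame(gene = gene, length_bp = as.integer(length_bp)),
            class = c("gene_annotation", "data.frame"))
}

#' Construct a ligand-receptor pair table
#'
#' Ordered (ligand gene, receptor gene) pairs defining the tested
#' interaction space, in the style of the Ramilowski reference list.
#'
#' @param ligand,receptor Character vectors of equal length; no duplicated
#'   (ligand, receptor) rows, no empty ids.
#' @return A data.frame of class `lr_pair_table` with columns `ligand`,
#'   `receptor` and a derived `pair` name (`ligand_receptor`).
#' @export
lr_pair_table <- function(ligand = character(), receptor = character()) {
  ligand <- as.character(ligand)
  receptor <- as.character(receptor)
  if (length(ligand) != length(receptor)) {
    stop("`ligand` and `receptor` lengths differ", call. = FALSE)
  }
  if (length(ligand) && (any(!nzchar(ligand)) || any(!nzchar(receptor)))) {
    stop("empty gene id in pair list", call. = FALSE)
  }
  key <- paste(ligand, receptor, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (ligand, receptor) rows", call. = FALSE)
  }
  df <- data.frame(ligand = ligand, receptor = receptor)
  df$pair <- if (nrow(df)) paste(ligand, receptor, sep = "_") else character()
  structure(df, class = c("lr_pair_table", "data.frame"))
}
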