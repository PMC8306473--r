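# Plain TSV input/output for every container. Doubles are written with
# "%.17g" so values survive a write/read round trip exactly and repeated
# runs are byte-identical.

fmt_cols <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  df
}

#' Write a data.frame as TSV
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  write.table(fmt_cols(as.data.frame(df)), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a TSV into a data.frame
#'
#' @param path Input path.
#' @return Data frame (`check.names = FALSE`).
#' @export
read_tsv <- function(path) {
  read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

matrix_to_df <- function(m) {
  cbind(data.frame(gene = rownames(m)), as.data.frame(m, optional = TRUE))
}

df_to_matrix <- function(df) {
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write / read a count matrix with its sample metadata
#'
#' The counts file has genes as rows and samples as columns (header row =
#' sample ids, first column `gene`); the metadata file has columns
#' `sample_id`, `cell_type`, `genotype`, `condition`.
#'
#' @param x A [count_matrix()].
#' @param counts_path,metadata_path File paths.
#' @return `write_counts` returns the paths invisibly; `read_counts`
#'   returns a [count_matrix()].
#' @export
write_counts <- function(x, counts_path, metadata_path) {
  if (!inherits(x, "count_matrix")) {
    stop("`x` must be a count_matrix", call. = FALSE)
  }
  write_tsv(matrix_to_df(x$counts), counts_path)
  write_tsv(x$samples, metadata_path)
  invisible(c(counts_path, metadata_path))
}

#' @rdname write_counts
#' @export
read_counts <- function(counts_path, metadata_path) {
  m <- df_to_matrix(read_tsv(counts_path))
  storage.mode(m) <- "integer"
  count_matrix(m, read_tsv(metadata_path))
}

#' Write / read a normalized expression matrix
#'
#' The values file mirrors the counts layout. The transform and pseudocount
#' are not stored in the file; `read_expression` takes them as arguments.
#'
#' @param x An [expression_matrix()].
#' @param values_path,metadata_path File paths.
#' @param transform,pseudocount Transform metadata for the values being
#'   read; see [expression_matrix()].
#' @return `read_expression` returns an [expression_matrix()].
#' @export
write_expression <- function(x, values_path, metadata_path) {
  if (!inherits(x, "expression_matrix")) {
    stop("`x` must be an expression_matrix", call. = FALSE)
  }
  write_tsv(matrix_to_df(x$values), values_path)
  write_tsv(x$samples, metadata_path)
  invisible(c(values_path, metadata_path))
}

#' @rdname write_expression
#' @export
read_expression <- function(values_path, metadata_path, transform,
                            pseudocount = NA_real_) {
  expression_matrix(df_to_matrix(read_tsv(values_path)),
                    read_tsv(metadata_path),
                    transform = transform, pseudocount = pseudocount)
}

#' Write / read a gene-length annotation table
#'
#' @param x A [gene_annotation()].
#' @param path File path (columns `gene`, `length_bp`).
#' @return `read_annotation` returns a [gene_annotation()].
#' @export
write_annotation <- function(x, path) {
  write_tsv(x, path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  df <- read_tsv(path)
  gene_annotation(df$gene, df$length_bp)
}

#' Write / read a ligand-receptor pair list
#'
#' @param x An [lr_pair_table()].
#' @param path File path (columns `ligand`, `receptor`).
#' @return `read_lr_pairs` returns an [lr_pair_table()].
#' @export
write_lr_pairs <- function(x, path) {
  write_tsv(x[, c("ligand", "receptor")], path)
}

#' @rdname write_lr_pairs
#' @export
read_lr_pairs <- function(path) {
  df <- read_tsv(path)
  lr_pair_table(df$ligand, df$receptor)
}

#' Write / read a differential-expression table
#'
#' The file has columns `gene`, `log2FC`, `log2CPM`, `p`, `p_adj`,
#' `comparison`. External tables lacking `p_adj` get it computed with
#' [bh_adjust()] on read.
#'
#' @param x A [de_table()].
#' @param path File path.
#' @param comparison Comparison label when the file has no `comparison`
#'   column.
#' @return `read_de_table` returns a [de_table()].
#' @export
write_de_table <- function(x, path) {
  if (!inherits(x, "de_table")) stop("`x` must be a de_table", call. = FALSE)
  df <- as.data.frame(x)
  df$comparison <- attr(x, "comparison")
  write_tsv(df, path)
}

#' @rdname write_de_table
#' @export
read_de_table <- function(path, comparison = NULL) {
  df <- read_tsv(path)
  if (is.null(comparison)) {
    if (is.null(df$comparison)) {
      stop("file has no comparison column; pass `comparison`", call. = FALSE)
    }
    comparison <- unique(df$comparison)
  }
  df$comparison <- NULL
  de_table(df, comparison = comparison)
}

#' Write an UpSet decomposition
#'
#' Emits the exclusive classes (pattern, size, comma-separated genes) and,
#' when present, the named category summary.
#'
#' @param decomposition An [upset_decompose()] result.
#' @param classes_path Path for the classes table.
#' @param categories_path Optional path for the [category_summary()] table.
#' @return Paths written, invisibly.
#' @export
write_decomposition <- function(decomposition, classes_path,
                                categories_path = NULL) {
  classes <- data.frame(
    pattern = names(decomposition$classes),
    size = vapply(decomposition$classes, length, integer(1)),
    genes = vapply(decomposition$classes, paste, character(1), collapse = ","),
    row.names = NULL
  )
  classes <- classes[order(classes$pattern), , drop = FALSE]
  write_tsv(classes, classes_path)
  if (!is.null(categories_path)) {
    if (is.null(decomposition$categories)) {
      stop("decomposition has no categories; run label_categories()",
           call. = FALSE)
    }
    write_tsv(category_summary(decomposition), categories_path)
  }
  invisible(c(classes_path, categories_path))
}
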