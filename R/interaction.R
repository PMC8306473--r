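# The core computation: per-pair ligand(OPC)-receptor(microglia) interaction
# scores with a gene-role permutation null, evaluated in each OPC-group x
# microglia-condition context; plus the dot-plot export.

#' Build an interaction context
#'
#' One context pairs the log-expression matrix of the ligand-bearing OPC
#' samples of a single (genotype, condition) group with that of the
#' receptor-bearing microglia samples of a single condition.
#'
#' @param ligand_matrix,receptor_matrix Log-transformed
#'   [expression_matrix()] objects (log2CPM or logFPKM) sharing no samples,
#'   each with at least one sample.
#' @param ligand_label,receptor_label Context labels (e.g. `"WT-St"`,
#'   `"EAE"`).
#' @return An object of class `interaction_context`.
#' @export
interaction_context <- function(ligand_matrix, receptor_matrix,
                                ligand_label = "ligand",
                                receptor_label = "receptor") {
  for (m in list(ligand_matrix, receptor_matrix)) {
    if (!inherits(m, "expression_matrix")) {
      stop("context matrices must be expression_matrix objects", call. = FALSE)
    }
    if (!is_log_transform(m$transform)) {
      stop("context matrices must be log-transformed (log2CPM or logFPKM)",
           call. = FALSE)
    }
    if (ncol(m$values) < 1) {
      stop("context matrices need at least one sample", call. = FALSE)
    }
  }
  shared <- intersect(colnames(ligand_matrix$values),
                      colnames(receptor_matrix$values))
  if (length(shared)) {
    stop("ligand and receptor matrices share sample(s): ",
         paste(shared, collapse = ", "), call. = FALSE)
  }
  structure(list(ligand_matrix = ligand_matrix,
                 receptor_matrix = receptor_matrix,
                 ligand_label = ligand_label,
                 receptor_label = receptor_label,
                 label = paste(ligand_label, receptor_label, sep = "|")),
            class = "interaction_context")
}

#' Ligand-receptor interaction score
#'
#' The score of one pair in one context: the mean of the ligand gene's
#' average log expression (OPC side) and the receptor gene's average log
#' expression (microglia side),
#' `(mean(ligand_values) + mean(receptor_values)) / 2`.
#'
#' @param ligand_values,receptor_values Non-empty finite numeric vectors of
#'   per-sample log expression.
#' @return The score, a single number.
#' @export
#' @examples
#' pair_score(c(2, 2, 2), c(4, 4, 4, 4))  # 3
pair_score <- function(ligand_values, receptor_values) {
  if (length(ligand_values) == 0 || length(receptor_values) == 0) {
    stop("expression vectors must be non-empty", call. = FALSE)
  }
  if (any(!is.finite(ligand_values)) || any(!is.finite(receptor_values))) {
    stop("expression vectors must be finite", call. = FALSE)
  }
  (mean(ligand_values) + mean(receptor_values)) / 2
}

#' Expressed-gene universe of a context
#'
#' Genes present in both context matrices whose mean log expression exceeds
#' `floor` in the ligand matrix or in the receptor matrix (a gene only needs
#' to be expressed on the side of the role it can be drawn for).
#'
#' @param context An [interaction_context()].
#' @param floor Expression floor on the mean log value; default 0, i.e.
#'   above the pseudocount-adjusted zero of a `log2(x + 1)` transform.
#' @return Character vector of gene ids.
#' @export
expressed_universe <- function(context, floor = 0) {
  shared <- intersect(rownames(context$ligand_matrix$values),
                      rownames(context$receptor_matrix$values))
  lmean <- rowMeans(context$ligand_matrix$values[shared, , drop = FALSE])
  rmean <- rowMeans(context$receptor_matrix$values[shared, , drop = FALSE])
  shared[lmean > floor | rmean > floor]
}

# mean log expression of each universe gene on each side of a context
context_role_means <- function(context, universe) {
  list(ligand = rowMeans(context$ligand_matrix$values[universe, , drop = FALSE]),
       receptor = rowMeans(context$receptor_matrix$values[universe, , drop = FALSE]))
}

#' Permutation null and p-value for one ligand-receptor pair
#'
#' Null scores are obtained by randomizing the gene-role assignment: each
#' permutation draws a ligand-role gene and a receptor-role gene
#' independently and uniformly from the expressed universe and scores them
#' in the same context (the bulk adaptation of CellPhoneDB's permutation
#' test; with 3-4 samples per group, sample-label permutation has too few
#' arrangements). The one-sided p-value uses the add-one estimator
#' `p = (1 + #\{null >= observed\}) / (1 + n_perm)`, so `p > 0` always and
#' ties count as extreme.
#'
#' @param ligand,receptor Gene ids of the pair; the ligand is looked up in
#'   the context's ligand (OPC) matrix, the receptor in its receptor
#'   (microglia) matrix.
#' @param context An [interaction_context()].
#' @param universe Character vector of at least two expressed gene ids
#'   present in both matrices; defaults to [expressed_universe()].
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed making the draw deterministic.
#' @return List with `observed` (the pair's score), `p_value`,
#'   `null_scores` (length `n_perm`) and `n_perm`.
#' @export
permutation_null <- function(ligand, receptor, context,
                             universe = expressed_universe(context),
                             n_perm = 1000, seed = 1) {
  if (!inherits(context, "interaction_context")) {
    stop("`context` must be an interaction_context", call. = FALSE)
  }
  if (length(universe) < 2) {
    stop("universe must contain at least 2 genes", call. = FALSE)
  }
  if (n_perm < 1) stop("`n_perm` must be >= 1", call. = FALSE)
  missing_l <- !(ligand %in% rownames(context$ligand_matrix$values))
  missing_r <- !(receptor %in% rownames(context$receptor_matrix$values))
  if (missing_l || missing_r) {
    stop("pair gene(s) missing from context matrices: ",
         paste(c(ligand[missing_l], receptor[missing_r]), collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(universe, intersect(rownames(context$ligand_matrix$values),
                                     rownames(context$receptor_matrix$values)))
  if (length(bad)) {
    stop("universe gene(s) missing from context matrices: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  observed <- pair_score(context$ligand_matrix$values[ligand, ],
                         context$receptor_matrix$values[receptor, ])
  means <- context_role_means(context, universe)
  null_scores <- withr::with_seed(seed, {
    li <- sample.int(length(universe), n_perm, replace = TRUE)
    ri <- sample.int(length(universe), n_perm, replace = TRUE)
    (means$ligand[li] + means$receptor[ri]) / 2
  })
  names(null_scores) <- NULL
  p_value <- (1 + sum(null_scores >= observed)) / (1 + n_perm)
  list(observed = observed, p_value = p_value,
       null_scores = null_scores, n_perm = as.integer(n_perm))
}

#' Exhaustive gene-role null for small universes
#'
#' Enumerates all `|universe|^2` ligand-role x receptor-role assignments and
#' returns the exact one-sided tail probability of the observed score. The
#' independent reference for the sampled permutation p-value.
#'
#' @inheritParams permutation_null
#' @return List with `observed`, `p_exact` (proportion of assignments with
#'   score >= observed) and `null_scores` (all enumerated scores).
#' @export
exhaustive_null <- function(ligand, receptor, context,
                            universe = expressed_universe(context)) {
  if (length(universe) < 2) {
    stop("universe must contain at least 2 genes", call. = FALSE)
  }
  observed <- pair_score(context$ligand_matrix$values[ligand, ],
                         context$receptor_matrix$values[receptor, ])
  means <- context_role_means(context, universe)
  null_scores <- as.vector(outer(means$ligand, means$receptor, `+`) / 2)
  list(observed = observed,
       p_exact = mean(null_scores >= observed),
       null_scores = null_scores)
}

#' Default contexts from the sample metadata
#'
#' Crosses every (genotype, condition) OPC group found in `opc_expr` with
#' every microglia condition found in `mg_expr`.
#'
#' @param opc_expr,mg_expr Log-transformed [expression_matrix()] objects for
#'   the OPC and microglia samples.
#' @return Data frame with columns `genotype`, `condition`, `mg_condition`.
#' @export
default_contexts <- function(opc_expr, mg_expr) {
  og <- unique(opc_expr$samples[, c("genotype", "condition")])
  mg <- unique(mg_expr$samples$condition)
  out <- merge(og, data.frame(mg_condition = mg), by = NULL)
  out <- out[order(match(out$genotype, og$genotype),
                   match(out$condition, og$condition),
                   match(out$mg_condition, mg)), ]
  rownames(out) <- NULL
  out
}

#' Score every ligand-receptor pair in every context
#'
#' For each context (one OPC genotype x condition group against one
#' microglia condition), computes every pair's interaction score and a
#' gene-role permutation p-value. Within a context all pairs are compared
#' against one shared null ensemble drawn from the same expressed universe
#' with the same `n_perm`, so p-values are directly comparable across pairs
#' (the null distribution depends only on the universe and the context, not
#' on the pair's identity). Pairs whose ligand is absent from the OPC
#' matrix or whose receptor is absent from the microglia matrix are skipped
#' and reported in the `skipped` attribute.
#'
#' @param opc_expr,mg_expr Log-transformed [expression_matrix()] objects
#'   (same transform) holding the OPC and microglia samples.
#' @param pairs An [lr_pair_table()].
#' @param contexts Data frame with columns `genotype`, `condition`,
#'   `mg_condition`; defaults to all combinations present in the metadata.
#' @param n_perm Permutations per context.
#' @param seed Integer seed; context `i` uses `seed + i - 1`.
#' @param expressed_floor Floor for [expressed_universe()].
#' @param adjust If `TRUE`, add a BH-adjusted `p_adj` column across pairs
#'   within each context (off by default; the dot plot reads per-pair p).
#' @return A data.frame of class `interaction_table`, one row per (pair,
#'   context), sorted by context then descending score, with columns
#'   `context`, `pair`, `ligand`, `receptor`, `ligand_mean`,
#'   `receptor_mean`, `score`, `p_value`, `n_permutations`. Attribute
#'   `skipped` is a data.frame (ligand, receptor, reason).
#' @export
run_interaction_analysis <- function(opc_expr, mg_expr, pairs,
                                     contexts = NULL, n_perm = 1000,
                                     seed = 1, expressed_floor = 0,
                                     adjust = FALSE) {
  if (!inherits(pairs, "lr_pair_table") || nrow(pairs) == 0) {
    stop("`pairs` must be a non-empty lr_pair_table", call. = FALSE)
  }
  for (m in list(opc_expr, mg_expr)) {
    if (!inherits(m, "expression_matrix") || !is_log_transform(m$transform)) {
      stop("expression matrices must be log-transformed expression_matrix ",
           "objects", call. = FALSE)
    }
  }
  if (is.null(contexts)) contexts <- default_contexts(opc_expr, mg_expr)
  if (!all(c("genotype", "condition", "mg_condition") %in% names(contexts))) {
    stop("`contexts` needs columns genotype, condition, mg_condition",
         call. = FALSE)
  }
  usable <- pairs$ligand %in% rownames(opc_expr$values) &
    pairs$receptor %in% rownames(mg_expr$values)
  skipped <- data.frame(ligand = character(), receptor = character(),
                        reason = character())
  if (any(!usable)) {
    bad <- pairs[!usable, , drop = FALSE]
    reason <- ifelse(!(bad$ligand %in% rownames(opc_expr$values)),
                     "ligand absent from OPC matrix",
                     "receptor absent from microglia matrix")
    skipped <- data.frame(ligand = bad$ligand, receptor = bad$receptor,
                          reason = reason)
  }
  pairs <- pairs[usable, , drop = FALSE]
  if (nrow(pairs) == 0) {
    stop("no pair gene is shared with the expression matrices", call. = FALSE)
  }

  rows <- vector("list", nrow(contexts))
  for (i in seq_len(nrow(contexts))) {
    cx_spec <- contexts[i, ]
    opc_ids <- select_samples(opc_expr, genotype = cx_spec$genotype,
                              condition = cx_spec$condition)
    mg_ids <- select_samples(mg_expr, condition = cx_spec$mg_condition)
    if (length(opc_ids) == 0 || length(mg_ids) == 0) {
      stop("context has no samples: ", cx_spec$genotype, "-",
           cx_spec$condition, " x ", cx_spec$mg_condition, call. = FALSE)
    }
    cx <- interaction_context(
      subset_samples(opc_expr, opc_ids),
      subset_samples(mg_expr, mg_ids),
      ligand_label = paste(cx_spec$genotype, cx_spec$condition, sep = "-"),
      receptor_label = cx_spec$mg_condition
    )
    universe <- expressed_universe(cx, floor = expressed_floor)
    if (length(universe) < 2) {
      stop("expressed universe has fewer than 2 genes in context ",
           cx$label, call. = FALSE)
    }
    means <- context_role_means(cx, universe)
    ligand_mean <- rowMeans(cx$ligand_matrix$values[pairs$ligand, ,
                                                    drop = FALSE])
    receptor_mean <- rowMeans(cx$receptor_matrix$values[pairs$receptor, ,
                                                        drop = FALSE])
    score <- (ligand_mean + receptor_mean) / 2
    null_scores <- withr::with_seed(seed + i - 1, {
      li <- sample.int(length(universe), n_perm, replace = TRUE)
      ri <- sample.int(length(universe), n_perm, replace = TRUE)
      (means$ligand[li] + means$receptor[ri]) / 2
    })
    exceed <- vapply(score, function(s) sum(null_scores >= s), numeric(1))
    p_value <- (1 + exceed) / (1 + n_perm)
    df <- data.frame(context = cx$label, pair = pairs$pair,
                     ligand = pairs$ligand, receptor = pairs$receptor,
                     ligand_mean = unname(ligand_mean),
                     receptor_mean = unname(receptor_mean),
                     score = unname(score), p_value = unname(p_value),
                     n_permutations = as.integer(n_perm))
    if (adjust) df$p_adj <- bh_adjust(df$p_value)
    df <- df[order(-df$score, df$pair), ]
    rows[[i]] <- df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, skipped = skipped,
            class = c("interaction_table", "data.frame"))
}

#' Top-ranked pair per context
#'
#' @param table An `interaction_table`.
#' @return Data frame with the highest-scoring row of each context, in
#'   context order.
#' @export
top_interactions <- function(table) {
  if (!inherits(table, "interaction_table")) {
    stop("`table` must be an interaction_table", call. = FALSE)
  }
  first <- !duplicated(table$context)
  out <- as.data.frame(table)[first, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Dot-plot export of an interaction table
#'
#' One row per (context, pair) with the quantities a dot plot encodes:
#' `score` as the color value and `neg_log10_p = -log10(p_value)` as the
#' circle size, so a lower p-value draws a bigger circle.
#'
#' @param table A non-empty `interaction_table`.
#' @return Data frame with columns `context`, `pair`, `ligand`, `receptor`,
#'   `score`, `p_value`, `neg_log10_p`.
#' @export
export_dotplot_data <- function(table) {
  if (!inherits(table, "interaction_table") || nrow(table) == 0) {
    stop("`table` must be a non-empty interaction_table", call. = FALSE)
  }
  data.frame(context = table$context, pair = table$pair,
             ligand = table$ligand, receptor = table$receptor,
             score = table$score, p_value = table$p_value,
             neg_log10_p = -log10(table$p_value))
}
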