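# Shared fixture builders and independent oracles, all constructed in code.

mk_meta <- function(ids, cell_type = "OPC", genotype = "WT", condition = "NS") {
  data.frame(sample_id = ids, cell_type = cell_type, genotype = genotype,
             condition = condition)
}

mk_counts <- function(values, genes = NULL, ids = NULL, ...) {
  values <- as.matrix(values)
  if (is.null(genes)) genes <- sprintf("G%03d", seq_len(nrow(values)))
  if (is.null(ids)) ids <- sprintf("s%d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, ids)
  storage.mode(values) <- "integer"
  count_matrix(values, mk_meta(ids, ...))
}

mk_log_expr <- function(values, genes = NULL, ids = NULL, cell_type = "OPC",
                        genotype = "WT", condition = "NS",
                        transform = "logFPKM") {
  values <- as.matrix(values)
  if (is.null(genes)) genes <- sprintf("G%03d", seq_len(nrow(values)))
  if (is.null(ids)) ids <- sprintf("%s%d", substr(cell_type, 1, 1),
                                   seq_len(ncol(values)))
  dimnames(values) <- list(genes, ids)
  expression_matrix(values, mk_meta(ids, cell_type, genotype, condition),
                    transform = transform, pseudocount = 1)
}

# a context over shared gene ids: ligand side OPC samples, receptor side
# microglia samples
mk_context <- function(lvals, rvals, genes = NULL) {
  lvals <- as.matrix(lvals)
  rvals <- as.matrix(rvals)
  if (is.null(genes)) genes <- sprintf("G%03d", seq_len(nrow(lvals)))
  interaction_context(
    mk_log_expr(lvals, genes = genes, ids = sprintf("opc%d", seq_len(ncol(lvals))),
                cell_type = "OPC", condition = "St"),
    mk_log_expr(rvals, genes = genes, ids = sprintf("mg%d", seq_len(ncol(rvals))),
                cell_type = "microglia", condition = "naive"),
    ligand_label = "WT-St", receptor_label = "naive"
  )
}

# Benjamini-Hochberg step-up computed from the closed form:
# adj_(i) = min(1, min_{j >= i} p_(j) * m / j), mapped back to input order.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in rev(seq_len(m - 1))) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# per-gene membership-bitmask decomposition oracle
bitmask_classes <- function(sets) {
  nm <- names(sets)
  u <- unique(unlist(sets, use.names = FALSE))
  if (length(u) == 0) return(list())
  key <- vapply(u, function(g) {
    members <- nm[vapply(sets, function(s) g %in% s, logical(1))]
    paste(sort(members), collapse = "&")
  }, character(1))
  lapply(split(u, key), function(g) sort(unname(g)))
}

# sample ids of one OPC group / microglia condition
opc_group <- function(x, genotype, condition) {
  select_samples(x, cell_type = "OPC", genotype = genotype,
                 condition = condition)
}
mg_group <- function(x, condition) {
  select_samples(x, cell_type = "microglia", condition = condition)
}
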