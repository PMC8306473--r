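# End-to-end pipeline over synthetic data: simulate -> normalize ->
# DE test + filter -> UpSet decomposition -> ligand-receptor interaction
# scoring. Every stage's tables are written as TSV under `outdir`, and all
# randomness flows from the configuration seed, so two runs with the same
# configuration are byte-identical.

#' Run the full crosstalk pipeline on synthetic data
#'
#' @param outdir Output directory (created if needed).
#' @param config A [simulation_config()]; its seed drives every stage.
#' @param filter A [filter_spec()] applied to each comparison's DE table.
#' @param n_perm Permutations per interaction context.
#' @param pseudocount Pseudocount of the log-FPKM transform.
#' @param red_mode Passed to [label_categories()].
#' @return Invisibly, a list with the intermediate objects: `sim`,
#'   `log_fpkm`, `de_tables`, `gene_sets`, `upset_up`, `upset_down`,
#'   `interactions`, `dotplot`.
#' @export
run_pipeline <- function(outdir, config = simulation_config(),
                         filter = filter_spec(), n_perm = 1000,
                         pseudocount = 1, red_mode = "exclusive") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  path <- function(...) file.path(outdir, ...)

  sim <- simulate_dataset(config)
  write_counts(sim$counts, path("counts.tsv"), path("metadata.tsv"))
  write_annotation(sim$annotation, path("annotation.tsv"))
  write_lr_pairs(sim$pairs, path("lr_pairs.tsv"))
  write_tsv(sim$truth$de_genes, path("truth_de_genes.tsv"))
  write_tsv(sim$truth$active_pairs, path("truth_active_pairs.tsv"))

  fpkm <- compute_fpkm(sim$counts, sim$annotation)
  log_fpkm <- log_transform(fpkm, pseudocount = pseudocount)
  write_expression(log_fpkm, path("log_fpkm.tsv"), path("metadata.tsv"))

  groups <- list(
    "KO-NS_vs_WT-NS" = list(a = c("WT", "NS"), b = c("KO", "NS")),
    "WT-St_vs_WT-NS" = list(a = c("WT", "NS"), b = c("WT", "St")),
    "KO-St_vs_KO-NS" = list(a = c("KO", "NS"), b = c("KO", "St")),
    "KO-St_vs_WT-St" = list(a = c("WT", "St"), b = c("KO", "St"))
  )
  opc_ids <- select_samples(sim$counts, cell_type = "OPC")
  opc_counts <- subset_samples(sim$counts, opc_ids)
  de_tables <- lapply(names(groups), function(cmp) {
    g <- groups[[cmp]]
    tab <- simple_de_test(
      opc_counts,
      group_a = select_samples(opc_counts, genotype = g$a[1],
                               condition = g$a[2]),
      group_b = select_samples(opc_counts, genotype = g$b[1],
                               condition = g$b[2]),
      comparison = cmp
    )
    write_de_table(tab, path(paste0("de_", cmp, ".tsv")))
    tab
  })
  names(de_tables) <- names(groups)

  gene_sets <- lapply(de_tables, apply_filters, spec = filter)
  up_sets <- lapply(gene_sets, `[[`, "up")
  down_sets <- lapply(gene_sets, `[[`, "down")
  upset_up <- label_categories(upset_decompose(up_sets), red_mode = red_mode)
  upset_down <- label_categories(upset_decompose(down_sets),
                                 red_mode = red_mode)
  write_decomposition(upset_up, path("upset_up_classes.tsv"),
                      path("upset_up_categories.tsv"))
  write_decomposition(upset_down, path("upset_down_classes.tsv"),
                      path("upset_down_categories.tsv"))

  mg_ids <- select_samples(sim$counts, cell_type = "microglia")
  interactions <- run_interaction_analysis(
    subset_samples(log_fpkm, opc_ids),
    subset_samples(log_fpkm, mg_ids),
    sim$pairs, n_perm = n_perm, seed = config$seed
  )
  write_tsv(interactions, path("interactions.tsv"))
  dotplot <- export_dotplot_data(interactions)
  write_tsv(dotplot, path("dotplot.tsv"))

  invisible(list(sim = sim, log_fpkm = log_fpkm, de_tables = de_tables,
                 gene_sets = gene_sets, upset_up = upset_up,
                 upset_down = upset_down, interactions = interactions,
                 dotplot = dotplot))
}
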