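test_that("identical seeds give bit-identical outputs", {
  cfg <- simulation_config(n_genes = 300, n_de_up = 50, n_de_down = 40,
                           n_lr_pairs = 40, seed = 11)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$annotation, b$annotation)
  expect_identical(a$pairs, b$pairs)
  expect_identical(a$truth, b$truth)
  # component wrappers agree with the joint generator
  expect_identical(simulate_counts(cfg)$counts$counts, a$counts$counts)
  expect_identical(simulate_annotation(cfg), a$annotation)
  expect_identical(simulate_lr_reference(cfg)$pairs, a$pairs)
})

test_that("zero-effect configuration is a null world", {
  cfg <- simulation_config(n_genes = 1500, n_de_up = 0, n_de_down = 0,
                           n_active_pairs = 0, n_replicates = 4, seed = 3)
  sim <- simulate_dataset(cfg)
  expect_equal(nrow(sim$truth$de_genes), 0)
  expect_equal(nrow(sim$truth$active_pairs), 0)
  # realized group-mean log-ratio across genes centers on zero once the
  # per-sample depth factors are scaled out (composition is exactly 1 here)
  cm <- sim$counts
  scaled <- sweep(cm$counts, 2, colSums(cm$counts), "/")
  ns <- rowMeans(scaled[, opc_group(cm, "WT", "NS")])
  st <- rowMeans(scaled[, opc_group(cm, "WT", "St")])
  lfc <- log2(st) - log2(ns)
  expect_lt(abs(mean(lfc)), 3 * sd(lfc) / sqrt(length(lfc)) + 0.01)
})

test_that("planted fold change is recovered by group-mean ratio on counts", {
  # oracle: direct recomputation of group means from the emitted matrix
  cfg <- simulation_config(n_genes = 2000, de_log2fc = 2, dispersion = 10,
                           seed = 7)
  sim <- simulate_dataset(cfg)
  up <- unique(sim$truth$de_genes$gene[sim$truth$de_genes$direction == "up" &
                                         sim$truth$de_genes$comparison ==
                                           "WT-St_vs_WT-NS"])
  cm <- sim$counts
  ns <- rowMeans(cm$counts[, opc_group(cm, "WT", "NS")])
  st <- rowMeans(cm$counts[, opc_group(cm, "WT", "St")])
  est_all <- log2(st / ns)
  # the median over all genes absorbs the shared library-depth term
  est <- est_all[up] - median(est_all)
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 2), 3 * se)

  # same recovery at n_replicates = 4 for the down direction
  cfg4 <- simulation_config(n_genes = 1000, n_de_up = 150, n_de_down = 150,
                            n_replicates = 4, seed = 8)
  sim4 <- simulate_dataset(cfg4)
  down <- unique(sim4$truth$de_genes$gene[sim4$truth$de_genes$direction ==
                                            "down"])
  cm4 <- sim4$counts
  ns4 <- rowMeans(cm4$counts[, opc_group(cm4, "KO", "NS")])
  st4 <- rowMeans(cm4$counts[, opc_group(cm4, "KO", "St")])
  est_all4 <- log2((st4 + 0.25) / (ns4 + 0.25))
  est4 <- est_all4[down] - median(est_all4)
  expect_lt(abs(mean(est4) + 2), 3 * sd(est4) / sqrt(length(est4)))
})

test_that("annotation lengths respect the configured range", {
  cfg <- simulation_config(n_genes = 500, n_de_up = 60, n_de_down = 60,
                           gene_length_range = c(1000, 1000), seed = 2)
  ann <- simulate_annotation(cfg)
  expect_true(all(ann$length_bp == 1000))

  cfg2 <- simulation_config(n_genes = 500, n_de_up = 60, n_de_down = 60,
                            gene_length_range = c(200, 900), seed = 2)
  ann2 <- simulate_annotation(cfg2)
  expect_equal(nrow(ann2), 500)
  expect_true(all(ann2$length_bp >= 200 & ann2$length_bp <= 900))
  expect_identical(simulate_annotation(cfg2), ann2)
})

test_that("pair list is unique, covers planted pairs, honours sizes", {
  cfg <- simulation_config(n_genes = 400, n_de_up = 60, n_de_down = 40,
                           n_lr_pairs = 80, n_active_pairs = 5, seed = 9)
  ref <- simulate_lr_reference(cfg)
  expect_equal(nrow(ref$pairs), 80)
  key <- paste(ref$pairs$ligand, ref$pairs$receptor)
  expect_equal(anyDuplicated(key), 0L)
  active_key <- paste(ref$truth$active_pairs$ligand,
                      ref$truth$active_pairs$receptor)
  expect_true(all(active_key %in% key))
  expect_equal(nrow(ref$truth$active_pairs) + nrow(ref$truth$null_pairs), 80)

  empty <- simulate_lr_reference(
    simulation_config(n_genes = 100, n_de_up = 10, n_de_down = 10,
                      n_lr_pairs = 0, n_active_pairs = 0, seed = 1))
  expect_equal(nrow(empty$pairs), 0)
})

test_that("planted structure sits in the right cells and conditions", {
  cfg <- simulation_config(n_genes = 800, n_de_up = 100, n_de_down = 100,
                           n_active_pairs = 2, n_replicates = 4, seed = 5)
  sim <- simulate_dataset(cfg)
  cm <- sim$counts
  rec <- sim$truth$active_pairs$receptor
  lig <- sim$truth$active_pairs$ligand
  # receptors high in microglia, higher at EAE, baseline in OPCs
  naive <- rowMeans(cm$counts[rec, mg_group(cm, "naive"), drop = FALSE])
  eae <- rowMeans(cm$counts[rec, mg_group(cm, "EAE"), drop = FALSE])
  opc <- rowMeans(cm$counts[rec, opc_group(cm, "WT", "NS"), drop = FALSE])
  expect_true(all(naive > 3 * opc))
  expect_true(all(eae > 2 * naive))
  # ligands up in stimulated OPCs of both genotypes
  for (g in c("WT", "KO")) {
    ns <- rowMeans(cm$counts[lig, opc_group(cm, g, "NS"), drop = FALSE])
    st <- rowMeans(cm$counts[lig, opc_group(cm, g, "St"), drop = FALSE])
    expect_true(all(st > 2 * ns))
  }
})

test_that("alias option renames planted pairs to familiar gene symbols", {
  cfg <- simulation_config(n_genes = 300, n_de_up = 40, n_de_down = 30,
                           n_active_pairs = 3, alias_planted = TRUE, seed = 4)
  sim <- simulate_dataset(cfg)
  expect_setequal(sim$truth$active_pairs$ligand, c("Ccl2", "Csf1", "Cx3cl1"))
  expect_setequal(sim$truth$active_pairs$receptor,
                  c("Ccr5", "Csf1r", "Cx3cr1"))
  expect_true(all(sim$truth$active_pairs$ligand %in%
                    rownames(sim$counts$counts)))
  expect_true(all(sim$truth$active_pairs$receptor %in% sim$annotation$gene))
})

test_that("invalid configuration fields are rejected by name", {
  expect_error(simulation_config(baseline_mean = -1), "baseline_mean")
  expect_error(simulation_config(dispersion = 0), "dispersion")
  expect_error(simulation_config(n_genes = 0), "n_genes")
  expect_error(simulation_config(de_log2fc = -2), "de_log2fc")
  expect_error(simulation_config(gene_length_range = c(500, 100)),
               "gene_length_range")
  expect_error(simulation_config(n_lr_pairs = 5, n_active_pairs = 6),
               "n_active_pairs")
  expect_error(simulation_config(n_genes = 100, n_de_up = 80, n_de_down = 30),
               "n_de")
})
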