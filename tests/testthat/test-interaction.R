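test_that("pair score closed forms and validation", {
  expect_equal(pair_score(c(2, 2, 2), c(4, 4, 4, 4)), 3)
  expect_equal(pair_score(rep(7, 3), rep(7, 5)), 7)     # symmetry
  expect_error(pair_score(numeric(), 1), "non-empty")
  expect_error(pair_score(c(1, NA), 1), "finite")
  set.seed(41)
  for (i in 1:50) {
    l <- rnorm(sample(1:6, 1))
    r <- rnorm(sample(1:6, 1))
    expect_equal(pair_score(l, r), (mean(l) + mean(r)) / 2,
                 tolerance = 1e-12)
  }
})

test_that("permutation p-value floor, ties and determinism", {
  # observed score strictly above every null score -> add-one floor
  lv <- matrix(c(rep(1, 9), 10, 10, 10), 4, 3, byrow = TRUE)
  rv <- matrix(c(rep(1, 9), 10, 10, 10), 4, 3, byrow = TRUE)
  cx <- mk_context(lv, rv)
  res <- permutation_null("G004", "G004", cx,
                          universe = sprintf("G%03d", 1:3),
                          n_perm = 200, seed = 2)
  expect_equal(res$p_value, 1 / 201)

  # constant universe: every null equals the observed -> p = 1
  cv <- matrix(3, 5, 3)
  cxc <- mk_context(cv, cv)
  resc <- permutation_null("G001", "G002", cxc, n_perm = 100, seed = 3)
  expect_equal(resc$p_value, 1)

  # determinism under a fixed seed
  set.seed(43)
  lv2 <- matrix(rnorm(24, 5), 8, 3)
  rv2 <- matrix(rnorm(24, 5), 8, 3)
  cx2 <- mk_context(lv2, rv2)
  a <- permutation_null("G002", "G005", cx2, n_perm = 500, seed = 9)
  b <- permutation_null("G002", "G005", cx2, n_perm = 500, seed = 9)
  expect_identical(a, b)
  expect_error(permutation_null("G001", "G002", cx2,
                                universe = "G001"), "at least 2")
})

test_that("sampled p-values converge to exhaustive enumeration", {
  set.seed(47)
  lv <- matrix(rnorm(15, 6, 2), 5, 3)
  rv <- matrix(rnorm(20, 6, 2), 5, 4)
  cx <- mk_context(lv, rv)
  u <- rownames(cx$ligand_matrix$values)
  for (pair in list(c(1, 1), c(2, 4), c(5, 3))) {
    ex <- exhaustive_null(u[pair[1]], u[pair[2]], cx, universe = u)
    expect_length(ex$null_scores, 25)  # all 5x5 role assignments
    mc <- permutation_null(u[pair[1]], u[pair[2]], cx, universe = u,
                           n_perm = 10000, seed = 51)
    se <- sqrt(ex$p_exact * (1 - ex$p_exact) / 10000)
    expect_lt(abs(mc$p_value - ex$p_exact), 3 * se + 2 / 10001)
  }
})

test_that("scores are translation-equivariant and p-values invariant", {
  set.seed(53)
  cfg <- simulation_config(n_genes = 150, n_de_up = 20, n_de_down = 20,
                           n_lr_pairs = 30, seed = 6)
  sim <- simulate_dataset(cfg)
  lf <- log_transform(compute_fpkm(sim$counts, sim$annotation))
  opc <- subset_samples(lf, select_samples(lf, cell_type = "OPC"))
  mg <- subset_samples(lf, select_samples(lf, cell_type = "microglia"))
  ctx <- data.frame(genotype = "WT", condition = "St", mg_condition = "EAE")
  r1 <- run_interaction_analysis(opc, mg, sim$pairs, contexts = ctx,
                                 n_perm = 300, seed = 5)
  shift <- function(x, c) {
    expression_matrix(x$values + c, x$samples, transform = x$transform,
                      pseudocount = x$pseudocount)
  }
  r2 <- run_interaction_analysis(shift(opc, 2.5), shift(mg, 2.5), sim$pairs,
                                 contexts = ctx, n_perm = 300, seed = 5)
  expect_equal(r2$score, r1$score + 2.5, tolerance = 1e-12)
  expect_identical(r2$p_value, r1$p_value)
  expect_identical(r2$pair, r1$pair)
})

test_that("full analysis composes pair_score, sorts, and is deterministic", {
  set.seed(59)
  lv <- matrix(rnorm(30, 8), 10, 3)
  rv <- matrix(rnorm(30, 8), 10, 3)
  genes <- sprintf("G%03d", 1:10)
  opc <- mk_log_expr(lv, genes = genes, ids = sprintf("o%d", 1:3),
                     cell_type = "OPC", genotype = "WT", condition = "St")
  mg <- mk_log_expr(rv, genes = genes, ids = sprintf("m%d", 1:3),
                    cell_type = "microglia", genotype = "WT",
                    condition = "naive")
  pairs1 <- lr_pair_table("G002", "G007")
  res <- run_interaction_analysis(opc, mg, pairs1, n_perm = 100, seed = 1)
  expect_equal(nrow(res), 1)
  expect_equal(res$score, pair_score(lv[2, ], rv[7, ]), tolerance = 1e-12)
  expect_equal(res$score, (res$ligand_mean + res$receptor_mean) / 2)

  pairs <- lr_pair_table(genes[1:5], genes[6:10])
  r1 <- run_interaction_analysis(opc, mg, pairs, n_perm = 200, seed = 4)
  r2 <- run_interaction_analysis(opc, mg, pairs, n_perm = 200, seed = 4)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  # sorted by descending score within context
  expect_true(all(diff(r1$score) <= 0))
  expect_true(all(r1$p_value > 0 & r1$p_value <= 1))
})

test_that("pairs with absent genes are skipped with a reason", {
  set.seed(61)
  genes <- sprintf("G%03d", 1:6)
  opc <- mk_log_expr(matrix(rnorm(18, 8), 6, 3), genes = genes,
                     ids = sprintf("o%d", 1:3), cell_type = "OPC",
                     condition = "St")
  mg <- mk_log_expr(matrix(rnorm(18, 8), 6, 3), genes = genes,
                    ids = sprintf("m%d", 1:3), cell_type = "microglia",
                    condition = "naive")
  pairs <- lr_pair_table(c("G001", "MISSING", "G002"),
                         c("G004", "G005", "GONE"))
  res <- run_interaction_analysis(opc, mg, pairs, n_perm = 50, seed = 1)
  expect_equal(nrow(res), 1)
  skipped <- attr(res, "skipped")
  expect_equal(nrow(skipped), 2)
  expect_true(any(grepl("ligand absent", skipped$reason)))
  expect_true(any(grepl("receptor absent", skipped$reason)))
  # nothing usable at all -> error
  none <- lr_pair_table("NOPE", "NADA")
  expect_error(run_interaction_analysis(opc, mg, none, n_perm = 10, seed = 1),
               "no pair gene")
})

test_that("context construction enforces its invariants", {
  lv <- mk_log_expr(matrix(1:6, 2, 3), ids = c("a", "b", "c"))
  rv <- mk_log_expr(matrix(1:6, 2, 3), ids = c("c", "d", "e"),
                    cell_type = "microglia")
  expect_error(interaction_context(lv, rv), "share sample")
  lin <- expression_matrix(lv$values, lv$samples, transform = "FPKM")
  rv2 <- mk_log_expr(matrix(1:6, 2, 3), ids = c("d", "e", "f"),
                     cell_type = "microglia")
  expect_error(interaction_context(lin, rv2), "log-transformed")
})

test_that("dot-plot export encodes p as circle size and round-trips", {
  set.seed(67)
  cfg <- simulation_config(n_genes = 120, n_de_up = 15, n_de_down = 15,
                           n_lr_pairs = 15, seed = 8)
  sim <- simulate_dataset(cfg)
  lf <- log_transform(compute_fpkm(sim$counts, sim$annotation))
  opc <- subset_samples(lf, select_samples(lf, cell_type = "OPC"))
  mg <- subset_samples(lf, select_samples(lf, cell_type = "microglia"))
  res <- run_interaction_analysis(opc, mg, sim$pairs, n_perm = 99, seed = 3)
  dp <- export_dotplot_data(res)
  expect_equal(dp$neg_log10_p, -log10(res$p_value))
  # p = 0.1 -> size 1; smaller p -> strictly larger circle
  expect_equal(-log10(0.1), 1)
  o <- order(dp$p_value)
  expect_true(all(diff(dp$neg_log10_p[o]) <= 0))

  tmp <- tempfile(fileext = ".tsv")
  write_tsv(dp, tmp)
  back <- read_tsv(tmp)
  expect_identical(back$score, dp$score)
  expect_identical(back$p_value, dp$p_value)
  expect_identical(back$neg_log10_p, dp$neg_log10_p)
})
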