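# Synthetic-data generator emulating the study design: OPC samples over
# genotype {WT, KO} x condition {NS, St}, microglia samples over condition
# {naive, EAE}, negative-binomial counts with planted stimulation-responsive
# genes and planted ligand/receptor structure, plus ground-truth tables.

#' Simulation configuration
#'
#' Parameters of the synthetic bulk RNA-seq experiment. Counts are negative
#' binomial with a common baseline mean per gene and per-sample log-normal
#' library-size factors; differential expression is planted as a
#' multiplicative shift of the group mean.
#'
#' @param n_genes Number of simulated genes.
#' @param n_replicates Biological replicates per cell type/condition group
#'   (the study design uses 3-4).
#' @param baseline_mean Negative-binomial mean of a typical gene.
#' @param dispersion Negative-binomial size parameter (larger = less
#'   overdispersed).
#' @param n_de_up,n_de_down Number of genes planted up-/down-regulated in
#'   stimulated OPCs (both genotypes).
#' @param de_log2fc Planted log2 fold change (positive; applied with sign by
#'   direction). Also used as the EAE up-shift of planted receptor genes in
#'   microglia.
#' @param n_lr_pairs Number of ligand-receptor pair-list rows to emit.
#' @param n_active_pairs Number of pairs planted as interacting: ligand
#'   up-regulated in stimulated OPCs, receptor constitutively high in
#'   microglia and further up-shifted at EAE.
#' @param gene_length_range Length-two integer vector, min and max transcript
#'   length in bp for the FPKM annotation.
#' @param library_size_sdlog Standard deviation (log scale) of the per-sample
#'   library-size factors, drawn log-normal with log-mean 0.
#' @param receptor_log2_expr Constitutive log2 elevation of planted receptor
#'   genes in microglia above `baseline_mean` (chemokine/fractalkine
#'   receptors sit well above a typical transcript in microglia).
#' @param alias_planted If `TRUE`, rename up to three planted pairs to the
#'   familiar mouse gene names Ccl2/Ccr5, Csf1/Csf1r, Cx3cl1/Cx3cr1 for
#'   readable fixtures.
#' @param seed Integer seed; identical seeds give bit-identical outputs.
#' @return An object of class `simulation_config` (validated list).
#' @export
#' @examples
#' cfg <- simulation_config(n_genes = 500, seed = 7)
simulation_config <- function(n_genes = 2000,
                              n_replicates = 3,
                              baseline_mean = 100,
                              dispersion = 10,
                              n_de_up = 400,
                              n_de_down = 300,
                              de_log2fc = 2,
                              n_lr_pairs = 200,
                              n_active_pairs = 3,
                              gene_length_range = c(500L, 5000L),
                              library_size_sdlog = 0.1,
                              receptor_log2_expr = 3,
                              alias_planted = FALSE,
                              seed = 1L) {
  chk_count <- function(x, field, min = 0) {
    if (length(x) != 1 || !is.numeric(x) || is.na(x) || x != round(x) || x < min) {
      stop(sprintf("invalid `%s`: must be an integer >= %d", field, min),
           call. = FALSE)
    }
    as.integer(x)
  }
  chk_pos <- function(x, field) {
    if (length(x) != 1 || !is.numeric(x) || is.na(x) || x <= 0) {
      stop(sprintf("invalid `%s`: must be a positive number", field),
           call. = FALSE)
    }
    as.numeric(x)
  }
  cfg <- list(
    n_genes = chk_count(n_genes, "n_genes", min = 1),
    n_replicates = chk_count(n_replicates, "n_replicates", min = 1),
    baseline_mean = chk_pos(baseline_mean, "baseline_mean"),
    dispersion = chk_pos(dispersion, "dispersion"),
    n_de_up = chk_count(n_de_up, "n_de_up"),
    n_de_down = chk_count(n_de_down, "n_de_down"),
    de_log2fc = chk_pos(de_log2fc, "de_log2fc"),
    n_lr_pairs = chk_count(n_lr_pairs, "n_lr_pairs"),
    n_active_pairs = chk_count(n_active_pairs, "n_active_pairs"),
    library_size_sdlog = {
      if (length(library_size_sdlog) != 1 || !is.numeric(library_size_sdlog) ||
          is.na(library_size_sdlog) || library_size_sdlog < 0) {
        stop("invalid `library_size_sdlog`: must be >= 0", call. = FALSE)
      }
      as.numeric(library_size_sdlog)
    },
    receptor_log2_expr = chk_pos(receptor_log2_expr, "receptor_log2_expr"),
    alias_planted = isTRUE(alias_planted),
    seed = chk_count(seed, "seed", min = -.Machine$integer.max)
  )
  if (length(gene_length_range) != 2 || !is.numeric(gene_length_range) ||
      any(is.na(gene_length_range)) ||
      any(gene_length_range != round(gene_length_range)) ||
      any(gene_length_range < 1) ||
      gene_length_range[1] > gene_length_range[2]) {
    stop("invalid `gene_length_range`: must be two integers 1 <= min <= max",
         call. = FALSE)
  }
  cfg$gene_length_range <- as.integer(gene_length_range)
  if (cfg$n_active_pairs > cfg$n_lr_pairs) {
    stop("invalid `n_active_pairs`: exceeds `n_lr_pairs`", call. = FALSE)
  }
  if (cfg$n_de_up + cfg$n_de_down > cfg$n_genes) {
    stop("invalid `n_de_up`/`n_de_down`: planted genes exceed `n_genes`",
         call. = FALSE)
  }
  if (cfg$n_active_pairs > cfg$n_de_up) {
    stop("invalid `n_active_pairs`: needs `n_de_up` >= `n_active_pairs` ",
         "(ligands are planted among the up-regulated genes)", call. = FALSE)
  }
  if (cfg$n_genes - cfg$n_de_up - cfg$n_de_down < cfg$n_active_pairs) {
    stop("invalid `n_active_pairs`: not enough non-DE genes left for planted ",
         "receptors", call. = FALSE)
  }
  structure(cfg, class = "simulation_config")
}

# Paper-name aliases for readable fixtures.
.lr_aliases <- list(ligand = c("Ccl2", "Csf1", "Cx3cl1"),
                    receptor = c("Ccr5", "Csf1r", "Cx3cr1"))

# Full deterministic generation pass; every public simulate_* wraps this so
# that gene roles stay consistent across counts, annotation and pair list.
simulate_dataset_impl <- function(cfg) {
  genes <- sprintf("G%06d", seq_len(cfg$n_genes))

  length_pool <- seq(cfg$gene_length_range[1], cfg$gene_length_range[2])
  lengths <- length_pool[sample.int(length(length_pool), cfg$n_genes,
                                    replace = TRUE)]

  de_up <- sample(genes, cfg$n_de_up)
  de_down <- sample(setdiff(genes, de_up), cfg$n_de_down)
  ligands <- de_up[seq_len(cfg$n_active_pairs)]
  receptors <- sample(setdiff(genes, c(de_up, de_down)), cfg$n_active_pairs)

  if (cfg$alias_planted && cfg$n_active_pairs > 0) {
    k <- min(cfg$n_active_pairs, length(.lr_aliases$ligand))
    relabel <- function(ids, from, to) {
      ids[match(from, ids)] <- to
      ids
    }
    genes <- relabel(genes, ligands[seq_len(k)], .lr_aliases$ligand[seq_len(k)])
    genes <- relabel(genes, receptors[seq_len(k)],
                     .lr_aliases$receptor[seq_len(k)])
    de_up[seq_len(k)] <- .lr_aliases$ligand[seq_len(k)]
    ligands[seq_len(k)] <- .lr_aliases$ligand[seq_len(k)]
    receptors[seq_len(k)] <- .lr_aliases$receptor[seq_len(k)]
  }

  opc_groups <- expand.grid(condition = c("NS", "St"),
                            genotype = c("WT", "KO"),
                            KEEP.OUT.ATTRS = FALSE,
                            stringsAsFactors = FALSE)[, c("genotype", "condition")]
  meta <- do.call(rbind, c(
    lapply(seq_len(nrow(opc_groups)), function(i) {
      g <- opc_groups$genotype[i]
      cn <- opc_groups$condition[i]
      data.frame(sample_id = sprintf("OPC_%s_%s_%d", g, cn,
                                     seq_len(cfg$n_replicates)),
                 cell_type = "OPC", genotype = g, condition = cn)
    }),
    lapply(c("naive", "EAE"), function(cn) {
      data.frame(sample_id = sprintf("MG_%s_%d", cn, seq_len(cfg$n_replicates)),
                 cell_type = "microglia", genotype = "WT", condition = cn)
    })
  ))

  n_samples <- nrow(meta)
  mu <- matrix(cfg$baseline_mean, cfg$n_genes, n_samples,
               dimnames = list(genes, meta$sample_id))
  opc_st <- meta$cell_type == "OPC" & meta$condition == "St"
  mg <- meta$cell_type == "microglia"
  mg_eae <- mg & meta$condition == "EAE"
  mu[de_up, opc_st] <- mu[de_up, opc_st] * 2^cfg$de_log2fc
  mu[de_down, opc_st] <- mu[de_down, opc_st] * 2^(-cfg$de_log2fc)
  mu[receptors, mg] <- mu[receptors, mg] * 2^cfg$receptor_log2_expr
  mu[receptors, mg_eae] <- mu[receptors, mg_eae] * 2^cfg$de_log2fc

  size_factors <- exp(rnorm(n_samples, 0, cfg$library_size_sdlog))
  mu_scaled <- sweep(mu, 2, size_factors, `*`)
  counts <- matrix(rnbinom(length(mu_scaled), mu = mu_scaled,
                           size = cfg$dispersion),
                   nrow = cfg$n_genes, dimnames = dimnames(mu))

  # pair list: planted pairs first, then unique random fillers
  active <- data.frame(ligand = ligands, receptor = receptors)
  n_null <- cfg$n_lr_pairs - cfg$n_active_pairs
  null_l <- character(0)
  null_r <- character(0)
  taken <- paste(active$ligand, active$receptor, sep = "\r")
  while (length(null_l) < n_null) {
    need <- n_null - length(null_l)
    cand_l <- sample(genes, 2 * need + 10, replace = TRUE)
    cand_r <- sample(genes, 2 * need + 10, replace = TRUE)
    key <- paste(cand_l, cand_r, sep = "\r")
    keep <- !duplicated(key) & !(key %in% taken)
    cand_l <- cand_l[keep]
    cand_r <- cand_r[keep]
    take <- seq_len(min(need, length(cand_l)))
    null_l <- c(null_l, cand_l[take])
    null_r <- c(null_r, cand_r[take])
    taken <- c(taken, paste(cand_l[take], cand_r[take], sep = "\r"))
  }
  pairs <- lr_pair_table(c(active$ligand, null_l), c(active$receptor, null_r))

  stim_comparisons <- c("WT-St_vs_WT-NS", "KO-St_vs_KO-NS")
  de_genes <- do.call(rbind, lapply(stim_comparisons, function(cmp) {
    rbind(
      if (length(de_up)) data.frame(gene = de_up, direction = "up",
                                    log2fc = cfg$de_log2fc, comparison = cmp),
      if (length(de_down)) data.frame(gene = de_down, direction = "down",
                                      log2fc = -cfg$de_log2fc, comparison = cmp)
    )
  }))
  if (length(receptors)) {
    de_genes <- rbind(de_genes,
                      data.frame(gene = receptors, direction = "up",
                                 log2fc = cfg$de_log2fc,
                                 comparison = "MG-EAE_vs_MG-naive"))
  }
  if (is.null(de_genes)) {
    de_genes <- data.frame(gene = character(), direction = character(),
                           log2fc = numeric(), comparison = character())
  }
  null_pairs <- data.frame(ligand = null_l, receptor = null_r)
  truth <- structure(list(de_genes = de_genes, active_pairs = active,
                          null_pairs = null_pairs),
                     class = "ground_truth")

  list(counts = count_matrix(counts, meta),
       annotation = gene_annotation(genes, lengths),
       pairs = pairs,
       truth = truth)
}

#' Simulate the full synthetic dataset
#'
#' Generates counts, gene-length annotation, the ligand-receptor pair list
#' and the ground-truth tables in one deterministic pass, so that planted
#' gene roles (DE genes, active ligands/receptors) are consistent across all
#' outputs.
#'
#' @param config A [simulation_config()].
#' @return List with elements `counts` ([count_matrix()]), `annotation`
#'   ([gene_annotation()]), `pairs` ([lr_pair_table()]) and `truth`
#'   (class `ground_truth`: data.frames `de_genes`, `active_pairs`,
#'   `null_pairs`).
#' @export
#' @examples
#' sim <- simulate_dataset(simulation_config(n_genes = 200, seed = 1))
#' dim(sim$counts)
simulate_dataset <- function(config) {
  if (!inherits(config, "simulation_config")) {
    stop("`config` must be a simulation_config", call. = FALSE)
  }
  withr::with_seed(config$seed, simulate_dataset_impl(config))
}

#' Simulate the count matrix and its ground truth
#'
#' @inheritParams simulate_dataset
#' @return List with elements `counts` and `truth`; see [simulate_dataset()].
#' @export
simulate_counts <- function(config) {
  sim <- simulate_dataset(config)
  sim[c("counts", "truth")]
}

#' Simulate the gene-length annotation
#'
#' @inheritParams simulate_dataset
#' @return A [gene_annotation()] with one length per simulated gene, uniform
#'   on the configured range.
#' @export
simulate_annotation <- function(config) {
  simulate_dataset(config)$annotation
}

#' Simulate the ligand-receptor reference pair list
#'
#' @inheritParams simulate_dataset
#' @return List with elements `pairs` and `truth`; planted active pairs
#'   reference genes that are up-regulated in stimulated OPCs (ligand side)
#'   and constitutively expressed in microglia (receptor side).
#' @export
simulate_lr_reference <- function(config) {
  sim <- simulate_dataset(config)
  sim[c("pairs", "truth")]
}
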