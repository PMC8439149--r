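#' Parameter-recovery experiment
#'
#' Simulates a pooled experiment under the default study conditions,
#' quantifies relative potential from the simulated count tables, and
#' reports the Spearman correlation between true and estimated log10
#' potential over (line, organ) pairs whose true potential lies above a
#' detection floor.
#'
#' @param seed master seed.
#' @param config a [sim_config()]; the seed is overridden by `seed`.
#' @param truth_floor true log10 potential above which a pair enters the
#'   correlation (default -3; below it, sub-cell outgrowth is unmeasurable
#'   at realistic depth).
#' @param floor estimate floor passed to the log transform.
#' @return list with `spearman`, `n_pairs`, and the `potential_table`.
#' @export
recovery_experiment <- function(seed = 1L, config = sim_config(),
                                truth_floor = -3, floor = 1e-4) {
  config$seed <- as.integer(seed)
  sim <- simulate_experiment(config)
  pt <- suppressWarnings(relative_potential(sim$counts, B = 10,
                                            seed = derive_seed(seed, "rec")))
  tp <- sim$truth$true_log10_potential
  est <- log10(pmax(pt$potential[rownames(tp), colnames(tp)], floor))
  above <- tp > truth_floor & !is.na(est)
  list(spearman = stats::cor(tp[above], est[above], method = "spearman"),
       n_pairs = sum(above), potential = pt, sim = sim)
}

#' Split-design concordance experiment
#'
#' Simulates the same ground truth under two pooling designs — one large
#' pool of all lines at few cells per line, and several sub-pools of 25
#' lines at proportionally more cells per line, each injected into its
#' own cohort — then compares the per-line overall potential estimates
#' from the two designs by Pearson correlation. This is the in-silico
#' analogue of profiling a 500-line pool and re-profiling the same lines
#' as 25-line pools.
#'
#' @param seed master seed.
#' @param n_lines total lines (multiple of `pool_size`).
#' @param pool_size lines per sub-pool (default 25).
#' @param cells_big cells per line in the big-pool design (default 500).
#' @param n_mice mice per organ cohort.
#' @param read_depth reads per sample.
#' @param floor estimate floor applied before the log.
#' @return list with `pearson` (Pearson r between the two designs' floored
#'   log10 relative potentials over all (line, organ) pairs),
#'   `pearson_overall` (r between per-line overall potentials),
#'   `log_potential_big`, `log_potential_split`, `truth`.
#' @export
split_design_experiment <- function(seed = 1L, n_lines = 125L,
                                    pool_size = 25L, cells_big = 500L,
                                    n_mice = 5L, read_depth = 1e6,
                                    floor = 1e-4) {
  stopifnot(n_lines %% pool_size == 0L)
  n_pools <- n_lines %/% pool_size
  organs <- c("brain", "lung", "liver", "kidney", "bone")
  tp <- with_seed(derive_seed(seed, "truth"), {
    matrix(stats::runif(n_lines * length(organs), -4, 1), n_lines,
           dimnames = list(sprintf("line%03d", seq_len(n_lines)), organs))
  })
  pen <- stats::plogis(1.5 * (tp + 1.5))
  estimate <- function(cfg) {
    sim <- simulate_experiment(cfg)
    pt <- suppressWarnings(relative_potential(sim$counts, B = 10,
                                              seed = cfg$seed))
    lp <- log10(pmax(pt$potential, floor))
    # simulator names lines within each run; map back by position
    rownames(lp) <- rownames(cfg$true_log10_potential)
    lp
  }
  big <- estimate(sim_config(n_lines = n_lines, organs = organs,
                             n_mice = n_mice, cells_per_line = cells_big,
                             true_log10_potential = tp, penetrance_prob = pen,
                             read_depth = read_depth,
                             seed = derive_seed(seed, "big")))
  split <- do.call(rbind, lapply(seq_len(n_pools), function(k) {
    rows <- ((k - 1L) * pool_size + 1L):(k * pool_size)
    estimate(sim_config(n_lines = pool_size, organs = organs,
                        n_mice = n_mice,
                        cells_per_line = cells_big * n_pools,
                        true_log10_potential = tp[rows, , drop = FALSE],
                        penetrance_prob = pen[rows, , drop = FALSE],
                        read_depth = read_depth,
                        seed = derive_seed(seed, paste0("pool", k))))
  }))
  split <- split[rownames(big), , drop = FALSE]
  list(pearson = stats::cor(as.vector(big), as.vector(split),
                            use = "complete.obs"),
       pearson_overall = stats::cor(rowMeans(big, na.rm = TRUE),
                                    rowMeans(split, na.rm = TRUE),
                                    use = "complete.obs"),
       log_potential_big = big, log_potential_split = split,
       truth = list(true_log10_potential = tp, penetrance_prob = pen))
}

#' Bootstrap coverage experiment
#'
#' Repeatedly draws lognormal per-mouse values, computes the nominal-level
#' percentile bootstrap interval for the mean, and reports the fraction of
#' replicates whose interval covers the true mean.
#'
#' @param seed master seed.
#' @param n_sim replicates (default 200).
#' @param n mice per replicate (default 10).
#' @param B bootstrap resamples.
#' @param level nominal level.
#' @param sdlog lognormal dispersion of the per-mouse values.
#' @return list with `coverage`, `n_sim`.
#' @export
coverage_experiment <- function(seed = 1L, n_sim = 200L, n = 10L, B = 1000L,
                                level = 0.95, sdlog = 0.3) {
  true_mean <- exp(sdlog^2 / 2)
  hits <- vapply(seq_len(n_sim), function(i) {
    x <- with_seed(derive_seed(seed, paste0("data", i)),
                   stats::rlnorm(n, 0, sdlog))
    ci <- bootstrap_ci(x, B = B, level = level,
                       seed = derive_seed(seed, paste0("boot", i)))
    ci[1] <= true_mean && true_mean <= ci[2]
  }, logical(1))
  list(coverage = mean(hits), n_sim = n_sim)
}

#' Mixture differential-expression calibration and power experiment
#'
#' Runs the full synthetic pipeline: simulate a pooled experiment,
#' simulate baseline and in vivo expression (in vivo = exact
#' composition-weighted mixture, plus multiplicative noise, plus `n_de`
#' spiked genes in one organ), rebuild the in-silico mixtures from the
#' true compositions, and test. Reports null calibration (fraction of
#' non-spiked analyses at q < 0.05 in a spike-free run) and spike
#' recovery.
#'
#' @param seed master seed.
#' @param n_genes genes simulated.
#' @param n_de spiked genes (power arm).
#' @param de_lfc spiked log2 fold-change.
#' @param noise_sd multiplicative (lognormal sdlog) noise on in vivo
#'   samples.
#' @param config simulator configuration.
#' @return list with `null_fraction_q05`, `power_hits` (spiked genes at
#'   q < 0.05), `n_de`, `median_lfc_spiked`.
#' @export
mixture_de_experiment <- function(seed = 1L, n_genes = 2000L, n_de = 100L,
                                  de_lfc = 2, noise_sd = 0.1,
                                  config = sim_config()) {
  config$seed <- derive_seed(seed, "simexp")
  sim <- simulate_experiment(config)
  run <- function(nde) {
    ex <- simulate_expression(sim, n_genes = n_genes, n_de = nde,
                              de_lfc = de_lfc, de_organ = config$organs[1],
                              noise_sd = noise_sd,
                              seed = derive_seed(seed, paste0("expr", nde)))
    mix <- insilico_mixtures(ex$invitro, ex$truth$compositions)
    res <- paired_moderated_test(log2_cpm(ex$invivo), log2_cpm(mix),
                                 organ_labels = ex$truth$organs)
    list(res = res[res$organ == config$organs[1], ], truth = ex$truth)
  }
  null <- run(0L)
  null_fraction <- mean(null$res$q_value < 0.05, na.rm = TRUE)
  pow <- run(n_de)
  spiked <- pow$truth$de_genes
  hits <- pow$res$gene[!is.na(pow$res$q_value) & pow$res$q_value < 0.05]
  list(null_fraction_q05 = null_fraction,
       power_hits = sum(spiked %in% hits), n_de = n_de,
       median_lfc_spiked = stats::median(pow$res$lfc[pow$res$gene %in% spiked]),
       false_hits = length(setdiff(hits, spiked)))
}

#' Simulate a mini-pool CRISPR screen with known depleted genes
#'
#' Guide counts are lognormal baselines Poisson-sampled per sample;
#' guides of depleted genes have tissue means multiplied by `2^lfc`.
#'
#' @param seed master seed.
#' @param n_genes targeted genes (default 29).
#' @param guides_per_gene guides per gene (default 2).
#' @param n_controls control guides.
#' @param n_ref,n_tissue reference / tissue replicates.
#' @param depleted character vector of truly depleted gene names.
#' @param lfc their true log2 fold-change (default -3).
#' @return list with `library` ([guide_library()]), `counts`, `reference`,
#'   `tissue`, `depleted`.
#' @export
simulate_screen <- function(seed = 1L, n_genes = 29L, guides_per_gene = 2L,
                            n_controls = 10L, n_ref = 3L, n_tissue = 5L,
                            depleted = character(0), lfc = -3) {
  with_seed(seed, {
    genes <- sprintf("gene%02d", seq_len(n_genes))
    lib <- guide_library(
      guide_id = c(sprintf("%s_g%d", rep(genes, each = guides_per_gene),
                           seq_len(guides_per_gene)),
                   sprintf("ctrl_g%d", seq_len(n_controls))),
      gene = c(rep(genes, each = guides_per_gene), rep("control", n_controls)))
    ng <- nrow(lib)
    base <- stats::rlnorm(ng, log(500), 0.4)
    ref <- matrix(stats::rpois(ng * n_ref, base), ng,
                  dimnames = list(lib$guide_id, paste0("ref", seq_len(n_ref))))
    mult <- rep(1, ng)
    mult[lib$gene %in% depleted] <- 2^lfc
    tis <- matrix(stats::rpois(ng * n_tissue, base * mult), ng,
                  dimnames = list(lib$guide_id, paste0("tis", seq_len(n_tissue))))
    list(library = lib, counts = cbind(ref, tis),
         reference = colnames(ref), tissue = colnames(tis),
         depleted = depleted)
  })
}

#' Screen recovery experiment
#'
#' Simulates the mini-pool screen with a known set of depleted genes and
#' scores it with [guide_depletion()].
#'
#' @param seed master seed.
#' @param depleted truly depleted genes (default 5 of the 29).
#' @param lfc true depletion log2 fold-change.
#' @return list with `recall`, `false_positives`, `result`.
#' @export
screen_experiment <- function(seed = 1L,
                              depleted = sprintf("gene%02d", c(3, 7, 11, 19, 26)),
                              lfc = -3) {
  s <- simulate_screen(derive_seed(seed, "screen"), depleted = depleted,
                       lfc = lfc)
  res <- guide_depletion(s$counts, s$library, s$reference, s$tissue)
  hits <- res$genes$gene[res$genes$q_value < 0.05]
  list(recall = length(intersect(hits, depleted)) / length(depleted),
       false_positives = length(setdiff(hits, depleted)),
       result = res, truth = s$depleted)
}
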