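#' Configuration for a simulated pooled in vivo barcoding experiment
#'
#' Defaults emulate the mapped assay's design: pools of 25 barcoded lines,
#' five target organs, cohorts of 5 mice, 500 injected cells per line,
#' organ-specific true potentials spanning more than four orders of
#' magnitude, incomplete penetrance, lognormal per-mouse outgrowth noise,
#' and overdispersed (Dirichlet-multinomial) amplicon read counts at one
#' million reads per sample.
#'
#' @param n_lines number of barcoded cell lines in the pool.
#' @param organs organ names.
#' @param n_mice mice per organ cohort.
#' @param cells_per_line injected cells per line per mouse.
#' @param true_log10_potential lines x organs matrix of true log10
#'   relative potentials; default drawn Uniform(-4, 1).
#' @param penetrance_prob lines x organs matrix of seeding probabilities;
#'   default logistic in the true potential,
#'   `plogis(1.5 * (true_log10_potential + 1.5))`, so aggressive lines
#'   seed nearly every mouse while weak lines show incomplete penetrance
#'   (petal width tracks petal length, as observed in the assay).
#' @param growth_cv lognormal sdlog of per-mouse outgrowth.
#' @param read_depth sequencing reads per sample.
#' @param overdispersion Dirichlet concentration scale; `Inf` gives the
#'   multinomial limit.
#' @param n_pre pre-injection replicate samples.
#' @param pre_jitter_cv lognormal jitter of pre-injection proportions
#'   around equality.
#' @param barcode_length,read_length nucleotides.
#' @param seed integer master seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_lines = 25L,
                       organs = c("brain", "lung", "liver", "kidney", "bone"),
                       n_mice = 5L, cells_per_line = 500L,
                       true_log10_potential = NULL, penetrance_prob = NULL,
                       growth_cv = 0.5, read_depth = 1e6, overdispersion = 100,
                       n_pre = 3L, pre_jitter_cv = 0.1,
                       barcode_length = 26L, read_length = 75L, seed = 1L) {
  stopifnot(n_lines >= 1, n_mice >= 1, cells_per_line >= 1, read_depth >= 1,
            overdispersion > 0, growth_cv >= 0, n_pre >= 1)
  cfg <- list(n_lines = as.integer(n_lines), organs = as.character(organs),
              n_mice = as.integer(n_mice),
              cells_per_line = as.integer(cells_per_line),
              true_log10_potential = true_log10_potential,
              penetrance_prob = penetrance_prob, growth_cv = growth_cv,
              read_depth = read_depth, overdispersion = overdispersion,
              n_pre = as.integer(n_pre), pre_jitter_cv = pre_jitter_cv,
              barcode_length = as.integer(barcode_length),
              read_length = as.integer(read_length), seed = as.integer(seed))
  if (!is.null(cfg$penetrance_prob) &&
      (any(cfg$penetrance_prob < 0) || any(cfg$penetrance_prob > 1))) {
    stop("penetrance_prob must lie in [0, 1]")
  }
  class(cfg) <- "sim_config"
  cfg
}

# One Dirichlet-multinomial draw: category probabilities are Dirichlet with
# parameters alpha = concentration * p (zero alpha -> category stays zero);
# concentration = Inf gives the plain multinomial limit.
rdirichlet_multinom <- function(size, p, concentration) {
  if (all(p == 0)) return(integer(length(p)))
  if (is.infinite(concentration)) {
    probs <- p / sum(p)
  } else {
    g <- stats::rgamma(length(p), shape = concentration * p, rate = 1)
    if (sum(g) == 0) g[which.max(p)] <- 1
    probs <- g / sum(g)
  }
  as.integer(stats::rmultinom(1L, size = size, prob = probs))
}

random_barcode_library <- function(n, length) {
  repeat {
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = ""),
      character(1))
    if (!anyDuplicated(seqs)) break
  }
  barcode_library(id = sprintf("BC%03d", seq_len(n)), sequence = seqs,
                  cell_line = sprintf("line%03d", seq_len(n)), pool_id = "pool1")
}

#' Forward-simulate a pooled in vivo barcoding experiment
#'
#' Generative model, per mouse m and organ i: each line j seeds with
#' probability `penetrance_prob[j, i]`; if seeded, its outgrown cell
#' number is `cells_per_line * 10^true_log10_potential[j, i] *`
#' `LogNormal(0, growth_cv)`, else 0. The sample composition is the cell
#' numbers renormalized to the simplex, and the sequenced counts are a
#' Dirichlet-multinomial draw of `read_depth` reads around that
#' composition. Pre-injection replicates are sequenced the same way from
#' the (jittered, renormalized) injected proportions. Deterministic given
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_experiment` with `counts`
#'   (a [barcode_count_table()] holding every organ sample and the
#'   pre-injection replicates), `cell_counts` (a [cell_count_table()] of
#'   realized totals), `library`, and `truth` (true potentials, penetrance
#'   probabilities, realized per-mouse cell numbers, realized compositions,
#'   pre-injection proportions).
#' @export
simulate_experiment <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    nl <- config$n_lines; orgs <- config$organs; nm <- config$n_mice
    lib <- random_barcode_library(nl, config$barcode_length)
    tp <- config$true_log10_potential
    if (is.null(tp)) {
      tp <- matrix(stats::runif(nl * length(orgs), -4, 1), nl,
                   dimnames = list(lib$cell_line, orgs))
    }
    pen <- config$penetrance_prob
    if (is.null(pen)) {
      pen <- stats::plogis(1.5 * (tp + 1.5))
      dimnames(pen) <- list(lib$cell_line, orgs)
    }
    if (all(pen == 0)) warning("all penetrance probabilities are zero")
    pre_p <- stats::rlnorm(nl, 0, config$pre_jitter_cv)
    pre_p <- pre_p / sum(pre_p)
    names(pre_p) <- lib$cell_line
    n_samples <- length(orgs) * nm + config$n_pre
    counts <- matrix(0L, nl, n_samples)
    rownames(counts) <- lib$id
    cells <- array(0, c(nl, length(orgs), nm),
                   dimnames = list(lib$cell_line, orgs, NULL))
    comps <- matrix(NA_real_, nl, length(orgs) * nm)
    sid <- character(n_samples); mouse <- character(n_samples)
    organ <- character(n_samples); repl <- integer(n_samples)
    cc_mouse <- character(0); cc_organ <- character(0); cc_total <- numeric(0)
    s <- 0L
    for (k in seq_len(nm)) {
      for (i in seq_along(orgs)) {
        seeded <- stats::rbinom(nl, 1L, pen[, i]) == 1L
        nc <- numeric(nl)
        if (any(seeded)) {
          nc[seeded] <- config$cells_per_line * 10^tp[seeded, i] *
            stats::rlnorm(sum(seeded), 0, config$growth_cv)
        }
        cells[, i, k] <- nc
        s <- s + 1L
        sid[s] <- sprintf("m%02d_%s", k, orgs[i])
        mouse[s] <- sprintf("m%02d", k); organ[s] <- orgs[i]; repl[s] <- k
        p <- if (sum(nc) > 0) nc / sum(nc) else numeric(nl)
        comps[, s] <- if (sum(nc) > 0) p else NA_real_
        counts[, s] <- rdirichlet_multinom(config$read_depth, p,
                                           config$overdispersion)
        cc_mouse <- c(cc_mouse, sprintf("m%02d", k))
        cc_organ <- c(cc_organ, orgs[i]); cc_total <- c(cc_total, sum(nc))
      }
    }
    for (r in seq_len(config$n_pre)) {
      s <- s + 1L
      sid[s] <- sprintf("pre%02d", r)
      mouse[s] <- NA_character_; organ[s] <- "pre_injection"; repl[s] <- r
      counts[, s] <- rdirichlet_multinom(config$read_depth, pre_p,
                                         config$overdispersion)
    }
    colnames(counts) <- sid
    colnames(comps) <- sid[seq_len(length(orgs) * nm)]
    rownames(comps) <- lib$cell_line
    meta <- sample_meta(sid, mouse_id = mouse, organ = organ,
                        replicate_index = repl)
    out <- list(
      counts = barcode_count_table(counts, library = lib, samples = meta),
      cell_counts = cell_count_table(cc_mouse, cc_organ, cc_total),
      library = lib,
      truth = list(true_log10_potential = tp, penetrance_prob = pen,
                   cells = cells, compositions = comps,
                   pre_proportions = pre_p))
    class(out) <- "sim_experiment"
    out
  })
}

#' Emit simulated FASTQ reads for a count table
#'
#' Writes one read per counted fragment: the line's barcode embedded at a
#' random offset inside random A/C/G/T flanking sequence, with optional
#' per-base substitution errors. With `error_rate = 0`, running
#' [count_barcodes()] on the output reproduces the input counts exactly.
#'
#' @param table a [barcode_count_table()].
#' @param library the [barcode_library()] (defaults to the table's).
#' @param dir output directory; one `<sample>.fastq` per sample.
#' @param read_length read length (must be >= barcode length).
#' @param error_rate per-base substitution probability.
#' @param seed integer seed.
#' @return named character vector of FASTQ paths.
#' @export
emit_fastq <- function(table, library = table$library, dir = tempdir(),
                       read_length = 75L, error_rate = 0, seed = 1L) {
  stopifnot(inherits(table, "barcode_count_table"))
  L <- barcode_length(library)
  if (read_length < L) stop("read_length (", read_length,
                            ") < barcode length (", L, ")")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    paths <- vapply(colnames(table$counts), function(smp) {
      cnt <- table$counts[, smp]
      n <- sum(cnt)
      path <- file.path(dir, paste0(smp, ".fastq"))
      if (n == 0) { file.create(path); return(path) }
      bc <- rep(library$sequence[match(names(cnt), library$id)], times = cnt)
      offs <- sample.int(read_length - L + 1L, n, replace = TRUE) - 1L
      reads <- vapply(seq_len(n), function(f) {
        left <- paste(sample(bases, offs[f], replace = TRUE), collapse = "")
        right <- paste(sample(bases, read_length - L - offs[f], replace = TRUE),
                       collapse = "")
        paste0(left, bc[f], right)
      }, character(1))
      if (error_rate > 0) {
        reads <- vapply(reads, function(r) {
          ch <- strsplit(r, "")[[1L]]
          hit <- stats::runif(length(ch)) < error_rate
          if (any(hit)) {
            ch[hit] <- vapply(ch[hit], function(b)
              sample(setdiff(bases, b), 1L), character(1))
          }
          paste(ch, collapse = "")
        }, character(1), USE.NAMES = FALSE)
      }
      qual <- strrep("I", read_length)
      rec <- as.vector(rbind(sprintf("@%s_frag%d", smp, seq_len(n)),
                             reads, "+", qual))
      writeLines(rec, path)
      path
    }, character(1))
    paths
  })
}

#' Simulate paired in vitro / in vivo expression data
#'
#' Baseline in vitro profiles per line are lognormal around gene-level
#' means; each in vivo sample is the composition-weighted linear mixture
#' of the baselines of its lines, with `n_de` genes multiplied by
#' `2^de_lfc` in `de_organ` and multiplicative lognormal noise on every
#' gene. This realizes exactly the structure the composition-corrected
#' paired test assumes, with known differential genes.
#'
#' @param sim a [simulate_experiment()] result (supplies compositions).
#' @param n_genes number of genes.
#' @param n_de number of truly differential genes in `de_organ`.
#' @param de_lfc their log2 fold-change.
#' @param de_organ organ receiving the effect.
#' @param noise_sd sdlog of the multiplicative noise on in vivo samples.
#' @param seed integer seed.
#' @return list with `invitro` and `invivo` [expression_matrix()] objects
#'   (linear `cpm`-like scale), and `truth` (`de_genes`, `de_organ`,
#'   `compositions`).
#' @export
simulate_expression <- function(sim, n_genes = 2000L, n_de = 100L, de_lfc = 2,
                                de_organ = "brain", noise_sd = 0.1, seed = 1L) {
  stopifnot(inherits(sim, "sim_experiment"))
  if (n_de > n_genes) stop("n_de cannot exceed n_genes")
  comps <- sim$truth$compositions
  keep <- colSums(is.na(comps)) == 0
  comps <- comps[, keep, drop = FALSE]
  meta <- sim$counts$samples
  organs <- meta$organ[match(colnames(comps), meta$sample_id)]
  with_seed(seed, {
    genes <- sprintf("gene%04d", seq_len(n_genes))
    lines <- rownames(comps)
    gene_mu <- stats::rlnorm(n_genes, meanlog = 4, sdlog = 1.5)
    base <- matrix(gene_mu, n_genes, length(lines)) *
      matrix(stats::rlnorm(n_genes * length(lines), 0, 0.3), n_genes)
    dimnames(base) <- list(genes, lines)
    de_genes <- sample(genes, n_de)
    mix <- base %*% comps
    if (n_de > 0) {
      hit <- organs == de_organ
      mix[de_genes, hit] <- mix[de_genes, hit] * 2^de_lfc
    }
    if (noise_sd > 0) {
      mix <- mix * matrix(stats::rlnorm(length(mix), 0, noise_sd), nrow(mix))
    }
    list(invitro = expression_matrix(base, scale = "cpm"),
         invivo = expression_matrix(mix, scale = "cpm"),
         truth = list(de_genes = de_genes, de_organ = de_organ,
                      compositions = comps, organs = organs))
  })
}
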