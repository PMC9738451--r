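#' Simulation configuration
#'
#' Parameters of the negative-binomial time-course simulator. Counts for
#' gene g in a sample of timepoint t have mean
#' `sf * mu_g * fold_change^pattern_g[t]` and variance `mu + alpha * mu^2`
#' (mean/dispersion parameterisation). A fraction of genes carries a
#' binary temporal pattern drawn uniformly from the `2^T - 1` non-zero
#' patterns; the rest are flat (all-zero pattern).
#'
#' Defaults mirror a 12-sample regeneration time course: five states
#' (control plus four post-amputation timepoints) with 3/2/2/3/2
#' replicates, 30% of genes patterned at an 8-fold effect, and log-normal
#' baseline expression.
#'
#' @param n_genes Number of genes (positive integer).
#' @param design Design data.frame, see [timepoint_design()]; default
#'   [study_design()].
#' @param frac_patterned Fraction of genes carrying a non-zero pattern,
#'   in `[0, 1]` (default 0.3).
#' @param fold_change Multiplicative effect (>= 1) applied where the
#'   pattern is 1 (default 8).
#' @param baseline_log_mu,baseline_log_sigma Mean and sd (>= 0) of the
#'   per-gene log baseline expression (log-normal; defaults 4 and 1, i.e.
#'   median baseline ~55 counts).
#' @param dispersion_range Length-2 positive range from which per-gene NB
#'   dispersions are drawn uniformly (default `c(0.02, 0.1)`, typical of
#'   bulk RNA-seq).
#' @param size_factor_range Length-2 positive range for per-sample size
#'   factors (default `c(0.7, 1.3)`).
#' @param seed Integer seed; the simulation is bit-reproducible given the
#'   configuration.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes,
                       design = study_design(),
                       frac_patterned = 0.3,
                       fold_change = 8,
                       baseline_log_mu = 4,
                       baseline_log_sigma = 1,
                       dispersion_range = c(0.02, 0.1),
                       size_factor_range = c(0.7, 1.3),
                       seed = 1L) {
  if (length(n_genes) != 1L || n_genes < 1 || n_genes != round(n_genes))
    stop("n_genes must be a positive integer")
  if (!nrow(design)) stop("design is empty")
  if (!is.null(design$replicate) && any(design$replicate != round(design$replicate)))
    stop("replicate counts must be integers")
  if (frac_patterned < 0 || frac_patterned > 1)
    stop("frac_patterned must lie in [0, 1]")
  if (fold_change < 1) stop("fold_change must be >= 1")
  if (baseline_log_sigma < 0) stop("baseline_log_sigma must be >= 0")
  stopifnot(length(dispersion_range) == 2L, all(dispersion_range > 0),
            length(size_factor_range) == 2L, all(size_factor_range > 0))
  structure(list(
    n_genes = as.integer(n_genes), design = design,
    frac_patterned = frac_patterned, fold_change = fold_change,
    baseline_log_mu = baseline_log_mu,
    baseline_log_sigma = baseline_log_sigma,
    dispersion_range = sort(as.numeric(dispersion_range)),
    size_factor_range = sort(as.numeric(size_factor_range)),
    seed = as.integer(seed)
  ), class = "sim_config")
}

# decode integers 0..2^T-1 into 0/1 rows, first timepoint = most
# significant bit so numeric order equals lexicographic order
.int_to_bits <- function(idx, n_tp) {
  out <- matrix(0L, length(idx), n_tp)
  for (t in seq_len(n_tp))
    out[, t] <- as.integer(bitwAnd(idx, bitwShiftL(1L, n_tp - t)) > 0L)
  out
}

#' Simulate a patterned negative-binomial count matrix
#'
#' Draws per-gene baselines and dispersions, per-sample size factors, and
#' plants binary temporal patterns in a random subset of genes (each
#' patterned gene's expression is multiplied by the fold change at its
#' "high" timepoints). The same configuration always yields bit-identical
#' output.
#'
#' @param config A [sim_config()].
#' @return A list with `counts` (a [count_matrix()]) and `truth`, a list
#'   holding the planted `pattern` matrix (gene x timepoint 0/1), per-gene
#'   `mu` and `alpha`, and per-sample `size_factors`.
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  design <- config$design
  tp <- timepoints(design)
  n_tp <- length(tp)
  n_g <- config$n_genes
  n_s <- nrow(design)
  genes <- sprintf("g%05d", seq_len(n_g))
  withr::with_seed(config$seed, {
    mu <- stats::rlnorm(n_g, config$baseline_log_mu, config$baseline_log_sigma)
    alpha <- stats::runif(n_g, config$dispersion_range[1], config$dispersion_range[2])
    sf <- stats::runif(n_s, config$size_factor_range[1], config$size_factor_range[2])
    patterned <- stats::runif(n_g) < config$frac_patterned
    pat <- matrix(0L, n_g, n_tp, dimnames = list(genes, tp))
    n_pat <- sum(patterned)
    if (n_pat > 0L && n_tp >= 1L) {
      idx <- sample.int(2L^n_tp - 1L, n_pat, replace = TRUE)
      pat[patterned, ] <- .int_to_bits(idx, n_tp)
    }
    tp_of_sample <- match(design$timepoint, tp)
    counts <- matrix(0L, n_g, n_s, dimnames = list(genes, design$sample))
    for (j in seq_len(n_s)) {
      mean_j <- sf[j] * mu * config$fold_change^pat[, tp_of_sample[j]]
      counts[, j] <- stats::rnbinom(n_g, mu = mean_j, size = 1 / alpha)
    }
  })
  names(sf) <- design$sample
  names(mu) <- names(alpha) <- genes
  list(
    counts = count_matrix(counts, design),
    truth = list(pattern = pat, mu = mu, alpha = alpha, size_factors = sf)
  )
}

#' Plant gene sets enriched at a chosen timepoint
#'
#' Builds gene sets whose members are over-represented among genes active
#' at a target timepoint, plus matched random control sets of the same
#' size. A `purity` fraction of each planted set is drawn (without
#' replacement within a set) from the active pool; the remainder, and the
#' control sets, are drawn uniformly from all genes. With
#' `specific = TRUE` (default) the active pool is restricted to genes
#' whose true pattern is 1 at the target timepoint and 0 everywhere else,
#' emulating a stage-specific pathway; with `specific = FALSE` any gene
#' active at the target qualifies.
#'
#' @param truth Truth component of [simulate_counts()] output.
#' @param n_sets Number of planted sets (an equal number of controls is
#'   generated).
#' @param set_size Members per set; must not exceed the number of genes.
#' @param target_timepoint Timepoint label the sets are planted at.
#' @param purity Fraction in `[0, 1]` of members drawn from the active
#'   pool.
#' @param seed Integer seed.
#' @param specific Restrict the active pool to genes active only at the
#'   target timepoint (default TRUE).
#' @return A list with `planted` and `control`, each a named list of
#'   gene-id vectors, plus `target_timepoint` and `purity`.
#' @export
simulate_genesets <- function(truth, n_sets, set_size, target_timepoint,
                              purity, seed = 1L, specific = TRUE) {
  pat <- truth$pattern
  if (!target_timepoint %in% colnames(pat))
    stop("unknown timepoint: ", target_timepoint)
  if (purity < 0 || purity > 1) stop("purity must lie in [0, 1]")
  genes <- rownames(pat)
  if (set_size > length(genes))
    stop("set_size exceeds the number of available genes")
  active <- pat[, target_timepoint] == 1L
  pool <- if (specific) genes[active & rowSums(pat) == 1L] else genes[active]
  n_target <- round(purity * set_size)
  if (n_target > length(pool))
    stop(sprintf("active pool at %s holds %d genes; %d needed per set",
                 target_timepoint, length(pool), n_target))
  withr::with_seed(seed, {
    planted <- lapply(seq_len(n_sets), function(i) {
      core <- if (n_target > 0L) sample(pool, n_target) else character()
      rest <- sample(setdiff(genes, core), set_size - n_target)
      sort(c(core, rest))
    })
    control <- lapply(seq_len(n_sets), function(i) sort(sample(genes, set_size)))
  })
  names(planted) <- sprintf("planted_%03d", seq_len(n_sets))
  names(control) <- sprintf("control_%03d", seq_len(n_sets))
  list(planted = planted, control = control,
       target_timepoint = target_timepoint, purity = purity)
}
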