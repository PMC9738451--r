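#' Enumerate timepoint comparisons
#'
#' Lists the group-vs-group comparisons to test. In `pairs` mode every
#' unordered pair of individual timepoints is compared (`T*(T-1)/2`
#' comparisons). In `contiguous_groups` mode all pairs of disjoint
#' contiguous timepoint runs are additionally included (singleton runs
#' give back the plain pairs). Group A always precedes group B in time;
#' ordering is deterministic: individual pairs before larger groupings
#' (total group size), then by start of A, length of A, start of B and
#' length of B.
#'
#' @param design Design data.frame or [count_matrix()].
#' @param mode `"pairs"` (default) or `"contiguous_groups"`.
#' @return A list of comparisons; each is a list with character vectors
#'   `group_a`, `group_b` and a `name` of the form `"A_vs_B"` with
#'   multi-timepoint groups joined by `"+"`.
#' @examples
#' length(all_comparisons(study_design()))  # 10
#' @export
all_comparisons <- function(design, mode = c("pairs", "contiguous_groups")) {
  mode <- match.arg(mode)
  tp <- timepoints(design)
  n <- length(tp)
  if (n < 2L) stop("at least two timepoints are required")
  runs <- list()
  max_len <- if (mode == "pairs") 1L else n
  for (len in 1L:max_len)
    for (start in 1L:(n - len + 1L))
      runs[[length(runs) + 1L]] <- c(start = start, end = start + len - 1L)
  out <- list()
  for (a in runs) for (b in runs) {
    if (a["end"] >= b["start"]) next
    ga <- tp[a["start"]:a["end"]]
    gb <- tp[b["start"]:b["end"]]
    out[[length(out) + 1L]] <- list(
      group_a = ga, group_b = gb,
      name = paste0(paste(ga, collapse = "+"), "_vs_", paste(gb, collapse = "+"))
    )
  }
  key <- vapply(out, function(cmp) {
    a <- match(cmp$group_a[1], tp); b <- match(cmp$group_b[1], tp)
    la <- length(cmp$group_a); lb <- length(cmp$group_b)
    sum(c(la + lb, a, la, b, lb) * (2 * n + 1)^c(4, 3, 2, 1, 0))
  }, numeric(1))
  out[order(key)]
}

# Moderated NB Wald machinery shared by comparisons ------------------------

# gene-wise method-of-moments dispersion from within-group variances of
# size-factor-normalised counts; variance model Var(K/sf) = mu/sf + alpha*mu^2
.mom_dispersion <- function(norm, groups) {
  n_gene <- nrow(norm)
  num <- rep(0, n_gene); den <- 0
  for (g in groups) {
    sub <- norm[, g$cols, drop = FALSE]
    n_j <- length(g$cols)
    if (n_j < 2L) next
    m <- rowMeans(sub)
    v <- rowSums((sub - m)^2) / (n_j - 1L)
    a <- (v - m * g$c_inv) / pmax(m, 1e-8)^2
    num <- num + (n_j - 1L) * a
    den <- den + (n_j - 1L)
  }
  num / max(den, 1L)
}

# shrink gene-wise dispersions toward a 1/mu trend (empirical Bayes with
# prior_df pseudo-observations); the trend absorbs the mean-dispersion
# relationship so strongly and weakly expressed genes share strength
.moderate_dispersion <- function(alpha_gene, mu, d_res, prior_df, floor = 1e-8) {
  ok <- is.finite(alpha_gene) & mu > 0
  trend <- if (sum(ok) >= 10L) {
    fit <- tryCatch(stats::lm.fit(cbind(1, 1 / mu[ok]), alpha_gene[ok])$coefficients,
                    error = function(e) NULL)
    if (is.null(fit) || any(!is.finite(fit)))
      rep(stats::median(alpha_gene[ok]), length(mu))
    else fit[1] + fit[2] / pmax(mu, 1e-8)
  } else {
    rep(if (any(ok)) stats::median(alpha_gene[ok]) else floor, length(mu))
  }
  trend <- pmax(trend, floor)
  a <- (d_res * ifelse(is.finite(alpha_gene), alpha_gene, trend) +
          prior_df * trend) / (d_res + prior_df)
  pmax(a, floor)
}

#' Pairwise differential expression between timepoint groups
#'
#' Moderated negative-binomial Wald test of one timepoint group against
#' another. Per gene, size-factor-normalised group means are compared on
#' the log2 scale with a half-count pseudocount
#' (`log2FC = log2((m_b + 1/2) / (m_a + 1/2))`, group B over group A);
#' the standard error comes from the NB variance model
#' `Var = mu/sf + alpha*mu^2` with a gene-wise method-of-moments
#' dispersion shrunk toward a fitted mean-dispersion trend
#' (`prior_df` pseudo-observations, dispersion floored at 1e-8). The
#' Wald statistic is referred to a t distribution with residual + prior
#' degrees of freedom, p-values are two-sided, and FDR is controlled by
#' Benjamini-Hochberg within the comparison.
#'
#' @param x A filtered [count_matrix()].
#' @param comparison One element of [all_comparisons()] (or any list with
#'   `group_a`, `group_b`, `name`).
#' @param fdr_threshold Significance threshold on FDR (default 0.05).
#' @param sf Size factors for the samples of `x`; computed on the full
#'   matrix by default so all comparisons share one normalisation.
#' @param prior_df Strength of dispersion moderation (default 20).
#' @return A data.frame with one row per gene: `gene`,
#'   `log2_fold_change`, `p_value`, `fdr` and `direction` (one of
#'   `"up_in_b"`, `"up_in_a"`, `"not_significant"`). The comparison name
#'   and threshold are attached as attributes.
#' @export
pairwise_de <- function(x, comparison, fdr_threshold = 0.05,
                        sf = size_factors(x), prior_df = 20) {
  stopifnot(inherits(x, "count_matrix"))
  design <- x$design
  cols_a <- which(design$timepoint %in% comparison$group_a)
  cols_b <- which(design$timepoint %in% comparison$group_b)
  if (length(intersect(comparison$group_a, comparison$group_b)))
    stop("comparison groups overlap")
  if (length(cols_a) < 2L || length(cols_b) < 2L)
    stop("each comparison group needs at least two samples")
  norm <- sweep(x$counts, 2L, sf, "/")
  n_a <- length(cols_a); n_b <- length(cols_b)
  m_a <- rowMeans(norm[, cols_a, drop = FALSE])
  m_b <- rowMeans(norm[, cols_b, drop = FALSE])
  groups <- list(list(cols = cols_a, c_inv = mean(1 / sf[cols_a])),
                 list(cols = cols_b, c_inv = mean(1 / sf[cols_b])))
  d_res <- n_a + n_b - 2L
  alpha_gene <- .mom_dispersion(norm, groups)
  mu_bar <- (n_a * m_a + n_b * m_b) / (n_a + n_b)
  alpha <- .moderate_dispersion(alpha_gene, mu_bar, d_res, prior_df)
  lfc <- log2((m_b + 0.5) / (m_a + 0.5))
  var_a <- (m_a * groups[[1]]$c_inv + alpha * m_a^2) / n_a
  var_b <- (m_b * groups[[2]]$c_inv + alpha * m_b^2) / n_b
  log2sq <- log(2)^2
  se <- sqrt(var_a / ((m_a + 0.5)^2 * log2sq) + var_b / ((m_b + 0.5)^2 * log2sq))
  z <- ifelse(se > 0, lfc / se, 0)
  p <- 2 * stats::pt(-abs(z), df = d_res + prior_df)
  fdr <- stats::p.adjust(p, method = "BH")
  direction <- ifelse(fdr < fdr_threshold,
                      ifelse(lfc > 0, "up_in_b", "up_in_a"),
                      "not_significant")
  res <- data.frame(gene = rownames(x$counts), log2_fold_change = lfc,
                    p_value = p, fdr = fdr, direction = direction,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "comparison") <- comparison
  attr(res, "fdr_threshold") <- fdr_threshold
  res
}

#' Run every comparison of a design
#'
#' Applies [pairwise_de()] to each comparison from [all_comparisons()],
#' sharing one set of size factors across comparisons.
#'
#' @inheritParams pairwise_de
#' @param comparisons List of comparisons; defaults to all individual
#'   timepoint pairs.
#' @param mode Passed to [all_comparisons()] when `comparisons` is NULL.
#' @return An object of class `de_results`: a list with `results` (named
#'   list of per-comparison data.frames), `comparisons`, `timepoints` and
#'   `fdr_threshold`.
#' @export
run_de <- function(x, comparisons = NULL, mode = c("pairs", "contiguous_groups"),
                   fdr_threshold = 0.05, sf = size_factors(x), prior_df = 20) {
  mode <- match.arg(mode)
  if (is.null(comparisons)) comparisons <- all_comparisons(x$design, mode)
  results <- lapply(comparisons, function(cmp)
    pairwise_de(x, cmp, fdr_threshold = fdr_threshold, sf = sf,
                prior_df = prior_df))
  names(results) <- vapply(comparisons, `[[`, "", "name")
  structure(list(results = results, comparisons = comparisons,
                 timepoints = timepoints(x$design),
                 fdr_threshold = fdr_threshold),
            class = "de_results")
}

#' @export
print.de_results <- function(x, ...) {
  n_sig <- vapply(x$results, function(r) sum(r$direction != "not_significant"),
                  integer(1))
  cat(sprintf("de_results: %d comparisons over %d timepoints (FDR < %g)\n",
              length(x$results), length(x$timepoints), x$fdr_threshold))
  for (nm in names(x$results))
    cat(sprintf("  %-28s %d significant\n", nm, n_sig[[nm]]))
  invisible(x)
}
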