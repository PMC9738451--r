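#' Curate a symbol-keyed gene set through a homology map
#'
#' Translates a gene set given as gene symbols into species gene ids via a
#' homology map (e.g. best-BLASTP annotation against a reference
#' proteome). A symbol without any homolog is dropped; a symbol matching
#' several species gene ids contributes all of them; the result is
#' deduplicated.
#'
#' @param symbols Character vector of gene symbols.
#' @param map Homology map: data.frame with columns `symbol` and
#'   `gene_id` (one association per row, one-to-many allowed).
#' @return Character vector of species gene ids, with attributes
#'   `n_unmapped` (symbols dropped) and `n_symbols` (input size).
#' @export
curate_geneset <- function(symbols, map) {
  stopifnot(all(c("symbol", "gene_id") %in% names(map)))
  if (any(!nzchar(map$symbol)) || any(!nzchar(map$gene_id)))
    stop("homology map contains empty id strings")
  symbols <- unique(symbols)
  hit <- map$symbol %in% symbols
  ids <- unique(map$gene_id[hit])
  mapped <- unique(map$symbol[hit])
  structure(ids, n_unmapped = length(symbols) - length(mapped),
            n_symbols = length(symbols))
}

#' Curate a collection of gene sets
#'
#' Applies [curate_geneset()] to every set; sets left empty after
#' curation are excluded with a warning.
#'
#' @param sets Named list of symbol vectors (e.g. from [read_gmt()]).
#' @inheritParams curate_geneset
#' @return Named list of curated id vectors.
#' @export
curate_genesets <- function(sets, map) {
  out <- lapply(sets, curate_geneset, map = map)
  empty <- lengths(out) == 0L
  if (any(empty))
    warning("sets empty after curation, excluded: ",
            paste(names(out)[empty], collapse = ", "))
  out[!empty]
}

#' Percentage of a gene set active at a timepoint
#'
#' The raw enrichment statistic: of the set members present in the binary
#' matrix, the percentage carrying a 1 ("dynamically high") at the given
#' timepoint. Members absent from the matrix are dropped before the
#' denominator is formed.
#'
#' @param bmat Binary gene x timepoint matrix from [binarize_all()].
#' @param members Character vector of gene ids.
#' @param timepoint Column label of `bmat`.
#' @return Percentage in `[0, 100]`, with attribute `n_members` (the
#'   effective set size) and `n_dropped`.
#' @export
active_proportion <- function(bmat, members, timepoint) {
  if (!timepoint %in% colnames(bmat)) stop("unknown timepoint: ", timepoint)
  members <- unique(members)
  inter <- intersect(members, rownames(bmat))
  if (!length(inter))
    stop("no gene-set member is present in the binary matrix")
  structure(100 * sum(bmat[inter, timepoint]) / length(inter),
            n_members = length(inter),
            n_dropped = length(members) - length(inter))
}

#' Hypergeometric null baseline for set activity
#'
#' Expected activity of a random set: drawing `s` genes without
#' replacement from a universe of `N` genes of which `K` are active, the
#' active fraction has mean `K/N` and the stated spread. `level = "sd"`
#' gives the one-standard-deviation band with the finite-population
#' correction,
#' `halfwidth = 100 * sqrt(s * (K/N) * (1 - K/N) * (N - s)/(N - 1)) / s`;
#' a numeric `level` in (0, 1) gives the central quantile band of the
#' hypergeometric overlap count instead, converted to percent of `s`.
#'
#' @param N Universe size.
#' @param K Number of active genes in the universe (`0 <= K <= N`).
#' @param s Set size (`1 <= s <= N`).
#' @param level `"sd"` (default) or a confidence level in (0, 1), e.g.
#'   0.5 or 0.99.
#' @return List with `baseline_percent`, `lower_percent`,
#'   `upper_percent` and `halfwidth_percent` (half the band width).
#' @export
hypergeometric_baseline <- function(N, K, s, level = "sd") {
  if (K < 0 || K > N) stop("K must lie in [0, N]")
  if (s < 1 || s > N) stop("s must lie in [1, N]")
  baseline <- 100 * K / N
  if (identical(level, "sd")) {
    hw <- if (N == 1L || s == N) 0
      else 100 * sqrt(s * (K / N) * (1 - K / N) * (N - s) / (N - 1)) / s
    lower <- baseline - hw; upper <- baseline + hw
  } else {
    if (!is.numeric(level) || level <= 0 || level >= 1)
      stop("level must be \"sd\" or a number in (0, 1)")
    a <- (1 - level) / 2
    lower <- 100 * stats::qhyper(a, K, N - K, s) / s
    upper <- 100 * stats::qhyper(1 - a, K, N - K, s) / s
    hw <- (upper - lower) / 2
  }
  list(baseline_percent = baseline, lower_percent = lower,
       upper_percent = upper, halfwidth_percent = hw)
}

#' Baseline-subtracted enrichment curve of a gene set
#'
#' For each timepoint, computes the set's raw active percentage, the
#' hypergeometric baseline for a random set of the same effective size,
#' and the baseline-subtracted ("adjusted") enrichment with its band. The
#' subtraction is floored at 0% -- a set less active than a random draw
#' shows no enrichment rather than a negative one -- and the same floor is
#' applied to the band, so `band_low = 0` and `band_high` is the
#' band's upper excursion above the baseline.
#'
#' @inheritParams active_proportion
#' @param level Band specification, see [hypergeometric_baseline()].
#' @param name Optional set name recorded in the output.
#' @return data.frame with one row per timepoint: `set`, `timepoint`,
#'   `raw_percent`, `baseline_percent`, `band_halfwidth_percent`,
#'   `adjusted_percent`, `band_low`, `band_high`.
#' @export
enrichment_curve <- function(bmat, members, level = "sd", name = "set") {
  tp <- colnames(bmat)
  N <- nrow(bmat)
  inter <- intersect(unique(members), rownames(bmat))
  if (!length(inter))
    stop("no gene-set member is present in the binary matrix")
  s <- length(inter)
  rows <- lapply(tp, function(t) {
    raw <- 100 * sum(bmat[inter, t]) / s
    base <- hypergeometric_baseline(N, sum(bmat[, t]), s, level)
    data.frame(
      set = name, timepoint = t, raw_percent = raw,
      baseline_percent = base$baseline_percent,
      band_halfwidth_percent = base$halfwidth_percent,
      adjusted_percent = max(0, raw - base$baseline_percent),
      band_low = max(0, base$lower_percent - base$baseline_percent),
      band_high = max(0, base$upper_percent - base$baseline_percent),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$timepoint <- factor(out$timepoint, levels = tp)
  out
}

#' Enrichment curves for a collection of sets
#'
#' @param sets Named list of gene-id vectors.
#' @inheritParams enrichment_curve
#' @return Long data.frame, the row-bound curves of all sets. Sets with
#'   no member in the matrix are skipped with a warning.
#' @export
enrichment_curves <- function(bmat, sets, level = "sd") {
  ok <- vapply(sets, function(m) length(intersect(m, rownames(bmat))) > 0,
               logical(1))
  if (any(!ok))
    warning("sets with no member in the matrix skipped: ",
            paste(names(sets)[!ok], collapse = ", "))
  do.call(rbind, c(Map(function(m, nm) enrichment_curve(bmat, m, level, nm),
                       sets[ok], names(sets)[ok]),
                   list(make.row.names = FALSE)))
}

#' Hypergeometric over-representation analysis
#'
#' Tests each gene set for over-representation in a query list drawn from
#' a gene universe: the upper-tail probability that a random draw of the
#' query's size contains at least the observed overlap,
#' `P(X >= k)` with `X ~ Hypergeometric(N, K, n)`. FDR is controlled by
#' Benjamini-Hochberg across sets.
#'
#' @param query Character vector of gene ids (the genes of interest);
#'   genes outside the universe are dropped with a warning.
#' @param universe Character vector of all eligible gene ids.
#' @param sets Named list of gene-id vectors; members are intersected
#'   with the universe.
#' @param fdr_threshold Significance threshold (default 0.05).
#' @return data.frame with one row per set: `set`, `set_size` (effective,
#'   within the universe), `overlap`, `expected`, `p_value`, `fdr`,
#'   `significant`.
#' @export
ora_test <- function(query, universe, sets, fdr_threshold = 0.05) {
  universe <- unique(universe)
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
  }
  N <- length(universe); n <- length(query)
  rows <- Map(function(members, nm) {
    members <- intersect(unique(members), universe)
    K <- length(members)
    k <- length(intersect(query, members))
    p <- if (n == 0L || K == 0L) 1
      else stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, set_size = K, overlap = k,
               expected = n * K / N, p_value = min(1, p),
               stringsAsFactors = FALSE)
  }, sets, names(sets))
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$fdr < fdr_threshold
  out
}
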