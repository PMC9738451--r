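#' Per-gene hierarchy of timepoint relations
#'
#' Condenses a gene's significant pairwise calls into a set of directed
#' relations "expression is higher at timepoint a than at timepoint b". An
#' individual-pair comparison contributes one relation oriented by its
#' direction call; a contiguous-group comparison (A vs B) is decomposed
#' into all member pairs, each oriented by the group-level call.
#' Duplicates are collapsed; if two comparisons imply opposite relations
#' for the same timepoint pair both are dropped with a warning.
#'
#' @param de A `de_results` object from [run_de()].
#' @param gene Gene id; a gene absent from every comparison table is an
#'   error, a gene simply non-significant everywhere yields an empty
#'   hierarchy.
#' @return Object of class `gene_hierarchy`: a data.frame with character
#'   columns `higher` and `lower` (one row per relation) and the gene id
#'   as attribute.
#' @export
build_hierarchy <- function(de, gene) {
  stopifnot(inherits(de, "de_results"))
  seen <- FALSE
  higher <- character(); lower <- character()
  for (i in seq_along(de$results)) {
    res <- de$results[[i]]
    row <- match(gene, res$gene)
    if (is.na(row)) next
    seen <- TRUE
    dir <- res$direction[row]
    if (dir == "not_significant") next
    cmp <- de$comparisons[[i]]
    pairs <- expand.grid(a = cmp$group_a, b = cmp$group_b,
                         stringsAsFactors = FALSE)
    if (dir == "up_in_b") {
      higher <- c(higher, pairs$b); lower <- c(lower, pairs$a)
    } else {
      higher <- c(higher, pairs$a); lower <- c(lower, pairs$b)
    }
  }
  if (!seen) stop("gene not present in any comparison: ", gene)
  rel <- unique(data.frame(higher = higher, lower = lower,
                           stringsAsFactors = FALSE))
  if (nrow(rel)) {
    fwd <- paste(rel$higher, rel$lower, sep = "\r")
    rev <- paste(rel$lower, rel$higher, sep = "\r")
    conflict <- fwd %in% rev
    if (any(conflict)) {
      warning(sprintf("gene %s: dropping %d conflicting relation(s)",
                      gene, sum(conflict)))
      rel <- rel[!conflict, , drop = FALSE]
    }
  }
  rownames(rel) <- NULL
  structure(rel, class = c("gene_hierarchy", "data.frame"), gene = gene)
}

.relation_counts <- function(hierarchy, tp) {
  bad <- setdiff(c(hierarchy$higher, hierarchy$lower), tp)
  if (length(bad))
    stop("relation names timepoint(s) outside the design: ",
         paste(unique(bad), collapse = ", "))
  list(up = tabulate(match(hierarchy$higher, tp), length(tp)),
       down = tabulate(match(hierarchy$lower, tp), length(tp)))
}

#' Score a binary pattern against a hierarchy
#'
#' A pattern assigns each timepoint "dynamically high" (1) or "dynamically
#' low" (0); its score counts agreements with the hierarchy's up/down
#' labels minus disagreements. Two readings are provided. `labelwise`
#' (default): every relation (a, b) labels a "up" and b "down", and each
#' label scores +1 when the pattern matches it (bit 1 at a, bit 0 at b)
#' and -1 when it does not. `pairwise`: a relation scores +1 only when the
#' pattern honours it fully (1 at a and 0 at b), -1 when fully reversed,
#' 0 otherwise.
#'
#' @param bits Integer 0/1 vector in timepoint order.
#' @param hierarchy A [build_hierarchy()] result.
#' @param tp Ordered timepoint labels the bits refer to.
#' @param mode `"labelwise"` or `"pairwise"`.
#' @return Integer score.
#' @export
score_pattern <- function(bits, hierarchy, tp, mode = c("labelwise", "pairwise")) {
  mode <- match.arg(mode)
  if (length(bits) != length(tp))
    stop("pattern length does not match the number of timepoints")
  if (!all(bits %in% c(0, 1))) stop("pattern bits must be 0 or 1")
  cnt <- .relation_counts(hierarchy, tp)
  bits <- as.integer(bits)
  if (mode == "labelwise")
    sum(cnt$up * (2L * bits - 1L)) + sum(cnt$down * (1L - 2L * bits))
  else
    sum((cnt$up - cnt$down) * bits)
}

#' Best-scoring binary pattern for a hierarchy
#'
#' Enumerates all `2^T` binary patterns, scores each against the
#' hierarchy with [score_pattern()] semantics, and returns the maximum.
#' Ties are broken deterministically in favour of the pattern with the
#' fewest 1-bits, then the lexicographically smallest bit string in
#' timepoint order -- so an uninformative (empty) hierarchy yields the
#' all-zero pattern.
#'
#' @inheritParams score_pattern
#' @return A list with `bits` (named integer 0/1 vector) and `score`.
#' @export
best_pattern <- function(hierarchy, tp, mode = c("labelwise", "pairwise")) {
  mode <- match.arg(mode)
  n_tp <- length(tp)
  if (n_tp < 1L || n_tp > 20L)
    stop("between 1 and 20 timepoints are supported for exhaustive search")
  cnt <- .relation_counts(hierarchy, tp)
  P <- .int_to_bits(0:(2L^n_tp - 1L), n_tp)
  scores <- if (mode == "labelwise")
    2 * as.vector(P %*% (cnt$up - cnt$down)) + sum(cnt$down) - sum(cnt$up)
  else
    as.vector(P %*% (cnt$up - cnt$down))
  # rows of P ascend lexicographically, so among equal scores and equal
  # 1-bit counts the smallest row index is the lexicographic minimum
  best <- order(-scores, rowSums(P), seq_len(nrow(P)))[1L]
  bits <- P[best, ]
  names(bits) <- tp
  list(bits = bits, score = as.integer(scores[best]))
}

#' Binary gene-time matrix from differential-expression results
#'
#' The atlas object: for every gene, builds its timepoint hierarchy from
#' the pairwise calls and assigns the best-scoring binary pattern, giving
#' a gene x timepoint 0/1 matrix with 1 marking dynamically high
#' expression. Conflicting relations are dropped silently per gene and
#' reported once in total.
#'
#' @param de A `de_results` object from [run_de()].
#' @param mode Scoring mode, see [score_pattern()].
#' @return Integer 0/1 matrix (genes x timepoints, dimnames set) with a
#'   `provenance` attribute recording the comparison set, FDR threshold,
#'   scoring mode and tie-break rule.
#' @export
binarize_all <- function(de, mode = c("labelwise", "pairwise")) {
  mode <- match.arg(mode)
  stopifnot(inherits(de, "de_results"))
  tp <- de$timepoints
  n_tp <- length(tp)
  genes <- de$results[[1]]$gene
  # accumulate relations comparison-wise, then resolve per gene
  rel_gene <- character(); rel_hi <- character(); rel_lo <- character()
  for (i in seq_along(de$results)) {
    res <- de$results[[i]]
    sig <- res$direction != "not_significant"
    if (!any(sig)) next
    cmp <- de$comparisons[[i]]
    pairs <- expand.grid(a = cmp$group_a, b = cmp$group_b,
                         stringsAsFactors = FALSE)
    for (k in seq_len(nrow(pairs))) {
      g <- res$gene[sig]
      up_b <- res$direction[sig] == "up_in_b"
      rel_gene <- c(rel_gene, g)
      rel_hi <- c(rel_hi, ifelse(up_b, pairs$b[k], pairs$a[k]))
      rel_lo <- c(rel_lo, ifelse(up_b, pairs$a[k], pairs$b[k]))
    }
  }
  out <- matrix(0L, length(genes), n_tp, dimnames = list(genes, tp))
  n_conflict <- 0L
  if (length(rel_gene)) {
    key <- paste(rel_gene, rel_hi, rel_lo, sep = "\r")
    keep <- !duplicated(key)
    rel_gene <- rel_gene[keep]; rel_hi <- rel_hi[keep]; rel_lo <- rel_lo[keep]
    fwd <- paste(rel_gene, rel_hi, rel_lo, sep = "\r")
    rev <- paste(rel_gene, rel_lo, rel_hi, sep = "\r")
    conflict <- fwd %in% rev
    n_conflict <- sum(conflict) %/% 2L
    rel_gene <- rel_gene[!conflict]
    rel_hi <- rel_hi[!conflict]; rel_lo <- rel_lo[!conflict]
    if (length(rel_gene)) {
      gi <- match(rel_gene, genes)
      up <- matrix(0L, length(genes), n_tp)
      down <- matrix(0L, length(genes), n_tp)
      hi_i <- match(rel_hi, tp); lo_i <- match(rel_lo, tp)
      for (t in seq_len(n_tp)) {
        up[, t] <- tabulate(gi[hi_i == t], length(genes))
        down[, t] <- tabulate(gi[lo_i == t], length(genes))
      }
      P <- .int_to_bits(0:(2L^n_tp - 1L), n_tp)
      ones <- rowSums(P)
      W <- up - down                     # genes x tp
      S <- P %*% t(W)                    # patterns x genes (shared term)
      offset <- if (mode == "labelwise") rowSums(down) - rowSums(up) else 0
      scale <- if (mode == "labelwise") 2 else 1
      active <- which(rowSums(abs(W)) > 0)
      for (g in active) {
        s <- scale * S[, g] + if (mode == "labelwise") offset[g] else 0
        out[g, ] <- P[order(-s, ones, seq_along(s))[1L], ]
      }
    }
  }
  if (n_conflict > 0L)
    warning(sprintf("dropped %d conflicting relation pair(s) across genes",
                    n_conflict))
  attr(out, "provenance") <- list(
    comparisons = vapply(de$comparisons, `[[`, "", "name"),
    fdr_threshold = de$fdr_threshold,
    scoring_mode = mode,
    tie_break = "fewest_ones_then_lexicographic",
    timepoints = tp, n_genes = length(genes)
  )
  out
}
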