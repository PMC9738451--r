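# Independent brute-force pattern scorer: plain loops over relations and
# over all 2^T candidate patterns, written without any of the package's
# vectorised machinery so it can serve as an oracle.
oracle_score <- function(bits, rel, tp, mode = "labelwise") {
  s <- 0L
  for (r in seq_len(nrow(rel))) {
    a <- match(rel$higher[r], tp)
    b <- match(rel$lower[r], tp)
    if (mode == "labelwise") {
      s <- s + (if (bits[a] == 1) 1L else -1L)
      s <- s + (if (bits[b] == 0) 1L else -1L)
    } else {
      if (bits[a] == 1 && bits[b] == 0) s <- s + 1L
      if (bits[a] == 0 && bits[b] == 1) s <- s - 1L
    }
  }
  s
}

oracle_all_patterns <- function(n_tp) {
  grid <- expand.grid(rep(list(0:1), n_tp))[, n_tp:1, drop = FALSE]
  unname(as.matrix(grid))
}

oracle_max_score <- function(rel, tp, mode = "labelwise") {
  patterns <- oracle_all_patterns(length(tp))
  best <- -.Machine$integer.max
  for (i in seq_len(nrow(patterns)))
    best <- max(best, oracle_score(patterns[i, ], rel, tp, mode))
  as.integer(best)
}

# random hierarchy: each unordered timepoint pair independently absent,
# forward or reverse (consistent with at most one relation per pair)
random_hierarchy <- function(tp) {
  pairs <- t(utils::combn(tp, 2))
  state <- sample(0:2, nrow(pairs), replace = TRUE)
  keep <- state > 0
  data.frame(
    higher = ifelse(state == 1, pairs[, 1], pairs[, 2])[keep],
    lower = ifelse(state == 1, pairs[, 2], pairs[, 1])[keep],
    stringsAsFactors = FALSE
  )
}

reverse_hierarchy <- function(rel) {
  data.frame(higher = rel$lower, lower = rel$higher, stringsAsFactors = FALSE)
}

# small count_matrix straight from a plain matrix
toy_counts <- function(m, timepoints_per_sample) {
  tp <- unique(timepoints_per_sample)
  design <- data.frame(sample = colnames(m),
                       timepoint = timepoints_per_sample,
                       order = match(timepoints_per_sample, tp),
                       stringsAsFactors = FALSE)
  count_matrix(m, design)
}
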