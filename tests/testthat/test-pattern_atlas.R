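# fabricate a de_results object directly from direction calls
fake_de <- function(calls, tp) {
  genes <- unique(unlist(lapply(calls, function(x) x$genes)))
  results <- list(); comparisons <- list()
  for (i in seq_along(calls)) {
    cmp <- calls[[i]]
    comparisons[[i]] <- list(group_a = cmp$a, group_b = cmp$b,
                             name = paste0(paste(cmp$a, collapse = "+"), "_vs_",
                                           paste(cmp$b, collapse = "+")))
    dir <- rep("not_significant", length(genes))
    dir[match(cmp$genes, genes)] <- cmp$dir
    results[[i]] <- data.frame(gene = genes,
                               log2_fold_change = rep(0, length(genes)),
                               p_value = rep(1, length(genes)),
                               fdr = rep(1, length(genes)), direction = dir,
                               stringsAsFactors = FALSE)
  }
  names(results) <- vapply(comparisons, `[[`, "", "name")
  structure(list(results = results, comparisons = comparisons,
                 timepoints = tp, fdr_threshold = 0.05),
            class = "de_results")
}

tp5 <- c("control", "2dpa", "7dpa", "14dpa", "21dpa")

test_that("hierarchies collect, decompose and deduplicate directed relations", {
  de <- fake_de(list(
    list(a = "control", b = "2dpa", genes = "g1", dir = "up_in_b"),
    list(a = "control", b = "7dpa", genes = "g1", dir = "up_in_b"),
    list(a = "2dpa", b = "7dpa", genes = character(), dir = character())
  ), tp5)
  h <- build_hierarchy(de, "g1")
  expect_setequal(paste(h$higher, h$lower), c("2dpa control", "7dpa control"))

  # non-significant everywhere: empty relation set
  de2 <- fake_de(list(list(a = "control", b = "2dpa", genes = "g9",
                           dir = "not_significant")), tp5)
  expect_identical(nrow(build_hierarchy(de2, "g9")), 0L)
  expect_error(build_hierarchy(de, "missing_gene"), "not present")
})

test_that("group comparisons decompose into member pairs", {
  de <- fake_de(list(
    list(a = "control", b = c("2dpa", "7dpa"), genes = "g1", dir = "up_in_b")
  ), tp5)
  h <- build_hierarchy(de, "g1")
  expect_setequal(paste(h$higher, h$lower),
                  c("2dpa control", "7dpa control"))
})

test_that("opposed relations from different comparisons cancel with a warning", {
  de <- fake_de(list(
    list(a = "control", b = "2dpa", genes = "g1", dir = "up_in_b"),
    list(a = c("control", "2dpa"), b = "7dpa", genes = "g1", dir = "up_in_b"),
    list(a = "2dpa", b = "7dpa", genes = "g1", dir = "up_in_a")
  ), tp5)
  # comparison 2 says 7dpa > 2dpa, comparison 3 says 2dpa > 7dpa
  expect_warning(h <- build_hierarchy(de, "g1"), "conflicting")
  expect_setequal(paste(h$higher, h$lower),
                  c("2dpa control", "7dpa control"))
})

test_that("pattern scores follow the label accounting in both modes", {
  h0 <- data.frame(higher = character(), lower = character())
  expect_identical(score_pattern(c(0, 1, 0, 1, 0), h0, tp5), 0L)
  expect_identical(score_pattern(rep(1, 5), h0, tp5, "pairwise"), 0L)

  h1 <- data.frame(higher = "2dpa", lower = "control")
  expect_identical(score_pattern(c(0, 1, 0, 0, 0), h1, tp5), 2L)
  expect_identical(score_pattern(c(1, 0, 0, 0, 0), h1, tp5), -2L)
  expect_identical(score_pattern(c(0, 1, 0, 0, 0), h1, tp5, "pairwise"), 1L)

  h3 <- data.frame(higher = c("2dpa", "7dpa", "2dpa"),
                   lower = c("control", "control", "14dpa"))
  expect_identical(score_pattern(c(0, 1, 1, 0, 0), h3, tp5), 6L)
  # exhaustive check: 6 is the maximum over all 32 patterns
  expect_identical(oracle_max_score(h3, tp5), 6L)

  expect_error(score_pattern(c(0, 1), h1, tp5), "length")
  expect_error(score_pattern(c(0, 2, 0, 0, 0), h1, tp5), "0 or 1")
  bad <- data.frame(higher = "42dpa", lower = "control")
  expect_error(score_pattern(c(0, 1, 0, 0, 0), bad, tp5), "outside the design")
})

test_that("best pattern enumerates candidates and breaks ties conservatively", {
  h0 <- data.frame(higher = character(), lower = character())
  b0 <- best_pattern(h0, tp5)
  expect_identical(unname(b0$bits), rep(0L, 5))
  expect_identical(b0$score, 0L)

  tp2 <- c("t0", "t1")
  b2 <- best_pattern(data.frame(higher = "t1", lower = "t0"), tp2)
  expect_identical(unname(b2$bits), c(0L, 1L))
  expect_identical(b2$score, 2L)
  # the four candidates score 0, +2, -2, 0: the maximum is unique
  expect_identical(oracle_max_score(data.frame(higher = "t1", lower = "t0"),
                                    tp2), 2L)

  expect_error(best_pattern(h0, paste0("t", 1:21)), "20 timepoints")
})

test_that("best pattern matches the brute-force oracle on random hierarchies", {
  set.seed(42)
  for (i in 1:150) {
    tp <- paste0("t", 1:sample(3:6, 1))
    rel <- random_hierarchy(tp)
    for (mode in c("labelwise", "pairwise")) {
      got <- best_pattern(rel, tp, mode)
      expect_identical(got$score, oracle_max_score(rel, tp, mode))
      expect_identical(oracle_score(unname(got$bits), rel, tp, mode), got$score)
    }
  }
})

test_that("complementing an optimum solves the reversed hierarchy", {
  set.seed(43)
  for (i in 1:100) {
    tp <- paste0("t", 1:5)
    rel <- random_hierarchy(tp)
    fwd <- best_pattern(rel, tp)
    rev <- best_pattern(reverse_hierarchy(rel), tp)
    expect_identical(fwd$score, rev$score)
    expect_identical(score_pattern(1 - fwd$bits, reverse_hierarchy(rel), tp),
                     rev$score)
  }
})

test_that("binarization assembles one row per gene with provenance", {
  de <- fake_de(list(
    list(a = "control", b = "2dpa", genes = c("g1", "g2"),
         dir = c("up_in_b", "up_in_a")),
    list(a = "2dpa", b = "7dpa", genes = "g1", dir = "up_in_a"),
    list(a = "control", b = "21dpa", genes = character(), dir = character())
  ), tp5)
  # add a gene with no significant call anywhere
  for (i in seq_along(de$results)) {
    de$results[[i]] <- rbind(de$results[[i]],
                             data.frame(gene = "g3", log2_fold_change = 0,
                                        p_value = 1, fdr = 1,
                                        direction = "not_significant"))
  }
  bmat <- binarize_all(de)
  expect_identical(dim(bmat), c(3L, 5L))
  expect_identical(colnames(bmat), tp5)
  # g1 is higher at 2dpa than both control and 7dpa
  expect_identical(unname(bmat["g1", ]), c(0L, 1L, 0L, 0L, 0L))
  # g2 is higher in control than at 2dpa
  expect_identical(unname(bmat["g2", ]), c(1L, 0L, 0L, 0L, 0L))
  expect_identical(unname(bmat["g3", ]), rep(0L, 5))
  prov <- attr(bmat, "provenance")
  expect_identical(prov$scoring_mode, "labelwise")
  expect_identical(prov$fdr_threshold, 0.05)
  expect_length(prov$comparisons, 3L)

  # all-non-significant input gives the all-zero matrix
  de0 <- fake_de(list(list(a = "control", b = "2dpa", genes = character(),
                           dir = character())), tp5)
  de0$results[[1]] <- data.frame(gene = c("a", "b"), log2_fold_change = 0,
                                 p_value = 1, fdr = 1,
                                 direction = "not_significant")
  expect_true(all(binarize_all(de0) == 0L))
})

test_that("binarization agrees with gene-by-gene hierarchy + best pattern", {
  set.seed(44)
  cfg <- sim_config(300, dispersion_range = c(0.05, 0.05), seed = 31)
  sim <- simulate_counts(cfg)
  de <- run_de(filter_genes(sim$counts))
  bmat <- binarize_all(de)
  for (g in sample(rownames(bmat), 25)) {
    h <- suppressWarnings(build_hierarchy(de, g))
    expect_identical(unname(bmat[g, ]),
                     unname(best_pattern(h, de$timepoints)$bits))
  }
})
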