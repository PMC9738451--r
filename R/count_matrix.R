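#' Ordered timepoint design table
#'
#' Builds the sample-to-timepoint design used throughout the package. Sample
#' ids are generated as `<timepoint>_r<replicate>`.
#'
#' @param timepoints Character vector of timepoint labels in chronological
#'   order (first label is the reference state).
#' @param replicates Integer vector, one replicate count per timepoint
#'   (each >= 1).
#' @return A data.frame with columns `sample`, `timepoint`, `order`
#'   (1-based chronological rank) and `replicate`.
#' @examples
#' timepoint_design(c("t0", "t1"), c(2, 2))
#' @export
timepoint_design <- function(timepoints, replicates) {
  timepoints <- as.character(timepoints)
  if (length(timepoints) < 1L || anyDuplicated(timepoints))
    stop("timepoints must be a non-empty vector of unique labels")
  if (length(replicates) != length(timepoints))
    stop("one replicate count is required per timepoint")
  if (any(replicates != as.integer(replicates)))
    stop("replicate counts must be integers")
  replicates <- as.integer(replicates)
  if (any(replicates < 1L))
    stop("every timepoint needs at least one replicate")
  data.frame(
    sample = unlist(Map(function(tp, n) paste0(tp, "_r", seq_len(n)),
                        timepoints, replicates), use.names = FALSE),
    timepoint = rep(timepoints, replicates),
    order = rep(seq_along(timepoints), replicates),
    replicate = unlist(lapply(replicates, seq_len), use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Default regeneration time-course design
#'
#' An uncut control followed by 2, 7, 14 and 21 days post-amputation with
#' 3, 2, 2, 3 and 2 replicates respectively (12 samples in total) -- the
#' layout of a typical tunicate neural-complex regeneration experiment.
#'
#' @return A design data.frame as produced by [timepoint_design()].
#' @export
study_design <- function() {
  timepoint_design(c("control", "2dpa", "7dpa", "14dpa", "21dpa"),
                   c(3L, 2L, 2L, 3L, 2L))
}

#' Gene-by-sample count matrix with design linkage
#'
#' The raw input object of the pipeline: an integer count matrix whose
#' columns are tied to ordered timepoints through a design table.
#'
#' @param counts Numeric matrix of non-negative integer counts with unique
#'   rownames (gene ids) and colnames (sample ids).
#' @param design Design data.frame (see [timepoint_design()]); must contain
#'   every sample in `counts` exactly once.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   and `design` (design rows reordered to match the column order).
#' @export
count_matrix <- function(counts, design) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if ((nrow(counts) > 0L && is.null(rownames(counts))) || is.null(colnames(counts)))
    stop("counts must have gene rownames and sample colnames")
  if (is.null(rownames(counts))) dimnames(counts)[1] <- list(character(0))
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids in counts")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids in counts")
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  required <- c("sample", "timepoint", "order")
  if (!all(required %in% names(design)))
    stop("design must have columns: ", paste(required, collapse = ", "))
  if (anyDuplicated(design$sample)) stop("duplicate sample ids in design")
  missing <- setdiff(colnames(counts), design$sample)
  if (length(missing))
    stop("samples absent from design: ", paste(missing, collapse = ", "))
  design <- design[match(colnames(counts), design$sample), , drop = FALSE]
  rownames(design) <- NULL
  structure(list(counts = counts, design = design), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  tp <- timepoints(x)
  cat(sprintf("count_matrix: %d genes x %d samples over %d timepoints (%s)\n",
              nrow(x$counts), ncol(x$counts), length(tp),
              paste(tp, collapse = " < ")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Ordered timepoint labels of a design or count matrix
#'
#' @param x A `count_matrix` or a design data.frame.
#' @return Character vector of timepoint labels in chronological order.
#' @export
timepoints <- function(x) {
  design <- if (inherits(x, "count_matrix")) x$design else x
  design <- design[order(design$order), , drop = FALSE]
  unique(design$timepoint)
}

#' Low-count gene filter
#'
#' Retains a gene when at least `min_samples` samples support it with at
#' least `min_count` reads; everything else is discarded before
#' differential testing. The defaults discard genes with <= 5 supporting
#' reads in fewer than 2 samples.
#'
#' @param x A [count_matrix()].
#' @param min_count Minimum read count a sample must reach to support a
#'   gene (default 5).
#' @param min_samples Minimum number of supporting samples (default 2).
#' @return A `count_matrix` with the surviving genes, original order and
#'   sample set preserved. Warns when nothing survives.
#' @export
filter_genes <- function(x, min_count = 5L, min_samples = 2L) {
  stopifnot(inherits(x, "count_matrix"), min_count >= 0, min_samples >= 0)
  keep <- rowSums(x$counts >= min_count) >= min_samples
  if (!any(keep)) warning("no genes survive the low-count filter")
  count_matrix(x$counts[keep, , drop = FALSE], x$design)
}

#' Median-of-ratios size factors
#'
#' Per-sample sequencing-depth factors estimated as the median, over genes
#' expressed in all samples, of the ratio between the sample's count and
#' the gene's geometric mean across samples. When no gene is expressed
#' everywhere the estimator falls back to total-count ratios (library size
#' over the geometric mean of library sizes) with a warning.
#'
#' @param x A [count_matrix()].
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  m <- x$counts
  eligible <- rowSums(m == 0L) == 0L
  if (!any(eligible)) {
    warning("no gene has non-zero counts in every sample; ",
            "falling back to total-count normalisation")
    libs <- colSums(m)
    if (any(libs == 0)) stop("sample with zero total counts")
    return(libs / exp(mean(log(libs))))
  }
  logm <- log(m[eligible, , drop = FALSE])
  geo <- rowMeans(logm)
  apply(exp(logm - geo), 2L, stats::median)
}
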