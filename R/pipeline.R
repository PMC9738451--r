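#' Pipeline configuration
#'
#' Bundles every parameter and input path of [run_pipeline()]. All
#' thresholds are validated here; file existence is checked at run time.
#'
#' @param counts,design Paths to the counts and design TSVs.
#' @param gmt,mapping Optional paths to a symbol-keyed GMT file and a
#'   homology mapping TSV; when either is NULL the enrichment stages are
#'   skipped (zero sets reported).
#' @param out_dir Output directory (created if absent).
#' @param min_count,min_samples Low-count filter, see [filter_genes()].
#' @param fdr_threshold Differential-expression significance level
#'   (default 0.05).
#' @param comparison_mode `"pairs"` or `"contiguous_groups"`.
#' @param scoring_mode `"labelwise"` or `"pairwise"`.
#' @param ci_level `"sd"` or a numeric confidence level in (0, 1).
#' @param prior_df Dispersion-moderation strength, see [pairwise_de()].
#' @param seed Integer recorded in the manifest (the pipeline itself is
#'   deterministic given its inputs).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(counts, design, gmt = NULL, mapping = NULL,
                            out_dir = "regenatlas_run",
                            min_count = 5L, min_samples = 2L,
                            fdr_threshold = 0.05,
                            comparison_mode = c("pairs", "contiguous_groups"),
                            scoring_mode = c("labelwise", "pairwise"),
                            ci_level = "sd", prior_df = 20, seed = 1L) {
  comparison_mode <- match.arg(comparison_mode)
  scoring_mode <- match.arg(scoring_mode)
  stopifnot(fdr_threshold > 0, fdr_threshold < 1,
            min_count >= 0, min_samples >= 0, prior_df >= 0)
  if (!identical(ci_level, "sd") &&
      (!is.numeric(ci_level) || ci_level <= 0 || ci_level >= 1))
    stop("ci_level must be \"sd\" or a number in (0, 1)")
  structure(list(counts = counts, design = design, gmt = gmt,
                 mapping = mapping, out_dir = out_dir,
                 min_count = min_count, min_samples = min_samples,
                 fdr_threshold = fdr_threshold,
                 comparison_mode = comparison_mode,
                 scoring_mode = scoring_mode, ci_level = ci_level,
                 prior_df = prior_df, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full atlas pipeline
#'
#' Executes filter -> normalise -> pairwise DE over all comparisons ->
#' binary pattern assignment -> gene-set curation -> enrichment curves ->
#' ORA, writing every intermediate artifact and a machine-readable
#' manifest (parameters, seed, input checksums, per-stage outputs) to the
#' output directory. Re-running with identical inputs and configuration
#' reproduces identical files.
#'
#' The ORA stage queries, for each timepoint, the genes dynamically high
#' there (a 1 in the binary matrix) against the matrix universe.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return The output directory, invisibly. The manifest is
#'   `manifest.json` inside it.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  inputs <- c(counts = config$counts, design = config$design,
              gmt = config$gmt, mapping = config$mapping)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing))
    stop("input file(s) not found: ", paste(missing, collapse = ", "))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  stages <- list()

  cm <- read_counts(config$counts, config$design)
  say("loaded %d genes x %d samples", nrow(cm$counts), ncol(cm$counts))

  filtered <- filter_genes(cm, config$min_count, config$min_samples)
  say("filter: %d of %d genes retained (>=%d samples with >=%d reads)",
      nrow(filtered$counts), nrow(cm$counts), config$min_samples,
      config$min_count)
  if (!nrow(filtered$counts)) stop("stage filter: no genes retained")
  write_counts(filtered, out("filtered_counts.tsv"), out("design.tsv"))
  stages$filter <- c("filtered_counts.tsv", "design.tsv")

  sf <- size_factors(filtered)
  .write_tsv(data.frame(sample = names(sf), size_factor = format(sf, digits = 17)),
             out("size_factors.tsv"))
  stages$normalise <- "size_factors.tsv"

  de <- run_de(filtered, mode = config$comparison_mode,
               fdr_threshold = config$fdr_threshold, sf = sf,
               prior_df = config$prior_df)
  de_files <- character()
  for (nm in names(de$results)) {
    f <- paste0("de_", gsub("[^A-Za-z0-9_+.-]", "_", nm), ".tsv")
    write_de_table(de$results[[nm]], out(f))
    de_files <- c(de_files, f)
  }
  say("de: %d comparisons tested", length(de$results))
  stages$de <- de_files

  bmat <- binarize_all(de, mode = config$scoring_mode)
  write_binary_matrix(bmat, out("binary_matrix.tsv"))
  say("binarize: %d of %d genes dynamic", sum(rowSums(bmat) > 0), nrow(bmat))
  stages$binarize <- c("binary_matrix.tsv", "binary_matrix.tsv.provenance.json")

  have_sets <- !is.null(config$gmt) && !is.null(config$mapping)
  curated <- list()
  if (have_sets) {
    raw_sets <- read_gmt(config$gmt)
    map <- read_mapping(config$mapping)
    curated <- curate_genesets(raw_sets, map)
    dropped <- sum(vapply(curated, function(s) attr(s, "n_unmapped"), 0L))
    say("curate: %d sets kept of %d; %d unmapped symbols dropped",
        length(curated), length(raw_sets), dropped)
    write_gmt(curated, out("curated_sets.gmt"))
    stages$curate <- "curated_sets.gmt"
  } else {
    say("curate: no gene sets supplied; enrichment reports zero sets")
  }

  if (length(curated)) {
    curves <- enrichment_curves(bmat, curated, level = config$ci_level)
    write_curves(curves, out("enrichment_curves.tsv"))
    jsonlite::write_json(
      list(ci_level = config$ci_level, curves = curves),
      out("enrichment_curves.json"), auto_unbox = TRUE, digits = NA)
    stages$enrich <- c("enrichment_curves.tsv", "enrichment_curves.json")

    universe <- rownames(bmat)
    ora <- do.call(rbind, lapply(colnames(bmat), function(t) {
      q <- universe[bmat[, t] == 1L]
      if (!length(q)) return(NULL)
      res <- ora_test(q, universe, curated, config$fdr_threshold)
      cbind(timepoint = t, res, stringsAsFactors = FALSE)
    }))
    if (is.null(ora))
      ora <- data.frame(timepoint = character(), set = character(),
                        set_size = integer(), overlap = integer(),
                        expected = numeric(), p_value = numeric(),
                        fdr = numeric(), significant = logical())
    num <- vapply(ora, is.numeric, logical(1))
    ora_fmt <- ora
    ora_fmt[num] <- lapply(ora_fmt[num], format, digits = 17)
    .write_tsv(ora_fmt, out("ora.tsv"))
    stages$ora <- "ora.tsv"
    say("enrich/ora: %d sets profiled over %d timepoints",
        length(curated), ncol(bmat))
  } else {
    stages$enrich <- character(); stages$ora <- character()
  }

  manifest <- list(
    package = "regenatlas",
    version = as.character(utils::packageVersion("regenatlas")),
    parameters = unclass(config)[setdiff(names(unclass(config)),
                                         c("counts", "design", "gmt", "mapping"))],
    seed = config$seed,
    inputs = lapply(as.list(inputs), function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    stages = stages,
    outputs_md5 = as.list(tools::md5sum(
      file.path(config$out_dir, unlist(stages, use.names = FALSE))))
  )
  names(manifest$outputs_md5) <- unlist(stages, use.names = FALSE)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  say("manifest written to %s", out("manifest.json"))
  invisible(config$out_dir)
}
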