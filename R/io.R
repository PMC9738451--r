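#' @name formats
#' @title Plain-text readers and writers
#' @description
#' All pipeline artifacts are tab-separated text with header rows (JSON
#' only for manifests and curve exports): counts TSV (first column
#' `gene`, one column per sample), design TSV (`sample`, `timepoint`,
#' `order`, `replicate`), truth TSV (`gene`, `pattern` as a 0/1 string,
#' `mu`, `alpha`), GMT gene sets (name, description, then member ids,
#' tab-separated), homology mapping TSV (`symbol`, `gene_id`), DE tables,
#' binary matrix TSV with a JSON provenance sidecar, and curve tables.
#' Every writer/reader pair round-trips exactly; malformed rows are
#' rejected with their line number.
NULL

.read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character")
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname formats
#' @param x,path,design_path Object to write / file paths.
#' @export
write_counts <- function(x, path, design_path) {
  stopifnot(inherits(x, "count_matrix"))
  df <- data.frame(gene = rownames(x$counts), x$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .write_tsv(df, path)
  .write_tsv(x$design, design_path)
  invisible(c(path, design_path))
}

#' @rdname formats
#' @export
read_counts <- function(path, design_path) {
  raw <- .read_tsv(path)
  if (names(raw)[1] != "gene") stop("counts TSV must start with a 'gene' column")
  if (anyDuplicated(raw$gene))
    stop("duplicate gene ids in counts file: ",
         paste(unique(raw$gene[duplicated(raw$gene)]), collapse = ", "))
  cells <- as.matrix(raw[, -1, drop = FALSE])
  bad <- which(!grepl("^[0-9]+$", cells))
  if (length(bad)) {
    line <- min((bad - 1L) %% nrow(cells) + 1L) + 1L  # +1 for the header line
    stop("non-integer count at line ", line, " of ", path)
  }
  m <- matrix(as.integer(cells), nrow(cells), ncol(cells),
              dimnames = list(raw$gene, colnames(cells)))
  design <- .read_tsv(design_path)
  need <- c("sample", "timepoint", "order")
  if (!all(need %in% names(design)))
    stop("design TSV needs columns: ", paste(need, collapse = ", "))
  design$order <- as.integer(design$order)
  if ("replicate" %in% names(design))
    design$replicate <- as.integer(design$replicate)
  count_matrix(m, design)
}

#' @rdname formats
#' @param truth Truth list from [simulate_counts()].
#' @export
write_truth <- function(truth, path) {
  df <- data.frame(gene = rownames(truth$pattern),
                   pattern = apply(truth$pattern, 1L, paste, collapse = ""),
                   mu = truth$mu, alpha = truth$alpha,
                   stringsAsFactors = FALSE, row.names = NULL)
  .write_tsv(df, path)
}

#' @rdname formats
#' @export
read_truth <- function(path) {
  df <- .read_tsv(path)
  bits <- strsplit(df$pattern, "")
  if (length(unique(lengths(bits))) > 1L) stop("ragged pattern strings")
  pat <- do.call(rbind, lapply(bits, as.integer))
  rownames(pat) <- df$gene
  list(pattern = pat,
       mu = stats::setNames(as.numeric(df$mu), df$gene),
       alpha = stats::setNames(as.numeric(df$alpha), df$gene))
}

#' @rdname formats
#' @param sets Named list of member-id vectors.
#' @param descriptions Optional character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname formats
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short))
    stop("GMT line ", short[1], " has fewer than 3 fields")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  nm <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(nm)) stop("duplicate set names in GMT")
  names(sets) <- nm
  attr(sets, "descriptions") <- vapply(parts, `[[`, "", 2L)
  sets
}

#' @rdname formats
#' @param map Homology map data.frame (`symbol`, `gene_id`).
#' @export
write_mapping <- function(map, path) .write_tsv(map[c("symbol", "gene_id")], path)

#' @rdname formats
#' @export
read_mapping <- function(path) {
  df <- .read_tsv(path)
  if (!all(c("symbol", "gene_id") %in% names(df)))
    stop("mapping TSV needs columns symbol and gene_id")
  empty <- which(!nzchar(df$symbol) | !nzchar(df$gene_id))
  if (length(empty)) stop("empty id at line ", empty[1] + 1L, " of ", path)
  df
}

#' @rdname formats
#' @param res A [pairwise_de()] result.
#' @export
write_de_table <- function(res, path) {
  df <- res
  df$log2_fold_change <- format(df$log2_fold_change, digits = 17)
  df$p_value <- format(df$p_value, digits = 17)
  df$fdr <- format(df$fdr, digits = 17)
  .write_tsv(df, path)
}

#' @rdname formats
#' @export
read_de_table <- function(path) {
  df <- .read_tsv(path)
  df$log2_fold_change <- as.numeric(df$log2_fold_change)
  df$p_value <- as.numeric(df$p_value)
  df$fdr <- as.numeric(df$fdr)
  df
}

#' @rdname formats
#' @param bmat Binary matrix from [binarize_all()].
#' @export
write_binary_matrix <- function(bmat, path) {
  df <- data.frame(gene = rownames(bmat), bmat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .write_tsv(df, path)
  prov <- attr(bmat, "provenance")
  if (!is.null(prov))
    jsonlite::write_json(prov, paste0(path, ".provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname formats
#' @export
read_binary_matrix <- function(path) {
  df <- .read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!all(m %in% c("0", "1"))) stop("binary matrix entries must be 0/1")
  m <- matrix(as.integer(m), nrow(m), ncol(m),
              dimnames = list(df$gene, colnames(m)))
  sidecar <- paste0(path, ".provenance.json")
  if (file.exists(sidecar))
    attr(m, "provenance") <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  m
}

#' @rdname formats
#' @param curves Curve table from [enrichment_curves()].
#' @export
write_curves <- function(curves, path) {
  df <- curves
  df$timepoint <- as.character(df$timepoint)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], format, digits = 17)
  .write_tsv(df, path)
}

#' @rdname formats
#' @export
read_curves <- function(path) {
  df <- .read_tsv(path)
  for (col in setdiff(names(df), c("set", "timepoint")))
    df[[col]] <- as.numeric(df[[col]])
  df
}
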