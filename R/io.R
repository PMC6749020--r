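#' Read a community table with sample metadata
#'
#' Supports the classic tab-separated OTU table (taxa in rows, samples in
#' columns, first header field `#OTU ID`) and BIOM (JSON, via the
#' \pkg{biomformat} package). Metadata is a TSV with columns `sample_id`,
#' `site`, `molecule`, `x`, `y`.
#'
#' @param path path to the OTU table.
#' @param metadata_path path to the sample metadata TSV.
#' @param format `"classic-tsv"` or `"biom"`.
#' @return a [community_table()].
#' @export
read_community <- function(path, metadata_path, format = c("classic-tsv", "biom")) {
  format <- match.arg(format)
  counts <- switch(format,
    "classic-tsv" = read_classic_otu(path),
    "biom" = read_biom_counts(path))
  if (any(counts < 0)) stopf("negative counts in %s", path)
  community_table(counts, read_metadata(metadata_path))
}

read_classic_otu <- function(path) {
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "#OTU ID"))
    stopf("not a classic OTU table (header must start with '#OTU ID'): %s", path)
  x <- read.table(path, sep = "\t", header = TRUE, comment.char = "",
                  check.names = FALSE, quote = "")
  taxa <- as.character(x[[1L]])
  if (anyDuplicated(taxa)) stopf("duplicate taxon ids in %s", path)
  m <- as.matrix(x[, -1L, drop = FALSE])
  rownames(m) <- taxa
  t(m)  # samples x taxa
}

read_biom_counts <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stopf("reading BIOM requires the 'biomformat' package")
  b <- biomformat::read_biom(path)
  m <- as(biomformat::biom_data(b), "matrix")  # taxa x samples
  t(m)
}

read_metadata <- function(path) {
  md <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  need <- c("sample_id", "site", "molecule", "x", "y")
  miss <- setdiff(need, names(md))
  if (length(miss))
    stopf("metadata %s lacks column(s): %s", path, paste(miss, collapse = ", "))
  if (anyDuplicated(md$sample_id)) stopf("duplicate sample ids in %s", path)
  rownames(md) <- md$sample_id
  md$sample_id <- NULL
  md
}

#' Read an environment table
#'
#' TSV with a `sample_id` column and numeric soil variables.
#'
#' @param path TSV path.
#' @param na_action `"error"` (default) refuses missing values;
#'   `"drop_samples"` removes incomplete samples with a warning.
#' @return an [env_table()].
#' @export
read_env <- function(path, na_action = c("error", "drop_samples")) {
  na_action <- match.arg(na_action)
  x <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  if (!"sample_id" %in% names(x)) stopf("env table %s lacks 'sample_id'", path)
  rownames(x) <- x$sample_id
  x$sample_id <- NULL
  if (!all(vapply(x, is.numeric, logical(1L))))
    stopf("non-numeric environment variable(s) in %s", path)
  if (anyNA(x)) {
    if (na_action == "error") stopf("missing values in %s", path)
    keep <- complete.cases(x)
    warnf("dropping %d incomplete sample(s) from %s", sum(!keep), path)
    x <- x[keep, , drop = FALSE]
  }
  env_table(as.matrix(x))
}

#' Write a community table and its metadata
#'
#' The counts go to a classic OTU TSV (or BIOM via \pkg{biomformat}); the
#' metadata to a TSV alongside. Writers are bit-stable given fixed inputs.
#'
#' @param tab a [community_table()].
#' @param path output path for the counts.
#' @param metadata_path optional output path for the metadata TSV.
#' @param format `"classic-tsv"` or `"biom"`.
#' @return `path`, invisibly.
#' @export
write_community <- function(tab, path, metadata_path = NULL,
                            format = c("classic-tsv", "biom")) {
  format <- match.arg(format)
  if (format == "classic-tsv") {
    m <- t(tab$counts)  # taxa x samples
    df <- data.frame("#OTU ID" = rownames(m), m, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stopf("writing BIOM requires the 'biomformat' package")
    b <- biomformat::make_biom(t(tab$counts))
    biomformat::write_biom(b, path)
  }
  if (!is.null(metadata_path)) {
    md <- data.frame(sample_id = rownames(tab$metadata), tab$metadata,
                     check.names = FALSE)
    write.table(md, metadata_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Write an environment table as TSV
#'
#' @param env an [env_table()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_env <- function(env, path) {
  df <- data.frame(sample_id = rownames(env$values), env$values,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a labeled square distance matrix
#'
#' @param x a [dist_matrix()] (for writing).
#' @param path TSV path.
#' @param kind,transform tags restored on reading.
#' @return `write_dist` returns `path` invisibly; `read_dist` a
#'   [dist_matrix()].
#' @export
write_dist <- function(x, path) {
  df <- data.frame(sample_id = rownames(x), unclass_dist(x), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dist
#' @export
read_dist <- function(path, kind, transform = "none") {
  x <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  rownames(x) <- x$sample_id
  x$sample_id <- NULL
  dist_matrix(as.matrix(x), kind = kind, transform = transform)
}
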