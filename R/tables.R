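#' Construct a community table
#'
#' A `community_table` holds a samples x taxa abundance matrix together with
#' per-sample metadata (site, molecule, x/y coordinates in meters). Raw
#' tables carry integer counts; rarefaction-averaged tables may hold
#' fractional counts whose rows sum to the rarefaction depth.
#'
#' @param counts numeric matrix, samples in rows, taxa in columns, with
#'   unique row (sample) and column (taxon) names; no negative entries.
#' @param metadata data.frame with one row per sample and columns
#'   `site`, `molecule`, `x`, `y`; row names (or a `sample_id` column)
#'   identify samples. Extra samples in `metadata` are dropped; samples in
#'   `counts` missing from `metadata` are an error.
#' @return an object of class `community_table` with elements `counts` and
#'   `metadata` (aligned to the row order of `counts`).
#' @export
community_table <- function(counts, metadata) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("counts must have sample row names and taxon column names")
  if (anyDuplicated(rownames(counts))) stopf("duplicate sample ids in counts")
  if (anyDuplicated(colnames(counts))) stopf("duplicate taxon ids in counts")
  if (any(counts < 0)) stopf("negative entries in counts")
  metadata <- as.data.frame(metadata)
  if ("sample_id" %in% names(metadata) &&
      anyDuplicated(metadata$sample_id) == 0) {
    rownames(metadata) <- metadata$sample_id
    metadata$sample_id <- NULL
  }
  need <- c("site", "molecule", "x", "y")
  miss <- setdiff(need, names(metadata))
  if (length(miss)) stopf("metadata lacks column(s): %s", paste(miss, collapse = ", "))
  absent <- setdiff(rownames(counts), rownames(metadata))
  if (length(absent))
    stopf("metadata missing for sample(s): %s", paste(absent, collapse = ", "))
  metadata <- metadata[rownames(counts), , drop = FALSE]
  structure(list(counts = counts, metadata = metadata),
            class = "community_table")
}

#' @export
print.community_table <- function(x, ...) {
  cat(sprintf("community_table: %d samples x %d taxa\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  sites: %s | molecules: %s\n",
              paste(unique(x$metadata$site), collapse = ", "),
              paste(unique(x$metadata$molecule), collapse = ", ")))
  cat(sprintf("  row sums: %s\n",
              paste(format(range(rowSums(x$counts)), digits = 6), collapse = " - ")))
  invisible(x)
}

#' @export
dim.community_table <- function(x) dim(x$counts)

sample_ids <- function(tab) rownames(tab$counts)
taxon_ids <- function(tab) colnames(tab$counts)

#' Subset a community table
#'
#' @param tab a [community_table()].
#' @param samples,taxa character, logical or integer indices; `NULL` keeps all.
#' @return a `community_table`.
#' @export
subset_table <- function(tab, samples = NULL, taxa = NULL) {
  counts <- tab$counts
  if (!is.null(samples)) counts <- counts[samples, , drop = FALSE]
  if (!is.null(taxa)) counts <- counts[, taxa, drop = FALSE]
  community_table(counts, tab$metadata[rownames(counts), , drop = FALSE])
}

#' Construct an environment table
#'
#' Numeric soil variables per sample (e.g. percent organic matter,
#' extractable P, pH, K, CEC, nitrate-N, S).
#'
#' @param values numeric matrix or data.frame, samples x variables, with
#'   sample row names and variable column names.
#' @return an object of class `env_table` with element `values`.
#' @export
env_table <- function(values) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stopf("env values must have sample row names and variable column names")
  if (anyNA(values)) stopf("missing values in environment table")
  structure(list(values = values), class = "env_table")
}

#' @export
print.env_table <- function(x, ...) {
  cat(sprintf("env_table: %d samples x %d variables (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(colnames(x$values), collapse = ", ")))
  invisible(x)
}

# ---- rarefaction ------------------------------------------------------------

# subsample one integer count vector to `depth` without replacement
rarefy_row <- function(row, depth) {
  pool <- rep.int(seq_along(row), row)
  tabulate(sample(pool, depth), nbins = length(row))
}

#' Rarefy a community table once
#'
#' Randomly subsamples each sample's counts, without replacement, to a
#' common depth, equalizing sampling effort. Samples whose total count is
#' below the depth are dropped with a warning (not an error), mirroring the
#' usual practice of excluding under-sequenced samples.
#'
#' @param tab a [community_table()] of raw integer counts.
#' @param depth integer rarefaction depth (> 0).
#' @param seed optional integer seed.
#' @return a `community_table` whose rows each sum exactly to `depth`.
#' @export
rarefy_once <- function(tab, depth, seed = NULL) {
  check_raref_input(tab, depth)
  tab <- drop_shallow(tab, depth)
  with_seed(seed, {
    out <- t(apply(tab$counts, 1L, rarefy_row, depth = depth))
    dimnames(out) <- dimnames(tab$counts)
    community_table(out, tab$metadata)
  })
}

#' Average repeated rarefactions of a community table
#'
#' Entrywise mean of `n_reps` independent rarefactions at `depth`. Averaging
#' stabilizes the subsampling noise of a single rarefaction; averaged counts
#' are fractional but every row still sums to `depth` (within numerical
#' tolerance). Deterministic given `seed`.
#'
#' @inheritParams rarefy_once
#' @param n_reps number of rarefaction replicates to average (default 100).
#' @return a `community_table` of averaged counts.
#' @export
rarefaction_average <- function(tab, depth, n_reps = 100, seed = NULL) {
  if (n_reps <= 0) stopf("n_reps must be positive")
  check_raref_input(tab, depth)
  tab <- drop_shallow(tab, depth)
  m <- ncol(tab$counts)
  with_seed(seed, {
    acc <- matrix(0, nrow(tab$counts), m, dimnames = dimnames(tab$counts))
    pools <- apply(tab$counts, 1L, function(r) rep.int(seq_len(m), r),
                   simplify = FALSE)
    for (rep in seq_len(n_reps)) {
      for (i in seq_along(pools)) {
        acc[i, ] <- acc[i, ] + tabulate(sample(pools[[i]], depth), nbins = m)
      }
    }
    community_table(acc / n_reps, tab$metadata)
  })
}

check_raref_input <- function(tab, depth) {
  if (depth <= 0) stopf("rarefaction depth must be positive")
  if (any(abs(tab$counts - round(tab$counts)) > 1e-8))
    stopf("rarefaction requires integer counts")
  invisible(TRUE)
}

drop_shallow <- function(tab, depth) {
  rs <- rowSums(tab$counts)
  low <- rs < depth
  if (any(low)) {
    warnf("dropping %d sample(s) below depth %d: %s",
          sum(low), depth, paste(rownames(tab$counts)[low], collapse = ", "))
    if (all(low)) stopf("all samples are below the rarefaction depth")
    tab <- subset_table(tab, samples = !low)
  }
  tab
}

# ---- richness & taxonomy ----------------------------------------------------

#' Per-sample taxon richness
#'
#' Number of taxa with abundance above a detection threshold in each sample.
#' On a rarefaction-averaged table the default threshold 0 counts a taxon as
#' detected if it was drawn in at least one rarefaction replicate.
#'
#' @param tab a [community_table()].
#' @param detection_threshold abundance strictly above which a taxon counts
#'   as detected (default 0).
#' @return named integer vector, one entry per sample.
#' @export
richness <- function(tab, detection_threshold = 0) {
  rowSums(tab$counts > detection_threshold)
}

#' Aggregate a community table to a taxonomic rank
#'
#' @param tab a [community_table()].
#' @param taxonomy named list or named character vector mapping taxon ids to
#'   lineage labels at `rank` (a data.frame with a `taxon_id` column plus
#'   rank columns is also accepted).
#' @param rank rank name, used when `taxonomy` is a data.frame (default
#'   `"phylum"`).
#' @param relative if `TRUE` rows are divided by their sums.
#' @return a `community_table` whose columns are rank labels; taxa absent
#'   from the map are pooled into `"Unassigned"` with a warning giving the
#'   count.
#' @export
aggregate_taxonomy <- function(tab, taxonomy, rank = "phylum", relative = FALSE) {
  if (is.data.frame(taxonomy)) {
    if (!all(c("taxon_id", rank) %in% names(taxonomy)))
      stopf("taxonomy data.frame needs columns 'taxon_id' and '%s'", rank)
    map <- setNames(as.character(taxonomy[[rank]]), taxonomy$taxon_id)
  } else map <- unlist(taxonomy)
  ids <- taxon_ids(tab)
  if (!length(intersect(ids, names(map))))
    stopf("no taxon of the table appears in the taxonomy map")
  labels <- map[ids]
  n_unmapped <- sum(is.na(labels))
  if (n_unmapped)
    warnf("%d unmapped taxa routed to 'Unassigned'", n_unmapped)
  labels[is.na(labels)] <- "Unassigned"
  agg <- t(rowsum(t(tab$counts), group = labels))
  if (relative) agg <- agg / rowSums(agg)
  community_table(agg, tab$metadata)
}
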