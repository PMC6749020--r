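# Homogenization-mechanism attribution: newcomer and bloomer
# identification, removal-and-recompute analyses, occurrence frequency,
# and the per-site mechanism report.

detected_taxa <- function(tab, threshold = 0) {
  taxon_ids(tab)[colSums(tab$counts > threshold) > 0]
}

taxon_set <- function(ids, provenance, reference_tab, target_tab,
                      threshold = 0) {
  rel <- target_tab$counts / rowSums(target_tab$counts)
  structure(list(
    taxa = ids,
    provenance = provenance,
    mean_rel_abund = if (length(ids))
      colMeans(rel[, ids, drop = FALSE]) else numeric(),
    freq_reference = occurrence_frequency(reference_tab, ids, threshold),
    freq_target = occurrence_frequency(target_tab, ids, threshold)),
    class = "taxon_set")
}

#' @export
print.taxon_set <- function(x, ...) {
  cat(sprintf("%s set: %d taxa, mean collective share %.3f%%\n",
              x$provenance, length(x$taxa),
              100 * sum(x$mean_rel_abund)))
  if (length(x$taxa))
    cat(sprintf("  occurrence frequency: reference %.3f, target %.3f\n",
                x$freq_reference$mean, x$freq_target$mean))
  invisible(x)
}

#' Identify newcomer taxa
#'
#' Taxa detected (abundance above the threshold in at least one sample) in
#' the converted (target) site but in no sample of the reference (forest)
#' site. On rarefaction-averaged tables the default threshold 0 counts a
#' taxon as detected if it was drawn in at least one rarefaction; a strict
#' mode requires presence in at least `min_reps` of `n_reps` rarefactions,
#' i.e. an averaged count above `min_reps / n_reps`.
#'
#' @param target,reference rarefaction-averaged [community_table()]s on a
#'   shared taxon universe.
#' @param threshold detection threshold on the averaged count (default 0).
#' @param min_reps,n_reps optional strict detection rule (overrides
#'   `threshold` with `min_reps / n_reps - 1e-9`).
#' @return a `taxon_set` (provenance `"newcomer"`) with per-taxon mean
#'   relative abundance in the target and occurrence frequencies.
#' @export
identify_newcomers <- function(target, reference, threshold = 0,
                               min_reps = NULL, n_reps = 100) {
  if (!nrow(target$counts) || !nrow(reference$counts))
    stopf("empty community table")
  if (!is.null(min_reps)) threshold <- min_reps / n_reps - 1e-9
  in_target <- detected_taxa(target, threshold)
  in_ref <- detected_taxa(reference, threshold)
  taxon_set(setdiff(in_target, in_ref), "newcomer", reference, target,
            threshold)
}

#' Identify bloomer taxa
#'
#' Runs the negative-binomial Wald test of the target site against the
#' reference on raw counts and keeps taxa with a positive log2 fold change
#' at BH-adjusted p below `alpha`. By default, candidates are restricted
#' to taxa detected in the reference site -- bloomers are conversions'
#' range expansions of resident taxa, and this keeps the bloomer set
#' disjoint from the newcomer set.
#'
#' @param target,reference raw-count [community_table()]s on a shared
#'   taxon universe.
#' @param alpha adjusted-p threshold (default 0.05).
#' @param require_reference_presence restrict to reference-detected taxa
#'   (default `TRUE`).
#' @param ... further arguments to [nb_wald()] (e.g. `min_sample_depth`).
#' @return a `taxon_set` (provenance `"bloomer"`) with the `diffabund`
#'   result attached as attribute `"diffabund"`.
#' @export
identify_bloomers <- function(target, reference, alpha = 0.05,
                              require_reference_presence = TRUE, ...) {
  if (!identical(taxon_ids(target), taxon_ids(reference)))
    stopf("target and reference must share one taxon universe")
  counts <- rbind(reference$counts, target$counts)
  groups <- factor(rep(c("reference", "target"),
                       c(nrow(reference$counts), nrow(target$counts))),
                   levels = c("reference", "target"))
  da <- nb_wald(counts, groups, ...)
  res <- da$results
  sig <- res$taxon[!is.na(res$padj) & res$padj < alpha & res$log2FoldChange > 0]
  if (require_reference_presence)
    sig <- intersect(sig, detected_taxa(reference))
  out <- taxon_set(sig, "bloomer", reference, target)
  attr(out, "diffabund") <- da
  out
}

#' Occurrence frequency of taxa across a site's samples
#'
#' Fraction of the site's samples in which each taxon is detected.
#'
#' @param tab a [community_table()].
#' @param taxa character vector of taxon ids (or a `taxon_set`).
#' @param threshold detection threshold (default 0).
#' @return list with per-taxon `freq`, plus `mean` and `sem`.
#' @export
occurrence_frequency <- function(tab, taxa, threshold = 0) {
  if (inherits(taxa, "taxon_set")) taxa <- taxa$taxa
  taxa <- intersect(taxa, taxon_ids(tab))
  if (!length(taxa))
    return(list(freq = numeric(), mean = NA_real_, sem = NA_real_))
  freq <- colMeans(tab$counts[, taxa, drop = FALSE] > threshold)
  list(freq = freq, mean = mean(freq),
       sem = if (length(freq) > 1L) sem(freq) else 0)
}

#' Remove a taxon set, re-rarefy, and recompute similarity and decay
#'
#' Drops the given taxa from a raw community table, re-equalizes sampling
#' extent by rarefaction averaging, and recomputes mean pairwise Canberra
#' similarity and the distance-decay fit, packaging the before and after
#' states. If removal leaves some sample below the rarefaction depth, the
#' depth is lowered to the minimum remaining row sum (logged as a warning);
#' a sample emptied by removal is an error.
#'
#' @param tab raw-count [community_table()].
#' @param remove taxa to remove (character vector or `taxon_set`).
#' @param depth rarefaction depth.
#' @param n_reps rarefactions averaged (default 100).
#' @param n_perm Mantel permutations for the decay fits (default 999).
#' @param seed integer master seed (stage seeds derived by offset). The
#'   same seed drives the before and after rarefactions.
#' @return list of class `removal_analysis` with `before` and `after`,
#'   each holding `similarity` (list mean/sem/n_pairs/pairs), `decay`
#'   (a [decay_fit()]) and the averaged table; plus the removed ids and
#'   the depth actually used.
#' @export
removal_analysis <- function(tab, remove, depth, n_reps = 100, n_perm = 999,
                             seed = 1) {
  if (inherits(remove, "taxon_set")) remove <- remove$taxa
  remove <- intersect(remove, taxon_ids(tab))
  if (length(remove) == ncol(tab$counts)) stopf("cannot remove every taxon")
  reduced <- subset_table(tab, taxa = setdiff(taxon_ids(tab), remove))
  rs <- rowSums(reduced$counts)
  if (any(rs == 0))
    stopf("removal empties sample(s): %s",
          paste(rownames(reduced$counts)[rs == 0], collapse = ", "))
  used_depth <- depth
  if (min(rs) < depth) {
    used_depth <- min(rs)
    warnf("removal leaves a sample below depth %d; lowering depth to %d",
          depth, used_depth)
  }
  state <- function(t) {
    avg <- rarefaction_average(t, used_depth, n_reps,
                               seed = derive_seed(seed, 11))
    d <- canberra(avg)
    geo <- geographic(avg)
    list(similarity = mean_pairwise_similarity(d),
         decay = decay_fit(as_similarity(d), geo, n_perm = n_perm,
                           seed = derive_seed(seed, 12)),
         table = avg)
  }
  structure(list(before = state(tab), after = state(reduced),
                 removed = remove, depth = used_depth),
            class = "removal_analysis")
}

#' @export
print.removal_analysis <- function(x, ...) {
  cat(sprintf("removal of %d taxa (depth %d):\n", length(x$removed), x$depth))
  cat(sprintf("  similarity %.3f +/- %.3f -> %.3f +/- %.3f\n",
              x$before$similarity$mean, x$before$similarity$sem,
              x$after$similarity$mean, x$after$similarity$sem))
  cat(sprintf("  decay slope %.4g (Mantel p %.3g) -> %.4g (Mantel p %.3g)\n",
              x$before$decay$slope, x$before$decay$mantel_p,
              x$after$decay$slope, x$after$decay$mantel_p))
  invisible(x)
}

# Verdict rule, made explicit: a taxon set "contributes" to homogenization
# iff its removal significantly lowers mean within-site similarity (Tukey,
# removed vs all-taxa) AND the post-removal similarity is not still
# significantly above the forest level (Tukey, removed vs forest).
verdict_contributes <- function(forest_pairs, all_pairs, removed_pairs,
                                alpha = 0.05) {
  groups <- list(forest = forest_pairs, all = all_pairs, removed = removed_pairs)
  tk <- tukey_hsd(groups)
  row_of <- function(a, b) {
    hit <- tk$contrast %in% c(paste(a, b, sep = "-"), paste(b, a, sep = "-"))
    tk[hit, , drop = FALSE]
  }
  ra <- row_of("removed", "all")
  rf <- row_of("removed", "forest")
  lowered <- mean(removed_pairs) < mean(all_pairs) && ra$p_adj < alpha
  above_forest <- mean(removed_pairs) > mean(forest_pairs) && rf$p_adj < alpha
  list(contributes = lowered && !above_forest,
       lowered = lowered, above_forest = above_forest, tukey = tk)
}

#' Mechanism report for a converted site
#'
#' Runs the full mechanism-attribution analysis for one forest/target
#' pair and both molecules: identifies newcomers (on rarefaction-averaged
#' tables) and bloomers (NB Wald on raw counts), performs the
#' removal-and-recompute analysis for each set, and issues a per-mechanism
#' verdict. A set "contributes" to homogenization when its removal
#' significantly decreases mean pairwise similarity (Tukey, alpha = 0.05)
#' and leaves similarity not significantly above the forest level.
#'
#' @param forest,target lists with `rna` and `dna` raw-count
#'   [community_table()]s on a shared taxon universe.
#' @param depth rarefaction depth (default 3790).
#' @param n_reps rarefactions averaged (default 100).
#' @param n_perm Mantel permutations (default 999).
#' @param alpha significance level for bloomer identification and verdicts.
#' @param seed integer master seed.
#' @param molecules which layers to analyze (default both).
#' @return object of class `mechanism_report`: per molecule, the newcomer
#'   and bloomer `taxon_set`s, their `removal_analysis` results, forest
#'   similarity summaries, and verdicts.
#' @export
mechanism_report <- function(forest, target, depth = 3790, n_reps = 100,
                             n_perm = 999, alpha = 0.05, seed = 1,
                             molecules = c("rna", "dna")) {
  out <- list(depth = depth, seed = seed)
  for (mol in molecules) {
    f_raw <- forest[[mol]]; t_raw <- target[[mol]]
    f_avg <- rarefaction_average(f_raw, depth, n_reps,
                                 seed = derive_seed(seed, 21))
    t_avg <- rarefaction_average(t_raw, depth, n_reps,
                                 seed = derive_seed(seed, 22))
    forest_sim <- mean_pairwise_similarity(canberra(f_avg))

    newcomers <- identify_newcomers(t_avg, f_avg)
    bloomers <- identify_bloomers(t_raw, f_raw, alpha = alpha,
                                  min_sample_depth = depth)
    res <- list(forest_similarity = forest_sim,
                newcomers = newcomers, bloomers = bloomers)
    for (set_name in c("newcomers", "bloomers")) {
      set <- res[[set_name]]
      ra <- removal_analysis(t_raw, set, depth, n_reps = n_reps,
                             n_perm = n_perm, seed = derive_seed(seed, 23))
      v <- verdict_contributes(forest_sim$pairs,
                               ra$before$similarity$pairs,
                               ra$after$similarity$pairs, alpha = alpha)
      res[[paste0(set_name, "_removal")]] <- ra
      res[[paste0(set_name, "_verdict")]] <- v
    }
    out[[mol]] <- res
  }
  structure(out, class = "mechanism_report")
}

#' @export
print.mechanism_report <- function(x, ...) {
  cat("mechanism report\n")
  for (mol in intersect(c("rna", "dna"), names(x))) {
    r <- x[[mol]]
    cat(sprintf("[%s] forest similarity %.3f +/- %.3f\n", toupper(mol),
                r$forest_similarity$mean, r$forest_similarity$sem))
    for (set_name in c("newcomers", "bloomers")) {
      ra <- r[[paste0(set_name, "_removal")]]
      v <- r[[paste0(set_name, "_verdict")]]
      cat(sprintf("  %s (%d taxa): similarity %.3f -> %.3f | contribute: %s\n",
                  set_name, length(r[[set_name]]$taxa),
                  ra$before$similarity$mean, ra$after$similarity$mean,
                  if (v$contributes) "yes" else "no"))
    }
  }
  invisible(x)
}

#' Serialize a mechanism report
#'
#' @param report a [mechanism_report()].
#' @param path output path (`.json`); a sibling `.tsv` summary is written
#'   alongside when `tsv = TRUE`.
#' @param tsv also write a per-molecule TSV summary.
#' @return `path`, invisibly.
#' @export
write_mechanism_report <- function(report, path, tsv = TRUE) {
  summarize <- function(mol) {
    r <- report[[mol]]
    do.call(rbind, lapply(c("newcomers", "bloomers"), function(s) {
      ra <- r[[paste0(s, "_removal")]]
      v <- r[[paste0(s, "_verdict")]]
      data.frame(molecule = toupper(mol), set = s,
                 n_taxa = length(r[[s]]$taxa),
                 collective_share = sum(r[[s]]$mean_rel_abund),
                 freq_reference = r[[s]]$freq_reference$mean,
                 freq_target = r[[s]]$freq_target$mean,
                 similarity_all = ra$before$similarity$mean,
                 similarity_removed = ra$after$similarity$mean,
                 similarity_forest = r$forest_similarity$mean,
                 decay_slope_all = ra$before$decay$slope,
                 decay_p_all = ra$before$decay$mantel_p,
                 decay_slope_removed = ra$after$decay$slope,
                 decay_p_removed = ra$after$decay$mantel_p,
                 contributes = v$contributes)
    }))
  }
  mols <- intersect(c("rna", "dna"), names(report))
  tab <- do.call(rbind, lapply(mols, summarize))
  jsonlite::write_json(list(depth = report$depth, seed = report$seed,
                            summary = tab),
                       path, auto_unbox = TRUE, digits = NA)
  if (tsv)
    write.table(tab, sub("\\.json$", ".tsv", path), sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(path)
}
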