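#' Pair-based confusion counts for a clustering against species labels
#'
#' Counts unordered ASV pairs: `TP` = pairs in the same cluster and the
#' same species; `NP` = all within-cluster pairs (summed over clusters);
#' `FP = NP - TP`; `FN` = same-species pairs split across clusters. ASVs
#' without a species label (missing or uncertain annotation) are excluded
#' with a warning.
#'
#' @param clusters data.frame with `asv_id`, `otu_id`.
#' @param labels Named character vector mapping ASV id to species label.
#' @return List of class `pair_counts` with `TP`, `FP`, `FN`, `NP`.
#' @export
pair_counts <- function(clusters, labels) {
  lab <- labels[clusters$asv_id]
  ok <- !is.na(lab) & nzchar(lab) & !is_uncertain(lab)
  if (any(!ok)) {
    warning(sum(!ok), " ASV(s) without species labels excluded from ",
            "pair counting")
  }
  cl <- clusters$otu_id[ok]
  sp <- unname(lab[ok])
  choose2 <- function(n) n * (n - 1) / 2
  np <- sum(choose2(table(cl)))
  tp <- sum(choose2(table(paste(cl, sp, sep = "\r"))))
  same_sp <- sum(choose2(table(sp)))
  structure(list(TP = tp, FP = np - tp, FN = same_sp - tp, NP = np),
            class = "pair_counts")
}

#' Precision, recall and F-score from pair counts
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`, and the
#' F-score is their harmonic mean. A 0/0 denominator yields 1.0 with a
#' warning (the trivially perfect case); the F-score is `NA` when
#' precision + recall is zero.
#'
#' @param pc A `pair_counts` object (or a list with `TP`, `FP`, `FN`).
#' @return Named numeric vector `precision`, `recall`, `f_score`.
#' @export
precision_recall <- function(pc) {
  stopifnot(pc$TP >= 0, pc$FP >= 0, pc$FN >= 0)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (0/0); reported as 1.0")
      1.0
    } else num / den
  }
  p <- safe_div(pc$TP, pc$TP + pc$FP, "precision")
  r <- safe_div(pc$TP, pc$TP + pc$FN, "recall")
  f <- if (p + r == 0) NA_real_ else 2 * p * r / (p + r)
  c(precision = p, recall = r, f_score = f)
}

#' ASVs identical to reference-library sequences
#'
#' Identifies "trusted" ASVs: those whose sequence matches a curated
#' reference barcode exactly over the full length.
#'
#' @param asvs data.frame as returned by [read_fasta()].
#' @param reference Character vector of reference sequences (or a
#'   data.frame with a `sequence` column).
#' @return Character vector of trusted ASV ids.
#' @export
trusted_asvs <- function(asvs, reference) {
  refs <- if (is.data.frame(reference)) reference$sequence else reference
  asvs$asv_id[asvs$sequence %in% toupper(refs)]
}

#' Benchmark metrics for a filtering step
#'
#' Summarizes the effect of removing ASVs from a dataset: counts and read
#' sums removed, the share of removed ASVs that were abundant (occupancy
#' greater than one sample), the fraction of trusted ASVs (reference-
#' identical) removed, and clustering-quality metrics on the retained
#' data: cluster-to-species ratio, number of species split over multiple
#' clusters ("multicluster species"), and pair-based precision / recall /
#' F-score.
#'
#' @param counts Integer ASV x sample count matrix of the full ("before")
#'   dataset.
#' @param removed_ids ASVs removed by the filtering step.
#' @param clusters data.frame with `asv_id`, `otu_id` covering the
#'   retained ASVs (used for the clustering metrics); `NULL` skips them.
#' @param labels Named character vector of species labels per ASV.
#' @param trusted_ids Character vector of trusted ASV ids; `NULL` or
#'   empty reports the trusted metrics as `NA`.
#' @return data.frame with columns `metric`, `value`.
#' @export
benchmark_metrics <- function(counts, removed_ids, clusters = NULL,
                              labels = NULL, trusted_ids = NULL) {
  removed_ids <- intersect(removed_ids, rownames(counts))
  occ <- rowSums(counts > 0)
  n_removed <- length(removed_ids)
  pct_abundant <- if (n_removed == 0L) 0 else
    100 * sum(occ[removed_ids] > 1) / n_removed
  reads_removed <- sum(counts[removed_ids, , drop = FALSE])
  if (is.null(trusted_ids) || length(trusted_ids) == 0L) {
    pct_trusted <- NA_real_
    trusted_reads <- NA_real_
  } else {
    pct_trusted <- 100 * length(intersect(removed_ids, trusted_ids)) /
      length(trusted_ids)
    trusted_reads <- sum(counts[intersect(removed_ids, trusted_ids), ,
                                drop = FALSE])
  }
  out <- data.frame(
    metric = c("asvs_removed", "pct_abundant_removed", "pct_trusted_removed",
               "reads_removed", "trusted_reads_removed"),
    value = c(n_removed, pct_abundant, pct_trusted, reads_removed,
              trusted_reads),
    stringsAsFactors = FALSE)
  if (!is.null(clusters) && !is.null(labels)) {
    keep_cl <- clusters[!clusters$asv_id %in% removed_ids, , drop = FALSE]
    lab <- labels[keep_cl$asv_id]
    ok <- !is.na(lab) & nzchar(lab) & !is_uncertain(lab)
    n_species <- length(unique(lab[ok]))
    n_clusters <- length(unique(keep_cl$otu_id))
    multi <- sum(vapply(split(keep_cl$otu_id[ok], lab[ok]),
                        function(x) length(unique(x)) > 1L, logical(1)))
    pc <- pair_counts(keep_cl, labels)
    pr <- precision_recall(pc)
    out <- rbind(out, data.frame(
      metric = c("cluster_species_ratio", "multicluster_species",
                 "precision", "recall", "f_score"),
      value = c(if (n_species > 0) n_clusters / n_species else NA_real_,
                multi, pr[["precision"]], pr[["recall"]],
                pr[["f_score"]]),
      stringsAsFactors = FALSE))
  }
  out
}
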