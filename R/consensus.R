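#' Consensus taxonomy parameters
#'
#' @param threshold Read-weighted share a label must reach to win a rank
#'   (strictly above 0.5, at most 1; compared with `>=`).
#' @param mode `"consensus"` (read-weighted vote) or `"representative"`
#'   (copy the representative ASV's annotation).
#' @return List of class `consensus_params`.
#' @export
consensus_params <- function(threshold = 0.80,
                             mode = c("consensus", "representative")) {
  stopifnot(threshold > 0.5, threshold <= 1)
  structure(list(threshold = threshold, mode = match.arg(mode)),
            class = "consensus_params")
}

#' Representative ASV of a cluster
#'
#' The member with the highest mean (default) or median read number
#' across all samples (zeros included). Ties are broken by total reads,
#' then by ascending ASV id.
#'
#' @param members Character vector of member ASV ids (non-empty).
#' @param counts Integer ASV x sample count matrix.
#' @param rule `"mean"` or `"median"`.
#' @return The representative ASV id.
#' @export
representative_asv <- function(members, counts, rule = c("mean", "median")) {
  rule <- match.arg(rule)
  stopifnot(length(members) > 0L, all(members %in% rownames(counts)))
  sub <- counts[members, , drop = FALSE]
  stat <- if (rule == "mean") rowMeans(sub)
          else apply(sub, 1L, stats::median)
  tot <- rowSums(sub)
  members[order(-stat, -tot, members, method = "radix")][1L]
}

#' Read-weighted consensus taxonomy for a cluster
#'
#' Iterates from the lowest (most resolved) rank to the highest. At each
#' rank the member labels are weighted by the members' total read counts;
#' if the top label's weighted share reaches the threshold it is adopted,
#' the parent-rank lineage is copied from the winning members, and every
#' child rank is set to `"unresolved."` plus the winning label. If no
#' label reaches the threshold the vote moves up one rank; if even the
#' highest rank fails, all ranks are `"unresolved"` (with a warning).
#'
#' Uncertain labels take part in the vote literally, so a cluster
#' dominated by `"unassigned.X"` members resolves to that label (which
#' remains uncertain for downstream filters).
#'
#' @param members Character vector of member ASV ids.
#' @param counts Integer ASV x sample count matrix.
#' @param taxa Character matrix of ASV-level taxonomy (rows named by ASV
#'   id, columns = ranks from highest to lowest).
#' @param params A [consensus_params()] object.
#' @return Named character vector of labels over the ranks of `taxa`. The
#'   attribute `shares` holds, for each rank visited, the winning label's
#'   weighted share.
#' @export
consensus_taxonomy <- function(members, counts, taxa,
                               params = consensus_params()) {
  stopifnot(inherits(params, "consensus_params"),
            all(members %in% rownames(taxa)),
            all(members %in% rownames(counts)))
  ranks <- colnames(taxa)
  if (params$mode == "representative") {
    rep_asv <- representative_asv(members, counts)
    out <- taxa[rep_asv, ]
    names(out) <- ranks
    return(out)
  }
  w <- rowSums(counts[members, , drop = FALSE])
  if (sum(w) == 0) w <- rep(1, length(members))  # zero-read degenerate case
  shares_seen <- numeric(0)
  for (r in rev(seq_along(ranks))) {
    labels <- taxa[members, ranks[r]]
    share <- tapply(w, labels, sum) / sum(w)
    top <- which.max(share)
    shares_seen[ranks[r]] <- share[[top]]
    if (share[[top]] >= params$threshold) {
      win <- names(share)[top]
      winners <- members[labels == win]
      src <- winners[order(-rowSums(counts[winners, , drop = FALSE]),
                           winners, method = "radix")][1L]
      out <- character(length(ranks))
      names(out) <- ranks
      if (r > 1L) out[seq_len(r - 1L)] <- taxa[src, seq_len(r - 1L)]
      out[r] <- win
      if (r < length(ranks)) {
        out[(r + 1L):length(ranks)] <- paste0("unresolved.", win)
      }
      attr(out, "shares") <- shares_seen
      return(out)
    }
  }
  warning("no rank reached the consensus threshold; all ranks unresolved")
  out <- stats::setNames(rep("unresolved", length(ranks)), ranks)
  attr(out, "shares") <- shares_seen
  out
}

#' Consensus taxonomy for every cluster
#'
#' Applies [consensus_taxonomy()] (or the representative-ASV rule) to each
#' OTU and returns an OTU-level taxonomy table.
#'
#' @param clusters data.frame with `asv_id`, `otu_id`.
#' @param counts Integer ASV x sample count matrix.
#' @param taxa ASV-level taxonomy matrix.
#' @param params A [consensus_params()] object.
#' @param rep_rule Representative-ASV rule recorded alongside.
#' @return Character matrix, rows named by OTU id, columns = ranks, with
#'   attribute `representative` (named vector of representative ASVs).
#' @export
otu_taxonomy <- function(clusters, counts, taxa,
                         params = consensus_params(),
                         rep_rule = c("mean", "median")) {
  rep_rule <- match.arg(rep_rule)
  otus <- sort(unique(clusters$otu_id))
  rows <- lapply(otus, function(o) {
    members <- clusters$asv_id[clusters$otu_id == o]
    consensus_taxonomy(members, counts, taxa, params)
  })
  m <- do.call(rbind, lapply(rows, function(x) { attributes(x) <- NULL; x }))
  dimnames(m) <- list(otus, colnames(taxa))
  reps <- vapply(otus, function(o) {
    representative_asv(clusters$asv_id[clusters$otu_id == o], counts,
                       rule = rep_rule)
  }, character(1))
  attr(m, "representative") <- reps
  m
}

#' Normalize uncertain labels down a lineage
#'
#' For each rank with an uncertain bare label: if the next-higher rank
#' carries a taxon `T`, the cell becomes `"unassigned.T"`; if the
#' next-higher rank is itself uncertain, its label is copied down
#' verbatim. Already-prefixed labels are left untouched.
#'
#' @param row Named character vector of labels, highest rank first.
#' @return The normalized row.
#' @export
propagate_unassigned <- function(row) {
  n <- length(row)
  if (n < 2L) return(row)
  bare <- function(x) is.na(x) | !nzchar(x) | x == "unassigned"
  for (i in 2:n) {
    if (bare(row[i])) {
      parent <- row[i - 1L]
      row[i] <- if (is_uncertain(parent)) parent
                else paste0("unassigned.", parent)
    }
  }
  row
}

#' Negative-control filter
#'
#' Discards clusters occurring in more than `max_fraction` of the
#' negative-control samples of any dataset. Applied per dataset; datasets
#' without negative controls are skipped with a warning.
#'
#' @param clusters data.frame with `asv_id`, `otu_id`.
#' @param counts Integer ASV x sample count matrix.
#' @param metadata data.frame from [read_sample_metadata()].
#' @param max_fraction Maximum tolerated fraction (strict `>` discards).
#' @return A filter report over all OTUs.
#' @export
filter_negative_controls <- function(clusters, counts, metadata,
                                     max_fraction = 0.1) {
  oc <- otu_counts(clusters, counts)
  metadata <- metadata[metadata$sample_id %in% colnames(oc), , drop = FALSE]
  frac <- matrix(0, nrow = nrow(oc), ncol = 0)
  for (d in unique(metadata$dataset)) {
    negs <- metadata$sample_id[metadata$dataset == d &
                                 metadata$is_negative_control]
    if (length(negs) == 0L) {
      warning("dataset '", d, "' has no negative controls; filter inert")
      next
    }
    f <- rowSums(oc[, negs, drop = FALSE] > 0) / length(negs)
    frac <- cbind(frac, f)
  }
  worst <- if (ncol(frac) == 0L) rep(0, nrow(oc)) else apply(frac, 1L, max)
  filter_report(rownames(oc),
                ifelse(worst > max_fraction, "discard", "keep"),
                "negative_controls",
                sprintf("max_neg_fraction=%s", format(worst)))
}

#' Spike-in filter
#'
#' Removes clusters corresponding to biological spike-in controls, either
#' by an explicit list of species/BIN labels (matched against the
#' cluster-level species annotation) or by an occurrence rule: clusters
#' annotated to a stated higher taxon and occupying more than
#' `occurrence_pct` percent of samples are deemed spike-ins.
#'
#' @param clusters data.frame with `asv_id`, `otu_id`.
#' @param taxa Character matrix of OTU-level taxonomy (rows named by OTU
#'   id).
#' @param counts Integer ASV x sample count matrix.
#' @param species Optional character vector of spike-in species/BIN
#'   labels (list mode).
#' @param taxon,occurrence_pct Optional higher taxon and percent
#'   occupancy threshold (occurrence mode).
#' @param species_rank,taxon_rank Ranks at which `species` and `taxon`
#'   are matched.
#' @return A filter report over all OTUs.
#' @export
filter_spikeins <- function(clusters, taxa, counts, species = NULL,
                            taxon = NULL, occurrence_pct = NULL,
                            species_rank = "Species",
                            taxon_rank = "Genus") {
  oc <- otu_counts(clusters, counts)
  otus <- rownames(oc)
  stopifnot(all(otus %in% rownames(taxa)))
  hit <- stats::setNames(rep(FALSE, length(otus)), otus)
  why <- stats::setNames(rep("", length(otus)), otus)
  if (!is.null(species)) {
    lab <- taxa[otus, species_rank]
    absent <- setdiff(species, lab)
    if (length(absent) > 0L) {
      warning("spike-in label(s) absent from data: ",
              paste(absent, collapse = ", "))
    }
    m <- lab %in% species
    hit[m] <- TRUE
    why[m] <- paste0("listed:", lab[m])
  }
  if (!is.null(taxon)) {
    stopifnot(!is.null(occurrence_pct))
    occ_pct <- 100 * rowSums(oc > 0) / ncol(oc)
    m <- taxa[otus, taxon_rank] == taxon & occ_pct > occurrence_pct
    hit[m] <- TRUE
    why[m] <- sprintf("occurrence:%.1f%%", occ_pct[m])
  }
  filter_report(otus, ifelse(hit, "discard", "keep"), "spikein", why)
}
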