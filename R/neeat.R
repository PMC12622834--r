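#' Echo filter parameters
#'
#' @param n_closest Number of closest authentic neighbors examined.
#' @param min_match Minimum percent identity for a neighbor (0-100].
#' @param min_overlap Minimum fraction of the candidate echo's occupied
#'   samples that must be shared with the parent (0-1].
#' @param require_corr Use a read-number regression when parent and echo
#'   co-occur in more than three samples.
#' @param max_p_val Significance level for the regression slope.
#' @param max_read_ratio Maximum echo/parent read ratio (or regression
#'   slope) compatible with an echo.
#' @param read_ratio_type Summarize per-sample read ratios by `"max"` or
#'   `"mean"`.
#' @return List of class `echo_params`.
#' @export
echo_params <- function(n_closest = 10L, min_match = 84, min_overlap = 0.95,
                        require_corr = TRUE, max_p_val = 0.05,
                        max_read_ratio = 1.0,
                        read_ratio_type = c("max", "mean")) {
  stopifnot(min_match > 0, min_match <= 100, min_overlap > 0,
            min_overlap <= 1, max_read_ratio > 0, n_closest >= 1)
  structure(list(n_closest = as.integer(n_closest), min_match = min_match,
                 min_overlap = min_overlap, require_corr = require_corr,
                 max_p_val = max_p_val, max_read_ratio = max_read_ratio,
                 read_ratio_type = match.arg(read_ratio_type)),
            class = "echo_params")
}

#' Evolutionary-signature filter parameters
#'
#' @param dist_type Evolutionary distance, `"wdadn"` (biochemically
#'   weighted) or `"dadn"` (unweighted).
#' @param dist_threshold Flag an OTU when
#'   `dist_value / edit_distance > dist_threshold`.
#' @param require_overlap Local mode: additionally require a minimum
#'   sample overlap with the neighbor.
#' @param min_overlap Minimum sample-overlap fraction in local mode.
#' @param n_closest,min_match Neighbor selection, as in [echo_params()].
#' @return List of class `evo_params`.
#' @export
evo_params <- function(dist_type = c("wdadn", "dadn"), dist_threshold = 1.0,
                       require_overlap = TRUE, min_overlap = 0.95,
                       n_closest = 10L, min_match = 84) {
  stopifnot(dist_threshold > 0)
  structure(list(dist_type = match.arg(dist_type),
                 dist_threshold = dist_threshold,
                 require_overlap = require_overlap,
                 min_overlap = min_overlap,
                 n_closest = as.integer(n_closest), min_match = min_match),
            class = "evo_params")
}

#' Abundance filter parameters
#'
#' @param cutoff Minimum read-number statistic an OTU must reach to be
#'   kept; OTUs strictly below the cutoff are discarded.
#' @param cutoff_type `"max"` (maximum reads in any sample; default),
#'   `"sum"` (total reads) or `"mean"` (mean reads over occupied samples).
#' @return List of class `abundance_params`.
#' @export
abundance_params <- function(cutoff = 3,
                             cutoff_type = c("max", "sum", "mean")) {
  stopifnot(cutoff >= 0)
  structure(list(cutoff = cutoff, cutoff_type = match.arg(cutoff_type)),
            class = "abundance_params")
}

#' Taxonomic annotation filter parameters
#'
#' @param assignment_rank Rank at which an uncertain annotation discards
#'   the OTU.
#' @return List of class `tax_filter_params`.
#' @export
tax_filter_params <- function(assignment_rank = "Order") {
  structure(list(assignment_rank = assignment_rank),
            class = "tax_filter_params")
}

#' Order OTUs for the authenticity sweep
#'
#' OTUs are sorted by number of occupied samples (primary criterion) and
#' total read number (secondary criterion), both descending, with ties
#' broken by ascending OTU id. The sweep filters treat earlier OTUs as
#' candidate parents of later ones.
#'
#' @param clusters data.frame with `asv_id`, `otu_id`.
#' @param counts Integer ASV x sample count matrix.
#' @return Character vector of OTU ids, most dominant first.
#' @export
order_otus <- function(clusters, counts) {
  if (nrow(clusters) == 0L) return(character(0))
  st <- otu_stats(clusters, counts)
  st$otu_id[order(-st$n_samples, -st$total_reads, st$otu_id,
                  method = "radix")]
}

# shared neighbor selection for the sweep filters: previously-authentic
# OTUs within min_match, ranked by identity descending (ties by authentic
# order), truncated to n_closest
select_neighbors <- function(otu, authentic, mlx, min_match, n_closest) {
  nb <- intersect(mlx$neighbors(otu), authentic)
  if (length(nb) == 0L) return(character(0))
  pid <- vapply(nb, function(p) mlx$lookup(otu, p)[1L], numeric(1))
  keep <- pid >= min_match
  nb <- nb[keep]; pid <- pid[keep]
  if (length(nb) == 0L) return(character(0))
  pos <- match(nb, authentic)
  nb <- nb[order(-pid, pos)]
  utils::head(nb, n_closest)
}

#' Echo filter
#'
#' Sweeps OTUs from most to least dominant (see [order_otus()]); the top
#' OTU is regarded as authentic. Each later OTU is compared to its
#' `n_closest` previously identified authentic neighbors within
#' `min_match` percent identity. An OTU is flagged as an echo of a
#' neighbor when it co-occurs with it in at least `min_overlap` of its
#' occupied samples and its read numbers track the neighbor's at a low
#' ratio: either an ordinary least-squares regression of echo reads on
#' parent reads over the shared samples with a significant slope below
#' `max_read_ratio` (when `require_corr` and more than three shared
#' samples), or a per-sample read ratio summary below `max_read_ratio`.
#' Flagged OTUs are discarded; the rest join the authentic set.
#'
#' @param clusters data.frame with `asv_id`, `otu_id`.
#' @param counts Integer ASV x sample count matrix.
#' @param matchlist Match list between OTU representative sequences, keyed
#'   by OTU id (percent identities).
#' @param params An [echo_params()] object.
#' @return A filter report over all OTUs.
#' @export
echo_filter <- function(clusters, counts, matchlist,
                        params = echo_params()) {
  stopifnot(inherits(params, "echo_params"))
  ord <- order_otus(clusters, counts)
  if (length(ord) == 0L) return(filter_report(character(0), character(0),
                                              "echo"))
  oc <- otu_counts(clusters, counts)
  mlx <- matchlist_index(matchlist)
  no_match <- setdiff(ord, ord[vapply(ord, mlx$has, logical(1))])
  if (length(no_match) > 0L) {
    warning(length(no_match), " OTU(s) absent from match list treated as ",
            "having no neighbors")
  }
  authentic <- ord[1L]
  decision <- stats::setNames(rep("keep", length(ord)), ord)
  detail <- stats::setNames(rep("", length(ord)), ord)
  detail[ord[1L]] <- "top"
  for (e in ord[-1L]) {
    nb <- select_neighbors(e, authentic, mlx, params$min_match,
                           params$n_closest)
    ce <- oc[e, ]
    occ_e <- ce > 0
    hit <- NULL
    for (p in nb) {
      cp <- oc[p, ]
      shared <- occ_e & cp > 0
      if (sum(occ_e) == 0L) break
      if (sum(shared) / sum(occ_e) < params$min_overlap) next
      if (echo_read_criterion(ce[shared], cp[shared], params)) {
        hit <- p
        break
      }
    }
    if (is.null(hit)) {
      authentic <- c(authentic, e)
    } else {
      decision[e] <- "discard"
      detail[e] <- paste0("parent=", hit)
    }
  }
  filter_report(ord, decision, "echo", detail)
}

# read-number criterion for one (echo, parent) pair over shared samples
echo_read_criterion <- function(e_reads, p_reads, params) {
  n <- length(e_reads)
  if (n == 0L) return(FALSE)
  if (params$require_corr && n > 3L) {
    fit <- stats::lm(e_reads ~ p_reads)
    sm <- summary(fit)$coefficients
    if (nrow(sm) < 2L) return(FALSE)   # degenerate predictor
    slope <- sm["p_reads", "Estimate"]
    p_val <- sm["p_reads", "Pr(>|t|)"]
    if (is.na(slope) || is.na(p_val)) return(FALSE)
    p_val < params$max_p_val && slope < params$max_read_ratio
  } else {
    ratios <- e_reads / p_reads
    stat <- if (params$read_ratio_type == "max") max(ratios)
            else mean(ratios)
    stat < params$max_read_ratio
  }
}

#' Evolutionary-signature filter
#'
#' Same ordered sweep and neighbor selection as [echo_filter()]. An OTU is
#' flagged as non-authentic when, for some authentic neighbor, the ratio
#' between the evolutionary distance (`dadn` or `wdadn`, see
#' [pair_signature()]) and the nucleotide edit distance exceeds
#' `dist_threshold`. In local mode (`require_overlap = TRUE`) a minimum
#' sample overlap with the neighbor is additionally required. Pairs with
#' edit distance 0 provide no evidence and are skipped; pairs with
#' nonsynonymous but no synonymous differences have infinite distance and
#' always exceed the threshold.
#'
#' @inheritParams echo_filter
#' @param seqs Named character vector of representative sequences per OTU
#'   (used to compute codon signatures on demand).
#' @param params An [evo_params()] object.
#' @param weight_matrix Amino-acid dissimilarity matrix for `wdadn`;
#'   `NULL` loads the packaged default.
#' @param code_table,frame_offset Genetic code and reading frame for
#'   codon alignment.
#' @param signatures Optional precomputed signature cache (environment),
#'   as used internally; pass the same environment across calls to reuse
#'   alignments.
#' @return A filter report over all OTUs; the `filter_name` is
#'   `"evo.local"` or `"evo.global"` according to `require_overlap`.
#' @export
evo_filter <- function(clusters, counts, matchlist, seqs,
                       params = evo_params(), weight_matrix = NULL,
                       code_table = "5", frame_offset = 0L,
                       signatures = NULL) {
  stopifnot(inherits(params, "evo_params"))
  fname <- if (params$require_overlap) "evo.local" else "evo.global"
  ord <- order_otus(clusters, counts)
  if (length(ord) == 0L) return(filter_report(character(0), character(0),
                                              fname))
  if (is.null(weight_matrix)) weight_matrix <- aa_dissimilarity()
  if (is.null(signatures)) signatures <- new.env(parent = emptyenv())
  oc <- otu_counts(clusters, counts)
  mlx <- matchlist_index(matchlist)
  get_sig <- function(a, b) {
    key <- paste(sort(c(a, b)), collapse = "\r")
    sig <- get0(key, envir = signatures, ifnotfound = NULL)
    if (is.null(sig)) {
      aln <- align_codon_pair(seqs[[a]], seqs[[b]], code_table = code_table,
                              frame_offset = frame_offset)
      sig <- pair_signature(aln, weight_matrix)
      assign(key, sig, envir = signatures)
    }
    sig
  }
  authentic <- ord[1L]
  decision <- stats::setNames(rep("keep", length(ord)), ord)
  detail <- stats::setNames(rep("", length(ord)), ord)
  detail[ord[1L]] <- "top"
  for (e in ord[-1L]) {
    nb <- select_neighbors(e, authentic, mlx, params$min_match,
                           params$n_closest)
    occ_e <- oc[e, ] > 0
    hit <- NULL
    for (p in nb) {
      if (params$require_overlap) {
        shared <- occ_e & oc[p, ] > 0
        if (sum(occ_e) == 0L ||
            sum(shared) / sum(occ_e) < params$min_overlap) next
      }
      ml_rec <- mlx$lookup(e, p)
      ed <- if (!is.null(ml_rec) && !is.na(ml_rec[2L])) ml_rec[2L] else NA
      sig <- NULL
      if (is.na(ed)) {
        sig <- get_sig(e, p)
        ed <- sig$edit_distance
      }
      if (ed == 0) next                    # no evidence
      if (is.null(sig)) sig <- get_sig(e, p)
      dist_value <- sig[[params$dist_type]]
      if (dist_value / ed > params$dist_threshold) {
        hit <- sprintf("neighbor=%s;%s=%s;edit=%d", p, params$dist_type,
                       format(dist_value), as.integer(ed))
        break
      }
    }
    if (is.null(hit)) {
      authentic <- c(authentic, e)
    } else {
      decision[e] <- "discard"
      detail[e] <- hit
    }
  }
  filter_report(ord, decision, fname, detail)
}

#' Abundance filter
#'
#' Discards OTUs whose read-number statistic falls strictly below the
#' cutoff. The statistic is the sum of reads across samples
#' (`cutoff_type = "sum"`), the maximum in any sample (`"max"`), or the
#' mean over occupied samples (`"mean"`).
#'
#' @inheritParams echo_filter
#' @param params An [abundance_params()] object.
#' @return A filter report over all OTUs.
#' @export
abundance_filter <- function(clusters, counts,
                             params = abundance_params()) {
  stopifnot(inherits(params, "abundance_params"))
  oc <- otu_counts(clusters, counts)
  stat <- switch(params$cutoff_type,
    sum = rowSums(oc),
    max = apply(oc, 1L, max),
    mean = apply(oc, 1L, function(x) {
      occ <- x[x > 0]
      if (length(occ) == 0L) 0 else mean(occ)
    }))
  filter_report(rownames(oc),
                ifelse(stat < params$cutoff, "discard", "keep"),
                "abundance",
                sprintf("%s=%s", params$cutoff_type, format(stat)))
}

#' Is a taxonomic label uncertain?
#'
#' Uncertain labels are the literal `"unassigned"` / `"unresolved"`,
#' labels prefixed `"unassigned."` or `"unresolved."`, empty strings and
#' `NA`.
#'
#' @param x Character vector of labels.
#' @return Logical vector.
#' @export
is_uncertain <- function(x) {
  is.na(x) | !nzchar(x) | x == "unassigned" | x == "unresolved" |
    startsWith(x, "unassigned.") | startsWith(x, "unresolved.")
}

#' Taxonomic annotation filter
#'
#' Discards OTUs with an uncertain annotation (see [is_uncertain()]) at
#' the assignment rank.
#'
#' @param taxa Character matrix of OTU-level taxonomy (rows named by OTU
#'   id, columns = ranks).
#' @param params A [tax_filter_params()] object.
#' @return A filter report over all OTUs in `taxa`.
#' @export
taxonomy_filter <- function(taxa, params = tax_filter_params()) {
  stopifnot(inherits(params, "tax_filter_params"),
            params$assignment_rank %in% colnames(taxa))
  lab <- taxa[, params$assignment_rank]
  filter_report(rownames(taxa),
                ifelse(is_uncertain(lab), "discard", "keep"),
                "taxonomy",
                paste0(params$assignment_rank, "=", lab))
}

#' Run the full NEEAT noise filter
#'
#' Applies, in fixed order, the echo filter, the evolutionary-signature
#' filter in local mode, the evolutionary-signature filter in global mode,
#' the abundance filter, and the taxonomic annotation filter, feeding the
#' OTUs retained by each step into the next. The final report records, for
#' every input OTU, whether it was kept and which filter discarded it.
#'
#' With `partition_rank` set, OTUs are partitioned by their annotation at
#' that rank and NEEAT runs independently within each partition (the
#' match list is restricted accordingly); results are concatenated.
#'
#' @inheritParams evo_filter
#' @param taxa Character matrix of OTU-level taxonomy (rows named by OTU
#'   id).
#' @param matchlist Match list between OTU representatives; `NULL`
#'   computes one from `seqs` with [compute_matchlist()].
#' @param echo,evo_local,evo_global,abundance,taxonomy Parameter objects
#'   for the component filters; pass `NULL` to skip a component.
#' @param partition_rank Optional rank name for per-taxon partitioning.
#' @return A filter report over all OTUs (one terminal decision each).
#' @export
run_neeat <- function(clusters, counts, taxa, matchlist = NULL, seqs = NULL,
                      echo = echo_params(),
                      evo_local = evo_params(require_overlap = TRUE),
                      evo_global = evo_params(require_overlap = FALSE),
                      abundance = abundance_params(),
                      taxonomy = tax_filter_params(),
                      partition_rank = NULL,
                      weight_matrix = NULL, code_table = "5",
                      frame_offset = 0L) {
  if (is.null(matchlist)) {
    stopifnot(!is.null(seqs))
    min_match <- min(c(if (!is.null(echo)) echo$min_match,
                       if (!is.null(evo_local)) evo_local$min_match,
                       if (!is.null(evo_global)) evo_global$min_match,
                       84))
    matchlist <- compute_matchlist(seqs, min_match = min_match)
  }
  if (!is.null(partition_rank)) {
    stopifnot(partition_rank %in% colnames(taxa))
    otus <- unique(clusters$otu_id)
    group <- taxa[otus, partition_rank]
    parts <- split(otus, group)
    reports <- lapply(parts[order(names(parts))], function(members) {
      cl <- clusters[clusters$otu_id %in% members, , drop = FALSE]
      ml <- matchlist[matchlist$query %in% members &
                        matchlist$target %in% members, , drop = FALSE]
      run_neeat(cl, counts, taxa, matchlist = ml, seqs = seqs,
                echo = echo, evo_local = evo_local,
                evo_global = evo_global, abundance = abundance,
                taxonomy = taxonomy, partition_rank = NULL,
                weight_matrix = weight_matrix, code_table = code_table,
                frame_offset = frame_offset)
    })
    out <- do.call(rbind, reports)
    out <- out[order(out$entity_id), , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }

  signatures <- new.env(parent = emptyenv())
  reports <- list()
  cl <- clusters
  stage <- function(fun) {
    rep <- fun(cl)
    reports[[length(reports) + 1L]] <<- rep
    cl <<- cl[cl$otu_id %in% kept(rep), , drop = FALSE]
  }
  if (!is.null(echo)) {
    stage(function(cl) echo_filter(cl, counts, matchlist, echo))
  }
  for (ep in list(evo_local, evo_global)) {
    if (!is.null(ep)) {
      local_ep <- ep
      stage(function(cl) evo_filter(cl, counts, matchlist, seqs, local_ep,
                                    weight_matrix = weight_matrix,
                                    code_table = code_table,
                                    frame_offset = frame_offset,
                                    signatures = signatures))
    }
  }
  if (!is.null(abundance)) {
    stage(function(cl) abundance_filter(cl, counts, abundance))
  }
  if (!is.null(taxonomy)) {
    stage(function(cl) {
      otus <- unique(cl$otu_id)
      taxonomy_filter(taxa[otus, , drop = FALSE], taxonomy)
    })
  }
  out <- if (length(reports) == 0L) {
    filter_report(unique(clusters$otu_id), "keep", "neeat", "")
  } else {
    do.call(combine_reports, reports)
  }
  # ensure every input OTU has a terminal decision
  missing <- setdiff(unique(clusters$otu_id), out$entity_id)
  if (length(missing) > 0L) {
    out <- rbind(out, filter_report(missing, "keep", "neeat", ""))
  }
  out <- out[order(out$entity_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
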