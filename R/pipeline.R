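#' Default pipeline configuration
#'
#' Returns the full nested list of pipeline settings. Any subset can be
#' overridden via a YAML file or by modifying the list; unknown fields
#' are rejected by [run_pipeline()].
#'
#' @return Nested list of settings.
#' @export
default_config <- function() {
  list(
    input = list(fasta = NULL, counts = NULL, taxonomy = NULL,
                 clusters = NULL, matchlist = NULL, chimera_calls = NULL,
                 metadata = NULL),
    output_dir = "neeatr_out",
    ranks = default_ranks(),
    seed = 1L,
    prefilter = list(enabled = TRUE, min_len = 403L, max_len = 418L,
                     code_table = "5", frame_offset = "auto"),
    chimera = list(enabled = TRUE, mode = "samplewise",
                   stringency = "strict"),
    consensus = list(threshold = 0.80, mode = "consensus",
                     rep_rule = "mean"),
    neeat = list(enabled = TRUE, partition_rank = "Order",
                 echo = list(), evo_local = list(), evo_global = list(),
                 abundance = list(), taxonomy = list()),
    negative_controls = list(enabled = FALSE, max_fraction = 0.1),
    spikeins = list(enabled = FALSE, species = NULL, taxon = NULL,
                    occurrence_pct = NULL)
  )
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file and merges it over [default_config()].
#'
#' @param path Path to the YAML file.
#' @return Nested configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_config(default_config(), user)
}

merge_config <- function(base, user) {
  for (k in names(user)) {
    if (!k %in% names(base)) stop("unknown configuration field: ", k)
    if (is.list(base[[k]]) && is.list(user[[k]])) {
      base[[k]] <- merge_config(base[[k]], user[[k]])
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

#' Run the full curation pipeline
#'
#' Chains the curation stages over externally produced inputs (denoised
#' ASVs with counts, taxonomic annotations, and a cluster map): (i)
#' sequence pre-filters (length window, in-frame stop codons); (ii)
#' co-occurrence post-filtering of chimera calls, when calls are
#' supplied; (iii) read-weighted consensus taxonomy per cluster; (iv)
#' NEEAT noise filtering, partitioned at the configured rank; and
#' optional negative-control and spike-in cluster filters. Every
#' intermediate table is written under the output directory together
#' with a machine-readable run manifest (package version, parameters,
#' input digests, per-stage retention counts).
#'
#' @param config A configuration list (see [default_config()]), or the
#'   path to a YAML file.
#' @param data Optionally, a named list carrying in-memory inputs
#'   (`asvs`, `counts`, `taxa`, `clusters`, `matchlist`, `chimera_calls`,
#'   `metadata`) overriding the file paths in `config$input`.
#' @return Invisibly, a list with the final `otu_counts`, `otu_taxa`,
#'   per-stage `reports`, the combined OTU-level `report`, and the
#'   `manifest`.
#' @export
run_pipeline <- function(config = default_config(), data = list()) {
  if (is.character(config)) config <- read_config(config)
  cfg <- merge_config(default_config(), config)
  inp <- cfg$input
  need <- function(x, what) {
    if (is.null(x)) stop("missing required input: ", what)
    x
  }
  asvs <- data$asvs %||% read_fasta(need(inp$fasta, "fasta"))
  counts <- data$counts %||% read_counts(need(inp$counts, "counts"))
  taxa <- data$taxa %||% read_taxonomy(need(inp$taxonomy, "taxonomy"),
                                       ranks = cfg$ranks,
                                       ids = asvs$asv_id)
  clusters <- data$clusters %||%
    read_cluster_map(need(inp$clusters, "clusters"))
  matchlist <- data$matchlist %||%
    (if (!is.null(inp$matchlist)) read_matchlist(inp$matchlist))
  calls <- data$chimera_calls %||%
    (if (!is.null(inp$chimera_calls)) read_chimera_calls(inp$chimera_calls))
  metadata <- data$metadata %||%
    (if (!is.null(inp$metadata)) read_sample_metadata(inp$metadata))
  stopifnot(all(clusters$asv_id %in% rownames(counts)))

  out_dir <- cfg$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  reports <- list()
  stage_counts <- list(input = nrow(asvs))
  log_stage <- function(name, retained, discarded) {
    message(sprintf("[%s] retained %d, discarded %d", name, retained,
                    discarded))
  }

  retained <- asvs$asv_id
  if (isTRUE(cfg$prefilter$enabled)) {
    rep_len_ <- filter_length(asvs, cfg$prefilter$min_len,
                              cfg$prefilter$max_len)
    asvs2 <- asvs[asvs$asv_id %in% kept(rep_len_), , drop = FALSE]
    rep_stop <- filter_stop_codons(asvs2, cfg$prefilter$code_table,
                                   cfg$prefilter$frame_offset)
    reports$length <- rep_len_
    reports$stop_codons <- rep_stop
    retained <- kept(rep_stop)
    log_stage("prefilter", length(retained), nrow(asvs) - length(retained))
    stage_counts$prefilter <- length(retained)
  }
  if (isTRUE(cfg$chimera$enabled) && !is.null(calls)) {
    pol <- chimera_policy(cfg$chimera$mode, cfg$chimera$stringency)
    sub <- counts[intersect(retained, rownames(counts)), , drop = FALSE]
    rep_chim <- apply_chimera_policy(
      calls[calls$asv_id %in% retained, , drop = FALSE], sub, pol)
    reports$chimera <- rep_chim
    retained <- intersect(retained, kept(rep_chim))
    log_stage("chimera", length(retained), length(discarded(rep_chim)))
    stage_counts$chimera <- length(retained)
  }

  clusters <- clusters[clusters$asv_id %in% retained, , drop = FALSE]
  if (nrow(clusters) == 0L) stop("no ASVs retained before clustering stage")
  cons_par <- consensus_params(cfg$consensus$threshold, cfg$consensus$mode)
  otu_taxa <- otu_taxonomy(clusters, counts, taxa, cons_par,
                           rep_rule = cfg$consensus$rep_rule)
  reps <- attr(otu_taxa, "representative")
  seq_of <- stats::setNames(asvs$sequence, asvs$asv_id)
  rep_seqs <- stats::setNames(seq_of[reps], names(reps))

  if (isTRUE(cfg$neeat$enabled)) {
    frame_off <- cfg$prefilter$frame_offset
    if (identical(frame_off, "auto")) {
      frame_off <- if (!is.null(reports$stop_codons))
        attr(reports$stop_codons, "frame_offset") else 0L
    }
    rep_neeat <- run_neeat(
      clusters, counts, otu_taxa, matchlist = matchlist, seqs = rep_seqs,
      echo = do.call(echo_params, cfg$neeat$echo),
      evo_local = do.call(evo_params,
                          c(cfg$neeat$evo_local,
                            list(require_overlap = TRUE))),
      evo_global = do.call(evo_params,
                           c(cfg$neeat$evo_global,
                             list(require_overlap = FALSE))),
      abundance = do.call(abundance_params, cfg$neeat$abundance),
      taxonomy = do.call(tax_filter_params, cfg$neeat$taxonomy),
      partition_rank = cfg$neeat$partition_rank,
      code_table = cfg$prefilter$code_table,
      frame_offset = as.integer(frame_off))
    reports$neeat <- rep_neeat
    keep_otus <- kept(rep_neeat)
    log_stage("neeat", length(keep_otus), length(discarded(rep_neeat)))
  } else {
    keep_otus <- sort(unique(clusters$otu_id))
  }
  stage_counts$neeat_otus <- length(keep_otus)

  if (isTRUE(cfg$negative_controls$enabled) && !is.null(metadata)) {
    cl <- clusters[clusters$otu_id %in% keep_otus, , drop = FALSE]
    rep_nc <- filter_negative_controls(cl, counts, metadata,
                                       cfg$negative_controls$max_fraction)
    reports$negative_controls <- rep_nc
    keep_otus <- intersect(keep_otus, kept(rep_nc))
  }
  if (isTRUE(cfg$spikeins$enabled)) {
    cl <- clusters[clusters$otu_id %in% keep_otus, , drop = FALSE]
    rep_sp <- filter_spikeins(cl, otu_taxa, counts,
                              species = cfg$spikeins$species,
                              taxon = cfg$spikeins$taxon,
                              occurrence_pct = cfg$spikeins$occurrence_pct)
    reports$spikeins <- rep_sp
    keep_otus <- intersect(keep_otus, kept(rep_sp))
  }
  stage_counts$final_otus <- length(keep_otus)

  final_clusters <- clusters[clusters$otu_id %in% keep_otus, , drop = FALSE]
  final_counts <- otu_counts(final_clusters, counts)
  final_taxa <- otu_taxa[sort(keep_otus), , drop = FALSE]

  write_counts(final_counts, file.path(out_dir, "otu_counts.tsv"),
               id_col = "otu_id")
  tax_out <- cbind(final_taxa,
                   representative_asv =
                     attr(otu_taxa, "representative")[rownames(final_taxa)],
                   consensus_mode = cfg$consensus$mode)
  write_taxonomy(tax_out, file.path(out_dir, "otu_taxonomy.tsv"),
                 id_col = "otu_id")
  write_cluster_map(final_clusters, file.path(out_dir, "clusters.tsv"))
  full_report <- do.call(combine_reports, unname(reports))
  write_report(full_report, file.path(out_dir, "filter_report.tsv"))

  digests <- lapply(inp, function(p) {
    if (is.null(p) || !file.exists(p)) NULL else unname(tools::md5sum(p))
  })
  manifest <- list(package = "neeatr",
                   version = as.character(utils::packageVersion("neeatr")),
                   parameters = cfg[setdiff(names(cfg),
                                            c("input", "output_dir"))],
                   input_md5 = digests[!vapply(digests, is.null, logical(1))],
                   stage_counts = stage_counts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(otu_counts = final_counts, otu_taxa = final_taxa,
                 reports = reports, report = full_report,
                 manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
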