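#' Read ASV sequences from a FASTA file
#'
#' Reads denoised amplicon sequence variants (ASVs) from FASTA. The ASV
#' identifier is the first whitespace-delimited token of each header line;
#' sequences are upper-cased.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `asv_id`, `sequence` and `length`
#'   (one row per record).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">asv1 some description", "acgtacgt"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) {
    warning("empty FASTA file: ", path)
    return(data.frame(asv_id = character(), sequence = character(),
                      length = integer(), stringsAsFactors = FALSE))
  }
  ids <- vapply(strsplit(names(ss), "[ \t]+"), `[[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate ID ", dup[[1L]], " in FASTA file ", path)
  }
  seqs <- toupper(as.character(ss))
  data.frame(asv_id = ids, sequence = unname(seqs),
             length = nchar(seqs), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Write ASV sequences to a FASTA file
#'
#' @param asvs data.frame as returned by [read_fasta()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(asvs, path) {
  ss <- Biostrings::DNAStringSet(asvs$sequence)
  names(ss) <- asvs$asv_id
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' Read an ASV x sample count table
#'
#' Expects a tab-separated file with a header row of sample identifiers and
#' ASV identifiers in the first column. Missing cells are treated as zero;
#' numeric cells with a zero fractional part are accepted and cast to
#' integer.
#'
#' @param path Path to the TSV count table.
#' @return An integer matrix with ASV row names and sample column names.
#' @export
read_counts <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("no ASVs in count table ", path)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate ASV ID ", ids[duplicated(ids)][1L],
                               " in count table ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (is.character(m)) {
    suppressWarnings(num <- matrix(as.numeric(m), nrow = nrow(m),
                                   dimnames = dimnames(m)))
    bad <- which(is.na(num) & !is.na(m) & nzchar(m), arr.ind = TRUE)
    if (nrow(bad) > 0L) {
      stop("non-numeric count at row '", ids[bad[1L, 1L]], "', column '",
           colnames(m)[bad[1L, 2L]], "' in ", path)
    }
    m <- num
  }
  m[is.na(m)] <- 0
  if (any(m < 0)) stop("negative count in ", path)
  if (any(m != floor(m))) {
    bad <- which(m != floor(m), arr.ind = TRUE)[1L, ]
    stop("non-integer count at row '", ids[bad[1L]], "', column '",
         colnames(m)[bad[2L]], "' in ", path)
  }
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  m
}

#' Write a count table as TSV
#' @param counts Integer matrix (ASVs x samples).
#' @param path Output path.
#' @param id_col Name for the leading identifier column.
#' @return Invisibly, `path`.
#' @export
write_counts <- function(counts, path, id_col = "asv_id") {
  df <- data.frame(rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default taxonomic rank order
#' @return Character vector of rank names, highest to lowest.
#' @export
default_ranks <- function() {
  c("Kingdom", "Phylum", "Class", "Order", "Family", "Genus", "Species")
}

#' Read a per-ASV taxonomy table
#'
#' Tab-separated, one row per ASV (first column), one column per rank.
#' Ranks are taken from the header; `ranks` restricts/validates them.
#' ASVs listed in `ids` but missing from the file are filled with
#' `"unassigned"` at all ranks, with a warning.
#'
#' @param path Path to the TSV taxonomy table.
#' @param ranks Optional character vector of expected rank columns.
#' @param ids Optional character vector of ASV ids that must be covered.
#' @return A character matrix, rows named by ASV id, columns = ranks.
#' @export
read_taxonomy <- function(path, ranks = NULL, ids = NULL) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  row_ids <- as.character(df[[1L]])
  if (anyDuplicated(row_ids)) {
    stop("duplicate ID ", row_ids[duplicated(row_ids)][1L],
         " in taxonomy table ", path)
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "character"
  rownames(m) <- row_ids
  if (!is.null(ranks)) {
    missing_ranks <- setdiff(ranks, colnames(m))
    if (length(missing_ranks) > 0L) {
      stop("taxonomy table lacks rank column(s): ",
           paste(missing_ranks, collapse = ", "))
    }
    m <- m[, ranks, drop = FALSE]
  }
  m[is.na(m) | !nzchar(m)] <- "unassigned"
  if (!is.null(ids)) {
    absent <- setdiff(ids, rownames(m))
    if (length(absent) > 0L) {
      warning(length(absent), " ASV(s) missing from taxonomy table; ",
              "filled with 'unassigned' at all ranks")
      fill <- matrix("unassigned", nrow = length(absent), ncol = ncol(m),
                     dimnames = list(absent, colnames(m)))
      m <- rbind(m, fill)
    }
    m <- m[ids, , drop = FALSE]
  }
  m
}

#' Write a taxonomy table as TSV
#' @param taxa Character matrix with row names.
#' @param path Output path.
#' @param id_col Name for the identifier column.
#' @return Invisibly, `path`.
#' @export
write_taxonomy <- function(taxa, path, id_col = "asv_id") {
  df <- data.frame(rownames(taxa), taxa, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pairwise match list
#'
#' Three-column TSV (query, target, identity) of sparse pairwise
#' similarities, in the dialect emitted by vsearch
#' (`--userout` with `query+target+id`). The identity scale is auto-detected:
#' when every value is at most 1.0, values are taken as fractions and
#' rescaled to percent. Self-pairs are dropped with a warning.
#'
#' @param path Path to the match list TSV.
#' @param header Logical; does the file carry a header row?
#' @return A data.frame with columns `query`, `target`, `pct_identity`, and
#'   `edit_distance` (NA unless a fourth column was present).
#' @export
read_matchlist <- function(path, header = FALSE) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, header = header, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("match list must have at least 3 columns")
  ml <- data.frame(query = as.character(df[[1L]]),
                   target = as.character(df[[2L]]),
                   pct_identity = as.numeric(df[[3L]]),
                   edit_distance = if (ncol(df) >= 4L) as.integer(df[[4L]])
                                   else NA_integer_,
                   stringsAsFactors = FALSE)
  if (anyNA(ml$pct_identity)) stop("non-numeric identity in ", path)
  if (nrow(ml) > 0L && max(ml$pct_identity) <= 1.0) {
    ml$pct_identity <- 100 * ml$pct_identity
  }
  if (any(ml$pct_identity < 0 | ml$pct_identity > 100)) {
    stop("identity outside [0, 100] in ", path)
  }
  self <- ml$query == ml$target
  if (any(self)) {
    warning(sum(self), " self-pair(s) dropped from match list")
    ml <- ml[!self, , drop = FALSE]
    rownames(ml) <- NULL
  }
  ml
}

#' Write a match list as TSV (vsearch dialect, no header)
#' @param ml Match list data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_matchlist <- function(ml, path) {
  out <- ml[, c("query", "target", "pct_identity")]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an ASV-to-cluster assignment table
#'
#' Two-column TSV mapping each ASV to its OTU; a header row is detected by
#' looking for non-identifier-like first lines is not attempted — pass
#' `header` explicitly for headerless files.
#'
#' @param path Path to the TSV.
#' @param header Logical; default TRUE (columns `asv_id`, `otu_id`).
#' @return A data.frame with columns `asv_id` and `otu_id`.
#' @export
read_cluster_map <- function(path, header = TRUE) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, header = header, sep = "\t",
                          stringsAsFactors = FALSE)
  cm <- data.frame(asv_id = as.character(df[[1L]]),
                   otu_id = as.character(df[[2L]]),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(cm$asv_id)) {
    stop("ASV ", cm$asv_id[duplicated(cm$asv_id)][1L],
         " assigned to more than one cluster")
  }
  cm
}

#' Write an ASV-to-cluster assignment table
#' @param clusters data.frame with `asv_id`, `otu_id`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_cluster_map <- function(clusters, path) {
  utils::write.table(clusters[, c("asv_id", "otu_id")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' TSV with columns `sample_id`, `dataset`, `is_negative_control`
#' (true/false).
#'
#' @param path Path to the TSV.
#' @return data.frame with columns `sample_id`, `dataset`,
#'   `is_negative_control` (logical).
#' @export
read_sample_metadata <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  md <- data.frame(sample_id = as.character(df[[1L]]),
                   dataset = as.character(df[[2L]]),
                   is_negative_control =
                     tolower(as.character(df[[3L]])) %in%
                       c("true", "t", "1", "yes"),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(md$sample_id)) {
    stop("duplicate sample_id in metadata: ",
         md$sample_id[duplicated(md$sample_id)][1L])
  }
  md
}

# ---- per-ASV / per-OTU aggregates ------------------------------------------

#' Per-ASV summary statistics from a count table
#'
#' @param counts Integer matrix (ASVs x samples).
#' @return data.frame with `asv_id`, `n_samples` (occupancy), `total_reads`,
#'   `max_reads`, `mean_reads`, `median_reads` (mean/median over all samples,
#'   zeros included).
#' @export
asv_stats <- function(counts) {
  data.frame(
    asv_id = rownames(counts),
    n_samples = as.integer(rowSums(counts > 0)),
    total_reads = as.integer(rowSums(counts)),
    max_reads = apply(counts, 1L, max),
    mean_reads = rowMeans(counts),
    median_reads = apply(counts, 1L, stats::median),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Aggregate a count table to the cluster (OTU) level
#'
#' @param clusters data.frame with `asv_id`, `otu_id`.
#' @param counts Integer matrix (ASVs x samples); must cover all ASVs in
#'   `clusters`.
#' @return Integer matrix of summed counts, OTUs x samples.
#' @export
otu_counts <- function(clusters, counts) {
  stopifnot(all(clusters$asv_id %in% rownames(counts)))
  m <- rowsum(counts[clusters$asv_id, , drop = FALSE],
              group = clusters$otu_id, reorder = TRUE)
  storage.mode(m) <- "integer"
  m
}

#' Per-OTU summary statistics
#'
#' @inheritParams otu_counts
#' @param rep_rule Representative-ASV rule, `"mean"` or `"median"` (see
#'   [representative_asv()]).
#' @return data.frame with `otu_id`, `n_samples`, `total_reads`, `max_reads`,
#'   `representative_asv`, ordered by `otu_id`.
#' @export
otu_stats <- function(clusters, counts, rep_rule = c("mean", "median")) {
  rep_rule <- match.arg(rep_rule)
  oc <- otu_counts(clusters, counts)
  reps <- vapply(rownames(oc), function(o) {
    representative_asv(clusters$asv_id[clusters$otu_id == o], counts,
                       rule = rep_rule)
  }, character(1))
  data.frame(
    otu_id = rownames(oc),
    n_samples = as.integer(rowSums(oc > 0)),
    total_reads = as.integer(rowSums(oc)),
    max_reads = apply(oc, 1L, max),
    representative_asv = unname(reps),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
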