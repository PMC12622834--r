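#' Chimera post-filtering policy
#'
#' De novo chimera callers (uchime and kin) are run either on the pooled
#' ASV set (`batchwise`) or once per sample on the sequences present there
#' (`samplewise`). This object names one of the four co-occurrence
#' post-filtering strategies applied on top of the raw calls:
#'
#' * `batchwise.strict`: discard an ASV if both parents are present
#'   (count > 0) in at least 50% of the samples in which the ASV occurs.
#' * `batchwise.lenient`: discard if both parents co-occur with the ASV in
#'   at least one sample.
#' * `samplewise.strict`: discard only if the ASV is called chimeric in
#'   every sample where it occurs.
#' * `samplewise.lenient`: discard if called chimeric in at least one
#'   sample.
#'
#' @param mode `"batchwise"` or `"samplewise"`.
#' @param stringency `"strict"` or `"lenient"`.
#' @return A list with class `chimera_policy`.
#' @export
chimera_policy <- function(mode = c("samplewise", "batchwise"),
                           stringency = c("strict", "lenient")) {
  structure(list(mode = match.arg(mode),
                 stringency = match.arg(stringency)),
            class = "chimera_policy")
}

#' Read chimera calls from a simplified 5-column TSV
#'
#' Columns: asv_id, sample_id (empty for batchwise calls), parent_a,
#' parent_b, verdict (`Y`/`chimeric` vs anything else). A header row is
#' optional.
#'
#' @param path Path to the TSV.
#' @param header Logical.
#' @return data.frame with columns `asv_id`, `sample_id`, `parent_a`,
#'   `parent_b`, `verdict` (`"chimeric"` or `"not"`).
#' @export
read_chimera_calls <- function(path, header = TRUE) {
  df <- utils::read.delim(path, header = header, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = NULL)
  if (ncol(df) < 5L) stop("chimera call table must have 5 columns")
  calls <- data.frame(asv_id = df[[1L]], sample_id = df[[2L]],
                      parent_a = df[[3L]], parent_b = df[[4L]],
                      verdict = normalize_verdict(df[[5L]]),
                      stringsAsFactors = FALSE)
  calls
}

normalize_verdict <- function(v) {
  ifelse(toupper(v) %in% c("Y", "YES", "CHIMERIC", "TRUE", "1"),
         "chimeric", "not")
}

#' Read vsearch `--uchimeout` tabular output
#'
#' Parses the 18-column uchimeout dialect: score, query, parent A, parent
#' B, top parent, followed by alignment statistics, with a final Y/N/?
#' verdict column. Query/parent labels are taken up to the first
#' semicolon (stripping `;size=` annotations).
#'
#' @param path Path to the uchimeout file.
#' @param sample_id Sample the calls belong to (`""` for batchwise runs).
#' @return data.frame in the format of [read_chimera_calls()].
#' @export
read_uchimeout <- function(path, sample_id = "") {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = NULL)
  if (ncol(df) < 18L) stop("uchimeout file must have 18 columns")
  strip <- function(x) sub(";.*$", "", x)
  data.frame(asv_id = strip(df[[2L]]), sample_id = sample_id,
             parent_a = strip(df[[3L]]), parent_b = strip(df[[4L]]),
             verdict = ifelse(df[[18L]] == "Y", "chimeric", "not"),
             stringsAsFactors = FALSE)
}

#' Apply a co-occurrence chimera policy to raw chimera calls
#'
#' @param calls data.frame of chimera calls (see [read_chimera_calls()]).
#'   For batchwise policies `sample_id` must be empty; for samplewise
#'   policies it must be non-empty.
#' @param counts Integer ASV x sample count matrix covering every ASV in
#'   `calls`.
#' @param policy A [chimera_policy()].
#' @return A filter report over all ASVs in `counts`.
#' @export
apply_chimera_policy <- function(calls, counts, policy) {
  stopifnot(inherits(policy, "chimera_policy"))
  asvs <- rownames(counts)
  chim <- calls[calls$verdict == "chimeric", , drop = FALSE]
  unknown <- setdiff(chim$asv_id, asvs)
  if (length(unknown) > 0L) {
    stop("chimera call for ASV absent from count table: ", unknown[[1L]])
  }
  discard <- character(0)
  detail <- character(0)

  if (policy$mode == "batchwise") {
    if (any(nzchar(chim$sample_id))) {
      stop("batchwise policy given samplewise calls (non-empty sample_id)")
    }
    for (i in seq_len(nrow(chim))) {
      a <- chim$asv_id[i]
      occ <- counts[a, ] > 0
      n_occ <- sum(occ)
      if (n_occ == 0L) next
      pa <- chim$parent_a[i]; pb <- chim$parent_b[i]
      if (!pa %in% asvs || !pb %in% asvs) next
      co <- occ & counts[pa, ] > 0 & counts[pb, ] > 0
      n_co <- sum(co)
      hit <- if (policy$stringency == "strict") n_co / n_occ >= 0.5
             else n_co >= 1L
      if (hit) {
        discard <- c(discard, a)
        detail <- c(detail, sprintf("parents=%s,%s;co_occ=%d/%d",
                                    pa, pb, n_co, n_occ))
      }
    }
  } else {
    if (any(!nzchar(chim$sample_id))) {
      stop("samplewise policy given batchwise calls (empty sample_id)")
    }
    bad <- mapply(function(a, s) counts[a, s] == 0,
                  chim$asv_id, chim$sample_id)
    if (any(bad)) {
      warning(sum(bad), " samplewise call(s) for samples where the ASV ",
              "has zero count; ignored")
      chim <- chim[!bad, , drop = FALSE]
    }
    for (a in unique(chim$asv_id)) {
      occ_samples <- colnames(counts)[counts[a, ] > 0]
      called <- unique(chim$sample_id[chim$asv_id == a])
      n_called <- length(intersect(called, occ_samples))
      hit <- if (policy$stringency == "strict") {
        length(occ_samples) > 0L && n_called == length(occ_samples)
      } else {
        n_called >= 1L
      }
      if (hit) {
        discard <- c(discard, a)
        detail <- c(detail, sprintf("chimeric_in=%d/%d", n_called,
                                    length(occ_samples)))
      }
    }
  }

  if (length(discard) > 0L) {            # one row per ASV, first call wins
    first <- !duplicated(discard)
    detail <- detail[first]
    discard <- discard[first]
  }
  name <- paste0("chimera_", policy$mode, ".", policy$stringency)
  keep_ids <- setdiff(asvs, discard)
  rbind(
    if (length(discard) > 0L)
      filter_report(discard, "discard", name, detail),
    filter_report(keep_ids, "keep", name, "")
  )
}
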