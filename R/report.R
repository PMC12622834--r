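#' Construct a filter report
#'
#' A filter report records, for each entity (ASV or OTU) examined by a
#' filter, a terminal keep/discard decision, the filter responsible, and a
#' free-text criterion value.
#'
#' @param entity_id Character vector of ASV or OTU identifiers.
#' @param decision Character vector, `"keep"` or `"discard"` (recycled).
#' @param filter_name Name of the filter responsible (recycled).
#' @param detail Free-text criterion values (recycled).
#' @return data.frame with columns `entity_id`, `decision`, `filter_name`,
#'   `detail`.
#' @export
filter_report <- function(entity_id, decision, filter_name,
                          detail = "") {
  stopifnot(all(decision %in% c("keep", "discard")))
  n <- length(entity_id)
  data.frame(entity_id = as.character(entity_id),
             decision = rep_len(as.character(decision), n),
             filter_name = rep_len(as.character(filter_name), n),
             detail = rep_len(as.character(detail), n),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Entities discarded by a filter report
#' @param report A filter report.
#' @return Character vector of discarded entity ids.
#' @export
discarded <- function(report) {
  report$entity_id[report$decision == "discard"]
}

#' Entities kept by a filter report
#' @param report A filter report.
#' @return Character vector of kept entity ids.
#' @export
kept <- function(report) {
  report$entity_id[report$decision == "keep"]
}

#' Write a filter report as TSV
#' @param report A filter report.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  utils::write.table(
    report[, c("entity_id", "decision", "filter_name", "detail")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a filter report written by [write_report()]
#' @param path Path to the TSV.
#' @return data.frame with the filter-report columns.
#' @export
read_report <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  df$detail[is.na(df$detail)] <- ""
  df[, c("entity_id", "decision", "filter_name", "detail")]
}

# rbind several reports, keeping one terminal decision per entity:
# the first discard wins; entities never discarded are kept with the
# last filter that saw them.
combine_reports <- function(...) {
  reps <- list(...)
  reps <- reps[!vapply(reps, is.null, logical(1))]
  if (length(reps) == 0L) {
    return(filter_report(character(0), character(0), character(0)))
  }
  all <- do.call(rbind, reps)
  disc <- all[all$decision == "discard", , drop = FALSE]
  disc <- disc[!duplicated(disc$entity_id), , drop = FALSE]
  keep_ids <- setdiff(unique(all$entity_id), disc$entity_id)
  kept_rows <- all[all$decision == "keep" & all$entity_id %in% keep_ids, ,
                   drop = FALSE]
  kept_rows <- kept_rows[!duplicated(kept_rows$entity_id, fromLast = TRUE), ,
                         drop = FALSE]
  out <- rbind(disc, kept_rows)
  out <- out[order(out$entity_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
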