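#' Length-window pre-filter
#'
#' Discards ASVs whose sequence length falls outside a closed interval.
#' The defaults bracket the 418 bp CO1 amplicon targeted by typical
#' arthropod metabarcoding protocols.
#'
#' @param asvs data.frame as returned by [read_fasta()].
#' @param min_len,max_len Closed length interval in bases.
#' @return A filter report over all ASVs.
#' @export
filter_length <- function(asvs, min_len = 403L, max_len = 418L) {
  stopifnot(min_len <= max_len)
  bad <- asvs$length < min_len | asvs$length > max_len
  filter_report(asvs$asv_id,
                ifelse(bad, "discard", "keep"),
                "length",
                paste0("len=", asvs$length))
}

# codon -> amino acid lookup for a NCBI genetic code id; codons containing
# characters other than A/C/G/T map to NA (indeterminate)
genetic_code <- function(code_table = "5") {
  Biostrings::getGeneticCode(as.character(code_table))
}

# split a sequence into complete codons at the given frame offset,
# dropping any trailing partial codon
split_codons <- function(seq, frame_offset = 0L) {
  s <- substr(seq, frame_offset + 1L, nchar(seq))
  n_codons <- nchar(s) %/% 3L
  if (n_codons == 0L) return(character(0))
  starts <- seq.int(1L, by = 3L, length.out = n_codons)
  substring(s, starts, starts + 2L)
}

# translate a vector of codons; NA for codons with ambiguous bases
translate_codons <- function(codons, code) {
  aa <- unname(code[codons])
  aa
}

# number of in-frame stop codons in one sequence
count_stops <- function(seq, code, frame_offset) {
  aa <- translate_codons(split_codons(seq, frame_offset), code)
  sum(aa == "*", na.rm = TRUE)
}

#' In-frame stop-codon pre-filter
#'
#' Translates each ASV in a single reading frame and discards sequences
#' containing one or more stop codons. The default genetic code is the
#' invertebrate mitochondrial code (NCBI table 5), appropriate for CO1
#' amplicons from arthropods. With `frame_offset = "auto"` the offset
#' (0, 1 or 2) minimizing the total number of stop codons across the whole
#' dataset is used, on the reasoning that authentic protein-coding amplicons
#' share a reading frame.
#'
#' Trailing partial codons are ignored. Sequences whose translation is
#' wholly indeterminate (e.g. all-N) are kept, with a warning.
#'
#' @param asvs data.frame as returned by [read_fasta()].
#' @param code_table NCBI genetic code id (default `"5"`).
#' @param frame_offset 0, 1, 2 or `"auto"`.
#' @return A filter report over all ASVs; the attribute `frame_offset`
#'   carries the offset used.
#' @export
filter_stop_codons <- function(asvs, code_table = "5",
                               frame_offset = "auto") {
  code <- genetic_code(code_table)
  if (identical(frame_offset, "auto")) {
    totals <- vapply(0:2, function(off) {
      sum(vapply(asvs$sequence, count_stops, numeric(1),
                 code = code, frame_offset = off))
    }, numeric(1))
    frame_offset <- which.min(totals) - 1L
  }
  frame_offset <- as.integer(frame_offset)
  stopifnot(frame_offset %in% 0:2)
  per_asv <- lapply(asvs$sequence, function(s) {
    aa <- translate_codons(split_codons(s, frame_offset), code)
    list(stops = sum(aa == "*", na.rm = TRUE),
         indeterminate = length(aa) > 0L && all(is.na(aa)))
  })
  stops <- vapply(per_asv, `[[`, numeric(1), "stops")
  indet <- vapply(per_asv, `[[`, logical(1), "indeterminate")
  if (any(indet)) {
    warning(sum(indet), " sequence(s) with indeterminate translation kept")
  }
  rep <- filter_report(asvs$asv_id,
                       ifelse(stops > 0, "discard", "keep"),
                       "stop_codons",
                       paste0("stops=", stops, ",frame=", frame_offset))
  attr(rep, "frame_offset") <- frame_offset
  rep
}
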