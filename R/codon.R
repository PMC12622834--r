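#' Amino-acid dissimilarity matrix for weighted nonsynonymous differences
#'
#' Loads a symmetric, zero-diagonal amino-acid dissimilarity matrix used to
#' weight nonsynonymous codon differences (the `wdadn` statistic). The
#' packaged default is derived from the BLOSUM62 substitution matrix via
#' the standard similarity-to-distance transform
#' `d(a,b) = s(a,a) + s(b,b) - 2 s(a,b)`; any user-supplied biochemical
#' distance matrix in the same TSV layout (row/column names = one-letter
#' amino-acid codes) can be substituted.
#'
#' With `rescale = TRUE` (default) the matrix is rescaled so that the mean
#' over all unordered pairs of distinct amino acids is 1.0. On that scale
#' `wdadn` is directly comparable to the unweighted `dadn`: an average
#' amino-acid replacement contributes weight 1.
#'
#' @param path Path to a TSV distance matrix; `NULL` loads the packaged
#'   default.
#' @param rescale Rescale mean off-diagonal weight to 1.0.
#' @return A symmetric numeric matrix over the 20 standard amino acids.
#' @export
aa_dissimilarity <- function(path = NULL, rescale = TRUE) {
  if (is.null(path)) {
    path <- system.file("extdata", "aa_dissimilarity_blosum62.tsv",
                        package = "neeatr", mustWork = TRUE)
  }
  m <- as.matrix(utils::read.delim(path, row.names = 1L,
                                   check.names = FALSE))
  storage.mode(m) <- "double"
  stopifnot(identical(rownames(m), colnames(m)),
            isTRUE(all.equal(m, t(m))),
            all(diag(m) == 0))
  if (rescale) {
    off <- m[upper.tri(m)]
    m <- m / mean(off)
  }
  m
}

#' Levenshtein edit distance between two sequences
#' @param a,b Character strings.
#' @return Integer edit distance.
#' @export
edit_distance <- function(a, b) {
  as.integer(utils::adist(a, b))
}

#' Codon-aware pairwise alignment of two protein-coding sequences
#'
#' Aligns two in-frame, stop-free DNA sequences at the codon level by
#' translating each to amino acids, computing a global pairwise amino-acid
#' alignment with affine gap penalties, and threading the gaps back onto
#' the codons (one amino-acid gap = one 3-nt codon gap). This mirrors the
#' translate / align / back-translate construction used to build
#' codon-aware multiple alignments, at pair scale.
#'
#' @param seq_a,seq_b DNA sequences (A/C/G/T; ambiguous bases translate to
#'   `X`).
#' @param code_table NCBI genetic code id (default `"5"`, invertebrate
#'   mitochondrial).
#' @param frame_offset Reading-frame offset (0, 1 or 2); trailing partial
#'   codons are dropped.
#' @param gap_opening,gap_extension Affine gap penalties for the
#'   amino-acid alignment.
#' @return A list of class `codon_alignment` with elements `codons_a`,
#'   `codons_b` (aligned codon vectors, `"---"` for gaps), `aa_a`, `aa_b`
#'   (aligned amino-acid vectors, `"-"` for gaps), and the original
#'   sequences `seq_a`, `seq_b`.
#' @export
align_codon_pair <- function(seq_a, seq_b, code_table = "5",
                             frame_offset = 0L,
                             gap_opening = 10, gap_extension = 0.5) {
  code <- genetic_code(code_table)
  ca <- split_codons(seq_a, frame_offset)
  cb <- split_codons(seq_b, frame_offset)
  if (length(ca) == 0L || length(cb) == 0L) {
    stop("sequence shorter than one codon at frame offset ", frame_offset)
  }
  aa_of <- function(codons) {
    aa <- translate_codons(codons, code)
    aa[is.na(aa)] <- "X"
    aa
  }
  aa_a <- aa_of(ca)
  aa_b <- aa_of(cb)
  mat <- get_blosum62()
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(paste(aa_a, collapse = "")),
    Biostrings::AAString(paste(aa_b, collapse = "")),
    type = "global", substitutionMatrix = mat,
    gapOpening = gap_opening, gapExtension = gap_extension)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  thread <- function(chars, codons) {
    out <- character(length(chars))
    j <- 0L
    for (i in seq_along(chars)) {
      if (chars[i] == "-") {
        out[i] <- "---"
      } else {
        j <- j + 1L
        out[i] <- codons[j]
      }
    }
    out
  }
  structure(list(codons_a = thread(pa, ca), codons_b = thread(pb, cb),
                 aa_a = pa, aa_b = pb,
                 seq_a = seq_a, seq_b = seq_b,
                 code_table = as.character(code_table),
                 frame_offset = as.integer(frame_offset)),
            class = "codon_alignment")
}

# BLOSUM62 from Biostrings, loaded once per session
get_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Evolutionary signature of an aligned sequence pair
#'
#' Counts synonymous and nonsynonymous codon differences between two
#' codon-aligned sequences and derives the `dadn` and `wdadn` statistics:
#' the ratio of nonsynonymous (amino-acid) to synonymous differences,
#' unweighted or with each amino-acid replacement weighted by a
#' biochemical dissimilarity. Authentic, functionally constrained CO1
#' haplotypes diverge mostly synonymously, so large values at small edit
#' distances flag NUMTs and other non-authentic sequences.
#'
#' Columns with a gap in either row, and columns where either codon
#' contains an ambiguous base, contribute to neither count. When there are
#' no synonymous differences, the ratio is 0 if there are also no
#' nonsynonymous differences and `Inf` otherwise.
#'
#' @param aln A `codon_alignment` from [align_codon_pair()].
#' @param weight_matrix Symmetric amino-acid dissimilarity matrix (see
#'   [aa_dissimilarity()]); `NULL` loads the packaged default.
#' @return A list of class `pair_signature` with `edit_distance` (Levenshtein
#'   distance between the unaligned sequences), `n_syn`, `n_nonsyn`,
#'   `weighted_nonsyn`, `dadn`, `wdadn`.
#' @export
pair_signature <- function(aln, weight_matrix = NULL) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (is.null(weight_matrix)) weight_matrix <- aa_dissimilarity()
  code <- genetic_code(aln$code_table)
  n_syn <- 0L
  n_nonsyn <- 0L
  weighted <- 0
  for (i in seq_along(aln$codons_a)) {
    ca <- aln$codons_a[i]
    cb <- aln$codons_b[i]
    if (ca == "---" || cb == "---") next
    if (ca == cb) next
    aa_a <- code[ca]
    aa_b <- code[cb]
    if (is.na(aa_a) || is.na(aa_b)) next
    if (aa_a == aa_b) {
      n_syn <- n_syn + 1L
    } else {
      n_nonsyn <- n_nonsyn + 1L
      w <- if (aa_a %in% rownames(weight_matrix) &&
               aa_b %in% colnames(weight_matrix)) {
        weight_matrix[aa_a, aa_b]
      } else 1
      weighted <- weighted + w
    }
  }
  ratio <- function(num, den) {
    if (den == 0) { if (num > 0) Inf else 0 } else num / den
  }
  structure(list(edit_distance = edit_distance(aln$seq_a, aln$seq_b),
                 n_syn = n_syn, n_nonsyn = n_nonsyn,
                 weighted_nonsyn = weighted,
                 dadn = ratio(n_nonsyn, n_syn),
                 wdadn = ratio(weighted, n_syn)),
            class = "pair_signature")
}

#' All-vs-all pairwise match list from sequences
#'
#' Computes Levenshtein distances between all sequence pairs and converts
#' them to percent identities (`100 * (1 - d / max(len_a, len_b))`),
#' keeping pairs at or above `min_match`. This is the desk-scale
#' replacement for an external all-vs-all similarity search; each
#' unordered pair appears once.
#'
#' @param seqs Named character vector of sequences (names = entity ids).
#' @param min_match Minimum percent identity to record.
#' @return A match-list data.frame (`query`, `target`, `pct_identity`,
#'   `edit_distance`).
#' @export
compute_matchlist <- function(seqs, min_match = 84) {
  ids <- names(seqs)
  stopifnot(!is.null(ids), !anyDuplicated(ids))
  n <- length(seqs)
  if (n < 2L) {
    return(data.frame(query = character(), target = character(),
                      pct_identity = numeric(),
                      edit_distance = integer(),
                      stringsAsFactors = FALSE))
  }
  d <- utils::adist(seqs)
  len <- nchar(seqs)
  maxlen <- outer(len, len, pmax)
  pid <- 100 * (1 - d / maxlen)
  ut <- which(upper.tri(d) & pid >= min_match, arr.ind = TRUE)
  data.frame(query = ids[ut[, 1L]], target = ids[ut[, 2L]],
             pct_identity = pid[ut], edit_distance = as.integer(d[ut]),
             stringsAsFactors = FALSE)
}

# fast symmetric lookup index over a match list: environment keyed by
# "a\rb" holding c(pct_identity, edit_distance)
matchlist_index <- function(ml) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  nbr <- new.env(hash = TRUE, parent = emptyenv())
  add_nbr <- function(a, b) {
    assign(a, c(get0(a, envir = nbr, ifnotfound = character(0)), b),
           envir = nbr)
  }
  for (i in seq_len(nrow(ml))) {
    q <- ml$query[i]; t <- ml$target[i]
    v <- c(ml$pct_identity[i],
           if (is.null(ml$edit_distance)) NA_real_
           else as.numeric(ml$edit_distance[i]))
    assign(paste(q, t, sep = "\r"), v, envir = env)
    assign(paste(t, q, sep = "\r"), v, envir = env)
    add_nbr(q, t); add_nbr(t, q)
  }
  list(
    lookup = function(a, b) {
      get0(paste(a, b, sep = "\r"), envir = env)
    },
    neighbors = function(a) {
      unique(get0(a, envir = nbr, ifnotfound = character(0)))
    },
    has = function(a) {
      !is.null(get0(a, envir = nbr, ifnotfound = NULL))
    }
  )
}
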