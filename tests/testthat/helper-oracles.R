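# Independent brute-force oracles used across tests. These deliberately
# re-derive results from first principles (plain loops over samples, pairs
# and codon columns) and never call the package's sweep/counting code.

# -- chimera policies --------------------------------------------------------

oracle_chimera <- function(calls, counts, mode, stringency) {
  chim <- calls[calls$verdict == "chimeric", , drop = FALSE]
  out <- character(0)
  if (mode == "batchwise") {
    for (i in seq_len(nrow(chim))) {
      a <- chim$asv_id[i]
      occ <- colnames(counts)[counts[a, ] > 0]
      if (length(occ) == 0) next
      co <- 0
      for (s in occ) {
        if (counts[chim$parent_a[i], s] > 0 &&
            counts[chim$parent_b[i], s] > 0) co <- co + 1
      }
      bad <- if (stringency == "strict") co / length(occ) >= 0.5 else co >= 1
      if (bad) out <- c(out, a)
    }
  } else {
    for (a in unique(chim$asv_id)) {
      occ <- colnames(counts)[counts[a, ] > 0]
      called <- character(0)
      for (i in which(chim$asv_id == a)) {
        s <- chim$sample_id[i]
        if (counts[a, s] > 0) called <- c(called, s)
      }
      called <- unique(called)
      bad <- if (stringency == "strict") {
        length(occ) > 0 && all(occ %in% called)
      } else length(called) >= 1
      if (bad) out <- c(out, a)
    }
  }
  sort(unique(out))
}

# -- pair-based clustering metrics -------------------------------------------

oracle_pair_counts <- function(clusters, labels) {
  ids <- clusters$asv_id[!is_uncertain(labels[clusters$asv_id])]
  tp <- fp <- fn <- np <- 0
  n <- length(ids)
  if (n >= 2) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        same_cl <- clusters$otu_id[clusters$asv_id == ids[i]] ==
          clusters$otu_id[clusters$asv_id == ids[j]]
        same_sp <- labels[[ids[i]]] == labels[[ids[j]]]
        if (same_cl) np <- np + 1
        if (same_cl && same_sp) tp <- tp + 1
        if (!same_cl && same_sp) fn <- fn + 1
      }
    }
  }
  list(TP = tp, FP = np - tp, FN = fn, NP = np)
}

# -- codon signature counting ------------------------------------------------

# per-column counting for equal-length, indel-free codon sequences
oracle_signature <- function(seq_a, seq_b, code) {
  ca <- substring(seq_a, seq(1, nchar(seq_a) - 2, 3),
                  seq(3, nchar(seq_a), 3))
  cb <- substring(seq_b, seq(1, nchar(seq_b) - 2, 3),
                  seq(3, nchar(seq_b), 3))
  n_syn <- n_nonsyn <- 0
  for (k in seq_along(ca)) {
    if (ca[k] == cb[k]) next
    if (code[[ca[k]]] == code[[cb[k]]]) n_syn <- n_syn + 1
    else n_nonsyn <- n_nonsyn + 1
  }
  list(n_syn = n_syn, n_nonsyn = n_nonsyn)
}

# -- ordered-sweep filters (exhaustive neighbors, no n_closest cap) ---------

# identity lookup from a matchlist data.frame
oracle_pid <- function(ml, a, b) {
  hit <- (ml$query == a & ml$target == b) | (ml$query == b & ml$target == a)
  if (any(hit)) ml$pct_identity[which(hit)[1]] else NA_real_
}

oracle_echo <- function(clusters, counts, ml, params) {
  ord <- order_otus(clusters, counts)
  oc <- otu_counts(clusters, counts)
  authentic <- ord[1]
  disc <- character(0)
  for (e in ord[-1]) {
    flagged <- FALSE
    for (p in authentic) {
      pid <- oracle_pid(ml, e, p)
      if (is.na(pid) || pid < params$min_match) next
      occ_e <- which(oc[e, ] > 0)
      shared <- occ_e[oc[p, occ_e] > 0]
      if (length(shared) / length(occ_e) < params$min_overlap) next
      er <- oc[e, shared]; pr <- oc[p, shared]
      ok <- if (params$require_corr && length(shared) > 3) {
        fit <- summary(stats::lm(er ~ pr))$coefficients
        nrow(fit) >= 2 && !is.na(fit[2, 4]) &&
          fit[2, 4] < params$max_p_val &&
          fit[2, 1] < params$max_read_ratio
      } else {
        stat <- if (params$read_ratio_type == "max") max(er / pr)
                else mean(er / pr)
        stat < params$max_read_ratio
      }
      if (ok) { flagged <- TRUE; break }
    }
    if (flagged) disc <- c(disc, e) else authentic <- c(authentic, e)
  }
  sort(disc)
}

oracle_evo <- function(clusters, counts, ml, seqs, params, code,
                       weight_matrix) {
  ord <- order_otus(clusters, counts)
  oc <- otu_counts(clusters, counts)
  authentic <- ord[1]
  disc <- character(0)
  for (e in ord[-1]) {
    flagged <- FALSE
    for (p in authentic) {
      pid <- oracle_pid(ml, e, p)
      if (is.na(pid) || pid < params$min_match) next
      if (params$require_overlap) {
        occ_e <- which(oc[e, ] > 0)
        shared <- occ_e[oc[p, occ_e] > 0]
        if (length(shared) / length(occ_e) < params$min_overlap) next
      }
      ed <- as.integer(utils::adist(seqs[[e]], seqs[[p]]))
      if (ed == 0) next
      sig <- oracle_signature(seqs[[e]], seqs[[p]], code)
      num <- if (params$dist_type == "dadn") sig$n_nonsyn else {
        # weighted: recount with weights
        ca <- substring(seqs[[e]], seq(1, nchar(seqs[[e]]) - 2, 3),
                        seq(3, nchar(seqs[[e]]), 3))
        cb <- substring(seqs[[p]], seq(1, nchar(seqs[[p]]) - 2, 3),
                        seq(3, nchar(seqs[[p]]), 3))
        w <- 0
        for (k in seq_along(ca)) {
          if (ca[k] != cb[k] && code[[ca[k]]] != code[[cb[k]]]) {
            w <- w + weight_matrix[code[[ca[k]]], code[[cb[k]]]]
          }
        }
        w
      }
      dist_val <- if (sig$n_syn == 0) { if (num > 0) Inf else 0 }
                  else num / sig$n_syn
      if (dist_val / ed > params$dist_threshold) { flagged <- TRUE; break }
    }
    if (flagged) disc <- c(disc, e) else authentic <- c(authentic, e)
  }
  sort(disc)
}

# -- random fixture builders -------------------------------------------------

random_counts <- function(n_asv, n_samp, density = 0.5, max_reads = 200) {
  m <- matrix(0L, n_asv, n_samp,
              dimnames = list(sprintf("a%02d", seq_len(n_asv)),
                              sprintf("s%02d", seq_len(n_samp))))
  occ <- matrix(stats::runif(n_asv * n_samp) < density, n_asv, n_samp)
  m[occ] <- sample.int(max_reads, sum(occ), replace = TRUE)
  storage.mode(m) <- "integer"
  m
}

singleton_clusters <- function(counts) {
  data.frame(asv_id = rownames(counts), otu_id = rownames(counts),
             stringsAsFactors = FALSE)
}

# random stop-free coding sequence and simple mutators (table-5 aware)
random_coding_seq <- function(n_codons, code) {
  nonstop <- names(code)[code != "*"]
  paste(sample(nonstop, n_codons, replace = TRUE), collapse = "")
}
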