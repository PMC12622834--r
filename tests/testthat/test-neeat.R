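code5 <- Biostrings::getGeneticCode("5")

ml_of <- function(...) {
  # build a matchlist from "a|b|pid" strings
  recs <- strsplit(c(...), "|", fixed = TRUE)
  data.frame(query = vapply(recs, `[[`, "", 1),
             target = vapply(recs, `[[`, "", 2),
             pct_identity = as.numeric(vapply(recs, `[[`, "", 3)),
             edit_distance = NA_integer_, stringsAsFactors = FALSE)
}

test_that("OTU ordering is by samples, then reads, then id", {
  counts <- matrix(0L, 3, 9, dimnames = list(c("A", "B", "C"),
                                             paste0("s", 1:9)))
  counts["A", 1:5] <- 20L    # 5 samples, 100 reads
  counts["B", 1:5] <- 40L    # 5 samples, 200 reads
  counts["C", 1:9] <- c(rep(1L, 8), 2L)  # 9 samples, 10 reads
  cl <- singleton_clusters(counts)
  expect_equal(order_otus(cl, counts), c("C", "B", "A"))

  # ties on both keys break lexicographically
  counts2 <- matrix(10L, 2, 2, dimnames = list(c("b", "a"), c("s1", "s2")))
  expect_equal(order_otus(singleton_clusters(counts2), counts2), c("a", "b"))

  expect_equal(order_otus(singleton_clusters(counts)[0, ], counts),
               character(0))
})

test_that("echo filter criteria behave at the documented boundaries", {
  counts <- matrix(0L, 2, 10, dimnames = list(c("P", "E"), paste0("s", 1:10)))
  counts["P", ] <- 100L
  counts["E", ] <- 10L   # ratio 0.1 in every sample
  cl <- singleton_clusters(counts)
  ml <- ml_of("E|P|90")
  par <- echo_params(require_corr = FALSE, read_ratio_type = "max")
  rep <- echo_filter(cl, counts, ml, par)
  expect_equal(discarded(rep), "E")

  # parent co-occurring in only 9/10 samples fails min_overlap 0.95
  counts2 <- counts
  counts2["P", "s10"] <- 0L
  rep2 <- echo_filter(cl, counts2, ml, par)
  expect_equal(discarded(rep2), character(0))

  # single OTU: always authentic
  one <- counts["P", , drop = FALSE]
  rep3 <- suppressWarnings(
    echo_filter(singleton_clusters(one), one, ml_of("x|y|90")[0, ],
                echo_params()))
  expect_equal(kept(rep3), "P")
})

test_that("echo filter matches the exhaustive-neighbor oracle", {
  set.seed(41)
  for (iter in 1:6) {
    n <- sample(10:16, 1)
    counts <- random_counts(n, 8, density = 0.6)
    # plant two strong echo relationships so discards occur
    counts[2, ] <- ifelse(counts[1, ] > 0, pmax(1L, counts[1, ] %/% 20L), 0L)
    counts[4, ] <- ifelse(counts[3, ] > 0, pmax(1L, counts[3, ] %/% 15L), 0L)
    ids <- rownames(counts)
    cl <- singleton_clusters(counts)
    # random sparse matchlist with identities straddling min_match;
    # the planted echo pairs are forced in (one record per pair)
    pairs <- t(combn(ids, 2))
    forced <- (pairs[, 1] == ids[1] & pairs[, 2] == ids[2]) |
      (pairs[, 1] == ids[3] & pairs[, 2] == ids[4])
    keep <- (runif(nrow(pairs)) < 0.5 & !forced)
    ml <- data.frame(query = pairs[keep, 1], target = pairs[keep, 2],
                     pct_identity = runif(sum(keep), 80, 100),
                     edit_distance = NA_integer_, stringsAsFactors = FALSE)
    ml <- rbind(ml, data.frame(query = c(ids[1], ids[3]),
                               target = c(ids[2], ids[4]),
                               pct_identity = c(97, 96),
                               edit_distance = NA_integer_))
    for (par in list(echo_params(require_corr = FALSE, min_overlap = 0.6,
                                 n_closest = 20),
                     echo_params(require_corr = TRUE, min_overlap = 0.6,
                                 n_closest = 20),
                     echo_params(require_corr = FALSE, min_overlap = 0.6,
                                 read_ratio_type = "mean",
                                 max_read_ratio = 0.5,
                                 n_closest = 20))) {
      got <- suppressWarnings(
        sort(discarded(echo_filter(cl, counts, ml, par))))
      expect_equal(got, oracle_echo(cl, counts, ml, par),
                   info = paste("iter", iter))
    }
  }
})

test_that("evo filter flags nonsynonymous-only neighbors and obeys limits", {
  set.seed(42)
  base <- random_coding_seq(40, code5)
  cu_nonstop <- names(code5)[code5 != "*"]
  cds <- substring(base, seq(1, 118, 3), seq(3, 120, 3))
  # variant with 3 nonsynonymous codon changes, no synonymous ones
  cds_numt <- cds
  for (i in c(5, 12, 20)) {
    repeat {
      cand <- sample(cu_nonstop, 1)
      if (code5[[cand]] != code5[[cds[i]]]) { cds_numt[i] <- cand; break }
    }
  }
  # variant with only synonymous changes
  cds_syn <- cds
  for (i in c(3, 9)) {
    syns <- setdiff(cu_nonstop[code5[cu_nonstop] == code5[[cds[i]]]], cds[i])
    if (length(syns) > 0) cds_syn[i] <- syns[1]
  }
  seqs <- c(P = base,
            N = paste(cds_numt, collapse = ""),
            S = paste(cds_syn, collapse = ""))
  counts <- matrix(0L, 3, 5, dimnames = list(names(seqs), paste0("s", 1:5)))
  counts["P", ] <- 100L
  counts["N", ] <- 5L
  counts["S", ] <- 5L
  cl <- singleton_clusters(counts)
  ml <- compute_matchlist(seqs, min_match = 84)
  rep <- evo_filter(cl, counts, ml, seqs,
                    evo_params(dist_type = "dadn", require_overlap = TRUE))
  expect_equal(discarded(rep), "N")   # dadn infinite -> flagged
  # the synonymous-only variant has ratio 0 and is never flagged
  expect_true("S" %in% kept(rep))
})

test_that("evo filter matches the exhaustive-neighbor oracle", {
  set.seed(43)
  W <- aa_dissimilarity()
  for (iter in 1:3) {
    # family of sequences derived from one base with varying signatures
    base <- random_coding_seq(35, code5)
    cds <- substring(base, seq(1, 103, 3), seq(3, 105, 3))
    nonstop <- names(code5)[code5 != "*"]
    n <- 12
    seqs <- character(n)
    seqs[1] <- base
    for (k in 2:n) {
      ck <- cds
      for (i in sample(35, sample(2:5, 1))) {
        ck[i] <- sample(nonstop, 1)
      }
      seqs[k] <- paste(ck, collapse = "")
    }
    names(seqs) <- sprintf("o%02d", 1:n)
    counts <- random_counts(n, 8, density = 0.7)
    rownames(counts) <- names(seqs)
    counts[1, ] <- counts[1, ] + 100L   # make o01 dominant
    cl <- singleton_clusters(counts)
    ml <- compute_matchlist(seqs, min_match = 84)
    for (par in list(
      evo_params(dist_type = "dadn", require_overlap = FALSE,
                 n_closest = 20),
      evo_params(dist_type = "wdadn", require_overlap = FALSE,
                 dist_threshold = 0.3, n_closest = 20),
      evo_params(dist_type = "dadn", require_overlap = TRUE,
                 min_overlap = 0.5, n_closest = 20))) {
      got <- sort(discarded(evo_filter(cl, counts, ml, seqs, par,
                                       weight_matrix = W)))
      expect_equal(got, oracle_evo(cl, counts, ml, seqs, par, code5, W),
                   info = paste("iter", iter, par$dist_type,
                                par$require_overlap))
    }
  }
})

test_that("abundance filter agrees with its predicate oracle", {
  counts <- matrix(c(0L, 0L, 7L), 1, 3, dimnames = list("O", paste0("s", 1:3)))
  cl <- singleton_clusters(counts)
  expect_equal(kept(abundance_filter(cl, counts, abundance_params(5, "max"))),
               "O")
  expect_equal(
    discarded(abundance_filter(cl, counts, abundance_params(8, "max"))), "O")

  set.seed(44)
  counts <- random_counts(25, 6, density = 0.5, max_reads = 20)
  cl <- singleton_clusters(counts)
  for (type in c("sum", "max", "mean")) {
    for (cutoff in c(3, 10, 25)) {
      rep <- abundance_filter(cl, counts, abundance_params(cutoff, type))
      stat <- apply(counts, 1, function(x) switch(type,
        sum = sum(x), max = max(x),
        mean = if (any(x > 0)) mean(x[x > 0]) else 0))
      expect_setequal(discarded(rep), rownames(counts)[stat < cutoff])
    }
  }
})

test_that("taxonomy filter discards uncertain annotations at the rank", {
  taxa <- matrix(c("Diptera", "unassigned.Insecta", "unresolved.Insecta",
                   "unassigned", "Hymenoptera"),
                 5, 1, dimnames = list(paste0("o", 1:5), "Order"))
  rep <- taxonomy_filter(taxa, tax_filter_params("Order"))
  expect_setequal(discarded(rep), c("o2", "o3", "o4"))
  expect_setequal(kept(rep), c("o1", "o5"))
})

test_that("monotonicity of the sweep filters in their thresholds", {
  # star-shaped fixture: one dominant parent P, satellites only matched
  # to P, so the authentic neighborhood is fixed and threshold effects
  # are not confounded by cascades through the authentic set
  set.seed(45)
  code5 <- Biostrings::getGeneticCode("5")
  n_sat <- 6
  base <- random_coding_seq(30, code5)
  cds <- substring(base, seq(1, 88, 3), seq(3, 90, 3))
  nonstop <- names(code5)[code5 != "*"]
  ids <- c("P", sprintf("V%d", 1:n_sat))
  seqs <- setNames(character(n_sat + 1), ids)
  seqs["P"] <- base
  for (k in 1:n_sat) {
    ck <- cds
    for (i in sample(30, k)) ck[i] <- sample(nonstop, 1)
    seqs[k + 1] <- paste(ck, collapse = "")
  }
  counts <- matrix(0L, n_sat + 1, 8,
                   dimnames = list(ids, paste0("s", 1:8)))
  counts["P", ] <- c(200L, 350L, 120L, 90L, 400L, 260L, 150L, 310L)
  for (k in 1:n_sat) {
    counts[k + 1, ] <- pmax(1L, as.integer(counts["P", ] * k / 10))
  }
  cl <- singleton_clusters(counts)
  ml <- data.frame(query = "P", target = ids[-1],
                   pct_identity = 95, edit_distance = NA_integer_,
                   stringsAsFactors = FALSE)
  # echo: raising max_read_ratio never shrinks the discard set
  prev <- character(0)
  for (mrr in c(0.15, 0.35, 0.55, 1)) {
    d <- discarded(echo_filter(cl, counts, ml,
                               echo_params(require_corr = FALSE,
                                           max_read_ratio = mrr)))
    expect_true(all(prev %in% d))
    prev <- d
  }
  expect_gt(length(prev), 0)
  # evo: raising dist_threshold never grows the discard set
  prev <- NULL
  for (thr in c(0.05, 0.5, 2, 10)) {
    d <- discarded(evo_filter(cl, counts, ml, seqs,
                              evo_params(dist_type = "dadn",
                                         require_overlap = FALSE,
                                         dist_threshold = thr)))
    if (!is.null(prev)) expect_true(all(d %in% prev))
    prev <- d
  }
  # abundance: raising cutoff never shrinks the discard set
  prev <- character(0)
  for (cut in c(2, 50, 500, 5000)) {
    d <- discarded(abundance_filter(cl, counts, abundance_params(cut, "sum")))
    expect_true(all(prev %in% d))
    prev <- d
  }
})

test_that("sweep results are invariant to input permutations", {
  com <- generate_community(community_spec(n_species = 15, seed = 5,
                                           chimera_count = 0L))
  seqs <- setNames(com$asvs$sequence, com$asvs$asv_id)
  ml <- compute_matchlist(seqs, min_match = 84)
  base <- suppressWarnings(
    run_neeat(com$clusters, com$counts, com$taxa, matchlist = ml,
              seqs = seqs))
  # permute count rows/columns and cluster rows
  set.seed(9)
  counts_p <- com$counts[sample(nrow(com$counts)), sample(ncol(com$counts))]
  cl_p <- com$clusters[sample(nrow(com$clusters)), ]
  ml_p <- ml[sample(nrow(ml)), ]
  again <- suppressWarnings(
    run_neeat(cl_p, counts_p, com$taxa, matchlist = ml_p, seqs = seqs))
  expect_equal(again, base)
})

test_that("run_neeat attributes each planted artifact to its filter", {
  # hand-built community: parent P; echo E (proportional, nested samples);
  # NUMT V (nonsynonymous-only changes, occupying samples beyond P so the
  # echo filter cannot claim it; caught by the global evo filter); a
  # low-abundance singleton R; an OTU U with unassigned order
  set.seed(46)
  base <- random_coding_seq(40, code5)
  cds <- substring(base, seq(1, 118, 3), seq(3, 120, 3))
  nonstop <- names(code5)[code5 != "*"]
  cds_v <- cds
  for (i in c(4, 18, 30)) {
    repeat {
      cand <- sample(nonstop, 1)
      if (code5[[cand]] != code5[[cds[i]]]) { cds_v[i] <- cand; break }
    }
  }
  cds_e <- cds
  syns <- setdiff(nonstop[code5[nonstop] == code5[[cds[7]]]], cds[7])
  cds_e[7] <- syns[1]
  seqs <- c(P = base, E = paste(cds_e, collapse = ""),
            V = paste(cds_v, collapse = ""),
            R = random_coding_seq(40, code5),
            U = random_coding_seq(40, code5))
  counts <- matrix(0L, 5, 10,
                   dimnames = list(names(seqs), paste0("s", 1:10)))
  counts["P", 1:8] <- c(120L, 340L, 80L, 210L, 55L, 400L, 95L, 160L)
  counts["E", 1:8] <- pmax(1L, counts["P", 1:8] %/% 20L)
  counts["V", c(1:4, 9, 10)] <- 30L   # half its samples outside P's range
  counts["R", 5] <- 2L
  counts["U", 1:6] <- 50L
  taxa <- matrix("x", 5, 7,
                 dimnames = list(names(seqs), default_ranks()))
  taxa[, "Order"] <- c("Diptera", "Diptera", "Diptera", "Diptera",
                       "unassigned.Insecta")
  cl <- singleton_clusters(counts)
  rep <- suppressWarnings(
    run_neeat(cl, counts, taxa, seqs = seqs,
              abundance = abundance_params(3, "max")))
  disc <- rep[rep$decision == "discard", ]
  expect_equal(disc$filter_name[disc$entity_id == "E"], "echo")
  expect_equal(disc$filter_name[disc$entity_id == "V"], "evo.global")
  expect_equal(disc$filter_name[disc$entity_id == "R"], "abundance")
  expect_equal(disc$filter_name[disc$entity_id == "U"], "taxonomy")
  expect_true("P" %in% kept(rep))

  # permissive parameters on an all-authentic community: zero discards
  com <- generate_community(community_spec(n_species = 10, seed = 2,
                                           numt_rate = 0, echo_rate = 0,
                                           chimera_count = 0L))
  seqs2 <- setNames(com$asvs$sequence, com$asvs$asv_id)
  rep2 <- suppressWarnings(
    run_neeat(com$clusters, com$counts, com$taxa, seqs = seqs2,
              abundance = abundance_params(0, "max")))
  expect_equal(discarded(rep2), character(0))
})

test_that("partitioned and unpartitioned NEEAT agree across distant orders", {
  com <- generate_community(community_spec(n_species = 24, seed = 7,
                                           chimera_count = 0L))
  seqs <- setNames(com$asvs$sequence, com$asvs$asv_id)
  ml <- compute_matchlist(seqs, min_match = 84)
  # no cross-order pair reaches min_match (independent random ancestors)
  ord_of <- com$taxa[, "Order"]
  expect_true(all(ord_of[ml$query] == ord_of[ml$target]))
  whole <- suppressWarnings(
    run_neeat(com$clusters, com$counts, com$taxa, matchlist = ml,
              seqs = seqs))
  parts <- suppressWarnings(
    run_neeat(com$clusters, com$counts, com$taxa, matchlist = ml,
              seqs = seqs, partition_rank = "Order"))
  expect_equal(parts$entity_id, whole$entity_id)
  expect_equal(parts$decision, whole$decision)
})
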