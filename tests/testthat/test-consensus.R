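ranks3 <- c("Family", "Genus", "Species")

five_asv_cluster <- function() {
  taxa <- matrix(c(rep("Family1", 5),
                   c("Genus1", "Genus1", "Genus2", "Genus2", "Genus2"),
                   c("Species1", "Species1", "Species2", "Species2",
                     "Species3")),
                 5, 3, dimnames = list(paste0("asv", 1:5), ranks3))
  counts <- matrix(c(10L, 10L, 50L, 10L, 20L), 5, 1,
                   dimnames = list(paste0("asv", 1:5), "s1"))
  list(taxa = taxa, counts = counts, members = paste0("asv", 1:5))
}

test_that("read-weighted consensus resolves the five-ASV example cluster", {
  fx <- five_asv_cluster()
  out <- consensus_taxonomy(fx$members, fx$counts, fx$taxa)
  expect_equal(as.character(out[ranks3]),
               c("Family1", "Genus2", "unresolved.Genus2"))
  shares <- attr(out, "shares")
  expect_equal(unname(shares["Species"]), 0.6)  # 20/60/20% -> top 60%
  expect_equal(unname(shares["Genus"]), 0.8)    # 20/80% -> adopted
})

test_that("consensus is unanimous, scale-free and order-invariant", {
  fx <- five_asv_cluster()
  # unanimity: identical lineages pass through unchanged
  taxa_u <- fx$taxa
  taxa_u[, "Genus"] <- "Genus9"
  taxa_u[, "Species"] <- "Species9"
  out <- consensus_taxonomy(fx$members, fx$counts, taxa_u)
  expect_equal(as.character(out), c("Family1", "Genus9", "Species9"))

  # two species at 50/50 reads with a shared genus escalate to genus
  taxa2 <- matrix(c("F", "F", "G", "G", "S1", "S2"), 2, 3,
                  dimnames = list(c("a", "b"), ranks3))
  counts2 <- matrix(c(30L, 30L), 2, 1, dimnames = list(c("a", "b"), "s1"))
  out2 <- consensus_taxonomy(c("a", "b"), counts2, taxa2)
  expect_equal(as.character(out2), c("F", "G", "unresolved.G"))

  # invariance under member reordering and count rescaling
  out_r <- consensus_taxonomy(rev(fx$members), fx$counts, fx$taxa)
  expect_equal(as.character(out_r),
               as.character(consensus_taxonomy(fx$members, fx$counts,
                                               fx$taxa)))
  out_s <- consensus_taxonomy(fx$members, fx$counts * 7L, fx$taxa)
  expect_equal(as.character(out_s), as.character(out_r))
})

test_that("threshold 1.0 equals unanimity-or-escalation via brute force", {
  set.seed(55)
  for (iter in 1:20) {
    n <- sample(2:6, 1)
    ids <- paste0("m", seq_len(n))
    taxa <- matrix(c(sample(paste0("F", 1:2), n, TRUE),
                     sample(paste0("G", 1:3), n, TRUE),
                     sample(paste0("S", 1:4), n, TRUE)),
                   n, 3, dimnames = list(ids, ranks3))
    counts <- matrix(sample(1:50, n), n, 1, dimnames = list(ids, "s1"))
    out <- suppressWarnings(
      consensus_taxonomy(ids, counts, taxa, consensus_params(1.0)))
    w <- counts[, 1]
    # brute-force: find lowest rank where one label carries all weight
    expected <- rep("unresolved", 3)
    for (r in 3:1) {
      sh <- tapply(w, taxa[, r], sum) / sum(w)
      if (max(sh) >= 1.0) {
        win <- names(sh)[which.max(sh)]
        src <- ids[taxa[, r] == win][which.max(w[taxa[, r] == win])]
        expected <- c(if (r > 1) taxa[src, seq_len(r - 1)], win,
                      if (r < 3) rep(paste0("unresolved.", win), 3 - r))
        break
      }
    }
    expect_equal(as.character(out), as.character(expected),
                 info = paste("iter", iter))
    # rank consistency: nothing assigned below an unresolved rank
    unres <- startsWith(as.character(out), "unresolved")
    if (any(unres)) expect_true(all(unres[seq(which(unres)[1], 3)]))
  }
})

test_that("representative ASV follows the mean/median rules and tie-breaks", {
  counts <- matrix(c(10L, 0L, 4L, 4L), 2, 2, byrow = TRUE,
                   dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_equal(representative_asv(c("a", "b"), counts, "mean"), "a")  # 5 > 4
  expect_equal(representative_asv(c("a", "b"), counts, "median"), "a") # 5 > 4
  expect_equal(representative_asv("b", counts), "b")

  # exact tie on the statistic and totals: lexicographic id
  tie <- matrix(c(6L, 2L, 2L, 6L), 2, 2, byrow = TRUE,
                dimnames = list(c("z", "y"), c("s1", "s2")))
  expect_equal(representative_asv(c("z", "y"), tie, "mean"), "y")
})

test_that("representative mode copies the representative's annotation", {
  fx <- five_asv_cluster()
  out <- consensus_taxonomy(fx$members, fx$counts, fx$taxa,
                            consensus_params(mode = "representative"))
  expect_equal(as.character(out), unname(fx$taxa["asv3", ]))  # highest reads
})

test_that("unassigned labels propagate down the lineage", {
  row <- c(Order = "Diptera", Family = "unassigned")
  expect_equal(unname(propagate_unassigned(row)[2]), "unassigned.Diptera")
  row2 <- c(Order = "unassigned.Insecta", Family = "unassigned")
  expect_equal(unname(propagate_unassigned(row2)[2]), "unassigned.Insecta")
  row3 <- c(Order = "Diptera", Family = "Muscidae")
  expect_equal(propagate_unassigned(row3), row3)
  # cascades: bare cells keep copying the uncertain parent down
  row4 <- c(Order = "Diptera", Family = "unassigned", Genus = "unassigned")
  out4 <- propagate_unassigned(row4)
  expect_equal(unname(out4[3]), "unassigned.Diptera")
})

test_that("negative-control filter applies per dataset with thresholds", {
  counts <- matrix(0L, 2, 6,
                   dimnames = list(c("o1", "o2"), paste0("s", 1:6)))
  counts["o1", c("s1", "s2", "s3")] <- 5L   # in 3 of 4 controls
  counts["o2", "s6"] <- 5L                  # in no control
  md <- data.frame(sample_id = paste0("s", 1:6), dataset = "d1",
                   is_negative_control = c(TRUE, TRUE, TRUE, TRUE, FALSE,
                                           FALSE),
                   stringsAsFactors = FALSE)
  cl <- singleton_clusters(counts)
  rep <- filter_negative_controls(cl, counts, md, max_fraction = 0.5)
  expect_equal(discarded(rep), "o1")   # 3/4 > 0.5
  rep2 <- filter_negative_controls(cl, counts, md, max_fraction = 1.0)
  expect_equal(discarded(rep2), character(0))
  md_none <- md
  md_none$is_negative_control <- FALSE
  expect_warning(rep3 <- filter_negative_controls(cl, counts, md_none, 0.5),
                 "no negative controls")
  expect_equal(discarded(rep3), character(0))
})

test_that("spike-in filter supports list and occurrence modes", {
  counts <- matrix(0L, 3, 10,
                   dimnames = list(c("o1", "o2", "o3"), paste0("s", 1:10)))
  counts["o1", 1:9] <- 3L   # 90% occupancy
  counts["o2", 1] <- 3L     # 10% occupancy
  counts["o3", 1:2] <- 3L
  taxa <- matrix(c("SpikeGenus", "SpikeGenus", "OtherGenus",
                   "SpA", "SpB", "SpC"),
                 3, 2, dimnames = list(c("o1", "o2", "o3"),
                                       c("Genus", "Species")))
  cl <- singleton_clusters(counts)
  rep <- filter_spikeins(cl, taxa, counts, taxon = "SpikeGenus",
                         occurrence_pct = 50)
  expect_equal(discarded(rep), "o1")
  expect_true(all(c("o2", "o3") %in% kept(rep)))
  # list mode hits regardless of occurrence
  rep2 <- filter_spikeins(cl, taxa, counts, species = "SpB")
  expect_equal(discarded(rep2), "o2")
  expect_warning(filter_spikeins(cl, taxa, counts, species = "Nope"),
                 "absent")
})
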