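#' Specification of a synthetic metabarcoding community
#'
#' Parameters of the ground-truth community generator. Authentic species
#' are stop-free codon sequences diverged (mostly synonymously) from a
#' per-order ancestor; planted noise classes mimic the statistical
#' structure that post-clustering noise filters exploit:
#'
#' * NUMTs: copies of a parent accumulating nonsynonymous changes at
#'   `numt_nonsyn_inflation` times the authentic nonsynonymous rate, with
#'   counts a fixed fraction of the parent's counts in exactly the
#'   parent's samples.
#' * echoes: 1-2 nt (synonymous) variants of a parent with proportional
#'   counts in the parent's samples.
#' * chimeras: left half of one abundant parent joined, at a codon
#'   boundary, to the right half of another; present only where both
#'   parents occur.
#'
#' @param n_species Number of authentic species.
#' @param n_samples Number of samples.
#' @param seed Integer seed fixing all randomness.
#' @param codon_length Sequence length in codons (139 codons = 417 nt,
#'   matching a 418 bp amplicon read in frame).
#' @param numt_rate Per-species probability of a planted NUMT.
#' @param numt_read_ratio NUMT/parent read ratio.
#' @param echo_rate Per-species probability of a planted echo.
#' @param echo_read_ratio Echo/parent read ratio.
#' @param chimera_count Number of planted chimeras.
#' @param chimera_read_ratio Chimera reads as a fraction of the rarer
#'   parent's reads in shared samples.
#' @param syn_rate,nonsyn_rate Per-codon probabilities of synonymous /
#'   nonsynonymous change for authentic divergence from the ancestor.
#' @param numt_nonsyn_inflation Multiplier (> 1) on `nonsyn_rate` for
#'   NUMT divergence from its parent.
#' @param occupancy_p Geometric parameter of the skewed sample-occupancy
#'   distribution (smaller = more widespread species).
#' @param reads_meanlog,reads_sdlog Log-normal read-count parameters per
#'   occupied sample.
#' @param code_table NCBI genetic code id.
#' @return List of class `community_spec`.
#' @export
community_spec <- function(n_species = 60L, n_samples = 30L, seed = 1L,
                           codon_length = 139L,
                           numt_rate = 0.35, numt_read_ratio = 0.05,
                           echo_rate = 0.35, echo_read_ratio = 0.05,
                           chimera_count = 5L, chimera_read_ratio = 0.05,
                           syn_rate = 0.30, nonsyn_rate = 0.02,
                           numt_nonsyn_inflation = 5,
                           occupancy_p = 0.15,
                           reads_meanlog = 5, reads_sdlog = 1,
                           code_table = "5") {
  rates <- c(numt_rate, numt_read_ratio, echo_rate, echo_read_ratio,
             syn_rate, nonsyn_rate, occupancy_p)
  stopifnot(all(rates >= 0), all(rates <= 1), numt_nonsyn_inflation >= 1,
            n_species >= 1, n_samples >= 1, codon_length >= 2)
  structure(as.list(environment()), class = "community_spec")
}

# codon utilities for the generator ------------------------------------------

codon_universe <- function(code) {
  codons <- names(code)
  nonstop <- codons[code != "*"]
  by_aa <- split(nonstop, code[nonstop])
  # synonymous single-nt neighbors of each non-stop codon
  syn1 <- lapply(stats::setNames(nonstop, nonstop), function(cd) {
    syns <- setdiff(by_aa[[code[[cd]]]], cd)
    syns[vapply(syns, function(s) {
      sum(strsplit(cd, "")[[1]] != strsplit(s, "")[[1]]) == 1L
    }, logical(1))]
  })
  list(nonstop = nonstop, by_aa = by_aa, syn1 = syn1)
}

# apply per-codon synonymous/nonsynonymous substitutions
mutate_codons <- function(codons, syn_p, nonsyn_p, cu, code) {
  for (i in seq_along(codons)) {
    cd <- codons[i]
    if (syn_p > 0 && stats::runif(1) < syn_p) {
      syns <- setdiff(cu$by_aa[[code[[cd]]]], cd)
      if (length(syns) > 0L) cd <- sample(syns, 1L)
    }
    if (nonsyn_p > 0 && stats::runif(1) < nonsyn_p) {
      others <- cu$nonstop[code[cu$nonstop] != code[[cd]]]
      cd <- sample(others, 1L)
    }
    codons[i] <- cd
  }
  codons
}

# force exactly k nonsynonymous codon replacements at random positions
force_nonsyn <- function(codons, k, cu, code) {
  pos <- sample(seq_along(codons), k)
  for (i in pos) {
    others <- cu$nonstop[code[cu$nonstop] != code[[codons[i]]]]
    codons[i] <- sample(others, 1L)
  }
  codons
}

#' Generate a ground-truth synthetic community
#'
#' Produces every input the curation pipeline consumes — ASV sequences,
#' an ASV x sample count table, an ASV-level taxonomy, a cluster map
#' (one singleton cluster per ASV), and a ground-truth table labelling
#' each ASV `authentic`, `numt`, `echo` or `chimera` with its parent(s).
#'
#' All sequences are stop-free in frame 0 under the configured genetic
#' code. Planted noise always ranks below its parent in [order_otus()]
#' (no more samples, strictly fewer reads).
#'
#' @param spec A [community_spec()].
#' @return List of class `synthetic_community` with elements `asvs`,
#'   `counts`, `taxa`, `clusters`, `truth`, `spec`.
#' @export
generate_community <- function(spec = community_spec()) {
  stopifnot(inherits(spec, "community_spec"))
  set.seed(spec$seed)
  code <- genetic_code(spec$code_table)
  cu <- codon_universe(code)
  L <- spec$codon_length
  n_orders <- max(2L, ceiling(spec$n_species / 15))
  order_of <- rep(seq_len(n_orders), length.out = spec$n_species)
  ancestors <- lapply(seq_len(n_orders), function(o) {
    sample(cu$nonstop, L, replace = TRUE)
  })

  samples <- sprintf("s%02d", seq_len(spec$n_samples))
  seqs <- list(); counts <- list(); taxa_rows <- list(); truth <- list()
  seen <- character(0)

  add_asv <- function(id, codons, reads, tax, class, parent = "",
                      parent_b = "") {
    s <- paste(codons, collapse = "")
    seqs[[id]] <<- s
    seen <<- c(seen, s)
    counts[[id]] <<- reads
    taxa_rows[[id]] <<- tax
    truth[[id]] <<- data.frame(asv_id = id, class = class,
                               parent = parent, parent_b = parent_b,
                               stringsAsFactors = FALSE)
  }

  sp_codons <- list()
  for (i in seq_len(spec$n_species)) {
    id <- sprintf("sp%03d", i)
    o <- order_of[i]
    repeat {
      cds <- mutate_codons(ancestors[[o]], spec$syn_rate, spec$nonsyn_rate,
                           cu, code)
      if (!paste(cds, collapse = "") %in% seen) break
    }
    sp_codons[[id]] <- cds
    j <- sum(order_of[seq_len(i)] == o)       # index within order
    tax <- c(Kingdom = "Animalia", Phylum = "Arthropoda", Class = "Insecta",
             Order = sprintf("Order%02d", o),
             Family = sprintf("Family%02d_%d", o, (j - 1) %/% 6 + 1),
             Genus = sprintf("Genus%02d_%d", o, (j - 1) %/% 3 + 1),
             Species = sprintf("Species%03d", i))
    n_occ <- min(spec$n_samples, 1L + stats::rgeom(1L, spec$occupancy_p))
    occ <- sample(spec$n_samples, n_occ)
    reads <- integer(spec$n_samples)
    reads[occ] <- pmax(10L, as.integer(round(
      stats::rlnorm(n_occ, spec$reads_meanlog, spec$reads_sdlog))))
    add_asv(id, cds, reads, tax, "authentic")
  }

  scale_counts <- function(parent_reads, ratio) {
    out <- integer(length(parent_reads))
    occ <- parent_reads > 0
    out[occ] <- pmax(1L, as.integer(round(ratio * parent_reads[occ])))
    out
  }

  for (i in seq_len(spec$n_species)) {
    pid <- sprintf("sp%03d", i)
    if (stats::runif(1) < spec$numt_rate) {
      repeat {
        cds <- mutate_codons(sp_codons[[pid]], 0,
                             spec$nonsyn_rate * spec$numt_nonsyn_inflation,
                             cu, code)
        n_diff <- sum(cds != sp_codons[[pid]])
        if (n_diff < 2L) {
          cds <- force_nonsyn(sp_codons[[pid]], 3L, cu, code)
        }
        if (!paste(cds, collapse = "") %in% seen) break
      }
      add_asv(paste0(pid, "_numt"), cds,
              scale_counts(counts[[pid]], spec$numt_read_ratio),
              taxa_rows[[pid]], "numt", parent = pid)
    }
    if (stats::runif(1) < spec$echo_rate) {
      repeat {
        cds <- sp_codons[[pid]]
        cand <- which(lengths(cu$syn1[cds]) > 0L)
        k <- min(sample(1:2, 1L), length(cand))
        pos <- if (length(cand) == 1L) cand else sample(cand, k)
        for (p in pos) {
          cds[p] <- sample(cu$syn1[[cds[p]]], 1L)
        }
        if (!paste(cds, collapse = "") %in% seen) break
      }
      add_asv(paste0(pid, "_echo"), cds,
              scale_counts(counts[[pid]], spec$echo_read_ratio),
              taxa_rows[[pid]], "echo", parent = pid)
    }
  }

  if (spec$chimera_count > 0L) {
    sp_ids <- sprintf("sp%03d", seq_len(spec$n_species))
    pairs <- list()
    for (a in seq_along(sp_ids)) {
      for (b in seq_along(sp_ids)) {
        if (a == b) next
        if (any(counts[[sp_ids[a]]] > 0 & counts[[sp_ids[b]]] > 0)) {
          pairs[[length(pairs) + 1L]] <- c(sp_ids[a], sp_ids[b])
        }
      }
    }
    n_chim <- min(spec$chimera_count, length(pairs))
    if (n_chim < spec$chimera_count) {
      warning("only ", n_chim, " of ", spec$chimera_count,
              " chimeras could be placed (too few co-occurring parents)")
    }
    if (n_chim > 0L) {
      sel <- sample(length(pairs), n_chim)
      m <- L %/% 2L
      for (k in seq_len(n_chim)) {
        pa <- pairs[[sel[k]]][1L]; pb <- pairs[[sel[k]]][2L]
        cds <- c(sp_codons[[pa]][1:m], sp_codons[[pb]][(m + 1L):L])
        if (paste(cds, collapse = "") %in% seen) next
        shared <- pmin(counts[[pa]], counts[[pb]])
        add_asv(sprintf("chim%02d", k), cds,
                scale_counts(shared, spec$chimera_read_ratio),
                taxa_rows[[pa]], "chimera", parent = pa, parent_b = pb)
      }
    }
  }

  ids <- names(seqs)
  cm <- do.call(rbind, counts[ids])
  dimnames(cm) <- list(ids, samples)
  storage.mode(cm) <- "integer"
  taxa <- do.call(rbind, taxa_rows[ids])
  rownames(taxa) <- ids
  asvs <- data.frame(asv_id = ids,
                     sequence = unlist(seqs[ids], use.names = FALSE),
                     stringsAsFactors = FALSE)
  asvs$length <- nchar(asvs$sequence)
  structure(list(
    asvs = asvs, counts = cm, taxa = taxa,
    clusters = data.frame(asv_id = ids, otu_id = ids,
                          stringsAsFactors = FALSE),
    truth = do.call(rbind, truth[ids]),
    spec = spec), class = "synthetic_community")
}

#' Generate oracle chimera calls for a synthetic community
#'
#' Emits perfect calls for every planted chimera (in samplewise mode, one
#' call per occupied sample; in batchwise mode, a single call), optionally
#' plus false-positive calls on authentic ASVs for stress-testing the
#' co-occurrence policies.
#'
#' @param community A `synthetic_community`.
#' @param mode `"samplewise"` or `"batchwise"`.
#' @param false_call_rate Fraction of authentic ASVs to mis-call as
#'   chimeric (in one random occupied sample for samplewise mode).
#' @return data.frame of chimera calls (see [read_chimera_calls()]).
#' @export
generate_chimera_calls <- function(community,
                                   mode = c("samplewise", "batchwise"),
                                   false_call_rate = 0) {
  mode <- match.arg(mode)
  stopifnot(inherits(community, "synthetic_community"))
  chim <- community$truth[community$truth$class == "chimera", ,
                          drop = FALSE]
  counts <- community$counts
  rows <- list()
  for (i in seq_len(nrow(chim))) {
    a <- chim$asv_id[i]
    if (mode == "batchwise") {
      rows[[length(rows) + 1L]] <- data.frame(
        asv_id = a, sample_id = "", parent_a = chim$parent[i],
        parent_b = chim$parent_b[i], verdict = "chimeric",
        stringsAsFactors = FALSE)
    } else {
      for (s in colnames(counts)[counts[a, ] > 0]) {
        rows[[length(rows) + 1L]] <- data.frame(
          asv_id = a, sample_id = s, parent_a = chim$parent[i],
          parent_b = chim$parent_b[i], verdict = "chimeric",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (false_call_rate > 0) {
    auth <- community$truth$asv_id[community$truth$class == "authentic"]
    hit <- auth[stats::runif(length(auth)) < false_call_rate]
    for (a in hit) {
      others <- setdiff(auth, a)
      ps <- sample(others, 2L)
      s <- if (mode == "batchwise") "" else
        sample(colnames(counts)[counts[a, ] > 0], 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        asv_id = a, sample_id = s, parent_a = ps[1L], parent_b = ps[2L],
        verdict = "chimeric", stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(asv_id = character(), sample_id = character(),
                      parent_a = character(), parent_b = character(),
                      verdict = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a synthetic community to a directory
#'
#' Writes the FASTA, count, taxonomy, cluster and ground-truth tables in
#' the formats the readers of this package consume.
#'
#' @param community A `synthetic_community`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of paths written.
#' @export
write_community <- function(community, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "asvs.fasta"),
             counts = file.path(dir, "counts.tsv"),
             taxonomy = file.path(dir, "taxonomy.tsv"),
             clusters = file.path(dir, "clusters.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_fasta(community$asvs, paths[["fasta"]])
  write_counts(community$counts, paths[["counts"]])
  write_taxonomy(community$taxa, paths[["taxonomy"]])
  write_cluster_map(community$clusters, paths[["clusters"]])
  utils::write.table(community$truth, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Match filter attributions against planted noise classes
#'
#' For each noise OTU discarded by a NEEAT report, checks whether the
#' filter responsible is one that targets the planted noise class.
#' Echoes are the designated target of the echo filter. NUMTs carry two
#' detectable signatures — they co-segregate with their parent at a low
#' read ratio (the co-occurrence signature the echo filter tests) and
#' they accumulate excess nonsynonymous change (the signature the
#' evolutionary filters test) — so either filter is a correct
#' attribution for a NUMT. Chimeras missed by dedicated chimera removal
#' are likewise legitimate prey of both sweep filters.
#'
#' @param report A filter report from [run_neeat()].
#' @param truth Ground-truth table of a `synthetic_community`.
#' @return data.frame with one row per discarded noise OTU: `asv_id`,
#'   `class`, `filter_name`, `matched`.
#' @export
noise_attribution <- function(report, truth) {
  expected <- list(echo = "echo",
                   numt = c("evo.local", "evo.global", "echo"),
                   chimera = c("evo.local", "evo.global", "echo"))
  disc <- report[report$decision == "discard", , drop = FALSE]
  noise <- truth[truth$class != "authentic" &
                   truth$asv_id %in% disc$entity_id, , drop = FALSE]
  if (nrow(noise) == 0L) {
    return(data.frame(asv_id = character(), class = character(),
                      filter_name = character(), matched = logical(),
                      stringsAsFactors = FALSE))
  }
  fn <- disc$filter_name[match(noise$asv_id, disc$entity_id)]
  data.frame(asv_id = noise$asv_id, class = noise$class, filter_name = fn,
             matched = mapply(function(cl, f) f %in% expected[[cl]],
                              noise$class, fn),
             row.names = NULL, stringsAsFactors = FALSE)
}
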