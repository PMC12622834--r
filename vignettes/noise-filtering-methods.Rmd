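---
title: "Methods: noise filtering of deep metabarcoding OTU tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: noise filtering of deep metabarcoding OTU tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neeatr)
```

## Scope and model

`neeatr` curates OTU tables produced from protein-coding amplicons
(CO1 being the motivating marker). Denoising, taxonomic annotation and
clustering are consumed as inputs; the package decides which clusters are
authentic. Two statistical signatures drive the decisions:

* **Co-occurrence.** Artifacts generated from a template during PCR and
  sequencing — error variants and co-amplified NUMTs — appear in the same
  samples as their template and at read counts roughly proportional to
  it. Authentic species, by contrast, have sample distributions of their
  own and read ratios with high variance across samples.
* **Selection.** An authentic CO1 haplotype diverges under strong
  purifying selection, so differences between close authentic neighbors
  are mostly synonymous. A NUMT evolves as a nuclear pseudogene under
  relaxed selection and accumulates nonsynonymous changes at a strongly
  inflated rate. The ratio of nonsynonymous to synonymous codon
  differences (`dadn`), normalized by the nucleotide edit distance,
  is therefore large exactly for evolutionarily implausible close
  neighbors.

## The ordered sweep

All sweep filters process OTUs in a fixed order: descending number of
occupied samples, then descending total reads, then ascending OTU id (the
deterministic tie-break). The top OTU is authentic by definition; each
later OTU is compared against the `n_closest` (default 10) previously
accepted OTUs within `min_match` (default 84%) percent identity, ranked
by identity with ties broken by acceptance order. Distances are computed
between cluster *representatives* (highest mean read rule by default;
median available): applying the filters to clustered data with a single
sequence per cluster is the only reading that scales.

The echo filter's read criterion has two branches. With `require_corr`
(default) and more than three shared samples, an ordinary least-squares
regression of echo reads on parent reads (with intercept) must have a
two-sided slope *p*-value below `max_p_val` (0.05) and a slope below
`max_read_ratio` (1.0); the slope is the natural estimate of the read
ratio. Otherwise a per-sample read-ratio summary (`max` by default, or
`mean`) over shared samples must fall below `max_read_ratio`. Ratios are
computed only over samples where both OTUs occur, as they are undefined
elsewhere. A degenerate regression (constant predictor, undefined slope)
counts as no evidence and does not flag.

The evolutionary filters flag an OTU when
`dist_value / edit_distance > dist_threshold` (default 1.0) for some
accepted neighbor, with `dist_value` either `dadn` or the biochemically
weighted `wdadn` (default). Conventions: pairs at edit distance 0 are
skipped (no evidence); `n_syn = 0` with `n_nonsyn > 0` gives an infinite
distance and always flags; columns with gaps or ambiguous bases count
toward neither class (the data carry no codon-level evidence there). The
local variant additionally requires `min_overlap` (0.95) sample overlap;
the global variant does not and can reach decoupled NUMTs.

NEEAT applies, in fixed order: echo, evo local, evo global, abundance,
taxonomic annotation — each stage consuming the OTUs the previous one
retained, so the report attributes every discard to the first filter
that claimed it. With `partition_rank` set (default Order in the
pipeline), the sweep runs independently per taxon partition; when no
cross-partition pair reaches `min_match`, partitioned and unpartitioned
runs are provably identical, which the tests verify.

## Codon-aware distances

Pairs are aligned at the codon level by translating (invertebrate
mitochondrial code, NCBI table 5, by default), aligning the amino-acid
sequences globally with affine gap penalties (BLOSUM62, gap open 10,
extend 0.5), and threading gaps back onto codons — the pairwise
equivalent of the translate/align/back-translate construction used for
codon-aware multiple alignments. Edit distances are unrestricted
Levenshtein distances on the unaligned nucleotides, or are taken from a
supplied match list when it carries them.

The `wdadn` weight matrix is a packaged, user-replaceable asset. The
default is derived from BLOSUM62 by the standard similarity-to-distance
transform `d(a,b) = s(a,a) + s(b,b) - 2 s(a,b)` and rescaled so the mean
over unordered unequal amino-acid pairs is 1.0; on that scale `wdadn`
and `dadn` are directly comparable and share the default threshold. Any
symmetric, zero-diagonal biochemical distance matrix in the same TSV
layout can be substituted.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `min_match` | 84% | neighbor radius (percent identity) |
| `n_closest` | 10 | accepted neighbors examined per OTU |
| `min_overlap` | 0.95 | fraction of the candidate's samples shared |
| `max_read_ratio` | 1.0 | echo/parent read ratio (or slope) bound |
| `max_p_val` | 0.05 | slope significance level |
| `dist_threshold` | 1.0 | bound on `dist_value`/edit distance |
| abundance `cutoff` | 3 (`max`) | minimum read statistic to keep |
| `assignment_rank` | Order | rank at which uncertainty discards |
| consensus `threshold` | 0.80 | read-weighted share to adopt a label |

The abundance statistic can be `sum`, `max` or `mean`; `max` across
samples is the default, being least sensitive to sample number. At the
default `dist_threshold` of 1.0 the unweighted evolutionary filter fires
essentially only on neighbors whose differences are exclusively
nonsynonymous (since each differing codon contributes at least one to
the edit distance, finite `dadn/edit` cannot exceed 1 once a synonymous
difference exists); the weighted variant can also fire on radical
replacements. Lower thresholds make the filters progressively more
aggressive.

Uncertain labels are the literal `unassigned`/`unresolved`, the prefixes
`unassigned.`/`unresolved.`, empty strings and missing values. In the
consensus vote these labels participate literally: counting them is
deterministic, and a cluster dominated by uncertain members resolves to
an uncertain label that downstream filters treat as such.

## The synthetic community generator

The generator emulates the structure the filters exploit, with all
randomness fixed by one seed:

* Authentic species are random stop-free codon sequences (139 codons =
  417 nt) diverged from a per-order ancestor mostly synonymously
  (synonymous changes at 0.30 per codon, nonsynonymous at 0.02). These
  rates place heterospecific pairs below the default 84% neighbor
  radius, as expected for distinct CO1 species barcodes, while noise
  derived from a parent stays well inside it.
* Sample occupancy is geometric (p = 0.15, min 1), giving the skewed,
  few-dominant-taxa structure of Malaise-trap communities; per-sample
  reads are log-normal (meanlog 5, sdlog 1, floor 10).
* NUMTs (per-species probability 0.35) copy their parent with
  nonsynonymous substitutions at 5 times the authentic nonsynonymous
  rate — and no synonymous ones, the young-NUMT limit in which `dadn`
  is infinite. Their counts are `0.05 ×` the parent's counts in exactly
  the parent's samples. Echoes (probability 0.35) are 1–2 silent
  single-nucleotide variants with counts `0.05 ×` the parent's.
  Deterministic ratios make the read-ratio criteria exactly testable.
* Chimeras (5 by default) join the left half of one co-occurring parent
  to the right half of another at a codon boundary, and occur only
  where both parents do.

What the generator does **not** emulate: PCR error models, index
hopping, abundance-dependent error rates, intragenomic CO1 variation, or
reference-database error. Passing tests demonstrate that the filters
recover noise with the statistical structure they assume, not
performance on any particular real survey.

Because planted NUMTs track their parent's sample distribution at a
fixed read ratio, the echo filter — which runs first — legitimately
claims most of them; the defining signature of an "echo" is precisely
the co-occurrence pattern that co-amplified NUMTs share. The evolutionary
filters are the detectors for NUMTs whose distribution is decoupled from
the parent's, and the attribution helper (`noise_attribution()`)
accordingly accepts either filter for the NUMT class. Planted chimeras
are about 70% identical to each parent, far outside the neighbor
radius, so NEEAT cannot see them: they are the designated prey of the
chimera co-occurrence policies, and end-to-end validation therefore runs
the chimera stage before NEEAT.

## Numerical and design choices

* Identifiers are opaque strings ordered lexicographically; every
  tie-break (OTU ordering, neighbor ranking, representative selection,
  consensus lineage source) resolves deterministically, so identical
  inputs give byte-identical outputs under any row/column permutation.
* Counts are integers; match-list identities are auto-detected as
  fractions when every value is ≤ 1.0 and rescaled to percent.
* The desk-scale match list (`compute_matchlist()`) converts Levenshtein
  distances to identities as `100 (1 − d / max(len))`; an external
  all-vs-all search tool's match list can be supplied instead.
* Abundance comparison is strict (`statistic < cutoff` discards); the
  consensus threshold is inclusive (`share ≥ threshold` adopts);
  chimera batchwise co-occurrence is inclusive (`≥ 50%`).
* A samplewise chimera call for a sample where the ASV has zero count is
  ignored with a warning; samples with no call count as "not chimeric"
  for the strict policy (the conservative reading).
* Raising `max_read_ratio` (without the regression branch) or the
  abundance cutoff enlarges discard sets, and raising `dist_threshold`
  shrinks them, *given a fixed accepted neighborhood*. Across a full
  sweep these monotonicities can be defeated by cascades (an OTU spared
  at one setting becomes an accepted neighbor able to flag others);
  the property tests therefore use star-shaped fixtures in which the
  neighborhood is pinned.
* Consensus escalation that fails even at the highest rank yields all
  ranks `unresolved` with a warning; zero-read clusters vote with equal
  weights.
* The tests and the acceptance script use communities of roughly
  60 species / 30 samples / ≤ 120 OTUs, a size at which every oracle
  (exhaustive pair enumeration, per-column codon counting,
  per-sample policy enumeration) runs in seconds while exercising all
  code paths.

## Known limitations

* The echo filter can claim a genuinely rare species whose samples nest
  inside an abundant, closely similar neighbor's range with
  systematically lower reads — indistinguishable, on these statistics,
  from an echo. The package inherits this limitation of the method.
* `dadn` is undefined for pairs differing only by indels (such columns
  contribute to neither count); those pairs are skipped rather than
  guessed.
* Representative-based distances assume one sequence per cluster is
  representative; clusters mixing divergent haplotypes will blur the
  evolutionary signal.
* The consensus vote trusts read counts as annotation weights; heavily
  chimeric or index-hopped clusters can still mislead it.
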