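# neeatr

Noise filtering and curation of deep metabarcoding OTU tables.

## The problem

Deep metabarcoding of protein-coding markers (typically the 418 bp CO1
fragment used for arthropods) produces hundreds of thousands of amplicon
sequence variants (ASVs), of which a large fraction are artifacts: nuclear
copies of mitochondrial DNA (NUMTs), PCR/sequencing-error variants that
"echo" an abundant template, and chimeras of co-amplified templates. Left
in place, these inflate richness estimates and split species across
clusters. `neeatr` is a post-clustering curation toolkit for this
situation: it consumes externally produced ASVs, counts, taxonomic
annotations and cluster assignments, and decides which OTUs to keep.

## What it implements

**NEEAT noise filtering.** OTUs are ordered by number of occupied samples,
then by total reads; the top OTU is taken as authentic and each later OTU
is compared to its *n* closest previously accepted neighbors within a
minimum percent identity (default 84%). Four component filters are applied
in a fixed sequence, each feeding its retained OTUs into the next:

1. *Echo filter* — flags an OTU that co-occurs with a more abundant
   neighbor in ≥ 95% of its samples and whose reads track the neighbor's
   at a low ratio (either a per-sample read-ratio summary, or an OLS
   regression of echo reads on parent reads with a significant slope
   below `max_read_ratio`).
2. *Evolutionary-signature filter (local)* — computes codon-aware
   distances between representatives: `dadn`, the ratio of nonsynonymous
   to synonymous codon differences, and `wdadn`, its biochemically
   weighted version. An OTU is flagged when `dadn/edit_distance` (or
   `wdadn/edit_distance`) exceeds a threshold for some accepted neighbor
   with high sample overlap — the signature of a NUMT diverging under
   relaxed selection, which accumulates amino-acid changes far faster
   than an authentic haplotype.
3. *Evolutionary-signature filter (global)* — the same test without the
   sample-overlap requirement.
4. *Abundance filter* — drops OTUs below a read cutoff (`max`, `sum` or
   `mean` statistic), then the
5. *Taxonomic annotation filter* — drops OTUs with uncertain annotation
   (`unassigned*`/`unresolved*`) at a chosen rank (default Order).

**Chimera co-occurrence policies.** De novo chimera calls (uchime-style,
batchwise or per-sample) are post-processed with one of four strategies:
`batchwise.strict` (parents co-occur in ≥ 50% of the ASV's samples),
`batchwise.lenient` (≥ 1 sample), `samplewise.strict` (called chimeric in
every occupied sample) or `samplewise.lenient` (≥ 1 sample).

**Consensus taxonomy.** Cluster annotations are resolved by a
read-weighted vote from the most resolved rank upwards: a label is
adopted when it carries ≥ 80% of member reads; child ranks become
`unresolved.<label>`. Representative ASVs use the highest mean (or
median) read rule.

**Evaluation.** Pair-based clustering metrics against species labels:
`precision = TP/(TP+FP)`, `recall = TP/(TP+FN)` with `FP = NP − TP`
(`NP` = within-cluster pairs), F-score as their harmonic mean, plus
cluster:species ratio, multicluster-species counts and removal summaries.

**Synthetic communities.** A seeded generator plants NUMTs (nonsynonymous
divergence at an inflated rate, proportional counts), echoes (1–2 nt
variants at a fixed read ratio) and chimeras (codon-boundary joins of
co-occurring parents) in a skewed multi-sample community, with ground
truth, so every filter can be validated against known noise.

## Worked example

```r
library(neeatr)

com  <- generate_community(community_spec(seed = 42))
table(com$truth$class)
#> authentic   chimera      echo      numt
#>        60         5        24        23

seqs  <- setNames(com$asvs$sequence, com$asvs$asv_id)
calls <- generate_chimera_calls(com, mode = "samplewise")
chim  <- apply_chimera_policy(calls, com$counts,
                              chimera_policy("samplewise", "strict"))
cl    <- com$clusters[com$clusters$asv_id %in% kept(chim), ]
rep   <- run_neeat(cl, com$counts, com$taxa, seqs = seqs,
                   partition_rank = "Order")
table(rep$filter_name[rep$decision == "discard"])
#> echo
#>   47
```

The chimera stage removes the 5 planted chimeras (they are called in
every sample where they occur, so the strict samplewise policy takes all
of them), and NEEAT removes the 47 echoes and NUMTs — both classes track
their parent's across-sample distribution at a read ratio of 0.05, so the
echo filter claims them first. All 52 planted noise OTUs are removed and
all 60 authentic species are retained. The evolutionary filters take over
for NUMT-like OTUs whose sample distribution is decoupled from the
parent's (see the methods vignette).

Pipelines driven by files and a YAML config use `run_pipeline()`, or the
CLI in `inst/scripts/neeatr-cli.R` with subcommands `simulate`,
`prefilter`, `chimera`, `neeat`, `consensus`, `evaluate` and `pipeline`.

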