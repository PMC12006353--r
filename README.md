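# ztakit

Locus- and transcript-resolved analysis of zygotic transposable-element
activation (ZTA) during early embryonic development.

## The problem

Transposable elements (TEs) make up half of some vertebrate genomes, and a
small subset of TE loci is transcribed zygotically during the
maternal-to-zygotic transition. Short-read analyses pool TE-derived reads at
the family level and cannot separate a transcript expressed *from* a TE
promoter from a gene transcript that merely *contains* a TE fragment.
Long-read transcript catalogs resolve this, but the downstream analysis —
classifying every transcript model against a RepeatMasker annotation, calling
when each locus switches on, clustering activation trajectories, measuring
where the transcripts accumulate in the cell, and dating the underlying
copies — involves many small, threshold-laden rules that are easy to get
subtly wrong. `ztakit` implements that analysis stack as composable,
tibble-in/tibble-out R functions, for developmental biologists and genome
scientists working with staged (embryonic) transcriptomes and TE annotation.

## What it computes

- **Catalog** (`classify_transcripts()` and friends): each transcript is
  **TE-alone** when more than 90% of its exonic sequence lies inside TE
  annotation *and* its first exon is TE-covered (TE promoter-driven
  transcription), **TE-gene** when exonic TE overlap is at least 10 bp (the
  smallest annotated TE fragment), else **gene**. Chimeric TE-alone
  transcripts spanning several subfamilies are resolved into major/minor
  components by their sequence share. Support filters (1/3/2 reads for
  annotated / novel-in-known-locus / novel-locus models), 98%/100% identity
  merging of redundant models, splice-signal surveys (GU–AG), conserved-domain
  classes and per-type structure summaries round out the module.
- **Dynamics** (`call_activation()`, `cluster_trajectories()`, ...):
  TPM normalization (`count / library size × 10⁶`); maternal status when
  TPM > 0 at the fertilized-egg or 1-cell stage (mouse preset: TPM > 5 at
  0 hpf); the activation stage is the earliest stage with previous TPM < 5,
  current TPM ≥ 5 and a continuous rise over the next two stages. Zygotic
  trajectories are log/z-transformed and Ward-clustered (`hclust`/`cutree`,
  k = 8); within-subfamily heterogeneity is the Shannon entropy of a
  subfamily's cluster labels, alongside activation-stage/cluster spread,
  aggregation to locus/subfamily/family/type, stage-correlation matrices and
  fold changes.
- **Localization** (`group_nc_proportion()`): the relative N/C proportion —
  a group's share of nuclear abundance divided by its share of cytosolic
  abundance (> 1 = nuclear bias), with a lincRNA vs protein-coding benchmark
  and a regression of localization on TE-fraction bins.
- **Evolution** (`kimura2p()`, `ltr_insertion_time()`, ...): Kimura
  two-parameter divergence K = −½ ln[(1−2p−q)√(1−2q)]; intactness (≥ 80% of
  consensus, ≤ 30 bp 5' and ≤ 100 bp 3' loss); LTR insertion ages via
  Jukes–Cantor, K = −¾ ln(1 − 4d/3), T = K/(2μ) with μ = 1.46 × 10⁻⁸
  substitutions/site/year; active-vs-silent divergence comparisons;
  strain-presence age groups (TU / TU-AB / TU-AB-Nadia / TU-AB-Nadia-CB);
  segmental-duplication vs transposition origin calls from 500 bp flank
  homology.
- **Synthetic data** (`simulate_zta_dataset()`): a seeded generator that
  emits every input above — genome, TE annotation, transcript models,
  staged counts, nuclear/cytosolic matrices, strain panel — with planted
  ground truth, so every stage of the pipeline is testable without any
  download.

## Worked example

```r
library(ztakit)
library(dplyr)

sim <- simulate_zta_dataset(fixture_spec(seed = 1))

catalog <- classify_transcripts(sim$transcripts, sim$exons, sim$copies)
count(catalog, class)
#>   class        n
#> 1 TE_alone    30
#> 2 TE_gene     30
#> 3 gene        30

tpm <- tpm_normalize(sim$counts) |> filter(transcript_id != "TX_FILLER")
act <- call_activation(tpm)        # zebrafish preset: maternal = TPM > 0
count(act, status)
#>   status       n
#> 1 maternal    32
#> 2 zygotic     58

zyg <- act |> filter(status == "zygotic",
  transcript_id %in% catalog$transcript_id[catalog$class == "TE_alone"])
traj <- cluster_trajectories(
  tpm |> filter(transcript_id %in% zyg$transcript_id), k = 8)
traj
#> Trajectory clustering: 28 trajectories in 8 clusters over 11 stages

loc <- group_nc_proportion(sim$nuclear, sim$cytosolic,
                           catalog |> transmute(transcript_id, group = class))
loc
#>   stage group    p_cyt  p_nuc ratio
#> 1 tpm   TE_alone 0.558 0.766  1.37
#> 2 tpm   TE_gene  0.240 0.165  0.686
#> 3 tpm   gene     0.201 0.0691 0.343

ltr_insertion_time(0.01)   # years since insertion at 1% inter-LTR divergence
#> [1] 344769.4
```

The catalog recovers exactly the 30/30/30 planted classes; the localization
ratios reflect the planted 4:2:1 nuclear bias of TE-alone, TE-gene and gene
transcripts (each divided by the abundance-weighted mean bias); cluster
mean curves are drawn with `autoplot(traj)`, and `tidy()`/`glance()` return
assignments and fit summaries.

A thin CLI mirrors the main entry points:
`exec/zta simulate --seed 1 --out DIR`, `exec/zta run-all --seed 1 --out DIR`.

## Vignette

`vignettes/ztakit-methods.Rmd` documents the model and rules, every
threshold with its default and rationale, what the synthetic generator does
and does not emulate, and the package's design decisions and limitations.
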