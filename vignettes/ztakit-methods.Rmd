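---
title: "Methods: classifying, timing and dating zygotic TE activation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying, timing and dating zygotic TE activation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ztakit)
```

`ztakit` analyses staged long-read transcript catalogs against a
RepeatMasker-style TE annotation to resolve zygotic transposable-element
activation (ZTA) at the level of individual loci and transcripts. This
vignette is the package's account of its methods: the rules and models it
implements, the parameters that matter, what the synthetic-data generator
emulates, and the design decisions taken where more than one reading was
defensible.

## Transcript classification

All interval arithmetic is done in 0-based half-open coordinates
(converted at the I/O boundaries: GTF and RepeatMasker `.out` are 1-based
inclusive, BED passes through unchanged). Overlap is computed on **exonic
(spliced) bases only**, because the transcript — not its genomic span — is
the object being classified, and introns may themselves be acquired TE
insertions. Where TE copies overlap one another, every exonic base is
assigned to exactly one copy (the earliest-starting copy, ties to the
lexicographically smaller subfamily), so subfamily components always sum to
the total exonic TE overlap.

A transcript is:

* **TE-alone** — exonic TE fraction strictly above 0.9 *and* first-exon TE
  evidence. The first-exon rule is interpreted as the transcript's 5'-most
  base (TSS, strand-aware) lying inside a TE copy, because the biological
  reading of the rule is TE promoter-driven transcription — a property of
  the start site. An alternative rule (≥ 50% of first-exon bases in TE) is
  available via `first_exon_rule = "half"`.
* **TE-gene** — otherwise, when exonic TE overlap is ≥ 10 bp, the size of
  the smallest annotated TE fragment.
* **gene** — otherwise. Overlaps of 1–9 bp fall into a gap the rules leave
  open; they are classified `gene` (the profile retains the bp count so the
  choice is auditable).

TE-alone transcripts drawing on ≥ 2 subfamilies are *chimeric*; the major
component is the subfamily with the largest share of the transcript, an
exact tie breaking toward the lexicographically smaller name with a
`major_tie` flag. TE-fraction bins for TE-gene transcripts are
`[0,20) [20,40) [40,60) [60,80) [80,100]` on the percent scale.

Support filtering keeps annotated transcripts with ≥ 1 read at some stage,
novel transcripts from known loci with ≥ 3, novel-locus transcripts with
≥ 2, and then drops transcripts below 1 TPM at every stage — except
TE-alone candidates, which are autonomously expressed and exempt.
Redundant models merge greedily longest-first within structural category:
ISM at ≥ 98% global identity (matches / alignment length, end gaps
penalized), NIC/NNC only at 100%; annotated and TE-alone models never
merge. The TPM pre-filter runs after merging, consistent with cluster
counts being summed onto representatives.

## Expression dynamics

TPM is `count / column sum × 10⁶` per stage, with the library defined by
the combined (FL + non-FL) counts. Stage order comes from the counts-file
column order and is never sorted — developmental order is semantic.

* **Maternal vs zygotic**: maternal iff TPM exceeds a threshold at a
  maternal stage. Zebrafish rule: TPM > 0 at fertilized egg or 1-cell.
  Mouse preset: TPM > 5 at the 1-cell/0 hpf stage. The thresholds are
  absolute TPM, so the calls are deliberately *not* scale-invariant.
* **Activation stage**: earliest stage with previous TPM < 5, current
  TPM ≥ 5, and strictly increasing TPM over the next two stages. The rule
  is stated explicitly only for the mouse subfamily analysis; the package
  applies the same rule (configurable thresholds) at the transcript level
  for zebrafish, since no separate zebrafish rule is stated, and ships both
  presets. Near the end of the series the increase is required over all
  remaining stages (at least one), otherwise late activation would be
  undetectable; the final stage itself can never activate. Maternal
  transcripts receive no activation stage.
* **Trajectory clustering**: rows are transformed `log2(TPM + 1)` then
  per-row z-scored (constant rows become zero vectors) — the standard
  heatmap-clustering transform; the source procedure does not state its
  transform, so this choice is configurable off. Clustering is
  agglomerative Ward (`hclust(method = "ward.D")`) on Euclidean distance,
  cut at k = 8 (`cutree`). Cluster ids are renumbered by the activation
  order of cluster mean trajectories so numbering is deterministic and
  interpretable.
* **Entropy and spread**: within-subfamily heterogeneity is the plug-in
  Shannon entropy of the subfamily's cluster-label distribution, in nats
  (the natural-log default of the standard entropy routine; bits
  available). It is 0 for a homogeneous subfamily and ln k for a uniform
  one. Spread counts distinct activation stages and distinct clusters per
  subfamily.
* Aggregation sums expression within locus/subfamily/family/type (total
  abundance is conserved); stage–stage similarity is Pearson correlation on
  `log2(TPM + 1)` (transform again unstated upstream, documented here);
  fold changes are ratios of stage totals with zero denominators flagged.

## Subcellular localization

Absolute nuclear vs cytosolic abundances are not directly comparable, so
localization is summarized relatively: a group's share of total nuclear
abundance divided by its share of total cytosolic abundance. Shares sum
to 1 within each compartment under any grouping, and the ratio is
invariant to rescaling either compartment. Subfamily-level ratios keep the
full transcript universe as the normalizing denominator, mirroring the
group-level definition (the denominator universe is not pinned down
upstream; the TE-alone-only alternative can be had by subsetting the input
matrices). Transcripts absent from one compartment are zero-filled, not
dropped. The lincRNA vs protein-coding benchmark removes maternal
transcripts first and checks the expected nuclear bias of lincRNAs. The
TE-fraction regression is OLS of bin-level ratios on bin midpoints
(10, 30, ..., 90) by default, matching how binned localization data are
presented; a per-transcript mode exists.

## Evolutionary analyses

* **Kimura two-parameter divergence**: K = −½ ln[(1−2p−q)√(1−2q)] with p
  the transition and q the transversion fraction. Gap columns and
  ambiguous bases (N) are excluded from p, q and the aligned length.
  Serialized in percent, matching the RepeatMasker convention. The
  correction saturates when 1−2p−q ≤ 0 or 1−2q ≤ 0 and the function
  errors rather than returning a number.
* **Intactness**: a copy is intact iff it covers ≥ 80% of its consensus
  with ≤ 30 bp 5' and ≤ 100 bp 3' loss. For three-part LTR elements
  (5'LTR + internal + 3'LTR) the stated rules are ambiguous about losing
  exactly one part; the package treats *any* missing part as non-intact
  and flags the single-loss case separately so the other reading stays
  recoverable.
* **LTR insertion dating**: the two LTRs are identical at insertion, so
  their divergence d dates it: K = −¾ ln(1 − 4d/3), T = K/(2μ), default
  μ = 1.46 × 10⁻⁸ substitutions/site/year (fish neutral rate). d is the
  fraction of differing aligned sites with gaps excluded from numerator
  and denominator (gap treatment is unstated upstream; exclusion is the
  conservative choice and matches the divergence summaries used
  elsewhere in the package). Inputs with d ≥ 0.75 error (Jukes–Cantor
  saturation).
* **Strain age groups**: presence of a locus across the four strains TU,
  AB, Nadia, CB maps to the nested groups TU, TU-AB, TU-AB-Nadia,
  TU-AB-Nadia-CB, young = {TU, TU-AB}, old = the rest. All 16
  presence/absence patterns map deterministically; the 12 non-nested
  patterns (impossible under the strain phylogeny) are reported as
  `inconsistent`/`unassigned`, never forced into a group.
* **Origin mechanism**: segmental duplication co-copies flanking sequence,
  transposition does not. From each locus's best non-self donor hit:
  duplication iff the TE body and *both* 500 bp flank windows align at
  high identity; transposition iff the body aligns but a flank fails; no
  donor hit ⇒ unclassified. The flank thresholds (identity ≥ 0.8 over
  ≥ 50% of the window) are not stated upstream; they were chosen once to
  separate the planted duplication/transposition scenarios robustly and
  both are configurable.

## The synthetic-data generator

`simulate_zta_dataset()` is a first-class module, not a test fixture: it
produces every pipeline input with planted ground truth from a single
seed, byte-deterministically.

* **Genome/annotation**: per-subfamily consensus sequences (1.5–3 kb);
  each copy mutates the consensus with a per-site substitution probability
  (0.02–0.15 per copy by default, Jukes–Cantor kernel) and is optionally
  end-truncated; copies are placed on two chromosomes with 500–900 bp
  spacers, a subset as adjacent different-subfamily pairs (40–60 bp gaps)
  to host chimeras. The annotation records consensus-span columns and the
  **realized** divergence, recomputed from the emitted sequence
  (`realized_divergence()`), because splice-signal planting may edit up to
  4 bases per intron inside a copy.
* **Transcripts**: TE-alone models sit fully inside copies (single- or
  two-exon, a share of loci with second isoforms, minus-strand cases);
  chimeras span a copy pair at > 90% exonic TE content with the TSS in
  the major copy; TE-gene models put exon 1 in TE-free spacer and run
  exon 2 60–200 bp into a copy; gene models live in TE-free chromosome
  tails. Intron donors are GT (GC at a planted 15% non-canonical rate)
  and acceptors AG on the coding strand.
* **Counts**: eleven zebrafish stages by default (fertilized egg →
  shield, fully configurable). Maternal transcripts decay from 20–60 TPM;
  zygotic transcripts follow one of eight archetypes — six flat-then-rise
  templates activating at successive stages, one rise-then-fall, one late
  riser — scaled by a random integer factor. Onset is 10 TPM tripling
  over the next two stages (the window the activation rule tests), then
  ×1.5 growth: zygotic induction is sharply exponential, and this keeps
  the planted onset recoverable under overdispersed counts. Templates are
  TPM-valued; a filler housekeeping transcript tops each stage to exactly
  10⁶ TPM so that at dispersion 0 TPM normalization returns the templates
  exactly. Counts are negative binomial around
  `template × library/10⁶` (library 3 × 10⁶, so 3 reads = 1 TPM);
  dispersion 0 gives the means exactly. Negative-binomial noise is the
  standard overdispersed RNA-seq count model; no specific noise model is
  stated upstream.
* **N/C matrices** plant per-class nuclear biases (default 4:2:1 for
  TE-alone : TE-gene : gene) as exact means, so estimated ratios have a
  closed form: class bias divided by the abundance-weighted mean bias.
* **Strain panel** plants nested presence groups uniformly and origin
  mechanisms (40/50/10% duplication/transposition/unclassified) with
  flank identities that the origin rule separates cleanly.

What the generator does **not** emulate: raw long reads and their error
modes, polyA artifacts, mapping ambiguity, replicate structure, nested TE
insertions inside copies, and chromatin signal. Passing recovery tests
therefore demonstrates that the rules are implemented correctly and are
recoverable under overdispersed counts — not that they are robust to
upstream alignment or annotation error in real data.

## Numerical choices and degenerate inputs

Half-up rounding to two decimals for reported percentages (base `round()`
is half-even and does not reproduce printed values such as 95.13 =
215/226). Zero-total stage columns normalize to all-zero TPM with a
warning; zero denominators in fold changes, percentages and N/C ratios
return `NA` with an `undefined` flag rather than `Inf`. Constant rows
z-score to zero vectors. Introns shorter than 4 bp are counted
non-canonical with a warning. Ward clustering ties are broken by
`hclust`'s deterministic merge order; cluster renumbering falls back to
peak stage, then cluster id, when mean curves have no activation stage.

## Problem sizes

The test-suite and acceptance runs use datasets of 90–1,000 transcripts
over 48–120 TE copies, 100 replicate LTR pairs of 5 kb at planted ages
10⁴–10⁶ years, and ~600-transcript dynamics fixtures (~420 zygotic), which
exercise every rule and keep full runs to a couple of minutes.

## Known limitations

* The 90% rule is computed on exonic bases by default; a genomic-span
  variant can be derived from the profile columns but is not the default
  (whether the original analysis used exonic or genomic span is not
  stated).
* Identity-based merging emulates greedy longest-first clustering; it is
  not a reimplementation of any specific clustering tool's word-filter
  heuristics.
* ORF and domain *detection* are out of scope: the domain table is an
  input; only its classification logic (per-type required domain sets) is
  implemented.
* The activation rule's brittleness to single-stage dips is inherited by
  design — the package reproduces the stated rule rather than smoothing
  around it.
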