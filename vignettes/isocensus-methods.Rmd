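---
title: "Methods: a splice-isoform census across tissues"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a splice-isoform census across tissues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isocensus)
```

# The problem

Medullary thymic epithelial cells (mTEC) transcribe most of the
protein-coding genome ("promiscuous gene expression") to present a mirror of
peripheral self-antigens to developing T cells. Gene-level coverage is not
the whole story: a gene's peptide repertoire is elaborated by alternative
splicing, so tolerance depends on which *isoforms* the thymus produces.
`isocensus` implements a detection-based census that asks, for every gene
with tissue-restricted expression, how much of the isoform, splice-junction
and exon-inclusion repertoire seen in the gene's home tissue is reproduced
in a TEC-like sample — together with the supporting statistics
(reproducibility filtering, tissue-specificity scoring, differential
splicing, transcript-structure tests, and motif enrichment for the RBFOX
splicing factor family).

Everything runs on synthetic data with planted truth. The generator is a
first-class module: it defines the study conditions under which the
pipeline's statistical claims are tested, and its defaults are fixed once
(below), not tuned per analysis.

# Models and procedures

## Reproducibility filter (npIDR)

Given two detection replicates and per-transcript abundance, transcripts in
the detection union are assigned to 20 equal-occupancy bins on
log10(TPM + 0.01) (left-closed edges). The raw npIDR per bin is the
fraction of its transcripts detected in exactly one replicate. Because
irreproducibility must not increase with expression, the curve is smoothed
by weighted isotonic regression (pool-adjacent-violators, non-increasing in
expression; bin occupancies as weights — `stats::isoreg` is unweighted,
hence the internal implementation). Empty bins inherit the nearest occupied
bin below. A transcript is accepted when the smoothed npIDR at its
expression is ≤ 0.1 (the conventional cutoff; a config key). This is the
standard expression-binned npIDR; no claim is made to reproduce any
particular refinement of it.

## Tissue specificity and gene categories

tau is computed on log2(TPM + 1)-transformed per-tissue summaries:
`tau = Σ(1 − x_i/x_max)/(N − 1)`, 0 for uniform and 1 for single-tissue
expression. The log transform is common practice and a config flag disables
it; raw-scale tau is exactly scale-invariant, the log variant preserves
ordering. The tissue panel for tau excludes the TEC-like samples —
restriction is defined against the periphery. Genes with tau ≥ 0.9
(inclusive, at gene or transcript level) are TRA genes; each is assigned to
its maximal-expression tissue (iTRA), with argmax ties broken by the
lexicographically smallest tissue name and logged. Splicing-factor
restriction uses the same machinery at tau > 0.5 with a user gene list.

Aire regulation is a per-gene decision: down-regulated more than 2-fold in
the Aire-knockout samples with BH-adjusted p < 0.05. Fold changes are
reported as positive ratios plus a direction field to avoid sign
ambiguity. Categories partition all genes: Aire-TRA, non-Aire-TRA,
non-TRA.

## Count statistics

The shared two-group count test is a negative-binomial conditional exact
test: conditioning on the total of the two (summed) counts, the first count
follows the conditional law of `NB(mu_a, 1/phi)` against `NB(mu_b, 1/phi)`
with means proportional to library size factors; the two-sided p doubles
the smaller tail (capped at 1). At dispersion 0 this is exactly the
binomial test. When each side is a sum of `r` replicates the test uses
dispersion `phi/r`, since a sum of `r` NB(mu, phi) draws is NB(r·mu,
phi/r). Fold changes use a 0.5 pseudo-count. The default per-replicate
dispersion is 0.1 (config), also used for single-sample ("no replicate")
comparisons. This deliberately simple test stands in for moderated count
frameworks; the pipeline's decisions depend on the thresholds (BH p < 0.05,
|fc| > 2), not on a particular likelihood.

Fisher's exact tests wrap the standard hypergeometric computation; the
reported odds ratio is the sample ratio `ad/bc` (`Inf` when `bc = 0`,
missing for 0/0, written as `"inf"`/`"."` in TSV). Set enrichment runs one
Fisher test per annotation set against an explicit, caller-supplied
universe (the universe is never inferred), with BH across sets; sidedness
is caller-specified because different overlap questions are one- or
two-sided.

The junction census counts *distinct* junctions with ≥ 1 supporting read
per gene (configurable to read counts), tests TEC versus one peripheral
sample per gene with the NB exact test, and then asks, per tissue, whether
its iTRA genes are enriched among genes with significantly more junctions
in the periphery (one-sided Fisher).

## Splicing events and PSI

Local events are enumerated from transcript models by comparing intron and
exon sets within each gene: SE (cassette flanked by shared junctions with a
direct skip junction), RI (an intron exactly spanned by another
transcript's exon with shared outer boundaries), MX (two never-co-occurring
cassettes sharing outer flanks), A5/A3 (introns sharing one boundary with
overlapping flanking exons; naming is strand-aware — the genomic-left
alternative site is the donor on `+`, the acceptor on `-`), and AF/AL
(non-overlapping terminal exons splicing to a shared site). Event ids are
deterministic coordinate strings. Inclusion-form conventions: the cassette
(SE), the retained intron (RI), the shorter intron (A5/A3), the
genomic-left alternative exon (MX/AF/AL).

PSI is computed two ways, both exposed because downstream analyses differ
in their inputs: transcript-ratio PSI (inclusion TPM over event TPM;
missing below 1 TPM) and length-normalized count PSI
`(I/len_I)/(I/len_I + S/len_S)` (missing below 10 reads). Differential
splicing fits, per event, a binomial GLM of inclusion counts on condition
and uses the likelihood-ratio test, BH across events, with the caller's
FDR and |ΔPSI| gates (defaults 0.05 and 0.2; a 0 delta gate reproduces
pure-FDR calling). The hierarchical models of dedicated tools are not
replicated; with binomially generated counts the GLM LRT is calibrated
(verified in the test suite) and recovers planted ΔPSI with bias < 0.03.

Exon-inclusion patterns retain exons > 50 nt with mean TEC PSI < 0.1, max
TEC PSI < 0.2 and PSI > 0.5 in at least one peripheral tissue. Microexons
are SE cassettes ≤ 30 nt (boundary inclusive).

## Transcript structure and the Aire analyses

Transcript length is mature length (sum of exon lengths), not genomic span
— the natural metric for "transcripts". 5′UTR/CDS/3′UTR lengths are
strand-aware exonic overlaps with the genomic CDS span and sum exactly to
the transcript length. A coding transcript with both UTRs is "classical";
coding with a missing UTR "nonclassical"; no CDS "unannotated".
Differential transcript usage reuses the NB exact test per transcript
(adjusted p < 0.05, fc ≥ 2 — the "≥" operationalizes an approximate
threshold). Length-shift comparisons between Aire-regulated and
non-regulated transcripts (restricted to genes containing at least one
regulated transcript) use the exact KS statistic and the two-sided
rank-sum test with midranks and tie-corrected variance.

## Motif positional enrichment

The RBFOX recognition element `WGCAUGM` (W = A/U, M = A/C) is scanned as an
IUPAC consensus (all overlapping matches, U≡T) on the sense strand of each
gene. Windows follow motif-map conventions — 250 nt of intron and 50 nt of
exon at each boundary, 31-nt smoothing — all config keys, since the
source conventions vary. Coverage at an offset is the fraction of exons
with ≥ 1 motif base overlapping the smoothing window centered there; exon
segments shorter than the window are padded and padding is excluded from
denominators. Significance uses permutations of exon *sets* (same-size
draws from an unregulated background pool), which preserves sequence
composition, rather than sequence shuffling. Empirical p-values
`(1 + #{null ≥ obs})/(n_perm + 1)` are BH-adjusted *within each window
segment*: with profile-wide adjustment, a fully enriched downstream window
relaxes the threshold for the other windows enough that smoothing-correlated
null offsets pass; per-window adjustment keeps the unplanted side nominal
without affecting planted-side detection. The mask is FDR ≤ 0.05 at 1000
permutations.

# The synthetic-data generator

The generator emulates the study design: `n_tissues` peripheral tissues
(one high-depth pool each; default 8 — enough tissues for per-tissue
enrichment tests while keeping desk-scale runtimes) plus a TEC-like cell
type with mature / immature / Aire-knockout conditions at 2 replicates each
(matching the real design's n = 2). Defaults, chosen once:

* Genes (default 200; study-scale checks use 1000) have 8 exons; exon 4 is
  the designated cassette. 20% of cassettes are microexons (9–30 nt).
  Isoform 1 is the full chain with a 1 kb-extended 3′ terminal exon — the
  long "classical" isoform; isoform 2 skips the cassette; further isoforms
  realize A5, A3, RI, MX, AF, AL geometries. Non-primary isoforms have
  mixed structures (40% missing a 3′UTR, 20% without CDS), so structural
  classes are informative.
* 30% of genes are TRA, expressed in exactly one home tissue (tau = 1 by
  construction); 40% of TRA genes are Aire-dependent. The TEC-like sample
  expresses TRA genes at 0.2 of the home level with only
  `tec_isoform_fraction` (0.5) of their isoforms on. Aire dependence is
  per transcript: the long classical isoform drops 8-fold in the knockout,
  other isoforms 1.5-fold (below the 2-fold call threshold), with the long
  isoform carrying 0.6 of usage so the gene-level drop exceeds 2-fold.
  This plants, simultaneously, the gene-level Aire calls, the ~+1 kb
  length shift and the classical-structure excess of Aire-regulated
  transcripts.
* Junction counts derive from transcript abundances through each
  transcript's junction set with negative-binomial noise (dispersion 0.1).
  TRA genes additionally carry 60–140 home-tissue-specific junctions —
  peripheral tissues splice their specialty genes far beyond a toy
  annotation's isoform set, and the per-gene junction numbers this yields
  (tens versus ~10 in TEC) are the scale at which a fixed-dispersion count
  test can separate signal from noise at all. Without this diversity the
  |fc| > 2 gate can mathematically never fire on ~8 annotated junctions.
* Event counts are binomial(coverage = 100, PSI) per replicate; 20% of SE
  events are regulated with |ΔPSI| = 0.4 in a random direction.
* Microexon inclusion is tissue-specific for non-TRA microexon genes:
  PSI 0.9 in the first panel tissue ("brain"), 0.05 everywhere else
  including TEC — mirroring the neuronal-microexon pattern.
* The genome is uniform-random ACGT; `WGCAUGM` instances are written in
  place (never shifting coordinates) at 5/kb in the downstream-intron
  window of splicing-enhanced cassettes and the upstream window of
  repressed ones, and at 0.5/kb in all other flank windows (random
  sequence alone contributes ~0.24 matches/kb).
* Detection pools drop transcripts with logistic probability in log10 TPM
  (slope 4, midpoint 1.2). On the synthetic TPM scale — a few thousand
  transcripts renormalized to 10⁶ — this places the irreproducible stratum
  in the weak tail (below ~30–60 TPM) while very highly expressed
  transcripts are detected in both pools with probability > 0.99. The
  curve stands in for sequencing depth and is not calibrated to read
  counts.

Everything is determined by (config, seed); stage seeds are small fixed
offsets of the config seed.

What the generator does *not* emulate: real gene architectures and
isoform-number distributions, sequence conservation, read-level noise
(fragments, positional bias), partially shared expression across tissues
(TRA genes are strictly single-tissue here), or assembly artifacts beyond
expression-dependent detection dropout. Passing tests therefore demonstrate
that the statistical machinery recovers planted effects under clean
conditions — not that effect sizes on real data would match.

# Numerical choices and degenerate inputs

GTF coordinates are converted to 0-based half-open exactly once at I/O;
output is deterministic (sorted by gene, transcript, start), so repeated
runs are byte-identical. All-zero expression vectors yield missing tau with
a warning; zero event denominators yield missing PSI; empty npIDR bins
inherit smoothed neighbors; OR = ∞ is reported explicitly, never dropped.
Binomial-tail doubling is capped at 1. Quartiles assign ties downward.
Detection is strict (`> threshold`). The pipeline's TPM-to-count conversion
for the NB tests uses a fixed depth factor (5 counts/TPM, config), which is
adequate for rank and threshold decisions though not a read-level model.

BH adjustment is the standard step-up via `stats::p.adjust` and is
order-invariant; note that re-adjusting an already adjusted vector is not a
no-op (step-up adjustment is not idempotent), so adjusted p-values are
computed exactly once per family.

# Problem sizes

The test suite validates formulas and oracles on toy inputs, calibration on
≥ 1000 features/events, and planted-truth recovery on a 1000-gene,
8-tissue simulation; the packaged CLI demo uses 60 genes and 5 tissues with
200 motif permutations. These sizes were chosen so the complete validation,
including 1000-permutation motif enrichment, runs comfortably on a single
CPU while leaving every statistical check well-powered.

# Known limitations

* The NB conditional exact test with a fixed dispersion bounds attainable
  significance for a given fold change regardless of counts; with the
  default 0.1 and single samples per side, only severalfold junction
  differences at tens of junctions reach BH significance — consistent with
  the magnitudes the census is designed to detect.
* Permutation enrichment compares a target exon set against a finite
  background pool; with a few hundred exons per set, global composition
  differences between target and pool can shift a whole window's profile
  and produce residual mask coverage on unplanted sides at some seeds.
  Interpret contiguous significant runs in the expected window, not
  isolated offsets.
* A3/A5 versus AF/AL disambiguation relies on exon overlap and terminal
  position within the given transcript models; transcripts with unusual
  terminal-exon structures not generated here may be classified by the
  nearest geometry.
* The exon-pattern and microexon analyses accept either PSI flavor;
  transcript-ratio PSI and count PSI can differ when isoform lengths are
  very unequal (the length normalization addresses the first-order
  effect).
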