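---
title: "Comparing transposable-element abundance and siRNA targeting between accessions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing transposable-element abundance and siRNA targeting between accessions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tedyn)
library(dplyr)
```

## The problem

In large plant genomes most DNA derives from transposable elements (TEs),
and the host silences them with small interfering RNAs (siRNAs) of two main
size classes: 22 nt (post-transcriptional silencing, the dominant class in
maize) and 24 nt (RNA-directed DNA methylation). Because reference
assemblies miss a substantial fraction of the repetitive genome, TE
abundance is better estimated by mapping whole-genome shotgun reads
against a database of *exemplar* sequences — one representative per TE
subfamily — and counting hits per exemplar. `tedyn` implements that
count-based comparative analysis end to end: abundance estimation,
classification of subfamilies into copy-number groups, between-accession
tests of abundance and of copy-number/siRNA proportionality, and
normalized fold-change summaries, together with a seeded synthetic-data
generator so every step can be validated against a known truth.

## Abundance: RPKM and approximate copy number

For exemplar $i$ with length $L_i$ (kb), hit count $N_i$ and total
exemplar-mapped reads $R$,

$$\mathrm{RPKM}_i = \frac{N_i}{L_i \cdot R/10^6}.$$

RPKM is proportional to the subfamily's copy number within one library and
satisfies the identity $\sum_i \mathrm{RPKM}_i L_i = 10^6$ exactly, which
the tests assert. An absolute copy-number estimate uses the annotated gene
set (FGS) as a single-copy coverage anchor: with mean read length
$\bar\ell$, FGS hit total $H_{FGS}$ and total FGS length $\Lambda_{FGS}$,
the per-base depth is $d = H_{FGS}\bar\ell/\Lambda_{FGS}$ and

$$\hat C_i = \frac{N_i \,\bar\ell}{L_i^{(bp)}\, d}.$$

Subfamilies with RPKM below **1.2** (roughly two copies at maize scale)
are flagged `LOW` and excluded from classification and group summaries;
the boundary value 1.2 itself is retained, since the removal rule is
"below 1.2". Filtering precedes classification. The exact RPKM-to-copies
correspondence depends on the library, so both RPKM and $\hat C_i$ are
reported and neither is hard-coded to the other.

### Counting rules

When counts are derived from alignments rather than supplied as tables,
the counter enforces: only alignments spanning **more than 30 bp** of the
read; identity at least 0.80 against the TE and knob/centromere sets and
0.90 against the gene set (applied whenever identity is available, with a
per-rule removal log); one read never contributes more than one hit to one
exemplar; a read whose best score ties across two or more distinct
exemplars is discarded outright; and reads matching several reference sets
resolve by the priority KnobC > TE set > FGS (knob repeats contain TE
fragments, and the gene set is imperfectly TE-filtered, so both
priorities push ambiguous reads toward the repeat databases).
Classification of a read is invariant to the order of its records. For
small-RNA libraries only zero-mismatch alignments of exactly 22 or 24 nt
reads are kept, and a read with $k$ target exemplars adds $1/k$ to each,
so library totals are conserved.

## Classification into D, R1 and R2

DNA-transposon abundances closely follow a log-normal distribution,
whereas RNA-element (retroelement) abundances are bimodal. Exemplars are
therefore partitioned into: **D** (DNA class), **R1** (low-copy
retroelements), **R2** (high-copy retroelements), plus **LOW**.
The R1/R2 boundary is not observable directly; `split_rna_bimodal()` fits
a two-component Gaussian mixture to log RPKM by EM and places the split
where the two posterior probabilities are equal.

Numerical choices, all made for determinism:

* initialization at the 25th/75th percentiles of log RPKM, equal weights,
  pooled variance — no random restarts, so permuting the input or
  changing the session seed cannot move the threshold;
* convergence at relative log-likelihood change $<10^{-8}$, at most 500
  iterations;
* a variance floor of $10^{-6}$; if a component collapses the fit falls
  back to a deterministic 1-d 2-means split with a warning;
* if the fitted mixture density has no real valley between the component
  means (valley at least 90% of the lower peak), a unimodality warning is
  issued but the posterior-equality threshold is still returned;
* the upper component is modelled as a second Gaussian on log scale: only
  the split point matters downstream, not the upper tail's exact family.

The threshold is log-shift equivariant: rescaling every RPKM by a common
factor scales the threshold by the same factor (asserted as a property
test). Group definitions are frozen on a designated reference accession
(`reference_accession` in `run_te_pipeline()`) and reused for the others;
`group_agreement()` quantifies how consistently the R1/R2 labels would
reproduce across accessions, restricted to RNA exemplars classified
non-LOW everywhere.

## The hypothesis tests

**Standard test.** `chi2_std()` is the Pearson chi-square on the 2x2
table (subfamily hits vs all-other hits, per accession), one degree of
freedom, no continuity correction — algebraically the squared
two-proportion Z statistic. It implicitly assumes the genomic *proportion*
of TEs is constant across accessions, which fails when overall repeat
content differs.

**Coverage-corrected test.** `chi2_corr()` replaces that assumption: under
the null of equal copy number, a read hitting subfamily $i$ falls in
accession A with probability $p = F_A/(F_A+F_B)$ set by the relative FGS
coverages. With $T_i = n_{iA}+n_{iB}$,

$$\chi^2_{Corr} = \frac{(n_{iA}-T_i p)^2}{T_i\,p(1-p)},$$

the squared normal approximation to Binomial($T_i$, $p$). With equal
coverages it reduces exactly to the $p=\tfrac12$ binomial statistic.
Its p-values agree with the exact binomial test's to better than 0.01
once expected counts reach the several hundreds; near the minimum
testable margins (expected counts of a few tens) the exact two-sided
p-value's discreteness produces gaps up to a few percent, concentrated at
large, non-significant p-values.

**Proportionality test.** `chi2_prop()` asks whether siRNA targeting
*per TE copy* is equal between accessions — whether siRNA expression
tracks copy number. Under that null the expected siRNA log ratio is

$$r = \ln\frac{n_{iA}}{n_{iB}} - \ln\frac{F_A}{F_B} +
      \ln\frac{\sigma_A}{\sigma_B},$$

the genomic copy-number ratio (coverage-corrected) rescaled by the siRNA
library coverages $\sigma$, estimated as each library's total
exemplar-mapped siRNA hits. The default statistic propagates sampling
noise from all four counts by the delta method:

$$\chi^2_{Prop} = \frac{\big(\ln(s_{iA}/s_{iB}) - r\big)^2}
 {1/s_{iA}+1/s_{iB}+1/n_{iA}+1/n_{iB}},$$

referred to $\chi^2_1$. A conditional-binomial variant
(`variant = "binomial"`) instead conditions on $s_{iA}+s_{iB}$ and ignores
genomic noise; it is provided for sensitivity analysis and rejects
somewhat more readily when genomic counts are small. Exemplars with any
zero count are flagged untestable rather than tested; untestable entries
carry no p-value and are excluded from the Benjamini-Hochberg family,
which otherwise flags significance at $q < 0.001$.

Both novel tests are calibrated by simulation in the test suite: under
their own nulls at expected counts of 50+, rejection at $\alpha = 0.05$
stays within the stated bands, and $\chi^2_{Prop}$'s power rises
monotonically as a planted deviation factor grows from 1 to 2. A uniform
deviation applied to *every* exemplar is undetectable by construction —
the multinomial renormalizes it away — so deviations are planted in
subsets.

**Group comparisons.** Trait differences among D/R1/R2 use Kruskal-Wallis
(the abundance-derived variables are heteroskedastic and non-normal,
so linear models are avoided), followed by Dunn-type pairwise z-tests on
the pooled ranks with BH correction and a compact letter display: groups
sharing a letter are not significantly different at the chosen level.
An all-tied variable yields a statistic of 0 by convention.

## Fold changes

Between accessions A and B three log2 fold changes are defined per
exemplar: genomic abundance
$FC_{TE} = \log_2\frac{n_{iA}\bar\ell_A/F_A}{n_{iB}\bar\ell_B/F_B}$
(FGS-coverage normalized; the read-length factor is retained even though
it cancels for equal-length libraries), and siRNA targeting $FC_{22}$,
$FC_{24}$ computed from counts normalized by each library's
**upper quartile** — the 75th percentile of *nonzero* per-exemplar counts,
nearest-rank convention (deterministic across platforms, invariant to
appending zero-count exemplars). Exemplars with zero hits in either
library are excluded from the corresponding FC, with exclusion counts
reported. All three variants are antisymmetric under swapping A and B and
invariant to per-library count rescaling.

The 24:22 targeting ratio handles zeros with a pseudocount (default 0.5
counts): the 22 nt counts are first rescaled to the 24 nt library total so
both sit on one count scale, then the pseudocount is added to both. As
the pseudocount tends to zero the ratio equals the RPKM ratio exactly,
and a doubly-zero exemplar gets exactly 1. The source study does not
specify zero handling for this ratio; this choice keeps the ratio finite,
symmetric and scale-free.

External expression fold-change tables (for instance a wild-type vs
*mop1*-style RDR2-mutant contrast, in which 24 nt siRNA biogenesis is
impaired) are consumed as provided in log2 units and joined by exemplar
name — the differential-expression call itself is upstream prior art and
is not recomputed.

## The synthetic world

`sim_params()` fixes a maize-like stated world once:

* **841 / 365 / 198** exemplars in D / R1 / R2 — the published group
  sizes for the maize reference line;
* exemplar lengths log-normal per group, medians 1.5 / 4 / 8 kb (high-copy
  retroelements longest, DNA elements shortest, matching the observed
  ordering);
* copy numbers log-normal: DNA median 30 (sdlog 1.0), R1 median 15 and R2
  median 2000 (sdlog 0.8 each) — the RNA class is an explicit two-mode
  mixture, about two orders of magnitude apart, and the implied TE space
  of roughly 3 Gb places RPKM 1.2 near 2–4 copies, so a realistic handful
  of exemplars fall below the filter;
* 15% of genomic reads in genes and 6.1% in knob/centromere repeats (the
  reference line's published mapping fractions); 100 bp reads (the
  sequencing platform of the study's era);
* siRNA rates per copy with D and R1 targeted several-fold more strongly
  than R2 and a higher 24:22 ratio, reproducing the qualitative per-copy
  targeting contrast;
* expression fold changes per group at +1.2-fold (D), −1.6-fold (R1) and
  1.03-fold (R2), given on the linear fold scale and converted internally
  ($-f \Rightarrow \log_2(1/f)$), with sd 1 log2 unit;
* library sizes default to $10^6$ reads per library — the sizes the
  desk-scale validation criteria themselves prescribe; lane-scale
  libraries (tens of millions of reads) are supported by overriding
  `library_size`.

Reads are allocated **multinomially** — gene compartment, knob
compartment, then exemplars proportionally to copy number × length — so
library totals are conserved exactly, and the total gene-set length
implied by the compartment fractions is recorded on each simulated
library, making the copy-number estimator consistent by construction
rather than by tuning. Each (library, purpose) pair draws from its own
RNG stream derived from the master seed via a stable label hash, so
regenerating one library never perturbs another. siRNA counts are
multinomial with weight copy × group rate × a per-exemplar deviation
factor; with all deviations at 1 the proportionality null holds exactly
in expectation. The empirical dispersion of real siRNA counts is unknown
at this level, so the generator defaults to multinomial and exposes an
optional gamma `overdispersion` knob without claiming provenance for it.

What the generator does **not** emulate: nucleotide-level reads and
alignment artefacts, cross-homology between exemplars (every simulated
read is unambiguous, so tie-discard and priority rules are exercised only
by the ingest unit tests), insertion-age structure, and biological
correlation between copy number and siRNA rate beyond the configured
group structure. A green simulation test therefore establishes the
statistical machinery, not the mapping pipeline upstream of it.

### A selection-bias pitfall the tests guard against

If groups (and the low-copy filter) are defined on one of the two
libraries being compared, exemplars near the filter boundary enter the
comparison preferentially when their count in that library fluctuated
high, biasing mean $FC_{TE}$ upward by roughly +0.1 log2 units in the
low-copy groups. Defining groups on an independent reference library —
as the study design does — removes the bias, and the replicate-null
acceptance test (two replicate libraries at lane-ish depth, groups frozen
on a third) checks group means of $FC_{TE}$ within ±0.05 of zero.

## Limitations

* The exemplar-level model ignores within-subfamily sequence divergence;
  "copy number" means exemplar-equivalent coverage, not insertion count.
* The proportionality statistic is a large-count approximation; at counts
  near the testability margin its calibration band is wider (the stated
  0.035–0.065 at expected counts of 50+).
* The full derivation behind the proportionality test's published version
  was not available; the delta-method construction here is the package's
  own and matches the published worked behaviour (zero under exact
  proportionality, the hand example, calibration under the null), with
  the conditional-binomial alternative kept for reconciliation.
* Aligners, trimmers and ncRNA filtering are out of scope; alignment
  inputs are assumed pre-filtered to those conventions.
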