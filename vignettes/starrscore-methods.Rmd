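---
title: "Methods: allelic activity analysis for barcoded STARR-seq screens"
author: "starrscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allelic activity analysis for barcoded STARR-seq screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(starrscore)
```

## The assay and its statistical model

A variant-centered STARR-seq screen clones a short genomic window around
each candidate SNP — in both allelic states — into the 3'-UTR of a reporter,
so that a window with enhancer activity drives transcription of itself. Each
synthesized allele receives several degenerate 5-nt barcodes during PCR, and
each barcode is an independent physical measurement of that allele. After
transfection, both the plasmid DNA pool and the transcribed RNA pool are
sequenced, and the activity of one barcode-allele molecule class in one
replicate is summarized as

$$
\mathrm{score} \;=\; \log_2
\frac{\;rna / rna_{\mathrm{total}}\;}{\;dna / dna_{\mathrm{total}}\;},
$$

the RNA read proportion normalized by the DNA read proportion. The DNA
proportion corrects for library representation: a barcode that is abundant
in the plasmid pool is expected to be proportionally abundant in RNA even
without any enhancer activity.

The pipeline applies three filters before any allele is scored:

* a molecule class needs **at least 10 DNA reads** (its representation must
  be measured reliably) and **at least 1 RNA read** (the log ratio must be
  finite) to yield a measurement;
* an allele needs **at least 3 pooled measurements** — barcode-replicate
  pairs, so the same barcode observed in two replicates counts twice —
  before its measurements are averaged into an allele activity.

Pool totals are totals of *assigned* (error-free, barcoded) reads per
replicate per pool, not raw FASTQ read counts: the normalization must be
internal to the quantified library, since rejected reads carry no
information about relative abundance. No pseudocounts are used anywhere —
the RNA ≥ 1 filter already excludes zeros.

Differential allelic activity is a two-sided Mann-Whitney U test of the
pooled minor-allele measurements against the pooled major-allele
measurements, per SNP, followed by Benjamini-Hochberg correction at an FDR
of 0.10 across all SNPs with both alleles scored. The effect size is
reported as the minor/major fold change $2^{\bar s_{minor} - \bar
s_{major}}$ on the linear scale. Two-sided testing is used because either
allele may be the more active one; measurements are pooled across
replicates rather than tested per replicate, matching how the allele
averages themselves are formed.

## Library design conventions

Each insert is the 196-nt plus-strand window around the variant. "Centered"
is ambiguous for an even width; the declared convention is **97 nt upstream
and 98 nt downstream**, placing the variant at 1-based insert offset 98.
The exported BED coordinates are 0-based half-open, `[pos - 98, pos + 98)`.
Every oligo is the insert flanked by the two 17-nt cloning adaptors
(`TCTAGAGCATGCACCGG` … `GCCGGTCAGAATGATGG`), giving 230 nt. Because an
allelic insert pair differs at exactly one base, exact string matching of a
read's first 196 nt against the insert reference is an unambiguous
assignment rule: it is the deterministic equivalent of aligning and keeping
only error-free molecules, and it is the reference counting path here. The
17-nt adaptor preceding the barcode must also match exactly — an adaptor
error marks a molecule as error-prone — and barcodes containing ambiguous
bases are rejected. Reject tallies are kept per reason so that read
conservation (counted + rejected = input) is checkable.

## What the synthetic-data generator emulates

`simulate_counts()` draws, per allele, a truncated-Poisson number of
barcodes (mean `barcodes_per_allele`), thins them by a bottleneck
(`dropout_prob`), gives each a log-normal DNA abundance, and then draws
per-replicate Poisson reads: DNA proportional to abundance, RNA
proportional to abundance times $2^{a+\epsilon}$ with $a$ the allele's true
log2 activity and $\epsilon$ per-barcode-per-replicate Gaussian noise. The
log-normal-Poisson mixture is the minimal model that reproduces the
overdispersion of MPRA count data.

The defaults are chosen to emulate the regime of a triplicate screen of 200
SNPs in which a scored allele ends up with roughly 12-13 pooled
measurements (`barcodes_per_allele = 6`, `dropout_prob = 0.3`, depths of
$10^6$ reads per pool per replicate, baseline activity spread 1 log2 unit,
replicate noise 0.5 log2 units). A differential SNP shifts its minor allele
by `effect_log2 = 1.32`, i.e. a 2.5-fold expression change. Under these
defaults the simulated screens show between-replicate Spearman correlations
around 0.9 and major-minor allele correlations around 0.9 — the
low-noise end of what real screens achieve, because the generator omits
several real-data features:

* no PCR jackpotting beyond the log-normal abundance tail, no chimeras;
* allele dropout is an independent per-barcode thinning, whereas real
  cloning bottlenecks are bursty — the generator therefore recovers a
  larger fraction of alleles (~98%) than a real screen would at the same
  mean barcode count;
* substitution errors are uniform and independent; no quality-score
  structure, indels, or paired-end artifacts.

Passing recovery and calibration tests on this generator therefore
demonstrates the correctness of the statistical machinery under its stated
model, not the performance of the assay on real libraries.

`simulate_reads()` emits one literal read per counted molecule
(insert + 3' adaptor + barcode, 218 nt) with iid per-base substitution
errors, which makes the error-free filter's retention rate exactly
binomial — the counting module's retained fraction can be checked against
$(1-e)^{196}$. `simulate_peaks()` overlaps each region with probability
$\mathrm{logit}^{-1}(\alpha + \beta\,a)$ of its activity, guaranteeing ≥1 bp
intersection for selected regions. `simulate_aei()` draws per-patient DNA
minor-allele fractions from a Beta centered at 0.5 and multiplies the RNA
odds by a true imbalance fold. `simulate_features()` builds a sparse linear
response on latent Gaussian features and exponentiates a subset of columns
so the emitted matrix is right-skewed, exercising the log-transform path.

## Enrichment analysis choices

Regions (major alleles with ≥3 measurements) are ranked by activity and
split into quintiles; when n is not divisible by 5 the remainder goes to
the *highest* quintiles, which reproduces the 251/251/251/251/250 split at
n = 1254. Ties are broken by snp_id so the partition is deterministic.

All 2×2 enrichment tests use the **Pearson chi-square without Yates
continuity correction**. This choice is pinned by arithmetic: only the
uncorrected statistic reproduces both reference p-values (2.0e-3 from
65/186 vs 37/213, and 1.67e-3 from 3/3 vs 117/1009) from their printed
contingency counts. Bonferroni correction multiplies by the number of peak
datasets supplied in the invocation — the correction family is run-scoped,
since the appropriate family depends on which datasets are co-tested.
Tables with any expected cell below 1 are computed anyway but flagged
unreliable.

## Allelic expression imbalance

Per-replicate AEI is the RNA minor/major ratio over the DNA minor/major
ratio, with a two-sided Fisher exact test on the allele-by-pool table. The
cohort arm works on allele *fractions* averaged over technical replicates —
one DNA and one RNA value per patient — compared by a two-sided
Mann-Whitney U test, and summarized by the median over patients of the
odds-ratio fold. For cohorts of up to nine patients per arm the exact U
distribution is used. Because averaged fractions are often tied (e.g.
simulated patients at exactly 0.5), the exact path enumerates all group
labelings on mid-ranks — the permutation distribution of U — rather than
relying on the tie-free closed form; with no ties the two are identical.

## The lasso model of enhancer activity

Features arrive as a regions × features matrix mixing sequence-derived
scores with experimentally measured signal. Signal-type features (ChIP-seq,
CAGE and similar) are right-skewed, so they are `log1p`-transformed —
flag-driven, with auto-detection at sample skewness > 1 when no flags are
given — and every feature is then z-scored so coefficient magnitudes are
comparable. Constant features are dropped and recorded.

The model is an L1-penalized linear regression. λ is selected by 10-fold
cross-validation minimizing mean squared error on an explicit log-spaced
grid that extends to a near-zero penalty (λ_max down to 10⁻⁶·λ_max): the
default early-stopping path would otherwise keep a noiseless fit away from
the least-squares limit. The minimum-CV-error rule is the default because
it is the plainest reading of "optimized by cross-validation"; the 1-SE
rule is available as an option. Out-of-fold predictions — evaluated by
Spearman correlation against observed activities — are **nested** by
default: λ is re-tuned inside each training fold on a grid derived from
that fold only, so held-out responses never influence any part of the
model that predicts them (a single-level, pre-validated mode exists for
comparison). Fold assignment is seeded and recorded. The reported model is
refit on all data at the selected λ, and the top-k coefficients are ranked
by magnitude with signs retained and name-based tie-breaks.

## Numerical and degenerate-input conventions

* Mann-Whitney: exact distribution when both groups ≤ 8 (tie-free) or by
  enumeration (tied, small); otherwise the normal approximation with tie
  and continuity corrections. The switch at 8 keeps fixture p-values
  deterministic where enumeration is cheap.
* Identical score lists give p = 1; empty groups are a contract violation,
  not a silent NA.
* Degenerate simulator configs (complete dropout, zero depth) produce
  empty tables, not errors; empty FASTQ inputs produce empty count tables
  with a warning.
* Scores are invariant to scaling any pool's depth by a constant (checked
  to 1e-12); a barcode with equal RNA and DNA proportions scores exactly 0.
* AEI folds with a zero denominator count are NA but still tested.

## Problem sizes

The test suite and the reproduction script run simulated screens of 200
SNPs in triplicate (about 5,000 scored barcodes), 20-seed batches for
calibration and recovery checks, feature matrices of 500 × 100 with 5
causal features, and nine-patient AEI cohorts at 10⁴ reads per pool —
sizes at which every property under test is already stable while a full
run stays interactive (well under a minute for the suite's longest file).

## Known limitations

* Exact insert matching discards all reads with any error in the window;
  at realistic error rates this is wasteful of reads (retention
  $(1-e)^{196}$) but bias-free under the generator's error model. An
  aligner-backed matcher could be plugged in but is not the reference path.
* The generator's bottleneck model cannot simultaneously match an observed
  mean measurements-per-allele and an observed allele-recovery rate; the
  true library bottleneck process is burstier than independent thinning.
* The enrichment module treats peaks as binary overlaps; signal-level
  enrichment and matched-background resampling are out of scope.
* The lead-SNP/LD-block structure of the variant table is carried through
  as an annotation but no LD-aware testing is performed.
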