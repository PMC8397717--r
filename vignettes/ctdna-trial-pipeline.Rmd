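---
title: "Hotspot ctDNA consensus calling and exact trial statistics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hotspot ctDNA consensus calling and exact trial statistics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(umitrial)
```

# Scope

`umitrial` implements the computational core of a single-arm phase II study
in metastatic uveal melanoma that combines four analysis stages:

1. **UMI consensus calling** — converting hairpin-barcoded amplicon reads
   into error-corrected read families and per-hotspot variant allele
   frequencies (VAF), for longitudinal ctDNA monitoring of the GNAQ, GNA11,
   CYSLTR2 and PLCB4 drivers;
2. **Mutational-signature refitting** — 96-channel single-base-substitution
   catalogs fitted against predefined signatures by nonnegative least
   squares, used to flag UV-damaged genomes (relevant for iris melanomas);
3. **Exact trial statistics** — Simon's optimal two-stage design by
   exhaustive enumeration, Clopper–Pearson intervals, response summaries and
   Fisher's exact test;
4. **Survival stratification** — Kaplan–Meier estimation and two-group
   log-rank tests over the biomarker splits used in such trials (ctDNA
   median, LDH versus its upper limit of normal, driver gene,
   BAP1-wildtype-or-UV).

Because the patient-level data of such studies sit under controlled access,
a fifth, first-class module generates synthetic inputs with the statistical
structure each stage assumes, together with machine-readable truth tables.
Everything here is therefore testable end to end without downloads.

# Consensus calling model

## Read structure and tagging

Reads are assumed to have the fixed amplicon layout
`anchor + barcode + hairpin stem + insert`. A read is assigned to at most
one assay by **exact match of the assay anchor at the read start**; the
barcode is the `barcode_length` bases (default 12 nt, configurable per
assay) immediately preceding the stem; a read is *valid* only when the stem
matches exactly at its expected offset and the barcode contains no
ambiguous base. The zero-mismatch stem rule is the strictest reading of
"barcode in the correct position relative to the hairpin stem"; a
`max_stem_mismatch` parameter relaxes it when a user's chemistry warrants.
Base qualities are carried through but not used by the consensus rule,
which is purely count-based.

## Families and the size-dependent threshold

Valid reads are grouped into families keyed by the *(amplicon, barcode)*
pair. A family represents one template molecule, so sequencing and PCR
errors can be voted out. The consensus rule per position is:

* families of fewer than 3 reads are discarded entirely (the reporting rule
  starts at 3);
* in families of **3–20 reads** (inclusive at both ends), a nonreference
  base is called only when it composes **100%** of the reads;
* in families of **more than 20 reads**, a nonreference base is called at
  **at least 90%** support;
* otherwise the reference base is called.

When several distinct nonreference bases occur at one position, the
threshold is applied to the single most frequent one (alphabetical
tie-break); this is the conservative reading — a fragmented pileup never
produces a variant call. If the modal nonreference base fails its threshold
*and* no read supports the reference, the position is recorded as a
**no-call** rather than silently imputed to reference; this is the one
place where the implementation refines the otherwise binary rule, and it is
what feeds the `nocall_families` accounting downstream.

## VAF definition

At the assay's hotspot, each surviving consensus family is classified as
mutant (equal to one of the configured alternate alleles), wildtype (equal
to the reference allele) or no-call (anything else). Then

$$\mathrm{VAF} = \frac{\#\text{mutant families}}{\#\text{mutant} + \#\text{wildtype families}},$$

reported in percent in exported tables. No-call families enter neither
numerator nor denominator, consistent with comparing mutant reads against
"reads with wildtype alleles". The analysis unit is the *family* (i.e. the
template molecule), which is the natural unit after error correction. When
no classifiable family exists the VAF is `NA` ("undetectable"), never 0 —
an absent assay must not masquerade as a negative result.

Coordinates are 0-based half-open internally and 1-based in exported
tables; assays are defined on the sequenced strand and no
reverse-complement handling happens inside the consensus stage.

# Signature refitting

## Catalog construction

Somatic SNVs enter the 96-channel catalog when they are autosomal
(chromosomes 1–22), absent from population variant resources (a precomputed
flag, since annotation is upstream of this package), and supported by at
least 5 alternate reads. Purine-reference mutations are reverse-complemented
into the pyrimidine-centered channel; the channel order is the standard one
(C>A, C>G, C>T, T>A, T>C, T>G, each by 5' then 3' flanking base). A context
whose center base contradicts the recorded reference allele raises a
data-consistency error instead of being silently re-complemented.

## NNLS

Given a signature matrix $W$ (96 × K, column-stochastic) and a catalog $m$,
the refit solves $\min_{x \ge 0} \lVert m - W x \rVert_2$ with a
Lawson–Hanson active-set solver written for this package: variables enter
the passive set by largest gradient with ties broken at the lowest column
index, and the convergence tolerance is $10^{-10}$ relative to the problem
scale, so the result is deterministic for fixed inputs. Relative
contributions are $x / \sum x$; an all-zero catalog yields zero exposures
with explicitly undefined (`NA`) relative contributions rather than NaN
propagation.

## The UV flag

A genome is flagged UV-damaged when the summed relative contribution of the
SBS7 family reaches a threshold. No threshold is standard for this call, so
the default of **0.5** — a genome *dominated* by UV signatures — is exposed
as a parameter (`flag_uv(..., threshold = )`). The comparison is inclusive
(`>=`).

## The synthetic signature set

COSMIC signature files are distributed by COSMIC and are treated as an
*input artifact*: the package reads and writes the COSMIC 96-row text
layout (normalizing any row order to the canonical one) but does not ship
the COSMIC estimates. For simulation and testing it provides
`synthetic_signature_set()`: five deterministic profiles with the
qualitative character of SBS1 (C>T at NpCpG), SBS5 (flat), SBS7a/b (C>T at
dipyrimidines with different context weighting) and SBS18 (C>A). They are
clearly labelled synthetic stand-ins; recovery tests only ever compare
against their own generating weights, so nothing depends on them matching
COSMIC numerically.

# Trial statistics

## Simon's optimal two-stage design

The search enumerates every design $(r_1/n_1, r/n)$ with $n \le n_{\max}$
(default 100) and computes the exact two-stage binomial error rates

$$\Pr(\text{declare active}) = \sum_{x_1 = r_1+1}^{n_1} \binom{n_1}{x_1} p^{x_1}(1-p)^{n_1-x_1}\, \Pr(X_2 > r - x_1),$$

at $p_0$ and $p_1$. Among designs with attained one-sided type I error
$\le \alpha$ and power $\ge 1-\beta$, the optimal design minimizes the
expected sample size under the null,
$EN_0 = n_1 + (1 - \mathrm{PET}_0)(n - n_1)$. Ties in $EN_0$ (rare, and a
gap in the usual description of the procedure) are broken deterministically:
smallest $n$, then smallest $n_1$, then largest $r_1$, then smallest $r$.
The implementation vectorizes the $(r_1, r)$ grid per $(n_1, n)$ pair; the
unit tests compare it against a deliberately naive quadruple-loop
enumeration on a grid of $(p_0, p_1)$ pairs.

For the design parameters of a 5% versus 20% response rate at one-sided
$\alpha = 0.05$ and 80% power this returns the 10-then-19-patient design
with futility at 0/10 and positivity at ≥ 4/29 — the allocation used in
the motivating trial.

## Exact intervals, response summary, Fisher

"Exact method" for a small-sample proportion is implemented as the
Clopper–Pearson tail inversion in its beta-quantile form; the printed
precision convention is whole percents for ORR/CBR and one decimal for CI
bounds. The ORR denominator is *all treated patients*, even when fewer are
radiologically evaluable — following the source convention of 4/29 ≈ 14%.
Fisher's two-sided p sums hypergeometric probabilities not exceeding the
observed table's probability (with a $1+10^{-7}$ relative guard against
floating-point equality, the same convention as `stats::fisher.test`); a
zero margin gives p = 1 by convention.

# Survival stratification

Kaplan–Meier curves and the two-group log-rank statistic are computed
through the `survival` package (`survfit` with log-scale Greenwood
intervals; `survdiff`), behind stable `km_fit()` / `logrank_test()`
surfaces; the tests verify both against hand-computed risk-set products and
per-event-time enumeration. The trial's own analysis obtained log-rank
p-values from a proportional-hazards fit with exact tie handling; the
classical log-rank statistic computed here can differ from that route in
the third decimal when event times are tied. This is documented rather than
hidden — with the package's continuous simulated times the two coincide.

Stratification rules:

* **median split**: values equal to the median go to the *low* group, so an
  odd cohort splits as evenly as possible (a 29-patient cohort splits
  15/14);
* **threshold** (e.g. LDH vs its upper limit of normal): low group is
  `value <= cut`;
* **BAP1-or-UV**: the favorable group is BAP1-wildtype *or* UV-flagged;
  records with unknown BAP1 or UV status are excluded (with a count), which
  mirrors how such cohorts shrink when biopsies fail sequencing QC;
* **driver gene**: GNAQ versus GNA11, others excluded.

One-year landmark survival is read directly off the right-continuous step
function at t = 12 months.

# Synthetic-data generators

All generators are pure functions of a specification object and a seed
(RNG state is saved and restored around every draw).

**Reads** (`simulate_reads`): each template molecule draws an allele
(mutant with probability `true_vaf`), a uniform random barcode, and a read
count from a zero-truncated Poisson with mean 10 — a typical amplicon
family-size scale, configurable. Reads are emitted as
`anchor + barcode + stem + insert` with independent per-base substitution
errors (uniform over the three alternatives; default rate $10^{-3}$) on the
barcode and insert, and optional per-read stem corruption (one substituted
stem base) that renders reads invalid. The anchor and stem are otherwise
error-free so that the tagging stage's bookkeeping has an exact truth; the
generator emulates read *structure* and substitution noise, not indels, PCR
chimeras, quality-score profiles or ctDNA shedding biology — so passing
tests demonstrate correctness of the consensus arithmetic, not robustness
to every real-world artifact. Barcode collisions are possible in principle
(random 12-mers) and counted in the truth table; at the default scale their
expected number is negligible.

**Catalogs** (`simulate_catalog`): a single multinomial draw over the 96
channels from the mixture $W w$.

**Cohorts** (`simulate_cohort`): exponential event times with a baseline
rate of $\ln 2 / 13.4$ per month (the favorable-stratum median observed in
this disease setting) multiplied by hazard ratios for ctDNA-high
($e^{0.9}$), LDH-above-ULN ($e^{0.8}$) and BAP1-mutant ($e^{0.7}$) —
moderate, prognostically plausible effects chosen once as defaults and
exposed as parameters. Administrative censoring reflects staggered accrual:
follow-up is `censor_time − U(0, accrual_months)` with defaults 22 and 10
months, giving the 12–22-month follow-up spread typical of a one-year
readout after a ten-month accrual window. Response categories default to
the 4 PR / 4 SD / 20 PD / 1 NE composition of a 29-patient cohort.

# Numerical choices and degenerate inputs

* Consensus thresholds are inclusive exactly as stated: the 100% rule
  covers sizes 3–20, the 90% rule starts at 21 (where
  $\lceil 0.9 \times 21 \rceil = 19$ concordant reads suffice and 18 do
  not).
* `quantify_vaf` with zero classifiable families warns and returns `NA`.
* NNLS gradient tolerance $10^{-10}$; the solver caps iterations at 30 per
  column as a safety net for rank-deficient inputs.
* The Simon search errors explicitly when no design is feasible within
  `n_max`, and rejects $p_1 \le p_0$.
* Log-rank with zero events in both groups returns statistic 0, p = 1 with
  a warning instead of failing.
* An empty stratification group is an error, not a silent one-group fit.

# Problem sizes in the test suite

The suite exercises the pipeline at the scales the methods operate at in
practice while staying laptop-friendly: VAF recovery uses 20 replicates ×
10,000 molecules per true-VAF level (0%, 0.5%, 2%, 10%) at error rate
$10^{-3}$; signature recovery uses 50 catalogs of 5,000 mutations;
the design-search oracle comparison caps enumeration at $n_{\max} = 45$;
log-rank calibration uses 400–1,000 simulated null cohorts. These sizes are
stated here as the package's own validation choices.

# Known limitations

* Amplicon-local coordinates only; no alignment, no indel consensus, no BAM
  export.
* Signature refitting assumes the supplied signature matrix is the right
  basis; no de novo extraction, no tumor-purity adjustment.
* The log-rank implementation covers the two-group unadjusted test used for
  the biomarker figures; Cox regression with covariates is out of scope.
* The ctDNA "total copies" biomarker is taken as a supplied per-patient
  scalar; its derivation from VAF and input copies is assay-specific and
  left to the user.
* Quantities that require patient-level trial data (median OS/PFS, the
  observed 14/15 ctDNA split, per-patient genomics) are represented by
  property-based checks on synthetic cohorts, not reproduced numerically.
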