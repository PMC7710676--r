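---
title: "Methods: set-based rare-variant burden testing in enhancers and coding regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Coding variation explains only part of the heritability of complex
neurodegenerative disease. Enhancers — distal cis-regulatory elements that
modulate a target gene's transcription through transcription-factor binding —
are a natural place to look for the remainder, but individual non-coding
variants are too rare to test marginally. `enhburden` tests the *aggregate*
burden of rare, evolutionarily constrained variants across all enhancers
linked to one gene (or to every gene of a pathway) in a case-control
whole-genome sequencing cohort, and the matching coding-region burden for
the same genes.

The enhancer-gene map itself (which intervals regulate which gene, from
epigenomic, transcriptomic or Hi-C chromatin-contact evidence) is consumed
as input; constructing such maps is outside the package's scope.

# Pipeline and models

## Quality control

Defaults mirror standard large-cohort WGS practice, strict on the "bad"
side of each comparator:

| stage | rule | default |
|---|---|---|
| sample | genotype missingness | excluded if > 10% |
| variant | missingness | removed if > 5% |
| variant | Hardy-Weinberg exact test in controls | removed if p < 1e-6 |
| variant | differential case/control missingness (Fisher exact) | removed if p < 1e-6 |
| variant | mean depth | removed if > 6 s.d. from cohort mean |
| variant | monomorphic after exclusions | removed |

The Hardy-Weinberg test is the exact conditional test (sum of probabilities
of heterozygote configurations no more probable than observed, given the
allele counts) — the chi-square approximation is invalid at rare-variant
counts. A widely circulated description of the sample-missingness rule is
stated as "excluded if missingness **< 10%**", which would exclude nearly
every sample; this package implements the only self-consistent reading,
exclusion when missingness *exceeds* 10%. Ancestry projection, inbreeding
and sex-concordance checks require genome-wide common-variant panels and
are accepted as a pre-filtered sample list instead of re-implemented.

## Variant prioritization

Enhancer mode retains a variant iff reference-panel AF < `maf_max`
(default 0.01) **and** conservation score > `cons_min` (default 0.8, a
LINSIGHT-style per-base probability of negative selection). Two deliberate
conventions, both strict inequalities at the printed thresholds:

* **Absent population AF passes rarity.** A variant unobserved in the
  reference panel is exactly the ultra-rare substrate the test targets.
* **Absent conservation score fails.** The filter demands positive
  evidence of constraint; missing evidence is not evidence.

Coding mode replaces the conservation rule with an impact-class rule:
HIGH/MODERATE/LOW kept, `synonymous` and `TF_binding_site_variant` always
dropped (they leave the protein sequence intact), unknown classes dropped.

Rarity filtering uses the external panel AF; *weighting* (below) uses the
cohort-combined MAF. These are distinct quantities on purpose.

## Null model and association tests

Case status is regressed on an intercept, sex and the first ten
principal-component eigenvectors of common-variant genotypes (supplied in
the sample table) by maximum-likelihood logistic regression. All set tests
are score tests conditioned on this fit, so per-set work is cheap.

With dosages $G$ ($n \times m$, missing calls mean-imputed per variant),
weights $w_j = \mathrm{Beta}(p_j; a_1, a_2)$ at cohort MAF $p_j$, residuals
$r = y - \hat\mu$ and $P = V - VX(X'VX)^{-1}X'V$, $V = \mathrm{diag}
(\hat\mu(1-\hat\mu))$:

$$Q_{\mathrm{skat}} = \sum_j (w_j g_j' r)^2, \qquad
  Q_{\mathrm{burden}} = \Big(\sum_j w_j g_j' r\Big)^2 .$$

$Q_{\mathrm{skat}}$ is a mixture of 1-df chi-squares with eigenvalues from
$W G' P G W$; SKAT-O scans $Q_\rho = (1-\rho)Q_{\mathrm{skat}} +
\rho\,Q_{\mathrm{burden}}$ over the classical eight-point grid
$\rho \in \{0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1\}$, takes the minimum
per-$\rho$ p and converts it to one p-value by integrating the conditional
null of the minimum-p statistic over the shared burden chi-square
component. The combined p is capped at (min-p × grid size).

**Weights.** $a_1 = 1$ is fixed (the standard monotone-decreasing
rare-variant family; only the second shape is ever tuned in practice) and
$a_2$ defaults to 250, the value a positive-control tuning on a
haploinsufficiency-gene enhancer set selects from the grid {25, 250, 2500}
(`tune_a2()` / `run_tune()` reproduce the selection: smallest p, ties to
the smallest $a_2$). Larger $a_2$ concentrates weight on ever rarer
variants; at $a_2 = 250$ a variant at MAF 0.001 receives ~195× the weight
of one at MAF 0.01.

**Coding burden.** Where filtering is functional and stringent, surviving
variants have comparable effects and a carrier-indicator regression is
more powerful than a variance-component test. The package fits Firth
penalized logistic regression (Jeffreys-prior penalty
$\tfrac12 \log\det I(\beta)$, modified-score Newton iterations with step
halving), which keeps $\hat\beta$ finite under the complete separation
that near-private variants routinely produce. The p-value is the penalized
likelihood-ratio test, not Wald — Wald collapses exactly in the sparse
regime this targets. For a single binary predictor the Firth estimate
equals the half-cell-corrected log odds ratio, which the test suite
verifies exhaustively on all zero-cell 2×2 tables with cells ≤ 10.

**Summaries.** A *carrier* holds ≥ 1 alternate allele at ≥ 1 retained set
variant; the *risk ratio* is the naive ratio of carrier frequencies
(undefined when no control carries). Published risk ratios that do not
match this naive definition on their own printed counts are not
special-cased; the package reports the definition above and documents the
discrepancy. Inflation is summarized by
$\lambda_{GC} = \mathrm{median}(\chi^2_{obs}) / 0.4549364$ and
$\lambda_{1000} = 1 + (\lambda_{GC}-1)(1/n_{case}+1/n_{ctrl})/(2/1000)$.

## Quadratic-form p-values

The textbook route to these tail probabilities is characteristic-function
inversion (Davies' algorithm) with a moment-matching fallback. This
implementation computes the same quantity by Ruben's exact expansion of a
positive quadratic form as an infinite *central chi-square mixture*,

$$P(Q \le q) = \sum_{k\ge0} a_k\, F_{\chi^2_{m+2k}}(q/\beta),
  \qquad \beta = 0.90625\,\lambda_{\min},$$

whose nonnegative coefficients $a_k$ sum to one, giving a *rigorous*
truncation bound (the unaccounted mass) with none of the oscillatory-tail
machinery CF inversion needs. Target accuracy 1e-9, series capped at 1e5
terms (5e3 inside SKAT-O); coefficients are computed once per eigenvalue
set and reused across quantiles, which is what makes the SKAT-O
conditional integral cheap. When eigenvalue spread stalls the series the
Liu-Tang-Zhang four-moment approximation is used and flagged
(`fallback_flag` in result tables). Eigenvalues below mean(λ)/1e5 are
dropped (the reference implementation's rule); p-values are clipped to
(1e-300, 1]. The SKAT-O outer integral substitutes $x = y^2$ to remove
the $\chi^2_1$ density singularity and uses fixed Gauss-Legendre panels
on $y \in (0, 8)$ (truncation error < 2e-15).

Correctness is pinned by chi-square closed forms, scale equivariance, a
10⁶-draw Monte-Carlo oracle (agreement within 3 s.e.), degenerate-grid
identities (ρ-grid {0} ≡ SKAT, {1} ≡ burden score test) and null-simulation
uniformity (Kolmogorov-Smirnov).

## TF-binding deltas

Motifs are read from MEME minimal files and converted to log2-odds against
the stated background with pseudocount 1e-4. A sequence window centred on
a variant is scanned at every offset on both strands; `N` contributes the
background-expected score at its position; ties resolve to the leftmost
offset, forward strand first. `binding_delta` reports best(wt) −
best(mut) per motif — positive means the mutation weakens the best
predicted site. No significance threshold is attached: none is
established for this quantity, so raw deltas are reported.

# The simulator: what it emulates, what it does not

`sim_config()` defaults *are* the stated world of a discovery-scale
cohort: 4,495 cases / 1,925 controls, ~40× depth, rare-variant MAF
spectrum Beta(0.3, 80) truncated to (1e-4, 0.01) (mean ≈ 3×10⁻³, a
realistic folded rare spectrum), 40% of variants conserved (score > 0.8),
0.5% genotype missingness, two enhancer intervals per gene set, sex and
10 PCs with mild case-mean shifts (0.05 and 0.1 on the first three) so the
null model has real confounding to absorb.

Planted effects operate at the **carrier level**: case/control carrier
probabilities implying the target risk ratio are drawn per sample and each
carrier receives one alternate allele at a uniformly chosen set variant.
This makes the planted truth directly comparable to `carrier_stats()`
output. Planted variants are given conservation scores in (0.85, 1) and
population AF 0 so they survive prioritization — the planted effect tests
the association machinery, not the filter (the filter has its own
enumeration tests).

Not emulated: linkage disequilibrium, sequencing-error/genotyping-error
models, population stratification beyond linear covariate effects, indel
length distributions. A green calibration test therefore establishes
correct type-I behaviour *under the assumed generative model*, not
robustness to cryptic relatedness or batch artifacts.

# Numerical and design choices

* Coordinates: VCF positions 1-based, all interval logic 0-based half-open;
  conversions centralized in one helper pair (single off-by-one authority).
* Variant identity is the exact `chrom:pos:ref:alt` key; inputs are assumed
  pre-normalized (one caller's output); annotation join misses are counted,
  never fatal.
* Null-model convergence at score tolerance ~1e-12; perfect separation on
  covariates is an error that names the remedy (Firth or covariate
  removal). Aliased or constant covariates are dropped with a warning.
* Sets with < 10 retained variants (configurable) are reported with
  `insufficient_flag` rather than suppressed.
* Config files are JSON (no YAML parser in the supported dependency set);
  the CLI contract (single declarative file, flag overrides, exit codes
  0/2/3) is unchanged.
* Determinism: one seeded stream per simulator run; the seed is recorded in
  every output header; identical config + inputs give byte-identical
  result files.

# Scaled-down validations

Two stated validations run at reduced scale to fit a CI-sized time budget,
with the statistics adjusted accordingly: the null-uniformity spot check in
the unit suite uses 250 replicates (the acceptance battery runs the full
2,000 and checks the rejection fraction against the exact binomial 99%
interval [0.037, 0.063] and λ ∈ [0.9, 1.1]), and the Firth
recovery property uses 120 replicates per effect size with a Monte-Carlo
s.e. criterion. The power battery plants a risk ratio of 5 at 1% case
carrier frequency (n = 2,000 + 2,000, 500 planted and 500 null replicates)
and requires the α = 10⁻³ rejection rate to exceed the matched null rate.

# Known limitations

* Summary-statistic-only testing against external control counts and
  cross-cohort meta-analysis are out of scope.
* Indel-to-conservation-score matching conventions vary between score
  tracks; the package requires a pre-joined annotation table rather than
  guessing.
* The exact-series p-value inherits an *absolute* accuracy target; p-values
  far below 1e-9 are reported with reduced relative accuracy (as with any
  fixed-accuracy CF inversion) and extreme eigenvalue spreads fall back to
  the flagged moment approximation.
* BCF/gVCF, phased genotypes and structural variants are not supported.
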