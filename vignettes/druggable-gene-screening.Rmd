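---
title: "Screening druggable genes from GWAS and eQTL summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening druggable genes from GWAS and eQTL summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(targetmr)
```

## The problem and the model

Drug targets with genetic support succeed in development far more often
than targets without it. For a disease with GWAS summary statistics and a
tissue with cis-eQTL summary statistics, a gene is a candidate target when
(i) its expression level is causally associated with disease risk and
(ii) its product is tractable for small molecules or biologics. `targetmr`
implements that screen as a four-stage cascade over summary-level data,
with hemorrhagic-stroke outcomes (intracranial aneurysm and its ruptured
form, subarachnoid hemorrhage; intracerebral hemorrhage) and blood
cis-eQTLs as the motivating application:

1. **SMR prioritization.** At a gene's top cis-eQTL (smallest eQTL
   p-value passing $p < 5\times10^{-8}$ and MAF $> 0.01$), with
   $z_x = \beta_x/s_x$ for expression and $z_y = \beta_y/s_y$ for disease,
   the SMR statistic is
   $T_{SMR} = z_x^2 z_y^2 / (z_x^2 + z_y^2) \sim \chi^2_1$, the causal
   ratio $b_{SMR} = \beta_y/\beta_x$ (log-OR per SD expression), and the
   delta-method error $s_{SMR} = |b_{SMR}|\sqrt{z_x^{-2} + z_y^{-2}}$.
   Genes with $p_{SMR} < 0.05$ continue. The HEIDI statistic (sum of
   squared standardized differences $b_{SMR}(i) - b_{SMR}(\text{top})$
   over SNPs in intermediate LD with the top SNP, with delta-method
   variances and LD-derived covariances, referred to a Satterthwaite
   moment-matched chi-square) distinguishes a single shared causal
   variant from linkage. HEIDI is *reported, not gated*: small HEIDI
   p-values can accompany genes that survive every other stage, so the
   default cascade records it and an optional `heidi_p_min` turns it
   into a filter.
2. **Two-sample MR confirmation.** Instruments are cis-eQTLs at
   $p < 5\times10^{-8}$ within $\pm 100$ kb of the TSS with MAF $> 0.01$,
   clumped greedily at $r^2 < 0.001$ within a 10,000-kb window. One
   instrument: Wald ratio $\beta_y/\beta_x$ with first-order error
   $s_y/|\beta_x|$. Several: inverse-variance weighting of the per-SNP
   ratios, with MR-Egger, weighted-median and weighted-mode estimates as
   sensitivity analyses; all computed estimates must agree in sign.
   Cochran's $Q$ is reported; the Egger intercept gates the gene
   (intercept $p \ge 0.05$ required) when more than two instruments
   exist, mirroring the usual "pleiotropy test needs $>2$ SNPs" practice.
   P-values are Benjamini–Hochberg adjusted within one family per
   (outcome, eQTL dataset) pair and genes pass at $p_{fdr} < 0.05$.
3. **Colocalization.** Over the gene $\pm 500$ kb, per-SNP Wakefield log
   approximate Bayes factors
   $\tfrac12[\log\frac{V}{V+W} + z^2\frac{W}{V+W}]$ are combined into the
   five single-causal-variant hypotheses H0–H4 under per-SNP priors
   $p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$; a gene passes at
   $PPH4 > 0.75$ or $PPH3 + PPH4 > 0.8$, and the rule that fired is
   recorded rather than merged (the second rule deliberately admits
   linkage).
4. **Druggability.** Surviving genes are looked up, case-insensitively,
   in a local druggable-genome list (a flat-file stand-in for a
   drug–gene interaction database export; no network access).

A fifth component dissects risk-factor pathways: multivariable IVW
(weighted least squares of outcome effects on several exposures' effects,
no intercept, dispersion floored at 1) estimates direct effects of
correlated exposures such as hypertension and systolic/diastolic blood
pressure, and the coefficient-product method decomposes a total effect as
`indirect = a*b`, `direct = total − indirect`, proportion mediated
`indirect/total` with delta-method error $\sqrt{a^2 s_b^2 + b^2 s_a^2}$.
Proportions outside $[0,1]$ are reported verbatim and flagged
"inconsistent" — published mediation tables legitimately contain values
such as 133.5%.

## Parameters that matter

| Parameter | Default | Units / meaning |
|---|---|---|
| `eqtl_p_max` | 5e-8 | instrument significance threshold |
| `maf_min` | 0.01 | minor-allele-frequency floor (exclusive) |
| `tss_window_kb` | 100 | instrument window around the TSS, kb |
| `clump_r2`, `clump_window_kb` | 0.001, 10000 | LD-independence ceiling and search window |
| `smr_p_max` | 0.05 | stage-1 SMR gate |
| `fdr_alpha` | 0.05 | stage-2 BH gate per (outcome, dataset) family |
| `egger_intercept_alpha` | 0.05 | pleiotropy gate when `n_snp > 2` |
| `coloc_priors` | 1e-4 / 1e-4 / 1e-5 | per-SNP priors $p_1, p_2, p_{12}$ |
| `pph4_min`, `pph34_min` | 0.75, 0.8 | colocalization decision rules |
| prior effect SD | 0.15 / 0.2 | Wakefield $W^{1/2}$: SD-units (quantitative) / log-OR (binary) |
| HEIDI | p < 1.57e-3, $r^2\in[0.05,0.9]$, $m\in[3,20]$ | candidate-SNP eligibility |

Every threshold is overridable through `cascade_config()`; the defaults
are the screen's standard operating values.

## What the simulator emulates — and what it does not

`simulate_region()` works on the standardized-genotype scale: a causal
cis-eQTL explaining fraction $q$ of expression variance has standardized
effect $\sqrt q$; under the shared-variant scenario the outcome's
log-odds effect at that variant is `causal_effect` (log-OR per SD
expression) times the expression effect. Marginal effects are
LD-propagated ($R\gamma$), observed z-scores add LD-correlated standard
normal noise ($z = z_{true} + L^\top\varepsilon$, $LL^\top = R$), and
per-allele standard errors follow the usual large-sample forms —
$1/\sqrt{2p(1-p)n}$ for a standardized quantitative trait and
$1/\sqrt{2p(1-p)Nv(1-v)}$ for a case-control trait with case fraction
$v$. Defaults mirror the screen's motivating datasets: $n = 31{,}684$
for blood eQTLs and $7495$ cases / $71{,}934$ controls for the outcome;
cis variance explained defaults to 2%, a typical top-signal scale for
blood cis-eQTLs. LD is AR(1) with $\rho = 0.9$ (a block model is
available for linkage scenarios), MAFs are uniform on $[0.05, 0.5]$, and
about 30% of GWAS rows are emitted on the swapped allele frame to
exercise harmonization.

The simulator does **not** emulate: multi-causal-variant architectures
within a trait, allele-frequency–dependent effect sizes, imputation
noise, sample overlap between the eQTL and GWAS studies, population
stratification, or mismatch between the analysis LD and the data's LD.
Passing tests therefore demonstrate correctness and calibration of the
estimators under their own assumptions, not robustness to those
real-data pathologies.

The 20-gene benchmark plants three H4 targets
(`causal_effect = 0.6` — a clearly detectable drug-target-scale effect
at these sample sizes, comparable to the upper range of published
per-SD-expression log-ORs) and fills the rest with decoys: H0 (nothing),
H1 (eQTL only), H2 (outcome only) and H3 (linkage). H0/H1/H2 decoys sit
*inside* the druggable list so that their exclusion rests on the
statistics; H3 decoys are excluded from the list because the
$PPH3+PPH4$ rule admits linkage by design, making druggability the stage
at which such genes fail — exactly the planted-construction logic the
benchmark is meant to verify.

## Numerical choices and degenerate inputs

* Clumping ties on p-value break by smaller position, then
  lexicographic SNP id, so results are independent of row order. The
  window bounds the search — a distant SNP is never removed on account
  of an index SNP outside the window.
* Palindromic (A/T, C/G) SNPs are dropped unconditionally during
  harmonization; there is no frequency-based rescue. Duplicate SNP ids
  are rejected, not merged.
* IVW uses multiplicative random-effects inflation
  $\sqrt{\max(1, Q/(k-1))}$ — over-dispersion is absorbed, never
  deflated. The same floor applies to MR-Egger and multivariable IVW,
  which makes single-exposure MVMR agree with univariable IVW to
  numerical precision.
* Weighted-median interpolation evaluates the inverse-variance CDF at
  bin midpoints; the weighted mode uses a normal kernel with bandwidth
  $0.9\,\min(\text{weighted SD}, \text{weighted MAD})\,k^{-1/5}$
  (degenerate MAD falls back to the SD; identical ratios return the
  common value with zero standard error). Median/mode standard errors
  are seeded parametric bootstraps (1000 draws), and the seed is
  recorded in the result.
* Colocalization accumulates hypothesis weights with log-sum-exp, so
  z-scores beyond 40 do not overflow; a single-SNP region yields
  $PPH3 = 0$ identically.
* HEIDI's correlated quadratic form is referred to a Satterthwaite
  moment-matched chi-square (matching mean $m$ and variance
  $2\sum R_{ij}^2$) — an approximation, adequate at the
  $m \le 20$ SNPs used.
* `instrument_strength()` uses $R^2 = 2p(1-p)\beta^2$ (standardized
  trait) and $F = (n-2)R^2/(1-R^2)$; it errors when the allele frequency
  or sample size is missing rather than guessing. The internal normal
  quantile is `qnorm(0.975)` at full precision, not 1.96.
* A gene whose region lacks an LD reference is marked untestable at the
  first stage that needs LD (clumping) and the run continues; missing
  eQTL signal marks a gene untestable at stage 1. Both appear in the
  ledger with the stage named.

## Design choices where the design was open

* **FDR family.** One BH family per (outcome, eQTL dataset) pair. This
  matches per-dataset reporting of results and keeps families comparable
  across outcomes.
* **MVMR instrument merging** is left to the caller (the exposure
  matrix is supplied pre-harmonized); for blood-pressure-type analyses
  the natural choice is the union of per-exposure instruments re-clumped
  jointly.
* **Mediator coefficient.** `mediation_product()` accepts the
  mediator-to-outcome effect from either a multivariable (exposure-
  adjusted) or univariable fit; in a simple chain without reverse paths
  the two coincide, and neither is asserted as canonical.
* **Conditional F for MVMR** is reported `NA`: computing it faithfully
  requires instrument-correlation information absent from summary-level
  inputs.
* **LD reference** is always user-supplied (a matrix per region);
  reference-panel retrieval is out of scope.

## Problem sizes used in the test-suite simulations

Calibration suites use 500 replicates for type-I error and interval
coverage (k = 20 instruments), 120 regions per HEIDI scenario and 200
per colocalization recovery check (100 SNPs per region), 300 replicates
for mediation recovery, and a 20-gene × 200-SNP benchmark for the
end-to-end cascade. These sizes give Monte Carlo standard errors of
about one percentage point on rates near 5% while keeping the whole
suite fast enough to run routinely.

## Known limitations

Single-causal-variant colocalization only (no SuSiE-style multi-signal
decomposition); no MR-PRESSO or Steiger filtering; no pQTL-specific
handling beyond treating the file identically; no cross-ancestry
analysis; the HEIDI p-value is approximate for very small $m$; and the
screen's real-data behaviour depends on consortium-scale inputs that are
deliberately outside the package's test surface.
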