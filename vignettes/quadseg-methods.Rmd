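---
title: "Quadrivalent segregation analysis for PGT-SR: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quadrivalent segregation analysis for PGT-SR: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quadseg)
```

## The biological model

A carrier of a balanced reciprocal translocation t(A;B) has two derivative
chromosomes, der(A) = CS(A)+TS(B) and der(B) = CS(B)+TS(A), where the
translocated segment (TS) is the part distal to the breakpoint and the
centric segment (CS) is the remainder, centromere included. At meiosis I
the four chromosomes pair as a quadrivalent and disjoin by one of five
modes: alternate ({A,B} or {der(A),der(B)}), adjacent-1 (homologous
centromeres apart: {A,der(B)}, {der(A),B}), adjacent-2 (homologous
centromeres together: {A,der(A)}, {B,der(B)}), 3:1 (eight products), or 4:0
(two products). That gives 16 composition classes; only the two alternate
products are genetically balanced.

`enumerate_gamete_classes()` materialises these classes as segment-dosage
vectors over (CS~A~, TS~A~, CS~B~, TS~B~). With
`include_recombinants = TRUE` each composition is also returned in a
recombinant state — one chromatid has undergone an interstitial crossover —
for the classical count of 32 gamete karyotypes. The crossover convention
matters: an interstitial exchange swaps translocated segments between a
chromosome and its derivative, so when the pairing partner segregates to
the *same* pole the exchange is copy-neutral, and when it does not, the
recombinant chromatid carries its partner's segment content. Under this
convention recombination introduces no new dosage vector (a recombinant
adjacent-1 gamete, for instance, is copy-number-identical to alternate), so
a classifier operating on the 16-class table is complete at CNV resolution.
This is also why the classifier never reports "recombinant": comprehensive
chromosome screening cannot see copy-neutral exchanges, just as it cannot
distinguish a balanced carrier embryo from a normal one.

An embryo is the carrier gamete plus a balanced partner gamete, so its
expected dosage is the gamete dosage plus (1,1,1,1). The 14 unbalanced
embryo signatures are pairwise distinct (verified by exhaustive enumeration
in the test suite), which is what makes per-embryo mode inference
well-posed at segment resolution.

## Coordinates, karyotypes and quadrivalent metrics

Internally all intervals are 0-based half-open; ISCN strings and the
1-based convention appear only at the parsing boundary. The ISCN parser
accepts exactly the two-autosome grammar
`46,[XX|XY],t(a;b)(armband;armband)`; sex-chromosome translocations,
three-way rearrangements and same-chromosome tokens are rejected as
unsupported rather than silently misread.

Band labels are resolved to the midpoint of the band interval (start/end
selectable), since sub-band precision is not available; sub-band queries
fall back to their parent band with a warning. The packaged band map is
*synthetic*: ISCN-like labels on arms divided at a plausible genomic scale
(file `cytobands_synthetic.tsv`). This is a deliberate choice, not a
shortcut with consequences: the pipeline treats band coordinates only as a
starting point and re-measures segment lengths from the CNV boundaries of
each carrier's unbalanced embryos (`estimate_breakpoints()`, applied
automatically in `build_cohort_table()`), which is also how the clinical
covariates are defined. Chromosome lengths and centromere intervals are
hg19-derived constants; an alternative assembly can be supplied as TSV.

The covariates are the quadrivalent geometry measures used in clinical risk
modelling: chromosome sizes, TS and CS lengths, TSR and CSR (longest/
shortest ratios), TAR (TS over its chromosome arm), and acrocentric
involvement (chromosomes 13, 14, 15, 21, 22). Index 1 refers to the longer
chromosome. Conventions differ between sources on this point, so
`compute_metrics()` also returns the per-chromosome breakdown keyed by
physical chromosome; all derived quantities are invariant to the input
order of the two breakpoints.

Breakpoint-estimate accuracy: the estimator is the per-chromosome median of
breakpoint-side CNV boundaries across unbalanced embryos, with raw median
absolute deviation as dispersion. With n embryos and boundary jitter SD
sigma the median's sampling error is roughly 1.25*sigma/sqrt(n); at n = 20
and sigma = 1 Mb about 93% of estimates fall within 0.5 Mb of the true
breakpoint, which the Monte-Carlo test asserts as a >=90% bound.

## Classification rules and their edge cases

`classify_embryo()` converts a profile to a segment-dosage vector by
matching each CNV call against the carrier's segment intervals within a
tolerance (`tol_bp`, default 5 Mb: the platform's stated 1–4 Mb resolution
plus band-midpoint uncertainty) and looks the vector up in the 15-entry
signature table. Design choices a user should know:

* **Ambiguous whole-chromosome matches.** When a translocated segment is
  shorter than the tolerance, a centric-segment call also passes the
  whole-chromosome test. Candidates are therefore scored by total boundary
  deviation and the closest interpretation wins, rather than the first.
* **Incidental aneuploidy.** Whole-chromosome events on uninvolved
  chromosomes (and segmental events on uninvolved chromosomes) are treated
  as incidental — typically mitotic or independent meiotic errors — and
  flagged without vetoing the quadrivalent mode. This mirrors the clinical
  distinction between embryos in alternate segregation and the smaller set
  of transferable normal/balanced embryos.
* **ND (not determined).** A partial event on an involved chromosome that
  matches no segment, or a dosage vector matching no signature, forces ND.
  ND embryos count as unbalanced (non-alternate) in the risk models, since
  the outcome contrast is alternate vs everything else.
* **Platform floor.** Calls under 1 Mb or with copy number outside 0–4 are
  dropped with a warning before matching.
* **Partner gamete** is assumed balanced. Deviations (e.g. double
  paternal/maternal imbalance) land in ND rather than being misattributed.

## Statistical battery

The embryo-level table couples each embryo's called mode with its carrier's
covariates. On top of it:

* `odds_ratio()`: cross-product OR with Haldane–Anscombe 0.5 correction
  when a cell is zero, Woolf log-normal CI, chi-square p without continuity
  correction. This combination reproduces, to three decimals, the printed
  stratified ORs of the large clinical cohort used for calibration.
* `cmh_analysis()`: Mantel–Haenszel common OR and CMH chi-square via
  `stats::mantelhaen.test` (continuity correction off by default), plus a
  hand-implemented Breslow–Day homogeneity test (Tarone adjustment
  optional) — no installed package provides it.
* `fit_binary_glmm()`: alternate vs non-alternate with a per-carrier random
  intercept, fitted by Laplace-approximate ML (`lme4::glmer`). Continuous
  covariates are standardized internally for optimizer stability and the
  coefficients are transformed back, so reported ORs stay per original unit
  (TS sizes are in Mb). Singular fits (random-intercept variance at zero)
  are valid boundary optima and are flagged, not failed. Genuine
  non-convergence produces a flagged fit with diagnostics, never a silent
  result.
* `fit_multinomial_glmm()`: the multinomial model is decomposed into
  independent binary contrasts against the alternate reference. A joint
  multinomial random-effects likelihood would add little beyond contrast-
  wise ORs, which is what clinical tables report; the decomposition is
  documented as an approximation. Contrasts with fewer than 10 events are
  skipped with a warning.
* `select_covariates()`: univariate screen at alpha = 0.05, preserving
  candidate order — the conventional univariate-to-multivariable step. No
  multiple-testing correction is applied (matching standard practice in
  this literature); the number of tests is reported alongside.
* `roc_evaluate()`: AUC as the rank statistic with sensitivity/specificity
  at the Youden-optimal cut. Scores are fixed-effects-only probabilities
  (`predict_risk()`), i.e. predictive for a new carrier rather than
  explanatory for a carrier already in the data.
* TAR1 is additionally dichotomized at 0.2 in reports where a stratified
  view is wanted, matching common clinical presentation.

## The synthetic cohort generator

`simulate_cohort()` exists so every pipeline stage can be exercised without
patient data. Its defaults *are* the study conditions of the calibration
cohort: 2,253 carriers, 45.6% female; diagnosed blastocysts per carrier
drawn zero-truncated Poisson with mean 4.8 (only totals are published, so
the count distribution is a modelling choice); autosome pairs uniform
(acrocentric involvement then arises at its combinatorial rate of ~41%,
close to the published split); breakpoints uniform within arms with a 5 Mb
minimum segment and no acrocentric p-arm breakpoints; baseline contrast
logits equal to log frequency ratios of the published five-way mode split
(46.1 / 31.3 / 12.4 / 5.4 / 4.7%, with true 4:0 products at their observed
4/10,846 rate and the rest of the 4.7% as ND); per-carrier random
intercepts (SD 0.5 log-odds) shared across all non-alternate contrasts —
the simplest clustering structure consistent with repeated embryos per
carrier; covariate effects from `default_mode_effects()` (female 1.293,
Acr-ch 1.208, TAR1 0.806), applied identically to each contrast so the
pooled unbalanced-vs-alternate conditional OR equals those values exactly;
1 Mb boundary jitter (the platform's resolution scale); 8% incidental
whole-chromosome aneuploidy (a typical blastocyst TE-biopsy rate, chosen
once as a neutral default — the source cohort does not report it); and ND
as profile corruption (a spurious segmental call on an involved
chromosome), not as a latent sixth mode, at rate 0.047.

Baseline logits are shifted by the covariate means of the karyotype sampler
(estimated once from a fixed internal stream and stored in the config) so
the stated frequencies hold at covariate means. Because contrast logits are
log-ratios to the alternate reference, the published marginal percentages
can be used directly without renormalisation.

Determinism: the cohort is a pure function of the config, seed included.
Per-carrier substreams are derived from the master seed, so adding a draw
site for one carrier never shifts another carrier's draws. Configs
round-trip losslessly through JSON (`sim_config_write()` /
`sim_config_read()`, 17 significant digits).

What the generator does *not* emulate: mosaicism, maternal-age aneuploidy
curves, segmental de-novo events away from the breakpoints, assay-specific
noise beyond Gaussian boundary jitter, and gamete-level (sperm FISH) data.
Passing tests on synthetic cohorts therefore validate the machinery —
classification is exact at zero noise, >=99% at platform noise, and
generating coefficients are recovered — but say nothing about biology not
encoded in the generator.

## Problem sizes and tolerances

The test suite runs the parameter-recovery experiment at 2,000 carriers
(about 10,000 embryos) and 20 replicates, requiring 95% CI coverage of the
generating value in at least 90% of replicates and the averaged female-sex
OR within 0.1 of truth; marginal-frequency checks use cohorts of roughly
10,000 embryos at a 3-Monte-Carlo-SE tolerance. These sizes were chosen to
make the binomial/coverage bounds sharp enough to detect real defects while
keeping a full run of the suite in the minutes range. GLMM convergence uses
lme4 defaults (relative deviance change at the optimizer's tolerance, at
most 200 inner iterations); all fits are deterministic given the data.

ND embryos enter the unbalanced side of the binary outcome, so the 4.7%
covariate-independent corruption slightly attenuates recovered ORs (by
design of the outcome definition, not a defect); the attenuation is well
inside the recovery tolerance at the default rates.

## Known limitations

* Balanced and normal embryos are indistinguishable by CNV profile, and
  copy-neutral recombinants are invisible; "alternate" therefore pools all
  of them.
* The classifier assumes one carrier-side meiotic event per embryo plus at
  most incidental aneuploidy; chaotic profiles go to ND rather than being
  forced into a mode.
* 3:1 subtypes (tertiary vs interchange) are distinguishable in the
  enumeration metadata but pooled for statistics, as clinical reports pool
  them.
* The published clinical ROC operating point and p-values depend on the
  unavailable patient data; the package reproduces the machinery
  (verified by rank-statistic and nesting properties) and the printed
  contingency quantities, not those patient-level numbers.
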