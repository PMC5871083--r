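---
title: "Methods: pathway scores, interaction analysis and the D-dimer/C4 diagnostic model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pathway scores, interaction analysis and the D-dimer/C4 diagnostic model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lupuscc)
```

`lupuscc` packages three statistical procedures used to study the
interplay of the coagulation cascade and the complement system in
systemic lupus erythematosus (SLE), together with a simulator that
generates cohorts on which every claim the procedures make can be
verified as parameter recovery. This vignette is the package's own
account of those methods: the models, their assumptions, the tunable
parameters, the numerical conventions, and what the simulations do and
do not establish.

## Composite pathway scores

An ELISA panel measures 21 analytes: complement activators C3a, C4a,
C5a, MASP2, C7 and inhibitors/de-activators C1q, FI, C4; coagulation
activators VWF, F7, TAT, FIB, F9, D-dimer and inhibitors PROS, F12,
F13, ATIII; and inflammatory cytokines TNF-RII, IL-6, IL-8 (all
activators). Activators rise with pathway activation; inhibitors fall.

Because analytes are assayed in different units, each analyte is first
**max-normalized within the analysis cohort**: divided by its maximum
over patients, so every analyte's maximum is exactly 1. The summary
score for a pathway is then the signed sum of normalized values
(+ activators, − inhibitors). Two consequences worth noting:

* scores are *scale-invariant* — multiplying any analyte column by a
  positive constant changes nothing — but *cohort-relative*: adding or
  removing patients can move a column maximum and hence everyone's
  score. `normalize_analytes()` always normalizes over exactly the
  rows given to it; pooling with external reference samples is the
  caller's decision.
* with $k$ activators and $j$ inhibitors a score lies in $[-j, +k]$
  (cytokine $[0,3]$, complement $[-3,5]$, coagulation $[-4,6]$ under
  the default catalog).

Missing analyte values are a hard error by default; an explicit
`na_action = "drop"` omits the analyte from that patient's sum without
rescaling and flags the row, because silently treating a missing assay
as zero would bias the score by a full activator/inhibitor unit.

## Interaction analysis on log disease activity

The outcome is ltSLEDAI = ln(SLEDAI). The natural log (not base 10) is
used because stratified group means of the transformed outcome in this
literature sit around 1.6–2.9, i.e. ln of SLEDAI scores 5–18; base 10
would give 0.7–1.3. SLEDAI must be ≥ 1; cohorts containing 0 can set a
+1 offset (`lt_transform(x, offset = 1)`), which is deliberately *not*
the default since silent offsets change coefficients.

The pipeline is: (1) `fit_joint_linear()` — OLS of ltSLEDAI on both
scores jointly, t-based 95% CIs; (2) `test_interaction()` — the same
model plus the product term, whose two-sided t p-value is the
interaction test (invariant to affine rescaling of either predictor);
(3) `dichotomize()` — median split, **ties to low** so the threshold
is unambiguous with discrete scores; (4) `stratified_means()` — the
2×2 cell table with pairwise comparisons; (5) `subgroup_moderation()`
— the whole pipeline repeated within the high/low halves of the
cytokine score (median split, ties low), with dichotomization
thresholds recomputed per subgroup, since effect modification by
inflammation is the scientific question.

For the cell comparisons two procedures are provided, as is standard
when variance homogeneity is in doubt: the LSD test (pairwise t using
the pooled 4-cell ANOVA error, df = N − 4) under homogeneous
variances, and Tamhane's T2 (pairwise Welch t with Sidak adjustment
over the 6 comparisons) otherwise. The selector is Levene's test
(classical, mean-centered) at α = 0.05 — the conventional SPSS-style
routing; `route = "LSD"`/`"TamhaneT2"` overrides it, which matters for
tiny cells where Levene's test itself is degenerate. When a pooled
error is exactly zero, p is 1 for equal means and 0 otherwise, by
convention. No multiplicity adjustment is applied across the row and
column comparisons of the stratified table (matching how such tables
are conventionally presented); Sidak appears only inside Tamhane T2,
where the procedure defines it.

## The quartile-coded D-dimer/C4 diagnostic model

Plasma D-dimer (µg/mL) and serum C4 (mg/mL) are coded into ordinal
risk quartiles 1–4 (4 = highest risk). Intervals are
left-open/right-closed on the concentration axis, so a value exactly
on a cut belongs to the lower concentration interval: D-dimer
(higher-is-risk) codes 1 iff v ≤ 0.56, 2 iff 0.56 < v ≤ 1.20, 3 iff
1.20 < v ≤ 2.80, 4 iff v > 2.80; C4 (lower-is-risk, reflecting
complement consumption) codes 4 iff v ≤ 0.05, 3 iff 0.05 < v ≤ 0.12,
2 iff 0.12 < v ≤ 0.20, 1 iff v > 0.20. `estimate_quartiles()` derives
cuts for new cohorts at the 25th/50th/75th percentiles
(linear-interpolation definition, `quantile(..., type = 7)`).

Activity (SLEDAI ≥ 8) is modeled by logistic regression on the two
codes and their product. The built-in reference coefficients are
$(\beta_0, \beta_1, \beta_2, \beta_3) = (-1.612, 0.361, 0.325, 0.093)$,
giving $z = 2.620$ and $P = 0.932$ at codes (4, 4) and $P = 0.303$ at
(1, 1). With all three slopes positive the 16 cell probabilities are
strictly increasing in each code and all distinct.

Three conventions in `evaluate_rules()` deserve justification:

* **Positivity is the rectangle rule** `code_D ≥ d* AND code_C ≥ c*`,
  not a threshold on P. The two differ: the 16 cell probabilities are
  not nested across rectangle rules (P(3,3) = 0.783 exceeds
  P(2,4) = 0.760, yet neither rule's positive region contains the
  other's), so a published cut-off table built from rectangle rules
  can legitimately violate the sensitivity monotonicity a pure
  probability threshold forces. A `rule = "probability"` mode is
  provided for the thresholded alternative.
* **Youden is reported as sensitivity + specificity**, matching the
  convention of the tabulated equation this model reproduces; the
  standard $J = \text{sens} + \text{spec} - 1$ is emitted alongside
  (`youden_j`).
* **Zero denominators report 0** (the all-inclusive rule has no test
  negatives, so NPV is reported as 0 and the row is flagged
  `degenerate`), rather than NA, again matching the tabulated
  convention.

The 16-cell odds-ratio grid (`or_grid()`) fits the activity label on
15 cell indicators against the lowest-risk reference cell (1, 1); ORs
are exponentiated coefficients with Wald 95% CIs (the CI method is a
package choice; profile CIs change nothing material at these n). Empty
non-reference cells are reported as NA, never dropped silently.

ROC machinery: `auroc()` computes the tie-corrected Mann–Whitney
AUROC (tied pairs count ½) and the threshold-sweep curve, whose
trapezoidal area equals the U-statistic exactly; markers that fall
with activity (C4, C3) use `direction = "lower_is_risk"`. Binary
comparison markers score as {0, 1}, so their ROC is the two-point
curve and their AUROC is (sens + spec)/2 — documented because they
are conventionally drawn on the same axes as continuous markers.
`compare_aurocs()` is a paired DeLong test on placement values;
comparing an ROC with itself returns difference 0 and p = 1.
`combined_score()` scores the two-marker combination by the equation's
predicted probability (equivalently z, by monotone invariance).

## The synthetic-cohort generators

The cohorts these methods were designed for are observational, so no
true data-generating process is available; the generators define one
in which the structural claims are literally true, making every
downstream behavior testable as parameter recovery.

**ELISA cohort (`gen_cohort2()`).** Latent pathway activations
$A_{\text{coag}}, A_{\text{comp}}, A_{\text{cyt}} \sim N(0,1)$ iid.
Analyte $a$ of pathway $p$ has lognormal concentration
$\exp(\mu + s_a \lambda A_p + \sigma \varepsilon)$ with $s_a = +1$ for
activators and $-1$ for inhibitors — so activator/inhibitor signs hold
by construction. The outcome is
$\text{ltSLEDAI} = \alpha + \beta_1 A_{\text{coag}} + \beta_2
A_{\text{comp}} + \beta_3 A_{\text{coag}} A_{\text{comp}} +
N(0, \sigma_\epsilon)$, and SLEDAI is $\max(1, \text{round}(e^{\text{ltSLEDAI}}))$
(the floor keeps the log transform defined; the integer rounding
mimics the discreteness of the clinical index and measurably does not
distort the interaction test's size). Defaults: n = 112 patients
(the ELISA cohort size this emulates), $\alpha = 2.1$ (median SLEDAI
near 10), $\beta_1 = 0.5$, $\beta_2 = 0.4$, $\sigma_\epsilon = 0.45$
(SLEDAI range roughly 1–45).

Two generator design choices were genuinely open:

* **The moderation switch conditions on the observed cytokine score,
  not the latent.** $\beta_3$ is 0.6 for patients above the median
  *observed* cytokine score and 0 below. Switching on the latent
  instead seems natural but makes the advertised subgroup property
  untestable: any realistic analyte noise makes the observed median
  split disagree with the latent split for 10–20% of patients, leaking
  interaction effect into the "low-inflammation" half, which then
  rejects far above nominal. Conditioning the switch on the same
  measured quantity the analysis splits on makes the generating
  subgroups identical to the analysis subgroups, so "interaction in
  the high half only" is exactly true.
* **The loading is mild** ($\lambda = 0.25$, analyte noise
  $\sigma = 0.4$, i.e. ~40% combined assay and biological CV). The
  summary score is a sum of *exponentials* of the latent; with strong
  loadings ($\lambda \approx 0.8$) that sum is visibly convex in
  $A_p$, the linear main-effect model fitted to the scores is
  misspecified, and the product-term test's type-I error inflates to
  ~0.11 at n = 112 (and ~0.10 in subgroups of 500). At
  $\lambda = 0.25$ the exponential is effectively linear over the
  latent's central range and the measured size is 0.052 (1000
  replicates, n = 112). This is a real lesson about the method, not
  only the simulator: composite scores built from strongly
  log-responsive analytes can manufacture spurious interactions in
  linear models. Absolute concentration scales are conventional
  ($\mu = 0$); max-normalization removes them.

**Clinical cohort (`gen_cohort3()`).** Quartile codes marginally
uniform on {1, 2, 3, 4} (a Gaussian copula supplies optional rank
correlation between the two codes, default 0 — real D-dimer and C4 are
plausibly correlated, but independence is the cleaner default for
parameter-recovery work); concentrations uniform within the coded
interval, the unbounded outer intervals closed at twice the outermost
cut (D-dimer top quartile (2.80, 5.60] µg/mL, C4 bottom-risk quartile
(0.20, 0.40] mg/mL — conventional widths, immaterial to anything
code-based); activity labels Bernoulli with the equation's cell
probability; SLEDAI drawn uniformly from 8–30 (active) or 0–7
(inactive) for consistency with the threshold; auxiliary C3 and
anti-dsDNA columns for ROC comparisons. A `cell_assignment =
"balanced"` mode cycles deterministically through the 16 cells (one
patient per cell at n = 16) for enumeration tests. Both generators are
deterministic given their seed and restore the caller's RNG state.

## Problem sizes and what the tests establish

The test suite verifies, among other things: exact reproduction of the
reference equation's worked example and all 16 cell probabilities;
recovery of all four logistic coefficients within 3 standard errors in
100/100 seeds at n = 20 000; simulated prevalence at n = 2025 within 3
binomial standard errors of the 16-cell analytic mean (0.6375);
type-I error 0.052 for the interaction test over 1000 replicates at
n = 112; and the high/low-inflammation significance pattern in 94% of
100 seeds at n = 1000. Property checks (normalization, bounds,
monotonicity, nested-rule monotonicity, AUROC-vs-U equivalence on 200
random instances) run on freshly generated inputs each time. These
sizes keep the default suite under half a minute while leaving the
stochastic assertions far from their thresholds.

Passing these tests shows the machinery is correct *under the
generator's assumptions*: lognormal analytes with a single latent per
pathway, independent latents, uniform independent quartile codes, a
hard moderation switch. Real cohorts differ in ways the simulator
deliberately omits: correlated pathway activations, analyte-specific
dynamic ranges and detection limits, plate effects, treatment effects
(DMARDs suppress both pathways), code correlation between D-dimer and
C4, and non-Bernoulli label noise in SLEDAI scoring. Published
coefficient values from real cohorts (regression slopes, correlations,
table sensitivities, AUROCs) therefore serve as qualitative anchors
only — the package asserts their *signs and patterns* on synthetic
data, not their magnitudes.

## Known limitations

* Scores are cohort-relative (max-normalization); cross-cohort score
  comparisons require a shared normalization, which the package does
  not impose.
* The LSD/Tamhane router inherits Levene's test's weakness in tiny
  cells; use the explicit `route` override there.
* `fit_equation()` treats the quartile codes as numeric 1–4 (the
  model's definition), so it cannot detect non-linear code effects;
  `or_grid()` is the saturated complement for that purpose.
* The DeLong comparison assumes paired designs; unpaired comparison is
  out of scope.
* No multiple-testing correction is applied across the many p-values a
  full run emits; that is a reporting decision left to the analyst.
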