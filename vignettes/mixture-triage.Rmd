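---
title: "Triage of formulated products and dose-addition mixture modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triage of formulated products and dose-addition mixture modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixtriage)
```

## The problem

A formulated plant-protection product (PPP) contains one or a few active
substances plus co-formulants — solvents, surfactants, emulsifiers —
whose systemic toxicity and, in particular, whose toxicokinetic
interactions with the active substances are rarely assessed. With on the
order of a thousand distinct co-formulants spread over ~1600 authorised
products, testing everything in vitro is not feasible. `mixtriage`
implements a two-part strategy:

1. **Rule-based prioritisation.** Aggregate in silico predictions
   (statistical QSAR alerts, expert-system likelihoods, ADME
   substrate/inhibitor calls) and formulation content into a short list of
   products that deserve in vitro follow-up.
2. **Mixture-effect assessment.** For a product's components, fit
   dose-response curves, predict the mixture's curve under concentration
   (dose) addition — the Loewe null model — and flag synergy or antagonism
   through the model deviation ratio (MDR).

Because real composition data are confidential, the package ships a
seeded synthetic-data generator that emulates the landscape with recorded
ground truth, so that every rule and every estimator can be validated end
to end.

## The prioritisation rules

**Two-source organ-toxicity score.** For each substance and endpoint
(hepatotoxicity, nephrotoxicity) two independent sources are combined:

* the *statistical* source reports binary alerts from a suite of
  sub-models (four hepatotoxicity sub-models, six nephrotoxicity
  sub-models); at least one positive alert contributes one point;
* the *expert* source reports an ordinal likelihood from
  `certain > probable > plausible > equivocal > doubted > improbable >
  impossible > inactive_or_no_alert > nothing_to_report`; any level of at
  least `equivocal` contributes one point.

The score is the sum, 0–2. A missing prediction and an explicit
`nothing_to_report` both contribute 0, but the output distinguishes them
for auditability. When one substance has several expert calls for an
endpoint, the strongest level wins.

**Content thresholds.** A product is flagged when it contains a score-2
co-formulant above 0.1% by mass, or a score-1 co-formulant above 10%.
Both comparisons are strict (`>`), matching the "exceeds" wording of the
underlying decision rule; a co-formulant at exactly the threshold does
not fire. Nephrotoxicity is scored but excluded from the default trigger
set because the available nephrotoxicity models have markedly lower
sensitivity than the hepatotoxicity ones; `endpoints =
c("hepatotoxicity", "nephrotoxicity")` re-enables it.

**Inhibitor–substrate pairing.** For each of CYP1A2, CYP2C9, CYP2C19,
CYP2D6, CYP3A4 and the efflux transporter P-gp, a product is flagged when
it simultaneously contains (i) a co-formulant predicted as an *in-scope*
inhibitor of the target with confidence strictly above 50%, present above
0.1% of the formulation, and (ii) an active substance predicted as an
in-scope substrate of the same target above 50% confidence. Out-of-scope
(outside the applicability domain) predictions never qualify. The
substrate side can be restricted to a supplied list of hepatotoxic active
substances (a cumulative assessment group); by default all active
substances qualify. The 0.1% content condition is implemented as a
configurable filter (`frac_min`).

**Sales ranking.** Per co-formulant, annual tonnage is product sales (kg)
times the co-formulant's mass percent, summed over products; entries
sharing a CAS number are one co-formulant. Products containing one of the
top-`n` (default 10) sellers are flagged. Ties are broken by CAS in
lexicographic order — an arbitrary but deterministic rule, chosen so
reports are byte-reproducible.

**Merge.** Calls are concatenated; the summary counts unique products per
trigger and overall (a product with several triggers counts once).

## Dose-response models

All fitting is ordinary least squares on untransformed % viability.
Concentrations are mg/L throughout; no molar conversion is attempted. Two
four-parameter families share one parameter vocabulary:

* exponential: $y = a\,[c - (c - 1)\,e^{-(x/b)^d}]$
* Hill: $y = a\,[1 + (c - 1)\,x^d/(b^d + x^d)]$

with $a$ the response at zero dose, $a\,c$ the asymptote at infinite dose
($c < 1$ for declining viability, $c > 1$ for activation), $b > 0$ a
potency scale in mg/L and $d > 0$ a shape exponent. The Hill form was
fixed so its parameters mean the same thing as the exponential ones. Per
treatment both families are fitted and the lower AIC wins, using the
Gaussian profile form $n \ln(\mathrm{RSS}/n) + 2k$ (valid for comparing
fits on identical observations); an exact tie prefers the exponential.

The EC50 — the dose giving 50% of the zero-dose response — has closed
forms: $b\,(-\ln\frac{c-0.5}{c-1})^{1/d}$ (exponential) and
$b\,(\theta/(1-\theta))^{1/d}$ with $\theta = 0.5/(1-c)$ (Hill). Both
require $c < 0.5$; otherwise the 50% level is unreachable and the fit
carries no EC50 (activation curves are a legitimate example).

For enzyme-inhibition readouts the package also fits the four-parameter
logistic on $X = \log_{10}$ concentration,
$Y = \mathrm{Bottom} + (\mathrm{Top}-\mathrm{Bottom})/(1 +
10^{(\mathrm{LogIC50} - X)\,\mathrm{HillSlope}})$, the parameterisation
of common plate-reader software, and reports $\mathrm{IC50} =
10^{\mathrm{LogIC50}}$. Zero-dose controls cannot be placed on the log
axis and are excluded from this fit only.

### Numerical choices

* **Initialisation.** Deterministic multi-start: $a$ at the control mean,
  $b$ at the geometric mean of the positive doses, $c \in \{0, 0.25\}$,
  $d \in \{0.5, 1, 2, 4\}$ (eight starts); best RSS wins. The 4PL starts
  span HillSlope $\in \{\pm 0.5, \pm 1, \pm 2\}$ so both orientations are
  covered. No start uses the data's random order, so refits are
  bit-reproducible.
* **Optimiser.** Levenberg–Marquardt (`minpack.lm::nlsLM`) with box
  constraints ($b \ge 10^{-9}$, $d \ge 10^{-3}$, $|c| \le 10$); where the
  LM implementation cannot finalise (exact zero-residual optima), a
  port-constrained Gauss–Newton pass and finally a direct L-BFGS-B
  minimisation of the RSS take over. The `converged` flag reports the
  optimiser's own verdict, never a guess.
* **Preconditions.** At least five distinct positive concentrations (four
  parameters plus one); all-constant responses are rejected as degenerate
  rather than "fitted".
* **Error model.** Independent, homoscedastic Gaussian residuals on %
  response. Viability data are often mildly heteroscedastic; with eight
  doses and three replicates the unweighted fit is the standard pragmatic
  choice, and the parameter-recovery simulations below quantify what it
  delivers.

## Concentration addition and the model deviation ratio

The mixture question is asked against Loewe additivity: components act as
dilutions of one another, so at a given effect level the total dose $D$
with mass fractions $\pi_i$ satisfies $\sum_i \pi_i D / \mathrm{ED}_i =
1$.

The package's primary construction is the **parallel-curve** special
case: all components are fitted *jointly* with shared $(a, c, d)$ and
component-specific potency scales $b_i$ (`fit_parallel_components()`).
Under that relative-potency assumption the dose-addition mixture curve is
again the shared-shape model with

$$b_\mathrm{mix} = \Big(\sum_i \pi_i / b_i\Big)^{-1},$$

the $\pi$-weighted harmonic combination, and its EC50 follows from the
closed form. Whether the shape parameter should be shared across
compounds is a genuine modelling choice; sharing all of $(a, c, d)$ is
what makes the theoretical mixture curve well-defined, and the joint fit
makes the assumption visible in its residuals rather than hiding it.

A general solver, `loewe_effective_dose()`, inverts arbitrary monotone
fitted curves numerically and combines them by the same harmonic rule.
It exists purely as an independent oracle: for parallel curves it must
agree with the closed-form construction (the test suite checks 21
response levels to $10^{-6}$ relative), and sham mixtures — a compound
mixed with itself at any split — must reproduce the single-compound
curve to $10^{-9}$.

The observed mixture data are fitted like any single treatment (AIC
selection included) and compared through the **model deviation ratio**

$$\mathrm{MDR} = \mathrm{EC50}_\mathrm{predicted} /
\mathrm{EC50}_\mathrm{observed}.$$

MDR > 2 is called `more_than_additive` (synergy; the observed points lie
left of the theoretical curve), MDR < 0.5 `less_than_additive`
(antagonism; right-shifted), otherwise `additive`. The factor-2 threshold
operationalises what is otherwise a visual left/right-shift judgement; it
is the conventional MDR band in mixture toxicology and is configurable
(`mdr_threshold`).

## What the synthetic generator emulates — and what it does not

`gen_landscape()` draws a registry (co-formulants with CAS, optional
SMILES, duplicate CAS entries, structureless substance classes), product
sales (log-normal, heavy right tail so a handful of co-formulants
dominate tonnage, qualitatively like real inventories where water and
bulk solvents lead), and compositions whose co-formulant fractions are
log-uniform between 0.02% and 40% — deliberately straddling the 0.1% and
10% decision thresholds so the rules are actually exercised. Truth rates
for the prediction sources (10% statistical / 3.5% expert hepatotoxicity
positives, 5% / 8% for nephrotoxicity, per-target inhibitor rates of
0.2–4% and substrate rates of 1.5–20%) were chosen once to resemble the
flagged fractions commercial batteries report on inventories of this
kind. `gen_prediction_tables()` then observes those labels with
configurable sensitivity/specificity; at 1/1 the tables encode the truth
exactly, which is what makes exact end-to-end truth recovery a testable
property rather than a statistical statement.

Synergy is injected as a potency multiplier $s \ge 1$ on the mixture's
effective dose — a toxicokinetic stand-in for, e.g., CYP inhibition
raising internal exposure. It is the simplest mechanism whose MDR is
analytically known: the observed EC50 is the additive EC50 divided by
$s$, so a noiseless dataset has MDR exactly $s$, and $s = 1$ reproduces
dose addition exactly. Real deviations need not follow this pattern
(dose-level-dependent interactions, response-surface effects), so a
passing power test shows the pipeline detects *this* kind of synergy at
the stated noise — not that every interaction type would be found.

The generator does **not** imitate real chemical structures (SMILES are
opaque tokens), real QSAR model internals, correlated prediction errors,
or heteroscedastic plate effects. Conclusions about those require real
data.

## Problem sizes used in the tests

The default landscape (1603 products, 1048 co-formulants, 250 active
substances) runs the full simulate–prioritise cycle in a few seconds, and
the test suite uses it for the scale checks; parameter-recovery and power
simulations use 100 seeded runs of the standard 8-doses × 3-replicates
design (noise sd 5% viability; sd 3 for the 4PL), which reproduces the
regression values recorded in the acceptance tests: median relative error
on $b$ around 5%, median $|\mathrm{LogIC50}|$ error around 0.02, synergy
at $s = 3$ detected in 100/100 runs with 0/100 false positives at
threshold 2.

## Known limitations

* The parallel-curve CA construction is only as good as the shared-shape
  assumption; strongly non-parallel components should be handled through
  `loewe_effective_dose()` on separately fitted curves, at the price of a
  numerically inverted (not closed-form) mixture curve.
* No bootstrap or profile confidence intervals on EC50s and MDRs in this
  version; the classification is a point decision at the MDR threshold.
* The MDR threshold of 2 is a convention, not an inferential statement;
  near-threshold calls deserve replication rather than belief.
* Sales aggregation keys on CAS; a substance marketed under several CAS
  numbers will count as several co-formulants, exactly as in the
  registry-based workflow the package mirrors.
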