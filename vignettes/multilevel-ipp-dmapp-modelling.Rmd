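---
title: "Multilevel kinetic modelling of IPP/DMAPP biosynthesis in engineered rice"
author: "mvamep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel kinetic modelling of IPP/DMAPP biosynthesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvamep)
```

# The modelling problem

Isopentenyl diphosphate (IPP) and dimethylallyl diphosphate (DMAPP) are the
two C5 monomers from which all plant terpenoids are polymerized. Rice makes
them through two compartmentally separated routes: the cytosolic mevalonate
(MVA) pathway from acetyl-CoA via HMG-CoA, mevalonate, MVP and MVPP, and the
plastidic methylerythritol 4-phosphate (MEP) pathway from G3P and pyruvate
via DXP, MEP, CDP-ME, CDP-MEP, MEcPP and HMBPP. Engineered lines add a third
route: a plastid-targeted ectopic MVA pathway in three increasingly complete
versions (Type I: HMGR alone; Type II: plus HMGS and MVK; Type III: plus PMK
and MVD, which completes the chain to plastid IPP).

`mvamep` implements the full multilevel analysis around these systems:
variant-specific kinetic ODE models, personalization from per-line gene
expression, steady-state stability and logarithmic sensitivity analysis,
minimal-intervention stabilization, phenomenological hormone coupling, and
linear phenotype prediction, together with a deterministic synthetic-data
generator so that every stage is testable end to end.

# The kinetic formalism

Every process (enzymatic step, compartment exchange, sink) uses one
saturating rational rate law

$$v \;=\; \frac{V \prod_i x_i}
  {\prod_i (K_i + x_i) \;+\; \prod_b (x_b + K_b)},$$

with saturation rate constant $V$ (mM per model-time unit), substrate
concentrations $x_i$ with apparent binding constants $K_i$, and optional
inhibitors $x_b$ with binding constants $K_b$. The formalism saturates to
$V$, is monotone decreasing in each inhibitor, and its parameters read like
classical enzyme kinetics.

**Empty-inhibitor convention.** When a reaction has no inhibitors the second
denominator product is omitted entirely (not replaced by 1), so a
one-substrate law is exactly Michaelis–Menten, $v = Vx/(K+x)$. This
preserves the classical-kinetics interpretation of the parameters; the
alternative (keeping a constant 1 in the denominator) would make every law
sub-Michaelis even in the absence of inhibition.

Each dynamic metabolite pool then obeys
$dM_i/dt = \sum_j f_j - \sum_k f_k$ over its producing and consuming fluxes,
stoichiometry-weighted. Acetyl-CoA, acetoacetyl-CoA, G3P and pyruvate are
treated as homeostatically fixed: they enter rate laws but never acquire an
equation. The wild-type system has 14 state variables; Types I, II and III
have 16, 17 and 18 (adding plastid HMG-CoA and MVA, then MVP, then MVPP).

# Calibration of the basal parameter set

No kinetic constants are available for these pathways in rice, so the
package calibrates its own basal set against the published wild-type
steady-state concentration table, under an explicit flux design:

* the MVA chain carries 1 flux unit, the MEP chain 2 (the plastid route is
  the dominant IPP/DMAPP source in seeds);
* HDR splits its HMBPP flux 70/30 between IPP and DMAPP;
* IPP and DMAPP exchange across the plastid envelope with the export
  (plastid to cytosol) $V$ exactly ten-fold the import $V$, implementing
  the observed one-way-symport asymmetry;
* sink reactions (the downstream polymerases, modelled deliberately as
  simple single-substrate saturating drains) close every balance.

Binding constants are set relative to the basal concentration of each
substrate: $K = 3x^*$ for enzymatic steps (quarter saturation, i.e.
four-fold capacity reserve at the operating point), $K = x^*$ for
transporters, and $K = 9x^*$ for sinks (first-order regime, ten-fold
reserve — downstream consumption is far from saturated in vivo). Given the
K's, every $V$ is solved so the published concentrations are an *exact*
steady state of the design fluxes. The synthetic calibration mode
(`generateParameterSet`) samples the K's log-uniformly within a factor of
two of these defaults and re-solves the V's, rejecting draws whose model is
not stable; provenance is recorded (`calibrated` vs `synthetic`) on the
model and in every report.

The four-fold enzymatic capacity reserve is a deliberate choice: with only
two-fold reserve ($K = x^*$), the ectopic flux returning from the plastid in
Type II saturates the lower MVA chain and the basal Type II model has no
steady state — a numerical artifact of calibration, not a biological claim.

Ectopic reactions copy the kinetic parameters of their endogenous
counterparts; a line's exogenous expression ratio (activity relative to the
endogenous enzyme's basal activity) then scales them. MVA-intermediate
exchanges (HMG-CoA, MVA, MVP, MVPP) run at 1% of the corresponding pathway
$V$ ("very slow"), with one exception: the *terminal* pool of a truncated
ectopic chain (MVA in Type I, MVP in Type II) has the exchange as its only
outlet, so that exchange carries the full reference $V$. Without this, any
Type II model would diverge in plastid MVP no matter what the MEP-side scan
does — contradicting the observation that only DXP, CDP-MEP and MEcPP
accumulate.

# Line personalization

Changes in gene expression are assumed proportional to changes in enzyme
activity: `scaleLine` multiplies the $V$ of every gene-tagged reaction by
the line's expression ratio for that gene. Exchanges and sinks carry no
gene tag and are untouched. Type-level "median models" use the per-gene
median expression across a type's lines (even counts: mean of the two
middle values; a hormone is flagged censored in the median line only when
more than half the lines are censored).

# Steady states, stability, sensitivities

`findSteadyState` runs a damped Newton iteration with the analytic Jacobian
(positivity-preserving step control), falling back to integration towards
quasi-stationarity (deSolve/lsoda, relative tolerance 1e-9) followed by a
Newton polish. Residual tolerance is 1e-8 mM per model-time unit in the
infinity norm. Divergent systems return a non-converged result carrying the
accumulating pools — those exceeding 1000 times basal within the integration
horizon ($t \le 10^4$) or still growing monotonically over its final decade.

The Jacobian is assembled analytically from the rational rate laws and is
validated against central finite differences (relative step 1e-6) in the
test suite. A state is stable exactly when all eigenvalue real parts are
negative.

Logarithmic sensitivities $S_{ij} = \partial\log X_i / \partial\log p_j$ are
computed by *re-solving* the steady state at log-centred relative
perturbations $p(1+\delta)$ and $p/(1+\delta)$ with $\delta = 1\%$, not by
local linearization; entries whose perturbed system loses stability are
excluded from aggregates with a warning. The aggregate indices divide the
Euclidean norm of each column (row) by the number of metabolites
(parameters) — norm over count, not root-mean-square — which is what makes
the indices comparable across variants whose state and parameter counts
grow from 14 to 18 and beyond.

# Stabilization by minimal Vmax intervention

Personalized mutant-line models typically lose their steady state, with DXP,
CDP-MEP, MEcPP or combinations accumulating. Emulating post-transcriptional
up-regulation, `scanStabilizingVmax` scans multipliers $2^k$,
$k \in \{-3,\dots,6\}$, over all 1-D, 2-D and 3-D subsets of the V's of the
three consuming steps (DXR, MDS, HDS), pools every stable grid point, and
`selectMinimalChange` picks the candidate with minimal normalized distance —
the Euclidean norm of the log2 multipliers divided by $\sqrt{\#\text{scanned
axes}}$ — with ties broken by fewest changed parameters, then
lexicographically. An unstable model with no stable grid point returns an
explicit empty candidate set; this genuinely occurs when a cohort's DXS
induction pushes the MEP influx beyond HDR's total capacity, which no
multiplier on the three scanned axes can repair.

# Hormone coupling

For each (hormone, response) pair with at least four detected lines, an
ordinary least-squares fit of $\log_{10}$ response on $\log_{10}$ hormone
estimates the exponent $g$; only pairs with slope p < 0.05 are kept (no
multiple-testing correction, logged in the reports). The formalism is chosen
by the ratio $|R^2_{adj}/g|$: strictly above 0.5 selects the power law
$\alpha H^g$ (fewer parameters), the boundary and below select the
saturating form $\alpha (H/(K+H))^g$ with $K$ set to the median observed
level. $\alpha$ anchors the multiplier to 1 at the reference (median/WT)
hormone level, so coupling never moves the basal model at reference
conditions. Hormones below the detection limit contribute a factor of
exactly 1 — the piecewise reversion to basal kinetics.

Gene links multiply the reactions tagged with the gene. Metabolite links
multiply the *producing* reactions only: applying the same factor to
production and consumption cancels at steady state and would make the
sign-validation exercise vacuous. Validation sweeps each linked hormone over
its observed range on the coupled median model and compares the simulated
correlation sign with the fitted one; sweeps that lose stability count as
ambiguous.

# Phenotype models

Forward stepwise regression builds each phenotype predictor
$\hat y = \beta_0 + \sum\beta_i x_i$: single-predictor fits gated at
significance 0.05 and adjusted $R^2 > 0.2$; best candidate by adjusted
$R^2$, with "similar" values (within 0.02) resolved by lowest AICc (within
2, back to $R^2$); extensions exclude predictors pairwise-collinear with an
included one ($|r| \ge 0.7$) and stop when the adjusted $R^2$ gain drops
below 0.02 or the new coefficient is not significant. Leaf-count models
round their predictions. The transcribed published models are shipped as
`shippedPhenotypeModels()`; leaf area is estimated as
$0.75 \times \text{length} \times \text{width}$.

The multilevel chain (`predictLinePhenotype`) personalizes the kinetic
model, stabilizes it if needed, takes metabolite predictors from the model
steady state (not from measurements), gene and hormone predictors from the
line profile, and evaluates each phenotype model; metabolite-dependent
responses of lines whose model cannot be stabilized are reported
unpredictable.

# What the synthetic generator emulates

The generator reproduces the statistical structure the analysis assumes,
with cohort sizes 12/10/12 for Types I/II/III:

* endogenous expression ratios log-normal (log-SD 0.3) around type-level
  medians in which DXS is induced and the later MEP steps DXR, MDS and HDS
  are repressed, increasingly from Type I to Type III — the configuration
  that destabilizes the line models in exactly the DXP/CDP-MEP/MEcPP pools
  and makes Types II and III require larger stabilizing changes than Type I;
* exogenous transgene activity log-normal around 0.5 with a shared per-line
  integration effect (log-SD 0.5) plus per-gene noise (0.33), present only
  in the matching variant;
* the eleven-hormone panel log10-normal (SD 0.2) with detection limits for
  GA3 and GA4 producing realistic censoring; censored levels are recorded at
  the limit and flagged;
* planted hormone-to-gene power laws (iP on the early MEP steps, ABA on
  MCT) acting multiplicatively on expression;
* phenotypes from planted linear models plus Gaussian noise calibrated to a
  target $R^2$ (defaults around 0.5–0.7, the published range), leaf counts
  rounded.

Everything is deterministic under the config seed. What the generator does
*not* emulate: transformation biology (integration-site effects beyond a
shared line factor), endosperm-specific expression programs, measurement
error correlation between hormones, or any transcriptional feedback from
the pathway onto gene expression. Passing recovery tests therefore shows
the pipeline's statistical machinery is sound under its own assumptions,
not that those assumptions hold in real rice data.

# Problem sizes and numerical choices

The test suite and examples run the full variant models (14–18 states,
23–36 reactions), sensitivity matrices over all V and K parameters
(~50–70 per model), full three-axis stabilization scans (1330 grid points),
and recovery studies of 200 replicates at 30 lines each; the complete suite
runs in a few minutes on one CPU. Tolerances: steady-state residual 1e-8,
integration relative tolerance 1e-9, sensitivity perturbation 1%, Jacobian
validation 1e-6.

# Known limitations

* The basal parameter set is calibrated, not measured; only the wild-type
  steady state is pinned to the published concentrations, so absolute mutant
  concentrations and eigenvalue magnitudes are in model-time units and not
  directly comparable to the published eigenvalue table.
* The stabilization scan is grid-only (as in the original procedure); the
  chosen multiplier is minimal on the grid, not continuously optimal.
* Hormone coupling is phenomenological; no causal claim is made, and a
  hormone-to-gene link affects all reactions tagged with that gene.
* Cohorts whose median expression pushes the MEP influx beyond HDR capacity
  are reported honestly as unstabilizable rather than forced stable.
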