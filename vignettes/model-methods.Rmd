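---
title: "Methods: a decision-tree cost-effectiveness model of thromboprophylaxis for cesarean delivery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a decision-tree cost-effectiveness model of thromboprophylaxis for cesarean delivery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vtecea)
```

## The decision problem

Cesarean delivery raises the risk of venous thromboembolism (VTE): deep
vein thrombosis (DVT) and, conditionally on DVT, pulmonary embolism (PE).
Pharmacological prophylaxis with low-molecular-weight heparin (LMWH)
lowers the VTE risk but raises bleeding risk; intermittent pneumatic
compression (IPC) is a mechanical alternative with no bleeding risk that,
worn intraoperatively, also reduces spinal-anesthesia hypotension. From a
hospital payer perspective, over the in-hospital horizon of two to three
days, which of no prophylaxis, IPC, or LMWH is the cost-effective choice?

The short, non-recursive horizon makes a decision tree the right model
class; no discounting is applied. Delivery costs common to all arms are
excluded; only prophylaxis costs and adverse-event management costs enter.

## Tree structure and payoffs

Each strategy's tree is the product of two chance nodes:

1. **Intraoperative**: hypotension with probability `p_hypo`, adding the
   hypotension management cost. Hypotension is an intermediate event: it
   contributes cost in every arm but never reduces effectiveness.
2. **Postoperative** (mutually exclusive): DVT with probability `p_dvt`
   (with a nested PE branch at `p_pe_given_dvt`), minor bleed, major
   bleed, or no adverse event as the complement
   `1 - p_dvt - p_minor - p_major`. If that complement would be negative
   the node is structurally invalid and the model stops with an error.

This yields 10 terminal pathways per strategy. The effectiveness payoff is
1 exactly on the no-adverse-event pathways, so expected effectiveness is
the probability that a patient avoids every VTE-related adverse event.
Expected values are computed by probability-weighted summation
("rollback") over the pathways.

Three structural choices were genuinely open and are resolved as follows:

* **PE costing is incremental.** A DVT-with-PE pathway accrues the DVT
  management cost plus the PE cost, since PE evolves from an initially
  managed DVT. The alternative (PE cost replacing DVT cost) changes base
  case costs by about 1% and was not adopted.
* **Independence of the two nodes.** No joint distribution of
  intraoperative and postoperative events is available, so they are
  modelled independent. Hypotension management cost therefore enters every
  strategy scaled by that strategy's hypotension probability.
* **Mortality is a secondary output.** The PE case-fatality input
  (0.0026) has no stated attachment point in the published tree, and
  non-adverse-event mortality is assumed zero over the horizon. We report
  expected deaths as `p_dvt * p_pe_given_dvt * p_mortality` per patient;
  death pathways accrue no extra cost and do not alter effectiveness, so
  this input cannot move any cost-effectiveness conclusion.

## Inputs

All inputs live in a single validated parameter set
(`default_parameters()`), with probabilities stored as fractions, costs in
2021 Brazilian Real, and relative risks unitless. Where a source provides
no variance, a ±10% range around the point value is generated
(mortality and hypotension probabilities; minor-bleed, major-bleed, LMWH
and IPC costs); these auto-ranges follow the value if it is overridden in
a configuration file. Ranges are interpreted as 95% intervals — the
reporting convention of the cited meta-analyses — which fixes the standard
deviation used by the probabilistic analysis at `(high - low) / 3.92`.

Strategy effects are multiplicative: LMWH scales the DVT, minor-bleed and
major-bleed baselines by its relative risks; IPC scales the hypotension
baseline by the limb-compression relative risk and the DVT baseline by
`rr_lmwh_dvt * rr_ipc_vs_lmwh_vte`. The chained composition is forced by
the available evidence — only an IPC-versus-LMWH relative risk exists, not
IPC-versus-nothing — and is applied to the DVT probability only, with
PE scaling through it, because PE arises only via DVT in the tree. Every
product is clamped to [0,1], which matters only for extreme probabilistic
draws (clamps are counted and reported, never silent).

```{r base-case}
params <- default_parameters()
results <- lapply(all_strategies(params),
                  function(s) build_and_rollback(params, s))
incremental_table(results)
```

### A known irreproducibility

The published version of this model reports an LMWH expected cost of
R$1,301 and effectiveness of 0.861. Neither is recoverable from the
published input table under any tree structure we tried: the inputs imply
a minor-bleed probability of `0.068 × 2.12 = 0.144` alone, capping LMWH
effectiveness near 0.83, and a correspondingly higher cost (about R$1,504).
The no-prophylaxis and IPC rows *are* reproduced to within rounding. We
keep the declared structure and the published inputs rather than
reverse-fitting hidden parameters, and document the discrepancy; the
IPC-versus-no-prophylaxis ICER is likewise sensitive to the unpublished
node arithmetic behind the printed increments. The qualitative
conclusions — IPC cost-effective versus no prophylaxis at the R$15,000
threshold, LMWH dominated — are unaffected.

## Deterministic sensitivity analyses

**One-way (tornado).** Each input in turn is set to the ends of its range
with all else at base. Two outcome metrics are exposed, matching the two
published tornado figures: the cost difference of IPC versus LMWH (or
versus no prophylaxis), and the IPC-versus-no-prophylaxis
cost-effectiveness ratio. For the latter we report the *signed* ratio
`ΔC/ΔE`: at high VTE incidence IPC becomes dominant and a conventional
ICER is undefined, while the signed ratio stays continuous (negative =
dominant) and preserves the ranking by swing. The baseline DVT probability
(range 0.001–0.03) is by far the largest driver.

**Threshold.** The break-even baseline VTE incidence — where IPC's
expected cost equals no prophylaxis's — is found by bisection to an
absolute cost tolerance of 1e-6 R$ (the difference is linear in `p_dvt`,
so bisection is exact to machine limits; a grid scan cross-checks it). The
x-axis quantity is the baseline DVT probability, the tree's entry VTE
event, reported as a percentage.

**Scenario.** IPC worn intra+post (base case), post-only (hypotension at
baseline), intra-only (DVT at baseline). The device cost is the same
per-patient R$102 in all three phases: the published scenario cost
ordering is consistent with a fixed per-use device cost, and no
phase-specific pricing is published. Effectiveness is identical for
intra+post and post-only (VTE protection is purely postoperative) and
equals the no-prophylaxis value for intra-only.

## Probabilistic sensitivity analysis

Distributions are assigned by measurement type — beta for probabilities,
gamma for costs, lognormal for relative risks — and fitted so that:

* beta and gamma match the point value as their **mean** and
  `(high - low)/3.92` as their standard deviation (method of moments);
* lognormal takes the point value as its **median** with
  `sdlog = (log high - log low)/3.92`, reflecting the log-scale symmetry
  of relative-risk confidence intervals. The lognormal mean therefore
  exceeds the point value — a deliberate, documented skew, which is why
  PSA mean costs for IPC and LMWH sit above their deterministic values.

A zero-width range degrades to a point mass rather than an error, so a
cost overridden to zero remains usable. The PE case-fatality input is held
fixed (it feeds only the secondary deaths output), leaving 17 sampled
quantities. Each of the 1,000 draws (the published iteration count;
reproducible from a single seed) samples one parameter vector, applies it
to **all three strategies** (common random numbers), and rolls back the
tree. Two guards act at extreme draws: individual probability products are
clamped to [0,1], and if the three postoperative probabilities jointly
exceed 1 the draw is proportionally renormalized; both events are counted
and reported on the PSA object (typically a handful per 1,000 draws, all
traceable to the very wide DVT relative-risk interval 0.01–7.93).

Summaries follow standard practice: the incremental cost-effectiveness
plane with the superiority quadrant proportion and a 95% confidence
ellipse (mean and covariance of the incremental pairs with the chi-square
0.95 quantile, 2 df; axes verifiable by independent eigendecomposition),
and the acceptability curve as the fraction of draws in which each
strategy attains the maximum net monetary benefit
`NMB = λE - C`, ties split equally, over a default willingness-to-pay grid
of 0–30,000 R$ in steps of 500 (bracketing the R$15,000 threshold; the
published figure does not state its axis range). "Superiority" in the
plane (strictly cheaper and more effective) and acceptance at the
threshold are different summaries; both are emitted and labelled.

## The microsimulation check

`simulate_cohort()` draws individual patients through the same tree:
Bernoulli hypotension, a single-uniform categorical draw for the
postoperative event with fixed ordering (DVT, minor, major, none),
Bernoulli PE within DVT, Bernoulli death within PE. Each stage consumes a
fixed-length block of `n` uniforms, so streams are reproducible across
platforms from a seed; the category ordering is documented because it
affects stream consumption. Per-patient costs are exactly the pathway
costs, so cohort means converge to the rollback expectations — the test
suite checks agreement within three standard errors at 200,000 patients
per strategy, which bounds any systematic discrepancy at about 0.2% of the
effectiveness scale. The generator emulates the model's homogeneous
theoretical cohort; it does not emulate patient covariates, risk
stratification, correlated events, or real-world coding noise, so passing
tests validate internal consistency of the model, not the external
validity of its inputs.

## Numerical and testing choices

* Problem sizes: 1,000 PSA draws per run (10-seed sweeps for stochastic
  summaries), 200,000 microsimulated patients per strategy for the
  convergence checks, 50-point threshold grids. These choices keep any
  full run in seconds-to-a-minute on one core.
* Configuration files are flat `key = value` text, written at full double
  precision (15 significant digits, widened to 17 when needed for an exact
  round trip), so parameter sets are diffable and reload bit-exactly.
* Result CSVs are byte-stable across reruns at a fixed seed; each output
  directory carries a manifest recording command, seed and version.
* Degenerate inputs have defined behaviour throughout: zero-probability
  trees collapse to the prophylaxis cost, equal-cost-equal-effect
  strategies are flagged as ties without an ICER, degenerate PSA
  covariance is flagged rather than silently inverted, and a threshold
  bracket without a sign change is an error naming the bracket.

## Limitations

Beyond the published model's own assumptions (mutually exclusive
postoperative events, zero non-event mortality, no long-term sequelae such
as post-thrombotic syndrome, maternal outcomes only), the package inherits
the evidence gaps of its inputs: the IPC-versus-LMWH relative risk comes
from non-obstetric surgery and carries an extremely wide interval, and the
LMWH row of the published results is not reproducible from the published
inputs (see above). Two-way sensitivity analysis, QALY outcomes, and
value-of-information analysis are out of scope.
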