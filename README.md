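# vtecea

Decision-analytic cost-effectiveness model of thromboprophylaxis for
cesarean delivery, from a Brazilian hospital perspective. The package
compares three strategies for preventing venous thromboembolism (VTE) in a
theoretical cohort of cesarean-delivery patients over the in-hospital
horizon (two to three days):

* **no prophylaxis**,
* **IPC** — intermittent pneumatic compression, a mechanical prophylaxis
  that also reduces intraoperative hypotension during spinal anesthesia,
* **LMWH** — low-molecular-weight heparin, a pharmacological prophylaxis
  that carries bleeding risk.

It is intended for health-economics analysts who want a scriptable,
testable version of this class of decision-tree model: every input,
assumption, and analysis step is an R function with a documented contract,
rather than nodes in a proprietary GUI model.

## The model

Each strategy is a two-stage decision tree. An intraoperative chance node
gives hypotension with probability `p_hypo` (adding its management cost
`c_hypo`; hypotension is an intermediate event, not a counted adverse
event). A mutually exclusive postoperative chance node gives deep vein
thrombosis (DVT) with probability `p_dvt` — with a nested pulmonary
embolism (PE) branch at `p_pe|dvt`, whose cost is incremental to the DVT
cost — minor bleeding, major bleeding, or no adverse event as the
complement. Strategy effects enter through relative risks applied to the
no-prophylaxis baselines; IPC's DVT effect is the product of the LMWH
relative risk and the IPC-versus-LMWH relative risk, the only composition
the source inputs permit.

Expected cost per patient and expected effectiveness
(`E = Pr(no VTE-related adverse event)`) come from probability-weighted
summation over the 10 terminal pathways. Strategies are compared by the
incremental cost-effectiveness ratio

    ICER = (C1 - C2) / (E1 - E2)   [R$ per adverse event avoided]

against a willingness-to-pay threshold of R$15,000 per adverse event
avoided, with strong and extended dominance handled on the efficiency
frontier. Uncertainty is explored by one-way (tornado) analysis, a
threshold analysis on the baseline VTE incidence, an IPC phase scenario
analysis, and probabilistic sensitivity analysis (PSA): beta distributions
for probabilities, gamma for costs, lognormal for relative risks, each
fitted to the input's point value and 95% range, propagated over 1,000
Monte Carlo draws and summarized as cost-effectiveness planes and
acceptability curves (CEAC). A patient-level microsimulation
(`simulate_cohort()`) provides an independent brute-force check of the
analytic rollback.

## Worked example

```r
library(vtecea)

params <- default_parameters()          # the model's published input set
results <- lapply(all_strategies(params),
                  function(s) build_and_rollback(params, s))
incremental_table(results)
#>         strategy expected_cost expected_effectiveness incremental_cost
#> 1 no_prophylaxis      920.2122              0.9110000               NA
#> 2            IPC      951.3595              0.9159903          31.1473
#> 3           LMWH     1503.5312              0.8328100         552.1717
#>   incremental_effectiveness     icer    status
#> 1                        NA       NA reference
#> 2                 0.0049903 6241.569  frontier
#> 3                -0.0831803       NA dominated
```

No prophylaxis is the cheapest strategy (R$920 per patient, 91.1% of
patients free of any VTE-related adverse event). IPC costs R$31 more and
avoids adverse events in an extra 0.50% of patients, an ICER of about
R$6,242 per adverse event avoided — well under the R$15,000 threshold, so
IPC is cost-effective. LMWH is dominated: more expensive than both
alternatives and less effective, because its bleeding risk outweighs its
VTE protection at these baselines.

```r
threshold_vte_incidence(params)
#> IPC and no prophylaxis have equal expected cost at a baseline VTE
#> incidence of 1.0751%; no_prophylaxis cheaper below the crossing, IPC cheaper above

psa <- run_psa(params, n = 1000, seed = 1)
ce_plane_summary(psa, comp = "IPC", ref = "LMWH")
#> CE plane, IPC vs LMWH:
#>   superior (cheaper & more effective) in 85.6% of draws
#>   acceptable at WTP R$15,000 in 94.9% of draws
```

A full run — base case, both tornado analyses, threshold, scenario, PSA
and CEAC, written as CSVs with a manifest — is one call:

```r
run_full_analysis(params, "results-dir", seed = 1)
```

or, from a shell, `Rscript inst/scripts/vtecea.R all --out results-dir`.
Custom inputs go through a plain-text configuration file
(`write_parameters()` / `load_parameters()`); keys are the canonical
parameter names shown by `print(default_parameters())`, e.g. `c_ipc = 80`
or `p_dvt_baseline.value = 0.012`.

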