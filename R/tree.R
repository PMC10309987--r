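#' Enumerate decision-tree pathways for one strategy
#'
#' Expands the per-strategy decision tree into its terminal pathways. The
#' tree has an intraoperative chance node (spinal-anesthesia hypotension,
#' which adds the hypotension management cost but is not counted as a
#' thromboprophylaxis-related adverse event) followed by a mutually exclusive
#' postoperative chance node: DVT (with a nested PE-given-DVT branch), minor
#' bleed, major bleed, or no adverse event as the complement. A DVT pathway
#' accrues the DVT management cost; a DVT-with-PE pathway additionally
#' accrues the PE cost (PE evolves from DVT, so its management is
#' incremental). Every pathway carries the strategy's prophylaxis cost. The
#' effectiveness payoff is 1 exactly on the no-adverse-event pathways.
#'
#' @param probs A `vte_event_probs` object from [resolve_strategy()].
#' @param params A `vte_params` object supplying the unit costs.
#' @return A data frame with 10 rows (2 intraoperative x 5 postoperative
#'   outcomes) and columns `strategy`, `phase`, `intraop_label`,
#'   `postop_label`, `probability`, `cost`, `effectiveness`, in a fixed
#'   deterministic order.
#' @export
enumerate_pathways <- function(probs, params) {
  if (!inherits(probs, "vte_event_probs"))
    stop("'probs' must come from resolve_strategy()")
  p_none <- 1 - probs$p_dvt - probs$p_minor - probs$p_major
  if (p_none < -1e-12)
    stop("postoperative event probabilities exceed 1 (p_dvt + p_minor + ",
         "p_major = ", format(probs$p_dvt + probs$p_minor + probs$p_major),
         "); the mutually exclusive chance node has no valid complement")
  p_none <- max(p_none, 0)
  v <- function(k) .pv(params, k)

  intra_label <- c("hypotension", "no_hypotension")
  p_intra <- c(probs$p_hypo, 1 - probs$p_hypo)
  c_intra <- c(v("c_hypo"), 0)
  post_label <- c("DVT_no_PE", "DVT_with_PE", "minor_bleed", "major_bleed",
                  "no_AE")
  p_post <- c(probs$p_dvt * (1 - probs$p_pe_given_dvt),
              probs$p_dvt * probs$p_pe_given_dvt,
              probs$p_minor, probs$p_major, p_none)
  c_post <- c(v("c_dvt"), v("c_dvt") + v("c_pe"), v("c_minor"), v("c_major"),
              0)
  eff_post <- c(0, 0, 0, 0, 1)

  i <- rep(1:2, each = 5)  # intraoperative branch index
  j <- rep(1:5, times = 2) # postoperative branch index
  data.frame(
    strategy = probs$strategy$name,
    phase = probs$strategy$phase,
    intraop_label = intra_label[i],
    postop_label = post_label[j],
    probability = p_intra[i] * p_post[j],
    cost = probs$c_prophylaxis + c_intra[i] + c_post[j],
    effectiveness = eff_post[j])
}

#' Roll back the decision tree to expected cost and effectiveness
#'
#' Computes a strategy's expected cost per patient and expected effectiveness
#' (probability of avoiding every VTE-related adverse event) by
#' probability-weighted summation over the enumerated terminal pathways.
#' Intraoperative hypotension contributes cost but never reduces
#' effectiveness. Expected deaths, a secondary output, is the probability of
#' the DVT-with-PE pathway times the PE case-fatality input; death pathways
#' accrue no extra cost.
#'
#' @param params A `vte_params` object.
#' @param probs A `vte_event_probs` object from [resolve_strategy()].
#' @return An object of class `vte_ce_result`: list with `strategy`,
#'   `expected_cost` (2021 R$ per patient), `expected_effectiveness` (fraction
#'   in \[0,1\]), `expected_deaths`, and the `pathways` data frame.
#' @examples
#' p <- default_parameters()
#' build_and_rollback(p, resolve_strategy(p, "no_prophylaxis"))
#' @export
build_and_rollback <- function(params, probs) {
  pw <- enumerate_pathways(probs, params)
  structure(list(
    strategy = probs$strategy,
    expected_cost = sum(pw$probability * pw$cost),
    expected_effectiveness = sum(pw$probability * pw$effectiveness),
    expected_deaths = probs$p_dvt * probs$p_pe_given_dvt *
      .pv(params, "p_mortality"),
    pathways = pw), class = "vte_ce_result")
}

#' @export
print.vte_ce_result <- function(x, ...) {
  cat(sprintf("%s: expected cost R$%.2f, expected effectiveness %.4f\n",
              .strategy_label(x$strategy), x$expected_cost,
              x$expected_effectiveness))
  cat(sprintf("  expected deaths per patient: %.3g\n", x$expected_deaths))
  invisible(x)
}
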