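# Deterministic uncertainty analyses: one-way (tornado), threshold on the
# baseline VTE incidence, and the IPC phase scenario analysis.

# Evaluate the base-case rollback for the three strategies under 'params'.
.evaluate_strategies <- function(params) {
  res <- lapply(all_strategies(params), function(s) build_and_rollback(params, s))
  names(res) <- c("no_prophylaxis", "IPC", "LMWH")
  res
}

.owsa_outcomes <- c("icer_ipc_vs_none", "delta_cost_ipc_vs_lmwh",
                    "delta_cost_ipc_vs_none")

.owsa_outcome_fun <- function(outcome) {
  switch(outcome,
    # signed cost-effectiveness ratio of IPC vs no prophylaxis; negative
    # values indicate IPC is dominant (cheaper and more effective)
    icer_ipc_vs_none = function(res) {
      dc <- res$IPC$expected_cost - res$no_prophylaxis$expected_cost
      de <- res$IPC$expected_effectiveness -
        res$no_prophylaxis$expected_effectiveness
      dc / de
    },
    delta_cost_ipc_vs_lmwh = function(res)
      res$IPC$expected_cost - res$LMWH$expected_cost,
    delta_cost_ipc_vs_none = function(res)
      res$IPC$expected_cost - res$no_prophylaxis$expected_cost,
    stop("unknown outcome name: ", outcome, "; use one of ",
         paste(.owsa_outcomes, collapse = ", ")))
}

#' One-way (tornado) sensitivity analysis
#'
#' Varies each uncertain input in turn to the low and high end of its range,
#' all other inputs held at base values, and records the outcome swing. The
#' available outcomes are the signed cost-effectiveness ratio of IPC versus
#' no prophylaxis (negative when IPC dominates) and the expected cost
#' differences of IPC versus LMWH or versus no prophylaxis. Entries are
#' sorted by descending swing, the ordering of a tornado diagram.
#'
#' @param params A `vte_params` object.
#' @param outcome One of `"icer_ipc_vs_none"`, `"delta_cost_ipc_vs_lmwh"`,
#'   `"delta_cost_ipc_vs_none"`.
#' @return A data frame of class `vte_tornado` with columns `parameter`,
#'   `low_input`, `high_input`, `outcome_at_low`, `outcome_at_high`,
#'   `base_outcome`, `swing`.
#' @export
one_way_sensitivity <- function(params, outcome = "icer_ipc_vs_none") {
  validate_parameters(params)
  if (!is.character(outcome) || length(outcome) != 1 ||
      !outcome %in% .owsa_outcomes)
    stop("unknown outcome name: ", paste(outcome, collapse = ", "),
         "; use one of ", paste(.owsa_outcomes, collapse = ", "))
  f <- .owsa_outcome_fun(outcome)
  base_outcome <- f(.evaluate_strategies(params))
  keys <- .vte_registry()$key
  rows <- lapply(keys, function(k) {
    q <- params$quantities[[k]]
    at_low <- f(.evaluate_strategies(.set_value(params, k, q$low)))
    at_high <- f(.evaluate_strategies(.set_value(params, k, q$high)))
    data.frame(parameter = k, low_input = q$low, high_input = q$high,
               outcome_at_low = at_low, outcome_at_high = at_high,
               base_outcome = base_outcome,
               swing = abs(at_high - at_low))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$swing, out$parameter), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "outcome") <- outcome
  class(out) <- c("vte_tornado", "data.frame")
  out
}

#' Threshold analysis on the baseline VTE incidence
#'
#' Finds, by bisection, the baseline DVT probability (the tree's entry VTE
#' event; PE scales through the PE-given-DVT probability) at which the
#' expected cost per patient of IPC equals that of no prophylaxis, all other
#' inputs held at base values. Above the crossing IPC is the cost-saving
#' strategy. An evaluation grid of per-strategy expected costs across the
#' bracket is returned for plotting.
#'
#' @param params A `vte_params` object.
#' @param lo,hi Bracket for the baseline DVT probability, as fractions.
#' @param tol Bisection stops when the absolute cost difference at the
#'   midpoint falls below `tol` (R$).
#' @param grid_points Number of grid evaluations across `[lo, hi]`.
#' @return An object of class `vte_threshold`: list with `parameter`,
#'   `crossing_value` (fraction), `crossing_percent`, `outcome_relation`,
#'   and `grid` (data frame of per-strategy expected costs).
#' @export
threshold_vte_incidence <- function(params, lo = 0.001, hi = 0.05,
                                    tol = 1e-6, grid_points = 50) {
  validate_parameters(params)
  if (!(lo >= 0 && hi <= 1 && lo < hi))
    stop("invalid bracket [", lo, ", ", hi, "]")
  cost_diff <- function(p) {
    pp <- .set_value(params, "p_dvt_baseline", p)
    res <- .evaluate_strategies(pp)
    res$IPC$expected_cost - res$no_prophylaxis$expected_cost
  }
  f_lo <- cost_diff(lo)
  f_hi <- cost_diff(hi)
  if (sign(f_lo) == sign(f_hi))
    stop("expected-cost difference (IPC - no prophylaxis) does not change ",
         "sign on the bracket [", lo, ", ", hi, "] (", format(f_lo), " vs ",
         format(f_hi), ")")
  a <- lo; b <- hi; fa <- f_lo
  mid <- (a + b) / 2
  for (iter in seq_len(200)) {
    mid <- (a + b) / 2
    fm <- cost_diff(mid)
    if (abs(fm) < tol) break
    if (sign(fm) == sign(fa)) {
      a <- mid; fa <- fm
    } else {
      b <- mid
    }
  }
  grid_p <- seq(lo, hi, length.out = grid_points)
  grid <- do.call(rbind, lapply(grid_p, function(p) {
    res <- .evaluate_strategies(.set_value(params, "p_dvt_baseline", p))
    data.frame(p_dvt_baseline = p,
               cost_no_prophylaxis = res$no_prophylaxis$expected_cost,
               cost_ipc = res$IPC$expected_cost,
               cost_lmwh = res$LMWH$expected_cost)
  }))
  cheaper_below <- if (f_lo > 0) "no_prophylaxis" else "IPC"
  cheaper_above <- if (f_hi > 0) "no_prophylaxis" else "IPC"
  structure(list(
    parameter = "p_dvt_baseline",
    crossing_value = mid,
    crossing_percent = 100 * mid,
    outcome_relation = sprintf(
      "%s cheaper below the crossing, %s cheaper above",
      cheaper_below, cheaper_above),
    grid = grid), class = "vte_threshold")
}

#' @export
print.vte_threshold <- function(x, ...) {
  cat(sprintf(
    "IPC and no prophylaxis have equal expected cost at a baseline VTE\nincidence of %.4f%%; %s\n",
    x$crossing_percent, x$outcome_relation))
  invisible(x)
}

#' Scenario analysis of IPC phase of use
#'
#' Evaluates the IPC strategy under its three phases of use: worn intra- and
#' postoperatively (base case), postoperatively only (no intraoperative
#' hypotension reduction), and intraoperatively only (no postoperative VTE
#' protection).
#'
#' @param params A `vte_params` object.
#' @return A data frame with columns `scenario`, `expected_cost`,
#'   `expected_effectiveness`.
#' @export
scenario_analysis <- function(params) {
  validate_parameters(params)
  phases <- c("intra_and_post", "post_only", "intra_only")
  rows <- lapply(phases, function(ph) {
    res <- build_and_rollback(params,
                              resolve_strategy(params, strategy_spec("IPC", ph)))
    data.frame(scenario = paste0("IPC_", ph),
               expected_cost = res$expected_cost,
               expected_effectiveness = res$expected_effectiveness)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
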