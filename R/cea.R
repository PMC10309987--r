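#' Incremental cost-effectiveness ratio with dominance classification
#'
#' Maps an incremental (cost, effectiveness) pair to either a numeric ICER in
#' R$ per adverse event avoided or a dominance status. All quadrants of the
#' incremental plane are covered: a positive-cost, positive-effect pair gives
#' the usual ratio; lower-or-equal cost with higher-or-equal effect (not both
#' zero) is `dominant`; higher-or-equal cost with lower effect (or higher
#' cost at equal effect) is `dominated`; both increments zero is a `tie`;
#' a both-negative pair is reported as a ratio from the cheaper comparator's
#' perspective.
#'
#' @param delta_cost Incremental cost in R$.
#' @param delta_effect Incremental effectiveness (fraction of adverse events
#'   avoided).
#' @return An object of class `vte_icer`: list with `status` (one of
#'   `"icer"`, `"dominant"`, `"dominated"`, `"tie"`), `value` (the ratio, or
#'   `NA` for a status), `delta_cost`, `delta_effect`.
#' @examples
#' icer(100, 0.5)$value      # 200
#' icer(351, -0.055)$status  # "dominated"
#' @export
icer <- function(delta_cost, delta_effect) {
  stopifnot(is.finite(delta_cost), is.finite(delta_effect))
  if (delta_cost == 0 && delta_effect == 0) {
    status <- "tie"; value <- NA_real_
  } else if (delta_cost <= 0 && delta_effect >= 0) {
    status <- "dominant"; value <- NA_real_
  } else if (delta_effect < 0 || (delta_cost > 0 && delta_effect == 0)) {
    status <- if (delta_cost < 0) "icer" else "dominated"
    value <- if (delta_cost < 0) delta_cost / delta_effect else NA_real_
    if (delta_cost >= 0) status <- "dominated"
  } else {
    status <- "icer"; value <- delta_cost / delta_effect
  }
  structure(list(status = status, value = value, delta_cost = delta_cost,
                 delta_effect = delta_effect), class = "vte_icer")
}

#' @export
print.vte_icer <- function(x, ...) {
  if (x$status == "icer")
    cat(sprintf("ICER: R$%.2f per AE avoided\n", x$value))
  else cat("ICER status:", x$status, "\n")
  invisible(x)
}

#' Net monetary benefit
#'
#' The decision metric underlying the acceptability curve: willingness-to-pay
#' times expected effectiveness minus expected cost. At a threshold of zero
#' it reduces to cost minimization.
#'
#' @param result A `vte_ce_result`, or a list with `expected_cost` and
#'   `expected_effectiveness`.
#' @param wtp Willingness-to-pay in R$ per adverse event avoided; must be
#'   non-negative.
#' @return Net monetary benefit in R$.
#' @export
net_monetary_benefit <- function(result, wtp) {
  if (!is.numeric(wtp) || length(wtp) != 1 || !is.finite(wtp) || wtp < 0)
    stop("'wtp' must be a non-negative number")
  wtp * result$expected_effectiveness - result$expected_cost
}

#' Incremental cost-effectiveness table
#'
#' Builds the incremental comparison across strategies: rows sorted by
#' ascending expected cost (the cheapest is the reference), incremental cost
#' and effectiveness versus the previous row, strong-dominance flags (a
#' strategy at least as costly and no more effective than another), an
#' equal-cost-equal-effect `tie` flag, extended-dominance flags (a strategy
#' whose frontier ICER exceeds that of a more effective strategy), and
#' numeric ICERs along the efficiency frontier (each frontier strategy
#' versus the previous frontier strategy).
#'
#' @param results A list of at least two `vte_ce_result` objects.
#' @return A data frame of class `vte_incremental_table` with columns
#'   `strategy`, `expected_cost`, `expected_effectiveness`,
#'   `incremental_cost`, `incremental_effectiveness`, `icer`, `status`
#'   (`reference`, `frontier`, `dominated`, `extendedly_dominated`, `tie`).
#' @examples
#' p <- default_parameters()
#' incremental_table(lapply(all_strategies(p), function(s)
#'   build_and_rollback(p, s)))
#' @export
incremental_table <- function(results) {
  if (length(results) < 2)
    stop("incremental comparison requires at least 2 strategies")
  df <- data.frame(
    strategy = vapply(results, function(r) .strategy_label(r$strategy), ""),
    expected_cost = vapply(results, function(r) r$expected_cost, 0),
    expected_effectiveness = vapply(results,
                                    function(r) r$expected_effectiveness, 0))
  df <- df[order(df$expected_cost, -df$expected_effectiveness), , drop = FALSE]
  rownames(df) <- NULL
  n <- nrow(df)
  status <- rep(NA_character_, n)

  # ties and strong dominance
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      ci <- df$expected_cost[i]; cj <- df$expected_cost[j]
      ei <- df$expected_effectiveness[i]; ej <- df$expected_effectiveness[j]
      if (ci == cj && ei == ej) {
        if (j < i) status[i] <- "tie"  # later duplicate is the flagged one
      } else if (cj <= ci && ej >= ei) {
        status[i] <- "dominated"
      }
      if (!is.na(status[i]) && status[i] == "dominated") break
    }
  }

  # efficiency frontier with extended dominance
  frontier <- which(is.na(status))
  repeat {
    if (length(frontier) < 3) break
    ic <- diff(df$expected_cost[frontier]) /
      diff(df$expected_effectiveness[frontier])
    worse <- which(diff(ic) < 0)  # ICER must be increasing along the frontier
    if (!length(worse)) break
    drop_idx <- frontier[worse[1] + 1]
    status[drop_idx] <- "extendedly_dominated"
    frontier <- frontier[frontier != drop_idx]
  }

  df$incremental_cost <- c(NA_real_, diff(df$expected_cost))
  df$incremental_effectiveness <- c(NA_real_, diff(df$expected_effectiveness))
  df$icer <- NA_real_
  if (length(frontier)) {
    status[frontier[1]] <- "reference"
    if (length(frontier) > 1) {
      status[frontier[-1]] <- "frontier"
      df$icer[frontier[-1]] <- diff(df$expected_cost[frontier]) /
        diff(df$expected_effectiveness[frontier])
    }
  }
  df$status <- status
  class(df) <- c("vte_incremental_table", "data.frame")
  df
}
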