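# Independent oracles used across the test files. These deliberately avoid
# the package's enumeration/rollback/frontier code paths: expectations are
# recomputed from first principles (explicit nested loops, exhaustive
# pairwise comparison) so agreement is informative.

# Expected cost/effectiveness by explicit nested-loop enumeration of the
# 2 x 5 terminal pathways.
oracle_expectation <- function(pr, params) {
  v <- function(k) params$quantities[[k]]$value
  total_p <- total_cost <- total_eff <- 0
  for (hypo in c(TRUE, FALSE)) {
    p_intra <- if (hypo) pr$p_hypo else 1 - pr$p_hypo
    c_intra <- if (hypo) v("c_hypo") else 0
    post <- list(
      list(p = pr$p_dvt * (1 - pr$p_pe_given_dvt), c = v("c_dvt"), e = 0),
      list(p = pr$p_dvt * pr$p_pe_given_dvt, c = v("c_dvt") + v("c_pe"), e = 0),
      list(p = pr$p_minor, c = v("c_minor"), e = 0),
      list(p = pr$p_major, c = v("c_major"), e = 0),
      list(p = 1 - pr$p_dvt - pr$p_minor - pr$p_major, c = 0, e = 1))
    for (ev in post) {
      p <- p_intra * ev$p
      total_p <- total_p + p
      total_cost <- total_cost + p * (pr$c_prophylaxis + c_intra + ev$c)
      total_eff <- total_eff + p * ev$e
    }
  }
  list(p = total_p, cost = total_cost, eff = total_eff)
}

# Construct a vte_event_probs object directly, bypassing resolve_strategy.
make_event_probs <- function(p_hypo, p_dvt, p_pe_given_dvt, p_minor, p_major,
                             c_prophylaxis, name = "IPC",
                             phase = "intra_and_post") {
  structure(list(p_hypo = p_hypo, p_dvt = p_dvt,
                 p_pe_given_dvt = p_pe_given_dvt, p_minor = p_minor,
                 p_major = p_major, c_prophylaxis = c_prophylaxis,
                 strategy = strategy_spec(name, phase)),
            class = "vte_event_probs", n_clamped = 0L)
}

# Random valid event probabilities (postoperative probabilities scaled to a
# random total below 1).
random_event_probs <- function() {
  raw <- stats::runif(3)
  scale <- stats::runif(1, 0, 0.95) / sum(raw)
  make_event_probs(p_hypo = stats::runif(1),
                   p_dvt = raw[1] * scale,
                   p_pe_given_dvt = stats::runif(1),
                   p_minor = raw[2] * scale,
                   p_major = raw[3] * scale,
                   c_prophylaxis = stats::runif(1, 0, 200))
}

# Exhaustive frontier construction: strong dominance by pairwise comparison,
# then the frontier walk that always takes the lowest ICER among strictly
# more effective candidates.
oracle_frontier <- function(cost, eff) {
  n <- length(cost)
  dominated <- vapply(seq_len(n), function(i)
    any(cost <= cost[i] & eff >= eff[i] & (cost < cost[i] | eff > eff[i])),
    logical(1))
  cand <- which(!dominated)
  cur <- cand[order(cost[cand], -eff[cand])][1]
  frontier <- cur
  repeat {
    better <- cand[eff[cand] > eff[cur]]
    if (!length(better)) break
    ic <- (cost[better] - cost[cur]) / (eff[better] - eff[cur])
    cur <- better[which.min(ic)]
    frontier <- c(frontier, cur)
  }
  frontier
}

# Minimal cost/effectiveness result stub accepted by the CEA functions
# (label is free-form so synthetic strategy sets of any size can be built).
make_ce_result <- function(name, cost, eff) {
  spec <- structure(list(name = name, phase = "intra_and_post"),
                    class = "strategy_spec")
  structure(list(strategy = spec, expected_cost = cost,
                 expected_effectiveness = eff, expected_deaths = 0,
                 pathways = NULL),
            class = "vte_ce_result")
}
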