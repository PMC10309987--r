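# Patient-level microsimulation: the brute-force counterpart of the analytic
# rollback, and a generator of perturbed parameter fixtures.

#' Simulate a patient cohort through the decision tree
#'
#' Draws individual patients through the per-strategy tree: intraoperative
#' hypotension as a Bernoulli event, the mutually exclusive postoperative
#' event as a categorical draw from a single uniform variate with fixed
#' category ordering (DVT, minor bleed, major bleed, none), PE as a Bernoulli
#' event within DVT, and death as a Bernoulli event within PE. Costs
#' accumulate exactly as on the corresponding decision-tree pathway, so
#' cohort means converge to the rollback expectations. Death neither
#' terminates cost accrual nor changes the effectiveness payoff. Each stage
#' consumes one fixed-length block of `n` uniform variates, making runs
#' reproducible by seed.
#'
#' @param params A `vte_params` object.
#' @param strategy A [strategy_spec()] or strategy name.
#' @param n Number of simulated patients.
#' @param seed RNG seed.
#' @return A data frame with one row per patient: `patient_id`, `strategy`,
#'   `phase`, `had_hypotension`, `postop_event`, `died`, `cost`, `ae_free`.
#' @examples
#' p <- default_parameters()
#' cohort <- simulate_cohort(p, "IPC", n = 1000, seed = 7)
#' mean(cohort$ae_free)
#' @export
simulate_cohort <- function(params, strategy, n, seed = params$rng_seed) {
  validate_parameters(params)
  if (is.character(strategy)) strategy <- strategy_spec(strategy)
  n <- as.integer(n)
  if (is.na(n) || n < 1) stop("'n' must be a positive integer")
  pr <- resolve_strategy(params, strategy)
  set.seed(as.integer(seed))
  u_hypo <- stats::runif(n)
  u_event <- stats::runif(n)
  u_pe <- stats::runif(n)
  u_death <- stats::runif(n)

  had_hypo <- u_hypo < pr$p_hypo
  # single-uniform categorical draw, fixed ordering: DVT, minor, major, none
  cut1 <- pr$p_dvt
  cut2 <- cut1 + pr$p_minor
  cut3 <- cut2 + pr$p_major
  if (cut3 > 1 + 1e-12)
    stop("postoperative event probabilities exceed 1; no valid complement")
  dvt <- u_event < cut1
  minor <- !dvt & u_event < cut2
  major <- !dvt & !minor & u_event < cut3
  pe <- dvt & (u_pe < pr$p_pe_given_dvt)
  died <- pe & (u_death < .pv(params, "p_mortality"))

  postop <- rep("no_AE", n)
  postop[major] <- "major_bleed"
  postop[minor] <- "minor_bleed"
  postop[dvt & !pe] <- "DVT_no_PE"
  postop[pe] <- "DVT_with_PE"

  event_cost <- c(DVT_no_PE = .pv(params, "c_dvt"),
                  DVT_with_PE = .pv(params, "c_dvt") + .pv(params, "c_pe"),
                  minor_bleed = .pv(params, "c_minor"),
                  major_bleed = .pv(params, "c_major"),
                  no_AE = 0)
  cost <- pr$c_prophylaxis + ifelse(had_hypo, .pv(params, "c_hypo"), 0) +
    unname(event_cost[postop])

  data.frame(patient_id = seq_len(n),
             strategy = strategy$name,
             phase = strategy$phase,
             had_hypotension = had_hypo,
             postop_event = postop,
             died = died,
             cost = cost,
             ae_free = as.integer(postop == "no_AE"))
}

#' Generate a perturbed parameter fixture
#'
#' Produces a valid parameter set with every point value independently
#' jittered by a uniform factor in `[1 - perturbation, 1 + perturbation]`
#' (ranges scaled by the same factor so ordering is preserved; probabilities
#' and their bounds clamped to \[0,1\]). Useful for exercising downstream
#' modules on inputs other than the defaults.
#'
#' @param params A `vte_params` object to perturb.
#' @param perturbation Maximum relative jitter, in `[0, 1)`.
#' @param seed RNG seed.
#' @return A validated `vte_params` object.
#' @export
generate_fixture <- function(params = default_parameters(), perturbation = 0.1,
                             seed = 1) {
  validate_parameters(params)
  if (!is.numeric(perturbation) || perturbation < 0 || perturbation >= 1)
    stop("'perturbation' must lie in [0, 1)")
  set.seed(as.integer(seed))
  reg <- .vte_registry()
  for (i in seq_len(nrow(reg))) {
    key <- reg$key[i]
    q <- params$quantities[[key]]
    f <- 1 + stats::runif(1, -perturbation, perturbation)
    q$value <- q$value * f
    q$low <- q$low * f
    q$high <- q$high * f
    if (reg$kind[i] == "prob") {
      q$value <- min(max(q$value, 0), 1)
      q$low <- min(max(q$low, 0), 1)
      q$high <- min(max(q$high, 0), 1)
    }
    params$quantities[[key]] <- q
  }
  validate_parameters(params)
  params
}
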