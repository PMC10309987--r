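# Probabilistic sensitivity analysis: distribution fitting, Monte Carlo
# propagation, cost-effectiveness plane and acceptability-curve summaries.

#' Fit a sampling distribution to an uncertain quantity
#'
#' Converts a point estimate with a 95% uncertainty range into a sampling
#' distribution. The range is read as a 95% interval, giving a standard
#' deviation of `(high - low) / 3.92`. Beta (probabilities) and gamma
#' (costs) distributions are fitted by the method of moments to the point
#' value and that standard deviation, so the fitted mean equals the point
#' value. Lognormal distributions (relative risks) take the point value as
#' their median, with `sdlog = (log(high) - log(low)) / 3.92`, matching the
#' log-scale symmetry of relative-risk confidence intervals. A degenerate
#' range (or the `fixed` family) yields a point mass.
#'
#' @param q An [uncertain_quantity()].
#' @return An object of class `vte_dist`: list with `family`, `par1`, `par2`
#'   (shape1/shape2 for beta, shape/rate for gamma, meanlog/sdlog for
#'   lognormal, value/0 for fixed), the fitted `mean` (for lognormal also the
#'   `median`), and `derived_from = c(value, low, high)`.
#' @examples
#' fit_distribution(uncertain_quantity(0.007, 0.001, 0.03, family = "beta"))
#' @export
fit_distribution <- function(q) {
  if (!inherits(q, "uncertain_quantity"))
    stop("'q' must be an uncertain_quantity")
  sdv <- (q$high - q$low) / 3.92
  out <- if (q$family == "fixed" || sdv <= 0) {
    list(family = "fixed", par1 = q$value, par2 = 0, mean = q$value)
  } else if (q$family == "beta") {
    m <- q$value
    v <- sdv^2
    if (m <= 0 || m >= 1)
      stop("beta fit needs a point value strictly inside (0,1); got ", m)
    if (v >= m * (1 - m))
      stop("beta fit infeasible: sd^2 = ", format(v),
           " >= value*(1-value) = ", format(m * (1 - m)))
    nu <- m * (1 - m) / v - 1
    list(family = "beta", par1 = m * nu, par2 = (1 - m) * nu, mean = m)
  } else if (q$family == "gamma") {
    m <- q$value
    if (m <= 0) stop("gamma fit needs a positive point value; got ", m)
    list(family = "gamma", par1 = (m / sdv)^2, par2 = m / sdv^2, mean = m)
  } else if (q$family == "lognormal") {
    if (q$low <= 0 || q$value <= 0)
      stop("lognormal fit needs strictly positive value and bounds; got low = ",
           q$low)
    sdlog <- (log(q$high) - log(q$low)) / 3.92
    list(family = "lognormal", par1 = log(q$value), par2 = sdlog,
         mean = exp(log(q$value) + sdlog^2 / 2), median = q$value)
  } else stop("unknown family: ", q$family)
  out$derived_from <- c(value = q$value, low = q$low, high = q$high)
  structure(out, class = "vte_dist")
}

#' Draw samples from a fitted distribution
#'
#' @param dist A `vte_dist` from [fit_distribution()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
sample_distribution <- function(dist, n) {
  if (!inherits(dist, "vte_dist")) stop("'dist' must be a vte_dist")
  switch(dist$family,
         fixed = rep(dist$par1, n),
         beta = stats::rbeta(n, dist$par1, dist$par2),
         gamma = stats::rgamma(n, shape = dist$par1, rate = dist$par2),
         lognormal = stats::rlnorm(n, meanlog = dist$par1, sdlog = dist$par2))
}

# Keys sampled in the PSA, in fixed registry order. The PE case-fatality
# input is held fixed: it feeds only the secondary expected-deaths output,
# leaving 17 sampled quantities.
.psa_sampled_keys <- function() {
  setdiff(.vte_registry()$key, "p_mortality")
}

#' Run the probabilistic sensitivity analysis
#'
#' Draws `n` Monte Carlo samples of the 17 uncertain model inputs from their
#' fitted beta/gamma/lognormal distributions, and for each draw resolves all
#' three strategies on the same sampled parameter vector (common random
#' numbers across strategies) and rolls back the decision tree. Probability
#' products are clamped to \[0,1\]; draws in which the mutually exclusive
#' postoperative probabilities jointly exceed 1 are proportionally
#' renormalized. Both kinds of adjustment are counted and reported in the
#' result, never applied silently. Output is reproducible given `(n, seed)`.
#'
#' @param params A `vte_params` object.
#' @param n Number of Monte Carlo draws (default `params$n_psa`).
#' @param seed RNG seed (default `params$rng_seed`).
#' @return An object of class `vte_psa`: list with `samples` (data frame
#'   `draw`, `strategy`, `expected_cost`, `expected_effectiveness`),
#'   `draws` (the n x 17 matrix of sampled inputs), `n`, `seed`, `wtp`,
#'   `n_clamped`, `n_renormalized`.
#' @export
run_psa <- function(params, n = NULL, seed = NULL) {
  validate_parameters(params)
  if (is.null(n)) n <- params$n_psa
  if (is.null(seed)) seed <- params$rng_seed
  n <- as.integer(n)
  if (is.na(n) || n < 1) stop("'n' must be a positive integer")
  keys <- .psa_sampled_keys()
  set.seed(as.integer(seed))
  draws <- matrix(NA_real_, nrow = n, ncol = length(keys),
                  dimnames = list(NULL, keys))
  for (k in keys)
    draws[, k] <- sample_distribution(fit_distribution(params$quantities[[k]]),
                                      n)
  strategies <- list(strategy_spec("no_prophylaxis"), strategy_spec("IPC"),
                     strategy_spec("LMWH"))
  labels <- vapply(strategies, .strategy_label, "")
  n_clamped <- 0L
  n_renorm <- 0L
  cost_m <- eff_m <- matrix(NA_real_, nrow = n, ncol = length(strategies),
                            dimnames = list(NULL, labels))
  p_i <- params
  for (i in seq_len(n)) {
    for (k in keys) {
      q <- p_i$quantities[[k]]
      q$value <- draws[i, k]
      q$low <- min(q$low, q$value)
      q$high <- max(q$high, q$value)
      p_i$quantities[[k]] <- q
    }
    for (s in seq_along(strategies)) {
      pr <- .resolve_strategy_impl(p_i, strategies[[s]])
      n_clamped <- n_clamped + attr(pr, "n_clamped")
      tot <- pr$p_dvt + pr$p_minor + pr$p_major
      if (tot > 1) {
        n_renorm <- n_renorm + 1L
        pr$p_dvt <- pr$p_dvt / tot
        pr$p_minor <- pr$p_minor / tot
        pr$p_major <- pr$p_major / tot
      }
      res <- build_and_rollback(p_i, pr)
      cost_m[i, s] <- res$expected_cost
      eff_m[i, s] <- res$expected_effectiveness
    }
  }
  samples <- data.frame(
    draw = rep(seq_len(n), each = length(strategies)),
    strategy = rep(labels, times = n),
    expected_cost = as.vector(t(cost_m)),
    expected_effectiveness = as.vector(t(eff_m)))
  structure(list(samples = samples, draws = draws,
                 n = n, seed = as.integer(seed), wtp = params$wtp,
                 n_clamped = n_clamped, n_renormalized = n_renorm),
            class = "vte_psa")
}

#' @export
print.vte_psa <- function(x, ...) {
  cat(sprintf("PSA: %d draws (seed %d), %d probability products clamped, %d draws renormalized\n",
              x$n, x$seed, x$n_clamped, x$n_renormalized))
  agg <- stats::aggregate(
    cbind(expected_cost, expected_effectiveness) ~ strategy, data = x$samples,
    FUN = mean)
  print(agg, row.names = FALSE)
  invisible(x)
}

# Wide (draws x strategies) matrices of PSA costs and effects.
.psa_wide <- function(psa, what) {
  s <- psa$samples
  strategies <- unique(s$strategy)
  m <- vapply(strategies, function(st) s[[what]][s$strategy == st],
              numeric(psa$n))
  if (is.null(dim(m))) m <- matrix(m, nrow = psa$n)
  colnames(m) <- strategies
  m
}

#' Cost-effectiveness plane summary for one comparison
#'
#' Summarizes the incremental (cost, effectiveness) cloud of one strategy
#' against another across the PSA draws: the proportion of draws in the
#' dominant quadrant (comparator cheaper and more effective, "superior"),
#' the proportion acceptable at the willingness-to-pay threshold (positive
#' incremental net monetary benefit, i.e. below the WTP line), and the 95%
#' confidence ellipse of the incremental pairs (mean and covariance with the
#' chi-square 0.95 quantile at 2 degrees of freedom).
#'
#' @param psa A `vte_psa` object.
#' @param comp Comparator strategy label (the strategy whose superiority is
#'   assessed), e.g. `"IPC"`.
#' @param ref Reference strategy label, e.g. `"LMWH"`.
#' @param wtp Willingness-to-pay threshold in R$ (default from the PSA).
#' @return An object of class `vte_ce_plane`: list with `deltas` (data frame
#'   `delta_cost`, `delta_effect`), `prop_superior`, `prop_acceptable`,
#'   `ellipse` (center, covariance, radii, angle in radians), `degenerate`
#'   flag, `comp`, `ref`, `wtp`.
#' @export
ce_plane_summary <- function(psa, comp = "IPC", ref = "LMWH", wtp = NULL) {
  if (!inherits(psa, "vte_psa")) stop("'psa' must come from run_psa()")
  if (psa$n < 2) stop("at least 2 PSA draws are required")
  if (is.null(wtp)) wtp <- psa$wtp
  costs <- .psa_wide(psa, "expected_cost")
  effs <- .psa_wide(psa, "expected_effectiveness")
  for (st in c(comp, ref))
    if (!st %in% colnames(costs)) stop("unknown strategy label: ", st)
  if (comp == ref) stop("'comp' and 'ref' must name different strategies")
  dc <- costs[, comp] - costs[, ref]
  de <- effs[, comp] - effs[, ref]
  sigma <- stats::cov(cbind(dc, de))
  ev <- eigen(sigma, symmetric = TRUE)
  degenerate <- ev$values[2] <= 1e-12 * max(ev$values[1], 1e-300)
  r2 <- stats::qchisq(0.95, df = 2)
  structure(list(
    deltas = data.frame(delta_cost = dc, delta_effect = de),
    prop_superior = mean(dc < 0 & de > 0),
    prop_acceptable = mean(wtp * de - dc > 0),
    ellipse = list(center = c(delta_cost = mean(dc), delta_effect = mean(de)),
                   cov = sigma,
                   radii = sqrt(pmax(ev$values, 0) * r2),
                   angle = atan2(ev$vectors[2, 1], ev$vectors[1, 1])),
    degenerate = degenerate, comp = comp, ref = ref, wtp = wtp),
    class = "vte_ce_plane")
}

#' @export
print.vte_ce_plane <- function(x, ...) {
  cat(sprintf("CE plane, %s vs %s:\n", x$comp, x$ref))
  cat(sprintf("  superior (cheaper & more effective) in %.1f%% of draws\n",
              100 * x$prop_superior))
  cat(sprintf("  acceptable at WTP R$%s in %.1f%% of draws\n",
              format(x$wtp, big.mark = ","), 100 * x$prop_acceptable))
  if (x$degenerate) cat("  note: degenerate (near-singular) covariance\n")
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value on a grid, the probability that each
#' strategy is the cost-effective choice: the fraction of PSA draws in which
#' it attains the maximum net monetary benefit across all strategies
#' simultaneously, with ties split equally. At a threshold of zero the curve
#' reduces to the fraction of draws in which each strategy is cheapest.
#'
#' @param psa A `vte_psa` object.
#' @param wtp_grid Vector of willingness-to-pay values in R$ (default 0 to
#'   30,000 in steps of 500, bracketing the R$15,000 threshold).
#' @return An object of class `vte_ceac`: data frame with columns `wtp`,
#'   `strategy`, `probability`; probabilities sum to 1 at every grid point.
#' @export
acceptability_curve <- function(psa, wtp_grid = seq(0, 30000, by = 500)) {
  if (!inherits(psa, "vte_psa")) stop("'psa' must come from run_psa()")
  if (!length(wtp_grid)) stop("'wtp_grid' must be non-empty")
  costs <- .psa_wide(psa, "expected_cost")
  effs <- .psa_wide(psa, "expected_effectiveness")
  strategies <- colnames(costs)
  rows <- lapply(wtp_grid, function(lambda) {
    nmb <- lambda * effs - costs
    best <- apply(nmb, 1, max)
    win <- nmb >= best - .Machine$double.eps * (abs(best) + 1)
    share <- win / rowSums(win)  # ties split equally
    data.frame(wtp = lambda, strategy = strategies,
               probability = colMeans(share))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("vte_ceac", "data.frame")
  out
}
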