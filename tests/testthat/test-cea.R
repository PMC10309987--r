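p0 <- default_parameters()

test_that("the ICER maps every quadrant of the incremental plane", {
  expect_equal(icer(100, 0.5)$value, 200)
  expect_equal(icer(100, 0.5)$status, "icer")
  expect_equal(icer(351, -0.055)$status, "dominated")
  expect_equal(icer(-10, 0.01)$status, "dominant")
  expect_equal(icer(-10, 0)$status, "dominant")
  expect_equal(icer(0, 0.01)$status, "dominant")
  expect_equal(icer(10, 0)$status, "dominated")
  expect_equal(icer(0, 0)$status, "tie")
  # both negative: ratio from the cheaper comparator's perspective
  both_neg <- icer(-100, -0.5)
  expect_equal(both_neg$status, "icer")
  expect_equal(both_neg$value, 200)
})

test_that("base-case incremental table flags LMWH as dominated with IPC on the frontier", {
  results <- lapply(all_strategies(p0), function(s) build_and_rollback(p0, s))
  tab <- incremental_table(results)
  expect_equal(tab$strategy, c("no_prophylaxis", "IPC", "LMWH"))
  expect_equal(tab$status, c("reference", "frontier", "dominated"))
  expect_true(is.na(tab$icer[tab$strategy == "LMWH"]))
  icer_ipc <- tab$icer[tab$strategy == "IPC"]
  expect_equal(icer_ipc,
               (tab$expected_cost[2] - tab$expected_cost[1]) /
                 (tab$expected_effectiveness[2] - tab$expected_effectiveness[1]))
  # synthetic set: costs (0, 10, 5), effects (0.5, 0.9, 0.6); the middle
  # point lies above the hull, so the frontier is {A, B} with C extendedly
  # dominated (ICER A->C of 50 exceeds A->B's 25) -- as the oracle confirms
  syn <- list(make_ce_result("A", 0, 0.5), make_ce_result("B", 10, 0.9),
              make_ce_result("C", 5, 0.6))
  tab2 <- incremental_table(syn)
  expect_equal(tab2$strategy, c("A", "C", "B"))
  expect_equal(tab2$status, c("reference", "extendedly_dominated", "frontier"))
  expect_equal(tab2$strategy[tab2$status %in% c("reference", "frontier")],
               c("A", "B", "C")[oracle_frontier(c(0, 10, 5), c(0.5, 0.9, 0.6))])
})

test_that("degenerate equal strategies yield a tie without an ICER", {
  tab <- incremental_table(list(make_ce_result("A", 5, 0.5),
                                make_ce_result("B", 5, 0.5)))
  expect_equal(sort(tab$status), c("reference", "tie"))
  expect_true(all(is.na(tab$icer)))
  expect_error(incremental_table(list(make_ce_result("A", 1, 0.5))),
               "at least 2")
})

test_that("frontier construction matches the exhaustive oracle on random strategy sets", {
  set.seed(404)
  for (rep in 1:40) {
    k <- sample(2:5, 1)
    cost <- round(stats::runif(k, 0, 100), 1)
    eff <- round(stats::runif(k), 3)
    labels <- paste0("S", seq_len(k))
    tab <- incremental_table(Map(make_ce_result, labels, cost, eff))
    got <- tab$strategy[tab$status %in% c("reference", "frontier")]
    want <- labels[oracle_frontier(cost, eff)]
    expect_equal(got, want,
                 info = paste("costs", paste(cost, collapse = ","),
                              "effects", paste(eff, collapse = ",")))
  }
})

test_that("extended dominance removes inside-the-hull strategies", {
  # B sits above the A-C segment: its ICER from A (10/0.1=100) exceeds C's
  # frontier ICER, so B is extendedly dominated
  syn <- list(make_ce_result("A", 0, 0.5), make_ce_result("B", 10, 0.6),
              make_ce_result("C", 12, 0.9))
  tab <- incremental_table(syn)
  expect_equal(tab$status[tab$strategy == "B"], "extendedly_dominated")
  expect_equal(tab$icer[tab$strategy == "C"], 12 / 0.4)
})

test_that("ICER and net-monetary-benefit decision rules agree on random pairs", {
  set.seed(505)
  for (rep in 1:200) {
    a <- make_ce_result("A", stats::runif(1, 0, 2000), stats::runif(1))
    b <- make_ce_result("B", stats::runif(1, 0, 2000), stats::runif(1))
    lambda <- stats::runif(1, 0, 30000)
    nmb_pref <- if (net_monetary_benefit(b, lambda) >
                      net_monetary_benefit(a, lambda)) "B" else "A"
    dc <- b$expected_cost - a$expected_cost
    de <- b$expected_effectiveness - a$expected_effectiveness
    ic <- icer(dc, de)
    icer_pref <- switch(ic$status,
      dominant = "B",
      dominated = "A",
      tie = "A",
      icer = if (de > 0) {
        if (ic$value < lambda) "B" else "A"     # pay for extra effect if cheap enough
      } else {
        if (ic$value > lambda) "B" else "A"     # accept less effect only if savings beat lambda
      })
    expect_equal(icer_pref, nmb_pref)
  }
})

test_that("ICERs scale linearly with costs and NMB has the stated limits", {
  results <- lapply(all_strategies(p0), function(s) build_and_rollback(p0, s))
  tab <- incremental_table(results)
  k <- 3.7
  scaled <- lapply(results, function(r) {
    r$expected_cost <- r$expected_cost * k
    r
  })
  tab_k <- incremental_table(scaled)
  expect_equal(tab_k$icer, tab$icer * k)
  expect_equal(net_monetary_benefit(list(expected_cost = 0,
                                         expected_effectiveness = 1), 15000),
               15000)
  expect_equal(net_monetary_benefit(list(expected_cost = 914,
                                         expected_effectiveness = 0.912), 0),
               -914)
  expect_error(net_monetary_benefit(results[[1]], -1), "non-negative")
})
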