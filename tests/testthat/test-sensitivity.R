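test_that("parameter sampling is moment-matched to the 95% interval", {
  set.seed(101)
  # utility: beta with sd = range/3.92
  sp <- param_spec("u_sd", "utilities.sd", 0.76, 0.608, 0.912, "beta")
  x <- sample_param(sp, 10000)
  expect_true(all(x > 0 & x < 1))
  expect_lt(abs(mean(x) - 0.76), 0.005)
  expect_lt(abs(sd(x) - (0.912 - 0.608) / 3.92), 0.01)
  # cost: gamma, strictly positive, mean within 1%
  sp <- param_spec("ibi305", "costs.ibi305", 1644.5916, 1315.5916,
                   1973.5916, "gamma")
  x <- sample_param(sp, 10000)
  expect_true(all(x > 0))
  expect_lt(abs(mean(x) / 1644.5916 - 1), 0.01)
  # disutility: beta on the magnitude, negated
  sp <- param_spec("dis", "ae.disutilities.ppe", -0.15, -0.18, -0.12,
                   "beta")
  x <- sample_param(sp, 5000)
  expect_true(all(x < 0))
  expect_lt(abs(mean(x) + 0.15), 0.005)
  # fixed family passes the base through
  sp <- param_spec("fix", "costs.followup", 59.2, 40, 80, "fixed")
  expect_equal(sample_param(sp, 5), rep(59.2, 5))
})

test_that("infeasible beta moment match falls back to uniform", {
  sp <- param_spec("wide", "utilities.pd", 0.5, 0, 1, "beta")
  sp$high <- 3 # sd too large for a beta on [0, 1]
  sp$low <- -2
  set.seed(1)
  expect_warning(x <- sample_param(sp, 100), "infeasible")
  expect_true(all(x >= -2 & x <= 3))
})

test_that("PSA is reproducible and collapses to the base case when fixed", {
  b <- load_config()
  m <- resolve_scenario(b, "medicare")
  d1 <- run_psa(m, n = 50, seed = 99)
  d2 <- run_psa(m, n = 50, seed = 99)
  expect_identical(d1, d2)
  # all-fixed families reproduce the deterministic base case per draw
  params <- default_param_specs(m, "psa")
  fixed <- lapply(params, function(p) { p$psa_family <- "fixed"; p })
  d <- run_psa(m, params = fixed, n = 5, seed = 1)
  base <- evaluate_model(m)
  expect_equal(d$incr_cost, rep(base$ce$incr_cost, 5), tolerance = 1e-9)
  expect_equal(d$incr_qaly, rep(base$ce$incr_qaly, 5), tolerance = 1e-9)
  expect_equal(d$incr_cost / d$incr_qaly, rep(base$ce$icer, 5),
               tolerance = 1e-9)
})

test_that("PSA totals equal a direct cohort evaluation of the sampled model", {
  b <- load_config()
  m <- resolve_scenario(b, "medicare")
  params <- default_param_specs(m, "psa")
  d <- run_psa(m, params = params, n = 3, seed = 7)
  # re-apply the sampled values and run the full cohort model
  for (i in 1:3) {
    mi <- m
    for (p in params) mi <- set_param(mi, p$binding, d[[p$name]][i])
    res <- evaluate_model(mi)
    expect_equal(d$cost_sintilimab_ibi305[i],
                 res$outcomes$sintilimab_ibi305$total_cost,
                 tolerance = 1e-9)
    expect_equal(d$qaly_sorafenib[i],
                 res$outcomes$sorafenib$total_qalys, tolerance = 1e-9)
  }
})

test_that("CEAC endpoints and monotonicity behave as NMB dictates", {
  fake <- tibble::tibble(incr_cost = c(100, 200, 300),
                         incr_qaly = c(0.1, 0.2, 0.3))
  attr(fake, "wtp") <- 38334
  expect_equal(ceac(fake, 0)$prob_cost_effective, 0)
  expect_equal(ceac(fake, 1e9)$prob_cost_effective, 1)
  grid <- ceac(fake, seq(0, 5000, by = 500))
  expect_true(all(diff(grid$prob_cost_effective) >= 0))
  expect_error(ceac(fake[0, ], 0), "at least one draw")
})

test_that("the CE plane projection is flag-consistent with the CEAC", {
  b <- load_config()
  m <- resolve_scenario(b, "medicare")
  d <- run_psa(m, n = 200, seed = 5)
  plane <- ce_plane(d, wtp = 38334)
  expect_equal(nrow(plane), 200)
  expect_equal(mean(plane$cost_effective),
               prob_cost_effective(d, 38334))
  expect_equal(plane$incr_qaly, d$incr_qaly)
})

test_that("one-way analysis ranks by spread and respects monotonicity", {
  b <- load_config()
  m <- resolve_scenario(b, "medicare")
  base_icer <- evaluate_model(m)$ce$icer
  params <- list(
    param_spec("Cost of sintilimab plus IBI305", "costs.sb_drugs",
               1763.8884, 0.8 * 1763.8884, 1.2 * 1763.8884, "gamma"),
    param_spec("Utility of SD", "utilities.sd", 0.76, 0.608, 0.912,
               "beta"),
    # zero-incidence AE: its cost cannot move the ICER
    param_spec("AE cost (inert)", "ae.costs.ppe", 16.63, 0, 33.26,
               "gamma"))
  m0 <- m
  m0$ae$incidence$sorafenib$ppe <- 0
  tw <- one_way(m0, params)
  expect_equal(tw$param[3], "AE cost (inert)")
  expect_equal(tw$spread[3], 0)
  # raising the regimen cost raises the ICER, lowering lowers it
  row <- tw[tw$param == "Cost of sintilimab plus IBI305", ]
  expect_gt(row$icer_at_high, base_icer)
  expect_lt(row$icer_at_low, base_icer)
  # degenerate +/-0% perturbation yields zero spread everywhere
  null_params <- lapply(params, function(p) {
    p$low <- p$base; p$high <- p$base; p
  })
  tw0 <- one_way(m0, null_params)
  expect_equal(tw0$spread, rep(0, 3))
  expect_error(one_way(m, list(param_spec("bad", "costs.nope", 1, 0, 2,
                                          "gamma"))),
               "cannot resolve")
})

test_that("threshold search hits the WTP and decreases with it", {
  b <- load_config()
  m <- resolve_scenario(b, "medicare")
  base_icer <- evaluate_model(m)$ce$icer
  # WTP at the base ICER: no reduction needed
  expect_equal(suppressMessages(
    as.numeric(threshold_price_reduction(m, wtp = base_icer + 1))), 0)
  red <- threshold_price_reduction(m, wtp = 38334)
  mult <- attr(red, "multiplier")
  m2 <- m
  m2$costs$sintilimab <- m2$costs$sintilimab * mult
  m2$costs$ibi305 <- m2$costs$ibi305 * mult
  expect_lt(abs(evaluate_model(m2)$ce$icer - 38334), 1)
  # monotone non-increasing in the willingness to pay
  wtps <- seq(40000, base_icer - 1000, length.out = 10)
  reds <- vapply(wtps, function(w) {
    as.numeric(threshold_price_reduction(m, wtp = w))
  }, numeric(1))
  expect_true(all(diff(reds) <= 1e-6))
})
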