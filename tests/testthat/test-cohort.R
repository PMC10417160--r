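test_that("transition matrices are row-stochastic at every cycle", {
  cfg <- model_config()
  s <- toy_strategy()
  for (k in c(1, 2, 10, 87, 174)) {
    m <- transition_matrix(s, k, cfg)
    expect_equal(unname(rowSums(m)), c(1, 1, 1), tolerance = 1e-12)
    expect_true(all(m >= 0 & m <= 1))
    # progression is irreversible, death absorbing
    expect_equal(m["pd", "sd"], 0)
    expect_equal(unname(m["dead", ]), c(0, 0, 1))
  }
  expect_error(transition_matrix(s, 0, cfg), "cycle_index")
})

test_that("cohort death fraction lies exactly on the fitted OS curve", {
  cfg <- model_config()
  for (s in list(toy_strategy(),
                 toy_strategy(os = so_os(), pfs = so_pfs()))) {
    tr <- run_cohort(s, cfg)
    expect_equal(tr$dead, 1 - survival_at(s$os, tr$t_months),
                 tolerance = 1e-10)
    # SD occupancy telescopes over the competing per-cycle exits
    u <- cfg$cycle_months
    tp_os <- cycle_transition_prob(s$os, u * (1:cfg$n_cycles), u)
    tp_pfs <- cycle_transition_prob(s$pfs, u * (1:cfg$n_cycles), u)
    stay <- 1 - tp_os - pmin(tp_pfs, 1 - tp_os)
    expect_equal(tr$sd, c(1, cumprod(stay)), tolerance = 1e-10)
  }
})

test_that("occupancy is conserved and monotone across random models", {
  for (seed in 1:100) {
    bundle <- random_model_config(seed = seed)
    model <- resolve_scenario(bundle, "list")
    strat <- build_strategies(model)[[sample(1:2, 1)]]
    tr <- run_cohort(strat, model$config)
    expect_equal(tr$sd + tr$pd + tr$dead, rep(1, nrow(tr)),
                 tolerance = 1e-12)
    expect_true(all(diff(tr$dead) >= -1e-12))
    expect_true(all(diff(tr$sd) <= 1e-12))
    expect_true(all(tr$sd >= 0 & tr$pd >= 0))
  }
})

test_that("zeroed costs and utilities produce zero totals", {
  cfg <- model_config()
  s <- toy_strategy(drug = 0, admin = 0, followup = 0, lab = 0,
                    subseq = 0, u_sd = 0, u_pd = 0)
  out <- evaluate_strategy(s, cfg)
  expect_equal(out$total_cost, 0)
  expect_equal(out$total_qalys, 0)
  expect_gt(out$total_lys, 0)
})

test_that("undiscounted QALYs at unit utility equal the OS restricted mean", {
  cfg <- model_config(discount_annual = 0)
  s <- toy_strategy(u_sd = 1, u_pd = 1)
  out <- evaluate_strategy(s, cfg)
  horizon <- cfg$n_cycles * cfg$cycle_months
  rmst <- stats::integrate(function(t) survival_at(s$os, t), 0, horizon,
                           subdivisions = 2000)$value / 12
  expect_equal(out$total_qalys, rmst, tolerance = 0.005)
  expect_equal(out$total_lys, rmst, tolerance = 0.005)
})

test_that("life-years approach the exponential mean at long horizons", {
  rate <- 0.08 # per month
  cfg <- model_config(horizon_years = 60, discount_annual = 0)
  s <- toy_strategy(os = surv_dist("exponential", rate = rate),
                    pfs = surv_dist("exponential", rate = rate * 2))
  out <- evaluate_strategy(s, cfg)
  expect_equal(out$total_lys, (1 / rate) / 12, tolerance = 0.01)
})

test_that("totals are linear in their per-cycle inputs", {
  cfg <- model_config()
  s1 <- toy_strategy()
  s2 <- toy_strategy(drug = 500, admin = 25, followup = 30, lab = 75,
                     subseq = 400)
  o1 <- evaluate_strategy(s1, cfg)
  o2 <- evaluate_strategy(s2, cfg)
  expect_equal(o2$total_cost, o1$total_cost / 2, tolerance = 1e-12)
  s3 <- toy_strategy(u_sd = 0.38, u_pd = 0.34)
  expect_equal(evaluate_strategy(s3, cfg)$total_qalys,
               o1$total_qalys / 2, tolerance = 1e-12)
})

test_that("adverse events enter as one-time expected flows at cycle 0", {
  cfg <- model_config()
  aes <- list(adverse_event("hypertension", 0.14, 155.56, -0.016),
              adverse_event("platelet", 0.08, 332.15, -0.146))
  s0 <- toy_strategy()
  s1 <- toy_strategy(aes = aes)
  o0 <- evaluate_strategy(s0, cfg)
  o1 <- evaluate_strategy(s1, cfg)
  expect_equal(o1$total_cost - o0$total_cost,
               0.14 * 155.56 + 0.08 * 332.15)
  expect_equal(o1$total_qalys - o0$total_qalys,
               0.14 * -0.016 + 0.08 * -0.146)
  expect_error(adverse_event("x", 1.4, 10, -0.1), "incidence")
  expect_error(adverse_event("x", 0.1, 10, 0.1), "disutility")
})

test_that("icer arithmetic and dominance classification", {
  out <- function(cost, qaly) {
    structure(list(name = "x", total_cost = cost, total_qalys = qaly,
                   total_lys = qaly), class = "strategy_outcome")
  }
  ce <- icer(out(44635.28, 1.30), out(27083.10, 0.97))
  expect_equal(ce$incr_cost, 17552.18)
  expect_equal(ce$incr_qaly, 0.33)
  expect_equal(ce$icer, 17552.18 / 0.33)
  expect_equal(ce$dominance, "tradeoff")
  expect_equal(icer(out(100, 2), out(200, 1))$dominance, "dominant")
  expect_equal(icer(out(200, 1), out(100, 2))$dominance, "dominated")
  same <- icer(out(100, 1), out(100, 1))
  expect_equal(same$incr_cost, 0)
  expect_equal(same$incr_qaly, 0)
  expect_true(is.na(same$icer))
})

test_that("Medicare pricing lowers both arms' costs and raises the ICER", {
  bundle <- load_config()
  res_list <- evaluate_model(resolve_scenario(bundle, "list"))
  res_medi <- evaluate_model(resolve_scenario(bundle, "medicare"))
  for (arm in c("sintilimab_ibi305", "sorafenib")) {
    expect_lt(res_medi$outcomes[[arm]]$total_cost,
              res_list$outcomes[[arm]]$total_cost)
    # utilities and survival are scenario-invariant
    expect_equal(res_medi$outcomes[[arm]]$total_qalys,
                 res_list$outcomes[[arm]]$total_qalys)
  }
  expect_gt(res_medi$ce$icer, res_list$ce$icer)
})

test_that("trace export writes one row per cycle", {
  cfg <- model_config()
  tr <- run_cohort(toy_strategy(), cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), cfg$n_cycles + 1)
  expect_named(back, c("cycle", "t_months", "sd", "pd", "dead",
                       "cost_cycle", "cost_disc", "qaly_cycle",
                       "qaly_disc", "ly_cycle", "ly_disc"))
})
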