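test_that("exponential MLE on uncensored data equals the analytic rate", {
  d <- simulate_ipd(surv_dist("exponential", rate = 0.2), 500, seed = 11)
  fit <- fit_mle(d, "exponential")
  expect_true(fit$converged)
  expect_equal(unname(fit$distribution$params["rate"]),
               sum(d$event) / sum(d$time), tolerance = 1e-5)
  # information criteria from their definitions (k = 1)
  expect_equal(fit$aic, 2 - 2 * fit$loglik)
  expect_equal(fit$bic, log(nrow(d)) - 2 * fit$loglik)
})

test_that("fitting recovers generating parameters", {
  # uncensored log-normal, n = 2000
  d <- simulate_ipd(surv_dist("lognormal", meanlog = 2.763, sdlog = 0.971),
                    2000, seed = 7)
  fit <- fit_mle(d, "lognormal")
  expect_lt(abs(fit$distribution$params[["meanlog"]] - 2.763), 0.06)
  expect_lt(abs(fit$distribution$params[["sdlog"]] - 0.971), 0.05)
  # administratively censored log-logistic
  d <- simulate_ipd(surv_dist("loglogistic", shape = 1.68, scale = 10.57),
                    2000, censoring = "administrative", t_max = 24,
                    seed = 8)
  expect_gt(mean(d$event == 0), 0.1) # censoring actually bites
  fit <- fit_mle(d, "loglogistic")
  expect_lt(abs(fit$distribution$params[["shape"]] - 1.68), 0.12)
  expect_lt(abs(fit$distribution$params[["scale"]] - 10.57), 0.5)
})

test_that("degenerate inputs are rejected", {
  expect_error(fit_mle(tibble::tibble(time = 1:5, event = 1), "weibull"),
               "at least 10")
  expect_error(
    fit_mle(tibble::tibble(time = 1:20, event = 0), "weibull"),
    "all records censored")
})

test_that("rank_fits sorts by AIC with BIC and family tie-breaks", {
  mk <- function(family, aic, bic) {
    structure(list(distribution = family_fixtures()[[family]],
                   loglik = 0, aic = aic, bic = bic, n = 100,
                   converged = TRUE), class = "fit_result")
  }
  fits <- list(mk("weibull", 510.2, 512), mk("lognormal", 498.7, 500),
               mk("gamma", 505.1, 506))
  ranked <- rank_fits(fits)
  expect_equal(vapply(ranked, `[[`, numeric(1), "aic"),
               c(498.7, 505.1, 510.2))
  # identical AIC: lower BIC first
  fits <- list(mk("weibull", 900, 900.1), mk("gamma", 900, 899.9))
  expect_equal(rank_fits(fits)[[1]]$distribution$family, "gamma")
  # identical AIC and BIC: canonical family order
  fits <- list(mk("gompertz", 900, 900), mk("weibull", 900, 900))
  expect_equal(rank_fits(fits)[[1]]$distribution$family, "weibull")
  expect_error(rank_fits(list()), "no fits")
  expect_error(rank_fits(list(mk("gamma", 1, 1),
                              structure(list(distribution = sb_os(),
                                             loglik = 0, aic = 1, bic = 1,
                                             n = 50, converged = TRUE),
                                        class = "fit_result"))),
               "different data")
})

test_that("model selection identifies the generating family at n = 2000", {
  d <- simulate_ipd(surv_dist("lognormal", meanlog = 1.6, sdlog = 1.03),
                    2000, seed = 21)
  best <- fit_families(d)[[1]]
  expect_equal(best$distribution$family, "lognormal")
})

test_that("selection recovers each fitted trial curve in most replicates", {
  # the four fitted endpoint curves; 10 seeded replicates each
  curves <- list(sb_os(), sb_pfs(), so_os(), so_pfs())
  for (gen in curves) {
    hits <- 0
    for (r in 1:10) {
      d <- simulate_ipd(gen, 2000, seed = 1000 + r)
      best <- fit_families(d)[[1]]
      hits <- hits + (best$distribution$family == gen$family)
    }
    expect_gte(hits, 9)
  }
})

test_that("fit reports round-trip through CSV", {
  d <- simulate_ipd(surv_dist("weibull", shape = 1.3, scale = 11), 300,
                    seed = 5)
  fits <- fit_families(d, c("weibull", "exponential"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_fit_report(fits, path)
  tab <- utils::read.csv(path)
  expect_equal(tab$family[1], fits[[1]]$distribution$family)
  expect_equal(tab$aic, vapply(fits, `[[`, numeric(1), "aic"))
  expect_match(tab$params[1], "^\\{\"shape\":")
})

test_that("IPD files round-trip through CSV", {
  d <- simulate_ipd(surv_dist("exponential", rate = 0.1), 50,
                    censoring = "administrative", t_max = 12, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ipd(d, path)
  expect_equal(read_ipd(path), d)
})
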