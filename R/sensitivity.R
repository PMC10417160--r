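#' Sensitivity-analysis parameter specification
#'
#' Binds one uncertain model input to its base value, its low/high
#' bounds (interpreted as a 95% interval for probabilistic sampling, and
#' used directly for one-way analysis) and a sampling family.
#'
#' Bindings are dot-separated paths into a resolved `cea_model`, e.g.
#' `"costs.ibi305"`, `"utilities.sd"`,
#' `"ae.incidence.sorafenib.ppe"`. The special binding
#' `"costs.sb_drugs"` addresses the combined sintilimab + IBI305
#' acquisition cost and scales both components proportionally.
#'
#' @param name Display name.
#' @param binding Dot path into the model (see Details).
#' @param base,low,high Base value and bounds, `low <= base <= high`.
#' @param psa_family `"gamma"` (costs), `"beta"` (probabilities,
#'   utilities and disutilities) or `"fixed"`.
#' @return A `param_spec` object.
#' @export
param_spec <- function(name, binding, base, low, high,
                       psa_family = c("gamma", "beta", "fixed")) {
  psa_family <- match.arg(psa_family)
  if (!(low <= base && base <= high)) {
    stop("parameter '", name, "': requires low <= base <= high",
         call. = FALSE)
  }
  if (psa_family == "beta" && base >= 0 && (base > 1 || high > 1)) {
    stop("parameter '", name, "': beta-bound values must lie in [0, 1]",
         call. = FALSE)
  }
  structure(list(name = name, binding = binding, base = base,
                 low = low, high = high, psa_family = psa_family),
            class = "param_spec")
}

#' Set one bound parameter in a resolved model
#'
#' @param model A `cea_model`.
#' @param binding Dot path (see [param_spec()]).
#' @param value New value.
#' @return The modified model.
#' @export
set_param <- function(model, binding, value) {
  if (identical(binding, "costs.sb_drugs")) {
    base <- model$costs$sintilimab + model$costs$ibi305
    r <- value / base
    model$costs$sintilimab <- model$costs$sintilimab * r
    model$costs$ibi305 <- model$costs$ibi305 * r
    return(model)
  }
  parts <- strsplit(binding, ".", fixed = TRUE)[[1]]
  cur <- tryCatch(model[[parts]], error = function(e) NULL)
  if (is.null(cur)) {
    stop("cannot resolve parameter binding '", binding, "'",
         call. = FALSE)
  }
  model[[parts]] <- value
  model
}

#' Default sensitivity-analysis parameter sets
#'
#' For the probabilistic analysis (`purpose = "psa"`): every ranged
#' input of the configuration — per-cycle costs (gamma), utilities
#' (beta), adverse-event incidences (beta), adverse-event costs (gamma)
#' and disutilities (beta on the magnitude) — with its configured
#' low/high treated as a 95% interval. Survival-curve parameters carry
#' no ranges and are held fixed.
#'
#' For the one-way tornado (`purpose = "one_way"`): the same inputs
#' varied by ±20% around base, with the sintilimab and IBI305
#' acquisition costs combined into a single regimen-cost parameter
#' (`"costs.sb_drugs"`), matching how the combination price is set in
#' practice.
#'
#' @param model A `cea_model` from [resolve_scenario()].
#' @param purpose `"psa"` or `"one_way"`.
#' @return List of [param_spec()] objects.
#' @export
default_param_specs <- function(model, purpose = c("psa", "one_way")) {
  purpose <- match.arg(purpose)
  fam_of <- function(binding) {
    if (grepl("^costs\\.", binding) || grepl("^ae\\.costs\\.", binding)) {
      "gamma"
    } else "beta"
  }
  label <- function(binding) {
    map <- c("costs.sintilimab" = "Cost of sintilimab",
             "costs.ibi305" = "Cost of IBI305",
             "costs.sb_drugs" = "Cost of sintilimab plus IBI305",
             "costs.sorafenib" = "Cost of sorafenib",
             "costs.regorafenib" = "Cost of regorafenib",
             "costs.followup" = "Follow-up cost",
             "costs.laboratory" = "Laboratory cost",
             "costs.administration" = "Administration cost",
             "utilities.sd" = "Utility of SD",
             "utilities.pd" = "Utility of PD")
    if (binding %in% names(map)) return(unname(map[binding]))
    gsub("ae.", "AE ", binding, fixed = TRUE)
  }
  at <- function(binding) {
    parts <- strsplit(binding, ".", fixed = TRUE)[[1]]
    model[[parts]]
  }
  if (purpose == "psa") {
    specs <- lapply(names(model$ranges), function(b) {
      r <- model$ranges[[b]]
      param_spec(label(b), b, at(b), r[["low"]], r[["high"]],
                 psa_family = fam_of(b))
    })
    return(specs)
  }
  # one-way: +/-20%, regimen cost combined
  bindings <- c("costs.sb_drugs", "costs.sorafenib", "costs.regorafenib",
                "costs.followup", "costs.laboratory",
                "costs.administration", "utilities.sd", "utilities.pd",
                grep("^ae\\.", names(model$ranges), value = TRUE))
  lapply(bindings, function(b) {
    base <- if (b == "costs.sb_drugs") {
      model$costs$sintilimab + model$costs$ibi305
    } else at(b)
    bounds <- sort(c(0.8, 1.2) * base)
    param_spec(label(b), b, base, bounds[1], bounds[2],
               psa_family = fam_of(b))
  })
}

eval_icer <- function(model) {
  evaluate_model(model)$ce
}

#' One-way (tornado) sensitivity analysis
#'
#' Re-evaluates the incremental cost-effectiveness ratio with each
#' parameter set to its low and high bound in turn, all others at base.
#'
#' @param model A `cea_model`.
#' @param params List of [param_spec()] objects; defaults to the ±20%
#'   one-way set of [default_param_specs()].
#' @return A `tornado` tibble sorted by decreasing ICER spread:
#'   `param`, `base`, `low`, `high`, `icer_at_low`, `icer_at_high`,
#'   `spread`; the base-case ICER is attached as attribute
#'   `base_icer`.
#' @export
one_way <- function(model, params = default_param_specs(model, "one_way")) {
  base_icer <- eval_icer(model)$icer
  rows <- lapply(params, function(p) {
    lo <- eval_icer(set_param(model, p$binding, p$low))$icer
    hi <- eval_icer(set_param(model, p$binding, p$high))$icer
    tibble::tibble(param = p$name, base = p$base, low = p$low,
                   high = p$high, icer_at_low = lo, icer_at_high = hi,
                   spread = abs(hi - lo))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$spread), ]
  structure(out, class = c("tornado", class(out)), base_icer = base_icer)
}

#' Threshold price-reduction analysis
#'
#' Finds, by bisection, the fractional reduction of the sintilimab +
#' IBI305 drug-acquisition cost at which the incremental
#' cost-effectiveness ratio equals the willingness-to-pay threshold.
#'
#' @param model A `cea_model`.
#' @param wtp Willingness-to-pay threshold, $/QALY; defaults to the
#'   model's configured value.
#' @param tol Convergence tolerance on `|ICER - wtp|`, $/QALY.
#' @param scale `"drug"` scales only the sintilimab + IBI305 per-cycle
#'   acquisition costs; `"all"` also scales the administration cost.
#' @return The required reduction as a fraction in `[0, 1]` (0 when the
#'   base-case ICER is already at or below `wtp`), with the price
#'   multiplier attached as attribute `multiplier`.
#' @export
threshold_price_reduction <- function(model, wtp = model$config$wtp,
                                      tol = 1,
                                      scale = c("drug", "all")) {
  scale <- match.arg(scale)
  icer_at <- function(m) {
    mod <- model
    mod$costs$sintilimab <- mod$costs$sintilimab * m
    mod$costs$ibi305 <- mod$costs$ibi305 * m
    if (scale == "all") {
      mod$costs$administration <- mod$costs$administration * m
    }
    ce <- eval_icer(mod)
    ce$incr_cost / ce$incr_qaly
  }
  base <- icer_at(1)
  if (is.na(base) || base <= wtp) {
    message("base-case ICER already at or below WTP; no reduction needed")
    return(structure(0, multiplier = 1))
  }
  lo <- 0; hi <- 1
  if (icer_at(0) > wtp) {
    message("ICER exceeds WTP even at zero drug cost")
    return(structure(1, multiplier = 0))
  }
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    v <- icer_at(mid)
    if (abs(v - wtp) < tol) break
    if (v > wtp) hi <- mid else lo <- mid
  }
  structure(1 - mid, multiplier = mid)
}

#' Sample one parameter for probabilistic analysis
#'
#' Beta and gamma draws are moment-matched to mean `base` and standard
#' deviation `(high - low)/3.92` (the bounds read as a 95% interval);
#' `"fixed"` returns the base value. Non-positive-valued parameters
#' (disutilities) are sampled as beta on their magnitude and negated.
#' If the implied variance is infeasible for a beta on `[0, 1]`, the
#' draw falls back to uniform on `[low, high]` with a warning.
#'
#' @param spec A [param_spec()].
#' @param n Number of draws.
#' @return Numeric vector of `n` draws (uses the session RNG).
#' @export
sample_param <- function(spec, n = 1) {
  if (spec$psa_family == "fixed") return(rep(spec$base, n))
  mu <- spec$base
  sigma <- (spec$high - spec$low) / 3.92
  if (sigma == 0) return(rep(mu, n))
  neg <- spec$psa_family == "beta" && mu < 0
  if (neg) {
    mu <- -mu
  }
  if (spec$psa_family == "gamma") {
    shape <- (mu / sigma)^2
    draws <- stats::rgamma(n, shape = shape, rate = mu / sigma^2)
  } else {
    if (sigma^2 >= mu * (1 - mu) || mu <= 0 || mu >= 1) {
      warning("parameter '", spec$name,
              "': beta moment match infeasible; sampling uniform(low, high)",
              call. = FALSE)
      draws <- if (neg) {
        stats::runif(n, min(abs(spec$low), abs(spec$high)),
                     max(abs(spec$low), abs(spec$high)))
      } else {
        stats::runif(n, spec$low, spec$high)
      }
    } else {
      nu <- mu * (1 - mu) / sigma^2 - 1
      draws <- stats::rbeta(n, mu * nu, (1 - mu) * nu)
    }
  }
  if (neg) -draws else draws
}

#' Probabilistic sensitivity analysis
#'
#' Draws every parameter from its assigned distribution, re-evaluates
#' both strategies per draw, and records the incremental cost and QALY.
#' Survival-curve parameters are held fixed (they carry no sampling
#' ranges), so the state-occupancy trace is common to all draws; the
#' per-draw totals are therefore computed exactly from the precomputed
#' discounted occupancy of each arm, which is algebraically identical to
#' re-running the cohort per draw. Draws are consumed
#' parameter-by-parameter in the order of `params`, making runs
#' bit-reproducible under a seed.
#'
#' @param model A `cea_model`.
#' @param params List of [param_spec()]s; defaults to the PSA set of
#'   [default_param_specs()].
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @return A `psa_draws` tibble: one row per draw with every sampled
#'   parameter (by name), per-strategy discounted cost and QALYs, and
#'   `incr_cost` / `incr_qaly`; attribute `wtp` carries the model's
#'   threshold.
#' @export
run_psa <- function(model, params = default_param_specs(model, "psa"),
                    n = 10000, seed = NULL) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  for (p in params) {
    # fail fast on unresolvable bindings
    invisible(set_param(model, p$binding, p$base))
  }
  draws <- lapply(params, sample_param, n = n)
  names(draws) <- vapply(params, `[[`, character(1), "name")
  occ <- lapply(build_strategies(model), function(s) {
    disc_occupancy(s, model$config)
  })
  res <- matrix(0, n, 4,
                dimnames = list(NULL, c("cost_sintilimab_ibi305",
                                        "qaly_sintilimab_ibi305",
                                        "cost_sorafenib",
                                        "qaly_sorafenib")))
  for (i in seq_len(n)) {
    m <- model
    for (j in seq_along(params)) {
      m <- set_param(m, params[[j]]$binding, draws[[j]][i])
    }
    strat <- build_strategies(m)
    sb <- totals_from_occupancy(strat$sintilimab_ibi305,
                                occ$sintilimab_ibi305)
    so <- totals_from_occupancy(strat$sorafenib, occ$sorafenib)
    res[i, ] <- c(sb$cost, sb$qaly, so$cost, so$qaly)
  }
  out <- tibble::as_tibble(c(list(draw = seq_len(n)), draws,
                             as.data.frame(res)))
  out$incr_cost <- out$cost_sintilimab_ibi305 - out$cost_sorafenib
  out$incr_qaly <- out$qaly_sintilimab_ibi305 - out$qaly_sorafenib
  structure(out, class = c("psa_draws", class(out)),
            wtp = model$config$wtp)
}

# discounted person-cycle accumulators of one strategy (occupancy does
# not depend on costs/utilities, so it can be shared across PSA draws)
disc_occupancy <- function(strategy, config) {
  trace <- run_cohort(strategy, config)
  K <- config$n_cycles
  if (config$half_cycle) {
    sd_k <- (trace$sd[-1] + trace$sd[-(K + 1)]) / 2
    pd_k <- (trace$pd[-1] + trace$pd[-(K + 1)]) / 2
    t_disc <- (seq_len(K) - 0.5) * config$cycle_months
  } else {
    sd_k <- trace$sd[-1]
    pd_k <- trace$pd[-1]
    t_disc <- seq_len(K) * config$cycle_months
  }
  v <- (1 + config$discount_annual)^(-t_disc / 12)
  list(A_sd = sum(sd_k * v), A_pd = sum(pd_k * v),
       uy = config$cycle_months / 12)
}

totals_from_occupancy <- function(strategy, occ) {
  cost_sd <- strategy$drug_cost_per_cycle + strategy$admin_cost_per_cycle +
    strategy$followup_cost_per_cycle + strategy$lab_cost_per_cycle
  cost_pd <- strategy$subsequent_tx_proportion *
    strategy$subsequent_tx_cost_per_cycle +
    strategy$followup_cost_per_cycle + strategy$lab_cost_per_cycle
  ae_cost <- sum(vapply(strategy$adverse_events,
                        function(a) a$incidence * a$cost, numeric(1)))
  ae_qaly <- sum(vapply(strategy$adverse_events,
                        function(a) a$incidence * a$disutility, numeric(1)))
  list(cost = occ$A_sd * cost_sd + occ$A_pd * cost_pd + ae_cost,
       qaly = (occ$A_sd * strategy$utility_sd +
                 occ$A_pd * strategy$utility_pd) * occ$uy + ae_qaly)
}

#' Probability of cost-effectiveness at one threshold
#'
#' Fraction of PSA draws with positive net monetary benefit,
#' `wtp * incr_qaly - incr_cost > 0`.
#'
#' @param draws A `psa_draws` tibble.
#' @param wtp Willingness-to-pay threshold; defaults to the threshold
#'   the PSA was run with.
#' @return A probability.
#' @export
prob_cost_effective <- function(draws, wtp = attr(draws, "wtp")) {
  mean(wtp * draws$incr_qaly - draws$incr_cost > 0)
}

#' Cost-effectiveness acceptability curve
#'
#' @param draws A `psa_draws` tibble.
#' @param wtp_grid Vector of thresholds, $/QALY.
#' @return Tibble `wtp`, `prob_cost_effective`.
#' @export
ceac <- function(draws, wtp_grid = seq(0, 100000, by = 2000)) {
  if (nrow(draws) < 1) stop("need at least one draw", call. = FALSE)
  tibble::tibble(
    wtp = wtp_grid,
    prob_cost_effective = vapply(wtp_grid, function(w) {
      prob_cost_effective(draws, w)
    }, numeric(1)))
}

#' Cost-effectiveness plane projection
#'
#' @param draws A `psa_draws` tibble.
#' @param wtp Reference threshold for the acceptability flag.
#' @return Tibble `incr_qaly`, `incr_cost`, `cost_effective`
#'   (net-monetary-benefit positivity at `wtp`).
#' @export
ce_plane <- function(draws, wtp = attr(draws, "wtp")) {
  if (nrow(draws) < 1) stop("need at least one draw", call. = FALSE)
  tibble::tibble(incr_qaly = draws$incr_qaly,
                 incr_cost = draws$incr_cost,
                 cost_effective = wtp * draws$incr_qaly -
                   draws$incr_cost > 0)
}

#' Export PSA draws to CSV
#'
#' @param draws A `psa_draws` tibble.
#' @param path Output path.
#' @export
write_psa <- function(draws, path) {
  utils::write.csv(as.data.frame(draws), path, row.names = FALSE)
  invisible(path)
}
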