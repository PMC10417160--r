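#' Markov model configuration
#'
#' Global settings of the three-state cohort model: a 21-day cycle, a
#' 10-year horizon, 5% annual discounting of both costs and utilities,
#' half-cycle correction, and the willingness-to-pay threshold (three
#' times China's 2021 GDP per capita, $38,334/QALY).
#'
#' The cycle length in months is `cycle_days / 30.4375` (average month).
#' The number of cycles is `ceiling(horizon_years * 12 / cycle_months)`
#' (174 for the defaults); the final cycle is kept whole.
#'
#' @param cycle_days Cycle length in days.
#' @param horizon_years Model horizon in years.
#' @param discount_annual Annual discount rate applied to costs, QALYs
#'   and life-years (`0 <= r < 1`).
#' @param half_cycle Apply the half-cycle (trapezoid) correction:
#'   per-cycle flows use the average of start- and end-of-cycle state
#'   occupancy and are discounted at mid-cycle.
#' @param wtp Willingness-to-pay threshold, $/QALY.
#' @return A `cea_config` object.
#' @export
model_config <- function(cycle_days = 21, horizon_years = 10,
                         discount_annual = 0.05, half_cycle = TRUE,
                         wtp = 38334) {
  if (cycle_days <= 0 || horizon_years <= 0) {
    stop("cycle_days and horizon_years must be positive", call. = FALSE)
  }
  if (discount_annual < 0 || discount_annual >= 1) {
    stop("discount_annual must be in [0, 1)", call. = FALSE)
  }
  cycle_months <- cycle_days / 30.4375
  structure(list(
    cycle_days = cycle_days,
    cycle_months = cycle_months,
    horizon_years = horizon_years,
    n_cycles = as.integer(ceiling(horizon_years * 12 / cycle_months)),
    discount_annual = discount_annual,
    half_cycle = isTRUE(half_cycle),
    wtp = wtp), class = "cea_config")
}

#' Adverse-event profile entry
#'
#' Grade 3-4 adverse events enter the model as a one-time expected cost
#' and QALY decrement applied at model start:
#' `sum(incidence * cost)` and `sum(incidence * disutility)`.
#'
#' @param name Event label.
#' @param incidence Probability of occurrence in `[0, 1]`.
#' @param cost One-time management cost, $ (non-negative).
#' @param disutility QALY decrement per occurrence (non-positive).
#' @return An `adverse_event` object.
#' @export
adverse_event <- function(name, incidence, cost, disutility) {
  if (incidence < 0 || incidence > 1) {
    stop("incidence must be in [0, 1]", call. = FALSE)
  }
  if (cost < 0) stop("cost must be non-negative", call. = FALSE)
  if (disutility > 0) stop("disutility must be <= 0", call. = FALSE)
  structure(list(name = name, incidence = incidence, cost = cost,
                 disutility = disutility), class = "adverse_event")
}

#' Treatment strategy specification
#'
#' One arm of the comparison: its fitted OS and PFS curves, per-cycle
#' costs by health state, the subsequent-therapy assumption in the
#' progressed state, health-state utilities, and the adverse-event
#' profile.
#'
#' While progression-free (SD) the cohort pays drug acquisition,
#' administration (intravenous regimens only), follow-up and laboratory
#' costs each cycle. After progression (PD) it pays
#' `subsequent_tx_proportion * subsequent_tx_cost_per_cycle` (second-line
#' regorafenib) plus follow-up and laboratory costs.
#'
#' @param name Strategy label.
#' @param os,pfs [surv_dist()] objects for overall and progression-free
#'   survival (months).
#' @param drug_cost_per_cycle Regimen acquisition cost per cycle in SD, $.
#' @param admin_cost_per_cycle Administration cost per cycle in SD, $.
#' @param followup_cost_per_cycle,lab_cost_per_cycle Disease-management
#'   costs per cycle, paid in both alive states, $.
#' @param subsequent_tx_proportion Fraction of progressed patients on
#'   second-line therapy.
#' @param subsequent_tx_cost_per_cycle Second-line regimen cost per
#'   cycle, $.
#' @param utility_sd,utility_pd Health-state utilities in `[0, 1]`.
#' @param adverse_events List of [adverse_event()] objects.
#' @return A `strategy_spec` object.
#' @export
strategy_spec <- function(name, os, pfs,
                          drug_cost_per_cycle,
                          admin_cost_per_cycle = 0,
                          followup_cost_per_cycle = 0,
                          lab_cost_per_cycle = 0,
                          subsequent_tx_proportion = 1,
                          subsequent_tx_cost_per_cycle = 0,
                          utility_sd = 0.76, utility_pd = 0.68,
                          adverse_events = list()) {
  stopifnot_surv_dist(os)
  stopifnot_surv_dist(pfs)
  costs <- c(drug_cost_per_cycle, admin_cost_per_cycle,
             followup_cost_per_cycle, lab_cost_per_cycle,
             subsequent_tx_cost_per_cycle)
  if (any(costs < 0)) stop("costs must be non-negative", call. = FALSE)
  if (subsequent_tx_proportion < 0 || subsequent_tx_proportion > 1) {
    stop("subsequent_tx_proportion must be in [0, 1]", call. = FALSE)
  }
  if (any(c(utility_sd, utility_pd) < 0) ||
      any(c(utility_sd, utility_pd) > 1)) {
    stop("utilities must be in [0, 1]", call. = FALSE)
  }
  structure(list(
    name = name, os = os, pfs = pfs,
    drug_cost_per_cycle = drug_cost_per_cycle,
    admin_cost_per_cycle = admin_cost_per_cycle,
    followup_cost_per_cycle = followup_cost_per_cycle,
    lab_cost_per_cycle = lab_cost_per_cycle,
    subsequent_tx_proportion = subsequent_tx_proportion,
    subsequent_tx_cost_per_cycle = subsequent_tx_cost_per_cycle,
    utility_sd = utility_sd, utility_pd = utility_pd,
    adverse_events = adverse_events), class = "strategy_spec")
}

#' Per-cycle transition matrix
#'
#' Builds the 3x3 row-stochastic matrix for the cycle ending at
#' `t = cycle_index * u` from the conditional survival probabilities
#' `tp_os = 1 - OS(t)/OS(t-u)` and `tp_pfs = 1 - PFS(t)/PFS(t-u)`.
#'
#' Exits from SD compete: patients die with probability `tp_os`,
#' progress with probability `min(tp_pfs, 1 - tp_os)`, and otherwise
#' remain progression-free. Progressed patients die at the same OS
#' conditional probability `tp_os`; death is absorbing and progression
#' is irreversible. Because every alive state loses exactly `tp_os` to
#' death each cycle, the cohort's cumulative death fraction telescopes
#' onto `1 - OS(t)` exactly, keeping the model on the fitted OS curve.
#'
#' @param strategy A [strategy_spec()].
#' @param cycle_index Cycle number (1-based).
#' @param config A [model_config()].
#' @return 3x3 matrix with rows/columns `sd`, `pd`, `dead`; each row
#'   sums to 1.
#' @export
transition_matrix <- function(strategy, cycle_index, config) {
  if (cycle_index < 1) stop("cycle_index must be >= 1", call. = FALSE)
  u <- config$cycle_months
  t <- cycle_index * u
  tp_pfs <- cycle_transition_prob(strategy$pfs, t, u)
  tp_os <- cycle_transition_prob(strategy$os, t, u)
  sd_to_pd <- min(tp_pfs, 1 - tp_os)
  m <- rbind(c(1 - tp_os - sd_to_pd, sd_to_pd, tp_os),
             c(0, 1 - tp_os, tp_os),
             c(0, 0, 1))
  dimnames(m) <- list(c("sd", "pd", "dead"), c("sd", "pd", "dead"))
  m
}

#' Run the cohort simulation for one strategy
#'
#' Starts the whole cohort progression-free and propagates state
#' occupancy through [transition_matrix()] to the horizon, accruing
#' discounted, half-cycle-corrected costs, QALYs and life-years.
#'
#' Per-cycle flows: SD pays drug + administration + follow-up +
#' laboratory; PD pays the subsequent-therapy cost (weighted by the
#' treated proportion) + follow-up + laboratory; QALYs accrue at
#' `utility_sd`/`utility_pd` per life-year. With the half-cycle
#' correction, flows for cycle `k` use the mean of the occupancy at the
#' start and end of the cycle and are discounted at mid-cycle,
#' `(1 + r)^(-(k - 1/2) u / 12)`; otherwise end-of-cycle occupancy and
#' discounting apply. The expected one-time adverse-event cost and
#' disutility are charged undiscounted at model start (cycle 0).
#'
#' @param strategy A [strategy_spec()].
#' @param config A [model_config()].
#' @return A `cohort_trace`: tibble with one row per cycle (`cycle`,
#'   `t_months`, `sd`, `pd`, `dead`, `cost_cycle`, `cost_disc`,
#'   `qaly_cycle`, `qaly_disc`, `ly_cycle`, `ly_disc`). Row `cycle = 0`
#'   holds the initial occupancy and the one-time adverse-event flows.
#' @export
run_cohort <- function(strategy, config) {
  K <- config$n_cycles
  u <- config$cycle_months
  occ <- matrix(0, K + 1, 3,
                dimnames = list(NULL, c("sd", "pd", "dead")))
  occ[1, ] <- c(1, 0, 0)
  for (k in seq_len(K)) {
    occ[k + 1, ] <- occ[k, ] %*% transition_matrix(strategy, k, config)
  }
  sd_occ <- occ[, "sd"]; pd_occ <- occ[, "pd"]
  if (config$half_cycle) {
    sd_k <- (sd_occ[-1] + sd_occ[-(K + 1)]) / 2
    pd_k <- (pd_occ[-1] + pd_occ[-(K + 1)]) / 2
    t_disc <- (seq_len(K) - 0.5) * u
  } else {
    sd_k <- sd_occ[-1]
    pd_k <- pd_occ[-1]
    t_disc <- seq_len(K) * u
  }
  v <- (1 + config$discount_annual)^(-t_disc / 12)
  cost_sd <- strategy$drug_cost_per_cycle + strategy$admin_cost_per_cycle +
    strategy$followup_cost_per_cycle + strategy$lab_cost_per_cycle
  cost_pd <- strategy$subsequent_tx_proportion *
    strategy$subsequent_tx_cost_per_cycle +
    strategy$followup_cost_per_cycle + strategy$lab_cost_per_cycle
  uy <- u / 12
  cost_cycle <- sd_k * cost_sd + pd_k * cost_pd
  qaly_cycle <- (sd_k * strategy$utility_sd + pd_k * strategy$utility_pd) * uy
  ly_cycle <- (sd_k + pd_k) * uy
  ae_cost <- sum(vapply(strategy$adverse_events,
                        function(a) a$incidence * a$cost, numeric(1)))
  ae_qaly <- sum(vapply(strategy$adverse_events,
                        function(a) a$incidence * a$disutility, numeric(1)))
  cost_all <- c(ae_cost, cost_cycle)
  cost_disc <- c(ae_cost, cost_cycle * v)
  qaly_all <- c(ae_qaly, qaly_cycle)
  qaly_disc <- c(ae_qaly, qaly_cycle * v)
  ly_all <- c(0, ly_cycle)
  ly_disc <- c(0, ly_cycle * v)
  trace <- tibble::tibble(
    cycle = 0:K,
    t_months = (0:K) * u,
    sd = sd_occ, pd = pd_occ, dead = occ[, "dead"],
    cost_cycle = cost_all,
    cost_disc = cost_disc,
    qaly_cycle = qaly_all,
    qaly_disc = qaly_disc,
    ly_cycle = ly_all,
    ly_disc = ly_disc)
  structure(trace, class = c("cohort_trace", class(trace)),
            strategy = strategy$name, config = config)
}

#' Total discounted outcomes for one strategy
#'
#' @param strategy A [strategy_spec()].
#' @param config A [model_config()].
#' @return A `strategy_outcome`: list with `name`, `total_cost`,
#'   `total_qalys`, `total_lys` (all discounted).
#' @export
evaluate_strategy <- function(strategy, config) {
  trace <- run_cohort(strategy, config)
  outcome_from_trace(trace, strategy$name)
}

outcome_from_trace <- function(trace, name) {
  structure(list(name = name,
                 total_cost = sum(trace$cost_disc),
                 total_qalys = sum(trace$qaly_disc),
                 total_lys = sum(trace$ly_disc)),
            class = "strategy_outcome")
}

#' @export
print.strategy_outcome <- function(x, ...) {
  cat(sprintf("<strategy_outcome> %s: cost $%.2f, %.4f QALYs, %.4f LYs\n",
              x$name, x$total_cost, x$total_qalys, x$total_lys))
  invisible(x)
}

#' Incremental cost-effectiveness ratio
#'
#' @param intervention,comparator `strategy_outcome` objects.
#' @return A `ce_result`: list with `incr_cost`, `incr_qaly`, `icer`
#'   ($/QALY; `NA` when the QALY increment is zero) and `dominance`, one
#'   of `"dominant"` (intervention cheaper and at least as effective, or
#'   more effective and no dearer), `"dominated"` (the reverse) or
#'   `"tradeoff"`.
#' @export
icer <- function(intervention, comparator) {
  dc <- intervention$total_cost - comparator$total_cost
  dq <- intervention$total_qalys - comparator$total_qalys
  if (dq == 0) {
    ratio <- NA_real_
    dominance <- if (dc < 0) "dominant" else if (dc > 0) "dominated"
                 else "tradeoff"
  } else {
    ratio <- dc / dq
    dominance <- if (dq > 0 && dc <= 0) "dominant"
                 else if (dq < 0 && dc >= 0) "dominated"
                 else "tradeoff"
  }
  structure(list(intervention = intervention$name,
                 comparator = comparator$name,
                 incr_cost = dc, incr_qaly = dq, icer = ratio,
                 dominance = dominance), class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  cat(sprintf("<ce_result> %s vs %s\n", x$intervention, x$comparator))
  cat(sprintf("  incremental cost  $%.2f\n", x$incr_cost))
  cat(sprintf("  incremental QALY  %.4f\n", x$incr_qaly))
  if (is.na(x$icer)) {
    cat("  ICER              undefined (zero QALY increment)\n")
  } else {
    cat(sprintf("  ICER              $%.2f/QALY\n", x$icer))
  }
  cat("  dominance         ", x$dominance, "\n", sep = "")
  invisible(x)
}

#' Export a cohort trace to CSV
#'
#' @param trace A `cohort_trace` from [run_cohort()].
#' @param path Output path.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
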