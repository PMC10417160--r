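# Table-1 fitted curves, used across tests
sb_os <- function() surv_dist("lognormal", meanlog = 2.763, sdlog = 0.971)
sb_pfs <- function() surv_dist("lognormal", meanlog = 1.60, sdlog = 1.03)
so_os <- function() surv_dist("loglogistic", shape = 1.68, scale = 10.57)
so_pfs <- function() surv_dist("lognormal", meanlog = 1.115, sdlog = 0.781)

# one fixed distribution per family, medians in a plausible range
family_fixtures <- function() {
  list(
    exponential = surv_dist("exponential", rate = 0.12),
    weibull     = surv_dist("weibull", shape = 1.3, scale = 11),
    gamma       = surv_dist("gamma", shape = 1.8, rate = 0.16),
    lognormal   = surv_dist("lognormal", meanlog = 2.0, sdlog = 0.9),
    loglogistic = surv_dist("loglogistic", shape = 1.68, scale = 10.57),
    gompertz    = surv_dist("gompertz", shape = 0.05, rate = 0.06))
}

# a bare two-state strategy with unit costs for cohort-engine tests
toy_strategy <- function(os = sb_os(), pfs = sb_pfs(),
                         drug = 1000, admin = 50, followup = 60,
                         lab = 150, prop = 1, subseq = 800,
                         u_sd = 0.76, u_pd = 0.68, aes = list()) {
  strategy_spec("toy", os = os, pfs = pfs,
                drug_cost_per_cycle = drug, admin_cost_per_cycle = admin,
                followup_cost_per_cycle = followup,
                lab_cost_per_cycle = lab,
                subsequent_tx_proportion = prop,
                subsequent_tx_cost_per_cycle = subseq,
                utility_sd = u_sd, utility_pd = u_pd,
                adverse_events = aes)
}

# numbers-at-risk table computed from simulated records
risk_table_from_ipd <- function(data, times) {
  tibble::tibble(
    time = times,
    n_at_risk = vapply(times, function(t) sum(data$time >= t), numeric(1)))
}
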