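#' Simulate censored individual patient data
#'
#' Draws event times from a parametric survival distribution by inverse
#' CDF sampling and applies an optional censoring mechanism; stands in
#' for trial-level time-to-event data when exercising the fitting and
#' reconstruction paths end to end.
#'
#' @param dist A [surv_dist()] object.
#' @param n Number of patients.
#' @param censoring `"none"`, `"administrative"` (cut-off at `t_max`) or
#'   `"exponential"` (independent random censoring with rate
#'   `censor_rate`).
#' @param t_max Administrative censoring time (months).
#' @param censor_rate Rate of the exponential censoring distribution
#'   (per month).
#' @param seed Optional integer seed; identical seeds give identical
#'   records.
#' @return IPD tibble (`time`, `event`).
#' @export
simulate_ipd <- function(dist, n,
                         censoring = c("none", "administrative",
                                       "exponential"),
                         t_max = NULL, censor_rate = NULL, seed = NULL) {
  censoring <- match.arg(censoring)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  t_event <- random_survival_times(dist, n)
  if (censoring == "none") {
    return(tibble::tibble(time = t_event, event = rep(1, n)))
  }
  if (censoring == "administrative") {
    if (is.null(t_max) || t_max <= 0) {
      stop("administrative censoring needs t_max > 0", call. = FALSE)
    }
    event <- as.numeric(t_event <= t_max)
    return(tibble::tibble(time = pmin(t_event, t_max), event = event))
  }
  if (is.null(censor_rate) || censor_rate <= 0) {
    stop("exponential censoring needs censor_rate > 0", call. = FALSE)
  }
  t_cens <- stats::rexp(n, censor_rate)
  tibble::tibble(time = pmin(t_event, t_cens),
                 event = as.numeric(t_event <= t_cens))
}

#' Emulate graph digitization of a KM curve
#'
#' Samples `n_points` positions along a Kaplan-Meier step function and
#' perturbs the survival values with truncated Gaussian noise, mimicking
#' manual curve extraction. Point placement is event-weighted by default
#' (denser where the curve drops, as a human digitizer works); the
#' perturbed points are re-monotonized with [clean_curve()].
#'
#' @param curve Curve points (`time`, `survival`), e.g. from
#'   [km_estimate()].
#' @param n_points Number of digitized points to keep.
#' @param jitter_sd Standard deviation of the survival-axis noise; 0
#'   returns points exactly on the step function.
#' @param seed Optional integer seed.
#' @param placement `"events"` (drop-weighted) or `"uniform"` (equally
#'   spaced over the curve's time span).
#' @return A cleaned curve tibble (`time`, `survival`).
#' @export
digitize_km <- function(curve, n_points, jitter_sd = 0, seed = NULL,
                        placement = c("events", "uniform")) {
  placement <- match.arg(placement)
  curve <- clean_curve(curve)
  if (!is.null(seed)) set.seed(seed)
  tmax <- max(curve$time)
  if (placement == "uniform") {
    times <- seq(0, tmax, length.out = n_points)
  } else {
    drops <- -diff(curve$survival)
    step_t <- curve$time[-1]
    keep <- drops > 0
    if (!any(keep)) {
      times <- seq(0, tmax, length.out = n_points)
    } else {
      # follow the curve the way a human digitizer does: pick the step
      # times sitting at evenly spaced quantiles of cumulative drop, so
      # point density tracks curve movement (deterministic)
      cand <- step_t[keep]
      cum <- cumsum(drops[keep])
      targets <- seq(0, cum[length(cum)], length.out = n_points)
      idx <- unique(findInterval(targets, cum, rightmost.closed = TRUE,
                                 left.open = TRUE) + 1L)
      idx <- idx[idx <= length(cand)]
      times <- sort(unique(c(0, tmax, cand[idx])))
    }
  }
  s <- km_at(curve, times)
  if (jitter_sd > 0) {
    s <- pmin(pmax(s + stats::rnorm(length(s), 0, jitter_sd), 0), 1)
    s[times == 0] <- 1
  }
  clean_curve(tibble::tibble(time = times, survival = s))
}

#' Random, valid two-strategy model configuration
#'
#' Draws a complete configuration bundle — survival distributions,
#' costs, utilities, adverse events, model settings — from wide but
#' sane ranges. Every draw passes [load_config()]-level validation and
#' runs end to end; intended for property-style testing of the cohort
#' engine and sensitivity machinery.
#'
#' @param seed Optional integer seed.
#' @return A validated `cea_bundle`.
#' @export
random_model_config <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rng <- function(base, spread = 0.2) {
    list(base = base, low = base * (1 - spread) - 1e-9,
         high = base * (1 + spread) + 1e-9)
  }
  rng_neg <- function(base, spread = 0.2) {
    list(base = base, low = base * (1 + spread) - 1e-9,
         high = base * (1 - spread) + 1e-9)
  }
  rand_dist <- function(median_lo, median_hi) {
    med <- stats::runif(1, median_lo, median_hi)
    fam <- sample(c("lognormal", "loglogistic", "weibull",
                    "exponential"), 1)
    switch(fam,
      lognormal = list(family = "lognormal", meanlog = log(med),
                       sdlog = stats::runif(1, 0.5, 1.2)),
      loglogistic = list(family = "loglogistic",
                         shape = stats::runif(1, 1.2, 2.5), scale = med),
      weibull = list(family = "weibull",
                     shape = stats::runif(1, 0.8, 1.8),
                     scale = med / log(2)^(1 / 1.2)),
      exponential = list(family = "exponential", rate = log(2) / med))
  }
  u_sd <- stats::runif(1, 0.6, 0.9)
  u_pd <- stats::runif(1, 0.4, u_sd)
  raw <- list(
    model = list(cycle_days = 21, horizon_years = 10,
                 discount_annual = stats::runif(1, 0, 0.08),
                 half_cycle = TRUE, wtp = stats::runif(1, 2e4, 6e4)),
    survival = list(
      sintilimab_ibi305 = list(os = rand_dist(10, 25),
                               pfs = rand_dist(3, 9)),
      sorafenib = list(os = rand_dist(6, 15), pfs = rand_dist(2, 6))),
    costs = list(
      sintilimab = rng(stats::runif(1, 100, 600)),
      sintilimab_medicare = rng(stats::runif(1, 50, 300)),
      ibi305 = rng(stats::runif(1, 500, 2500)),
      sorafenib = rng(stats::runif(1, 400, 2000)),
      sorafenib_medicare = rng(stats::runif(1, 200, 1000)),
      regorafenib = rng(stats::runif(1, 300, 1200)),
      followup = rng(stats::runif(1, 20, 120)),
      laboratory = rng(stats::runif(1, 50, 300)),
      administration = rng(stats::runif(1, 20, 120))),
    utilities = list(
      sd = list(base = u_sd, low = u_sd * 0.8, high = min(u_sd * 1.2, 1)),
      pd = list(base = u_pd, low = u_pd * 0.8, high = min(u_pd * 1.2, 1))),
    subsequent_treatment = list(
      sintilimab_ibi305 = stats::runif(1),
      sorafenib = stats::runif(1)),
    adverse_events = list(
      costs = list(ppe = rng(stats::runif(1, 5, 50)),
                   platelet = rng(stats::runif(1, 100, 500)),
                   hypertension = rng(stats::runif(1, 50, 300))),
      disutilities = list(ppe = rng_neg(-stats::runif(1, 0.05, 0.2)),
                          platelet = rng_neg(-stats::runif(1, 0.05, 0.2)),
                          hypertension = rng_neg(-stats::runif(1, 0.005, 0.05))),
      incidence = list(
        sintilimab_ibi305 = list(
          hypertension = rng(stats::runif(1, 0.02, 0.3)),
          platelet = rng(stats::runif(1, 0.02, 0.3))),
        sorafenib = list(
          ppe = rng(stats::runif(1, 0.02, 0.3)),
          hypertension = rng(stats::runif(1, 0.02, 0.3)),
          platelet = rng(stats::runif(1, 0.02, 0.3))))))
  validate_bundle(raw)
}
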