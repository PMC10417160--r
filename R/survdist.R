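#' Parametric survival distributions
#'
#' Constructor for the six parametric survival families used to
#' extrapolate progression-free and overall survival beyond trial
#' follow-up. Times are in months throughout the package.
#'
#' Parameterizations follow the usual survival-analysis conventions
#' (those of the \pkg{flexsurv} package):
#' \describe{
#'   \item{exponential}{`rate`; hazard constant at `rate`.}
#'   \item{weibull}{`shape`, `scale`; \eqn{S(t) = \exp\{-(t/scale)^{shape}\}}.}
#'   \item{gamma}{`shape`, `rate`.}
#'   \item{lognormal}{`meanlog`, `sdlog`; \eqn{S(t) = 1 - \Phi((\log t - meanlog)/sdlog)}.}
#'   \item{loglogistic}{`shape`, `scale`; \eqn{S(t) = 1/(1 + (t/scale)^{shape})}.}
#'   \item{gompertz}{`shape`, `rate`; hazard \eqn{rate \cdot e^{shape \cdot t}}.}
#' }
#'
#' @param family One of `"exponential"`, `"weibull"`, `"gamma"`,
#'   `"lognormal"`, `"loglogistic"`, `"gompertz"`.
#' @param ... Named parameters for the family (see Details). Scale, rate,
#'   sdlog and non-Gompertz shape parameters must be strictly positive;
#'   the Gompertz shape and the log-normal meanlog may be any real.
#' @return An object of class `surv_dist`.
#' @examples
#' d <- surv_dist("lognormal", meanlog = 2.763, sdlog = 0.971)
#' survival_at(d, exp(2.763)) # 0.5, the median
#' @export
surv_dist <- function(family, ...) {
  family <- match.arg(family, surv_families())
  params <- c(...)
  expected <- surv_param_names(family)
  if (!identical(sort(names(params)), sort(expected))) {
    stop("family '", family, "' needs parameters: ",
         paste(expected, collapse = ", "), call. = FALSE)
  }
  params <- params[expected]
  if (any(!is.finite(params))) {
    stop("non-finite parameter for family '", family, "'", call. = FALSE)
  }
  # parameters that must be strictly positive
  pos <- setdiff(expected, c("meanlog", if (family == "gompertz") "shape"))
  bad <- pos[params[pos] <= 0]
  if (length(bad)) {
    stop("parameter(s) ", paste(bad, collapse = ", "),
         " must be strictly positive for family '", family, "'",
         call. = FALSE)
  }
  structure(list(family = family, params = params, time_unit = "months"),
            class = "surv_dist")
}

#' @export
print.surv_dist <- function(x, ...) {
  cat("<surv_dist> ", x$family, "(",
      paste(names(x$params), signif(x$params, 6), sep = " = ",
            collapse = ", "),
      "), time in ", x$time_unit, "\n", sep = "")
  invisible(x)
}

#' Supported survival families
#'
#' @return Character vector of the six family names, in canonical order
#'   (used for tie-breaking when ranking fits).
#' @export
surv_families <- function() {
  c("exponential", "weibull", "gamma", "lognormal", "loglogistic",
    "gompertz")
}

surv_param_names <- function(family) {
  switch(family,
    exponential = "rate",
    weibull     = c("shape", "scale"),
    gamma       = c("shape", "rate"),
    lognormal   = c("meanlog", "sdlog"),
    loglogistic = c("shape", "scale"),
    gompertz    = c("shape", "rate"))
}

stopifnot_surv_dist <- function(dist) {
  if (!inherits(dist, "surv_dist")) {
    stop("expected a 'surv_dist' object", call. = FALSE)
  }
}

dist_fun <- function(dist, what = c("p", "d", "q", "r")) {
  what <- match.arg(what)
  p <- as.list(dist$params)
  switch(dist$family,
    exponential = switch(what,
      p = function(t) stats::pexp(t, p$rate, lower.tail = FALSE),
      d = function(t) stats::dexp(t, p$rate),
      q = function(u) stats::qexp(u, p$rate),
      r = function(n) stats::rexp(n, p$rate)),
    weibull = switch(what,
      p = function(t) stats::pweibull(t, p$shape, p$scale, lower.tail = FALSE),
      d = function(t) stats::dweibull(t, p$shape, p$scale),
      q = function(u) stats::qweibull(u, p$shape, p$scale),
      r = function(n) stats::rweibull(n, p$shape, p$scale)),
    gamma = switch(what,
      p = function(t) stats::pgamma(t, p$shape, p$rate, lower.tail = FALSE),
      d = function(t) stats::dgamma(t, p$shape, p$rate),
      q = function(u) stats::qgamma(u, p$shape, p$rate),
      r = function(n) stats::rgamma(n, p$shape, p$rate)),
    lognormal = switch(what,
      p = function(t) stats::plnorm(t, p$meanlog, p$sdlog, lower.tail = FALSE),
      d = function(t) stats::dlnorm(t, p$meanlog, p$sdlog),
      q = function(u) stats::qlnorm(u, p$meanlog, p$sdlog),
      r = function(n) stats::rlnorm(n, p$meanlog, p$sdlog)),
    loglogistic = switch(what,
      p = function(t) flexsurv::pllogis(t, p$shape, p$scale, lower.tail = FALSE),
      d = function(t) flexsurv::dllogis(t, p$shape, p$scale),
      q = function(u) flexsurv::qllogis(u, p$shape, p$scale),
      r = function(n) flexsurv::rllogis(n, p$shape, p$scale)),
    gompertz = switch(what,
      p = function(t) flexsurv::pgompertz(t, p$shape, p$rate, lower.tail = FALSE),
      d = function(t) flexsurv::dgompertz(t, p$shape, p$rate),
      q = function(u) flexsurv::qgompertz(u, p$shape, p$rate),
      r = function(n) flexsurv::rgompertz(n, p$shape, p$rate)))
}

#' Survival function S(t)
#'
#' @param dist A [surv_dist()] object.
#' @param t Vector of non-negative times (months).
#' @return S(t) in `[0, 1]`, same length as `t`.
#' @export
survival_at <- function(dist, t) {
  stopifnot_surv_dist(dist)
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  dist_fun(dist, "p")(t)
}

#' Hazard function h(t)
#'
#' @inheritParams survival_at
#' @return Instantaneous hazard at `t`.
#' @export
hazard_at <- function(dist, t) {
  stopifnot_surv_dist(dist)
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  dist_fun(dist, "d")(t) / pmax(dist_fun(dist, "p")(t), 1e-300)
}

#' Median survival time
#'
#' Closed forms are used where they exist (exponential, Weibull,
#' log-normal, log-logistic); the gamma and Gompertz medians come from
#' the corresponding quantile functions.
#'
#' @param dist A [surv_dist()] object.
#' @return The time `t` at which `S(t) = 0.5`, in months.
#' @export
median_survival <- function(dist) {
  stopifnot_surv_dist(dist)
  p <- as.list(dist$params)
  switch(dist$family,
    exponential = log(2) / p$rate,
    weibull     = p$scale * log(2)^(1 / p$shape),
    lognormal   = exp(p$meanlog),
    loglogistic = p$scale,
    dist_fun(dist, "q")(0.5))
}

#' Per-cycle transition probability from a survival curve
#'
#' Converts a survival curve into the conditional probability of leaving
#' the curve's event-free set during the cycle ending at `t`:
#' \eqn{tp(t) = 1 - S(t)/S(t - u)}. Consecutive cycles telescope, so the
#' product of per-cycle survival probabilities over cycles `1..K`
#' recovers `S(K u)` exactly. The denominator is floored at `1e-12`;
#' once the curve is exhausted the transition is absorbing (returns 1).
#'
#' @param dist A [surv_dist()] object.
#' @param t End time of the cycle (months); vectorized. The first cycle
#'   uses `t = u`, giving `1 - S(u)/S(0) = 1 - S(u)`.
#' @param u Cycle length (months), positive scalar.
#' @return Probabilities in `[0, 1]`, same length as `t`.
#' @export
cycle_transition_prob <- function(dist, t, u) {
  stopifnot_surv_dist(dist)
  if (length(u) != 1 || u <= 0) stop("u must be a positive scalar", call. = FALSE)
  if (any(t < u - 1e-12 & t != 0)) {
    stop("t must be 0 or at least u", call. = FALSE)
  }
  s1 <- survival_at(dist, pmax(t, 0))
  s0 <- survival_at(dist, pmax(t - u, 0))
  tp <- ifelse(s0 <= 1e-12, 1, 1 - s1 / pmax(s0, 1e-12))
  pmin(pmax(tp, 0), 1)
}

#' Draw random survival times
#'
#' @param dist A [surv_dist()] object.
#' @param n Number of draws.
#' @return Vector of `n` event times (months). Uses the session RNG;
#'   wrap in [withr::with_seed] or call `set.seed()` for reproducibility.
#' @keywords internal
random_survival_times <- function(dist, n) {
  stopifnot_surv_dist(dist)
  # inverse-CDF so that a single runif stream drives every family
  dist_fun(dist, "q")(stats::runif(n))
}
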