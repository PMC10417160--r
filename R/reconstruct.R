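#' Repair a digitized Kaplan-Meier curve
#'
#' Graph digitization introduces small ordering and rounding errors.
#' `clean_curve` sorts points by time, clamps survival to `[0, 1]`,
#' enforces monotone non-increase by isotonic clipping (each value is
#' capped at the running minimum of its predecessors), and prepends the
#' anchor point `(0, 1)` when absent. Already-clean curves pass through
#' unchanged.
#'
#' @param points Data frame with columns `time` and `survival`.
#' @return A tibble `time`, `survival` forming a valid monotone curve.
#' @export
clean_curve <- function(points) {
  if (!all(c("time", "survival") %in% names(points))) {
    stop("curve needs columns 'time' and 'survival'", call. = FALSE)
  }
  if (nrow(points) < 2) {
    stop("need at least 2 digitized points", call. = FALSE)
  }
  ord <- order(points$time)
  t <- as.numeric(points$time[ord])
  s <- pmin(pmax(as.numeric(points$survival[ord]), 0), 1)
  if (any(t < 0)) stop("times must be non-negative", call. = FALSE)
  if (t[1] > 0 || s[1] < 1) {
    t <- c(0, t)
    s <- c(1, s)
  }
  s <- cummin(s)
  tibble::tibble(time = t, survival = s)
}

#' Kaplan-Meier estimate from individual patient data
#'
#' Standard product-limit estimator (via [survival::survfit()]),
#' returned as a step function sampled at the event times only, with the
#' anchor `(0, 1)` prepended.
#'
#' @param data IPD data frame (`time`, `event`).
#' @return A tibble of curve points `time`, `survival`.
#' @export
km_estimate <- function(data) {
  data <- validate_ipd(data)
  if (nrow(data) < 1) stop("need at least one record", call. = FALSE)
  if (!any(data$event == 1)) {
    return(tibble::tibble(time = 0, survival = 1))
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = data)
  keep <- fit$n.event > 0
  tibble::tibble(time = c(0, fit$time[keep]),
                 survival = c(1, fit$surv[keep]))
}

#' Evaluate a KM step function at arbitrary times
#'
#' @param curve Curve points (`time`, `survival`), e.g. from
#'   [km_estimate()].
#' @param t Times at which to evaluate (right-continuous step).
#' @return Survival values at `t`.
#' @export
km_at <- function(curve, t) {
  stats::approx(curve$time, curve$survival, xout = t, method = "constant",
                f = 0, yleft = 1, rule = 2)$y
}

#' Reconstruct pseudo-individual patient data from a digitized curve
#'
#' Interval-wise reconstruction of event and censoring times from
#' digitized Kaplan-Meier coordinates and a numbers-at-risk table
#' (the Guyot algorithm). Within each risk-table interval the number of
#' censorings is chosen so that the implied number still at risk at the
#' start of the next interval matches the published figure, censoring
#' times are spread uniformly across the interval (deterministically, so
#' reconstruction needs no seed), and event counts are read off the
#' digitized survival drops through a running product-limit estimate.
#'
#' @param points Digitized curve (`time`, `survival`); cleaned with
#'   [clean_curve()] internally.
#' @param risk_table Data frame `time`, `n_at_risk`; at minimum one row
#'   at time 0 carrying the initial sample size. Counts must be
#'   non-increasing.
#' @param total_events Optional total number of events; when given, the
#'   censoring level of the final interval is adjusted so the
#'   reconstructed event count matches.
#' @return A tibble of IPD records (`time`, `event`) with
#'   `nrow == risk_table$n_at_risk[1]`.
#' @references Guyot P, Ades AE, Ouwens MJ, Welton NJ. Enhanced
#'   secondary analysis of survival data: reconstructing the data from
#'   published Kaplan-Meier survival curves. BMC Med Res Methodol 2012.
#' @export
reconstruct_ipd <- function(points, risk_table, total_events = NULL) {
  pts <- clean_curve(points)
  if (!all(c("time", "n_at_risk") %in% names(risk_table))) {
    stop("risk table needs columns 'time' and 'n_at_risk'", call. = FALSE)
  }
  rt <- risk_table[order(risk_table$time), ]
  t.risk <- as.numeric(rt$time)
  n.risk <- as.numeric(rt$n_at_risk)
  if (any(n.risk < 0) || any(n.risk != round(n.risk))) {
    stop("n_at_risk must be non-negative integers", call. = FALSE)
  }
  up <- which(diff(n.risk) > 0)
  if (length(up)) {
    stop("inconsistent risk table: n_at_risk increases in the interval ",
         "starting at ", t.risk[up[1] + 1], call. = FALSE)
  }
  t.S <- pts$time
  S <- pts$survival
  n.t <- length(t.S)
  if (max(t.risk) > max(t.S) + 1e-9) {
    stop("risk-table times extend beyond the digitized curve", call. = FALSE)
  }
  # first digitized coordinate at or after each risk-table time
  lower <- vapply(t.risk, function(x) which(t.S >= x - 1e-9)[1], integer(1))
  n.int <- length(t.risk)
  upper <- c(lower[-1] - 1L, n.t)
  if (any(upper < lower)) {
    stop("risk-table intervals must each contain at least one digitized ",
         "point", call. = FALSE)
  }

  cen <- rep(0, n.t)
  d <- rep(0, n.t)
  KM.hat <- rep(1, n.t)
  n.hat <- rep(n.risk[1], n.t + 1)
  last.i <- rep(1L, n.int)

  spread_censor <- function(ncen, from_t, to_t, breaks) {
    # deterministic uniform placement, counted per digitized sub-interval
    if (ncen <= 0 || to_t <= from_t) {
      return(list(counts = rep(0, length(breaks) - 1), times = numeric(0)))
    }
    ct <- from_t + seq_len(ncen) * (to_t - from_t) / (ncen + 1)
    counts <- graphics::hist(ct, breaks = breaks, plot = FALSE,
                             right = FALSE)$counts
    list(counts = counts, times = ct)
  }

  run_interval <- function(i, ncen_i) {
    first <- lower[i]; last_k <- upper[i]
    end_t <- if (i < n.int) t.S[lower[i + 1]] else t.S[last_k]
    brk_last <- if (i < n.int) lower[i + 1] else last_k
    if (brk_last > first) {
      sp <- spread_censor(ncen_i, t.S[first], end_t, t.S[first:brk_last])
      cen[first:(brk_last - 1)] <<- sp$counts
      if (brk_last - 1 < last_k) cen[brk_last:last_k] <<- 0
    } else {
      sp <- list(times = numeric(0))
    }
    n.hat[first] <<- n.risk[i]
    last <- last.i[i]
    for (k in first:last_k) {
      if (k == 1) {
        d[k] <<- 0
        KM.hat[k] <<- 1
      } else if (KM.hat[last] > 0) {
        d[k] <<- round(n.hat[k] * (1 - S[k] / KM.hat[last]))
        d[k] <<- max(min(d[k], n.hat[k]), 0)
        KM.hat[k] <<- if (n.hat[k] > 0) {
          KM.hat[last] * (1 - d[k] / n.hat[k])
        } else KM.hat[last]
      } else {
        d[k] <<- 0
        KM.hat[k] <<- 0
      }
      n.hat[k + 1] <<- n.hat[k] - d[k] - cen[k]
      if (n.hat[k + 1] < 0) {
        n.hat[k + 1] <<- 0
        cen[k] <<- max(n.hat[k] - d[k], 0)
      }
      if (d[k] != 0) last <- k
    }
    last
  }

  if (n.int > 1) {
    for (i in 1:(n.int - 1)) {
      ncen <- round(n.risk[i] * S[lower[i + 1]] / S[lower[i]]) - n.risk[i + 1]
      guard <- 0
      repeat {
        ncen <- max(ncen, 0)
        last <- run_interval(i, ncen)
        gap <- n.hat[lower[i + 1]] - n.risk[i + 1]
        guard <- guard + 1
        if (gap == 0 || (gap < 0 && ncen == 0) || guard > 1000) break
        ncen <- ncen + gap
      }
      # digitization error can leave fewer survivors than published;
      # carry the implied count forward (published-algorithm behavior)
      if (n.hat[lower[i + 1]] < n.risk[i + 1]) {
        n.risk[i + 1] <- n.hat[lower[i + 1]]
      }
      last.i[i + 1] <- last
    }
  }
  # final interval: assume the average censoring rate of earlier intervals
  if (n.int > 1) {
    span_prev <- t.S[upper[n.int - 1]] - t.S[lower[1]]
    ncen_last <- if (span_prev > 0) {
      round(sum(cen[1:(lower[n.int] - 1)]) *
              (t.S[upper[n.int]] - t.S[lower[n.int]]) / span_prev)
    } else 0
    ncen_last <- min(max(ncen_last, 0), n.risk[n.int])
  } else {
    ncen_last <- 0
  }
  run_interval(n.int, ncen_last)

  if (!is.null(total_events)) {
    guard <- 0
    while (sum(d) != total_events && guard < 200) {
      ncen_last <- ncen_last + (sum(d) - total_events)
      ncen_last <- min(max(ncen_last, 0), n.risk[n.int])
      run_interval(n.int, ncen_last)
      guard <- guard + 1
      if (ncen_last %in% c(0, n.risk[n.int]) &&
          sum(d) != total_events) break
    }
  }

  # assemble records: events at digitized times, within-interval censors
  # at sub-interval midpoints, survivors censored at the last time seen
  n0 <- n.risk[1]
  times <- rep(t.S[n.t], n0)
  events <- rep(0, n0)
  k <- 1
  for (j in seq_len(n.t)) {
    if (d[j] > 0) {
      idx <- k:(k + d[j] - 1)
      times[idx] <- t.S[j]
      events[idx] <- 1
      k <- k + d[j]
    }
  }
  for (j in seq_len(n.t - 1)) {
    if (cen[j] > 0) {
      idx <- k:(k + cen[j] - 1)
      times[idx] <- (t.S[j] + t.S[j + 1]) / 2
      events[idx] <- 0
      k <- k + cen[j]
    }
  }
  tibble::tibble(time = times, event = events)
}

#' Read digitized curve / risk-table CSV files
#'
#' @param path CSV with columns `time,survival` (curve) or
#'   `time,n_at_risk` (risk table).
#' @return A tibble.
#' @export
read_curve <- function(path) {
  d <- utils::read.csv(path)
  clean_curve(d)
}

#' @rdname read_curve
#' @export
read_risk_table <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time", "n_at_risk") %in% names(d))) {
    stop("risk table needs columns 'time' and 'n_at_risk'", call. = FALSE)
  }
  tibble::tibble(time = as.numeric(d$time),
                 n_at_risk = as.integer(d$n_at_risk))
}
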