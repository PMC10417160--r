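#' Fit a parametric survival family by maximum likelihood
#'
#' Maximizes the right-censored log-likelihood
#' \eqn{\sum_{events} \log f(t_i) + \sum_{censored} \log S(t_i)}
#' for one of the six supported families. Fitting is delegated to
#' [flexsurv::flexsurvreg()], whose starting values are derived
#' deterministically from the data, so results are reproducible without
#' a seed.
#'
#' @param data Data frame with columns `time` (months, non-negative) and
#'   `event` (1 = observed, 0 = right-censored).
#' @param family One of [surv_families()].
#' @return A `fit_result` object: list with elements `distribution`
#'   ([surv_dist()]), `se` (delta-method standard errors on the natural
#'   scale), `loglik`, `aic` (`2k - 2 loglik`), `bic`
#'   (`k log n - 2 loglik`), `n`, `converged`.
#' @export
fit_mle <- function(data, family) {
  family <- match.arg(family, surv_families())
  data <- validate_ipd(data)
  if (nrow(data) < 10) stop("need at least 10 records to fit", call. = FALSE)
  if (!any(data$event == 1)) {
    stop("degenerate data: all records censored", call. = FALSE)
  }
  dist_name <- switch(family,
    exponential = "exp", weibull = "weibull", gamma = "gamma",
    lognormal = "lnorm", loglogistic = "llogis", gompertz = "gompertz")
  # flexsurvreg chokes on t = 0 exactly; nudge to half the smallest
  # positive time (digitized curves can yield zero-time events)
  tt <- data$time
  if (any(tt <= 0)) tt[tt <= 0] <- min(tt[tt > 0], 1) / 2
  fit <- tryCatch(
    flexsurv::flexsurvreg(survival::Surv(tt, data$event) ~ 1,
                          dist = dist_name),
    error = function(e) e)
  if (inherits(fit, "error")) {
    stop("fit failed for family '", family, "': ",
         conditionMessage(fit), call. = FALSE)
  }
  est <- fit$res[, "est"]
  se <- fit$res[, "se"]
  names(est) <- names(se) <- rownames(fit$res)
  # flexsurv reports gamma/gompertz/exponential with 'rate'; map names
  # onto the package's canonical order for the family
  est <- est[surv_param_names(family)]
  se <- se[surv_param_names(family)]
  k <- fit$npars
  n <- nrow(data)
  ll <- fit$loglik
  converged <- is.null(fit$opt$convergence) || fit$opt$convergence == 0
  structure(
    list(distribution = do.call(surv_dist, c(list(family), as.list(est))),
         se = se,
         loglik = ll,
         aic = 2 * k - 2 * ll,
         bic = k * log(n) - 2 * ll,
         n = n,
         converged = isTRUE(converged)),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> ", x$distribution$family,
      sprintf(" loglik %.3f AIC %.3f BIC %.3f (n = %d%s)\n",
              x$loglik, x$aic, x$bic, x$n,
              if (x$converged) "" else ", NOT converged"), sep = "")
  print(x$distribution)
  invisible(x)
}

#' Fit several families and rank them
#'
#' @param data As in [fit_mle()].
#' @param families Families to try; defaults to all six.
#' @return A list of `fit_result` objects ranked by [rank_fits()].
#' @export
fit_families <- function(data, families = surv_families()) {
  fits <- lapply(families, function(f) fit_mle(data, f))
  rank_fits(fits)
}

#' Rank fitted distributions by information criteria
#'
#' Sorts ascending by AIC; ties are broken by BIC, then by the canonical
#' family order of [surv_families()]. Lower AIC/BIC indicate better fit
#' and drive the final choice of extrapolation distribution.
#'
#' @param fits A list of `fit_result` objects fitted to the same data.
#' @return The same list, sorted best-first.
#' @export
rank_fits <- function(fits) {
  if (length(fits) == 0) stop("no fits to rank", call. = FALSE)
  if (!all(vapply(fits, inherits, logical(1), "fit_result"))) {
    stop("all elements must be 'fit_result' objects", call. = FALSE)
  }
  n <- vapply(fits, `[[`, numeric(1), "n")
  if (length(unique(n)) > 1) {
    stop("fits were made on different data (n differs)", call. = FALSE)
  }
  fam <- vapply(fits, function(f) f$distribution$family, character(1))
  ord <- order(vapply(fits, `[[`, numeric(1), "aic"),
               vapply(fits, `[[`, numeric(1), "bic"),
               match(fam, surv_families()))
  fits[ord]
}

#' Model-selection table for a set of fits
#'
#' @param fits A list of `fit_result` objects (typically ranked).
#' @return A tibble with one row per fit: family, parameter estimates
#'   (as a compact JSON string), log-likelihood, AIC, BIC, convergence.
#' @export
fit_table <- function(fits) {
  tibble::tibble(
    family = vapply(fits, function(f) f$distribution$family, character(1)),
    params = vapply(fits, function(f) params_json(f$distribution), character(1)),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    aic = vapply(fits, `[[`, numeric(1), "aic"),
    bic = vapply(fits, `[[`, numeric(1), "bic"),
    converged = vapply(fits, `[[`, logical(1), "converged"))
}

params_json <- function(dist) {
  paste0("{", paste0('"', names(dist$params), '":',
                     formatC(dist$params, digits = 10, format = "g"),
                     collapse = ","), "}")
}

#' Write a model-selection report to CSV
#'
#' @param fits List of `fit_result` objects.
#' @param path Output CSV path.
#' @export
write_fit_report <- function(fits, path) {
  utils::write.csv(as.data.frame(fit_table(fits)), path, row.names = FALSE)
  invisible(path)
}

#' Read / write individual patient data
#'
#' Two-column CSV, `time` (months) and `event` (0/1), header required.
#'
#' @param path CSV path.
#' @return A tibble with columns `time` and `event`.
#' @export
read_ipd <- function(path) {
  d <- utils::read.csv(path)
  validate_ipd(d)
}

#' @rdname read_ipd
#' @param data IPD data frame (`time`, `event`).
#' @export
write_ipd <- function(data, path) {
  data <- validate_ipd(data)
  utils::write.csv(as.data.frame(data[c("time", "event")]), path,
                   row.names = FALSE)
  invisible(path)
}

validate_ipd <- function(data) {
  if (!all(c("time", "event") %in% names(data))) {
    stop("IPD must have columns 'time' and 'event'", call. = FALSE)
  }
  if (any(!is.finite(data$time)) || any(data$time < 0)) {
    stop("times must be finite and non-negative", call. = FALSE)
  }
  ev <- as.numeric(data$event)
  if (!all(ev %in% c(0, 1))) {
    stop("event must be 0 (censored) or 1 (observed)", call. = FALSE)
  }
  tibble::tibble(time = as.numeric(data$time), event = ev)
}
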