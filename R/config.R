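#' Path to the packaged model configuration
#'
#' The shipped YAML encodes every model input at full printed precision:
#' fitted survival parameters per arm and endpoint, per-cycle costs with
#' and without Medicare coverage, health-state utilities, adverse-event
#' incidences/costs/disutilities, the subsequent-treatment assumption,
#' and the global model settings.
#'
#' @return Filesystem path to `orient32.yaml`.
#' @export
hccea_config_path <- function() {
  system.file("extdata", "orient32.yaml", package = "hccea",
              mustWork = TRUE)
}

#' Load and validate a model configuration
#'
#' Reads a YAML model configuration and validates it exhaustively: all
#' required keys present and numeric, `low <= base <= high` for every
#' ranged input, utilities and incidences in `[0, 1]`, disutilities
#' non-positive, costs non-negative, survival specifications valid.
#' Every violation is reported at once, each naming the offending key
#' path.
#'
#' @param path YAML file path; defaults to the packaged configuration.
#' @return A validated `cea_bundle` (nested list).
#' @export
load_config <- function(path = hccea_config_path()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop("cannot parse YAML at ", path, ": ", conditionMessage(e),
         call. = FALSE)
  })
  validate_bundle(raw)
}

#' Write a configuration bundle back to YAML
#'
#' `load_config(dump_config(bundle, path))` reproduces `bundle`
#' exactly.
#'
#' @param bundle A `cea_bundle`.
#' @param path Output path.
#' @export
dump_config <- function(bundle, path) {
  yaml::write_yaml(unclass(bundle), path, precision = 15)
  invisible(path)
}

arms <- function() c("sintilimab_ibi305", "sorafenib")

validate_bundle <- function(raw) {
  errs <- character(0)
  note <- function(...) errs <<- c(errs, paste0(...))
  num_at <- function(path) {
    x <- raw[[path]]
    if (is.null(x) || !is.numeric(x) || length(x) != 1 || !is.finite(x)) {
      note(paste(path, collapse = "."), ": missing or not a number")
      NA_real_
    } else x
  }
  rng_at <- function(path, lo_ok = -Inf, hi_ok = Inf) {
    b <- num_at(c(path, "base")); l <- num_at(c(path, "low"))
    h <- num_at(c(path, "high"))
    key <- paste(path, collapse = ".")
    if (!anyNA(c(b, l, h))) {
      if (!(l <= b && b <= h)) note(key, ": requires low <= base <= high")
      if (b < lo_ok || b > hi_ok) {
        note(key, ": base outside [", lo_ok, ", ", hi_ok, "]")
      }
    }
    c(base = b, low = l, high = h)
  }
  if (is.null(raw) || !is.list(raw) || !length(raw)) {
    stop("configuration is empty", call. = FALSE)
  }

  for (k in c("cycle_days", "horizon_years", "discount_annual", "wtp")) {
    num_at(c("model", k))
  }
  d <- raw$model$discount_annual
  if (is.numeric(d) && length(d) == 1 && (d < 0 || d >= 1)) {
    note("model.discount_annual: must be in [0, 1)")
  }

  for (arm in arms()) {
    for (ep in c("os", "pfs")) {
      spec <- raw$survival[[arm]][[ep]]
      key <- paste("survival", arm, ep, sep = ".")
      if (is.null(spec$family) || !spec$family %in% surv_families()) {
        note(key, ".family: must be one of ",
             paste(surv_families(), collapse = ", "))
      } else {
        ok <- tryCatch({
          do.call(surv_dist,
                  c(list(spec$family), spec[surv_param_names(spec$family)]))
          TRUE
        }, error = function(e) {
          note(key, ": ", conditionMessage(e)); FALSE
        })
      }
    }
  }

  cost_keys <- c("sintilimab", "sintilimab_medicare", "ibi305",
                 "sorafenib", "sorafenib_medicare", "regorafenib",
                 "followup", "laboratory", "administration")
  for (k in cost_keys) rng_at(c("costs", k), lo_ok = 0)
  for (k in c("sd", "pd")) rng_at(c("utilities", k), lo_ok = 0, hi_ok = 1)
  for (arm in arms()) {
    p <- num_at(c("subsequent_treatment", arm))
    if (!is.na(p) && (p < 0 || p > 1)) {
      note("subsequent_treatment.", arm, ": must be in [0, 1]")
    }
  }
  ae_names <- c("ppe", "platelet", "hypertension")
  for (k in ae_names) rng_at(c("adverse_events", "costs", k), lo_ok = 0)
  for (k in ae_names) {
    r <- rng_at(c("adverse_events", "disutilities", k))
    if (!anyNA(r) && r[["base"]] > 0) {
      note("adverse_events.disutilities.", k, ": must be <= 0")
    }
  }
  for (arm in arms()) {
    inc <- raw$adverse_events$incidence[[arm]]
    if (is.null(inc) || !length(inc)) {
      note("adverse_events.incidence.", arm, ": missing")
    } else {
      for (k in names(inc)) {
        rng_at(c("adverse_events", "incidence", arm, k),
               lo_ok = 0, hi_ok = 1)
        if (!k %in% ae_names) {
          note("adverse_events.incidence.", arm, ".", k,
               ": no matching cost/disutility entry")
        }
      }
    }
  }

  if (length(errs)) {
    stop("invalid configuration:\n  - ",
         paste(errs, collapse = "\n  - "), call. = FALSE)
  }
  structure(raw, class = "cea_bundle")
}

#' Resolve a configuration bundle to one pricing scenario
#'
#' Selects the list-price or Medicare per-cycle drug prices (sintilimab
#' and sorafenib are the only inputs that differ between the two; IBI305
#' and regorafenib are identical across scenarios) and flattens the
#' bundle into a ready-to-evaluate model object.
#'
#' @param bundle A `cea_bundle` from [load_config()].
#' @param scenario `"list"` or `"medicare"`.
#' @return A `cea_model`: list with `config` ([model_config()]),
#'   `survival` (fitted [surv_dist()] curves per arm), `costs`,
#'   `utilities`, `subsequent`, `ae`, `ranges` (low/high per sampled
#'   parameter binding) and `scenario`.
#' @export
resolve_scenario <- function(bundle, scenario = c("medicare", "list")) {
  if (!inherits(bundle, "cea_bundle")) {
    stop("expected a 'cea_bundle' from load_config()", call. = FALSE)
  }
  scenario <- match.arg(scenario)
  cfg <- model_config(cycle_days = bundle$model$cycle_days,
                      horizon_years = bundle$model$horizon_years,
                      discount_annual = bundle$model$discount_annual,
                      half_cycle = isTRUE(bundle$model$half_cycle),
                      wtp = bundle$model$wtp)
  mk_dist <- function(spec) {
    do.call(surv_dist, c(list(spec$family),
                         spec[surv_param_names(spec$family)]))
  }
  sint_key <- if (scenario == "medicare") "sintilimab_medicare" else "sintilimab"
  sora_key <- if (scenario == "medicare") "sorafenib_medicare" else "sorafenib"
  base_of <- function(x) x$base
  costs <- list(
    sintilimab = base_of(bundle$costs[[sint_key]]),
    ibi305 = base_of(bundle$costs$ibi305),
    sorafenib = base_of(bundle$costs[[sora_key]]),
    regorafenib = base_of(bundle$costs$regorafenib),
    followup = base_of(bundle$costs$followup),
    laboratory = base_of(bundle$costs$laboratory),
    administration = base_of(bundle$costs$administration))
  ranges <- list(
    "costs.sintilimab" = bundle$costs[[sint_key]],
    "costs.ibi305" = bundle$costs$ibi305,
    "costs.sorafenib" = bundle$costs[[sora_key]],
    "costs.regorafenib" = bundle$costs$regorafenib,
    "costs.followup" = bundle$costs$followup,
    "costs.laboratory" = bundle$costs$laboratory,
    "costs.administration" = bundle$costs$administration,
    "utilities.sd" = bundle$utilities$sd,
    "utilities.pd" = bundle$utilities$pd)
  for (k in names(bundle$adverse_events$costs)) {
    ranges[[paste0("ae.costs.", k)]] <- bundle$adverse_events$costs[[k]]
    ranges[[paste0("ae.disutilities.", k)]] <-
      bundle$adverse_events$disutilities[[k]]
  }
  for (arm in arms()) {
    for (k in names(bundle$adverse_events$incidence[[arm]])) {
      ranges[[paste0("ae.incidence.", arm, ".", k)]] <-
        bundle$adverse_events$incidence[[arm]][[k]]
    }
  }
  structure(list(
    config = cfg,
    survival = list(
      sintilimab_ibi305 = list(
        os = mk_dist(bundle$survival$sintilimab_ibi305$os),
        pfs = mk_dist(bundle$survival$sintilimab_ibi305$pfs)),
      sorafenib = list(
        os = mk_dist(bundle$survival$sorafenib$os),
        pfs = mk_dist(bundle$survival$sorafenib$pfs))),
    costs = costs,
    utilities = list(sd = bundle$utilities$sd$base,
                     pd = bundle$utilities$pd$base),
    subsequent = list(
      sintilimab_ibi305 = bundle$subsequent_treatment$sintilimab_ibi305,
      sorafenib = bundle$subsequent_treatment$sorafenib),
    ae = list(
      costs = lapply(bundle$adverse_events$costs, base_of),
      disutilities = lapply(bundle$adverse_events$disutilities, base_of),
      incidence = lapply(bundle$adverse_events$incidence,
                         function(arm) lapply(arm, base_of))),
    ranges = lapply(ranges, function(r) c(low = r$low, high = r$high)),
    scenario = scenario), class = "cea_model")
}

#' Build the two strategy specifications of a resolved model
#'
#' Administration cost attaches to the intravenous sintilimab + IBI305
#' regimen only; follow-up and laboratory costs apply to both arms in
#' both alive states.
#'
#' @param model A `cea_model` from [resolve_scenario()].
#' @return Named list of two [strategy_spec()] objects.
#' @export
build_strategies <- function(model) {
  ae_list <- function(arm) {
    inc <- model$ae$incidence[[arm]]
    lapply(names(inc), function(k) {
      adverse_event(k, inc[[k]], model$ae$costs[[k]],
                    model$ae$disutilities[[k]])
    })
  }
  list(
    sintilimab_ibi305 = strategy_spec(
      name = "Sintilimab + IBI305",
      os = model$survival$sintilimab_ibi305$os,
      pfs = model$survival$sintilimab_ibi305$pfs,
      drug_cost_per_cycle = model$costs$sintilimab + model$costs$ibi305,
      admin_cost_per_cycle = model$costs$administration,
      followup_cost_per_cycle = model$costs$followup,
      lab_cost_per_cycle = model$costs$laboratory,
      subsequent_tx_proportion = model$subsequent$sintilimab_ibi305,
      subsequent_tx_cost_per_cycle = model$costs$regorafenib,
      utility_sd = model$utilities$sd, utility_pd = model$utilities$pd,
      adverse_events = ae_list("sintilimab_ibi305")),
    sorafenib = strategy_spec(
      name = "Sorafenib",
      os = model$survival$sorafenib$os,
      pfs = model$survival$sorafenib$pfs,
      drug_cost_per_cycle = model$costs$sorafenib,
      admin_cost_per_cycle = 0,
      followup_cost_per_cycle = model$costs$followup,
      lab_cost_per_cycle = model$costs$laboratory,
      subsequent_tx_proportion = model$subsequent$sorafenib,
      subsequent_tx_cost_per_cycle = model$costs$regorafenib,
      utility_sd = model$utilities$sd, utility_pd = model$utilities$pd,
      adverse_events = ae_list("sorafenib")))
}

#' Evaluate a resolved model
#'
#' Runs the cohort simulation for both strategies and computes the
#' incremental comparison of sintilimab + IBI305 against sorafenib.
#'
#' @param model A `cea_model`.
#' @return List with `outcomes` (two `strategy_outcome`s), `ce`
#'   (a `ce_result`), `wtp` and `scenario`.
#' @export
evaluate_model <- function(model) {
  strat <- build_strategies(model)
  outcomes <- lapply(strat, evaluate_strategy, config = model$config)
  list(outcomes = outcomes,
       ce = icer(outcomes$sintilimab_ibi305, outcomes$sorafenib),
       wtp = model$config$wtp,
       scenario = model$scenario)
}

#' Run the base case under both pricing scenarios
#'
#' Evaluates both strategies at list prices and under Medicare coverage
#' and wraps the outcomes, the incremental block and a decision line
#' into one report per scenario. Report numbers are the
#' [evaluate_strategy()] outputs unmodified.
#'
#' @param bundle A `cea_bundle`.
#' @return A `scenario_reports` list with elements `list` and
#'   `medicare`.
#' @export
run_scenarios <- function(bundle) {
  reports <- lapply(c(list = "list", medicare = "medicare"),
                    function(sc) {
    res <- evaluate_model(resolve_scenario(bundle, sc))
    res$decision <- if (!is.na(res$ce$icer) && res$ce$icer <= res$wtp ||
                        res$ce$dominance == "dominant") {
      "cost-effective at the willingness-to-pay threshold"
    } else {
      "not cost-effective at the willingness-to-pay threshold"
    }
    res
  })
  structure(reports, class = "scenario_reports")
}

#' @export
print.scenario_reports <- function(x, ...) {
  lab <- c(list = "List prices", medicare = "Medicare coverage")
  for (sc in names(x)) {
    r <- x[[sc]]
    cat("== ", lab[[sc]], " ==\n", sep = "")
    for (o in r$outcomes) {
      cat(sprintf("  %-22s cost $%9.2f  QALYs %.2f  LYs %.2f\n",
                  o$name, o$total_cost, o$total_qalys, o$total_lys))
    }
    cat(sprintf("  incremental cost $%.2f, incremental QALYs %.2f\n",
                r$ce$incr_cost, r$ce$incr_qaly))
    cat(sprintf("  ICER $%.2f/QALY vs WTP $%.0f/QALY: %s\n\n",
                r$ce$icer, r$wtp, r$decision))
  }
  invisible(x)
}

#' Export scenario reports as JSON
#'
#' @param reports A `scenario_reports` object.
#' @param path Output path.
#' @export
write_results <- function(reports, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("the 'jsonlite' package is required for JSON export",
         call. = FALSE)
  }
  out <- lapply(reports, function(r) {
    list(scenario = r$scenario,
         strategies = lapply(r$outcomes, function(o) {
           list(cost = o$total_cost, qalys = o$total_qalys,
                lys = o$total_lys)
         }),
         incremental = list(cost = r$ce$incr_cost,
                            qaly = r$ce$incr_qaly, icer = r$ce$icer,
                            dominance = r$ce$dominance),
         wtp = r$wtp, decision = r$decision)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
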