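# End-to-end workflows and model comparison.
#
# Scenario I: data -> implicit sparse regression -> SIO analysis ->
# reparameterization (if needed) -> dictionary reformulation -> M*.
# Scenario II: additionally takes a prior model, makes it FISPO (PM*), and
# compares PM* with the discovered M* structurally, parametrically and
# predictively.

.digest <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2^31
  sprintf("%08x", h)
}

.log_stage <- function(log, stage, input, outcome) {
  log[[length(log) + 1]] <- list(stage = stage, input_digest = .digest(input),
                                 outcome = outcome, time = format(Sys.time()))
  log
}

#' Scenario I: model discovery with no prior knowledge
#'
#' Runs the full pipeline on time-series data: implicit sparse regression,
#' SIO classification, automatic reparameterization when the candidate is
#' not FISPO, and dictionary reformulation. Every stage's outcome is
#' recorded in a structured log.
#'
#' @param data training `ts_data`.
#' @param degree library degree (scalar or per state).
#' @param validation held-out `ts_data` (see [validation_data()]); optional.
#' @param lambdas threshold grid.
#' @param dictionary a [kinetic_dictionary()].
#' @param name model name for the candidate.
#' @return list of class `scenario_result`: `model` (the final M*), `fit`,
#'   `sio` (candidate's report), `chain` (repar chain or NULL),
#'   `reformulation`, `log`.
#' @export
run_scenario_1 <- function(data, degree, validation = NULL,
                           lambdas = lambda_grid(),
                           dictionary = kinetic_dictionary(), name = "CM") {
  log <- list()
  fit <- discover(data, degree = degree, lambdas = lambdas,
                  validation = validation, name = name)
  log <- .log_stage(log, "discover", data$provenance,
                    paste(length(fit$model$params), "coefficients"))
  rep0 <- classify(fit$model)
  log <- .log_stage(log, "classify", fit$model$dynamics,
                    if (rep0$fispo) "FISPO" else
                      paste("rank deficit", rep0$nxt - rep0$rank))
  chain <- NULL
  cur <- fit$model
  if (!rep0$fispo) {
    chain <- autorepar(cur)
    if (chain$unresolved)
      stop("reparameterization could not resolve the rank deficiency ",
           "(see autorepar)")
    cur <- chain$model
    log <- .log_stage(log, "autorepar", rep0,
                      paste(length(chain$steps), "symmetries broken"))
  }
  reform <- reformulate_model(cur, dictionary)
  log <- .log_stage(log, "reformulate", cur$dynamics,
                    paste0("FISPO=", reform$fispo_confirmed,
                           ", equivalent=", reform$equivalent))
  structure(list(model = reform$model, fit = fit, sio = rep0, chain = chain,
                 reformulation = reform, log = log),
            class = "scenario_result")
}

#' Scenario II: discovery with a prior model
#'
#' The prior model (PM) is classified and, if not FISPO, reparameterized to
#' PM*. In parallel the data branch runs [run_scenario_1()] to produce M*.
#' The two are then compared with [compare_models()].
#'
#' @param prior an [ode_model] (the prior/ground-truth structure).
#' @param data training `ts_data` generated from the system.
#' @param degree,validation,lambdas,dictionary as in [run_scenario_1()].
#' @param compare_data `ts_data` under held-out conditions for the
#'   predictive comparison (defaults to `validation`).
#' @return list of class `scenario2_result`: `pm_star`, `pm_chain`,
#'   `scenario1` (the data branch), `comparison`, `log`.
#' @export
run_scenario_2 <- function(prior, data, degree, validation = NULL,
                           lambdas = lambda_grid(),
                           dictionary = kinetic_dictionary(),
                           compare_data = NULL) {
  log <- list()
  pm_rep <- classify(prior)
  log <- .log_stage(log, "classify_pm", prior$dynamics,
                    if (pm_rep$fispo) "FISPO" else
                      paste("rank deficit", pm_rep$nxt - pm_rep$rank))
  pm_chain <- NULL
  pm_star <- prior
  if (!pm_rep$fispo) {
    pm_chain <- autorepar(prior)
    if (pm_chain$unresolved)
      stop("prior-model reparameterization could not resolve the deficiency")
    pm_star <- pm_chain$model
    log <- .log_stage(log, "autorepar_pm", pm_rep,
                      paste(length(pm_chain$steps), "symmetries broken"))
  }
  s1 <- run_scenario_1(data, degree, validation = validation,
                       lambdas = lambdas, dictionary = dictionary)
  cmp_data <- compare_data %||% validation
  comparison <- compare_models(pm_star, s1$model, cmp_data)
  log <- .log_stage(log, "compare", list(pm_star$dynamics, s1$model$dynamics),
                    sprintf("precision=%.3f recall=%.3f",
                            comparison$structural$precision,
                            comparison$structural$recall))
  structure(list(pm_star = pm_star, pm_chain = pm_chain, pm_report = pm_rep,
                 scenario1 = s1, comparison = comparison, log = log),
            class = "scenario2_result")
}

# implicit-form support of a model: per state, the monomial keys of N and of
# the derivative-times-monomial terms of D (denominator normalized)
.implicit_support <- function(model) {
  rfm <- to_rational_form(model)
  out <- list()
  for (s in model$states) {
    N <- sp_from_mp(rfm[[s]]$num, model$states)
    D <- sp_from_mp(rfm[[s]]$den, model$states)
    nk <- if (sp_is_zero(N)) character(0) else
      vapply(seq_len(nrow(N$E)), function(i) sp_mono_string(N, i), character(1))
    # the normalized constant of D is the fixed left-hand side, not an
    # active term; only nonconstant denominator rows count as support
    drows <- which(rowSums(D$E) > 0)
    dk <- vapply(drows, function(i)
      paste0("d", s, "*", sp_mono_string(D, i)), character(1))
    out[[s]] <- c(nk, dk)
  }
  out
}

# numeric implicit-form coefficients (denominator-normalized), named by the
# same keys as .implicit_support
.implicit_coefs <- function(model) {
  if (is.null(model$param_values)) return(NULL)
  rfm <- to_rational_form(model)
  out <- list()
  for (s in model$states) {
    N <- sp_from_mp_numeric(rfm[[s]]$num, model$states, model$param_values)
    D <- sp_from_mp_numeric(rfm[[s]]$den, model$states, model$param_values)
    v <- numeric(0)
    if (!sp_is_zero(N))
      v <- c(v, stats::setNames(
        vapply(N$cf, cf_num_value, numeric(1)),
        vapply(seq_len(nrow(N$E)), function(i) sp_mono_string(N, i),
               character(1))))
    drows <- which(rowSums(D$E) > 0)
    if (length(drows))
      v <- c(v, stats::setNames(
        vapply(D$cf[drows], cf_num_value, numeric(1)),
        vapply(drows, function(i)
          paste0("d", s, "*", sp_mono_string(D, i)), character(1))))
    out[[s]] <- v
  }
  out
}

#' Compare a prior model with a discovered model
#'
#' Structural accuracy: precision/recall of the discovered model's active
#' implicit-form support (numerator monomials and denominator terms) against
#' the prior's. Parametric accuracy: relative errors of the
#' denominator-normalized implicit coefficients on the shared support
#' (requires parameter values on both sides). Predictive accuracy: per-state
#' normalized root-mean-square error between the two models' trajectories
#' from held-out initial conditions.
#'
#' @param pm the prior (reference) [ode_model].
#' @param mstar the discovered [ode_model].
#' @param valid held-out `ts_data` (its first row provides the initial
#'   condition and its time grid the horizon); NULL skips the predictive
#'   section.
#' @return an object of class `comparison_report`.
#' @export
compare_models <- function(pm, mstar, valid = NULL) {
  if (!identical(pm$states, mstar$states))
    stop("models have different state spaces")
  sup_pm <- .implicit_support(pm)
  sup_ms <- .implicit_support(mstar)
  tp <- 0; n_ms <- 0; n_pm <- 0
  table <- list()
  for (s in pm$states) {
    common <- intersect(sup_pm[[s]], sup_ms[[s]])
    tp <- tp + length(common)
    n_ms <- n_ms + length(sup_ms[[s]])
    n_pm <- n_pm + length(sup_pm[[s]])
    table[[s]] <- list(shared = common,
                       missed = setdiff(sup_pm[[s]], sup_ms[[s]]),
                       spurious = setdiff(sup_ms[[s]], sup_pm[[s]]))
  }
  structural <- list(precision = if (n_ms) tp / n_ms else NA_real_,
                     recall = if (n_pm) tp / n_pm else NA_real_,
                     table = table)
  # parametric
  parametric <- NULL
  c_pm <- .implicit_coefs(pm); c_ms <- .implicit_coefs(mstar)
  if (!is.null(c_pm) && !is.null(c_ms)) {
    errs <- list()
    for (s in pm$states) {
      shared <- intersect(names(c_pm[[s]]), names(c_ms[[s]]))
      shared <- shared[abs(c_pm[[s]][shared]) > 1e-12]
      if (length(shared))
        errs[[s]] <- abs(c_ms[[s]][shared] - c_pm[[s]][shared]) /
          abs(c_pm[[s]][shared])
    }
    all_errs <- unlist(errs)
    parametric <- list(per_term = errs,
                       max_rel_error = if (length(all_errs)) max(all_errs)
                                       else NA_real_)
  }
  # predictive
  predictive <- NULL
  if (!is.null(valid) && !is.null(pm$param_values) &&
      !is.null(mstar$param_values)) {
    x0 <- stats::setNames(valid$X[1, ], pm$states)
    times <- sort(unique(valid$time - valid$time[1]))
    s_pm <- simulate_model(pm, x0 = x0, times = times)
    s_ms <- tryCatch(simulate_model(mstar, x0 = x0, times = times),
                     error = function(e) NULL)
    if (!is.null(s_ms)) {
      nrmse <- vapply(seq_along(pm$states), function(i) {
        sc <- stats::sd(s_pm$X[, i])
        sqrt(mean((s_ms$X[, i] - s_pm$X[, i])^2)) / max(sc, 1e-12)
      }, numeric(1))
      predictive <- stats::setNames(nrmse, pm$states)
    }
  }
  structure(list(structural = structural, parametric = parametric,
                 predictive = predictive),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("model comparison\n")
  cat(sprintf(" structural: precision = %.3f, recall = %.3f\n",
              x$structural$precision, x$structural$recall))
  for (s in names(x$structural$table)) {
    t <- x$structural$table[[s]]
    if (length(t$missed))
      cat("  ", s, "missed:", paste(t$missed, collapse = ", "), "\n")
    if (length(t$spurious))
      cat("  ", s, "spurious:", paste(t$spurious, collapse = ", "), "\n")
  }
  if (!is.null(x$parametric))
    cat(sprintf(" parametric: max relative coefficient error = %.3g\n",
                x$parametric$max_rel_error))
  else cat(" parametric: unavailable (missing parameter values)\n")
  if (!is.null(x$predictive))
    cat(" predictive NRMSE per state:",
        paste(sprintf("%.3g", x$predictive), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("Scenario I result\n")
  print(x$model)
  cat(" stages:\n")
  for (l in x$log) cat("  ", l$stage, "->", l$outcome, "\n")
  invisible(x)
}

#' @export
print.scenario2_result <- function(x, ...) {
  cat("Scenario II result\n PM*: ")
  cat(x$pm_star$name, "(", length(x$pm_star$params), "parameters )\n M*: ")
  cat(x$scenario1$model$name, "(", length(x$scenario1$model$params),
      "parameters )\n")
  print(x$comparison)
  invisible(x)
}
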