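# Trajectory simulation and training-data generation.

# Compile model dynamics to a deSolve-compatible rate function.
model_rhs <- function(model, params = model$param_values) {
  exprs <- model$dynamics
  states <- model$states
  penv <- list2env(as.list(params %||% numeric()), parent = baseenv())
  function(t, y, parms) {
    env <- list2env(as.list(stats::setNames(y, states)), parent = penv)
    list(vapply(exprs, function(e) eval(e, env), numeric(1)))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a model on a time grid
#'
#' Integrates \eqn{\dot x = f(x, p)} with a stiff-capable adaptive solver
#' (`deSolve::lsoda`) and evaluates the derivatives exactly by applying the
#' right-hand side at the sampled states.
#'
#' @param model an [ode_model].
#' @param params named parameter values (defaults to the model's).
#' @param x0 named initial conditions (defaults to the model's).
#' @param times strictly increasing time grid.
#' @param rtol,atol integrator tolerances.
#' @return a `ts_data` object: `time`, `X` (m x n states), `Xdot` (m x n exact
#'   derivatives), `traj` (trajectory index) and `provenance`.
#' @export
simulate_model <- function(model, params = NULL, x0 = NULL,
                           times = seq(0, 10, length.out = 200),
                           rtol = 1e-10, atol = 1e-10) {
  params <- params %||% model$param_values
  x0 <- x0 %||% model$x0
  if (is.null(x0)) stop("no initial conditions given or stored in model")
  missing_p <- setdiff(model$params, names(params))
  if (length(missing_p))
    stop("missing parameter values: ", paste(missing_p, collapse = ", "))
  if (any(diff(times) <= 0)) stop("time grid must be strictly increasing")
  rhs <- model_rhs(model, params)
  sol <- deSolve::lsoda(y = x0[model$states], times = times, func = rhs,
                        parms = NULL, rtol = rtol, atol = atol)
  X <- unname(as.matrix(sol[, model$states, drop = FALSE]))
  if (nrow(X) < length(times) || any(!is.finite(X))) {
    bad <- which(apply(X, 1, function(r) any(!is.finite(r))))[1]
    t_bad <- if (is.na(bad)) times[nrow(X)] else times[bad]
    stop("simulation failed (non-finite state or denominator crossing) near t = ",
         signif(t_bad, 4))
  }
  Xdot <- t(apply(X, 1, function(y) rhs(0, stats::setNames(y, model$states),
                                        NULL)[[1]]))
  if (length(model$states) == 1) Xdot <- matrix(Xdot, ncol = 1)
  Xdot <- unname(Xdot)
  ts_data(time = times, X = X, Xdot = Xdot, states = model$states,
          provenance = list(model = model$name, params = as.list(params),
                            x0 = as.list(x0), noise = 0, seed = NA,
                            deriv = "exact"))
}

ts_data <- function(time, X, Xdot, states, traj = rep(1L, length(time)),
                    provenance = list()) {
  stopifnot(nrow(X) == length(time), nrow(Xdot) == length(time),
            all(is.finite(X)), all(is.finite(Xdot)))
  structure(list(time = time, X = X, Xdot = Xdot, states = states,
                 traj = traj, provenance = provenance),
            class = "ts_data")
}

#' @export
print.ts_data <- function(x, ...) {
  cat("time-series data: ", length(x$time), " samples, ",
      ncol(x$X), " states (", paste(x$states, collapse = ", "), "), ",
      length(unique(x$traj)), " trajectories\n", sep = "")
  cat(" provenance: model=", x$provenance$model %||% "?",
      " noise=", x$provenance$noise %||% 0,
      " deriv=", x$provenance$deriv %||% "exact", "\n", sep = "")
  invisible(x)
}

# row-bind two ts_data sets, renumbering trajectories
ts_bind <- function(a, b) {
  b$traj <- b$traj + max(a$traj)
  ts_data(time = c(a$time, b$time), X = rbind(a$X, b$X),
          Xdot = rbind(a$Xdot, b$Xdot), states = a$states,
          traj = c(a$traj, b$traj), provenance = a$provenance)
}

#' Add measurement noise and recompute derivatives
#'
#' States are perturbed by zero-mean Gaussian noise scaled per state by
#' `noise_level` times that state's standard deviation. Derivatives are then
#' recomputed from the noisy states by the requested method (`exact` keeps the
#' stored derivatives untouched; `finite_difference` uses central differences
#' within each trajectory; `smoothed` applies a short moving average before
#' differencing).
#'
#' @param data a `ts_data` object.
#' @param noise_level nonnegative noise fraction.
#' @param seed integer seed (results are reproducible given the same seed).
#' @param derivative_method one of `"exact"`, `"finite_difference"`,
#'   `"smoothed"`.
#' @return a `ts_data` object.
#' @export
corrupt <- function(data, noise_level, seed = 1,
                    derivative_method = c("exact", "finite_difference",
                                          "smoothed")) {
  derivative_method <- match.arg(derivative_method)
  if (noise_level < 0) stop("noise_level must be >= 0")
  out <- data
  if (noise_level > 0) {
    set.seed(seed)
    sds <- apply(data$X, 2, stats::sd)
    noise <- matrix(stats::rnorm(length(data$X)), nrow(data$X))
    out$X <- data$X + noise * rep(noise_level * sds, each = nrow(data$X))
  }
  if (derivative_method != "exact") {
    Xs <- out$X
    if (derivative_method == "smoothed") {
      for (id in unique(out$traj)) {
        i <- which(out$traj == id)
        if (length(i) >= 5)
          Xs[i, ] <- apply(out$X[i, , drop = FALSE], 2, function(v)
            stats::filter(v, rep(1 / 3, 3), sides = 2) |>
              (\(f) { f[1] <- v[1]; f[length(v)] <- v[length(v)]; f })())
      }
    }
    Xd <- out$Xdot
    for (id in unique(out$traj)) {
      i <- which(out$traj == id)
      t <- out$time[i]; Z <- Xs[i, , drop = FALSE]
      m <- length(i)
      D <- Z
      D[2:(m - 1), ] <- (Z[3:m, , drop = FALSE] - Z[1:(m - 2), , drop = FALSE]) /
        (t[3:m] - t[1:(m - 2)])
      D[1, ] <- (Z[2, ] - Z[1, ]) / (t[2] - t[1])
      D[m, ] <- (Z[m, ] - Z[m - 1, ]) / (t[m] - t[m - 1])
      Xd[i, ] <- D
    }
    out$Xdot <- Xd
  }
  out$provenance$noise <- noise_level
  out$provenance$seed <- seed
  out$provenance$deriv <- derivative_method
  out
}

#' Generate a training ensemble from a model
#'
#' Simulates `n_traj` trajectories from initial conditions obtained by
#' jittering the nominal `x0` multiplicatively (uniform factors in
#' `1 +/- x0_spread`), so the data cover a neighbourhood of state space rather
#' than a single solution curve, and concatenates them.
#'
#' @param model an [ode_model] with parameter values and `x0`.
#' @param n_traj number of trajectories.
#' @param t_end horizon; `n_points` samples per trajectory.
#' @param n_points samples per trajectory.
#' @param x0_spread multiplicative jitter halfwidth (default 0.4).
#' @param seed integer seed.
#' @return a `ts_data` object.
#' @export
training_data <- function(model, n_traj = 8, t_end = 10, n_points = 60,
                          x0_spread = 0.4, seed = 1) {
  set.seed(seed)
  times <- seq(0, t_end, length.out = n_points)
  out <- NULL
  for (k in seq_len(n_traj)) {
    fac <- if (k == 1) rep(1, length(model$x0))
           else stats::runif(length(model$x0), 1 - x0_spread, 1 + x0_spread)
    x0 <- model$x0 * fac
    d <- simulate_model(model, x0 = x0, times = times)
    d$traj <- rep(k, length(times))
    out <- if (is.null(out)) d else ts_bind(out, d)
  }
  out$provenance$seed <- seed
  out$provenance$n_traj <- n_traj
  out
}

#' Held-out validation data
#'
#' Generates data under conditions different from training: the nominal
#' initial state is scaled by `factor` (default 1.25) per state.
#'
#' @inheritParams training_data
#' @param factor multiplicative perturbation of `x0`.
#' @return a `ts_data` object.
#' @export
validation_data <- function(model, t_end = 10, n_points = 60, factor = 1.25,
                            seed = 2) {
  times <- seq(0, t_end, length.out = n_points)
  d <- simulate_model(model, x0 = model$x0 * factor, times = times)
  d$provenance$seed <- seed
  d$provenance$validation_factor <- factor
  d
}

#' Write / read time-series data as delimited text
#'
#' Column layout: `t, x1..xn, dx1..dxn, traj`; a provenance sidecar JSON is
#' written alongside.
#' @param data a `ts_data`.
#' @param path CSV destination.
#' @export
write_ts <- function(data, path) {
  df <- data.frame(t = data$time, data$X, data$Xdot, traj = data$traj)
  names(df) <- c("t", data$states, paste0("d", data$states), "traj")
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(data$provenance, paste0(path, ".prov.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ts
#' @export
read_ts <- function(path) {
  df <- utils::read.csv(path)
  states <- grep("^d|^t$|^traj$", names(df), value = TRUE, invert = TRUE)
  prov_path <- paste0(path, ".prov.json")
  prov <- if (file.exists(prov_path)) jsonlite::read_json(prov_path) else list()
  ts_data(time = df$t, X = unname(as.matrix(df[states])),
          Xdot = unname(as.matrix(df[paste0("d", states)])), states = states,
          traj = if ("traj" %in% names(df)) df$traj else rep(1L, nrow(df)),
          provenance = prov)
}
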