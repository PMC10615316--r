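# Shared helpers: case loading and a cache so the discovery pipelines are
# run once per session and reused across test files.

.case_env <- new.env(parent = emptyenv())

case_model <- function(id, which = c("gt", "cm")) {
  which <- match.arg(which)
  cs <- get_case(id)
  if (which == "gt") cs$gt_model else cs$cm_model
}

# training + validation data for a case under its registry defaults
case_data <- function(id, seed = 1) {
  key <- paste0("data_", id, "_", seed)
  if (!is.null(.case_env[[key]])) return(.case_env[[key]])
  cs <- get_case(id)
  out <- list(
    train = training_data(cs$gt_model, n_traj = cs$n_traj, t_end = cs$t_end,
                          n_points = cs$n_points, seed = seed),
    valid = validation_data(cs$gt_model, t_end = cs$t_end,
                            n_points = cs$n_points))
  .case_env[[key]] <- out
  out
}

# full discovery fit for a case (quiet; cached)
case_fit <- function(id, seed = 1) {
  key <- paste0("fit_", id, "_", seed)
  if (!is.null(.case_env[[key]])) return(.case_env[[key]])
  cs <- get_case(id)
  d <- case_data(id, seed)
  fit <- suppressWarnings(
    discover(d$train, degree = cs$library_degree, validation = d$valid,
             name = paste0(id, "CM")))
  .case_env[[key]] <- fit
  fit
}

# autorepar chain for a case's printed candidate structure (cached)
case_cm_chain <- function(id) {
  key <- paste0("chain_", id)
  if (!is.null(.case_env[[key]])) return(.case_env[[key]])
  ch <- autorepar(case_model(id, "cm"))
  .case_env[[key]] <- ch
  ch
}

expect_rf_equal <- function(expr1, expr2, symbols) {
  r1 <- sindysio:::rf_from_string(expr1, symbols)
  r2 <- sindysio:::rf_from_string(expr2, symbols)
  expect_true(sindysio:::rf_equal(r1, r2),
              label = paste(expr1, "==", expr2))
}

# dynamics of two models are identical rational functions state by state
# after renaming m2's parameters according to `map` (new -> old expression)
expect_dynamics_equal <- function(m1, m2, map = list()) {
  expect_true(verify_equivalence(m1, m2, map))
}
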