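# End-to-end scenarios and model comparison.

test_that("scenario I on noiseless convection data returns the true model", {
  d <- case_data("Lorenz")
  s1 <- suppressWarnings(run_scenario_1(d$train, degree = 2,
                                        validation = d$valid))
  expect_true(s1$reformulation$fispo_confirmed)
  expect_null(s1$chain)  # already FISPO, no reparameterization needed
  expect_equal(length(s1$model$params), 7)
  expect_true(all(c("discover", "classify", "reformulate") %in%
                  vapply(s1$log, `[[`, character(1), "stage")))
})

test_that("scenario I on constant data returns the trivial FISPO model", {
  const <- ode_model("const", "x1", character(), "0", x0 = c(x1 = 2))
  tr <- training_data(const, n_traj = 3, t_end = 2, n_points = 25, seed = 2)
  s1 <- suppressWarnings(run_scenario_1(tr, degree = 1))
  r <- classify(s1$model)
  expect_true(r$fispo)
})

test_that("comparison of identical models reports zero error everywhere", {
  lor <- case_model("Lorenz")
  d <- case_data("Lorenz")
  cmp <- compare_models(lor, lor, d$valid)
  expect_equal(cmp$structural$precision, 1)
  expect_equal(cmp$structural$recall, 1)
  expect_equal(cmp$parametric$max_rel_error, 0)
  expect_true(all(cmp$predictive < 1e-10))
})

test_that("a missing true term lowers recall and is flagged in the table", {
  lor <- case_model("Lorenz")
  partial <- ode_model("partial", lor$states, c("a", "b", "c"),
                       c("a*(x2 - x1)", "x1*b - x2", "x1*x2 - c*x3"),
                       x0 = lor$x0, param_values = lor$param_values)
  cmp <- compare_models(lor, partial)
  expect_lt(cmp$structural$recall, 1)
  expect_true("x1*x3" %in% cmp$structural$table$x2$missed)
})

test_that("the full prior-model scenario is deterministic at fixed seeds", {
  d <- case_data("Microbial")
  run_once <- function() suppressWarnings(
    run_scenario_2(case_model("Microbial"), d$train, degree = 2,
                   validation = d$valid))
  a <- run_once(); b <- run_once()
  expect_identical(vapply(a$scenario1$model$dynamics, deparse1, character(1)),
                   vapply(b$scenario1$model$dynamics, deparse1, character(1)))
  expect_identical(a$scenario1$model$param_values,
                   b$scenario1$model$param_values)
  expect_identical(a$comparison$structural, b$comparison$structural)
})

test_that("prior-branch reparameterization feeds the comparison (crypt)", {
  d <- case_data("Crypt")
  s2 <- suppressWarnings(
    run_scenario_2(case_model("Crypt"), d$train, degree = 3,
                   validation = d$valid))
  # the prior is not FISPO; PM* loses the two translation redundancies
  expect_false(s2$pm_report$fispo)
  expect_equal(length(s2$pm_star$params), 9)
  expect_true(classify(s2$pm_star)$fispo)
  # discovered M* is FISPO and predicts the held-out trajectories
  expect_true(s2$scenario1$reformulation$fispo_confirmed)
  expect_true(all(s2$comparison$predictive < 0.05))
})
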