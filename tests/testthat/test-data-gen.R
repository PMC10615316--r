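# Simulation and training-data generation.

test_that("simulation reproduces closed forms and conservation laws", {
  const <- ode_model("const", "x1", character(), "0", x0 = c(x1 = 5))
  d <- simulate_model(const, times = seq(0, 1, length.out = 20))
  expect_equal(unname(d$X[, 1]), rep(5, 20))
  expect_equal(unname(d$Xdot[, 1]), rep(0, 20))

  dec <- ode_model("decay", "x", character(), "-x", x0 = c(x = 1))
  d2 <- simulate_model(dec, times = seq(0, 3, length.out = 50))
  expect_equal(unname(d2$X[, 1]), exp(-d2$time), tolerance = 1e-7)

  # substrate-yield invariant: with zero decay, x1 + gamma*x2 is conserved
  mic <- case_model("Microbial")
  pv <- mic$param_values; pv["Kd"] <- 0
  d3 <- simulate_model(mic, params = pv, times = seq(0, 10, length.out = 60))
  inv <- d3$X[, 1] + pv[["gamma"]] * d3$X[, 2]
  expect_lt(diff(range(inv)), 1e-6 * abs(inv[1]))
})

test_that("simulation failure reports the offending time", {
  blow <- ode_model("blow", "x", character(), "x^2", x0 = c(x = 1))
  expect_error(simulate_model(blow, times = seq(0, 5, length.out = 50)),
               "simulation failed")
})

test_that("corruption is reproducible and the identity at zero noise", {
  d <- simulate_model(case_model("Lorenz"), times = seq(0, 2, length.out = 80))
  expect_identical(corrupt(d, 0, seed = 1, "exact")$X, d$X)
  c1 <- corrupt(d, 0.05, seed = 11, "finite_difference")
  c2 <- corrupt(d, 0.05, seed = 11, "finite_difference")
  expect_identical(c1$X, c2$X)
  expect_identical(c1$Xdot, c2$Xdot)
  expect_false(identical(corrupt(d, 0.05, seed = 12)$X, c1$X))
  expect_error(corrupt(d, -1), "noise_level")
})

test_that("finite differences track the truth within the difference-oracle bound", {
  # oracle: central differences of the analytic e^(-t) samples bound the
  # achievable accuracy; noisy differences must stay within that bound
  # inflated by the noise amplification 2*sigma/h
  dec <- ode_model("decay", "x", character(), "-x", x0 = c(x = 1))
  tt <- seq(0, 2, length.out = 101)
  d <- simulate_model(dec, times = tt)
  h <- tt[2] - tt[1]
  xs <- exp(-tt)
  oracle <- (xs[3:101] - xs[1:99]) / (2 * h)
  oracle_err <- max(abs(oracle - (-xs[2:100])))
  noise_level <- 0.01
  cn <- corrupt(d, noise_level, seed = 3, "finite_difference")
  sigma <- noise_level * stats::sd(d$X[, 1])
  bound <- oracle_err + 4 * sigma / h
  expect_lt(max(abs(cn$Xdot[2:100, 1] - (-cn$X[2:100, 1]))), bound)
})

test_that("central differences converge at second order on refinement", {
  dec <- ode_model("cube", "x", character(), "-x", x0 = c(x = 1))
  errs <- vapply(c(51, 101, 201), function(m) {
    d <- simulate_model(dec, times = seq(0, 2, length.out = m))
    fd <- corrupt(d, 0, seed = 1, "finite_difference")
    max(abs(fd$Xdot[2:(m - 1), 1] - d$Xdot[2:(m - 1), 1]))
  }, numeric(1))
  order1 <- log2(errs[1] / errs[2])
  order2 <- log2(errs[2] / errs[3])
  expect_gt(order1, 1.8)
  expect_gt(order2, 1.8)
})

test_that("training ensembles and text round-trips preserve provenance", {
  lor <- case_model("Lorenz")
  tr <- training_data(lor, n_traj = 3, t_end = 1, n_points = 20, seed = 5)
  expect_equal(length(unique(tr$traj)), 3)
  tr2 <- training_data(lor, n_traj = 3, t_end = 1, n_points = 20, seed = 5)
  expect_identical(tr$X, tr2$X)
  f <- tempfile(fileext = ".csv")
  write_ts(tr, f)
  back <- read_ts(f)
  expect_equal(back$X, tr$X, tolerance = 1e-12)
  expect_equal(back$Xdot, tr$Xdot, tolerance = 1e-12)
  unlink(c(f, paste0(f, ".prov.json")))
})
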