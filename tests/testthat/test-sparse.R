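# Implicit libraries, STLSQ, candidate assembly and selection.

test_that("the two-state degree-2 library has the canonical 12-term layout", {
  lib <- build_implicit_library(c("x1", "x2"), "x1", 2)
  expect_identical(lib$terms,
                   c("1", "x1", "x2", "x1^2", "x1*x2", "x2^2",
                     "dx1", "dx1*x1", "dx1*x2", "dx1*x1^2", "dx1*x1*x2",
                     "dx1*x2^2"))
  # the second state's library carries its own derivative instead
  lib2 <- build_implicit_library(c("x1", "x2"), "x2", 2)
  expect_identical(lib2$terms[7], "dx2")
  # degenerate case
  lib0 <- build_implicit_library("x1", "x1", 0)
  expect_identical(lib0$terms, c("1", "dx1"))
})

test_that("library size is 2*choose(n+d, d) for n <= 4, d <= 6", {
  for (n in 1:4) for (d in 0:6) {
    states <- paste0("x", seq_len(n))
    lib <- build_implicit_library(states, states[1], d)
    expect_equal(length(lib$terms), 2 * choose(n + d, d),
                 label = paste("n =", n, "d =", d))
  }
})

test_that("stlsq thresholds, reduces to OLS at zero, and is a fixed point", {
  A <- diag(2)
  xi <- stlsq(A, c(3, 0.001), 0.01)
  expect_equal(unname(as.numeric(xi)), c(3, 0))
  set.seed(9)
  A2 <- matrix(rnorm(60), 20, 3)
  b2 <- rnorm(20)
  expect_equal(as.numeric(stlsq(A2, b2, 0)),
               as.numeric(qr.coef(qr(A2), b2)), tolerance = 1e-10)
  # fixed point: re-running on the active set changes nothing
  xi2 <- stlsq(A2, b2, 0.2)
  act <- which(xi2 != 0)
  xi3 <- stlsq(A2[, act, drop = FALSE], b2, 0.2)
  expect_equal(as.numeric(xi2[act]), as.numeric(xi3), tolerance = 1e-12)
  # all columns eliminated: flagged all-zero, no exception
  xi4 <- stlsq(A2, b2, 100)
  expect_true(attr(xi4, "all_zero"))
  expect_equal(as.numeric(xi4), rep(0, 3))
})

test_that("stlsq recovers supports certified by exhaustive subset search", {
  set.seed(31)
  for (rep in 1:5) {
    A <- matrix(rnorm(240), 40, 6)
    xi_true <- numeric(6)
    sup <- sample(6, 2)
    xi_true[sup] <- sample(c(-1, 1), 2, TRUE) * runif(2, 1, 3)
    b <- as.numeric(A %*% xi_true)
    got <- stlsq(A, b, 0.1)
    # oracle: smallest support whose least-squares residual vanishes
    best <- NULL
    for (mask in 1:63) {
      cols <- which(bitwAnd(mask, bitwShiftL(1L, 0:5)) > 0)
      rss <- sum(qr.resid(qr(A[, cols, drop = FALSE]), b)^2)
      if (rss < 1e-18 && (is.null(best) || length(cols) < length(best)))
        best <- cols
    }
    expect_identical(which(got != 0), best)
    expect_identical(sort(best), sort(sup))
  }
})

test_that("sweeping yields the expected fit families", {
  lor <- case_model("Lorenz")
  d <- case_data("Lorenz")
  lib <- build_implicit_library(lor$states, "x1", 2)
  fits <- sweep_candidates(lib, d$train, lambdas = c(0.05))
  expect_gt(length(fits), 0)
  # among fits, one with lhs dx1 active exactly on {x1, x2}
  hit <- Filter(function(f)
    lib$terms[f$lhs] == "dx1" &&
      identical(lib$terms[which(f$xi != 0)], c("x1", "x2")), fits)
  expect_equal(length(hit), 1)
  expect_equal(sort(hit[[1]]$xi[hit[[1]]$xi != 0]), c(-10, 10),
               tolerance = 1e-6)
  # a single lambda and a single admissible lhs give exactly one fit
  lib0 <- build_implicit_library("x", "x", 1)
  dec <- ode_model("decay", "x", character(), "-x", x0 = c(x = 1))
  dd <- simulate_model(dec, times = seq(0, 2, length.out = 30))
  f1 <- sweep_candidates(lib0, dd, lambdas = 0.05)
  expect_gte(length(f1), 1)
})

test_that("a too-small library shows visibly larger residuals", {
  d <- case_data("Lorenz")
  lib1 <- build_implicit_library(c("x1", "x2", "x3"), "x2", 1)
  lib2 <- build_implicit_library(c("x1", "x2", "x3"), "x2", 2)
  best_rss <- function(lib) {
    fits <- suppressWarnings(sweep_candidates(lib, d$train, lambdas = 0.01))
    min(vapply(fits, `[[`, numeric(1), "rss"))
  }
  expect_gt(best_rss(lib1), 1e4 * best_rss(lib2))
})

test_that("explicit assembly solves the implicit equation for the derivative", {
  lib <- build_implicit_library(c("x1", "x2"), "x1", 2)
  # lhs dx1, active on x1 and x2: already explicit
  xi <- numeric(length(lib$terms))
  xi[match(c("x1", "x2"), lib$terms)] <- c(2, -3)
  asm <- assemble_explicit(list(lhs = match("dx1", lib$terms), xi = xi), lib)
  expect_equal(sindysio:::sp_to_string(asm$den), "1")
  expect_equal(sindysio:::sp_to_string(asm$num), "2*x1 - 3*x2")
  # lhs dx1*x1, xi active on {x1^2, dx1}: dx1 = a*x1^2 / (x1 - b)
  xi2 <- numeric(length(lib$terms))
  xi2[match(c("x1^2", "dx1"), lib$terms)] <- c(0.5, 0.25)
  asm2 <- assemble_explicit(list(lhs = match("dx1*x1", lib$terms), xi = xi2),
                            lib)
  # (0.5 x1^2) / (x1 - 0.25), normalized to constant term 1 in D
  X <- cbind(x1 = c(1, 2, 3), x2 = 0)
  got <- sindysio:::sp_eval_rows(asm2$num, X) /
    sindysio:::sp_eval_rows(asm2$den, X)
  expect_equal(got, 0.5 * X[, 1]^2 / (X[, 1] - 0.25), tolerance = 1e-12)
  # vanishing derivative coefficient is an assembly error
  xi3 <- numeric(length(lib$terms))
  xi3[match("x1", lib$terms)] <- 1
  expect_error(assemble_explicit(list(lhs = match("dx1", lib$terms),
                                      xi = xi3, check = TRUE), lib), NA)
})

test_that("AIC selection prefers the true structure over padded versions", {
  d <- case_data("Lorenz")
  states <- c("x1", "x2", "x3")
  mk <- function(coefs) {
    E <- matrix(0L, length(coefs), 3)
    for (i in seq_along(coefs)) E[i, ] <- coefs[[i]]$e
    sindysio:::sp_make(states, E, lapply(coefs, `[[`, "c"))
  }
  true_num <- mk(list(list(e = c(0, 1, 0), c = 10), list(e = c(1, 0, 0), c = -10)))
  spur_num <- mk(list(list(e = c(0, 1, 0), c = 10), list(e = c(1, 0, 0), c = -10),
                      list(e = c(0, 0, 1), c = 1e-9), list(e = c(2, 0, 0), c = -1e-9),
                      list(e = c(0, 2, 0), c = 1e-9)))
  one <- sindysio:::sp_const(states, 1)
  cands <- list(list(num = true_num, den = one, complexity = 3),
                list(num = spur_num, den = one, complexity = 6))
  sel <- select_pareto(cands, d$train, d$valid, state = 1)
  expect_equal(as.integer(sel), 1)
  # independent AIC computation from the two residual sums
  aic_of <- function(cand, k) {
    pred <- sindysio:::sp_eval_rows(cand$num, d$valid$X)
    msr <- mean((d$valid$Xdot[, 1] - pred)^2)
    floor_ <- (1e-9 * stats::sd(d$valid$Xdot[, 1]))^2
    length(d$valid$time) * log(max(msr, floor_)) + 2 * k
  }
  expect_lte(aic_of(cands[[1]], 3), aic_of(cands[[2]], 6))
  # a single candidate is returned unconditionally
  expect_equal(as.integer(select_pareto(cands[1], d$train, d$valid, 1)), 1)
})

test_that("candidates with vanishing denominators on data are discarded", {
  d <- case_data("Lorenz")  # x1 changes sign along the attractor
  states <- c("x1", "x2", "x3")
  num <- sindysio:::sp_make(states, matrix(c(0L, 1L, 0L), 1), list(1))
  den <- sindysio:::sp_make(states, matrix(c(1L, 0L, 0L), 1), list(1))
  good <- list(num = num, den = sindysio:::sp_const(states, 1), complexity = 2)
  bad <- list(num = num, den = den, complexity = 2)
  sel <- select_pareto(list(bad, good), d$train, d$valid, 1)
  expect_equal(as.integer(sel), 2)
  tab <- attr(sel, "table")
  expect_false(tab[[1]]$ok)
  expect_match(tab[[1]]$reason, "denominator")
})
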