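# Exact polynomial / rational-function layer: arithmetic agrees with
# numeric evaluation, division identities hold, canonical forms are stable.

rfs <- function(s, allowed = NULL) sindysio:::rf_from_string(s, allowed)

test_that("polynomial arithmetic agrees with a numeric evaluation oracle", {
  set.seed(42)
  vars <- c("x", "y", "z")
  rand_poly <- function() {
    nt <- sample(1:5, 1)
    E <- matrix(sample(0:3, 3 * nt, replace = TRUE), nt, 3)
    sindysio:::mp_make(vars, E, sample(-9:9, nt, replace = TRUE),
                       sample(1:4, nt, replace = TRUE))
  }
  for (rep in 1:25) {
    a <- rand_poly(); b <- rand_poly()
    env <- list(x = runif(1, 0.5, 2), y = runif(1, 0.5, 2),
                z = runif(1, 0.5, 2))
    ev <- function(p) sindysio:::mp_eval_num(p, env)
    expect_equal(ev(sindysio:::mp_add(a, b)), ev(a) + ev(b), tolerance = 1e-10)
    expect_equal(ev(sindysio:::mp_mul(a, b)), ev(a) * ev(b), tolerance = 1e-10)
    expect_equal(ev(sindysio:::mp_sub(a, b)), ev(a) - ev(b), tolerance = 1e-10)
    # derivative vs central difference
    h <- 1e-6
    envp <- env; envp$x <- env$x + h
    envm <- env; envm$x <- env$x - h
    expect_equal(ev(sindysio:::mp_deriv(a, "x")),
                 (sindysio:::mp_eval_num(a, envp) -
                  sindysio:::mp_eval_num(a, envm)) / (2 * h),
                 tolerance = 1e-4)
  }
})

test_that("multivariate division satisfies N = q*d + r with reduced r", {
  set.seed(7)
  for (rep in 1:15) {
    N <- rfs(paste0(sample(2:9, 1), "*x^", sample(0:4, 1), "*y^",
                    sample(0:3, 1), " + ", sample(1:9, 1), "*x + ",
                    sample(1:9, 1)))$num
    d <- rfs(paste0(sample(1:5, 1), "*x + ", sample(1:5, 1), "*y + 1"))$num
    dv <- sindysio:::mp_divrem(N, d)
    lhs <- sindysio:::mp_add(sindysio:::mp_mul(dv$q, d), dv$r)
    expect_true(sindysio:::mp_equal(lhs, N))
  }
})

test_that("rational simplification cancels exact factors", {
  r <- rfs("x1/(1+x1) + x1")
  expect_equal(sindysio:::rf_to_string(r), "(x1^2 + 2*x1)/(x1 + 1)")
  r2 <- rfs("(x^2 - 1)/(x - 1)")
  expect_true(sindysio:::rf_equal(r2, rfs("x + 1")))
  # quotient-rule derivative matches the closed form
  f <- rfs("x^2/(1 + x)")
  fp <- sindysio:::rf_deriv(f, "x")
  expect_true(sindysio:::rf_equal(fp, rfs("(x^2 + 2*x)/(1 + x)^2")))
})

test_that("doubles rationalize exactly for simple fractions", {
  expect_equal(sindysio:::.as_rat(8 / 3), c(8, 3))
  expect_equal(sindysio:::.as_rat(-0.25), c(-1, 4))
  expect_equal(sindysio:::.as_rat(5), c(5, 1))
  # an OLS-style value snaps to the clean fraction
  expect_equal(sindysio:::.as_rat(2 / 3 + 3e-13), c(2, 3))
})

test_that("modular evaluation matches rational arithmetic", {
  p <- rfs("(8/3)*x^2 + y")$num
  prime <- sindysio:::SIO_PRIME
  got <- sindysio:::mp_eval_mod(p, c(x = 5, y = 7), prime)
  inv3 <- sindysio:::.mod_inv(3, prime)
  expect_equal(got, (8 * 25 * inv3 + 7) %% prime)
})
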