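# Lie symmetry detection and symmetry-breaking reparameterization.

test_that("a parameter-sum invariance is found as a translation", {
  m <- ode_model("t1", "x", c("p1", "p2"), "(p1 + p2)*x")
  tr <- find_symmetries(m)
  expect_equal(length(tr), 1)
  expect_equal(tr[[1]]$kind, "translation")
  expect_setequal(tr[[1]]$affected, c("p1", "p2"))
  # opposite weights: p1* = p1 + eps, p2* = p2 - eps
  expect_equal(abs(unname(tr[[1]]$weights["p1"])), 1)
  expect_equal(unname(tr[[1]]$weights["p1"] + tr[[1]]$weights["p2"]), 0)
})

test_that("the QSSM model carries a single scaling between gamma and alpha", {
  tr <- find_symmetries(case_model("Immunity"))
  expect_equal(length(tr), 1)
  expect_equal(tr[[1]]$kind, "scaling")
  expect_setequal(tr[[1]]$affected, c("gamma", "alpha"))
  # breaking at alpha gives the gamma* = gamma/alpha normal form
  br <- break_symmetry(case_model("Immunity"), tr[[1]], pivot = "alpha")
  expect_identical(br$eliminated, "alpha")
  expect_identical(deparse1(br$param_map$gammas), "gamma/alpha")
  expect_dynamics_equal(case_model("Immunity"), br$model, br$param_map)
})

test_that("the crypt model carries two renewal/death translations", {
  tr <- find_symmetries(case_model("Crypt"))
  expect_equal(length(tr), 2)
  expect_true(all(vapply(tr, function(t) t$kind, character(1)) ==
                  "translation"))
  aff <- sort(unlist(lapply(tr, `[[`, "affected")))
  expect_identical(aff, c("a1", "a3", "b1", "b3"))
})

test_that("symmetry transforms leave the simulated output invariant", {
  # the same trajectories arise from transformed parameter values
  set.seed(21)
  for (id in c("Immunity", "Crypt")) {
    m <- case_model(id)
    trs <- find_symmetries(m)
    times <- seq(0, 3, length.out = 40)
    base <- simulate_model(m, times = times)
    for (tr in trs) for (eps in stats::runif(5, -0.5, 0.5)) {
      pv <- apply_symmetry(tr, eps, m$param_values)
      alt <- simulate_model(m, params = pv, times = times)
      expect_lt(max(abs(alt$X - base$X)), 1e-6 * max(1, max(abs(base$X))))
    }
  }
})

test_that("breaking substitutes an equivalent model with one less parameter", {
  for (id in c("Immunity", "Crypt")) {
    m <- case_model(id)
    tr <- find_symmetries(m)[[1]]
    br <- break_symmetry(m, tr)
    expect_equal(length(unknown_params(br$model)),
                 length(unknown_params(m)) - 1)
    expect_dynamics_equal(m, br$model, br$param_map)
  }
  # pivot validation
  m <- case_model("Immunity")
  tr <- find_symmetries(m)[[1]]
  expect_error(break_symmetry(m, tr, pivot = "beta"), "not in the affected")
})

test_that("autorepar reaches FISPO and is idempotent", {
  for (id in c("Immunity", "Crypt")) {
    ch <- autorepar(case_model(id))
    expect_true(ch$fispo)
    expect_false(ch$unresolved)
    # composed map reproduces the original dynamics
    expect_dynamics_equal(case_model(id), ch$model, ch$param_map)
    # a second pass is the empty chain
    ch2 <- autorepar(ch$model)
    expect_equal(length(ch2$steps), 0)
    expect_true(ch2$fispo)
  }
})

test_that("candidate structures break via per-term scalings as published", {
  ch_b <- case_cm_chain("Bacterial")
  expect_true(ch_b$fispo)
  expect_equal(length(ch_b$steps), 4)
  expect_true(all(vapply(ch_b$steps, function(s) s$transform$kind,
                         character(1)) == "scaling"))
  expect_equal(length(ch_b$model$params), 12)
  expect_dynamics_equal(case_model("Bacterial", "cm"), ch_b$model,
                        ch_b$param_map)

  ch_g <- case_cm_chain("Glycolysis")
  expect_true(ch_g$fispo)
  expect_equal(length(ch_g$steps), 3)
  affected <- lapply(ch_g$steps, function(s) sort(s$transform$affected))
  expect_identical(affected, list(c("p2", "p3", "p4"), c("p7", "p8", "p9"),
                                  c("p24", "p25", "p26")))
  # the published normalizations: each term scaled by its denominator
  # constant, p2* = p2/p4, p3* = p3/p4, and so on
  pivots <- vapply(ch_g$steps, `[[`, character(1), "pivot")
  expect_identical(pivots, c("p4", "p9", "p25"))
  expect_identical(deparse1(ch_g$param_map$p2s), "p2/p4")
  expect_identical(deparse1(ch_g$param_map$p3s), "p3/p4")
  expect_identical(deparse1(ch_g$param_map$p7s), "p7/p9")
  expect_identical(deparse1(ch_g$param_map$p24s), "p24/p25")
  expect_dynamics_equal(case_model("Glycolysis", "cm"), ch_g$model,
                        ch_g$param_map)
})
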