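# Structural identifiability and observability.

test_that("symbolic Lie-derivative rows match closed forms", {
  m <- ode_model("toy", "x", "p", "-p*x")
  oi <- lie_derivative_rows(m, 1)
  str_of <- function(r) sindysio:::rf_to_string(r)
  expect_equal(length(oi$rows), 2)
  expect_identical(vapply(oi$rows[[1]], str_of, character(1)), c("1", "0"))
  expect_identical(vapply(oi$rows[[2]], str_of, character(1)), c("-p", "-x"))
  # order-0 rows of a fully observed system: identity on states, zero on
  # parameters
  lor <- case_model("Lorenz")
  oi0 <- lie_derivative_rows(lor, 0)
  M0 <- do.call(rbind, lapply(oi0$rows, function(r)
    vapply(r, function(e) sindysio:::rf_eval_num(e, list()), numeric(1))))
  expect_equal(M0, cbind(diag(3), matrix(0, 3, 3)))
  # row counting: 3 outputs x 6 orders for the 6-dim augmented system
  oi5 <- lie_derivative_rows(lor, 5)
  expect_equal(length(oi5$rows), 18)
  expect_equal(length(oi5$vars), 6)
})

test_that("generic rank handles closed-form and degenerate cases", {
  m <- ode_model("toy", "x", "p", "-p*x")
  expect_equal(generic_rank(m), 2)
  expect_equal(generic_rank(lie_derivative_rows(m, 1)), 2)
  # all-zero rows: rank 0
  z <- matrix(0, 3, 3)
  expect_equal(sindysio:::rank_mod(z, sindysio:::SIO_PRIME), 0)
  # symbolic and series routes agree on a rational model (the rank of the
  # Monod system stabilizes by order 2, so order 3 suffices symbolically)
  mic <- case_model("Microbial")
  expect_equal(generic_rank(lie_derivative_rows(mic, 3)), generic_rank(mic))
})

test_that("rank is monotone in Lie order and bounded by the dimension", {
  m <- ode_model("sat", c("x1", "x2"), c("p1", "p2", "p3"),
                 c("p1*x1/(1 + p2*x2)", "-p3*x2"))
  ranks <- vapply(0:4, function(k)
    generic_rank(lie_derivative_rows(m, k), seed = 3), numeric(1))
  expect_true(all(diff(ranks) >= 0))
  expect_true(all(ranks <= augment(m)$nxt))
  expect_equal(ranks[5], 5)  # the saturated-growth model is FISPO
})

test_that("the six ground-truth models reproduce the published FISPO pattern", {
  verdicts <- vapply(case_ids(), function(id) classify(case_model(id))$fispo,
                     logical(1))
  expect_identical(unname(verdicts), c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE))
})

test_that("per-parameter classification matches the published sets", {
  r_imm <- classify(case_model("Immunity"))
  expect_setequal(r_imm$unidentifiable, c("gamma", "alpha"))
  expect_setequal(r_imm$unobservable, character(0))

  r_cry <- classify(case_model("Crypt"))
  expect_setequal(r_cry$unidentifiable, c("a1", "a3", "b1", "b3"))

  r_icm <- classify(case_model("Immunity", "cm"))
  expect_setequal(r_icm$unidentifiable, c("p4", "p5", "p6"))

  r_bcm <- classify(case_model("Bacterial", "cm"))
  expect_setequal(r_bcm$identifiable, "p1")

  r_mcm <- classify(case_model("Microbial", "cm"))
  expect_setequal(r_mcm$identifiable, "p1")

  r_ccm <- classify(case_model("Crypt", "cm"))
  expect_setequal(r_ccm$identifiable, c("p1", "p2", "p16", "p17", "p21"))

  r_gcm <- classify(case_model("Glycolysis", "cm"))
  expect_setequal(r_gcm$unidentifiable,
                  paste0("p", c(2, 3, 4, 7, 8, 9, 24, 25, 26)))
})

test_that("verdicts are stable across specialization seeds", {
  for (seed in c(2, 5, 11)) {
    r <- classify(case_model("Immunity"), seed = seed)
    expect_false(r$fispo)
    expect_setequal(r$unidentifiable, c("gamma", "alpha"))
    expect_equal(r$rank, 10)
  }
})

test_that("rank deficiency equals the number of independent symmetries", {
  for (id in c("Immunity", "Crypt")) {
    m <- case_model(id)
    r <- classify(m)
    tr <- find_symmetries(m)
    expect_equal(r$nxt - r$rank, length(tr), label = id)
  }
  r_bcm <- classify(case_model("Bacterial", "cm"))
  expect_equal(r_bcm$nxt - r_bcm$rank,
               length(find_symmetries(case_model("Bacterial", "cm"))))
})
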