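# Model parsing, serialization, rational form and augmentation.

test_that("parsing a convection-system definition yields the right dynamics", {
  m <- parse_model(c("name: lor", "states: x1 x2 x3", "params: a b c",
                     "dx1/dt = a*(x2 - x1)",
                     "dx2/dt = x1*(b - x3) - x2",
                     "dx3/dt = x1*x2 - c*x3"))
  expect_identical(m$states, c("x1", "x2", "x3"))
  expect_rf_equal(deparse1(m$dynamics$x1), "a*x2 - a*x1",
                  c(m$states, m$params))
  expect_rf_equal(deparse1(m$dynamics$x2), "b*x1 - x1*x3 - x2",
                  c(m$states, m$params))
})

test_that("degenerate and invalid definitions behave as specified", {
  m0 <- parse_model(c("states: x1", "dx1/dt = 0"))
  expect_identical(deparse1(m0$dynamics$x1), "0")
  expect_error(parse_model(c("states: x1", "dx1/dt = q*x1")),
               "undeclared symbol.*q")
  expect_error(parse_model(c("states: x1 x2", "dx1/dt = x1")),
               "structural error")
  expect_error(ode_model("m", "x1", "x1", "x1"), "collide")
  expect_error(ode_model("m", "x1", character(), "exp(x1)"),
               "unsupported")
})

test_that("models round-trip through text and JSON serialization", {
  for (id in c("Lorenz", "Immunity", "Crypt")) {
    m <- case_model(id)
    m2 <- parse_model(format_model(m))
    expect_identical(m2$states, m$states)
    expect_identical(m2$params, m$params)
    expect_dynamics_equal(m, m2)
    jf <- tempfile(fileext = ".json")
    write_model(m, jf)
    m3 <- read_model(jf)
    expect_dynamics_equal(m, m3)
    expect_equal(m3$param_values, m$param_values)
    unlink(jf)
  }
})

test_that("implicit rational form reproduces the dynamics exactly", {
  for (id in case_ids()) {
    m <- case_model(id)
    rfm <- to_rational_form(m)
    allowed <- c(m$states, m$params)
    for (s in m$states) {
      lhs <- sindysio:::rf_make(rfm[[s]]$num, rfm[[s]]$den)
      rhs <- sindysio:::rf_from_expr(m$dynamics[[s]], allowed)
      expect_true(sindysio:::rf_equal(lhs, rhs),
                  label = paste(id, s, "N/D == f"))
    }
  }
})

test_that("implicit-form degrees match the case-study structure", {
  degs <- vapply(case_ids(), function(id) rational_degrees(case_model(id)),
                 numeric(2))
  # numerator degrees across Lorenz..Glycolysis
  expect_equal(unname(degs["deg_num", ]), c(2, 3, 6, 2, 3, 6))
  # denominator degrees computed from the printed equations
  expect_equal(unname(degs["deg_den", ]), c(0, 1, 6, 1, 2, 4))
  # non-rational entries are rejected
  expect_error(to_rational_form(
    structure(list(name = "bad", states = "x", params = character(),
                   dynamics = list(x = quote(exp(x))), outputs = list(quote(x)),
                   known = character()), class = "ode_model")),
    "unsupported")
})

test_that("augmentation appends constant parameter states", {
  lor <- case_model("Lorenz")
  a <- augment(lor)
  expect_equal(a$nxt, 6)
  expect_identical(a$states, c("x1", "x2", "x3", "a", "b", "c"))
  expect_true(all(vapply(a$dynamics[4:6], identical, logical(1), quote(0))))
  # outputs carried over verbatim
  expect_identical(a$outputs, lor$outputs)
  # all-known parameters: augmented dimension collapses to n
  lork <- lor; lork$known <- lor$params
  expect_equal(augment(lork)$nxt, 3)
  # the large candidate structure: 7 states + 29 coefficients
  expect_equal(augment(case_model("Glycolysis", "cm"))$nxt, 36)
})
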