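test_that("a well-formed model validates with no diagnostics", {
  expect_identical(validate_model(benchmark_model()), character(0))
  expect_identical(validate_model(immigration_death_model()), character(0))
})

test_that("structural violations produce targeted diagnostics", {
  short <- ode_model(c("a", "b"), function(x, t) x[1], c(1, 2))
  d <- validate_model(short)
  expect_true(any(grepl("drift length mismatch", d)))

  bad_dec <- ode_model(
    c("a", "b"), function(x, t) -x, c(1, 2),
    decomposition = list(production = function(x, t) -x + 1,
                         degradation = function(x, t) rep(0, 2))
  )
  d <- validate_model(bad_dec)
  expect_true(any(grepl("inconsistent", d)))
  expect_true(any(grepl("\\ba\\b", d))) # names the offending species

  raising <- ode_model("a", function(x, t) stop("boom"), 1)
  d <- validate_model(raising)
  expect_true(any(grepl("raised an error", d)))
})

test_that("concentration-to-count conversion applies Omega = N_A * V * u", {
  m <- ode_model(
    data.frame(name = "x", compartment = "cell", unit = "concentration"),
    drift = function(x, t) -x, initial_state = 1,
    compartments = list(compartment("cell", 1e-15))
  )
  cv <- convert_to_counts(m, "uM")
  expect_equal(cv$report$omega, 6.02214076e23 * 1e-15 * 1e-6)
  expect_equal(cv$report$initial_count, 602.214076, tolerance = 1e-9)
  expect_true(all(cv$model$species$unit == "count"))
  # drift transforms covariantly: pure decay stays pure decay of the counts
  expect_equal(cv$model$drift(602.214076, 0), -602.214076)
})

test_that("count-only models convert to themselves with Omega = 1", {
  m <- benchmark_model()
  cv <- convert_to_counts(m, "uM")
  expect_identical(cv$model, m)
  expect_true(all(cv$report$omega == 1))
})

test_that("converted decay reproduces the closed-form solution", {
  m <- ode_model(
    data.frame(name = "x", compartment = "cell", unit = "concentration"),
    drift = function(x, t) -x, initial_state = 1,
    compartments = list(compartment("cell", 1e-15))
  )
  n <- convert_to_counts(m, "uM")$model
  tr <- ode_solve(n, T = 1, rtol = 1e-10, atol = 1e-12,
                  grid = c(0, 1))
  expect_equal(unname(tr$states[2, 1]), 602.214076 * exp(-1),
               tolerance = 1e-6)
})

test_that("conversion errors identify the offending species", {
  m <- ode_model(
    data.frame(name = c("x", "y"), compartment = c("cell", NA),
               unit = c("count", "concentration")),
    drift = function(x, t) -x, initial_state = c(1, 1),
    compartments = list(compartment("cell", 1e-15))
  )
  expect_error(convert_to_counts(m, "uM"), "y")
})

test_that("conversion round-trip reproduces polynomial drifts", {
  # dx1/dt = 2 - 3 x1 + x1 x2, dx2/dt = x1^2 - x2
  f <- function(x, t) c(2 - 3 * x[1] + x[1] * x[2], x[1]^2 - x[2])
  m <- ode_model(
    data.frame(name = c("x1", "x2"), compartment = "c",
               unit = "concentration"),
    drift = f, initial_state = c(0.5, 0.25),
    compartments = list(compartment("c", 2e-15))
  )
  cv <- convert_to_counts(m, "nM")
  om <- cv$report$omega
  for (x in list(c(0.5, 0.25), c(1, 2), c(0.01, 3))) {
    expect_equal(cv$model$drift(om * x, 0) / om, f(x, 0),
                 tolerance = 1e-12)
  }
})

test_that("zero-clamp decomposition matches hand-evaluated examples", {
  m <- ode_model("M", function(x, t) 5 - x, 3)
  dec <- default_decomposition(m)
  expect_equal(dec$production(3, 0), 5)
  expect_equal(dec$degradation(3, 0), 3)

  # repression drift f_m = beta/(1+p^2) - m with beta=10: at (m,p) = (4,3)
  mp <- ode_model(c("m", "p"),
                  function(x, t) c(10 / (1 + x[2]^2) - x[1], 0),
                  c(4, 3))
  dec <- default_decomposition(mp)
  expect_equal(dec$production(c(4, 3), 0)[1], 1)
  expect_equal(dec$degradation(c(4, 3), 0)[1], 4)

  # pure decay at the absorbing zero state
  dm <- ode_model("x", function(x, t) -x, 0)
  dec <- default_decomposition(dm)
  expect_equal(dec$production(0, 0), 0)
  expect_equal(dec$degradation(0, 0), 0)
})

test_that("zero-clamp split is exact for linear mass-action drifts", {
  # chain with constant and linear production, linear degradation
  f <- function(x, t) c(4 - 2 * x[1], 3 * x[1] - 0.5 * x[2])
  m <- ode_model(c("a", "b"), f, c(2, 12))
  dec <- default_decomposition(m)
  expect_true(dec$consistent)
  states <- rbind(c(0, 0), c(1, 5), c(7, 0.1), c(0.3, 44))
  for (k in seq_len(nrow(states))) {
    x <- states[k, ]
    expect_equal(dec$production(x, 0) - dec$degradation(x, 0), f(x, 0),
                 tolerance = 1e-12)
    # no degradation pressure at zero copies
    for (i in 1:2) {
      xi <- x
      xi[i] <- 0
      expect_equal(dec$degradation(xi, 0)[i], 0)
    }
  }
})

test_that("autocatalytic production is detected and flagged", {
  m <- ode_model("x", function(x, t) 0.5 * x, 1) # production ~ own species
  expect_warning(dec <- default_decomposition(m), "explicit")
  expect_false(dec$consistent)
})

test_that("drift undefined at zero copy asks for an explicit split", {
  m <- ode_model("x", function(x, t) 1 / x, 1)
  expect_error(default_decomposition(m), "explicit")
})

test_that("a user decomposition is returned untouched", {
  m <- immigration_death_model()
  expect_identical(default_decomposition(m), m$decomposition)
})

test_that("input signals require strictly increasing event times", {
  expect_error(input_signal("u", function(t) 1, c(1, 1)), "increasing")
  expect_silent(input_signal("u", function(t) 1, c(1, 2, 3)))
})

test_that("compartments reject non-positive volumes", {
  expect_error(compartment("c", 0), "positive")
  expect_error(compartment("c", -1), "positive")
})
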