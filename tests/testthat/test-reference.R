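test_that("networks derive two channels per species from the split", {
  net <- network_from_decomposition(benchmark_model())
  expect_equal(ncol(net$stoich), 4L)
  expect_equal(net$propensity(c(3, 100), 0), c(5, 3, 150, 10))
  expect_equal(net$stoich[, 1], c(1, 0))
  expect_equal(net$stoich[, 2], c(-1, 0))
  expect_equal(net$stoich[, 3], c(0, 1))
  expect_equal(net$stoich[, 4], c(0, -1))
  zero <- ode_model("x", function(x, t) 0, 1,
                    decomposition = list(production = function(x, t) 0,
                                         degradation = function(x, t) 0))
  znet <- network_from_decomposition(zero)
  expect_equal(znet$propensity(10, 0), c(0, 0))
})

test_that("an inconsistent decomposition cannot build a network", {
  m <- ode_model("x", function(x, t) 0.5 * x, 1)
  expect_warning(expect_error(network_from_decomposition(m),
                              "inconsistent"))
})

test_that("SSA freezes when all propensities vanish", {
  zero <- reaction_network("x", matrix(1, 1, 1),
                           function(x, t) 0, init = 4)
  tr <- ssa_direct(zero, T = 10, seed = 1, grid = seq(0, 10))
  expect_true(all(tr$states == 4))
})

test_that("SSA stationary law of immigration-death is Poisson", {
  net <- network_from_decomposition(immigration_death_model())
  tr <- ssa_direct(net, T = 3000, seed = 101, grid = seq(0, 3000, by = 1))
  st <- stationary_stats(tr, burn_in = 50)
  expect_equal(st$mean, 5, tolerance = 0.05)
  expect_equal(st$variance, 5, tolerance = 0.12)
  x <- tr$states[tr$times >= 50, 1]
  expect_equal(mean(x == 0), exp(-5), tolerance = 0.6)
})

test_that("SSA histogram passes a chi-square test against Poisson(5)", {
  net <- network_from_decomposition(immigration_death_model())
  tr <- ssa_direct(net, T = 15000, seed = 17, grid = seq(0, 15000, by = 3))
  x <- tr$states[tr$times >= 50, 1]
  breaks <- c(-0.5, seq(0.5, 11.5), Inf)
  obs <- table(cut(x, breaks))
  pr <- diff(ppois(c(-1, 0:11, Inf), 5))
  pv <- suppressWarnings(chisq.test(as.vector(obs), p = pr)$p.value)
  expect_gt(pv, 0.01)
})

test_that("pure-death ensemble mean follows binomial thinning", {
  net <- network_from_decomposition(decay_model(x0 = 10))
  finals <- vapply(1:400, function(r) {
    ssa_direct(net, T = log(2), seed = 1000 + r,
               grid = c(0, log(2)))$states[2, 1]
  }, numeric(1))
  se <- sqrt(10 * 0.5 * 0.5 / 400)
  expect_lt(abs(mean(finals) - 5), 3 * se + 1e-9)
})

test_that("tau-leaping is exact for constant propensities", {
  # pure immigration at rate 5 to T = 10: final count ~ Poisson(50)
  net <- reaction_network("x", matrix(1, 1, 1), function(x, t) 5, init = 0)
  finals <- vapply(1:400, function(r) {
    tau_leap(net, tau = 0.5, T = 10, seed = 2000 + r,
             grid = c(0, 10))$states[2, 1]
  }, numeric(1))
  expect_lt(abs(mean(finals) - 50), 3 * sqrt(50 / 400))
  expect_equal(var(finals), 50, tolerance = 0.3)
})

test_that("a leap longer than the horizon is a single step", {
  net <- reaction_network("x", matrix(1, 1, 1), function(x, t) 5, init = 0)
  tr <- tau_leap(net, tau = 20, T = 10, seed = 1, grid = c(0, 10))
  expect_equal(attr(tr, "n_steps"), 1L)
})

test_that("tau-leap halving prevents negative counts", {
  net <- network_from_decomposition(decay_model(x0 = 3, d = 10))
  tr <- tau_leap(net, tau = 1, T = 5, seed = 6, grid = seq(0, 5, by = 0.5))
  expect_true(all(tr$states >= 0))
})

test_that("tau-leap matches the SSA oracle at small tau", {
  net <- network_from_decomposition(immigration_death_model())
  tr <- tau_leap(net, tau = 0.02, T = 6000, seed = 31,
                 grid = seq(0, 6000, by = 0.5))
  st <- stationary_stats(tr, burn_in = 50)
  expect_equal(st$mean, 5, tolerance = 0.02)
})

test_that("HR with all channels fast equals the ODE solve", {
  net <- network_from_decomposition(benchmark_model())
  grid <- seq(0, 50, by = 1)
  tr <- hr_hybrid(net, channel_partition(net, integer(0)), T = 50,
                  seed = 1, grid = grid)
  od <- ode_solve(benchmark_model(), T = 50, grid = grid)
  expect_lt(max(abs(tr$states - od$states)), 1e-3)
})

test_that("HR with all channels slow reproduces the Poisson law", {
  net <- network_from_decomposition(immigration_death_model())
  tr <- hr_hybrid(net, channel_partition(net, "X"), T = 1500, seed = 23,
                  grid = seq(0, 1500, by = 1))
  x <- tr$states[tr$times >= 50, 1]
  expect_equal(mean(x), 5, tolerance = 0.06)
  expect_equal(mean((x - mean(x))^2), 5, tolerance = 0.2)
  breaks <- c(-0.5, seq(0.5, 11.5), Inf)
  obs <- table(cut(x, breaks))
  pr <- diff(ppois(c(-1, 0:11, Inf), 5))
  pv <- suppressWarnings(chisq.test(as.vector(obs), p = pr)$p.value)
  expect_gt(pv, 0.001)
})

test_that("HR on the benchmark matches the two-stage statistics", {
  net <- network_from_decomposition(benchmark_model())
  tr <- hr_hybrid(net, channel_partition(net, "M"), T = 1500, seed = 12)
  st <- stationary_stats(tr, burn_in = 50)
  expect_equal(st$mean[st$species == "M"], 5, tolerance = 0.08)
  expect_equal(st$mean[st$species == "P"], 2500, tolerance = 0.04)
})

test_that("reference engines are bitwise reproducible given the seed", {
  net <- network_from_decomposition(benchmark_model())
  grid <- seq(0, 20, by = 0.1)
  expect_identical(ssa_direct(net, 20, seed = 5, grid = grid)$states,
                   ssa_direct(net, 20, seed = 5, grid = grid)$states)
  expect_identical(tau_leap(net, 0.05, 20, seed = 5, grid = grid)$states,
                   tau_leap(net, 0.05, 20, seed = 5, grid = grid)$states)
  expect_identical(
    hr_hybrid(net, channel_partition(net, "M"), 20, seed = 5,
              grid = grid)$states,
    hr_hybrid(net, channel_partition(net, "M"), 20, seed = 5,
              grid = grid)$states)
})

test_that("ode_solve matches closed forms and handles zero drift", {
  tr <- ode_solve(decay_model(x0 = 10), T = log(2), rtol = 1e-8,
                  atol = 1e-10, grid = c(0, log(2)))
  expect_equal(unname(tr$states[2, 1]), 5, tolerance = 1e-6)
  z <- ode_model("x", function(x, t) 0, 3)
  expect_true(all(ode_solve(z, T = 5, grid = seq(0, 5))$states == 3))
  tr <- ode_solve(benchmark_model(), T = 200, grid = seq(0, 200, by = 1))
  expect_equal(tr$states[201, ], c(5, 2500), tolerance = 1e-3,
               ignore_attr = TRUE)
})
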