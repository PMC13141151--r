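test_that("benchmark model has the documented steady state and channels", {
  m <- benchmark_model()
  expect_equal(species_names <- m$species$name, c("M", "P"))
  expect_equal(m$drift(c(5, 2500), 0), c(0, 0))
  expect_equal(m$decomposition$production(c(3, 100), 0), c(5, 150))
  expect_equal(m$decomposition$degradation(c(3, 100), 0), c(3, 10))
  expect_identical(validate_model(m), character(0))
})

test_that("repressilator toy is a six-species oscillator", {
  m <- repressilator_model()
  expect_equal(m$species$name, c("m1", "m2", "m3", "p1", "p2", "p3"))
  # symmetric fixed point: r = alpha / (1 + r^2)
  r <- uniroot(function(r) 216 / (1 + r^2) - r, c(1, 216))$root
  expect_equal(m$drift(rep(r, 6), 0), rep(0, 6), tolerance = 1e-6)
  # sustained oscillation: >= 3 local maxima of m1 over horizon 500
  tr <- run_presim(m, horizon = 500, n_grid = 2001)
  d <- diff(tr$states[, "m1"])
  s <- sign(d)
  s <- s[s != 0]
  n_maxima <- sum(s[-length(s)] > 0 & s[-1] < 0)
  expect_gte(n_maxima, 3)
})

test_that("corpus generation is deterministic in the spec", {
  spec <- corpus_spec(n_models = 6L, seed = 7L)
  c1 <- generate_corpus(spec)
  c2 <- generate_corpus(spec)
  expect_identical(
    lapply(c1$models, `[[`, "family_params"),
    lapply(c2$models, `[[`, "family_params")
  )
  expect_identical(c1$metadata, c2$metadata)
})

test_that("the default corpus has the expected size and structure", {
  corp <- generate_corpus(corpus_spec())
  expect_equal(length(corp$models), 40L)
  total <- sum(corp$metadata$n_species)
  expect_gte(total, 200)
  expect_lte(total, 400)
  # corpus invariant: every model validates
  for (m in corp$models) {
    expect_identical(validate_model(m), character(0))
  }
})

test_that("generated abundances are bimodal around the labeling band", {
  corp <- generate_corpus(corpus_spec())
  finals <- unlist(lapply(corp$models, function(m) {
    tr <- run_presim(m, horizon = corp$spec$presim_horizon, n_grid = 201)
    tr$states[nrow(tr$states), ]
  }))
  in_band <- finals >= 150 & finals <= 300
  expect_gte(mean(!in_band), 0.9)
})

test_that("generated drifts cannot push a species negative at zero", {
  corp <- generate_corpus(corpus_spec(n_models = 10L, seed = 3L))
  for (m in corp$models) {
    probes <- hybridsim:::probe_states(m, n = 8L, seed = 5L)
    for (k in seq_len(nrow(probes))) {
      x <- probes[k, ]
      for (i in seq_along(x)) {
        xi <- x
        xi[i] <- 0
        expect_gte(m$drift(xi, 0)[i], -1e-12)
      }
    }
  }
})

test_that("degenerate corpus specs are rejected", {
  expect_error(corpus_spec(family_mix = c(birth_death_chain = 0)),
               "positive sum")
  expect_error(corpus_spec(family_mix = c(nosuch = 1)), "unknown")
  expect_error(corpus_spec(low_copy_scale_range = c(5, 1)), "ordered")
})

test_that("model files round-trip through the declarative schema", {
  dir <- withr::local_tempdir()
  m <- generate_corpus(corpus_spec(n_models = 3L, seed = 11L))$models[[2]]
  path <- file.path(dir, "m.json")
  write_model_file(m, path)
  m2 <- read_model_file(path)
  expect_identical(m2$species, m$species)
  expect_equal(m2$initial_state, m$initial_state)
  probes <- hybridsim:::probe_states(m, n = 5L, seed = 2L)
  for (k in seq_len(nrow(probes))) {
    expect_equal(m2$drift(probes[k, ], 0), m$drift(probes[k, ], 0),
                 tolerance = 1e-12)
  }
  expect_error(read_model_file(path, plugins = list()), NA)
  # unknown keys rejected
  doc <- jsonlite::read_json(path)
  doc$bogus <- 1
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  expect_error(read_model_file(path), "unknown keys")
})

test_that("corpora round-trip through a serialized directory", {
  dir <- withr::local_tempdir()
  corp <- generate_corpus(corpus_spec(n_models = 4L, seed = 13L))
  write_corpus(corp, dir)
  corp2 <- read_corpus(dir)
  expect_equal(corp2$metadata$model_id, corp$metadata$model_id)
  expect_equal(corp2$spec$seed, corp$spec$seed)
  x0 <- corp$models[[1]]$initial_state
  expect_equal(corp2$models[[1]]$drift(x0, 0),
               corp$models[[1]]$drift(x0, 0))
})
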