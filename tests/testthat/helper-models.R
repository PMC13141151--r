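# Small fixture models built in code.

# one-species immigration-death process: dx/dt = k - d*x, stationary
# Poisson(k/d) under exact stochastic dynamics
immigration_death_model <- function(k = 5, d = 1, x0 = 0) {
  ode_model(
    "X", drift = function(x, t) k - d * x, initial_state = x0,
    parameters = list(k = k, d = d),
    decomposition = list(production = function(x, t) k,
                         degradation = function(x, t) d * x,
                         source = "user", consistent = TRUE),
    name = "immigration_death"
  )
}

decay_model <- function(x0 = 10, d = 1) {
  ode_model("X", drift = function(x, t) -d * x, initial_state = x0,
            decomposition = list(production = function(x, t) 0,
                                 degradation = function(x, t) d * x,
                                 source = "user", consistent = TRUE),
            name = "decay")
}

# linearly separable labeled-example table: the label is exactly the
# indicator q99 < 200 (and q80 < 200), learnable by a single-feature split
toy_examples <- function(n_models = 6L, n_per = 10L, seed = 99L) {
  withr::with_seed(seed, {
    rows <- lapply(seq_len(n_models), function(m) {
      stoch <- runif(n_per) < 0.5
      q99 <- ifelse(stoch, runif(n_per, 5, 120), runif(n_per, 400, 5000))
      q80 <- q99 * runif(n_per, 0.5, 0.9)
      tibble::tibble(
        model_id = sprintf("toy_%02d", m),
        species = sprintf("s%d", seq_len(n_per)),
        label = as.integer(q80 < 200 & q99 < 200),
        mean = q80 * runif(n_per, 0.8, 1.2),
        q50 = q80 * runif(n_per, 0.7, 1.1),
        q80 = q80, q99 = q99
      )
    })
    dplyr::bind_rows(rows)
  })
}

empty_corpus <- function() {
  structure(list(models = list(),
                 metadata = tibble::tibble(model_id = character(),
                                           family = character(),
                                           seed_offset = integer(),
                                           n_species = integer()),
                 spec = corpus_spec(n_models = 1L)),
            class = "corpus")
}
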