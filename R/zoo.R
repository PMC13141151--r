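# Model zoo: canonical fixed models plus a seeded generator of random
# biochemical ODE models used as a training corpus for the regime
# classifier. Every generated model is parameter-driven: a family "builder"
# reconstructs the model (drift + exact production/degradation decomposition)
# deterministically from a plain-data parameter list, which is what gets
# serialized to disk.

runif_log <- function(n, lo, hi) exp(runif(n, log(lo), log(hi)))

#' Two-stage gene-expression benchmark model
#'
#' The canonical benchmark used throughout the package: constitutive mRNA
#' production and first-order decay driving protein synthesis and decay,
#' \deqn{dM/dt = k_1 - d_1 M, \qquad dP/dt = k_2 M - d_2 P,}
#' with `k1 = 5`, `d1 = 1`, `k2 = 50`, `d2 = 0.1`, both species starting at 0
#' in count units, and the exact decomposition attached. The deterministic
#' steady state is `M* = k1/d1 = 5`, `P* = k1 k2/(d1 d2) = 2500`; under exact
#' stochastic dynamics the stationary law of M is Poisson(5) (variance 5) and
#' the stationary protein variance is `P*(1 + k2/(d1+d2)) = 116136.4`.
#'
#' The rate constants are a package design choice that pins the model to
#' those round-number stationary statistics; see the methods vignette.
#'
#' @return An [ode_model()] in count units with exact decomposition.
#' @examples
#' m <- benchmark_model()
#' m$drift(c(5, 2500), 0) # c(0, 0)
#' @export
benchmark_model <- function() {
  build_family("benchmark",
               list(k1 = 5, d1 = 1, k2 = 50, d2 = 0.1, init = c(0, 0)),
               name = "benchmark")
}

#' Six-species symmetric repressilator
#'
#' Classic three-gene ring oscillator in reduced symmetric form:
#' \deqn{dm_i/dt = \alpha/(1 + p_{i-1}^n) - m_i, \qquad
#'       dp_i/dt = \beta m_i - \beta p_i,}
#' with cyclic repression (gene 1 repressed by protein 3), `alpha = 216`,
#' `n = 2`, `beta = 0.2` and initial state `(10, 0, 0, 1, 1, 1.2)` for
#' `(m1, m2, m3, p1, p2, p3)`. These parameters give sustained oscillations.
#'
#' @return An [ode_model()] in count units with exact decomposition.
#' @export
repressilator_model <- function() {
  build_family("repressilator_variant",
               list(alpha = 216, n_hill = 2, beta = 0.2,
                    init = c(10, 0, 0, 1, 1, 1.2)),
               name = "repressilator")
}

# ---------------------------------------------------------------------------
# family builders (deterministic in their params)

build_family <- function(family, params, name = family) {
  builder <- zoo_builders[[family]]
  if (is.null(builder)) {
    stop("unknown model family '", family, "'; known families: ",
         paste(names(zoo_builders), collapse = ", "), call. = FALSE)
  }
  builder(params, name)
}

#' List the model families known to the zoo
#' @return Character vector of family names.
#' @export
zoo_families <- function() names(zoo_builders)

build_benchmark <- function(p, name) {
  k1 <- p$k1; d1 <- p$d1; k2 <- p$k2; d2 <- p$d2
  ode_model(
    species = c("M", "P"),
    drift = function(x, t) c(k1 - d1 * x[1], k2 * x[1] - d2 * x[2]),
    initial_state = p$init,
    parameters = list(k1 = k1, d1 = d1, k2 = k2, d2 = d2),
    decomposition = list(
      production = function(x, t) c(k1, k2 * x[1]),
      degradation = function(x, t) c(d1 * x[1], d2 * x[2]),
      source = "user", consistent = TRUE),
    name = name, family = "benchmark", family_params = p
  )
}

build_birth_death_chain <- function(p, name) {
  n <- length(p$target)
  d <- p$d
  k0 <- d[1] * p$target[1]
  cc <- if (n > 1) d[-1] * p$target[-1] / p$target[-n] else numeric()
  ode_model(
    species = paste0("X", seq_len(n)),
    drift = function(x, t) c(k0, cc * x[-n]) - d * x,
    initial_state = p$init,
    parameters = list(k0 = k0, c = cc, d = d),
    decomposition = list(
      production = function(x, t) c(k0, cc * x[-n]),
      degradation = function(x, t) d * x,
      source = "user", consistent = TRUE),
    name = name, family = "birth_death_chain", family_params = p
  )
}

build_expression_cascade <- function(p, name) {
  k <- length(p$m_target) # tiers; species interleaved m1,p1,m2,p2,...
  dm <- p$dm; dp <- p$dp
  a <- dp * p$p_target / p$m_target
  k0 <- dm[1] * p$m_target[1]
  K <- if (k > 1) p$p_target[-k] else numeric() # activation scale, tier j>=2
  b <- if (k > 1) 2 * dm[-1] * p$m_target[-1] else numeric()
  im <- 2 * seq_len(k) - 1
  ip <- 2 * seq_len(k)
  production <- function(x, t) {
    out <- numeric(2 * k)
    out[im[1]] <- k0
    if (k > 1) {
      pp <- x[ip[-k]]
      out[im[-1]] <- b * pp^2 / (K^2 + pp^2)
    }
    out[ip] <- a * x[im]
    out
  }
  degradation <- function(x, t) {
    out <- numeric(2 * k)
    out[im] <- dm * x[im]
    out[ip] <- dp * x[ip]
    out
  }
  ode_model(
    species = as.vector(rbind(paste0("m", seq_len(k)),
                              paste0("p", seq_len(k)))),
    drift = function(x, t) production(x, t) - degradation(x, t),
    initial_state = p$init,
    parameters = list(k0 = k0, a = a, b = b, K = K, dm = dm, dp = dp),
    decomposition = list(production = production, degradation = degradation,
                         source = "user", consistent = TRUE),
    name = name, family = "expression_cascade", family_params = p
  )
}

build_repressilator_variant <- function(p, name) {
  alpha <- p$alpha; nh <- p$n_hill; beta <- p$beta
  prev <- c(6L, 4L, 5L) # p3 represses m1, p1 -> m2, p2 -> m3
  production <- function(x, t) {
    c(alpha / (1 + x[prev]^nh), beta * x[1:3])
  }
  degradation <- function(x, t) c(x[1:3], beta * x[4:6])
  ode_model(
    species = c("m1", "m2", "m3", "p1", "p2", "p3"),
    drift = function(x, t) production(x, t) - degradation(x, t),
    initial_state = p$init,
    parameters = list(alpha = alpha, n = nh, beta = beta),
    decomposition = list(production = production, degradation = degradation,
                         source = "user", consistent = TRUE),
    name = name, family = "repressilator_variant", family_params = p
  )
}

build_michaelis_menten_module <- function(p, name) {
  n <- length(p$target)
  kin <- p$kin; Km <- p$Km
  Vmax <- kin * (Km + p$target[1]) / p$target[1]
  d <- p$d
  d[2] <- kin / p$target[2]
  cc <- if (n > 2) d[3:n] * p$target[3:n] / p$target[2:(n - 1)] else numeric()
  production <- function(x, t) {
    flux <- Vmax * x[1] / (Km + x[1])
    c(kin, flux, if (n > 2) cc * x[2:(n - 1)])
  }
  degradation <- function(x, t) {
    flux <- Vmax * x[1] / (Km + x[1])
    c(flux, d[-1] * x[-1])
  }
  ode_model(
    species = paste0("X", seq_len(n)),
    drift = function(x, t) production(x, t) - degradation(x, t),
    initial_state = p$init,
    parameters = list(kin = kin, Km = Km, Vmax = Vmax, d = d, c = cc),
    decomposition = list(production = production, degradation = degradation,
                         source = "user", consistent = TRUE),
    name = name, family = "michaelis_menten_module", family_params = p
  )
}

build_autoregulation <- function(p, name) {
  dm <- p$dm; dp <- p$dp; nh <- p$n_hill
  K <- p$p_target
  alpha <- 2 * dm * p$m_target
  km <- dp * p$p_target / p$m_target
  production <- function(x, t) c(alpha / (1 + (x[2] / K)^nh), km * x[1])
  degradation <- function(x, t) c(dm * x[1], dp * x[2])
  ode_model(
    species = c("m", "p"),
    drift = function(x, t) production(x, t) - degradation(x, t),
    initial_state = p$init,
    parameters = list(alpha = alpha, K = K, n = nh, dm = dm, dp = dp,
                      km = km),
    decomposition = list(production = production, degradation = degradation,
                         source = "user", consistent = TRUE),
    name = name, family = "autoregulation", family_params = p
  )
}

zoo_builders <- list(
  benchmark = build_benchmark,
  birth_death_chain = build_birth_death_chain,
  expression_cascade = build_expression_cascade,
  repressilator_variant = build_repressilator_variant,
  michaelis_menten_module = build_michaelis_menten_module,
  autoregulation = build_autoregulation
)

# ---------------------------------------------------------------------------
# family samplers: draw a parameter list from the corpus spec. All draws use
# the current RNG stream (generate_corpus seeds it once), so a corpus is a
# pure function of its spec.

sample_scale <- function(n, spec) {
  lo <- spec$low_copy_scale_range
  hi <- spec$high_copy_scale_range
  low <- runif(n) < 0.5
  out <- numeric(n)
  out[low] <- runif_log(sum(low), lo[1], lo[2])
  out[!low] <- runif_log(sum(!low), hi[1], hi[2])
  out
}

sample_birth_death_chain <- function(spec) {
  n <- sample(5:6, 1L)
  target <- sample_scale(n, spec)
  list(target = target,
       d = runif_log(n, 0.1, 2),
       init = target * runif(n, 0.6, 1.15))
}

sample_expression_cascade <- function(spec) {
  k <- sample(5:6, 1L) # tiers -> 2k species
  lo <- spec$low_copy_scale_range
  hi <- spec$high_copy_scale_range
  m_target <- runif_log(k, lo[1], lo[2])
  p_target <- runif_log(k, hi[1], hi[2])
  dm <- runif_log(k, 0.2, 2)
  dp <- runif_log(k, 0.05, 0.5)
  m_init <- m_target * runif(k, 0.6, 1.15)
  # transient-burst mRNA: high initial spike decaying to a low-copy baseline;
  # its mean/median stay low while the upper quantiles catch the spike, the
  # case where plain abundance heuristics mislabel
  burst_tier <- 0L
  if (runif(1) < 0.6) {
    burst_tier <- sample.int(k, 1L)
    m_target[burst_tier] <- runif_log(1L, 1, 80)
    dm[burst_tier] <- runif(1, 0.15, 0.3)
    m_init[burst_tier] <- runif(1, 2000, 6000)
  }
  init <- as.vector(rbind(m_init, p_target * runif(k, 0.6, 1.15)))
  list(m_target = m_target, p_target = p_target, dm = dm, dp = dp,
       burst_tier = burst_tier, init = init)
}

sample_repressilator_variant <- function(spec) {
  alpha <- runif_log(1, 10, spec$low_copy_scale_range[2])
  list(alpha = alpha,
       n_hill = sample(2:4, 1L),
       beta = runif_log(1, 0.1, 1),
       init = alpha * c(0.1, 0.02, 0.01, 0.05, 0.05, 0.06))
}

sample_michaelis_menten_module <- function(spec) {
  n <- sample(4:5, 1L)
  target <- sample_scale(n, spec)
  d <- runif_log(n, 0.1, 1)
  kin <- d[2] * target[2]
  list(target = target, kin = kin,
       Km = target[1] * runif_log(1, 0.3, 3), d = d,
       init = target * runif(n, 0.6, 1.15))
}

sample_autoregulation <- function(spec) {
  m_target <- sample_scale(1, spec)
  p_target <- sample_scale(1, spec)
  list(m_target = m_target, p_target = p_target,
       dm = runif_log(1, 0.1, 1), dp = runif_log(1, 0.1, 1),
       n_hill = sample(c(1, 2, 4), 1L),
       init = c(m_target * runif(1, 0.6, 0.9),
                p_target * runif(1, 1.0, 1.3)))
}

zoo_samplers <- list(
  birth_death_chain = sample_birth_death_chain,
  expression_cascade = sample_expression_cascade,
  repressilator_variant = sample_repressilator_variant,
  michaelis_menten_module = sample_michaelis_menten_module,
  autoregulation = sample_autoregulation
)

# ---------------------------------------------------------------------------

#' Specify a synthetic training corpus
#'
#' Defines the conditions under which [generate_corpus()] draws random
#' biochemical ODE models. The defaults emulate a curated multi-model
#' training set with a bimodal abundance structure: low-copy species (mRNA
#' scale, 1-120 molecules) and abundant species (protein/metabolite scale,
#' 400-1e6 molecules), with equal weight on five model families.
#'
#' @param n_models Number of models.
#' @param seed Integer seed; the corpus is a deterministic function of the
#'   spec including this seed.
#' @param family_mix Named non-negative weights over
#'   `zoo_families()` (excluding the fixed `benchmark` family).
#' @param low_copy_scale_range,high_copy_scale_range Ranges (molecules) from
#'   which per-species stationary target scales are drawn log-uniformly.
#' @param presim_horizon Default pre-simulation horizon (time units) used
#'   downstream when building training tables from this corpus.
#' @return A `corpus_spec` object.
#' @export
corpus_spec <- function(n_models = 40L, seed = 1L,
                        family_mix = c(birth_death_chain = 1,
                                       expression_cascade = 1,
                                       repressilator_variant = 1,
                                       michaelis_menten_module = 1,
                                       autoregulation = 1),
                        low_copy_scale_range = c(1, 120),
                        high_copy_scale_range = c(400, 1e6),
                        presim_horizon = 500) {
  stopifnot(n_models >= 1L, length(low_copy_scale_range) == 2L,
            length(high_copy_scale_range) == 2L)
  if (any(family_mix < 0) || sum(family_mix) <= 0) {
    stop("family_mix weights must be non-negative with positive sum",
         call. = FALSE)
  }
  unknown <- setdiff(names(family_mix), names(zoo_samplers))
  if (length(unknown) > 0L) {
    stop("unknown families in family_mix: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (any(low_copy_scale_range <= 0) || diff(low_copy_scale_range) <= 0 ||
      any(high_copy_scale_range <= 0) || diff(high_copy_scale_range) <= 0) {
    stop("scale ranges must be ordered with positive endpoints",
         call. = FALSE)
  }
  structure(list(n_models = as.integer(n_models), seed = as.integer(seed),
                 family_mix = family_mix,
                 low_copy_scale_range = low_copy_scale_range,
                 high_copy_scale_range = high_copy_scale_range,
                 presim_horizon = presim_horizon),
            class = "corpus_spec")
}

#' Generate a synthetic model corpus
#'
#' Draws `n_models` random ODE models from the family mix of the spec.
#' Families: linear birth-death chains, gene-expression cascades with Hill
#' activation between tiers (optionally containing one transient-burst mRNA),
#' repressilator variants with randomized repression strength, Michaelis-
#' Menten conversion modules, and negatively autoregulated two-species
#' motifs. Rate constants are sampled log-uniformly and then solved so that
#' each species' deterministic stationary value equals its sampled target
#' scale; every model carries an exact production/degradation decomposition
#' and passes [validate_model()]. The same spec always yields the identical
#' corpus.
#'
#' @param spec A [corpus_spec()].
#' @return A `corpus` object: list with `models` (named list of
#'   [ode_model()]s), `metadata` (tibble with `model_id`, `family`,
#'   `seed_offset`, `n_species`) and `spec`.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  fams <- names(spec$family_mix)[spec$family_mix > 0]
  wts <- spec$family_mix[spec$family_mix > 0]
  models <- vector("list", spec$n_models)
  meta <- vector("list", spec$n_models)
  withr::with_seed(spec$seed, {
    for (i in seq_len(spec$n_models)) {
      fam <- if (length(fams) == 1L) fams else
        sample(fams, 1L, prob = wts)
      params <- zoo_samplers[[fam]](spec)
      id <- sprintf("model_%02d", i)
      m <- build_family(fam, params, name = id)
      diags <- validate_model(m)
      if (length(diags) > 0L) {
        stop("generated model ", id, " failed validation: ",
             paste(diags, collapse = "; "), call. = FALSE)
      }
      models[[i]] <- m
      meta[[i]] <- tibble::tibble(model_id = id, family = fam,
                                  seed_offset = i,
                                  n_species = n_species(m))
    }
  })
  names(models) <- vapply(models, `[[`, character(1), "name")
  structure(list(models = models, metadata = dplyr::bind_rows(meta),
                 spec = spec),
            class = "corpus")
}

#' @export
print.corpus <- function(x, ...) {
  cat("<corpus> ", length(x$models), " models, ",
      sum(x$metadata$n_species), " species (seed ", x$spec$seed, ")\n",
      sep = "")
  print(dplyr::count(x$metadata, .data$family))
  invisible(x)
}

# ---------------------------------------------------------------------------
# declarative model files and corpus serialization

#' Write / read a declarative model file
#'
#' Models whose drift comes from a registered zoo family (every generated or
#' canonical model) are serialized as JSON (or YAML) carrying the family name
#' and its parameter list, plus species, compartments, initial state and
#' name. Reading rebuilds the drift and exact decomposition through the
#' family builder; user-defined families can be supplied through the
#' `plugins` argument as named builder functions `function(params, name)`.
#' Unknown top-level keys are rejected.
#'
#' @param model An [ode_model()] carrying family metadata.
#' @param path File path; extension `.json` or `.yaml`/`.yml`.
#' @return `write_model_file()` returns `path` invisibly; `read_model_file()`
#'   returns the rebuilt [ode_model()].
#' @export
write_model_file <- function(model, path) {
  stopifnot(inherits(model, "ode_model"))
  if (is.null(model$family)) {
    stop("model has no registered family; only zoo-backed models (or user ",
         "plugin families) can be serialized", call. = FALSE)
  }
  doc <- list(
    name = model$name, family = model$family,
    family_params = model$family_params,
    species = as.list(model$species),
    compartments = lapply(unname(model$compartments),
                          function(cp) list(id = cp$id,
                                            volume_litres = cp$volume)),
    initial_state = model$initial_state
  )
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required for YAML model files",
           call. = FALSE)
    }
    writeLines(yaml::as.yaml(doc), path)
  } else {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_model_file
#' @param plugins Named list of user builder functions for families not in
#'   the zoo.
#' @export
read_model_file <- function(path, plugins = list()) {
  doc <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required for YAML model files",
           call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  allowed <- c("name", "family", "family_params", "species", "compartments",
               "initial_state")
  unknown <- setdiff(names(doc), allowed)
  if (length(unknown) > 0L) {
    stop("unknown keys in model file: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  builders <- c(plugins, zoo_builders)
  builder <- builders[[doc$family]]
  if (is.null(builder)) {
    stop("no builder registered for family '", doc$family,
         "'; pass one via plugins=", call. = FALSE)
  }
  params <- doc$family_params
  m <- builder(params, doc$name %||% doc$family)
  if (!is.null(doc$initial_state)) {
    m$initial_state <- as.numeric(doc$initial_state)
  }
  if (!is.null(doc$compartments) && length(doc$compartments) > 0L) {
    cps <- lapply(doc$compartments,
                  function(cp) compartment(cp$id, cp$volume_litres))
    names(cps) <- vapply(cps, `[[`, character(1), "id")
    m$compartments <- cps
  }
  m
}

#' Write / read a corpus directory
#'
#' One declarative model file per model plus a JSON manifest with the spec
#' and per-model metadata.
#'
#' @param corpus A `corpus`.
#' @param dir Directory (created if missing).
#' @return `write_corpus()` returns `dir` invisibly; `read_corpus()` returns
#'   the corpus.
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "corpus"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(corpus$models))
  for (i in seq_along(corpus$models)) {
    files[i] <- paste0(corpus$models[[i]]$name, ".json")
    write_model_file(corpus$models[[i]], file.path(dir, files[i]))
  }
  spec <- corpus$spec
  manifest <- list(
    spec = list(n_models = spec$n_models, seed = spec$seed,
                family_mix = as.list(spec$family_mix),
                low_copy_scale_range = spec$low_copy_scale_range,
                high_copy_scale_range = spec$high_copy_scale_range,
                presim_horizon = spec$presim_horizon),
    models = cbind(corpus$metadata, file = files)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  sp <- manifest$spec
  spec <- corpus_spec(
    n_models = sp$n_models, seed = sp$seed,
    family_mix = unlist(sp$family_mix),
    low_copy_scale_range = sp$low_copy_scale_range,
    high_copy_scale_range = sp$high_copy_scale_range,
    presim_horizon = sp$presim_horizon
  )
  models <- lapply(manifest$models$file,
                   function(f) read_model_file(file.path(dir, f)))
  names(models) <- manifest$models$model_id
  structure(list(models = models,
                 metadata = tibble::as_tibble(
                   manifest$models[, c("model_id", "family", "seed_offset",
                                       "n_species")]),
                 spec = spec),
            class = "corpus")
}
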