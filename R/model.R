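#' Define a compartment
#'
#' A compartment is a well-mixed reaction volume. Volumes are used by
#' [convert_to_counts()] to turn concentrations into molecule numbers via
#' `n = N_A * V * c`.
#'
#' @param id Short character identifier.
#' @param volume Compartment volume in litres; must be positive and finite.
#' @return A `hs_compartment` object.
#' @examples
#' compartment("cell", 1e-15)
#' @export
compartment <- function(id, volume) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!is.numeric(volume) || length(volume) != 1L || !is.finite(volume) ||
      volume <= 0) {
    stop("compartment '", id, "': volume must be a positive finite number ",
         "(litres)", call. = FALSE)
  }
  structure(list(id = id, volume = as.numeric(volume)),
            class = "hs_compartment")
}

#' Define an external input signal
#'
#' Input signals model non-autonomous forcing (for example pulsed stimuli).
#' The simulation engines evaluate the signal at the local simulation time
#' and never step across a declared discontinuity.
#'
#' @param name Character name.
#' @param value Function of time `t` returning the signal value.
#' @param event_times Strictly increasing numeric vector of times at which the
#'   signal is discontinuous.
#' @return A `hs_input_signal` object.
#' @export
input_signal <- function(name, value, event_times = numeric()) {
  stopifnot(is.character(name), length(name) == 1L, is.function(value))
  event_times <- as.numeric(event_times)
  if (length(event_times) > 1L && any(diff(event_times) <= 0)) {
    stop("input signal '", name, "': event_times must be strictly increasing",
         call. = FALSE)
  }
  structure(list(name = name, value = value, event_times = event_times),
            class = "hs_input_signal")
}

#' Construct an ODE model
#'
#' The central container of the package: an ODE-defined biochemical model
#' given by a drift evaluator `f(x, t)` together with species metadata,
#' parameters, optional compartments (needed for unit conversion), an optional
#' explicit production/degradation decomposition of the drift, and optional
#' time-dependent input signals.
#'
#' @param species Either a character vector of species names (all species are
#'   then unitless molecule counts with no compartment) or a data frame with
#'   columns `name`, `compartment` (id or `NA`) and `unit` (`"count"` or
#'   `"concentration"`).
#' @param drift Function `(x, t)` returning the derivative vector, same length
#'   and order as `species`.
#' @param initial_state Numeric vector of initial values, one per species.
#' @param parameters Named list of model parameters (metadata; drift closures
#'   capture their own parameters).
#' @param compartments List of [compartment()] objects.
#' @param decomposition Optional list with elements `production` and
#'   `degradation`, each a function `(x, t)` returning a non-negative vector
#'   per species such that `production - degradation == drift`.
#' @param inputs Optional list of [input_signal()] objects.
#' @param name Model name.
#' @param family,family_params Internal metadata used by the model zoo so
#'   generated models can be serialized and rebuilt; leave `NULL` for models
#'   constructed by hand.
#' @return An `ode_model` object.
#' @seealso [validate_model()], [convert_to_counts()],
#'   [default_decomposition()]
#' @examples
#' decay <- ode_model("x", function(x, t) -x, initial_state = 10)
#' validate_model(decay)
#' @export
ode_model <- function(species, drift, initial_state, parameters = list(),
                      compartments = list(), decomposition = NULL,
                      inputs = list(), name = "model",
                      family = NULL, family_params = NULL) {
  species <- normalize_species(species)
  stopifnot(is.function(drift))
  initial_state <- as.numeric(initial_state)
  if (length(initial_state) != nrow(species)) {
    stop("initial_state must have one entry per species", call. = FALSE)
  }
  if (length(compartments) > 0L) {
    if (!all(vapply(compartments, inherits, logical(1), "hs_compartment"))) {
      stop("compartments must be a list of compartment() objects",
           call. = FALSE)
    }
    names(compartments) <- vapply(compartments, `[[`, character(1), "id")
  }
  if (!is.null(decomposition)) {
    decomposition <- normalize_decomposition(decomposition)
  }
  if (length(inputs) > 0L &&
      !all(vapply(inputs, inherits, logical(1), "hs_input_signal"))) {
    stop("inputs must be a list of input_signal() objects", call. = FALSE)
  }
  structure(
    list(species = species, drift = drift, initial_state = initial_state,
         parameters = parameters, compartments = compartments,
         decomposition = decomposition, inputs = inputs, name = name,
         family = family, family_params = family_params),
    class = "ode_model"
  )
}

normalize_species <- function(species) {
  if (is.character(species)) {
    species <- tibble::tibble(name = species, compartment = NA_character_,
                              unit = "count")
  } else {
    species <- tibble::as_tibble(species)
    if (!all(c("name", "unit") %in% names(species))) {
      stop("species data frame needs columns 'name' and 'unit'",
           call. = FALSE)
    }
    if (!"compartment" %in% names(species)) {
      species$compartment <- NA_character_
    }
    species <- species[, c("name", "compartment", "unit")]
  }
  bad <- setdiff(unique(species$unit), c("count", "concentration"))
  if (length(bad) > 0L) {
    stop("unknown unit kind(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  species
}

normalize_decomposition <- function(dec) {
  stopifnot(is.list(dec), is.function(dec$production),
            is.function(dec$degradation))
  list(production = dec$production, degradation = dec$degradation,
       source = dec$source %||% "user",
       consistent = dec$consistent %||% TRUE)
}

n_species <- function(model) nrow(model$species)

species_names <- function(model) model$species$name

#' @export
print.ode_model <- function(x, ...) {
  cat("<ode_model> ", x$name, ": ", n_species(x), " species (",
      paste(utils::head(species_names(x), 8L), collapse = ", "),
      if (n_species(x) > 8L) ", ..." else "", ")\n", sep = "")
  cat("  units: ", paste(unique(x$species$unit), collapse = "/"),
      "; decomposition: ",
      if (is.null(x$decomposition)) "none" else x$decomposition$source,
      "; inputs: ", length(x$inputs), "\n", sep = "")
  invisible(x)
}

# Probe states used by validation and decomposition-consistency checks:
# the initial state plus `n` states drawn component-wise as the initial
# state scaled by Uniform(0.1, 10), under a fixed seed.
probe_states <- function(model, n = 32L, seed = 1234L) {
  x0 <- model$initial_state
  scales <- withr::with_seed(seed, {
    matrix(runif(n * length(x0), 0.1, 10), nrow = n)
  })
  rbind(x0, sweep(scales, 2L, x0, `*`), deparse.level = 0L)
}

#' Validate an ODE model
#'
#' Checks the structural invariants of an [ode_model()]: unique species
#' names, positive compartment volumes, strictly increasing input event
#' times, a drift evaluator that returns a finite vector of the right length,
#' and (when a decomposition is present) non-negative production/degradation
#' parts that sum back to the drift. The drift and decomposition are probed
#' at the initial state and 32 random non-negative states drawn under a fixed
#' seed, so the result is reproducible.
#'
#' @param model An [ode_model()].
#' @param n_probe Number of random probe states.
#' @param probe_seed Seed for the probe draw.
#' @return A character vector of human-readable diagnostics; empty when all
#'   invariants hold. The model is never modified.
#' @export
validate_model <- function(model, n_probe = 32L, probe_seed = 1234L) {
  stopifnot(inherits(model, "ode_model"))
  diags <- character()
  sp <- species_names(model)
  if (anyDuplicated(sp)) {
    diags <- c(diags, paste0("duplicated species names: ",
                             paste(unique(sp[duplicated(sp)]), collapse = ", ")))
  }
  for (cmp in model$compartments) {
    if (!is.finite(cmp$volume) || cmp$volume <= 0) {
      diags <- c(diags, paste0("compartment '", cmp$id,
                               "' has non-positive volume"))
    }
  }
  for (inp in model$inputs) {
    if (length(inp$event_times) > 1L && any(diff(inp$event_times) <= 0)) {
      diags <- c(diags, paste0("input '", inp$name,
                               "': event_times not strictly increasing"))
    }
  }
  probes <- probe_states(model, n = n_probe, seed = probe_seed)
  S <- n_species(model)
  tol <- function(f) 1e-9 * (1 + abs(f))
  for (k in seq_len(nrow(probes))) {
    x <- probes[k, ]
    f <- tryCatch(model$drift(x, 0), error = function(e) e)
    if (inherits(f, "error")) {
      diags <- c(diags, paste0("drift evaluator raised an error at probe ",
                               k, ": ", conditionMessage(f)))
      next
    }
    if (length(f) != S) {
      diags <- c(diags, paste0("drift length mismatch at probe ", k, ": got ",
                               length(f), ", expected ", S))
      next
    }
    if (!all(is.finite(f))) {
      diags <- c(diags, paste0("drift returned non-finite values at probe ",
                               k, " for species ",
                               paste(sp[!is.finite(f)], collapse = ", ")))
      next
    }
    if (!is.null(model$decomposition)) {
      fp <- tryCatch(model$decomposition$production(x, 0),
                     error = function(e) e)
      fm <- tryCatch(model$decomposition$degradation(x, 0),
                     error = function(e) e)
      if (inherits(fp, "error") || inherits(fm, "error")) {
        diags <- c(diags, paste0("decomposition raised an error at probe ", k))
        next
      }
      bad <- which(abs(fp - fm - f) > tol(f))
      if (length(bad) > 0L) {
        diags <- c(diags, paste0(
          "decomposition inconsistent (production - degradation != drift) ",
          "at probe ", k, " for species ", paste(sp[bad], collapse = ", ")))
      }
      neg <- which(fp < -1e-12 | fm < -1e-12)
      if (length(neg) > 0L) {
        diags <- c(diags, paste0(
          "decomposition has negative production or degradation at probe ",
          k, " for species ", paste(sp[neg], collapse = ", ")))
      }
    }
  }
  unique(diags)
}
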