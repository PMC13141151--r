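#' Derive a default production/degradation split of the drift
#'
#' The hybrid engine and the reaction-network baselines need, for each
#' species, a non-negative production flux and a non-negative degradation
#' flux whose difference is the ODE drift. When the model does not carry an
#' explicit user-supplied decomposition, a minimal one is derived by a
#' zero-clamp rule: production for species `i` is the drift evaluated with
#' `x_i` set to zero (clamped at zero from below) and degradation is the
#' remainder,
#' \deqn{f^+_i(x,t) = \max(f_i(x_{[x_i=0]}, t), 0), \quad
#'       f^-_i(x,t) = \max(f^+_i(x,t) - f_i(x,t), 0).}
#' Degradation terms of mass-action type vanish at zero copy number, so for
#' such drifts the split is exact. When production depends on the species
#' itself (autocatalysis) the identity `f+ - f- = f` fails; this is detected
#' on a fixed set of probe states, flagged in the returned object, and a
#' warning asks the user to provide an explicit decomposition.
#'
#' @param model An [ode_model()] without a user decomposition. If the model
#'   already has one it is returned untouched.
#' @param n_probe,probe_seed Probe states used for the consistency check (the
#'   initial state plus `n_probe` seeded random non-negative states).
#' @return A decomposition list with elements `production`, `degradation`
#'   (total evaluators `(x, t)`), `source` (`"auto"` or the original source)
#'   and `consistent` (logical consistency flag from the probe check).
#' @examples
#' m <- ode_model("M", function(x, t) 5 - x, initial_state = 3)
#' dec <- default_decomposition(m)
#' dec$production(3, 0) # 5
#' dec$degradation(3, 0) # 3
#' @export
default_decomposition <- function(model, n_probe = 32L, probe_seed = 1234L) {
  stopifnot(inherits(model, "ode_model"))
  if (!is.null(model$decomposition)) {
    return(model$decomposition)
  }
  f <- model$drift
  S <- n_species(model)
  sp <- species_names(model)

  production <- function(x, t) {
    out <- numeric(S)
    for (i in seq_len(S)) {
      xi <- x
      xi[i] <- 0
      out[i] <- f(xi, t)[i]
    }
    pmax(out, 0)
  }
  degradation <- function(x, t) pmax(production(x, t) - f(x, t), 0)

  # probe: drift must be defined with each species clamped to zero, and the
  # split must reproduce the drift (fails for autocatalytic production)
  probes <- probe_states(model, n = n_probe, seed = probe_seed)
  consistent <- TRUE
  for (k in seq_len(nrow(probes))) {
    x <- probes[k, ]
    for (i in seq_len(S)) {
      xi <- x
      xi[i] <- 0
      fi <- tryCatch(f(xi, 0)[i], error = function(e) e)
      if (inherits(fi, "error") || !is.finite(fi)) {
        stop("drift for species '", sp[i], "' is undefined when its value ",
             "is clamped to zero; supply an explicit production/degradation ",
             "decomposition for this model", call. = FALSE)
      }
    }
    fv <- f(x, 0)
    resid <- abs(production(x, 0) - degradation(x, 0) - fv)
    if (any(resid > 1e-9 * (1 + abs(fv)))) consistent <- FALSE
  }
  if (!consistent) {
    warning("zero-clamp decomposition does not reproduce the drift at all ",
            "probe states (production likely depends on the species itself); ",
            "degradation is clipped at zero -- supply an explicit ",
            "decomposition for quantitative stochastic updates",
            call. = FALSE)
  }
  list(production = production, degradation = degradation,
       source = "auto", consistent = consistent)
}

# The decomposition the engines should use: the user's if present, else the
# derived zero-clamp split.
model_decomposition <- function(model, ...) {
  model$decomposition %||% default_decomposition(model, ...)
}
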