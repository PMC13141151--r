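# Shared stiff-capable integration helper. deSolve's lsoda switches
# automatically between Adams and BDF, so stiff systems are handled without
# user intervention.
integrate_drift <- function(drift, init, times, rtol, atol, names = NULL) {
  deriv <- function(t, y, p) list(drift(y, t))
  out <- deSolve::ode(y = init, times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (nrow(out) < length(times)) {
    stop("ODE integration failed (step-size collapse) at t = ",
         format(out[nrow(out), 1]), call. = FALSE)
  }
  states <- unname(out[, -1, drop = FALSE])
  if (!all(is.finite(states))) {
    bad <- which(colSums(!is.finite(states)) > 0)
    stop("ODE integration produced non-finite values for species ",
         paste((names %||% as.character(bad))[bad], collapse = ", "),
         call. = FALSE)
  }
  states
}

#' Deterministic pre-simulation
#'
#' Integrates the model's drift from its initial state on a uniform time grid
#' with a stiff-capable adaptive solver (lsoda). The resulting trajectory is
#' the input to per-species feature extraction and regime labeling.
#'
#' @param model A validated [ode_model()].
#' @param horizon Final time (time units of the model); default 500.
#' @param n_grid Number of uniformly spaced grid points including `t = 0`
#'   (at least 16); default 2001.
#' @param rtol,atol Relative/absolute solver tolerances.
#' @return A trajectory object (`hs_trajectory`) with `n_grid` points.
#' @examples
#' traj <- run_presim(benchmark_model(), horizon = 100, n_grid = 101)
#' as_tibble(traj)
#' @export
run_presim <- function(model, horizon = 500, n_grid = 2001L,
                       rtol = 1e-6, atol = 1e-9) {
  stopifnot(inherits(model, "ode_model"), horizon > 0, n_grid >= 16L)
  diags <- validate_model(model)
  if (length(diags) > 0L) {
    stop("model failed validation:\n  ", paste(diags, collapse = "\n  "),
         call. = FALSE)
  }
  times <- seq(0, horizon, length.out = n_grid)
  states <- integrate_drift(model$drift, model$initial_state, times,
                            rtol, atol, names = species_names(model))
  new_trajectory(times, states, species_names(model),
                 unit_kind = model$species$unit)
}
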