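#' Avogadro constant (1/mol), CODATA exact value
#' @keywords internal
AVOGADRO <- 6.02214076e23

MOLAR_UNITS <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9)

#' Convert a concentration-based model to molecule counts
#'
#' For every species declared in concentration units, computes the scale
#' factor `Omega = N_A * V * u` (molecules per concentration unit), where `V`
#' is the volume of the species' compartment in litres and `u` converts the
#' chosen molar unit to mol/L. The returned model evolves counts
#' `n = Omega * x` with drift `dn/dt = Omega * f(n / Omega, t)`; time units
#' are unchanged. Species already declared in counts keep `Omega = 1`. A
#' user-supplied decomposition is transformed identically.
#'
#' @param model An [ode_model()].
#' @param molar_unit One of `"M"`, `"mM"`, `"uM"`, `"nM"` (the unit the
#'   concentrations are expressed in; `"µM"` is accepted as an alias for
#'   `"uM"`). No free-text unit parsing is attempted.
#' @return A list with elements `model` (the converted [ode_model()], all
#'   species in count units) and `report`, a tibble with one row per species:
#'   `species`, `omega` (molecules per concentration unit), `original_unit`
#'   and `initial_count`.
#' @examples
#' m <- ode_model(
#'   data.frame(name = "x", compartment = "cell", unit = "concentration"),
#'   drift = function(x, t) -x, initial_state = 1,
#'   compartments = list(compartment("cell", 1e-15))
#' )
#' convert_to_counts(m, "uM")$report
#' @export
convert_to_counts <- function(model, molar_unit = c("M", "mM", "uM", "nM")) {
  stopifnot(inherits(model, "ode_model"))
  if (identical(molar_unit, "µM")) molar_unit <- "uM"
  molar_unit <- match.arg(molar_unit)
  u <- MOLAR_UNITS[[molar_unit]]
  sp <- model$species
  omega <- rep(1, nrow(sp))
  for (i in seq_len(nrow(sp))) {
    if (sp$unit[i] == "concentration") {
      cid <- sp$compartment[i]
      if (is.na(cid) || !cid %in% names(model$compartments)) {
        stop("species '", sp$name[i], "' is in concentration units but has ",
             "no compartment with a known volume", call. = FALSE)
      }
      vol <- model$compartments[[cid]]$volume
      if (!is.finite(vol) || vol <= 0) {
        stop("species '", sp$name[i], "': compartment '", cid,
             "' has a non-positive volume", call. = FALSE)
      }
      omega[i] <- AVOGADRO * vol * u
    }
  }
  report <- tibble::tibble(
    species = sp$name, omega = omega, original_unit = sp$unit,
    initial_count = omega * model$initial_state
  )
  if (all(sp$unit == "count")) {
    return(list(model = model, report = report))
  }

  f <- model$drift
  new_drift <- function(x, t) omega * f(x / omega, t)
  new_dec <- NULL
  if (!is.null(model$decomposition)) {
    fp <- model$decomposition$production
    fm <- model$decomposition$degradation
    new_dec <- list(
      production = function(x, t) omega * fp(x / omega, t),
      degradation = function(x, t) omega * fm(x / omega, t),
      source = model$decomposition$source,
      consistent = model$decomposition$consistent
    )
  }
  new_inputs <- model$inputs
  sp$unit <- "count"
  converted <- ode_model(
    species = sp, drift = new_drift,
    initial_state = omega * model$initial_state,
    parameters = model$parameters, compartments = model$compartments,
    decomposition = new_dec, inputs = new_inputs,
    name = model$name
  )
  list(model = converted, report = report)
}
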