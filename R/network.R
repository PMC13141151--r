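# Reference engines on explicit reaction networks: exact Gillespie SSA,
# fixed-step tau-leaping with step-halving on negativity, the
# Haseltine-Rawlings hybrid with integrated-hazard jump timing, and plain
# stiff ODE integration.

#' Derive a birth-death reaction network from a model's decomposition
#'
#' Builds an explicit reaction network with two channels per species: a
#' production channel (`+1`, propensity `f+_i`) and a degradation channel
#' (`-1`, propensity `f-_i`), using the model's (consistent) production/
#' degradation decomposition. Channel order is species-major with birth
#' before death, matching the hybrid engine. Initial counts are the
#' round-half-up of the initial values.
#'
#' @param model An [ode_model()] in count units with a consistent
#'   decomposition (explicit, or a consistent [default_decomposition()]).
#' @return A `reaction_network`: species names, `S x 2S` stoichiometry
#'   matrix, a propensity evaluator `(x, t) -> vector over channels`,
#'   channel tags, species each channel touches, initial counts, and any
#'   declared input event times.
#' @examples
#' net <- network_from_decomposition(benchmark_model())
#' net$propensity(c(3, 100), 0) # 5, 3, 150, 10
#' @export
network_from_decomposition <- function(model) {
  stopifnot(inherits(model, "ode_model"))
  dec <- model$decomposition
  if (is.null(dec)) {
    dec <- default_decomposition(model)
  }
  if (!isTRUE(dec$consistent)) {
    stop("model decomposition is inconsistent with the drift; supply an ",
         "explicit production/degradation decomposition", call. = FALSE)
  }
  S <- n_species(model)
  stoich <- matrix(0L, nrow = S, ncol = 2L * S)
  for (i in seq_len(S)) {
    stoich[i, 2L * i - 1L] <- 1L
    stoich[i, 2L * i] <- -1L
  }
  fp <- dec$production
  fm <- dec$degradation
  propensity <- function(x, t) {
    as.vector(rbind(fp(x, t), fm(x, t)))
  }
  structure(
    list(species = species_names(model), stoich = stoich,
         propensity = propensity,
         tag = rep(c("production", "degradation"), S),
         channel_species = rep(species_names(model), each = 2L),
         init = round_half_up(model$initial_state),
         event_times = sort(unique(unlist(
           lapply(model$inputs, `[[`, "event_times"))))),
    class = "reaction_network"
  )
}

#' Construct a reaction network directly
#'
#' For models that are naturally reaction networks (used mainly in tests and
#' small studies). Channels are given as a stoichiometry matrix and a vector
#' propensity evaluator.
#'
#' @param species Character vector of species names.
#' @param stoich `S x C` integer stoichiometry matrix.
#' @param propensity Function `(x, t)` returning the `C` channel propensities
#'   (non-negative at non-negative states).
#' @param init Initial counts.
#' @param tag Optional per-channel tags.
#' @param event_times Optional input discontinuity times.
#' @return A `reaction_network`.
#' @export
reaction_network <- function(species, stoich, propensity, init,
                             tag = NULL, event_times = numeric()) {
  stoich <- as.matrix(stoich)
  stopifnot(nrow(stoich) == length(species), is.function(propensity),
            length(init) == length(species))
  structure(
    list(species = species, stoich = stoich, propensity = propensity,
         tag = tag %||% rep("", ncol(stoich)),
         channel_species = rep(NA_character_, ncol(stoich)),
         init = round_half_up(init),
         event_times = as.numeric(event_times)),
    class = "reaction_network"
  )
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("<reaction_network> ", length(x$species), " species, ",
      ncol(x$stoich), " channels\n", sep = "")
  invisible(x)
}

next_break <- function(t, event_times, T) {
  later <- event_times[event_times > t]
  if (length(later) > 0L) min(later[1], T) else T
}

#' Exact stochastic simulation (Gillespie direct method)
#'
#' Draws exponential waiting times with the total propensity and selects the
#' firing channel proportionally to its propensity; event timing is exact.
#' When the total propensity is zero the state is frozen until the next
#' declared input event or the final time (not an error). Counts are
#' recorded on the output grid as right-continuous step functions.
#'
#' @param network A `reaction_network`.
#' @param T Final time (> 0).
#' @param seed Integer seed.
#' @param grid Output grid (default `seq(0, T, by = 0.1)`).
#' @return A trajectory with attributes `seed` and `n_events`.
#' @export
ssa_direct <- function(network, T, seed = 1L, grid = NULL) {
  stopifnot(inherits(network, "reaction_network"), T > 0)
  grid <- grid %||% seq(0, T, by = 0.1)
  prop <- network$propensity
  stoich <- network$stoich
  evs <- network$event_times
  G <- length(grid)
  S <- length(network$species)
  out <- matrix(0, nrow = G, ncol = S)
  n_events <- 0L
  withr::with_seed(seed, {
    x <- as.numeric(network$init)
    t <- 0
    gi <- 1L
    while (t < T) {
      a <- pmax(prop(x, t), 0)
      a0 <- sum(a)
      if (!is.finite(a0)) stop("propensity overflow at t = ", format(t),
                               call. = FALSE)
      tnext <- if (a0 > 0) t + rexp(1L, a0) else Inf
      tstop <- min(tnext, next_break(t, evs, T))
      while (gi <= G && grid[gi] < tstop) {
        out[gi, ] <- x
        gi <- gi + 1L
      }
      if (tstop == tnext && tnext <= T) {
        j <- findInterval(runif(1L) * a0, cumsum(a)) + 1L
        x <- pmax(x + stoich[, j], 0)
        n_events <- n_events + 1L
      }
      t <- tstop
    }
    while (gi <= G) {
      out[gi, ] <- x
      gi <- gi + 1L
    }
  })
  tr <- new_trajectory(grid, out, network$species, unit_kind = "count")
  attr(tr, "seed") <- seed
  attr(tr, "n_events") <- n_events
  tr
}

#' Fixed-step tau-leaping
#'
#' Per step, every channel fires a Poisson number of times with its
#' propensity frozen at the step start. If the aggregate update would drive
#' any count negative the step is retried with the leap halved (up to 20
#' halvings), then falls back to a single exact SSA event for that step.
#'
#' @param network A `reaction_network`.
#' @param tau Leap length (> 0).
#' @param T Final time.
#' @param seed Integer seed.
#' @param grid Output grid.
#' @param max_halvings Halvings before the single-event fallback.
#' @return A trajectory with attributes `seed`, `n_steps`, `n_halvings`.
#' @export
tau_leap <- function(network, tau, T, seed = 1L, grid = NULL,
                     max_halvings = 20L) {
  stopifnot(inherits(network, "reaction_network"), tau > 0, T > 0)
  grid <- grid %||% seq(0, T, by = 0.1)
  prop <- network$propensity
  stoich <- network$stoich
  G <- length(grid)
  S <- length(network$species)
  C <- ncol(stoich)
  out <- matrix(0, nrow = G, ncol = S)
  n_steps <- 0L
  n_halvings <- 0L
  withr::with_seed(seed, {
    x <- as.numeric(network$init)
    t <- 0
    gi <- 1L
    while (t < T) {
      a <- pmax(prop(x, t), 0)
      step <- min(tau, T - t)
      accepted <- FALSE
      for (try in 0:max_halvings) {
        k <- rpois(C, a * step)
        xn <- x + as.vector(stoich %*% k)
        if (all(xn >= 0)) {
          accepted <- TRUE
          break
        }
        step <- step / 2
        n_halvings <- n_halvings + 1L
      }
      if (!accepted) {
        # single exact event within the (tiny) remaining step
        a0 <- sum(a)
        if (a0 > 0) {
          te <- rexp(1L, a0)
          if (te <= step) {
            j <- findInterval(runif(1L) * a0, cumsum(a)) + 1L
            xn <- pmax(x + stoich[, j], 0)
          } else xn <- x
        } else xn <- x
      }
      tstop <- t + step
      while (gi <= G && grid[gi] < tstop) {
        out[gi, ] <- x
        gi <- gi + 1L
      }
      x <- xn
      t <- tstop
      n_steps <- n_steps + 1L
    }
    while (gi <= G) {
      out[gi, ] <- x
      gi <- gi + 1L
    }
  })
  tr <- new_trajectory(grid, out, network$species, unit_kind = "count")
  attr(tr, "seed") <- seed
  attr(tr, "n_steps") <- n_steps
  attr(tr, "n_halvings") <- n_halvings
  tr
}

#' Partition reaction channels into slow and fast sets
#'
#' @param network A `reaction_network`.
#' @param slow Channel indices, or species names (all channels touching
#'   those species, for networks built by [network_from_decomposition()]).
#' @return A `channel_partition` with disjoint covering `slow` and `fast`
#'   index sets.
#' @export
channel_partition <- function(network, slow) {
  C <- ncol(network$stoich)
  if (is.character(slow)) {
    slow <- which(network$channel_species %in% slow)
  }
  slow <- sort(unique(as.integer(slow)))
  stopifnot(all(slow >= 1L), all(slow <= C))
  structure(list(slow = slow, fast = setdiff(seq_len(C), slow)),
            class = "channel_partition")
}

#' Haseltine-Rawlings hybrid simulation
#'
#' Fast channels are pooled into a deterministic drift
#' `sum_fast nu_j a_j(x, t)` advanced continuously by the stiff solver; slow
#' channels fire as exact jumps using the time-integrated hazard: the ODE is
#' augmented with `dg/dt = sum_slow a_j(x(t), t)`, a unit-mean exponential
#' threshold is drawn, and the solver's root-finder locates the instant
#' where `g` crosses it. The firing channel is selected proportionally to
#' the slow propensities at the located firing time, its stoichiometry is
#' applied, `g` is reset, and integration resumes.
#'
#' @param network A `reaction_network`.
#' @param partition A [channel_partition()] (or the `slow` argument to one).
#' @param T Final time.
#' @param seed Integer seed.
#' @param rtol,atol Solver tolerances.
#' @param grid Output grid.
#' @return A trajectory with attributes `seed` and `n_events`.
#' @export
hr_hybrid <- function(network, partition, T, seed = 1L,
                      rtol = 1e-6, atol = 1e-9, grid = NULL) {
  stopifnot(inherits(network, "reaction_network"), T > 0)
  if (!inherits(partition, "channel_partition")) {
    partition <- channel_partition(network, partition)
  }
  grid <- grid %||% seq(0, T, by = 0.1)
  prop <- network$propensity
  stoich <- network$stoich
  slow <- partition$slow
  fast <- partition$fast
  S <- length(network$species)
  G <- length(grid)
  out <- matrix(NA_real_, nrow = G, ncol = S)
  n_events <- 0L

  fast_sto <- stoich[, fast, drop = FALSE]
  deriv <- function(tt, y, p) {
    xx <- y[seq_len(S)]
    a <- pmax(prop(xx, tt), 0)
    dx <- if (length(fast) > 0L) as.vector(fast_sto %*% a[fast])
          else numeric(S)
    list(c(dx, sum(a[slow])))
  }

  withr::with_seed(seed, {
    x <- as.numeric(network$init)
    t <- 0
    g <- 0
    thr <- if (length(slow) > 0L) rexp(1L) else Inf
    gi <- 1L
    while (gi <= G && grid[gi] <= t) {
      out[gi, ] <- x
      gi <- gi + 1L
    }
    while (t < T) {
      # integrate in chunks of upcoming grid points; stop at a firing root
      rem <- if (gi <= G) grid[seq(gi, min(gi + 63L, G))] else numeric()
      chunk_times <- unique(c(t, rem[rem > t]))
      if (length(chunk_times) < 2L) chunk_times <- c(t, min(T, t + 1))
      rootf <- function(tt, y, p) y[S + 1L] - thr
      sol <- deSolve::lsodar(y = c(x, g), times = chunk_times, func = deriv,
                             parms = NULL, rootfunc = rootf,
                             rtol = rtol, atol = atol)
      troot <- attr(sol, "troot")
      fired <- length(troot) > 0L && is.finite(troot[1])
      last <- nrow(sol)
      # record chunk grid points reached before any root
      for (r in seq_len(last)) {
        tt <- sol[r, 1L]
        if (fired && tt >= troot[1]) break
        while (gi <= G && grid[gi] <= tt + 1e-12 && grid[gi] > t) {
          out[gi, ] <- sol[r, 1L + seq_len(S)]
          gi <- gi + 1L
        }
      }
      if (fired) {
        te <- troot[1]
        xe <- sol[last, 1L + seq_len(S)]
        as <- pmax(prop(xe, te)[slow], 0)
        a0 <- sum(as)
        if (a0 <= 0) {
          # hazard reached the threshold with zero instantaneous rate
          # (numerically degenerate); restart the clock
          t <- te
          x <- xe
          g <- 0
          thr <- rexp(1L)
          next
        }
        j <- slow[findInterval(runif(1L) * a0, cumsum(as)) + 1L]
        x <- pmax(xe + stoich[, j], 0)
        t <- te
        g <- 0
        thr <- rexp(1L)
        n_events <- n_events + 1L
        # a grid point exactly at the firing time takes the post-jump state
        while (gi <= G && grid[gi] <= t + 1e-12) {
          out[gi, ] <- x
          gi <- gi + 1L
        }
      } else {
        x <- sol[last, 1L + seq_len(S)]
        g <- sol[last, S + 2L]
        t <- sol[last, 1L]
        while (gi <= G && grid[gi] <= t + 1e-12) {
          out[gi, ] <- sol[last, 1L + seq_len(S)]
          gi <- gi + 1L
        }
      }
    }
    while (gi <= G) {
      out[gi, ] <- x
      gi <- gi + 1L
    }
  })
  tr <- new_trajectory(grid, out, network$species, unit_kind = "count")
  attr(tr, "seed") <- seed
  attr(tr, "n_events") <- n_events
  tr
}

#' Deterministic ODE solve
#'
#' Stiff-capable adaptive integration (lsoda) of a model's drift, or of the
#' deterministic mass-action drift `sum_j nu_j a_j(x, t)` of a reaction
#' network, with dense output on the grid.
#'
#' @param x An [ode_model()] or `reaction_network`.
#' @param T Final time.
#' @param rtol,atol Tolerances.
#' @param grid Output grid (default `seq(0, T, by = 0.1)`).
#' @return A trajectory.
#' @export
ode_solve <- function(x, T, rtol = 1e-6, atol = 1e-9, grid = NULL) {
  stopifnot(T > 0)
  grid <- grid %||% seq(0, T, by = 0.1)
  if (inherits(x, "ode_model")) {
    drift <- x$drift
    init <- x$initial_state
    sp <- species_names(x)
    uk <- x$species$unit
  } else if (inherits(x, "reaction_network")) {
    stoich <- x$stoich
    prop <- x$propensity
    drift <- function(xx, tt) as.vector(stoich %*% prop(xx, tt))
    init <- as.numeric(x$init)
    sp <- x$species
    uk <- "count"
  } else {
    stop("x must be an ode_model or a reaction_network", call. = FALSE)
  }
  states <- integrate_drift(drift, init, grid, rtol, atol, names = sp)
  new_trajectory(grid, states, sp, unit_kind = uk)
}
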