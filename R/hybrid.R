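# The hybrid engine: a piecewise-deterministic Markov process in which
# species labeled stochastic evolve by +/-1 birth-death events whose
# propensities come from the production/degradation split of the ODE drift,
# while the remaining species follow the ODE between events. Propensities
# are frozen between re-evaluations, which happen after every event and at
# least every synchronization interval dt.

#' Assemble a hybrid system from a model and a partition
#'
#' Splits the species into a stochastic index set (label 1) and a
#' deterministic set (label 0). Stochastic species get one birth and one
#' death channel with propensities taken from the model's decomposition (a
#' user-supplied decomposition is preferred; otherwise the zero-clamp
#' [default_decomposition()] is derived — if that derived split is flagged
#' inconsistent, an explicit decomposition is demanded). Stochastic initial
#' values are rounded half-up to integer counts; deterministic coordinates
#' stay real-valued.
#'
#' @param model An [ode_model()] in count units.
#' @param labels Per-species 0/1 labels: an integer vector in species order,
#'   a named vector, or the tibble returned by [predict_partition()].
#' @param dt Synchronization interval (time units, > 0): the longest span
#'   over which frozen propensities are trusted before re-evaluation.
#' @param rtol,atol Tolerances of the stiff deterministic sub-integrator.
#' @return A `hybrid_system` object.
#' @examples
#' sys <- build_hybrid_system(benchmark_model(), c(M = 1, P = 0))
#' @export
build_hybrid_system <- function(model, labels, dt = 0.1,
                                rtol = 1e-6, atol = 1e-9) {
  stopifnot(inherits(model, "ode_model"), dt > 0)
  if (any(model$species$unit != "count")) {
    stop("hybrid simulation requires count units; use convert_to_counts()",
         call. = FALSE)
  }
  sp <- species_names(model)
  labels <- normalize_labels(labels, sp)
  dec <- model$decomposition
  if (is.null(dec)) {
    dec <- default_decomposition(model)
    if (!dec$consistent) {
      stop("the automatically derived production/degradation split does not ",
           "reproduce the drift; supply an explicit decomposition in ",
           "ode_model()", call. = FALSE)
    }
  }
  s_idx <- which(labels == 1L)
  d_idx <- which(labels == 0L)
  init <- model$initial_state
  init[s_idx] <- round_half_up(init[s_idx])
  structure(
    list(model = model, labels = labels, s_idx = s_idx, d_idx = d_idx,
         decomposition = dec, dt = dt, rtol = rtol, atol = atol,
         init = init,
         event_times = sort(unique(unlist(
           lapply(model$inputs, `[[`, "event_times"))))),
    class = "hybrid_system"
  )
}

normalize_labels <- function(labels, sp) {
  if (is.data.frame(labels)) {
    stopifnot(all(c("species", "label") %in% names(labels)))
    labels <- setNames(labels$label, labels$species)
  }
  if (!is.null(names(labels))) {
    missing_sp <- setdiff(sp, names(labels))
    if (length(missing_sp) > 0L) {
      stop("labels missing for species: ",
           paste(missing_sp, collapse = ", "), call. = FALSE)
    }
    labels <- labels[sp]
  }
  labels <- as.integer(labels)
  if (length(labels) != length(sp) || !all(labels %in% c(0L, 1L))) {
    stop("labels must be one 0/1 value per species", call. = FALSE)
  }
  labels
}

#' @export
print.hybrid_system <- function(x, ...) {
  sp <- species_names(x$model)
  cat("<hybrid_system> ", x$model$name, ": ", length(x$s_idx),
      " stochastic (", paste(sp[x$s_idx], collapse = ", "), "), ",
      length(x$d_idx), " deterministic; dt = ", x$dt, "\n", sep = "")
  invisible(x)
}

#' Run one hybrid simulation
#'
#' Event-driven loop: at each iteration the birth/death propensities of all
#' stochastic species are evaluated at the current hybrid state and local
#' time (negative values are clipped to zero and counted); an exponential
#' waiting time with the total rate is drawn; the system is advanced by
#' `h = min(waiting time, dt, gap to the next declared input event, time
#' remaining)`, with the deterministic coordinates integrated by the stiff
#' solver while the stochastic counts stay frozen; if the waiting time was
#' the binding constraint, one channel is selected by cumulative-sum
#' inversion (channels in species order, birth before death) and its species
#' is updated by +/-1, clamped at zero. Counts are recorded on the output
#' grid as right-continuous step functions and deterministic coordinates by
#' interpolation of the segment endpoints. Fully reproducible given `seed`.
#'
#' @param system A `hybrid_system`.
#' @param T Final time (> 0).
#' @param seed Integer seed.
#' @param grid Output time grid (default `seq(0, T, by = 0.1)`).
#' @return A trajectory (`hs_trajectory`) on `grid` with attributes `seed`,
#'   `n_clipped` (negative-propensity clips) and `n_events`.
#' @export
simulate_hybrid <- function(system, T, seed = 1L, grid = NULL) {
  stopifnot(inherits(system, "hybrid_system"), T > 0)
  grid <- grid %||% seq(0, T, by = 0.1)
  model <- system$model
  sp <- species_names(model)

  if (length(system$s_idx) == 0L) {
    # deterministic limit: plain stiff ODE solve of the full model
    states <- integrate_drift(model$drift, system$init, grid,
                              system$rtol, system$atol, names = sp)
    out <- new_trajectory(grid, states, sp, unit_kind = model$species$unit)
    attr(out, "seed") <- seed
    attr(out, "n_clipped") <- 0L
    attr(out, "n_events") <- 0L
    return(out)
  }
  res <- withr::with_seed(seed, hybrid_loop(system, T))
  states <- segments_to_grid(res$seg_t, res$seg_x, grid,
                             count_idx = system$s_idx,
                             cont_idx = system$d_idx)
  out <- new_trajectory(grid, states, sp, unit_kind = model$species$unit)
  attr(out, "seed") <- seed
  attr(out, "n_clipped") <- res$n_clipped
  attr(out, "n_events") <- res$n_events
  out
}

hybrid_loop <- function(system, T) {
  model <- system$model
  fp <- system$decomposition$production
  fm <- system$decomposition$degradation
  s_idx <- system$s_idx
  d_idx <- system$d_idx
  dt <- system$dt
  evs <- system$event_times
  has_det <- length(d_idx) > 0L
  drift <- model$drift

  # reduced drift: deterministic coordinates move, stochastic frozen
  xfull <- system$init
  deriv <- function(tt, y, p) {
    xx <- xfull
    xx[d_idx] <- y
    list(drift(xx, tt)[d_idx])
  }

  cap <- 65536L
  seg_t <- numeric(cap)
  seg_x <- matrix(0, nrow = cap, ncol = length(xfull))
  nseg <- 1L
  seg_t[1L] <- 0
  seg_x[1L, ] <- xfull

  t <- 0
  n_clipped <- 0L
  n_eval <- 0L
  n_events <- 0L

  while (t < T) {
    ap <- fp(xfull, t)[s_idx]
    am <- fm(xfull, t)[s_idx]
    a <- as.vector(rbind(ap, am)) # species order, birth before death
    n_eval <- n_eval + length(a)
    neg <- a < 0
    if (any(neg)) {
      n_clipped <- n_clipped + sum(neg)
      a[neg] <- 0
    }
    a0 <- sum(a)
    if (!is.finite(a0)) {
      stop("propensity overflow at t = ", format(t), call. = FALSE)
    }
    tau <- if (a0 > 0) rexp(1L, a0) else Inf
    gap_ev <- if (length(evs) > 0L && any(evs > t)) min(evs[evs > t]) - t
              else Inf
    h <- min(tau, dt, gap_ev, T - t)
    fire <- is.finite(tau) && tau <= min(dt, gap_ev, T - t)

    if (has_det && h > 0) {
      out <- deSolve::ode(y = xfull[d_idx], times = c(t, t + h),
                          func = deriv, parms = NULL, method = "lsoda",
                          rtol = system$rtol, atol = system$atol)
      if (nrow(out) < 2L || !all(is.finite(out[2L, -1L]))) {
        stop("deterministic sub-integration failed at t = ", format(t),
             call. = FALSE)
      }
      xfull[d_idx] <- out[2L, -1L]
    }
    t <- t + h
    if (fire) {
      j <- findInterval(runif(1L) * a0, cumsum(a)) + 1L
      si <- s_idx[ceiling(j / 2)]
      delta <- if (j %% 2L == 1L) 1 else -1
      xfull[si] <- max(xfull[si] + delta, 0)
      n_events <- n_events + 1L
    }
    nseg <- nseg + 1L
    if (nseg > cap) {
      cap <- cap * 2L
      seg_t <- c(seg_t, numeric(cap / 2L))
      seg_x <- rbind(seg_x, matrix(0, nrow = cap / 2L, ncol = ncol(seg_x)))
    }
    seg_t[nseg] <- t
    seg_x[nseg, ] <- xfull
  }
  if (n_eval > 0L && n_clipped / n_eval > 0.001) {
    warning(sprintf(
      "negative propensities clipped in %.2f%% of evaluations; the ",
      100 * n_clipped / n_eval), "production/degradation split may be ",
      "inappropriate for this partition", call. = FALSE)
  }
  list(seg_t = seg_t[seq_len(nseg)], seg_x = seg_x[seq_len(nseg), ,
                                                   drop = FALSE],
       n_clipped = n_clipped, n_events = n_events)
}

# Map piecewise segments onto an output grid: counts as right-continuous
# step functions (value at the segment start), continuous coordinates by
# linear interpolation between segment endpoints (endpoints are at most one
# synchronization interval apart).
segments_to_grid <- function(seg_t, seg_x, grid, count_idx, cont_idx) {
  G <- length(grid)
  states <- matrix(0, nrow = G, ncol = ncol(seg_x))
  pos <- findInterval(grid, seg_t, rightmost.closed = TRUE)
  pos[pos < 1L] <- 1L
  for (i in count_idx) {
    states[, i] <- seg_x[pos, i]
  }
  for (i in cont_idx) {
    states[, i] <- stats::approx(seg_t, seg_x[, i], xout = grid,
                                 rule = 2, ties = "ordered")$y
  }
  states
}

#' Run an ensemble of hybrid replicates
#'
#' Replicate `r` uses seed `base_seed + r`, so the ensemble is independent
#' of execution order and reproducible. A failing replicate does not abort
#' the ensemble: partial results are returned together with a failure
#' manifest.
#'
#' @param system A `hybrid_system`.
#' @param T Final time.
#' @param n_reps Number of replicates (>= 1).
#' @param base_seed Integer base seed.
#' @param grid Shared output grid (default `seq(0, T, by = 0.1)`).
#' @return An `hs_ensemble`: list with `trajectories`, `seeds`, `failures`
#'   (named character vector of error messages, empty when all succeeded).
#' @export
run_ensemble <- function(system, T, n_reps, base_seed = 1L, grid = NULL) {
  stopifnot(n_reps >= 1L)
  grid <- grid %||% seq(0, T, by = 0.1)
  seeds <- base_seed + seq_len(n_reps)
  failures <- character()
  trajectories <- lapply(seeds, function(s) {
    tryCatch(simulate_hybrid(system, T, seed = s, grid = grid),
             error = function(e) {
               failures[as.character(s)] <<- conditionMessage(e)
               NULL
             })
  })
  keep <- !vapply(trajectories, is.null, logical(1))
  structure(list(trajectories = trajectories[keep], seeds = seeds[keep],
                 failures = failures),
            class = "hs_ensemble")
}

#' @export
print.hs_ensemble <- function(x, ...) {
  cat("<ensemble> ", length(x$trajectories), " replicates",
      if (length(x$failures) > 0L)
        paste0(" (", length(x$failures), " failed)") else "",
      "\n", sep = "")
  invisible(x)
}

#' Tidy an ensemble into long format
#' @param x An `hs_ensemble`.
#' @param ... Unused.
#' @return Tibble with `replicate`, `time`, `species`, `value`.
#' @exportS3Method generics::tidy
tidy.hs_ensemble <- function(x, ...) {
  purrr::imap_dfr(x$trajectories, function(tr, i) {
    dplyr::mutate(tidy(tr), replicate = i, .before = 1L)
  })
}

#' Plot an ensemble as mean and spread
#'
#' @param object An `hs_ensemble`.
#' @param species Optional subset of species.
#' @param ... Unused.
#' @return A ggplot object showing the across-replicate mean with a +/-1 sd
#'   ribbon.
#' @exportS3Method ggplot2::autoplot
autoplot.hs_ensemble <- function(object, species = NULL, ...) {
  df <- tidy(object)
  if (!is.null(species)) df <- dplyr::filter(df, .data$species %in% !!species)
  df <- dplyr::summarise(
    dplyr::group_by(df, .data$time, .data$species),
    mean = mean(.data$value), sd = stats::sd(.data$value), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~species, scales = "free_y") +
    ggplot2::labs(x = "time", y = "abundance (molecules)")
}
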