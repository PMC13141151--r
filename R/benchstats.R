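# Stationary statistics, relative-error comparisons and the cross-method
# benchmark table.

#' Stationary statistics of a trajectory or ensemble
#'
#' Two estimation modes. `"pooled"` (ergodic averaging, the default) pools
#' all grid samples with `t >= burn_in` across replicates and reports the
#' per-species mean and population variance (denominator `n`). `"endpoint"`
#' uses only the final grid sample of each replicate, which is the natural
#' estimator for deterministic runs (a single deterministic trajectory then
#' has variance exactly 0).
#'
#' @param x A trajectory (`hs_trajectory`) or ensemble (`hs_ensemble`).
#' @param burn_in Time before which samples are discarded (must leave a
#'   non-empty window).
#' @param mode `"pooled"` or `"endpoint"`.
#' @return A tibble with `species`, `mean`, `variance`, `n`, `burn_in`,
#'   `window`.
#' @examples
#' tr <- ode_solve(benchmark_model(), T = 200)
#' stationary_stats(tr, burn_in = 50)
#' @export
stationary_stats <- function(x, burn_in = 0, mode = c("pooled", "endpoint")) {
  mode <- match.arg(mode)
  trajs <- if (inherits(x, "hs_ensemble")) x$trajectories
           else if (inherits(x, "hs_trajectory")) list(x)
           else stop("x must be a trajectory or an ensemble", call. = FALSE)
  tmax <- max(trajs[[1]]$times)
  if (burn_in >= tmax) {
    stop("burn_in must be smaller than the final time", call. = FALSE)
  }
  sp <- trajs[[1]]$species
  mats <- lapply(trajs, function(tr) {
    if (mode == "endpoint") {
      tr$states[nrow(tr$states), , drop = FALSE]
    } else {
      tr$states[tr$times >= burn_in, , drop = FALSE]
    }
  })
  pooled <- do.call(rbind, mats)
  if (nrow(pooled) == 0L) stop("empty stationary window", call. = FALSE)
  m <- colMeans(pooled)
  v <- colMeans(sweep(pooled, 2L, m)^2) # population variance
  tibble::tibble(species = sp, mean = unname(m), variance = unname(v),
                 n = nrow(pooled), burn_in = burn_in,
                 window = tmax - burn_in)
}

#' Mean absolute relative deviation of stationary means
#'
#' `epsilon = (1/S) * sum_i |mean_i - ref_i| / |ref_i|` over species. The
#' reference is typically the deterministic ODE steady state.
#'
#' @param summary Tibble from [stationary_stats()].
#' @param reference_means Numeric vector of reference means (optionally
#'   named by species), all nonzero.
#' @return A single non-negative number.
#' @examples
#' s <- tibble::tibble(species = c("M", "P"), mean = c(5.10, 2528.79))
#' relative_error(s, c(M = 5, P = 2500)) # ~0.01576
#' @export
relative_error <- function(summary, reference_means) {
  stopifnot(is.data.frame(summary), "mean" %in% names(summary))
  ref <- reference_means
  if (!is.null(names(ref))) {
    missing_sp <- setdiff(summary$species, names(ref))
    if (length(missing_sp) > 0L) {
      stop("reference means missing for ",
           paste(missing_sp, collapse = ", "), call. = FALSE)
    }
    ref <- ref[summary$species]
  }
  if (length(ref) != nrow(summary)) {
    stop("reference_means must have one entry per species", call. = FALSE)
  }
  if (any(ref == 0)) {
    stop("reference means must be nonzero", call. = FALSE)
  }
  mean(abs(summary$mean - ref) / abs(ref))
}

#' Benchmark run configuration
#'
#' Bundles the protocol shared by [compare_methods()]: model, horizon,
#' burn-in, output grid, synchronization interval, leap size, replicate
#' count, seed and solver tolerances, plus the species partition used by the
#' hybrid engine (explicit labels, or a trained `partition_model` to
#' classify with) and the species whose channels the Haseltine-Rawlings
#' method treats as slow.
#'
#' @param model An [ode_model()] in count units.
#' @param T Horizon; `burn_in` must be smaller.
#' @param burn_in Burn-in time for stationary statistics.
#' @param grid_by Output grid spacing.
#' @param dt Hybrid synchronization interval.
#' @param tau Tau-leap step.
#' @param n_reps Replicates for the hybrid ensemble (>= 1).
#' @param seed Base seed; each method uses a fixed documented offset from it.
#' @param rtol,atol Solver tolerances.
#' @param partition Per-species 0/1 labels for the hybrid engine, or a
#'   `partition_model` (the species are then classified from a
#'   pre-simulation), or `NULL` to label every species stochastic.
#' @param hr_slow Species whose birth/death channels are slow (jump) in the
#'   Haseltine-Rawlings baseline; defaults to the hybrid's stochastic set.
#' @param reference Optional named vector of reference means; when `NULL`
#'   the deterministic steady state is computed by integrating the ODE to
#'   `T` and taking the final state.
#' @return A `run_config` list.
#' @export
run_config <- function(model, T = 5000, burn_in = 50, grid_by = 0.1,
                       dt = 0.1, tau = 0.01, n_reps = 1L, seed = 1L,
                       rtol = 1e-6, atol = 1e-9, partition = NULL,
                       hr_slow = NULL, reference = NULL) {
  stopifnot(inherits(model, "ode_model"), burn_in < T, n_reps >= 1L)
  structure(list(model = model, T = T, burn_in = burn_in, grid_by = grid_by,
                 dt = dt, tau = tau, n_reps = as.integer(n_reps),
                 seed = as.integer(seed), rtol = rtol, atol = atol,
                 partition = partition, hr_slow = hr_slow,
                 reference = reference),
            class = "run_config")
}

BENCH_METHODS <- c("ode", "ssa", "tau_leap", "hr_hybrid", "hybrid")

# fixed per-method seed offsets so the table is reproducible as a whole
METHOD_SEED_OFFSET <- c(ode = 0L, ssa = 101L, tau_leap = 202L,
                        hr_hybrid = 303L, hybrid = 404L)

#' Compare simulation methods on one model
#'
#' Runs each requested method on the configured model, computes stationary
#' statistics (time-pooled after burn-in for the stochastic methods; final
#' state with zero variance for the deterministic ODE) and the mean absolute
#' relative deviation of the stationary means from the reference (the
#' deterministic ODE steady state unless overridden). Fully seeded: an
#' identical configuration reproduces the table byte for byte.
#'
#' @param config A [run_config()].
#' @param methods Subset of `"ode"`, `"ssa"`, `"tau_leap"`, `"hr_hybrid"`,
#'   `"hybrid"`.
#' @return A `benchmark_table` tibble: one row per method and species with
#'   `mean`, `variance`, `n` and the method-level `rel_error`.
#' @export
compare_methods <- function(config, methods = BENCH_METHODS) {
  stopifnot(inherits(config, "run_config"))
  unknown <- setdiff(methods, BENCH_METHODS)
  if (length(unknown) > 0L) {
    stop("unknown method(s): ", paste(unknown, collapse = ", "),
         "; valid methods are ", paste(BENCH_METHODS, collapse = ", "),
         call. = FALSE)
  }
  model <- config$model
  grid <- seq(0, config$T, by = config$grid_by)
  ref <- config$reference
  if (is.null(ref)) {
    det <- ode_solve(model, T = config$T, rtol = config$rtol,
                     atol = config$atol, grid = grid)
    ref <- setNames(det$states[nrow(det$states), ], det$species)
  }
  labels <- hybrid_labels(config)

  rows <- lapply(methods, function(mth) {
    sd_seed <- config$seed + METHOD_SEED_OFFSET[[mth]]
    st <- switch(
      mth,
      ode = {
        tr <- ode_solve(model, T = config$T, rtol = config$rtol,
                        atol = config$atol, grid = grid)
        stationary_stats(tr, burn_in = config$burn_in, mode = "endpoint")
      },
      ssa = {
        net <- network_from_decomposition(model)
        stationary_stats(ssa_direct(net, T = config$T, seed = sd_seed,
                                    grid = grid),
                         burn_in = config$burn_in)
      },
      tau_leap = {
        net <- network_from_decomposition(model)
        stationary_stats(tau_leap(net, tau = config$tau, T = config$T,
                                  seed = sd_seed, grid = grid),
                         burn_in = config$burn_in)
      },
      hr_hybrid = {
        net <- network_from_decomposition(model)
        slow <- config$hr_slow %||% species_names(model)[labels == 1L]
        stationary_stats(hr_hybrid(net, channel_partition(net, slow),
                                   T = config$T, seed = sd_seed,
                                   rtol = config$rtol, atol = config$atol,
                                   grid = grid),
                         burn_in = config$burn_in)
      },
      hybrid = {
        sys <- build_hybrid_system(model, labels, dt = config$dt,
                                   rtol = config$rtol, atol = config$atol)
        ens <- run_ensemble(sys, T = config$T, n_reps = config$n_reps,
                            base_seed = sd_seed, grid = grid)
        stationary_stats(ens, burn_in = config$burn_in)
      }
    )
    dplyr::mutate(st, method = mth, rel_error = relative_error(st, ref),
                  .before = 1L)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("benchmark_table", class(out))
  attr(out, "reference") <- ref
  out
}

hybrid_labels <- function(config) {
  model <- config$model
  p <- config$partition
  if (is.null(p)) {
    return(rep(1L, n_species(model)))
  }
  if (inherits(p, "partition_model")) {
    return(normalize_labels(predict_partition(model, p),
                            species_names(model)))
  }
  normalize_labels(p, species_names(model))
}

#' Write a benchmark table to CSV
#' @param table Tibble from [compare_methods()].
#' @param path Output path.
#' @export
write_benchmark_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
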