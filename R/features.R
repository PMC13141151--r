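FEATURE_NAMES <- c(
  "mean", "sd", "cv", "min", "max", "range", "q05", "q50", "q80", "q99",
  "log10_1p_mean", "log10_1p_q80", "log10_1p_q99", "fano_proxy",
  "n_extrema", "lag1_autocorr", "final_over_max", "frac_above_halfmax"
)

#' Extract per-species trajectory features
#'
#' Summarises each species of a deterministic pre-simulation trajectory by 18
#' statistical and dynamical descriptors covering amplitude (mean, min, max,
#' quantiles, log-scale versions), variability (sd, cv, Fano-style ratio),
#' dynamic range (range, final/max, fraction of time above half-maximum) and
#' temporal behaviour (number of local extrema, lag-1 autocorrelation).
#'
#' Conventions: quantiles use linear interpolation of order statistics
#' (type 7); `sd` is the population standard deviation over grid points;
#' ratios use a guard `eps = 1e-9` in the denominator; `n_extrema` counts
#' strict sign changes of the first differences (zero differences dropped);
#' `lag1_autocorr` is computed on the mean-removed series and set to 0 for a
#' constant series. Features are deterministic given the trajectory.
#'
#' @param traj A trajectory with at least 3 grid points.
#' @return A tibble with one row per species: a `species` column plus the 18
#'   feature columns. The trajectory's unit kind is carried along as the
#'   `unit_kind` attribute (used by [label_by_rule()] to refuse
#'   concentration-unit features).
#' @examples
#' traj <- run_presim(benchmark_model(), horizon = 100, n_grid = 1001)
#' extract_features(traj)
#' @export
extract_features <- function(traj) {
  stopifnot(inherits(traj, "hs_trajectory"))
  if (length(traj$times) < 3L) {
    stop("feature extraction needs at least 3 grid points", call. = FALSE)
  }
  if (any(!is.finite(traj$states))) {
    stop("trajectory contains non-finite values", call. = FALSE)
  }
  rows <- lapply(seq_along(traj$species), function(j) {
    series_features(traj$states[, j])
  })
  out <- tibble::as_tibble(do.call(rbind, rows))
  out <- dplyr::bind_cols(tibble::tibble(species = traj$species), out)
  attr(out, "unit_kind") <- attr(traj, "unit_kind")
  out
}

series_features <- function(y) {
  eps <- 1e-9
  n <- length(y)
  m <- mean(y)
  s <- sqrt(mean((y - m)^2)) # population sd
  q <- unname(quantile(y, c(0.05, 0.5, 0.8, 0.99), type = 7))
  mx <- max(y)
  mn <- min(y)
  d <- diff(y)
  sg <- sign(d)
  sg <- sg[sg != 0]
  n_ext <- if (length(sg) > 1L) sum(sg[-1] * sg[-length(sg)] < 0) else 0L
  z <- y - m
  denom <- sum(z^2)
  lag1 <- if (denom > 0) sum(z[-1] * z[-n]) / denom else 0
  c(mean = m, sd = s, cv = s / (m + eps), min = mn, max = mx,
    range = mx - mn, q05 = q[1], q50 = q[2], q80 = q[3], q99 = q[4],
    log10_1p_mean = log10(1 + m), log10_1p_q80 = log10(1 + q[3]),
    log10_1p_q99 = log10(1 + q[4]), fano_proxy = s^2 / (m + eps),
    n_extrema = as.numeric(n_ext), lag1_autocorr = lag1,
    final_over_max = y[n] / (mx + eps),
    frac_above_halfmax = mean(y > mx / 2))
}

#' Write a feature table to CSV
#'
#' One row per species, one column per feature.
#' @param features Tibble from [extract_features()].
#' @param path Output path.
#' @export
write_features_csv <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}
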