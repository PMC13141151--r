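new_trajectory <- function(times, states, species, unit_kind = NULL) {
  states <- as.matrix(states)
  colnames(states) <- species
  structure(list(times = as.numeric(times), states = states,
                 species = species),
            unit_kind = unit_kind, class = "hs_trajectory")
}

#' @export
print.hs_trajectory <- function(x, ...) {
  cat("<trajectory> ", length(x$species), " species x ", length(x$times),
      " time points on [", format(x$times[1]), ", ",
      format(x$times[length(x$times)]), "]\n", sep = "")
  invisible(x)
}

#' Coerce a trajectory to a wide tibble
#'
#' @param x A trajectory as returned by [run_presim()], [simulate_hybrid()]
#'   or the reference solvers.
#' @param ... Unused.
#' @return A tibble with a `time` column and one column per species.
#' @exportS3Method tibble::as_tibble
as_tibble.hs_trajectory <- function(x, ...) {
  tibble::as_tibble(cbind(data.frame(time = x$times),
                          as.data.frame(x$states)))
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Tidy a trajectory into long format
#'
#' @param x A trajectory.
#' @param ... Unused.
#' @return A tibble with columns `time`, `species`, `value`.
#' @exportS3Method generics::tidy
tidy.hs_trajectory <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x), -"time", names_to = "species",
                      values_to = "value")
}

#' Write / read a trajectory as CSV
#'
#' Plain CSV with header `time,<species...>`, shared by all engines.
#'
#' @param traj A trajectory.
#' @param path File path.
#' @return `write_trajectory_csv()` returns `path` invisibly;
#'   `read_trajectory_csv()` returns a trajectory.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as_tibble(traj), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "time") stop("expected a 'time' first column")
  new_trajectory(df$time, as.matrix(df[-1]), names(df)[-1])
}

#' Plot a trajectory
#'
#' @param object A trajectory.
#' @param species Optional character vector restricting the species plotted.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.hs_trajectory <- function(object, species = NULL, ...) {
  df <- tidy(object)
  if (!is.null(species)) df <- dplyr::filter(df, .data$species %in% !!species)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value,
                                   colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = "abundance (molecules)", colour = NULL)
}
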