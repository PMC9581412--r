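# broom-style tidiers and ggplot2 autoplot methods for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an MSM: eigenvalues and implied timescales
#'
#' @param x An `msm_model`.
#' @param ... Unused.
#' @return Tibble with `process`, `eigenvalue`, `timescale_ns`.
#' @export
tidy.msm_model <- function(x, ...) {
  tibble::tibble(
    process = seq_along(x$eigenvalues),
    eigenvalue = x$eigenvalues,
    timescale_ns = c(Inf, implied_timescale(x$eigenvalues[-1], x$lag_ns))
  )
}

#' @rdname tidy.msm_model
#' @export
glance.msm_model <- function(x, ...) {
  tibble::tibble(
    n_microstates = nrow(x$count_matrix),
    n_active = length(x$active_set),
    lag_frames = x$lag,
    lag_ns = x$lag_ns,
    total_counts = sum(x$count_matrix),
    slowest_timescale_ns = implied_timescale(x$eigenvalues[2], x$lag_ns)
  )
}

#' Tidy a tICA model
#'
#' @param x A `tica_model`.
#' @param ... Unused.
#' @return Tibble with `component`, `eigenvalue`, `timescale_frames`.
#' @export
tidy.tica_model <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$eigenvalues),
    eigenvalue = x$eigenvalues,
    timescale_frames = implied_timescale(x$eigenvalues, x$lag)
  )
}

#' @rdname tidy.tica_model
#' @export
glance.tica_model <- function(x, ...) {
  tibble::tibble(
    n_features = length(x$mean),
    n_components = length(x$eigenvalues),
    lag_frames = x$lag,
    regularization = x$regularization
  )
}

#' Tidy a macrostate model: populations and core counts
#'
#' @param x A `macrostate_model`.
#' @param ... Unused.
#' @export
tidy.macrostate_model <- function(x, ...) {
  counts <- attr(x$core_assignment, "counts")
  dplyr::mutate(x$macro_pi, core_frames = as.integer(counts))
}

#' @rdname tidy.macrostate_model
#' @export
glance.macrostate_model <- function(x, ...) {
  tibble::tibble(
    n_macro = x$n_macro,
    core_threshold = x$core_threshold,
    n_transition_frames = attr(x$core_assignment, "n_transition"),
    min_population = min(x$macro_pi$pi),
    max_population = max(x$macro_pi$pi)
  )
}

#' Tidy an importance profile (per-residue table)
#'
#' @param x An `importance_profile`.
#' @param ... Unused.
#' @export
tidy.importance_profile <- function(x, ...) x$per_residue

#' Plot implied timescales against lag time
#'
#' Timescales on a log axis with the unresolvable region below the
#' identity line shaded.
#'
#' @param object An [implied_timescales()] table.
#' @param ... Unused.
#' @export
autoplot.implied_timescales <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lag_ns, y = .data$its_ns,
                                       colour = factor(.data$process))) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = 0, ymax = .data$lag_ns),
                         fill = "grey80", colour = NA) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "lag time (ns)", y = "implied timescale (ns)",
                  colour = "process")
}

#' Plot a free-energy surface
#'
#' @param object A `free_energy_surface` from [weighted_statistics()].
#' @param ... Unused.
#' @export
autoplot.free_energy_surface <- function(object, ...) {
  ggplot2::ggplot(dplyr::filter(object, is.finite(.data$free_energy)),
                  ggplot2::aes(x = .data$x, y = .data$y,
                               fill = .data$free_energy)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = expression(F / k[B] * T)) +
    ggplot2::labs(x = "tIC 1", y = "tIC 2")
}

#' Plot per-residue importance profiles per macrostate
#'
#' @param object An `importance_profile`.
#' @param ... Unused.
#' @export
autoplot.importance_profile <- function(object, ...) {
  ggplot2::ggplot(object$per_residue,
                  ggplot2::aes(x = .data$resid, y = .data$importance)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~ .data$macrostate, ncol = 1,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "residue", y = "normalized importance")
}
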