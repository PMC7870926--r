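#' Plot a global kinetic fit against the measured time courses
#'
#' Points with SEM error bars and the fitted model curves, one panel per
#' species, coloured by strain background.
#'
#' @param object An `srna_fit` from [fit_kinetics()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.srna_fit <- function(object, ...) {
  res <- object$residuals
  grid <- res |>
    dplyr::distinct(.data$background) |>
    dplyr::pull(.data$background)
  curves <- purrr::map_dfr(grid, function(bg) {
    tt <- seq(min(res$time_s), max(res$time_s), length.out = 100)
    sim <- simulate_kinetics(object$params[[bg]], object$state0[[bg]],
                             tt, object$cell)
    sim$background <- bg
    sim
  })
  ggplot2::ggplot(res, ggplot2::aes(x = .data$time_s / 60)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_copies - .data$sem,
                   ymax = .data$mean_copies + .data$sem,
                   colour = .data$background), width = 0.3, alpha = 0.6) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean_copies,
                                     colour = .data$background), size = 1.5) +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(y = .data$copies,
                                    colour = .data$background)) +
    ggplot2::facet_wrap(~species, scales = "free_y") +
    ggplot2::labs(x = "time after induction (min)", y = "copies per cell",
                  colour = NULL) +
    ggplot2::theme_bw()
}

#' Plot a decay fit
#'
#' @param object A `decay_fit` from [fit_decay()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.decay_fit <- function(object, ...) {
  if (is.null(object$fit)) stop("nothing to plot: indeterminate fit", call. = FALSE)
  mf <- if (object$model == "loglinear") {
    d <- stats::model.frame(object$fit)
    tibble::tibble(time_s = d$tt, value = exp(d$`log(vv)`))
  } else {
    env <- environment(stats::formula(object$fit))
    tibble::tibble(time_s = env$tt, value = env$vv)
  }
  tt <- seq(min(mf$time_s), max(mf$time_s), length.out = 100)
  pred <- if (object$model == "loglinear") {
    exp(object$intercept - object$rate * tt)
  } else {
    object$plateau + object$span * exp(-object$rate * tt)
  }
  ggplot2::ggplot(mf, ggplot2::aes(.data$time_s / 60, .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = tibble::tibble(time_s = tt, value = pred)) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (min)", y = "abundance",
                  subtitle = sprintf("rate %.3g s⁻¹, lifetime %.3g min",
                                     object$rate, object$lifetime_s / 60)) +
    ggplot2::theme_bw()
}

#' Heatmap of mutational effects along the sRNA
#'
#' Renders the position-by-base grid from [heatmap_matrix()]: colour for
#' the effect statistic, black cells for the wild-type base, crossed cells
#' for mutants missing from the library.
#'
#' @param hm Tidy heatmap tibble from [heatmap_matrix()].
#' @return A ggplot object.
#' @export
plot_effect_heatmap <- function(hm) {
  ggplot2::ggplot(hm, ggplot2::aes(.data$coordinate, .data$base)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$value), colour = "grey80") +
    ggplot2::geom_tile(data = dplyr::filter(hm, .data$wild_type),
                       fill = "black") +
    ggplot2::geom_point(data = dplyr::filter(hm, .data$missing),
                        shape = 4, size = 1) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  na.value = "grey95", name = "z") +
    ggplot2::labs(x = "nucleotide position", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
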