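# ggplot2 views of the main result types.

#' Plot a polarity field as a quiver diagram
#'
#' @param field Data frame with `x`, `y`, `px`, `py` (e.g.
#'   [state_polarity()] or [gen_ideal_field()]).
#' @param scale Arrow length in position units.
#' @return A ggplot object.
#' @export
plot_polarity_field <- function(field, scale = 1) {
  ok <- is.finite(field$px) & is.finite(field$py)
  ggplot2::ggplot(field[ok, ],
                  ggplot2::aes(x = .data$x, y = .data$y,
                               xend = .data$x + scale * .data$px,
                               yend = .data$y + scale * .data$py)) +
    ggplot2::geom_segment(arrow = ggplot2::arrow(length = ggplot2::unit(0.1, "cm"))) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x / b", y = "y / b")
}

#' @export
autoplot.gel_modes <- function(object, ...) {
  ggplot2::ggplot(object$coef,
                  ggplot2::aes(x = factor(.data$m), y = .data$Q)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "mode m", y = expression(Q[m]))
}

#' @export
autoplot.contraction_fit <- function(object, ...) {
  d <- object$data
  curve <- tibble::tibble(
    time = seq(min(d$time), max(d$time), length.out = 400)
  )
  curve$radius <- object$R_min +
    object$dR * tanh((curve$time - object$t_cont) / object$dt_width)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$radius)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_line(data = curve, colour = "red") +
    ggplot2::labs(x = "t", y = "R(t)")
}

#' @export
autoplot.gel_msad <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$dt, y = .data$msad)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(Delta * t),
                  y = expression("<(" * Delta * theta * ")"^2 * ">"))
}

#' @export
autoplot.gel_trajectory <- function(object, ...) {
  ob <- tidyr::pivot_longer(
    object$observables[, c("time", "radius", "n_mot", "Q1")],
    cols = -"time", names_to = "observable", values_to = "value"
  )
  ggplot2::ggplot(ob, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~observable, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "t")
}
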