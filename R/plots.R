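#' Bland-Altman plot
#'
#' Differences against averages with the mean-difference line (solid) and
#' limits of agreement at mean +/- 2 SD (dotted).
#'
#' @param object A [bland_altman()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bland_altman
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$average, y = .data$difference)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$mean_diff, linewidth = 0.6) +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dotted") +
    ggplot2::labs(x = "Average of the two measurements",
                  y = "Difference (first - second)",
                  title = "Bland-Altman agreement",
                  subtitle = sprintf("mean %0.3g, limits of agreement [%0.3g, %0.3g] (mean ± 2 SD), n = %d",
                                     object$mean_diff, object$loa_low,
                                     object$loa_high, object$n)) +
    ggplot2::theme_minimal()
}

#' Cochlear duct length against insertion angle for both models
#'
#' Draws the modelled length-at-angle curves for one cochlea, with optional
#' horizontal reference lines at the electrode's C1 and tip lengths so the
#' predicted angular depths can be read off the intersections.
#'
#' @param A,B Basal-turn diameter and width, mm.
#' @param electrode Optional [electrode_spec()] for the reference lines.
#' @param params A [cochlear_params()] object.
#' @param theta_max Upper end of the plotted angle range, degrees.
#' @return A ggplot.
#' @examples
#' plot_cdl_curves(A = 9.2, B = 6.8, electrode = flex28())
#' @export
plot_cdl_curves <- function(A, B, electrode = NULL,
                            params = cochlear_params(), theta_max = 720) {
  theta <- seq(0, theta_max, by = 2)
  curves <- dplyr::bind_rows(
    tibble::tibble(model = "escude", theta_deg = theta,
                   cdl_mm = cdl_escude(A, theta, params = params)),
    tibble::tibble(model = "eca", theta_deg = theta,
                   cdl_mm = cdl_eca(A, B, theta, params = params))
  )
  p <- ggplot2::ggplot(curves,
                       ggplot2::aes(x = .data$theta_deg, y = .data$cdl_mm,
                                    colour = .data$model)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Insertion angle (deg)",
                  y = "Cochlear duct length at the electrode level (mm)",
                  colour = "Model",
                  title = sprintf("Modelled insertion depth (A = %g mm, B = %g mm)", A, B)) +
    ggplot2::theme_minimal()
  if (!is.null(electrode)) {
    p <- p + ggplot2::geom_hline(
      yintercept = c(electrode$c1_to_stopper_mm, electrode$total_length_mm),
      linetype = "dashed", colour = "grey40")
  }
  p
}

#' Prediction-error dot plot per model and observer
#'
#' Signed errors (actual minus predicted) for each record; points below zero
#' are insertions the prediction overestimated.
#'
#' @param errors Output of [prediction_error()].
#' @param domain `"angular"` (degrees) or `"linear"` (mm).
#' @return A ggplot.
#' @export
plot_errors <- function(errors, domain = c("angular", "linear")) {
  domain <- match.arg(domain)
  col <- if (domain == "angular") "angular_error_deg" else "linear_error_mm"
  lab <- if (domain == "angular") "Angular error (deg)" else "Linear error (mm)"
  d <- dplyr::filter(errors, is.finite(.data[[col]]))
  has_observer <- "observer" %in% names(d)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$model, y = .data[[col]])) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          colour = "red3", linewidth = 0.3) +
    ggplot2::labs(x = "Model", y = lab,
                  title = "Prediction error (actual - predicted)",
                  subtitle = "negative = prediction overestimated the achieved depth") +
    ggplot2::theme_minimal()
  if (has_observer) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$observer),
                                 labeller = ggplot2::label_both)
  }
  p
}
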