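#' Plot an individual fit: observed vs model-predicted INR
#'
#' Observed visit INRs (points) against the fitted steady-state prediction at
#' each visit's dose (open circles), over visit time.
#'
#' @param object A `warfinr_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.warfinr_fit <- function(object, ...) {
  v <- object$visits
  pred <- steady_state_inr(object$estimate, v$dose_mg, v$tau_h)
  t <- if ("t_days" %in% names(v)) v$t_days else seq_len(nrow(v))
  df <- tibble::tibble(t_days = rep(t, 2),
                       inr = c(v$inr, pred),
                       which = rep(c("observed", "fitted"), each = nrow(v)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_days, y = .data$inr,
                                   colour = .data$which, shape = .data$which)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "Time (days)", y = "PT-INR", colour = NULL, shape = NULL,
                  title = "MAP fit: observed vs predicted steady-state INR") +
    ggplot2::theme_minimal()
}

#' Plot a cohort report: fitted PK parameter distributions
#'
#' Histograms of the four back-predicted PK parameters across converged
#' fits, with the cohort mean marked.
#'
#' @param object A `warfinr_report`.
#' @param bins Histogram bins. Default 30.
#' @param ... Unused.
#' @return A ggplot (facetted 2 x 2).
#' @exportS3Method ggplot2::autoplot
autoplot.warfinr_report <- function(object, bins = 30, ...) {
  ok <- object$parameters[object$parameters$converged, ]
  long <- tidyr::pivot_longer(ok[c("c_max", "k", "cl", "v_d")],
                              dplyr::everything(),
                              names_to = "parameter", values_to = "value")
  means <- long |> dplyr::group_by(.data$parameter) |>
    dplyr::summarise(mean = mean(.data$value), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(data = means, ggplot2::aes(xintercept = .data$mean),
                        linetype = 2) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "Estimate", y = "Patients",
                  title = "Back-predicted PK parameter distributions") +
    ggplot2::theme_minimal()
}

#' INR trajectories for a subset of patients
#'
#' @param visits Visit table with `patient_id`, `t_days`, `inr`.
#' @param patients Patient ids to draw (default: first 6).
#' @param low,high Therapeutic band to shade. Defaults 2 and 3.
#' @return A ggplot.
#' @export
plot_inr_trajectories <- function(visits, patients = NULL, low = 2, high = 3) {
  visits <- tibble::as_tibble(visits)
  if (is.null(patients)) patients <- head(unique(visits$patient_id), 6)
  df <- visits[visits$patient_id %in% patients, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_days, y = .data$inr,
                                   colour = .data$patient_id)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf, ymin = low, ymax = high,
                      alpha = 0.15, fill = "darkgreen") +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1.5) +
    ggplot2::labs(x = "Time (days)", y = "PT-INR", colour = "Patient") +
    ggplot2::theme_minimal()
}
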