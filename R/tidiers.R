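#' Tidy a MAP fit into a parameter table
#'
#' @param x A `warfinr_fit`.
#' @param ... Unused.
#' @return A tibble with one row per PK parameter: `term`, `estimate`,
#'   `prior_mean`, `prior_sd`.
#' @exportS3Method generics::tidy
tidy.warfinr_fit <- function(x, ...) {
  terms <- c("c_max", "k", "cl", "v_d")
  tibble::tibble(
    term = terms,
    estimate = vapply(terms, function(p) x$estimate[[p]], numeric(1)),
    prior_mean = unname(x$prior$mean[terms]),
    prior_sd = unname(x$prior$sd[terms])
  )
}

#' One-row fit diagnostics
#'
#' @param x A `warfinr_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `objective`, `converged`, `n_visits`,
#'   `condition_number`, `sigma_res`.
#' @exportS3Method generics::glance
glance.warfinr_fit <- function(x, ...) {
  tibble::tibble(objective = x$objective, converged = x$converged,
                 n_visits = x$n_visits, condition_number = x$condition_number,
                 sigma_res = x$prior$sigma_res)
}

#' Per-value outlier flags
#'
#' @param x A `warfinr_outliers`.
#' @param ... Unused.
#' @return A tibble: `value`, `flag`.
#' @exportS3Method generics::tidy
tidy.warfinr_outliers <- function(x, ...) {
  tibble::tibble(value = x$values, flag = x$flag)
}

#' One-row outlier-classification summary
#'
#' @param x A `warfinr_outliers`.
#' @param ... Unused.
#' @return A one-row tibble with the band, rule and counts.
#' @exportS3Method generics::glance
glance.warfinr_outliers <- function(x, ...) {
  tibble::tibble(parameter = x$parameter %||% NA_character_,
                 n = length(x$values), n_within = x$n_within,
                 n_outside = x$n_outside, mean = x$mean, sd = x$sd,
                 z = x$z, sided = x$sided, lower = x$lower, upper = x$upper)
}

#' Cohort-level report summary
#'
#' @param x A `warfinr_report`.
#' @param ... Unused.
#' @return The report's summary tibble (means and SDs of the fitted PK
#'   parameters and PD indices).
#' @exportS3Method generics::glance
glance.warfinr_report <- function(x, ...) x$summary
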