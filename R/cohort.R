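#' Normal-curve outlier classification
#'
#' Fits a normal reference band to a per-patient parameter vector and flags
#' values outside `mean +/- z * SD` (two-sided by default; one-sided variants
#' reproduce per-parameter conventions some reports use). At `z = 1.96` the
#' band covers 95 % of a normal population, so about 5 % of draws are flagged.
#' Boundaries are computed from the same cohort being classified.
#'
#' @param values Numeric vector of a parameter across the cohort (>= 3 finite
#'   values, non-zero SD).
#' @param z Half-width of the band in SD units. Default 1.96.
#' @param sided `"two"` (default), `"lower"` (flag only below `mean - z*SD`)
#'   or `"upper"`.
#' @param parameter Optional parameter name carried into the result.
#'
#' @return An object of class `warfinr_outliers`; [tidy()] gives the
#'   per-value flags, [glance()] the boundaries and counts.
#' @export
#'
#' @examples
#' cls <- classify_outliers(c(rep(1, 9), 50))
#' glance(cls)
classify_outliers <- function(values, z = 1.96,
                              sided = c("two", "lower", "upper"),
                              parameter = NULL) {
  sided <- match.arg(sided)
  if (sum(is.finite(values)) < 3) {
    abort("Outlier classification needs at least 3 finite values.",
          class = "warfinr_schema_error")
  }
  if (any(!is.finite(values))) {
    abort("All values must be finite; drop non-converged fits first.",
          class = "warfinr_schema_error")
  }
  mu <- mean(values)
  s <- sd(values)
  if (s == 0) abort("Zero SD; outlier boundaries are undefined.",
                    class = "warfinr_domain_error")
  lower <- if (sided == "upper") -Inf else mu - z * s
  upper <- if (sided == "lower") Inf else mu + z * s
  flag <- ifelse(values < lower | values > upper, "outside", "within")
  structure(list(
    parameter = parameter, values = values, flag = flag,
    mean = mu, sd = s, z = z, sided = sided,
    lower = lower, upper = upper,
    n_within = sum(flag == "within"), n_outside = sum(flag == "outside")
  ), class = "warfinr_outliers")
}

#' @export
print.warfinr_outliers <- function(x, ...) {
  cat(sprintf("<warfinr_outliers>%s band [%.4g, %.4g] (z = %g, %s-sided): %d within, %d outside\n",
              if (is.null(x$parameter)) "" else paste0(" ", x$parameter),
              x$lower, x$upper, x$z, x$sided, x$n_within, x$n_outside))
  invisible(x)
}

#' Between-group comparison table
#'
#' Compares two groups on numeric variables with the two-sided Mann-Whitney U
#' test and on categorical variables with the Pearson chi-square test of
#' association, reporting group mean (SD) or n (%) alongside each p-value.
#' Raw p-values are kept (no correction is applied to the decisions) with a
#' Holm-adjusted column alongside for transparency.
#'
#' @param data Data frame with one row per patient.
#' @param group Name of a two-level grouping column.
#' @param numeric_vars,categorical_vars Character vectors of column names.
#'   Numeric variables with fewer than 2 observations in a group are skipped
#'   with a warning.
#'
#' @return A tibble: `variable`, `test`, per-group summaries, `p_value`,
#'   `p_holm`.
#' @export
compare_groups <- function(data, group, numeric_vars = character(),
                           categorical_vars = character()) {
  data <- tibble::as_tibble(data)
  g <- data[[group]]
  levels <- sort(unique(as.character(g[!is.na(g)])))
  if (length(levels) != 2) {
    abort("`group` must have exactly two observed levels.",
          class = "warfinr_schema_error")
  }
  a <- data[g == levels[1], , drop = FALSE]
  b <- data[g == levels[2], , drop = FALSE]

  num_rows <- purrr::map(numeric_vars, function(v) {
    xa <- a[[v]][is.finite(a[[v]])]
    xb <- b[[v]][is.finite(b[[v]])]
    if (length(xa) < 2 || length(xb) < 2) {
      warn(sprintf("Skipping `%s`: fewer than 2 observations in a group.", v))
      return(NULL)
    }
    p <- suppressWarnings(wilcox.test(xa, xb)$p.value)
    tibble::tibble(
      variable = v, test = "mann-whitney",
      group_a = sprintf("%.6g (%.6g)", mean(xa), sd(xa)),
      group_b = sprintf("%.6g (%.6g)", mean(xb), sd(xb)),
      p_value = p)
  })
  cat_rows <- purrr::map(categorical_vars, function(v) {
    tab <- table(as.character(g), as.character(data[[v]]))
    p <- tryCatch(suppressWarnings(chisq.test(tab, correct = FALSE)$p.value),
                  error = function(e) {
                    warn(sprintf("Chi-square undefined for `%s` (single category); p set to NA.", v))
                    NA_real_
                  })
    pos <- colnames(tab)[ncol(tab)]
    tibble::tibble(
      variable = v, test = "chi-square",
      group_a = sprintf("%d (%.3g%%)", tab[levels[1], pos],
                        100 * tab[levels[1], pos] / sum(tab[levels[1], ])),
      group_b = sprintf("%d (%.3g%%)", tab[levels[2], pos],
                        100 * tab[levels[2], pos] / sum(tab[levels[2], ])),
      p_value = p)
  })
  out <- dplyr::bind_rows(c(num_rows, cat_rows))
  if (nrow(out)) out$p_holm <- p.adjust(out$p_value, method = "holm")
  attr(out, "group_levels") <- levels
  out
}

#' Age-group binning for stratified summaries
#'
#' Cuts age into the bands used for stratified PK summaries: young (<65),
#' middle-aged and older (65–74), elderly (75–84) and very elderly (>= 85)
#' by default; the boundaries are configurable.
#'
#' @param age Numeric ages in years.
#' @param breaks Increasing interior cut points. Default c(65, 75, 85).
#' @return An ordered factor with labels like `"<65"`, `"65-74"`, `">=85"`.
#' @export
age_groups <- function(age, breaks = c(65, 75, 85)) {
  stopifnot(all(diff(breaks) > 0))
  labels <- c(sprintf("<%g", breaks[1]),
              if (length(breaks) > 1)
                sprintf("%g-%g", head(breaks, -1), tail(breaks, -1) - 1),
              sprintf(">=%g", tail(breaks, 1)))
  cut(age, c(-Inf, breaks, Inf), labels = labels, right = FALSE,
      ordered_result = TRUE)
}

#' Pairwise Pearson correlations
#'
#' Pearson correlation coefficient and two-sided p-value for each requested
#' variable pair. The default pair set is the PK panel of interest — C_max
#' against CL, V_d and k, plus CL and V_d against predicted liver weight —
#' restricted to columns present in `data`.
#'
#' @param data Data frame with one row per patient.
#' @param pairs List of length-2 character vectors (or a two-column data
#'   frame) naming the column pairs. Default as above.
#'
#' @return A tibble: `var1`, `var2`, `n`, `r`, `p_value`, `p_holm`.
#' @export
correlations <- function(data, pairs = NULL) {
  data <- tibble::as_tibble(data)
  if (is.null(pairs)) {
    candidates <- list(c("c_max", "cl"), c("c_max", "v_d"), c("c_max", "k"),
                       c("cl", "liver_weight"), c("v_d", "liver_weight"))
    pairs <- purrr::keep(candidates, function(p) all(p %in% names(data)))
    if (!length(pairs)) {
      abort("No default correlation pair has both columns in `data`; pass `pairs`.",
            class = "warfinr_schema_error")
    }
  }
  if (is.data.frame(pairs)) {
    pairs <- purrr::map(seq_len(nrow(pairs)), function(i) as.character(unlist(pairs[i, 1:2])))
  }
  out <- purrr::map_dfr(pairs, function(p) {
    x <- data[[p[1]]]
    y <- data[[p[2]]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3) {
      abort(sprintf("Pair %s/%s has fewer than 3 complete observations.", p[1], p[2]),
            class = "warfinr_schema_error")
    }
    if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      abort(sprintf("Pair %s/%s includes a constant vector; r is undefined.", p[1], p[2]),
            class = "warfinr_domain_error")
    }
    ct <- cor.test(x[ok], y[ok], method = "pearson")
    tibble::tibble(var1 = p[1], var2 = p[2], n = sum(ok),
                   r = unname(ct$estimate), p_value = ct$p.value)
  })
  out$p_holm <- p.adjust(out$p_value, method = "holm")
  out
}
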