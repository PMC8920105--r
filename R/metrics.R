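#' Warfarin sensitivity index
#'
#' WSI is the last observed PT-INR divided by the warfarin dose (mg) recorded
#' at that same final visit: the INR response obtained per milligram at the
#' end of follow-up. Low values indicate warfarin resistance.
#'
#' @param visits Data frame of one patient's visits with columns `inr`,
#'   `dose_mg` and optionally `t_days` (used to find the final visit).
#'
#' @return The WSI, INR per mg.
#' @export
#'
#' @examples
#' wsi(tibble::tibble(t_days = c(0, 30), inr = c(2.2, 3.0), dose_mg = c(10, 10)))
wsi <- function(visits) {
  visits <- as_visit_tbl(visits)
  if (nrow(visits) < 1) abort("At least one visit is required.", class = "warfinr_no_visits")
  last <- visits[nrow(visits), ]
  if (!is.finite(last$dose_mg) || last$dose_mg == 0) {
    abort("Last-visit dose is zero or missing; WSI is undefined.",
          class = "warfinr_domain_error")
  }
  last$inr / last$dose_mg
}

# Person-time a linearly interpolated segment spends inside [low, high].
segment_in_range <- function(d, y0, y1, low, high) {
  if (y0 == y1) return(d * (y0 >= low && y0 <= high))
  slope <- (y1 - y0) / d
  t_bounds <- sort(c((low - y0) / slope, (high - y0) / slope))
  max(0, min(d, t_bounds[2]) - max(0, t_bounds[1]))
}

#' Time in therapeutic range (Rosendaal linear interpolation)
#'
#' Percent of follow-up person-time the linearly interpolated INR spends
#' inside the therapeutic range. INR is interpolated linearly between
#' consecutive visits; inter-visit gaps longer than `max_gap` days are
#' dropped from both numerator and denominator (the usual Rosendaal
#' convention for unmonitored stretches).
#'
#' @param visits One patient's visits with columns `t_days` and `inr`.
#' @param low,high Therapeutic range bounds. Defaults 2.0 and 3.0; use
#'   2.5–3.5 for mechanical heart-valve indications.
#' @param max_gap Longest inter-visit gap (days) still counted as monitored
#'   person-time. Default 56.
#'
#' @return TTR in percent, in `[0, 100]`.
#' @export
#'
#' @examples
#' v <- tibble::tibble(t_days = c(0, 10), inr = c(1.5, 2.5), dose_mg = c(5, 5))
#' ttr_rosendaal(v)  # 50: the interpolated INR crosses 2.0 at day 5
ttr_rosendaal <- function(visits, low = 2, high = 3, max_gap = 56) {
  visits <- tibble::as_tibble(visits)
  if (!all(c("t_days", "inr") %in% names(visits))) {
    abort("`visits` needs columns t_days and inr.", class = "warfinr_schema_error")
  }
  visits <- visits[order(visits$t_days), ]
  t <- visits$t_days
  y <- visits$inr
  if (length(unique(t)) < 2) {
    abort("TTR needs at least two visits at distinct times.",
          class = "warfinr_undefined_ttr")
  }
  dt <- diff(t)
  use <- dt > 0 & dt <= max_gap
  if (!any(use)) {
    abort(sprintf("No inter-visit interval is within the %g-day gap limit; TTR is undefined.", max_gap),
          class = "warfinr_undefined_ttr")
  }
  in_range <- vapply(which(use), function(i) {
    segment_in_range(dt[i], y[i], y[i + 1], low, high)
  }, numeric(1))
  100 * sum(in_range) / sum(dt[use])
}

#' Inter-visit INR variability
#'
#' For each consecutive visit pair the squared INR change is divided by the
#' time interval in days and multiplied by the pair's mean INR; the
#' variability statistic sigma is the square root of the average of these
#' per-pair quantities, and its base-10 logarithm is the log-INR variability
#' used in the composite measure. Doubling every time interval therefore
#' divides sigma by sqrt(2).
#'
#' @param visits One patient's visits with columns `t_days` and `inr`,
#'   strictly increasing in time.
#'
#' @return A one-row tibble: `sigma` (INR variability), `log_inr_var`
#'   (log10 sigma; `-Inf` when all INR values are equal) and
#'   `zero_variability` flag. Flagged patients are excluded from
#'   composite-measure standardisation.
#' @export
#'
#' @examples
#' v <- tibble::tibble(t_days = c(0, 5), inr = c(2, 3), dose_mg = c(5, 5))
#' inr_variability(v)  # sigma = sqrt((1/5) * 2.5) = sqrt(0.5)
inr_variability <- function(visits) {
  visits <- tibble::as_tibble(visits)
  if (!all(c("t_days", "inr") %in% names(visits))) {
    abort("`visits` needs columns t_days and inr.", class = "warfinr_schema_error")
  }
  visits <- visits[order(visits$t_days), ]
  if (nrow(visits) < 2) {
    abort("INR variability needs at least two visits.", class = "warfinr_no_visits")
  }
  dt <- diff(visits$t_days)
  if (any(dt <= 0)) {
    abort(sprintf("Zero or negative time interval between visit pair %d and %d.",
                  which(dt <= 0)[1], which(dt <= 0)[1] + 1),
          class = "warfinr_domain_error")
  }
  y <- visits$inr
  pair_mean <- (head(y, -1) + tail(y, -1)) / 2
  v <- diff(y)^2 / dt * pair_mean
  sigma <- sqrt(mean(v))
  tibble::tibble(
    sigma = sigma,
    log_inr_var = if (sigma > 0) log10(sigma) else -Inf,
    zero_variability = sigma == 0
  )
}

#' Warfarin composite measure
#'
#' Combines anticoagulation stability and time in range into one cohort-
#' standardised score: `wcm = z(log_inr_var) - z(ttr)` under the default
#' convention, where `z` standardises by the cohort mean and SD. Higher
#' scores mean worse control (high variability, low TTR); the cohort mean is
#' zero by construction. The opposite sign convention is selectable because
#' the measure's published direction is ambiguous.
#'
#' @param ttr Per-patient TTR values (any affine rescaling gives the same
#'   result; standardisation removes location and scale).
#' @param log_inr_var Per-patient log-INR variability values.
#' @param convention `"higher_worse"` (default, `z(var) - z(ttr)`) or
#'   `"higher_better"` (`z(ttr) - z(var)`).
#'
#' @return Numeric vector of composite scores, cohort mean 0.
#' @export
wcm <- function(ttr, log_inr_var,
                convention = c("higher_worse", "higher_better")) {
  convention <- match.arg(convention)
  if (length(ttr) != length(log_inr_var) || length(ttr) < 2) {
    abort("`ttr` and `log_inr_var` must be equal-length vectors of length >= 2.",
          class = "warfinr_schema_error")
  }
  if (any(!is.finite(ttr)) || any(!is.finite(log_inr_var))) {
    abort("WCM inputs must be finite; exclude flagged zero-variability patients first.",
          class = "warfinr_domain_error")
  }
  if (sd(ttr) == 0 || sd(log_inr_var) == 0) {
    abort("Zero cohort SD in TTR or log-INR variability; Z-scores are undefined.",
          class = "warfinr_domain_error")
  }
  z_ttr <- (ttr - mean(ttr)) / sd(ttr)
  z_var <- (log_inr_var - mean(log_inr_var)) / sd(log_inr_var)
  if (convention == "higher_worse") z_var - z_ttr else z_ttr - z_var
}

#' Predicted liver weight
#'
#' Anthropometric regression for adult liver weight:
#' `218 + 12.3 * body weight (kg) + 51 * [male]` grams.
#'
#' @param body_weight Body weight in kg, positive.
#' @param sex `"M"`/`"F"` (or `"male"`/`"female"`, case-insensitive), or a
#'   0/1 male indicator.
#'
#' @return Predicted liver weight in grams.
#' @export
#'
#' @examples
#' liver_weight(70, "M")  # 1130
liver_weight <- function(body_weight, sex) {
  if (any(!is.finite(body_weight)) || any(body_weight <= 0)) {
    abort("Body weight must be finite and positive.", class = "warfinr_domain_error")
  }
  male <- sex_indicator(sex)
  218 + 12.3 * body_weight + 51 * male
}

sex_indicator <- function(sex) {
  if (is.numeric(sex)) {
    if (any(!sex %in% c(0, 1))) {
      abort("Numeric `sex` must be 0 (female) or 1 (male).", class = "warfinr_schema_error")
    }
    return(as.numeric(sex))
  }
  s <- toupper(as.character(sex))
  out <- dplyr::case_when(s %in% c("M", "MALE") ~ 1,
                          s %in% c("F", "FEMALE") ~ 0,
                          TRUE ~ NA_real_)
  if (any(is.na(out))) {
    abort("`sex` must be one of M/F/male/female (or 0/1).", class = "warfinr_schema_error")
  }
  out
}

#' Per-patient anticoagulation quality indices
#'
#' Computes the full index panel for every patient in a cohort: WSI, Rosendaal
#' TTR with its good/poor classification (good when TTR >= 65 %), INR
#' variability and its log10, the warfarin composite measure, and predicted
#' liver weight. Patients with zero INR variability are flagged and excluded
#' from the composite-measure standardisation (their `wcm` is `NA`).
#'
#' @param visits Visit table (`patient_id`, `t_days`, `inr`, `dose_mg`).
#' @param demographics One row per patient: `patient_id`, `age_years`, `sex`,
#'   `body_weight_kg` (and any extra columns, carried through).
#' @param low,high Therapeutic range. Defaults 2–3.
#' @param max_gap Rosendaal gap limit in days. Default 56.
#' @param wcm_convention Passed to [wcm()].
#'
#' @return A tibble, one row per patient: `patient_id`, `wsi`, `ttr`,
#'   `ttr_class`, `sigma_inr`, `log_inr_var`, `wcm`, `liver_weight`, joined
#'   to the demographics columns.
#' @export
anticoag_indices <- function(visits, demographics, low = 2, high = 3,
                             max_gap = 56,
                             wcm_convention = c("higher_worse", "higher_better")) {
  wcm_convention <- match.arg(wcm_convention)
  visits <- as_visit_tbl(visits, require_id = TRUE)
  demographics <- tibble::as_tibble(demographics)

  per_patient <- visits |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::group_modify(function(v, key) {
      variability <- inr_variability(v)
      tibble::tibble(
        wsi = wsi(v),
        ttr = ttr_rosendaal(v, low = low, high = high, max_gap = max_gap),
        sigma_inr = variability$sigma,
        log_inr_var = variability$log_inr_var,
        zero_variability = variability$zero_variability
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(ttr_class = ifelse(.data$ttr >= 65, "good", "poor"))

  usable <- is.finite(per_patient$log_inr_var) & is.finite(per_patient$ttr)
  per_patient$wcm <- NA_real_
  if (sum(usable) >= 2) {
    per_patient$wcm[usable] <- wcm(per_patient$ttr[usable],
                                   per_patient$log_inr_var[usable],
                                   convention = wcm_convention)
  }
  if (any(!usable)) {
    warn(sprintf("%d patient(s) with zero INR variability excluded from WCM standardisation.",
                 sum(!usable)))
  }

  out <- dplyr::left_join(per_patient, demographics, by = "patient_id")
  out$liver_weight <- liver_weight(out$body_weight_kg, out$sex)
  dplyr::select(out, "patient_id", "wsi", "ttr", "ttr_class", "sigma_inr",
                "log_inr_var", "wcm", "liver_weight", dplyr::everything(),
                -"zero_variability")
}
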