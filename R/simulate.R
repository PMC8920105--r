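#' Synthetic-cohort generator configuration
#'
#' Defaults reproduce the statistical structure of the warfarin maintenance
#' cohort the analysis assumes: 220 patients, age 66.6 (13.4) years, body
#' weight 75.2 (18.1) kg, 1:1 male:female, 61.8 % on potentially interacting
#' co-medication, and true individual PK parameters drawn from the population
#' distributions C_max 5.8 (0.4) mg/L, k 1 (0.1) /day, CL 2.1 (0.2) L/day,
#' V_d 7.6 (0.2) L (truncated-positive normals). Each patient contributes 8
#' visits separated by uniform 20–40 day gaps; the clinician's target INR is
#' drawn from U(2, 3) and redrawn at each visit with probability 0.3
#' (creating the within-patient dose variation real titration produces); the
#' prescribed dose is the model-exact dose for the target rounded to 0.5 mg;
#' the observed INR is the model INR at the rounded dose perturbed by
#' lognormal assay/biology noise with 5 % CV.
#'
#' @param n_patients Cohort size. Default 220.
#' @param age Mean and SD of age, years (truncated at `age_min`).
#' @param age_min Minimum age, years. Default 18 (adult cohort).
#' @param body_weight Mean and SD of body weight, kg (truncated at
#'   `weight_min`).
#' @param weight_min Minimum body weight, kg. Default 35.
#' @param male_fraction Probability a patient is male. Default 0.5.
#' @param pk Named list of `c(mean, sd)` population distributions for
#'   `c_max`, `k`, `cl`, `v_d`.
#' @param pk_family `"truncnorm"` (normal truncated at zero, default) or
#'   `"lognormal"` (matched mean/SD).
#' @param m PD slope constant used by the simulator (shared with fitting).
#' @param n_visits Visits per patient. Default 8.
#' @param gap_range Uniform range of inter-visit gaps, days. Default c(20, 40).
#' @param target_range Uniform range of the clinician's target INR.
#'   Default c(2, 3).
#' @param target_redraw_prob Per-visit probability of re-drawing the target.
#'   Default 0.3.
#' @param noise_cv Lognormal coefficient of variation of the observed INR.
#'   Default 0.05.
#' @param dose_increment Tablet rounding increment in mg (0 disables
#'   rounding). Default 0.5.
#' @param interacting_prob Probability of a potentially interacting
#'   co-medication. Default 0.618.
#' @param tau_h Dosing interval in hours. Default 24.
#'
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 220,
                          age = c(66.6, 13.4), age_min = 18,
                          body_weight = c(75.2, 18.1), weight_min = 35,
                          male_fraction = 0.5,
                          pk = list(c_max = c(5.8, 0.4), k = c(1, 0.1),
                                    cl = c(2.1, 0.2), v_d = c(7.6, 0.2)),
                          pk_family = c("truncnorm", "lognormal"),
                          m = 1,
                          n_visits = 8, gap_range = c(20, 40),
                          target_range = c(2, 3), target_redraw_prob = 0.3,
                          noise_cv = 0.05, dose_increment = 0.5,
                          interacting_prob = 0.618, tau_h = 24) {
  pk_family <- match.arg(pk_family)
  stopifnot(n_patients >= 1, n_visits >= 1, noise_cv >= 0, dose_increment >= 0,
            all(vapply(pk, function(p) length(p) == 2 && all(p > 0), logical(1))))
  structure(as.list(environment()), class = "cohort_config")
}

# Normal truncated below at `lower` by rejection; means here sit many SDs
# above the bound so rejection is essentially free.
rtrunc_norm <- function(n, mean, sd, lower = 0) {
  out <- rnorm(n, mean, sd)
  while (any(bad <- out <= lower)) out[bad] <- rnorm(sum(bad), mean, sd)
  out
}

draw_pk <- function(n, spec, family) {
  if (family == "truncnorm") return(rtrunc_norm(n, spec[1], spec[2]))
  sdlog <- sqrt(log(1 + (spec[2] / spec[1])^2))
  stats::rlnorm(n, log(spec[1]) - sdlog^2 / 2, sdlog)
}

#' Simulate a warfarin maintenance cohort
#'
#' Draws patient truths and demographics from [cohort_config()] distributions
#' and rolls each patient forward through a dose-titration visit schedule:
#' at every visit the prescribed dose is [dose_for_target_inr()] at the
#' current target (rounded to the tablet increment) and the observed INR is
#' [steady_state_inr()] at that dose times lognormal noise. With zero noise
#' and no rounding the observed INR equals the target exactly (the model's
#' inverse identity). Byte-identical output for a fixed seed.
#'
#' @param config [cohort_config()].
#' @param seed Integer seed; `NULL` uses the current RNG state.
#'
#' @return An object of class `warfinr_cohort`: a list of tibbles `visits`
#'   (`patient_id`, `t_days`, `inr`, `dose_mg`, `tau_h`), `demographics`
#'   (`patient_id`, `age_years`, `sex`, `body_weight_kg`, `interacting_drug`)
#'   and `truth` (`patient_id`, true `c_max`, `k`, `cl`, `v_d`, `m`), plus
#'   the generating `config`.
#' @export
#'
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_patients = 5), seed = 1)
#' cohort$visits
simulate_cohort <- function(config = cohort_config(), seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(seed)) {
    return(withr::with_seed(seed, simulate_cohort(config)))
  }
  n <- config$n_patients
  ids <- sprintf("P%04d", seq_len(n))

  truth <- tibble::tibble(
    patient_id = ids,
    c_max = draw_pk(n, config$pk$c_max, config$pk_family),
    k = draw_pk(n, config$pk$k, config$pk_family),
    cl = draw_pk(n, config$pk$cl, config$pk_family),
    v_d = draw_pk(n, config$pk$v_d, config$pk_family),
    m = config$m
  )
  demographics <- tibble::tibble(
    patient_id = ids,
    age_years = round(rtrunc_norm(n, config$age[1], config$age[2],
                                  lower = config$age_min), 1),
    sex = ifelse(rbinom(n, 1, config$male_fraction) == 1, "M", "F"),
    body_weight_kg = round(rtrunc_norm(n, config$body_weight[1],
                                       config$body_weight[2],
                                       lower = config$weight_min), 1),
    interacting_drug = rbinom(n, 1, config$interacting_prob)
  )

  visits <- purrr::map_dfr(seq_len(n), function(i) {
    theta <- pk_parameters(truth$c_max[i], truth$k[i], truth$cl[i],
                           truth$v_d[i], m = truth$m[i])
    gaps <- runif(config$n_visits - 1, config$gap_range[1], config$gap_range[2])
    t_days <- c(0, cumsum(gaps))
    target <- numeric(config$n_visits)
    target[1] <- runif(1, config$target_range[1], config$target_range[2])
    for (j in seq_len(config$n_visits)[-1]) {
      target[j] <- if (runif(1) < config$target_redraw_prob) {
        runif(1, config$target_range[1], config$target_range[2])
      } else {
        target[j - 1]
      }
    }
    dose <- dose_for_target_inr(theta, target, tau = config$tau_h)
    if (config$dose_increment > 0) {
      dose <- round(dose / config$dose_increment) * config$dose_increment
    }
    if (any(dose <= 0)) {
      abort(sprintf("Dose rounded to a non-positive value for patient %s; lower `dose_increment`.",
                    ids[i]),
            class = "warfinr_generation_error")
    }
    inr <- steady_state_inr(theta, dose, tau = config$tau_h)
    if (config$noise_cv > 0) {
      inr <- inr * exp(rnorm(config$n_visits, 0, config$noise_cv))
    }
    tibble::tibble(patient_id = ids[i], t_days = t_days, inr = inr,
                   dose_mg = dose, tau_h = config$tau_h)
  })

  structure(list(visits = visits, demographics = demographics, truth = truth,
                 config = config),
            class = "warfinr_cohort")
}

#' @export
print.warfinr_cohort <- function(x, ...) {
  cat(sprintf("<warfinr_cohort> %d patients, %d visits (%d per patient)\n",
              nrow(x$truth), nrow(x$visits), x$config$n_visits))
  invisible(x)
}

#' Score parameter recovery against the generator's truth
#'
#' Joins a fitted-parameter table to the generator's truth table and reports,
#' for each PK parameter, the cohort mean of the estimates, the mean relative
#' bias against individual truths, the RMSE, and (when population means are
#' supplied) the relative error of the cohort mean against the population
#' mean the generator drew from.
#'
#' @param truth Truth tibble from [simulate_cohort()].
#' @param fitted Fit tibble from [fit_cohort()] (non-converged rows are
#'   dropped with a warning).
#' @param pop_means Optional named vector of population means
#'   (`c_max`, `k`, `cl`, `v_d`).
#'
#' @return A tibble, one row per parameter: `parameter`, `n`, `true_mean`,
#'   `est_mean`, `mean_rel_bias`, `rmse`, and `pop_mean`/`rel_err_vs_pop`
#'   when `pop_means` is given.
#' @export
score_recovery <- function(truth, fitted, pop_means = NULL) {
  if (!setequal(truth$patient_id, fitted$patient_id)) {
    abort("Truth and fitted tables must cover the same patient ids.",
          class = "warfinr_schema_error")
  }
  if (any(!fitted$converged)) {
    warn(sprintf("Dropping %d non-converged fit(s) from recovery scoring.",
                 sum(!fitted$converged)))
    fitted <- fitted[fitted$converged, , drop = FALSE]
    truth <- truth[truth$patient_id %in% fitted$patient_id, , drop = FALSE]
  }
  joined <- dplyr::inner_join(truth, fitted, by = "patient_id",
                              suffix = c("_true", "_est"))
  out <- purrr::map_dfr(c("c_max", "k", "cl", "v_d"), function(p) {
    tr <- joined[[paste0(p, "_true")]]
    es <- joined[[paste0(p, "_est")]]
    tibble::tibble(parameter = p, n = length(tr),
                   true_mean = mean(tr), est_mean = mean(es),
                   mean_rel_bias = mean((es - tr) / tr),
                   rmse = sqrt(mean((es - tr)^2)))
  })
  if (!is.null(pop_means)) {
    out$pop_mean <- unname(pop_means[out$parameter])
    out$rel_err_vs_pop <- (out$est_mean - out$pop_mean) / out$pop_mean
  }
  out
}
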