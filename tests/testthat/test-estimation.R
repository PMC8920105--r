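test_that("noise-free visits with a truth-centred prior are recovered exactly", {
  set.seed(31)
  for (i in 1:5) {
    theta <- rand_params()
    visits <- visits_from_targets(theta, c(2, 2.2, 2.5, 2.8, 3.0))
    fit <- fit_individual(visits, prior = prior_at(theta))
    expect_true(fit$converged)
    for (p in c("c_max", "k", "cl", "v_d")) {
      expect_equal(fit$estimate[[p]], theta[[p]], tolerance = 1e-4)
    }
    expect_lt(max(abs(fit$residuals)), 1e-6)
  }
})

test_that("a single visit shrinks the estimate toward the prior mean", {
  theta <- pk_parameters(6.4, 1.15, 2.35, 7.9)
  visits <- visits_from_targets(theta, 2.5)
  prior <- population_prior()
  fit <- fit_individual(visits, prior = prior)
  est <- c(fit$estimate$c_max, fit$estimate$k, fit$estimate$cl, fit$estimate$v_d)
  # optimality: the returned point beats the prior mean itself
  f_obs <- pd_transform(visits$inr)
  obj_at <- function(th) warfinr:::map_objective(th, f_obs, visits$dose_mg,
                                                 visits$tau_h, 1, prior)
  expect_lte(fit$objective, obj_at(prior$mean))
  expect_equal(fit$objective, obj_at(est), tolerance = 1e-8)
  # shrinkage: estimates land between prior mean and truth for the
  # data-informed directions, and never outside the prior by much
  expect_true(all(est > 0))
})

test_that("estimates collapse to the prior mean as residual weight vanishes", {
  theta <- pk_parameters(6.5, 1.2, 2.4, 8.0)
  visits <- visits_from_targets(theta, c(2, 2.5, 3))
  prior <- population_prior(sigma_res = 1e6)
  fit <- fit_individual(visits, prior = prior)
  est <- c(fit$estimate$c_max, fit$estimate$k, fit$estimate$cl, fit$estimate$v_d)
  expect_equal(unname(est), unname(prior$mean), tolerance = 1e-3)
})

test_that("estimates respect positivity and report curvature diagnostics", {
  set.seed(17)
  theta <- rand_params()
  visits <- visits_from_targets(theta, runif(6, 2, 3))
  visits$inr <- visits$inr * exp(rnorm(6, 0, 0.05))
  fit <- fit_individual(visits)
  est <- unlist(fit$estimate[c("c_max", "k", "cl", "v_d")])
  expect_true(all(est > 0))
  expect_true(is.finite(fit$condition_number) && fit$condition_number >= 1)
  expect_identical(fit$n_visits, 6L)
})

test_that("implausible visits are screened before fitting", {
  theta <- pk_parameters(5.8, 1, 2.1, 7.6)
  good <- visits_from_targets(theta, c(2.2, 2.6, 2.9))
  bad <- tibble::tibble(t_days = c(200, 230), inr = c(12, 0.2),
                        dose_mg = c(8, 8), tau_h = 24)
  expect_message(fit <- fit_individual(dplyr::bind_rows(good, bad)),
                 "plausibility screen")
  expect_identical(fit$n_visits, 3L)
  all_bad <- tibble::tibble(t_days = 0, inr = 15, dose_mg = 8, tau_h = 24)
  expect_error(suppressMessages(fit_individual(all_bad)),
               class = "warfinr_no_visits")
})

test_that("last_n restricts fitting to the most recent visits", {
  theta <- pk_parameters(5.8, 1, 2.1, 7.6)
  visits <- visits_from_targets(theta, c(2, 2.2, 2.5, 2.8))
  fit <- fit_individual(visits, last_n = 2)
  expect_identical(fit$n_visits, 2L)
})

test_that("cohort fitting is order-invariant and matches individual fits", {
  set.seed(41)
  cohort <- simulate_cohort(cohort_config(n_patients = 4), seed = 41)
  fits <- fit_cohort(cohort$visits)
  shuffled <- cohort$visits[sample(nrow(cohort$visits)), ]
  fits_shuffled <- fit_cohort(shuffled)
  expect_equal(fits, fits_shuffled)

  one <- cohort$visits[cohort$visits$patient_id == fits$patient_id[1], ]
  single <- fit_individual(one)
  expect_equal(fits$c_max[1], single$estimate$c_max, tolerance = 1e-10)
  expect_equal(fits$objective[1], single$objective, tolerance = 1e-10)
})

test_that("per-patient failures are flagged rows, not batch aborts", {
  good <- simulate_cohort(cohort_config(n_patients = 2), seed = 5)$visits
  bad <- tibble::tibble(patient_id = "BAD", t_days = 0, inr = 15,
                        dose_mg = 8, tau_h = 24)
  fits <- suppressMessages(fit_cohort(dplyr::bind_rows(good, bad)))
  expect_identical(nrow(fits), 3L)
  expect_false(fits$converged[fits$patient_id == "BAD"])
  expect_true(all(fits$converged[fits$patient_id != "BAD"]))
})

test_that("tidy and glance expose broom-style views of a fit", {
  theta <- pk_parameters(5.8, 1, 2.1, 7.6)
  fit <- fit_individual(visits_from_targets(theta, c(2.2, 2.7)))
  td <- tidy(fit)
  expect_identical(td$term, c("c_max", "k", "cl", "v_d"))
  expect_identical(nrow(glance(fit)), 1L)
  expect_true(glance(fit)$converged)
})
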