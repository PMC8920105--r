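# Independent brute-force evaluators: literal transcriptions of the model's
# published algebra, kept deliberately separate from the package's refactored
# implementation so they can catch transcription errors in it.

inr_direct <- function(c_max, k, cl, v_d, m, dose, tau) {
  ((1 / (-(m * cl / v_d) / (k^2) * (1 - (k * tau / 24) / (1 - exp(-k * tau / 24))) -
           (m / k) * log((dose / v_d) / (c_max * (1 - exp(-(cl / v_d) * (tau / 24)))))) +
      3.36) / 4.368)^(1 / 0.383)
}

dose_direct <- function(c_max, k, cl, v_d, m, inr, tau) {
  exp((1 + ((m * cl / v_d) / k^2) * (1 - (k * tau / 24) / (1 - exp(-k * tau / 24))) *
         (4.368 * inr^(0.383) - 3.36)) /
        ((-m / k) * (4.368 * inr^(0.383) - 3.36))) *
    c_max * (1 - exp((-cl / v_d) * tau / 24)) * v_d
}

# Random plausible individual parameters, spanning about +/- 3 population SDs.
rand_params <- function() {
  pk_parameters(
    c_max = runif(1, 4.6, 7.0),
    k = runif(1, 0.7, 1.3),
    cl = runif(1, 1.5, 2.7),
    v_d = runif(1, 7.0, 8.2)
  )
}

# Model-exact noise-free visit table for one patient.
visits_from_targets <- function(theta, targets, gap = 30) {
  doses <- dose_for_target_inr(theta, targets)
  tibble::tibble(
    t_days = gap * (seq_along(targets) - 1),
    inr = steady_state_inr(theta, doses),
    dose_mg = doses,
    tau_h = 24
  )
}

prior_at <- function(theta, sds = c(0.4, 0.1, 0.2, 0.2), sigma_res = 0.1) {
  population_prior(c_max = c(theta$c_max, sds[1]), k = c(theta$k, sds[2]),
                   cl = c(theta$cl, sds[3]), v_d = c(theta$v_d, sds[4]),
                   sigma_res = sigma_res)
}
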