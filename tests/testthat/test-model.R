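mean_theta <- pk_parameters(c_max = 5.8, k = 1, cl = 2.1, v_d = 7.6)

test_that("PD transform matches its closed form and inverts exactly", {
  expect_equal(pd_transform(1), 4.368 - 3.36, tolerance = 1e-12)
  root <- (3.36 / 4.368)^(1 / 0.383)
  expect_equal(pd_transform(root), 0, tolerance = 1e-12)
  expect_equal(pd_inverse(0), root, tolerance = 1e-12)
  expect_equal(pd_inverse(1.008), 1, tolerance = 1e-10)
  for (x in c(1.5, 2.5, 3.5)) {
    expect_equal(pd_inverse(pd_transform(x)), x, tolerance = 1e-10)
  }
  set.seed(4)
  f <- runif(25, -3, 10)
  expect_equal(pd_transform(pd_inverse(f)), f, tolerance = 1e-8)
  inr <- seq(0.6, 5, by = 0.1)
  expect_true(all(diff(pd_transform(inr)) > 0))
  expect_error(pd_transform(0), class = "warfinr_domain_error")
  expect_error(pd_inverse(-3.36), class = "warfinr_domain_error")
})

test_that("dose equation is the exact algebraic inverse of the INR equation", {
  for (target in c(2.0, 2.5, 3.0)) {
    d <- dose_for_target_inr(mean_theta, target)
    expect_equal(steady_state_inr(mean_theta, d), target, tolerance = 1e-10)
  }
  set.seed(11)
  for (i in 1:50) {
    th <- rand_params()
    target <- runif(1, 1.5, 3.5)
    tau <- sample(c(12, 24, 48), 1)
    d <- dose_for_target_inr(th, target, tau = tau)
    expect_equal(steady_state_inr(th, d, tau = tau), target, tolerance = 1e-8)
  }
})

test_that("refactored equations agree with a literal transcription oracle", {
  set.seed(7)
  for (i in 1:100) {
    th <- rand_params()
    target <- runif(1, 1.3, 4)
    tau <- runif(1, 12, 48)
    d_oracle <- dose_direct(th$c_max, th$k, th$cl, th$v_d, th$m, target, tau)
    expect_equal(dose_for_target_inr(th, target, tau = tau), d_oracle,
                 tolerance = 1e-12)
    expect_equal(steady_state_inr(th, d_oracle, tau = tau),
                 inr_direct(th$c_max, th$k, th$cl, th$v_d, th$m, d_oracle, tau),
                 tolerance = 1e-12)
  }
})

test_that("INR is strictly increasing in dose and dose in target INR", {
  doses <- seq(2, 12, by = 0.25)
  inr <- steady_state_inr(mean_theta, doses)
  expect_true(all(diff(inr) > 0))
  targets <- seq(0.6, 5, by = 0.1)
  d <- dose_for_target_inr(mean_theta, targets)
  expect_true(all(diff(d) > 0))
  set.seed(23)
  for (i in 1:10) {
    th <- rand_params()
    expect_true(all(diff(steady_state_inr(th, seq(3, 6, by = 0.25))) > 0))
  }
})

test_that("changing the dosing interval re-evaluates the printed expression", {
  d <- 6
  expect_equal(steady_state_inr(mean_theta, d, tau = 48),
               inr_direct(5.8, 1, 2.1, 7.6, 1, d, 48), tolerance = 1e-12)
  expect_equal(steady_state_inr(mean_theta, d, tau = 12),
               inr_direct(5.8, 1, 2.1, 7.6, 1, d, 12), tolerance = 1e-12)
})

test_that("dose scales with V_d as the closed form dictates", {
  target <- 2.5
  base <- dose_for_target_inr(mean_theta, target)
  h <- 1e-5
  th_up <- pk_parameters(5.8, 1, 2.1, 7.6 + h)
  num_grad <- (dose_for_target_inr(th_up, target) - base) / h
  oracle_grad <- (dose_direct(5.8, 1, 2.1, 7.6 + h, 1, target, 24) -
                    dose_direct(5.8, 1, 2.1, 7.6, 1, target, 24)) / h
  expect_equal(num_grad, oracle_grad, tolerance = 1e-8)
})

test_that("the concentration-labelled equation is the INR equation", {
  set.seed(3)
  for (i in 1:10) {
    th <- rand_params()
    d <- dose_for_target_inr(th, runif(1, 1.8, 3.2))
    expect_identical(steady_state_cs(th, d), steady_state_inr(th, d))
  }
  expect_gt(steady_state_cs(mean_theta, 8), 0)
  expect_error(steady_state_cs(mean_theta, 14), class = "warfinr_domain_error")
})

test_that("domain violations raise term-tagged errors", {
  err <- tryCatch(steady_state_inr(mean_theta, 14), error = identity)
  expect_s3_class(err, "warfinr_domain_error")
  expect_true(!is.null(err$term))
  expect_error(steady_state_inr(mean_theta, -1), class = "warfinr_domain_error")
  expect_error(steady_state_inr(mean_theta, 8, tau = 0), class = "warfinr_domain_error")
  root <- (3.36 / 4.368)^(1 / 0.383)
  expect_error(dose_for_target_inr(mean_theta, root), class = "warfinr_singular_target")
  expect_error(pk_parameters(-1, 1, 1, 1), class = "warfinr_invalid_parameters")
})
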