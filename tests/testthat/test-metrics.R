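visits_tbl <- function(t, inr, dose = 5) {
  tibble::tibble(t_days = t, inr = inr, dose_mg = dose, tau_h = 24)
}

test_that("WSI is the last-visit INR per mg of the last dose", {
  expect_equal(wsi(visits_tbl(c(0, 30), c(2.0, 3.0), c(5, 10))), 0.3)
  expect_equal(wsi(visits_tbl(c(0, 30), c(2.0, 2.5), c(10, 5))), 0.5)
  # unordered input still uses the chronologically last visit
  expect_equal(wsi(visits_tbl(c(30, 0), c(3.0, 2.0), c(10, 5))), 0.3)
  expect_error(wsi(visits_tbl(0, 2.5, 0)), class = "warfinr_domain_error")
})

test_that("Rosendaal TTR interpolates linearly between visits", {
  expect_equal(ttr_rosendaal(visits_tbl(c(0, 30), c(2.5, 2.5))), 100)
  # crosses the lower bound exactly halfway
  expect_equal(ttr_rosendaal(visits_tbl(c(0, 10), c(1.5, 2.5))), 50)
  expect_equal(ttr_rosendaal(visits_tbl(c(0, 10), c(1.0, 1.5))), 0)
  # crossing both bounds: 1.0 -> 4.0 over 30 days is in [2,3] for 10 days
  expect_equal(ttr_rosendaal(visits_tbl(c(0, 30), c(1.0, 4.0))), 100 / 3)
  expect_error(ttr_rosendaal(visits_tbl(c(5, 5), c(2, 3))),
               class = "warfinr_undefined_ttr")
})

test_that("TTR is invariant to inserting a collinear visit", {
  base <- visits_tbl(c(0, 20), c(1.8, 3.2))
  with_mid <- visits_tbl(c(0, 10, 20), c(1.8, 2.5, 3.2))
  expect_equal(ttr_rosendaal(base), ttr_rosendaal(with_mid), tolerance = 1e-12)
})

test_that("gaps beyond the monitoring limit drop out of the denominator", {
  v <- visits_tbl(c(0, 10, 100), c(2.5, 2.5, 1.0))
  # the 90-day gap is unmonitored; only the first 10 in-range days count
  expect_equal(ttr_rosendaal(v), 100)
  expect_equal(ttr_rosendaal(v, max_gap = 120), 100 * (10 + 30) / 100)
  expect_error(ttr_rosendaal(visits_tbl(c(0, 100), c(2, 3))),
               class = "warfinr_undefined_ttr")
})

test_that("INR variability matches its hand-computed single-pair value", {
  res <- inr_variability(visits_tbl(c(0, 5), c(2, 3)))
  expect_equal(res$sigma, sqrt((1 / 5) * 2.5), tolerance = 1e-12)
  expect_equal(res$log_inr_var, log10(sqrt(0.5)), tolerance = 1e-12)
  expect_false(res$zero_variability)
})

test_that("constant INR yields the flagged zero-variability sentinel", {
  res <- inr_variability(visits_tbl(c(0, 10, 20), c(2.5, 2.5, 2.5)))
  expect_equal(res$sigma, 0)
  expect_identical(res$log_inr_var, -Inf)
  expect_true(res$zero_variability)
})

test_that("variability obeys its time-scaling law and ignores time origin", {
  v <- visits_tbl(c(0, 4, 10, 17), c(2.1, 2.9, 2.4, 3.1))
  base <- inr_variability(v)$sigma
  doubled <- inr_variability(visits_tbl(c(0, 8, 20, 34), c(2.1, 2.9, 2.4, 3.1)))$sigma
  expect_equal(doubled, base / sqrt(2), tolerance = 1e-12)
  shifted <- inr_variability(visits_tbl(c(0, 4, 10, 17) + 365, c(2.1, 2.9, 2.4, 3.1)))$sigma
  expect_equal(shifted, base, tolerance = 1e-12)
  expect_error(inr_variability(visits_tbl(c(0, 0, 5), c(2, 2.5, 3))),
               class = "warfinr_domain_error")
})

test_that("WCM standardises to cohort mean zero with the stated convention", {
  ttr <- c(50, 60, 70)
  logvar <- c(-0.6, -0.8, -1.0)
  w <- wcm(ttr, logvar)
  # patient 1: 1 SD below mean TTR and 1 SD above mean log-variability
  expect_equal(w[1], 2)
  expect_equal(mean(w), 0, tolerance = 1e-12)
  expect_equal(wcm(ttr, logvar, convention = "higher_better"), -w)
  # affine rescaling of either input changes nothing
  expect_equal(wcm(ttr / 100, logvar), w, tolerance = 1e-12)
  expect_equal(wcm(ttr, 10 * logvar + 3), w, tolerance = 1e-12)
  expect_error(wcm(c(60, 60, 60), logvar), class = "warfinr_domain_error")
})

test_that("liver weight follows the anthropometric formula exactly", {
  expect_equal(liver_weight(70, "M"), 1130)
  expect_equal(liver_weight(75.2, "F"), 1142.96)
  expect_equal(liver_weight(80, "M") - liver_weight(80, "F"), 51)
  # slope recovered by finite difference
  expect_equal((liver_weight(61, "F") - liver_weight(60, "F")), 12.3)
  expect_equal(liver_weight(70, 1), 1130)
  expect_error(liver_weight(-1, "M"), class = "warfinr_domain_error")
  expect_error(liver_weight(70, "X"), class = "warfinr_schema_error")
})

test_that("the index panel assembles per patient with the NICE boundary at 65", {
  # P1: 60 in-range days, then 2.5 -> 6.5 over 40 days crosses 3.0 after
  # 5 days, so TTR = (60 + 5) / 100 = 65 exactly (all gaps within 56 days)
  visits <- dplyr::bind_rows(
    dplyr::mutate(visits_tbl(c(0, 30, 60, 100), c(2.5, 2.5, 2.5, 6.5)), patient_id = "P1"),
    dplyr::mutate(visits_tbl(c(0, 40, 80), c(1.2, 1.4, 1.3), dose = 8), patient_id = "P2"))
  demo <- tibble::tibble(patient_id = c("P1", "P2"), age_years = c(70, 60),
                         sex = c("M", "F"), body_weight_kg = c(70, 75.2),
                         interacting_drug = c(1, 0))
  idx <- anticoag_indices(visits, demo)
  p1 <- idx[idx$patient_id == "P1", ]
  expect_equal(p1$ttr, 65)                # boundary value ...
  expect_identical(p1$ttr_class, "good")  # ... classifies as good
  expect_identical(idx$ttr_class[idx$patient_id == "P2"], "poor")
  expect_equal(p1$liver_weight, 1130)
  expect_equal(mean(idx$wcm), 0, tolerance = 1e-12)
  expect_equal(p1$wsi, 6.5 / 5)
})

test_that("zero-variability patients are excluded from WCM with a warning", {
  visits <- dplyr::bind_rows(
    dplyr::mutate(visits_tbl(c(0, 30, 60), c(2.5, 2.5, 2.5)), patient_id = "Z1"),
    dplyr::mutate(visits_tbl(c(0, 30, 60), c(2.0, 2.8, 2.2)), patient_id = "Z2"),
    dplyr::mutate(visits_tbl(c(0, 30, 60), c(2.4, 1.0, 2.9)), patient_id = "Z3"))
  demo <- tibble::tibble(patient_id = c("Z1", "Z2", "Z3"),
                         age_years = c(60, 65, 70), sex = c("M", "F", "M"),
                         body_weight_kg = c(70, 80, 90),
                         interacting_drug = c(0, 1, 0))
  expect_warning(idx <- anticoag_indices(visits, demo), "zero INR variability")
  expect_true(is.na(idx$wcm[idx$patient_id == "Z1"]))
  expect_identical(idx$log_inr_var[idx$patient_id == "Z1"], -Inf)
  expect_true(all(is.finite(idx$wcm[idx$patient_id != "Z1"])))
})
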