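#' Pharmacodynamic transform constants
#'
#' The warfarin steady-state model maps PT-INR to a transformed
#' pharmacodynamic response through a power law,
#' \deqn{f(\mathrm{INR}) = b \cdot \mathrm{INR}^{p} - a,}
#' with the fixed constants of the validated inbuilt model:
#' `a = 3.36`, `b = 4.368`, `p = 0.383`. These are the calibrated values of
#' the model this package implements; overriding them changes the meaning of
#' every downstream quantity and is reported loudly.
#'
#' @param a Offset of the transform (dimensionless). Default 3.36.
#' @param b Scale of the transform (dimensionless, positive). Default 4.368.
#' @param p Power exponent, in (0, 1). Default 0.383.
#'
#' @return An object of class `pd_constants`: a named list with elements
#'   `a`, `b`, `p`.
#' @export
#'
#' @examples
#' pd_constants()
pd_constants <- function(a = 3.36, b = 4.368, p = 0.383) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(p),
            length(a) == 1, length(b) == 1, length(p) == 1)
  if (b <= 0) abort("`b` must be positive.", class = "warfinr_invalid_constants")
  if (p <= 0 || p >= 1) {
    abort("`p` must lie in (0, 1).", class = "warfinr_invalid_constants")
  }
  if (a != 3.36 || b != 4.368 || p != 0.383) {
    inform(sprintf(
      "Non-default PD constants in use (a = %g, b = %g, p = %g); results are no longer on the calibrated model scale.",
      a, b, p))
  }
  structure(list(a = a, b = b, p = p), class = "pd_constants")
}

#' Individual warfarin pharmacokinetic parameters
#'
#' Container for the individual quadruple the steady-state model is written
#' in, plus the pharmacodynamic slope constant `m` shared by the forward and
#' inverse equations.
#'
#' @param c_max Maximum plasma concentration at steady state, mg/L.
#' @param k First-order elimination rate constant, 1/day.
#' @param cl Total clearance, L/day.
#' @param v_d Apparent volume of distribution, L.
#' @param m Pharmacodynamic slope constant (dimensionless). The model is
#'   stated in terms of `m` but no calibrated value accompanies it; any
#'   positive `m` shared between simulation and estimation preserves all
#'   round-trip identities. Default 1.
#'
#' @return An object of class `pk_parameters` (named list).
#' @export
#'
#' @examples
#' pk_parameters(c_max = 5.8, k = 1, cl = 2.1, v_d = 7.6)
pk_parameters <- function(c_max, k, cl, v_d, m = 1) {
  vals <- c(c_max = c_max, k = k, cl = cl, v_d = v_d, m = m)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    abort("All of c_max, k, cl, v_d and m must be finite and strictly positive.",
          class = "warfinr_invalid_parameters")
  }
  structure(as.list(vals), class = "pk_parameters")
}

as_pk_parameters <- function(x) {
  if (inherits(x, "pk_parameters")) return(x)
  x <- as.list(x)
  if (!all(c("c_max", "k", "cl", "v_d") %in% names(x))) {
    abort("Parameters must supply c_max, k, cl and v_d.",
          class = "warfinr_invalid_parameters")
  }
  pk_parameters(x$c_max, x$k, x$cl, x$v_d, m = x$m %||% 1)
}

#' @export
print.pk_parameters <- function(x, ...) {
  cat("<pk_parameters>\n")
  cat(sprintf("  C_max %.4g mg/L | k %.4g /day | CL %.4g L/day | V_d %.4g L | m %.4g\n",
              x$c_max, x$k, x$cl, x$v_d, x$m))
  invisible(x)
}

domain_abort <- function(term, message) {
  abort(message, class = "warfinr_domain_error", term = term)
}

#' Forward pharmacodynamic transform of PT-INR
#'
#' Computes `f(INR) = b * INR^p - a`, the transformed response scale on which
#' the steady-state model (and the MAP residuals) are linear in the log dose.
#' Strictly increasing in INR; its root sits at `(a/b)^(1/p)` (about INR
#' 0.50 at the default constants).
#'
#' @param inr PT-INR value(s), dimensionless, strictly positive.
#' @param consts [pd_constants()].
#'
#' @return Numeric vector of transformed responses.
#' @seealso [pd_inverse()]
#' @export
#'
#' @examples
#' pd_transform(1)     # 4.368 - 3.36 = 1.008
#' pd_transform(2.5)
pd_transform <- function(inr, consts = pd_constants()) {
  if (!is.numeric(inr) || any(!is.finite(inr)) || any(inr <= 0)) {
    domain_abort("inr", "PT-INR must be finite and strictly positive.")
  }
  consts$b * inr^consts$p - consts$a
}

#' Inverse pharmacodynamic transform
#'
#' Inverts [pd_transform()]: `INR = ((f + a) / b)^(1/p)`. Defined for
#' `f > -a`.
#'
#' @param f Transformed response value(s).
#' @param consts [pd_constants()].
#'
#' @return PT-INR value(s).
#' @export
#'
#' @examples
#' pd_inverse(1.008)   # 1
pd_inverse <- function(f, consts = pd_constants()) {
  if (!is.numeric(f) || any(!is.finite(f)) || any(f <= -consts$a)) {
    domain_abort("transform-offset",
                 sprintf("Transformed response must exceed -a = %g.", -consts$a))
  }
  ((f + consts$a) / consts$b)^(1 / consts$p)
}

# Transformed steady-state response f for given parameters, dose (mg) and
# dosing interval tau (hours). Quiet variant: returns NA outside the model
# domain instead of raising, for use inside the MAP objective.
ss_transformed <- function(params, dose, tau, quiet = FALSE) {
  with(params, {
    x <- k * tau / 24
    shape <- 1 - x / (1 - exp(-x))
    amp <- (m * cl / v_d) / k^2
    accum <- 1 - exp(-(cl / v_d) * tau / 24)
    log_arg <- (dose / v_d) / (c_max * accum)
    if (any(log_arg <= 0)) {
      if (quiet) return(rep(NA_real_, length(dose)))
      domain_abort("log-argument",
                   "Dose / (V_d * C_max * accumulation) must be positive: the log argument of the steady-state equation is not.")
    }
    denom <- -amp * shape - (m / k) * log(log_arg)
    f <- ifelse(denom == 0, NA_real_, 1 / denom)
    if (any(!is.finite(f))) {
      if (quiet) return(ifelse(is.finite(f), f, NA_real_))
      domain_abort("reciprocal",
                   "The steady-state expression 1/f has a zero reciprocal at this dose; the predicted response is unbounded.")
    }
    f
  })
}

#' Predicted steady-state PT-INR for a maintenance regimen
#'
#' The forward steady-state model: with transformed response
#' \eqn{f} defined by
#' \deqn{1/f = -\frac{m\,CL/V_d}{k^2}\Big(1 - \frac{k\tau/24}{1 - e^{-k\tau/24}}\Big)
#'   - \frac{m}{k}\,\ln\frac{D/V_d}{C_{max}\,(1 - e^{-(CL/V_d)\,\tau/24})},}
#' the predicted INR is `pd_inverse(f)`. Times are in days (`tau/24`
#' converts the dosing interval from hours), matching the per-day units of
#' `k` and `cl`.
#'
#' @param params [pk_parameters()] (or a named list coercible to one).
#' @param dose Maintenance dose per administration, mg. May be a vector.
#' @param tau Dosing interval, hours. Default 24 (once-daily warfarin).
#' @param consts [pd_constants()].
#'
#' @return Predicted PT-INR (vectorised over `dose`/`tau`).
#' @seealso [dose_for_target_inr()] for the exact algebraic inverse,
#'   [steady_state_cs()] for the concentration-labelled alias.
#' @export
#'
#' @examples
#' theta <- pk_parameters(c_max = 5.8, k = 1, cl = 2.1, v_d = 7.6)
#' steady_state_inr(theta, dose = 8.8)
steady_state_inr <- function(params, dose, tau = 24, consts = pd_constants()) {
  params <- as_pk_parameters(params)
  if (any(!is.finite(dose)) || any(dose <= 0)) {
    domain_abort("dose", "Dose must be finite and strictly positive.")
  }
  if (any(!is.finite(tau)) || any(tau <= 0)) {
    domain_abort("tau", "Dosing interval tau must be finite and strictly positive.")
  }
  f <- ss_transformed(params, dose, tau)
  pd_inverse(f, consts)
}

#' Steady-state response, concentration-labelled form
#'
#' The source model states its concentration equation with exactly the same
#' right-hand side as its INR equation (an apparent typesetting duplication
#' in the model's published form). This function is therefore a documented
#' alias of [steady_state_inr()] and returns the identical value; no separate
#' concentration formula is invented.
#'
#' @inheritParams steady_state_inr
#' @return Identical to `steady_state_inr(params, dose, tau, consts)`.
#' @export
steady_state_cs <- function(params, dose, tau = 24, consts = pd_constants()) {
  steady_state_inr(params, dose, tau, consts)
}

#' Maintenance dose achieving a target steady-state INR
#'
#' Closed-form algebraic inverse of [steady_state_inr()]:
#' \deqn{D = \exp\!\Big(\frac{1 + A S f}{(-m/k) f}\Big)\,
#'   C_{max}\,(1 - e^{-(CL/V_d)\tau/24})\,V_d,}
#' where `f = pd_transform(target_inr)`, `A = (m CL/V_d)/k^2` and
#' `S = 1 - (k tau/24)/(1 - exp(-k tau/24))`. Undefined at the transform root
#' `target_inr = (a/b)^(1/p)` (about 0.50), far below any therapeutic target.
#'
#' @param params [pk_parameters()].
#' @param target_inr Desired steady-state PT-INR (vectorised).
#' @param tau Dosing interval, hours. Default 24.
#' @param consts [pd_constants()].
#'
#' @return Dose in mg per administration.
#' @export
#'
#' @examples
#' theta <- pk_parameters(c_max = 5.8, k = 1, cl = 2.1, v_d = 7.6)
#' d <- dose_for_target_inr(theta, 2.5)
#' steady_state_inr(theta, d)  # 2.5
dose_for_target_inr <- function(params, target_inr, tau = 24,
                                consts = pd_constants()) {
  params <- as_pk_parameters(params)
  f <- pd_transform(target_inr, consts)
  if (any(abs(f) < 1e-12)) {
    abort(sprintf(
      "Target INR %.6g is the root of the PD transform; the dose equation is singular there.",
      (consts$a / consts$b)^(1 / consts$p)),
      class = "warfinr_singular_target")
  }
  if (any(!is.finite(tau)) || any(tau <= 0)) {
    domain_abort("tau", "Dosing interval tau must be finite and strictly positive.")
  }
  with(params, {
    x <- k * tau / 24
    shape <- 1 - x / (1 - exp(-x))
    amp <- (m * cl / v_d) / k^2
    accum <- 1 - exp(-(cl / v_d) * tau / 24)
    exp((1 + amp * shape * f) / ((-m / k) * f)) * c_max * accum * v_d
  })
}
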