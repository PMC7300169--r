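#' Fit a mono-exponential function to activity samples
#'
#' Fits `f(t) = A1 * exp(-(lambda1 + lambda_phys) * t)` to measured
#' activities, with the physical decay constant fixed. With two samples the
#' fit is the exact interpolant; with three or more, ordinary least squares
#' on log-activity versus time is used by default (the maximum-likelihood
#' fit under multiplicative log-normal noise). `space = "linear"` instead
#' minimizes squared residuals on the activity scale via [stats::nls()].
#'
#' If the fitted slope would imply a negative biological clearance rate
#' (activity growing beyond physical decay, which makes the TIAC integral
#' unstable or divergent), `lambda1` is clamped to 0, the amplitude is
#' re-estimated with the slope fixed at `-lambda_phys`, and the fit is
#' flagged `clamped`.
#'
#' @param times Sample times (h p.i.), distinct, length >= 2.
#' @param activities Measured activities (MBq), positive.
#' @param lambda_phys Physical decay constant (1/h).
#' @param space `"log"` (default) or `"linear"` fitting scale.
#' @return A list of class `monoexp_fit` with elements `A1`, `lambda1`,
#'   `lambda_phys`, `n_points`, `clamped`.
#' @export
#' @examples
#' fit <- fit_monoexp(c(20, 192), 100 * exp(-0.01 * c(20, 192)))
#' fit$A1            # 100
#' fit$lambda1       # 0.01 - lu177_lambda_phys()
fit_monoexp <- function(times, activities,
                        lambda_phys = lu177_lambda_phys(),
                        space = c("log", "linear")) {
  space <- match.arg(space)
  if (!is.numeric(times) || !is.numeric(activities) ||
      length(times) != length(activities)) {
    stop("'times' and 'activities' must be numeric vectors of equal length",
         call. = FALSE)
  }
  if (length(times) < 2L) {
    stop("at least 2 samples are required for a mono-exponential fit",
         call. = FALSE)
  }
  if (anyDuplicated(times)) stop("sample times must be distinct",
                                 call. = FALSE)
  if (any(!is.finite(activities)) || any(activities <= 0)) {
    stop("activities must be positive and finite", call. = FALSE)
  }
  y <- log(activities)
  tbar <- mean(times)
  slope <- sum((times - tbar) * (y - mean(y))) / sum((times - tbar)^2)
  lambda1 <- -slope - lambda_phys
  clamped <- FALSE
  if (lambda1 < 0) {
    lambda1 <- 0
    clamped <- TRUE
  }
  if (space == "log" || clamped || length(times) == 2L) {
    intercept <- mean(y) + (lambda1 + lambda_phys) * tbar
    A1 <- exp(intercept)
    if (clamped && space == "linear") {
      ## fixed slope -lambda_phys: closed-form linear LS amplitude
      g <- exp(-lambda_phys * times)
      A1 <- sum(activities * g) / sum(g^2)
    }
  } else {
    start_A1 <- exp(mean(y) + (lambda1 + lambda_phys) * tbar)
    resid0 <- activities - start_A1 * exp(-(lambda1 + lambda_phys) * times)
    if (max(abs(resid0)) <= 1e-10 * max(activities)) {
      ## log-space start already interpolates (noiseless data): nls would
      ## only warn about zero residuals
      A1 <- start_A1
    } else {
      fit <- stats::nls(activities ~ A1 * exp(-(l1 + lambda_phys) * times),
                        start = list(A1 = start_A1, l1 = lambda1),
                        control = stats::nls.control(warnOnly = TRUE))
      cf <- stats::coef(fit)
      A1 <- unname(cf["A1"])
      lambda1 <- unname(cf["l1"])
    }
    if (lambda1 < 0) {
      lambda1 <- 0
      clamped <- TRUE
      g <- exp(-lambda_phys * times)
      A1 <- sum(activities * g) / sum(g^2)
    }
  }
  structure(list(A1 = A1, lambda1 = lambda1, lambda_phys = lambda_phys,
                 n_points = length(times), clamped = clamped),
            class = "monoexp_fit")
}

#' Evaluate a fitted mono-exponential curve
#'
#' @param fit A `monoexp_fit`.
#' @param t Times (h), vectorized.
#' @return Fitted activity `A1 * exp(-(lambda1 + lambda_phys) * t)`.
#' @export
predict_monoexp <- function(fit, t) {
  stopifnot(inherits(fit, "monoexp_fit"))
  fit$A1 * exp(-(fit$lambda1 + fit$lambda_phys) * t)
}

#' TIAC from the planar fit alone
#'
#' Analytical integral of the fitted mono-exponential from zero to infinity,
#' normalized by the injected activity:
#' `TIAC = A1 / (A0 * (lambda1 + lambda_phys))`.
#'
#' @param fit A `monoexp_fit`.
#' @param A0 Injected activity (MBq).
#' @return TIAC estimate in hours.
#' @export
tiac_planar <- function(fit, A0) {
  stopifnot(inherits(fit, "monoexp_fit"))
  .assert_scalar_num(A0, "A0", positive = TRUE)
  leff <- fit$lambda1 + fit$lambda_phys
  if (leff <= 0) stop("non-positive effective decay rate: TIAC diverges",
                      call. = FALSE)
  fit$A1 / (A0 * leff)
}

#' TIAC with the hybrid planar/SPECT method
#'
#' Rescales the planar TIAC by the ratio of the quantitative SPECT/CT
#' activity to the fitted planar curve at the SPECT time:
#' `TIAC_hybrid = A_spect / f_planar(t_spect) * TIAC_planar`. A systematic
#' multiplicative planar error scales `A1` but not `lambda1`, so it cancels
#' exactly in the ratio.
#'
#' @param fit A `monoexp_fit` of the planar samples.
#' @param t_spect SPECT/CT measurement time (h).
#' @param a_spect Quantitative SPECT/CT activity (MBq).
#' @param A0 Injected activity (MBq).
#' @return TIAC estimate in hours.
#' @export
tiac_hybrid <- function(fit, t_spect, a_spect, A0) {
  .assert_scalar_num(t_spect, "t_spect", positive = TRUE)
  .assert_scalar_num(a_spect, "a_spect", positive = TRUE)
  f <- predict_monoexp(fit, t_spect)
  if (f <= 0) stop("fitted planar curve is zero at t_spect", call. = FALSE)
  (a_spect / f) * tiac_planar(fit, A0)
}

#' TIAC from a single quantitative measurement
#'
#' The Hanscheid single-time-point approximation
#' `TIAC = (2 / log(2)) * A_spect * t_ref / A0`. It is exact when the true
#' curve is mono-exponential and `t_ref` equals the effective half-life; for
#' a mono-exponential truth the estimate/truth ratio is the closed form
#' `2 * log(2) * (t_ref / T_eff) * 2^(-t_ref / T_eff)`.
#'
#' @param t_ref Measurement time (h), positive.
#' @param a_spect Quantitative SPECT/CT activity (MBq), positive.
#' @param A0 Injected activity (MBq).
#' @return TIAC estimate in hours.
#' @export
#' @examples
#' ## exact at t_ref = T_eff for a mono-exponential curve
#' tiac_single_tp(52, 0.5, 1)  # = 52 / log(2)
tiac_single_tp <- function(t_ref, a_spect, A0) {
  .assert_scalar_num(t_ref, "t_ref", positive = TRUE)
  .assert_scalar_num(a_spect, "a_spect", positive = TRUE)
  .assert_scalar_num(A0, "A0", positive = TRUE)
  (2 / log(2)) * a_spect * t_ref / A0
}
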