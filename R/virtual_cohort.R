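#' Region kinetics: ground-truth time-activity curve parameters
#'
#' The ground-truth time-activity curve of a source region (kidney or
#' tumour lesion) is a two-exponential uptake/washout curve scaled by
#' physical decay:
#'
#' \deqn{A(t) = C (e^{-(\lambda_{bio}+\lambda_{phys}) t} -
#'              e^{-(\lambda_{up}+\lambda_{phys}) t})}
#'
#' with biological clearance rate `lambda_bio`, uptake rate `lambda_up`
#' (`lambda_up > lambda_bio`, possibly `Inf` for instantaneous uptake, i.e.
#' a pure mono-exponential washout) and the fixed 177Lu physical decay
#' constant `lambda_phys`. The curve starts at zero, peaks at
#' `t_max = log(lu/lb)/(lu - lb)` in terms of the effective rates
#' `lb = lambda_bio + lambda_phys`, `lu = lambda_up + lambda_phys`, and
#' decays mono-exponentially with effective half-life
#' `log(2)/(lambda_bio + lambda_phys)` thereafter.
#'
#' @param C Amplitude (MBq), positive.
#' @param lambda_bio Biological clearance rate (1/h), non-negative.
#' @param lambda_up Uptake rate (1/h), greater than `lambda_bio`; may be
#'   `Inf` for a pure mono-exponential curve.
#' @param lambda_phys Physical decay constant (1/h); defaults to the 177Lu
#'   value [lu177_lambda_phys()].
#' @return A list of class `region_kinetics`.
#' @export
region_kinetics <- function(C, lambda_bio, lambda_up = Inf,
                            lambda_phys = lu177_lambda_phys()) {
  .assert_scalar_num(C, "C", positive = TRUE)
  .assert_scalar_num(lambda_bio, "lambda_bio")
  .assert_scalar_num(lambda_phys, "lambda_phys", positive = TRUE)
  if (lambda_bio < 0) stop("'lambda_bio' must be >= 0", call. = FALSE)
  if (!is.numeric(lambda_up) || length(lambda_up) != 1L ||
      is.na(lambda_up) || lambda_up <= lambda_bio) {
    stop("'lambda_up' must exceed 'lambda_bio' (Inf allowed)",
         call. = FALSE)
  }
  structure(list(C = C, lambda_bio = lambda_bio, lambda_up = lambda_up,
                 lambda_phys = lambda_phys),
            class = "region_kinetics")
}

#' True region activity at time t
#'
#' Evaluates the ground-truth time-activity curve (see
#' [region_kinetics()]). Vectorized over `t`.
#'
#' @param k A `region_kinetics` object.
#' @param t Time(s) post injection in hours, non-negative.
#' @return Activity in MBq; zero at `t = 0`, tending to zero as `t -> Inf`.
#' @export
true_activity <- function(k, t) {
  stopifnot(inherits(k, "region_kinetics"))
  if (!is.numeric(t) || anyNA(t) || any(t < 0)) {
    stop("'t' must be non-negative hours", call. = FALSE)
  }
  lb <- k$lambda_bio + k$lambda_phys
  lu <- k$lambda_up + k$lambda_phys
  up <- if (is.infinite(lu)) ifelse(t > 0, 0, 1) else exp(-lu * t)
  pmax(k$C * (exp(-lb * t) - up), 0)
}

#' Time of maximum of the ground-truth curve
#'
#' @param k A `region_kinetics` object.
#' @return Time of the curve maximum in hours (0 for instantaneous uptake).
#' @export
time_of_max <- function(k) {
  stopifnot(inherits(k, "region_kinetics"))
  lb <- k$lambda_bio + k$lambda_phys
  lu <- k$lambda_up + k$lambda_phys
  if (is.infinite(lu)) return(0)
  log(lu / lb) / (lu - lb)
}

#' True time-integrated activity coefficient
#'
#' Analytical integral of the ground-truth curve from zero to infinity,
#' normalized by the injected activity:
#' \deqn{TIAC = \frac{C}{A_0}\left(\frac{1}{\lambda_{bio}+\lambda_{phys}} -
#'       \frac{1}{\lambda_{up}+\lambda_{phys}}\right)}
#'
#' @param k A `region_kinetics` object.
#' @param A0 Injected activity (MBq), positive.
#' @return TIAC in hours.
#' @export
true_tiac <- function(k, A0) {
  stopifnot(inherits(k, "region_kinetics"))
  .assert_scalar_num(A0, "A0", positive = TRUE)
  lb <- k$lambda_bio + k$lambda_phys
  lu <- k$lambda_up + k$lambda_phys
  if (lb <= 0) stop("non-integrable kinetics: effective decay <= 0",
                    call. = FALSE)
  up <- if (is.infinite(lu)) 0 else 1 / lu
  (k$C / A0) * (1 / lb - up)
}

#' Effective half-life of the washout phase
#'
#' `log(2) / (lambda_bio + lambda_phys)`, the half-life governing the
#' mono-exponential washout beyond the uptake phase.
#'
#' @param k A `region_kinetics` object.
#' @return Effective half-life in hours.
#' @export
effective_half_life <- function(k) {
  stopifnot(inherits(k, "region_kinetics"))
  log(2) / (k$lambda_bio + k$lambda_phys)
}

#' Cohort configuration
#'
#' Distributional assumptions for the virtual-patient generator. Defaults
#' emulate the kinetic statistics of a 13-patient 177Lu-PSMA cohort:
#' effective half-lives with median 40 h (range 30-62 h) for the kidneys
#' and 50 h (range 34-94 h) for the tumour lesions (triangular
#' distributions with mode at the median), kidney curve maxima between
#' 0.6 h and 3 h (with at least 96.8 % of the maximum reached by 1 h),
#' tumour maxima between 0.5 h and 9 h, and injected activities of
#' 7300 +/- 300 MBq.
#'
#' @param n_patients Number of virtual patients (default 13).
#' @param kidney_teff `c(min, mode, max)` of the kidney effective half-life
#'   triangular distribution, hours.
#' @param tumour_teff Same for tumour lesions.
#' @param kidney_tmax `c(min, max)` of the kidney time-of-maximum range (h).
#' @param tumour_tmax Same for tumour lesions.
#' @param kidney_uptake_1h Minimum fraction of the kidney curve maximum that
#'   must already be reached 1 h post injection (default 0.968).
#' @param a0_mean,a0_sd Injected activity distribution (MBq).
#' @param kidney_peak_frac `c(min, max)` peak kidney uptake as a fraction of
#'   the injected activity.
#' @param lesion_peak_frac Same for tumour lesions.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 13L,
                          kidney_teff = c(30, 40, 62),
                          tumour_teff = c(34, 50, 94),
                          kidney_tmax = c(0.6, 3),
                          tumour_tmax = c(0.5, 9),
                          kidney_uptake_1h = 0.968,
                          a0_mean = 7300, a0_sd = 300,
                          kidney_peak_frac = c(0.01, 0.03),
                          lesion_peak_frac = c(0.0005, 0.02),
                          seed = 1L) {
  stopifnot(n_patients >= 1L,
            length(kidney_teff) == 3L, !is.unsorted(kidney_teff),
            all(kidney_teff > 0),
            length(tumour_teff) == 3L, !is.unsorted(tumour_teff),
            all(tumour_teff > 0),
            length(kidney_tmax) == 2L, kidney_tmax[1] > 0,
            kidney_tmax[1] < kidney_tmax[2],
            length(tumour_tmax) == 2L, tumour_tmax[1] > 0,
            tumour_tmax[1] < tumour_tmax[2],
            a0_mean > 0, a0_sd >= 0,
            kidney_peak_frac[1] > 0,
            kidney_peak_frac[1] <= kidney_peak_frac[2],
            lesion_peak_frac[1] > 0,
            lesion_peak_frac[1] <= lesion_peak_frac[2],
            kidney_uptake_1h > 0, kidney_uptake_1h < 1)
  lphys <- lu177_lambda_phys()
  if (log(2) / max(kidney_teff) < lphys ||
      log(2) / max(tumour_teff) < lphys) {
    stop("infeasible T_eff range: maximum exceeds the physical half-life ",
         "(would imply a negative biological clearance rate)",
         call. = FALSE)
  }
  structure(list(n_patients = as.integer(n_patients),
                 kidney_teff = kidney_teff, tumour_teff = tumour_teff,
                 kidney_tmax = kidney_tmax, tumour_tmax = tumour_tmax,
                 kidney_uptake_1h = kidney_uptake_1h,
                 a0_mean = a0_mean, a0_sd = a0_sd,
                 kidney_peak_frac = kidney_peak_frac,
                 lesion_peak_frac = lesion_peak_frac,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

## Solve the effective uptake rate lu (> lb) so that the curve maximum
## log(lu/lb)/(lu - lb) equals t_max. Monotone in lu; bisection via uniroot
## on the ratio r = lu/lb.
.solve_lambda_up_eff <- function(lb_eff, t_max) {
  stopifnot(lb_eff > 0, t_max > 0)
  g <- function(r) log(r) / (lb_eff * (r - 1)) - t_max
  ## g(1+) = 1/lb_eff - t_max must be positive for a solution r > 1
  if (1 / lb_eff <= t_max) {
    stop("t_max too large for the given washout rate", call. = FALSE)
  }
  r <- uniroot(g, lower = 1 + 1e-9, upper = 1e12, tol = 1e-12)$root
  lb_eff * r
}

## One region's kinetics: draw T_eff (triangular) and t_max (uniform),
## solve the uptake rate, and scale the amplitude so the curve peak is
## `peak_frac * A0`.
.sample_region <- function(teff3, tmax2, peak_frac2, A0,
                           uptake_1h_min = NULL, max_tries = 10000L) {
  lphys <- lu177_lambda_phys()
  teff <- .rtriangular(1L, teff3[1], teff3[2], teff3[3])
  lb_eff <- log(2) / teff
  lambda_bio <- lb_eff - lphys
  for (i in seq_len(max_tries)) {
    t_max <- runif(1L, tmax2[1], tmax2[2])
    lu_eff <- .solve_lambda_up_eff(lb_eff, t_max)
    peak_shape <- exp(-lb_eff * t_max) - exp(-lu_eff * t_max)
    if (is.null(uptake_1h_min)) break
    val_1h <- exp(-lb_eff * 1) - exp(-lu_eff * 1)
    if (val_1h >= uptake_1h_min * peak_shape) break
    if (i == max_tries) {
      stop("could not satisfy the early-uptake condition", call. = FALSE)
    }
  }
  peak <- runif(1L, peak_frac2[1], peak_frac2[2]) * A0
  region_kinetics(C = peak / peak_shape, lambda_bio = lambda_bio,
                  lambda_up = lu_eff - lphys, lambda_phys = lphys)
}

#' Generate a virtual-patient cohort
#'
#' Draws `n_patients` virtual patients, each with an injected activity, one
#' kidney curve and two tumour-lesion curves (see [cohort_config()] for the
#' sampled quantities). Kidney draws are rejected until at least the
#' configured fraction of the curve maximum is reached 1 h post injection.
#' Fully deterministic for a fixed `config$seed`.
#'
#' @param config A `cohort_config`.
#' @return A list of `virtual_patient` objects (fields `patient_id`, `A0`,
#'   `kidney`, `lesions`), of class `virtual_cohort`, with the
#'   configuration attached as attribute `config`.
#' @export
#' @examples
#' cohort <- sample_cohort(cohort_config(seed = 42))
#' length(cohort)  # 13
sample_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  patients <- vector("list", config$n_patients)
  for (p in seq_len(config$n_patients)) {
    A0 <- -1
    while (A0 <= 0) A0 <- rnorm(1L, config$a0_mean, config$a0_sd)
    kidney <- .sample_region(config$kidney_teff, config$kidney_tmax,
                             config$kidney_peak_frac, A0,
                             uptake_1h_min = config$kidney_uptake_1h)
    lesions <- lapply(1:2, function(i) {
      .sample_region(config$tumour_teff, config$tumour_tmax,
                     config$lesion_peak_frac, A0)
    })
    patients[[p]] <- structure(
      list(patient_id = p, A0 = A0, kidney = kidney, lesions = lesions),
      class = "virtual_patient")
  }
  structure(patients, class = "virtual_cohort", config = config)
}

## region accessor: r = 1 kidney, 2/3 the two lesions
.patient_region <- function(patient, r) {
  if (r == 1L) patient$kidney else patient$lesions[[r - 1L]]
}

.region_names <- c("kidney", "lesion1", "lesion2")

#' Write a cohort to a JSON file
#'
#' Serializes all kinetic parameters, injected activities and the
#' generating configuration so a cohort can be pinned and re-read exactly.
#'
#' @param cohort A `virtual_cohort`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "virtual_cohort"))
  config <- attr(cohort, "config")
  enc_k <- function(k) list(C = k$C, lambda_bio = k$lambda_bio,
                            lambda_up = if (is.infinite(k$lambda_up))
                              "Inf" else k$lambda_up,
                            lambda_phys = k$lambda_phys)
  doc <- list(
    format = "ossdosim-cohort",
    seed = config$seed,
    config = unclass(config),
    patients = lapply(cohort, function(pt) {
      list(patient_id = pt$patient_id, A0 = pt$A0,
           kidney = enc_k(pt$kidney),
           lesions = lapply(pt$lesions, enc_k))
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a cohort from a JSON file
#'
#' @param path File written by [write_cohort()].
#' @return A `virtual_cohort`.
#' @export
read_cohort <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$format, "ossdosim-cohort")) {
    stop("not an ossdosim cohort file: ", path, call. = FALSE)
  }
  dec_k <- function(x) {
    region_kinetics(C = as.numeric(x$C),
                    lambda_bio = as.numeric(x$lambda_bio),
                    lambda_up = as.numeric(x$lambda_up),
                    lambda_phys = as.numeric(x$lambda_phys))
  }
  patients <- lapply(doc$patients, function(pt) {
    structure(list(patient_id = as.integer(pt$patient_id),
                   A0 = as.numeric(pt$A0),
                   kidney = dec_k(pt$kidney),
                   lesions = lapply(pt$lesions, dec_k)),
              class = "virtual_patient")
  })
  config <- doc$config
  cfg <- cohort_config(
    n_patients = config$n_patients,
    kidney_teff = unlist(config$kidney_teff),
    tumour_teff = unlist(config$tumour_teff),
    kidney_tmax = unlist(config$kidney_tmax),
    tumour_tmax = unlist(config$tumour_tmax),
    kidney_uptake_1h = config$kidney_uptake_1h,
    a0_mean = config$a0_mean, a0_sd = config$a0_sd,
    kidney_peak_frac = unlist(config$kidney_peak_frac),
    lesion_peak_frac = unlist(config$lesion_peak_frac),
    seed = config$seed)
  structure(patients, class = "virtual_cohort", config = cfg)
}
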