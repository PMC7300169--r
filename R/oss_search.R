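#' Root-mean-squared error from pooled mean and standard deviation
#'
#' `RMSE = sqrt(mu^2 + sigma^2)`, combining accuracy (bias `mu`) and
#' precision (spread `sigma`) of the pooled relative TIAC deviations.
#'
#' @param mu Mean relative deviation (percent).
#' @param sigma Standard deviation of the relative deviations (percent).
#' @return RMSE in percent. Vectorized.
#' @export
#' @examples
#' rmse(-2.8, 6.4)  # ~7.0
rmse <- function(mu, sigma) {
  if (any(sigma < 0)) stop("'sigma' must be >= 0", call. = FALSE)
  sqrt(mu^2 + sigma^2)
}

#' Joint kidney/tumour RMSE score
#'
#' `RMSE_joint = w_k * RMSE_K + RMSE_T`; the kidney term is up-weighted
#' (default `w_k = 2`) to prioritize accurate renal dosimetry when ranking
#' schedules.
#'
#' @param rmse_k Kidney RMSE (percent).
#' @param rmse_t Tumour RMSE (percent).
#' @param w_k Kidney weight, positive (default 2).
#' @return Joint score. Vectorized.
#' @export
joint_rmse <- function(rmse_k, rmse_t, w_k = 2) {
  if (any(rmse_k < 0) || any(rmse_t < 0)) {
    stop("RMSE inputs must be >= 0", call. = FALSE)
  }
  if (any(w_k <= 0)) stop("'w_k' must be positive", call. = FALSE)
  w_k * rmse_k + rmse_t
}

#' Search configuration
#'
#' @param n_reps Monte-Carlo replicates per schedule and patient
#'   (default 1000).
#' @param w_k Kidney weight in the joint RMSE (default 2).
#' @param seed Global integer seed for the noise streams.
#' @param t_last_max Optional limit (h) on the last planar time.
#' @return A list of class `search_config`.
#' @export
search_config <- function(n_reps = 1000L, w_k = 2, seed = 1L,
                          t_last_max = NULL) {
  n_reps <- as.integer(n_reps)
  stopifnot(n_reps >= 1L, w_k > 0)
  if (!is.null(t_last_max)) {
    .assert_scalar_num(t_last_max, "t_last_max", positive = TRUE)
  }
  structure(list(n_reps = n_reps, w_k = w_k, seed = as.integer(seed),
                 t_last_max = t_last_max),
            class = "search_config")
}

## schedule method from its class
.schedule_method <- function(schedule) {
  if (inherits(schedule, "hybrid_schedule")) "hybrid"
  else if (inherits(schedule, "single_tp_schedule")) "single_tp"
  else "planar"
}

## Vectorized mono-exponential log-OLS over replicate rows.
## t: times (length n); Y: n_reps x n matrix of log-activities.
## Returns A1, lambda1 vectors and a clamp flag per row. Identical maths to
## fit_monoexp(space = "log") applied row-wise.
.fit_monoexp_rows <- function(t, Y, lambda_phys) {
  tbar <- mean(t)
  tc <- t - tbar
  w <- tc / sum(tc^2)
  slope <- as.numeric(Y %*% w)
  ybar <- rowMeans(Y)
  lambda1 <- -slope - lambda_phys
  clamped <- lambda1 < 0
  lambda1[clamped] <- 0
  intercept <- ybar + (lambda1 + lambda_phys) * tbar
  list(A1 = exp(intercept), lambda1 = lambda1, clamped = clamped)
}

## Relative TIAC deviations (percent) for all patients/regions/replicates
## of one schedule. Returns pooled kidney and tumour deviation vectors and
## the clamped-fit count.
.schedule_deviations <- function(cohort, schedule, n_reps, noise_cfg,
                                 seed) {
  method <- .schedule_method(schedule)
  sig <- .planar_sigmas(noise_cfg)
  sd_spect <- .sdlog_from_cv(noise_cfg$cv_spect)
  lphys <- lu177_lambda_phys()
  planar_times <- switch(method,
                         hybrid = schedule$planar,
                         planar = as.numeric(schedule),
                         single_tp = numeric(0))
  t_spect <- switch(method,
                    hybrid = schedule$t_spect,
                    single_tp = schedule$t_ref,
                    planar = NULL)
  n_t <- length(planar_times)
  P <- length(cohort)
  kid <- vector("list", P)
  tum <- vector("list", 2L * P)
  n_clamped <- 0L
  for (p in seq_len(P)) {
    patient <- cohort[[p]]
    A0 <- patient$A0
    for (r in 1:3) {
      kin <- .patient_region(patient, r)
      tiac0 <- true_tiac(kin, A0)
      draws <- .noise_streams(seed, patient$patient_id, r, planar_times,
                              t_spect, n_reps, sig["syst"], sig["stoch"],
                              sd_spect)
      if (method == "single_tp") {
        a_sp <- true_activity(kin, schedule$t_ref) * draws$m_spect
        tiac <- (2 / log(2)) * a_sp * schedule$t_ref / A0
      } else {
        a_true <- true_activity(kin, planar_times)
        A <- draws$m_stoch * draws$m_syst  # m_syst recycles down columns
        Y <- log(A) + matrix(log(a_true), nrow = n_reps, ncol = n_t,
                             byrow = TRUE)
        fit <- .fit_monoexp_rows(planar_times, Y, lphys)
        n_clamped <- n_clamped + sum(fit$clamped)
        tiacp <- fit$A1 / ((fit$lambda1 + lphys) * A0)
        if (method == "hybrid") {
          tsp <- schedule$t_spect
          f_pl <- fit$A1 * exp(-(fit$lambda1 + lphys) * tsp)
          a_sp <- true_activity(kin, tsp) * draws$m_spect
          tiac <- (a_sp / f_pl) * tiacp
        } else {
          tiac <- tiacp
        }
      }
      delta <- 100 * (tiac / tiac0 - 1)
      if (r == 1L) kid[[p]] <- delta
      else tum[[2L * (p - 1L) + (r - 1L)]] <- delta
    }
  }
  list(kidney = unlist(kid, use.names = FALSE),
       tumour = unlist(tum, use.names = FALSE),
       n_clamped = n_clamped)
}

## population standard deviation
.sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

## schedule display string and anchor
.schedule_label <- function(schedule) {
  switch(.schedule_method(schedule),
         hybrid = paste(schedule$planar, collapse = ","),
         planar = paste(as.numeric(schedule), collapse = ","),
         single_tp = as.character(schedule$t_ref))
}

.schedule_anchor <- function(schedule) {
  if (inherits(schedule, "hybrid_schedule")) schedule$anchor else NA_integer_
}

#' Monte-Carlo metrics for one sampling schedule
#'
#' Runs `cfg$n_reps` noise replicates per patient, estimates the TIAC of
#' every region with the method implied by the schedule type (hybrid,
#' planar-only, or single time point), pools the relative deviations from
#' the true TIACs over patients x replicates (kidneys) and lesions x
#' patients x replicates (tumours), and summarizes them as mean, population
#' standard deviation, per-region RMSE and the weighted joint RMSE.
#'
#' At the defaults (13 patients, 1000 replicates) each schedule pools
#' 13000 kidney and 26000 tumour deviation values.
#'
#' @param cohort A `virtual_cohort`.
#' @param schedule A `hybrid_schedule`, `single_tp_schedule`, or numeric
#'   vector / `planar_schedule` of planar times.
#' @param cfg A `search_config`.
#' @param noise_cfg A `noise_config`.
#' @return One-row data.frame with columns `schedule_times`, `spect_anchor`,
#'   `method`, `f_syst`, `n_reps`, `t_last`, `mu_K`, `sigma_K`, `rmse_K`,
#'   `mu_T`, `sigma_T`, `rmse_T`, `rmse_joint`, `n_clamped`, `n_dev_K`,
#'   `n_dev_T`.
#' @export
schedule_metrics <- function(cohort, schedule, cfg = search_config(),
                             noise_cfg = noise_config()) {
  stopifnot(inherits(cohort, "virtual_cohort"), length(cohort) >= 1L,
            inherits(cfg, "search_config"),
            inherits(noise_cfg, "noise_config"))
  row <- .metrics_row(cohort, schedule, cfg, noise_cfg)
  as.data.frame(row, stringsAsFactors = FALSE)
}

## metrics as a plain named list (fast path for run_search)
.metrics_row <- function(cohort, schedule, cfg, noise_cfg) {
  dev <- .schedule_deviations(cohort, schedule, cfg$n_reps, noise_cfg,
                              cfg$seed)
  mu_k <- mean(dev$kidney); sd_k <- .sd_pop(dev$kidney)
  mu_t <- mean(dev$tumour); sd_t <- .sd_pop(dev$tumour)
  r_k <- rmse(mu_k, sd_k); r_t <- rmse(mu_t, sd_t)
  list(schedule_times = .schedule_label(schedule),
       spect_anchor = .schedule_anchor(schedule),
       method = .schedule_method(schedule),
       f_syst = noise_cfg$f_syst,
       n_reps = cfg$n_reps,
       t_last = last_planar_time(schedule),
       mu_K = mu_k, sigma_K = sd_k, rmse_K = r_k,
       mu_T = mu_t, sigma_T = sd_t, rmse_T = r_t,
       rmse_joint = joint_rmse(r_k, r_t, cfg$w_k),
       n_clamped = dev$n_clamped,
       n_dev_K = length(dev$kidney),
       n_dev_T = length(dev$tumour))
}

#' Evaluate many sampling schedules
#'
#' Applies [schedule_metrics()] to a list of schedules. Noise streams are
#' derived from the schedule content, not its list position, so results for
#' a schedule are identical whether it is evaluated alone or inside any
#' enumeration.
#'
#' @param cohort A `virtual_cohort`.
#' @param schedules List of schedule objects (see [schedule_metrics()]).
#' @param cfg A `search_config`; if `cfg$t_last_max` is set, schedules are
#'   filtered with [filter_by_last_tp()] first.
#' @param noise_cfg A `noise_config`.
#' @param progress_every Emit a progress message every this many schedules
#'   (0 disables).
#' @return data.frame with one [schedule_metrics()] row per schedule.
#' @export
run_search <- function(cohort, schedules, cfg = search_config(),
                       noise_cfg = noise_config(), progress_every = 1000L) {
  stopifnot(is.list(schedules), length(schedules) >= 1L)
  if (!is.null(cfg$t_last_max)) {
    schedules <- filter_by_last_tp(schedules, cfg$t_last_max)
    if (length(schedules) == 0L) {
      stop("no schedule satisfies t_last_max = ", cfg$t_last_max,
           call. = FALSE)
    }
  }
  n <- length(schedules)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    rows[[i]] <- .metrics_row(cohort, schedules[[i]], cfg, noise_cfg)
    if (progress_every > 0L && i %% progress_every == 0L) {
      message(sprintf("evaluated %d / %d schedules", i, n))
    }
  }
  cols <- names(rows[[1]])
  out <- lapply(cols, function(cn) {
    unlist(lapply(rows, `[[`, cn), use.names = FALSE)
  })
  names(out) <- cols
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Rank schedules and identify the optimal sampling schedule
#'
#' Sorts a metrics table ascending by `rmse_joint`; ties are broken by the
#' earlier last planar time, then by lexicographic order of the schedule
#' label. The rank-1 row is the optimal sampling schedule (OSS).
#'
#' @param metrics data.frame from [run_search()] / [schedule_metrics()].
#' @return The same data.frame, sorted, with a leading `rank` column.
#' @export
find_oss <- function(metrics) {
  if (!is.data.frame(metrics) || nrow(metrics) == 0L) {
    stop("'metrics' must be a non-empty data.frame", call. = FALSE)
  }
  ord <- order(metrics$rmse_joint, metrics$t_last,
               metrics$schedule_times, metrics$spect_anchor)
  out <- metrics[ord, , drop = FALSE]
  rownames(out) <- NULL
  cbind(rank = seq_len(nrow(out)), out)
}

#' Best achievable RMSE under last-time-point limits
#'
#' For each limit in `t_last_list`, restricts the candidate schedules to
#' those whose last planar time does not exceed the limit and reports the
#' minimum kidney, tumour and joint RMSE over the retained schedules,
#' together with the joint-optimal schedule. Because the feasible sets are
#' nested, each best-RMSE column is non-increasing in the limit.
#'
#' @param cohort A `virtual_cohort`.
#' @param candidates List of schedule objects.
#' @param cfg,noise_cfg See [run_search()].
#' @param t_last_list Ascending limits (h) for the last planar time.
#' @param metrics Optional precomputed [run_search()] table for
#'   `candidates`; if `NULL` it is computed.
#' @return data.frame with one row per limit: `t_last_max`, `n_schedules`,
#'   `best_rmse_K`, `best_rmse_T`, `best_rmse_joint`, `best_schedule`,
#'   `best_spect_anchor` (NA row if no candidate survives a limit).
#' @export
constrained_search <- function(cohort, candidates, cfg = search_config(),
                               noise_cfg = noise_config(),
                               t_last_list = c(48, 72, 96, 120, 144, 168,
                                               192),
                               metrics = NULL) {
  stopifnot(!is.unsorted(t_last_list), all(t_last_list > 0))
  if (is.null(metrics)) {
    metrics <- run_search(cohort, candidates, cfg, noise_cfg,
                          progress_every = 0L)
  }
  rows <- lapply(t_last_list, function(lim) {
    sub <- metrics[metrics$t_last <= lim, , drop = FALSE]
    if (nrow(sub) == 0L) {
      return(data.frame(t_last_max = lim, n_schedules = 0L,
                        best_rmse_K = NA_real_, best_rmse_T = NA_real_,
                        best_rmse_joint = NA_real_,
                        best_schedule = NA_character_,
                        best_spect_anchor = NA_integer_,
                        stringsAsFactors = FALSE))
    }
    best <- find_oss(sub)[1L, ]
    data.frame(t_last_max = lim, n_schedules = nrow(sub),
               best_rmse_K = min(sub$rmse_K),
               best_rmse_T = min(sub$rmse_T),
               best_rmse_joint = best$rmse_joint,
               best_schedule = best$schedule_times,
               best_spect_anchor = best$spect_anchor,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Vary the last two time points of a schedule
#'
#' Holds the leading planar times of a hybrid base schedule fixed and
#' re-evaluates every admissible (penultimate, last) pair from the grid
#' (penultimate < last, both later than the fixed times), keeping the base
#' schedule's SPECT anchor index. Used to map how the kidney and tumour
#' RMSE react to moving the late measurements.
#'
#' @param base A `hybrid_schedule` with >= 2 planar times.
#' @param grid A `time_grid` supplying candidate times.
#' @param cohort,cfg,noise_cfg See [run_search()].
#' @return Long-format data.frame sorted by `(t_penultimate, t_last)` with
#'   the [schedule_metrics()] columns plus `t_penultimate`.
#' @export
vary_last_two <- function(base, grid, cohort, cfg = search_config(),
                          noise_cfg = noise_config()) {
  stopifnot(inherits(base, "hybrid_schedule"))
  k <- length(base$planar)
  fixed <- if (k > 2L) base$planar[seq_len(k - 2L)] else numeric(0)
  times <- as.numeric(grid)
  times <- times[times > if (length(fixed)) max(fixed) else 0]
  if (length(times) < 2L) {
    stop("grid leaves no admissible (penultimate, last) pairs",
         call. = FALSE)
  }
  pairs <- t(combn(times, 2L))
  schedules <- lapply(seq_len(nrow(pairs)), function(i) {
    hybrid_schedule(c(fixed, pairs[i, ]), base$anchor, base$offset)
  })
  out <- run_search(cohort, schedules, cfg, noise_cfg,
                    progress_every = 0L)
  out$t_penultimate <- pairs[, 1L]
  out$t_last <- pairs[, 2L]
  out[order(out$t_penultimate, out$t_last), , drop = FALSE]
}
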