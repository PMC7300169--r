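#' Construct a time-point grid
#'
#' A time grid is the set of allowed measurement times (hours post
#' injection) from which sampling schedules are drawn. Times must be
#' positive, unique and strictly increasing.
#'
#' @param times Numeric vector of hours post injection.
#' @return A numeric vector of class `time_grid`.
#' @seealso [default_grid()]
#' @export
time_grid <- function(times) {
  if (!is.numeric(times) || length(times) < 1L || anyNA(times)) {
    stop("'times' must be a non-empty numeric vector without NAs",
         call. = FALSE)
  }
  times <- as.numeric(times)
  if (any(times <= 0)) stop("grid times must be positive", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE)) {
    stop("grid times must be strictly increasing", call. = FALSE)
  }
  structure(times, class = "time_grid")
}

#' Default 24-point measurement grid
#'
#' The default grid contains 24 candidate times between 1 h and 192 h post
#' injection, restricted to clinical working hours: 1, 2, 3, 4, 20, 22, 24,
#' 26, 28, 44, 48, 52, 68, 72, 76, 92, 96, 100, 116, 120, 124, 144, 168 and
#' 192 h.
#'
#' @return A `time_grid` of length 24.
#' @export
#' @examples
#' g <- default_grid()
#' length(g)  # 24
default_grid <- function() {
  time_grid(c(1, 2, 3, 4, 20, 22, 24, 26, 28, 44, 48, 52, 68, 72, 76,
              92, 96, 100, 116, 120, 124, 144, 168, 192))
}

#' Planar sampling schedule
#'
#' An ordered subset of a time grid at which planar whole-body images are
#' acquired.
#'
#' @param times Strictly increasing numeric vector of 2-4 times (h p.i.).
#' @param grid Optional `time_grid`; if supplied, all times must be members.
#' @return Numeric vector of class `planar_schedule`.
#' @export
planar_schedule <- function(times, grid = NULL) {
  times <- as.numeric(times)
  if (length(times) < 2L || length(times) > 4L) {
    stop("a planar schedule has 2 to 4 time points", call. = FALSE)
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stop("schedule times must be strictly increasing", call. = FALSE)
  }
  if (!is.null(grid) && !all(times %in% as.numeric(grid))) {
    stop("all schedule times must be members of the grid", call. = FALSE)
  }
  structure(times, class = "planar_schedule")
}

#' Enumerate all planar sampling schedules
#'
#' Generates every subset of `n_tp` grid times in deterministic
#' lexicographic order. For four time points an early-time-point constraint
#' applies: exactly one or two of the four times must lie within the first
#' `early_window` hours post injection. Two- and three-point schedules are
#' unconstrained. On the default grid this yields 276 (2 TPs), 2024 (3 TPs)
#' and 5700 (4 TPs) schedules.
#'
#' @param grid A `time_grid`.
#' @param n_tp Number of planar time points, one of 2, 3, 4.
#' @param early_constraint Apply the early-TP constraint for `n_tp = 4`?
#' @param early_window Upper edge (h) of the early window; default 4 h.
#' @return Matrix with `n_tp` columns; each row is one schedule, times
#'   ascending within a row, rows in lexicographic order.
#' @export
#' @examples
#' nrow(enumerate_planar_schedules(default_grid(), 2))  # 276
enumerate_planar_schedules <- function(grid, n_tp,
                                       early_constraint = TRUE,
                                       early_window = 4) {
  times <- as.numeric(grid)
  if (!is.numeric(n_tp) || length(n_tp) != 1L || !n_tp %in% c(2, 3, 4)) {
    stop("'n_tp' must be 2, 3 or 4", call. = FALSE)
  }
  n_tp <- as.integer(n_tp)
  sets <- t(combn(times, n_tp))
  if (n_tp == 4L && isTRUE(early_constraint)) {
    n_early <- rowSums(sets <= early_window)
    sets <- sets[n_early >= 1 & n_early <= 2, , drop = FALSE]
  }
  sets
}

#' Hybrid planar/SPECT sampling schedule
#'
#' A planar schedule plus one quantitative SPECT/CT measurement acquired a
#' fixed offset (default 0.5 h) after one of the planar images (the
#' "anchor").
#'
#' @param planar Numeric vector of planar times (or a `planar_schedule`).
#' @param anchor Index of the planar time the SPECT/CT follows.
#' @param offset SPECT/CT delay after the anchor planar image, in hours.
#' @return A list of class `hybrid_schedule` with elements `planar`,
#'   `anchor`, `offset` and the derived `t_spect`.
#' @export
hybrid_schedule <- function(planar, anchor, offset = 0.5) {
  planar <- as.numeric(planar)
  if (is.unsorted(planar, strictly = TRUE) || length(planar) < 2L) {
    stop("'planar' must be >= 2 strictly increasing times", call. = FALSE)
  }
  anchor <- as.integer(anchor)
  if (anchor < 1L || anchor > length(planar)) {
    stop("'anchor' must index a planar time", call. = FALSE)
  }
  .assert_scalar_num(offset, "offset", positive = TRUE)
  structure(list(planar = planar, anchor = anchor, offset = offset,
                 t_spect = planar[anchor] + offset),
            class = "hybrid_schedule")
}

#' Attach a SPECT/CT measurement to a planar schedule
#'
#' Expands one planar schedule into the full set of hybrid planar/SPECT
#' schedules: one per planar time, with the SPECT/CT `offset` hours after
#' that time.
#'
#' @inheritParams hybrid_schedule
#' @return List of `hybrid_schedule` objects, anchor running over all
#'   planar indices.
#' @export
#' @examples
#' hs <- attach_spect(c(3, 96, 192))
#' vapply(hs, `[[`, numeric(1), "t_spect")  # 3.5 96.5 192.5
attach_spect <- function(planar, offset = 0.5) {
  planar <- as.numeric(planar)
  lapply(seq_along(planar), function(a) hybrid_schedule(planar, a, offset))
}

#' Enumerate all hybrid planar/SPECT schedules
#'
#' All planar schedules of size `n_tp` crossed with every possible SPECT
#' anchor: 2 x 276, 3 x 2024 and 4 x 5700 schedules on the default grid.
#'
#' @inheritParams enumerate_planar_schedules
#' @param offset SPECT/CT delay after the anchor planar image (h).
#' @return List of `hybrid_schedule` objects in deterministic order
#'   (lexicographic by planar times, anchor innermost).
#' @export
enumerate_hybrid_schedules <- function(grid, n_tp, offset = 0.5,
                                       early_constraint = TRUE,
                                       early_window = 4) {
  sets <- enumerate_planar_schedules(grid, n_tp, early_constraint,
                                     early_window)
  out <- vector("list", nrow(sets) * n_tp)
  k <- 0L
  for (i in seq_len(nrow(sets))) {
    for (a in seq_len(n_tp)) {
      k <- k + 1L
      out[[k]] <- hybrid_schedule(sets[i, ], a, offset)
    }
  }
  out
}

#' Single-time-point schedule
#'
#' One quantitative SPECT/CT measurement at `t_ref`; no planar imaging.
#'
#' @param t_ref Measurement time (h p.i.).
#' @param grid Optional `time_grid`; if supplied `t_ref` must be a member.
#' @return A list of class `single_tp_schedule`.
#' @export
single_tp_schedule <- function(t_ref, grid = NULL) {
  .assert_scalar_num(t_ref, "t_ref", positive = TRUE)
  if (!is.null(grid) && !t_ref %in% as.numeric(grid)) {
    stop("'t_ref' must be a member of the grid", call. = FALSE)
  }
  structure(list(t_ref = as.numeric(t_ref)), class = "single_tp_schedule")
}

#' Enumerate single-time-point schedules
#'
#' One schedule per grid time (24 on the default grid).
#'
#' @param grid A `time_grid`.
#' @return List of `single_tp_schedule` objects in grid order.
#' @export
enumerate_single_tp_schedules <- function(grid) {
  lapply(as.numeric(grid), single_tp_schedule)
}

#' Last planar measurement time of a schedule
#'
#' For hybrid schedules the SPECT/CT offset does not count towards the last
#' measurement time; for single-time-point schedules it is `t_ref`.
#'
#' @param schedule A `planar_schedule`/numeric vector, `hybrid_schedule` or
#'   `single_tp_schedule`.
#' @return Last planar time in hours.
#' @export
last_planar_time <- function(schedule) {
  if (inherits(schedule, "hybrid_schedule")) {
    max(schedule$planar)
  } else if (inherits(schedule, "single_tp_schedule")) {
    schedule$t_ref
  } else {
    max(as.numeric(schedule))
  }
}

#' Filter schedules by the time of the last measurement
#'
#' Retains schedules whose latest planar time does not exceed `t_last_max`.
#' The fixed SPECT/CT offset of hybrid schedules may exceed the limit by the
#' offset (a schedule ending at 96 h keeps its SPECT/CT at 96.5 h).
#'
#' @param schedules Either a matrix of planar schedules (one row each, as
#'   returned by [enumerate_planar_schedules()]) or a list of schedule
#'   objects.
#' @param t_last_max Upper limit for the last planar time (h), positive.
#' @return Filtered object of the same shape as the input.
#' @export
filter_by_last_tp <- function(schedules, t_last_max) {
  .assert_scalar_num(t_last_max, "t_last_max", positive = TRUE)
  if (is.matrix(schedules)) {
    keep <- apply(schedules, 1L, max) <= t_last_max
    schedules[keep, , drop = FALSE]
  } else if (is.list(schedules)) {
    keep <- vapply(schedules, last_planar_time, numeric(1)) <= t_last_max
    schedules[keep]
  } else {
    stop("'schedules' must be a matrix or a list of schedules",
         call. = FALSE)
  }
}
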