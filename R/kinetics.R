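#' Cytokine secretion time course
#'
#' Per-donor, per-condition cytokine amounts (pg per reference cell
#' count) at ordered timepoints. The amount at t = 0 defaults to 0 —
#' stimulation starts the clock with no pre-existing cytokine — but can
#' be supplied explicitly for pre-loaded cultures.
#'
#' @param timepoints_h Strictly increasing timepoints in hours.
#' @param amounts Nonnegative amounts, pg per `reference_count` cells,
#'   one per timepoint.
#' @param donor,condition Optional labels.
#' @param reference_count Reference cell number the amounts are
#'   normalized to. Default 1e5.
#' @return An object of class `"time_course"`.
#' @examples
#' tc <- time_course(c(0, 2, 4, 8, 24), c(0, 100, 250, 400, 450))
#' interval_rates(tc)
#' @export
time_course <- function(timepoints_h, amounts, donor = NA, condition = NA,
                        reference_count = 1e5) {
  if (!is.numeric(timepoints_h) || !is.numeric(amounts))
    stop("timepoints and amounts must be numeric")
  if (length(timepoints_h) != length(amounts))
    stop("timepoints and amounts must have equal length")
  if (any(duplicated(timepoints_h)))
    stop("duplicate timepoints")
  if (is.unsorted(timepoints_h, strictly = TRUE))
    stop("timepoints must be strictly increasing")
  if (any(amounts < 0)) stop("amounts must be nonnegative")
  structure(
    list(timepoints_h = timepoints_h, amounts = amounts,
         donor = donor, condition = condition,
         reference_count = reference_count),
    class = "time_course"
  )
}

#' @export
print.time_course <- function(x, ...) {
  cat(sprintf("Cytokine time course%s%s, pg per %g cells\n",
              if (!is.na(x$donor)) paste0(", donor ", x$donor) else "",
              if (!is.na(x$condition)) paste0(", ", x$condition) else "",
              x$reference_count))
  print(stats::setNames(x$amounts, paste0(x$timepoints_h, "h")))
  invisible(x)
}

#' @export
plot.time_course <- function(x, ...) {
  graphics::plot(x$timepoints_h, x$amounts, type = "b", pch = 19,
                 xlab = "time (h)",
                 ylab = sprintf("amount (pg per %g cells)", x$reference_count),
                 ...)
  invisible(x)
}

#' Per-interval production rates with clearance flags
#'
#' Finite-difference production rate over each consecutive pair of
#' timepoints: (amount_end - amount_start) / (t_end - t_start), in pg/h
#' per reference cells. A negative rate means more cytokine disappeared
#' than was produced during the interval — apparent clearance
#' (consumption, degradation or assay loss) — and is flagged.
#'
#' @param tc A [time_course()] with >= 2 timepoints.
#' @return A data frame of class `"rate_table"`: `t_start`, `t_end`,
#'   `rate_pg_per_h`, `clearance`.
#' @examples
#' interval_rates(time_course(c(0, 2, 4), c(0, 100, 300)))  # rates 50, 100
#' @export
interval_rates <- function(tc) {
  tc <- as_time_course(tc)
  if (length(tc$timepoints_h) < 2) stop("need at least 2 timepoints")
  t <- tc$timepoints_h
  y <- tc$amounts
  rate <- diff(y) / diff(t)
  out <- data.frame(
    t_start = t[-length(t)], t_end = t[-1],
    rate_pg_per_h = rate, clearance = rate < 0
  )
  class(out) <- c("rate_table", "data.frame")
  out
}

as_time_course <- function(tc) {
  if (inherits(tc, "time_course")) return(tc)
  if (is.data.frame(tc) && all(c("timepoint_h", "amount_pg_per_1e5_cells") %in% names(tc)))
    return(time_course(tc$timepoint_h, tc$amount_pg_per_1e5_cells))
  stop("`tc` must be a time_course or a timecourse data frame")
}

#' Normalize a time course to its per-donor maximum
#'
#' Divides every amount by the course maximum, giving a relative course
#' in [0, 1] that is invariant to the absolute scale (and hence to donor
#' effects and to the reference cell count used upstream).
#'
#' @param tc A [time_course()] with a positive maximum.
#' @return A `time_course` of relative amounts (reference count dropped).
#' @examples
#' normalize_to_max(time_course(c(0, 2, 4, 8), c(0, 50, 100, 80)))
#' @export
normalize_to_max <- function(tc) {
  tc <- as_time_course(tc)
  m <- max(tc$amounts)
  if (m <= 0) stop("cannot normalize an all-zero time course")
  time_course(tc$timepoints_h, tc$amounts / m,
              donor = tc$donor, condition = tc$condition,
              reference_count = 1)
}

#' Telescoping consistency between a time course and its rates
#'
#' The interval rates times the interval widths must telescope back to
#' the net amount change: sum(rate_i x dt_i) = amount_last - amount_first.
#' Used as an internal consistency check after rate computation.
#'
#' @param tc A [time_course()].
#' @param rates Its [interval_rates()] table.
#' @param tol Residual tolerance. Default 1e-9.
#' @return List with `ok` (logical) and `residual`.
#' @export
rate_sum_check <- function(tc, rates, tol = 1e-9) {
  tc <- as_time_course(tc)
  if (!is.data.frame(rates) ||
      !all(c("t_start", "t_end", "rate_pg_per_h") %in% names(rates)))
    stop("`rates` must be an interval_rates table")
  if (nrow(rates) != max(length(tc$timepoints_h) - 1L, 0L) ||
      (nrow(rates) > 0 &&
       (any(rates$t_start != tc$timepoints_h[-length(tc$timepoints_h)]) ||
        any(rates$t_end != tc$timepoints_h[-1]))))
    stop("rate table does not match the time course intervals")
  lhs <- sum(rates$rate_pg_per_h * (rates$t_end - rates$t_start))
  rhs <- if (length(tc$amounts) > 0)
    tc$amounts[length(tc$amounts)] - tc$amounts[1] else 0
  residual <- abs(lhs - rhs)
  list(ok = residual < tol, residual = residual)
}

#' Production shutoff time
#'
#' Operationalizes "the cells stopped producing": the earliest time at
#' which the cumulative amount reaches `fraction` (default 95\%) of the
#' final amount. With `interpolate = TRUE` (default) the crossing is
#' located by linear interpolation between timepoints; otherwise the
#' first measured timepoint at or past the crossing is returned.
#'
#' Higher culture densities shut production off earlier — the
#' density-dependent (quorum-sensing-like) signature this statistic is
#' designed to expose.
#'
#' @param tc A [time_course()] whose final amount is positive.
#' @param fraction Fraction of the final amount defining shutoff.
#'   Default 0.95.
#' @param interpolate Linearly interpolate the crossing time. Default `TRUE`.
#' @return Shutoff time in hours.
#' @examples
#' tc <- time_course(c(0, 2, 4, 8, 24), c(0, 200, 380, 400, 400))
#' shutoff_time(tc)   # reaches 95% of final before 8 h
#' @export
shutoff_time <- function(tc, fraction = 0.95, interpolate = TRUE) {
  tc <- as_time_course(tc)
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("`fraction` must lie in (0, 1]")
  final <- tc$amounts[length(tc$amounts)]
  if (final <= 0) stop("final amount must be positive")
  target <- fraction * final
  idx <- which(tc$amounts >= target)[1]
  if (is.na(idx)) stop("course never reaches the target fraction")  # unreachable
  if (!interpolate || idx == 1) return(tc$timepoints_h[idx])
  t0 <- tc$timepoints_h[idx - 1]; t1 <- tc$timepoints_h[idx]
  y0 <- tc$amounts[idx - 1]; y1 <- tc$amounts[idx]
  if (y1 == y0) return(t1)
  t0 + (target - y0) / (y1 - y0) * (t1 - t0)
}
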