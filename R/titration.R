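#' Fit a cytokine titration curve
#'
#' Builds a monotone mapping between known cytokine concentrations
#' (pg/mL) and measured median fluorescence intensity (MFI), from
#' standards measured on capture-antibody-coated cells. The fitted curve
#' converts single-cell fluorescence directly into cytokine content.
#'
#' Two forms are supported:
#' \describe{
#'   \item{`"loglog"` (default)}{Piecewise-linear interpolation in
#'     log-concentration vs log-signal space. Passes exactly through every
#'     standard, so the forward/invert round trip is exact at the knots
#'     and accurate to interpolation error between them.}
#'   \item{`"4pl"`}{Four-parameter logistic
#'     \eqn{y = d + (a - d) / (1 + (x/c)^{-\beta})} fitted by
#'     Levenberg-Marquardt least squares on log signals, the standard
#'     immunoassay dose-response form. `a` is the zero-dose asymptote,
#'     `d` the saturating asymptote, `c` the inflection (EC50) and
#'     \eqn{\beta > 0} the slope.}
#' }
#'
#' The curve records its valid range (lowest to highest standard);
#' signals outside it are clamped and flagged by [signal_to_amount()].
#'
#' @param standards A data frame with columns `concentration_pg_ml` and
#'   `mfi` (aliases `concentration`/`signal` accepted), strictly
#'   increasing in both.
#' @param form `"loglog"` or `"4pl"`.
#' @return An object of class `"titration_curve"` with `print`, `coef`,
#'   `predict` and `plot` methods. `predict(curve, x)` maps concentration
#'   to signal; `predict(curve, x, inverse = TRUE)` maps signal back to
#'   concentration.
#' @examples
#' std <- data.frame(concentration_pg_ml = c(10, 100, 1000),
#'                   mfi = c(100, 1000, 10000))
#' curve <- fit_titration(std)
#' predict(curve, 100)                    # 1000
#' predict(curve, 1000, inverse = TRUE)   # 100
#' @export
fit_titration <- function(standards, form = c("loglog", "4pl")) {
  form <- match.arg(form)
  std <- normalize_standards(standards)
  conc <- std$concentration_pg_ml
  sig <- std$mfi
  n <- length(conc)
  if (n < 2) stop("need at least 2 titration standards")
  dup_c <- which(diff(conc) <= 0)
  if (length(dup_c))
    stop(sprintf("standard concentrations must be strictly increasing (rows %d and %d)",
                 dup_c[1], dup_c[1] + 1L))
  dup_s <- which(diff(sig) <= 0)
  if (length(dup_s))
    stop(sprintf("standard signals must be strictly increasing (rows %d and %d); the curve must be monotone",
                 dup_s[1], dup_s[1] + 1L))
  if (any(conc <= 0) || any(sig <= 0))
    stop("concentrations and signals must be strictly positive")

  fit <- NULL
  if (form == "4pl") {
    # the 4PL in log-concentration is the self-start logistic SSfpl
    # (xmid = log C, scal = 1/B); use it for starting values, then
    # refine on the log-signal scale, where multiplicative assay noise
    # is homoscedastic
    df <- data.frame(lx = log(conc), y = sig)
    start <- tryCatch(
      as.list(stats::coef(stats::nls(y ~ SSfpl(lx, A, D, xmid, scal),
                                     data = df))),
      # self-start can fail on (near-)exact data; fall back to heuristics
      error = function(e) list(A = 0.9 * min(sig), D = 1.1 * max(sig),
                               xmid = mean(log(range(conc))),
                               scal = 1 / diff(range(log(conc))) * 4)
    )
    # pmax guards the log against transiently inverted asymptotes (D < A)
    # during early Levenberg-Marquardt steps
    fit <- minpack.lm::nlsLM(
      log(y) ~ log(pmax(A + (D - A) / (1 + exp((xmid - lx) / scal)), 1e-12)),
      data = df, start = start,
      lower = c(A = 0, D = 0, xmid = -Inf, scal = 1e-8),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )
  }
  structure(
    list(standards = data.frame(concentration_pg_ml = conc, mfi = sig),
         form = form, fit = fit,
         range_concentration = range(conc),
         range_signal = range(sig)),
    class = "titration_curve"
  )
}

normalize_standards <- function(standards) {
  if (!is.data.frame(standards)) stop("`standards` must be a data frame")
  nm <- names(standards)
  cc <- intersect(c("concentration_pg_ml", "concentration"), nm)[1]
  sc <- intersect(c("mfi", "signal"), nm)[1]
  if (is.na(cc) || is.na(sc))
    stop("standards need columns `concentration_pg_ml` (or `concentration`) and `mfi` (or `signal`)")
  out <- data.frame(concentration_pg_ml = standards[[cc]], mfi = standards[[sc]])
  out[order(out$concentration_pg_ml), , drop = FALSE]
}

#' @export
coef.titration_curve <- function(object, ...) {
  if (object$form == "4pl") {
    p <- stats::coef(object$fit)
    c(A = unname(p["A"]), D = unname(p["D"]),
      C = exp(unname(p["xmid"])), B = 1 / unname(p["scal"]))
  } else {
    stats::setNames(object$standards$mfi,
                    paste0("mfi@", object$standards$concentration_pg_ml))
  }
}

#' @export
print.titration_curve <- function(x, ...) {
  cat(sprintf("Titration curve (%s), %d standards\n",
              if (x$form == "loglog") "log-log interpolation" else "4-parameter logistic",
              nrow(x$standards)))
  cat(sprintf("  valid range: %g to %g pg/mL (signal %g to %g)\n",
              x$range_concentration[1], x$range_concentration[2],
              x$range_signal[1], x$range_signal[2]))
  if (x$form == "4pl") {
    p <- stats::coef(x)
    cat(sprintf("  A = %.4g, D = %.4g, C (EC50) = %.4g pg/mL, slope B = %.4g\n",
                p["A"], p["D"], p["C"], p["B"]))
  }
  invisible(x)
}

#' Evaluate or invert a titration curve
#'
#' @param object A fitted [fit_titration()] curve.
#' @param x Concentrations in pg/mL (forward) or signals (when
#'   `inverse = TRUE`).
#' @param inverse Map signal back to concentration instead.
#' @param ... Unused.
#' @return Numeric vector of signals (forward) or concentrations (inverse).
#'   Inputs outside the standards' range are evaluated by clamping to the
#'   range boundary; see [signal_to_amount()] for flagged clamping.
#' @export
predict.titration_curve <- function(object, x, inverse = FALSE, ...) {
  if (!is.numeric(x)) stop("`x` must be numeric")
  if (inverse) titration_invert(object, x) else titration_forward(object, x)
}

titration_forward <- function(curve, conc) {
  conc <- pmin(pmax(conc, curve$range_concentration[1]), curve$range_concentration[2])
  if (curve$form == "loglog") {
    exp(stats::approx(log(curve$standards$concentration_pg_ml),
                      log(curve$standards$mfi),
                      xout = log(conc), rule = 2)$y)
  } else {
    p <- stats::coef(curve$fit)
    unname(p["A"] + (p["D"] - p["A"]) /
             (1 + exp((p["xmid"] - log(conc)) / p["scal"])))
  }
}

titration_invert <- function(curve, signal) {
  signal <- pmin(pmax(signal, curve$range_signal[1]), curve$range_signal[2])
  if (curve$form == "loglog") {
    exp(stats::approx(log(curve$standards$mfi),
                      log(curve$standards$concentration_pg_ml),
                      xout = log(signal), rule = 2)$y)
  } else {
    p <- stats::coef(curve$fit)
    # y = A + (D-A)/(1+exp((xmid-lx)/scal)) => lx = xmid - scal log((D-A)/(y-A) - 1)
    ratio <- (p["D"] - p["A"]) / (signal - p["A"]) - 1
    out <- exp(unname(p["xmid"] - p["scal"] * log(pmax(ratio, 1e-300))))
    pmin(pmax(out, curve$range_concentration[1]), curve$range_concentration[2])
  }
}

#' @export
plot.titration_curve <- function(x, n = 200, ...) {
  grid <- exp(seq(log(x$range_concentration[1]), log(x$range_concentration[2]),
                  length.out = n))
  graphics::plot(grid, titration_forward(x, grid), type = "l", log = "xy",
                 xlab = "concentration (pg/mL)", ylab = "signal (MFI)",
                 main = "Titration curve", ...)
  graphics::points(x$standards$concentration_pg_ml, x$standards$mfi, pch = 19)
  invisible(x)
}

#' Convert per-cell fluorescence to cytokine amounts
#'
#' Inverts a titration curve for each event's signal, giving a per-cell
#' cytokine amount. Signals below the curve's valid range are clamped to
#' the lowest standard and flagged `below_range`; signals above it are
#' clamped to the highest standard and flagged `saturated` (the capture
#' antibodies have finite capacity, so saturation is flagged rather than
#' corrected). Clamping rather than dropping conserves the cell count, so
#' downstream fraction estimates are not biased.
#'
#' @param curve A fitted [fit_titration()] curve.
#' @param events An `EventTable` data frame with an `il10_signal` (or
#'   `tnfa_signal`, see `channel`) column, or a numeric signal vector.
#' @param channel Which signal column to convert when `events` is a data
#'   frame. Default `"il10_signal"`.
#' @param conversion Scale from the curve's concentration units (pg/mL)
#'   to per-cell amount (pg/cell). Default 1e-3, which places mid-range
#'   standards at order-1 pg per cell; set from the titration geometry
#'   (cells per sample and sample volume) when known.
#' @return `events` (or a new data frame) with columns `amount_pg`,
#'   `below_range`, `saturated` appended.
#' @export
signal_to_amount <- function(curve, events, channel = "il10_signal",
                             conversion = 1e-3) {
  if (!inherits(curve, "titration_curve")) stop("`curve` must be a titration_curve")
  if (is.data.frame(events)) {
    if (!channel %in% names(events))
      stop(sprintf("events table has no `%s` column", channel))
    signal <- events[[channel]]
    out <- events
  } else {
    signal <- events
    out <- data.frame(signal = signal)
  }
  if (length(signal) == 0) stop("no events supplied")
  out$below_range <- signal < curve$range_signal[1]
  out$saturated <- signal > curve$range_signal[2]
  out$amount_pg <- titration_invert(curve, signal) * conversion
  out
}

#' Total cytokine production normalized to a reference cell count
#'
#' Sums quantified per-cell amounts and rescales to a reference
#' population size, enabling comparison of total production between
#' single-cell and bulk cultures regardless of how many cells were
#' measured.
#'
#' @param amounts Per-cell amounts in pg (numeric vector, or a data frame
#'   holding an `amount_pg` column as produced by [signal_to_amount()]).
#' @param reference_count Reference cell number. Default 1e5.
#' @return Total pg per `reference_count` cells.
#' @examples
#' total_production(rep(0.5, 10))  # 5000 pg per 1e5 cells
#' @export
total_production <- function(amounts, reference_count = 1e5) {
  if (is.data.frame(amounts)) {
    if (!"amount_pg" %in% names(amounts))
      stop("data frame input must have an `amount_pg` column")
    amounts <- amounts$amount_pg
  }
  if (!is.numeric(amounts) || length(amounts) == 0)
    stop("no quantified cells supplied")
  if (any(amounts < 0)) stop("per-cell amounts must be nonnegative")
  sum(amounts) * reference_count / length(amounts)
}

#' Normalize an ELISA concentration to volume and cell count
#'
#' Converts a supernatant concentration into total cytokine per reference
#' cell number: concentration x sample volume gives total pg, divided by
#' the number of cells that produced it and rescaled to the reference
#' count.
#'
#' @param concentration_pg_ml Measured concentration, pg/mL (> 0 allowed 0).
#' @param volume_ml Sample volume in mL (> 0).
#' @param cell_count Number of cells in the sample (> 0).
#' @param reference_count Reference cell number. Default 1e5.
#' @return pg per `reference_count` cells. Vectorized over all arguments.
#' @examples
#' elisa_normalize(200, 0.5, 50000)  # 200 pg per 1e5 cells
#' @export
elisa_normalize <- function(concentration_pg_ml, volume_ml, cell_count,
                            reference_count = 1e5) {
  if (any(!is.finite(concentration_pg_ml)) || any(concentration_pg_ml < 0))
    stop("concentration must be nonnegative")
  if (any(!is.finite(volume_ml)) || any(volume_ml <= 0))
    stop("volume must be positive")
  if (any(!is.finite(cell_count)) || any(cell_count <= 0))
    stop("cell count must be positive")
  concentration_pg_ml * volume_ml / cell_count * reference_count
}
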