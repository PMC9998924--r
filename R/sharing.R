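#' Multi-cell droplet IL-10 sharing model
#'
#' In multi-cell droplets, IL-10 secreted by a minority of producer cells
#' (fraction \eqn{b}, roughly 10\% of LPS-stimulated macrophages) can
#' transfer to co-encapsulated non-producers and render them IL-10
#' positive. These functions predict the population fraction of positive
#' cells as a function of the mean occupancy \eqn{a}:
#'
#' \itemize{
#'   \item [paper_fraction_positive()] evaluates the published summation
#'     formula term by term:
#'     \deqn{100 \cdot \frac{\sum_{k=1}^{k_{max}} \frac{a^k e^{-a}}{k!}\, b\, k^2}
#'                         {\sum_{k=1}^{k_{max}} \frac{a^k e^{-a}}{k!}\, k}}
#'     The numerator term \eqn{b k^2} counts \eqn{bk} expected producers
#'     each converting all \eqn{k} cells, which double-counts droplets
#'     holding two or more producers; the untruncated sums collapse to the
#'     closed form \eqn{100\, b\,(1+a)}, which exceeds 100\% for
#'     \eqn{a > 1/b - 1}. A cap at 100\% is applied by default and the
#'     uncapped value is always reported alongside.
#'   \item [exact_fraction_positive()] is the exact expectation under the
#'     same all-or-none sharing mechanism, without double counting: a
#'     droplet of size \eqn{k} contributes \eqn{k} positive cells if it
#'     holds at least one producer, so the expected positive count is
#'     \eqn{k (1 - (1-b)^k)} and the prediction is
#'     \deqn{100 \cdot \frac{\sum_k p(k)\, k\, (1-(1-b)^k)}{\sum_k p(k)\, k}}
#'     which never exceeds 100\%.
#'   \item [simulate_sharing()] is the stochastic counterpart: Poisson
#'     occupancies, binomial producers, all-or-none positivity per droplet.
#' }
#'
#' @param a Mean cells per droplet (> 0). May be a vector.
#' @param b Producer fraction in [0, 1].
#' @param kmax Truncation of the occupancy sum. Default 30.
#' @param cap_at_100 Cap the reported fraction at 100\%? Default `TRUE`.
#' @return An object of class `"sharing_prediction"`: a data frame with
#'   columns `a`, `method`, `fraction_pct` (capped when requested) and
#'   `uncapped_pct`.
#' @examples
#' paper_fraction_positive(a = 2, b = 0.1)    # 30%
#' exact_fraction_positive(a = 2, b = 0.1)    # slightly below 30%
#' @name sharing_model
NULL

check_sharing_params <- function(a, b, kmax) {
  if (!is.numeric(a) || length(a) < 1 || any(!is.finite(a)) || any(a <= 0))
    stop("`a` (mean cells/droplet) must be finite and positive")
  if (!is.numeric(b) || length(b) != 1 || !is.finite(b) || b < 0 || b > 1)
    stop("`b` (producer fraction) must lie in [0, 1]")
  check_kmax(kmax)
}

sharing_prediction <- function(a, method, uncapped, cap_at_100,
                               lower = NULL, upper = NULL) {
  out <- data.frame(
    a = a, method = method,
    fraction_pct = if (cap_at_100) pmin(uncapped, 100) else uncapped,
    uncapped_pct = uncapped
  )
  if (!is.null(lower)) {
    out$lower_pct <- if (cap_at_100) pmin(lower, 100) else lower
    out$upper_pct <- if (cap_at_100) pmin(upper, 100) else upper
  }
  class(out) <- c("sharing_prediction", "data.frame")
  attr(out, "cap_at_100") <- cap_at_100
  out
}

#' @export
print.sharing_prediction <- function(x, digits = 4, ...) {
  cat("Predicted fraction of IL-10 positive cells (%)\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' @rdname sharing_model
#' @export
paper_fraction_positive <- function(a, b, kmax = 30, cap_at_100 = TRUE) {
  kmax <- check_sharing_params(a, b, kmax)
  k <- seq_len(kmax)
  uncapped <- vapply(a, function(ai) {
    terms <- stats::dpois(k, lambda = ai)
    100 * sum(terms * b * k^2) / sum(terms * k)
  }, numeric(1))
  sharing_prediction(a, "paper-formula", uncapped, cap_at_100)
}

#' @rdname sharing_model
#' @export
exact_fraction_positive <- function(a, b, kmax = 30, cap_at_100 = TRUE) {
  kmax <- check_sharing_params(a, b, kmax)
  k <- seq_len(kmax)
  uncapped <- vapply(a, function(ai) {
    terms <- stats::dpois(k, lambda = ai)
    100 * sum(terms * k * (1 - (1 - b)^k)) / sum(terms * k)
  }, numeric(1))
  sharing_prediction(a, "exact", uncapped, cap_at_100)
}

#' Simulate IL-10 sharing in a droplet population
#'
#' Draws droplet occupancies from Poisson(`a`) and producer counts from
#' Binomial(k, `b`); every cell in a droplet holding at least one producer
#' is scored IL-10 positive. Empty droplets contribute no cells. The
#' standard error treats droplets (not cells) as the independent units,
#' via the usual linearization of the ratio estimator.
#'
#' @inheritParams sharing_model
#' @param n_droplets Number of droplets to simulate (>= 1).
#' @param seed Optional integer seed.
#' @return A list with `fraction_pct`, `se_pct`, `n_cells`, `n_droplets`,
#'   and a `droplets` data frame (`droplet_id`, `n_cells`, `n_producers`,
#'   `n_positive`).
#' @examples
#' sim <- simulate_sharing(a = 4, b = 0.1, n_droplets = 2000, seed = 1)
#' sim$fraction_pct
#' @export
simulate_sharing <- function(a, b, n_droplets, kmax = 30, seed = NULL) {
  check_sharing_params(a, b, kmax)
  if (length(a) != 1) stop("`a` must be a single value for simulation")
  if (!is.numeric(n_droplets) || length(n_droplets) != 1 || n_droplets < 1)
    stop("`n_droplets` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  n_droplets <- as.integer(n_droplets)
  k <- stats::rpois(n_droplets, lambda = a)
  producers <- integer(n_droplets)
  nz <- k > 0
  producers[nz] <- stats::rbinom(sum(nz), size = k[nz], prob = b)
  positive <- ifelse(producers >= 1, k, 0L)
  n_cells <- sum(k)
  if (n_cells == 0)
    stop("all simulated droplets were empty; increase `n_droplets` or `a`")
  frac <- sum(positive) / n_cells
  # ratio-estimator SE with droplets as clusters
  resid <- positive - frac * k
  se <- sqrt(sum(resid^2)) / n_cells
  list(
    fraction_pct = 100 * frac,
    se_pct = 100 * se,
    n_cells = n_cells,
    n_droplets = n_droplets,
    droplets = data.frame(droplet_id = seq_len(n_droplets), n_cells = k,
                          n_producers = producers, n_positive = positive)
  )
}

#' Estimate the IL-10 producer fraction from single-cell events
#'
#' For events measured in the single-cell regime (occupancy <= 1, so no
#' sharing), the producer fraction \eqn{b} is the proportion of cells
#' whose IL-10 signal exceeds the positivity threshold. A 95\% Wilson
#' score interval is attached; with zero positives the interval is
#' naturally one-sided at zero.
#'
#' The threshold defaults to the 99th percentile of an unstimulated
#' control signal distribution when one is supplied, mirroring gating
#' against unstimulated controls. A percentile gate lets a known
#' fraction of background events through, so when a control sample
#' defines the gate the estimate is background-corrected by default:
#' the control's own exceedance of the gate is subtracted from the
#' event exceedance (the usual percent-positive-minus-control
#' convention), floored at zero.
#'
#' @param events A data frame with an `il10_signal` column (an
#'   `EventTable`, e.g. from [generate_single_cell_events()]), or a
#'   numeric vector of IL-10 signals.
#' @param positivity_threshold Signal above which a cell counts as an
#'   IL-10 producer. Required unless `control_signal` is given.
#' @param control_signal Optional numeric vector of unstimulated-control
#'   signals; the threshold is then their 99th percentile.
#' @param background_correct Subtract the control's gate exceedance?
#'   Default `TRUE` when `control_signal` is supplied, otherwise no
#'   correction is possible and the raw proportion is reported.
#' @param conf_level Confidence level for the Wilson interval. Default 0.95.
#' @return A list with `b_hat`, `lower`, `upper`, `n_positive`, `n`,
#'   `threshold`, of class `"producer_fraction"`.
#' @examples
#' sig <- c(rep(10, 90), rep(1000, 10))
#' estimate_producer_fraction(sig, positivity_threshold = 100)$b_hat  # 0.1
#' @export
estimate_producer_fraction <- function(events, positivity_threshold = NULL,
                                       control_signal = NULL,
                                       background_correct = !is.null(control_signal),
                                       conf_level = 0.95) {
  signal <- if (is.data.frame(events)) {
    if (!"il10_signal" %in% names(events))
      stop("`events` must contain an `il10_signal` column")
    events$il10_signal
  } else events
  if (!is.numeric(signal) || length(signal) == 0)
    stop("no events supplied")
  if (is.null(positivity_threshold)) {
    if (is.null(control_signal))
      stop("supply `positivity_threshold` or `control_signal`")
    positivity_threshold <- stats::quantile(control_signal, 0.99, names = FALSE)
  }
  background <- if (background_correct) {
    if (is.null(control_signal))
      stop("background correction needs `control_signal`")
    mean(control_signal > positivity_threshold)
  } else 0
  n <- length(signal)
  x <- sum(signal > positivity_threshold)
  ci <- wilson_interval(x, n, conf_level)
  structure(
    list(b_hat = max(0, x / n - background),
         lower = max(0, ci[1] - background),
         upper = max(0, ci[2] - background),
         n_positive = x, n = n, background = background,
         threshold = positivity_threshold, conf_level = conf_level),
    class = "producer_fraction"
  )
}

# Wilson score interval for a binomial proportion
wilson_interval <- function(x, n, conf_level = 0.95) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, center - half), min(1, center + half))
}

#' @export
print.producer_fraction <- function(x, ...) {
  cat(sprintf(
    "Producer fraction: b = %.4f (%d/%d positive), %g%% Wilson CI [%.4f, %.4f]\n",
    x$b_hat, x$n_positive, x$n, 100 * x$conf_level, x$lower, x$upper))
  cat(sprintf("  positivity threshold: %g%s\n", x$threshold,
              if (x$background > 0)
                sprintf(" (background-corrected by %.4f)", x$background) else ""))
  invisible(x)
}

#' Confidence band for the modelled positive fraction
#'
#' Propagates replicate-to-replicate variation in the producer fraction
#' into a 95\% band around the model curve. The default (`method =
#' "mapped"`) forms a t-based confidence interval for the mean of the
#' replicate `b` values and maps its endpoints through the model — valid
#' because the prediction is monotone increasing in `b` at fixed `a`. The
#' alternative (`method = "percentile"`) evaluates the model per replicate
#' and takes the t-interval across the replicate predictions at each `a`.
#'
#' @param b_values Producer fractions from >= 2 independent replicates.
#' @param a_grid Grid of mean occupancies at which to evaluate the band.
#' @param model `"paper"` (the published formula) or `"exact"`.
#' @param method Band construction, `"mapped"` (default) or `"percentile"`.
#' @param conf_level Confidence level. Default 0.95.
#' @inheritParams sharing_model
#' @return A `"sharing_prediction"` data frame with `lower_pct` and
#'   `upper_pct` columns.
#' @examples
#' prediction_band(c(0.08, 0.10, 0.12), a_grid = c(2, 4, 8, 12))
#' @export
prediction_band <- function(b_values, a_grid,
                            model = c("paper", "exact"),
                            method = c("mapped", "percentile"),
                            kmax = 30, cap_at_100 = TRUE, conf_level = 0.95) {
  model <- match.arg(model)
  method <- match.arg(method)
  if (!is.numeric(b_values) || length(b_values) < 2)
    stop("need >= 2 replicate producer fractions to form a band")
  if (any(b_values < 0 | b_values > 1)) stop("producer fractions must lie in [0, 1]")
  predict_fn <- if (model == "paper") paper_fraction_positive else exact_fraction_positive
  n <- length(b_values)
  b_bar <- mean(b_values)
  point <- predict_fn(a_grid, b_bar, kmax, cap_at_100 = FALSE)$uncapped_pct
  if (method == "mapped") {
    half <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1) *
      stats::sd(b_values) / sqrt(n)
    b_lo <- max(0, b_bar - half)
    b_hi <- min(1, b_bar + half)
    lower <- predict_fn(a_grid, b_lo, kmax, cap_at_100 = FALSE)$uncapped_pct
    upper <- predict_fn(a_grid, b_hi, kmax, cap_at_100 = FALSE)$uncapped_pct
  } else {
    per_rep <- vapply(b_values, function(bi)
      predict_fn(a_grid, bi, kmax, cap_at_100 = FALSE)$uncapped_pct,
      numeric(length(a_grid)))
    per_rep <- matrix(per_rep, nrow = length(a_grid))
    m <- rowMeans(per_rep)
    s <- apply(per_rep, 1, stats::sd)
    half <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1) * s / sqrt(n)
    lower <- pmax(0, m - half)
    upper <- m + half
  }
  sharing_prediction(a_grid, paste0(model, "-band-", method), point,
                     cap_at_100, lower = lower, upper = upper)
}
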