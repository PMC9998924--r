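#' Droplet loading specification
#'
#' Physical loading parameters that determine the mean droplet occupancy.
#' Cell encapsulation in droplet microfluidics is a random process: the
#' number of cells per droplet follows a Poisson distribution whose mean
#' \eqn{a} is set by the cell concentration times the droplet volume.
#'
#' The default droplet volume of 0.8 nL reproduces the standard pairings
#' used for multi-cell experiments (2.5, 5, 10, 15 x 10^6 cells/mL giving
#' roughly 2, 4, 8 and 12 cells per droplet); override it for other devices.
#'
#' @param cell_concentration Cell concentration in cells per mL (> 0).
#' @param droplet_volume Droplet volume in nL (> 0). Default 0.8.
#' @param kmax Maximum occupancy considered when tabulating the
#'   distribution (positive integer). Default 30.
#' @return An object of class `"droplet_spec"`.
#' @examples
#' spec <- droplet_spec(2.5e6)        # ~2 cells/droplet
#' mean_occupancy(spec)
#' @export
droplet_spec <- function(cell_concentration, droplet_volume = 0.8, kmax = 30) {
  stopifnot(is.numeric(cell_concentration), length(cell_concentration) == 1,
            is.numeric(droplet_volume), length(droplet_volume) == 1)
  if (!is.finite(cell_concentration) || cell_concentration <= 0)
    stop("`cell_concentration` must be a finite positive number (cells/mL)")
  if (!is.finite(droplet_volume) || droplet_volume <= 0)
    stop("`droplet_volume` must be a finite positive number (nL)")
  kmax <- check_kmax(kmax)
  structure(
    list(cell_concentration = cell_concentration,
         droplet_volume = droplet_volume,
         kmax = kmax),
    class = "droplet_spec"
  )
}

check_kmax <- function(kmax) {
  if (!is.numeric(kmax) || length(kmax) != 1 || !is.finite(kmax) ||
      kmax < 1 || kmax != round(kmax))
    stop("`kmax` must be a positive integer")
  as.integer(kmax)
}

#' @export
print.droplet_spec <- function(x, ...) {
  cat("Droplet loading specification\n")
  cat(sprintf("  cell concentration: %g cells/mL\n", x$cell_concentration))
  cat(sprintf("  droplet volume:     %g nL\n", x$droplet_volume))
  cat(sprintf("  mean occupancy a:   %g cells/droplet (kmax = %d)\n",
              mean_occupancy(x), x$kmax))
  invisible(x)
}

#' Mean cells per droplet
#'
#' Mean Poisson occupancy \eqn{a} = cell concentration (cells/mL) x droplet
#' volume (nL) x 1e-6 (mL per nL). Linear in both factors; no rounding.
#'
#' @param spec A [droplet_spec()], or a cell concentration in cells/mL.
#' @param droplet_volume Droplet volume in nL, used when `spec` is numeric.
#' @return Mean occupancy in cells per droplet.
#' @examples
#' mean_occupancy(2.5e6, 0.8)  # 2
#' mean_occupancy(15e6, 0.8)   # 12
#' @export
mean_occupancy <- function(spec, droplet_volume = 0.8) {
  if (inherits(spec, "droplet_spec")) {
    conc <- spec$cell_concentration
    vol <- spec$droplet_volume
  } else {
    conc <- spec
    vol <- droplet_volume
    if (!is.numeric(conc) || any(!is.finite(conc)) || any(conc <= 0))
      stop("cell concentration must be finite and positive")
    if (!is.numeric(vol) || any(!is.finite(vol)) || any(vol <= 0))
      stop("droplet volume must be finite and positive")
  }
  conc * vol * 1e-6
}

#' Poisson occupancy distribution of a droplet population
#'
#' Tabulates the Poisson probability mass \eqn{a^k e^{-a} / k!} at
#' occupancies k = 0..kmax. `raw_terms` are the untruncated formula values
#' (they sum to at most 1; the deficit is the mass beyond `kmax`);
#' `normalized_pmf` rescales them to sum to exactly 1 for simulation and
#' goodness-of-fit use.
#'
#' Evaluation goes through [stats::dpois()], which works on the log scale
#' and is therefore overflow-safe for large k (up to well beyond k = 170,
#' where naive factorials overflow double precision).
#'
#' @param a Mean cells per droplet (> 0), or a [droplet_spec()].
#' @param kmax Maximum occupancy tabulated. Default 30.
#' @return An object of class `"occupancy_pmf"` with fields `a`, `k`,
#'   `raw_terms`, `normalized_pmf`.
#' @examples
#' pmf <- occupancy_pmf(2)
#' pmf$raw_terms[1]  # P(k = 0) = exp(-2)
#' @export
occupancy_pmf <- function(a, kmax = 30) {
  if (inherits(a, "droplet_spec")) {
    kmax <- a$kmax
    a <- mean_occupancy(a)
  }
  if (!is.numeric(a) || length(a) != 1 || !is.finite(a) || a <= 0)
    stop("`a` (mean cells/droplet) must be a finite positive number")
  kmax <- check_kmax(kmax)
  k <- 0:kmax
  raw <- stats::dpois(k, lambda = a)
  structure(
    list(a = a, k = k, raw_terms = raw,
         normalized_pmf = raw / sum(raw)),
    class = "occupancy_pmf"
  )
}

#' @export
print.occupancy_pmf <- function(x, digits = 4, ...) {
  cat(sprintf("Poisson droplet occupancy, a = %g cells/droplet, k = 0..%d\n",
              x$a, max(x$k)))
  cat(sprintf("  mass captured by truncation: %.6f\n", sum(x$raw_terms)))
  show <- x$k <= min(max(x$k), 12)
  tab <- round(rbind(raw = x$raw_terms[show], normalized = x$normalized_pmf[show]),
               digits)
  colnames(tab) <- paste0("k=", x$k[show])
  print(tab)
  if (any(!show)) cat("  ...\n")
  invisible(x)
}

#' @export
plot.occupancy_pmf <- function(x, ...) {
  graphics::barplot(x$normalized_pmf, names.arg = x$k,
                    xlab = "cells per droplet", ylab = "probability",
                    main = sprintf("Poisson occupancy, a = %g", x$a), ...)
  invisible(x)
}

#' Simulate random cell encapsulation
#'
#' Draws independent per-droplet cell counts from an untruncated
#' Poisson(a) distribution — the physical loading process puts no upper
#' bound on occupancy, so the simulation does not either (truncation is a
#' property of the tabulated model, not of the droplets).
#'
#' @param a Mean cells per droplet (> 0), or a [droplet_spec()].
#' @param n_droplets Number of droplets to simulate (>= 1).
#' @param seed Optional integer seed for reproducibility.
#' @return Integer vector of per-droplet cell counts.
#' @examples
#' counts <- simulate_encapsulation(2, 1000, seed = 1)
#' mean(counts)
#' @export
simulate_encapsulation <- function(a, n_droplets, seed = NULL) {
  if (inherits(a, "droplet_spec")) a <- mean_occupancy(a)
  if (!is.numeric(a) || length(a) != 1 || !is.finite(a) || a <= 0)
    stop("`a` must be a finite positive number")
  if (!is.numeric(n_droplets) || length(n_droplets) != 1 || n_droplets < 1)
    stop("`n_droplets` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  stats::rpois(as.integer(n_droplets), lambda = a)
}

#' Compare observed droplet occupancy with the Poisson expectation
#'
#' Builds an observed-vs-expected table over occupancies 0..kmax and a
#' chi-square goodness-of-fit statistic, the computational counterpart of
#' overlaying a Poisson curve on manually counted cell distributions.
#' Expected frequencies are total x pmf at each k; bins with expected
#' count below `pool_floor` are pooled into the tail bin before the
#' statistic is formed (the standard small-expected-count safeguard).
#'
#' @param observed_counts Either a vector of per-droplet cell counts, or a
#'   named numeric histogram whose names are occupancies ("0", "1", ...).
#' @param a Mean cells per droplet under the null.
#' @param kmax Maximum occupancy tabulated. Defaults to covering the data.
#' @param renormalize If `TRUE` (default) expected frequencies use the
#'   truncation-renormalized pmf (so expected totals match the observed
#'   total exactly); if `FALSE` the raw untruncated Poisson terms are used.
#' @param pool_floor Bins with expected count below this are pooled into
#'   the tail. Default 1.
#' @return An object of class `"occupancy_fit"`: a comparison table
#'   (`k`, `observed`, `expected`), the pooled table actually tested,
#'   `statistic`, `df` and `p_value`.
#' @examples
#' counts <- simulate_encapsulation(4, 200, seed = 7)
#' compare_occupancy(counts, a = 4)
#' @export
compare_occupancy <- function(observed_counts, a, kmax = NULL,
                              renormalize = TRUE, pool_floor = 1) {
  hist <- as_occupancy_histogram(observed_counts)
  total <- sum(hist)
  if (total < 1) stop("observed histogram is empty")
  if (is.null(kmax)) kmax <- max(30L, length(hist) - 1L)
  kmax <- check_kmax(kmax)
  if (length(hist) - 1L > kmax)
    kmax <- length(hist) - 1L
  pmf <- occupancy_pmf(a, kmax)
  obs <- c(hist, rep(0, kmax + 1L - length(hist)))
  p <- if (renormalize) pmf$normalized_pmf else pmf$raw_terms
  expected <- total * p
  table <- data.frame(k = 0:kmax, observed = obs, expected = expected)

  # pool sparse tail bins (expected < pool_floor) into the last kept bin
  keep <- which(expected >= pool_floor)
  if (length(keep) == 0) stop("all expected counts below `pool_floor`")
  cut <- max(keep)
  pooled_obs <- c(obs[seq_len(cut)], sum(obs[-seq_len(cut)]))
  pooled_exp <- c(expected[seq_len(cut)], sum(expected[-seq_len(cut)]))
  lead <- which(pooled_exp >= pool_floor)
  if (lead[1] > 1) {  # pool a sparse head too (tiny P(0) at large a)
    h <- seq_len(lead[1] - 1L)
    pooled_obs <- c(sum(pooled_obs[h]) + pooled_obs[lead[1]], pooled_obs[-seq_len(lead[1])])
    pooled_exp <- c(sum(pooled_exp[h]) + pooled_exp[lead[1]], pooled_exp[-seq_len(lead[1])])
  }
  statistic <- sum((pooled_obs - pooled_exp)^2 / pooled_exp)
  df <- max(length(pooled_obs) - 1L, 1L)
  structure(
    list(a = a, total = total, table = table,
         pooled = data.frame(observed = pooled_obs, expected = pooled_exp),
         statistic = statistic, df = df,
         p_value = stats::pchisq(statistic, df, lower.tail = FALSE),
         renormalize = renormalize),
    class = "occupancy_fit"
  )
}

as_occupancy_histogram <- function(x) {
  if (!is.numeric(x) || length(x) == 0) stop("observed counts must be numeric and non-empty")
  if (is.null(names(x))) {
    if (any(x < 0) || any(x != round(x))) stop("cell counts must be nonnegative integers")
    tabulate(x + 1L, nbins = max(x) + 1L)
  } else {
    k <- suppressWarnings(as.integer(names(x)))
    if (any(is.na(k)) || any(k < 0)) stop("histogram names must be nonnegative occupancies")
    out <- numeric(max(k) + 1L)
    out[k + 1L] <- x
    out
  }
}

#' @export
print.occupancy_fit <- function(x, ...) {
  cat(sprintf("Poisson occupancy goodness of fit (a = %g, n = %g droplets)\n",
              x$a, x$total))
  cat(sprintf("  chi-square = %.4g on %d df, p = %.4g (%s expected pmf)\n",
              x$statistic, x$df, x$p_value,
              if (x$renormalize) "renormalized" else "raw truncated"))
  invisible(x)
}
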