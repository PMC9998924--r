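#' Synthetic-data generator configuration
#'
#' Bundles every parameter of the forward models used to emulate the
#' pipeline's inputs: a bimodal producer/non-producer single-cell
#' secretion distribution, Poisson multi-cell droplets with
#' producer-to-co-occupant cytokine transfer, monotone titration
#' standards with multiplicative noise, and density-dependent ELISA time
#' courses in which higher density shortens the production window.
#'
#' Defaults reflect the study conditions this package models: ~10\% of
#' LPS-stimulated macrophages secrete IL-10; multi-cell droplets at mean
#' occupancies 2, 4, 8 and 12; densities 2.5, 5, 10 and 15 x 10^6
#' cells/mL sampled at 0, 2, 4, 8 and 24 h; IL-10 production shutting
#' off at 24, 20, 12 and 8 h (earlier at higher density, with the
#' highest density done by 8 h) and TNF-alpha at 24, 16, 8 and 4 h with
#' post-peak clearance at the two highest densities. Per-producer
#' secretion is lognormal with median 1 pg/cell and geometric SD 2 — an
#' order-of-magnitude scale, configurable, since absolute per-cell
#' amounts are donor- and assay-dependent.
#'
#' @param producer_fraction Probability that a stimulated cell secretes
#'   IL-10. Default 0.10.
#' @param secretion_median_pg,secretion_gsd Median (pg/cell) and
#'   geometric SD of the lognormal per-producer IL-10 secretion.
#' @param background_median,background_gsd Lognormal background signal
#'   (MFI) of non-producers / unstimulated cells.
#' @param signal_noise_gsd Multiplicative lognormal measurement noise on
#'   rendered signals (geometric SD; 1 = noise-free). Default 1.05.
#' @param titration_params 4PL parameters (A, D, C, B) of the generative
#'   fluorescence response.
#' @param titration_concentrations Standard concentrations, pg/mL.
#' @param titration_noise_gsd Multiplicative noise on standard signals.
#' @param conversion pg/cell per pg/mL linking secreted amount to the
#'   concentration axis of the titration response. Default 1e-3.
#' @param occupancy_means Mean cells/droplet of the multi-cell
#'   conditions. Default c(2, 4, 8, 12).
#' @param n_droplets Droplets per multi-cell condition. Default 5000.
#' @param densities Culture densities, cells/mL. Default
#'   c(2.5e6, 5e6, 10e6, 15e6).
#' @param timepoints_h ELISA sampling times. Default c(0, 2, 4, 8, 24).
#' @param il10_shutoff_h,tnfa_shutoff_h Production shutoff times per
#'   density, strictly decreasing in density.
#' @param il10_total_pg,tnfa_total_pg Plateau totals per density, pg per
#'   1e5 cells (lower at higher density).
#' @param tnfa_decay_per_h Post-shutoff exponential clearance rate of
#'   TNF-alpha at the two highest densities. Default 0.05.
#' @param n_donors Donors for the time-course generator. Default 3.
#' @param donor_sdlog SD of the lognormal multiplicative donor effect on
#'   totals. Default 0.2.
#' @return A list of class `"generator_config"`.
#' @export
generator_config <- function(producer_fraction = 0.10,
                             secretion_median_pg = 1,
                             secretion_gsd = 2,
                             background_median = 60,
                             background_gsd = 1.5,
                             signal_noise_gsd = 1.05,
                             titration_params = c(A = 50, D = 50000, C = 500, B = 1.2),
                             titration_concentrations = 10^seq(0, 4, by = 0.5),
                             titration_noise_gsd = 1.02,
                             conversion = 1e-3,
                             occupancy_means = c(2, 4, 8, 12),
                             n_droplets = 5000,
                             densities = c(2.5e6, 5e6, 10e6, 15e6),
                             timepoints_h = c(0, 2, 4, 8, 24),
                             il10_shutoff_h = c(24, 20, 12, 8),
                             tnfa_shutoff_h = c(24, 16, 8, 4),
                             il10_total_pg = c(1200, 900, 550, 350),
                             tnfa_total_pg = c(8000, 7000, 4500, 3000),
                             tnfa_decay_per_h = 0.05,
                             n_donors = 3,
                             donor_sdlog = 0.2) {
  cfg <- list(producer_fraction = producer_fraction,
              secretion_median_pg = secretion_median_pg,
              secretion_gsd = secretion_gsd,
              background_median = background_median,
              background_gsd = background_gsd,
              signal_noise_gsd = signal_noise_gsd,
              titration_params = titration_params,
              titration_concentrations = titration_concentrations,
              titration_noise_gsd = titration_noise_gsd,
              conversion = conversion,
              occupancy_means = occupancy_means,
              n_droplets = n_droplets,
              densities = densities,
              timepoints_h = timepoints_h,
              il10_shutoff_h = il10_shutoff_h,
              tnfa_shutoff_h = tnfa_shutoff_h,
              il10_total_pg = il10_total_pg,
              tnfa_total_pg = tnfa_total_pg,
              tnfa_decay_per_h = tnfa_decay_per_h,
              n_donors = n_donors,
              donor_sdlog = donor_sdlog)
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  b <- cfg$producer_fraction
  if (!is.numeric(b) || b < 0 || b > 1)
    stop("producer_fraction must lie in [0, 1]")
  scales <- c(cfg$secretion_median_pg, cfg$secretion_gsd,
              cfg$background_median, cfg$background_gsd,
              cfg$signal_noise_gsd, cfg$titration_noise_gsd,
              cfg$conversion, cfg$il10_total_pg, cfg$tnfa_total_pg)
  if (any(!is.finite(scales)) || any(scales <= 0))
    stop("all scale parameters must be positive")
  if (length(cfg$il10_shutoff_h) != length(cfg$densities) ||
      length(cfg$tnfa_shutoff_h) != length(cfg$densities))
    stop("shutoff maps must give one time per density")
  if (any(diff(cfg$il10_shutoff_h) >= 0) || any(diff(cfg$tnfa_shutoff_h) >= 0))
    stop("shutoff times must be strictly decreasing in density")
  if (is.unsorted(cfg$densities, strictly = TRUE))
    stop("densities must be strictly increasing")
  if (is.unsorted(cfg$timepoints_h, strictly = TRUE))
    stop("timepoints must be strictly increasing")
  invisible(cfg)
}

# render a secreted per-cell amount (pg) into an MFI through the
# generative 4PL response, with multiplicative measurement noise
render_signal <- function(amount_pg, cfg) {
  p <- cfg$titration_params
  conc <- amount_pg / cfg$conversion
  clean <- unname(p["A"] + (p["D"] - p["A"]) / (1 + (conc / p["C"])^(-p["B"])))
  if (cfg$signal_noise_gsd > 1)
    clean <- clean * stats::rlnorm(length(clean), 0, log(cfg$signal_noise_gsd))
  clean
}

draw_background <- function(n, cfg) {
  stats::rlnorm(n, log(cfg$background_median), log(cfg$background_gsd))
}

#' Generate synthetic single-cell secretion events
#'
#' Each cell is independently an IL-10 producer with probability
#' `producer_fraction`; producers draw a lognormal secreted amount which
#' is rendered into fluorescence through the generative titration
#' response, non-producers draw from the background distribution. All
#' cells get a positive TNF-alpha signal — essentially every stimulated
#' macrophage secretes TNF-alpha — drawn well above background.
#'
#' @param n_cells Number of cells.
#' @param config A [generator_config()].
#' @param donor,condition Labels stored in the table.
#' @param seed Optional integer seed.
#' @return An `EventTable` data frame: `cell_id`, `donor`, `condition`,
#'   `tnfa_signal`, `il10_signal`, `viable`, plus ground-truth columns
#'   `true_producer` and `true_amount_pg` (0 for non-producers) for
#'   recovery testing.
#' @export
generate_single_cell_events <- function(n_cells, config = generator_config(),
                                        donor = "D1", condition = "single-cell",
                                        seed = NULL) {
  validate_generator_config(config)
  if (!is.null(seed)) set.seed(seed)
  n_cells <- as.integer(n_cells)
  producer <- stats::runif(n_cells) < config$producer_fraction
  il10 <- draw_background(n_cells, config)
  true_amount <- numeric(n_cells)
  if (any(producer)) {
    amount <- stats::rlnorm(sum(producer),
                            log(config$secretion_median_pg),
                            log(config$secretion_gsd))
    true_amount[producer] <- amount
    il10[producer] <- render_signal(amount, config)
  }
  tnfa_amount <- stats::rlnorm(n_cells, log(10 * config$secretion_median_pg),
                               log(config$secretion_gsd))
  data.frame(
    cell_id = seq_len(n_cells),
    donor = donor, condition = condition,
    tnfa_signal = render_signal(tnfa_amount, config),
    il10_signal = il10,
    viable = TRUE,
    true_producer = producer,
    true_amount_pg = true_amount
  )
}

#' Generate synthetic multi-cell droplet datasets
#'
#' Implements the exact sharing mechanism as a forward model, per
#' occupancy condition: droplet occupancy ~ Poisson(a), producer count ~
#' Binomial(k, b), and every cell in a droplet holding at least one
#' producer is IL-10 positive. Positive cells receive an equal share of
#' the droplet's total secreted IL-10, rendered into fluorescence through
#' the titration response; negative cells draw background signal.
#'
#' @param config A [generator_config()]; conditions come from its
#'   `occupancy_means` and `n_droplets`.
#' @param seed Optional integer seed.
#' @return A list with one element per occupancy mean, each holding
#'   `a`, `droplets` (droplet_id, n_cells, n_producers, n_positive) and
#'   `events` (an `EventTable` with `true_positive` flags).
#' @export
generate_multicell_dataset <- function(config = generator_config(), seed = NULL) {
  validate_generator_config(config)
  if (!is.null(seed)) set.seed(seed)
  lapply(config$occupancy_means, function(a) {
    k <- stats::rpois(config$n_droplets, lambda = a)
    producers <- integer(length(k))
    nz <- k > 0
    producers[nz] <- stats::rbinom(sum(nz), size = k[nz],
                                   prob = config$producer_fraction)
    positive <- producers >= 1
    droplets <- data.frame(droplet_id = seq_along(k), n_cells = k,
                           n_producers = producers,
                           n_positive = ifelse(positive, k, 0L))
    # expand to per-cell events
    cell_droplet <- rep(seq_along(k), k)
    n_cells <- length(cell_droplet)
    cell_positive <- rep(positive, k)
    il10 <- draw_background(n_cells, config)
    if (any(cell_positive)) {
      tot <- numeric(length(k))
      tot[producers > 0] <- vapply(which(producers > 0), function(i) {
        sum(stats::rlnorm(producers[i], log(config$secretion_median_pg),
                          log(config$secretion_gsd)))
      }, numeric(1))
      share <- (tot / pmax(k, 1))[cell_droplet]   # equal split among occupants
      il10[cell_positive] <- render_signal(share[cell_positive], config)
    }
    tnfa_amount <- stats::rlnorm(n_cells, log(10 * config$secretion_median_pg),
                                 log(config$secretion_gsd))
    events <- data.frame(
      cell_id = seq_len(n_cells),
      donor = "D1",
      condition = sprintf("a=%g", a),
      droplet_id = cell_droplet,
      tnfa_signal = render_signal(tnfa_amount, config),
      il10_signal = il10,
      viable = TRUE,
      true_positive = cell_positive
    )
    list(a = a, droplets = droplets, events = events)
  })
}

#' Generate synthetic titration standards
#'
#' Evaluates the configured 4PL fluorescence response at the standard
#' concentrations and applies multiplicative lognormal noise
#' (`titration_noise_gsd`; set to 1 for noise-free standards exactly on
#' the curve).
#'
#' @param config A [generator_config()].
#' @param cytokine Label column value. Default "IL-10".
#' @param seed Optional integer seed.
#' @return A standards data frame: `cytokine`, `concentration_pg_ml`, `mfi`.
#' @export
generate_titration_standards <- function(config = generator_config(),
                                         cytokine = "IL-10", seed = NULL) {
  validate_generator_config(config)
  if (!is.null(seed)) set.seed(seed)
  p <- config$titration_params
  conc <- config$titration_concentrations
  mfi <- unname(p["A"] + (p["D"] - p["A"]) / (1 + (conc / p["C"])^(-p["B"])))
  if (config$titration_noise_gsd > 1)
    mfi <- mfi * stats::rlnorm(length(mfi), 0, log(config$titration_noise_gsd))
  data.frame(cytokine = cytokine, concentration_pg_ml = conc, mfi = mfi)
}

# cumulative production curve: saturating rise with time constant
# tau = shutoff/3 (so ~95% of the plateau is reached at the shutoff
# time), frozen at the plateau afterwards; optional post-shutoff
# exponential clearance
cumulative_curve <- function(t, total, shutoff, decay = 0) {
  tau <- shutoff / 3
  y <- total * (1 - exp(-pmin(t, shutoff) / tau))
  if (decay > 0) {
    after <- t > shutoff
    y[after] <- y[after] * exp(-decay * (t[after] - shutoff))
  }
  y
}

#' Generate synthetic density-dependent cytokine time courses
#'
#' Emulates ELISA time courses across culture densities: cumulative
#' production rises as total x (1 - exp(-t/tau)) with tau tied to the
#' density-specific shutoff time, plateaus after shutoff, and for
#' TNF-alpha decays after the peak at the two highest densities
#' (producing the negative apparent production rates read as clearance).
#' Higher densities get earlier shutoffs and lower per-cell totals.
#' Donor heterogeneity is a multiplicative lognormal effect on totals.
#'
#' @param config A [generator_config()].
#' @param seed Optional integer seed.
#' @return A timecourse data frame: `donor`, `condition`, `cytokine`,
#'   `density_cells_per_ml`, `timepoint_h`, `amount_pg_per_1e5_cells`.
#' @export
generate_density_timecourse <- function(config = generator_config(), seed = NULL) {
  validate_generator_config(config)
  if (!is.null(seed)) set.seed(seed)
  n_dens <- length(config$densities)
  decay_dens <- if (n_dens >= 2) c(n_dens - 1L, n_dens) else n_dens
  rows <- list()
  for (d in seq_len(config$n_donors)) {
    donor_mult <- stats::rlnorm(1, 0, config$donor_sdlog)
    for (i in seq_len(n_dens)) {
      for (cyt in c("IL-10", "TNFa")) {
        if (cyt == "IL-10") {
          total <- config$il10_total_pg[i]
          shutoff <- config$il10_shutoff_h[i]
          decay <- 0
        } else {
          total <- config$tnfa_total_pg[i]
          shutoff <- config$tnfa_shutoff_h[i]
          decay <- if (i %in% decay_dens) config$tnfa_decay_per_h else 0
        }
        y <- cumulative_curve(config$timepoints_h, total * donor_mult,
                              shutoff, decay)
        rows[[length(rows) + 1L]] <- data.frame(
          donor = sprintf("D%d", d),
          condition = sprintf("%.1fe6/mL", config$densities[i] / 1e6),
          cytokine = cyt,
          density_cells_per_ml = config$densities[i],
          timepoint_h = config$timepoints_h,
          amount_pg_per_1e5_cells = y
        )
      }
    }
  }
  do.call(rbind, rows)
}
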