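test_that("generator configuration enforces its invariants", {
  expect_error(generator_config(producer_fraction = 1.5), "\\[0, 1\\]")
  expect_error(generator_config(secretion_median_pg = -1), "positive")
  expect_error(generator_config(il10_shutoff_h = c(8, 12, 20, 24)),
               "decreasing")
  expect_error(generator_config(il10_shutoff_h = c(24, 12)), "one time per density")
  cfg <- generator_config()
  expect_equal(cfg$producer_fraction, 0.10)
  expect_equal(cfg$occupancy_means, c(2, 4, 8, 12))
  expect_equal(cfg$densities, c(2.5e6, 5e6, 10e6, 15e6))
})

test_that("single-cell generator respects b with bimodal separated signals", {
  cfg <- generator_config()
  expect_equal(sum(generate_single_cell_events(
    500, generator_config(producer_fraction = 0), seed = 1)$true_producer), 0)
  expect_equal(sum(generate_single_cell_events(
    500, generator_config(producer_fraction = 1), seed = 1)$true_producer), 500)
  ev <- generate_single_cell_events(20000, cfg, seed = 4)
  expect_lt(abs(mean(ev$true_producer) - 0.10), 0.01)
  # the two signal modes are separated by an inter-modal gate at 300 MFI:
  # background P(X > 300) ~ 4e-5, producers effectively never below it
  est <- estimate_producer_fraction(ev, positivity_threshold = 300)
  expect_lt(abs(est$b_hat - mean(ev$true_producer)), 0.002)
  # a 99th-percentile control gate admits its nominal 1% of background
  ctrl <- qlnorm(0.99, log(cfg$background_median), log(cfg$background_gsd))
  raw <- estimate_producer_fraction(ev, positivity_threshold = ctrl)
  expect_equal(raw$b_hat, mean(ev$true_producer) * 1 +
                 (1 - mean(ev$true_producer)) * 0.01, tolerance = 0.05)
  # TNFa signal positive for essentially all cells
  expect_true(all(ev$tnfa_signal > 0))
  expect_gt(mean(ev$tnfa_signal > 300), 0.99)
  expect_identical(generate_single_cell_events(100, cfg, seed = 2),
                   generate_single_cell_events(100, cfg, seed = 2))
})

test_that("multi-cell generator realizes the exact sharing mechanism", {
  cfg <- generator_config(n_droplets = 20000)
  sets <- generate_multicell_dataset(cfg, seed = 6)
  for (s in sets) {
    # positivity is all-or-none per droplet
    expect_true(all(s$droplets$n_positive %in% c(0, s$droplets$n_cells)))
    expect_true(all((s$droplets$n_producers >= 1) ==
                      (s$droplets$n_positive == s$droplets$n_cells &
                         s$droplets$n_cells > 0)))
    # generated positive fraction matches the exact expectation within 4 SE
    frac <- 100 * mean(s$events$true_positive)
    k <- s$droplets$n_cells
    resid <- s$droplets$n_positive - (frac / 100) * k
    se <- 100 * sqrt(sum(resid^2)) / sum(k)
    expect_lt(abs(frac - exact_fraction_positive(s$a, 0.1)$fraction_pct),
              4 * se)
  }
  # dilute regime matches the size-biased exact expectation...
  low <- generate_multicell_dataset(
    generator_config(occupancy_means = 0.3, n_droplets = 50000), seed = 9)[[1]]
  expect_lt(abs(100 * mean(low$events$true_positive) -
                  exact_fraction_positive(0.3, 0.1)$fraction_pct), 1)
  # ...and collapses to b itself in the true single-cell limit a -> 0
  sc <- generate_multicell_dataset(
    generator_config(occupancy_means = 0.05, n_droplets = 2e5), seed = 9)[[1]]
  expect_lt(abs(mean(sc$events$true_positive) - 0.1), 0.01)
  expect_identical(generate_multicell_dataset(cfg, seed = 6),
                   generate_multicell_dataset(cfg, seed = 6))
})

test_that("titration standards sit on the configured response and refit cleanly", {
  cfg <- generator_config(titration_noise_gsd = 1)
  std <- generate_titration_standards(cfg)
  p <- cfg$titration_params
  expect_equal(std$mfi,
               fourpl(std$concentration_pg_ml, p["A"], p["D"], p["C"], p["B"]))
  # noiseless refit reproduces the forward map within 0.1% at the knots
  curve <- fit_titration(std)
  expect_lt(max(abs(predict(curve, std$concentration_pg_ml) - std$mfi) / std$mfi),
            1e-3)
  noisy <- generate_titration_standards(generator_config(), seed = 10)
  expect_false(all(noisy$mfi == std$mfi))
  expect_true(all(diff(noisy$mfi) > 0))  # noise small enough to stay monotone
})

test_that("generated tables round-trip losslessly through CSV", {
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  ev <- generate_single_cell_events(200, generator_config(), seed = 14)
  write_table_csv(ev, tmp, units = c(il10_signal = "MFI"))
  back <- read_table_csv(tmp)
  expect_equal(back$il10_signal, ev$il10_signal)
  expect_equal(back$true_producer, ev$true_producer)
  tc <- generate_density_timecourse(generator_config(n_donors = 1), seed = 15)
  write_table_csv(tc, tmp)
  expect_equal(read_table_csv(tmp)$amount_pg_per_1e5_cells,
               tc$amount_pg_per_1e5_cells)
})
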