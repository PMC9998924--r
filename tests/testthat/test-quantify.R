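test_that("log-log titration interpolation passes through knots and round-trips", {
  curve <- fit_titration(two_point_standards())
  expect_equal(predict(curve, 100), 1000)       # log-log linearity
  expect_equal(predict(curve, 10), 100)         # exact at knots
  expect_equal(predict(curve, 1000), 10000)
  expect_equal(predict(curve, 1000, inverse = TRUE), 100)
  std <- data.frame(concentration_pg_ml = 10^seq(0, 4),
                    mfi = fourpl(10^seq(0, 4), 50, 50000, 500, 1.2))
  curve2 <- fit_titration(std)
  set.seed(3)
  conc <- 10^runif(1000, 0, 4)
  sig <- predict(curve2, conc)
  expect_lt(max(abs(predict(curve2, predict(curve2, sig, inverse = TRUE)) - sig) / sig),
            1e-3)
  # strictly monotone inversion
  s <- sort(runif(50, min(std$mfi), max(std$mfi)))
  expect_true(all(diff(predict(curve2, s, inverse = TRUE)) > 0))
})

test_that("titration fitting rejects malformed standards", {
  expect_error(fit_titration(data.frame(concentration_pg_ml = 10, mfi = 100)),
               "at least 2")
  bad <- data.frame(concentration_pg_ml = c(10, 100, 1000),
                    mfi = c(100, 90, 1000))
  expect_error(fit_titration(bad), "rows 1 and 2")
  expect_error(fit_titration(data.frame(concentration_pg_ml = c(10, 10),
                                        mfi = c(1, 2))),
               "strictly increasing")
})

test_that("4PL fit recovers generative parameters from noisy standards", {
  true <- c(A = 50, D = 50000, C = 500, B = 1.2)
  conc <- 10^seq(0, 4, by = 0.25)
  set.seed(17)
  std <- data.frame(concentration_pg_ml = conc,
                    mfi = fourpl(conc, true["A"], true["D"], true["C"], true["B"]) *
                      rlnorm(length(conc), 0, log(1.02)))
  curve <- fit_titration(std, form = "4pl")
  expect_lt(abs(coef(curve)["C"] - true["C"]) / true["C"], 0.05)
  # inverse is a proper inverse of the fitted logistic in-range
  sig <- fourpl(c(30, 300, 3000), true["A"], true["D"], true["C"], true["B"])
  back <- predict(curve, predict(curve, c(30, 300, 3000)), inverse = TRUE)
  expect_equal(back, c(30, 300, 3000), tolerance = 0.02)
})

test_that("signal conversion clamps out-of-range events with flags, never drops", {
  curve <- fit_titration(two_point_standards())
  events <- data.frame(cell_id = 1:4, donor = "D1", condition = "sc",
                       tnfa_signal = 1, il10_signal = c(0, 100, 5000, 1e6),
                       viable = TRUE)
  out <- signal_to_amount(curve, events, conversion = 1)
  expect_equal(nrow(out), 4)                        # counts conserved
  expect_equal(out$below_range, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(out$saturated, c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(out$amount_pg[1], 10)                # clamped to lowest standard
  expect_equal(out$amount_pg[2], 10)                # knot identity
  expect_equal(out$amount_pg[4], 1000)              # clamped to highest
  expect_error(signal_to_amount(curve, events, channel = "missing"), "missing")
})

test_that("totals normalize to the reference count and are order invariant", {
  # 10 cells x 0.5 pg = 5 pg, rescaled by 1e5/10
  expect_equal(total_production(rep(0.5, 10)), 50000)
  expect_equal(total_production(rep(0, 7)), 0)
  set.seed(5)
  amounts <- rlnorm(200)
  expect_equal(total_production(amounts), total_production(sample(amounts)))
  expect_equal(total_production(rep(amounts, 2)), total_production(amounts))
  expect_error(total_production(numeric(0)), "no quantified")
})

test_that("ELISA normalization arithmetic, identity reference and linearity", {
  expect_equal(elisa_normalize(200, 0.5, 50000), 200)
  expect_equal(elisa_normalize(123, 0.7, 4e4, reference_count = 4e4), 123 * 0.7)
  expect_equal(elisa_normalize(50, 1.0, 1e5), 2 * elisa_normalize(50, 0.5, 1e5))
  expect_error(elisa_normalize(50, 0.5, 0), "positive")
})

test_that("population totals recover the generative secretion on synthetic events", {
  cfg <- generator_config(signal_noise_gsd = 1, background_median = 1e-6,
                          background_gsd = 1.000001)
  ev <- generate_single_cell_events(10000, cfg, seed = 8)
  std <- generate_titration_standards(
    generator_config(titration_noise_gsd = 1))
  curve <- fit_titration(std, form = "4pl")
  q <- signal_to_amount(curve, ev, conversion = cfg$conversion)
  # producers only: non-producer background sits below the curve range
  est_total <- sum(q$amount_pg[!q$below_range])
  true_total <- sum(ev$true_amount_pg)
  expect_lt(abs(est_total - true_total) / true_total, 0.05)
})
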