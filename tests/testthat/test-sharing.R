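test_that("published formula matches brute-force summation and its closed form", {
  for (a in grid_a) {
    for (b in c(0.01, 0.05, 0.1, 0.3)) {
      got <- paper_fraction_positive(a, b, cap_at_100 = FALSE)$uncapped_pct
      expect_equal(got, brute_force_paper_formula(a, b), tolerance = 1e-12)
    }
  }
  # untruncated sums collapse to 100 b (1 + a); truncation negligible at a <= 8
  expect_equal(paper_fraction_positive(2, 0.1)$uncapped_pct, 30,
               tolerance = 1e-10)
  expect_equal(paper_fraction_positive(8, 0.3)$uncapped_pct, 100 * 0.3 * 9,
               tolerance = 1e-8)
  expect_equal(paper_fraction_positive(5, 0)$uncapped_pct, 0)
})

test_that("the 100% cap engages where the formula overshoots", {
  pred <- paper_fraction_positive(12, 0.1)
  expect_equal(pred$fraction_pct, 100)
  expect_equal(pred$uncapped_pct, 100 * 0.1 * 13, tolerance = 1e-4)
  uncapped <- paper_fraction_positive(12, 0.1, cap_at_100 = FALSE)
  expect_gt(uncapped$fraction_pct, 100)
  expect_error(paper_fraction_positive(2, 1.2), "\\[0, 1\\]")
})

test_that("exact model hits its boundary cases and brute-force oracle", {
  expect_equal(exact_fraction_positive(3, 1)$fraction_pct, 100)
  expect_equal(exact_fraction_positive(3, 0)$fraction_pct, 0)
  for (a in c(0.5, 2, 8)) {
    for (b in c(0.05, 0.3)) {
      expect_equal(exact_fraction_positive(a, b)$uncapped_pct,
                   brute_force_exact_model(a, b), tolerance = 1e-12)
    }
  }
  expect_true(all(exact_fraction_positive(grid_a, 0.37)$uncapped_pct <= 100))
})

test_that("published formula dominates the exact model, converging as b -> 0", {
  for (a in grid_a) {
    for (b in grid_b) {
      gap <- paper_fraction_positive(a, b, cap_at_100 = FALSE)$uncapped_pct -
        exact_fraction_positive(a, b)$uncapped_pct
      expect_gte(gap, -1e-12)
      if (b > 0 && b < 1) expect_gt(gap, 0)
    }
    paper <- paper_fraction_positive(a, 1e-3, cap_at_100 = FALSE)$uncapped_pct
    exact <- exact_fraction_positive(a, 1e-3)$uncapped_pct
    expect_lt((paper - exact) / exact, 0.01)
  }
})

test_that("both models are monotone in b and in a", {
  b_seq <- seq(0.01, 0.99, by = 0.07)
  for (a in c(0.5, 4, 15)) {
    paper <- sapply(b_seq, function(b)
      paper_fraction_positive(a, b, cap_at_100 = FALSE)$uncapped_pct)
    exact <- sapply(b_seq, function(b)
      exact_fraction_positive(a, b)$uncapped_pct)
    expect_true(all(diff(paper) > 0))
    expect_true(all(diff(exact) > 0))
  }
  a_seq <- seq(0.25, 15, by = 0.5)
  expect_true(all(diff(paper_fraction_positive(a_seq, 0.1,
                                               cap_at_100 = FALSE)$uncapped_pct) > 0))
  expect_true(all(diff(exact_fraction_positive(a_seq, 0.1)$uncapped_pct) > 0))
})

test_that("droplet simulator agrees with the exact expectation", {
  sim <- simulate_sharing(a = 4, b = 0.1, n_droplets = 1e5, seed = 5)
  expect_lt(abs(sim$fraction_pct - exact_fraction_positive(4, 0.1)$fraction_pct),
            4 * sim$se_pct)
  expect_equal(simulate_sharing(2, 0, 1000, seed = 1)$fraction_pct, 0)
  sim1 <- simulate_sharing(2, 1, 1000, seed = 1)
  expect_equal(sim1$fraction_pct, 100)
  expect_identical(simulate_sharing(3, 0.2, 500, seed = 9)$droplets,
                   simulate_sharing(3, 0.2, 500, seed = 9)$droplets)
  expect_error(simulate_sharing(1e-9, 0.1, 2, seed = 1), "empty")
})

test_that("producer fraction estimation counts, bounds and one-sided cases", {
  sig <- c(rep(10, 90), rep(1000, 10))
  est <- estimate_producer_fraction(sig, positivity_threshold = 100)
  expect_equal(est$b_hat, 0.10)
  expect_lt(est$lower, 0.10)
  expect_gt(est$upper, 0.10)
  # Wilson interval cross-checked against the closed form and against
  # the score interval prop.test computes without continuity correction
  z <- qnorm(0.975)
  n <- 100; p <- 0.1
  expect_equal(est$lower,
               ((p + z^2 / (2 * n)) - z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
                 (1 + z^2 / n))
  expect_equal(c(est$lower, est$upper),
               as.numeric(prop.test(10, 100, correct = FALSE)$conf.int),
               tolerance = 1e-10)
  zero <- estimate_producer_fraction(rep(1, 50), positivity_threshold = 100)
  expect_equal(zero$b_hat, 0)
  expect_equal(zero$lower, 0)
  expect_gt(zero$upper, 0)
  expect_error(estimate_producer_fraction(numeric(0), 1), "no events")
  # threshold from an unstimulated control distribution
  set.seed(31)
  ctrl <- rlnorm(5000, log(60), log(1.5))
  est2 <- estimate_producer_fraction(sig, control_signal = ctrl)
  expect_equal(est2$threshold, quantile(ctrl, 0.99, names = FALSE))
})

test_that("prediction band maps the replicate b interval through the model", {
  b_reps <- c(0.08, 0.10, 0.12)
  band <- prediction_band(b_reps, a_grid = c(2, 4, 8, 12))
  expect_equal(band$fraction_pct[band$a == 2], 30)
  # hand-computed t-interval on mean b, mapped through 100 b (1 + a)
  half <- qt(0.975, df = 2) * sd(b_reps) / sqrt(3)
  expect_equal(band$lower_pct[band$a == 2],
               brute_force_paper_formula(2, 0.10 - half), tolerance = 1e-10)
  expect_equal(band$upper_pct[band$a == 2],
               brute_force_paper_formula(2, 0.10 + half), tolerance = 1e-10)
  expect_true(all(band$lower_pct <= band$fraction_pct + 1e-12))
  # identical replicates give a zero-width band
  flat <- prediction_band(c(0.1, 0.1, 0.1), a_grid = c(1, 6))
  expect_equal(flat$lower_pct, flat$upper_pct)
  expect_equal(flat$lower_pct, flat$fraction_pct)
  expect_error(prediction_band(0.1, a_grid = 2), ">= 2")
  # percentile variant stays ordered
  pb <- prediction_band(b_reps, a_grid = c(2, 8), method = "percentile")
  expect_true(all(pb$lower_pct <= pb$upper_pct))
})
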