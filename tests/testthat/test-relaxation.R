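r2_schedule <- c(1, 2, 4, 6, 8, 12, 16, 20, 25, 30) * 0.0156466

test_that("noiseless exponential decays are recovered to solver tolerance", {
  series <- data.frame(delay = r2_schedule, height = 10 * exp(-2.5 * r2_schedule))
  est <- fit_exponential(series, n_mc = 0)
  expect_equal(est$rate, 2.5, tolerance = 1e-8)
  expect_equal(est$I0, 10, tolerance = 1e-8)
  # constant heights: exact R = 0
  flat <- data.frame(delay = r2_schedule, height = rep(7, 10))
  est0 <- fit_exponential(flat, n_mc = 0)
  expect_identical(est0$rate, 0)
  expect_identical(est0$I0, 7)
})

test_that("the fit is scale invariant and permutation invariant", {
  set.seed(3)
  h <- 10 * exp(-3 * r2_schedule) * (1 + rnorm(10, 0, 0.02))
  base <- fit_exponential(data.frame(delay = r2_schedule, height = h), n_mc = 0)
  scaled <- fit_exponential(data.frame(delay = r2_schedule, height = 100 * h),
                            n_mc = 0)
  expect_equal(scaled$rate, base$rate, tolerance = 1e-8)
  expect_equal(scaled$I0, 100 * base$I0, tolerance = 1e-6)
  perm <- sample(10)
  shuffled <- fit_exponential(data.frame(delay = r2_schedule[perm],
                                         height = h[perm]), n_mc = 0)
  expect_equal(shuffled$rate, base$rate, tolerance = 1e-8)
})

test_that("too few distinct delays are rejected", {
  expect_error(fit_exponential(data.frame(delay = c(0.1, 0.1, 0.2),
                                          height = c(5, 5, 3))),
               "3 distinct delays")
})

test_that("replicate error: closed forms and generator recovery", {
  # identical replicates: sigma = 0
  series <- data.frame(delay = c(0.1, 0.1, 0.2), height = c(5, 5, 3),
                       replicate = c(1, 2, 1))
  expect_equal(attr(replicate_error(series), "pooled_sd"), 0)
  # a pair differing by d has sd d / sqrt(2)
  d <- 0.34
  series$height <- c(5, 5 + d, 3)
  expect_equal(attr(replicate_error(series), "pooled_sd"), d / sqrt(2))
  expect_error(replicate_error(data.frame(delay = c(0.1, 0.2),
                                          height = c(5, 3),
                                          replicate = c(1, 1))),
               "no replicate pairs")
  # generator-injected 2% fractional noise is recovered on average
  fracs <- vapply(1:100, function(s) {
    cfg <- sim_config(seed = s, intensity_noise = 0.02)
    tab <- simulate_decays(data.frame(residue = 1, value = 2.5), cfg, "R1")
    attr(replicate_error(decay_series(tab, 1)), "fractional")
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.02) / 0.02, 0.2)
})

test_that("heteronuclear NOE follows the saturated-over-reference convention", {
  sat <- data.frame(residue = 1:3, height = c(1, 0.45, -0.1),
                    sigma = c(0.02, 0.02, 0.02))
  unsat <- data.frame(residue = 1:3, height = c(1, 1, 1),
                      sigma = c(0.02, 0.02, 0.02))
  res <- compute_hetnoe(sat, unsat)
  expect_equal(res$noe, c(1, 0.45, -0.1))
  expect_true(all(res$sigma > 0))
  # zero reference intensity masks the residue
  unsat$height[2] <- 0
  expect_false(compute_hetnoe(sat, unsat)$mask[2])
  # inverted convention available behind a flag
  inv <- compute_hetnoe(sat, data.frame(residue = 1:3, height = rep(2, 3)),
                        invert = TRUE)
  expect_equal(inv$noe[2], 2 / 0.45)
})

test_that("relaxation record propagates masks and computes R2/R1 ratios", {
  r1 <- data.frame(residue = 1:3, value = c(2, 2, NA), sigma = c(0.1, 0.1, NA))
  r2 <- data.frame(residue = 1:3, value = c(5, 4, 3), sigma = c(0.2, 0.2, 0.2))
  noe <- data.frame(residue = 1:3, noe = c(0.4, NA, 0.2),
                    sigma = c(0.02, NA, 0.02), mask = c(TRUE, FALSE, TRUE))
  rec <- relaxation_record(r1, r2, noe)
  expect_equal(rec$r2_over_r1[1:2], c(2.5, 2))
  expect_true(is.na(rec$r2_over_r1[3]))
  expect_true(is.na(rec$noe[2]))
})

test_that("cis/trans isomer fractions recover the generator truth", {
  expect_equal(isomer_fraction(data.frame(residue = 1, height = 2),
                               data.frame(residue = 1, height = 2))$fraction,
               0.5)
  expect_equal(isomer_fraction(data.frame(residue = 1, height = 2),
                               data.frame(residue = 1, height = 0))$fraction,
               0)
  expect_error(isomer_fraction(data.frame(residue = 1, height = 0),
                               data.frame(residue = 1, height = 0)),
               "all-zero")
  set.seed(7)
  true_frac <- 0.2
  major <- data.frame(residue = 1:8,
                      height = 100 * (1 - true_frac) * (1 + rnorm(8, 0, 0.1)))
  minor <- data.frame(residue = 1:8,
                      height = 100 * true_frac * (1 + rnorm(8, 0, 0.1)))
  est <- isomer_fraction(major, minor)
  expect_lt(abs(est$fraction - true_frac), 0.05)
})
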