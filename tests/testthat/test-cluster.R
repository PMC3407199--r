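test_that("residue weights follow the size rule", {
  w <- residue_weights(tc5b, "size_weighted")
  expect_identical(which(w == 1), c(10L, 11L, 15L))  # the three glycines
  expect_true(all(w[-c(10, 11, 15)] == 7))
  expect_true(all(residue_weights(tc5b, "uniform") == 1))
  polyg <- load_sequence("GGGGGG")
  expect_true(all(residue_weights(polyg, "size_weighted") == 1))
  expect_true(all(residue_weights(polyg, "uniform") == 1))
})

test_that("model_r2 matches the brute-force double loop", {
  w <- residue_weights(tc5b, "size_weighted")
  comp <- data.frame(R2c = 2, xc = 8, Delta = 3)
  got <- model_r2(0.05, 2, w, comp)
  expect_equal(as.vector(got), brute_force_model_r2(0.05, 2, w, comp, 1:20),
               tolerance = 1e-12)
  # property: random parameter sets
  set.seed(42)
  for (rep in 1:25) {
    A <- runif(1, 0, 0.3); l0 <- runif(1, 0.2, 10)
    kk <- sample(0:2, 1)
    comp <- if (kk > 0)
      data.frame(R2c = runif(kk, 0, 4), xc = runif(kk, 0, 21),
                 Delta = runif(kk, 0.6, 8))
    else NULL
    got <- model_r2(A, l0, w, comp)
    expect_equal(as.vector(got), brute_force_model_r2(A, l0, w, comp, 1:20),
                 tolerance = 1e-12)
  }
})

test_that("baseline limits and structure are correct", {
  w <- residue_weights(tc5b, "size_weighted")
  # no components: profile equals the baseline exactly
  got <- model_r2(0.1, 2, w)
  expect_equal(as.vector(got), attr(got, "baseline"))
  # lambda0 -> 0+: baseline collapses to the self term A * w_i
  tiny <- model_r2(0.1, 1e-4, w)
  expect_equal(as.vector(tiny), 0.1 * w, tolerance = 1e-10)
  # two sequences with identical weight vectors give identical baselines
  other <- load_sequence("WWWWWWWWWGGVVVGVVVVV")  # same Gly positions
  expect_identical(residue_weights(other), w)
  expect_equal(as.vector(model_r2(0.1, 2, residue_weights(other))),
               as.vector(got))
})

test_that("adding a cluster component never lowers the predicted profile", {
  w <- residue_weights(tc5b, "size_weighted")
  base <- model_r2(0.1, 2, w)
  set.seed(9)
  for (rep in 1:10) {
    comp <- data.frame(R2c = runif(1, 0, 5), xc = runif(1, -1, 22),
                       Delta = runif(1, 0.6, 10))
    expect_true(all(model_r2(0.1, 2, w, comp) >= base - 1e-12))
  }
})

test_that("a noiseless K=1 profile is recovered to solver tolerance", {
  w <- residue_weights(tc5b, "size_weighted")
  comp <- data.frame(R2c = 2, xc = 8, Delta = 3)
  clean <- model_r2(0.05, 2, w, comp)
  profile <- data.frame(residue = 1:20, value = as.vector(clean))
  fit <- fit_cluster_model(profile, tc5b, k = 1, n_boot = 0)
  expect_true(fit$converged)
  expect_equal(fit$A, 0.05, tolerance = 1e-6)
  expect_equal(fit$lambda0, 2, tolerance = 1e-5)
  expect_equal(fit$components$R2c, 2, tolerance = 1e-6)
  expect_equal(fit$components$xc, 8, tolerance = 1e-6)
  expect_equal(fit$components$Delta, 3, tolerance = 1e-6)
  expect_equal(fit$predicted, fit$baseline +
                 (fit$predicted - fit$baseline), tolerance = 1e-12)
})

test_that("the fit is equivariant under residue renumbering", {
  w <- residue_weights(tc5b, "size_weighted")
  comp <- data.frame(R2c = 2, xc = 8, Delta = 3)
  clean <- as.vector(model_r2(0.05, 2, w, comp))
  offset <- 100
  shifted_seq <- load_sequence(paste(unclass(tc5b), collapse = ""),
                               first = 1 + offset)
  fit0 <- fit_cluster_model(data.frame(residue = 1:20, value = clean),
                            tc5b, k = 1, n_boot = 0)
  fit1 <- fit_cluster_model(data.frame(residue = 1:20 + offset, value = clean),
                            shifted_seq, k = 1, n_boot = 0)
  expect_equal(fit1$components$xc, fit0$components$xc + offset,
               tolerance = 1e-6)
  expect_equal(fit1$A, fit0$A, tolerance = 1e-6)
})

test_that("masked profiles and identifiability limits are enforced", {
  prof <- data.frame(residue = 1:20, value = NA_real_)
  expect_error(fit_cluster_model(prof, tc5b, k = 1), "unmasked residues")
  prof$value[1:4] <- 2
  expect_error(fit_cluster_model(prof, tc5b, k = 1), "unmasked residues")
})

test_that("variant comparison is deterministic and localizes the cluster under both schemes", {
  sim <- simulate_r2_profile(sim_config(seed = 21,
                                        truth = list(A = 0.1, lambda0 = 2,
                                                     R2c = 2, xc = 8, Delta = 3,
                                                     variant = "uniform")))
  rep1 <- compare_variants(sim$profile, sim$seq, k = 1)
  rep2 <- compare_variants(sim$profile, sim$seq, k = 1)
  expect_equal(rep1$summary, rep2$summary)
  expect_lt(abs(rep1$summary$xc[rep1$summary$variant == "size_weighted"] - 8), 1)
  expect_lt(abs(rep1$summary$xc[rep1$summary$variant == "uniform"] - 8), 1)
})

test_that("model selection distinguishes clustered from cluster-free profiles", {
  sim1 <- simulate_r2_profile(sim_config(seed = 5))
  sel1 <- select_n_clusters(sim1$profile, sim1$seq, k_max = 1)
  expect_equal(sel1$k, 1)
  sim0 <- simulate_r2_profile(sim_config(
    seed = 5, truth = list(A = 0.1, lambda0 = 2, R2c = 0, xc = 6.5, Delta = 3,
                           variant = "size_weighted")))
  sel0 <- select_n_clusters(sim0$profile, sim0$seq, k_max = 1)
  expect_equal(sel0$k, 0)
})
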