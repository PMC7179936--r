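# Two-step parameter estimation and identifiability.

truth <- params_yh(0)$producer

test_that("closed forms invert noiseless data exactly", {
  ds <- generate_rate_dataset(truth, default_paper_like_design(
    replicates = 1, noise_cv = 0))
  est <- closed_form_estimates(ds, fixed_constants)
  expect_equal(est$k_g, 1.53, tolerance = 1e-10)
  expect_equal(est$k_over, 0.17, tolerance = 1e-10)
  expect_equal(est$k_a, 0.97, tolerance = 1e-10)
  expect_equal(est$Y_g, 0.44, tolerance = 1e-10)
  expect_equal(est$Y_a, 0.298, tolerance = 1e-10)
})

test_that("acetate yield inversion matches the growth-rate balance", {
  # single acetate-only record at saturation: Y_a = (mu + k_deg) / r_up_a
  r_up_a <- 0.97
  mu <- 0.298 * r_up_a - 0.0044
  ds <- data.frame(condition = c("acetate_only", "glucose_only"),
                   G = c(0, 3.6), A = c(5000, 0),
                   mu_plus = c(mu, 0.62),
                   rupg_plus = c(0, 1.49),
                   net_acetate_plus = c(r_up_a * 5000 / 5000.5, -0.13))
  est <- closed_form_estimates(ds, fixed_constants)
  expect_equal(est$Y_a, (mu + 0.0044) / (r_up_a * 5000 / 5000.5),
               tolerance = 1e-12)
})

test_that("closed forms fail informatively on unusable data", {
  ds <- generate_rate_dataset(truth, default_paper_like_design(
    replicates = 1, noise_cv = 0))
  expect_error(closed_form_estimates(ds[ds$condition != "acetate_only", ],
                                     fixed_constants), "acetate_only")
  expect_error(closed_form_estimates(ds[ds$condition != "glucose_only", ],
                                     fixed_constants), "glucose_only")
  # glucose-only record below the overflow threshold cannot identify k_over
  low <- ds
  low$rupg_plus[low$condition == "glucose_only"] <- 0.5
  expect_error(closed_form_estimates(low, fixed_constants), "overflow")
})

test_that("step-2 fit recovers the inhibition parameters from clean data", {
  ds <- generate_rate_dataset(truth, default_paper_like_design(
    replicates = 1, noise_cv = 0))
  cal <- calibrate_two_step(ds, fixed_constants)
  expect_equal(unname(cal$fit$estimates),
               c(0.52, 1, 0.25, 1), tolerance = 1e-3)
  expect_true(all(cal$fit$r_squared > 1 - 1e-8))
})

test_that("datasets without an acetate gradient are flagged unidentifiable", {
  d <- data_design(glucose_only_levels = 3.6, acetate_only_levels = c(1, 2),
                   mixed_G = 3.6, mixed_A_levels = c(0, 0, 0))
  ds <- generate_rate_dataset(truth, d)
  base <- truth
  expect_warning(fit <- fit_inhibition_params(ds, base, n_starts = 1),
                 "unidentifiable")
  expect_false(fit$identifiable)
})

test_that("exponential-rate predictions match hand arithmetic", {
  pred <- predict_exponential_rates(truth, 1e9, 0)
  expect_equal(pred$mu_plus, 0.44 * 1.53 - 0.298 * 0.17 * (1.53 - 0.7) -
                 0.0044, tolerance = 1e-8)
  pred_a <- predict_exponential_rates(truth, 0, 1e9)
  expect_equal(pred_a$mu_plus, 0.298 * 0.97 - 0.0044, tolerance = 1e-6)
  expect_equal(predict_exponential_rates(truth, 0, 0)$mu_plus, -0.0044)
})

test_that("R-squared follows its definition", {
  obs <- c(1, 2, 3, 4)
  expect_equal(goodness_of_fit(obs, obs), 1)
  expect_equal(goodness_of_fit(rep(mean(obs), 4), obs), 0)
  # fixed residual construction
  pred <- obs + c(0.1, -0.1, 0.2, -0.2)
  expect_equal(goodness_of_fit(pred, obs), 1 - 0.1 / 5)
  expect_error(goodness_of_fit(obs, rep(2, 4)), "zero variance")
})

test_that("maintenance relation and uptake mutations are linear", {
  expect_identical(kdeg_from_maintenance(0, 0.44), 0)
  expect_equal(kdeg_from_maintenance(0.01, 0.44), 0.0044)
  expect_equal(kdeg_from_maintenance(0.02, 0.88), 4 * 0.0044)

  expect_equal(apply_uptake_mutation(truth, 1)$k_g, truth$k_g)
  # 4-fold PTS reduction lands close to the cleaner's residual rate
  expect_equal(apply_uptake_mutation(truth, 0.25)$k_g, 0.3825)
  expect_equal(abs(apply_uptake_mutation(truth, 0.25)$k_g - 0.38) < 0.005,
               TRUE)
  mut0 <- apply_uptake_mutation(truth, 0)
  expect_equal(predict_exponential_rates(mut0, 3.6, 0)$mu_plus, -mut0$k_deg)
  expect_error(apply_uptake_mutation(truth, 1.2), "uptake_fraction")
})

test_that("closed forms stay within 5% under 5% noise (median of 20 runs)", {
  ests <- vapply(1:20, function(i) {
    ds <- generate_rate_dataset(truth, default_paper_like_design(
      replicates = 3, noise_cv = 0.05, seed = 100 + i))
    unlist(closed_form_estimates(ds, fixed_constants))
  }, numeric(5))
  med <- apply(ests, 1, stats::median)
  ref <- c(k_g = 1.53, k_over = 0.17, k_a = 0.97, Y_g = 0.44, Y_a = 0.298)
  expect_true(all(abs(med - ref) / ref < 0.05))
})

test_that("bootstrap is deterministic and degenerates at zero noise", {
  ds0 <- generate_rate_dataset(truth, default_paper_like_design(
    replicates = 2, noise_cv = 0))
  cal <- calibrate_two_step(ds0, fixed_constants, n_starts = 1)
  b1 <- bootstrap_identifiability(ds0, cal$params, cal$fit, n_boot = 20,
                                  seed = 5)
  b2 <- bootstrap_identifiability(ds0, cal$params, cal$fit, n_boot = 20,
                                  seed = 5)
  expect_identical(b1$ci, b2$ci)
  # resampling identical records leaves nothing to vary
  expect_lt(max(b1$ci[, "upper"] - b1$ci[, "lower"]), 1e-4)
})
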