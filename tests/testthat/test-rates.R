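# Rate laws and growth-rate expressions of the two strains.

test_that("producer rates match their defining expressions at anchor points", {
  p <- params_yh(0)$producer

  expect_equal(unname(producer_rates(0, 0, p)), c(0, 0, 0))
  # saturation limit in G with no acetate equals k_g
  expect_equal(producer_rates(1e12, 0, p)[["r_up_g"]], p$k_g, tolerance = 1e-9)
  # A = Theta_a with n = 1 halves the uptake
  half <- producer_rates(5, p$Theta_a, p)[["r_up_g"]]
  expect_equal(half, 0.5 * p$k_g * 5 / (5 + p$K_g), tolerance = 1e-12)
  expect_error(producer_rates(-1, 0, p), "nonnegative")

  # overflow is proportional to the excess uptake: r_up_g = 0.8 gives
  # k_over * (0.8 - l) = 0.17 * 0.1
  # (construct G so that r_up_g = 0.8 exactly, A = 0)
  G <- 0.8 * p$K_g / (p$k_g - 0.8)
  r <- producer_rates(G, 0, p)
  expect_equal(r[["r_up_g"]], 0.8, tolerance = 1e-12)
  expect_equal(r[["r_over_a"]], 0.017, tolerance = 1e-12)
})

test_that("cleaner rates use the residual PTS rate and the Acs term", {
  cl <- params_yh(0)$cleaner
  expect_equal(unname(cleaner_rates(0, 0, cl)), c(0, 0, 0))
  expect_equal(cleaner_rates(1e12, 0, cl)[["r_up_g"]], cl$k_dPTS,
               tolerance = 1e-9)
  # acetate saturation with no glucose: CCR factor is 1, Acs adds on top
  expect_equal(cleaner_rates(0, 1e12, cl)[["r_up_a"]], cl$k_a + cl$k_Acs,
               tolerance = 1e-6)
  expect_equal(cleaner_rates(0, 1e12, cl)[["r_up_a"]], 2.43, tolerance = 1e-6)
})

test_that("glucose uptake is monotone in G and A; acetate uptake in A", {
  p <- params_yh(0)$producer
  cl <- params_yh(0)$cleaner
  G_grid <- c(0, 0.01, 0.05, 0.2, 1, 5, 20)
  A_grid <- c(0, 0.05, 0.2, 0.52, 1, 3, 10)
  for (pars in list(p, cl)) {
    for (A in A_grid) {
      rg <- vapply(G_grid, function(G) strain_rates(G, A, pars)[["r_up_g"]],
                   numeric(1))
      expect_true(all(diff(rg) >= 0))
    }
    for (G in G_grid) {
      rg <- vapply(A_grid, function(A) strain_rates(G, A, pars)[["r_up_g"]],
                   numeric(1))
      expect_true(all(diff(rg) <= 0))
      ra <- vapply(A_grid, function(A) strain_rates(G, A, pars)[["r_up_a"]],
                   numeric(1))
      expect_true(all(diff(ra) >= 0))
    }
  }
})

test_that("overflow is continuous and piecewise linear with kink at l", {
  p <- params_yh(0)$producer
  # r_over as a function of r_up_g via G at A = 0
  G_for <- function(r) r * p$K_g / (p$k_g - r)
  eps <- 1e-9
  below <- producer_rates(G_for(p$l - eps), 0, p)[["r_over_a"]]
  above <- producer_rates(G_for(p$l + eps), 0, p)[["r_over_a"]]
  expect_identical(below, 0)
  expect_lt(above, 1e-8)  # continuity across the kink
  # linear above the kink
  r1 <- producer_rates(G_for(0.9), 0, p)[["r_over_a"]]
  r2 <- producer_rates(G_for(1.1), 0, p)[["r_over_a"]]
  expect_equal(r2 - r1, p$k_over * 0.2, tolerance = 1e-10)
})

test_that("specific growth rate follows the biomass-weighted net rate", {
  p <- params_yh(0)$producer
  zero <- c(r_up_g = 0, r_up_a = 0, r_over_a = 0)
  expect_equal(specific_growth_rate(zero, 1, 1, p), -p$k_deg)
  expect_equal(specific_growth_rate(zero, 1, 1, p), -0.0044)
  # at the overflow threshold with no acetate exchange, mu = Y_g l - k_deg
  r <- c(r_up_g = p$l, r_up_a = 0, r_over_a = 0)
  expect_equal(specific_growth_rate(r, 1, 1, p), 0.44 * 0.7 - 0.0044)
  expect_error(specific_growth_rate(zero, 0, 0, p), "B_tot")
  # protein burden enters through B/B_tot = 1 - Y_h
  p2 <- params_yh(0.2)$producer
  mu_burden <- specific_growth_rate(r, 0.8, 1, p2)
  expect_equal(mu_burden, 0.8 * 0.44 * 0.7 - 0.0044, tolerance = 1e-12)
})

test_that("overflow-onset dilution rate follows (1 - Y_h) Y_g l - k_deg", {
  expect_equal(overflow_onset_dilution(params_yh(0)$producer), 0.3036)
  expect_equal(overflow_onset_dilution(params_yh(0.2)$producer), 0.242)
  p1 <- params_yh(0)$producer
  p1$Y_h <- 1 - 1e-15
  expect_equal(overflow_onset_dilution(p1), -p1$k_deg, tolerance = 1e-12)
})

test_that("protein burden shifts the onset like a proportional yield loss", {
  # raising Y_h acts on the onset exactly as scaling Y_g by (1 - Y_h)
  p <- params_yh(0.2)$producer
  p_equiv <- params_yh(0)$producer
  p_equiv$Y_g <- p_equiv$Y_g * (1 - 0.2)
  expect_equal(overflow_onset_dilution(p), overflow_onset_dilution(p_equiv))
})
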