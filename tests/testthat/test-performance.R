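# Productivity and process yield.

test_that("process yield obeys the producer-biomass identity", {
  pp <- params_yh(0.2)
  u <- chemostat(0.4, 20)
  res <- steady_state_by_integration(u, pp$producer, pp$cleaner)
  perf <- chemostat_performance(res, u, Y_h = 0.2)
  expect_equal(perf$productivity, u$D * res$state[["H"]])
  expect_equal(perf$process_yield, 0.2 * B_totP(res$state) / u$G_in,
               tolerance = 1e-8)
})

test_that("degenerate cases: washout, no product yield, G_in = 0", {
  pp <- params_yh(0.2)
  u <- chemostat(0.68, 20)
  res <- steady_state_by_integration(u, pp$producer, pp$cleaner)
  perf <- chemostat_performance(res, u, Y_h = 0.2)
  expect_identical(perf$regime, "washout")
  expect_lt(perf$productivity, 1e-6)

  pp0 <- params_yh(0)
  res0 <- steady_state_by_integration(chemostat(0.3, 20), pp0$producer,
                                      pp0$cleaner)
  expect_identical(res0$state[["H"]], 0)

  u0 <- chemostat(0.1, 0)
  res_u0 <- steady_state_by_integration(u0, pp$producer, pp$cleaner)
  expect_warning(perf0 <- chemostat_performance(res_u0, u0, Y_h = 0.2),
                 "G_in = 0")
  expect_true(is.na(perf0$process_yield))
})

test_that("below the coexistence band both variants coincide", {
  pp <- params_yh(0.2)
  u <- chemostat(0.15, 20)
  res_c <- steady_state_by_integration(u, pp$producer, pp$cleaner)
  res_p <- steady_state_by_integration(u, pp$producer, NULL)
  expect_identical(res_c$regime, "producer_only")
  expect_equal(res_c$state, res_p$state, tolerance = 1e-5)
})

test_that("consortium beats the producer's biomass inside the band only", {
  pp <- params_yh(0.2)
  tb <- total_biomass_comparison(pp$producer, pp$cleaner, G_in = 20,
                                 D_grid = c(0.15, 0.4, 0.46))
  # identical without a cleaner population
  expect_equal(tb$consortium[1], tb$producer_alone[1], tolerance = 1e-5)
  # higher total biomass for part of the coexistence band
  expect_true(any(tb$consortium[-1] > tb$producer_alone[-1]))
})

test_that("fed-batch summary orders productivity and yield as a trade-off", {
  pp <- params_yh(0.2)
  run_c <- fedbatch_run(pp$producer, pp$cleaner, G_held = 20, horizon = 50)
  run_p <- fedbatch_run(pp$producer, NULL, G_held = 20, horizon = 50)
  fb <- fedbatch_performance(run_c$stats, run_p$stats)
  expect_true(fb$consortium_faster)
  expect_true(fb$producer_higher_yield)
})

test_that("a cleaner with no glucose uptake cannot persist below overflow", {
  pp <- params_yh(0.2)
  cl0 <- pp$cleaner
  cl0$k_dPTS <- 0
  # below the overflow onset (0.242 1/h) there is no acetate to feed on
  res <- steady_state_by_integration(chemostat(0.2, 20), pp$producer, cl0)
  expect_identical(res$regime, "producer_only")
  # with residual uptake restored the default scenario is recovered
  res_def <- steady_state_by_integration(chemostat(0.2, 20), pp$producer,
                                         pp$cleaner)
  expect_identical(res_def$regime, "producer_only")
  res_band <- steady_state_by_integration(chemostat(0.4, 20), pp$producer,
                                          cl0)
  expect_identical(res_band$regime, "coexistence")
})

test_that("energy dissipation advances and steepens acetate overflow", {
  pp <- params_yh(0)
  p_lowY <- pp$producer
  p_lowY$Y_g <- 0.27
  # onset moves to lower dilution rates
  expect_lt(overflow_onset_dilution(p_lowY),
            overflow_onset_dilution(pp$producer))
  # the steady-state overflow rate rises more steeply with D
  slope <- function(p) {
    D1 <- overflow_onset_dilution(p) + 0.02
    D2 <- D1 + 0.05
    r1 <- steady_state_by_integration(chemostat(D1, 20), p, NULL)$state
    r2 <- steady_state_by_integration(chemostat(D2, 20), p, NULL)$state
    o1 <- producer_rates(r1[["G"]], r1[["A"]], p)[["r_over_a"]]
    o2 <- producer_rates(r2[["G"]], r2[["A"]], p)[["r_over_a"]]
    (o2 - o1) / (D2 - D1)
  }
  expect_gt(slope(p_lowY), slope(pp$producer))
})
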