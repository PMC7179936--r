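# Steady-state computation, stability and classification.

test_that("analytic Jacobian matches central finite differences", {
  pp <- params_yh(0.2)
  u <- chemostat(0.35, 15)
  set.seed(7)
  for (rep in 1:6) {
    x <- c(G = runif(1, 0.01, 15), A = runif(1, 0.001, 2),
           B_P = runif(1, 0.01, 5), H = runif(1, 0.01, 1),
           B_C = runif(1, 0.01, 3))
    J_num <- pracma::jacobian(function(y) {
      names(y) <- c("G", "A", "B_P", "H", "B_C")
      consortium_rhs(y, u, pp$producer, pp$cleaner)
    }, x)
    J_ana <- consortium_jacobian(x, u, pp$producer, pp$cleaner)
    expect_equal(unname(J_ana), J_num, tolerance = 1e-6)
  }
})

test_that("washout is stable exactly when no strain can grow at rate D", {
  pp <- params_yh(0.2)
  washout <- c(G = 20, A = 0, B_P = 0, H = 0, B_C = 0)
  # far above any achievable growth rate
  J_hi <- consortium_jacobian(washout, chemostat(0.65, 20),
                              pp$producer, pp$cleaner)
  expect_lt(max(Re(eigen(J_hi, only.values = TRUE)$values)), 0)
  # well below: the producer invades, washout is unstable
  J_lo <- consortium_jacobian(washout, chemostat(0.2, 20),
                              pp$producer, pp$cleaner)
  expect_gt(max(Re(eigen(J_lo, only.values = TRUE)$values)), 0)
})

test_that("growth rates balance dilution at nonzero-biomass equilibria", {
  pp <- params_yh(0.2)
  u <- chemostat(0.4, 20)
  res <- steady_state_by_integration(u, pp$producer, pp$cleaner)
  expect_true(res$converged)
  expect_identical(res$regime, "coexistence")
  expect_equal(mu_at_state(res$state, pp$producer), u$D, tolerance = 1e-6)
  expect_equal(mu_at_state(res$state, pp$cleaner, cleaner_strain = TRUE),
               u$D, tolerance = 1e-6)
  # product fraction of producer biomass is Y_h at steady state
  expect_equal(res$state[["H"]] / B_totP(res$state), 0.2, tolerance = 1e-6)
})

test_that("producer-only branch satisfies the linear uptake-dilution law", {
  # below overflow, r_up_g* = (k_deg + D) / ((1 - Y_h) Y_g)
  pp <- params_yh(0.2)
  p <- pp$producer
  for (D in c(0.1, 0.2)) {
    res <- steady_state_by_integration(chemostat(D, 20), p, pp$cleaner)
    expect_identical(res$regime, "producer_only")
    r <- producer_rates(res$state[["G"]], res$state[["A"]], p)
    expect_lt(r[["r_up_g"]], p$l)
    expect_equal(r[["r_up_g"]], (p$k_deg + D) / ((1 - p$Y_h) * p$Y_g),
                 tolerance = 1e-8)
  }
})

test_that("root finding reproduces the integration endpoint", {
  pp <- params_yh(0)
  for (cell in list(c(0.2, 10), c(0.45, 20), c(0.65, 5))) {
    u <- chemostat(cell[1], cell[2])
    by_int <- steady_state_by_integration(u, pp$producer, pp$cleaner)
    roots <- steady_state_by_rootfinding(u, pp$producer, pp$cleaner,
                                         seed = 1)
    stable <- Filter(function(r) r$stable, roots)
    expect_length(stable, 1L)
    expect_equal(stable[[1]]$state, by_int$state,
                 tolerance = 1e-5)
    expect_identical(stable[[1]]$regime, by_int$regime)
  }
})

test_that("the steady state is unique over random positive inocula", {
  pp <- params_yh(0.2)
  set.seed(11)
  for (cell in list(c(0.3, 20), c(0.45, 10))) {
    u <- chemostat(cell[1], cell[2])
    states <- lapply(1:5, function(i) {
      x0 <- consortium_state(G = runif(1, 0, cell[2]), A = runif(1, 0, 1),
                             B_P = runif(1, 0.001, 2), H = 0,
                             B_C = runif(1, 0.001, 2))
      steady_state_by_integration(u, pp$producer, pp$cleaner, x0 = x0)$state
    })
    ref <- states[[1]]
    scale <- max(1, max(abs(ref)))
    for (s in states[-1]) expect_lt(max(abs(s - ref)) / scale, 1e-5)
  }
})

test_that("regimes are classified from the presence threshold", {
  expect_identical(classify_regime(c(G = 5, A = 0, B_P = 0, H = 0, B_C = 0)),
                   "washout")
  expect_identical(classify_regime(c(G = 1, A = 0.1, B_P = 2, H = 0.1,
                                     B_C = 0.3)), "coexistence")
  expect_identical(classify_regime(c(G = 1, A = 0, B_P = 2, H = 0,
                                     B_C = 1e-9)), "producer_only")
  expect_identical(classify_regime(c(G = 1, A = 0, B_P = 0, H = 0,
                                     B_C = 0.5)), "cleaner_only")
})

test_that("a heavy protein burden can hand the reactor to the cleaner", {
  # if the producer diverts nearly all synthesis to product, the cleaner
  # out-grows it on glucose and survives alone
  pp <- params_yh(0.9)
  res <- steady_state_by_integration(chemostat(0.1, 20), pp$producer,
                                     pp$cleaner)
  expect_identical(res$regime, "cleaner_only")
})

test_that("phase diagram scan covers the regime sequence along D", {
  pp <- params_yh(0)
  sw <- scan_phase_diagram(pp$producer, pp$cleaner,
                           D_grid = c(0.1, 0.3, 0.45, 0.6, 0.68),
                           Gin_grid = c(0, 20))
  expect_identical(nrow(sw), 10L)
  # no glucose in the feed: washout everywhere
  expect_true(all(sw$regime[sw$G_in == 0] == "washout"))
  expect_identical(sw$regime[sw$G_in == 20],
                   c("producer_only", "producer_only", "coexistence",
                     "producer_only", "washout"))
  expect_true(all(sw$converged))
})
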