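# Steady states of the consortium in chemostat. Two routes are provided:
# long-horizon integration (the workhorse; the system has a unique stable
# steady state for positive initial biomasses) and root finding over the
# overflow branches of the piecewise rate laws, with Jacobian stability
# analysis (the cross-check).

#' Analytic Jacobian of the consortium system
#'
#' 5x5 matrix of partial derivatives of the right-hand side with respect to
#' the state `(G, A, B_P, H, B_C)`. On the overflow kink (`r_up_g = l` for a
#' strain) the one-sided derivative of the state's overflow branch is used
#' and a warning is emitted.
#'
#' @param x state vector.
#' @param u `reactor_inputs`.
#' @param producer,cleaner `strain_params`; `cleaner = NULL` treats the
#'   cleaner biomass as absent.
#' @return 5x5 numeric matrix with dimnames `G, A, B_P, H, B_C`.
#' @export
consortium_jacobian <- function(x, u, producer, cleaner = NULL) {
  v <- as_state_vector(x)
  G <- if (u$mode == "fedbatch") u$G_held else v[["G"]]
  A <- v[["A"]]; B_P <- v[["B_P"]]; B_C <- v[["B_C"]]
  D <- if (u$mode == "chemostat") u$D else 0
  Y_h <- producer$Y_h

  pp <- strain_rate_partials(G, A, producer)
  if (abs(pp$r_up_g - producer$l) < 1e-12 && pp$r_up_g > 0)
    warning("producer glucose uptake exactly at the overflow kink; ",
            "using the one-sided derivative of the state's branch")
  if (!is.null(cleaner)) {
    pc <- strain_rate_partials(G, A, cleaner)
  } else {
    zero2 <- c(G = 0, A = 0)
    pc <- list(r_up_g = 0, r_up_a = 0, r_over_a = 0,
               dg = zero2, da = zero2, dover = zero2)
    B_C <- 0
  }

  r_net_P <- producer$Y_g * pp$r_up_g + producer$Y_a * (pp$r_up_a - pp$r_over_a)
  drnetP <- producer$Y_g * pp$dg + producer$Y_a * (pp$da - pp$dover)
  Y_gC <- if (is.null(cleaner)) 0 else cleaner$Y_g
  Y_aC <- if (is.null(cleaner)) 0 else cleaner$Y_a
  k_degC <- if (is.null(cleaner)) 0 else cleaner$k_deg
  r_net_C <- Y_gC * pc$r_up_g + Y_aC * (pc$r_up_a - pc$r_over_a)
  drnetC <- Y_gC * pc$dg + Y_aC * (pc$da - pc$dover)

  J <- matrix(0, 5, 5, dimnames = list(state_names, state_names))
  # dG/dt
  J["G", "G"] <- -pp$dg[["G"]] * B_P - pc$dg[["G"]] * B_C - D
  J["G", "A"] <- -pp$dg[["A"]] * B_P - pc$dg[["A"]] * B_C
  J["G", "B_P"] <- -pp$r_up_g
  J["G", "B_C"] <- -pc$r_up_g
  # dA/dt
  J["A", "G"] <- (pp$dover[["G"]] - pp$da[["G"]]) * B_P +
    (pc$dover[["G"]] - pc$da[["G"]]) * B_C
  J["A", "A"] <- (pp$dover[["A"]] - pp$da[["A"]]) * B_P +
    (pc$dover[["A"]] - pc$da[["A"]]) * B_C - D
  J["A", "B_P"] <- pp$r_over_a - pp$r_up_a
  J["A", "B_C"] <- pc$r_over_a - pc$r_up_a
  # dB_P/dt
  J["B_P", "G"] <- (1 - Y_h) * drnetP[["G"]] * B_P
  J["B_P", "A"] <- (1 - Y_h) * drnetP[["A"]] * B_P
  J["B_P", "B_P"] <- (1 - Y_h) * r_net_P - producer$k_deg - D
  # dH/dt
  J["H", "G"] <- Y_h * drnetP[["G"]] * B_P
  J["H", "A"] <- Y_h * drnetP[["A"]] * B_P
  J["H", "B_P"] <- Y_h * r_net_P
  J["H", "H"] <- -producer$k_deg - D
  # dB_C/dt
  J["B_C", "G"] <- drnetC[["G"]] * B_C
  J["B_C", "A"] <- drnetC[["A"]] * B_C
  J["B_C", "B_C"] <- r_net_C - k_degC - D

  if (u$mode == "fedbatch") J["G", ] <- 0
  J
}

rhs_residual <- function(x, u, producer, cleaner) {
  max(abs(consortium_rhs(x, u, producer, cleaner)))
}

state_partition <- function(x, u, producer, cleaner) {
  v <- as_state_vector(x)
  G <- if (u$mode == "fedbatch") u$G_held else v[["G"]]
  overP <- producer_rates(G, v[["A"]], producer)[["r_up_g"]] > producer$l
  overC <- if (is.null(cleaner)) FALSE else
    cleaner_rates(G, v[["A"]], cleaner)[["r_up_g"]] > cleaner$l
  # X1: neither strain overflows; X2: only cleaner; X3: only producer;
  # X4: both.
  c("X1", "X2", "X3", "X4")[1L + overP * 2L + overC]
}

#' Classify the ecological regime of an equilibrium state
#'
#' @param state equilibrium state vector.
#' @param presence_threshold biomass above which a strain counts as present
#'   \[gDW L^-1\].
#' @return One of `"coexistence"`, `"producer_only"`, `"cleaner_only"`,
#'   `"washout"`.
#' @export
classify_regime <- function(state, presence_threshold = 1e-6) {
  v <- as_state_vector(state)
  P <- (v[["B_P"]] + v[["H"]]) > presence_threshold
  C <- v[["B_C"]] > presence_threshold
  if (P && C) "coexistence" else if (P) "producer_only" else
    if (C) "cleaner_only" else "washout"
}

make_ss_result <- function(x, u, producer, cleaner, converged,
                           presence_threshold = 1e-6) {
  x <- as_state_vector(x)
  x[x < 0] <- 0
  J <- consortium_jacobian(x, u, producer, cleaner)
  ev <- eigen(J, only.values = TRUE)$values
  structure(list(
    state = x,
    residual = rhs_residual(x, u, producer, cleaner),
    converged = converged,
    eigenvalues = ev,
    stable = max(Re(ev)) < 0,
    regime = classify_regime(x, presence_threshold),
    partition = state_partition(x, u, producer, cleaner),
    inputs = u
  ), class = "steady_state_result")
}

#' @export
print.steady_state_result <- function(x, ...) {
  cat(sprintf("steady state (%s, %s, partition %s)\n",
              x$regime, if (x$stable) "stable" else "unstable", x$partition))
  print(round(x$state, 8))
  cat(sprintf("  residual %.3g, spectral abscissa %.3g, converged: %s\n",
              x$residual, max(Re(x$eigenvalues)), x$converged))
  invisible(x)
}

#' Stable steady state by long-horizon integration
#'
#' Integrates the chemostat model in chunks of increasing length until the
#' infinity norm of the right-hand side drops below `tol` or the horizon is
#' exhausted. The default initial condition places a small positive inoculum
#' of both strains in an empty reactor, so any reachable nonzero equilibrium
#' is attained.
#'
#' @param u `reactor_inputs` (chemostat mode).
#' @param producer,cleaner `strain_params` (`cleaner = NULL` for the
#'   producer alone).
#' @param x0 initial state; default `(G, A, B_P, H, B_C) = (0, 0, 0.01, 0,
#'   0.01)` (cleaner inoculum dropped when `cleaner` is `NULL`).
#' @param horizon cap on total integrated time \[h\].
#' @param tol convergence tolerance on the residual.
#' @param presence_threshold passed to [classify_regime()].
#' @return A `steady_state_result`; `converged = FALSE` flags failure to
#'   reach `tol` within the horizon.
#' @export
steady_state_by_integration <- function(u, producer, cleaner = NULL,
                                        x0 = NULL, horizon = 1e6,
                                        tol = 1e-9,
                                        presence_threshold = 1e-6) {
  if (u$mode != "chemostat") stop("steady-state analysis requires chemostat mode")
  if (is.null(x0)) {
    x0 <- c(G = 0, A = 0, B_P = 0.01, H = 0,
            B_C = if (is.null(cleaner)) 0 else 0.01)
  }
  x <- as_state_vector(x0)
  t_done <- 0
  chunk <- 200
  repeat {
    if (rhs_residual(x, u, producer, cleaner) < tol) break
    if (t_done >= horizon) {
      return(make_ss_result(x, u, producer, cleaner, converged = FALSE,
                            presence_threshold))
    }
    chunk <- min(chunk, horizon - t_done)
    traj <- simulate_consortium(x, u, producer, cleaner, horizon = chunk,
                                times = c(0, chunk))
    x <- unlist(traj[nrow(traj), state_names])
    t_done <- t_done + chunk
    chunk <- chunk * 4
  }
  make_ss_result(x, u, producer, cleaner, converged = TRUE,
                 presence_threshold)
}

# ---- root finding -----------------------------------------------------------

# Right-hand side with the overflow terms forced to a fixed branch
# (overP/overC TRUE: linear form k_over (r_up_g - l); FALSE: 0), so each
# branch is smooth and Newton-differentiable.
branch_rhs <- function(x, u, producer, cleaner, overP, overC) {
  v <- x
  G <- v[["G"]]; A <- v[["A"]]; B_P <- v[["B_P"]]; H <- v[["H"]]; B_C <- v[["B_C"]]
  if (G < 0) G <- 0
  if (A < 0) A <- 0
  D <- u$D
  Y_h <- producer$Y_h
  rgP <- producer$k_g * monod(G, producer$K_g) * inhib(A, producer$Theta_a, producer$n)
  raP <- producer$k_a * monod(A, producer$K_a) * inhib(rgP, producer$Theta_g, producer$m)
  roP <- if (overP) producer$k_over * (rgP - producer$l) else 0
  if (!is.null(cleaner)) {
    rgC <- cleaner$k_dPTS * monod(G, cleaner$K_g) * inhib(A, cleaner$Theta_a, cleaner$n)
    raC <- cleaner$k_a * monod(A, cleaner$K_a) * inhib(rgC, cleaner$Theta_g, cleaner$m) +
      cleaner$k_Acs * monod(A, cleaner$K_Acs)
    roC <- if (overC) cleaner$k_over * (rgC - cleaner$l) else 0
    rnC <- cleaner$Y_g * rgC + cleaner$Y_a * (raC - roC)
    kdC <- cleaner$k_deg
  } else {
    rgC <- raC <- roC <- rnC <- kdC <- 0
    B_C <- 0
  }
  rnP <- producer$Y_g * rgP + producer$Y_a * (raP - roP)
  c(G = -rgP * B_P - rgC * B_C + D * (u$G_in - G),
    A = (roP - raP) * B_P + (roC - raC) * B_C - D * A,
    B_P = (1 - Y_h) * rnP * B_P - producer$k_deg * B_P - D * B_P,
    H = Y_h * rnP * B_P - producer$k_deg * H - D * H,
    B_C = rnC * B_C - kdC * B_C - D * B_C)
}

# Damped Newton on a residual function of a free subset of the state.
damped_newton <- function(fn, x0, max_iter = 60, tol = 1e-11) {
  x <- x0
  f <- fn(x)
  for (it in seq_len(max_iter)) {
    if (max(abs(f)) < tol) return(list(x = x, f = f, converged = TRUE))
    J <- pracma::jacobian(fn, x)
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) {
      return(list(x = x, f = f, converged = FALSE))
    }
    lam <- 1
    repeat {
      x_new <- x + lam * step
      f_new <- tryCatch(fn(x_new), error = function(e) rep(Inf, length(f)))
      if (all(is.finite(f_new)) && max(abs(f_new)) < max(abs(f))) break
      lam <- lam / 2
      if (lam < 1e-10) return(list(x = x, f = f, converged = FALSE))
    }
    x <- x_new
    f <- f_new
  }
  list(x = x, f = f, converged = max(abs(f)) < tol)
}

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' All steady states by branch-wise root finding
#'
#' Enumerates equilibrium candidates of the chemostat model in three
#' families: the closed-form washout state, single-strain equilibria
#' (reduced root problems with the other biomass fixed at 0) and interior
#' coexistence equilibria, each solved per overflow branch of the piecewise
#' rate laws with a multi-start damped Newton iteration (Latin-hypercube
#' starts in log-scaled state space). Candidates violating their branch's
#' defining rate inequality or nonnegativity are discarded; the survivors
#' are deduplicated and equipped with Jacobian stability verdicts.
#'
#' @param u `reactor_inputs` (chemostat).
#' @param producer,cleaner `strain_params`.
#' @param n_starts Latin-hypercube starts per family and branch.
#' @param seed seed for the start sampling (restored afterwards).
#' @param residual_tol acceptance tolerance on the true right-hand side.
#' @param presence_threshold passed to [classify_regime()].
#' @return List of `steady_state_result` objects (washout always included).
#' @export
steady_state_by_rootfinding <- function(u, producer, cleaner,
                                        n_starts = 32, seed = 1,
                                        residual_tol = 1e-8,
                                        presence_threshold = 1e-6) {
  if (u$mode != "chemostat") stop("steady-state analysis requires chemostat mode")
  Y_h <- producer$Y_h
  D <- u$D
  G_in <- u$G_in
  cand <- list(c(G = G_in, A = 0, B_P = 0, H = 0, B_C = 0))

  # closed-form boundary equilibria with A* = 0 (a strain growing on
  # glucose below overflow secretes no acetate): the growth balance fixes
  # the uptake rate, hence G*, and the glucose balance fixes the biomass
  single_on_glucose <- function(strain, k_max, yield_factor, as_producer) {
    rg <- (strain$k_deg + D) / yield_factor
    if (rg <= 0 || rg >= k_max) return(NULL)
    G <- rg * strain$K_g / (k_max - rg)
    if (G >= G_in || rg > strain$l) return(NULL)
    B <- D * (G_in - G) / rg
    if (B <= 0) return(NULL)
    if (as_producer) {
      c(G = G, A = 0, B_P = B, H = Y_h / (1 - Y_h) * B, B_C = 0)
    } else {
      c(G = G, A = 0, B_P = 0, H = 0, B_C = B)
    }
  }
  if (Y_h < 1) {
    cp <- single_on_glucose(producer, producer$k_g,
                            (1 - Y_h) * producer$Y_g, TRUE)
    if (!is.null(cp)) cand <- c(cand, list(cp))
  }
  if (!is.null(cleaner)) {
    cc <- single_on_glucose(cleaner, cleaner$k_dPTS, cleaner$Y_g, FALSE)
    if (!is.null(cc)) cand <- c(cand, list(cc))
  }

  # scale bounds for start sampling
  G_hi <- max(G_in, 1e-3)
  A_hi <- 5
  B_hi <- max(producer$Y_g * G_in, 1e-2)

  lhs_starts <- function(k, lo, hi) {
    # log-uniform Latin hypercube between lo and hi (vectors per dim)
    U <- lhs::randomLHS(k, length(lo))
    t(exp(log(lo) + t(U) * (log(hi) - log(lo))))
  }

  solve_family <- function(free, assemble, overP, overC, starts) {
    res <- list()
    fn <- function(z) {
      x <- assemble(z)
      branch_rhs(x, u, producer, cleaner, overP, overC)[free]
    }
    for (i in seq_len(nrow(starts))) {
      ans <- damped_newton(fn, starts[i, ])
      if (ans$converged) res[[length(res) + 1L]] <- assemble(ans$x)
    }
    res
  }

  fams <- with_local_seed(seed, {
    out <- list()
    # producer-only: unknowns (G, A, B_P); H tied to B_P at equilibrium
    asm_P <- function(z) c(G = z[[1]], A = z[[2]], B_P = z[[3]],
                           H = if (Y_h < 1) Y_h / (1 - Y_h) * z[[3]] else 0,
                           B_C = 0)
    # cleaner-only: unknowns (G, A, B_C)
    asm_C <- function(z) c(G = z[[1]], A = z[[2]], B_P = 0, H = 0,
                           B_C = z[[3]])
    # interior: unknowns (G, A, B_P, B_C)
    asm_I <- function(z) c(G = z[[1]], A = z[[2]], B_P = z[[3]],
                           H = if (Y_h < 1) Y_h / (1 - Y_h) * z[[3]] else 0,
                           B_C = z[[4]])
    k3 <- max(4L, n_starts %/% 4L)
    for (oP in c(FALSE, TRUE)) {
      s3 <- lhs_starts(k3, c(1e-4, 1e-4, 1e-3), c(G_hi, A_hi, B_hi))
      out <- c(out, solve_family(c("G", "A", "B_P"), asm_P, oP, FALSE, s3))
      for (oC in c(FALSE, TRUE)) {
        s4 <- lhs_starts(n_starts, c(1e-4, 1e-4, 1e-3, 1e-3),
                         c(G_hi, A_hi, B_hi, B_hi))
        out <- c(out, solve_family(c("G", "A", "B_P", "B_C"), asm_I, oP, oC, s4))
      }
      s3c <- lhs_starts(k3, c(1e-4, 1e-4, 1e-3), c(G_hi, A_hi, B_hi))
      out <- c(out, solve_family(c("G", "A", "B_C"), asm_C, FALSE, oP, s3c))
    }
    out
  })
  cand <- c(cand, fams)

  # filter: nonnegativity, true-residual, branch consistency implicit in
  # using the exact rhs; dedupe
  keep <- list()
  scale <- max(1, G_in)
  for (x in cand) {
    if (any(x < -1e-9)) next
    x[x < 0] <- 0
    if (rhs_residual(x, u, producer, cleaner) > residual_tol) next
    dup <- any(vapply(keep, function(y) max(abs(y - x)) / scale < 1e-6,
                      logical(1)))
    if (!dup) keep[[length(keep) + 1L]] <- x
  }
  if (!length(keep)) stop("root finding returned no admissible equilibria")
  lapply(keep, make_ss_result, u = u, producer = producer, cleaner = cleaner,
         converged = TRUE, presence_threshold = presence_threshold)
}

# ---- sweeps, phase diagram, boundaries -------------------------------------

#' Steady states along a dilution-rate grid
#'
#' Computes the stable steady state per dilution rate at fixed `G_in` by
#' long-horizon integration, warm-starting each solve from the previous
#' equilibrium with a small inoculum restored to both strains (the steady
#' state is unique for positive initial biomasses, so continuation only
#' speeds up convergence).
#'
#' @param producer,cleaner `strain_params` (`cleaner = NULL` for the
#'   producer alone).
#' @param G_in inflow glucose concentration \[g L^-1\].
#' @param D_grid increasing vector of dilution rates \[h^-1\].
#' @param presence_threshold regime-classification threshold \[gDW L^-1\].
#' @param tol residual convergence tolerance.
#' @return Data frame with one row per `D`: the equilibrium state, total
#'   producer biomass, regime, residual and convergence flag. The raw
#'   `steady_state_result` list is attached as attribute `"results"`.
#' @export
sweep_dilution <- function(producer, cleaner = NULL, G_in, D_grid,
                           presence_threshold = 1e-6, tol = 1e-9) {
  x_prev <- NULL
  rows <- vector("list", length(D_grid))
  results <- vector("list", length(D_grid))
  for (i in seq_along(D_grid)) {
    u <- reactor_inputs(D = D_grid[i], G_in = G_in, mode = "chemostat")
    x0 <- warm_start(x_prev, cleaner)
    res <- steady_state_by_integration(u, producer, cleaner, x0 = x0,
                                       tol = tol,
                                       presence_threshold = presence_threshold)
    x_prev <- res$state
    results[[i]] <- res
    rows[[i]] <- data.frame(D = D_grid[i], G_in = G_in,
                            t(res$state), B_totP = B_totP(res$state),
                            regime = res$regime, residual = res$residual,
                            converged = res$converged)
  }
  out <- do.call(rbind, rows)
  attr(out, "results") <- results
  out
}

warm_start <- function(x_prev, cleaner) {
  if (is.null(x_prev)) return(NULL)
  x0 <- x_prev
  x0[["B_P"]] <- max(x0[["B_P"]], 0.01)
  x0[["B_C"]] <- if (is.null(cleaner)) 0 else max(x0[["B_C"]], 0.01)
  x0
}

#' Phase diagram of steady-state regimes over (D, G_in)
#'
#' @param producer,cleaner `strain_params`.
#' @param D_grid,Gin_grid grids of dilution rates and inflow glucose
#'   concentrations.
#' @param presence_threshold regime threshold \[gDW L^-1\].
#' @param tol residual tolerance.
#' @return Long-format data frame (`D`, `G_in`, equilibrium state, regime,
#'   residual, converged), one row per grid cell.
#' @export
scan_phase_diagram <- function(producer, cleaner, D_grid, Gin_grid,
                               presence_threshold = 1e-6, tol = 1e-9) {
  cols <- lapply(Gin_grid, function(Gin) {
    sweep_dilution(producer, cleaner, G_in = Gin, D_grid = D_grid,
                   presence_threshold = presence_threshold, tol = tol)
  })
  out <- do.call(rbind, cols)
  rownames(out) <- NULL
  out
}

#' Regime boundaries along the dilution rate at fixed inflow glucose
#'
#' Scans `D` on a regular grid, locates the regime transitions (coexistence
#' onset, cleaner washout, full washout) and refines each by bisection in
#' `D`. Also reports the closed-form overflow-onset dilution rate, which
#' lies slightly below the coexistence onset (overflow must not only start
#' but suffice to sustain the cleaner).
#'
#' @param producer,cleaner `strain_params`.
#' @param G_in inflow glucose concentration \[g L^-1\].
#' @param D_max upper end of the scan \[h^-1\].
#' @param step grid step \[h^-1\].
#' @param refine_tol bisection tolerance on each boundary \[h^-1\].
#' @param presence_threshold biomass presence threshold \[gDW L^-1\].
#' @return List with `coexist_lower`, `coexist_upper`, `full_washout`,
#'   `overflow_onset` (all \[h^-1\]; `NA` when the transition is absent from
#'   the scanned range) and the scan data frame `sweep`.
#' @export
coexistence_boundaries <- function(producer, cleaner, G_in = 20,
                                   D_max = 0.7, step = 0.005,
                                   refine_tol = 1e-3,
                                   presence_threshold = 1e-6) {
  D_grid <- seq(0, D_max, by = step)
  sw <- sweep_dilution(producer, cleaner, G_in = G_in, D_grid = D_grid,
                       presence_threshold = presence_threshold)
  results <- attr(sw, "results")

  cleaner_present <- sw$B_C > presence_threshold
  producer_present <- sw$B_totP > presence_threshold

  solve_at <- function(D, x_near) {
    u <- reactor_inputs(D = D, G_in = G_in, mode = "chemostat")
    steady_state_by_integration(u, producer, cleaner,
                                x0 = warm_start(x_near, cleaner),
                                presence_threshold = presence_threshold)
  }
  # bisection between grid points i (indicator FALSE) and i+1 (TRUE), or the
  # reverse, on a logical indicator of the steady state
  bisect <- function(lo, hi, x_lo, indicator) {
    x_near <- x_lo
    while (hi - lo > refine_tol) {
      mid <- (lo + hi) / 2
      res <- solve_at(mid, x_near)
      x_near <- res$state
      if (indicator(res)) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  ind_cleaner <- function(res) res$state[["B_C"]] > presence_threshold
  ind_no_cleaner <- function(res) res$state[["B_C"]] <= presence_threshold
  ind_washout <- function(res) B_totP(res$state) <= presence_threshold &&
    res$state[["B_C"]] <= presence_threshold

  coexist_lower <- coexist_upper <- full_washout <- NA_real_
  if (any(cleaner_present)) {
    i1 <- which(cleaner_present)[1]
    if (i1 > 1) {
      coexist_lower <- bisect(D_grid[i1 - 1], D_grid[i1],
                              results[[i1 - 1]]$state, ind_cleaner)
    } else coexist_lower <- D_grid[1]
    i2 <- max(which(cleaner_present))
    if (i2 < length(D_grid)) {
      coexist_upper <- bisect(D_grid[i2], D_grid[i2 + 1],
                              results[[i2]]$state, ind_no_cleaner)
    }
  }
  # full washout: first washout cell above the last D where any strain
  # survives (D = 0 itself can be washout in the scanned range: with no
  # inflow the closed reactor decays to an empty state)
  alive <- cleaner_present | producer_present
  if (any(alive)) {
    i3 <- max(which(alive))
    if (i3 < length(D_grid)) {
      full_washout <- bisect(D_grid[i3], D_grid[i3 + 1],
                             results[[i3]]$state, ind_washout)
    }
  }
  list(coexist_lower = coexist_lower,
       coexist_upper = coexist_upper,
       full_washout = full_washout,
       overflow_onset = overflow_onset_dilution(producer),
       sweep = sw)
}
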