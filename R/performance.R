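# Productivity and process yield of the protein production process.
# Chemostat productivity is the steady-state product outflow D * H*; the
# process yield is the product outflow per substrate inflow,
# D H* / (D G_in) = H*/G_in, which at steady state equals Y_h B_totP*/G_in.

#' Productivity and process yield at a chemostat steady state
#'
#' @param res a `steady_state_result`.
#' @param u `reactor_inputs` used to compute it.
#' @param Y_h product yield fraction of the producer.
#' @return List with `D`, `G_in`, `productivity` (`D H*`,
#'   \[g L^-1 h^-1\]), `process_yield` (`H*/G_in`, dimensionless; `NA` with
#'   a warning when `G_in = 0`), `B_totP`, `B_C` and the regime label.
#' @export
chemostat_performance <- function(res, u, Y_h) {
  H <- res$state[["H"]]
  if (u$G_in == 0) {
    warning("process yield undefined for G_in = 0")
    y <- NA_real_
  } else {
    y <- H / u$G_in
  }
  list(D = u$D, G_in = u$G_in,
       productivity = u$D * H,
       process_yield = y,
       B_totP = B_totP(res$state),
       B_C = res$state[["B_C"]],
       regime = res$regime)
}

sweep_performance <- function(sw, Y_h) {
  data.frame(D = sw$D, G_in = sw$G_in,
             productivity = sw$D * sw$H,
             process_yield = sw$H / sw$G_in,
             B_totP = sw$B_totP, B_C = sw$B_C, regime = sw$regime)
}

# golden-section refinement of the argmax of a scalar function on [lo, hi]
golden_max <- function(f, lo, hi, tol = 1e-3) {
  phi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - phi * (b - a); x2 <- a + phi * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while (b - a > tol) {
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + phi * (b - a); f2 <- f(x2)
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - phi * (b - a); f1 <- f(x1)
    }
  }
  x <- (a + b) / 2
  list(argmax = x, max = f(x))
}

refine_max_productivity <- function(producer, cleaner, G_in, sw, tol = 1e-3) {
  prod_grid <- sw$D * sw$H
  i <- which.max(prod_grid)
  lo <- sw$D[max(1L, i - 1L)]
  hi <- sw$D[min(nrow(sw), i + 1L)]
  x_near <- attr(sw, "results")[[i]]$state
  f <- function(D) {
    u <- reactor_inputs(D = D, G_in = G_in, mode = "chemostat")
    res <- steady_state_by_integration(u, producer, cleaner,
                                       x0 = warm_start(x_near, cleaner))
    D * res$state[["H"]]
  }
  golden_max(f, lo, hi, tol = tol)
}

#' Compare consortium and producer-alone performance over dilution rates
#'
#' Computes steady states of the full consortium and of the producer
#' growing in isolation over the same `D` grid at fixed `G_in`, derives
#' productivity (`D H*`) and process yield (`H*/G_in`) curves, refines the
#' productivity maxima by golden-section search, and reports the relative
#' productivity gain of the consortium.
#'
#' @param producer,cleaner `strain_params`.
#' @param G_in inflow glucose concentration \[g L^-1\].
#' @param D_grid increasing dilution-rate grid \[h^-1\].
#' @param refine_tol tolerance of the argmax refinement \[h^-1\].
#' @return List with per-variant curves (`consortium`, `producer_alone`,
#'   data frames) and a `summary` list: per-variant `max_productivity`,
#'   `argmax_D`, `max_yield`, `argmax_D_yield`, and `gain_percent`
#'   `= 100 (max_cons - max_prod) / max_prod`.
#' @export
compare_consortium_vs_producer <- function(producer, cleaner, G_in, D_grid,
                                           refine_tol = 1e-3) {
  Y_h <- producer$Y_h
  sw_c <- sweep_dilution(producer, cleaner, G_in = G_in, D_grid = D_grid)
  sw_p <- sweep_dilution(producer, NULL, G_in = G_in, D_grid = D_grid)
  perf_c <- sweep_performance(sw_c, Y_h)
  perf_p <- sweep_performance(sw_p, Y_h)

  mx_c <- refine_max_productivity(producer, cleaner, G_in, sw_c, refine_tol)
  mx_p <- refine_max_productivity(producer, NULL, G_in, sw_p, refine_tol)

  summarize <- function(perf, mx) {
    iy <- which.max(perf$process_yield)
    list(max_productivity = mx$max, argmax_D = mx$argmax,
         max_yield = perf$process_yield[iy], argmax_D_yield = perf$D[iy])
  }
  s_c <- summarize(perf_c, mx_c)
  s_p <- summarize(perf_p, mx_p)
  list(consortium = perf_c, producer_alone = perf_p,
       summary = list(
         consortium = s_c, producer_alone = s_p,
         gain_percent = 100 * (s_c$max_productivity - s_p$max_productivity) /
           s_p$max_productivity))
}

#' Total steady-state biomass of consortium versus producer alone
#'
#' @inheritParams compare_consortium_vs_producer
#' @return Data frame with per-`D` total biomass (`B_totP* + B_C*` for the
#'   consortium, `B_totP*` for the producer alone) and regimes.
#' @export
total_biomass_comparison <- function(producer, cleaner, G_in, D_grid) {
  sw_c <- sweep_dilution(producer, cleaner, G_in = G_in, D_grid = D_grid)
  sw_p <- sweep_dilution(producer, NULL, G_in = G_in, D_grid = D_grid)
  data.frame(D = D_grid,
             consortium = sw_c$B_totP + sw_c$B_C,
             producer_alone = sw_p$B_totP,
             regime_consortium = sw_c$regime,
             regime_producer = sw_p$regime)
}

#' Fed-batch productivity/yield trade-off summary
#'
#' Compares exponential-regime statistics of the consortium and of the
#' producer alone obtained at the same held glucose level: the rate of
#' increase of the product `H` serves as the productivity index, the
#' constant instantaneous yield as the efficiency index.
#'
#' @param consortium_stats,producer_stats results of
#'   [exponential_regime_stats()] for the two variants.
#' @return List with both rates and yields and logical orderings
#'   `consortium_faster` and `producer_higher_yield`.
#' @export
fedbatch_performance <- function(consortium_stats, producer_stats) {
  list(dlogH_consortium = consortium_stats$dlogH_plus,
       dlogH_producer = producer_stats$dlogH_plus,
       yield_consortium = consortium_stats$yield_plus,
       yield_producer = producer_stats$yield_plus,
       consortium_faster =
         consortium_stats$dlogH_plus > producer_stats$dlogH_plus,
       producer_higher_yield =
         producer_stats$yield_plus > consortium_stats$yield_plus)
}

#' Performance with a cleaner lacking residual glucose uptake
#'
#' Repeats [compare_consortium_vs_producer()] for a hypothetical cleaner
#' with `k_dPTS = 0` (no growth on glucose at all). The rate-yield
#' trade-off persists qualitatively; the coexistence band shrinks since the
#' cleaner can no longer supplement acetate growth with glucose.
#'
#' @inheritParams compare_consortium_vs_producer
#' @export
cleaner_without_glucose_uptake_scenario <- function(producer, cleaner,
                                                    G_in, D_grid,
                                                    refine_tol = 1e-3) {
  cleaner0 <- cleaner
  cleaner0$k_dPTS <- 0
  compare_consortium_vs_producer(producer, cleaner0, G_in, D_grid,
                                 refine_tol = refine_tol)
}
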