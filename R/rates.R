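# Rate laws. Glucose uptake follows a Monod term in G multiplied by an
# acetate-inhibition term; acetate uptake follows a Monod term in A
# multiplied by a carbon-catabolite-repression (CCR) term driven by the
# glucose uptake rate; acetate overflow is proportional to the excess of
# glucose uptake over the threshold l. At zero concentration each Monod
# factor is defined by continuous extension (value 0), so no 0/0 arises.

monod <- function(S, K) {
  if (S <= 0) return(0)
  S / (S + K)
}

# inhibition factor Theta^e / (x^e + Theta^e); value 1 at x = 0
inhib <- function(x, Theta, e) {
  if (x <= 0) return(1)
  Te <- Theta^e
  Te / (x^e + Te)
}

#' Specific uptake and overflow rates of the producer strain
#'
#' Computes the glucose uptake rate `r_up_g`, the acetate uptake rate
#' `r_up_a` and the acetate overflow rate `r_over_a` at ambient glucose `G`
#' and acetate `A`:
#' \deqn{r_{up,g} = k_g \frac{G}{G+K_g}\frac{\Theta_a^n}{A^n+\Theta_a^n}}
#' \deqn{r_{up,a} = k_a \frac{A}{A+K_a}\frac{\Theta_g^m}{r_{up,g}^m+\Theta_g^m}}
#' \deqn{r_{over,a} = k_{over}\max(0, r_{up,g}-l)}
#'
#' @param G,A ambient glucose and acetate concentrations \[g L^-1\].
#' @param p producer `strain_params`.
#' @return Named numeric vector `(r_up_g, r_up_a, r_over_a)`
#'   \[g gDW^-1 h^-1\].
#' @export
producer_rates <- function(G, A, p) {
  if (G < 0 || A < 0) stop("concentrations must be nonnegative")
  r_up_g <- p$k_g * monod(G, p$K_g) * inhib(A, p$Theta_a, p$n)
  r_up_a <- p$k_a * monod(A, p$K_a) * inhib(r_up_g, p$Theta_g, p$m)
  r_over_a <- p$k_over * max(0, r_up_g - p$l)
  c(r_up_g = r_up_g, r_up_a = r_up_a, r_over_a = r_over_a)
}

#' Specific uptake and overflow rates of the cleaner strain
#'
#' As [producer_rates()], with the maximal glucose uptake rate replaced by
#' the residual post-ptsG-deletion rate `k_dPTS` and an additional
#' Acs-mediated acetate uptake term
#' \eqn{k_{Acs} A/(A+K_{Acs})} that escapes CCR.
#'
#' @inheritParams producer_rates
#' @param p cleaner `strain_params` (`is_cleaner = TRUE`).
#' @return Named numeric vector `(r_up_g, r_up_a, r_over_a)`.
#' @export
cleaner_rates <- function(G, A, p) {
  if (G < 0 || A < 0) stop("concentrations must be nonnegative")
  r_up_g <- p$k_dPTS * monod(G, p$K_g) * inhib(A, p$Theta_a, p$n)
  r_up_a <- p$k_a * monod(A, p$K_a) * inhib(r_up_g, p$Theta_g, p$m) +
    p$k_Acs * monod(A, p$K_Acs)
  r_over_a <- p$k_over * max(0, r_up_g - p$l)
  c(r_up_g = r_up_g, r_up_a = r_up_a, r_over_a = r_over_a)
}

#' Rates of a strain, dispatching on the parameter variant
#'
#' @inheritParams producer_rates
#' @param p `strain_params` of either variant.
#' @export
strain_rates <- function(G, A, p) {
  if (p$is_cleaner) cleaner_rates(G, A, p) else producer_rates(G, A, p)
}

#' Specific growth rate from rates and biomass composition
#'
#' \deqn{\mu = (Y_g r_{up,g} + Y_a (r_{up,a} - r_{over,a}))\,B/B_{tot} - k_{deg}}
#' The factor \eqn{B/B_{tot}} accounts for the fact that only autocatalytic
#' biomass (not the heterologous protein) participates in growth; at steady
#' state it equals \eqn{1 - Y_h}.
#'
#' @param rates named rate vector as returned by [strain_rates()].
#' @param B autocatalytic biomass \[gDW L^-1\].
#' @param B_tot total biomass \[gDW L^-1\]; must be positive.
#' @param p `strain_params`.
#' @return Growth rate \[h^-1\].
#' @export
specific_growth_rate <- function(rates, B, B_tot, p) {
  if (B_tot <= 0) stop("specific growth rate undefined for B_tot = 0")
  if (B < 0 || B > B_tot) stop("need 0 <= B <= B_tot")
  r_net <- p$Y_g * rates[["r_up_g"]] +
    p$Y_a * (rates[["r_up_a"]] - rates[["r_over_a"]])
  r_net * B / B_tot - p$k_deg
}

#' Dilution rate at which steady-state glucose uptake reaches the overflow
#' threshold
#'
#' At a producer steady state below overflow, \eqn{\mu^* = D} and CCR keeps
#' acetate uptake negligible, so the uptake rate reaching the threshold `l`
#' corresponds to \deqn{D = (1-Y_h) Y_g l - k_{deg}.}
#' Both a lower glucose yield and a higher product yield shift this onset to
#' lower dilution rates.
#'
#' @param p producer `strain_params`.
#' @return Dilution rate \[h^-1\] (can be negative if `Y_h` is close to 1).
#' @export
overflow_onset_dilution <- function(p) {
  (1 - p$Y_h) * p$Y_g * p$l - p$k_deg
}

#' Right-hand side of the consortium ODE system
#'
#' Time derivatives of `(G, A, B_P, H, B_C)` for a producer-cleaner
#' co-culture in a bioreactor. With `B_C = 0` the system reduces exactly to
#' the producer-only model. In fed-batch mode the glucose balance is removed
#' structurally (`dG/dt = 0`, the implicit feed holding `G` constant) and
#' `D = 0`.
#'
#' @param x state vector (named `G, A, B_P, H, B_C` or `consortium_state`).
#' @param u `reactor_inputs`.
#' @param producer producer `strain_params`.
#' @param cleaner cleaner `strain_params`, or `NULL` for producer-only runs
#'   (the `B_C` derivative is then 0).
#' @return Named numeric derivative vector (same layout as the state).
#' @export
consortium_rhs <- function(x, u, producer, cleaner = NULL) {
  v <- as_state_vector(x)
  G <- if (u$mode == "fedbatch") u$G_held else v[["G"]]
  A <- v[["A"]]; B_P <- v[["B_P"]]; H <- v[["H"]]; B_C <- v[["B_C"]]
  D <- if (u$mode == "chemostat") u$D else 0
  Y_h <- producer$Y_h

  rp <- producer_rates(G, A, producer)
  r_net_P <- producer$Y_g * rp[["r_up_g"]] +
    producer$Y_a * (rp[["r_up_a"]] - rp[["r_over_a"]])

  if (!is.null(cleaner) && B_C != 0) {
    rc <- cleaner_rates(G, A, cleaner)
    r_net_C <- cleaner$Y_g * rc[["r_up_g"]] +
      cleaner$Y_a * (rc[["r_up_a"]] - rc[["r_over_a"]])
  } else {
    rc <- c(r_up_g = 0, r_up_a = 0, r_over_a = 0)
    r_net_C <- 0
    if (is.null(cleaner)) B_C <- 0
  }

  dG <- -rp[["r_up_g"]] * B_P - rc[["r_up_g"]] * B_C + D * (u$G_in - G)
  dA <- (rp[["r_over_a"]] - rp[["r_up_a"]]) * B_P +
    (rc[["r_over_a"]] - rc[["r_up_a"]]) * B_C - D * A
  dB_P <- (1 - Y_h) * r_net_P * B_P - producer$k_deg * B_P - D * B_P
  dH <- Y_h * r_net_P * B_P - producer$k_deg * H - D * H
  k_deg_C <- if (is.null(cleaner)) 0 else cleaner$k_deg
  dB_C <- r_net_C * B_C - k_deg_C * B_C - D * B_C

  if (u$mode == "fedbatch") dG <- 0
  c(G = dG, A = dA, B_P = dB_P, H = dH, B_C = dB_C)
}

# ---- analytic partial derivatives of the rate laws --------------------------
# Used by the analytic Jacobian of the consortium system. Each strain's
# rates depend on the state only through (G, A); the overflow kink at
# r_up_g = l is handled by the indicator of the current overflow branch
# (one-sided derivative on the kink itself).

strain_rate_partials <- function(G, A, p) {
  kg <- if (p$is_cleaner) p$k_dPTS else p$k_g
  mg <- monod(G, p$K_g)
  ia <- inhib(A, p$Theta_a, p$n)
  r_up_g <- kg * mg * ia

  dmg_dG <- if (G <= 0) (if (p$K_g > 0) 1 / p$K_g else 0) else
    p$K_g / (G + p$K_g)^2
  # d/dA of Theta^n/(A^n + Theta^n); at A = 0 the derivative is 0 for n > 1,
  # -n/Theta for n = 1, unbounded for n < 1 (approximated by one-sided 0).
  dia_dA <- if (A <= 0) {
    if (p$n == 1) -1 / p$Theta_a else 0
  } else {
    -p$Theta_a^p$n * p$n * A^(p$n - 1) / (A^p$n + p$Theta_a^p$n)^2
  }
  dg_dG <- kg * dmg_dG * ia
  dg_dA <- kg * mg * dia_dA

  ma <- monod(A, p$K_a)
  ccr <- inhib(r_up_g, p$Theta_g, p$m)
  dccr_dr <- if (r_up_g <= 0) {
    if (p$m == 1) -1 / p$Theta_g else 0
  } else {
    -p$Theta_g^p$m * p$m * r_up_g^(p$m - 1) / (r_up_g^p$m + p$Theta_g^p$m)^2
  }
  dma_dA <- if (A <= 0) (if (p$K_a > 0) 1 / p$K_a else 0) else
    p$K_a / (A + p$K_a)^2

  da_dG <- p$k_a * ma * dccr_dr * dg_dG
  da_dA <- p$k_a * (dma_dA * ccr + ma * dccr_dr * dg_dA)
  if (p$is_cleaner) {
    dmacs_dA <- if (A <= 0) (if (p$K_Acs > 0) 1 / p$K_Acs else 0) else
      p$K_Acs / (A + p$K_Acs)^2
    da_dA <- da_dA + p$k_Acs * dmacs_dA
  }

  over <- r_up_g > p$l
  list(
    r_up_g = r_up_g,
    r_up_a = p$k_a * ma * ccr +
      if (p$is_cleaner) p$k_Acs * monod(A, p$K_Acs) else 0,
    r_over_a = p$k_over * max(0, r_up_g - p$l),
    dg = c(G = dg_dG, A = dg_dA),
    da = c(G = da_dG, A = da_dA),
    dover = c(G = if (over) p$k_over * dg_dG else 0,
              A = if (over) p$k_over * dg_dA else 0)
  )
}
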