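# Synthetic calibration datasets. The generator emulates the structure of
# the exponential-growth rate measurements used for calibration: one
# glucose-only condition class (with overflow), an acetate-only class at
# several acetate levels, and a mixed class with an acetate gradient at
# fixed high glucose. Measurement error is multiplicative lognormal,
# applied sign-preservingly to the magnitude of each observable.

#' Design of a synthetic calibration experiment
#'
#' @param glucose_only_levels glucose concentrations of the glucose-only
#'   class \[g L^-1\].
#' @param acetate_only_levels acetate concentrations of the acetate-only
#'   class \[g L^-1\].
#' @param mixed_G fixed glucose level of the mixed class \[g L^-1\].
#' @param mixed_A_levels acetate gradient of the mixed class \[g L^-1\].
#' @param replicates replicate measurements per condition.
#' @param noise_cv multiplicative coefficient of variation of the
#'   measurement error (0 disables noise).
#' @param seed RNG seed used by [generate_rate_dataset()].
#' @return A validated `data_design` list.
#' @export
data_design <- function(glucose_only_levels, acetate_only_levels,
                        mixed_G, mixed_A_levels,
                        replicates = 1L, noise_cv = 0, seed = 1L) {
  d <- list(glucose_only_levels = glucose_only_levels,
            acetate_only_levels = acetate_only_levels,
            mixed_G = mixed_G, mixed_A_levels = mixed_A_levels,
            replicates = as.integer(replicates), noise_cv = noise_cv,
            seed = as.integer(seed))
  if (any(c(d$glucose_only_levels, d$acetate_only_levels, d$mixed_G,
            d$mixed_A_levels) < 0))
    stop("all concentration levels must be nonnegative")
  if (d$noise_cv < 0) stop("noise_cv must be nonnegative")
  if (d$replicates < 1L) stop("replicates must be >= 1")
  class(d) <- "data_design"
  d
}

#' Default calibration design
#'
#' Mirrors the visible structure of the calibration experiment: exponential
#' growth at saturating glucose (glucose-only), on acetate alone at several
#' levels, and on high glucose with an acetate gradient
#' `A in {0, 0.25, 0.5, 1, 2, 4} g L^-1`. Three replicates per condition
#' and a 5% multiplicative CV are the defaults; both are modelling choices,
#' stable across package versions.
#'
#' @param replicates replicates per condition.
#' @param noise_cv multiplicative noise CV.
#' @param seed RNG seed.
#' @return A `data_design`.
#' @export
default_paper_like_design <- function(replicates = 3L, noise_cv = 0.05,
                                      seed = 1L) {
  data_design(glucose_only_levels = 3.6,
              acetate_only_levels = c(0.5, 1, 2, 4),
              mixed_G = 3.6,
              mixed_A_levels = c(0, 0.25, 0.5, 1, 2, 4),
              replicates = replicates, noise_cv = noise_cv, seed = seed)
}

#' Generate a synthetic rate dataset from known parameters
#'
#' Computes the noise-free observables of every condition in the design via
#' [predict_exponential_rates()] and applies independent multiplicative
#' lognormal noise with the design's coefficient of variation to each
#' observable (mean-one factors; the sign of net secretion values is
#' preserved, noise acting on the magnitude). With `noise_cv = 0` the
#' output is a pure function of `(true_params, design)`. Reproducible under
#' the design seed; the session RNG state is restored.
#'
#' @param true_params generating `strain_params` (producer variant).
#' @param design a `data_design`.
#' @return A validated rate dataset data frame (see
#'   [validate_rate_dataset()]) with the design attached as attribute
#'   `"design"`.
#' @export
generate_rate_dataset <- function(true_params, design) {
  stopifnot(inherits(design, "data_design"))
  grid <- rbind(
    data.frame(condition = "glucose_only",
               G = design$glucose_only_levels, A = 0),
    data.frame(condition = "acetate_only",
               G = 0, A = design$acetate_only_levels),
    data.frame(condition = "glucose_plus_acetate",
               G = design$mixed_G, A = design$mixed_A_levels))
  grid <- grid[rep(seq_len(nrow(grid)), each = design$replicates), ]
  rownames(grid) <- NULL
  pred <- predict_exponential_rates(true_params, grid$G, grid$A)
  obs <- as.matrix(pred)
  if (design$noise_cv > 0) {
    sdlog <- sqrt(log(1 + design$noise_cv^2))
    noise <- with_local_seed(design$seed, {
      matrix(stats::rlnorm(length(obs), meanlog = -sdlog^2 / 2, sdlog = sdlog),
             nrow = nrow(obs))
    })
    obs <- obs * noise  # multiplicative on the magnitude; sign untouched
  }
  out <- data.frame(condition = grid$condition, G = grid$G, A = grid$A,
                    mu_plus = obs[, "mu_plus"],
                    rupg_plus = obs[, "rupg_plus"],
                    net_acetate_plus = obs[, "net_acetate_plus"])
  validate_rate_dataset(out)
  attr(out, "design") <- design
  out
}

#' Full two-step calibration of a rate dataset
#'
#' Convenience pipeline: closed-form step-1 inversion followed by the
#' step-2 least-squares fit, returning a complete producer parameter set.
#'
#' @param data rate dataset.
#' @param fixed named list of literature-fixed constants
#'   (`K_g, K_a, l, k_deg`).
#' @param ... passed to [fit_inhibition_params()].
#' @return List with `step1` (closed-form estimates), `fit` (the
#'   `fit_result`) and `params` (calibrated `strain_params`).
#' @export
calibrate_two_step <- function(data, fixed, ...) {
  step1 <- closed_form_estimates(data, fixed)
  base <- strain_params(
    k_g = step1$k_g, K_g = fixed$K_g, Theta_a = 1, n = 1,
    k_over = step1$k_over, l = fixed$l, k_a = step1$k_a, K_a = fixed$K_a,
    Theta_g = 1, m = 1, Y_g = step1$Y_g, Y_a = step1$Y_a,
    Y_h = 0, k_deg = fixed$k_deg)
  fit <- fit_inhibition_params(data, base, ...)
  list(step1 = step1, fit = fit, params = fit$params)
}
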