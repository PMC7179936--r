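# Two-step calibration from exponential-growth rate measurements.
# Step 1 fixes the maximal-rate and yield constants by closed-form inversion
# of the steady-state rate relations in the two single-substrate condition
# classes; step 2 estimates the acetate-inhibition and CCR parameters from
# the mixed glucose+acetate gradient by bound-constrained least squares.

rate_dataset_columns <- c("condition", "G", "A", "mu_plus", "rupg_plus",
                          "net_acetate_plus")
condition_classes <- c("glucose_only", "acetate_only", "glucose_plus_acetate")

#' Validate a calibration rate dataset
#'
#' A rate dataset holds exponential-growth measurements: condition class,
#' ambient glucose `G` and acetate `A` \[g L^-1\], growth rate `mu_plus`
#' \[h^-1\], glucose uptake rate `rupg_plus` \[g gDW^-1 h^-1\] and net
#' acetate exchange rate `net_acetate_plus = r_up_a - r_over_a`
#' \[g gDW^-1 h^-1\], negative for net secretion.
#'
#' @param data data frame to validate.
#' @return The data (invisibly) after checks; errors name the problem.
#' @export
validate_rate_dataset <- function(data) {
  missing_cols <- setdiff(rate_dataset_columns, names(data))
  if (length(missing_cols))
    stop("rate dataset lacks columns: ", paste(missing_cols, collapse = ", "))
  bad <- !data$condition %in% condition_classes
  if (any(bad))
    stop("unknown condition class in rows: ",
         paste(which(bad), collapse = ", "))
  if (any(data$G < 0) || any(data$A < 0))
    stop("concentrations must be nonnegative")
  g <- data$condition == "glucose_only"
  if (any(data$A[g] > 1e-6))
    stop("glucose_only records must have A = 0")
  a <- data$condition == "acetate_only"
  if (any(data$G[a] > 0))
    stop("acetate_only records must have G = 0")
  invisible(data)
}

#' Read / write the calibration CSV dialect
#'
#' Fixed header `condition, G, A, mu_plus, rupg_plus, net_acetate_plus`.
#'
#' @param path file path.
#' @return [read_rate_dataset()]: validated data frame.
#' @export
read_rate_dataset <- function(path) {
  data <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_rate_dataset(data)
  data
}

#' @rdname read_rate_dataset
#' @param data rate dataset data frame.
#' @export
write_rate_dataset <- function(data, path) {
  validate_rate_dataset(data)
  utils::write.csv(data[rate_dataset_columns], path, row.names = FALSE)
  invisible(path)
}

#' Closed-form step-1 estimates of the maximal-rate and yield constants
#'
#' From acetate-only records (no glucose, hence no overflow and no CCR):
#' \deqn{k_a = r^+_{up,a} (A+K_a)/A, \quad Y_a = (\mu^+ + k_{deg})/r^+_{up,a}.}
#' From glucose-only records with overflow (`A = 0`, so the inhibition term
#' is 1 and CCR shuts off acetate uptake, making the measured net acetate
#' exchange pure secretion):
#' \deqn{k_g = r^+_{up,g}(G+K_g)/G,\quad
#'       k_{over} = -r^+_{net,a}/(r^+_{up,g}-l),\quad
#'       Y_g = (\mu^+ + k_{deg} - Y_a r^+_{net,a})/r^+_{up,g}.}
#' Multiple records are averaged after per-record inversion.
#'
#' @param data rate dataset with `glucose_only` (overflow present) and
#'   `acetate_only` records.
#' @param fixed named list of the literature-fixed parameters
#'   `K_g, K_a, l, k_deg`.
#' @return Named list `k_g, k_over, k_a, Y_g, Y_a`.
#' @export
closed_form_estimates <- function(data, fixed) {
  validate_rate_dataset(data)
  for (nm in c("K_g", "K_a", "l", "k_deg"))
    if (is.null(fixed[[nm]])) stop("fixed parameter '", nm, "' missing")
  ac <- data[data$condition == "acetate_only", ]
  gl <- data[data$condition == "glucose_only", ]
  if (!nrow(ac)) stop("no acetate_only records in dataset")
  if (!nrow(gl)) stop("no glucose_only records in dataset")
  if (any(ac$A <= 0))
    stop("acetate_only record with A = 0 cannot be inverted (row ",
         which(data$condition == "acetate_only" & data$A <= 0)[1], ")")
  # with G = 0 there is no overflow, so the measured net exchange is r_up_a
  k_a <- mean(ac$net_acetate_plus * (ac$A + fixed$K_a) / ac$A)
  Y_a <- mean((ac$mu_plus + fixed$k_deg) / ac$net_acetate_plus)
  if (any(gl$G <= 0)) stop("glucose_only record with G = 0 cannot be inverted")
  over <- gl$rupg_plus - fixed$l
  if (any(over <= 0))
    stop("glucose_only record without overflow (r_up_g <= l) in row ",
         which(data$condition == "glucose_only")[which(over <= 0)[1]])
  k_g <- mean(gl$rupg_plus * (gl$G + fixed$K_g) / gl$G)
  k_over <- mean(-gl$net_acetate_plus / over)
  Y_g <- mean((gl$mu_plus + fixed$k_deg - Y_a * gl$net_acetate_plus) /
                gl$rupg_plus)
  list(k_g = k_g, k_over = k_over, k_a = k_a, Y_g = Y_g, Y_a = Y_a)
}

#' Model predictions of the exponential-growth observables
#'
#' Wild-type exponential growth in batch (`D = 0`, `Y_h = 0`): the rates at
#' ambient `(G, A)` and the growth rate
#' \eqn{\mu^+ = Y_g r_{up,g} + Y_a (r_{up,a} - r_{over,a}) - k_{deg}}.
#'
#' @param p `strain_params` (producer variant).
#' @param G,A ambient concentrations (vectorized) \[g L^-1\].
#' @return Data frame with `mu_plus`, `rupg_plus`, `net_acetate_plus`.
#' @export
predict_exponential_rates <- function(p, G, A) {
  stopifnot(length(G) == length(A))
  out <- t(vapply(seq_along(G), function(i) {
    r <- producer_rates(G[i], A[i], p)
    net <- r[["r_up_a"]] - r[["r_over_a"]]
    c(mu_plus = p$Y_g * r[["r_up_g"]] + p$Y_a * net - p$k_deg,
      rupg_plus = r[["r_up_g"]],
      net_acetate_plus = net)
  }, numeric(3)))
  as.data.frame(out)
}

#' Coefficient of determination per observable
#'
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}} with the total sum of squares taken
#' about the mean of the observations.
#'
#' @param predicted,observed paired numeric vectors.
#' @return Scalar R-squared; error when the observations have zero variance.
#' @export
goodness_of_fit <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed))
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) stop("R^2 undefined: observations have zero variance")
  1 - sum((observed - predicted)^2) / ss_tot
}

fit_objective <- function(theta, data, base) {
  p <- base
  p$Theta_a <- theta[[1]]; p$n <- theta[[2]]
  p$Theta_g <- theta[[3]]; p$m <- theta[[4]]
  pred <- predict_exponential_rates(p, data$G, data$A)
  sum((pred$mu_plus - data$mu_plus)^2) +
    sum((pred$rupg_plus - data$rupg_plus)^2) +
    sum((pred$net_acetate_plus - data$net_acetate_plus)^2)
}

#' Step-2 estimation of the inhibition and CCR parameters
#'
#' Estimates `Theta_a, n, Theta_g, m` from the mixed glucose+acetate
#' records by minimizing the pooled (unweighted) sum of squared errors of
#' the three observables, holding the step-1 constants fixed. The
#' bound-constrained optimization (`optim`, L-BFGS-B) is multi-started to
#' guard against local minima; estimates pinned at a bound are flagged.
#'
#' @param data rate dataset containing `glucose_plus_acetate` records.
#' @param base `strain_params` carrying the fixed step-1 constants.
#' @param init optional numeric start `(Theta_a, n, Theta_g, m)`.
#' @param lower,upper box bounds on `(Theta_a, n, Theta_g, m)`.
#' @param n_starts number of optimizer starts (the first is `init`).
#' @return List of class `fit_result`: `params` (updated `strain_params`),
#'   `estimates`, `rss`, per-observable `r_squared`, `at_bounds` flags,
#'   `identifiable` diagnostics and `convergence` code.
#' @export
fit_inhibition_params <- function(data, base, init = NULL,
                                  lower = c(0.01, 0.5, 0.01, 0.5),
                                  upper = c(10, 4, 5, 4),
                                  n_starts = 8) {
  validate_rate_dataset(data)
  mix <- data[data$condition == "glucose_plus_acetate", ]
  if (!nrow(mix)) stop("no glucose_plus_acetate records in dataset")
  identifiable <- any(mix$A > 0)
  if (!identifiable)
    warning("all mixed records have A = 0: Theta_a and n are unidentifiable")
  if (is.null(init)) init <- c(0.5, 1, 0.25, 1)

  starts <- matrix(rep(init, n_starts), nrow = n_starts, byrow = TRUE)
  if (n_starts > 1) {
    # spread the extra starts geometrically across the box
    fr <- seq(0.15, 0.85, length.out = n_starts - 1)
    for (j in 1:4) {
      starts[-1, j] <- exp(log(lower[j]) + fr * (log(upper[j]) - log(lower[j])))
    }
  }
  best <- NULL
  for (i in seq_len(n_starts)) {
    fit <- tryCatch(
      stats::optim(starts[i, ], fit_objective, data = mix, base = base,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(factr = 1e7, maxit = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("all optimizer starts failed")
  if (best$convergence != 0)
    warning("optimizer did not report convergence (code ", best$convergence, ")")
  theta <- best$par
  names(theta) <- c("Theta_a", "n", "Theta_g", "m")
  at_bounds <- theta <= lower + 1e-8 | theta >= upper - 1e-8
  if (any(at_bounds))
    warning("estimates pinned at bounds: ",
            paste(names(theta)[at_bounds], collapse = ", "))

  p <- base
  p$Theta_a <- theta[["Theta_a"]]; p$n <- theta[["n"]]
  p$Theta_g <- theta[["Theta_g"]]; p$m <- theta[["m"]]
  pred <- predict_exponential_rates(p, mix$G, mix$A)
  r2_safe <- function(pr, ob) {
    tryCatch(goodness_of_fit(pr, ob), error = function(e) NA_real_)
  }
  r2 <- c(mu_plus = r2_safe(pred$mu_plus, mix$mu_plus),
          rupg_plus = r2_safe(pred$rupg_plus, mix$rupg_plus),
          net_acetate_plus = r2_safe(pred$net_acetate_plus,
                                     mix$net_acetate_plus))
  structure(list(params = p, estimates = theta, rss = best$value,
                 r_squared = r2, at_bounds = at_bounds,
                 identifiable = identifiable,
                 convergence = best$convergence,
                 lower = lower, upper = upper),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("inhibition/CCR parameter fit\n")
  print(round(x$estimates, 6))
  cat(sprintf("  RSS %.4g; R^2: %s\n", x$rss,
              paste(sprintf("%s %.3f", names(x$r_squared), x$r_squared),
                    collapse = ", ")))
  invisible(x)
}

#' Bootstrap confidence intervals for the step-2 estimates
#'
#' Case resampling with replacement, stratified by condition class, of the
#' full dataset; step 2 is refit per replicate starting from the point
#' estimate. Percentile intervals are returned. Deterministic under a fixed
#' seed; the RNG state of the session is restored afterwards.
#'
#' @param data rate dataset used for the original fit.
#' @param base `strain_params` with the step-1 constants.
#' @param fit `fit_result` from [fit_inhibition_params()].
#' @param n_boot number of bootstrap replicates.
#' @param seed RNG seed.
#' @param level confidence level.
#' @return List with `ci` (matrix, rows `Theta_a, n, Theta_g, m`, columns
#'   `lower, upper`), the replicate `estimates` matrix and the number of
#'   failed replicates; errors if more than 20% of replicates fail.
#' @export
bootstrap_identifiability <- function(data, base, fit, n_boot = 200,
                                      seed = 1, level = 0.95) {
  validate_rate_dataset(data)
  strata <- split(seq_len(nrow(data)), data$condition)
  reps <- with_local_seed(seed, {
    lapply(seq_len(n_boot), function(b) {
      idx <- unlist(lapply(strata, function(s)
        s[sample.int(length(s), length(s), replace = TRUE)]))
      boot <- data[idx, ]
      suppressWarnings(tryCatch(
        fit_inhibition_params(boot, base, init = unname(fit$estimates),
                              lower = fit$lower, upper = fit$upper,
                              n_starts = 1)$estimates,
        error = function(e) NULL))
    })
  })
  failed <- sum(vapply(reps, is.null, logical(1)))
  if (failed > 0.2 * n_boot)
    stop(failed, " of ", n_boot, " bootstrap replicates failed to fit")
  est <- do.call(rbind, reps[!vapply(reps, is.null, logical(1))])
  alpha <- (1 - level) / 2
  ci <- t(apply(est, 2, stats::quantile, probs = c(alpha, 1 - alpha),
                names = FALSE))
  colnames(ci) <- c("lower", "upper")
  list(ci = ci, estimates = est, failed = failed)
}

#' Biomass degradation rate from the maintenance coefficient
#'
#' Growth-independent maintenance expenditure `C_m` \[g gDW^-1 h^-1\]
#' relates to the first-order biomass degradation rate by
#' `k_deg = C_m * Y_g`.
#'
#' @param C_m maintenance coefficient \[g gDW^-1 h^-1\].
#' @param Y_g glucose biomass yield \[gDW g^-1\].
#' @return `k_deg` \[h^-1\].
#' @export
kdeg_from_maintenance <- function(C_m, Y_g) {
  if (C_m < 0 || Y_g < 0) stop("C_m and Y_g must be nonnegative")
  C_m * Y_g
}

#' Scale the maximal glucose uptake rate of a strain
#'
#' Glucose-uptake-system deletions reduce the uptake rate; the observed
#' relative decrease maps onto the same proportional decrease of `k_g`. The
#' default cleaner's residual rate corresponds to a fraction of 1/4 (ptsG
#' deletion).
#'
#' @param p `strain_params`.
#' @param uptake_fraction factor in \[0, 1\] applied to `k_g`.
#' @return Modified `strain_params`.
#' @export
apply_uptake_mutation <- function(p, uptake_fraction) {
  if (uptake_fraction < 0 || uptake_fraction > 1)
    stop("uptake_fraction must lie in [0, 1]")
  p$k_g <- p$k_g * uptake_fraction
  p
}
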