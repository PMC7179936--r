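#' Kinetic and yield parameters of one strain
#'
#' Builds a validated parameter set for either the heterologous-protein
#' producer or the acetate cleaner variant of the model. Units are fixed
#' package-wide: time in h, substrate concentrations in g L^-1, biomass in
#' gDW L^-1, specific rates in g gDW^-1 h^-1.
#'
#' @param k_g maximal glucose uptake rate \[g gDW^-1 h^-1\].
#' @param K_g glucose half-saturation constant \[g L^-1\].
#' @param Theta_a acetate growth-inhibition constant \[g L^-1\].
#' @param n acetate-inhibition exponent (dimensionless).
#' @param k_over acetate overflow proportionality constant (dimensionless).
#' @param l overflow threshold on the glucose uptake rate \[g gDW^-1 h^-1\].
#' @param k_a maximal acetate uptake rate \[g gDW^-1 h^-1\].
#' @param K_a acetate half-saturation constant \[g L^-1\].
#' @param Theta_g carbon catabolite repression (CCR) constant
#'   \[g gDW^-1 h^-1\].
#' @param m CCR exponent (dimensionless).
#' @param Y_g glucose biomass yield \[gDW g^-1\].
#' @param Y_a acetate biomass yield \[gDW g^-1\].
#' @param Y_h fraction of biomass synthesis diverted to heterologous protein
#'   (dimensionless, in \[0, 1)). Forced to 0 for the cleaner.
#' @param k_deg first-order biomass degradation (maintenance) rate \[h^-1\].
#' @param k_dPTS residual glucose uptake rate of the cleaner after ptsG
#'   deletion \[g gDW^-1 h^-1\] (cleaner only).
#' @param k_Acs maximal Acs-mediated acetate uptake rate \[g gDW^-1 h^-1\]
#'   (cleaner only).
#' @param K_Acs half-saturation constant of the Acs uptake term \[g L^-1\]
#'   (cleaner only).
#' @param is_cleaner logical; selects the cleaner rate-law variant.
#'
#' @return An object of class `strain_params` (a named list).
#' @export
strain_params <- function(k_g, K_g, Theta_a, n, k_over, l, k_a, K_a,
                          Theta_g, m, Y_g, Y_a, Y_h = 0, k_deg = 0,
                          k_dPTS = NA_real_, k_Acs = NA_real_,
                          K_Acs = NA_real_, is_cleaner = FALSE) {
  p <- list(k_g = k_g, K_g = K_g, Theta_a = Theta_a, n = n, k_over = k_over,
            l = l, k_a = k_a, K_a = K_a, Theta_g = Theta_g, m = m,
            Y_g = Y_g, Y_a = Y_a, Y_h = Y_h, k_deg = k_deg,
            k_dPTS = k_dPTS, k_Acs = k_Acs, K_Acs = K_Acs,
            is_cleaner = isTRUE(is_cleaner))
  nonneg <- c("k_g", "K_g", "Theta_a", "n", "k_over", "l", "k_a", "K_a",
              "Theta_g", "m", "Y_g", "Y_a", "Y_h", "k_deg")
  for (nm in nonneg) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      stop(sprintf("parameter '%s' must be a single nonnegative number", nm))
    }
  }
  if (p$is_cleaner) {
    p$Y_h <- 0
    for (nm in c("k_dPTS", "k_Acs", "K_Acs")) {
      v <- p[[nm]]
      if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
        stop(sprintf("cleaner parameter '%s' must be a nonnegative number", nm))
      }
    }
  } else if (p$Y_h >= 1) {
    stop("producer Y_h must lie in [0, 1)")
  }
  class(p) <- "strain_params"
  p
}

#' @export
print.strain_params <- function(x, ...) {
  cat(if (x$is_cleaner) "Cleaner" else "Producer", "strain parameters:\n")
  flds <- setdiff(names(x), "is_cleaner")
  if (!x$is_cleaner) flds <- setdiff(flds, c("k_dPTS", "k_Acs", "K_Acs"))
  for (nm in flds) cat(sprintf("  %-8s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Bioreactor control inputs
#'
#' @param D dilution rate \[h^-1\]; must be 0 in batch and fed-batch modes.
#' @param G_in glucose concentration in the inflow \[g L^-1\].
#' @param mode one of `"batch"`, `"chemostat"`, `"fedbatch"`.
#' @param G_held reactor glucose concentration held constant by the
#'   (implicit) feed in fed-batch mode \[g L^-1\].
#'
#' @return An object of class `reactor_inputs`.
#' @export
reactor_inputs <- function(D = 0, G_in = 0, mode = c("chemostat", "batch", "fedbatch"),
                           G_held = NA_real_) {
  mode <- match.arg(mode)
  if (!is.numeric(D) || length(D) != 1L || is.na(D) || D < 0)
    stop("D must be a single nonnegative number")
  if (!is.numeric(G_in) || length(G_in) != 1L || is.na(G_in) || G_in < 0)
    stop("G_in must be a single nonnegative number")
  if (mode == "batch" && D != 0) stop("batch mode requires D = 0")
  if (mode == "fedbatch") {
    if (D != 0) stop("fed-batch mode requires D = 0")
    if (!is.numeric(G_held) || is.na(G_held) || G_held <= 0)
      stop("fed-batch mode requires G_held > 0")
  }
  structure(list(D = D, G_in = G_in, mode = mode, G_held = G_held),
            class = "reactor_inputs")
}

#' Consortium state vector
#'
#' State of the bioreactor: glucose `G`, acetate `A`, producer autocatalytic
#' biomass `B_P`, heterologous protein `H`, cleaner biomass `B_C`. The total
#' producer biomass is `B_totP = B_P + H`.
#'
#' @param G,A,B_P,H,B_C nonnegative concentrations (\[g L^-1\] for
#'   substrates, \[gDW L^-1\] for biomass components).
#' @return A named numeric vector of class `consortium_state`.
#' @export
consortium_state <- function(G = 0, A = 0, B_P = 0, H = 0, B_C = 0) {
  x <- c(G = G, A = A, B_P = B_P, H = H, B_C = B_C)
  if (any(!is.finite(x)) || any(x < 0))
    stop("all state components must be finite and nonnegative")
  class(x) <- c("consortium_state", "numeric")
  x
}

state_names <- c("G", "A", "B_P", "H", "B_C")

as_state_vector <- function(x) {
  v <- unclass(x)
  if (is.null(names(v))) names(v) <- state_names
  v[state_names]
}

#' Total producer biomass of a state
#'
#' @param x a `consortium_state` (or named state vector).
#' @return `B_P + H` \[gDW L^-1\].
#' @export
B_totP <- function(x) {
  v <- as_state_vector(x)
  unname(v[["B_P"]] + v[["H"]])
}

# ---- parameter file I/O -----------------------------------------------------
# Flat TOML-style `key = value` files, keys named after the model symbols.
# Lines starting with '#' and blank lines are ignored.

#' Read a flat key = value parameter file
#'
#' @param path file path.
#' @return Named list of numeric (or logical) values.
#' @export
read_params_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed parameter line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(kv[2])
    out[[key]] <- if (val %in% c("true", "false")) val == "true" else as.numeric(val)
  }
  out
}

#' Write a flat key = value parameter file
#'
#' @param params named list of scalar values.
#' @param path file path.
#' @export
write_params_file <- function(params, path) {
  fmt <- vapply(params, function(v) {
    if (is.logical(v)) tolower(as.character(v)) else format(v, digits = 15)
  }, character(1))
  writeLines(paste(names(params), "=", fmt), path)
  invisible(path)
}

#' Default calibrated parameter sets
#'
#' Reads the packaged default parameter file (the calibrated wild-type
#' kinetic constants plus the cleaner-design constants) and returns the
#' producer and cleaner `strain_params`. The producer's product yield can be
#' overridden; the shipped default is `Y_h = 0.2`.
#'
#' @param Y_h product yield fraction of the producer; `NULL` keeps the value
#'   in the file.
#' @param path optional path to an alternative parameter file.
#' @return List with elements `producer` and `cleaner`.
#' @export
default_params <- function(Y_h = NULL, path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_params.toml", package = "coculture")
  }
  kv <- read_params_file(path)
  if (!is.null(Y_h)) kv$Y_h <- Y_h
  producer <- strain_params(
    k_g = kv$k_g, K_g = kv$K_g, Theta_a = kv$Theta_a, n = kv$n,
    k_over = kv$k_over, l = kv$l, k_a = kv$k_a, K_a = kv$K_a,
    Theta_g = kv$Theta_g, m = kv$m, Y_g = kv$Y_g, Y_a = kv$Y_a,
    Y_h = kv$Y_h, k_deg = kv$k_deg)
  cleaner <- strain_params(
    k_g = kv$k_g, K_g = kv$K_g, Theta_a = kv$Theta_a, n = kv$n,
    k_over = kv$k_over, l = kv$l, k_a = kv$k_a, K_a = kv$K_a,
    Theta_g = kv$Theta_g, m = kv$m, Y_g = kv$Y_g, Y_a = kv$Y_a,
    Y_h = 0, k_deg = kv$k_deg, k_dPTS = kv$k_dPTS, k_Acs = kv$k_Acs,
    K_Acs = kv$K_Acs, is_cleaner = TRUE)
  list(producer = producer, cleaner = cleaner)
}
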