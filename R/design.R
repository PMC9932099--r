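R_KCAL <- 1.9872e-3  # gas constant, kcal mol^-1 K^-1

#' Thermal energy RT in kcal/mol
#'
#' @param temperature Temperature in K.
#' @return \eqn{R T} in kcal mol^-1 (R = 1.9872e-3 kcal mol^-1 K^-1);
#'   0.602 kcal/mol at 303 K.
#' @export
rt_energy <- function(temperature = 303.15) {
  stopifnot(all(temperature > 0))
  R_KCAL * temperature
}

#' Check the dilute-host design rule for a titration
#'
#' Accurate extraction of a binding constant from shift titrations requires
#' the host concentration to satisfy \eqn{[H]_T K < 1}; violating it (as can
#' be forced by signal-to-noise constraints for very strong binders) leads
#' to a larger uncertainty in the derived constant.
#'
#' @param host_total Total host concentration in M.
#' @param K_guess A-priori association constant in M^-1.
#' @return List with `product` (\eqn{[H]_T K}), `pass`, and a `message`.
#' @examples
#' check_dilute_regime(1e-5, 3.01e4)  # pass, product 0.301
#' @export
check_dilute_regime <- function(host_total, K_guess) {
  stopifnot(host_total > 0, K_guess > 0)
  prod <- host_total * K_guess
  list(product = prod, pass = prod < 1,
       message = if (prod < 1) "dilute regime satisfied ([H]T K < 1)"
       else paste("[H]T K >= 1: expect a larger uncertainty in the",
                  "derived binding constant"))
}

#' Recommended total-guest range for a shift titration
#'
#' Returns the guest (titrant) concentration window
#' \deqn{G_{min} = (0.2 [H]_T + 0.25)/K, \qquad
#'       G_{max} = (0.8 [H]_T + 4)/K}
#' that spans the informative part of the 1:1 binding isotherm for an
#' a-priori constant `K_guess`. `G_min < G_max` always.
#'
#' @param host_total Total host concentration in M.
#' @param K_guess A-priori association constant in M^-1.
#' @return Named vector `c(G_min = , G_max = )` in M.
#' @export
titrant_range <- function(host_total, K_guess) {
  stopifnot(host_total >= 0, K_guess > 0)
  c(G_min = (0.2 * host_total + 0.25) / K_guess,
    G_max = (0.8 * host_total + 4) / K_guess)
}

#' Build a titration schedule of total guest concentrations
#'
#' The first point is always the guest-free reference; the remaining
#' `n_points - 1` values span the [titrant_range()] window, log-spaced by
#' default (the isotherm is closer to linear in log guest concentration).
#'
#' @param host_total Total host concentration in M.
#' @param K_guess A-priori association constant in M^-1.
#' @param n_points Total number of titration points including the reference
#'   (>= 3; >= 6 recommended for fitting).
#' @param spacing `"log"` (default) or `"linear"`.
#' @return Numeric vector of total guest concentrations, starting at 0.
#' @export
make_schedule <- function(host_total, K_guess, n_points = 12L,
                          spacing = c("log", "linear")) {
  spacing <- match.arg(spacing)
  n_points <- as.integer(n_points)
  stopifnot(n_points >= 3L)
  rng <- titrant_range(host_total, K_guess)
  g <- if (spacing == "log")
    exp(seq(log(rng[["G_min"]]), log(rng[["G_max"]]),
            length.out = n_points - 1L))
  else seq(rng[["G_min"]], rng[["G_max"]], length.out = n_points - 1L)
  c(0, g)
}

#' Convert an association constant to a standard free energy
#'
#' \deqn{\Delta G^\circ = -R T \ln K} with R = 1.9872e-3 kcal mol^-1 K^-1.
#' K must be expressed in M^-1 (relative to the 1 M standard state).
#'
#' @param K Association constant(s) in M^-1 (> 0).
#' @param temperature Temperature in K.
#' @return Free energy in kcal mol^-1.
#' @examples
#' K_to_deltaG(66500, 303)  # about -6.69 kcal/mol
#' @export
K_to_deltaG <- function(K, temperature = 303.15) {
  if (any(!is.finite(K)) || any(K <= 0))
    stop("K must be positive", call. = FALSE)
  stopifnot(all(temperature > 0))
  -rt_energy(temperature) * log(K)
}

#' Weighted fit of NMR affinity against simulation binding energy
#'
#' Regresses \eqn{\ln K} (K in M^-1) on the simulation interaction energy
#' \eqn{\langle U+W \rangle} (kcal/mol) over the records flagged `charged`
#' (the filled points); neutral-host records are carried along but excluded
#' from the fit, since self-inclusion of their arms breaks the trend. The
#' fit is weighted least squares with effective variances that fold the
#' energy (x) uncertainties into the \eqn{\ln K} (y) uncertainties through
#' the current slope, iterated to self-consistency. The reference slope
#' \eqn{-1/(RT)} - the line expected if \eqn{\ln K} tracked the energy as a
#' pure Boltzmann factor, i.e. the RT guide line - is reported for
#' comparison. With equal uncertainties the fit reduces to ordinary least
#' squares.
#'
#' @param records Data frame with columns `host`, `K_mM` (constant in
#'   mM^-1), `K_err_mM`, `energy` (kcal/mol), `energy_err`, and logical
#'   `charged`.
#' @param temperature Temperature in K (for the reference slope).
#' @return An `affinity_energy_fit`: `slope`, `slope_se`, `intercept`,
#'   `intercept_se`, `reference_slope`, `n_used`, and the working data with
#'   weights.
#' @export
correlate_affinity_energy <- function(records, temperature = 303.15) {
  need <- c("host", "K_mM", "K_err_mM", "energy", "energy_err", "charged")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (any(records$K_mM <= 0))
    stop("binding constants must be positive", call. = FALSE)
  use <- records[as.logical(records$charged), , drop = FALSE]
  if (nrow(use) < 3L)
    stop("at least 3 records with uncertainties are required for the fit",
         call. = FALSE)
  y <- log(use$K_mM * 1000)            # ln K with K in M^-1
  sy <- use$K_err_mM / use$K_mM        # d(ln K)
  x <- use$energy
  sx <- use$energy_err

  slope <- stats::coef(stats::lm(y ~ x))[2]
  fit <- NULL
  for (it in 1:8) {
    v_eff <- sy^2 + slope^2 * sx^2
    v_eff[v_eff == 0] <- min(v_eff[v_eff > 0], 1)  # guard exact inputs
    fit <- stats::lm(y ~ x, weights = 1 / v_eff)
    new_slope <- stats::coef(fit)[2]
    if (abs(new_slope - slope) <= 1e-12 * max(abs(slope), 1)) break
    slope <- new_slope
  }
  sm <- summary(fit)$coefficients
  structure(list(slope = unname(sm[2, 1]), slope_se = unname(sm[2, 2]),
                 intercept = unname(sm[1, 1]), intercept_se = unname(sm[1, 2]),
                 reference_slope = -1 / rt_energy(temperature),
                 n_used = nrow(use),
                 excluded = records$host[!as.logical(records$charged)],
                 residuals = unname(stats::residuals(fit)),
                 weights = 1 / v_eff, data = use,
                 temperature = temperature),
            class = "affinity_energy_fit")
}

#' @export
print.affinity_energy_fit <- function(x, ...) {
  cat("Affinity vs simulation energy (weighted fit of ln K on <U+W>)\n")
  cat(sprintf("  slope     %.4g +/- %.2g (ln K per kcal/mol)\n",
              x$slope, x$slope_se))
  cat(sprintf("  intercept %.4g +/- %.2g\n", x$intercept, x$intercept_se))
  cat(sprintf("  reference (Boltzmann) slope -1/RT = %.4g at %.1f K\n",
              x$reference_slope, x$temperature))
  cat(sprintf("  records used: %d%s\n", x$n_used,
              if (length(x$excluded))
                paste0(" (excluded: ", paste(x$excluded, collapse = ", "), ")")
              else ""))
  invisible(x)
}
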