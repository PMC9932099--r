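default_sensitivities <- function(model) {
  # plausible invented per-proton limiting shifts (ppm): cavity-facing H3/H5
  # large, exterior H1/H6 small; second bound state gets a distinct pattern
  # including a sign flip so multi-state curves can be non-monotonic.
  # These magnitudes are generator defaults, not measured values.
  base <- list(
    c(H1 = 0.020, H3 = 0.120, H5 = 0.150, H6 = 0.040),
    c(H1 = 0.030, H3 = -0.060, H5 = 0.100, H6 = 0.015),
    c(H1 = -0.010, H3 = 0.050, H5 = -0.080, H6 = 0.025))
  sp <- model$species$label
  sens <- sapply(seq_along(sp), function(i) base[[((i - 1L) %% 3L) + 1L]])
  colnames(sens) <- sp
  sens
}

# Two-state experiments must sweep the guest well past the host so the
# secondary 2:1 state populates and then depletes (the non-monotonic
# signature that identifies its constant): the 1:1 design window is extended
# tenfold at the top and sampled with 14 points.
two_state_schedule <- function(host_total, K1, n_points = 14L) {
  tr <- titrant_range(host_total, K1)
  c(0, exp(seq(log(tr[["G_min"]]), log(10 * tr[["G_max"]]),
               length.out = n_points - 1L)))
}

#' Define a synthetic titration scenario
#'
#' Bundles the ground truth of a simulated study: the binding model with its
#' true constants, true per-proton shift sensitivities, the host
#' concentration, the guest schedule, the shift noise level and the number
#' of replicate experiments. Defaults mirror the conditions of dilute
#' cyclodextrin work: host below 0.1 mM, a 12-point log-spaced schedule
#' spanning the recommended titrant window, Gaussian shift noise of
#' 0.002 ppm, and triplicate experiments.
#'
#' @param host Host label (free text).
#' @param model A [binding_model()] carrying the true constants.
#' @param sens True sensitivities (protons x species matrix or named vector
#'   for single-species models); invented defaults are used when `NULL`.
#' @param host_total Total host concentration in M.
#' @param schedule Total guest schedule in M (first point 0); built with
#'   [make_schedule()] from the model's effective constant when `NULL`.
#' @param n_points Schedule length when `schedule` is `NULL`.
#' @param noise_sd Gaussian shift noise in ppm (>= 0).
#' @param replicates Number of replicate experiments (>= 1).
#' @param seed Base RNG seed recorded in all outputs.
#' @param temperature Temperature in K.
#'
#' @return A `scenario_spec`.
#' @export
scenario <- function(host, model, sens = NULL, host_total,
                     schedule = NULL, n_points = 12L, noise_sd = 0.002,
                     replicates = 3L, seed = 20230215L,
                     temperature = 303.15) {
  stopifnot(inherits(model, "binding_model"), host_total > 0,
            noise_sd >= 0, replicates >= 1L)
  if (is.null(sens)) sens <- default_sensitivities(model)
  sens <- normalize_sensitivities(sens, model)
  if (is.null(rownames(sens)))
    rownames(sens) <- paste0("p", seq_len(nrow(sens)))
  if (is.null(schedule)) {
    keff <- effective_one_to_one_constant(model)
    if (!is.finite(keff)) {
      sp <- model$species
      keff <- sp$beta[which(sp$host == 1L & sp$guest == 1L)[1]]
    }
    schedule <- make_schedule(host_total, keff, n_points)
  }
  structure(list(host = host, model = model, sens = sens,
                 host_total = host_total, schedule = schedule,
                 noise_sd = noise_sd, replicates = as.integer(replicates),
                 seed = as.integer(seed), temperature = temperature),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("Scenario '%s': %s\n", x$host, x$model$name))
  cat(sprintf("  [H]T = %.3g M, %d points, noise %.3g ppm, %d replicates, seed %d\n",
              x$host_total, length(x$schedule), x$noise_sd, x$replicates,
              x$seed))
  invisible(x)
}

#' Generate synthetic titration datasets from a scenario
#'
#' Computes the noise-free fast-exchange shift curves from the scenario's
#' true model and adds iid Gaussian noise of `noise_sd` ppm to every point
#' and proton except the first (guest-free) point, which is exactly zero by
#' the referencing convention. Output is deterministic for a fixed seed; the
#' full ground truth travels with each dataset as the `"truth"` attribute.
#'
#' @param spec A [scenario()].
#' @param seed Overrides the scenario seed when given.
#' @return List of [titration_data()] objects, one per replicate, each with
#'   a `"truth"` attribute (model, sensitivities, noise_sd, seed, replicate).
#' @export
generate_titration <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (is.null(seed)) seed <- spec$seed
  clean <- predict_shifts(spec$model, spec$sens, spec$host_total,
                          spec$schedule)
  set.seed(seed)
  lapply(seq_len(spec$replicates), function(rep) {
    noise <- matrix(stats::rnorm(length(clean), 0, spec$noise_sd),
                    nrow(clean), ncol(clean))
    noise[1L, ] <- 0
    y <- clean + noise
    y[1L, ] <- 0
    d <- titration_data(spec$host_total, spec$schedule, y,
                        temperature = spec$temperature)
    attr(d, "truth") <- list(host = spec$host, model = spec$model,
                             sens = spec$sens, noise_sd = spec$noise_sd,
                             seed = seed, replicate = rep)
    d
  })
}

#' Generate a synthetic Job (continuous-variation) dataset
#'
#' Simulates the shift-based Job ordinate \eqn{\Delta\delta \cdot [H]_T}
#' from the scenario's true model and adds Gaussian shift noise (scaled by
#' \eqn{[H]_T} on the ordinate); the r = 0 and r = 1 endpoints are
#' noise-free zeros.
#'
#' @param spec A [scenario()].
#' @param total_conc Fixed total concentration \eqn{C_T} in M.
#' @param grid Host mole fractions.
#' @param noise_sd Shift noise in ppm (defaults to the scenario's).
#' @param seed Overrides the scenario seed when given.
#' @return A `job_data` with a `"truth"` attribute.
#' @export
generate_job <- function(spec, total_conc, grid = seq(0, 1, length.out = 21),
                         noise_sd = NULL, seed = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (is.null(noise_sd)) noise_sd <- spec$noise_sd
  if (is.null(seed)) seed <- spec$seed
  jd <- simulate_job(spec$model, total_conc, grid, sens = spec$sens)
  if (noise_sd > 0) {
    set.seed(seed)
    interior <- jd$r > 0 & jd$r < 1
    eps <- matrix(stats::rnorm(sum(interior) * ncol(jd$ordinate), 0, noise_sd),
                  sum(interior), ncol(jd$ordinate))
    jd$ordinate[interior, ] <- jd$ordinate[interior, ] +
      eps * (jd$r[interior] * total_conc)
  }
  attr(jd, "truth") <- list(host = spec$host, model = spec$model,
                            sens = spec$sens, noise_sd = noise_sd,
                            seed = seed)
  jd
}

#' Built-in synthetic scenarios spanning the studied affinity range
#'
#' A library of immutable scenarios whose true constants span the measured
#' cyclodextrin:fentanyl range (simple 1:1 constants 0.2-30.1 mM^-1 over
#' five hosts, plus two-state scenarios at 44/2.1 and 67/2.5 mM^-1 using
#' the 2:1 self-competition variant). Host concentrations are all below
#' 0.1 mM, chosen to satisfy the dilute rule [H]T K < 1 wherever the
#' affinity permits (the strongest binder violates it, as the real
#' experiment had to). Shift sensitivities are plausible invented values -
#' the underlying study reports none - with cavity-facing H3/H5 protons
#' given the largest responses.
#'
#' @param host Optional scenario name; when given, that single
#'   [scenario()] is returned (unknown names are an error).
#' @return A named list of `scenario_spec` objects, or a single one.
#' @export
builtin_scenarios <- function(host = NULL) {
  lib <- list(
    `SBX-1` = scenario("SBX-1", one_to_one_model(21.7e3, "SBX-1 simple 1:1"),
                       host_total = 2e-5),
    SBX = scenario("SBX", one_to_one_model(30.1e3, "SBX simple 1:1"),
                   host_total = 3e-5),
    `SBN-1` = scenario("SBN-1", one_to_one_model(2.7e3, "SBN-1 simple 1:1"),
                       host_total = 8e-5),
    SBN = scenario("SBN", one_to_one_model(1.6e3, "SBN simple 1:1"),
                   host_total = 8e-5),
    `SBN+1` = scenario("SBN+1", one_to_one_model(0.2e3, "SBN+1 simple 1:1"),
                       host_total = 8e-5),
    SBX_two_state = scenario(
      "SBX_two_state",
      host_sandwich_model(44e3, 2.1e3, "SBX two-state"),
      host_total = 2e-5,
      schedule = two_state_schedule(2e-5, 44e3)),
    `SBX+1_two_state` = scenario(
      "SBX+1_two_state",
      host_sandwich_model(67e3, 2.5e3, "SBX+1 two-state"),
      host_total = 9e-5,
      schedule = two_state_schedule(9e-5, 67e3))
  )
  if (is.null(host)) return(lib)
  if (!host %in% names(lib))
    stop("unknown scenario: ", host, call. = FALSE)
  lib[[host]]
}
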