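#' @importFrom minpack.lm nls.lm nls.lm.control
NULL

# min-norm least squares via SVD; tolerates rank-deficient bases
svd_solve <- function(A, B, tol = 1e-10) {
  sv <- svd(A)
  keep <- sv$d > tol * max(sv$d, .Machine$double.eps)
  coef <- sv$v[, keep, drop = FALSE] %*%
    ((t(sv$u[, keep, drop = FALSE]) %*% B) / sv$d[keep])
  list(coef = coef, rank = sum(keep))
}

# inflection heuristic: K ~ 1/[G]_T at half-maximal shift of the
# largest-amplitude proton; plateau gives the sensitivity scale
guess_constants <- function(data, model, fit_labels) {
  Y <- data$shifts
  n <- nrow(Y)
  p_star <- which.max(abs(Y[n, ]))
  y <- abs(Y[, p_star])
  half <- y[n] / 2
  j <- which(y >= half)
  j <- j[j > 1L]
  j <- if (length(j)) min(j) else n
  K0 <- 1 / data$total_guest[j]
  sp <- model$species
  beta0 <- stats::setNames(sp$beta, sp$label)
  for (lab in fit_labels) {
    i <- match(lab, sp$label)
    ord <- sp$host[i] + sp$guest[i]
    beta0[lab] <- if (ord == 1L) 0.5 else K0 * (K0 / 20) ^ (ord - 2L)
  }
  beta0
}

set_betas <- function(model, beta) {
  model$species$beta[match(names(beta), model$species$label)] <- beta
  model
}

#' Global nonlinear least-squares fit of binding constants to titration data
#'
#' Fits the formation constants of `model` to the referenced shift changes of
#' all reporter protons simultaneously: the constants are shared across
#' protons while each (proton, species) pair has its own shift sensitivity.
#' Constants are fitted in log space (guaranteeing positivity) by
#' Levenberg-Marquardt; for any trial set of constants the sensitivities,
#' which enter linearly, are profiled out by least squares (variable
#' projection). Standard errors come from the Gauss-Newton covariance of the
#' full parameter vector (constants and sensitivities) at the optimum, and
#' the full parameter correlation matrix is returned. A Jacobian whose
#' numerical rank is below the parameter count - the signature of a
#' structurally degenerate model such as two 1:1 orientations - is flagged
#' `rank_deficient`, and standard errors are then computed from the
#' pseudo-inverse (unidentifiable directions get `NA` correlation).
#'
#' @param data A [titration_data()]; at least 6 points.
#' @param model A [binding_model()]; its `beta` values serve as initial
#'   guesses unless `init` or the built-in heuristic overrides them.
#' @param init Optional named vector of initial constants (by species label).
#'   By default initial values come from the inflection heuristic
#'   (K of order 1/[G]_T at half-maximal shift).
#' @param fit_species Labels of species whose constants are fitted
#'   (default: all).
#' @param weights Optional per-proton weights (e.g. `1/sigma_p`) applied to
#'   the residuals; default equal weighting.
#' @param lower,upper Soft bounds on each fitted constant (applied on the
#'   log scale). Defaults span 1e-2 to 1e9 for second-order (1:1) species
#'   and a correspondingly wider range for higher-order formation constants.
#' @param control Passed to [minpack.lm::nls.lm.control()].
#'
#' @return A `global_fit` object: fitted `model`, `sensitivities` (protons x
#'   species, ppm), `constants` data frame with standard errors,
#'   `correlation` matrix over all parameters, `rss`, `sigma`, `fitted`
#'   curves, `converged` and `rank_deficient` flags.
#' @export
fit_global <- function(data, model, init = NULL, fit_species = NULL,
                       weights = NULL, lower = NULL, upper = NULL,
                       control = list()) {
  stopifnot(inherits(data, "titration_data"), inherits(model, "binding_model"))
  sp <- model$species
  fit_labels <- if (is.null(fit_species)) sp$label else fit_species
  if (!all(fit_labels %in% sp$label))
    stop("unknown species in `fit_species`", call. = FALSE)
  n <- length(data$total_guest)
  P <- ncol(data$shifts)
  n_par <- length(fit_labels) + P * nrow(sp)
  if (n < 6L || (n - 1L) * P < n_par + 2L)
    stop("too few titration points for the number of free parameters",
         call. = FALSE)

  w <- if (is.null(weights)) rep(1, P) else rep_len(as.numeric(weights), P)

  beta0 <- guess_constants(data, model, fit_labels)
  if (!is.null(init)) {
    if (is.null(names(init)) && length(init) == length(fit_labels))
      names(init) <- fit_labels
    beta0[names(init)] <- init
  }
  th0 <- log(beta0[fit_labels])

  ord <- sp$host[match(fit_labels, sp$label)] +
    sp$guest[match(fit_labels, sp$label)]
  if (is.null(lower)) lower <- ifelse(ord <= 2L, 1e-2, 1e-4)
  if (is.null(upper)) upper <- ifelse(ord <= 2L, 1e9, 1e14)
  th0 <- pmin(pmax(th0, log(lower)), log(upper))

  # first (reference) point carries no information by construction
  Yw <- sweep(data$shifts[-1L, , drop = FALSE], 2, w, `*`)

  basis_at <- function(th) {
    m <- set_betas(model, stats::setNames(exp(th), fit_labels))
    shift_basis(m, data$total_host, data$total_guest)[-1L, , drop = FALSE]
  }
  resid_at <- function(th) {
    FF <- basis_at(th)
    S <- svd_solve(FF, Yw)$coef          # species x protons (weighted)
    as.vector(Yw - FF %*% S)
  }

  ctrl <- do.call(minpack.lm::nls.lm.control,
                  utils::modifyList(list(maxiter = 200, ftol = 1e-15,
                                         ptol = 1e-13), control))
  lmfit <- minpack.lm::nls.lm(par = th0, fn = resid_at,
                              lower = log(lower), upper = log(upper),
                              control = ctrl)
  th_hat <- lmfit$par
  converged <- lmfit$info %in% c(1, 2, 3, 4)

  FF <- basis_at(th_hat)
  sol <- svd_solve(FF, Yw)
  Sw <- sol$coef                               # species x protons, weighted
  S_hat <- t(sweep(Sw, 2, w, `/`))             # protons x species, ppm
  dimnames(S_hat) <- list(colnames(data$shifts), sp$label)
  res_mat <- Yw - FF %*% Sw
  rss <- sum(res_mat^2)

  # full Jacobian over (log constants, sensitivities)
  nres <- (n - 1L) * P
  k <- length(fit_labels)
  par_names <- c(paste0("logK_", fit_labels),
                 paste0("dd_", rep(colnames(data$shifts), each = nrow(sp)),
                        ".", rep(sp$label, P)))
  J <- matrix(0, nres, k + P * nrow(sp), dimnames = list(NULL, par_names))
  hstep <- 1e-6
  for (i in seq_len(k)) {
    e <- rep(0, k); e[i] <- hstep
    dF <- (basis_at(th_hat + e) - basis_at(th_hat - e)) / (2 * hstep)
    pred_d <- dF %*% Sw                        # (n-1) x P, weighted
    J[, i] <- -as.vector(pred_d)
  }
  for (p in seq_len(P)) {
    rows <- (p - 1L) * (n - 1L) + seq_len(n - 1L)
    for (s in seq_len(nrow(sp))) {
      J[rows, k + (p - 1L) * nrow(sp) + s] <- -FF[, s] * w[p]
    }
  }

  svj <- svd(J)
  rank <- sum(svj$d > 1e-8 * max(svj$d))
  rank_deficient <- rank < ncol(J)
  dof <- max(nres - rank, 1L)
  sigma2 <- rss / dof
  dinv <- ifelse(svj$d > 1e-8 * max(svj$d), 1 / svj$d^2, 0)
  covp <- sigma2 * svj$v %*% (dinv * t(svj$v))
  dimnames(covp) <- list(par_names, par_names)
  se <- sqrt(pmax(diag(covp), 0))
  corr <- covp / outer(se, se)
  corr[!is.finite(corr)] <- NA_real_
  diag(corr) <- 1

  beta_hat <- stats::setNames(sp$beta, sp$label)
  beta_hat[fit_labels] <- exp(th_hat)
  model_hat <- set_betas(model, beta_hat)
  se_logK <- stats::setNames(rep(NA_real_, nrow(sp)), sp$label)
  se_logK[fit_labels] <- se[seq_len(k)]
  constants <- data.frame(
    label = sp$label, host = sp$host, guest = sp$guest,
    beta = beta_hat[sp$label],
    se_beta = beta_hat[sp$label] * se_logK[sp$label],
    se_log = se_logK[sp$label],
    fitted = sp$label %in% fit_labels,
    row.names = NULL, stringsAsFactors = FALSE)

  fitted_full <- predict_shifts(model_hat, S_hat,
                                data$total_host, data$total_guest)
  res_full <- data$shifts - fitted_full

  out <- structure(list(
    model = model_hat, sensitivities = S_hat, constants = constants,
    covariance = covp, correlation = corr, rss = rss,
    sigma = sqrt(sigma2), dof = dof, rank = rank,
    rank_deficient = rank_deficient, converged = converged,
    info = lmfit$info, message = lmfit$message,
    fitted = fitted_full, residuals = res_full,
    weights = w, fit_species = fit_labels, data = data), class = "global_fit")
  if (!converged)
    warning("fit did not converge: ", lmfit$message, call. = FALSE)
  out
}

#' @export
print.global_fit <- function(x, ...) {
  cat("Global titration fit:", x$model$name, "\n")
  cc <- x$constants[x$constants$fitted, ]
  for (i in seq_len(nrow(cc))) {
    cat(sprintf("  %-8s beta = %.4g +/- %.2g (%s)\n", cc$label[i],
                cc$beta[i], cc$se_beta[i],
                if (cc$host[i] + cc$guest[i] == 2L)
                  format_K(cc$beta[i]) else "higher order"))
  }
  cat(sprintf("  RSS = %.4g, sigma = %.3g ppm, converged: %s%s\n",
              x$rss, x$sigma, x$converged,
              if (x$rank_deficient) ", RANK DEFICIENT (degenerate model)" else ""))
  invisible(x)
}

format_K <- function(K_M) sprintf("%.3g mM^-1", K_M / 1000)

delta_logratio_se <- function(cov, a, b) {
  # se of log(beta_a) - log(beta_b)
  sqrt(max(cov[a, a] + cov[b, b] - 2 * cov[a, b], 0))
}

#' Fit the two-state ("self-competitive") extension of the 1:1 model
#'
#' Fits titration data with a model containing two bound states. Shipped
#' variants:
#' \describe{
#'   \item{`"host_sandwich"` (default)}{H + G = HG (K1) plus H + HG = H2G
#'     (stepwise K2): a second host competes for the bound guest. This
#'     variant is identifiable and reproduces the non-monotonic
#'     reporter-proton curves and off-0.5 Job maxima that motivate the
#'     two-state analysis.}
#'   \item{`"guest_sandwich"`}{HG + G = HG2 (stepwise K2).}
#'   \item{`"two_orientation"`}{two distinct 1:1 bound states (guest "up" /
#'     "down"). In fast exchange this model is structurally degenerate - only
#'     K1 + K2 is identifiable - and the fit is flagged rank-deficient.}
#'   \item{`"conformer"`}{1:1 binding competing with a guest-free
#'     self-included host conformer; likewise degenerate in fast exchange.}
#' }
#' Constants are reported ordered K1 >= K2 for the exchangeable
#' two-orientation variant; for the sandwich variants K1 is the 1:1 constant
#' and K2 the stepwise second-association constant. Assignment of the two
#' constants to physical bound orientations cannot be made from titration
#' data alone and requires external (ROESY / simulation) evidence; the
#' returned `note` records this. A warning is raised when the secondary
#' state's host population never exceeds `population_threshold`, and the fit
#' is flagged `less_robust` when any parameter correlation exceeds 0.95 in
#' magnitude.
#'
#' @param data A [titration_data()].
#' @param variant Two-state model variant (see Details).
#' @param init Optional `c(K1 = , K2 = )` initial constants in M^-1
#'   (K2 stepwise for the sandwich variants; dimensionless conformer
#'   constant for `"conformer"`).
#' @param population_threshold Secondary-state host-population fraction below
#'   which a low-population warning is raised (default 0.05).
#' @param ... Passed to [fit_global()].
#'
#' @return A `two_state_fit` (also a `global_fit`) with elements `K1`, `K2`,
#'   `K1_se`, `K2_se`, `secondary_population`, `low_population`,
#'   `max_correlation`, `less_robust`, and `note`.
#' @export
fit_two_state <- function(data, variant = c("host_sandwich", "guest_sandwich",
                                            "two_orientation", "conformer"),
                          init = NULL, population_threshold = 0.05, ...) {
  variant <- match.arg(variant)
  K10 <- if (!is.null(init) && "K1" %in% names(init)) init[["K1"]] else {
    tmp <- guess_constants(data, one_to_one_model(1), "HG")
    tmp[["HG"]]
  }

  # the two-state objective has boundary local optima (pure 1:1, pure
  # second state); a small multistart over the secondary constant keeps the
  # fit out of them
  starts <- if (!is.null(init) && "K2" %in% names(init)) {
    list(c(K10, init[["K2"]]))
  } else if (variant == "two_orientation") {
    list(c(K10, K10 / 3))
  } else if (variant == "conformer") {
    list(c(K10, 0.5), c(K10, 0.05))
  } else {
    list(c(K10, K10 / 5), c(K10, K10 / 50), c(K10, K10 / 500),
         c(3 * K10, K10 / 20))
  }

  make_model <- function(k1, k2) switch(variant,
    host_sandwich = host_sandwich_model(k1, k2),
    guest_sandwich = guest_sandwich_model(k1, k2),
    two_orientation = two_orientation_model(k1, k2),
    conformer = conformer_model(k1, k2))

  fit <- NULL
  for (st in starts) {
    model <- make_model(st[1], st[2])
    cand <- withCallingHandlers(
      tryCatch(fit_global(data, model,
                          init = stats::setNames(model$species$beta,
                                                 model$species$label), ...),
               error = function(e) NULL),
      warning = function(w) invokeRestart("muffleWarning"))
    if (is.null(cand)) next
    if (is.null(fit) || (cand$converged && !fit$converged) ||
        (cand$converged == fit$converged && cand$rss < fit$rss))
      fit <- cand
  }
  if (is.null(fit))
    stop("two-state fit failed from every starting point", call. = FALSE)
  if (!fit$converged)
    warning("two-state fit did not converge: ", fit$message, call. = FALSE)
  cov <- fit$covariance
  bb <- stats::setNames(fit$constants$beta, fit$constants$label)

  labs <- fit$constants$label
  if (variant %in% c("host_sandwich", "guest_sandwich")) {
    second <- labs[2]
    K1 <- bb[["HG"]]; K2 <- bb[[second]] / bb[["HG"]]
    K1_se <- K1 * sqrt(cov["logK_HG", "logK_HG"])
    K2_se <- K2 * delta_logratio_se(cov, paste0("logK_", second), "logK_HG")
  } else if (variant == "two_orientation") {
    k <- sort(bb, decreasing = TRUE)
    K1 <- k[[1]]; K2 <- k[[2]]
    K1_se <- K1 * sqrt(cov[paste0("logK_", names(k)[1]),
                           paste0("logK_", names(k)[1])])
    K2_se <- K2 * sqrt(cov[paste0("logK_", names(k)[2]),
                           paste0("logK_", names(k)[2])])
    second <- names(k)[2]
  } else {
    K1 <- bb[["HG"]]; K2 <- bb[["H-closed"]]
    K1_se <- K1 * sqrt(cov["logK_HG", "logK_HG"])
    K2_se <- K2 * sqrt(cov["logK_H-closed", "logK_H-closed"])
    second <- "H-closed"
  }

  # secondary-state host population along the titration
  sp <- fit$model$species
  i2 <- match(second, sp$label)
  pop <- vapply(seq_along(data$total_guest), function(j) {
    st <- solve_speciation(fit$model, data$total_host[j], data$total_guest[j])
    sp$host[i2] * st$complexes[[second]] / data$total_host[j]
  }, numeric(1))
  low_pop <- max(pop) < population_threshold
  if (low_pop)
    warning(sprintf(
      "secondary state population never exceeds %.1f%%; its constant is poorly determined",
      100 * population_threshold), call. = FALSE)

  off <- fit$correlation
  diag(off) <- 0
  max_corr <- max(abs(off), na.rm = TRUE)
  less_robust <- fit$rank_deficient || max_corr > 0.95

  fit$variant <- variant
  fit$K1 <- unname(K1); fit$K2 <- unname(K2)
  fit$K1_se <- unname(K1_se); fit$K2_se <- unname(K2_se)
  fit$secondary_species <- second
  fit$secondary_population <- pop
  fit$low_population <- low_pop
  fit$max_correlation <- max_corr
  fit$less_robust <- less_robust
  fit$note <- paste("Assignment of K1/K2 to physical bound orientations",
                    "requires external (ROESY or simulation) evidence;",
                    "titration data alone cannot make it.")
  class(fit) <- c("two_state_fit", class(fit))
  fit
}

#' @export
print.two_state_fit <- function(x, ...) {
  cat("Two-state fit (", x$variant, "): ", x$model$name, "\n", sep = "")
  cat(sprintf("  K1 = %s +/- %.2g mM^-1\n", format_K(x$K1), x$K1_se / 1000))
  if (x$variant == "conformer")
    cat(sprintf("  conformer beta = %.3g +/- %.2g (dimensionless)\n",
                x$K2, x$K2_se))
  else
    cat(sprintf("  K2 = %s +/- %.2g mM^-1\n", format_K(x$K2), x$K2_se / 1000))
  cat(sprintf("  max |parameter correlation| = %.3f%s\n", x$max_correlation,
              if (x$less_robust) " (less robust)" else ""))
  if (x$low_population)
    cat(sprintf("  secondary state population stays below %.0f%%\n",
                100 * max(x$secondary_population)))
  if (x$rank_deficient)
    cat("  RANK DEFICIENT: constants not separately identifiable\n")
  cat(" ", x$note, "\n")
  invisible(x)
}

# named constants of a fit, for replicate aggregation
fit_constants <- function(fit) {
  if (inherits(fit, "two_state_fit")) c(K1 = fit$K1, K2 = fit$K2)
  else {
    cc <- fit$constants[fit$constants$fitted, ]
    stats::setNames(cc$beta, cc$label)
  }
}

#' Aggregate binding constants over replicate fits
#'
#' Experiments are typically run in triplicate; the headline constant is the
#' sample mean across replicate fits and its uncertainty the sample standard
#' deviation (n - 1 denominator).
#'
#' @param results List of `global_fit` (or `two_state_fit`) objects from the
#'   same model fitted to replicate datasets; at least 2.
#'
#' @return A `replicate_summary`: data frame of per-constant `mean`, `sd`
#'   (M^-1) plus the replicate count.
#' @examples
#' # K fits of 28.0, 30.0 and 32.3 mM^-1 average to 30.1 +/- 2.15 mM^-1
#' @export
aggregate_replicates <- function(results) {
  if (length(results) < 2L)
    stop("at least 2 replicate fits are required for a standard deviation",
         call. = FALSE)
  stopifnot(all(vapply(results, inherits, logical(1), "global_fit")))
  sig <- vapply(results, function(f)
    paste(f$model$name, paste(f$model$species$label, collapse = "|"),
          if (inherits(f, "two_state_fit")) f$variant else ""), character(1))
  if (length(unique(sig)) != 1L)
    stop("replicate fits must come from the same model", call. = FALSE)
  km <- do.call(rbind, lapply(results, fit_constants))
  structure(list(
    constants = data.frame(
      constant = colnames(km),
      mean = colMeans(km),
      sd = apply(km, 2, stats::sd),
      row.names = NULL, stringsAsFactors = FALSE),
    n = length(results), model_name = results[[1]]$model$name),
    class = "replicate_summary")
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat(sprintf("Replicate summary (%d replicates): %s\n", x$n, x$model_name))
  cc <- x$constants
  for (i in seq_len(nrow(cc)))
    cat(sprintf("  %-6s %.4g +/- %.3g M^-1  (%s +/- %.3g mM^-1)\n",
                cc$constant[i], cc$mean[i], cc$sd[i],
                format_K(cc$mean[i]), cc$sd[i] / 1000))
  invisible(x)
}

#' Assess whether the simple 1:1 model is adequate for a titration
#'
#' Compares the simple 1:1 fit against a two-state fit on the same data and
#' tests each reporter-proton curve for non-monotonic behaviour beyond
#' noise. The per-proton noise scale is the median absolute deviation of the
#' first differences of the curve; a proton is non-monotonic when the curve
#' shows an interior extremum whose rise and fall both exceed 3 sigma. The
#' 1:1 model is declared inadequate when any proton is non-monotonic or when
#' its residual sum of squares exceeds the (converged) two-state model's by
#' more than `rss_factor`. When no proton moves beyond 3 sigma at all, the
#' verdict is that no significant binding is detected (K consistent with 0)
#' and neither model is supported.
#'
#' @param data The [titration_data()] both fits were run on.
#' @param fit_simple `global_fit` of the simple 1:1 model.
#' @param fit_two_state Optional `two_state_fit` on the same data.
#' @param rss_factor Residual-ratio threshold (default 2).
#'
#' @return An `adequacy_report`: per-proton table, RSS comparison, and a
#'   `verdict` of `"adequate"`, `"inadequate"` or `"no_binding"`.
#' @export
model_adequacy <- function(data, fit_simple, fit_two_state = NULL,
                           rss_factor = 2) {
  stopifnot(inherits(data, "titration_data"),
            inherits(fit_simple, "global_fit"))
  Y <- data$shifts
  per <- lapply(seq_len(ncol(Y)), function(p) {
    y <- Y[, p]
    sig <- stats::mad(diff(y))
    if (sig == 0) sig <- .Machine$double.eps
    imax <- which.max(y); imin <- which.min(y)
    peak <- imax > 1L && imax < length(y) &&
      (y[imax] - y[1]) > 3 * sig && (y[imax] - y[length(y)]) > 3 * sig
    trough <- imin > 1L && imin < length(y) &&
      (y[1] - y[imin]) > 3 * sig && (y[length(y)] - y[imin]) > 3 * sig
    data.frame(proton = colnames(Y)[p], sigma_hat = sig,
               amplitude = max(abs(y)), non_monotonic = peak || trough,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)

  no_binding <- all(per$amplitude < 3 * per$sigma_hat)
  rss_simple <- fit_simple$rss
  rss_two <- if (!is.null(fit_two_state)) fit_two_state$rss else NA_real_
  ratio <- rss_simple / rss_two
  rss_flag <- !is.null(fit_two_state) && fit_two_state$converged &&
    is.finite(ratio) && ratio > rss_factor

  verdict <- if (no_binding) "no_binding"
  else if (any(per$non_monotonic) || rss_flag) "inadequate"
  else "adequate"

  structure(list(per_proton = per, rss_simple = rss_simple,
                 rss_two_state = rss_two, rss_ratio = ratio,
                 rss_factor = rss_factor, verdict = verdict,
                 recommend_two_state = verdict == "inadequate"),
            class = "adequacy_report")
}

#' @export
print.adequacy_report <- function(x, ...) {
  msg <- switch(x$verdict,
    adequate = "simple 1:1 model adequate",
    inadequate = "1:1 model does not hold; two-state model recommended",
    no_binding = "no significant binding detected (K consistent with 0)")
  cat("Model adequacy:", msg, "\n")
  if (any(x$per_proton$non_monotonic))
    cat("  non-monotonic protons:",
        paste(x$per_proton$proton[x$per_proton$non_monotonic],
              collapse = ", "), "\n")
  if (is.finite(x$rss_ratio))
    cat(sprintf("  RSS(1:1) / RSS(two-state) = %.3g (threshold %.3g)\n",
                x$rss_ratio, x$rss_factor))
  invisible(x)
}
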