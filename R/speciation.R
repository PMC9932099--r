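#' Declare a complex species for an equilibrium binding model
#'
#' A species is defined by its host and guest stoichiometry and its overall
#' formation constant \eqn{\beta} relative to free host H and free guest G:
#' \deqn{[H_m G_n] = \beta \, [H]^m [G]^n .}
#' For a 1:1 complex \eqn{\beta} is the familiar association constant
#' \eqn{K_a = [HG]/([H][G])} in M\eqn{^{-1}}; in general its units are
#' M\eqn{^{-(m+n-1)}}. A species with `guest = 0` and `host = 1` represents a
#' guest-free host conformer (e.g. a self-included cyclodextrin arm), with a
#' dimensionless \eqn{\beta}.
#'
#' @param host Positive integer host stoichiometry \eqn{m}.
#' @param guest Non-negative integer guest stoichiometry \eqn{n}.
#' @param beta Overall formation constant (> 0), concentrations in molar.
#' @param label Species label, unique within a model (e.g. `"HG"`, `"H2G"`).
#'
#' @return A `complex_species` object (named list).
#' @seealso [binding_model()]
#' @export
complex_species <- function(host = 1L, guest = 1L, beta, label = NULL) {
  host <- as.integer(host)
  guest <- as.integer(guest)
  if (is.na(host) || host < 1L)
    stop("`host` stoichiometry must be a positive integer", call. = FALSE)
  if (is.na(guest) || guest < 0L)
    stop("`guest` stoichiometry must be a non-negative integer", call. = FALSE)
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0)
    stop("`beta` must be a single positive finite number", call. = FALSE)
  if (guest == 0L && host > 1L)
    stop("guest-free species must have host stoichiometry 1 (self-included conformer)",
         call. = FALSE)
  if (is.null(label)) {
    label <- paste0(if (host > 1L) paste0("H", host) else "H",
                    if (guest > 1L) paste0("G", guest) else if (guest == 1L) "G" else "*")
  }
  structure(list(host = host, guest = guest, beta = as.numeric(beta),
                 label = as.character(label)),
            class = "complex_species")
}

#' Assemble an equilibrium binding model from complex species
#'
#' A binding model is an ordered set of [complex_species()] sharing the same
#' free host and free guest. It must contain at least one 1:1 host-guest
#' species and all labels must be unique.
#'
#' @param ... `complex_species` objects (or a single list of them).
#' @param name Model name, free text.
#'
#' @return A `binding_model` object with a `species` data frame
#'   (columns `label`, `host`, `guest`, `beta`).
#' @examples
#' m <- binding_model(complex_species(1, 1, 1e4, "HG"), name = "simple 1:1")
#' solve_speciation(m, 1e-4, 1e-4)
#' @export
binding_model <- function(..., name = "binding model") {
  sp <- list(...)
  if (length(sp) == 1L && !inherits(sp[[1L]], "complex_species")) sp <- sp[[1L]]
  if (length(sp) == 0L) stop("a binding model needs at least one species", call. = FALSE)
  ok <- vapply(sp, inherits, logical(1), "complex_species")
  if (!all(ok)) stop("all arguments must be complex_species objects", call. = FALSE)
  species <- data.frame(
    label = vapply(sp, `[[`, character(1), "label"),
    host = vapply(sp, `[[`, integer(1), "host"),
    guest = vapply(sp, `[[`, integer(1), "guest"),
    beta = vapply(sp, `[[`, numeric(1), "beta"),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(species$label))
    stop("species labels must be unique", call. = FALSE)
  if (!any(species$host == 1L & species$guest == 1L))
    stop("model must contain at least one 1:1 host-guest species", call. = FALSE)
  structure(list(name = name, species = species), class = "binding_model")
}

#' @export
print.binding_model <- function(x, ...) {
  cat("Binding model:", x$name, "\n")
  sp <- x$species
  units <- ifelse(sp$host + sp$guest - 1L == 0L, "(dimensionless)",
                  paste0("M^-", sp$host + sp$guest - 1L))
  for (i in seq_len(nrow(sp))) {
    cat(sprintf("  %-8s H%dG%d  beta = %.6g %s\n", sp$label[i],
                sp$host[i], sp$guest[i], sp$beta[i], units[i]))
  }
  invisible(x)
}

#' Convenience constructors for common binding models
#'
#' `one_to_one_model()` builds a single 1:1 complex with association constant
#' `K`. `two_orientation_model()` builds two distinct 1:1 bound states
#' (e.g. guest "up" / "down" orientations) with constants `K1`, `K2`; note
#' that in fast exchange this model is observationally degenerate with a
#' single 1:1 model of constant `K1 + K2` (see [effective_one_to_one_constant()]).
#' `conformer_model()` adds a guest-free self-included host conformer
#' (dimensionless `beta_conf`) competing with 1:1 guest binding; it is likewise
#' degenerate in fast exchange. `host_sandwich_model()` is the 2:1
#' self-competition model H + G = HG (K1), H + HG = H2G (stepwise K2);
#' `guest_sandwich_model()` the 1:2 analogue HG + G = HG2 (stepwise K2).
#' The sandwich models are the non-degenerate two-state variants.
#'
#' @param K,K1,K2 Association constants in M^-1 (`K2` stepwise for the
#'   sandwich models).
#' @param beta_conf Dimensionless conformer formation constant.
#' @param name Model name.
#' @return A [binding_model()].
#' @export
one_to_one_model <- function(K, name = "simple 1:1") {
  binding_model(complex_species(1, 1, K, "HG"), name = name)
}

#' @rdname one_to_one_model
#' @export
two_orientation_model <- function(K1, K2, name = "two-orientation 1:1") {
  binding_model(complex_species(1, 1, K1, "HG-up"),
                complex_species(1, 1, K2, "HG-down"), name = name)
}

#' @rdname one_to_one_model
#' @export
conformer_model <- function(K, beta_conf, name = "1:1 + self-included conformer") {
  binding_model(complex_species(1, 1, K, "HG"),
                complex_species(1, 0, beta_conf, "H-closed"), name = name)
}

#' @rdname one_to_one_model
#' @export
host_sandwich_model <- function(K1, K2, name = "1:1 + 2:1 self-competition") {
  binding_model(complex_species(1, 1, K1, "HG"),
                complex_species(2, 1, K1 * K2, "H2G"), name = name)
}

#' @rdname one_to_one_model
#' @export
guest_sandwich_model <- function(K1, K2, name = "1:1 + 1:2") {
  binding_model(complex_species(1, 1, K1, "HG"),
                complex_species(1, 2, K1 * K2, "HG2"), name = name)
}

new_speciation_state <- function(free_host, free_guest, complexes,
                                 total_host, total_guest) {
  structure(list(free_host = free_host, free_guest = free_guest,
                 complexes = complexes, total_host = total_host,
                 total_guest = total_guest),
            class = "speciation_state")
}

#' @export
print.speciation_state <- function(x, ...) {
  cat(sprintf("Speciation at [H]T = %.4g M, [G]T = %.4g M\n",
              x$total_host, x$total_guest))
  cat(sprintf("  free host  %.6g M\n  free guest %.6g M\n",
              x$free_host, x$free_guest))
  for (nm in names(x$complexes))
    cat(sprintf("  %-8s   %.6g M\n", nm, x$complexes[[nm]]))
  invisible(x)
}

#' Closed-form speciation of a single 1:1 host-guest equilibrium
#'
#' Solves the 1:1 mass balances exactly. The complex concentration
#' \eqn{x = [HG]} is the physical root of
#' \deqn{K x^2 - (K([H]_T + [G]_T) + 1) x + K [H]_T [G]_T = 0}
#' lying in \eqn{[0, \min([H]_T, [G]_T)]}, evaluated in the numerically
#' stable form \eqn{x = 2c / (b + \sqrt{b^2 - 4 K c})}.
#'
#' @param total_host,total_guest Total (analytical) concentrations in M.
#' @param K 1:1 association constant in M^-1 (> 0).
#'
#' @return A `speciation_state` with the complex labelled `"HG"`.
#' @examples
#' st <- solve_one_to_one(1e-4, 1e-4, 1e4)
#' st$complexes[["HG"]]   # 3.8197e-5 M
#' @export
solve_one_to_one <- function(total_host, total_guest, K) {
  if (!is.numeric(total_host) || total_host < 0 ||
      !is.numeric(total_guest) || total_guest < 0)
    stop("total concentrations must be non-negative", call. = FALSE)
  if (!is.numeric(K) || K <= 0 || !is.finite(K))
    stop("K must be positive and finite (use a no-binding model for K = 0)",
         call. = FALSE)
  b <- K * (total_host + total_guest) + 1
  cc <- K * total_host * total_guest
  x <- if (cc == 0) 0 else 2 * cc / (b + sqrt(b * b - 4 * K * cc))
  new_speciation_state(free_host = total_host - x,
                       free_guest = total_guest - x,
                       complexes = c(HG = x),
                       total_host = total_host, total_guest = total_guest)
}

speciation_complexes <- function(species, h, g) {
  # 0^0 := 1 so guest-free conformers survive g = 0
  ch <- ifelse(species$host == 0L, 1, h ^ species$host)
  cg <- ifelse(species$guest == 0L, 1, g ^ species$guest)
  stats::setNames(species$beta * ch * cg, species$label)
}

solver_error <- function(message, residuals) {
  stop(errorCondition(message, residuals = residuals,
                      class = c("cdbind_solver_error", "error")))
}

# host balance for guest-free composition: h + sum over conformers m*beta*h^m
solve_host_only <- function(species, total_host) {
  conf <- species[species$guest == 0L, , drop = FALSE]
  if (nrow(conf) == 0L || total_host == 0) return(total_host)
  f <- function(h) h + sum(conf$host * conf$beta * h ^ conf$host) - total_host
  stats::uniroot(f, lower = 0, upper = total_host, tol = .Machine$double.eps,
                 maxiter = 1000L)$root
}

#' General equilibrium speciation solver
#'
#' Solves the coupled host and guest mass balances
#' \deqn{[H]_T = [H] + \sum_s m_s \beta_s [H]^{m_s}[G]^{n_s}, \quad
#'       [G]_T = [G] + \sum_s n_s \beta_s [H]^{m_s}[G]^{n_s}}
#' for the free concentrations of an arbitrary \eqn{H_m G_n} model by damped
#' Newton iteration on log-concentrations (which guarantees positivity and is
#' robust for stiff formation constants), with a nested-bisection fallback.
#' Both balances are converged to `tol` relative; the iteration cap is
#' `maxit`. The degenerate composition (0, 0) returns the all-zero state.
#'
#' @param model A [binding_model()].
#' @param total_host,total_guest Total concentrations in M.
#' @param tol Relative convergence tolerance on both mass balances.
#' @param maxit Newton iteration cap before the bisection fallback.
#'
#' @return A `speciation_state`.
#' @export
solve_speciation <- function(model, total_host, total_guest,
                             tol = 1e-12, maxit = 200L) {
  stopifnot(inherits(model, "binding_model"))
  if (!is.numeric(total_host) || total_host < 0 ||
      !is.numeric(total_guest) || total_guest < 0)
    stop("total concentrations must be non-negative", call. = FALSE)
  sp <- model$species
  zero <- stats::setNames(numeric(nrow(sp)), sp$label)

  if (total_host == 0) {
    # every species contains host, so nothing forms
    return(new_speciation_state(0, total_guest, zero, total_host, total_guest))
  }
  if (total_guest == 0) {
    h <- solve_host_only(sp, total_host)
    cx <- speciation_complexes(sp, h, 0)
    cx[sp$guest > 0L] <- 0
    return(new_speciation_state(h, 0, cx, total_host, total_guest))
  }

  m <- sp$host; n <- sp$guest; beta <- sp$beta
  balance <- function(h, g) {
    c_s <- beta * h ^ m * g ^ n
    c(h + sum(m * c_s) - total_host,
      g + sum(n * c_s) - total_guest)
  }
  rel <- function(f) max(abs(f[1]) / total_host, abs(f[2]) / total_guest)

  # effective 1:1 initial guess where available, else half the totals
  keff <- effective_one_to_one_constant(model)
  if (is.finite(keff)) {
    st0 <- solve_one_to_one(total_host, total_guest, keff)
    h <- max(st0$free_host, 1e-3 * total_host)
    g <- max(st0$free_guest, 1e-3 * total_guest)
  } else {
    h <- total_host / 2
    g <- total_guest / 2
  }

  x <- c(log(h), log(g))
  f <- balance(exp(x[1]), exp(x[2]))
  r <- rel(f)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    if (r <= tol) { converged <- TRUE; break }
    h <- exp(x[1]); g <- exp(x[2])
    c_s <- beta * h ^ m * g ^ n
    # Jacobian wrt (log h, log g)
    J <- matrix(c(h + sum(m * m * c_s), sum(m * n * c_s),
                  sum(m * n * c_s), g + sum(n * n * c_s)),
                2, 2, byrow = TRUE)
    step <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    # cap step length in log units, then damp by halving
    sn <- sqrt(sum(step^2))
    if (sn > 4) step <- step * (4 / sn)
    lambda <- 1
    repeat {
      xn <- x - lambda * step
      fn <- balance(exp(xn[1]), exp(xn[2]))
      rn <- rel(fn)
      if (is.finite(rn) && rn < r) break
      lambda <- lambda / 2
      if (lambda < 1e-12) break
    }
    if (lambda < 1e-12) break
    x <- xn; f <- fn; r <- rn
  }
  if (r <= tol) converged <- TRUE

  if (!converged) {
    # nested bisection: host balance is monotone in h for fixed g, and the
    # guest residual is monotone in g along h(g)
    h_of_g <- function(g) {
      fh <- function(h) h + sum(m * beta * h ^ m * g ^ n) - total_host
      stats::uniroot(fh, lower = 0, upper = total_host, tol = .Machine$double.eps,
                     maxiter = 1000L)$root
    }
    fg <- function(g) {
      h <- h_of_g(g)
      g + sum(n * beta * h ^ m * g ^ n) - total_guest
    }
    g <- tryCatch(
      stats::uniroot(fg, lower = 0, upper = total_guest, tol = .Machine$double.eps,
                     maxiter = 1000L)$root,
      error = function(e) NA_real_)
    if (is.na(g)) solver_error("speciation solver failed to converge", f)
    h <- h_of_g(g)
    f <- balance(h, g)
    r <- rel(f)
    if (r > 1e-10)
      solver_error("speciation solver failed to converge", f)
    x <- c(log(h), log(g))
  }

  h <- exp(x[1]); g <- exp(x[2])
  new_speciation_state(h, g, speciation_complexes(sp, h, g),
                       total_host, total_guest)
}

#' Effective 1:1 constant of a degenerate multi-state model
#'
#' A model whose guest-containing species are all 1:1 is observationally
#' degenerate, in speciation, with a single 1:1 model. Without guest-free
#' conformers the effective constant is \eqn{\sum_s K_s}; with self-included
#' conformers it is \eqn{\sum_s K_s / (1 + \sum_c \beta_c)}. For any model
#' containing a non-1:1 species no effective constant exists and `NA` is
#' returned.
#'
#' @param model A [binding_model()].
#' @return Effective constant in M^-1, or `NA_real_` when undefined.
#' @export
effective_one_to_one_constant <- function(model) {
  stopifnot(inherits(model, "binding_model"))
  sp <- model$species
  bound <- sp[sp$guest > 0L, , drop = FALSE]
  conf <- sp[sp$guest == 0L, , drop = FALSE]
  if (any(bound$host != 1L | bound$guest != 1L)) return(NA_real_)
  if (any(conf$host != 1L)) return(NA_real_)
  sum(bound$beta) / (1 + sum(conf$beta))
}

#' Check mass balance of a speciation state
#'
#' Returns the maximum relative mass-balance violation over the host and
#' guest balances (relative to the respective totals, absolute when a total
#' is zero).
#'
#' @param state A `speciation_state`.
#' @param model The [binding_model()] that produced it.
#' @return Maximum relative residual (numeric scalar).
#' @export
mass_balance_error <- function(state, model) {
  sp <- model$species
  cx <- state$complexes[sp$label]
  hres <- state$free_host + sum(sp$host * cx) - state$total_host
  gres <- state$free_guest + sum(sp$guest * cx) - state$total_guest
  max(abs(hres) / max(state$total_host, 1),
      abs(gres) / max(state$total_guest, 1))
}

#' Serialize a binding model to a plain-text file
#'
#' Models are written as a small YAML document: a `name` and a `species`
#' list with `label`, `host`, `guest`, `beta` per species. `read_binding_model()`
#' restores and re-validates the model.
#'
#' @param model A [binding_model()].
#' @param path File path.
#' @return `write_binding_model()` returns `path` invisibly;
#'   `read_binding_model()` returns a [binding_model()].
#' @export
write_binding_model <- function(model, path) {
  stopifnot(inherits(model, "binding_model"))
  sp <- model$species
  doc <- list(name = model$name,
              species = lapply(seq_len(nrow(sp)), function(i)
                list(label = sp$label[i], host = sp$host[i],
                     guest = sp$guest[i], beta = sp$beta[i])))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_binding_model
#' @export
read_binding_model <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$species))
    stop("model file has no `species` list", call. = FALSE)
  sp <- lapply(doc$species, function(s)
    complex_species(s$host, s$guest, s$beta, s$label))
  binding_model(sp, name = if (is.null(doc$name)) "binding model" else doc$name)
}
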