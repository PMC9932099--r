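#' Construct a titration dataset
#'
#' The unit of fitting: a schedule of total host and guest concentrations
#' with referenced chemical-shift changes for one or more reporter protons.
#' By the referencing convention the first point is the guest-free sample
#' (`total_guest[1] == 0`) and its shift changes are identically zero; the
#' constructor enforces both. Total guest must be strictly increasing.
#'
#' @param total_host Total host concentration in M; a scalar (constant over
#'   the titration, the usual concentrated-titrant design) or one value per
#'   point when dilution is modelled explicitly.
#' @param total_guest Total guest concentration in M per point, strictly
#'   increasing from 0.
#' @param shifts Numeric matrix (points x protons) of referenced shift
#'   changes in ppm, with column names giving the reporter proton labels
#'   (e.g. `"H1"`, `"H3"`, `"H5"`, `"H6"`).
#' @param temperature Temperature in K (default 303.15).
#'
#' @return A `titration_data` object.
#' @export
titration_data <- function(total_host, total_guest, shifts,
                           temperature = 303.15) {
  total_guest <- as.numeric(total_guest)
  n <- length(total_guest)
  shifts <- as.matrix(shifts)
  if (is.null(colnames(shifts)))
    colnames(shifts) <- paste0("p", seq_len(ncol(shifts)))
  if (nrow(shifts) != n)
    stop("`shifts` must have one row per titration point", call. = FALSE)
  total_host <- rep_len(as.numeric(total_host), n)
  if (any(total_host <= 0))
    stop("total host concentration must be positive at every point", call. = FALSE)
  if (any(total_guest < 0) || total_guest[1] != 0)
    stop("total guest must start at 0 (guest-free reference point)", call. = FALSE)
  if (any(diff(total_guest) <= 0))
    stop("total guest must be strictly increasing", call. = FALSE)
  if (any(abs(shifts[1, ]) > 1e-12))
    stop("first-point shift changes must be zero (referencing convention); ",
         "use reference_shifts() on raw data", call. = FALSE)
  structure(list(total_host = total_host, total_guest = total_guest,
                 shifts = shifts, proton_labels = colnames(shifts),
                 temperature = temperature),
            class = "titration_data")
}

#' @export
print.titration_data <- function(x, ...) {
  cat(sprintf("Titration: %d points, %d reporter protons (%s)\n",
              length(x$total_guest), ncol(x$shifts),
              paste(x$proton_labels, collapse = ", ")))
  cat(sprintf("  [H]T %s M, [G]T 0 to %.4g M, T = %.2f K\n",
              if (length(unique(x$total_host)) == 1L)
                sprintf("%.4g", x$total_host[1])
              else sprintf("%.4g-%.4g", min(x$total_host), max(x$total_host)),
              max(x$total_guest), x$temperature))
  invisible(x)
}

#' Reference raw chemical shifts against an internal standard and the
#' guest-free point
#'
#' Raw shifts are first corrected for drift of the internal reference
#' (acetonitrile, nominally 2.014 ppm) and then the corrected shift of the
#' first (guest-free) point is subtracted, so the output for point j and
#' proton i is
#' \deqn{\Delta\delta_{i,j} = (raw_{i,j} - corr_j) - (raw_{i,1} - corr_1)}
#' and the first row is exactly zero.
#'
#' @param raw_shifts Numeric matrix (points x protons) of raw shifts in ppm.
#' @param reference_offset Per-point reference correction in ppm (observed
#'   internal-standard shift minus its nominal value); scalar or one per
#'   point. Ignored when `acetonitrile_ppm` is given.
#' @param acetonitrile_ppm Optional per-point observed acetonitrile shift;
#'   the correction is then `acetonitrile_ppm - 2.014`.
#'
#' @return Matrix of referenced shift changes, first row zero.
#' @export
reference_shifts <- function(raw_shifts, reference_offset = 0,
                             acetonitrile_ppm = NULL) {
  raw <- as.matrix(raw_shifts)
  if (nrow(raw) < 1L)
    stop("the first (guest-free) point is required", call. = FALSE)
  if (!is.null(acetonitrile_ppm))
    reference_offset <- acetonitrile_ppm - 2.014
  corr <- rep_len(as.numeric(reference_offset), nrow(raw))
  adj <- sweep(raw, 1, corr, `-`)
  out <- sweep(adj, 2, adj[1, ], `-`)
  out[1, ] <- 0
  out
}

# Referenced per-species population fractions: F[j, s] = c_s(j)/H_j minus the
# same quantity at (H_j, 0). Only guest-free conformer species have a nonzero
# reference term. This matrix is the linear basis of the fast-exchange shift
# model and of the variable-projection fitter.
shift_basis <- function(model, total_host, total_guest, ...) {
  n <- length(total_guest)
  total_host <- rep_len(total_host, n)
  if (any(total_host <= 0))
    stop("total host must be positive at every point", call. = FALSE)
  sp <- model$species
  FF <- matrix(0, n, nrow(sp), dimnames = list(NULL, sp$label))
  refs <- new.env()
  for (j in seq_len(n)) {
    st <- solve_speciation(model, total_host[j], total_guest[j], ...)
    key <- format(total_host[j], digits = 15)
    if (is.null(refs[[key]])) {
      st0 <- solve_speciation(model, total_host[j], 0, ...)
      refs[[key]] <- st0$complexes / total_host[j]
    }
    FF[j, ] <- st$complexes / total_host[j] - refs[[key]]
  }
  FF
}

normalize_sensitivities <- function(sens, model, proton_labels = NULL) {
  sp_labels <- model$species$label
  if (is.null(dim(sens))) {
    if (length(sp_labels) != 1L)
      stop("for multi-species models `sens` must be a protons x species matrix",
           call. = FALSE)
    sens <- matrix(sens, ncol = 1,
                   dimnames = list(names(sens), sp_labels))
  }
  sens <- as.matrix(sens)
  if (is.null(colnames(sens))) {
    if (ncol(sens) != length(sp_labels))
      stop("`sens` must have one column per model species", call. = FALSE)
    colnames(sens) <- sp_labels
  }
  if (!setequal(colnames(sens), sp_labels))
    stop("sensitivity columns must match the model species labels", call. = FALSE)
  sens <- sens[, sp_labels, drop = FALSE]
  if (is.null(rownames(sens)) && !is.null(proton_labels))
    rownames(sens) <- proton_labels
  sens
}

#' Predict fast-exchange chemical-shift changes from a binding model
#'
#' In fast exchange the observed shift of a host reporter proton is the
#' population-weighted average over free and complexed host, so the
#' referenced shift change is
#' \deqn{\Delta\delta_{i} = \sum_s \Delta\delta_{c,s,i}\, c_s / [H]_T}
#' minus its value at the guest-free composition (which is nonzero only for
#' models with guest-free conformer species). At \eqn{[G]_T = 0} the
#' prediction is exactly 0; for a single 1:1 species it tends to
#' \eqn{\Delta\delta_{c,i}} as the guest saturates the host.
#'
#' @param model A [binding_model()].
#' @param sens Shift sensitivities \eqn{\Delta\delta_c} in ppm: a protons x
#'   species matrix (column names = species labels), or a named vector over
#'   protons for a single-species model.
#' @param total_host,total_guest Schedule in M (`total_host` scalar or per
#'   point; must be positive).
#'
#' @return Matrix (points x protons) of predicted shift changes in ppm.
#' @examples
#' m <- one_to_one_model(1e4)
#' predict_shifts(m, c(H3 = 0.1), 1e-4, c(0, 1e-4))
#' @export
predict_shifts <- function(model, sens, total_host, total_guest) {
  stopifnot(inherits(model, "binding_model"))
  sens <- normalize_sensitivities(sens, model)
  FF <- shift_basis(model, total_host, total_guest)
  out <- FF %*% t(sens)
  rownames(out) <- NULL
  out
}
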