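#' Read and write titration CSV files
#'
#' The interchange schema is one row per titration point with columns:
#' `point_index` (optional), `H_total_M` (optional; otherwise supply
#' `host_total`), `G_total_M` (required), and one `<label>_ppm` column of
#' referenced shift changes per reporter proton (e.g. `H1_ppm`). All
#' concentrations are molar. On reading, rows are sorted by `G_total_M`
#' (with a warning if they were unordered), and if the first point is not
#' already the zero reference the shifts are re-referenced against it with
#' a warning. Malformed numeric fields are reported with their row numbers.
#'
#' @param path CSV file path.
#' @param host_total Host concentration in M, used when the file has no
#'   `H_total_M` column.
#' @param temperature Temperature in K.
#' @return `read_titration_csv()` returns a [titration_data()];
#'   `write_titration_csv()` returns `path` invisibly.
#' @export
read_titration_csv <- function(path, host_total = NULL, temperature = 303.15) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  proton_cols <- grep("_ppm$", names(df), value = TRUE)
  missing_cols <- character(0)
  if (!"G_total_M" %in% names(df)) missing_cols <- c(missing_cols, "G_total_M")
  if (length(proton_cols) == 0L)
    missing_cols <- c(missing_cols, "<proton>_ppm")
  if (length(missing_cols))
    stop("titration CSV is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  num_cols <- c("G_total_M", intersect("H_total_M", names(df)), proton_cols)
  for (cl in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(v) & !is.na(df[[cl]]) & df[[cl]] != "")
    if (length(bad))
      stop(sprintf("non-numeric values in column %s at row(s) %s",
                   cl, paste(bad, collapse = ", ")), call. = FALSE)
    if (anyNA(v))
      stop(sprintf("missing values in column %s at row(s) %s",
                   cl, paste(which(is.na(v)), collapse = ", ")),
           call. = FALSE)
    df[[cl]] <- v
  }

  if (is.unsorted(df$G_total_M, strictly = TRUE)) {
    warning("titration points were not ordered by G_total_M; sorting",
            call. = FALSE)
    df <- df[order(df$G_total_M), , drop = FALSE]
  }
  H <- if ("H_total_M" %in% names(df)) df$H_total_M
  else if (!is.null(host_total)) host_total
  else stop("file has no H_total_M column; supply `host_total`",
            call. = FALSE)

  Y <- as.matrix(df[proton_cols])
  colnames(Y) <- sub("_ppm$", "", proton_cols)
  if (df$G_total_M[1] != 0 || any(abs(Y[1, ]) > 1e-12)) {
    warning("first point is not the zero reference; re-referencing against it",
            call. = FALSE)
    Y <- sweep(Y, 2, Y[1, ], `-`)
    if (df$G_total_M[1] != 0)
      stop("first point must have G_total_M = 0 (guest-free reference)",
           call. = FALSE)
  }
  titration_data(H, df$G_total_M, Y, temperature = temperature)
}

#' @rdname read_titration_csv
#' @param data A [titration_data()].
#' @export
write_titration_csv <- function(data, path) {
  stopifnot(inherits(data, "titration_data"))
  df <- data.frame(point_index = seq_along(data$total_guest),
                   H_total_M = data$total_host,
                   G_total_M = data$total_guest)
  Y <- data$shifts
  colnames(Y) <- paste0(colnames(Y), "_ppm")
  utils::write.csv(cbind(df, Y), path, row.names = FALSE)
  invisible(path)
}

#' Read and write Job-plot CSV files
#'
#' Schema: columns `r` (host mole fraction), `H_total_M`, `G_total_M`, and
#' one `<label>_ppm` column per proton. The ordinate is reconstructed as
#' \eqn{\Delta\delta \cdot [H]_T}; the total concentration must be constant
#' across rows.
#'
#' @param path CSV file path.
#' @return `read_job_csv()` returns a `job_data`; `write_job_csv()` returns
#'   `path` invisibly.
#' @export
read_job_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("r", "H_total_M", "G_total_M")
  miss <- setdiff(need, names(df))
  proton_cols <- grep("_ppm$", names(df), value = TRUE)
  if (length(proton_cols) == 0L) miss <- c(miss, "<proton>_ppm")
  if (length(miss))
    stop("job CSV is missing required columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  tot <- df$H_total_M + df$G_total_M
  if (diff(range(tot)) > 1e-9 * max(tot))
    stop("total concentration must be fixed in a continuous-variation run",
         call. = FALSE)
  dd <- as.matrix(df[proton_cols])
  ord <- dd * df$H_total_M
  colnames(ord) <- sub("_ppm$", "", proton_cols)
  structure(list(r = df$r, ordinate = ord, total_conc = tot[1],
                 kind = "shift"), class = "job_data")
}

#' @rdname read_job_csv
#' @param data A `job_data` with shift-based ordinate.
#' @export
write_job_csv <- function(data, path) {
  stopifnot(inherits(data, "job_data"))
  H <- data$r * data$total_conc
  dd <- data$ordinate
  dd[H > 0, ] <- dd[H > 0, , drop = FALSE] / H[H > 0]
  dd[H == 0, ] <- 0
  colnames(dd) <- paste0(colnames(data$ordinate), "_ppm")
  df <- data.frame(r = data$r, H_total_M = H,
                   G_total_M = (1 - data$r) * data$total_conc)
  utils::write.csv(cbind(df, dd), path, row.names = FALSE)
  invisible(path)
}

#' Read a Table-1-style affinity/energy CSV
#'
#' Schema: `host`, `K_mM`, `K_err_mM`, `energy_kcal`, `energy_err_kcal`,
#' `charged` (TRUE/FALSE or 1/0). Used by [correlate_affinity_energy()].
#'
#' @param path CSV file path.
#' @return Data frame with the columns expected by
#'   [correlate_affinity_energy()].
#' @export
read_affinity_energy_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("host", "K_mM", "K_err_mM", "energy_kcal", "energy_err_kcal",
            "charged")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("affinity/energy CSV is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  data.frame(host = df$host, K_mM = df$K_mM, K_err_mM = df$K_err_mM,
             energy = df$energy_kcal, energy_err = df$energy_err_kcal,
             charged = as.logical(df$charged), stringsAsFactors = FALSE)
}

report_payload <- function(x) {
  if (inherits(x, "two_state_fit")) {
    list(type = "two_state_fit", model = x$model$name, variant = x$variant,
         K1_M = x$K1, K1_mM = x$K1 / 1000, K1_se_M = x$K1_se,
         K2 = x$K2, K2_mM = if (x$variant == "conformer") NULL else x$K2 / 1000,
         K2_se = x$K2_se,
         constants = x$constants, sensitivities_ppm = x$sensitivities,
         correlation = x$correlation, rss = x$rss, sigma_ppm = x$sigma,
         converged = x$converged, rank_deficient = x$rank_deficient,
         less_robust = x$less_robust, low_population = x$low_population,
         max_correlation = x$max_correlation, note = x$note)
  } else if (inherits(x, "global_fit")) {
    cc <- x$constants
    cc$K_mM <- ifelse(cc$host + cc$guest == 2L, cc$beta / 1000, NA_real_)
    list(type = "global_fit", model = x$model$name, constants = cc,
         sensitivities_ppm = x$sensitivities, correlation = x$correlation,
         rss = x$rss, sigma_ppm = x$sigma, converged = x$converged,
         rank_deficient = x$rank_deficient)
  } else if (inherits(x, "replicate_summary")) {
    cc <- x$constants
    cc$mean_mM <- cc$mean / 1000
    cc$sd_mM <- cc$sd / 1000
    list(type = "replicate_summary", model = x$model_name,
         n_replicates = x$n, constants = cc)
  } else if (inherits(x, "job_verdict")) {
    list(type = "job_verdict", verdict = x$verdict, r_max = x$r_max,
         offset = x$offset, tolerance = x$tolerance, note = x$note)
  } else stop("no report method for class ", class(x)[1], call. = FALSE)
}

#' Write a machine- and human-readable report of an analysis result
#'
#' Writes `<path>.json` (full numeric precision, re-parses losslessly) and
#' `<path>.txt` (the object's printed summary). Binding constants appear in
#' both M^-1 and mM^-1. Works for `global_fit`, `two_state_fit`,
#' `replicate_summary` and `job_verdict` objects; unconverged fits are
#' written with their convergence flag set to `FALSE` rather than refused.
#'
#' @param x Result object.
#' @param path Output path without extension.
#' @return Character vector of the two file paths, invisibly.
#' @export
write_report <- function(x, path) {
  payload <- c(list(package = "cdbind",
                    version = as.character(utils::packageVersion("cdbind"))),
               report_payload(x))
  json_path <- paste0(path, ".json")
  txt_path <- paste0(path, ".txt")
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null", matrix = "rowmajor", dataframe = "columns")
  txt <- utils::capture.output(print(x))
  writeLines(txt, txt_path)
  invisible(c(json = json_path, text = txt_path))
}
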