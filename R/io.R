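# Readers and writers for the package's plain-text formats: plasma and
# dissolution CSVs, flat key-value model-parameter files (YAML/JSON),
# and JSON serialisation of fit results.

read_numeric_col <- function(df, col, path) {
  v <- suppressWarnings(as.numeric(df[[col]]))
  bad <- which(is.na(v) & !is.na(df[[col]]))
  if (length(bad))
    stop_domain(sprintf("%s: non-numeric '%s' at data row(s) %s", path, col,
                        paste(utils::head(bad, 5), collapse = ", ")))
  if (anyNA(v))
    stop_domain(sprintf("%s: missing '%s' values", path, col))
  v
}

#' Read a plasma concentration CSV
#'
#' Expected header: \code{subject_id, formulation_id, dose_mg, time_h,
#' conc_ng_ml} with an optional logical \code{blq} column. Rows are
#' sorted by subject then time; duplicate (subject, time) pairs,
#' negative times and non-numeric fields are rejected with row-numbered
#' messages. When \code{blq} is absent it is derived as
#' \code{conc_ng_ml < lloq}.
#'
#' @param path CSV file path.
#' @param lloq LLOQ (ng/mL) used to derive missing \code{blq} flags.
#' @return A data frame (long format) with the five columns plus
#'   \code{blq}.
#' @export
read_plasma_csv <- function(path, lloq = 5) {
  if (!file.exists(path)) stop_domain("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "formulation_id", "dose_mg", "time_h", "conc_ng_ml")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_domain(path, ": missing column(s) ", paste(miss, collapse = ", "))
  if (nrow(df) == 0) stop_domain(path, ": no data rows")
  df$dose_mg <- read_numeric_col(df, "dose_mg", path)
  df$time_h <- read_numeric_col(df, "time_h", path)
  df$conc_ng_ml <- read_numeric_col(df, "conc_ng_ml", path)
  if (any(df$time_h < 0))
    stop_domain(sprintf("%s: negative time at data row(s) %s", path,
                        paste(utils::head(which(df$time_h < 0), 5),
                              collapse = ", ")))
  if (any(df$conc_ng_ml < 0))
    stop_domain(path, ": negative concentrations")
  dup <- duplicated(df[, c("subject_id", "time_h")])
  if (any(dup))
    stop_domain(sprintf("%s: duplicated (subject, time) at data row(s) %s",
                        path, paste(utils::head(which(dup), 5),
                                    collapse = ", ")))
  if (is.null(df$blq)) df$blq <- df$conc_ng_ml < lloq
  df <- df[order(df$subject_id, df$time_h), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @rdname read_plasma_csv
#' @param data plasma data frame in the same layout.
#' @export
write_plasma_csv <- function(data, path) {
  need <- c("subject_id", "formulation_id", "dose_mg", "time_h", "conc_ng_ml")
  stopifnot(all(need %in% names(data)))
  utils::write.csv(data[, c(need, intersect("blq", names(data)))],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read an in vitro dissolution CSV
#'
#' Expected header: \code{formulation_id, ph, vessel_id, time_h,
#' pct_dissolved}. Percentages above 110 (beyond assay noise around
#' complete release) and negative times are rejected.
#'
#' @param path CSV file path.
#' @return A data frame with the five columns, sorted by formulation,
#'   pH, vessel, time.
#' @export
read_dissolution_csv <- function(path) {
  if (!file.exists(path)) stop_domain("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(ph = "character"))
  need <- c("formulation_id", "ph", "vessel_id", "time_h", "pct_dissolved")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_domain(path, ": missing column(s) ", paste(miss, collapse = ", "))
  if (nrow(df) == 0) stop_domain(path, ": no data rows")
  df$time_h <- read_numeric_col(df, "time_h", path)
  df$pct_dissolved <- read_numeric_col(df, "pct_dissolved", path)
  if (any(df$time_h < 0)) stop_domain(path, ": negative times")
  bad <- which(df$pct_dissolved < 0 | df$pct_dissolved > 110)
  if (length(bad))
    stop_domain(sprintf("%s: pct_dissolved outside [0, 110] at data row(s) %s",
                        path, paste(utils::head(bad, 5), collapse = ", ")))
  dup <- duplicated(df[, c("formulation_id", "ph", "vessel_id", "time_h")])
  if (any(dup))
    stop_domain(path, ": duplicated (formulation, ph, vessel, time) rows")
  df <- df[order(df$formulation_id, df$ph, df$vessel_id, df$time_h), ,
           drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @rdname read_dissolution_csv
#' @param data dissolution data frame in the same layout.
#' @export
write_dissolution_csv <- function(data, path) {
  need <- c("formulation_id", "ph", "vessel_id", "time_h", "pct_dissolved")
  stopifnot(all(need %in% names(data)))
  utils::write.csv(data[, need], path, row.names = FALSE)
  invisible(path)
}

#' Read or write a flat key-value model parameter file
#'
#' Flat YAML or JSON (chosen by file extension) with keys named exactly
#' as the structural parameters: \code{imax, t_get, hill_stomach,
#' diss_max, t_itt, t_ctt, hill_intestine, vmax_invivo, am50_invivo,
#' k_lag, k_a, v1, v2, cl, cld} (any subset).
#'
#' @param path file path ending in .yaml/.yml or .json.
#' @return Named list of numeric values.
#' @export
read_model_params <- function(path) {
  if (!file.exists(path)) stop_domain("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop_domain("unsupported parameter file extension: .", ext))
  if (!is.list(vals)) vals <- as.list(vals)
  allowed <- c("imax", "t_get", "hill_stomach", "diss_max", "t_itt",
               "t_ctt", "hill_intestine", "vmax_invivo", "am50_invivo",
               "vmax_invitro", "am50_invitro",
               "k_lag", "k_a", "v1", "v2", "cl", "cld", "dose", "sigma")
  unknown <- setdiff(names(vals), allowed)
  if (length(unknown))
    stop_domain(path, ": unknown parameter key(s) ",
                paste(unknown, collapse = ", "))
  bad <- names(vals)[!vapply(vals, function(v)
    is.numeric(v) && all(is.finite(v)), logical(1))]
  if (length(bad))
    stop_domain(path, ": non-numeric value(s) for ",
                paste(bad, collapse = ", "))
  lapply(vals, as.numeric)
}

#' @rdname read_model_params
#' @param params named list or vector of numeric parameter values.
#' @export
write_model_params <- function(params, path) {
  ext <- tolower(tools::file_ext(path))
  params <- as.list(params)
  switch(ext,
    yaml = , yml = yaml::write_yaml(params, path),
    json = jsonlite::write_json(params, path, auto_unbox = TRUE,
                                digits = NA),
    stop_domain("unsupported parameter file extension: .", ext))
  invisible(path)
}

#' Serialise a fit result to JSON with provenance
#'
#' Writes the parameter estimates together with the seed, options and a
#' lightweight checksum of the input data, so a fit can be traced back
#' to what produced it.
#'
#' @param fit a fit object from [fit_invitro_mm()], [fit_popk()] or
#'   [fit_power_ivivc()].
#' @param path output .json path.
#' @export
write_fit_json <- function(fit, path) {
  payload <- if (inherits(fit, "popk_fit")) {
    list(kind = "popk_fit", theta = as.list(fit$model$theta),
         omega2 = as.list(fit$model$omega2), sigma = fit$model$sigma,
         converged = fit$converged, iterations = fit$iterations,
         loglik = unclass(fit$loglik), seed = fit$options$seed,
         options = fit$options[c("n_samples", "max_iter", "tol",
                                 "tol_window")],
         data_checksum = fit$data_checksum)
  } else if (inherits(fit, "invitro_fit")) {
    list(kind = "invitro_fit", vmax = fit$params$vmax,
         am50 = fit$params$am50, sse = fit$sse, n_obs = fit$n_obs,
         formulation_id = fit$formulation_id)
  } else if (inherits(fit, "ivivc_fit")) {
    list(kind = "ivivc_fit", a = fit$a, b = fit$b, c = fit$c,
         r2 = fit$r2, form = fit$form, weighting = fit$weighting,
         pairs = fit$pairs)
  } else stop_domain("unsupported fit object of class ",
                     paste(class(fit), collapse = "/"))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# Cheap order-insensitive checksum for provenance records.
data_checksum <- function(df) {
  num <- unlist(df[vapply(df, is.numeric, logical(1))], use.names = FALSE)
  sprintf("n%d-s%.6g", nrow(df), sum(num) %% 1e9)
}
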