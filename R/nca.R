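#' Terminal slope estimation for non-compartmental analysis
#'
#' Log-linear regression on the terminal portion of a concentration-time
#' profile. Candidate point sets are all suffixes of the post-Tmax
#' quantifiable observations (the Cmax point itself excluded) with at
#' least three points; the set maximising the adjusted r-squared of
#' \code{lm(log(conc) ~ time)} is selected, the standard automated
#' convention.
#'
#' @param time,conc numeric vectors of sampling times (h) and
#'   concentrations (ng/mL).
#' @param blq optional logical vector flagging below-LLOQ observations
#'   (treated as missing here).
#' @return A list with \code{lambda_z} (1/h), \code{t_half} (h),
#'   \code{n_points}, \code{r2_adj}, and the \code{time_range} used.
#' @export
compute_lambda_z <- function(time, conc, blq = NULL) {
  stopifnot(length(time) == length(conc))
  if (is.null(blq)) blq <- rep(FALSE, length(time))
  keep <- !blq & is.finite(conc) & conc > 0
  t <- time[keep]; y <- conc[keep]
  if (length(y) == 0) stop_domain("no quantifiable concentrations")
  i_max <- which.max(y)
  t_tail <- t[-seq_len(i_max)]
  y_tail <- y[-seq_len(i_max)]
  if (length(y_tail) < 3)
    stop_domain("fewer than 3 quantifiable points after Tmax")
  best <- NULL
  for (start in seq_len(length(y_tail) - 2)) {
    ts <- t_tail[start:length(t_tail)]
    ys <- log(y_tail[start:length(y_tail)])
    fit <- lm(ys ~ ts)
    slope <- coef(fit)[[2]]
    if (!is.finite(slope) || slope >= 0) next
    # summary.lm warns on numerically perfect fits; those are fine here
    r2a <- suppressWarnings(summary(fit)$adj.r.squared)
    if (is.null(best) || r2a > best$r2_adj + 1e-12)
      best <- list(lambda_z = -slope, n_points = length(ts), r2_adj = r2a,
                   time_range = range(ts))
  }
  if (is.null(best))
    stop_domain("terminal phase not declining: no candidate with negative slope")
  best$t_half <- log(2) / best$lambda_z
  best
}

# Linear (or linear-up/log-down) trapezoid between quantifiable points.
trapz_auc <- function(t, y, method = c("linear", "linear_log")) {
  method <- match.arg(method)
  if (length(t) < 2) return(0)
  dt <- diff(t); y1 <- head(y, -1); y2 <- tail(y, -1)
  seg <- dt * (y1 + y2) / 2
  if (method == "linear_log") {
    dn <- y2 < y1 & y2 > 0 & y1 > 0
    seg[dn] <- dt[dn] * (y1[dn] - y2[dn]) / log(y1[dn] / y2[dn])
  }
  sum(seg)
}

#' Non-compartmental analysis of a plasma profile
#'
#' Computes the standard exposure metrics: Cmax and Tmax directly from
#' the observations; AUC to the last quantifiable point by the
#' trapezoidal rule (linear by default, linear-up/log-down optionally);
#' AUC extrapolated to infinity as \eqn{AUC_{all} + C_{last}/\lambda_z};
#' terminal half-life from [compute_lambda_z()]; apparent clearance
#' CL/F in mL/min as \eqn{dose \cdot 10^6 / AUC_{inf} / 60} (dose in
#' mg, AUC in ng.h/mL) and apparent volume Vz/F in L as
#' \eqn{(CL/F)/\lambda_z} (unit-converted). Observations flagged BLQ are
#' treated as zero before the first quantifiable point and as missing
#' afterwards.
#'
#' @inheritParams compute_lambda_z
#' @param dose administered dose (mg).
#' @param reference optional reference \code{nca_result} (plus
#'   \code{ref_dose}) for relative bioavailability: the ratio of
#'   dose-normalised AUC_inf, in percent.
#' @param ref_dose reference dose (mg).
#' @param auc_method \code{"linear"} (default) or \code{"linear_log"}.
#' @return An object of class \code{"nca_result"}: a named list with
#'   cmax, tmax, lambda_z, t_half, auc_all, auc_inf, vz_f (L), cl_f
#'   (mL/min), n_lambda_points, r2_adj, extrapolated fraction and flags;
#'   \code{relative_ba} when a reference is supplied.
#' @examples
#' t <- c(0.25, 0.5, 1, 2, 4, 6, 8, 12, 24)
#' nca <- compute_nca(t, 100 * exp(-0.2 * t), dose = 1)
#' nca$auc_inf
#' @export
compute_nca <- function(time, conc, dose, blq = NULL, reference = NULL,
                        ref_dose = NULL,
                        auc_method = c("linear", "linear_log")) {
  auc_method <- match.arg(auc_method)
  check_scalar_pos(dose, "dose")
  stopifnot(length(time) == length(conc))
  o <- order(time); time <- time[o]; conc <- conc[o]
  if (is.null(blq)) blq <- rep(FALSE, length(time)) else blq <- blq[o]
  keep <- !blq & is.finite(conc)
  t_q <- time[keep]; y_q <- conc[keep]
  if (!length(y_q)) stop_domain("no quantifiable concentrations")
  i_cmax <- which.max(y_q)
  cmax <- y_q[i_cmax]; tmax <- t_q[i_cmax]
  # leading BLQ points (before the first quantifiable one) enter as zeros
  lead <- time < min(t_q) & blq
  t_auc <- c(time[lead], t_q); y_auc <- c(rep(0, sum(lead)), y_q)
  o2 <- order(t_auc)
  auc_all <- trapz_auc(t_auc[o2], y_auc[o2], auc_method)
  lz <- compute_lambda_z(time, conc, blq)
  c_last <- y_q[length(y_q)]
  auc_inf <- auc_all + c_last / lz$lambda_z
  extrap <- (auc_inf - auc_all) / auc_inf
  cl_f_ml_min <- dose * 1e6 / auc_inf / 60
  cl_f_l_h <- cl_f_ml_min * 60 / 1000
  vz_f <- cl_f_l_h / lz$lambda_z
  out <- list(cmax = cmax, tmax = tmax, lambda_z = lz$lambda_z,
              t_half = lz$t_half, auc_all = auc_all, auc_inf = auc_inf,
              vz_f = vz_f, cl_f = cl_f_ml_min, dose = dose,
              n_lambda_points = lz$n_points, r2_adj = lz$r2_adj,
              extrap_fraction = extrap,
              high_extrapolation = extrap > 0.5)
  if (out$high_extrapolation)
    warning("AUC extrapolation exceeds 50% of AUC_inf", call. = FALSE)
  if (!is.null(reference)) {
    stopifnot(inherits(reference, "nca_result"))
    if (is.null(ref_dose)) ref_dose <- reference$dose
    out$relative_ba <- 100 * (auc_inf / dose) /
      (reference$auc_inf / ref_dose)
  }
  structure(out, class = "nca_result")
}

#' @export
print.nca_result <- function(x, ...) {
  cat(sprintf("NCA: Cmax %.4g ng/mL at %.3g h; AUC_all %.5g, AUC_inf %.5g ng.h/mL (%.1f%% extrapolated)\n",
              x$cmax, x$tmax, x$auc_all, x$auc_inf,
              100 * x$extrap_fraction))
  cat(sprintf("     lambda_z %.4g 1/h (t1/2 %.3g h, %d points, adj r2 %.4f); CL/F %.4g mL/min; Vz/F %.4g L\n",
              x$lambda_z, x$t_half, x$n_lambda_points, x$r2_adj, x$cl_f,
              x$vz_f))
  if (!is.null(x$relative_ba))
    cat(sprintf("     relative BA %.1f%%\n", x$relative_ba))
  invisible(x)
}

#' Cohort-level NCA table
#'
#' Applies [compute_nca()] to every subject of a long-format plasma
#' dataset and appends per-formulation mean and SD rows. Relative
#' bioavailability is computed against the mean dose-normalised AUC_inf
#' of the reference formulation when one is named.
#'
#' @param data long plasma data frame (see [read_plasma_csv()]).
#' @param reference_formulation optional formulation id used as the
#'   relative-bioavailability reference.
#' @param ... passed to [compute_nca()].
#' @return A data frame with one row per subject plus \code{mean}/
#'   \code{sd} summary rows per formulation.
#' @export
nca_table <- function(data, reference_formulation = NULL, ...) {
  need <- c("subject_id", "formulation_id", "dose_mg", "time_h",
            "conc_ng_ml")
  stopifnot(all(need %in% names(data)))
  if (is.null(data$blq)) data$blq <- FALSE
  subjects <- split(data, data$subject_id)
  rows <- lapply(subjects, function(d) {
    # subjects whose terminal phase cannot be estimated (too few
    # quantifiable points after Tmax) keep their direct metrics and get
    # NA for the lambda_z-derived ones
    r <- tryCatch(
      suppressWarnings(compute_nca(d$time_h, d$conc_ng_ml,
                                   dose = d$dose_mg[1], blq = d$blq, ...)),
      error = function(e) {
        keep <- !d$blq
        i <- which.max(d$conc_ng_ml[keep])
        list(cmax = d$conc_ng_ml[keep][i], tmax = d$time_h[keep][i],
             t_half = NA_real_, lambda_z = NA_real_,
             auc_all = trapz_auc(d$time_h[keep], d$conc_ng_ml[keep]),
             auc_inf = NA_real_, vz_f = NA_real_, cl_f = NA_real_)
      })
    data.frame(subject_id = d$subject_id[1],
               formulation_id = d$formulation_id[1], row = "subject",
               dose_mg = d$dose_mg[1], cmax = r$cmax, tmax = r$tmax,
               t_half = r$t_half, lambda_z = r$lambda_z,
               auc_all = r$auc_all, auc_inf = r$auc_inf, vz_f = r$vz_f,
               cl_f = r$cl_f, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows); rownames(tab) <- NULL
  if (!is.null(reference_formulation)) {
    ref <- tab[tab$formulation_id == reference_formulation, ]
    if (!nrow(ref)) stop_domain("reference formulation not in data")
    ref_dn <- mean(ref$auc_inf / ref$dose_mg, na.rm = TRUE)
    tab$relative_ba <- 100 * (tab$auc_inf / tab$dose_mg) / ref_dn
  }
  metr <- setdiff(names(tab), c("subject_id", "formulation_id", "row"))
  summ <- do.call(rbind, lapply(split(tab, tab$formulation_id), function(g) {
    m <- g[1, ]; s <- g[1, ]
    m$subject_id <- ""; m$row <- "mean"
    s$subject_id <- ""; s$row <- "sd"
    m[metr] <- lapply(g[metr], mean, na.rm = TRUE)
    s[metr] <- lapply(g[metr], sd, na.rm = TRUE)
    rbind(m, s)
  }))
  out <- rbind(tab, summ); rownames(out) <- NULL
  out
}
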