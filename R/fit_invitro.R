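#' Fit the Michaelis-Menten model to in vitro dissolution profiles
#'
#' Least-squares estimation of the dose-normalised release parameters
#' \code{vmax} and \code{am50} from one formulation's vessel profiles.
#' The observed percentage dissolved is normalised to fraction of dose
#' internally (profiles given as fractions are detected and left alone),
#' and the optimisation runs in log-parameter space to enforce
#' positivity, with Levenberg-Marquardt refinement from multiple starts:
#' \code{vmax} initialised from the maximal observed release slope and
#' \code{am50} from \{0.1, 0.3, 0.5\}. Ties in the residual sum of
#' squares are broken towards the smallest \code{am50}.
#'
#' @param profiles a data frame as returned by [read_dissolution_csv()]
#'   or [generate_invitro_dataset()] (columns \code{time_h},
#'   \code{pct_dissolved}, optionally \code{formulation_id}, \code{ph},
#'   \code{vessel_id}).
#' @param ph which pH label to fit when several are present (default
#'   "1.2", the medium in which Michaelis-Menten release holds; other
#'   media are typically incomplete and are not fitted).
#' @param am50_starts starting values for \code{am50}.
#' @return An object of class \code{"invitro_fit"} with the estimated
#'   [invitro_release_params()] in \code{$params}, the residual SSE (on
#'   the fraction scale), observation count, and the fitted data.
#' @examples
#' d <- generate_invitro_dataset(invitro_release_params(6.58, 0.395),
#'                               noise_sd = 0, seed = 1)
#' fit <- fit_invitro_mm(d)
#' coef(fit)
#' @export
fit_invitro_mm <- function(profiles, ph = "1.2",
                           am50_starts = c(0.1, 0.3, 0.5)) {
  stopifnot(is.data.frame(profiles),
            all(c("time_h", "pct_dissolved") %in% names(profiles)))
  d <- profiles
  if (!is.null(d$ph) && length(unique(d$ph)) > 1)
    d <- d[d$ph == ph, , drop = FALSE]
  if (!is.null(d$formulation_id) && length(unique(d$formulation_id)) > 1)
    stop_domain("fit_invitro_mm expects profiles from a single formulation")
  if (nrow(d) < 4) stop_domain("need at least 4 dissolution observations")
  y_raw <- d$pct_dissolved
  # internal normalisation: percent vs fraction
  y <- if (max(y_raw) > 1.5) y_raw / 100 else y_raw
  t <- d$time_h
  if (all(y == 0) || sd(y) == 0)
    stop_domain("flat dissolution profile: release parameters not identifiable")
  # mean curve over vessels for the slope-based vmax start
  mc <- tapply(y, t, mean)
  mt <- as.numeric(names(mc))
  o <- order(mt); mt <- mt[o]; mc <- as.numeric(mc)[o]
  slopes <- diff(c(0, mc)) / diff(c(0, mt))
  vmax0 <- max(slopes, 1e-3)

  resid_fun <- function(lp) {
    p <- invitro_release_params(exp(lp[1]), exp(lp[2]))
    y - solve_invitro_dissolution(p, mt)[match(t, mt)]
  }
  best <- NULL
  for (a0 in sort(am50_starts)) {
    fit <- try(minpack.lm::nls.lm(
      par = c(log(vmax0), log(a0)), fn = resid_fun,
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    sse <- sum(fit$fvec^2)
    if (is.null(best) || sse < best$sse - 1e-12)
      best <- list(par = fit$par, sse = sse, info = fit$info,
                   start_am50 = a0)
  }
  if (is.null(best)) stop_domain("in vitro fit failed from every start")
  params <- invitro_release_params(exp(best$par[1]), exp(best$par[2]))
  structure(list(
    params = params, sse = best$sse, n_obs = length(y),
    formulation_id = if (!is.null(d$formulation_id))
      d$formulation_id[1] else NA_character_,
    ph = ph, data = d, scale = if (max(y_raw) > 1.5) "percent" else
      "fraction",
    start_am50 = best$start_am50, convergence_info = best$info
  ), class = "invitro_fit")
}

#' @export
print.invitro_fit <- function(x, ...) {
  cat(sprintf("In vitro Michaelis-Menten fit (%s, pH %s): Vmax/dose = %.4g 1/h, AM50/dose = %.4g (SSE %.3g, n = %d)\n",
              x$formulation_id, x$ph, x$params$vmax, x$params$am50,
              x$sse, x$n_obs))
  invisible(x)
}

#' @export
coef.invitro_fit <- function(object, ...) {
  c(vmax = object$params$vmax, am50 = object$params$am50)
}

#' @export
summary.invitro_fit <- function(object, ...) {
  r <- residuals(object)
  structure(list(fit = object, rmse_pct = 100 * sqrt(mean(r^2)),
                 resid_range_pct = 100 * range(r)),
            class = "summary.invitro_fit")
}

#' @export
print.summary.invitro_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  residual RMSE %.2f %%-points (range %.2f to %.2f)\n",
              x$rmse_pct, x$resid_range_pct[1], x$resid_range_pct[2]))
  invisible(x)
}

#' @export
residuals.invitro_fit <- function(object, ...) {
  y <- object$data$pct_dissolved
  if (object$scale == "percent") y <- y / 100
  y - solve_invitro_dissolution(object$params, unique(sort(object$data$time_h)))[
    match(object$data$time_h, unique(sort(object$data$time_h)))]
}

#' @export
predict.invitro_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) times <- sort(unique(object$data$time_h))
  100 * solve_invitro_dissolution(object$params, times)
}

#' @export
plot.invitro_fit <- function(x, ...) {
  d <- x$data
  tt <- seq(0, max(d$time_h), length.out = 200)
  plot(d$time_h, if (x$scale == "percent") d$pct_dissolved else
    100 * d$pct_dissolved,
    xlab = "Time (h)", ylab = "Dissolved (%)", ...)
  lines(tt, predict(x, tt), col = "red3")
  invisible(x)
}
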