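#' Parameters of the time-varying dissolved-fraction function
#'
#' The dissolved fraction \eqn{F_{Diss,total}(t)} modulates the in vivo
#' dissolution rate as the dose moves along the gastrointestinal tract.
#' It is the sum of a gastric component that switches off around the
#' gastric-emptying time and an intestinal/colonic component that rises
#' and falls during intestinal and colon transit, both shaped by steep
#' Hill functions:
#' \deqn{F_{stomach}(t) = 1 - I_{max} \frac{t^{h_s}}{T_{GET}^{h_s} + t^{h_s}}}
#' \deqn{F_{intestine}(t) = Diss_{max}
#'   \frac{t^{h_i}}{T_{trans1}^{h_i} + t^{h_i}}
#'   \left(1 - \frac{t^{h_i}}{T_{trans2}^{h_i} + t^{h_i}}\right)}
#' with \eqn{T_{trans1} = T_{GET} + T_{ITT}} and
#' \eqn{T_{trans2} = T_{GET} + T_{ITT} + T_{CTT}}.
#'
#' @param imax maximum fractional decrease of the gastric component,
#'   in (0, 1].
#' @param t_get gastric-emptying half-time (h), > 0.
#' @param hill_stomach Hill coefficient of the gastric switch, > 0.
#' @param diss_max maximum fractional increase of the intestinal
#'   component, >= 0.
#' @param t_itt intestinal transit time (h), > 0.
#' @param t_ctt colon transit time (h), > 0.
#' @param hill_intestine Hill coefficient of the intestinal rise/fall, > 0.
#'
#' @return An object of class \code{"fdiss_params"}, a named list with
#'   the seven parameters plus the derived transit landmarks
#'   \code{t_trans1} and \code{t_trans2}.
#' @seealso [f_diss_total()], [sildenafil_popk_model()]
#' @examples
#' p <- fdiss_params(imax = 0.992, t_get = 0.73, hill_stomach = 16.7,
#'                   diss_max = 0.115, t_itt = 2.18, t_ctt = 4.1,
#'                   hill_intestine = 13.1)
#' f_diss_total(c(0, 1, 4, 12), p)
#' @export
fdiss_params <- function(imax, t_get, hill_stomach, diss_max,
                         t_itt, t_ctt, hill_intestine) {
  imax <- check_scalar_pos(imax, "imax")
  if (imax > 1) stop_domain("'imax' must be <= 1 (it is a fraction)")
  p <- list(
    imax = imax,
    t_get = check_scalar_pos(t_get, "t_get"),
    hill_stomach = check_scalar_pos(hill_stomach, "hill_stomach"),
    diss_max = check_scalar_pos(diss_max, "diss_max", strict = FALSE),
    t_itt = check_scalar_pos(t_itt, "t_itt"),
    t_ctt = check_scalar_pos(t_ctt, "t_ctt"),
    hill_intestine = check_scalar_pos(hill_intestine, "hill_intestine")
  )
  p$t_trans1 <- p$t_get + p$t_itt
  p$t_trans2 <- p$t_get + p$t_itt + p$t_ctt
  structure(p, class = "fdiss_params")
}

#' @export
print.fdiss_params <- function(x, ...) {
  cat("Dissolved-fraction (F_Diss) parameters:\n")
  cat(sprintf("  gastric   : imax = %.4g, t_get = %.4g h, hill = %.4g\n",
              x$imax, x$t_get, x$hill_stomach))
  cat(sprintf("  intestinal: diss_max = %.4g, t_trans1 = %.4g h, t_trans2 = %.4g h, hill = %.4g\n",
              x$diss_max, x$t_trans1, x$t_trans2, x$hill_intestine))
  invisible(x)
}

# Overflow-safe rising Hill fraction t^h / (t50^h + t^h); continuous
# extension 0 at t = 0 (0^h = 0 for h > 0).
hill_rise <- function(t, t50, h) {
  out <- numeric(length(t))
  pos <- t > 0
  r <- (t50 / t[pos])^h
  r[!is.finite(r)] <- Inf
  out[pos] <- 1 / (1 + r)
  out
}

check_time_nonneg <- function(t) {
  if (!is.numeric(t) || any(!is.finite(t)))
    stop_domain("time must be finite numeric")
  if (any(t < 0)) stop_domain("time must be non-negative")
  invisible(t)
}

#' Dissolved-fraction components and total
#'
#' Evaluate the gastric component, the intestinal component, or their sum
#' at (a vector of) times since dose. The gastric component falls from 1
#' to \code{1 - imax}; the intestinal component rises from 0 towards
#' \code{diss_max} and falls back as the dose enters the distal colon.
#'
#' @param t time since dose (h), non-negative, vectorised.
#' @param p an [fdiss_params()] object.
#' @return Numeric vector of dimensionless fractions.
#' @export
f_diss_stomach <- function(t, p) {
  stopifnot(inherits(p, "fdiss_params"))
  check_time_nonneg(t)
  1 - p$imax * hill_rise(t, p$t_get, p$hill_stomach)
}

#' @rdname f_diss_stomach
#' @export
f_diss_intestine <- function(t, p) {
  stopifnot(inherits(p, "fdiss_params"))
  check_time_nonneg(t)
  p$diss_max * hill_rise(t, p$t_trans1, p$hill_intestine) *
    (1 - hill_rise(t, p$t_trans2, p$hill_intestine))
}

#' @rdname f_diss_stomach
#' @export
f_diss_total <- function(t, p) {
  f_diss_stomach(t, p) + f_diss_intestine(t, p)
}

#' Summarise the F_Diss trajectory on a fine grid
#'
#' Evaluates \code{f_diss_total} on a regular grid and reports the
#' post-dose minimum together with the time window (after that minimum)
#' during which the dissolved fraction stays at or above a threshold --
#' the distal window in which colonic dissolution resumes.
#'
#' @param p an [fdiss_params()] object.
#' @param t_max end of the evaluation grid (h).
#' @param dt grid spacing (h).
#' @param threshold dissolved-fraction threshold defining the window.
#' @return A list with \code{minimum}, \code{t_minimum}, and the window
#'   bounds \code{window_start}/\code{window_end} (NA when the fraction
#'   never re-crosses the threshold).
#' @export
fdiss_profile_summary <- function(p, t_max = 12, dt = 0.001,
                                  threshold = 0.10) {
  grid <- seq(0, t_max, by = dt)
  v <- f_diss_total(grid, p)
  i_min <- which.min(v)
  after <- grid > grid[i_min]
  above <- after & v >= threshold
  list(
    minimum = v[i_min],
    t_minimum = grid[i_min],
    window_start = if (any(above)) min(grid[above]) else NA_real_,
    window_end = if (any(above)) max(grid[above]) else NA_real_,
    threshold = threshold
  )
}
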