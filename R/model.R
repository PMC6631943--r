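#' Right-hand side of the in vivo dissolution-absorption-disposition model
#'
#' The full structural model couples Michaelis-Menten tablet release,
#' modulated by the time-varying dissolved fraction
#' \eqn{F_{Diss,total}(t)}, to a first-order lumen-to-gut transfer, a
#' first-order absorption step, and a linear two-compartment disposition
#' model:
#' \deqn{dX_{tab}/dt = -V_{max} X_{tab}/(AM_{50}+X_{tab}) F_{Diss}(t)}
#' \deqn{dX_{lum}/dt = +V_{max} X_{tab}/(AM_{50}+X_{tab}) F_{Diss}(t) - k_{lag} X_{lum}}
#' \deqn{dX_{gut}/dt = k_{lag} X_{lum} - k_a X_{gut}}
#' \deqn{dX_1/dt = k_a X_{gut} D - (CLD + CL) C_1 + CLD\, C_2}
#' \deqn{dX_2/dt = CLD\,(C_1 - C_2), \qquad dX_{elim}/dt = CL\, C_1}
#' with \eqn{C_1 = X_1/V_1}, \eqn{C_2 = X_2/V_2}. Tablet, lumen and gut
#' states are fractions of dose; central/peripheral/eliminated amounts
#' are in mg (the absorption term multiplies by the dose \eqn{D}).
#' The eliminated-amount state is bookkeeping that makes mass
#' conservation checkable:
#' \eqn{X_{tab}+X_{lum}+X_{gut}+(X_1+X_2+X_{elim})/D = 1} at all times.
#'
#' This R implementation mirrors the compiled C right-hand side used by
#' [simulate_pk()]; the two are tested for equivalence.
#'
#' @param state named numeric vector with elements \code{x_tablet},
#'   \code{x_lumen}, \code{x_gut}, \code{x1}, \code{x2}, \code{x_elim}.
#' @param t time since dose (h).
#' @param sp a [subject_params()] object.
#' @return Named numeric vector of derivatives, in state order.
#' @export
ode_rhs <- function(state, t, sp) {
  stopifnot(inherits(sp, "subject_params"))
  need <- c("x_tablet", "x_lumen", "x_gut", "x1", "x2", "x_elim")
  if (is.null(names(state))) names(state) <- need
  stopifnot(all(need %in% names(state)))
  check_time_nonneg(t)
  fd <- f_diss_total(t, sp$f_diss)
  xt <- state[["x_tablet"]]
  rate <- if (xt > 0)
    sp$dissolution$vmax * xt / (sp$dissolution$am50 + xt) * fd else 0
  c1 <- state[["x1"]] / sp$disposition$v1
  c2 <- state[["x2"]] / sp$disposition$v2
  c(x_tablet = -rate,
    x_lumen = rate - sp$disposition$k_lag * state[["x_lumen"]],
    x_gut = sp$disposition$k_lag * state[["x_lumen"]] -
      sp$disposition$k_a * state[["x_gut"]],
    x1 = sp$disposition$k_a * state[["x_gut"]] * sp$dose -
      (sp$disposition$cld + sp$disposition$cl) * c1 +
      sp$disposition$cld * c2,
    x2 = sp$disposition$cld * (c1 - c2),
    x_elim = sp$disposition$cl * c1)
}

# Internal workhorse: integrate the model and return the deSolve matrix
# with columns time, states, conc. `times` must include 0 or it is
# prepended. The compiled engine is the default; the pure-R engine is
# kept for cross-checking.
integrate_model <- function(sp, times, rtol = 1e-8, atol = 1e-10,
                            engine = c("compiled", "r")) {
  engine <- match.arg(engine)
  y0 <- c(x_tablet = 1, x_lumen = 0, x_gut = 0, x1 = 0, x2 = 0, x_elim = 0)
  tt <- times
  prepended <- FALSE
  if (tt[1] > 0) { tt <- c(0, tt); prepended <- TRUE }
  if (engine == "compiled") {
    out <- deSolve::lsoda(
      y = y0, times = tt, func = "sild_derivs", parms = subject_parm_vector(sp),
      dllname = "pkivivc", initfunc = "sild_initmod",
      nout = 1, outnames = "conc", rtol = rtol, atol = atol)
  } else {
    rhs <- function(t, y, parms) {
      d <- ode_rhs(y, t, sp)
      list(d, conc = y[["x1"]] / sp$disposition$v1 * 1000)
    }
    out <- deSolve::lsoda(y = y0, times = tt, func = rhs, parms = NULL,
                          rtol = rtol, atol = atol)
  }
  if (inherits(attr(out, "istate"), "numeric") &&
      attr(out, "istate")[1] < 0)
    stop_domain("ODE solver failed (istate = ", attr(out, "istate")[1],
                ") for subject ", sp$subject_id)
  if (nrow(out) < length(tt))
    stop_domain("ODE solver returned a truncated trajectory for subject ",
                sp$subject_id)
  if (prepended) out <- out[-1, , drop = FALSE]
  out
}

#' Simulate a plasma concentration-time profile
#'
#' Integrates the full model from an intact tablet
#' (\code{x_tablet = 1}, all other states 0) and returns the central
#' compartment concentration in ng/mL at the requested times.
#'
#' @param sp a [subject_params()] object.
#' @param times non-decreasing sampling times (h).
#' @param rtol,atol solver tolerances (stiff-capable \code{lsoda}; the
#'   steep Hill switches in \eqn{F_{Diss}} make tight tolerances
#'   worthwhile).
#' @param engine \code{"compiled"} (default, C right-hand side) or
#'   \code{"r"}.
#' @param keep_states also return the full state trajectory as attribute
#'   \code{"states"}.
#' @return A data frame of class \code{"pk_profile"} with columns
#'   \code{time_h} and \code{conc_ng_ml}, and attributes
#'   \code{subject_id}, \code{formulation_id}, \code{dose}.
#' @examples
#' pop <- sildenafil_popk_model()
#' prof <- simulate_pk(typical_subject(pop, "IR"), seq(0, 12, 0.25))
#' head(prof)
#' @export
simulate_pk <- function(sp, times, rtol = 1e-8, atol = 1e-10,
                        engine = c("compiled", "r"), keep_states = FALSE) {
  stopifnot(inherits(sp, "subject_params"))
  check_time_nonneg(times)
  if (length(times) > 1 && any(diff(times) < 0))
    stop_domain("'times' must be non-decreasing")
  out <- integrate_model(sp, times, rtol = rtol, atol = atol,
                         engine = match.arg(engine))
  prof <- data.frame(time_h = out[, "time"], conc_ng_ml = out[, "conc"])
  attr(prof, "subject_id") <- sp$subject_id
  attr(prof, "formulation_id") <- sp$formulation_id
  attr(prof, "dose") <- sp$dose
  if (keep_states) attr(prof, "states") <- out
  class(prof) <- c("pk_profile", "data.frame")
  prof
}

#' In vivo dissolved percentage
#'
#' Percentage of the dose dissolved in vivo by time \code{t}:
#' \eqn{100 (1 - X_{tablet}(t))}, obtained by integrating the full model.
#'
#' @param sp a [subject_params()] object.
#' @param t time(s) since dose (h).
#' @param ... passed to the integrator (\code{rtol}, \code{atol},
#'   \code{engine}).
#' @return Numeric vector of percentages, non-decreasing in \code{t}.
#' @export
in_vivo_dissolved_pct <- function(sp, t, ...) {
  stopifnot(inherits(sp, "subject_params"))
  check_time_nonneg(t)
  tt <- sort(unique(c(0, t)))
  if (length(tt) == 1) return(rep(0, length(t)))
  out <- integrate_model(sp, tt, ...)
  100 * (1 - out[match(t, out[, "time"]), "x_tablet"])
}

#' @export
print.pk_profile <- function(x, n = 6L, ...) {
  cat(sprintf("Simulated plasma profile: subject %s, formulation %s, dose %g mg, %d times\n",
              attr(x, "subject_id"), attr(x, "formulation_id"),
              attr(x, "dose"), nrow(x)))
  print(utils::head(as.data.frame(x), n))
  if (nrow(x) > n) cat("...\n")
  invisible(x)
}

#' @export
plot.pk_profile <- function(x, log = "", ...) {
  plot(x$time_h, x$conc_ng_ml, type = "l", xlab = "Time (h)",
       ylab = "Concentration (ng/mL)", log = log, ...)
  invisible(x)
}
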