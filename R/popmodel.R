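#' Population pharmacokinetic model specification
#'
#' A population model is a set of structural population means
#' (\code{theta}), log-scale between-subject variances (\code{omega2}),
#' and a residual-error model. Individual parameters follow the
#' exponential variability model \eqn{\theta_i = \theta e^{\eta_i}},
#' \eqn{\eta_i \sim N(0, \omega^2)} independently per parameter
#' (diagonal covariance). All structural parameters are shared across
#' formulations except the in vivo release rate, which is entered as one
#' \code{"vmax_invivo:<formulation>"} element per formulation.
#'
#' The residual error is proportional by default
#' (\eqn{sd = \sigma f}); a combined model is obtained by setting
#' \code{sigma_add} > 0 (\eqn{sd = \sqrt{\sigma_{add}^2 + (\sigma f)^2}}).
#'
#' @param theta named numeric vector of population means. Required names:
#'   \code{v1, v2, cl, cld, k_lag, k_a, t_get, imax, hill_stomach, t_itt,
#'   t_ctt, diss_max, hill_intestine, am50} plus one
#'   \code{vmax_invivo:<id>} entry per formulation.
#' @param omega2 named numeric vector of log-scale variances, same names
#'   as \code{theta} (entries may be 0); missing entries default to 0.
#' @param sigma proportional residual-error coefficient (> 0).
#' @param formulations data frame with columns \code{formulation_id} and
#'   \code{dose_mg}.
#' @param sigma_add additive residual component on the ng/mL scale
#'   (>= 0, default 0).
#' @param lloq lower limit of quantification (ng/mL) associated with the
#'   model's data.
#' @return An object of class \code{"popk_model"}.
#' @seealso [sildenafil_popk_model()], [fit_popk()], [sample_individual()]
#' @export
popk_model <- function(theta, omega2 = NULL, sigma = 0.15,
                       formulations, sigma_add = 0, lloq = 5) {
  shared <- c("v1", "v2", "cl", "cld", "k_lag", "k_a", "t_get", "imax",
              "hill_stomach", "t_itt", "t_ctt", "diss_max",
              "hill_intestine", "am50")
  stopifnot(is.numeric(theta), !is.null(names(theta)))
  if (!all(shared %in% names(theta)))
    stop_domain("theta is missing entries: ",
                paste(setdiff(shared, names(theta)), collapse = ", "))
  if (!is.data.frame(formulations) ||
      !all(c("formulation_id", "dose_mg") %in% names(formulations)))
    stop_domain("'formulations' must have columns formulation_id, dose_mg")
  vkeys <- paste0("vmax_invivo:", formulations$formulation_id)
  if (!all(vkeys %in% names(theta)))
    stop_domain("theta needs one 'vmax_invivo:<formulation>' entry per formulation")
  if (any(!is.finite(theta)) || any(theta <= 0))
    stop_domain("all theta values must be finite and positive")
  if (is.null(omega2)) omega2 <- setNames(numeric(length(theta)), names(theta))
  om <- setNames(numeric(length(theta)), names(theta))
  om[names(omega2)] <- omega2
  if (any(om < 0)) stop_domain("omega2 values must be >= 0")
  check_scalar_pos(sigma, "sigma", strict = FALSE)
  check_scalar_pos(sigma_add, "sigma_add", strict = FALSE)
  structure(list(
    theta = theta[c(shared, vkeys)],
    omega2 = om[c(shared, vkeys)],
    sigma = sigma, sigma_add = sigma_add,
    formulations = formulations, lloq = lloq
  ), class = "popk_model")
}

#' @export
print.popk_model <- function(x, ...) {
  cat("Population PK model (site-dependent dissolution)\n")
  cat(sprintf("  formulations: %s\n",
              paste(sprintf("%s (%g mg)", x$formulations$formulation_id,
                            x$formulations$dose_mg), collapse = ", ")))
  tab <- data.frame(theta = x$theta, omega2 = x$omega2)
  print(round(tab, 4))
  cat(sprintf("  residual: proportional sigma = %.4g", x$sigma))
  if (x$sigma_add > 0) cat(sprintf(" + additive %.4g ng/mL", x$sigma_add))
  cat("\n")
  invisible(x)
}

#' @export
coef.popk_model <- function(object, ...) object$theta

# eta names relevant for a subject on one formulation: the shared
# parameters plus that formulation's release rate.
subject_param_names <- function(model, formulation_id) {
  vkey <- paste0("vmax_invivo:", formulation_id)
  if (!vkey %in% names(model$theta))
    stop_domain("unknown formulation '", formulation_id, "'")
  c(setdiff(names(model$theta),
            grep("^vmax_invivo:", names(model$theta), value = TRUE)),
    vkey)
}

# Build a subject_params object from population means times exp(eta).
# eta is a named vector over subject_param_names(); missing names -> 0.
subject_from_model <- function(model, formulation_id, dose = NULL,
                               eta = NULL, subject_id = "typical") {
  nm <- subject_param_names(model, formulation_id)
  e <- setNames(numeric(length(nm)), nm)
  if (!is.null(eta)) e[names(eta)] <- eta
  th <- model$theta[nm] * exp(e)
  # imax is a fraction; lognormal draws occasionally exceed 1 and are
  # truncated (BSV on imax is tiny, so this is rare).
  th["imax"] <- min(th[["imax"]], 1)
  if (is.null(dose)) {
    i <- match(formulation_id, model$formulations$formulation_id)
    dose <- model$formulations$dose_mg[i]
  }
  vkey <- paste0("vmax_invivo:", formulation_id)
  subject_params(
    f_diss = fdiss_params(imax = th[["imax"]], t_get = th[["t_get"]],
                          hill_stomach = th[["hill_stomach"]],
                          diss_max = th[["diss_max"]], t_itt = th[["t_itt"]],
                          t_ctt = th[["t_ctt"]],
                          hill_intestine = th[["hill_intestine"]]),
    dissolution = invivo_release_params(vmax = th[[vkey]],
                                        am50 = th[["am50"]]),
    disposition = disposition_params(k_lag = th[["k_lag"]], k_a = th[["k_a"]],
                                     v1 = th[["v1"]], v2 = th[["v2"]],
                                     cl = th[["cl"]], cld = th[["cld"]]),
    subject_id = subject_id, formulation_id = formulation_id, dose = dose
  )
}

#' Typical-subject parameters from a population model
#'
#' @param model a [popk_model()].
#' @param formulation_id formulation to instantiate.
#' @param dose dose in mg; defaults to the formulation's design dose.
#' @return A [subject_params()] object at the population means.
#' @export
typical_subject <- function(model, formulation_id, dose = NULL) {
  subject_from_model(model, formulation_id, dose = dose)
}
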