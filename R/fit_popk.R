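# Population estimation by importance-sampling Monte Carlo EM.
#
# E-step: per subject, random effects are sampled from an adaptive
# normal proposal (centred initially at the conditional mode, then at
# the previous iteration's weighted mean) and weighted by the joint
# density of data and random effects. Common random numbers are reused
# across iterations so parameter trajectories are smooth and the run is
# deterministic given the seed.
# M-step: population means are updated as weighted means of individual
# log-parameters, between-subject variances as their weighted second
# moments, and the proportional residual CV from the weighted relative
# residual sum of squares.

#' Control options for the population fit
#'
#' @param n_samples importance samples per subject per iteration.
#' @param max_iter maximum EM iterations.
#' @param tol relative parameter-change threshold for convergence.
#' @param tol_window number of consecutive iterations that must satisfy
#'   \code{tol} before the fit is declared converged.
#' @param seed integer seed (the fit is deterministic given it).
#' @param min_obs minimum quantifiable observations per subject;
#'   subjects below it are excluded with a warning.
#' @param sigma_floor,omega_floor lower bounds keeping the residual CV
#'   and the between-subject variances away from exact zero (the
#'   importance proposal degenerates there).
#' @param ess_min effective-sample-size trigger below which the
#'   proposal is re-centred by a conditional-mode search.
#' @param rtol,atol ODE tolerances used inside the likelihood (looser
#'   than the simulation defaults; the likelihood is smooth at this
#'   accuracy).
#' @param mode_start centre the initial proposal at each subject's
#'   conditional mode.
#' @param mode_maxit iteration cap for mode searches.
#' @param proposal_inflation scale inflation of the adapted proposal sd.
#' @param n_starts number of EM runs from jittered initial values; the
#'   run with the best final log-likelihood is kept (the structural
#'   model's clustered rate constants create local optima; see the
#'   methods vignette).
#' @param start_jitter log-scale sd of the initial-value jitter applied
#'   to starts after the first.
#' @param verbose print per-iteration progress.
#' @return A list of class \code{"popk_control"}.
#' @export
popk_control <- function(n_samples = 1000, max_iter = 100, tol = 1e-3,
                         tol_window = 10, seed = 1, min_obs = 5,
                         sigma_floor = 1e-3, omega_floor = 1e-2,
                         ess_min = 8, rtol = 1e-6, atol = 1e-8,
                         mode_start = TRUE, mode_maxit = 100,
                         proposal_inflation = 1.2, n_starts = 1,
                         start_jitter = 0.1, verbose = FALSE) {
  structure(as.list(environment()), class = "popk_control")
}

# Compiled-parms vector for a subject; order must match src/pkmodel.c.
build_parms <- function(th, vkey, dose) {
  c(th[[vkey]], th[["am50"]], min(th[["imax"]], 1), th[["t_get"]],
    th[["hill_stomach"]], th[["diss_max"]], th[["t_itt"]], th[["t_ctt"]],
    th[["hill_intestine"]], th[["k_lag"]], th[["k_a"]], th[["v1"]],
    th[["v2"]], th[["cl"]], th[["cld"]], dose)
}

.popk_y0 <- c(x_tablet = 1, x_lumen = 0, x_gut = 0, x1 = 0, x2 = 0,
              x_elim = 0)

# Model-predicted concentrations at obs times; NULL on solver failure.
conc_at <- function(pv, times, rtol, atol) {
  out <- try(suppressWarnings(deSolve::lsoda(
    y = .popk_y0, times = c(0, times), func = "sild_derivs", parms = pv,
    dllname = "pkivivc", initfunc = "sild_initmod", nout = 1,
    outnames = "conc", rtol = rtol, atol = atol, maxsteps = 2000)),
    silent = TRUE)
  if (inherits(out, "try-error") || nrow(out) < length(times) + 1)
    return(NULL)
  out[-1, "conc"]
}

# Reject physiologically absurd individual parameter sets before paying
# for an ODE solve (extreme Hill exponents in particular make the
# system needlessly stiff; such draws carry essentially zero posterior
# mass anyway).
params_plausible <- function(th, vkey) {
  all(is.finite(th)) && all(th > 0) &&
    th[["hill_stomach"]] <= 60 && th[["hill_intestine"]] <= 60 &&
    th[["k_lag"]] <= 1e3 && th[["k_a"]] <= 1e3 && th[[vkey]] <= 1e3 &&
    th[["t_get"]] >= 1e-3 && th[["t_itt"]] >= 1e-3 &&
    th[["t_ctt"]] >= 1e-3
}

# Per-subject log-likelihood plus the relative residual sum of squares
# used by the sigma update. Proportional (optionally combined) error.
subject_loglik <- function(eta, sub, theta, sigma, sigma_add, ctrl) {
  if (any(abs(eta) > 4)) return(list(ll = -Inf, rss = NA_real_))
  th <- theta[sub$nm] * exp(eta)
  if (!params_plausible(th, sub$vkey))
    return(list(ll = -Inf, rss = NA_real_))
  f <- conc_at(build_parms(th, sub$vkey, sub$dose), sub$t,
               ctrl$rtol, ctrl$atol)
  if (is.null(f)) return(list(ll = -Inf, rss = NA_real_))
  fmin <- pmax(f, 1e-3)
  sdv <- sqrt(sigma_add^2 + (sigma * fmin)^2)
  list(ll = sum(dnorm(sub$y, f, sdv, log = TRUE)),
       rss = sum(((sub$y - f) / fmin)^2))
}

# Negative joint log density of data and random effects (for the
# conditional-mode search). `free` marks the eta dimensions with
# nonzero prior variance; the others are pinned at zero.
neg_joint <- function(eta_free, free, sub, theta, omega2, sigma,
                      sigma_add, ctrl) {
  eta <- numeric(length(free)); eta[free] <- eta_free
  names(eta) <- sub$nm
  ll <- subject_loglik(eta, sub, theta, sigma, sigma_add, ctrl)$ll
  if (!is.finite(ll)) return(1e10)
  lp <- sum(dnorm(eta[free], 0, sqrt(omega2[sub$nm][free]), log = TRUE))
  -(ll + lp)
}

# Conditional-mode search by Levenberg-Marquardt on the stacked
# (weighted data residuals, scaled eta) vector: minimising its sum of
# squares maximises the joint density for fixed sigma. Returns the mode
# and a Laplace-style marginal sd for the importance proposal.
mode_search_lm <- function(start, free, sub, theta, omega2, sigma,
                           sigma_add, ctrl, maxiter = 50) {
  om_sd <- sqrt(pmax(omega2[sub$nm][free], 1e-10))
  n_res <- length(sub$y) + sum(free)
  bad <- rep(1e4, n_res)
  resfun <- function(ef) {
    if (any(abs(ef) > 4)) return(bad)
    eta <- numeric(length(free)); eta[free] <- ef
    th <- theta[sub$nm] * exp(eta)
    if (!params_plausible(th, sub$vkey)) return(bad)
    f <- conc_at(build_parms(th, sub$vkey, sub$dose), sub$t,
                 ctrl$rtol, ctrl$atol)
    if (is.null(f)) return(bad)
    fmin <- pmax(f, 1e-3)
    sdv <- sqrt(sigma_add^2 + (sigma * fmin)^2)
    c((sub$y - f) / sdv, ef / om_sd)
  }
  fit <- try(suppressWarnings(minpack.lm::nls.lm(
    par = start, fn = resfun,
    # epsfcn keeps finite-difference steps well above the ODE solver's
    # output noise; the default machine-precision step produces garbage
    # Jacobians on an adaptively meshed solution
    control = minpack.lm::nls.lm.control(maxiter = maxiter,
                                         ptol = 1e-10, ftol = 1e-10,
                                         epsfcn = 1e-6))),
    silent = TRUE)
  if (inherits(fit, "try-error") || any(!is.finite(fit$par)))
    return(NULL)
  # -log joint curvature ~ H/2 with H the LM Hessian of the SSE;
  # marginal sds from its inverse, with diagonal-precision fallback
  sd_lap <- NULL
  H <- fit$hessian / 2
  cv <- try(solve(H), silent = TRUE)
  if (!inherits(cv, "try-error")) {
    dg <- diag(cv)
    if (all(is.finite(dg)) && all(dg > 0)) sd_lap <- sqrt(dg)
  }
  if (is.null(sd_lap)) {
    dg <- diag(H)
    sd_lap <- ifelse(is.finite(dg) & dg > 0, 1 / sqrt(dg), om_sd)
  }
  list(eta = fit$par, sd = pmin(pmax(sd_lap, 1e-3), 2), sse = fit$deviance)
}

#' Empirical-Bayes conditional mode for one subject
#'
#' Maximises the joint density of one subject's data and random effects
#' under a population model -- the empirical-Bayes estimate used to
#' centre the importance-sampling proposal. Dimensions whose
#' between-subject variance is exactly zero are pinned at the
#' population mean.
#'
#' @param subject_data data frame of one subject's rows (columns
#'   \code{time_h}, \code{conc_ng_ml}, \code{formulation_id},
#'   \code{dose_mg}, optional \code{blq}).
#' @param model a [popk_model()].
#' @param control a [popk_control()] (its \code{rtol}/\code{atol} and
#'   \code{mode_maxit} are used).
#' @return A list with \code{subject} (a [subject_params()] at the
#'   mode), \code{eta} (named vector), \code{objective} and
#'   \code{converged}.
#' @export
conditional_mode <- function(subject_data, model,
                             control = popk_control()) {
  stopifnot(inherits(model, "popk_model"))
  d <- subject_data
  if (is.null(d$blq)) d$blq <- d$conc_ng_ml < model$lloq
  d <- d[!d$blq, , drop = FALSE]
  if (nrow(d) == 0) stop_domain("subject has no quantifiable observations")
  fid <- as.character(d$formulation_id[1])
  sub <- list(t = d$time_h, y = d$conc_ng_ml,
              nm = subject_param_names(model, fid),
              vkey = paste0("vmax_invivo:", fid), dose = d$dose_mg[1],
              id = if (!is.null(d$subject_id)) d$subject_id[1] else "subj")
  om <- model$omega2[sub$nm]
  free <- om > 0
  eta <- setNames(numeric(length(sub$nm)), sub$nm)
  converged <- TRUE
  if (any(free)) {
    ms <- mode_search_lm(numeric(sum(free)), free, sub, model$theta,
                         model$omega2, model$sigma, model$sigma_add,
                         control, maxiter = control$mode_maxit)
    if (is.null(ms)) {
      warning("conditional-mode search failed; falling back to population means",
              call. = FALSE)
      converged <- FALSE
    } else {
      eta[free] <- ms$eta
    }
  }
  list(subject = subject_from_model(model, fid, dose = sub$dose,
                                    eta = eta, subject_id = sub$id),
       eta = eta,
       objective = neg_joint(eta[free], free, sub, model$theta,
                             model$omega2, model$sigma, model$sigma_add,
                             control),
       converged = converged)
}

#' Fit the population PK model by importance-sampling Monte Carlo EM
#'
#' Simultaneously fits all formulations' plasma profiles to the
#' site-dependent dissolution model with exponential between-subject
#' variability. All structural parameters are shared across
#' formulations except the in vivo release rate, which is estimated per
#' formulation. Observations below the LLOQ are excluded from the
#' likelihood; subjects left with fewer than \code{min_obs}
#' quantifiable observations are dropped with a warning. The fit is
#' deterministic given \code{control$seed}.
#'
#' @param data long plasma data frame (see [read_plasma_csv()]).
#' @param init a [popk_model()] holding starting values (theta, omega2,
#'   sigma) and the formulation/dose table.
#' @param control a [popk_control()].
#' @return An object of class \code{"popk_fit"}: the estimated
#'   [popk_model()] in \code{$model}, the importance-sampled
#'   observed-data log-likelihood trajectory and its Monte Carlo
#'   standard errors, the per-iteration parameter path, per-subject
#'   conditional means, convergence information, and provenance.
#' @export
fit_popk <- function(data, init, control = popk_control()) {
  stopifnot(inherits(init, "popk_model"),
            inherits(control, "popk_control"))
  if (control$n_starts <= 1)
    return(fit_popk_single(data, init, control))
  fits <- vector("list", control$n_starts)
  for (s in seq_len(control$n_starts)) {
    init_s <- init
    if (s > 1) {
      init_s$theta <- with_seed(control$seed + 7000L + s, {
        init$theta * exp(rnorm(length(init$theta), 0,
                               control$start_jitter))
      })
    }
    fits[[s]] <- withCallingHandlers(
      try(fit_popk_single(data, init_s, control), silent = TRUE),
      warning = function(w) invokeRestart("muffleWarning"))
    if (control$verbose && !inherits(fits[[s]], "try-error"))
      message(sprintf("start %d: logLik %.2f (%s)", s,
                      tail(fits[[s]]$loglik, 1),
                      if (fits[[s]]$converged) "converged" else
                        "not converged"))
  }
  ok <- !vapply(fits, inherits, logical(1), "try-error")
  if (!any(ok)) stop_domain("every EM start failed")
  lls <- vapply(fits, function(f)
    if (inherits(f, "try-error")) -Inf else tail(f$loglik, 1), numeric(1))
  best <- fits[[which.max(lls)]]
  best$start_logliks <- lls
  if (!best$converged)
    warning("best EM start did not meet the convergence criterion",
            call. = FALSE)
  best
}

fit_popk_single <- function(data, init, control = popk_control()) {
  need <- c("subject_id", "formulation_id", "dose_mg", "time_h",
            "conc_ng_ml")
  stopifnot(all(need %in% names(data)))
  if (is.null(data$blq)) data$blq <- data$conc_ng_ml < init$lloq
  q <- data[!data$blq, , drop = FALSE]
  subs <- list()
  for (sid in unique(data$subject_id)) {
    d <- q[q$subject_id == sid, , drop = FALSE]
    if (nrow(d) < control$min_obs) {
      warning(sprintf("subject %s excluded: %d quantifiable observation(s) (< %d)",
                      sid, nrow(d), control$min_obs), call. = FALSE)
      next
    }
    fid <- as.character(d$formulation_id[1])
    subs[[sid]] <- list(id = sid, fid = fid,
                        nm = subject_param_names(init, fid),
                        vkey = paste0("vmax_invivo:", fid),
                        dose = d$dose_mg[1], t = d$time_h,
                        y = d$conc_ng_ml, n_obs = nrow(d))
  }
  if (length(subs) < 2) stop_domain("need at least 2 usable subjects")
  ns <- length(subs)
  theta <- init$theta
  pnames <- names(theta)
  # parameters whose initial BSV is exactly zero carry no random effect:
  # they are pure fixed effects, updated by a pooled likelihood step
  # (the EM in its degenerate omega^2 -> 0 limit)
  ran <- pnames[init$omega2 > 0]
  fixonly <- setdiff(pnames, ran)
  omega2 <- init$omega2
  omega2[ran] <- pmax(omega2[ran], control$omega_floor)
  sigma <- max(init$sigma, control$sigma_floor)
  sigma_add <- init$sigma_add

  n <- control$n_samples
  for (k in seq_len(ns))
    subs[[k]]$free <- subs[[k]]$nm %in% ran
  nobs_all <- sum(vapply(subs, `[[`, numeric(1), "n_obs"))

  with_seed(control$seed, {
    # common random numbers, one block per subject
    Z <- lapply(subs, function(s) matrix(rnorm(sum(s$free) * n),
                                         nrow = sum(s$free)))
    prop_m <- lapply(subs, function(s) setNames(numeric(length(s$nm)),
                                                s$nm))
    prop_s <- lapply(subs, function(s) sqrt(pmax(omega2[s$nm], 1e-4)))

    ll_path <- numeric(0); ll_se_path <- numeric(0)
    theta_path <- matrix(NA_real_, control$max_iter, length(theta),
                         dimnames = list(NULL, pnames))
    sigma_path <- numeric(control$max_iter)
    ok_streak <- 0L; converged <- FALSE; iter_done <- 0L
    pooled_sse <- NA_real_

    for (iter in seq_len(control$max_iter)) {
      Ebar <- matrix(0, ns, length(pnames),
                     dimnames = list(names(subs), pnames))
      E2 <- Ebar
      used <- Ebar  # indicator: subject informs this random effect
      rss_tot <- 0
      ll_tot <- 0; ll_var <- 0

      for (k in seq_len(ns)) {
        s <- subs[[k]]
        free <- s$free
        if (!any(free)) {
          # no random effects: plain likelihood contribution at eta = 0
          r <- subject_loglik(setNames(numeric(length(s$nm)), s$nm), s,
                              theta, sigma, sigma_add, control)
          if (!is.finite(r$ll))
            stop_domain("non-finite likelihood for subject ", s$id)
          ll_tot <- ll_tot + r$ll
          rss_tot <- rss_tot + r$rss
          next
        }
        # E-step proposal: conditional mode (Levenberg-Marquardt on the
        # penalised residuals, warm-started) with Laplace marginal sds
        if (control$mode_start || iter > 1) {
          ms <- mode_search_lm(as.numeric(prop_m[[k]][free]), free, s,
                               theta, omega2, sigma, sigma_add, control,
                               maxiter = if (iter == 1)
                                 control$mode_maxit else 25)
          if (!is.null(ms)) {
            prop_m[[k]][free] <- ms$eta
            prop_s[[k]][free] <- ms$sd * control$proposal_inflation
          }
        }
        m <- prop_m[[k]][free]
        om_k <- omega2[s$nm][free]
        sd_k <- pmin(pmax(prop_s[[k]][free], 1e-3),
                     pmax(2 * sqrt(om_k), 0.5))
        eta_f <- m + sd_k * Z[[k]]             # free dims x n
        lp <- colSums(dnorm(eta_f, 0, sqrt(om_k), log = TRUE))
        lq <- colSums(dnorm(eta_f, m, sd_k, log = TRUE))
        eta_full <- setNames(numeric(length(s$nm)), s$nm)
        lw <- numeric(n); rss <- numeric(n)
        for (j in seq_len(n)) {
          eta_full[free] <- eta_f[, j]
          r <- subject_loglik(eta_full, s, theta, sigma, sigma_add,
                              control)
          lw[j] <- r$ll + lp[j] - lq[j]
          rss[j] <- r$rss
        }
        Mx <- max(lw)
        if (!is.finite(Mx))
          stop_domain("non-finite likelihood for every sample of subject ",
                      s$id)
        w <- exp(lw - Mx); W <- w / sum(w)
        ess <- 1 / sum(W^2)
        ll_tot <- ll_tot + Mx + log(mean(w))
        ll_var <- ll_var + var(w) / (n * mean(w)^2)
        e1 <- as.numeric(eta_f %*% W)
        e2 <- as.numeric((eta_f^2) %*% W)
        rss_k <- sum(W * rss, na.rm = TRUE)
        if (ess < control$ess_min) {
          # weights collapsed (sharply concentrated conditional
          # density): treat the density as a Gaussian at the mode with
          # the Laplace spread
          lap_v <- (sd_k / control$proposal_inflation)^2
          e1 <- as.numeric(m)
          e2 <- e1^2 + pmin(lap_v, om_k + 1e-6)
          eta_full[free] <- e1
          rm_ <- subject_loglik(eta_full, s, theta, sigma, sigma_add,
                                control)$rss
          if (is.finite(rm_)) rss_k <- rm_
        }
        Ebar[k, s$nm[free]] <- e1; E2[k, s$nm[free]] <- e2
        used[k, s$nm[free]] <- 1
        rss_tot <- rss_tot + rss_k
      }

      theta_old <- theta; sigma_old <- sigma
      # M-step, random-effect parameters: weighted first and second
      # moments of the individual log-parameters
      nsub_p <- colSums(used)
      delta <- colSums(Ebar) / pmax(nsub_p, 1)
      delta[nsub_p == 0] <- 0
      theta <- theta * exp(delta)
      m2 <- colSums(E2) / pmax(nsub_p, 1)
      omega2_new <- pmax(m2 - delta^2, control$omega_floor)
      omega2_new[nsub_p == 0] <- omega2[nsub_p == 0]
      omega2 <- omega2_new
      omega2[fixonly] <- 0
      # re-express proposal means relative to the shifted theta
      for (k in seq_len(ns))
        prop_m[[k]] <- prop_m[[k]] - delta[subs[[k]]$nm]
      # M-step, fixed-only parameters: pooled Levenberg-Marquardt on
      # the stacked residuals of all subjects (etas held at their
      # conditional means)
      if (length(fixonly)) {
        big <- rep(1e4, nobs_all)
        # log-scale residuals: equivalent to the multiplicative error
        # model near the optimum and far better conditioned away from
        # it than 1/f-weighted residuals
        stack_res <- function(lf) {
          th_f <- exp(lf)
          if (any(!is.finite(th_f))) return(big)
          theta_try <- theta; theta_try[fixonly] <- th_f
          out <- vector("list", ns)
          for (k in seq_len(ns)) {
            s <- subs[[k]]
            th <- theta_try[s$nm] * exp(prop_m[[k]])
            if (!params_plausible(th, s$vkey)) return(big)
            f <- conc_at(build_parms(th, s$vkey, s$dose), s$t,
                         control$rtol, control$atol)
            if (is.null(f)) return(big)
            out[[k]] <- log(s$y) - log(pmax(f, 1e-6))
          }
          unlist(out)
        }
        # trust box: each EM iteration moves the pooled fixed effects
        # by at most +/-0.3 on the log scale, so a single wild
        # Levenberg-Marquardt excursion cannot leave the current valley
        lf0 <- log(theta[fixonly])
        lmf <- try(suppressWarnings(minpack.lm::nls.lm(
          par = lf0, fn = stack_res,
          lower = lf0 - 0.05, upper = lf0 + 0.05,
          control = minpack.lm::nls.lm.control(
            maxiter = 25,
            ptol = 1e-10, ftol = 1e-10, epsfcn = 1e-6))), silent = TRUE)
        if (!inherits(lmf, "try-error") && all(is.finite(lmf$par))) {
          theta[fixonly] <- exp(lmf$par)
          pooled_sse <- lmf$deviance
        }
      }
      sigma <- max(sqrt(rss_tot / nobs_all), control$sigma_floor)

      ll_path <- c(ll_path, ll_tot)
      ll_se_path <- c(ll_se_path, sqrt(ll_var))
      theta_path[iter, ] <- theta
      sigma_path[iter] <- sigma
      iter_done <- iter
      rel <- max(abs(c(theta - theta_old, sigma - sigma_old)) /
                   abs(c(theta_old, sigma_old)))
      if (control$verbose)
        message(sprintf("iter %3d  logLik %.3f (se %.3f)  sigma %.4f  max rel change %.2e",
                        iter, ll_tot, sqrt(ll_var), sigma, rel))
      if (rel < control$tol) ok_streak <- ok_streak + 1L else
        ok_streak <- 0L
      if (ok_streak >= control$tol_window) { converged <- TRUE; break }
      # a purely fixed-effect run still far from an adequate fit after
      # several pooled steps is descending the wrong valley: abandon it
      # (multi-start keeps the best run)
      if (!length(ran) && iter >= 6 && is.finite(pooled_sse) &&
          pooled_sse > 1) break
    }
  })

  model <- popk_model(theta = theta, omega2 = omega2, sigma = sigma,
                      formulations = init$formulations,
                      sigma_add = sigma_add, lloq = init$lloq)
  if (!converged)
    warning(sprintf("EM did not meet the convergence criterion within %d iterations",
                    iter_done), call. = FALSE)
  structure(list(
    model = model, init = init,
    loglik = ll_path, loglik_se = ll_se_path,
    theta_path = theta_path[seq_len(iter_done), , drop = FALSE],
    sigma_path = sigma_path[seq_len(iter_done)],
    conditional_means = lapply(prop_m, identity),
    converged = converged, iterations = iter_done,
    n_subjects = ns,
    options = control, data_checksum = data_checksum(data)
  ), class = "popk_fit")
}

#' @export
print.popk_fit <- function(x, ...) {
  cat(sprintf("Population fit (MC-PEM, importance sampling): %d subjects, %d iterations, %s\n",
              x$n_subjects, x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  final logLik %.2f (MC se %.2f), sigma %.4f\n",
              tail(x$loglik, 1), tail(x$loglik_se, 1), x$model$sigma))
  invisible(x)
}

#' @export
summary.popk_fit <- function(object, ...) {
  tab <- data.frame(theta = object$model$theta,
                    omega2 = object$model$omega2,
                    init_theta = object$init$theta)
  structure(list(fit = object, table = tab), class = "summary.popk_fit")
}

#' @export
print.summary.popk_fit <- function(x, ...) {
  print(x$fit)
  print(round(x$table, 4))
  invisible(x)
}

#' @export
coef.popk_fit <- function(object, ...) object$model$theta

#' @export
logLik.popk_fit <- function(object, ...) {
  structure(tail(object$loglik, 1), df = length(object$model$theta) +
              length(object$model$omega2) + 1, class = "logLik")
}

#' Visual predictive check
#'
#' Simulates individuals (between-subject variability plus residual
#' noise) under a population model and the study design, and returns
#' percentile bands of the simulated concentrations per formulation and
#' sampling time, for overlay on observed data.
#'
#' @param model a [popk_model()].
#' @param design a [study_design()].
#' @param n_sim simulated individuals per formulation (>= 100).
#' @param seed integer seed.
#' @param probs percentiles for the bands.
#' @return A data frame of class \code{"popk_vpc"} with columns
#'   \code{formulation_id}, \code{time_h}, one column per percentile,
#'   and the typical (noise-free population-mean) profile.
#' @export
visual_predictive_check <- function(model, design = study_design(),
                                    n_sim = 200, seed = 1,
                                    probs = c(0.05, 0.5, 0.95)) {
  stopifnot(inherits(model, "popk_model"), inherits(design, "study_design"))
  if (n_sim < 100) stop_domain("n_sim must be >= 100")
  tt <- design$plasma_times
  out <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(nrow(design$formulations)), function(i) {
      fid <- design$formulations$formulation_id[i]
      dose <- design$formulations$dose_mg[i]
      sim <- vapply(seq_len(n_sim), function(j) {
        sp <- sample_individual(model, fid, dose = dose,
                                subject_id = sprintf("vpc%04d", j))
        f <- simulate_pk(sp, tt)$conc_ng_ml
        sdv <- sqrt(model$sigma_add^2 + (model$sigma * f)^2)
        pmax(f + sdv * rnorm(length(f)), 0)
      }, numeric(length(tt)))
      qs <- t(apply(sim, 1, quantile, probs = probs))
      colnames(qs) <- paste0("p", formatC(100 * probs, format = "g"))
      typ <- simulate_pk(typical_subject(model, fid, dose = dose),
                         tt)$conc_ng_ml
      cbind(data.frame(formulation_id = fid, time_h = tt),
            as.data.frame(qs), typical = typ)
    }))
  })
  class(out) <- c("popk_vpc", "data.frame")
  out
}

#' @export
plot.popk_vpc <- function(x, formulation_id = NULL, ...) {
  d <- as.data.frame(x)
  if (is.null(formulation_id)) formulation_id <- d$formulation_id[1]
  d <- d[d$formulation_id == formulation_id, ]
  pc <- grep("^p[0-9]", names(d), value = TRUE)
  plot(d$time_h, d[[pc[length(pc)]]], type = "n", xlab = "Time (h)",
       ylab = "Concentration (ng/mL)", main = formulation_id, ...)
  polygon(c(d$time_h, rev(d$time_h)),
          c(d[[pc[1]]], rev(d[[pc[length(pc)]]])),
          col = adjustcolor("steelblue", 0.3), border = NA)
  lines(d$time_h, d$p50, col = "steelblue4")
  lines(d$time_h, d$typical, col = "red3", lty = 2)
  invisible(x)
}
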