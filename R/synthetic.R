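#' Study design for synthetic data generation
#'
#' Captures the crossover-free parallel design the generators emulate:
#' four formulations (IR 20 mg; three SR 60 mg), three subjects per
#' formulation, 19 plasma sampling times over 0-48 h, a 14-point
#' dissolution sampling schedule over 24 h with six vessels, and an
#' assay LLOQ of 5 ng/mL.
#'
#' @param formulations data frame with \code{formulation_id},
#'   \code{dose_mg}.
#' @param n_subjects subjects per formulation.
#' @param plasma_times plasma sampling schedule (h).
#' @param dissolution_times dissolution sampling schedule (h).
#' @param lloq lower limit of quantification (ng/mL).
#' @param n_vessels dissolution vessels per run.
#' @return An object of class \code{"study_design"}.
#' @export
study_design <- function(
    formulations = data.frame(
      formulation_id = c("IR", "SR_fast", "SR_medium", "SR_slow"),
      dose_mg = c(20, 60, 60, 60), stringsAsFactors = FALSE),
    n_subjects = 3,
    plasma_times = c(0, 0.25, 0.5, 0.75, 1, 1.5, 2, 2.5, 3, 3.5, 4, 5, 6,
                     7, 8, 12, 24, 36, 48),
    dissolution_times = c(0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4, 6, 8, 10, 12,
                          16, 24),
    lloq = 5, n_vessels = 6) {
  stopifnot(is.data.frame(formulations),
            all(c("formulation_id", "dose_mg") %in% names(formulations)),
            n_subjects >= 1, n_vessels >= 1, lloq > 0,
            all(diff(plasma_times) > 0), all(diff(dissolution_times) > 0),
            all(plasma_times >= 0), all(dissolution_times >= 0))
  structure(list(formulations = formulations,
                 n_subjects = as.integer(n_subjects),
                 plasma_times = plasma_times,
                 dissolution_times = dissolution_times,
                 lloq = lloq, n_vessels = as.integer(n_vessels)),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("Study design: %d formulations x %d subjects, %d plasma times (0-%g h), LLOQ %g ng/mL\n",
              nrow(x$formulations), x$n_subjects, length(x$plasma_times),
              max(x$plasma_times), x$lloq))
  invisible(x)
}

#' Draw an individual from the population model
#'
#' Individual parameters follow the exponential between-subject
#' variability model \eqn{\theta_i = \theta e^{\eta}},
#' \eqn{\eta \sim N(0, \omega^2)} independently per parameter.
#'
#' @param pop a [popk_model()].
#' @param formulation_id formulation the subject receives.
#' @param dose dose in mg (defaults to the formulation's design dose).
#' @param seed optional integer seed (the draw is a pure function of it).
#' @param subject_id identifier for the new subject.
#' @return A [subject_params()] object.
#' @export
sample_individual <- function(pop, formulation_id, dose = NULL,
                              seed = NULL, subject_id = "sim") {
  stopifnot(inherits(pop, "popk_model"))
  nm <- subject_param_names(pop, formulation_id)
  with_seed(seed, {
    eta <- rnorm(length(nm), 0, sqrt(pop$omega2[nm]))
    names(eta) <- nm
    subject_from_model(pop, formulation_id, dose = dose, eta = eta,
                       subject_id = subject_id)
  })
}

#' Generate a synthetic plasma cohort
#'
#' Simulates every subject of the design from the population model,
#' adds proportional residual noise
#' (\eqn{y = f (1 + \sigma \epsilon)}, plus an additive component when
#' the model specifies one), truncates negative values at zero, and
#' flags observations below the LLOQ. The generating individual
#' parameters are returned alongside the data so that estimation can be
#' scored against the truth.
#'
#' @param pop a [popk_model()].
#' @param design a [study_design()].
#' @param seed integer seed; the cohort is a pure function of
#'   (pop, design, seed).
#' @return A list of class \code{"synthetic_cohort"} with elements
#'   \code{data} (long data frame: subject_id, formulation_id, dose_mg,
#'   time_h, conc_ng_ml, blq), \code{truth} (list of
#'   [subject_params()]), \code{model}, \code{design}, \code{seed}.
#' @export
generate_cohort <- function(pop, design = study_design(), seed = 1) {
  stopifnot(inherits(pop, "popk_model"), inherits(design, "study_design"))
  with_seed(seed, {
    rows <- list(); truth <- list(); k <- 0L
    for (i in seq_len(nrow(design$formulations))) {
      fid <- design$formulations$formulation_id[i]
      dose <- design$formulations$dose_mg[i]
      for (j in seq_len(design$n_subjects)) {
        k <- k + 1L
        sid <- sprintf("%s_%02d", fid, j)
        sp <- sample_individual(pop, fid, dose = dose, subject_id = sid)
        prof <- simulate_pk(sp, design$plasma_times)
        f <- prof$conc_ng_ml
        sdv <- sqrt(pop$sigma_add^2 + (pop$sigma * f)^2)
        y <- pmax(f + sdv * rnorm(length(f)), 0)
        rows[[k]] <- data.frame(
          subject_id = sid, formulation_id = fid, dose_mg = dose,
          time_h = design$plasma_times, conc_ng_ml = y,
          blq = y < design$lloq, stringsAsFactors = FALSE)
        truth[[sid]] <- sp
      }
    }
    structure(list(data = do.call(rbind, rows), truth = truth,
                   model = pop, design = design, seed = seed),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects, %d observations (%.0f%% BLQ), seed %s\n",
              length(x$truth), nrow(x$data), 100 * mean(x$data$blq),
              format(x$seed)))
  invisible(x)
}

#' Generate a synthetic in vitro dissolution dataset
#'
#' Noise-free vessel curves come from the closed-form Michaelis-Menten
#' solution; per-vessel additive Gaussian noise (in percentage points,
#' emulating assay and sampling variability) is added and the result is
#' clipped to [0, 105]%.
#'
#' @param p an [invitro_release_params()] object (the generating truth).
#' @param design a [study_design()] (supplies times and vessel count).
#' @param formulation_id label for the generated profiles.
#' @param ph pH label attached to the profiles (default "1.2").
#' @param noise_sd additive noise standard deviation, percentage points.
#' @param seed integer seed.
#' @return A data frame with columns formulation_id, ph, vessel_id,
#'   time_h, pct_dissolved, plus the generating parameters in attribute
#'   \code{"truth"}.
#' @export
generate_invitro_dataset <- function(p, design = study_design(),
                                     formulation_id = "F1", ph = "1.2",
                                     noise_sd = 2, seed = 1) {
  stopifnot(inherits(p, "mm_release"))
  check_scalar_pos(noise_sd, "noise_sd", strict = FALSE)
  tt <- design$dissolution_times
  mean_curve <- 100 * solve_invitro_dissolution(p, tt)
  with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(design$n_vessels), function(v) {
      y <- mean_curve + rnorm(length(tt), 0, noise_sd)
      data.frame(formulation_id = formulation_id, ph = ph,
                 vessel_id = sprintf("V%d", v), time_h = tt,
                 pct_dissolved = pmin(pmax(y, 0), 105),
                 stringsAsFactors = FALSE)
    }))
    attr(out, "truth") <- list(vmax = p$vmax, am50 = p$am50,
                               noise_sd = noise_sd, seed = seed)
    out
  })
}
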