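---
title: "Population PK modelling of site-dependent dissolution and the IVIVC it supports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population PK modelling of site-dependent dissolution and the IVIVC it supports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pkivivc)
```

## The problem this package models

Sildenafil is a BCS class II compound: highly permeable, poorly
soluble, and — decisively for oral sustained-release (SR) design — its
solubility collapses as pH rises above ~6. A tablet that releases
quickly dissolves almost entirely in the stomach; a slow-releasing SR
tablet carries most of its payload into the small intestine, where the
drug barely dissolves at all, and only partially recovers in the
slightly more acidic colon. The observable consequences in beagle dogs
are (i) bioavailability that *falls* as the release rate slows and
(ii) secondary plasma peaks a few hours after dosing, produced by
colonic re-dissolution rather than enterohepatic recycling.

Classical level-A IVIVC methods (Wagner–Nelson, Loo–Riegelman,
numerical deconvolution) estimate a single combined absorption profile
and cannot separate *where* dissolution happens from *how fast* drug is
absorbed. This package implements the model-based alternative: a
population PK model in which dissolution is modulated by a
time-varying, gastrointestinal-site-dependent dissolved fraction, so
that in vivo dissolution becomes an estimable latent process, and the
in vitro ↔ in vivo link reduces to a regression between two release
rates.

## The structural model

Undissolved drug in the tablet, the dissolved amount in the lumen and
the absorbable amount in the gut are carried as fractions of dose;
central and peripheral amounts in mg.

**Release.** In vitro and in vivo release both follow Michaelis–Menten
depletion,
$$\frac{dX_{tab}}{dt} = -\frac{V_{max}\,X_{tab}}{AM_{50}+X_{tab}}\; F_{Diss}(t),$$
with $F_{Diss}\equiv 1$ in the dissolution vessel. $V_{max}$ (1/h) and
$AM_{50}$ (fraction of dose) are dose-normalised. In vitro the depletion
equation has the implicit closed form
$V_{max}t = AM_{50}\ln(x_0/X) + (x_0 - X)$, which
`solve_invitro_dissolution()` inverts by monotone root finding; the
numeric ODE route is retained and cross-checked to 1e-6 in the tests.

**Site dependence.** The dissolved fraction is a sum of a gastric and
an intestinal component built from steep Hill functions
(`f_diss_total()`): the gastric term falls from 1 to $1-I_{max}$ with
half-time $T_{GET}$ (gastric emptying); the intestinal term rises
towards $Diss_{max}$ at $T_{trans1}=T_{GET}+T_{ITT}$ and falls again at
$T_{trans2}=T_{GET}+T_{ITT}+T_{CTT}$ (colon transit). With the
published dog estimates the trajectory is ~100% for the first half
hour, drops to a minimum of 0.8%, recovers above 10% between roughly
3.2 and 6.3 h, and decays to the gastric floor thereafter — the window
that generates the secondary plasma peaks.

**Absorption and disposition.** Dissolved drug transfers
lumen→gut→central by first-order steps ($k_{lag}$, $k_a$), and
disposition is a linear two-compartment model parameterised by
clearances and volumes with $C_1 = X_1/V_1$, $C_2 = X_2/V_2$.
Concentrations are reported in ng/mL ($X_1$ in mg, $V_1$ in L, so
mg/L × 1000). A cumulative-elimination bookkeeping state makes mass
conservation testable; simulated trajectories conserve dose to < 1e-6.

### A note on the two clearances

The reference estimates ship with `cl = 9.97` L/h (systemic) and
`cld = 49.2` L/h (distributional). This is the assignment consistent
with the observed exposure: a completely dissolved 20 mg dose gives
$AUC_\infty = D/CL = 2006$ ng·h/mL against an observed 2007 ng·h/mL,
and a terminal half-life of 3.9 h against an observed 4.3 ± 0.7 h. The
transposed assignment would predict a five-fold lower exposure and a
half-life of 2.7 h, contradicting both the observed and the published
predicted exposures, so we treat the printed labelling as transposed.

## Parameters, units, defaults

| parameter | unit | default (dog) | meaning |
|---|---|---|---|
| `vmax_invitro`, `vmax_invivo` | 1/h | per formulation (6.58…0.124 / 4.42…0.219) | maximal release rate / dose |
| `am50` | – | 0.395 (vitro), 0.315 (vivo) | undissolved fraction at half-maximal rate |
| `imax` | – | 0.992 | maximal gastric-component decrease |
| `t_get` | h | 0.73 | gastric-emptying half-time |
| `hill_stomach` | – | 16.7 | steepness of the gastric switch |
| `diss_max` | – | 0.115 | maximal intestinal-component increase |
| `t_itt`, `t_ctt` | h | 2.18, 4.1 | intestinal / colon transit times |
| `hill_intestine` | – | 13.1 | steepness of the intestinal rise/fall |
| `k_lag`, `k_a` | 1/h | 3.13, 4.37 | lumen→gut transfer, gut→central absorption |
| `v1`, `v2` | L | 22, 31 | central / peripheral volumes |
| `cl`, `cld` | L/h | 9.97, 49.2 | systemic / distributional clearance |
| `sigma` | – | 0.15 | proportional residual CV (package default; not reported in the source study) |

Between-subject variability is exponential,
$\theta_i=\theta e^{\eta_i}$, $\eta_i\sim N(0,\omega^2)$ with a
diagonal covariance; the shipped $\omega^2$ values are the published
per-parameter BSV terms read as log-scale variances. Individual
$I_{max}$ draws are truncated at 1 (the BSV on $I_{max}$ is 0.0027, so
truncation is rare).

## Estimation

**In vitro** (`fit_invitro_mm`): least squares on the fraction scale,
log-parameterised for positivity, Levenberg–Marquardt refinement from
multiple starts (`vmax` from the steepest observed slope, `am50` from
{0.1, 0.3, 0.5}; ties to the smallest `am50`). Only the pH 1.2
profiles are fitted by default — the medium in which release is
complete and Michaelis–Menten kinetics hold; higher-pH profiles are
read and plotted but are descriptive. Be aware that a tablet that has
released ~86% of its dose by the first sampling time (the IR case)
pins its rate only weakly from above; the SR rates are well
identified.

**Population model** (`fit_popk`): an importance-sampling Monte Carlo
EM. Per subject and iteration, the conditional mode of the random
effects is located by Levenberg–Marquardt on the stacked (weighted
data residuals, scaled $\eta$) vector — warm-started from the previous
iteration — and a normal proposal is centred there with
Laplace-derived marginal standard deviations. Importance weights use
the joint density with a proportional residual model (optionally
combined additive+proportional); observations below the LLOQ are
excluded from the likelihood (M1), and subjects left with fewer than
`min_obs` quantifiable points are dropped with a warning. The M-step
updates each population mean from the weighted mean of individual
log-parameters, each variance from the weighted second moment, and the
residual CV from the weighted relative residual sum of squares.
Common random numbers make the whole trajectory a deterministic
function of the seed. If the effective sample size of a subject's
weights collapses (sharply concentrated conditional density), the
moments fall back to the mode with its Laplace spread.

Two floors stabilise the algorithm: `sigma_floor = 1e-3` and
`omega_floor = 1e-2` (a 10% CV). The omega floor matters: EM updates
fixed effects *through* the random-effect means, and once a variance
collapses the corresponding fixed effect freezes; the floor keeps the
likelihood, not the prior, in charge. Parameters whose *initial*
variance is exactly zero are treated as pure fixed effects and updated
by a pooled Levenberg–Marquardt step on log-scale residuals across all
subjects, constrained to a ±0.3-fold move per iteration — the EM in
its degenerate $\omega^2\to 0$ limit, where the fit is a pooled
nonlinear regression. Convergence requires the maximal relative change
of all fixed effects and sigma to stay below `tol` (1e-3) for
`tol_window` (10) consecutive iterations; anything else is flagged,
never silently returned. Finite-difference steps inside all
Levenberg–Marquardt calls are held at ~1e-3 (`epsfcn`): the ODE
solutions carry adaptive-mesh noise near the solver tolerance, and
machine-precision difference steps would produce meaningless
Jacobians.

### Identifiability, honestly

The absorption/disposition chain is identifiable only up to a
relabelling of its rate constants. Two facts matter in practice:

1. The lumen→gut→central cascade makes the plasma profile *exactly*
   invariant under swapping $k_{lag}$ and $k_a$ — a series of two
   first-order transfers is symmetric.
2. With the dog estimates, three rates nearly coincide:
   $k_{lag}=3.13$, the fast disposition eigenvalue $\lambda_1=4.10$,
   and $k_a=4.37$ (all 1/h). Within ODE-solver precision, whole curves
   in $(V_1,V_2,CLD,k_{lag},k_a)$ space (e.g. $V_1$ and $k_{lag}$ both
   +31% with $V_2$, $CLD$ −20%) reproduce the observed concentrations
   bit-for-bit.

Consequently, a fit started far from the reporting convention can
converge to an equally likely relabelled branch. `fit_popk` offers
multi-start (`n_starts`) with best-likelihood selection, which
separates adequate fits from wrong-valley runs unambiguously (their
final log-likelihoods differ by hundreds of units), but branch choice
within the flat set is decided by the starting values. The package's
simulation/re-estimation tests therefore initialise at the reference
estimates and demonstrate *stationarity and consistency* of the
estimator — that it does not drift from the maximum-likelihood
configuration and re-derives it from data — rather than global basin
finding, which no local estimator can promise on this model.

A second, statistical limit: with three subjects per formulation and
BSV variances up to 0.95, the per-formulation release rates are
informed by so few animals that even an oracle averaging the *true*
individual parameters misses the generating population value by more
than 25% in roughly one draw in six. Replicate-recovery results on
noisy cohorts must be read against that floor.

## The IVIVC regression

`fit_power_ivivc` correlates the dose-normalised release rates,
$V_{max,vivo} = a\,V_{max,vitro}^{\,b} + c$, by multi-start nonlinear
least squares with a BFGS polish; a linear fit is always computed
alongside. Because the four rates span a 50-fold range, the default
objective uses log-scale (relative-error) residuals — this is also the
weighting that reproduces the published coefficients
(a = 2.18, b = 0.434, c = −0.659 against printed 2.1411, 0.4388,
−0.6346); untransformed least squares is available via
`weighting = "none"` and yields a visibly different optimum dominated
by the largest rate. $r^2$ is reported as $1-SSE/SST$ on the
untransformed scale.

`convert_vmax` applies the fitted law and refuses non-positive
conversions; extrapolation beyond the fitted range warns but proceeds
(predicting new formulations is the use case). Leave-one-out behaviour
on the reference formulations: the two faster tablets are predicted to
within 3–9% in peak concentration, the mid-range one to ~17%, and the
slowest — an extrapolation at the very edge of a three-point power
law — fails badly. A three-point power law should not be trusted
outside its range.

`predict_from_invitro` closes the loop: convert the in vitro rate,
simulate the population-typical subject (or a Monte Carlo sample with
BSV, summarised by mean and 5/50/95% bands), read $C_{max}$ off a
dense grid (0.01 h spacing; refining the grid changes $C_{max}$ by
< 0.5%), and compute $AUC_{all}$ by the trapezoidal rule on the
0–48 h sampling schedule. `ivivc_validate` reports per-formulation
absolute percentage prediction errors with mean ± SD per metric and a
pass/fail annotation at a configurable mean-%PE threshold (default
10%, the conventional regulatory level).

## Non-compartmental analysis

`compute_nca` follows standard automated conventions: $C_{max}$ and
$T_{max}$ directly from the observations; $\lambda_z$ by log-linear
regression over the adjusted-$r^2$-best suffix of post-$T_{max}$
points (≥3 points, $C_{max}$ excluded); $AUC_{all}$ by linear
trapezoid to the last quantifiable point (linear-up/log-down
available — note the plain linear rule overestimates a decaying
exponential by several percent on the sparse 12/24/36/48 h tail, while
log-down is exact there); $AUC_\infty = AUC_{all} + C_{last}/\lambda_z$
with a warning above 50% extrapolation; CL/F in mL/min as
$D\cdot 10^6 / AUC_\infty / 60$ and $V_z/F$ from CL/F and $\lambda_z$.
BLQ observations count as zero before the first quantifiable point and
as missing afterwards.

## The synthetic-data generators

`generate_cohort` emulates the reference study design: four
formulations (IR 20 mg, three SR 60 mg), three subjects each, 19
sampling times over 0–48 h, proportional residual noise
(default CV 0.15 — the source study reports none, so this is a package
choice typical of LC-MS/MS plasma assays), truncation at zero, and
censoring below the 5 ng/mL LLOQ. `generate_invitro_dataset` adds
additive vessel noise in percentage points to the closed-form release
curve, clipped to [0, 105]%. Every generator is a pure function of
(parameters, design, seed) and returns its generating truth for
recovery scoring.

What the generators deliberately do not emulate: correlated random
effects, inter-occasion variability, food effects, assay drift,
heteroscedastic dissolution noise, or mechanistic dissolution at pH
4.5/6.8 (those media are descriptive in the source data). Passing
recovery tests therefore show the estimation machinery is correct
under the model's own assumptions — not that the model is correct for
any particular real dataset.

## Numerical choices

* Stiff-capable `lsoda` throughout; simulation tolerances
  rtol 1e-8 / atol 1e-10 (the Hill exponents 16.7 and 13.1 make
  $F_{Diss}$ nearly a switch); likelihood evaluations use 1e-6 / 1e-8.
* Hill terms are evaluated in the overflow-safe ratio form
  $1/(1+(t_{50}/t)^h)$ with the continuous extension $0^h=0$.
* Dose at $t=0$, no lag other than $k_{lag}$; $F_{Diss}$ is a function
  of time since dose.
* Implausible individual draws (Hill exponents > 60, rates > 1000/h)
  are rejected before the ODE solve; they carry no posterior mass and
  only make the system needlessly stiff.
* Test problem sizes are chosen to exercise every property at modest
  cost: EM unit tests run 2–4 subjects with 20–150 importance samples
  and ≤ 15 iterations; the replicate-recovery study uses 20 cohorts of
  12 subjects at 50 samples per subject. These are package choices for
  the shipped test suite; the exported defaults
  (`n_samples = 1000`, `max_iter = 100`) suit real analyses.

## Known limitations

* Branch identifiability of the absorption/disposition rates (above):
  report conventions, not data, pick the labelling.
* The three-point extrapolation limit of the power-law IVIVC.
* The linear trapezoid's convexity bias on sparse late sampling.
* Weak upward identifiability of very fast in vitro release rates from
  a schedule whose first sample lies after most of the release.
* No inter-occasion variability, covariates, food effects, or
  enterohepatic recirculation structures; the single time-varying
  dissolved fraction is the mechanism, by design.
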