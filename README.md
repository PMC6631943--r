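# pkivivc

Population-PK-based in vitro–in vivo correlation (IVIVC) for oral
formulations whose dissolution depends on the gastrointestinal site.

Sildenafil-type BCS class II drugs dissolve freely at gastric pH,
barely at intestinal pH, and moderately again in the colon. For
sustained-release (SR) tablets this produces falling bioavailability
as release slows and secondary plasma peaks a few hours after dosing —
behaviour that defeats deconvolution-based IVIVC. This package
implements the model-based alternative: Michaelis–Menten tablet
release modulated by a time-varying dissolved fraction built from
steep Hill functions of transit time,

F<sub>Diss</sub>(t) = 1 − I<sub>max</sub>·t<sup>h<sub>s</sub></sup>/(T<sub>GET</sub><sup>h<sub>s</sub></sup>+t<sup>h<sub>s</sub></sup>)
 + Diss<sub>max</sub>·[t<sup>h<sub>i</sub></sup>/(T<sub>trans1</sub><sup>h<sub>i</sub></sup>+t<sup>h<sub>i</sub></sup>)]·[1 − t<sup>h<sub>i</sub></sup>/(T<sub>trans2</sub><sup>h<sub>i</sub></sup>+t<sup>h<sub>i</sub></sup>)],

dX<sub>tab</sub>/dt = −V<sub>max</sub>·X<sub>tab</sub>/(AM<sub>50</sub>+X<sub>tab</sub>)·F<sub>Diss</sub>(t),

coupled to first-order lumen→gut→central transfer and a linear
two-compartment disposition model (compiled ODE core under `src/`).
On top of the structural model the package provides:

* `fit_invitro_mm()` — Michaelis–Menten release parameters from vessel
  profiles (multi-start Levenberg–Marquardt, log-parameterised);
* `fit_popk()` — population estimation by importance-sampling Monte
  Carlo EM with exponential between-subject variability, all
  formulations fitted simultaneously, release rate per formulation;
* `compute_nca()` / `nca_table()` — non-compartmental exposure metrics
  (Cmax, Tmax, λz, t½, AUC, CL/F, Vz/F, relative bioavailability);
* `fit_power_ivivc()`, `convert_vmax()`, `predict_from_invitro()`,
  `ivivc_validate()` — the power-law rate correlation
  V<sub>max,vivo</sub> = a·V<sub>max,vitro</sub><sup>b</sup> + c,
  forward prediction of plasma exposure from dissolution data, and
  %PE validation;
* `generate_cohort()` / `generate_invitro_dataset()` — synthetic-data
  generators emulating the beagle-dog study design (4 formulations ×
  3 dogs, 19 samples over 48 h, LLOQ 5 ng/mL) with known truth for
  recovery testing;
* CSV/JSON/YAML readers and writers for all of the above.

The published dog estimates ship as `sildenafil_popk_model()`,
`sildenafil_invitro_params()` and `sildenafil_observed_exposure()`.

## Worked example

```r
library(pkivivc)
pop   <- sildenafil_popk_model()
ivp   <- sildenafil_invitro_params()
ivivc <- fit_power_ivivc(ivp$vmax,
                         coef(pop)[paste0("vmax_invivo:", names(ivp$vmax))],
                         labels = names(ivp$vmax))
ivivc
#> IVIVC regression of dose-normalised release rates
#>   power : Vmax_invivo = 2.1776 * Vmax_invitro^0.4338 -0.6592   (r2 = 0.9955)
#>   linear: intercept 0.4977, slope 0.6073                (r2 = 0.9744)

preds <- lapply(names(ivp$vmax), function(fid)
  predict_from_invitro(ivivc, pop,
                       invitro_release_params(ivp$vmax[[fid]], ivp$am50),
                       fid, mode = "typical"))
preds[[1]]
#> IVIVC prediction (IR, 20 mg, typical mode): Cmax 350.9 ng/mL, AUC_all 2106.5 ng.h/mL
#>   Vmax in vitro 6.58 -> in vivo 4.272 1/h

ivivc_validate(sildenafil_observed_exposure(), preds)
#> IVIVC prediction-error report
#>  formulation_id cmax_obs cmax_pred cmax_pe auc_obs auc_pred auc_pe
#>              IR    366.5     350.9     4.3    1913     2106   10.1
#>         SR_fast    831.0     849.0     2.2    5885     6341    7.8
#>       SR_medium    410.3     398.8     2.8    4221     4618    9.4
#>         SR_slow    124.9     125.6     0.6    1009     1591   57.7
#>   mean %PE: Cmax 2.5 +/- 1.5, AUC 21.2 +/- 24.3  [FAIL at 10% threshold]
```

Reading the output: the fitted power law converts each formulation's
in vitro release rate into an in vivo one; simulating the
population-typical subject then predicts every peak concentration to
within 5% of the observed means. The AUC column is harder: the
typical-subject simulation keeps dissolving at the 0.8% gastric floor
out to 48 h, which overshoots the slowest tablet's observed exposure —
a genuine property of extrapolating the slowest release to late times,
discussed in the methods vignette alongside the dissolved-fraction
trajectory itself:

```r
s <- fdiss_profile_summary(fdiss_params(0.992, 0.73, 16.7, 0.115,
                                        2.18, 4.1, 13.1))
#> F_Diss minimum 0.8%, >10% window 3.2-6.3 h
```

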