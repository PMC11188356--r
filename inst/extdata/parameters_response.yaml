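# Clinical response model: published final point estimates for drug effects,
# the shared JAK-inhibitor onset rate, and covariate coefficients. The
# restricted-cubic-spline placebo coefficients are a package calibration
# (the source prints no spline coefficients); they reproduce a typical
# placebo response time-course rising to ~43% by week 12 with a slow
# decline thereafter. See the methods vignette.
endpoint: response
placebo:
  form: rcs
  knots: [2.0, 6.0, 16.0]
  coeffs: [-2.894730, 0.348752, -0.435631]
drugs:
  infliximab:   {drug: infliximab,   dose_model: emax_flat, Emax: 1.03}
  adalimumab:   {drug: adalimumab,   dose_model: emax_flat, Emax: 0.704}
  golimumab:    {drug: golimumab,    dose_model: emax_flat, Emax: 0.616}
  vedolizumab:  {drug: vedolizumab,  dose_model: emax_flat, Emax: 1.15}
  etrolizumab:  {drug: etrolizumab,  dose_model: emax_flat, Emax: 0.661}
  ustekinumab:  {drug: ustekinumab,  dose_model: emax_flat, Emax: 1.30}
  mirikizumab:  {drug: mirikizumab,  dose_model: emax_flat, Emax: 1.27}
  tofacitinib:  {drug: tofacitinib,  dose_model: emax_flat, Emax: 1.88, onset: jak}
  upadacitinib: {drug: upadacitinib, dose_model: emax_flat, Emax: 0.234, onset: jak,
                 regimen_overrides: {45mg: 2.90}}
  filgotinib:   {drug: filgotinib,   dose_model: linear, slope: 6.87e-3, onset: jak}
  ozanimod:     {drug: ozanimod,     dose_model: emax_flat, Emax: 0.428}
  etrasimod:    {drug: etrasimod,    dose_model: linear, slope: 0.544}
onset_rates:
  jak: 0.103
covariate_effects:
  - {covariate: prior_tnf_pct, target: placebo, form: additive, theta: -2.90e-3,
     cov_mean: 22.4}
  - {covariate: duration, target: drug, form: power, theta: -0.829, cov_mean: 7.53,
     dose_models: [emax_flat, emax]}
  - {covariate: age, target: drug, form: additive, theta: -2.31e-3, cov_mean: 41.2,
     dose_models: [emax_flat, emax]}
  - {covariate: steroid_pct, target: drug, form: power, theta: -0.759, cov_mean: 46.0,
     dose_models: [emax_flat, emax]}
omega2: 0.09
sigma: 1.0
autocorr: none
rho: 0.0
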