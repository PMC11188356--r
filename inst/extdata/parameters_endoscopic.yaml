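# Endoscopic improvement model: published final point estimates; spline
# placebo coefficients are a package calibration reproducing a typical
# endoscopic placebo time-course peaking near 24% (methods vignette).
endpoint: endoscopic
placebo:
  form: rcs
  knots: [2.0, 6.0, 16.0]
  coeffs: [-3.31732, 0.282894, -0.351094]
drugs:
  infliximab:   {drug: infliximab,   dose_model: emax_flat, Emax: 1.22}
  adalimumab:   {drug: adalimumab,   dose_model: emax_flat, Emax: 0.586}
  golimumab:    {drug: golimumab,    dose_model: emax_flat, Emax: 1.12}
  vedolizumab:  {drug: vedolizumab,  dose_model: emax_flat, Emax: 1.18}
  etrolizumab:  {drug: etrolizumab,  dose_model: emax_flat, Emax: 0.715}
  ustekinumab:  {drug: ustekinumab,  dose_model: emax_flat, Emax: 0.751}
  mirikizumab:  {drug: mirikizumab,  dose_model: emax_flat, Emax: 0.763}
  tofacitinib:  {drug: tofacitinib,  dose_model: emax_flat, Emax: 0.732}
  upadacitinib: {drug: upadacitinib, dose_model: linear, slope: 3.18e-2}
  filgotinib:   {drug: filgotinib,   dose_model: emax_flat, Emax: 0.721}
  ozanimod:     {drug: ozanimod,     dose_model: emax_flat, Emax: 0.348}
  etrasimod:    {drug: etrasimod,    dose_model: linear, slope: 0.442}
onset_rates: {}
covariate_effects:
  - {covariate: duration, target: placebo, form: power, theta: -1.24, cov_mean: 7.53}
  - {covariate: duration, target: drug, form: additive, theta: -5.38e-4, cov_mean: 7.53,
     dose_models: [emax_flat, emax]}
  - {covariate: prior_tnf_pct, target: drug, form: additive, theta: -2.85e-2,
     cov_mean: 22.4, dose_models: [emax_flat, emax]}
omega2: 0.09
sigma: 1.0
autocorr: none
rho: 0.0
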