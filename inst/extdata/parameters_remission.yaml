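# Clinical remission model: published final point estimates.
# omega2 / sigma are package calibration choices (see methods vignette).
endpoint: remission
placebo:
  form: exponential
  B: -39.26
  A: 37.04
  k_pbo: 0.66
drugs:
  infliximab:   {drug: infliximab,   dose_model: emax_flat, Emax: 1.48}
  adalimumab:   {drug: adalimumab,   dose_model: emax_flat, Emax: 0.864, onset: adalimumab}
  golimumab:    {drug: golimumab,    dose_model: emax_flat, Emax: 1.35}
  vedolizumab:  {drug: vedolizumab,  dose_model: emax_flat, Emax: 1.24}
  etrolizumab:  {drug: etrolizumab,  dose_model: emax_flat, Emax: 0.859}
  ustekinumab:  {drug: ustekinumab,  dose_model: emax_flat, Emax: 0.864}
  mirikizumab:  {drug: mirikizumab,  dose_model: emax_flat, Emax: 1.06}
  tofacitinib:  {drug: tofacitinib,  dose_model: emax_flat, Emax: 1.15}
  upadacitinib: {drug: upadacitinib, dose_model: emax_flat, Emax: 1.35}
  filgotinib:   {drug: filgotinib,   dose_model: emax_flat, Emax: 1.54, onset: filgotinib}
  ozanimod:     {drug: ozanimod,     dose_model: emax_flat, Emax: 0.934, onset: ozanimod}
onset_rates:
  adalimumab: 0.198
  filgotinib: 0.0476
  ozanimod: 0.0978
covariate_effects:
  - {covariate: duration, target: placebo, form: additive, theta: 0.695, cov_mean: 7.53}
  - {covariate: duration, target: drug, form: additive, theta: 0.589, cov_mean: 7.53,
     dose_models: [emax_flat, emax]}
omega2: 0.09
sigma: 1.0
autocorr: none
rho: 0.0
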