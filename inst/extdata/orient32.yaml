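# Model inputs for first-line sintilimab + IBI305 vs sorafenib in
# unresectable HCC (Chinese payer perspective, 2021 USD, CNY 6.34/USD).
# Monetary values are per 21-day cycle unless noted; low/high bound the
# 95% interval used for sensitivity analyses.
model:
  cycle_days: 21
  horizon_years: 10
  discount_annual: 0.05
  half_cycle: true
  wtp: 38334.0
survival: # fitted extrapolation curves, time in months
  sintilimab_ibi305:
    os: {family: lognormal, meanlog: 2.763, sdlog: 0.971}
    pfs: {family: lognormal, meanlog: 1.60, sdlog: 1.03}
  sorafenib:
    os: {family: loglogistic, shape: 1.68, scale: 10.57}
    pfs: {family: lognormal, meanlog: 1.115, sdlog: 0.781}
costs:
  sintilimab: {base: 340.848, low: 272.848, high: 408.848}
  sintilimab_medicare: {base: 119.2968, low: 102.2544, high: 136.3392}
  ibi305: {base: 1644.5916, low: 1315.5916, high: 1973.5916}
  sorafenib: {base: 1259.244, low: 1007.244, high: 1511.244}
  sorafenib_medicare: {base: 629.622, low: 539.676, high: 719.568}
  regorafenib: {base: 800.2827, low: 685.9566, high: 914.6088}
  followup: {base: 59.2, low: 47.36, high: 71.04}
  laboratory: {base: 157.5, low: 126.0, high: 189.0}
  administration: {base: 69.81, low: 55.85, high: 83.77}
utilities:
  sd: {base: 0.76, low: 0.608, high: 0.912}
  pd: {base: 0.68, low: 0.544, high: 0.816}
subsequent_treatment:
  # second-line regorafenib (insured price) charged to the whole
  # progressed-state occupancy of both arms; trial-reported uptake was
  # 0.29 (sintilimab + IBI305) and 0.47 (sorafenib) for scenario use
  sintilimab_ibi305: 1.0
  sorafenib: 1.0
adverse_events: # grade 3-4, one-time expected cost / QALY decrement
  costs:
    ppe: {base: 16.63, low: 13.30, high: 19.95}
    platelet: {base: 332.15, low: 265.72, high: 398.58}
    hypertension: {base: 155.56, low: 124.45, high: 186.68}
  disutilities:
    ppe: {base: -0.15, low: -0.18, high: -0.12}
    platelet: {base: -0.146, low: -0.175, high: -0.117}
    hypertension: {base: -0.016, low: -0.019, high: -0.013}
  incidence:
    sintilimab_ibi305:
      hypertension: {base: 0.14, low: 0.112, high: 0.168}
      platelet: {base: 0.08, low: 0.064, high: 0.096}
    sorafenib:
      ppe: {base: 0.12, low: 0.096, high: 0.144}
      hypertension: {base: 0.06, low: 0.048, high: 0.072}
      platelet: {base: 0.03, low: 0.024, high: 0.036}
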