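# Default trajectory presets: five qualitative mortality shapes (M1-M5)
# and five fecundity shapes (F1-F5). Parameter values are fixed package
# defaults chosen to span the qualitative shapes observed in wild
# vertebrates: senescent exponential increase, bathtub, near-constant,
# decelerating-plateau, and declining mortality; flat, increasing,
# declining, early-hump and late-hump fecundity. Maturity is at age 2 for
# every fecundity shape; fecundity levels are nominal because calibration
# rescales them.
mortality:
  M1:
    family: gompertz
    params: {a: 0.05, b: 0.15}
  M2:
    family: siler_bathtub
    params: {a1: 0.4, b1: 0.8, c: 0.03, a2: 0.015, b2: 0.25}
  M3:
    family: constant
    params: {c: 0.22}
  M4:
    family: logistic
    params: {a: 0.15, b: 0.35, s: 1.2}
  M5:
    family: weibull3
    params: {a: 0.45, l: 0.4, c: 0.18}
fecundity:
  F1:
    shape: F1_flat
    params: {level: 1.0}
    maturity: 2
  F2:
    shape: F2_increasing
    params: {level: 1.0, rate: 0.25}
    maturity: 2
  F3:
    shape: F3_declining
    params: {level: 1.0, rate: 0.12}
    maturity: 2
  F4:
    shape: F4_hump_early
    params: {level: 1.0, peak: 5.0, width: 3.0}
    maturity: 2
  F5:
    shape: F5_hump_late
    params: {level: 1.0, peak: 14.0, width: 4.0}
    maturity: 2
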