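# placentadr

Combined diffusion-relaxation MRI analysis of the placenta, for
quantitative-MRI researchers studying pregnancies at risk of extreme
preterm birth. The package implements the full analysis chain around a
multi-echo multi-b acquisition — 60 diffusion preparations over
b = 5–1600 s/mm² at echo times 78/114/150/186 ms — together with a
synthetic phantom and cohort generator, so every stage is testable
without patient data.

Two voxel-wise signal models sit at the core, both referenced to the
shortest echo time TE_min:

* **T2\*-ADC:**
  S(TE, b) = S₀ · exp(−(TE − TE_min)/T₂\*) · exp(−b·ADC)
* **T2\*-IVIM (two compartments):**
  S(TE, b) = S₀ [ f · exp(−(TE − TE_min)/T₂\*_fast) · exp(−b·D\*) +
  (1 − f) · exp(−(TE − TE_min)/T₂\*_slow) · exp(−b·ADC) ]

with the perfusion fraction f attached to the fast (perfusing)
compartment (labelled so D\* > ADC), plus fractional anisotropy from a
single-tensor fit at the first echo time. Around the fits: a
supraphysiological T2\* exclusion (> 200 ms) before region averaging,
and the cohort statistics of a preterm-birth case-control design —
gestational-age trends among controls, GA-adjusted case contrasts with
membrane-status subgroups, and a standardised latency-ratio split
(time-to-delivery vs time-since-symptoms) among cases.

## Worked example

Fit the two-compartment model to one noisy voxel acquired on the full
protocol, then run cohort statistics on a simulated study:

```r
library(placentadr)

s <- build_paper_scheme()               # 240 measurements, TE_min = 78 ms
truth <- ivim_params(100, 0.25, 80, 50, 0.05, 2e-3)
y <- add_noise(signal_ivim(truth, s), 3.3, "rician", seed = 42)
fit_ivim(y, s)
#> <ivim fit> converged: TRUE, residual norm 47.06 (9 iterations)
#>           s0            f t2_star_fast t2_star_slow       d_star          adc
#> 1.009044e+02 2.422920e-01 1.055205e+02 4.769975e+01 5.233242e-02 2.091813e-03

co <- make_cohort(seed = 1)             # 23 cases (14 ruptured), 52 controls
group_contrast(co, "t2_star")
#> <regression> t2_star: all_cases vs controls (GA-adjusted)
#>   case = -12.24 (SE 1.23), p = 4.129e-15, n = 75
ga_trend(co, "t2_star")
#> <regression> t2_star: GA-at-MRI trend among controls
#>   ga_mri = -2.54 (SE 0.135), p = 2.556e-24, n = 52
```

The single-voxel fit recovers the generating parameters (f = 0.24 vs
0.25, T₂\*_slow = 47.7 ms vs 50) with the fast compartment, as always,
the least certain. The cohort calls recover the structure the generator
injects: T2\* is reduced in women who go on to deliver preterm
(−12.2 ms case effect) and declines by ≈ 2.5 ms/week of gestation among
controls. `run_end_to_end(pipeline_config(...))` runs the same chain
through the full imaging path (phantom → 4D signal → voxel-wise fits →
thresholding → ROI table → statistics) and writes TSV tables plus a
reproducibility manifest.

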