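# petkin

Quantification of reversible PET radioligand brain kinetics from arterial
input, built around the SV2A (synaptic density) tracer [18F]UCB-H but
applicable to any reversible tracer quantified the same way.

Given regional time–activity curves (TACs) and serial arterial blood data,
the package:

* builds the **metabolite-corrected arterial input function**: a constrained
  biexponential `pf(t) = A1 e^(-λ1 t) + (1-A1) e^(-λ2 t)` (with `pf(0) = 1`)
  is fitted to measured intact-parent fractions and multiplied pointwise
  into the plasma activity curve;
* fits **one- and two-tissue compartment models** by weighted nonlinear
  least squares — including the coupled variant (2TCM-c) that shares one
  non-displaceable distribution volume `V_ND = K1/k2` across all regions —
  reporting micro-parameters `K1, k2, k3, k4`, macro-parameters
  `V_T = V_ND (1 + k3/k4)`, `BP_ND = k3/k4`, delta-method standard errors,
  AIC, and a reliability flag (`%SE(V_T) < 25`);
* estimates `V_T` by **Logan graphical analysis** (fixed `t* = 60` min) and
  **MA1**;
* computes **test–retest statistics**: absolute test–retest variability
  `aTRV = 100 |test − retest| / mean(test, retest)` and the two-way
  mixed-effects single-measure ICC (absolute agreement by default);
* analyses **displacement studies**: SUV conversion, normalisation to the
  pre-drug frame, pointwise baseline averaging, percent displacement
  `100 (B − D)/B`, and occupancy arithmetic (`occ = C/(C + K_D)`,
  `BP_ND = f/(1−f)`, observed/maximal scaling);
* generates **complete synthetic studies** (blood tables, parent fractions,
  test/retest TACs, displacement arms) from known ground truth, so every
  stage of the analysis is testable without any scan data.

## Worked example

Generate a noiseless synthetic study at the default conditions (seven
regions sharing `V_ND = 7.89` mL/cm³, grey-matter `K1` averaging 0.37
mL/cm³/min, region `k3/k4` averaging 1.07) and recover the truth:

```r
library(petkin)

cfg   <- study_config(noise_scale = 0)
blood <- make_input_function(cfg, subject = 1, seed = 1)
pf    <- fit_parent_fraction(blood$pf_samples$time_min,
                             blood$pf_samples$parent_fraction)
pf
#> Biexponential parent-fraction model: pf(t) = 0.800 exp(-0.1000 t) + 0.200 exp(-0.0095 t)
#>   RSS = 0, converged = TRUE

input <- build_mcaif(blood$blood, pf)
tacs  <- make_tacs(cfg, input, "test", seed = 1, include_whole_brain = FALSE)
fit_coupled(tacs, input)
#> Coupled 2TCM fit: 7 regions, shared VND = 7.890 (SE 0.000)
#>   striatum         K1=0.400 k3/k4=1.16 VT=17.04
#>   thalamus         K1=0.390 k3/k4=1.03 VT=16.02
#>   cerebellum       K1=0.370 k3/k4=1.24 VT=17.67
#>   white_matter     K1=0.250 k3/k4=0.73 VT=13.65
#>   frontal_cortex   K1=0.360 k3/k4=1.25 VT=17.75
#>   temporal_cortex  K1=0.350 k3/k4=1 VT=15.78
#>   parietal_cortex  K1=0.350 k3/k4=1.08 VT=16.41

logan_fit(tacs$striatum, input)
#> LOGAN fit, region 'striatum': VT = 16.981 mL/cm^3 (t* = 60 min, 6 points, r^2 = 1.0000)
```

The coupled fit returns the generating truth exactly: the shared `V_ND` is
7.89 mL/cm³, each region's `k3/k4` matches its configured value (mean 1.07),
and striatal `V_T = 7.89 × (1 + 1.16) = 17.04` mL/cm³. The Logan slope for
the same region is 16.98 — about 0.4% below the compartmental value, the
expected small linearisation bias at `t* = 60` min.

Higher-level drivers: `make_study()` builds a multi-subject test–retest
study, `run_quantification()` runs every method and returns the long
estimates table plus per-region aTRV/ICC summaries (with the %SE < 25
filter applied), and `run_displacement()` handles displacement arms. A thin
command-line wrapper with `simulate` / `fit` / `logan` / `reliability` /
`displace` subcommands is installed at `inst/cli/petkin.R`.

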