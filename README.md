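# ECSmorph

Quantitative analysis of cell-volume dynamics in nervous tissue, for
electrophysiologists and imaging labs studying how astrocytes and the
extracellular space (ECS) respond to potassium challenges, ischemia-like
insults or disease models. The package implements the two standard assays
end to end, together with seeded synthetic generators that provide ground
truth for validation.

## The two assays

**Real-time iontophoresis (RTI).** A micropipette releases the
membrane-impermeant probe TMA⁺ at rate *Q = I·n/(zF)* during a current
step (standard protocol: 200 nA for 24 s on a continuously applied 20 nA
bias). An ion-selective microelectrode (ISM) 50–100 μm away records the
concentration transient, which in tissue follows the point-source solution
of the modified diffusion equation

```
∂C/∂t = (D/λ²) ∇²C + (Q/α) δ(r) − k′C

C(r,t) = (Q λ²)/(8π D α r) · [ e^{rλ√(k′/D)} erfc( rλ/(2√(Dt)) + √(k′t) )
                             + e^{−rλ√(k′/D)} erfc( rλ/(2√(Dt)) − √(k′t) ) ]
```

where α is the ECS volume fraction, λ the tortuosity and k′ the
non-specific uptake rate. ISM voltages map to concentrations through the
Nikolski (Nicolsky–Eisenman) equation *V = v₀ + s·log₁₀(c + cᵢ)*, whose
constants are fitted from a five-solution calibration series
(`fitCalibration`). A curve recorded in dilute agar (a free medium:
α = 1, λ = 1, k′ = 0) determines the electrode constants *n* and *D*
(`fitAgar`); the tissue curve is then fitted for (α, λ, k′) by a
Nelder–Mead simplex (`fitTissue`). The closed form is cross-validated
against an independent radial finite-difference solver
(`solveRadialDiffusionFD`).

**3D confocal morphometry.** Fluorescent-astrocyte z-stacks (voxel
0.41 × 0.41 × 0.5 μm) acquired over a potassium challenge are reduced by
average-intensity projection, registered by subpixel translation,
photobleach-corrected by a linear fit over the baseline stacks, and
segmented with the Isodata intermeans threshold. The soma area Ss of the
seeded connected component converts to a normalized volume time course via
the isotropic-scaling law *Vs ∝ Ss^{3/2}*, expressed as percent of the
volume at t = 0 (`analyzeCellSeries`).

## Worked example

Simulate a tissue recording at the standard protocol and recover its
parameters:

```r
library(ECSmorph)

cal <- IsmCalibration(v0 = 10, slope = 58)
cfg <- curveSimConfig(noise_sigma_rel = 0.02, seed = 42)  # alpha=0.19, lambda=1.6
sim <- simulateDiffusionTrace(cfg, cal)
curve <- preprocessCurve(sim$voltage_mV, sim$times_s, cal, cfg$source)
fit <- fitTissue(curve, n_transport = 0.3, D = 1.2e-5)
fit
#> FitResult (converged): SSE = 0.4769 (mM)^2, 664 evaluations
#> DiffusionParams:
#>   alpha = 0.1901, lambda = 1.603, k' = 0.005177 1/s
#>   D = 1.2e-05 cm^2/s, transport number n = 0.3
```

The fitted α = 0.1901 and λ = 1.603 recover the generating values
(0.19, 1.6) to within 0.2 % under 2 % multiplicative electrode noise; k′ is the
hardest parameter and typically scatters a few percent.

The morphometry side, on a synthetic astrocyte whose soma swells to 340 %
and recovers:

```r
sim <- simulateCellSeries(cellSimConfig(
  volume_profile_pct = c(100, 100, 190, 340, 100),
  timepoints_min     = c(-5, 0, 10, 20, 60),
  n_baseline = 2, seed = 14))
vt <- analyzeCellSeries(sim$its, seed_point = round(sim$center_px[2, ]))
round(volPercent(vt), 1)
#> [1]  98.1 100.0 186.0 342.4  98.8
```

Group summaries and the percent-change reports used for ECS data:

```r
percentDrop(0.193, 0.130, rounded = TRUE)  # 33 (% drop of alpha)
washoutRecovery(0.193, 0.130, 0.189)       # 93.7% of the deficit recovered
```

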