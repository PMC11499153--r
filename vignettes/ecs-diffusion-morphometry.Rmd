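---
title: "Measuring extracellular-space diffusion parameters and astrocyte volume dynamics"
author: "ECSmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring extracellular-space diffusion parameters and astrocyte volume dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ECSmorph)
```

ECSmorph implements the two quantitative assays used to study
potassium-evoked cell swelling in nervous tissue: real-time iontophoresis
(RTI), which measures the diffusion properties of the extracellular space
(ECS), and 3D confocal morphometry, which tracks the volume of individual
fluorescent astrocytes. This vignette documents the models, the
parameters that matter, the numerical choices, what the synthetic
generators emulate, and the limits of what the validation shows.

## The RTI forward model

The tracer TMA⁺ is released from an iontophoretic micropipette treated as
an ideal point source; its molar release rate is $Q = I\,n/(zF)$ with $I$
the effective current, $n$ the electrode transport number (the fraction
of current carried by TMA⁺), $z = 1$ and $F$ the Faraday constant. A 20 nA
bias current runs continuously to keep $n$ stable, so the recorded
baseline already contains the bias's equilibrated contribution; by linear
superposition the step response is driven by $I = i_{step} - i_{bias}$
(180 nA at the standard 200/20 nA protocol). This bias convention is a
design choice of the package; the alternative — using the full step
current — is available via `use_step_only = FALSE` in `sourceRate()`.

In an isotropic porous medium with volume fraction $\alpha$, tortuosity
$\lambda$ (apparent diffusivity $D^\ast = D/\lambda^2$) and first-order
non-specific uptake $k'$, the ECS concentration obeys

$$\frac{\partial C}{\partial t} = D^\ast \nabla^2 C +
  \frac{Q}{\alpha}\,\delta(\mathbf r) - k' C,$$

whose point-source step response is

$$C(r,t) = \frac{Q\lambda^2}{8\pi D\alpha r}\left[
  e^{r\lambda\sqrt{k'/D}}\,\mathrm{erfc}\!\left(\frac{r\lambda}{2\sqrt{Dt}}
  + \sqrt{k't}\right) +
  e^{-r\lambda\sqrt{k'/D}}\,\mathrm{erfc}\!\left(\frac{r\lambda}{2\sqrt{Dt}}
  - \sqrt{k't}\right)\right].$$

With $\alpha = \lambda = 1$, $k' = 0$ this reduces to the free-medium
solution $Q/(4\pi Dr)\,\mathrm{erfc}(r/2\sqrt{Dt})$ — the regime of the
dilute-agar calibration. The pulse response is the on-response minus the
same response delayed by the pulse duration (superposition), plus the
0.1 mM TMA⁺ background.

**Overflow control.** $e^{r\lambda\sqrt{k'/D}}$ can exceed $10^{300}$ in
admissible regimes, so each $e^b\,\mathrm{erfc}(x)$ product is evaluated
through the scaled complementary error function
$\mathrm{erfcx}(x) = e^{x^2}\mathrm{erfc}(x)$; with
$a = r\lambda/2\sqrt{Dt}$, $s = \sqrt{k't}$ one has $b = 2as$, so every
remaining exponent is $-(a^2 + s^2) \le 0$ and the evaluation can neither
overflow nor return non-finite values. `pracma::erfcx` itself degrades
past $x \approx 26$, so the implementation switches to the four-term
asymptotic series beyond $x = 20$, where the series is already accurate
to ~1e-11.

**Units.** All internals run in cm, s, mol/cm³ and A — the units in which
$D$ (cm²/s) is conventionally reported. Constructors and curves take μm,
nA and mM, and the converters (`umToCm()`, `mMToMolPerCm3()`, ...) are
exported because mixed units are the dominant failure mode in this
analysis. $r < 1\,\mu m$ is rejected as unphysical for a 50–100 μm
electrode array. $C(\cdot, 0) = 0$ by convention.

**Independent cross-check.** `solveRadialDiffusionFD()` integrates the
same PDE on a logarithmically graded spherical finite-volume grid
(400 cells to 1000 μm, source deposited in the innermost shell,
`deSolve::lsoda` with a banded Jacobian). It shares no code with the
closed form and agrees with it to ≲0.3% at $t \ge 1$ s over the admissible
parameter ranges; the residual discrepancy is the FD discretisation
error, largest at early times when the front is steep.

## ISM calibration

ISM voltages follow the Nicolsky–Eisenman ("Nikolski") form
$V = v_0 + s\,\log_{10}(c + c_i)$, with the interfering ions lumped into
one equivalent concentration $c_i$ — the parameterization matching the
"slope and interference" constants reported per electrode. The
calibration fit (`fitCalibration`) is a bounded Levenberg–Marquardt
nonlinear least squares (`minpack.lm`) on the standard five-solution
series (0.1, 0.3, 1, 3, 10 mM); $v_0$ and $s$ start from a log-linear fit
of the top three concentrations, where the interference term is
negligible, and $c_i$ starts at 0 with a lower bound of 0 — interference
only bends the low end of the curve, which makes this initialization
reliable. The pipeline assumes voltages are already referenced
differentially against the reference barrel. The inverse map clips
negative concentrations at zero; temperature-dependent Nernst slopes and
per-ion selectivity coefficients are out of scope.

## Inverse fitting

`fitAgar()` fits $(n, D)$ with the free-medium model; `fitTissue()` holds
$(n, D)$ at the agar values and fits $(\alpha, \lambda, k')$. Both use
the Nelder–Mead simplex, the standard optimizer for this analysis, on
SSE in (mM)²:

* bounds $\alpha \in (0.01, 1]$, $\lambda \in [1, 3]$,
  $k' \in [0, 0.1]\,s^{-1}$, enforced by logistic transforms (so the
  optimizer itself is unconstrained); a fit ending within 1e-3 of a bound
  (scaled by the bound range) is flagged *bound-constrained*, not failed;
* starting values $\alpha = 0.2$, $\lambda = 1.5$,
  $k' = 3\times10^{-3}\,s^{-1}$ — the physiological grey-matter regime —
  with two additional deterministically perturbed restarts, followed by
  polish passes until a refit improves SSE by less than 1e-6 relative
  (this makes the reported optimum idempotent by construction);
* SSE tolerance 1e-10, at most 5000 iterations per pass;
* the fitted window runs from pulse onset to pulse end plus two pulse
  durations of decay; the pre-pulse window only defines the baseline
  (median of pre-pulse concentration), which is subtracted before
  residuals are formed;
* a curve whose increment never exceeds 1e-4 mM carries no usable signal
  and is returned with `converged = FALSE`.

Whether $D$ should be refit in tissue was left open by the protocol's
description; the two-step workflow ("knowing $n$ and $D$...") implies it
is held fixed, which is the default here, with `fit_D = TRUE` available.
An onset-time nuisance offset (`fit_t0`) is likewise available for
recordings whose trigger and pulse are imperfectly aligned; it defaults
to off because the synthetic protocol has exact onsets.

On noiseless synthetic curves all parameters are recovered to ~1e-10
relative; under 2% multiplicative noise the median errors of
$\hat\alpha$, $\hat\lambda$ over 100 replicates are ~0.1–0.2%, and using
$(\hat n, \hat D)$ from a noisy agar fit propagates a comparable relative
error into $\hat\alpha$ (the two enter the prefactor together).

## Morphometry

The measurement chain mirrors the standard Fiji workflow: average
intensity projection along z; translation-only registration to the first
frame; linear photobleach correction; Isodata segmentation; soma area →
volume.

* **Registration** estimates each frame's shift by the integer FFT
  cross-correlation peak refined by Nelder–Mead on the windowed
  (Hann) squared difference under exact Fourier shifting; both frames are
  variance-normalized first so intensity decay cannot bias the optimum.
  Aligned frames are produced by bilinear resampling. Translation
  suffices for stage drift; rotation is out of scope. Integer shifts are
  recovered to ~1e-5 px and half-pixel shifts to ~1e-6 px on smooth
  scenes; the stated tolerances (0.1 / 0.2 px) are far above this.
* **Bleach correction** fits a straight line to total frame intensity
  over the baseline acquisitions (a static scene by design, which
  decouples bleaching from swelling — the reason total intensity is used
  rather than ROI intensity) and divides every frame by the line's
  relative prediction, extrapolated past the baseline. An increasing
  baseline cannot be bleaching: factors are capped at 1 with a warning.
  Factors are floored at 0.05 to keep a pathological extrapolation from
  dividing by ~0.
* **Isodata** iterates the intermeans map on a 256-bin histogram of the
  frame's min–max range: the threshold is the fixed point
  $T = (\mu_{\le T} + \mu_{>T})/2$, the split index moves by
  round-half-up in bin units, convergence is movement < 0.5 bin, and a
  period-2 cycle resolves to the split nearer its own image. Histogram
  and pixel-iterative Isodata variants agree on this fixed-point
  definition, which is what the tests pin down against exhaustive search
  over all 255 candidate splits.
* **Soma area.** Segmentation runs on the average projection (not
  per-slice), and the soma is the 8-connected supra-threshold component
  containing a user-supplied seed point; $S_s$ = pixel count × pixel
  area. Volume follows the isotropic-scaling law
  $V_s \propto S_s^{3/2}$, normalized to 100% at the reference timepoint
  (the last baseline stack, $t = 0$). The assay tracks the *soma*; the
  processes' contribution to total cell volume is not measured, and the
  2 μm circular ROI intensity is reported alongside as the traditional
  intensity-based proxy.

## Synthetic generators

`simulateDiffusionTrace()` evaluates the pulse model at the protocol
constants (200 nA / 24 s on 20 nA bias, 0.1 mM background, 100 μm
separation, $\alpha = 0.19$, $\lambda = 1.6$,
$k' = 5\times10^{-3}\,s^{-1}$, 10 Hz sampling — the grey-matter regime),
applies multiplicative Gaussian noise to the concentration (electrode
noise scales with signal), voltage-encodes through the Nikolski function
and adds optional linear drift. `simulateCellSeries()` renders an
ellipsoidal soma (default semi-axes 6 × 5 × 4 μm) with tapering
processes at 4× laterally supersampled resolution, block-averaged back to
the 0.41 × 0.41 × 0.5 μm voxel grid; the cell is scaled isotropically to
follow a programmed volume profile (default: three baseline stacks, a
swell to 340% across four 5-min acquisitions — the upper range evoked by
a 50 mM K⁺ challenge — and washout recovery at +20/+40 min), with linear
per-stack bleaching (2%/stack default), lateral drift and
Poisson–Gaussian noise (shot-noise gain $snr^2$, so relative noise at
unit intensity is $1/snr$). Process intensity (0.25) is deliberately
below the soma's (1.0) as in real projections, which is also what keeps
the Isodata threshold between processes and soma so the segmented
component is the soma.

Every generator is deterministic under its seed and returns its ground
truth. The phantom validates itself: its supra-half-maximum voxel count
tracks the programmed volume factor within 3%.

**What passing these tests does not show.** The phantoms are convex,
high-contrast, noise-stationary and drift-linear; real astrocytes have
irregular somata, intensity-variable neighbours, occasional z-drift and
non-linear bleaching. Recovery within 10% on the phantom therefore
demonstrates the correctness of the measurement chain, not the field
accuracy of the assay; tissue-level group means (e.g. initial
$\alpha \approx 0.19$) come from animal recordings and are inputs here,
not reproducible outputs.

## Reporting conventions

`percentDrop()` reports $100(x_0 - x_t)/x_0$, signed (an increase is a
negative drop), rounded to integer percent for display. Applied to the
printed spinal-cord group means of a 50 mM K⁺ challenge at 20 min,
0.196 → 0.171 gives 13% and 0.193 → 0.130 gives 32.6% (printed as 32 when
computed from unrounded means). `washoutRecovery()` implements both
conventions found in practice — *fraction-of-deficit recovered* and
*ratio-to-peak* (the 20-min value set to 100%) — and records the choice
on its result, because published washout percentages are not always
recomputable from printed means and the convention must travel with the
number. Group curves aggregate as mean ± SEM with $n$ recorded;
inferential statistics (ANOVA families, multiple-comparison corrections)
are deliberately exported to dedicated tools via `tidyTimecourses()`
rather than re-implemented.

## Problem sizes used in validation

The shipped validation runs at desk scale, chosen to exercise every code
path with comfortable margins: 10 Hz × 82 s curves (821 samples),
100 noisy fit replicates, 20 random parameter sets against the
finite-difference solver (400 radial cells), 100 random frames against
the exhaustive Isodata search, and 96 × 96 × 28 phantom stacks over
5–9 timepoints.

## Known limitations

Ideal point source and isotropic diffusion only (no electrode geometry,
no anisotropy, no multi-compartment uptake); translation-only
registration; linear bleaching model; soma-based volume (no process
arbor); single-cell analysis (no tracking of multiple cells per field).
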