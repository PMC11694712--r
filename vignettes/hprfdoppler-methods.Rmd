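---
title: "Quantifying regurgitant volume with simulated 3D HPRF Doppler: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying regurgitant volume with simulated 3D HPRF Doppler: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Valvular regurgitation — blood leaking backward through the aortic valve in
diastole (AR) or the mitral valve in systole (MR) — is graded clinically by
the regurgitant volume per beat, RVol (mL): mild below 30 mL, moderate
30–59 mL, severe at 60 mL and above. The established echocardiographic
estimate, 2D PISA, assumes a hemispheric flow-convergence shell on the
upstream side of the orifice (flow rate $Q = 2\pi r^2 V_a$ at the aliasing
velocity $V_a$), and is known to be sensitive to violations of that
assumption. 3D high pulse repetition frequency Doppler (3D HPRFD) instead
quantifies the jet itself: a single broad transmit beam insonifies a
20 mm sample volume containing the narrow high-velocity jet core just
downstream of the orifice; per frame the method estimates the jet
cross-sectional area, the instantaneous flow rate as the spatial integral
of the velocities over that cross-section, and RVol as the temporal
integral of the flow rate over the regurgitant phase.

`hprfdoppler` implements this estimation chain together with a desk-scale
simulator that generates the inputs with known ground truth: jet phantoms,
scatterer clouds, and HPRF pulsed-Doppler IQ ensembles with the
characteristic HPRF artefacts (range ambiguity, aliasing, receiver
saturation). Reference quantifications (PISA with temporal averaging and
multi-jet summation, phase-contrast flow with polynomial background
correction, indirect mitral RVol, disc-summation ventricular volume) and
the agreement statistics used in clinical validation (Cohen's kappa,
ICC(3,1), Spearman's rho, Pearson chi-square) close the validation loop.

## The acquisition model

**Beam.** The broad beam is modelled per lateral axis as a paraxial
Gaussian beam parameterized by aperture width, wavelength and geometric
focus depth. Diffraction shifts the effective focus toward the transducer
($z_\mathrm{eff} = F/(1+(\lambda F/\pi w_a^2)^2) \le F$) — lowering the
transmit frequency therefore brings the effective focus closer, narrowing
the beam at typical imaging depth. A "slightly diverging" beam is a
virtual focus behind the transducer face (negative focus depth); at equal
aperture the focused configuration returns a stronger on-axis two-way
amplitude and a narrower beam, the trade-off the clinical acquisition
navigates.

**Two-way sensitivity.** The ensemble is produced directly on a beamformed
lateral × elevation × gate-depth grid; element data and beamforming are not
simulated. The two-way sensitivity is transmit × receive with the two
factors playing different roles: the single broad *transmit* beam is fixed
on the axis, while *receive* beamforming focuses dynamically at every
depth, translating a diffraction-limited profile (1/e radius
$w_\mathrm{rx}(z) = z\lambda/\pi w_a$, about 2.9 mm at 90 mm for a 20 mm
aperture at 1.5 MHz) to each grid point. A jet displaced laterally beyond
the transmit beam width is therefore captured incompletely — the mechanism
by which valve-plane excursion degrades eccentric-jet quantification —
while the lateral resolution of the images stays sharp, as with a real
dynamic-receive beamformer; a purely translation-invariant two-way
point-spread function would hide the first effect, and a broad receive
profile would make the jet cross-section nearly unidentifiable. For the
synthetic images used in segmentation this yields a receive power PSF of
$\sigma = w_\mathrm{rx}(z)/2$ per axis under a slowly varying transmit
power envelope $\exp(-2x^2/w_\mathrm{tx}^2)$, which the model applies to
the ellipse indicator before convolution.

**HPRF.** The pulse repetition frequency (12–18 kHz) sets the Nyquist
velocity $v_\mathrm{nyq} = c\,\mathrm{PRF}/(4 f_0)$; echoes from depths
separated by $c/(2\,\mathrm{PRF})$ arrive in the same receive gate and
sum (range ambiguity), so raising the PRF adds a sample volume near the
transducer. Both effects are implemented exactly: per pulse every
scatterer contributes amplitude × two-way beam amplitude × Gaussian
range-gate window × $e^{i 4\pi f_0 z / c}$ into the gate bin congruent to
its depth modulo the ambiguity spacing. Receiver saturation is hard
clipping of I and Q at a configurable dynamic-range bound — the simplest
mechanism by which a strong apical reflector inside a near-field ambiguous
volume destroys the weaker jet signal arriving in the same gate.

## The scatterer cloud

Blood scatterers (Gaussian amplitudes, i.e. fully developed speckle) are
seeded uniformly in the swept core region at a configurable density and
advected by the phantom velocity field with per-pulse Euler steps; tissue
clutter (default +40 dB) drifts quasi-statically (≤ 2 cm/s); discrete
apical reflectors (≥ +40 dB, default +60 dB) are fixed. Three cloud
mechanics matter for realistic Doppler statistics and were each adopted
after measuring the artefact they prevent:

* **Entrance/exit taper (3 mm).** Scatterers recycle through the core
  slab; without an amplitude taper the recycling step is an amplitude
  discontinuity inside the sensed gate and raises a broadband pedestal
  that corrupts the maximum-velocity envelope.
* **Radial re-randomization at recycling.** A recycled scatterer is new
  blood entering through the orifice and receives a fresh random radial
  position; re-entering on the same streamline would freeze the lateral
  speckle pattern of the whole recording into a single random draw.
* **Coherence modulation (40 ms period).** Each blood scatterer's
  amplitude is modulated by a unit-power cosine with a random phase,
  emulating the millisecond-scale echo decorrelation of real blood that
  purely laminar mean-flow advection lacks. Velocities are untouched: the
  cloud invariant that blood scatterer velocities match the phantom field
  holds exactly.

## Spectral processing

Slow-time segments (default 128 samples, 50% overlap — at PRF 13 kHz about
200 map frames/s) are clutter-filtered by polynomial regression (degree ≤
order removed exactly; default order 4, which leaves 2 cm/s clutter drift
71 dB below the jet, where order 2 leaves it only 23 dB down),
Hann-windowed, and transformed to periodograms whose frequency axis maps
to velocity (toward-transducer positive, wrapped to
$\pm v_\mathrm{nyq}$). Three per-voxel quantities are kept:

* total post-filter **power** (the power-Doppler image);
* the **maximum-velocity envelope**: largest $|v|$ bin above both the
  noise floor plus a 6 dB margin and the per-spectrum peak −20 dB, with a
  clutter stop band of 1.5 spectral bins;
* the power-weighted **mean velocity** of the qualifying bins.

The envelope deliberately reads the upper edge of the spectrum, and
transit-time broadening through the ~1 mm range gate scales with velocity
($\sigma_v/v = c/(4\pi f_0 \sigma_\mathrm{gate}) \approx 0.14$ at
1.5 MHz), so the envelope overestimates the jet speed by a roughly
constant factor (~25% measured on top-hat phantoms). The flow-rate
integration therefore defaults to the spectral *mean* velocity — for any
velocity profile the first moment of the Doppler spectrum is the unbiased
flux density, and symmetric broadening cancels — while the envelope is
retained for display, jet tracking and the aliasing detector, which need
the spectral extremes.

## The estimation chain

1. **Jet-core depth trace**: per frame, the gate-depth bin maximizing the
   95th-percentile Doppler power of pixels with detectable flow (the
   strongest core slice; a velocity-based criterion would lock onto the
   spectrally broadened core entrance), median-smoothed.
2. **Cross-section segmentation**: the lateral × elevation power slice at
   the jet depth — averaged over ±6 map frames and ±1 depth bin
   (persistence; the cross-section indicator does not depend on the
   instantaneous flow rate, so the temporal averaging is bias-free, while
   wider depth averaging would smear the laterally shifting cross-section
   of tilted jets) — after subtraction of the expected noise pedestal, is
   matched
   with a synthetic image: transmit-weighted ellipse indicator convolved
   with the receive power PSF. The fit minimizes normalized squared error
   in the amplitude (√power) domain, which variance-stabilizes speckle,
   with a closed-form amplitude scale (a fixed unit-peak match would
   shrink the ellipse because the observed speckle peak is biased high).
   Initialization comes from PSF-deconvolved second moments of the −10 dB
   thresholded image; Nelder–Mead refinement runs from that start and from
   the previous frame's fit, the better objective wins, ties break toward
   smaller area, and a hinge penalty activates only for axes reaching
   beyond the image.
3. **Flow rate**: $Q(t) = \sum |v|\,\Delta A$ over pixels inside the
   fitted ellipse at the jet-depth slice, with fractional pixel coverage
   by 4 × 4 sub-pixel quadrature (whole-pixel membership would quantize
   the area by ~±10% at 2 mm grids); undetectable pixels contribute zero.
   m/s × mm² conveniently integrates to mL/s.
4. **RVol**: trapezoidal integral of $Q$ over the detected regurgitant
   phase — the largest contiguous run of frames with $Q$ above 5% of its
   peak; a single cycle, no beat averaging.
5. **Feasibility**: a recording is non-feasible when RVol calculation is
   impossible due to (a) *no detectable flow*; (b) *insufficient PRF* —
   alias pile-up, detected as the envelope spending more than 20% of the
   regurgitant phase either within 1.5 bins of $\pm v_\mathrm{nyq}$ or
   folded over to the sign opposite the declared jet direction at
   substantial speed ($|v| > 0.25\,v_\mathrm{nyq}$; deep aliasing parks
   the wrapped ridge far from the Nyquist edge, so the boundary criterion
   alone cannot see it), with the envelope read at the strongest
   detectable pixel so stray noise detections cannot masquerade as
   aliasing; (c) *low SNR* — median jet-core power less than 10 dB above
   the expected noise-only spectrum power, or receiver overflow telemetry
   reporting saturation on more than 20% of beam-time samples (heavily
   clipped cells go silent while partially clipped ones emit
   intermodulation residue that registers as power, so the overflow flags
   — which real scanners provide — are the reliable witness of a
   saturated, unusable recording). Decreasing SNR can only move a
   recording toward non-feasibility.

## Reference methods

* **PISA**: $Q = 2\pi r^2 V_a$ per measurement; with temporal averaging
  the per-jet flow rate (not the radius) is averaged over ≥ 3 time points;
  EROA $= Q/V_\mathrm{max}$, RVol $=$ EROA × VTI from the continuous-wave
  envelope; clearly separated jets are quantified separately and summed.
  On an exact hemispheric convergence field the recovered flow rate is
  $V_a$-invariant; a funnel-shaped convergence biases it upward — the
  geometry the feasibility rules exclude.
* **Phase-contrast flow**: pixel phase → velocity via
  $v = \mathrm{VENC}\,\varphi/\pi$; a full second-degree 2D polynomial
  (6 coefficients) fitted to a stationary-phantom reference phase is
  subtracted (per-slice 2D, exact and idempotent on quadratic references);
  forward stroke volume and regurgitant volume are the positive and
  negative parts of the cycle integral. Phase wrap inside the ROI is a
  hard error — aliased recordings are discarded, not unwrapped.
* **Indirect mitral RVol** = LV stroke volume (disc summation over an
  8 mm short-axis stack) − aortic stroke volume; negative results carry a
  quality flag.
* **Severity grades** use the 30/60 mL bins as right-open intervals
  ([30, 60) moderate, ≥ 60 severe) for both valves.

## Agreement statistics

Implemented from first principles and cross-checked against independent
routes (two-way ANOVA via `lm`, `cor(method = "spearman")`,
`chisq.test(correct = FALSE)`, and a pair-counting oracle for kappa):
unweighted Cohen's kappa from integer sums; ICC(3,1) — two-way mixed,
consistency, single measures, insensitive to fixed rater offsets;
Spearman's rho with average ranks for ties; Pearson chi-square without
continuity correction, two-sided p-values from the chi-square survival
function. The bundled clinical summary tables (severity cross-tables and
feasibility counts from a 45 + 45 patient AR/MR cohort) provide the worked
examples: kappa 0.59 (AR) and 0.90 (MR), pooled feasibility 50% overall
and 25% in severe regurgitation, and chi-square p ≈ 0.006 (AR) / 0.014
(MR) for feasibility by jet direction.

## Study conditions of the synthetic validation

The standard phantom is a central top-hat jet with a half-sine
holodiastolic waveform: orifice 7.5 × 6.37 mm semi-axes (~150 mm² jet
cross-section), orifice depth 95 mm, 20 mm core, regurgitant phase 0.3 s
in a 0.45 s cycle, true RVol set via the peak flow rate. Acquisition:
1.5 MHz transmit, PRF 13 kHz ($v_\mathrm{nyq} = 3.34$ m/s), 90 mm gate
depth, 20 mm gate, 15 × 15 lateral grid at 2 mm, 2 mm gate bins, ~5900
frames (one cycle). Velocities stay in 0.4–2.1 m/s, inside the Nyquist
limit with margin for spectral broadening.

The beam-to-jet angle experiment uses a smaller (5.5 × 4.5 mm, ~78 mm²)
orifice with a 30 mm core, and `standard_phantom()` aims angled
acquisitions like an operator, offsetting the orifice so the mid-core
lies on the beam axis. The geometry forces all three choices: a depth
slice through a 50°-tilted cylinder spans ±*a*/cos θ·sin θ ≈ ±6.6 mm
*along the core axis*, so with a 20 mm core no slice cuts a complete
cross-section (the cut is clipped by the orifice plane and the core end),
and with the orifice on the beam axis the complete cross-sections sit
7–16 mm into the transmit-beam skirt. With the default large orifice the
50° footprint outgrows the transmit beam altogether and RVol is
underestimated by ~25% — the large-eccentric-jet failure mode the
clinical study reports, reproduced rather than hidden.

What the phantoms do *not* emulate: jet spreading and entrainment beyond
the non-spreading elliptical core, computational fluid dynamics,
turbulence in the velocity field, wall impingement geometry, attenuation
and time-gain compensation, probe motion, and multiple simultaneous jets.
Passing tests therefore demonstrate that the estimation chain is correct
and well-behaved under the idealized jet-core model it assumes — not that
the method is accurate on patient data, where the clinical experience this
package mirrors found low feasibility and weak agreement.

## Numerical choices and degenerate inputs

Trapezoidal integration throughout; time wraps modulo the cycle length;
seeds are explicit everywhere (cloud, noise, respawn pool) and no global
RNG state leaks. The ellipse model image is rendered by separable
quadrature at 0.5 mm; rotation is unidentifiable for circular fits and any
value is accepted; `a >= b` is enforced by swapping axes. Degenerate
inputs signal classed conditions rather than numbers: single-category
kappa tables, zero-variance ICC, constant Spearman vectors, empty
scatterer clouds (noise-only ensemble with a warning), images below the
noise floor, aliased phase-contrast ROIs, and underdetermined background
fits.

## Problem sizes

The bundled tests and the acceptance script run the full pipeline at the
study conditions above (≈ 1–2 minutes per case) for the recovery and
angle-robustness checks, and use a compact variant (9 × 9 grid, 12 mm
gate, 0.23 s cycle, ~2800–3100 frames) for the stochastic degradation
sweeps and physics checks, with scatterer densities of 0.2–0.3 per mm³.
These sizes were chosen so a complete validation runs on a laptop-class
single core in well under an hour while every check still exercises the
full simulate–process–estimate chain.
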