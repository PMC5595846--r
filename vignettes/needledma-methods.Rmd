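---
title: "Methods: a digital twin for needle-based micro-indentation DMA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a digital twin for needle-based micro-indentation DMA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(needledma)
```

## Scope and model

This package reproduces, in software, a needle-deliverable ferrule-top
micro-indenter operated in dynamic mechanical analysis (DMA) mode, and
the analysis that converts its recordings into frequency-dependent
storage and loss shear moduli. The physical chain is: a piezo actuator
moves a cantilever (spring constant $k$, Hooke's-law force transducer
$F = k d$) whose spherical bead tip (radius $R$) indents a sample; the
cantilever deflection $d$ is read interferometrically; a feedback loop
on the measured load drives the piezo.

### Contact mechanics

The sample is an isotropic, homogeneous, linear-viscoelastic half-space
in frictionless Hertzian contact with a rigid sphere:
$F = \tfrac{4}{3} E_{\mathrm{eff}} \sqrt{R}\, h^{3/2}$ with
$E_{\mathrm{eff}} = E/(1-\nu^2)$, $E = 2G(1+\nu)$. Linearizing about
the static depth $h_0$ gives the dynamic stiffness
$S = 2 E_{\mathrm{eff}} \sqrt{R h_0}$, and for a small load oscillation
of amplitude $F_1$, indentation amplitude $h_1$ and phase lag $\varphi$,

$$G' = \frac{(1-\nu) F_1 \cos\varphi}{4 h_1 \sqrt{R h_0}}, \qquad
  G'' = \frac{(1-\nu) F_1 \sin\varphi}{4 h_1 \sqrt{R h_0}}.$$

Moduli are reported as shear moduli; the single Poisson conversion
$G = E/(2(1+\nu))$ lives in the contact module, with $\nu = 0.5$
(incompressible soft tissue) as default, so $G = E/3$ exactly. No
adhesion, no finite-thickness (bottom-effect) correction, no
poroelasticity: the analysis is the plain Hertzian linearization.

### Viscoelasticity in the time domain

Frequency-domain models: elastic $G^* = G_e$; Kelvin–Voigt
$G^* = G_e + i\omega\eta$; standard linear solid / generalized Maxwell
$G^* = G_e + \sum_j G_j\, i\omega\tau_j/(1 + i\omega\tau_j)$; springpot
$G^* = c_\alpha (i\omega)^\alpha$. For simulation the hereditary
(Lee–Radok) form is applied to the pseudo-strain $u = h^{3/2}$:
$F(t) = \tfrac{8\sqrt{R}}{3(1-\nu)} \int G(t-s)\, \dot u(s)\, ds$.
Each Maxwell branch is advanced by its exact exponential solution under
piecewise-linear strain,
$\sigma_j \leftarrow \sigma_j e^{-\Delta t/\tau_j} + G_j \dot u\, \tau_j (1 - e^{-\Delta t/\tau_j})$,
which is unconditionally stable — essential because one sampling rate
(1 kHz) must serve 2.3 decades of sweep frequency. The update is linear
in the strain increment, so the per-step cantilever/sample equilibrium
$k d = F_{\mathrm{sample}}(h)$, $h = z_p - d - z_c$, is a monotone
scalar root solved by safeguarded Newton. The springpot is excluded
from time-domain simulation rather than approximated by a Prony fit:
an approximation would blur the recovery tolerances that the twin
exists to certify. Frequency/time consistency is enforced by test: the
steady-state sinusoidal response of the kernel matches
`complex_modulus()` within 0.5 % in magnitude and 0.5° in phase across
0.05–10 Hz.

### Instrument and protocol emulation

The twin executes the measurement protocol with time-scheduled
segments: constant-speed approach (10 µm/s across a 20 µm free gap),
debounced contact detection (threshold 5× the deflection noise RMS,
20 ms persistence — isolated spikes from e.g. lumen contamination are
rejected), proportional–integral load control to the static setpoint,
a 60 s hold for stress dissipation, one oscillation segment per sweep
frequency, and a 100 µm retraction. The cantilever is quasi-static
($F = k d$): the sweep band (≤ 10 Hz) lies orders of magnitude below
any cantilever resonance.

Several of the protocol's numeric values are printed without units in
the source material; the defaults here read them as 300 µN static load,
10 µN oscillation amplitude, 40 µm maximum static indentation and
100 µm retraction, which is the only combination consistent with a
60–70 N/m cantilever, a 150 µm bead (which itself must pass an 18G
needle lumen of ~1.1 mm), and kPa-scale tissue. They are recorded as
assumptions, not facts. The default oscillation amplitude is
`static_load / 30`, preserving the 300:10 ratio so that
$h_1/h_0 \approx \tfrac{2}{3}(F_1/F_0) \approx 0.022$ stays inside the
linear regime at any load.

**Static load is an operator choice.** With the default 300 µN, a
sample softer than ~18 kPa would exceed the 40 µm depth bound, exactly
as it would on the physical instrument; the operator lowers the load
for soft samples. The test and acceptance ground truths therefore pair
soft models with smaller static loads (e.g. 25 µN for a 2 kPa nucleus-
pulposus-like solid, giving $h_0 \approx 33$ µm), the same way the
physical protocol kept the maximum depth at 40 µm.

**Controller design.** A discrete PI acts on the measured-load error
and drives the piezo velocity ($K_p = 0.2$ m s⁻¹ N⁻¹,
$K_i = 1$ m s⁻² N⁻¹, anti-windup clamped). The loop gain is
$g K_p$ with $g = kS/(k+S)$, stable for all supported stiffnesses at
1 kHz. During oscillation segments the integrator is frozen at the
value it learned during the hold (it encodes the drift-compensation
velocity): its pole would otherwise resonate with sweep frequencies
near $\sqrt{g K_i}$ on compliant samples. The sinusoid itself is
tracked by an adaptive feed-forward: a complex piezo phasor initialized
from the linearized plant estimate and corrected once per period from
the single-bin Fourier amplitude of the measured load. For a linear
plant one correction is exact, so after the first (discarded) period
the commanded amplitude is tracked within 2 % at every sweep frequency;
the tolerance is enforced by test.

**Noise and drift.** Additive Gaussian deflection noise (default 2 nm
RMS) and linear drift (default 0.05 nm/s) are applied to the sensed and
recorded deflection. The drift default describes a probe in good
working order: at 65 N/m, 0.05 nm/s costs ~1 µN of true static load
over a six-minute full-band sweep. Probes with visible drift are
rejected at glass calibration in the physical workflow, and a drift an
order of magnitude larger would silently unload a 25 µN soft-sample
measurement during the sweep — the twin reproduces exactly that failure
if configured to.

**Stick–slip needle friction** (off by default) emulates the probe
binding in the needle shaft after piercing stiff tissue. Static
friction engages only after the commanded transmission speed stays
below `v_crit` (3 µm/s) for a dwell time (0.5 s, a junction-aging
picture) and releases after 0.2 µm of accumulated play. Sweep
frequencies whose peak piezo speed exceeds `v_crit` pass through
cleanly; at the bottom of the reduced band (0.5 Hz, peak speed
~2 µm/s on a 2 kPa sample) the transmission degrades into a staircase,
the single-frequency fit residual rises far above the broadband noise
floor, and the row is flagged `phase_unreliable` — the package's
mechanistic reproduction of the known low-frequency loss-modulus
unreliability of this instrument class.

### Interferometric readout

The fiber–cantilever Fabry–Pérot cavity is modeled as a two-beam
interferometer, $I = I_0[1 + V\cos(4\pi(L_0-d)/\lambda_t)]$, with
high-frequency wavelength modulation providing quadrature: expanding
the cavity phase in Bessel harmonics of the modulation frequency, the
lock-in components at $f_m$ and $2f_m$ are proportional to
$J_1(m)\sin\theta$ and $J_2(m)\cos\theta$. Defaults ($\lambda$ 1550 nm
telecom fiber, $L_0$ 500 µm, depth 1 nm, $f_m$ 500 Hz) set the
modulation index $m \approx 2.62$ where $J_1 \approx J_2$, the
balanced-quadrature point. Demodulation is ratiometric (insensitive to
$I_0$ and $V$ scaling), uses a zero-phase one-modulation-period lowpass
(half-end-weight kernel when the period is an even number of samples —
a plain even boxcar would masquerade as extra phase lag at 10 Hz), and
unwraps the phase sample-to-sample. When the signal spans multiple
fringes the two quadrature scales are re-estimated from the data
itself (ellipse normalization), removing the residual dependence on the
nominal modulation index. A wrapped phase step larger than $\pi$ is
unobservable in principle, so the guard rejects steps above $\pi/2$ as
a slew fault. Simulating raw intensity is an opt-in fidelity level
(`fidelity = "raw_intensity"`, requiring a sample rate ≥ 10× $f_m$);
the default pipeline simulates the demodulated deflection directly so
routine tests stay fast while the readout path keeps its own round-trip
tests (≤ 1 nm RMS noise-free over ≥ 3 fringes, ≤ 5 nm at 40 dB SNR).

### Analysis pipeline

Per oscillation segment the first period is discarded (controller
adaptation and sample-memory settling), the window is truncated to a
whole number of periods so that harmonics stay orthogonal to the
fundamental, and both channels are fitted with
$a\sin + b\cos + c + e t$; the drift term absorbs slow creep, and
$\varphi$ is the difference of fitted phases (exact at known frequency,
convention-free between channels). $h_0$ is the segment-mean
indentation rather than the pre-oscillation hold value, because the
true static depth creeps during long low-frequency segments and the
inversion wants the operating point of *that* segment. Small negative
fitted phases (within 0.05 rad) are clipped to zero and flagged rather
than propagated as negative loss — a passivity prior. The contact point
is re-detected from the approach segment (threshold crossing, debounced,
back-extrapolated by threshold/$k$).

QC flags (attached, never silently dropped): `linearity`
($h_1/h_0 > 0.05$), `geometry` ($h_0/R > 0.4$), `max_depth`
($h_0 > 40$ µm), `negative_phase_clipped`, `phase_range`
($\varphi \notin [0, \pi/2)$), and `phase_unreliable` (fit residual in
quadrature excess of the broadband noise floor exceeding 5 % of the
amplitude). The noise floor is estimated from the hold segment via the
first-difference MAD, which ignores slow controller motion and sparse
slip events — a deliberate choice so that a disturbance that corrupts
the hold cannot mask its own signature in the sweep.

Repeated sweeps are averaged arithmetically per frequency (no
weighting), flagged rows excluded, dispersion reported as the standard
deviation with $n = 1$ giving 0 by convention.

## What the generator does and does not emulate

Emulated: Hertzian spherical contact on a linear viscoelastic
half-space, Hooke's-law load sensing, closed-loop load control with its
real settling artifacts, additive readout noise, slow drift,
sensitivity miscalibration, fringe-level interferometry, and the sweep
protocol (15 log-spaced frequencies 0.05–10 Hz full band; 5 over
0.5–10 Hz in the reduced in-situ mode; 5 periods each; ≥ 60 s hold).

Not emulated: nonlinear or poroelastic tissue behavior, adhesion,
substrate effects, tissue damage and time-dependent degradation, needle
insertion mechanics, thermal drift spectra, cantilever dynamics. A
passing recovery test therefore certifies the *instrument and analysis
chain* under the stated contact model — it does not certify that real
tissue satisfies that model. Real constitutive parameters for the
silicone phantom or nucleus pulposus are unknown; the ground-truth
models here (standard linear solids at 2–4 kPa and 20–30 kPa, a
Kelvin–Voigt solid, a two-branch generalized Maxwell up to ~50 kPa)
were chosen once to span the tissue-relevant storage range reported for
in-situ disc measurements (a few kPa) up to phantom/ex-situ scales
(tens of kPa), with loss tangents of order 0.05–0.3 in the band.

## Numerical choices and degenerate inputs

* Sample rate 1 kHz: ≥ 100 samples per period at 10 Hz; the exponential
  integrator keeps the kernel exact at any rate.
* Newton solve of the contact equilibrium: bracketed on
  $[0, z_p - z_c]$, bisection fallback, relative tolerance $10^{-13}$.
* Contact loss (hereditary tension at the surface): the step reports
  zero force and lets branch stresses relax freely — adhesion is out of
  scope, and the state only matters during retraction.
* Piezo travel is capped at 500 µm; an unreachable setpoint raises a
  protocol fault rather than winding up.
* The contact threshold has a 10 pm floor so noise-free recordings
  remain detectable; the known bias of threshold detection (the
  Hertzian depth already accrued at the threshold force, ~2–3 µm on a
  2 kPa sample at the default noise level, i.e. a few percent of $h_0$)
  is the dominant systematic in noisy soft-sample storage recovery and
  is documented rather than hidden.
* File I/O writes doubles at 17 significant digits (lossless
  round trip), rejects non-uniform time grids with the offending line
  number, and reconstructs missing segment labels from the protocol
  metadata when possible.

## Validation scale

The validation suite and acceptance script run full-protocol
simulations (hold 60 s, complete 15-frequency sweeps — about 395 s of
instrument time, 4×10⁵ samples per recording) for four ground-truth
models noise-free plus three models × 5 seeds at default noise; the
closed-loop core is compiled, so the whole acceptance computation is a
few seconds of CPU. Noise-free recovery lands near 1 % in $G'$ and
under 1 % in $G''$; noisy 5-seed averages stay within ~5 % / ~12 %,
dominated by the contact-point bias above, comfortably inside the
10 % / 20 % acceptance bands.

## Known limitations

* The inversion assumes the linearized stiffness; at $h_1/h_0 = 0.05$
  the linearization error reaches the percent level (tested to stay
  below $2 h_1/h_0$).
* Contact-point detection by threshold is biased soft-side (above); a
  Hertz-consistent contact-point regression would remove it but is not
  part of the emulated instrument's workflow.
* The loss modulus at the lowest frequencies is intrinsically fragile:
  the phase lag is a few hundredths of a radian, so any waveform
  distortion (needle friction) or phase bias maps to large relative
  $G''$ errors. This is a property of the method, faithfully
  reproduced, not a defect of the implementation.
* The springpot model participates only in frequency-domain
  computations and property tests.
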