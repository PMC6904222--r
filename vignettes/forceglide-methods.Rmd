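---
title: "Models and methods behind forceglide"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind forceglide}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forceglide)
```

# The assay and what the package computes

In a force-gliding assay the usual motility geometry is inverted: kinesin-1
motors are anchored to a passivated coverslip through long (1565 bp, 532 nm
contour) dsDNA tethers, each motor carrying a quantum dot, and a fluorescent
microtubule glides over them as the common cargo. Because every motor is held
by its own calibrated polymer spring, the displacement of a motor from its
anchor ("equilibrium position") reports both the direction and, through the
worm-like-chain elasticity of the tether, the magnitude of the force it
exchanges with the cargo. Motors displaced *against* the gliding direction
push the microtubule forward (*driving*); motors displaced *along* the
gliding direction hold it back (*resisting*). `forceglide` implements the
full analysis chain for this geometry — tether mechanics, spot tracking,
drive/resist state classification and kinetics, stuck/fast velocity
decomposition, and rupture-force survival analysis — together with synthetic
data generators that provide ground truth for every stage.

# Tether mechanics

Forces are never measured directly; they are inferred from extension through
the worm-like chain. Three closed forms coexist in the package because they
are accurate in different regimes, and because the two published stiffness
values for this tether are each consistent with a different form:

* `ms_force()` — the inextensible Marko–Siggia interpolation
  \(F(x) = (k_BT/L_p)\,[\tfrac{1}{4}(1-x/L_c)^{-2} - \tfrac14 + x/L_c]\),
  adequate below ~0.5 pN where enthalpic stretching is negligible. Its
  analytic derivative (`ms_stiffness()`) evaluated at extension 246 nm
  (displacement 266 nm minus the 20 nm offset) gives 6.6e-4 pN/nm, the
  low-extension elasticity quoted for this tether.
* `ewlc_extension()` / `ewlc_force()` / `ewlc_stiffness()` — the high-force
  extensible series \(x(F) = L_c(1 - \tfrac12\sqrt{k_BT/FL_p} + F/K_0)\),
  appropriate above ~0.5 pN; its stiffness at 496 nm extension is ~0.2 pN/nm,
  the value quoted at large extension.
* `ems_force()` — the full extensible interpolation with
  \(l = x/L_c - F/K_0\) solved self-consistently; this bridges both regimes
  and is what `displacement_to_force()` uses for pipeline force traces.

Parameter defaults: persistence length 50 nm and contour length 532 nm are
the tether's constitutive values; the 20 nm distance offset absorbs the
physical size of the quantum dot and linkers and is subtracted from every
displacement before conversion to extension. Two parameters are not printed
anywhere for this construct and are fixed here by standard physics: thermal
energy 4.14 pN·nm (T ≈ 300 K) and stretch modulus 1200 pN (canonical
dsDNA). The analytic low-extension stiffness reproduces the printed value to
two significant figures under these choices, and the large-extension
stiffness is within 5% of the printed 0.19 pN/nm over the plausible range
K0 ∈ [800, 1200] pN, so neither choice is delicate.

Numerics: all inverse maps use bracketed root-finding (`uniroot`, tolerance
1e-12); round trips are exact to 1e-6 and every map is strictly monotone on
its domain. `ewlc_force()` refuses extensions outside the F ∈ [0.05, 100] pN
image rather than extrapolating.

# The event-level generator and its calibration closure

`generate_event_traces()` is the workhorse for validating the inference: it
emits per-motor on-axis displacement traces with complete ground truth at
the assay's published operating point, encoded in `event_calibration()`.
Each motor produces a renewal sequence of events. Within an event the
displacement ramps away from equilibrium (the motor runs at its free
relative speed until the tether is taut), plateaus (tether taut, motor
locked to the cargo speed, i.e. stationary in the lab), and snaps back to
equilibrium at detachment. Gaussian localization noise (20 nm sd) is added
throughout.

The calibration is deliberately over-complete — per-role mean durations
(3.0 / 2.15 s), per-role mean run lengths (2.31 / 1.42 µm), ramp relative
speeds (~1300 / ~500 nm/s), and a nominal cargo speed — and these numbers
are not mutually independent under the ramp/plateau kinematics. Writing
\(R_d, R_r\) for the run-length means and \(\bar d_d, \bar d_r\) for the
duration means, the run length of an event of duration \(D\) is
\(v_0\min(D,\tau) + v_c(D-\tau)^+\) with \(\tau\) the ramp time, so taking
expectations over both roles forces

\[ v_c = \frac{R_d + R_r}{\bar d_d + \bar d_r} \approx 724\ \text{nm/s},
\qquad A = R_d - v_c\,\bar d_d \approx 137\ \text{nm}, \]

where \(A\) is the plateau amplitude. The generator solves this closure at
construction. Two consequences are worth knowing. First, the engaged cargo
speed implied by the published moments (724 nm/s) is below the unloaded
gliding speed (830 nm/s); the generator therefore runs the cargo at the
engaged speed while any event is active and at the nominal speed otherwise.
Second, a naive parameterization with the cargo at 830 nm/s cannot
reproduce the driving run length (it predicts at least 2.49 µm): the
published summary statistics are only jointly consistent with the slower
engaged speed.

Two further calibration interpretations:

* **Driving fraction.** The published ~65% driving fraction is a per-frame
  statistic over engaged motors. Because driving events last longer, a
  per-event Bernoulli(0.65) would produce a 72% per-frame fraction. The
  generator therefore treats `p_drive` as the engaged-time fraction and
  derives the per-event probability
  \(p_{ev} = p\,\bar d_r / [(1-p)\bar d_d + p\,\bar d_r] \approx 0.571\).
* **Durations.** Durations are drawn as `min_duration` (0.7 s) plus an
  exponential, keeping each role's mean exact while guaranteeing that every
  emitted event spans several camera frames. Sub-frame attachments are not
  scoreable events in the real assay either; without the floor, events
  shorter than the two-point detection criterion would be silently censored
  and every recovered mean would be biased upward by the censoring
  threshold (memorylessness adds the threshold to the conditional mean).

Role sequences are either independent draws (`role_process = "iid"`) or a
two-state Markov chain whose transition matrix is derived from the
calibrated transition-type mix (52/16/16/16% over drive-drive,
drive-resist, resist-drive, resist-resist), for studies of switching
statistics. Unbound gaps are exponential with mean set so the expected
number of transitions per motor-minute matches the calibrated 4.9/min on a
track of the requested length (including the finite-track correction).

What the generator does *not* emulate: microtubule bending and off-axis
excursions (displacements are one-dimensional along the gliding axis, as
are all the published statistics), motor-motor mechanical coupling within a
trace (events are placed by a renewal process, not by a force balance — the
mechanistic simulator covers that), photophysics (blinking), and drift.
Tests passing on these fixtures therefore demonstrate correctness of the
inference chain under the published operating point, not robustness to
every artifact of real microscopy data.

# The mechanistic simulator

`simulate_gliding()` closes the loop that the event-level generator leaves
open: motor state and cargo motion emerge from a stochastic tug-of-war
rather than being prescribed. Anchored motors bind (2 /s within a 400 nm
capture radius, at zero tension, head at the lattice site nearest the
anchor), walk with a piecewise-linear force-velocity relation (plateau
within ±2 pN, stall at 6 pN hindering, modest assisted speed-up saturating
at 6 pN), and unbind with role-dependent Bell rates
(0.25/s · e^{F/4 pN} driving, 0.35/s · e^{F/2 pN} resisting — the resisting
motor detaches faster under load, which is the asymmetry that sustains a
two-thirds driving fraction). Per-motor unloaded speeds are truncated
normal (mean 830, sd 250 nm/s), expressing the natural speed variation that
decides which newly bound motors end up driving. The cargo advances
quasi-statically: each step solves
\(\sum_i \mathrm{sign}(-d_i) F(|d_i|) - \gamma \dot X = 0\) for the new
cargo position by bracketed root-finding (drag γ = 1e-3 pN·s/nm, step
10 ms); the balance residual is recorded and stays below 1e-6 pN. Tether
forces use a 0.5 nm-grid interpolant of the full extensible interpolation
(interpolation error ≪ 1e-3 pN).

Roadblocks are a Poisson set on the lattice; a motor that would step across
one stalls (force-dependent unbinding continues), which reproduces both the
stuck/fast cargo velocity mixture and its rescue by larger teams: a stuck
motor is dragged to higher tension by its teammates and releases sooner.
Anchor rupture under a Bell–Evans hazard is optional. Because a gliding
cargo continuously leaves its anchor field, anchor slots that fall behind
the capture zone are recycled to the front of the lane with freshly drawn
motor speeds — the 1-D equivalent of a gliding assay's motor carpet, which
keeps the motor density under the cargo stationary.

The simulator's kinetic defaults were fixed once against the single-motor
force-velocity/run-length phenomenology and then checked (not iterated) at
the team level: three-motor runs hold the engaged driving fraction between
0.55 and 0.75, mean engaged tension under 4 pN, and tension within the
first 0.8 s after binding under 0.4 pN.

# Tracking

The imaging chain mirrors standard single-particle tracking practice at
160 nm/pixel and 5 Hz. Detection is Laplacian-of-Gaussian with the kernel
scale set by a 4-pixel blob diameter and an automatic (Otsu) response
threshold; sub-pixel positions come from integrated 2-D Gaussian
least-squares fits (FIONA-style), reaching ~0.006 px on bright spots and
< 5 nm RMS at high photon counts. Linking is a two-pass linear-assignment
tracker: optimal frame-to-frame matching on squared distance (4-pixel gate)
followed by track-segment stitching across gaps of up to 20 frames within
4 pixels. The assignment core is a Jonker–Volgenant-style Hungarian solver
written in R and unit-tested against brute-force enumeration.

Microtubule velocity comes from a kymograph sampled along a piecewise-linear
backbone polyline (bilinear interpolation, averaged across a 3-pixel line
width). Intensity edges — the texture of the labeled lattice — are detected
per frame as gradient-magnitude maxima above an Otsu threshold with
parabolic sub-pixel refinement, linked across frames by continuity, and
differentiated with a Savitzky–Golay filter (window 7 frames; the window is
the bias-variance compromise at 5 Hz — narrower windows leave >5% RMS
velocity noise, wider ones smear velocity steps beyond two frames). Where
the original workflow patched kymograph edges manually, the package
interpolates missing frames and flags them (`n_edges = 0`) instead. Motor
tracks are projected onto the backbone's arc length, so bent microtubules
contribute arc rather than chord distance; points beyond a capture distance
are flagged off-axis.

# State classification and kinetics

`find_equilibrium()` estimates the anchor position as the kernel-density
peak of the quiescent (low-|velocity|) portion of a trace — robust to
traces that spend up to roughly half their time on excursion plateaus — and
the baseline noise as `mad(diff(x))/sqrt(2)`, which first differences make
insensitive to the slow excursions themselves.

`classify_events()` implements the published inclusion rule: an excursion
qualifies as an event if it has at least two points displaced more than
100 nm, or points displaced more than twice the baseline noise — the two
branches are alternatives, and the unspecified noise branch requires three
points here so that an automated pipeline is not swamped by Gaussian noise
doublets (at 20 nm noise, two consecutive 2σ outliers occur about once per
600 s track; three effectively never). Traces with more than 5 s of
contiguous missing data are discarded whole. Roles follow the sign of the
excursion relative to the gliding direction (negative = driving), using the
direction of mean microtubule motion rather than its instantaneous sign so
stuck episodes do not flip labels.

Event boundaries are where automated and by-eye analysis genuinely differ,
and the choice matters: delimiting events at the 2σ threshold crossings
systematically clips the stretching ramp and biases mean durations low
(by up to ~6% for the slow resisting ramps). The package instead
extrapolates the start back to the equilibrium crossing using a local ramp
slope — the steepest inter-frame step, floored by two physical bounds (the
pre-excursion frame sat below the baseline noise; a next frame already at
the plateau dates the rise to about one frame interval) — and takes the end
as the midpoint between the last displaced frame and the next (detachment
recoil is sub-frame). Against generator ground truth this leaves residual
duration biases of about +1% (driving) and −1.5% (resisting), the floor set
by 0.2 s frame quantization.

Run lengths are the integral of relative velocity over the event,
\(\int (v_{MT} - v_{kin})\,dt\), computed exactly as
\(\int v_{MT}\,dt - \Delta x_{kin}\) because the motor-velocity integral
telescopes to its net displacement — this avoids differentiating through
the detachment jump, which would otherwise subtract the full plateau
amplitude from the estimate. Transition statistics treat every ordered pair
of consecutive events of one motor as a transition regardless of the
intervening unbound time (an optional maximum gap is deliberately not
imposed by default, matching the counting convention in which a motor may
detach between events). The per-frame driving fraction is pooled by the
number of simultaneously engaged motors with Wilson confidence intervals;
relative-velocity curves are aligned at event start and averaged per role
over surviving events (no survivor-bias reweighting — late-time bins simply
carry fewer, longer events).

# Velocity populations

Microtubule velocities, sampled as 1 s window means, are decomposed into
stuck and fast populations by a two-Gaussian fit. The primary fit is binned
least squares on the 50 nm/s histogram — matching how such histograms are
usually fitted — under the physical constraints |stuck mean| ≤ 50 nm/s,
stuck sd ≤ 150 nm/s, fast mean ≥ 400 nm/s; a constrained EM fit on the raw
samples (`em_two_gaussians()`) is kept as an independent route and agrees
within ±0.03 in weight on separated mixtures. Negative samples are
retained: the stuck component is genuinely centered at zero, not truncated.
Fits collapsing to one component are flagged degenerate rather than
reported as a 0/100 split.

# Rupture analysis

Optical-trap pulls of single tethers are simulated under the stiff-trap
approximation (extension follows the trap separation at 10 or 100 nm/s),
with forces from the high-force eWLC and rupture from a Bell–Evans hazard
k0·e^{F/Fb}. The bond defaults (k0 = 0.01/s, Fb = 6.5 pN) are a
*calibration* chosen so that the slow-pull median rupture force lands near
30 pN (and the fast-pull median near 45 pN); they are not measured
antibody-bond parameters and are labeled accordingly. The closed-form
constant-loading-rate survival
\(S(F) = \exp[-(k_0F_b/\dot F)(e^{F/F_b}-1)]\) serves as the analytic
oracle: Monte-Carlo hazard simulations stay inside the
Dvoretzky–Kiefer–Wolfowitz band at n = 1000.

Rupture detection calls the maximum force preceding a >50% force drop
within three samples; curves without such a drop are right-censored at
their final force, so fast-ramp medians are reported as lower bounds when
more than half the tethers outlive the ramp. Survival curves are
Kaplan–Meier with a midpoint convention where the curve sits exactly at
one half. Force–extension fits (`fit_fec()`) free any subset of (Lp, Lc,
K0); a second parallel tether is flagged not only by residuals — the eWLC
family fits a halved-compliance curve deceptively well — but by the
tell-tale collapse of the apparent persistence length to about half the
construct value.

# Pipeline, reproducibility, problem sizes

`run_pipeline()` executes the stages in dependency order from a single
validated configuration; every output table carries a hash of the
configuration (invariant to field reordering), per-stage seeds are derived
deterministically from the master seed, and a manifest records inputs,
outputs, versions and wall-clock. Fixed seeds give bit-identical runs. A
thin command-line wrapper (`inst/cli/forceglide.R`) exposes the same entry
point to shell users; the package functions remain the primary interface.

The shipped validation uses moderate problem sizes chosen to estimate each
statistic well: ~2500 events (100 motors × 5 min) for kinetics recovery,
~1900 transitions for switching statistics, ~2 × 10⁴ motor-frames for the
driving fraction, 5000 velocity samples for mixtures, and 10³ pulls for
survival oracles. All are the package's own defaults for validation runs
and scale linearly if larger studies are wanted.

# Known limitations

* Geometry is one-dimensional along the gliding axis; off-axis motion
  enters only as isotropic localization noise, and microtubule bending is
  handled purely as a backbone polyline downstream.
* Event-boundary estimation is frame-rate limited; duration biases of
  ±1–2% remain at 5 Hz and would shrink with faster sampling.
* The two printed tether stiffnesses are not reproducible with a single
  eWLC form at the stated extensions; the package exposes both forms
  rather than forcing a compromise fit.
* The mechanistic simulator's binding model (constant rate within a capture
  radius, zero initial tension) is the simplest consistent choice; real
  attachment geometry is unknown.
* Bond parameters for rupture are calibrated, not measured; survival
  analyses of real pulls should fit their own BondModel.
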