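---
title: "Modeling intermittent postural control and analyzing perturbed stance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling intermittent postural control and analyzing perturbed stance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Human upright stance is modeled as a sagittal double inverted pendulum:
a leg link (LE, both lower extremities lumped together) pivoting about
the ankle and a head-arms-trunk link (HAT) pivoting about the hip, with
the feet fixed to the support surface. With joint angles
$\theta = (\theta_a, \theta_h)^T$ (forward rotation positive), the
equations of motion are

$$M(\theta)\,\ddot\theta + C(\theta,\dot\theta) + G(\theta)
  = T^{pass} + T^{act} + T^{reflex} + T^{pert} + T^{n},$$

where $M$, $C$ and $G$ are the inertia matrix, the
centrifugal/Coriolis vector and the gravitational toppling vector of
the planar two-link chain, derived in closed form from the Lagrangian
(`derive_dynamics_terms()`). The derivation is validated two ways in
the test suite: energy conservation of the free, gravity-free chain
under high-accuracy integration, and agreement of the
support-acceleration coupling with a numerically differentiated
kinematic Jacobian.

The torque components are:

* **Passive viscoelasticity** $T^{pass} = -(K\theta + B\dot\theta)$
  per joint. By model assumption the passive ankle stiffness $K_a$ is
  *below* the gravitational load stiffness
  $K_{load} = g\,(m_{LE} c_{LE} + m_{HAT}(l_{LE}+c_{HAT}))$, so the
  upright equilibrium of the control-OFF dynamics is a saddle; the hip
  is rigidly stabilized by large $K_h$, $B_h$.
* **Intermittent control** $T^{act}$: an ankle-only delayed PD feedback
  of the CoM tilt state,
  $\tau_a^{act} = -(P\,\theta_{CoM}(t-\Delta) + D\,\dot\theta_{CoM}(t-\Delta))$,
  switched ON or OFF according to the region of the
  $\theta_{CoM}$–$\dot\theta_{CoM}$ phase plane occupied by the
  *delay-affected* state ($\Delta = 200$ ms). In the OFF region — a
  sector of the 2nd/4th quadrants containing the slow directions of the
  saddle — the controller is silent and the body coasts on the saddle
  flow, transiently approaching upright along the stable manifold.
* **Reflexive control** $T^{reflex}$: a high-gain delayed PD term
  ($P^{reflex} = 327$ N m/rad, $D^{reflex} = 50$ N m s/rad,
  $\Delta_{reflex} = 50$ ms) active only in a short window after a
  support-surface perturbation; while active it preempts the
  intermittent controller.
* **Perturbation** $T^{pert}$: d'Alembert pseudo-forces
  $-m_i\,\alpha$ applied horizontally at each link CoM for a
  piecewise-constant support acceleration $\alpha(t)$ (default:
  $-4$ m/s$^2$ for 100 ms, then $+4$ m/s$^2$ for 100 ms).
* **Noise** $T^{n}$: white Gaussian torque noise, scaled by
  $1/\sqrt{dt}$ per integration step so its integrated effect is
  independent of the step size.

Integration is forward Euler (default $dt = 10^{-3}$ s) with
ring-buffer delay lines, implemented in compiled code; delays are
rounded to integer step multiples and the pre-history is back-filled
with the initial state. A run halts with a `fallen` flag when
$|\theta_{CoM}|$ exceeds 1.2 rad, safely below the folded-chain rest
angle (~1.48 rad) an uncontrolled fall ends in.

## Default parameters and their calibration

Body defaults: 60 kg total mass split HAT:LE = 0.62:0.35 (remainder to
the feet), link lengths 0.9/0.8 m, link CoM at mid-link, uniform-rod
inertias. These give $K_{load} \approx 567$ N m/rad. Control defaults:
$K_a = 0.8\,K_{load}$, $B_a = 35$ N m s/rad, $K_h = 2000$ N m/rad,
$B_h = 200$ N m s/rad, $P = 0.25\,K_{load} \approx 142$ N m/rad,
$D = 100$ N m s/rad, noise intensity 0.1 N m $\sqrt{s}$ per joint.

Because the switched small-angle dynamics are *positively homogeneous*
(linear dynamics, switching on rays through the origin), orbits have no
intrinsic amplitude scale: the model's small quiet-stance oscillation
is a *near-neutral* orbit whose ~0.01 rad amplitude is inherited from
the standard initial tilt of 0.01 rad. The OFF sector was therefore
calibrated so that this orbit is as close to neutral as the default
step size resolves. Three design choices matter:

1. **OFF-sector geometry.** The OFF region is the sector between a
   near-horizontal boundary of slope $-0.115$ and a steep boundary of
   slope $-P/D$. With the exact 2nd/4th quadrants as the OFF region the
   orbit expands by ~0.1/s and saturates only at a ~0.7 rad nonlinear
   cycle; tilting the lower boundary slightly below the horizontal axis
   restores neutrality at small amplitude.
2. **Torque-continuous steep boundary.** On the ray
   $\dot\theta = -(P/D)\,\theta$ the PD torque vanishes identically, so
   switching while the state grazes that boundary injects no torque
   step into the ankle. With the conventional small derivative gain
   ($D \approx 10$) every noise-induced grazing switch produces a CoP
   step of $(P + D s)\theta$, and these steps occur at 13–26 Hz,
   contaminating every CoP-derived statistic. Choosing $D = 100$ puts
   the silent ray just inside the stable eigendirection of the saddle
   and removes the artifact at its mechanical source. The trade-off is
   documented honestly: at these gains a *persistently operated*
   delayed PD controller would be stabilizing, so the classical
   argument that intermittency is strictly necessary holds only in the
   small-$D$ regime.
3. **Passive ankle damping.** $B_a = 35$ N m s/rad (rather than ~10)
   flattens the very-low-frequency wander of the near-neutral orbit so
   that the CoP spectral exponent over 0.02–0.2 Hz settles near the
   hallmark value (about 1.63 on 1000-s runs at default noise) instead
   of drifting toward the random-walk value of 2.

With these defaults the model reproduces the three quiet-stance
hallmarks of intermittent control: a noiseless steady-state tilt
oscillation of ~0.013 rad peak amplitude, an $f^{-\beta}$ low-frequency
CoP spectrum with $\beta \approx 1.6$, and a CoM–CoP upward
zero-crossing rate of ~1.0 Hz.

One perturbed-stance showcase is *not* reproduced at these defaults:
terminating the reflexive controller at 0.23 s instead of 0.25 s is
supposed to convert a clean single switch-OFF into chattering-like
ON–OFF switching. In this re-derivation the chattering requires a
delay-relay at the OFF boundary, which needs $P \gtrsim 0.33\,K_{load}$;
calibrations in that regime do produce exactly the clean/chattering
dichotomy at the 0.25/0.23 s offsets, but they steepen the long-run CoP
exponent to 1.8–1.95 and were rejected in favor of the spectral
hallmark. The corresponding test is kept and fails at defaults, by
design.

## Phase-plane analytics

`linearize_off()` reduces the control-OFF dynamics to the
single-link-equivalent tilt coordinate
($I_{eq}\ddot\theta = (K_{load}-K_a)\theta - B_a\dot\theta$) and
returns the saddle eigenstructure; the delay-free linearization is used
deliberately — the delay-differential stable manifold is
infinite-dimensional and out of scope. `detect_switch_events()`
timestamps ON/OFF/REFLEX mode changes.

The intermittency statistic is built on
$\varepsilon(t) = \mathrm{CoM}(t) - \mathrm{CoP}(t)$: its upward zero
crossings approximate switch-OFF events, with a steady quiet-stance
rate near 1 Hz that drops sharply after a perturbation (CoM and CoP
separate widely) and recovers as stance re-equilibrates.
`off_onset_time()` defines the OFF-period onset as the earliest
post-perturbation minimum of the sliding-window crossing rate (window
2 s, step 0.1 s — chosen to resolve a ~1 Hz rate while tracking the
post-perturbation dip). `epsilon_series()` band-limits CoM and CoP to
the trembling band (zero-lag Butterworth, default cut-off 2.5 Hz)
before subtracting: the model's control torque switches
instantaneously, giving the raw model CoP a wide-band tail that
physical torque transmission (muscle activation dynamics) does not
have, and zero-crossing counts of a wide-band residual measure filter
bandwidth rather than trembling occurrence. For the same reason the
quasi-static model CoP excludes the white noise torque term, whose
$1/\sqrt{dt}$ sample scaling has no dt-convergent instantaneous value.

## Posturography

The experimental-side chain mirrors standard practice:
left/right markers are averaged after sagittal projection and inverted
to joint angles; CoM is the mass-weighted combination of the link CoMs
(HAT:LE = 0.62:0.35, mid-link CoMs), low-pass filtered with a zero-lag
4th-order Butterworth at 10 Hz, with central-difference velocities;
CoP is expressed relative to the ankle (which rides on the moving
belt) and filtered identically. All zero-lag filters use
forward-backward passes over odd-reflection-padded series, so DC is
preserved exactly and the amplitude at the nominal cut-off is ~0.5
(two −3 dB passes). Quiet-stance sway metrics are per-axis SDs and the
two-regime log-log spectral slopes (0.02–0.2 Hz and 1–8 Hz) of a Welch
PSD (Hann window, 50% overlap, segments of at least 100 s for the low
regime), fitted by ordinary least squares.

EMG envelopes follow the standard chain — zero-lag 20–450 Hz 4th-order
band-pass, full-wave rectification, zero-lag 2nd-order 15 Hz low-pass,
left/right averaging, event-locked averaging, normalization by the
peak. Inverse dynamics inverts the model's own rigid-body equations in
the accelerating support frame
($\tau = M\ddot\theta + C + G - T^{pert}$); with the feet fixed to the
support the chain torques follow from kinematics and belt acceleration
alone, so GRF/CoP inputs serve only a quasi-static consistency
diagnostic. Samples inside the finite-difference support of a
support-acceleration discontinuity are flagged (`transition`): no
differentiation scheme can recover an instantaneous torque step, and
the forward/inverse round trip is accurate to well under 5% outside
those samples.

## EEG analysis

Preprocessing is deliberately light (the synthetic EEG is generated
clean): resampling to the analysis rate, a zero-lag first-order 1 Hz
high-pass, and average re-referencing. ERPs are event-locked means;
peaks are located in polarity-specific windows (P1 [20, 90] ms
positive, N1 [90, 200] ms negative, P2 [200, 400] ms positive, N2
[400, 700] ms negative) after a 20 Hz zero-lag low-pass and refined to
sub-sample latency by parabolic interpolation — both standard guards
against residual-noise peak jitter.

Time-frequency analysis uses complex Morlet wavelets on a 2–60 Hz grid
with 0.5 Hz spacing. The cycle count grows linearly with frequency
from 3 at the lowest frequency with growth factor 0.5 (the convention
of the reference EEG toolbox); samples within three wavelet SDs of an
epoch edge are flagged invalid. ERSP averages power across epochs
*before* the dB transform (dB of mean), with the per-frequency
baseline taken as the mean power over [−5, −1] s before the event; at
the lowest frequencies the usable baseline starts slightly inside that
window because of the wavelet edge zone. Significance uses the
baseline-resampling bootstrap: per replicate, one baseline time point
is drawn per epoch, the surrogate across-epoch mean power forms the
per-frequency null distribution, and cells outside the two-tailed
percentile band at $\alpha = 0.05$ are significant; masked
presentations set non-significant cells to 0 dB. The type-I error of
this procedure is verified to be $\approx \alpha$ on stationary noise.

Inter-trial coherence is the length of the mean unit phase vector
across epochs; its null mean is $\tfrac{\sqrt\pi}{2} n^{-1/2}$
($\approx 0.14$ at $n = 40$), and significance defaults to the
Rayleigh approximation $p = e^{-nR^2}$ with a permutation alternative.
Band summaries use theta 4–7, alpha 8–12 (the Methods convention is
adopted over the 8–13 variant that appears in one figure caption),
low-beta 13–20, high-beta 21–30 and gamma 40–60 Hz. The onset of a
sustained band-limited ERS is the earliest time from which at least
half the band's bins stay significant with the right sign for at least
200 ms. The baseline-vs-quiet-stance check runs paired Wilcoxon
signed-rank tests per 0.5 Hz bin with Benjamini–Hochberg FDR
correction (the named variant is a package choice; the source of the
procedure only cites the FDR idea). Note a structural property at
$n = 9$ participants: the smallest attainable signed-rank p-value is
$2^{-8}$, so after FDR correction across 117 bins a genuine shift
confined to a handful of bins cannot reach significance — the
confinement property, not per-bin power, is what the tests assert.

## Synthetic data and what it does (not) show

`synth_trial()` generates complete multi-rate trial recordings from
one noisy model run with repeated perturbations (default 20 events at
20 s spacing): markers by forward kinematics plus 0.5 mm Gaussian
jitter at 300 Hz (ankle markers ride on the belt), force-plate CoP/GRF
at 1200 Hz in the global frame, and EMG at 1000 Hz as unit-variance
noise carriers with burst envelopes peaking 150 ms (soleus, medial
gastrocnemius) and 200 ms (tibialis anterior) after each onset.
`synth_eeg()` builds epochs as $1/f$ background (RMS 6 µV — a
post-cleaning residual level at which the stated recovery contracts
hold at 40 epochs), plus phase-locked Gaussian-windowed ERP templates
(P1/N1/P2 at 41/116/264 ms and +5.1/−17.2/+8.5 µV, the group means of
perturbed-stance studies; N2 at 450 ms with a representative −6 µV)
and non-phase-locked band-limited modulations implemented as
multiplicative envelope gains on the band component of the background:
a high-beta event-related desynchronization peaking at 0.45 s, a
long-lasting high-beta synchronization (beta rebound) over 1–4 s
peaking at 3.27 s, and a theta desynchronization over 1–4 s, each ±8 dB
at peak with raised-cosine edge ramps (100 ms) and a tilted plateau so
the planted peak time is identifiable. Because ERPs are additive and
identical across epochs while the modulations ride on per-epoch noise,
inter-trial coherence separates the phase-locked early response from
the non-phase-locked ERD/ERS exactly as intended.

What passing recovery tests does *not* show: the generator contains no
volume conduction, no artifacts (blinks, muscle, line noise), no
inter-individual variability, and its ERD/ERS band edges coincide with
the analysis bands. Success on synthetic recovery validates the
*analysis chain*, not the physiological claims; real recordings would
add preprocessing stages (artifact rejection, component removal) that
are explicitly out of scope here.

## Problem sizes and numerical choices

Default test and validation scales were chosen to keep every
statistic's Monte-Carlo error well below its tolerance: 1000-s
simulations replicated over up to 40 seeds for the spectral exponent
(per-seed SD ~0.14), 300-s runs for crossing rates, 40 epochs at 250 Hz for the
EEG recovery contract, 500 bootstrap replicates and 20 seeds for the
type-I calibration. The integrator's convergence is checked by step
halving (≤1% change in the perturbed tilt at 5 s from a 0.5 ms base
step). Ties and degenerate inputs follow explicit rules: switching
boundaries belong to the OFF region (the passive default), equal
crossing-rate minima resolve to the earliest window, all-tied Wilcoxon
bins are flagged and excluded from the FDR adjustment, and zero
wavelet coefficients are excluded cell-wise from ITC.
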