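---
title: "The muscle-tendon model behind mtusim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The muscle-tendon model behind mtusim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtusim)
```

## The scientific question

When the torque-angular-velocity relation (T-&omega;-r) of the plantar
flexors is measured on an isokinetic dynamometer, two experimental choices
contaminate the inference back to the fibers' force-velocity relation:
whether the muscle is *preloaded* (fully activated under fixed-end
conditions before the joint is released) and how *compliant* the Achilles
tendon is.  A preloaded, stretched tendon recoils during the rotation, so
the contractile element (CE) shortens more slowly than the joint kinematics
suggest and produces more force than a non-preloaded contraction at the
same angular velocity.  `mtusim` implements a gastrocnemius medialis (GM)
muscle-tendon unit (MTU) model with which these two factors can be varied
independently - something impossible in vivo - together with the
dynamometry/EMG/ultrasound processing chain used on recorded trials and a
synthetic trial generator that makes the chain testable end to end.

## Model structure

The MTU is a lumped Hill-type CE in series with a tendon, spanning a path
of length $\ell^P(\theta) = \ell^P_{ref} - r\,\theta$ behind the ankle
($\theta$ in radians, plantar flexion positive, constant moment arm
$r = 5.6$ cm), so the path velocity is $v^P = -r\omega$.  The CE acts at a
pennation angle $\alpha$ with $\ell^{CE}\sin\alpha$ constant
($\alpha_o = 32.5^\circ$ at the optimal length $\ell_o^{CE} = 3.78$ cm).
The default GM parameters are $f_o^{CE} = 894.7$ N, tendon slack length
$\ell_s^T = 40.1$ cm (Achilles tendon plus aponeurosis), and a maximum
shortening velocity of $10\,\ell_o^{CE}/\mathrm{s}$.  A second parameter
set ($\ell_o^{CE} = 5.1$ cm, $\alpha_o = 9.9^\circ$, $f_o^{CE} = 1308$ N,
`muscle_architecture_alt()`) is used to confirm that the study's
conclusions do not hinge on the CE architecture.

Activation follows first-order dynamics with a 15 ms activation and 50 ms
deactivation time constant.  The force balance along the tendon,

$$ f^T(\varepsilon)\; [\,+\,\beta^T v^T/f_o^{CE}\,] \;=\;
   \big(a\,f^L(\tilde\ell)\,f^V(\tilde v) + f^{PE}(\tilde\ell) +
   \beta\,\tilde v\big)\cos\alpha , $$

is solved for the normalized fiber velocity $\tilde v$ at every instant
(damped equilibrium).  The fiber damping $\beta$ regularizes the classic
elastic-equilibrium formulation, which is singular at zero activation -
necessary here because the non-preloaded protocol starts from rest.  On the
concentric branch the balance reduces to a quadratic with a closed-form
root; the eccentric branch is solved by safeguarded Newton iteration.  The
two-state system (activation, fiber length) plus the cumulative CE work is
integrated by an embedded Dormand-Prince 5(4) method with dense 1 kHz
output; all derived channels are recomputed from the state at every emitted
sample, so the force-balance residual column in a trace certifies the trace
itself.

## Characteristic curves

The source study delegates the curve shapes to its reference
implementation's defaults without printing coefficients, so the exact
shapes are a replication choice.  `mtusim` uses smooth $C^1$ curves
matching that implementation's default anchors:

* **Active force-length** `eval_fl()`: cubic Hermite segments with compact
  support on $(0.4441, 1.8123)$, a steep ascending limb to a shoulder at
  $\tilde\ell = 0.73$ (value $0.767$), a shallow ascending segment of slope
  $0.8616$ into the optimum, and a smooth descending limb.  The
  ascending-limb shoulder matters: it sets the static torque-angle curve on
  which both the calibration and the quasi-static work integral depend.
* **Force-velocity** `eval_fv()`: a Hill hyperbola on the concentric
  branch with curvature $a/f_o = 0.45$.  This value reproduces the
  reference implementation's corner-blended default (endpoint slopes 5 and
  0.25, curviness 0.6) at interior points, and is noticeably "fatter" than
  the classic $a/f_o = 0.25$ hyperbola; with $0.25$ the fast-velocity work
  values come out markedly lower.  The eccentric branch is a saturating
  exponential approaching 1.4 with a matched slope at $\tilde v = 0$, so
  the curve is $C^1$ and has a closed-form inverse on both branches
  (`inv_fv()`).  Velocities below $-1$ clamp to zero force with a warning.
* **Passive force-length** `eval_fpe()`: zero up to the optimal length,
  cubic growth reaching 1 at a CE strain of 0.7 beyond optimal.
* **Tendon force-strain** `eval_ft()`: a quadratic toe ending at
  $2\varepsilon_o/3$ (normalized force 0.5), then linear with slope
  $1.5/\varepsilon_o$, so the tendon carries $f_o^{CE}$ exactly at its
  nominal maximum strain $\varepsilon_o$ - 4.9% for the typical tendon,
  9.2% for the highly compliant one.  The associated stiffness
  $K^T = (f_o^{CE}/\ell_s^T)\, df^T\!/d\varepsilon$ and damping law
  $\beta^T = 0.05\,K^T(\ell^T)$ are exposed as `tendon_stiffness()` and
  `tendon_damping_beta()`.  Tendon damping is off by default and exists
  for sensitivity experiments; it has little effect on the headline
  results.

## Protocols and calibration

`calibrate_path_offset()` places the MTU origin so that the *active*
fixed-end torque-angle curve (fully activated minus passive) peaks at 17
degrees of dorsiflexion.  Because the moment arm is constant, static torque
depends on the angle only through the path length; the calibration
therefore reduces to a one-dimensional maximization and is exact to the
optimizer tolerance.  Using the active rather than the total torque is
essential: the passive curve grows without bound at long lengths and would
otherwise push the "peak" to the end of the range.

Simulated trials (`simulate_trial()`) rotate from 15&deg; dorsiflexion to
15&deg; plantar flexion at a prescribed constant angular velocity, sampled
at 0&deg; (`sample_at_angle()`).  Preload is a *force* criterion: the 50%
condition finds the constant excitation whose steady fixed-end force at the
start angle is half of the fully excited value (`preload_excitation()`),
since "50% of MVIC" describes force, not activation.  The 0&deg;/s grid
point is the fixed-end reference contraction at 0&deg; against which each
profile is normalized.

## CE work accounting

`ce_work()` integrates $F^T\cdot(-v^{CE}_{AT})$ from excitation onset to
the first 0&deg; crossing; preloaded trials include the tendon-stretching
work of the preload phase.  For the 0&deg;/s condition the work is the
quasi-static limit of the shortening protocol
(`ce_work_quasistatic()`): full activation at the start angle followed by a
quasi-static rotation to 0&deg;, i.e. tendon strain energy at the end state
plus the integral of the static torque-angle curve.  A fixed-end
contraction at 0&deg; alone cannot be the intended quantity: its CE work
equals the tendon strain energy, which for the typical tendon is bounded by
a few joules for any convex force-strain curve anchored at
$(\varepsilon_o, f_o^{CE})$, far below the reported magnitude, and the
0&deg;/s work explicitly includes the work of rotating the ankle to the
target angle.  In the quasi-static limit the preloaded and non-preloaded
protocols coincide (the state depends only on the angle), which is why
`ce_work_quasistatic()` takes no preload argument.

Energy bookkeeping closes by construction for an undamped elastic tendon:
$W_{CE} = \Delta E_T + W_{out}$.  `energy_closure()` checks this with the
analytic strain-energy function and a phase-wise output-work integral (the
path velocity is discontinuous at rotation onset and stop, so trapezoids
must not straddle those corners); with tendon damping enabled the residual
is the dissipated energy and must be non-negative.

## Fitting tendon compliance

`fit_tendon_strain()` estimates $\varepsilon_o$ from an observed normalized
profile by bounded scalar minimization of the sum of squared torque errors
against re-simulated profiles.  For Monte-Carlo studies,
`build_towr_cache()` precomputes profiles on an $\varepsilon_o$ grid
(step 0.0025) and the fit interpolates them with natural cubic splines;
the profile varies smoothly and slowly with $\varepsilon_o$ on this scale,
so the interpolation error is far below the fit tolerance of $10^{-4}$
strain.  Flat, rigid-like objectives are reported at the search boundary
with a warning rather than silently returned.

## The in vivo chain and its synthetic test bed

The processing chain mirrors the experimental pipeline: torque smoothed by
a 4th-order dual-pass 10 Hz Butterworth low-pass; gravity and passive
torque removed via a polynomial (degree &le; 4) fitted to passive trials
(the original correction procedure lives in an unavailable supplement; the
polynomial is this package's documented stand-in); moment arms from the
tendon-excursion method scaled by 1.22; GM force as torque &times;
0.159 / moment arm; EMG offset-corrected, band-passed 10-450 Hz (450 Hz =
0.45 of the 1 kHz rate, the closest realizable corner to the nominal
500 Hz Nyquist edge), rectified, and smoothed with a 75 ms moving average;
fascicle velocity as the least-squares slope of the sparse 61.5 Hz
length channel; angular velocity at 0&deg; from a 6 Hz zero-lag-filtered
angle derivative.  All zero-phase filters use odd-reflection end padding:
without it the filter's start-up transient corrupts the fixed-end MVIC
maximum by several percent.

The synthetic generator (`generate_invivo_trial()`, `generate_battery()`)
drives the simulator through the recorded protocol: fixed-end preload at
15&deg; dorsiflexion, rotation triggered when the simulated torque exceeds
95% of the steady fixed-end maximum, and trapezoidal dynamometer kinematics
with a 400&deg;/s&sup2; crank acceleration that decelerates to stop at the
end of the range.  Under that stop constraint the peak attainable velocity
over 30&deg; is $\sqrt{400 \times 30} \approx 109.5$&deg;/s, so settings of
120&deg;/s and above produce triangular profiles and a warning - the
generator stores both the setting and the true velocity at 0&deg;, and the
chain uses the measured one.  Gaussian noise is added per channel (defaults:
torque 0.5 N m, angle 0.05&deg;, EMG floor 0.02 mV, fascicle 0.05 cm,
excursion length 0.2 mm - magnitudes typical of dynamometry, surface EMG
and manual ultrasound digitization); EMG is synthesized as 20-450 Hz
band-limited noise amplitude-modulated by activation, a plumbing choice
with no counterpart in the source study.  The fascicle channel can emit
either the simulated CE length or, as a chain-validation mode
(`fascicle_mode = "linear"`), an idealized linear-in-time shortening at a
rate proportional to the trial's angular velocity at 0&deg;.

What the generator deliberately does not emulate: soft-tissue artifact,
dynamometer compliance and heel lift, antagonist torque (the TA channel is
noise only, matching the decision to monitor but never subtract
co-contraction), inter-subject variability, and ultrasound image formation.
Passing chain-recovery tests therefore show the *processing* is faithful,
not that these real-world nuisances are harmless.

## Numerical choices and edge cases

* Integrator: embedded RK 5(4), relative tolerance $10^{-8}$, absolute
  $10^{-10}$, maximum step 2 ms, restarted at every kinematic or
  excitation breakpoint so steps never straddle a discontinuity.  Halving
  the tolerances changes sampled torques by well under 0.01%.
* Fiber damping default $\beta = 0.1$ (force in units of $f_o^{CE}$ per
  unit normalized velocity) - small enough to leave the T-&omega;-r
  essentially unchanged, large enough to keep the velocity solve regular
  at $a = 0$.
* With a slack tendon and zero activation the damped formulation yields
  zero fiber velocity (no force gradient, no motion) rather than making
  the CE follow the path; the tendon simply grows slacker.  This differs
  from the purely elastic formulation's convention but only affects
  passive, force-free transients.
* Static solves bracket the along-tendon CE length by a sign-change scan
  followed by bisection to machine precision; degenerate no-tension
  geometries place the tendon exactly at slack.
* Problem sizes: block studies run 21 velocities per condition (eight
  conditions for the two-factor design plus 50% preload); compliance fits
  use a five-velocity subset; the synthetic battery uses ten settings
  between 20 and 200&deg;/s.  A full block simulates in about a second on
  one core, which keeps Monte-Carlo envelopes cheap.

## Known limitations

The model is GM-only; simulated torques are a fraction of whole-joint
dynamometer torques, and all profile comparisons are made on normalized
torque for that reason.  The moment arm is constant by design.  The exact
default curve coefficients of the reference implementation are not printed
in the source study; fidelity beyond the documented anchors is a
replication choice, and reported CE work values are sensitive to the
ascending-limb and concentric-curvature shapes at roughly the ten-percent
level.  History-dependent force depression/enhancement is out of scope.
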