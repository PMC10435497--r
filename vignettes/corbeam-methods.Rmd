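---
title: "Modelling and minimizing off-target neuronal excitation in LIFU neuromodulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and minimizing off-target neuronal excitation in LIFU neuromodulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(corbeam)
```

## The problem

Low-intensity focused ultrasound (LIFU) can excite neurons reversibly and
non-invasively, but the acoustic focus of a phased-array transducer is never a
point: sidelobes, the elongated axial focal lobe, and skull reverberation
deposit intensity into brain tissue away from the target.  Wherever that
off-target intensity crosses the neuronal excitation threshold, unintended
spiking is elicited.  `corbeam` quantifies this side effect as the
**off-target activation area (OTAA)** and minimizes it by optimizing the
complex per-element drive of the array.

## Acoustic model

An M-element array at frequency $f$ drives each element $m$ with a constant
sine of amplitude $A_m$ and phase $\phi_m$, collected in the complex drive
vector $w_m = A_m e^{-i\phi_m}$.  In the linear steady state the pressure
phasor at a grid point $G$ is the superposition
$\tilde p(G) = h(G)^H w$, where the column $h(G)$ holds the per-element
transfer coefficients.  The time-averaged intensity is the quadratic form

$$ I(G) = \frac{|h(G)^H w|^2}{2\rho(G)c(G)} = w^H Q(G)\, w, \qquad
   Q(G) = \frac{h(G)h(G)^H}{2\rho(G)c(G)}, $$

with $\rho$, $c$ the local density and sound speed.  $Q(G)$ is Hermitian,
positive semi-definite and rank 1; the package never materializes it,
working with the factored columns instead.

Two solvers produce $h(G)$:

* `greens_transfer()` — the analytic outgoing 2-D line-source Green's
  function $H_0(kr)\,e^{-\alpha(f) r}$ for homogeneous media, with power-law
  attenuation $\alpha(f)=\alpha_0 (f/1\,\mathrm{MHz})^y$ converted to Np/mm.
  A unit drive is calibrated to 1 Pa at 1 mm; only relative patterns and the
  target-intensity scaling matter downstream.
* `helmholtz_transfer()` — a frequency-domain finite-difference (FDFD)
  solution of the heterogeneous Helmholtz equation with a second-order
  5-point stencil, complex-coordinate-stretching PML (12 cells by default)
  and one sparse LU factorization shared by all element sources.  Sub-cell
  element positions are preserved by bilinear source spreading.  Skull
  reflection and refraction enter through the spatially varying complex
  wavenumber.  In homogeneous water the two solvers agree to well under 5%
  relative L2 error at 30 cells per wavelength; with the 5-point stencil the
  dominant error is numerical dispersion, so accuracy degrades gracefully as
  resolution drops toward the 6 cells-per-wavelength floor (a warning is
  issued below 10).

The phase convention pairs the $H_0^{(1)}$ Hankel function with decaying
$\mathrm{Im}\,k>0$ absorption; every exported quantity depends only on
relative phases and magnitudes, so the conjugate convention would produce
identical results.

## Neuronal response and the OTAA

Biophysical simulations of ultrasound neuromodulation (intramembrane
cavitation models) predict sharp intensity thresholds for spiking:
about 0.05 W/cm² for 100 ms continuous waves and about 0.45 W/cm² for
pulsed waves at 1 kHz PRF and 36% duty cycle.  `neuron_response_model()`
emulates this behaviour with two thresholds:

* $I_h$ — the excitation threshold the target must reach, modelled by a
  strength–duration (rheobase/chronaxie) curve
  $I_h(d) = I_r(1 + \tau/d)$ with $I_r = 0.05/1.2$ W/cm² and
  $\tau = 20$ ms, calibrated so $I_h(100\,\mathrm{ms}) = 0.05$;
  for pulsed waves it is multiplied by $(1/\mathrm{duty})^{2.15}$, which
  reproduces 0.45 W/cm² at 36% duty and degenerates to the continuous
  threshold at 100% duty.
* $I_l = \mathrm{ratio}\cdot I_h \le I_h$ — a conservative off-target
  threshold (default ratio 0.6) providing a robustness margin.

Above threshold, `spike_count()` grows logarithmically with intensity and
linearly with duration for continuous waves, and more slowly — with a
configurable non-monotonic dip — for pulsed waves of low duty cycle; counts
are floored to integers and capped at one spike per millisecond.  These
curve shapes are qualitative: only the thresholds and monotonicity carry
scientific weight, and any intensity-to-count function can be plugged in.

The OTAA of a drive $w$ is

$$ S(w) = \sum_{G \ne G^*} \chi\big(I(G) - I_l\big), \qquad
   \text{s.t. } I(G^*) \ge I_h, $$

with $\chi$ the closed step function ($\chi(0)=1$), the sum running over the
brain mask only, and the area reported as cell count times cell area.
Exposure of supportive tissue (skin, skull) is reported as a separate
diagnostic, not as part of the OTAA.  `otaa()` refuses nothing but flags
`target_excited = FALSE` whenever the constraint fails, and the pipeline
marks such OTAA values invalid.

## Beam focusing methods

All three methods operate on the power sphere $\|w\|_2^2 = P$ (we take
$P = 1$ without loss of generality).

**Conjugate (time-reversal)**: $w = \sqrt P\, h(G^*)/\|h(G^*)\|$, the exact
maximizer of target intensity — the benchmark equivalent of standard
focusing practice.

**Off-target suppression benchmark**: maximize the (phase-anchored) target
response $\mathrm{Re}(h(G^*)^H w)$ subject to $\|w\|^2 \le P$ and per-point
caps $I(G_i) \le \mathrm{cap}\cdot t$, $t$ the achieved target intensity.
Two implementation choices were genuinely open:

* *Cap set.* Capping every off-target cell is structurally infeasible on a
  grid — the diffraction-limited focal lobe several millimetres long
  carries near-target intensity for every admissible drive, so a hard cap
  there admits no solution.  By default the caps therefore exclude the
  conjugate beam's connected focal lobe above `cap` times its target
  intensity (found by flood fill and one-cell dilation), which turns the
  method into classical sidelobe-constrained pattern synthesis; a fixed
  exclusion radius can be supplied instead.
* *Solver.* The convex subproblem at fixed $t$ is solved by projected
  gradient with quadratic-penalty continuation on the normalized cap
  violations ($\lambda = 1, 10, 100, 1000$), wrapped in a damped fixed
  point on $t$; this vectorizes over thousands of control points where
  cyclic projections would not.  A collapsing fixed point (caps the
  geometry cannot meet) or a residual violation above 5% is reported via
  the `infeasible` flag with the best iterate returned.

**CORB** minimizes the count itself.  Substituting the power constraint
turns the counting objective into
$\sum_{G\ne G^*} \chi\!\big(w^H Q^*(G) w\big)$ with
$Q^*(G) = Q(G) - \frac{I_l}{I_h} Q(G^*)$ (rank ≤ 2, kept factored).  The
step function is smoothed by a logistic $\big(1+e^{-\mu w^H Q^* w}\big)^{-1}$
and minimized by projected gradient
$w^{(n+1)} = \mathbb P\big(w^{(n)} - \gamma\,\mu D_\mu w^{(n)}\big)$, where
$D_\mu$ is the logistic-derivative-weighted sum of the $Q^*(G)$ and
$\mathbb P$ renormalizes to the power sphere.  Numerical choices:

* *Initialization* at the conjugate drive $w_{\mathrm{conj}}$.
* *Continuation in $\mu$*: 4 stages multiplying $\mu$ by 10, starting where
  the largest $|\mu\, w^H Q^* w|$ at initialization is about 1 — a sharp
  logistic at the start has vanishing gradients almost everywhere.
* *Step size*: initialized from the first gradient norm and adapted by an
  Armijo-style backtracking halving (acceptance on non-increase), growing
  1.5-fold after clean steps; this makes the per-stage objective trace
  provably non-increasing.
* *Stopping*: iterate displacement below $\beta = 10^{-6}$ or 2000
  iterations per stage; ties at $\chi(0)$ count as activated.
* The algorithm is deterministic given the field; randomness exists only in
  test-instance generation.

On two-element instances the gradient-projection solution matches an
exhaustive grid search over amplitude split (step 0.005) and phase
difference (step 0.005 rad) in at least 90% of seeded cases and is never
worse by more than one activated point — evidence that the smoothing
continuation does not get trapped far from the global optimum at small
scale.  At realistic scale no global guarantee is claimed (the problem is
non-convex and discontinuous); the suite instead asserts the orderings the
method must deliver.

Because the OTAA evaluation scales the drive so that $I(G^*)$ equals the
stimulation intensity and counts cells above the fixed $I_l$, the ratio the
optimizer must use is $I_l / I(G^*)$ — the spec'd $I_l/I_h$ only when the
target is driven exactly at threshold.  `run_experiment()` derives this
effective ratio automatically, and `run_sweep()` re-fits the
optimization-based methods at every swept operating condition for the same
reason (the conjugate drive needs no refit).  Rescaling the solution so
that $I(G^*) = I_h$ provably preserves the activated set, since both
criteria reduce to the same sign condition on $w^H Q^* w$; the suite
verifies this identity exactly.

## Resolution lower bound

Even optimal beamforming cannot beat diffraction.  For a homogeneous medium
the package approximates the conjugate OTAA of a focused continuous line
aperture (length $L$, range $R$, wavelength $\lambda$) by quadrature of the
aperture integral — lateral pattern $\mathrm{sinc}^2(Lx/\lambda R)$, axial
pattern from the on-axis Fresnel integral — and derives a lower bound
$S_{LB}$ as **one quarter of the mainlobe superlevel-set area at the given
intensity ratio**: the uniform aperture has the narrowest mainlobe
attainable without superdirective drive, and aggressive power-normalized
apodization is credited with at most a factor-2 narrowing per dimension.
The closed-form derivation this reconstructs is not publicly available, so
the bound is validated operationally: it is never violated by the measured
conjugate or CORB areas on homogeneous CSF and white-matter phantoms across
0.25–1 MHz, it is monotone non-increasing in frequency and aperture (within
the focusing regime $R < L^2/4\lambda$), and it omits attenuation, so the
bound is evaluated at a nominal 1540 m/s soft-tissue sound speed for all
media — CSF and white matter then share one curve, as the underlying
analysis intends.  Outside the focusing regime (aperture too small to focus
at the requested range) the far-field pattern degenerates and monotonicity
in aperture no longer holds; the functions warn in that regime.  The bound
assumes no skull: `bound_validation_curve()` refuses heterogeneous media.

## Synthetic phantoms and study conditions

`make_head_phantom()` emulates a 2-D head cross-section as concentric
annuli — skin, one-layer homogeneous skull, CSF, brain — with registered
acoustic properties (overridable): water/CSF (1007 kg/m³, 1504 m/s,
0.05 dB/(MHz^y·cm)), grey/generic brain (1046, 1546, 0.6), white matter
(1041, 1562, 0.8), skull (1900, 2800, 8.0), skin (1109, 1624, 0.4).  A seed
perturbs the layer boundaries with a smooth angular jitter (0.15 mm
default) so phantoms are not perfectly circular yet bit-reproducible.
Three deployments mirror the study conditions: a transcranial arc on the
skin, a single intracranial arc on the dura, and a synchronous double
intracranial arc (one combined drive vector).

What the phantom does **not** emulate: a real segmented head raster (the
layers are annuli, not anatomy), skull heterogeneity (one homogeneous
layer), 3-D geometry, nonlinear propagation and thermal effects, and
biophysical neuron dynamics (the response model is a calibrated threshold
curve).  Passing tests therefore demonstrate the internal consistency and
the comparative claims of the method — orderings, monotonicities, bound
non-violation — not absolute areas for any real head.

## Default problem sizes

The packaged experiments use a 128 × 128 grid at 0.5 mm (transcranial head
phantom, 32 elements) and 96 × 96 grids at 0.5 mm for the homogeneous
intracranial setups (16 and 16 + 16 elements), all with control-point
stride 2;
solver-oracle comparisons run on a 64 × 64 grid at 0.1 mm (30 cells per
wavelength).  At 0.5 mm and 500 kHz the shortest wavelength (water, 3 mm)
is resolved by 6 cells — adequate for counting activated cells and for
comparisons that share one field, while the dispersion warning reminds the
user that absolute field accuracy would need a finer grid.  Control-point
subsampling by a stride speeds the optimizers roughly proportionally but
blinds them to the skipped cells; at stride 2 the optimized drives retain
their orderings against the full-grid activation count, while coarser
strides start to leak intensity into cells the optimizer never saw.

## Known limitations

* The suppression benchmark and the lower bound are reconstructions of
  methods whose original formulations are not publicly available; both are
  documented above and validated through the properties they must satisfy.
* The 5-point FDFD stencil is dispersive; quantitative field accuracy needs
  ≥ 20–30 cells per wavelength, far above the counting resolution used in
  the comparative experiments.
* OTAA is a 2-D areal metric; 3-D volumes, brain-region-specific neuron
  types, PRF selectivity, inhibition and network propagation of spikes are
  out of scope.
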