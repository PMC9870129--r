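---
title: "Models and methods behind ratefield"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ratefield}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`ratefield` simulates and analyzes a two-population neural field: excitatory
and inhibitory firing-rate variables $r_e(x,t)$, $r_i(x,t)$ on the unit
interval (1D ring) or unit square (2D torus) with periodic boundaries,

$$\tau_e \,\partial_t r_e = -r_e + \phi\!\big(W_{ee}\, g_{\sigma_e}\!*r_e
  + W_{ei}\, g_{\sigma_i}\!*r_i + I_e\big),$$
$$\tau_i \,\partial_t r_i = -r_i + \phi\!\big(W_{ie}\, g_{\sigma_e}\!*r_e
  + W_{ii}\, g_{\sigma_i}\!*r_i + I_i\big),$$

where $\phi(u)=\max(u,0)^2$ is the rectified-quadratic transfer function,
$*$ is periodic spatial convolution with a Gaussian footprint of width
$\sigma_\beta$ (a fraction of the domain length), $W_{\alpha\beta}$ are mean
connection strengths, and $I_\alpha$ is the external input — a static drive
$\mu_\alpha$, optionally with Ornstein–Uhlenbeck noise. The reference
parameter set is $W_{ee}=80$, $W_{ei}=-160$, $W_{ie}=80$, $W_{ii}=-150$,
$\tau_e=5$ ms, $\sigma_e=0.1$, $\mu_e=0.48$, $\mu_i=0.32$; the inhibitory
scales $\tau_i$ (ms) and $\sigma_i$ are the swept control parameters. These
choices encode three generic cortical features: distance-dependent
connectivity, inhibition slower than excitation, and a power-law
rate-response function.

The periodic Gaussian kernel is defined spectrally: its Fourier coefficient
at integer mode $\vec n$ is $\tilde g(\vec n, \sigma) =
\exp(-2\|\vec n\|^2\pi^2\sigma^2)$ (a wrapped Gaussian). Because
$\tilde g(0)=1$, convolution preserves spatial means, and spatially uniform
states evolve exactly by the two-unit reduction
$\tau_\alpha \dot r_\alpha = -r_\alpha + \phi(W_{\alpha e}r_e +
W_{\alpha i}r_i + \mu_\alpha)$.

# Numerics

**Integration.** Classical fixed-step RK4 with default $dt=0.1$ ms
($\tau_e/50$; the constructor enforces $dt \le \tau_e/10$). With noise the
OU input is held constant over each step and updated by its exact
discretization at step boundaries; since $\tau_n = 5\,\mathrm{ms} \gg dt$
the input is effectively smooth on the step scale. Plain Euler stepping
with held noise is numerically unstable at $dt=0.1$ ms in
the stiff pattern-forming corner of the sweep (large $\tau_i$, small
$\sigma_i$, strong noise), whereas held-noise RK4 is stable there at the same
step; a single integrator family also keeps noiseless and noisy trajectories
directly comparable. Halving $dt$ from $0.025$ ms changes a 1 s regular
(oscillatory) trajectory endpoint by $<10^{-4}$ relative; at the default
$dt=0.1$ ms the accumulated phase error over 1 s of oscillation is about
0.5%, irrelevant for the attractor statistics studied here.

**Spatial coupling.** The spectral convolution is implemented two ways that
agree to machine precision and are cross-checked in the tests against an
$O(N^2)$ direct wrapped-Gaussian sum: an FFT multiply (`apply_coupling`,
the definitional route) and, inside the compiled integrator, the separable
circulant form $G F G$ with $G$ the symmetric circulant matrix built from
the 1D mode coefficients — the wrapped Gaussian factorizes across axes, and
dense $50\times 50$ BLAS products are several times faster than FFTs of
that size in this environment.

**Grid.** The reference grid is $100\times100$ per population; analyses in
the tests and the acceptance script run at $32^2$ or $50^2$. These sizes
are chosen on spectral grounds: at the widths studied
($\sigma \ge 0.03$) the kernel coefficient at $k=8$ is already
$\tilde g \le 10^{-5}$, so a $32^2$ grid resolves every mode that the
coupling can amplify, and the stability analyses are grid-free (they work
on integer wave numbers directly). Coordinates are cell centers
$(i+\tfrac12)/n$, so 1D and 2D code share indexing. We verified that the
chaotic example's Lyapunov exponent and spectral statistics are stable
across $32^2$, $50^2$ and $100^2$.

**Overflow guard.** $\phi$ is quadratic, so badly balanced parameters can
genuinely diverge; any rate above $10^6$ aborts with the offending step
rather than propagating `Inf` through a sweep.

**Degenerate inputs.** $\phi'(0)$ is taken as 0 (left and right limits of
$2\max(u,0)$ agree). The fixed-point solver (damped Newton from a coarse
grid scan) requires a residual below $10^{-10}$; for the reference
parameters the fixed point is unique, which we checked by excluding the
rectified boundary branches analytically and by an exhaustive refined grid
search in the tests.

# The analysis chain

**Two-unit reduction** (`two_unit_fixed_point`, `hopf_point`,
`find_limit_cycle`, `bistability_interval`). The Hopf point is located by
bisection on the leading eigenvalue's real part (the fixed point itself
does not depend on $\tau_i$); for the reference parameters the crossing is
at $\tau_i = 7.8016$ ms, with trace zero and positive determinant. The
limit cycle is detected from upward mean-level crossings of $r_e$ with
local quadratic interpolation, averaged over the final $\ge 10$ cycles;
this is robust for the strongly pulse-like orbits this model produces. The
bistability window's lower edge uses a hysteresis sweep (decreasing
$\tau_i$ in 0.01 ms steps, 2 s of integration per step, re-seeding from the
previous endpoint, amplitude-collapse threshold $10^{-4}$), which brackets
the cycle's fold without a boundary-value solver; the computed window is
$[7.16, 7.80]$ ms.

**Mode-wise linear stability** (`fixed_point_stability`,
`bulk_oscillation_stability`). Linearizing around the uniform fixed point
in Fourier space gives a $2\times2$ Jacobian per wave number whose coupling
entries are scaled by $\tilde g(k,\sigma_\alpha)$; the scan covers integer
$k = 0..50$ (beyond $k=50$, $\tilde g < e^{-2\pi^2 \cdot 50^2\sigma^2}
\approx 0$ for every $\sigma \ge 0.03$, and verdicts are tested to be
cutoff-invariant). For the bulk oscillation, the variational system along
the cycle has periodic coefficients; the monodromy matrix $M(k)$ is
integrated by RK4 vectorized over wave numbers, with the gains
$\phi'(u^*_\alpha(t))$ obtained by periodic cubic interpolation of the
equilibrium inputs ($\phi'$ is piecewise linear, so interpolating $u$ and
then applying $\phi'$ preserves the kink; orbits carry $\ge 4000$ samples
per period and an interpolation-error estimate gates the computation). A
real multiplier below $-1$ marks period doubling (alternating patterns), a
real multiplier above $+1$ same-period pattern formation; at $k=0$ one
multiplier equals 1 (tangent direction), reproduced to $10^{-3}$ and used
as a self-check. A piecewise-constant matrix-exponential product with
$10^4$ pieces serves as the independent oracle in the tests.

**Maximal Lyapunov exponent** (`max_lyapunov`). The renormalized-
perturbation (Benettin) scheme: after a transient (default 2 s), perturb by
magnitude $d_M = 10^{-6}$ (first direction random, seeded), advance
reference and perturbed trajectories by $\Delta t = 10$ ms with identical
dynamics — and identical frozen noise — record the separation in the
Euclidean norm over the concatenated $(r_e, r_i)$ fields, renormalize, and
average: $\mathrm{MLE} = (n\Delta t)^{-1}\sum_i \log(|D z_i|/d_M)$,
reported in 1/ms. Times are stated in ms throughout, so the decision
thresholds used by the classifier (chaos above $0.005$/ms, periodic below
$0.002$/ms) apply directly. Desk-scale runs use $n = 3000$–$10^4$
renormalizations; the running-average convergence curve is attached to
every estimate, and at a stable fixed point the estimate matches the
leading mode-Jacobian eigenvalue to well under 10%.

**Input noise** (`noise_params`, `noise_paths`). Each unit receives
$I^\alpha_k = \mu_\alpha + \sigma_n(\sqrt{1-c}\,\eta^\alpha_k +
\sqrt{c}\,\eta^\alpha_c)$ with private and common OU processes
($\tau_n = 5$ ms), advanced by the exact discretization. The literal OU
equation $\tau_n\,d\eta = -\eta\,dt + dW$ has stationary variance
$1/(2\tau_n)$; by default the paths are rescaled to unit variance
(`normalize_unit_variance = TRUE`) so that $\sigma_n$ *is* the input
standard deviation — the reading under which pairwise input correlation
equals $c$ and total input variance equals $\sigma_n^2$ regardless of $c$,
both verified by sampling. The two common paths $\eta^e_c$, $\eta^i_c$ are
independent of each other: the common term is defined per population.
Every stream is seeded by a counter scheme keyed on (seed, population,
unit), so realizations are bitwise reproducible and independent of
traversal order; the private path of unit $k$ can be regenerated in
isolation and matches the one used inside the simulator.

**Population statistics** (`spatial_correlation`, `power_spectrum`,
`dimension_95`). The displacement correlation map is computed spectrally
(time-accumulated spatial power, inverse-transformed), which equals the
direct all-pairs displacement average exactly and normalizes by the
spatially averaged temporal variance, the reading of the correlation
definition under which near-homogeneous torus statistics make the single
variance term and per-pair variance products agree. Spectra use Welch's
method (Hann window, 2 s segments, 50% overlap, 1 kHz sampling — chosen
over a raw periodogram for variance reduction at desk scale; peak and
power-law exponent are insensitive to the smoothing, which the tests
check), rescaled so that $\sum S\,\Delta f$ equals the mean single-unit
variance. The power-law exponent $\gamma$ is the negative log–log slope
over 50–200 Hz (band exposed as an argument; lower edge where the spectrum
leaves its low-frequency peak structure, upper edge below Nyquist).
Dimensionality is the number of leading covariance eigenvalues (no
variance normalization) reaching 95% cumulative variance for seeded unit
samples; a white-noise control (dimension $\approx 0.95\,n$) calibrates
the criterion against trivial saturation.

**Regime classification** (`classify_regime`). The regime
taxonomy is codified as an explicit decision tree over recorded evidence
scores (temporal/spatial variance, single-unit autocorrelation peak,
dominant spatial mode and whether its 90°-rotated partner carries
comparable power — bump lattices do, stripes do not — phase-drift linearity
for traveling patterns, half-period pattern anti-correlation for
alternating ones, laminar-epoch fraction for intermittency), with all
thresholds exposed and the scores returned for audit. MLE cutoffs are
0.005 (chaos) and 0.002 (periodic). Ambiguity yields the best-scoring
label flagged `confidence = "low"`, never a silent failure.

# Attractor selection at desk scale

Several pattern states coexist at the same parameters. From spatially white
perturbations of the fixed point, moderate grids do not always reach the
attractor that a $100^2$ grid reaches: at $(\tau_i, \sigma_i) = (8, 0.1)$
random seeds on grids below $32^2$ sometimes land on a weakly chaotic
branch instead of the traveling wave, and at $(9, 0.1)$ the basin of the
alternating-stripe state is small at every size we tried. `stripe_state`
therefore provides a deterministic single-mode initial condition (fixed
point plus a cosine at the pattern's natural wave number, phase-shifted
between populations to break the standing/traveling symmetry) that
converges reliably onto the pattern branch: $k=1$ for the traveling wave
at $(8, 0.1)$, $k=2$ for the alternating stripes at $(9, 0.1)$. Analyses
that presuppose a periodic base state (the noise-collapse sweeps, the
near-zero-MLE check of the traveling wave) use it; everything else starts
from seeded perturbations, with the seed recorded in the result.

# What the synthetic data do and do not emulate

All inputs are generated by the model itself: the simulator *is* the data
generator, and every statistic is computed from trajectories produced under
the reference parameters above. The synthetic data reproduce the
qualitative phenomenology of cortical population recordings that motivates
the model — broadband single-unit power with a 1/f-like tail,
distance-dependent correlations decaying to zero on the domain scale, and
population activity confined to a few tens of dimensions. They do not
contain spiking noise, measurement noise, heterogeneous cell parameters,
non-stationary brain states, or stimulus structure; passing tests
therefore demonstrate properties of the model class, not a fit to any
recorded dataset.

# Problem sizes used by the tests and the acceptance script

The test suite runs the field analyses at $16^2$–$50^2$ with
$n = 300$–3000 Lyapunov renormalizations; the acceptance script uses
$50^2$ grids with $dt = 0.2$ ms and $n = 10^4$ renormalizations for the
Lyapunov targets, and 10 s of recorded activity at 1 ms resolution for the
statistics targets. These sizes follow the spectral-resolution argument
above and the observed insensitivity of the reported quantities between
$32^2$ and $100^2$.

# Known limitations

* Stability of traveling waves and localized bump branches is assessed by
  direct simulation and classification, not by continuation; there is no
  boundary-value solver.
* The regime classifier is heuristic by construction; near regime borders
  (e.g. intermittency) labels legitimately depend on the observation
  window, which is why the evidence scores ship with every label.
* The Lyapunov estimate at scaled $n$ carries a few-percent estimation
  error; dM-halving and convergence-curve diagnostics bound it, but values
  within $\pm 0.002$/ms of zero should be read as "periodic or marginal".
* Trajectory archival uses RDS plus CSV exporters for tabular results.
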