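---
title: "Nucleation statistics for supercooling preservation: models, fitting, and scale-up"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nucleation statistics for supercooling preservation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(supercoolr)
```

## The problem

Supercooled storage keeps a preservation solution liquid below its melting
point. Whether it stays liquid is a race against stochastic ice nucleation,
and the odds depend on two things: the *energy barrier* the container
interface presents to a critical ice nucleus, and the *statistics* of rare
nucleation events over the container's area and the storage duration. This
package treats both.

## Layer 1: nucleation barriers on nano-confined patches

### Model

Classical nucleation theory describes the critical nucleus as a spherical
cap of radius (Gibbs–Thomson)

$$R_c(\Delta T) = \frac{2\,\gamma_{WI}\,T_m}{\rho_i\,L_f\,\Delta T},$$

with $\gamma_{WI}$ the water–ice interfacial tension, $T_m$ the melting
point, $\rho_i$ the ice density, $L_f$ the latent heat, and $\Delta T$ the
supercooling degree. On an unbounded surface with intrinsic ice contact
angle $\theta_0$ (set by Young's equation from the three interfacial
tensions), the heterogeneous barrier is reduced relative to homogeneous
nucleation by the spherical-cap factor

$$f(m) = \tfrac{1}{4}(2 + m)(1 - m)^2, \qquad m = \cos\theta_0,$$

which is also the cap-to-sphere volume ratio (the test suite verifies this
identity by direct quadrature).

If the surface is icephobic except for nucleation-prone patches of maximum
diameter $L_{max}$, a patch can host an *unpinned* critical cap only while
its contact circle fits: $L_{max} \ge 2R_c\sin\theta_0$. Below that, the
nucleus is pinned at the patch rim and its contact angle is forced onto the
obtuse branch

$$\theta_i = 180^\circ - \arcsin\!\big(L_{max}/2R_c\big),$$

so the barrier ratio becomes $f(\cos\theta_i) \to 1$ as
$L_{max}/2R_c \to 0$: the zero-size effect, by which a sufficiently
nano-confined surface behaves *quasi-homogeneously*. The largest nucleus a
patch supports unpinned is $R_{max} = L_{max}/(2\sin\theta_0)$; when
$R_c(\Delta T) > R_{max}$ throughout the working range, the surface is no
easier to nucleate on than bulk water.

```{r}
patch <- patch_geometry(L_max = 2.1e-9, theta_0 = 100)
max_nucleation_radius(patch) * 1e9   # nm
cnt_curve(patch, delta_T = c(5, 15, 30))
```

### Branch choice and continuity

$\arcsin$ is double-valued on $[0^\circ, 180^\circ]$. The obtuse branch is
the physical one: along the pinned growth path the cap's curvature radius
stays below $R_c$ (free energy still rising) until the *major*-cap
stationary point, so the barrier is evaluated there; the acute branch would
also violate the homogeneous limit at $L \to 0$. For obtuse intrinsic
angles ($\theta_0 \ge 90^\circ$, the case for icephobic materials) the two
regimes meet continuously at $L_{max}/2R_c = \sin\theta_0$, and the
barrier-ratio curve has a single kink there. For acute $\theta_0$ the
pinned obtuse cap has a strictly higher barrier than the free cap at the
transition, so the model's barrier jumps upward as the patch shrinks past
the footprint — a real feature of rim pinning, not a numerical artefact.
The continuity tests therefore sweep $\theta_0$ over the obtuse range.

### Defaults

`thermo_params()` defaults — $\gamma_{WI} = 30$ mJ m⁻², $T_m = 273.15$ K,
$\rho_i = 917$ kg m⁻³, $L_f = 3.34\times 10^5$ J kg⁻¹ — are conventional
literature values for pure water and are configurable (e.g. via the `cnt:`
YAML block read by `read_cnt_config()`), since reported water–ice tensions
vary by some tens of percent. All paper-facing outputs of this layer are
ratios or lengths, which are insensitive to the absolute barrier scale.

## Layer 2: non-homogeneous Poisson freezing statistics

### Model

Nucleation events on the container interface of area $S$ form a Poisson
process with rate per area $J(\Delta T) = \gamma\,\Delta T^n$; $\gamma$ and
$n$ are empirical properties of the surface. Two regimes matter:

**Linear cooling ramp** at rate $k$ (K s⁻¹): time and supercooling are tied
by $\Delta T = k t$, so the survival probability is

$$\chi(\Delta T) = \exp\!\Big(-\frac{S}{k}\int_0^{\Delta T} J(x)\,dx\Big)
  = \exp\!\Big(-\frac{S\gamma}{k(n+1)}\Delta T^{\,n+1}\Big),$$

a Weibull law with shape $n+1$ and scale
$\lambda = (k(n+1)/S\gamma)^{1/(n+1)}$. Its mean,

$$\mathbb E[\Delta T] = \lambda\,\Gamma\!\Big(\frac{n+2}{n+1}\Big),$$

decreases with $S$ as $S^{-1/(n+1)}$ — the quantitative reason larger
preservers supercool less, and the bridge from droplet assays to
organ-scale containers (`mean_supercooling()`, `predict_scaleup()`).

The survival integrand is written per unit *area* because the container
interface is the dominant nucleation site in a quasi-homogeneous system; a
volume-dominated system obeys the same mathematics with $S$ read as a
volume and $\gamma$ in volumetric units (the units string stored with every
`rate_model` makes the convention explicit).

**Isothermal hold** at fixed $\Delta T$: the hazard $S\,J(\Delta T)$ is
constant, so waiting times are exponential with mean $t = 1/(S J)$
(`isothermal_time()`) and the freezing probability over a hold is
$P = 1 - e^{-S J t}$ (`freezing_probability()`). This closed form is the
unique consequence of the fitted rate law at constant temperature; holds
are memoryless, which the tests assert exactly. At $\Delta T = 0$ the rate
vanishes and the expected time is reported as `Inf`, a value, not an error.

### Fitting

`fit_rate_model()` maximises the Weibull/censoring likelihood: uncensored
cycles contribute the density, cycles that reached the ramp floor unfrozen
contribute $\chi(\text{floor})$. Numerical choices:

* Optimisation in $(\log\gamma,\ \log(n+1))$, which makes the domain
  unconstrained and the likelihood well scaled. $\gamma$ has a closed-form
  profile maximiser at fixed shape, so the search is effectively
  one-dimensional; the profile optimum is then polished jointly (BFGS,
  relative tolerance $10^{-14}$).
* The starting value is the graphical estimate of `fit_rate_loglog()`:
  regression of $\log(-\log\chi)$ on $\log\Delta T$ over the Kaplan–Meier
  curve (step midpoints, so the terminal zero-survival step stays usable).
  That secondary route is exported and cross-checked against the MLE on
  clean synthetic data; the MLE is also cross-checked against
  `survival::survreg`'s Weibull fit in the test suite.
* Standard errors come from the observed information at the optimum;
  confidence intervals are built on the transformed scale and
  back-transformed, so they respect $\gamma > 0$, $n \ge 0$. With 100
  cycles the nominal 95% interval for $n$ achieves ~93–97% empirical
  coverage in the bundled recovery study.
* Degenerate inputs fail loudly: all-identical supercooling degrees (shape
  unidentifiable), all-censored assays, exponent estimates escaping to the
  search bound.

`empirical_survival()` is the product-limit estimator (via
`survival::survfit`), reducing to $1-$ECDF without censoring.

### The simulator and what it does (not) emulate

`generate_assay()` / `sample_ramp_freezing()` draw supercooling degrees by
inverse-CDF sampling — exact for the Weibull law, with seeded determinism
(`withr::with_seed`, leaving the caller's RNG untouched). A deliberately
slow hazard-increment time-stepping sampler is kept in the test suite as an
independent second oracle. `synth_trace()` emulates the thermocouple
signature of a freezing cycle: a linear ramp with iid Gaussian sensor
noise, and recalescence as an instantaneous jump to the latent-heat plateau
(0 °C for pure water).

Default study conditions mirror a droplet-scale assay: cooling at
6 °C min⁻¹ ($k = 0.1$ K s⁻¹), 100 cycles per assay, droplet interface
$S = 10^{-5}$ m². The rate parameters of a real icephobic surface are not
tabulated anywhere we could take them from, so the generator's illustrative
defaults $\gamma = 10^{-3}$ m⁻² s⁻¹ K⁻ⁿ, $n = 8$ were chosen once to give
a realistic droplet-scale mean supercooling of ≈7 K with the sharply rising
rate typical of heterogeneous ice nucleation.

What the simulator does *not* model — and what passing tests therefore do
not certify about real data: thermal lag between bath and sample (real
traces jump after the bath temperature passed the nucleation point),
droplet-to-droplet heterogeneity (site-spectrum mixtures broaden the
survival curve beyond Weibull), surface aging over many cycles, and
freezing-point depression of preservation solutions (the detector's
`melting_point` argument handles the reference shift, not the chemistry).

### Event detection

`detect_nucleation()` flags the first rise exceeding `jump_threshold`
(default 1 K) across a `window` of 3 samples, scanning a lightly smoothed
copy of the trace (centred 5-sample running mean) so that single-sample
noise excursions cannot trigger it; the event time is then localised on the
raw trace as the largest single-step rise near the flagged window, which
pins the jump to within one sampling interval. The supercooling degree is
the melting point minus the *smoothed* pre-jump minimum: on a monotone ramp
the raw minimum is biased deep by the extreme-value statistics of sensor
noise (≈0.3 K at 0.1 K noise over a thousand samples), while the smoothed
minimum stays within 0.05 K. Detection is exactly equivariant under
constant temperature offsets. Thresholds are package defaults, documented
here, not inferred from any particular instrument.

### The planner

`safe_temperature()` inverts the freezing probability for $\Delta T$:
$\Delta T = (-\ln(1-\text{risk})/(S\gamma t))^{1/n}$, so
$\log \Delta T$ falls linearly in $\log t$ with slope $-1/n$.
`envelope_table()` tabulates this over labelled areas and durations. The
envelope is risk-based (a probability threshold) because storage decisions
are about acceptable failure rates; a mean-time mode (direct
$t = 1/(SJ)$) is available in the CLI as `--mode mean`. Degenerate cases
are reported, not silent: $n = 0$ has no finite solution (probability is
temperature-independent), and risks near 1 would allow unbounded
supercooling, so solutions are clipped at 273.15 K with a warning. Any
bundled organ/container areas in examples are illustrative inputs, not
measurements.

## Problem sizes used in the checks

The test suite runs the distributional oracles at $10^5$ Monte-Carlo draws
(3-standard-error and 1%-level Kolmogorov–Smirnov tolerances), the
closed-form-vs-quadrature identities at relative tolerance $10^{-8}$ or
tighter over 50 random parameter draws, the parameter-recovery and coverage
study at 200 replicate assays of 100 cycles, and the trace round-trip at
1000 seeded traces — sizes at which the whole suite completes in well under
a minute on a laptop while leaving the statistical assertions sharp.

## Known limitations

* The power law $J = \gamma\,\Delta T^n$ is an empirical surrogate for the
  exponential CNT rate over the fitted supercooling range; extrapolating a
  fitted model far beyond the assay's $\Delta T$ range inherits the
  surrogate's error.
* Scale-up assumes the large container's interface has the same $(\gamma,
  n)$ as the assayed surface and that area is the only thing that changes;
  contents (e.g. tissue surfaces) that nucleate more readily than the
  container wall would break the prediction.
* The fit treats cycles as exchangeable; surface conditioning or
  carry-over between freeze–thaw cycles would violate that silently.
* Wald intervals are asymptotic; below ~30 cycles, profile or bootstrap
  intervals would be preferable to the reported ones.
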