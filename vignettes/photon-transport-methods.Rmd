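---
title: "Monte Carlo photon transport: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monte Carlo photon transport: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photonmc)
```

photonmc solves the radiative transport equation in layered turbid media by
simulating photon random walks. This vignette documents the physical model,
the three absorption-weighting estimators, the variance accounting, the
perturbation/differential Monte Carlo machinery and the inverse solver, and
records the numerical design decisions a maintainer would want to know
about.

## The transport model

A tissue is a stack of plane-parallel layers bounded in depth ($z = 0$ is
the surface, $z$ grows downward), each with absorption coefficient
$\mu_a$ (1/mm), scattering coefficient $\mu_s$ (1/mm), scattering
anisotropy $g$ (the mean cosine of the single-scattering deflection angle)
and refractive index $n$. Air half-spaces sit above and below. One
ellipsoidal inclusion may be embedded strictly inside a layer; membership
is the quadratic test $\sum_i ((p_i - c_i)/a_i)^2 < 1$ and ray-surface
distances use the exact quadratic roots, so curved surfaces carry no
voxelization error. Voxelized, mesh-based or image-derived geometry is out
of scope.

A photon life cycle is: launch (with specular bookkeeping at an external
interface), then repeatedly sample a step length, move (truncating the
step at any boundary), account for absorption, scatter, and play Russian
roulette, until the photon exits, is absorbed, or is killed. Intercollision
distances follow $\mu \exp(-\mu s)$; because the exponential law is
memoryless, the engine resamples a fresh step after every boundary
crossing in the new region's coefficient rather than carrying a rescaled
leftover step. The two procedures are statistically identical; resampling
keeps the loop simpler and is what the unit tests pin down.

Scattering uses the Henyey-Greenstein phase function,
$\cos\theta$ drawn by inverting its CDF (with the uniform limit at
$g = 0$) and a uniform azimuth, applied in the photon's local frame with a
degenerate-pole branch when the direction is within $10^{-12}$ of
$\pm z$. A `Bidirectional` phase function is also provided for
one-dimensional slab problems: the photon continues with probability
$(1+g)/2$ or reverses with probability $(1-g)/2$. It is restricted at
validation time to a normal-incidence point source on a refractive-index
matched layered slab, because only there is the 1D closed form below
meaningful.

At refractive-index mismatched interfaces the unpolarized Fresnel average
of the s- and p-polarizations decides reflection versus Snell refraction,
with total internal reflection handled exactly. Time of flight advances by
$\ell n / c$ with $c = 299.792458$ mm/ns.

## Absorption weighting estimators

Three unbiased estimators of the same transport solution are provided:

* **Analog** — the photon carries weight exactly 1; at each collision it is
  absorbed and terminated with probability $\mu_a/\mu_t$
  ($\mu_t = \mu_a + \mu_s$); steps are sampled with $\mu_t$. Specular
  reflection at launch is a Bernoulli split so weights stay exactly 1.
* **Discrete (DAW)** — steps with $\mu_t$; at each collision the photon
  deposits $w\,\mu_a/\mu_t$ at the collision point and continues with
  $w \leftarrow w\,\mu_s/\mu_t$.
* **Continuous (CAW)** — steps with $\mu_s$; along every traveled segment
  of length $\ell$ the photon deposits $w(1 - e^{-\mu_a \ell})$ and decays
  $w \leftarrow w e^{-\mu_a \ell}$ (Beer's law), with no per-collision
  deweighting. The segment deposit is assigned to the segment midpoint for
  spatially resolved absorption tallies — the paper-silent choice that
  minimizes bin bias at the default bin sizes.

Per photon, `specular + deposited + exit weight = 1` to $10^{-12}$ under
DAW/CAW with roulette off; analog photons contribute exactly 1 to exactly
one fate. These identities are enforced by tests and make the run-level
balance `specular + A + R_d + T_d = 1` exact.

Russian roulette accelerates DAW/CAW runs: once $w$ falls below the
threshold, the photon survives with probability $P$ (weight amplified by
$1/P$) or dies. $P = 0.1$ by default — the long-standing convention of
layered-tissue MC codes, which makes roulette-on/roulette-off comparisons
meaningful. Weights that underflow to numerical zero (below $10^{-300}$,
reachable only with roulette disabled) deposit their remainder and
terminate; this is exact, since a zero weight can never contribute to a
tally. A defensive cap of $10^6$ collisions per photon exists and is
counted in the run statistics; none of the shipped benchmarks comes near
it.

## Detectors, second moments and efficiency

Exit detectors bin the photon state at the moment it leaves the tissue:
total diffuse reflectance and transmittance, $R(\rho)$, $R(x,y)$,
$R(\rho,t)$, and the frequency-domain tallies $R(f_x)$ and
$R(\rho,\Omega)$ which accumulate complex weights
$w e^{-i 2\pi f_x x}$ and $w e^{-i 2\pi \Omega t}$ so a single simulation
yields every listed frequency. History detectors accumulate absorbed
weight at interaction sites: the total absorbed fraction, $A(\rho,z)$,
and fluence $\Phi(\rho,z) = A(\rho,z)/\mu_a$ using the $\mu_a$ of the
region at the bin center (bins straddling an interface are therefore
approximate — refine the grid near boundaries if that matters).

Bins are half-open $[a,b)$ with index $\lfloor (v - a)/\Delta \rfloor$;
values beyond the final bin (or below the first) accumulate in the nearest
edge bin. This overflow convention makes the conservation identities exact
and testable: summing $R(\rho)$ bins recovers the diffuse reflectance,
summing the time axis of $R(\rho,t)$ recovers $R(\rho)$ bin-wise, and the
$A(\rho,z)$ grid sums to the total absorbed weight. Spatially resolved
means are reported per unit area (exact annulus areas
$\pi(\rho_{i+1}^2 - \rho_i^2)$ for cylindrical bins), per ns for time and
per mm for depth; totals are per-photon fractions.

With `second_moment = TRUE` a detector also accumulates the squared
per-photon contributions, giving the standard error of each bin mean as
$\sqrt{(\overline{\xi^2} - \bar\xi^2)/N}$ with no Bessel correction — the
$O(1/N)$ difference is far below the reported precision. Complex tallies
accumulate the real and imaginary squares separately. The comparative
figure of merit for estimators is the efficiency
$\mathrm{Eff} = 1/(R^2 T)$ with relative error $R = \sigma/\bar\xi$ and run
time $T$; `efficiency()` reports it.

## Databases and perturbation Monte Carlo

A run can stream every exiting photon's position, direction, weight, exit
side and time of flight to a `DiffuseReflectance` database; with
`pMCDiffuseReflectance` (discrete or continuous weighting only) it also
records the per-region path lengths $L_r$ and collision counts $j_r$. The
header stores $N$ launched, so re-tallies normalize by photons launched,
never by photons detected. Because the live tally and the re-tally share
one code path, a post-processed detector is bit-identical to the live one.
The on-disk format is deliberately plain: little-endian float64 records
plus a JSON header (collision counts are exact in doubles far beyond any
realistic count).

Perturbation MC re-weights each stored history for perturbed coefficients
$(\mu_a^*, \mu_s^*)$ in any set of regions with the likelihood ratio

$$ w^* / w \;=\; \prod_r \left(\frac{\mu_s^{*}}{\mu_s}\right)^{j_r}
   e^{-(\mu_t^{*} - \mu_t) L_r}. $$

For a CAW database with a $\mu_a$-only change this reduces algebraically
to the Beer's-law factor $e^{-\Delta\mu_a L_r}$, so one code path serves
both cases. Differential MC tallies the analytic derivative of that
multiplier: $-L_r$ for $\partial/\partial\mu_a$ and $j_r/\mu_s - L_r$ for
$\partial/\partial\mu_s$, evaluated at the perturbed point when one is
given. Perturbing $g$ or $n$ is rejected — the likelihood ratio above does
not cover them. Large perturbations are allowed rather than hard-limited,
but the reported standard errors inflate accordingly and should be
watched: the $(\mu_s^*/\mu_s)^{j}$ factor is heavy-tailed when detected
photons carry many collisions.

## The inverse solver

`mc_inverse_fit()` recovers $\mu_a$ and/or $\mu_s' = \mu_s(1-g)$ of one
region from a measured $R(\rho)$, using pMC re-tallies of a baseline
database as the forward model and dMC tallies as the Jacobian (chain rule
$\partial/\partial\mu_s' = (1-g)^{-1}\partial/\partial\mu_s$). A damped
Gauss-Newton (Levenberg-Marquardt) iteration runs on log-parameters, which
keeps them positive and the steps scale-free; accepted steps never
increase the objective and iteration stops at a relative parameter change
of $10^{-6}$ or 100 iterations. The fit is deterministic given database
and measurement.

Residuals are inverse-variance weighted (the measurement's standard errors
when supplied, otherwise relative residuals). This was a deliberate
departure from plain unweighted least squares: $R(\rho)$ spans orders of
magnitude across a detection grid and the absorption information lives in
the low-amplitude tail, so an unweighted objective is dominated by the
near-source bins and $\mu_a$ stalls around 14% error in the recovery
experiment below; with weighting it recovers to a few percent.

## What the synthetic benchmarks do and do not show

The test suite and the acceptance script validate against three kinds of
problems, all generated in code:

* **Bidirectional 1D slab** ($\mu_a = 0.01$/mm, $\mu_s' = 1$/mm,
  $g = 0.8$, matched index, 5 mm): the two-flux closed form
  ($\sigma_b = \mu_s(1-g)/2$, $\alpha = \mu_a + \sigma_b$,
  $\kappa = \sqrt{\mu_a(\mu_a + 2\sigma_b)}$,
  $R = \sigma_b \sinh(\kappa d)/(\kappa\cosh(\kappa d) + \alpha\sinh(\kappa d))$,
  $T = \kappa/(\kappa\cosh(\kappa d) + \alpha\sinh(\kappa d))$) is the
  independent oracle, giving $R = 0.68818$, $A = 0.04780$, $T = 0.26402$.
  At $N = 10^6$ the CAW estimator reproduces all three within three
  standard errors (about $4\times 10^{-4}$ on $R$).
* **Two-layer tissue** (0.1 mm with $\mu_a = 2$, $\mu_s = 20$, $g = 0.7$,
  $n = 1.3$ over a semi-infinite layer with $\mu_a = 1$, $\mu_s = 20$,
  $g = 0.9$, $n = 1.4$; air $n = 1$ above): specular reflectance equals
  the normal-incidence Fresnel closed form 0.0170 exactly, and at
  $N = 10^5$ under DAW with roulette threshold $10^{-4}$ the diffuse
  reflectance and absorbed fraction land within a few parts per thousand
  of the established multi-layer benchmark values (0.1049 / 0.8780).
  $N = 10^5$ rather than $10^6$ keeps the default validation run fast;
  the tolerance scales accordingly.
* **Isotropic recovery phantom** ($\mu_a = 0.012$/mm, $\mu_s' = 1.2$/mm,
  $g = 0$, 10 mm slab, $R(\rho)$ on 20 bins to 6 mm): synthetic
  "measurements" are independent simulations (different seed) at truth
  parameters drawn within $\pm 30\%$ of the baseline; the pMC/dMC fit
  recovers both parameters with median relative error below 5% from an
  $N = 10^5$ baseline database. The phantom is isotropic on purpose:
  with $g = 0.8$ the detected photons carry enough collisions that the
  pMC scattering reweighting becomes heavy-tailed near $+30\%$ and the
  recovery quality depends on the database realization. That is a real
  limitation of pMC at large scattering perturbations, not of the fit.

Passing these does not certify behaviour the generators do not emulate:
real detector noise models, index-mismatched inverse problems,
wavelength-dependent chromophore fitting (which needs external extinction
spectra and is out of scope), or heterogeneous geometry beyond a single
ellipsoid.

## Numerical details worth knowing

* **Randomness.** One Mersenne Twister stream per (sub-)run, consumed as
  raw 32-bit draws mapped into (0,1), so runs are bit-reproducible across
  platforms for a fixed seed. `seed = -1` draws a seed from the system and
  records it in the output so the run can be replayed. `cpucount = k`
  executes k sequential sub-simulations on seeds $s, s+1, \dots$ and pools
  tallies and second moments; independence rests on distinct seeds of a
  long-period generator, a documented approximation rather than
  guaranteed-disjoint substreams.
* **Boundary nudge.** After every crossing the position advances
  $10^{-9}$ mm along the new direction before the next region query,
  avoiding on-surface ambiguity; a step landing exactly on a boundary
  resolves to the crossing branch (a measure-zero tie).
* **Degenerate media.** A region with a zero step coefficient is traversed
  ballistically; a photon heading down in a semi-infinite bottom layer
  with nothing ahead and no interaction possible is terminated defensively
  (absorbed if $\mu_a > 0$).
* **Tie-breaks and overflow.** Half-open bins, overflow to edge bins,
  collision-on-boundary resolved to the boundary branch — all chosen so
  that conservation identities are exact rather than approximate.
* **Problem sizes.** The shipped tests run the full study conditions where
  the benchmarks state them ($N = 10^6$ for the 1D slab, $N = 10^5$ for
  the two-layer tissue and each recovery fit); smaller $N$ appears only in
  unit tests whose assertions are scaled to their own standard errors.
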