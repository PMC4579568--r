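---
title: "From ring positions to motor mechanics: the models behind dyneinflex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From ring positions to motor mechanics: the models behind dyneinflex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyneinflex)
```

## The problem

Side-view cryo-EM projections of dimeric dynein bound to a microtubule
(MT) show each AAA+ ring as a circle at a variable height above the MT
surface. The motor flexes almost entirely at one hinge, the
stalk-stalkhead junction near the MT surface, so the ring centre moves on
an arc of fixed radius about that hinge. That single fact lets a set of
simple, auditable calculations turn per-particle ring coordinates into
mechanics: the stalk angle of every motor, the position of its MT-binding
stalkhead, the torsional stiffness of the hinge, the tension transmitted
between the two heads of a dimer, and the stiffness of the elastic
linkage connecting them. `dyneinflex` implements that chain, together
with a synthetic-data generator that makes every stage testable without
micrographs.

## Geometry: one hinge, one arc

Each motor is a rigid body hinged `hinge_height` nm above the MT surface.
With `ring_to_hinge` the (constant) distance from ring centre to hinge,
a measured ring height $h$ gives the stalk angle

$$\theta = \arcsin\!\left(\frac{h - h_0}{L_{rh}}\right),$$

and the stalkhead sits on the MT surface minus-end-ward of the ring at

$$x_{head} = x_{ring} + L_{rh}\cos\theta .$$

All axial coordinates increase toward the MT minus end (the stepping
direction). Defaults: $L_{rh} = 18.8$ nm (measured mean ring-to-hinge
distance) and $h_0 = 1.8$ nm. The hinge height is not directly
measurable in projections; 1.8 nm is the unique value consistent with
the observed mean ring height (14.4 nm) at the observed mean stalk angle
(42 degrees), and it is an exposed parameter of `motor_geometry()`, not
a hard-wired constant.

Numerical edges: measurement noise can push the arcsine argument past 1.
Arguments in $(1, 1.02]$ are clamped to 90 degrees and flagged; larger
arguments, or heights at or below the hinge, are unmeasurable and
`measure_particles()` drops those rows (reporting the count) rather than
guessing.

Within a dimer, roles are assigned by *stalkhead* position, not ring
position: the leading motor is the one whose stalkhead is anchored
farther toward the minus end. Because stalk angles scatter widely, the
two stalks sometimes cross, in which case the leading stalkhead belongs
to the ring that trails; the ring-centre separation is then negative.
Exact stalkhead ties are broken toward the lower particle id and flagged
ambiguous — arbitrary, but deterministic and visible.

## The MT lattice

Stalkheads bind at tubulin-dimer intervals (8.3 nm) along a
protofilament; adjacent protofilaments of the 14-protofilament, 3-start
lattice are staggered by 0.9 nm, and a dimer straddling the seam picks up
an extra ~4 nm. `site_axial_offset()` composes these three terms, and
`separation_classes()` enumerates the resulting stalkhead separations
(0.9, 8.3, 16.6, 24.9 nm and their stagger partners). The seam is a
single boolean offset, not full helical indexing: nothing downstream
needs more, and the seam offset itself is only known to ~1 nm, so it is a
parameter.

## Mechanics chain

**Equipartition.** A torsion spring explored thermally at temperature
$T$ has angular variance $\sigma^2 = k_BT/\kappa$, so

$$\kappa = \frac{k_BT}{\sigma^2}, \qquad k_BT = 4.045\ \mathrm{pN\,nm\ at\ 293\ K}.$$

Angle standard deviations use denominator $n-1$ and are converted to
radians only inside this formula; all interfaces speak degrees because
that is how the measurements are reported.

**Cantilever stiffness.** An axial force applied at the base of the
stalk (where the linker ends, lever $L = L_{rh} - r_{head} = 12.3$ nm
from the hinge) works through the moment arm $L\sin\phi$, so the
apparent axial stiffness of an attached motor at mean angle $\phi$ is
$k = \kappa/(L\sin\phi)^2$. The per-class mean angles (41.9, 42.7,
41.5 degrees for leading, trailing, superposed) are used rather than a
generic 42 degrees; this is what reproduces the reported stiffness
triplet to the printed precision.

**Tension.** If mean stalk angle responds to stalkhead separation with
slope $m$ (degrees per nm, from an unweighted OLS fit — the observed
relation is linear and no error model for individual angles is
available), torque balance at the hinge gives the inter-head tension
growth per nm of separation:

$$T' = \frac{\kappa\,|m_{rad}|}{L\sin\phi}.$$

Multiplying the leading/trailing average $T'$ by a lattice separation
gives the time-averaged tension for that configuration.

**Tether stiffness.** All elements between the two rings carry this
tension in series, so dividing a tension increment by the corresponding
increment in mean ring-centre separation estimates the stiffness of the
head-head linkage. The package computes the ring-separation increments
from the two angle regressions in either of two conventions:

* `as_published` — a first-order linearization about the regression
  intercepts. This reproduces the reported ring separations (-0.1, 6.6,
  14.2, 21.7 nm at the four lattice separations) and is the default for
  report generation.
* `geometric` — exact evaluation of
  $x - L_{rh}\cos\theta_l(x) + L_{rh}\cos\theta_t(x)$ along the
  regression lines. This is self-consistent with the forward geometry
  (and is what the synthetic-data closure tests use), but differs from
  the linearized values by up to ~1 nm at small separations (about +0.9
  nm at $x = 0$). The exact derivation behind the published linearized
  values cannot be reconstructed from their description, so both
  conventions are kept side by side rather than silently reconciled;
  `mechanics_report(mode = ...)` records which one was used.

**Running averages.** Trends of angle against separation are also shown
as 100-point sliding-window means (window slid one point at a time over
separation-sorted data). The window of 100 matches the scale at which
the angle scatter (s.d. ~13 degrees) averages down to ~1.3 degrees,
comparable to the systematic change across one 8.3-nm lattice step.

**Association equilibrium.** Among dimers whose stalkheads are
superposed (0.9-nm class), the ratio of superposed-ring to offset-ring
counts estimates the unloaded equilibrium constant of the head-head
association, $K \approx 10$.

## The synthetic-data generator

The generator is the package's stand-in for micrographs: a Boltzmann
mechanical model on the lattice. A dimer with stalkheads `sep` apart has
energy

$$E(\theta_t, \theta_l) = \tfrac12\kappa_t(\theta_t-\theta_0)^2
 + \tfrac12\kappa_l(\theta_l-\theta_0)^2
 + \tfrac12 k_{teth}\,(\delta(\theta_t,\theta_l) - d_0)^2,$$

with $\delta = sep - a\cos\theta_l + a\cos\theta_t$ the axial elongation
of the tether between the two attachment points at radius $a$ from the
hinges. Three modelling choices deserve explanation:

* **Tether attachment at the lever point** ($a$ defaults to
  `lever_length` = 12.3 nm, the base of the stalk where the linker ends,
  not the ring centre). This is where the torque-balance formula above
  applies the force, so the generator and the estimator describe the same
  physics. It is also what makes the generated angle-separation slopes
  come out near the observed ±0.2 degrees per nm at
  $\kappa \approx 71$ and $k_{teth} = 0.035$ pN/nm; attaching the tether
  at the ring centre (18.8 nm) would inflate the slopes by ~50% and break
  the closure between the generator and the estimation chain. The radius
  is exposed as `tether_attach` for sensitivity checks.
* **Rest elongation $d_0 = 0$**: the superposed configuration is the
  observed zero-strain state.
* **Rest angle 42 degrees**, the common mean of all three angle
  distributions.

Sampling is by Metropolis random walk in $(\theta_t, \theta_l)$:
Gaussian proposals of s.d. 5 degrees, 1,000-step burn-in, thinning 10,
run as many independent vectorized chains (10 draws per chain). The
cosine coupling makes the joint density non-Gaussian, so no closed-form
sampler exists in general; Metropolis is exact for any energy, and the
tests validate its moments against direct grid quadrature of the density
(400x400 in the coupled case). Draws are bitwise reproducible given
(parameters, seed). A sampled angle outside the measurable (0, 90)
degree range (well under 1% of dimers at the default stiffnesses) would
have no side-view interpretation and is dropped at table-building time;
the samplers themselves are left untruncated so equipartition closures
stay unbiased.

`generate_particles()` assembles a study-condition data set: class
weights 0.45/0.35/0.15/0.05 over the 0.9/8.3/16.6/24.9-nm separations
(most stalkheads ~8 nm apart, fewer at ~16, few at ~24), the 0.9-nm
class split 10:1 between superposed and offset rings by the association
equilibrium, 0.5-nm Gaussian measurement noise on ring coordinates, and
150-nm spacing along the MT so the ±40-nm isolation rule finds every
molecule. Superposed dimers carry twice the monomer pixel sum, which is
what the pixel-sum classifier (threshold 1.5x monomer, boundary
inclusive — the midpoint of the expected 1x and 2x) keys on. The toy
micrograph renderer draws the same quantities as images (uniform MT
band, annular rings, line-segment stalks, additive intensities, pale
protein on a zero-mean background) so the pixel-sum measurement itself
can be exercised at chosen signal-to-noise ratios.

What the generator does *not* emulate: contrast transfer, projection of
azimuthal geometry, alignment and classification errors, seam-crossing
dimers, crowded regions (placement is available via `place_on_mt()` but
the default table is sparse), and any correlation between the two heads
beyond the tether. Passing closures therefore validate the estimation
chain, not the microscopy: they show that *if* molecules behave like the
elastic model, the pipeline recovers the model's parameters.

## Kinetics

Run lengths, durations and velocities are fitted by least squares on the
empirical CDF evaluated at the sorted data points — no histogram, hence
no bin choice: an exponential with a detection floor,
$F(l) = 1 - e^{-(l - l_0)/l_{mean}}$, for runs and durations, and the
Gaussian $F(v) = \tfrac12(1 + \mathrm{erf}((v - v_{mean})/\sqrt{2\sigma^2}))$
for velocities.

Duty ratios use the independent-heads formalism: each mechanical cycle
the run ends only if both heads are detached at once, probability
$(1-r)^2$, so the per-cycle survival is $q = 1-(1-r)^2$ and run lengths
are geometric. The solver finds $r$ such that a run of $N$ steps is the
*median*: $q^N = \tfrac12$, by bisection to $10^{-8}$. The median
criterion is adopted because it reproduces the full reported triplet
(36, 72, 144 steps giving 0.86, 0.90, 0.93) and closes against the
stochastic simulator (`simulate_runs()`), whose median run at
$r = $ `duty_ratio(N)` is $N$ steps within sampling error. The
alternative mean-run criterion $N = 1/(1-r)^2$ is provided behind
`criterion = "mean"`; the two differ in the third decimal at these $N$.
Note one formalism quirk the analysis scripts surface explicitly: for
geometric runs the fitted exponential mean exceeds the median by
$1/\ln 2$, so duty ratios quoted from a fitted mean and from a run
median differ slightly; the reported values correspond to treating the
600-nm figure as the criterion run length.

`atp_budget()` closes the loop on experimental validity: at the imaging
concentrations (0.66 uM heads, 3.7 uM MT, $k_{cat}$ 15 /s per head,
$K_m$ 2.5 uM) the Michaelis-Menten consumption over the ~46 s between
ATP addition and freezing leaves >3 mM of the starting 3.6 mM ATP, so
the imaged molecules are stepping in effectively constant ATP.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `axial_repeat` | 8.3 | nm | tubulin dimer repeat along a protofilament |
| `pf_stagger` | 0.9 | nm | lateral stagger of the 14_3 lattice |
| `seam_extra_offset` | 4.0 | nm | approximate extra offset across the seam |
| `ring_to_hinge` | 18.8 | nm | measured mean ring-centre-to-hinge distance |
| `head_radius` | 6.5 | nm | AAA+ ring radius; fixes lever = 12.3 nm |
| `hinge_height` | 1.8 | nm | inferred from 14.4-nm mean ring height at 42 deg |
| `kappa_leading/trailing/superposed` | 72 / 71 / 101 | pN nm rad^-2 | equipartition values from the angle s.d.s |
| `rest_angle` | 42 | deg | common mean stalk angle |
| `tether_stiffness` | 0.035 | pN/nm | head-head linkage stiffness |
| `tether_attach` | lever (12.3) | nm | torque-balance consistency (see above) |
| `thermal_energy` | 4.045 | pN nm | $k_B \cdot$ 293 K |
| `pair_window`, `exclusion` | 40, 40 | nm | isolation rule, axial distances |
| dimer/monomer threshold | 1.5 | x monomer | midpoint of expected 1x and 2x |
| `window` | 100 | points | running-average window |

## Problem sizes and tolerances

The test suite runs the samplers at $n = 2\times10^4$ to $10^5$ draws
(seconds per call with the vectorized chains), the tether-recovery chain
at $10^4$ dimers per separation class, run-length closures at $10^5$
runs, and the isolation filter against its brute-force oracle on 1,000
random fields. Monte-Carlo comparisons use ~3 standard errors with a
conservative effective sample size of $n/10$ to allow for residual chain
correlation; the equipartition closure demands recovered $\kappa$ within
5%, and the full regression-tension-stiffness chain recovers the tether
stiffness within 25% — the slack is dominated by the linearization bias
of the chain, not by sampling noise (the observed error is ~10-15%).
The analysis scripts under `analysis/` use 4,000 dimers and 5,000 runs,
which keeps the whole workflow under a minute while leaving counting
errors at the few-percent level.

## Known limitations

* Heights are perpendicular distances in the projected side view; motors
  bound azimuthally away from the MT silhouette edge would be
  foreshortened, and nothing in the package models that.
* The equipartition estimate pools angles across separation classes when
  applied to a full dimer table; the systematic angle-separation trend
  then inflates the apparent variance slightly (a few percent on
  $\kappa$, visible in the analysis output), and measurement noise adds
  $\approx (noise/L_{rh}\cos\theta)$ of angular spread. Neither
  correction is applied automatically — the reported values are what the
  method yields on the data given to it.
* The published linearized ring-separation convention and the
  self-consistent geometric one genuinely disagree at small separations;
  users must choose a `mode` and report it.
* Run statistics assume a single exponential population with a hard
  detection floor; mixtures or photobleaching are out of scope.
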