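---
title: "Modelling light-directed maskless DNA microarray synthesis"
author: "masSim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling light-directed maskless DNA microarray synthesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(masSim)
```

# The system being modelled

Maskless array synthesis (MAS) builds DNA microarrays by projecting
"virtual masks" from a digital micromirror device (DMD) onto a glass
substrate. Each synthesis cycle couples a phosphoramidite carrying a
photolabile 5'-NPPOC protecting group, then exposes selected features to
~365 nm light to deprotect them for the next coupling. Three coupled
processes decide sequence quality:

* **Photodeprotection kinetics.** NPPOC removal is first order in the
  remaining protected groups, so after a radiant exposure $D$ the
  protected fraction is $e^{-D/\tau}$, with $\tau$ the dose constant
  (default 2.5 J/cm^2 in `PhotolysisParams`-style arguments; all
  simulator doses are expressed in $\tau$-units).
* **Coupling chemistry.** Each coupling succeeds with stepwise
  efficiency $\gamma$ (defaults around 0.99, the efficiency of current
  MAS chemistry); failures produce single-base deletions unless capped.
* **Optical contrast.** Diffraction, flare and back reflection deliver a
  stray dose $d/R$ to nominally dark sites ($R$ the contrast ratio),
  deprotecting them with probability $1 - e^{-d/(\tau R)}$ and causing
  insertions at the next amidite delivery.

The closed-form correct-sequence yield of an $N$-mer under the
one-base-per-four-cycles protocol is

$$Y(R, d) = (\gamma\,\delta_{Bright})^N\,(1 - \delta_{Dark})^{3N},
\qquad \delta_{Bright} = 1 - e^{-d},\quad
\delta_{Dark} = 1 - e^{-d/R},$$

with $d$ in $\tau$-units. `correctSequenceYield()` evaluates it exactly
(never through an $e^{-N p}$ approximation), and the interior maximum in
$d$ has the closed form implemented by `optimalDose()`:

$$d^\ast = \ln\!\left(1 + \frac{R}{n_{dark}}\right),$$

independent of $\gamma$ and $N$ ($n_{dark} = 3$ for the four-cycle
protocol; for arbitrary schedules `darkExposureCount()` supplies the
actual count).

```{r}
optimalDose(350)
correctSequenceYield(0.99, 350, 25, optimalDose(350))
```

# The optical model

`aerialImage()` implements scalar Fourier imaging of the rasterized mask.
Each ON mirror is a reflective square of side `mirrorPitch - mirrorGap`
(defaults 13.68 um and 1 um; the 1:1 Offner relay maps the DMD directly
onto the synthesis plane). In the default coherent mode (the projection
system homogenizes the illumination to effectively zero partial
coherence) the amplitude is low-pass filtered by a circular pupil of
cutoff $NA/\lambda$ cycles per micrometre and the magnitude squared; the
incoherent option convolves the intensity with the diffraction point
spread via the standard circular-aperture OTF.

Numerical choices:

* **Frequency-domain filtering with periodic boundary**, guarded by at
  least 4 mirror pitches of zero padding per side; frequencies exactly at
  the cutoff are excluded (strict `<`), which makes the filter
  deterministic under grid changes.
* **Plateau normalization.** Every image is divided by the mean interior
  intensity of the central mirror of a 9x9 all-ON calibration block
  computed with identical settings, so "1" always means the nominal
  exposure of an ON synthesis pixel. Gap and stray-light levels quoted by
  the package (e.g. by `gapCenterIntensity()`) are therefore fractions of
  the ON-pixel plateau.
* **Gibbs ringing.** True coherent imaging of sharp squares overshoots:
  along the central line through mirror centres the peak stays below 1.3x
  the plateau (the classical edge-ringing bound, asserted by the test
  suite), but 2D corner peaks reach ~1.5-1.7x. This is a property of
  coherent physics, not a numerical artifact; real systems blur it with
  residual partial coherence.
* **Sampling.** The default 0.25 um grid resolves the 1 um gap with four
  samples and oversamples the pupil cutoff ~9-fold; a Nyquist check
  rejects configurations whose grid cannot represent the cutoff.

With these defaults, the all-ON pattern leaves the inter-mirror gap at
about 40% of the ON-pixel plateau, and a lone ON mirror leaks about 10%
of its exposure into the adjacent gap — diffraction alone cannot darken
the 1 um gaps, which is why gap regions grow short spurious
oligonucleotides:

```{r}
m3 <- aerialImage(maskPattern(matrix(1, 3, 3)))
gapCenterIntensity(m3, 2, 2, "right")
```

Stray-light terms are modelled separately and additively:

* `globalFlare()` — spatially homogeneous, linear through the origin in
  the ON-mirror fraction, anchored at the measured 0.1% of direct
  irradiance at 64% ON. At a typical 25%-ON step this gives 0.039%,
  i.e. a flare-only contrast denominator of 2560.
* `addBackReflection()` — the reflection from the rear face of the
  quartz block, the dominant local-flare term, modelled as one laterally
  shifted scaled copy of the image (a small tilt of the thick block walks
  the reflection onto neighbouring pixels; default offset two pitches,
  reflectance 0.25% coated / 3.75% uncoated from `fresnelReflectance()`).
* `addEdgeScatter()` — mirror-edge scattering, a narrow additive
  Gaussian kernel along all mirror-cell boundaries. Only an upper bound
  on its magnitude is measurable (0.1% of direct irradiance), so the
  amplitude is a free parameter capped at 0.001.

# Scheduling

`cyclicSchedule()` turns designs into per-cycle masks. Designs are stored
5'→3' but deposition proceeds 3'→5' (the surface linker end first), so
scheduling walks the reversed strings; this follows the physical
substrate-first chemistry. The base delivery order is fixed at A, C, G, T
— the order is a free convention with no effect on any statistic. Two
modes are provided:

* **naive** — the one-base-per-four-cycles protocol: block $k$ deposits
  base position $k$ of every design, so length-$N$ designs take exactly
  $4N$ cycles and each feature accumulates $3N$ dark exposures on a
  dense array.
* **skip-empty** — the greedy cyclic schedule: a feature couples whenever
  the cycle base matches its next-needed base and all-OFF cycles are
  dropped. Minimum-length (shortest-common-supersequence) scheduling is
  deliberately out of scope; externally optimized mask sets can be loaded
  with `readMasks()`.

Both modes satisfy the deposition invariant — replaying any generated
schedule with perfect chemistry reproduces every design — which the test
suite asserts on random designs. Streets (multi-mirror dark margins) and
inverse capping (an initial CAP cycle whose mask is the street/unused
mirror set) are expressed in `arrayLayout()`.

# The stochastic simulator

`simulateSynthesis()` tracks, per reaction site, the assembled strand,
a free-hydroxyl flag and a capped flag. Exposure either applies the
aggregate first-order law $1 - e^{-d_{site}}$ or draws explicit photon
arrivals (Poisson counts apportioned by inverse-transform sampling of
the intensity distribution, each photon succeeding with the quantum
efficiency). The two modes agree in law because the quantum efficiency
is calibrated as `1/photonsPerTau` (`calibrateQuantumEfficiency()`), a
closed-form identity rather than an empirical tuning. Coupling and
capping are zero-order events applied with their efficiencies; oxidation
is treated as fully efficient and is not simulated.

Two modelling decisions deserve emphasis:

* **Deprotected state persists.** A 5'-OH that failed to couple remains
  reactive in later cycles; since amidite delivery is global, it couples
  the next delivered base. The schedule-driven simulator therefore
  produces substitution-like errors the closed form does not know about.
* **The scalar oracle mode is memoryless.** `scalarSimulate()` simulates
  exactly the independence assumptions of the closed-form yield model:
  per designed base, one bright exposure/coupling and `nDarkPerBase`
  independent dark exposures whose stray deprotections couple the
  upcoming base. Its event statistics converge to
  `expectedErrorRates()` and `correctSequenceYield()` by construction,
  which makes it a stochastic cross-check of the closed forms (and vice
  versa) rather than a second free model.

Default scales are chosen for desk runtimes: 4x4 reaction sites per
mirror, hundreds to thousands of replicates per design, seeds recorded
in every product set. All randomness flows through one seeded generator
per run, so results are bit-reproducible.

# Error analysis and parameter fitting

`globalAlign()` is a unit-cost global aligner (no affine gaps — no
scoring scheme is implied by the data, so the simplest defensible
convention is used) with a deterministic traceback preference
match > substitute > delete > insert. Rates are normalized per design
base, and terminal truncations count as deletions. `computeErrorStats()`
aggregates over a product set; `fitSynthesisParams()` inverts the closed
forms by coarse grid search over $(\gamma, d, \log R)$ followed by
Nelder-Mead refinement, minimizing summed squared *relative* deviations
so the small insertion rate is not swamped by the deletion rate.

A caution the package makes explicit: alignment-measured rates are not
the same observable as synthesis-event rates. An inserted copy of the
next base adjacent to a deletion of that base aligns as a match, and
adjacent insertion-deletion pairs align as one substitution, so at high
error rates alignment undercounts both indel classes. For that reason
`scalarSimulate()` also records its true event counts
(`eventErrorStats()`), the quantity the closed forms predict; the
alignment route is validated against the closed forms at gentle error
rates where the merging bias is negligible.

```{r}
er <- expectedErrorRates(0.983, 340, 2.1)
pm <- correctSequenceYield(0.983, 340, 70, 2.1)
fitSynthesisParams(list(deletionRate = er$deletion,
                        insertionRate = er$insertion,
                        perfectMatchFraction = pm), N = 70)
```

# Synthetic data

The fixture generators produce exactly the study designs the estimators
expect: `genCouplingSeries()` the twelve-point terminally-labelled
length series with intensity $\gamma^{n-1}$ and multiplicative Gaussian
noise; `genDoseResponse()` the 13-step 0-30 J/cm^2 exposure gradient
with additive noise; `genDesigns()` uniform random designs, optionally
as 70-mers (15-mer primer + 40-mer core + 15-mer primer). They emulate
the statistical structure of the calibration experiments — exponential
decay, saturating dose response, seeded noise — but none of the
systematic effects of real arrays: spatial intensity gradients,
scanner saturation, surface quenching, background subtraction errors, or
sequencing/PCR artifacts in product pools. Passing tests therefore
demonstrate correctness of the estimators and simulator under the
model's own assumptions, not instrument-level accuracy.

# Known limitations

* Instrument-scale experimental observables that depend on raw chip
  data (sequencing-measured rates of real arrays, per-chip stepwise
  efficiencies, externally optimized mask sets) are outside what a desk
  model can reproduce; the package covers them through the closed-form
  consistency checks described above.
* Vector diffraction, polarization, DMD blaze effects, partial
  coherence, depurination and strand cleavage are out of scope.
* The measured "about 50% of maximum" gap intensity is reproduced as
  40% of the ON-pixel plateau; the squared-magnitude coherent model
  cannot push the 1 um gap higher at NA 0.08, and coarser simulation
  grids (which cannot resolve the gap bottom) read higher. The package
  reports the resolved value.
* Problem sizes in the tests (9x9 calibration blocks, 3x3 patterns at
  0.25 um, $10^4$ scalar replicates of 70-mers, alignment oracles over
  all 2-letter strings up to length 6) were chosen as the smallest
  scales at which the statistical assertions are sharp.
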