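# masSim

Modelling and simulation of light-directed **maskless array synthesis
(MAS)** of DNA microarrays, for synthesis chemists and gene-assembly
pipeline developers who need to reason quantitatively about sequence
error before (or instead of) sequencing a chip.

In MAS, a digital micromirror device projects "virtual masks" of ~365 nm
light onto a glass substrate; exposed features lose their photolabile
5'-NPPOC protecting group and couple the next phosphoramidite. Sequence
quality is set by three interacting quantities: the stepwise coupling
efficiency γ, the photodeprotection dose *d* (in units of the dose
constant τ ≈ 2.5 J/cm²), and the optical contrast *R* between bright and
dark synthesis sites. The package implements the closed-form
correct-sequence yield of an *N*-mer under the one-base-per-four-cycles
protocol,

    Y(R, d) = (γ δ_Bright)^N (1 − δ_Dark)^(3N)
    δ_Bright = 1 − e^(−d),   δ_Dark = 1 − e^(−d/R)

with its closed-form optimal dose `d* = ln(1 + R/3)`, together with
everything needed to simulate and analyse a synthesis end to end:

* **Optics** — coherent/incoherent scalar Fourier aerial images of
  virtual masks (`aerialImage`), global flare (`globalFlare`), Fresnel
  back reflection (`fresnelReflectance`, `addBackReflection`),
  mirror-edge scatter (`addEdgeScatter`), contrast ratios
  (`contrastRatio`).
* **Photochemistry** — dose response and τ fitting (`fitTau`),
  coupling-efficiency fits `f(n) = A e^(−bn)` (`fitCouplingEfficiency`),
  capping efficiency (`cappingEfficiency`).
* **Yield model** — `correctSequenceYield`, `optimalDose`,
  `expectedErrorRates`, full-length yield fold changes.
* **Mask scheduling** — cyclic base-deposition schedules with
  dark-exposure accounting (`cyclicSchedule`, `darkExposureCount`),
  PBM mask round-trips (`writeMasks`/`readMasks`).
* **Monte-Carlo synthesis** — per-site stochastic simulation emitting
  FASTA-writable products (`simulateSynthesis`, `scalarSimulate`).
* **Error analysis** — unit-cost global alignment (`globalAlign`),
  insertion/deletion/perfect-match statistics (`computeErrorStats`),
  synthesis-parameter recovery (`fitSynthesisParams`).

## Worked example

Optimal dose and yield for a 25-mer at contrast 1/350 with 99% coupling:

```r
library(masSim)
optimalDose(350)
#> [1] 4.767856
correctSequenceYield(0.99, 350, 25, optimalDose(350))
#> [1] 0.2262048
```

So at the yield-optimal exposure of ~4.77 τ, about 23% of 25-mers are
perfect copies — deletions from the remaining protected fraction and
stray-light insertions consume the rest.

Simulate a synthesis at the parameters recovered from sequenced arrays
(γ = 0.983, d = 2.1 τ, R = 340, 70-mers) and compare the simulator's
event statistics with the closed forms:

```r
ps <- scalarSimulate(0.983, 2.1, 340, 70, replicates = 2000, seed = 7)
eventErrorStats(ps)
#> ErrorStats: deletion 0.137, insertion 0.01866, substitution 0 per design base
#>   perfect match 0 (2000 products, 140000 design bases)
expectedErrorRates(0.983, 340, 2.1)
#> $deletion
#> [1] 0.1373893
#> $insertion
#> [1] 0.01816075
```

The simulated deletion rate (0.137 per design base, one per ~7 bases)
matches the closed form, and recovering the generating parameters from
closed-form statistics inverts the model exactly:

```r
er <- expectedErrorRates(0.983, 340, 2.1)
pm <- correctSequenceYield(0.983, 340, 70, 2.1)
fitSynthesisParams(list(deletionRate = er$deletion,
                        insertionRate = er$insertion,
                        perfectMatchFraction = pm), N = 70)
#> SynthesisFit: gamma 0.983, d 2.1 tau, R 340 (objective 1.4e-15)
```

Diffraction at NA 0.08 leaves the 1 µm inter-mirror gap of an all-ON
pattern at ~40% of the ON-pixel plateau — the reason gap regions grow
short spurious sequences:

```r
m3 <- aerialImage(maskPattern(matrix(1, 3, 3)))
gapCenterIntensity(m3, 2, 2)
#> [1] 0.4003537
```

See `vignettes/mas-model.Rmd` for the model assumptions, numerical
choices and limitations.

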