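test_that("quantum-efficiency calibration reproduces the aggregate dose law", {
  expect_equal(calibrateQuantumEfficiency(100), 0.01)
  # per-photon deprotection probability equals 1 - exp(-d I) for any
  # photon budget: P(no success) = E[(1-q)^K], K ~ Poisson(ppt * d * I)
  for (ppt in c(5, 50, 500)) {
    q <- calibrateQuantumEfficiency(ppt)
    d <- 2.1
    expect_equal(1 - exp(-ppt * d * q), 1 - exp(-d))
  }
})

test_that("bilinear upsampling preserves nodes and linear ramps", {
  v <- matrix(rep(3.7, 12 * 10), 12, 10)
  m <- intensityMap(v, 0.5)
  expect_equal(upsampleIntensity(m, c(1.3, 2.2), c(0.9, 3.3)), c(3.7, 3.7))

  ramp <- outer(seq_len(20), seq_len(16), function(i, j) 2 * i + 3 * j)
  mr <- intensityMap(ramp, 1)
  # exact on interpolants: sample centres at (i - 0.5)
  expect_equal(upsampleIntensity(mr, 4.5, 6.5), ramp[7, 5])
  expect_equal(upsampleIntensity(mr, 5.0, 6.0), (ramp[7, 5] + ramp[7, 6] +
                                                 ramp[6, 5] + ramp[6, 6]) / 4)
  set.seed(4)
  rv <- matrix(runif(50), 10, 5)
  mrv <- intensityMap(rv, 2)
  xs <- (seq_len(5) - 0.5) * 2; ys <- (seq_len(10) - 0.5) * 2
  expect_equal(upsampleIntensity(mrv, rep(xs, each = 10), rep(ys, 5)),
               as.vector(rv))
})

test_that("photon arrivals follow the intensity distribution", {
  cfg <- simulationConfig(photonMode = "per_photon", photonsPerTau = 100,
                          seed = 2)
  expect_true(all(samplePhotonArrivals(matrix(0, 3, 3), 5, cfg) == 0))

  set.seed(12)
  i2 <- c(3, 1)
  counts <- samplePhotonArrivals(i2, 250, cfg)  # ~1e5 photons
  expect_equal(sum(counts), 1e5, tolerance = 0.05)
  # 3:1 intensity ratio -> 3:1 count ratio (chi-squared on the split)
  chi <- stats::chisq.test(counts, p = c(0.75, 0.25))
  expect_gt(chi$p.value, 1e-4)

  set.seed(13)
  u <- samplePhotonArrivals(rep(1, 20), 500, cfg)
  expect_gt(stats::chisq.test(u)$p.value, 1e-4)
})

test_that("per-photon and aggregate modes deprotect identically in law", {
  # both modes give P(deprotect) = 1 - exp(-d) per site
  d <- 1.2; n <- 20000
  pExp <- 1 - exp(-d)
  for (mode in c("aggregate_dose", "per_photon")) {
    cfg <- simulationConfig(photonMode = mode, photonsPerTau = 7, seed = 31)
    set.seed(31)
    sites <- masSim:::.newSites(n, rep("x", n))
    out <- runCycle(sites, "LABEL", rep(d, n), cfg, coupling = FALSE)
    pHat <- mean(out$hydroxyl)
    expect_lt(abs(pHat - pExp), 3 * sqrt(pExp * (1 - pExp) / n))
  }
})

test_that("perfect chemistry replays the design exactly", {
  sch <- cyclicSchedule(c(x = "ACGTTGCA"), dose = 30)
  cfg <- simulationConfig(couplingEff = 1, seed = 7)
  ps <- simulateSynthesis(sch, cfg, replicates = 5)
  expect_true(all(as.character(products(ps)) == "ACGTTGCA"))
})

test_that("capped sites never grow", {
  cfg <- simulationConfig(couplingEff = 1, cappingEff = 1, seed = 1)
  sites <- masSim:::.newSites(4, rep("x", 4))
  sites$capped <- rep(TRUE, 4)
  out <- runCycle(sites, "A", rep(30, 4), cfg, coupling = TRUE)
  expect_true(all(out$seq == ""))
})

test_that("with full capping no product grows past its first failure", {
  set.seed(2)
  designs <- as.character(genDesigns(3, 15, seed = 2))
  sch <- withCapping(cyclicSchedule(designs, dose = 30))
  cfg <- simulationConfig(couplingEff = 0.85, cappingEff = 1, seed = 5)
  ps <- simulateSynthesis(sch, cfg, replicates = 40)
  prods <- as.character(products(ps))
  ok <- vapply(seq_along(prods), function(k) {
    endsWith(ps@metadata$designs[[designIds(ps)[k]]], prods[k])
  }, logical(1))
  expect_true(all(ok))
  expect_gt(sum(nchar(prods) < 15), 0)   # some truncations occurred
})

test_that("simulation is bit-identical under a fixed seed", {
  sch <- cyclicSchedule(c(a = "ACGT", b = "TGCA"), dose = 5)
  cfg <- simulationConfig(couplingEff = 0.95, seed = 99)
  p1 <- simulateSynthesis(sch, cfg, contrast = 300, replicates = 20)
  p2 <- simulateSynthesis(sch, cfg, contrast = 300, replicates = 20)
  expect_identical(as.character(products(p1)), as.character(products(p2)))
})

test_that("product length is bounded by design plus dark exposures", {
  designs <- c(a = "ACGTACGTAC", b = "GGTTCCAAGT")
  sch <- cyclicSchedule(designs, dose = 7)
  dark <- darkExposureCount(sch)
  cfg <- simulationConfig(couplingEff = 0.98, seed = 17)
  ps <- simulateSynthesis(sch, cfg, contrast = 20, replicates = 50)
  lim <- nchar(designs[designIds(ps)]) + dark[designIds(ps)]
  expect_true(all(Biostrings::width(products(ps)) <= lim))
})

test_that("scalar simulation converges to the closed-form expectations", {
  g <- 0.99; d <- 3; R <- 500; N <- 25; reps <- 6000
  ps <- scalarSimulate(g, d, R, N, replicates = reps, seed = 8)
  ev <- eventErrorStats(ps)
  er <- expectedErrorRates(g, R, d)
  nBases <- reps * N
  expect_true(within3SigmaBinomial(ev@deletionRate, er$deletion, nBases))
  # insertion events: up to 3 per design base
  sigmaIns <- sqrt(3 * (er$insertion / 3) * (1 - er$insertion / 3) / nBases)
  expect_lt(abs(ev@insertionRate - er$insertion), 3 * sigmaIns)
  pmExp <- correctSequenceYield(g, R, N, d)
  expect_true(within3SigmaBinomial(perfectMatchFraction(ev), pmExp, reps))
})

test_that("simulated intensity-map dosing reaches the chemistry", {
  # single ON mirror: its sites see the plateau dose, neighbours the
  # diffracted stray dose, so neighbour sites occasionally couple
  lay <- arrayLayout(3, 3, data.frame(id = c("on", "off"),
                                      row = c(1, 1), col = c(1, 0),
                                      nrow = 1, ncol = 1))
  seqs <- c(on = "TTTT", off = "TTTT")
  sch <- cyclicSchedule(seqs, layout = lay, skipEmpty = TRUE, dose = 7)
  maps <- lapply(sch@masks, aerialImage)
  cfg <- simulationConfig(sitesPerMirror = 2, couplingEff = 1, seed = 3)
  A <- assignFeatures(seqs, lay)
  ps <- simulateSynthesis(sch, cfg, intensityMaps = maps, assignment = A)
  prods <- as.character(products(ps))
  onSites <- which(designIds(ps) == "on")
  expect_true(all(prods[onSites] == "TTTT"))
  # unassigned/OFF sites receive partial exposure at most
  expect_true(mean(nchar(prods[-onSites])) < 4)
})

test_that("products serialize to FASTA with site headers", {
  ps <- scalarSimulate(0.99, 5, 1000, 10, replicates = 5, seed = 3)
  fa <- tempfile(fileext = ".fa")
  writeProducts(ps, fa)
  back <- Biostrings::readDNAStringSet(fa)
  expect_equal(length(back), 5)
  expect_true(all(grepl("design=design1", names(back))))
  unlink(fa)
})
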