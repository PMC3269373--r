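test_that("rasterization renders ON mirrors with the correct footprint", {
  cfg <- opticalConfig()
  expect_error(maskPattern(matrix(integer(0), 0, 0)), "non-empty")

  a0 <- rasterizeMask(maskPattern(matrix(0, 3, 3)), cfg)
  expect_true(all(a0 == 0))

  a1 <- rasterizeMask(maskPattern(matrix(1, 1, 1)), cfg)
  area <- sum(a1) * cfg@gridResolution^2
  expect_equal(area, (13.68 - 1)^2, tolerance = 0.02)  # grid quantization

  # all-ON: ON sample fraction over the mask footprint matches the
  # analytic fill factor ((pitch - gap)/pitch)^2
  a9 <- rasterizeMask(maskPattern(matrix(1, 3, 3)), cfg)
  footprint <- (3 * 13.68)^2
  expect_equal(sum(a9) * cfg@gridResolution^2 / footprint,
               ((13.68 - 1) / 13.68)^2, tolerance = 0.02)
})

test_that("coherent imaging reproduces the closed-form straight-edge response", {
  # for a long straight edge the coherent amplitude profile is the
  # sine-integral edge response a(u) = 1/2 + Si(2 pi fc u)/pi (the
  # projection of the circular pupil's point spread onto the edge
  # normal is an ideal 1D low-pass); use one huge gapless-in-practice
  # mirror so its boundary is locally a half-plane edge
  cfg <- opticalConfig(mirrorPitch = 60, mirrorGap = 0.5,
                       gridResolution = 0.25)
  m <- aerialImage(maskPattern(matrix(1, 1, 1)), cfg, normalize = FALSE)
  fc <- 0.08 / 0.365
  ys <- (seq_len(nrow(m@values)) - 0.5) * 0.25
  iy <- which.min(abs(ys - 4.5 * 60))            # row through mirror centre
  edgeX <- 4 * 60 + 0.25                          # left mirror edge (um)
  # compare where the half-plane formula applies: outside and near the
  # edge (deeper inside, the opposite edge and the square's corners add
  # their own ripple to the plateau)
  for (ix in which.min(abs(ys - edgeX)) + seq(-8, 4, by = 2)) {
    u <- ys[ix] - edgeX                           # offset of this sample
    Si <- stats::integrate(function(t) ifelse(t == 0, 1, sin(t) / t), 0,
                           abs(2 * pi * fc * u))$value * sign(u)
    expected <- (0.5 + Si / pi)^2
    expect_lt(abs(m@values[iy, ix] - expected), 0.012)
  }
})

test_that("plateau normalization gives a unit interior plateau", {
  cfg <- opticalConfig()
  m5 <- aerialImage(maskPattern(matrix(1, 5, 5)), cfg)
  ctr <- mirrorRegion(m5, 3, 3)
  expect_equal(mean(m5@values[ctr$rows, ctr$cols]), 1, tolerance = 0.02)

  # all-OFF mask images to zero
  z <- aerialImage(maskPattern(matrix(0, 3, 3)), cfg)
  expect_lt(max(z@values), 1e-12)
})

test_that("aerial images reproduce the measured gap exposures", {
  cfg <- opticalConfig()
  # all-ON 3x3: the inter-mirror gap stays substantially exposed
  m3 <- aerialImage(maskPattern(matrix(1, 3, 3)), cfg)
  gap <- gapCenterIntensity(m3, 2, 2, "right")
  expect_gt(gap, 0.3)
  expect_lt(gap, 0.6)

  # single ON mirror: adjacent gap receives ~10% of the ON exposure
  single <- matrix(0, 3, 3); single[2, 2] <- 1
  m1 <- aerialImage(maskPattern(single), cfg)
  on <- mirrorRegion(m1, 2, 2)
  onPlateau <- mean(m1@values[on$rows, on$cols])
  g <- gapRegion(m1, 2, 2, "right")
  rel <- mean(m1@values[g$rows, g$cols]) / onPlateau
  expect_gt(rel, 0.05)
  expect_lt(rel, 0.2)
})

test_that("coherent Gibbs overshoot along the central line is bounded", {
  cfg <- opticalConfig()
  m3 <- aerialImage(maskPattern(matrix(1, 3, 3)), cfg)
  ctr <- mirrorRegion(m3, 2, 2)
  line <- m3@values[ctr$rows[ceiling(length(ctr$rows) / 2)], ]
  plateau <- mean(line[ctr$cols])
  expect_lte(max(line), 1.3 * plateau)
})

test_that("incoherent imaging conserves energy and needs no negative fixup", {
  cfg <- opticalConfig(coherenceMode = "incoherent")
  mask <- maskPattern(matrix(c(1, 0, 1, 1, 1, 0, 0, 1, 1), 3, 3))
  a <- rasterizeMask(mask, cfg)
  m <- aerialImage(mask, cfg, normalize = FALSE)
  expect_equal(sum(m@values), sum(a^2), tolerance = 0.01)
})

test_that("images of mirror-symmetric masks are mirror-symmetric", {
  cfg <- opticalConfig()
  mask <- matrix(0, 3, 3); mask[2, ] <- 1      # symmetric under up-down flip
  m <- aerialImage(maskPattern(mask), cfg, normalize = FALSE)
  expect_equal(m@values, m@values[nrow(m@values):1, ], tolerance = 1e-10)
})

test_that("aerial imaging rejects a Nyquist-violating grid", {
  # legal configs cap gridResolution at gap/2, so widen the gap to reach
  # a resolution coarser than the pupil's Nyquist limit
  cfg <- opticalConfig(numericalAperture = 0.9, wavelength = 0.365,
                       mirrorGap = 13, mirrorPitch = 40, gridResolution = 6)
  expect_error(aerialImage(maskPattern(matrix(1, 2, 2)), cfg), "Nyquist")
})

test_that("global flare is linear through the measured anchor", {
  expect_equal(globalFlare(0.64), 0.001)
  expect_equal(globalFlare(0), 0)
  expect_equal(globalFlare(0.25), 0.000390625)
  expect_error(globalFlare(1.2), "onFraction")
  # additivity
  a <- runif(20, 0, 0.5); b <- runif(20, 0, 0.5)
  expect_equal(globalFlare(a + b), globalFlare(a) + globalFlare(b))
})

test_that("Fresnel reflectance matches the interface estimates", {
  expect_equal(fresnelReflectance(1.48, 1.50), ((1.48 - 1.5) / 2.98)^2)
  expect_lt(abs(fresnelReflectance(1.48, 1.50) - 5e-5), 1e-5)  # ~0.005%
  expect_equal(fresnelReflectance(1.48, 1.00), 0.0375, tolerance = 0.005)
  expect_equal(fresnelReflectance(1.33, 1.33), 0)
  expect_equal(fresnelReflectance(1.2, 1.7), fresnelReflectance(1.7, 1.2))
  expect_error(fresnelReflectance(-1, 1.5), "positive")
})

test_that("back reflection superposes a shifted scaled copy", {
  u <- intensityMap(matrix(1, 40, 40), 1)
  expect_equal(addBackReflection(u, 0, c(5, 0))@values, u@values)
  r <- addBackReflection(u, 0.0025, c(5, 0))
  expect_equal(r@values[20, 20], 1.0025)
  expect_error(addBackReflection(u, 1.5, c(0, 0)), "reflectance")

  # bright half shifted onto a dark half at 4% -> contrast denominator 25
  v <- matrix(0, 40, 80); v[, 1:40] <- 1
  m <- addBackReflection(intensityMap(v, 1), 0.04, c(20, 0))
  bright <- matrix(FALSE, 40, 80); bright[, 1:20] <- TRUE  # unshadowed part
  dark <- matrix(FALSE, 40, 80); dark[, 45:60] <- TRUE
  expect_equal(contrastRatio(m, bright, dark), 25, tolerance = 1e-6)
})

test_that("edge scatter is bounded, local and proportional to edge length", {
  cfg <- opticalConfig()
  single <- maskPattern(matrix(1, 1, 1))
  m <- aerialImage(single, cfg)
  expect_identical(addEdgeScatter(m, single, 0, cfg), m)
  expect_error(addEdgeScatter(m, single, 0.002, cfg), "upper bound")

  s1 <- addEdgeScatter(m, single, 0.001, cfg)
  added1 <- s1@values - m@values
  # localized within +-2 gaps of the mirror outline
  p <- 13.68; g <- 1; pad <- 4
  ys <- (seq_len(nrow(added1)) - 0.5) * 0.25
  outside <- ys < pad * p - 2 * g | ys > (pad + 1) * p + 2 * g
  expect_lt(max(added1[outside, outside]), 1e-6)

  duo <- maskPattern(matrix(1, 1, 2))
  m2 <- aerialImage(duo, cfg)
  s2 <- addEdgeScatter(m2, duo, 0.001, cfg)
  # lattice edge length: 4 pitches (1x1) vs 7 pitches (1x2)
  expect_equal(sum(s2@values - m2@values) / sum(added1), 7 / 4,
               tolerance = 0.02)
})

test_that("contrast ratio handles uniform maps and degenerate darks", {
  u <- intensityMap(matrix(1, 10, 10), 1)
  b <- matrix(FALSE, 10, 10); b[1:5, ] <- TRUE
  d <- !b
  expect_equal(contrastRatio(u, b, d), 1)
  z <- intensityMap(rbind(matrix(1, 5, 10), matrix(0, 5, 10)), 1)
  r <- contrastRatio(z, b, d)
  expect_true(is.infinite(r) && isTRUE(attr(r, "degenerate")))
  expect_error(contrastRatio(u, matrix(FALSE, 10, 10), d), "empty")
})

test_that("site dose map averages intensity over site footprints", {
  cfg <- opticalConfig()
  m <- aerialImage(maskPattern(matrix(1, 2, 2)), cfg)
  sd <- siteDoseMap(m, plateauDose = 5, siteGrid = 4)
  expect_equal(dim(sd), c(8, 8))
  # interior sites approach the plateau dose; corner sites (mirror edge
  # plus surrounding dark padding) receive clearly less
  expect_equal(sd[3, 3], 5, tolerance = 0.3)
  expect_lt(sd[1, 1], sd[3, 3])
  u <- intensityMap(matrix(2, nrow(m@values), ncol(m@values)),
                    m@pixelSize, m@meta)
  expect_true(all(abs(siteDoseMap(u, 3, 2) - 6) < 1e-12))
})
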