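# Scalar Fourier imaging of DMD virtual masks.
#
# The DMD is imaged 1:1 onto the synthesis plane. Each ON mirror is a
# reflective square of side (pitch - gap); gaps and OFF mirrors contribute
# no amplitude. Coherent imaging low-pass filters the amplitude with a
# circular pupil of cutoff NA/lambda cycles/um (strictly below the cutoff;
# ties excluded for determinism) and squares the magnitude; incoherent
# imaging applies the autocorrelation OTF (cutoff 2NA/lambda) to the
# squared amplitude. Images are plateau-normalized against a 9x9 all-ON
# calibration block computed with identical settings.

# sample-center coordinates along one axis
.sampleCenters <- function(n, res) (seq_len(n) - 0.5) * res

#' Rasterize a virtual mask to an amplitude grid
#'
#' Renders each ON mirror as a filled square of side `pitch - gap` centred
#' in its mirror cell, on a sample grid with `padPitches` mirror pitches of
#' guard padding per side. Sample centres falling inside an ON mirror get
#' amplitude 1; gaps, OFF mirrors and padding are 0.
#'
#' @param mask a [MaskPattern-class].
#' @param config an [OpticalConfig-class].
#' @return Numeric matrix of 0/1 amplitudes with attributes `pixelSize`
#'   (um/sample) and `meta` (geometry needed to locate mirror cells).
#' @examples
#' a <- rasterizeMask(maskPattern(matrix(1, 1, 1)), opticalConfig())
#' sum(a > 0) * attr(a, "pixelSize")^2  # approximately (13.68 - 1)^2
#' @export
rasterizeMask <- function(mask, config = opticalConfig()) {
  stopifnot(is(mask, "MaskPattern"), is(config, "OpticalConfig"))
  validObject(config)
  states <- mirrorStates(mask)
  if (length(states) == 0) stop("empty mask grid")
  p <- config@mirrorPitch; g <- config@mirrorGap
  res <- config@gridResolution; pad <- config@padPitches
  nr <- nrow(states); nc <- ncol(states)
  nx <- round((nc + 2 * pad) * p / res)
  ny <- round((nr + 2 * pad) * p / res)
  xs <- .sampleCenters(nx, res); ys <- .sampleCenters(ny, res)
  half <- (p - g) / 2
  a <- matrix(0, ny, nx)
  on <- which(states == 1L, arr.ind = TRUE)
  for (k in seq_len(nrow(on))) {
    cy <- (pad + on[k, 1] - 0.5) * p
    cx <- (pad + on[k, 2] - 0.5) * p
    a[abs(ys - cy) < half, abs(xs - cx) < half] <- 1
  }
  attr(a, "pixelSize") <- res
  attr(a, "meta") <- list(pitch = p, gap = g, padPitches = pad,
                          mirrorDim = c(nr, nc))
  a
}

# FFT sample frequencies (cycles per um), numpy fftfreq convention
.fftFreq <- function(n, d) {
  c(0:(ceiling(n / 2) - 1), -(floor(n / 2):1)) / (n * d)
}

# diffraction-limited image of an amplitude grid (unnormalized)
.diffract <- function(a, config) {
  res <- config@gridResolution
  fc <- config@numericalAperture / config@wavelength
  if (fc >= 1 / (2 * res))
    stop("grid resolution too coarse for the pupil cutoff (Nyquist violation)")
  ny <- nrow(a); nx <- ncol(a)
  fr <- sqrt(outer(.fftFreq(ny, res)^2, .fftFreq(nx, res)^2, "+"))
  if (config@coherenceMode == "coherent") {
    pupil <- fr < fc             # strict: ties at the cutoff excluded
    A <- stats::fft(stats::fft(a) * pupil, inverse = TRUE) / (nx * ny)
    Mod(A)^2
  } else {
    rho <- pmin(fr / (2 * fc), 1)
    otf <- (2 / pi) * (acos(rho) - rho * sqrt(1 - rho^2))  # diffraction OTF
    I <- stats::fft(stats::fft(a^2) * otf, inverse = TRUE) / (nx * ny)
    pmax(Re(I), 0)
  }
}

# plateau level of a 9x9 all-ON calibration block: mean intensity over the
# full interior footprint of the central mirror. Cached per configuration.
.plateauCache <- new.env(parent = emptyenv())

.plateauLevel <- function(config) {
  key <- paste(config@numericalAperture, config@wavelength,
               config@mirrorPitch, config@mirrorGap, config@gridResolution,
               config@coherenceMode, config@padPitches, sep = "|")
  hit <- .plateauCache[[key]]
  if (!is.null(hit)) return(hit)
  cal <- rasterizeMask(maskPattern(matrix(1L, 9, 9)), config)
  I <- .diffract(cal, config)
  idx <- .mirrorIndices(dim(I), config, 9, 9, row = 5, col = 5, shrink = 0)
  level <- mean(I[idx$rows, idx$cols])
  .plateauCache[[key]] <- level
  level
}

# sample indices of the interior footprint of mirror (row, col), 1-based
# mirror coordinates, given grid geometry
.mirrorIndicesGeom <- function(gridDim, pitch, gap, res, pad, row, col,
                               shrink = 0) {
  cy <- (pad + row - 0.5) * pitch
  cx <- (pad + col - 0.5) * pitch
  half <- (pitch - gap) / 2 - shrink
  ys <- .sampleCenters(gridDim[1], res)
  xs <- .sampleCenters(gridDim[2], res)
  list(rows = which(abs(ys - cy) < half), cols = which(abs(xs - cx) < half))
}

.mirrorIndices <- function(gridDim, config, nr, nc, row, col, shrink = 0) {
  .mirrorIndicesGeom(gridDim, config@mirrorPitch, config@mirrorGap,
                     config@gridResolution, config@padPitches,
                     row, col, shrink)
}

#' Compute the aerial image of a virtual mask
#'
#' Forms the diffraction-limited relative-irradiance map of a mask with the
#' scalar Fourier model (see [opticalConfig()] for the parameters), then
#' normalizes it so that the interior plateau of a large all-ON block
#' equals 1 (9x9 all-ON calibration computed with identical settings).
#'
#' @param mask a [MaskPattern-class].
#' @param config an [OpticalConfig-class].
#' @param normalize plateau-normalize (default TRUE).
#' @return An [IntensityMap-class]; its `meta` carries the mirror geometry
#'   so that [mirrorRegion()] and [gapRegion()] can address it.
#' @examples
#' m <- aerialImage(maskPattern(matrix(1, 3, 3)))
#' gapCenterIntensity(m, 2, 2, "right")  # diffraction fills the gap
#' @export
aerialImage <- function(mask, config = opticalConfig(), normalize = TRUE) {
  a <- rasterizeMask(mask, config)
  I <- .diffract(a, config)
  meta <- attr(a, "meta")
  if (normalize) {
    plateau <- .plateauLevel(config)
    I <- I / plateau
    meta$plateauRaw <- plateau
  }
  intensityMap(I, pixelSize = config@gridResolution, meta = meta)
}

.requireAerialMeta <- function(map) {
  m <- map@meta
  if (is.null(m$pitch) || is.null(m$mirrorDim))
    stop("this IntensityMap carries no mirror geometry (not from aerialImage)")
  m
}

#' Address mirror footprints and gaps on an aerial image
#'
#' `mirrorRegion` returns the sample indices of the interior footprint of a
#' mirror (the `pitch - gap` square, optionally shrunk); `gapRegion` the
#' strip of gap between a mirror and its neighbour on one side;
#' `gapCenterIntensity` the plateau-normalized intensity at the centre of
#' that gap on the line through the mirror centres.
#'
#' @param map an [IntensityMap-class] produced by [aerialImage()].
#' @param row,col 1-based mirror coordinates (row 1 = top).
#' @param shrink shrink the footprint inward by this many micrometres.
#' @param side which neighbouring gap: `"right"`, `"left"`, `"top"` or
#'   `"bottom"`.
#' @return For the region helpers, a list with integer `rows` and `cols`;
#'   for `gapCenterIntensity`, a single intensity value.
#' @export
mirrorRegion <- function(map, row, col, shrink = 0) {
  meta <- .requireAerialMeta(map)
  .mirrorIndicesGeom(dim(map@values), meta$pitch, meta$gap, map@pixelSize,
                     meta$padPitches, row, col, shrink)
}

#' @rdname mirrorRegion
#' @export
gapRegion <- function(map, row, col, side = c("right", "left", "top", "bottom")) {
  side <- match.arg(side)
  meta <- .requireAerialMeta(map)
  p <- meta$pitch; g <- meta$gap; res <- map@pixelSize
  pad <- meta$padPitches
  cy <- (pad + row - 0.5) * p
  cx <- (pad + col - 0.5) * p
  half <- (p - g) / 2
  ys <- .sampleCenters(nrow(map@values), res)
  xs <- .sampleCenters(ncol(map@values), res)
  along <- function(centers, c0) which(abs(centers - c0) < half)
  strip <- function(centers, edge, dir)
    which(dir * (centers - edge) > 0 & dir * (centers - edge) < g)
  switch(side,
    right  = list(rows = along(ys, cy), cols = strip(xs, cx + half, +1)),
    left   = list(rows = along(ys, cy), cols = strip(xs, cx - half, -1)),
    bottom = list(rows = strip(ys, cy + half, +1), cols = along(xs, cx)),
    top    = list(rows = strip(ys, cy - half, -1), cols = along(xs, cx)))
}

#' @rdname mirrorRegion
#' @export
gapCenterIntensity <- function(map, row, col,
                               side = c("right", "left", "top", "bottom")) {
  side <- match.arg(side)
  meta <- .requireAerialMeta(map)
  p <- meta$pitch; res <- map@pixelSize; pad <- meta$padPitches
  cy <- (pad + row - 0.5) * p
  cx <- (pad + col - 0.5) * p
  gx <- switch(side, right = cx + p / 2, left = cx - p / 2, cx)
  gy <- switch(side, bottom = cy + p / 2, top = cy - p / 2, cy)
  ys <- .sampleCenters(nrow(map@values), res)
  xs <- .sampleCenters(ncol(map@values), res)
  map@values[which.min(abs(ys - gy)), which.min(abs(xs - gx))]
}

#' Global flare as a fraction of direct irradiance
#'
#' Global flare (dust and imperfections along the optical path) produces a
#' spatially homogeneous background proportional to the number of ON
#' mirrors. The model is linear through the origin, scaled by a measured
#' anchor: by default a flare of 0.1% of direct irradiance at 64% ON
#' mirrors, so 25% ON gives about 0.04%.
#'
#' @param onFraction fraction of ON mirrors in \[0, 1\] (vectorized).
#' @param config an [OpticalConfig-class] carrying the anchor.
#' @return Flare irradiance as a fraction of direct irradiance.
#' @examples
#' globalFlare(0.64)   # 0.001 (the anchor)
#' globalFlare(0.25)   # ~0.00039 -> contrast denominator > 2500
#' @export
globalFlare <- function(onFraction, config = opticalConfig()) {
  if (any(onFraction < 0 | onFraction > 1))
    stop("onFraction must be in [0, 1]")
  anchor <- config@globalFlareAnchor
  anchor[1] * onFraction / anchor[2]
}

#' Normal-incidence Fresnel reflectance
#'
#' `((n1 - n2) / (n1 + n2))^2` for two media of refractive index `n1`,
#' `n2`. The quartz (1.48) / DMSO (1.50) interface at the back of the
#' reaction cell reflects about 0.005%; an uncoated glass-air interface
#' about 4%.
#'
#' @param n1,n2 refractive indices (> 0; vectorized).
#' @return Reflected fraction of normally incident light.
#' @examples
#' fresnelReflectance(1.48, 1.50)  # ~4.5e-5
#' fresnelReflectance(1.48, 1.00)  # ~0.0375
#' @export
fresnelReflectance <- function(n1, n2) {
  if (any(n1 <= 0) || any(n2 <= 0))
    stop("refractive indices must be positive")
  ((n1 - n2) / (n1 + n2))^2
}

#' Add a back-surface reflection to an intensity map
#'
#' Models the reflection from the rear face of the quartz block as a single
#' scaled copy of the map, shifted laterally (a small tilt of the thick
#' block displaces the reflection onto neighbouring synthesis pixels).
#' Content shifted beyond the grid is discarded.
#'
#' @param map an [IntensityMap-class].
#' @param reflectance reflected fraction in \[0, 1\].
#' @param offset length-2 lateral shift (x, y) in micrometres.
#' @return The map plus `reflectance` times its shifted copy.
#' @export
addBackReflection <- function(map, reflectance = 0.0025,
                              offset = c(2 * 13.68, 0)) {
  stopifnot(is(map, "IntensityMap"))
  if (reflectance < 0 || reflectance > 1)
    stop("reflectance must be in [0, 1]")
  v <- map@values
  sh <- round(c(offset[2], offset[1]) / map@pixelSize)  # (rows, cols)
  shifted <- matrix(0, nrow(v), ncol(v))
  srcR <- seq_len(nrow(v)) - sh[1]
  srcC <- seq_len(ncol(v)) - sh[2]
  okR <- srcR >= 1 & srcR <= nrow(v)
  okC <- srcC >= 1 & srcC <= ncol(v)
  shifted[okR, okC] <- v[srcR[okR], srcC[okC]]
  intensityMap(v + reflectance * shifted, map@pixelSize, map@meta)
}

#' Add mirror-edge scattering to an intensity map
#'
#' Mirror edges scatter light into the interstices between synthesis
#' pixels, for ON and OFF mirrors alike. Modelled as a narrow additive
#' Gaussian kernel (width of the order of the mirror gap) along every
#' mirror-cell boundary, scaled so that a long straight edge adds
#' `amplitude` times the direct irradiance at its crest. The measured upper
#' bound is 0.1% of the all-ON direct irradiance, so amplitudes above 0.001
#' are rejected.
#'
#' @param map an [IntensityMap-class] from [aerialImage()].
#' @param mask the [MaskPattern-class] the map was computed from.
#' @param amplitude crest amplitude as a fraction of direct irradiance,
#'   in \[0, 0.001\].
#' @param config the [OpticalConfig-class] used for the map.
#' @return The map with edge scatter added.
#' @export
addEdgeScatter <- function(map, mask, amplitude, config = opticalConfig()) {
  stopifnot(is(map, "IntensityMap"), is(mask, "MaskPattern"))
  if (amplitude < 0 || amplitude > 0.001)
    stop("edge-scatter amplitude must be in [0, 0.001] (measured upper bound)")
  if (amplitude == 0) return(map)
  meta <- .requireAerialMeta(map)
  p <- meta$pitch; g <- meta$gap; res <- map@pixelSize
  pad <- meta$padPitches
  dimM <- meta$mirrorDim
  ny <- nrow(map@values); nx <- ncol(map@values)
  ys <- .sampleCenters(ny, res); xs <- .sampleCenters(nx, res)
  edge <- matrix(0, ny, nx)
  # mirror-cell boundary lines (all boundaries of the mirror lattice)
  rowLines <- (pad + 0:dimM[1]) * p
  colLines <- (pad + 0:dimM[2]) * p
  spanY <- ys >= pad * p & ys <= (pad + dimM[1]) * p
  spanX <- xs >= pad * p & xs <= (pad + dimM[2]) * p
  for (yl in rowLines) edge[which.min(abs(ys - yl)), spanX] <- 1
  for (xl in colLines) edge[spanY, which.min(abs(xs - xl))] <- 1
  # Gaussian kernel, sd = gap/2, support +-2 gaps; crest of a straight
  # line response equals `amplitude`
  sd <- g / 2
  half <- ceiling(2 * g / res)
  u <- (-half:half) * res
  k1 <- exp(-u^2 / (2 * sd^2))
  k2 <- outer(k1, k1)
  k2 <- k2 * amplitude / sum(k1)   # line crest = amplitude * sum(k1)/sum(k1)
  scat <- .convolve2(edge, k2)
  intensityMap(map@values + scat, res, map@meta)
}

# zero-padded FFT convolution, 'same' output size
.convolve2 <- function(x, k) {
  ny <- nrow(x) + nrow(k) - 1
  nx <- ncol(x) + ncol(k) - 1
  X <- matrix(0, ny, nx); X[seq_len(nrow(x)), seq_len(ncol(x))] <- x
  K <- matrix(0, ny, nx); K[seq_len(nrow(k)), seq_len(ncol(k))] <- k
  full <- Re(stats::fft(stats::fft(X) * stats::fft(K), inverse = TRUE)) / (ny * nx)
  offR <- (nrow(k) - 1) %/% 2; offC <- (ncol(k) - 1) %/% 2
  full[offR + seq_len(nrow(x)), offC + seq_len(ncol(x))]
}

#' Contrast ratio between a bright and a dark region
#'
#' `R = mean(bright) / mean(dark)`. A dark mean of zero yields `Inf` with a
#' `degenerate` attribute flag.
#'
#' @param map an [IntensityMap-class].
#' @param bright,dark logical matrices (same dimensions as the map) or
#'   region lists with `rows`/`cols` as returned by [mirrorRegion()].
#' @return The contrast ratio (dimensionless).
#' @export
contrastRatio <- function(map, bright, dark) {
  stopifnot(is(map, "IntensityMap"))
  pick <- function(region, what) {
    if (is.list(region) && !is.null(region$rows)) {
      if (!length(region$rows) || !length(region$cols))
        stop(what, " region is empty")
      map@values[region$rows, region$cols]
    } else {
      region <- as.logical(region)
      if (!any(region)) stop(what, " region is empty")
      map@values[region]
    }
  }
  b <- pick(bright, "bright"); d <- pick(dark, "dark")
  if (is.list(bright) && is.list(dark) &&
      identical(bright$rows, dark$rows) && identical(bright$cols, dark$cols))
    stop("bright and dark regions must be disjoint")
  dm <- mean(d)
  if (dm == 0) return(structure(Inf, degenerate = TRUE))
  mean(b) / dm
}

#' Per-site photodeprotection dose from an intensity map
#'
#' Divides each mirror cell (full pitch footprint) into `siteGrid` x
#' `siteGrid` reaction sites and returns the mean relative irradiance over
#' each site footprint times the plateau dose.
#'
#' @param map an [IntensityMap-class] from [aerialImage()].
#' @param plateauDose dose delivered at plateau intensity (any dose unit;
#'   tau-units in the simulator).
#' @param siteGrid sites per mirror per axis.
#' @return Numeric matrix of per-site doses, `(rows * siteGrid) x
#'   (cols * siteGrid)`.
#' @export
siteDoseMap <- function(map, plateauDose, siteGrid = 4L) {
  meta <- .requireAerialMeta(map)
  p <- meta$pitch; res <- map@pixelSize; pad <- meta$padPitches
  dimM <- meta$mirrorDim
  ys <- .sampleCenters(nrow(map@values), res)
  xs <- .sampleCenters(ncol(map@values), res)
  w <- p / siteGrid
  out <- matrix(NA_real_, dimM[1] * siteGrid, dimM[2] * siteGrid)
  for (i in seq_len(dimM[1] * siteGrid)) {
    y0 <- pad * p + (i - 1) * w
    ri <- which(ys >= y0 & ys < y0 + w)
    for (j in seq_len(dimM[2] * siteGrid)) {
      x0 <- pad * p + (j - 1) * w
      ci <- which(xs >= x0 & xs < x0 + w)
      out[i, j] <- mean(map@values[ri, ci])
    }
  }
  out * plateauDose
}
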