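#' @include AllGenerics.R
NULL

#' Optical configuration of the maskless array synthesizer imaging path
#'
#' Holds the parameters of the scalar Fourier imaging model: the numerical
#' aperture and wavelength set the pupil cutoff (NA/lambda cycles per
#' micrometre in coherent mode, twice that in incoherent mode); the mirror
#' pitch and inter-mirror gap set the DMD geometry imaged 1:1 onto the
#' synthesis plane; the grid resolution is the sampling of the synthesis
#' plane. Stray-light terms: a global-flare anchor (measured flare fraction
#' at a reference ON-mirror fraction), a back-surface reflectance with its
#' lateral offset, and a bounded mirror-edge scatter amplitude.
#'
#' @slot numericalAperture numeric, dimensionless, in (0, 1).
#' @slot wavelength numeric, micrometres.
#' @slot mirrorPitch numeric, micrometres, centre-to-centre mirror spacing.
#' @slot mirrorGap numeric, micrometres, unreflective gap between mirrors.
#' @slot gridResolution numeric, micrometres per sample.
#' @slot coherenceMode character, \code{"coherent"} or \code{"incoherent"}.
#' @slot globalFlareAnchor numeric length-2: flare fraction of direct
#'   irradiance and the ON-mirror fraction at which it was measured.
#' @slot backReflectance numeric fraction reflected from the rear quartz
#'   surface (0.0025 for a broadband-antireflection-coated surface, 0.0375
#'   for uncoated glass-air).
#' @slot backReflectionOffset numeric length-2, lateral shift (x, y) of the
#'   back reflection in micrometres.
#' @slot edgeScatterAmplitude numeric fraction of direct irradiance added
#'   along mirror edges; bounded above by 0.001 (the measured detection
#'   limit).
#' @slot padPitches numeric, guard padding around the rasterized mask, in
#'   mirror pitches per side.
#'
#' @seealso [opticalConfig()], [aerialImage()]
#' @export
setClass("OpticalConfig",
  representation(
    numericalAperture   = "numeric",
    wavelength          = "numeric",
    mirrorPitch         = "numeric",
    mirrorGap           = "numeric",
    gridResolution      = "numeric",
    coherenceMode       = "character",
    globalFlareAnchor   = "numeric",
    backReflectance     = "numeric",
    backReflectionOffset = "numeric",
    edgeScatterAmplitude = "numeric",
    padPitches          = "numeric"
  )
)

setValidity("OpticalConfig", function(object) {
  msg <- character()
  na <- object@numericalAperture
  if (length(na) != 1 || is.na(na) || na <= 0 || na >= 1)
    msg <- c(msg, "numericalAperture must be a single value in (0, 1)")
  if (object@wavelength <= 0)
    msg <- c(msg, "wavelength must be positive")
  if (!(object@mirrorPitch > object@mirrorGap && object@mirrorGap > 0))
    msg <- c(msg, "must have mirrorPitch > mirrorGap > 0")
  if (object@gridResolution > object@mirrorGap / 2)
    msg <- c(msg, "gridResolution must be <= mirrorGap / 2")
  if (!object@coherenceMode %in% c("coherent", "incoherent"))
    msg <- c(msg, "coherenceMode must be 'coherent' or 'incoherent'")
  gfa <- object@globalFlareAnchor
  if (length(gfa) != 2 || any(gfa < 0) || any(gfa > 1) || gfa[2] == 0)
    msg <- c(msg, "globalFlareAnchor must be (fraction, on_fraction) in [0,1], on_fraction > 0")
  if (object@backReflectance < 0 || object@backReflectance > 1)
    msg <- c(msg, "backReflectance must be in [0, 1]")
  if (length(object@backReflectionOffset) != 2)
    msg <- c(msg, "backReflectionOffset must be length 2 (x, y) in micrometres")
  esa <- object@edgeScatterAmplitude
  if (esa < 0 || esa > 0.001)
    msg <- c(msg, "edgeScatterAmplitude must be in [0, 0.001] (above the measured upper bound)")
  if (object@padPitches < 4)
    msg <- c(msg, "padPitches must be >= 4")
  if (length(msg)) msg else TRUE
})

#' Construct an optical configuration
#'
#' Defaults correspond to the imaging system modelled here: NA 0.08,
#' 365 nm illumination, 13.68 um mirror pitch with a 1 um gap, a 0.25 um
#' sampling grid, fully coherent imaging, a measured global-flare anchor of
#' 0.1% of direct irradiance at 64% ON mirrors, and a coated back surface
#' (0.25% reflectance) offset laterally by two mirror pitches.
#'
#' @param numericalAperture dimensionless NA of the projection optics.
#' @param wavelength illumination wavelength, micrometres.
#' @param mirrorPitch DMD mirror pitch, micrometres.
#' @param mirrorGap gap between mirrors, micrometres.
#' @param gridResolution synthesis-plane sampling, micrometres per sample.
#' @param coherenceMode `"coherent"` (default) or `"incoherent"`.
#' @param globalFlareAnchor length-2 numeric `(flare fraction, on fraction)`.
#' @param backReflectance back-surface reflectance fraction; 0.0025 coated,
#'   0.0375 for an uncoated glass-air interface.
#' @param backReflectionOffset length-2 lateral shift of the back-reflected
#'   image, micrometres; default two mirror pitches in x.
#' @param edgeScatterAmplitude additive edge-scatter amplitude as a fraction
#'   of direct irradiance, at most 0.001.
#' @param padPitches guard padding in mirror pitches per side (>= 4).
#' @return An [OpticalConfig-class] object.
#' @examples
#' cfg <- opticalConfig()
#' cfg
#' @export
opticalConfig <- function(numericalAperture = 0.08,
                          wavelength = 0.365,
                          mirrorPitch = 13.68,
                          mirrorGap = 1.0,
                          gridResolution = 0.25,
                          coherenceMode = c("coherent", "incoherent"),
                          globalFlareAnchor = c(0.001, 0.64),
                          backReflectance = 0.0025,
                          backReflectionOffset = c(2 * mirrorPitch, 0),
                          edgeScatterAmplitude = 0,
                          padPitches = 4) {
  coherenceMode <- match.arg(coherenceMode)
  new("OpticalConfig",
      numericalAperture = numericalAperture,
      wavelength = wavelength,
      mirrorPitch = mirrorPitch,
      mirrorGap = mirrorGap,
      gridResolution = gridResolution,
      coherenceMode = coherenceMode,
      globalFlareAnchor = globalFlareAnchor,
      backReflectance = backReflectance,
      backReflectionOffset = backReflectionOffset,
      edgeScatterAmplitude = edgeScatterAmplitude,
      padPitches = padPitches)
}

setMethod("show", "OpticalConfig", function(object) {
  cat("OpticalConfig:",
      sprintf("NA %.3g, lambda %.4g um, pitch %.4g um, gap %.3g um",
              object@numericalAperture, object@wavelength,
              object@mirrorPitch, object@mirrorGap), "\n")
  cat(sprintf("  grid %.3g um/sample, %s imaging, pad %g pitches\n",
              object@gridResolution, object@coherenceMode, object@padPitches))
  cat(sprintf("  flare anchor %.3g @ %.3g ON, back reflectance %.3g, edge scatter %.3g\n",
              object@globalFlareAnchor[1], object@globalFlareAnchor[2],
              object@backReflectance, object@edgeScatterAmplitude))
})

#' Binary virtual mask (DMD mirror states)
#'
#' A rows-by-cols grid of mirror states, row 1 at the top, entries 0 (OFF)
#' or 1 (ON). The ON fraction is derived, never stored.
#'
#' @slot states integer matrix of 0/1 mirror states.
#' @seealso [maskPattern()], [aerialImage()], [writeMasks()]
#' @export
setClass("MaskPattern", representation(states = "matrix"))

setValidity("MaskPattern", function(object) {
  s <- object@states
  if (length(s) == 0) return("mask grid must be non-empty")
  if (!all(s %in% c(0L, 1L))) return("mirror states must be 0 or 1")
  TRUE
})

#' Construct a mask pattern
#' @param states matrix (or object coercible to one) of 0/1 mirror states,
#'   row 1 = top row of the DMD.
#' @return A [MaskPattern-class] object.
#' @examples
#' maskPattern(matrix(c(0, 1, 0, 1), 2, 2))
#' @export
maskPattern <- function(states) {
  m <- as.matrix(states)
  storage.mode(m) <- "integer"
  new("MaskPattern", states = m)
}

#' @rdname MaskPattern-class
#' @param x a `MaskPattern`.
#' @export
setMethod("mirrorStates", "MaskPattern", function(x) x@states)

#' @rdname MaskPattern-class
#' @export
setMethod("onFraction", "MaskPattern", function(x) mean(x@states == 1L))

setMethod("show", "MaskPattern", function(object) {
  cat(sprintf("MaskPattern: %d x %d mirrors, %.3g%% ON\n",
              nrow(object@states), ncol(object@states),
              100 * onFraction(object)))
})

#' Relative irradiance map on the synthesis plane
#'
#' A 2D grid of dimensionless relative irradiance, normalized so the interior
#' plateau of a large all-ON mirror block equals 1. Carries the sampling
#' pitch and, for maps produced by [aerialImage()], the mirror geometry
#' needed to locate mirror footprints and gaps ([mirrorRegion()],
#' [gapRegion()]).
#'
#' @slot values numeric matrix of relative irradiance (>= 0, finite).
#' @slot pixelSize numeric, micrometres per sample.
#' @slot meta list of geometry metadata (mirror pitch/gap, padding, mask
#'   dimensions, raw plateau level) or empty for free-standing maps.
#' @seealso [intensityMap()], [aerialImage()]
#' @export
setClass("IntensityMap",
  representation(values = "matrix", pixelSize = "numeric", meta = "list"))

setValidity("IntensityMap", function(object) {
  v <- object@values
  if (length(v) == 0) return("intensity grid must be non-empty")
  if (any(!is.finite(v))) return("intensity values must be finite")
  if (any(v < 0)) return("intensity values must be >= 0")
  if (object@pixelSize <= 0) return("pixelSize must be positive")
  TRUE
})

#' Construct an intensity map
#' @param values numeric matrix of relative irradiance.
#' @param pixelSize micrometres per sample.
#' @param meta optional geometry metadata list.
#' @return An [IntensityMap-class] object.
#' @export
intensityMap <- function(values, pixelSize, meta = list()) {
  values <- as.matrix(values)
  attributes(values) <- list(dim = dim(values))   # drop stray attributes
  new("IntensityMap", values = values, pixelSize = pixelSize,
      meta = meta)
}

#' @rdname IntensityMap-class
#' @param x an `IntensityMap`.
#' @export
setMethod("intensityValues", "IntensityMap", function(x) x@values)

#' @rdname IntensityMap-class
#' @export
setMethod("pixelSize", "IntensityMap", function(x) x@pixelSize)

#' @rdname IntensityMap-class
#' @export
setMethod("physicalExtent", "IntensityMap",
          function(x) rev(dim(x@values)) * x@pixelSize)

setMethod("show", "IntensityMap", function(object) {
  d <- dim(object@values)
  cat(sprintf("IntensityMap: %d x %d samples (%.4g x %.4g um), range [%.3g, %.3g]\n",
              d[1], d[2], d[2] * object@pixelSize, d[1] * object@pixelSize,
              min(object@values), max(object@values)))
})

#' Microarray layout on the DMD
#'
#' Maps design sequences to rectangular mirror blocks, with optional
#' one-in-two / one-in-four sparse mirror use within blocks, multi-mirror
#' dark streets between blocks, and an inverse-capping flag (streets and
#' unused mirrors exposed and capped before synthesis begins).
#'
#' Mirror coordinates are 0-based, row-major, origin top-left: a block with
#' `row = 0, col = 0` starts at the top-left mirror.
#'
#' @slot dmdRows,dmdCols integer DMD dimensions in mirrors.
#' @slot featureBlocks data.frame with columns `id`, `row`, `col` (0-based
#'   top-left corner), `nrow`, `ncol`.
#' @slot layoutMode character: `"one_in_one"`, `"one_in_two"` or
#'   `"one_in_four"`.
#' @slot streetWidth integer, dark margin in mirrors around blocks
#'   (validated spacing between blocks).
#' @slot inverseCapping logical.
#' @seealso [arrayLayout()], [assignFeatures()]
#' @export
setClass("ArrayLayout",
  representation(
    dmdRows = "integer", dmdCols = "integer",
    featureBlocks = "data.frame",
    layoutMode = "character",
    streetWidth = "integer",
    inverseCapping = "logical"
  )
)

setValidity("ArrayLayout", function(object) {
  msg <- character()
  fb <- object@featureBlocks
  need <- c("id", "row", "col", "nrow", "ncol")
  if (!all(need %in% names(fb)))
    return(paste("featureBlocks needs columns:", paste(need, collapse = ", ")))
  if (!object@layoutMode %in% c("one_in_one", "one_in_two", "one_in_four"))
    msg <- c(msg, "layoutMode must be one_in_one, one_in_two or one_in_four")
  if (nrow(fb)) {
    if (anyDuplicated(fb$id))
      msg <- c(msg, "feature block ids must be unique")
    if (any(fb$row < 0 | fb$col < 0 |
            fb$row + fb$nrow > object@dmdRows |
            fb$col + fb$ncol > object@dmdCols))
      msg <- c(msg, "feature blocks must lie within the DMD bounds")
    # pairwise disjoint
    if (nrow(fb) > 1) {
      for (i in seq_len(nrow(fb) - 1)) for (j in (i + 1):nrow(fb)) {
        ri <- fb[i, ]; rj <- fb[j, ]
        if (ri$row < rj$row + rj$nrow && rj$row < ri$row + ri$nrow &&
            ri$col < rj$col + rj$ncol && rj$col < ri$col + ri$ncol) {
          msg <- c(msg, "feature blocks must be pairwise disjoint")
          break
        }
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct an array layout
#'
#' @param dmdRows,dmdCols DMD dimensions in mirrors (default 0.7 XGA,
#'   768 x 1024).
#' @param featureBlocks data.frame of blocks (`id`, `row`, `col`, `nrow`,
#'   `ncol`; 0-based top-left corners). Use [gridBlocks()] to build a
#'   regular grid with streets.
#' @param layoutMode `"one_in_one"` (all mirrors of a block),
#'   `"one_in_two"` (checkerboard) or `"one_in_four"` (every second mirror
#'   in both axes).
#' @param streetWidth dark margin between blocks, mirrors.
#' @param inverseCapping expose and cap streets/unused mirrors before
#'   synthesis.
#' @return An [ArrayLayout-class] object.
#' @export
arrayLayout <- function(dmdRows = 768L, dmdCols = 1024L,
                        featureBlocks = data.frame(
                          id = character(), row = integer(), col = integer(),
                          nrow = integer(), ncol = integer()),
                        layoutMode = c("one_in_one", "one_in_two", "one_in_four"),
                        streetWidth = 0L,
                        inverseCapping = FALSE) {
  layoutMode <- match.arg(layoutMode)
  new("ArrayLayout", dmdRows = as.integer(dmdRows),
      dmdCols = as.integer(dmdCols),
      featureBlocks = featureBlocks, layoutMode = layoutMode,
      streetWidth = as.integer(streetWidth),
      inverseCapping = inverseCapping)
}

setMethod("show", "ArrayLayout", function(object) {
  cat(sprintf("ArrayLayout: %d x %d DMD, %d feature block(s), %s, street %d%s\n",
              object@dmdRows, object@dmdCols, nrow(object@featureBlocks),
              object@layoutMode, object@streetWidth,
              if (object@inverseCapping) ", inverse capping" else ""))
})

#' Synthesis schedule: ordered exposure/coupling cycles
#'
#' The program of a synthesis: for each cycle, the delivered base (`A`,
#' `C`, `G`, `T`, or the pseudo-bases `CAP` and `LABEL`), the
#' photodeprotection dose (tau-units), whether a phosphoramidite coupling
#' follows, the set of features whose mirrors are ON, and optionally the
#' full mirror mask. Designs are stored 5'->3'; deposition proceeds
#' 3'->5' (the surface linker end first), so cycle bases follow the
#' reversed design strings.
#'
#' @slot base character vector of cycle bases.
#' @slot dose numeric vector of cycle doses, tau-units.
#' @slot coupling logical vector, TRUE for coupling cycles.
#' @slot onFeatures list of character vectors, feature ids ON per cycle.
#' @slot masks list of [MaskPattern-class] (possibly empty).
#' @slot featureIds character vector of all feature ids.
#' @slot designs named character vector of design sequences (5'->3'),
#'   possibly empty for externally loaded mask sets.
#' @seealso [cyclicSchedule()], [darkExposureCount()], [simulateSynthesis()]
#' @export
setClass("SynthesisSchedule",
  representation(
    base = "character", dose = "numeric", coupling = "logical",
    onFeatures = "list", masks = "list",
    featureIds = "character", designs = "character"
  )
)

setValidity("SynthesisSchedule", function(object) {
  n <- length(object@base)
  if (length(object@dose) != n || length(object@coupling) != n ||
      length(object@onFeatures) != n)
    return("base, dose, coupling and onFeatures must have one entry per cycle")
  if (!all(object@base %in% c("A", "C", "G", "T", "CAP", "LABEL")))
    return("cycle base must be one of A, C, G, T, CAP, LABEL")
  if (any(object@dose < 0)) return("doses must be >= 0")
  if (length(object@masks) && length(object@masks) != n)
    return("masks, when present, must have one entry per cycle")
  TRUE
})

#' @rdname SynthesisSchedule-class
#' @param x a `SynthesisSchedule`.
#' @export
setMethod("cycleTable", "SynthesisSchedule", function(x) {
  data.frame(cycle = seq_along(x@base), base = x@base, dose = x@dose,
             coupling = x@coupling,
             nOn = vapply(x@onFeatures, length, integer(1)))
})

#' @rdname SynthesisSchedule-class
#' @export
setMethod("cycleMasks", "SynthesisSchedule", function(x) x@masks)

setMethod("length", "SynthesisSchedule", function(x) length(x@base))

setMethod("show", "SynthesisSchedule", function(object) {
  cat(sprintf("SynthesisSchedule: %d cycles, %d feature(s)\n",
              length(object@base), length(object@featureIds)))
  if (length(object@base)) {
    cpl <- sum(object@coupling & object@base %in% c("A", "C", "G", "T"))
    cat(sprintf("  %d base-coupling cycles, doses %.3g-%.3g tau\n",
                cpl, min(object@dose), max(object@dose)))
  }
})

#' Monte-Carlo simulation configuration
#'
#' @slot sitesPerMirror integer, reaction-site grid factor per mirror axis
#'   (default 4, i.e. 4 x 4 sites per mirror).
#' @slot photonMode `"aggregate_dose"` (deprotection probability
#'   `1 - exp(-d_site/tau)`) or `"per_photon"` (explicit Poisson photon
#'   arrivals, each succeeding with the quantum efficiency).
#' @slot photonsPerTau numeric, expected photons per site per tau of dose
#'   (per-photon mode).
#' @slot quantumEfficiency numeric, per-photon deprotection probability;
#'   calibrated as `1/photonsPerTau` so the per-photon mode reproduces the
#'   aggregate dose law (see [calibrateQuantumEfficiency()]).
#' @slot couplingEff named numeric, per-base stepwise coupling efficiency
#'   (`A`, `C`, `G`, `T`).
#' @slot cappingEff numeric fraction.
#' @slot oxidationEff numeric, fixed at 1 (oxidation assumed complete).
#' @slot seed integer random seed.
#' @seealso [simulationConfig()], [simulateSynthesis()]
#' @export
setClass("SimulationConfig",
  representation(
    sitesPerMirror = "integer", photonMode = "character",
    photonsPerTau = "numeric", quantumEfficiency = "numeric",
    couplingEff = "numeric", cappingEff = "numeric",
    oxidationEff = "numeric", seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (!object@photonMode %in% c("aggregate_dose", "per_photon"))
    msg <- c(msg, "photonMode must be 'aggregate_dose' or 'per_photon'")
  if (object@photonsPerTau < 1)
    msg <- c(msg, "photonsPerTau must be >= 1")
  fr <- c(object@quantumEfficiency, object@couplingEff, object@cappingEff)
  if (any(fr < 0 | fr > 1))
    msg <- c(msg, "efficiencies must be fractions in [0, 1]")
  if (!identical(sort(names(object@couplingEff)), c("A", "C", "G", "T")))
    msg <- c(msg, "couplingEff must be named A, C, G, T")
  if (object@oxidationEff != 1)
    msg <- c(msg, "oxidationEff is fixed at 1 (oxidation assumed complete)")
  if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#' @param sitesPerMirror reaction-site grid factor per mirror axis.
#' @param photonMode `"aggregate_dose"` or `"per_photon"`.
#' @param photonsPerTau expected photons per site per tau of dose.
#' @param quantumEfficiency per-photon deprotection probability; `NULL`
#'   calibrates it to `1/photonsPerTau`.
#' @param couplingEff per-base stepwise coupling efficiencies, named
#'   `A`,`C`,`G`,`T` (a single value is recycled).
#' @param cappingEff capping probability per CAP cycle.
#' @param seed integer seed for the simulation generator.
#' @return A [SimulationConfig-class] object.
#' @export
simulationConfig <- function(sitesPerMirror = 4L,
                             photonMode = c("aggregate_dose", "per_photon"),
                             photonsPerTau = 100,
                             quantumEfficiency = NULL,
                             couplingEff = 0.99,
                             cappingEff = 0.95,
                             seed = 1L) {
  photonMode <- match.arg(photonMode)
  if (is.null(quantumEfficiency))
    quantumEfficiency <- calibrateQuantumEfficiency(photonsPerTau)
  if (length(couplingEff) == 1 && is.null(names(couplingEff)))
    couplingEff <- setNames(rep(couplingEff, 4), c("A", "C", "G", "T"))
  new("SimulationConfig", sitesPerMirror = as.integer(sitesPerMirror),
      photonMode = photonMode, photonsPerTau = photonsPerTau,
      quantumEfficiency = quantumEfficiency,
      couplingEff = couplingEff[c("A", "C", "G", "T")],
      cappingEff = cappingEff, oxidationEff = 1.0, seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf("SimulationConfig: %d x %d sites/mirror, %s mode, seed %d\n",
              object@sitesPerMirror, object@sitesPerMirror,
              object@photonMode, object@seed))
  cat(sprintf("  gamma(A,C,G,T) = %s, capping %.3g\n",
              paste(format(object@couplingEff, digits = 3), collapse = ", "),
              object@cappingEff))
})

#' Set of simulated product oligonucleotides
#'
#' Final per-site product sequences (5'->3', FASTA-serializable) with the
#' design each site was assigned to and run metadata (seed, configuration
#' digest, and for the scalar oracle mode the per-replicate synthesis event
#' counts).
#'
#' @slot sequences a [Biostrings::DNAStringSet] of products, 5'->3'.
#' @slot designId character vector, design id per product.
#' @slot site data.frame of site coordinates (or replicate indices).
#' @slot metadata list.
#' @seealso [scalarSimulate()], [simulateSynthesis()], [writeProducts()]
#' @export
setClass("ProductSet",
  representation(sequences = "DNAStringSet", designId = "character",
                 site = "data.frame", metadata = "list"))

setValidity("ProductSet", function(object) {
  if (length(object@sequences) != length(object@designId))
    return("one designId per product sequence required")
  TRUE
})

#' @rdname ProductSet-class
#' @param x a `ProductSet`.
#' @export
setMethod("products", "ProductSet", function(x) x@sequences)

#' @rdname ProductSet-class
#' @export
setMethod("designIds", "ProductSet", function(x) x@designId)

setMethod("length", "ProductSet", function(x) length(x@sequences))

setMethod("show", "ProductSet", function(object) {
  cat(sprintf("ProductSet: %d product(s), %d design(s), lengths %s\n",
              length(object@sequences), length(unique(object@designId)),
              if (length(object@sequences))
                paste0(min(Biostrings::width(object@sequences)), "-",
                       max(Biostrings::width(object@sequences)))
              else "-"))
})

#' Per-base synthesis error statistics
#'
#' Deletion, insertion and substitution rates per design base, plus the
#' perfect-match fraction (products identical to their design).
#'
#' @slot deletionRate,insertionRate,substitutionRate numeric, events per
#'   design base.
#' @slot perfectMatchFraction numeric in \[0, 1\].
#' @slot nProducts,nDesignBases integer counts.
#' @seealso [computeErrorStats()], [fitSynthesisParams()]
#' @export
setClass("ErrorStats",
  representation(deletionRate = "numeric", insertionRate = "numeric",
                 substitutionRate = "numeric",
                 perfectMatchFraction = "numeric",
                 nProducts = "integer", nDesignBases = "integer"))

setValidity("ErrorStats", function(object) {
  if (any(c(object@deletionRate, object@insertionRate,
            object@substitutionRate) < 0))
    return("rates must be >= 0")
  p <- object@perfectMatchFraction
  if (p < 0 || p > 1) return("perfectMatchFraction must be in [0, 1]")
  TRUE
})

#' Construct error statistics
#' @param deletionRate,insertionRate,substitutionRate events per design base.
#' @param perfectMatchFraction fraction of zero-edit products.
#' @param nProducts,nDesignBases counts behind the rates.
#' @return An [ErrorStats-class] object.
#' @export
errorStats <- function(deletionRate, insertionRate, substitutionRate = 0,
                       perfectMatchFraction, nProducts = NA_integer_,
                       nDesignBases = NA_integer_) {
  new("ErrorStats", deletionRate = deletionRate,
      insertionRate = insertionRate, substitutionRate = substitutionRate,
      perfectMatchFraction = perfectMatchFraction,
      nProducts = as.integer(nProducts),
      nDesignBases = as.integer(nDesignBases))
}

#' @rdname ErrorStats-class
#' @param x an `ErrorStats`.
#' @export
setMethod("errorRates", "ErrorStats", function(x) {
  c(deletion = x@deletionRate, insertion = x@insertionRate,
    substitution = x@substitutionRate)
})

#' @rdname ErrorStats-class
#' @export
setMethod("perfectMatchFraction", "ErrorStats",
          function(x) x@perfectMatchFraction)

setMethod("show", "ErrorStats", function(object) {
  cat(sprintf(paste0("ErrorStats: deletion %.4g, insertion %.4g, ",
                     "substitution %.4g per design base\n"),
              object@deletionRate, object@insertionRate,
              object@substitutionRate))
  cat(sprintf("  perfect match %.4g (%d products, %d design bases)\n",
              object@perfectMatchFraction, object@nProducts,
              object@nDesignBases))
})

#' Exponential coupling-efficiency fit
#'
#' Result of fitting a normalized fluorescence series `f(n)` with the
#' two-parameter decay `A * exp(-b * n)`; the average stepwise coupling
#' yield is `100 * (1 - b)` percent.
#'
#' @slot A amplitude.
#' @slot b decay per coupling (clipped at 0 from below).
#' @slot stepwiseYieldPercent `100 * (1 - b)`.
#' @slot residualNorm residual sum of squares of the fit.
#' @slot clipped logical, TRUE if a negative fitted decay was clipped to 0.
#' @seealso [fitCouplingEfficiency()]
#' @export
setClass("CouplingFit",
  representation(A = "numeric", b = "numeric",
                 stepwiseYieldPercent = "numeric",
                 residualNorm = "numeric", clipped = "logical"))

setValidity("CouplingFit", function(object) {
  if (object@b < 0 || object@b >= 1)
    return("decay b must satisfy 0 <= b < 1 for a valid fit")
  if (abs(object@stepwiseYieldPercent - 100 * (1 - object@b)) > 1e-8)
    return("stepwiseYieldPercent must equal 100 * (1 - b)")
  TRUE
})

setMethod("show", "CouplingFit", function(object) {
  cat(sprintf("CouplingFit: A = %.4g, b = %.4g -> stepwise yield %.2f%%%s\n",
              object@A, object@b, object@stepwiseYieldPercent,
              if (object@clipped) " (negative decay clipped to 0)" else ""))
})

#' Photodeprotection dose-constant fit
#'
#' @slot tau dose constant, in the units of the supplied doses
#'   (J/cm^2 for calibration series).
#' @slot residualNorm residual sum of squares.
#' @slot nPoints number of dose points fitted.
#' @seealso [fitTau()]
#' @export
setClass("TauFit",
  representation(tau = "numeric", residualNorm = "numeric",
                 nPoints = "integer"))

setValidity("TauFit", function(object) {
  if (object@tau <= 0) return("tau must be positive") else TRUE
})

setMethod("show", "TauFit", function(object) {
  cat(sprintf("TauFit: tau = %.4g (residual norm %.3g, %d points)\n",
              object@tau, object@residualNorm, object@nPoints))
})

#' Synthesis-parameter fit from observed error statistics
#'
#' @slot gamma stepwise coupling efficiency.
#' @slot d photodeprotection dose, tau-units.
#' @slot R optical contrast.
#' @slot objective value of the summed squared relative deviation.
#' @slot gridStep numeric length-3, the coarse grid spacing in
#'   (gamma, d, log R) used before refinement.
#' @slot boundary logical, TRUE when the fit sits on a search bound (e.g.
#'   degenerate zero-error statistics).
#' @seealso [fitSynthesisParams()]
#' @export
setClass("SynthesisFit",
  representation(gamma = "numeric", d = "numeric", R = "numeric",
                 objective = "numeric", gridStep = "numeric",
                 boundary = "logical"))

setMethod("show", "SynthesisFit", function(object) {
  cat(sprintf("SynthesisFit: gamma %.4g, d %.4g tau, R %.4g (objective %.3g)%s\n",
              object@gamma, object@d, object@R, object@objective,
              if (object@boundary) " [boundary]" else ""))
})
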