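# Stochastic per-site synthesis simulation.
#
# Each reaction site carries a growing strand (deposition order), a
# hydroxyl flag (deprotected but not yet coupled - the state persists
# across cycles until a coupling succeeds) and a capped flag (no further
# growth). Exposure either draws explicit photon arrivals (Poisson counts
# apportioned by inverse-transform sampling of the intensity distribution,
# each photon succeeding with the quantum efficiency) or applies the
# aggregate first-order dose law 1 - exp(-d_site). Coupling and capping
# are zero-order events applied with their efficiencies; oxidation is
# taken as complete.

#' Calibrate the per-photon quantum efficiency
#'
#' In per-photon mode a site receiving relative intensity `I` during a
#' dose of `d` tau-units draws `Poisson(photonsPerTau * d * I)` photons,
#' each deprotecting with probability `q`. The deprotection probability is
#' then `1 - exp(-photonsPerTau * d * I * q)`, so `q = 1/photonsPerTau`
#' makes the per-photon mode reproduce the aggregate first-order law
#' `1 - exp(-d I)` exactly, for any photon budget.
#'
#' @param photonsPerTau expected photons per site per tau of plateau dose.
#' @return The calibrated quantum efficiency `1/photonsPerTau`.
#' @export
calibrateQuantumEfficiency <- function(photonsPerTau) {
  if (any(photonsPerTau < 1)) stop("photonsPerTau must be >= 1")
  1 / photonsPerTau
}

#' Bilinearly upsample an intensity map to reaction-site density
#'
#' Interpolates the map at arbitrary query points (bilinear in the two
#' axes; values at original sample nodes are preserved). With the default
#' site layout, sites form a `siteGrid` x `siteGrid` grid per mirror cell.
#'
#' @param map an [IntensityMap-class].
#' @param x,y query coordinates in micrometres (sample centres sit at
#'   `(i - 0.5) * pixelSize`). Both are recycled to a common length.
#' @return Numeric vector of interpolated intensities.
#' @export
upsampleIntensity <- function(map, x, y) {
  stopifnot(is(map, "IntensityMap"))
  v <- map@values; res <- map@pixelSize
  nr <- nrow(v); nc <- ncol(v)
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  # fractional sample coordinates (1-based, sample centres at integers)
  fx <- pmin(pmax(x / res + 0.5, 1), nc)
  fy <- pmin(pmax(y / res + 0.5, 1), nr)
  x0 <- pmin(floor(fx), nc - 1); y0 <- pmin(floor(fy), nr - 1)
  wx <- fx - x0; wy <- fy - y0
  v[cbind(y0, x0)] * (1 - wx) * (1 - wy) +
    v[cbind(y0, x0 + 1)] * wx * (1 - wy) +
    v[cbind(y0 + 1, x0)] * (1 - wx) * wy +
    v[cbind(y0 + 1, x0 + 1)] * wx * wy
}

#' Sample photon arrivals over reaction sites
#'
#' Draws a total photon count `Poisson(photonsPerTau * dose * sum(I))` and
#' assigns each photon to a site by inverse-transform sampling of the
#' cumulative site-intensity distribution.
#'
#' @param intensity non-negative per-site relative intensities (vector or
#'   matrix).
#' @param dose plateau dose in tau-units.
#' @param config a [SimulationConfig-class] (per-photon parameters).
#' @return Integer photon counts with the shape of `intensity`.
#' @export
samplePhotonArrivals <- function(intensity, dose, config = simulationConfig()) {
  if (any(intensity < 0)) stop("intensities must be >= 0")
  tot <- sum(intensity)
  counts <- intensity * 0L
  if (tot == 0 || dose == 0) return(counts)
  n <- rpois(1, config@photonsPerTau * dose * tot)
  if (n == 0) return(counts)
  cdf <- cumsum(as.vector(intensity)) / tot
  idx <- findInterval(runif(n), cdf) + 1L   # inverse-transform assignment
  tab <- tabulate(idx, nbins = length(intensity))
  counts[] <- tab
  counts
}

# fresh site-state store
.newSites <- function(n, designId) {
  list(seq = character(n),          # assembled strand, deposition order
       hydroxyl = logical(n),       # deprotected, awaiting coupling
       capped = logical(n),
       designId = designId)
}

#' Run one synthesis cycle over a set of sites
#'
#' Exposure phase: sites become hydroxyl-free (deprotected) according to
#' the per-site dose, via the aggregate dose law or explicit photon
#' arrivals; the deprotected state persists across cycles until a
#' coupling succeeds. Coupling phase (base cycles): each deprotected,
#' uncapped site appends the cycle base with the base's coupling
#' efficiency. CAP cycles cap each deprotected site with the capping
#' efficiency; capped sites never grow again.
#'
#' @param sites site-state list from a simulation (fields `seq`,
#'   `hydroxyl`, `capped`, `designId`).
#' @param base cycle base (`A`,`C`,`G`,`T`, `CAP` or `LABEL`).
#' @param doses per-site dose vector, tau-units (length of the site set).
#' @param config a [SimulationConfig-class].
#' @param coupling whether a coupling follows the exposure.
#' @return The updated site-state list.
#' @export
runCycle <- function(sites, base, doses, config = simulationConfig(),
                     coupling = TRUE) {
  n <- length(sites$seq)
  if (length(doses) != n)
    stop("dose grid shape mismatch: ", length(doses), " doses for ", n,
         " sites")
  # exposure
  if (any(doses > 0)) {
    if (config@photonMode == "per_photon") {
      k <- samplePhotonArrivals(doses, 1, config)  # dose folded into rate
      pDep <- 1 - (1 - config@quantumEfficiency)^k
    } else {
      pDep <- 1 - exp(-doses)
    }
    sites$hydroxyl <- sites$hydroxyl | (runif(n) < pDep)
  }
  if (base == "CAP") {
    hit <- sites$hydroxyl & !sites$capped &
      (runif(n) < config@cappingEff)
    sites$capped <- sites$capped | hit
    sites$hydroxyl[hit] <- FALSE
  } else if (coupling && base %in% c("A", "C", "G", "T")) {
    gamma <- config@couplingEff[[base]]
    can <- sites$hydroxyl & !sites$capped
    ok <- can & (runif(n) < gamma)
    sites$seq[ok] <- paste0(sites$seq[ok], base)
    sites$hydroxyl[ok] <- FALSE
  }
  sites
}

.reverseStrings <- function(x) {
  vapply(strsplit(x, ""), function(ch) paste(rev(ch), collapse = ""), "")
}

#' Simulate a synthesis schedule over replicate sites
#'
#' Runs every cycle of a schedule over `replicates` reaction sites per
#' feature. Per-site doses come from the schedule: a feature ON in a cycle
#' receives the cycle dose; a feature OFF while others are ON receives the
#' stray dose `dose / contrast` (scalar-contrast mode). Supplying per-cycle
#' intensity maps instead routes doses through [siteDoseMap()].
#'
#' @param schedule a [SynthesisSchedule-class] with designs.
#' @param config a [SimulationConfig-class]; its `seed` fixes the run.
#' @param contrast scalar optical contrast R (default `Inf`: no stray
#'   light).
#' @param replicates sites per feature (default `sitesPerMirror^2`).
#' @param intensityMaps optional list of [IntensityMap-class], one per
#'   cycle (aerial images of the cycle masks); requires `assignment`.
#'   Sites are then the physical `sitesPerMirror^2`-per-mirror grid and
#'   per-cycle doses come from [siteDoseMap()], so diffraction, flare and
#'   gap exposure reach the simulated chemistry. `replicates` is ignored.
#' @param assignment mirror-to-feature matrix from [assignFeatures()]
#'   (map mode only).
#' @return A [ProductSet-class] (sequences 5'->3').
#' @examples
#' sch <- cyclicSchedule(c(x = "ACGT"), dose = 20)
#' cfg <- simulationConfig(couplingEff = 1, seed = 7)
#' as.character(products(simulateSynthesis(sch, cfg)))  # perfect replay
#' @export
simulateSynthesis <- function(schedule, config = simulationConfig(),
                              contrast = Inf, replicates = NULL,
                              intensityMaps = NULL, assignment = NULL) {
  stopifnot(is(schedule, "SynthesisSchedule"))
  validObject(config)
  set.seed(config@seed)
  if (is.null(replicates)) replicates <- config@sitesPerMirror^2
  ids <- schedule@featureIds
  if (!length(ids)) stop("schedule carries no features")
  useMaps <- !is.null(intensityMaps)
  if (useMaps) {
    if (is.null(assignment))
      stop("intensity-map mode needs the mirror-to-feature assignment")
    if (length(intensityMaps) != length(schedule@base))
      stop("need one intensity map per cycle")
    s <- config@sitesPerMirror
    # expand the mirror assignment to the site grid
    designId <- assignment[rep(seq_len(nrow(assignment)), each = s),
                           rep(seq_len(ncol(assignment)), each = s)]
    siteDf <- expand.grid(row = seq_len(nrow(assignment) * s),
                          col = seq_len(ncol(assignment) * s))
    designId <- as.vector(designId)
  } else {
    designId <- rep(ids, each = replicates)
    siteDf <- data.frame(feature = designId,
                         replicate = rep(seq_len(replicates),
                                         times = length(ids)))
  }
  sites <- .newSites(length(designId), ifelse(is.na(designId), "",
                                              designId))
  for (k in seq_along(schedule@base)) {
    on <- schedule@onFeatures[[k]]
    d <- schedule@dose[k]
    if (useMaps) {
      sd <- siteDoseMap(intensityMaps[[k]], d, config@sitesPerMirror)
      doses <- as.vector(sd)
    } else {
      doses <- numeric(length(designId))
      if (length(on)) {
        onSite <- !is.na(designId) & designId %in% on
        doses[onSite] <- d
        if (is.finite(contrast)) doses[!onSite] <- d / contrast
      }
    }
    sites <- runCycle(sites, schedule@base[k], doses, config,
                      schedule@coupling[k])
  }
  new("ProductSet",
      sequences = Biostrings::DNAStringSet(.reverseStrings(sites$seq)),
      designId = sites$designId,
      site = siteDf,
      metadata = list(seed = config@seed, contrast = contrast,
                      nCycles = length(schedule@base),
                      designs = schedule@designs))
}

#' Scalar-mode Monte-Carlo synthesis (closed-form oracle mode)
#'
#' Simulates the independence assumptions of the closed-form yield model
#' exactly, without a schedule: each replicate strand experiences, per
#' designed base, `nDarkPerBase` dark exposures at dose `d/R` (each
#' deprotecting with probability `1 - exp(-d/R)` and then coupling the
#' upcoming base with probability `gamma` - an insertion) followed by one
#' bright exposure at dose `d` (deprotecting with probability
#' `1 - exp(-d)`) and its coupling (probability `gamma`). All events are
#' independent, so the per-base deletion rate, insertion rate and
#' perfect-match fraction converge to the closed forms of
#' [expectedErrorRates()] and [correctSequenceYield()].
#'
#' @param gamma stepwise coupling efficiency.
#' @param dose bright dose d, tau-units.
#' @param contrast optical contrast R.
#' @param length design length N (ignored when `design` is given).
#' @param nDarkPerBase dark exposures per designed base.
#' @param replicates number of strands.
#' @param seed integer seed.
#' @param design optional explicit design (5'->3'); default a random
#'   N-mer drawn under the seed.
#' @return A [ProductSet-class]; `metadata$events` holds per-run totals
#'   (`deletions`, `insertions`, `perfect` count) measured from the
#'   simulated events themselves.
#' @examples
#' ps <- scalarSimulate(0.983, 2.1, 340, 70, replicates = 200, seed = 1)
#' ps@metadata$events$deletions / (200 * 70)   # ~ closed-form 0.137
#' @export
scalarSimulate <- function(gamma, dose, contrast, length = 70,
                           nDarkPerBase = 3, replicates = 1000,
                           seed = 1, design = NULL) {
  .checkYieldArgs(gamma, contrast, 1, dose, nDarkPerBase)
  set.seed(seed)
  if (is.null(design)) {
    design <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                    collapse = "")
  }
  N <- nchar(design)
  depBases <- rev(strsplit(design, "")[[1]])   # deposition order
  pBright <- (1 - exp(-dose)) * gamma
  pDark <- if (is.finite(contrast)) (1 - exp(-dose / contrast)) * gamma else 0
  # per (replicate, base): present flag and dark-insertion count
  present <- matrix(runif(replicates * N) < pBright, replicates, N)
  ins <- matrix(rbinom(replicates * N, nDarkPerBase, pDark), replicates, N)
  seqs <- vapply(seq_len(replicates), function(r) {
    paste(rep(depBases, ins[r, ] + present[r, ]), collapse = "")
  }, "")
  perfect <- rowSums(!present) == 0 & rowSums(ins) == 0
  new("ProductSet",
      sequences = Biostrings::DNAStringSet(.reverseStrings(seqs)),
      designId = rep("design1", replicates),
      site = data.frame(replicate = seq_len(replicates)),
      metadata = list(
        seed = seed, mode = "scalar",
        params = list(gamma = gamma, dose = dose, contrast = contrast,
                      N = N, nDarkPerBase = nDarkPerBase),
        designs = c(design1 = design),
        events = list(deletions = sum(!present), insertions = sum(ins),
                      perfect = sum(perfect),
                      nDesignBases = replicates * N,
                      nProducts = replicates)))
}

#' Insert a capping step after every coupling cycle
#'
#' Returns the schedule with a zero-dose CAP cycle following each
#' base-coupling cycle: sites left with a free hydroxyl by a failed
#' coupling are capped (with the configured capping efficiency) and take
#' no further part in synthesis — the standard failure-truncation step.
#'
#' @param schedule a [SynthesisSchedule-class].
#' @return The expanded [SynthesisSchedule-class].
#' @export
withCapping <- function(schedule) {
  stopifnot(is(schedule, "SynthesisSchedule"))
  base <- character(); dose <- numeric(); coupling <- logical()
  onF <- list(); masks <- list()
  hasMasks <- length(schedule@masks) > 0
  zeroMask <- if (hasMasks)
    maskPattern(mirrorStates(schedule@masks[[1]]) * 0L)
  for (k in seq_along(schedule@base)) {
    base <- c(base, schedule@base[k])
    dose <- c(dose, schedule@dose[k])
    coupling <- c(coupling, schedule@coupling[k])
    onF <- c(onF, schedule@onFeatures[k])
    if (hasMasks) masks <- c(masks, schedule@masks[k])
    if (schedule@coupling[k] && schedule@base[k] %in% c("A", "C", "G", "T")) {
      base <- c(base, "CAP"); dose <- c(dose, 0)
      coupling <- c(coupling, FALSE); onF <- c(onF, list(character()))
      if (hasMasks) masks <- c(masks, list(zeroMask))
    }
  }
  new("SynthesisSchedule", base = base, dose = dose, coupling = coupling,
      onFeatures = onF, masks = masks,
      featureIds = schedule@featureIds, designs = schedule@designs)
}

#' Event-count error statistics of a scalar simulation
#'
#' Rates computed from the simulator's own recorded synthesis events
#' (deletions = failed designed bases, insertions = stray couplings),
#' not from alignment; see [computeErrorStats()] for the alignment-based
#' measurement.
#'
#' @param productSet a [ProductSet-class] from [scalarSimulate()].
#' @return An [ErrorStats-class].
#' @export
eventErrorStats <- function(productSet) {
  ev <- productSet@metadata$events
  if (is.null(ev)) stop("no event record in this ProductSet")
  errorStats(deletionRate = ev$deletions / ev$nDesignBases,
             insertionRate = ev$insertions / ev$nDesignBases,
             substitutionRate = 0,
             perfectMatchFraction = ev$perfect / ev$nProducts,
             nProducts = ev$nProducts, nDesignBases = ev$nDesignBases)
}

#' Write a product set to FASTA
#'
#' Headers follow `site_<row>_<col> design=<id>` (or
#' `rep_<k> design=<id>` for scalar replicates).
#'
#' @param productSet a [ProductSet-class].
#' @param path output FASTA path.
#' @return The path, invisibly.
#' @export
writeProducts <- function(productSet, path) {
  stopifnot(is(productSet, "ProductSet"))
  s <- productSet@sequences
  st <- productSet@site
  labels <- if (all(c("row", "col") %in% names(st))) {
    sprintf("site_%d_%d design=%s", st$row, st$col, productSet@designId)
  } else if (all(c("feature", "replicate") %in% names(st))) {
    sprintf("site_%s_%d design=%s", st$feature, st$replicate,
            productSet@designId)
  } else {
    sprintf("rep_%d design=%s", seq_along(s), productSet@designId)
  }
  names(s) <- labels
  Biostrings::writeXStringSet(s, path)
  invisible(path)
}
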