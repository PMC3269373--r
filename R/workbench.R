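# Seedable synthetic fixtures and the end-to-end demo pipeline.
#
# Every generator is a pure function of its arguments including the seed,
# so all stages are testable without external data.

#' Generate a synthetic coupling-efficiency series
#'
#' Emulates the 4-plex length-series experiment: oligonucleotides
#' `T15-Xn-T2` with `n` experimental couplings, terminally labelled, whose
#' background-corrected normalized intensity decays as `gamma^(n-1)`
#' (the first coupling defines the reference). Multiplicative Gaussian
#' noise models scanner and background-subtraction error.
#'
#' @param gamma generating stepwise coupling efficiency.
#' @param nMax largest coupling count (default 12, the experiment's
#'   design).
#' @param noiseSd multiplicative Gaussian noise standard deviation.
#' @param seed integer seed (`NULL` leaves the generator state alone).
#' @return data.frame with columns `n` (1..nMax) and `f`.
#' @export
genCouplingSeries <- function(gamma = 0.99, nMax = 12, noiseSd = 0,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- seq_len(nMax)
  f <- gamma^(n - 1) * (1 + rnorm(nMax, 0, noiseSd))
  data.frame(n = n, f = f)
}

#' Generate a synthetic photodeprotection dose-response series
#'
#' The direct-labelling dose-calibration experiment: responses
#' `1 - exp(-dose/tau)` plus additive Gaussian noise, over a default
#' 13-step 0-30 J/cm^2 gradient.
#'
#' @param tau generating dose constant, J/cm^2.
#' @param doses dose grid, J/cm^2.
#' @param noiseSd additive Gaussian noise standard deviation.
#' @param seed integer seed.
#' @return data.frame with columns `dose` and `response`.
#' @export
genDoseResponse <- function(tau = 2.5, doses = seq(0, 30, by = 2.5),
                            noiseSd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(dose = doses,
             response = 1 - exp(-doses / tau) + rnorm(length(doses), 0,
                                                      noiseSd))
}

#' Generate random design sequences
#'
#' Uniform random DNA designs; in primer-flanked mode each design is a
#' 70-mer built from a random core of `length` bases (default 40) between
#' the same pair of random 15-mer primers, the layout used for
#' sequencing-ready arrays.
#'
#' @param nSeqs number of designs.
#' @param length core design length in bases.
#' @param seed integer seed.
#' @param primerFlanked flank each core with common 15-mer primers.
#' @return A [Biostrings::DNAStringSet] named `seq1 ... seqN`.
#' @export
genDesigns <- function(nSeqs, length = 40, seed = NULL,
                       primerFlanked = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  rand <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                   replace = TRUE), collapse = "")
  if (primerFlanked) {
    left <- rand(15); right <- rand(15)
    seqs <- vapply(seq_len(nSeqs),
                   function(i) paste0(left, rand(length), right), "")
  } else {
    seqs <- vapply(seq_len(nSeqs), function(i) rand(length), "")
  }
  Biostrings::DNAStringSet(setNames(seqs, paste0("seq", seq_len(nSeqs))))
}

#' Read and write a run configuration
#'
#' A JSON document with a `seed`, optional `outputDir` and `logLevel`,
#' and per-module parameter blocks `optics`, `simulation` and `fitting`.
#' Unknown top-level keys are rejected.
#'
#' @param path JSON file path.
#' @param config a run-configuration list.
#' @return `readRunConfig` the validated configuration list.
#' @export
readRunConfig <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("seed", "outputDir", "logLevel", "optics", "simulation",
             "fitting")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop("unknown configuration keys: ", paste(extra, collapse = ", "))
  cfg
}

#' @rdname readRunConfig
#' @export
writeRunConfig <- function(config, path) {
  known <- c("seed", "outputDir", "logLevel", "optics", "simulation",
             "fitting")
  extra <- setdiff(names(config), known)
  if (length(extra))
    stop("unknown configuration keys: ", paste(extra, collapse = ", "))
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run the end-to-end demonstration pipeline
#'
#' Designs -> cyclic schedule -> scalar-contrast Monte-Carlo synthesis ->
#' alignment error statistics -> synthesis-parameter fit, with the
#' closed-form expectations alongside. Scales are chosen for interactive
#' desk use.
#'
#' @param seed integer seed controlling every random draw.
#' @param nSeqs,designLength array design (defaults 4 designs of 25
#'   bases).
#' @param gamma,dose,contrast synthesis conditions (tau-unit dose).
#' @param replicates Monte-Carlo strands per design.
#' @param dir optional directory; when given, products (FASTA), stats and
#'   the report (JSON) are written there.
#' @return Report list: schedule summary, observed [ErrorStats-class]
#'   values, closed-form expectations, and the recovered parameters.
#' @export
demoPipeline <- function(seed = 1, nSeqs = 4, designLength = 25,
                         gamma = 0.99, dose = 4.77, contrast = 350,
                         replicates = 400, dir = NULL) {
  designs <- genDesigns(nSeqs, designLength, seed = seed)
  sch <- cyclicSchedule(designs, skipEmpty = FALSE, dose = dose)
  dark <- darkExposureCount(sch)
  cfg <- simulationConfig(couplingEff = gamma, seed = seed + 1)
  ps <- simulateSynthesis(sch, cfg, contrast = contrast,
                          replicates = replicates)
  stats <- computeErrorStats(ps, as.character(designs))
  nDark <- mean(dark) / designLength     # this schedule's dark exposures
  expected <- expectedErrorRates(gamma, contrast, dose, nDark)
  expected$perfectMatch <- correctSequenceYield(gamma, contrast,
                                                designLength, dose, nDark)
  fit <- fitSynthesisParams(stats, N = designLength, nDarkPerBase = nDark)
  report <- list(
    seed = seed,
    schedule = list(cycles = length(sch), meanDarkPerBase =
                      mean(dark) / designLength),
    observed = list(deletionRate = stats@deletionRate,
                    insertionRate = stats@insertionRate,
                    substitutionRate = stats@substitutionRate,
                    perfectMatchFraction = stats@perfectMatchFraction),
    closedForm = expected,
    fit = list(gamma = fit@gamma, d = fit@d, R = fit@R,
               objective = fit@objective))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeProducts(ps, file.path(dir, "products.fa"))
    jsonlite::write_json(report, file.path(dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}
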