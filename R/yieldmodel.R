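# Closed-form correct-sequence yield under a scalar-contrast model.
#
# In the one-base-per-four-cycles protocol every designed base costs one
# bright exposure (dose d, tau-units) and leaves the feature dark for the
# other three exposures, each delivering the stray dose d/R through the
# finite optical contrast R. With stepwise coupling efficiency gamma the
# correct-sequence yield of an N-mer is
#
#   Y(R, d) = (gamma * deltaBright)^N * (1 - deltaDark)^(nDark * N)
#   deltaBright = 1 - exp(-d),  deltaDark = 1 - exp(-d / R)
#
# which has an interior maximum in d for finite R: more dose completes the
# intended deprotections, but also drives stray-light insertions.

.checkYieldArgs <- function(gamma, contrast, length, dose, nDarkPerBase) {
  if (any(gamma <= 0 | gamma > 1)) stop("gamma must be in (0, 1]")
  if (any(contrast <= 0)) stop("contrast R must be positive")
  if (any(length < 1)) stop("design length N must be >= 1")
  if (any(dose < 0)) stop("dose must be >= 0")
  if (any(nDarkPerBase < 0)) stop("nDarkPerBase must be >= 0")
  invisible(TRUE)
}

#' Closed-form correct-sequence yield
#'
#' Probability that an N-mer is synthesized without deletions or
#' stray-light insertions:
#' `(gamma * (1 - exp(-d)))^N * exp(-d/R)^(nDarkPerBase * N)`.
#'
#' @param gamma stepwise coupling efficiency fraction in (0, 1].
#' @param contrast optical contrast R (> 0; dark dose = bright dose / R).
#'   `Inf` is accepted (no stray light).
#' @param length design length N in bases.
#' @param dose photodeprotection dose d, tau-units (vectorized).
#' @param nDarkPerBase dark exposures per designed base (3 for the
#'   one-base-per-four-cycles protocol; see [darkExposureCount()] for
#'   arbitrary schedules).
#' @return Correct-sequence yield in \[0, 1\].
#' @examples
#' correctSequenceYield(0.99, 350, 25, optimalDose(350))
#' @export
correctSequenceYield <- function(gamma, contrast, length, dose,
                                 nDarkPerBase = 3) {
  .checkYieldArgs(gamma, contrast, length, dose, nDarkPerBase)
  bright <- gamma * (1 - exp(-dose))
  darkOK <- if (is.infinite(contrast)) 1 else exp(-dose / contrast)
  bright^length * darkOK^(nDarkPerBase * length)
}

#' Optimal photodeprotection dose for maximum correct-sequence yield
#'
#' The stationary point of the yield in `d` is independent of `gamma` and
#' `N` and has the closed form `d* = log(1 + R / nDarkPerBase)` tau-units.
#' For infinite contrast the yield is monotone in dose and no interior
#' maximum exists (error).
#'
#' @param contrast optical contrast R (finite, > 0; vectorized).
#' @param nDarkPerBase dark exposures per designed base.
#' @return Optimal dose in tau-units.
#' @examples
#' optimalDose(350)        # ~4.77 tau
#' optimalDose(3)          # log(2)
#' @export
optimalDose <- function(contrast, nDarkPerBase = 3) {
  if (any(!is.finite(contrast)))
    stop("contrast is infinite: yield is monotone in dose, no interior maximum")
  if (any(contrast <= 0)) stop("contrast R must be positive")
  if (any(nDarkPerBase <= 0))
    stop("nDarkPerBase must be positive for an interior maximum")
  log(1 + contrast / nDarkPerBase)
}

#' Full-length yield and fold change between coupling efficiencies
#'
#' `fullLengthYield` is the fraction of chains reaching full length,
#' `gamma^N`; `yieldFoldChange` compares two stepwise efficiencies,
#' `(g1/g2)^N`. Raising the stepwise efficiency of 60-mer synthesis from
#' 93% to 99% multiplies the full-length yield about 40-fold; from 97.5%
#' to 99%, about 2.5-fold.
#'
#' @param gamma,g1,g2 stepwise coupling efficiencies in (0, 1].
#' @param length design length N in bases.
#' @return A yield fraction, or a fold change (dimensionless).
#' @examples
#' yieldFoldChange(0.99, 0.93, 60)    # ~42.6
#' yieldFoldChange(0.99, 0.975, 60)   # ~2.5
#' @export
fullLengthYield <- function(gamma, length) {
  if (any(gamma <= 0 | gamma > 1)) stop("gamma must be in (0, 1]")
  gamma^length
}

#' @rdname fullLengthYield
#' @export
yieldFoldChange <- function(g1, g2, length) {
  fullLengthYield(g1, length) / fullLengthYield(g2, length)
}

#' Final-yield effect of a small stepwise-efficiency drop
#'
#' Relative reduction of the correct-sequence yield of an N-mer when the
#' stepwise coupling efficiency drops by `delta` (in absolute percentage
#' points expressed as a fraction): `1 - ((gamma - delta)/gamma)^N`. A 0.2
#' percentage-point drop costs about 5% of the final yield of 25-mers.
#'
#' @param gamma reference stepwise efficiency in (0, 1].
#' @param delta absolute drop (fraction, e.g. 0.002 for 0.2 points).
#' @param length design length N.
#' @return Relative final-yield reduction in \[0, 1\].
#' @examples
#' stepwiseDeltaEffect(1.0, 0.002, 25)   # ~0.049
#' @export
stepwiseDeltaEffect <- function(gamma, delta, length) {
  if (any(gamma <= 0 | gamma > 1)) stop("gamma must be in (0, 1]")
  if (any(delta < 0 | delta >= gamma)) stop("delta must be in [0, gamma)")
  1 - ((gamma - delta) / gamma)^length
}

#' Expected per-base deletion and insertion rates
#'
#' Under the scalar-contrast model each designed base is deleted when its
#' bright deprotection or its coupling fails:
#' `deletion = 1 - gamma * (1 - exp(-d))`; and each of the `nDarkPerBase`
#' dark exposures per base inserts with probability
#' `gamma * (1 - exp(-d/R))`, so the expected insertions per design base
#' are `nDarkPerBase * gamma * (1 - exp(-d/R))`.
#'
#' @inheritParams correctSequenceYield
#' @return List with `deletion` and `insertion`, events per design base.
#' @examples
#' expectedErrorRates(0.983, 340, 2.1)   # deletion ~0.137
#' @export
expectedErrorRates <- function(gamma, contrast, dose, nDarkPerBase = 3) {
  if (any(gamma <= 0 | gamma > 1)) stop("gamma must be in (0, 1]")
  if (any(contrast <= 0)) stop("contrast R must be positive")
  if (any(dose < 0)) stop("dose must be >= 0")
  darkDep <- if (all(is.infinite(contrast))) 0 else 1 - exp(-dose / contrast)
  list(deletion = 1 - gamma * (1 - exp(-dose)),
       insertion = nDarkPerBase * gamma * darkDep)
}
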