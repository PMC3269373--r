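# Photodeprotection kinetics and efficiency estimation.
#
# Removal of the photolabile 5'-hydroxyl protecting group is first order in
# the remaining protected fraction: dsigma/dt = -k I sigma, so after a
# radiant exposure (dose) D the protected fraction is exp(-D/tau) with
# tau = 1/k the dose constant (about 2.5 J/cm^2 for NPPOC under i-line
# exposure in 1% imidazole/DMSO).

.doseTau <- function(dose, tau, units) {
  units <- match.arg(units, c("J", "tau"))
  if (any(dose < 0)) stop("dose must be >= 0")
  if (units == "J") {
    if (tau <= 0) stop("tau must be positive")
    dose / tau
  } else dose
}

#' Protected fraction after a photodeprotection dose
#'
#' `exp(-dose/tau)`: the fraction of 5'-protecting groups surviving a
#' radiant exposure.
#'
#' @param dose radiant exposure (vectorized), in J/cm^2 (`units = "J"`,
#'   default) or already in tau-units (`units = "tau"`).
#' @param tau dose constant in J/cm^2 (ignored for `units = "tau"`).
#' @param units dose units.
#' @return Protected fraction in \[0, 1\].
#' @examples
#' protectedFraction(12, tau = 2.5)   # ~0.0082 at the full-deprotection dose
#' @export
protectedFraction <- function(dose, tau = 2.5, units = c("J", "tau")) {
  exp(-.doseTau(dose, tau, units))
}

#' Photodeprotection yield after a dose
#'
#' `1 - exp(-dose/tau)`: monotone in dose, approaching 1. At 5 tau the
#' yield is 99.33% (commonly quoted as "full" deprotection).
#'
#' @inheritParams protectedFraction
#' @return Deprotection yield in \[0, 1).
#' @examples
#' deprotectionYield(5, units = "tau")   # 0.9933
#' @export
deprotectionYield <- function(dose, tau = 2.5, units = c("J", "tau")) {
  1 - exp(-.doseTau(dose, tau, units))
}

#' Radiant exposure from irradiance and time
#'
#' @param irradiance W/cm^2 (vectorized).
#' @param time seconds.
#' @return Dose in J/cm^2. A typical 0.1 W/cm^2 lamp delivers 6 J/cm^2 in
#'   60 s.
#' @export
radiantExposure <- function(irradiance, time) {
  if (any(irradiance < 0) || any(time < 0))
    stop("irradiance and time must be >= 0")
  irradiance * time
}

.checkSeries <- function(x, cols) {
  x <- as.data.frame(x)
  if (!all(cols %in% names(x)))
    stop("series needs columns: ", paste(cols, collapse = ", "))
  x
}

#' Fit the photodeprotection dose constant to a dose-response series
#'
#' Least-squares fit of `F(d) = 1 - exp(-d/tau)` to normalized fluorescence
#' responses, the direct-labelling dose-calibration experiment. Initialized
#' log-linearly from `log(1 - F)` over points with `F < 1`, then refined
#' with Levenberg-Marquardt. Responses are not constrained to be at most 1
#' (measurement noise); the fit is unconstrained.
#'
#' @param series data.frame with columns `dose` (J/cm^2, or any consistent
#'   unit) and `response` (normalized fluorescence fraction); at least 3
#'   distinct doses.
#' @return A [TauFit-class] with `tau` in the dose units supplied.
#' @examples
#' s <- genDoseResponse(tau = 2.5, noiseSd = 0)
#' fitTau(s)
#' @export
fitTau <- function(series) {
  s <- .checkSeries(series, c("dose", "response"))
  if (length(unique(s$dose)) < 3)
    stop("at least 3 distinct doses are required")
  if (any(s$dose < 0)) stop("doses must be >= 0")
  if (all(s$response <= 0))
    stop("degenerate series: all responses are <= 0")
  pos <- s$dose > 0 & s$response > 0 & s$response < 1
  tau0 <- if (sum(pos) >= 2) {
    f <- stats::lm(log(1 - s$response[pos]) ~ 0 + s$dose[pos])
    -1 / unname(coef(f)[1])
  } else max(s$dose) / 3
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- max(s$dose) / 3
  fit <- tryCatch(
    minpack.lm::nlsLM(response ~ 1 - exp(-dose / tau), data = s,
                      start = list(tau = tau0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("tau fit did not converge: ",
                             conditionMessage(e)))
  tau <- unname(coef(fit)[["tau"]])
  if (tau <= 0) stop("tau fit converged to a non-positive dose constant")
  new("TauFit", tau = tau, residualNorm = sum(resid(fit)^2),
      nPoints = nrow(s))
}

#' Background-corrected normalized fluorescence intensity
#'
#' `(Ia - Ib) / (Ic - Id)`: a labelled feature minus its unlabelled
#' background, relative to a reference feature minus its background. Used
#' to express coupling-series intensities on a common scale.
#'
#' @param Ia,Ib,Ic,Id fluorescence intensities (arbitrary units,
#'   vectorized); the reference difference `Ic - Id` must be positive.
#' @return Normalized intensity fraction.
#' @export
normalizedIntensity <- function(Ia, Ib, Ic, Id) {
  den <- Ic - Id
  if (any(den <= 0)) stop("reference difference Ic - Id must be positive")
  (Ia - Ib) / den
}

#' Fit stepwise coupling efficiency to a normalized intensity series
#'
#' Fits the two-parameter single-exponential decay `f(n) = A * exp(-b n)`
#' to normalized intensities of an oligonucleotide length series; the
#' average stepwise coupling yield over the series is `100 (1 - b)`
#' percent. A negative fitted decay (rising series, within noise) is
#' clipped to 0 with a warning, capping the yield at 100%.
#'
#' @param series data.frame with columns `n` (coupling count, strictly
#'   increasing, >= 1) and `f` (normalized intensity); at least 3 points.
#' @return A [CouplingFit-class].
#' @examples
#' s <- genCouplingSeries(gamma = 0.99, noiseSd = 0)
#' fitCouplingEfficiency(s)   # 99% stepwise yield
#' @export
fitCouplingEfficiency <- function(series) {
  s <- .checkSeries(series, c("n", "f"))
  if (nrow(s) < 3) stop("at least 3 points are required")
  if (any(diff(s$n) <= 0)) stop("coupling counts n must be strictly increasing")
  if (any(s$f <= 0)) stop("normalized intensities must be positive for the fit")
  ini <- stats::lm(log(f) ~ n, data = s)
  start <- list(A = exp(unname(coef(ini)[1])), b = -unname(coef(ini)[2]))
  iniRss <- sum((start$A * exp(-start$b * s$n) - s$f)^2)
  if (iniRss < 1e-20) {
    # log-linear initialization is already an exact fit (e.g. a constant
    # or noiseless series); the gradient step would be singular
    A <- start$A; b <- start$b; rss <- iniRss
  } else {
    fit <- tryCatch(
      minpack.lm::nlsLM(f ~ A * exp(-b * n), data = s, start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) stop("coupling fit did not converge: ",
                               conditionMessage(e)))
    A <- unname(coef(fit)[["A"]]); b <- unname(coef(fit)[["b"]])
    rss <- sum(resid(fit)^2)
  }
  clipped <- FALSE
  if (b < 0) {
    warning("negative fitted decay clipped to 0 (yield capped at 100%)")
    b <- 0; clipped <- TRUE
  }
  if (b >= 1) stop("fitted decay b >= 1: series is not an exponential decay")
  new("CouplingFit", A = A, b = b, stepwiseYieldPercent = 100 * (1 - b),
      residualNorm = rss, clipped = clipped)
}

#' Capping efficiency from a labelled/unlabelled intensity quadruple
#'
#' `(I_fakeCy3 - I_fake) / (I_dTCy3 - I_dT)`: the background-corrected
#' label signal of the feature that received a deliberately failed
#' ("fake", plain-acetonitrile) coupling followed by capping, relative to
#' the background-corrected signal of a genuine dT coupling cycle. Values
#' above 1 can occur with noisy inputs and are flagged via attribute
#' `flagged`, never clipped silently.
#'
#' @param iFakeCy3,iFake intensities of the fake-coupled feature with and
#'   without terminal label.
#' @param iDtCy3,iDt intensities of the dT-coupled reference with and
#'   without label; `iDtCy3 - iDt` must be positive.
#' @return Capping efficiency fraction (attribute `flagged` set if > 1).
#' @examples
#' cappingEfficiency(95, 3, 100, 4)   # 0.958
#' @export
cappingEfficiency <- function(iFakeCy3, iFake, iDtCy3, iDt) {
  den <- iDtCy3 - iDt
  if (any(den <= 0)) stop("reference difference iDtCy3 - iDt must be positive")
  eff <- (iFakeCy3 - iFake) / den
  if (any(eff > 1)) {
    warning("capping efficiency exceeds 1 (noisy input); flagged, not clipped")
    attr(eff, "flagged") <- TRUE
  }
  eff
}
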