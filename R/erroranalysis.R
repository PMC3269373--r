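# Alignment-based error statistics and synthesis-parameter fitting.

.checkDNA <- function(x, what) {
  if (is(x, "DNAStringSet")) x <- as.character(x)
  if (any(grepl("[^ACGT]", x)))
    stop(what, " must be over {A,C,G,T}")
  x
}

#' Globally align a product sequence to its design
#'
#' Minimum-edit-distance global alignment with unit costs (Levenshtein; no
#' affine gaps) and a deterministic traceback tie-break: match >
#' substitute > delete > insert. Replaying the edit script on the design
#' yields the product; the cost equals the number of non-match operations.
#'
#' @param product product sequence (may be empty).
#' @param design design sequence.
#' @return List with `ops` (character vector of `match`, `substitute`,
#'   `delete`, `insert`) and integer `cost`.
#' @examples
#' globalAlign("AGT", "ACGT")   # one deletion, cost 1
#' @export
globalAlign <- function(product, design) {
  product <- .checkDNA(as.character(product), "product")
  design <- .checkDNA(as.character(design), "design")
  stopifnot(length(product) == 1, length(design) == 1)
  .nwAlign(design, product)
}

#' Alignment error statistics of a product set
#'
#' Aligns every product to its design and accumulates edit-operation
#' counts. Rates are total operation counts divided by total design bases
#' (the per-design-base convention); the perfect-match fraction is the
#' fraction of zero-cost products. Terminal truncations count as deletions
#' at the 5' end.
#'
#' @param productSet a [ProductSet-class], or a character vector of
#'   products.
#' @param designs named character vector or
#'   [Biostrings::DNAStringSet] of designs; defaults to the product set's
#'   own metadata designs.
#' @return An [ErrorStats-class].
#' @examples
#' ps <- scalarSimulate(0.99, 5, 1000, 20, replicates = 50, seed = 2)
#' computeErrorStats(ps)
#' @export
computeErrorStats <- function(productSet, designs = NULL) {
  if (is(productSet, "ProductSet")) {
    prods <- as.character(productSet@sequences)
    ids <- productSet@designId
    if (is.null(designs)) designs <- productSet@metadata$designs
  } else {
    prods <- as.character(productSet)
    ids <- names(prods)
    if (is.null(ids)) {
      if (length(designs) == 1)
        ids <- rep(if (is.null(names(designs))) "design1"
                   else names(designs)[1], length(prods))
      else stop("unnamed products need a single design or a ProductSet")
    }
  }
  if (is.null(designs)) stop("no designs supplied or recorded")
  designs <- .checkDNA(designs, "designs")
  if (is.null(names(designs)) && length(designs) == 1)
    names(designs) <- "design1"
  prods <- .checkDNA(prods, "products")
  if (!all(ids %in% names(designs)))
    stop("products reference designs not supplied: ",
         paste(head(setdiff(ids, names(designs))), collapse = ", "))
  cnt <- .nwCounts(unname(designs[ids]), prods)
  nBases <- sum(nchar(designs[ids]))
  errorStats(deletionRate = sum(cnt[, "del"]) / nBases,
             insertionRate = sum(cnt[, "ins"]) / nBases,
             substitutionRate = sum(cnt[, "sub"]) / nBases,
             perfectMatchFraction = mean(cnt[, "cost"] == 0),
             nProducts = length(prods), nDesignBases = nBases)
}

#' Fit synthesis parameters to observed error statistics
#'
#' Recovers `(gamma, d, R)` from observed deletion/insertion rates and the
#' perfect-match fraction by matching the closed-form predictions
#' ([expectedErrorRates()] and [correctSequenceYield()]): a coarse grid
#' search over `gamma`, `d` and `log R` minimizing the summed squared
#' relative deviation (relative, so the small insertion rate is not
#' swamped by the deletion rate), followed by Nelder-Mead refinement
#' within the bounds.
#'
#' @param observed an [ErrorStats-class], or a list with `deletionRate`,
#'   `insertionRate` and `perfectMatchFraction`.
#' @param N design length in bases.
#' @param nDarkPerBase dark exposures per designed base.
#' @param bounds list of length-2 ranges for `gamma`, `d` (tau-units) and
#'   `R`.
#' @param gridSize coarse grid points per parameter (gamma, d, log R).
#' @param refine run local refinement after the grid (default TRUE).
#' @return A [SynthesisFit-class]. Degenerate all-zero statistics return a
#'   boundary-flagged fit (gamma at 1, d at the upper bound). A single
#'   zero component (e.g. a perfect-match fraction below the sampling
#'   floor) is dropped from the objective; with only two informative
#'   statistics the three parameters are not fully identifiable and the
#'   boundary flag should be checked.
#' @examples
#' er <- expectedErrorRates(0.983, 340, 2.1)
#' pm <- correctSequenceYield(0.983, 340, 70, 2.1)
#' fitSynthesisParams(list(deletionRate = er$deletion,
#'                         insertionRate = er$insertion,
#'                         perfectMatchFraction = pm), N = 70)
#' @export
fitSynthesisParams <- function(observed, N, nDarkPerBase = 3,
                               bounds = list(gamma = c(0.9, 1),
                                             d = c(0.5, 8),
                                             R = c(50, 3000)),
                               gridSize = c(21, 31, 25),
                               refine = TRUE) {
  if (is(observed, "ErrorStats"))
    observed <- list(deletionRate = observed@deletionRate,
                     insertionRate = observed@insertionRate,
                     perfectMatchFraction = observed@perfectMatchFraction)
  obs <- c(del = observed$deletionRate, ins = observed$insertionRate,
           pm = observed$perfectMatchFraction)
  if (any(!is.finite(obs))) stop("observed statistics must be finite")
  gridG <- seq(bounds$gamma[1], bounds$gamma[2], length.out = gridSize[1])
  gridD <- seq(bounds$d[1], bounds$d[2], length.out = gridSize[2])
  gridL <- seq(log(bounds$R[1]), log(bounds$R[2]), length.out = gridSize[3])
  step <- c(gamma = diff(gridG[1:2]), d = diff(gridD[1:2]),
            logR = diff(gridL[1:2]))
  if (all(obs == 0)) {
    return(new("SynthesisFit", gamma = 1, d = bounds$d[2], R = bounds$R[2],
               objective = 0, gridStep = unname(step), boundary = TRUE))
  }
  # a component observed as exactly 0 carries no relative-deviation
  # information (e.g. a perfect-match fraction below the sampling floor)
  # and is dropped from the objective
  use <- obs > 0
  objective <- function(g, d, R) {
    er <- expectedErrorRates(g, R, d, nDarkPerBase)
    pm <- correctSequenceYield(g, R, N, d, nDarkPerBase)
    pred <- c(er$deletion, er$insertion, pm)
    sum(((pred[use] - obs[use]) / obs[use])^2)
  }
  best <- c(obj = Inf, g = NA, d = NA, R = NA)
  for (g in gridG) for (d in gridD) for (l in gridL) {
    o <- objective(g, d, exp(l))
    if (o < best["obj"]) best <- c(obj = o, g = g, d = d, R = exp(l))
  }
  par <- best[c("g", "d", "R")]
  obj <- best[["obj"]]
  if (refine) {
    fn <- function(p) {
      g <- min(max(p[1], bounds$gamma[1]), bounds$gamma[2])
      d <- min(max(p[2], bounds$d[1]), bounds$d[2])
      R <- min(max(exp(p[3]), bounds$R[1]), bounds$R[2])
      objective(g, d, R)
    }
    o <- stats::optim(c(par[["g"]], par[["d"]], log(par[["R"]])), fn,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
    if (o$value <= obj) {
      par <- c(g = min(max(o$par[1], bounds$gamma[1]), bounds$gamma[2]),
               d = min(max(o$par[2], bounds$d[1]), bounds$d[2]),
               R = min(max(exp(o$par[3]), bounds$R[1]), bounds$R[2]))
      obj <- o$value
    }
  }
  onBound <- isTRUE(par[["g"]] %in% bounds$gamma) ||
    isTRUE(par[["d"]] %in% bounds$d) || isTRUE(par[["R"]] %in% bounds$R)
  new("SynthesisFit", gamma = unname(par[["g"]]), d = unname(par[["d"]]),
      R = unname(par[["R"]]), objective = unname(obj),
      gridStep = unname(step), boundary = onBound)
}
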