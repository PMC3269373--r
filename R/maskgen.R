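# Mask scheduling: design sequences + layout -> ordered virtual masks.
#
# Designs are stored 5'->3' but deposition proceeds 3'->5' (the surface
# linker end couples first), so scheduling walks the reversed design
# strings. In the cyclic protocol the four bases are delivered in a fixed
# repeating order; a feature's mirrors are ON in a cycle exactly when its
# next-needed base (in deposition order) equals the cycle base.

.DEPOSITION <- function(seqs) {
  # reversed design strings: deposition order 3'->5'
  vapply(strsplit(seqs, ""), function(ch) paste(rev(ch), collapse = ""), "")
}

.checkDesigns <- function(sequences) {
  if (is(sequences, "DNAStringSet")) sequences <- as.character(sequences)
  if (is.null(names(sequences)) || any(names(sequences) == ""))
    names(sequences) <- paste0("seq", seq_along(sequences))
  if (anyDuplicated(names(sequences))) stop("design ids must be unique")
  bad <- grepl("[^ACGT]", sequences)
  if (any(bad))
    stop("designs must be over {A,C,G,T}; offending: ",
         paste(names(sequences)[bad], collapse = ", "))
  if (any(nchar(sequences) == 0)) stop("designs must be non-empty")
  sequences
}

#' Build a regular grid of feature blocks with streets
#'
#' Lays `nBlockRows * nBlockCols` rectangular blocks of
#' `blockRows x blockCols` mirrors, separated by `street` dark mirrors,
#' starting at the top-left corner of the DMD.
#'
#' @param nBlockRows,nBlockCols blocks per axis.
#' @param blockRows,blockCols mirrors per block per axis.
#' @param street dark street width in mirrors between blocks.
#' @param ids feature ids, row-major; defaults to `f1, f2, ...`.
#' @return data.frame suitable for the `featureBlocks` of [arrayLayout()].
#' @export
gridBlocks <- function(nBlockRows, nBlockCols, blockRows, blockCols,
                       street = 2L,
                       ids = paste0("f", seq_len(nBlockRows * nBlockCols))) {
  k <- 0L
  out <- vector("list", nBlockRows * nBlockCols)
  for (i in seq_len(nBlockRows)) for (j in seq_len(nBlockCols)) {
    k <- k + 1L
    out[[k]] <- data.frame(
      id = ids[k],
      row = (i - 1L) * (blockRows + street),
      col = (j - 1L) * (blockCols + street),
      nrow = blockRows, ncol = blockCols)
  }
  do.call(rbind, out)
}

#' Assign design sequences to DMD mirrors
#'
#' Every mirror maps to at most one sequence; street and unused mirrors map
#' to none. In `one_in_two` mode only the checkerboard half of each block's
#' mirrors is used; in `one_in_four` only every second mirror in both axes
#' (one quarter), leaving one-mirror dark margins around used mirrors.
#'
#' @param sequences named character vector or
#'   [Biostrings::DNAStringSet] of designs (ids must match the layout's
#'   block ids).
#' @param layout an [ArrayLayout-class].
#' @return Character matrix `dmdRows x dmdCols` of feature ids
#'   (`NA` = unassigned).
#' @export
assignFeatures <- function(sequences, layout) {
  stopifnot(is(layout, "ArrayLayout"))
  validObject(layout)
  sequences <- .checkDesigns(sequences)
  fb <- layout@featureBlocks
  missing <- setdiff(fb$id, names(sequences))
  if (length(missing))
    stop("layout blocks without a design: ", paste(missing, collapse = ", "))
  A <- matrix(NA_character_, layout@dmdRows, layout@dmdCols)
  for (k in seq_len(nrow(fb))) {
    rows <- fb$row[k] + seq_len(fb$nrow[k])   # 0-based block corner
    cols <- fb$col[k] + seq_len(fb$ncol[k])
    use <- matrix(TRUE, fb$nrow[k], fb$ncol[k])
    if (layout@layoutMode == "one_in_two") {
      use <- outer(seq_len(fb$nrow[k]), seq_len(fb$ncol[k]),
                   function(i, j) (i + j) %% 2L == 0L)
    } else if (layout@layoutMode == "one_in_four") {
      use <- outer(seq_len(fb$nrow[k]), seq_len(fb$ncol[k]),
                   function(i, j) i %% 2L == 1L & j %% 2L == 1L)
    }
    block <- A[rows, cols, drop = FALSE]
    block[use] <- fb$id[k]
    A[rows, cols] <- block
  }
  A
}

.scheduleMasks <- function(onFeatures, assignment) {
  lapply(onFeatures, function(on) {
    maskPattern((matrix(assignment %in% on, nrow(assignment),
                        ncol(assignment))) * 1L)
  })
}

#' Generate a cyclic base-deposition schedule
#'
#' Cycles repeat the bases of `baseOrder`; a feature's mirrors are ON in a
#' cycle exactly when its next-needed base (deposition order, 3'->5')
#' equals the cycle base, so after the cycle that feature has grown by one
#' base. The naive schedule runs full four-cycle blocks until every design
#' is complete (4N cycles for mixed designs of length N); `skipEmpty`
#' drops cycles in which no mirror is ON (the greedy cyclic schedule).
#'
#' @param sequences named character vector or [Biostrings::DNAStringSet]
#'   of designs (5'->3', over `{A,C,G,T}`).
#' @param layout optional [ArrayLayout-class]; when supplied, per-cycle
#'   [MaskPattern-class] masks are generated from [assignFeatures()], and
#'   the layout's `inverseCapping` flag prepends a CAP cycle whose mask is
#'   the street/unused-mirror set.
#' @param baseOrder four-character base delivery order, default `"ACGT"`.
#' @param skipEmpty drop all-OFF cycles.
#' @param dose photodeprotection dose per exposure, tau-units.
#' @return A [SynthesisSchedule-class].
#' @examples
#' cycleTable(cyclicSchedule(c(x = "AC", y = "CA"), skipEmpty = TRUE))
#' @export
cyclicSchedule <- function(sequences, layout = NULL, baseOrder = "ACGT",
                           skipEmpty = FALSE, dose = 7) {
  sequences <- .checkDesigns(sequences)
  bo <- strsplit(baseOrder, "")[[1]]
  if (!identical(sort(bo), c("A", "C", "G", "T")))
    stop("baseOrder must be a permutation of ACGT")
  dep <- .DEPOSITION(sequences)
  need <- strsplit(dep, "")
  len <- nchar(dep)
  base <- character(); onF <- list()
  if (skipEmpty) {
    # greedy cyclic schedule: a feature couples whenever the cycle base
    # matches its next-needed base; all-OFF cycles are dropped
    ptr <- setNames(rep(1L, length(dep)), names(dep))
    cyc <- 0L
    while (any(ptr <= len)) {
      cyc <- cyc + 1L
      b <- bo[(cyc - 1L) %% 4L + 1L]
      active <- names(dep)[ptr <= len]
      on <- active[vapply(active, function(id) need[[id]][ptr[id]] == b,
                          logical(1))]
      if (length(on)) {
        base <- c(base, b)
        onF <- c(onF, list(on))
      }
      ptr[on] <- ptr[on] + 1L
    }
  } else {
    # naive one-base-per-four-cycles protocol: block k deposits base
    # position k of every design, one cycle per base of baseOrder
    # (4N cycles for length-N designs)
    for (k in seq_len(max(len))) for (b in bo) {
      on <- names(dep)[len >= k &
                         vapply(need, function(x) length(x) >= k &&
                                  x[k] == b, logical(1))]
      base <- c(base, b)
      onF <- c(onF, list(on))
    }
  }
  masks <- list()
  if (!is.null(layout)) {
    assignment <- assignFeatures(sequences, layout)
    masks <- .scheduleMasks(onF, assignment)
    if (layout@inverseCapping) {
      streets <- is.na(assignment)
      base <- c("CAP", base)
      onF <- c(list(character()), onF)
      masks <- c(list(maskPattern(streets * 1L)), masks)
    }
  }
  coupling <- base %in% c("A", "C", "G", "T")
  new("SynthesisSchedule", base = base, dose = rep(dose, length(base)),
      coupling = coupling, onFeatures = onF, masks = masks,
      featureIds = names(sequences), designs = sequences)
}

#' Count dark exposures of a feature in a schedule
#'
#' A dark exposure is a coupling-cycle exposure in which the feature's
#' mirrors are OFF while at least one other mirror is ON — the events that
#' admit stray-light insertions (the `3N` exponent of the closed-form
#' yield for the naive four-cycle protocol).
#'
#' @param schedule a [SynthesisSchedule-class].
#' @param feature feature id(s); default all.
#' @return Named integer vector of dark-exposure counts.
#' @examples
#' s <- cyclicSchedule(c(x = "AC", y = "CA"), skipEmpty = TRUE)
#' darkExposureCount(s)          # x: 1, y: 1
#' @export
darkExposureCount <- function(schedule, feature = NULL) {
  stopifnot(is(schedule, "SynthesisSchedule"))
  ids <- if (is.null(feature)) schedule@featureIds else feature
  couplingOn <- schedule@coupling & schedule@base %in% c("A", "C", "G", "T")
  vapply(ids, function(id) {
    sum(vapply(which(couplingOn), function(k) {
      on <- schedule@onFeatures[[k]]
      length(on) > 0 && !(id %in% on)
    }, logical(1)))
  }, integer(1))
}

#' Replay a schedule with perfect chemistry
#'
#' Applies every coupling cycle with unit coupling efficiency, full
#' deprotection and no stray light: the reconstruction of each feature's
#' design. Used to assert the deposition invariant of generated schedules.
#'
#' @param schedule a [SynthesisSchedule-class].
#' @return Named character vector of reconstructed sequences, 5'->3'.
#' @export
replaySchedule <- function(schedule) {
  stopifnot(is(schedule, "SynthesisSchedule"))
  built <- setNames(rep("", length(schedule@featureIds)),
                    schedule@featureIds)
  for (k in seq_along(schedule@base)) {
    if (!schedule@coupling[k]) next
    b <- schedule@base[k]
    if (!b %in% c("A", "C", "G", "T")) next
    on <- schedule@onFeatures[[k]]
    built[on] <- paste0(built[on], b)
  }
  # built is in deposition order (3'->5'); return 5'->3'
  .DEPOSITION(built)
}

#' Exposure-gradient schedule fragment
#'
#' A series of non-coupling exposures that delivers a linear dose ramp
#' across `nSteps` feature groups: group `k` (0-based) accumulates
#' `k * doseMax / (nSteps - 1)`, from 0 (never exposed) to `doseMax`. Used
#' for dose-calibration arrays where different areas receive 0 to 30
#' J/cm^2 before a terminal label coupling.
#'
#' @param nSteps number of dose groups (>= 2).
#' @param doseMax maximum cumulative dose (any dose unit).
#' @param ids group ids; defaults to `g0 ... g(nSteps-1)`.
#' @return A [SynthesisSchedule-class] of `nSteps - 1` LABEL-phase
#'   exposures (no coupling).
#' @export
exposureGradientSchedule <- function(nSteps, doseMax,
                                     ids = paste0("g", 0:(nSteps - 1))) {
  if (nSteps < 2) stop("nSteps must be >= 2")
  if (doseMax <= 0) stop("doseMax must be positive")
  inc <- doseMax / (nSteps - 1)
  onF <- lapply(seq_len(nSteps - 1),
                function(k) ids[seq(k + 1, nSteps)])  # groups k..max ON
  new("SynthesisSchedule",
      base = rep("LABEL", nSteps - 1),
      dose = rep(inc, nSteps - 1),
      coupling = rep(FALSE, nSteps - 1),
      onFeatures = onF, masks = list(),
      featureIds = ids, designs = character())
}

#' Cumulative per-feature dose of a schedule
#'
#' @param schedule a [SynthesisSchedule-class].
#' @return Named numeric vector: total dose received by each feature over
#'   the cycles in which it was ON.
#' @export
cumulativeDose <- function(schedule) {
  stopifnot(is(schedule, "SynthesisSchedule"))
  out <- setNames(numeric(length(schedule@featureIds)),
                  schedule@featureIds)
  for (k in seq_along(schedule@base)) {
    on <- schedule@onFeatures[[k]]
    out[on] <- out[on] + schedule@dose[k]
  }
  out
}
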