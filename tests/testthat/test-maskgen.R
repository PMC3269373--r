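test_that("feature assignment respects layout modes and streets", {
  lay <- arrayLayout(8, 8, data.frame(id = "a", row = 0, col = 0,
                                      nrow = 8, ncol = 8))
  A <- assignFeatures(c(a = "ACGT"), lay)
  expect_true(all(A == "a"))

  lay4 <- arrayLayout(8, 8, data.frame(id = "a", row = 0, col = 0,
                                       nrow = 8, ncol = 8),
                      layoutMode = "one_in_four")
  A4 <- assignFeatures(c(a = "ACGT"), lay4)
  expect_equal(mean(!is.na(A4)), 1 / 4)

  lay2 <- arrayLayout(8, 8, data.frame(id = "a", row = 0, col = 0,
                                       nrow = 8, ncol = 8),
                      layoutMode = "one_in_two")
  expect_equal(mean(!is.na(assignFeatures(c(a = "ACGT"), lay2))), 1 / 2)

  # overlapping or out-of-bounds blocks are rejected
  expect_error(arrayLayout(8, 8, data.frame(id = c("a", "b"),
                                            row = c(0, 1), col = c(0, 1),
                                            nrow = c(4, 4), ncol = c(4, 4))),
               "disjoint")
  expect_error(arrayLayout(4, 4, data.frame(id = "a", row = 0, col = 0,
                                            nrow = 5, ncol = 4)),
               "bounds")
})

test_that("the sequencing-array block grid must fit the DMD", {
  # an 8x10 grid of 100x100-mirror blocks needs at least 800x1000
  # mirrors and cannot fit an XGA DMD at any street width
  fb <- gridBlocks(8, 10, 100, 100, street = 0)
  expect_error(arrayLayout(768, 1024, fb), "bounds")
  # trimmed blocks with streets do fit
  fb2 <- gridBlocks(8, 10, 76, 96, street = 6)
  lay <- arrayLayout(768, 1024, fb2)
  expect_s4_class(lay, "ArrayLayout")
  expect_equal(nrow(lay@featureBlocks), 80)
})

test_that("cyclic schedules deposit every design (deposition invariant)", {
  # homopolymer: skip-empty collapses to one cycle per base
  s15 <- cyclicSchedule(c(t15 = strrep("T", 15)), skipEmpty = TRUE)
  expect_equal(length(s15), 15)
  expect_true(all(s15@base == "T"))

  # naive protocol: four cycles per deposited base
  seqs <- c(a = "ACGTACGT", b = "TTGACCAG")
  naive <- cyclicSchedule(seqs, skipEmpty = FALSE)
  expect_equal(length(naive), 4 * 8)

  # greedy cyclic schedule for the crossing pair
  s <- cyclicSchedule(c(x = "AC", y = "CA"), skipEmpty = TRUE)
  expect_equal(s@base, c("A", "C", "A"))

  expect_error(cyclicSchedule(c(bad = "ACGU")), "A,C,G,T|ACGT|\\{A,C,G,T\\}")

  # replaying any schedule with perfect chemistry reproduces the designs
  set.seed(3)
  rand <- as.character(genDesigns(5, 12, seed = 3))
  for (skip in c(TRUE, FALSE)) {
    sch <- cyclicSchedule(rand, skipEmpty = skip)
    expect_identical(replaySchedule(sch), rand)
  }
  # skip-empty never lengthens the schedule
  expect_lte(length(cyclicSchedule(rand, skipEmpty = TRUE)),
             length(cyclicSchedule(rand, skipEmpty = FALSE)))
})

test_that("dark-exposure counts match the schedule structure", {
  # single-sequence array: never dark during an exposure
  single <- cyclicSchedule(c(only = "ACGTA"), skipEmpty = TRUE)
  expect_equal(unname(darkExposureCount(single)), 0L)

  # naive four-cycle protocol over base-rotated designs: 3N dark
  # exposures per feature (every cycle has some mirror ON)
  rot <- c(r1 = "ACGTACGT", r2 = "CGTACGTA", r3 = "GTACGTAC",
           r4 = "TACGTACG")
  naive <- cyclicSchedule(rot, skipEmpty = FALSE)
  expect_true(all(darkExposureCount(naive) == 3 * 8))

  s <- cyclicSchedule(c(x = "AC", y = "CA"), skipEmpty = TRUE)
  expect_equal(darkExposureCount(s, "x"), c(x = 1L))
  expect_equal(darkExposureCount(s, "y"), c(y = 1L))
})

test_that("exposure gradients accumulate a linear dose ramp", {
  two <- exposureGradientSchedule(2, 30)
  expect_equal(unname(cumulativeDose(two)), c(0, 30))

  g <- exposureGradientSchedule(13, 30)
  expect_equal(unname(cumulativeDose(g)), seq(0, 30, by = 2.5))
  # the zero-dose group is never ON
  expect_false(any(vapply(g@onFeatures, function(on) "g0" %in% on,
                          logical(1))))
  expect_true(all(!g@coupling))
})

test_that("masks round-trip through PBM files and the manifest", {
  lay <- arrayLayout(6, 6, data.frame(id = c("x", "y"),
                                      row = c(0, 0), col = c(0, 3),
                                      nrow = 6, ncol = c(3, 3)))
  sch <- cyclicSchedule(c(x = "ACG", y = "GAT"), layout = lay,
                        skipEmpty = TRUE, dose = 4.5)
  for (fmt in c("P1", "P4")) {
    dir <- file.path(tempdir(), paste0("masks_", fmt))
    writeMasks(sch, dir, format = fmt)
    back <- readMasks(dir)
    expect_equal(back@base, sch@base)
    expect_equal(back@dose, sch@dose)
    expect_equal(back@coupling, sch@coupling)
    for (k in seq_along(sch@base))
      expect_identical(mirrorStates(back@masks[[k]]),
                       mirrorStates(sch@masks[[k]]))
    unlink(dir, recursive = TRUE)
  }
})

test_that("PBM readers and writers are exact inverses", {
  set.seed(9)
  m <- matrix(rbinom(35 * 17, 1, 0.4), 35, 17)  # width not a byte multiple
  for (fmt in c("P1", "P4")) {
    p <- tempfile(fileext = ".pbm")
    writePBM(m, p, fmt)
    expect_identical(readPBM(p), matrix(as.integer(m), 35, 17))
    unlink(p)
  }
})

test_that("inverse capping prepends a street CAP cycle", {
  lay <- arrayLayout(6, 6, data.frame(id = "x", row = 0, col = 0,
                                      nrow = 6, ncol = 3),
                     inverseCapping = TRUE)
  sch <- cyclicSchedule(c(x = "ACG"), layout = lay, skipEmpty = TRUE)
  expect_equal(sch@base[1], "CAP")
  capMask <- mirrorStates(sch@masks[[1]])
  expect_true(all(capMask[, 4:6] == 1L))   # streets exposed for capping
  expect_true(all(capMask[, 1:3] == 0L))
  # deposition invariant still holds with the CAP cycle in front
  expect_identical(replaySchedule(sch), c(x = "ACG"))
})
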