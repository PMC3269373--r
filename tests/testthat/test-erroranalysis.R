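test_that("global alignment matches hand cases and replays correctly", {
  same <- globalAlign("ACGT", "ACGT")
  expect_equal(same$cost, 0)
  expect_true(all(same$ops == "match"))

  del <- globalAlign("AGT", "ACGT")
  expect_equal(del$cost, 1)
  expect_equal(sum(del$ops == "delete"), 1)

  expect_error(globalAlign("ACGU", "ACGT"), "A,C,G,T")

  # empty product: all deletions
  empty <- globalAlign("", "ACG")
  expect_equal(empty$cost, 3)
  expect_true(all(empty$ops == "delete"))

  # the edit script replays the design into the product
  set.seed(6)
  for (k in 1:25) {
    d <- paste(sample(c("A", "C", "G", "T"), sample(1:8, 1),
                      replace = TRUE), collapse = "")
    p <- paste(sample(c("A", "C", "G", "T"), sample(0:8, 1),
                      replace = TRUE), collapse = "")
    al <- globalAlign(p, d)
    expect_identical(replayEditScript(d, p, al$ops), p)
    expect_equal(al$cost, sum(al$ops != "match"))
  }
})

test_that("alignment cost equals the exhaustive edit distance", {
  strings <- allStrings(c("A", "C"), 4)
  for (a in strings) for (b in strings) {
    expect_equal(globalAlign(b, a)$cost, bruteEditDistance(a, b))
  }
})

test_that("alignment cost is symmetric with insertions and deletions swapped", {
  set.seed(7)
  for (k in 1:20) {
    d <- paste(sample(c("A", "C", "G", "T"), 10, replace = TRUE),
               collapse = "")
    p <- paste(sample(c("A", "C", "G", "T"), sample(6:14, 1),
                      replace = TRUE), collapse = "")
    f <- globalAlign(p, d); r <- globalAlign(d, p)
    expect_equal(f$cost, r$cost)
    # the indel balance always equals the length difference
    expect_equal(sum(f$ops == "insert") - sum(f$ops == "delete"),
                 nchar(p) - nchar(d))
    expect_equal(sum(r$ops == "insert") - sum(r$ops == "delete"),
                 nchar(d) - nchar(p))
  }
})

test_that("alignment agrees with an independent aligner on random pairs", {
  set.seed(8)
  for (k in 1:30) {
    d <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
               collapse = "")
    p <- paste(sample(c("A", "C", "G", "T"), sample(20:40, 1),
                      replace = TRUE), collapse = "")
    expect_equal(globalAlign(p, d)$cost,
                 as.integer(utils::adist(d, p)))
  }
})

test_that("error statistics aggregate per design base", {
  designs <- c(d1 = "ACGTACGTAC")
  perfect <- rep("ACGTACGTAC", 10)
  st <- computeErrorStats(setNames(perfect, rep("d1", 10)), designs)
  expect_equal(unname(errorRates(st)), c(0, 0, 0))
  expect_equal(perfectMatchFraction(st), 1)

  oneDel <- c(rep("ACGTACGTAC", 9), "ACGTCGTAC")  # one deletion in 100 bases
  st2 <- computeErrorStats(setNames(oneDel, rep("d1", 10)), designs)
  expect_equal(st2@deletionRate, 0.01)
  expect_equal(perfectMatchFraction(st2), 0.9)

  # permutation invariance over products
  sh <- sample(10)
  st3 <- computeErrorStats(setNames(oneDel[sh], rep("d1", 10)), designs)
  expect_equal(st3@deletionRate, st2@deletionRate)
  expect_equal(perfectMatchFraction(st3), perfectMatchFraction(st2))
})

test_that("alignment statistics of the scalar oracle match the closed forms", {
  # gentle error rates keep indel-merging bias far inside the 3-sigma band
  g <- 0.995; d <- 6; R <- 2000; N <- 20; reps <- 4000
  ps <- scalarSimulate(g, d, R, N, replicates = reps, seed = 14)
  st <- computeErrorStats(ps)
  er <- expectedErrorRates(g, R, d)
  nBases <- reps * N
  expect_true(within3SigmaBinomial(st@deletionRate, er$deletion, nBases))
  sigmaIns <- sqrt(3 * (er$insertion / 3) / nBases)
  expect_lt(abs(st@insertionRate - er$insertion), 3 * sigmaIns)
  pmExp <- correctSequenceYield(g, R, N, d)
  expect_true(within3SigmaBinomial(perfectMatchFraction(st), pmExp, reps))
})

test_that("synthesis parameters are recovered from closed-form statistics", {
  er <- expectedErrorRates(0.983, 340, 2.1)
  pm <- correctSequenceYield(0.983, 340, 70, 2.1)
  fit <- fitSynthesisParams(list(deletionRate = er$deletion,
                                 insertionRate = er$insertion,
                                 perfectMatchFraction = pm), N = 70)
  step <- fit@gridStep
  expect_lt(abs(fit@gamma - 0.983), step[1])
  expect_lt(abs(fit@d - 2.1), step[2])
  expect_lt(abs(log(fit@R) - log(340)), step[3])

  # degenerate zero-error statistics hit the boundary with a flag
  z <- fitSynthesisParams(list(deletionRate = 0, insertionRate = 0,
                               perfectMatchFraction = 0), N = 70)
  expect_true(z@boundary)
})

test_that("parameters recovered from simulated statistics are close", {
  ps <- scalarSimulate(0.98, 3, 400, 40, replicates = 5000, seed = 23)
  fit <- fitSynthesisParams(eventErrorStats(ps), N = 40)
  expect_equal(fit@gamma, 0.98, tolerance = 0.01)
  expect_equal(fit@d, 3, tolerance = 0.15)
  expect_equal(log(fit@R), log(400), tolerance = 0.25)
})
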