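# Shared oracles and fixtures, built in code.

# pure-R recursive edit distance (unit costs), exhaustive oracle
bruteEditDistance <- function(a, b) {
  m <- nchar(a); n <- nchar(b)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i == 0) return(j)
    if (j == 0) return(i)
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    v <- min(rec(i - 1, j - 1) + (av[i] != bv[j]),
             rec(i - 1, j) + 1,
             rec(i, j - 1) + 1)
    memo[[key]] <- v
    v
  }
  rec(m, n)
}

# all strings over an alphabet up to a maximum length
allStrings <- function(alphabet, maxLen) {
  out <- ""
  for (l in seq_len(maxLen)) {
    grids <- do.call(expand.grid, rep(list(alphabet), l))
    out <- c(out, apply(grids, 1, paste, collapse = ""))
  }
  out
}

# replay an edit script on a design: must reproduce the product
replayEditScript <- function(design, product, ops) {
  d <- strsplit(design, "")[[1]]; p <- strsplit(product, "")[[1]]
  i <- 0; j <- 0; built <- character()
  for (op in ops) {
    if (op == "match") { i <- i + 1; j <- j + 1; built <- c(built, d[i])
    } else if (op == "substitute") { i <- i + 1; j <- j + 1
      built <- c(built, p[j])
    } else if (op == "delete") { i <- i + 1
    } else { j <- j + 1; built <- c(built, p[j]) }
  }
  paste(built, collapse = "")
}

# binomial 3-sigma band check: observed proportion vs expected, using the
# larger of the two proportions for the standard error (guards the
# near-zero expectation case)
within3SigmaBinomial <- function(observed, expected, n) {
  p <- max(observed, expected)
  sigma <- sqrt(max(p * (1 - p), 1e-300) / n)
  abs(observed - expected) <= 3 * sigma
}
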