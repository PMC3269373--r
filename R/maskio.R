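# PBM mask bitmaps and the JSON cycle manifest.
#
# Virtual masks are 1-bit images, row-major, origin top-left. PBM uses
# 1 = black; here 1 = mirror ON (the convention is recorded in the
# manifest). P1 is plain text, P4 packs 8 pixels per byte.

#' Read and write 1-bit PBM mask bitmaps
#'
#' `writePBM` writes a 0/1 matrix as PBM, plain (`P1`) or binary (`P4`);
#' `readPBM` reads either, returning the 0/1 matrix (row 1 = top).
#'
#' @param states 0/1 matrix (or [MaskPattern-class]).
#' @param path file path.
#' @param format `"P1"` (plain text) or `"P4"` (packed binary).
#' @return `readPBM` returns an integer 0/1 matrix.
#' @export
writePBM <- function(states, path, format = c("P1", "P4")) {
  format <- match.arg(format)
  if (is(states, "MaskPattern")) states <- mirrorStates(states)
  stopifnot(all(states %in% c(0L, 1L)))
  h <- nrow(states); w <- ncol(states)
  if (format == "P1") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P1", paste(w, h)), con)
    apply(states, 1, function(r) writeLines(paste(r, collapse = " "), con))
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw(sprintf("P4\n%d %d\n", w, h)), con)
    bytesPerRow <- ceiling(w / 8)
    for (i in seq_len(h)) {
      bits <- c(states[i, ], rep(0L, bytesPerRow * 8 - w))
      bytes <- vapply(seq_len(bytesPerRow), function(b) {
        as.raw(sum(bits[(b - 1) * 8 + 1:8] * c(128, 64, 32, 16, 8, 4, 2, 1)))
      }, raw(1))
      writeBin(bytes, con)
    }
  }
  invisible(path)
}

#' @rdname writePBM
#' @export
readPBM <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2))
  if (!magic %in% c("P1", "P4")) stop("not a PBM file (P1/P4): ", path)
  # header tokens: width, height (comments allowed)
  tokens <- character(); buf <- character()
  repeat {
    ch <- rawToChar(readBin(con, "raw", 1))
    if (length(ch) == 0 || ch == "") stop("truncated PBM header")
    if (ch == "#") { repeat { c2 <- rawToChar(readBin(con, "raw", 1))
                              if (c2 == "\n") break }; next }
    if (grepl("[ \t\r\n]", ch)) {
      if (nzchar(paste(buf, collapse = ""))) {
        tokens <- c(tokens, paste(buf, collapse = "")); buf <- character()
      }
      if (length(tokens) == 2 && magic == "P4") break
      next
    }
    buf <- c(buf, ch)
    if (magic == "P1" && length(tokens) == 2) break
  }
  if (magic == "P1") {
    rest <- rawToChar(readBin(con, "raw", file.size(path)))
    digits <- strsplit(gsub("[^01]", "", paste(c(buf, rest), collapse = "")),
                       "")[[1]]
    w <- as.integer(tokens[1]); h <- as.integer(tokens[2])
    if (length(digits) < w * h) stop("truncated P1 data")
    matrix(as.integer(digits[seq_len(w * h)]), h, w, byrow = TRUE)
  } else {
    w <- as.integer(tokens[1]); h <- as.integer(tokens[2])
    bytesPerRow <- ceiling(w / 8)
    raws <- readBin(con, "raw", h * bytesPerRow)
    if (length(raws) < h * bytesPerRow) stop("truncated P4 data")
    bits <- as.integer(rawToBits(raws))    # little-endian within byte
    m <- matrix(0L, h, w)
    for (i in seq_len(h)) {
      rowBits <- bits[((i - 1) * bytesPerRow * 8) + seq_len(bytesPerRow * 8)]
      # PBM packs MSB first; rawToBits yields LSB first
      ord <- as.vector(matrix(seq_len(bytesPerRow * 8), 8)[8:1, ])
      m[i, ] <- rowBits[ord][seq_len(w)]
    }
    m
  }
}

#' Write or read a schedule's masks with a cycle manifest
#'
#' `writeMasks` writes one PBM per cycle plus `manifest.json` recording
#' cycle order, base, dose and coupling flag; `readMasks` restores a
#' [SynthesisSchedule-class] from such a directory (mirror states and
#' cycle metadata round-trip exactly; feature assignment is not stored in
#' bitmaps, so the restored schedule carries masks only).
#'
#' @param schedule a [SynthesisSchedule-class] with masks.
#' @param dir directory (created if needed).
#' @param format PBM flavour, `"P1"` or `"P4"`.
#' @return `writeMasks` the directory (invisibly); `readMasks` a
#'   [SynthesisSchedule-class].
#' @export
writeMasks <- function(schedule, dir, format = c("P1", "P4")) {
  format <- match.arg(format)
  stopifnot(is(schedule, "SynthesisSchedule"))
  if (!length(schedule@masks))
    stop("schedule carries no masks (generate with a layout)")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("cycle_%03d.pbm", seq_along(schedule@base))
  for (k in seq_along(schedule@base))
    writePBM(schedule@masks[[k]], file.path(dir, files[k]), format)
  manifest <- list(
    convention = "1 = mirror ON, row-major, origin top-left",
    cycles = data.frame(cycle = seq_along(schedule@base),
                        base = schedule@base, dose = schedule@dose,
                        coupling = schedule@coupling, file = files))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname writeMasks
#' @export
readMasks <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  cy <- manifest$cycles
  ord <- order(cy$cycle)
  cy <- cy[ord, ]
  masks <- lapply(file.path(dir, cy$file),
                  function(p) maskPattern(readPBM(p)))
  new("SynthesisSchedule", base = cy$base, dose = cy$dose,
      coupling = cy$coupling,
      onFeatures = rep(list(character()), nrow(cy)),
      masks = masks, featureIds = character(), designs = character())
}
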