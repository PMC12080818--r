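# ENVI raster I/O: a plain-text .hdr companion describing a flat binary file.
# Only the keys the format requires for pixel access are interpreted
# (samples, lines, bands, data type, interleave, byte order, header offset);
# everything else (map info, wavelength, ...) is passed through untouched.

# ENVI "data type" codes -> readBin arguments
envi_dtypes <- list(
  `1`  = list(what = "integer", size = 1L, signed = FALSE),
  `2`  = list(what = "integer", size = 2L, signed = TRUE),
  `3`  = list(what = "integer", size = 4L, signed = TRUE),
  `4`  = list(what = "double",  size = 4L, signed = TRUE),
  `5`  = list(what = "double",  size = 8L, signed = TRUE),
  `12` = list(what = "integer", size = 2L, signed = FALSE)
)

# internal: locate the header/data pair from either path
envi_paths <- function(path) {
  if (grepl("\\.hdr$", path, ignore.case = TRUE)) {
    hdr <- path
    base <- sub("\\.hdr$", "", path, ignore.case = TRUE)
    cands <- c(base, paste0(base, c(".img", ".dat", ".bsq", ".bil", ".bip", ".raw")))
    dat <- cands[file.exists(cands)][1L]
    if (is.na(dat)) {
      stop("ENVI data file for header '", hdr, "' not found", call. = FALSE)
    }
  } else {
    dat <- path
    cands <- c(paste0(path, ".hdr"),
               paste0(tools::file_path_sans_ext(path), ".hdr"))
    hdr <- cands[file.exists(cands)][1L]
    if (is.na(hdr)) {
      stop("ENVI header for '", dat, "' not found (tried ",
           paste(cands, collapse = ", "), ")", call. = FALSE)
    }
  }
  list(hdr = hdr, dat = dat)
}

# internal: parse an ENVI header into a named list (values as strings;
# brace-delimited values joined across lines)
parse_envi_header <- function(hdr_path) {
  lines <- readLines(hdr_path, warn = FALSE)
  if (length(lines) == 0L || !grepl("^ENVI", trimws(lines[1L]))) {
    stop("'", hdr_path, "' is not an ENVI header (missing ENVI magic line)",
         call. = FALSE)
  }
  # fold multi-line { ... } blocks onto one line, then split key = value
  out <- list()
  buf <- ""
  in_brace <- FALSE
  for (ln in lines[-1L]) {
    buf <- if (in_brace) paste(buf, ln) else ln
    in_brace <- grepl("\\{", buf) && !grepl("\\}", buf)
    if (in_brace) next
    ln2 <- buf
    buf <- ""
    if (!grepl("=", ln2)) next
    key <- tolower(trimws(sub("=.*$", "", ln2)))
    val <- trimws(sub("^[^=]*=", "", ln2))
    val <- trimws(gsub("[{}]", "", val))
    out[[key]] <- val
  }
  out
}

#' Read an ENVI raster into a hyperspectral cube
#'
#' Accepts either the `.hdr` path or the binary path (the companion is found
#' automatically). All three interleaves (BSQ, BIL, BIP), both byte orders and
#' data types 1 (uint8), 2 (int16), 3 (int32), 4 (float32), 5 (float64) and
#' 12 (uint16) are supported; the returned cube is always `(row, col, band)`
#' in double precision regardless of on-disk layout.
#'
#' @param path path to the `.hdr` or data file.
#' @return numeric 3-D array `(rows, cols, bands)`.
#' @export
read_envi <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  pp <- envi_paths(path)
  h <- parse_envi_header(pp$hdr)
  need <- c("samples", "lines", "bands", "data type", "interleave")
  miss <- setdiff(need, names(h))
  if (length(miss)) {
    stop("ENVI header missing key(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  cols <- as.integer(h[["samples"]])
  rows <- as.integer(h[["lines"]])
  bands <- as.integer(h[["bands"]])
  dtype <- envi_dtypes[[h[["data type"]]]]
  if (is.null(dtype)) {
    stop("unsupported ENVI data type ", h[["data type"]], call. = FALSE)
  }
  endian <- if (!is.null(h[["byte order"]]) && h[["byte order"]] == "1")
    "big" else "little"
  offset <- if (!is.null(h[["header offset"]]))
    as.integer(h[["header offset"]]) else 0L
  interleave <- tolower(h[["interleave"]])
  n <- rows * cols * bands
  con <- file(pp$dat, "rb")
  on.exit(close(con))
  if (offset > 0L) readBin(con, "raw", n = offset)
  v <- readBin(con, dtype$what, n = n, size = dtype$size,
               signed = dtype$signed, endian = endian)
  if (length(v) != n) {
    stop("ENVI data file too short: expected ", n, " values, got ", length(v),
         call. = FALSE)
  }
  # on-disk orderings (fastest-varying first):
  #   bsq: col, row, band;  bil: col, band, row;  bip: band, col, row
  cube <- switch(interleave,
    bsq = aperm(array(v, dim = c(cols, rows, bands)), c(2L, 1L, 3L)),
    bil = aperm(array(v, dim = c(cols, bands, rows)), c(3L, 1L, 2L)),
    bip = aperm(array(v, dim = c(bands, cols, rows)), c(3L, 2L, 1L)),
    stop("unsupported interleave '", interleave, "'", call. = FALSE)
  )
  hypercube(cube)
}

#' Write a cube as an ENVI raster
#'
#' Writes the flat binary plus its `.hdr` companion. Data are stored as
#' float64 (ENVI data type 5) so that `read_envi(write_envi(cube))` is
#' bit-exact.
#'
#' @param cube numeric 3-D array `(rows, cols, bands)` (a 2-D matrix is
#'   written as a single-band raster).
#' @param path output path for the binary data file; `paste0(path, ".hdr")`
#'   is written alongside.
#' @param interleave on-disk layout, one of `"bsq"`, `"bil"`, `"bip"`.
#' @return `path`, invisibly.
#' @export
write_envi <- function(cube, path, interleave = c("bsq", "bil", "bip")) {
  interleave <- match.arg(interleave)
  cube <- check_cube(hypercube(cube))
  d <- dim(cube)
  v <- switch(interleave,
    bsq = as.vector(aperm(cube, c(2L, 1L, 3L))),
    bil = as.vector(aperm(cube, c(2L, 3L, 1L))),
    bip = as.vector(aperm(cube, c(3L, 2L, 1L)))
  )
  con <- file(path, "wb")
  writeBin(v, con, size = 8L, endian = "little")
  close(con)
  hdr <- c(
    "ENVI",
    "description = {written by fhcdsr}",
    paste0("samples = ", d[2L]),
    paste0("lines = ", d[1L]),
    paste0("bands = ", d[3L]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 5",
    paste0("interleave = ", interleave),
    "byte order = 0"
  )
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(path)
}
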