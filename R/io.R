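#' Read a hyperspectral cube from any supported container
#'
#' Dispatches on `format` (or the file extension when `"auto"`): ENVI
#' (`.hdr` + flat binary), GeoTIFF/TIFF, or MATLAB MAT v5. The result is
#' always a `(row, col, band)` double-precision array regardless of the
#' on-disk interleave or sample layout.
#'
#' For MAT containers, when `mat_variable` is not given, the file must hold
#' exactly one 3-D numeric variable; if several are present an error lists
#' the candidates.
#'
#' @param path input file path.
#' @param format one of `"auto"`, `"envi"`, `"geotiff"`, `"mat"`.
#' @param mat_variable variable name inside a MAT container.
#' @return numeric 3-D array `(rows, cols, bands)`.
#' @examples
#' \dontrun{
#' t1 <- read_cube("hermiston_2004.mat", mat_variable = "HypeRvieW")
#' }
#' @export
read_cube <- function(path, format = c("auto", "envi", "geotiff", "mat"),
                      mat_variable = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      hdr = "envi", img = "envi", dat = "envi", bsq = "envi", bil = "envi",
      bip = "envi", raw = "envi",
      tif = "geotiff", tiff = "geotiff",
      mat = "mat",
      {
        # extensionless or unknown: ENVI if a header is nearby
        if (file.exists(paste0(path, ".hdr"))) "envi"
        else stop("cannot infer format of '", path,
                  "'; pass format= explicitly", call. = FALSE)
      })
  }
  switch(format,
    envi = read_envi(path),
    geotiff = read_geotiff(path),
    mat = {
      vars <- read_mat(path)
      if (!is.null(mat_variable)) {
        if (!mat_variable %in% names(vars)) {
          stop("variable '", mat_variable, "' not found in ", path,
               "; available: ", paste(names(vars), collapse = ", "),
               call. = FALSE)
        }
        v <- vars[[mat_variable]]
      } else {
        is3d <- vapply(vars, function(x) length(dim(x)) == 3L, logical(1))
        if (sum(is3d) == 0L) {
          stop("no 3-D variable found in ", path, call. = FALSE)
        }
        if (sum(is3d) > 1L) {
          stop("ambiguous MAT container ", path, ": multiple 3-D variables (",
               paste(names(vars)[is3d], collapse = ", "),
               "); pass mat_variable=", call. = FALSE)
        }
        v <- vars[[which(is3d)]]
      }
      if (length(dim(v)) != 3L) {
        stop("MAT variable has ", length(dim(v)),
             " dimensions; a cube needs 3", call. = FALSE)
      }
      hypercube(v)
    }
  )
}

#' Read a (Geo)TIFF into a hyperspectral cube
#'
#' Multi-band layouts are accepted either as multiple samples per pixel or as
#' multiple directories (one band plane each). Integer sample values are
#' returned as stored (`as.is`), never rescaled; georeferencing tags are
#' ignored.
#'
#' @param path path to the TIFF file.
#' @return numeric 3-D array `(rows, cols, bands)`.
#' @export
read_geotiff <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  imgs <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(imgs)) imgs <- list(imgs)
  planes <- lapply(imgs, function(x) {
    if (is.matrix(x)) {
      list(x)
    } else if (is.array(x) && length(dim(x)) == 3L) {
      lapply(seq_len(dim(x)[3L]), function(b) x[, , b])
    } else {
      stop("unsupported TIFF payload with ", length(dim(x)),
           " dimensions in ", path, call. = FALSE)
    }
  })
  planes <- do.call(c, planes)
  d1 <- dim(planes[[1L]])
  if (!all(vapply(planes, function(p) identical(dim(p), d1), logical(1)))) {
    stop("TIFF directories of '", path, "' have inconsistent sizes",
         call. = FALSE)
  }
  cube <- array(unlist(planes, use.names = FALSE),
                dim = c(d1[1L], d1[2L], length(planes)))
  hypercube(cube)
}

#' Write a hyperspectral cube
#'
#' Writers are provided for the two containers that hold float64 exactly:
#' ENVI (`format = "envi"`, the default; `.hdr` companion written alongside)
#' and MAT v5 (`format = "mat"`, variable name `"cube"`). Both round-trip
#' bit-exactly through [read_cube()].
#'
#' @param cube numeric 3-D array `(rows, cols, bands)`.
#' @param path output path.
#' @param format `"envi"` or `"mat"`.
#' @param ... passed to the format writer (e.g. `interleave` for ENVI).
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path, format = c("envi", "mat"), ...) {
  format <- match.arg(format)
  switch(format,
    envi = write_envi(cube, path, ...),
    mat = write_mat(list(cube = cube), path)
  )
  invisible(path)
}

#' Read a binary change mask
#'
#' Accepts PNG, single-band (Geo)TIFF, ENVI, or MAT containers holding a 2-D
#' (or single-band 3-D) array. Nonzero entries map to 1, zero entries to 0.
#'
#' @param path input path.
#' @param mat_variable variable name for MAT containers (default: the sole
#'   2-D variable).
#' @return integer matrix of 0/1 labels.
#' @export
read_mask <- function(path, mat_variable = NULL) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  m <- if (ext == "png") {
    x <- png::readPNG(path)
    if (length(dim(x)) == 3L) x <- x[, , 1L]
    x
  } else if (ext %in% c("tif", "tiff")) {
    x <- read_geotiff(path)
    if (dim(x)[3L] != 1L) {
      stop("mask TIFF '", path, "' has ", dim(x)[3L],
           " bands; expected a single band", call. = FALSE)
    }
    x[, , 1L]
  } else if (ext == "mat") {
    vars <- read_mat(path)
    v <- if (!is.null(mat_variable)) {
      if (!mat_variable %in% names(vars)) {
        stop("variable '", mat_variable, "' not found in ", path,
             call. = FALSE)
      }
      vars[[mat_variable]]
    } else {
      is2d <- vapply(vars, function(x) length(dim(x)) == 2L, logical(1))
      if (sum(is2d) != 1L) {
        stop("need exactly one 2-D variable in mask file ", path,
             " (found ", sum(is2d), "); pass mat_variable=", call. = FALSE)
      }
      vars[[which(is2d)]]
    }
    if (length(dim(v)) != 2L) {
      stop("mask variable is not 2-D", call. = FALSE)
    }
    v
  } else {
    x <- read_envi(path)
    if (dim(x)[3L] != 1L) {
      stop("mask raster '", path, "' has ", dim(x)[3L],
           " bands; expected a single band", call. = FALSE)
    }
    x[, , 1L]
  }
  if (!is.matrix(m)) {
    stop("mask payload in '", path, "' is not 2-D", call. = FALSE)
  }
  matrix(as.integer(m != 0), nrow(m), ncol(m))
}

#' Write a binary change mask
#'
#' @param mask 0/1 integer matrix.
#' @param path output path; `.png` writes PNG (0 -> black, 1 -> white),
#'   anything else writes a single-band ENVI raster.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  mask <- as.matrix(mask)
  if (!all(mask %in% c(0, 1))) {
    stop("mask must be binary 0/1", call. = FALSE)
  }
  if (tolower(tools::file_ext(path)) == "png") {
    png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  } else {
    write_envi(array(as.numeric(mask), dim = c(dim(mask), 1L)), path)
  }
  invisible(path)
}
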