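#' Validate and construct a hyperspectral cube
#'
#' A hyperspectral cube is represented as a plain numeric 3-D array indexed
#' `(row, col, band)`. Radiometric units are treated as opaque: integer digital
#' numbers are coerced to double but never rescaled. An optional integer
#' attribute `band_labels` records the original 1-based band identifiers that
#' survive band exclusion (see [exclude_bands()]).
#'
#' @param values numeric 3-D array `(rows, cols, bands)`, or a matrix which is
#'   treated as a single-band cube.
#' @param band_labels optional strictly increasing integer vector of original
#'   1-based band identifiers, one per band.
#' @return a numeric 3-D array of class-free storage with optional
#'   `band_labels` attribute; all values finite doubles.
#' @examples
#' cube <- hypercube(array(runif(4 * 5 * 3), dim = c(4, 5, 3)))
#' dim(cube)
#' @export
hypercube <- function(values, band_labels = NULL) {
  if (is.matrix(values)) {
    values <- array(values, dim = c(dim(values), 1L))
  }
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("hyperspectral cube must be a 3-D array (rows, cols, bands), got ",
         paste(dim(values), collapse = "x"), call. = FALSE)
  }
  if (!is.numeric(values)) {
    stop("hyperspectral cube must be numeric", call. = FALSE)
  }
  storage.mode(values) <- "double"
  if (anyNA(values) || any(!is.finite(values))) {
    stop("hyperspectral cube contains non-finite values (NaN/Inf/NA); ",
         "inputs must be cleaned before loading", call. = FALSE)
  }
  if (!is.null(band_labels)) {
    band_labels <- as.integer(band_labels)
    if (length(band_labels) != dim(values)[3L]) {
      stop("band_labels length (", length(band_labels),
           ") does not match band count (", dim(values)[3L], ")", call. = FALSE)
    }
    if (is.unsorted(band_labels, strictly = TRUE)) {
      stop("band_labels must be strictly increasing", call. = FALSE)
    }
    attr(values, "band_labels") <- band_labels
  }
  values
}

#' @rdname hypercube
#' @param cube object to check.
#' @export
is_hypercube <- function(cube) {
  is.array(cube) && length(dim(cube)) == 3L && is.numeric(cube)
}

# internal: stop unless `cube` is a valid cube; returns it validated
check_cube <- function(cube, arg = deparse(substitute(cube))) {
  if (!is_hypercube(cube)) {
    stop("`", arg, "` must be a numeric 3-D array (rows, cols, bands)",
         call. = FALSE)
  }
  hypercube(cube, band_labels = attr(cube, "band_labels"))
}

#' Remove uncalibrated or noisy bands from a cube
#'
#' Drops every band covered by the given 1-based index ranges, keeping the
#' original band order. Benchmark scenes ship with known-bad detector bands
#' (e.g. uncalibrated or water-absorption bands) that must be excluded before
#' any analysis; the surviving original indices are recorded in the result's
#' `band_labels` attribute so provenance is never lost.
#'
#' @param cube numeric 3-D array `(rows, cols, bands)`.
#' @param excluded ranges of 1-based band indices to drop. Accepted forms: a
#'   list of length-2 vectors `c(start, end)`, an integer vector of single
#'   indices, or character ranges like `"58-76"` (also `"B058-B076"`).
#'   Overlapping ranges are allowed. `NULL` or an empty list is a no-op.
#' @return the cube restricted to surviving bands, with `band_labels` giving
#'   the original 1-based index of each kept band.
#' @examples
#' cube <- hypercube(array(1, dim = c(2, 2, 242)))
#' slim <- exclude_bands(cube, c("1-7", "58-76", "225-242"))
#' dim(slim)[3] # 198
#' @export
exclude_bands <- function(cube, excluded = NULL) {
  cube <- check_cube(cube)
  nb <- dim(cube)[3L]
  labels <- attr(cube, "band_labels")
  if (is.null(labels)) labels <- seq_len(nb)
  # ranges are matched against original labels, so re-applying an already
  # applied range set is a no-op (idempotence); for an already-subset cube
  # the original extent is unknown, so only positivity can be validated
  bound <- if (is.null(attr(cube, "band_labels"))) nb else Inf
  drop_idx <- parse_band_ranges(excluded, bound)
  if (length(drop_idx) == 0L) {
    return(cube)
  }
  keep <- which(!(labels %in% drop_idx))
  if (length(keep) == 0L) {
    stop("no bands remain after exclusion", call. = FALSE)
  }
  if (length(keep) == nb) {
    return(cube)
  }
  out <- cube[, , keep, drop = FALSE]
  attr(out, "band_labels") <- as.integer(labels[keep])
  out
}

# internal: normalize an exclusion spec into a sorted vector of unique 1-based
# band indices, validating against the band count
parse_band_ranges <- function(excluded, nbands) {
  if (is.null(excluded) || length(excluded) == 0L) return(integer(0))
  if (is.list(excluded) && all(vapply(excluded, is.character, logical(1)))) {
    excluded <- unlist(excluded) # YAML configs deliver a list of strings
  }
  if (is.character(excluded)) {
    excluded <- lapply(excluded, function(s) {
      s <- gsub("[Bb]", "", trimws(s))
      parts <- strsplit(s, "-", fixed = TRUE)[[1L]]
      parts <- suppressWarnings(as.integer(parts))
      if (anyNA(parts) || !(length(parts) %in% c(1L, 2L))) {
        stop("cannot parse band range '", s,
             "'; expected 'start-end' or a single index", call. = FALSE)
      }
      parts
    })
  } else if (is.numeric(excluded)) {
    excluded <- as.list(excluded)
  } else if (!is.list(excluded)) {
    stop("`excluded` must be a list of ranges, an integer vector, ",
         "or character 'start-end' strings", call. = FALSE)
  }
  idx <- unlist(lapply(excluded, function(r) {
    r <- as.integer(r)
    if (length(r) == 1L) r <- c(r, r)
    if (length(r) != 2L || anyNA(r)) {
      stop("each exclusion range must be one index or c(start, end)",
           call. = FALSE)
    }
    if (r[1L] > r[2L]) {
      stop("band range start (", r[1L], ") exceeds end (", r[2L], ")",
           call. = FALSE)
    }
    seq.int(r[1L], r[2L])
  }))
  idx <- sort(unique(idx))
  if (length(idx) && (idx[1L] < 1L || idx[length(idx)] > nbands)) {
    stop("band exclusion index out of range [1, ", nbands, "]", call. = FALSE)
  }
  idx
}
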