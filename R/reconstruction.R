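#' Normalized 4-neighbor weights for one 3x3 spectral neighborhood
#'
#' Computes the affinity between a center spectrum and its four nearest
#' neighbors (up, down, left, right) and normalizes the four values to sum to
#' one. Two weighting semantics are provided:
#'
#' * `mode = "similarity"` (default): similar neighbors get large weights —
#'   cosine similarity, `1 / (1 + Euclidean distance)`, or the cosine of the
#'   spectral angle. This is the semantics that smooths homogeneous regions
#'   while letting dissimilar (boundary) neighbors contribute little.
#' * `mode = "distance"`: the raw distances themselves are normalized into
#'   weights (cosine distance `1 - cos`, Euclidean distance, or the spectral
#'   angle in radians), so dissimilar neighbors dominate. Kept for
#'   completeness; see the methods vignette for why similarity is the default.
#'
#' Negative cosine affinities are clamped to zero so raw weights are always
#' nonnegative. A zero-norm spectrum makes the cosine/spectral-angle affinity
#' of that pair 0 (with a warning) rather than dividing by zero. If all four
#' raw affinities are zero the weights fall back to uniform 1/4 (with a
#' warning).
#'
#' @param window_spectra the five spectra `X0..X4` as a 5-row matrix (rows:
#'   center, up, down, left, right) or a list of five equal-length numeric
#'   vectors.
#' @param metric one of `"cosine"`, `"euclidean"`, `"sam"`.
#' @param mode one of `"similarity"`, `"distance"`.
#' @return a list of class `"neighbor_weights"` with components `w_center`
#'   (the trade-off scalar, always 1 here), `w_raw` (four nonnegative raw
#'   affinities) and `w_norm` (the four normalized weights, summing to 1).
#' @examples
#' w <- neighbor_weights(rbind(c(1, 0), c(1, 0), c(0, 1), c(1, 0), c(0, 1)))
#' w$w_norm # 0.5, 0, 0.5, 0
#' @export
neighbor_weights <- function(window_spectra,
                             metric = c("cosine", "euclidean", "sam"),
                             mode = c("similarity", "distance")) {
  metric <- match.arg(metric)
  mode <- match.arg(mode)
  if (is.list(window_spectra)) {
    len <- lengths(window_spectra)
    if (length(window_spectra) != 5L || length(unique(len)) != 1L) {
      stop("window_spectra must hold five equal-length spectra X0..X4",
           call. = FALSE)
    }
    window_spectra <- do.call(rbind, window_spectra)
  }
  if (!is.matrix(window_spectra) || nrow(window_spectra) != 5L) {
    stop("window_spectra must be a 5-row matrix (center, up, down, left, right)",
         call. = FALSE)
  }
  center <- window_spectra[1L, , drop = FALSE]
  raw <- numeric(4L)
  zero_norm <- FALSE
  for (i in 1:4) {
    a <- raw_affinity(center, window_spectra[i + 1L, , drop = FALSE],
                      metric, mode)
    raw[i] <- a$value
    zero_norm <- zero_norm || a$zero_norm
  }
  if (zero_norm) {
    warning("zero-norm spectrum in neighborhood; affinity set to 0",
            call. = FALSE)
  }
  eta <- sum(raw)
  if (eta <= 0) {
    warning("all neighbor affinities are zero; falling back to uniform weights",
            call. = FALSE)
    w_norm <- rep(0.25, 4L)
  } else {
    w_norm <- raw / eta
  }
  structure(list(w_center = 1, w_raw = raw, w_norm = w_norm,
                 metric = metric, mode = mode),
            class = "neighbor_weights")
}

# internal: scalar affinity between two 1xB spectra under metric/mode.
# Returns list(value, zero_norm). Matches the vectorised path bit-for-bit.
raw_affinity <- function(x, y, metric, mode) {
  nx <- sqrt(sum(x^2))
  ny <- sqrt(sum(y^2))
  if (metric == "euclidean") {
    d <- sqrt(sum((x - y)^2))
    v <- if (mode == "similarity") 1 / (1 + d) else d
    return(list(value = v, zero_norm = FALSE))
  }
  if (nx == 0 || ny == 0) {
    return(list(value = 0, zero_norm = TRUE))
  }
  cs <- min(max(sum(x * y) / (nx * ny), -1), 1)
  v <- switch(paste(metric, mode, sep = "."),
    cosine.similarity = max(cs, 0),
    cosine.distance   = 1 - cs,
    sam.similarity    = max(cos(acos(cs)), 0),
    sam.distance      = acos(cs)
  )
  list(value = v, zero_norm = FALSE)
}

#' Reconstruct one spectrum from its weighted neighbors
#'
#' Solves the zero-Laplacian condition `w0 * X0 - sum_i wi~ * Xi = 0` for the
#' center spectrum: `X0 = (1 / w0) * sum_i wi~ * Xi`. With the default
#' `w0 = 1` this is the convex combination of the four neighbor spectra under
#' the normalized weights.
#'
#' @param weights a `"neighbor_weights"` object from [neighbor_weights()], or
#'   a numeric vector of four normalized weights.
#' @param neighbors the four neighbor spectra `X1..X4` as a 4-row matrix or a
#'   list of four equal-length vectors.
#' @param w0 positive trade-off scalar; `w0 = 0` is rejected (the
#'   reconstruction is undefined).
#' @return the reconstructed spectrum (numeric vector).
#' @examples
#' reconstruct_spectrum(rep(1 / 4, 4),
#'                      rbind(c(4, 0), c(0, 4), c(2, 2), c(2, 2))) # c(2, 2)
#' @export
reconstruct_spectrum <- function(weights, neighbors, w0 = 1) {
  if (inherits(weights, "neighbor_weights")) weights <- weights$w_norm
  weights <- as.numeric(weights)
  if (length(weights) != 4L) {
    stop("weights must be four normalized neighbor weights", call. = FALSE)
  }
  if (is.list(neighbors)) neighbors <- do.call(rbind, neighbors)
  if (!is.matrix(neighbors) || nrow(neighbors) != 4L) {
    stop("neighbors must be a 4-row matrix (up, down, left, right)",
         call. = FALSE)
  }
  if (w0 == 0) {
    stop("w0 = 0 leaves the reconstruction undefined", call. = FALSE)
  }
  drop(crossprod(neighbors, weights)) / w0
}

#' Spatially reconstruct a cube under the weighted Laplacian constraint
#'
#' Mirror-pads the cube, then replaces every pixel's spectrum by the
#' similarity-weighted combination of its four nearest neighbors implied by
#' setting the weighted Laplacian to zero. Neighbors are always taken from the
#' *original* (padded) cube — a single Jacobi-style pass, so the result is
#' deterministic and independent of pixel visiting order. Spatially constant
#' cubes are fixed points: the output equals the input exactly.
#'
#' @inheritParams neighbor_weights
#' @param cube numeric 3-D array `(rows, cols, bands)`.
#' @param w0 positive trade-off scalar (default 1); with `w0 = 1` every
#'   reconstructed band value lies within the range of its four neighbors.
#' @return the reconstructed cube, same shape and `band_labels` as the input.
#' @export
reconstruct_cube <- function(cube,
                             metric = c("cosine", "euclidean", "sam"),
                             mode = c("similarity", "distance"),
                             w0 = 1) {
  metric <- match.arg(metric)
  mode <- match.arg(mode)
  cube <- check_cube(cube)
  if (w0 == 0) {
    stop("w0 = 0 leaves the reconstruction undefined", call. = FALSE)
  }
  d <- dim(cube)
  r <- d[1L]; c <- d[2L]; b <- d[3L]
  p <- pad_mirror(cube)
  n <- r * c
  flat <- function(x) matrix(x, nrow = n, ncol = b)
  center <- flat(cube)
  nbrs <- list(
    up    = flat(p[1:r, 2:(c + 1L), , drop = FALSE]),
    down  = flat(p[3:(r + 2L), 2:(c + 1L), , drop = FALSE]),
    left  = flat(p[2:(r + 1L), 1:c, , drop = FALSE]),
    right = flat(p[2:(r + 1L), 3:(c + 2L), , drop = FALSE])
  )
  w <- neighbor_weights_matrix(center, nbrs, metric, mode)
  y <- matrix(0, n, b)
  for (i in 1:4) y <- y + w[, i] * nbrs[[i]]
  y <- y / w0
  out <- array(y, dim = d)
  attr(out, "band_labels") <- attr(cube, "band_labels")
  out
}

# internal: n x 4 normalized weight matrix for all pixels at once.
# center and each element of nbrs are n x b matrices. Warnings are aggregated
# over pixels rather than emitted per pixel.
neighbor_weights_matrix <- function(center, nbrs, metric, mode) {
  n <- nrow(center)
  raw <- matrix(0, n, 4L)
  zero_norm_pairs <- 0L
  if (metric == "euclidean") {
    for (i in 1:4) {
      d <- sqrt(rowSums((center - nbrs[[i]])^2))
      raw[, i] <- if (mode == "similarity") 1 / (1 + d) else d
    }
  } else {
    n0 <- sqrt(rowSums(center^2))
    for (i in 1:4) {
      ni <- sqrt(rowSums(nbrs[[i]]^2))
      ok <- n0 > 0 & ni > 0
      cs <- numeric(n)
      cs[ok] <- rowSums(center[ok, , drop = FALSE] *
                          nbrs[[i]][ok, , drop = FALSE]) /
        (n0[ok] * ni[ok])
      cs <- pmin(pmax(cs, -1), 1)
      v <- switch(paste(metric, mode, sep = "."),
        cosine.similarity = pmax(cs, 0),
        cosine.distance   = 1 - cs,
        sam.similarity    = pmax(cos(acos(cs)), 0),
        sam.distance      = acos(cs)
      )
      v[!ok] <- 0
      zero_norm_pairs <- zero_norm_pairs + sum(!ok)
      raw[, i] <- v
    }
  }
  if (zero_norm_pairs > 0L) {
    warning(zero_norm_pairs,
            " neighbor pair(s) involved a zero-norm spectrum; affinity set to 0",
            call. = FALSE)
  }
  eta <- rowSums(raw)
  degenerate <- eta <= 0
  if (any(degenerate)) {
    warning(sum(degenerate),
            " pixel(s) had all-zero neighbor affinities; uniform weights used",
            call. = FALSE)
    raw[degenerate, ] <- 0.25
    eta[degenerate] <- 1
  }
  raw / eta
}
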