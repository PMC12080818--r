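#' Modified spectral-angle weight between two spectra
#'
#' Returns `arctan((<x, y> / (||x|| * ||y||))^2)`, a squared-cosine spectral
#' angle passed through `arctan`. For entrywise nonnegative spectra the value
#' lies in `[0, pi/4]`: it is `pi/4` exactly when the two spectra are
#' positively collinear (identical material, possibly different intensity) and
#' 0 when they are orthogonal. If either spectrum has zero norm the weight is
#' 0 (with a warning) rather than a division-by-zero fault.
#'
#' @param x,y equal-length numeric spectra.
#' @return scalar weight.
#' @examples
#' spectral_weight(c(1, 2), c(2, 4)) # pi/4
#' spectral_weight(c(1, 0), c(0, 1)) # 0
#' spectral_weight(c(1, 0), c(1, 1)) # atan(0.5)
#' @export
spectral_weight <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 1L) {
    stop("spectra must have equal length >= 1", call. = FALSE)
  }
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) {
    warning("zero-norm spectrum; spectral weight set to 0", call. = FALSE)
    return(0)
  }
  atan((sum(x * y) / (nx * ny))^2)
}

#' Windowed change score for one pixel
#'
#' The change statistic for a single pixel: the band-energy difference summed
#' over the full 3x3 window (9 pixels including the center),
#' `sum_k sum_b (y_kb^2 - x_kb^2)`, multiplied by the modified spectral-angle
#' weight of the two center spectra, with the absolute value taken so the
#' score is a nonnegative change magnitude regardless of whether radiance
#' increased or decreased.
#'
#' @param window_t1,window_t2 numeric `3 x 3 x bands` arrays holding the two
#'   dates' windows around the same pixel.
#' @return scalar change score `|sum_k sum_b (y_kb^2 - x_kb^2)| * W`.
#' @examples
#' w1 <- array(1, dim = c(3, 3, 1)); w2 <- array(2, dim = c(3, 3, 1))
#' fhcdsr_score(w1, w2) # 27 * pi / 4
#' @export
fhcdsr_score <- function(window_t1, window_t2) {
  if (!is.array(window_t1) || !is.array(window_t2) ||
      !identical(dim(window_t1), dim(window_t2)) ||
      length(dim(window_t1)) != 3L ||
      any(dim(window_t1)[1:2] != 3L)) {
    stop("windows must be two 3 x 3 x bands arrays of equal shape",
         call. = FALSE)
  }
  w <- spectral_weight(window_t1[2L, 2L, ], window_t2[2L, 2L, ])
  abs(sum(window_t2^2) - sum(window_t1^2)) * w
}

#' Detect per-pixel change between two dates
#'
#' The main entry point. Scores every pixel of a co-registered bi-temporal
#' hyperspectral pair with one of three detectors:
#'
#' * `"fhcdsr"`: both cubes are spatially reconstructed under the
#'   similarity-weighted zero-Laplacian constraint ([reconstruct_cube()]),
#'   mirror-padded, and scored with the 3x3-window energy-difference statistic
#'   weighted by the modified spectral angle ([fhcdsr_score()]).
#' * `"ad"`: Absolute Distance — the per-pixel Euclidean norm of the spectral
#'   difference between dates.
#' * `"aad"`: Absolute Average Difference — the per-pixel band-mean absolute
#'   spectral difference.
#'
#' @param cube_t1,cube_t2 numeric 3-D arrays `(rows, cols, bands)` of
#'   identical shape (co-registered scenes at times T1 and T2).
#' @param method detector: `"fhcdsr"` (default), `"ad"`, or `"aad"`.
#' @param metric,mode,w0 reconstruction parameters, see [reconstruct_cube()]
#'   (fhcdsr only).
#' @param reconstruct set `FALSE` to run the windowed fhcdsr scorer directly
#'   on the raw cubes, skipping spatial reconstruction (an ablation; fhcdsr
#'   only).
#' @param use_reconstructed_centers if `TRUE` (default) the spectral-angle
#'   weight uses the reconstructed center spectra; if `FALSE`, the original
#'   ones (fhcdsr only).
#' @param normalize if `TRUE` (default) the score map is min-max scaled to
#'   `[0, 1]` (a constant map becomes all zeros). ROC/AUC is rank-based and
#'   unaffected either way.
#' @return an object of class `"change_scores"`: a list with `scores` (rows x
#'   cols numeric matrix), `method`, `normalized`, and the parameters used.
#'   Supports `print()`, `summary()`, `plot()`, `as.matrix()` and [roc()].
#' @examples
#' t1 <- array(runif(6 * 6 * 5), dim = c(6, 6, 5))
#' detect_change(t1, t1, method = "ad")$scores[1, 1] # 0
#' @export
detect_change <- function(cube_t1, cube_t2,
                          method = c("fhcdsr", "ad", "aad"),
                          metric = c("cosine", "euclidean", "sam"),
                          mode = c("similarity", "distance"),
                          w0 = 1,
                          reconstruct = TRUE,
                          use_reconstructed_centers = TRUE,
                          normalize = TRUE) {
  method <- match.arg(method)
  metric <- match.arg(metric)
  mode <- match.arg(mode)
  cube_t1 <- check_cube(cube_t1)
  cube_t2 <- check_cube(cube_t2)
  if (!identical(dim(cube_t1), dim(cube_t2))) {
    stop("cubes are not co-registered: shapes ",
         paste(dim(cube_t1), collapse = "x"), " vs ",
         paste(dim(cube_t2), collapse = "x"), call. = FALSE)
  }
  d <- dim(cube_t1)
  scores <- switch(method,
    ad = {
      m <- sqrt(rowSums(matrix((cube_t2 - cube_t1)^2, nrow = d[1L] * d[2L])))
      matrix(m, d[1L], d[2L])
    },
    aad = {
      m <- rowMeans(matrix(abs(cube_t2 - cube_t1), nrow = d[1L] * d[2L]))
      matrix(m, d[1L], d[2L])
    },
    fhcdsr = {
      if (reconstruct) {
        y1 <- reconstruct_cube(cube_t1, metric = metric, mode = mode, w0 = w0)
        y2 <- reconstruct_cube(cube_t2, metric = metric, mode = mode, w0 = w0)
      } else {
        y1 <- cube_t1
        y2 <- cube_t2
      }
      c1 <- if (use_reconstructed_centers) y1 else cube_t1
      c2 <- if (use_reconstructed_centers) y2 else cube_t2
      fhcdsr_score_map(y1, y2, c1, c2)
    }
  )
  structure(list(scores = if (normalize) minmax_scale(scores) else scores,
                 method = method, normalized = normalize,
                 params = list(metric = metric, mode = mode, w0 = w0,
                               reconstruct = reconstruct,
                               use_reconstructed_centers =
                                 use_reconstructed_centers),
                 dim = d),
            class = "change_scores")
}

# internal: vectorised windowed scorer. y1/y2 supply the 3x3 windows
# (mirror-padded here), c1/c2 the center spectra for the angle weight.
fhcdsr_score_map <- function(y1, y2, c1, c2) {
  d <- dim(y1)
  r <- d[1L]; cc <- d[2L]; b <- d[3L]
  p1 <- pad_mirror(y1)
  p2 <- pad_mirror(y2)
  # per-pixel band-energy difference on the padded grid
  e <- matrix(rowSums(matrix(p2^2 - p1^2, nrow = (r + 2L) * (cc + 2L))),
              r + 2L, cc + 2L)
  # 3x3 box sum at every interior pixel
  s <- matrix(0, r, cc)
  for (dr in 0:2) {
    for (dc in 0:2) {
      s <- s + e[dr + seq_len(r), dc + seq_len(cc)]
    }
  }
  n <- r * cc
  m1 <- matrix(c1, nrow = n)
  m2 <- matrix(c2, nrow = n)
  n1 <- sqrt(rowSums(m1^2))
  n2 <- sqrt(rowSums(m2^2))
  ok <- n1 > 0 & n2 > 0
  cs <- numeric(n)
  cs[ok] <- rowSums(m1[ok, , drop = FALSE] * m2[ok, , drop = FALSE]) /
    (n1[ok] * n2[ok])
  if (any(!ok)) {
    warning(sum(!ok), " pixel(s) with a zero-norm center spectrum; ",
            "spectral weight set to 0", call. = FALSE)
  }
  w <- matrix(atan(cs^2), r, cc)
  abs(s) * w
}

# internal: min-max scale a matrix to [0, 1]; constant maps map to all zeros
minmax_scale <- function(x) {
  rng <- range(x)
  if (rng[2L] == rng[1L]) {
    return(matrix(0, nrow(x), ncol(x)))
  }
  (x - rng[1L]) / (rng[2L] - rng[1L])
}

#' @export
print.change_scores <- function(x, ...) {
  cat(sprintf("Change score map (%s): %d x %d pixels%s\n",
              x$method, x$dim[1L], x$dim[2L],
              if (x$normalized) ", min-max normalized" else ""))
  cat(sprintf("  scores: min %.4g, median %.4g, max %.4g\n",
              min(x$scores), stats::median(x$scores), max(x$scores)))
  invisible(x)
}

#' @export
summary.change_scores <- function(object, ...) {
  s <- summary(as.vector(object$scores))
  cat(sprintf("Detector: %s%s\n", object$method,
              if (object$method == "fhcdsr")
                sprintf(" (metric=%s, mode=%s, w0=%g%s)",
                        object$params$metric, object$params$mode,
                        object$params$w0,
                        if (object$params$reconstruct) ""
                        else ", no reconstruction")
              else ""))
  print(s)
  invisible(s)
}

#' @export
as.matrix.change_scores <- function(x, ...) x$scores

#' Display a change score map
#'
#' @param x a `"change_scores"` object.
#' @param ... passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.change_scores <- function(x, ...) {
  sc <- x$scores
  graphics::image(t(sc)[, nrow(sc):1, drop = FALSE],
                  col = grDevices::gray.colors(256, start = 0, end = 1),
                  axes = FALSE, asp = nrow(sc) / ncol(sc),
                  main = sprintf("%s change scores", x$method), ...)
  invisible(x)
}
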