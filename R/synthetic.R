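#' Specification of a synthetic bi-temporal crop scene
#'
#' Describes a seeded, fully reproducible benchmark scene: a piecewise-
#' homogeneous class map (seeded Voronoi patches at a characteristic
#' `region_scale`), smooth per-class spectral signatures, compact
#' rectangular change fields where the T2 class differs from the T1 class,
#' additive Gaussian noise, and an optional global radiometric gain between
#' dates. The defaults are the package's standard benchmark configuration
#' (64 x 64 x 40, 4 classes, 10% change, 5% noise, 5% inter-date gain,
#' seed 17).
#'
#' Signatures are built as a shared smooth vegetation-like baseline times a
#' class-specific amplitude, plus small class-specific Gaussian bumps along
#' the band axis. Crop spectra in real scenes are strongly correlated in
#' shape and differ mainly in level and in narrow features; the generator
#' mirrors that, which is exactly the regime the spectral-angle-weighted
#' detector is designed for. `noise_sigma` is expressed relative to the
#' maximum signature amplitude.
#'
#' @param rows,cols,bands scene dimensions.
#' @param n_classes number of land-cover classes (>= 2).
#' @param change_fraction fraction of pixels whose class switches at T2, in
#'   `[0, 1)`; 0 plants no change.
#' @param region_scale characteristic patch size in pixels, for both class
#'   regions and change fields.
#' @param noise_sigma additive Gaussian noise standard deviation relative to
#'   the maximum signature amplitude (>= 0).
#' @param gain_t2 global multiplicative radiometric factor applied to the T2
#'   date (> 0); models illumination drift between acquisitions.
#' @param seed integer seed; every random draw flows from it.
#' @return a validated list of class `"scene_spec"`.
#' @export
scene_spec <- function(rows = 64L, cols = 64L, bands = 40L, n_classes = 4L,
                       change_fraction = 0.10, region_scale = 16L,
                       noise_sigma = 0.05, gain_t2 = 1.05, seed = 17L) {
  spec <- list(rows = as.integer(rows), cols = as.integer(cols),
               bands = as.integer(bands), n_classes = as.integer(n_classes),
               change_fraction = change_fraction,
               region_scale = as.integer(region_scale),
               noise_sigma = noise_sigma, gain_t2 = gain_t2,
               seed = as.integer(seed))
  stopifnot(spec$rows >= 1L, spec$cols >= 1L, spec$bands >= 1L,
            spec$n_classes >= 2L, spec$region_scale >= 2L)
  if (spec$change_fraction < 0 || spec$change_fraction >= 1) {
    stop("change_fraction must lie in [0, 1)", call. = FALSE)
  }
  if (spec$noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  if (spec$gain_t2 <= 0) stop("gain_t2 must be > 0", call. = FALSE)
  structure(spec, class = "scene_spec")
}

#' Generate a synthetic bi-temporal scene with known change mask
#'
#' Realizes a [scene_spec()]: partitions the grid into contiguous Voronoi
#' class patches, plants non-overlapping rectangular change fields (2-pixel
#' margin from the border and from each other) covering as close to
#' `floor(change_fraction * rows * cols)` pixels as rectangle geometry
#' allows, cyclically reassigns the class of every planted pixel, and renders
#'
#' \deqn{T1 = S[class_1] + \sigma \epsilon_1, \quad
#'       T2 = g (S[class_2] + \sigma \epsilon_2)}
#'
#' with independent standard-normal fields \eqn{\epsilon_1, \epsilon_2}.
#' The unit noise fields depend only on the seed, never on `noise_sigma`, so
#' sweeps over noise levels at a fixed seed reuse identical noise shapes.
#' The truth mask marks exactly the pixels whose class was reassigned.
#'
#' @param spec a `"scene_spec"` (or arguments for one via `...`).
#' @param ... passed to [scene_spec()] when `spec` is missing.
#' @return a list of class `"hsi_scene"`: `t1`, `t2` (cubes), `truth` (0/1
#'   integer matrix), `n_changed`, `classes_t1`, `classes_t2` (integer
#'   matrices), `signatures` (`n_classes x bands`), and `spec`.
#' @examples
#' sc <- generate_scene(scene_spec(rows = 24, cols = 24, bands = 10,
#'                                 region_scale = 8, seed = 1))
#' sc$n_changed
#' @export
generate_scene <- function(spec = scene_spec(...), ...) {
  if (!inherits(spec, "scene_spec")) {
    stop("spec must be a scene_spec object", call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  sig <- class_signatures(spec$n_classes, spec$bands)
  cls1 <- voronoi_classes(spec$rows, spec$cols, spec$n_classes,
                          spec$region_scale)
  blobs <- plant_change_fields(spec)
  cls2 <- cls1
  for (blob in blobs) {
    shift <- sample.int(spec$n_classes - 1L, 1L)
    idx <- blob # matrix of (row, col) index pairs
    cls2[idx] <- ((cls1[idx] - 1L + shift) %% spec$n_classes) + 1L
  }
  truth <- matrix(as.integer(cls2 != cls1), spec$rows, spec$cols)

  n <- spec$rows * spec$cols
  sigma_abs <- spec$noise_sigma * max(sig)
  eps1 <- matrix(stats::rnorm(n * spec$bands), n, spec$bands)
  eps2 <- matrix(stats::rnorm(n * spec$bands), n, spec$bands)
  t1 <- array(sig[as.vector(cls1), ] + sigma_abs * eps1,
              dim = c(spec$rows, spec$cols, spec$bands))
  t2 <- array(spec$gain_t2 * (sig[as.vector(cls2), ] + sigma_abs * eps2),
              dim = c(spec$rows, spec$cols, spec$bands))

  structure(list(t1 = t1, t2 = t2, truth = truth,
                 n_changed = sum(truth),
                 classes_t1 = cls1, classes_t2 = cls2,
                 signatures = sig, spec = spec),
            class = "hsi_scene")
}

#' @export
print.hsi_scene <- function(x, ...) {
  cat(sprintf(
    "Synthetic bi-temporal scene: %d x %d x %d, %d classes, seed %d\n",
    x$spec$rows, x$spec$cols, x$spec$bands, x$spec$n_classes, x$spec$seed))
  cat(sprintf("  changed pixels: %d of %d (%.2f%%)\n", x$n_changed,
              x$spec$rows * x$spec$cols,
              100 * x$n_changed / (x$spec$rows * x$spec$cols)))
  cat(sprintf("  noise_sigma = %g, gain_t2 = %g\n",
              x$spec$noise_sigma, x$spec$gain_t2))
  invisible(x)
}

# internal: n_classes x bands signature matrix. Shared smooth baseline times
# a class-specific amplitude plus small class-specific Gaussian bumps, so
# classes are strongly correlated in direction (realistic for crops) and
# differ mainly in radiometric level. All values strictly positive.
class_signatures <- function(n_classes, bands) {
  b <- seq_len(bands)
  baseline <- 0.5 + 0.4 * exp(-((b - 0.7 * bands)^2) / (2 * (0.2 * bands)^2))
  amp <- seq(0.7, 1.6, length.out = n_classes)
  sig <- matrix(0, n_classes, bands)
  for (k in seq_len(n_classes)) {
    bumps <- numeric(bands)
    for (j in 1:2) {
      a <- stats::runif(1, 0.05, 0.15)
      mu <- stats::runif(1, 1, bands)
      sd <- stats::runif(1, bands / 10, bands / 5)
      bumps <- bumps + a * exp(-((b - mu)^2) / (2 * sd^2))
    }
    sig[k, ] <- amp[k] * (baseline + bumps)
  }
  sig
}

# internal: contiguous class patches from a seeded Voronoi partition;
# guarantees all classes are present among the sites
voronoi_classes <- function(rows, cols, n_classes, region_scale) {
  n_sites <- max(n_classes, round(rows * cols / region_scale^2))
  sr <- stats::runif(n_sites, 1, rows)
  sc <- stats::runif(n_sites, 1, cols)
  site_class <- c(seq_len(n_classes),
                  if (n_sites > n_classes)
                    sample.int(n_classes, n_sites - n_classes, replace = TRUE))
  gr <- rep(seq_len(rows), times = cols)
  gc <- rep(seq_len(cols), each = rows)
  d2 <- outer(gr, sr, `-`)^2 + outer(gc, sc, `-`)^2
  nearest <- max.col(-d2, ties.method = "first")
  matrix(site_class[nearest], rows, cols)
}

# internal: plant non-overlapping filled rectangles totalling (up to
# rectangle-geometry rounding, at most 3 pixels short) the requested changed
# fraction. Rectangles keep a 2-pixel margin from the scene border and a
# >= 2-pixel gap from each other. Returns a list of 2-column (row, col)
# index matrices, one per field.
plant_change_fields <- function(spec) {
  target <- floor(spec$change_fraction * spec$rows * spec$cols)
  if (target == 0L) return(list())
  sizes <- list()
  remaining <- target
  while (remaining >= 4L) {
    s <- min(spec$region_scale^2, remaining)
    h <- max(2L, floor(sqrt(s)))
    w <- max(2L, s %/% h)
    if (h * w > remaining) break
    sizes[[length(sizes) + 1L]] <- c(h, w)
    remaining <- remaining - h * w
  }
  if (length(sizes) == 0L) {
    stop("change_fraction ", spec$change_fraction,
         " is unreachable with the rectangular field geometry; ",
         "increase it to plant at least a 2x2 field", call. = FALSE)
  }
  occ <- matrix(FALSE, spec$rows, spec$cols)
  blobs <- vector("list", length(sizes))
  for (i in seq_along(sizes)) {
    h <- sizes[[i]][1L]; w <- sizes[[i]][2L]
    placed <- FALSE
    for (try in 1:2000) {
      if (spec$rows - h - 1L < 3L || spec$cols - w - 1L < 3L) break
      r0 <- sample(3:(spec$rows - h - 1L), 1L)
      c0 <- sample(3:(spec$cols - w - 1L), 1L)
      rr <- max(1L, r0 - 2L):min(spec$rows, r0 + h + 1L)
      cc <- max(1L, c0 - 2L):min(spec$cols, c0 + w + 1L)
      if (!any(occ[rr, cc])) {
        occ[r0:(r0 + h - 1L), c0:(c0 + w - 1L)] <- TRUE
        blobs[[i]] <- as.matrix(expand.grid(row = r0:(r0 + h - 1L),
                                            col = c0:(c0 + w - 1L)))
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("could not place all change fields: change_fraction ",
           spec$change_fraction, " is unreachable with region_scale ",
           spec$region_scale, " on a ", spec$rows, "x", spec$cols,
           " scene; reduce change_fraction or region_scale", call. = FALSE)
    }
  }
  blobs
}

#' Write a generated scene to disk
#'
#' Writes `t1` and `t2` as ENVI rasters (or MAT containers), the truth mask
#' as PNG, and the resolved scene specification as YAML, into `dir`.
#'
#' @param scene an `"hsi_scene"` from [generate_scene()].
#' @param dir output directory (created if needed).
#' @param format `"envi"` or `"mat"` for the cubes.
#' @return named character vector of the written paths, invisibly.
#' @export
write_scene <- function(scene, dir, format = c("envi", "mat")) {
  format <- match.arg(format)
  if (!inherits(scene, "hsi_scene")) {
    stop("scene must come from generate_scene()", call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "mat") ".mat" else ""
  paths <- c(t1 = file.path(dir, paste0("t1", ext)),
             t2 = file.path(dir, paste0("t2", ext)),
             truth = file.path(dir, "truth.png"),
             spec = file.path(dir, "scene_spec.yaml"))
  write_cube(scene$t1, paths[["t1"]], format = format)
  write_cube(scene$t2, paths[["t2"]], format = format)
  write_mask(scene$truth, paths[["truth"]])
  yaml::write_yaml(unclass(scene$spec), paths[["spec"]])
  invisible(paths)
}
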