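#' Mirror-pad a cube by one pixel on every side
#'
#' Enlarges each band plane from `(rows, cols)` to `(rows + 2, cols + 2)` by
#' edge-inclusive symmetric reflection, so that every original pixel has a
#' fully populated 3x3 window. For pad width 1 the edge-inclusive convention
#' duplicates the nearest interior row/column (corners duplicate the nearest
#' interior corner), which is well defined even on 1-pixel-wide scenes.
#' Original pixel `(r, c)` maps to padded pixel `(r + 1, c + 1)`.
#'
#' @param cube numeric 3-D array `(rows, cols, bands)`.
#' @return numeric 3-D array `(rows + 2, cols + 2, bands)` whose interior
#'   equals `cube` exactly.
#' @seealso [unpad()]
#' @examples
#' pad_mirror(array(matrix(1:4, 2, 2), dim = c(2, 2, 1)))[, , 1]
#' @export
pad_mirror <- function(cube) {
  cube <- check_cube(cube)
  d <- dim(cube)
  ri <- c(1L, seq_len(d[1L]), d[1L])
  ci <- c(1L, seq_len(d[2L]), d[2L])
  out <- cube[ri, ci, , drop = FALSE]
  attr(out, "band_labels") <- attr(cube, "band_labels")
  out
}

#' Strip a one-pixel border from a padded cube
#'
#' Inverse of [pad_mirror()]: returns the interior `(rows, cols, bands)` slice
#' of a `(rows + 2, cols + 2, bands)` cube.
#'
#' @param padded numeric 3-D array with at least 3 rows and 3 columns.
#' @return the interior cube, exactly equal to the original pre-padding cube.
#' @export
unpad <- function(padded) {
  padded <- check_cube(padded)
  d <- dim(padded)
  if (d[1L] < 3L || d[2L] < 3L) {
    stop("padded cube must be at least 3x3 spatially", call. = FALSE)
  }
  out <- padded[2:(d[1L] - 1L), 2:(d[2L] - 1L), , drop = FALSE]
  attr(out, "band_labels") <- attr(padded, "band_labels")
  out
}
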