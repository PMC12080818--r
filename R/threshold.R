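#' Binarize a change score map
#'
#' Turns a real-valued change score map into a binary change mask. Three
#' strategies:
#'
#' * `"otsu"` (default): the threshold maximizing between-class variance on a
#'   256-bin histogram of the min-max-normalized map. A constant map yields an
#'   all-zero mask with a warning.
#' * `"quantile"`: marks (approximately) the top `param` fraction of pixels as
#'   changed, i.e. all pixels whose score is at least the `k`-th largest with
#'   `k = max(1, floor(param * n))`; score ties at the cut may mark more than
#'   `k` pixels.
#' * `"fixed"`: marks pixels with score strictly greater than `param`.
#'
#' @param map a `"change_scores"` object or a numeric score matrix.
#' @param strategy `"otsu"`, `"quantile"` or `"fixed"`.
#' @param param the changed fraction (quantile) or the threshold (fixed);
#'   ignored for otsu.
#' @return an integer matrix of 0/1 labels with attribute `threshold` (the
#'   score cut actually applied).
#' @examples
#' m <- matrix(c(rep(0, 8), 10), 3, 3)
#' sum(threshold_map(m, "quantile", 1 / 9)) # 1
#' @export
threshold_map <- function(map, strategy = c("otsu", "quantile", "fixed"),
                          param = NULL) {
  strategy <- match.arg(strategy)
  scores <- if (inherits(map, "change_scores")) map$scores else as.matrix(map)
  if (!is.numeric(scores) || anyNA(scores) || any(!is.finite(scores))) {
    stop("score map must be finite numeric", call. = FALSE)
  }
  thr <- switch(strategy,
    otsu = {
      if (max(scores) == min(scores)) {
        warning("constant score map; Otsu threshold undefined, ",
                "returning all-zero mask", call. = FALSE)
        Inf
      } else {
        rng <- range(scores)
        otsu_threshold(minmax_scale(scores)) * (rng[2L] - rng[1L]) + rng[1L]
      }
    },
    quantile = {
      if (is.null(param) || param <= 0 || param > 1) {
        stop("quantile strategy needs param in (0, 1]", call. = FALSE)
      }
      k <- max(1L, floor(param * length(scores)))
      sort(scores, decreasing = TRUE)[k] - .Machine$double.eps^0.5
    },
    fixed = {
      if (is.null(param)) stop("fixed strategy needs a threshold param",
                               call. = FALSE)
      param
    }
  )
  mask <- matrix(as.integer(scores > thr), nrow(scores), ncol(scores))
  attr(mask, "threshold") <- thr
  mask
}

# internal: Otsu's method on values in [0, 1] with a 256-bin histogram.
# Returns the bin-edge threshold maximizing between-class variance;
# classification is score > threshold.
otsu_threshold <- function(x, levels = 256L) {
  breaks <- seq(0, 1, length.out = levels + 1L)
  h <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
                nbins = levels)
  p <- h / sum(h)
  mids <- (breaks[-1L] + breaks[-(levels + 1L)]) / 2
  omega <- cumsum(p)                    # class-0 mass at threshold after bin t
  mu <- cumsum(p * mids)                # partial mean
  mu_t <- mu[levels]
  # between-class variance for thresholds after bins 1..levels-1
  om <- omega[-levels]
  valid <- om > 0 & om < 1
  sigma_b <- numeric(levels - 1L)
  sigma_b[valid] <- (mu_t * om[valid] - mu[-levels][valid])^2 /
    (om[valid] * (1 - om[valid]))
  # the variance curve is flat across empty histogram gaps; take the mean of
  # all maximizing thresholds (the usual tie rule, mid-gap for bimodal maps)
  t_best <- which(sigma_b >= max(sigma_b) - 1e-12)
  mean(breaks[t_best + 1L])
}
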