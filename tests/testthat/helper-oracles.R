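# Independent brute-force oracles, deliberately written with plain loops and
# their own formulas so they share no code path with the package internals.

rand_cube <- function(rows, cols, bands, seed, lo = 0.1, hi = 2) {
  set.seed(seed)
  array(runif(rows * cols * bands, lo, hi), dim = c(rows, cols, bands))
}

# edge-clamped neighbor lookup, equivalent to 1-pixel edge-inclusive mirror
clamp_idx <- function(i, n) min(max(i, 1L), n)

# naive per-pixel spatial reconstruction (similarity/cosine unless told
# otherwise), computing affinities from first principles
naive_reconstruct <- function(cube, metric = "cosine", mode = "similarity",
                              w0 = 1) {
  d <- dim(cube)
  out <- array(0, dim = d)
  for (r in seq_len(d[1])) {
    for (cc in seq_len(d[2])) {
      x0 <- cube[r, cc, ]
      nb <- list(cube[clamp_idx(r - 1L, d[1]), cc, ],
                 cube[clamp_idx(r + 1L, d[1]), cc, ],
                 cube[r, clamp_idx(cc - 1L, d[2]), ],
                 cube[r, clamp_idx(cc + 1L, d[2]), ])
      raw <- vapply(nb, function(xi) {
        if (metric == "euclidean") {
          dist <- sqrt(sum((x0 - xi)^2))
          return(if (mode == "similarity") 1 / (1 + dist) else dist)
        }
        n0 <- sqrt(sum(x0^2)); ni <- sqrt(sum(xi^2))
        if (n0 == 0 || ni == 0) return(0)
        cs <- min(max(sum(x0 * xi) / (n0 * ni), -1), 1)
        if (mode == "similarity") max(cs, 0) else
          if (metric == "cosine") 1 - cs else acos(cs)
      }, numeric(1))
      eta <- sum(raw)
      wn <- if (eta > 0) raw / eta else rep(0.25, 4)
      acc <- numeric(d[3])
      for (i in 1:4) acc <- acc + wn[i] * nb[[i]]
      out[r, cc, ] <- acc / w0
    }
  }
  out
}

# naive windowed detector on two already-reconstructed cubes: per-pixel
# triple loop over the 3x3 window and every band
naive_score_map <- function(y1, y2) {
  d <- dim(y1)
  out <- matrix(0, d[1], d[2])
  for (r in seq_len(d[1])) {
    for (cc in seq_len(d[2])) {
      acc <- 0
      for (dr in -1:1) {
        for (dc in -1:1) {
          rr <- clamp_idx(r + dr, d[1])
          ccc <- clamp_idx(cc + dc, d[2])
          for (b in seq_len(d[3])) {
            acc <- acc + y2[rr, ccc, b]^2 - y1[rr, ccc, b]^2
          }
        }
      }
      a <- y1[r, cc, ]; b2 <- y2[r, cc, ]
      na <- sqrt(sum(a^2)); nb <- sqrt(sum(b2^2))
      w <- if (na == 0 || nb == 0) 0 else atan((sum(a * b2) / (na * nb))^2)
      out[r, cc] <- abs(acc) * w
    }
  }
  out
}

# exhaustive pairwise Mann-Whitney AUC: P(pos > neg) + 0.5 P(tie)
pairwise_auc <- function(scores, labels) {
  s <- as.numeric(scores)
  y <- as.integer(as.numeric(labels) != 0)
  pos <- s[y == 1]
  neg <- s[y == 0]
  cmp <- outer(pos, neg, `-`)
  (sum(cmp > 0) + 0.5 * sum(cmp == 0)) / (length(pos) * length(neg))
}
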