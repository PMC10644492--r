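## Fixtures and independent oracles used across the test files.

## --- simple rasters -------------------------------------------------------

disk_mask <- function(r, dim = 2 * r + 21, center = c(dim, dim) / 2) {
  m <- matrix(0L, dim, dim)
  idx <- expand.grid(row = seq_len(dim), col = seq_len(dim))
  inside <- (idx$row - center[1])^2 + (idx$col - center[2])^2 <= r^2
  m[cbind(idx$row[inside], idx$col[inside])] <- 1L
  m
}

rect_mask <- function(h, w, pad = 10) {
  m <- matrix(0L, h + 2 * pad, w + 2 * pad)
  m[pad + seq_len(h), pad + seq_len(w)] <- 1L
  m
}

ellipse_blob <- function(a, b, theta_deg, dim = 2 * ceiling(a) + 21) {
  m <- matrix(0L, dim, dim)
  th <- theta_deg * pi / 180
  ctr <- dim / 2
  idx <- expand.grid(row = seq_len(dim), col = seq_len(dim))
  dx <- idx$col - ctr; dy <- idx$row - ctr
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  m[cbind(idx$row[inside], idx$col[inside])] <- 1L
  m
}

## analytic closed contours ((x, y) matrices)
contour_ellipse <- function(a, b, cx = 0, cy = 0, n = 360) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(x = cx + a * cos(t), y = cy + b * sin(t))
}

contour_rect <- function(w, h) {
  cbind(x = c(seq(0, w, by = 1), rep(w, h - 1), seq(w, 0, by = -1), rep(0, h - 1)),
        y = c(rep(0, w + 1), seq(1, h, by = 1), rep(h, w), seq(h - 1, 1, by = -1)))
}

contour_star <- function(n = 720, k = 5, r0 = 40, amp = 12) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  r <- r0 + amp * cos(k * t)
  cbind(x = r * cos(t), y = r * sin(t))
}

## elongated asymmetric blob whose first-harmonic ellipse is well separated
## from a circle (normalization needs a defined major axis)
contour_egg <- function(n = 720) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(x = 50 * cos(t) + 8 * cos(2 * t), y = 25 * sin(t) + 5 * sin(3 * t))
}

## --- independent oracles --------------------------------------------------

## Elliptical Fourier coefficients by exact piecewise-linear Fourier
## integration (integration by parts per polygon segment) — an independent
## route from the chain-integral formulas in the package.
efd_oracle <- function(contour, n_harmonics) {
  x <- contour[, 1]; y <- contour[, 2]
  if (x[1] == x[length(x)] && y[1] == y[length(y)]) {
    x <- x[-length(x)]; y <- y[-length(y)]
  }
  dx <- diff(c(x, x[1])); dy <- diff(c(y, y[1]))
  dt <- sqrt(dx^2 + dy^2)
  t1 <- cumsum(dt); t0 <- c(0, t1[-length(t1)])
  T <- t1[length(t1)]
  seg_cos <- function(vals, slopes, w) {
    A <- vals - slopes * t0
    F <- function(t) A * sin(w * t) / w + slopes * (cos(w * t) / w^2 + t * sin(w * t) / w)
    sum(F(t1) - F(t0))
  }
  seg_sin <- function(vals, slopes, w) {
    A <- vals - slopes * t0
    F <- function(t) -A * cos(w * t) / w + slopes * (sin(w * t) / w^2 - t * cos(w * t) / w)
    sum(F(t1) - F(t0))
  }
  mx <- dx / dt; my <- dy / dt
  out <- matrix(0, n_harmonics, 4, dimnames = list(NULL, c("a", "b", "c", "d")))
  for (n in seq_len(n_harmonics)) {
    w <- 2 * pi * n / T
    out[n, "a"] <- 2 / T * seg_cos(x, mx, w)
    out[n, "b"] <- 2 / T * seg_sin(x, mx, w)
    out[n, "c"] <- 2 / T * seg_cos(y, my, w)
    out[n, "d"] <- 2 / T * seg_sin(y, my, w)
  }
  out
}

## Brute-force Euclidean distance transform (O(n^2), small rasters only).
edt_oracle <- function(mask) {
  fg <- which(mask > 0, arr.ind = TRUE)
  bg <- which(mask == 0, arr.ind = TRUE)
  out <- matrix(0, nrow(mask), ncol(mask))
  if (nrow(bg) == 0) { out[] <- Inf; return(out) }
  for (i in seq_len(nrow(fg))) {
    out[fg[i, 1], fg[i, 2]] <-
      sqrt(min((bg[, 1] - fg[i, 1])^2 + (bg[, 2] - fg[i, 2])^2))
  }
  out
}

## All-pairs shortest paths on a skeleton raster by iterated relaxation
## (Bellman-Ford style; tiny inputs only). Returns the longest
## endpoint-to-endpoint geodesic.
path_length_oracle <- function(skel) {
  idx <- which(skel > 0, arr.ind = TRUE)
  n <- nrow(idx)
  d <- matrix(Inf, n, n); diag(d) <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    dr <- abs(idx[i, 1] - idx[j, 1]); dc <- abs(idx[i, 2] - idx[j, 2])
    if (i != j && dr <= 1 && dc <= 1) d[i, j] <- if (dr + dc == 2) sqrt(2) else 1
  }
  for (k in seq_len(n)) d <- pmin(d, outer(d[, k], d[k, ], `+`))
  deg <- vapply(seq_len(n), function(i) sum(is.finite(d[i, ]) &
    abs(idx[, 1] - idx[i, 1]) <= 1 & abs(idx[, 2] - idx[i, 2]) <= 1) - 1, 0)
  ends <- which(deg == 1)
  max(d[ends, ends][is.finite(d[ends, ends])])
}

## Otsu oracle: direct two-class between-class variance scan over pixel
## values (shares the package's documented mid-plateau tie-break).
otsu_oracle <- function(gray) {
  v <- as.integer(round(gray))
  n <- length(v)
  sb <- vapply(0:255, function(t) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (length(lo) == 0 || length(hi) == 0) return(-Inf)
    (length(lo) / n) * (length(hi) / n) * (mean(lo) - mean(hi))^2
  }, 0)
  best <- (0:255)[sb >= max(sb) - 1e-9]
  round(mean(best))
}

## one rendered small scene + truth, shared by several tests
small_scene <- function(n_spikes = 3, seed = 42, arc = 300, n_spikelets = 5) {
  spikes <- replicate(n_spikes, spike_spec(arc_length = arc, n_spikelets = n_spikelets),
                      simplify = FALSE)
  render_scene(scene_spec(spikes, height = arc + 220, width = 180 * n_spikes + 100,
                          seed = seed))
}
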