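## Shape descriptors: geometric region properties of a binary mask and
## elliptical Fourier analysis of its outline (coefficients, normalization,
## harmonic power, reconstruction).

#' Geometric descriptors of a region
#'
#' * `area`: pixel count.
#' * `eccentricity`, `major_axis`, `minor_axis`: from the ellipse with the
#'   region's normalized second central moments.
#' * `equivalent_diameter`: `sqrt(4 * area / pi)`.
#' * `extent`: area / bounding-box area.
#' * `solidity`: area / filled convex-hull area (hull rasterized, so <= 1).
#' * `feret_max`: largest pairwise distance between hull vertices;
#'   `feret_min`: smallest caliper width over hull edge directions
#'   (rotating calipers).
#' * `perimeter`: boundary chain length with steps of 1 (orthogonal) and
#'   sqrt(2) (diagonal).
#'
#' @param mask 0/1 matrix, non-empty.
#' @return one-row data.frame of class `"geometry_record"`.
#' @export
region_geometry <- function(mask) {
  .check_mask(mask)
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask", call. = FALSE)
  area <- nrow(idx)
  me <- .moment_ellipse(idx)
  ecc <- if (me$a > 0) sqrt(max(0, 1 - (me$b / me$a)^2)) else 0
  bb <- .bbox(mask)
  extent <- area / ((bb$r1 - bb$r0 + 1) * (bb$c1 - bb$c0 + 1))
  hull_mask <- .convex_hull_mask(mask)
  solidity <- min(1, area / sum(hull_mask))
  x <- idx[, 2]; y <- idx[, 1]
  if (area >= 3) {
    h <- grDevices::chull(x, y)
    hx <- x[h]; hy <- y[h]
  } else {
    hx <- x; hy <- y
  }
  feret_max <- sqrt(max(outer(hx, hx, `-`)^2 + outer(hy, hy, `-`)^2))
  feret_min <- .min_caliper(hx, hy)
  perim <- .chain_perimeter(mask)
  structure(data.frame(area = area, eccentricity = ecc,
                       equivalent_diameter = sqrt(4 * area / pi),
                       extent = extent, feret_max = feret_max, feret_min = feret_min,
                       major_axis = 2 * me$a, minor_axis = 2 * me$b,
                       perimeter = perim, solidity = solidity),
            class = c("geometry_record", "data.frame"))
}

## Rotating calipers: minimum width over hull edge directions.
.min_caliper <- function(hx, hy) {
  n <- length(hx)
  if (n == 1) return(1)
  if (n == 2) return(1)  # degenerate 1-px-wide set
  widths <- vapply(seq_len(n), function(i) {
    j <- if (i == n) 1L else i + 1L
    ex <- hx[j] - hx[i]; ey <- hy[j] - hy[i]
    len <- sqrt(ex^2 + ey^2)
    if (len < 1e-12) return(Inf)
    ## distance of all vertices from the edge line
    d <- abs((hx - hx[i]) * ey - (hy - hy[i]) * ex) / len
    max(d)
  }, 0)
  w <- min(widths[is.finite(widths)])
  max(w, 1)  # a rasterized set is at least one pixel wide
}

## Weighted boundary chain length of the outer contour.
.chain_perimeter <- function(mask) {
  ct <- extract_contour(mask, fill_holes = TRUE)
  dx <- diff(c(ct[, 1], ct[1, 1]))
  dy <- diff(c(ct[, 2], ct[1, 2]))
  sum(sqrt(dx^2 + dy^2))
}

#' Extract the outer contour of a mask
#'
#' Interior holes are filled first; the outer boundary pixel chain is then
#' traced and returned as a closed `(x, y)` sequence (x = column, y = row,
#' 0-based, top-left origin), oriented counter-clockwise in the y-down image
#' frame (positive shoelace area).
#'
#' @param mask 0/1 matrix with a single foreground component.
#' @param fill_holes fill interior holes before tracing (default `TRUE`).
#' @return numeric matrix with columns `x`, `y`.
#' @export
extract_contour <- function(mask, fill_holes = TRUE) {
  .check_mask(mask)
  if (sum(mask > 0) < 4) stop("degenerate contour: mask has fewer than 4 px", call. = FALSE)
  im <- .ebi((mask > 0) * 1)
  if (fill_holes) im <- EBImage::fillHull(im)
  oc <- EBImage::ocontour(EBImage::bwlabel(im))
  ## keep the longest contour (the outer boundary of the main component)
  ct <- oc[[which.max(vapply(oc, nrow, 0))]]
  ct <- cbind(x = ct[, 1], y = ct[, 2])
  ## signed (shoelace) area; enforce positive orientation in the y-down frame
  x <- ct[, 1]; y <- ct[, 2]
  a2 <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
  if (a2 < 0) ct <- ct[rev(seq_len(nrow(ct))), , drop = FALSE]
  ct
}

#' Elliptical Fourier coefficients of a closed contour
#'
#' Per-harmonic coefficients `a_n, b_n, c_n, d_n` of the outline's x/y
#' coordinate series, computed with the closed-form chain-integral formulas
#' for a polygonal contour (arc-length parameterization); `A0`/`C0` are the
#' offsets of the elliptic loci (the curve's arc-length centroid).
#'
#' @param contour closed `(x, y)` matrix as from [extract_contour()].
#' @param n_harmonics number of harmonics (>= 1).
#' @return object of class `"efd"`: list with `an`, `bn`, `cn`, `dn`, `A0`,
#'   `C0`, `n_harmonics`, `normalized`.
#' @export
efd_coefficients <- function(contour, n_harmonics = 20) {
  if (n_harmonics < 1) stop("n_harmonics must be >= 1", call. = FALSE)
  if (!is.matrix(contour) || ncol(contour) < 2 || nrow(contour) < 3) {
    stop("contour must be a closed (x, y) matrix with >= 3 points", call. = FALSE)
  }
  x <- contour[, 1]; y <- contour[, 2]
  ## drop an explicit closing point and consecutive duplicates
  if (x[1] == x[length(x)] && y[1] == y[length(y)]) {
    x <- x[-length(x)]; y <- y[-length(y)]
  }
  keep <- c(TRUE, diff(x) != 0 | diff(y) != 0)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("degenerate contour", call. = FALSE)
  dx <- diff(c(x, x[1])); dy <- diff(c(y, y[1]))
  dt <- sqrt(dx^2 + dy^2)
  t1 <- cumsum(dt)
  t0 <- c(0, t1[-length(t1)])
  T <- t1[length(t1)]
  n <- seq_len(n_harmonics)
  ang1 <- outer(n, t1) * (2 * pi / T)
  ang0 <- outer(n, t0) * (2 * pi / T)
  co <- cos(ang1) - cos(ang0)
  si <- sin(ang1) - sin(ang0)
  fac <- T / (2 * pi^2 * n^2)
  an <- fac * as.vector((co %*% (dx / dt)))
  bn <- fac * as.vector((si %*% (dx / dt)))
  cn <- fac * as.vector((co %*% (dy / dt)))
  dn <- fac * as.vector((si %*% (dy / dt)))
  ## arc-length centroid (trapezoid is exact for a polygonal chain)
  xs <- c(x, x[1]); ys <- c(y, y[1])
  A0 <- sum(dt * (xs[-1] + xs[-length(xs)]) / 2) / T
  C0 <- sum(dt * (ys[-1] + ys[-length(ys)]) / 2) / T
  structure(list(an = an, bn = bn, cn = cn, dn = dn, A0 = A0, C0 = C0,
                 n_harmonics = n_harmonics, normalized = FALSE),
            class = "efd")
}

#' Normalize elliptical Fourier coefficients
#'
#' Makes the representation insensitive to the contour's size, rotation and
#' starting point: the phase of the first harmonic is rotated out
#' (starting-point normalization), the shape is rotated so the first
#' harmonic's major axis lies along x, and all coefficients are divided by the
#' first harmonic's semi-major magnitude. Idempotent.
#'
#' @param efd an [efd_coefficients()] object.
#' @return normalized `"efd"` object (`A0`/`C0` zeroed).
#' @export
normalize_efd <- function(efd) {
  stopifnot(inherits(efd, "efd"))
  if (isTRUE(efd$normalized)) return(efd)
  a1 <- efd$an[1]; b1 <- efd$bn[1]; c1 <- efd$cn[1]; d1 <- efd$dn[1]
  if (a1^2 + b1^2 + c1^2 + d1^2 < 1e-24) stop("degenerate shape: zero first harmonic", call. = FALSE)
  theta <- 0.5 * atan2(2 * (a1 * b1 + c1 * d1), a1^2 + c1^2 - b1^2 - d1^2)
  n <- seq_len(efd$n_harmonics)
  an <- efd$an; bn <- efd$bn; cn <- efd$cn; dn <- efd$dn
  rot_start <- function(theta) {
    ct <- cos(n * theta); st <- sin(n * theta)
    list(an = an * ct + bn * st, bn = -an * st + bn * ct,
         cn = cn * ct + dn * st, dn = -cn * st + dn * ct)
  }
  r <- rot_start(theta)
  ## resolve the half-period ambiguity so the first harmonic's a is positive
  psi <- atan2(r$cn[1], r$an[1])
  E <- sqrt(r$an[1]^2 + r$cn[1]^2)
  if (E < 1e-12) stop("degenerate shape: zero first harmonic", call. = FALSE)
  cp <- cos(psi); sp <- sin(psi)
  an2 <- cp * r$an + sp * r$cn; cn2 <- -sp * r$an + cp * r$cn
  bn2 <- cp * r$bn + sp * r$dn; dn2 <- -sp * r$bn + cp * r$dn
  if (an2[1] < 0) {  # flip both normalizations by half a period
    r <- rot_start(theta + pi)
    psi <- atan2(r$cn[1], r$an[1])
    cp <- cos(psi); sp <- sin(psi)
    an2 <- cp * r$an + sp * r$cn; cn2 <- -sp * r$an + cp * r$cn
    bn2 <- cp * r$bn + sp * r$dn; dn2 <- -sp * r$bn + cp * r$dn
    E <- sqrt(r$an[1]^2 + r$cn[1]^2)
  }
  an2 <- an2 / E; bn2 <- bn2 / E; cn2 <- cn2 / E; dn2 <- dn2 / E
  ## a residual joint ambiguity remains: advancing the starting point half a
  ## period together with a half-turn rotation flips every even-harmonic
  ## coefficient. Pin it by making the dominant even-harmonic coefficient
  ## positive (harmless when there is no even-harmonic content).
  ev <- seq_len(efd$n_harmonics)[seq_len(efd$n_harmonics) %% 2 == 0]
  if (length(ev) > 0) {
    v <- c(an2[ev], bn2[ev], cn2[ev], dn2[ev])
    j <- which.max(abs(v))
    if (abs(v[j]) > 1e-10 && v[j] < 0) {
      an2[ev] <- -an2[ev]; bn2[ev] <- -bn2[ev]
      cn2[ev] <- -cn2[ev]; dn2[ev] <- -dn2[ev]
    }
  }
  structure(list(an = an2, bn = bn2, cn = cn2, dn = dn2,
                 A0 = 0, C0 = 0, n_harmonics = efd$n_harmonics, normalized = TRUE),
            class = "efd")
}

#' Per-harmonic Fourier power
#'
#' Power of harmonic n is `(a_n^2 + b_n^2 + c_n^2 + d_n^2) / 2`; the
#' cumulative fraction (relative to the total over the available harmonics) is
#' non-decreasing and reaches 1.
#'
#' @param efd an `"efd"` object.
#' @return list with `power` (per harmonic) and `cumulative` (fractions).
#' @export
fourier_power <- function(efd) {
  stopifnot(inherits(efd, "efd"))
  p <- (efd$an^2 + efd$bn^2 + efd$cn^2 + efd$dn^2) / 2
  list(power = p, cumulative = cumsum(p) / sum(p))
}

#' Harmonics needed to reach a Fourier power threshold
#'
#' Smallest n whose cumulative power fraction exceeds `threshold`
#' (default 0.9999), used as an "optimal" harmonic count.
#'
#' @param contour closed `(x, y)` contour matrix.
#' @param threshold power fraction on (0, 1).
#' @param max_harmonics number of harmonics the total power is computed over.
#' @return integer n*.
#' @export
harmonics_for_power <- function(contour, threshold = 0.9999, max_harmonics = 100) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be on (0, 1)", call. = FALSE)
  efd <- efd_coefficients(contour, n_harmonics = max_harmonics)
  cf <- fourier_power(efd)$cumulative
  n <- which(cf > threshold)
  if (length(n) == 0) {
    warning("threshold not exceeded within max_harmonics")
    return(max_harmonics)
  }
  min(n)
}

#' Reconstruct a contour from truncated Fourier series
#'
#' Evaluates the elliptic loci from the first `n` harmonics at `n_points`
#' evenly spaced parameter values.
#'
#' @param efd an `"efd"` object.
#' @param n number of harmonics to use (<= `efd$n_harmonics`).
#' @param n_points number of output points.
#' @return `(x, y)` matrix.
#' @export
reconstruct_contour <- function(efd, n = efd$n_harmonics, n_points = 300) {
  stopifnot(inherits(efd, "efd"))
  if (n > efd$n_harmonics) stop("n exceeds the available harmonics", call. = FALSE)
  t <- seq(0, 2 * pi, length.out = n_points + 1)[-(n_points + 1)]
  x <- rep(efd$A0, n_points); y <- rep(efd$C0, n_points)
  for (k in seq_len(n)) {
    x <- x + efd$an[k] * cos(k * t) + efd$bn[k] * sin(k * t)
    y <- y + efd$cn[k] * cos(k * t) + efd$dn[k] * sin(k * t)
  }
  cbind(x = x, y = y)
}

#' Mean reconstruction error of a truncated series
#'
#' Mean distance from the original contour points to the reconstructed
#' polygon (point-to-segment).
#'
#' @param contour closed `(x, y)` matrix.
#' @param n number of harmonics.
#' @param max_harmonics harmonics computed before truncation.
#' @param n_points reconstruction resolution.
#' @return mean distance in px.
#' @export
reconstruction_error <- function(contour, n, max_harmonics = max(n, 30), n_points = 400) {
  efd <- efd_coefficients(contour, n_harmonics = max_harmonics)
  rec <- reconstruct_contour(efd, n = n, n_points = n_points)
  mean(.points_to_polyline(contour[, 1], contour[, 2], rec[, 1], rec[, 2]))
}

## distance from each point (px, py) to a closed polyline (qx, qy)
.points_to_polyline <- function(px, py, qx, qy) {
  q2x <- c(qx[-1], qx[1]); q2y <- c(qy[-1], qy[1])
  ex <- q2x - qx; ey <- q2y - qy
  el2 <- ex^2 + ey^2
  vapply(seq_along(px), function(i) {
    tx <- px[i] - qx; ty <- py[i] - qy
    tt <- pmin(1, pmax(0, (tx * ex + ty * ey) / pmax(el2, 1e-12)))
    min(sqrt((tx - tt * ex)^2 + (ty - tt * ey)^2))
  }, 0)
}

#' Split coefficients into symmetric and asymmetric components
#'
#' The `b_n`/`c_n` coefficients carry the symmetric source of variance, the
#' `a_n`/`d_n` coefficients the asymmetric one; the two power sums partition
#' the total Fourier power.
#'
#' @param efd a normalized `"efd"` object.
#' @return list with `symmetric` (`bn`, `cn`, `power`), `asymmetric`
#'   (`an`, `dn`, `power`) and `total_power`.
#' @export
efd_symmetry_split <- function(efd) {
  stopifnot(inherits(efd, "efd"))
  sym <- sum(efd$bn^2 + efd$cn^2) / 2
  asym <- sum(efd$an^2 + efd$dn^2) / 2
  list(symmetric = list(bn = efd$bn, cn = efd$cn, power = sym),
       asymmetric = list(an = efd$an, dn = efd$dn, power = asym),
       total_power = sym + asym)
}
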