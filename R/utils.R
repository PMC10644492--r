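## Internal helpers shared across modules.
##
## Raster conventions used throughout the package:
##  * an RGB image is a numeric array [nrow, ncol, 3] with values on 0..255,
##    origin at the top-left, rows running downwards;
##  * a mask is a 0/1 (or logical) matrix [nrow, ncol];
##  * EBImage stores rasters transposed (first dimension = x), so every call
##    into EBImage goes through .ebi()/.unebi().

.ebi <- function(m) EBImage::Image(t(m))

.unebi <- function(im) t(EBImage::imageData(im))

.clip8 <- function(x) {
  x[x < 0] <- 0
  x[x > 255] <- 255
  x
}

.is_rgb <- function(image) is.array(image) && length(dim(image)) == 3L && dim(image)[3] == 3L

.check_rgb <- function(image) {
  if (!.is_rgb(image)) {
    stop("expected an RGB raster: numeric array [rows, cols, 3] on 0..255", call. = FALSE)
  }
  invisible(image)
}

.check_mask <- function(mask) {
  if (!is.matrix(mask)) stop("expected a binary mask matrix", call. = FALSE)
  invisible(mask)
}

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

## Derive a per-item seed from a base seed, staying inside 32-bit range.
.subseed <- function(seed, i) as.integer((as.numeric(seed) + 7919 * i) %% .Machine$integer.max)

## Exact 8-connected labelling: EBImage::bwlabel is 4-connected, so labels that
## touch only diagonally are merged through a union on the label graph.
.label8 <- function(mask) {
  lab <- .unebi(EBImage::bwlabel(.ebi(mask > 0)))
  k <- max(lab)
  if (k < 2) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  ## diagonal neighbour pairs carrying two different labels
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # SE direction
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]   # SW direction
  p <- rbind(cbind(as.vector(a1), as.vector(b1)), cbind(as.vector(a2), as.vector(b2)))
  p <- p[p[, 1] > 0 & p[, 2] > 0 & p[, 1] != p[, 2], , drop = FALSE]
  if (nrow(p) == 0) return(lab)
  g <- igraph::graph_from_edgelist(matrix(as.character(p), ncol = 2), directed = FALSE)
  g <- igraph::add_vertices(g, length(setdiff(as.character(seq_len(k)), igraph::V(g)$name)),
                            name = setdiff(as.character(seq_len(k)), igraph::V(g)$name))
  comp <- igraph::components(g)$membership
  map <- integer(k)
  map[as.integer(names(comp))] <- comp
  out <- lab
  out[lab > 0] <- map[lab[lab > 0]]
  ## renumber 1..k' in increasing old-label order
  u <- sort(unique(out[out > 0]))
  re <- integer(max(u)); re[u] <- seq_along(u)
  out[out > 0] <- re[out[out > 0]]
  out
}

## Bounding box of positive pixels: list(r0, r1, c0, c1).
.bbox <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  list(r0 = min(idx[, 1]), r1 = max(idx[, 1]), c0 = min(idx[, 2]), c1 = max(idx[, 2]))
}

## Second-central-moment ellipse of a pixel set. Returns centroid, semi-axis
## lengths (a >= b, each 2*sqrt(eigenvalue)) and orientation of the major axis
## in the image frame (x = columns rightwards, y = rows downwards), radians.
.moment_ellipse <- function(idx) {
  n <- nrow(idx)
  x <- idx[, 2]; y <- idx[, 1]
  mx <- mean(x); my <- mean(y)
  ## population (biased) central moments of pixel centres
  mu20 <- mean((x - mx)^2); mu02 <- mean((y - my)^2); mu11 <- mean((x - mx) * (y - my))
  tr <- mu20 + mu02
  det_ <- sqrt(max(0, (mu20 - mu02)^2 + 4 * mu11^2))
  l1 <- (tr + det_) / 2
  l2 <- max(0, (tr - det_) / 2)
  theta <- 0.5 * atan2(2 * mu11, mu20 - mu02)
  list(centroid = c(row = my, col = mx), a = 2 * sqrt(l1), b = 2 * sqrt(l2),
       theta = theta, n = n)
}

## Orientation in degrees on [0, 180), top-left-origin frame.
.theta_deg <- function(theta) {
  d <- (theta * 180 / pi) %% 180
  if (d < 0) d <- d + 180
  d
}

## Scanline fill of a simple polygon given vertices (x, y) in pixel-centre
## coordinates; returns a mask of the requested dimensions. Used to rasterize
## convex hulls.
.fill_polygon <- function(px, py, nrow_, ncol_) {
  m <- matrix(0L, nrow_, ncol_)
  n <- length(px)
  x2 <- c(px[-1], px[1]); y2 <- c(py[-1], py[1])
  for (r in seq_len(nrow_)) {
    yr <- r
    ## edges crossing the scanline (half-open rule avoids double counting)
    cross <- (py <= yr & y2 > yr) | (y2 <= yr & py > yr)
    if (!any(cross)) next
    xi <- px[cross] + (yr - py[cross]) * (x2[cross] - px[cross]) / (y2[cross] - py[cross])
    xi <- sort(xi)
    for (j in seq(1, length(xi) - 1, by = 2)) {
      c0 <- ceiling(xi[j] - 1e-9); c1 <- floor(xi[j + 1] + 1e-9)
      if (c1 >= c0) m[r, max(1, c0):min(ncol_, c1)] <- 1L
    }
  }
  m
}
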