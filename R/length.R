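## Spike length estimation by four methods: moment ellipse, convex hull,
## Zhang-Suen skeleton and medial axis. The thinning methods blur the mask
## (low-pass) before reducing it to a single-pixel-wide centerline, prune
## spikelet-induced spurs, and measure the longest endpoint-to-endpoint
## geodesic with step costs 1 (orthogonal) and sqrt(2) (diagonal).

## value of m at (r + dr, c + dc), zero-padded outside
.nb <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  sr <- (1 + max(0, dr)):(nr + min(0, dr))
  sc <- (1 + max(0, dc)):(nc + min(0, dc))
  out[sr - dr, sc - dc] <- m[sr, sc]
  out
}

## clockwise 8-neighbourhood starting north: p2..p9
.nb_offsets <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                    c(1, 0), c(1, -1), c(0, -1), c(-1, -1))

.neighbour_stack <- function(m) {
  lapply(.nb_offsets, function(o) .nb(m, o[1], o[2]))
}

## A = number of 0->1 transitions around the pixel, B = neighbour count
.crossing_stats <- function(nbs) {
  B <- Reduce(`+`, nbs)
  A <- matrix(0L, nrow(B), ncol(B))
  for (i in seq_along(nbs)) {
    j <- if (i == length(nbs)) 1L else i + 1L
    A <- A + (nbs[[i]] == 0L & nbs[[j]] == 1L)
  }
  list(A = A, B = B)
}

## Zhang-Suen parallel thinning of a 0/1 matrix.
.thin_zhang_suen <- function(m) {
  m <- (m > 0) * 1L
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      nbs <- .neighbour_stack(m)
      cs <- .crossing_stats(nbs)
      p2 <- nbs[[1]]; p4 <- nbs[[3]]; p6 <- nbs[[5]]; p8 <- nbs[[7]]
      if (sub == 1) {
        cond <- p2 * p4 * p6 == 0L & p4 * p6 * p8 == 0L
      } else {
        cond <- p2 * p4 * p8 == 0L & p2 * p6 * p8 == 0L
      }
      del <- m == 1L & cs$B >= 2L & cs$B <= 6L & cs$A == 1L & cond
      if (any(del)) {
        m[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

## Hilditch crossing number: the simple-point test for 8-connected
## foreground / 4-connected background. A border pixel with XH == 1 can be
## deleted without changing the mask's topology (unlike the Rutovitz
## transition count, this also clears redundant pixels on thick diagonal
## staircases).
.hilditch_crossing <- function(nbs) {
  ## nbs order: N, NE, E, SE, S, SW, W, NW
  x1 <- nbs[[3]]; x2 <- nbs[[2]]; x3 <- nbs[[1]]; x4 <- nbs[[8]]
  x5 <- nbs[[7]]; x6 <- nbs[[6]]; x7 <- nbs[[5]]; x8 <- nbs[[4]]
  (x1 == 0L & (x2 == 1L | x3 == 1L)) +
  (x3 == 0L & (x4 == 1L | x5 == 1L)) +
  (x5 == 0L & (x6 == 1L | x7 == 1L)) +
  (x7 == 0L & (x8 == 1L | x1 == 1L))
}

## Medial-axis thinning: distance-ordered homotopic thinning. Pixels are
## peeled in order of increasing Euclidean distance to the background, in four
## checkerboard subfields (no two same-subfield pixels are 8-adjacent, so
## simultaneous deletion preserves topology); only simple (Hilditch), non-end
## pixels are deleted, leaving a 1-px skeleton centred on the EDT ridge.
.thin_medial_axis <- function(m) {
  m <- (m > 0) * 1L
  d <- .unebi(EBImage::distmap(.ebi(m)))
  rpar <- matrix(seq_len(nrow(m)) %% 2L, nrow(m), ncol(m))
  cpar <- matrix(rep(seq_len(ncol(m)) %% 2L, each = nrow(m)), nrow(m), ncol(m))
  subfield <- rpar * 2L + cpar
  for (level in seq_len(ceiling(max(d)))) {
    repeat {
      changed <- FALSE
      for (sf in 0:3) {
        nbs <- .neighbour_stack(m)
        B <- Reduce(`+`, nbs)
        del <- m == 1L & d <= level & subfield == sf &
          B >= 2L & .hilditch_crossing(nbs) == 1L
        if (any(del)) {
          m[del] <- 0L
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  .sequential_cleanup(m, d)
}

## XH and B for a single pixel, read directly off the matrix.
.pixel_simple_stats <- function(m, r, c) {
  nr <- nrow(m); nc <- ncol(m)
  val <- function(dr, dc) {
    rr <- r + dr; cc <- c + dc
    if (rr < 1 || rr > nr || cc < 1 || cc > nc) 0L else m[rr, cc]
  }
  ## order: N, NE, E, SE, S, SW, W, NW
  v <- c(val(-1, 0), val(-1, 1), val(0, 1), val(1, 1),
         val(1, 0), val(1, -1), val(0, -1), val(-1, -1))
  x1 <- v[3]; x2 <- v[2]; x3 <- v[1]; x4 <- v[8]
  x5 <- v[7]; x6 <- v[6]; x7 <- v[5]; x8 <- v[4]
  xh <- (x1 == 0L && (x2 == 1L || x3 == 1L)) + (x3 == 0L && (x4 == 1L || x5 == 1L)) +
        (x5 == 0L && (x6 == 1L || x7 == 1L)) + (x7 == 0L && (x8 == 1L || x1 == 1L))
  c(xh = xh, B = sum(v))
}

## Parallel subfield passes can stall on 2x2 blocks and chorded staircases;
## a sequential sweep (one deletion at a time, in EDT order) is topology-safe
## and leaves a fully thinned 1-px skeleton.
.sequential_cleanup <- function(m, d) {
  nr <- nrow(m)
  repeat {
    nbs <- .neighbour_stack(m)
    B <- Reduce(`+`, nbs)
    cand <- which(m == 1L & B >= 2L & .hilditch_crossing(nbs) == 1L)
    if (length(cand) == 0) break
    cand <- cand[order(d[cand])]
    changed <- FALSE
    for (p in cand) {
      r <- (p - 1) %% nr + 1; c <- (p - 1) %/% nr + 1
      st <- .pixel_simple_stats(m, r, c)
      if (st["xh"] == 1 && st["B"] >= 2) {
        m[p] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

#' Thin a spike mask to a single-pixel centerline
#'
#' Applies a Gaussian low-pass filter (`blur_sigma`), re-binarizes at 0.5, and
#' thins with either Zhang-Suen's parallel algorithm (`"skeleton"`) or
#' distance-ordered homotopic thinning along the Euclidean distance-transform
#' ridge (`"medial_axis"`). The two methods differ only in the thinning
#' operator.
#'
#' @param mask 0/1 matrix, a single connected component.
#' @param method `"skeleton"` or `"medial_axis"`.
#' @param blur_sigma Gaussian blur SD in px; 0 skips the blur.
#' @return 0/1 matrix, 8-connected and one pixel wide.
#' @export
thin_mask <- function(mask, method = c("skeleton", "medial_axis"), blur_sigma = 2) {
  method <- match.arg(method)
  .check_mask(mask)
  m <- (mask > 0) * 1
  if (sum(m) == 0) stop("empty mask", call. = FALSE)
  if (blur_sigma > 0) {
    m <- (.unebi(EBImage::gblur(.ebi(m), sigma = blur_sigma)) > 0.5) * 1L
    if (sum(m) == 0) stop("degenerate input: mask vanished after blurring", call. = FALSE)
  }
  ## interior holes (enclosed background specks, e.g. pinched between
  ## serrations after the blur) would survive homotopic thinning as loops and
  ## break the endpoint-to-endpoint length path; spike masks are solid, so
  ## fill them before thinning
  m <- .unebi(EBImage::fillHull(.ebi(m)))
  sk <- if (method == "skeleton") .thin_zhang_suen(m) else .thin_medial_axis(m)
  if (sum(sk) == 0) {
    ## parallel thinning can annihilate small compact blobs outright; degrade
    ## to the blob centre (deepest point of the distance transform)
    d <- .unebi(EBImage::distmap(.ebi(m)))
    sk[which.max(d)] <- 1L
  }
  sk
}

## 8-neighbour degree of each skeleton pixel
.skel_degree <- function(m) {
  Reduce(`+`, .neighbour_stack(m)) * m
}

## Remove leaf branches (endpoint-to-junction chains) shorter than prune_px.
.prune_spurs <- function(skel, prune_px) {
  m <- (skel > 0) * 1L
  if (prune_px <= 0) return(m)
  nr <- nrow(m); nc <- ncol(m)
  step_w <- function(p, q) {
    if (((p - 1) %% nr != (q - 1) %% nr) && ((p - 1) %/% nr != (q - 1) %/% nr)) sqrt(2) else 1
  }
  nbrs_of <- function(p) {
    r <- (p - 1) %% nr + 1; c <- (p - 1) %/% nr + 1
    out <- integer(0)
    for (o in .nb_offsets) {
      rr <- r + o[1]; cc <- c + o[2]
      if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc && m[rr, cc] == 1L) {
        out <- c(out, (cc - 1L) * nr + rr)
      }
    }
    out
  }
  repeat {
    deg <- .skel_degree(m)
    ends <- which(m == 1L & deg == 1L)
    removed_any <- FALSE
    for (e in ends) {
      if (m[e] == 0L) next
      chain <- e; cur <- e; prev <- 0L; len <- 0
      spur <- FALSE
      repeat {
        nb <- nbrs_of(cur)
        nxt <- nb[nb != prev & !(nb %in% chain)]
        if (length(nxt) == 0) break                    # path runs to another endpoint: keep
        if (length(nxt) > 1) {                         # cur itself branches: drop the lead-in
          chain <- chain[chain != cur]
          spur <- length(chain) > 0
          break
        }
        len <- len + step_w(cur, nxt)
        if (deg[nxt] >= 3L) { spur <- TRUE; break }    # next pixel is a junction: chain is a spur
        if (len >= prune_px) break                     # long enough: keep
        prev <- cur; cur <- nxt
        chain <- c(chain, cur)
      }
      if (spur && len < prune_px) {
        m[chain] <- 0L
        removed_any <- TRUE
      }
    }
    if (!removed_any) break
  }
  m
}

## Build the weighted skeleton graph (vertices = pixels, 8-neighbour edges).
.skel_graph <- function(m) {
  nr <- nrow(m)
  idx <- which(m > 0)
  if (length(idx) == 0) stop("empty skeleton", call. = FALSE)
  vid <- integer(length(m)); vid[idx] <- seq_along(idx)
  edges <- NULL; weights <- NULL
  for (o in list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
    a <- .nb(m, o[1], o[2])
    from <- which(m > 0 & a > 0)
    if (!length(from)) next
    to <- from + o[1] + o[2] * nr
    edges <- rbind(edges, cbind(vid[from], vid[to]))
    weights <- c(weights, rep(if (sum(abs(o)) == 2) sqrt(2) else 1, length(from)))
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges), weight = weights)
  list(g = g, idx = idx)
}

#' Geodesic length of a skeleton
#'
#' Longest endpoint-to-endpoint shortest path on the skeleton pixel graph,
#' with step cost 1 for orthogonal and sqrt(2) for diagonal moves. Spurs
#' shorter than `prune_px` are removed first. A skeleton without endpoints
#' (a cycle) is measured by a two-sweep farthest-point search.
#'
#' @param skel 0/1 skeleton matrix.
#' @param prune_px spur-length threshold in px.
#' @return length in px (0 for a single pixel).
#' @export
skeleton_path_length <- function(skel, prune_px = 15) {
  .check_mask(skel)
  if (sum(skel > 0) == 0) stop("empty skeleton", call. = FALSE)
  m <- .prune_spurs(skel, prune_px)
  if (sum(m) <= 1) return(0)
  sg <- .skel_graph(m)
  deg <- igraph::degree(sg$g)
  ends <- which(deg == 1)
  if (length(ends) >= 2) {
    d <- igraph::distances(sg$g, v = ends, to = ends)
    return(max(d[is.finite(d)]))
  }
  ## cycle or blob: double sweep
  d1 <- igraph::distances(sg$g, v = 1)
  u <- which.max(replace(d1, !is.finite(d1), -1))
  d2 <- igraph::distances(sg$g, v = u)
  max(d2[is.finite(d2)])
}

## Longest endpoint-to-endpoint geodesic as an ordered pixel path
## ((row, col) matrix). Assumes spurs already pruned.
.longest_geodesic_path <- function(m) {
  sg <- .skel_graph(m)
  deg <- igraph::degree(sg$g)
  ends <- which(deg == 1)
  ## two-sweep farthest-point pair: exact on trees, and a safety net when a
  ## tip region carries no degree-1 pixel (locally unresolved braid)
  d1 <- igraph::distances(sg$g, v = 1)
  u <- which.max(replace(d1, !is.finite(d1), -1))
  d2 <- igraph::distances(sg$g, v = u)
  v <- which.max(replace(d2, !is.finite(d2), -1))
  cand <- unique(c(ends, u, v))
  if (length(cand) >= 2) {
    d <- igraph::distances(sg$g, v = cand, to = cand)
    d[!is.finite(d)] <- -1
    ij <- which(d == max(d), arr.ind = TRUE)[1, ]
    vpair <- cand[ij]
  } else {
    vpair <- cand
  }
  if (length(unique(vpair)) < 2) {
    idx <- sg$idx[vpair[1]]
    return(cbind(row = (idx - 1) %% nrow(m) + 1, col = (idx - 1) %/% nrow(m) + 1))
  }
  p <- igraph::shortest_paths(sg$g, from = vpair[1], to = vpair[2])$vpath[[1]]
  idx <- sg$idx[as.integer(p)]
  cbind(row = (idx - 1) %% nrow(m) + 1, col = (idx - 1) %/% nrow(m) + 1)
}

## Chord-resampled length of a pixel path: summing 1/sqrt(2) step weights
## overestimates digital curves at intermediate orientations (anisotropic
## digitization bias, up to ~8%); chords over every `step`-th pixel remove it
## and average out the small ridge meander induced by boundary serrations
## (step chosen near the serration wavelength).
.chord_length <- function(path, step = 15) {
  n <- nrow(path)
  if (n < 2) return(0)
  i <- unique(c(seq(1, n, by = step), n))
  sum(sqrt(diff(path[i, 1])^2 + diff(path[i, 2])^2))
}

#' Spike length from the moment ellipse
#'
#' Full major-axis length (2 x semi-major axis) of the ellipse with the same
#' normalized second central moments as the mask.
#'
#' @param mask 0/1 matrix.
#' @return list of class `"length_result"`: `method`, `length_px`, `time_s`.
#' @export
length_ellipse <- function(mask) {
  .check_mask(mask)
  t0 <- proc.time()[3]
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask", call. = FALSE)
  me <- .moment_ellipse(idx)
  structure(list(method = "ellipse", length_px = 2 * me$a,
                 time_s = proc.time()[3] - t0), class = "length_result")
}

## Rasterized filled convex hull of a mask.
.convex_hull_mask <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) < 3) return((mask > 0) * 1L)
  h <- grDevices::chull(idx[, 2], idx[, 1])
  hm <- .fill_polygon(idx[h, 2], idx[h, 1], nrow(mask), ncol(mask))
  pmax(hm, (mask > 0) * 1L)
}

#' Spike length from the convex-hull ellipse
#'
#' Same moment-ellipse rule as [length_ellipse()], applied to the filled
#' convex hull of the mask.
#'
#' @param mask 0/1 matrix.
#' @return a `"length_result"`.
#' @export
length_convex_hull <- function(mask) {
  .check_mask(mask)
  t0 <- proc.time()[3]
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask", call. = FALSE)
  hm <- .convex_hull_mask(mask)
  me <- .moment_ellipse(which(hm > 0, arr.ind = TRUE))
  structure(list(method = "convex_hull", length_px = 2 * me$a,
                 time_s = proc.time()[3] - t0), class = "length_result")
}

#' Estimate spike length by one or more methods
#'
#' Methods: `"ellipse"`, `"convex_hull"`, `"skeleton"` (Zhang-Suen) and
#' `"medial_axis"`. The thinning methods report the pruned-skeleton geodesic
#' length and can return an overlay of the centerline on the mask.
#'
#' @param mask 0/1 matrix, one spike.
#' @param methods subset of the four method names (default all).
#' @param blur_sigma Gaussian blur SD for the thinning methods.
#' @param prune_px spur-pruning threshold for the thinning methods.
#' @param overlay if `TRUE`, attach for each thinning method a raster with the
#'   mask at 1 and the centerline at 2.
#' @return data.frame with columns `method`, `length_px`, `time_s`; overlays
#'   (if requested) in `attr(, "overlays")`.
#' @export
spk_length <- function(mask, methods = c("ellipse", "convex_hull", "skeleton", "medial_axis"),
                       blur_sigma = 2, prune_px = 15, overlay = FALSE) {
  all_methods <- c("ellipse", "convex_hull", "skeleton", "medial_axis")
  if (length(methods) == 0) {
    return(data.frame(method = character(0), length_px = numeric(0), time_s = numeric(0)))
  }
  if (!all(methods %in% all_methods)) {
    stop("unknown length method(s): ", paste(setdiff(methods, all_methods), collapse = ", "),
         call. = FALSE)
  }
  overlays <- list()
  rows <- lapply(methods, function(mth) {
    if (mth == "ellipse") {
      r <- length_ellipse(mask)
    } else if (mth == "convex_hull") {
      r <- length_convex_hull(mask)
    } else {
      t0 <- proc.time()[3]
      sk <- thin_mask(mask, method = mth, blur_sigma = blur_sigma)
      skp <- .prune_spurs(sk, prune_px)
      path <- .longest_geodesic_path(skp)
      len <- .chord_length(path)
      r <- list(method = mth, length_px = len, time_s = proc.time()[3] - t0)
      if (overlay) {
        ov <- (mask > 0) * 1L
        ov[cbind(path[, 1], path[, 2])] <- 2L
        overlays[[mth]] <<- ov
      }
    }
    data.frame(method = r$method, length_px = r$length_px, time_s = r$time_s)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (overlay) attr(out, "overlays") <- overlays
  out
}
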