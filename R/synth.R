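## Synthetic scanner scenes with exact ground truth.
##
## The generator emulates dry grass spikes laid on a dark flatbed scanner:
## a near-black noisy background, elongated (possibly curved) spikes made of a
## thin rachis plus alternately attached ellipsoidal spikelets in a
## green-to-tan colour range. Every scene carries its ground truth (spike
## count, per-spike centerline arc length, spikelet count and centres), which
## is what makes segmentation, length and spikelet counting testable at desk
## scale.

#' Specify a synthetic spike
#'
#' A spike is a parametric centerline (straight segment for `curvature = 0`,
#' otherwise a circular arc of radius `1/abs(curvature)` px) carrying a rachis
#' band of width `rachis_width` and `n_spikelets` filled rotated ellipses
#' attached alternately left/right of the rachis.
#'
#' Spikelet size is modulated along the rachis by `(1 - u^2)^taper` (with `u`
#' on \[-1, 1\] from base to tip and a floor of 0.3), mimicking the tapering of
#' real ryegrass spikes towards the tip; see the package vignette for why this
#' profile also makes the moment-ellipse length estimator well behaved on
#' straight spikes.
#'
#' @param arc_length centerline arc length in px (> 0).
#' @param curvature signed curvature in 1/px; 0 gives a straight spike.
#' @param rachis_width rachis band width in px (>= 3).
#' @param n_spikelets number of spikelets (>= 0).
#' @param spikelet_spacing spacing between consecutive spikelet attachment
#'   points along the centerline, px.
#' @param spikelet_axes numeric length-2: (semi-major, semi-minor) spikelet
#'   ellipse axes in px at full size (mid-spike).
#' @param attach_angle angle in degrees between the spikelet major axis and the
#'   local rachis tangent; the sign alternates with the attachment side.
#' @param lateral_offset lateral displacement of each spikelet centre from the
#'   centerline, as a fraction of its semi-minor axis; large enough that
#'   consecutive spikelets touch only the rachis, never each other.
#' @param taper exponent of the spikelet size profile along the rachis.
#' @param base_color RGB triple on 0..255 for spikelet pixels.
#' @param rachis_color RGB triple for rachis-only pixels; default
#'   `0.85 * base_color`.
#' @param color_jitter per-channel Gaussian noise SD added per pixel.
#' @param orientation direction of travel of the centerline at the base, in
#'   degrees (0 = rightwards along columns, 90 = downwards along rows).
#' @return an object of class `"spike_spec"`.
#' @export
spike_spec <- function(arc_length = 500, curvature = 0, rachis_width = 11,
                       n_spikelets = 9, spikelet_spacing = 50,
                       spikelet_axes = c(40, 30), attach_angle = 35,
                       lateral_offset = 1.0, taper = 0.1,
                       base_color = c(115, 130, 60),
                       rachis_color = NULL, color_jitter = 8,
                       orientation = 90) {
  if (!is.numeric(arc_length) || arc_length <= 0) stop("arc_length must be > 0", call. = FALSE)
  if (rachis_width < 3) stop("rachis_width must be >= 3", call. = FALSE)
  if (n_spikelets < 0) stop("n_spikelets must be >= 0", call. = FALSE)
  if (spikelet_spacing <= 0) stop("spikelet_spacing must be > 0", call. = FALSE)
  if (any(base_color < 0) || any(base_color > 255)) stop("base_color must be on 0..255", call. = FALSE)
  if (length(spikelet_axes) != 2 || spikelet_axes[1] < spikelet_axes[2]) {
    stop("spikelet_axes must be (semi-major, semi-minor) with semi-major >= semi-minor", call. = FALSE)
  }
  if (n_spikelets > 0 && (n_spikelets - 1) * spikelet_spacing > arc_length) {
    stop("spikelets at this spacing do not fit on the centerline", call. = FALSE)
  }
  if (is.null(rachis_color)) rachis_color <- 0.85 * base_color
  structure(list(arc_length = arc_length, curvature = curvature,
                 rachis_width = rachis_width, n_spikelets = n_spikelets,
                 spikelet_spacing = spikelet_spacing, spikelet_axes = spikelet_axes,
                 attach_angle = attach_angle, lateral_offset = lateral_offset,
                 taper = taper,
                 base_color = base_color, rachis_color = rachis_color,
                 color_jitter = color_jitter, orientation = orientation),
            class = "spike_spec")
}

## Centerline point(s) and tangent heading at arc-length s (vectorised).
.centerline <- function(spec, s) {
  phi0 <- spec$orientation * pi / 180
  k <- spec$curvature
  if (abs(k) < 1e-12) {
    list(x = s * cos(phi0), y = s * sin(phi0), phi = rep(phi0, length(s)))
  } else {
    list(x = (sin(phi0 + k * s) - sin(phi0)) / k,
         y = -(cos(phi0 + k * s) - cos(phi0)) / k,
         phi = phi0 + k * s)
  }
}

## Spikelet size multiplier along the rachis.
.taper_scale <- function(spec, s) {
  u <- 2 * s / spec$arc_length - 1
  pmax(0.3, (1 - u^2)^spec$taper)
}

#' Render a single synthetic spike
#'
#' @param spec a [spike_spec()].
#' @param seed integer seed driving the colour noise.
#' @return list with `mask` (0/1 matrix, a single 8-connected component),
#'   `patch` (RGB array 0..255, background pixels zero) and `truth`
#'   (list: `arc_length`, `spikelet_count`, `centers` as a (row, col) matrix,
#'   `s` attachment arc-positions, `polyline_length` of the rendered
#'   centerline).
#' @export
render_spike <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "spike_spec"))
  L <- spec$arc_length
  sgrid <- seq(0, L, by = 0.5)
  cl <- .centerline(spec, sgrid)
  polyline_length <- sum(sqrt(diff(cl$x)^2 + diff(cl$y)^2))

  n <- spec$n_spikelets
  if (n > 0) {
    s0 <- (L - (n - 1) * spec$spikelet_spacing) / 2
    s_att <- s0 + (seq_len(n) - 1) * spec$spikelet_spacing
  } else {
    s_att <- numeric(0)
  }
  f <- .taper_scale(spec, s_att)
  att <- .centerline(spec, s_att)
  side <- ifelse(seq_len(n) %% 2 == 1, 1, -1)
  aj <- spec$spikelet_axes[1] * f
  bj <- spec$spikelet_axes[2] * f
  off <- spec$lateral_offset * bj
  cx <- att$x + side * off * cos(att$phi + pi / 2)
  cy <- att$y + side * off * sin(att$phi + pi / 2)
  psi <- att$phi + side * spec$attach_angle * pi / 180

  margin <- ceiling(max(spec$spikelet_axes[1], spec$rachis_width) + spec$rachis_width + 4)
  xs <- c(cl$x, cx); ys <- c(cl$y, cy)
  colshift <- margin + 1 - floor(min(xs))
  rowshift <- margin + 1 - floor(min(ys))
  W <- ceiling(max(xs)) + colshift + margin
  H <- ceiling(max(ys)) + rowshift + margin

  ## rachis: discs of tapering radius stamped along the centerline (the
  ## rachis thins towards base and tip with the same profile as the spikelets)
  mask <- matrix(0L, H, W)
  rad <- pmax(1.5, spec$rachis_width * .taper_scale(spec, sgrid) / 2)
  rr <- pmin(H, pmax(1, round(cl$y + rowshift)))
  cc <- pmin(W, pmax(1, round(cl$x + colshift)))
  for (rl in unique(ceiling(rad))) {
    sel <- ceiling(rad) == rl
    dd <- expand.grid(dr = -rl:rl, dc = -rl:rl)
    dd <- dd[dd$dr^2 + dd$dc^2 <= rl^2, ]
    pr <- outer(rr[sel], dd$dr, `+`); pc <- outer(cc[sel], dd$dc, `+`)
    ok <- pr >= 1 & pr <= H & pc >= 1 & pc <= W
    mask[cbind(as.vector(pr)[ok], as.vector(pc)[ok])] <- 1L
  }

  spikelet_mask <- matrix(0L, H, W)
  for (j in seq_len(n)) {
    ecx <- cx[j] + colshift; ecy <- cy[j] + rowshift
    ext <- ceiling(aj[j]) + 1
    c0 <- max(1, floor(ecx - ext)); c1 <- min(W, ceiling(ecx + ext))
    r0 <- max(1, floor(ecy - ext)); r1 <- min(H, ceiling(ecy + ext))
    g <- expand.grid(r = r0:r1, c = c0:c1)
    dx <- g$c - ecx; dy <- g$r - ecy
    um <- dx * cos(psi[j]) + dy * sin(psi[j])
    vm <- -dx * sin(psi[j]) + dy * cos(psi[j])
    inside <- (um / aj[j])^2 + (vm / bj[j])^2 <= 1
    spikelet_mask[cbind(g$r[inside], g$c[inside])] <- 1L
  }
  mask <- pmax(mask, spikelet_mask)

  ## crop canvas tight to the footprint
  bb <- .bbox(mask)
  r0 <- bb$r0; r1 <- bb$r1
  c0 <- bb$c0; c1 <- bb$c1
  mask <- mask[r0:r1, c0:c1]
  spikelet_mask <- spikelet_mask[r0:r1, c0:c1]
  Hc <- nrow(mask); Wc <- ncol(mask)

  patch <- with_seed(seed, {
    p <- array(0, c(Hc, Wc, 3))
    fg <- mask > 0
    spk <- spikelet_mask > 0
    for (ch in 1:3) {
      plane <- matrix(0, Hc, Wc)
      plane[fg] <- spec$rachis_color[ch]
      plane[spk] <- spec$base_color[ch]
      jit <- matrix(stats::rnorm(Hc * Wc, 0, spec$color_jitter), Hc, Wc)
      plane[fg] <- pmin(255, pmax(40, plane[fg] + jit[fg]))
      p[, , ch] <- round(plane)
    }
    p
  })

  centers <- cbind(row = cy + rowshift - r0 + 1, col = cx + colshift - c0 + 1)
  truth <- list(arc_length = L, spikelet_count = n, centers = centers,
                s = s_att, polyline_length = polyline_length)
  list(mask = mask, patch = patch, truth = truth)
}

#' Specify a synthetic scene
#'
#' @param spikes list of [spike_spec()] objects.
#' @param height,width scene dimensions in px.
#' @param background_level mean 8-bit background intensity (dark, low
#'   reflectance; the default 10 sits well below the default red-channel
#'   segmentation threshold of 20).
#' @param background_noise_sd per-pixel Gaussian background noise SD.
#' @param seed integer; drives placement jitter, background noise and the
#'   per-spike colour noise.
#' @param min_gap minimum horizontal gap between spike footprints, px.
#' @return an object of class `"scene_spec"`.
#' @export
scene_spec <- function(spikes, height = 1100, width = 1500,
                       background_level = 10, background_noise_sd = 3,
                       seed = 1, min_gap = 8) {
  stopifnot(is.list(spikes), all(vapply(spikes, inherits, TRUE, "spike_spec")))
  if (background_level < 0 || background_level > 255) stop("background_level must be on 0..255", call. = FALSE)
  structure(list(spikes = spikes, height = height, width = width,
                 background_level = background_level,
                 background_noise_sd = background_noise_sd,
                 seed = as.integer(seed), min_gap = min_gap),
            class = "scene_spec")
}

#' Render a synthetic scanner scene
#'
#' Spikes are laid side by side left-to-right (as on a scanner bed) with
#' seeded random horizontal slack and vertical offsets, guaranteeing pairwise
#' disjoint footprints; if the spikes cannot fit disjointly a placement error
#' is raised. Rendering is fully deterministic for a fixed spec and seed.
#'
#' @param spec a [scene_spec()].
#' @return list with `image` (RGB array 0..255) and `truth`: `n_spikes` plus a
#'   per-spike list (ordered left to right) of `arc_length`, `spikelet_count`,
#'   `centers` (scene coordinates), `anchor` (top-left of the footprint bbox),
#'   `bbox` and local `footprint` mask.
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  n <- length(spec$spikes)
  rendered <- lapply(seq_len(n), function(i) {
    render_spike(spec$spikes[[i]], seed = .subseed(spec$seed, i))
  })
  H <- spec$height; W <- spec$width

  anchors <- NULL
  if (n > 0) {
    ws <- vapply(rendered, function(r) ncol(r$mask), 0)
    hs <- vapply(rendered, function(r) nrow(r$mask), 0)
    if (any(hs > H)) stop("placement error: a spike is taller than the scene", call. = FALSE)
    need <- sum(ws) + (n + 1) * spec$min_gap
    if (need > W) stop("placement error: spikes cannot be placed disjointly", call. = FALSE)
    anchors <- with_seed(.subseed(spec$seed, 0), {
      slack <- W - need
      extra <- if (n >= 1) as.vector(stats::rmultinom(1, size = slack, prob = rep(1, n + 1))) else numeric(0)
      cols <- spec$min_gap + cumsum(c(0, ws[-n] + spec$min_gap)) + cumsum(extra[seq_len(n)]) + 1
      rows <- vapply(hs, function(h) sample.int(H - h + 1, 1), 0)
      cbind(row = rows, col = cols)
    })
  }

  image <- with_seed(.subseed(spec$seed, n + 1), {
    img <- array(stats::rnorm(H * W * 3, spec$background_level, spec$background_noise_sd),
                 c(H, W, 3))
    img <- round(.clip8(img))
    for (i in seq_len(n)) {
      r <- rendered[[i]]
      rr <- anchors[i, "row"] + seq_len(nrow(r$mask)) - 1
      cc <- anchors[i, "col"] + seq_len(ncol(r$mask)) - 1
      fg <- r$mask > 0
      for (ch in 1:3) {
        plane <- img[rr, cc, ch]
        plane[fg] <- r$patch[, , ch][fg]
        img[rr, cc, ch] <- plane
      }
    }
    img
  })

  entries <- lapply(seq_len(n), function(i) {
    r <- rendered[[i]]
    ctr <- r$truth$centers
    if (length(ctr)) {
      ctr[, "row"] <- ctr[, "row"] + anchors[i, "row"] - 1
      ctr[, "col"] <- ctr[, "col"] + anchors[i, "col"] - 1
    }
    ar <- unname(anchors[i, "row"]); ac <- unname(anchors[i, "col"])
    list(arc_length = r$truth$arc_length, spikelet_count = r$truth$spikelet_count,
         centers = ctr, anchor = c(row = ar, col = ac),
         bbox = c(r0 = ar, r1 = ar + nrow(r$mask) - 1,
                  c0 = ac, c1 = ac + ncol(r$mask) - 1),
         footprint = r$mask)
  })
  if (n > 0) entries <- entries[order(vapply(entries, function(e) e$bbox["c0"], 0))]
  list(image = image, truth = list(n_spikes = n, spikes = entries))
}

#' Write a rendered scene to disk
#'
#' Writes the RGB scene as 8-bit PNG, per-spike footprint masks as 0/255 PNG,
#' and the ground truth as JSON
#' (`{"n_spikes", "spikes": [{"arc_length", "spikelet_count", "centers"}]}`).
#'
#' @param scene result of [render_scene()].
#' @param dir output directory (created if missing).
#' @param name basename for the output files.
#' @return invisibly, the path of the scene PNG.
#' @export
write_scene <- function(scene, dir, name = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img_path <- file.path(dir, paste0(name, ".png"))
  png::writePNG(scene$image / 255, img_path)
  for (i in seq_along(scene$truth$spikes)) {
    e <- scene$truth$spikes[[i]]
    png::writePNG((e$footprint > 0) * 1.0, file.path(dir, sprintf("%s_mask_%02d.png", name, i)))
  }
  truth <- list(
    n_spikes = scene$truth$n_spikes,
    spikes = lapply(scene$truth$spikes, function(e) {
      list(arc_length = e$arc_length, spikelet_count = e$spikelet_count,
           centers = unname(apply(e$centers, 1, function(p) c(p["row"], p["col"]),
                                  simplify = FALSE)))
    })
  )
  jsonlite::write_json(truth, file.path(dir, paste0(name, "_truth.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(img_path)
}

#' Colour recipes for separability experiments
#'
#' Three spike colour recipes with near-identical mean colour but different
#' pixel-distribution signatures (within-spike jitter, rachis/spikelet tone
#' contrast). Per-spike base colours are drawn around each recipe mean so that
#' plain mean-RGB summaries overlap across recipes while distributional
#' descriptors still separate them.
#'
#' @return named list of three recipes, each with `base_color`, `between_sd`
#'   (per-spike SD of the base colour), `jitter` (within-spike pixel SD) and
#'   `rachis_contrast` (multiplier giving the rachis tone).
#' @export
spike_color_recipes <- function() {
  list(
    green_crisp = list(base_color = c(100, 133, 60), between_sd = 10, jitter = 5,
                       rachis_contrast = 0.85),
    green_mottled = list(base_color = c(104, 130, 64), between_sd = 10, jitter = 20,
                         rachis_contrast = 0.85),
    green_palerachis = list(base_color = c(97, 135, 58), between_sd = 10, jitter = 5,
                            rachis_contrast = 1.35)
  )
}

#' Draw a spike spec from a colour recipe
#'
#' @param recipe one element of [spike_color_recipes()].
#' @param seed integer seed for the per-spike base colour draw.
#' @param ... further arguments passed to [spike_spec()] (geometry).
#' @return a [spike_spec()].
#' @export
sample_recipe_spike <- function(recipe, seed, ...) {
  base <- with_seed(seed, .clip8(stats::rnorm(3, recipe$base_color, recipe$between_sd)))
  spike_spec(base_color = base,
             rachis_color = .clip8(base * recipe$rachis_contrast),
             color_jitter = recipe$jitter, ...)
}

#' Appressed (dense-spikelet) spike morphotype
#'
#' Convenience [spike_spec()] wrapper for the band-like morph in which many
#' small spikelets lie appressed against a broad rachis, giving a smooth
#' serrated silhouette. This is the morph suited to centerline length
#' estimation; the [spike_spec()] default describes the spreading morph with
#' large distinct spikelets suited to spikelet counting.
#'
#' @param arc_length centerline arc length in px.
#' @param curvature signed curvature in 1/px.
#' @param ... overrides passed on to [spike_spec()].
#' @return a [spike_spec()].
#' @export
appressed_spike_spec <- function(arc_length = 500, curvature = 0, ...) {
  args <- list(arc_length = arc_length, curvature = curvature,
               rachis_width = 21, n_spikelets = floor(arc_length / 30) - 1,
               spikelet_spacing = 30, spikelet_axes = c(18, 12),
               attach_angle = 35, lateral_offset = 0.75, taper = 0.35)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(spike_spec, args)
}
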