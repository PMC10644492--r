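## Spike segmentation: separate spikes from the dark scanner background by a
## manual channel threshold or a scaled Otsu threshold, enumerate them and cut
## out per-spike crops in RGB, HSV and CIELAB.

#' Segmentation parameters
#'
#' @param method `"channel_thresh"` (manual threshold on one RGB channel) or
#'   `"otsu_scaled"` (automatic Otsu threshold on the grayscale image, scaled
#'   by `otsu_factor`; scaling is needed because on dark backgrounds plain Otsu
#'   is too stringent).
#' @param channel channel for the manual method: `"R"`, `"G"` or `"B"`.
#' @param threshold 8-bit threshold for the manual method; foreground is
#'   strictly greater. Default 20, the optimum on the red channel reported for
#'   600-dpi scans on black velvet.
#' @param otsu_factor scaling factor on (0, 1] for the Otsu threshold; the
#'   default 0.29 is the reported optimum.
#' @param rescale_rgb optional image down-scaling factor on (0, 1] applied
#'   before thresholding to cut processing time.
#' @param min_area minimum component area in px at full resolution (debris
#'   filter); scaled by `rescale_rgb^2` when the image is rescaled.
#' @param pad_px padding added around each spike crop.
#' @return object of class `"segmentation_params"`.
#' @export
segmentation_params <- function(method = c("channel_thresh", "otsu_scaled"),
                                channel = "R", threshold = 20, otsu_factor = 0.29,
                                rescale_rgb = 1, min_area = 2000, pad_px = 10) {
  method <- match.arg(method)
  if (threshold < 0 || threshold > 255) stop("threshold must be on 0..255", call. = FALSE)
  if (otsu_factor <= 0 || otsu_factor > 1) stop("otsu_factor must be on (0, 1]", call. = FALSE)
  if (rescale_rgb <= 0 || rescale_rgb > 1) stop("rescale_rgb must be on (0, 1]", call. = FALSE)
  structure(list(method = method, channel = channel, threshold = threshold,
                 otsu_factor = otsu_factor, rescale_rgb = rescale_rgb,
                 min_area = min_area, pad_px = pad_px),
            class = "segmentation_params")
}

#' Convert an RGB raster to 8-bit luminance gray
#'
#' Uses the Rec. 601 luma weights `0.299 R + 0.587 G + 0.114 B`, rounded to
#' integers.
#'
#' @param image RGB array \[rows, cols, 3\] on 0..255.
#' @return integer-valued gray matrix on 0..255.
#' @export
to_gray <- function(image) {
  .check_rgb(image)
  g <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  round(g)
}

#' Threshold one RGB channel
#'
#' Foreground if the channel value is strictly greater than `t`.
#'
#' @param image RGB array on 0..255.
#' @param channel `"R"`, `"G"` or `"B"`.
#' @param t threshold on 0..255.
#' @return 0/1 mask matrix.
#' @export
channel_threshold_mask <- function(image, channel = "R", t = 20) {
  .check_rgb(image)
  if (t < 0 || t > 255) stop("t must be on 0..255", call. = FALSE)
  ch <- match(toupper(channel), c("R", "G", "B"))
  if (is.na(ch)) stop("channel must be one of R, G, B", call. = FALSE)
  (image[, , ch] > t) * 1L
}

#' Otsu threshold of a gray raster
#'
#' Picks the 8-bit threshold maximizing the between-class variance of the
#' gray-level histogram; foreground is defined by strict `gray > t`. When the
#' maximum is attained on a plateau (histograms with an empty gap between
#' modes), the rounded midpoint of the maximizing set is returned. A constant
#' image has no separable classes: its value is returned with a warning.
#'
#' @param gray numeric matrix on 0..255.
#' @return scalar threshold on 0..255.
#' @export
otsu_threshold <- function(gray) {
  if (length(gray) == 0) stop("empty gray raster", call. = FALSE)
  v <- as.integer(round(gray))
  if (min(v) == max(v)) {
    warning("constant image: no separable classes; returning the constant value")
    return(min(v))
  }
  h <- tabulate(v + 1L, nbins = 256L)
  p <- h / sum(h)
  levels <- 0:255
  omega <- cumsum(p)                  # P(gray <= t)
  mu <- cumsum(p * levels)            # partial mean
  mu_t <- mu[256]
  ## between-class variance for split at threshold t = levels
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- -Inf
  best <- levels[sb >= max(sb) - 1e-9]
  round(mean(best))
}

#' Scaled Otsu foreground mask
#'
#' `mask = gray > f * otsu_threshold(gray)`; `f = 1` reproduces the plain Otsu
#' segmentation.
#'
#' @param image RGB array on 0..255.
#' @param f scaling factor on (0, 1]; default 0.29.
#' @return 0/1 mask matrix.
#' @export
scaled_otsu_mask <- function(image, f = 0.29) {
  if (f <= 0 || f > 1) stop("f must be on (0, 1]", call. = FALSE)
  g <- to_gray(image)
  (g > f * otsu_threshold(g)) * 1L
}

#' Rescale an RGB image
#'
#' Bilinear interpolation; output dimensions are `round(factor * dims)`.
#' `factor = 1` returns the input unchanged.
#'
#' @param image RGB array on 0..255.
#' @param factor scaling factor on (0, 1].
#' @return RGB array.
#' @export
rescale_image <- function(image, factor) {
  .check_rgb(image)
  if (factor <= 0 || factor > 1) stop("factor must be on (0, 1]", call. = FALSE)
  if (factor == 1) return(image)
  h <- round(dim(image)[1] * factor)
  w <- round(dim(image)[2] * factor)
  if (h < 1 || w < 1) stop("rescaled dimension below 1 px", call. = FALSE)
  out <- array(0, c(h, w, 3))
  for (ch in 1:3) {
    out[, , ch] <- .clip8(.unebi(EBImage::resize(.ebi(image[, , ch]), w = w, h = h,
                                                 filter = "bilinear")))
  }
  out
}

#' Label spikes in a foreground mask
#'
#' 8-connected components with area >= `min_area`, renumbered 1..k left to
#' right (bounding-box left edge, ties broken by top edge), matching spikes
#' laid side by side on a scanner bed.
#'
#' @param mask 0/1 matrix.
#' @param min_area minimum component area in px.
#' @return object of class `"labeled_scene"`: list with `labels` (label
#'   raster), `k` (spike count), `bboxes` and `centroids`.
#' @export
label_spikes <- function(mask, min_area = 2000) {
  .check_mask(mask)
  lab <- .label8(mask)
  k0 <- max(lab)
  if (k0 == 0) {
    return(structure(list(labels = lab, k = 0L, bboxes = list(), centroids = NULL),
                     class = "labeled_scene"))
  }
  areas <- tabulate(lab[lab > 0], nbins = k0)
  keep <- which(areas >= min_area)
  if (length(keep) == 0) {
    return(structure(list(labels = matrix(0L, nrow(mask), ncol(mask)), k = 0L,
                          bboxes = list(), centroids = NULL),
                     class = "labeled_scene"))
  }
  info <- lapply(keep, function(l) .bbox(lab == l))
  ord <- order(vapply(info, `[[`, 0, "c0"), vapply(info, `[[`, 0, "r0"))
  keep <- keep[ord]; info <- info[ord]
  out <- matrix(0L, nrow(mask), ncol(mask))
  centroids <- matrix(0, length(keep), 2, dimnames = list(NULL, c("row", "col")))
  for (i in seq_along(keep)) {
    sel <- lab == keep[i]
    out[sel] <- i
    idx <- which(sel, arr.ind = TRUE)
    centroids[i, ] <- c(mean(idx[, 1]), mean(idx[, 2]))
  }
  structure(list(labels = out, k = length(keep), bboxes = info, centroids = centroids),
            class = "labeled_scene")
}

#' Extract one spike as a padded multi-space crop
#'
#' Background pixels are zeroed, the crop is padded by `pad_px` on all sides
#' (padding eases the later morphological operations), and the crop is
#' returned in RGB, HSV and CIELAB (D65) alongside the binary mask.
#' Channel scales: H in \[0, 360) degrees, S and V on 0..255, L* on
#' \[0, 100\], a*/b* signed.
#'
#' @param image RGB array the scene was labelled on.
#' @param scene a [label_spikes()] result.
#' @param label spike label on 1..k.
#' @param pad_px padding in px.
#' @return object of class `"spike_record"`: list with `label`, `mask`,
#'   `rgb`, `hsv`, `lab`, `bbox`, `area`, `pad_px`.
#' @export
extract_spike <- function(image, scene, label, pad_px = 10) {
  .check_rgb(image)
  stopifnot(inherits(scene, "labeled_scene"))
  if (!(label %in% seq_len(scene$k))) stop("unknown spike label", call. = FALSE)
  sel <- scene$labels == label
  bb <- .bbox(sel)
  h <- bb$r1 - bb$r0 + 1; w <- bb$c1 - bb$c0 + 1
  mask <- matrix(0L, h + 2 * pad_px, w + 2 * pad_px)
  rgbc <- array(0, c(h + 2 * pad_px, w + 2 * pad_px, 3))
  rr <- pad_px + seq_len(h); cc <- pad_px + seq_len(w)
  sub <- sel[bb$r0:bb$r1, bb$c0:bb$c1]
  mask[rr, cc] <- sub * 1L
  for (ch in 1:3) {
    plane <- image[bb$r0:bb$r1, bb$c0:bb$c1, ch]
    plane[!sub] <- 0
    rgbc[rr, cc, ch] <- plane
  }
  structure(list(label = label, mask = mask, rgb = rgbc,
                 hsv = .rgb_array_to_hsv(rgbc), lab = .rgb_array_to_lab(rgbc),
                 bbox = bb, area = sum(mask), pad_px = pad_px),
            class = "spike_record")
}

#' Count RMSE between predicted and observed per-image counts
#'
#' `rmse = sqrt(mean((p - o)^2))`; the spread statistic is the standard
#' deviation of the absolute per-image count error.
#'
#' @param predicted,observed equal-length numeric vectors of counts.
#' @return named numeric: `rmse`, `sd`.
#' @export
count_rmse <- function(predicted, observed) {
  if (length(predicted) == 0 || length(predicted) != length(observed)) {
    stop("predicted and observed must be non-empty and of equal length", call. = FALSE)
  }
  err <- predicted - observed
  c(rmse = sqrt(mean(err^2)),
    sd = if (length(err) > 1) stats::sd(abs(err)) else 0)
}

#' Segment a scene into spikes
#'
#' Convenience composition: optional rescale, threshold (manual channel or
#' scaled Otsu), label, and extract per-spike crops.
#'
#' @param image RGB array on 0..255.
#' @param params a [segmentation_params()].
#' @param extract if `FALSE`, skip the per-spike crop extraction (counting
#'   only); `spikes` is then an empty list.
#' @return list with `scene` (a `labeled_scene`), `spikes` (list of
#'   `spike_record`), `mask` and the possibly rescaled `image`.
#' @export
spike_segm <- function(image, params = segmentation_params(), extract = TRUE) {
  if (params$rescale_rgb < 1) image <- rescale_image(image, params$rescale_rgb)
  mask <- switch(params$method,
                 channel_thresh = channel_threshold_mask(image, params$channel, params$threshold),
                 otsu_scaled = scaled_otsu_mask(image, params$otsu_factor))
  min_area <- params$min_area * params$rescale_rgb^2
  scene <- label_spikes(mask, min_area = min_area)
  spikes <- if (extract) {
    lapply(seq_len(scene$k), function(l) extract_spike(image, scene, l, params$pad_px))
  } else list()
  list(scene = scene, spikes = spikes, mask = mask, image = image)
}
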