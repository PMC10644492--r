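## Colour descriptors: distributional statistics of the foreground pixel
## values across nine channels in three colour spaces (R, G, B, H, S, V,
## L*, a*, b*), including scale-free spread measures (CV, QCV) and sign-split
## statistics for a* and b*.
##
## The canonical record has exactly 77 fields: 7 channels (R, G, B, H, S, V,
## L*) x {min, max, mean, sd, p5, p25, p50, p75, p95} plus a*, b* x
## {mean, sd, p5, p25, p50, p75, p95}. CV/QCV and the a*/b* sign splits live
## in the extended block.

.channel_names <- c("R", "G", "B", "H", "S", "V", "L", "aStar", "bStar")

#' Per-channel foreground pixel values of a spike
#'
#' Values are taken at foreground-mask pixels only, on the package channel
#' scales (H in degrees \[0, 360), S/V on 0..255, L* on \[0, 100\], a*/b*
#' signed).
#'
#' @param record a `spike_record` from [extract_spike()], or any list with
#'   `rgb` (array 0..255) and `mask`.
#' @return named list of nine numeric vectors
#'   (`R, G, B, H, S, V, L, aStar, bStar`), one value per foreground pixel.
#' @export
channel_values <- function(record) {
  mask <- record$mask
  fg <- which(mask > 0)
  if (length(fg) == 0) stop("empty foreground", call. = FALSE)
  rgbm <- cbind(record$rgb[, , 1][fg], record$rgb[, , 2][fg], record$rgb[, , 3][fg])
  hsv <- if (!is.null(record$hsv)) {
    cbind(record$hsv[, , 1][fg], record$hsv[, , 2][fg], record$hsv[, , 3][fg])
  } else .rgb_to_hsv(rgbm)
  lab <- if (!is.null(record$lab)) {
    cbind(record$lab[, , 1][fg], record$lab[, , 2][fg], record$lab[, , 3][fg])
  } else .rgb_to_lab(rgbm)
  out <- list(R = rgbm[, 1], G = rgbm[, 2], B = rgbm[, 3],
              H = hsv[, 1], S = hsv[, 2], V = hsv[, 3],
              L = lab[, 1], aStar = lab[, 2], bStar = lab[, 3])
  out
}

#' Distributional statistics of a value vector
#'
#' Returns min, max, mean, population standard deviation, percentiles
#' 5/25/50/75/95 (linear interpolation between order statistics),
#' `cv = sd / mean` and `qcv = (p75 - p25) / (p75 + p25)` (the quartile
#' coefficient of dispersion). `cv` is `NA` when the mean is zero, `qcv` when
#' `p75 + p25` is zero.
#'
#' @param values non-empty numeric vector.
#' @return named numeric vector
#'   `min, max, mean, sd, p5, p25, p50, p75, p95, cv, qcv`.
#' @export
channel_stats <- function(values) {
  if (length(values) == 0) stop("empty value vector", call. = FALSE)
  q <- unname(stats::quantile(values, c(0.05, 0.25, 0.5, 0.75, 0.95), type = 7, names = FALSE))
  m <- mean(values)
  s <- sqrt(mean((values - m)^2))  # population sd
  cv <- if (abs(m) < 1e-12) NA_real_ else s / m
  qcv <- if (abs(q[2] + q[4]) < 1e-12) NA_real_ else (q[4] - q[2]) / (q[4] + q[2])
  c(min = min(values), max = max(values), mean = m, sd = s,
    p5 = q[1], p25 = q[2], p50 = q[3], p75 = q[4], p95 = q[5],
    cv = cv, qcv = qcv)
}

#' Sign-split statistics for a* and b*
#'
#' The full statistic battery over the strictly negative and strictly
#' positive subsets of the a* and b* vectors, plus the fraction of pixels in
#' each subset. An empty subset yields all-`NA` statistics and fraction 0.
#'
#' @param a_values,b_values a* and b* pixel vectors.
#' @return named list `aStarNeg`, `aStarPos`, `bStarNeg`, `bStarPos`; each is
#'   the [channel_stats()] vector with an extra `frac` element.
#' @export
sign_split_stats <- function(a_values, b_values) {
  one <- function(v, total) {
    if (length(v) == 0) {
      out <- rep(NA_real_, 11)
      names(out) <- c("min", "max", "mean", "sd", "p5", "p25", "p50", "p75", "p95", "cv", "qcv")
      return(c(out, frac = 0))
    }
    c(channel_stats(v), frac = length(v) / total)
  }
  list(aStarNeg = one(a_values[a_values < 0], length(a_values)),
       aStarPos = one(a_values[a_values > 0], length(a_values)),
       bStarNeg = one(b_values[b_values < 0], length(b_values)),
       bStarPos = one(b_values[b_values > 0], length(b_values)))
}

#' Colour descriptor record for one spike
#'
#' Canonical mode emits exactly the 77-descriptor record
#' (`<channel>_<stat>` names, e.g. `aStar_p75`); extended mode appends
#' per-channel `cv`/`qcv` and the a*/b* sign-split batteries.
#'
#' @param record a `spike_record`, or a precomputed [channel_values()] list.
#' @param extended append the extended block (default `FALSE`).
#' @return named numeric vector; 77 elements in canonical mode.
#' @export
channel_percentiles <- function(record, extended = FALSE) {
  vals <- if (is.list(record) && all(.channel_names %in% names(record))) record
          else channel_values(record)
  stats_all <- lapply(vals, channel_stats)
  full_stats <- c("min", "max", "mean", "sd", "p5", "p25", "p50", "p75", "p95")
  ab_stats <- c("mean", "sd", "p5", "p25", "p50", "p75", "p95")
  out <- numeric(0)
  for (ch in c("R", "G", "B", "H", "S", "V", "L")) {
    s <- stats_all[[ch]][full_stats]
    names(s) <- paste0(ch, "_", full_stats)
    out <- c(out, s)
  }
  for (ch in c("aStar", "bStar")) {
    s <- stats_all[[ch]][ab_stats]
    names(s) <- paste0(ch, "_", ab_stats)
    out <- c(out, s)
  }
  if (extended) {
    for (ch in .channel_names) {
      s <- stats_all[[ch]][c("cv", "qcv")]
      names(s) <- paste0(ch, "_", c("cv", "qcv"))
      out <- c(out, s)
    }
    ss <- sign_split_stats(vals$aStar, vals$bStar)
    for (nm in names(ss)) {
      s <- ss[[nm]]
      names(s) <- paste0(nm, "_", names(s))
      out <- c(out, s)
    }
  }
  out
}
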