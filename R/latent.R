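## Latent-trait utilities: standardized principal-component projection,
## mean pairwise Euclidean-distance separability, and the feature
## preprocessing used before model fitting (near-zero variance, correlation
## and curvature-outlier filtering, centering and scaling).

#' Project a descriptor table onto standardized principal components
#'
#' Columns are centered and scaled, the top-k principal-component scores are
#' computed and each score column is min-max standardized to \[0, 1\].
#' Component signs are fixed (largest-magnitude loading positive) so the
#' projection is invariant to column order.
#'
#' @param table numeric data.frame or matrix, rows = spikes.
#' @param k number of components (default 2).
#' @return list with `scores` (n x k matrix on \[0, 1\]) and
#'   `variance_explained` (fractions).
#' @export
pca_project <- function(table, k = 2) {
  x <- as.matrix(table)
  if (nrow(x) < 2 || ncol(x) < k) stop("need >= 2 rows and >= k columns", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (all(sds < 1e-12)) stop("degenerate table: all columns constant", call. = FALSE)
  x <- x[, sds > 1e-12, drop = FALSE]
  if (ncol(x) < k) stop("fewer than k non-constant columns", call. = FALSE)
  p <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  k <- min(k, ncol(p$x))
  scores <- p$x[, seq_len(k), drop = FALSE]
  ## deterministic sign: largest-|loading| entry of each rotation column positive
  for (j in seq_len(k)) {
    l <- p$rotation[, j]
    if (l[which.max(abs(l))] < 0) scores[, j] <- -scores[, j]
  }
  rng <- apply(scores, 2, range)
  for (j in seq_len(k)) {
    span <- rng[2, j] - rng[1, j]
    scores[, j] <- if (span < 1e-12) 0 else (scores[, j] - rng[1, j]) / span
  }
  ve <- p$sdev^2 / sum(p$sdev^2)
  list(scores = scores, variance_explained = ve[seq_len(k)])
}

#' Mean pairwise Euclidean distance
#'
#' Mean and standard deviation of all pairwise Euclidean distances over the
#' selected rows; used to quantify how well a projection separates spikes.
#'
#' @param scores numeric matrix, rows = spikes.
#' @param subset optional row indices (or logical vector).
#' @return named numeric: `mean`, `sd`.
#' @export
mean_pairwise_ed <- function(scores, subset = NULL) {
  x <- as.matrix(scores)
  if (!is.null(subset)) x <- x[subset, , drop = FALSE]
  if (nrow(x) < 2) stop("need >= 2 rows", call. = FALSE)
  d <- as.vector(stats::dist(x))
  c(mean = mean(d), sd = if (length(d) > 1) stats::sd(d) else 0)
}

#' Filter, center and scale a descriptor table
#'
#' Applies the preprocessing used before model fitting: rows whose curvature
#' exceeds `mean + 5.5 * sd` of the curvature column are dropped; columns with
#' near-zero variance (fewer than 2 distinct values, or variance below 1e-8
#' after unit scaling) are dropped; of each column pair with
#' `|Pearson r| > 0.85` the member with the larger mean absolute correlation
#' is dropped (greedy, via `caret::findCorrelation`); the survivors are
#' centered to mean 0 and scaled to SD 1. Idempotent.
#'
#' @param table numeric data.frame, rows = spikes.
#' @param curvature optional name of the curvature column, or a numeric
#'   vector (one value per row). The curvature column itself is kept out of
#'   the returned descriptor matrix.
#' @param cor_cutoff correlation threshold (default 0.85).
#' @param sd_cutoff curvature outlier threshold in SDs (default 5.5).
#' @return list with `table` (filtered, standardized data.frame), `removed`
#'   (list: `rows`, `near_zero_var`, `correlated`).
#' @export
feature_filter <- function(table, curvature = NULL, cor_cutoff = 0.85, sd_cutoff = 5.5) {
  x <- as.data.frame(table)
  removed_rows <- integer(0)
  curv_col <- NULL
  if (!is.null(curvature)) {
    if (is.character(curvature)) {
      curv_col <- curvature
      cv <- x[[curvature]]
      if (is.null(cv)) stop("curvature column not found", call. = FALSE)
    } else {
      cv <- curvature
      if (length(cv) != nrow(x)) stop("curvature vector length mismatch", call. = FALSE)
    }
    thr <- mean(cv) + sd_cutoff * stats::sd(cv)
    removed_rows <- which(cv > thr)
    if (length(removed_rows)) x <- x[-removed_rows, , drop = FALSE]
    if (!is.null(curv_col)) x <- x[, setdiff(names(x), curv_col), drop = FALSE]
  }
  ## near-zero variance columns
  nzv <- vapply(x, function(col) {
    if (length(unique(col)) < 2) return(TRUE)
    s <- stats::sd(col)
    m <- mean(abs(col))
    (s / max(m, 1))^2 < 1e-8 || s^2 < 1e-8
  }, TRUE)
  nzv_names <- names(x)[nzv]
  x <- x[, !nzv, drop = FALSE]
  if (ncol(x) == 0) stop("degenerate: all columns removed", call. = FALSE)
  cor_names <- character(0)
  if (ncol(x) > 1) {
    cm <- stats::cor(as.matrix(x))
    drop_idx <- caret::findCorrelation(cm, cutoff = cor_cutoff, exact = TRUE)
    cor_names <- names(x)[drop_idx]
    if (length(drop_idx)) x <- x[, -drop_idx, drop = FALSE]
  }
  if (ncol(x) == 0) stop("degenerate: all columns removed", call. = FALSE)
  x <- as.data.frame(scale(as.matrix(x)))
  list(table = x,
       removed = list(rows = removed_rows, near_zero_var = nzv_names,
                      correlated = cor_names))
}

#' Curvature index of a spike
#'
#' Proxy used for outlier flagging: medial-axis path length divided by the
#' moment-ellipse length, minus 1. Zero for a straight spike, growing with
#' curvature.
#'
#' @param mask 0/1 spike mask.
#' @param ... passed to [spk_length()].
#' @return scalar curvature index.
#' @export
curvature_index <- function(mask, ...) {
  r <- spk_length(mask, methods = c("ellipse", "medial_axis"), ...)
  r$length_px[r$method == "medial_axis"] / r$length_px[r$method == "ellipse"] - 1
}
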