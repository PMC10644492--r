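test_that("moment-ellipse length matches closed forms", {
  ## uniform rectangle: major axis = 2 * L / sqrt(3)
  r <- length_ellipse(rect_mask(300, 10))
  expect_lt(abs(r$length_px - 2 * 300 / sqrt(3)), 0.02 * 346.4)
  expect_equal(r$method, "ellipse")
  expect_gte(r$time_s, 0)

  ## disk: major ~ minor ~ 2r
  d <- length_ellipse(disk_mask(50))
  expect_lt(abs(d$length_px - 100) / 100, 0.03)

  ## single pixel: degenerate moments
  one <- matrix(0L, 5, 5); one[3, 3] <- 1L
  expect_equal(length_ellipse(one)$length_px, 0)
  expect_error(length_ellipse(matrix(0L, 5, 5)), "empty")
})

test_that("convex-hull length equals the ellipse rule on the filled hull", {
  m <- rect_mask(200, 40)
  expect_lt(abs(length_convex_hull(m)$length_px - length_ellipse(m)$length_px), 1)
  expect_lt(abs(length_convex_hull(disk_mask(40))$length_px - 80) / 80, 0.03)

  ## C-shaped band: the hull fills the cavity; check against direct moments of
  ## the rasterized hull
  arc <- render_spike(spike_spec(arc_length = 450, curvature = pi / 450,
                                 n_spikelets = 0, rachis_width = 25), seed = 1)
  hm <- spikescan:::.convex_hull_mask(arc$mask)
  me <- spikescan:::.moment_ellipse(which(hm > 0, arr.ind = TRUE))
  expect_equal(length_convex_hull(arc$mask)$length_px, 2 * me$a)
  expect_gt(sum(hm), sum(arc$mask))
})

test_that("thinning produces 1-px skeletons and is idempotent on lines", {
  line <- matrix(0L, 20, 120); line[10, 10:110] <- 1L
  for (m in c("skeleton", "medial_axis")) {
    sk <- thin_mask(line, m, blur_sigma = 0)
    expect_identical(sk, line)
  }
  rectsk <- thin_mask(rect_mask(300, 10), "skeleton")
  len <- skeleton_path_length(rectsk, prune_px = 0)
  expect_lt(abs(len - 295) / 295, 0.05)
  ## a disk collapses to a small central cluster under parallel thinning;
  ## the digital medial axis keeps ridge arms to the octagonal corners, so it
  ## is bounded by the diameter instead
  dsk <- thin_mask(disk_mask(30), "skeleton")
  expect_lt(skeleton_path_length(dsk, prune_px = 0), 12)
  dma <- thin_mask(disk_mask(30), "medial_axis")
  expect_lt(skeleton_path_length(dma, prune_px = 0), 2 * 30 + 10)
  expect_error(thin_mask(matrix(0L, 5, 5), "skeleton"), "empty")
})

test_that("skeleton path length uses 1/sqrt(2) step weights", {
  horiz <- matrix(0L, 5, 110); horiz[3, 6:105] <- 1L
  expect_equal(skeleton_path_length(horiz, prune_px = 0), 99)
  diag_ <- matrix(0L, 110, 110); diag_[cbind(6:105, 6:105)] <- 1L
  expect_equal(skeleton_path_length(diag_, prune_px = 0), 99 * sqrt(2))
  expect_error(skeleton_path_length(matrix(0L, 3, 3)), "empty")
})

test_that("longest geodesic matches a brute-force all-pairs oracle on a Y", {
  y <- matrix(0L, 40, 40)
  y[cbind(5:20, 20)] <- 1L           # stem
  y[cbind(21:32, 21:32)] <- 1L       # arm 1 (diagonal)
  y[cbind(21:30, 19:10)] <- 1L       # arm 2 (anti-diagonal)
  expect_equal(skeleton_path_length(y, prune_px = 0), path_length_oracle(y))
})

test_that("spurs shorter than prune_px are removed before measuring", {
  m <- matrix(0L, 30, 120)
  m[15, 10:110] <- 1L
  m[cbind(10:14, 60)] <- 1L   # 5-px spur off the middle
  expect_equal(skeleton_path_length(m, prune_px = 8), 100)
  ## with pruning off, the path may route through the spur but never shrinks
  expect_gte(skeleton_path_length(m, prune_px = 0), 100)
})

test_that("spk_length dispatches methods and validates names", {
  expect_equal(nrow(spk_length(disk_mask(10), methods = character(0))), 0)
  expect_error(spk_length(disk_mask(10), methods = "banana"), "unknown")
  r <- spk_length(rect_mask(100, 12), methods = c("ellipse", "skeleton"), overlay = TRUE)
  expect_equal(r$method, c("ellipse", "skeleton"))
  ov <- attr(r, "overlays")$skeleton
  expect_true(any(ov == 2) && any(ov == 1))
  expect_true(all(r$time_s >= 0))
})

test_that("all four estimators recover a straight appressed spike within 5%", {
  r <- render_spike(appressed_spike_spec(400), seed = 5)
  res <- spk_length(r$mask)
  expect_true(all(abs(res$length_px - 400) / 400 < 0.05))
})

test_that("thinning estimators beat chord-based ones on a semicircular spike", {
  L <- 628
  r <- render_spike(appressed_spike_spec(L, curvature = pi / L), seed = 6)
  res <- spk_length(r$mask)
  err <- abs(res$length_px - L) / L
  names(err) <- res$method
  expect_lt(err[["skeleton"]], 0.05)
  expect_lt(err[["medial_axis"]], 0.05)
  expect_gt(err[["ellipse"]], max(err[c("skeleton", "medial_axis")]))
  expect_gt(err[["convex_hull"]], max(err[c("skeleton", "medial_axis")]))
  ## chord-based estimates undershoot the arc
  expect_lt(res$length_px[res$method == "ellipse"], res$length_px[res$method == "skeleton"])
})

test_that("length estimates are stable under 90-degree rotation and rescaling", {
  r <- render_spike(appressed_spike_spec(350), seed = 8)
  m <- r$mask
  rot <- t(m)[ncol(m):1, ]   # 90-degree rotation
  l0 <- spk_length(m)
  l90 <- spk_length(rot)
  expect_true(all(abs(l90$length_px - l0$length_px) / l0$length_px < 0.02))

  ## scale the mask down by 0.8: estimates scale within 2%
  s <- 0.8
  small <- (spikescan:::.unebi(EBImage::resize(spikescan:::.ebi(m),
            w = round(ncol(m) * s), h = round(nrow(m) * s), filter = "bilinear")) > 0.5) * 1L
  ls <- spk_length(small, methods = c("ellipse", "convex_hull", "skeleton"))
  for (mm in c("ellipse", "convex_hull")) {
    expect_lt(abs(ls$length_px[ls$method == mm] / (s * l0$length_px[l0$method == mm]) - 1),
              0.02)
  }
  ## thinning re-digitizes the serrated boundary at the coarser scale, so its
  ## equivariance is looser
  expect_lt(abs(ls$length_px[ls$method == "skeleton"] /
                (s * l0$length_px[l0$method == "skeleton"]) - 1), 0.05)
})
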