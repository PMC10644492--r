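test_that("morphological cleaning retreats the boundary but keeps the body", {
  m <- rect_mask(200, 120)
  cl <- preprocess_mask(m)
  expect_gt(sum(cl), 0)
  expect_true(all(dim(cl) == dim(m)))
  ## output within a one-upscale-cell dilation of the input
  grown <- spikescan:::.unebi(EBImage::dilate(spikescan:::.ebi(m),
                                              EBImage::makeBrush(21, "box")))
  expect_equal(sum(cl > 0 & grown == 0), 0)
  ## boundary retreat of at most ~3 upscale cells
  inner <- rect_mask(200, 120) * 0L
  inner[10 + 31:170, 10 + 31:90] <- 1L
  expect_equal(sum(inner > 0 & cl == 0), 0)

  ## identity configuration
  p0 <- spikelet_params(morph_rescale = 1, iterations = 0)
  expect_identical(preprocess_mask(m, p0), m)

  ## masks thinner than a downscaled cell vanish
  thin <- matrix(0L, 100, 100); thin[, 48:52] <- 1L
  expect_error(preprocess_mask(thin), "degenerate")
  expect_error(preprocess_mask(matrix(0L, 10, 10)), "degenerate")
})

test_that("distance map equals a brute-force nearest-background scan", {
  d <- distance_map(disk_mask(15, dim = 41, center = c(21, 21)))
  expect_lt(abs(max(d) - 15) / 15, 0.1)
  expect_equal(max(abs(which(d == max(d), arr.ind = TRUE)[1, ] - c(21, 21))), 0)

  one <- matrix(0L, 7, 7); one[4, 4] <- 1L
  expect_equal(distance_map(one)[4, 4], 1)

  set.seed(12)
  for (i in 1:5) {
    m <- matrix(rbinom(40 * 40, 1, 0.55), 40, 40)
    expect_lt(max(abs(distance_map(m) - edt_oracle(m))), 1e-6)
  }
})

test_that("peak markers respect the minimum separation", {
  m <- matrix(0L, 60, 140)
  for (cc in c(40, 100)) {
    idx <- expand.grid(r = 1:60, c = 1:140)
    sel <- (idx$r - 30)^2 + (idx$c - cc)^2 <= 20^2
    m[cbind(idx$r[sel], idx$c[sel])] <- 1L
  }
  d <- distance_map(m)
  mk <- find_markers(d, 25)
  expect_equal(nrow(mk), 2)
  expect_lt(max(abs(mk[order(mk[, "col"]), "col"] - c(40, 100))), 2)
  expect_equal(nrow(find_markers(d, 70)), 1)
  expect_equal(nrow(find_markers(matrix(0, 10, 10), 5)), 0)
  expect_error(find_markers(d, 0.5), "min_distance")
})

test_that("marker count never increases with min_distance", {
  set.seed(3)
  for (i in 1:5) {
    m <- matrix(rbinom(60 * 60, 1, 0.7), 60, 60)
    d <- distance_map(m)
    counts <- vapply(c(2, 4, 8, 15, 25, 40), function(md) nrow(find_markers(d, md)), 0)
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("watershed split partitions the mask with one label per marker", {
  ## symmetric dumbbell
  m <- matrix(0L, 60, 120)
  idx <- expand.grid(r = 1:60, c = 1:120)
  sel <- pmin((idx$r - 30)^2 + (idx$c - 35)^2, (idx$r - 30)^2 + (idx$c - 85)^2) <= 25^2
  m[cbind(idx$r[sel], idx$c[sel])] <- 1L
  d <- distance_map(m)
  mk <- find_markers(d, 25)
  lab <- watershed_split(d, mk, m)
  expect_equal(sort(unique(lab[lab > 0])), 1:2)
  ## exact partition
  expect_identical(lab > 0, m > 0)
  ## boundary near the symmetry axis (col 60)
  b1 <- max(which(lab == lab[30, 35], arr.ind = TRUE)[, 2])
  expect_lt(abs(b1 - 60), 2.5)

  ## single marker covers everything; no markers labels nothing
  one <- mk[1, , drop = FALSE]
  lab1 <- watershed_split(d, one, m)
  expect_identical(lab1 > 0, m > 0)
  expect_equal(max(lab1), 1)
  expect_equal(max(watershed_split(d, mk[0, , drop = FALSE], m)), 0)
  expect_error(watershed_split(d, cbind(row = 1, col = 1, value = 1), m), "inside the mask")
})

test_that("ellipse fits recover orientation and area of rendered blobs", {
  for (ang in c(0, 45, 120)) {
    blob <- ellipse_blob(30, 12, ang)
    rec <- fit_spikelet_ellipses(blob)
    expect_equal(nrow(rec), 1)
    diff_ang <- min(abs(rec$angle_deg - ang), 180 - abs(rec$angle_deg - ang))
    expect_lt(diff_ang, 2)
    expect_lt(abs(rec$area_px - pi * 30 * 12) / (pi * 30 * 12), 0.03)
    expect_gte(rec$angle_deg, 0); expect_lt(rec$angle_deg, 180)
  }
  ## degenerate region flagged
  tiny <- matrix(0L, 8, 8); tiny[4, 4:6] <- 1L
  rec <- fit_spikelet_ellipses(tiny)
  expect_true(rec$degenerate)
  expect_true(is.na(rec$angle_deg))
})

test_that("spikelet segmentation counts match ground truth on synthetic spikes", {
  r <- render_spike(spike_spec(arc_length = 550, n_spikelets = 10,
                               spikelet_spacing = 50), seed = 77)
  seg <- spikelet_segm(r$mask)
  expect_equal(seg$count, 10)
  expect_equal(max(seg$labels), 10)
  expect_equal(nrow(seg$records), 10)
  ## detected centroids near the true centres (cleaning shrinks each body)
  ord <- order(seg$records$centroid_r)
  expect_lt(max(abs(seg$records$centroid_r[ord] - sort(r$truth$centers[, "row"]))), 8)

  ## rachis-only spike: cleaned away, zero spikelets with a warning
  r0 <- render_spike(spike_spec(n_spikelets = 0), seed = 1)
  expect_warning(s0 <- spikelet_segm(r0$mask), "0 spikelets")
  expect_lte(s0$count, 1)
})

test_that("the size filter removes area outliers", {
  lab <- matrix(0L, 60, 60)
  lab[10:30, 10:30] <- 1L       # 441 px
  lab[40:42, 40:42] <- 2L       # 9-px speck
  d <- distance_map((lab > 0) * 1L)
  ## emulate the records path through spikelet_segm via fit + filter bounds
  rec <- fit_spikelet_ellipses(lab)
  keep <- rec$area_px >= 50 & rec$area_px <= 5000
  expect_equal(rec$spikelet_id[!keep], 2)
})

test_that("min-distance sweep reports RMSE per distance with its minimum below the spacing", {
  masks <- lapply(1:3, function(i) {
    render_spike(spike_spec(arc_length = 450, n_spikelets = 8,
                            spikelet_spacing = 50), seed = i)$mask
  })
  truth <- rep(8, 3)
  sw <- min_distance_sweep(masks, truth, distances = c(25, 40, 90))
  expect_equal(names(sw), c("min_distance", "rmse", "sd"))
  expect_equal(sw$rmse[1], 0)
  ## a suppression radius beyond the true centre separation undercounts
  expect_gt(sw$rmse[3], 0)
  expect_error(min_distance_sweep(masks, truth, numeric(0)), "empty")
  expect_error(min_distance_sweep(list(), integer(0), 25), "non-empty")
})
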