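test_that("geometric descriptors match closed forms on canonical shapes", {
  sq <- rect_mask(100, 100)
  g <- region_geometry(sq)
  expect_equal(g$area, 10000)
  expect_equal(g$extent, 1)
  expect_gt(g$solidity, 0.98)
  expect_lte(g$solidity, 1)
  expect_lt(abs(g$feret_max - 100 * sqrt(2)) / (100 * sqrt(2)), 0.02)
  expect_lt(abs(g$feret_min - 100) / 100, 0.02)
  expect_lt(g$eccentricity, 0.1)                      # square moments isotropic
  expect_lt(abs(g$perimeter - 400) / 400, 0.02)
  expect_equal(g$equivalent_diameter, sqrt(4 * g$area / pi))

  dk <- disk_mask(50)
  gd <- region_geometry(dk)
  expect_lt(abs(gd$area - pi * 50^2) / (pi * 50^2), 0.02)
  expect_lt(abs(gd$equivalent_diameter - 100) / 100, 0.01)
  expect_gt(gd$solidity, 0.98)
  expect_lt(abs(gd$perimeter - 2 * pi * 50) / (2 * pi * 50), 0.05)

  rc <- rect_mask(200, 20)
  gr <- region_geometry(rc)
  expect_lt(abs(gr$major_axis - 2 * 200 / sqrt(3)) / (2 * 200 / sqrt(3)), 0.02)
  expect_lt(abs(gr$minor_axis - 2 * 20 / sqrt(3)) / (2 * 20 / sqrt(3)), 0.05)
  expect_true(gr$feret_min <= gr$feret_max)
  expect_true(gr$minor_axis <= gr$major_axis)

  line <- matrix(0L, 80, 80); line[cbind(5:75, 5:75)] <- 1L   # diagonal 1-px line
  gl <- region_geometry(line)
  expect_lt(gl$extent, 0.05)
  expect_lt(gl$feret_min, 1.5)
  expect_error(region_geometry(matrix(0L, 4, 4)), "empty")
})

test_that("contour extraction fills holes and is closed and positively oriented", {
  sq <- rect_mask(60, 60)
  holed <- sq; holed[30:40, 30:40] <- 0L
  ct <- extract_contour(holed)
  ct0 <- extract_contour(sq)
  expect_equal(nrow(ct), nrow(ct0))   # hole does not change the outer boundary
  ## closed chain of 8-connected steps
  dd <- sqrt(diff(c(ct[, 1], ct[1, 1]))^2 + diff(c(ct[, 2], ct[1, 2]))^2)
  expect_lte(max(dd), sqrt(2) + 1e-9)
  ## positive shoelace area (counter-clockwise in the y-down frame)
  x <- ct[, 1]; y <- ct[, 2]
  expect_gt(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y), 0)
  ## perimeter of the square contour ~ 4 s
  expect_lt(abs(sum(dd) - 240) / 240, 0.03)
  ## disk circumference
  ctd <- extract_contour(disk_mask(40))
  dd2 <- sqrt(diff(c(ctd[, 1], ctd[1, 1]))^2 + diff(c(ctd[, 2], ctd[1, 2]))^2)
  expect_lt(abs(sum(dd2) - 2 * pi * 40) / (2 * pi * 40), 0.05)
  expect_error(extract_contour(matrix(0L, 5, 5)), "degenerate")
})

test_that("EFD coefficients match the exact piecewise-linear Fourier oracle", {
  fixtures <- list(
    contour_ellipse(40, 15),
    contour_rect(60, 25),
    contour_star(),
    extract_contour(disk_mask(30)),
    extract_contour(render_spike(spike_spec(arc_length = 250, n_spikelets = 4),
                                 seed = 3)$mask)
  )
  for (ct in fixtures) {
    e <- efd_coefficients(ct, 12)
    o <- efd_oracle(ct, 12)
    expect_lt(max(abs(cbind(e$an, e$bn, e$cn, e$dn) - o)), 1e-6)
  }
})

test_that("translation moves only the locus offsets", {
  ct <- contour_star()
  e0 <- efd_coefficients(ct, 10)
  e1 <- efd_coefficients(sweep(ct, 2, c(17.3, -4.2), `+`), 10)
  expect_equal(e1$an, e0$an, tolerance = 1e-12)
  expect_equal(e1$bn, e0$bn, tolerance = 1e-12)
  expect_equal(e1$cn, e0$cn, tolerance = 1e-12)
  expect_equal(e1$dn, e0$dn, tolerance = 1e-12)
  expect_equal(e1$A0 - e0$A0, 17.3, tolerance = 1e-9)
  expect_equal(e1$C0 - e0$C0, -4.2, tolerance = 1e-9)
})

test_that("normalization removes rotation, scale and starting point", {
  ct <- contour_egg()
  th <- 37 * pi / 180; sc <- 2.3
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  ct2 <- (ct %*% t(R)) * sc
  ct2 <- ct2[c(301:720, 1:300), ]            # new starting point
  n1 <- normalize_efd(efd_coefficients(ct, 15))
  n2 <- normalize_efd(efd_coefficients(ct2, 15))
  expect_lt(max(abs(c(n1$an - n2$an, n1$bn - n2$bn, n1$cn - n2$cn, n1$dn - n2$dn))), 1e-6)
  expect_true(n1$normalized)
  expect_equal(n1$an[1], 1, tolerance = 1e-9)      # unit semi-major
  ## idempotence
  n11 <- normalize_efd(n1)
  expect_identical(n11$an, n1$an)
  ## circle: canonical unit-circle pattern, cross-checked with the oracle
  circ <- contour_ellipse(30, 30, n = 720)
  nc <- normalize_efd(efd_coefficients(circ, 8))
  oc <- efd_oracle(circ, 8)
  scale1 <- sqrt(oc[1, "a"]^2 + oc[1, "c"]^2)
  expect_equal(nc$an[1], 1, tolerance = 1e-6)
  expect_equal(abs(nc$dn[1]), unname(sqrt(oc[1, "b"]^2 + oc[1, "d"]^2) / scale1),
               tolerance = 1e-6)
  expect_lt(max(abs(c(nc$bn[1], nc$cn[1]))), 1e-6)
})

test_that("fourier power concentrates and n* behaves monotonically", {
  circ <- contour_ellipse(40, 40, n = 720)
  expect_equal(harmonics_for_power(circ, 0.9999), 1)
  p <- fourier_power(efd_coefficients(circ, 20))
  expect_gt(p$cumulative[1], 0.9999)
  ## cumulative power non-decreasing, reaching 1
  ell <- contour_ellipse(40, 30)
  pe <- fourier_power(efd_coefficients(ell, 25))
  expect_true(all(diff(pe$cumulative) >= -1e-12))
  expect_equal(pe$cumulative[25], 1)
  expect_gt(pe$cumulative[1], 0.998)     # moderate ellipse: h1 dominates
  ## a square needs more harmonics; verify n* against the oracle's powers
  sq <- contour_rect(50, 50)
  n_star <- harmonics_for_power(sq, 0.9999, max_harmonics = 60)
  o <- efd_oracle(sq, 60)
  po <- rowSums(o^2) / 2
  cf <- cumsum(po) / sum(po)
  expect_equal(n_star, min(which(cf > 0.9999)))
  ## threshold monotonicity
  expect_lte(harmonics_for_power(sq, 0.5, max_harmonics = 60), n_star)
  expect_error(harmonics_for_power(sq, 1.2), "threshold")
})

test_that("reconstruction error shrinks with harmonics and n=1 is an ellipse", {
  ct <- extract_contour(render_spike(spike_spec(arc_length = 300, n_spikelets = 5),
                                     seed = 11)$mask)
  errs <- vapply(c(1, 10, 30), function(n) reconstruction_error(ct, n, max_harmonics = 30), 0)
  expect_true(all(diff(errs) <= 0))
  ## full-order reconstruction of an analytic ellipse is near-exact
  ell <- contour_ellipse(40, 25, n = 400)
  expect_lt(reconstruction_error(ell, 20, max_harmonics = 20), 0.5)
  ## the n=1 locus is an ellipse: an algebraic conic fits its points exactly
  e <- efd_coefficients(ct, 10)
  rec1 <- reconstruct_contour(e, 1, n_points = 300)
  x <- scale(rec1[, 1], scale = FALSE); y <- scale(rec1[, 2], scale = FALSE)
  M <- cbind(x^2, x * y, y^2, x, y)
  fit <- lm.fit(M, rep(1, nrow(M)))
  expect_lt(max(abs(fit$residuals)), 1e-6)
  cf <- fit$coefficients
  expect_lt(cf[2]^2 - 4 * cf[1] * cf[3], 0)   # ellipse discriminant
  expect_error(reconstruct_contour(e, 11), "exceeds")
})

test_that("symmetric/asymmetric coefficient split partitions the power", {
  ct <- contour_star()
  e <- normalize_efd(efd_coefficients(ct, 12))
  sp <- efd_symmetry_split(e)
  expect_equal(sp$symmetric$power + sp$asymmetric$power, sp$total_power)
  p <- fourier_power(e)
  expect_equal(sp$total_power, sum(p$power))
  ## zeroed symmetric block
  e0 <- e; e0$bn[] <- 0; e0$cn[] <- 0
  expect_equal(efd_symmetry_split(e0)$symmetric$power, 0)
  ## a mirror-symmetric contour concentrates power in one block after
  ## normalization: compare with its mirrored copy
  ell <- contour_ellipse(40, 18, n = 400)
  ne <- normalize_efd(efd_coefficients(ell, 12))
  spe <- efd_symmetry_split(ne)
  mirrored <- cbind(x = ell[, 1], y = -ell[, 2])[nrow(ell):1, ]
  nm <- normalize_efd(efd_coefficients(mirrored, 12))
  spm <- efd_symmetry_split(nm)
  expect_equal(spe$asymmetric$power / spe$total_power,
               spm$asymmetric$power / spm$total_power, tolerance = 1e-6)
  expect_gt(spe$asymmetric$power, spe$symmetric$power)
})
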