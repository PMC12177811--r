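test_that("resampling yields uniform spacing with preserved endpoints", {
  s <- streamline(cbind(seq(0, 49, length.out = 7), 0, 0))
  r <- resample_streamline(s, 50)
  expect_equal(unclass(r)[, 1], 0:49, tolerance = 1e-12)
  ## arbitrary smooth curve: consecutive chord lengths equalize (up to the
  ## curvature-induced chord-vs-arc difference, far below 1% here)
  h <- helix_streamline(80)
  r2 <- resample_streamline(h, 50)
  seg <- sqrt(rowSums(diff(unclass(r2))^2))
  expect_lt(max(abs(seg - mean(seg))) / mean(seg), 0.01)
  expect_equal(unclass(r2)[1, ], unclass(h)[1, ])
  expect_equal(unclass(r2)[50, ], unclass(h)[80, ])
  ## half-circle chord bound: resampled points stay on the circle
  th <- seq(0, pi, length.out = 50)
  half <- streamline(cbind(10 * cos(th), 10 * sin(th), 0))
  rr <- unclass(resample_streamline(half, 50))
  expect_lt(max(abs(sqrt(rr[, 1]^2 + rr[, 2]^2) - 10)), 0.05)
  expect_error(resample_streamline(streamline(rbind(c(0, 0, 0), c(0, 0, 1e-300),
                                                    c(0, 0, 0)))),
               "zero-length|degenerate")
})

test_that("curvature matches analytic values and endpoint convention", {
  line <- resample_streamline(streamline(cbind(0:20, 2 * (0:20), 0)), 21)
  expect_equal(curvature_profile(line)$kappa, rep(0, 21), tolerance = 1e-10)
  circ <- resample_streamline(circle_streamline(200, r = 10), 50)
  cp <- curvature_profile(circ)
  expect_equal(cp$kappa[c(1, 50)], c(0, 0))
  expect_lt(max(abs(cp$kappa[2:49] - 0.1) / 0.1), 0.02)
  ## rigid invariance
  set.seed(6)
  tf <- rigid_transform(rot_z(37), c(4, -7, 2))
  cp2 <- curvature_profile(apply_rigid(tf, circ))
  expect_lt(max(abs(cp2$kappa - cp$kappa)), 1e-9)
  expect_error(curvature_profile(streamline(rbind(c(0, 0, 0), c(1, 0, 0),
                                                  c(2, 0, 0), c(30, 0, 0)))),
               "not uniformly resampled")
})

test_that("ROI dissection applies endpoint, waypoint and exclusion rules", {
  rois <- c(af_roi_preset("left"),
            list(roi_spec(c(-56, -9, 10), 24, "waypoint")))
  ## streamline between the AF endpoint spheres through the waypoint
  mk <- function(from, to, via) {
    a <- rbind(from, via, to)
    unclass(resample_streamline(streamline(a), 30))
  }
  good <- mk(c(-53, 27, 20), c(-60, -45, 0), c(-56, -9, 10))
  away <- mk(c(-53, 27, 20) + c(30, 0, 0), c(-60, -45, 0), c(-56, -9, 10))
  b <- bundle(list(good, good[nrow(good):1, ], away), "s", "left")
  kept <- filter_by_rois(b, rois)
  expect_equal(length(kept), 2L)  # both orientations pass, displaced fails
  ## exclusion removes
  rois_ex <- c(rois, list(roi_spec(c(-56, -9, 10), 10, "exclusion")))
  expect_error(filter_by_rois(bundle(list(good), "s", "left"), rois_ex),
               "no streamlines survive")
  ## one endpoint sphere alone is a config error
  expect_error(filter_by_rois(b, rois[1]), "two endpoint spheres")
  ## result independent of vertex order
  b_rev <- bundle(lapply(b$streamlines, function(s) s[nrow(s):1, ]), "s", "left")
  expect_equal(length(filter_by_rois(b_rev, rois)), 2L)
})

test_that("mirroring is an involution that flips hemisphere, keeps curvature", {
  spec <- cohort_spec(jitter_sd_mm = 0.5, outlier_fraction = 0,
                      streamlines_per_bundle = 10, seed = 1)
  b <- make_arc_bundle(spec, "left", seed = 7)
  m <- mirror_bundle(b)
  expect_equal(m$hemisphere, "right")
  expect_true(all(bundle_points(m)$points[, 1] > 0))
  mm <- mirror_bundle(m)
  expect_equal(mm$streamlines, b$streamlines)
  s <- resample_streamline(b$streamlines[[1]], 50)
  sm <- resample_streamline(m$streamlines[[1]], 50)
  expect_equal(curvature_profile(sm)$kappa, curvature_profile(s)$kappa,
               tolerance = 1e-9)
})

test_that("medoid representative is correct, order-invariant", {
  base <- cbind(seq(0, 30, length.out = 50), 0, 0)
  mk <- function(off) base + rep(c(0, off, 0), each = 50)
  b <- bundle(list(mk(-1), mk(0), mk(1)), "s", "left")
  rep0 <- representative_streamline(b)
  expect_equal(unclass(rep0), mk(0), ignore_attr = TRUE)
  ## brute force over the 3 candidates
  cost <- vapply(b$streamlines, function(s)
    sum(vapply(b$streamlines, function(t) mean(sqrt(rowSums((s - t)^2))), 0)),
    0)
  expect_equal(which.min(cost), 2L)
  b_perm <- bundle(b$streamlines[c(3, 1, 2)], "s", "left")
  expect_equal(unclass(representative_streamline(b_perm)),
               unclass(rep0), ignore_attr = TRUE)
  ## a bundle of identical streamlines returns that streamline
  b_id <- bundle(list(mk(0), mk(0)), "s", "left")
  expect_equal(unclass(representative_streamline(b_id)), mk(0),
               ignore_attr = TRUE)
})

test_that("ICP recovers known rigid transforms and is monotone", {
  h <- resample_streamline(helix_streamline(60), 50)
  tf0 <- rigid_transform(rot_z(20), c(5, -3, 2))
  fx <- apply_rigid(tf0, h)
  tf <- icp_align(h, fx)
  expect_lt(norm(tf$rotation - tf0$rotation, "F"), 1e-3)
  expect_lt(max(abs(tf$translation - tf0$translation)), 1e-3)
  ## identity case
  tfi <- icp_align(h, h)
  expect_lt(attr(tfi, "rmsd"), 1e-6)
  expect_lt(norm(tfi$rotation - diag(3), "F"), 1e-6)
  ## random transforms, moderate angles
  set.seed(8)
  for (rep in 1:5) {
    tfr <- rigid_transform(rot_z(runif(1, -30, 30)), rnorm(3, sd = 5))
    got <- icp_align(h, apply_rigid(tfr, h))
    expect_lt(norm(got$rotation - tfr$rotation, "F"), 1e-3)
    expect_lt(attr(got, "rmsd"), 1e-6)
  }
})

test_that("mirrored right representative aligns onto the left one", {
  spec <- cohort_spec(jitter_sd_mm = 0.5, outlier_fraction = 0,
                      streamlines_per_bundle = 60, seed = 1)
  bl <- harmonize_orientation(make_arc_bundle(spec, "left", seed = 21))
  br <- harmonize_orientation(mirror_bundle(make_arc_bundle(spec, "right",
                                                            seed = 22)))
  rl <- resample_streamline(representative_streamline(bl), 50)
  rr <- resample_streamline(representative_streamline(br), 50)
  tf <- icp_align(rr, rl)
  ## independently jittered medoids keep ~ jitter-level noise each; the
  ## attainable post-alignment bound is a small multiple of jitter_sd
  expect_lt(attr(tf, "rmsd"), 2.5 * spec$jitter_sd_mm)
  ## and alignment must beat the unaligned distance decisively
  d0 <- sqrt(mean(rowSums((unclass(rr) - unclass(rl))^2)))
  expect_lt(attr(tf, "rmsd"), d0)
})

test_that("rigid transforms validate and compose", {
  expect_error(rigid_transform(diag(c(1, 1, -1))), "determinant")
  expect_error(rigid_transform(matrix(2 * diag(3), 3, 3)), "orthonormal")
  tf <- rigid_transform(rot_z(90), c(1, 0, 0))
  p <- matrix(c(1, 0, 0), 1)
  expect_equal(as.numeric(apply_rigid(tf, p)), c(1, 1, 0), tolerance = 1e-12)
})
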