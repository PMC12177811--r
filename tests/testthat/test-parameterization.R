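spec_param <- cohort_spec(jitter_sd_mm = 0.4, outlier_fraction = 0,
                          streamlines_per_bundle = 30, seed = 5)

test_that("ISOMAP coordinate tracks arc length on a noiseless-ish arc", {
  b <- make_arc_bundle(spec_param, "left", seed = 5)
  jp <- joint_parameterize(list(b), n_landmarks = 600,
                           anchor_point = arc_anchor_point(spec_param, "left"))
  expect_equal(range(jp$t_raw), c(0, 1))
  rho <- vapply(split(jp$t_raw, jp$streamline),
                function(tt) abs(cor(tt, seq_along(tt), method = "spearman")),
                0)
  expect_gte(min(rho), 0.99)
  ## anchored direction: temporal (u = 0) end maps near 0
  expect_lt(mean(jp$t_raw[jp$vertex == 1]), 0.1)
})

test_that("identical subjects receive identical coordinates", {
  b <- make_arc_bundle(spec_param, "left", seed = 6)
  jp <- joint_parameterize(list(b, b), n_landmarks = 500,
                           anchor_point = arc_anchor_point(spec_param, "left"))
  expect_lt(max(abs(jp$t_raw[jp$bundle == 1] - jp$t_raw[jp$bundle == 2])),
            1e-6)
})

test_that("joint parameterization is rigid-equivariant", {
  b <- make_arc_bundle(spec_param, "left", seed = 8)
  jp1 <- joint_parameterize(list(b), n_landmarks = 400, seed = 2)
  tf <- rigid_transform(rot_z(25), c(10, -4, 7))
  b2 <- apply_rigid(tf, b)
  jp2 <- joint_parameterize(list(b2), n_landmarks = 400, seed = 2)
  expect_lt(max(abs(jp1$t_raw - jp2$t_raw)), 1e-6)
})

test_that("core extraction keeps full coverage, trims truncated sections", {
  b <- make_arc_bundle(spec_param, "left", seed = 9)
  jp <- joint_parameterize(list(b), n_landmarks = 600,
                           anchor_point = arc_anchor_point(spec_param, "left"))
  jpc <- extract_core(jp)
  core <- attr(jpc, "core")
  expect_lte(core[1], 0.02)
  expect_gte(core[2], 0.98)
  ## core re-normalization is affine onto [0, 1]
  inside <- !is.na(jpc$t)
  expect_equal(jpc$t[inside],
               (jpc$t_raw[inside] - core[1]) / (core[2] - core[1]))

  ## a third of subjects truncated beyond t ~ 0.9 pulls the core bound down
  spec6 <- cohort_spec(jitter_sd_mm = 0.6, outlier_fraction = 0,
                       streamlines_per_bundle = 40, seed = 9)
  bs <- lapply(1:6, function(i)
    make_arc_bundle(spec6, "left", subject_id = paste0("s", i), seed = 100 + i))
  for (i in 5:6)
    bs[[i]]$streamlines <- lapply(bs[[i]]$streamlines,
                                  function(s) streamline(unclass(s)[1:45, ]))
  jpt <- joint_parameterize(bs, n_landmarks = 800,
                            anchor_point = arc_anchor_point(spec6, "left"))
  jptc <- extract_core(jpt)
  expect_lte(attr(jptc, "core")[2], 0.92)
  ## too-aggressive thresholds error out rather than return a sliver
  expect_error(extract_core(jpt, min_vertex_density = 1e6), "core|adequate")
})

test_that("bin profiles: constant field, t-midpoints, closure and missing", {
  b <- make_arc_bundle(spec_param, "left", seed = 10)
  jp <- extract_core(joint_parameterize(
    list(b), n_landmarks = 600,
    anchor_point = arc_anchor_point(spec_param, "left")))
  nv <- sum(jp$bundle == 1)
  expect_equal(bin_scalar_profile(jp, 1, rep(0.4, nv)), rep(0.4, 7))
  ## values = t itself -> bin means near bin midpoints
  prof <- bin_scalar_profile(jp, 1, jp$t[jp$bundle == 1])
  expect_equal(prof, (2 * (1:7) - 1) / 14, tolerance = 0.02)
  ## t = 1 lands in bin 7 (closure), bins partition half-open
  expect_equal(tractcrowd:::.assign_bins(c(0, 1 / 7 - 1e-9, 1 / 7, 1), 7L),
               c(1L, 1L, 2L, 7L))
  ## NA values are dropped; all-NA bins are missing markers
  v <- jp$t[jp$bundle == 1]
  v[jp$bin[jp$bundle == 1] %in% 4] <- NA
  expect_true(is.na(bin_scalar_profile(jp, 1, v)[4]))
})

test_that("whole-tract mean equals vertex-weighted mean of bin means", {
  b <- make_arc_bundle(spec_param, "left", seed = 12)
  jp <- extract_core(joint_parameterize(
    list(b), n_landmarks = 500,
    anchor_point = arc_anchor_point(spec_param, "left")))
  set.seed(1)
  v <- runif(sum(jp$bundle == 1))
  prof <- bin_scalar_profile(jp, 1, v)
  w <- table(jp$bin[jp$bundle == 1])
  expect_equal(sum(prof * as.numeric(w)) / sum(w),
               mean(v[!is.na(jp$bin[jp$bundle == 1])]), tolerance = 1e-12)
})

test_that("normalization divides by the skeleton mean and validates it", {
  expect_equal(normalize_profile(0.48, 0.4), 1.2)
  expect_equal(normalize_profile(c(0.4, 0.44), 0.4), c(1.0, 1.1))
  expect_error(normalize_profile(0.5, 0), "positive")
  expect_error(normalize_profile(0.5, -1), "positive")
})

test_that("pipeline bins recover the generator's effect segment", {
  spec <- cohort_spec(n_group_a = 3, n_group_b = 3,
                      streamlines_per_bundle = 60, jitter_sd_mm = 1,
                      outlier_fraction = 0, seed = 33)
  bs <- aligned_arc_bundles(spec, n_left = 3, n_right = 3, seed_base = 200)
  jp <- extract_core(joint_parameterize(
    bs, n_landmarks = 1000, anchor_point = arc_anchor_point(spec, "left")))
  ad <- tractcrowd:::.arc_distance(spec,
                                   do.call(rbind, bs[[1]]$streamlines), "left")
  sel <- jp$bundle == 1
  for (k in c(3, 5)) {
    inseg <- ad$u > (k - 1) / 7 & ad$u <= k / 7
    binv <- jp$bin[sel][inseg]
    expect_gte(mean(abs(binv - k) <= 1, na.rm = TRUE), 0.95)
  }
})
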