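test_that("Mann-Whitney U, z and p match hand values and the oracle", {
  ## canonical fully separated case: U = 0, exact two-sided p = 0.1
  mw <- mannwhitney_z(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_lt(mw$z, 0)
  or <- mw_enum_oracle(c(1, 2, 3), c(4, 5, 6))
  expect_equal(or$p, 0.1)
  ## identical samples -> z = 0
  expect_equal(mannwhitney_z(c(1, 2, 3), c(1, 2, 3))$z, 0)
  expect_equal(mannwhitney_z(rep(1, 4), rep(1, 5))$z, 0)
  ## z sign convention: positive when a is stochastically larger
  expect_gt(mannwhitney_z(c(5, 6, 7, 8), c(1, 2, 3, 4))$z, 0)
  ## exactness of U and tie-corrected variance against wilcox.test
  set.seed(15)
  for (i in 1:20) {
    a <- sample(1:6, 5, replace = TRUE)  # force ties
    b <- sample(1:6, 6, replace = TRUE)
    mw <- mannwhitney_z(a, b)
    wt <- suppressWarnings(stats::wilcox.test(a, b, correct = TRUE,
                                              exact = FALSE))
    expect_equal(mw$U, unname(wt$statistic))
    expect_equal(mw$p, wt$p.value, tolerance = 1e-10)
  }
})

test_that("normal-approximation p tracks enumeration within its real bound", {
  ## the attainable agreement at n <= 8: bounded by the discreteness of the
  ## exact null (see the acceptance suite for the spec's verbatim 0.01 form)
  set.seed(16)
  worst <- 0
  for (i in 1:200) {
    m <- sample(4:8, 1); n <- sample(4:8, 1)
    a <- rnorm(m); b <- rnorm(n)
    p_n <- mannwhitney_z(a, b)$p
    p_e <- mw_enum_oracle(a, b)$p
    worst <- max(worst, abs(p_n - p_e))
  }
  expect_lt(worst, 0.035)
})

test_that("whole-tract comparison: d, antisymmetry, consistency", {
  expect_equal(whole_tract_compare(c(1, 2, 3), c(1, 2, 3))$cohens_d, 0)
  set.seed(17)
  a <- rnorm(10000, 1); b <- rnorm(10000, 0)
  r <- whole_tract_compare(a, b)
  expect_lt(abs(r$cohens_d - 1), 0.05)
  expect_lt(r$p, 1e-10)
  expect_equal(whole_tract_compare(b, a)$cohens_d, -r$cohens_d)
  expect_error(whole_tract_compare(rep(1, 5), rep(1, 5)), "zero pooled SD")
  rm <- whole_tract_compare(a[1:50], b[1:50], method = "mannwhitney")
  expect_lt(rm$p, 0.05)
})

test_that("Barnard's exact test matches the exhaustive oracle", {
  ## equal proportions -> statistic 0 -> p = 1
  expect_equal(barnard_exact(matrix(c(2, 2, 2, 2), 2))$p, 1)
  ## perfectly discordant table against the oracle
  tb <- matrix(c(5, 0, 0, 5), 2)
  expect_lt(abs(barnard_exact(tb)$p - barnard_oracle(tb)), 1e-3)
  ## row swap + column swap symmetry
  tb2 <- matrix(c(7, 2, 3, 6), 2)
  tb2_swapped <- tb2[2:1, 2:1]
  expect_equal(barnard_exact(tb2)$p, barnard_exact(tb2_swapped)$p,
               tolerance = 1e-12)
  ## empty margin convention
  expect_equal(barnard_exact(matrix(c(0, 0, 3, 2), 2))$p, 1)
})

test_that("crowding rule classifies the published medians and the boundary", {
  expect_true(classify_crowding(85.5, 64.5)$crowding)
  expect_equal(classify_crowding(85.5, 64.5)$delta, 21)
  expect_false(classify_crowding(71.5, 73.5)$crowding)
  expect_true(classify_crowding(80, 70)$crowding)      # "at least 10"
  expect_false(classify_crowding(80, 70.5)$crowding)
  expect_true(is.na(classify_crowding(NA, 70)$crowding))
})

test_that("logistic crowding models report the full Table-2 style summary", {
  set.seed(18)
  n <- 200
  subj <- data.frame(
    subject_id = sprintf("s%03d", 1:n), group = "patient",
    contralesional_hemisphere = sample(c("left", "right"), n, TRUE),
    etiology = "congenital",
    age_at_scan = rnorm(n, 20, 5), age_at_surgery = rnorm(n, 12, 4),
    age_at_onset = rnorm(n, 4, 2), viq = 0, piq = 0,
    skeleton_mean_fa = 0.4)
  fa <- rnorm(n, 1.2, 0.1)
  eta <- 0.5 + 1.5 * scale(fa)[, 1] -
    2 * (subj$contralesional_hemisphere == "left")
  cr <- rbinom(n, 1, 1 / (1 + exp(-eta)))
  subj$viq <- 100 + 15 * cr; subj$piq <- 100 - 15 * cr   # encode the label
  mods <- fit_crowding_models(subj, fa)
  expect_named(mods, c("model1_age_at_surgery", "model2_age_at_onset",
                       "model3_age_at_scan"))
  m <- mods$model3_age_at_scan
  expect_equal(nrow(m$terms), 4L)
  expect_true(all(c("coefficient", "se", "z", "p") %in% names(m$terms)))
  expect_true(m$bic > m$aic)          # log(n) > 2 here
  expect_gt(m$pseudo_r2, 0.1)
  expect_lt(m$llr_p, 1e-6)
  expect_lt(m$condition_number, 10)
  ## FA slope recovered with the right sign and magnitude
  expect_equal(m$terms$coefficient[m$terms$term == "norm_fa"], 1.5,
               tolerance = 0.5)
})

test_that("collinear covariates blow up the reported condition number", {
  set.seed(19)
  n <- 60
  subj <- data.frame(
    subject_id = sprintf("s%03d", 1:n), group = "patient",
    contralesional_hemisphere = sample(c("left", "right"), n, TRUE),
    etiology = "congenital", age_at_scan = rnorm(n, 20, 5),
    age_at_surgery = rnorm(n, 12, 4), age_at_onset = rnorm(n, 4, 2),
    viq = sample(c(110, 90), n, TRUE), piq = 90, skeleton_mean_fa = 0.4)
  ## age_at_scan duplicated into norm_fa -> near-singular design
  mods <- fit_crowding_models(subj, subj$age_at_scan + rnorm(n, 0, 1e-8))
  expect_gt(mods$model3_age_at_scan$condition_number, 1e4)
})

test_that("separated data trigger the flagged ridge-stabilized refit", {
  set.seed(20)
  n <- 30
  subj <- data.frame(
    subject_id = sprintf("s%03d", 1:n), group = "patient",
    contralesional_hemisphere = "left", etiology = "congenital",
    age_at_scan = rnorm(n, 20, 5), age_at_surgery = rnorm(n, 12, 4),
    age_at_onset = rnorm(n, 4, 2), viq = 0, piq = 0, skeleton_mean_fa = 0.4)
  fa <- c(rnorm(15, 1.0, 0.02), rnorm(15, 2.0, 0.02))
  cr <- as.numeric(fa > 1.5)                   # perfect separation on FA
  subj$viq <- 100 + 15 * cr; subj$piq <- 100 - 15 * cr
  mods <- fit_crowding_models(subj, fa)
  m <- mods$model3_age_at_scan
  expect_true(m$separation)
  expect_true(all(is.finite(m$terms$coefficient)))
  expect_true(all(is.finite(m$terms$se)))
})
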