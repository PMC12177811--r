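## Synthetic cohort generator: arc-shaped "arcuate-like" bundles, FA volumes
## with an optional localized group effect, outlier streamlines, and
## VIQ/PIQ scores with a controlled crowding prevalence. A stated world for
## calibration and power studies -- not a DWI simulator.

.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specify a synthetic cohort
#'
#' Defaults describe the emulated study: two groups of ~20 subjects, ~100
#' streamlines per bundle, a 30 mm radius / 180 degree sagittal arc, 1 mm
#' vertex jitter, 10% outlier streamlines, FA 0.5 with 0.05 between-subject
#' SD, and (when an effect is requested) a Cohen's d shift confined to one
#' of 7 equal arc-length segments.
#'
#' @param n_group_a,n_group_b patients / controls counts (>= 2).
#' @param streamlines_per_bundle streamline count per subject per hemisphere.
#' @param arc_radius_mm,arc_span_deg arc geometry.
#' @param jitter_sd_mm per-vertex Gaussian positional noise.
#' @param outlier_fraction fraction of displaced streamlines, in [0, 0.5).
#' @param effect_bin index 1..n_bins of the affected segment, or `NULL`.
#' @param effect_size_d Cohen's d of the FA shift in `effect_bin`.
#' @param effect_group `"patient"` (all of group a) or `"crowding"`
#'   (crowding-positive patients only).
#' @param effect_hemisphere `"both"`, `"left"` or `"right"`.
#' @param fa_baseline,fa_noise_sd tract FA mean and between-subject SD.
#' @param crowding_prevalence fraction of group a with VIQ - PIQ >= 10.
#' @param n_bins segments used to place the effect (default 7).
#' @param seed RNG seed for [make_cohort()].
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_group_a = 20L, n_group_b = 20L,
                        streamlines_per_bundle = 100L,
                        arc_radius_mm = 30, arc_span_deg = 180,
                        jitter_sd_mm = 1, outlier_fraction = 0.1,
                        effect_bin = NULL, effect_size_d = 0,
                        effect_group = c("patient", "crowding"),
                        effect_hemisphere = c("both", "left", "right"),
                        fa_baseline = 0.5, fa_noise_sd = 0.05,
                        crowding_prevalence = 0.5, n_bins = 7L,
                        seed = 1L) {
  effect_group <- match.arg(effect_group)
  effect_hemisphere <- match.arg(effect_hemisphere)
  stopifnot(n_group_a >= 2L, n_group_b >= 2L, streamlines_per_bundle >= 1L,
            arc_radius_mm > 0, arc_span_deg > 0, jitter_sd_mm >= 0,
            outlier_fraction >= 0, outlier_fraction < 0.5,
            effect_size_d >= 0,
            crowding_prevalence >= 0, crowding_prevalence <= 1)
  if (fa_baseline - 4 * fa_noise_sd <= 0 || fa_baseline + 4 * fa_noise_sd >= 1)
    stop("fa_baseline +/- 4 * fa_noise_sd must stay inside (0, 1)")
  if (!is.null(effect_bin))
    stopifnot(effect_bin >= 1L, effect_bin <= n_bins)
  structure(list(n_group_a = as.integer(n_group_a),
                 n_group_b = as.integer(n_group_b),
                 streamlines_per_bundle = as.integer(streamlines_per_bundle),
                 arc_radius_mm = arc_radius_mm, arc_span_deg = arc_span_deg,
                 jitter_sd_mm = jitter_sd_mm,
                 outlier_fraction = outlier_fraction,
                 effect_bin = effect_bin, effect_size_d = effect_size_d,
                 effect_group = effect_group,
                 effect_hemisphere = effect_hemisphere,
                 fa_baseline = fa_baseline, fa_noise_sd = fa_noise_sd,
                 crowding_prevalence = crowding_prevalence,
                 n_bins = as.integer(n_bins), seed = seed),
            class = "cohort_spec")
}

## Ideal left-hemisphere arc: sagittal plane x = -35, arching in (y, z).
## u in [0, 1] runs posterior/temporal (u = 0) to anterior/frontal (u = 1);
## a circular arc is uniform in angle, so u IS the arc-length fraction.
## The angular window sits asymmetrically about the apex (the temporal limb
## dips lower), as the real arcuate does; a window symmetric about the apex
## would make the curve its own mirror image end-for-end and leave rigid
## ICP genuinely unable to resolve bundle orientation.
.arc_phi_range <- c(-0.58, 0.42)

.arc_template <- function(spec, u, side = "left") {
  span <- spec$arc_span_deg * pi / 180
  phi <- (.arc_phi_range[1L] + u) * span
  x <- rep(if (side == "left") -35 else 35, length(u))
  cbind(x = x,
        y = -10 + spec$arc_radius_mm * sin(phi),
        z = 10 + spec$arc_radius_mm * cos(phi))
}

#' World-space anchor of the arc's temporal (u = 0) end
#' @param spec a `cohort_spec`; @param side hemisphere.
#' @return 3-vector, world mm.
#' @export
arc_anchor_point <- function(spec, side = "left") {
  as.numeric(.arc_template(spec, 0, side))
}

#' Generate one synthetic arc bundle
#'
#' Streamlines are noisy copies of a planar circular arc; a fraction are
#' displaced whole-streamline outliers (offset norm uniform in
#' `[12, 20] * jitter_sd_mm`, hence always >= 10 jitter SDs). The right-side
#' template is the mirror image (x -> -x) of the left.
#'
#' @param spec a [cohort_spec()].
#' @param side `"left"` or `"right"`.
#' @param subject_id bundle metadata.
#' @param n_vertices vertices per generated streamline (default 50).
#' @param seed optional seed (otherwise the ambient RNG stream is used).
#' @return a `tract_bundle`; attribute `outlier_index` marks displaced
#'   streamlines.
#' @export
make_arc_bundle <- function(spec, side = c("left", "right"),
                            subject_id = "sim", n_vertices = 50L,
                            seed = NULL) {
  side <- match.arg(side)
  .with_seed(seed, {
    n <- spec$streamlines_per_bundle
    n_out <- round(spec$outlier_fraction * n)
    out_idx <- if (n_out > 0L) sample.int(n, n_out) else integer(0)
    sls <- vector("list", n)
    for (i in seq_len(n)) {
      ## random per-streamline vertex phase (as real step-wise tractography
      ## has); in the noiseless limit all streamlines are exact arc copies
      phase <- if (spec$jitter_sd_mm > 0) runif(1L) else 0
      u <- (seq_len(n_vertices) - 1L + phase) / n_vertices
      template <- .arc_template(spec, u, side)
      pts <- template +
        matrix(rnorm(3L * n_vertices, sd = spec$jitter_sd_mm), n_vertices, 3L)
      if (i %in% out_idx && spec$jitter_sd_mm > 0) {
        ## whole-streamline displacement; redraw directions that run
        ## tangentially along the arc until the displaced streamline is
        ## at least 10 jitter SDs away from the ideal curve everywhere
        for (try in 1:50) {
          dir <- rnorm(3L)
          dir <- dir / sqrt(sum(dir^2))
          cand <- pts + rep(runif(1L, 12, 20) * spec$jitter_sd_mm * dir,
                            each = n_vertices)
          d <- .arc_distance(spec, cand, side)$dist
          if (min(d) >= 10 * spec$jitter_sd_mm) break
        }
        pts <- cand
      }
      sls[[i]] <- pts
    }
    b <- bundle(sls, subject_id = subject_id, hemisphere = side,
                tract_name = "AF")
    attr(b, "outlier_index") <- sort(out_idx)
    b
  })
}

## Distance from world points to the ideal arc and the arc-length fraction
## of the closest arc point (clamped to the arc ends).
.arc_distance <- function(spec, pts, side) {
  span <- spec$arc_span_deg * pi / 180
  cx <- if (side == "left") -35 else 35
  dy <- pts[, 2L] + 10
  dz <- pts[, 3L] - 10
  phi <- atan2(dy, dz)
  phi <- pmin(pmax(phi, .arc_phi_range[1L] * span), .arc_phi_range[2L] * span)
  u <- phi / span - .arc_phi_range[1L]
  closest <- cbind(cx, -10 + spec$arc_radius_mm * sin(phi),
                   10 + spec$arc_radius_mm * cos(phi))
  d <- sqrt(rowSums((pts - closest)^2))
  list(dist = d, u = u)
}

## voxel_mm default matches the emulated acquisition's DWI resolution
.make_fa_volume <- function(spec, side, tract_value, effect_shift,
                            bg_value, voxel_mm = 1.7, tract_radius = 6) {
  u <- seq(0, 1, length.out = 101L)
  arc <- .arc_template(spec, u, side)
  lo <- floor(apply(arc, 2L, min)) - (tract_radius + 8)
  hi <- ceiling(apply(arc, 2L, max)) + (tract_radius + 8)
  dims <- as.integer(ceiling((hi - lo) / voxel_mm)) + 1L
  aff <- diag(c(voxel_mm, voxel_mm, voxel_mm, 1))
  aff[1:3, 4L] <- lo
  grid <- as.matrix(expand.grid(
    x = lo[1L] + voxel_mm * (seq_len(dims[1L]) - 1L),
    y = lo[2L] + voxel_mm * (seq_len(dims[2L]) - 1L),
    z = lo[3L] + voxel_mm * (seq_len(dims[3L]) - 1L)))
  ad <- .arc_distance(spec, grid, side)
  in_tract <- ad$dist <= tract_radius
  val <- rep(bg_value, nrow(grid))
  val[in_tract] <- tract_value
  if (effect_shift != 0 && !is.null(spec$effect_bin)) {
    k <- spec$effect_bin
    in_bin <- ad$u > (k - 1) / spec$n_bins & ad$u <= k / spec$n_bins
    val[in_tract & in_bin] <- val[in_tract & in_bin] + effect_shift
  }
  val <- pmin(pmax(val, 0.05), 0.95)
  vol <- scalar_volume(array(val, dims), aff, metric = "FA")
  attr(vol, "skeleton_mean") <- mean(val[!in_tract])
  vol
}

.draw_iq <- function(is_patient, crowding) {
  if (is_patient && crowding) {
    viq <- round(rnorm(1L, 85, 8))
    delta <- 10 + round(abs(rnorm(1L, 11, 7)))
  } else if (is_patient) {
    viq <- round(rnorm(1L, 72, 9))
    repeat {
      delta <- round(rnorm(1L, -2, 6))
      if (delta < 10) break
    }
  } else {
    viq <- round(rnorm(1L, 100, 12))
    delta <- round(rnorm(1L, 0, 7))
  }
  c(viq = viq, piq = viq - delta)
}

#' Generate a full synthetic cohort
#'
#' Per subject: one bundle per hemisphere and one FA volume per hemisphere
#' whose tract value is `fa_baseline` plus subject-level noise, shifted by
#' `effect_size_d * fa_noise_sd` inside the arc segment mapping to
#' `effect_bin` for affected subjects/hemispheres; VIQ/PIQ such that a
#' `crowding_prevalence` fraction of group a satisfies VIQ - PIQ >= 10 (and,
#' mirroring the emulated cohort, crowding occurs only with congenital
#' etiology when counts permit); `skeleton_mean_fa` is the tract-free mean of
#' the subject's volumes. The generator is a pure function of (spec, seed).
#'
#' @param spec a [cohort_spec()].
#' @return list with `subjects` (data.frame), `bundles` (per subject: list
#'   `left`/`right` of `tract_bundle`), and `volumes` (same shape,
#'   [scalar_volume()]s).
#' @export
make_cohort <- function(spec) {
  .with_seed(spec$seed, {
    n_a <- spec$n_group_a; n_b <- spec$n_group_b
    ids <- c(sprintf("pat%02d", seq_len(n_a)), sprintf("con%02d", seq_len(n_b)))
    group <- rep(c("patient", "control"), c(n_a, n_b))

    ## clinical structure of group a
    n_cong <- round(0.77 * n_a)
    etiology <- rep("n/a", n_a + n_b)
    etiology[seq_len(n_a)] <- sample(rep(c("congenital", "acquired"),
                                        c(n_cong, n_a - n_cong)))
    n_crowd <- round(spec$crowding_prevalence * n_a)
    cong_idx <- which(etiology[seq_len(n_a)] == "congenital")
    pool <- if (n_crowd <= length(cong_idx)) cong_idx else seq_len(n_a)
    crowd <- rep(FALSE, n_a + n_b)
    if (n_crowd > 0L) crowd[sample(pool, n_crowd)] <- TRUE

    hemi <- rep("n/a", n_a + n_b)
    hemi[seq_len(n_a)] <- sample(c("left", "right"), n_a, replace = TRUE,
                                 prob = c(0.45, 0.55))

    age_onset <- age_surgery <- age_scan <- numeric(n_a + n_b)
    age_onset[] <- NA; age_surgery[] <- NA
    for (i in seq_len(n_a)) {
      age_onset[i] <- round(abs(rnorm(1L, 3.5, 2.5)), 1)
      age_surgery[i] <- age_onset[i] + round(abs(rnorm(1L, 8, 5)), 1)
      age_scan[i] <- age_surgery[i] + 1.2 + round(abs(rnorm(1L, 8, 5)), 1)
    }
    age_scan[(n_a + 1L):(n_a + n_b)] <-
      round(pmax(rnorm(n_b, 24, 8), 15), 1)

    iq <- t(vapply(seq_len(n_a + n_b),
                   function(i) .draw_iq(group[i] == "patient", crowd[i]),
                   numeric(2L)))

    bundles <- volumes <- vector("list", n_a + n_b)
    names(bundles) <- names(volumes) <- ids
    skel <- numeric(n_a + n_b)
    shift <- spec$effect_size_d * spec$fa_noise_sd
    for (i in seq_along(ids)) {
      base_i <- spec$fa_baseline + rnorm(1L, 0, spec$fa_noise_sd)
      bg_i <- 0.25 + rnorm(1L, 0, 0.01)
      affected <- if (spec$effect_group == "patient") group[i] == "patient"
                  else crowd[i]
      bl <- make_arc_bundle(spec, "left", subject_id = ids[i])
      br <- make_arc_bundle(spec, "right", subject_id = ids[i])
      sides <- switch(spec$effect_hemisphere, both = c("left", "right"),
                      left = "left", right = "right")
      vl <- .make_fa_volume(spec, "left", base_i,
                            if (affected && "left" %in% sides) shift else 0,
                            bg_i)
      vr <- .make_fa_volume(spec, "right", base_i,
                            if (affected && "right" %in% sides) shift else 0,
                            bg_i)
      bundles[[i]] <- list(left = bl, right = br)
      volumes[[i]] <- list(left = vl, right = vr)
      skel[i] <- mean(c(attr(vl, "skeleton_mean"), attr(vr, "skeleton_mean")))
    }

    subjects <- data.frame(
      subject_id = ids, group = group,
      contralesional_hemisphere = hemi, etiology = etiology,
      viq = iq[, 1L], piq = iq[, 2L],
      age_at_scan = age_scan, age_at_surgery = age_surgery,
      age_at_onset = age_onset, skeleton_mean_fa = skel,
      stringsAsFactors = FALSE)
    list(subjects = subjects, bundles = bundles, volumes = volumes,
         spec = spec)
  })
}

#' Write a synthetic cohort to disk in the pipeline's input layout
#'
#' `<dir>/subjects.tsv`, `<dir>/streamlines/<id>_<hemi>_AF.tck` and
#' `<dir>/volumes/<id>_<hemi>_fa.nii.gz` -- exactly the layout
#' [run_study()] reads.
#'
#' @param cohort result of [make_cohort()].
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "streamlines"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "volumes"), showWarnings = FALSE)
  write_subjects(cohort$subjects, file.path(dir, "subjects.tsv"))
  for (id in names(cohort$bundles)) {
    for (h in c("left", "right")) {
      write_streamlines(cohort$bundles[[id]][[h]],
                        file.path(dir, "streamlines",
                                  sprintf("%s_%s_AF.tck", id, h)))
      write_nifti(cohort$volumes[[id]][[h]],
                  file.path(dir, "volumes", sprintf("%s_%s_fa.nii.gz", id, h)))
    }
  }
  invisible(dir)
}

#' Simulate bin-profile matrices directly (stats-level generator)
#'
#' Bypasses the imaging chain and draws the subjects x bins matrix the
#' sectional statistics consume: per subject a shared baseline
#' `N(fa_baseline, between_sd)` plus per-bin noise `N(0, within_sd)`, with
#' group a shifted by `effect_size_d * between_sd` in `effect_bin`. Used for
#' family-wise-error calibration and power studies where hundreds of
#' replicate cohorts are needed.
#'
#' @param n_a,n_b group sizes.
#' @param n_bins number of bins (default 7).
#' @param effect_bin affected bin or `NULL`.
#' @param effect_size_d Cohen's d of the shift, in units of `between_sd`.
#' @param fa_baseline,between_sd,within_sd noise model.
#' @return list with `profiles` (matrix), `labels` (character vector).
#' @export
simulate_bin_profiles <- function(n_a, n_b, n_bins = 7L, effect_bin = NULL,
                                  effect_size_d = 0, fa_baseline = 0.5,
                                  between_sd = 0.05, within_sd = 0.01) {
  n <- n_a + n_b
  base <- rnorm(n, fa_baseline, between_sd)
  profiles <- matrix(rnorm(n * n_bins, 0, within_sd), n, n_bins) + base
  if (!is.null(effect_bin) && effect_size_d != 0)
    profiles[seq_len(n_a), effect_bin] <-
      profiles[seq_len(n_a), effect_bin] + effect_size_d * between_sd
  list(profiles = profiles,
       labels = rep(c("a", "b"), c(n_a, n_b)))
}
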