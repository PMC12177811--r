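## Full study replica: dissection -> outlier removal -> mirroring/ICP ->
## joint parameterization -> profiles -> normalization -> group contrasts ->
## TSV/JSON/PNG reports.

#' Analysis configuration
#'
#' @param tract_name tract label used in file names (default `"AF"`).
#' @param metrics subset of `c("fa", "curvature")` to profile.
#' @param n_bins bins along the core (default 7).
#' @param nu one-class-SVM outlier fraction (default 0.1).
#' @param n_vertices resampling target (default 50).
#' @param knn,n_landmarks ISOMAP graph parameters.
#' @param min_subject_coverage,min_vertex_density core-extraction thresholds.
#' @param tfce a [tfce_params()] list.
#' @param crowding_threshold VIQ - PIQ cut (default 10).
#' @param alpha significance level (default 0.05).
#' @param normalize_by_skeleton divide FA by the subject skeleton mean
#'   (default TRUE).
#' @param control_hemispheres `"both"` (controls enter left and right
#'   contrasts) or `"matched"` reserved for future use.
#' @param anchor_point optional 3-vector anchoring t = 0 (temporal end).
#' @param rois optional list of [roi_spec()] for dissection.
#' @param seed master seed; every random step derives from it.
#' @export
analysis_config <- function(tract_name = "AF", metrics = c("fa", "curvature"),
                            n_bins = 7L, nu = 0.1, n_vertices = 50L,
                            knn = 10L, n_landmarks = 1500L,
                            min_subject_coverage = 0.8, min_vertex_density = 5,
                            tfce = tfce_params(), crowding_threshold = 10,
                            alpha = 0.05, normalize_by_skeleton = TRUE,
                            control_hemispheres = "both",
                            anchor_point = NULL, rois = NULL, seed = 1L) {
  stopifnot(alpha > 0, alpha < 1)
  metrics <- match.arg(metrics, c("fa", "curvature"), several.ok = TRUE)
  list(tract_name = tract_name, metrics = metrics, n_bins = as.integer(n_bins),
       nu = nu, n_vertices = as.integer(n_vertices), knn = as.integer(knn),
       n_landmarks = as.integer(n_landmarks),
       min_subject_coverage = min_subject_coverage,
       min_vertex_density = min_vertex_density, tfce = tfce,
       crowding_threshold = crowding_threshold, alpha = alpha,
       normalize_by_skeleton = normalize_by_skeleton,
       control_hemispheres = control_hemispheres,
       anchor_point = anchor_point, rois = rois, seed = seed)
}

## units of analysis: patients contribute the contralesional hemisphere
## only (the ipsilesional one is excluded), controls both hemispheres
.analysis_units <- function(subjects) {
  units <- list()
  for (i in seq_len(nrow(subjects))) {
    s <- subjects[i, ]
    hemis <- if (s$group == "patient") {
      if (s$contralesional_hemisphere %in% c("left", "right"))
        s$contralesional_hemisphere else character(0)
    } else c("left", "right")
    for (h in hemis)
      units[[length(units) + 1L]] <- list(subject_id = s$subject_id,
                                          hemisphere = h, row = i)
  }
  units
}

.load_unit_bundle <- function(data_dir, id, hemi, tract) {
  path <- file.path(data_dir, "streamlines",
                    sprintf("%s_%s_%s.tck", id, hemi, tract))
  if (!file.exists(path)) {
    alt <- sub("\\.tck$", ".trk", path)
    if (file.exists(alt)) path <- alt else return(NULL)
  }
  read_streamlines(path, subject_id = id, hemisphere = hemi, tract_name = tract)
}

.load_unit_volume <- function(data_dir, id, hemi) {
  for (ext in c(".nii.gz", ".nii")) {
    path <- file.path(data_dir, "volumes", sprintf("%s_%s_fa%s", id, hemi, ext))
    if (file.exists(path)) return(read_nifti(path, metric = "FA"))
  }
  NULL
}

#' Run the full along-tract study on a data directory
#'
#' Expects `subjects.tsv`, `streamlines/<id>_<hemi>_<tract>.tck` (or `.trk`)
#' and `volumes/<id>_<hemi>_fa.nii[.gz]` under `data_dir` (the layout
#' [write_cohort()] produces). Executes, per hemisphere of interest:
#' whole-tract and 7-bin TFCE-corrected contrasts of patients vs controls
#' and crowding vs no-crowding (per metric), plus the pooled
#' congenital-crowding vs acquired-no-crowding contrast, Barnard's
#' etiology x crowding test and the three logistic crowding models. All
#' randomness derives from `config$seed`; reruns are byte-identical.
#'
#' @param config an [analysis_config()].
#' @param data_dir input directory.
#' @param out_dir optional output directory for TSV/JSON/PNG reports.
#' @return a `study_result` list.
#' @export
run_study <- function(config, data_dir, out_dir = NULL) {
  subjects <- read_subjects(file.path(data_dir, "subjects.tsv"))
  units <- .analysis_units(subjects)
  if (length(units) == 0L) stop("no analyzable subject-hemisphere units")
  log_rows <- list()

  .with_seed(config$seed, {
    prepared <- list()
    for (u in units) {
      b <- .load_unit_bundle(data_dir, u$subject_id, u$hemisphere,
                             config$tract_name)
      if (is.null(b)) {
        warning("missing bundle for ", u$subject_id, "/", u$hemisphere,
                "; unit skipped")
        next
      }
      n0 <- n_streamlines(b)
      if (!is.null(config$rois)) b <- filter_by_rois(b, config$rois)
      n1 <- n_streamlines(b)
      fr <- remove_outliers(b, nu = config$nu, n_vertices = config$n_vertices)
      b <- fr$kept
      n2 <- n_streamlines(b)
      b <- map_streamlines(b, function(s)
        unclass(resample_streamline(s, config$n_vertices)))
      b <- harmonize_orientation(b)
      if (!is.null(config$anchor_point)) {
        ## orient toward the (hemisphere-appropriate) temporal anchor so
        ## that ICP can preserve orientation across bundles
        anchor_native <- config$anchor_point
        if (u$hemisphere == "right") anchor_native[1L] <- -anchor_native[1L]
        b <- orient_bundle_to_anchor(b, anchor_native)
      }
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        subject_id = u$subject_id, hemisphere = u$hemisphere,
        streamlines_raw = n0, after_roi = n1, after_outlier = n2)
      prepared[[length(prepared) + 1L]] <-
        list(unit = u, bundle = b,
             volume = .load_unit_volume(data_dir, u$subject_id, u$hemisphere))
    }
    if (length(prepared) < 4L) stop("too few units survived preparation")

    ## mirror right-side bundles, then rigidly align every bundle's
    ## representative to a common reference (the first prepared unit)
    aligned <- vector("list", length(prepared))
    reps <- vector("list", length(prepared))
    for (i in seq_along(prepared)) {
      ab <- prepared[[i]]$bundle
      if (ab$hemisphere == "right") ab <- mirror_bundle(ab)
      reps[[i]] <- representative_streamline(ab)
      aligned[[i]] <- ab
    }
    ref <- reps[[1L]]
    icp_orientation <- if (is.null(config$anchor_point)) "free" else "preserve"
    for (i in seq_along(aligned)) {
      tf <- icp_align(reps[[i]], ref, orientation = icp_orientation)
      aligned[[i]] <- apply_rigid(tf, aligned[[i]])
    }

    jp <- joint_parameterize(aligned, knn = config$knn,
                             n_landmarks = config$n_landmarks,
                             anchor_point = config$anchor_point,
                             n_bins = config$n_bins, seed = config$seed)
    jp <- extract_core(jp, config$min_subject_coverage,
                       config$min_vertex_density)

    ## per-unit, per-metric bin profiles + whole-tract means
    n_units <- length(prepared)
    profiles <- list()
    whole <- list()
    for (metric in config$metrics) {
      P <- matrix(NA_real_, n_units, config$n_bins)
      W <- rep(NA_real_, n_units)
      for (i in seq_len(n_units)) {
        b <- prepared[[i]]$bundle
        vals <- if (metric == "fa") {
          vol <- prepared[[i]]$volume
          if (is.null(vol)) next
          v <- sample_scalar_at_points(vol, bundle_points(b)$points)
          if (config$normalize_by_skeleton) {
            sk <- subjects$skeleton_mean_fa[prepared[[i]]$unit$row]
            v <- normalize_profile(v, sk)
          }
          v
        } else {
          unlist(lapply(b$streamlines,
                        function(s) curvature_profile(s)$kappa),
                 use.names = FALSE)
        }
        P[i, ] <- bin_scalar_profile(jp, i, vals)
        W[i] <- mean(vals, na.rm = TRUE)
      }
      profiles[[metric]] <- P
      whole[[metric]] <- W
    }

    meta <- data.frame(
      subject_id = vapply(prepared, function(p) p$unit$subject_id, ""),
      hemisphere = vapply(prepared, function(p) p$unit$hemisphere, ""),
      row = vapply(prepared, function(p) p$unit$row, 0L))
    meta$group <- subjects$group[meta$row]
    cl <- classify_crowding(subjects$viq[meta$row], subjects$piq[meta$row],
                            config$crowding_threshold)
    meta$crowding <- cl$crowding
    meta$etiology <- subjects$etiology[meta$row]

    contrast_defs <- list()
    for (h in c("left", "right")) {
      sel <- meta$hemisphere == h
      contrast_defs[[paste0("patient_vs_control_", h)]] <-
        list(sel = sel, labels = ifelse(meta$group == "patient", "patient",
                                        "control"))
      selc <- sel & meta$group == "patient" & !is.na(meta$crowding)
      contrast_defs[[paste0("crowding_vs_nocrowding_", h)]] <-
        list(sel = selc, labels = ifelse(meta$crowding %in% TRUE, "crowding",
                                         "no_crowding"))
    }
    sel_et <- meta$group == "patient" & !is.na(meta$crowding) &
      ((meta$etiology == "congenital" & meta$crowding) |
         (meta$etiology == "acquired" & !meta$crowding))
    contrast_defs[["congenital_crowding_vs_acquired_nocrowding"]] <-
      list(sel = sel_et,
           labels = ifelse(meta$etiology == "congenital", "congenital_crowding",
                           "acquired_nocrowding"))

    bin_results <- list()
    whole_results <- list()
    for (cname in names(contrast_defs)) {
      cd <- contrast_defs[[cname]]
      sel <- cd$sel
      labs <- cd$labels[sel]
      if (length(unique(labs)) < 2L || min(table(labs)) < 2L) {
        warning("contrast ", cname, " has an empty/too-small subgroup; skipped")
        next
      }
      for (metric in names(profiles)) {
        key <- paste(cname, metric, sep = ".")
        bin_results[[key]] <- permutation_fwe(
          profiles[[metric]][sel, , drop = FALSE], labs,
          params = config$tfce, alpha = config$alpha)
        grp <- unique(labs)
        wt <- tryCatch(
          whole_tract_compare(whole[[metric]][sel][labs == grp[1L]],
                              whole[[metric]][sel][labs == grp[2L]]),
          error = function(e) list(p = NA_real_, cohens_d = NA_real_))
        whole_results[[key]] <- c(list(group_a = grp[1L], group_b = grp[2L]),
                                  wt)
      }
    }

    ## subject-level (not unit-level) crowding x etiology and models
    pat <- subjects[subjects$group == "patient", , drop = FALSE]
    pcl <- classify_crowding(pat$viq, pat$piq, config$crowding_threshold)
    et_tab <- table(factor(ifelse(pcl$crowding, "crowding", "no_crowding"),
                           levels = c("crowding", "no_crowding")),
                    factor(pat$etiology,
                           levels = c("congenital", "acquired")))
    barnard <- barnard_exact(unclass(et_tab))

    fa_whole_by_subject <- rep(NA_real_, nrow(subjects))
    if ("fa" %in% names(whole)) {
      agg <- tapply(whole$fa, meta$row, mean, na.rm = TRUE)
      fa_whole_by_subject[as.integer(names(agg))] <- agg
    }
    models <- tryCatch(
      fit_crowding_models(subjects, fa_whole_by_subject,
                          config$crowding_threshold),
      error = function(e) {
        warning("logistic models skipped: ", conditionMessage(e))
        NULL
      })

    result <- structure(list(
      config = config, subjects = subjects, meta = meta,
      attrition = do.call(rbind, log_rows),
      parameterization = list(core = attr(jp, "core"),
                              n_bins = attr(jp, "n_bins")),
      profiles = profiles, whole_tract = whole,
      bin_results = bin_results, whole_results = whole_results,
      etiology_table = et_tab, barnard = barnard, models = models),
      class = "study_result")
    if (!is.null(out_dir)) write_study_report(result, out_dir)
    result
  })
}

#' Write a study's TSV/JSON/PNG report files
#' @param result a `study_result`; @param out_dir directory (created).
#' @return `out_dir`, invisibly.
#' @export
write_study_report <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  bins <- do.call(rbind, lapply(names(result$bin_results), function(key) {
    r <- result$bin_results[[key]]
    data.frame(contrast = key, bin = seq_along(r$z_obs),
               z = sprintf("%.10g", r$z_obs),
               tfce = sprintf("%.10g", r$tfce_obs),
               p_corrected = sprintf("%.10g", r$p_corrected),
               significant = r$significant)
  }))
  write.table(bins, file.path(out_dir, "bin_results.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  wt <- do.call(rbind, lapply(names(result$whole_results), function(key) {
    r <- result$whole_results[[key]]
    data.frame(contrast = key, group_a = r$group_a, group_b = r$group_b,
               p = sprintf("%.10g", r$p),
               cohens_d = sprintf("%.10g", r$cohens_d))
  }))
  write.table(wt, file.path(out_dir, "whole_tract.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(result$attrition, file.path(out_dir, "attrition.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(
    core = result$parameterization$core,
    etiology_table = as.list(as.data.frame(result$etiology_table)),
    barnard_p = result$barnard$p,
    models = if (!is.null(result$models)) {
      lapply(result$models, function(m)
        list(terms = m$terms, aic = m$aic, bic = m$bic,
             pseudo_r2 = m$pseudo_r2, llr_p = m$llr_p,
             condition_number = m$condition_number,
             separation = m$separation))
    })
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  for (key in names(result$bin_results)) {
    r <- result$bin_results[[key]]
    grDevices::png(file.path(out_dir, paste0("bins_", key, ".png")),
                   width = 640, height = 420)
    graphics::plot(seq_along(r$z_obs), r$z_obs, type = "b", pch = 19,
                   xlab = "bin", ylab = "Mann-Whitney z", main = key)
    graphics::abline(h = 0, lty = 2)
    if (any(r$significant))
      graphics::points(which(r$significant), r$z_obs[r$significant],
                       col = "red", pch = 8, cex = 2)
    grDevices::dev.off()
  }
  invisible(out_dir)
}
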