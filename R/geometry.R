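## Streamline geometry: resampling, curvature, ROI dissection, mirroring,
## medoid representatives and rigid ICP alignment.

#' Total arc length of a streamline (mm)
#' @param s V x 3 matrix.
#' @export
streamline_length <- function(s) {
  d <- diff(unclass(s))
  sum(sqrt(rowSums(d * d)))
}

#' Resample a streamline to equal arc-length spacing
#'
#' Places `n` vertices at equal arc-length intervals along the piecewise
#' linear curve; both endpoints are preserved exactly.
#'
#' @param s streamline (V x 3), V >= 2.
#' @param n number of output vertices (default 50, the along-tract
#'   convention used throughout the package).
#' @return resampled `streamline` with `n` vertices.
#' @export
resample_streamline <- function(s, n = 50L) {
  s <- unclass(as.matrix(s))
  seg <- sqrt(rowSums(diff(s)^2))
  L <- sum(seg)
  if (L <= 0) stop("cannot resample a zero-length streamline")
  cs <- c(0, cumsum(seg))
  target <- seq(0, L, length.out = n)
  out <- matrix(NA_real_, n, 3L)
  out[1L, ] <- s[1L, ]
  out[n, ] <- s[nrow(s), ]
  if (n > 2L) {
    idx <- findInterval(target[2:(n - 1L)], cs, rightmost.closed = TRUE)
    idx <- pmin(idx, length(seg))
    w <- (target[2:(n - 1L)] - cs[idx]) / pmax(seg[idx], .Machine$double.eps)
    out[2:(n - 1L), ] <- s[idx, , drop = FALSE] * (1 - w) +
      s[idx + 1L, , drop = FALSE] * w
  }
  streamline(out)
}

#' Discrete curvature profile of a uniformly resampled streamline
#'
#' Curvature at interior vertex i is the magnitude of the second central
#' difference with respect to arc length,
#' kappa_i = ||x_{i+1} - 2 x_i + x_{i-1}|| / ds^2, with ds the (uniform)
#' arc-length spacing. Curvature is undefined at the two endpoints and set
#' to zero there.
#'
#' @param s streamline resampled to uniform spacing, V >= 3.
#' @param tol spacing-uniformity guard: error when any segment deviates
#'   from the mean spacing by more than `tol * mean` (default 1). The guard
#'   only rejects clearly non-resampled input; equal arc-length resampling
#'   of a noisy polyline legitimately leaves chord lengths varying by up to
#'   the noise amplitude.
#' @return list of class `curvature_profile` with `kappa` (length V, 1/mm)
#'   and `delta_s` (mm).
#' @export
curvature_profile <- function(s, tol = 1) {
  s <- unclass(as.matrix(s))
  V <- nrow(s)
  if (V < 3L) stop("curvature needs at least 3 vertices")
  seg <- sqrt(rowSums(diff(s)^2))
  L <- sum(seg)
  ds <- L / (V - 1L)
  if (max(abs(seg - ds)) > tol * ds) {
    stop("streamline is not uniformly resampled; call resample_streamline() first")
  }
  mid <- 2:(V - 1L)
  d2 <- s[mid + 1L, , drop = FALSE] - 2 * s[mid, , drop = FALSE] +
    s[mid - 1L, , drop = FALSE]
  kappa <- c(0, sqrt(rowSums(d2 * d2)) / ds^2, 0)
  structure(list(kappa = kappa, delta_s = ds), class = "curvature_profile")
}

#' Mirror a bundle across the midsagittal plane
#'
#' Maps x to -x for every vertex and flips the hemisphere label. Mirroring
#' is required before rigid ICP between hemispheres: an arched bundle and
#' its reflection are not related by any rotation + translation.
#'
#' @param b a `tract_bundle`.
#' @return the mirrored bundle.
#' @export
mirror_bundle <- function(b) {
  b <- map_streamlines(b, function(s) {
    s[, 1L] <- -s[, 1L]
    s
  })
  b$hemisphere <- if (b$hemisphere == "left") "right" else "left"
  b
}

#' Define a spherical region of interest
#'
#' @param center 3-vector, world mm.
#' @param diameter sphere diameter in mm.
#' @param role one of `"endpoint_sphere"`, `"waypoint"`, `"exclusion"`.
#' @param label optional anatomical label (e.g. `"temporal"`); the label
#'   `"temporal"` also anchors the direction of the 1-D parameterization.
#' @export
roi_spec <- function(center, diameter,
                     role = c("endpoint_sphere", "waypoint", "exclusion"),
                     label = NULL) {
  role <- match.arg(role)
  stopifnot(length(center) == 3L, is.finite(diameter), diameter > 0)
  structure(list(center = as.numeric(center), diameter = as.numeric(diameter),
                 role = role, label = label), class = "roi_spec")
}

.inside_roi <- function(pts, roi) {
  d <- sweep(pts, 2L, roi$center)
  sqrt(rowSums(d * d)) < roi$diameter / 2
}

#' Dissect a bundle with spherical ROIs
#'
#' A streamline is retained iff (i) its two terminal vertices lie one in
#' each of the two endpoint spheres (in either orientation), (ii) at least
#' one vertex lies inside every waypoint ROI and (iii) no vertex lies inside
#' any exclusion ROI. "Inside" is strict Euclidean distance < radius;
#' "terminates" refers to the first/last vertex only.
#'
#' @param b a `tract_bundle`.
#' @param rois list of [roi_spec()] objects.
#' @return the filtered bundle (may error if empty afterwards).
#' @export
filter_by_rois <- function(b, rois) {
  roles <- vapply(rois, `[[`, "", "role")
  ends <- rois[roles == "endpoint_sphere"]
  ways <- rois[roles == "waypoint"]
  excl <- rois[roles == "exclusion"]
  if (length(ends) != 0L && length(ends) != 2L)
    stop("exactly two endpoint spheres are required when any is given")
  keep <- vapply(b$streamlines, function(s) {
    term <- s[c(1L, nrow(s)), , drop = FALSE]
    if (length(ends) == 2L) {
      inA <- .inside_roi(term, ends[[1L]])
      inB <- .inside_roi(term, ends[[2L]])
      ok_end <- (inA[1L] && inB[2L]) || (inA[2L] && inB[1L])
      if (!ok_end) return(FALSE)
    }
    for (w in ways) if (!any(.inside_roi(s, w))) return(FALSE)
    for (e in excl) if (any(.inside_roi(s, e))) return(FALSE)
    TRUE
  }, logical(1))
  if (!any(keep)) stop("no streamlines survive ROI dissection")
  b$streamlines <- b$streamlines[keep]
  b
}

#' Built-in arcuate fasciculus ROI presets (MNI mm)
#'
#' Endpoint spheres: temporal (20 mm diameter) and frontal (30 mm diameter),
#' per hemisphere, at the standard MNI coordinates used for AF dissection;
#' a fronto-parietal waypoint must be supplied per-study (it depends on the
#' central-sulcus level) and is therefore not part of the preset.
#'
#' @param hemisphere `"left"` or `"right"`.
#' @return list of two [roi_spec()] objects.
#' @export
af_roi_preset <- function(hemisphere = c("left", "right")) {
  hemisphere <- match.arg(hemisphere)
  if (hemisphere == "left") {
    list(roi_spec(c(-60, -45, 0), 20, "endpoint_sphere", label = "temporal"),
         roi_spec(c(-53, 27, 20), 30, "endpoint_sphere", label = "frontal"))
  } else {
    list(roi_spec(c(60, -43, -1), 20, "endpoint_sphere", label = "temporal"),
         roi_spec(c(49, 27, 20), 30, "endpoint_sphere", label = "frontal"))
  }
}

#' Harmonize streamline orientations within a bundle
#'
#' Flips any streamline whose endpoint order disagrees with the bundle
#' majority (first streamline seeds the reference; iterate once).
#'
#' @param b a `tract_bundle`, all streamlines with equal vertex count.
#' @return bundle with consistent vertex order.
#' @export
harmonize_orientation <- function(b) {
  ref <- unclass(b$streamlines[[1L]])
  b$streamlines <- lapply(b$streamlines, function(s) {
    s <- unclass(s)
    dd <- sum((s - ref)^2)
    dr <- sum((s[rev(seq_len(nrow(s))), , drop = FALSE] - ref)^2)
    if (dr < dd) s <- s[rev(seq_len(nrow(s))), , drop = FALSE]
    streamline(s)
  })
  b
}

#' Orient a bundle's streamlines toward an anatomical anchor
#'
#' Reverses the vertex order of any streamline whose last vertex lies
#' closer to `anchor` than its first, so vertex 1 is always the anchor
#' (e.g. temporal) end. Needed before orientation-preserving ICP: a planar
#' circular arc can be rigidly mapped onto itself end-for-end, so geometry
#' alone cannot fix which end is which across bundles.
#'
#' @param b a `tract_bundle`.
#' @param anchor 3-vector, world mm, near the desired first-vertex end.
#' @return the re-oriented bundle.
#' @export
orient_bundle_to_anchor <- function(b, anchor) {
  b$streamlines <- lapply(b$streamlines, function(s) {
    s <- unclass(s)
    d_first <- sum((s[1L, ] - anchor)^2)
    d_last <- sum((s[nrow(s), ] - anchor)^2)
    if (d_last < d_first) s <- s[rev(seq_len(nrow(s))), , drop = FALSE]
    streamline(s)
  })
  b
}

#' Medoid representative streamline of a bundle
#'
#' The member minimizing the summed mean point-to-point distance to all
#' other members. A medoid (rather than a mean curve) guarantees an
#' anatomically realized representative and is robust to residual outliers.
#'
#' @param b a `tract_bundle` with all streamlines resampled to a common
#'   vertex count and harmonized orientation.
#' @return the representative `streamline`.
#' @export
representative_streamline <- function(b) {
  ns <- n_streamlines(b)
  if (ns == 0L) stop("empty bundle")
  if (ns == 1L) return(b$streamlines[[1L]])
  V <- vapply(b$streamlines, nrow, integer(1))
  if (length(unique(V)) != 1L) stop("streamlines must share a vertex count")
  X <- t(vapply(b$streamlines, function(s) as.numeric(unclass(s)),
                numeric(3L * V[1L])))
  ## mean point-to-point distance decomposes per vertex
  total <- numeric(ns)
  for (v in seq_len(V[1L])) {
    cols <- c(v, v + V[1L], v + 2L * V[1L])
    total <- total + colSums(as.matrix(dist(X[, cols, drop = FALSE])) / V[1L])
  }
  b$streamlines[[which.min(total)]]
}

#' Rigid transform (rotation + translation)
#' @param rotation 3 x 3 orthonormal matrix, det +1.
#' @param translation length-3 vector (mm).
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (abs(det(rotation) - 1) > 1e-6 ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("rotation must be orthonormal with determinant +1")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to points, a streamline, or a bundle
#' @param tf a `rigid_transform`; @param x matrix of points or `tract_bundle`.
#' @export
apply_rigid <- function(tf, x) {
  f <- function(p) sweep(p %*% t(tf$rotation), 2L, tf$translation, "+")
  if (inherits(x, "tract_bundle")) return(map_streamlines(x, f))
  streamline_in <- inherits(x, "streamline")
  out <- f(unclass(as.matrix(x)))
  if (streamline_in) streamline(out) else out
}

## Kabsch: least-squares rotation+translation mapping P onto Q (rows paired)
.kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- crossprod(sweep(P, 2L, cp), sweep(Q, 2L, cq))
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(R, cq - as.numeric(R %*% cp))
}

#' Iterative closest point rigid registration
#'
#' Classical Besl-McKay ICP between two streamlines (or point sets) with
#' nearest-vertex correspondence and closed-form (Kabsch) rigid updates.
#' RMSD is non-increasing across iterations by construction.
#'
#' @param moving,fixed V x 3 matrices (typically resampled streamlines).
#' @param max_iter iteration cap (default 200).
#' @param tol stop when the RMSD improvement drops below this (mm, default 1e-6).
#' @param orientation `"free"` (default Besl-McKay: both end-to-end
#'   orientations are candidate initializations) or `"preserve"` (only the
#'   vertex-order-respecting initialization; use after
#'   [orient_bundle_to_anchor()] so that near-symmetric curves such as
#'   arcs cannot be aligned end-reversed).
#' @return a `rigid_transform` with attributes `rmsd` (final), `iterations`,
#'   and `converged` (`FALSE` triggers a warning, best-so-far is returned).
#' @export
icp_align <- function(moving, fixed, max_iter = 200L, tol = 1e-6,
                      orientation = c("free", "preserve")) {
  orientation <- match.arg(orientation)
  P0 <- unclass(as.matrix(moving)); Q <- unclass(as.matrix(fixed))
  ## initialization: identity, plus (for equal vertex counts, the
  ## representative-streamline case) the closed-form fits under index
  ## correspondence -- cheap insurance against the tangential-sliding
  ## local optima of curve-on-curve ICP
  inits <- list(rigid_transform())
  if (nrow(P0) == nrow(Q)) {
    inits <- c(inits, list(.kabsch(P0, Q)))
    if (orientation == "free")
      inits <- c(inits, list(
        .kabsch(P0[rev(seq_len(nrow(P0))), , drop = FALSE], Q)))
  }
  rmsd_of <- function(tf) {
    P <- apply_rigid(tf, P0)
    d2 <- outer(rowSums(P^2), rowSums(Q^2), "+") - 2 * tcrossprod(P, Q)
    sqrt(mean(pmax(apply(d2, 1L, min), 0)))
  }
  tf <- inits[[which.min(vapply(inits, rmsd_of, numeric(1)))]]
  P <- apply_rigid(tf, P0)
  rmsd_prev <- Inf
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    ## nearest-vertex correspondence
    d2 <- outer(rowSums(P^2), rowSums(Q^2), "+") - 2 * tcrossprod(P, Q)
    nn <- max.col(-d2, ties.method = "first")
    tf <- .kabsch(P0, Q[nn, , drop = FALSE])
    P <- apply_rigid(tf, P0)
    rmsd <- sqrt(mean(rowSums((P - Q[nn, , drop = FALSE])^2)))
    if (rmsd_prev - rmsd < tol) {
      converged <- TRUE
      break
    }
    rmsd_prev <- rmsd
  }
  if (!converged) warning("ICP did not converge; returning best-so-far transform")
  ## report rmsd under final correspondence
  d2 <- outer(rowSums(P^2), rowSums(Q^2), "+") - 2 * tcrossprod(P, Q)
  attr(tf, "rmsd") <- sqrt(mean(pmax(apply(d2, 1L, min), 0)))
  attr(tf, "iterations") <- it
  attr(tf, "converged") <- converged
  tf
}
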