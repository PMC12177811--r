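## Joint 1-D parameterization of pooled, co-aligned bundles: k-NN geodesic
## graph on landmark vertices, classical MDS (ISOMAP) to one dimension,
## nearest-landmark projection of the remaining vertices, [0,1] rescaling,
## core extraction and equal-width binning.

#' Jointly parameterize a set of co-aligned bundles
#'
#' All bundles (every subject, both hemispheres; right-side bundles already
#' mirrored and ICP-aligned into the common space) contribute their vertices
#' to one point cloud. A k-nearest-neighbour graph over at most
#' `n_landmarks` landmark vertices yields geodesic distances; classical MDS
#' of those distances gives the 1-D ISOMAP coordinate, which is affinely
#' rescaled to [0, 1]. Non-landmark vertices are projected by
#' inverse-distance interpolation over their 3 nearest landmarks.
#'
#' The coordinate's direction is anchored so that `anchor_point` (typically
#' the temporal endpoint-sphere center) maps near 0; without an anchor, the
#' majority streamline direction (first vertex -> low t) is used.
#'
#' @param bundles list of `tract_bundle`s in a common space.
#' @param knn neighbour count for the geodesic graph (default 10); doubled
#'   up to 4 times if the graph is disconnected.
#' @param n_landmarks landmark budget (default 1500).
#' @param anchor_point optional 3-vector, world mm.
#' @param n_bins number of bins (default 7).
#' @param seed seed for landmark subsampling.
#' @return a `joint_param` object: a `data.table` (columns `bundle`,
#'   `subject_id`, `hemisphere`, `streamline`, `vertex`, `t_raw`, `t`,
#'   `bin`) with attributes `core`, `n_bins`, `bin_edges`.
#' @export
joint_parameterize <- function(bundles, knn = 10L, n_landmarks = 1500L,
                               anchor_point = NULL, n_bins = 7L, seed = 1L) {
  stopifnot(length(bundles) >= 1L)
  tabs <- vector("list", length(bundles))
  for (bi in seq_along(bundles)) {
    bp <- bundle_points(bundles[[bi]])
    tabs[[bi]] <- data.table::data.table(
      bundle = bi, subject_id = bundles[[bi]]$subject_id,
      hemisphere = bundles[[bi]]$hemisphere,
      streamline = bp$streamline, vertex = bp$vertex,
      x = bp$points[, 1L], y = bp$points[, 2L], z = bp$points[, 3L])
  }
  tab <- data.table::rbindlist(tabs)
  pts <- as.matrix(tab[, c("x", "y", "z")])
  n <- nrow(pts)

  land_idx <- if (n > n_landmarks) {
    .with_seed(seed, sort(sample.int(n, n_landmarks)))
  } else seq_len(n)
  L <- pts[land_idx, , drop = FALSE]
  nl <- nrow(L)

  D2 <- outer(rowSums(L^2), rowSums(L^2), "+") - 2 * tcrossprod(L)
  D2[D2 < 0] <- 0
  Dl <- sqrt(D2)
  k <- min(as.integer(knn), nl - 1L)
  g <- NULL
  for (attempt in 1:4) {
    nnmat <- apply(Dl, 1L, function(row) order(row)[2:(k + 1L)])
    edges <- cbind(rep(seq_len(nl), each = k), as.integer(nnmat))
    w <- Dl[edges]
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    igraph::E(g)$weight <- w
    g <- igraph::simplify(g, edge.attr.comb = "min")
    if (igraph::components(g)$no == 1L) break
    if (attempt == 4L)
      stop("k-NN graph disconnected even after increasing k to ", k)
    k <- min(2L * k, nl - 1L)
  }
  geo <- igraph::distances(g)
  ## classical MDS to 1-D (first ISOMAP coordinate)
  t_land <- cmdscale(geo, k = 1L)[, 1L]

  ## project every vertex: inverse-distance weights over 3 nearest landmarks
  t_all <- numeric(n)
  chunk <- 4096L
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    P <- pts[s:e, , drop = FALSE]
    cd2 <- outer(rowSums(P^2), rowSums(L^2), "+") - 2 * tcrossprod(P, L)
    cd2[cd2 < 0] <- 0
    nn3 <- t(apply(cd2, 1L, function(row) order(row)[1:3]))
    w <- 1 / pmax(sqrt(cd2[cbind(rep(seq_len(nrow(P)), 3L), as.integer(nn3))]),
                  1e-9)
    w <- matrix(w, nrow(P), 3L)
    tv <- matrix(t_land[as.integer(nn3)], nrow(P), 3L)
    t_all[s:e] <- rowSums(w * tv) / rowSums(w)
  }

  rng <- range(t_all)
  if (diff(rng) <= 0) stop("degenerate embedding: zero spread")
  t_all <- (t_all - rng[1L]) / diff(rng)

  flip <- if (!is.null(anchor_point)) {
    d <- sqrt(colSums((t(pts) - anchor_point)^2))
    near <- d <= quantile(d, 0.05)
    mean(t_all[near]) > 0.5
  } else {
    mean(t_all[tab$vertex == max(tab$vertex)]) <
      mean(t_all[tab$vertex == 1L])
  }
  if (flip) t_all <- 1 - t_all

  tab[, c("x", "y", "z") := NULL]
  tab$t_raw <- t_all
  tab$t <- t_all
  tab$bin <- .assign_bins(t_all, n_bins)
  data.table::setattr(tab, "core", c(0, 1))
  data.table::setattr(tab, "n_bins", as.integer(n_bins))
  data.table::setattr(tab, "bin_edges", seq(0, 1, length.out = n_bins + 1L))
  data.table::setattr(tab, "class",
                      c("joint_param", class(data.table::data.table())))
  tab[]
}

## half-open bins [ (k-1)/K, k/K ), last bin closed at 1; NA passes through
.assign_bins <- function(t, n_bins) {
  b <- floor(t * n_bins) + 1L
  b[!is.na(t) & t >= 1] <- n_bins
  b[!is.na(t) & (t < 0 | t > 1)] <- NA_integer_
  as.integer(b)
}

#' Restrict a joint parameterization to its well-supported core
#'
#' The [0,1] coordinate is split into 0.01-wide cells; a cell is adequate
#' when at least `min_subject_coverage` of the bundles have a vertex in it
#' and it holds on average `min_vertex_density` vertices per bundle. The
#' largest contiguous run of adequate cells becomes the core, which is
#' re-normalized to [0,1]; vertices outside get `t = NA` and are excluded
#' from binning.
#'
#' @param jp a `joint_param`.
#' @param min_subject_coverage default 0.8.
#' @param min_vertex_density default 5 (vertices per bundle per cell).
#' @return the updated `joint_param` (attribute `core` holds the interval
#'   in raw-t units).
#' @export
extract_core <- function(jp, min_subject_coverage = 0.8,
                         min_vertex_density = 5) {
  n_bins <- attr(jp, "n_bins")
  cell <- pmin(floor(jp$t_raw * 100) + 1L, 100L)
  nb <- length(unique(jp$bundle))
  cov_ok <- dens_ok <- logical(100L)
  per_cell_bundles <- tapply(jp$bundle, cell, function(b) length(unique(b)))
  per_cell_count <- tapply(jp$bundle, cell, length)
  idx <- as.integer(names(per_cell_bundles))
  cov_ok[idx] <- per_cell_bundles / nb >= min_subject_coverage
  dens_ok[idx] <- per_cell_count / nb >= min_vertex_density
  ok <- cov_ok & dens_ok
  if (!any(ok)) stop("no adequate core cells; bundle too inconsistent")
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  best <- which(runs$values)[which.max(runs$lengths[runs$values])]
  lo <- (starts[best] - 1L) / 100
  hi <- ends[best] / 100
  if (hi - lo < 0.3)
    stop(sprintf("core [%.2f, %.2f] shorter than 0.3; bundle too inconsistent",
                 lo, hi))
  t_new <- (jp$t_raw - lo) / (hi - lo)
  t_new[t_new < 0 | t_new > 1] <- NA_real_
  jp$t <- t_new
  jp$bin <- .assign_bins(t_new, n_bins)
  data.table::setattr(jp, "core", c(lo, hi))
  jp[]
}

#' Per-bin mean scalar profile for one bundle
#'
#' @param jp a `joint_param` (core extracted or not).
#' @param bundle_index which bundle's vertices to aggregate.
#' @param values scalar per vertex of that bundle, in [bundle_points()]
#'   order (streamline-major); `NA` samples are dropped.
#' @return numeric vector of length `n_bins`; `NA` marks empty bins.
#' @export
bin_scalar_profile <- function(jp, bundle_index, values) {
  n_bins <- attr(jp, "n_bins")
  rows <- jp$bundle == bundle_index
  if (!any(rows)) stop("no such bundle in parameterization: ", bundle_index)
  bins <- jp$bin[rows]
  if (length(values) != sum(rows))
    stop("values length does not match bundle vertex count")
  out <- rep(NA_real_, n_bins)
  keep <- !is.na(bins) & !is.na(values)
  if (any(keep)) {
    m <- tapply(values[keep], bins[keep], mean)
    out[as.integer(names(m))] <- m
  }
  out
}

#' Normalize a bin profile by a skeleton mean
#'
#' Divides each bin mean (and any whole-tract mean appended to the profile)
#' by the subject's white-matter skeleton mean of the same metric, the
#' TBSS-style correction for global confounds such as age.
#'
#' @param row numeric vector of bin means.
#' @param skeleton_mean positive scalar.
#' @return normalized vector.
#' @export
normalize_profile <- function(row, skeleton_mean) {
  if (!is.finite(skeleton_mean) || skeleton_mean <= 0)
    stop("skeleton_mean must be positive")
  row / skeleton_mean
}
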