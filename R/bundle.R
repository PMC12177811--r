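#' @useDynLib tractcrowd, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cmdscale cor dist glm median pchisq pnorm pt qnorm quantile
#'   rnorm runif sd var binomial coef vcov logLik rbinom setNames aggregate
#' @importFrom utils head read.delim tail write.table
"_PACKAGE"

.datatable.aware <- TRUE

#' Construct a streamline
#'
#' A streamline is an ordered polyline through white matter, stored as a
#' numeric V x 3 matrix of world-space coordinates (mm, RAS). This is the
#' single internal coordinate convention; format-specific conventions (e.g.
#' TrackVis voxel-mm) are converted at the I/O boundary.
#'
#' @param points numeric V x 3 matrix (or coercible), V >= 2.
#' @return a `streamline` object (matrix with class attribute).
#' @export
streamline <- function(points) {
  pts <- as.matrix(points)
  storage.mode(pts) <- "double"
  if (ncol(pts) != 3L) stop("streamline points must be V x 3")
  if (nrow(pts) < 2L) stop("streamline needs at least 2 vertices")
  if (!all(is.finite(pts))) stop("streamline coordinates must be finite")
  if (max(abs(pts[-1L, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])) == 0)
    stop("degenerate streamline: all consecutive points identical")
  structure(pts, class = c("streamline", "matrix"))
}

#' Construct a fiber bundle
#'
#' @param streamlines list of V x 3 matrices (coerced via [streamline()]).
#' @param subject_id subject identifier.
#' @param hemisphere `"left"` or `"right"`.
#' @param tract_name tract label, e.g. `"AF"`.
#' @return a `tract_bundle` object.
#' @export
bundle <- function(streamlines, subject_id = "unknown",
                   hemisphere = c("left", "right"), tract_name = "AF") {
  hemisphere <- match.arg(hemisphere)
  if (length(streamlines) == 0L) stop("empty bundle")
  sl <- lapply(streamlines, streamline)
  structure(list(streamlines = sl, subject_id = subject_id,
                 hemisphere = hemisphere, tract_name = tract_name),
            class = "tract_bundle")
}

#' @export
print.tract_bundle <- function(x, ...) {
  nv <- vapply(x$streamlines, nrow, integer(1))
  cat(sprintf("<tract_bundle> %s / %s / %s: %d streamlines, %d-%d vertices\n",
              x$subject_id, x$hemisphere, x$tract_name,
              length(x$streamlines), min(nv), max(nv)))
  invisible(x)
}

#' @export
length.tract_bundle <- function(x) length(x$streamlines)

n_streamlines <- function(b) length(b$streamlines)

#' Stack all bundle vertices into one matrix
#'
#' @param b a `tract_bundle`.
#' @return list with `points` (N x 3), `streamline` (index per vertex),
#'   `vertex` (within-streamline index).
#' @export
bundle_points <- function(b) {
  nv <- vapply(b$streamlines, nrow, integer(1))
  pts <- do.call(rbind, b$streamlines)
  list(points = pts,
       streamline = rep.int(seq_along(nv), nv),
       vertex = unlist(lapply(nv, seq_len), use.names = FALSE))
}

#' Apply a function to every streamline of a bundle
#' @param b a `tract_bundle`; @param f function matrix -> matrix.
#' @return the transformed bundle.
#' @keywords internal
map_streamlines <- function(b, f) {
  b$streamlines <- lapply(b$streamlines, function(s) streamline(f(s)))
  b
}
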