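## Minimal NIfTI-1 I/O for scalar maps (FA/MD/RD/AD), plus world-space
## trilinear sampling. Little-endian .nii / .nii.gz, single 3-D volume;
## sform preferred, qform quaternion fallback. This is deliberately a small
## subset of the standard -- enough to round-trip the maps this pipeline
## consumes and to interoperate with nibabel/FSL outputs.

#' Construct a scalar volume
#'
#' @param data 3-D numeric array of scalar values.
#' @param affine 4 x 4 voxel-to-world (RAS mm) matrix; must be invertible.
#'   Voxel indices are 0-based voxel centers, the NIfTI convention.
#' @param metric metric name (`"FA"`, `"MD"`, ...).
#' @export
scalar_volume <- function(data, affine = diag(4), metric = "FA") {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("scalar volume must be a 3-D array")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("affine must be 4 x 4")
  if (abs(det(affine)) < 1e-12) stop("affine is not invertible")
  structure(list(data = data, affine = affine, metric = metric),
            class = "scalar_volume")
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat(sprintf("<scalar_volume> %s: %s voxels\n", x$metric,
              paste(dim(x$data), collapse = " x ")))
  invisible(x)
}

#' Write a scalar volume as NIfTI-1 (.nii or .nii.gz)
#'
#' Data are stored as float32 with an sform affine (code 1).
#'
#' @param vol a [scalar_volume()].
#' @param path output path; a `.gz` suffix enables gzip compression.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path) {
  dims <- dim(vol$data)
  aff <- vol$affine
  pixdim <- sqrt(colSums(aff[1:3, 1:3]^2))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w_f32 <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)
  w_i32(348L)                    # sizeof_hdr
  w_raw(10L + 18L + 4L + 2L + 1L + 1L)  # data_type..dim_info
  w_i16(c(3L, dims, 1L, 1L, 1L, 1L))    # dim[8]
  w_f32(c(0, 0, 0)); w_i16(0L)          # intent
  w_i16(16L); w_i16(32L)                # datatype float32, bitpix
  w_i16(0L)                             # slice_start
  w_f32(c(1, pixdim, 1, 1, 1, 1))       # pixdim[8]
  w_f32(352); w_f32(1); w_f32(0)        # vox_offset, scl_slope, scl_inter
  w_i16(0L); w_raw(2L)                  # slice_end, slice_code, xyzt_units
  w_f32(c(0, 0, 0, 0))                  # cal_max..toffset
  w_i32(c(0L, 0L))                      # glmax, glmin
  desc <- charToRaw(sprintf("tractcrowd %s map", vol$metric))
  writeBin(c(desc, raw(80L - length(desc))), con)
  w_raw(24L)                            # aux_file
  w_i16(0L); w_i16(1L)                  # qform_code 0, sform_code 1
  w_f32(numeric(6L))                    # quaternion + qoffset
  w_f32(aff[1L, ]); w_f32(aff[2L, ]); w_f32(aff[3L, ])
  w_raw(16L)                            # intent_name
  writeBin(c(charToRaw("n+1"), raw(1L)), con)   # magic
  w_raw(4L)                             # extension indicator
  w_f32(as.numeric(vol$data))
  invisible(path)
}

.quat_to_affine <- function(b, c_, d, qoffset, pixdim, qfac) {
  a2 <- 1 - b^2 - c_^2 - d^2
  a <- sqrt(max(a2, 0))
  R <- matrix(c(
    a^2 + b^2 - c_^2 - d^2, 2 * (b * c_ - a * d), 2 * (b * d + a * c_),
    2 * (b * c_ + a * d), a^2 + c_^2 - b^2 - d^2, 2 * (c_ * d - a * b),
    2 * (b * d - a * c_), 2 * (c_ * d + a * b), a^2 + d^2 - b^2 - c_^2
  ), 3L, 3L, byrow = TRUE)
  R <- R %*% diag(c(pixdim[1:2], qfac * pixdim[3L]))
  rbind(cbind(R, qoffset), c(0, 0, 0, 1))
}

#' Read a NIfTI-1 scalar volume (.nii or .nii.gz)
#'
#' Supports little-endian single-frame volumes with datatypes uint8, int16,
#' int32, float32 and float64; `scl_slope`/`scl_inter` are applied.
#'
#' @param path input path.
#' @param metric metric name attached to the result.
#' @return a [scalar_volume()].
#' @export
read_nifti <- function(path, metric = "FA") {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- gzfile(path, "rb")     # reads plain files too
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop("malformed NIfTI header (truncated): ", path)
  r_i32 <- function(off) readBin(hdr[(off + 1L):(off + 4L)], "integer",
                                 size = 4L, endian = "little")
  r_i16 <- function(off, n = 1L) readBin(hdr[(off + 1L):(off + 2L * n)],
                                         "integer", size = 2L, n = n,
                                         endian = "little")
  r_f32 <- function(off, n = 1L) readBin(hdr[(off + 1L):(off + 4L * n)],
                                         "numeric", size = 4L, n = n,
                                         endian = "little")
  if (r_i32(0L) != 348L)
    stop("unsupported NIfTI file (not little-endian NIfTI-1): ", path)
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("malformed NIfTI magic: ", path)
  dim8 <- r_i16(40L, 8L)
  ndim <- dim8[1L]
  if (ndim < 3L || any(dim8[5:8] > 1L))
    stop("only single-frame 3-D volumes are supported")
  dims <- dim8[2:4]
  datatype <- r_i16(70L)
  pixdim <- r_f32(76L, 8L)
  vox_offset <- r_f32(108L)
  scl_slope <- r_f32(112L); scl_inter <- r_f32(116L)
  qform_code <- r_i16(252L); sform_code <- r_i16(254L)
  if (sform_code > 0L) {
    aff <- rbind(matrix(r_f32(280L, 12L), 3L, 4L, byrow = TRUE), c(0, 0, 0, 1))
  } else if (qform_code > 0L) {
    q <- r_f32(256L, 6L)
    qfac <- if (pixdim[1L] == -1) -1 else 1
    aff <- .quat_to_affine(q[1L], q[2L], q[3L], q[4:6], pixdim[2:4], qfac)
  } else {
    aff <- diag(c(pixdim[2:4], 1))
  }
  skip <- vox_offset - 348L
  if (skip > 0L) invisible(readBin(con, "raw", n = skip))
  nvox <- prod(dims)
  data <- switch(as.character(datatype),
    "2"  = as.numeric(readBin(con, "integer", n = nvox, size = 1L, signed = FALSE)),
    "4"  = as.numeric(readBin(con, "integer", n = nvox, size = 2L, endian = "little")),
    "8"  = as.numeric(readBin(con, "integer", n = nvox, size = 4L, endian = "little")),
    "16" = readBin(con, "numeric", n = nvox, size = 4L, endian = "little"),
    "64" = readBin(con, "numeric", n = nvox, size = 8L, endian = "little"),
    stop("unsupported NIfTI datatype: ", datatype))
  if (length(data) != nvox) stop("truncated NIfTI data: ", path)
  if (!is.na(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    data <- data * scl_slope + scl_inter
  scalar_volume(array(data, dims), aff, metric = metric)
}

#' Sample a scalar volume at world-space points
#'
#' Points are mapped to voxel space with the inverse affine and sampled by
#' trilinear interpolation. Points outside the grid (or falling on non-finite
#' voxels) yield `NA`, never an error; downstream profile means drop them.
#'
#' @param volume a [scalar_volume()].
#' @param points N x 3 matrix of world-mm coordinates.
#' @return numeric vector of length N with `NA` for out-of-volume samples.
#' @export
sample_scalar_at_points <- function(volume, points) {
  pts <- unclass(as.matrix(points))
  if (ncol(pts) != 3L) stop("points must be N x 3")
  if (!all(is.finite(pts))) stop("points must be finite")
  inv <- solve(volume$affine)
  vox <- sweep(pts %*% t(inv[1:3, 1:3]), 2L, inv[1:3, 4L], "+")
  dims <- dim(volume$data)
  ok <- vox[, 1L] >= 0 & vox[, 1L] <= dims[1L] - 1 &
        vox[, 2L] >= 0 & vox[, 2L] <= dims[2L] - 1 &
        vox[, 3L] >= 0 & vox[, 3L] <= dims[3L] - 1
  out <- rep(NA_real_, nrow(pts))
  if (!any(ok)) return(out)
  v <- vox[ok, , drop = FALSE]
  i0 <- pmin(floor(v), dims[col(v)] - 2)   # keep i0+1 in range at upper face
  i0 <- pmax(i0, 0)
  f <- v - i0
  g <- function(dx, dy, dz) {
    volume$data[cbind(i0[, 1L] + dx + 1L, i0[, 2L] + dy + 1L,
                      i0[, 3L] + dz + 1L)]
  }
  val <-
    g(0, 0, 0) * (1 - f[, 1]) * (1 - f[, 2]) * (1 - f[, 3]) +
    g(1, 0, 0) * f[, 1] * (1 - f[, 2]) * (1 - f[, 3]) +
    g(0, 1, 0) * (1 - f[, 1]) * f[, 2] * (1 - f[, 3]) +
    g(0, 0, 1) * (1 - f[, 1]) * (1 - f[, 2]) * f[, 3] +
    g(1, 1, 0) * f[, 1] * f[, 2] * (1 - f[, 3]) +
    g(1, 0, 1) * f[, 1] * (1 - f[, 2]) * f[, 3] +
    g(0, 1, 1) * (1 - f[, 1]) * f[, 2] * f[, 3] +
    g(1, 1, 1) * f[, 1] * f[, 2] * f[, 3]
  out[ok] <- val
  out
}
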