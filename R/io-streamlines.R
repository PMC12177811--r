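## Tractography file formats.
##
## TCK (MRtrix): text key-value header, then little-endian float32 triplets;
## streamlines separated by a NaN triplet, file terminated by an Inf triplet.
## Coordinates are already world mm (RAS).
##
## TRK (TrackVis, v2): fixed 1000-byte binary header carrying a vox_to_ras
## affine; coordinates are stored in "voxel-mm" with the origin at the CORNER
## of voxel (0,0,0), i.e. world = M %*% (p / voxel_size - 0.5). Converted to
## world mm at this boundary so the rest of the package never sees it.

#' Read a streamline bundle from TCK or TRK
#'
#' @param path file path.
#' @param dialect `"tck"`, `"trk"`, or `NULL` to infer from the extension.
#' @param subject_id,hemisphere,tract_name metadata attached to the bundle.
#' @return a [bundle()] with coordinates in world mm (RAS).
#' @export
read_streamlines <- function(path, dialect = NULL, subject_id = "unknown",
                             hemisphere = "left", tract_name = "AF") {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(dialect)) {
    dialect <- tolower(sub(".*\\.", "", path))
  }
  sl <- switch(dialect,
               tck = .read_tck(path),
               trk = .read_trk(path),
               stop("unknown streamline dialect: ", dialect))
  if (length(sl) == 0L) stop("empty bundle in ", path)
  bundle(sl, subject_id = subject_id, hemisphere = hemisphere,
         tract_name = tract_name)
}

#' Write a streamline bundle to TCK or TRK
#'
#' @param b a `tract_bundle` (world mm RAS).
#' @param path output path; extension selects the format unless `dialect` is
#'   given.
#' @param dialect `"tck"`, `"trk"` or `NULL`.
#' @param affine 4 x 4 voxel-to-world matrix stored in the TRK header
#'   (defaults to 1 mm isotropic with origin chosen to cover the bundle).
#' @return `path`, invisibly.
#' @export
write_streamlines <- function(b, path, dialect = NULL, affine = NULL) {
  if (is.null(dialect)) dialect <- tolower(sub(".*\\.", "", path))
  switch(dialect,
         tck = .write_tck(b$streamlines, path),
         trk = .write_trk(b$streamlines, path, affine),
         stop("unknown streamline dialect: ", dialect))
  invisible(path)
}

.read_tck <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  ## header is ASCII up to a line reading "END"; locate it in the raw bytes
  ## (the binary payload that follows is not valid text)
  pat <- charToRaw("\nEND\n")
  limit <- min(length(raw), 8192L)
  cand <- which(raw[seq_len(limit)] == pat[1L])
  end_at <- NA_integer_
  for (p in cand) {
    if (p + 4L <= length(raw) && identical(raw[p:(p + 4L)], pat)) {
      end_at <- p
      break
    }
  }
  if (is.na(end_at)) stop("malformed TCK header (no END): ", path)
  hdr <- strsplit(rawToChar(raw[seq_len(end_at - 1L)]), "\n",
                  fixed = TRUE)[[1L]]
  if (length(hdr) == 0L || !grepl("^mrtrix tracks", hdr[1L]))
    stop("malformed TCK header (bad magic): ", path)
  kv <- hdr[grepl(":", hdr, fixed = TRUE)]
  keys <- trimws(sub(":.*$", "", kv))
  vals <- trimws(sub("^[^:]*:", "", kv))
  dt <- vals[match("datatype", keys)]
  if (is.na(dt) || !dt %in% c("Float32LE", "Float32BE"))
    stop("unsupported TCK datatype: ", dt)
  endian <- if (dt == "Float32LE") "little" else "big"
  off_field <- vals[match("file", keys)]
  if (is.na(off_field)) stop("malformed TCK header (no file offset)")
  offset <- as.integer(sub("^\\.\\s*", "", off_field))
  if (is.na(offset) || offset > length(raw)) stop("malformed TCK header offset")
  v <- readBin(raw[(offset + 1L):length(raw)], "numeric", size = 4L,
               n = (length(raw) - offset) %/% 4L, endian = endian)
  if (length(v) %% 3L != 0L) stop("truncated TCK data: ", path)
  m <- matrix(v, ncol = 3L, byrow = TRUE)
  if (!any(is.infinite(m[, 1L]))) stop("truncated TCK data (no terminator): ", path)
  .split_nan_separated(m)
}

.split_nan_separated <- function(m) {
  stop_at <- which(is.infinite(m[, 1L]))[1L]
  m <- m[seq_len(stop_at - 1L), , drop = FALSE]
  sep <- is.nan(m[, 1L])
  grp <- cumsum(c(TRUE, sep[-length(sep)]))
  out <- lapply(split.data.frame(m[!sep, , drop = FALSE], grp[!sep]), as.matrix)
  names(out) <- NULL
  out[vapply(out, nrow, integer(1)) >= 2L]
}

.write_tck <- function(streamlines, path) {
  n <- length(streamlines)
  mk_hdr <- function(offset) {
    paste0("mrtrix tracks\ndatatype: Float32LE\ncount: ", n,
           "\nfile: . ", offset, "\nEND\n")
  }
  offset <- nchar(mk_hdr(0L))
  while (nchar(mk_hdr(offset)) != offset) offset <- nchar(mk_hdr(offset))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(mk_hdr(offset), con, eos = NULL)
  for (s in streamlines) {
    writeBin(as.numeric(t(unclass(s))), con, size = 4L, endian = "little")
    writeBin(rep(NaN, 3L), con, size = 4L, endian = "little")
  }
  writeBin(rep(Inf, 3L), con, size = 4L, endian = "little")
}

.trk_default_affine <- function(streamlines) {
  pts <- do.call(rbind, lapply(streamlines, unclass))
  lo <- floor(apply(pts, 2L, min)) - 5
  aff <- diag(4)
  aff[1:3, 4L] <- lo
  aff
}

.write_trk <- function(streamlines, path, affine = NULL) {
  if (is.null(affine)) affine <- .trk_default_affine(streamlines)
  voxel_size <- sqrt(colSums(affine[1:3, 1:3]^2))
  inv <- solve(affine)
  pts <- do.call(rbind, lapply(streamlines, unclass))
  vox <- sweep(pts %*% t(inv[1:3, 1:3]), 2L, inv[1:3, 4L], "+")
  dim3 <- pmax(as.integer(ceiling(apply(vox, 2L, max))) + 2L, 1L)

  con <- file(path, "wb")
  on.exit(close(con))
  wchar <- function(s, width) {
    r <- charToRaw(s)
    writeBin(c(r[seq_len(min(length(r), width))],
               raw(max(0L, width - length(r)))), con)
  }
  wchar("TRACK", 6L)
  writeBin(as.integer(dim3), con, size = 2L, endian = "little")
  writeBin(as.numeric(voxel_size), con, size = 4L, endian = "little")
  writeBin(numeric(3L), con, size = 4L, endian = "little")   # origin (unused)
  writeBin(0L, con, size = 2L, endian = "little")            # n_scalars
  wchar("", 200L)
  writeBin(0L, con, size = 2L, endian = "little")            # n_properties
  wchar("", 200L)
  writeBin(as.numeric(t(affine)), con, size = 4L, endian = "little")
  wchar("", 444L)                                            # reserved
  wchar("RAS", 4L)                                           # voxel_order
  wchar("", 4L)                                              # pad2
  writeBin(c(1, 0, 0, 0, 1, 0), con, size = 4L, endian = "little")
  wchar("", 2L)                                              # pad1
  writeBin(raw(6L), con)                                     # invert/swap flags
  writeBin(length(streamlines), con, size = 4L, endian = "little")
  writeBin(2L, con, size = 4L, endian = "little")            # version
  writeBin(1000L, con, size = 4L, endian = "little")         # hdr_size
  for (s in streamlines) {
    s <- unclass(s)
    v <- sweep(s %*% t(inv[1:3, 1:3]), 2L, inv[1:3, 4L], "+")  # voxel centers
    voxmm <- sweep(v + 0.5, 2L, voxel_size, "*")
    writeBin(nrow(s), con, size = 4L, endian = "little")
    writeBin(as.numeric(t(voxmm)), con, size = 4L, endian = "little")
  }
}

.read_trk <- function(path) {
  sz <- file.size(path)
  if (is.na(sz) || sz < 1000L) stop("malformed TRK file (too small): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 6L)
  if (rawToChar(magic[1:5]) != "TRACK") stop("malformed TRK header: ", path)
  invisible(readBin(con, "integer", n = 3L, size = 2L, endian = "little"))
  voxel_size <- readBin(con, "numeric", n = 3L, size = 4L, endian = "little")
  invisible(readBin(con, "numeric", n = 3L, size = 4L, endian = "little"))
  n_scalars <- readBin(con, "integer", n = 1L, size = 2L, endian = "little")
  invisible(readBin(con, "raw", n = 200L))
  n_props <- readBin(con, "integer", n = 1L, size = 2L, endian = "little")
  invisible(readBin(con, "raw", n = 200L))
  aff <- matrix(readBin(con, "numeric", n = 16L, size = 4L, endian = "little"),
                4L, 4L, byrow = TRUE)
  invisible(readBin(con, "raw", n = 444L + 4L + 4L + 24L + 2L + 6L))
  n_count <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  version <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  hdr_size <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (hdr_size != 1000L) stop("malformed TRK header (hdr_size != 1000): ", path)
  if (version < 2L || all(aff == 0)) {
    stop("TRK file lacks a vox_to_ras affine (version < 2); cannot map to world mm")
  }
  if (any(voxel_size <= 0)) stop("malformed TRK header (voxel_size)")
  out <- list()
  repeat {
    np <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    if (length(np) == 0L) break
    if (np < 0L) stop("truncated TRK data: ", path)
    vals <- readBin(con, "numeric", n = np * (3L + n_scalars) + n_props,
                    size = 4L, endian = "little")
    if (length(vals) != np * (3L + n_scalars) + n_props)
      stop("truncated TRK data: ", path)
    m <- matrix(vals[seq_len(np * (3L + n_scalars))],
                ncol = 3L + n_scalars, byrow = TRUE)[, 1:3, drop = FALSE]
    vox <- sweep(m, 2L, voxel_size, "/") - 0.5
    world <- sweep(vox %*% t(aff[1:3, 1:3]), 2L, aff[1:3, 4L], "+")
    if (np >= 2L) out[[length(out) + 1L]] <- world
  }
  if (n_count > 0L && length(out) != n_count)
    stop("truncated TRK data (count mismatch): ", path)
  out
}
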