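#' Construct a point cloud
#'
#' A point cloud is the universal input of every index in this package: an
#' N x 3 matrix of (x, y, z) coordinates in meters, plus a source label.
#' Clouds are expected to be height-normalized (z = height above ground)
#' with ground returns removed; a warning is issued when min(z) < -0.5 m,
#' which usually indicates an un-normalized cloud.
#'
#' @param points numeric matrix (or data frame) with at least 3 columns,
#'   taken as x, y, z in meters.
#' @param source_id character label identifying the plot or file.
#' @return An object of class \code{point_cloud}: a list with elements
#'   \code{points} (N x 3 numeric matrix, columns \code{x,y,z}) and
#'   \code{source_id}.
#' @export
point_cloud <- function(points, source_id = "cloud") {
  points <- as.matrix(points)
  if (ncol(points) < 3L) stop("point cloud needs 3 coordinate columns")
  points <- points[, 1:3, drop = FALSE]
  storage.mode(points) <- "double"
  if (nrow(points) < 1L) stop("empty point cloud: need at least 1 point")
  if (!all(is.finite(points))) stop("point cloud contains non-finite coordinates")
  colnames(points) <- c("x", "y", "z")
  rownames(points) <- NULL
  if (min(points[, 3L]) < -0.5) {
    warning("min z < -0.5 m: cloud may not be height-normalized", call. = FALSE)
  }
  structure(list(points = points, source_id = as.character(source_id)[1L]),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  bb <- bounding_box(x)
  cat(sprintf("point_cloud '%s': %d points\n", x$source_id, nrow(x$points)))
  cat(sprintf("  extent (m): dx=%.3f dy=%.3f dz=%.3f\n",
              bb$extents[1L], bb$extents[2L], bb$extents[3L]))
  invisible(x)
}

#' Number of points in a cloud
#' @param cloud a \code{point_cloud}.
#' @return integer point count.
#' @export
n_points <- function(cloud) nrow(cloud$points)

#' Axis-aligned bounding box of a cloud
#'
#' @param cloud a \code{point_cloud}.
#' @return list with \code{min_corner}, \code{max_corner} and
#'   \code{extents} (all length-3 numeric, meters).
#' @export
bounding_box <- function(cloud) {
  stopifnot(inherits(cloud, "point_cloud"))
  mn <- c(min(cloud$points[, 1L]), min(cloud$points[, 2L]), min(cloud$points[, 3L]))
  mx <- c(max(cloud$points[, 1L]), max(cloud$points[, 2L]), max(cloud$points[, 3L]))
  names(mn) <- names(mx) <- c("x", "y", "z")
  list(min_corner = mn, max_corner = mx, extents = mx - mn)
}

#' Crop a cloud to a square plot window
#'
#' Keeps the points inside the closed axis-aligned square of the given side
#' centred at \code{center_xy}; all heights are kept (a vertical column).
#' Boundary points are retained (closed interval on both edges).
#'
#' @param cloud a \code{point_cloud}.
#' @param center_xy numeric length-2, plot centre (x, y) in meters.
#' @param side plot side length in meters (> 0).
#' @return the cropped \code{point_cloud}.
#' @export
crop_to_plot <- function(cloud, center_xy, side) {
  stopifnot(inherits(cloud, "point_cloud"), side > 0, length(center_xy) >= 2L)
  h <- side / 2
  keep <- abs(cloud$points[, 1L] - center_xy[1L]) <= h &
          abs(cloud$points[, 2L] - center_xy[2L]) <= h
  if (!any(keep)) stop("empty point cloud: no points inside the crop window")
  point_cloud(cloud$points[keep, , drop = FALSE], cloud$source_id)
}

#' Read a point cloud from disk
#'
#' Supports plain-text XYZ (whitespace- or comma-separated; the first three
#' numeric columns are taken as x, y, z; an optional header line and extra
#' columns are ignored) and uncompressed LAS (versions 1.1-1.4, any point
#' record format; only x, y, z are consumed). Compressed LAZ is not
#' supported: decompress to LAS (e.g. with laszip) or export XYZ first.
#'
#' @param path file path.
#' @param format one of \code{"auto"} (by extension), \code{"xyz"},
#'   \code{"las"}, \code{"laz"}.
#' @param source_id label for the cloud; defaults to the file name.
#' @return a \code{point_cloud}.
#' @export
read_point_cloud <- function(path, format = c("auto", "xyz", "las", "laz"),
                             source_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read point cloud: no such file: ", path)
  if (is.null(source_id)) source_id <- sub("\\.[^.]*$", "", basename(path))
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", basename(path)))
    format <- if (ext %in% c("las", "laz")) ext else "xyz"
  }
  pts <- switch(format,
    xyz = read_xyz_matrix(path),
    las = read_las_matrix(path),
    laz = stop("LAZ (compressed LAS) is not supported: decompress '", path,
               "' to .las or export XYZ text")
  )
  if (is.null(pts) || nrow(pts) == 0L) {
    stop("empty point cloud: no points parsed from ", path)
  }
  point_cloud(pts, source_id)
}

read_xyz_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty point cloud: file has no content: ", path)
  toks <- strsplit(trimws(first), "[,;[:space:]]+")[[1L]]
  has_header <- any(is.na(suppressWarnings(as.numeric(toks[seq_len(min(3L, length(toks)))]))))
  dt <- data.table::fread(path, header = FALSE, skip = if (has_header) 1L else 0L,
                          data.table = FALSE, showProgress = FALSE)
  if (nrow(dt) == 0L) stop("empty point cloud: no data rows in ", path)
  numeric_cols <- which(vapply(dt, is.numeric, logical(1L)))
  if (length(numeric_cols) < 3L) {
    stop("cannot read point cloud: fewer than 3 numeric columns in ", path)
  }
  as.matrix(dt[, numeric_cols[1:3], drop = FALSE])
}

#' Write a point cloud to disk
#'
#' XYZ is written as three whitespace-separated columns with no header.
#' LAS is written as an uncompressed LAS 1.2 file, point record format 0,
#' scale 0.001 m (millimeter quantization), offsets at the cloud minimum.
#'
#' @param cloud a \code{point_cloud}.
#' @param path output file path.
#' @param format \code{"auto"} (by extension), \code{"xyz"} or \code{"las"}.
#' @return \code{path}, invisibly.
#' @export
write_point_cloud <- function(cloud, path, format = c("auto", "xyz", "las")) {
  stopifnot(inherits(cloud, "point_cloud"))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", basename(path)))
    format <- if (ext == "las") "las" else "xyz"
  }
  if (format == "xyz") {
    data.table::fwrite(data.table::as.data.table(cloud$points), path,
                       sep = " ", col.names = FALSE)
  } else {
    write_las_matrix(cloud$points, path)
  }
  invisible(path)
}

# --- minimal LAS reader/writer (uncompressed, xyz only) ---------------------
# LAS stores coordinates as int32 counts of a scale unit plus an offset;
# only the header fields needed to locate and decode point records are read.

read_las_matrix <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 227L) stop("cannot read point cloud: truncated LAS file: ", path)
  sig <- rawToChar(raw[1:4])
  if (sig != "LASF") stop("cannot read point cloud: not a LAS file (bad signature): ", path)
  u16 <- function(off) readBin(raw[(off + 1L):(off + 2L)], "integer", size = 2L,
                               signed = FALSE, endian = "little")
  u32 <- function(off) {
    v <- readBin(raw[(off + 1L):(off + 4L)], "integer", size = 4L, endian = "little")
    if (v < 0) v + 2^32 else as.numeric(v)
  }
  f64 <- function(off) readBin(raw[(off + 1L):(off + 8L)], "double", size = 8L,
                               endian = "little")
  ver_major <- as.integer(raw[25L]); ver_minor <- as.integer(raw[26L])
  off_points <- u32(96L)
  pt_format  <- as.integer(raw[105L]) %% 128L  # high bit flags LAZ compression
  if (as.integer(raw[105L]) >= 128L) {
    stop("LAZ (compressed LAS) is not supported: decompress '", path, "' to .las")
  }
  rec_len <- u16(105L)
  n_legacy <- u32(107L)
  scale  <- c(f64(131L), f64(139L), f64(147L))
  offset <- c(f64(155L), f64(163L), f64(171L))
  n <- n_legacy
  if (n == 0 && ver_major == 1L && ver_minor >= 4L && length(raw) >= 247L) {
    lo <- u32(247L); hi <- u32(251L)
    n <- hi * 2^32 + lo
  }
  if (n == 0) stop("empty point cloud: LAS file declares zero points: ", path)
  need <- off_points + n * rec_len
  if (length(raw) < need) stop("cannot read point cloud: truncated LAS point data: ", path)
  starts <- off_points + (seq_len(n) - 1) * rec_len
  coord <- matrix(0, nrow = n, ncol = 3L)
  for (d in 1:3) {
    idx <- as.vector(outer(1:4 + (d - 1L) * 4L, starts, `+`))
    ints <- readBin(raw[idx], "integer", n = n, size = 4L, endian = "little")
    coord[, d] <- ints * scale[d] + offset[d]
  }
  coord
}

write_las_matrix <- function(pts, path, scale = 1e-3) {
  n <- nrow(pts)
  mins <- apply(pts, 2L, min); maxs <- apply(pts, 2L, max)
  header_size <- 227L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("LASF", con, nchars = 4L, eos = NULL)
  writeBin(rep(0L, 2L), con, size = 2L)                       # source id, encoding
  writeBin(rep(0L, 4L), con, size = 4L)                       # guid (16 bytes)
  writeBin(as.raw(c(1L, 2L)), con)                            # version 1.2
  sysid <- charToRaw(sprintf("%-32s", "canopycomplexity"))
  gensw <- charToRaw(sprintf("%-32s", "canopycomplexity"))
  writeBin(sysid[1:32], con); writeBin(gensw[1:32], con)
  writeBin(c(1L, 2026L), con, size = 2L)                      # day, year
  writeBin(header_size, con, size = 2L)                       # header size
  writeBin(header_size, con, size = 4L)                       # offset to points
  writeBin(0L, con, size = 4L)                                # n VLRs
  writeBin(as.raw(0L), con)                                   # point format 0
  writeBin(20L, con, size = 2L)                               # record length
  writeBin(n, con, size = 4L)                                 # legacy point count
  writeBin(rep(0L, 5L), con, size = 4L)                       # points by return
  writeBin(rep(scale, 3L), con, size = 8L)                    # x/y/z scale
  writeBin(mins, con, size = 8L)                              # x/y/z offset
  writeBin(c(maxs[1L], mins[1L], maxs[2L], mins[2L], maxs[3L], mins[3L]),
           con, size = 8L)                                    # min/max pairs
  rec <- matrix(0L, nrow = 5L, ncol = n)                      # 20 bytes = 5 int32
  for (d in 1:3) rec[d, ] <- as.integer(round((pts[, d] - mins[d]) / scale))
  writeBin(as.vector(rec), con, size = 4L, endian = "little")
  invisible(path)
}

# --- index-record table I/O -------------------------------------------------

index_record_columns <- c("source_id", "n_points", "db", "ce", "ce_xy", "ce_xz",
                          "ce_yz", "sdb_detected", "final_voxel_size", "t_db", "t_ce")

#' Write a table of per-cloud index records as CSV
#'
#' One row per cloud, with the fixed header
#' \code{source_id,n_points,db,ce,ce_xy,ce_xz,ce_yz,sdb_detected,final_voxel_size,t_db,t_ce}.
#' Extra columns (such as a \code{site} label) are appended after the fixed ones.
#'
#' @param records data frame of index records.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_index_records <- function(records, path) {
  missing_cols <- setdiff(index_record_columns, names(records))
  if (length(missing_cols)) {
    stop("index record table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(names(records), index_record_columns)
  data.table::fwrite(records[, c(index_record_columns, extra), drop = FALSE], path)
  invisible(path)
}

#' Read a per-cloud index record CSV written by \code{write_index_records}
#' @param path CSV path.
#' @return data frame of index records.
#' @export
read_index_records <- function(path) {
  data.table::fread(path, data.table = FALSE)
}
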