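#' Read a tractogram from TCK or TRK
#'
#' Streamlines are returned in world RAS millimeters regardless of the
#' on-disk dialect: TCK stores world mm natively, while TRK stores
#' voxel-mm coordinates (corner-anchored) that are converted through the
#' header's voxel-to-world matrix at load. Streamline count and per-streamline
#' point counts are preserved; consecutive duplicate points are dropped with
#' a warning and sub-2-point streamlines are rejected.
#'
#' @param path file path.
#' @param format `"tck"`, `"trk"` or `"auto"` (sniff the magic bytes, then
#'   the extension).
#' @param ref optional [spatial_reference()]. TRK files carry their own grid
#'   and ignore this; TCK files carry none, so either supply one or a
#'   1 mm isotropic grid bounding the streamlines (2-voxel pad) is built.
#' @return A [tractogram()].
#' @export
read_tractogram <- function(path, format = c("auto", "tck", "trk"), ref = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") format <- sniff_format(path)
  switch(format,
    tck = read_tck(path, ref = ref),
    trk = read_trk(path)
  )
}

#' Write a tractogram to TCK or TRK
#'
#' The inverse of [read_tractogram()]: a written file reloads to the same
#' streamlines within float32 precision. TRK output converts world mm back
#' to the voxel-mm dialect using the tractogram's spatial reference, which is
#' stored in the header.
#'
#' @param t a [tractogram()].
#' @param path output file path.
#' @param format `"tck"`, `"trk"` or `"auto"` (from the extension).
#' @return `path`, invisibly.
#' @export
write_tractogram <- function(t, path, format = c("auto", "tck", "trk")) {
  if (!inherits(t, "tractogram")) stop("'t' must be a tractogram", call. = FALSE)
  format <- match.arg(format)
  if (format == "auto") {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("tck", "trk"))
      stop("unknown format for extension '", tools::file_ext(path), "'", call. = FALSE)
  }
  switch(format, tck = write_tck(t, path), trk = write_trk(t, path))
  invisible(path)
}

sniff_format <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 13L)
  if (length(magic) >= 13L && identical(magic, charToRaw("mrtrix tracks"))) return("tck")
  if (length(magic) >= 5L && identical(magic[1:5], charToRaw("TRACK"))) return("trk")
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tck", "trk")) return(ext)
  stop("unknown tractogram format: ", path, call. = FALSE)
}

# Reference used when a TCK file is loaded without grid context: a 1 mm
# isotropic grid whose corner sits 2 voxels below the point cloud minimum.
bounding_reference <- function(streamlines, voxel = 1) {
  if (length(streamlines) == 0L) {
    return(spatial_reference(diag(c(voxel, voxel, voxel, 1)), c(1L, 1L, 1L)))
  }
  all_pts <- do.call(rbind, streamlines)
  lo <- apply(all_pts, 2, min) - 2 * voxel
  hi <- apply(all_pts, 2, max) + 2 * voxel
  dims <- pmax(1L, as.integer(ceiling((hi - lo) / voxel)))
  aff <- diag(c(voxel, voxel, voxel, 1))
  aff[1:3, 4] <- lo + voxel / 2   # center of voxel (0,0,0)
  spatial_reference(aff, dims)
}

## ---- TCK (MRtrix): ASCII header ending in END, float32 triplets, ----
## ---- NaN-triplet separators, Inf-triplet terminator.              ----

read_tck <- function(path, ref = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- read_tck_header(con, path)
  endian <- if (grepl("BE$", header$datatype)) "big" else "little"
  seek(con, header$offset)
  body_bytes <- file.size(path) - header$offset
  vals <- readBin(con, "double", n = body_bytes %/% 4L, size = 4L, endian = endian)
  if (length(vals) %% 3L != 0L)
    stop("truncated TCK body in ", path, call. = FALSE)
  pts <- matrix(vals, ncol = 3L, byrow = TRUE)
  inf_row <- which(is.infinite(pts[, 1L]))
  if (length(inf_row) == 0L)
    stop("truncated TCK body (no end-of-file triplet) in ", path, call. = FALSE)
  pts <- pts[seq_len(inf_row[1L] - 1L), , drop = FALSE]
  sep <- is.nan(pts[, 1L])
  ids <- cumsum(c(TRUE, sep[-length(sep)])) # streamline id per row
  keep <- !sep
  streamlines <- if (any(keep)) {
    unname(lapply(split.data.frame(pts[keep, , drop = FALSE], ids[keep]), identity))
  } else list()
  if (is.null(ref)) ref <- bounding_reference(streamlines)
  tractogram(streamlines, ref)
}

read_tck_header <- function(con, path) {
  line1 <- read_header_line(con)
  if (!identical(line1, "mrtrix tracks"))
    stop("unreadable TCK header (bad magic) in ", path, call. = FALSE)
  fields <- list()
  repeat {
    ln <- read_header_line(con)
    if (is.null(ln)) stop("unreadable TCK header (no END) in ", path, call. = FALSE)
    if (ln == "END") break
    kv <- regmatches(ln, regexec("^([^:]+):\\s*(.*)$", ln))[[1L]]
    if (length(kv) == 3L) fields[[trimws(kv[2L])]] <- trimws(kv[3L])
  }
  if (is.null(fields$file))
    stop("unreadable TCK header (no file field) in ", path, call. = FALSE)
  offset <- as.integer(sub("^\\.\\s+", "", fields$file))
  if (is.na(offset)) stop("unreadable TCK header (bad offset) in ", path, call. = FALSE)
  datatype <- fields$datatype %||% "Float32LE"
  if (!datatype %in% c("Float32LE", "Float32BE"))
    stop("unsupported TCK datatype: ", datatype, call. = FALSE)
  list(offset = offset, datatype = datatype, count = fields$count)
}

read_header_line <- function(con) {
  bytes <- raw()
  repeat {
    b <- readBin(con, "raw", n = 1L)
    if (length(b) == 0L) return(NULL)
    if (b == as.raw(10L)) return(rawToChar(bytes))
    bytes <- c(bytes, b)
  }
}

write_tck <- function(t, path) {
  body <- c("datatype: Float32LE",
            sprintf("count: %d", length(t$streamlines)))
  # the 'file' field stores the byte offset of the binary section, which
  # depends on the header length; fixed-width offset keeps it one pass
  header_for <- function(off) {
    paste0("mrtrix tracks\n", paste(body, collapse = "\n"),
           sprintf("\nfile: . %d\nEND\n", off))
  }
  off <- nchar(header_for(0L), type = "bytes")
  off <- nchar(header_for(off), type = "bytes")          # stabilize width
  header <- header_for(off)
  stopifnot(nchar(header, type = "bytes") == off)
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot write ", path, call. = FALSE))
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  for (s in t$streamlines) {
    writeBin(as.numeric(t(s)), con, size = 4L, endian = "little")
    writeBin(rep(NaN, 3L), con, size = 4L, endian = "little")
  }
  writeBin(rep(Inf, 3L), con, size = 4L, endian = "little")
}

## ---- TRK (TrackVis): 1000-byte header, voxel-mm coordinates. ----

TRK_HEADER_SIZE <- 1000L

read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = TRK_HEADER_SIZE)
  if (length(hdr_raw) < TRK_HEADER_SIZE)
    stop("unreadable TRK header (short file) in ", path, call. = FALSE)
  if (rawToChar(hdr_raw[1:5]) != "TRACK")
    stop("unreadable TRK header (bad magic) in ", path, call. = FALSE)
  endian <- "little"
  hdr_size <- read_int32(hdr_raw, 997L, endian)
  if (hdr_size != TRK_HEADER_SIZE) {
    endian <- "big"
    hdr_size <- read_int32(hdr_raw, 997L, endian)
    if (hdr_size != TRK_HEADER_SIZE)
      stop("unreadable TRK header (bad hdr_size) in ", path, call. = FALSE)
  }
  dims <- read_int16(hdr_raw, 7L, 3L, endian)
  voxel_size <- read_float32(hdr_raw, 13L, 3L, endian)
  n_scalars <- read_int16(hdr_raw, 37L, 1L, endian)
  n_properties <- read_int16(hdr_raw, 239L, 1L, endian)
  vox2ras <- matrix(read_float32(hdr_raw, 441L, 16L, endian), 4L, 4L, byrow = TRUE)
  n_count <- read_int32(hdr_raw, 989L, endian)
  if (all(vox2ras == 0)) {
    warning("TRK header has no voxel-to-world matrix; assuming axis-aligned grid",
            call. = FALSE)
    vox2ras <- diag(c(voxel_size, 1))
  }
  ref <- spatial_reference(vox2ras, pmax(dims, 1L))

  streamlines <- list()
  scalars <- list()
  properties <- list()
  repeat {
    n_pts <- readBin(con, "integer", n = 1L, size = 4L, endian = endian)
    if (length(n_pts) == 0L) break
    if (n_pts < 0L) stop("truncated TRK body in ", path, call. = FALSE)
    vals <- readBin(con, "double", n = n_pts * (3L + n_scalars), size = 4L,
                    endian = endian)
    props <- readBin(con, "double", n = n_properties, size = 4L, endian = endian)
    if (length(vals) < n_pts * (3L + n_scalars) ||
        length(props) < n_properties)
      stop("truncated TRK body in ", path, call. = FALSE)
    rec <- matrix(vals, ncol = 3L + n_scalars, byrow = TRUE)
    streamlines[[length(streamlines) + 1L]] <- trk_to_world(rec[, 1:3, drop = FALSE],
                                                            voxel_size, ref)
    if (n_scalars > 0L) scalars[[length(scalars) + 1L]] <- rec[, -(1:3), drop = FALSE]
    if (n_properties > 0L) properties[[length(properties) + 1L]] <- props
  }
  if (n_count > 0L && length(streamlines) != n_count)
    stop("truncated TRK body (count mismatch) in ", path, call. = FALSE)
  t <- tractogram(streamlines, ref)
  if (length(scalars)) attr(t, "trk_scalars") <- scalars
  if (length(properties)) attr(t, "trk_properties") <- properties
  t
}

# TRK stores corner-anchored voxel-mm: voxel center (i,j,k) lies at
# ((i,j,k) + 0.5) * voxel_size. Convert through center-based voxel indices.
trk_to_world <- function(pts_voxmm, voxel_size, ref) {
  vox <- sweep(pts_voxmm, 2, voxel_size, "/") - 0.5
  sweep(vox %*% t(ref$affine[1:3, 1:3]), 2, ref$affine[1:3, 4], "+")
}

world_to_trk <- function(pts_world, voxel_size, ref) {
  vox <- sweep(pts_world %*% t(ref$inverse[1:3, 1:3]), 2, ref$inverse[1:3, 4], "+")
  sweep(vox + 0.5, 2, voxel_size, "*")
}

write_trk <- function(t, path) {
  ref <- t$ref
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot write ", path, call. = FALSE))
  on.exit(close(con))
  hdr <- raw(TRK_HEADER_SIZE)
  hdr[1:6] <- c(charToRaw("TRACK"), as.raw(0L))
  hdr <- poke(hdr, 7L, writeBin(as.integer(ref$dims), raw(), size = 2L, endian = "little"))
  hdr <- poke(hdr, 13L, writeBin(as.numeric(ref$voxel_sizes), raw(), size = 4L, endian = "little"))
  # n_scalars = n_properties = 0; offsets 37 and 239
  hdr <- poke(hdr, 441L, writeBin(as.numeric(t(ref$affine)), raw(), size = 4L, endian = "little"))
  hdr <- poke(hdr, 949L, charToRaw(voxel_order_code(ref)))
  hdr <- poke(hdr, 989L, writeBin(length(t$streamlines), raw(), size = 4L, endian = "little"))
  hdr <- poke(hdr, 993L, writeBin(2L, raw(), size = 4L, endian = "little"))  # version
  hdr <- poke(hdr, 997L, writeBin(TRK_HEADER_SIZE, raw(), size = 4L, endian = "little"))
  writeBin(hdr, con)
  for (s in t$streamlines) {
    writeBin(nrow(s), con, size = 4L, endian = "little")
    writeBin(as.numeric(t(world_to_trk(s, ref$voxel_sizes, ref))), con,
             size = 4L, endian = "little")
  }
}

# Nearest-axis anatomical orientation codes of the affine columns.
voxel_order_code <- function(ref) {
  labels <- c("L", "R", "P", "A", "I", "S")   # -x,+x,-y,+y,-z,+z
  code <- vapply(1:3, function(j) {
    col <- ref$affine[1:3, j]
    ax <- which.max(abs(col))
    labels[2L * ax - (col[ax] < 0)]
  }, character(1))
  paste(code, collapse = "")   # 4th header byte stays NUL
}

poke <- function(hdr, at, bytes) {
  hdr[seq(at, length.out = length(bytes))] <- bytes
  hdr
}
read_int16 <- function(r, at, n, endian)
  readBin(r[seq(at, length.out = 2L * n)], "integer", n = n, size = 2L, endian = endian)
read_int32 <- function(r, at, endian)
  readBin(r[seq(at, length.out = 4L)], "integer", n = 1L, size = 4L, endian = endian)
read_float32 <- function(r, at, n, endian)
  readBin(r[seq(at, length.out = 4L * n)], "double", n = n, size = 4L, endian = endian)

`%||%` <- function(a, b) if (is.null(a)) b else a
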