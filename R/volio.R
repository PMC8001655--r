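# Volume and projection-series I/O.
#
# Two on-disk formats:
#  * multi-page grayscale TIFF (baseline, uncompressed, one slice per page,
#    64-bit float samples; voxel size carried in ImageDescription). The codec
#    below is a minimal self-contained baseline-TIFF reader/writer: it writes
#    little-endian float64 and reads uncompressed single-sample pages of
#    8/16/32-bit integer or 32/64-bit float data in either byte order.
#  * raw binary + plain-text sidecar (`<path>.meta`) with shape, dtype,
#    voxel size and origin; column-major (z fastest), little-endian float64.

TIFF_TYPE_ASCII <- 2L
TIFF_TYPE_SHORT <- 3L
TIFF_TYPE_LONG <- 4L

tiff_read_uint <- function(r, off, size, endian) {
  # off is 0-based byte offset into raw vector r
  b <- r[(off + 1L):(off + size)]
  if (endian == "big") b <- rev(b)
  sum(as.numeric(b) * 256^(seq_len(size) - 1L))
}

tiff_entry_values <- function(r, entry_off, endian) {
  type <- tiff_read_uint(r, entry_off + 2L, 2L, endian)
  count <- tiff_read_uint(r, entry_off + 4L, 4L, endian)
  tsize <- c(1L, 1L, 2L, 4L)[type]
  if (is.na(tsize)) return(NULL)  # unsupported field type: ignore tag
  total <- tsize * count
  voff <- if (total <= 4L) entry_off + 8L else
    tiff_read_uint(r, entry_off + 8L, 4L, endian)
  if (type == TIFF_TYPE_ASCII) {
    bytes <- r[(voff + 1L):(voff + count)]
    return(rawToChar(bytes[bytes != as.raw(0L)]))
  }
  vapply(seq_len(count) - 1L, function(i) {
    tiff_read_uint(r, voff + i * tsize, tsize, endian)
  }, numeric(1L))
}

tiff_decode_strip <- function(bytes, bits, fmt, endian) {
  n <- length(bytes) %/% (bits %/% 8L)
  if (fmt == 3) {
    if (bits == 64L) {
      return(readBin(bytes, "double", n, size = 8L, endian = endian))
    }
    if (bits == 32L) {
      return(readBin(bytes, "double", n, size = 4L, endian = endian))
    }
    stopf("unsupported float bit depth %d", bits)
  }
  signed <- fmt == 2
  if (bits == 8L) {
    return(as.numeric(readBin(bytes, "integer", n, size = 1L,
                              signed = signed)))
  }
  if (bits == 16L) {
    return(as.numeric(readBin(bytes, "integer", n, size = 2L,
                              signed = signed, endian = endian)))
  }
  if (bits == 32L) {
    x <- as.numeric(readBin(bytes, "integer", n, size = 4L, endian = endian))
    if (!signed) x <- x + ifelse(x < 0, 2^32, 0)
    return(x)
  }
  stopf("unsupported integer bit depth %d", bits)
}

# Read every page of a baseline TIFF; returns list(pages = list of matrices
# [row, col], description = first ImageDescription or NULL)
tiff_read_pages <- function(path) {
  r <- readBin(path, "raw", file.size(path))
  if (length(r) < 8L) stopf("unreadable TIFF file: %s", path)
  magic <- rawToChar(r[1:2])
  endian <- if (magic == "II") "little" else if (magic == "MM") "big" else
    stopf("not a TIFF file (bad byte-order mark): %s", path)
  if (tiff_read_uint(r, 2L, 2L, endian) != 42) {
    stopf("not a TIFF file (bad magic): %s", path)
  }
  ifd <- tiff_read_uint(r, 4L, 4L, endian)
  pages <- list()
  description <- NULL
  while (ifd != 0) {
    nent <- tiff_read_uint(r, ifd, 2L, endian)
    tags <- list()
    for (i in seq_len(nent) - 1L) {
      eoff <- ifd + 2L + i * 12L
      tag <- tiff_read_uint(r, eoff, 2L, endian)
      tags[[as.character(tag)]] <- tiff_entry_values(r, eoff, endian)
    }
    need <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) {
        if (is.null(default)) stopf("TIFF page missing required tag %d", tag)
        default
      } else v
    }
    width <- need(256L)
    height <- need(257L)
    bits <- need(258L, 1)
    if (need(259L, 1) != 1) stopf("compressed TIFF is not supported")
    if (need(277L, 1) != 1) stopf("multi-sample TIFF is not supported")
    fmt <- need(339L, 1)
    offs <- need(273L)
    counts <- need(279L)
    if (is.null(description) && !is.null(tags[["270"]])) {
      description <- tags[["270"]]
    }
    vals <- unlist(lapply(seq_along(offs), function(i) {
      bytes <- r[(offs[i] + 1L):(offs[i] + counts[i])]
      tiff_decode_strip(bytes, as.integer(bits), fmt, endian)
    }))
    if (length(vals) != width * height) {
      stopf("TIFF strip data does not match page dimensions")
    }
    # strips are row-major: column index fastest
    pages[[length(pages) + 1L]] <- t(matrix(vals, nrow = width,
                                            ncol = height))
    ifd <- tiff_read_uint(r, ifd + 2L + nent * 12L, 4L, endian)
  }
  if (length(pages) == 0L) stopf("TIFF file contains no pages: %s", path)
  shapes <- vapply(pages, dim, integer(2L))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1])) {
    stopf("inconsistent slice shapes across TIFF pages")
  }
  list(pages = pages, description = description)
}

tiff_write_pages <- function(pages, path, description) {
  desc_raw <- c(charToRaw(description), as.raw(0L))
  if (length(desc_raw) %% 2L == 1L) desc_raw <- c(desc_raw, as.raw(0L))
  npage <- length(pages)
  ny <- nrow(pages[[1L]])
  nx <- ncol(pages[[1L]])
  nbytes <- ny * nx * 8L
  ifd_size <- 2L + 11L * 12L + 4L
  data_off <- desc_off <- ifd_off <- integer(npage)
  pos <- 8L
  for (i in seq_len(npage)) {
    data_off[i] <- pos
    pos <- pos + nbytes
    desc_off[i] <- pos
    pos <- pos + length(desc_raw)
    ifd_off[i] <- pos
    pos <- pos + ifd_size
  }
  con <- file(path, "wb")
  on.exit(close(con))
  wr16 <- function(x) writeBin(as.integer(x), con, size = 2L,
                               endian = "little")
  wr32 <- function(x) writeBin(as.integer(x), con, size = 4L,
                               endian = "little")
  entry <- function(tag, type, count, value) {
    wr16(tag); wr16(type); wr32(count)
    if (type == TIFF_TYPE_SHORT && count == 1L) {
      wr16(value); wr16(0L)
    } else {
      wr32(value)
    }
  }
  writeChar("II", con, nchars = 2L, eos = NULL)
  wr16(42L)
  wr32(ifd_off[1L])
  for (i in seq_len(npage)) {
    writeBin(as.vector(t(pages[[i]])), con, size = 8L, endian = "little")
    writeBin(desc_raw, con)
    wr16(11L)
    entry(256L, TIFF_TYPE_LONG, 1L, nx)              # ImageWidth
    entry(257L, TIFF_TYPE_LONG, 1L, ny)              # ImageLength
    entry(258L, TIFF_TYPE_SHORT, 1L, 64L)            # BitsPerSample
    entry(259L, TIFF_TYPE_SHORT, 1L, 1L)             # Compression: none
    entry(262L, TIFF_TYPE_SHORT, 1L, 1L)             # Photometric: min-is-black
    entry(270L, TIFF_TYPE_ASCII, length(desc_raw), desc_off[i])
    entry(273L, TIFF_TYPE_LONG, 1L, data_off[i])     # StripOffsets
    entry(277L, TIFF_TYPE_SHORT, 1L, 1L)             # SamplesPerPixel
    entry(278L, TIFF_TYPE_LONG, 1L, ny)              # RowsPerStrip
    entry(279L, TIFF_TYPE_LONG, 1L, nbytes)          # StripByteCounts
    entry(339L, TIFF_TYPE_SHORT, 1L, 3L)             # SampleFormat: float
    wr32(if (i < npage) ifd_off[i + 1L] else 0L)
  }
  invisible(NULL)
}

is_tiff_path <- function(path) grepl("\\.tiff?$", path, ignore.case = TRUE)

volume_description <- function(v) {
  jsonlite::toJSON(list(voxel_size_um = v$voxel_size, origin_um = v$origin),
                   auto_unbox = FALSE, digits = NA)
}

parse_volume_description <- function(desc) {
  if (is.null(desc)) return(NULL)
  meta <- tryCatch(jsonlite::fromJSON(desc), error = function(e) NULL)
  if (is.null(meta) || is.null(meta$voxel_size_um)) return(NULL)
  meta
}

raw_sidecar_path <- function(path) paste0(path, ".meta")

write_raw_sidecar <- function(v, path) {
  d <- dim(v$data)
  lines <- c(
    sprintf("shape_zyx = %d %d %d", d[1], d[2], d[3]),
    "dtype = float64",
    "byte_order = little",
    "layout = column_major_z_fastest",
    sprintf("voxel_size_um = %s",
            paste(format(v$voxel_size, digits = 17), collapse = " ")),
    sprintf("origin_um = %s",
            paste(format(v$origin, digits = 17), collapse = " ")))
  writeLines(lines, raw_sidecar_path(path))
}

read_raw_sidecar <- function(path) {
  sc <- raw_sidecar_path(path)
  if (!file.exists(sc)) return(NULL)
  lines <- readLines(sc, warn = FALSE)
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) next
    kv[[trimws(parts[1L])]] <- trimws(parts[2L])
  }
  kv
}

#' Write a volume to disk
#'
#' TIFF output (`.tif`/`.tiff`) stores one axial slice per page as
#' uncompressed 64-bit float with the voxel size and origin embedded in the
#' ImageDescription tag; any other extension writes raw little-endian float64
#' (column-major, z fastest) plus a `<path>.meta` key-value sidecar. Both
#' round-trip bit-exactly through [read_volume()].
#'
#' @param v a [volume()].
#' @param path output path; parent directory must exist.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  check_volume(v)
  if (!dir.exists(dirname(path))) {
    stopf("directory does not exist: %s", dirname(path))
  }
  if (is_tiff_path(path)) {
    pages <- lapply(seq_len(dim(v$data)[1L]), function(z) v$data[z, , ])
    # a 1 x 1 slice drops to scalar; restore matrix shape
    pages <- lapply(pages, function(p) {
      if (!is.matrix(p)) matrix(p, dim(v$data)[2L], dim(v$data)[3L]) else p
    })
    tiff_write_pages(pages, path, volume_description(v))
  } else {
    writeBin(as.vector(v$data), path, size = 8L, endian = "little")
    write_raw_sidecar(v, path)
  }
  invisible(path)
}

#' Read a volume from disk
#'
#' Accepts multi-page grayscale TIFF stacks (uncompressed, single-sample;
#' 8/16/32-bit integer or 32/64-bit float, either byte order) or raw binary
#' with a `<path>.meta` sidecar as written by [write_volume()]. Slices are
#' ordered along the axial (z) dimension.
#'
#' @param path input file.
#' @param voxel_size_override voxel size in micrometres used when the file
#'   carries no voxel-size metadata (and overriding it when it does).
#' @return a [volume()].
#' @export
read_volume <- function(path, voxel_size_override = NULL) {
  if (!file.exists(path)) stopf("file does not exist: %s", path)
  if (is_tiff_path(path)) {
    tf <- tiff_read_pages(path)
    ny <- nrow(tf$pages[[1L]])
    nx <- ncol(tf$pages[[1L]])
    nz <- length(tf$pages)
    data <- array(0, c(nz, ny, nx))
    for (z in seq_len(nz)) data[z, , ] <- tf$pages[[z]]
    meta <- parse_volume_description(tf$description)
    if (is.null(meta) && is.null(voxel_size_override)) {
      stopf("TIFF carries no voxel-size metadata; pass voxel_size_override")
    }
    vs <- if (!is.null(voxel_size_override)) voxel_size_override else
      meta$voxel_size_um
    org <- if (!is.null(meta) && !is.null(meta$origin_um)) meta$origin_um
      else 0
    return(volume(data, voxel_size = vs, origin = org))
  }
  kv <- read_raw_sidecar(path)
  if (is.null(kv)) {
    stopf("raw volume has no sidecar (%s) and cannot be interpreted",
          raw_sidecar_path(path))
  }
  shape <- as.integer(strsplit(kv$shape_zyx, "\\s+")[[1L]])
  if (length(shape) != 3L || anyNA(shape)) stopf("invalid sidecar shape")
  if (!identical(kv$dtype, "float64")) {
    stopf("unsupported raw dtype: %s", kv$dtype)
  }
  n <- prod(shape)
  vals <- readBin(path, "double", n, size = 8L, endian = "little")
  if (length(vals) != n) stopf("raw file shorter than sidecar shape implies")
  vs <- if (!is.null(voxel_size_override)) voxel_size_override else
    as.numeric(strsplit(kv$voxel_size_um, "\\s+")[[1L]])
  if (is.null(vs) || anyNA(vs)) stopf("missing voxel size")
  org <- if (!is.null(kv$origin_um)) {
    as.numeric(strsplit(kv$origin_um, "\\s+")[[1L]])
  } else 0
  volume(array(vals, shape), voxel_size = vs, origin = org)
}

#' Write a projection series to disk
#'
#' Frames go to a multi-page TIFF in acquisition order; angles, sub-scan
#' indices and reference flags go to a JSON sidecar (`<path>.json`).
#'
#' @param series a [projection_series()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_projections <- function(series, path) {
  if (!inherits(series, "dvct_projections")) {
    stopf("series must be a dvct_projections")
  }
  if (!dir.exists(dirname(path))) {
    stopf("directory does not exist: %s", dirname(path))
  }
  desc <- jsonlite::toJSON(list(kind = "projection_series"),
                           auto_unbox = TRUE)
  tiff_write_pages(series$frames, path, desc)
  jsonlite::write_json(
    list(angles_deg = series$angles_deg,
         subscan_index = series$subscan_index,
         is_reference = series$is_reference),
    paste0(path, ".json"), digits = NA)
  invisible(path)
}

#' Read a projection series and annotate it from a scan plan
#'
#' The frame count must equal the plan's total including one reference
#' exposure per sub-scan; frames are assumed stored in acquisition order
#' (each sub-scan: reference frame first, then its angular projections).
#'
#' @param path multi-page TIFF of frames.
#' @param plan a [build_scan_plan()] result.
#' @return a [projection_series()] annotated per the plan.
#' @export
read_projections <- function(path, plan) {
  check_scan_plan(plan)
  tf <- tiff_read_pages(path)
  expected <- plan$n_subscans * (plan$n_per_subscan + 1L)
  if (length(tf$pages) != expected) {
    stopf("frame count %d does not match plan total %d (with references)",
          length(tf$pages), expected)
  }
  ann <- scan_plan_annotation(plan)
  projection_series(tf$pages, ann$angles_deg, ann$subscan_index,
                    ann$is_reference)
}
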