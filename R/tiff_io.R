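#' Minimal TIFF hyperstack I/O
#'
#' Reader and writer for uncompressed grayscale multi-page TIFF files
#' (8/16-bit unsigned), sufficient for round-tripping the movies this
#' package generates and analyses.  Pages are ordered T, then Z, then C
#' (TZCYX); the hyperstack layout and calibration are recorded in the
#' ImageDescription tag as a JSON string and recovered on read.  No
#' compression, tiling, or colour support.
#'
#' @name tiff_io
NULL

TIFF_TAGS <- c(ImageWidth = 256L, ImageLength = 257L, BitsPerSample = 258L,
               Compression = 259L, Photometric = 262L,
               ImageDescription = 270L, StripOffsets = 273L,
               RowsPerStrip = 278L, StripByteCounts = 279L,
               SampleFormat = 339L)

#' Write a movie to an uncompressed multi-page TIFF
#'
#' Values are rounded and clamped to the 16-bit unsigned range.
#'
#' @param m a `cq_movie`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_movie <- function(m, path) {
  stopifnot(inherits(m, "cq_movie"))
  d <- movie_dim(m)
  ny <- d[["y"]]; nx <- d[["x"]]
  npages <- d[["t"]] * d[["z"]] * d[["c"]]
  desc <- jsonlite::toJSON(list(
    shape = list(t = d[["t"]], z = d[["z"]], c = d[["c"]],
                 y = ny, x = nx),
    order = "TZC",
    pixel_size_um = m$pixel_size_um,
    z_step_um = m$z_step_um,
    frame_interval_s = m$frame_interval_s,
    channel_roles = as.list(m$channel_roles)
  ), auto_unbox = TRUE)
  desc_raw <- c(charToRaw(as.character(desc)), as.raw(0L))
  if (length(desc_raw) %% 2 == 1) desc_raw <- c(desc_raw, as.raw(0L))

  con <- file(path, "wb")
  on.exit(close(con))
  # header: little-endian
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  page_bytes <- ny * nx * 2
  n_entries <- 10L
  ifd_size <- 2 + n_entries * 12 + 4
  # layout: header (8) | desc | then per page: pixel data followed by IFD
  desc_off <- 8L
  first_ifd <- desc_off + length(desc_raw) + page_bytes
  writeBin(as.integer(first_ifd), con, size = 4, endian = "little")
  writeBin(desc_raw, con)

  write_entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3L && count == 1L) {  # SHORT packed into 4 bytes
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }

  page <- 0L
  offset <- desc_off + length(desc_raw)
  for (t in seq_len(d[["t"]])) for (z in seq_len(d[["z"]])) for (cc in seq_len(d[["c"]])) {
    img <- m$data[, , z, cc, t]
    v <- as.integer(pmin(pmax(round(img), 0), 65535))
    # row-major pixel order within the page
    writeBin(as.vector(t(matrix(v, ny, nx))), con, size = 2, endian = "little")
    ifd_off <- offset + page_bytes
    writeBin(n_entries, con, size = 2, endian = "little")
    write_entry(TIFF_TAGS[["ImageWidth"]], 4L, 1L, nx)
    write_entry(TIFF_TAGS[["ImageLength"]], 4L, 1L, ny)
    write_entry(TIFF_TAGS[["BitsPerSample"]], 3L, 1L, 16L)
    write_entry(TIFF_TAGS[["Compression"]], 3L, 1L, 1L)
    write_entry(TIFF_TAGS[["Photometric"]], 3L, 1L, 1L)
    write_entry(TIFF_TAGS[["ImageDescription"]], 2L, length(desc_raw), desc_off)
    write_entry(TIFF_TAGS[["StripOffsets"]], 4L, 1L, offset)
    write_entry(TIFF_TAGS[["RowsPerStrip"]], 4L, 1L, ny)
    write_entry(TIFF_TAGS[["StripByteCounts"]], 4L, 1L, page_bytes)
    write_entry(TIFF_TAGS[["SampleFormat"]], 3L, 1L, 1L)
    page <- page + 1L
    next_ifd <- if (page == npages) 0L else ifd_off + ifd_size + page_bytes
    writeBin(as.integer(next_ifd), con, size = 4, endian = "little")
    offset <- ifd_off + ifd_size
  }
  invisible(path)
}

read_u <- function(raw, off, size) {
  # little-endian unsigned integer at 0-based offset
  b <- as.integer(raw[(off + 1):(off + size)])
  sum(b * 256^(seq_len(size) - 1))
}

#' Read a movie from an uncompressed multi-page TIFF
#'
#' Understands the grayscale files produced by [write_movie()] (hyperstack
#' layout recovered from the JSON ImageDescription) and generic uncompressed
#' single-sample TIFFs, in which case the page count is interpreted with the
#' declared `shape`.
#'
#' @param path TIFF file path.
#' @param shape optional named list/vector with t, z, c page layout when the
#'   file carries no embedded description.
#' @param channel_roles optional channel role mapping overriding the stored
#'   one.
#' @return a `cq_movie`.
#' @export
read_movie <- function(path, shape = NULL, channel_roles = NULL) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (!(rawToChar(raw[1:2]) %in% c("II")))
    stop("only little-endian TIFF is supported")
  if (read_u(raw, 2, 2) != 42) stop("not a TIFF file")
  ifd_off <- read_u(raw, 4, 4)
  pages <- list()
  desc <- NULL
  while (ifd_off != 0) {
    n <- read_u(raw, ifd_off, 2)
    tags <- list()
    for (k in seq_len(n)) {
      e <- ifd_off + 2 + (k - 1) * 12
      tag <- read_u(raw, e, 2)
      type <- read_u(raw, e + 2, 2)
      count <- read_u(raw, e + 4, 4)
      val <- if (type == 3 && count == 1) read_u(raw, e + 8, 2) else read_u(raw, e + 8, 4)
      tags[[as.character(tag)]] <- list(type = type, count = count, value = val)
    }
    need <- function(tag, default = NULL) {
      t <- tags[[as.character(tag)]]
      if (is.null(t)) {
        if (is.null(default)) stop("missing TIFF tag ", tag)
        return(default)
      }
      t$value
    }
    if (need(259, 1) != 1) stop("compressed TIFF is not supported")
    w <- need(256); h <- need(257)
    bps <- need(258, 16)
    if (!bps %in% c(8, 16)) stop("only 8/16-bit TIFF is supported")
    soff <- need(273); sbytes <- need(279, w * h * bps / 8)
    if (is.null(desc) && !is.null(tags[["270"]])) {
      dt <- tags[["270"]]
      dbytes <- raw[(dt$value + 1):(dt$value + dt$count)]
      txt <- rawToChar(dbytes[dbytes != as.raw(0L)])
      desc <- tryCatch(jsonlite::fromJSON(txt), error = function(e) NULL)
    }
    bytes_per <- bps / 8
    if (sbytes < w * h * bytes_per) stop("multi-strip TIFF is not supported")
    vals <- readBin(raw[(soff + 1):(soff + w * h * bytes_per)],
                    what = "integer", n = w * h, size = bytes_per,
                    signed = FALSE, endian = "little")
    pages[[length(pages) + 1]] <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
    ifd_off <- read_u(raw, ifd_off + 2 + n * 12, 4)
  }
  np <- length(pages)
  if (!is.null(desc) && !is.null(desc$shape)) {
    s <- desc$shape
    lay <- c(t = s$t, z = s$z, c = s$c)
  } else if (!is.null(shape)) {
    lay <- c(t = shape[["t"]], z = shape[["z"]], c = shape[["c"]])
  } else {
    lay <- c(t = np, z = 1L, c = 1L)
  }
  if (prod(lay) != np)
    stop(sprintf("declared layout t=%d z=%d c=%d does not match %d pages",
                 lay[["t"]], lay[["z"]], lay[["c"]], np))
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  arr <- array(0, dim = c(ny, nx, lay[["z"]], lay[["c"]], lay[["t"]]))
  p <- 1L
  for (t in seq_len(lay[["t"]])) for (z in seq_len(lay[["z"]])) for (cc in seq_len(lay[["c"]])) {
    arr[, , z, cc, t] <- pages[[p]]
    p <- p + 1L
  }
  roles <- channel_roles
  if (is.null(roles) && !is.null(desc$channel_roles))
    roles <- unlist(desc$channel_roles)
  if (is.null(roles)) roles <- c(chromosomes = 1L)
  movie(arr,
        pixel_size_um = if (!is.null(desc$pixel_size_um)) desc$pixel_size_um else default_pixel_size(),
        z_step_um = if (!is.null(desc$z_step_um)) desc$z_step_um else 1.0,
        frame_interval_s = if (!is.null(desc$frame_interval_s)) desc$frame_interval_s else 10.0,
        channel_roles = roles)
}

#' Write / read a ground-truth sidecar as JSON
#' @param truth ground-truth list from a generator.
#' @param path JSON path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
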