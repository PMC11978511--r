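# Minimal baseline TIFF writer with OME-XML ImageDescription.
#
# The `tiff` package is used for reading, but its writer cannot emit
# ImageDescription or resolution tags, which the pipeline needs so that label
# and intensity outputs carry their voxel size. This writer emits plain
# little-endian, uncompressed, single-strip baseline TIFF (one sample per
# pixel, greyscale) that `tiff::readTIFF` and common viewers read back.

TIFF_TYPES <- list(
  uint8   = list(bits = 8L,  fmt = 1L),
  uint16  = list(bits = 16L, fmt = 1L),
  uint32  = list(bits = 32L, fmt = 1L),
  float32 = list(bits = 32L, fmt = 3L)
)

ome_description <- function(dim4, spacing3, frame_interval, dtype, flat) {
  px_type <- c(uint8 = "uint8", uint16 = "uint16", uint32 = "uint32",
               float32 = "float")[[dtype]]
  fmt <- function(x) sprintf("%.17g", x)
  phys_z <- if (flat) "" else sprintf(' PhysicalSizeZ="%s" PhysicalSizeZUnit="µm"', fmt(spacing3[1]))
  tinc <- if (!is.null(frame_interval) && !is.na(frame_interval))
    sprintf(' TimeIncrement="%s" TimeIncrementUnit="s"', fmt(frame_interval)) else ""
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<OME xmlns="http://www.openmicroscopy.org/Schemas/OME/2016-06">',
    '<Image ID="Image:0"><Pixels ID="Pixels:0" DimensionOrder="XYZTC" Type="', px_type, '"',
    sprintf(' SizeX="%d" SizeY="%d" SizeZ="%d" SizeC="1" SizeT="%d"',
            dim4[4], dim4[3], dim4[2], dim4[1]),
    sprintf(' PhysicalSizeX="%s" PhysicalSizeXUnit="µm" PhysicalSizeY="%s" PhysicalSizeYUnit="µm"',
            fmt(spacing3[3]), fmt(spacing3[2])),
    phys_z, tinc,
    '><TiffData/></Pixels></Image></OME>')
}

# pages: list of Y x X numeric matrices, written in order
write_tiff_pages <- function(pages, path, dtype, description, dx, dy) {
  tt <- TIFF_TYPES[[dtype]]
  if (is.null(tt)) stop("unsupported TIFF sample type: ", dtype)
  bytes_px <- tt$bits %/% 8L
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  npages <- length(pages)
  desc_raw <- c(charToRaw(enc2utf8(description)), as.raw(0L))
  if (length(desc_raw) %% 2L == 1L) desc_raw <- c(desc_raw, as.raw(0L))

  pad2 <- function(n) if (n %% 2L == 1L) n + 1L else n
  # layout: header | description | xres | yres | page data ... | IFDs
  off_desc <- 8L
  off_xres <- off_desc + length(desc_raw)
  off_yres <- off_xres + 8L
  off_data0 <- off_yres + 8L
  page_bytes <- as.integer(ny) * as.integer(nx) * bytes_px
  page_stride <- pad2(page_bytes)
  off_data <- off_data0 + (seq_len(npages) - 1L) * page_stride
  off_ifd0 <- off_data0 + npages * page_stride
  n_entries <- function(p) if (p == 1L) 14L else 13L
  ifd_size <- function(p) 2L + 12L * n_entries(p) + 4L
  off_ifd <- integer(npages)
  off_ifd[1] <- off_ifd0
  if (npages > 1) for (p in 2:npages) off_ifd[p] <- off_ifd[p - 1] + ifd_size(p - 1L)

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  # header
  writeBin(charToRaw("II"), con)
  w16(42L); w32(off_ifd0)
  # description, resolutions (rational: pixels per micron)
  writeBin(desc_raw, con)
  res_rational <- function(d) {
    den <- 1000000L
    num <- as.integer(round(den / d))
    c(num, den)
  }
  w32(res_rational(dx)); w32(res_rational(dy))
  # pixel data (row-major within page: TIFF stores rows sequentially)
  for (p in seq_len(npages)) {
    m <- pages[[p]]
    v <- as.vector(t(m))  # row-major
    if (dtype == "float32") {
      writeBin(as.numeric(v), con, size = 4, endian = "little")
    } else if (dtype == "uint32") {
      v <- as.numeric(v)
      if (any(v < 0 | v > 4294967295)) stop("value out of uint32 range")
      hi <- v >= 2147483648
      v[hi] <- v[hi] - 4294967296
      writeBin(as.integer(v), con, size = 4, endian = "little")
    } else {
      maxv <- 2^tt$bits - 1
      if (any(v < 0 | v > maxv)) stop("value out of ", dtype, " range")
      writeBin(as.integer(v), con, size = bytes_px, endian = "little")
    }
    if (page_bytes %% 2L == 1L) writeBin(as.raw(0L), con)
  }
  # IFDs
  entry <- function(tag, type, count, value) {
    w16(tag); w16(type); w32(count)
    if (type == 3L) { w16(value); w16(0L) } else w32(value)
  }
  for (p in seq_len(npages)) {
    w16(n_entries(p))
    entry(256L, 4L, 1L, nx)                    # ImageWidth
    entry(257L, 4L, 1L, ny)                    # ImageLength
    entry(258L, 3L, 1L, tt$bits)               # BitsPerSample
    entry(259L, 3L, 1L, 1L)                    # Compression: none
    entry(262L, 3L, 1L, 1L)                    # Photometric: min-is-black
    if (p == 1L) entry(270L, 2L, length(desc_raw), off_desc)
    entry(273L, 4L, 1L, off_data[p])           # StripOffsets
    entry(277L, 3L, 1L, 1L)                    # SamplesPerPixel
    entry(278L, 4L, 1L, ny)                    # RowsPerStrip
    entry(279L, 4L, 1L, page_bytes)            # StripByteCounts
    entry(282L, 5L, 1L, off_xres)              # XResolution
    entry(283L, 5L, 1L, off_yres)              # YResolution
    entry(296L, 3L, 1L, 1L)                    # ResolutionUnit: none
    entry(339L, 3L, 1L, tt$fmt)                # SampleFormat
    w32(if (p < npages) off_ifd[p + 1] else 0L)
  }
  invisible(path)
}

#' Write a canonical (T, Z, Y, X) array as an OME-TIFF
#'
#' Planes are written in XYZTC order (z fastest) with voxel size, and frame
#' interval where present, recorded in the OME-XML ImageDescription.
#'
#' @param data 3D (z, y, x) or 4D (t, z, y, x) numeric array.
#' @param path output file path.
#' @param spacing voxel spacing, `(dz, dy, dx)` or `(dy, dx)`, in microns.
#' @param frame_interval seconds between frames, or `NULL`.
#' @param dtype one of `"uint8"`, `"uint16"`, `"uint32"`, `"float32"`.
#' @return the path, invisibly.
#' @export
write_ome_tiff <- function(data, path, spacing, frame_interval = NULL,
                           dtype = "float32") {
  if (length(dim(data)) == 3) dim(data) <- c(1L, dim(data))
  d <- dim(data)
  sp3 <- spacing3_of(spacing)
  flat <- d[2] == 1L && length(spacing) == 2
  desc <- ome_description(d, sp3, frame_interval, dtype, flat)
  pages <- vector("list", d[1] * d[2])
  k <- 0L
  for (t in seq_len(d[1])) for (z in seq_len(d[2])) {
    k <- k + 1L
    pages[[k]] <- array(data[t, z, , ], dim = d[3:4])
  }
  write_tiff_pages(pages, path, dtype, desc, dx = sp3[3], dy = sp3[2])
}
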