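# ImageStack: canonical in-memory representation of a microscopy stack.

new_image_stack <- function(data, spacing, frame_interval, axes, source_path,
                            report = list()) {
  stopifnot(length(dim(data)) %in% c(4L, 5L))
  structure(list(
    data = data,                       # (T, Z, Y, X), or (T, C, Z, Y, X) pre-slicing
    spacing = as.numeric(spacing),     # (dz, dy, dx) um, or (dy, dx) for 2D
    frame_interval = frame_interval,   # seconds, NULL for single-frame
    axes = axes,                       # source axis order, e.g. "TZYX"
    source_path = source_path,
    report = report
  ), class = "ImageStack")
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$data)
  cat("ImageStack:", paste(d, collapse = " x "),
      if (length(d) == 5) "(T,C,Z,Y,X)" else "(T,Z,Y,X)", "\n")
  cat("  source axes:", x$axes, "  spacing (um):",
      paste(signif(x$spacing, 6), collapse = ", "), "\n")
  if (!is.null(x$frame_interval))
    cat("  frame interval (s):", x$frame_interval, "\n")
  if (!is.null(x$source_path)) cat("  source:", x$source_path, "\n")
  invisible(x)
}

n_frames <- function(stack) dim(stack$data)[1]
stack_dim3 <- function(stack) {
  d <- dim(stack$data)
  d[(length(d) - 2):length(d)]
}

parse_ome_pixels <- function(desc) {
  doc <- tryCatch(xml2::read_xml(desc), error = function(e) NULL)
  if (is.null(doc)) return(NULL)
  px <- xml2::xml_find_first(doc, "//*[local-name()='Pixels']")
  if (inherits(px, "xml_missing")) return(NULL)
  a <- function(name) {
    v <- xml2::xml_attr(px, name)
    if (is.na(v)) NULL else v
  }
  num <- function(name) { v <- a(name); if (is.null(v)) NULL else as.numeric(v) }
  int <- function(name) { v <- a(name); if (is.null(v)) NULL else as.integer(v) }
  list(dim_order = a("DimensionOrder"),
       size = c(X = int("SizeX"), Y = int("SizeY"), Z = int("SizeZ"),
                C = int("SizeC"), T = int("SizeT")),
       physical = c(X = num("PhysicalSizeX"), Y = num("PhysicalSizeY"),
                    Z = num("PhysicalSizeZ")),
       time_increment = num("TimeIncrement"))
}

parse_imagej_desc <- function(desc) {
  lines <- strsplit(desc, "\n", fixed = TRUE)[[1]]
  kv <- strsplit(lines, "=", fixed = TRUE)
  kv <- kv[vapply(kv, length, 1L) == 2L]
  vals <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  num <- function(k) if (k %in% names(vals)) as.numeric(vals[[k]]) else NULL
  int <- function(k) if (k %in% names(vals)) as.integer(vals[[k]]) else NULL
  list(images = int("images"), slices = int("slices"), frames = int("frames"),
       channels = int("channels"), spacing = num("spacing"),
       finterval = num("finterval"))
}

# Axis strings are numpy-style, slowest to fastest, ending in "YX".
validate_axes_string <- function(axes, npages, page_dim_sizes = NULL) {
  axes <- toupper(axes)
  chars <- strsplit(axes, "")[[1]]
  if (anyDuplicated(chars) || !all(chars %in% c("T", "C", "Z", "Y", "X")))
    stop("invalid axis string: ", axes)
  if (length(chars) < 2 || paste(chars[(length(chars) - 1):length(chars)], collapse = "") != "YX")
    stop("axis string must end in YX: ", axes)
  axes
}

#' Load a TIFF / OME-TIFF stack into canonical (T, Z, Y, X) form
#'
#' Metadata (axis order, voxel spacing, frame interval) are inferred from the
#' OME-XML ImageDescription when present, else from ImageJ-style description
#' tags and TIFF resolution tags. OME metadata takes precedence over ImageJ
#' tags; explicit overrides beat both. Voxel spacing is required: the
#' downstream structural filter is spacing-adaptive, so a stack with no
#' inferred spacing and no override is an error.
#'
#' @param path TIFF or OME-TIFF file.
#' @param dim_order_override axis string, slowest to fastest, ending "YX"
#'   (e.g. `"TZYX"`, `"TYX"`, `"ZYX"`, `"YX"`, optionally containing `"C"`).
#' @param spacing_override voxel spacing in microns: `(dz, dy, dx)` when a Z
#'   axis is present, `(dy, dx)` otherwise.
#' @param interval_override frame interval in seconds.
#' @return an `ImageStack`; `$report` records inferred vs used metadata.
#' @export
load_stack <- function(path, dim_order_override = NULL, spacing_override = NULL,
                       interval_override = NULL) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  pages <- tryCatch(
    suppressWarnings(tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE)),
    error = function(e) {
      # float TIFFs refuse as.is; their values are already in native scale
      tryCatch(
        suppressWarnings(tiff::readTIFF(path, all = TRUE, info = TRUE)),
        error = function(e2) stop("unreadable TIFF: ", path, " (",
                                  conditionMessage(e2), ")"))
    })
  if (!is.list(pages)) pages <- list(pages)
  npages <- length(pages)
  info <- attributes(pages[[1]])
  desc <- info$description
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])

  inferred <- list(axes = NULL, spacing = NULL, frame_interval = NULL,
                   sizes = NULL, source = "none")
  ome <- if (!is.null(desc) && grepl("<OME", desc, fixed = TRUE)) parse_ome_pixels(desc) else NULL
  ij  <- if (!is.null(desc) && grepl("ImageJ", desc, fixed = TRUE)) parse_imagej_desc(desc) else NULL

  if (!is.null(ome)) {
    sz <- ome$size
    for (k in c("Z", "C", "T")) if (is.na(sz[k]) || is.null(sz[k])) sz[k] <- 1L
    # canonical slowest-to-fastest axis string from the OME sizes
    ax <- "YX"
    if (sz[["Z"]] > 1) ax <- paste0("Z", ax)
    if (sz[["C"]] > 1) ax <- paste0("C", ax)
    if (sz[["T"]] > 1) ax <- paste0("T", ax)
    inferred$axes <- ax
    inferred$sizes <- c(T = unname(sz[["T"]]), C = unname(sz[["C"]]), Z = unname(sz[["Z"]]))
    inferred$dim_order <- if (!is.null(ome$dim_order)) ome$dim_order else "XYZCT"
    sp <- ome$physical
    if (!is.null(sp) && !is.na(sp["X"]) && !is.na(sp["Y"])) {
      inferred$spacing <- if (sz[["Z"]] > 1) {
        if (!is.na(sp["Z"])) c(sp[["Z"]], sp[["Y"]], sp[["X"]]) else NULL
      } else c(sp[["Y"]], sp[["X"]])
    }
    inferred$frame_interval <- ome$time_increment
    inferred$source <- "OME"
  } else if (!is.null(ij)) {
    nC <- if (!is.null(ij$channels)) ij$channels else 1L
    nZ <- if (!is.null(ij$slices)) ij$slices else 1L
    nT <- if (!is.null(ij$frames)) ij$frames else max(1L, npages %/% (nC * nZ))
    ax <- "YX"
    if (nZ > 1) ax <- paste0("Z", ax)
    if (nC > 1) ax <- paste0("C", ax)
    if (nT > 1) ax <- paste0("T", ax)
    inferred$axes <- ax
    inferred$sizes <- c(T = nT, C = nC, Z = nZ)
    inferred$dim_order <- "imagej"   # page order: T slowest, then Z, then C fastest
    dy <- dx <- NULL
    if (!is.null(info$x.resolution) && info$x.resolution > 0) dx <- 1 / info$x.resolution
    if (!is.null(info$y.resolution) && info$y.resolution > 0) dy <- 1 / info$y.resolution
    if (!is.null(dx) && is.null(dy)) dy <- dx
    if (!is.null(dx)) {
      inferred$spacing <- if (nZ > 1) {
        if (!is.null(ij$spacing)) c(ij$spacing, dy, dx) else NULL
      } else c(dy, dx)
    }
    inferred$frame_interval <- ij$finterval
    inferred$source <- "ImageJ"
  }

  used_axes <- if (!is.null(dim_order_override)) {
    validate_axes_string(dim_order_override, npages)
  } else if (!is.null(inferred$axes)) inferred$axes
  else if (npages == 1L) "YX" else "TYX"

  chars <- strsplit(used_axes, "")[[1]]
  if (!is.null(dim_order_override) && !is.null(inferred$sizes)) {
    absent <- setdiff(names(inferred$sizes)[inferred$sizes > 1], chars)
    if (length(absent))
      stop("axis string ", used_axes, " inconsistent with file axes (",
           paste(absent, collapse = ","), " present in file)")
  }
  page_axes <- chars[!(chars %in% c("Y", "X"))]   # slowest to fastest
  # per-axis sizes for the page dimensions
  sizes <- c(T = 1L, C = 1L, Z = 1L)
  if (!is.null(dim_order_override) || is.null(inferred$sizes)) {
    if (length(page_axes) == 0) {
      if (npages != 1L) stop("axis string ", used_axes, " inconsistent with ",
                             npages, " pages")
    } else if (length(page_axes) == 1) {
      sizes[page_axes] <- npages
    } else {
      # without per-axis sizes a multi-axis page dimension is ambiguous
      if (!is.null(inferred$sizes)) {
        sizes[names(inferred$sizes)] <- inferred$sizes
      } else stop("axis string ", used_axes,
                  " needs per-axis sizes that the file does not provide")
    }
  } else sizes[names(inferred$sizes)] <- inferred$sizes
  if (prod(sizes) != npages)
    stop("axis string ", used_axes, " implies ", prod(sizes),
         " pages but file has ", npages)

  # page index (0-based) -> (t, c, z), honouring plane ordering
  fastest_first <- if (!is.null(dim_order_override) || inferred$source == "none" ||
                       identical(inferred$dim_order, "imagej")) {
    if (identical(inferred$dim_order, "imagej") && is.null(dim_order_override))
      c("C", "Z", "T") else rev(page_axes)
  } else {
    po <- strsplit(sub("^XY", "", inferred$dim_order), "")[[1]]
    po[po %in% page_axes]
  }
  fastest_first <- fastest_first[fastest_first %in% names(sizes)]
  decomp <- matrix(0L, nrow = npages, ncol = 3,
                   dimnames = list(NULL, c("T", "C", "Z")))
  rem <- 0:(npages - 1)
  for (axn in fastest_first) {
    decomp[, axn] <- rem %% sizes[[axn]]
    rem <- rem %/% sizes[[axn]]
  }

  nT <- sizes[["T"]]; nC <- sizes[["C"]]; nZ <- sizes[["Z"]]
  has_c <- "C" %in% chars && nC > 1
  if (has_c) {
    data <- array(0, dim = c(nT, nC, nZ, ny, nx))
    for (p in seq_len(npages))
      data[decomp[p, "T"] + 1L, decomp[p, "C"] + 1L, decomp[p, "Z"] + 1L, , ] <-
        as.numeric(pages[[p]])
  } else {
    data <- array(0, dim = c(nT, nZ, ny, nx))
    for (p in seq_len(npages))
      data[decomp[p, "T"] + 1L, decomp[p, "Z"] + 1L, , ] <- as.numeric(pages[[p]])
  }

  has_z <- "Z" %in% chars && nZ > 1
  spacing <- spacing_override
  if (!is.null(spacing)) {
    if (length(spacing) != (if (has_z) 3L else 2L))
      stop("spacing override must have length ", if (has_z) 3 else 2)
  } else spacing <- inferred$spacing
  missing_fields <- character()
  if (is.null(spacing)) {
    stop("no voxel spacing in metadata and no spacing_override given; ",
         "the structural filter is spacing-adaptive and requires it")
  }
  fi <- if (!is.null(interval_override)) interval_override else inferred$frame_interval
  warnings <- character()
  if (nT > 1 && is.null(fi)) {
    fi <- 1.0
    warnings <- c(warnings, "no frame interval in metadata; defaulting to 1 s (velocities read per-frame)")
    warning("no frame interval in metadata; defaulting to 1 s")
  }
  if (nT == 1) fi <- NULL

  report <- list(
    inferred = inferred[c("axes", "spacing", "frame_interval", "source")],
    used = list(axes = used_axes, spacing = spacing, frame_interval = fi,
                sizes = as.list(sizes)),
    overrides = list(axes = dim_order_override, spacing = spacing_override,
                     interval = interval_override),
    missing = missing_fields, warnings = warnings)

  new_image_stack(data, spacing, fi, used_axes, path, report)
}

#' Restrict a stack to one channel and a frame range
#'
#' Frame ranges are 0-based and half-open: frames `[t_start, t_end)` are
#' kept. A channel (0-based) is required exactly when the stack has a channel
#' axis, and selecting it removes that axis.
#'
#' @param stack an `ImageStack`.
#' @param channel 0-based channel index, required iff a C axis is present.
#' @param t_start,t_end 0-based half-open frame range; defaults keep all.
#' @return the restricted `ImageStack`, metadata preserved.
#' @export
select_slices <- function(stack, channel = NULL, t_start = NULL, t_end = NULL) {
  d <- dim(stack$data)
  has_c <- length(d) == 5L
  if (has_c) {
    if (is.null(channel)) stop("stack has a channel axis; channel selection required")
    if (channel < 0 || channel >= d[2]) stop("channel index out of range")
    data <- array(stack$data[, channel + 1L, , , ], dim = d[-2])
    axes <- gsub("C", "", stack$axes)
  } else {
    if (!is.null(channel)) stop("channel given for channel-less data")
    data <- stack$data
    axes <- stack$axes
  }
  nT <- dim(data)[1]
  if (is.null(t_start)) t_start <- 0L
  if (is.null(t_end)) t_end <- nT
  if (t_start < 0 || t_end > nT) stop("frame range out of bounds")
  if (t_start >= t_end) stop("empty frame selection [", t_start, ", ", t_end, ")")
  keep <- (t_start + 1L):t_end
  data <- array(data[keep, , , ], dim = c(length(keep), dim(data)[2:4]))
  fi <- if (length(keep) > 1) stack$frame_interval else NULL
  new_image_stack(data, stack$spacing, fi, axes, stack$source_path, stack$report)
}

#' Build an ImageStack directly from an array
#'
#' Convenience constructor for arrays already in canonical order.
#'
#' @param data 2D (y, x), 3D (z, y, x) or 4D (t, z, y, x) array; a 3D array
#'   is interpreted per `axes`.
#' @param spacing `(dz, dy, dx)` or `(dy, dx)` in microns.
#' @param frame_interval seconds per frame (`NULL` for single-frame).
#' @param axes axis string for `data` (default guessed from shape and
#'   spacing length).
#' @return an `ImageStack`.
#' @export
image_stack <- function(data, spacing, frame_interval = NULL, axes = NULL) {
  nd <- length(dim(data))
  if (is.null(axes)) {
    axes <- if (nd == 2) "YX"
    else if (nd == 3 && length(spacing) == 2) "TYX"
    else if (nd == 3) "ZYX"
    else "TZYX"
  }
  if (nd == 2) dim(data) <- c(1L, 1L, dim(data))
  else if (nd == 3 && axes == "TYX") {
    d <- dim(data); data <- array(data, dim = c(d[1], 1L, d[2], d[3]))
  } else if (nd == 3) dim(data) <- c(1L, dim(data))
  if (dim(data)[1] == 1L) frame_interval <- NULL
  new_image_stack(data, spacing, frame_interval, axes, NULL)
}
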