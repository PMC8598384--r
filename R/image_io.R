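# Reading scans and their resolution metadata, plus the ROI and settings
# text formats. All readers reduce to 8-bit intensities: 16-bit samples are
# divided by 257 (full scale maps to full scale) and colour images keep only
# the red channel, the convention of transparency-unit root scans where the
# red channel carries the most root/background contrast.

#' Load a root scan
#'
#' Reads a PNG, JPEG, BMP or TIFF raster into a [RootImage-class]. Colour
#' images are reduced to their red channel; 16-bit images are rescaled to
#' 0--255 by integer division by 257. Spatial resolution is taken from the
#' file's metadata when embedded (PNG pHYs / TIFF resolution tags / BMP
#' pixels-per-metre), otherwise the image is loaded in pixel-only mode.
#'
#' @param path path to an image file.
#' @return A [RootImage-class].
#' @examples
#' f <- tempfile(fileext = ".png")
#' png::writePNG(matrix(runif(100), 10, 10), f)
#' loadImage(f)
#' @export
loadImage <- function(path) {
  if (!file.exists(path)) stop("cannot read image file: ", path)
  ext <- tolower(tools::file_ext(path))
  res <- numeric()
  out <- tryCatch(switch(ext,
    png = {
      a <- png::readPNG(path, info = TRUE)
      info <- attr(a, "info")
      if (!is.null(info$dpi) && all(is.finite(info$dpi)) && info$dpi[1] > 0)
        res <- info$dpi[1] / 25.4
      list(a = a, bits = info$bit.depth %||% 8L)
    },
    jpg = ,
    jpeg = {
      list(a = jpeg::readJPEG(path), bits = 8L)
    },
    tif = ,
    tiff = {
      a <- tiff::readTIFF(path, info = TRUE)
      bits <- attr(a, "bits.per.sample") %||% 8L
      xres <- attr(a, "x.resolution")
      unit <- attr(a, "resolution.unit") %||% "inch"
      if (!is.null(xres) && is.finite(xres) && xres > 0)
        res <- switch(unit, cm = xres / 10, xres / 25.4)
      list(a = a, bits = bits)
    },
    bmp = .readBMP(path),
    stop("unsupported image format: ", path)
  ), error = function(e) stop("cannot decode image file ", path, ": ",
                              conditionMessage(e), call. = FALSE))
  if (!is.null(out$res) && length(out$res)) res <- out$res
  a <- out$a
  if (length(dim(a)) == 3L) a <- a[, , 1L, drop = TRUE]  # red channel only
  if (!is.matrix(a)) a <- as.matrix(a)
  if (nrow(a) < 1L || ncol(a) < 1L) stop("zero-sized image: ", path)
  px <- if (identical(out$bits, 16L) || identical(out$bits, 16))
    round(a * 65535) %/% 257
  else if (max(a) <= 1)  # normalised [0,1] from png/jpeg/tiff readers
    round(a * 255)
  else
    round(a)  # already 0-255 (BMP reader)
  rootImage(px, pxPerMm = res)
}

# Minimal BMP reader: uncompressed 8-bit palette/greyscale and 24-bit BI_RGB
# only (no installed package decodes BMP). Returns 0-255 values directly.
.readBMP <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  sig <- readBin(con, "raw", 2)
  if (!identical(rawToChar(sig), "BM")) stop("not a BMP file")
  readBin(con, "integer", 2, size = 4)               # file size, reserved
  offset <- readBin(con, "integer", 1, size = 4)
  hdrsize <- readBin(con, "integer", 1, size = 4)
  if (hdrsize < 40) stop("unsupported BMP header")
  w <- readBin(con, "integer", 1, size = 4)
  h <- readBin(con, "integer", 1, size = 4)
  readBin(con, "integer", 1, size = 2)               # planes
  bpp <- readBin(con, "integer", 1, size = 2)
  compression <- readBin(con, "integer", 1, size = 4)
  readBin(con, "integer", 1, size = 4)               # image size
  ppmx <- readBin(con, "integer", 1, size = 4)       # px per metre
  readBin(con, "integer", 3, size = 4)               # ppmy, colours used/imp.
  if (compression != 0) stop("compressed BMP not supported")
  if (!bpp %in% c(8L, 24L)) stop("only 8- and 24-bit BMP supported")
  pal <- NULL
  if (bpp == 8L) {
    npal <- (offset - 14L - hdrsize) %/% 4L
    if (npal > 0) {
      praw <- readBin(con, "raw", npal * 4L)
      pal <- matrix(as.integer(praw), ncol = 4L, byrow = TRUE)  # B,G,R,0
    }
  }
  seek(con, offset)
  topdown <- h < 0
  h <- abs(h)
  if (w < 1 || h < 1) stop("zero-sized image")
  bytesPerRow <- ((w * bpp / 8 + 3) %/% 4) * 4
  raw <- readBin(con, "raw", bytesPerRow * h)
  if (length(raw) < bytesPerRow * h) stop("truncated BMP pixel data")
  rows <- matrix(as.integer(raw), nrow = bytesPerRow)[, seq_len(h),
                                                      drop = FALSE]
  if (bpp == 8L) {
    v <- rows[seq_len(w), , drop = FALSE]
    if (!is.null(pal)) v[] <- pal[v + 1L, 3L]        # red palette entry
  } else {
    v <- rows[seq(3, by = 3, length.out = w), , drop = FALSE]  # red bytes
  }
  a <- t(v)[seq_len(h), , drop = FALSE]
  if (!topdown) a <- a[rev(seq_len(h)), , drop = FALSE]  # bottom-up rows
  res <- if (is.finite(ppmx) && ppmx > 0) ppmx / 1000 else numeric()
  list(a = a, bits = 8L, res = res)
}

#' Convert a resolution specification to pixels per mm
#'
#' @param dpi scanner resolution in dots per inch, or `NULL`.
#' @param pxPerMm resolution in pixels per mm, or `NULL`.
#' @return Pixels per mm (`dpi / 25.4` when given as DPI), or `NULL` when
#'   both arguments are `NULL` (conversion disabled; traits are reported in
#'   pixel units).
#' @examples
#' resolutionToPxPerMm(dpi = 600)   # 23.62205
#' @export
resolutionToPxPerMm <- function(dpi = NULL, pxPerMm = NULL) {
  if (is.null(dpi) && is.null(pxPerMm)) return(NULL)
  if (!is.null(dpi) && !is.null(pxPerMm))
    stop("give exactly one of dpi and pxPerMm")
  v <- if (!is.null(dpi)) dpi / 25.4 else pxPerMm
  if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
    stop("resolution must be a single positive number")
  as.numeric(v)
}

# ---------------------------------------------------------------------------
# ROI annotation files
# ---------------------------------------------------------------------------

.ROI_HEADER <- "#rootquant-roi v1"

#' Read and write region-of-interest annotation files
#'
#' One ROI per line in the versioned text format
#' `name,x,y,width,height`, where `x`,`y` are the 0-based top-left pixel
#' coordinates (origin top-left, y downward). A write/read round trip
#' reproduces the ROI list exactly, order preserved.
#'
#' @param path path of the annotation file.
#' @param rois a data.frame with columns `name`, `x`, `y`, `width`, `height`.
#' @return `readROIFile()` returns such a data.frame (zero rows for an empty
#'   file); `writeROIFile()` returns `path` invisibly.
#' @export
readROIFile <- function(path) {
  if (!file.exists(path)) stop("cannot read ROI file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  out <- data.frame(name = character(), x = integer(), y = integer(),
                    width = integer(), height = integer(),
                    stringsAsFactors = FALSE)
  for (i in which(keep)) {
    parts <- strsplit(lines[i], ",", fixed = TRUE)[[1]]
    if (length(parts) != 5L)
      stop(sprintf("ROI file %s line %d: expected 'name,x,y,width,height'",
                   path, i))
    num <- suppressWarnings(as.numeric(parts[2:5]))
    if (anyNA(num))
      stop(sprintf("ROI file %s line %d: non-numeric coordinates", path, i))
    if (num[3] < 1 || num[4] < 1)
      stop(sprintf("ROI file %s line %d: width and height must be >= 1",
                   path, i))
    if (num[1] < 0 || num[2] < 0)
      stop(sprintf("ROI file %s line %d: x and y must be >= 0", path, i))
    out[nrow(out) + 1L, ] <- list(trimws(parts[1]), as.integer(num[1]),
                                  as.integer(num[2]), as.integer(num[3]),
                                  as.integer(num[4]))
  }
  out
}

#' @rdname readROIFile
#' @export
writeROIFile <- function(rois, path) {
  need <- c("name", "x", "y", "width", "height")
  if (!all(need %in% names(rois)))
    stop("rois must have columns ", paste(need, collapse = ", "))
  if (any(grepl(",", rois$name, fixed = TRUE)))
    stop("ROI names must not contain commas")
  if (nrow(rois) && (any(rois$width < 1) || any(rois$height < 1)))
    stop("ROI width and height must be >= 1")
  lines <- c(.ROI_HEADER,
             sprintf("%s,%d,%d,%d,%d", rois$name, as.integer(rois$x),
                     as.integer(rois$y), as.integer(rois$width),
                     as.integer(rois$height)))
  writeLines(lines, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Settings CSV
# ---------------------------------------------------------------------------

.configKeys <- function() {
  list(
    mode = list(get = function(cfg) cfg@mode,
                parse = function(v) {
                  if (!v %in% c("broken_roots", "whole_root"))
                    stop("invalid value for key 'mode': ", v)
                  v
                }),
    threshold_level = list(get = function(cfg) cfg@thresholdLevel,
                           parse = .parseNum("threshold_level")),
    invert = list(get = function(cfg) cfg@invert,
                  parse = .parseBool("invert")),
    filter_background = list(get = function(cfg) cfg@filterBackground,
                             parse = .parseBool("filter_background")),
    max_component_size = list(get = function(cfg) cfg@maxComponentSize,
                              parse = .parseNum("max_component_size")),
    fill_holes = list(get = function(cfg) cfg@fillHoles,
                      parse = .parseBool("fill_holes")),
    max_hole_size = list(get = function(cfg) cfg@maxHoleSize,
                         parse = .parseNum("max_hole_size")),
    edge_smoothing = list(get = function(cfg) cfg@edgeSmoothing,
                          parse = .parseBool("edge_smoothing")),
    rdp_tolerance_px = list(get = function(cfg) cfg@rdpTolerancePx,
                            parse = .parseNum("rdp_tolerance_px")),
    pruning_enabled = list(get = function(cfg) cfg@pruningEnabled,
                           parse = .parseBool("pruning_enabled")),
    pruning_threshold_px = list(get = function(cfg) cfg@pruningThresholdPx,
                                parse = .parseNum("pruning_threshold_px")),
    diameter_bin_edges = list(
      get = function(cfg) paste(cfg@diameterBinEdges, collapse = ";"),
      parse = function(v) {
        if (!nzchar(v)) return(numeric())
        e <- suppressWarnings(as.numeric(strsplit(v, ";", fixed = TRUE)[[1]]))
        if (anyNA(e))
          stop("invalid value for key 'diameter_bin_edges': ", v)
        e
      }),
    dpi = list(get = function(cfg)
                 if (length(cfg@dpi)) cfg@dpi else "",
               parse = .parseOptNum("dpi")),
    px_per_mm = list(get = function(cfg)
                       if (length(cfg@pxPerMm)) cfg@pxPerMm else "",
                     parse = .parseOptNum("px_per_mm")))
}

.parseNum <- function(key) function(v) {
  x <- suppressWarnings(as.numeric(v))
  if (is.na(x)) stop("invalid value for key '", key, "': ", v)
  x
}

.parseOptNum <- function(key) function(v) {
  if (!nzchar(v)) return(numeric())
  x <- suppressWarnings(as.numeric(v))
  if (is.na(x)) stop("invalid value for key '", key, "': ", v)
  x
}

.parseBool <- function(key) function(v) {
  x <- switch(tolower(v), "true" = TRUE, "false" = FALSE,
              "1" = TRUE, "0" = FALSE, NA)
  if (is.na(x)) stop("invalid value for key '", key, "': ", v)
  x
}

#' Read and write analysis settings as a key,value CSV
#'
#' Missing keys take the documented defaults of [analysisConfig()]; unknown
#' keys produce a warning and are ignored; an unparsable value for a known
#' key is an error naming that key. A write/read round trip is lossless.
#'
#' @param path path of the settings CSV.
#' @param config an [AnalysisConfig-class].
#' @return `readConfig()` returns an [AnalysisConfig-class];
#'   `writeConfig()` returns `path` invisibly.
#' @export
readConfig <- function(path) {
  if (!file.exists(path)) stop("cannot read settings file: ", path)
  keys <- .configKeys()
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  vals <- list()
  for (ln in lines) {
    parts <- strsplit(ln, ",", fixed = TRUE)[[1]]
    key <- trimws(parts[1])
    if (identical(key, "key")) next  # optional header row
    value <- if (length(parts) >= 2L)
      trimws(paste(parts[-1], collapse = ",")) else ""
    if (!key %in% names(keys)) {
      warning("ignoring unknown settings key: ", key)
      next
    }
    vals[[key]] <- keys[[key]]$parse(value)
  }
  analysisConfig(
    mode = vals$mode %||% "broken_roots",
    thresholdLevel = vals$threshold_level %||% 128,
    invert = vals$invert %||% FALSE,
    filterBackground = vals$filter_background %||% FALSE,
    maxComponentSize = vals$max_component_size %||% 8,
    fillHoles = vals$fill_holes %||% FALSE,
    maxHoleSize = vals$max_hole_size %||% 8,
    edgeSmoothing = vals$edge_smoothing %||% FALSE,
    rdpTolerancePx = vals$rdp_tolerance_px %||% 2,
    pruningEnabled = vals$pruning_enabled %||% FALSE,
    pruningThresholdPx = vals$pruning_threshold_px %||% 5,
    diameterBinEdges = vals$diameter_bin_edges %||% numeric(),
    dpi = vals$dpi %||% numeric(),
    pxPerMm = vals$px_per_mm %||% numeric())
}

#' @rdname readConfig
#' @export
writeConfig <- function(config, path) {
  stopifnot(is(config, "AnalysisConfig"))
  keys <- .configKeys()
  lines <- vapply(names(keys), function(k) {
    v <- keys[[k]]$get(config)
    if (is.logical(v)) v <- tolower(as.character(v))
    sprintf("%s,%s", k, as.character(v))
  }, character(1))
  writeLines(c("key,value", lines), path)
  invisible(path)
}

# Effective pixels-per-mm for a config: explicit resolution wins over the
# image's embedded metadata.
configPxPerMm <- function(config, img = NULL) {
  if (length(config@dpi)) return(config@dpi / 25.4)
  if (length(config@pxPerMm)) return(config@pxPerMm)
  if (!is.null(img) && length(pxPerMm(img))) return(pxPerMm(img))
  numeric()
}
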