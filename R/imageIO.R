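#' @include AllClasses.R
NULL

.SUPPORTED_EXT <- c("tiff", "tif", "png", "gif", "jpeg", "jpg", "bmp")

## Minimal reader for uncompressed 24/32-bit BMP (no installed package
## decodes BMP). Returns an H x W x 3 integer array in (R, G, B) order,
## 8-bit values.
.readBMP <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 2L)
  if (!identical(as.integer(hdr), c(0x42L, 0x4DL))) stop("not a BMP file")
  readBin(con, "raw", 8L)
  offset <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  hdrSize <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  W <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  H <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  readBin(con, "integer", 1L, size = 2L, endian = "little")  # planes
  bpp <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  comp <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (!bpp %in% c(24L, 32L) || comp != 0L)
    stop("only uncompressed 24/32-bit BMP is supported")
  seek(con, offset)
  bytespp <- bpp %/% 8L
  rowBytes <- ((W * bytespp + 3L) %/% 4L) * 4L
  flip <- H > 0
  H <- abs(H)
  raw <- readBin(con, "raw", rowBytes * H)
  px <- array(0L, c(H, W, 3L))
  for (r in seq_len(H)) {
    rowOff <- (r - 1L) * rowBytes
    bytes <- as.integer(raw[rowOff + seq_len(W * bytespp)])
    m <- matrix(bytes, nrow = bytespp)        # BMP stores B, G, R(, A)
    rr <- if (flip) H - r + 1L else r
    px[rr, , 1L] <- m[3L, ]
    px[rr, , 2L] <- m[2L, ]
    px[rr, , 3L] <- m[1L, ]
  }
  px
}

## Decode one file into (pixels RGB-order array, bit depth). Raises on
## unreadable input; the batch loader converts that into a warning + skip.
.decodeImage <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tiff", "tif")) {
    x <- tiff::readTIFF(path, info = TRUE)   # scaled to [0, 1]
    bits <- attr(x, "bits.per.sample")
    depth <- if (!is.null(bits) && bits <= 8) 8L else 16L
    v <- round(x * (2^depth - 1))
    storage.mode(v) <- "integer"
    attributes(v) <- list(dim = if (length(dim(x)) == 2L) c(dim(x), 1L)
                          else dim(x))
    return(list(pixels = v, depth = depth))
  }
  if (ext == "png") {
    x <- png::readPNG(path)                   # always scaled to [0, 1]
    v <- array(as.integer(round(x * 65535)), dim = if (length(dim(x)) == 2L)
      c(dim(x), 1L) else dim(x))
    depth <- if (all(v %% 257L == 0L)) 8L else 16L
    if (depth == 8L) v <- v %/% 257L
    return(list(pixels = v, depth = depth))
  }
  if (ext %in% c("jpeg", "jpg")) {
    if (!requireNamespace("jpeg", quietly = TRUE))
      stop("the 'jpeg' package is required to read JPEG files")
    x <- jpeg::readJPEG(path)
    v <- array(as.integer(round(x * 255)), dim = if (length(dim(x)) == 2L)
      c(dim(x), 1L) else dim(x))
    return(list(pixels = v, depth = 8L))
  }
  if (ext == "bmp") return(list(pixels = .readBMP(path), depth = 8L))
  if (ext == "gif")
    stop("GIF decoding is not supported by this build; convert to PNG/TIFF")
  stop("unsupported image extension: ", ext)
}

## RGB(A)/grey array in native depth -> OverlayImage ((B,G,R), 16-bit)
.toOverlay <- function(pixels, depth, path = "") {
  d <- dim(pixels)
  if (length(d) == 2L) pixels <- array(pixels, c(d, 1L))
  nc <- dim(pixels)[3]
  if (nc == 1L) pixels <- pixels[, , c(1L, 1L, 1L), drop = FALSE]
  if (nc == 2L) pixels <- pixels[, , c(1L, 1L, 1L), drop = FALSE]  # grey+alpha
  if (nc >= 4L) pixels <- pixels[, , 1:3, drop = FALSE]            # drop alpha
  bgr <- pixels[, , c(3L, 2L, 1L), drop = FALSE]                   # RGB -> BGR
  normalizeBitDepth(bgr, depth, sourcePath = path)
}

#' Read one microscopy image as a 16-bit (B, G, R) overlay
#'
#' TIFF, PNG, JPEG and uncompressed BMP are decoded; greyscale and RGBA
#' inputs are expanded/reduced to 3 channels; 8-bit files are lifted to the
#' 16-bit processing domain (`v * 257`).
#'
#' @param path image file
#' @return an [OverlayImage-class]
#' @export
loadImage <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dec <- .decodeImage(path)
  .toOverlay(dec$pixels, dec$depth, path)
}

#' Load a folder of microscopy images in deterministic order
#'
#' Files matching `extensions` are decoded and returned sorted
#' lexicographically by filename, so the image index used throughout the
#' output tables does not depend on filesystem enumeration order.
#' Undecodable files are skipped with a warning; the load is fatal only when
#' the folder is missing, no file matches, or every file fails to decode.
#'
#' @param folder directory of images
#' @param extensions file extensions to include (subset of
#'   tiff/tif/png/gif/jpeg/jpg/bmp)
#' @return an [ImageBatch-class]
#' @export
loadImageBatch <- function(folder, extensions = c("tiff", "tif", "png")) {
  if (!dir.exists(folder)) stop("folder not found: ", folder)
  extensions <- tolower(extensions)
  bad <- setdiff(extensions, .SUPPORTED_EXT)
  if (length(bad)) stop("unsupported extensions: ", paste(bad, collapse = ", "))
  files <- list.files(folder)
  files <- files[tolower(tools::file_ext(files)) %in% extensions]
  files <- sort(files, method = "radix")      # lexicographic, locale-free
  if (length(files) == 0L) stop("no images found in ", folder)
  images <- vector("list", length(files))
  keep <- logical(length(files))
  for (i in seq_along(files)) {
    img <- tryCatch(loadImage(file.path(folder, files[i])), error = function(e) {
      warning("skipping ", files[i], ": ", conditionMessage(e), call. = FALSE)
      NULL
    })
    if (!is.null(img)) { images[[i]] <- img; keep[i] <- TRUE }
  }
  if (!any(keep)) stop("no images could be decoded in ", folder)
  new("ImageBatch", paths = file.path(folder, files[keep]),
      images = images[keep], folder = folder)
}

#' Normalize raw pixel data to the 16-bit processing domain
#'
#' 8-bit values are scaled by 257 so both extremes map exactly
#' (0 -> 0, 255 -> 65535); 16-bit values pass through.
#'
#' @param raw `H x W x 3` array in (B, G, R) order
#' @param depth declared bit depth, 8 or 16
#' @param sourcePath recorded origin (optional)
#' @return an [OverlayImage-class]
#' @export
normalizeBitDepth <- function(raw, depth, sourcePath = "") {
  depth <- as.integer(depth)
  if (!depth %in% c(8L, 16L)) stop("depth must be 8 or 16")
  if (min(raw) < 0L) stop("negative intensities")
  if (max(raw) > (if (depth == 8L) 255L else 65535L))
    stop("values exceed the declared bit depth of ", depth)
  px <- if (depth == 8L) raw * 257L else raw
  storage.mode(px) <- "integer"
  new("OverlayImage", pixels = px, sourcePath = sourcePath,
      bitDepthOriginal = depth)
}

#' Export a result table to CSV or tab-delimited text
#'
#' CSV is comma-delimited with a header row (RFC-4180 style); txt is
#' tab-delimited with a header row. Numeric values keep full precision
#' (>= 6 significant digits round-trip).
#'
#' @param table data.frame of records
#' @param path output file
#' @param dialect "csv" or "txt"
#' @return `path`, invisibly
#' @export
exportTable <- function(table, path, dialect = c("csv", "txt")) {
  dialect <- match.arg(dialect)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory not writable: ", dir)
  sep <- if (dialect == "csv") "," else "\t"
  utils::write.table(table, path, sep = sep, row.names = FALSE,
                     col.names = TRUE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Write an overlay image to a 16-bit TIFF
#'
#' @param img an [OverlayImage-class]
#' @param path output .tiff path
#' @return `path`, invisibly
#' @export
writeImage16 <- function(img, path) {
  stopifnot(is(img, "OverlayImage"))
  rgb <- img@pixels[, , c(3L, 2L, 1L), drop = FALSE] / 65535
  tiff::writeTIFF(rgb, path, bits.per.sample = 16L)
  invisible(path)
}
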