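#' Construct an intensity image grid
#'
#' A thin container for single-channel rasters (matrix) or multi-channel
#' stacks (3-D array, channels in the third dimension) with a physical
#' pixel size. Intensities must be non-negative; micrographs and landing
#' photographs are stored as raw integer counts.
#'
#' @param data numeric matrix or 3-D array of non-negative intensities.
#' @param pixel_size physical size of one pixel edge (e.g. um/pixel or
#'   cm/pixel, caller's choice; must be > 0).
#' @param channels optional character vector of channel labels for 3-D
#'   stacks.
#' @return `data` with class `image_grid` and attributes `pixel_size`,
#'   `channels`.
#' @export
image_grid <- function(data, pixel_size = 1, channels = NULL) {
  if (!(is.matrix(data) || (is.array(data) && length(dim(data)) == 3L))) {
    stop("image_grid: data must be a matrix or a 3-D array")
  }
  if (any(!is.finite(data)) || any(data < 0)) {
    stop("image_grid: intensities must be finite and non-negative")
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0) {
    stop("image_grid: pixel_size must be a single positive number")
  }
  if (!is.null(channels)) {
    if (length(dim(data)) != 3L || dim(data)[3L] != length(channels)) {
      stop("image_grid: channel labels do not match the third dimension")
    }
  }
  structure(data, pixel_size = pixel_size, channels = channels,
            class = c("image_grid", class(data)))
}

#' Read a TIFF or PNG raster as an image grid
#'
#' Pixel values are restored to their integer bit scale (0..255 for 8-bit,
#' 0..65535 for 16-bit) so that a write/read round trip is bit exact.
#'
#' @param path `.tif`/`.tiff` or `.png` file, 8- or 16-bit.
#' @param channel optional channel index (or label position) to extract
#'   from a multi-channel image; `NULL` keeps all channels.
#' @param pixel_size physical pixel size recorded on the returned grid.
#' @return an [image_grid()].
#' @export
read_image <- function(path, channel = NULL, pixel_size = 1) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = TRUE)
  } else if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    info <- attr(img, "info")
    depth <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
    if (!depth %in% c(8L, 16L)) {
      stop("read_image: unsupported PNG bit depth: ", depth)
    }
    img <- round(img * (2^depth - 1))
  } else {
    stop("read_image: unsupported file type '.", ext, "' (use TIFF or PNG)")
  }
  img <- unclass(img)
  attributes(img) <- attributes(img)["dim"]
  if (!is.null(channel)) {
    if (length(dim(img)) != 3L) {
      stop("read_image: channel requested but image is single-channel")
    }
    if (channel < 1L || channel > dim(img)[3L]) {
      stop("read_image: channel index out of range")
    }
    img <- img[, , channel]
  }
  image_grid(img, pixel_size = pixel_size)
}

#' Write an image grid to TIFF or PNG
#'
#' @param img an [image_grid()] (or plain matrix) of integer intensities.
#' @param path output path ending in `.tif`/`.tiff` or `.png`.
#' @param bits bit depth, 8 or 16.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, bits = 16L) {
  if (!bits %in% c(8L, 16L)) stop("write_image: bits must be 8 or 16")
  maxval <- 2^bits - 1
  dat <- unclass(img)
  attributes(dat) <- attributes(dat)["dim"]
  if (any(dat < 0) || any(dat > maxval)) {
    stop("write_image: intensities out of range for ", bits, "-bit output")
  }
  scaled <- dat / maxval
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(scaled, path, bits.per.sample = as.integer(bits))
  } else if (ext == "png") {
    if (bits != 8L) {
      stop("write_image: PNG output is 8-bit only; use TIFF for 16-bit")
    }
    png::writePNG(scaled, path)
  } else {
    stop("write_image: unsupported file type '.", ext, "'")
  }
  invisible(path)
}
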