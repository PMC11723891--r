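#' Construct a linear reflectance image
#'
#' A `reflectance_image` is the substrate for all color and pattern metrics:
#' an H x W x 3 array of linear reflectance values in \[0, 1\] (long-wave R,
#' medium-wave G, short-wave B channels), a pixel scale, and named binary
#' region masks (typically `"animal"` and `"background"`).
#'
#' @param pixels numeric H x W x 3 array of linear reflectance in \[0, 1\].
#' @param px_per_mm positive pixel scale (pixels per millimetre).
#' @param masks named list of logical H x W matrices; nonzero/`TRUE` marks
#'   pixels belonging to the region.
#' @return an object of class `reflectance_image`.
#' @export
reflectance_image <- function(pixels, px_per_mm, masks = list()) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be an H x W x 3 array")
  if (!all(is.finite(pixels)))
    stop("reflectance values must all be finite")
  if (min(pixels) < 0 || max(pixels) > 1)
    stop("reflectance values must lie in [0, 1]")
  if (!is.numeric(px_per_mm) || length(px_per_mm) != 1L ||
      !is.finite(px_per_mm) || px_per_mm <= 0)
    stop("`px_per_mm` must be a positive number")
  hw <- dim(pixels)[1:2]
  masks <- lapply(masks, function(m) {
    m <- as.matrix(m)
    if (!identical(dim(m), hw))
      stop("mask dimensions must match the image")
    matrix(as.logical(m != 0), nrow = hw[1], ncol = hw[2])
  })
  structure(list(pixels = pixels, px_per_mm = px_per_mm, masks = masks),
            class = "reflectance_image")
}

#' @export
print.reflectance_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("reflectance_image: %d x %d px, %.1f px/mm, masks: %s\n",
              d[1], d[2], x$px_per_mm,
              if (length(x$masks)) paste(names(x$masks), collapse = ", ")
              else "<none>"))
  invisible(x)
}

#' Calibrate a raw image to linear reflectance using gray standards
#'
#' Gray-standard patches of known reflectance photographed alongside the
#' subject control for variation in light conditions.  Assuming a linear
#' sensor, each channel is mapped from raw pixel value to reflectance by a
#' least-squares straight line through the origin fitted to the standards;
#' calibrated values are clipped to \[0, 1\] (the number of out-of-gamut
#' pixels is recorded in the `"clipped"` attribute).
#'
#' @param raw_image numeric H x W x 3 array of raw (linear) pixel values.
#' @param standards data frame with columns `mean_R`, `mean_G`, `mean_B`
#'   (raw patch means) and `known_reflectance` in \[0, 1\]; at least two rows.
#' @param px_per_mm pixel scale passed through to the result.
#' @param masks named list of region masks passed through to the result.
#' @return a [reflectance_image] with a `"clipped"` attribute counting
#'   out-of-gamut pixels per channel.
#' @export
calibrate_from_gray_standards <- function(raw_image, standards,
                                          px_per_mm = 1, masks = list()) {
  if (is.null(dim(raw_image)) || length(dim(raw_image)) != 3L ||
      dim(raw_image)[3] != 3L)
    stop("`raw_image` must be an H x W x 3 array")
  if (!all(is.finite(raw_image)))
    stop("raw pixel values must be finite")
  standards <- as.data.frame(standards)
  need <- c("mean_R", "mean_G", "mean_B", "known_reflectance")
  if (!all(need %in% names(standards)))
    stop("`standards` must have columns ", paste(need, collapse = ", "))
  if (nrow(standards) < 2L)
    stop("calibration requires at least 2 gray standards")
  if (any(diff(sort(standards$known_reflectance)) <= 0))
    stop("gray-standard known reflectances must be distinct")

  out <- raw_image
  clipped <- integer(3)
  chan_cols <- c("mean_R", "mean_G", "mean_B")
  for (k in 1:3) {
    raw <- standards[[chan_cols[k]]]
    refl <- standards$known_reflectance
    if (sum(raw^2) <= 0)
      stop("gray standards have zero variance in channel ", chan_cols[k],
           "; calibration fit is degenerate")
    slope <- sum(raw * refl) / sum(raw^2)  # LS line through the origin
    v <- raw_image[, , k] * slope
    clipped[k] <- sum(v < 0 | v > 1)
    out[, , k] <- pmin(pmax(v, 0), 1)
  }
  if (sum(clipped) > 0)
    warning(sprintf("%d calibrated pixel values clipped to [0, 1]",
                    sum(clipped)))
  img <- reflectance_image(out, px_per_mm = px_per_mm, masks = masks)
  attr(img, "clipped") <- clipped
  img
}

#' Mean reflectance of a masked region
#'
#' @param image a [reflectance_image].
#' @param mask_name name of the mask to average over.
#' @return named numeric triple `c(R =, G =, B =)` of per-channel means.
#' @export
mean_region_reflectance <- function(image, mask_name) {
  stopifnot(inherits(image, "reflectance_image"))
  m <- image$masks[[mask_name]]
  if (is.null(m))
    stop("no mask named '", mask_name, "' in image")
  if (!any(m))
    stop("mask '", mask_name, "' is empty")
  c(R = mean(image$pixels[, , 1][m]),
    G = mean(image$pixels[, , 2][m]),
    B = mean(image$pixels[, , 3][m]))
}

check_rgb <- function(rgb) {
  if (length(rgb) != 3L || !all(is.finite(rgb)))
    stop("`rgb` must be a finite numeric triple")
  as.numeric(rgb)
}

#' Color metrics from an RGB reflectance triple
#'
#' Four region-level color descriptors computed from mean channel
#' reflectances, separating achromatic and chromatic properties:
#' \describe{
#'   \item{`brightness()`}{light intensity, the channel mean (R + G + B)/3.}
#'   \item{`saturation()`}{Euclidean distance from pure white (1, 1, 1);
#'     larger distances mean less white light mixed in, i.e. higher
#'     saturation.  Bounded by sqrt(3) for channels in \[0, 1\].}
#'   \item{`hue1()`}{opponent-channel ratio R/G; high values indicate red,
#'     low values green reflectance.}
#'   \item{`hue2()`}{opponent-channel ratio (R + G)/B; high values indicate
#'     yellow, low values blue reflectance.}
#' }
#'
#' @param rgb numeric triple of channel reflectances (R, G, B).
#' @return a single numeric value.
#' @export
brightness <- function(rgb) {
  rgb <- check_rgb(rgb)
  mean(rgb)
}

#' @rdname brightness
#' @export
saturation <- function(rgb) {
  rgb <- check_rgb(rgb)
  if (any(rgb < 0 | rgb > 1))
    stop("saturation requires channels in [0, 1]")
  sqrt(sum((1 - rgb)^2))
}

#' @rdname brightness
#' @export
hue1 <- function(rgb) {
  rgb <- check_rgb(rgb)
  if (rgb[2] == 0)
    stop("hue1 = R/G undefined when G = 0")
  rgb[1] / rgb[2]
}

#' @rdname brightness
#' @export
hue2 <- function(rgb) {
  rgb <- check_rgb(rgb)
  if (rgb[3] == 0)
    stop("hue2 = (R+G)/B undefined when B = 0")
  (rgb[1] + rgb[2]) / rgb[3]
}

#' All four color metrics for one region
#'
#' @param image a [reflectance_image].
#' @param mask_name region mask name.
#' @return named numeric vector `brightness`, `saturation`, `hue1`, `hue2`
#'   computed on the region's mean RGB.
#' @export
region_color_metrics <- function(image, mask_name) {
  rgb <- mean_region_reflectance(image, mask_name)
  c(brightness = brightness(rgb), saturation = saturation(rgb),
    hue1 = hue1(rgb), hue2 = hue2(rgb))
}

#' Read an image file (PNG or TIFF) as a raw H x W x 3 array
#'
#' Values are read as linear by default; set `assume_srgb = TRUE` to apply
#' the inverse sRGB transfer function first (for gamma-encoded files).
#'
#' @param path image file path (`.png`, `.tif`, `.tiff`).
#' @param assume_srgb apply inverse sRGB electro-optical transfer first.
#' @return numeric H x W x 3 array in \[0, 1\].
#' @export
read_image_rgb <- function(path, assume_srgb = FALSE) {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
              png = png::readPNG(path),
              tif = ,
              tiff = tiff::readTIFF(path),
              stop("unsupported image format: .", ext))
  if (length(dim(x)) == 2L)
    x <- array(rep(x, 3), dim = c(dim(x), 3))
  x <- x[, , 1:3, drop = FALSE]
  if (assume_srgb) {
    lo <- x <= 0.04045
    x[lo] <- x[lo] / 12.92
    x[!lo] <- ((x[!lo] + 0.055) / 1.055)^2.4
  }
  x
}

#' Read a single-channel mask image (nonzero = in region)
#'
#' @param path PNG/TIFF file path.
#' @return logical matrix.
#' @export
read_mask <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
              png = png::readPNG(path),
              tif = ,
              tiff = tiff::readTIFF(path),
              stop("unsupported mask format: .", ext))
  if (length(dim(x)) == 3L) x <- x[, , 1]
  x != 0
}
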