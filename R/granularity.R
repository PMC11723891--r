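#' Build a geometric bank of spatial scales for granularity analysis
#'
#' Scales (band centers, wavelengths in pixels) form a geometric sequence
#' `min_px * ratio^k` up to `max_px` inclusive; with the defaults this is
#' the standard camouflage-granularity bank of 15 filters from 2 to 256 px
#' in multiples of sqrt(2).  Band edges sit at the geometric midpoints
#' between adjacent scales; the outermost edges are `min_px` (the Nyquist
#' wavelength at the default) and `max_px`.
#'
#' @param min_px smallest scale in pixels (> 0).
#' @param max_px largest scale in pixels (>= `min_px`).
#' @param ratio geometric step between scales (> 1).
#' @return object of class `scale_bank` with elements `scales_px` and
#'   `band_edges_px` (matrix with columns `lower`, `upper`; bands are
#'   half-open `[lower, upper)` except the last, which is closed).
#' @export
build_scale_bank <- function(min_px = 2, max_px = 256, ratio = sqrt(2)) {
  if (!is.finite(min_px) || min_px <= 0 || !is.finite(max_px) ||
      max_px < min_px || !is.finite(ratio) || ratio <= 1)
    stop("require 0 < min_px <= max_px and ratio > 1")
  n <- floor(log(max_px / min_px) / log(ratio) + 1e-9) + 1L
  scales <- min_px * ratio^(seq_len(n) - 1L)
  if (n == 1L) {
    edges <- cbind(lower = min_px, upper = max_px)
  } else {
    mids <- sqrt(scales[-n] * scales[-1])
    edges <- cbind(lower = c(min_px, mids), upper = c(mids, max_px))
  }
  structure(list(scales_px = scales, band_edges_px = edges),
            class = "scale_bank")
}

#' @export
print.scale_bank <- function(x, ...) {
  cat(sprintf("scale_bank: %d scales, %.4g .. %.4g px\n",
              length(x$scales_px), min(x$scales_px), max(x$scales_px)))
  invisible(x)
}

next_pow2 <- function(n) 2^ceiling(log2(n))

# Wavelength (px/cycle) of every FFT bin of an H2 x W2 raster; Inf at DC.
fft_wavelengths <- function(h, w) {
  fu <- pmin(0:(h - 1), h - (0:(h - 1))) / h
  fv <- pmin(0:(w - 1), w - (0:(w - 1))) / w
  f <- sqrt(outer(fu^2, fv^2, `+`))
  wl <- 1 / f
  wl[1, 1] <- Inf
  wl
}

# Mean-center, optionally Hann-window, zero-pad to powers of two, FFT.
# Returns the padded spectrum plus the normalization constant that makes
# total in-band energy equal the mean-centered raster's variance.
channel_spectrum <- function(channel, hann = FALSE) {
  channel <- as.matrix(channel)
  h <- nrow(channel); w <- ncol(channel)
  if (h < 2L || w < 2L) stop("raster must be at least 2 x 2")
  x <- channel - mean(channel)
  if (hann) {
    wh <- 0.5 - 0.5 * cos(2 * pi * (seq_len(h) - 1) / (h - 1))
    ww <- 0.5 - 0.5 * cos(2 * pi * (seq_len(w) - 1) / (w - 1))
    x <- x * outer(wh, ww)
  }
  h2 <- next_pow2(h); w2 <- next_pow2(w)
  pad <- matrix(0, h2, w2)
  pad[seq_len(h), seq_len(w)] <- x
  list(F = stats::fft(pad), wl = fft_wavelengths(h2, w2),
       norm = as.numeric(h2) * w2 * h * w, n_orig = h * w,
       dim_pad = c(h2, w2))
}

#' Pattern energy of a raster within one wavelength band
#'
#' The raster is mean-centered, zero-padded to powers of two, and Fourier
#' transformed.  Band energy is the sum of squared spectral amplitudes over
#' all frequency bins whose wavelength (pixels per cycle) falls inside the
#' band, normalized so that the energies of a complete set of bands sum to
#' the variance of the mean-centered raster (a Parseval identity).
#'
#' @param channel numeric matrix (single-channel raster), at least 2 x 2.
#' @param band numeric length-2 `(lower, upper)` wavelength interval in
#'   pixels; bins are counted in `[lower, upper)`, or `[lower, upper]` when
#'   `include_upper = TRUE`.
#' @param include_upper include wavelengths equal to the upper edge.
#' @return non-negative scalar energy.
#' @export
band_energy <- function(channel, band, include_upper = FALSE) {
  if (length(band) != 2L || !all(is.finite(band)) || band[1] <= 0 ||
      band[2] <= band[1])
    stop("`band` must be a positive increasing (lower, upper) pair")
  sp <- channel_spectrum(channel)
  if (band[1] > max(dim(as.matrix(channel))))
    stop("band lies outside wavelengths representable in this raster")
  sel <- sp$wl >= band[1] &
    (if (include_upper) sp$wl <= band[2] else sp$wl < band[2])
  sum(Mod(sp$F[sel])^2) / sp$norm
}

#' Granularity spectrum and its three pattern descriptors
#'
#' Decomposes a region raster into the wavelength bands of a [scale
#' bank][build_scale_bank] and summarizes the band energies as: overall
#' pattern contrast (total energy across all scales), dominant marking size
#' (the scale whose band holds the most energy; ties broken toward the
#' smallest scale), and pattern diversity (the proportion of energy at the
#' dominant scale).
#'
#' @param channel numeric matrix, e.g. from [pattern_channel()].
#' @param bank a [scale_bank][build_scale_bank]; defaults to the standard
#'   15-scale bank.
#' @param energy `"power"` (spectral power per annular band; default) or
#'   `"sd"` (standard deviation of the band-pass filtered image, an
#'   alternative used by some granularity implementations).
#' @param diversity `"of_total"` (max energy / total energy, in (0, 1\];
#'   default) or `"of_rest"` (max energy / remaining energy).
#' @param hann apply a Hann window before the transform (off by default;
#'   windowing breaks the exact Parseval identity).
#' @return object of class `granularity_spectrum` with `scales_px`,
#'   `energy`, `overall_contrast`, `dominant_size_px`, `diversity`, and an
#'   `undefined` flag set when the region is constant (zero total energy),
#'   in which case the three descriptors are `NA` and the record should be
#'   excluded downstream.
#' @export
granularity_spectrum <- function(channel, bank = build_scale_bank(),
                                 energy = c("power", "sd"),
                                 diversity = c("of_total", "of_rest"),
                                 hann = FALSE) {
  energy <- match.arg(energy)
  diversity <- match.arg(diversity)
  stopifnot(inherits(bank, "scale_bank"))
  sp <- channel_spectrum(channel, hann = hann)
  edges <- bank$band_edges_px
  nb <- nrow(edges)
  e <- numeric(nb)
  for (i in seq_len(nb)) {
    sel <- sp$wl >= edges[i, "lower"] &
      (if (i == nb) sp$wl <= edges[i, "upper"] else sp$wl < edges[i, "upper"])
    e[i] <- if (energy == "power") {
      sum(Mod(sp$F[sel])^2) / sp$norm
    } else {
      filt <- sp$F
      filt[!sel] <- 0
      img <- Re(stats::fft(filt, inverse = TRUE)) / prod(sp$dim_pad)
      h <- nrow(as.matrix(channel)); w <- ncol(as.matrix(channel))
      stats::sd(img[seq_len(h), seq_len(w)])
    }
  }
  tot <- sum(e)
  undefined <- !(tot > 0)
  if (undefined) {
    dom <- NA_real_; div <- NA_real_; contrast <- NA_real_
  } else {
    contrast <- tot
    k <- which.max(e)          # which.max takes the first (smallest) scale on ties
    dom <- bank$scales_px[k]
    div <- if (diversity == "of_total") max(e) / tot
           else max(e) / (tot - max(e))
  }
  structure(list(scales_px = bank$scales_px, energy = e,
                 overall_contrast = contrast, dominant_size_px = dom,
                 diversity = div, undefined = undefined),
            class = "granularity_spectrum")
}

#' @export
print.granularity_spectrum <- function(x, ...) {
  if (x$undefined) {
    cat("granularity_spectrum: undefined (constant region)\n")
  } else {
    cat(sprintf(paste0("granularity_spectrum: contrast %.4g, dominant size",
                       " %.4g px, diversity %.3f\n"),
                x$overall_contrast, x$dominant_size_px, x$diversity))
  }
  invisible(x)
}

#' Extract the pattern channel of a masked region
#'
#' Granularity analysis runs on the mean of the red and green channels
#' (the luminance-like channel used for marking analysis), restricted to
#' the mask's bounding box.  Out-of-mask pixels inside the box are filled
#' with the in-mask mean so they contribute no spurious band energy.
#'
#' @param image a [reflectance_image].
#' @param mask_name region mask name.
#' @return list with `channel` (matrix), `mask` (logical matrix over the
#'   bounding box), and `n_in_mask`.
#' @export
pattern_channel <- function(image, mask_name) {
  stopifnot(inherits(image, "reflectance_image"))
  m <- image$masks[[mask_name]]
  if (is.null(m)) stop("no mask named '", mask_name, "' in image")
  if (!any(m)) stop("mask '", mask_name, "' is empty")
  rows <- range(which(rowSums(m) > 0))
  cols <- range(which(colSums(m) > 0))
  ri <- rows[1]:rows[2]; ci <- cols[1]:cols[2]
  ch <- (image$pixels[, , 1] + image$pixels[, , 2]) / 2
  ch <- ch[ri, ci, drop = FALSE]
  sub <- m[ri, ci, drop = FALSE]
  fill <- mean(ch[sub])
  ch[!sub] <- fill
  list(channel = ch, mask = sub, n_in_mask = sum(sub))
}

#' Pixel-scale adequacy check for pattern analysis
#'
#' Marking analysis is only meaningful above a minimum spatial resolution;
#' the conventional requirement is 15 pixels per millimetre.  Images below
#' the threshold are excluded from pattern (but not color) analysis.
#'
#' @param px_per_mm pixel scale of the image (> 0).
#' @param threshold minimum acceptable scale (default 15 px/mm).
#' @return `TRUE` (pass) or `FALSE` (exclude from pattern analysis).
#' @export
check_pixel_scale <- function(px_per_mm, threshold = 15) {
  if (!is.numeric(px_per_mm) || length(px_per_mm) != 1L ||
      !is.finite(px_per_mm) || px_per_mm <= 0)
    stop("`px_per_mm` must be a positive number")
  px_per_mm >= threshold
}

#' Granularity descriptors for one masked region of an image
#'
#' @inheritParams pattern_channel
#' @param bank a [scale_bank][build_scale_bank].
#' @param ... passed to [granularity_spectrum()].
#' @return a `granularity_spectrum`.
#' @export
region_granularity <- function(image, mask_name, bank = build_scale_bank(),
                               ...) {
  pc <- pattern_channel(image, mask_name)
  granularity_spectrum(pc$channel, bank = bank, ...)
}
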