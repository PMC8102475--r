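# FLER perfusion cartography rendering

#' Render a perfusion cartography overlay from a rise-time map
#'
#' Maps rise times through a perceptually uniform colormap between fixed
#' normalization bounds into an RGBA overlay. Invalid pixels are fully
#' transparent; values outside the bounds are clamped to the endpoints.
#' Overlaying ("fluorescence-based enhanced reality") is done with
#' [blendCartography()] or at write time with [writeCartography()].
#'
#' @param map a [TTPMap-class].
#' @param bounds length-2 `(ttp_lo, ttp_hi)` in seconds; defaults to the
#'   range of valid rise times (requires at least two distinct values).
#' @param colormap an `grDevices::hcl.colors` palette name.
#' @param alpha overlay opacity for valid pixels, in `[0, 1]`.
#' @return a [Cartography-class].
#' @export
renderCartography <- function(map, bounds = NULL, colormap = "viridis",
                              alpha = 0.6) {
  stopifnot(is(map, "TTPMap"))
  v <- validMask(map)
  if (is.null(bounds)) {
    if (!any(v)) bounds <- c(0, 1)
    else {
      bounds <- range(ttp(map)[v])
      if (diff(bounds) <= 0) bounds <- bounds + c(-0.5, 0.5)
    }
  }
  if (length(bounds) != 2L || bounds[1L] >= bounds[2L])
    stop("'bounds' must be finite with ttp_lo < ttp_hi", call. = FALSE)
  ncolors <- 256L
  pal <- grDevices::hcl.colors(ncolors, palette = colormap)
  rgbpal <- grDevices::col2rgb(pal) / 255
  d <- dim(map)
  rgba <- array(0, c(d[1L], d[2L], 4L))
  if (any(v)) {
    z <- clamp((ttp(map)[v] - bounds[1L]) / diff(bounds), 0, 1)
    idx <- pmin(ncolors, 1L + floor(z * ncolors))
    for (ch in 1:3) {
      band <- matrix(0, d[1L], d[2L])
      band[v] <- rgbpal[ch, idx]
      rgba[, , ch] <- band
    }
    a <- matrix(0, d[1L], d[2L])
    a[v] <- alpha
    rgba[, , 4L] <- a
  }
  new("Cartography", rgba = rgba, bounds = as.numeric(bounds),
      colormap = colormap)
}

#' Alpha-blend a cartography overlay onto a background frame
#'
#' @param cart a [Cartography-class].
#' @param background numeric `H x W` grayscale frame (any range; rescaled
#'   by `backgroundMax` to `[0, 1]`).
#' @param backgroundMax value mapped to white (default `max(background)`,
#'   or 1 if the background is blank).
#' @return numeric `H x W x 3` RGB array in `[0, 1]`; equals the
#'   (grayscale) background wherever the overlay is transparent.
#' @export
blendCartography <- function(cart, background, backgroundMax = NULL) {
  stopifnot(is(cart, "Cartography"))
  rgba <- overlayArray(cart)
  if (!is.matrix(background) ||
      !identical(dim(background), dim(rgba)[1:2]))
    stop("background dimensions must match the cartography", call. = FALSE)
  if (is.null(backgroundMax)) backgroundMax <- max(background, 1e-12)
  bg <- clamp(background / backgroundMax, 0, 1)
  out <- array(0, c(dim(bg), 3L))
  a <- rgba[, , 4L]
  for (ch in 1:3) out[, , ch] <- a * rgba[, , ch] + (1 - a) * bg
  out
}

#' Write a cartography (optionally blended onto a background) as PNG
#'
#' @inheritParams blendCartography
#' @param path output PNG file.
#' @param background optional background frame; if omitted the RGBA
#'   overlay itself is written (transparent where invalid).
#' @return `path`, invisibly.
#' @export
writeCartography <- function(cart, path, background = NULL,
                             backgroundMax = NULL) {
  img <- if (is.null(background)) overlayArray(cart)
         else blendCartography(cart, background, backgroundMax)
  png::writePNG(img, target = path)
  invisible(path)
}
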