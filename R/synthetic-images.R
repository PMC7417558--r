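#' Generate a synthetic panel image stack with known coverage
#'
#' Plants a single connected foreground region (the first
#' `round(coverageFrac * width * height)` pixels in raster order) at gray
#' level 220 on a background of 50, replicated over `depth` slices, and adds
#' independent Gaussian pixel noise per slice. The stored true coverage is
#' the exact planted foreground pixel fraction before noise.
#'
#' @param width,height image size in pixels (> 0).
#' @param depth number of slices (>= 1).
#' @param coverageFrac planted foreground fraction in \[0, 1\].
#' @param noiseSd Gaussian noise sd in gray levels (>= 0).
#' @param seed integer seed.
#' @return A [PanelImageStack] with `trueCoverage` set.
#' @examples
#' st <- genPanelStack(32, 32, depth = 3, coverageFrac = 0.5, noiseSd = 0,
#'                     seed = 1)
#' trueCoverage(st)
#' @export
genPanelStack <- function(width, height, depth = 1, coverageFrac,
                          noiseSd = 0, seed) {
  if (width < 1 || height < 1 || depth < 1)
    stop("image dimensions must be positive")
  stopifnotFraction(coverageFrac, "coverageFrac")
  if (noiseSd < 0) stop("'noiseSd' must be >= 0")
  npix <- as.integer(width) * as.integer(height)
  k <- round(coverageFrac * npix)
  mask <- matrix(seq_len(npix) <= k, nrow = height, ncol = width, byrow = TRUE)
  base <- ifelse(mask, 220, 50)
  withSeed(seed, {
    px <- array(0, dim = c(depth, height, width))
    for (z in seq_len(depth)) {
      noisy <- base + if (noiseSd > 0) rnorm(npix, 0, noiseSd) else 0
      px[z, , ] <- round(clamp(noisy, 0, 255))
    }
    PanelImageStack(px, bitDepth = 8, trueCoverage = k / npix)
  })
}

#' Write a panel stack as one PNG file per slice
#'
#' @param stack a [PanelImageStack].
#' @param prefix path prefix; slice `z` goes to `<prefix>_z<z>.png`.
#' @return Character vector of written paths, invisibly.
#' @export
writePanelStack <- function(stack, prefix) {
  px <- stackPixels(stack)
  maxv <- if (stack@bitDepth == 8) 255 else 65535
  paths <- character(dim(px)[1])
  for (z in seq_len(dim(px)[1])) {
    paths[z] <- sprintf("%s_z%03d.png", prefix, z)
    png::writePNG(px[z, , ] / maxv, paths[z])
  }
  invisible(paths)
}

#' Read a panel stack from PNG slice files
#'
#' @param paths PNG files, one per slice, in slice order.
#' @return A [PanelImageStack] (8-bit scale).
#' @export
readPanelStack <- function(paths) {
  slices <- lapply(paths, function(p) {
    im <- png::readPNG(p)
    if (length(dim(im)) == 3L) im <- apply(im, c(1, 2), mean)
    round(im * 255)
  })
  h <- nrow(slices[[1]]); w <- ncol(slices[[1]])
  px <- array(0, dim = c(length(slices), h, w))
  for (z in seq_along(slices)) px[z, , ] <- slices[[z]]
  PanelImageStack(px, bitDepth = 8)
}
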