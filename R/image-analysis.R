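# Panel-photograph quantification: maximum-intensity projection, 8-bit
# conversion, Otsu binarization, small-particle removal, percent coverage.

#' Maximum intensity projection of an image stack
#'
#' Per-pixel maximum across the slices: `out(y, x) = max_z in(z, y, x)`.
#' A depth-1 stack returns its single slice unchanged; projecting an
#' already-projected image is the identity.
#'
#' @param stack a [PanelImageStack] or a `depth x height x width` array.
#' @return Numeric matrix `height x width`.
#' @export
maxIntensityProjection <- function(stack) {
  px <- if (is(stack, "PanelImageStack")) stackPixels(stack) else stack
  if (is.matrix(px)) return(px)
  if (length(dim(px)) != 3L || dim(px)[1] < 1L)
    stop("'stack' must have at least one slice")
  apply(px, c(2, 3), max)
}

#' Convert an image to 8-bit grayscale
#'
#' Multichannel inputs (height x width x channels) are averaged across
#' channels, then intensities are rescaled linearly from the input bit
#' range to 0..255 and rounded half up. 8-bit grayscale input is returned
#' unchanged.
#'
#' @param image matrix or height x width x channels array.
#' @param bitDepth input bit depth, 8 or 16; by default guessed from the
#'   data (16 when any intensity exceeds 255).
#' @return Integer-valued matrix with entries in 0..255.
#' @examples
#' toGray8(matrix(65535, 2, 2))  # all 255
#' @export
toGray8 <- function(image, bitDepth = NULL) {
  if (length(dim(image)) == 3L) image <- apply(image, c(1, 2), mean)
  image <- as.matrix(image)
  if (is.null(bitDepth)) bitDepth <- if (max(image) > 255) 16 else 8
  if (!bitDepth %in% c(8, 16)) stop("'bitDepth' must be 8 or 16")
  maxIn <- 2^bitDepth - 1
  scaled <- image / maxIn * 255
  out <- floor(scaled + 0.5)   # round half up
  matrix(clamp(out, 0, 255), nrow(image), ncol(image))
}

#' Otsu threshold of an 8-bit image
#'
#' The threshold `t` in 0..254 maximizing the between-class variance of the
#' 256-bin histogram split into \{0..t\} and \{t+1..255\}; the smallest
#' maximizer is returned.
#'
#' @param image 8-bit matrix.
#' @return Integer threshold; foreground is conventionally `> t`.
#' @export
otsuThreshold <- function(image) {
  v <- as.vector(image)
  h <- tabulate(v + 1L, nbins = 256L)
  n <- sum(h)
  lev <- 0:255
  w0 <- cumsum(h)
  m0 <- cumsum(h * lev)
  mT <- m0[256]
  w0k <- w0[1:255]
  w1k <- n - w0k
  valid <- w0k > 0 & w1k > 0
  if (!any(valid)) return(NA_integer_)
  mu0 <- m0[1:255] / w0k
  mu1 <- (mT - m0[1:255]) / w1k
  bc <- w0k * w1k * (mu0 - mu1)^2
  bc[!valid] <- -Inf
  which.max(bc) - 1L
}

# 8-connected component labels of a logical mask, via a pixel-adjacency
# graph; returns an integer matrix (0 = background).
labelComponents <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  fg <- which(mask)
  lab <- matrix(0L, h, w)
  if (!length(fg)) return(lab)
  row <- (fg - 1L) %% h + 1L
  col <- (fg - 1L) %/% h + 1L
  idxOf <- matrix(0L, h, w)
  idxOf[fg] <- seq_along(fg)
  edges <- list()
  for (dd in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- row + dd[1]; c2 <- col + dd[2]
    ok <- r2 >= 1L & r2 <= h & c2 >= 1L & c2 <= w
    if (!any(ok)) next
    nb <- idxOf[cbind(r2[ok], c2[ok])]
    has <- nb > 0L
    if (any(has))
      edges[[length(edges) + 1L]] <-
        cbind(which(ok)[has], nb[has])
  }
  gr <- igraph::graph_from_edgelist(
    if (length(edges)) do.call(rbind, edges) else matrix(0L, 0, 2),
    directed = FALSE)
  gr <- igraph::add_vertices(gr, max(0L, length(fg) - igraph::vcount(gr)))
  comp <- igraph::components(gr)$membership
  lab[fg] <- comp
  lab
}

#' Binarize an 8-bit image and remove small particles
#'
#' Thresholds the image (Otsu by default, or a fixed level), orients the
#' foreground according to `polarity`, and removes 8-connected components
#' smaller than `minParticlePx` pixels (the noise filter preceding particle
#' analysis). A constant image under Otsu falls back to the fixed midpoint
#' 128 with a warning.
#'
#' @param image 8-bit matrix (e.g. from [toGray8()]).
#' @param thresholdMethod `"otsu"` or `"fixed"`.
#' @param fixedThreshold level in 0..255, required when
#'   `thresholdMethod = "fixed"`.
#' @param polarity `"bright_is_fouling"` (foreground above threshold) or
#'   `"dark_is_fouling"`.
#' @param minParticlePx minimum particle size kept, in pixels (default 5).
#' @return Logical mask matrix; the threshold used is attached as attribute
#'   `"threshold"`.
#' @export
binarizeAndClean <- function(image,
                             thresholdMethod = c("otsu", "fixed"),
                             fixedThreshold = NULL,
                             polarity = c("bright_is_fouling",
                                          "dark_is_fouling"),
                             minParticlePx = 5) {
  thresholdMethod <- match.arg(thresholdMethod)
  polarity <- match.arg(polarity)
  if (thresholdMethod == "fixed") {
    if (is.null(fixedThreshold))
      stop("'fixedThreshold' is required with thresholdMethod = 'fixed'")
    thr <- fixedThreshold
  } else {
    thr <- otsuThreshold(image)
    if (is.na(thr)) {
      warning("constant image: Otsu undefined, falling back to threshold 128")
      thr <- 128L
    }
  }
  mask <- if (polarity == "bright_is_fouling") image > thr else image <= thr
  if (minParticlePx > 1) {
    lab <- labelComponents(mask)
    if (any(lab > 0L)) {
      sizes <- tabulate(lab[lab > 0L])
      drop <- which(sizes < minParticlePx)
      if (length(drop)) mask[lab %in% drop] <- FALSE
    }
  }
  attr(mask, "threshold") <- thr
  mask
}

#' Percent coverage of a binary mask
#'
#' `100 * foreground pixels within the ROI / ROI pixel count`. The ROI is
#' 0-based and half-open: `c(x0, y0, x1, y1)` covers columns `x0..x1-1` and
#' rows `y0..y1-1`.
#'
#' @param mask logical matrix (foreground = `TRUE`).
#' @param roi integer(4) `c(x0, y0, x1, y1)` or `NULL` for the whole mask.
#' @return Coverage percentage in \[0, 100\].
#' @examples
#' coveragePercent(matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2))  # 50
#' @export
coveragePercent <- function(mask, roi = NULL) {
  if (!is.null(roi)) {
    if (length(roi) != 4L) stop("'roi' must be c(x0, y0, x1, y1)")
    x0 <- roi[1]; y0 <- roi[2]; x1 <- roi[3]; y1 <- roi[4]
    if (x1 <= x0 || y1 <= y0) stop("empty ROI")
    if (x0 < 0 || y0 < 0 || x1 > ncol(mask) || y1 > nrow(mask))
      stop("ROI outside mask bounds")
    mask <- mask[(y0 + 1):y1, (x0 + 1):x1, drop = FALSE]
  }
  if (!length(mask)) stop("empty ROI")
  100 * sum(mask) / length(mask)
}

#' Full coverage measurement of a panel stack
#'
#' Convenience wrapper running the whole chain: maximum intensity
#' projection, 8-bit conversion, Otsu (or fixed) binarization with particle
#' cleaning, and percent coverage within the stack's ROI.
#'
#' @param stack a [PanelImageStack].
#' @param ... passed to [binarizeAndClean()].
#' @return Coverage percentage.
#' @export
measureCoverage <- function(stack, ...) {
  img <- toGray8(maxIntensityProjection(stack), bitDepth = stack@bitDepth)
  mask <- binarizeAndClean(img, ...)
  roi <- if (length(stack@roi)) stack@roi else NULL
  coveragePercent(mask, roi)
}
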