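# Coordinate convention used throughout the image code: 0-based (x, y)
# coordinates with pixel centers at integers; an image array is indexed
# image[y + 1, x + 1].

# add one symmetric 2D Gaussian (integrated amplitude at the peak =
# `amp`) to an image, vectorized over its local +/-4 sigma window
addGaussianSpot <- function(img, x, y, amp, sigma) {
  h <- nrow(img); w <- ncol(img)
  r <- ceiling(4 * sigma)
  xs <- max(0L, floor(x - r)):min(w - 1L, ceiling(x + r))
  ys <- max(0L, floor(y - r)):min(h - 1L, ceiling(y + r))
  if (!length(xs) || !length(ys)) return(img)
  g <- amp * exp(-outer((ys - y)^2, (xs - x)^2, "+") / (2 * sigma^2))
  img[ys + 1L, xs + 1L] <- img[ys + 1L, xs + 1L] + g
  img
}

#' Render a synthetic two-channel CoSMoS movie
#'
#' Tethered-molecule spots are rendered as symmetric 2D Gaussians (the PSF
#' model used for 5x5-window spot fits). The red (>635 nm) channel carries
#' the always-on RNA spots plus fiducial beads; the green (<635 nm) channel
#' carries the ligand fluorescence, switched on per frame by the binding
#' matrix, at coordinates transformed by the channel mapping. Fiducials are
#' bright in both channels. Drift is applied cumulatively, camera noise is
#' Poisson shot noise plus Gaussian read noise, and the full ground truth is
#' returned (and can be serialized) alongside the pixel data.
#'
#' @param positions n x 2 matrix of red-channel spot centers (x, y), 0-based;
#'   must be at least 3 px inside the image.
#' @param binding n x nFrames logical matrix; TRUE = ligand present on that
#'   molecule in that frame.
#' @param dim image size \code{c(height, width)} in px.
#' @param fiducials m x 2 matrix of fiducial bead centers (red-channel
#'   coordinates).
#' @param transform \linkS4class{SimilarityTransform} mapping red to green
#'   coordinates (default identity).
#' @param drift nFrames x 2 matrix of cumulative (dx, dy) displacements.
#' @param psfSigma PSF standard deviation, px.
#' @param amplitude peak photon count of a single fluorophore spot.
#' @param background background photon count per pixel.
#' @param readNoiseSD Gaussian read-noise sd (counts).
#' @param poisson apply Poisson shot noise.
#' @param seed mandatory seed.
#' @return list with \code{red} and \code{green} (h x w x nFrames arrays),
#'   \code{fiducialsRed}, \code{fiducialsGreen} and \code{truth} (inputs
#'   echoed back as ground truth).
#' @export
renderMovie <- function(positions, binding, dim = c(64L, 64L),
                        fiducials = NULL, transform = NULL, drift = NULL,
                        psfSigma = 1.1, amplitude = 400, background = 100,
                        readNoiseSD = 5, poisson = TRUE, seed) {
  if (missing(seed)) stop("a seed is mandatory for stochastic simulation")
  positions <- as.matrix(positions)
  binding <- as.matrix(binding)
  stopifnot(nrow(binding) == nrow(positions))
  nFrames <- ncol(binding)
  h <- dim[1L]; w <- dim[2L]
  if (nrow(positions) &&
      (any(positions[, 1L] < 3) || any(positions[, 1L] > w - 4) ||
       any(positions[, 2L] < 3) || any(positions[, 2L] > h - 4))) {
    stop("spot positions must lie at least 3 px inside the image")
  }
  if (nrow(positions) > 1L) {
    dmat <- as.matrix(dist(positions))
    diag(dmat) <- Inf
    if (min(dmat) < 4) {
      warning("spots closer than 4 px: Gaussian fits may be ambiguous")
    }
  }
  if (is.null(transform)) {
    transform <- new("SimilarityTransform", scale = 1, rotation = 0,
                     translation = c(0, 0), rmsResidual = NA_real_)
  }
  if (is.null(drift)) drift <- matrix(0, nFrames, 2L)
  if (is.null(fiducials)) fiducials <- matrix(numeric(0), 0L, 2L)
  fiducials <- as.matrix(fiducials)
  posGreen <- if (nrow(positions)) applyMapping(transform, positions) else
    positions
  fidGreen <- if (nrow(fiducials)) applyMapping(transform, fiducials) else
    fiducials

  set.seed(as.integer(seed))
  red <- array(0, c(h, w, nFrames))
  green <- array(0, c(h, w, nFrames))
  for (t in seq_len(nFrames)) {
    fr <- matrix(background, h, w)
    fg <- matrix(background, h, w)
    dx <- drift[t, 1L]; dy <- drift[t, 2L]
    for (i in seq_len(nrow(positions))) {
      fr <- addGaussianSpot(fr, positions[i, 1L] + dx,
                            positions[i, 2L] + dy, amplitude, psfSigma)
      if (binding[i, t]) {
        fg <- addGaussianSpot(fg, posGreen[i, 1L] + dx,
                              posGreen[i, 2L] + dy, amplitude, psfSigma)
      }
    }
    for (i in seq_len(nrow(fiducials))) {
      fr <- addGaussianSpot(fr, fiducials[i, 1L] + dx,
                            fiducials[i, 2L] + dy, 4 * amplitude, psfSigma)
      fg <- addGaussianSpot(fg, fidGreen[i, 1L] + dx,
                            fidGreen[i, 2L] + dy, 4 * amplitude, psfSigma)
    }
    if (poisson) {
      fr[] <- rpois(length(fr), fr)
      fg[] <- rpois(length(fg), fg)
    }
    if (readNoiseSD > 0) {
      fr <- fr + rnorm(length(fr), 0, readNoiseSD)
      fg <- fg + rnorm(length(fg), 0, readNoiseSD)
    }
    red[, , t] <- fr
    green[, , t] <- fg
  }
  list(red = red, green = green, fiducialsRed = fiducials,
       fiducialsGreen = fidGreen,
       truth = list(positionsRed = positions, positionsGreen = posGreen,
                    binding = binding, drift = drift, psfSigma = psfSigma,
                    amplitude = amplitude, background = background))
}

#' Write / read a movie channel as a multi-page TIFF
#'
#' Stores a h x w x T stack as 16-bit TIFF pages (counts clipped to
#' [0, 65535]); \code{readMovieTIFF} restores the counts.
#'
#' @param stack h x w x T numeric array.
#' @param path output file.
#' @export
writeMovieTIFF <- function(stack, path) {
  pages <- lapply(seq_len(dim(stack)[3L]), function(t) {
    m <- stack[, , t]
    m[m < 0] <- 0; m[m > 65535] <- 65535
    m / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname writeMovieTIFF
#' @param path TIFF file written by \code{writeMovieTIFF}.
#' @export
readMovieTIFF <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, c(dim(pages[[1L]])[1:2], length(pages)))
  for (t in seq_along(pages)) arr[, , t] <- pages[[t]] * 65535
  arr
}

#' Serialize movie ground truth as JSON
#'
#' @param movie result of \code{\link{renderMovie}}.
#' @param path output JSON file.
#' @export
writeMovieTruth <- function(movie, path) {
  jsonlite::write_json(movie$truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
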