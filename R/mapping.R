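#' Estimate the nonreflective similarity mapping between two channels
#'
#' Least-squares fit of a similarity transform (scale, rotation,
#' translation; reflections excluded) taking matched fiducial-bead
#' coordinates in the source channel onto the destination channel. The
#' closed-form solution treats point pairs as complex numbers and solves
#' w = a z + b by least squares; |a| is the scale and Arg(a) the rotation.
#'
#' @param src n x 2 matrix of (x, y) source coordinates.
#' @param dst n x 2 matrix of matched destination coordinates.
#' @return a \linkS4class{SimilarityTransform} with its RMS residual.
#' @export
estimateMapping <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  if (nrow(src) < 2L || nrow(src) != nrow(dst)) {
    stop("need at least 2 matched point pairs")
  }
  z <- complex(real = src[, 1L], imaginary = src[, 2L])
  w <- complex(real = dst[, 1L], imaginary = dst[, 2L])
  zc <- mean(z); wc <- mean(w)
  denom <- sum(Mod(z - zc)^2)
  if (denom < 1e-12) stop("source points are all coincident")
  a <- sum(Conj(z - zc) * (w - wc)) / denom
  b <- wc - a * zc
  pred <- a * z + b
  rms <- sqrt(mean(Mod(w - pred)^2))
  new("SimilarityTransform", scale = Mod(a), rotation = Arg(a),
      translation = c(Re(b), Im(b)), rmsResidual = rms)
}

#' Apply, invert or compose similarity transforms
#'
#' @param transform a \linkS4class{SimilarityTransform}.
#' @param points n x 2 matrix (or length-2 vector) of (x, y) coordinates.
#' @return transformed coordinates (same shape).
#' @export
applyMapping <- function(transform, points) {
  vec <- is.null(dim(points))
  if (vec) points <- matrix(points, 1L)
  a <- complex(modulus = transform@scale, argument = transform@rotation)
  z <- complex(real = points[, 1L], imaginary = points[, 2L])
  w <- a * z + complex(real = transform@translation[1L],
                       imaginary = transform@translation[2L])
  out <- cbind(Re(w), Im(w))
  if (vec) out[1L, ] else out
}

#' @rdname applyMapping
#' @export
invertMapping <- function(transform) {
  a <- complex(modulus = transform@scale, argument = transform@rotation)
  b <- complex(real = transform@translation[1L],
               imaginary = transform@translation[2L])
  ai <- 1 / a
  bi <- -b / a
  new("SimilarityTransform", scale = Mod(ai), rotation = Arg(ai),
      translation = c(Re(bi), Im(bi)), rmsResidual = NA_real_)
}

#' @rdname applyMapping
#' @param t1,t2 transforms; the result applies \code{t1} then \code{t2}.
#' @export
composeMapping <- function(t1, t2) {
  a1 <- complex(modulus = t1@scale, argument = t1@rotation)
  a2 <- complex(modulus = t2@scale, argument = t2@rotation)
  b1 <- complex(real = t1@translation[1L], imaginary = t1@translation[2L])
  b2 <- complex(real = t2@translation[1L], imaginary = t2@translation[2L])
  a <- a2 * a1
  b <- a2 * b1 + b2
  new("SimilarityTransform", scale = Mod(a), rotation = Arg(a),
      translation = c(Re(b), Im(b)), rmsResidual = NA_real_)
}

# ---- drift estimation -------------------------------------------------

# subpixel image registration by upsampled cross-correlation: returns the
# (dx, dy) shift of image b relative to reference a
registerImages <- function(a, b, upsample = 20L) {
  h <- nrow(a); w <- ncol(a)
  A <- stats::fft(a - mean(a))
  B <- stats::fft(b - mean(b))
  R <- A * Conj(B)
  cc <- Re(stats::fft(R, inverse = TRUE))
  pk <- which(cc == max(cc), arr.ind = TRUE)[1L, ]
  sy <- pk[1L] - 1L; if (sy > h / 2) sy <- sy - h
  sx <- pk[2L] - 1L; if (sx > w / 2) sx <- sx - w
  # refine on an upsampled grid +/- 1 px around the coarse peak
  fy <- c(0:(ceiling(h / 2) - 1L), -floor(h / 2):-1) / h
  fx <- c(0:(ceiling(w / 2) - 1L), -floor(w / 2):-1) / w
  gy <- sy + seq(-1, 1, by = 1 / upsample)
  gx <- sx + seq(-1, 1, by = 1 / upsample)
  ky <- exp(2i * pi * gy %o% fy)
  kx <- exp(2i * pi * gx %o% fx)
  ccU <- Re(ky %*% R %*% t(kx))
  pkU <- which(ccU == max(ccU), arr.ind = TRUE)[1L, ]
  # shift of b relative to a: b(x) ~ a(x - d)  =>  d = -peak location
  c(dx = -gx[pkU[2L]], dy = -gy[pkU[1L]])
}

#' Estimate lateral drift of a movie
#'
#' Computes cumulative (dx, dy) displacement per frame relative to frame 1
#' by subpixel cross-correlation (upsampled discrete Fourier transform) of
#' block-averaged frames; block averaging over \code{blockSize} frames
#' suppresses shot noise. Frame displacements between block centers are
#' linearly interpolated. Blocks with no detectable structure (flat images)
#' are flagged and their displacement interpolated from neighbors.
#'
#' @param stack h x w x T numeric array.
#' @param blockSize frames per block average.
#' @param upsample subpixel upsampling factor.
#' @return data.frame with \code{frame}, \code{dx}, \code{dy},
#'   \code{interpolated}.
#' @export
estimateDrift <- function(stack, blockSize = 10L, upsample = 20L) {
  nT <- dim(stack)[3L]
  if (nT < 2L) stop("need at least 2 frames")
  blockSize <- max(1L, min(blockSize, nT))
  starts <- seq(1L, nT, by = blockSize)
  centers <- numeric(length(starts))
  shifts <- matrix(NA_real_, length(starts), 2L)
  ref <- NULL
  for (k in seq_along(starts)) {
    ix <- starts[k]:min(starts[k] + blockSize - 1L, nT)
    blk <- apply(stack[, , ix, drop = FALSE], c(1L, 2L), mean)
    centers[k] <- mean(ix)
    flat <- stats::sd(blk) < 1e-12
    if (k == 1L) {
      ref <- blk
      shifts[k, ] <- c(0, 0)
      if (flat) warning("reference block is featureless")
      next
    }
    if (flat) next  # leave NA, interpolate below
    shifts[k, ] <- registerImages(ref, blk, upsample)
  }
  interpolated <- !stats::complete.cases(shifts)
  for (j in 1:2) {
    ok <- !is.na(shifts[, j])
    if (sum(ok) >= 2L) {
      shifts[!ok, j] <- stats::approx(centers[ok], shifts[ok, j],
                                      xout = centers[!ok], rule = 2L)$y
    } else {
      shifts[!ok, j] <- 0
    }
  }
  dx <- stats::approx(centers, shifts[, 1L], xout = seq_len(nT),
                      rule = 2L)$y
  dy <- stats::approx(centers, shifts[, 2L], xout = seq_len(nT),
                      rule = 2L)$y
  blockOf <- findInterval(seq_len(nT), starts)
  data.frame(frame = seq_len(nT), dx = dx - dx[1L], dy = dy - dy[1L],
             interpolated = interpolated[blockOf])
}

# ---- GLRT detection and Gaussian fitting ------------------------------

gaussianTemplate <- function(window, sigma) {
  r <- (window - 1L) / 2
  d <- seq(-r, r)
  g <- exp(-outer(d^2, d^2, "+") / (2 * sigma^2))
  g
}

# 2D correlation of image with small kernel (same size, zero-padded edges)
correlate2d <- function(img, kern) {
  h <- nrow(img); w <- ncol(img)
  kh <- nrow(kern); kw <- ncol(kern)
  ry <- (kh - 1L) / 2; rx <- (kw - 1L) / 2
  out <- matrix(0, h, w)
  for (a in seq_len(kh)) {
    for (b in seq_len(kw)) {
      k <- kern[a, b]
      if (k == 0) next
      sy <- a - 1L - ry; sx <- b - 1L - rx
      ys <- max(1L, 1L + sy):min(h, h + sy)
      xs <- max(1L, 1L + sx):min(w, w + sx)
      out[ys - sy, xs - sx] <- out[ys - sy, xs - sx] + k * img[ys, xs]
    }
  }
  out
}

# robust image noise sd from median absolute horizontal differences
imageNoiseSD <- function(img) {
  stats::mad(diff(t(img))) / sqrt(2)
}

#' Detect areas of interest by a generalized likelihood ratio test
#'
#' Tests every pixel of a detection image (typically the average of the
#' first five frames) for a Gaussian-PSF spot against a flat local
#' background. With the background and amplitude profiled out, the GLRT
#' statistic is the matched-filter correlation with the mean-subtracted PSF
#' template, normalized by the noise sd; under the null it is standard
#' normal, so the threshold is the (1 - pFA) normal quantile. Local maxima
#' above threshold are refined by \code{\link{fitSpot}} and gated on fit
#' quality.
#'
#' @param image 2D numeric detection image.
#' @param pFA per-pixel false-alarm probability.
#' @param psfSigma PSF sd, px.
#' @param window odd fit/template window size (default 5).
#' @param refine run \code{\link{fitSpot}} on candidates and apply gates.
#' @param sigmaRange accepted fitted-sigma range, px.
#' @param maxShift accepted distance between fit center and window center,
#'   px.
#' @param residualGate accepted fit residual RMS in units of the image
#'   noise sd.
#' @return data.frame of AOIs: \code{x}, \code{y} (subpixel when refined),
#'   \code{glrt}, plus fit columns when refined.
#' @export
detectAOIs <- function(image, pFA = 1e-6, psfSigma = 1.1, window = 5L,
                       refine = TRUE, sigmaRange = c(0.3, 3) * psfSigma,
                       maxShift = 1.5, residualGate = 3) {
  h <- nrow(image); w <- ncol(image)
  if (h < window || w < window) stop("image smaller than the test kernel")
  g <- gaussianTemplate(window, psfSigma)
  gt <- g - mean(g)
  sigma <- imageNoiseSD(image)
  if (sigma < 1e-12) sigma <- 1e-12
  num <- correlate2d(image, gt)
  z <- num / (sigma * sqrt(sum(gt^2)))
  thr <- qnorm(1 - pFA)
  # strict local maxima in the 8-neighborhood
  isMax <- z >= thr
  for (sy in -1:1) for (sx in -1:1) {
    if (sy == 0L && sx == 0L) next
    nb <- matrix(-Inf, h, w)
    ys <- max(1L, 1L + sy):min(h, h + sy)
    xs <- max(1L, 1L + sx):min(w, w + sx)
    nb[ys - sy, xs - sx] <- z[ys, xs]
    isMax <- isMax & (z >= nb)
  }
  r <- (window - 1L) / 2
  cand <- which(isMax, arr.ind = TRUE)
  if (nrow(cand)) {
    inb <- cand[, 1L] > r & cand[, 1L] <= h - r &
      cand[, 2L] > r & cand[, 2L] <= w - r
    cand <- cand[inb, , drop = FALSE]
  }
  aois <- data.frame(x = cand[, 2L] - 1, y = cand[, 1L] - 1,
                     glrt = z[cand])
  if (!refine || nrow(aois) == 0L) return(aois)
  fits <- lapply(seq_len(nrow(aois)), function(i) {
    fitSpot(image, c(aois$x[i], aois$y[i]), psfSigma = psfSigma,
            window = window)
  })
  keep <- vapply(fits, function(f) {
    f$ok && f$sigma >= sigmaRange[1L] && f$sigma <= sigmaRange[2L] &&
      f$shift <= maxShift && f$residual <= residualGate * sigma
  }, TRUE)
  aois <- aois[keep, , drop = FALSE]
  fits <- fits[keep]
  aois$x <- vapply(fits, `[[`, 0, "x")
  aois$y <- vapply(fits, `[[`, 0, "y")
  aois$amplitude <- vapply(fits, `[[`, 0, "amplitude")
  aois$sigma <- vapply(fits, `[[`, 0, "sigma")
  aois$background <- vapply(fits, `[[`, 0, "background")
  aois$residual <- vapply(fits, `[[`, 0, "residual")
  rownames(aois) <- NULL
  aois
}

#' Drop AOIs near known positions (e.g. fiducial beads)
#'
#' @param aois AOI data.frame from \code{\link{detectAOIs}}.
#' @param points k x 2 matrix of positions to exclude.
#' @param radius exclusion radius, px.
#' @return filtered AOI data.frame.
#' @export
excludeNearAOIs <- function(aois, points, radius = 4) {
  if (nrow(aois) == 0L || is.null(points) || nrow(points) == 0L) {
    return(aois)
  }
  points <- as.matrix(points)
  keep <- vapply(seq_len(nrow(aois)), function(i) {
    min(sqrt((points[, 1L] - aois$x[i])^2 +
             (points[, 2L] - aois$y[i])^2)) > radius
  }, TRUE)
  aois[keep, , drop = FALSE]
}

#' Fit a symmetric 2D Gaussian spot in a 5x5 window
#'
#' Nonlinear least squares (Levenberg-Marquardt) of amplitude, center,
#' sigma and constant background within the window centered on the rounded
#' candidate position. Degenerate windows (near-zero amplitude, failed
#' convergence) are returned with \code{ok = FALSE}.
#'
#' @param image 2D numeric image.
#' @param center candidate (x, y), 0-based.
#' @param psfSigma starting sigma, px.
#' @param window odd window size.
#' @return list with \code{amplitude}, \code{x}, \code{y}, \code{sigma},
#'   \code{background}, \code{residual} (RMS), \code{shift} (distance from
#'   window center) and \code{ok}.
#' @export
fitSpot <- function(image, center, psfSigma = 1.1, window = 5L) {
  h <- nrow(image); w <- ncol(image)
  r <- (window - 1L) / 2
  cx <- round(center[1L]); cy <- round(center[2L])
  bad <- list(amplitude = NA_real_, x = NA_real_, y = NA_real_,
              sigma = NA_real_, background = NA_real_,
              residual = NA_real_, shift = NA_real_, ok = FALSE)
  if (cx - r < 0 || cx + r > w - 1L || cy - r < 0 || cy + r > h - 1L) {
    return(bad)
  }
  xs <- (cx - r):(cx + r); ys <- (cy - r):(cy + r)
  win <- image[ys + 1L, xs + 1L]
  df <- data.frame(v = as.vector(win),
                   x = rep(xs, each = length(ys)),
                   y = rep(ys, times = length(xs)))
  b0 <- min(win); a0 <- max(win) - b0
  if (a0 <= 0) return(bad)
  wpos <- pmax(win - b0, 0)
  x0 <- sum(df$x * wpos) / sum(wpos)
  y0 <- sum(df$y * wpos) / sum(wpos)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ b + a * exp(-((x - mx)^2 + (y - my)^2) / (2 * s^2)), data = df,
      start = list(b = b0, a = a0, mx = x0, my = y0, s = psfSigma),
      lower = c(-Inf, 0, cx - r, cy - r, 0.1),
      upper = c(Inf, Inf, cx + r, cy + r, window),
      control = minpack.lm::nls.lm.control(maxiter = 200L)),
    error = function(e) NULL)
  if (is.null(fit)) return(bad)
  p <- as.list(stats::coef(fit))
  resid <- sqrt(mean(stats::resid(fit)^2))
  shift <- sqrt((p$mx - cx)^2 + (p$my - cy)^2)
  noise <- imageNoiseSD(image)
  ok <- p$a > 3 * max(noise, 1e-12) && shift <= r
  list(amplitude = p$a, x = p$mx, y = p$my, sigma = p$s, background = p$b,
       residual = resid, shift = shift, ok = ok)
}

#' Extract intensity traces from a movie at mapped, drift-corrected AOIs
#'
#' For every AOI detected in one channel, integrates the other channel's
#' intensity in the 5x5 window centered on the mapped, drift-corrected
#' position, frame by frame. Windows that leave the image are marked
#' partial (NA intensity for those frames).
#'
#' @param stack h x w x T array of the channel to read intensities from.
#' @param aois data.frame with \code{x}, \code{y} (coordinates in the
#'   detection channel).
#' @param mapping \linkS4class{SimilarityTransform} from the detection
#'   channel into \code{stack}'s channel (NULL = identity).
#' @param drift data.frame from \code{\link{estimateDrift}} (NULL = none).
#' @param window odd integration window size.
#' @return data.frame with \code{molecule_id}, \code{frame}, \code{time_s}
#'   (NA spacing filled by the caller), \code{intensity}, \code{partial}.
#' @export
extractTraces <- function(stack, aois, mapping = NULL, drift = NULL,
                          window = 5L) {
  nT <- dim(stack)[3L]
  h <- dim(stack)[1L]; w <- dim(stack)[2L]
  r <- (window - 1L) / 2
  pos <- as.matrix(aois[, c("x", "y")])
  if (!is.null(mapping)) pos <- applyMapping(mapping, pos)
  out <- vector("list", nrow(aois))
  for (i in seq_len(nrow(aois))) {
    inten <- numeric(nT)
    part <- logical(nT)
    for (t in seq_len(nT)) {
      x <- pos[i, 1L] + if (is.null(drift)) 0 else drift$dx[t]
      y <- pos[i, 2L] + if (is.null(drift)) 0 else drift$dy[t]
      cx <- round(x); cy <- round(y)
      if (cx - r < 0 || cx + r > w - 1L || cy - r < 0 || cy + r > h - 1L) {
        inten[t] <- NA_real_
        part[t] <- TRUE
      } else {
        inten[t] <- sum(stack[(cy - r):(cy + r) + 1L,
                              (cx - r):(cx + r) + 1L, t])
      }
    }
    out[[i]] <- data.frame(molecule_id = i, frame = seq_len(nT),
                           intensity = inten, partial = part)
  }
  do.call(rbind, out)
}
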