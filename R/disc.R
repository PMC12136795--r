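# ---- change-point segmentation + agglomerative clustering (DISC-style) --

# Change-point segmentation: exact minimization of segment SSE plus a
# per-changepoint penalty (PELT dynamic programming in C++). The penalty is
# a chi-squared(1) critical value, Bonferroni-corrected over candidate
# split points, scaled by the noise variance; using the noise variance
# rather than a segment's own (structure-inflated) variance keeps short
# dwells detectable. Over-segmentation is cleaned up by the clustering
# stage.
segmentTrace <- function(x, sigma0, alpha = 0.05) {
  n <- length(x)
  crit <- qchisq(1 - alpha / n, df = 1L)
  cpp_pelt(x, crit * sigma0^2)
}

# agglomerative merge path of weighted segment means; returns list of
# cluster assignments (per segment) for k = nseg .. 1
mergePath <- function(means, weights) {
  k <- length(means)
  assign <- seq_len(k)
  path <- list()
  cmean <- means; cw <- weights
  active <- seq_len(k)
  path[[k]] <- assign
  while (length(active) > 1L) {
    # merge the pair of adjacent-in-mean clusters with least SSE increase
    ord <- order(cmean[active])
    a <- active[ord]
    dm <- diff(cmean[a])
    w1 <- cw[a[-length(a)]]; w2 <- cw[a[-1L]]
    inc <- (w1 * w2 / (w1 + w2)) * dm^2
    j <- which.min(inc)
    keep <- a[j]; drop <- a[j + 1L]
    newm <- (cmean[keep] * cw[keep] + cmean[drop] * cw[drop]) /
      (cw[keep] + cw[drop])
    cmean[keep] <- newm; cw[keep] <- cw[keep] + cw[drop]
    assign[assign == drop] <- keep
    active <- setdiff(active, drop)
    path[[length(active)]] <- assign
  }
  path
}

#' Idealize an intensity trace (DISC-style)
#'
#' Divisive segmentation and clustering: (a) recursive binary change-point
#' segmentation, accepting splits that improve the information criterion;
#' (b) agglomerative clustering of segment means, the same criterion picking
#' the number of intensity levels (at most \code{maxStates}); (c) Viterbi
#' refinement with Gaussian emissions per level. The procedure is fully
#' deterministic. Levels closer than \code{minStepSD} noise standard
#' deviations are merged so that noise is never split into two levels.
#'
#' @param x numeric intensity trace (or data.frame with an
#'   \code{intensity} column), length >= 10.
#' @param maxStates maximum number of intensity levels.
#' @param minStepSD minimum separation of adjacent levels, in units of the
#'   estimated noise sd.
#' @param frameInterval seconds per frame (carried into the result).
#' @return an \linkS4class{IdealizedTrace}; level 0 is the lowest-mean
#'   ("dark") level.
#' @export
idealizeDISC <- function(x, maxStates = 4L, minStepSD = 3,
                         frameInterval = 3) {
  if (is.data.frame(x)) x <- x$intensity
  x <- as.numeric(x)
  n <- length(x)
  if (n < 10L) stop("trace must have at least 10 frames")

  sd0 <- mad(diff(x)) / sqrt(2)
  if (is.na(sd0) || sd0 == 0) {
    # (near-)noiseless trace: scale to the smallest nonzero step
    nz <- abs(diff(x))
    nz <- nz[nz > 0]
    sd0 <- if (length(nz)) min(nz) / 10 else 1e-9
  }

  # two-pass segmentation: the first pass removes structure so the noise sd
  # can be re-estimated from within-segment residuals
  segStats <- function(cps) {
    starts <- c(1L, cps)
    ends <- c(starts[-1L] - 1L, n)
    segMean <- vapply(seq_along(starts),
                      function(i) mean(x[starts[i]:ends[i]]), 0)
    list(starts = starts, ends = ends, mean = segMean,
         len = ends - starts + 1L)
  }
  s1 <- segStats(segmentTrace(x, sd0))
  resid1 <- x - rep(s1$mean, s1$len)
  sd1 <- mad(resid1)  # robust to structure missed by the first pass
  if (is.na(sd1) || sd1 < 1e-12) sd1 <- sd0
  seg <- segStats(segmentTrace(x, sd1))
  segMean <- seg$mean
  segLen <- seg$len
  sd0 <- sd1

  # cluster segment means; choose level count by BIC on the frame likelihood
  path <- mergePath(segMean, segLen)
  kmax <- min(maxStates, length(segMean))
  best <- NULL; bestBIC <- Inf
  for (k in seq_len(kmax)) {
    assign <- path[[k]]
    labs <- unique(assign)
    mu <- vapply(labs, function(l) {
      sel <- assign == l
      sum(segMean[sel] * segLen[sel]) / sum(segLen[sel])
    }, 0)
    segLev <- match(assign, labs)
    frameMu <- rep(mu[segLev], segLen)
    sse <- sum((x - frameMu)^2)
    bic <- n * log(sse / n + 1e-12) + (2 * k) * log(n)
    if (bic < bestBIC) {
      bestBIC <- bic
      best <- list(k = k, mu = mu, segLev = segLev)
    }
  }

  mu <- best$mu; segLev <- best$segLev
  # enforce the minimum step gate by merging too-close adjacent levels
  repeat {
    ord <- order(mu)
    mu <- mu[ord]
    segLev <- match(segLev, ord)
    if (length(mu) < 2L) break
    gaps <- diff(mu)
    if (all(gaps >= minStepSD * sd0)) break
    j <- which.min(gaps)
    w <- vapply(seq_along(mu),
                function(l) sum(segLen[segLev == l]), 0)
    mu[j] <- (mu[j] * w[j] + mu[j + 1L] * w[j + 1L]) /
      (w[j] + w[j + 1L])
    mu <- mu[-(j + 1L)]
    segLev[segLev == j + 1L] <- j
    segLev[segLev > j + 1L] <- segLev[segLev > j + 1L] - 1L
  }

  states <- rep(segLev, segLen) - 1L
  k <- length(mu)

  if (k > 1L) {
    # Viterbi refinement with Gaussian emissions and empirical transitions
    resid <- x - mu[states + 1L]
    sdr <- sd(resid)
    if (is.na(sdr) || sdr < 1e-9) sdr <- sd0
    trans <- matrix(1, k, k)  # +1 pseudocount
    tfrom <- states[-n] + 1L; tto <- states[-1L] + 1L
    for (i in seq_along(tfrom)) trans[tfrom[i], tto[i]] <-
        trans[tfrom[i], tto[i]] + 1
    trans <- trans / rowSums(trans)
    states <- cpp_viterbi_gauss(x, mu, sdr, log(trans),
                                rep(log(1 / k), k))
    # recompute level means from the refined assignment; drop empty levels
    occ <- tabulate(states + 1L, nbins = k)
    keep <- which(occ > 0L)
    mu <- vapply(keep, function(l) mean(x[states == l - 1L]), 0)
    states <- match(states + 1L, keep) - 1L
    ord <- order(mu)
    mu <- mu[ord]
    states <- match(states + 1L, ord) - 1L
    k <- length(mu)
  }

  cp <- which(diff(states) != 0L) + 1L
  new("IdealizedTrace", states = as.integer(states), stateMeans = mu,
      changePoints = as.integer(cp), frameInterval = frameInterval)
}

#' Collapse an idealized trace to a binary bound/unbound signal
#'
#' Level 0 (lowest mean) is unbound; every higher occupancy level counts as
#' bound.
#'
#' @param ideal an \linkS4class{IdealizedTrace}.
#' @return data.frame with columns \code{frame}, \code{time_s}, \code{bound}.
#' @export
toBinary <- function(ideal) {
  stopifnot(is(ideal, "IdealizedTrace"))
  n <- length(ideal@states)
  data.frame(frame = seq_len(n),
             time_s = (seq_len(n) - 1L) * ideal@frameInterval,
             bound = ideal@states >= 1L)
}

#' Fraction of time spent at occupancy two or higher
#'
#' Total time across all traces at level >= 2 (two ligands bound
#' simultaneously) divided by total observed time, with per-replicate values
#' when a grouping is given.
#'
#' @param ideals list of \linkS4class{IdealizedTrace}.
#' @param replicate optional integer/character vector grouping traces into
#'   technical replicates.
#' @return list with \code{fraction} (overall) and \code{perReplicate}.
#' @export
multiOccupancyFraction <- function(ideals, replicate = NULL) {
  if (length(ideals) == 0L) stop("empty trace set")
  hi <- vapply(ideals, function(id) sum(id@states >= 2L), 0)
  tot <- vapply(ideals, function(id) length(id@states), 0)
  overall <- sum(hi) / sum(tot)
  per <- NULL
  if (!is.null(replicate)) {
    stopifnot(length(replicate) == length(ideals))
    per <- vapply(split(seq_along(ideals), replicate),
                  function(ix) sum(hi[ix]) / sum(tot[ix]), 0)
  }
  list(fraction = overall, perReplicate = per)
}
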