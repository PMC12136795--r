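#' Extract dwell times from binary traces
#'
#' Run-length encodes each binary bound/unbound trace into dwells of
#' duration (run length x frame interval). The first and last dwell of every
#' trace are flagged censored: their true duration is truncated by the
#' observation window.
#'
#' @param binaries list of binary traces (logical vectors, or data.frames
#'   from \code{\link{toBinary}} with a \code{bound} column).
#' @param frameInterval seconds per frame.
#' @return a \linkS4class{DwellSet} containing both bound and unbound dwells.
#' @export
extractDwells <- function(binaries, frameInterval = 3) {
  if (is.data.frame(binaries) || is.logical(binaries)) {
    binaries <- list(binaries)
  }
  rows <- vector("list", length(binaries))
  ids <- names(binaries)
  if (is.null(ids)) ids <- as.character(seq_along(binaries))
  for (i in seq_along(binaries)) {
    b <- binaries[[i]]
    if (is.data.frame(b)) b <- b$bound
    if (length(b) < 1L) {
      warning("trace ", ids[i], " shorter than one frame; skipped")
      next
    }
    r <- rle(as.logical(b))
    nr <- length(r$lengths)
    rows[[i]] <- data.frame(
      molecule_id = ids[i],
      state = ifelse(r$values, "bound", "unbound"),
      duration_s = r$lengths * frameInterval,
      censored = seq_len(nr) %in% c(1L, nr),
      stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) {
    return(new("DwellSet", dwells = data.frame(
      molecule_id = character(), state = character(),
      duration_s = numeric(), censored = logical())))
  }
  new("DwellSet", dwells = do.call(rbind, rows))
}

#' Subset a DwellSet by state
#'
#' @param dwells a \linkS4class{DwellSet}.
#' @param state \code{"bound"} or \code{"unbound"}.
#' @return a \linkS4class{DwellSet}.
#' @export
dwellSubset <- function(dwells, state) {
  new("DwellSet", dwells = dwells@dwells[dwells@dwells$state == state, ,
                                         drop = FALSE])
}

# log-sum-exp over matrix rows
rowLogSumExp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

# mixture log-likelihood; x uncensored, cc censored durations
mixLogLik <- function(A, tau, x, cc) {
  ll <- 0
  if (length(x)) {
    ld <- sweep(outer(x, -1 / tau), 2L, log(A) - log(tau), "+")
    ll <- ll + sum(rowLogSumExp(ld))
  }
  if (length(cc)) {
    ls <- sweep(outer(cc, -1 / tau), 2L, log(A), "+")
    ll <- ll + sum(rowLogSumExp(ls))
  }
  ll
}

emExpMixture <- function(x, cc, A, tau, maxIter = 500L, tol = 1e-8) {
  out <- cpp_em_expmix(as.numeric(x), as.numeric(cc), as.numeric(A),
                       as.numeric(tau), as.integer(maxIter), tol)
  list(A = out$A, tau = out$tau, logL = out$logL,
       converged = out$converged)
}

#' Fit an exponential-mixture dwell-time model by maximum likelihood
#'
#' Fits P(x) = sum_k (A_k / tau_k) exp(-x / tau_k) by EM with multi-start.
#' In \code{"drop"} mode (the default for mixture fits) censored dwells are
#' excluded; in \code{"likelihood"} mode they contribute survival-function
#' terms sum_k A_k exp(-c / tau_k), the appropriate treatment when a large
#' fraction of dwells outlives the movie. Time constants are reported in
#' ascending order (the short-/long-lived convention).
#'
#' @param dwells a \linkS4class{DwellSet} or numeric vector of durations.
#' @param K number of exponential components.
#' @param censoring \code{"drop"} or \code{"likelihood"}.
#' @param seed mandatory seed (multi-start jitter).
#' @param state optional state label to subset a DwellSet.
#' @param nStarts number of EM initializations.
#' @param init optional list(A, tau) used as an additional starting point.
#' @return an \linkS4class{ExpMixtureFit}.
#' @export
fitExpMixture <- function(dwells, K = 2L, censoring = c("drop", "likelihood"),
                          seed, state = NULL, nStarts = 10L, init = NULL) {
  if (missing(seed)) stop("a seed is mandatory (EM multi-start)")
  censoring <- match.arg(censoring)
  K <- as.integer(K)
  if (is(dwells, "DwellSet")) {
    d <- dwells@dwells
    if (!is.null(state)) d <- d[d$state == state, , drop = FALSE]
    x <- d$duration_s[!d$censored]
    cc <- d$duration_s[d$censored]
  } else {
    x <- as.numeric(dwells)
    cc <- numeric(0)
  }
  if (censoring == "drop") cc <- numeric(0)
  nTot <- length(x) + length(cc)
  # K = 1 has a closed form and works from any nonempty sample; mixtures
  # need a minimal sample per component
  if ((K == 1L && nTot < 1L) || (K > 1L && nTot < 5L * K)) {
    stop(sprintf("need at least %d dwells to fit K=%d",
                 if (K == 1L) 1L else 5L * K, K))
  }
  if (K == 1L) {
    # closed form: total observed time / number of uncensored dwells
    tau <- (sum(x) + sum(cc)) / max(length(x), 1L)
    return(new("ExpMixtureFit", K = 1L, A = 1, tau = tau,
               logL = mixLogLik(1, tau, x, cc), censoring = censoring,
               nDwells = as.integer(nTot), nCensored = length(cc),
               converged = TRUE))
  }
  all <- c(x, cc)
  set.seed(as.integer(seed))
  best <- NULL
  for (s in seq_len(nStarts)) {
    qs <- quantile(all, probs = (seq_len(K) - 0.5) / K, names = FALSE)
    jit <- if (s == 1L) rep(1, K) else exp(runif(K, -1, 1))
    tau0 <- pmax(qs * jit, 1e-6)
    A0 <- rep(1 / K, K)
    fit <- emExpMixture(x, cc, A0, tau0)
    if (is.null(best) || fit$logL > best$logL) best <- fit
  }
  if (!is.null(init) && length(init$A) == K) {
    fit <- emExpMixture(x, cc, init$A / sum(init$A), pmax(init$tau, 1e-6))
    if (fit$logL > best$logL) best <- fit
  }
  # degenerate equal-tau start: reproduces the K = 1 optimum exactly, so a
  # K-component fit can never fall below the single-exponential fit
  tau1 <- (sum(x) + sum(cc)) / max(length(x), 1L)
  fit <- emExpMixture(x, cc, rep(1 / K, K), rep(tau1, K))
  if (fit$logL > best$logL) best <- fit
  ord <- order(best$tau)
  new("ExpMixtureFit", K = K, A = unname(best$A[ord]),
      tau = unname(best$tau[ord]), logL = best$logL, censoring = censoring,
      nDwells = as.integer(nTot), nCensored = length(cc),
      converged = best$converged)
}

#' Select the number of exponential components (and a gamma alternative)
#'
#' Fits K = 1..Kmax exponential mixtures and climbs a log-likelihood-ratio
#' ladder: K+1 replaces K when 2(logL[K+1] - logL[K]) exceeds the
#' chi-squared critical value with 2 degrees of freedom (one amplitude + one
#' time constant) at level \code{alpha}. A gamma distribution is fitted to
#' the same dwells and compared with the selected mixture by BIC. The
#' mixture LLR test does not satisfy standard regularity conditions (the
#' null lies on the parameter-space boundary), making the chi-squared
#' calibration conservative; see the package vignette.
#'
#' @param dwells a \linkS4class{DwellSet} or numeric vector.
#' @param Kmax largest number of components to consider.
#' @param alpha LLR test level.
#' @param censoring passed to \code{\link{fitExpMixture}}.
#' @param seed mandatory seed.
#' @param state optional state subset.
#' @return a \linkS4class{ModelComparison}.
#' @export
selectMixtureModel <- function(dwells, Kmax = 3L, alpha = 0.05,
                               censoring = c("drop", "likelihood"), seed,
                               state = NULL) {
  if (missing(seed)) stop("a seed is mandatory")
  censoring <- match.arg(censoring)
  fits <- list()
  llr <- data.frame(K0 = integer(), K1 = integer(), stat = numeric(),
                    p = numeric())
  selectedK <- 1L
  for (K in seq_len(Kmax)) {
    init <- if (K > 1L && length(fits) >= K - 1L) {
      # warm start at the previous fit with a near-zero extra component, so
      # logL is nondecreasing in K
      prev <- fits[[K - 1L]]
      list(A = c(prev@A * (1 - 1e-8), 1e-8),
           tau = c(prev@tau, max(prev@tau) * 3))
    } else NULL
    fit <- tryCatch(
      fitExpMixture(dwells, K = K, censoring = censoring, seed = seed,
                    state = state, init = init),
      error = function(e) NULL)
    if (is.null(fit)) break
    fits[[K]] <- fit
    if (K > 1L) {
      stat <- 2 * (fits[[K]]@logL - fits[[K - 1L]]@logL)
      p <- stats::pchisq(stat, df = 2L, lower.tail = FALSE)
      llr <- rbind(llr, data.frame(K0 = K - 1L, K1 = K, stat = stat, p = p))
      if (K == selectedK + 1L && stat > qchisq(1 - alpha, df = 2L)) {
        selectedK <- K
      }
    }
  }
  sel <- fits[[selectedK]]
  n <- sel@nDwells
  bicExp <- (2L * selectedK - 1L) * log(n) - 2 * sel@logL
  gamma <- list()
  selected <- "exponential"
  gfit <- tryCatch({
    if (is(dwells, "DwellSet")) {
      d <- dwells@dwells
      if (!is.null(state)) d <- d[d$state == state, , drop = FALSE]
      if (censoring == "drop") {
        fitdistrplus::fitdist(d$duration_s[!d$censored], "gamma",
                              lower = c(1e-8, 1e-8))
      } else {
        cens <- data.frame(left = d$duration_s,
                           right = ifelse(d$censored, NA, d$duration_s))
        fitdistrplus::fitdistcens(cens, "gamma")
      }
    } else {
      fitdistrplus::fitdist(as.numeric(dwells), "gamma",
                            lower = c(1e-8, 1e-8))
    }
  }, error = function(e) NULL)
  if (!is.null(gfit)) {
    bicGamma <- 2 * log(n) - 2 * gfit$loglik
    gamma <- list(shape = unname(gfit$estimate["shape"]),
                  rate = unname(gfit$estimate["rate"]),
                  logL = gfit$loglik, bic = bicGamma)
    if (is.finite(bicGamma) && bicGamma < bicExp) selected <- "gamma"
  }
  new("ModelComparison", fits = fits, llr = llr, gamma = gamma,
      selectedK = selectedK, selected = selected)
}

#' Fraction of time spent bound
#'
#' Total bound time divided by total observed time, per technical replicate,
#' with the mean and SD across replicates.
#'
#' @param binaries list of binary traces (logical vectors or
#'   \code{\link{toBinary}} data.frames).
#' @param replicate optional grouping vector (default: one replicate).
#' @return list with \code{mean}, \code{sd}, \code{perReplicate}.
#' @export
occupancyFraction <- function(binaries, replicate = NULL) {
  if (length(binaries) == 0L) stop("empty trace set")
  boundFrames <- vapply(binaries, function(b) {
    if (is.data.frame(b)) b <- b$bound
    sum(b)
  }, 0)
  totFrames <- vapply(binaries, function(b) {
    if (is.data.frame(b)) b <- b$bound
    length(b)
  }, 0)
  if (is.null(replicate)) replicate <- rep(1L, length(binaries))
  ok <- totFrames > 0
  if (!all(ok)) warning("empty traces excluded")
  per <- vapply(split(seq_along(binaries)[ok], replicate[ok]),
                function(ix) sum(boundFrames[ix]) / sum(totFrames[ix]), 0)
  list(mean = mean(per), sd = if (length(per) > 1L) sd(per) else 0,
       perReplicate = per)
}

#' Binding events per molecule
#'
#' Counts bound dwells (censored included) per trace. When a reference mean
#' is supplied the result is also reported relative to it (reference
#' condition = 1).
#'
#' @param binaries list of binary traces.
#' @param reference optional reference mean events per molecule.
#' @return list with \code{perMolecule}, \code{mean}, \code{relative}.
#' @export
eventsPerMolecule <- function(binaries, reference = NULL) {
  counts <- vapply(binaries, function(b) {
    if (is.data.frame(b)) b <- b$bound
    r <- rle(as.logical(b))
    sum(r$values)
  }, 0)
  m <- if (length(counts)) mean(counts) else 0
  list(perMolecule = counts, mean = m,
       relative = if (is.null(reference)) NA_real_ else m / reference)
}

#' Rastergram interval table
#'
#' Per-molecule bound intervals with row indices assigned by the time of the
#' first binding event (earliest first); molecules without events come last,
#' in input order.
#'
#' @param binaries named list of binary traces.
#' @param frameInterval seconds per frame.
#' @return list with \code{order} (data.frame molecule_id, row,
#'   first_event_s) and \code{intervals} (data.frame molecule_id, row,
#'   start_s, end_s).
#' @export
rastergramData <- function(binaries, frameInterval = 3) {
  ids <- names(binaries)
  if (is.null(ids)) ids <- as.character(seq_along(binaries))
  first <- rep(Inf, length(binaries))
  ivs <- vector("list", length(binaries))
  for (i in seq_along(binaries)) {
    b <- binaries[[i]]
    if (is.data.frame(b)) b <- b$bound
    r <- rle(as.logical(b))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    sel <- which(r$values)
    if (length(sel)) {
      first[i] <- (starts[sel[1L]] - 1L) * frameInterval
      ivs[[i]] <- data.frame(molecule_id = ids[i],
                             start_s = (starts[sel] - 1L) * frameInterval,
                             end_s = ends[sel] * frameInterval,
                             stringsAsFactors = FALSE)
    }
  }
  ord <- order(first, seq_along(first))
  rowOf <- integer(length(binaries))
  rowOf[ord] <- seq_along(ord) - 1L
  intervals <- do.call(rbind, ivs[!vapply(ivs, is.null, TRUE)])
  if (is.null(intervals)) {
    intervals <- data.frame(molecule_id = character(), start_s = numeric(),
                            end_s = numeric())
  }
  intervals$row <- rowOf[match(intervals$molecule_id, ids)]
  list(order = data.frame(molecule_id = ids, row = rowOf,
                          first_event_s = ifelse(is.finite(first), first,
                                                 NA_real_),
                          stringsAsFactors = FALSE),
       intervals = intervals)
}

#' Photobleaching control: censored single-exponential lifetime
#'
#' For an immobilized-dye control movie every spot is "on" until it bleaches
#' or the movie ends, so lifetimes are right-censored single-exponential
#' draws. The censored MLE is total observed time divided by the number of
#' uncensored (bleached) spots. When every spot outlives the movie only a
#' lower bound can be reported.
#'
#' @param dwells a \linkS4class{DwellSet} of spot lifetimes.
#' @return list with \code{tau} (s), \code{n}, \code{nCensored},
#'   \code{lowerBoundOnly}.
#' @export
photobleachControl <- function(dwells) {
  d <- dwells@dwells
  nUnc <- sum(!d$censored)
  tot <- sum(d$duration_s)
  if (nUnc == 0L) {
    return(list(tau = tot, n = nrow(d), nCensored = nrow(d),
                lowerBoundOnly = TRUE))
  }
  list(tau = tot / nUnc, n = nrow(d), nCensored = sum(d$censored),
       lowerBoundOnly = FALSE)
}
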