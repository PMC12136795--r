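#' Observable class series of an idealized trace
#'
#' Maps occupancy levels to observable classes: level 0 -> dark, level 1 ->
#' bound, level >= 2 -> bound2.
#'
#' @param ideal an \linkS4class{IdealizedTrace} (or integer level vector).
#' @return character vector of observable classes.
#' @export
toClassSeries <- function(ideal) {
  lev <- if (is(ideal, "IdealizedTrace")) ideal@states else as.integer(ideal)
  OBS_CLASSES[pmin(lev, 2L) + 1L]
}

# Truncate observation classes to the scheme's observable alphabet: a
# double-occupancy frame still implies "bound" for a scheme without a
# bound2 state (spurious extra levels from idealization would otherwise
# make whole traces impossible).
collapseClasses <- function(classes, scheme) {
  if ("bound2" %in% scheme@observableClass) return(classes)
  lapply(classes, function(cs) ifelse(cs == "bound2", "bound", cs))
}

# run-length encode class series for the C++ forward kernel
encodeClassData <- function(classes) {
  segLens <- integer(0); segCls <- integer(0); nSeg <- integer(0)
  nFrames <- 0L
  for (cs in classes) {
    r <- rle(match(cs, OBS_CLASSES) - 1L)
    segLens <- c(segLens, r$lengths)
    segCls <- c(segCls, r$values)
    nSeg <- c(nSeg, length(r$lengths))
    nFrames <- nFrames + length(cs)
  }
  list(segLens = segLens, segCls = segCls, nSeg = nSeg, nFrames = nFrames)
}

# scheme with its free rates replaced by `values` (in edge order)
freeRateIndex <- function(scheme) {
  which(t(scheme@rates) > 0, arr.ind = FALSE)  # row-major order
}

rateNames <- function(scheme) {
  ij <- which(scheme@rates > 0, arr.ind = TRUE)
  ij <- ij[order(ij[, 1L], ij[, 2L]), , drop = FALSE]
  sprintf("%s->%s", scheme@stateNames[ij[, 1L]],
          scheme@stateNames[ij[, 2L]])
}

setRates <- function(scheme, values) {
  R <- t(scheme@rates)
  idx <- freeRateIndex(scheme)
  stopifnot(length(values) == length(idx))
  R[idx] <- values
  scheme@rates <- t(R)
  scheme
}

getRates <- function(scheme) {
  R <- t(scheme@rates)
  setNames(R[freeRateIndex(scheme)], rateNames(scheme))
}

# is each free rate a second-order (concentration-scaled) constant?
rateIsConc <- function(scheme) {
  Cm <- t(scheme@concEdges)
  unname(Cm[freeRateIndex(scheme)])
}

#' Log-likelihood of idealized class sequences under a kinetic scheme
#'
#' Discrete-time likelihood of per-frame observable-class sequences under
#' the aggregated Markov chain with transition matrix exp(Q dt): the forward
#' algorithm marginalizes the hidden states within each observable class
#' (the emission map is deterministic). The chain is assumed stationary at
#' frame one. Sequences are summed over molecules and concentrations.
#'
#' @param scheme a \linkS4class{KineticScheme} carrying the rate values to
#'   evaluate.
#' @param datasets list of datasets, each a list with elements
#'   \code{concentration} (nM) and \code{classes} (list of per-molecule
#'   class-series character vectors).
#' @param frameInterval frame interval, s.
#' @return total log-likelihood (\code{-Inf} when a sequence is impossible).
#' @export
schemeLogLik <- function(scheme, datasets, frameInterval) {
  if (frameInterval <= 0) stop("frame interval must be positive")
  enc <- lapply(datasets, function(d)
    encodeClassData(collapseClasses(d$classes, scheme)))
  conc <- vapply(datasets, function(d) d$concentration, 0)
  .schemeLogLikEncoded(scheme, enc, conc, frameInterval)
}

.schemeLogLikEncoded <- function(scheme, enc, conc, frameInterval) {
  classOf <- match(scheme@observableClass, OBS_CLASSES) - 1L
  total <- 0
  for (i in seq_along(enc)) {
    Q <- rateMatrix(scheme, conc[i])
    A <- tryCatch(as.matrix(Matrix::expm(Q * frameInterval)),
                  error = function(e) NULL)
    if (is.null(A) || anyNA(A)) return(-Inf)
    A[A < 0] <- 0
    pi0 <- tryCatch(stationaryDistribution(scheme, conc[i]),
                    error = function(e) NULL)
    if (is.null(pi0) || anyNA(pi0)) return(-Inf)
    total <- total + cpp_forward_rle(enc[[i]]$segLens, enc[[i]]$segCls,
                                     enc[[i]]$nSeg, A, classOf, pi0)
    if (!is.finite(total)) return(-Inf)
  }
  total
}

#' Bayesian Information Criterion
#'
#' BIC = k * log(N) - 2 * logL, with N the number of frames analyzed.
#'
#' @param k number of free parameters.
#' @param N number of frames.
#' @param logL maximized log-likelihood.
#' @return the BIC value.
#' @export
bic <- function(k, N, logL) {
  if (N < 1) stop("N must be at least 1")
  k * log(N) - 2 * logL
}

#' Globally fit a kinetic scheme across concentrations
#'
#' Maximum-likelihood estimation of all free rate constants of a scheme from
#' idealized trajectories observed at several ligand concentrations
#' (second-order constants are shared across concentrations and scale with
#' concentration, which is what makes them identifiable). Optimization is
#' bounded quasi-Newton (L-BFGS-B) on log-rates with multi-start; Wald
#' confidence intervals come from the observed information, and rates whose
#' information is flat are flagged with bound-to-bound intervals.
#'
#' @param scheme a \linkS4class{KineticScheme} template; its rate values
#'   serve as the first starting point.
#' @param datasets as in \code{\link{schemeLogLik}}.
#' @param frameInterval frame interval, s.
#' @param seed mandatory seed (multi-start jitter).
#' @param nStarts number of optimization starts.
#' @param bounds list with elements \code{firstOrder} and
#'   \code{secondOrder}, each \code{c(lower, upper)}.
#' @return a \linkS4class{GlobalFitResult}.
#' @export
fitGlobal <- function(scheme, datasets, frameInterval, seed, nStarts = 3L,
                      bounds = list(firstOrder = c(1e-6, 1e2),
                                    secondOrder = c(1e4, 1e10))) {
  if (missing(seed)) stop("a seed is mandatory (multi-start)")
  if (length(datasets) < 2L && any(rateIsConc(scheme))) {
    warning("second-order constants need >= 2 concentrations to be well",
            " identified")
  }
  enc <- lapply(datasets, function(d)
    encodeClassData(collapseClasses(d$classes, scheme)))
  conc <- vapply(datasets, function(d) d$concentration, 0)
  nFrames <- sum(vapply(enc, function(e) e$nFrames, 0L))
  isConc <- rateIsConc(scheme)
  lower <- log(ifelse(isConc, bounds$secondOrder[1L], bounds$firstOrder[1L]))
  upper <- log(ifelse(isConc, bounds$secondOrder[2L], bounds$firstOrder[2L]))
  nll <- function(theta) {
    ll <- .schemeLogLikEncoded(setRates(scheme, exp(theta)), enc, conc,
                               frameInterval)
    if (!is.finite(ll)) 1e12 else -ll
  }
  theta0 <- pmin(pmax(log(unname(getRates(scheme))), lower), upper)
  set.seed(as.integer(seed))
  starts <- list(theta0)
  for (s in seq_len(max(nStarts - 1L, 0L))) {
    starts[[s + 1L]] <- pmin(pmax(theta0 + runif(length(theta0), -1.5, 1.5),
                                  lower), upper)
  }
  best <- NULL
  converged <- FALSE
  for (th in starts) {
    opt <- tryCatch(
      optim(th, nll, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 500L)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) {
      best <- opt
      converged <- opt$convergence == 0L
    }
  }
  if (is.null(best)) stop("all optimization starts failed")
  theta <- best$par
  rates <- setNames(exp(theta), rateNames(scheme))
  logL <- -best$value

  flags <- character(0)
  ci <- cbind(exp(lower), exp(upper))
  rownames(ci) <- names(rates)
  H <- tryCatch(optimHess(theta, nll), error = function(e) NULL)
  if (!is.null(H)) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V)) {
      seLog <- sqrt(pmax(diag(V), 0))
      ok <- is.finite(seLog) & seLog > 0 & seLog < 5
      ci[ok, 1L] <- exp(theta[ok] - 1.96 * seLog[ok])
      ci[ok, 2L] <- exp(theta[ok] + 1.96 * seLog[ok])
      if (any(!ok)) {
        flags <- c(flags, sprintf("non-identifiable: %s",
                                  paste(names(rates)[!ok], collapse = ", ")))
      }
    } else {
      flags <- c(flags, "observed information singular; CIs are bounds")
    }
  }
  k <- length(rates)
  new("GlobalFitResult", scheme = setRates(scheme, unname(rates)),
      rates = rates, ci = ci, logL = logL, nFrames = as.integer(nFrames),
      bic = bic(k, nFrames, logL), converged = converged, flags = flags)
}

#' Fit and rank candidate kinetic schemes by BIC
#'
#' Fits every candidate scheme globally and ranks them by BIC (k log N -
#' 2 logL). Ties are broken toward fewer free parameters; candidates that
#' fail to converge are ranked last and flagged.
#'
#' @param candidates list of \linkS4class{KineticScheme} templates.
#' @param datasets as in \code{\link{schemeLogLik}}.
#' @param frameInterval frame interval, s.
#' @param seed mandatory seed.
#' @param ... passed to \code{\link{fitGlobal}}.
#' @return list with \code{results} (fits ranked best first) and
#'   \code{table} (data.frame of states, k, logL, BIC, deltaBIC).
#' @export
selectScheme <- function(candidates, datasets, frameInterval, seed, ...) {
  if (length(candidates) < 2L) stop("need at least 2 candidate schemes")
  fits <- lapply(candidates, function(sch) {
    tryCatch(fitGlobal(sch, datasets, frameInterval, seed = seed, ...),
             error = function(e) NULL)
  })
  failed <- vapply(fits, is.null, TRUE) |
    !vapply(fits, function(f) is.null(f) || f@converged, TRUE)
  bics <- vapply(fits, function(f) if (is.null(f)) Inf else f@bic, 0)
  ks <- vapply(fits, function(f) if (is.null(f)) NA_integer_
               else length(f@rates), 0L)
  bics[failed & !is.finite(bics)] <- Inf
  ord <- order(failed, bics, ks)
  results <- fits[ord]
  tab <- data.frame(
    rank = seq_along(ord),
    states = vapply(results, function(f) if (is.null(f)) NA_integer_
                    else length(f@scheme@stateNames), 0L),
    k = ks[ord],
    logL = vapply(results, function(f) if (is.null(f)) NA_real_
                  else f@logL, 0),
    bic = bics[ord],
    converged = !failed[ord])
  tab$deltaBIC <- tab$bic - tab$bic[1L]
  list(results = results, table = tab)
}
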