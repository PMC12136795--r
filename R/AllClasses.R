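#' @import methods
#' @importFrom stats rexp rnorm runif rpois optim qchisq qnorm sd
#'   quantile mad median setNames optimHess dist aggregate
#' @importFrom utils head tail read.csv write.csv
#' @useDynLib cosmosKinetics, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

OBS_CLASSES <- c("dark", "bound", "bound2")

#' KineticScheme: a continuous-time Markov binding scheme
#'
#' States of a continuous-time Markov chain describing ligand binding to a
#' tethered molecule. Off-diagonal entries of \code{rates} are rate constants:
#' first-order edges in s^-1, concentration-dependent edges (marked in
#' \code{concEdges}) in M^-1 s^-1. Several states may share one observable
#' class (\code{dark}, \code{bound}, \code{bound2}), making the chain an
#' aggregated Markov model: only the class sequence is observable.
#'
#' @slot stateNames character vector of state labels.
#' @slot rates square numeric matrix of rate constants (diagonal zero).
#' @slot concEdges logical matrix marking second-order (concentration-scaled)
#'   edges.
#' @slot observableClass character vector (one of \code{dark}, \code{bound},
#'   \code{bound2}) per state.
#' @slot initialState integer index of the state occupied at time zero.
#' @exportClass KineticScheme
setClass("KineticScheme",
  representation(
    stateNames = "character",
    rates = "matrix",
    concEdges = "matrix",
    observableClass = "character",
    initialState = "integer"
  )
)

setValidity("KineticScheme", function(object) {
  n <- length(object@stateNames)
  msg <- character()
  if (n < 1L) msg <- c(msg, "at least one state required")
  if (!all(dim(object@rates) == c(n, n))) {
    msg <- c(msg, "rates must be a square matrix matching stateNames")
  }
  if (!all(dim(object@concEdges) == c(n, n))) {
    msg <- c(msg, "concEdges must match rates in dimension")
  }
  if (any(object@rates[row(object@rates) != col(object@rates)] < 0)) {
    msg <- c(msg, "off-diagonal rates must be nonnegative")
  }
  if (any(diag(object@rates) != 0)) {
    msg <- c(msg, "diagonal of the rate-constant matrix must be zero")
  }
  if (!all(object@observableClass %in% OBS_CLASSES)) {
    msg <- c(msg, sprintf("observable classes must be in {%s}",
                          paste(OBS_CLASSES, collapse = ", ")))
  }
  if (length(object@observableClass) != n) {
    msg <- c(msg, "one observable class per state required")
  }
  if (!("dark" %in% object@observableClass) ||
      !any(object@observableClass %in% c("bound", "bound2"))) {
    msg <- c(msg, "scheme needs at least one dark and one bound-class state")
  }
  if (length(object@initialState) != 1L || is.na(object@initialState) ||
      object@initialState < 1L || object@initialState > n) {
    msg <- c(msg, "initialState must index a declared state")
  }
  # connectivity of the undirected support graph
  if (n > 1L) {
    adj <- (object@rates > 0) | t(object@rates > 0)
    reach <- logical(n); reach[1L] <- TRUE
    repeat {
      new <- reach | apply(adj[, reach, drop = FALSE], 1L, any)
      if (identical(new, reach)) break
      reach <- new
    }
    if (!all(reach)) msg <- c(msg, "state graph is disconnected")
  }
  if (length(msg)) msg else TRUE
})

#' IntensityNoise: emission model for synthetic traces
#'
#' Gaussian emission model mapping observable classes to camera intensities.
#' Class means must be strictly increasing dark < bound < bound2 so that a
#' doubly occupied molecule is one binding step brighter than a singly
#' occupied one.
#'
#' @slot levelMeans named numeric, mean intensity per observable class
#'   (arbitrary units).
#' @slot levelSD numeric, per-frame Gaussian standard deviation.
#' @exportClass IntensityNoise
setClass("IntensityNoise",
  representation(levelMeans = "numeric", levelSD = "numeric")
)

setValidity("IntensityNoise", function(object) {
  msg <- character()
  if (!all(OBS_CLASSES %in% names(object@levelMeans))) {
    msg <- c(msg, "levelMeans must name dark, bound and bound2")
  } else if (any(diff(object@levelMeans[OBS_CLASSES]) <= 0)) {
    msg <- c(msg, "level means must be strictly increasing dark < bound < bound2")
  }
  if (length(object@levelSD) != 1L || object@levelSD <= 0) {
    msg <- c(msg, "levelSD must be a single positive number")
  }
  if (length(msg)) msg else TRUE
})

#' SimConfig: settings for a synthetic CoSMoS movie
#'
#' Frame timing follows the alternating-laser acquisition used on two-channel
#' TIRF setups: with 1 s exposures and ~0.5 s lag per channel the effective
#' frame interval of the binding channel is 3 s.
#'
#' @slot frameInterval effective frame interval in seconds.
#' @slot movieLength movie duration in seconds.
#' @slot nMolecules number of tethered molecules.
#' @slot concentration ligand concentration in nM.
#' @slot seed master seed; every stochastic draw derives from it.
#' @slot noise an \linkS4class{IntensityNoise}.
#' @exportClass SimConfig
setClass("SimConfig",
  representation(
    frameInterval = "numeric",
    movieLength = "numeric",
    nMolecules = "integer",
    concentration = "numeric",
    seed = "integer",
    noise = "IntensityNoise"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@frameInterval <= 0) msg <- c(msg, "frameInterval must be > 0")
  if (object@movieLength < object@frameInterval) {
    msg <- c(msg, "movieLength must be at least one frame")
  }
  if (object@nMolecules < 1L) msg <- c(msg, "nMolecules must be >= 1")
  if (object@concentration < 0) msg <- c(msg, "concentration must be >= 0")
  if (length(object@seed) != 1L || is.na(object@seed)) {
    msg <- c(msg, "a seed is mandatory")
  }
  if (length(msg)) msg else TRUE
})

#' IdealizedTrace: piecewise-constant interpretation of an intensity trace
#'
#' @slot states integer vector, per-frame level index (0 = dark).
#' @slot stateMeans numeric, fitted intensity per level, strictly increasing.
#' @slot changePoints integer, sorted frame indices at which the level changes
#'   (index of the first frame of each new segment, 1-based).
#' @slot frameInterval seconds per frame.
#' @exportClass IdealizedTrace
setClass("IdealizedTrace",
  representation(
    states = "integer",
    stateMeans = "numeric",
    changePoints = "integer",
    frameInterval = "numeric"
  )
)

setValidity("IdealizedTrace", function(object) {
  msg <- character()
  if (length(object@stateMeans) &&
      any(diff(object@stateMeans) <= 0)) {
    msg <- c(msg, "state means must be strictly increasing with level index")
  }
  if (is.unsorted(object@changePoints, strictly = TRUE)) {
    msg <- c(msg, "change points must be sorted and unique")
  }
  if (length(object@states) &&
      (min(object@states) < 0L ||
       max(object@states) >= length(object@stateMeans))) {
    msg <- c(msg, "state indices must address stateMeans")
  }
  if (object@frameInterval <= 0) msg <- c(msg, "frameInterval must be > 0")
  if (length(msg)) msg else TRUE
})

#' DwellSet: state-labelled dwell durations with censoring flags
#'
#' Wraps a data.frame with columns \code{molecule_id}, \code{state}
#' (\code{"bound"} or \code{"unbound"}), \code{duration_s} and
#' \code{censored}. Dwells truncated by the start or end of a movie carry
#' \code{censored = TRUE}; their true duration is only bounded from below.
#'
#' @slot dwells the underlying data.frame.
#' @exportClass DwellSet
setClass("DwellSet", representation(dwells = "data.frame"))

setValidity("DwellSet", function(object) {
  d <- object@dwells
  need <- c("molecule_id", "state", "duration_s", "censored")
  msg <- character()
  if (!all(need %in% names(d))) {
    msg <- c(msg, sprintf("dwell table needs columns %s",
                          paste(need, collapse = ", ")))
  } else {
    if (nrow(d) && any(d$duration_s <= 0)) {
      msg <- c(msg, "dwell durations must be positive")
    }
    if (nrow(d) && !is.logical(d$censored)) {
      msg <- c(msg, "censored must be logical")
    }
  }
  if (length(msg)) msg else TRUE
})

#' ExpMixtureFit: maximum-likelihood exponential-mixture dwell model
#'
#' The fitted density is P(x) = sum_k (A_k / tau_k) exp(-x / tau_k) with
#' amplitudes summing to one and time constants sorted ascending; censored
#' dwells contribute survival terms when fitted in \code{"likelihood"} mode.
#'
#' @slot K integer number of components.
#' @slot A numeric amplitudes (sum to 1).
#' @slot tau numeric time constants in seconds, ascending.
#' @slot logL maximized log-likelihood.
#' @slot censoring \code{"drop"} or \code{"likelihood"}.
#' @slot nDwells number of dwells entering the fit.
#' @slot nCensored number of censored dwells entering the fit.
#' @slot converged logical.
#' @exportClass ExpMixtureFit
setClass("ExpMixtureFit",
  representation(
    K = "integer", A = "numeric", tau = "numeric", logL = "numeric",
    censoring = "character", nDwells = "integer", nCensored = "integer",
    converged = "logical"
  )
)

setValidity("ExpMixtureFit", function(object) {
  msg <- character()
  if (length(object@A) != object@K || length(object@tau) != object@K) {
    msg <- c(msg, "A and tau must have length K")
  }
  if (abs(sum(object@A) - 1) > 1e-9) msg <- c(msg, "amplitudes must sum to 1")
  if (any(object@A < -1e-12) || any(object@A > 1 + 1e-12)) {
    msg <- c(msg, "amplitudes must lie in [0, 1]")
  }
  if (any(object@tau <= 0)) msg <- c(msg, "time constants must be positive")
  if (object@K > 1L && any(diff(object@tau) < 0)) {
    msg <- c(msg, "time constants must be sorted ascending")
  }
  if (length(msg)) msg else TRUE
})

#' ModelComparison: exponential-mixture model selection report
#'
#' @slot fits list of \linkS4class{ExpMixtureFit}, K = 1..Kmax.
#' @slot llr data.frame of successive log-likelihood-ratio tests.
#' @slot gamma list with the gamma-alternative fit (shape, scale, logL, bic)
#'   or empty when unavailable.
#' @slot selectedK integer, K chosen by the LLR ladder.
#' @slot selected character, \code{"exponential"} or \code{"gamma"} after the
#'   BIC comparison.
#' @exportClass ModelComparison
setClass("ModelComparison",
  representation(
    fits = "list", llr = "data.frame", gamma = "list",
    selectedK = "integer", selected = "character"
  )
)

#' SimilarityTransform: nonreflective similarity between two channels
#'
#' Maps coordinates as \code{s * R %*% x + t} with a rotation matrix R (no
#' reflection) and positive scale s.
#'
#' @slot scale positive scale factor.
#' @slot rotation rotation angle in radians.
#' @slot translation numeric length-2 translation in pixels.
#' @slot rmsResidual root-mean-square fit residual in pixels (NA when exact).
#' @exportClass SimilarityTransform
setClass("SimilarityTransform",
  representation(
    scale = "numeric", rotation = "numeric", translation = "numeric",
    rmsResidual = "numeric"
  )
)

setValidity("SimilarityTransform", function(object) {
  msg <- character()
  if (length(object@scale) != 1L || object@scale <= 0) {
    msg <- c(msg, "scale must be a single positive number (nonreflective)")
  }
  if (length(object@translation) != 2L) {
    msg <- c(msg, "translation must have length 2")
  }
  if (length(msg)) msg else TRUE
})

#' GlobalFitResult: globally fitted rate constants for one scheme
#'
#' @slot scheme the fitted \linkS4class{KineticScheme} template.
#' @slot rates named numeric, fitted rate constants (s^-1, or M^-1 s^-1 for
#'   concentration-scaled edges).
#' @slot ci 2-column matrix of confidence bounds per rate.
#' @slot logL maximized log-likelihood over all molecules and concentrations.
#' @slot nFrames total number of frames analyzed (the N of the BIC).
#' @slot bic k*log(N) - 2*logL.
#' @slot converged logical.
#' @slot flags character vector of warnings (e.g. non-identifiable rates).
#' @exportClass GlobalFitResult
setClass("GlobalFitResult",
  representation(
    scheme = "KineticScheme", rates = "numeric", ci = "matrix",
    logL = "numeric", nFrames = "integer", bic = "numeric",
    converged = "logical", flags = "character"
  )
)

setValidity("GlobalFitResult", function(object) {
  k <- length(object@rates)
  bad <- abs(object@bic -
             (k * log(object@nFrames) - 2 * object@logL)) > 1e-6
  if (length(object@bic) && !is.na(object@bic) && bad) {
    "BIC must equal k*log(N) - 2*logL"
  } else TRUE
})

#' FourPLFit: four-parameter logistic binding-curve fit
#'
#' Model: %Bound = FPmin + (FPmax - FPmin) /
#'   (1 + 10^((logKD - log10([Protein])) * H)), H > 0.
#'
#' @slot FPmin,FPmax normalized minimum/maximum percent bound.
#' @slot KD dissociation constant in nM.
#' @slot H Hill coefficient (positive by convention).
#' @slot seLogKD standard error of log10(KD).
#' @slot residualNorm residual sum of squares of the fit.
#' @slot extrapolated TRUE when KD falls outside the assayed range.
#' @exportClass FourPLFit
setClass("FourPLFit",
  representation(
    FPmin = "numeric", FPmax = "numeric", KD = "numeric", H = "numeric",
    seLogKD = "numeric", residualNorm = "numeric", extrapolated = "logical"
  )
)

setValidity("FourPLFit", function(object) {
  msg <- character()
  if (object@KD <= 0) msg <- c(msg, "KD must be positive")
  if (object@FPmax <= object@FPmin) msg <- c(msg, "FPmax must exceed FPmin")
  if (length(msg)) msg else TRUE
})
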