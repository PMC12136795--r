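#' Accessors
#'
#' Small accessor generics for the package's S4 result objects; use these in
#' preference to direct slot access.
#'
#' @param object an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("stateNames", function(object) standardGeneric("stateNames"))
#' @rdname accessors
#' @export
setGeneric("observableClasses",
           function(object) standardGeneric("observableClasses"))
#' @rdname accessors
#' @export
setGeneric("freeParameters", function(object) standardGeneric("freeParameters"))
#' @rdname accessors
#' @export
setGeneric("amplitudes", function(object) standardGeneric("amplitudes"))
#' @rdname accessors
#' @export
setGeneric("timeConstants", function(object) standardGeneric("timeConstants"))
#' @rdname accessors
#' @export
setGeneric("fittedRates", function(object) standardGeneric("fittedRates"))
#' @rdname accessors
#' @export
setGeneric("dwellTable", function(object) standardGeneric("dwellTable"))

setMethod("stateNames", "KineticScheme", function(object) object@stateNames)
setMethod("observableClasses", "KineticScheme",
          function(object) setNames(object@observableClass, object@stateNames))
setMethod("freeParameters", "KineticScheme",
          function(object) sum(object@rates[row(object@rates) !=
                                            col(object@rates)] > 0))
setMethod("amplitudes", "ExpMixtureFit", function(object) object@A)
setMethod("timeConstants", "ExpMixtureFit", function(object) object@tau)
setMethod("fittedRates", "GlobalFitResult", function(object) object@rates)
setMethod("dwellTable", "DwellSet", function(object) object@dwells)

#' @importFrom stats logLik
#' @export
logLik.ExpMixtureFit <- function(object, ...) {
  structure(object@logL, df = 2L * object@K - 1L, class = "logLik")
}

#' @export
logLik.GlobalFitResult <- function(object, ...) {
  structure(object@logL, df = length(object@rates), class = "logLik")
}

setMethod("show", "KineticScheme", function(object) {
  n <- length(object@stateNames)
  cat(sprintf("KineticScheme with %d states, %d free rate parameters\n",
              n, freeParameters(object)))
  cat("  states:", paste(sprintf("%s[%s]", object@stateNames,
                                 object@observableClass), collapse = " "),
      "\n")
  ij <- which(object@rates > 0, arr.ind = TRUE)
  if (nrow(ij)) {
    for (r in seq_len(nrow(ij))) {
      i <- ij[r, 1L]; j <- ij[r, 2L]
      unit <- if (object@concEdges[i, j]) "M^-1 s^-1" else "s^-1"
      cat(sprintf("  %s -> %s : %.4g %s\n", object@stateNames[i],
                  object@stateNames[j], object@rates[i, j], unit))
    }
  }
  invisible(NULL)
})

setMethod("show", "ExpMixtureFit", function(object) {
  cat(sprintf(
    "ExpMixtureFit K=%d (%s censoring, %d dwells, %d censored)\n",
    object@K, object@censoring, object@nDwells, object@nCensored))
  for (k in seq_len(object@K)) {
    cat(sprintf("  A%d = %.3f  tau%d = %.3g s\n", k, object@A[k], k,
                object@tau[k]))
  }
  cat(sprintf("  logL = %.3f%s\n", object@logL,
              if (object@converged) "" else "  [not converged]"))
  invisible(NULL)
})

setMethod("show", "GlobalFitResult", function(object) {
  cat(sprintf("GlobalFitResult: %d-state scheme, k=%d, N=%d frames\n",
              length(object@scheme@stateNames), length(object@rates),
              object@nFrames))
  for (nm in names(object@rates)) {
    cat(sprintf("  %-14s %.4g  [%.3g, %.3g]\n", nm, object@rates[nm],
                object@ci[nm, 1L], object@ci[nm, 2L]))
  }
  cat(sprintf("  logL = %.2f  BIC = %.2f%s\n", object@logL, object@bic,
              if (length(object@flags)) paste0("  flags: ",
                paste(object@flags, collapse = "; ")) else ""))
  invisible(NULL)
})

setMethod("show", "SimilarityTransform", function(object) {
  cat(sprintf(
    "SimilarityTransform: scale %.6g, rotation %.6g rad, translation (%.4g, %.4g) px",
    object@scale, object@rotation, object@translation[1L],
    object@translation[2L]))
  if (!is.na(object@rmsResidual)) {
    cat(sprintf(", RMS residual %.4g px", object@rmsResidual))
  }
  cat("\n")
  invisible(NULL)
})

setMethod("show", "DwellSet", function(object) {
  d <- object@dwells
  cat(sprintf("DwellSet: %d dwells (%d censored) from %d molecules\n",
              nrow(d), sum(d$censored), length(unique(d$molecule_id))))
  if (nrow(d)) {
    for (s in unique(d$state)) {
      sel <- d$state == s
      cat(sprintf("  %-8s n=%d, median %.3g s\n", s, sum(sel),
                  median(d$duration_s[sel])))
    }
  }
  invisible(NULL)
})

setMethod("show", "FourPLFit", function(object) {
  cat(sprintf(
    "FourPLFit: KD = %.4g nM (H = %.3g, FPmin = %.3g, FPmax = %.3g)%s\n",
    object@KD, object@H, object@FPmin, object@FPmax,
    if (object@extrapolated) "  [extrapolated]" else ""))
  invisible(NULL)
})
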