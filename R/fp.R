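#' Normalize raw fluorescence-polarization titrations to percent bound
#'
#' Per replicate, rescales raw polarization so the value at the lowest
#' protein concentration (0 nM well, or the smallest assayed concentration)
#' maps to 0% and the highest value to 100%, then averages across
#' replicates. The rescale is affine, so any affine transform of the raw
#' data yields identical output.
#'
#' @param raw data.frame with columns \code{concentration_nM},
#'   \code{replicate}, \code{polarization}.
#' @return list with \code{perReplicate} (columns \code{concentration_nM},
#'   \code{replicate}, \code{percent_bound}) and \code{averaged} (columns
#'   \code{concentration_nM}, \code{percent_bound}).
#' @export
normalizeFP <- function(raw) {
  need <- c("concentration_nM", "replicate", "polarization")
  if (!all(need %in% names(raw))) {
    stop("raw FP table needs columns ", paste(need, collapse = ", "))
  }
  out <- lapply(split(raw, raw$replicate), function(d) {
    ref <- d$polarization[which.min(d$concentration_nM)][1L]
    top <- max(d$polarization)
    if (abs(top - ref) < 1e-12) {
      stop("maximum equals the 0 nM reference; cannot normalize")
    }
    d$percent_bound <- 100 * (d$polarization - ref) / (top - ref)
    d[, c("concentration_nM", "replicate", "percent_bound")]
  })
  per <- do.call(rbind, out)
  rownames(per) <- NULL
  avg <- aggregate(percent_bound ~ concentration_nM, per, mean)
  list(perReplicate = per, averaged = avg)
}

#' Fit a four-parameter logistic binding curve
#'
#' Nonlinear least squares of %Bound = FPmin + (FPmax - FPmin) /
#' (1 + 10^((logKD - log10([Protein])) * H)) on the log-concentration axis,
#' with the Hill coefficient constrained positive (the H < 0 mirror
#' solution swaps FPmin/FPmax and is excluded by convention). Multi-start
#' over logKD; deterministic given the seed.
#'
#' @param data data.frame with \code{concentration_nM} and
#'   \code{percent_bound} (replicates averaged internally if a
#'   \code{replicate} column is present).
#' @param seed mandatory seed.
#' @param nStarts number of logKD starting values.
#' @return a \linkS4class{FourPLFit}.
#' @export
fit4PL <- function(data, seed, nStarts = 8L) {
  if (missing(seed)) stop("a seed is mandatory (multi-start)")
  if ("replicate" %in% names(data)) {
    data <- aggregate(percent_bound ~ concentration_nM, data, mean)
  }
  data <- data[order(data$concentration_nM), ]
  conc <- data$concentration_nM
  pb <- data$percent_bound
  if (length(unique(conc)) < 5L) {
    stop("need at least 5 distinct concentrations spanning the inflection")
  }
  lx <- log10(conc)
  set.seed(as.integer(seed))
  grid <- seq(min(lx), max(lx), length.out = nStarts) +
    runif(nStarts, -0.05, 0.05)
  best <- NULL
  for (lk in grid) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        pb ~ FPmin + (FPmax - FPmin) / (1 + 10^((logKD - lx) * H)),
        data = data.frame(pb = pb, lx = lx),
        start = list(FPmin = min(pb), FPmax = max(pb), logKD = lk, H = 1),
        lower = c(-Inf, -Inf, min(lx) - 3, 1e-3),
        upper = c(Inf, Inf, max(lx) + 3, 10),
        control = minpack.lm::nls.lm.control(maxiter = 300L)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("4PL fit failed from every start")
  p <- as.list(stats::coef(best$fit))
  se <- tryCatch(summary(best$fit)$coefficients["logKD", "Std. Error"],
                 error = function(e) NA_real_)
  kd <- 10^p$logKD
  new("FourPLFit", FPmin = p$FPmin, FPmax = p$FPmax, KD = kd, H = p$H,
      seLogKD = se, residualNorm = best$rss,
      extrapolated = kd < min(conc) || kd > max(conc))
}
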