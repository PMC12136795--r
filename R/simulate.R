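#' @rdname simConfig
#' @param levelMeans named class means (arbitrary units).
#' @param levelSD per-frame Gaussian standard deviation.
#' @export
intensityNoise <- function(levelMeans = c(dark = 100, bound = 300,
                                          bound2 = 500),
                           levelSD = 25) {
  new("IntensityNoise", levelMeans = levelMeans, levelSD = levelSD)
}

#' Simulation configuration
#'
#' Defaults reflect a typical two-channel alternating-laser CoSMoS
#' acquisition: ~1800 s movies at an effective 3 s frame interval for the
#' binding channel (1 s exposure + 0.5 s lag per channel), and an emission
#' model with one binding step per occupancy level at SNR (step / sd) = 8.
#'
#' @param frameInterval effective frame interval, s.
#' @param movieLength movie duration, s.
#' @param nMolecules number of tethered molecules.
#' @param concentration ligand concentration, nM.
#' @param seed master seed (mandatory; all stochastic draws derive from it).
#' @param noise an \linkS4class{IntensityNoise}.
#' @return a \linkS4class{SimConfig}.
#' @export
simConfig <- function(seed, frameInterval = 3, movieLength = 1800,
                      nMolecules = 100L, concentration = 10,
                      noise = intensityNoise()) {
  if (missing(seed)) stop("a seed is mandatory for stochastic simulation")
  new("SimConfig", frameInterval = frameInterval, movieLength = movieLength,
      nMolecules = as.integer(nMolecules), concentration = concentration,
      seed = as.integer(seed), noise = noise)
}

# one fixed master seed -> n reproducible per-molecule sub-seeds
subSeeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate one continuous-time state trajectory
#'
#' Exact (Gillespie) simulation of the scheme's continuous-time Markov chain
#' over \code{[0, duration]}. A state with zero exit rate is absorbing: the
#' path simply stays there to the end of the movie.
#'
#' @param scheme a \linkS4class{KineticScheme}.
#' @param duration trajectory length, s.
#' @param concentration ligand concentration, nM (required when the scheme
#'   has concentration-dependent edges).
#' @param seed mandatory seed.
#' @param start \code{"initial"}: the path starts in the scheme's declared
#'   initial state; \code{"stationary"}: drawn from the stationary
#'   distribution; \code{"dark"}: drawn from the stationary distribution
#'   conditioned on the dark class (a molecule equilibrated among its unbound
#'   states before ligand arrives).
#' @return data.frame with columns \code{start}, \code{end}, \code{state}
#'   (state name) and \code{class} (observable class), one row per sojourn.
#' @export
simulateTrajectory <- function(scheme, duration, concentration = NA_real_,
                               seed, start = c("initial", "stationary",
                                               "dark")) {
  if (missing(seed)) stop("a seed is mandatory for stochastic simulation")
  start <- match.arg(start)
  stopifnot(duration > 0)
  Q <- rateMatrix(scheme, concentration)
  set.seed(as.integer(seed))
  s <- scheme@initialState
  if (start != "initial") {
    pi0 <- stationaryDistribution(scheme, concentration)
    if (start == "dark") {
      dark <- scheme@observableClass == "dark"
      pi0[!dark] <- 0
    }
    s <- sample.int(length(pi0), 1L, prob = pi0)
  }
  t0 <- 0
  starts <- numeric(0); ends <- numeric(0); states <- integer(0)
  repeat {
    exit <- -Q[s, s]
    dt <- if (exit > 0) rexp(1L, exit) else Inf
    t1 <- min(t0 + dt, duration)
    starts <- c(starts, t0); ends <- c(ends, t1); states <- c(states, s)
    if (t1 >= duration) break
    p <- Q[s, ]; p[s] <- 0
    s <- sample.int(length(p), 1L, prob = p)
    t0 <- t1
  }
  data.frame(start = starts, end = ends,
             state = scheme@stateNames[states],
             class = scheme@observableClass[states],
             stringsAsFactors = FALSE)
}

#' Discretize a trajectory to frame resolution
#'
#' Assigns each camera frame the observable class that occupies the majority
#' of the frame window, mimicking camera integration: an excursion occupying
#' less than half of every frame it touches is missed. Ties are broken toward
#' the lower occupancy class (dark < bound < bound2).
#'
#' @param path trajectory data.frame from \code{\link{simulateTrajectory}}.
#' @param frameInterval frame interval, s.
#' @param movieLength optional movie length, s (default: end of the path);
#'   the number of frames is \code{floor(movieLength / frameInterval)}.
#' @return character vector of observable classes, one per frame.
#' @export
discretizePath <- function(path, frameInterval, movieLength = NULL) {
  if (is.null(path) || nrow(path) == 0L) stop("empty trajectory")
  stopifnot(frameInterval > 0)
  if (is.null(movieLength)) movieLength <- max(path$end)
  nFrames <- floor(movieLength / frameInterval)
  if (nFrames < 1L) stop("movie shorter than one frame")
  occ <- matrix(0, nFrames, length(OBS_CLASSES),
                dimnames = list(NULL, OBS_CLASSES))
  for (r in seq_len(nrow(path))) {
    a <- path$start[r]; b <- min(path$end[r], nFrames * frameInterval)
    if (b <= a) next
    f0 <- floor(a / frameInterval) + 1L
    f1 <- min(ceiling(b / frameInterval), nFrames)
    fr <- f0:f1
    lo <- pmax(a, (fr - 1L) * frameInterval)
    hi <- pmin(b, fr * frameInterval)
    occ[fr, path$class[r]] <- occ[fr, path$class[r]] + (hi - lo)
  }
  OBS_CLASSES[max.col(occ, ties.method = "first")]
}

#' Render a noisy intensity trace from a class series
#'
#' Draws one Gaussian intensity per frame around the class mean of the
#' emission model. The ground-truth class series is returned alongside.
#'
#' @param classSeries character vector of observable classes per frame.
#' @param noise an \linkS4class{IntensityNoise}.
#' @param seed mandatory seed.
#' @return data.frame with columns \code{frame}, \code{intensity},
#'   \code{truth_state}.
#' @export
renderIntensity <- function(classSeries, noise = intensityNoise(), seed) {
  if (missing(seed)) stop("a seed is mandatory for stochastic simulation")
  if (!all(classSeries %in% names(noise@levelMeans))) {
    stop("class series contains classes absent from the emission model")
  }
  set.seed(as.integer(seed))
  mu <- unname(noise@levelMeans[classSeries])
  data.frame(frame = seq_along(classSeries),
             intensity = rnorm(length(classSeries), mu, noise@levelSD),
             truth_state = classSeries, stringsAsFactors = FALSE)
}

#' Simulate a full set of intensity traces
#'
#' Runs \code{\link{simulateTrajectory}}, \code{\link{discretizePath}} and
#' \code{\link{renderIntensity}} for every molecule in the configuration.
#' Each molecule uses an independent sub-seed derived from the master seed,
#' so the output is bit-reproducible.
#'
#' @param scheme a \linkS4class{KineticScheme}.
#' @param cfg a \linkS4class{SimConfig}.
#' @param start initial-state rule, see \code{\link{simulateTrajectory}};
#'   defaults to \code{"dark"} (molecules equilibrated among unbound states
#'   before the movie starts).
#' @return data.frame with columns \code{molecule_id}, \code{frame},
#'   \code{time_s}, \code{intensity}, \code{truth_state}.
#' @export
simulateTraces <- function(scheme, cfg, start = "dark") {
  stopifnot(is(cfg, "SimConfig"))
  seeds <- subSeeds(cfg@seed, 2L * cfg@nMolecules)
  out <- vector("list", cfg@nMolecules)
  for (i in seq_len(cfg@nMolecules)) {
    path <- simulateTrajectory(scheme, cfg@movieLength, cfg@concentration,
                               seed = seeds[2L * i - 1L], start = start)
    cls <- discretizePath(path, cfg@frameInterval, cfg@movieLength)
    tr <- renderIntensity(cls, cfg@noise, seed = seeds[2L * i])
    tr$molecule_id <- i
    tr$time_s <- (tr$frame - 1L) * cfg@frameInterval
    out[[i]] <- tr[, c("molecule_id", "frame", "time_s", "intensity",
                       "truth_state")]
  }
  do.call(rbind, out)
}

#' Sample dwell times from an exponential mixture
#'
#' Draws \code{n} dwells from sum_k A_k Exp(tau_k) and right-censors values
#' exceeding \code{censorAt} (e.g. the movie length), flagging them censored.
#'
#' @param A amplitudes, summing to 1.
#' @param tau time constants, s.
#' @param n number of dwells (> 0).
#' @param censorAt right-censoring horizon, s, or \code{Inf} for none.
#' @param seed mandatory seed.
#' @param state dwell label for the resulting \linkS4class{DwellSet}.
#' @return a \linkS4class{DwellSet}.
#' @export
sampleDwells <- function(A, tau, n, censorAt = Inf, seed, state = "bound") {
  if (missing(seed)) stop("a seed is mandatory for stochastic simulation")
  if (n <= 0) stop("n must be positive")
  stopifnot(length(A) == length(tau), all(tau > 0),
            abs(sum(A) - 1) < 1e-9)
  set.seed(as.integer(seed))
  comp <- sample.int(length(A), n, replace = TRUE, prob = A)
  x <- rexp(n, rate = 1 / tau[comp])
  cens <- x > censorAt
  x[cens] <- censorAt
  new("DwellSet", dwells = data.frame(
    molecule_id = seq_len(n), state = state, duration_s = x,
    censored = cens, stringsAsFactors = FALSE))
}

#' Fitted dwell-time mixtures for the study conditions
#'
#' Two-exponential dwell-time parameters for binding of the Lsm2-8 ring to
#' the U6 snRNA 3' end constructs (1-113-OH unprocessed, 1-112-P
#' 3'-phosphate, 1-112-OH short diol), with and without Prp24. Amplitudes
#' are paired with ascending time constants. Components whose value is an
#' assumption rather than a reported fit (the long unbound and short bound
#' time constants, and the off-dominant pairings) carry \code{assumed = TRUE}.
#'
#' @return data.frame with columns \code{rna}, \code{prp24}, \code{state},
#'   \code{A1}, \code{tau1}, \code{A2}, \code{tau2}, \code{assumed}.
#' @export
dwellMixtureCatalog <- function() {
  rbind(
    data.frame(rna = "U6_1-113-OH", prp24 = FALSE, state = "unbound",
               A1 = 0.50, tau1 = 86, A2 = 0.50, tau2 = 400, assumed = TRUE),
    data.frame(rna = "U6_1-112-P", prp24 = FALSE, state = "unbound",
               A1 = 0.81, tau1 = 32, A2 = 0.19, tau2 = 400, assumed = TRUE),
    data.frame(rna = "U6_1-113-OH", prp24 = FALSE, state = "bound",
               A1 = 0.80, tau1 = 15, A2 = 0.20, tau2 = 183, assumed = TRUE),
    data.frame(rna = "U6_1-112-P", prp24 = FALSE, state = "bound",
               A1 = 0.69, tau1 = 15, A2 = 0.31, tau2 = 250, assumed = TRUE),
    data.frame(rna = "U6_1-112-OH", prp24 = FALSE, state = "bound",
               A1 = 0.99, tau1 = 12, A2 = 0.01, tau2 = 200, assumed = TRUE),
    data.frame(rna = "U6_1-113-OH", prp24 = TRUE, state = "bound",
               A1 = 0.45, tau1 = 15, A2 = 0.55, tau2 = 290, assumed = TRUE)
  )
}

#' Look up one condition of the dwell-mixture catalog
#'
#' @param rna one of \code{"U6_1-113-OH"}, \code{"U6_1-112-P"},
#'   \code{"U6_1-112-OH"}.
#' @param state \code{"bound"} or \code{"unbound"}.
#' @param prp24 logical, presence of Prp24.
#' @return list with elements \code{A} and \code{tau} (ascending tau).
#' @export
dwellMixture <- function(rna, state, prp24 = FALSE) {
  cat. <- dwellMixtureCatalog()
  row <- cat.[cat.$rna == rna & cat.$state == state & cat.$prp24 == prp24, ]
  if (nrow(row) != 1L) stop("condition not in catalog")
  list(A = c(row$A1, row$A2), tau = c(row$tau1, row$tau2))
}

#' Four-parameter logistic parameters
#'
#' @param FPmin,FPmax normalized minimum and maximum percent bound.
#' @param KD dissociation constant, nM.
#' @param H Hill coefficient.
#' @return named list of validated parameters.
#' @export
fourPLParams <- function(FPmin = 0, FPmax = 100, KD = 10, H = 1) {
  if (FPmax <= FPmin) stop("FPmax must exceed FPmin")
  if (KD <= 0) stop("KD must be positive")
  list(FPmin = FPmin, FPmax = FPmax, KD = KD, H = H)
}

#' Four-parameter logistic binding curve
#'
#' %Bound = FPmin + (FPmax - FPmin) / (1 + 10^((log10(KD) -
#' log10(conc)) * H)). At conc = KD the curve passes through the midpoint
#' (FPmin + FPmax) / 2.
#'
#' @param conc protein concentration, nM.
#' @param params list from \code{\link{fourPLParams}}.
#' @return percent bound.
#' @export
fourPL <- function(conc, params) {
  params$FPmin + (params$FPmax - params$FPmin) /
    (1 + 10^((log10(params$KD) - log10(conc)) * params$H))
}

#' Generate a fluorescence-polarization titration dataset
#'
#' Evaluates the four-parameter logistic curve on a concentration grid and
#' adds Gaussian noise, in triplicate, mirroring a plate-reader titration
#' (protein from 0.01 to 1000 nM against a fixed labeled RNA).
#'
#' @param params list from \code{\link{fourPLParams}}.
#' @param concentrations protein concentrations, nM (all > 0).
#' @param noiseSD Gaussian noise sd in percent-bound units.
#' @param seed mandatory seed.
#' @param replicates number of technical replicates.
#' @return data.frame with columns \code{concentration_nM},
#'   \code{replicate}, \code{percent_bound}.
#' @export
generateFPDataset <- function(params, concentrations, noiseSD = 2, seed,
                              replicates = 3L) {
  if (missing(seed)) stop("a seed is mandatory for stochastic simulation")
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  set.seed(as.integer(seed))
  grid <- expand.grid(concentration_nM = concentrations,
                      replicate = seq_len(replicates))
  mu <- fourPL(grid$concentration_nM, params)
  grid$percent_bound <- mu + rnorm(nrow(grid), 0, noiseSD)
  grid[order(grid$concentration_nM, grid$replicate), ]
}
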