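# shared fixtures, all generated in code

# class series for a two-state chain, discretized at dt
simulateClassSeries <- function(scheme, n, concentration, seed,
                                movieLength = 1800, dt = 3) {
  seeds <- cosmosKinetics:::subSeeds(seed, n)
  lapply(seq_len(n), function(i) {
    p <- simulateTrajectory(scheme, movieLength, concentration,
                            seed = seeds[i], start = "stationary")
    discretizePath(p, dt, movieLength)
  })
}

# grid of well-separated spot positions inside a square image
spotGrid <- function(n, lo = 10, hi = 115, by = 15, jitter = 2, seed = 11) {
  set.seed(seed)
  g <- expand.grid(x = seq(lo, hi, by = by), y = seq(lo, hi, by = by))
  stopifnot(nrow(g) >= n)
  cbind(g$x[seq_len(n)] + runif(n, -jitter, jitter),
        g$y[seq_len(n)] + runif(n, -jitter, jitter))
}

# noiseless step trace: level `hi` on frames in `on`, else `lo`
stepTrace <- function(n, on, lo = 100, hi = 300) {
  x <- rep(lo, n)
  x[on] <- hi
  x
}
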