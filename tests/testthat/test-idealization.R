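test_that("degenerate traces idealize to the obvious answer", {
  # constant trace: one state, no change points
  id <- idealizeDISC(rep(5, 100))
  expect_equal(length(id@stateMeans), 1L)
  expect_length(id@changePoints, 0L)

  # noiseless 0 -> 1 -> 0 step: exact change points, 2 states
  x <- stepTrace(60, 21:40)
  id2 <- idealizeDISC(x)
  expect_equal(length(id2@stateMeans), 2L)
  expect_equal(id2@changePoints, c(21L, 41L))
  expect_equal(id2@stateMeans, c(100, 300))
  expect_equal(id2@states, as.integer(x == 300))

  expect_error(idealizeDISC(rep(1, 5)), "10 frames")
})

test_that("idealization is deterministic and noise-vanishing exact", {
  sch <- twoStateScheme(1e7, 0.05)
  p <- simulateTrajectory(sch, 1800, 10, seed = 3, start = "stationary")
  cls <- discretizePath(p, 3, 1800)
  tr <- renderIntensity(cls, intensityNoise(levelSD = 25), seed = 4)
  expect_identical(idealizeDISC(tr), idealizeDISC(tr))  # no RNG

  # sd -> 0: idealized output equals the discretized ground truth
  tr0 <- renderIntensity(cls, intensityNoise(levelSD = 1e-9), seed = 4)
  id0 <- idealizeDISC(tr0)
  expect_identical(toClassSeries(id0), cls)
})

test_that("frame accuracy is high at realistic SNR", {
  sch <- twoStateScheme(1.94e7, 0.045)
  accAt <- function(sd, seed) {
    p <- simulateTrajectory(sch, 1800, 3, seed = seed,
                            start = "stationary")
    cls <- discretizePath(p, 3, 1800)
    tr <- renderIntensity(cls, intensityNoise(levelSD = sd),
                          seed = seed + 50)
    id <- idealizeDISC(tr)
    mean((id@states >= 1L) == (cls != "dark"))
  }
  # SNR 5 (step 200, sd 40): >= 95% frame accuracy
  acc5 <- vapply(1:5, function(s) accAt(40, s), 0)
  expect_gt(mean(acc5), 0.95)
  # SNR 8: >= 99% round-trip accuracy
  acc8 <- vapply(1:5, function(s) accAt(25, s), 0)
  expect_gt(mean(acc8), 0.99)
})

test_that("level count respects maxStates and the noise gate", {
  # three-level trace (double occupancy)
  x <- c(rep(100, 50), rep(300, 50), rep(500, 30), rep(300, 20),
         rep(100, 50))
  set.seed(1)
  xn <- x + rnorm(length(x), 0, 20)
  id <- idealizeDISC(xn)
  expect_equal(length(id@stateMeans), 3L)
  expect_false(is.unsorted(id@stateMeans, strictly = TRUE))
  id2 <- idealizeDISC(xn, maxStates = 2L)
  expect_lte(length(id2@stateMeans), 2L)
})

test_that("binary collapse maps level >= 1 to bound", {
  x <- c(rep(100, 20), rep(300, 20), rep(500, 10), rep(100, 10))
  id <- idealizeDISC(x, frameInterval = 3)
  b <- toBinary(id)
  expect_equal(b$bound, id@states >= 1L)
  expect_equal(b$time_s, (seq_along(x) - 1) * 3)
  # all-dark trace
  expect_true(all(!toBinary(idealizeDISC(rep(7, 50)))$bound))
  # bound fraction pools levels 1 and 2
  expect_equal(mean(b$bound), 30 / 60)
})

test_that("double-occupancy time fraction is counted correctly", {
  mk <- function(states) {
    new("IdealizedTrace", states = as.integer(states),
        stateMeans = c(0, 1, 2), changePoints = integer(0),
        frameInterval = 3)
  }
  # never above level 1
  ids <- list(mk(c(0, 1, 1, 0)), mk(rep(1L, 4)))
  expect_equal(multiOccupancyFraction(ids)$fraction, 0)
  # 15% of frames at level 2 by construction
  states <- rep(0L, 200); states[1:30] <- 2L
  expect_equal(multiOccupancyFraction(list(mk(states)))$fraction, 0.15)
  # two conditions at a 3x double-binding ratio
  s1 <- rep(0L, 100); s1[1:15] <- 2L
  s2 <- rep(0L, 100); s2[1:5] <- 2L
  r <- multiOccupancyFraction(list(mk(s1)))$fraction /
    multiOccupancyFraction(list(mk(s2)))$fraction
  expect_equal(r, 3)
  expect_error(multiOccupancyFraction(list()), "empty")
  # per-replicate values
  pr <- multiOccupancyFraction(list(mk(s1), mk(s2)),
                               replicate = c(1, 2))$perReplicate
  expect_equal(unname(pr), c(0.15, 0.05))
})
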