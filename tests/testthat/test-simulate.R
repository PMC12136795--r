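test_that("trajectory simulation is exact and reproducible", {
  # absorbing case: no exits from the initial state
  sch <- buildScheme(c("U", "UL"),
                     data.frame(from = "UL", to = "U", rate = 0.1),
                     observable = c(U = "dark", UL = "bound"))
  p <- simulateTrajectory(sch, 100, seed = 1)
  expect_equal(nrow(p), 1L)
  expect_equal(p$end - p$start, 100)
  expect_equal(p$state, "U")

  # same seed => bit-identical paths
  s2 <- twoStateScheme(1e7, 0.05)
  expect_identical(simulateTrajectory(s2, 1800, 10, seed = 42),
                   simulateTrajectory(s2, 1800, 10, seed = 42))
  # seed is mandatory
  expect_error(simulateTrajectory(s2, 100, 10), "seed")
})

test_that("time-averaged occupancy matches the stationary distribution", {
  # kon*C = 0.1 /s, koff = 0.05 /s -> bound fraction 2/3
  sch <- twoStateScheme(1e7, 0.05)
  p <- simulateTrajectory(sch, 1e5, 10, seed = 7)
  dur <- p$end - p$start
  bound <- sum(dur[p$class == "bound"]) / 1e5
  # 3 SE via effective number of cycles
  nCycles <- sum(p$class == "bound")
  se <- sqrt(2 / 3 * 1 / 3 / nCycles)
  expect_lt(abs(bound - 2 / 3), 3 * se)
})

test_that("four-state occupancy also matches its stationary solution", {
  sch <- fourStateScheme()
  p <- simulateTrajectory(sch, 4e5, 10, seed = 8, start = "stationary")
  piB <- sum(stationaryDistribution(sch, 10)[c("UL", "ULstar")])
  # block the path into 20 stretches to estimate the SE under slow mixing
  edges <- seq(0, 4e5, length.out = 21L)
  blockFrac <- vapply(seq_len(20L), function(b) {
    lo <- edges[b]; hi <- edges[b + 1L]
    ov <- pmin(p$end, hi) - pmax(p$start, lo)
    ov[ov < 0] <- 0
    sum(ov[p$class == "bound"]) / (hi - lo)
  }, 0)
  se <- sd(blockFrac) / sqrt(20)
  expect_lt(abs(mean(blockFrac) - piB), 3 * se)
})

test_that("simulated dwells are exponential with the generating rate", {
  sch <- twoStateScheme(1e7, 0.05)
  dwells <- c()
  i <- 0L
  while (length(dwells) < 1e4) {
    i <- i + 1L
    p <- simulateTrajectory(sch, 2e5, 10, seed = 100 + i)
    d <- (p$end - p$start)[p$class == "bound"]
    dwells <- c(dwells, d[-c(1L, length(d))])  # drop boundary dwells
  }
  dwells <- dwells[1:1e4]
  expect_equal(mean(dwells), 20, tolerance = 0.03)
  ks <- suppressWarnings(stats::ks.test(dwells, "pexp", rate = 0.05))
  expect_gt(ks$p.value, 0.01)
})

test_that("discretization applies the majority-occupancy rule", {
  sch <- twoStateScheme(1e7, 0.05)
  # constant bound path
  path <- data.frame(start = 0, end = 1800, state = "UL", class = "bound")
  cls <- discretizePath(path, 3, 1800)
  expect_equal(length(cls), 600L)
  expect_true(all(cls == "bound"))

  # dwell shorter than frameInterval/2 inside one frame is missed
  path2 <- data.frame(start = c(0, 30.5, 31.5), end = c(30.5, 31.5, 60),
                      state = c("U", "UL", "U"),
                      class = c("dark", "bound", "dark"))
  cls2 <- discretizePath(path2, 3, 60)
  expect_true(all(cls2 == "dark"))

  # a dwell covering the majority of its frame is kept
  path3 <- data.frame(start = c(0, 30.2, 32.3), end = c(30.2, 32.3, 60),
                      state = c("U", "UL", "U"),
                      class = c("dark", "bound", "dark"))
  expect_equal(sum(discretizePath(path3, 3, 60) == "bound"), 1L)

  expect_error(discretizePath(data.frame(), 3), "empty")
  # n_frames = floor(movieLength / frameInterval)
  expect_length(discretizePath(path, 3, 1799), 599L)
})

test_that("intensity rendering follows the emission model", {
  cls <- c(rep("dark", 10), rep("bound", 10), rep("bound2", 10))
  noise <- intensityNoise(levelSD = 1e-9)
  tr <- renderIntensity(cls, noise, seed = 1)
  expect_equal(tr$intensity,
               unname(noise@levelMeans[cls]), tolerance = 1e-6)
  expect_identical(tr$truth_state, cls)
  # bound2 is one binding step above bound, two above dark
  m <- noise@levelMeans
  expect_equal(unname(m["bound2"] - m["bound"]),
               unname(m["bound"] - m["dark"]))
  expect_error(renderIntensity(c("dark", "weird"), noise, seed = 1),
               "classes")
  # reproducibility
  tr2 <- renderIntensity(cls, intensityNoise(), seed = 9)
  tr3 <- renderIntensity(cls, intensityNoise(), seed = 9)
  expect_identical(tr2, tr3)
})

test_that("simulateTraces produces the documented schema, reproducibly", {
  cfg <- simConfig(seed = 3, nMolecules = 4L, movieLength = 300,
                   concentration = 10)
  tr <- simulateTraces(twoStateScheme(1e7, 0.05), cfg)
  expect_named(tr, c("molecule_id", "frame", "time_s", "intensity",
                     "truth_state"))
  expect_equal(nrow(tr), 4L * 100L)
  expect_identical(tr, simulateTraces(twoStateScheme(1e7, 0.05), cfg))
  expect_error(simConfig(), "seed")
})

test_that("dwell sampling reproduces mixture moments and censoring", {
  # K = 1 law of large numbers
  d <- sampleDwells(1, 10, 1e5, seed = 5)
  expect_equal(mean(dwellTable(d)$duration_s), 10, tolerance = 0.01)

  # censored fraction ~ exp(-1800/2682) ~ 0.512
  d2 <- sampleDwells(1, 2682, 2e4, censorAt = 1800, seed = 6)
  frac <- mean(dwellTable(d2)$censored)
  expect_equal(frac, exp(-1800 / 2682), tolerance = 0.02)

  # single dwell
  d3 <- sampleDwells(1, 5, 1, censorAt = 1e6, seed = 7)
  expect_equal(nrow(dwellTable(d3)), 1L)
  expect_false(dwellTable(d3)$censored)

  expect_error(sampleDwells(1, 5, 0, seed = 1), "positive")
})

test_that("FP titration generation follows the 4PL curve", {
  p <- fourPLParams(FPmin = 5, FPmax = 95, KD = 10, H = 1)
  # midpoint identity at [Protein] = KD
  expect_equal(fourPL(10, p), 50)
  # asymptote
  expect_equal(fourPL(1e9, p), 95, tolerance = 1e-6)
  dat <- generateFPDataset(p, 10^seq(-2, 3, length.out = 12),
                           noiseSD = 1e-12, seed = 8)
  expect_equal(nrow(dat), 36L)  # triplicate
  expect_equal(sort(unique(dat$replicate)), 1:3)
  expect_equal(dat$percent_bound,
               fourPL(dat$concentration_nM, p), tolerance = 1e-9)
  expect_error(generateFPDataset(p, c(-1, 10), seed = 1), "positive")
})

test_that("the dwell-mixture catalog is internally consistent", {
  cat. <- dwellMixtureCatalog()
  expect_true(all(abs(cat.$A1 + cat.$A2 - 1) < 1e-12))
  expect_true(all(cat.$tau1 < cat.$tau2))
  m <- dwellMixture("U6_1-112-P", "unbound")
  expect_equal(m$A[1], 0.81)
  expect_equal(m$tau[1], 32)
  expect_error(dwellMixture("U6_1-112-P", "bound", prp24 = TRUE),
               "catalog")
})
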