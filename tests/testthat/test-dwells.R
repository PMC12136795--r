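test_that("dwell extraction run-length encodes with boundary censoring", {
  # whole movie bound: one censored bound dwell
  d <- extractDwells(list(rep(TRUE, 600)), frameInterval = 3)
  expect_equal(nrow(dwellTable(d)), 1L)
  expect_true(dwellTable(d)$censored)
  expect_equal(dwellTable(d)$duration_s, 1800)
  expect_equal(dwellTable(d)$state, "bound")

  # U(5) B(10) U(5) at dt = 3: one uncensored 30 s bound dwell,
  # two censored unbound dwells
  b <- c(rep(FALSE, 5), rep(TRUE, 10), rep(FALSE, 5))
  d2 <- dwellTable(extractDwells(list(b), frameInterval = 3))
  expect_equal(d2$duration_s[d2$state == "bound"], 30)
  expect_false(d2$censored[d2$state == "bound"])
  expect_equal(d2$censored[d2$state == "unbound"], c(TRUE, TRUE))

  # simulated 2-state data: uncensored dwell means near 1/rate
  sch <- twoStateScheme(1e7, 0.05)
  cls <- simulateClassSeries(sch, 60, 1, seed = 21)
  d3 <- dwellTable(extractDwells(lapply(cls, function(x) x != "dark"),
                                 frameInterval = 3))
  mb <- mean(d3$duration_s[d3$state == "bound" & !d3$censored])
  expect_equal(mb, 20, tolerance = 0.15)
  expect_warning(extractDwells(list(logical(0))), "skipped")
})

test_that("exponential-mixture MLE recovers known parameters", {
  # K = 1 closed form is the sample mean
  f1 <- fitExpMixture(c(2, 4, 6), K = 1, seed = 1)
  expect_equal(f1@tau, 4)

  # two-component recovery at n = 1e4
  d <- sampleDwells(c(0.81, 0.19), c(5, 32), 1e4, seed = 22)
  f2 <- fitExpMixture(d, K = 2, seed = 22)
  expect_equal(f2@A[1], 0.81, tolerance = 0.05)
  expect_equal(f2@tau, c(5, 32), tolerance = 0.1)
  expect_equal(sum(f2@A), 1, tolerance = 1e-9)
  expect_false(is.unsorted(f2@tau))

  # K = 2 on single-exponential data: logL gain below chi2_{0.05,2}/2
  set.seed(123)
  x <- rexp(2000, 1 / 40)
  g1 <- fitExpMixture(x, K = 1, seed = 23)
  g2 <- fitExpMixture(x, K = 2, seed = 23)
  expect_gte(g2@logL, g1@logL - 1e-6)  # logL nondecreasing in K
  expect_lt(2 * (g2@logL - g1@logL), stats::qchisq(0.95, 2))
})

test_that("censored likelihood is unbiased where dropping censored is not", {
  # tau = 1.5x the censoring horizon
  tau <- 2700; horizon <- 1800
  d <- sampleDwells(1, tau, 1e4, censorAt = horizon, seed = 24)
  fLik <- fitExpMixture(d, K = 1, censoring = "likelihood", seed = 24)
  fDrop <- fitExpMixture(d, K = 1, censoring = "drop", seed = 24)
  expect_equal(fLik@tau, tau, tolerance = 0.02)
  # dropping censored dwells caps durations at the horizon: strong bias
  expect_lt(fDrop@tau, 0.3 * tau)
})

test_that("model selection picks the generating complexity", {
  # well-separated K = 2, n = 2000
  d <- sampleDwells(c(0.5, 0.5), c(5, 200), 2000, seed = 25)
  mc <- selectMixtureModel(d, Kmax = 3, seed = 25)
  expect_equal(mc@selectedK, 2L)
  expect_equal(mc@selected, "exponential")
  # logL nondecreasing across K
  lls <- vapply(mc@fits, function(f) f@logL, 0)
  expect_true(all(diff(lls) >= -1e-4))

  # single-exponential data at small n: stays at K = 1
  d2 <- sampleDwells(1, 50, 10, seed = 26)
  expect_equal(selectMixtureModel(d2, Kmax = 3, seed = 26)@selectedK, 1L)

  # gamma-distributed dwells are recognized by the BIC comparison
  set.seed(27)
  g <- stats::rgamma(3000, shape = 4, rate = 0.1)
  mcg <- selectMixtureModel(g, Kmax = 2, seed = 27)
  expect_equal(mcg@selected, "gamma")
})

test_that("occupancy fraction matches construction and theory", {
  expect_equal(occupancyFraction(list(rep(TRUE, 10), rep(TRUE, 5)))$mean, 1)
  expect_equal(occupancyFraction(list(rep(TRUE, 10)))$sd, 0)

  # 2-state at 10 nM, kon = 1.94e7, koff = 0.045: fraction ~ 0.81
  sch <- twoStateScheme(1.94e7, 0.045)
  cls <- simulateClassSeries(sch, 90, 10, seed = 28)
  oc <- occupancyFraction(lapply(cls, function(x) x != "dark"),
                          replicate = rep(1:3, each = 30))
  pBound <- 0.194 / (0.194 + 0.045)
  expect_equal(oc$mean, pBound, tolerance = 0.05)
  expect_length(oc$perReplicate, 3L)
  expect_true(all(oc$perReplicate >= 0 & oc$perReplicate <= 1))
})

test_that("event counting and normalization behave", {
  expect_equal(eventsPerMolecule(list(rep(FALSE, 10)))$mean, 0)
  # homogeneous arrivals: ~ lambda * T events per molecule
  sch <- twoStateScheme(1e7, 0.2)  # short dwells, frequent events
  set.seed(29)
  nEv <- eventsPerMolecule(lapply(1:40, function(i) {
    p <- simulateTrajectory(sch, 1800, 10, seed = 290 + i)
    discretizePath(p, 3, 1800) != "dark"
  }))
  expect_gt(nEv$mean, 5)
  # reference normalization identity
  expect_equal(eventsPerMolecule(list(c(F, T, F, T, F)),
                                 reference = 2)$relative, 1)
})

test_that("rastergram rows sort by first event time", {
  b1 <- c(rep(FALSE, 3), TRUE, TRUE, FALSE)   # first event frame 4
  b2 <- c(FALSE, TRUE, rep(FALSE, 4))          # first event frame 2
  b3 <- rep(FALSE, 6)                          # no events
  r <- rastergramData(list(a = b1, b = b2, c = b3), frameInterval = 3)
  expect_equal(r$order$row[r$order$molecule_id == "b"], 0L)
  expect_equal(r$order$row[r$order$molecule_id == "a"], 1L)
  expect_equal(r$order$row[r$order$molecule_id == "c"], 2L)
  # permutation invariance of the assigned order
  r2 <- rastergramData(list(c = b3, b = b2, a = b1), frameInterval = 3)
  m <- merge(r$order, r2$order, by = "molecule_id")
  expect_equal(m$row.x, m$row.y)
  # single molecule gets row 0
  expect_equal(rastergramData(list(b1))$order$row, 0L)
})

test_that("photobleaching control recovers censored lifetimes", {
  # no censoring: MLE is the sample mean
  d0 <- sampleDwells(1, 100, 500, seed = 30)
  pb0 <- photobleachControl(d0)
  expect_equal(pb0$tau, mean(dwellTable(d0)$duration_s))

  # tau 2682 s against an 1800 s movie, 500 spots: within 15%
  d <- sampleDwells(1, 2682, 500, censorAt = 1800, seed = 31)
  pb <- photobleachControl(d)
  expect_equal(pb$tau, 2682, tolerance = 0.15)
  # at least ~9x longer than a 290 s bound-state lifetime
  expect_gte(pb$tau / 290, 9)

  # all censored: lower bound only
  dAll <- new("DwellSet", dwells = data.frame(
    molecule_id = 1:3, state = "bound", duration_s = rep(1800, 3),
    censored = rep(TRUE, 3)))
  pbAll <- photobleachControl(dAll)
  expect_true(pbAll$lowerBoundOnly)
  expect_equal(pbAll$tau, 5400)
})
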