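test_that("BIC formula is exact", {
  expect_equal(bic(0, 100, -500), 1000)
  expect_equal(bic(6, 1000, -500), 6 * log(1000) + 1000)
  expect_equal(bic(6, 1000, -500), 1041.447, tolerance = 1e-6)
  # nested models on the same data differ by delta-k * log(N)
  expect_equal(bic(6, 5000, -10) - bic(2, 5000, -10), 4 * log(5000))
  expect_error(bic(2, 0, -10), "at least 1")
})

test_that("frame transition matrices are proper and the likelihood sane", {
  sch <- fourStateScheme()
  for (cn in c(1, 3, 10)) {
    A <- as.matrix(Matrix::expm(rateMatrix(sch, cn) * 3))
    expect_lt(max(abs(rowSums(A) - 1)), 1e-10)
    expect_true(all(A >= -1e-12))
  }

  # single-frame sequences: logL = log stationary class probabilities
  s2 <- twoStateScheme(1e7, 0.05)
  pi <- stationaryDistribution(s2, 10)
  d1 <- list(list(concentration = 10, classes = list("bound")))
  expect_equal(schemeLogLik(s2, d1, 3), log(unname(pi["UL"])))
  d0 <- list(list(concentration = 10, classes = list("dark")))
  expect_equal(schemeLogLik(s2, d0, 3), log(unname(pi["U"])))

  # slower switching fits a constant sequence better
  dConst <- list(list(concentration = 10,
                      classes = list(rep("bound", 100))))
  llSlow <- schemeLogLik(twoStateScheme(1e7, 1e-4), dConst, 3)
  llFast <- schemeLogLik(twoStateScheme(1e7, 0.5), dConst, 3)
  expect_gt(llSlow, llFast)

  expect_error(schemeLogLik(s2, d1, 0), "positive")
})

test_that("frame-likelihood MLE agrees with the dwell-based estimator", {
  # dwells >> frame interval so discretization bias is negligible
  sch <- twoStateScheme(1e6, 0.008)  # at 10 nM: tau ~ 100 s / 125 s
  classes <- simulateClassSeries(sch, 120, 10, seed = 41,
                                 movieLength = 7200)
  datasets <- list(list(concentration = 10, classes = classes))
  # one concentration is fine here: kon enters only via the known C
  fit <- suppressWarnings(fitGlobal(twoStateScheme(5e5, 0.02), datasets,
                                    3, seed = 1))

  # dwell-based closed-form oracle on the same class series
  d <- dwellTable(extractDwells(lapply(classes, function(x) x != "dark"),
                                frameInterval = 3))
  koffDwell <- 1 / mean(d$duration_s[d$state == "bound" & !d$censored])
  konDwell <- 1 / (mean(d$duration_s[d$state == "unbound" &
                                     !d$censored]) * 10e-9)
  expect_equal(unname(fit@rates["UL->U"]), koffDwell, tolerance = 0.02)
  expect_equal(unname(fit@rates["U->UL"]), konDwell, tolerance = 0.02)
})

test_that("degenerate data flag unidentifiable rates", {
  # no binding events at all: koff cannot be identified
  classes <- lapply(1:20, function(i) rep("dark", 200))
  datasets <- list(list(concentration = 1, classes = classes),
                   list(concentration = 10, classes = classes))
  fit <- suppressWarnings(fitGlobal(twoStateScheme(1e6, 0.05), datasets,
                                    3, seed = 2))
  expect_true(length(fit@flags) > 0)
  expect_equal(unname(fit@ci["UL->U", ]), c(1e-6, 1e2))
})

test_that("scheme selection ranks the generating scheme first", {
  # data truly from a 2-state scheme: extra states are penalized away
  sch <- twoStateScheme(1.94e7, 0.045)
  datasets <- lapply(c(1, 10), function(cn) {
    list(concentration = cn,
         classes = simulateClassSeries(sch, 60, cn, seed = 50 + cn))
  })
  sel <- selectScheme(
    list(twoStateScheme(1e7, 0.1),
         threeStateBoundScheme(1e7, 0.1, 0.005, 0.005),
         fourStateScheme(1e7, 0.1, 0.005, 0.005, 0.005, 0.005)),
    datasets, 3, seed = 3)
  expect_equal(sel$table$k[1], 2L)
  expect_equal(sel$table$deltaBIC[1], 0)
  expect_true(all(diff(sel$table$bic) >= 0))
  expect_error(selectScheme(list(twoStateScheme()), datasets, 3, seed = 1),
               "2 candidate")
})
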