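test_that("channel mapping is recovered exactly on consistent data", {
  set.seed(1)
  P <- matrix(runif(40, 10, 500), 20, 2)
  truth <- new("SimilarityTransform", scale = 1.01,
               rotation = 2 * pi / 180, translation = c(3.2, -1.7),
               rmsResidual = NA_real_)
  est <- estimateMapping(P, applyMapping(truth, P))
  expect_equal(est@scale, 1.01, tolerance = 1e-9)
  expect_equal(est@rotation, 2 * pi / 180, tolerance = 1e-9)
  expect_equal(est@translation, c(3.2, -1.7), tolerance = 1e-6)
  expect_lt(est@rmsResidual, 1e-9)

  # identity on identical point sets
  id <- estimateMapping(P, P)
  expect_equal(id@scale, 1)
  expect_equal(id@rotation, 0)
  expect_equal(id@translation, c(0, 0))

  # estimate(apply(T, P), P) composed with T is the identity
  inv <- estimateMapping(applyMapping(truth, P), P)
  comp <- composeMapping(truth, inv)
  expect_equal(comp@scale, 1, tolerance = 1e-9)
  expect_equal(comp@rotation, 0, tolerance = 1e-9)
  expect_lt(max(abs(comp@translation)), 1e-9)

  # noise floor: 0.1 px noise on 20 pairs -> RMS residual <= 0.15 px
  set.seed(2)
  noisy <- applyMapping(truth, P) + matrix(rnorm(40, 0, 0.1), 20, 2)
  expect_lte(estimateMapping(P, noisy)@rmsResidual, 0.15)

  expect_error(estimateMapping(P[1, , drop = FALSE],
                               P[1, , drop = FALSE]), "2 matched")
  expect_error(estimateMapping(matrix(5, 3, 2), matrix(1:6, 3, 2)),
               "coincident")
})

test_that("drift estimation recovers injected displacement series", {
  set.seed(3)
  pos <- spotGrid(20, lo = 10, hi = 55, by = 10, jitter = 1.5, seed = 3)
  # static movie: displacements ~ 0
  mvS <- renderMovie(pos, matrix(TRUE, 20, 40), dim = c(64, 64),
                     amplitude = 1000, seed = 5)
  dS <- estimateDrift(mvS$red)
  expect_lt(max(abs(c(dS$dx, dS$dy))), 0.02)

  # linear ramp 0.01 px/frame x 600 frames
  drift <- cbind(0.01 * (0:599), 0)
  mvL <- renderMovie(pos, matrix(TRUE, 20, 600), dim = c(64, 64),
                     drift = drift, amplitude = 1000, seed = 6)
  dL <- estimateDrift(mvL$red)
  expect_lt(abs(dL$dx[600] - drift[600, 1]), 0.1)
  rms <- sqrt(mean((dL$dx - drift[, 1])^2 + (dL$dy - drift[, 2])^2))
  expect_lt(rms, 0.05)

  # slow sinusoidal drift of 1 px amplitude
  driftS <- cbind(sin(2 * pi * (0:299) / 300), 0)
  mvSin <- renderMovie(pos, matrix(TRUE, 20, 300), dim = c(64, 64),
                       drift = driftS, amplitude = 1000, seed = 7)
  dSin <- estimateDrift(mvSin$red)
  rmsSin <- sqrt(mean((dSin$dx - driftS[, 1])^2 +
                      (dSin$dy - driftS[, 2])^2))
  expect_lt(rmsSin, 0.1)

  expect_error(estimateDrift(array(0, c(8, 8, 1))), "2 frames")
})

test_that("GLRT detection controls false alarms and finds bright spots", {
  # pure noise: expected false alarms = pFA * npix ~ 0.26 per 512^2 image
  fa <- vapply(1:5, function(s) {
    set.seed(s)
    img <- matrix(rnorm(512^2, 100, 5), 512, 512)
    nrow(detectAOIs(img, pFA = 1e-6, refine = FALSE))
  }, 0L)
  expect_lte(sum(fa), 2L)

  # blank image with essentially infinite threshold: no AOIs
  set.seed(9)
  blank <- matrix(rnorm(64^2, 100, 5), 64, 64)
  expect_equal(nrow(detectAOIs(blank, pFA = 1e-300, refine = FALSE)), 0L)

  # 50 bright spots: >= 49 detected with subpixel centers within 0.5 px
  pos <- spotGrid(50)
  mv <- renderMovie(pos, matrix(TRUE, 50, 5), dim = c(128, 128),
                    amplitude = 200, background = 100, readNoiseSD = 5,
                    seed = 12)
  avg <- apply(mv$red[, , 1:5], c(1, 2), mean)
  aois <- detectAOIs(avg)
  hits <- vapply(seq_len(50), function(i) {
    min(sqrt((aois$x - pos[i, 1])^2 + (aois$y - pos[i, 2])^2))
  }, 0)
  expect_gte(sum(hits < 0.5), 49L)

  # ROC monotonicity: a stricter threshold never detects more
  aoisStrict <- detectAOIs(avg, pFA = 1e-12)
  expect_lte(nrow(aoisStrict), nrow(aois))

  expect_error(detectAOIs(matrix(0, 3, 3)), "smaller")
})

test_that("2D Gaussian spot fits are exact on noise-free data and gated", {
  img <- matrix(50, 32, 32)
  img <- cosmosKinetics:::addGaussianSpot(img, 15.3, 16.7, 120, 1.1)
  f <- fitSpot(img, c(15, 17))
  expect_equal(f$amplitude, 120, tolerance = 1e-6)
  expect_equal(f$x, 15.3, tolerance = 1e-6)
  expect_equal(f$y, 16.7, tolerance = 1e-6)
  expect_equal(f$sigma, 1.1, tolerance = 1e-6)
  expect_equal(f$background, 50, tolerance = 1e-6)
  expect_true(f$ok)

  # flat window: rejected (no amplitude)
  expect_false(fitSpot(matrix(50, 32, 32), c(15, 17))$ok)

  # two overlapping spots in one window: residual above gate
  img2 <- matrix(100, 32, 32)
  img2 <- cosmosKinetics:::addGaussianSpot(img2, 15, 16, 200, 1.1)
  img2 <- cosmosKinetics:::addGaussianSpot(img2, 17, 16, 200, 1.1)
  set.seed(13)
  img2 <- img2 + rnorm(length(img2), 0, 2)
  f2 <- fitSpot(img2, c(16, 16))
  sigmaHat <- cosmosKinetics:::imageNoiseSD(img2)
  expect_gt(f2$residual, 3 * sigmaHat)

  # window out of bounds
  expect_false(fitSpot(img, c(1, 1))$ok)
})

test_that("trace extraction follows mapped, drift-corrected windows", {
  set.seed(20)
  n <- 12
  pos <- spotGrid(n, lo = 10, hi = 52, by = 14, jitter = 1, seed = 20)
  sch <- twoStateScheme(1.94e7, 0.045)
  cls <- simulateClassSeries(sch, n, 5, seed = 99, movieLength = 600)
  binding <- t(vapply(cls, function(x) x != "dark", logical(200)))
  tr <- new("SimilarityTransform", scale = 1.005, rotation = 0.01,
            translation = c(2.1, -1.3), rmsResidual = NA_real_)
  fid <- cbind(c(6, 57, 30), c(57, 6, 4))
  mv <- renderMovie(pos, binding, dim = c(72, 72), fiducials = fid,
                    transform = tr, amplitude = 300, seed = 21)
  map <- estimateMapping(mv$fiducialsRed, mv$fiducialsGreen)
  expect_lt(map@rmsResidual, 1e-9)

  avg <- apply(mv$red[, , 1:5], c(1, 2), mean)
  aois <- excludeNearAOIs(detectAOIs(avg), fid)
  expect_gte(nrow(aois), n - 1L)
  traces <- extractTraces(mv$green, aois, mapping = map)
  corr <- vapply(split(traces, traces$molecule_id), function(d) {
    i <- which.min((pos[, 1] - aois$x[d$molecule_id[1]])^2 +
                   (pos[, 2] - aois$y[d$molecule_id[1]])^2)
    suppressWarnings(cor(d$intensity, as.numeric(binding[i, ])))
  }, 0)
  expect_gt(median(corr, na.rm = TRUE), 0.99)

  # AOIs at empty surface positions see far fewer binding events
  empty <- cbind(c(20, 40, 60) + 7, c(20, 40, 60) + 7)
  emptyTr <- extractTraces(mv$green, data.frame(x = empty[, 1],
                                                y = empty[, 2]))
  thr <- mean(emptyTr$intensity, na.rm = TRUE) +
    5 * sd(emptyTr$intensity, na.rm = TRUE)
  onRate <- mean(traces$intensity > thr, na.rm = TRUE)
  offRate <- mean(emptyTr$intensity > thr, na.rm = TRUE)
  expect_gt(onRate, 5 * max(offRate, 1e-3))

  # out-of-bounds mapped window marked partial
  far <- extractTraces(mv$green, data.frame(x = 1, y = 1))
  expect_true(all(far$partial))
})
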