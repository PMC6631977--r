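test_that("mean centering fits on calibration and re-applies stored means", {
  r <- meanCenter(rbind(c(1, 3), c(3, 5)))
  expect_equal(unname(r$mean), c(2, 4))
  expect_equal(unname(r$X), rbind(c(-1, -1), c(1, 1)))

  applied <- meanCenter(rbind(c(2, 4)), fittedMean = c(2, 4))
  expect_equal(unname(applied$X), rbind(c(0, 0)))

  one <- meanCenter(rbind(c(0.4, 0.7, 0.1)))
  expect_true(all(one$X == 0))

  expect_error(meanCenter(rbind(c(1, 2)), fittedMean = 1:3), "shape error")
})

test_that("SNV matches its closed form and is idempotent", {
  expect_equal(unname(snvTransform(c(1, 2, 3))[1, ]), c(-1, 0, 1))
  set.seed(1)
  X <- matrix(rnorm(30, 0.5, 0.2), 5)
  Z <- snvTransform(X)
  expect_equal(unname(rowMeans(Z)), rep(0, 5))
  expect_equal(unname(apply(Z, 1, sd)), rep(1, 5))
  expect_equal(snvTransform(Z), Z)
  expect_error(snvTransform(c(2, 2, 2)), "degenerate-spectrum")
})

test_that("MSC recovers affine distortions of the reference", {
  ref <- sin(seq(0, 3, length.out = 50)) + 1
  expect_equal(unname(mscTransform(2 + 3 * ref, ref)[1, ]), ref)
  expect_equal(unname(mscTransform(ref, ref)[1, ]), ref)
  ## spectrum uncorrelated with the reference: slope ~ 0
  expect_error(mscTransform(rep(1, 50) + c(1e-13, rep(0, 49)), ref),
               "degenerate-fit")
})

test_that("finite-difference derivatives match closed forms", {
  expect_equal(unname(spectralDerivative(c(0, 1, 2, 3), 1)[1, ]),
               rep(1, 4))
  k <- 0:4
  sd2 <- spectralDerivative(k^2, 2)[1, ]
  expect_equal(unname(sd2[2:4]), rep(2, 3))
  expect_error(spectralDerivative(c(1, 2), 1), "length error")
  expect_error(spectralDerivative(1:5, 3), "parameter error")
  expect_error(spectralDerivative(matrix(1:10, 2), 1,
                                  grid = c(10, 8, 7, 5, 1)),
               "uniform")
})

test_that("Savitzky-Golay weights match the brute-force least-squares oracle", {
  expect_equal(sgCoefficients(5, 2), c(-3, 12, 17, 12, -3) / 35)

  set.seed(7)
  x <- rnorm(40)
  for (p in list(c(5L, 2L), c(7L, 3L))) {
    expect_equal(unname(savitzkyGolay(x, p[1], p[2])[1, ]),
                 sgOracle(x, p[1], p[2]), tolerance = 1e-10)
  }
})

test_that("Savitzky-Golay reproduces low-degree polynomials and validates parameters", {
  z <- seq_len(30)
  cubic <- 2 + 0.5 * z - 0.01 * z^2 + 0.001 * z^3
  expect_equal(unname(savitzkyGolay(cubic, 11, 3)[1, ]), cubic,
               tolerance = 1e-9)
  ## polyorder = window - 1 interpolates: identity
  set.seed(3)
  r <- rnorm(20)
  expect_equal(unname(savitzkyGolay(r, 5, 4)[1, ]), r, tolerance = 1e-9)
  expect_error(savitzkyGolay(r, 4, 2), "parameter error")
  expect_error(savitzkyGolay(r, 5, 5), "parameter error")
})

test_that("Norris derivative reduces to plain differences and handles edges", {
  x <- c(1, 4, 2, 8, 5, 7)
  nd <- norrisDerivative(x, segment = 1, gap = 1, order = 1)[1, ]
  expect_equal(unname(nd[1:5]), diff(x))

  lin <- seq(0, 10, length.out = 21)
  out <- norrisDerivative(lin, segment = 5, gap = 3, order = 1)[1, ]
  expect_equal(unname(out[3:15]), rep(0.5, 13))

  expect_equal(unname(norrisDerivative(rep(2, 10), segment = 3, gap = 2)[1, ]),
               rep(0, 10))
  expect_error(norrisDerivative(x, segment = 2, gap = 1), "parameter error")
  expect_error(norrisDerivative(x, segment = 5, gap = 2), "parameter error")
})

test_that("strategy strings parse with parameters and enforce invariants", {
  st <- preprocessStrategy("SNV+NDS+FD+MC")
  expect_equal(vapply(st@steps, `[[`, "", "op"), c("SNV", "NDS", "FD", "MC"))
  expect_equal(strategyId(st), "SNV+NDS(5,5)+FD+MC")

  st2 <- preprocessStrategy("SGS(7,2)+MC")
  expect_equal(st2@steps[[1]]$params$window, 7L)
  expect_equal(st2@steps[[1]]$params$polyorder, 2L)

  expect_error(preprocessStrategy("XY+MC"), "unknown operator")
  expect_error(fitApplyStrategy("MC+SNV", matrix(1:6, 2)), "final step")
  expect_error(fitApplyStrategy("SNV+SNV", matrix(1:6, 2)), "at most once")
})

test_that("strategy composition matches hand-computed closed forms", {
  X <- rbind(c(1, 2, 4), c(5, 3, 1))
  r <- fitApplyStrategy("MC", X)
  expect_equal(unname(r$cal), sweep(X, 2, colMeans(X)))

  ## SNV then MC, composed by hand
  snvRow <- function(x) (x - mean(x)) / sd(x)
  Z <- t(apply(X, 1, snvRow))
  expected <- sweep(Z, 2, colMeans(Z))
  got <- fitApplyStrategy("SNV+MC", X)
  expect_equal(unname(got$cal), unname(expected))

  ## MSC+MC fixed point: calibration spectra that are exact affine
  ## transforms of their mean all correct back to it, so a new spectrum
  ## equal to that mean maps to the zero vector after centering
  base <- sin(seq(0, 4, length.out = 15)) + 2
  Xc <- rbind(0.2 + 1.5 * base, -0.1 + 0.8 * base, 0.05 + 1.1 * base,
              -0.15 + 0.6 * base)
  ref <- colMeans(Xc)
  out <- fitApplyStrategy("MSC+MC", Xc, X_new = rbind(ref))
  expect_equal(unname(out$new), matrix(0, 1, 15), tolerance = 1e-8)
})

test_that("fitted strategies never leak state from new data", {
  set.seed(9)
  Xc <- matrix(rnorm(80, 1, 0.2), 8)
  fitted <- fitApplyStrategy("MSC+MC", Xc)$strategy
  A <- matrix(rnorm(20, 5, 2), 2)
  B <- matrix(rnorm(30, -3, 0.5), 3)
  outA <- applyStrategy(fitted, A)
  outB <- applyStrategy(fitted, rbind(A, B))
  ## transforming A alone or with B attached gives identical rows
  expect_equal(outA, outB[1:2, , drop = FALSE])
  ## and the fitted state is untouched by application
  expect_identical(fitted@fitted,
                   fitApplyStrategy("MSC+MC", Xc)$strategy@fitted)
  expect_error(applyStrategy(preprocessStrategy("MC"), A), "state error")
})

test_that("all operators preserve matrix shape", {
  set.seed(2)
  X <- matrix(rnorm(5 * 25, 0.5, 0.1), 5)
  ops <- list(
    function(x) meanCenter(x)$X,
    snvTransform,
    function(x) mscTransform(x, colMeans(x)),
    function(x) spectralDerivative(x, 1),
    function(x) spectralDerivative(x, 2),
    function(x) savitzkyGolay(x, 7, 2),
    function(x) norrisDerivative(x, 3, 2))
  for (f in ops) expect_equal(dim(f(X)), dim(X))
})
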