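grid05 <- seq(-6, 12, by = 0.5)

renderClean <- function(cth, sigma, y0 = 80, y1 = 1100, y2 = 170) {
  data.frame(position_mm = grid05,
             intensity = modelProfile(list(y0 = y0, y1 = y1, y2 = y2,
                                           x0 = 0, x1 = cth, sigma = sigma),
                                      grid05))
}

test_that("the blurred-cortex model matches independent erf evaluation", {
  # step limit: mid-cortex value is the cortical density
  expect_equal(modelProfile(list(y0 = 0, y1 = 1000, y2 = 200, x0 = 0,
                                 x1 = 2, sigma = 0.01), 1), 1000)
  # asymptotes
  p <- list(y0 = 37, y1 = 950, y2 = 180, x0 = 1, x1 = 3, sigma = 0.8)
  expect_equal(modelProfile(p, p$x0 - 10 * p$sigma), p$y0, tolerance = 1e-6)
  expect_equal(modelProfile(p, p$x1 + 10 * p$sigma), p$y2, tolerance = 1e-6)
  # wide blur mid-value against pracma::erf as the independent normal CDF
  phi <- function(z) 0.5 * (1 + pracma::erf(z / sqrt(2)))
  want <- 0 + 1000 * phi(0 / 1.5) + (200 - 1000) * phi((0 - 2) / 1.5)
  expect_equal(modelProfile(list(y0 = 0, y1 = 1000, y2 = 200, x0 = 0,
                                 x1 = 2, sigma = 1.5), 0), want)
  expect_equal(want, 427.0, tolerance = 1e-3)
})

test_that("free-mode fits recover above-resolution noiseless profiles within 1%", {
  for (cth in c(1.5, 2, 3, 5)) for (sg in c(0.5, 1)) {
    if (cth < 1.5 * sg) next
    fit <- fitProfile(renderClean(cth, sg), mode = "free")
    expect_true(fit$converged)
    expect_lt(abs(fit$measurement$cth - cth) / cth, 0.01)
    expect_lt(abs(fit$measurement$cbmd - 1100) / 1100, 0.01)
  }
})

test_that("constrained-density mode keeps CM accurate below the blur width", {
  sweep <- seq(0.3, 1.5, by = 0.2)
  cmErr <- cthErrFree <- numeric(length(sweep))
  for (i in seq_along(sweep)) {
    cth <- sweep[i]
    pr <- renderClean(cth, 1.5)
    fc <- fitProfile(pr, mode = "constrained_density", y1Fixed = 1100)
    ff <- fitProfile(pr, mode = "free")
    cmErr[i] <- abs(fc$measurement$cm - 0.1 * cth * 1100) / (0.1 * cth * 1100)
    cthErrFree[i] <- abs(ff$measurement$cth - cth) / cth
  }
  expect_true(all(cmErr <= 0.05))
  # free-mode thickness is unreliable below resolution: the constrained CM
  # error undercuts the free CTh error on at least 90% of the sweep
  expect_gte(mean(cmErr < cthErrFree), 0.9)
  expect_gt(max(cthErrFree), 0.20)
})

test_that("constrained-mode CM is nearly unbiased under 5% intensity noise", {
  set.seed(42)
  errs <- replicate(300, {
    pr <- renderClean(1.0, 1.5)
    pr$intensity <- pr$intensity + rnorm(nrow(pr), 0, 55)
    f <- fitProfile(pr, mode = "constrained_density", y1Fixed = 1100)
    (f$measurement$cm - 110) / 110
  })
  expect_lt(abs(mean(errs)), 0.03)
})

test_that("degenerate profiles are rejected", {
  flat <- data.frame(position_mm = grid05, intensity = rep(100, length(grid05)))
  expect_error(fitProfile(flat), "degenerate")
  mono <- data.frame(position_mm = grid05, intensity = seq_along(grid05))
  expect_error(fitProfile(mono), "degenerate")
  short <- data.frame(position_mm = 1:5, intensity = c(1, 5, 9, 5, 1))
  expect_error(fitProfile(short), "at least 8")
  expect_error(fitProfile(renderClean(2, 1), mode = "constrained_density"),
               "y1Fixed")
})

test_that("derived CBM variables follow their definitions", {
  p <- c(y0 = 0, y1 = 1000, y2 = 150, x0 = 0, x1 = 2, sigma = 1)
  m <- deriveCbmVariables(p)
  expect_equal(m$cm, 200)            # 0.1 * 2 mm * 1000 mg/cm^3
  expect_equal(m$cbmd, 1000)
  expect_equal(m$ectd, 150)          # point convention reads y2
  z <- deriveCbmVariables(c(y0 = 0, y1 = 900, y2 = 100, x0 = 1, x1 = 1,
                            sigma = 1))
  expect_equal(z$cth, 0)
  expect_equal(z$cm, 0)
  expect_error(deriveCbmVariables(p, "band", bandMm = 0), "positive")
  # band convention averages the fitted tail, converging to y2 deep in
  b <- deriveCbmVariables(p, "band", bandMm = 3)
  expect_true(b$ectd > 150 && b$ectd < 1000)
  # the cm identity holds for every fitted measurement
  fit <- fitProfile(renderClean(2, 1), mode = "free")
  expect_equal(fit$measurement$cm,
               0.1 * fit$measurement$cth * fit$measurement$cbmd)
})

test_that("global density estimation is robust and round-trips", {
  mk <- function(y1) renderClean(4, 0.8, y1 = y1)
  profs <- c(lapply(c(990, 1000, 1010, 5000), mk),
             lapply(rep(1000, 6), mk))
  expect_equal(estimateGlobalDensity(profs), 1000, tolerance = 0.02)
  expect_error(estimateGlobalDensity(profs[1:3]), "insufficient")
  # rendered at y1 = 1100, sigma = 1, noise 20: estimate within 3%
  set.seed(7)
  noisy <- lapply(1:12, function(i) {
    pr <- renderClean(3.5, 1, y1 = 1100)
    pr$intensity <- pr$intensity + rnorm(nrow(pr), 0, 20)
    pr
  })
  expect_lt(abs(estimateGlobalDensity(noisy) - 1100) / 1100, 0.03)
})

test_that("batch measurement returns one converged row per vertex", {
  pr <- renderProfiles(cth = c(1.2, 2.5, 3.1), cbmd = 1100, ectd = 170,
                       sigmaBlur = 1, noiseSd = 0, seed = 3)
  out <- measureProfiles(pr, mode = "constrained_density", y1Fixed = 1100)
  expect_equal(nrow(out), 3L)
  expect_true(all(out$converged))
  expect_equal(out$cth, c(1.2, 2.5, 3.1), tolerance = 0.02)
})
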