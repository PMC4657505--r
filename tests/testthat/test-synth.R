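test_that("CM equals 0.1 * CTh * CBMD exactly at every vertex and side", {
  pop <- simulatePopulation(fixMeshSmall, 30, seed = 4, sides = "both")
  for (side in c("", "_left", "_right")) {
    cm <- assay(pop, paste0("CM", side))
    expect_identical(cm, 0.1 * assay(pop, paste0("CTh", side)) *
                       assay(pop, paste0("CBMD", side)))
  }
  # combined is the mean of the two sides
  expect_equal(assay(pop, "CTh"),
               (assay(pop, "CTh_left") + assay(pop, "CTh_right")) / 2)
})

test_that("zero noise and zero slopes reproduce the baseline exactly", {
  spec <- trueEffectSpec(
    effectFraction = c(CTh = 0, CBMD = 0, ECTD = 0),
    spatialNoiseSd = c(CTh = 0, CBMD = 0, ECTD = 0),
    subjectSd = c(CTh = 0, CBMD = 0, ECTD = 0),
    lrNoiseSd = 0, ageSlope = 0, weightSlope = 0, siteSd = 0)
  pop <- simulatePopulation(fixMeshSmall, 10, spec, seed = 2)
  expect_true(all(assay(pop, "CTh") == spec$baseline[["CTh"]]))
  expect_true(all(assay(pop, "ECTD") == spec$baseline[["ECTD"]]))
})

test_that("empty populations and bad arguments are handled", {
  pop <- simulatePopulation(fixMeshSmall, 0, seed = 1)
  expect_equal(ncol(pop), 0L)
  expect_error(drawCaseCohort(fixPlanted, 0), "alpha")
  expect_error(drawCaseCohort(fixPlanted, 1.2), "alpha")
  expect_error(hazardSpec(-0.1), "non-negative")
})

test_that("risk-decile field contrast matches the planted effect fraction", {
  spec <- trueEffectSpec(effectFraction = c(CTh = -0.10, CBMD = 0, ECTD = 0))
  pop <- simulatePopulation(fixMeshMid, 500, spec, seed = 6,
                            sides = "combined", shapes = FALSE)
  sel <- regionIdx(fixMeshMid, "trochanter_superolateral")
  pmTroch <- colMeans(assay(pop, "CTh")[sel, ])
  qs <- quantile(pop$u_troch, c(0.1, 0.9))
  gap <- (mean(pmTroch[pop$u_troch >= qs[2]]) -
          mean(pmTroch[pop$u_troch <= qs[1]])) / mean(pmTroch)
  expect_lt(abs(gap - (-0.10)), 0.02)
})

test_that("generators are seed-reproducible and differ across seeds", {
  a <- simulatePopulation(fixMeshSmall, 20, seed = 9, shapes = FALSE)
  b <- simulatePopulation(fixMeshSmall, 20, seed = 9, shapes = FALSE)
  c <- simulatePopulation(fixMeshSmall, 20, seed = 10, shapes = FALSE)
  expect_identical(assay(a, "CTh"), assay(b, "CTh"))
  expect_identical(a$age, b$age)
  expect_false(identical(assay(a, "CTh"), assay(c, "CTh")))
})

test_that("covariate means at n = 5000 match the configured distributions", {
  tiny <- makeCanonicalMesh(100, seed = 1)
  pop <- simulatePopulation(tiny, 5000, seed = 12, sides = "combined",
                            shapes = FALSE)
  # age is Normal(74, 6) truncated at 65: mean of |N(74,6)-65|+65
  m <- 74 - 65
  ageMean <- 65 + m * (1 - 2 * pnorm(-m / 6)) + 2 * 6 * dnorm(m / 6)
  expect_lt(abs(mean(pop$age) - ageMean), 3 * 6 / sqrt(5000))
  expect_lt(abs(mean(pop$weight) - 84), 3 * 14 / sqrt(5000))
  expect_lt(abs(mean(pop$height) - 174), 3 * 7 / sqrt(5000))
})

test_that("competing types split evenly under symmetric hazards", {
  tiny <- makeCanonicalMesh(100, seed = 1)
  hz <- hazardSpec(0.03, 0.03, coefTroch = c(cm = 0, ectd = 0, age = 0),
                   coefNeck = c(cm = 0, ectd = 0, age = 0))
  pop <- simulatePopulation(tiny, 2000, seed = 13, sides = "combined",
                            shapes = FALSE)
  pop <- simulateFractureOutcomes(pop, hz, seed = 14)
  tab <- table(pop$fracture_type)
  frac <- tab[["trochanteric"]] + tab[["neck"]]
  expect_gt(frac, 100)
  # binomial check on the 50/50 type split
  expect_gt(binom.test(tab[["trochanteric"]], frac, 0.5)$p.value, 0.001)
  # fracture_type == none <=> censored
  expect_identical(pop$censored, as.character(pop$fracture_type) == "none")
  expect_true(all(pop$event_time > 0))
})

test_that("zero baseline rates censor everyone at the horizon", {
  pop <- simulatePopulation(fixMeshSmall, 50, seed = 1, sides = "combined",
                            shapes = FALSE)
  pop <- simulateFractureOutcomes(pop, hazardSpec(0, 0), horizon = 10,
                                  seed = 2)
  expect_true(all(pop$fracture_type == "none"))
  expect_true(all(pop$event_time == 10))
})

test_that("strong negative ECTD coefficient pushes neck cases to low ECTD", {
  pop <- makePlantedStudy(500, fixMeshSmall, seedPop = 21, seedOut = 22,
                          shapes = FALSE)
  sel <- regionIdx(fixMeshSmall, "neck_superior")
  ectd <- colMeans(assay(pop, "ECTD")[sel, ])
  expect_lt(mean(ectd[pop$fracture_type == "neck"]),
            mean(ectd[pop$fracture_type == "none"]))
})

test_that("case-cohort sampling hits the printed bookkeeping", {
  df <- data.frame(id = sprintf("P%04d", 1:3515),
                   fracture_type = "none")
  s <- drawCaseCohort(df, alpha = 308 / 3515, seed = 3)
  expect_equal(sum(s@inSubcohort), 308L)
  # subcohort inclusion probability equals alpha over repeated draws
  df2 <- data.frame(id = sprintf("Q%03d", 1:200),
                    fracture_type = rep(c("none", "neck"), c(190, 10)))
  hits <- integer(200)
  for (r in 1:500) {
    s2 <- drawCaseCohort(df2, 0.2, seed = 1000 + r)
    hits[match(s2@ids[s2@inSubcohort], df2$id)] <-
      hits[match(s2@ids[s2@inSubcohort], df2$id)] + 1L
  }
  expect_gt(binom.test(sum(hits), 500 * 200, 0.2)$p.value, 0.01)
  # all fractured subjects are cases, exactly once
  expect_equal(sort(s2@ids[s2@isCase]), sprintf("Q%03d", 191:200))
})

test_that("alpha = 1 yields the whole population at weight 1", {
  pop <- makePlantedStudy(60, fixMeshSmall, shapes = FALSE)
  s <- drawCaseCohort(pop, 1, seed = 2)
  expect_equal(length(s@ids), 60L)
  expect_true(all(s@inSubcohort))
  expect_true(all(s@weight == 1))
})

test_that("repeat scans honour the error SD and the seed", {
  pop <- simulatePopulation(fixMeshSmall, 25, seed = 31, sides = "combined",
                            shapes = FALSE)
  z <- simulateRepeatScans(pop, list(CTh = 0), seed = 5)
  expect_identical(z$CTh$scan1, z$CTh$scan2)
  a <- simulateRepeatScans(pop, list(CTh = 0.2), seed = 6)
  b <- simulateRepeatScans(pop, list(CTh = 0.2), seed = 6)
  expect_identical(a$CTh$scan1, b$CTh$scan1)
  expect_error(simulateRepeatScans(pop, list(CTh = -1), seed = 1),
               "non-negative")
})

test_that("rendered profiles are exact at zero noise and demand a covering grid", {
  pr <- renderProfiles(cth = 3, cbmd = 1000, ectd = 200, sigmaBlur = 1,
                       noiseSd = 0, seed = 1)
  expect_equal(pr$intensity,
               modelProfile(list(y0 = 80, y1 = 1000, y2 = 200, x0 = 0,
                                 x1 = 3, sigma = 1), pr$position_mm))
  expect_error(renderProfiles(3, 1000, 200, sigmaBlur = 1,
                              grid = seq(0, 4, 0.5), seed = 1), "grid")
  # round-trip: free-mode fit on a noiseless rendered thick cortex
  fit <- fitProfile(pr, mode = "free")
  expect_lt(abs(fit$measurement$cth - 3) / 3, 0.01)
})
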