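test_that("pair-counting AUC matches hand-counted examples and the trapezoid", {
  r <- rocAuc(c(0.9, 0.4, 0.6, 0.2), c("f", "f", "n", "n"), "f", nBoot = 0)
  expect_equal(r$auc, 0.75)          # 3 of 4 pairs concordant
  # perfect separation
  expect_equal(rocAuc(c(5, 6, 1, 2), rep(c("y", "n"), each = 2), "y",
                      nBoot = 0)$auc, 1)
  # trapezoidal area equals the Mann-Whitney value on tied, noisy scores
  set.seed(2)
  sc <- round(runif(300), 2)
  oc <- sample(c("a", "b"), 300, TRUE)
  r2 <- rocAuc(sc, oc, "a", nBoot = 0)
  o <- order(r2$roc$fpr, r2$roc$tpr)
  trap <- sum(diff(r2$roc$fpr[o]) *
                (head(r2$roc$tpr[o], -1) + tail(r2$roc$tpr[o], -1)) / 2)
  expect_equal(trap, r2$auc, tolerance = 1e-10)
  # null scores give AUC near one half
  expect_lt(abs(r2$auc - 0.5), 0.05)
  # monotone transforms leave AUC unchanged
  r3 <- rocAuc(qlogis((sc + 0.5) / 2), oc, "a", nBoot = 0)
  expect_equal(r3$auc, r2$auc)
  expect_error(rocAuc(sc, rep("a", 300), "a", nBoot = 0), "undefined")
  # bootstrap CI brackets the point estimate
  r4 <- rocAuc(sc, oc, "a", nBoot = 200, seed = 4)
  expect_true(r4$ci[1] <= r4$auc && r4$auc <= r4$ci[2])
})

test_that("AUC agrees with pROC on a shared example", {
  skip_if_not_installed("pROC")
  set.seed(6)
  sc <- rnorm(200)
  oc <- ifelse(rbinom(200, 1, plogis(sc)) == 1, "pos", "neg")
  ours <- rocAuc(sc, oc, "pos", nBoot = 0)$auc
  ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(oc, sc,
                                                         levels = c("neg", "pos")))))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("logistic fits recover known odds ratios and flag separation", {
  set.seed(11)
  n <- 2000
  d <- data.frame(id = as.character(1:n), age = rnorm(n, 74, 6),
                  height = rnorm(n, 174, 7),
                  site = factor(sample(paste0("s", 1:3), n, TRUE)),
                  marker = rnorm(n))
  lp <- -1.2 - 1.0 * d$marker          # beta 1.0 per SD decrease
  y <- rbinom(n, 1, plogis(lp))
  d$fracture_type <- ifelse(y == 1, "neck", "none")
  d$event_time <- ifelse(y == 1, runif(n, 0, 10), 10)
  f <- fitFractureModel(d, modelSpec("m+marker", "marker", "binary_any"))
  orHat <- f$or$or[f$or$term == "marker"]
  expect_gt(orHat, 2.2); expect_lt(orHat, 3.4)     # true e^1 = 2.72
  expect_false(f$separation)
  # a perfect predictor flags separation
  d2 <- d; d2$marker <- ifelse(d2$fracture_type == "neck", 5, -5)
  f2 <- fitFractureModel(d2, modelSpec("sep", "marker", "binary_any"))
  expect_true(f2$separation)
})

test_that("intercept-only trichotomous fits give symmetric probabilities", {
  set.seed(12)
  n <- 900
  d <- data.frame(id = as.character(1:n), age = rnorm(n, 74, 6),
                  height = rnorm(n, 174, 7),
                  site = factor(sample(paste0("s", 1:3), n, TRUE)),
                  fracture_type = sample(c("none", "trochanteric", "neck"),
                                         n, TRUE),
                  event_time = runif(n, 0, 9))
  f <- fitFractureModel(d, modelSpec("m", character(), "trichotomous"))
  expect_equal(max(abs(rowSums(f$probs) - 1)), 0, tolerance = 1e-12)
  expect_lt(max(abs(colMeans(f$probs) - 1 / 3)), 0.05)
})

test_that("CTh/CBMD patch variables are rejected unless overridden", {
  d <- data.frame(id = "a")
  expect_error(fitFractureModel(d, modelSpec("bad", "cth_troch_patch",
                                             "binary_any")),
               "completeness only")
  expect_error(looPredict(fixPlanted, modelSpec("bad", "cbmd_neck_patch",
                                                "trichotomous")),
               "completeness only")
})

test_that("cross-validation holds out every subject and re-runs SPM per fold", {
  pop <- fixPlanted[, 1:60]
  spec <- modelSpec("m+CBM", "CBM", "trichotomous")
  pr <- looPredict(pop, spec, folds = 60, spmMethod = "bonferroni",
                   seed = 3)
  expect_equal(pr$folds, 60L)
  expect_false(anyNA(pr$probs))
  # one SPM pass per fold and per patch definition (4 patches)
  expect_equal(pr$nSpmRuns, 60L * 4L)
  expect_equal(max(abs(rowSums(pr$probs) - 1)), 0, tolerance = 1e-10)
  expect_error(looPredict(fixPlanted[, 1:20], spec), "at least 30")
})

test_that("cross-validated AUC does not beat in-sample AUC on average", {
  set.seed(14)
  deltas <- vapply(1:25, function(r) {
    n <- 120
    d <- data.frame(id = as.character(1:n), age = rnorm(n, 74, 6),
                    height = rnorm(n, 174, 7),
                    site = factor(sample(paste0("s", 1:3), n, TRUE)),
                    m1 = rnorm(n), m2 = rnorm(n), m3 = rnorm(n))
    lp <- -1 - 0.4 * d$m1
    d$fracture_type <- ifelse(rbinom(n, 1, plogis(lp)) == 1, "neck", "none")
    d$event_time <- 5
    spec <- modelSpec("m+3", c("m1", "m2", "m3"), "binary_any")
    fin <- fitFractureModel(d, spec)
    aucIn <- rocAuc(fin$probs, ifelse(d$fracture_type == "none", "n", "f"),
                    "f", nBoot = 0)$auc
    # 10-fold CV on the same data via plain refits
    folds <- sample(rep_len(1:10, n))
    pcv <- numeric(n)
    for (k in 1:10) {
      fk <- fitFractureModel(d[folds != k, ], spec)
      dk <- cbmfrax:::.standardizeLike(fk, d[folds == k, ])
      pcv[folds == k] <- predict(fk$fit, newdata = dk, type = "response")
    }
    aucCv <- rocAuc(pcv, ifelse(d$fracture_type == "none", "n", "f"),
                    "f", nBoot = 0)$auc
    aucIn - aucCv
  }, numeric(1))
  expect_gt(mean(deltas), 0)         # cross-validation removes optimism
})

test_that("deviance comparison enforces nesting and matches the chi-squared null", {
  set.seed(15)
  n <- 400
  d <- data.frame(id = as.character(1:n), age = rnorm(n, 74, 6),
                  height = rnorm(n, 174, 7),
                  site = factor(sample(paste0("s", 1:3), n, TRUE)),
                  noise1 = rnorm(n), noise2 = rnorm(n), dxa = rnorm(n))
  d$fracture_type <- ifelse(rbinom(n, 1, 0.3) == 1, "neck", "none")
  d$event_time <- 5
  base <- modelSpec("m", character(), "binary_any")
  big <- modelSpec("m+noise", c("noise1", "noise2"), "binary_any")
  fS <- fitFractureModel(d, base)
  fL <- fitFractureModel(d, big)
  cmp <- compareDeviance(fS, fL)
  expect_equal(cmp$df, 2L)
  expect_gte(cmp$statistic, 0)
  # identical specs: zero statistic, p = 1
  same <- compareDeviance(fS, fitFractureModel(d, base))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  # disjoint additions are not nested
  fD <- fitFractureModel(d, modelSpec("m+DXA", "dxa", "binary_any"))
  expect_error(compareDeviance(fD, fL), "not nested")
  # null distribution of the statistic is chi-squared with 2 df
  stats <- vapply(1:300, function(r) {
    dd <- d
    dd$fracture_type <- ifelse(rbinom(n, 1, 0.3) == 1, "neck", "none")
    dd$noise1 <- rnorm(n); dd$noise2 <- rnorm(n)
    compareDeviance(fitFractureModel(dd, base),
                    fitFractureModel(dd, big))$statistic
  }, numeric(1))
  expect_gt(ks.test(stats, pchisq, df = 2)$p.value, 0.01)
})
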