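test_that("a response fully explained by age leaves the fracture contrast flat", {
  pop <- fixPlanted[, 1:200]
  # overwrite one assay with a field purely linear in age (no noise)
  Y <- matrix(rep(2 + 0.05 * pop$age, each = nrow(pop)), nrow(pop))
  assay(pop, "CTh", withDimnames = FALSE) <- Y
  res <- fitVertexGlm(pop, "CTh", "trochanteric")
  expect_lt(max(abs(res@tStat)), 0.5)
})

test_that("raw p values are calibrated under permuted labels", {
  pop <- fixPlanted
  set.seed(33)
  pop$fracture_type <- sample(pop$fracture_type)
  res <- fitVertexGlm(pop, "CM", "trochanteric")
  expect_lt(abs(mean(res@pRaw < 0.05) - 0.05), 0.02)
})

test_that("the planted trochanteric CM deficit is localized and recovered", {
  pop <- fixPlanted
  truth <- regionIdx(fixMeshMid, "trochanter_superolateral")
  res <- fitVertexGlm(pop, "CM", "trochanteric")
  ratio <- mean(abs(res@tStat[truth])) / mean(abs(res@tStat[-truth]))
  expect_gt(ratio, 3)
  patch <- extractSignificantPatches(pop, res, nPerm = 500, seed = 7)
  expect_identical(patch@fallback, "none")
  expect_gte(diceOverlap(patch, truth), 0.5)
  # effect size in the recovered patch is a deficit of roughly 10%
  eff <- median(res@effectPct[patch@vertices])
  expect_lt(eff, -5); expect_gt(eff, -20)
  # the neck ECTD deficit is likewise localized
  truthN <- regionIdx(fixMeshMid, "neck_superior")
  resN <- fitVertexGlm(pop, "ECTD", "neck")
  patchN <- extractSignificantPatches(pop, resN, nPerm = 500, seed = 7)
  expect_gte(diceOverlap(patchN, truthN), 0.5)
})

test_that("patches are unions of surviving clusters; empty results fall back flagged", {
  pop <- fixPlanted
  res <- fitVertexGlm(pop, "CM", "trochanteric")
  # bonferroni mask can be disjoint; the patch is exactly the masked set
  pb <- extractSignificantPatches(pop, res, method = "bonferroni")
  expect_setequal(pb@vertices, which(res@pRaw < 0.05 / nrow(pop)))
  comps <- cbmfrax:::.surfaceClusters(femurMesh(pop), pb@vertices)
  expect_setequal(unlist(comps), pb@vertices)
  # permuted labels: corrected map is empty, fallback flagged, never silent
  set.seed(90)
  popN <- pop; popN$fracture_type <- sample(pop$fracture_type)
  resN <- fitVertexGlm(popN, "CM", "trochanteric")
  pN <- extractSignificantPatches(popN, resN, nPerm = 500, seed = 3)
  expect_true(pN@fallback %in% c("uncorrected", "top_fraction"))
  expect_gt(length(pN@vertices), 0)
  expect_error(extractSignificantPatches(pop, res, nPerm = 100), "at least 500")
})

test_that("the surface union-find matches igraph components", {
  skip_if_not_installed("igraph")
  m <- fixMeshSmall
  set.seed(4)
  vs <- sample.int(nVertices(m), 80)
  ours <- cbmfrax:::.surfaceClusters(m, vs)
  ed <- meshEdges(m)
  keep <- ed[ed[, 1] %in% vs & ed[, 2] %in% vs, , drop = FALSE]
  g <- igraph::graph_from_edgelist(matrix(as.character(keep), ncol = 2),
                                   directed = FALSE)
  g <- g + igraph::vertices(setdiff(as.character(vs), igraph::V(g)$name))
  ref <- split(as.integer(igraph::V(g)$name),
               igraph::components(g)$membership)
  key <- function(cl) sort(vapply(unname(cl),
                                  function(x) paste(sort(x), collapse = ","),
                                  character(1)))
  expect_identical(key(ours), key(ref))
})

test_that("rank-deficient designs fail loudly, naming the collinear column", {
  pop <- fixPlanted[, 1:100]
  colData(pop)$dup <- pop$age
  expect_error(fitVertexGlm(pop, "CM", "trochanteric",
                            covariates = c("age", "dup")),
               "collinear.*dup")
  expect_error(fitVertexGlm(fixPlanted[, 1:20], "CM", "trochanteric"),
               "too few subjects")
})

test_that("patch averaging is an unweighted mean with strict preconditions", {
  patch <- new("PatchDefinition", variable = "CM", contrast = "neck",
               vertices = c(2L, 5L), provenance = "full_sample",
               fallback = "none")
  f <- c(10, 1, 10, 10, 3)
  expect_equal(patchAverage(f, patch), 2)
  expect_equal(patchAverage(rep(7, 5), patch), 7)
  empty <- new("PatchDefinition", variable = "CM", contrast = "neck",
               vertices = integer(0), provenance = "full_sample",
               fallback = "empty")
  expect_error(patchAverage(f, empty), "empty")
  f[2] <- NA
  expect_error(patchAverage(f, patch), "incomplete")
})

test_that("effect maps are masked to significance with the ECTD caveat", {
  pop <- fixPlanted
  res <- fitVertexGlm(pop, "ECTD", "neck")
  p <- extractSignificantPatches(pop, res, method = "bonferroni")
  maps <- reportEffectMaps(pop, list(ECTD_neck = attr(p, "result")))
  m <- maps$ECTD_neck
  expect_true(all(is.na(m[!attr(p, "result")@mask])))
  expect_match(attr(m, "caveat"), "near zero")
})
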