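# Shared fixtures, built once per test run. Sizes are chosen for desk-scale
# runtime; the methods vignette documents the corresponding full-scale
# settings.

suppressPackageStartupMessages({
  library(SummarizedExperiment)
  library(S4Vectors)
})

fixMeshSmall <- makeCanonicalMesh(500, seed = 11)
fixMeshMid <- makeCanonicalMesh(1000, seed = 11)

# planted-patch study: case-enriched cohort with ~-10% case-vs-cohort CM
# deficit in the superolateral trochanter and an ECTD deficit in the
# superior neck (the package's standing validation scenario)
makePlantedStudy <- function(n = 400, mesh = fixMeshMid, seedPop = 2,
                             seedOut = 102, shapes = TRUE) {
  sc <- plantedPatchScenario()
  pop <- simulatePopulation(mesh, n, sc$spec, seed = seedPop,
                            sides = "combined", shapes = shapes)
  pop <- simulateFractureOutcomes(pop, sc$hazard, seed = seedOut)
  if (shapes) pop <- addShapeScores(pop)
  pop
}

fixPlanted <- makePlantedStudy()

# Dice overlap between a patch and a vertex index set
diceOverlap <- function(patch, truthIdx) {
  2 * length(intersect(patch@vertices, truthIdx)) /
    (length(patch@vertices) + length(truthIdx))
}

regionIdx <- function(mesh, region) which(as.character(regionLabels(mesh)) == region)
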