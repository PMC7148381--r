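# Synthetic CSI phantom: beam curves, seeded generation, organ regimes.

test_that("depth-dose curve has plateau, distal falloff and a single peak", {
  expect_gt(beamDepthDose(0, 80, 10), 0.7)
  expect_lt(beamDepthDose(0, 80, 10), 1.3)
  expect_lt(beamDepthDose(80 + 2 * 10, 80, 10), 0.01)
  expect_lt(beamDepthDose(80 + 3 * 10, 80, 10), 0.01)
  # peak at or above plateau, just proximal of the range
  prof <- beamDepthDose(0:120, 80, 10)
  peakDepth <- which.max(prof) - 1
  expect_gte(max(prof), prof[1])
  expect_lt(peakDepth, 80)
  expect_gt(peakDepth, 80 - 2 * 10)
  # unimodal: once the 1 mm-sampled profile drops materially it never rises
  # again (differences within float noise of the flat plateau count as flat)
  d <- diff(prof)
  firstDrop <- which(d < -1e-9)[1]
  expect_true(all(d[firstDrop:length(d)] <= 1e-9))
  expect_error(beamDepthDose(10, -5, 10), "rangeMm")
  expect_error(beamDepthDose(-1, 80, 10), "depth")
})

test_that("depth-LET curve rises monotonically from plateau to distal max", {
  expect_equal(beamDepthLET(0, 80, 1.8, 15), 1.8, tolerance = 1e-6)
  prof <- beamDepthLET(0:200, 80, 1.8, 15)
  expect_true(all(diff(prof) >= 0))
  expect_lte(max(prof), 15)
  expect_gte(which.max(prof) - 1, 80)  # maximum attained at/beyond the range
  expect_error(beamDepthLET(0, 80, 5, 3), "distalLetMax")
})

test_that("patient generation is bit-identical for fixed seed and index", {
  cfg <- coarseConfig()
  a <- generatePatient(cfg, 3L)
  b <- generatePatient(cfg, 3L)
  expect_identical(
    lapply(phases(a), function(p) voxelData(p@physicalDose)),
    lapply(phases(b), function(p) voxelData(p@physicalDose)))
  expect_identical(organMasks(a), organMasks(b))
  # a different index gives different fields
  c <- generatePatient(cfg, 4L)
  expect_false(identical(voxelData(phases(a)$csi@physicalDose),
                         voxelData(phases(c)$csi@physicalDose)))
})

test_that("zero jitter degenerates to identical organ masks across patients", {
  geom <- phantomConfig()@organGeometry
  geom <- lapply(geom, function(g) { g$jitter <- c(0, 0, 0); g })
  cfg <- coarseConfig(organGeometry = geom)
  cohort <- generatePopulation(cfg, 10)
  oars <- c("brainstem", "thyroid", "heart", "lungs")
  for (o in oars)
    for (pt in cohort[-1])
      expect_identical(organMasks(pt)[[o]], organMasks(cohort[[1]])[[o]])
})

test_that("default jitter yields distinct thyroid placements and wide dose spread", {
  cohort <- generatePopulation(coarseConfig(), 10)
  centroids <- t(vapply(cohort, function(pt) {
    idx <- which(organMasks(pt)$thyroid, arr.ind = TRUE)
    colMeans(idx)
  }, numeric(3)))
  expect_equal(nrow(unique(round(centroids, 6))), 10)
  thyroidMeans <- vapply(cohort, function(pt)
    mean(totalPhysDose(pt)[organMasks(pt)$thyroid]), 0)
  expect_gte(max(thyroidMeans) / min(thyroidMeans), 4)
})

test_that("organ placements reproduce the characteristic dose/LET regimes", {
  cohort <- generatePopulation(coarseConfig(), 10)
  for (pt in cohort) {
    tot <- totalPhysDose(pt)
    m <- organMasks(pt)
    # brainstem sits in the boost: ~54/1.1 Gy physical
    expect_gte(median(tot[m$brainstem]), 45)
    expect_lte(median(tot[m$brainstem]), 53)
    # LET ordering: heart (distal) > lungs (intermediate) > brainstem (target)
    letc <- protonRBE:::.combinedLET(pt)
    meanLET <- vapply(c("heart", "lungs", "brainstem"),
                      function(o) mean(voxelData(letc)[m[[o]]]), 0)
    expect_gt(meanLET[["heart"]], meanLET[["lungs"]])
    expect_gt(meanLET[["lungs"]], meanLET[["brainstem"]])
  }
})

test_that("phase doses are normalized to prescription / 1.1 at the target", {
  pt <- generatePatient(coarseConfig(), 0L)
  m <- organMasks(pt)
  csi <- median(voxelData(phases(pt)$csi@physicalDose)[m$ptv_csi])
  boost <- median(voxelData(phases(pt)$boost@physicalDose)[m$ptv_boost])
  expect_equal(csi * 1.1, 23.4, tolerance = 0.05)
  expect_equal(boost * 1.1, 30.6, tolerance = 0.05)
  # consistency with the fraction schedule: n_fx * d_fx / 1.1
  expect_equal(csi, 13 * 1.8 / 1.1, tolerance = 0.05)
  expect_equal(boost, 17 * 1.8 / 1.1, tolerance = 0.05)
})

test_that("jitter that would push an organ outside the grid is clamped", {
  geom <- phantomConfig()@organGeometry
  geom$thyroid$jitter <- c(500, 500, 500)
  cfg <- coarseConfig(organGeometry = geom)
  for (i in 0:4) {
    pt <- generatePatient(cfg, i)
    expect_true(any(organMasks(pt)$thyroid))
  }
})

test_that("per-voxel LET spectra integrate to dose and reproduce LETd", {
  cfg <- phantomConfig(gridShape = c(12L, 12L, 24L),
                       voxelSpacing = c(13, 13, 16), nSpectrumBins = 16L)
  pt <- generatePatient(cfg, 0L)
  for (ph in phases(pt)) {
    sp <- ph@spectrum
    expect_s4_class(sp, "LETSpectrum")
    M <- matrix(sp@masses, ncol = length(sp@binCenters))
    D <- as.vector(voxelData(ph@physicalDose))
    L <- as.vector(voxelData(ph@letd))
    expect_lt(max(abs(rowSums(M) - D) / pmax(D, 1e-300)), 1e-6)
    davg <- as.vector(M %*% sp@binCenters) / rowSums(M)
    expect_lt(max(abs(davg - L) / L), 1e-3)
  }
})

test_that("population generation validates n and returns indexed cases", {
  cfg <- coarseConfig()
  expect_error(generatePopulation(cfg, 0), "n")
  single <- generatePopulation(cfg, 1)
  expect_length(single, 1)
  expect_identical(patientId(single[[1]]), "patient_00")
})

test_that("invalid phantom configurations are rejected", {
  expect_error(phantomConfig(distalLetMax = 1.5), "distalLetMax")
  expect_error(phantomConfig(falloffWidthMm = 0), "falloffWidthMm")
  expect_error(phantomConfig(boostRegion = c(50, 110, 30, 100, 305, 500)),
               "boostRegion")
  geom <- phantomConfig()@organGeometry
  geom$heart$center <- c(5, 5, 5)  # box spills outside the grid
  expect_error(phantomConfig(organGeometry = geom), "heart")
})
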