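# Phase RBE fields and accumulation over treatment phases.

test_that("uniform phase reproduces the scalar LQ evaluation everywhere", {
  pt <- makeUniformPatient(doseTotals = c(csi = 21.27), lets = c(csi = 0),
                           nFx = c(csi = 13L))
  field <- computePhaseRBE(phases(pt)$csi, rbeModel("mcn"),
                           TissueParams("brainstem", 2.1))
  # independent closed-form arithmetic at d = 21.27/13, LET 0
  d <- 21.27 / 13; ab <- 2.1; rmax <- 0.99064; rmin <- 1.1012
  expected <- (sqrt(ab^2 + 4 * d * ab * rmax + 4 * d^2 * rmin^2) - ab) / (2 * d)
  expect_true(all(abs(voxelData(field) - expected) < 1e-12))
})

test_that("constant model gives 1.1 everywhere and scales dose exactly", {
  pt <- generatePatient(coarseConfig(), 0L)
  res <- accumulateDose(pt, rbeModel("constant_1p1"))
  for (f in rbeFields(res))
    expect_true(all(voxelData(f) == 1.1))
  # phase sums commute with the constant factor up to float rounding
  expect_equal(voxelData(totalRBEWeightedDose(res)),
               1.1 * voxelData(totalPhysicalDose(res)), tolerance = 1e-12)
  # a single-phase patient is bit-exact
  single <- makeUniformPatient(doseTotals = c(csi = 12.3),
                               lets = c(csi = 3), nFx = c(csi = 13L))
  resS <- accumulateDose(single, rbeModel("constant_1p1"),
                         tissueMap = list(organ = TissueParams("organ", 3)),
                         precedence = NULL)
  expect_identical(voxelData(totalRBEWeightedDose(resS)),
                   1.1 * voxelData(totalPhysicalDose(resS)))
})

test_that("a high-LET low-dose voxel outranks a low-LET high-dose voxel", {
  dose <- array(c(2, 40), dim = c(2, 1, 1))   # Gy over 13 fractions
  letd <- array(c(12, 1.8), dim = c(2, 1, 1))
  pt <- makeFieldPatient(dose, letd)
  field <- computePhaseRBE(phases(pt)$csi, rbeModel("mcn"),
                           TissueParams("t", 3))
  expect_gt(voxelData(field)[1], voxelData(field)[2])
  # scalar cross-check of both voxels
  for (i in 1:2) {
    d <- dose[i] / 13
    expect_equal(voxelData(field)[i],
                 lqRBE(d, 3, mcnRBEmax(letd[i], 3), mcnRBEmin(letd[i], 3)))
  }
})

test_that("two-phase accumulation matches hand-summed toy arithmetic", {
  dims <- c(2L, 1L, 1L); sp <- c(5, 5, 5)
  d1 <- array(c(10, 4), dims); l1 <- array(c(2, 6), dims)
  d2 <- array(c(20, 1), dims); l2 <- array(c(2.5, 9), dims)
  mkPhase <- function(nm, d, l, nfx)
    new("TreatmentPhase", name = nm, physicalDose = VoxelField(d, sp),
        letd = VoxelField(l, sp), spectrum = NULL, nFractions = nfx,
        fractionDoseRBE11 = 1.8)
  pt <- new("PatientCase", patientId = "toy2",
            phases = list(csi = mkPhase("csi", d1, l1, 13L),
                          boost = mkPhase("boost", d2, l2, 17L)),
            masks = list(organ = array(TRUE, dims)), spacing = sp)
  tissue <- TissueParams("organ", 3)
  res <- accumulateDose(pt, rbeModel("mcn"),
                        tissueMap = list(organ = tissue), precedence = NULL)
  hand <- vapply(1:2, function(i) {
    r1 <- lqRBE(d1[i] / 13, 3, mcnRBEmax(l1[i], 3), mcnRBEmin(l1[i], 3))
    r2 <- lqRBE(d2[i] / 17, 3, mcnRBEmax(l2[i], 3), mcnRBEmin(l2[i], 3))
    r1 * d1[i] + r2 * d2[i]
  }, 0)
  expect_equal(as.vector(voxelData(totalRBEWeightedDose(res))), hand,
               tolerance = 1e-12)
  expect_equal(as.vector(voxelData(totalPhysicalDose(res))),
               as.vector(d1 + d2))
})

test_that("physical dose scales linearly but RBE-weighted dose sublinearly", {
  pt <- generatePatient(coarseConfig(), 1L)
  res1 <- accumulateDose(pt, rbeModel("mcn"))
  k <- 1.5
  scaled <- pt
  for (nm in names(scaled@phases)) {
    f <- scaled@phases[[nm]]@physicalDose
    slot(scaled@phases[[nm]], "physicalDose", check = FALSE) <-
      VoxelField(voxelData(f) * k, voxelSpacing(f))
  }
  res2 <- accumulateDose(scaled, rbeModel("mcn"))
  expect_equal(voxelData(totalPhysicalDose(res2)),
               k * voxelData(totalPhysicalDose(res1)), tolerance = 1e-12)
  # RBE falls with dose (rbeMax > rbeMin here), so the weighted total
  # grows by less than k
  expect_true(all(voxelData(totalRBEWeightedDose(res2)) <
                    k * voxelData(totalRBEWeightedDose(res1)) + 1e-9))
})

test_that("tissue assignment is organ-local", {
  pt <- generatePatient(coarseConfig(), 2L)
  tp <- defaultTissueParams()
  base <- accumulateDose(pt, rbeModel("mcn"))
  tweaked <- tp[c("brainstem", "thyroid", "heart", "lungs")]
  tweaked$thyroid <- TissueParams("thyroid", 1.5)
  alt <- accumulateDose(pt, rbeModel("mcn"), tissueMap = tweaked)
  thy <- organMasks(pt)$thyroid
  outside <- !thy
  expect_identical(voxelData(totalRBEWeightedDose(base))[outside],
                   voxelData(totalRBEWeightedDose(alt))[outside])
  expect_false(identical(voxelData(totalRBEWeightedDose(base))[thy],
                         voxelData(totalRBEWeightedDose(alt))[thy]))
})

test_that("overlapping masks require a precedence order", {
  dims <- c(2L, 2L, 2L); sp <- c(5, 5, 5)
  ph <- new("TreatmentPhase", name = "csi",
            physicalDose = VoxelField(array(10, dims), sp),
            letd = VoxelField(array(2, dims), sp), spectrum = NULL,
            nFractions = 13L, fractionDoseRBE11 = 1.8)
  a <- array(TRUE, dims)
  b <- array(FALSE, dims); b[1, , ] <- TRUE   # overlaps a
  pt <- new("PatientCase", patientId = "ov", phases = list(csi = ph),
            masks = list(heart = a, lungs = b), spacing = sp)
  tm <- defaultTissueParams()[c("heart", "lungs")]
  expect_error(accumulateDose(pt, rbeModel("mcn"), tissueMap = tm,
                              precedence = NULL), "precedence")
  res <- accumulateDose(pt, rbeModel("mcn"), tissueMap = tm,
                        precedence = c("heart", "lungs"))
  expect_s4_class(res, "RBEWeightedResult")
  # heart wins the overlap: all voxels evaluated at heart (alpha/beta)x = 3
  uniform <- computePhaseRBE(ph, rbeModel("mcn"), TissueParams("heart", 3))
  expect_identical(voxelData(rbeFields(res)$csi), voxelData(uniform))
})

test_that("corrupt (negative) dose input is rejected loudly", {
  pt <- makeUniformPatient(doseTotals = c(csi = 10), lets = c(csi = 2),
                           nFx = c(csi = 13L))
  bad <- phases(pt)$csi
  d <- voxelData(bad@physicalDose); d[1] <- -0.5
  slot(bad, "physicalDose", check = FALSE) <-
    VoxelField(d, voxelSpacing(bad@physicalDose))
  expect_error(computePhaseRBE(bad, rbeModel("mcn"), TissueParams("t", 3)),
               "negative")
  # a tissue whose mask is missing is a precondition failure
  expect_error(accumulateDose(pt, rbeModel("mcn"),
                              tissueMap = list(spleen = TissueParams("spleen", 3))),
               "spleen")
})
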