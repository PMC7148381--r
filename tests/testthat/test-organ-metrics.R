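# DVH/LVH machinery and scalar organ metrics.

test_that("cumulative DVH is an exact counting curve", {
  dims <- c(4L, 4L, 4L); sp <- c(2, 2, 2)
  mask <- array(TRUE, dims)
  # uniform field: full volume up to the value, zero above
  u <- VoxelField(array(7, dims), sp)
  dvh <- cumulativeDVH(u, mask, nBins = 15)
  expect_true(all(dvh$volume_fraction[dvh$axis <= 7] == 1))
  expect_identical(dvh$volume_fraction[1], 1)
  # two-voxel counting example
  two <- VoxelField(array(c(1, 3), c(2L, 1L, 1L)), sp)
  m2 <- array(TRUE, c(2L, 1L, 1L))
  vf2 <- cumulativeDVH(two, m2, nBins = 7)  # axis includes 2 Gy
  expect_equal(vf2$volume_fraction[vf2$axis == 2], 0.5)
  # random field vs brute-force re-count at every axis point
  set.seed(21)
  v <- array(rexp(1000), c(10L, 10L, 10L))
  f <- VoxelField(v, sp)
  m <- array(TRUE, dim(v))
  dvh <- cumulativeDVH(f, m, nBins = 64)
  recount <- vapply(dvh$axis, function(t) sum(v >= t) / length(v), 0)
  expect_identical(dvh$volume_fraction, recount)
  expect_true(all(diff(dvh$volume_fraction) <= 0))
  expect_error(cumulativeDVH(f, array(FALSE, dim(v)), organ = "heart"),
               "heart")
})

test_that("dose-at-volume follows the descending-sort counting convention", {
  expect_equal(doseAtVolume(as.numeric(1:100), volumePct = 2), 99)
  expect_equal(doseAtVolume(as.numeric(1:100), volumePct = 50), 51)
  # uniform values give the value at any volume
  expect_equal(doseAtVolume(rep(3.2, 57), volumePct = 37), 3.2)
  # D2% >= D50% on arbitrary inputs
  set.seed(5)
  for (i in 1:20) {
    v <- rgamma(200, shape = runif(1, 0.5, 4))
    expect_gte(doseAtVolume(v, volumePct = 2), doseAtVolume(v, volumePct = 50))
    expect_equal(doseAtVolume(v, volumePct = 2), bruteDoseAtVolume(v, 2))
  }
  expect_error(doseAtVolume(1:10, volumePct = 0), "volumePct")
  expect_error(doseAtVolume(1:10, volumePct = 100), "volumePct")
})

test_that("organ-mean LET is a plain mean with an optional dose threshold", {
  dims <- c(2L, 1L, 1L); sp <- c(5, 5, 5)
  f <- VoxelField(array(c(1.8, 2.2), dims), sp)
  m <- array(TRUE, dims)
  expect_equal(organMeanLET(f, m), 2)
  # threshold drops the low-dose voxel (0.3 Gy * 1.1 < 0.5 Gy(RBE))
  dose <- VoxelField(array(c(0.3, 10), dims), sp)
  expect_equal(organMeanLET(f, m, dose, doseThreshold = 0.5), 2.2)
  expect_error(organMeanLET(f, m, doseThreshold = 0.5), "doseField")
  set.seed(31)
  v <- array(runif(512, 0, 15), c(8L, 8L, 8L))
  fm <- array(runif(512) > 0.5, c(8L, 8L, 8L))
  expect_equal(organMeanLET(VoxelField(v, sp), fm), mean(v[fm]))
})

test_that("dose-weighted organ RBE matches hand arithmetic and its identity", {
  dims <- c(3L, 1L, 1L); sp <- c(5, 5, 5)
  mkRes <- function(dose, rbe) {
    new("RBEWeightedResult",
        rbeFieldPerPhase = list(csi = VoxelField(array(rbe, dims), sp)),
        totalPhysicalDose = VoxelField(array(dose, dims), sp),
        totalRBEWeightedDose = VoxelField(array(dose * rbe, dims), sp),
        modelId = "mcn", tissueMap = list())
  }
  m <- array(TRUE, dims)
  # {1,2,3} Gy with RBE {1.5,1.2,1.1}: (1.5 + 2.4 + 3.3)/6 = 1.2
  expect_equal(rbeD(mkRes(c(1, 2, 3), c(1.5, 1.2, 1.1)), m), 1.2)
  # spatially uniform RBE r is recovered exactly, any dose distribution
  expect_equal(rbeD(mkRes(c(0.2, 5, 40), rep(1.37, 3)), m), 1.37)
  expect_equal(rbeD2pct(mkRes(c(0.2, 5, 40), rep(1.37, 3)), m), 1.37)
  # Eq-1 identity and bounds on random organs
  set.seed(41)
  for (i in 1:25) {
    n <- 64L
    dose <- runif(n, 0.01, 50); rbe <- runif(n, 1, 2)
    res <- mkRes2 <- new("RBEWeightedResult",
        rbeFieldPerPhase = list(),
        totalPhysicalDose = VoxelField(array(dose, c(n, 1L, 1L)), sp),
        totalRBEWeightedDose = VoxelField(array(dose * rbe, c(n, 1L, 1L)), sp),
        modelId = "mcn", tissueMap = list())
    mk <- array(TRUE, c(n, 1L, 1L))
    # dose-weighted voxel mean == ratio of means
    expect_equal(rbeD(res, mk), sum(rbe * dose) / sum(dose),
                 tolerance = 1e-12)
    expect_gte(rbeD(res, mk), min(rbe))
    expect_lte(rbeD(res, mk), max(rbe))
    # invariant under uniform physical rescaling at fixed RBE field
    res2 <- new("RBEWeightedResult", rbeFieldPerPhase = list(),
        totalPhysicalDose = VoxelField(array(3 * dose, c(n, 1L, 1L)), sp),
        totalRBEWeightedDose = VoxelField(array(3 * dose * rbe, c(n, 1L, 1L)), sp),
        modelId = "mcn", tissueMap = list())
    expect_equal(rbeD(res2, mk), rbeD(res, mk), tolerance = 1e-12)
  }
  # zero organ dose is undefined, not zero
  expect_error(rbeD(mkRes(rep(0, 3), rep(1.2, 3)), m), "undefined")
})

test_that("heart-like anticorrelated dose/LET gives RBE_D2% below mean RBE", {
  # high LET where dose is low: the near-maximum (high-dose) voxels carry
  # low LET and higher per-fraction dose, both depressing their RBE
  n <- 400L
  dose <- seq(8, 0.05, length.out = n)
  letd <- seq(1.5, 14, length.out = n)
  pt <- makeFieldPatient(array(dose, c(n, 1L, 1L)), array(letd, c(n, 1L, 1L)))
  res <- accumulateDose(pt, rbeModel("mcn"),
                        tissueMap = list(organ = TissueParams("heart", 3)),
                        precedence = NULL)
  m <- organMasks(pt)$organ
  expect_lt(rbeD2pct(res, m), rbeD(res, m))
})

test_that("constant model yields rbe_d = rbe_d2pct = 1.1 exactly", {
  pt <- generatePatient(coarseConfig(), 0L)
  res <- accumulateDose(pt, rbeModel("constant_1p1"))
  for (o in c("brainstem", "thyroid", "heart", "lungs")) {
    m <- organMasks(pt)[[o]]
    expect_equal(rbeD(res, m, o), 1.1, tolerance = 1e-12)
    expect_equal(rbeD2pct(res, m, organ = o), 1.1, tolerance = 1e-12)
  }
})

test_that("metrics table recomputes from its own stored fields", {
  pt <- generatePatient(coarseConfig(), 4L)
  res <- accumulateDose(pt, rbeModel("mcn"))
  met <- organMetrics(pt, res)
  expect_setequal(met$organ, c("brainstem", "thyroid", "heart", "lungs"))
  # rbe_d is the ratio of the stored mean doses, to numerical identity
  expect_equal(met$rbe_d, met$mean_dose / met$mean_phys_dose,
               tolerance = 1e-12)
  expect_true(all(met$d2 >= met$d50))
  expect_equal(met$alpha_beta[met$organ == "brainstem"], 2.1)
  expect_equal(met$alpha_beta[met$organ == "lungs"], 4.0)
})
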