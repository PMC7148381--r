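# Synthetic cranio-spinal irradiation phantom.
#
# The real treatment uses two posterior spinal fields plus lateral cranial
# and boost fields; the phantom collapses these to an analytic depth-dose /
# depth-LET curve applied along the anterior (y) axis for the spinal field
# and uniform dose baths for the cranial and boost fields. The analysis
# downstream needs realistic organ dose/LET statistics, not transport
# physics. Axes: x lateral, y posterior->anterior (beam direction),
# z caudal->cranial. Voxel centres at (index - 0.5) * spacing mm.

.CSI_FRACTIONS <- 13L     # 23.4 Gy(RBE) / 1.8 Gy(RBE) per fraction
.BOOST_FRACTIONS <- 17L   # (54 - 23.4) Gy(RBE) / 1.8 Gy(RBE) per fraction
.FRACTION_DOSE_RBE11 <- 1.8
.CLINICAL_RBE <- 1.1

#' Configuration of the synthetic CSI phantom generator
#'
#' Defaults emulate a paediatric cranio-spinal irradiation course: a
#' cranio-spinal phase prescribed 23.4 Gy(RBE1.1) in 1.8 Gy(RBE) fractions
#' (13 fractions) plus a posterior-fossa boost of 30.6 Gy(RBE1.1)
#' (17 fractions), on a 64 x 64 x 160 grid of 2.5 mm voxels
#' (160 x 160 x 400 mm). Organ boxes are jittered per patient so that the
#' cohort spans the characteristic dose/LET regimes: brainstem inside the
#' boost (high dose, low LET), thyroid straddling the spinal distal falloff
#' (highly variable dose, intermediate LET), lungs intermediate, heart
#' distal to the falloff (low dose, high LET).
#'
#' @param gridShape integer(3), voxels per axis.
#' @param voxelSpacing numeric(3), mm per axis.
#' @param spineRangeMm depth (mm along y) of the spinal-field distal edge.
#' @param boostRegion numeric(6) mm box \code{c(xmin, xmax, ymin, ymax,
#'   zmin, zmax)} defining the posterior fossa boost volume.
#' @param organGeometry named list; per organ a list with \code{center} and
#'   \code{size} (mm, nominal box) and \code{jitter} (mm, per-axis uniform
#'   half-width of the per-patient placement jitter). The \code{lungs} entry
#'   may carry \code{gapHalfWidth} (mm) excluded around the midline to form
#'   two lobes.
#' @param plateauLet entrance/plateau dose-averaged LET, keV/um.
#' @param distalLetMax maximum distal dose-averaged LET, keV/um
#'   (must exceed \code{plateauLet}).
#' @param falloffWidthMm distance over which the depth dose drops from 80\%
#'   to 20\% of plateau.
#' @param nSpectrumBins LET-spectrum bins per voxel; 0 disables spectra.
#' @param seed integer root seed; patient i uses stream \code{seed + i}.
#' @param boostLet dose-averaged LET of the boost bath, keV/um.
#' @param craniumZMm z coordinate (mm) above which lies the cranium.
#' @param noiseSd sd of the multiplicative log-normal voxel noise on dose.
#' @return A \linkS4class{PhantomConfig}.
#' @examples
#' cfg <- phantomConfig(gridShape = c(32L, 32L, 80L), voxelSpacing = c(5, 5, 5))
#' @export
phantomConfig <- function(gridShape = c(64L, 64L, 160L),
                          voxelSpacing = c(2.5, 2.5, 2.5),
                          spineRangeMm = 80,
                          boostRegion = c(50, 110, 30, 100, 305, 360),
                          organGeometry = list(
                            brainstem = list(center = c(80, 70, 330),
                                             size = c(16, 16, 30),
                                             jitter = c(2, 2, 2)),
                            thyroid = list(center = c(80, 80, 260),
                                           size = c(24, 16, 16),
                                           jitter = c(3, 10, 3)),
                            heart = list(center = c(80, 110, 180),
                                         size = c(50, 40, 50),
                                         jitter = c(4, 6, 4)),
                            lungs = list(center = c(80, 78, 200),
                                         size = c(100, 44, 80),
                                         jitter = c(3, 3, 3),
                                         gapHalfWidth = 12)
                          ),
                          plateauLet = 1.8,
                          distalLetMax = 15,
                          falloffWidthMm = 10,
                          nSpectrumBins = 0L,
                          seed = 1L,
                          boostLet = 2.2,
                          craniumZMm = 300,
                          noiseSd = 0.015) {
  new("PhantomConfig",
      gridShape = as.integer(gridShape), voxelSpacing = as.numeric(voxelSpacing),
      spineRangeMm = as.numeric(spineRangeMm), boostRegion = as.numeric(boostRegion),
      organGeometry = organGeometry, plateauLet = as.numeric(plateauLet),
      distalLetMax = as.numeric(distalLetMax),
      falloffWidthMm = as.numeric(falloffWidthMm),
      nSpectrumBins = as.integer(nSpectrumBins), seed = as.integer(seed),
      boostLet = as.numeric(boostLet), craniumZMm = as.numeric(craniumZMm),
      noiseSd = as.numeric(noiseSd))
}

#' Analytic depth-dose curve of the collapsed spinal field
#'
#' A Bragg-curve stand-in: a plateau normalized to ~1, a modest peak just
#' proximal of the range, and a logistic distal falloff dropping from 80\%
#' to 20\% over \code{falloffWidthMm}, below 1\% beyond
#' \code{rangeMm + 2 * falloffWidthMm}. Unimodal by construction.
#'
#' @param depth depth along the beam axis, mm, >= 0. Vectorized.
#' @param rangeMm distal-edge range, mm, > 0.
#' @param falloffWidthMm 80\%-20\% falloff distance, mm, > 0.
#' @return Dimensionless per-fraction dose scale factor.
#' @examples
#' beamDepthDose(c(0, 70, 100), rangeMm = 80, falloffWidthMm = 10)
#' @export
beamDepthDose <- function(depth, rangeMm, falloffWidthMm) {
  if (any(depth < 0)) stop("'depth' must be >= 0 (mm)")
  if (length(rangeMm) != 1L || !is.finite(rangeMm) || rangeMm <= 0)
    stop("'rangeMm' must be a single positive number (mm)")
  if (length(falloffWidthMm) != 1L || falloffWidthMm <= 0)
    stop("'falloffWidthMm' must be a single positive number (mm)")
  w <- falloffWidthMm / (2 * log(4))  # logistic scale for 80->20% over the width
  fall <- 1 / (1 + exp((depth - rangeMm) / w))
  peak <- 1 + 0.15 * exp(-(depth - (rangeMm - falloffWidthMm))^2 /
                           (2 * falloffWidthMm^2))
  fall * peak
}

#' Analytic depth-LET curve of the collapsed spinal field
#'
#' Dose-averaged LET rises monotonically along the beam direction from the
#' plateau value towards \code{distalLetMax}, with the steep rise centred
#' just beyond the range (the high-LET region sits in the distal falloff,
#' where low-energy protons stop).
#'
#' @inheritParams beamDepthDose
#' @param plateauLet entrance LET, keV/um, > 0.
#' @param distalLetMax distal maximum LET, keV/um, > \code{plateauLet}.
#' @return Dose-averaged LET in keV/um.
#' @examples
#' beamDepthLET(c(0, 80, 120), 80, plateauLet = 1.8, distalLetMax = 15)
#' @export
beamDepthLET <- function(depth, rangeMm, plateauLet, distalLetMax,
                         falloffWidthMm = 10) {
  if (any(depth < 0)) stop("'depth' must be >= 0 (mm)")
  if (length(rangeMm) != 1L || !is.finite(rangeMm) || rangeMm <= 0)
    stop("'rangeMm' must be a single positive number (mm)")
  if (distalLetMax <= plateauLet || plateauLet <= 0)
    stop("'distalLetMax' must exceed 'plateauLet' and both must be positive")
  w <- falloffWidthMm / 2
  s <- 1 / (1 + exp(-(depth - (rangeMm + w)) / w))
  plateauLet + (distalLetMax - plateauLet) * s
}

# run expr under a private RNG stream, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# smooth lateral field profile: logistic edges of scale pw around +-hw of cx
.lateralProfile <- function(x, cx, hw = 45, pw = 3) {
  1 / (1 + exp(-(x - (cx - hw)) / pw)) / (1 + exp(-((cx + hw) - x) / pw))
}

# logical 3D box mask from per-axis logical vectors
.boxMask <- function(xl, yl, zl) outer(outer(xl, yl, `&`), zl, `&`)

# soft 3D box: product of logistic edge factors, edge scale `soft` mm
.softBox <- function(xc, yc, zc, box, soft = 2) {
  edge <- function(v, lo, hi)
    1 / (1 + exp(-(v - lo) / soft)) / (1 + exp(-(hi - v) / soft))
  outer(outer(edge(xc, box[1], box[2]), edge(yc, box[3], box[4])),
        edge(zc, box[5], box[6]))
}

# two-component binned LET spectrum (narrow primary peak + scattered
# high-LET tail), assigned to the bin grid by moment-preserving linear
# interpolation so each voxel's dose-weighted spectrum mean reproduces its
# stored LETd and its mass integrates to its physical dose.
.buildSpectrum <- function(dose, letd, nBins, maxLet) {
  if (nBins < 4L) stop("'nSpectrumBins' must be 0 (disabled) or >= 4")
  centers <- seq(0, maxLet, length.out = nBins)
  dims <- dim(dose)
  D <- as.vector(dose); L <- as.vector(letd)
  w1 <- 0.9
  L2 <- pmin(3 * L, centers[nBins])          # scattered tail component
  L1 <- (L - (1 - w1) * L2) / w1             # primary component keeps the mean
  M <- matrix(0, nrow = length(D), ncol = nBins)
  addMass <- function(M, l, m) {
    idx <- pmin(pmax(findInterval(l, centers), 1L), nBins - 1L)
    frac <- pmin(pmax((l - centers[idx]) / (centers[idx + 1L] - centers[idx]),
                      0), 1)
    v <- seq_along(l)
    M[cbind(v, idx)] <- M[cbind(v, idx)] + m * (1 - frac)
    M[cbind(v, idx + 1L)] <- M[cbind(v, idx + 1L)] + m * frac
    M
  }
  M <- addMass(M, L1, w1 * D)
  M <- addMass(M, L2, (1 - w1) * D)
  new("LETSpectrum", binCenters = centers,
      masses = array(M, dim = c(dims, nBins)))
}

#' Generate one synthetic CSI patient
#'
#' Deterministic for fixed (config seed, patient index): patient i draws
#' from the stream \code{seed + i}, so any patient can be regenerated
#' without the rest of the cohort. Each patient gets a per-patient range
#' jitter, uniform per-organ placement jitter (clamped so organ boxes stay
#' inside the grid, never silently empty), and multiplicative log-normal
#' voxel noise. Both phases are normalized so the target-region median
#' physical dose equals prescription / 1.1 exactly.
#'
#' Masks produced: the four organs at risk plus \code{ptv_csi} (spinal +
#' cranial target) and \code{ptv_boost} (posterior fossa).
#'
#' @param config a \linkS4class{PhantomConfig}.
#' @param patientIndex 0-based patient index.
#' @return A \linkS4class{PatientCase} with \code{csi} and \code{boost}
#'   phases.
#' @examples
#' cfg <- phantomConfig(gridShape = c(32L, 32L, 80L), voxelSpacing = c(5, 5, 5))
#' pt <- generatePatient(cfg, 0L)
#' @export
generatePatient <- function(config, patientIndex) {
  stopifnot(is(config, "PhantomConfig"))
  validObject(config)
  if (length(patientIndex) != 1L || patientIndex < 0)
    stop("'patientIndex' must be a single non-negative integer")
  patientIndex <- as.integer(patientIndex)

  dims <- config@gridShape; sp <- config@voxelSpacing
  extent <- dims * sp
  xc <- (seq_len(dims[1]) - 0.5) * sp[1]
  yc <- (seq_len(dims[2]) - 0.5) * sp[2]
  zc <- (seq_len(dims[3]) - 0.5) * sp[3]
  nvox <- prod(dims)
  cranial <- zc >= config@craniumZMm

  withSeed(config@seed + patientIndex, {
    rangeJitter <- runif(1, -3, 3)
    jitters <- lapply(config@organGeometry, function(g)
      runif(3, -1, 1) * g$jitter)
    noise <- replicate(4, exp(rnorm(nvox, 0, config@noiseSd)),
                       simplify = FALSE)

    range_i <- config@spineRangeMm + rangeJitter

    # ---- CSI phase: spinal depth-dose field + cranial bath --------------
    lat <- .lateralProfile(xc, cx = extent[1] / 2)
    profY <- beamDepthDose(yc, range_i, config@falloffWidthMm)
    letY <- beamDepthLET(yc, range_i, config@plateauLet, config@distalLetMax,
                         config@falloffWidthMm)
    spinalDose <- outer(lat, profY)                      # nx x ny
    spinalLet <- matrix(letY, nrow = dims[1], ncol = dims[2], byrow = TRUE)
    csiDose <- array(spinalDose, dim = dims)
    csiLet <- array(spinalLet, dim = dims)
    csiDose[, , cranial] <- 1
    csiLet[, , cranial] <- config@plateauLet
    csiDose <- csiDose * array(noise[[1]], dims)
    csiLet <- csiLet * array(exp(log(noise[[2]]) * 0.5), dims)

    # ---- boost phase: soft posterior-fossa bath -------------------------
    boostDose <- .softBox(xc, yc, zc, config@boostRegion) *
      array(noise[[3]], dims)
    boostLet <- array(config@boostLet, dims) *
      array(exp(log(noise[[4]]) * 0.5), dims)

    # ---- target masks and dose normalization ----------------------------
    spineHW <- 20
    ptvSpinal <- .boxMask(abs(xc - extent[1] / 2) <= spineHW,
                          yc >= range_i - 25 & yc <= range_i - 2,
                          !cranial)
    ptvCsi <- ptvSpinal |
      .boxMask(rep(TRUE, dims[1]), rep(TRUE, dims[2]), cranial)
    br <- config@boostRegion
    ptvBoost <- .boxMask(xc >= br[1] & xc <= br[2],
                         yc >= br[3] & yc <= br[4],
                         zc >= br[5] & zc <= br[6])

    csiRx <- .CSI_FRACTIONS * .FRACTION_DOSE_RBE11        # 23.4 Gy(RBE1.1)
    boostRx <- .BOOST_FRACTIONS * .FRACTION_DOSE_RBE11    # 30.6 Gy(RBE1.1)
    csiDose <- csiDose * (csiRx / .CLINICAL_RBE) / median(csiDose[ptvCsi])
    # normalize the boost on the box core (eroded past the soft penumbra)
    boostCore <- .boxMask(xc >= br[1] + 6 & xc <= br[2] - 6,
                          yc >= br[3] + 6 & yc <= br[4] - 6,
                          zc >= br[5] + 6 & zc <= br[6] - 6)
    boostDose <- boostDose * (boostRx / .CLINICAL_RBE) /
      median(boostDose[boostCore])

    # ---- organ masks (jittered, clamped inside the grid) ----------------
    masks <- list()
    for (nm in names(config@organGeometry)) {
      g <- config@organGeometry[[nm]]
      ctr <- g$center + jitters[[nm]]
      ctr <- pmin(pmax(ctr, g$size / 2), extent - g$size / 2)
      m <- .boxMask(abs(xc - ctr[1]) <= g$size[1] / 2,
                    abs(yc - ctr[2]) <= g$size[2] / 2,
                    abs(zc - ctr[3]) <= g$size[3] / 2)
      if (!is.null(g$gapHalfWidth))
        m <- m & .boxMask(abs(xc - ctr[1]) >= g$gapHalfWidth,
                          rep(TRUE, dims[2]), rep(TRUE, dims[3]))
      masks[[nm]] <- m
    }
    masks$ptv_csi <- ptvCsi
    masks$ptv_boost <- ptvBoost

    csiSpectrum <- boostSpectrum <- NULL
    if (config@nSpectrumBins > 0L) {
      maxLet <- 3 * config@distalLetMax
      csiSpectrum <- .buildSpectrum(csiDose, csiLet,
                                    config@nSpectrumBins, maxLet)
      boostSpectrum <- .buildSpectrum(boostDose, boostLet,
                                      config@nSpectrumBins, maxLet)
    }

    csi <- new("TreatmentPhase", name = "csi",
               physicalDose = VoxelField(csiDose, sp),
               letd = VoxelField(csiLet, sp), spectrum = csiSpectrum,
               nFractions = .CSI_FRACTIONS,
               fractionDoseRBE11 = .FRACTION_DOSE_RBE11)
    boost <- new("TreatmentPhase", name = "boost",
                 physicalDose = VoxelField(boostDose, sp),
                 letd = VoxelField(boostLet, sp), spectrum = boostSpectrum,
                 nFractions = .BOOST_FRACTIONS,
                 fractionDoseRBE11 = .FRACTION_DOSE_RBE11)
    new("PatientCase", patientId = sprintf("patient_%02d", patientIndex),
        phases = list(csi = csi, boost = boost), masks = masks, spacing = sp)
  })
}

#' Generate a synthetic CSI patient cohort
#'
#' @param config a \linkS4class{PhantomConfig}.
#' @param n number of patients, >= 1; indices 0..n-1.
#' @return List of \linkS4class{PatientCase} objects.
#' @examples
#' cfg <- phantomConfig(gridShape = c(32L, 32L, 80L), voxelSpacing = c(5, 5, 5))
#' cohort <- generatePopulation(cfg, 2)
#' @export
generatePopulation <- function(config, n) {
  if (length(n) != 1L || n < 1) stop("'n' must be a single integer >= 1")
  lapply(seq_len(n) - 1L, function(i) generatePatient(config, i))
}
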