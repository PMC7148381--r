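# Shared fixtures: hand-built toy patients, a coarse phantom configuration,
# and independent numerical oracles (voxel loops, root solves) kept separate
# from the implementation paths they check.

coarseConfig <- function(...) {
  phantomConfig(gridShape = c(32L, 32L, 80L), voxelSpacing = c(5, 5, 5), ...)
}

# a patient with spatially uniform dose/LET per phase, for scalar oracles
makeUniformPatient <- function(doseTotals = c(csi = 21.27, boost = 27.82),
                               lets = c(csi = 2, boost = 2.2),
                               dims = c(4L, 4L, 4L), spacing = c(5, 5, 5),
                               nFx = c(csi = 13L, boost = 17L)) {
  mask <- array(TRUE, dims)
  phs <- lapply(names(doseTotals), function(nm) {
    new("TreatmentPhase", name = nm,
        physicalDose = VoxelField(array(doseTotals[[nm]], dims), spacing),
        letd = VoxelField(array(lets[[nm]], dims), spacing),
        spectrum = NULL, nFractions = nFx[[nm]], fractionDoseRBE11 = 1.8)
  })
  names(phs) <- names(doseTotals)
  new("PatientCase", patientId = "toy", phases = phs,
      masks = list(organ = mask), spacing = spacing)
}

# a patient with arbitrary per-voxel dose/LET arrays (single or dual phase)
makeFieldPatient <- function(dose, letd, spacing = c(5, 5, 5),
                             nFx = 13L, masks = NULL) {
  dims <- dim(dose)
  if (is.null(masks)) masks <- list(organ = array(TRUE, dims))
  ph <- new("TreatmentPhase", name = "csi",
            physicalDose = VoxelField(dose, spacing),
            letd = VoxelField(letd, spacing),
            spectrum = NULL, nFractions = nFx, fractionDoseRBE11 = 1.8)
  new("PatientCase", patientId = "field", phases = list(csi = ph),
      masks = masks, spacing = spacing)
}

# independent LQ oracle: numeric root-solve of the effect-matching equation
# alpha_x D + beta_x D^2 = alpha_p d + beta_p d^2, RBE = D / d, with
# alpha_p = rmax alpha_x and beta_p = rmin^2 beta_x (scale of beta_x cancels)
lqNumericOracle <- function(d, ab, rmax, rmin, betaX = 0.05) {
  alphaX <- ab * betaX
  effect <- rmax * alphaX * d + rmin^2 * betaX * d^2
  f <- function(D) alphaX * D + betaX * D^2 - effect
  upper <- max(10, 10 * d * max(abs(rmax), abs(rmin), 1))
  uniroot(f, c(0, upper), tol = 1e-14)$root / d
}

# independent D_x%: explicit descending sort and count
bruteDoseAtVolume <- function(v, pct) {
  s <- sort(v, decreasing = TRUE)
  s[ceiling(pct / 100 * length(s))]
}

totalPhysDose <- function(patient)
  Reduce(`+`, lapply(phases(patient), function(p) voxelData(p@physicalDose)))
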