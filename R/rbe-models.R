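#' Load an RBE model from the versioned coefficient file
#'
#' Model coefficients live in a versioned JSON file shipped with the package
#' (\code{inst/extdata/rbe_coefficients.json}) rather than in code, so that a
#' coefficient revision is visible as a data change. Three models are known:
#' \describe{
#'   \item{\code{constant_1p1}}{the clinical constant RBE of 1.1; ignores
#'     LET, dose and tissue inputs entirely.}
#'   \item{\code{mcn}}{the McNamara phenomenological model: RBEmax affine
#'     increasing in dose-averaged LET with slope inversely proportional to
#'     (alpha/beta)x, RBEmin affine decreasing in LET, combined through the
#'     linear-quadratic closed form (\code{\link{lqRBE}}).}
#'   \item{\code{ror}}{a spectrum-based model: a nonlinear per-LET response
#'     averaged dose-weighted over the voxel's LET spectrum gives RBEmax,
#'     and RBEmin is fixed at exactly 1. The default response coefficients
#'     are synthetic (the published ones are not redistributed); the
#'     structural properties of the model class are preserved.}
#' }
#'
#' @param id one of \code{"constant_1p1"}, \code{"mcn"}, \code{"ror"}.
#' @param coefficientFile path to a coefficient JSON file; defaults to the
#'   file shipped with the package.
#' @return An \linkS4class{RBEModel}.
#' @examples
#' mcn <- rbeModel("mcn")
#' mcnRBEmax(2.2, 2.1, mcn)
#' @export
rbeModel <- function(id = c("constant_1p1", "mcn", "ror"),
                     coefficientFile = NULL) {
  id <- match.arg(id)
  if (is.null(coefficientFile))
    coefficientFile <- system.file("extdata", "rbe_coefficients.json",
                                   package = "protonRBE", mustWork = TRUE)
  spec <- jsonlite::read_json(coefficientFile, simplifyVector = TRUE)
  if (!id %in% names(spec$models))
    stop(sprintf("model '%s' not found in coefficient file", id))
  new("RBEModel",
      modelId = id,
      coefficients = unlist(spec$models[[id]]$parameters),
      requiresSpectrum = identical(id, "ror"),
      version = as.character(spec$version))
}

.coef <- function(model, name) {
  v <- model@coefficients[[name]]
  if (is.null(v)) stop(sprintf("model '%s' lacks coefficient '%s'",
                               model@modelId, name))
  v
}

.checkLetAlphaBeta <- function(letD, alphaBetaX) {
  if (any(letD < 0)) stop("'letD' must be >= 0 (keV/um)")
  if (any(alphaBetaX <= 0)) stop("'alphaBetaX' must be > 0 (Gy)")
  invisible(TRUE)
}

#' McNamara RBEmax and RBEmin
#'
#' \code{mcnRBEmax} is the asymptotic RBE in the zero-dose limit:
#' \code{p0 + p1 * LETd / (alpha/beta)x}, affine increasing in LET with a
#' slope inversely proportional to the tissue's (alpha/beta)x.
#' \code{mcnRBEmin}, the infinite-dose limit, is
#' \code{p2 - p3 * sqrt((alpha/beta)x) * LETd}, affine decreasing in LET.
#' Both are vectorized over \code{letD} and \code{alphaBetaX}.
#'
#' @param letD dose-averaged LET in keV/um, >= 0.
#' @param alphaBetaX tissue (alpha/beta)x in Gy, > 0.
#' @param model an \linkS4class{RBEModel} of id \code{"mcn"} (defaults to the
#'   shipped coefficients).
#' @return Dimensionless RBEmax / RBEmin values.
#' @export
mcnRBEmax <- function(letD, alphaBetaX, model = rbeModel("mcn")) {
  .checkLetAlphaBeta(letD, alphaBetaX)
  .coef(model, "p0") + .coef(model, "p1") * letD / alphaBetaX
}

#' @rdname mcnRBEmax
#' @export
mcnRBEmin <- function(letD, alphaBetaX, model = rbeModel("mcn")) {
  .checkLetAlphaBeta(letD, alphaBetaX)
  .coef(model, "p2") - .coef(model, "p3") * sqrt(alphaBetaX) * letD
}

#' Linear-quadratic RBE at a given fraction dose
#'
#' Solves the LQ effect-matching equation for the photon dose producing the
#' same effect as the proton fraction dose, giving
#' \deqn{RBE(d) = \frac{1}{2d}\left(\sqrt{(\alpha/\beta)_x^2 +
#'   4 d (\alpha/\beta)_x\, RBE_{max} + 4 d^2 RBE_{min}^2} -
#'   (\alpha/\beta)_x\right).}
#' The function is continuous with limits \code{rbeMax} as d -> 0 and
#' \code{rbeMin} as d -> Inf; \code{dPhys = 0} returns \code{rbeMax} by the
#' analytic limit (no division by zero). \code{rbeMax >= rbeMin} is not
#' required. Vectorized over all arguments.
#'
#' @param dPhys physical dose per fraction in Gy, >= 0.
#' @param alphaBetaX tissue (alpha/beta)x in Gy, > 0.
#' @param rbeMax,rbeMin asymptotic RBE values (dimensionless).
#' @return Dimensionless RBE.
#' @examples
#' lqRBE(1.8 / 1.1, 2.1, mcnRBEmax(2.2, 2.1), mcnRBEmin(2.2, 2.1))
#' @export
lqRBE <- function(dPhys, alphaBetaX, rbeMax, rbeMin) {
  if (any(dPhys < 0)) stop("'dPhys' must be >= 0 (Gy)")
  if (any(alphaBetaX <= 0)) stop("'alphaBetaX' must be > 0 (Gy)")
  n <- max(length(dPhys), length(alphaBetaX), length(rbeMax), length(rbeMin))
  dPhys <- rep_len(dPhys, n); alphaBetaX <- rep_len(alphaBetaX, n)
  rbeMax <- rep_len(rbeMax, n); rbeMin <- rep_len(rbeMin, n)
  out <- rbeMax  # d = 0 voxels take the zero-dose limit
  # rbeMax == rbeMin collapses analytically to that value at every dose;
  # taking the shortcut keeps the identity exact in floating point
  pos <- dPhys > 0 & rbeMax != rbeMin
  if (any(pos)) {
    d <- dPhys[pos]; ab <- alphaBetaX[pos]
    disc <- ab^2 + 4 * d * ab * rbeMax[pos] + 4 * d^2 * rbeMin[pos]^2
    out[pos] <- (sqrt(disc) - ab) / (2 * d)
  }
  out
}

#' Spectrum-averaged nonlinear RBEmax
#'
#' Evaluates a per-LET response function r(L) dose-weighted over a binned
#' LET spectrum: \code{sum(w_i r(L_i)) / sum(w_i)} with \code{w_i} the dose
#' mass in bin i. For a degenerate single-bin spectrum this equals
#' \code{r(LETd)} exactly, and for a linear response it reduces to the
#' linear model evaluated at the dose-averaged LET.
#'
#' The default response is a saturating exponential,
#' \code{r(L) = r0 + (slope/(alpha/beta)x) * let_scale * (1 - exp(-L/let_scale))},
#' nonlinear (concave) in LET with initial slope \code{slope/(alpha/beta)x}.
#' A custom response can be supplied via \code{responseFn(L, alphaBetaX)}.
#'
#' @param binCenters LET bin centres in keV/um.
#' @param masses non-negative dose masses per bin; either a vector (one
#'   spectrum) or a matrix with one row per voxel and one column per bin.
#' @param alphaBetaX tissue (alpha/beta)x in Gy.
#' @param model an \linkS4class{RBEModel} of id \code{"ror"}.
#' @param responseFn optional function \code{(L, alphaBetaX) -> r}.
#' @return Dimensionless RBEmax; one value per spectrum (row).
#' @export
rorRBEmax <- function(binCenters, masses, alphaBetaX,
                      model = rbeModel("ror"), responseFn = NULL) {
  if (any(alphaBetaX <= 0)) stop("'alphaBetaX' must be > 0 (Gy)")
  if (is.null(responseFn)) responseFn <- function(L, ab) rorResponse(L, ab, model)
  if (is.matrix(masses)) {
    if (ncol(masses) != length(binCenters))
      stop("spectrum columns must match bin centres")
    if (any(masses < 0)) stop("spectrum bin masses must be >= 0")
    tot <- rowSums(masses)
    if (any(tot <= 0))
      stop("undefined RBE: spectrum with zero total dose mass")
    ab <- rep_len(alphaBetaX, nrow(masses))
    # response depends on alphaBetaX, so evaluate per distinct tissue value
    out <- numeric(nrow(masses))
    for (a in unique(ab)) {
      idx <- ab == a
      out[idx] <- (masses[idx, , drop = FALSE] %*% responseFn(binCenters, a)) /
        tot[idx]
    }
    out
  } else {
    if (length(masses) != length(binCenters))
      stop("spectrum length must match bin centres")
    if (any(masses < 0)) stop("spectrum bin masses must be >= 0")
    if (sum(masses) <= 0)
      stop("undefined RBE: spectrum with zero total dose mass")
    sum(masses * responseFn(binCenters, alphaBetaX)) / sum(masses)
  }
}

#' @rdname rorRBEmax
#' @param L LET values in keV/um.
#' @export
rorResponse <- function(L, alphaBetaX, model = rbeModel("ror")) {
  .checkLetAlphaBeta(L, alphaBetaX)
  Ls <- .coef(model, "let_scale")
  .coef(model, "r0") +
    (.coef(model, "slope") / alphaBetaX) * Ls * (1 - exp(-L / Ls))
}

#' Voxel RBE under a pluggable model
#'
#' Dispatches to the requested model: \code{constant_1p1} returns exactly
#' 1.1; \code{mcn} combines \code{\link{mcnRBEmax}} and \code{\link{mcnRBEmin}}
#' through \code{\link{lqRBE}}; \code{ror} combines the spectrum-averaged
#' \code{\link{rorRBEmax}} with RBEmin = 1 through \code{\link{lqRBE}}.
#'
#' The spectrum model evaluated without a spectrum is an error unless
#' \code{rorFallback = TRUE}, in which case the nonlinear response is
#' evaluated at the dose-averaged LET instead — an approximation (the
#' response is concave, so this overestimates the spectrum average) that is
#' off by default and should be flagged wherever used.
#'
#' @param model an \linkS4class{RBEModel}.
#' @param dPhys physical dose per fraction in Gy.
#' @param letD dose-averaged LET in keV/um (ignored by \code{constant_1p1}).
#' @param tissue a \linkS4class{TissueParams} or a numeric (alpha/beta)x.
#' @param spectrum optional list with \code{binCenters} and \code{masses}
#'   (vector or voxel-by-bin matrix) for the spectrum model.
#' @param rorFallback logical; allow the LETd approximation for \code{ror}.
#' @return Dimensionless RBE, vectorized like the inputs.
#' @examples
#' voxelRBE(rbeModel("constant_1p1"), 1.6, 2.2, 2.1)
#' voxelRBE(rbeModel("mcn"), 1.8 / 1.1, 2.2, 2.1)
#' @export
voxelRBE <- function(model, dPhys, letD, tissue, spectrum = NULL,
                     rorFallback = FALSE) {
  ab <- if (is(tissue, "TissueParams")) tissue@alphaBeta else as.numeric(tissue)
  switch(model@modelId,
    constant_1p1 = rep_len(.coef(model, "rbe"), max(length(dPhys), length(letD))),
    mcn = lqRBE(dPhys, ab,
                mcnRBEmax(letD, ab, model = model),
                mcnRBEmin(letD, ab, model = model)),
    ror = {
      if (is.null(spectrum)) {
        if (!rorFallback)
          stop("the spectrum-based model requires an LET spectrum; ",
               "set rorFallback = TRUE to approximate with the ",
               "dose-averaged LET")
        rmax <- rorResponse(letD, ab, model = model)
      } else {
        rmax <- rorRBEmax(spectrum$binCenters, spectrum$masses, ab,
                          model = model)
      }
      lqRBE(dPhys, ab, rmax, 1)
    })
}

#' Organ tissue parameters used in proton CSI analyses
#'
#' Loads the organ-specific (alpha/beta)x values (Gy) with 95\% confidence
#' intervals from the shipped tissue file: heart 3 (1.5-4.5), brainstem
#' 2.1 (1.1-3.2), lungs 4.0 (2.0-6.0), thyroid 3 (1.5-4.5), plus a generic
#' late-effects default of 3 Gy for unassigned tissue.
#'
#' @param tissueFile optional path to a tissue JSON file.
#' @return Named list of \linkS4class{TissueParams}.
#' @examples
#' defaultTissueParams()[["brainstem"]]
#' @export
defaultTissueParams <- function(tissueFile = NULL) {
  if (is.null(tissueFile))
    tissueFile <- system.file("extdata", "tissue_alpha_beta.json",
                              package = "protonRBE", mustWork = TRUE)
  spec <- jsonlite::read_json(tissueFile, simplifyVector = TRUE)
  out <- lapply(names(spec$tissues), function(nm) {
    t <- spec$tissues[[nm]]
    TissueParams(nm, t$alpha_beta, t$ci)
  })
  names(out) <- names(spec$tissues)
  out
}
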