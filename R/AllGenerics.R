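#' Constructors and accessors for the core imaging containers
#'
#' @param data array of voxel values.
#' @param spacing voxel size in mm (recycled to length 3).
#' @return the corresponding S4 object.
#' @export
ScalarVolume <- function(data, spacing = c(1, 1, 1)) {
  new("ScalarVolume", data = data, spacing = rep(as.numeric(spacing), length.out = 3))
}

#' @rdname ScalarVolume
#' @param labels data.frame with columns id, name, class.
#' @export
LabelVolume <- function(data, spacing = c(1, 1, 1), labels) {
  storage.mode(data) <- "integer"
  new("LabelVolume", data = data,
      spacing = rep(as.numeric(spacing), length.out = 3), labels = labels)
}

#' @rdname ScalarVolume
#' @export
DisplacementField <- function(data, spacing = c(1, 1, 1)) {
  new("DisplacementField", data = data,
      spacing = rep(as.numeric(spacing), length.out = 3))
}

#' @rdname ScalarVolume
#' @param annualized logical, whether values are per-year ratios.
#' @param intervalYears interval used for annualization (or NULL).
#' @export
JacobianMap <- function(data, spacing = c(1, 1, 1), annualized = FALSE,
                        intervalYears = NULL) {
  new("JacobianMap", data = data,
      spacing = rep(as.numeric(spacing), length.out = 3),
      annualized = annualized, intervalYears = intervalYears)
}

#' Voxel data of an imaging object
#' @param x a ScalarVolume, LabelVolume, DisplacementField or JacobianMap.
#' @return the underlying array.
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' @rdname voxelData
#' @export
setMethod("voxelData", "ScalarVolume", function(x) x@data)
#' @rdname voxelData
#' @export
setMethod("voxelData", "LabelVolume", function(x) x@data)
#' @rdname voxelData
#' @export
setMethod("voxelData", "DisplacementField", function(x) x@data)
#' @rdname voxelData
#' @export
setMethod("voxelData", "JacobianMap", function(x) x@data)

#' Voxel spacing (mm) of an imaging object
#' @param x an imaging object.
#' @return numeric length 3.
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "ScalarVolume", function(x) x@spacing)
#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "LabelVolume", function(x) x@spacing)
#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "DisplacementField", function(x) x@spacing)
#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "JacobianMap", function(x) x@spacing)

#' Label table of a LabelVolume
#' @param x a LabelVolume.
#' @return data.frame with id, name, class.
#' @export
setGeneric("labelTable", function(x) standardGeneric("labelTable"))
#' @rdname labelTable
#' @export
setMethod("labelTable", "LabelVolume", function(x) x@labels)

#' Annualization state of a JacobianMap
#' @param x a JacobianMap.
#' @return logical.
#' @export
setGeneric("isAnnualized", function(x) standardGeneric("isAnnualized"))
#' @rdname isAnnualized
#' @export
setMethod("isAnnualized", "JacobianMap", function(x) x@annualized)

setMethod("show", "ScalarVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("ScalarVolume %dx%dx%d, spacing %s mm, range [%.3g, %.3g]\n",
              d[1], d[2], d[3], paste(signif(object@spacing, 3), collapse = "x"),
              min(object@data), max(object@data)))
})

setMethod("show", "LabelVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("LabelVolume %dx%dx%d, %d labels (%s)\n", d[1], d[2], d[3],
              nrow(object@labels),
              paste(sort(unique(object@labels$class)), collapse = ", ")))
})

setMethod("show", "DisplacementField", function(object) {
  d <- dim(object@data)
  cat(sprintf("DisplacementField %dx%dx%d, max |u| = %.3g mm\n",
              d[1], d[2], d[3], sqrt(max(rowSums(matrix(object@data^2,
                ncol = 3))))))
})

setMethod("show", "JacobianMap", function(object) {
  d <- dim(object@data)
  cat(sprintf("JacobianMap %dx%dx%d, %s, range [%.4f, %.4f]\n", d[1], d[2],
              d[3], if (object@annualized) "annualized" else "raw interval",
              min(object@data, na.rm = TRUE), max(object@data, na.rm = TRUE)))
})

#' Phantom specification
#'
#' Defaults describe a 48^3 grid at 3 mm isotropic spacing: a head-sized
#' ellipsoidal brain with an 8-fold cortical ribbon, mild acquisition noise and
#' a 5\% smooth scanner bias field.
#'
#' @param gridShape voxels per axis (length 3, all >= 16).
#' @param voxelSizeMm isotropic voxel size in mm.
#' @param corticalFoldCount azimuthal fold frequency (0 = unfolded).
#' @param noiseSd additive intensity noise SD.
#' @param scannerBias multiplicative bias amplitude.
#' @param seed RNG seed for acquisition noise.
#' @return a PhantomSpec object.
#' @export
phantomSpec <- function(gridShape = c(48L, 48L, 48L), voxelSizeMm = 3,
                        corticalFoldCount = 8L, noiseSd = 1.5,
                        scannerBias = 0.05, seed = 1L) {
  new("PhantomSpec", gridShape = as.integer(rep(gridShape, length.out = 3)),
      voxelSizeMm = as.numeric(voxelSizeMm),
      corticalFoldCount = as.integer(corticalFoldCount),
      noiseSd = as.numeric(noiseSd), scannerBias = as.numeric(scannerBias),
      seed = as.integer(seed))
}

#' Atrophy specification
#'
#' Default rates are the study-condition annualized volume-change
#' distributions: cases lose 1.55 +/- 2.19 \%/yr of grey matter and
#' 1.49 +/- 2.20 \%/yr of white matter; controls lose 0.55 +/- 1.13 \%/yr of
#' grey matter and gain 0.26 +/- 1.11 \%/yr of white matter. The default
#' sulcal excess (1.065) and scanner offset (0.012 on annual log-JD) are
#' calibrated so the sulcus-by-group interaction is of order 0.001 on the JD
#' scale and the scanner explains roughly 9\% of summary-JD variance.
#'
#' @param rateMean,rateSd 2x2 matrices (case/control x GM/WM), percent/yr.
#' @param rateCor correlation between a subject's GM and WM rate draws.
#' @param sulcalExcess multiplicative sulcal-vs-gyral rate factor for cases.
#' @param lesionProb per-case focal lesion probability.
#' @param lesionRadiusMm lesion radius (mm).
#' @param scannerOffset between-scanner shift of annual log-JD.
#' @return an AtrophySpec object.
#' @export
atrophySpec <- function(
    rateMean = matrix(c(-1.55, -0.55, -1.49, 0.26), 2, 2,
                      dimnames = list(c("case", "control"), c("GM", "WM"))),
    rateSd = matrix(c(2.19, 1.13, 2.20, 1.11), 2, 2,
                    dimnames = list(c("case", "control"), c("GM", "WM"))),
    rateCor = 0.7, sulcalExcess = 1.065, lesionProb = 0.672,
    lesionRadiusMm = 9, scannerOffset = 0.012) {
  new("AtrophySpec", rateMean = rateMean, rateSd = rateSd,
      rateCor = as.numeric(rateCor), sulcalExcess = as.numeric(sulcalExcess),
      lesionProb = as.numeric(lesionProb),
      lesionRadiusMm = as.numeric(lesionRadiusMm),
      scannerOffset = as.numeric(scannerOffset))
}

#' Registration parameters
#'
#' @param levels pyramid levels (coarsest is downsampled by 2^(levels-1)).
#' @param iterations per-level iteration counts, coarsest first.
#' @param fluidSigmaMm Gaussian sigma (mm) for the update field.
#' @param diffusionSigmaMm Gaussian sigma (mm) for the velocity field.
#' @param squaringSteps scaling-and-squaring steps.
#' @param imageFwhmMm FWHM (mm) of the Gaussian applied to both images
#'   before estimation; suppresses acquisition noise that weakly-regularized
#'   demons would otherwise fit as deformation.
#' @param tol relative per-iteration objective improvement below which a
#'   level stops iterating.
#' @return a RegistrationParams object.
#' @export
registrationParams <- function(levels = 3L, iterations = c(50L, 50L, 25L),
                               fluidSigmaMm = 2, diffusionSigmaMm = 1,
                               squaringSteps = 6L, imageFwhmMm = 7,
                               tol = 1e-3) {
  new("RegistrationParams", levels = as.integer(levels),
      iterations = as.integer(rep(iterations, length.out = levels)),
      fluidSigmaMm = as.numeric(fluidSigmaMm),
      diffusionSigmaMm = as.numeric(diffusionSigmaMm),
      squaringSteps = as.integer(squaringSteps),
      imageFwhmMm = as.numeric(imageFwhmMm), tol = as.numeric(tol))
}

#' TFCE parameters
#'
#' Defaults are the de facto volumetric standard: E = 0.5, H = 2,
#' 26-connectivity, 100 integration steps (dh = max-stat / 100).
#'
#' @param E extent exponent.
#' @param H height exponent.
#' @param nSteps number of integration heights.
#' @param connectivity 6 or 26.
#' @return a TFCEParams object.
#' @export
tfceParams <- function(E = 0.5, H = 2, nSteps = 100L, connectivity = 26L) {
  new("TFCEParams", E = as.numeric(E), H = as.numeric(H),
      nSteps = as.integer(nSteps), connectivity = as.integer(connectivity))
}
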