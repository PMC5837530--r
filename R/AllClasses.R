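#' @import methods
#' @importFrom stats rnorm runif rbinom qnorm pnorm pt sd var lm lm.fit
#'   model.matrix cor.test p.adjust logLik anova ks.test quantile median
#'   setNames complete.cases as.formula coef vcov resid fitted rlnorm
#' @importFrom utils combn head
#' @useDynLib longdbm, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' ScalarVolume: a 3-D intensity image on a regular grid
#'
#' Minimal container for a single-channel volume: a numeric 3-D array plus
#' isotropic-or-not voxel spacing in mm. World coordinates are
#' \code{(index - 1) * spacing} on each axis (RAS-aligned axes, origin at the
#' first voxel), which is the convention used throughout the package and when
#' writing NIfTI.
#'
#' @slot data numeric 3-D array of intensities.
#' @slot spacing numeric length-3, voxel size in mm per axis (all > 0).
#' @export
setClass("ScalarVolume",
  representation(data = "array", spacing = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@data)) != 3L)
      msg <- c(msg, "data must be a 3-D array")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      msg <- c(msg, "spacing must be 3 positive finite values (mm)")
    if (length(msg)) msg else TRUE
  })

#' LabelVolume: integer anatomical labels with a class table
#'
#' @slot data integer 3-D array of label ids (0 = background).
#' @slot spacing numeric length-3 voxel size (mm).
#' @slot labels data.frame with columns \code{id}, \code{name}, \code{class};
#'   class is one of \code{gyrus}, \code{sulcus}, \code{subcortical-GM},
#'   \code{WM}, \code{CSF}, \code{background}.
#' @export
setClass("LabelVolume",
  representation(data = "array", spacing = "numeric", labels = "data.frame"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@data)) != 3L)
      msg <- c(msg, "data must be a 3-D array")
    if (!all(c("id", "name", "class") %in% names(object@labels)))
      msg <- c(msg, "labels must have columns id, name, class")
    else {
      ok <- c("gyrus", "sulcus", "subcortical-GM", "WM", "CSF", "background")
      if (!all(object@labels$class %in% ok))
        msg <- c(msg, "unknown label class")
      present <- unique(as.vector(object@data))
      if (!all(present %in% object@labels$id))
        msg <- c(msg, "every voxel label must appear in the label table")
    }
    if (length(msg)) msg else TRUE
  })

#' DisplacementField: a voxelwise 3-vector warp in mm
#'
#' Represents the map phi(x) = x + u(x) with u stored as a 4-D array whose
#' last axis holds the (x, y, z) displacement components in mm.
#'
#' @slot data numeric 4-D array, dim = c(nx, ny, nz, 3), mm.
#' @slot spacing numeric length-3 voxel size (mm).
#' @export
setClass("DisplacementField",
  representation(data = "array", spacing = "numeric"),
  validity = function(object) {
    d <- dim(object@data)
    msg <- character()
    if (length(d) != 4L || d[4] != 3L)
      msg <- c(msg, "data must be a 4-D array with last dim 3")
    if (any(!is.finite(object@data)))
      msg <- c(msg, "displacements must be finite")
    if (length(msg)) msg else TRUE
  })

#' JacobianMap: voxelwise volume-change ratio of a warp
#'
#' Values below 1 denote local volume loss from baseline to follow-up, above 1
#' local expansion. A map may be annualized (geometric: exp(log(JD)/years)).
#'
#' @slot data numeric 3-D array of positive ratios (NA allowed where flagged).
#' @slot spacing numeric length-3 voxel size (mm).
#' @slot annualized logical flag.
#' @slot intervalYears numeric or NULL; the interval used for annualization.
#' @export
setClass("JacobianMap",
  representation(data = "array", spacing = "numeric", annualized = "logical",
                 intervalYears = "numericOrNULL"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@data)) != 3L)
      msg <- c(msg, "data must be a 3-D array")
    if (length(object@annualized) != 1L)
      msg <- c(msg, "annualized must be a single logical")
    if (length(msg)) msg else TRUE
  })

#' PhantomSpec: geometry and acquisition parameters of the synthetic phantom
#'
#' @slot gridShape integer length-3, voxels per axis (all >= 16).
#' @slot voxelSizeMm single positive number, isotropic spacing in mm.
#' @slot corticalFoldCount integer >= 0; azimuthal frequency of the radial
#'   sinusoid folding the cortical ribbon (0 = unfolded ribbon).
#' @slot noiseSd additive intensity noise SD (intensity units, >= 0).
#' @slot scannerBias amplitude of the smooth multiplicative per-scanner bias
#'   field (fraction, >= 0).
#' @slot seed integer RNG seed for acquisition noise.
#' @export
setClass("PhantomSpec",
  representation(gridShape = "integer", voxelSizeMm = "numeric",
                 corticalFoldCount = "integer", noiseSd = "numeric",
                 scannerBias = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@gridShape) != 3L || any(object@gridShape < 16L))
      msg <- c(msg, "gridShape must be 3 integers, all >= 16")
    if (object@voxelSizeMm <= 0) msg <- c(msg, "voxelSizeMm must be > 0")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    if (object@corticalFoldCount < 0L)
      msg <- c(msg, "corticalFoldCount must be >= 0")
    if (object@scannerBias < 0) msg <- c(msg, "scannerBias must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' AtrophySpec: the ground-truth atrophy model for the synthetic cohort
#'
#' Annual volume-change rates (percent per year; negative = loss) are drawn per
#' subject and tissue from group-specific normal distributions. Atrophy
#' compounds geometrically over the inter-scan interval:
#' total ratio = (1 + r/100)^interval.
#'
#' @slot rateMean 2 x 2 numeric matrix of mean annual rates, rows
#'   \code{case}/\code{control}, columns \code{GM}/\code{WM} (percent/yr).
#' @slot rateSd matching matrix of SDs (>= 0).
#' @slot rateCor within-subject correlation between the GM and WM rate draws.
#' @slot sulcalExcess factor (>= 1) by which sulcal cortical labels atrophy
#'   faster than gyral ones in the case group.
#' @slot lesionProb probability a case carries a focal lesion.
#' @slot lesionRadiusMm lesion radius in mm.
#' @slot scannerOffset additive shift on the annual log-JD between the two
#'   scanners (scanner A gets +offset/2, scanner B -offset/2).
#' @export
setClass("AtrophySpec",
  representation(rateMean = "matrix", rateSd = "matrix", rateCor = "numeric",
                 sulcalExcess = "numeric", lesionProb = "numeric",
                 lesionRadiusMm = "numeric", scannerOffset = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!identical(dim(object@rateMean), c(2L, 2L)) ||
        !identical(dim(object@rateSd), c(2L, 2L)))
      msg <- c(msg, "rateMean and rateSd must be 2x2 (case/control x GM/WM)")
    if (any(object@rateSd < 0)) msg <- c(msg, "rate SDs must be >= 0")
    if (object@sulcalExcess < 1) msg <- c(msg, "sulcalExcess must be >= 1")
    if (object@lesionProb < 0 || object@lesionProb > 1)
      msg <- c(msg, "lesionProb must be in [0, 1]")
    if (abs(object@rateCor) > 1) msg <- c(msg, "rateCor must be in [-1, 1]")
    if (length(msg)) msg else TRUE
  })

#' RegistrationParams: symmetric demons registration settings
#'
#' @slot levels integer >= 1, multi-resolution pyramid depth.
#' @slot iterations integer vector (length = levels), iterations per level,
#'   coarsest first.
#' @slot fluidSigmaMm Gaussian sigma (mm) applied to each update field.
#' @slot diffusionSigmaMm Gaussian sigma (mm) applied to the velocity field
#'   after each accepted update.
#' @slot squaringSteps scaling-and-squaring steps for exponentiation (>= 1).
#' @slot imageFwhmMm Gaussian FWHM (mm) applied to both images before
#'   estimation (outputs are computed from the raw images).
#' @slot tol relative per-iteration improvement below which a level stops.
#' @export
setClass("RegistrationParams",
  representation(levels = "integer", iterations = "integer",
                 fluidSigmaMm = "numeric", diffusionSigmaMm = "numeric",
                 squaringSteps = "integer", imageFwhmMm = "numeric",
                 tol = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@levels < 1L) msg <- c(msg, "levels must be >= 1")
    if (length(object@iterations) != object@levels)
      msg <- c(msg, "iterations must have one entry per level")
    if (object@fluidSigmaMm < 0 || object@diffusionSigmaMm < 0)
      msg <- c(msg, "sigmas must be >= 0")
    if (object@imageFwhmMm < 0) msg <- c(msg, "imageFwhmMm must be >= 0")
    if (object@squaringSteps < 1L) msg <- c(msg, "squaringSteps must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' TFCEParams: threshold-free cluster enhancement settings
#'
#' @slot E extent exponent (> 0), default 0.5.
#' @slot H height exponent (> 0), default 2.
#' @slot nSteps number of integration heights; the step is max-stat / nSteps.
#' @slot connectivity 6 or 26 (3-D neighbourhood).
#' @export
setClass("TFCEParams",
  representation(E = "numeric", H = "numeric", nSteps = "integer",
                 connectivity = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@E <= 0 || object@H <= 0) msg <- c(msg, "E and H must be > 0")
    if (object@nSteps < 1L) msg <- c(msg, "nSteps must be >= 1")
    if (!object@connectivity %in% c(6L, 26L))
      msg <- c(msg, "connectivity must be 6 or 26")
    if (length(msg)) msg else TRUE
  })
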