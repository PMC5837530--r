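#' Build the deterministic template phantom
#'
#' Constructs a head-sized "brain" on a regular grid: an ellipsoidal brain mask
#' containing (inside out) a central CSF ventricle, a deep (subcortical) grey
#' matter shell, white matter, and a cortical grey-matter ribbon whose inner
#' and outer surfaces are modulated by a radial sinusoid in the azimuthal
#' angle. Fold crowns (ribbon pushed outward) carry gyral labels, fold troughs
#' sulcal labels; cortical regions of interest are defined by azimuthal
#' half-period times polar band, giving (with the default fold count of 8)
#' 24 gyral and 24 sulcal ROIs. Class intensities are distinct (CSF 25, deep
#' GM 85, cortical GM 80, WM 120, background 0) and a smooth deterministic
#' texture (+/- 6 units) is added inside the brain so that tissue interiors
#' carry registration-usable gradients, as T1-weighted anatomy does.
#'
#' The build is fully deterministic: acquisition noise and scanner bias are
#' added later, when image pairs are synthesized.
#'
#' @param spec a \code{\link{phantomSpec}}.
#' @return list with elements \code{template} (ScalarVolume) and
#'   \code{labels} (LabelVolume).
#' @export
buildTemplatePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  dims <- spec@gridShape
  vs <- rep(spec@voxelSizeMm, 3)
  extent <- dims * vs
  centre <- (dims - 1) / 2 * vs
  semi <- extent * c(0.42, 0.38, 0.35)

  # ribbon must be resolvable: thickness ~= 0.26 * min semi-axis
  ribbonMm <- 0.26 * min(semi)
  if (ribbonMm < 2 * spec@voxelSizeMm)
    stop("grid too small: cortical ribbon would be under 2 voxels thick (",
         signif(ribbonMm, 3), " mm at ", spec@voxelSizeMm, " mm spacing)")

  co <- coordArrays(dims, vs)
  xn <- (co$x - centre[1]) / semi[1]
  yn <- (co$y - centre[2]) / semi[2]
  zn <- (co$z - centre[3]) / semi[3]
  rho <- sqrt(xn^2 + yn^2 + zn^2)
  az <- atan2(yn, xn)                      # [-pi, pi]
  pol <- acos(pmin(pmax(zn / pmax(rho, 1e-9), -1), 1))  # [0, pi]

  foldFreq <- if (spec@corticalFoldCount > 0L) spec@corticalFoldCount else 8L
  amp <- if (spec@corticalFoldCount > 0L) 0.10 else 0
  m <- sin(foldFreq * az)
  ri <- 0.70 + amp * m
  ro <- 0.96 + amp * m

  lab <- array(0L, dims)
  lab[rho <= 0.28] <- 1L                                # CSF ventricle
  lab[rho > 0.28 & rho <= 0.40] <- 2L                   # deep GM
  lab[rho > 0.40 & rho <= ri] <- 3L                     # WM
  cortex <- rho > ri & rho <= ro

  # cortical ROI ids: azimuthal half-period (2*foldFreq wedges) x 3 polar bands
  wedge <- pmin(floor((az + pi) * foldFreq / pi), 2 * foldFreq - 1)
  band <- findInterval(pol, c(pi / 3, 2 * pi / 3))      # 0,1,2
  roiId <- 10L + as.integer(band) * 2L * foldFreq + as.integer(wedge)
  lab[cortex] <- roiId[cortex]

  gyral <- sin(foldFreq * az) >= 0
  roiIds <- sort(unique(lab[cortex]))
  roiClass <- vapply(roiIds, function(id) {
    sel <- lab == id
    if (mean(gyral[sel]) >= 0.5) "gyrus" else "sulcus"
  }, character(1))
  roiName <- sprintf("%s_%02d", ifelse(roiClass == "gyrus", "G", "S"),
                     seq_along(roiIds))
  labels <- rbind(
    data.frame(id = c(0L, 1L, 2L, 3L),
               name = c("background", "ventricle", "deep_gm", "white_matter"),
               class = c("background", "CSF", "subcortical-GM", "WM")),
    data.frame(id = roiIds, name = roiName, class = roiClass))

  if (sum(labels$class == "gyrus") < 6L || sum(labels$class == "sulcus") < 6L)
    stop("phantom construction yielded fewer than 6 gyral or sulcal labels")

  geometry <- list(semi = semi, centreMm = centre, bCsf = 0.28, bDeep = 0.40,
                   bInner = 0.70, bOuter = 0.96, amp = amp,
                   foldFreq = foldFreq)

  intens <- c(`0` = 0, `1` = 25, `2` = 85, `3` = 120)
  img <- array(0, dims)
  img[lab == 1L] <- 25
  img[lab == 2L] <- 85
  img[lab == 3L] <- 120
  img[cortex] <- 80
  # smooth deterministic texture inside the brain
  brain <- lab > 0L
  texture <- 6 * sin(2 * pi * co$x / 61) * sin(2 * pi * co$y / 53) *
    sin(2 * pi * co$z / 67)
  img[brain] <- img[brain] + texture[brain]

  attr(lab, "geometry") <- geometry
  list(template = ScalarVolume(img, vs),
       labels = LabelVolume(lab, vs, labels))
}

#' Tissue class membership helpers
#'
#' \code{classMask} returns a logical mask of voxels whose label class is in
#' \code{classes}; \code{tissueMask} maps the conventional tissue names
#' (\code{"GM"} = gyrus + sulcus + subcortical-GM, \code{"WM"}, \code{"CSF"},
#' \code{"brain"} = all non-background) onto classes.
#'
#' @param labels a LabelVolume.
#' @param classes character vector of label classes.
#' @return logical 3-D array.
#' @export
classMask <- function(labels, classes) {
  stopifnot(is(labels, "LabelVolume"))
  tab <- labelTable(labels)
  unknown <- setdiff(classes, tab$class)
  if (length(unknown))
    stop("unknown label class(es): ", paste(unknown, collapse = ", "))
  ids <- tab$id[tab$class %in% classes]
  array(voxelData(labels) %in% ids, dim(voxelData(labels)))
}

#' @rdname classMask
#' @param tissue one of "GM", "WM", "CSF", "brain", "cortex".
#' @export
tissueMask <- function(labels, tissue) {
  classes <- switch(tissue,
    GM = c("gyrus", "sulcus", "subcortical-GM"),
    WM = "WM",
    CSF = "CSF",
    cortex = c("gyrus", "sulcus"),
    brain = c("gyrus", "sulcus", "subcortical-GM", "WM", "CSF"),
    stop("unknown tissue: ", tissue))
  classMask(labels, classes)
}
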