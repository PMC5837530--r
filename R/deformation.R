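#' Draw a subject's ground-truth deformation
#'
#' Annual volume-change rates for GM and WM are drawn from the subject's
#' group-specific (mean, SD) with correlation \code{rateCor}; in cases,
#' sulcal cortex atrophies faster by the factor \code{sulcalExcess}. The
#' deformation is a radial mass-conserving shell map: along each ray from the
#' brain centre (in ellipsoid-normalized coordinates), the cubed radius is
#' remapped piecewise linearly so that every tissue shell's volume scales by
#' exactly its ratio \eqn{c_k = [(1 + r_k/100) e^{off}]^{T}} (interval T in
#' years, off the scanner offset on annual log-JD). Because the map sends
#' radii to radii, its Jacobian determinant equals \eqn{c_k} exactly inside
#' each shell, independent of the fold-modulated shell boundaries; sulcal and
#' gyral rates are blended smoothly across sector borders so the map stays
#' continuous. Displacements taper to zero just outside the brain surface.
#' The pullback field (the inverse map, used to resample the template into
#' the follow-up image) is obtained by fixed-point inversion.
#'
#' @param atrophy an \code{\link{atrophySpec}}.
#' @param record one-row data.frame (or list) with at least \code{id},
#'   \code{group} ("case"/"control"), \code{scanner} ("A"/"B") and
#'   \code{interval_years}.
#' @param labels template LabelVolume from \code{\link{buildTemplatePhantom}}
#'   (carries the phantom geometry).
#' @param seed integer seed for the rate draws.
#' @param squaringSteps unused placeholder kept for backward compatibility.
#' @return list with \code{forward} (DisplacementField, the anatomical map
#'   with JD < 1 under atrophy), \code{pullback} (DisplacementField used
#'   to synthesize the follow-up image), and \code{truth} (list: drawn
#'   \code{rates} in percent/yr, closed-form \code{annualJd} and
#'   \code{jdTotal} JacobianMaps, realized \code{compartmentRates},
#'   \code{roiTruth} table, \code{intervalYears}, \code{scannerOffset}).
#' @export
drawSubjectDeformation <- function(atrophy, record, labels, seed,
                                   squaringSteps = 6L) {
  stopifnot(is(atrophy, "AtrophySpec"), is(labels, "LabelVolume"))
  record <- as.list(record)
  if (is.null(record$interval_years) || record$interval_years <= 0)
    stop("record$interval_years must be > 0")
  grp <- match.arg(record$group, c("case", "control"))
  interval <- record$interval_years
  rates <- drawSubjectRates(atrophy, grp, seed)

  lab <- voxelData(labels)
  geo <- attr(lab, "geometry")
  if (is.null(geo))
    stop("labels must come from buildTemplatePhantom (missing geometry)")
  vs <- voxelSpacing(labels)
  dims <- dim(lab)

  offScan <- switch(match.arg(record$scanner, c("A", "B")),
                    A = atrophy@scannerOffset / 2,
                    B = -atrophy@scannerOffset / 2)

  co <- coordArrays(dims, vs)
  xi1 <- (co$x - geo$centreMm[1]) / geo$semi[1]
  xi2 <- (co$y - geo$centreMm[2]) / geo$semi[2]
  xi3 <- (co$z - geo$centreMm[3]) / geo$semi[3]
  rho <- sqrt(xi1^2 + xi2^2 + xi3^2)
  az <- atan2(xi2, xi1)

  # annual JD per shell; sulcal/gyral cortical rates blended smoothly in
  # azimuth so the displacement is continuous across sector borders
  eo <- exp(offScan)
  jdCsf <- eo
  jdGm <- (1 + rates[["GM"]] / 100) * eo
  jdWm <- (1 + rates[["WM"]] / 100) * eo
  sSulc <- stats::plogis(-sin(geo$foldFreq * az) / 0.15)
  rCtx <- rates[["GM"]] * (1 + (atrophy@sulcalExcess - 1) *
                             (if (grp == "case") sSulc else 0))
  jdCtx <- (1 + rCtx / 100) * eo

  # total (interval) volume ratios per shell
  cCsf <- jdCsf^interval; cGm <- jdGm^interval
  cWm <- jdWm^interval; cCtx <- jdCtx^interval

  # shell boundaries (normalized radius), fold-modulated for the cortex
  mAz <- geo$amp * sin(geo$foldFreq * az)
  b0 <- geo$bCsf; b1 <- geo$bDeep
  b2 <- geo$bInner + mAz; b3 <- geo$bOuter + mAz
  m0 <- b0^3; m1 <- b1^3; m2 <- b2^3; m3 <- b3^3

  # cumulative scaled volume: piecewise linear in m = rho^3 along each ray
  M0 <- cCsf * m0
  M1 <- M0 + cGm * (m1 - m0)
  M2 <- M1 + cWm * (m2 - m1)
  M3 <- M2 + cCtx * (m3 - m2)
  m <- rho^3
  M <- ifelse(m < m0, cCsf * m,
       ifelse(m < m1, M0 + cGm * (m - m0),
       ifelse(m < m2, M1 + cWm * (m - m1),
       ifelse(m < m3, M2 + cCtx * (m - m2),
              M3 + (m - m3)))))
  factor <- ifelse(rho > 1e-9, M^(1 / 3) / rho, 1)

  # taper displacements to zero outside the brain (surface tops out ~1.06)
  t <- pmin(pmax((rho - 1.10) / 0.35, 0), 1)
  w <- 1 - t * t * (3 - 2 * t)
  fac <- 1 + w * (factor - 1)
  u <- array(0, c(dims, 3))
  u[, , , 1] <- (fac - 1) * (co$x - geo$centreMm[1])
  u[, , , 2] <- (fac - 1) * (co$y - geo$centreMm[2])
  u[, , , 3] <- (fac - 1) * (co$z - geo$centreMm[3])
  forward <- DisplacementField(u, vs)
  pullback <- DisplacementField(invertDisp(u, vs), vs)

  # closed-form analytic JD (exact per shell; 1 outside the brain)
  jdTotArr <- ifelse(m < m0, cCsf,
              ifelse(m < m1, cGm,
              ifelse(m < m2, cWm,
              ifelse(m < m3, cCtx, 1))))
  jdAnnArr <- jdTotArr^(1 / interval)
  jdTotal <- JacobianMap(jdTotArr, vs, annualized = FALSE,
                         intervalYears = NULL)
  annualJd <- JacobianMap(jdAnnArr, vs, annualized = TRUE,
                          intervalYears = interval)

  aj <- jdAnnArr
  brain <- lab > 0L
  compRates <- c(
    GM = 100 * (mean(aj[tissueMask(labels, "GM")]) - 1),
    WM = 100 * (mean(aj[tissueMask(labels, "WM")]) - 1),
    brain = 100 * (mean(aj[brain]) - 1))
  roiTruth <- roiMeanJd(annualJd, labels)

  list(forward = forward, pullback = pullback,
       truth = list(rates = rates, annualJd = annualJd, jdTotal = jdTotal,
                    compartmentRates = compRates, roiTruth = roiTruth,
                    intervalYears = interval, scannerOffset = offScan))
}

# Fixed-point inversion of a displacement field:
# uinv(y) = -u(y + uinv(y)), iterated; accurate for small smooth fields.
invertDisp <- function(u, spacing, iters = 12L) {
  d <- dim(u)
  uinv <- -u
  for (i in seq_len(iters)) {
    new <- array(0, d)
    for (c in 1:3)
      new[, , , c] <- -sampleWarped(u[, , , c], uinv, spacing,
                                    clampEdge = TRUE)
    uinv <- new
  }
  uinv
}

# Draw a subject's annual GM/WM (and sulcal-GM) rates in percent/yr.
drawSubjectRates <- function(atrophy, grp, seed) {
  withSeed(seed, {
    mu <- atrophy@rateMean[grp, ]
    sdv <- atrophy@rateSd[grp, ]
    rc <- atrophy@rateCor
    ok <- FALSE
    for (try in 1:10) {
      z1 <- rnorm(1)
      z2 <- rc * z1 + sqrt(1 - rc^2) * rnorm(1)
      r <- c(GM = mu["GM"] + sdv["GM"] * z1, WM = mu["WM"] + sdv["WM"] * z2)
      names(r) <- c("GM", "WM")
      rs <- r["GM"] * if (grp == "case") atrophy@sulcalExcess else 1
      if (all(1 + c(r, rs) / 100 > 0.02)) { ok <- TRUE; break }
    }
    if (!ok) stop("could not draw rates with positive volume ratio")
    c(r, sulcalGM = unname(rs))
  })
}

#' Synthesize a baseline/follow-up image pair
#'
#' The baseline is the template under the subject's scanner bias field plus
#' additive Gaussian noise; the follow-up is the template resampled through
#' the pullback field (linear interpolation), with the same bias and an
#' independent noise draw. When \code{record$lesion} is true, a spherical
#' intensity drop (to 35\% of local intensity) is inserted at a reproducible
#' cortical location in both time points; lesions are intensity-only and do
#' not deform the anatomy.
#'
#' @param template ScalarVolume from \code{\link{buildTemplatePhantom}}.
#' @param field pullback DisplacementField from
#'   \code{\link{drawSubjectDeformation}} (maps follow-up coordinates onto the
#'   template).
#' @param record subject record (needs \code{scanner}; optionally
#'   \code{lesion}).
#' @param spec the \code{\link{phantomSpec}} (noise and bias amplitudes).
#' @param seed integer seed for noise and lesion placement.
#' @param labels optional LabelVolume; when given, lesion centres are drawn
#'   from cortical voxels, otherwise from GM-intensity voxels.
#' @param lesionRadiusMm lesion radius in mm (from the atrophy spec).
#' @return list(baseline, followup) of ScalarVolumes.
#' @export
synthesizePair <- function(template, field, record, spec, seed,
                           labels = NULL, lesionRadiusMm = 9) {
  stopifnot(is(template, "ScalarVolume"), is(field, "DisplacementField"))
  record <- as.list(record)
  img <- voxelData(template)
  dims <- dim(img)
  vs <- voxelSpacing(template)
  u <- voxelData(field)

  # margin check: content must not be pulled from outside the grid
  maxDisp <- max(abs(u))
  contentIdx <- which(img > 0.05 * max(img), arr.ind = TRUE)
  marginVox <- min(contentIdx - 1, sweep(-contentIdx, 2, dims, `+`))
  if (maxDisp > (marginVox + 0.5) * min(vs))
    stop(sprintf(
      "field displacement (%.1f mm) exceeds content-to-edge margin (%.1f mm)",
      maxDisp, marginVox * min(vs)))

  bias <- scannerBiasField(dims, vs, record$scanner, spec@scannerBias)
  warped <- sampleWarped(img, u, vs, clampEdge = FALSE, outside = 0)

  withSeed(seed, {
    lesionMask <- NULL
    if (isTRUE(record$lesion) || isTRUE(record$lesion == 1)) {
      if (!is.null(labels)) {
        cand <- which(tissueMask(labels, "cortex"))
      } else {
        cand <- which(img > 70 & img < 95)
      }
      ctr <- arrayInd(cand[sample.int(length(cand), 1)], dims)
      co <- coordArrays(dims, vs)
      d2 <- (co$x - (ctr[1] - 1) * vs[1])^2 + (co$y - (ctr[2] - 1) * vs[2])^2 +
        (co$z - (ctr[3] - 1) * vs[3])^2
      lesionMask <- d2 <= lesionRadiusMm^2
    }
    mk <- function(base) {
      if (!is.null(lesionMask)) base[lesionMask] <- 0.35 * base[lesionMask]
      out <- base * bias
      if (spec@noiseSd > 0)
        out <- out + array(rnorm(prod(dims), sd = spec@noiseSd), dims)
      out
    }
    baseline <- mk(img)
    followup <- mk(warped)
    list(baseline = ScalarVolume(baseline, vs),
         followup = ScalarVolume(followup, vs))
  })
}

# Smooth multiplicative bias field, deterministic per scanner.
scannerBiasField <- function(dims, vs, scanner, amplitude) {
  if (amplitude <= 0) return(array(1, dims))
  scanner <- match.arg(scanner, c("A", "B"))
  ph <- if (scanner == "A") c(0.3, 1.1, 2.0) else c(1.7, 0.2, 0.9)
  sgn <- if (scanner == "A") 1 else -1
  co <- coordArrays(dims, vs)
  ext <- dims * vs
  1 + sgn * amplitude *
    sin(pi * co$x / ext[1] + ph[1]) *
    sin(pi * co$y / ext[2] + ph[2]) *
    sin(pi * co$z / ext[3] + ph[3])
}
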