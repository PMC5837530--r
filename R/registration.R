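#' Exponentiate a stationary velocity field
#'
#' Scaling and squaring: the field is divided by 2^steps, treated as a small
#' displacement, and composed with itself \code{steps} times, giving the flow
#' of the velocity at time 1. The result is diffeomorphic for any smooth
#' velocity of moderate magnitude.
#'
#' @param v DisplacementField holding the velocity (mm).
#' @param steps number of squarings (>= 1).
#' @return DisplacementField of the flow at time 1.
#' @export
expVelocity <- function(v, steps = 6L) {
  stopifnot(is(v, "DisplacementField"), steps >= 1)
  if (any(!is.finite(voxelData(v)))) stop("non-finite velocities")
  u <- voxelData(v) / 2^steps
  sp <- voxelSpacing(v)
  for (i in seq_len(steps)) u <- composeDisp(u, u, sp)
  DisplacementField(u, sp)
}

#' Jacobian determinant map of a displacement field
#'
#' Computes det of the spatial gradient of phi(x) = x + u(x) with central
#' differences in the interior and one-sided differences at the faces; voxel
#' size is folded into the gradients so the determinant is a unit-free volume
#' ratio. Non-positive determinants (folding) are reported via a warning and
#' recorded in the \code{foldingCount} attribute of the returned map's data;
#' values are never clamped.
#'
#' @param field a DisplacementField.
#' @return a JacobianMap (not annualized).
#' @export
jacobianMap <- function(field) {
  stopifnot(is(field, "DisplacementField"))
  u <- voxelData(field)
  sp <- voxelSpacing(field)
  g <- list(gradient3d(u[, , , 1], sp),
            gradient3d(u[, , , 2], sp),
            gradient3d(u[, , , 3], sp))
  a11 <- 1 + g[[1]][[1]]; a12 <- g[[1]][[2]]; a13 <- g[[1]][[3]]
  a21 <- g[[2]][[1]]; a22 <- 1 + g[[2]][[2]]; a23 <- g[[2]][[3]]
  a31 <- g[[3]][[1]]; a32 <- g[[3]][[2]]; a33 <- 1 + g[[3]][[3]]
  det <- a11 * (a22 * a33 - a23 * a32) -
         a12 * (a21 * a33 - a23 * a31) +
         a13 * (a21 * a32 - a22 * a31)
  nfold <- sum(det <= 0)
  if (nfold > 0)
    warning("folding: ", nfold, " voxel(s) with non-positive Jacobian")
  attr(det, "foldingCount") <- nfold
  JacobianMap(det, sp, annualized = FALSE, intervalYears = NULL)
}

#' Annualize a Jacobian determinant map
#'
#' Geometric annualization: out = exp(log(jd) / interval), so volume change is
#' treated as compounding over the inter-scan interval. Non-positive voxels
#' cannot be annualized; they are set to NA and reported.
#'
#' @param jd a raw (not yet annualized) JacobianMap.
#' @param intervalYears inter-scan interval in years (> 0).
#' @return an annualized JacobianMap.
#' @export
annualizeJd <- function(jd, intervalYears) {
  stopifnot(is(jd, "JacobianMap"))
  if (isAnnualized(jd)) stop("map is already annualized")
  if (!is.numeric(intervalYears) || intervalYears <= 0)
    stop("intervalYears must be > 0")
  x <- voxelData(jd)
  bad <- which(!is.na(x) & x <= 0)
  if (length(bad)) {
    warning(length(bad), " non-positive JD voxel(s) excluded from annualization")
    x[bad] <- NA_real_
  }
  out <- exp(log(x) / intervalYears)
  JacobianMap(out, voxelSpacing(jd), annualized = TRUE,
              intervalYears = intervalYears)
}

#' Gaussian smoothing of a volume by FWHM in mm
#'
#' sigma = fwhm / (2 sqrt(2 ln 2)) per axis; fwhm 0 is the identity.
#'
#' @param image ScalarVolume, JacobianMap, or 3-D array (then supply spacing).
#' @param fwhmMm full width at half maximum, mm (>= 0).
#' @param spacing voxel size, only when image is a bare array.
#' @return same type as the input.
#' @export
smoothVolume <- function(image, fwhmMm, spacing = NULL) {
  stopifnot(fwhmMm >= 0)
  if (fwhmMm == 0) return(image)
  sigma <- fwhmMm / (2 * sqrt(2 * log(2)))
  if (is(image, "ScalarVolume"))
    return(ScalarVolume(gaussSmoothMm(voxelData(image), sigma,
                                      voxelSpacing(image)),
                        voxelSpacing(image)))
  if (is(image, "JacobianMap"))
    return(JacobianMap(gaussSmoothMm(voxelData(image), sigma,
                                     voxelSpacing(image)),
                       voxelSpacing(image), image@annualized,
                       image@intervalYears))
  if (is.null(spacing)) stop("spacing required for array input")
  gaussSmoothMm(image, sigma, spacing)
}

#' Symmetric within-subject registration
#'
#' Symmetric stationary-velocity demons: one velocity field v is estimated so
#' that the baseline warped by exp(-v/2) matches the follow-up warped by
#' exp(+v/2); the midpoint ("temporal average") is the voxel mean of the two
#' half-warped images, and the full warp W = exp(v) satisfies
#' followup(W(x)) = baseline(x), so its Jacobian determinant is below 1 where
#' tissue was lost between the scans. Updates use sum-of-squared-difference
#' demons forces with fluid (update-field) and diffusion (velocity-field)
#' Gaussian regularization over a multi-resolution pyramid; a candidate update
#' is only accepted if the masked mean-squared intensity difference does not
#' increase, so the per-level objective trace is non-increasing. Estimation
#' runs on copies of the images smoothed by \code{imageFwhmMm} (noise that is
#' independent between the scans would otherwise be "explained" as
#' deformation); the returned midpoint and warps are applied to the raw
#' images. Updates are confined to a dilated support mask around image
#' content so noise-only background cannot accumulate drift.
#'
#' @param baseline,followup ScalarVolumes on the same grid.
#' @param params a \code{\link{registrationParams}}.
#' @param verbose print per-level objective values.
#' @return list: \code{midpoint} (ScalarVolume), \code{halfForward} and
#'   \code{halfBackward} (DisplacementFields exp(-v/2), exp(+v/2)),
#'   \code{fullWarp} (DisplacementField exp(v)), \code{velocity},
#'   \code{objective} (per-level numeric traces), \code{improved} (logical).
#' @export
registerSymmetric <- function(baseline, followup,
                              params = registrationParams(),
                              verbose = FALSE) {
  stopifnot(is(baseline, "ScalarVolume"), is(followup, "ScalarVolume"))
  if (!identical(dim(voxelData(baseline)), dim(voxelData(followup))) ||
      any(abs(voxelSpacing(baseline) - voxelSpacing(followup)) > 1e-9))
    stop("baseline and follow-up must share grid and spacing")
  if (any(!is.finite(voxelData(baseline))) ||
      any(!is.finite(voxelData(followup))))
    stop("images must be finite")

  I1full <- voxelData(baseline)
  I2full <- voxelData(followup)
  sp0 <- voxelSpacing(baseline)
  L <- params@levels

  # estimation runs on noise-suppressed images; outputs use the raw ones
  I1est <- if (params@imageFwhmMm > 0)
    smoothVolume(I1full, params@imageFwhmMm, sp0) else I1full
  I2est <- if (params@imageFwhmMm > 0)
    smoothVolume(I2full, params@imageFwhmMm, sp0) else I2full

  pyr1 <- list(I1est); pyr2 <- list(I2est); sps <- list(sp0)
  if (L > 1) for (l in 2:L) {
    pyr1[[l]] <- downsample2(pyr1[[l - 1]])
    pyr2[[l]] <- downsample2(pyr2[[l - 1]])
    sps[[l]] <- sps[[l - 1]] * 2
  }

  steps <- params@squaringSteps
  v <- NULL
  traces <- vector("list", L)
  improvedAny <- FALSE

  for (lev in L:1) {
    I1 <- pyr1[[lev]]; I2 <- pyr2[[lev]]; sp <- sps[[lev]]
    d <- dim(I1)
    if (is.null(v)) {
      v <- array(0, c(d, 3))
    } else {
      vNew <- array(0, c(d, 3))
      for (c in 1:3) vNew[, , , c] <- upsampleTo(v[, , , c], d)
      v <- vNew
    }
    thr <- 0.05 * max(max(I1), max(I2))
    mask <- (I1 > thr) | (I2 > thr)
    nm <- sum(mask)
    sscale <- mean(sp)
    # support mask: updates are confined to the content neighbourhood so
    # noise-only background cannot accumulate a random-walk deformation
    support <- mask
    for (dil in 1:2) {
      grown <- support
      for (axis in 1:3) for (s in c(-1L, 1L))
        grown <- grown | shift3d(support, axis, s)
      support <- grown
    }
    supportN <- as.numeric(support)

    evalObj <- function(vv) {
      hf <- expDispRaw(-vv / 2, sp, steps)
      hb <- expDispRaw(vv / 2, sp, steps)
      A <- sampleWarped(I1, hf, sp, clampEdge = FALSE, outside = 0)
      B <- sampleWarped(I2, hb, sp, clampEdge = FALSE, outside = 0)
      list(obj = sum(((A - B)[mask])^2) / nm, A = A, B = B)
    }

    st <- evalObj(v)
    trace <- st$obj
    # images already identical (up to numerical noise): nothing to estimate
    scale0 <- mean(I1[mask]^2)
    if (st$obj <= 1e-12 * max(scale0, 1e-12)) improvedAny <- TRUE
    stepScale <- 1
    iters <- params@iterations[L - lev + 1]  # iterations are coarsest-first
    for (it in seq_len(iters)) {
      r <- st$A - st$B
      gA <- gradient3d(st$A, sp)
      gB <- gradient3d(st$B, sp)
      Jx <- (gA[[1]] + gB[[1]]) / 2
      Jy <- (gA[[2]] + gB[[2]]) / 2
      Jz <- (gA[[3]] + gB[[3]]) / 2
      den <- Jx^2 + Jy^2 + Jz^2 + r^2 / sscale^2
      q <- ifelse(den > 1e-12, r / den, 0)
      upd <- array(0, c(d, 3))
      upd[, , , 1] <- supportN *
        gaussSmoothMm(q * Jx, params@fluidSigmaMm, sp)
      upd[, , , 2] <- supportN *
        gaussSmoothMm(q * Jy, params@fluidSigmaMm, sp)
      upd[, , , 3] <- supportN *
        gaussSmoothMm(q * Jz, params@fluidSigmaMm, sp)

      accepted <- FALSE
      for (attempt in 1:3) {
        vTry <- v + stepScale * upd
        if (params@diffusionSigmaMm > 0)
          for (c in 1:3)
            vTry[, , , c] <- gaussSmoothMm(vTry[, , , c],
                                           params@diffusionSigmaMm, sp)
        stTry <- evalObj(vTry)
        if (stTry$obj <= trace[length(trace)] * (1 + 1e-12)) {
          v <- vTry; st <- stTry; accepted <- TRUE
          break
        }
        stepScale <- stepScale / 2
      }
      if (!accepted) break
      improvedAny <- improvedAny || st$obj < trace[1]
      prev <- trace[length(trace)]
      trace <- c(trace, st$obj)
      stepScale <- min(1, stepScale * 1.2)
      # stop once the relative per-iteration improvement is below tolerance
      if (prev - st$obj < params@tol * max(prev, 1e-12)) break
    }
    traces[[lev]] <- trace
    if (verbose)
      message(sprintf("level %d: obj %.4g -> %.4g (%d iters)",
                      lev, trace[1], trace[length(trace)], length(trace) - 1))
  }

  if (!improvedAny) {
    warning("registration could not improve on identity; returning identity")
    v <- array(0, c(dim(I1full), 3))
  }

  sp <- sp0
  hf <- expDispRaw(-v / 2, sp, steps)
  hb <- expDispRaw(v / 2, sp, steps)
  A <- sampleWarped(I1full, hf, sp, clampEdge = FALSE, outside = 0)
  B <- sampleWarped(I2full, hb, sp, clampEdge = FALSE, outside = 0)
  full <- expDispRaw(v, sp, steps)

  list(midpoint = ScalarVolume((A + B) / 2, sp),
       halfForward = DisplacementField(hf, sp),
       halfBackward = DisplacementField(hb, sp),
       fullWarp = DisplacementField(full, sp),
       velocity = DisplacementField(v, sp),
       objective = traces,
       improved = improvedAny)
}

# scaling-and-squaring on a raw 4-D array
expDispRaw <- function(v, sp, steps) {
  u <- v / 2^steps
  for (i in seq_len(steps)) u <- composeDisp(u, u, sp)
  u
}
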