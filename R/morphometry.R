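#' Annualized atrophy rate from compartment volumes
#'
#' rate = 100 * (followup - baseline) / baseline / interval, in percent per
#' year (negative = loss). This is the linear annualization used for the
#' volumetric summaries; it agrees with geometric JD annualization to first
#' order for small rates.
#'
#' @param baselineVolume,followupVolume volumes in mm^3 (baseline > 0).
#' @param intervalYears inter-scan interval (> 0).
#' @return percent per year.
#' @export
annualizedAtrophyRate <- function(baselineVolume, followupVolume,
                                  intervalYears) {
  if (any(baselineVolume <= 0)) stop("baselineVolume must be > 0")
  if (any(intervalYears <= 0)) stop("intervalYears must be > 0")
  100 * (followupVolume - baselineVolume) / baselineVolume / intervalYears
}

#' Volume of selected label classes
#'
#' @param labels a LabelVolume.
#' @param classes label classes to include (e.g. c("gyrus","sulcus")).
#' @return volume in mm^3 (voxel count times voxel volume).
#' @export
compartmentVolume <- function(labels, classes) {
  stopifnot(is(labels, "LabelVolume"), length(classes) >= 1)
  m <- classMask(labels, classes)
  n <- sum(m)
  if (n == 0) warning("empty class selection")
  n * prod(voxelSpacing(labels))
}

#' Mean Jacobian determinant over a tissue mask
#'
#' @param jd a JacobianMap.
#' @param mask logical array on the same grid.
#' @return list(mean, sd, n).
#' @export
tissueMeanJd <- function(jd, mask) {
  stopifnot(is(jd, "JacobianMap"))
  x <- voxelData(jd)
  if (!identical(dim(x), dim(mask))) stop("mask grid mismatch")
  vals <- x[mask & !is.na(x)]
  if (length(vals) == 0) stop("empty mask")
  list(mean = mean(vals), sd = if (length(vals) > 1) sd(vals) else 0,
       n = length(vals))
}

#' Per-ROI mean Jacobian determinant table
#'
#' One row per non-empty cortical ROI (classes gyrus and sulcus); ROIs of
#' other classes are included when \code{includeNonCortical} is TRUE. Means
#' are unweighted voxel means. Empty ROIs are omitted with a message.
#'
#' @param jd a JacobianMap.
#' @param labels a LabelVolume on the same grid.
#' @param includeNonCortical include WM/subcortical/CSF labels.
#' @return data.frame(roi_id, roi_name, class, mean_jd, n_voxels).
#' @export
roiMeanJd <- function(jd, labels, includeNonCortical = FALSE) {
  stopifnot(is(jd, "JacobianMap"), is(labels, "LabelVolume"))
  x <- voxelData(jd)
  lab <- voxelData(labels)
  if (!identical(dim(x), dim(lab))) stop("label grid mismatch")
  tab <- labelTable(labels)
  keep <- if (includeNonCortical) tab$class != "background" else
    tab$class %in% c("gyrus", "sulcus")
  tab <- tab[keep, , drop = FALSE]
  ok <- !is.na(x)
  sums <- tapply(x[ok], factor(lab[ok], levels = tab$id), sum)
  cnts <- tapply(x[ok], factor(lab[ok], levels = tab$id), length)
  cnts[is.na(cnts)] <- 0
  empty <- cnts == 0
  if (any(empty))
    message(sum(empty), " ROI(s) with zero voxels omitted")
  data.frame(roi_id = tab$id[!empty], roi_name = tab$name[!empty],
             class = tab$class[!empty],
             mean_jd = as.numeric(sums[!empty] / cnts[!empty]),
             n_voxels = as.integer(cnts[!empty]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Percentage of significant voxels in a corrected p map
#'
#' @param pMap array of corrected p values in [0, 1].
#' @param mask logical array.
#' @param alpha significance level.
#' @return percent of mask voxels with p < alpha.
#' @export
percentSignificantVoxels <- function(pMap, mask, alpha = 0.05) {
  if (any(pMap < 0 | pMap > 1, na.rm = TRUE)) stop("p values must be in [0,1]")
  n <- sum(mask)
  if (n == 0) stop("empty mask")
  100 * sum(pMap[mask] < alpha, na.rm = TRUE) / n
}

#' Per-subject summary of a Jacobian determinant map
#'
#' Produces the summary measures analysed downstream: mean annualized JD over
#' the GM, WM and whole-brain masks, annualized atrophy rates per compartment
#' (linear rate of the JD-integrated compartment volume), and the per-ROI mean
#' JD table.
#'
#' @param id subject id.
#' @param jdTotal raw (interval) JacobianMap of the full warp.
#' @param labels LabelVolume on the same grid.
#' @param intervalYears inter-scan interval (> 0).
#' @return list: \code{summary} one-row data.frame
#'   (id, mean_jd_gm, mean_jd_wm, mean_jd_brain, rate_gm, rate_wm,
#'   rate_brain, interval_years), and \code{roi} the ROI table with id column.
#' @export
subjectSummary <- function(id, jdTotal, labels, intervalYears) {
  stopifnot(is(jdTotal, "JacobianMap"), !isAnnualized(jdTotal))
  ann <- suppressWarnings(annualizeJd(jdTotal, intervalYears))
  masks <- list(gm = tissueMask(labels, "GM"), wm = tissueMask(labels, "WM"))
  masks$brain <- masks$gm | masks$wm
  means <- lapply(masks, function(m) tissueMeanJd(ann, m)$mean)
  vv <- prod(voxelSpacing(labels))
  tot <- voxelData(jdTotal)
  rates <- lapply(masks, function(m) {
    v0 <- sum(m) * vv
    v1 <- sum(tot[m], na.rm = TRUE) * vv
    annualizedAtrophyRate(v0, v1, intervalYears)
  })
  roi <- roiMeanJd(ann, labels)
  roi <- cbind(id = id, roi, stringsAsFactors = FALSE)
  list(summary = data.frame(id = id, mean_jd_gm = means$gm,
                            mean_jd_wm = means$wm,
                            mean_jd_brain = means$brain,
                            rate_gm = rates$gm, rate_wm = rates$wm,
                            rate_brain = rates$brain,
                            interval_years = intervalYears,
                            stringsAsFactors = FALSE),
       roi = roi)
}
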