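#' Read and write volumes as NIfTI-1
#'
#' Volumes are stored float32 with an RAS affine derived from the voxel
#' spacing (origin at the first voxel); displacement fields as 4-D NIfTI with
#' the vector component on the last axis (mm); Jacobian maps carry an
#' accompanying JSON sidecar recording the annualization state.
#'
#' @param path file path (.nii or .nii.gz).
#' @param type one of "scalar", "label", "displacement", "jd".
#' @return the corresponding S4 object.
#' @export
readVolume <- function(path, type = c("scalar", "label", "displacement",
                                      "jd")) {
  type <- match.arg(type)
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  a <- as.array(img)
  attributes(a) <- list(dim = dim(a))
  switch(type,
    scalar = ScalarVolume(a, sp),
    label = {
      storage.mode(a) <- "integer"
      tabPath <- sub("\\.nii(\\.gz)?$", "_labels.csv", path)
      if (!file.exists(tabPath))
        stop("label table not found: ", tabPath)
      gPath <- sub("\\.nii(\\.gz)?$", "_geometry.json", path)
      if (file.exists(gPath)) {
        geo <- jsonlite::read_json(gPath, simplifyVector = TRUE)
        attr(a, "geometry") <- geo
      }
      LabelVolume(a, sp, utils::read.csv(tabPath, stringsAsFactors = FALSE))
    },
    displacement = DisplacementField(a, sp),
    jd = {
      sc <- jdSidecarPath(path)
      meta <- if (file.exists(sc)) jsonlite::read_json(sc) else
        list(annualized = FALSE, intervalYears = NULL)
      JacobianMap(a, sp, annualized = isTRUE(meta$annualized),
                  intervalYears = if (is.null(meta$intervalYears)) NULL else
                    as.numeric(meta$intervalYears))
    })
}

#' @rdname readVolume
#' @param x a ScalarVolume, LabelVolume, DisplacementField or JacobianMap.
#' @export
writeVolume <- function(x, path) {
  a <- voxelData(x)
  sp <- voxelSpacing(x)
  geo <- attr(a, "geometry")
  attributes(a) <- list(dim = dim(a))
  dt <- if (is(x, "LabelVolume")) "int16" else "float"
  nd <- length(dim(a))
  pd <- c(-1, sp, rep(0, 4))
  if (nd == 4) pd[5] <- 1
  img <- RNifti::asNifti(a, reference = list(pixdim = pd), datatype = dt)
  RNifti::writeNifti(img, path)
  written <- path
  if (is(x, "LabelVolume")) {
    tabPath <- sub("\\.nii(\\.gz)?$", "_labels.csv", path)
    utils::write.csv(labelTable(x), tabPath, row.names = FALSE)
    written <- c(written, tabPath)
    if (!is.null(geo)) {
      gPath <- sub("\\.nii(\\.gz)?$", "_geometry.json", path)
      jsonlite::write_json(geo, gPath, auto_unbox = TRUE, digits = NA)
      written <- c(written, gPath)
    }
  }
  if (is(x, "JacobianMap")) {
    sc <- jdSidecarPath(path)
    jsonlite::write_json(list(annualized = isAnnualized(x),
                              intervalYears = x@intervalYears),
                         sc, auto_unbox = TRUE, null = "null")
    written <- c(written, sc)
  }
  invisible(written)
}

jdSidecarPath <- function(path) sub("\\.nii(\\.gz)?$", ".json", path)

#' Read and write cohort tables
#'
#' The cohort CSV uses fixed column names: id, group, age_years, sex,
#' scanner, interval_years, tsi_months, lesion, microbleed, pta, gcs,
#' icv_mm3. Missing required columns are an error (named); unknown columns
#' produce a warning and are kept.
#'
#' @param path CSV file path.
#' @return data.frame.
#' @export
readCohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("id", "group", "age_years", "sex", "scanner",
                "interval_years", "icv_mm3")
  optional <- c("tsi_months", "lesion", "microbleed", "pta", "gcs")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("cohort CSV missing required column(s): ",
         paste(missing, collapse = ", "))
  unknown <- setdiff(names(df), c(required, optional))
  if (length(unknown))
    warning("unknown cohort column(s): ", paste(unknown, collapse = ", "))
  if (any(df$interval_years <= 0)) stop("interval_years must be > 0")
  df
}

#' @rdname readCohort
#' @param df data.frame to write.
#' @export
writeCohort <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
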