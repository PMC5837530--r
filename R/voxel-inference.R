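#' Voxelwise general linear model
#'
#' Ordinary least squares at every voxel of a subject stack, returning the t
#' statistic for one contrast column with n - p degrees of freedom.
#'
#' @param stack 4-D array (x, y, z, subject); subject order must match
#'   \code{design} rows.
#' @param design data.frame of per-subject covariates.
#' @param formula model formula over \code{design} columns (default
#'   \code{~ group}).
#' @param contrast name of the design-matrix column to test; defaults to the
#'   first column whose name starts with "group".
#' @return list: \code{tMap} (3-D array), \code{df}, \code{contrast},
#'   \code{X} (the design matrix).
#' @export
fitVoxelGlm <- function(stack, design, formula = ~ group, contrast = NULL) {
  d <- dim(stack)
  if (length(d) != 4) stop("stack must be a 4-D array (x, y, z, subject)")
  n <- d[4]
  if (nrow(design) != n) stop("design rows must match stack subjects")
  X <- model.matrix(formula, design)
  p <- ncol(X)
  if (n <= p) stop("more design columns than subjects")
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[setdiff(seq_len(p), qrX$pivot[seq_len(qrX$rank)])]
    stop("design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  if (is.null(contrast)) {
    contrast <- grep("^group", colnames(X), value = TRUE)[1]
    if (is.na(contrast)) stop("no group column found; supply `contrast`")
  }
  if (!contrast %in% colnames(X)) stop("unknown contrast column: ", contrast)
  cvec <- as.numeric(colnames(X) == contrast)

  Y <- matrix(stack, nrow = prod(d[1:3]), ncol = n)
  XtXinv <- chol2inv(chol(crossprod(X)))
  beta <- tcrossprod(XtXinv, X) %*% t(Y)      # p x V
  res <- t(Y) - X %*% beta                     # n x V
  dfres <- n - p
  sigma2 <- colSums(res^2) / dfres
  cb <- as.numeric(crossprod(cvec, beta))
  cvar <- as.numeric(crossprod(cvec, XtXinv %*% cvec))
  tvals <- cb / sqrt(pmax(sigma2 * cvar, .Machine$double.eps))
  list(tMap = array(tvals, d[1:3]), df = dfres, contrast = contrast, X = X)
}

#' Threshold-free cluster enhancement
#'
#' Integrates cluster extent^E x height^H over thresholds h = dh, 2dh, ...,
#' with dh = max-stat / nSteps per sign. Negative statistics are enhanced on
#' the negated map and returned with negative sign (sign-split), so the output
#' carries the direction of the input.
#'
#' @param stat 3-D statistic array.
#' @param params a \code{\link{tfceParams}}.
#' @param mask logical array (default: all voxels).
#' @param dh explicit integration step; the default (NULL) uses
#'   max-stat / nSteps per sign. A fixed dh makes the enhancement exactly
#'   monotone in the input statistics.
#' @return 3-D array of signed enhanced values.
#' @export
tfceEnhance <- function(stat, params = tfceParams(), mask = NULL,
                        dh = NULL) {
  d <- dim(stat)
  if (is.null(mask)) mask <- array(TRUE, d)
  if (!any(mask)) stop("empty mask")
  if (any(!is.finite(stat[mask]))) stop("non-finite statistics in mask")
  if (is.null(dh)) dh <- -1
  pos <- tfce_cpp(as.double(pmax(stat, 0)), as.logical(mask), as.integer(d),
                  params@E, params@H, dh, params@nSteps, params@connectivity)
  neg <- tfce_cpp(as.double(pmax(-stat, 0)), as.logical(mask), as.integer(d),
                  params@E, params@H, dh, params@nSteps, params@connectivity)
  array(pos - neg, d)
}

#' Permutation-corrected voxelwise inference
#'
#' Freedman-Lane scheme: nuisance covariates are regressed out, the reduced-
#' model residuals are permuted and the full model refitted, building the null
#' distribution of the maximum TFCE statistic per sign. Corrected p values use
#' the add-one estimator p = (1 + #[perm max >= TFCE]) / (m + 1); two-sided
#' inference applies a Bonferroni factor of 2 across the two sign tails. In
#' exhaustive mode all distinct group relabelings are enumerated instead of
#' sampled (intended for designs whose nuisance is the intercept only) and the
#' add-one estimator is replaced by the exact enumeration fraction.
#'
#' @param stack 4-D array (x, y, z, subject).
#' @param design data.frame of covariates including the group factor.
#' @param formula full-model formula (default \code{~ group}).
#' @param contrast contrast column (see \code{\link{fitVoxelGlm}}).
#' @param m number of permutations (default 1000; the study-scale default for
#'   final maps is 10000).
#' @param seed RNG seed for sampled permutations.
#' @param exhaustive enumerate all distinct group relabelings.
#' @param tfce a \code{\link{tfceParams}}.
#' @param mask logical array (default all).
#' @return list: \code{pMap} (corrected two-sided p), \code{tMap},
#'   \code{tfceMap}, \code{nullMax} (matrix pos/neg), \code{mEffective}.
#' @export
permutationCorrect <- function(stack, design, formula = ~ group,
                               contrast = NULL, m = 1000L, seed = 1L,
                               exhaustive = FALSE, tfce = tfceParams(),
                               mask = NULL) {
  d <- dim(stack)
  n <- d[4]
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  fit <- fitVoxelGlm(stack, design, formula, contrast)
  contrast <- fit$contrast
  X <- fit$X
  ci <- which(colnames(X) == contrast)
  Z <- X[, -ci, drop = FALSE]

  Y <- matrix(stack, nrow = prod(d[1:3]), ncol = n)
  gammaHat <- qr.solve(Z, t(Y))
  fitted0 <- Z %*% gammaHat
  E <- t(Y) - fitted0                      # n x V reduced-model residuals

  enh <- function(tmap) {
    list(pos = tfce_cpp(as.double(pmax(tmap, 0)), as.logical(mask),
                        as.integer(d[1:3]), tfce@E, tfce@H, -1, tfce@nSteps,
                        tfce@connectivity),
         neg = tfce_cpp(as.double(pmax(-tmap, 0)), as.logical(mask),
                        as.integer(d[1:3]), tfce@E, tfce@H, -1, tfce@nSteps,
                        tfce@connectivity))
  }
  obs <- enh(fit$tMap)

  tFor <- function(Yn) {
    XtXinv <- chol2inv(chol(crossprod(X)))
    beta <- tcrossprod(XtXinv, X) %*% Yn
    res <- Yn - X %*% beta
    sigma2 <- colSums(res^2) / fit$df
    cvar <- XtXinv[ci, ci]
    array(beta[ci, ] / sqrt(pmax(sigma2 * cvar, .Machine$double.eps)), d[1:3])
  }

  perms <- NULL
  if (exhaustive) {
    gcol <- X[, ci]
    if (length(unique(gcol)) != 2)
      stop("exhaustive mode needs a two-level group contrast")
    pos1 <- which(gcol == max(gcol))
    pos0 <- which(gcol == min(gcol))
    sets <- combn(n, length(pos1))
    mEff <- ncol(sets)
    if (m < mEff)
      message("exhaustive mode: using all ", mEff, " distinct relabelings")
    if (m > mEff)
      message("requested ", m, " permutations capped at ", mEff,
              " distinct relabelings")
    perms <- lapply(seq_len(mEff), function(j) {
      pidx <- integer(n)
      pidx[pos1] <- sets[, j]
      pidx[pos0] <- setdiff(seq_len(n), sets[, j])
      pidx
    })
  } else {
    mEff <- m
    perms <- withSeed(seed, lapply(seq_len(m), function(j) sample.int(n)))
  }

  nullMax <- matrix(0, length(perms), 2,
                    dimnames = list(NULL, c("pos", "neg")))
  for (j in seq_along(perms)) {
    Yp <- fitted0 + E[perms[[j]], , drop = FALSE]
    ej <- enh(tFor(Yp))
    nullMax[j, ] <- c(max(ej$pos), max(ej$neg))
  }

  countGe <- function(values, nulls) {
    sn <- sort(nulls)
    length(sn) - findInterval(values, sn, left.open = TRUE)
  }
  if (exhaustive) {
    pPos <- countGe(obs$pos, nullMax[, "pos"]) / mEff
    pNeg <- countGe(obs$neg, nullMax[, "neg"]) / mEff
  } else {
    pPos <- (1 + countGe(obs$pos, nullMax[, "pos"])) / (mEff + 1)
    pNeg <- (1 + countGe(obs$neg, nullMax[, "neg"])) / (mEff + 1)
  }
  tvec <- as.vector(fit$tMap)
  pMap <- ifelse(tvec >= 0, pmin(1, 2 * pPos), pmin(1, 2 * pNeg))
  pMap[!as.vector(mask)] <- NA_real_
  list(pMap = array(pMap, d[1:3]), tMap = fit$tMap,
       tfceMap = array(obs$pos - obs$neg, d[1:3]),
       nullMax = nullMax, mEffective = mEff, contrast = contrast)
}
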