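#' Simulate a longitudinal phantom cohort
#'
#' Draws subject records with group-specific demographics (ages, sex and
#' scanner mixes, log-normal inter-scan intervals and times since injury,
#' clinical flags) emulating a two-group longitudinal morphometry study
#' (cases n = 61, controls n = 32 by default), then generates each subject's
#' ground-truth deformation and, optionally, the baseline/follow-up image
#' pair. All draws derive from the master seed via stable per-subject streams,
#' so results are reproducible under any subject ordering.
#'
#' @param nCase,nControl group sizes (>= 2).
#' @param atrophy an \code{\link{atrophySpec}}.
#' @param phantom a \code{\link{phantomSpec}}.
#' @param seed master seed.
#' @param makeImages synthesize image pairs (set FALSE for summary-level
#'   studies, which need only the ground truth).
#' @param makeFields build per-subject deformation fields and analytic JD
#'   maps (FALSE gives a rates-only ground truth, for large-n calibration
#'   studies; implies no images).
#' @param template optional pre-built phantom (list template/labels) to reuse.
#' @return list: \code{cohort} (data.frame: id, group, age_years, sex,
#'   scanner, interval_years, tsi_months, lesion, microbleed, pta, gcs,
#'   icv_mm3), \code{truth} (per-subject ground-truth lists),
#'   \code{pairs} (per-subject baseline/follow-up, or NULL),
#'   \code{template}, \code{labels}, and \code{realizedRates} (group means of
#'   drawn GM/WM rates).
#' @export
simulateCohort <- function(nCase, nControl, atrophy = atrophySpec(),
                           phantom = phantomSpec(), seed = 1L,
                           makeImages = TRUE, makeFields = TRUE,
                           template = NULL) {
  stopifnot(nCase >= 2, nControl >= 2)
  if (!makeFields) makeImages <- FALSE
  if (is.null(template) && makeFields)
    template <- buildTemplatePhantom(phantom)
  labels <- template$labels

  cohort <- withSeed(deriveSeed(seed, "cohort-records"), {
    n <- nCase + nControl
    grp <- rep(c("case", "control"), c(nCase, nControl))
    id <- sprintf("%s%03d", ifelse(grp == "case", "P", "C"),
                  c(seq_len(nCase), seq_len(nControl)))
    age <- ifelse(grp == "case", rnorm(n, 41.55, 12.77), rnorm(n, 34.22, 10.29))
    age <- pmin(pmax(age, 18), 80)
    sex <- ifelse(runif(n) < ifelse(grp == "case", 49 / 61, 18 / 32), "M", "F")
    scanner <- ifelse(runif(n) < ifelse(grp == "case", 36 / 61, 13 / 32),
                      "A", "B")
    interval <- ifelse(grp == "case",
                       rlnorm(n, log(13.08 / 12), 0.39),
                       rlnorm(n, log(12.72 / 12), 0.12))
    interval <- pmin(pmax(interval, 0.3), 4)
    tsi <- ifelse(grp == "case", rlnorm(n, log(11.71), 1.27), NA_real_)
    lesion <- ifelse(grp == "case", runif(n) < atrophy@lesionProb, FALSE)
    microbleed <- ifelse(grp == "case", runif(n) < 29 / 61, FALSE)
    pta <- ifelse(grp == "case", runif(n) < 56 / 61, FALSE)
    gcs <- ifelse(grp == "case" & runif(n) < 28 / 61,
                  round(pmin(pmax(rnorm(n, 8.36, 4.92), 3), 15)), NA_real_)
    icv <- rnorm(n, ifelse(sex == "M", 1.55e6, 1.40e6), 1.2e5)
    data.frame(id = id, group = grp, age_years = age, sex = sex,
               scanner = scanner, interval_years = interval,
               tsi_months = tsi, lesion = lesion, microbleed = microbleed,
               pta = pta, gcs = gcs, icv_mm3 = icv,
               stringsAsFactors = FALSE)
  })

  truth <- vector("list", nrow(cohort))
  pairs <- if (makeImages) vector("list", nrow(cohort)) else NULL
  names(truth) <- cohort$id
  if (makeImages) names(pairs) <- cohort$id
  for (i in seq_len(nrow(cohort))) {
    rec <- cohort[i, ]
    if (!makeFields) {
      truth[[i]] <- list(
        rates = drawSubjectRates(atrophy, rec$group,
                                 deriveSeed(seed, paste0("def-", rec$id))),
        intervalYears = rec$interval_years)
      next
    }
    def <- drawSubjectDeformation(atrophy, rec, labels,
                                  deriveSeed(seed, paste0("def-", rec$id)))
    truth[[i]] <- def$truth
    if (makeImages) {
      pairs[[i]] <- synthesizePair(template$template, def$pullback, rec,
                                   phantom,
                                   deriveSeed(seed, paste0("img-", rec$id)),
                                   labels = labels,
                                   lesionRadiusMm = atrophy@lesionRadiusMm)
      pairs[[i]]$forward <- def$forward
    }
  }

  drawn <- do.call(rbind, lapply(truth, function(t) t$rates[c("GM", "WM")]))
  realized <- stats::aggregate(drawn, list(group = cohort$group), mean)

  list(cohort = cohort, truth = truth, pairs = pairs,
       template = template$template, labels = labels,
       realizedRates = realized)
}

#' Simulate neuropsychological panels coupled to atrophy
#'
#' Scores for four tests (Trail Making B-A, People recall, WASI Similarities,
#' choice reaction time) at baseline and follow-up are generated by a
#' Gaussian copula against each subject's true atrophy summary: the latent
#' Pearson correlation is set to 2*sin(pi*rho/6) so the population Spearman
#' correlation equals the requested \code{targetRho}. Marginals are normal
#' with study-like means/SDs per test and visit. Missingness is applied per
#' cell at the study-like rates (reproducible from the seed).
#'
#' @param records cohort data.frame (needs \code{id}).
#' @param atrophySummary numeric vector (one per record row): the subject's
#'   true summary atrophy measure (e.g. mean GM annual JD).
#' @param targetRho 4 x 2 matrix (tests x visits baseline/followup) of target
#'   Spearman correlations, or a single number recycled. Defaults reproduce
#'   the study-like pattern with a follow-up memory correlation of 0.51.
#' @param missRate 4 x 2 matrix of per-cell missingness probabilities.
#' @param seed integer seed.
#' @return long data.frame: id, visit ("baseline"/"followup"), test, score
#'   (NA when missing).
#' @export
simulateNeuropsych <- function(records, atrophySummary, targetRho = NULL,
                               missRate = NULL, seed = 1L) {
  tests <- c("tmt_b_minus_a", "people_recall", "wasi_similarities",
             "choice_rt")
  visits <- c("baseline", "followup")
  if (is.null(targetRho))
    targetRho <- matrix(c(0.09, 0.14, 0.36, 0.01,
                          0.07, 0.51, -0.06, 0.43), 4, 2,
                        dimnames = list(tests, visits))
  if (length(targetRho) == 1)
    targetRho <- matrix(targetRho, 4, 2)
  dimnames(targetRho) <- list(tests, visits)
  if (any(abs(targetRho) > 1)) stop("|targetRho| must be <= 1")
  if (is.null(missRate))
    missRate <- matrix(c(4, 4, 25, 14, 17, 17, 38, 44) / 61, 4, 2)
  dimnames(missRate) <- list(tests, visits)
  marg <- list(
    tmt_b_minus_a = list(baseline = c(37.9, 29.2), followup = c(33.1, 29.2)),
    people_recall = list(baseline = c(23.5, 7.7), followup = c(25.6, 8.8)),
    wasi_similarities = list(baseline = c(36.7, 5.0), followup = c(34.7, 5.9)),
    choice_rt = list(baseline = c(497, 102), followup = c(541, 112)))

  n <- nrow(records)
  stopifnot(length(atrophySummary) == n)
  withSeed(seed, {
    # normal scores of the atrophy ranks: exact copula marginal
    za <- qnorm(rank(atrophySummary, ties.method = "first") / (n + 1))
    out <- list()
    for (v in visits) for (te in tests) {
      rho <- targetRho[te, v]
      r <- 2 * sin(pi * rho / 6)
      z <- if (abs(r) >= 1) sign(r) * za else
        r * za + sqrt(1 - r^2) * rnorm(n)
      ms <- marg[[te]][[v]]
      score <- ms[1] + ms[2] * z
      miss <- runif(n) < missRate[te, v]
      score[miss] <- NA_real_
      out[[paste(v, te)]] <- data.frame(id = records$id, visit = v,
                                        test = te, score = score,
                                        stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, out)
    row.names(df) <- NULL
    df
  })
}

#' Simulate per-ROI summary tables from the mixed-effects model
#'
#' Generates cortical ROI mean-JD tables (plus a minimal cohort) directly at
#' the summary level, for replicate-scale studies of the sulcus-versus-gyrus
#' mixed model that do not need images: per subject a random intercept and a
#' random class slope, plus fixed group, class and group-by-class effects on
#' the annualized JD scale, with ROI-level residual noise.
#'
#' @param nCase,nControl group sizes.
#' @param nGyral,nSulcal cortical ROIs per class.
#' @param mu control gyral mean annual JD.
#' @param betaGroup fixed case effect (JD units).
#' @param betaClass fixed sulcus effect.
#' @param betaInteraction group-by-class (case-sulcus) effect.
#' @param tauIntercept,tauSlope random intercept/slope SDs.
#' @param sigma ROI-level residual SD.
#' @param seed integer seed.
#' @return list: \code{roi} (data.frame id, roi_id, roi_name, class,
#'   mean_jd, n_voxels), \code{cohort} (id, group, age_years, sex, scanner,
#'   interval_years, icv_mm3, lesion).
#' @export
simulateRoiSummaries <- function(nCase, nControl, nGyral = 24L,
                                 nSulcal = 24L, mu = 0.9945,
                                 betaGroup = -0.008, betaClass = 0.002,
                                 betaInteraction = -0.001,
                                 tauIntercept = 0.012, tauSlope = 0.002,
                                 sigma = 0.004, seed = 1L) {
  withSeed(seed, {
    n <- nCase + nControl
    grp <- rep(c("case", "control"), c(nCase, nControl))
    id <- sprintf("%s%03d", ifelse(grp == "case", "P", "C"),
                  c(seq_len(nCase), seq_len(nControl)))
    cohort <- data.frame(
      id = id, group = grp,
      age_years = pmin(pmax(rnorm(n, 38, 12), 18), 80),
      sex = sample(c("M", "F"), n, replace = TRUE),
      scanner = sample(c("A", "B"), n, replace = TRUE),
      interval_years = rlnorm(n, log(1.09), 0.3),
      icv_mm3 = rnorm(n, 1.5e6, 1.2e5),
      lesion = grp == "case" & runif(n) < 0.672,
      stringsAsFactors = FALSE)
    b0 <- rnorm(n, 0, tauIntercept)
    b1 <- rnorm(n, 0, tauSlope)
    cls <- rep(c("gyrus", "sulcus"), c(nGyral, nSulcal))
    roiName <- sprintf("%s_%02d", ifelse(cls == "gyrus", "G", "S"),
                       seq_along(cls))
    rows <- lapply(seq_len(n), function(i) {
      isCase <- grp[i] == "case"
      isSulc <- cls == "sulcus"
      mj <- mu + betaGroup * isCase + betaClass * isSulc +
        betaInteraction * isCase * isSulc + b0[i] + b1[i] * isSulc +
        rnorm(length(cls), 0, sigma)
      data.frame(id = id[i], roi_id = 10L + seq_along(cls) - 1L,
                 roi_name = roiName, class = cls, mean_jd = mj,
                 n_voxels = 50L, stringsAsFactors = FALSE)
    })
    list(roi = do.call(rbind, rows), cohort = cohort)
  })
}
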