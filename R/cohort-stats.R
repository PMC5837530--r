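#' Adjusted group comparison of a summary measure
#'
#' Linear model: outcome ~ group + age + sex + ICV + scanner, reporting the
#' group coefficient with its SE, t and p. The group factor is releveled so
#' the reported effect is case minus control.
#'
#' @param summaries per-subject summary data.frame (needs \code{id} and the
#'   outcome column).
#' @param cohort cohort data.frame (id, group, age_years, sex, scanner,
#'   icv_mm3).
#' @param outcome name of the outcome column in \code{summaries}.
#' @return object of class \code{dbmModelFit}: coefficients table (b, se, t,
#'   p), \code{groupEffect} row, \code{n}, \code{logLik}.
#' @export
fitGroupAdjusted <- function(summaries, cohort, outcome = "mean_jd_gm") {
  df <- merge(summaries, cohort, by = "id")
  if (!outcome %in% names(df)) stop("unknown outcome: ", outcome)
  y <- df[[outcome]]
  if (sd(y) == 0) stop("outcome is constant")
  df$group <- factor(df$group, levels = c("control", "case"))
  df$.y <- y
  X <- model.matrix(~ group + age_years + sex + icv_mm3 + scanner, df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[setdiff(seq_len(ncol(X)),
                               qrX$pivot[seq_len(qrX$rank)])]
    stop("collinear covariate column(s): ", paste(bad, collapse = ", "))
  }
  fit <- lm(.y ~ group + age_years + sex + icv_mm3 + scanner, df)
  makeModelFit(fit, effect = "groupcase", n = nrow(df))
}

makeModelFit <- function(fit, effect = NULL, n = NULL) {
  sm <- summary(fit)$coefficients
  tab <- data.frame(term = rownames(sm), b = sm[, 1], se = sm[, 2],
                    t = sm[, 3], p = sm[, 4], row.names = NULL,
                    stringsAsFactors = FALSE)
  out <- list(coefficients = tab,
              groupEffect = if (!is.null(effect) && effect %in% tab$term)
                tab[tab$term == effect, ] else NULL,
              n = if (is.null(n)) length(resid(fit)) else n,
              logLik = as.numeric(logLik(fit)))
  class(out) <- "dbmModelFit"
  out
}

#' @export
print.dbmModelFit <- function(x, ...) {
  cat("Model fit (n =", x$n, ", logLik =", signif(x$logLik, 6), ")\n")
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Hierarchical partitioning of R-squared
#'
#' Decomposes the full-model R^2 of a least-squares regression into each
#' predictor's independent contribution I (the average, over all predictor
#' orderings, of the incremental R^2 when that predictor enters) and joint
#' contribution J = marginal R^2 - I. I is computed by the subset-size
#' weighting identity (Shapley value) over all 2^k predictor subsets rather
#' than explicit ordering enumeration. The I values sum exactly to the
#' full-model R^2.
#'
#' @param outcome numeric response vector.
#' @param predictors data.frame of k predictors (numeric or factor).
#' @return object of class \code{dbmPartition}: data.frame
#'   (predictor, independent, joint, marginal) and \code{fullR2}.
#' @export
hierarchicalPartition <- function(outcome, predictors) {
  stopifnot(is.data.frame(predictors), ncol(predictors) >= 1)
  k <- ncol(predictors)
  if (k > 12) stop("too many predictors (k > 12)")
  n <- length(outcome)
  if (n <= k + 1) stop("need n > k + 1 observations")
  tss <- sum((outcome - mean(outcome))^2)
  if (tss == 0) stop("outcome is constant")

  r2 <- numeric(2^k)               # index = bitmask + 1
  r2[1] <- 0
  for (s in 1:(2^k - 1)) {
    sel <- which(bitwAnd(s, bitwShiftL(1L, 0:(k - 1))) > 0)
    X <- model.matrix(~ ., predictors[, sel, drop = FALSE])
    if (qr(X)$rank < ncol(X))
      stop("rank-deficient subset fit: predictors ",
           paste(names(predictors)[sel], collapse = ", "))
    f <- lm.fit(X, outcome)
    r2[s + 1] <- 1 - sum(f$residuals^2) / tss
  }

  lfact <- lgamma(seq_len(k + 1))  # lfact[i] = log((i-1)!)
  I <- numeric(k)
  for (j in seq_len(k)) {
    bit <- bitwShiftL(1L, j - 1L)
    acc <- 0
    for (s in 0:(2^k - 1)) {
      if (bitwAnd(s, bit) > 0) next
      ssize <- sum(bitwAnd(s, bitwShiftL(1L, 0:(k - 1))) > 0)
      w <- exp(lfact[ssize + 1] + lfact[k - ssize] - lfact[k + 1])
      acc <- acc + w * (r2[bitwOr(s, bit) + 1] - r2[s + 1])
    }
    I[j] <- acc
  }
  marginal <- vapply(seq_len(k),
                     function(j) r2[bitwShiftL(1L, j - 1L) + 1], numeric(1))
  out <- list(table = data.frame(predictor = names(predictors),
                                 independent = I, joint = marginal - I,
                                 marginal = marginal, row.names = NULL,
                                 stringsAsFactors = FALSE),
              fullR2 = r2[2^k])
  class(out) <- "dbmPartition"
  out
}

#' @export
print.dbmPartition <- function(x, ...) {
  cat("Hierarchical partitioning (full R2 =", signif(x$fullR2, 4), ")\n")
  print(x$table, digits = 3)
  invisible(x)
}

#' Sulcus-versus-gyrus mixed-effects interaction
#'
#' Linear mixed model on per-ROI mean JD values: fixed effects for group,
#' ROI class (gyrus/sulcus) and covariates, a random intercept per subject and
#' a random class slope per subject. The group-by-class interaction is tested
#' by a likelihood-ratio comparison of maximum-likelihood fits with and
#' without the interaction term. If the random-effects covariance is singular
#' the model is refitted with a random intercept only (with a warning).
#'
#' @param roiTable data.frame from \code{\link{roiMeanJd}} rows per subject
#'   (columns id, class, mean_jd).
#' @param cohort cohort data.frame.
#' @param covariates include age/sex/ICV/scanner fixed effects (needs those
#'   columns in \code{cohort}).
#' @return list: \code{main} and \code{interaction} (dbmModelFit),
#'   \code{lrtP}, \code{interactionEstimate}, \code{interactionSe},
#'   \code{singular}.
#' @export
fitSulcalInteraction <- function(roiTable, cohort, covariates = TRUE) {
  df <- merge(roiTable, cohort, by = "id")
  df <- df[df$class %in% c("gyrus", "sulcus"), ]
  perClass <- table(df$id, df$class)
  if (any(perClass < 2))
    stop("every subject needs >= 2 ROIs of each class")
  df$group <- factor(df$group, levels = c("control", "case"))
  df$class <- factor(df$class, levels = c("gyrus", "sulcus"))
  if (covariates) {
    df$age_c <- as.numeric(scale(df$age_years))
    df$icv_c <- as.numeric(scale(df$icv_mm3))
    fixed <- "group + class + age_c + sex + icv_c + scanner"
  } else {
    fixed <- "group + class"
  }
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  reTerm <- "(1 + class | id)"
  fMain <- as.formula(paste("mean_jd ~", fixed, "+", reTerm))
  fInt <- as.formula(paste("mean_jd ~", fixed, "+ group:class +", reTerm))
  main <- suppressWarnings(lme4::lmer(fMain, df, REML = FALSE, control = ctrl))
  inter <- suppressWarnings(lme4::lmer(fInt, df, REML = FALSE, control = ctrl))
  singular <- lme4::isSingular(main, tol = 1e-5) ||
    lme4::isSingular(inter, tol = 1e-5)
  if (singular) {
    warning("singular random-effects covariance; refitting intercept-only")
    fMain <- as.formula(paste("mean_jd ~", fixed, "+ (1 | id)"))
    fInt <- as.formula(paste("mean_jd ~", fixed,
                             "+ group:class + (1 | id)"))
    main <- suppressWarnings(lme4::lmer(fMain, df, REML = FALSE,
                                        control = ctrl))
    inter <- suppressWarnings(lme4::lmer(fInt, df, REML = FALSE,
                                         control = ctrl))
  }
  lrt <- anova(main, inter)
  lrtP <- lrt$`Pr(>Chisq)`[2]
  co <- lme4::fixef(inter)
  se <- sqrt(diag(as.matrix(vcov(inter))))
  iname <- grep(":", names(co), value = TRUE)[1]
  list(main = mixedModelFit(main), interaction = mixedModelFit(inter),
       lrtP = lrtP, interactionEstimate = unname(co[iname]),
       interactionSe = unname(se[iname]), singular = singular)
}

mixedModelFit <- function(fit) {
  co <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  tv <- co / se
  tab <- data.frame(term = names(co), b = unname(co), se = unname(se),
                    t = unname(tv), p = 2 * pnorm(-abs(unname(tv))),
                    stringsAsFactors = FALSE)
  out <- list(coefficients = tab, groupEffect = NULL,
              n = stats::nobs(fit), logLik = as.numeric(logLik(fit)))
  class(out) <- "dbmModelFit"
  out
}

#' Spearman correlations between neuropsychological scores and summary JD
#'
#' For each of the four tests and three visits (baseline, follow-up, and
#' longitudinal change = follow-up minus baseline) the Spearman correlation
#' against the tissue mean JD is computed on pairwise-complete cases.
#' Benjamini-Hochberg FDR is applied across the 12 test-by-visit cells,
#' separately per tissue. Cells with fewer than 5 complete pairs or all-tied
#' scores are flagged and excluded from the adjustment.
#'
#' @param panel long panel from \code{\link{simulateNeuropsych}} (id, visit,
#'   test, score).
#' @param summaries per-subject summary data.frame (id, mean_jd_gm,
#'   mean_jd_wm).
#' @param tissues named list mapping tissue label to summary column.
#' @return data.frame(test, visit, tissue, rho, p, p_fdr, n, flagged).
#' @export
neuropsychCorrelations <- function(panel, summaries,
                                   tissues = c(gm = "mean_jd_gm",
                                               wm = "mean_jd_wm")) {
  tests <- unique(panel$test)
  wide <- list()
  for (te in tests) {
    b <- panel[panel$test == te & panel$visit == "baseline", c("id", "score")]
    f <- panel[panel$test == te & panel$visit == "followup", c("id", "score")]
    names(b)[2] <- "baseline"; names(f)[2] <- "followup"
    w <- merge(b, f, by = "id", all = TRUE)
    w$change <- w$followup - w$baseline
    wide[[te]] <- w
  }
  rows <- list()
  for (ti in names(tissues)) {
    jd <- summaries[, c("id", tissues[[ti]])]
    names(jd)[2] <- "jd"
    for (te in tests) for (vi in c("baseline", "followup", "change")) {
      w <- merge(wide[[te]][, c("id", vi)], jd, by = "id")
      names(w)[2] <- "score"
      cc <- complete.cases(w$score, w$jd)
      nOk <- sum(cc)
      flagged <- FALSE
      rho <- NA_real_; pv <- NA_real_
      if (nOk < 5 || length(unique(w$score[cc])) < 2) {
        flagged <- TRUE
      } else {
        ct <- suppressWarnings(cor.test(w$score[cc], w$jd[cc],
                                        method = "spearman", exact = FALSE))
        rho <- unname(ct$estimate); pv <- ct$p.value
      }
      rows[[paste(ti, te, vi)]] <- data.frame(test = te, visit = vi,
                                              tissue = ti, rho = rho, p = pv,
                                              n = nOk, flagged = flagged,
                                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out$p_fdr <- NA_real_
  for (ti in names(tissues)) {
    sel <- out$tissue == ti & !out$flagged
    out$p_fdr[sel] <- p.adjust(out$p[sel], method = "BH")
  }
  out[, c("test", "visit", "tissue", "rho", "p", "p_fdr", "n", "flagged")]
}

#' Longitudinal change in neuropsychological scores
#'
#' Per test: mixed-effects model score ~ visit + (1 | subject); the visit
#' effect is the estimated mean follow-up minus baseline change.
#'
#' @param panel long panel (id, visit, test, score).
#' @return named list of dbmModelFit, one per test.
#' @export
scoreChangeModels <- function(panel) {
  tests <- unique(panel$test)
  out <- list()
  for (te in tests) {
    df <- panel[panel$test == te & !is.na(panel$score), ]
    both <- intersect(df$id[df$visit == "baseline"],
                      df$id[df$visit == "followup"])
    if (length(both) == 0)
      stop("no subject with both visits for test ", te)
    df$visit <- factor(df$visit, levels = c("baseline", "followup"))
    fit <- suppressWarnings(
      lme4::lmer(score ~ visit + (1 | id), df, REML = TRUE,
                 control = lme4::lmerControl(calc.derivs = FALSE,
                                             check.conv.singular = "ignore")))
    out[[te]] <- mixedModelFit(fit)
  }
  out
}

#' Re-run a statistic on a filtered subcohort
#'
#' Applies a row predicate to the cohort (e.g. excluding lesioned cases),
#' checks both groups remain represented, filters any additional data.frames
#' that carry an \code{id} column to the retained subjects, and calls the
#' supplied function.
#'
#' @param cohort cohort data.frame.
#' @param keep logical vector (length nrow) or predicate function applied to
#'   the cohort data.frame returning one.
#' @param fun function to call; it receives the filtered versions of the
#'   arguments in \code{...} plus \code{cohort = filtered cohort} if it has a
#'   \code{cohort} argument.
#' @param ... further arguments to \code{fun}; data.frames with an \code{id}
#'   column are filtered to retained subjects.
#' @return list: \code{result}, \code{excluded} (count), \code{keptIds}.
#' @export
subgroupRerun <- function(cohort, keep, fun, ...) {
  if (is.function(keep)) keep <- keep(cohort)
  stopifnot(is.logical(keep), length(keep) == nrow(cohort))
  sub <- cohort[keep, , drop = FALSE]
  if (!all(c("case", "control") %in% unique(sub$group)))
    stop("filter emptied a group")
  args <- lapply(list(...), function(a) {
    if (is.data.frame(a) && "id" %in% names(a)) a[a$id %in% sub$id, , drop = FALSE]
    else a
  })
  if ("cohort" %in% names(formals(fun))) args$cohort <- sub
  list(result = do.call(fun, args), excluded = sum(!keep), keptIds = sub$id)
}
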