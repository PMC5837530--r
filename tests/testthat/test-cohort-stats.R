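simulateSummaryCohort <- function(n1, n2, effect, sd1 = 0.02, sd2 = 0.01,
                                  seed = 1) {
  set.seed(seed)
  n <- n1 + n2
  grp <- rep(c("case", "control"), c(n1, n2))
  co <- data.frame(id = sprintf("S%03d", seq_len(n)), group = grp,
                   age_years = rnorm(n, 38, 12),
                   sex = sample(c("M", "F"), n, TRUE),
                   scanner = sample(c("A", "B"), n, TRUE),
                   icv_mm3 = rnorm(n, 1.5e6, 1.2e5),
                   lesion = grp == "case" & runif(n) < 0.5,
                   stringsAsFactors = FALSE)
  y <- 0.99 + effect * (grp == "case") +
    rnorm(n, 0, ifelse(grp == "case", sd1, sd2))
  list(cohort = co,
       summaries = data.frame(id = co$id, mean_jd_gm = y,
                              stringsAsFactors = FALSE))
}

test_that("adjusted group model recovers a known JD offset", {
  hits <- 0
  for (r in 1:100) {
    sim <- simulateSummaryCohort(100, 100, effect = -0.010, seed = r)
    fit <- fitGroupAdjusted(sim$summaries, sim$cohort)
    g <- fit$groupEffect
    hits <- hits + (g$b - 1.96 * g$se <= -0.010 &&
                      -0.010 <= g$b + 1.96 * g$se)
  }
  expect_gte(hits, 90)
})

test_that("adjusted group model holds its type-I error", {
  rej <- 0
  for (r in 1:200) {
    sim <- simulateSummaryCohort(50, 50, effect = 0, seed = 1000 + r)
    fit <- fitGroupAdjusted(sim$summaries, sim$cohort)
    rej <- rej + (fit$groupEffect$p < 0.05)
  }
  expect_gte(rej / 200, 0.01)
  expect_lte(rej / 200, 0.09)
})

test_that("degenerate designs are rejected with informative errors", {
  sim <- simulateSummaryCohort(20, 20, effect = 0, seed = 5)
  const <- sim$summaries
  const$mean_jd_gm <- 1
  expect_error(fitGroupAdjusted(const, sim$cohort), "constant")
  dup <- sim$cohort
  dup$age_years <- as.numeric(dup$group == "case")  # duplicates the contrast
  expect_error(fitGroupAdjusted(sim$summaries, dup), "collinear")
})

test_that("hierarchical partitioning satisfies its exact identities", {
  set.seed(9)
  n <- 60
  x1 <- rnorm(n)
  y <- 2 * x1 + rnorm(n)
  hp1 <- hierarchicalPartition(y, data.frame(x1 = x1))
  expect_equal(hp1$table$independent, hp1$fullR2, tolerance = 1e-12)
  expect_equal(hp1$table$joint, 0, tolerance = 1e-12)

  # exactly orthogonal predictors (also orthogonal to the intercept):
  # I equals marginal R2, J = 0
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 2), n, 2))))[, 2:3]
  yo <- Q[, 1] + 0.5 * Q[, 2] + rnorm(n, 0, 0.5)
  hpo <- hierarchicalPartition(yo, data.frame(a = Q[, 1], b = Q[, 2]))
  expect_equal(hpo$table$independent, hpo$table$marginal, tolerance = 1e-10)
  expect_equal(hpo$table$joint, c(0, 0), tolerance = 1e-10)

  # correlated k = 3: subset weighting equals explicit ordering average
  S <- matrix(0.6, 3, 3); diag(S) <- 1
  X <- matrix(rnorm(n * 3), n, 3) %*% chol(S)
  yc <- X %*% c(1, -0.5, 0.25) + rnorm(n)
  preds <- data.frame(p1 = X[, 1], p2 = X[, 2], p3 = X[, 3])
  hp <- hierarchicalPartition(as.numeric(yc), preds)
  oracle <- partitionByOrderings(as.numeric(yc), preds)
  expect_equal(hp$table$independent, oracle, tolerance = 1e-10)
  expect_equal(sum(hp$table$independent), hp$fullR2, tolerance = 1e-10)
})

test_that("sulcal interaction is null when classes are identical", {
  sim <- simulateRoiSummaries(10, 8, betaClass = 0, betaInteraction = 0,
                              tauSlope = 0, sigma = 0.004, seed = 3)
  roi <- sim$roi
  # copy each subject's gyral values onto its sulcal ROIs
  for (id in unique(roi$id)) {
    g <- roi$mean_jd[roi$id == id & roi$class == "gyrus"]
    roi$mean_jd[roi$id == id & roi$class == "sulcus"] <- g
  }
  fit <- suppressWarnings(fitSulcalInteraction(roi, sim$cohort,
                                               covariates = FALSE))
  expect_lt(abs(fit$interactionEstimate), 1e-8)
})

test_that("sulcal interaction model enforces its data contract", {
  sim <- simulateRoiSummaries(6, 4, seed = 4)
  broken <- sim$roi[sim$roi$class == "gyrus" | sim$roi$roi_id == 34, ]
  expect_error(fitSulcalInteraction(broken, sim$cohort), "2 ROIs")
})

test_that("neuropsych correlations respect Spearman invariances and FDR", {
  set.seed(11)
  n <- 40
  ids <- sprintf("S%03d", 1:n)
  jd <- sort(rnorm(n, 0.98, 0.01))
  sm <- data.frame(id = ids, mean_jd_gm = jd, mean_jd_wm = jd)
  # strictly monotone score in JD at follow-up
  panel <- data.frame(
    id = rep(ids, 2),
    visit = rep(c("baseline", "followup"), each = n),
    test = "people_recall",
    score = c(rnorm(n), rank(jd) * 2),
    stringsAsFactors = FALSE)
  res <- neuropsychCorrelations(panel, sm)
  fu <- res[res$visit == "followup" & res$tissue == "gm", ]
  expect_equal(fu$rho, 1)
  # monotone transform of the score leaves per-visit rho unchanged
  # (the derived change scores are legitimately affected)
  panel2 <- panel
  panel2$score[panel2$visit == "followup"] <-
    exp(panel2$score[panel2$visit == "followup"] / 10)
  res2 <- neuropsychCorrelations(panel2, sm)
  perVisit <- res$visit %in% c("baseline", "followup")
  expect_equal(res2$rho[perVisit], res$rho[perVisit], tolerance = 1e-12)
  # adjusted p never below raw p; family is the 12 cells per tissue
  ok <- !res$flagged
  expect_true(all(res$p_fdr[ok] >= res$p[ok] - 1e-15))
  expect_equal(sum(res$tissue == "gm"), 3)  # one test here, 3 visits
  expect_true(all(res$p_fdr[ok] <= 1))
})

test_that("BH adjustment follows the step-up arithmetic", {
  # hand-checked: (0.01, 0.02, 0.04) with m = 3 -> (0.03, 0.03, 0.04)
  expect_equal(p.adjust(c(0.01, 0.02, 0.04), "BH"), c(0.03, 0.03, 0.04))
})

test_that("score change models estimate the visit effect", {
  n <- 30
  ids <- sprintf("S%03d", 1:n)
  base <- rnorm(n, 20, 5)
  panel <- data.frame(
    id = rep(ids, 2),
    visit = rep(c("baseline", "followup"), each = n),
    test = "people_recall",
    score = c(base, base + 2),
    stringsAsFactors = FALSE)
  fits <- scoreChangeModels(panel)
  b <- fits$people_recall$coefficients
  expect_equal(b$b[b$term == "visitfollowup"], 2, tolerance = 1e-8)

  same <- panel
  same$score <- rep(base, 2)
  fits0 <- suppressWarnings(scoreChangeModels(same))
  b0 <- fits0$people_recall$coefficients
  expect_lt(abs(b0$b[b0$term == "visitfollowup"]), 1e-8)

  # simulated change 2.0 with SD 8.2 at n = 41 recovered within 2 SE
  set.seed(21)
  ids41 <- sprintf("S%03d", 1:41)
  b41 <- rnorm(41, 23.5, 7.7)
  ch <- rnorm(41, 2, 8.2)
  p41 <- data.frame(id = rep(ids41, 2),
                    visit = rep(c("baseline", "followup"), each = 41),
                    test = "people_recall", score = c(b41, b41 + ch),
                    stringsAsFactors = FALSE)
  f41 <- scoreChangeModels(p41)$people_recall$coefficients
  est <- f41$b[f41$term == "visitfollowup"]
  se <- f41$se[f41$term == "visitfollowup"]
  expect_lt(abs(est - 2), 2 * se + 1e-9)
})

test_that("subgroup reruns filter consistently", {
  sim <- simulateSummaryCohort(30, 20, effect = -0.01, seed = 31)
  full <- fitGroupAdjusted(sim$summaries, sim$cohort)
  noop <- subgroupRerun(sim$cohort, rep(TRUE, 50), fitGroupAdjusted,
                        summaries = sim$summaries)
  expect_equal(noop$result$groupEffect$b, full$groupEffect$b)
  expect_equal(noop$excluded, 0)

  lf <- subgroupRerun(sim$cohort, function(co) !co$lesion, fitGroupAdjusted,
                      summaries = sim$summaries)
  expect_gt(lf$excluded, 0)
  # lesion-independent atrophy: estimate moves less than 2 SE
  expect_lt(abs(lf$result$groupEffect$b - full$groupEffect$b),
            2 * full$groupEffect$se)

  expect_error(subgroupRerun(sim$cohort, sim$cohort$group == "case",
                             fitGroupAdjusted, summaries = sim$summaries),
               "group")
})
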