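test_that("zero rates give identity deformation and unit Jacobian", {
  ph <- stdPhantom()
  def <- drawSubjectDeformation(uniformAtrophy(0), caseRecord(), ph$labels,
                                seed = 1)
  expect_equal(max(abs(voxelData(def$forward))), 0)
  expect_equal(max(abs(voxelData(def$truth$annualJd) - 1)), 0)
})

test_that("uniform -2 %/yr produces analytic mean JD of 0.98", {
  ph <- stdPhantom()
  def <- drawSubjectDeformation(uniformAtrophy(-2), caseRecord(), ph$labels,
                                seed = 1)
  aj <- voxelData(def$truth$annualJd)
  brain <- tissueMask(ph$labels, "brain")
  expect_equal(mean(aj[brain]), 0.98, tolerance = 1e-3)
  expect_true(all(voxelData(def$truth$jdTotal) > 0))
})

test_that("atrophy compounds geometrically over the interval", {
  ph <- stdPhantom()
  def <- drawSubjectDeformation(uniformAtrophy(-2), caseRecord(interval = 2),
                                ph$labels, seed = 1)
  jd <- voxelData(def$truth$jdTotal)
  brain <- tissueMask(ph$labels, "brain")
  # total compartment volume ratio after 2 years at -2 %/yr: 0.98^2
  expect_equal(mean(jd[brain]), 0.9604, tolerance = 0.5 * 0.9604 / 100)
})

test_that("analytic JD integrates to the simulated compartment ratio", {
  ph <- stdPhantom()
  def <- drawSubjectDeformation(atrophySpec(scannerOffset = 0,
                                            sulcalExcess = 1),
                                caseRecord(interval = 1.3), ph$labels,
                                seed = 42)
  jd <- voxelData(def$truth$jdTotal)
  for (tissue in c("GM", "WM")) {
    m <- tissueMask(ph$labels, tissue)
    target <- (1 + def$truth$rates[[tissue]] / 100)^1.3
    expect_equal(mean(jd[m]), target, tolerance = 0.005)
  }
})

test_that("pair synthesis is deterministic and respects the null case", {
  ph <- buildTemplatePhantom(cleanSpec())
  zero <- DisplacementField(array(0, c(dim(voxelData(ph$template)), 3)),
                            voxelSpacing(ph$template))
  pr <- synthesizePair(ph$template, zero, caseRecord(), cleanSpec(), seed = 2)
  expect_identical(voxelData(pr$baseline), voxelData(pr$followup))
  expect_identical(voxelData(pr$baseline), voxelData(ph$template))

  noisy <- phantomSpec()
  p1 <- synthesizePair(ph$template, zero, caseRecord(), noisy, seed = 7)
  p2 <- synthesizePair(ph$template, zero, caseRecord(), noisy, seed = 7)
  expect_identical(voxelData(p1$baseline), voxelData(p2$baseline))
  expect_identical(voxelData(p1$followup), voxelData(p2$followup))
  expect_false(identical(voxelData(p1$baseline), voxelData(p1$followup)))
})

test_that("focal lesions darken a sphere in both time points", {
  ph <- buildTemplatePhantom(cleanSpec())
  zero <- DisplacementField(array(0, c(dim(voxelData(ph$template)), 3)),
                            voxelSpacing(ph$template))
  pr <- synthesizePair(ph$template, zero, caseRecord(lesion = TRUE),
                       cleanSpec(), seed = 3, labels = ph$labels,
                       lesionRadiusMm = 9)
  img0 <- voxelData(ph$template)
  b <- voxelData(pr$baseline)
  lesioned <- which(b < img0 - 1)
  expect_gt(length(lesioned), 10)
  expect_lt(mean(b[lesioned]), 0.5 * mean(img0[lesioned]))
  f <- voxelData(pr$followup)
  expect_lt(mean(f[lesioned]), 0.5 * mean(img0[lesioned]))
})

test_that("field content pulled from outside the grid is rejected", {
  ph <- buildTemplatePhantom(cleanSpec())
  dims <- dim(voxelData(ph$template))
  huge <- DisplacementField(array(200, c(dims, 3)),
                            voxelSpacing(ph$template))
  expect_error(synthesizePair(ph$template, huge, caseRecord(), cleanSpec(),
                              seed = 1), "margin")
})

test_that("cohort rate draws are calibrated to the configured moments", {
  sim <- simulateCohort(200, 200, seed = 11, makeFields = FALSE)
  g <- sim$cohort$group
  gm <- vapply(sim$truth, function(t) t$rates[["GM"]], numeric(1))
  wm <- vapply(sim$truth, function(t) t$rates[["WM"]], numeric(1))
  expect_lt(abs(mean(gm[g == "case"]) - (-1.55)), 2 * 2.19 / sqrt(200))
  expect_lt(abs(mean(gm[g == "control"]) - (-0.55)), 2 * 1.13 / sqrt(200))
  expect_lt(abs(mean(wm[g == "case"]) - (-1.49)), 2 * 2.20 / sqrt(200))
  expect_lt(abs(mean(wm[g == "control"]) - 0.26), 2 * 1.11 / sqrt(200))
  # scanner assignment: binomial bound at n = 400
  expect_gt(mean(sim$cohort$scanner == "A"), 0.40)
  expect_lt(mean(sim$cohort$scanner == "A"), 0.60)
})

test_that("zero-variance draws equal the configured means exactly", {
  at <- atrophySpec(rateSd = matrix(0, 2, 2,
    dimnames = list(c("case", "control"), c("GM", "WM"))),
    scannerOffset = 0)
  sim <- simulateCohort(2, 2, atrophy = at, seed = 4, makeFields = FALSE)
  g <- sim$cohort$group
  gm <- vapply(sim$truth, function(t) t$rates[["GM"]], numeric(1))
  expect_equal(unname(gm[g == "case"]), c(-1.55, -1.55))
  expect_equal(unname(gm[g == "control"]), c(-0.55, -0.55))
})

test_that("neuropsych copula hits the target Spearman correlation", {
  rec <- data.frame(id = sprintf("S%03d", 1:500))
  atr <- rnorm(500)
  panel <- simulateNeuropsych(rec, atr, targetRho = 0.5,
                              missRate = matrix(0, 4, 2), seed = 8)
  sc <- panel$score[panel$visit == "followup" &
                      panel$test == "people_recall"]
  expect_lt(abs(cor(sc, atr, method = "spearman") - 0.5), 0.1)

  exact <- simulateNeuropsych(rec, atr, targetRho = 1,
                              missRate = matrix(0, 4, 2), seed = 8)
  sc1 <- exact$score[exact$visit == "baseline" & exact$test == "choice_rt"]
  expect_equal(cor(sc1, atr, method = "spearman"), 1)

  atr200 <- rnorm(200)
  nullp <- simulateNeuropsych(data.frame(id = sprintf("S%03d", 1:200)),
                              atr200, targetRho = 0,
                              missRate = matrix(0, 4, 2), seed = 9)
  sc0 <- nullp$score[nullp$visit == "baseline" & nullp$test == "people_recall"]
  expect_lt(abs(cor(sc0, atr200, method = "spearman")), 0.2)

  # missingness is reproducible from the seed
  a <- simulateNeuropsych(rec, atr, seed = 10)
  b <- simulateNeuropsych(rec, atr, seed = 10)
  expect_identical(is.na(a$score), is.na(b$score))
})
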