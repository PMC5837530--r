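test_that("voxelwise GLM matches the closed-form pooled t", {
  set.seed(1)
  y <- c(rnorm(6, 1), rnorm(5))
  stack <- array(y, c(1, 1, 1, 11))
  des <- data.frame(group = factor(rep(c("case", "control"), c(6, 5)),
                                   levels = c("control", "case")))
  f <- fitVoxelGlm(stack, des)
  tt <- t.test(y[1:6], y[7:11], var.equal = TRUE)
  expect_equal(f$tMap[1, 1, 1], unname(tt$statistic))
  expect_equal(f$df, 9)

  # identical groups give t = 0
  same <- array(rep(rnorm(1), 11), c(1, 1, 1, 11))
  same[] <- rep(c(1, 2), length.out = 11) # identical distribution per subject
  sameStack <- array(rep(as.vector(same[, , , 1]), 11), c(1, 1, 1, 11))
  f0 <- fitVoxelGlm(sameStack, des)
  expect_lt(abs(f0$tMap[1, 1, 1]), 1e-6)

  # reordering subjects together with design rows changes nothing
  set.seed(2)
  stack2 <- array(rnorm(8 * 4), c(2, 2, 2, 4))
  des2 <- data.frame(group = factor(c("case", "case", "control", "control"),
                                    levels = c("control", "case")),
                     age = c(30, 40, 35, 45))
  f1 <- fitVoxelGlm(stack2, des2, ~ group + age)
  ord <- c(3, 1, 4, 2)
  f2 <- fitVoxelGlm(stack2[, , , ord, drop = FALSE], des2[ord, ],
                    ~ group + age)
  expect_equal(f1$tMap, f2$tMap)

  # collinearity is reported with the offending column
  des3 <- cbind(des2, dup = as.numeric(des2$group == "case"))
  expect_error(fitVoxelGlm(stack2, des3, ~ group + dup), "dup")
})

test_that("TFCE matches a fine-step Riemann oracle on a uniform cluster", {
  d <- c(12, 12, 12)
  stat <- array(0, d)
  stat[4:9, 4:9, 4:9] <- 2.5
  coarse <- tfceEnhance(stat, tfceParams(nSteps = 100L))
  fine <- tfceEnhance(stat, tfceParams(nSteps = 10000L))
  inCl <- stat > 0
  expect_lt(max(abs(coarse[inCl] / fine[inCl] - 1)), 0.02)
  # analytic value for a constant cluster: e0^E * h0^(H+1) / (H+1)
  expect_equal(mean(fine[inCl]), sqrt(6^3) * 2.5^3 / 3, tolerance = 0.01)
  expect_true(all(coarse[!inCl] == 0))
  # all-zero map stays zero
  expect_equal(tfceEnhance(array(0, d)), array(0, d))
})

test_that("TFCE is local and monotone", {
  d <- c(14, 8, 8)
  two <- array(0, d)
  two[2:4, 2:4, 2:4] <- 1.5
  two[10:13, 2:5, 2:5] <- 2.2
  both <- tfceEnhance(two, tfceParams(nSteps = 200L))
  solo <- two; solo[10:13, 2:5, 2:5] <- 0
  one <- tfceEnhance(solo, tfceParams(nSteps = 200L))
  # values inside the first cluster are driven by that cluster alone;
  # equal step counts over each cluster's height make them comparable
  expect_equal(both[3, 3, 3], one[3, 3, 3], tolerance = 0.05)

  # monotonicity is exact for a fixed integration step
  set.seed(5)
  base <- array(rnorm(6^3), c(6, 6, 6))
  dh <- max(base) / 50
  e0 <- tfceEnhance(base, tfceParams(nSteps = 50L), dh = dh)
  for (i in 1:5) {
    bumped <- base
    idx <- sample(length(base), 1)
    bumped[idx] <- bumped[idx] + abs(rnorm(1))
    e1 <- tfceEnhance(bumped, tfceParams(nSteps = 50L), dh = dh)
    pos <- base > 0 & bumped > 0
    expect_true(all(e1[pos] >= e0[pos] - 1e-9))
  }
})

test_that("exhaustive permutation p values are enumeration fractions", {
  set.seed(7)
  stack <- array(rnorm(27 * 8), c(3, 3, 3, 8))
  stack[2, 2, 2, 1:4] <- stack[2, 2, 2, 1:4] + 3
  des <- data.frame(group = factor(rep(c("case", "control"), each = 4),
                                   levels = c("control", "case")))
  pc <- suppressMessages(
    permutationCorrect(stack, des, exhaustive = TRUE, m = 10000))
  expect_equal(pc$mEffective, 70)
  expect_true(all(pc$pMap >= 1 / 70))
  halves <- pc$pMap * 70 / 2
  expect_true(all(abs(halves - round(halves)) < 1e-9 | pc$pMap == 1))
})

test_that("sampled corrected p values stay near exhaustive values", {
  set.seed(8)
  stack <- array(rnorm(27 * 8), c(3, 3, 3, 8))
  stack[1:2, 1:2, 1:2, 1:4] <- stack[1:2, 1:2, 1:2, 1:4] + 2
  des <- data.frame(group = factor(rep(c("case", "control"), each = 4),
                                   levels = c("control", "case")))
  ex <- suppressMessages(
    permutationCorrect(stack, des, exhaustive = TRUE, m = 100))
  sa <- permutationCorrect(stack, des, m = 69, seed = 42)
  expect_true(all(sa$pMap >= 1 / 70 - 1e-12 & sa$pMap <= 1))
  # one-tailed p agreement within a generous binomial 95% envelope
  pEx <- ex$pMap / 2
  pSa <- sa$pMap / 2
  bound <- 2 * sqrt(pEx * (1 - pEx) / 69) + 1.5 / 70
  expect_true(all(abs(pSa - pEx) <= bound | ex$pMap >= 1))
})
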