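test_that("velocity exponentiation reproduces analytic flows", {
  dims <- c(20, 20, 20)
  sp <- c(2, 2, 2)
  # zero velocity -> identity
  zero <- DisplacementField(array(0, c(dims, 3)), sp)
  expect_equal(max(abs(voxelData(expVelocity(zero, 6)))), 0)

  # constant velocity -> pure translation in the interior
  v <- array(0, c(dims, 3)); v[, , , 1] <- 1
  tr <- expVelocity(DisplacementField(v, sp), 6)
  interior <- voxelData(tr)[5:16, 5:16, 5:16, ]
  expect_lt(max(abs(interior[, , , 1] - 1)), 1e-3)
  expect_lt(max(abs(interior[, , , 2:3])), 1e-3)

  # exp(v) composed with exp(-v) is near identity (inverse consistency)
  set.seed(3)
  vr <- array(rnorm(prod(dims) * 3, sd = 2), c(dims, 3))
  for (c in 1:3) vr[, , , c] <- smoothVolume(vr[, , , c], 12, spacing = sp)
  fw <- expVelocity(DisplacementField(vr, sp), 6)
  bw <- expVelocity(DisplacementField(-vr, sp), 6)
  comp <- longdbm:::composeDisp(voxelData(bw), voxelData(fw), sp)
  resMm <- sqrt(rowSums(matrix(comp, ncol = 3)^2))
  expect_lt(mean(resMm) / mean(sp), 0.05)

  expect_error(expVelocity(DisplacementField(array(c(NaN,
    rep(0, prod(dims) * 3 - 1)), c(dims, 3)), sp)), "finite")
})

test_that("Jacobian determinants match analytic values", {
  dims <- c(16, 16, 16)
  sp <- c(2, 2, 2)
  zero <- DisplacementField(array(0, c(dims, 3)), sp)
  expect_equal(max(abs(voxelData(jacobianMap(zero)) - 1)), 0)

  # linear contraction u(x) = (c-1) x with c = 0.98: JD = 0.98^3
  co <- longdbm:::coordArrays(dims, sp)
  u <- array(0, c(dims, 3))
  u[, , , 1] <- -0.02 * co$x; u[, , , 2] <- -0.02 * co$y
  u[, , , 3] <- -0.02 * co$z
  jd <- voxelData(jacobianMap(DisplacementField(u, sp)))
  expect_lt(max(abs(jd[2:15, 2:15, 2:15] - 0.98^3)), 1e-6)

  # small rigid rotation about the grid centre is volume preserving
  th <- 0.05
  ctr <- (dims - 1) / 2 * sp
  x <- co$x - ctr[1]; y <- co$y - ctr[2]
  u2 <- array(0, c(dims, 3))
  u2[, , , 1] <- cos(th) * x - sin(th) * y - x
  u2[, , , 2] <- sin(th) * x + cos(th) * y - y
  jd2 <- voxelData(jacobianMap(DisplacementField(u2, sp)))
  expect_lt(max(abs(jd2[2:15, 2:15, 2:15] - 1)), 5e-3)
})

test_that("annualization is geometric and validates input", {
  dims <- c(4, 4, 4)
  one <- JacobianMap(array(1, dims), c(1, 1, 1))
  expect_equal(voxelData(annualizeJd(one, 2.7)), array(1, dims))
  jd <- JacobianMap(array(0.96, dims), c(1, 1, 1))
  a1 <- annualizeJd(jd, 1)
  expect_equal(voxelData(a1), voxelData(jd))
  expect_true(isAnnualized(a1))
  a2 <- annualizeJd(jd, 2)
  expect_equal(voxelData(a2)[1], 0.979796, tolerance = 1e-6)
  expect_error(annualizeJd(jd, 0), "intervalYears")
  expect_error(annualizeJd(a2, 2), "already")
  neg <- JacobianMap(array(c(-1, rep(1, 63)), dims), c(1, 1, 1))
  expect_warning(res <- annualizeJd(neg, 1), "non-positive")
  expect_true(is.na(voxelData(res)[1]))
})

test_that("volume smoothing preserves constants and interior mass", {
  a <- array(5, c(10, 10, 10))
  expect_equal(smoothVolume(a, 8, spacing = c(2, 2, 2)), a)
  expect_identical(smoothVolume(a, 0, spacing = c(2, 2, 2)), a)
  set.seed(2)
  b <- array(0, c(24, 24, 24))
  b[9:16, 9:16, 9:16] <- rexp(512)
  sm <- smoothVolume(b, 6, spacing = c(2, 2, 2))
  expect_lt(abs(sum(sm) - sum(b)) / sum(b), 0.001)
})

test_that("registering an image to itself returns the identity", {
  ph <- buildTemplatePhantom(cleanSpec(gridShape = c(32L, 32L, 32L),
                                       voxelSizeMm = 4))
  img <- ph$template
  reg <- suppressWarnings(registerSymmetric(img, img))
  jd <- voxelData(jacobianMap(reg$fullWarp))
  expect_lt(max(abs(jd - 1)), 1e-6)
  expect_equal(voxelData(reg$midpoint), voxelData(img), tolerance = 1e-8)
})

test_that("mismatched grids are rejected", {
  a <- ScalarVolume(array(0, c(8, 8, 8)), c(1, 1, 1))
  b <- ScalarVolume(array(0, c(8, 8, 9)), c(1, 1, 1))
  expect_error(registerSymmetric(a, b), "grid")
  c2 <- ScalarVolume(array(0, c(8, 8, 8)), c(2, 1, 1))
  expect_error(registerSymmetric(a, c2), "grid")
})

test_that("objective traces are non-increasing over accepted steps", {
  ph <- buildTemplatePhantom(phantomSpec(gridShape = c(32L, 32L, 32L),
                                         voxelSizeMm = 4, noiseSd = 1))
  def <- drawSubjectDeformation(uniformAtrophy(-3), caseRecord(), ph$labels,
                                seed = 5)
  pr <- synthesizePair(ph$template, def$pullback, caseRecord(),
                       phantomSpec(gridShape = c(32L, 32L, 32L),
                                   voxelSizeMm = 4, noiseSd = 1),
                       seed = 6, labels = ph$labels)
  reg <- registerSymmetric(pr$baseline, pr$followup,
                           registrationParams(iterations = c(10L, 10L, 5L)))
  for (tr in reg$objective) expect_true(all(diff(tr) <= 1e-12))
  expect_true(reg$improved)
})
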