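test_that("annualized atrophy rate follows the linear formula", {
  expect_equal(annualizedAtrophyRate(1000, 1000, 1), 0)
  expect_equal(annualizedAtrophyRate(1000, 980, 1), -2)
  expect_equal(annualizedAtrophyRate(1200, 1164, 1.5), -2)
  expect_error(annualizedAtrophyRate(0, 10, 1), "baseline")
  expect_error(annualizedAtrophyRate(10, 10, 0), "interval")
})

test_that("compartment volumes are voxel counts times voxel volume", {
  ph <- stdPhantom()
  vWm <- compartmentVolume(ph$labels, "WM")
  expect_equal(vWm, sum(tissueMask(ph$labels, "WM")) * 27)
  vAll <- compartmentVolume(ph$labels,
                            c("gyrus", "sulcus", "subcortical-GM", "WM",
                              "CSF"))
  expect_equal(vAll, sum(voxelData(ph$labels) > 0) * 27)
  expect_error(compartmentVolume(ph$labels, "bone"), "unknown")
  expect_warning(v0 <- compartmentVolume(
    LabelVolume(array(0L, c(4, 4, 4)), c(1, 1, 1),
                data.frame(id = 0L, name = "background",
                           class = "background")), "background"), NA)
})

test_that("tissue mean JD reduces masked voxels correctly", {
  jd <- JacobianMap(array(0.98, c(6, 6, 6)), c(1, 1, 1))
  m <- array(TRUE, c(6, 6, 6))
  r <- tissueMeanJd(jd, m)
  expect_equal(r$mean, 0.98)
  expect_equal(r$sd, 0)
  one <- array(FALSE, c(6, 6, 6)); one[1] <- TRUE
  expect_equal(tissueMeanJd(jd, one)$n, 1)
  half <- array(c(0.96, 1), c(6, 6, 6))
  jd2 <- JacobianMap(half, c(1, 1, 1))
  expect_equal(tissueMeanJd(jd2, m)$mean, 0.98)
  expect_error(tissueMeanJd(jd, array(FALSE, c(6, 6, 6))), "empty")
})

test_that("ROI means track the labels and omit empty ROIs", {
  ph <- stdPhantom()
  dims <- dim(voxelData(ph$labels))
  jd <- JacobianMap(array(1, dims), voxelSpacing(ph$labels),
                    annualized = TRUE, intervalYears = 1)
  tab <- roiMeanJd(jd, ph$labels)
  expect_true(all(tab$mean_jd == 1))
  expect_true(all(tab$n_voxels > 0))
  ctab <- labelTable(ph$labels)
  expect_equal(nrow(tab), sum(ctab$class %in% c("gyrus", "sulcus")))

  # lower JD only inside sulcal labels
  x <- array(1, dims)
  x[classMask(ph$labels, "sulcus")] <- 0.95
  tab2 <- roiMeanJd(JacobianMap(x, voxelSpacing(ph$labels)), ph$labels)
  expect_true(all(tab2$mean_jd[tab2$class == "gyrus"] == 1))
  expect_true(all(tab2$mean_jd[tab2$class == "sulcus"] < 1))
})

test_that("percent significant voxels is a simple masked fraction", {
  m <- array(TRUE, c(4, 4, 4))
  expect_equal(percentSignificantVoxels(array(1, c(4, 4, 4)), m), 0)
  expect_equal(percentSignificantVoxels(array(0, c(4, 4, 4)), m), 100)
  p <- array(c(0.01, 0.99), c(4, 4, 4))
  expect_equal(percentSignificantVoxels(p, m), 50)
  expect_error(percentSignificantVoxels(array(2, c(4, 4, 4)), m), "0,1")
  expect_error(percentSignificantVoxels(p, array(FALSE, c(4, 4, 4))),
               "empty")
})

test_that("subject summaries agree with ground truth and Eq-1 linearity", {
  ph <- stdPhantom()
  def <- drawSubjectDeformation(uniformAtrophy(-2), caseRecord(), ph$labels,
                                seed = 3)
  s <- subjectSummary("P001", def$truth$jdTotal, ph$labels, 1)
  # recovered summaries sit on the simulated rate
  expect_equal(s$summary$mean_jd_gm, 0.98, tolerance = 5e-3)
  expect_equal(s$summary$mean_jd_wm, 0.98, tolerance = 5e-3)
  # Eq 1 (linear) and geometric annualization agree to first order
  expect_lt(abs(s$summary$rate_gm - 100 * (s$summary$mean_jd_gm - 1)), 0.1)
  expect_lt(abs(s$summary$rate_wm - 100 * (s$summary$mean_jd_wm - 1)), 0.1)
  expect_equal(sort(unique(s$roi$class)), c("gyrus", "sulcus"))
})
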