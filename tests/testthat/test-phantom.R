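test_that("template phantom build is deterministic", {
  a <- buildTemplatePhantom(phantomSpec(seed = 5L))
  b <- buildTemplatePhantom(phantomSpec(seed = 5L))
  expect_identical(voxelData(a$template), voxelData(b$template))
  expect_identical(voxelData(a$labels), voxelData(b$labels))
})

test_that("tissue classes partition the brain mask", {
  ph <- stdPhantom()
  lab <- voxelData(ph$labels)
  nBrain <- sum(lab > 0L)
  nGm <- sum(tissueMask(ph$labels, "GM"))
  nWm <- sum(tissueMask(ph$labels, "WM"))
  nCsf <- sum(tissueMask(ph$labels, "CSF"))
  expect_equal(nGm + nWm + nCsf, nBrain)
  # gyrus + sulcus exactly tile the cortical ribbon
  expect_equal(sum(classMask(ph$labels, "gyrus")) +
                 sum(classMask(ph$labels, "sulcus")),
               sum(tissueMask(ph$labels, "cortex")))
  tab <- labelTable(ph$labels)
  expect_gte(sum(tab$class == "gyrus"), 6)
  expect_gte(sum(tab$class == "sulcus"), 6)
})

test_that("class intensities are distinct before noise", {
  ph <- stdPhantom()
  img <- voxelData(ph$template)
  med <- vapply(c("WM", "CSF", "cortex"), function(t)
    median(img[tissueMask(ph$labels, t)]), numeric(1))
  expect_gt(med["WM"], med["cortex"])
  expect_gt(med["cortex"], med["CSF"])
  expect_equal(median(img[voxelData(ph$labels) == 0L]), 0)
})

test_that("zero fold count removes sulcal-depth modulation", {
  ph <- buildTemplatePhantom(phantomSpec(corticalFoldCount = 0L))
  lab <- voxelData(ph$labels)
  dims <- dim(lab)
  centre <- (dims + 1) / 2
  idx <- which(lab > 3L, arr.ind = TRUE)
  r <- sqrt(rowSums(sweep(idx, 2, centre)^2))
  cls <- labelTable(ph$labels)
  gy <- cls$id[cls$class == "gyrus"]
  isG <- lab[lab > 3L] %in% gy
  expect_true(any(isG) && any(!isG))
  expect_lt(abs(mean(r[isG]) - mean(r[!isG])), 0.1)
})

test_that("grids too small for a 2-voxel ribbon are rejected", {
  expect_error(buildTemplatePhantom(phantomSpec(gridShape = c(16L, 16L, 16L),
                                               voxelSizeMm = 3)),
               "ribbon")
  expect_error(phantomSpec(gridShape = c(8L, 48L, 48L)), "16")
})
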