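test_that("half-up rounding reproduces the printed precision rules", {
  expect_equal(roundHalfUp(5.161, 1), 5.2)
  expect_equal(roundHalfUp(65.72, 1), 65.7)
  expect_equal(roundHalfUp(0.25, 1), 0.3)
  expect_equal(roundHalfUp(-0.25, 1), -0.3)
  expect_equal(roundHalfUp(2.5, 0), 3)
  expect_equal(roundHalfUp(60.118, 1), 60.1)
})

test_that("volume comparison columns match the published per-case values", {
  expect_equal(volumeRatioPercent(5.08, 8.45), 60.1)
  expect_equal(volumeRatioPercent(2.40, 2.20), 109.1)
  expect_equal(volumeRatioPercent(4.00, 4.00), 100.0)
  expect_error(volumeRatioPercent(1, 0), "positive")

  expect_equal(volumeDifference(8.45, 5.08), 3.4)
  expect_equal(volumeDifference(2.20, 2.40), -0.2)
  expect_equal(volumeDifference(4.0, 4.0), 0.0)
})

test_that("dimension comparison columns follow the printed-input arithmetic", {
  expect_equal(dimensionPercentChange(2.0, 2.0), 0.0)
  # computed from the printed rounded inputs (the published cell derives
  # from unrounded source measurements and differs)
  expect_equal(dimensionPercentChange(3.7, 1.9), 48.6)
  expect_equal(dimensionPercentChange(3, 0), 100.0)
  expect_error(dimensionPercentChange(0, 1), "positive")

  expect_equal(dimensionDifference(3.9, 0.7), 3.2)
  expect_equal(dimensionDifference(2.2, 3.9), -1.7)
  expect_equal(dimensionDifference(1.1, 1.1), 0.0)
})

test_that("cohort summary reproduces the published median and average rows", {
  tab <- cohortPrinted()
  rows <- data.frame(mri_volume_cm3 = tab$mri_volume_cm3,
                     histo_volume_cm3 = tab$histo_volume_cm3,
                     volume_difference_cm3 = tab$printed_diff,
                     volume_ratio_pct = tab$printed_ratio)
  sm <- summarizeCohort(rows)
  expect_equal(sm["median", "mri_volume_cm3"], 4.0)
  expect_equal(sm["average", "mri_volume_cm3"], 5.2)
  expect_equal(sm["median", "histo_volume_cm3"], 2.6)
  expect_equal(sm["average", "histo_volume_cm3"], 2.8)
  expect_equal(sm["median", "volume_difference_cm3"], 1.0)
  expect_equal(sm["average", "volume_difference_cm3"], 2.4)
  expect_equal(sm["median", "volume_ratio_pct"], 66.7)
  expect_equal(sm["average", "volume_ratio_pct"], 65.7)

  # permutation invariance and the single-row degenerate case
  perm <- rows[sample.int(nrow(rows)), ]
  expect_equal(summarizeCohort(perm), sm)
  one <- summarizeCohort(rows[3, ])
  expect_equal(one["median", ], one["average", ], ignore_attr = TRUE)
  expect_error(summarizeCohort(rows[0, ]), "at least one")
})

test_that("table ingestion derives every comparison column", {
  rep <- reportFromTable(cohortVolumeTable())
  rows <- reportRows(rep)
  tab <- cohortPrinted()
  expect_equal(rows$volume_difference_cm3, tab$printed_diff)
  expect_equal(rows$volume_ratio_pct, tab$printed_ratio)
  expect_equal(rows$ap_difference_cm,
               roundHalfUp(tab$mri_ap_cm - tab$histo_ap_cm, 1))
  # ratio exceeds 100% exactly when histopathology outgrew the MRI model
  expect_equal(rows$volume_ratio_pct > 100,
               rows$histo_volume_cm3 > rows$mri_volume_cm3)
})

test_that("the mesh path composes the geometry primitives per case", {
  cases <- list()
  for (seed in c(71, 72, 73)) {
    ph <- generatePhantom(phantomSpec(seed, shrinkage = 0.95))
    mri <- applyTransform(maskToMesh(ph@mriMask),
                          fitLandmarkTransform(ph@landmarksMRI,
                                               ph@landmarksSpecimen))
    histo <- interpolateSurface(ph@contourStack, spacing = 1)
    cases[[sprintf("ph%d", seed)]] <- list(histo = histo, mri = mri)
  }
  rep <- buildReport(cases)
  rows <- reportRows(rep)
  expect_equal(nrow(rows), 3)
  # rows equal direct per-operation calls
  c1 <- cases[[1]]
  expect_equal(rows$mri_volume_cm3[1], roundHalfUp(meshVolume(c1$mri), 2))
  expect_equal(rows$volume_ratio_pct[1],
               volumeRatioPercent(meshVolume(c1$histo), meshVolume(c1$mri)))
  expect_equal(rows$cc_difference_cm[1],
               dimensionDifference(directionalExtent(c1$mri, "CC"),
                                   directionalExtent(c1$histo, "CC")))
  expect_equal(rows$mri_max_diameter_cm[1],
               roundHalfUp(maxDiameter(c1$mri), 1))
  # diameter dominates the per-axis MRI dims (within reporting rounding)
  expect_true(all(rows$mri_max_diameter_cm + 0.05 >=
                    pmax(rows$mri_ap_cm, rows$mri_cc_cm, rows$mri_lr_cm)))
  expect_equal(reportSummary(rep),
               summarizeCohort(rows))

  # a defective case is refused with its id in the message
  open <- TriangleMesh(vertices(cubeMesh(10)),
                       faces(cubeMesh(10))[-1, ], "open")
  bad <- cases
  bad[["bad_case"]] <- list(histo = open, mri = cases[[1]]$mri)
  expect_error(buildReport(bad), "bad_case")
})

test_that("reports serialize to CSV and JSON with stable columns", {
  rep <- reportFromTable(cohortVolumeTable())
  fc <- withr::local_tempfile(fileext = ".csv")
  fj <- withr::local_tempfile(fileext = ".json")
  writeReport(rep, fc)
  writeReport(rep, fj)
  back <- utils::read.csv(fc)
  expect_equal(nrow(back), 11) # 9 cases + median + average
  expect_equal(back$volume_ratio_pct[1:9], reportRows(rep)$volume_ratio_pct)
  expect_equal(back$case_id[10:11], c("median", "average"))
  j <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_equal(j$rows$mri_volume_cm3, reportRows(rep)$mri_volume_cm3)
  expect_equal(j$summary$volume_ratio_pct, c(66.7, 65.7))
})
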