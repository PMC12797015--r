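test_that("identical seeds generate bit-identical phantoms", {
  a <- generatePhantom(phantomSpec(1))
  b <- generatePhantom(phantomSpec(1))
  expect_identical(vertices(a@tumorMesh), vertices(b@tumorMesh))
  expect_identical(a@mriMask@voxels, b@mriMask@voxels)
  expect_identical(a@contourStack@slices, b@contourStack@slices)
  expect_identical(a@landmarksMRI@points, b@landmarksMRI@points)
  expect_identical(a@truth$transform@rotation, b@truth$transform@rotation)
  # and the generator does not disturb the caller's RNG stream
  set.seed(99); x <- stats::runif(1)
  set.seed(99); invisible(generatePhantom(phantomSpec(2)))
  expect_identical(stats::runif(1), x)
})

test_that("an unperturbed phantom matches the analytic ellipsoid", {
  ph <- generatePhantom(phantomSpec(2, semiAxes = c(20, 10, 5),
                                    perturbAmplitude = 0))
  analytic <- 4 / 3 * pi * 20 * 10 * 5 / 1000
  expect_lt(abs(ph@truth$volume_cm3 / analytic - 1), 0.01)
  expect_lt(abs(ph@truth$diameter_cm - 4), 0.02)
})

test_that("shrinkage scales the histology-side truth by its cube", {
  ph <- generatePhantom(phantomSpec(3, shrinkage = 0.95))
  expect_equal(ph@truth$histo_volume_cm3 / ph@truth$volume_cm3, 0.95^3,
               tolerance = 1e-12)
  # the grossed contours really are smaller than the unshrunk tumor
  expect_lt(planimetricVolume(ph@contourStack), ph@truth$volume_cm3)
})

test_that("parameters outside the cohort conditions are refused", {
  expect_error(phantomSpec(1, targetVolume = 20), "0.4, 12.6")
  expect_error(phantomSpec(1, nSlices = 30), "7, 21")
  expect_error(phantomSpec(1, mriSpacing = c(1, 1, 6)), "3, 4")
  expect_error(phantomSpec(1, shrinkage = 0.8), "0.94")
  expect_error(phantomSpec(1, perturbAmplitude = 0.5), "0.3")
  expect_error(phantomSpec(1, targetVolume = 12, semiAxes = c(5, 5, 5)),
               "unreachable")
})

test_that("mesh cross-sections match analytic level sets", {
  sph <- icosphereMesh(15, subdivisions = 4)
  st <- sliceMeshToContours(sph, 0, axis = c(0, 1, 0), thickness = 3)
  ct <- st@slices[[1]]$contours
  expect_length(ct, 1)
  r <- sqrt(rowSums(ct[[1]]$points^2))
  expect_true(all(abs(r - 15) < 0.1))

  far <- sliceMeshToContours(sph, 35, axis = c(0, 1, 0), thickness = 3)
  expect_length(far@slices[[1]]$contours, 0)

  ell <- ellipsoidMesh(c(20, 10, 5), subdivisions = 4)
  half <- sliceMeshToContours(ell, 2.5, axis = c(0, 0, 1), thickness = 1)
  pts <- half@slices[[1]]$contours[[1]]$points
  expect_lt(abs(max(abs(pts[, 1])) - 20 * sqrt(0.75)), 0.2)
  expect_lt(abs(max(abs(pts[, 2])) - 10 * sqrt(0.75)), 0.2)

  expect_error(sliceMeshToContours(
    TriangleMesh(vertices(sph), faces(sph)[-1, ], "open"), 0), "watertight")
})

test_that("voxelization labels exactly the interior voxel centres", {
  cube <- cubeMesh(10, center = c(5, 5, 5))
  lv <- rasterizeMesh(cube, spacing = c(1, 1, 1))
  expect_equal(sum(lv@voxels), 1000)
  lv2 <- rasterizeMesh(cube, spacing = c(1, 1, 4))
  expect_lt(abs(voxelCountVolume(lv2) - 1), 0.2)
  expect_error(rasterizeMesh(TriangleMesh(matrix(0, 0, 3),
                                          matrix(0L, 0, 3))), "empty")
})

test_that("phantom landmarks sit on the specimen and are non-degenerate", {
  for (seed in 4:6) {
    ph <- generatePhantom(phantomSpec(seed))
    p <- ph@landmarksSpecimen@points
    expect_gte(nrow(p), 4)
    ctr <- sweep(p, 2, colMeans(p))
    expect_gt(svd(ctr)$d[2], 1) # far from collinear
    # truth transform maps the MRI pins back onto the specimen pins
    mapped <- applyTransform(ph@landmarksMRI, ph@truth$transform)
    expect_equal(unname(mapped@points), unname(p), tolerance = 1e-9)
  }
})

test_that("well-sampled phantoms are recovered end to end", {
  # cohort-scale bodies with at least 10 grossing slabs and noiseless pins
  set.seed(900)
  vols <- stats::runif(20, 3, 12.6)
  for (seed in 901:920) {
    ph <- generatePhantom(phantomSpec(seed, shrinkage = 0.95, nSlices = 14,
                                      targetVolume = vols[seed - 900]))
    expect_gte(length(ph@contourStack@slices), 10)
    res <- suppressMessages(runCase(list(
      case_id = sprintf("ph%d", seed),
      mri_mask = ph@mriMask,
      contour_stack = ph@contourStack,
      landmarks_mri = ph@landmarksMRI,
      landmarks_specimen = ph@landmarksSpecimen)))
    expect_lt(max(abs(res$transform@rotation -
                        ph@truth$transform@rotation)), 1e-6)
    expect_lt(abs(meshVolume(res$mriMesh) / ph@truth$volume_cm3 - 1), 0.10)
    expect_lt(abs(meshVolume(res$histoMesh) / ph@truth$histo_volume_cm3 - 1),
              0.10)
    expect_lt(abs(reportRows(res$report)$volume_ratio_pct -
                    100 * 0.95^3), 5 + 2) # 5 points plus discretization
    # directional extents within one MRI slice / one grossing spacing
    sp <- diff(vapply(ph@contourStack@slices, `[[`, 0, "position"))[1]
    tol <- max(ph@mriMask@spacing[3], sp) / 10 + 0.05
    for (ax in c("LR", "AP", "CC"))
      expect_lt(abs(directionalExtent(res$mriMesh, ax) -
                      ph@truth$extents_cm[[ax]]), tol)
  }
})

test_that("phantom cases serialize to a complete on-disk case directory", {
  ph <- generatePhantom(phantomSpec(8, shrinkage = 0.96))
  d <- withr::local_tempdir()
  writePhantomCase(ph, d)
  expect_true(all(file.exists(file.path(d, c(
    "specimen.stl", "tumor_truth.stl", "mri_mask.nii.gz", "contours.json",
    "landmarks_mri.json", "landmarks_specimen.json", "truth.json",
    "case.yaml")))))
  truth <- jsonlite::read_json(file.path(d, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$volume_cm3, ph@truth$volume_cm3)
  expect_equal(truth$shrinkage, 0.96)
  lm <- readLandmarks(file.path(d, "landmarks_specimen.json"))
  expect_equal(lm@points, ph@landmarksSpecimen@points, tolerance = 1e-12)
})
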