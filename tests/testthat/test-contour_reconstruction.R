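test_that("stack validation reports ordering, simplicity and emptiness", {
  clean <- circleStack(c(8, 10, 8), c(0, 4, 8), 4)
  expect_equal(nrow(validateStack(clean)[
    validateStack(clean)$severity == "fatal", ]), 0)

  eight <- rbind(c(0, 0), c(10, 10), c(10, 0), c(0, 10))
  bad <- ContourStack(list(list(position = 0, thickness = 4,
                                contours = list(Contour(eight)))))
  f <- validateStack(bad)
  expect_true(any(f$severity == "fatal" &
                    grepl("self-intersecting", f$message)))

  disord <- ContourStack(list(
    list(position = 0, thickness = 4,
         contours = list(Contour(circlePoints(5)))),
    list(position = 8, thickness = 4,
         contours = list(Contour(circlePoints(5)))),
    list(position = 4, thickness = 4,
         contours = list(Contour(circlePoints(5))))))
  f <- validateStack(disord)
  expect_true(any(f$severity == "fatal" & grepl("increasing", f$message)))
  expect_error(interpolateSurface(disord), "fatal")

  withEmpty <- ContourStack(list(
    list(position = 0, thickness = 4,
         contours = list(Contour(circlePoints(5)))),
    list(position = 4, thickness = 4, contours = list())))
  f <- validateStack(withEmpty)
  expect_true(any(f$severity == "warning" & grepl("no contours", f$message)))
})

test_that("the slice signed-distance field has the right sign and scale", {
  sdf <- contourSDF(list(Contour(circlePoints(10))), spacing = 0.5)
  at <- function(u, v) sdf$field[which.min(abs(sdf$u - u)),
                                 which.min(abs(sdf$v - v))]
  expect_lt(abs(at(0, 0) - (-10)), 0.5)

  sdf2 <- contourSDF(list(Contour(circlePoints(10))), spacing = 0.5,
                     bounds = list(u = c(-16, 16), v = c(-16, 16)))
  at2 <- function(u, v) sdf2$field[which.min(abs(sdf2$u - u)),
                                   which.min(abs(sdf2$v - v))]
  expect_lt(abs(at2(15, 0) - 5), 0.5)

  ann <- contourSDF(list(Contour(circlePoints(10)),
                         Contour(circlePoints(4), hole = TRUE)),
                    spacing = 0.5)
  atA <- function(u, v) ann$field[which.min(abs(ann$u - u)),
                                  which.min(abs(ann$v - v))]
  expect_gt(atA(0, 0), 0)   # inside the hole is outside the tumor
  expect_lt(atA(7, 0), 0)   # the ring itself is inside

  expect_error(contourSDF(list(Contour(circlePoints(1))), spacing = 2),
               "too coarse")
})

test_that("planimetric (Cavalieri) volume matches analytic slabs", {
  one <- circleStack(10, 0, 4)
  expect_equal(planimetricVolume(one), pi * 100 * 4 / 1000,
               tolerance = 0.005)
  two <- circleStack(c(10, 10), c(0, 4), 4)
  expect_equal(planimetricVolume(two), pi * 100 * 8 / 1000,
               tolerance = 0.005)
  empty <- ContourStack(list())
  expect_equal(planimetricVolume(empty), 0)
  # holes subtract
  ann <- ContourStack(list(list(position = 0, thickness = 4, contours = list(
    Contour(circlePoints(10)), Contour(circlePoints(4), hole = TRUE)))))
  expect_equal(planimetricVolume(ann), pi * (100 - 16) * 4 / 1000,
               tolerance = 0.01)
})

test_that("shape-based interpolation reproduces analytic bodies", {
  # single slab closes to half a thickness on each side of its plane
  single <- interpolateSurface(circleStack(10, 0, 4))
  expect_true(isWatertight(single))
  expect_lt(abs(directionalExtent(single, "AP") - 0.4), 0.06)

  # two identical circles one slab apart: a capped cylinder
  two <- interpolateSurface(circleStack(c(10, 10), c(0, 4), 4))
  expect_lt(abs(meshVolume(two) - 2.513) / 2.513, 0.10)

  # a sphere sliced every 3 mm
  r <- 15
  pos <- seq(-13.5, 13.5, by = 3)
  sph <- interpolateSurface(
    circleStack(sqrt(r^2 - pos^2), pos, 3))
  expect_true(isWatertight(sph))
  expect_lt(abs(meshVolume(sph) - 14.137) / 14.137, 0.05)

  expect_error(interpolateSurface(ContourStack(list(
    list(position = 0, thickness = 4, contours = list())))), "empty")
})

test_that("reconstruction agrees with the Cavalieri estimate on uniform stacks", {
  for (seed in c(21, 22, 23)) {
    ph <- generatePhantom(phantomSpec(seed))
    stack <- ph@contourStack
    recon <- interpolateSurface(stack)
    expect_lt(abs(meshVolume(recon) / planimetricVolume(stack) - 1), 0.15)
  }
})

test_that("slice-and-reconstruct round-trip recovers convex phantoms", {
  for (seed in c(31, 32)) {
    ph <- generatePhantom(phantomSpec(seed, perturbAmplitude = 0))
    truth <- ph@truth$volume_cm3
    recon <- interpolateSurface(ph@contourStack)
    expect_lt(abs(meshVolume(recon) / truth - 1), 0.05)
    sp <- diff(vapply(ph@contourStack@slices, `[[`, 0, "position"))[1]
    for (ax in c("LR", "AP", "CC"))
      expect_lt(abs(directionalExtent(recon, ax) -
                      ph@truth$extents_cm[[ax]]), sp / 10 + 1e-9)
  }
})

test_that("adding an interior slice tends to improve volume recovery", {
  deltas <- vapply(1:20, function(seed) {
    ph <- generatePhantom(phantomSpec(100 + seed, perturbAmplitude = 0.1))
    shrunk <- ph@tumorMesh
    axis <- ph@contourStack@grossingAxis
    w <- vertices(shrunk) %*% axis
    ext <- max(w) - min(w)
    coarsePos <- min(w) + ext * (seq_len(5) - 0.5) / 5
    coarse <- sliceMeshToContours(shrunk, coarsePos, axis,
                                  thickness = ext / 5)
    # insert one extra interior cut between the second and third slabs
    finePos <- sort(c(coarsePos, min(w) + ext * 0.4))
    fine <- sliceMeshToContours(shrunk, finePos, axis, thickness = ext / 5)
    truth <- ph@truth$volume_cm3
    errC <- abs(meshVolume(interpolateSurface(coarse, spacing = 1)) - truth)
    errF <- abs(meshVolume(interpolateSurface(fine, spacing = 1)) - truth)
    errC - errF
  }, 0)
  expect_gte(stats::median(deltas), 0)
})

test_that("multifocal stacks reconstruct as independent components", {
  c1 <- Contour(circlePoints(8, c(-15, 0), 48))
  c2 <- Contour(circlePoints(8, c(15, 0), 48))
  mk <- function(ctrs) ContourStack(lapply(0:2, function(p)
    list(position = 4 * p, thickness = 4, contours = ctrs)))
  both <- interpolateSurface(mk(list(c1, c2)))
  a <- interpolateSurface(mk(list(c1)))
  b <- interpolateSurface(mk(list(c2)))
  expect_equal(meshComponents(both), 2)
  expect_lt(abs(meshVolume(both) / (meshVolume(a) + meshVolume(b)) - 1),
            0.01)
})

test_that("contour stacks survive JSON and text round-trips", {
  ph <- generatePhantom(phantomSpec(41))
  f <- withr::local_tempfile(fileext = ".json")
  writeContourStack(ph@contourStack, f)
  back <- readContourStack(f)
  expect_equal(back@grossingAxis, ph@contourStack@grossingAxis)
  expect_equal(length(back@slices), length(ph@contourStack@slices))
  expect_equal(back@slices[[1]]$contours[[1]]$points,
               ph@contourStack@slices[[1]]$contours[[1]]$points,
               tolerance = 1e-12)
  expect_equal(planimetricVolume(back), planimetricVolume(ph@contourStack),
               tolerance = 1e-9)

  txt <- withr::local_tempfile(fileext = ".txt")
  pts <- circlePoints(10, n = 8)
  writeLines(c("slice 0 4",
               apply(pts, 1, paste, collapse = " "),
               "",
               "slice 4 4 hole",
               apply(pts / 2, 1, paste, collapse = " ")), txt)
  st <- readContourText(txt)
  expect_equal(length(st@slices), 2)
  expect_false(st@slices[[1]]$contours[[1]]$hole)
  expect_true(st@slices[[2]]$contours[[1]]$hole)
})
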