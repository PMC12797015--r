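test_that("identical landmark sets give the identity transform", {
  set.seed(61)
  lm <- randomLandmarks(4, "mri")
  fx <- LandmarkSet(lm@points, "specimen")
  tr <- fitLandmarkTransform(lm, fx)
  expect_equal(tr@rotation, diag(3), tolerance = 1e-12)
  expect_equal(tr@translation, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(fiducialRegistrationError(lm, fx, tr), 0, tolerance = 1e-12)
})

test_that("a known rigid motion is recovered exactly from noiseless pins", {
  set.seed(62)
  lm <- randomLandmarks(5, "mri")
  a <- 30 * pi / 180
  R <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  true <- RigidTransform(R, c(5, -3, 2))
  fx <- applyTransform(lm, true)
  fx@frame <- "specimen"
  fit <- fitLandmarkTransform(lm, fx)
  expect_lt(max(abs(fit@rotation - R)), 1e-9)
  expect_lt(max(abs(fit@translation - c(5, -3, 2))), 1e-9)
  expect_lt(fiducialRegistrationError(lm, fx, fit), 1e-9)
})

test_that("the closed form beats a brute-force rotation grid under noise", {
  set.seed(63)
  lm <- randomLandmarks(5, "mri")
  a <- 8 * pi / 180
  R <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  fx <- applyTransform(lm, RigidTransform(R, c(4, 1, -2)))
  fx@points <- fx@points + matrix(stats::rnorm(15, sd = 0.5), 5, 3)
  fx@frame <- "specimen"
  fit <- fitLandmarkTransform(lm, fx)
  rssT <- function(Rot) {
    M <- lm@points %*% t(Rot)
    tr <- colMeans(fx@points) - colMeans(M)
    sum((sweep(M, 2, tr, "+") - fx@points)^2)
  }
  best <- Inf
  grid <- seq(-10, 10, by = 2) * pi / 180
  rotZ <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0,
                               0, 0, 1), 3, 3)
  rotY <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0,
                               sin(t), 0, cos(t)), 3, 3)
  for (t1 in grid) for (t2 in grid) for (t3 in grid) {
    cand <- rotZ(a + t1) %*% rotY(t2) %*% rotZ(t3)
    v <- rssT(cand)
    if (v < best) best <- v
  }
  fitRss <- sum((applyTransform(lm@points, fit) - fx@points)^2)
  expect_lte(fitRss, best + 1e-9)
})

test_that("fit-then-apply recovers arbitrary rigid motions of phantom pins", {
  set.seed(64)
  for (i in 1:20) {
    lm <- randomLandmarks(sample(4:8, 1), "mri")
    true <- randomRigid()
    fx <- applyTransform(lm, true)
    fx@frame <- "specimen"
    fit <- fitLandmarkTransform(lm, fx)
    expect_lt(sqrt(sum((fit@rotation - true@rotation)^2)), 1e-8)
    expect_lt(max(abs(fit@translation - true@translation)), 1e-8)
  }
})

test_that("FRE behaves as an RMS residual metric", {
  set.seed(65)
  lm <- randomLandmarks(4, "mri")
  fx <- LandmarkSet(lm@points, "specimen")
  # single shared point at distance 4 under the identity
  a <- LandmarkSet(list(p = c(0, 0, 0)), "mri")
  b <- LandmarkSet(list(p = c(0, 0, 4)), "specimen")
  expect_equal(fiducialRegistrationError(a, b, RigidTransform()), 4)

  # invariant under simultaneous rigid motion of both sets
  tr <- fitLandmarkTransform(lm, fx)
  noisy <- fx
  noisy@points <- noisy@points + matrix(stats::rnorm(12, sd = 0.3), 4, 3)
  e0 <- fiducialRegistrationError(lm, noisy, fitLandmarkTransform(lm, noisy))
  mot <- randomRigid()
  lm2 <- applyTransform(lm, mot)
  noisy2 <- applyTransform(noisy, mot)
  e1 <- fiducialRegistrationError(lm2, noisy2,
                                  fitLandmarkTransform(lm2, noisy2))
  expect_equal(e0, e1, tolerance = 1e-9)

  # with >= 3 points and noise sigma, FRE lands in (0, 3 sigma)
  sig <- 0.5
  fres <- vapply(1:100, function(i) {
    p <- randomLandmarks(4, "mri")
    q <- p
    q@points <- q@points + matrix(stats::rnorm(12, sd = sig), 4, 3)
    q@frame <- "specimen"
    fiducialRegistrationError(p, q, fitLandmarkTransform(p, q))
  }, 0)
  expect_true(all(fres > 0 & fres < 3 * sig))
})

test_that("similarity mode recovers formalin-scale shrinkage exactly", {
  set.seed(66)
  for (s in c(0.94, 0.95, 0.96)) {
    lm <- randomLandmarks(5, "mri")
    true <- randomRigid()
    true@scale <- s
    fx <- applyTransform(lm, true)
    fx@frame <- "specimen"
    fit <- fitLandmarkTransform(lm, fx, allowScale = TRUE)
    expect_lt(abs(fit@scale - s), 1e-8)
    # rigid-only fitting of scaled pins cannot reach scale
    rigid <- fitLandmarkTransform(lm, fx)
    expect_equal(rigid@scale, 1)
  }
})

test_that("degenerate or mismatched landmark sets are refused", {
  line <- LandmarkSet(list(a = c(0, 0, 0), b = c(1, 0, 0), c = c(2, 0, 0)),
                      "mri")
  lineF <- LandmarkSet(line@points, "specimen")
  expect_error(fitLandmarkTransform(line, lineF), "collinear")

  a <- LandmarkSet(list(p1 = c(0, 0, 0), p2 = c(1, 0, 0), x1 = c(0, 1, 0)),
                   "mri")
  b <- LandmarkSet(list(p1 = c(0, 0, 0), p2 = c(1, 0, 0), y9 = c(0, 1, 0)),
                   "specimen")
  err <- tryCatch(fitLandmarkTransform(a, b), error = conditionMessage)
  expect_match(err, "x1")
  expect_match(err, "y9")
  expect_match(err, ">= 3 common")
})

test_that("the closed form agrees with an independent Procrustes solver", {
  set.seed(67)
  lm <- randomLandmarks(6, "mri")
  fx <- applyTransform(lm, randomRigid())
  fx@points <- fx@points + matrix(stats::rnorm(18, sd = 0.4), 6, 3)
  fx@frame <- "specimen"
  fit <- fitLandmarkTransform(lm, fx)
  pro <- vegan::procrustes(fx@points, lm@points, scale = FALSE,
                           symmetric = FALSE)
  ourRss <- sum((applyTransform(lm@points, fit) - fx@points)^2)
  expect_equal(ourRss, sum(stats::residuals(pro)^2), tolerance = 1e-8)
  # same optimal rotation up to the solver's convention
  expect_equal(abs(det(pro$rotation)), 1, tolerance = 1e-10)
})

test_that("transforms apply correctly to meshes and serialize to JSON", {
  cube <- cubeMesh(10)
  expect_equal(meshVolume(applyTransform(cube, RigidTransform())), 1)
  moved <- applyTransform(cube, RigidTransform(translation = c(3, 4, 5)))
  expect_equal(meshVolume(moved), 1, tolerance = 1e-12)
  expect_equal(directionalExtent(moved, "LR"), 1)
  scaled <- applyTransform(cube, RigidTransform(scale = 0.95))
  expect_equal(meshVolume(scaled), 0.857375, tolerance = 1e-9)

  set.seed(68)
  tr <- randomRigid()
  tr@scale <- 0.97
  f <- withr::local_tempfile(fileext = ".json")
  writeTransform(tr, f)
  back <- readTransform(f)
  expect_equal(back@rotation, tr@rotation, tolerance = 1e-12)
  expect_equal(back@translation, tr@translation, tolerance = 1e-12)
  expect_equal(back@scale, tr@scale)

  inv <- composeTransforms(invertTransform(tr), tr)
  expect_equal(inv@rotation, diag(3), tolerance = 1e-12)
  expect_equal(inv@translation, c(0, 0, 0), tolerance = 1e-10)
  expect_equal(inv@scale, 1, tolerance = 1e-12)
})
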