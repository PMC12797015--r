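# Shared fixtures, all generated in code.

circlePoints <- function(r, center = c(0, 0), n = 72) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

circleStack <- function(radii, positions, thickness) {
  ContourStack(mapply(function(r, p, t) {
    list(position = p, thickness = t,
         contours = list(Contour(circlePoints(r))))
  }, radii, positions, rep(thickness, length.out = length(positions)),
  SIMPLIFY = FALSE))
}

# unit tetrahedron scaled to 10 mm legs, outward-oriented
tetraMesh <- function() {
  v <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(0, 0, 10))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3))
  TriangleMesh(v, f, "tetra")
}

randomRigid <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
                2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
                2 * (x * z - w * y), 2 * (y * z + w * x),
                1 - 2 * (x^2 + y^2)), 3, 3)
  RigidTransform(R, stats::runif(3, -30, 30))
}

randomLandmarks <- function(n = 5, frame = "mri") {
  pts <- matrix(stats::runif(3 * n, -25, 25), n, 3)
  rownames(pts) <- paste0("lm", seq_len(n))
  LandmarkSet(pts, frame)
}

# the published nine-case cohort table plus its printed derived columns
cohortPrinted <- function() {
  tab <- cohortVolumeTable()
  tab$printed_diff <- c(3.4, 1.0, 3.7, 11.5, 0.2, -0.2, 1.3, 0.0, 0.6)
  tab$printed_ratio <- c(60.1, 37.5, 54.9, 8.7, 66.7, 109.1, 66.7, 100.0,
                         87.8)
  tab
}
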