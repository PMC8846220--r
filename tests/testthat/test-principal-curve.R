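test_that("a principal circle recovers a noiseless circle within 2%", {
  set.seed(21)
  th <- runif(1500L) * 2 * pi
  pts <- cbind(cos(th), sin(th))
  cv <- fit_principal_curve(pts, q = 30L, closed = TRUE,
                            lambda = 0.001, mu = 0.01)
  radii <- sqrt(rowSums(cv$nodes^2))
  expect_lt(max(abs(radii - 1)), 0.02)
  # polyline length close to the inscribed polygon perimeter
  expect_equal(curve_length(cv), 2 * pi * mean(radii), tolerance = 0.02)
})

test_that("with zero elasticity the fit reduces to k-means centroids", {
  set.seed(22)
  ctrs <- rbind(c(0, 0), c(5, 0), c(10, 5))
  pts <- do.call(rbind, lapply(1:3, function(i)
    sweep(matrix(rnorm(200L, 0, 0.05), ncol = 2L), 2L, ctrs[i, ], `+`)))
  cv <- fit_principal_curve(pts, q = 3L, closed = FALSE,
                            lambda = 0, mu = 0)
  got <- cv$nodes[order(cv$nodes[, 1L]), ]
  expect_equal(unname(got), unname(ctrs), tolerance = 0.05)
})

test_that("the fitting energy never increases across iterations", {
  set.seed(23)
  pts <- cbind(runif(400L), runif(400L))
  cv <- fit_principal_curve(pts, q = 12L, closed = TRUE)
  expect_true(all(diff(cv$energy) <= 1e-12))
  expect_error(fit_principal_curve(matrix(1, 50L, 2L), q = 5L),
               "degenerate")
})

test_that("pseudotime is the geodesic edge-unit distance from the root", {
  # hand-built open polyline along the x axis
  nodes <- cbind(0:4, rep(0, 5L))
  cv <- structure(list(nodes = nodes, closed = FALSE,
                       partition = rep(1L, 3L), energy = 0,
                       lambda = 0, mu = 0),
                  class = "cct_principal_curve")
  pts <- rbind(c(0, 0), c(4, 0), c(2.5, 0.3))
  s <- assign_pseudotime(cv, pts, root = 1L)
  expect_equal(as.numeric(s), c(0, 4, 2.5))   # midpoint of edge 3 -> 2.5
  # rooting at the far end reverses the scale
  s2 <- assign_pseudotime(cv, pts, root = 5L)
  expect_equal(as.numeric(s2), c(4, 0, 1.5))
  expect_error(assign_pseudotime(cv, pts, root = 3L), "endpoint")
})

test_that("orientation follows the increasing-totals convention", {
  set.seed(24)
  th <- runif(1200L) * 2 * pi
  pts <- cbind(cos(th), sin(th)) + matrix(rnorm(2400L, 0, 0.02), ncol = 2L)
  # totals rise along the cycle with a sharp drop at the division angle
  totals <- 1000 + 800 * (th / (2 * pi))
  cv <- fit_principal_curve(pts, q = 30L, closed = TRUE)
  s <- assign_pseudotime(cv, pts, orient_scalar = totals)
  # the totals scalar is smooth except at the wrap, so the automatic root
  # can sit a node or two off the true division angle
  expect_gt(cor(as.numeric(s), totals, method = "spearman"), 0.8)
})

test_that("curvature vanishes on a line and matches the circle closed form", {
  line <- structure(list(nodes = cbind(0:9, 2 * (0:9)), closed = FALSE,
                         partition = integer(0L), energy = 0,
                         lambda = 0, mu = 0),
                    class = "cct_principal_curve")
  cp <- curvature_profile(line)
  expect_lt(max(cp$curvature), 1e-8)
  # q equispaced nodes on a circle of radius r: |y''| = r (2 pi / q)^2
  q <- 24L; r <- 3
  ang <- 2 * pi * (0:(q - 1L)) / q
  circ <- structure(list(nodes = cbind(r * cos(ang), r * sin(ang)),
                         closed = TRUE, partition = integer(0L),
                         energy = 0, lambda = 0, mu = 0),
                    class = "cct_principal_curve")
  cpc <- curvature_profile(circ)
  expect_equal(cpc$curvature, rep(r * (2 * pi / q)^2, q), tolerance = 0.01)
  expect_error(curvature_profile(structure(list(
    nodes = rbind(c(0, 0), c(0, 0), c(1, 1), c(2, 2), c(3, 3)),
    closed = FALSE, partition = integer(0L), energy = 0, lambda = 0,
    mu = 0), class = "cct_principal_curve")), "duplicate")
})

test_that("spline curvature agrees with central finite differences", {
  set.seed(25)
  q <- 40L
  s <- 0:(q - 1L)
  nodes <- cbind(sin(s / 6), cos(s / 8), (s / 10)^2)
  cv <- structure(list(nodes = nodes, closed = FALSE,
                       partition = integer(0L), energy = 0, lambda = 0,
                       mu = 0), class = "cct_principal_curve")
  cp <- curvature_profile(cv)
  fd <- sqrt(rowSums((nodes[1:(q - 2L), ] - 2 * nodes[2:(q - 1L), ] +
                        nodes[3:q, ])^2))
  interior <- 5:(q - 4L)
  expect_equal(cp$curvature[interior], fd[interior - 1L],
               tolerance = 1e-2)
})

test_that("curvature peaks sit at planted corners of a polygonal loop", {
  # a rounded triangle traced by 30 nodes: corners at nodes 1, 11, 21
  q <- 30L
  corners <- rbind(c(0, 0), c(4, 0), c(2, 3))
  path <- do.call(rbind, lapply(1:3, function(i) {
    a <- corners[i, ]; b <- corners[(i %% 3L) + 1L, ]
    fr <- (0:9) / 10
    cbind(a[1L] + fr * (b[1L] - a[1L]), a[2L] + fr * (b[2L] - a[2L]))
  }))
  cv <- structure(list(nodes = path, closed = TRUE,
                       partition = integer(0L), energy = 0, lambda = 0,
                       mu = 0), class = "cct_principal_curve")
  cp <- curvature_profile(cv)
  expect_setequal(sort(cp$peaks), c(0, 10, 20))
})

test_that("epoch segmentation cuts the cyclic pseudotime axis", {
  s <- c(0.5, 3, 7, 9.5)
  seg <- segment_epochs(s, boundaries = c(0, 2, 6, 8),
                        labels = c("T1", "T1s", "T2s", "Tm"))
  expect_equal(as.character(seg), c("T1", "T1s", "T2s", "Tm"))
  # values past the last boundary wrap into the first segment
  seg2 <- segment_epochs(c(9.9, 0.1), boundaries = c(1, 5, 9))
  expect_equal(as.character(seg2), c("seg3", "seg3"))
})
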