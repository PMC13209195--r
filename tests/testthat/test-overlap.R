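test_that("self-overlap gives unit shape Tanimoto", {
  conf <- amide_conformer()
  ov <- gaussian_overlap(conf, conf)
  expect_equal(ov$shape_tanimoto, 1, tolerance = 1e-6)
  expect_equal(ov$color_tanimoto, 0)  # features not perceived yet
  conf$features <- perceive_features(conf)
  ov2 <- gaussian_overlap(conf, conf)
  expect_equal(ov2$combined, 2, tolerance = 1e-5)
})

test_that("single-atom limits: perfect after superposition, zero far apart", {
  a <- conformer(matrix(0, 1, 3), "C")
  b <- conformer(matrix(c(100, 0, 0), 1, 3), "C")
  ov <- gaussian_overlap(a, b)                    # optimizer translates
  expect_equal(ov$shape_tanimoto, 1, tolerance = 1e-4)
  ov_fixed <- gaussian_overlap(a, b, optimize = FALSE)
  expect_lt(ov_fixed$shape_tanimoto, 1e-6)
})

test_that("fixed-pose overlap matches 3D quadrature within 1%", {
  xyzA <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(0.8, 1.2, 0))
  xyzB <- rbind(c(0.4, 0.3, 0.2), c(1.2, -0.5, 0.6), c(2.0, 1.0, -0.3))
  confA <- conformer(xyzA, c("C", "N", "O"))
  confB <- conformer(xyzB, c("C", "C", "O"))
  analytic <- gaussian_overlap_fixed(confA, confB)
  # quadrature oracle: product of summed Gaussian densities on a grid
  ga <- qsarphore:::conf_gaussians(confA)
  gb <- qsarphore:::conf_gaussians(confB)
  h <- 0.25
  gx <- seq(-5, 7, by = h)
  dens <- function(g, pts) {
    out <- numeric(nrow(pts))
    for (i in seq_along(g$alpha)) {
      d2 <- rowSums(sweep(pts, 2, g$xyz[i, ])^2)
      out <- out + 2.7 * exp(-g$alpha[i] * d2)
    }
    out
  }
  total <- 0
  for (z in gx) {
    pts <- as.matrix(expand.grid(x = gx, y = gx, z = z))
    total <- total + sum(dens(ga, pts) * dens(gb, pts)) * h^3
  }
  expect_lt(abs(total - analytic) / analytic, 0.01)
})

test_that("compiled kernel agrees with the pure-R reference", {
  set.seed(14)
  for (i in 1:5) {
    nA <- sample(2:6, 1); nB <- sample(2:6, 1)
    ga <- list(xyz = matrix(rnorm(nA * 3), nA, 3),
               alpha = runif(nA, 0.5, 1.5))
    gb <- list(xyz = matrix(rnorm(nB * 3), nB, 3),
               alpha = runif(nB, 0.5, 1.5))
    expect_equal(
      qsarphore:::pair_overlap_volume(ga$xyz, ga$alpha, gb$xyz, gb$alpha),
      qsarphore:::pair_overlap_volume_r(ga$xyz, ga$alpha, gb$xyz, gb$alpha),
      tolerance = 1e-10)
  }
})

test_that("overlap is symmetric and rigid-motion invariant", {
  ds <- small_synthetic(seed = 3, n_act = 2, n_inact = 2, n_lib = 2)
  a <- ds$molecules[[1]]$conformers[[1]]
  b <- ds$molecules[[2]]$conformers[[1]]
  ov_ab <- gaussian_overlap(a, b)
  ov_ba <- gaussian_overlap(b, a)
  expect_equal(ov_ab$shape_tanimoto, ov_ba$shape_tanimoto, tolerance = 1e-6)
  expect_equal(ov_ab$color_tanimoto, ov_ba$color_tanimoto, tolerance = 1e-6)
  expect_equal(ov_ab$combined, ov_ba$combined, tolerance = 1e-6)
  moved <- rigid_transform_conformer(b, rotmat_z(1.3), c(5, 5, -5))
  ov_mv <- gaussian_overlap(a, moved)
  expect_equal(ov_mv$shape_tanimoto, ov_ab$shape_tanimoto, tolerance = 1e-4)
  expect_true(ov_ab$shape_tanimoto >= 0 && ov_ab$shape_tanimoto <= 1)
  expect_true(ov_ab$combined >= 0 && ov_ab$combined <= 2)
})

test_that("deleting an atom never increases fixed-pose overlap", {
  set.seed(19)
  xyzA <- matrix(rnorm(15), 5, 3)
  xyzB <- matrix(rnorm(12), 4, 3)
  confA <- conformer(xyzA, rep("C", 5))
  o_full <- gaussian_overlap_fixed(confA, conformer(xyzB, rep("C", 4)))
  for (drop in 1:4) {
    o_less <- gaussian_overlap_fixed(
      confA, conformer(xyzB[-drop, , drop = FALSE], rep("C", 3)))
    expect_lte(o_less, o_full + 1e-12)
  }
})

test_that("color Tanimoto anchors: identical one, disjoint kinds zero", {
  ftA <- feature_sites(c("D", "D"), rbind(c(0, 0, 0), c(3, 0, 0)))
  ftB <- feature_sites(c("A", "A"), rbind(c(0, 0, 0), c(3, 0, 0)))
  expect_equal(color_tanimoto(ftA, ftA), 1, tolerance = 1e-9)
  expect_equal(color_tanimoto(ftA, ftB), 0)
  expect_equal(color_tanimoto(NULL, ftA), 0)
})

test_that("empty conformers are rejected", {
  empty <- conformer(matrix(numeric(0), 0, 3), character(0))
  expect_error(gaussian_overlap(empty, amide_conformer()))
})
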