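test_that("single atom occupies exactly one heavy-atom cube", {
  grid <- structure(list(origin = c(0, 0, 0), shape = c(4L, 4L, 4L),
                         spacing = 1.0), class = "qp_grid")
  conf <- conformer(matrix(c(0.5, 0.5, 0.5), 1, 3), "C")
  bits <- occupancy_bits(conf, grid)
  expect_equal(sum(bits), 1)
  expect_true(bits[1])  # cube (0,0,0) is the first linear index
})

test_that("atoms on a cube face belong to the higher-index cube", {
  grid <- structure(list(origin = c(0, 0, 0), shape = c(4L, 4L, 4L),
                         spacing = 1.0), class = "qp_grid")
  conf <- conformer(matrix(c(1.0, 0.5, 0.5), 1, 3), "C")
  bits <- occupancy_bits(conf, grid)
  expect_true(bits[2])   # x index 1 (cube [1,2)), not cube [0,1)
  expect_false(bits[1])
})

test_that("occupancy equals a brute-force floor-division oracle", {
  set.seed(8)
  grid <- structure(list(origin = c(-3, -3, -3), shape = c(8L, 8L, 8L),
                         spacing = 1.0), class = "qp_grid")
  for (rep in 1:5) {
    n <- sample(3:10, 1)
    xyz <- matrix(runif(n * 3, -2.5, 4.5), n, 3)
    conf <- conformer(xyz, rep("C", n))
    bits <- occupancy_bits(conf, grid)
    oracle <- logical(prod(grid$shape) * 7)
    for (i in seq_len(n)) {
      ijk <- floor(xyz[i, ] - grid$origin)
      idx <- 1 + ijk[1] + 8 * (ijk[2] + 8 * ijk[3])
      oracle[idx] <- TRUE
    }
    expect_identical(bits, oracle)
  }
})

test_that("feature sites occupy their kind's class block", {
  grid <- structure(list(origin = c(0, 0, 0), shape = c(2L, 2L, 2L),
                         spacing = 1.0), class = "qp_grid")
  conf <- conformer(matrix(c(0.5, 0.5, 0.5), 1, 3), "C")
  conf$features <- feature_sites("R", matrix(c(0.5, 0.5, 0.5), 1, 3))
  bits <- occupancy_bits(conf, grid)
  ncube <- 8
  r_block <- which(qsarphore:::OCC_CLASSES == "R")
  expect_true(bits[(r_block - 1) * ncube + 1])
  expect_equal(sum(bits), 2)  # heavy-atom bit + R bit
})

test_that("hydrogens are excluded from occupancy", {
  grid <- structure(list(origin = c(0, 0, 0), shape = c(2L, 2L, 2L),
                         spacing = 1.0), class = "qp_grid")
  conf <- conformer(rbind(c(0.5, 0.5, 0.5), c(1.5, 0.5, 0.5)),
                    c("C", "H"))
  expect_equal(sum(occupancy_bits(conf, grid)), 1)
})

test_that("unalignable compounds abort matrix construction by name", {
  ds <- small_synthetic(seed = 2)
  h <- planted_hypothesis(ds)
  bad <- molecule("featureless", pIC50 = 5,
                  conformers = list(conformer(matrix(0, 1, 3), "C")))
  bad$conformers[[1]]$features <- feature_sites(character(0),
                                                matrix(numeric(0), ncol = 3))
  expect_error(build_occupancy_matrix(c(ds$molecules[1], list(bad)), h),
               "featureless")
})
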