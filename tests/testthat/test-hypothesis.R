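test_that("candidate enumeration counts and distance vectors", {
  conf <- conformer(matrix(rnorm(18), 6, 3), rep("C", 6))
  conf$features <- feature_sites(c("A", "D", "D", "R", "R", "R"),
                                 matrix(c(0,0,0, 3,0,0, 0,4,0, 0,0,5,
                                          6,0,0, 0,7,0), 6, 3, byrow = TRUE))
  expect_equal(length(enumerate_pharmacophores(conf, 6)), 1)
  conf7 <- conf
  conf7$features <- rbind(conf$features,
                          feature_sites("H", matrix(c(9, 9, 9), 1, 3)))
  expect_equal(length(enumerate_pharmacophores(conf7, 6)), 7)
  # equilateral 3-site toy
  tri <- conf
  tri$features <- feature_sites(c("A", "A", "A"),
                                rbind(c(0, 0, 0), c(3, 0, 0),
                                      c(1.5, 3 * sqrt(3) / 2, 0)))
  cand <- enumerate_pharmacophores(tri, 3)
  expect_equal(length(cand), 1)
  expect_equal(cand[[1]]$dists, c(3, 3, 3), tolerance = 1e-9)
  # too few sites -> empty, not an error
  expect_equal(length(enumerate_pharmacophores(tri, 5)), 0)
})

test_that("distance binning splits candidates at bin edges", {
  params <- partition_params()
  mk <- function(d) list(label = "AD", dists = d)
  k1 <- qsarphore:::candidate_key(mk(3.9), params)
  k2 <- qsarphore:::candidate_key(mk(4.1), params)
  expect_false(k1 == k2)
  # clipping beyond the last bin
  expect_equal(qsarphore:::distance_bins(25, params), 7)
})

test_that("identical planted candidates group together and survive", {
  tmpl <- default_template_sites()
  mols <- lapply(1:3, function(i) {
    conf <- conformer(matrix(0, 1, 3), "C")
    conf$features <- tmpl
    molecule(paste0("m", i), pIC50 = 6 + i, conformers = list(conf))
  })
  hyps <- find_common_pharmacophores(mols, k = 6)
  expect_equal(length(hyps), 1)
  expect_equal(hyps[[1]]$label, "ADDRRR")
  expect_equal(hyps[[1]]$n_actives_matched, 3)
  expect_equal(hyps[[1]]$reference_ligand_id, "m3")  # highest pIC50
})

test_that("partitioning agrees with a brute-force bin-vector oracle", {
  set.seed(5)
  params <- partition_params()
  for (rep in 1:3) {
    mols <- lapply(1:4, function(i) {
      n <- sample(6:8, 1)
      conf <- conformer(matrix(0, 1, 3), "C")
      conf$features <- feature_sites(
        sample(c("A", "D", "R"), n, replace = TRUE),
        matrix(runif(n * 3, 0, 12), n, 3))
      molecule(paste0("m", i), pIC50 = 5 + i, conformers = list(conf))
    })
    # oracle: exact group-by over (label, binned sorted distance vector)
    oracle <- new.env()
    for (m in mols) for (cand in enumerate_pharmacophores(m$conformers[[1]], 4)) {
      key <- paste0(cand$label, ":",
                    paste(pmin(floor(sort(cand$dists) / params$bin_width_A),
                               params$n_bins - 1), collapse = ","))
      oracle[[key]] <- union(oracle[[key]] %||% character(0), m$id)
    }
    surviving_keys <- Filter(function(k) length(oracle[[k]]) >= 2, ls(oracle))
    hyps <- find_common_pharmacophores(mols, k = 4, params = params)
    expect_setequal(vapply(hyps, `[[`, character(1), "key"), surviving_keys)
    for (h in hyps) {
      expect_setequal(h$matched_ids, oracle[[h$key]])
    }
  }
})

test_that("the planted template label survives on synthetic data", {
  ds <- generate_dataset(synthetic_spec(n_actives = 20, n_inactives = 5,
                                        n_library = 2, seed = 13))
  actives <- Filter(function(m) isTRUE(m$is_active), ds$molecules)
  hyps <- find_common_pharmacophores(actives, k = 6)
  labs <- vapply(hyps, `[[`, character(1), "label")
  expect_true("ADDRRR" %in% labs)
  best <- Filter(function(h) h$label == "ADDRRR", hyps)[[1]]
  expect_gte(best$n_actives_matched, 0.9 * length(actives))
})
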