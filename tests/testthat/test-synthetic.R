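test_that("generation is deterministic and fixture files round-trip", {
  spec <- synthetic_spec(n_actives = 4, n_inactives = 4, n_library = 5,
                         seed = 11)
  d1 <- tempfile("fixA"); d2 <- tempfile("fixB")
  p1 <- write_fixture_files(generate_dataset(spec), d1)
  p2 <- write_fixture_files(generate_dataset(spec), d2)
  expect_identical(readLines(p1["train"]), readLines(p2["train"]))
  expect_identical(readLines(p1["library"]), readLines(p2["library"]))
  expect_identical(readLines(p1["truth"]), readLines(p2["truth"]))

  ds <- generate_dataset(spec)
  back <- read_dataset(p1["train"], "sdf")
  ids0 <- vapply(ds$molecules, `[[`, character(1), "id")
  for (m in back) {
    orig <- ds$molecules[[match(m$id, ids0)]]
    expect_equal(m$pIC50, orig$pIC50, tolerance = 1e-6)
    expect_equal(m$conformers[[1]]$coords, orig$conformers[[1]]$coords,
                 tolerance = 1e-4)
  }
  lib <- read_dataset(p1["library"], "sdf", require_activity = FALSE)
  expect_equal(length(lib), 5)
  truth <- jsonlite::read_json(p1["truth"], simplifyVector = TRUE)
  expect_equal(truth$beta, ds$truth$beta, tolerance = 1e-9)
})

test_that("zero-jitter actives realize the template exactly", {
  spec <- synthetic_spec(n_actives = 5, n_inactives = 2, n_library = 2,
                         site_jitter_A = 0, seed = 4)
  ds <- generate_dataset(spec)
  actives <- Filter(function(m) isTRUE(m$is_active), ds$molecules)
  hyp <- hypothesis_from_sites(spec$template_sites)
  for (m in actives) {
    al <- align_conformer_to_hypothesis(m$conformers[[1]], hyp)
    expect_equal(al$n_matched, 6)
    expect_lt(al$rmsd, 1e-6)
  }
})

test_that("actives match the planted template within the jitter radius", {
  ds <- small_synthetic(seed = 7)
  actives <- Filter(function(m) isTRUE(m$is_active), ds$molecules)
  hyp <- hypothesis_from_sites(ds$truth$template_sites)
  for (m in actives) {
    al <- align_conformer_to_hypothesis(m$conformers[[1]], hyp)
    expect_equal(al$n_matched, 6)
    expect_lt(al$rmsd, ds$spec$site_jitter_A + 1e-9)
  }
})

test_that("inactive decoys lack two template sites", {
  ds <- small_synthetic(seed = 7)
  inact <- Filter(function(m) !isTRUE(m$is_active), ds$molecules)
  for (m in inact) {
    kinds <- table(factor(m$conformers[[1]]$features$kind,
                          levels = c("A", "D", "H", "N", "P", "R")))
    expect_equal(sum(kinds[c("A", "D", "R")]), 4)  # 6 core sites minus 2
  }
})

test_that("activity bands respect the 6.0 threshold structure", {
  ds <- generate_dataset(synthetic_spec(n_actives = 30, n_inactives = 30,
                                        n_library = 2, seed = 9))
  tr <- ds$truth$compounds
  lin_act <- tr$true_linear_pIC50[tr$role == "active"]
  lin_ina <- tr$true_linear_pIC50[tr$role == "inactive"]
  expect_true(all(lin_act >= 6.0 & lin_act <= 9.0))
  expect_true(all(lin_ina >= 3.0 & lin_ina < 6.0))
})

test_that("noiseless planted activity is exactly linear in decorations", {
  spec <- synthetic_spec(n_actives = 12, n_inactives = 6, n_library = 2,
                         activity_noise_sd = 0, seed = 21)
  ds <- generate_dataset(spec)
  tr <- ds$truth$compounds
  z <- do.call(rbind, lapply(strsplit(tr$z, ""), as.integer))
  nmiss <- vapply(strsplit(tr$missing_sites, ";"),
                  function(v) sum(nzchar(v)), numeric(1))
  recon <- ds$truth$intercept + as.numeric(z %*% ds$truth$beta) -
    ds$truth$site_penalty * nmiss
  expect_equal(recon, tr$true_linear_pIC50, tolerance = 1e-9)
  pic <- vapply(ds$molecules, `[[`, numeric(1), "pIC50")
  ids <- vapply(ds$molecules, `[[`, character(1), "id")
  expect_equal(pic, tr$true_linear_pIC50[match(ids, tr$id)], tolerance = 1e-9)
})

test_that("infeasible template geometry is rejected", {
  bad <- feature_sites(c("A", "D"), rbind(c(0, 0, 0), c(0.5, 0, 0)))
  expect_error(synthetic_spec(template_sites = bad), "infeasible")
})
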