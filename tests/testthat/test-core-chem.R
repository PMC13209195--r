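test_that("pIC50 conversion matches known anchors and round-trips", {
  expect_equal(to_pIC50(1000), 6.0)
  expect_equal(to_pIC50(1), 9.0)
  expect_equal(round(to_pIC50(54), 2), 7.27)
  for (a in c(0.3, 54, 1000, 88123)) {
    expect_equal(from_pIC50(to_pIC50(a)), a, tolerance = 1e-9)
  }
  expect_error(to_pIC50(0))
  expect_error(to_pIC50(-5))
})

test_that("pIC50 is strictly decreasing in activity", {
  a <- sort(exp(runif(20, 0, 10)))
  expect_true(all(diff(to_pIC50(a)) < 0))
})

test_that("feature perception finds canonical sites on toy structures", {
  ft <- perceive_features(benzene_conformer())
  expect_equal(nrow(ft), 1)
  expect_equal(ft$kind, "R")
  expect_equal(unlist(ft[1, c("x", "y", "z")]), c(x = 0, y = 0, z = 0),
               tolerance = 1e-8)
  expect_equal(sqrt(sum(ft[1, c("dx", "dy", "dz")]^2)), 1, tolerance = 1e-6)

  ft2 <- perceive_features(amide_conformer())
  expect_setequal(ft2$kind, c("A", "D", "H"))  # carbonyl O, amide N, methyl
  expect_equal(sum(ft2$kind == "A"), 1)
  expect_equal(sum(ft2$kind == "D"), 1)

  # methane: single carbon, no features
  ft3 <- perceive_features(conformer(matrix(0, 1, 3), "C"))
  expect_equal(nrow(ft3), 0)
})

test_that("feature perception is equivariant under rigid motion", {
  set.seed(42)
  conf <- amide_conformer()
  ft0 <- perceive_features(conf)
  for (i in 1:5) {
    rot <- qsarphore:::random_rotation()
    trans <- runif(3, -10, 10)
    moved <- conf
    moved$coords <- apply_rigid(conf$coords, rot, trans)
    ft1 <- perceive_features(moved)
    expect_equal(ft1$kind, ft0$kind)
    expect_equal(qsarphore:::site_xyz(ft1),
                 apply_rigid(qsarphore:::site_xyz(ft0), rot, trans),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("empty rule table errors; disabled kinds are skipped", {
  expect_error(perceive_features(benzene_conformer(),
                                 rules = data.frame()))
  ft <- perceive_features(amide_conformer(),
                          rules = pharmacophore_feature_rules(exclude = "H"))
  expect_false("H" %in% ft$kind)
})

test_that("rotatable bond counting follows the single/non-ring/non-terminal rule", {
  expect_equal(count_rotatable_bonds(benzene_conformer()), 0L)
  # acetamide: the only single bonds end at terminal heavy atoms
  expect_equal(count_rotatable_bonds(amide_conformer()), 0L)
  # N-methyl propanamide: C-C(=O) rotatable; amide C-N toggles
  chain <- conformer(rbind(c(0,0,0), c(1.5,0,0), c(3,0,0), c(3.6,1.1,0),
                           c(4.5,-1,0), c(6,-1,0)),
                     c("C", "C", "C", "O", "N", "C"),
                     rbind(c(1,2,1), c(2,3,1), c(3,4,2), c(3,5,1), c(5,6,1)))
  expect_equal(count_rotatable_bonds(chain, vary_amide = TRUE), 2L)
  expect_equal(count_rotatable_bonds(chain, vary_amide = FALSE), 1L)
})

test_that("conformer caps honour rotatable-bond and total limits", {
  p <- conformer_params()
  rigid <- benzene_conformer()
  expect_equal(qsarphore:::conformer_cap(rigid, p), 10L)  # floor of one bond
  expect_equal(min(p$max_per_rotatable_bond * max(3, 1), p$max_total), 30L)
  # 25 rotatable bonds would exceed the overall cap
  expect_equal(min(10L * 25L, p$max_total), 100L)
  expect_error(conformer_params(max_total = 0))
  expect_error(conformer_params(energy_window_kcal = -1))
})

test_that("energy re-referencing sets the ensemble minimum to zero", {
  confs <- list(conformer(matrix(0, 1, 3), "C", energy = 12),
                conformer(matrix(0, 1, 3), "C", energy = 15.5))
  out <- rereference_energies(confs)
  expect_equal(sapply(out, `[[`, "energy"), c(0, 3.5))
})
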