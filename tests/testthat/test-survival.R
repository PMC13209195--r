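test_that("survival score reproduces a line-by-line manual evaluation", {
  # two-site toy hypothesis; two actives with engineered RMSDs 0 and 1.0
  # (tolerance 2.0), no direction vectors, no reference conformer (volume
  # term neutral at 1), no inactives
  sites <- feature_sites(c("H", "H"), rbind(c(0, 0, 0), c(4, 0, 0)))
  hyp <- hypothesis_from_sites(sites, reference_ligand_id = "a1",
                               reference_pIC50 = 7.5)
  mk <- function(id, rmsd, pic) {
    conf <- conformer(matrix(0, 1, 3), "C")
    # for a 2-point set the post-superposition RMSD is half the segment
    # length difference: stretch the segment by 2*rmsd
    conf$features <- feature_sites(c("H", "H"),
                                   rbind(c(0, 0, 0), c(4 + 2 * rmsd, 0, 0)))
    molecule(id, pIC50 = pic, conformers = list(conf))
  }
  actives <- list(mk("a1", 0, 7.5), mk("a2", 1.0, 6.4))
  scored <- score_hypothesis_survival(hyp, actives)
  s <- scored$survival
  # manual: s_site = mean(1 - 0/2, 1 - 1/2) = 0.75; s_vec = 1 (no vectors);
  # s_vol = 1 (neutral); s_sel = 0 (no decoy pool); m = 2 - 1 = 1;
  # delta_e = 0; activity = 7.5
  expect_equal(s$s_site, 0.75, tolerance = 1e-9)
  expect_equal(s$s_vec, 1)
  expect_equal(s$s_vol, 1)
  expect_equal(s$s_sel, 0)
  expect_equal(s$m_reward, 1)
  expect_equal(s$total, 0.75 + 1 + 1 + 0 + 1 - 0 + 7.5, tolerance = 1e-9)
  expect_equal(s$ranking, s$total)  # no inactives
})

test_that("survival total satisfies the weighted-sum identity", {
  ds <- small_synthetic(seed = 6)
  actives <- Filter(function(m) isTRUE(m$is_active), ds$molecules)
  inactives <- Filter(function(m) !isTRUE(m$is_active), ds$molecules)
  h <- planted_hypothesis(ds)
  scored <- score_hypothesis_survival(h, actives, inactives)
  s <- scored$survival
  w <- s$weights
  lhs <- w$w_site * s$s_site + w$w_vec * s$s_vec + w$w_vol * s$s_vol +
    w$w_sel * s$s_sel + w$w_rew * s$m_reward - w$w_e * s$delta_e +
    w$w_act * s$activity_term
  expect_equal(s$total, lhs, tolerance = 1e-9)
})

test_that("single matched active gives zero reward; min-energy reference gives zero penalty", {
  sites <- feature_sites(c("H", "H"), rbind(c(0, 0, 0), c(4, 0, 0)))
  hyp <- hypothesis_from_sites(sites, reference_ligand_id = "solo",
                               reference_pIC50 = 6.1)
  conf <- conformer(matrix(0, 1, 3), "C")
  conf$features <- sites
  scored <- score_hypothesis_survival(hyp, list(
    molecule("solo", pIC50 = 6.1, conformers = list(conf))))
  expect_equal(scored$survival$m_reward, 0)
  expect_equal(scored$survival$delta_e, 0)
})

test_that("survival ranking is invariant under global rigid motion", {
  ds <- small_synthetic(seed = 10, n_act = 5, n_inact = 5, n_lib = 2)
  actives <- Filter(function(m) isTRUE(m$is_active), ds$molecules)
  inactives <- Filter(function(m) !isTRUE(m$is_active), ds$molecules)
  h <- planted_hypothesis(ds)
  r0 <- score_hypothesis_survival(h, actives, inactives)$survival$ranking
  rot <- rotmat_z(0.7); trans <- c(-4, 1, 2)
  move_all <- function(mols) lapply(mols, function(m) {
    m$conformers <- lapply(m$conformers, rigid_transform_conformer, rot, trans)
    m
  })
  r1 <- score_hypothesis_survival(h, move_all(actives),
                                  move_all(inactives))$survival$ranking
  expect_equal(r1, r0, tolerance = 1e-6)
})

test_that("matched inactives lower and matched actives raise the ranking at fixed sub-scores", {
  sites <- feature_sites(c("H", "H"), rbind(c(0, 0, 0), c(4, 0, 0)))
  hyp <- hypothesis_from_sites(sites, reference_ligand_id = "a1",
                               reference_pIC50 = 7)
  perfect <- function(id, pic) {
    conf <- conformer(matrix(0, 1, 3), "C")
    conf$features <- sites
    molecule(id, pIC50 = pic, conformers = list(conf))
  }
  actives <- list(perfect("a1", 7), perfect("a2", 7.2))
  r_base <- score_hypothesis_survival(hyp, actives)$survival$ranking
  # add a perfectly matching inactive: sub-scores stay 1, penalty grows
  r_with_inact <- score_hypothesis_survival(
    hyp, actives, list(perfect("i1", 4), perfect("i2", 4)))$survival$ranking
  expect_lt(r_with_inact, r_base)
  # add a perfectly matching active: reward grows
  r_more_act <- score_hypothesis_survival(
    hyp, c(actives, list(perfect("a3", 7.1))))$survival$ranking
  expect_gt(r_more_act, r_base)
})

test_that("fitness score matches manual values and is capped at 3", {
  ds <- small_synthetic(seed = 2)
  h <- planted_hypothesis(ds)
  expect_equal(fitness_score(h$reference_conformer, h), 3.0, tolerance = 1e-6)

  # toy: RMSD 1.0 at tolerance 2.0, cosines 1, engineered overlap
  sites <- feature_sites(c("H", "H"), rbind(c(0, 0, 0), c(4, 0, 0)))
  hyp <- hypothesis_from_sites(sites)
  conf <- conformer(matrix(0, 1, 3), "C")
  conf$features <- feature_sites(c("H", "H"),
                                 rbind(c(0, 0, 0), c(6, 0, 0)))
  fit <- fitness_score(conf, hyp)
  # site term 0.5, vec term 1 (vacuous), vol term 1 (no reference conformer)
  expect_equal(fit, 0.5 + 1 + 1, tolerance = 1e-9)

  # matched pairs exactly at tolerance -> site term 0
  conf2 <- conf
  conf2$features <- feature_sites(c("H", "H"),
                                  rbind(c(0, 0, 0), c(8, 0, 0)))
  expect_equal(fitness_score(conf2, hyp), 0 + 1 + 1, tolerance = 1e-9)

  # non-hit -> NA
  conf3 <- conf
  conf3$features <- feature_sites("A", matrix(0, 1, 3))
  expect_true(is.na(fitness_score(conf3, hyp)))
})
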