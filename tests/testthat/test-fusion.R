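toy_table <- function(n = 10, seed = 1) {
  set.seed(seed)
  data.frame(compound_id = sprintf("c%03d", 1:n),
             combined = runif(n, 0, 2),
             fitness = runif(n, 0, 3),
             predicted_pIC50 = runif(n, 4, 9),
             stringsAsFactors = FALSE)
}

test_that("fused values equal a manual spreadsheet evaluation", {
  tab <- data.frame(compound_id = c("a", "b", "c"),
                    combined = c(1.0, 1.5, 2.0),
                    fitness = c(1.0, 2.0, 3.0),
                    predicted_pIC50 = c(5, 6, 7))
  z <- function(v) (v - mean(v)) / sd(v)
  Z <- cbind(z(tab$combined), z(tab$fitness), z(tab$predicted_pIC50))
  f_sum <- fuse_scores(tab, method = "sum")
  expect_equal(f_sum$fused, rowSums(Z), tolerance = 1e-12)
  f_prod <- fuse_scores(tab, method = "product")
  shifted <- sweep(Z, 2, apply(Z, 2, min), `-`) + 1
  expect_equal(f_prod$fused, apply(shifted, 1, prod), tolerance = 1e-12)
  f_exp <- fuse_scores(tab, method = "exp")
  expect_equal(f_exp$fused, rowSums(exp(Z)), tolerance = 1e-12)
})

test_that("sum fusion is invariant to positive affine transforms", {
  tab <- toy_table(20, seed = 2)
  r1 <- rank(fuse_scores(tab, method = "sum")$fused)
  tab2 <- tab
  tab2$combined <- 10 + 3 * tab2$combined
  tab2$fitness <- 0.5 * tab2$fitness - 2
  r2 <- rank(fuse_scores(tab2, method = "sum")$fused)
  expect_equal(r2, r1)
  # two columns that are affine copies rank like either column alone
  tab3 <- data.frame(compound_id = tab$compound_id, a = tab$combined,
                     b = 5 + 2 * tab$combined)
  f3 <- fuse_scores(tab3, columns = c("a", "b"), method = "sum")
  expect_equal(rank(f3$fused), rank(tab$combined))
})

test_that("degenerate and incomplete tables are handled", {
  tab <- toy_table(5)
  tab$combined <- 1
  expect_error(fuse_scores(tab), "zero-variance")
  tab2 <- toy_table(6)
  tab2$fitness[2] <- NA
  f <- fuse_scores(tab2)
  expect_true(is.na(f$fused[2]))
  expect_false(f$fusion_complete[2])
  expect_error(fuse_scores(toy_table(4), columns = "nope"))
})

test_that("top-fraction selection counts and ties are deterministic", {
  big <- data.frame(compound_id = sprintf("z%04d", 1:3800),
                    fused = rnorm(3800))
  expect_equal(nrow(select_top_fraction(big, 0.10)), 380)
  for (n in c(10, 100)) {
    tab <- data.frame(compound_id = sprintf("c%04d", 1:n), fused = rnorm(n))
    expect_equal(nrow(select_top_fraction(tab, 0.10)),
                 max(1, floor(0.1 * n)))
    expect_equal(nrow(select_top_fraction(tab, 1.0)), n)
  }
  # idempotence at fraction 1.0
  tab <- data.frame(compound_id = letters[1:10], fused = rnorm(10))
  once <- select_top_fraction(tab, 1.0)
  twice <- select_top_fraction(once, 1.0)
  expect_equal(twice$compound_id, once$compound_id)
  # distinct scores, fraction 0.10 -> the single maximum
  tab$fused <- 1:10
  expect_equal(select_top_fraction(tab, 0.10)$compound_id, "j")
  # boundary ties break by id
  tie <- data.frame(compound_id = c("b", "a", "c"), fused = c(1, 1, 0))
  expect_equal(select_top_fraction(tie, 1 / 3)$compound_id, "a")
  expect_error(select_top_fraction(tab[0, ], 0.1), "empty")
})

test_that("clustering is deterministic, exhaustive and representative", {
  ds <- small_synthetic(seed = 3, n_act = 4, n_inact = 4, n_lib = 8)
  mols <- ds$library
  scores <- seq_along(mols)
  c1 <- cluster_hits(mols, scores, k = 3, seed = 5)
  c2 <- cluster_hits(mols, scores, k = 3, seed = 5)
  expect_identical(c1$labels, c2$labels)
  expect_equal(sort(unique(c1$labels)), 1:3)        # every cluster non-empty
  expect_true(all(c1$representatives$compound_id %in%
                    vapply(mols, `[[`, character(1), "id")))
  for (r in seq_len(nrow(c1$representatives))) {
    cl <- c1$representatives$cluster[r]
    members <- names(c1$labels)[c1$labels == cl]
    expect_true(c1$representatives$compound_id[r] %in% members)
    expect_equal(c1$representatives$score[r],
                 max(scores[match(members, names(c1$labels))]))
  }
  # k = n: singleton clusters
  cn <- cluster_hits(mols, scores, k = length(mols), seed = 1)
  expect_equal(length(unique(cn$labels)), length(mols))
  expect_error(cluster_hits(mols, scores, k = 99), "exceeds")
})

test_that("two planted scaffold families separate at k = 2", {
  dsA <- generate_dataset(synthetic_spec(n_actives = 6, n_inactives = 2,
                                         n_library = 2, seed = 41))
  # second family uses charged site kinds, so its realizations carry
  # distinct elements and the fingerprints genuinely separate
  shifted <- feature_sites(
    c("N", "N", "P", "P", "A", "D"),
    rbind(c(0, 0, 0), c(3.1, 0, 0), c(0, 3.3, 0), c(5.3, 2.2, 1),
          c(2.2, 5.1, -1), c(7.1, 6.2, 0.5)))
  dsB <- generate_dataset(synthetic_spec(n_actives = 6, n_inactives = 2,
                                         n_library = 2,
                                         template_sites = shifted,
                                         seed = 42))
  famA <- Filter(function(m) isTRUE(m$is_active), dsA$molecules)
  famB <- Filter(function(m) isTRUE(m$is_active), dsB$molecules)
  mols <- c(famA, famB)
  truth_lab <- rep(1:2, c(length(famA), length(famB)))
  cl <- cluster_hits(mols, rep(1, length(mols)), k = 2, seed = 3)
  agreement <- max(mean((cl$labels == 1) == (truth_lab == 1)),
                   mean((cl$labels == 2) == (truth_lab == 1)))
  expect_equal(agreement, 1)
})
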