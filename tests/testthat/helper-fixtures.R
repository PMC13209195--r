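# Shared fixtures: tiny deterministic conformers and datasets built in code.
options(qsarphore.verbose = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

benzene_conformer <- function(z = 0) {
  ang <- seq(0, 2 * pi, length.out = 7)[1:6]
  xyz <- cbind(1.39 * cos(ang), 1.39 * sin(ang), z)
  bonds <- cbind(1:6, c(2:6, 1), rep(c(2L, 1L), 3))
  conformer(xyz, rep("C", 6), bonds)
}

# acetamide-like toy: CH3-C(=O)-NH2
amide_conformer <- function() {
  conformer(rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.1, 1.1, 0), c(2.2, -1.2, 0)),
            c("C", "C", "O", "N"),
            rbind(c(1, 2, 1), c(2, 3, 2), c(2, 4, 1)))
}

rigid_transform_conformer <- function(conf, rot, trans) {
  out <- conf
  out$coords <- apply_rigid(conf$coords, rot, trans)
  if (!is.null(conf$features)) {
    ft <- conf$features
    xyz <- apply_rigid(qsarphore:::site_xyz(ft), rot, trans)
    ft$x <- xyz[, 1]; ft$y <- xyz[, 2]; ft$z <- xyz[, 3]
    dirs <- qsarphore:::site_dir(ft)
    ok <- !is.na(dirs[, 1])
    if (any(ok)) {
      dirs[ok, ] <- dirs[ok, , drop = FALSE] %*% t(rot)
      ft$dx <- dirs[, 1]; ft$dy <- dirs[, 2]; ft$dz <- dirs[, 3]
    }
    out$features <- ft
  }
  out
}

rotmat_z <- function(theta) {
  matrix(c(cos(theta), -sin(theta), 0,
           sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

small_synthetic <- function(seed = 1, n_act = 8, n_inact = 8, n_lib = 6) {
  generate_dataset(synthetic_spec(n_actives = n_act, n_inactives = n_inact,
                                  n_library = n_lib, seed = seed))
}

planted_hypothesis <- function(ds, k = 6) {
  actives <- Filter(function(m) isTRUE(m$is_active), ds$molecules)
  hyps <- find_common_pharmacophores(actives, k = k)
  cand <- Filter(function(h) h$label == "ADDRRR", hyps)
  stopifnot(length(cand) > 0)
  cand[[1]]
}
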