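#' Specification for a synthetic ligand set with planted ground truth
#'
#' The generator emulates a multi-scaffold inhibitor dataset: ~85 compounds
#' whose pIC50 spans the activity threshold of 6.0, several conformers per
#' compound, a planted six-point pharmacophore (default typed ADDRRR) shared
#' by every active, and a planted linear structure-activity signal carried
#' by optional decoration groups. Chemical realism is secondary to
#' geometric and statistical fidelity: molecules are decorated scaffolds
#' whose substituents realize the template feature types at the template
#' geometry.
#'
#' Actives carry all six template sites (jittered within `site_jitter_A`);
#' their pIC50 is `intercept + sum(beta_j z_j) + noise` where `z_j` indicates
#' presence of decoration `j`. Inactives lack exactly two template sites and
#' are penalized `site_penalty` per missing site, placing them in the
#' inactive band below 6.0 while keeping activity an exact linear function
#' of group presence. Library decoys additionally include
#' geometry-distortion decoys (sites displaced by > 2 A).
#'
#' @param n_actives,n_inactives,n_library set sizes.
#' @param template_sites planted hypothesis as a [feature_sites()] table
#'   (default [default_template_sites()], typed ADDRRR).
#' @param site_jitter_A per-site positional jitter radius (Angstrom).
#' @param activity_noise_sd Gaussian noise on pIC50.
#' @param active_pIC50_range,inactive_pIC50_range target activity bands;
#'   the linear model's intercept/coefficients are chosen to respect them.
#' @param n_decorations number of decoration slots carrying the signal.
#' @param n_conformers conformers per compound (first realizes the planted
#'   pose; the rest are torsionally bent, higher-energy poses).
#' @param library_active_fraction fraction of the library that are planted
#'   actives (the rest are decoys).
#' @param seed integer RNG seed; everything downstream is deterministic in it.
#' @return list of class `qp_synthetic_spec`.
#' @export
synthetic_spec <- function(n_actives = 40L, n_inactives = 45L,
                           n_library = 200L,
                           template_sites = default_template_sites(),
                           site_jitter_A = 0.3, activity_noise_sd = 0.3,
                           active_pIC50_range = c(6.0, 9.0),
                           inactive_pIC50_range = c(3.0, 5.9),
                           n_decorations = 8L, n_conformers = 2L,
                           library_active_fraction = 0.1, seed = 1L) {
  stopifnot(n_actives > 0, n_inactives > 0, n_library > 0,
            site_jitter_A >= 0, activity_noise_sd >= 0,
            n_conformers >= 1, n_decorations >= 1)
  stopifnot(active_pIC50_range[1] >= ACTIVE_PIC50_THRESHOLD,
            inactive_pIC50_range[2] < ACTIVE_PIC50_THRESHOLD)
  d <- as.matrix(stats::dist(site_xyz(template_sites)))
  diag(d) <- Inf
  if (any(d < 1)) stop("infeasible template geometry: sites closer than 1 A")
  structure(list(
    n_actives = as.integer(n_actives), n_inactives = as.integer(n_inactives),
    n_library = as.integer(n_library), template_sites = template_sites,
    site_jitter_A = site_jitter_A, activity_noise_sd = activity_noise_sd,
    active_pIC50_range = active_pIC50_range,
    inactive_pIC50_range = inactive_pIC50_range,
    n_decorations = as.integer(n_decorations),
    n_conformers = as.integer(n_conformers),
    library_active_fraction = library_active_fraction,
    seed = as.integer(seed)
  ), class = "qp_synthetic_spec")
}

#' The default planted template: six sites typed ADDRRR
#'
#' An elongated cap-linker-tail arrangement spanning ~14 A, with an
#' aromatic cap ring, two donors, a central ring, a tail carbonyl acceptor
#' and a terminal ring.
#'
#' @return a [feature_sites()] table.
#' @export
default_template_sites <- function() {
  feature_sites(
    kind = c("R", "D", "D", "R", "A", "R"),
    xyz = rbind(
      c(-0.57, -0.83, -0.12),
      c(1.53, 0.94, 0.60),
      c(6.05, -0.73, 1.58),
      c(8.43, 0.60, 0.84),
      c(10.25, -1.53, -0.66),
      c(12.07, -0.09, -2.27)
    ),
    dir = rbind(
      c(0, 0, 1),
      unit_vec(c(0.45, 0.85, 0.30)),
      unit_vec(c(-0.20, -0.90, 0.40)),
      unit_vec(c(0.20, 0.30, 0.95)),
      unit_vec(c(0.30, -0.90, 0.20)),
      unit_vec(c(0.10, 0.40, 0.90))
    )
  )
}

#' Generate the synthetic training/test/library sets
#'
#' @param spec a [synthetic_spec()].
#' @return list of class `qp_synthetic_dataset` with elements
#'   `molecules` (actives + inactives, pIC50 filled, features perceived),
#'   `library` (screening set, planted actives + decoys, no activities) and
#'   `truth` (template geometry, decoration slots, planted coefficients and
#'   per-compound ground truth).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "qp_synthetic_spec"))
  with_seed(spec$seed, {
    slots <- decoration_slots(spec$template_sites, spec$n_decorations)
    # planted coefficients: evenly spread magnitudes (randomly assigned to
    # slots) so the structure-activity signal has a well-defined ordering;
    # their sum keeps actives inside the active pIC50 band
    beta_span <- diff(spec$active_pIC50_range) * 0.73
    beta <- sample(seq(0.05, beta_span / spec$n_decorations * 1.82,
                       length.out = spec$n_decorations))
    intercept <- 6.2
    site_penalty <- 1.5
    truth_rows <- list()
    mols <- list()

    make_compound <- function(id, kind) {
      z <- stats::rbinom(spec$n_decorations, 1, 0.5)
      missing_sites <- integer(0)
      distort <- NULL
      if (kind == "inactive" || kind == "decoy_del") {
        # delete interior sites only: decoys keep the two extremal anchor
        # sites so every compound stays globally superimposable (real
        # inactive analogs typically share the scaffold termini)
        interior <- setdiff(seq_len(nrow(spec$template_sites)),
                            c(1L, nrow(spec$template_sites)))
        missing_sites <- sort(sample(interior, 2L))
      } else if (kind == "decoy_dist") {
        distort <- sort(sample(nrow(spec$template_sites), 3L))
      }
      conf_list <- build_planted_conformers(
        spec$template_sites, slots, z, missing_sites, distort,
        spec$site_jitter_A, spec$n_conformers)
      lin <- intercept + sum(beta * z) - site_penalty * length(missing_sites)
      is_lib <- kind %in% c("lib_active", "decoy_del", "decoy_dist")
      pic <- if (is_lib) NA_real_ else lin + stats::rnorm(1, 0, spec$activity_noise_sd)
      m <- molecule(id, pIC50 = pic, conformers = conf_list,
                    is_active = kind %in% c("active", "lib_active"))
      truth_rows[[length(truth_rows) + 1]] <<- data.frame(
        id = id, role = kind, true_linear_pIC50 = lin,
        missing_sites = paste(missing_sites, collapse = ";"),
        z = paste(z, collapse = ""), stringsAsFactors = FALSE)
      m
    }

    for (i in seq_len(spec$n_actives)) {
      mols[[length(mols) + 1]] <- make_compound(sprintf("ACT_%03d", i), "active")
    }
    for (i in seq_len(spec$n_inactives)) {
      mols[[length(mols) + 1]] <- make_compound(sprintf("INA_%03d", i), "inactive")
    }
    lib <- list()
    n_lib_act <- round(spec$library_active_fraction * spec$n_library)
    for (i in seq_len(spec$n_library)) {
      kind <- if (i <= n_lib_act) "lib_active" else {
        if (i %% 2 == 0) "decoy_del" else "decoy_dist"
      }
      lib[[length(lib) + 1]] <- make_compound(sprintf("LIB_%03d", i), kind)
    }
    mols <- perceive_dataset_features(mols)
    lib <- perceive_dataset_features(lib)
    truth <- list(
      template_sites = spec$template_sites,
      decoration_slots = slots,
      beta = beta, intercept = intercept, site_penalty = site_penalty,
      compounds = do.call(rbind, truth_rows),
      seed = spec$seed
    )
    structure(list(molecules = mols, library = lib, truth = truth,
                   spec = spec),
              class = "qp_synthetic_dataset")
  })
}

#' Decoration slots: rigid-cluster anchor positions hung off the
#' template's ring sites (or, lacking rings, off any site). Placement is a
#' deterministic greedy max-min search over ring-anchored candidates
#' (twelve in-plane angles x two out-of-plane elevations) so every slot
#' keeps clear of the template sites and of the other slots.
#' @noRd
decoration_slots <- function(template, n_dec) {
  hosts <- which(template$kind == "R")
  if (length(hosts) == 0) hosts <- seq_len(nrow(template))
  host <- rep(hosts, length.out = n_dec)
  tmpl_xyz <- site_xyz(template)
  placed <- matrix(numeric(0), ncol = 3)
  pos <- matrix(0, n_dec, 3)
  for (j in seq_len(n_dec)) {
    ctr <- as.numeric(template[host[j], c("x", "y", "z")])
    nrm <- as.numeric(template[host[j], c("dx", "dy", "dz")])
    if (any(is.na(nrm))) nrm <- c(0, 0, 1)
    u <- unit_vec(pracma_nullspace_vec(nrm))
    v <- unit_vec(cross3(nrm, u))
    best <- NULL; best_d <- -Inf
    for (ang in 2 * pi * (0:11) / 12) {
      for (h in c(2.2, -2.2)) {
        cand <- ctr + 2.0 * (cos(ang) * u + sin(ang) * v) + h * nrm
        ref <- rbind(tmpl_xyz, placed)
        d <- min(sqrt(rowSums(sweep(ref, 2, cand)^2)))
        if (d > best_d) { best_d <- d; best <- cand }
      }
    }
    pos[j, ] <- best
    placed <- rbind(placed, best)
  }
  list(host = host, pos = pos)
}

#' @noRd
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Any vector orthogonal to v
#' @noRd
pracma_nullspace_vec <- function(v) {
  a <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  cross3(v, a)
}

#' Realize a planted compound as conformers (atoms, bonds, energies)
#' @noRd
build_planted_conformers <- function(template, slots, z, missing_sites,
                                     distort, jitter, n_conf) {
  sites <- template
  if (!is.null(distort)) {
    for (s in distort) {
      d <- unit_vec(stats::rnorm(3)) * stats::runif(1, 2.5, 5.0)
      sites[s, c("x", "y", "z")] <- sites[s, c("x", "y", "z")] + d
    }
  }
  keep <- setdiff(seq_len(nrow(sites)), missing_sites)
  sites <- sites[keep, , drop = FALSE]
  # per-site jitter, bounded by the jitter radius
  if (jitter > 0) {
    for (s in seq_len(nrow(sites))) {
      d <- unit_vec(stats::rnorm(3)) * stats::runif(1, 0, jitter)
      sites[s, c("x", "y", "z")] <- sites[s, c("x", "y", "z")] + d
    }
  }
  built <- realize_site_groups(sites)
  # decorations on surviving host sites
  host_alive <- slots$host %in% keep
  host_newidx <- match(slots$host, keep)
  for (j in which(z == 1 & host_alive)) {
    # decorations sit at their exact template-frame positions (the shared
    # rigid scaffold carries them); positional noise enters the dataset
    # through the jittered core sites, so the occupancy signal of a
    # decoration stays concentrated in a stable set of grid cubes
    p <- slots$pos[j, ]
    attach_to <- built$link_atoms[host_newidx[j]]
    # cage-like cluster: centre plus an octahedral shell (1.8 A), ring
    # closed so no terminal-carbon hydrophobe sites are spawned
    centre <- nrow(built$coords) + 1L
    built$coords <- rbind(built$coords, p)
    built$elements <- c(built$elements, "C")
    built$charges <- c(built$charges, 0L)
    built$bonds <- rbind(built$bonds, c(centre, attach_to, 1L))
    oct <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
    tidx <- integer(6)
    for (t in seq_len(nrow(oct))) {
      built$coords <- rbind(built$coords, p + 1.8 * oct[t, ])
      built$elements <- c(built$elements, "C")
      built$charges <- c(built$charges, 0L)
      tidx[t] <- nrow(built$coords)
      built$bonds <- rbind(built$bonds, c(tidx[t], centre, 1L))
    }
    ring_order <- c(1, 3, 2, 4)
    for (t in seq_len(4)) {
      built$bonds <- rbind(built$bonds,
        c(tidx[ring_order[t]], tidx[ring_order[if (t == 4) 1 else t + 1]], 1L))
    }
    built$bonds <- rbind(built$bonds, c(tidx[5], tidx[1], 1L),
                         c(tidx[6], tidx[2], 1L))
  }
  base <- conformer(built$coords, built$elements, built$bonds, energy = 0,
                    charges = built$charges)
  confs <- list(base)
  if (n_conf >= 2) {
    for (k in 2:n_conf) confs[[k]] <- bend_conformer(base)
  }
  energies <- c(stats::runif(1, 0, 0.5),
                if (n_conf >= 2) stats::runif(n_conf - 1, 2, 8))
  for (k in seq_along(confs)) {
    rot <- random_rotation()
    trans <- stats::runif(3, -5, 5)
    confs[[k]]$coords <- apply_rigid(confs[[k]]$coords, rot, trans)
    confs[[k]]$energy <- energies[k]
  }
  rereference_energies(confs)
}

#' Place atoms/bonds realizing each typed site; returns the assembly plus
#' one designated linkable atom per site (used for backbone and decorations).
#' @noRd
realize_site_groups <- function(sites) {
  coords <- matrix(numeric(0), ncol = 3)
  elements <- character(0)
  bonds <- matrix(integer(0), ncol = 3)
  link_atoms <- integer(nrow(sites))   # decoration/backbone attachment
  entry_atoms <- integer(nrow(sites))  # backbone attachment on the other side
  charge_pairs <- matrix(integer(0), ncol = 2)
  add_atom <- function(p, el) {
    coords <<- rbind(coords, p)
    elements <<- c(elements, el)
    nrow(coords)
  }
  add_bond <- function(a, b, o) bonds <<- rbind(bonds, c(a, b, as.integer(o)))
  for (s in seq_len(nrow(sites))) {
    p <- as.numeric(sites[s, c("x", "y", "z")])
    dirv <- as.numeric(sites[s, c("dx", "dy", "dz")])
    if (any(is.na(dirv))) dirv <- c(0, 0, 1)
    kind <- sites$kind[s]
    if (kind == "R") {
      u <- unit_vec(pracma_nullspace_vec(dirv))
      v <- unit_vec(cross3(dirv, u))
      idx <- integer(6)
      for (a in 1:6) {
        ang <- 2 * pi * (a - 1) / 6
        idx[a] <- add_atom(p + 1.39 * (cos(ang) * u + sin(ang) * v), "C")
      }
      for (a in 1:6) add_bond(idx[a], idx[if (a == 6) 1 else a + 1],
                              if (a %% 2 == 1) 2L else 1L)
      link_atoms[s] <- idx[2]
      entry_atoms[s] <- idx[5]
    } else if (kind == "D") {
      nA <- add_atom(p, "N")
      cA <- add_atom(p - 1.47 * dirv, "C")
      add_bond(nA, cA, 1L)
      link_atoms[s] <- cA
      entry_atoms[s] <- cA
    } else if (kind == "A") {
      oA <- add_atom(p, "O")
      cA <- add_atom(p - 1.23 * dirv, "C")
      add_bond(cA, oA, 2L)
      link_atoms[s] <- cA
      entry_atoms[s] <- cA
    } else if (kind == "H") {
      hA <- add_atom(p, "C")
      cA <- add_atom(p - 1.52 * dirv, "C")
      add_bond(hA, cA, 1L)
      link_atoms[s] <- cA
      entry_atoms[s] <- cA
    } else if (kind %in% c("N", "P")) {
      q <- if (kind == "N") -1L else 1L
      el <- if (kind == "N") "O" else "N"
      xA <- add_atom(p, el)
      cA <- add_atom(p - 1.4 * dirv, "C")
      add_bond(xA, cA, 1L)
      link_atoms[s] <- cA
      entry_atoms[s] <- cA
      charge_pairs <- rbind(charge_pairs, c(xA, q))
    }
  }
  # backbone: connect consecutive groups so the molecule is one fragment
  if (nrow(sites) > 1) {
    for (s in seq_len(nrow(sites) - 1)) {
      add_bond(link_atoms[s], entry_atoms[s + 1], 1L)
    }
  }
  chg <- integer(nrow(coords))
  if (nrow(charge_pairs) > 0) chg[charge_pairs[, 1]] <- charge_pairs[, 2]
  list(coords = coords, elements = elements, bonds = bonds,
       link_atoms = link_atoms, charges = chg)
}

#' Torsion-like distortion: rotate the spatial "tail" half of the molecule
#' about a random axis through its centroid boundary.
#' @noRd
bend_conformer <- function(conf) {
  xyz <- conf$coords
  pc1 <- svd(sweep(xyz, 2, colMeans(xyz)))$v[, 1]
  proj <- as.numeric(sweep(xyz, 2, colMeans(xyz)) %*% pc1)
  tail_idx <- which(proj > stats::median(proj))
  pivot <- colMeans(xyz[tail_idx, , drop = FALSE])
  axis <- unit_vec(stats::rnorm(3))
  ang <- stats::runif(1, pi / 6, pi / 2)
  rot <- rotvec_to_matrix(axis * ang)
  xyz[tail_idx, ] <- sweep(sweep(xyz[tail_idx, , drop = FALSE], 2, pivot) %*% t(rot),
                           2, pivot, `+`)
  conformer(xyz, conf$elements, conf$bonds, energy = conf$energy,
            charges = conf$charges)
}

#' Write fixture files for a synthetic dataset
#'
#' Emits `train.sdf`, `test.sdf` (7:3 diversity split of the labelled
#' molecules), `library.sdf`, `activities.csv` and `truth.json` (planted
#' coefficients and template geometry).
#'
#' @param dataset from [generate_dataset()].
#' @param out_dir output directory (created if needed).
#' @param split_seed seed for the diversity split (defaults to the
#'   generator seed).
#' @return named character vector of file paths.
#' @export
write_fixture_files <- function(dataset, out_dir, split_seed = NULL) {
  stopifnot(inherits(dataset, "qp_synthetic_dataset"),
            length(dataset$molecules) > 0)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) stop("cannot create directory ", out_dir)
  }
  seed <- split_seed %||% dataset$spec$seed
  sp <- diversity_split(dataset$molecules, split_spec(seed = seed))
  paths <- c(train = file.path(out_dir, "train.sdf"),
             test = file.path(out_dir, "test.sdf"),
             library = file.path(out_dir, "library.sdf"),
             activities = file.path(out_dir, "activities.csv"),
             truth = file.path(out_dir, "truth.json"))
  write_sdf_dataset(sp$train, paths["train"])
  write_sdf_dataset(sp$test, paths["test"])
  write_sdf_dataset(dataset$library, paths["library"])
  acts <- data.frame(
    id = vapply(dataset$molecules, `[[`, character(1), "id"),
    pIC50 = vapply(dataset$molecules, `[[`, numeric(1), "pIC50"),
    is_active = vapply(dataset$molecules, function(m) isTRUE(m$is_active),
                       logical(1)))
  utils::write.csv(acts, paths["activities"], row.names = FALSE)
  truth <- dataset$truth
  truth_json <- list(
    template_sites = truth$template_sites,
    decoration_slots = list(host = truth$decoration_slots$host,
                            pos = truth$decoration_slots$pos),
    beta = truth$beta, intercept = truth$intercept,
    site_penalty = truth$site_penalty, compounds = truth$compounds,
    seed = truth$seed)
  jsonlite::write_json(truth_json, paths["truth"], digits = NA,
                       dataframe = "columns", matrix = "rowmajor")
  paths
}

#' Recovered per-decoration effects of a fitted QSAR model
#'
#' Parameter-recovery experiment: `n_probe` fresh probe compounds are
#' generated from the planted template (random decoration patterns, the
#' dataset's jitter), predicted with the model, and the predictions are
#' regressed on the decoration indicator matrix. The regression
#' coefficients are the model's recovered per-decoration effects,
#' comparable to the planted vector `truth$beta`. A single zero-jitter
#' probe per slot would under-sample the occupancy smear that positional
#' jitter spreads over neighbouring grid cubes; regressing over jittered
#' probes integrates it out.
#'
#' @param model a fitted `qp_qsar_model`.
#' @param dataset the `qp_synthetic_dataset` the model was trained on (its
#'   truth block provides template, slots and beta).
#' @param n_probe number of probe compounds.
#' @param seed RNG seed for the probe set.
#' @return data.frame with columns slot, beta (planted), effect (recovered).
#' @export
decoration_effects <- function(model, dataset, n_probe = 200L, seed = 1L) {
  truth <- dataset$truth
  spec <- dataset$spec
  slots <- truth$decoration_slots
  n_dec <- length(truth$beta)
  with_seed(seed, {
    Z <- matrix(stats::rbinom(n_probe * n_dec, 1, 0.5), n_probe, n_dec)
    pred <- numeric(n_probe)
    for (i in seq_len(n_probe)) {
      confs <- build_planted_conformers(
        truth$template_sites, slots, Z[i, ], integer(0), NULL,
        spec$site_jitter_A, 1L)
      cf <- confs[[1]]
      cf$features <- perceive_features(cf)
      pred[i] <- predict_activity(model, cf)
    }
    ok <- !is.na(pred)
    fit <- stats::lm.fit(cbind(1, Z[ok, , drop = FALSE]), pred[ok])
    data.frame(slot = seq_len(n_dec), beta = truth$beta,
               effect = unname(fit$coefficients[-1]))
  })
}
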