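#' Conformer-ensemble generation parameters
#'
#' Caps mirror the screening protocol: at most 10 conformers per rotatable
#' bond (with a floor of one bond for rigid molecules), at most 100 in
#' total, and an energy window above the ensemble minimum of 10 kcal/mol
#' for library compounds (query ensembles use 30 kcal/mol). Amide-bond
#' rotamers are enumerated by default.
#'
#' @param max_per_rotatable_bond integer cap per rotatable bond.
#' @param max_total overall conformer cap.
#' @param energy_window_kcal retain conformers within this window of the
#'   minimum (kcal/mol).
#' @param vary_amide treat amide C-N bonds as rotatable.
#' @return list of class `qp_conformer_params`.
#' @export
conformer_params <- function(max_per_rotatable_bond = 10L, max_total = 100L,
                             energy_window_kcal = 10.0, vary_amide = TRUE) {
  stopifnot(max_per_rotatable_bond > 0, max_total > 0, energy_window_kcal > 0)
  structure(list(max_per_rotatable_bond = as.integer(max_per_rotatable_bond),
                 max_total = as.integer(max_total),
                 energy_window_kcal = energy_window_kcal,
                 vary_amide = isTRUE(vary_amide)),
            class = "qp_conformer_params")
}

#' Count rotatable bonds from the connection table
#'
#' A bond is rotatable when it is a single bond, not in a ring, and both
#' atoms have at least one further heavy neighbour (no terminal twists).
#' Amide C-N bonds are counted only when `vary_amide` is TRUE.
#'
#' @param conf a [conformer()].
#' @param vary_amide include amide bonds.
#' @return integer count.
#' @export
count_rotatable_bonds <- function(conf, vary_amide = TRUE) {
  bonds <- conf$bonds
  if (nrow(bonds) == 0) return(0L)
  el <- conf$elements
  n <- nrow(conf$coords)
  adj <- bond_adjacency(bonds, n)
  ring_atoms <- find_rings(bonds, n, sizes = 3:8)
  in_ring_bond <- function(a1, a2) {
    any(vapply(ring_atoms, function(r) {
      a1 %in% r && a2 %in% r
    }, logical(1)))
  }
  heavy_deg <- vapply(seq_len(n), function(i) sum(el[adj[[i]]] != "H"), integer(1))
  cnt <- 0L
  for (b in seq_len(nrow(bonds))) {
    a1 <- bonds[b, 1]; a2 <- bonds[b, 2]
    if (bonds[b, 3] != 1) next
    if (el[a1] == "H" || el[a2] == "H") next
    if (heavy_deg[a1] < 2 || heavy_deg[a2] < 2) next
    if (in_ring_bond(a1, a2)) next
    if (!vary_amide && is_amide_bond(conf, a1, a2)) next
    cnt <- cnt + 1L
  }
  cnt
}

#' @noRd
is_amide_bond <- function(conf, a1, a2) {
  el <- conf$elements
  pair_is <- function(c_at, n_at) {
    if (el[c_at] != "C" || el[n_at] != "N") return(FALSE)
    rows <- bond_rows(conf$bonds, c_at)
    any(conf$bonds[rows, 3] == 2 &
          el[ifelse(conf$bonds[rows, 1] == c_at,
                    conf$bonds[rows, 2], conf$bonds[rows, 1])] == "O")
  }
  pair_is(a1, a2) || pair_is(a2, a1)
}

#' Generate a conformer ensemble for a molecule
#'
#' For molecules with a connection table (real structures) the ensemble is
#' produced by OpenBabel's systematic torsion driver (confab) and scored
#' with the MMFF94 force field; the enumeration is deterministic, so the
#' result is identical for any seed. Synthetic molecules built by
#' [generate_dataset()] already carry generator-assigned ensembles and are
#' returned unchanged. Energies are re-referenced so the ensemble minimum
#' is zero and conformers outside the energy window are discarded; the
#' ensemble is truncated to `min(max_per_rotatable_bond * max(rotbonds, 1),
#' max_total)` lowest-energy members.
#'
#' @param mol a [molecule()] with at least one 3D conformer (or a SMILES
#'   that can be embedded).
#' @param params a [conformer_params()].
#' @param seed integer; kept for interface stability (the torsion driver is
#'   systematic and seed-independent).
#' @return the molecule with its conformer list replaced.
#' @export
generate_conformers <- function(mol, params = conformer_params(), seed = 1L) {
  stopifnot(inherits(mol, "qp_molecule"))
  if (length(mol$conformers) == 0) {
    if (is.na(mol$smiles) || !has_obabel()) {
      stop("molecule ", mol$id, " has no 3D conformer and cannot be embedded")
    }
    mol <- embed_molecules_3d(list(mol))[[1]]
    if (length(mol$conformers) == 0) {
      stop("3D embedding failed for molecule ", mol$id)
    }
  }
  base <- mol$conformers[[1]]
  cap <- conformer_cap(base, params)
  if (has_obabel() && nrow(base$bonds) > 0) {
    ens <- confab_ensemble(base, mol$id, cap, params$energy_window_kcal)
    if (length(ens) > 0) mol$conformers <- ens
  }
  mol$conformers <- rereference_energies(mol$conformers)
  mol$conformers <- Filter(function(cf) cf$energy <= params$energy_window_kcal,
                           mol$conformers)
  o <- order(vapply(mol$conformers, `[[`, numeric(1), "energy"))
  mol$conformers <- mol$conformers[o][seq_len(min(cap, length(mol$conformers)))]
  mol
}

#' @noRd
conformer_cap <- function(conf, params) {
  rb <- count_rotatable_bonds(conf, params$vary_amide)
  min(params$max_per_rotatable_bond * max(rb, 1L), params$max_total)
}

#' Systematic ensemble via obabel --confab, energies via obenergy (MMFF94)
#' @noRd
confab_ensemble <- function(conf, id, cap, window) {
  fin <- tempfile(fileext = ".sdf")
  fout <- tempfile(fileext = ".sdf")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(conformer_to_sdf(conf, id), fin)
  obabel_run(c(fin, "-O", fout, "--confab",
               "--conf", as.character(cap),
               "--ecutoff", as.character(window)))
  if (!file.exists(fout) || file.size(fout) == 0) return(list())
  ens_mols <- tryCatch(read_sdf_dataset(fout), error = function(e) NULL)
  if (is.null(ens_mols)) return(list())
  confs <- unlist(lapply(ens_mols, `[[`, "conformers"), recursive = FALSE)
  energies <- obenergy_kcal(fout)
  if (length(energies) == length(confs)) {
    for (i in seq_along(confs)) confs[[i]]$energy <- energies[i]
  } else {
    for (i in seq_along(confs)) confs[[i]]$energy <- 0
  }
  confs
}

#' @noRd
obenergy_kcal <- function(sdf_path) {
  out <- suppressWarnings(system2("obenergy", c("-ff", "MMFF94", sdf_path),
                                  stdout = TRUE, stderr = FALSE))
  vals <- grep("TOTAL ENERGY", out, value = TRUE)
  as.numeric(sub(".*=\\s*([-0-9.eE+]+)\\s*kcal/mol.*", "\\1", vals))
}

#' Re-reference conformer energies so the ensemble minimum is 0
#' @export
#' @param conformers list of [conformer()] objects.
#' @return the list with shifted energies.
rereference_energies <- function(conformers) {
  if (length(conformers) == 0) return(conformers)
  e <- vapply(conformers, `[[`, numeric(1), "energy")
  e <- e - min(e)
  for (i in seq_along(conformers)) conformers[[i]]$energy <- e[i]
  conformers
}

#' Perceive features on every conformer of every molecule
#'
#' @param mols list of molecules.
#' @param rules feature rule table.
#' @return the molecules with per-conformer feature tables filled.
#' @export
perceive_dataset_features <- function(mols, rules = pharmacophore_feature_rules()) {
  lapply(mols, function(m) {
    m$conformers <- lapply(m$conformers, function(cf) {
      cf$features <- perceive_features(cf, rules)
      cf
    })
    m
  })
}
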