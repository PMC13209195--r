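#' Molecule, conformer and pharmacophore-site containers
#'
#' Small-molecule records flow through the pipeline as lightweight S3 lists:
#' a `qp_molecule` carries an id, a SMILES string when known, an activity
#' (IC50 in nM and/or its pIC50), and a list of `qp_conformer` objects. A
#' conformer holds heavy-atom 3D coordinates in Angstrom, element symbols,
#' the bond table, a relative conformational energy (kcal/mol, re-referenced
#' so the ensemble minimum is 0) and, once perceived, a table of typed
#' pharmacophore sites.
#'
#' @param id character scalar, unique within a dataset.
#' @param smiles SMILES string or `NA`.
#' @param activity_nM positive IC50 in nanomolar, or `NA`.
#' @param pIC50 negative log10 of molar IC50, or `NA`; when exactly one of
#'   `activity_nM`/`pIC50` is given the other is filled by conversion.
#' @param conformers list of `qp_conformer` objects.
#' @param is_active optional logical ground-truth label (synthetic sets).
#' @return An object of class `qp_molecule`.
#' @export
molecule <- function(id, smiles = NA_character_, activity_nM = NA_real_,
                     pIC50 = NA_real_, conformers = list(), is_active = NA) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!is.na(activity_nM) && activity_nM <= 0) {
    stop("activity_nM must be positive for molecule ", id)
  }
  if (is.na(pIC50) && !is.na(activity_nM)) pIC50 <- to_pIC50(activity_nM)
  if (is.na(activity_nM) && !is.na(pIC50)) activity_nM <- from_pIC50(pIC50)
  structure(
    list(id = id, smiles = smiles, activity_nM = activity_nM,
         pIC50 = pIC50, conformers = conformers, is_active = is_active),
    class = "qp_molecule"
  )
}

#' @param coords numeric n x 3 matrix of heavy-atom positions (Angstrom).
#' @param elements character vector of element symbols, length n.
#' @param bonds integer m x 3 matrix: atom1, atom2, bond order (4 = aromatic);
#'   may have zero rows for disconnected point sets.
#' @param energy relative conformational energy in kcal/mol (>= 0 once the
#'   ensemble is re-referenced).
#' @param charges integer formal charges per atom (default all 0).
#' @param features pharmacophore site table from [perceive_features()], or
#'   `NULL` before perception.
#' @rdname molecule
#' @export
conformer <- function(coords, elements, bonds = NULL, energy = 0,
                      charges = NULL, features = NULL) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3, nrow(coords) == length(elements))
  if (is.null(bonds)) bonds <- matrix(integer(0), ncol = 3)
  bonds <- matrix(as.integer(bonds), ncol = 3)
  if (is.null(charges)) charges <- integer(nrow(coords))
  stopifnot(length(charges) == nrow(coords), energy >= -1e-9 || is.na(energy))
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(
    list(coords = coords, elements = as.character(elements), bonds = bonds,
         energy = as.numeric(energy), charges = as.integer(charges),
         features = features),
    class = "qp_conformer"
  )
}

#' Construct a pharmacophore feature-site table
#'
#' Sites are typed points with an optional unit direction: `A` (H-bond
#' acceptor), `D` (donor), `H` (hydrophobe), `N` (negative), `P` (positive),
#' `R` (aromatic ring). Directions are carried for A, D and R sites
#' (lone-pair / H axis, ring normal).
#'
#' @param kind character vector over the six-letter alphabet A/D/H/N/P/R.
#' @param xyz numeric n x 3 matrix of site positions (Angstrom).
#' @param dir numeric n x 3 matrix of unit directions; rows may be `NA` for
#'   kinds that carry no direction.
#' @return A data.frame with columns kind, x, y, z, dx, dy, dz.
#' @export
feature_sites <- function(kind, xyz, dir = NULL) {
  kind <- as.character(kind)
  stopifnot(all(kind %in% c("A", "D", "H", "N", "P", "R")))
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  stopifnot(nrow(xyz) == length(kind))
  if (is.null(dir)) dir <- matrix(NA_real_, nrow(xyz), 3)
  dir <- matrix(as.numeric(dir), ncol = 3)
  ok <- !is.na(dir[, 1])
  if (any(ok)) {
    nrm <- sqrt(rowSums(dir[ok, , drop = FALSE]^2))
    if (any(abs(nrm - 1) > 1e-6)) {
      dir[ok, ] <- dir[ok, , drop = FALSE] / nrm
    }
  }
  data.frame(kind = kind, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             dx = dir[, 1], dy = dir[, 2], dz = dir[, 3],
             stringsAsFactors = FALSE)
}

#' Order a feature table deterministically: by kind, then position
#' @noRd
order_features <- function(ft) {
  if (is.null(ft) || nrow(ft) == 0) return(ft)
  o <- order(ft$kind, round(ft$x, 6), round(ft$y, 6), round(ft$z, 6))
  ft <- ft[o, , drop = FALSE]
  rownames(ft) <- NULL
  ft
}

#' @export
print.qp_molecule <- function(x, ...) {
  cat(sprintf("<molecule %s> pIC50=%s conformers=%d\n", x$id,
              ifelse(is.na(x$pIC50), "NA", sprintf("%.2f", x$pIC50)),
              length(x$conformers)))
  invisible(x)
}

#' @export
print.qp_conformer <- function(x, ...) {
  cat(sprintf("<conformer> atoms=%d energy=%.2f kcal/mol features=%s\n",
              nrow(x$coords), x$energy,
              if (is.null(x$features)) "unperceived" else nrow(x$features)))
  invisible(x)
}

#' Heavy-atom coordinates of a conformer (hydrogens excluded)
#' @noRd
heavy_coords <- function(conf) {
  conf$coords[conf$elements != "H", , drop = FALSE]
}

#' Feature positions as a matrix
#' @noRd
site_xyz <- function(ft) {
  as.matrix(ft[, c("x", "y", "z"), drop = FALSE])
}

#' Feature directions as a matrix
#' @noRd
site_dir <- function(ft) {
  as.matrix(ft[, c("dx", "dy", "dz"), drop = FALSE])
}
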