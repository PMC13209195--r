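# SDF (V2000) bridge: conformers are written with an in-package text writer
# (so property fields, energies and formal charges are fully controlled) and
# read back through ChemmineR's parser.

chg_to_code <- function(chg) {
  code <- integer(length(chg))
  code[chg == 3] <- 1L; code[chg == 2] <- 2L; code[chg == 1] <- 3L
  code[chg == -1] <- 5L; code[chg == -2] <- 6L; code[chg == -3] <- 7L
  code
}

code_to_chg <- function(code) {
  chg <- integer(length(code))
  chg[code == 1] <- 3L; chg[code == 2] <- 2L; chg[code == 3] <- 1L
  chg[code == 5] <- -1L; chg[code == 6] <- -2L; chg[code == 7] <- -3L
  chg
}

#' Render one conformer as an SDF (V2000) record
#'
#' @param conf a [conformer()].
#' @param id record id written to the header and the `<id>` field.
#' @param fields named character/numeric vector of extra data fields
#'   (e.g. activity); the conformer energy is always written as
#'   `<energy_kcal>`.
#' @return character vector of SDF lines (including the `$$$$` terminator).
#' @export
conformer_to_sdf <- function(conf, id, fields = c()) {
  n <- nrow(conf$coords)
  nb <- nrow(conf$bonds)
  lines <- c(id, "  qsarphore", "")
  lines <- c(lines, sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
  codes <- chg_to_code(conf$charges)
  for (i in seq_len(n)) {
    lines <- c(lines, sprintf(
      "%10.4f%10.4f%10.4f %-3s%2d%3d  0  0  0  0  0  0  0  0  0  0",
      conf$coords[i, 1], conf$coords[i, 2], conf$coords[i, 3],
      conf$elements[i], 0L, codes[i]))
  }
  for (b in seq_len(nb)) {
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                              conf$bonds[b, 1], conf$bonds[b, 2],
                              conf$bonds[b, 3]))
  }
  chgd <- which(conf$charges != 0)
  if (length(chgd) > 0) {
    for (grp in split(chgd, ceiling(seq_along(chgd) / 8))) {
      lines <- c(lines, paste0(
        sprintf("M  CHG%3d", length(grp)),
        paste(sprintf("%4d%4d", grp, conf$charges[grp]), collapse = "")))
    }
  }
  lines <- c(lines, "M  END")
  fields <- c(fields, energy_kcal = sprintf("%.6f", conf$energy))
  fields <- c(id = id, fields)
  for (nm in names(fields)) {
    lines <- c(lines, sprintf(">  <%s>", nm), as.character(fields[[nm]]), "")
  }
  c(lines, "$$$$")
}

#' Write molecules to an SDF file
#'
#' Each conformer becomes one record; records of the same molecule share the
#' molecule id and data fields and are distinguished by a `<conformer>`
#' index field.
#'
#' @param mols list of [molecule()] objects (with conformers).
#' @param path output file.
#' @param all_conformers write every conformer (default) or only the first.
#' @return `path`, invisibly.
#' @export
write_sdf_dataset <- function(mols, path, all_conformers = TRUE) {
  out <- character(0)
  for (m in mols) {
    confs <- if (all_conformers) m$conformers else m$conformers[1]
    for (ci in seq_along(confs)) {
      fields <- c(conformer = as.character(ci))
      if (!is.na(m$pIC50)) fields <- c(fields, pIC50 = sprintf("%.6f", m$pIC50))
      if (!is.na(m$activity_nM)) {
        fields <- c(fields, activity_nM = sprintf("%.6f", m$activity_nM))
      }
      if (!is.na(m$smiles)) fields <- c(fields, smiles = m$smiles)
      if (!is.na(m$is_active)) {
        fields <- c(fields, is_active = as.character(as.integer(m$is_active)))
      }
      out <- c(out, conformer_to_sdf(confs[[ci]], m$id, fields))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Parse an SDF file into molecules (ChemmineR parser underneath)
#'
#' Multi-record molecules (same `<id>` field) are merged into one molecule
#' with a conformer per record. Unparsable records are skipped with a count
#' reported.
#'
#' @param path SDF file.
#' @return list of [molecule()] objects.
#' @export
read_sdf_dataset <- function(path) {
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(path, skipErrors = TRUE))
  valid <- ChemmineR::validSDF(sdfset)
  n_bad <- sum(!valid)
  if (n_bad > 0) qp_log(n_bad, " unparsable SDF record(s) skipped in ", path)
  raw_chg <- raw_record_charges(path)
  sdfset <- sdfset[valid]
  raw_chg <- raw_chg[valid]
  if (length(sdfset) == 0) stop("no parsable records in ", path)
  getf <- function(db, nm) if (nm %in% names(db)) db[[nm]] else NULL
  mols <- list()
  for (i in seq_along(sdfset)) {
    sdf <- sdfset[[i]]
    conf <- sdf_to_conformer(sdf, raw_chg[[i]])
    db <- ChemmineR::datablock(sdf)
    id <- getf(db, "id") %||% ChemmineR::sdfid(sdfset[i])
    if (is.null(id) || is.na(id) || !nzchar(id)) id <- paste0("mol_", i)
    energy <- suppressWarnings(as.numeric(getf(db, "energy_kcal") %||% NA))
    if (!is.na(energy)) conf$energy <- energy
    pic <- suppressWarnings(as.numeric(getf(db, "pIC50") %||% NA))
    act <- suppressWarnings(as.numeric(getf(db, "activity_nM") %||% NA))
    smi <- getf(db, "smiles") %||% NA_character_
    lab <- suppressWarnings(as.integer(getf(db, "is_active") %||% NA))
    if (is.null(mols[[id]])) {
      mols[[id]] <- molecule(id, smiles = smi, activity_nM = act, pIC50 = pic,
                             conformers = list(conf),
                             is_active = if (is.na(lab)) NA else lab == 1L)
    } else {
      mols[[id]]$conformers <- c(mols[[id]]$conformers, list(conf))
    }
  }
  unname(mols)
}

#' Convert one ChemmineR SDF object to a conformer
#' @noRd
sdf_to_conformer <- function(sdf, charge_pairs = NULL) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  coords <- ab[, 1:3, drop = FALSE]
  elements <- sub("_.*$", "", rownames(ab))
  bonds <- if (nrow(bb) > 0) {
    matrix(as.integer(as.matrix(bb[, 1:3, drop = FALSE])), ncol = 3)
  } else matrix(integer(0), ncol = 3)
  charges <- integer(nrow(coords))
  if (!is.null(charge_pairs) && nrow(charge_pairs) > 0) {
    ok <- charge_pairs[, 1] >= 1 & charge_pairs[, 1] <= nrow(coords)
    charges[charge_pairs[ok, 1]] <- charge_pairs[ok, 2]
  }
  conformer(coords, elements, bonds, energy = 0, charges = charges)
}

#' Per-record formal charges from raw M CHG lines (ChemmineR drops them).
#' Returns a list (one 2-column matrix atom/charge per record) aligned with
#' the file's record order; tolerant of Windows line endings.
#' @noRd
raw_record_charges <- function(path) {
  lines <- gsub("\r$", "", readLines(path, warn = FALSE))
  rec_end <- grep("^\\$\\$\\$\\$", lines)
  starts <- c(1L, head(rec_end, -1) + 1L)
  lapply(seq_along(rec_end), function(i) {
    seg <- lines[starts[i]:rec_end[i]]
    pairs <- matrix(integer(0), ncol = 2)
    for (ln in grep("^M  CHG", seg, value = TRUE)) {
      body <- sub("^M  CHG\\s*\\d+", "", ln)
      vals <- suppressWarnings(as.integer(strsplit(trimws(body), "\\s+")[[1]]))
      if (length(vals) >= 2) {
        pairs <- rbind(pairs, cbind(vals[seq(1, length(vals) - 1, 2)],
                                    vals[seq(2, length(vals), 2)]))
      }
    }
    pairs
  })
}
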