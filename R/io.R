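#' Read a ligand dataset with cleaning rules
#'
#' Ingests an SDF file or a SMILES+CSV table, then applies the dataset
#' curation rules: salt/fragment stripping (largest organic fragment kept),
#' removal of duplicate canonical structures, and removal of records whose
#' declared activity is not an exact number (range-based entries such as
#' `">10000"` are dropped). Exactly-one of IC50 (nM) and pIC50 is required
#' per record; the other is filled by conversion.
#'
#' @param path input file. For `format = "smiles_csv"` a CSV with columns
#'   `id`, `smiles` and (optionally) `activity_nM` or `pIC50`.
#' @param format `"sdf"` or `"smiles_csv"`.
#' @param require_activity when TRUE (an activity column is declared),
#'   records without an exact numeric activity are dropped.
#' @param embed_3d for SMILES input, generate one 3D conformer per molecule
#'   (OpenBabel); requires the `obabel` executable.
#' @return list of [molecule()] objects with unique ids.
#' @export
read_dataset <- function(path, format = c("sdf", "smiles_csv"),
                         require_activity = TRUE, embed_3d = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty input file: ", path)
  if (format == "sdf") {
    mols <- read_sdf_dataset(path)
  } else {
    mols <- read_smiles_csv(path, embed_3d = embed_3d)
  }
  has_activity_col <- any(vapply(mols, function(m) {
    !is.na(m$pIC50) || !is.na(m$activity_nM) || isTRUE(attr(m, "bad_activity"))
  }, logical(1)))
  if (require_activity && has_activity_col) {
    n0 <- length(mols)
    mols <- Filter(function(m) !is.na(m$pIC50), mols)
    if (n0 - length(mols) > 0) {
      qp_log(n0 - length(mols), " record(s) dropped: no exact numeric activity")
    }
  }
  mols <- deduplicate_molecules(mols)
  if (length(mols) == 0) stop("zero molecules survive dataset cleaning: ", path)
  ids <- vapply(mols, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate molecule ids after cleaning: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  mols
}

#' @noRd
read_smiles_csv <- function(path, embed_3d = TRUE) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(tab) <- tolower(names(tab))
  if (!all(c("id", "smiles") %in% names(tab))) {
    stop("smiles_csv input needs columns id, smiles")
  }
  n_skip <- 0L
  mols <- list()
  for (i in seq_len(nrow(tab))) {
    act <- NA_real_; pic <- NA_real_; bad <- FALSE
    if ("activity_nm" %in% names(tab)) {
      raw <- as.character(tab$activity_nm[i])
      act <- suppressWarnings(as.numeric(raw))
      if (is.na(act) && nzchar(trimws(raw %||% ""))) bad <- TRUE
      if (!is.na(act) && act <= 0) { act <- NA_real_; bad <- TRUE }
    }
    if ("pic50" %in% names(tab)) {
      pic <- suppressWarnings(as.numeric(as.character(tab$pic50[i])))
    }
    m <- tryCatch(
      molecule(as.character(tab$id[i]), smiles = tab$smiles[i],
               activity_nM = act, pIC50 = pic),
      error = function(e) NULL)
    if (is.null(m)) { n_skip <- n_skip + 1L; next }
    attr(m, "bad_activity") <- bad
    mols[[length(mols) + 1]] <- m
  }
  if (n_skip > 0) qp_log(n_skip, " unparsable CSV record(s) skipped")
  if (length(mols) == 0) stop("no parsable records in ", path)
  if (embed_3d) mols <- embed_molecules_3d(mols)
  mols
}

#' Remove duplicate structures arising from salt forms or fragments.
#'
#' The duplicate key is the canonical SMILES of the largest organic
#' fragment (OpenBabel `-r -ocan`); the first record (file order) of each
#' key is kept. Molecules with no structure (no SMILES and no conformer)
#' are keyed by id.
#' @noRd
deduplicate_molecules <- function(mols) {
  keys <- canonical_structure_keys(mols)
  keep <- !duplicated(keys)
  if (any(!keep)) {
    qp_log(sum(!keep), " duplicate structure(s) removed (salt/fragment forms)")
  }
  mols[keep]
}

#' Canonical largest-fragment SMILES per molecule via obabel; id fallback.
#' @noRd
canonical_structure_keys <- function(mols) {
  smis <- vapply(mols, function(m) {
    if (!is.na(m$smiles)) m$smiles else NA_character_
  }, character(1))
  keys <- paste0("id:", vapply(mols, `[[`, character(1), "id"))
  have <- which(!is.na(smis))
  no_smiles <- which(is.na(smis) &
                       vapply(mols, function(m) length(m$conformers) > 0, logical(1)))
  if (length(no_smiles) > 0 && has_obabel()) {
    # derive SMILES from the first conformer via a temporary SDF
    tmp <- tempfile(fileext = ".sdf")
    on.exit(unlink(tmp), add = TRUE)
    write_sdf_dataset(mols[no_smiles], tmp, all_conformers = FALSE)
    out <- obabel_run(c(tmp, "-ocan"))
    if (length(out) == length(no_smiles)) {
      smi2 <- vapply(strsplit(out, "\t|\\s+"), `[[`, character(1), 1)
      smis[no_smiles] <- smi2
      have <- which(!is.na(smis))
    }
  }
  if (length(have) > 0 && has_obabel()) {
    tmp <- tempfile(fileext = ".smi")
    on.exit(unlink(tmp), add = TRUE)
    writeLines(smis[have], tmp)
    out <- obabel_run(c(tmp, "-ocan", "-r"))
    if (length(out) == length(have)) {
      can <- vapply(strsplit(out, "\t|\\s+"), `[[`, character(1), 1)
      keys[have] <- paste0("can:", can)
    } else {
      keys[have] <- paste0("smi:", smis[have])
    }
  } else if (length(have) > 0) {
    keys[have] <- paste0("smi:", smis[have])
  }
  keys
}

#' Generate one 3D conformer per molecule from SMILES (OpenBabel --gen3d)
#' @noRd
embed_molecules_3d <- function(mols) {
  if (!has_obabel()) {
    qp_log("obabel not found; molecules left without 3D coordinates")
    return(mols)
  }
  smi <- tempfile(fileext = ".smi")
  sdf <- tempfile(fileext = ".sdf")
  on.exit(unlink(c(smi, sdf)), add = TRUE)
  ids <- vapply(mols, `[[`, character(1), "id")
  writeLines(paste0(vapply(mols, `[[`, character(1), "smiles"), "\t", ids), smi)
  obabel_run(c(smi, "-O", sdf, "--gen3d"))
  if (!file.exists(sdf) || file.size(sdf) == 0) {
    stop("3D embedding failed for all molecules")
  }
  embedded <- read_sdf_dataset(sdf)
  emb_ids <- vapply(embedded, `[[`, character(1), "id")
  failed <- setdiff(ids, emb_ids)
  if (length(failed) > 0) {
    qp_log(length(failed), " molecule(s) failed 3D embedding and were excluded: ",
           paste(failed, collapse = ", "))
  }
  out <- list()
  for (m in mols) {
    j <- match(m$id, emb_ids)
    if (is.na(j)) next
    m$conformers <- embedded[[j]]$conformers
    out[[length(out) + 1]] <- m
  }
  out
}

#' @noRd
has_obabel <- function() {
  nzchar(Sys.which("obabel"))
}

#' Run obabel quietly, returning stdout lines
#' @noRd
obabel_run <- function(args) {
  suppressWarnings(system2("obabel", args, stdout = TRUE, stderr = FALSE))
}

#' Join an external docking-score column onto a score table
#'
#' Docking scores are never computed here; they are accepted as an optional
#' per-compound CSV (`compound_id`, `docking_score`) and joined by id.
#'
#' @param table data.frame with a `compound_id` column.
#' @param csv_path CSV with columns compound_id, docking_score.
#' @return `table` with a `docking_score` column (NA where unmatched).
#' @export
join_docking_scores <- function(table, csv_path) {
  d <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  names(d) <- tolower(names(d))
  stopifnot(all(c("compound_id", "docking_score") %in% names(d)))
  table$docking_score <- d$docking_score[match(table$compound_id, d$compound_id)]
  table
}
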