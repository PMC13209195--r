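#' Common-pharmacophore hypothesis generation
#'
#' Candidate pharmacophores are k-site subsets of a conformer's perceived
#' sites. Candidates from the active compounds are grouped by a tree-style
#' distance partition: the sorted vector of all k(k-1)/2 pairwise intersite
#' distances is discretized into `n_bins` bins of `bin_width_A` (defaults: 8
#' bins of 2 A, covering [0, 16) with distances beyond the range clipped to
#' the top bin), and candidates sharing their canonical type label and the
#' full bin vector fall in the same group — equivalent to descending a
#' fixed binary tree of depth log2(n_bins) per pair. Groups matched by at
#' least `min_actives_matched` of the actives become hypotheses; each takes
#' its sites from the member contributed by the highest-pIC50 active (the
#' reference ligand).
#'
#' @name hypothesis-generation
NULL

#' Partition parameters for common-pharmacophore identification
#'
#' @param n_bins number of distance bins (8).
#' @param bin_width_A bin width in Angstrom (2.0).
#' @param min_actives_matched minimum fraction of actives a group must
#'   cover to survive (0.5).
#' @return list of class `qp_partition_params`.
#' @export
partition_params <- function(n_bins = 8L, bin_width_A = 2.0,
                             min_actives_matched = 0.5) {
  stopifnot(n_bins > 0, bin_width_A > 0,
            min_actives_matched > 0, min_actives_matched <= 1)
  structure(list(n_bins = as.integer(n_bins), bin_width_A = bin_width_A,
                 min_actives_matched = min_actives_matched),
            class = "qp_partition_params")
}

#' Enumerate candidate k-site pharmacophores of one conformer
#'
#' All C(n, k) site subsets (subject to `cap`, with deterministic
#' label-lexicographic truncation), each carrying its canonical label (site
#' kinds sorted alphabetically) and the sorted vector of pairwise intersite
#' distances.
#'
#' @param conf conformer with perceived features.
#' @param k subset size (>= 3 for a rigid pharmacophore; 2 allowed for toys).
#' @param cap maximum number of candidates returned.
#' @return list of candidates: `site_idx`, `label`, `dists` (sorted);
#'   empty list when the conformer has fewer than k sites.
#' @export
enumerate_pharmacophores <- function(conf, k, cap = 20000L) {
  ft <- conf$features
  if (is.null(ft)) stop("conformer features not perceived")
  n <- nrow(ft)
  if (n < k) return(list())
  xyz <- site_xyz(ft)
  combos <- utils::combn(n, k, simplify = FALSE)
  out <- lapply(combos, function(ix) {
    d <- stats::dist(xyz[ix, , drop = FALSE])
    list(site_idx = ix,
         label = paste(sort(ft$kind[ix]), collapse = ""),
         dists = sort(as.numeric(d)))
  })
  if (length(out) > cap) {
    labs <- vapply(out, `[[`, character(1), "label")
    out <- out[order(labs)][seq_len(cap)]
  }
  out
}

#' Bin vector of a sorted distance vector (clipped to the top bin)
#' @noRd
distance_bins <- function(dists, params) {
  b <- floor(dists / params$bin_width_A)
  pmin(b, params$n_bins - 1L)
}

#' @noRd
candidate_key <- function(cand, params) {
  paste0(cand$label, ":", paste(distance_bins(cand$dists, params),
                                collapse = ","))
}

#' Identify common pharmacophores across active compounds
#'
#' @param actives list of molecules with perceived conformer features;
#'   actives lacking any conformer with >= k sites are excluded with a log
#'   entry.
#' @param k number of sites per hypothesis (default 6; 3-7 sensible).
#' @param params a [partition_params()].
#' @param cap per-conformer candidate cap (see [enumerate_pharmacophores()]).
#' @return list of `qp_hypothesis` objects sorted by decreasing number of
#'   matched actives then label; empty (with a warning) when no group
#'   covers enough actives.
#' @export
find_common_pharmacophores <- function(actives, k = 6L,
                                       params = partition_params(),
                                       cap = 20000L) {
  stopifnot(length(actives) > 0)
  groups <- new.env(hash = TRUE)
  n_used <- 0L
  for (m in actives) {
    any_conf <- FALSE
    for (ci in seq_along(m$conformers)) {
      cands <- enumerate_pharmacophores(m$conformers[[ci]], k, cap)
      if (length(cands) == 0) next
      any_conf <- TRUE
      for (cand in cands) {
        key <- candidate_key(cand, params)
        ent <- groups[[key]]
        if (is.null(ent)) ent <- list()
        ent[[length(ent) + 1]] <- list(mol_id = m$id, pIC50 = m$pIC50,
                                       conf_idx = ci, cand = cand)
        groups[[key]] <- ent
      }
    }
    if (!any_conf) {
      qp_log("active ", m$id, " has no conformer with >= ", k,
             " sites; excluded from hypothesis generation")
    } else {
      n_used <- n_used + 1L
    }
  }
  if (n_used == 0L) stop("no active compound has enough pharmacophore sites")
  min_count <- params$min_actives_matched * n_used
  mol_index <- stats::setNames(seq_along(actives),
                               vapply(actives, `[[`, character(1), "id"))
  hyps <- list()
  for (key in ls(groups)) {
    members <- groups[[key]]
    mol_ids <- unique(vapply(members, `[[`, character(1), "mol_id"))
    if (length(mol_ids) < min_count) next
    pic <- vapply(members, `[[`, numeric(1), "pIC50")
    ids <- vapply(members, `[[`, character(1), "mol_id")
    # reference = member from the highest-pIC50 active; ties by id then
    # lower conformer index
    o <- order(-pic, ids, vapply(members, `[[`, numeric(1), "conf_idx"))
    ref <- members[[o[1]]]
    ref_mol <- actives[[mol_index[[ref$mol_id]]]]
    ref_conf <- ref_mol$conformers[[ref$conf_idx]]
    sites <- order_features(ref_conf$features[ref$cand$site_idx, , drop = FALSE])
    hyps[[length(hyps) + 1]] <- new_hypothesis(
      sites = sites, label = ref$cand$label,
      reference_ligand_id = ref$mol_id,
      reference_pIC50 = ref$pIC50,
      reference_conformer = ref_conf,
      n_actives_matched = length(mol_ids),
      matched_ids = sort(mol_ids),
      key = key)
  }
  if (length(hyps) == 0) {
    warning("no common pharmacophore covers the required fraction of actives")
    return(list())
  }
  o <- order(-vapply(hyps, `[[`, numeric(1), "n_actives_matched"),
             vapply(hyps, `[[`, character(1), "label"),
             vapply(hyps, `[[`, character(1), "key"))
  hyps[o]
}

#' @noRd
new_hypothesis <- function(sites, label, reference_ligand_id, reference_pIC50,
                           reference_conformer, n_actives_matched = NA_integer_,
                           matched_ids = character(0), key = NA_character_) {
  stopifnot(nrow(sites) >= 2)
  structure(list(sites = sites, label = label,
                 reference_ligand_id = reference_ligand_id,
                 reference_pIC50 = reference_pIC50,
                 reference_conformer = reference_conformer,
                 n_actives_matched = n_actives_matched,
                 matched_ids = matched_ids, key = key,
                 survival = NULL),
            class = "qp_hypothesis")
}

#' Construct a hypothesis directly from a site table (toys, planted truth)
#'
#' @param sites [feature_sites()] table.
#' @param reference_ligand_id,reference_pIC50 reference ligand metadata.
#' @param reference_conformer conformer realizing the sites (optional; used
#'   for volume scoring).
#' @return `qp_hypothesis` object.
#' @export
hypothesis_from_sites <- function(sites, reference_ligand_id = "ref",
                                  reference_pIC50 = NA_real_,
                                  reference_conformer = NULL) {
  sites <- order_features(sites)
  new_hypothesis(sites, paste(sort(sites$kind), collapse = ""),
                 reference_ligand_id, reference_pIC50, reference_conformer)
}

#' @export
print.qp_hypothesis <- function(x, ...) {
  cat(sprintf("<hypothesis %s> ref=%s pIC50=%s actives_matched=%s\n",
              x$label, x$reference_ligand_id,
              ifelse(is.na(x$reference_pIC50), "NA",
                     sprintf("%.2f", x$reference_pIC50)),
              x$n_actives_matched))
  invisible(x)
}

#' Serialize hypotheses to JSON / a Table-style CSV report
#'
#' @param hyps list of hypotheses (survival-scored or not).
#' @param json_path,csv_path output paths (either may be NULL).
#' @return invisibly, the report data.frame.
#' @export
write_hypothesis_report <- function(hyps, json_path = NULL, csv_path = NULL) {
  rows <- lapply(seq_along(hyps), function(i) {
    h <- hyps[[i]]
    s <- h$survival
    data.frame(
      ID = paste0(h$label, ".", i),
      label = h$label,
      reference = h$reference_ligand_id,
      reference_pIC50 = h$reference_pIC50,
      actives_matched = h$n_actives_matched,
      survival_active = if (is.null(s)) NA_real_ else s$total,
      ranking = if (is.null(s)) NA_real_ else s$ranking,
      stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  if (!is.null(csv_path)) utils::write.csv(rep, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    payload <- lapply(seq_along(hyps), function(i) {
      h <- hyps[[i]]
      list(id = paste0(h$label, ".", i), label = h$label,
           reference = h$reference_ligand_id,
           reference_pIC50 = h$reference_pIC50,
           sites = h$sites, survival = h$survival)
    })
    jsonlite::write_json(payload, json_path, digits = NA, auto_unbox = TRUE,
                         dataframe = "columns")
  }
  invisible(rep)
}
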