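#' Shape + pharmacophore similarity screening of a conformer library
#'
#' ROCS-style "M by N" screening: every library conformer is superposed on
#' every query conformer by Gaussian shape overlap; a compound's score is
#' the best combined Tanimoto (shape + feature color, range [0, 2]) over
#' the pair grid. Compounds that additionally match the pharmacophore
#' model (>= `min_match` features within the tolerance) carry a fitness
#' score and a QSAR-predicted activity. Output is sorted by combined
#' Tanimoto (descending, ties by compound id) and truncated to `hit_cap`.
#'
#' The query ensemble is conventionally generated with a 30 kcal/mol
#' energy window and library ensembles with 10 kcal/mol; both windows are
#' honoured upstream by [conformer_params()].
#'
#' @param library list of molecules with conformers and perceived features.
#' @param query a molecule (the hypothesis reference ligand) with its
#'   conformer ensemble, or a single conformer.
#' @param model optional fitted `qp_qsar_model` (for fitness + predicted
#'   activity its hypothesis is used).
#' @param hit_cap maximum number of records returned (1000).
#' @param tolerance_A,min_match pharmacophore matching parameters.
#' @param maxit refinement iterations per overlap optimization.
#' @return data.frame of class `qp_screen_table`: compound_id, combined,
#'   shape, color, conformer_index, fitness, predicted_pIC50.
#' @export
screen_library <- function(library, query, model = NULL, hit_cap = 1000L,
                           tolerance_A = 2.0, min_match = 2L, maxit = 20L) {
  if (length(library) == 0) stop("empty screening library")
  query_confs <- if (inherits(query, "qp_molecule")) query$conformers
  else if (inherits(query, "qp_conformer")) list(query)
  else stop("query must be a molecule or conformer")
  if (length(query_confs) == 0) stop("query has no conformers")
  rows <- vector("list", length(library))
  for (i in seq_along(library)) {
    mol <- library[[i]]
    best <- NULL
    for (ci in seq_along(mol$conformers)) {
      for (qc in query_confs) {
        ov <- gaussian_overlap(qc, mol$conformers[[ci]], maxit = maxit)
        if (is.null(best) || ov$combined > best$combined) {
          best <- list(combined = ov$combined, shape = ov$shape_tanimoto,
                       color = ov$color_tanimoto, conf_idx = ci)
        }
      }
    }
    fitness <- NA_real_
    pred <- NA_real_
    if (!is.null(model) && !is.null(model$hypothesis)) {
      bm <- best_molecule_alignment(mol, model$hypothesis, tolerance_A,
                                    min_match)
      if (!is.null(bm)) {
        conf <- mol$conformers[[bm$conf_idx]]
        fitness <- fitness_score(conf, model$hypothesis,
                                 tolerance_A = tolerance_A,
                                 min_match = min_match)
        pred <- predict_activity(model, conf, tolerance_A, min_match)
      }
    }
    rows[[i]] <- data.frame(
      compound_id = mol$id, combined = best$combined, shape = best$shape,
      color = best$color, conformer_index = best$conf_idx,
      fitness = fitness, predicted_pIC50 = pred,
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$combined, tab$compound_id), , drop = FALSE]
  tab <- utils::head(tab, hit_cap)
  rownames(tab) <- NULL
  class(tab) <- c("qp_screen_table", class(tab))
  tab
}

#' Write a screening score table as CSV (with optional docking join)
#'
#' @param tab a screen table.
#' @param path output CSV.
#' @param docking_csv optional CSV with compound_id, docking_score.
#' @return the (possibly joined) table, invisibly.
#' @export
write_screen_table <- function(tab, path, docking_csv = NULL) {
  if (!is.null(docking_csv)) tab <- join_docking_scores(tab, docking_csv)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}
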