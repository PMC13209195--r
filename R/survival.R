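#' Survival scoring of pharmacophore hypotheses
#'
#' A hypothesis is ranked by its survival score,
#' `S = w_site*S_site + w_vec*S_vec + w_vol*S_vol + w_sel*S_sel +
#' w_rew*m - w_e*dE + w_act*A`, with every weight 1.0 by default:
#' site alignment quality (RMSD-linear, in [0,1]), direction-vector
#' agreement (mean cosine over matched A/D/R pairs), pairwise Gaussian
#' volume overlap with the reference ligand, a selectivity estimate of the
#' hypothesis's rarity (negative log2 match fraction over a decoy pool), a
#' reward `m` = matched actives minus one, a penalty for the reference
#' conformer's strain energy `dE`, and the reference ligand's activity `A`.
#' The ranking score subtracts the corresponding sub-scores accumulated
#' over the inactives from the actives' survival score.
#'
#' @name survival-scoring
NULL

#' Default survival-score weights (all 1.0)
#' @return named list of weights.
#' @export
survival_weights <- function() {
  list(w_site = 1.0, w_vec = 1.0, w_vol = 1.0, w_sel = 1.0,
       w_rew = 1.0, w_e = 1.0, w_act = 1.0)
}

#' Best alignment of a molecule onto a hypothesis over its conformers
#'
#' Maximizes matched-pair count, then minimizes RMSD; ties by conformer
#' index.
#'
#' @param mol molecule with perceived conformer features.
#' @param hyp hypothesis.
#' @param tolerance_A,min_match see [align_conformer_to_hypothesis()].
#' @return list with `alignment` and `conf_idx`, or `NULL` if no conformer
#'   matches.
#' @export
best_molecule_alignment <- function(mol, hyp, tolerance_A = 2.0,
                                    min_match = 2L) {
  best <- NULL
  for (ci in seq_along(mol$conformers)) {
    al <- align_conformer_to_hypothesis(mol$conformers[[ci]], hyp,
                                        tolerance_A, min_match)
    if (is.null(al)) next
    if (is.null(best) ||
        al$n_matched > best$alignment$n_matched ||
        (al$n_matched == best$alignment$n_matched &&
           al$rmsd < best$alignment$rmsd - 1e-12)) {
      best <- list(alignment = al, conf_idx = ci)
    }
  }
  best
}

#' Sub-scores for one matched conformer/alignment against a hypothesis
#' @noRd
alignment_subscores <- function(conf, al, hyp, tolerance_A) {
  s_site <- max(0, 1 - al$rmsd / tolerance_A)
  # direction agreement over matched A/D/R pairs
  hd <- site_dir(hyp$sites)
  cd <- site_dir(conf$features)
  cosines <- numeric(0)
  for (r in seq_len(nrow(al$pairs))) {
    hi <- al$pairs[r, 1]; ci <- al$pairs[r, 2]
    if (!hyp$sites$kind[hi] %in% c("A", "D", "R")) next
    if (any(is.na(hd[hi, ])) || any(is.na(cd[ci, ]))) next
    v <- as.numeric(al$rot %*% cd[ci, ])
    cs <- sum(hd[hi, ] * v)
    # ring normals are axial (sign-free)
    if (hyp$sites$kind[hi] == "R") cs <- abs(cs)
    cosines <- c(cosines, cs)
  }
  s_vec <- if (length(cosines) == 0) 1 else max(0, min(1, mean(cosines)))
  s_vol <- if (is.null(hyp$reference_conformer)) 1 else {
    moved <- conf
    moved$coords <- apply_rigid(conf$coords, al$rot, al$trans)
    shape_tanimoto_fixed(hyp$reference_conformer, moved)
  }
  list(s_site = s_site, s_vec = s_vec, s_vol = s_vol)
}

#' Score a hypothesis by survival against actives and inactives
#'
#' @param hyp hypothesis (its reference ligand must be among the actives).
#' @param actives,inactives molecule lists with perceived features.
#' @param weights from [survival_weights()].
#' @param tolerance_A,min_match matching parameters.
#' @param decoy_pool conformer pool for the selectivity estimate; default
#'   all inactive conformers. Selectivity is 0 when the pool is empty; a
#'   zero match count is floored at half a count to keep the log finite.
#' @return the hypothesis with `$survival` filled: all sub-scores, the
#'   active-set total, the inactive-set partial score and the ranking
#'   (active minus inactive).
#' @export
score_hypothesis_survival <- function(hyp, actives, inactives = list(),
                                      weights = survival_weights(),
                                      tolerance_A = 2.0, min_match = 2L,
                                      decoy_pool = NULL) {
  act_ids <- vapply(actives, `[[`, character(1), "id")
  if (!(hyp$reference_ligand_id %in% c(act_ids, "ref"))) {
    stop("reference ligand ", hyp$reference_ligand_id,
         " is not among the actives")
  }
  set_scores <- function(mols) {
    subs <- list()
    for (m in mols) {
      bm <- best_molecule_alignment(m, hyp, tolerance_A, min_match)
      if (is.null(bm)) next
      conf <- m$conformers[[bm$conf_idx]]
      subs[[length(subs) + 1]] <- alignment_subscores(conf, bm$alignment,
                                                      hyp, tolerance_A)
    }
    if (length(subs) == 0) {
      return(list(n = 0L, s_site = 0, s_vec = 0, s_vol = 0))
    }
    list(n = length(subs),
         s_site = mean(vapply(subs, `[[`, numeric(1), "s_site")),
         s_vec = mean(vapply(subs, `[[`, numeric(1), "s_vec")),
         s_vol = mean(vapply(subs, `[[`, numeric(1), "s_vol")))
  }
  act <- set_scores(actives)
  ina <- set_scores(inactives)
  if (is.null(decoy_pool)) {
    decoy_pool <- unlist(lapply(inactives, `[[`, "conformers"),
                         recursive = FALSE)
  }
  s_sel <- 0
  if (length(decoy_pool) > 0) {
    n_match <- sum(vapply(decoy_pool, function(cf) {
      !is.null(align_conformer_to_hypothesis(cf, hyp, tolerance_A, min_match))
    }, logical(1)))
    frac <- max(n_match, 0.5) / length(decoy_pool)
    s_sel <- max(0, -log2(min(1, frac)))
  }
  m_reward <- max(act$n - 1L, 0L)
  delta_e <- if (!is.null(hyp$reference_conformer)) {
    hyp$reference_conformer$energy
  } else 0
  activity_term <- if (is.na(hyp$reference_pIC50)) 0 else hyp$reference_pIC50
  w <- weights
  total <- w$w_site * act$s_site + w$w_vec * act$s_vec +
    w$w_vol * act$s_vol + w$w_sel * s_sel + w$w_rew * m_reward -
    w$w_e * delta_e + w$w_act * activity_term
  inactive_partial <- w$w_site * ina$s_site + w$w_vec * ina$s_vec +
    w$w_vol * ina$s_vol + w$w_rew * max(ina$n - 1L, 0L)
  hyp$survival <- list(
    s_site = act$s_site, s_vec = act$s_vec, s_vol = act$s_vol,
    s_sel = s_sel, m_reward = m_reward, delta_e = delta_e,
    activity_term = activity_term, weights = w, total = total,
    n_actives_matched = act$n, n_inactives_matched = ina$n,
    inactive_partial = inactive_partial,
    ranking = total - inactive_partial)
  hyp
}

#' Fitness score of a conformer against a hypothesis
#'
#' The per-ligand restriction of the survival score used during screening:
#' `w_site*max(0, 1 - RMSD/tol) + w_vec*<cos> + w_vol*overlap`, maximum 3.0
#' at unit weights. `NA` when the conformer does not align (non-hit).
#'
#' @param conf conformer with perceived features.
#' @param hyp hypothesis.
#' @param weights from [survival_weights()] (site/vec/vol entries used).
#' @param tolerance_A,min_match matching parameters.
#' @return fitness in [0, 3] at default weights, or `NA`.
#' @export
fitness_score <- function(conf, hyp, weights = survival_weights(),
                          tolerance_A = 2.0, min_match = 2L) {
  al <- align_conformer_to_hypothesis(conf, hyp, tolerance_A, min_match)
  if (is.null(al)) return(NA_real_)
  s <- alignment_subscores(conf, al, hyp, tolerance_A)
  weights$w_site * s$s_site + weights$w_vec * s$s_vec +
    weights$w_vol * s$s_vol
}
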