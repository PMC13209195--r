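#' Align a conformer onto a pharmacophore hypothesis
#'
#' Searches kind-respecting correspondences between the hypothesis sites
#' and the conformer's perceived sites, superposes each candidate
#' correspondence by least squares (Kabsch), and returns the best
#' alignment: the largest correspondence (>= `min_match` pairs) for which
#' every matched pair lies within `tolerance_A` after superposition, ties
#' broken by lower site RMSD, then by site order. Returns `NULL` when no
#' correspondence qualifies (the compound is a non-hit; absence is a value,
#' not an error).
#'
#' @param conf a conformer with perceived features.
#' @param hyp a hypothesis (see [find_common_pharmacophores()]).
#' @param tolerance_A intersite matching tolerance (2.0 A).
#' @param min_match minimum number of matched feature pairs (2).
#' @param max_assignments cap on enumerated correspondences (deterministic
#'   order, so truncation is reproducible).
#' @return list with `pairs` (matrix: hypothesis site index, conformer site
#'   index), `rot`, `trans` (rigid transform taking conformer coordinates
#'   into the hypothesis frame), `rmsd`, `n_matched`; or `NULL`.
#' @export
align_conformer_to_hypothesis <- function(conf, hyp, tolerance_A = 2.0,
                                          min_match = 2L,
                                          max_assignments = 50000L) {
  ft <- conf$features
  if (is.null(ft)) stop("conformer features not perceived")
  hs <- hyp$sites
  k <- nrow(hs)
  if (nrow(ft) == 0 || k == 0) return(NULL)
  hxyz <- site_xyz(hs)
  cxyz <- site_xyz(ft)
  best <- NULL
  n_assign <- 0L
  # candidate conformer sites per hypothesis site (same kind)
  cands <- lapply(seq_len(k), function(i) which(ft$kind == hs$kind[i]))
  if (sum(lengths(cands) > 0) < min_match) return(NULL)
  min_match <- max(as.integer(min_match), 1L)
  if (k < min_match) return(NULL)
  # subsets of hypothesis sites, largest first
  for (m in seq(k, min_match, by = -1L)) {
    subsets <- utils::combn(k, m, simplify = FALSE)
    for (S in subsets) {
      if (any(lengths(cands[S]) == 0)) next
      # enumerate injective assignments over the subset
      assignments <- enumerate_injections(cands[S])
      for (a in assignments) {
        n_assign <- n_assign + 1L
        if (n_assign > max_assignments) break
        fit <- kabsch(cxyz[a, , drop = FALSE], hxyz[S, , drop = FALSE])
        moved <- apply_rigid(cxyz[a, , drop = FALSE], fit$rot, fit$trans)
        dd <- sqrt(rowSums((moved - hxyz[S, , drop = FALSE])^2))
        if (max(dd) > tolerance_A) next
        cand <- list(pairs = cbind(hyp_site = S, conf_site = a),
                     rot = fit$rot, trans = fit$trans, rmsd = fit$rmsd,
                     n_matched = m)
        if (is.null(best) || fit$rmsd < best$rmsd - 1e-12) best <- cand
      }
      if (n_assign > max_assignments) break
    }
    if (!is.null(best)) break  # largest correspondence size wins
    if (n_assign > max_assignments) break
  }
  best
}

#' All injective assignments: one conformer site per hypothesis slot,
#' no conformer site reused. Deterministic order.
#' @noRd
enumerate_injections <- function(cand_list) {
  out <- list()
  rec <- function(i, used, acc) {
    if (i > length(cand_list)) {
      out[[length(out) + 1]] <<- acc
      return(invisible(NULL))
    }
    for (c in cand_list[[i]]) {
      if (c %in% used) next
      rec(i + 1, c(used, c), c(acc, c))
    }
  }
  rec(1, integer(0), integer(0))
  out
}
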