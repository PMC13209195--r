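#' Score fusion, top-fraction selection and K-means triage
#'
#' Per-compound screening scores (combined Tanimoto, fitness, predicted
#' activity, optionally an externally supplied docking score) are fused
#' into a single ranking column, the upper fraction (10% by default) is
#' selected, and survivors are clustered on structural fingerprints to
#' pick diverse representatives.
#'
#' Fusion methods (each defined over per-column z-scores, higher = better):
#' * `sum`: sum of z-scores (the "Z" fusion).
#' * `product`: product of positively shifted z-scores,
#'   `prod(z - min(z) + 1)` per column over the included records.
#' * `exp`: sum of exponentiated z-scores.
#' The product/exponential functional forms are documented choices and
#' flagged in the table's metadata attribute.
#'
#' @name score-fusion
NULL

#' Fuse score columns into a single ranking
#'
#' @param table data.frame with a `compound_id` column and the score
#'   columns named in `columns`. Records with any missing fused input are
#'   excluded from fusion and flagged in `fusion_complete`.
#' @param columns character vector of column names to fuse.
#' @param method `"sum"`, `"product"` or `"exp"`.
#' @return the table with `fused` (NA for incomplete records),
#'   `fusion_complete`, and attribute `fusion_method`.
#' @export
fuse_scores <- function(table, columns = c("combined", "fitness",
                                           "predicted_pIC50"),
                        method = c("sum", "product", "exp")) {
  method <- match.arg(method)
  miss <- setdiff(columns, names(table))
  if (length(miss) > 0) stop("missing score columns: ",
                             paste(miss, collapse = ", "))
  complete <- stats::complete.cases(table[, columns, drop = FALSE])
  if (!any(complete)) stop("no record has all fused columns")
  Z <- matrix(NA_real_, nrow(table), length(columns))
  for (j in seq_along(columns)) {
    v <- table[[columns[j]]][complete]
    s <- stats::sd(v)
    if (s < 1e-12) stop("zero-variance score column: ", columns[j])
    Z[complete, j] <- (table[[columns[j]]][complete] - mean(v)) / s
  }
  fused <- rep(NA_real_, nrow(table))
  Zc <- Z[complete, , drop = FALSE]
  fused[complete] <- switch(method,
    sum = rowSums(Zc),
    product = {
      shifted <- sweep(Zc, 2, apply(Zc, 2, min), `-`) + 1
      apply(shifted, 1, prod)
    },
    exp = rowSums(exp(Zc)))
  table$fused <- fused
  table$fusion_complete <- complete
  attr(table, "fusion_method") <- method
  attr(table, "fusion_columns") <- columns
  if (sum(!complete) > 0) {
    qp_log(sum(!complete), " record(s) lack a fused column and were flagged")
  }
  table
}

#' Select the top fraction of records by a score column
#'
#' Exactly `floor(fraction * n)` records with the highest score are
#' selected (at least one); boundary ties are broken by compound id
#' (ascending), so the selection is deterministic.
#'
#' @param table data.frame with `compound_id` and the score column.
#' @param fraction fraction in (0, 1] (default 0.10).
#' @param by score column name (default `"fused"`).
#' @return the selected subset, ordered by descending score.
#' @export
select_top_fraction <- function(table, fraction = 0.10, by = "fused") {
  if (nrow(table) == 0) stop("empty score table")
  stopifnot(fraction > 0, fraction <= 1, by %in% names(table))
  n_sel <- max(1L, floor(fraction * nrow(table)))
  usable <- table[!is.na(table[[by]]), , drop = FALSE]
  o <- order(-usable[[by]], usable$compound_id)
  out <- utils::head(usable[o, , drop = FALSE], n_sel)
  rownames(out) <- NULL
  out
}

#' K-means triage of selected hits on structural fingerprints
#'
#' 1024-bit hashed path-based fingerprints are computed, projected onto
#' their first `d` principal components, and clustered by K-means
#' (multiple starts, fixed seed). One representative per cluster is the
#' member with the highest fused score (ties by id).
#'
#' @param mols list of molecules (the selected hits).
#' @param scores numeric vector aligned with `mols` (fused scores).
#' @param k number of clusters (default 8).
#' @param seed RNG seed.
#' @param d number of principal components (default 10, capped by rank).
#' @return list with `labels` (named by compound id), `representatives`
#'   (data.frame cluster, compound_id, score, n_members) and `pca` scores.
#' @export
cluster_hits <- function(mols, scores, k = 8L, seed = 1L, d = 10L) {
  n <- length(mols)
  if (k > n) stop("k (", k, ") exceeds number of hits (", n, ")")
  stopifnot(length(scores) == n)
  ids <- vapply(mols, `[[`, character(1), "id")
  fp <- structure_fingerprints(mols)
  keep <- which(apply(fp, 2, stats::sd) > 0)
  proj <- if (length(keep) >= 2 && n > 2) {
    pc <- stats::prcomp(fp[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
    pc$x[, seq_len(min(d, ncol(pc$x))), drop = FALSE]
  } else {
    fp
  }
  # identical fingerprints would leave fewer distinct points than centres;
  # an infinitesimal deterministic offset keeps kmeans well-posed without
  # affecting any real separation
  proj <- proj + 1e-8 * seq_len(n)
  cluster_assign <- if (k == n) {
    seq_len(n)  # one compound per cluster
  } else {
    with_seed(seed, stats::kmeans(proj, centers = k, nstart = 10,
                                  iter.max = 50))$cluster
  }
  labels <- stats::setNames(cluster_assign, ids)
  reps <- do.call(rbind, lapply(seq_len(k), function(cl) {
    members <- which(cluster_assign == cl)
    o <- members[order(-scores[members], ids[members])]
    data.frame(cluster = cl, compound_id = ids[o[1]], score = scores[o[1]],
               n_members = length(members), stringsAsFactors = FALSE)
  }))
  list(labels = labels, representatives = reps, pca = proj)
}
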