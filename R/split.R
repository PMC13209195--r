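#' Training/test split specification
#'
#' @param train_fraction fraction of compounds assigned to training (0.7,
#'   i.e. the 7:3 ratio).
#' @param seed integer seed (the assignment is deterministic given it).
#' @return list of class `qp_split_spec`.
#' @export
split_spec <- function(train_fraction = 0.7, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  structure(list(train_fraction = train_fraction, seed = as.integer(seed)),
            class = "qp_split_spec")
}

#' Structure fingerprints (hashed path-based, 1024 bits)
#'
#' FP2 fingerprints computed by OpenBabel through ChemmineR; used for the
#' diversity split and for K-means triage of screening hits.
#'
#' @param mols list of molecules (first conformer of each is used).
#' @return integer matrix, one row per molecule, 1024 columns.
#' @export
structure_fingerprints <- function(mols) {
  stopifnot(length(mols) > 0)
  tmp <- tempfile(fileext = ".sdf")
  on.exit(unlink(tmp), add = TRUE)
  write_sdf_dataset(mols, tmp, all_conformers = FALSE)
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(tmp))
  fp <- ChemmineR::fingerprintOB(sdfset, "FP2")
  m <- ChemmineR::as.matrix(fp)
  rownames(m) <- vapply(mols, `[[`, character(1), "id")
  m
}

#' Tanimoto distance matrix between binary fingerprint rows
#' @noRd
tanimoto_dist <- function(fp) {
  common <- fp %*% t(fp)
  counts <- rowSums(fp)
  union <- outer(counts, counts, `+`) - common
  sim <- ifelse(union > 0, common / union, 1)
  1 - sim
}

#' Diversity-based training/test split
#'
#' Assigns `train_fraction` of the dataset to training so that (a) the most
#' and least active compounds are always in training, and (b) remaining
#' training members are picked by MaxMin on fingerprint Tanimoto distance
#' within pIC50 strata (quartiles), spreading both structural and activity
#' diversity into the training set. Deterministic given the seed; ties are
#' broken by compound id.
#'
#' @param mols list of molecules with pIC50.
#' @param spec a [split_spec()].
#' @return list with `train` and `test` molecule lists.
#' @export
diversity_split <- function(mols, spec = split_spec()) {
  n <- length(mols)
  if (n < 5) stop("dataset too small to split (need >= 5 compounds)")
  pic <- vapply(mols, `[[`, numeric(1), "pIC50")
  if (any(is.na(pic))) stop("all molecules need a pIC50 for splitting")
  ids <- vapply(mols, `[[`, character(1), "id")
  n_train <- max(2L, round(spec$train_fraction * n))
  fp <- structure_fingerprints(mols)
  D <- tanimoto_dist(fp)
  forced <- c(which.max(pic), which.min(pic))
  forced <- unique(forced)
  # activity strata (quartiles), train slots allocated proportionally
  qs <- stats::quantile(pic, probs = c(0.25, 0.5, 0.75), names = FALSE)
  stratum <- findInterval(pic, qs, left.open = TRUE) + 1L
  selected <- forced
  # proportional allocation, largest remainder
  remaining_slots <- n_train - length(selected)
  strat_sizes <- tabulate(stratum, nbins = 4L)
  strat_taken <- tabulate(stratum[selected], nbins = 4L)
  alloc <- pmax(0, round(remaining_slots * strat_sizes / sum(strat_sizes)))
  while (sum(alloc) > remaining_slots) alloc[which.max(alloc)] <- alloc[which.max(alloc)] - 1L
  while (sum(alloc) < remaining_slots) {
    room <- strat_sizes - strat_taken - alloc
    alloc[which.max(room)] <- alloc[which.max(room)] + 1L
  }
  for (s in 1:4) {
    pool <- setdiff(which(stratum == s), selected)
    take <- min(alloc[s], length(pool))
    for (t in seq_len(take)) {
      # MaxMin: farthest (min distance to current training set) first
      mind <- apply(D[pool, selected, drop = FALSE], 1, min)
      o <- order(-mind, ids[pool])
      pick <- pool[o[1]]
      selected <- c(selected, pick)
      pool <- setdiff(pool, pick)
    }
  }
  # top up across strata if allocations were capped
  while (length(selected) < n_train) {
    pool <- setdiff(seq_len(n), selected)
    mind <- apply(D[pool, selected, drop = FALSE], 1, min)
    o <- order(-mind, ids[pool])
    selected <- c(selected, pool[o[1]])
  }
  selected <- sort(unique(selected))
  list(train = mols[selected], test = mols[setdiff(seq_len(n), selected)])
}
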