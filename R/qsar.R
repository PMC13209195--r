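#' Hypothesis-aligned grid-occupancy 3D-QSAR
#'
#' Training conformers are aligned onto a pharmacophore hypothesis; space
#' around them is divided into cubes (1.0 A spacing by default, box =
#' bounding box of all aligned heavy atoms padded by 2 A and snapped to
#' integer Angstrom); the independent variables are binary occupancies of
#' the cubes by structural components — one atom class for any heavy atom
#' plus one class per pharmacophore feature kind (so feature-bearing atoms
#' are deliberately counted twice). pIC50 is regressed on the bits by
#' partial least squares, adding factors while cross-validated Q2 keeps
#' improving appreciably, then pruning coefficients whose jackknife t-value
#' falls below the cutoff (2.0) and refitting once.
#'
#' @name qsar-grid
NULL

OCC_CLASSES <- c("any", "A", "D", "H", "N", "P", "R")

#' Grid geometry covering a set of aligned point clouds
#'
#' @param points_list list of n x 3 matrices (already in the hypothesis
#'   frame).
#' @param spacing cube edge (A).
#' @param pad padding around the bounding box (A), snapped outward to
#'   integers.
#' @return list of class `qp_grid`: origin, shape (3 ints), spacing.
#' @export
occupancy_grid <- function(points_list, spacing = 1.0, pad = 2.0) {
  all_pts <- do.call(rbind, points_list)
  stopifnot(nrow(all_pts) > 0)
  origin <- floor((apply(all_pts, 2, min) - pad) / spacing) * spacing
  upper <- ceiling((apply(all_pts, 2, max) + pad) / spacing) * spacing
  shape <- as.integer(round((upper - origin) / spacing))
  structure(list(origin = origin, shape = shape, spacing = spacing),
            class = "qp_grid")
}

#' Cube index (1-based linear) of points; NA when outside the grid.
#' Cubes are half-open, `[i, i+1)` in grid units: a point exactly on a
#' face belongs to the higher-index cube.
#' @noRd
cube_index <- function(grid, pts) {
  ijk <- floor(sweep(sweep(pts, 2, grid$origin), 2, grid$spacing, `/`))
  ok <- ijk[, 1] >= 0 & ijk[, 1] < grid$shape[1] &
    ijk[, 2] >= 0 & ijk[, 2] < grid$shape[2] &
    ijk[, 3] >= 0 & ijk[, 3] < grid$shape[3]
  idx <- 1 + ijk[, 1] + grid$shape[1] * (ijk[, 2] + grid$shape[2] * ijk[, 3])
  idx[!ok] <- NA_integer_
  as.integer(idx)
}

#' Occupancy bit vector of one aligned conformer on a grid
#'
#' Bits are laid out class-major: the `any` heavy-atom class first, then
#' one block per feature kind (A, D, H, N, P, R), each block of length
#' `prod(shape)`.
#'
#' @param conf conformer (coordinates already in the hypothesis frame).
#' @param grid a [occupancy_grid()].
#' @return logical vector of length `prod(shape) * 7`.
#' @export
occupancy_bits <- function(conf, grid) {
  ncube <- prod(grid$shape)
  bits <- logical(ncube * length(OCC_CLASSES))
  hv <- heavy_coords(conf)
  ci <- cube_index(grid, hv)
  bits[ci[!is.na(ci)]] <- TRUE
  ft <- conf$features
  if (!is.null(ft) && nrow(ft) > 0) {
    fi <- cube_index(grid, site_xyz(ft))
    for (k in seq_along(ft$kind)) {
      if (is.na(fi[k])) next
      cls <- match(ft$kind[k], OCC_CLASSES)
      bits[(cls - 1) * ncube + fi[k]] <- TRUE
    }
  }
  bits
}

#' Align molecules to a hypothesis and build the occupancy design matrix
#'
#' @param mols training molecules with perceived features.
#' @param hyp hypothesis.
#' @param spacing grid spacing (1.0 A).
#' @param tolerance_A,min_match alignment parameters.
#' @return list: `X` binary design matrix (rows = molecules), `grid`,
#'   `alignments` (per molecule), `ids`. Errors naming the compound when a
#'   molecule cannot be aligned.
#' @export
build_occupancy_matrix <- function(mols, hyp, spacing = 1.0,
                                   tolerance_A = 2.0, min_match = 2L) {
  aligned <- vector("list", length(mols))
  for (i in seq_along(mols)) {
    bm <- best_molecule_alignment(mols[[i]], hyp, tolerance_A, min_match)
    if (is.null(bm)) {
      stop("compound ", mols[[i]]$id, " cannot be aligned to hypothesis ",
           hyp$label)
    }
    conf <- mols[[i]]$conformers[[bm$conf_idx]]
    moved <- conf
    moved$coords <- apply_rigid(conf$coords, bm$alignment$rot,
                                bm$alignment$trans)
    if (!is.null(conf$features)) {
      ft <- conf$features
      xyz <- apply_rigid(site_xyz(ft), bm$alignment$rot, bm$alignment$trans)
      ft$x <- xyz[, 1]; ft$y <- xyz[, 2]; ft$z <- xyz[, 3]
      dirs <- site_dir(ft)
      ok <- !is.na(dirs[, 1])
      if (any(ok)) {
        dirs[ok, ] <- dirs[ok, , drop = FALSE] %*% t(bm$alignment$rot)
        ft$dx <- dirs[, 1]; ft$dy <- dirs[, 2]; ft$dz <- dirs[, 3]
      }
      moved$features <- ft
    }
    aligned[[i]] <- list(conf = moved, alignment = bm)
  }
  grid <- occupancy_grid(lapply(aligned, function(a) heavy_coords(a$conf)),
                         spacing = spacing)
  X <- t(vapply(aligned, function(a) occupancy_bits(a$conf, grid),
                logical(prod(grid$shape) * length(OCC_CLASSES))))
  storage.mode(X) <- "double"
  list(X = X, grid = grid, alignments = aligned,
       ids = vapply(mols, `[[`, character(1), "id"))
}

# ---- PLS ----------------------------------------------------------------

#' NIPALS PLS1 fit on a fixed number of factors
#' @noRd
pls1_fit <- function(X, y, m) {
  xbar <- colMeans(X)
  ybar <- mean(y)
  Xc <- sweep(X, 2, xbar)
  yc <- y - ybar
  p <- ncol(X)
  W <- matrix(0, p, 0); P <- matrix(0, p, 0); Q <- numeric(0)
  for (a in seq_len(m)) {
    w <- as.numeric(crossprod(Xc, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t_ <- as.numeric(Xc %*% w)
    tt <- sum(t_^2)
    if (tt < 1e-12) break
    pl <- as.numeric(crossprod(Xc, t_)) / tt
    q <- sum(yc * t_) / tt
    Xc <- Xc - tcrossprod(t_, pl)
    yc <- yc - q * t_
    W <- cbind(W, w); P <- cbind(P, pl); Q <- c(Q, q)
  }
  if (ncol(W) == 0) stop("X carries no information about y (zero covariance)")
  B <- W %*% solve(crossprod(P, W), Q)
  b0 <- ybar - sum(xbar * B)
  list(coef = as.numeric(B), intercept = b0, n_factors = ncol(W))
}

#' @noRd
pls1_predict <- function(fit, X) {
  as.numeric(X %*% fit$coef) + fit$intercept
}

#' Leave-one-out cross-validated Q2 of an m-factor PLS1 model
#' @noRd
pls1_loo_q2 <- function(X, y, m) {
  n <- length(y)
  press <- 0
  for (i in seq_len(n)) {
    f <- pls1_fit(X[-i, , drop = FALSE], y[-i], m)
    press <- press + (pls1_predict(f, X[i, , drop = FALSE]) - y[i])^2
  }
  1 - press / sum((y - mean(y))^2)
}

#' Fit the grid-occupancy PLS QSAR model
#'
#' Factors are added while cross-validated Q2 improves appreciably
#' (relative gain > `q2_gain`); at the first decline or stall the previous
#' count is kept. Coefficients whose jackknife t-value (coefficient over
#' its leave-one-out standard error) is below `t_cutoff` are zeroed and
#' the model is refitted once on the retained bits (if the filter would
#' empty the model, all bits are retained).
#'
#' When `X_val`/`y_val` are supplied the factor-selection Q2 is computed
#' externally on them instead of by LOO.
#'
#' @param X binary design matrix (molecules x bits).
#' @param y pIC50 vector.
#' @param max_factors largest PLS factor count considered.
#' @param t_cutoff jackknife t-value filter threshold (2.0).
#' @param q2_gain minimal relative Q2 improvement to accept another factor.
#' @param min_support drop bits set in at most this fraction of training
#'   rows (0.2). Rare bits are dominated by alignment wobble -- a compound
#'   whose frame tilts slightly occupies a private shell of cubes -- and
#'   act as in-sample class markers that do not generalize; minimum-support
#'   descriptor filtering is the standard treatment.
#' @param X_val,y_val optional external validation set for factor selection.
#' @param grid,hypothesis,ids optional metadata stored on the model.
#' @return object of class `qp_qsar_model`.
#' @export
fit_qsar_pls <- function(X, y, max_factors = 10L, t_cutoff = 2.0,
                         q2_gain = 0.01, min_support = 0.2,
                         X_val = NULL, y_val = NULL,
                         grid = NULL, hypothesis = NULL, ids = NULL) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), length(y) >= 5)
  if (stats::sd(y) < 1e-12) stop("constant activity vector: nothing to fit")
  rate <- colMeans(X)
  keep <- which(rate > min_support & rate < 1)
  if (length(keep) == 0) keep <- which(rate > 0 & rate < 1)
  if (length(keep) == 0) stop("X has zero informative (non-constant) columns")
  # collapse exact duplicate columns (feature-class bits duplicate the
  # heavy-atom bits of the same cube; identical columns would split one
  # effect across copies and depress every copy's jackknife t-value)
  sig <- apply(X[, keep, drop = FALSE], 2, paste, collapse = "")
  keep <- keep[!duplicated(sig)]
  Xk <- X[, keep, drop = FALSE]
  max_factors <- min(max_factors, nrow(X) - 2L, length(keep))
  q2_of_m <- function(m) {
    if (!is.null(X_val)) {
      f <- pls1_fit(Xk, y, m)
      pred <- pls1_predict(f, X_val[, keep, drop = FALSE])
      1 - sum((pred - y_val)^2) / sum((y_val - mean(y_val))^2)
    } else {
      pls1_loo_q2(Xk, y, m)
    }
  }
  q2_curve <- numeric(0)
  m_best <- 1L
  for (m in seq_len(max_factors)) {
    q2_curve[m] <- q2_of_m(m)
    if (m > 1) {
      gain <- q2_curve[m] - q2_curve[m - 1]
      if (gain <= q2_gain * max(abs(q2_curve[m - 1]), 1e-6)) break
    }
    m_best <- m
  }
  fit <- pls1_fit(Xk, y, m_best)
  # jackknife standard errors of coefficients at the chosen factor count
  n <- nrow(Xk)
  cmat <- matrix(0, n, length(keep))
  for (i in seq_len(n)) {
    cmat[i, ] <- pls1_fit(Xk[-i, , drop = FALSE], y[-i], m_best)$coef
  }
  cbar <- colMeans(cmat)
  se <- sqrt((n - 1) / n * colSums(sweep(cmat, 2, cbar)^2))
  tval <- ifelse(se > 1e-12, abs(fit$coef) / se, Inf)
  retained <- which(tval >= t_cutoff)
  if (length(retained) == 0) retained <- seq_along(keep)
  # the refit on the pruned bit set uses as many factors as the set
  # supports: with the noise bits gone, shrinkage only re-compresses the
  # surviving effects and under-disperses the predictions
  fit2 <- pls1_fit(Xk[, retained, drop = FALSE], y,
                   min(length(retained), nrow(Xk) - 2L))
  model <- structure(list(
    hypothesis = hypothesis, grid = grid,
    n_factors = m_best,
    retained_bit_index = keep[retained],
    coefficients = fit2$coef,
    intercept = fit2$intercept,
    t_cutoff = t_cutoff,
    q2_curve = q2_curve,
    fitted = as.numeric(X[, keep[retained], drop = FALSE] %*% fit2$coef) +
      fit2$intercept,
    training_ids = ids,
    y_train = y,
    n_bits_total = ncol(X)
  ), class = "qp_qsar_model")
  model
}

#' Predict pIC50 for a raw design row / matrix
#' @param model a `qp_qsar_model`.
#' @param X design matrix with the model's full bit layout.
#' @return numeric predictions.
#' @export
predict_occupancy <- function(model, X) {
  X <- matrix(X, ncol = model$n_bits_total)
  as.numeric(X[, model$retained_bit_index, drop = FALSE] %*%
               model$coefficients) + model$intercept
}

#' Predict the activity of a conformer from a fitted QSAR model
#'
#' The conformer is aligned to the model's hypothesis, its occupancy is
#' computed on the stored grid, and the linear model applied. `NA` when
#' the conformer does not align (non-hit); predictions are invariant to
#' rigid motion of the input.
#'
#' @param model a `qp_qsar_model` (with grid and hypothesis metadata).
#' @param conf conformer with perceived features.
#' @param tolerance_A,min_match alignment parameters.
#' @return predicted pIC50, or `NA`.
#' @export
predict_activity <- function(model, conf, tolerance_A = 2.0, min_match = 2L) {
  stopifnot(!is.null(model$hypothesis), !is.null(model$grid))
  al <- align_conformer_to_hypothesis(conf, model$hypothesis, tolerance_A,
                                      min_match)
  if (is.null(al)) return(NA_real_)
  moved <- conf
  moved$coords <- apply_rigid(conf$coords, al$rot, al$trans)
  if (!is.null(conf$features)) {
    ft <- conf$features
    xyz <- apply_rigid(site_xyz(ft), al$rot, al$trans)
    ft$x <- xyz[, 1]; ft$y <- xyz[, 2]; ft$z <- xyz[, 3]
    moved$features <- ft
  }
  bits <- occupancy_bits(moved, model$grid)
  predict_occupancy(model, as.numeric(bits))
}

#' Best prediction for a molecule over its conformers
#' @param model a `qp_qsar_model`.
#' @param mol molecule.
#' @param tolerance_A,min_match alignment parameters.
#' @return predicted pIC50 from the best-aligned conformer, or `NA`.
#' @export
predict_molecule <- function(model, mol, tolerance_A = 2.0, min_match = 2L) {
  bm <- best_molecule_alignment(mol, model$hypothesis, tolerance_A, min_match)
  if (is.null(bm)) return(NA_real_)
  predict_activity(model, mol$conformers[[bm$conf_idx]], tolerance_A,
                   min_match)
}

#' Fit a QSAR model directly from molecules and a hypothesis
#'
#' Convenience wrapper: builds the occupancy matrix, fits the PLS model
#' and attaches the grid/hypothesis metadata needed for prediction.
#'
#' @param mols training molecules.
#' @param hyp hypothesis.
#' @param spacing grid spacing.
#' @param ... passed to [fit_qsar_pls()].
#' @return a `qp_qsar_model`.
#' @export
fit_qsar_dataset <- function(mols, hyp, spacing = 1.0, ...) {
  occ <- build_occupancy_matrix(mols, hyp, spacing = spacing)
  y <- vapply(mols, `[[`, numeric(1), "pIC50")
  fit_qsar_pls(occ$X, y, grid = occ$grid, hypothesis = hyp,
               ids = occ$ids, ...)
}

#' @export
print.qp_qsar_model <- function(x, ...) {
  cat(sprintf("<qsar model> factors=%d retained_bits=%d r2(train)=%.3f\n",
              x$n_factors, length(x$retained_bit_index),
              stats::cor(x$fitted, x$y_train)^2))
  invisible(x)
}

#' Serialize a QSAR model to JSON
#' @param model a `qp_qsar_model`.
#' @param path output file.
#' @export
write_qsar_model <- function(model, path) {
  payload <- list(
    n_factors = model$n_factors,
    retained_bit_index = model$retained_bit_index,
    coefficients = model$coefficients,
    intercept = model$intercept,
    t_cutoff = model$t_cutoff,
    q2_curve = model$q2_curve,
    training_ids = model$training_ids,
    grid = if (!is.null(model$grid)) {
      list(origin = model$grid$origin, shape = model$grid$shape,
           spacing = model$grid$spacing)
    },
    hypothesis_label = if (!is.null(model$hypothesis)) model$hypothesis$label,
    n_bits_total = model$n_bits_total)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
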