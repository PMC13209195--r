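#' Gaussian shape overlap and combined Tanimoto similarity
#'
#' Heavy atoms are modelled as spherical Gaussians whose integral matches a
#' hard sphere of the element's van der Waals radius at amplitude p = 2.7
#' (the classic shape-overlay parameterization): for radius sigma the decay
#' is `alpha = pi * (3 p / (4 pi sigma^3))^(2/3)`. The overlap volume of two
#' Gaussian sets is evaluated in closed form over first-order atom pairs
#' (higher-order inclusion-exclusion terms are omitted, a documented
#' approximation):
#' `V_ij = p^2 (pi/(a_i+a_j))^{3/2} exp(-a_i a_j d_ij^2/(a_i+a_j))`.
#'
#' `gaussian_overlap()` optimizes the rigid superposition of B onto A from
#' four deterministic starts (centroid-aligned principal axes and the three
#' 180-degree flips) with local quasi-Newton refinement, and keeps the
#' single best overlap. Shape Tanimoto is `o_ab/(o_aa + o_bb - o_ab)`;
#' color (feature) Tanimoto uses one Gaussian per pharmacophore site,
#' matched within kinds only, under the shape-optimal transform. The
#' computation is symmetrized by canonical argument ordering, so swapping A
#' and B changes nothing.
#'
#' @name shape-overlap
NULL

VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, F = 1.47,
               Cl = 1.75, Br = 1.85, I = 1.98, B = 1.92, Si = 2.10, H = 1.10)
GAUSS_P <- 2.7
COLOR_SIGMA <- 1.0  # Gaussian radius for feature sites (A)

#' @noRd
gauss_alpha <- function(sigma) {
  pi * (3 * GAUSS_P / (4 * pi * sigma^3))^(2 / 3)
}

#' Closed-form first-order overlap volume between two Gaussian atom sets
#' at fixed pose (compiled kernel; pure-R reference kept for tests).
#' @noRd
pair_overlap_volume <- function(xyzA, alphaA, xyzB, alphaB) {
  if (nrow(xyzA) == 0 || nrow(xyzB) == 0) return(0)
  overlap_volume_cpp(xyzA, alphaA, xyzB, alphaB)
}

#' @noRd
pair_overlap_volume_r <- function(xyzA, alphaA, xyzB, alphaB) {
  if (nrow(xyzA) == 0 || nrow(xyzB) == 0) return(0)
  d2 <- outer(rowSums(xyzA^2), rowSums(xyzB^2), `+`) - 2 * (xyzA %*% t(xyzB))
  d2[d2 < 0] <- 0
  asum <- outer(alphaA, alphaB, `+`)
  aprod <- outer(alphaA, alphaB)
  sum(GAUSS_P^2 * (pi / asum)^1.5 * exp(-aprod * d2 / asum))
}

#' @noRd
conf_gaussians <- function(conf) {
  heavy <- conf$elements != "H"
  el <- conf$elements[heavy]
  r <- VDW_RADII[el]
  r[is.na(r)] <- 1.70
  list(xyz = conf$coords[heavy, , drop = FALSE], alpha = gauss_alpha(r))
}

#' Gaussian overlap volume between two conformers at a fixed pose
#'
#' No superposition is performed; useful as the volume kernel inside
#' survival/fitness scoring and as the oracle target for quadrature tests.
#'
#' @param confA,confB conformers.
#' @return overlap volume (A^3).
#' @export
gaussian_overlap_fixed <- function(confA, confB) {
  ga <- conf_gaussians(confA)
  gb <- conf_gaussians(confB)
  pair_overlap_volume(ga$xyz, ga$alpha, gb$xyz, gb$alpha)
}

#' Shape Tanimoto at a fixed pose
#' @param confA,confB conformers.
#' @return shape Tanimoto in [0, 1].
#' @export
shape_tanimoto_fixed <- function(confA, confB) {
  ga <- conf_gaussians(confA)
  gb <- conf_gaussians(confB)
  oab <- pair_overlap_volume(ga$xyz, ga$alpha, gb$xyz, gb$alpha)
  oaa <- pair_overlap_volume(ga$xyz, ga$alpha, ga$xyz, ga$alpha)
  obb <- pair_overlap_volume(gb$xyz, gb$alpha, gb$xyz, gb$alpha)
  oab / (oaa + obb - oab)
}

#' Optimized Gaussian shape (+ color) overlap between two conformers
#'
#' @param confA,confB conformers with heavy atoms (features optional; color
#'   Tanimoto is 0 when both feature sets are empty).
#' @param optimize superpose B onto A (default TRUE); FALSE scores the
#'   given poses directly.
#' @param maxit iteration cap for each local refinement.
#' @return list of class `qp_overlap`: `o_ab`, `o_aa`, `o_bb`,
#'   `shape_tanimoto`, `color_tanimoto`, `combined`, `rot`, `trans` (the
#'   transform applied to `confB`'s coordinates).
#' @export
gaussian_overlap <- function(confA, confB, optimize = TRUE, maxit = 30L) {
  na <- sum(confA$elements != "H")
  nb <- sum(confB$elements != "H")
  if (na == 0 || nb == 0) stop("empty conformer in gaussian_overlap")
  # canonical order => exact A/B symmetry of all Tanimotos
  swapped <- canonical_swap(confA, confB)
  if (swapped) { tmp <- confA; confA <- confB; confB <- tmp }
  ga <- conf_gaussians(confA)
  gb <- conf_gaussians(confB)
  oaa <- pair_overlap_volume(ga$xyz, ga$alpha, ga$xyz, ga$alpha)
  obb <- pair_overlap_volume(gb$xyz, gb$alpha, gb$xyz, gb$alpha)
  if (optimize) {
    fit <- optimize_superposition(ga, gb, maxit)
    rot <- fit$rot; trans <- fit$trans; oab <- fit$oab
  } else {
    rot <- diag(3); trans <- c(0, 0, 0)
    oab <- pair_overlap_volume(ga$xyz, ga$alpha, gb$xyz, gb$alpha)
  }
  st <- oab / (oaa + obb - oab)
  ct <- color_tanimoto_at_pose(confA$features, confB$features, rot, trans)
  if (swapped) {
    # report the transform for the caller's B (our A): the inverse motion
    rot_out <- t(rot)
    trans_out <- as.numeric(-t(rot) %*% trans)
    o_aa_out <- obb; o_bb_out <- oaa
  } else {
    rot_out <- rot; trans_out <- trans
    o_aa_out <- oaa; o_bb_out <- obb
  }
  res <- list(o_ab = oab, o_aa = o_aa_out, o_bb = o_bb_out,
              shape_tanimoto = st, color_tanimoto = ct,
              combined = st + ct, rot = rot_out, trans = trans_out,
              swapped = swapped)
  class(res) <- "qp_overlap"
  res
}

#' Deterministic canonical ordering of a conformer pair
#' @noRd
canonical_swap <- function(confA, confB) {
  ka <- conf_order_key(confA)
  kb <- conf_order_key(confB)
  kb < ka
}

#' @noRd
conf_order_key <- function(conf) {
  heavy <- conf$elements != "H"
  xyz <- conf$coords[heavy, , drop = FALSE]
  sprintf("%06d_%s", sum(heavy),
          paste(sprintf("%.4f", c(sum(xyz^2), colSums(xyz))), collapse = "_"))
}

#' Four deterministic starts (principal-axes alignment and 180-degree
#' flips), each refined by BFGS over rotation vector + translation.
#' @noRd
optimize_superposition <- function(ga, gb, maxit = 30L) {
  ca <- colMeans(ga$xyz)
  cb <- colMeans(gb$xyz)
  A0 <- sweep(ga$xyz, 2, ca)
  B0 <- sweep(gb$xyz, 2, cb)
  pa <- principal_axes(A0)
  pb <- principal_axes(B0)
  flips <- list(diag(3), diag(c(1, -1, -1)), diag(c(-1, 1, -1)),
                diag(c(-1, -1, 1)))
  best <- NULL
  for (Fm in flips) {
    R0 <- pa %*% Fm %*% t(pb)   # rotates centered B onto centered A frame
    obj <- function(par) {
      overlap_objective_cpp(par, A0, ga$alpha, B0, gb$alpha, R0)
    }
    grad <- function(par) {
      overlap_gradient_cpp(par, A0, ga$alpha, B0, gb$alpha, R0)
    }
    opt <- stats::optim(rep(0, 6), obj, gr = grad, method = "BFGS",
                        control = list(maxit = maxit, reltol = 1e-7))
    if (is.null(best) || opt$value < best$value) {
      best <- opt
      best$R0 <- R0
    }
  }
  R <- rotvec_to_matrix(best$par[1:3]) %*% best$R0
  # full transform in original coordinates: x -> R (x - cb) + t* + ca
  trans <- as.numeric(ca + best$par[4:6] - R %*% cb)
  list(rot = R, trans = trans, oab = -best$value)
}

#' @noRd
principal_axes <- function(centered_xyz) {
  if (nrow(centered_xyz) == 1) return(diag(3))
  sv <- svd(centered_xyz)
  V <- sv$v
  if (ncol(V) < 3) V <- cbind(V, diag(3)[, seq(ncol(V) + 1, 3), drop = FALSE])
  # right-handed, deterministic signs
  for (j in 1:2) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  V[, 3] <- cross3(V[, 1], V[, 2])
  V
}

#' Feature (color) Tanimoto between two site tables
#'
#' One Gaussian per site (radius `COLOR_SIGMA`); overlap is accumulated
#' within kinds only and Tanimoto-combined across all kinds. Defined as 0
#' when both feature sets are empty and when the kinds are disjoint.
#'
#' @param ftA,ftB feature tables (possibly NULL/empty).
#' @param rot,trans rigid transform applied to B's sites (default identity).
#' @return color Tanimoto in [0, 1].
#' @export
color_tanimoto <- function(ftA, ftB, rot = diag(3), trans = c(0, 0, 0)) {
  color_tanimoto_at_pose(ftA, ftB, rot, trans)
}

#' @noRd
color_tanimoto_at_pose <- function(ftA, ftB, rot, trans) {
  if (is.null(ftA) || is.null(ftB) || nrow(ftA) == 0 || nrow(ftB) == 0) {
    return(0)
  }
  alpha <- gauss_alpha(COLOR_SIGMA)
  kinds <- union(ftA$kind, ftB$kind)
  oab <- oaa <- obb <- 0
  xyzB_all <- apply_rigid(site_xyz(ftB), rot, trans)
  for (kd in kinds) {
    ia <- which(ftA$kind == kd)
    ib <- which(ftB$kind == kd)
    xa <- site_xyz(ftA)[ia, , drop = FALSE]
    xb <- xyzB_all[ib, , drop = FALSE]
    aa <- rep(alpha, length(ia))
    ab <- rep(alpha, length(ib))
    oab <- oab + pair_overlap_volume(xa, aa, xb, ab)
    oaa <- oaa + pair_overlap_volume(xa, aa, xa, aa)
    obb <- obb + pair_overlap_volume(xb, ab, xb, ab)
  }
  denom <- oaa + obb - oab
  if (denom <= 0) return(0)
  max(0, min(1, oab / denom))
}
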