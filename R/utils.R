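# Internal geometry and bookkeeping helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize a 3-vector to unit length
#' @noRd
unit_vec <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) return(c(0, 0, 1))
  v / n
}

#' Rotation matrix from a rotation vector (axis * angle, radians)
#' @noRd
rotvec_to_matrix <- function(r) {
  theta <- sqrt(sum(r^2))
  if (theta < 1e-12) return(diag(3))
  k <- r / theta
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Apply a rigid transform (rotation R then translation t) to an n x 3 matrix
#' @noRd
apply_rigid <- function(xyz, rot, trans) {
  out <- sweep(xyz %*% t(rot), 2, trans, `+`)
  dimnames(out) <- dimnames(xyz)
  out
}

#' Optimal rigid superposition (Kabsch) of moving onto fixed point sets.
#'
#' Returns rotation, translation and RMSD such that
#' moving %*% t(R) + t approximates fixed in least squares.
#' @noRd
kabsch <- function(moving, fixed, weights = NULL) {
  stopifnot(nrow(moving) == nrow(fixed), ncol(moving) == 3)
  w <- weights %||% rep(1, nrow(moving))
  w <- w / sum(w)
  cm <- colSums(moving * w)
  cf <- colSums(fixed * w)
  A <- sweep(moving, 2, cm)
  B <- sweep(fixed, 2, cf)
  H <- t(A * w) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  rot <- sv$v %*% D %*% t(sv$u)
  trans <- cf - as.vector(rot %*% cm)
  moved <- apply_rigid(moving, rot, trans)
  rmsd <- sqrt(mean(rowSums((moved - fixed)^2)))
  list(rot = rot, trans = trans, rmsd = rmsd)
}

#' Random rotation matrix (uniform over SO(3)) using the current RNG stream
#' @noRd
random_rotation <- function() {
  # quaternion method
  u <- stats::runif(3)
  q <- c(
    sqrt(1 - u[1]) * sin(2 * pi * u[2]),
    sqrt(1 - u[1]) * cos(2 * pi * u[2]),
    sqrt(u[1]) * sin(2 * pi * u[3]),
    sqrt(u[1]) * cos(2 * pi * u[3])
  )
  w <- q[4]; x <- q[1]; y <- q[2]; z <- q[3]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

#' Derive a per-stage seed from a global seed (kept below 2^31)
#' @noRd
stage_seed <- function(seed, offset) {
  (as.integer(seed) %% 100000L) * 1000L + as.integer(offset) %% 1000L
}

#' Evaluate code with a local RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Quiet message helper honouring options(qsarphore.verbose = FALSE)
#' @noRd
qp_log <- function(...) {
  if (isTRUE(getOption("qsarphore.verbose", TRUE))) {
    message("[qsarphore] ", ...)
  }
  invisible(NULL)
}
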