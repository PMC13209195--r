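#' Pharmacophore feature perception
#'
#' Sites of six kinds are perceived from a conformer's connection table:
#' hydrogen-bond acceptors (A), donors (D), hydrophobes (H), negatively (N)
#' and positively (P) charged groups, and aromatic rings (R). The rule table
#' is explicit and versioned (see [pharmacophore_feature_rules()]): published
#' pharmacophore dialects differ in detail, so the definitions are pinned
#' here rather than inherited from any external tool.
#'
#' Rules (version 1.0), applied to heavy atoms with implicit hydrogen counts
#' derived from standard valences:
#' * `D`: uncharged N or O bearing at least one hydrogen; direction along
#'   the idealized X-H axis (away from the mean heavy-neighbour direction).
#' * `A`: uncharged O (carbonyl, ether, hydroxyl), aromatic N without H
#'   (pyridine-like) or nitrile N; direction along the lone-pair axis.
#' * `R`: aromatic 5- or 6-ring; site at the ring centroid, direction along
#'   the ring-plane normal.
#' * `H`: terminal carbon bonded only to carbon (methyl-like) or halogen on
#'   carbon.
#' * `N`: atom with negative formal charge. `P`: atom with positive formal
#'   charge.
#'
#' Output order is deterministic: by kind, then position lexicographically.
#'
#' @param conf a [conformer()].
#' @param rules feature rule table, by default [pharmacophore_feature_rules()].
#' @return Feature-site data.frame (see [feature_sites()]).
#' @export
perceive_features <- function(conf, rules = pharmacophore_feature_rules()) {
  stopifnot(inherits(conf, "qp_conformer"))
  if (is.null(rules) || nrow(rules) == 0) stop("empty feature rule table")
  n <- nrow(conf$coords)
  el <- conf$elements
  xyz <- conf$coords
  chg <- conf$charges
  adj <- bond_adjacency(conf$bonds, n)
  hyd <- implicit_h_counts(conf)
  rings <- aromatic_rings(conf)
  in_arom_ring <- rep(FALSE, n)
  for (r in rings) in_arom_ring[r] <- TRUE

  kinds <- character(0)
  pos <- matrix(numeric(0), ncol = 3)
  dirs <- matrix(numeric(0), ncol = 3)
  add_site <- function(kind, p, d = c(NA_real_, NA_real_, NA_real_)) {
    kinds <<- c(kinds, kind)
    pos <<- rbind(pos, p)
    dirs <<- rbind(dirs, d)
  }
  lone_pair_dir <- function(i) {
    nb <- adj[[i]]
    nb <- nb[el[nb] != "H"]
    if (length(nb) == 0) return(c(0, 0, 1))
    unit_vec(xyz[i, ] - colMeans(xyz[nb, , drop = FALSE]))
  }
  active <- function(rule) isTRUE(rules$enabled[rules$kind == rule][1])

  heavy <- which(el != "H")
  for (i in heavy) {
    e <- el[i]
    nb <- adj[[i]]
    nb_heavy <- nb[el[nb] != "H"]
    deg <- length(nb_heavy)
    if (chg[i] < 0 && active("N")) add_site("N", xyz[i, ])
    if (chg[i] > 0 && active("P")) add_site("P", xyz[i, ])
    if (chg[i] != 0) next
    if (e %in% c("N", "O") && hyd[i] >= 1 && active("D")) {
      add_site("D", xyz[i, ], lone_pair_dir(i))
    }
    if (active("A")) {
      is_acceptor <-
        (e == "O") ||
        (e == "N" && in_arom_ring[i] && hyd[i] == 0) ||
        (e == "N" && deg == 1 && any(conf$bonds[, 3][bond_rows(conf$bonds, i)] == 3))
      if (is_acceptor) add_site("A", xyz[i, ], lone_pair_dir(i))
    }
    if (active("H")) {
      is_hydrophobe <-
        (e == "C" && deg == 1 && all(el[nb_heavy] == "C") && !in_arom_ring[i]) ||
        (e %in% c("F", "Cl", "Br", "I") && deg == 1 && el[nb_heavy] == "C")
      if (is_hydrophobe) add_site("H", xyz[i, ])
    }
  }
  if (active("R")) {
    for (r in rings) {
      ring_xyz <- xyz[r, , drop = FALSE]
      centroid <- colMeans(ring_xyz)
      add_site("R", centroid, ring_normal(ring_xyz))
    }
  }
  if (length(kinds) == 0) {
    return(feature_sites(character(0), matrix(numeric(0), ncol = 3)))
  }
  order_features(feature_sites(kinds, pos, dirs))
}

#' The versioned feature-definition table
#'
#' One row per site kind with its textual definition; `enabled` toggles a
#' kind off (e.g. to build hypotheses over a restricted alphabet).
#'
#' @param exclude character vector of kinds to disable.
#' @return data.frame with columns kind, definition, enabled and an attached
#'   `version` attribute.
#' @export
pharmacophore_feature_rules <- function(exclude = character(0)) {
  tab <- data.frame(
    kind = c("A", "D", "H", "N", "P", "R"),
    definition = c(
      "uncharged O; aromatic N without H; nitrile N",
      "uncharged N or O with >= 1 implicit/explicit H",
      "terminal C bonded only to C; halogen on C",
      "formal charge < 0",
      "formal charge > 0",
      "aromatic 5- or 6-ring centroid"
    ),
    stringsAsFactors = FALSE
  )
  tab$enabled <- !(tab$kind %in% exclude)
  attr(tab, "version") <- "1.0"
  tab
}

# ---- connection-table helpers -------------------------------------------

#' @noRd
bond_adjacency <- function(bonds, n) {
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  if (nrow(bonds) > 0) {
    for (b in seq_len(nrow(bonds))) {
      a1 <- bonds[b, 1]; a2 <- bonds[b, 2]
      adj[[a1]] <- c(adj[[a1]], a2)
      adj[[a2]] <- c(adj[[a2]], a1)
    }
  }
  adj
}

#' @noRd
bond_rows <- function(bonds, i) {
  which(bonds[, 1] == i | bonds[, 2] == i)
}

#' Implicit hydrogen count per atom from standard valences.
#' Aromatic bonds (order 4) count 1.5; totals are rounded before the
#' subtraction. Explicit H neighbours are included in the count.
#' @noRd
implicit_h_counts <- function(conf) {
  std_val <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1, Br = 1,
               I = 1, B = 3, Si = 4)
  n <- nrow(conf$coords)
  el <- conf$elements
  chg <- conf$charges
  ords <- numeric(n)
  if (nrow(conf$bonds) > 0) {
    for (b in seq_len(nrow(conf$bonds))) {
      o <- conf$bonds[b, 3]
      oo <- if (o == 4) 1.5 else o
      ords[conf$bonds[b, 1]] <- ords[conf$bonds[b, 1]] + oo
      ords[conf$bonds[b, 2]] <- ords[conf$bonds[b, 2]] + oo
    }
  }
  out <- integer(n)
  for (i in seq_len(n)) {
    v <- std_val[el[i]]
    if (is.na(v)) { out[i] <- 0L; next }
    # charge shifts valence: N+ has 4, O- has 1, etc.
    v <- v + if (el[i] %in% c("N", "P")) chg[i] else -chg[i]
    out[i] <- max(0L, as.integer(round(v - round(ords[i]))))
  }
  out
}

#' Enumerate simple rings of size 5 or 6 and keep the aromatic ones.
#'
#' Aromaticity rule (pinned): all ring atoms in {C,N,O,S}; ring bonds all
#' order 4, or the ring carries >= floor(size/2) in-ring double bonds
#' (Kekule benzene/pyridine: 3; furan/thiophene/pyrrole: 2).
#' @noRd
aromatic_rings <- function(conf) {
  rings <- find_rings(conf$bonds, nrow(conf$coords), sizes = c(5L, 6L))
  el <- conf$elements
  keep <- list()
  for (r in rings) {
    if (!all(el[r] %in% c("C", "N", "O", "S"))) next
    k <- length(r)
    ords <- integer(k)
    ok <- TRUE
    for (j in seq_len(k)) {
      a1 <- r[j]; a2 <- r[if (j == k) 1 else j + 1]
      row <- which((conf$bonds[, 1] == a1 & conf$bonds[, 2] == a2) |
                     (conf$bonds[, 1] == a2 & conf$bonds[, 2] == a1))
      if (length(row) == 0) { ok <- FALSE; break }
      ords[j] <- conf$bonds[row[1], 3]
    }
    if (!ok) next
    if (all(ords == 4) || sum(ords == 2) >= floor(k / 2)) {
      keep[[length(keep) + 1]] <- r
    }
  }
  keep
}

#' All simple cycles of the requested sizes, deduplicated by atom set.
#' Molecules are small; a depth-limited DFS is adequate.
#' @noRd
find_rings <- function(bonds, natoms, sizes = c(5L, 6L)) {
  if (nrow(bonds) == 0) return(list())
  adj <- bond_adjacency(bonds, natoms)
  maxlen <- max(sizes)
  found <- new.env(hash = TRUE)
  out <- list()
  dfs <- function(start, path) {
    last <- path[length(path)]
    for (nb in adj[[last]]) {
      if (nb == start && length(path) >= 3 && length(path) %in% sizes) {
        key <- paste(sort(path), collapse = ",")
        if (is.null(found[[key]])) {
          found[[key]] <- TRUE
          out[[length(out) + 1]] <<- path
        }
      } else if (!(nb %in% path) && nb > start && length(path) < maxlen) {
        dfs(start, c(path, nb))
      }
    }
  }
  for (s in seq_len(natoms)) dfs(s, s)
  out
}

#' Unit normal of a (near-)planar ring via SVD; sign fixed so the first
#' coordinate triple has positive orientation, for determinism.
#' @noRd
ring_normal <- function(ring_xyz) {
  ctr <- colMeans(ring_xyz)
  sv <- svd(sweep(ring_xyz, 2, ctr))
  nrm <- sv$v[, 3]
  # deterministic sign: make the largest-magnitude component positive
  i <- which.max(abs(nrm))
  if (nrm[i] < 0) nrm <- -nrm
  unit_vec(nrm)
}
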