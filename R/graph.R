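# SMILES -> molecular graph with initial atom/bond features.
#
# Parsing (atoms, bonds, formal charges, ring perception and aromaticity) is
# delegated to ChemmineR/ChemmineOB (OpenBabel). The feature binning is local:
# the atom vector encodes exactly 8 property groups and the bond vector exactly
# 4. Graphs are heavy-atom only; hydrogens enter as an atom-level count.

.ATOM_ELEMENTS <- c("B", "C", "N", "O", "F", "Si", "P", "S", "Cl", "Br", "I")
.DEFAULT_VALENCE <- c(B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3,
                      S = 2, Cl = 1, Br = 1, I = 1)
.ATOMIC_NUMBER <- c(B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15,
                    S = 16, Cl = 17, Br = 35, I = 53)
.ATOMIC_MASS <- c(B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
                  Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45,
                  Br = 79.904, I = 126.904)
.MDL_CHARGE <- c(`0` = 0, `1` = 3, `2` = 2, `3` = 1, `4` = 0, `5` = -1,
                 `6` = -2, `7` = -3)

.onehot <- function(value, levels) as.numeric(levels == value)

#' Number of atom feature dimensions
#' @return Length of the initial atom feature vector.
#' @export
atom_feature_dim <- function() {
  length(.ATOM_ELEMENTS) + 1L +  # element (+ other)
    6L +                         # degree 0..5
    5L +                         # formal charge -2..+2
    4L +                         # chirality parity none/CW/CCW/either
    5L +                         # attached hydrogens 0..4
    4L +                         # hybridization sp/sp2/sp3/other
    1L +                         # aromatic flag
    1L                           # atomic mass * 0.01
}

#' Number of bond feature dimensions
#' @return Length of the initial bond feature vector.
#' @export
bond_feature_dim <- function() 4L + 1L + 1L + 2L

#' Number of atom/bond property groups encoded in the initial features
#' @return Named integer vector with entries `atom` (8) and `bond` (4).
#' @export
graph_property_counts <- function() c(atom = 8L, bond = 4L)

.parse_sdf_one <- function(sdf, smiles) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  if (!all(grepl("^[A-Za-z]+_[0-9]+$", rownames(ab))))
    stop("malformed atom block")
  if (is.null(dim(bb))) bb <- matrix(bb, nrow = length(bb) %/% 7, ncol = 7,
                                     byrow = FALSE)
  elements <- sub("_.*$", "", rownames(ab))
  n <- length(elements)
  n_bonds <- if (is.null(bb) || nrow(bb) == 0L) 0L else nrow(bb)

  charge_code <- if ("C6" %in% colnames(ab)) ab[, "C6"] else rep(0, n)
  charge <- unname(.MDL_CHARGE[as.character(charge_code)])
  charge[is.na(charge)] <- 0
  parity <- if ("C7" %in% colnames(ab)) ab[, "C7"] else rep(0, n)

  bond_a <- if (n_bonds) as.integer(bb[, 1]) else integer(0)
  bond_b <- if (n_bonds) as.integer(bb[, 2]) else integer(0)
  bond_order <- if (n_bonds) as.integer(bb[, 3]) else integer(0)
  bond_stereo <- if (n_bonds && ncol(bb) >= 4) as.integer(bb[, 4]) else integer(n_bonds)

  # ring perception: in-ring membership and aromaticity
  ring_pairs <- character(0)
  arom_pairs <- character(0)
  aromatic_atom <- rep(FALSE, n)
  if (n_bonds) {
    ri <- tryCatch(ChemmineR::rings(sdf, type = "all", arom = TRUE),
                   error = function(e) list(RINGS = list(), AROMATIC = logical(0)))
    rlist <- ri$RINGS
    for (i in seq_along(rlist)) {
      idx <- as.integer(sub("^.*_", "", rlist[[i]]))
      cyc <- cbind(idx, c(idx[-1], idx[1]))
      keys <- paste(pmin(cyc[, 1], cyc[, 2]), pmax(cyc[, 1], cyc[, 2]))
      ring_pairs <- c(ring_pairs, keys)
      if (isTRUE(ri$AROMATIC[[i]])) {
        arom_pairs <- c(arom_pairs, keys)
        aromatic_atom[idx] <- TRUE
      }
    }
  }
  bond_key <- paste(pmin(bond_a, bond_b), pmax(bond_a, bond_b))
  bond_in_ring <- bond_key %in% ring_pairs
  bond_aromatic <- bond_key %in% arom_pairs

  degree <- tabulate(c(bond_a, bond_b), nbins = n)

  # bond-order sum per atom (aromatic bonds contribute 1.5)
  order_num <- ifelse(bond_aromatic, 1.5, bond_order)
  osum <- rep(0, n)
  for (i in seq_len(n_bonds)) {
    osum[bond_a[i]] <- osum[bond_a[i]] + order_num[i]
    osum[bond_b[i]] <- osum[bond_b[i]] + order_num[i]
  }
  osum <- round(osum)

  # implicit hydrogens from default valences, charge-adjusted
  eff <- unname(.DEFAULT_VALENCE[elements]) + charge
  eff[is.na(eff)] <- 0
  h_count <- pmax(0, eff - osum)

  # hybridization by local bond pattern
  n_double <- n_triple <- rep(0L, n)
  for (i in seq_len(n_bonds)) {
    if (!bond_aromatic[i] && bond_order[i] == 2L) {
      n_double[bond_a[i]] <- n_double[bond_a[i]] + 1L
      n_double[bond_b[i]] <- n_double[bond_b[i]] + 1L
    }
    if (bond_order[i] == 3L) {
      n_triple[bond_a[i]] <- n_triple[bond_a[i]] + 1L
      n_triple[bond_b[i]] <- n_triple[bond_b[i]] + 1L
    }
  }
  hybrid <- ifelse(n_triple > 0 | n_double >= 2, "sp",
                   ifelse(n_double > 0 | aromatic_atom, "sp2", "sp3"))
  conj_atom <- hybrid %in% c("sp", "sp2")

  atom_features <- t(vapply(seq_len(n), function(i) {
    el <- elements[i]
    c(.onehot(if (el %in% .ATOM_ELEMENTS) el else "other",
              c(.ATOM_ELEMENTS, "other")),
      .onehot(min(degree[i], 5L), 0:5),
      .onehot(max(-2L, min(2L, charge[i])), -2:2),
      .onehot(min(parity[i], 3), 0:3),
      .onehot(min(h_count[i], 4L), 0:4),
      .onehot(hybrid[i], c("sp", "sp2", "sp3", "other")),
      as.numeric(aromatic_atom[i]),
      if (el %in% names(.ATOMIC_MASS)) 0.01 * .ATOMIC_MASS[[el]] else 0)
  }, numeric(atom_feature_dim())))

  # two directed edges per bond, interleaved so rev_edge is a cheap involution
  E <- 2L * n_bonds
  src <- tgt <- integer(E)
  bond_features <- matrix(0, E, bond_feature_dim())
  rev_edge <- integer(E)
  for (i in seq_len(n_bonds)) {
    e1 <- 2L * i - 1L; e2 <- 2L * i
    src[e1] <- bond_a[i]; tgt[e1] <- bond_b[i]
    src[e2] <- bond_b[i]; tgt[e2] <- bond_a[i]
    rev_edge[e1] <- e2; rev_edge[e2] <- e1
    btype <- if (bond_aromatic[i]) "aromatic" else
      c("single", "double", "triple")[min(bond_order[i], 3L)]
    conj <- conj_atom[bond_a[i]] && conj_atom[bond_b[i]]
    feat <- c(.onehot(btype, c("single", "double", "triple", "aromatic")),
              as.numeric(bond_in_ring[i]),
              as.numeric(conj),
              .onehot(min(bond_stereo[i], 1L), 0:1))
    bond_features[e1, ] <- feat
    bond_features[e2, ] <- feat
  }

  structure(list(n_atoms = n, elements = elements,
                 atom_features = atom_features,
                 edges = cbind(src = src, tgt = tgt),
                 bond_features = bond_features,
                 rev_edge = rev_edge,
                 aromatic = aromatic_atom,
                 degree = degree, h_count = h_count,
                 smiles = smiles),
            class = "molecular_graph")
}

#' Convert a SMILES string to a featurized molecular graph
#'
#' Parses the SMILES (OpenSMILES dialect, via OpenBabel) into a heavy-atom
#' graph with two directed edges per chemical bond and a reverse-edge map.
#' Atom feature vectors encode eight property groups (element, degree, formal
#' charge, chirality parity, attached hydrogens, hybridization, aromaticity,
#' scaled atomic mass); bond vectors encode four (bond type, ring position,
#' conjugation, stereo marking).
#'
#' @param smiles A single SMILES string.
#' @param cache Reuse previously parsed graphs for identical strings
#'   (default TRUE; parsing dominates featurization cost).
#' @return A `molecular_graph`: list with `n_atoms`, `atom_features`
#'   (n_atoms x [atom_feature_dim()]), `edges` (E x 2 matrix of directed
#'   src/tgt atom indices, E = 2 x bonds), `bond_features`
#'   (E x [bond_feature_dim()]), `rev_edge` (involution over edges),
#'   `aromatic`, `elements`, `smiles`.
#' @export
#' @examples
#' \donttest{
#' g <- smiles_to_graph("CCO")
#' g$n_atoms      # 3
#' nrow(g$edges)  # 4 directed edges (2 bonds)
#' }
smiles_to_graph <- function(smiles, cache = TRUE) {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(smiles))
    stop_invalid("`smiles` must be a non-empty string")
  if (is.null(.dtifuse_env$graph_cache))
    .dtifuse_env$graph_cache <- new.env(parent = emptyenv())
  gc_env <- .dtifuse_env$graph_cache
  if (cache && !is.null(gc_env[[smiles]])) return(gc_env[[smiles]])
  txt <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat(
      "SMI", "SDF", paste0(smiles, "\tmol"))),
    error = function(e) "")
  if (!nzchar(trimws(txt)))
    stop(errorCondition(
      sprintf("SMILES string could not be parsed: '%s'", smiles),
      class = c("dtifuse_parse_error", "dtifuse_error"), smiles = smiles))
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  counts <- strsplit(trimws(lines[4]), "\\s+")[[1]]
  n_atoms <- as.integer(counts[1]); n_bonds <- as.integer(counts[2])
  g <- if (n_bonds == 0L) {
    # ChemmineR cannot represent bond-free molecules; read the atom lines
    elements <- vapply(lines[5:(4L + n_atoms)], function(ln)
      strsplit(trimws(ln), "\\s+")[[1]][4], character(1), USE.NAMES = FALSE)
    .graph_from_atoms(elements, smiles)
  } else {
    sdf <- suppressWarnings(ChemmineR::read.SDFset(lines))
    .parse_sdf_one(sdf[[1]], smiles)
  }
  if (cache) gc_env[[smiles]] <- g
  g
}

# bond-free molecule: isolated atoms, no directed edges
.graph_from_atoms <- function(elements, smiles) {
  n <- length(elements)
  atom_features <- t(vapply(elements, function(el) {
    dv <- if (el %in% names(.DEFAULT_VALENCE)) .DEFAULT_VALENCE[[el]] else 0
    c(.onehot(if (el %in% .ATOM_ELEMENTS) el else "other",
              c(.ATOM_ELEMENTS, "other")),
      .onehot(0L, 0:5),
      .onehot(0L, -2:2),
      .onehot(0L, 0:3),
      .onehot(min(dv, 4L), 0:4),
      .onehot("sp3", c("sp", "sp2", "sp3", "other")),
      0,
      if (el %in% names(.ATOMIC_MASS)) 0.01 * .ATOMIC_MASS[[el]] else 0)
  }, numeric(atom_feature_dim())))
  structure(list(n_atoms = n, elements = unname(elements),
                 atom_features = atom_features,
                 edges = cbind(src = integer(0), tgt = integer(0)),
                 bond_features = matrix(0, 0L, bond_feature_dim()),
                 rev_edge = integer(0),
                 aromatic = rep(FALSE, n),
                 degree = rep(0L, n),
                 h_count = vapply(elements, function(el)
                   if (el %in% names(.DEFAULT_VALENCE)) .DEFAULT_VALENCE[[el]] else 0,
                   numeric(1), USE.NAMES = FALSE),
                 smiles = smiles),
            class = "molecular_graph")
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf("<molecular_graph> %s: %d atoms, %d bonds\n",
              x$smiles, x$n_atoms, nrow(x$edges) %/% 2L))
  invisible(x)
}
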