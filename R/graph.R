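# Molecular graphs: heavy-atom skeleton with implicit hydrogens.
#
# Representation: elements (character), hydrogens (integer, attached H per
# heavy atom), bonds (matrix with columns i, j, order), optional per-atom
# assigned 13C shifts (NA for unassigned/non-carbon).  Formal charges are
# fixed at zero; aromatic systems are kept as Kekule alternating bond orders.

default_valence <- function(elements) {
  vapply(elements, function(e) {
    if (!e %in% names(.ELEMENTS)) stop(sprintf("unknown element '%s'", e))
    .ELEMENTS[[e]]$valence
  }, integer(1))
}

#' Construct a molecular graph
#'
#' @param elements Character vector of heavy-atom element symbols.
#' @param hydrogens Integer vector of attached hydrogen counts per atom.
#' @param bonds Matrix (or data.frame) with columns `i`, `j`, `order`
#'   (1-based atom indices, order in 1..3). May have zero rows.
#' @param shifts Optional numeric vector of assigned 13C shifts (ppm),
#'   `NA` where unassigned.
#' @param valences Optional integer vector of per-atom valences overriding the
#'   defaults (C 4, N 3, O 2, ...), e.g. to explore pentavalent nitrogen.
#' @param validate Check valence closure and connectivity (default `TRUE`).
#' @return An object of class `molgraph`.
#' @export
molgraph <- function(elements, hydrogens, bonds, shifts = NULL,
                     valences = NULL, validate = TRUE) {
  n <- length(elements)
  if (n == 0L) stop("molecular graph must contain at least one atom")
  hydrogens <- as.integer(hydrogens)
  if (length(hydrogens) != n) stop("hydrogens must match atom count")
  if (is.data.frame(bonds)) bonds <- as.matrix(bonds)
  if (is.null(bonds) || length(bonds) == 0L) {
    bonds <- matrix(integer(0), ncol = 3L)
  }
  bonds <- matrix(as.integer(bonds), ncol = 3L,
                  dimnames = list(NULL, c("i", "j", "order")))
  if (is.null(valences)) valences <- default_valence(elements)
  valences <- as.integer(valences)
  if (is.null(shifts)) shifts <- rep(NA_real_, n)
  g <- structure(list(elements = as.character(elements),
                      hydrogens = hydrogens,
                      bonds = bonds,
                      shifts = as.numeric(shifts),
                      valences = valences),
                 class = "molgraph")
  if (validate) validate_molgraph(g)
  g
}

validate_molgraph <- function(g) {
  n <- n_atoms(g)
  b <- g$bonds
  if (nrow(b) > 0L) {
    if (any(b[, "i"] < 1L | b[, "i"] > n | b[, "j"] < 1L | b[, "j"] > n))
      stop("bond endpoint out of range")
    if (any(b[, "i"] == b[, "j"])) stop("self-bonds are not allowed")
    if (!all(b[, "order"] %in% 1:3)) stop("bond orders must be 1, 2 or 3")
    key <- paste(pmin(b[, "i"], b[, "j"]), pmax(b[, "i"], b[, "j"]))
    if (anyDuplicated(key)) stop("at most one bond per atom pair")
  }
  deg <- bond_order_sums(g)
  bad <- which(deg + g$hydrogens != g$valences)
  if (length(bad))
    stop(sprintf("valence violation at atom %d (%s): bonds %d + H %d != valence %d",
                 bad[1], g$elements[bad[1]], deg[bad[1]], g$hydrogens[bad[1]],
                 g$valences[bad[1]]))
  if (!is_connected_graph(g)) stop("molecular graph must be connected")
  invisible(g)
}

n_atoms <- function(g) length(g$elements)

bond_order_sums <- function(g) {
  deg <- integer(n_atoms(g))
  b <- g$bonds
  for (k in seq_len(nrow(b))) {
    deg[b[k, "i"]] <- deg[b[k, "i"]] + b[k, "order"]
    deg[b[k, "j"]] <- deg[b[k, "j"]] + b[k, "order"]
  }
  deg
}

# number of pi bonds per atom: sum of (order - 1) over incident bonds
pi_counts <- function(g) {
  p <- integer(n_atoms(g))
  b <- g$bonds
  for (k in seq_len(nrow(b))) {
    extra <- b[k, "order"] - 1L
    p[b[k, "i"]] <- p[b[k, "i"]] + extra
    p[b[k, "j"]] <- p[b[k, "j"]] + extra
  }
  p
}

as_igraph <- function(g) {
  ig <- igraph::make_empty_graph(n = n_atoms(g), directed = FALSE)
  if (nrow(g$bonds) > 0L)
    ig <- igraph::add_edges(ig, t(g$bonds[, c("i", "j"), drop = FALSE]))
  ig
}

is_connected_graph <- function(g) {
  if (n_atoms(g) == 1L) return(TRUE)
  igraph::is_connected(as_igraph(g))
}

# all-pairs skeletal (topological) distances, in bonds
skeleton_distances <- function(g) {
  igraph::distances(as_igraph(g))
}

#' Molecular formula of a graph (heavy atoms + implicit hydrogens)
#' @param g A `molgraph`.
#' @return A `molformula`.
#' @export
graph_formula <- function(g) {
  tab <- table(g$elements)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  h <- sum(g$hydrogens)
  if (h > 0L) counts["H"] <- (if ("H" %in% names(counts)) counts[["H"]] else 0L) + h
  class(counts) <- "molformula"
  counts
}

#' @export
print.molgraph <- function(x, ...) {
  cat(sprintf("<molgraph> %s: %d heavy atoms, %d bonds\n",
              format(graph_formula(x)), n_atoms(x), nrow(x$bonds)))
  invisible(x)
}

# Vertex-colored transform for canonicalization: atoms colored by
# (element, H count, valence); each bond becomes an auxiliary vertex colored
# by its order, joined to both endpoints.  BLISS canonicalization on vertex
# colors then covers the edge-colored (bond-ordered) graph.
canon_transform <- function(g) {
  n <- n_atoms(g)
  nb <- nrow(g$bonds)
  atom_label <- paste0("A:", g$elements, ":", g$hydrogens, ":", g$valences)
  bond_label <- if (nb > 0L) paste0("B:", g$bonds[, "order"]) else character(0)
  labels <- c(atom_label, bond_label)
  # stable color assignment: rank within sorted unique labels
  colors <- match(labels, sort(unique(labels)))
  ig <- igraph::make_empty_graph(n = n + nb, directed = FALSE)
  if (nb > 0L) {
    ends <- rbind(cbind(g$bonds[, "i"], n + seq_len(nb)),
                  cbind(g$bonds[, "j"], n + seq_len(nb)))
    ig <- igraph::add_edges(ig, t(ends))
  }
  list(graph = ig, colors = colors, labels = labels, n_atoms = n)
}

#' Canonical key of a molecular graph
#'
#' An opaque string equal for two graphs exactly when they are isomorphic
#' (preserving element, attached-H count and bond order), and invariant under
#' atom relabeling. Used for duplicate removal of generated structures.
#'
#' @param g A `molgraph`.
#' @return Canonical key string.
#' @export
canonical_key <- function(g) {
  if (!is_connected_graph(g)) stop("canonical_key requires a connected graph")
  tr <- canon_transform(g)
  perm <- igraph::canonical_permutation(tr$graph, colors = tr$colors)$labeling
  # position of original atom vertices in canonical order
  n <- tr$n_atoms
  atom_rank <- rank(perm[seq_len(n)])
  atom_lab <- paste0(g$elements, ":", g$hydrogens, ":", g$valences)
  atoms_sorted <- atom_lab[order(atom_rank)]
  b <- g$bonds
  if (nrow(b) > 0L) {
    ci <- atom_rank[b[, "i"]]
    cj <- atom_rank[b[, "j"]]
    bonds_str <- paste0(pmin(ci, cj), "-", pmax(ci, cj), ":", b[, "order"])
    bonds_str <- sort(bonds_str)
  } else bonds_str <- character(0)
  paste(paste(atoms_sorted, collapse = ","),
        paste(bonds_str, collapse = ","), sep = "|")
}

#' Test two molecular graphs for isomorphism
#'
#' Element-, hydrogen-count- and bond-order-preserving isomorphism, decided by
#' comparing canonical keys.
#'
#' @param g1,g2 `molgraph` objects.
#' @return Logical.
#' @export
are_isomorphic <- function(g1, g2) {
  if (n_atoms(g1) == 0L || n_atoms(g2) == 0L) stop("graphs must contain atoms")
  if (n_atoms(g1) != n_atoms(g2)) return(FALSE)
  canonical_key(g1) == canonical_key(g2)
}

# apply a permutation to atom labels: atom k becomes perm[k]
relabel_graph <- function(g, perm) {
  inv <- integer(length(perm))
  inv[perm] <- seq_along(perm)
  b <- g$bonds
  if (nrow(b) > 0L) {
    b[, "i"] <- perm[b[, "i"]]
    b[, "j"] <- perm[b[, "j"]]
  }
  molgraph(g$elements[inv], g$hydrogens[inv], b, shifts = g$shifts[inv],
           valences = g$valences[inv], validate = FALSE)
}
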