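# Small distance-geometry conformer embedder.
#
# Bounds: exact bonded distances by element/order, exact geminal (1-3)
# distances from hybridization angles, 1-4 windows (syn..anti) around single
# bonds and exact cis/trans 1-4 distances across stereogenic double bonds;
# triangle smoothing; random metric embedding into 3D followed by gradient
# refinement of bound violations plus chiral-volume terms (stereocenter
# parities) and sp2 planarity terms.  Deliberately minimal: rigid and
# semi-rigid fixtures embed well; floppy macrocycles are out of scope.

.BOND_LEN <- function(e1, e2, order) {
  key <- paste(sort(c(e1, e2)), collapse = "-")
  tab1 <- c("C-C" = 1.54, "C-N" = 1.47, "C-O" = 1.43, "N-O" = 1.40,
            "N-N" = 1.45, "O-O" = 1.48, "C-H" = 1.09, "H-N" = 1.01,
            "H-O" = 0.96, "C-S" = 1.82, "C-F" = 1.35, "C-Cl" = 1.77,
            "Br-C" = 1.94, "C-I" = 2.14)
  tab2 <- c("C-C" = 1.34, "C-N" = 1.29, "C-O" = 1.22, "N-N" = 1.25,
            "N-O" = 1.21)
  tab3 <- c("C-C" = 1.20, "C-N" = 1.16)
  v <- switch(order, tab1[key], tab2[key], tab3[key])
  if (is.null(v) || is.na(v)) 1.5 else unname(v)
}

# explicit-hydrogen expansion: returns elements, parent map, bonds
expand_hydrogens <- function(g) {
  n <- n_atoms(g)
  elements <- g$elements
  bonds <- g$bonds
  h_parent <- integer(0)
  for (a in seq_len(n)) {
    for (k in seq_len(g$hydrogens[a])) {
      elements <- c(elements, "H")
      h_parent <- c(h_parent, a)
      bonds <- rbind(bonds, c(length(elements), a, 1L))
    }
  }
  colnames(bonds) <- c("i", "j", "order")
  list(elements = elements, bonds = bonds, n_heavy = n,
       h_parent = h_parent, h_index = n + seq_along(h_parent))
}

hyb_angle <- function(pi_count) c(109.47, 120, 180)[pmin(pi_count, 2L) + 1L]

d13 <- function(r1, r2, theta_deg) {
  th <- theta_deg * pi / 180
  sqrt(r1^2 + r2^2 - 2 * r1 * r2 * cos(th))
}

# 1-4 distance for chain A-B-C-D with given dihedral (deg)
d14 <- function(rab, rbc, rcd, thB, thC, dihedral_deg) {
  tB <- thB * pi / 180; tC <- thC * pi / 180; ph <- dihedral_deg * pi / 180
  A <- c(rab * cos(tB), rab * sin(tB), 0)            # angle A-B-C = thB at origin
  D <- c(rbc - rcd * cos(tC),                         # angle B-C-D = thC
         rcd * sin(tC) * cos(ph),
         rcd * sin(tC) * sin(ph))
  sqrt(sum((A - D)^2))
}

build_bounds <- function(ex, g, config) {
  N <- length(ex$elements)
  lo <- matrix(2.2, N, N)
  isH <- ex$elements == "H"
  lo[isH, ] <- 1.8; lo[, isH] <- 1.8
  hi <- matrix(60, N, N)
  diag(lo) <- 0; diag(hi) <- 0
  pi_full <- c(pi_counts(g), rep(0L, length(ex$h_parent)))
  # adjacency with orders on the expanded graph
  nb <- vector("list", N)
  blen <- matrix(0, N, N)
  for (k in seq_len(nrow(ex$bonds))) {
    i <- ex$bonds[k, "i"]; j <- ex$bonds[k, "j"]; o <- ex$bonds[k, "order"]
    r <- .BOND_LEN(ex$elements[i], ex$elements[j], o)
    lo[i, j] <- lo[j, i] <- r; hi[i, j] <- hi[j, i] <- r
    blen[i, j] <- blen[j, i] <- r
    nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
  }
  # geminal 1-3
  for (b in seq_len(N)) {
    ns <- nb[[b]]
    if (length(ns) < 2L) next
    th <- hyb_angle(pi_full[b])
    for (x in seq_along(ns)) for (y in seq_along(ns)) {
      if (x >= y) next
      i <- ns[x]; j <- ns[y]
      r <- d13(blen[i, b], blen[j, b], th)
      lo[i, j] <- lo[j, i] <- r; hi[i, j] <- hi[j, i] <- r
    }
  }
  # 1-4 windows and double-bond stereo
  ez <- config$ez %||% character(0)
  bond_order_mat <- matrix(0L, N, N)
  for (k in seq_len(nrow(ex$bonds))) {
    bond_order_mat[ex$bonds[k, "i"], ex$bonds[k, "j"]] <- ex$bonds[k, "order"]
    bond_order_mat[ex$bonds[k, "j"], ex$bonds[k, "i"]] <- ex$bonds[k, "order"]
  }
  for (k in seq_len(nrow(ex$bonds))) {
    b <- ex$bonds[k, "i"]; c2 <- ex$bonds[k, "j"]; o <- ex$bonds[k, "order"]
    for (a in setdiff(nb[[b]], c2)) for (d in setdiff(nb[[c2]], b)) {
      if (a == d) next
      thB <- hyb_angle(pi_full[b]); thC <- hyb_angle(pi_full[c2])
      r_cis <- d14(blen[a, b], blen[b, c2], blen[c2, d], thB, thC, 0)
      r_trans <- d14(blen[a, b], blen[b, c2], blen[c2, d], thB, thC, 180)
      key <- paste(min(b, c2), max(b, c2), sep = "-")
      if (o == 2L && key %in% names(ez)) {
        # stereogenic double bond: reference substituents are the
        # lowest-index heavy (or only) neighbors on each side
        ra <- ref_substituent(nb, ex, b, c2)
        rd <- ref_substituent(nb, ex, c2, b)
        same_side <- (a == ra) == (d == rd)
        want_cis <- (ez[[key]] == "Z") == same_side
        r <- if (want_cis) r_cis else r_trans
        lo[a, d] <- lo[d, a] <- max(lo[a, d], r - 0.05)
        hi[a, d] <- hi[d, a] <- min(hi[a, d], r + 0.05)
      } else if (o == 2L || pi_full[b] + pi_full[c2] >= 2L) {
        # planar but not declared stereogenic: allow either side
        lo[a, d] <- lo[d, a] <- max(lo[a, d], min(r_cis, r_trans) - 0.05)
        hi[a, d] <- hi[d, a] <- min(hi[a, d], max(r_cis, r_trans) + 0.05)
      } else {
        lo[a, d] <- lo[d, a] <- max(lo[a, d], r_cis - 0.1)
        hi[a, d] <- hi[d, a] <- min(hi[a, d], r_trans + 0.1)
      }
    }
  }
  # triangle smoothing on upper bounds; pull up crossed lower bounds
  for (k in seq_len(N)) hi <- pmin(hi, outer(hi[, k], hi[k, ], `+`))
  lo <- pmin(lo, hi)
  list(lo = lo, hi = hi)
}

ref_substituent <- function(nb, ex, end, other) {
  subs <- setdiff(nb[[end]], other)
  heavy <- subs[ex$elements[subs] != "H"]
  if (length(heavy)) min(heavy) else min(subs)
}

# objective: squared-distance bound violations + chiral/planarity terms
dg_objective <- function(X, bounds, chiral, planar, w_chiral = 0.5) {
  N <- nrow(X)
  Dx <- as.matrix(stats::dist(X))
  D2 <- Dx^2
  over <- pmax(D2 - bounds$hi^2, 0)
  under <- pmax(bounds$lo^2 - D2, 0)
  f <- sum(over^2 + under^2) / 2
  for (ch in chiral) {
    v <- X[ch$atoms[2], ] - X[ch$atoms[1], ]
    w <- X[ch$atoms[3], ] - X[ch$atoms[1], ]
    u <- X[ch$atoms[4], ] - X[ch$atoms[1], ]
    V <- det(rbind(v, w, u))
    f <- f + w_chiral * (V - ch$target)^2
  }
  for (pl in planar) {
    v <- X[pl[2], ] - X[pl[1], ]
    w <- X[pl[3], ] - X[pl[1], ]
    u <- X[pl[4], ] - X[pl[1], ]
    V <- det(rbind(v, w, u))
    f <- f + w_chiral * V^2
  }
  f
}

dg_gradient <- function(X, bounds, chiral, planar, w_chiral = 0.5) {
  N <- nrow(X)
  G <- matrix(0, N, 3)
  Dx <- as.matrix(stats::dist(X))
  D2 <- Dx^2
  over <- pmax(D2 - bounds$hi^2, 0)
  under <- pmax(bounds$lo^2 - D2, 0)
  coef <- 2 * (over - under)          # d f / d (D2) per pair
  for (i in seq_len(N)) {
    diff <- sweep(-X, 2, -X[i, ])     # X[i,] - X[j,] rows
    G[i, ] <- G[i, ] + 2 * colSums(coef[i, ] * diff)
  }
  vol_terms <- c(lapply(chiral, function(ch) list(atoms = ch$atoms, target = ch$target)),
                 lapply(planar, function(pl) list(atoms = pl, target = 0)))
  for (tm in vol_terms) {
    a <- tm$atoms
    v <- X[a[2], ] - X[a[1], ]; w <- X[a[3], ] - X[a[1], ]; u <- X[a[4], ] - X[a[1], ]
    V <- det(rbind(v, w, u))
    c2 <- 2 * w_chiral * (V - tm$target)
    gv <- c2 * c(w[2] * u[3] - w[3] * u[2], w[3] * u[1] - w[1] * u[3],
                 w[1] * u[2] - w[2] * u[1])
    gw <- c2 * c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
                 u[1] * v[2] - u[2] * v[1])
    gu <- c2 * c(v[2] * w[3] - v[3] * w[2], v[3] * w[1] - v[1] * w[3],
                 v[1] * w[2] - v[2] * w[1])
    G[a[2], ] <- G[a[2], ] + gv
    G[a[3], ] <- G[a[3], ] + gw
    G[a[4], ] <- G[a[4], ] + gu
    G[a[1], ] <- G[a[1], ] - gv - gw - gu
  }
  G
}

#' Embed conformers for a configured structure (distance geometry)
#'
#' The default embedding provider for [select_stereoisomer()]: builds
#' distance bounds from the constitution and the requested configuration
#' (stereocenter parities as chiral-volume targets, double-bond geometry as
#' exact 1-4 distances), then refines random metric embeddings.
#'
#' @param g A `molgraph`.
#' @param config `list(parity = named c("<atom>" = +/-1), ez = named
#'   c("<i>-<j>" = "E"/"Z"))` as produced by [enumerate_stereoisomers()].
#' @param n_conf Number of conformers (random restarts).
#' @param seed Integer seed.
#' @return `list(conformers = list of N x 3 matrices (heavy atoms then
#'   hydrogens), energies = numeric, h_index, h_parent, n_heavy)`.
#' @export
embed_conformers <- function(g, config = list(), n_conf = 4L, seed = 1L) {
  ex <- expand_hydrogens(g)
  bounds <- build_bounds(ex, g, config)
  N <- length(ex$elements)
  # chiral targets: ordered substituents = sorted heavy neighbors then H
  chiral <- list()
  for (nm in names(config$parity %||% list())) {
    c0 <- as.integer(nm)
    ns <- sort(c(neighbors_of(g, c0),
                 ex$h_index[ex$h_parent == c0]))
    heavy <- ns[ns <= ex$n_heavy]; hs <- ns[ns > ex$n_heavy]
    ordered <- c(sort(heavy), hs)[1:4]
    lbar <- mean(vapply(ordered, function(x)
      .BOND_LEN(g$elements[c0], ex$elements[x], 1L), numeric(1)))
    chiral[[length(chiral) + 1L]] <-
      list(atoms = ordered, target = config$parity[[nm]] * 3.08 * lbar^3 *
             (8 / 16))          # half the ideal substituent-frame volume
  }
  planar <- list()
  pi_full <- pi_counts(g)
  for (a in seq_len(ex$n_heavy)) {
    if (pi_full[a] != 1L) next
    ns <- c(neighbors_of(g, a), ex$h_index[ex$h_parent == a])
    if (length(ns) == 3L) planar[[length(planar) + 1L]] <- c(a, ns)
  }
  set.seed(seed)
  confs <- list(); energies <- numeric(0)
  for (cf in seq_len(n_conf)) {
    Dm <- matrix(stats::runif(N * N), N, N)
    Dm <- (Dm + t(Dm)) / 2
    Ds <- bounds$lo + Dm * (bounds$hi - bounds$lo)
    diag(Ds) <- 0
    # classical MDS to 3D
    D2 <- Ds^2
    J <- diag(N) - matrix(1 / N, N, N)
    B <- -0.5 * J %*% D2 %*% J
    eg <- eigen(B, symmetric = TRUE)
    X <- eg$vectors[, 1:3] %*% diag(sqrt(pmax(eg$values[1:3], 1e-6)))
    X <- X + matrix(stats::rnorm(N * 3, 0, 0.05), N, 3)
    opt <- stats::optim(as.vector(X),
                        fn = function(p) dg_objective(matrix(p, N, 3), bounds, chiral, planar),
                        gr = function(p) as.vector(dg_gradient(matrix(p, N, 3), bounds, chiral, planar)),
                        method = "BFGS", control = list(maxit = 400, reltol = 1e-10))
    confs[[cf]] <- matrix(opt$par, N, 3)
    energies[cf] <- opt$value
  }
  list(conformers = confs, energies = energies, h_index = ex$h_index,
       h_parent = ex$h_parent, n_heavy = ex$n_heavy)
}
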