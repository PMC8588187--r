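# Relative stereochemistry from NOE distance classes: enumerate the
# stereoisomers of a constitution, embed conformers per configuration, and
# rank configurations by a penalty over NOE distance-class violations with
# r^-6 conformer averaging.

.NOE_RANGES <- list(strong = c(1.8, 2.5), medium = c(2.5, 4.0),
                    weak = c(4.0, 5.0))
.NOE_ABSENCE_CUTOFF <- 5.0

#' An NOE/ROE distance-class constraint between two protons
#'
#' Protons are referenced by their carrier heavy atoms; the distance is
#' measured between the closest pair of attached hydrogens. Distance classes
#' (Angstrom): strong 1.8-2.5, medium 2.5-4.0, weak 4.0-5.0; responses are
#' not expected beyond 5.0.
#'
#' @param u,v Carrier heavy-atom indices (each must bear at least one H).
#' @param cls `"strong"`, `"medium"` or `"weak"`.
#' @return A `noe_constraint`.
#' @export
noe_constraint <- function(u, v, cls = c("strong", "medium", "weak")) {
  cls <- match.arg(cls)
  if (u == v) stop("an NOE constraint needs two distinct proton carriers")
  structure(list(u = as.integer(u), v = as.integer(v), cls = cls),
            class = "noe_constraint")
}

# branch descriptor of neighbor u seen from center c: rooted canonical key
# of u's component after deleting c (ring neighbors stay distinguished by
# the root position)
branch_descriptor <- function(g, c0, u) {
  keep <- setdiff(seq_len(n_atoms(g)), c0)
  remap <- integer(n_atoms(g)); remap[keep] <- seq_along(keep)
  b <- g$bonds
  sel <- b[, "i"] != c0 & b[, "j"] != c0
  b <- b[sel, , drop = FALSE]
  if (nrow(b)) { b[, "i"] <- remap[b[, "i"]]; b[, "j"] <- remap[b[, "j"]] }
  sub <- molgraph(g$elements[keep], g$hydrogens[keep], b,
                  valences = g$valences[keep], validate = FALSE)
  comp <- igraph::components(as_igraph(sub))$membership
  inc <- which(comp == comp[remap[u]])
  remap2 <- integer(n_atoms(sub)); remap2[inc] <- seq_along(inc)
  b2 <- sub$bonds
  sel2 <- b2[, "i"] %in% inc & b2[, "j"] %in% inc
  b2 <- b2[sel2, , drop = FALSE]
  if (nrow(b2)) { b2[, "i"] <- remap2[b2[, "i"]]; b2[, "j"] <- remap2[b2[, "j"]] }
  comp_g <- molgraph(sub$elements[inc], sub$hydrogens[inc], b2,
                     valences = sub$valences[inc], validate = FALSE)
  canonical_key_rooted(comp_g, remap2[remap[u]])
}

#' Detect tetrahedral stereocenters
#'
#' An sp3 carbon with at most one hydrogen whose substituent branches
#' (components after removing the center, rooted at each neighbor) are
#' pairwise distinct. Configuration-dependent ("para") stereocenters are not
#' detected.
#'
#' @param g A `molgraph`.
#' @return Integer vector of atom indices.
#' @export
find_stereocenters <- function(g) {
  p <- pi_counts(g)
  out <- integer(0)
  for (a in seq_len(n_atoms(g))) {
    if (g$elements[a] != "C" || p[a] != 0L || g$hydrogens[a] > 1L) next
    ns <- neighbors_of(g, a)
    if (length(ns) + g$hydrogens[a] != 4L) next
    desc <- vapply(ns, function(u) branch_descriptor(g, a, u), character(1))
    if (anyDuplicated(desc)) next
    out <- c(out, a)
  }
  out
}

#' Detect stereogenic double bonds
#'
#' C=C double bonds not in a ring whose both ends carry two distinguishable
#' substituents (counting H).
#'
#' @param g A `molgraph`.
#' @return Matrix with columns i, j (one row per stereogenic bond).
#' @export
find_stereo_double_bonds <- function(g) {
  out <- matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("i", "j")))
  ig <- as_igraph(g)
  for (k in seq_len(nrow(g$bonds))) {
    if (g$bonds[k, "order"] != 2L) next
    i <- g$bonds[k, "i"]; j <- g$bonds[k, "j"]
    if (g$elements[i] != "C" || g$elements[j] != "C") next
    ig2 <- igraph::delete_edges(ig, igraph::get_edge_ids(ig, c(i, j)))
    if (igraph::distances(ig2, i, j) < Inf) next      # in a ring
    end_ok <- function(e, other) {
      subs <- setdiff(neighbors_of(g, e), other)
      nH <- g$hydrogens[e]
      if (length(subs) + nH != 2L) return(FALSE)
      if (nH == 2L) return(FALSE)
      if (nH == 1L) return(TRUE)                      # H vs heavy: distinct
      branch_descriptor(g, e, subs[1]) != branch_descriptor(g, e, subs[2])
    }
    if (end_ok(i, j) && end_ok(j, i))
      out <- rbind(out, c(i, j))
  }
  out
}

# full automorphism list of the (element, H, bond-order)-colored graph,
# generated from BLISS generators; capped
automorphism_list <- function(g, cap = 20000L) {
  tr <- canon_transform(g)
  gens <- igraph::automorphism_group(tr$graph, colors = tr$colors)
  n <- tr$n_atoms
  gens <- lapply(gens, function(p) as.integer(p[seq_len(n)]))
  id <- seq_len(n)
  elems <- list(id)
  keys <- paste(id, collapse = ",")
  frontier <- list(id)
  while (length(frontier)) {
    nxt <- list()
    for (e in frontier) for (gp in gens) {
      comp <- gp[e]
      k <- paste(comp, collapse = ",")
      if (!k %in% keys) {
        keys <- c(keys, k)
        elems[[length(elems) + 1L]] <- comp
        nxt[[length(nxt) + 1L]] <- comp
        if (length(elems) >= cap) return(elems)
      }
    }
    frontier <- nxt
  }
  elems
}

perm_sign <- function(p) {
  visited <- logical(length(p)); s <- 1L
  for (i in seq_along(p)) {
    if (visited[i]) next
    j <- i; len <- 0L
    while (!visited[j]) { visited[j] <- TRUE; j <- p[j]; len <- len + 1L }
    if (len %% 2L == 0L) s <- -s
  }
  s
}

config_string <- function(cfg) {
  paste(c(sprintf("%s:%s", names(cfg$parity), ifelse(cfg$parity > 0, "+", "-")),
          sprintf("%s:%s", names(cfg$ez), cfg$ez)), collapse = ";")
}

#' Enumerate relative stereoisomer configurations
#'
#' All parity combinations over the detected stereocenters times E/Z states
#' over stereogenic double bonds, reduced modulo the constitution's
#' symmetry group (an automorphism permutes the centers and multiplies each
#' parity by the sign of the induced substituent permutation) and the global
#' mirror (all parities flipped): only relative stereochemistry is retained.
#'
#' @param g A `molgraph`.
#' @param cap Cap on raw configurations before reduction (default 2^14).
#' @return List of configurations `list(parity, ez)` (named vectors), one
#'   representative per equivalence class; attribute `n_raw` gives the
#'   pre-reduction count.
#' @export
enumerate_stereoisomers <- function(g, cap = 2^14) {
  centers <- find_stereocenters(g)
  dbl <- find_stereo_double_bonds(g)
  k <- length(centers); kb <- nrow(dbl)
  n_raw <- 2^(k + kb)
  if (n_raw > cap)
    stop(sprintf("%d stereo elements give %g configurations, above the cap %g",
                 k + kb, n_raw, cap))
  if (k + kb == 0L)
    return(structure(list(list(parity = integer(0) , ez = character(0))),
                     n_raw = 1))
  auts <- automorphism_list(g)
  # precompute per automorphism: center mapping + sign, bond mapping + flip
  center_names <- as.character(centers)
  bond_names <- if (kb) sprintf("%d-%d", pmin(dbl[, 1], dbl[, 2]),
                                pmax(dbl[, 1], dbl[, 2])) else character(0)
  actions <- lapply(auts, function(s) {
    cmap <- match(s[centers], centers)
    if (anyNA(cmap)) return(NULL)
    signs <- vapply(seq_len(k), function(ci) {
      c0 <- centers[ci]
      ns <- sort(neighbors_of(g, c0))
      image_sorted <- sort(s[ns])
      perm_sign(match(s[ns], image_sorted))
    }, integer(1))
    bmap <- integer(kb); flips <- logical(kb)
    if (kb) {
      nbl <- lapply(seq_len(n_atoms(g)), function(a) neighbors_of(g, a))
      exl <- list(elements = g$elements)
      for (bi in seq_len(kb)) {
        i <- dbl[bi, 1]; j <- dbl[bi, 2]
        si <- s[i]; sj <- s[j]
        key <- sprintf("%d-%d", min(si, sj), max(si, sj))
        tgt <- match(key, bond_names)
        if (is.na(tgt)) return(NULL)
        bmap[bi] <- tgt
        ri <- ref_sub_heavy(g, i, j); rj <- ref_sub_heavy(g, j, i)
        ri2 <- ref_sub_heavy(g, si, sj); rj2 <- ref_sub_heavy(g, sj, si)
        # flip when exactly one end's reference substituent maps off-reference
        flips[bi] <- xor(!identical(s[ri], ri2) && !is.na(ri) && !is.na(ri2),
                         !identical(s[rj], rj2) && !is.na(rj) && !is.na(rj2))
      }
    }
    list(cmap = cmap, signs = signs, bmap = bmap, flips = flips)
  })
  actions <- Filter(Negate(is.null), actions)
  combos <- expand.grid(rep(list(c(-1L, 1L)), k + 0L),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ez_combos <- expand.grid(rep(list(c("E", "Z")), kb),
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (k == 0L) combos <- data.frame(row.names = 1)
  if (kb == 0L) ez_combos <- data.frame(row.names = 1)
  reps <- list()
  seen <- character(0)
  for (ri in seq_len(max(nrow(combos), 1L))) {
    for (rj in seq_len(max(nrow(ez_combos), 1L))) {
      par <- if (k) as.integer(combos[ri, ]) else integer(0)
      ez <- if (kb) as.character(unlist(ez_combos[rj, ])) else character(0)
      # canonical representative over group x mirror
      best <- NULL
      for (ac in actions) for (mirror in c(1L, -1L)) {
        p2 <- integer(k); e2 <- character(kb)
        if (k) p2[ac$cmap] <- par * ac$signs * mirror
        if (kb) {
          e2[ac$bmap] <- ez
          e2[ac$bmap[ac$flips]] <- ifelse(ez[ac$flips] == "E", "Z", "E")
        }
        key <- paste(c(p2, e2), collapse = ",")
        if (is.null(best) || key < best) best <- key
      }
      if (!best %in% seen) {
        seen <- c(seen, best)
        names(par) <- center_names
        names(ez) <- bond_names
        reps[[length(reps) + 1L]] <- list(parity = par, ez = ez)
      }
    }
  }
  structure(reps, n_raw = n_raw)
}

ref_sub_heavy <- function(g, end, other) {
  subs <- setdiff(neighbors_of(g, end), other)
  heavy <- subs[g$elements[subs] != "H"]
  if (length(heavy)) min(heavy) else if (length(subs)) min(subs) else NA_integer_
}

#' NOE penalty of an embedded stereoisomer candidate
#'
#' Per constraint, the effective proton-proton distance is the r^-6
#' conformer average `(mean r^-6)^(-1/6)` of the closest attached-H pair;
#' the penalty is zero inside the class range and the squared distance to
#' the nearest bound outside; the total is the sum over constraints.
#'
#' @param candidate Embedding result from [embed_conformers()] (or any
#'   provider honoring its contract).
#' @param constraints List of [noe_constraint()].
#' @return Non-negative penalty.
#' @export
noe_penalty <- function(candidate, constraints) {
  if (!length(constraints)) return(0)
  total <- 0
  for (cn in constraints) {
    hu <- candidate$h_index[candidate$h_parent == cn$u]
    hv <- candidate$h_index[candidate$h_parent == cn$v]
    if (!length(hu) || !length(hv))
      stop(sprintf("atom %d or %d carries no hydrogen", cn$u, cn$v))
    r6 <- vapply(candidate$conformers, function(X) {
      d <- Inf
      for (a in hu) for (b in hv)
        d <- min(d, sqrt(sum((X[a, ] - X[b, ])^2)))
      d^(-6)
    }, numeric(1))
    r_eff <- mean(r6)^(-1 / 6)
    rng <- .NOE_RANGES[[cn$cls]]
    if (r_eff < rng[1]) total <- total + (rng[1] - r_eff)^2
    else if (r_eff > rng[2]) total <- total + (r_eff - rng[2])^2
  }
  total
}

#' Select the relative configuration best satisfying NOE constraints
#'
#' Enumerates stereoisomers, embeds conformers per configuration with the
#' supplied provider, scores each by [noe_penalty()], and returns candidates
#' sorted by (penalty, energy proxy). A configuration whose embedding fails
#' is flagged, not dropped. With no constraints the order is by energy alone;
#' when no configuration fits, the minimum-penalty one is still returned
#' first with a warning.
#'
#' @param g A `molgraph`.
#' @param constraints List of [noe_constraint()].
#' @param embedder Embedding provider with the [embed_conformers()] contract.
#' @param n_conf Conformers per configuration.
#' @param seed Integer seed (passed to the embedder).
#' @return List of `list(config, label, penalty, energy, rank, failed)`,
#'   best first.
#' @export
select_stereoisomer <- function(g, constraints = list(),
                                embedder = embed_conformers,
                                n_conf = 4L, seed = 1L) {
  configs <- enumerate_stereoisomers(g)
  out <- list()
  for (cfg in configs) {
    emb <- tryCatch(embedder(g, cfg, n_conf = n_conf, seed = seed),
                    error = function(e) e)
    if (inherits(emb, "error")) {
      out[[length(out) + 1L]] <- list(config = cfg, label = config_string(cfg),
                                      penalty = Inf, energy = Inf,
                                      rank = NA_integer_, failed = TRUE)
      next
    }
    pen <- noe_penalty(emb, constraints)
    out[[length(out) + 1L]] <- list(config = cfg, label = config_string(cfg),
                                    penalty = pen,
                                    energy = min(emb$energies),
                                    rank = NA_integer_, failed = FALSE)
  }
  ord <- order(vapply(out, `[[`, numeric(1), "penalty"),
               vapply(out, `[[`, numeric(1), "energy"))
  out <- out[ord]
  for (i in seq_along(out)) out[[i]]$rank <- i
  if (length(constraints) && length(out) &&
      is.finite(out[[1]]$penalty) && out[[1]]$penalty > 0)
    warning("no configuration satisfies all NOE constraints; returning the least-violating one")
  out
}

#' Write a stereo ranking report as CSV
#' @param candidates Result of [select_stereoisomer()].
#' @param path Output CSV path.
#' @return The summary data frame, invisibly.
#' @export
write_stereo_report <- function(candidates, path) {
  df <- data.frame(rank = vapply(candidates, `[[`, numeric(1), "rank"),
                   configuration = vapply(candidates, `[[`, character(1), "label"),
                   penalty = vapply(candidates, `[[`, numeric(1), "penalty"),
                   energy = vapply(candidates, `[[`, numeric(1), "energy"),
                   failed = vapply(candidates, `[[`, logical(1), "failed"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Read NOE constraints from CSV
#'
#' Columns `h_a,h_b,class`: proton shifts are resolved to carrier carbons of
#' `g` through the package's proton-shift map of the assigned carbon shifts.
#'
#' @param path CSV path.
#' @param g Assigned `molgraph` used for resolution.
#' @param tol Proton-shift matching tolerance (ppm).
#' @return List of [noe_constraint()].
#' @export
read_noe_csv <- function(path, g, tol = 0.02) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  prot <- which(g$elements == "C" & g$hydrogens > 0L & !is.na(g$shifts))
  hs <- h_shift_of(g$shifts[prot])
  resolve <- function(x) {
    i <- which.min(abs(hs - x))
    if (abs(hs[i] - x) > tol) stop(sprintf("no proton within %.3g ppm of %.3f", tol, x))
    prot[i]
  }
  lapply(seq_len(nrow(df)), function(i)
    noe_constraint(resolve(df$h_a[i]), resolve(df$h_b[i]), df$class[i]))
}
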