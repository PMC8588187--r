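# Fragment mode: build user fragment databases from assigned structures,
# search them against an experimental 13C spectrum with tolerance E, and
# embed found fragments into MCDs as fixed bonds to shrink the generation
# space.  The fragment-cutting rule is sphere (radius 1-3) plus
# ring-with-first-shell extraction, chosen so fragments stay compatible with
# the environment-code predictor.

#' Fragment search configuration
#'
#' @param E Shift-matching tolerance in ppm (default 1.5).
#' @param min_fragments_per_mcd Minimum fragments embedded per MCD variant
#'   (default 1; raise to e.g. 3 to absorb more skeletal atoms).
#' @param max_found Cap on found fragments returned by a search.
#' @param max_assignments Per-fragment cap on enumerated assignments.
#' @param max_mcds Cap on MCD variants produced by embedding.
#' @return A `fragment_config` list.
#' @export
fragment_config <- function(E = 1.5, min_fragments_per_mcd = 1L,
                            max_found = 200L, max_assignments = 1e5,
                            max_mcds = 50L) {
  stopifnot(E > 0)
  structure(list(E = E, min_fragments_per_mcd = as.integer(min_fragments_per_mcd),
                 max_found = as.integer(max_found),
                 max_assignments = max_assignments,
                 max_mcds = as.integer(max_mcds)),
            class = "fragment_config")
}

induced_fragment <- function(g, atoms) {
  atoms <- sort(unique(atoms))
  remap <- integer(n_atoms(g)); remap[atoms] <- seq_along(atoms)
  b <- g$bonds
  sel <- b[, "i"] %in% atoms & b[, "j"] %in% atoms
  b <- b[sel, , drop = FALSE]
  if (nrow(b)) { b[, "i"] <- remap[b[, "i"]]; b[, "j"] <- remap[b[, "j"]] }
  molgraph(g$elements[atoms], g$hydrogens[atoms], b, shifts = g$shifts[atoms],
           valences = g$valences[atoms], validate = FALSE)
}

# small-ring perception: for each edge, the shortest cycle through it
find_rings <- function(g, max_size = 8L) {
  rings <- list()
  seen <- character(0)
  ig <- as_igraph(g)
  for (k in seq_len(nrow(g$bonds))) {
    i <- g$bonds[k, "i"]; j <- g$bonds[k, "j"]
    ig2 <- igraph::delete_edges(ig, igraph::get_edge_ids(ig, c(i, j)))
    sp <- suppressWarnings(igraph::shortest_paths(ig2, i, j)$vpath[[1]])
    if (length(sp) < 2L || length(sp) > max_size) next
    ring <- sort(as.integer(sp))
    key <- paste(ring, collapse = ",")
    if (!key %in% seen) { seen <- c(seen, key); rings[[length(rings) + 1L]] <- ring }
  }
  rings
}

canonical_atom_rank <- function(g) {
  tr <- canon_transform(g)
  perm <- igraph::canonical_permutation(tr$graph, colors = tr$colors)$labeling
  rank(perm[seq_len(tr$n_atoms)])
}

#' Cut a user fragment database from assigned structures
#'
#' Emits, per structure, all atom-centered spheres of radius 1-3 and all
#' small rings with their first shell, capped at `size_cap` heavy atoms, with
#' at least 2 heavy atoms and complete carbon shift assignments. Duplicates
#' (by canonical key) are merged with per-atom shift averaging in canonical
#' coordinates.
#'
#' @param structures List of assigned `molgraph`, or an SDF path.
#' @param size_cap Maximum fragment heavy-atom count (default 8).
#' @return List of fragment records `list(graph, n_merged, source)`.
#' @export
build_user_fragment_db <- function(structures, size_cap = 8L) {
  if (is.character(structures)) {
    recs <- read_sdf(structures)
    structures <- lapply(recs, `[[`, "graph")
  }
  frags <- list()
  index <- new.env(parent = emptyenv())
  add_frag <- function(g, atoms, src) {
    atoms <- sort(unique(atoms))
    if (length(atoms) < 2L || length(atoms) > size_cap) return(invisible())
    fr <- induced_fragment(g, atoms)
    if (any(fr$elements == "C" & is.na(fr$shifts)))
      stop(sprintf("structure %s has an unassigned carbon in a fragment", src))
    key <- canonical_key(fr)
    rk <- canonical_atom_rank(fr)
    shifts_canon <- fr$shifts[order(rk)]
    if (exists(key, envir = index, inherits = FALSE)) {
      i <- get(key, envir = index)
      old <- frags[[i]]
      m <- old$n_merged
      delta <- shifts_canon - old$shifts_canon
      canon_mean <- old$shifts_canon + delta / (m + 1)
      old$M2_canon <- old$M2_canon + delta * (shifts_canon - canon_mean)
      old$shifts_canon <- canon_mean
      old$n_merged <- m + 1L
      rk_old <- canonical_atom_rank(old$graph)
      old$graph$shifts <- canon_mean[rk_old]
      old$graph$shift_sd <- sqrt(old$M2_canon / m)[rk_old]
      frags[[i]] <<- old
    } else {
      fr$shift_sd <- rep(0, n_atoms(fr))
      frags[[length(frags) + 1L]] <<- list(graph = fr, shifts_canon = shifts_canon,
                                           M2_canon = rep(0, length(shifts_canon)),
                                           n_merged = 1L, source = src)
      assign(key, length(frags), envir = index)
    }
    invisible()
  }
  for (si in seq_along(structures)) {
    g <- structures[[si]]
    D <- skeleton_distances(g)
    for (a in seq_len(n_atoms(g)))
      for (r in 1:3)
        add_frag(g, which(D[a, ] <= r), si)
    for (ring in find_rings(g)) {
      shell <- unique(unlist(lapply(ring, function(a) neighbors_of(g, a))))
      add_frag(g, ring, si)
      add_frag(g, union(ring, shell), si)
    }
  }
  frags
}

# open attachment points: valence minus attached H minus internal bond orders
fragment_open_valences <- function(fr) {
  fr$valences - fr$hydrogens - bond_order_sums(fr)
}

#' Search fragments against an observed 13C spectrum
#'
#' A fragment is found when an injective carbon-to-peak mapping exists with
#' per-carbon shift difference at most `E`, compatible multiplicities, and no
#' resolved 2D correlation between mapped peaks demanding a shorter distance
#' than the fragment's internal topology allows. All assignments are
#' enumerated per fragment up to a cap (a fragment whose assignment space
#' exceeds the cap is skipped and logged).
#'
#' @param db Fragment list from [build_user_fragment_db()].
#' @param observed 13C peak data frame (shift, multiplicity, degeneracy).
#' @param peak_constraints Optional peak-level distance constraints, e.g.
#'   from [mcd_peak_constraints()]: a mapped assignment is rejected when two
#'   mapped peaks demand a shorter distance than the fragment's internal
#'   topology can ever provide (internal distance below `dlo`; supergraph
#'   paths can only shorten distances, so an internal distance above `dhi`
#'   is not a contradiction).
#' @param cfg A [fragment_config()].
#' @return List of found records `list(fragment_id, graph, assignments,
#'   best_maxdev)`; attribute `skipped` lists capped fragment ids.
#' @export
search_fragments <- function(db, observed, peak_constraints = NULL,
                             cfg = fragment_config()) {
  if (!nrow(observed)) stop("observed peak list is empty")
  found <- list()
  skipped <- integer(0)
  cap_per_peak <- if (!is.null(observed$degeneracy)) observed$degeneracy else
    rep(1L, nrow(observed))
  for (fi in seq_along(db)) {
    fr <- db[[fi]]$graph
    carbons <- which(fr$elements == "C")
    if (!length(carbons)) next
    Dfr <- skeleton_distances(fr)
    mult <- c("C", "CH", "CH2", "CH3")[pmin(fr$hydrogens[carbons], 3L) + 1L]
    # candidate peaks per fragment carbon; a merged fragment's per-atom
    # spread (sd across merged occurrences) widens the tolerance, since its
    # stored mean averages over distinct parent contexts
    sd_a <- if (!is.null(fr$shift_sd)) fr$shift_sd else rep(0, n_atoms(fr))
    cands <- lapply(seq_along(carbons), function(k) {
      tol <- cfg$E + sd_a[carbons[k]]
      ok <- abs(observed$shift - fr$shifts[carbons[k]]) <= tol
      if (!is.null(observed$multiplicity))
        ok <- ok & (is.na(observed$multiplicity) | observed$multiplicity == mult[k])
      which(ok)
    })
    if (any(!vapply(cands, length, integer(1)))) next
    space <- prod(vapply(cands, length, integer(1)))
    if (space > cfg$max_assignments) { skipped <- c(skipped, fi); next }
    used <- integer(nrow(observed))
    assigns <- list()
    rec <- function(k, acc) {
      if (length(assigns) >= cfg$max_assignments) return(invisible())
      if (k > length(carbons)) {
        assigns[[length(assigns) + 1L]] <<- acc
        return(invisible())
      }
      for (pk in cands[[k]]) {
        if (used[pk] >= cap_per_peak[pk]) next
        used[pk] <<- used[pk] + 1L
        rec(k + 1L, c(acc, pk))
        used[pk] <<- used[pk] - 1L
      }
      invisible()
    }
    rec(1L, integer(0))
    if (length(peak_constraints) && length(assigns)) {
      ok <- vapply(assigns, function(am) {
        for (pc in peak_constraints) {
          ku <- which(am == pc$u); kv <- which(am == pc$v)
          if (length(ku) && length(kv) &&
              min(Dfr[carbons[ku], carbons[kv]]) < pc$dlo) return(FALSE)
        }
        TRUE
      }, logical(1))
      assigns <- assigns[ok]
    }
    if (!length(assigns)) next
    best <- min(vapply(assigns, function(am)
      max(abs(observed$shift[am] - fr$shifts[carbons])), numeric(1)))
    found[[length(found) + 1L]] <- list(fragment_id = fi, graph = fr,
                                        carbons = carbons,
                                        assignments = assigns,
                                        best_maxdev = best)
    if (length(found) >= cfg$max_found) break
  }
  structure(found, skipped = skipped)
}

#' Peak-level distance constraints of an MCD
#'
#' Projects the MCD's singleton atom-pair constraints onto 13C peak indices
#' for use by [search_fragments()].
#'
#' @param mcd An `mcd`.
#' @return List of `list(u, v, dlo, dhi)` on peak indices.
#' @export
mcd_peak_constraints <- function(mcd) {
  out <- list()
  for (cn in mcd$constraints) {
    if (length(cn$us) != 1L || length(cn$vs) != 1L) next
    pu <- mcd$atoms$peak[cn$us]; pv <- mcd$atoms$peak[cn$vs]
    if (is.na(pu) || is.na(pv)) next
    out[[length(out) + 1L]] <- list(u = pu, v = pv, dlo = cn$dlo, dhi = cn$dhi)
  }
  out
}

#' Embed found fragments into an MCD
#'
#' Each output MCD fixes the internal bonds of one compatible,
#' non-atom-overlapping combination of found fragments (combination size at
#' least `min_fragments_per_mcd`), so the generator only explores the
#' remaining skeleton. Compatibility requires consistent peak assignments and
#' a constraint set that still passes the stage-1/2 quick check. Combinations
#' are ranked by skeletal coverage and capped.
#'
#' @param mcd The base `mcd`.
#' @param found Result of [search_fragments()].
#' @param cfg A [fragment_config()].
#' @return List of MCD variants (possibly empty, with a warning, when no
#'   combination reaches the minimum count).
#' @export
embed_fragments <- function(mcd, found, cfg = fragment_config()) {
  if (!length(found)) {
    warning("no found fragments to embed")
    return(list())
  }
  # one embedding option per (fragment, assignment): map fragment atoms to
  # concrete MCD atom ids
  options_list <- list()
  for (fd in found) {
    fr <- fd$graph
    for (am in fd$assignments) {
      claimed <- integer(0)
      amap <- integer(n_atoms(fr))       # fragment atom -> mcd atom
      ok <- TRUE
      hetero_slots <- setdiff(which(mcd$atoms$element != "C"), integer(0))
      for (k in seq_along(fd$carbons)) {
        slots <- setdiff(peak_atoms(mcd, am[k]), claimed)
        if (!length(slots)) { ok <- FALSE; break }
        amap[fd$carbons[k]] <- slots[1]
        claimed <- c(claimed, slots[1])
      }
      if (!ok) next
      for (a in setdiff(seq_len(n_atoms(fr)), fd$carbons)) {
        slots <- setdiff(which(mcd$atoms$element == fr$elements[a]), claimed)
        if (!length(slots)) { ok <- FALSE; break }
        amap[a] <- slots[1]
        claimed <- c(claimed, slots[1])
      }
      if (!ok) next
      b <- fr$bonds
      fb <- cbind(i = amap[b[, "i"]], j = amap[b[, "j"]], order = b[, "order"])
      options_list[[length(options_list) + 1L]] <-
        list(fragment_id = fd$fragment_id, atoms = claimed, bonds = fb)
    }
  }
  if (!length(options_list)) {
    warning("no embeddable fragment assignment")
    return(list())
  }
  # greedy combination enumeration by coverage
  ord <- order(-vapply(options_list, function(o) length(o$atoms), integer(1)))
  options_list <- options_list[ord]
  combos <- list()
  build <- function(start, cur, atoms_used) {
    if (length(combos) >= 4L * cfg$max_mcds) return(invisible())
    if (length(cur))
      combos[[length(combos) + 1L]] <<- cur
    for (i in seq(from = start, length.out = max(0L, length(options_list) - start + 1L))) {
      o <- options_list[[i]]
      if (length(intersect(o$atoms, atoms_used))) next
      build(i + 1L, c(cur, list(o)), c(atoms_used, o$atoms))
    }
    invisible()
  }
  build(1L, list(), integer(0))
  combos <- Filter(function(cb) length(cb) >= cfg$min_fragments_per_mcd, combos)
  if (!length(combos)) {
    warning(sprintf("no fragment combination reaches min_fragments_per_mcd = %d",
                    cfg$min_fragments_per_mcd))
    return(list())
  }
  cov <- vapply(combos, function(cb) sum(vapply(cb, function(o)
    length(o$atoms), integer(1))), integer(1))
  combos <- combos[order(-cov)]
  out <- list()
  for (cb in combos) {
    fb <- do.call(rbind, lapply(cb, `[[`, "bonds"))
    fb <- unique(fb)
    m2 <- mcd
    m2$fixed_bonds <- rbind(mcd$fixed_bonds, fb)
    if (!quick_consistency(m2)$feasible) next
    out[[length(out) + 1L]] <- m2
    if (length(out) >= cfg$max_mcds) break
  }
  out
}
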