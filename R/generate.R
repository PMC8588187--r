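# Structure generation: exhaustive enumeration of all non-isomorphic
# molecular graphs consistent with an MCD, and fuzzy structure generation
# (FSG) over suspect-correlation subsets.

#' Generation options
#' @param max_structures Cap on structures returned (per generation run).
#' @param node_budget Search-node budget (determinism-friendly stand-in for a
#'   wall-clock limit).
#' @param explore_alt_valences Also explore pentavalent nitrogen.
#' @return A `gen_options` list.
#' @export
gen_options <- function(max_structures = 50000L, node_budget = 5e8,
                        explore_alt_valences = FALSE) {
  stopifnot(max_structures > 0, node_budget > 0)
  structure(list(max_structures = as.integer(max_structures),
                 node_budget = node_budget,
                 explore_alt_valences = isTRUE(explore_alt_valences)),
            class = "gen_options")
}

#' Fuzzy structure generation options
#'
#' `m` is the maximum number of connectivities treated as non-standard and
#' `a` the elongation in bonds applied to each selected connectivity; by
#' convention `a = 16` means the selected connectivities are deleted instead
#' of elongated.
#'
#' @param m Maximum subset size of connectivities to relax.
#' @param a Elongation in bonds; 16 = delete.
#' @param restrict_to_suspicious Relax only the suspicious set found by
#'   [check_consistency()] when detection succeeded (else all connectivities).
#' @param auto Escalate m = 1, 2, ... until a non-empty result (used by the
#'   pipeline driver).
#' @return An `fsg_options` list.
#' @export
fsg_options <- function(m = 1L, a = 1L, restrict_to_suspicious = TRUE,
                        auto = FALSE) {
  stopifnot(m >= 0, a >= 1)
  structure(list(m = as.integer(m), a = as.integer(a),
                 restrict_to_suspicious = isTRUE(restrict_to_suspicious),
                 auto = isTRUE(auto)),
            class = "fsg_options")
}

# atom ordering heuristic: constrained atoms first, unconstrained heteroatoms
# last; returns the permutation old -> new position
generation_order <- function(mcd) {
  n <- nrow(mcd$atoms)
  score <- numeric(n)
  for (cn in mcd$constraints) {
    ids <- c(cn$us, cn$vs)
    score[ids] <- score[ids] + 1 / length(ids)
  }
  score[mcd$atoms$element != "C"] <- score[mcd$atoms$element != "C"] - 100
  ord <- order(-score, seq_len(n))   # ord[k] = old index at new position k
  perm <- integer(n); perm[ord] <- seq_len(n)
  perm
}

mcd_to_cpp_inputs <- function(mcd, perm) {
  at <- mcd$atoms
  n <- nrow(at)
  inv <- integer(n); inv[perm] <- seq_len(n)
  at2 <- at[inv, , drop = FALSE]
  valence <- as.integer(at2$valence)
  h_fixed <- ifelse(is.na(at2$hydrogens), -1L, as.integer(at2$hydrogens))
  hetero <- as.integer(at2$element != "C")
  pi_mask <- as.integer(at2$hyb_mask)
  hflag <- as.integer(at2$hetero_flag)
  min_ord <- matrix(0L, n, n); max_ord <- matrix(3L, n, n); diag(max_ord) <- 0L
  # hetero-forbidden carbons cannot bond heteroatoms
  fbc <- which(hflag == 1L)
  het <- which(hetero == 1L)
  if (length(fbc) && length(het)) {
    max_ord[fbc, het] <- 0L; max_ord[het, fbc] <- 0L
  }
  cons <- list()
  for (cn in mcd$constraints) {
    us <- perm[cn$us]; vs <- perm[cn$vs]
    if (length(us) == 1L && length(vs) == 1L) {
      if (cn$dlo >= 2L) { max_ord[us, vs] <- 0L; max_ord[vs, us] <- 0L }
      if (cn$dlo == 1L && cn$dhi == 1L) {
        min_ord[us, vs] <- max(min_ord[us, vs], 1L)
        min_ord[vs, us] <- min_ord[us, vs]
      }
    }
    cons[[length(cons) + 1L]] <- list(us = as.integer(us), vs = as.integer(vs),
                                      dlo = cn$dlo, dhi = cn$dhi)
  }
  for (k in seq_len(nrow(mcd$fixed_bonds))) {
    i <- perm[mcd$fixed_bonds[k, "i"]]; j <- perm[mcd$fixed_bonds[k, "j"]]
    o <- mcd$fixed_bonds[k, "order"]
    min_ord[i, j] <- min_ord[j, i] <- o
    max_ord[i, j] <- max_ord[j, i] <- o
  }
  # interchangeable-atom groups for symmetry breaking: identical element,
  # valence, fixed-H, properties, peak identity and constraint membership,
  # and not incident to any user-fixed bond
  mem <- vapply(seq_len(n), function(x_new) {
    x_old <- inv[x_new]
    ids <- which(vapply(mcd$constraints, function(cn)
      x_old %in% cn$us || x_old %in% cn$vs, logical(1)))
    paste(ids, collapse = "+")
  }, character(1))
  fixed_atoms <- perm[unique(as.integer(mcd$fixed_bonds[, c("i", "j")]))]
  key <- paste(at2$element, valence, h_fixed, pi_mask, hflag,
               ifelse(is.na(at2$peak), "-", at2$peak), mem)
  key[seq_len(n) %in% fixed_atoms] <- paste0("fixed", seq_len(n))[seq_len(n) %in% fixed_atoms]
  prev_same <- rep(-1L, n)
  last_of <- list()
  for (x in seq_len(n)) {
    k <- key[x]
    if (!is.null(last_of[[k]])) prev_same[x] <- last_of[[k]] - 1L  # 0-based
    last_of[[k]] <- x
  }
  list(valence = valence, h_fixed = h_fixed, free_h = mcd$free_h,
       hetero = hetero, pi_mask = pi_mask, hflag = hflag,
       prev_same = prev_same,
       min_ord = min_ord, max_ord = max_ord, cons = cons)
}

run_enumeration <- function(mcd, options, valence_override = NULL) {
  perm <- generation_order(mcd)
  n <- nrow(mcd$atoms)
  inp <- mcd_to_cpp_inputs(mcd, perm)
  if (!is.null(valence_override)) {
    inv <- integer(n); inv[perm] <- seq_len(n)
    inp$valence <- as.integer(valence_override[inv])
    inp$prev_same <- rep(-1L, n)   # overridden valences break interchangeability
  }
  res <- .cpp_enumerate(inp$valence, inp$h_fixed, inp$free_h, inp$hetero,
                        inp$pi_mask, inp$hflag, inp$prev_same,
                        inp$min_ord, inp$max_ord,
                        inp$cons, options$max_structures, options$node_budget)
  inv <- integer(n); inv[perm] <- seq_len(n)
  graphs <- vector("list", length(res$bonds))
  at <- mcd$atoms
  for (k in seq_along(res$bonds)) {
    b <- res$bonds[[k]]
    # map atom indices back to MCD order
    if (nrow(b)) {
      b[, 1] <- inv[b[, 1]]; b[, 2] <- inv[b[, 2]]
    }
    colnames(b) <- c("i", "j", "order")
    hyd <- res$hydrogens[[k]][perm]
    val <- if (is.null(valence_override)) at$valence else valence_override
    graphs[[k]] <- molgraph(at$element, hyd, b, shifts = at$shift,
                            valences = val, validate = FALSE)
  }
  attr(graphs, "complete") <- res$complete
  attr(graphs, "nodes") <- res$nodes
  graphs
}

dedup_graphs <- function(graphs) {
  if (!length(graphs)) return(graphs)
  keys <- vapply(graphs, canonical_key, character(1))
  keep <- !duplicated(keys)
  out <- graphs[keep]
  attr(out, "keys") <- keys[keep]
  out
}

#' Generate all structures consistent with an MCD
#'
#' Exhaustive and duplicate-free up to isomorphism: every returned graph
#' satisfies the valence, hydrogen-count, hybridization, hetero-flag and
#' connectivity-distance constraints of the MCD, every satisfying graph
#' appears, and one representative per isomorphism class is returned (atoms
#' in MCD order, so per-atom shifts carry over).
#'
#' @param mcd An `mcd`.
#' @param options A [gen_options()] list.
#' @return List of `molgraph` with attributes `complete` (FALSE when a cap or
#'   budget truncated the search), `nodes`, and `keys` (canonical keys).
#' @export
generate <- function(mcd, options = gen_options()) {
  graphs <- run_enumeration(mcd, options)
  extra_complete <- TRUE
  if (options$explore_alt_valences && any(mcd$atoms$element == "N")) {
    nidx <- which(mcd$atoms$element == "N")
    base <- mcd$atoms$valence
    subsets <- unlist(lapply(seq_along(nidx), function(k)
      utils::combn(nidx, k, simplify = FALSE)), recursive = FALSE)
    for (ss in subsets) {
      vo <- base; vo[ss] <- 5L
      g2 <- run_enumeration(mcd, options, valence_override = vo)
      extra_complete <- extra_complete && attr(g2, "complete")
      graphs <- c(graphs, g2)
    }
  }
  complete <- attr(graphs, "complete") %||% TRUE
  out <- dedup_graphs(graphs)
  attr(out, "complete") <- isTRUE(complete) && extra_complete
  attr(out, "nodes") <- attr(graphs, "nodes")
  out
}

#' Verify a candidate structure against an MCD
#'
#' Independent from-scratch audit: recomputes valences, attached-H counts,
#' hybridization pi budgets, hetero flags, connectedness and every
#' connectivity constraint (BFS path lengths). Also serves as the spectral
#' filter for fuzzy-generation unions.
#'
#' @param g A `molgraph` whose atom order matches the MCD.
#' @param mcd The `mcd` to audit against.
#' @return `list(ok = logical, violations = character vector)`.
#' @export
verify_candidate <- function(g, mcd) {
  v <- character(0)
  at <- mcd$atoms
  if (n_atoms(g) != nrow(at)) return(list(ok = FALSE, violations = "atom count mismatch"))
  if (!identical(g$elements, as.character(at$element)))
    v <- c(v, "element sequence mismatch")
  hk <- which(!is.na(at$hydrogens))
  bad <- hk[g$hydrogens[hk] != at$hydrogens[hk]]
  if (length(bad)) v <- c(v, sprintf("attached-H mismatch at atom %d", bad[1]))
  flex <- which(is.na(at$hydrogens))
  if (sum(g$hydrogens[flex]) != mcd$free_h)
    v <- c(v, "free hydrogen count mismatch")
  deg <- bond_order_sums(g)
  vbad <- which(deg + g$hydrogens != g$valences)
  if (length(vbad)) v <- c(v, sprintf("valence violation at atom %d", vbad[1]))
  if (!is_connected_graph(g)) v <- c(v, "graph not connected")
  p <- pi_counts(g)
  for (a in seq_len(nrow(at))) {
    if (p[a] > 2L || !bitwAnd(at$hyb_mask[a], bitwShiftL(1L, p[a]))) {
      v <- c(v, sprintf("hybridization violation at atom %d (%d pi bonds)", a, p[a]))
    }
  }
  het <- at$element != "C"
  adj <- matrix(FALSE, nrow(at), nrow(at))
  for (k in seq_len(nrow(g$bonds))) {
    adj[g$bonds[k, "i"], g$bonds[k, "j"]] <- TRUE
    adj[g$bonds[k, "j"], g$bonds[k, "i"]] <- TRUE
  }
  for (a in which(at$hetero_flag != 0L)) {
    has <- any(adj[a, ] & het)
    if (at$hetero_flag[a] == 1L && has)
      v <- c(v, sprintf("forbidden hetero neighbor at atom %d", a))
    if (at$hetero_flag[a] == 2L && !has)
      v <- c(v, sprintf("missing obligatory hetero neighbor at atom %d", a))
  }
  D <- skeleton_distances(g)
  for (ci in seq_along(mcd$constraints)) {
    cn <- mcd$constraints[[ci]]
    ok <- FALSE
    for (u in cn$us) for (vv in cn$vs) {
      if (u == vv) next
      if (D[u, vv] >= cn$dlo && D[u, vv] <= cn$dhi) ok <- TRUE
    }
    if (!ok)
      v <- c(v, sprintf("constraint %d (%s, [%d,%d]) unsatisfied", ci, cn$origin,
                        cn$dlo, cn$dhi))
  }
  for (k in seq_len(nrow(mcd$fixed_bonds))) {
    i <- mcd$fixed_bonds[k, "i"]; j <- mcd$fixed_bonds[k, "j"]
    o <- mcd$fixed_bonds[k, "order"]
    hit <- which((g$bonds[, "i"] == i & g$bonds[, "j"] == j) |
                 (g$bonds[, "i"] == j & g$bonds[, "j"] == i))
    if (!length(hit) || g$bonds[hit[1], "order"] != o)
      v <- c(v, sprintf("fixed bond %d-%d (order %d) missing", i, j, o))
  }
  list(ok = length(v) == 0L, violations = v)
}

#' Count fuzzy-generation connectivity combinations
#'
#' Single-size mode returns `choose(N, m)` (the convention of the N = 60,
#' m = 5 example, about 5.5 million); cumulative mode returns
#' `sum_{i=1..m} choose(N, i)`, the number of non-empty subsets FSG iterates.
#'
#' @param N Eligible connectivity count.
#' @param m Subset size (or maximum size in cumulative mode).
#' @param cumulative Sum over sizes 1..m (default `FALSE`).
#' @return Exact count as a numeric.
#' @export
count_combinations <- function(N, m, cumulative = FALSE) {
  stopifnot(m >= 0, N >= 0, m <= N)
  if (cumulative) {
    if (m == 0L) return(1)
    sum(choose(N, seq_len(m)))
  } else choose(N, m)
}

relax_constraint <- function(cn, a) {
  if (a == 16L) return(NULL)              # deletion convention
  cn$dhi <- cn$dhi + a
  cn
}

#' Fuzzy structure generation over suspect connectivities
#'
#' Iterates subsets of size 0..m of the eligible connectivity set (the
#' suspicious set from [check_consistency()] when `restrict_to_suspicious`
#' and detection succeeded, else all connectivities). Per subset, the
#' selected connectivities are elongated by `a` bonds (or deleted when
#' `a = 16`), infeasible combinations are skipped by the stage-1/2 quick
#' check, structures are generated from the renewed constraint set, and all
#' outputs are unified and deduplicated by canonical key.
#'
#' @param mcd An `mcd`.
#' @param fsg [fsg_options()].
#' @param gen [gen_options()].
#' @param consistency Optional result of [check_consistency()] (recomputed
#'   when missing and `restrict_to_suspicious` is set).
#' @return `list(structures, result)` where `result` is an `fsg_result` with
#'   fields n_math, n_real, k_generated, k_filtered, k_unique, t_g and a
#'   per-combination log.
#' @export
fuzzy_generate <- function(mcd, fsg = fsg_options(), gen = gen_options(),
                           consistency = NULL) {
  t0 <- proc.time()[["elapsed"]]
  eligible <- seq_along(mcd$constraints)
  if (fsg$restrict_to_suspicious) {
    if (is.null(consistency)) consistency <- check_consistency(mcd)
    if (!consistency$feasible && length(consistency$suspicious_constraints))
      eligible <- consistency$suspicious_constraints
  }
  N <- length(eligible)
  m <- min(fsg$m, N)
  n_math <- sum(choose(N, 0:m))   # subsets of size <= m, empty set included
  subsets <- list(integer(0))
  if (m > 0L)
    for (k in seq_len(m))
      subsets <- c(subsets, utils::combn(eligible, k, simplify = FALSE))
  all_graphs <- list()
  n_real <- 0L; k_generated <- 0L
  complete <- TRUE
  log <- list()
  for (ss in subsets) {
    m2 <- mcd
    if (length(ss)) {
      newc <- list()
      for (ci in seq_along(mcd$constraints)) {
        cn <- mcd$constraints[[ci]]
        if (ci %in% ss) cn <- relax_constraint(cn, fsg$a)
        if (!is.null(cn)) newc[[length(newc) + 1L]] <- cn
      }
      m2$constraints <- newc
    }
    q <- quick_consistency(m2)
    if (!q$feasible) {
      log[[length(log) + 1L]] <- list(subset = ss, skipped = TRUE, k = 0L)
      next
    }
    n_real <- n_real + 1L
    res <- run_enumeration(m2, gen)
    complete <- complete && attr(res, "complete")
    k_generated <- k_generated + length(res)
    log[[length(log) + 1L]] <- list(subset = ss, skipped = FALSE, k = length(res))
    all_graphs <- c(all_graphs, res)
  }
  # spectral filtering of the union against the relaxed-by-any-combo sets is
  # already enforced per combination; filter the union against the common
  # structural requirements (valences, connectivity) as an audit
  keep <- vapply(all_graphs, function(g)
    isTRUE(tryCatch({ validate_molgraph(g); TRUE }, error = function(e) FALSE)),
    logical(1))
  filtered <- all_graphs[keep]
  uniq <- dedup_graphs(filtered)
  result <- structure(list(n_math = n_math, n_real = n_real,
                           k_generated = k_generated,
                           k_filtered = length(filtered),
                           k_unique = length(uniq),
                           t_g = proc.time()[["elapsed"]] - t0,
                           eligible = eligible, complete = complete,
                           log = log),
                      class = "fsg_result")
  list(structures = uniq, result = result)
}

#' @export
print.fsg_result <- function(x, ...) {
  cat(sprintf("<fsg_result> combos: %g theoretical, %d processed; k = %d -> %d -> %d unique; %.2f s%s\n",
              x$n_math, x$n_real, x$k_generated, x$k_filtered, x$k_unique, x$t_g,
              if (x$complete) "" else " [incomplete]"))
  invisible(x)
}

#' Build an unconstrained (or lightly constrained) MCD from a formula alone
#'
#' Every atom is flexible: attached hydrogens are distributed by the
#' generator. Used for formula-only enumeration and as the scaffold for the
#' brute-force oracle.
#'
#' @param formula `molformula` or string.
#' @param constraints Optional constraint list on heavy-atom indices
#'   (carbons first, then heteroatoms in formula order).
#' @return An `mcd`.
#' @export
mcd_from_formula <- function(formula, constraints = list()) {
  if (is.character(formula)) formula <- parse_formula(formula)
  atoms <- list()
  for (el in c(intersect("C", names(formula)),
               sort(setdiff(names(formula), c("C", "H"))))) {
    for (k in seq_len(formula[[el]]))
      atoms[[length(atoms) + 1L]] <- data.frame(
        element = el, hydrogens = NA_integer_, shift = NA_real_,
        hyb_mask = .HYB_ALL, hetero_flag = 0L, peak = NA_integer_,
        valence = .ELEMENTS[[el]]$valence)
  }
  atoms <- do.call(rbind, atoms)
  cons <- lapply(constraints, function(cn) {
    cn$us <- as.integer(cn$us); cn$vs <- as.integer(cn$vs)
    cn$origin <- cn$origin %||% "user"
    cn$suspicious <- isTRUE(cn$suspicious); cn$ambiguous <- isTRUE(cn$ambiguous)
    cn$sources <- cn$sources %||% NA
    cn
  })
  new_mcd(formula, atoms, formula_count(formula, "H"), cons)
}

#' Does a known constitution fit an MCD under some peak assignment?
#'
#' Decides whether any mapping of the atoms of `g` onto the MCD's skeleton
#' slots (respecting element, attached-H count, hybridization and hetero
#' flags) satisfies every connectivity constraint — i.e. whether [generate()]
#' would return `g`'s isomorphism class. Backtracking over slots with
#' within-peak ordering to cut degenerate permutations.
#'
#' @param g A `molgraph` (shifts ignored).
#' @param mcd An `mcd`.
#' @return Logical.
#' @export
admits_assignment <- function(g, mcd) {
  at <- mcd$atoms
  n <- nrow(at)
  if (n_atoms(g) != n) return(FALSE)
  p <- pi_counts(g)
  adj_het <- vapply(seq_len(n), function(a)
    any(g$elements[neighbors_of(g, a)] != "C"), logical(1))
  D <- skeleton_distances(g)
  compat <- matrix(FALSE, n, n)          # compat[slot, atom]
  for (k in seq_len(n)) for (a in seq_len(n)) {
    ok <- at$element[k] == g$elements[a] &&
      (is.na(at$hydrogens[k]) || at$hydrogens[k] == g$hydrogens[a]) &&
      p[a] <= 2L && bitwAnd(at$hyb_mask[k], bitwShiftL(1L, p[a])) != 0L &&
      !(at$hetero_flag[k] == 1L && adj_het[a]) &&
      !(at$hetero_flag[k] == 2L && !adj_het[a])
    compat[k, a] <- ok
  }
  # order slots by constraint involvement for earlier pruning
  score <- numeric(n)
  for (cn in mcd$constraints) score[c(cn$us, cn$vs)] <- score[c(cn$us, cn$vs)] + 1
  slot_order <- order(-score)
  sigma <- integer(n)                    # slot -> atom, 0 = unassigned
  used <- logical(n)
  pos_in_order <- match(seq_len(n), slot_order)
  check_partial <- function() {
    for (cn in mcd$constraints) {
      ids_u <- sigma[cn$us]; ids_v <- sigma[cn$vs]
      if (any(ids_u == 0L) || any(ids_v == 0L)) next
      ok <- FALSE
      for (a in ids_u) for (b in ids_v)
        if (a != b && D[a, b] >= cn$dlo && D[a, b] <= cn$dhi) ok <- TRUE
      if (!ok) return(FALSE)
    }
    for (kfb in seq_len(nrow(mcd$fixed_bonds))) {
      i <- sigma[mcd$fixed_bonds[kfb, "i"]]; j <- sigma[mcd$fixed_bonds[kfb, "j"]]
      if (i == 0L || j == 0L) next
      if (bond_order_between(g, i, j) != mcd$fixed_bonds[kfb, "order"]) return(FALSE)
    }
    TRUE
  }
  rec <- function(step) {
    if (step > n) return(TRUE)
    k <- slot_order[step]
    cand <- which(compat[k, ] & !used)
    # same-peak slots are interchangeable: force increasing atom ids
    if (!is.na(at$peak[k])) {
      mates <- which(!is.na(at$peak) & at$peak == at$peak[k])
      assigned <- sigma[mates]
      if (any(assigned > 0L)) cand <- cand[cand > max(assigned)]
    }
    for (a in cand) {
      sigma[k] <<- a; used[a] <<- TRUE
      if (check_partial() && rec(step + 1L)) return(TRUE)
      sigma[k] <<- 0L; used[a] <<- FALSE
    }
    FALSE
  }
  res <- rec(1L)
  if (res) {
    # free-H bookkeeping for flexible slots
    flex <- which(is.na(at$hydrogens))
    if (sum(g$hydrogens[sigma[flex]]) != mcd$free_h) {
      # exact H budget can in principle rule the fit out; fall back to the
      # generator itself for the rare flexible-H mismatch
      res <- canonical_key(g) %in% attr(generate(mcd), "keys")
    }
  }
  res
}

#' Align a reference structure's atoms to MCD order
#'
#' Maps each MCD skeleton atom to an atom of `g` with the same element,
#' matching assigned 13C shifts within `tol` (symmetry-equivalent atoms are
#' interchangeable, so any within-class bijection is valid). Used to audit a
#' known structure against the MCD built from its own simulated data.
#'
#' @param g A `molgraph` with carbon shifts assigned.
#' @param mcd The `mcd` to align to.
#' @param tol Shift-matching tolerance in ppm.
#' @return `g` with atoms permuted into MCD order.
#' @export
align_to_mcd <- function(g, mcd, tol = 0.05) {
  at <- mcd$atoms
  n <- nrow(at)
  if (n_atoms(g) != n) stop("atom count mismatch")
  used <- logical(n)
  sel <- integer(n)               # sel[k] = atom of g placed at MCD position k
  for (k in seq_len(n)) {
    cand <- which(!used & g$elements == at$element[k])
    if (!is.na(at$shift[k]))
      cand <- cand[!is.na(g$shifts[cand]) & abs(g$shifts[cand] - at$shift[k]) <= tol]
    if (!is.na(at$hydrogens[k]))
      cand <- cand[g$hydrogens[cand] == at$hydrogens[k]]
    if (!length(cand))
      stop(sprintf("no unused atom of g matches MCD atom %d (%s, %.2f ppm)",
                   k, at$element[k], at$shift[k]))
    used[cand[1]] <- TRUE
    sel[k] <- cand[1]
  }
  perm <- integer(n); perm[sel] <- seq_len(n)
  relabel_graph(g, perm)
}

#' Brute-force structure enumeration (test oracle)
#'
#' Independent exhaustive enumeration in plain R over all bond-order
#' assignments on atom pairs, with only valence pruning, then filtering by
#' connectivity, hydrogen balance and constraints, and deduplication. Exact
#' but exponential; guarded to at most 7 heavy atoms.
#'
#' @param formula `molformula` or string.
#' @param constraints Optional constraint list as in [mcd_from_formula()].
#' @return List of `molgraph` with attribute `keys`.
#' @export
brute_force_enumerate <- function(formula, constraints = list()) {
  mcd <- mcd_from_formula(formula, constraints)
  at <- mcd$atoms
  n <- nrow(at)
  if (n > 7L) stop("brute-force oracle is limited to 7 heavy atoms")
  valence <- at$valence
  free_h <- mcd$free_h
  pairs <- if (n > 1L) t(utils::combn(n, 2L)) else matrix(integer(0), ncol = 2L)
  found <- list()
  B <- matrix(0L, n, n)
  deg <- integer(n)
  check_leaf <- function() {
    h <- valence - deg
    if (any(h < 0L) || sum(h) != free_h) return(NULL)
    if (n > 1L && any(deg == 0L)) return(NULL)
    # connectivity by simple reach
    seen <- logical(n); seen[1] <- TRUE; frontier <- 1L
    while (length(frontier)) {
      nxt <- integer(0)
      for (x in frontier) for (y in seq_len(n))
        if (B[x, y] > 0L && !seen[y]) { seen[y] <- TRUE; nxt <- c(nxt, y) }
      frontier <- nxt
    }
    if (!all(seen)) return(NULL)
    bonds <- which(upper.tri(B) & B > 0L, arr.ind = TRUE)
    bm <- cbind(i = bonds[, 1], j = bonds[, 2],
                order = B[cbind(bonds[, 1], bonds[, 2])])
    g <- molgraph(at$element, h, bm, valences = valence, validate = FALSE)
    D <- skeleton_distances(g)
    for (cn in mcd$constraints) {
      ok <- FALSE
      for (u in cn$us) for (vv in cn$vs)
        if (u != vv && D[u, vv] >= cn$dlo && D[u, vv] <= cn$dhi) ok <- TRUE
      if (!ok) return(NULL)
    }
    g
  }
  tdeg <- 0L
  T_needed <- sum(valence) - free_h        # total heavy-bond degree required
  rec <- function(pi_) {
    if (pi_ > nrow(pairs)) {
      g <- check_leaf()
      if (!is.null(g)) found[[length(found) + 1L]] <<- g
      return(invisible())
    }
    # degree bookkeeping bound: each remaining pair adds at most 6 degree
    if (tdeg > T_needed || tdeg + 6L * (nrow(pairs) - pi_ + 1L) < T_needed)
      return(invisible())
    i <- pairs[pi_, 1]; j <- pairs[pi_, 2]
    row_end <- j == n
    for (o in 0:3) {
      if (o > 0L && (deg[i] + o > valence[i] || deg[j] + o > valence[j])) break
      B[i, j] <<- o; B[j, i] <<- o
      deg[i] <<- deg[i] + o; deg[j] <<- deg[j] + o
      tdeg <<- tdeg + 2L * o
      # once row i is complete atom i's bonds are final: it must be bonded
      # (connectivity) and the committed hydrogens must fit the budget
      ok <- TRUE
      if (row_end) {
        if (n > 1L && deg[i] == 0L) ok <- FALSE
        if (ok && sum(valence[1:i] - deg[1:i]) > free_h) ok <- FALSE
        if (ok && i == n - 1L && n > 1L && deg[n] == 0L) ok <- FALSE
        if (ok && i == n - 1L && sum(valence - deg) != free_h) ok <- FALSE
      }
      if (ok) rec(pi_ + 1L)
      deg[i] <<- deg[i] - o; deg[j] <<- deg[j] - o
      tdeg <<- tdeg - 2L * o
      B[i, j] <<- 0L; B[j, i] <<- 0L
    }
  }
  if (n == 1L) {
    if (valence[1] == free_h)
      found[[1]] <- molgraph(at$element, free_h, NULL, valences = valence)
  } else rec(1L)
  dedup_graphs(found)
}
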