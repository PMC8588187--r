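# Molecular Connectivity Diagram: the generator's input.  Skeleton atoms with
# APCT-derived property constraints plus heavy-atom connectivity constraints
# translated from COSY/HMBC, with contradiction (non-standard correlation)
# detection.
#
# Atom table columns: element, hydrogens (NA = flexible, e.g. heteroatoms),
# shift (NA for heteroatoms), hyb_mask (bitmask sp3=1 sp2=2 sp=4),
# hetero_flag (0 undefined, 1 forbidden, 2 obligatory), peak (13C peak index
# or NA), valence.
#
# Constraints are existential over atom groups: list(us, vs, dlo, dhi,
# origin, suspicious, ambiguous, sources).  Groups with more than one atom
# arise from degenerate (symmetry-equivalent) peaks and from ambiguous shift
# matches; the constraint holds if some pair of carrier atoms lies in range.

new_mcd <- function(formula, atoms, free_h, constraints = list(),
                    fixed_bonds = NULL) {
  if (is.null(fixed_bonds) || !length(fixed_bonds))
    fixed_bonds <- matrix(integer(0), ncol = 3L,
                          dimnames = list(NULL, c("i", "j", "order")))
  structure(list(formula = formula, atoms = atoms, free_h = as.integer(free_h),
                 constraints = constraints, fixed_bonds = fixed_bonds),
            class = "mcd")
}

#' @export
print.mcd <- function(x, ...) {
  cat(sprintf("<mcd> %s: %d skeleton atoms, %d free H, %d constraints, %d fixed bonds\n",
              format(x$formula), nrow(x$atoms), x$free_h, length(x$constraints),
              nrow(x$fixed_bonds)))
  invisible(x)
}

mult_h_count <- function(mult) {
  unname(c(C = 0L, CH = 1L, CH2 = 2L, CH3 = 3L)[mult])
}

#' Build a Molecular Connectivity Diagram
#'
#' Lays out one skeleton atom per heavy atom of the formula: carbons are taken
#' from the 13C peak list (expanded by degeneracy) with attached-H counts from
#' their multiplicities and APCT-derived property constraints; heteroatoms are
#' added unplaced; the hydrogen balance becomes the free-H count (OH/NH
#' protons). 2D correlations, previously resolved by [match_shifts()], are
#' translated into heavy-atom connectivity constraints.
#'
#' @param set A resolved `correlation_set` (see [match_shifts()]); a set with
#'   no correlations yields an unconstrained MCD.
#' @param apct APCT table from [load_apct()].
#' @param fixed_bonds Optional matrix (i, j, order) of user-fixed bonds.
#' @return An object of class `mcd`.
#' @export
build_mcd <- function(set, apct = load_apct(), fixed_bonds = NULL) {
  f <- set$formula
  nC <- formula_count(f, "C")
  nH <- formula_count(f, "H")
  pc <- set$peaks_c13
  atoms <- list()
  # carbons, one per 13C peak x degeneracy
  for (i in seq_len(nrow(pc))) {
    prop <- apply_apct(pc$shift[i], pc$multiplicity[i], apct)
    h <- if (is.na(pc$multiplicity[i])) NA_integer_ else mult_h_count(pc$multiplicity[i])
    for (d in seq_len(pc$degeneracy[i]))
      atoms[[length(atoms) + 1L]] <- data.frame(
        element = "C", hydrogens = h, shift = pc$shift[i],
        hyb_mask = hyb_mask(prop$hyb), hetero_flag = .HETERO_CODE[[prop$hetero]],
        peak = i, valence = 4L)
  }
  n_peak_c <- length(atoms)
  if (n_peak_c > nC)
    stop(sprintf("13C peak table implies %d carbons but formula has %d", n_peak_c, nC))
  # carbons not represented by any peak (rare; e.g. missing quaternary peaks)
  for (k in seq_len(nC - n_peak_c))
    atoms[[length(atoms) + 1L]] <- data.frame(
      element = "C", hydrogens = NA_integer_, shift = NA_real_,
      hyb_mask = .HYB_ALL, hetero_flag = 0L, peak = NA_integer_, valence = 4L)
  # heteroatoms, unplaced
  for (el in setdiff(names(f), c("C", "H"))) {
    for (k in seq_len(f[[el]]))
      atoms[[length(atoms) + 1L]] <- data.frame(
        element = el, hydrogens = NA_integer_, shift = NA_real_,
        hyb_mask = .HYB_ALL, hetero_flag = 0L, peak = NA_integer_,
        valence = .ELEMENTS[[el]]$valence)
  }
  atoms <- do.call(rbind, atoms)
  rownames(atoms) <- NULL
  attached <- sum(atoms$hydrogens, na.rm = TRUE)
  if (attached > nH)
    stop(sprintf("CHn multiplicities imply %d protons but formula has only %d",
                 attached, nH))
  flexible <- sum(is.na(atoms$hydrogens))
  free_h <- nH - attached
  if (flexible == 0L && free_h != 0L)
    stop(sprintf("hydrogen bookkeeping violation: %d protons unaccounted for", free_h))
  mcd <- new_mcd(set$formula, atoms, free_h, list(), fixed_bonds)
  mcd$constraints <- translate_correlations(set, mcd)
  mcd
}

# carbon atoms carrying a given 13C peak index
peak_atoms <- function(mcd, peak_idx) {
  unlist(lapply(peak_idx, function(p) which(!is.na(mcd$atoms$peak) & mcd$atoms$peak == p)))
}

# carrier carbons of a 1H peak: carbons bound to that proton per HSQC
h_carrier_atoms <- function(set, mcd, h_peaks) {
  co <- set$correlations
  hs <- co[co$kind == "HSQC", , drop = FALSE]
  cps <- integer(0)
  for (hp in h_peaks) {
    rows <- which(vapply(strsplit(hs$a_peaks, ","), function(v) hp %in% as.integer(v),
                         logical(1)))
    for (r in rows) cps <- c(cps, as.integer(strsplit(hs$b_peaks[r], ",")[[1]]))
  }
  unique(peak_atoms(mcd, unique(cps)))
}

#' Translate resolved 2D correlations into connectivity constraints
#'
#' A COSY response between protons with an assumed coupling length of
#' `[n_lo, n_hi]` bonds constrains the skeletal distance between the carrier
#' heavy atoms to `[n_lo - 2, n_hi - 2]`; an HMBC response between a proton
#' and a carbon constrains the distance between the proton's carrier and that
#' carbon to `[n_lo - 1, n_hi - 1]`. Duplicate constraints on one atom pair
#' are merged by interval intersection (an empty intersection is a
#' contradiction error naming the records). Ambiguously matched correlations
#' become existential constraints over all candidate atoms, flagged
#' `ambiguous`. Geminal COSY (both protons on one carbon) is dropped.
#'
#' @param set Resolved `correlation_set`.
#' @param mcd The MCD whose atoms the constraints reference.
#' @return List of constraints.
#' @export
translate_correlations <- function(set, mcd) {
  co <- set$correlations
  if (!nrow(co)) return(list())
  if (is.null(co$a_peaks)) stop("correlations must be resolved by match_shifts() first")
  cons <- list()
  for (i in seq_len(nrow(co))) {
    kind <- co$kind[i]
    if (!kind %in% c("COSY", "HMBC", "HN_HMBC")) next
    cls <- co$intensity_class[i]
    rng <- set$policy[[paste(kind, cls, sep = ".")]]
    if (is.null(rng)) rng <- set$policy[[paste(kind, "undefined", sep = ".")]]
    hpa <- as.integer(strsplit(co$a_peaks[i], ",")[[1]])
    if (kind == "COSY") {
      hpb <- as.integer(strsplit(co$b_peaks[i], ",")[[1]])
      us <- h_carrier_atoms(set, mcd, hpa)
      vs <- h_carrier_atoms(set, mcd, hpb)
      d <- c(rng[1] - 2L, rng[2] - 2L)
    } else if (kind == "HMBC") {
      us <- h_carrier_atoms(set, mcd, hpa)
      vs <- peak_atoms(mcd, as.integer(strsplit(co$b_peaks[i], ",")[[1]]))
      d <- c(rng[1] - 1L, rng[2] - 1L)
    } else {                               # HN_HMBC: target is a nitrogen
      us <- h_carrier_atoms(set, mcd, hpa)
      vs <- which(mcd$atoms$element == "N")
      d <- c(rng[1] - 1L, rng[2] - 1L)
    }
    if (!length(us) || !length(vs)) next   # e.g. proton with no HSQC carrier (NH/OH)
    if (length(us) == 1L && length(vs) == 1L && us == vs) next  # geminal COSY
    d[1] <- max(d[1], 1L)                  # distinct heavy atoms are >= 1 bond apart
    cons[[length(cons) + 1L]] <- list(us = sort(unique(us)), vs = sort(unique(vs)),
                                      dlo = d[1], dhi = d[2], origin = kind,
                                      suspicious = FALSE,
                                      ambiguous = isTRUE(co$ambiguous[i]) ||
                                        length(us) > 1L || length(vs) > 1L,
                                      sources = i)
  }
  merge_constraints(cons)
}

constraint_pair_key <- function(cn) {
  a <- paste(cn$us, collapse = "+"); b <- paste(cn$vs, collapse = "+")
  if (a <= b) paste(a, b, sep = "|") else paste(b, a, sep = "|")
}

# merge duplicates on one atom-group pair by interval intersection; an empty
# intersection names both source records
merge_constraints <- function(cons) {
  if (!length(cons)) return(cons)
  keys <- vapply(cons, constraint_pair_key, character(1))
  out <- list()
  for (k in unique(keys)) {
    grp <- cons[keys == k]
    m <- grp[[1]]
    for (g in grp[-1]) {
      lo <- max(m$dlo, g$dlo); hi <- min(m$dhi, g$dhi)
      if (lo > hi)
        stop(sprintf("contradictory constraints between records %s and %s: [%d,%d] vs [%d,%d]",
                     paste(m$sources, collapse = "+"), paste(g$sources, collapse = "+"),
                     m$dlo, m$dhi, g$dlo, g$dhi))
      m$dlo <- lo; m$dhi <- hi
      m$sources <- c(m$sources, g$sources)
      m$origin <- paste(unique(c(m$origin, g$origin)), collapse = "+")
    }
    out[[length(out) + 1L]] <- m
  }
  out
}

atom_free_valence <- function(mcd) {
  h <- mcd$atoms$hydrogens
  mcd$atoms$valence - ifelse(is.na(h), 0L, h)
}

# stages 1-2 of the consistency heuristic; returns list(feasible, atoms, cons)
quick_consistency <- function(mcd) {
  n <- nrow(mcd$atoms)
  fv <- atom_free_valence(mcd)
  bad_atoms <- integer(0); bad_cons <- integer(0)
  singleton <- vapply(mcd$constraints, function(cn)
    length(cn$us) == 1L && length(cn$vs) == 1L, logical(1))
  # stage 1: pigeonhole on forced distance-1 partners
  for (a in seq_len(n)) {
    forced <- integer(0)
    for (ci in seq_along(mcd$constraints)) {
      cn <- mcd$constraints[[ci]]
      if (!singleton[ci] || cn$dlo != 1L || cn$dhi != 1L) next
      if (cn$us == a) forced <- c(forced, cn$vs)
      if (cn$vs == a) forced <- c(forced, cn$us)
    }
    fb <- nrow(mcd$fixed_bonds)
    if (fb) {
      forced <- c(forced, mcd$fixed_bonds[mcd$fixed_bonds[, "i"] == a, "j"],
                  mcd$fixed_bonds[mcd$fixed_bonds[, "j"] == a, "i"])
    }
    if (length(unique(forced)) > fv[a]) bad_atoms <- c(bad_atoms, a)
  }
  # stage 2: interval propagation + ball-size bound
  ub <- matrix(Inf, n, n); diag(ub) <- 0
  for (k in seq_len(nrow(mcd$fixed_bonds))) {
    i <- mcd$fixed_bonds[k, "i"]; j <- mcd$fixed_bonds[k, "j"]
    ub[i, j] <- ub[j, i] <- 1
  }
  lb <- matrix(0, n, n)
  for (ci in seq_along(mcd$constraints)) {
    if (!singleton[ci]) next
    cn <- mcd$constraints[[ci]]
    u <- cn$us; v <- cn$vs
    ub[u, v] <- ub[v, u] <- min(ub[u, v], cn$dhi)
    lb[u, v] <- lb[v, u] <- max(lb[u, v], cn$dlo)
  }
  for (k in seq_len(n)) {
    nk <- outer(ub[, k], ub[k, ], `+`)
    ub <- pmin(ub, nk)
  }
  viol <- which(ub < lb, arr.ind = TRUE)
  if (nrow(viol)) bad_atoms <- unique(c(bad_atoms, as.integer(viol)))
  maxfv <- max(fv)
  for (a in seq_len(n)) {
    for (r in 1:3) {
      ball <- sum(ub[a, ] <= r) - 1L
      cap <- if (fv[a] == 0L) 0 else fv[a] * sum((maxfv - 1) ^ (0:(r - 1)))
      if (ball > cap) { bad_atoms <- unique(c(bad_atoms, a)); break }
    }
  }
  if (length(bad_atoms)) {
    for (ci in seq_along(mcd$constraints)) {
      cn <- mcd$constraints[[ci]]
      if (length(intersect(c(cn$us, cn$vs), bad_atoms))) bad_cons <- c(bad_cons, ci)
    }
  }
  list(feasible = length(bad_atoms) == 0L,
       atoms = sort(unique(bad_atoms)), cons = sort(unique(bad_cons)))
}

#' Check an MCD for contradictions (non-standard correlations)
#'
#' Three-stage heuristic: (1) per-atom pigeonhole — forced distance-1
#' partners cannot exceed an atom's free valence; (2) interval propagation —
#' triangle-inequality closure of distance upper bounds against lower bounds,
#' plus a ball-size bound from free valences; (3) optional bounded trial
#' generation — if an exhaustive (node-budgeted) generation run completes
#' with zero structures the constraint set is infeasible. When infeasibility
#' is localized to an atom, all constraints incident to it are marked
#' suspicious; when stage 3 detects infeasibility without localization, every
#' constraint is suspicious. Detection is heuristic: a feasible verdict does
#' not prove the data are free of non-standard correlations.
#'
#' @param mcd An `mcd`.
#' @param trial_generation Run stage 3 (default `TRUE`).
#' @param node_budget Search-node budget for stage 3.
#' @return `list(feasible, suspicious_atoms, suspicious_constraints, stage,
#'   conclusive)`.
#' @export
check_consistency <- function(mcd, trial_generation = TRUE, node_budget = 2e6) {
  q <- quick_consistency(mcd)
  if (!q$feasible)
    return(list(feasible = FALSE, suspicious_atoms = q$atoms,
                suspicious_constraints = q$cons, stage = 2L, conclusive = TRUE))
  if (trial_generation && length(mcd$constraints)) {
    res <- generate(mcd, gen_options(max_structures = 1L, node_budget = node_budget))
    if (length(res) == 0L && attr(res, "complete"))
      return(list(feasible = FALSE, suspicious_atoms = integer(0),
                  suspicious_constraints = seq_along(mcd$constraints),
                  stage = 3L, conclusive = TRUE))
    if (!attr(res, "complete") && length(res) == 0L)
      return(list(feasible = TRUE, suspicious_atoms = integer(0),
                  suspicious_constraints = integer(0), stage = 3L,
                  conclusive = FALSE))
  }
  list(feasible = TRUE, suspicious_atoms = integer(0),
       suspicious_constraints = integer(0), stage = 3L, conclusive = TRUE)
}

#' Serialize an MCD to JSON for inspection or manual editing
#' @param mcd An `mcd`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
mcd_to_json <- function(mcd, path) {
  obj <- list(formula = format(mcd$formula), atoms = mcd$atoms,
              free_h = mcd$free_h,
              constraints = lapply(mcd$constraints, function(cn)
                cn[c("us", "vs", "dlo", "dhi", "origin", "suspicious", "ambiguous")]),
              fixed_bonds = as.data.frame(mcd$fixed_bonds))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an MCD back from its JSON serialization
#' @param path JSON path written by [mcd_to_json()].
#' @return An `mcd`.
#' @export
mcd_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  atoms <- as.data.frame(obj$atoms)
  cons <- list()
  if (length(obj$constraints)) {
    raw <- obj$constraints
    if (is.data.frame(raw)) raw <- split(raw, seq_len(nrow(raw)))
    for (cn in raw)
      cons[[length(cons) + 1L]] <- list(us = as.integer(unlist(cn$us)),
                                        vs = as.integer(unlist(cn$vs)),
                                        dlo = as.integer(cn$dlo), dhi = as.integer(cn$dhi),
                                        origin = as.character(cn$origin),
                                        suspicious = isTRUE(cn$suspicious),
                                        ambiguous = isTRUE(cn$ambiguous), sources = NA)
  }
  fb <- obj$fixed_bonds
  fb <- if (length(fb) && nrow(as.data.frame(fb))) as.matrix(as.data.frame(fb)) else NULL
  new_mcd(parse_formula(obj$formula), atoms, obj$free_h, cons, fb)
}
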