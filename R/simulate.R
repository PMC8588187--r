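# Forward simulation of correlation tables from a known structure, so the
# whole elucidation loop is testable without external spectrometer data.
#
# Reference shifts are produced by the package's own incremental predictor
# plus fixed per-symmetry-class offsets (internally consistent ground truth;
# no claim of matching literature spectra).  1H shifts are derived from the
# carbon shifts by a fixed affine map.  Symmetry-equivalent atoms are
# collapsed to one peak with a degeneracy count.

#' Simulation options
#'
#' @param include_cosy,include_hmbc,include_hn_hmbc Which experiments to emit.
#' @param hmbc_range H-to-C coupling lengths emitted for HMBC (default 2-3
#'   bonds).
#' @param cosy_range H-to-H coupling lengths emitted for COSY (default 3J
#'   only; geminal 2J off).
#' @param nsc_injections List of `list(kind, u, v, n)`: append a correlation
#'   of `kind` between carbons `u` (protonated) and `v` whose true coupling
#'   length `n` exceeds the default range; the elucidator is not told.
#' @param drop_probability Probability of dropping each COSY/HMBC record
#'   (HSQC is never dropped; it anchors the CHn groups).
#' @param shift_noise_sd Gaussian noise sd (ppm) on 13C 2D coordinates
#'   (1H coordinates get a tenth of it).
#' @param seed Integer seed for drops and noise.
#' @return A `sim_options` list.
#' @export
sim_options <- function(include_cosy = TRUE, include_hmbc = TRUE,
                        include_hn_hmbc = FALSE, hmbc_range = c(2L, 3L),
                        cosy_range = c(3L, 3L), nsc_injections = list(),
                        drop_probability = 0, shift_noise_sd = 0, seed = 1L) {
  stopifnot(drop_probability >= 0, drop_probability <= 1,
            all(hmbc_range >= 2L), all(hmbc_range <= 6L),
            all(cosy_range >= 2L), all(cosy_range <= 6L))
  structure(list(include_cosy = include_cosy, include_hmbc = include_hmbc,
                 include_hn_hmbc = include_hn_hmbc,
                 hmbc_range = as.integer(hmbc_range),
                 cosy_range = as.integer(cosy_range),
                 nsc_injections = nsc_injections,
                 drop_probability = drop_probability,
                 shift_noise_sd = shift_noise_sd, seed = as.integer(seed)),
            class = "sim_options")
}

# symmetry-equivalence classes of atoms: atoms are equivalent iff their
# root-marked canonical serializations of the whole graph coincide
atom_equivalence_classes <- function(g) {
  codes <- vapply(seq_len(n_atoms(g)), function(a)
    canonical_key_rooted(g, a), character(1))
  match(codes, unique(codes))
}

# deterministic per-class shift offsets: separate equivalence classes that
# the additive scheme cannot distinguish, keeping equivalent carbons exactly
# degenerate.  Class offsets come from a fixed linear-congruential sequence
# (stable across platforms), then classes closer than min_sep are spread.
reference_shifts <- function(g, min_sep = 0.8) {
  cls <- atom_equivalence_classes(g)
  base <- predict_c13_incremental(g)
  carbons <- which(g$elements == "C")
  shifts <- rep(NA_real_, n_atoms(g))
  ccls <- cls[carbons]
  ucls <- unique(ccls)
  lcg <- function(k) ((1103515245 * k + 12345) %% 2^31) / 2^31  # in [0,1)
  for (i in seq_along(ucls)) {
    members <- carbons[ccls == ucls[i]]
    off <- (lcg(ucls[i]) - 0.5) * 6      # +/- 3 ppm
    shifts[members] <- mean(base$shift[match(members, base$atom)]) + off
  }
  # spread classes that collide (sorted sweep, preserves order)
  vals <- sort(unique(shifts[carbons]))
  if (length(vals) > 1L) {
    for (rep_i in 1:50) {
      moved <- FALSE
      for (k in 2:length(vals)) {
        if (vals[k] - vals[k - 1] < min_sep) {
          vals[k] <- vals[k - 1] + min_sep
          moved <- TRUE
        }
      }
      if (!moved) break
    }
    key <- match(shifts[carbons], sort(unique(shifts[carbons])))
    shifts[carbons] <- vals[key]
  }
  shifts <- pmax(pmin(shifts, 239), 1)
  shifts
}

h_shift_of <- function(c_shift) round(0.055 * c_shift + 0.2, 3)

#' Simulate 1D peak tables and 2D correlation tables from a structure
#'
#' Emits one HSQC record per protonated-carbon class, COSY records for every
#' proton pair whose H-H coupling path length falls in `cosy_range`
#' (default 3J: vicinal protons), HMBC records for every (H, C) pair with
#' H-C coupling length in `hmbc_range` (2-3 bonds: the carrier carbon lies
#' 1-2 skeletal bonds from the target), plus any injected non-standard
#' correlations. Records are collapsed over symmetry-equivalent atoms with
#' degeneracy counts; drops and Gaussian coordinate noise are applied under
#' the seed.
#'
#' @param g A `molgraph` with complete carbon `$shifts` (see
#'   [reference_shifts()]).
#' @param opts A [sim_options()] list.
#' @return A `correlation_set`.
#' @export
simulate_correlations <- function(g, opts = sim_options()) {
  carbons <- which(g$elements == "C")
  if (anyNA(g$shifts[carbons])) stop("structure must carry complete 13C shifts")
  set.seed(opts$seed)
  D <- skeleton_distances(g)
  cls <- atom_equivalence_classes(g)
  # 13C peak table: one row per distinct carbon class
  ccls <- unique(cls[carbons])
  c13 <- do.call(rbind, lapply(ccls, function(ci) {
    members <- carbons[cls[carbons] == ci]
    a <- members[1]
    data.frame(shift = g$shifts[a],
               multiplicity = c("C", "CH", "CH2", "CH3")[min(g$hydrogens[a], 3L) + 1L],
               intensity = length(members), degeneracy = length(members))
  }))
  prot <- carbons[g$hydrogens[carbons] > 0L]
  pcls <- unique(cls[prot])
  h1 <- do.call(rbind, lapply(pcls, function(ci) {
    members <- prot[cls[prot] == ci]
    a <- members[1]
    data.frame(shift = h_shift_of(g$shifts[a]),
               intensity = length(members) * g$hydrogens[a],
               degeneracy = length(members))
  }))
  if (is.null(h1)) h1 <- empty_peaks_h1()
  corr <- list()
  add <- function(kind, sa, sb, cl) {
    corr[[length(corr) + 1L]] <<- data.frame(kind = kind, shift_a = sa,
                                             shift_b = sb, intensity_class = cl)
  }
  # HSQC anchors
  for (a in prot[!duplicated(cls[prot])])
    add("HSQC", h_shift_of(g$shifts[a]), g$shifts[a], "strong")
  droppable <- integer(0)
  if (opts$include_cosy && length(prot) > 1L) {
    seen <- character(0)
    for (u in prot) for (v in prot) {
      if (u >= v) next
      nlen <- D[u, v] + 2L                       # H-C...C-H coupling length
      if (nlen < opts$cosy_range[1] || nlen > opts$cosy_range[2]) next
      key <- paste(sort(c(cls[u], cls[v])), collapse = "-")
      if (key %in% seen) next
      seen <- c(seen, key)
      add("COSY", h_shift_of(g$shifts[u]), h_shift_of(g$shifts[v]), "strong")
      droppable <- c(droppable, length(corr))
    }
  }
  if (opts$include_hmbc) {
    seen <- character(0)
    for (u in prot) for (v in carbons) {
      if (u == v) next
      nlen <- D[u, v] + 1L                       # H-C...C coupling length
      if (nlen < opts$hmbc_range[1] || nlen > opts$hmbc_range[2]) next
      key <- paste(cls[u], cls[v], sep = ">")
      if (key %in% seen) next
      seen <- c(seen, key)
      add("HMBC", h_shift_of(g$shifts[u]), g$shifts[v],
          if (nlen == 2L) "strong" else "weak")
      droppable <- c(droppable, length(corr))
    }
  }
  if (opts$include_hn_hmbc) {
    nitro <- which(g$elements == "N")
    seen <- character(0)
    for (u in prot) for (v in nitro) {
      nlen <- D[u, v] + 1L
      if (nlen < opts$hmbc_range[1] || nlen > opts$hmbc_range[2]) next
      key <- paste(cls[u], cls[v], sep = ">")
      if (key %in% seen) next
      seen <- c(seen, key)
      add("HN_HMBC", h_shift_of(g$shifts[u]), 120, "strong")
      droppable <- c(droppable, length(corr))
    }
  }
  keep <- rep(TRUE, length(corr))
  if (opts$drop_probability > 0 && length(droppable))
    keep[droppable] <- stats::runif(length(droppable)) >= opts$drop_probability
  corr <- corr[keep]
  # injected non-standard correlations (true length n beyond default range)
  class_min_dist <- function(u, v) {
    mu <- which(cls == cls[u]); mv <- which(cls == cls[v])
    min(D[mu, mv, drop = FALSE][outer(mu, mv, `!=`)])
  }
  for (inj in opts$nsc_injections) {
    u <- inj$u; v <- inj$v
    if (!u %in% prot) stop("NSC injection requires a protonated carbon u")
    if (inj$kind == "HMBC") {
      if (class_min_dist(u, v) + 1L != inj$n)
        stop(sprintf("injection length mismatch: class distance %d but n=%d",
                     class_min_dist(u, v) + 1L, inj$n))
      add("HMBC", h_shift_of(g$shifts[u]), g$shifts[v], "strong")
    } else if (inj$kind == "COSY") {
      if (class_min_dist(u, v) + 2L != inj$n) stop("injection length mismatch")
      add("COSY", h_shift_of(g$shifts[u]), h_shift_of(g$shifts[v]), "strong")
    } else stop("unsupported injection kind")
  }
  co <- if (length(corr)) unique(do.call(rbind, corr)) else empty_correlations()
  if (opts$shift_noise_sd > 0 && nrow(co)) {
    h_cols <- co$kind %in% c("COSY", "NOESY")
    co$shift_a <- co$shift_a + stats::rnorm(nrow(co), 0, opts$shift_noise_sd / 10)
    co$shift_b <- co$shift_b + stats::rnorm(nrow(co), 0,
                                            ifelse(h_cols, opts$shift_noise_sd / 10,
                                                   opts$shift_noise_sd))
  }
  correlation_set(graph_formula(g), c13, h1, co)
}

.FIXTURE_SMILES <- c(
  indole            = "C1=CC2=CC=CC=C2N1",
  quinoline         = "C1=CC=C2N=CC=CC2=C1",
  naphthalene       = "C1=CC=C2C=CC=CC2=C1",
  para_xylene       = "CC1=CC=C(C)C=C1",
  anisaldehyde      = "COC1=CC=C(C=O)C=C1",
  menthone_like     = "CC1CCC(C(C)C)C(=O)C1",
  geraniol_like     = "CC(C)=CCCC(C)=CCO",
  dimethyluracil    = "CN1C=CC(=O)N(C)C1=O",
  benzoquinone      = "O=C1C=CC(=O)C=C1",
  coumarin          = "O=C1C=CC2=CC=CC=C2O1",
  vanillin          = "COC1=CC(C=O)=CC=C1O",
  acetylpyridine    = "CC(=O)C1=CC=CC=N1"
)

#' Convert a (Kekule) SMILES string to a molecular graph
#'
#' Thin wrapper over ChemmineR/OpenBabel; used to define the fixture corpus.
#' @param smiles SMILES string with explicit alternating bond orders.
#' @return A `molgraph`.
#' @export
graph_from_smiles <- function(smiles) {
  if (!requireNamespace("ChemmineR", quietly = TRUE))
    stop("graph_from_smiles requires the ChemmineR package")
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_[0-9]+$", "", rownames(ab))
  bonds <- cbind(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                 order = as.integer(bb[, 3]))
  keepH <- elements != "H"
  deg <- integer(length(elements))
  for (k in seq_len(nrow(bonds))) {
    deg[bonds[k, 1]] <- deg[bonds[k, 1]] + bonds[k, 3]
    deg[bonds[k, 2]] <- deg[bonds[k, 2]] + bonds[k, 3]
  }
  if (!all(keepH)) stop("explicit hydrogens unsupported in fixture SMILES")
  hyd <- default_valence(elements) - deg
  if (any(hyd < 0)) stop("SMILES implies valence beyond the default table")
  molgraph(elements, hyd, bonds)
}

#' The packaged fixture corpus
#'
#' Twelve molecules (8-16 heavy atoms) spanning fused aromatics and
#' N-heteroaromatics, a symmetric para-disubstituted benzene, terpenoid-like
#' aliphatics, and proton-deficient structures with hydrogen-free ("silent")
#' substructures, each carrying internally consistent reference shifts from
#' [reference_shifts()].
#'
#' @return Named list of `molgraph` with `$shifts` assigned.
#' @export
fixture_molecules <- function() {
  out <- lapply(.FIXTURE_SMILES, function(s) {
    g <- graph_from_smiles(s)
    g$shifts <- reference_shifts(g)
    g
  })
  out
}

# deterministically pick an NSC injection site: a (protonated u, carbon v)
# pair whose coupling length is n bonds at the observable (peak) level, i.e.
# the minimum skeletal distance between the symmetry classes of u and v is
# n-1 (in a symmetric molecule a long-range response between degenerate
# peaks is only non-standard if no equivalent pair is closer); selection is
# seed-rotated over the eligible sites
pick_nsc_site <- function(g, n = 4L, seed = 1L) {
  D <- skeleton_distances(g)
  cls <- atom_equivalence_classes(g)
  carbons <- which(g$elements == "C")
  prot <- carbons[g$hydrogens[carbons] > 0L]
  sites <- list()
  seen <- character(0)
  for (u in prot) for (v in carbons) {
    if (u == v) next
    key <- paste(cls[u], cls[v], sep = ">")
    if (key %in% seen) next
    seen <- c(seen, key)
    members_u <- intersect(which(cls == cls[u]), prot)
    members_v <- intersect(carbons, which(cls == cls[v]))
    dmin <- min(D[members_u, members_v, drop = FALSE][
      outer(members_u, members_v, `!=`)])
    if (dmin == n - 1L) sites[[length(sites) + 1L]] <- c(u, v)
  }
  if (!length(sites)) return(list())
  rot <- ((seq_along(sites) + (seed %% length(sites)) - 1L) %% length(sites)) + 1L
  lapply(sites[rot], function(s) list(kind = "HMBC", u = s[1], v = s[2], n = n))
}

#' Build the deterministic fixture suite
#'
#' Per corpus molecule: one clean case (ideal data), one case with a single
#' injected 4-bond HMBC (a non-standard correlation the elucidator is not
#' told about), and one noisy case (coordinate noise sd 0.03 ppm, 10%
#' COSY/HMBC drops). Same seed, byte-identical suite.
#'
#' @param seed Integer seed.
#' @return List of fixture cases: `list(name, kind, structure, options,
#'   simulated, truth, nsc)`.
#' @export
make_fixture_suite <- function(seed = 1L) {
  mols <- fixture_molecules()
  suite <- list()
  for (nm in names(mols)) {
    g <- mols[[nm]]
    truth <- canonical_key(g)
    clean_opts <- sim_options(seed = seed)
    suite[[length(suite) + 1L]] <- list(
      name = nm, kind = "clean", structure = g, options = clean_opts,
      simulated = simulate_correlations(g, clean_opts), truth = truth, nsc = NULL)
    # an injection qualifies as a non-standard-correlation case only if it
    # actually excludes the true constitution from the common-mode solution
    # set (in symmetric molecules a long-range response can alias onto an
    # admissible short-range one, leaving the data non-contradictory)
    for (site in pick_nsc_site(g, n = 4L, seed = seed)) {
      nsc_opts <- sim_options(nsc_injections = list(site), seed = seed)
      sim <- simulate_correlations(g, nsc_opts)
      mcd2 <- build_mcd(match_shifts(sim))
      if (!admits_assignment(g, mcd2)) {
        suite[[length(suite) + 1L]] <- list(
          name = nm, kind = "nsc", structure = g, options = nsc_opts,
          simulated = sim, truth = truth, nsc = site)
        break
      }
    }
    noisy_opts <- sim_options(drop_probability = 0.1, shift_noise_sd = 0.03,
                              seed = seed)
    suite[[length(suite) + 1L]] <- list(
      name = nm, kind = "noisy", structure = g, options = noisy_opts,
      simulated = simulate_correlations(g, noisy_opts), truth = truth, nsc = NULL)
  }
  suite
}
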