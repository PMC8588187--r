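# Independent oracles and fixture builders for the test suite.
# These deliberately avoid the package's own canonicalization/generation
# machinery wherever they are used to check it.

# --- backtracking isomorphism matcher (independent of canonical_key) -------

adjacency_with_orders <- function(g) {
  n <- length(g$elements)
  A <- matrix(0L, n, n)
  for (k in seq_len(nrow(g$bonds))) {
    A[g$bonds[k, "i"], g$bonds[k, "j"]] <- g$bonds[k, "order"]
    A[g$bonds[k, "j"], g$bonds[k, "i"]] <- g$bonds[k, "order"]
  }
  A
}

oracle_isomorphic <- function(g1, g2) {
  n <- length(g1$elements)
  if (length(g2$elements) != n) return(FALSE)
  lab1 <- paste(g1$elements, g1$hydrogens)
  lab2 <- paste(g2$elements, g2$hydrogens)
  if (!identical(sort(lab1), sort(lab2))) return(FALSE)
  A1 <- adjacency_with_orders(g1)
  A2 <- adjacency_with_orders(g2)
  if (!identical(sort(A1[upper.tri(A1)]), sort(A2[upper.tri(A2)]))) return(FALSE)
  map <- integer(n)       # map[i in g1] -> vertex of g2
  used <- logical(n)
  rec <- function(i) {
    if (i > n) return(TRUE)
    for (v in which(!used & lab2 == lab1[i])) {
      ok <- TRUE
      for (j in seq_len(i - 1L)) {
        if (A1[i, j] != A2[v, map[j]]) { ok <- FALSE; break }
      }
      if (ok) {
        map[i] <<- v; used[v] <<- TRUE
        if (rec(i + 1L)) return(TRUE)
        used[v] <<- FALSE
      }
    }
    FALSE
  }
  rec(1L)
}

# --- random connected molecular graphs -------------------------------------

random_molecule <- function(n, seed, elements = c("C", "C", "C", "N", "O")) {
  set.seed(seed)
  repeat {
    els <- sample(elements, n, replace = TRUE)
    val <- vapply(els, function(e) c(C = 4L, N = 3L, O = 2L)[[e]], integer(1))
    deg <- integer(n)
    bonds <- NULL
    ok <- TRUE
    # random spanning tree
    for (i in 2:n) {
      cand <- which(seq_len(n) < i & deg < val[seq_len(n)])
      cand <- cand[deg[cand] < val[cand]]
      if (!length(cand)) { ok <- FALSE; break }
      j <- if (length(cand) == 1L) cand else sample(cand, 1L)
      bonds <- rbind(bonds, c(j, i, 1L))
      deg[i] <- deg[i] + 1L; deg[j] <- deg[j] + 1L
    }
    if (!ok) next
    # sprinkle extra bonds / raise orders
    for (rep_k in seq_len(sample(0:2, 1L))) {
      free <- which(deg < val)
      if (length(free) < 2L) break
      p <- sample(free, 2L)
      ex <- which((bonds[, 1] == min(p) & bonds[, 2] == max(p)))
      if (length(ex)) {
        bonds[ex, 3] <- bonds[ex, 3] + 1L
        if (bonds[ex, 3] > 3L) { bonds[ex, 3] <- 3L; next }
      } else {
        bonds <- rbind(bonds, c(min(p), max(p), 1L))
      }
      deg[p] <- deg[p] + 1L
    }
    h <- val - deg
    if (any(h < 0L)) next
    colnames(bonds) <- c("i", "j", "order")
    return(molgraph(els, h, bonds))
  }
}

random_relabel <- function(g, seed) {
  set.seed(seed)
  perm <- sample(length(g$elements))
  casenmr:::relabel_graph(g, perm)
}

# --- exhaustive assignment oracle ------------------------------------------
# permutation matrices are cached per size so the n = 8 case (40320 rows)
# is enumerated once

perm_cache <- new.env(parent = emptyenv())

all_perms_matrix <- function(n) {
  key <- as.character(n)
  if (!exists(key, envir = perm_cache)) {
    rec <- function(v) {
      if (length(v) == 1L) return(matrix(v, 1L))
      out <- NULL
      for (k in seq_along(v))
        out <- rbind(out, cbind(v[k], rec(v[-k])))
      out
    }
    assign(key, rec(seq_len(n)), envir = perm_cache)
  }
  get(key, envir = perm_cache)
}

oracle_min_assignment <- function(pred, obs) {
  n <- length(pred)
  P <- all_perms_matrix(n)
  costs <- abs(matrix(obs[P], nrow(P)) -
               matrix(pred, nrow(P), n, byrow = TRUE))
  min(rowSums(costs)) / n
}

# --- shared fixtures --------------------------------------------------------

ethanol_graph <- function() {
  molgraph(c("C", "C", "O"), c(3L, 2L, 1L),
           rbind(c(1, 2, 1), c(2, 3, 1)),
           shifts = c(18.3, 57.8, NA))
}

dme_graph <- function() {
  molgraph(c("C", "O", "C"), c(3L, 0L, 3L),
           rbind(c(1, 2, 1), c(2, 3, 1)))
}

butane_graph <- function() {
  molgraph(rep("C", 4), c(3L, 2L, 2L, 3L),
           rbind(c(1, 2, 1), c(2, 3, 1), c(3, 4, 1)))
}

isobutane_graph <- function() {
  molgraph(rep("C", 4), c(3L, 1L, 3L, 3L),
           rbind(c(1, 2, 1), c(2, 3, 1), c(2, 4, 1)))
}

benzene_graph <- function() {
  molgraph(rep("C", 6), rep(1L, 6),
           rbind(c(1, 2, 2), c(2, 3, 1), c(3, 4, 2),
                 c(4, 5, 1), c(5, 6, 2), c(6, 1, 1)))
}

butene2_graph <- function() {
  molgraph(c("C", "C", "C", "C"), c(3L, 1L, 1L, 3L),
           rbind(c(1, 2, 1), c(2, 3, 2), c(3, 4, 1)))
}

# cached fixture corpus (SMILES conversion is not free)
fixture_cache <- new.env(parent = emptyenv())

cached_fixtures <- function() {
  if (!exists("mols", envir = fixture_cache))
    assign("mols", fixture_molecules(), envir = fixture_cache)
  get("mols", envir = fixture_cache)
}

cached_suite <- function(seed = 1L) {
  key <- paste0("suite", seed)
  if (!exists(key, envir = fixture_cache))
    assign(key, make_fixture_suite(seed), envir = fixture_cache)
  get(key, envir = fixture_cache)
}

cached_shift_db <- function() {
  if (!exists("db", envir = fixture_cache)) {
    mols <- cached_fixtures()
    hs <- lapply(mols, function(g)
      ifelse(g$elements == "C" & g$hydrogens > 0L,
             casenmr:::h_shift_of(g$shifts), NA_real_))
    assign("db", build_shift_db(unname(mols), h_shifts = unname(hs)),
           envir = fixture_cache)
  }
  get("db", envir = fixture_cache)
}
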