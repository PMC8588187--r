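# Environment-code ("HOSE-style") empirical 13C shift prediction.
#
# The code of a carbon at depth d is the canonical serialization of the
# induced subgraph on all atoms within d bonds, with the root atom marked;
# it is invariant under relabeling, and two carbons share a code exactly when
# their bonded environments to that depth are isomorphic.  A shift database
# stores count/mean/sd per (depth, code); prediction looks up depth 4 and
# falls back through 3, 2, 1.

ball_subgraph <- function(g, atom, depth) {
  D <- skeleton_distances(g)
  keep <- which(D[atom, ] <= depth)
  keep <- keep[order(keep)]
  remap <- integer(n_atoms(g)); remap[keep] <- seq_along(keep)
  b <- g$bonds
  sel <- b[, "i"] %in% keep & b[, "j"] %in% keep
  b <- b[sel, , drop = FALSE]
  if (nrow(b)) {
    b[, "i"] <- remap[b[, "i"]]; b[, "j"] <- remap[b[, "j"]]
  }
  list(graph = molgraph(g$elements[keep], g$hydrogens[keep], b,
                        valences = g$valences[keep], validate = FALSE),
       root = remap[atom])
}

canonical_key_rooted <- function(g, root) {
  tr <- canon_transform(g)
  colors <- tr$colors + 1L
  colors[root] <- 1L                      # distinguish the root
  perm <- igraph::canonical_permutation(tr$graph, colors = colors)$labeling
  n <- tr$n_atoms
  atom_rank <- rank(perm[seq_len(n)])
  lab <- paste0(g$elements, ":", g$hydrogens, ":", g$valences)
  lab[root] <- paste0(lab[root], ":*")
  atoms_sorted <- lab[order(atom_rank)]
  b <- g$bonds
  bonds_str <- character(0)
  if (nrow(b)) {
    ci <- atom_rank[b[, "i"]]; cj <- atom_rank[b[, "j"]]
    bonds_str <- sort(paste0(pmin(ci, cj), "-", pmax(ci, cj), ":", b[, "order"]))
  }
  paste(paste(atoms_sorted, collapse = ","),
        paste(bonds_str, collapse = ","), sep = "|")
}

#' Environment code of a carbon atom
#'
#' @param g A `molgraph`.
#' @param atom Carbon atom index.
#' @param depth Sphere depth, 1..4.
#' @return Canonical code string (depth-prefixed).
#' @export
hose_code <- function(g, atom, depth) {
  if (g$elements[atom] != "C") stop("environment codes are computed for carbon atoms")
  if (!depth %in% 1:4) stop("depth must be 1..4")
  ball <- ball_subgraph(g, atom, depth)
  paste0("d", depth, "/", canonical_key_rooted(ball$graph, ball$root))
}

new_shift_db <- function(provenance = "user") {
  structure(list(entries = new.env(parent = emptyenv()), provenance = provenance),
            class = "shift_db")
}

db_add <- function(db, code, shift, h_shift = NA_real_) {
  e <- db$entries
  cur <- if (exists(code, envir = e, inherits = FALSE)) get(code, envir = e) else
    list(n = 0L, mean = 0, M2 = 0, h_n = 0L, h_mean = 0)
  cur$n <- cur$n + 1L
  d <- shift - cur$mean
  cur$mean <- cur$mean + d / cur$n
  cur$M2 <- cur$M2 + d * (shift - cur$mean)
  if (!is.na(h_shift)) {
    cur$h_n <- cur$h_n + 1L
    cur$h_mean <- cur$h_mean + (h_shift - cur$h_mean) / cur$h_n
  }
  assign(code, cur, envir = e)
  invisible(db)
}

db_lookup <- function(db, code) {
  if (exists(code, envir = db$entries, inherits = FALSE))
    get(code, envir = db$entries) else NULL
}

#' Number of entries in a shift database
#' @param db A `shift_db`.
#' @return Integer count of (depth, code) entries.
#' @export
db_size <- function(db) length(ls(db$entries))

#' @export
print.shift_db <- function(x, ...) {
  cat(sprintf("<shift_db> %d environment-code entries (%s)\n", db_size(x),
              x$provenance))
  invisible(x)
}

#' Build a shift database from assigned structures
#'
#' Every carbon of every structure contributes one entry per depth 1..4
#' (running count, mean and sd per code). Proton shifts, when supplied,
#' are accumulated per code for 1H prediction.
#'
#' @param structures List of `molgraph` with complete 13C assignments
#'   (`$shifts`), or SDF path readable by [read_sdf()].
#' @param h_shifts Optional list of per-atom 1H shifts parallel to
#'   `structures` (NA where carbon carries no H).
#' @param provenance Tag recorded on the database.
#' @return A `shift_db`.
#' @export
build_shift_db <- function(structures, h_shifts = NULL, provenance = "user") {
  if (is.character(structures)) {
    recs <- read_sdf(structures)
    structures <- lapply(recs, `[[`, "graph")
  }
  db <- new_shift_db(provenance)
  for (si in seq_along(structures)) {
    g <- structures[[si]]
    carbons <- which(g$elements == "C")
    if (any(is.na(g$shifts[carbons])))
      stop(sprintf("structure %d has unassigned carbons", si))
    hs <- if (!is.null(h_shifts)) h_shifts[[si]] else rep(NA_real_, n_atoms(g))
    for (a in carbons) {
      for (d in 1:4)
        db_add(db, hose_code(g, a, d), g$shifts[a], hs[a])
    }
  }
  db
}

#' Predict 13C shifts by environment-code lookup
#'
#' For each carbon the depth-4 code is looked up, falling back through depths
#' 3, 2 and 1; the deepest hit's mean shift is returned. A carbon with no hit
#' at any depth receives the element-class default (110 ppm, the midpoint of
#' the 13C range) and is flagged with `matched_depth = 0`.
#'
#' @param g A `molgraph`.
#' @param db A `shift_db`.
#' @return Data frame with columns atom, shift, h_shift, matched_depth, n_obs.
#' @export
predict_c13_hose <- function(g, db) {
  carbons <- which(g$elements == "C")
  out <- data.frame(atom = carbons, shift = NA_real_, h_shift = NA_real_,
                    matched_depth = 0L, n_obs = 0L)
  for (k in seq_along(carbons)) {
    a <- carbons[k]
    for (d in 4:1) {
      hit <- db_lookup(db, hose_code(g, a, d))
      if (!is.null(hit)) {
        out$shift[k] <- hit$mean
        out$h_shift[k] <- if (hit$h_n > 0L) hit$h_mean else NA_real_
        out$matched_depth[k] <- d
        out$n_obs[k] <- hit$n
        break
      }
    }
    if (out$matched_depth[k] == 0L) out$shift[k] <- 110
  }
  out
}

#' Persist a shift database as a sorted text table
#' @param db A `shift_db`.
#' @param path Output path (columns: code, n, mean, sd, h_n, h_mean).
#' @return `path`, invisibly.
#' @export
write_shift_db <- function(db, path) {
  codes <- sort(ls(db$entries))
  rows <- vapply(codes, function(cd) {
    e <- get(cd, envir = db$entries)
    sd <- if (e$n > 1L) sqrt(e$M2 / (e$n - 1L)) else 0
    sprintf("%s\t%d\t%.4f\t%.4f\t%d\t%.4f", cd, e$n, e$mean, sd, e$h_n, e$h_mean)
  }, character(1))
  writeLines(c("code\tn\tmean\tsd\th_n\th_mean", rows), path)
  invisible(path)
}

#' Read a shift database written by [write_shift_db()]
#' @param path Text table path.
#' @return A `shift_db`.
#' @export
read_shift_db <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  db <- new_shift_db(provenance = path)
  for (i in seq_len(nrow(tab))) {
    e <- list(n = tab$n[i], mean = tab$mean[i],
              M2 = tab$sd[i]^2 * max(tab$n[i] - 1L, 0L),
              h_n = tab$h_n[i], h_mean = tab$h_mean[i])
    assign(tab$code[i], e, envir = db$entries)
  }
  db
}
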