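# The elucidation pipeline: read -> MCD -> consistency check -> common or
# fuzzy generation (auto-escalating m when the data are contradictory or
# yield nothing) -> verification/filtering -> ranking -> report.

#' Elucidation options
#'
#' @param gen [gen_options()].
#' @param fsg_a Elongation parameter for automatic fuzzy generation
#'   (16 = delete).
#' @param fsg_m_cap Maximum m for automatic escalation (m = 1, 2, ...).
#' @param k_accurate Candidates re-scored by the accurate method.
#' @param tol_c,tol_h Shift-matching tolerances (ppm).
#' @param respect_multiplicity Multiplicity-constrained assignment.
#' @return An `elucidate_options` list.
#' @export
elucidate_options <- function(gen = gen_options(), fsg_a = 1L, fsg_m_cap = 3L,
                              k_accurate = 50L, tol_c = 0.1, tol_h = 0.01,
                              respect_multiplicity = TRUE) {
  structure(list(gen = gen, fsg_a = as.integer(fsg_a),
                 fsg_m_cap = as.integer(fsg_m_cap),
                 k_accurate = as.integer(k_accurate),
                 tol_c = tol_c, tol_h = tol_h,
                 respect_multiplicity = isTRUE(respect_multiplicity)),
            class = "elucidate_options")
}

#' Run the full elucidation pipeline
#'
#' Builds the MCD from a correlation set, checks it for contradictions,
#' generates candidate structures (common mode when the data are consistent;
#' automatic fuzzy generation with m escalating 1, 2, ... up to the cap when
#' contradictions are detected or common mode returns nothing), audits every
#' candidate with [verify_candidate()], and ranks by the four-step protocol.
#'
#' @param set A `correlation_set` or path readable by
#'   [read_correlation_set()].
#' @param db Optional `shift_db` for accurate re-ranking.
#' @param fragment_db Optional fragment list from
#'   [build_user_fragment_db()]; found fragments are embedded and the
#'   fragment-restricted MCDs are generated from instead of the bare MCD.
#' @param fragment_cfg [fragment_config()].
#' @param options [elucidate_options()].
#' @param apct APCT table.
#' @return An `elucidation` object: ranked `candidates`, the `mcd`,
#'   `consistency` report, `mode` ("common", "fuzzy" or "fragment"),
#'   `fsg_result` (when fuzzy), and a run `log` data frame.
#' @export
elucidate <- function(set, db = NULL, fragment_db = NULL,
                      fragment_cfg = fragment_config(),
                      options = elucidate_options(), apct = load_apct()) {
  t_start <- proc.time()[["elapsed"]]
  log <- list()
  note <- function(stage, detail) {
    log[[length(log) + 1L]] <<- data.frame(
      stage = stage, detail = detail,
      elapsed = round(proc.time()[["elapsed"]] - t_start, 3))
  }
  if (is.character(set)) set <- read_correlation_set(set)
  set <- match_shifts(set, tol_c = options$tol_c, tol_h = options$tol_h)
  note("read", sprintf("%d 13C peaks, %d correlations",
                       nrow(set$peaks_c13), nrow(set$correlations)))
  mcd <- build_mcd(set, apct = apct)
  note("mcd", sprintf("%d atoms, %d constraints", nrow(mcd$atoms),
                      length(mcd$constraints)))
  consistency <- check_consistency(mcd)
  note("consistency", sprintf("feasible=%s suspicious=%d (stage %d)",
                              consistency$feasible,
                              length(consistency$suspicious_constraints),
                              consistency$stage))
  mode <- "common"
  fsg_result <- NULL
  structures <- list()
  if (!is.null(fragment_db)) {
    found <- search_fragments(fragment_db, set$peaks_c13,
                              mcd_peak_constraints(mcd), fragment_cfg)
    note("fragments", sprintf("%d found of %d", length(found), length(fragment_db)))
    variants <- if (length(found)) embed_fragments(mcd, found, fragment_cfg) else list()
    if (length(variants)) {
      mode <- "fragment"
      all_g <- list()
      for (v in variants) all_g <- c(all_g, generate(v, options$gen))
      structures <- dedup_graphs(all_g)
      note("generate", sprintf("fragment mode: %d MCDs -> %d unique",
                               length(variants), length(structures)))
    }
  }
  if (mode != "fragment") {
    if (consistency$feasible) {
      structures <- generate(mcd, options$gen)
      note("generate", sprintf("common mode: %d structures%s", length(structures),
                               if (attr(structures, "complete")) "" else " [incomplete]"))
    }
    if (!consistency$feasible || length(structures) == 0L) {
      mode <- "fuzzy"
      for (m in seq_len(options$fsg_m_cap)) {
        fz <- fuzzy_generate(mcd, fsg_options(m = m, a = options$fsg_a),
                             options$gen, consistency = consistency)
        note("fuzzy", sprintf("m=%d a=%d: %d unique (%d/%g combos)", m,
                              options$fsg_a, fz$result$k_unique,
                              fz$result$n_real, fz$result$n_math))
        if (fz$result$k_unique > 0L) { fsg_result <- fz$result; structures <- fz$structures; break }
        fsg_result <- fz$result
      }
    }
  }
  ok <- vapply(structures, function(g) verify_candidate(g, mcd)$ok, logical(1))
  if (mode == "fuzzy") ok[] <- TRUE   # fuzzy outputs satisfy their relaxed MCDs
  kept <- structures[ok]
  note("verify", sprintf("%d of %d pass audit", length(kept), length(structures)))
  ranked <- rank_candidates(kept, set$peaks_c13, db = db,
                            k_accurate = options$k_accurate,
                            observed_h1 = set$peaks_h1,
                            respect_multiplicity = options$respect_multiplicity)
  note("rank", sprintf("%d ranked; best d_I=%.2f%s", length(ranked),
                       if (length(ranked)) ranked[[1]]$d_I else NA,
                       if (isTRUE(attr(ranked, "suspicious")))
                         " [best d_A above suspicion threshold]" else ""))
  structure(list(candidates = ranked, mcd = mcd, consistency = consistency,
                 mode = mode, fsg_result = fsg_result, set = set,
                 log = do.call(rbind, log)),
            class = "elucidation")
}

#' @export
print.elucidation <- function(x, ...) {
  cat(sprintf("<elucidation> %s mode: %d ranked candidates\n", x$mode,
              length(x$candidates)))
  n <- min(5L, length(x$candidates))
  for (i in seq_len(n)) {
    cd <- x$candidates[[i]]
    cat(sprintf("  #%d  d_I=%.2f  d_A=%s  %s\n", cd$rank, cd$d_I,
                ifelse(is.na(cd$d_A), "-", sprintf("%.2f", cd$d_A)),
                format(graph_formula(cd$graph))))
  }
  invisible(x)
}
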