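# Assignment-based deviation between predicted and observed spectra,
# duplicate removal, and the four-step ranking protocol:
#   (1) fast incremental prediction, d_I for all candidates;
#   (2) duplicate removal keeping each family's best-assigned representative;
#   (3) sort by d_I;
#   (4) environment-code re-scoring (d_A, and d_H when 1H data are present)
#       of the top k candidates; final order d_A within the head.

carbon_multiplicities <- function(g) {
  carbons <- which(g$elements == "C")
  c("C", "CH", "CH2", "CH3")[pmin(g$hydrogens[carbons], 3L) + 1L]
}

expand_observed <- function(observed) {
  deg <- if (!is.null(observed$degeneracy)) observed$degeneracy else rep(1L, nrow(observed))
  idx <- rep(seq_len(nrow(observed)), deg)
  data.frame(shift = observed$shift[idx],
             multiplicity = if (!is.null(observed$multiplicity))
               observed$multiplicity[idx] else rep(NA_character_, length(idx)))
}

assign_block <- function(pred, obs) {
  if (!length(pred)) return(0)
  cost <- abs(outer(pred, obs, `-`))
  .cpp_assign(cost)$cost
}

#' Optimal-assignment deviation between predicted and observed shifts
#'
#' The mean absolute deviation minimized over all assignments of predicted to
#' observed peaks, solved as a min-cost bipartite assignment. When
#' multiplicities are respected (the default), CH3 predictions may only map
#' to CH3 peaks and so on; peaks whose multiplicity is undetermined fall back
#' to free assignment.
#'
#' @param predicted Numeric vector of predicted shifts (ppm).
#' @param observed Peak data frame (columns shift, multiplicity, degeneracy).
#' @param multiplicities Optional character vector parallel to `predicted`
#'   with classes C/CH/CH2/CH3.
#' @param respect_multiplicity Constrain the assignment within multiplicity
#'   classes (default `TRUE`).
#' @return Mean absolute deviation in ppm.
#' @export
deviation <- function(predicted, observed, multiplicities = NULL,
                      respect_multiplicity = TRUE) {
  obs <- expand_observed(observed)
  if (length(predicted) != nrow(obs))
    stop(sprintf("count mismatch: %d predicted vs %d observed",
                 length(predicted), nrow(obs)))
  n <- length(predicted)
  if (n == 0L) return(0)
  use_classes <- respect_multiplicity && !is.null(multiplicities) &&
    !anyNA(multiplicities) && !anyNA(obs$multiplicity)
  if (use_classes) {
    total <- 0
    for (cls in unique(multiplicities)) {
      p <- predicted[multiplicities == cls]
      o <- obs$shift[obs$multiplicity == cls]
      if (length(p) != length(o))
        stop(sprintf("count mismatch in multiplicity class %s: %d vs %d",
                     cls, length(p), length(o)))
      total <- total + assign_block(p, o)
    }
    extra <- setdiff(unique(obs$multiplicity), unique(multiplicities))
    if (length(extra))
      stop(sprintf("count mismatch in multiplicity class %s: 0 vs %d",
                   extra[1], sum(obs$multiplicity == extra[1])))
    total / n
  } else {
    assign_block(predicted, obs$shift) / n
  }
}

graph_d_I <- function(g, observed, increments, respect_multiplicity = TRUE) {
  pred <- predict_c13_incremental(g, increments)
  deviation(pred$shift, observed, carbon_multiplicities(g), respect_multiplicity)
}

graph_d_A <- function(g, observed, db, respect_multiplicity = TRUE) {
  pred <- predict_c13_hose(g, db)
  deviation(pred$shift, observed, carbon_multiplicities(g), respect_multiplicity)
}

# 1H deviation: one predicted value per protonated carbon (environment-code
# proton means), matched freely against the 1H peak list
graph_d_H <- function(g, observed_h1, db) {
  pred <- predict_c13_hose(g, db)
  ph <- pred$h_shift[!is.na(pred$h_shift)]
  obs <- expand_observed(observed_h1)
  if (length(ph) != nrow(obs)) return(NA_real_)
  if (!length(ph)) return(NA_real_)
  assign_block(ph, obs$shift) / length(ph)
}

#' Remove duplicate structures, keeping each family's best representative
#'
#' Structures are grouped by canonical key; within a family the member with
#' the lowest fast-method deviation d_I is retained (its assignment best
#' matches the observed spectrum), at the position where the family first
#' appeared.
#'
#' @param candidates List of `molgraph`, or of lists with `graph` and `d_I`.
#' @param observed 13C peak data frame (used to compute d_I when missing).
#' @param increments Increment table.
#' @param respect_multiplicity Passed to [deviation()].
#' @return List of `list(graph, d_I)`, deduplicated.
#' @export
remove_duplicates <- function(candidates, observed,
                              increments = load_increments(),
                              respect_multiplicity = TRUE) {
  if (!length(candidates)) return(list())
  cands <- lapply(candidates, function(cd) {
    if (inherits(cd, "molgraph")) cd <- list(graph = cd, d_I = NA_real_)
    if (is.na(cd$d_I))
      cd$d_I <- graph_d_I(cd$graph, observed, increments, respect_multiplicity)
    cd
  })
  keys <- vapply(cands, function(cd) canonical_key(cd$graph), character(1))
  out <- list()
  pos <- integer(0)
  for (i in seq_along(cands)) {
    k <- keys[i]
    if (k %in% names(pos)) {
      j <- pos[[k]]
      if (cands[[i]]$d_I < out[[j]]$d_I) out[[j]] <- cands[[i]]
    } else {
      out[[length(out) + 1L]] <- cands[[i]]
      pos[[k]] <- length(out)
    }
  }
  out
}

#' Rank candidate structures against an observed spectrum
#'
#' The four-step protocol: d_I by the fast incremental method for every
#' candidate; duplicate removal by best representative; sort by d_I; then
#' environment-code re-scoring of the top `k_accurate` candidates, which are
#' re-ordered by d_A (the tail keeps its d_I order). d_H is added for the
#' head when a 1H peak list is given. A candidate whose d_A exceeds the
#' suspicion threshold is flagged: a large d_A on the first-ranked structure
#' is indirect evidence of undetected non-standard correlations.
#'
#' @param candidates List of `molgraph`.
#' @param observed 13C peak data frame.
#' @param db `shift_db` for the accurate method (skipped when `NULL`).
#' @param k_accurate Number of head candidates re-scored (default 50).
#' @param observed_h1 Optional 1H peak data frame.
#' @param increments Increment table.
#' @param suspicion_threshold d_A threshold in ppm for the suspicious flag
#'   (default 5.5).
#' @param respect_multiplicity Passed to [deviation()].
#' @return List of ranked candidates `list(graph, d_I, d_A, d_H, rank,
#'   suspicious)`, best first; attribute `suspicious` is `TRUE` when the
#'   best candidate's d_A exceeds the threshold.
#' @export
rank_candidates <- function(candidates, observed, db = NULL, k_accurate = 50L,
                            observed_h1 = NULL, increments = load_increments(),
                            suspicion_threshold = 5.5,
                            respect_multiplicity = TRUE) {
  if (!length(candidates)) return(structure(list(), suspicious = FALSE))
  dedup <- remove_duplicates(candidates, observed, increments,
                             respect_multiplicity)
  keys <- vapply(dedup, function(cd) canonical_key(cd$graph), character(1))
  ord <- order(vapply(dedup, `[[`, numeric(1), "d_I"), keys)
  dedup <- dedup[ord]; keys <- keys[ord]
  k <- min(k_accurate, length(dedup))
  if (!is.null(db) && k > 0L) {
    head_idx <- seq_len(k)
    dA <- vapply(head_idx, function(i)
      graph_d_A(dedup[[i]]$graph, observed, db, respect_multiplicity), numeric(1))
    dH <- if (!is.null(observed_h1))
      vapply(head_idx, function(i) graph_d_H(dedup[[i]]$graph, observed_h1, db),
             numeric(1)) else rep(NA_real_, k)
    ho <- order(dA, vapply(head_idx, function(i) dedup[[i]]$d_I, numeric(1)),
                keys[head_idx])
    reord <- c(head_idx[ho], setdiff(seq_along(dedup), head_idx))
    dedup <- dedup[reord]
    dA_full <- c(dA[ho], rep(NA_real_, length(dedup) - k))
    dH_full <- c(dH[ho], rep(NA_real_, length(dedup) - k))
  } else {
    dA_full <- rep(NA_real_, length(dedup))
    dH_full <- rep(NA_real_, length(dedup))
  }
  out <- lapply(seq_along(dedup), function(i)
    list(graph = dedup[[i]]$graph, d_I = dedup[[i]]$d_I, d_A = dA_full[i],
         d_H = dH_full[i], rank = i,
         suspicious = !is.na(dA_full[i]) && dA_full[i] > suspicion_threshold))
  attr(out, "suspicious") <- length(out) > 0L && isTRUE(out[[1]]$suspicious)
  out
}
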