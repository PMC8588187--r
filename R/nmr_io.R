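# 1D peak tables and 2D correlation tables in a small documented CSV dialect.
#
# File format (one header line, then records; fields beyond a record's arity
# may be left empty):
#   record,f1,f2,f3,f4
#   formula,C10H14,,,
#   C13,21.3,CH3,100,1        # shift, multiplicity, intensity, degeneracy
#   H1,2.31,95,2,             # shift, intensity, degeneracy
#   HSQC,2.31,21.3,strong,    # 1H shift, 13C shift, intensity class
#   COSY,2.31,7.05,strong,    # 1H, 1H
#   HMBC,2.31,137.8,weak,     # 1H, 13C
#   HN_HMBC,8.11,120.4,strong # 1H, 15N
#   NOESY,2.31,7.05,strong
#   policy,COSY,strong,2,3    # bond-range override (kind, class, lo, hi)
#
# The default bond-range policy: COSY 2-3 bonds for strong peaks, 3-4 for
# weak ones; HMBC 2-3 bonds.

.CORR_KINDS <- c("HSQC", "COSY", "HMBC", "HN_HMBC", "NOESY")
.INTENSITY_CLASSES <- c("strong", "weak", "undefined")
.C13_MULTS <- c("C", "CH", "CH2", "CH3")

#' Default coupling-length policy
#'
#' Bond-range intervals assumed for 2D correlations: COSY 2-3 bonds (strong)
#' and 3-4 bonds (weak); HMBC 2-3 bonds regardless of intensity.
#'
#' @return Named list mapping `"KIND.class"` to `c(lo, hi)` in bonds.
#' @export
default_bond_policy <- function() {
  list(COSY.strong = c(2L, 3L), COSY.weak = c(3L, 4L), COSY.undefined = c(2L, 3L),
       HMBC.strong = c(2L, 3L), HMBC.weak = c(2L, 3L), HMBC.undefined = c(2L, 3L),
       HN_HMBC.strong = c(2L, 3L), HN_HMBC.weak = c(2L, 3L),
       HN_HMBC.undefined = c(2L, 3L))
}

empty_peaks_c13 <- function() {
  data.frame(shift = numeric(0), multiplicity = character(0),
             intensity = numeric(0), degeneracy = integer(0))
}

empty_peaks_h1 <- function() {
  data.frame(shift = numeric(0), intensity = numeric(0), degeneracy = integer(0))
}

empty_correlations <- function() {
  data.frame(kind = character(0), shift_a = numeric(0), shift_b = numeric(0),
             intensity_class = character(0))
}

#' Assemble a correlation set
#'
#' @param formula A `molformula` (or formula string).
#' @param peaks_c13 Data frame with columns shift, multiplicity, intensity,
#'   degeneracy.
#' @param peaks_h1 Data frame with columns shift, intensity, degeneracy.
#' @param correlations Data frame with columns kind, shift_a, shift_b,
#'   intensity_class.
#' @param policy Bond-range policy; defaults to [default_bond_policy()].
#' @return An object of class `correlation_set`.
#' @export
correlation_set <- function(formula, peaks_c13 = empty_peaks_c13(),
                            peaks_h1 = empty_peaks_h1(),
                            correlations = empty_correlations(),
                            policy = default_bond_policy()) {
  if (is.character(formula)) formula <- parse_formula(formula)
  peaks_c13$degeneracy <- if (nrow(peaks_c13) && !is.null(peaks_c13$degeneracy))
    as.integer(ifelse(is.na(peaks_c13$degeneracy), 1L, peaks_c13$degeneracy)) else
      rep(1L, nrow(peaks_c13))
  peaks_h1$degeneracy <- if (nrow(peaks_h1) && !is.null(peaks_h1$degeneracy))
    as.integer(ifelse(is.na(peaks_h1$degeneracy), 1L, peaks_h1$degeneracy)) else
      rep(1L, nrow(peaks_h1))
  if (nrow(peaks_c13) && !all(peaks_c13$multiplicity %in% c(.C13_MULTS, NA)))
    stop("carbon multiplicity must be C, CH, CH2, CH3 or NA")
  if (nrow(correlations)) {
    bad <- which(!correlations$kind %in% .CORR_KINDS)
    if (length(bad)) stop(sprintf("unknown correlation kind '%s'", correlations$kind[bad[1]]))
    if (any(!is.finite(correlations$shift_a)) || any(!is.finite(correlations$shift_b)))
      stop("correlation shifts must be finite")
  }
  structure(list(formula = formula, peaks_c13 = peaks_c13, peaks_h1 = peaks_h1,
                 correlations = correlations, policy = policy),
            class = "correlation_set")
}

#' @export
print.correlation_set <- function(x, ...) {
  cat(sprintf("<correlation_set> %s: %d 13C peaks, %d 1H peaks, %d correlations\n",
              format(x$formula), nrow(x$peaks_c13), nrow(x$peaks_h1),
              nrow(x$correlations)))
  invisible(x)
}

num_field <- function(x, what, lineno) {
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v)) stop(sprintf("line %d: non-numeric %s '%s'", lineno, what, x))
  v
}

#' Read a correlation table file
#'
#' Parses the package's CSV dialect (see the format comment in this file and
#' the methods vignette). Unknown record kinds and malformed numbers raise
#' line-numbered errors; `policy` records override the default bond-range
#' policy.
#'
#' @param path File path.
#' @return A `correlation_set`.
#' @export
read_correlation_set <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  if (length(lines) < 1L) stop("empty correlation file")
  formula <- NULL
  c13 <- list(); h1 <- list(); corr <- list()
  policy <- default_bond_policy()
  for (li in seq_along(lines)[-1]) {         # first line is the header
    f <- trimws(strsplit(lines[li], ",", fixed = TRUE)[[1]])
    kind <- f[1]
    if (kind == "formula") {
      formula <- parse_formula(f[2])
    } else if (kind == "C13") {
      mult <- if (length(f) >= 3L && nzchar(f[3])) f[3] else NA_character_
      if (!is.na(mult) && !mult %in% .C13_MULTS)
        stop(sprintf("line %d: bad carbon multiplicity '%s'", li, mult))
      c13[[length(c13) + 1L]] <- data.frame(
        shift = num_field(f[2], "shift", li), multiplicity = mult,
        intensity = if (length(f) >= 4L && nzchar(f[4])) num_field(f[4], "intensity", li) else 1,
        degeneracy = if (length(f) >= 5L && nzchar(f[5])) as.integer(f[5]) else 1L)
    } else if (kind == "H1") {
      h1[[length(h1) + 1L]] <- data.frame(
        shift = num_field(f[2], "shift", li),
        intensity = if (length(f) >= 3L && nzchar(f[3])) num_field(f[3], "intensity", li) else 1,
        degeneracy = if (length(f) >= 4L && nzchar(f[4])) as.integer(f[4]) else 1L)
    } else if (kind %in% .CORR_KINDS) {
      cls <- if (length(f) >= 4L && nzchar(f[4])) f[4] else "undefined"
      if (!cls %in% .INTENSITY_CLASSES)
        stop(sprintf("line %d: bad intensity class '%s'", li, cls))
      corr[[length(corr) + 1L]] <- data.frame(
        kind = kind, shift_a = num_field(f[2], "shift", li),
        shift_b = num_field(f[3], "shift", li), intensity_class = cls)
    } else if (kind == "policy") {
      key <- paste(f[2], f[3], sep = ".")
      policy[[key]] <- c(as.integer(f[4]), as.integer(f[5]))
    } else {
      stop(sprintf("line %d: unknown record kind '%s'", li, kind))
    }
  }
  if (is.null(formula)) stop("correlation file must contain a formula record")
  correlation_set(formula,
                  if (length(c13)) do.call(rbind, c13) else empty_peaks_c13(),
                  if (length(h1)) do.call(rbind, h1) else empty_peaks_h1(),
                  if (length(corr)) do.call(rbind, corr) else empty_correlations(),
                  policy)
}

#' Write a correlation set to the CSV dialect
#' @param set A `correlation_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_correlation_set <- function(set, path) {
  out <- "record,f1,f2,f3,f4"
  out <- c(out, sprintf("formula,%s,,,", format(set$formula)))
  for (i in seq_len(nrow(set$peaks_c13))) {
    p <- set$peaks_c13[i, ]
    out <- c(out, sprintf("C13,%.6f,%s,%g,%d", p$shift,
                          ifelse(is.na(p$multiplicity), "", p$multiplicity),
                          p$intensity, p$degeneracy))
  }
  for (i in seq_len(nrow(set$peaks_h1))) {
    p <- set$peaks_h1[i, ]
    out <- c(out, sprintf("H1,%.6f,%g,%d,", p$shift, p$intensity, p$degeneracy))
  }
  for (i in seq_len(nrow(set$correlations))) {
    r <- set$correlations[i, ]
    out <- c(out, sprintf("%s,%.6f,%.6f,%s,", r$kind, r$shift_a, r$shift_b,
                          r$intensity_class))
  }
  def <- default_bond_policy()
  for (key in names(set$policy)) {
    if (!identical(set$policy[[key]], def[[key]])) {
      kc <- strsplit(key, ".", fixed = TRUE)[[1]]
      out <- c(out, sprintf("policy,%s,%s,%d,%d", kc[1], kc[2],
                            set$policy[[key]][1], set$policy[[key]][2]))
    }
  }
  writeLines(out, path)
  invisible(path)
}

nearest_peaks <- function(coord, shifts, tol) {
  d <- abs(shifts - coord)
  which(d <= tol + 1e-12)
}

#' Snap 2D correlation coordinates to 1D peaks
#'
#' Every 2D coordinate is matched to the nearest 1D peak within tolerance.
#' When two or more peaks lie within tolerance the correlation is marked
#' ambiguous (all candidate peak ids recorded) rather than silently resolved.
#'
#' @param set A `correlation_set`.
#' @param tol_c 13C matching tolerance in ppm (default 0.1).
#' @param tol_h 1H matching tolerance in ppm (default 0.01).
#' @param tol_n 15N matching tolerance in ppm (default 0.2); 15N coordinates
#'   are carried through unmatched when no 15N peak list is present.
#' @return The set with columns `a_peaks`, `b_peaks` (comma-joined candidate
#'   peak indices into the 1H/13C tables) and `ambiguous` added to
#'   `$correlations`.
#' @export
match_shifts <- function(set, tol_c = 0.1, tol_h = 0.01, tol_n = 0.2) {
  co <- set$correlations
  if (!nrow(co)) {
    set$resolved <- TRUE
    return(set)
  }
  if (!nrow(set$peaks_h1) && any(co$kind %in% c("COSY", "HSQC", "HMBC", "HN_HMBC", "NOESY")))
    stop("cannot match correlations without a 1H peak list")
  a_peaks <- character(nrow(co)); b_peaks <- character(nrow(co))
  ambiguous <- logical(nrow(co))
  for (i in seq_len(nrow(co))) {
    k <- co$kind[i]
    ida <- nearest_peaks(co$shift_a[i], set$peaks_h1$shift, tol_h)
    if (!length(ida))
      stop(sprintf("correlation %d (%s): no 1H peak within %.3g ppm of %.3f",
                   i, k, tol_h, co$shift_a[i]))
    if (k %in% c("COSY", "NOESY")) {
      idb <- nearest_peaks(co$shift_b[i], set$peaks_h1$shift, tol_h)
      if (!length(idb))
        stop(sprintf("correlation %d (%s): no 1H peak within %.3g ppm of %.3f",
                     i, k, tol_h, co$shift_b[i]))
    } else if (k == "HN_HMBC") {
      idb <- integer(0)                      # 15N coordinates pass through
    } else {
      idb <- nearest_peaks(co$shift_b[i], set$peaks_c13$shift, tol_c)
      if (!length(idb))
        stop(sprintf("correlation %d (%s): no 13C peak within %.3g ppm of %.3f",
                     i, k, tol_c, co$shift_b[i]))
    }
    a_peaks[i] <- paste(ida, collapse = ",")
    b_peaks[i] <- paste(idb, collapse = ",")
    ambiguous[i] <- length(ida) > 1L || length(idb) > 1L
  }
  co$a_peaks <- a_peaks; co$b_peaks <- b_peaks; co$ambiguous <- ambiguous
  # HSQC sanity: a carbon cannot carry more distinct 1H multiplets than H atoms
  hs <- co[co$kind == "HSQC" & !co$ambiguous, , drop = FALSE]
  if (nrow(hs)) {
    for (cb in unique(hs$b_peaks)) {
      ci <- as.integer(cb)
      nh <- length(unique(hs$a_peaks[hs$b_peaks == cb]))
      mult <- set$peaks_c13$multiplicity[ci]
      hmax <- c(C = 0L, CH = 1L, CH2 = 2L, CH3 = 3L)[mult]
      if (!is.na(hmax) && nh > hmax)
        stop(sprintf("carbon peak %d (%s) carries %d HSQC protons, more than its H count",
                     ci, mult, nh))
    }
  }
  set$correlations <- co
  set$resolved <- TRUE
  set
}

#' Write ranked candidates to SDF with a summary table
#'
#' One SDF record per candidate carrying RANK, D_I, D_A, D_H and SUSPICIOUS
#' data fields, in rank order; a CSV summary is written alongside when `csv`
#' is given. An empty candidate list produces an empty file with a warning.
#'
#' @param candidates List of ranked candidates from [rank_candidates()].
#' @param path Output SDF path.
#' @param csv Optional CSV path for the summary table.
#' @return Summary data frame, invisibly.
#' @export
write_report <- function(candidates, path, csv = NULL) {
  if (!length(candidates)) {
    warning("no candidates to report; writing empty file")
    writeLines(character(0), path)
    if (!is.null(csv)) utils::write.csv(data.frame(), csv, row.names = FALSE)
    return(invisible(data.frame()))
  }
  graphs <- lapply(candidates, `[[`, "graph")
  fmt_dev <- function(x) ifelse(is.na(x), "NA", sprintf("%.4f", x))
  data <- lapply(candidates, function(cd)
    c(RANK = as.character(cd$rank), D_I = fmt_dev(cd$d_I), D_A = fmt_dev(cd$d_A),
      D_H = fmt_dev(cd$d_H), SUSPICIOUS = as.character(isTRUE(cd$suspicious))))
  titles <- sprintf("rank_%d", vapply(candidates, `[[`, numeric(1), "rank"))
  write_sdf(graphs, path, data = data, titles = titles)
  summary <- data.frame(rank = vapply(candidates, `[[`, numeric(1), "rank"),
                        d_I = vapply(candidates, `[[`, numeric(1), "d_I"),
                        d_A = vapply(candidates, function(x) x$d_A %||% NA_real_, numeric(1)),
                        d_H = vapply(candidates, function(x) x$d_H %||% NA_real_, numeric(1)),
                        key = vapply(candidates, function(x) canonical_key(x$graph), character(1)))
  if (!is.null(csv)) utils::write.csv(summary, csv, row.names = FALSE)
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a
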