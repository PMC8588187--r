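#' @useDynLib casenmr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Nominal (principal-isotope) masses and default valences for the element set
# the engine handles.  S and P are accepted through the valence extension in
# molgraph(); they are not part of the default generation alphabet.
.ELEMENTS <- list(
  C = list(mass = 12, valence = 4L),
  H = list(mass = 1,  valence = 1L),
  N = list(mass = 14, valence = 3L),
  O = list(mass = 16, valence = 2L),
  F = list(mass = 19, valence = 1L),
  Cl = list(mass = 35, valence = 1L),
  Br = list(mass = 79, valence = 1L),
  I = list(mass = 127, valence = 1L),
  S = list(mass = 32, valence = 2L),
  P = list(mass = 31, valence = 3L)
)

.HALOGENS <- c("F", "Cl", "Br", "I")

#' Parse a Hill-notation molecular formula
#'
#' Parses strings such as `"C32H22N4O"` into a named count vector. Element
#' symbols must belong to the supported set (C, H, N, O, F, Cl, Br, I, S, P);
#' anything else is an error naming the offending token.
#'
#' @param text Formula string in Hill-style notation, e.g. `"C2H6O"`.
#' @return An object of class `molformula`: a named integer vector of element
#'   counts.
#' @examples
#' parse_formula("C32H22N4O")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    stop("formula must be a single non-empty string")
  s <- gsub("[[:space:]]", "", text)
  tokens <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1]]
  matched <- regmatches(s, gregexpr("([A-Z][a-z]?)([0-9]*)", s))[[1]]
  if (sum(nchar(matched)) != nchar(s))
    stop(sprintf("malformed formula '%s': unparseable characters", text))
  counts <- integer(0)
  for (tok in matched) {
    el <- sub("[0-9]+$", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!el %in% names(.ELEMENTS))
      stop(sprintf("unknown element symbol '%s' in formula '%s'", el, text))
    counts[el] <- (if (el %in% names(counts)) counts[el] else 0L) + n
  }
  if (sum(counts[setdiff(names(counts), "H")]) < 1L)
    stop("formula must contain at least one non-hydrogen atom")
  class(counts) <- "molformula"
  counts
}

#' @export
format.molformula <- function(x, ...) {
  els <- names(x)
  # Hill order: C, H, then alphabetical
  ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  paste0(vapply(ord, function(e) {
    if (x[[e]] == 0L) "" else if (x[[e]] == 1L) e else paste0(e, x[[e]])
  }, ""), collapse = "")
}

#' @export
print.molformula <- function(x, ...) {
  cat("<molformula>", format(x), "\n")
  invisible(x)
}

formula_count <- function(f, el) {
  if (el %in% names(f)) as.integer(f[[el]]) else 0L
}

#' Nominal (integer) molecular mass
#'
#' Sum of principal-isotope nominal masses, e.g. 478 u for C32H22N4O
#' (so the protonated ion MH+ appears at 479).
#'
#' @param f A `molformula` (or a string, parsed on the fly).
#' @return Integer mass in u.
#' @export
nominal_mass <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  sum(vapply(names(f), function(e) .ELEMENTS[[e]]$mass * f[[e]], numeric(1)))
}

#' Degree of unsaturation (double-bond equivalents)
#'
#' DBE = (2C + 2 + N - H - X)/2 with X the halogen count. A half-integer
#' result indicates a radical or an inconsistent formula and is returned
#' with a warning rather than an error; a negative DBE is an error.
#'
#' @param f A `molformula` (or a string).
#' @return DBE as a (possibly half-integer) numeric.
#' @export
degree_of_unsaturation <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  x <- sum(vapply(.HALOGENS, function(e) formula_count(f, e), numeric(1)))
  dbe <- (2 * formula_count(f, "C") + 2 + formula_count(f, "N") -
            formula_count(f, "H") - x) / 2
  if (dbe < 0)
    stop(sprintf("infeasible formula %s: negative degree of unsaturation", format(f)))
  if (dbe %% 1 != 0)
    warning(sprintf("half-integer DBE (%.1f) for %s: radical or inconsistent formula",
                    dbe, format(f)))
  dbe
}
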