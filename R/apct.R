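# Atom Property Correlation Table: maps a 13C shift (and optional DEPT/HSQC
# multiplicity) to the hybridization possibilities and hetero-neighbor flag
# of the carbon.  The packaged table lives in inst/apct.yaml and is config,
# not code.

.HYB_BITS <- c(sp3 = 1L, sp2 = 2L, sp = 4L)
.HYB_ALL <- 7L

hyb_mask <- function(hybs) {
  if (!length(hybs)) return(.HYB_ALL)
  sum(.HYB_BITS[match(hybs, names(.HYB_BITS))])
}

hyb_set <- function(mask) names(.HYB_BITS)[bitwAnd(mask, .HYB_BITS) != 0L]

.HETERO_CODE <- c(undefined = 0L, fb = 1L, ob = 2L)

#' Load an APCT rule table
#'
#' @param path YAML file; defaults to the packaged table.
#' @return A list of rules usable by [apply_apct()].
#' @export
load_apct <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("apct.yaml", package = "casenmr", mustWork = TRUE)
  tab <- yaml::read_yaml(path)
  stopifnot(is.list(tab$rules), length(tab$rules) >= 1L)
  for (r in c(tab$rules, tab$mult_rules)) {
    if (r$lo >= r$hi) stop("APCT rule must have lo < hi")
    if (!all(unlist(r["hyb"]) %in% names(.HYB_BITS))) stop("bad hybridization in APCT")
  }
  tab
}

rule_matches <- function(r, shift, multiplicity, last_hi) {
  inlo <- shift >= r$lo
  inhi <- if (r$hi >= last_hi) shift <= r$hi else shift < r$hi
  if (!(inlo && inhi)) return(FALSE)
  if (!is.null(r$mult) && (is.null(multiplicity) || is.na(multiplicity) ||
                           r$mult != multiplicity)) return(FALSE)
  TRUE
}

#' Assign atom properties from a 13C chemical shift
#'
#' Intersects all matching shift-range rules of the APCT. A shift outside
#' 0-240 ppm yields fully undefined properties with a warning.
#'
#' @param shift 13C shift in ppm.
#' @param multiplicity Optional carbon multiplicity (`"C"`, `"CH"`, `"CH2"`,
#'   `"CH3"`).
#' @param table APCT table from [load_apct()].
#' @return `list(hyb = character subset of c("sp3","sp2","sp"),
#'   hetero = "undefined"|"fb"|"ob")`.
#' @export
apply_apct <- function(shift, multiplicity = NULL, table = load_apct()) {
  if (is.na(shift) || shift < 0 || shift > 240) {
    if (!is.na(shift))
      warning(sprintf("shift %.1f ppm outside APCT domain 0-240; properties undefined", shift))
    return(list(hyb = names(.HYB_BITS), hetero = "undefined"))
  }
  rules <- c(table$rules, table$mult_rules)
  last_hi <- max(vapply(table$rules, function(r) r$hi, numeric(1)))
  mask <- .HYB_ALL
  hetero <- character(0)
  for (r in rules) {
    if (!rule_matches(r, shift, multiplicity, last_hi)) next
    mask <- bitwAnd(mask, hyb_mask(unlist(r["hyb"], use.names = FALSE)))
    if (!is.null(r$hetero) && r$hetero != "undefined") hetero <- c(hetero, r$hetero)
  }
  if (mask == 0L) stop("APCT rules intersect to an empty hybridization set")
  hetero <- unique(hetero)
  list(hyb = hyb_set(mask),
       hetero = if (length(hetero) == 1L) hetero else "undefined")
}
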