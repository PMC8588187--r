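# Molfile / SDF V2000 read and write for molgraph objects.
#
# Heavy atoms only are written; hydrogens are implicit (the molfile valence
# field is set when an atom uses a non-default valence).  Assigned 13C shifts
# travel in a "PPM_C13" SDF data field as space-separated atom-index:shift
# pairs.  Explicit hydrogens in input files are folded into the attached-H
# count of their heavy neighbor.

fmt_atom_line <- function(element, valence_override) {
  sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0%3d  0  0  0  0  0",
          0, 0, 0, element, valence_override)
}

molfile_block <- function(g, title = "") {
  n <- n_atoms(g)
  nb <- nrow(g$bonds)
  vdef <- default_valence(g$elements)
  vover <- ifelse(g$valences == vdef, 0L,
                  ifelse(g$valences == 0L, 15L, g$valences))
  lines <- c(title, "  casenmr", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
  for (a in seq_len(n)) lines <- c(lines, fmt_atom_line(g$elements[a], vover[a]))
  for (k in seq_len(nb))
    lines <- c(lines, sprintf("%3d%3d%3d  0",
                              g$bonds[k, "i"], g$bonds[k, "j"], g$bonds[k, "order"]))
  c(lines, "M  END")
}

shift_field <- function(g) {
  idx <- which(!is.na(g$shifts))
  if (!length(idx)) return(NULL)
  paste(sprintf("%d:%.4f", idx, g$shifts[idx]), collapse = " ")
}

#' Write molecular graphs to an SDF file
#'
#' @param graphs A `molgraph` or list of them.
#' @param path Output file path.
#' @param data Optional list (one element per graph) of named character/numeric
#'   vectors written as SDF data fields.
#' @param titles Optional character vector of record titles.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(graphs, path, data = NULL, titles = NULL) {
  if (inherits(graphs, "molgraph")) graphs <- list(graphs)
  out <- character(0)
  for (i in seq_along(graphs)) {
    g <- graphs[[i]]
    title <- if (!is.null(titles)) titles[i] else sprintf("mol_%d", i)
    out <- c(out, molfile_block(g, title))
    fields <- list()
    sf <- shift_field(g)
    if (!is.null(sf)) fields[["PPM_C13"]] <- sf
    if (!is.null(data) && length(data) >= i && length(data[[i]]))
      for (nm in names(data[[i]])) fields[[nm]] <- format(data[[i]][[nm]])
    for (nm in names(fields))
      out <- c(out, sprintf("> <%s>", nm), as.character(fields[[nm]]), "")
    out <- c(out, "$$$$")
  }
  writeLines(out, path)
  invisible(path)
}

parse_molfile_lines <- function(lines, fold_hydrogens = TRUE) {
  if (length(lines) < 4L) stop("truncated molfile block")
  counts <- lines[4]
  n <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  if (is.na(n) || is.na(nb)) stop("malformed molfile counts line")
  elements <- character(n); vover <- integer(n)
  for (a in seq_len(n)) {
    ln <- lines[4 + a]
    elements[a] <- trimws(substr(ln, 32, 34))
    v <- suppressWarnings(as.integer(substr(ln, 49, 51)))
    vover[a] <- if (is.na(v)) 0L else v
  }
  bonds <- matrix(integer(0), ncol = 3L,
                  dimnames = list(NULL, c("i", "j", "order")))
  if (nb > 0L) {
    bonds <- t(vapply(seq_len(nb), function(k) {
      ln <- lines[4 + n + k]
      c(as.integer(substr(ln, 1, 3)), as.integer(substr(ln, 4, 6)),
        as.integer(substr(ln, 7, 9)))
    }, integer(3)))
    colnames(bonds) <- c("i", "j", "order")
  }
  valences <- default_valence_or_na(elements)
  valences[vover > 0L & vover < 15L] <- vover[vover > 0L & vover < 15L]
  valences[vover == 15L] <- 0L
  deg <- integer(n)
  for (k in seq_len(nrow(bonds))) {
    deg[bonds[k, 1]] <- deg[bonds[k, 1]] + bonds[k, 3]
    deg[bonds[k, 2]] <- deg[bonds[k, 2]] + bonds[k, 3]
  }
  hydrogens <- pmax(valences - deg, 0L)
  if (fold_hydrogens && any(elements == "H")) {
    hidx <- which(elements == "H")
    keep <- setdiff(seq_len(n), hidx)
    remap <- integer(n); remap[keep] <- seq_along(keep)
    extraH <- integer(length(keep))
    keepbonds <- matrix(integer(0), ncol = 3L)
    for (k in seq_len(nrow(bonds))) {
      i <- bonds[k, 1]; j <- bonds[k, 2]
      if (elements[i] == "H" && elements[j] == "H")
        stop("H-H bond unsupported")
      if (elements[i] == "H") extraH[remap[j]] <- extraH[remap[j]] + 1L
      else if (elements[j] == "H") extraH[remap[i]] <- extraH[remap[i]] + 1L
      else keepbonds <- rbind(keepbonds, c(remap[i], remap[j], bonds[k, 3]))
    }
    elements <- elements[keep]
    deg2 <- integer(length(keep))
    for (k in seq_len(nrow(keepbonds))) {
      deg2[keepbonds[k, 1]] <- deg2[keepbonds[k, 1]] + keepbonds[k, 3]
      deg2[keepbonds[k, 2]] <- deg2[keepbonds[k, 2]] + keepbonds[k, 3]
    }
    valences <- valences[keep]
    hydrogens <- pmax(valences - deg2, 0L)
    bonds <- keepbonds
    if (nrow(bonds)) colnames(bonds) <- c("i", "j", "order")
  }
  molgraph(elements, hydrogens, bonds, valences = valences)
}

default_valence_or_na <- function(elements) {
  vapply(elements, function(e)
    if (e %in% names(.ELEMENTS)) .ELEMENTS[[e]]$valence else 0L, integer(1))
}

#' Read an SDF file into molecular graphs
#'
#' @param path SDF file path.
#' @return A list of records, each `list(graph = molgraph, title = character,
#'   data = named character vector)`. Assigned shifts from a `PPM_C13` data
#'   field are attached to the graph.
#' @export
read_sdf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  recs <- list()
  start <- 1L
  seps <- which(trimws(lines) == "$$$$")
  if (!length(seps)) seps <- length(lines) + 1L
  for (s in seps) {
    block <- lines[start:(s - 1L)]
    start <- s + 1L
    if (!length(block) || all(!nzchar(trimws(block)))) next
    mend <- which(trimws(block) == "M  END")
    if (!length(mend)) stop("SDF record missing M END")
    g <- parse_molfile_lines(block[1:mend[1]])
    dat <- character(0)
    i <- mend[1] + 1L
    while (i <= length(block)) {
      ln <- block[i]
      if (grepl("^> *<", ln)) {
        nm <- sub("^> *<([^>]+)>.*$", "\\1", ln)
        val <- character(0)
        i <- i + 1L
        while (i <= length(block) && nzchar(trimws(block[i]))) {
          val <- c(val, block[i]); i <- i + 1L
        }
        dat[nm] <- paste(val, collapse = "\n")
      }
      i <- i + 1L
    }
    if ("PPM_C13" %in% names(dat)) {
      pairs <- strsplit(trimws(dat[["PPM_C13"]]), "[[:space:]]+")[[1]]
      for (p in pairs) {
        kv <- strsplit(p, ":", fixed = TRUE)[[1]]
        g$shifts[as.integer(kv[1])] <- as.numeric(kv[2])
      }
    }
    recs[[length(recs) + 1L]] <- list(graph = g, title = block[1], data = dat)
  }
  recs
}
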