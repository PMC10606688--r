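# Allele labels follow the reference-database convention: an integer repeat
# count, optionally followed by ".d" where d (1-3) is the number of extra
# bases of a partial repeat ("microvariant"), e.g. "13.1". Multi-copy cells
# join several labels with "-", e.g. "11-14".

ALLELE_RE <- "^[0-9]+(\\.[1-3])?$"

#' Parse a Y-STR allele label
#'
#' Converts a printed allele label such as `"14"` or the microvariant
#' `"13.1"` into its repeat-count components. A microvariant `"13.1"` means
#' 13 full repeat units plus 1 extra base; the partial count must be smaller
#' than one repeat unit (1-3 bases).
#'
#' @param text a single allele label.
#' @return An object of class `ystr_allele`: a list with integer fields
#'   `repeats` and `partial` (`partial == 0` for full-repeat alleles).
#'   `format()` reproduces the input label exactly.
#' @examples
#' parse_allele("13.1")
#' format(parse_allele("14"))
#' @export
parse_allele <- function(text) {
  if (length(text) != 1L || is.na(text))
    stop("parse_allele() expects a single allele label", call. = FALSE)
  text <- trimws(as.character(text))
  if (!grepl(ALLELE_RE, text))
    stop("malformed allele label: '", text, "'", call. = FALSE)
  parts <- strsplit(text, ".", fixed = TRUE)[[1L]]
  structure(
    list(repeats = as.integer(parts[1L]),
         partial = if (length(parts) == 2L) as.integer(parts[2L]) else 0L),
    class = "ystr_allele"
  )
}

#' @export
format.ystr_allele <- function(x, ...) {
  if (x$partial == 0L) as.character(x$repeats)
  else paste0(x$repeats, ".", x$partial)
}

#' @export
print.ystr_allele <- function(x, ...) {
  cat("Y-STR allele ", format(x), " (", x$repeats, " repeats",
      if (x$partial > 0L) paste0(" + ", x$partial, " bases"), ")\n", sep = "")
  invisible(x)
}

#' Numeric value of an allele
#'
#' The conventional numeric reading of a label: `repeats + partial/10`, so
#' `"13.1"` maps to 13.1. Used only where a distance computation needs a
#' single number; for identity and counting the label itself is canonical.
#'
#' @param a a `ystr_allele` or a character vector of labels.
#' @return numeric vector.
#' @export
allele_value <- function(a) {
  if (inherits(a, "ystr_allele")) return(a$repeats + a$partial / 10)
  bad <- !is.na(a) & !grepl(ALLELE_RE, a)
  if (any(bad))
    stop("malformed allele label: '", a[bad][1L], "'", call. = FALSE)
  as.numeric(a)
}

#' Canonical form of a locus call cell
#'
#' A cell holds the allele multiset observed at one locus for one man:
#' one label for a regular single-copy call, two for the duplicated locus
#' DYS385a/b, three or more for copy-number variants. The canonical form
#' sorts labels ascending by numeric value and joins them with `sep`, so
#' `"14-11"` and `"11-14"` are the same call.
#'
#' @param cell a character vector of cells (each possibly multi-allele).
#' @param sep separator between alleles within a cell.
#' @return character vector of canonical cells; `NA` stays `NA`.
#' @examples
#' canonical_cell(c("14-11", "13.1", "15"))
#' @export
canonical_cell <- function(cell, sep = "-") {
  vapply(as.character(cell), function(x) {
    if (is.na(x)) return(NA_character_)
    labs <- trimws(strsplit(x, sep, fixed = TRUE)[[1L]])
    hits <- gregexpr(sep, x, fixed = TRUE)[[1L]]
    nsep <- if (hits[1L] == -1L) 0L else length(hits)
    if (length(labs) != nsep + 1L ||  # catches dangling separators
        length(labs) == 0L || any(!nzchar(labs)) ||
        any(!grepl(ALLELE_RE, labs)))
      stop("malformed cell: '", x, "'", call. = FALSE)
    paste(labs[order(as.numeric(labs), labs)], collapse = sep)
  }, character(1L), USE.NAMES = FALSE)
}

#' Number of alleles in a cell
#'
#' @param cell character vector of (canonical or raw) cells.
#' @param sep separator between alleles.
#' @return integer vector; `NA` for missing cells. Values above 1 at a
#'   single-copy locus, or above 2 at DYS385a/b, flag copy-number variants.
#' @export
cell_size <- function(cell, sep = "-") {
  n <- lengths(strsplit(as.character(cell), sep, fixed = TRUE))
  n[is.na(cell)] <- NA_integer_
  as.integer(n)
}
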