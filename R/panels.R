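# Marker panel registry. The five built-in panels are the standard forensic
# multiplexes, forming a nested chain:
#   Minimal < PowerPlexY12 < Yfiler < PowerPlexY23 < Microreader24Y
# The duplicated locus DYS385a/b occupies one column ("DYS385ab") whose cell
# holds the unordered allele pair, so the 9-marker Minimal haplotype has 8
# columns. The registry is data-driven (JSON) so alternative panel
# definitions can be loaded.

panel_env <- new.env(parent = emptyenv())

#' Marker panel registry
#'
#' Returns the named panels, each an ordered character vector of locus
#' column names. With no arguments the five built-in nested panels are
#' returned (Minimal, PowerPlexY12, Yfiler, PowerPlexY23, Microreader24Y).
#'
#' @param file optional path to a JSON file mapping panel name to locus
#'   list, replacing the built-ins for this call.
#' @return named list of character vectors.
#' @examples
#' names(ystr_panels())
#' ystr_panels()[["Minimal"]]
#' @export
ystr_panels <- function(file = NULL) {
  if (!is.null(file)) {
    p <- jsonlite::read_json(file, simplifyVector = TRUE)
    return(lapply(p, as.character))
  }
  if (is.null(panel_env$builtin)) {
    path <- system.file("extdata", "panels.json", package = "ystrkit",
                        mustWork = TRUE)
    panel_env$builtin <- lapply(
      jsonlite::read_json(path, simplifyVector = TRUE), as.character)
  }
  panel_env$builtin
}

#' Resolve a panel argument to an ordered locus vector
#'
#' @param panel a registered panel name, or a character vector of locus
#'   names used as-is.
#' @return character vector of locus column names.
#' @export
panel_loci <- function(panel) {
  if (length(panel) == 1L && panel %in% names(ystr_panels()))
    return(ystr_panels()[[panel]])
  as.character(panel)
}

# all loci named by any built-in panel (used to warn on unknown columns)
known_loci <- function() unique(unlist(ystr_panels(), use.names = FALSE))

#' Default per-locus founder allele ranges
#'
#' Plausible integer repeat-count ranges for each built-in locus, used by
#' the synthetic-data generators. These are conventional ranges for the
#' markers, not estimates from any particular population.
#'
#' @param file optional JSON override mapping locus to `[min, max]`.
#' @return named list of integer length-2 vectors.
#' @export
allele_ranges <- function(file = NULL) {
  path <- if (is.null(file))
    system.file("extdata", "allele_ranges.json", package = "ystrkit",
                mustWork = TRUE)
  else file
  lapply(jsonlite::read_json(path, simplifyVector = TRUE),
         function(r) as.integer(r))
}
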