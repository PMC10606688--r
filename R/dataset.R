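# Haplotype dataset container. One row per male individual, one column per
# locus; each cell is the canonical allele multiset string at that locus
# (see canonical_cell()). Haplotype identity is defined on canonical cells,
# so entry order within multi-allele cells never matters.

#' Construct a haplotype dataset
#'
#' @param cells character matrix (individuals x loci) of allele cells;
#'   column names are locus names. Cells are canonicalised; `NA` marks a
#'   missing call.
#' @param samples character vector of sample identifiers (default
#'   `S0001...`).
#' @param populations population label per individual, or one label
#'   recycled.
#' @param name dataset name.
#' @return an object of class `ystr_dataset`: a list with fields `name`,
#'   `samples`, `populations`, `loci`, `cells`.
#' @export
ystr_dataset <- function(cells, samples = NULL, populations = "pop1",
                         name = "dataset") {
  cells <- as.matrix(cells)
  if (is.null(colnames(cells)))
    stop("cells must have locus column names", call. = FALSE)
  n <- nrow(cells)
  storage.mode(cells) <- "character"
  for (j in seq_len(ncol(cells))) cells[, j] <- canonical_cell(cells[, j])
  if (is.null(samples)) samples <- sprintf("S%04d", seq_len(n))
  if (length(populations) == 1L) populations <- rep(populations, n)
  stopifnot(length(samples) == n, length(populations) == n)
  rownames(cells) <- NULL
  structure(
    list(name = name, samples = as.character(samples),
         populations = as.character(populations),
         loci = colnames(cells), cells = cells),
    class = "ystr_dataset"
  )
}

#' @export
print.ystr_dataset <- function(x, ...) {
  cat("Y-STR haplotype dataset '", x$name, "': ",
      nrow(x$cells), " individuals, ", length(x$loci), " loci (",
      length(unique(x$populations)), " population",
      if (length(unique(x$populations)) > 1L) "s", ")\n", sep = "")
  invisible(x)
}

#' Number of individuals in a dataset
#' @param d a `ystr_dataset`.
#' @return integer sample count N.
#' @export
n_samples <- function(d) nrow(d$cells)

#' Canonical haplotype keys
#'
#' A haplotype key is a deterministic string over a locus set: the loci in
#' sorted order, each paired with its canonical cell. Two haplotypes are
#' equal iff their keys are equal. Individuals with a missing call at any
#' requested locus get `NA`.
#'
#' @param d a `ystr_dataset`.
#' @param loci loci to include (default: all loci of `d`).
#' @return character vector of keys, one per individual.
#' @export
haplotype_keys <- function(d, loci = d$loci) {
  missing_loci <- setdiff(loci, d$loci)
  if (length(missing_loci))
    stop("dataset lacks loci: ", paste(missing_loci, collapse = ", "),
         call. = FALSE)
  loci <- sort(loci)
  sub <- d$cells[, loci, drop = FALSE]
  keys <- apply(sub, 1L, function(r) paste(loci, r, sep = "=", collapse = ";"))
  keys[rowSums(is.na(sub)) > 0L] <- NA_character_
  keys
}

#' Project a dataset onto a marker panel
#'
#' Restricts every haplotype to the loci of a panel. Projecting onto the
#' dataset's own locus set is the identity; for nested panels the
#' projections compose.
#'
#' @param d a `ystr_dataset`.
#' @param panel panel name or character vector of loci.
#' @return a `ystr_dataset` containing exactly the panel's loci.
#' @export
project_to_panel <- function(d, panel) {
  loci <- panel_loci(panel)
  absent <- setdiff(loci, d$loci)
  if (length(absent))
    stop("incomplete haplotypes: dataset lacks panel loci ",
         paste(absent, collapse = ", "), call. = FALSE)
  out <- d
  out$cells <- d$cells[, loci, drop = FALSE]
  out$loci <- loci
  out
}

# Drop individuals with a missing call at any of the given loci, with a
# logged count (message). Returns the filtered dataset.
drop_incomplete <- function(d, loci = d$loci, quiet = FALSE) {
  keep <- rowSums(is.na(d$cells[, loci, drop = FALSE])) == 0L
  if (!all(keep) && !quiet)
    message(sum(!keep), " individual(s) excluded: missing calls at panel loci")
  d$cells <- d$cells[keep, , drop = FALSE]
  d$samples <- d$samples[keep]
  d$populations <- d$populations[keep]
  d
}

#' Haplotype multiplicity spectrum
#'
#' Counts how many distinct haplotypes occur once, twice, thrice, ... under
#' a panel. The spectrum satisfies `sum(k * spectrum[k]) == N` and
#' `sum(spectrum) == M`, the number of distinct haplotypes.
#'
#' @param d a `ystr_dataset`.
#' @param panel panel name or locus vector (default: all loci of `d`).
#' @return named integer vector: names are multiplicities k (ascending),
#'   values the number of distinct haplotypes observed exactly k times.
#' @examples
#' d <- dataset_from_spectrum(c("1" = 3, "2" = 1), "Minimal", seed = 7)
#' multiplicity_spectrum(d, "Minimal")
#' @export
multiplicity_spectrum <- function(d, panel = NULL) {
  loci <- if (is.null(panel)) d$loci else panel_loci(panel)
  d <- drop_incomplete(d, loci)
  if (n_samples(d) == 0L)
    stop("empty dataset: no complete haplotypes for the requested loci",
         call. = FALSE)
  mult <- table(haplotype_keys(d, loci))
  sp <- table(factor(mult))
  out <- as.integer(sp)
  names(out) <- names(sp)
  out[order(as.integer(names(out)))]
}

#' Read a haplotype table
#'
#' Reads a UTF-8 tab-separated haplotype table: header columns `sample_id`,
#' `population`, then one column per locus. Multi-allele cells join labels
#' with `sep_allele` (e.g. `"11-14"` at DYS385a/b); missing calls use the
#' `missing` sentinel (default empty). Columns not named by any registered
#' panel are kept with a warning.
#'
#' @param path file path.
#' @param missing sentinel string marking a missing call.
#' @param sep_allele separator inside multi-allele cells.
#' @param name dataset name (default: file base name).
#' @return a `ystr_dataset` with one haplotype per data row.
#' @export
read_haplotype_table <- function(path, missing = "", sep_allele = "-",
                                 name = NULL) {
  df <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                   check.names = FALSE, na.strings = NULL,
                   fileEncoding = "UTF-8")
  if (nrow(df) == 0L) stop("empty dataset: ", path, call. = FALSE)
  reserved <- c("sample_id", "population")
  if (!all(reserved %in% names(df)))
    stop("haplotype table must have 'sample_id' and 'population' columns",
         call. = FALSE)
  loci <- setdiff(names(df), reserved)
  if (length(loci) == 0L) stop("no locus columns in ", path, call. = FALSE)
  unknown <- setdiff(loci, known_loci())
  if (length(unknown))
    warning("unknown locus column(s) kept: ", paste(unknown, collapse = ", "),
            call. = FALSE)
  cells <- as.matrix(df[, loci, drop = FALSE])
  cells[cells == missing] <- NA_character_
  lab_re <- "[0-9]+(\\.[1-3])?"
  cell_re <- sprintf("^\\s*%s(\\s*\\%s\\s*%s)*\\s*$", lab_re, sep_allele, lab_re)
  for (j in seq_along(loci)) {
    bad <- which(!is.na(cells[, j]) & !grepl(cell_re, cells[, j]))
    if (length(bad))
      stop("malformed cell at row ", bad[1L], ", column '", loci[j], "': '",
           cells[bad[1L], j], "'", call. = FALSE)
    cells[, j] <- canonical_cell(cells[, j], sep = sep_allele)
  }
  ystr_dataset(cells, samples = df$sample_id, populations = df$population,
               name = name %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Write a haplotype table
#'
#' Inverse of [read_haplotype_table()]: writes the canonical TSV dialect.
#' A write/read round trip reproduces identical haplotype keys.
#'
#' @param d a `ystr_dataset`.
#' @param path output file path.
#' @param missing sentinel written for missing calls.
#' @return `path`, invisibly.
#' @export
write_haplotype_table <- function(d, path, missing = "") {
  cells <- d$cells
  cells[is.na(cells)] <- missing
  df <- data.frame(sample_id = d$samples, population = d$populations,
                   cells, check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
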