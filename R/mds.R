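# Classical (metric) multidimensional scaling, also known as principal
# coordinates analysis: double-center the squared distances,
# B = -1/2 J D^2 J with J = I - 11'/n, eigendecompose, and scale the top
# eigenvectors by the square roots of their eigenvalues. Non-positive
# eigenvalues contribute zero coordinates.

#' Classical multidimensional scaling of a distance matrix
#'
#' Embeds population labels in `dims` dimensions so that Euclidean
#' distances approximate the input distances. Negative input entries
#' (slightly negative Rst) are clamped to 0. For an exact Euclidean
#' distance matrix the configuration is recovered up to rotation. Each
#' output axis is oriented so that its largest-magnitude coordinate is
#' positive, making plots reproducible across platforms.
#'
#' @param m symmetric zero-diagonal numeric matrix with dimnames, or an
#'   `rst_matrix` (uses the clamped values).
#' @param dims number of output dimensions (default 2).
#' @return numeric matrix (labels x dims) of coordinates, centered at the
#'   origin, with eigenvalues in attribute `"eig"`. If `dims` exceeds the
#'   number of positive eigenvalues the extra coordinates are zero (with a
#'   warning).
#' @examples
#' pts <- rbind(A = c(0, 0), B = c(3, 0), C = c(0, 4))
#' d <- as.matrix(dist(pts))
#' classical_mds(d, 2)
#' @export
classical_mds <- function(m, dims = 2L) {
  if (inherits(m, "rst_matrix")) m <- m$clamped
  m <- as.matrix(m)
  n <- nrow(m)
  if (n != ncol(m) || max(abs(m - t(m))) > 1e-8 || any(abs(diag(m)) > 1e-12))
    stop("classical_mds() needs a symmetric zero-diagonal matrix",
         call. = FALSE)
  m <- pmax(m, 0)
  J <- diag(n) - 1 / n
  B <- -0.5 * J %*% (m^2) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  n_pos <- sum(e$values > max(e$values, 0) * 1e-12)
  if (dims > n_pos)
    warning("requested ", dims, " dimensions but rank is ", n_pos,
            "; padding with zeros", call. = FALSE)
  coords <- matrix(0, n, dims,
                   dimnames = list(rownames(m), paste0("Dim", seq_len(dims))))
  for (j in seq_len(min(dims, n_pos))) {
    v <- e$vectors[, j] * sqrt(e$values[j])
    if (v[which.max(abs(v))] < 0) v <- -v  # deterministic sign convention
    coords[, j] <- v
  }
  attr(coords, "eig") <- e$values
  coords
}

#' Write MDS coordinates as TSV
#'
#' @param coords matrix from [classical_mds()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mds_tsv <- function(coords, path) {
  df <- data.frame(label = rownames(coords), coords, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
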