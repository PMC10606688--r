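# Neighbor joining (Saitou & Nei). At each step the pair (i, j) minimizing
#   Q(i,j) = (L - 2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)
# is joined; ties are broken on the lexicographically smallest pair of
# representative leaf labels so the result is deterministic. Limb lengths
# use the standard formulas with negative lengths clamped to 0. The result
# is an unrooted tree in "phylo" form (compatible with the ape package):
# an edge matrix, edge lengths, tip labels, and a degree-3 "root".

#' Neighbor-joining tree from a distance matrix
#'
#' Agglomerative distance-based tree reconstruction; exact on additive
#' distance matrices (path lengths on the output tree reproduce the
#' inputs). Intended for the pairwise Rst matrix of populations, where
#' negative entries are clamped to 0 first.
#'
#' @param m symmetric zero-diagonal numeric matrix with row/column labels,
#'   or an `rst_matrix` (uses the clamped values). At least 3 labels.
#' @return an unrooted binary tree of class `phylo` (fields `edge`,
#'   `edge.length`, `tip.label`, `Nnode`), with `L - 2` internal nodes for
#'   `L` leaves.
#' @examples
#' d <- matrix(c(0, 2, 3, 3, 2, 0, 3, 3, 3, 3, 0, 2, 3, 3, 2, 0), 4, 4,
#'             dimnames = list(LETTERS[1:4], LETTERS[1:4]))
#' neighbor_joining(d)
#' @export
neighbor_joining <- function(m) {
  if (inherits(m, "rst_matrix")) m <- m$clamped
  m <- as.matrix(m)
  L <- nrow(m)
  if (L < 3L) stop("neighbor joining needs at least 3 labels", call. = FALSE)
  if (is.null(rownames(m))) stop("matrix must be labelled", call. = FALSE)
  if (ncol(m) != L || max(abs(m - t(m))) > 1e-8)
    stop("neighbor joining needs a symmetric matrix", call. = FALSE)
  labels <- rownames(m)
  D <- pmax(unname(m), 0)
  act <- seq_len(L)              # node ids of active clusters (tips 1..L)
  rep_lab <- labels              # smallest leaf label within each cluster
  edges <- NULL                  # rows: parent id, child id, length
  next_id <- L

  while (length(act) > 3L) {
    n <- length(act)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-9 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    key <- apply(cand, 1L, function(ij) {
      p <- sort(c(rep_lab[ij[1L]], rep_lab[ij[2L]]))
      paste(p, collapse = "\r")
    })
    pick <- cand[order(key)[1L], ]
    i <- pick[1L]; j <- pick[2L]
    if (rep_lab[j] < rep_lab[i]) { k <- i; i <- j; j <- k }
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- D[i, j] - li
    next_id <- next_id + 1L
    edges <- rbind(edges,
                   c(next_id, act[i], max(li, 0)),
                   c(next_id, act[j], max(lj, 0)))
    dnew <- pmax((D[i, ] + D[j, ] - D[i, j]) / 2, 0)[-c(i, j)]
    D <- D[-c(i, j), -c(i, j), drop = FALSE]
    D <- rbind(cbind(D, dnew), c(dnew, 0))
    rep_new <- min(rep_lab[c(i, j)])
    act <- c(act[-c(i, j)], next_id)
    rep_lab <- c(rep_lab[-c(i, j)], rep_new)
  }

  # final star over the last three clusters (ordered by representative
  # label so equivalent inputs serialise identically): three-point formulas
  o3 <- order(rep_lab)
  act <- act[o3]; D <- D[o3, o3]
  d12 <- D[1L, 2L]; d13 <- D[1L, 3L]; d23 <- D[2L, 3L]
  limbs <- pmax(c((d12 + d13 - d23) / 2,
                  (d12 + d23 - d13) / 2,
                  (d13 + d23 - d12) / 2), 0)
  root <- next_id + 1L
  edges <- rbind(edges, cbind(root, act, limbs))

  # renumber internal nodes in preorder from the degree-3 root so the edge
  # table follows the usual phylo conventions (root = L + 1)
  kids <- split(seq_len(nrow(edges)), edges[, 1L])
  new_id <- integer(root); new_id[seq_len(L)] <- seq_len(L)
  counter <- L
  edge <- matrix(0L, nrow(edges), 2L)
  len <- numeric(nrow(edges))
  pos <- 0L
  visit <- function(node) {
    counter <<- counter + 1L
    new_id[node] <<- counter
    for (e in kids[[as.character(node)]]) {
      child <- edges[e, 2L]
      pos <<- pos + 1L
      row <- pos
      edge[row, 1L] <<- new_id[node]
      len[row] <<- edges[e, 3L]
      if (child <= L) edge[row, 2L] <<- as.integer(child)
      else {
        visit(child)
        edge[row, 2L] <<- new_id[child]
      }
    }
  }
  visit(root)
  structure(list(edge = edge, edge.length = len, Nnode = L - 2L,
                 tip.label = labels),
            class = "phylo", order = "cladewise")
}

# children-of-node index for a phylo edge table
phylo_children <- function(tree) {
  split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
}

newick_label <- function(lab) {
  if (is.na(lab) || !nzchar(lab))
    stop("tree labels must be non-empty", call. = FALSE)
  if (grepl("[][()':;, \t]", lab))
    paste0("'", gsub("'", "''", lab, fixed = TRUE), "'")
  else lab
}

#' Serialise a tree as a Newick string or file
#'
#' Standard Newick with branch lengths at 6-decimal precision. Labels
#' containing Newick metacharacters are single-quoted. Parsing the output
#' (e.g. with `ape::read.tree`) reproduces topology and lengths.
#'
#' @param tree a `phylo` object (as from [neighbor_joining()]).
#' @param path output file; if `NULL` the string is returned.
#' @param digits decimal places for branch lengths.
#' @return the Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL, digits = 6L) {
  stopifnot(inherits(tree, "phylo"))
  kids <- phylo_children(tree)
  L <- length(tree$tip.label)
  fmt <- paste0("%.", digits, "f")
  build <- function(node) {
    k <- kids[[as.character(node)]]
    if (is.null(k)) return(newick_label(tree$tip.label[node]))
    inner <- vapply(k, function(e) {
      paste0(build(tree$edge[e, 2L]), ":",
             sprintf(fmt, tree$edge.length[e]))
    }, character(1L))
    paste0("(", paste(inner, collapse = ","), ")")
  }
  s <- paste0(build(L + 1L), ";")
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}
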