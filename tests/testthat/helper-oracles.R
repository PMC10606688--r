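# Independent oracles, kept deliberately naive: direct transcriptions of
# the defining formulas with explicit loops, sharing no code with the
# package implementations they check.

# two-level AMOVA Rst by brute force
amova_oracle <- function(values, pop) {
  values <- as.matrix(values)
  N <- nrow(values)
  groups <- unique(pop)
  P <- length(groups)
  d <- matrix(0, N, N)
  for (i in seq_len(N)) for (j in seq_len(N))
    d[i, j] <- sum((values[i, ] - values[j, ])^2)
  ssd_total <- 0
  for (i in seq_len(N)) for (j in seq_len(N)) ssd_total <- ssd_total + d[i, j]
  ssd_total <- ssd_total / (2 * N)
  ssd_within <- 0
  sizes <- numeric(P)
  for (g in seq_along(groups)) {
    idx <- which(pop == groups[g])
    sizes[g] <- length(idx)
    s <- 0
    for (i in idx) for (j in idx) s <- s + d[i, j]
    ssd_within <- ssd_within + s / (2 * length(idx))
  }
  msd_among <- (ssd_total - ssd_within) / (P - 1)
  msd_within <- ssd_within / (N - P)
  n_c <- (N - sum(sizes^2) / N) / (P - 1)
  sigma2_a <- (msd_among - msd_within) / n_c
  if (sigma2_a + msd_within == 0) return(0)
  sigma2_a / (sigma2_a + msd_within)
}

# exhaustive pairwise haplotype match probability: matches / N^2
hmp_oracle <- function(keys) {
  N <- length(keys)
  matches <- 0
  for (i in seq_len(N)) for (j in seq_len(N))
    if (keys[i] == keys[j]) matches <- matches + 1
  matches / N^2
}

# residual of the best rigid (rotation/reflection + translation) fit of Y
# onto X
procrustes_residual <- function(X, Y) {
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  s <- svd(t(Yc) %*% Xc)
  R <- s$u %*% t(s$v)
  sqrt(sum((Xc - Yc %*% R)^2))
}

# canonical set of non-trivial bipartitions of a phylo tree (topology
# comparison independent of node numbering and rooting)
tree_splits <- function(tree) {
  L <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  desc <- function(node) {
    if (node <= L) return(tree$tip.label[node])
    unlist(lapply(kids[[as.character(node)]],
                  function(e) desc(tree$edge[e, 2L])))
  }
  splits <- character()
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2L]
    if (child > L) {
      side <- sort(desc(child))
      other <- sort(setdiff(tree$tip.label, side))
      if (length(side) >= 2L && length(other) >= 2L) {
        a <- paste(side, collapse = ",")
        b <- paste(other, collapse = ",")
        splits <- c(splits, paste(min(a, b), max(a, b), sep = "|"))
      }
    }
  }
  sort(unique(splits))
}

# random additive distance matrix from a random tree; returns the matrix
# and the generating (unrooted) tree
random_additive <- function(n_leaves, seed) {
  set.seed(seed)
  tr <- ape::unroot(ape::rtree(n_leaves, br = function(k) runif(k, 0.1, 1)))
  D <- ape::cophenetic.phylo(tr)
  D <- D[order(rownames(D)), order(colnames(D))]
  list(D = D, tree = tr)
}
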