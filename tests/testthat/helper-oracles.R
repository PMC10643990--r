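# Independent oracles used across test files. These deliberately take the
# slow, direct route (enumeration, exhaustive scoring, grid search) and
# share no code with the implementation paths they check.

# Random tree with uniform branch lengths, reproducible.
random_tree <- function(n_tips, seed, min_bl = 0.05, max_bl = 2) {
  set.seed(seed)
  tr <- ape::rtree(n_tips)
  tr$edge.length <- stats::runif(nrow(tr$edge), min_bl, max_bl)
  tr
}

random_states <- function(tree, seed) {
  set.seed(seed)
  stats::setNames(sample(c("--", "-D", "A-", "AD"), ape::Ntip(tree),
                         replace = TRUE),
                  tree$tip.label)
}

# Likelihood by exhaustive summation over all internal-node state
# assignments (brute force; only usable on tiny trees).
enum_loglik <- function(tree, tip_states, Q, pi = rep(0.25, 4)) {
  states <- rownames(Q)
  tree <- ape::reorder.phylo(tree, "postorder")
  nt <- ape::Ntip(tree)
  nn <- nt + tree$Nnode
  sidx <- match(tip_states[tree$tip.label], states)
  internals <- (nt + 1L):nn
  P <- lapply(seq_len(nrow(tree$edge)), function(e)
    as.matrix(Matrix::expm(Q * tree$edge.length[e])))
  grid <- as.matrix(expand.grid(rep(list(seq_along(states)),
                                    length(internals))))
  tot <- 0
  for (g in seq_len(nrow(grid))) {
    a <- integer(nn)
    a[seq_len(nt)] <- sidx
    a[internals] <- grid[g, ]
    p <- pi[a[nt + 1L]]
    for (e in seq_len(nrow(tree$edge)))
      p <- p * P[[e]][a[tree$edge[e, 1L]], a[tree$edge[e, 2L]]]
    tot <- tot + p
  }
  log(tot)
}

# MAD oracle: score a candidate root point (edge e, distance x from the
# parent endpoint) from root-to-tip distances alone, using the generic
# point-to-path projection d(a,i) = (d_ij + d(r,i) - d(r,j)) / 2.
mad_oracle_score <- function(tree, D, below, e, x) {
  nt <- ape::Ntip(tree)
  u <- tree$edge[e, 1L]; v <- tree$edge[e, 2L]
  bl <- tree$edge.length[e]
  droot <- numeric(nt)
  for (i in seq_len(nt)) {
    droot[i] <- if (below[v, i]) D[v, i] + (bl - x) else D[u, i] + x
  }
  r2 <- c()
  for (i in seq_len(nt - 1L)) for (j in (i + 1L):nt) {
    dij <- D[i, j]
    if (dij == 0) next
    dai <- (dij + droot[i] - droot[j]) / 2
    r2 <- c(r2, (2 * dai / dij - 1)^2)
  }
  sqrt(mean(r2))
}

# Dense grid search over every branch; returns best edge, position, score.
mad_grid_search <- function(tree, step = 1e-3) {
  tree <- ape::reorder.phylo(ape::unroot(tree), "postorder")
  nt <- ape::Ntip(tree)
  nn <- nt + tree$Nnode
  D <- ape::dist.nodes(tree)
  below <- matrix(FALSE, nn, nt)
  below[cbind(seq_len(nt), seq_len(nt))] <- TRUE
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    below[p, ] <- below[p, ] | below[ch, ]
  }
  best <- list(score = Inf)
  for (e in seq_len(nrow(tree$edge))) {
    bl <- tree$edge.length[e]
    xs <- if (bl > 0) seq(0, bl, by = step * bl) else 0
    for (x in xs) {
      sc <- mad_oracle_score(tree, D, below, e, x)
      if (sc < best$score)
        best <- list(edge = e, x = x, score = sc,
                     child_tips = sort(tree$tip.label[below[tree$edge[e, 2L], ]]))
    }
  }
  best
}

# Exhaustive PSSM window scoring with plain loops.
brute_scan_scores <- function(pssm, seq) {
  chars <- strsplit(toupper(seq), "")[[1L]]
  L <- pssm$length
  n <- length(chars) - L + 1L
  if (n < 1L) return(numeric(0))
  sapply(seq_len(n), function(off) {
    s <- 0
    for (p in seq_len(L)) {
      aa <- chars[off + p - 1L]
      s <- s + if (aa %in% colnames(pssm$scores)) pssm$scores[p, aa] else 0
    }
    s
  })
}

# The unrooted bipartition induced by the original root of a rooted tree.
root_bipartition <- function(rooted) {
  root <- ape::Ntip(rooted) + 1L
  k <- rooted$edge[rooted$edge[, 1L] == root, 2L][1L]
  side <- if (k <= ape::Ntip(rooted)) rooted$tip.label[k]
          else ape::extract.clade(rooted, k)$tip.label
  sort(side)
}

bipartition_equal <- function(a, b, all_tips) {
  a <- sort(a); b <- sort(b)
  identical(a, b) || identical(a, sort(setdiff(all_tips, b)))
}
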