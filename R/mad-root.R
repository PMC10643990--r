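#' Minimal ancestor deviation (MAD) rooting
#'
#' Roots an unrooted tree at the branch position that minimizes the
#' root-mean-square relative deviation of inferred ancestors from tip-pair
#' midpoints. For a candidate root point and a tip pair (i, j), the ancestor
#' `a` is the point on the path i--j closest to the candidate root, and the
#' relative deviation is `r_ij = |2 d(a,i)/d(i,j) - 1|`; a strictly
#' clock-like tree rooted at its true root has all `r_ij = 0`. For pairs
#' whose path crosses the candidate branch the optimal position on the
#' branch has the closed form
#' `x* = sum((d_ij - 2 d(u,i))/d_ij^2) / (2 sum(1/d_ij^2))`
#' (i on the side of branch endpoint `u`), clamped to the branch.
#'
#' @param tree An [ape::phylo] object with branch lengths; a rooted input is
#'   unrooted first (its root-adjacent branches merge into one candidate).
#' @return A list of class `"mad_result"` with elements
#'   \describe{
#'     \item{tree}{the rooted tree (root inserted at the optimal point)}
#'     \item{branch}{endpoints (parent, child node numbers in the unrooted
#'       tree) of the chosen branch and the tip set on its child side}
#'     \item{rho}{relative root position along the chosen branch, in
#'       \[0, 1\], measured from the parent endpoint}
#'     \item{score}{the minimal root-mean-square relative deviation}
#'     \item{table}{per-branch score table (parent, child, length, rho,
#'       score)}
#'     \item{tie}{`TRUE` if another branch scored equally (within 1e-12);
#'       the first branch in postorder is kept}
#'   }
#' @examples
#' tr <- read_tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' mad_root(tr)$score  # 0: perfectly clock-like
#' @export
mad_root <- function(tree) {
  validate_tree(tree)
  if (ape::Ntip(tree) < 3L) stop2("MAD rooting needs at least 3 tips")
  if (all(tree$edge.length == 0))
    stop2("degenerate tree: all branch lengths are zero")

  utree <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  utree <- ape::reorder.phylo(utree, "postorder")
  nt <- ape::Ntip(utree)
  nn <- nt + utree$Nnode
  D <- ape::dist.nodes(utree)
  Dtt <- D[seq_len(nt), seq_len(nt), drop = FALSE]

  zero_pair <- Dtt == 0
  diag(zero_pair) <- TRUE
  if (any(zero_pair[upper.tri(zero_pair)]))
    warning("tip pairs with zero patristic distance excluded from MAD score")
  ok_pair <- !zero_pair
  npairs <- sum(ok_pair) / 2
  if (npairs == 0) stop2("no tip pair with positive distance")

  # tip membership of the clade below each node (display orientation)
  below <- matrix(FALSE, nn, nt)
  below[cbind(seq_len(nt), seq_len(nt))] <- TRUE
  for (e in seq_len(nrow(utree$edge))) {
    p <- utree$edge[e, 1L]; ch <- utree$edge[e, 2L]
    below[p, ] <- below[p, ] | below[ch, ]
  }

  ne <- nrow(utree$edge)
  tab <- data.frame(parent = utree$edge[, 1L], child = utree$edge[, 2L],
                    length = utree$edge.length, rho = NA_real_,
                    score = NA_real_)

  side_ss <- function(tips, ref) {
    # sum of r^2 over valid pairs both in `tips`, ancestors projected on ref
    if (length(tips) < 2L) return(0)
    dref <- D[tips, ref]
    dd <- Dtt[tips, tips, drop = FALSE]
    r <- outer(dref, dref, "-") / dd
    r[!ok_pair[tips, tips, drop = FALSE]] <- 0
    sum(r[upper.tri(r)]^2)
  }

  for (e in seq_len(ne)) {
    u <- tab$parent[e]; v <- tab$child[e]; bl <- tab$length[e]
    inV <- below[v, ]
    tipsV <- which(inV); tipsU <- which(!inV)
    ss <- side_ss(tipsV, v) + side_ss(tipsU, u)
    x <- 0
    if (length(tipsU) && length(tipsV)) {
      duv <- Dtt[tipsU, tipsV, drop = FALSE]
      okuv <- ok_pair[tipsU, tipsV, drop = FALSE]
      dui <- matrix(D[tipsU, u], nrow = length(tipsU), ncol = length(tipsV))
      num <- sum(((duv - 2 * dui) / duv^2)[okuv])
      den <- 2 * sum((1 / duv^2)[okuv])
      x <- if (den > 0) min(max(num / den, 0), bl) else 0
      rsp <- (2 * (dui + x) / duv - 1)^2
      ss <- ss + sum(rsp[okuv])
    }
    tab$rho[e] <- if (bl > 0) x / bl else 0
    tab$score[e] <- sqrt(ss / npairs)
  }

  best <- which.min(tab$score)
  tie <- sum(tab$score <= tab$score[best] + 1e-12) > 1L
  if (tie) message("MAD: tie between branches for the minimal score; ",
                   "keeping the first in postorder")

  u <- tab$parent[best]; v <- tab$child[best]
  x <- tab$rho[best] * tab$length[best]
  rooted <- root_on_branch(utree, u, v, x)

  structure(list(
    tree = rooted,
    branch = list(parent = u, child = v,
                  child_side_tips = utree$tip.label[below[v, ]]),
    rho = tab$rho[best],
    score = tab$score[best],
    table = tab,
    tie = tie
  ), class = "mad_result")
}

# Root `tree` on the branch (u, v) at distance x from u (the parent end).
root_on_branch <- function(tree, u, v, x) {
  bl <- tree$edge.length[tree$edge[, 1L] == u & tree$edge[, 2L] == v]
  if (!length(bl)) stop2("no branch between nodes ", u, " and ", v)
  x <- min(max(x, 0), bl)
  rooted <- phytools::reroot(tree, node.number = v, position = x)
  validate_tree(rooted)
}

#' @export
print.mad_result <- function(x, ...) {
  cat("MAD rooting\n")
  cat(sprintf("  minimal RMS relative deviation: %.6g\n", x$score))
  cat(sprintf("  root branch: nodes %d--%d (rho = %.4f from parent end)\n",
              x$branch$parent, x$branch$child, x$rho))
  cat(sprintf("  tips on child side: %d\n", length(x$branch$child_side_tips)))
  if (isTRUE(x$tie)) cat("  note: tied optimum, first postorder branch kept\n")
  invisible(x)
}
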