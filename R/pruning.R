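#' Log-likelihood of tip states by Felsenstein pruning
#'
#' Computes the log-likelihood of discrete tip states on a rooted tree under
#' a continuous-time Markov model with rate matrix `Q`, by the post-order
#' pruning algorithm. Partial likelihoods are rescaled at every edge, so
#' deep trees and tiny rates do not underflow. Polytomies are handled
#' naturally (the product at a node runs over all of its children).
#'
#' @param tree A rooted [ape::phylo] with branch lengths.
#' @param tip_states Named character vector (or factor) mapping every tip
#'   label to a state name of `Q` (for the intein models: `"--"`, `"-D"`,
#'   `"A-"`, `"AD"`).
#' @param Q Rate matrix with state names as dimnames (see
#'   [build_rate_matrix()]).
#' @param pi Root prior: `"flat"` (default), `"equilibrium"` (stationary
#'   distribution of `Q`), or a numeric probability vector over the states.
#' @return The log-likelihood (a single number; `-Inf` if the data are
#'   impossible under `Q`).
#' @examples
#' tr <- read_tree(text = "((A:1,B:1):0.5,(C:1,D:1):0.5);")
#' Q <- build_rate_matrix(transition_model("no_cohoming"), rep(0.3, 8))
#' x <- c(A = "AD", B = "AD", C = "--", D = "-D")
#' pruning_loglik(tr, x, Q)
#' @export
pruning_loglik <- function(tree, tip_states, Q, pi = "flat") {
  validate_tree(tree)
  if (!ape::is.rooted(tree)) stop2("tree must be rooted (see mad_root())")
  states <- rownames(Q)
  if (is.null(states)) stop2("Q must have state names as dimnames")
  tip_states <- check_tip_states(tree, tip_states, states)
  pi <- resolve_root_prior(pi, Q)
  dec <- ctmc_decompose(Q)
  pruning_loglik_impl(tree, tip_states, dec, pi, states)
}

# tip_states: named vector covering exactly the tree tips; returns it
# reordered to tree$tip.label.
check_tip_states <- function(tree, tip_states, states) {
  tip_states <- stats::setNames(as.character(tip_states), names(tip_states))
  if (is.null(names(tip_states)) || any(!nzchar(names(tip_states))))
    stop2("tip_states must be named by taxon")
  miss <- setdiff(tree$tip.label, names(tip_states))
  extra <- setdiff(names(tip_states), tree$tip.label)
  if (length(miss) || length(extra))
    stop2("tip/state table mismatch.",
          if (length(miss)) paste0(" Missing states for: ",
                                   paste(miss, collapse = ", "), "."),
          if (length(extra)) paste0(" Not in tree: ",
                                    paste(extra, collapse = ", "), "."))
  bad <- setdiff(unique(tip_states), states)
  if (length(bad))
    stop2("unknown state value(s): ", paste(bad, collapse = ", "),
          " (expected ", paste(states, collapse = ", "), ")")
  if (anyNA(tip_states))
    stop2("missing/ambiguous tip states are not supported")
  tip_states[tree$tip.label]
}

resolve_root_prior <- function(pi, Q) {
  ns <- nrow(Q)
  if (is.character(pi)) {
    pi <- match.arg(pi, c("flat", "equilibrium"))
    pi <- if (pi == "flat") rep(1 / ns, ns) else stationary_distribution(Q)
  }
  if (length(pi) != ns || any(pi < 0) || abs(sum(pi) - 1) > 1e-8)
    stop2("root prior must be a probability vector over ", ns, " states")
  as.numeric(pi)
}

# Core loop, shared by the user-facing function and the optimizer. `dec` is
# a ctmc_decompose() result so Q is decomposed once per likelihood call.
pruning_loglik_impl <- function(tree, tip_states, dec, pi, states) {
  tr <- ape::reorder.phylo(tree, "postorder")
  nt <- ape::Ntip(tr)
  nn <- nt + tr$Nnode
  ns <- length(states)
  P <- edge_tpms(dec, tr$edge.length)
  sidx <- match(tip_states, states)

  L <- matrix(1, nn, ns)
  L[seq_len(nt), ] <- 0
  L[cbind(seq_len(nt), sidx)] <- 1

  logscale <- 0
  parents <- tr$edge[, 1L]
  children <- tr$edge[, 2L]
  for (e in seq_along(parents)) {
    m <- P[, , e] %*% L[children[e], ]
    mx <- max(m)
    if (mx == 0) return(-Inf)
    logscale <- logscale + log(mx)
    L[parents[e], ] <- L[parents[e], ] * (m / mx)
  }
  root <- nt + 1L
  lik <- sum(pi * L[root, ])
  if (lik <= 0) return(-Inf)
  log(lik) + logscale
}
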