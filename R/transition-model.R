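#' Constrained transition models for paired intein occupancy
#'
#' The joint occupancy of the two neighboring insertion sites is one of four
#' states, indexed in the fixed order `"--"`, `"-D"`, `"A-"`, `"AD"` (site a
#' first, site d second). Two nested all-rates-different models are
#' supported:
#' \describe{
#'   \item{`no_cohoming`}{only single-site gains and losses are allowed
#'     (8 free rates): `-- <-> -D`, `-- <-> A-`, `-D <-> AD`, `A- <-> AD`.}
#'   \item{`cohoming`}{additionally allows the simultaneous gain or loss of
#'     both inteins in one event, `-- <-> AD` (10 free rates).}
#' }
#'
#' @param name `"no_cohoming"` or `"cohoming"`.
#' @return An object of class `"transition_model"`: a list with `name`,
#'   `states`, a `transitions` data frame (`from`, `to` state indices,
#'   `label`), and the free-parameter count `k`.
#' @examples
#' transition_model("cohoming")$k  # 10
#' @export
transition_model <- function(name = c("no_cohoming", "cohoming")) {
  name <- match.arg(name)
  base <- rbind(
    c(1L, 2L), c(1L, 3L),  # gains from the empty allele, one site at a time
    c(2L, 1L), c(2L, 4L),  # loss of d / gain of a next to d
    c(3L, 1L), c(3L, 4L),  # loss of a / gain of d next to a
    c(4L, 2L), c(4L, 3L)   # single losses from the doubly invaded allele
  )
  if (name == "cohoming") base <- rbind(base, c(1L, 4L), c(4L, 1L))
  trans <- data.frame(from = base[, 1L], to = base[, 2L])
  trans$label <- paste(OCC_STATES[trans$from], OCC_STATES[trans$to], sep = "=>")
  structure(list(name = name, states = OCC_STATES, transitions = trans,
                 k = nrow(trans)),
            class = "transition_model")
}

#' @export
print.transition_model <- function(x, ...) {
  cat(sprintf("transition model \"%s\": %d states, %d free rates\n",
              x$name, length(x$states), x$k))
  cat("  allowed:", paste(x$transitions$label, collapse = ", "), "\n")
  invisible(x)
}

#' Build an instantaneous rate matrix from per-transition rates
#'
#' @param model A [transition_model()].
#' @param rates Non-negative numeric vector, one rate per allowed transition,
#'   in the model's declared transition order (names, if present, must match
#'   the transition labels). Units: expected transitions per unit branch
#'   length.
#' @return A 4x4 matrix `Q` with the given rates on the allowed
#'   off-diagonal cells, exact zeros on disallowed cells, and diagonal
#'   entries set so each row sums to zero.
#' @examples
#' Q <- build_rate_matrix(transition_model("no_cohoming"), rep(1, 8))
#' rowSums(Q)  # all zero
#' @export
build_rate_matrix <- function(model, rates) {
  stopifnot(inherits(model, "transition_model"))
  if (length(rates) != model$k)
    stop2("expected ", model$k, " rates for model \"", model$name,
          "\", got ", length(rates))
  if (any(!is.finite(rates)) || any(rates < 0))
    stop2("rates must be finite and non-negative")
  if (!is.null(names(rates)) &&
      !identical(names(rates), model$transitions$label))
    stop2("rate names do not match the model's transition labels")
  ns <- length(model$states)
  Q <- matrix(0, ns, ns, dimnames = list(model$states, model$states))
  Q[cbind(model$transitions$from, model$transitions$to)] <- rates
  diag(Q) <- -rowSums(Q)
  Q
}

#' Transition probability matrix of a CTMC
#'
#' Computes `P(t) = exp(Q t)` for a branch of length `t`. An
#' eigendecomposition is used when it reconstructs `Q` to high accuracy;
#' otherwise the computation falls back to scaling-and-squaring
#' ([Matrix::expm]). Entries are clamped to \[0, 1\] against roundoff.
#'
#' @param Q A square rate matrix (rows summing to zero).
#' @param t Branch length, `t >= 0`.
#' @return A row-stochastic matrix of the same dimension as `Q`.
#' @examples
#' Q <- build_rate_matrix(transition_model("no_cohoming"), rep(0.5, 8))
#' rowSums(transition_probabilities(Q, 2))
#' @export
transition_probabilities <- function(Q, t) {
  if (length(t) != 1L || !is.finite(t) || t < 0)
    stop2("branch length t must be a single finite value >= 0")
  dec <- ctmc_decompose(Q)
  P <- tpm_from_decomposition(dec, t)
  dimnames(P) <- dimnames(Q)
  P
}

# Precompute what is needed to evaluate exp(Qt) for many t.
# Returns either an eigendecomposition-based evaluator or a fallback flag.
ctmc_decompose <- function(Q) {
  Q <- as.matrix(Q)
  if (nrow(Q) != ncol(Q)) stop2("Q must be square")
  eg <- tryCatch(eigen(Q), error = function(e) NULL)
  if (!is.null(eg)) {
    Vinv <- tryCatch(solve(eg$vectors), error = function(e) NULL)
    if (!is.null(Vinv)) {
      recon <- eg$vectors %*% diag(eg$values, nrow(Q)) %*% Vinv
      scale <- max(abs(Q), 1)
      if (max(abs(Re(recon) - Q)) / scale < 1e-12 &&
          max(abs(Im(recon))) / scale < 1e-12) {
        ns <- nrow(Q)
        # M[k, ] = vec(V[,k] %o% Vinv[k,]) so that vec(P(t)) = exp(lambda t) %*% M
        M <- matrix(0i, ns, ns * ns)
        for (k in seq_len(ns))
          M[k, ] <- as.vector(outer(eg$vectors[, k], Vinv[k, ]))
        return(list(method = "eigen", values = eg$values, M = M, Q = Q,
                    ns = ns))
      }
    }
  }
  list(method = "expm", Q = Q, ns = nrow(Q))
}

tpm_from_decomposition <- function(dec, t) {
  if (t == 0) return(diag(dec$ns))  # exact identity, no roundoff dirt
  if (dec$method == "eigen") {
    v <- exp(dec$values * t)
    P <- matrix(Re(v %*% dec$M), dec$ns, dec$ns)
  } else {
    P <- as.matrix(Matrix::expm(dec$Q * t))
  }
  P[P < 0] <- 0
  P[P > 1] <- 1
  P
}

# Transition matrices for a whole vector of branch lengths at once.
# Accepts a rate matrix or a ctmc_decompose() result; returns an array
# ns x ns x length(lens).
edge_tpms <- function(Q, lens) {
  dec <- if (is.list(Q) && !is.null(Q$method)) Q else ctmc_decompose(Q)
  ns <- dec$ns
  if (dec$method == "eigen") {
    E <- exp(outer(lens, dec$values))        # n_edges x ns
    Pm <- Re(E %*% dec$M)                    # n_edges x ns^2 (vec by column)
    Pm[Pm < 0] <- 0
    Pm[Pm > 1] <- 1
    Pm[lens == 0, ] <- rep(as.vector(diag(ns)), each = sum(lens == 0))
    array(t(Pm), dim = c(ns, ns, length(lens)))
  } else {
    out <- array(0, dim = c(ns, ns, length(lens)))
    for (i in seq_along(lens)) out[, , i] <- tpm_from_decomposition(dec, lens[i])
    out
  }
}

#' Stationary distribution of a rate matrix
#'
#' Solves `pi Q = 0`, `sum(pi) = 1` by a null-space computation. Used for
#' the `"equilibrium"` root prior.
#'
#' @param Q A rate matrix with rows summing to zero.
#' @return A probability vector over the states of `Q`.
#' @export
stationary_distribution <- function(Q) {
  ns <- nrow(Q)
  A <- rbind(t(Q), rep(1, ns))
  b <- c(rep(0, ns), 1)
  pi_hat <- stats::lm.fit(A, b)$coefficients
  pi_hat[pi_hat < 0] <- 0
  pi_hat <- pi_hat / sum(pi_hat)
  stats::setNames(as.numeric(pi_hat), rownames(Q))
}
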