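#' Options for maximum-likelihood model fitting
#'
#' @param pi Root prior: `"flat"` (default), `"equilibrium"`, or a numeric
#'   probability vector over the four states. The choice is recorded in the
#'   fit result.
#' @param lower,upper Rate bounds (per unit branch length). The default
#'   upper bound of 1e5 leaves room for effectively instantaneous
#'   transitions on short branches.
#' @param restarts Number of multi-start local optimizations. The first
#'   start is a data-driven guess (roughly one event per tip over the total
#'   tree length); the rest are drawn log-uniformly between the bounds.
#' @param seed Integer seed making the restart draws reproducible.
#' @param reltol Relative convergence tolerance passed to the optimizer.
#' @return A list of class `"fit_options"`.
#' @export
fit_options <- function(pi = "flat", lower = 1e-9, upper = 1e5,
                        restarts = 10L, seed = 1L, reltol = 1e-10) {
  if (lower <= 0) stop2("lower rate bound must be > 0")
  if (upper < lower) stop2("upper rate bound must be >= lower")
  if (restarts < 1L) stop2("need at least one restart")
  structure(list(pi = pi, lower = lower, upper = upper,
                 restarts = as.integer(restarts), seed = as.integer(seed),
                 reltol = reltol),
            class = "fit_options")
}

#' Fit a constrained occupancy model by maximum likelihood
#'
#' Maximizes the pruning log-likelihood over the model's per-transition
#' rates, optimizing in log-rate space with box constraints and multiple
#' restarts. All restart optima are retained so a flat likelihood surface
#' is visible in the result.
#'
#' @param tree A rooted [ape::phylo] with branch lengths.
#' @param tip_states Named character vector of occupancy states (see
#'   [pruning_loglik()]).
#' @param model A [transition_model()] or its name.
#' @param opts A [fit_options()] object.
#' @param extra_starts Optional list of rate vectors (length `k`) used as
#'   additional optimization starts, e.g. the optimum of a nested model
#'   padded with bound values.
#' @return An object of class `"intein_fit"`: model name, named `rates`,
#'   `lnL`, `k`, `n` (taxon count), `AICc`, a `restarts` data frame with
#'   per-restart optima, a `converged` flag, and the root-prior setting.
#' @examples
#' sim <- simulate_dataset(n_tips = 40, rates = rep(1, 8), seed = 7)
#' fit <- fit_model(sim$tree, sim$tip_states, "no_cohoming",
#'                  fit_options(restarts = 2))
#' fit$AICc
#' @export
fit_model <- function(tree, tip_states, model = "no_cohoming",
                      opts = fit_options(), extra_starts = NULL) {
  if (is.character(model)) model <- transition_model(model)
  stopifnot(inherits(model, "transition_model"), inherits(opts, "fit_options"))
  validate_tree(tree)
  if (!ape::is.rooted(tree)) stop2("tree must be rooted (see mad_root())")
  states <- model$states
  tip_states <- check_tip_states(tree, tip_states, states)
  n <- ape::Ntip(tree)
  k <- model$k
  tr <- ape::reorder.phylo(tree, "postorder")

  fixed_pi <- !identical(opts$pi, "equilibrium")
  pi_num <- if (fixed_pi) resolve_root_prior(opts$pi, diag(0, 4)) else NULL

  negll <- function(logr) {
    Q <- build_rate_matrix(model, exp(logr))
    dec <- ctmc_decompose(Q)
    pv <- if (fixed_pi) pi_num else stationary_distribution(Q)
    ll <- pruning_loglik_impl(tr, tip_states, dec, pv, states)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  lo <- log(opts$lower); hi <- log(opts$upper)
  # data-driven first start: one event per tip spread over the tree length
  tl <- sum(tr$edge.length)
  guess <- min(max(n / max(tl, .Machine$double.eps), opts$lower), opts$upper)
  starts <- matrix(log(guess), nrow = 1L, ncol = k)
  if (!is.null(extra_starts)) {
    for (st in extra_starts) {
      if (length(st) != k) stop2("extra start has wrong length")
      starts <- rbind(starts,
                      log(pmin(pmax(st, opts$lower), opts$upper)))
    }
  }
  if (opts$restarts > 1L) {
    extra <- with_seed(opts$seed, matrix(
      stats::runif((opts$restarts - 1L) * k, lo, hi),
      nrow = opts$restarts - 1L))
    starts <- rbind(starts, extra)
  }

  res <- vector("list", nrow(starts))
  for (r in seq_len(nrow(starts))) {
    res[[r]] <- stats::nlminb(starts[r, ], negll, lower = lo, upper = hi,
                              control = list(iter.max = 1000L,
                                             eval.max = 4000L,
                                             rel.tol = opts$reltol))
  }
  lnLs <- vapply(res, function(z) -z$objective, numeric(1))
  conv <- vapply(res, function(z) z$convergence == 0L, logical(1))
  best <- which.max(lnLs)
  rates <- stats::setNames(exp(res[[best]]$par), model$transitions$label)

  structure(list(
    model = model$name,
    transition_model = model,
    rates = rates,
    lnL = lnLs[best],
    k = k,
    n = n,
    AICc = aicc(lnLs[best], k, n),
    restarts = data.frame(restart = seq_len(nrow(starts)), lnL = lnLs,
                          converged = conv),
    converged = conv[best],
    pi = opts$pi,
    bounds = c(lower = opts$lower, upper = opts$upper),
    seed = opts$seed
  ), class = "intein_fit")
}

#' @export
print.intein_fit <- function(x, ...) {
  cat(sprintf("ML fit, model \"%s\" (k = %d free rates, n = %d taxa)\n",
              x$model, x$k, x$n))
  cat(sprintf("  lnL = %.4f   AICc = %.2f   converged: %s\n",
              x$lnL, x$AICc, x$converged))
  cat("  rates (transitions per unit branch length):\n")
  for (i in seq_along(x$rates))
    cat(sprintf("    %-8s %s\n", names(x$rates)[i],
                format(x$rates[i], digits = 4)))
  spread <- diff(range(x$restarts$lnL))
  cat(sprintf("  restart lnL spread: %.4g over %d restarts\n",
              spread, nrow(x$restarts)))
  invisible(x)
}

#' Corrected Akaike information criterion
#'
#' `AICc = -2 lnL + 2k + 2k(k+1)/(n-k-1)`, with the sample size `n` taken
#' as the number of taxa.
#'
#' @param lnL Maximized log-likelihood.
#' @param k Number of free parameters.
#' @param n Sample size (taxa); must exceed `k + 1`.
#' @return The AICc value.
#' @export
aicc <- function(lnL, k, n) {
  if (n - k - 1 <= 0)
    stop2("AICc undefined: need n > k + 1 (n = ", n, ", k = ", k, ")")
  -2 * lnL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Compare fitted models by AICc relative likelihood
#'
#' For each fit `i`, the relative likelihood (evidence weight against the
#' best model) is `exp((AICc_min - AICc_i)/2)`; the best model scores 1.
#'
#' @param ... Two or more `intein_fit` objects (or a single list of them),
#'   fitted to the same data (same taxon count).
#' @return A data frame with one row per model: `model`, `lnL`, `k`, `n`,
#'   `AICc`, `delta_AICc`, `rel_lik`, ordered as given.
#' @examples
#' \donttest{
#' sim <- simulate_dataset(n_tips = 60, rates = rep(1, 8), seed = 11)
#' f1 <- fit_model(sim$tree, sim$tip_states, "no_cohoming",
#'                 fit_options(restarts = 2))
#' f2 <- fit_model(sim$tree, sim$tip_states, "cohoming",
#'                 fit_options(restarts = 2))
#' compare_models(f1, f2)
#' }
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && !inherits(fits[[1L]], "intein_fit"))
    fits <- fits[[1L]]
  if (length(fits) < 2L) stop2("need at least two fits to compare")
  if (!all(vapply(fits, inherits, logical(1), "intein_fit")))
    stop2("all arguments must be intein_fit objects")
  ns <- vapply(fits, `[[`, numeric(1), "n")
  if (length(unique(ns)) != 1L)
    stop2("fits are not on the same data: taxon counts ",
          paste(unique(ns), collapse = ", "))
  a <- vapply(fits, `[[`, numeric(1), "AICc")
  data.frame(
    model = vapply(fits, `[[`, character(1), "model"),
    lnL = vapply(fits, `[[`, numeric(1), "lnL"),
    k = vapply(fits, `[[`, numeric(1), "k"),
    n = ns,
    AICc = a,
    delta_AICc = a - min(a),
    rel_lik = exp((min(a) - a) / 2)
  )
}
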