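test_that("transition models declare the allowed transitions and k", {
  m0 <- transition_model("no_cohoming")
  expect_equal(m0$k, 8L)
  expect_false(any(m0$transitions$from == m0$transitions$to))
  got <- paste(m0$transitions$from, m0$transitions$to)
  want <- c("1 2", "1 3", "2 1", "2 4", "3 1", "3 4", "4 2", "4 3")
  expect_setequal(got, want)

  m1 <- transition_model("cohoming")
  expect_equal(m1$k, 10L)
  expect_setequal(paste(m1$transitions$from, m1$transitions$to),
                  c(want, "1 4", "4 1"))
})

test_that("rate matrices honor constraints and row sums", {
  m0 <- transition_model("no_cohoming")
  expect_equal(build_rate_matrix(m0, rep(0, 8)), matrix(0, 4, 4,
    dimnames = list(c("--", "-D", "A-", "AD"), c("--", "-D", "A-", "AD"))))

  Q <- build_rate_matrix(m0, rep(1, 8))
  expect_equal(Q["--", "AD"], 0)
  expect_equal(Q["AD", "--"], 0)
  expect_equal(Q["--", "--"], -2)
  expect_equal(unname(rowSums(Q)), rep(0, 4))

  m1 <- transition_model("cohoming")
  Qc <- build_rate_matrix(m1, 1:10)
  for (i in seq_len(10))
    expect_equal(Qc[m1$transitions$from[i], m1$transitions$to[i]], i)
  offdiag <- Qc; diag(offdiag) <- 0
  expect_equal(sum(offdiag != 0), 10L)
  expect_equal(unname(rowSums(Qc)), rep(0, 4))

  expect_error(build_rate_matrix(m0, rep(1, 7)), "expected 8")
  expect_error(build_rate_matrix(m0, c(rep(1, 7), -1)), "non-negative")
})

test_that("P(t) = exp(Qt): identity at 0, stochastic rows, domain errors", {
  set.seed(5)
  Q <- build_rate_matrix(transition_model("cohoming"), runif(10, 0, 3))
  expect_equal(transition_probabilities(Q, 0), diag(4),
               ignore_attr = TRUE, tolerance = 1e-12)
  for (t in c(0.01, 0.5, 3)) {
    P <- transition_probabilities(Q, t)
    expect_true(all(P >= 0))
    expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
  }
  expect_error(transition_probabilities(Q, -1), "must be")
})

test_that("Chapman-Kolmogorov holds on random rate matrices", {
  for (seed in 1:5) {
    set.seed(seed)
    Q <- build_rate_matrix(transition_model("no_cohoming"), runif(8, 0, 2))
    s <- runif(1, 0, 5); t <- runif(1, 0, 5)
    lhs <- transition_probabilities(Q, s) %*% transition_probabilities(Q, t)
    rhs <- transition_probabilities(Q, s + t)
    expect_lt(max(abs(lhs - rhs)), 1e-8)
  }
})

test_that("two-state submodel reproduces the symmetric closed form", {
  r <- 0.8
  rates <- rep(0, 8)
  rates[1] <- r  # -- => -D
  rates[3] <- r  # -D => --
  Q <- build_rate_matrix(transition_model("no_cohoming"), rates)
  for (t in c(0.1, 1.3, 4)) {
    expect_equal(transition_probabilities(Q, t)["--", "-D"],
                 (1 - exp(-2 * r * t)) / 2, tolerance = 1e-10)
  }
})

test_that("matrix exponential agrees with an independent implementation", {
  set.seed(9)
  Q <- build_rate_matrix(transition_model("cohoming"), runif(10, 0, 4))
  for (t in c(0.2, 1, 2.5)) {
    expect_lt(max(abs(transition_probabilities(Q, t) -
                        ape::matexpo(Q * t))), 1e-9)
  }
})

test_that("stationary distribution satisfies pi Q = 0", {
  set.seed(2)
  Q <- build_rate_matrix(transition_model("no_cohoming"), runif(8, 0.2, 2))
  pi_hat <- stationary_distribution(Q)
  expect_equal(sum(pi_hat), 1, tolerance = 1e-12)
  expect_lt(max(abs(pi_hat %*% Q)), 1e-10)

  # the "equilibrium" root prior is exactly the stationary vector
  tr <- random_tree(6, seed = 3)
  x <- random_states(tr, seed = 4)
  expect_equal(pruning_loglik(tr, x, Q, pi = "equilibrium"),
               pruning_loglik(tr, x, Q, pi = pi_hat), tolerance = 1e-12)
})

test_that("pruning matches hand values on degenerate trees", {
  Q <- build_rate_matrix(transition_model("no_cohoming"), rep(1, 8))
  tr0 <- read_tree(text = "(A:0,B:0);")
  expect_equal(pruning_loglik(tr0, c(A = "AD", B = "AD"), Q), log(0.25),
               tolerance = 1e-12)
  # different states on zero-length branches are impossible
  expect_equal(pruning_loglik(tr0, c(A = "AD", B = "--"), Q), -Inf)
})

test_that("pruning equals exhaustive enumeration on small random trees", {
  for (seed in 1:10) {
    nt <- 3L + (seed %% 4L)
    tr <- random_tree(nt, seed = seed)
    x <- random_states(tr, seed = seed + 100)
    set.seed(seed + 200)
    Q <- build_rate_matrix(transition_model("cohoming"), runif(10, 0.1, 3))
    expect_equal(pruning_loglik(tr, x, Q), enum_loglik(tr, x, Q),
                 tolerance = 1e-10)
  }
})

test_that("pruning handles polytomies (checked against enumeration)", {
  tr <- read_tree(text = "((A:0.3,B:0.4,C:0.5):0.2,D:0.8,E:0.6);")
  tr <- ape::root(tr, outgroup = "D", resolve.root = TRUE)
  x <- c(A = "AD", B = "A-", C = "AD", D = "--", E = "-D")
  set.seed(77)
  Q <- build_rate_matrix(transition_model("no_cohoming"), runif(8, 0.2, 2))
  expect_equal(pruning_loglik(tr, x, Q), enum_loglik(tr, x, Q),
               tolerance = 1e-10)
})

test_that("on infinitely long branches tips become stationary draws", {
  set.seed(13)
  Q <- build_rate_matrix(transition_model("cohoming"), runif(10, 0.5, 2))
  pi_hat <- stationary_distribution(Q)
  tr <- random_tree(5, seed = 13)
  tr$edge.length <- rep(1e4, nrow(tr$edge))
  x <- random_states(tr, seed = 14)
  expect_equal(pruning_loglik(tr, x, Q, pi = pi_hat),
               sum(log(pi_hat[x])), tolerance = 1e-6)
})

test_that("likelihood is invariant to child order and tip-table order", {
  tr <- random_tree(8, seed = 21)
  x <- random_states(tr, seed = 22)
  set.seed(23)
  Q <- build_rate_matrix(transition_model("no_cohoming"), runif(8, 0.1, 2))
  base <- pruning_loglik(tr, x, Q)
  expect_equal(pruning_loglik(tr, rev(x), Q), base, tolerance = 1e-12)
  rot <- ape::rotateConstr(tr, rev(tr$tip.label))
  expect_equal(pruning_loglik(rot, x, Q), base, tolerance = 1e-12)
})

test_that("pruning validates its inputs with labeled errors", {
  tr <- read_tree(text = "((A:1,B:1):0.5,C:2);")
  Q <- build_rate_matrix(transition_model("no_cohoming"), rep(1, 8))
  expect_error(pruning_loglik(tr, c(A = "AD", B = "--"), Q), "C")
  expect_error(pruning_loglik(tr, c(A = "AD", B = "--", C = "--", Z = "AD"),
                              Q), "Z")
  expect_error(pruning_loglik(tr, c(A = "AD", B = "bad", C = "--"), Q),
               "unknown state")
  expect_error(pruning_loglik(ape::unroot(tr),
                              c(A = "AD", B = "--", C = "--"), Q), "rooted")
})
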