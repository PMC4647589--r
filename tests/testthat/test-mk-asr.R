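test_that("transition matrix has the closed form of the symmetric 2-state chain", {
  expect_equal(transition_matrix(0, 5), diag(2), ignore_attr = TRUE)
  # saturation: qt -> Inf gives the stationary (1/2, 1/2) matrix
  expect_equal(unclass(transition_matrix(50, 20)),
               matrix(0.5, 2, 2), ignore_attr = TRUE, tolerance = 1e-12)
  P <- transition_matrix(0.5, 1)
  expect_equal(P[1, 2], (1 - exp(-1)) / 2, tolerance = 1e-15)
  expect_equal(rowSums(P), c("0" = 1, "1" = 1))
  expect_error(transition_matrix(-1, 1), "non-negative")
  expect_error(transition_matrix(0.1, -2), "non-negative")
})

test_that("transition matrix agrees with the numerical matrix exponential", {
  skip_if_not_installed("Matrix")
  for (q in c(0.01, 0.1, 0.5, 1, 3, 10)) {
    for (t in c(0.1, 0.5, 1, 2, 7)) {
      Q <- matrix(c(-q, q, q, -q), 2, 2, byrow = TRUE)
      expect_lt(max(abs(transition_matrix(q, t) -
                          as.matrix(Matrix::expm(Q * t)))), 1e-12)
    }
  }
})

test_that("pruning likelihood honours the q = 0 limits and missing data", {
  tr <- set_unit_branch_lengths(parse_newick("((A,B),(C,D));"))
  all1 <- c(A = 1, B = 1, C = 1, D = 1)
  expect_equal(tree_log_likelihood(tr, all1, 0), log(0.5))
  mixed <- c(A = 1, B = 0, C = 1, D = 0)
  expect_identical(tree_log_likelihood(tr, mixed, 0), -Inf)
  # a '?' tip contributes (1,1): with q = 0 the remaining tips fix the state
  with_na <- c(A = 1, B = 1, C = 1, D = NA)
  expect_equal(tree_log_likelihood(tr, with_na, 0), log(0.5))
  expect_error(tree_log_likelihood(tr, c(A = 1, B = 0, C = 1), 0.1),
               "no state given")
})

test_that("2-tip cherry likelihood equals the analytic product", {
  tr <- set_unit_branch_lengths(parse_newick("(A:1,B:1);"))
  for (q in c(0.05, 0.3, 1)) {
    P <- transition_matrix(q, 1)
    # opposite states: 0.5 * (stay*switch + switch*stay) = stay * switch
    expect_equal(exp(tree_log_likelihood(tr, c(A = 1, B = 0), q)),
                 P[1, 1] * P[1, 2], tolerance = 1e-12)
    # same state: 0.5 * (stay^2 + switch^2)
    expect_equal(exp(tree_log_likelihood(tr, c(A = 1, B = 1), q)),
                 0.5 * (P[1, 1]^2 + P[1, 2]^2) * 2 * 0.5, tolerance = 1e-12)
  }
})

test_that("pruning equals exhaustive enumeration on random trees and polytomies", {
  set.seed(5)
  for (i in 1:6) {
    tr <- set_unit_branch_lengths(simulate_yule_tree(sample(4:6, 1),
                                                     seed = 400 + i))
    for (q in c(0.05, 0.3, 1.0)) {
      x <- setNames(sample(c(0, 1, NA), ape::Ntip(tr), TRUE,
                           prob = c(.45, .45, .1)), tr$tip.label)
      if (all(is.na(x))) x[1] <- 1
      expect_equal(tree_log_likelihood(tr, x, q),
                   tree_log_likelihood_bruteforce(tr, x, q),
                   tolerance = 1e-10)
    }
  }
  for (i in 1:4) { # multifurcations handled by the product over children
    tr <- random_polytomy_tree(7, seed = 500 + i)
    x <- setNames(sample(0:1, 7, TRUE), tr$tip.label)
    for (q in c(0.05, 0.3, 1.0))
      expect_equal(tree_log_likelihood(tr, x, q),
                   tree_log_likelihood_bruteforce(tr, x, q),
                   tolerance = 1e-10)
  }
})

test_that("per-node rescaling does not change the log-likelihood (200 tips, q = 5)", {
  tr <- set_unit_branch_lengths(simulate_yule_tree(200, seed = 8))
  set.seed(8)
  x <- setNames(sample(0:1, 200, TRUE), tr$tip.label)
  l_scaled <- tree_log_likelihood(tr, x, 5, scale = TRUE)
  l_plain <- tree_log_likelihood(tr, x, 5, scale = FALSE)
  expect_true(is.finite(l_scaled))
  expect_equal(l_scaled, l_plain, tolerance = 1e-9)
})

test_that("rate estimation: boundary on monomorphic data, 0/1 relabeling symmetry", {
  tr <- set_unit_branch_lengths(simulate_yule_tree(16, seed = 21))
  mono <- setNames(rep(1, 16), tr$tip.label)
  fit <- estimate_rate(tr, mono)
  expect_true(fit$boundary)
  expect_equal(fit$q, 1e-8, tolerance = 1e-3)
  expect_equal(fit$logL, log(0.5), tolerance = 1e-6)

  sim <- simulate_character(tr, 0.2, seed = 22)
  f1 <- estimate_rate(tr, sim$tip_states)
  f2 <- estimate_rate(tr, 1 - sim$tip_states)
  expect_equal(f1$q, f2$q, tolerance = 1e-9)
  expect_equal(f1$logL, f2$logL, tolerance = 1e-12)
})

test_that("rate and marginals agree with ape::ace under the ER model", {
  tr <- set_unit_branch_lengths(simulate_yule_tree(16, seed = 11))
  sim <- simulate_character(tr, 0.15, seed = 5)
  fit <- estimate_rate(tr, sim$tip_states)
  a <- ape::ace(sim$tip_states[tr$tip.label], tr, type = "discrete",
                model = "ER", marginal = FALSE)
  expect_equal(fit$q, unname(a$rates), tolerance = 1e-4)
  # ace omits the flat root prior factor: offset of exactly log(1/2)
  expect_equal(fit$logL, a$loglik + log(0.5), tolerance = 1e-6)
  asr <- marginal_node_proportions(tr, sim$tip_states, fit)
  expect_lt(max(abs(asr$p_present - a$lik.anc[, 2])), 1e-6)
})

test_that("up-down marginals equal clamp-and-renormalize everywhere", {
  set.seed(13)
  for (i in 1:6) {
    tr <- set_unit_branch_lengths(simulate_yule_tree(sample(4:6, 1),
                                                     seed = 600 + i))
    x <- setNames(sample(c(0, 1, NA), ape::Ntip(tr), TRUE,
                         prob = c(.45, .45, .1)), tr$tip.label)
    if (all(is.na(x))) x[1] <- 0
    for (q in c(0.05, 0.3, 1.0)) {
      a <- marginal_node_proportions(tr, x, q)
      b <- marginal_node_proportions_clamp(tr, x, q)
      expect_lt(max(abs(a$p_present - b$p_present)), 1e-10)
      expect_lt(max(abs(a$p_absent + a$p_present - 1)), 1e-12)
    }
  }
  for (i in 1:4) { # polytomies
    tr <- random_polytomy_tree(7, seed = 700 + i)
    x <- setNames(sample(0:1, 7, TRUE), tr$tip.label)
    a <- marginal_node_proportions(tr, x, 0.3)
    b <- marginal_node_proportions_clamp(tr, x, 0.3)
    expect_lt(max(abs(a$p_present - b$p_present)), 1e-10)
  }
})

test_that("marginals respect symmetry: balanced split gives a 50/50 root,
           0/1 relabeling swaps every node's pair", {
  tr <- set_unit_branch_lengths(parse_newick("((A:1,B:1):1,(C:1,D:1):1);"))
  x <- c(A = 1, B = 1, C = 0, D = 0)
  for (q in c(0.05, 0.5, 2)) {
    asr <- marginal_node_proportions(tr, x, q)
    root <- asr[asr$node == 5, ]
    expect_equal(root$p_present, 0.5, tolerance = 1e-12)
  }
  a <- marginal_node_proportions(tr, x, 0.3)
  b <- marginal_node_proportions(tr, 1 - x, 0.3)
  expect_equal(a$p_present, b$p_absent, tolerance = 1e-12)

  # monomorphic-present data at a tiny rate: presence ~certain everywhere
  tr16 <- set_unit_branch_lengths(simulate_yule_tree(16, seed = 31))
  mono <- setNames(rep(1, 16), tr16$tip.label)
  fit <- estimate_rate(tr16, mono)
  asr16 <- marginal_node_proportions(tr16, mono, fit)
  expect_true(all(asr16$p_present >= 0.99))
})

test_that("branch painting is strict at the threshold and anti-monotone", {
  tr <- set_unit_branch_lengths(parse_newick("((A:1,B:1):1,(C:1,D:1):1);"))
  x <- c(A = 1, B = 1, C = 0, D = 0)
  asr <- marginal_node_proportions(tr, x, 0.3)
  painted <- paint_branches(asr, 0.5)
  expect_false(5 %in% painted) # root is exactly 0.50: not painted
  expect_true(all(c(1, 2) %in% painted)) # tips observed present
  expect_true(6 %in% painted) # (A,B) ancestor

  mono <- setNames(rep(1, 4), tr$tip.label)
  fitm <- estimate_rate(tr, mono)
  all_painted <- paint_branches(marginal_node_proportions(tr, mono, fitm))
  expect_setequal(all_painted, tr$edge[, 2]) # every branch painted

  p70 <- paint_branches(asr, 0.7)
  expect_true(all(p70 %in% painted))
})

test_that("clade_report: fixed characters, deep singletons, mismatch errors", {
  tr <- read_newick(fertsig_example("bee_supertree_reconstructed.nwk"))
  tr <- set_unit_branch_lengths(tr)
  clades <- read_clade_definitions(fertsig_example("clades_bees.yml"))
  species <- tr$tip.label
  mat <- cbind(
    everywhere = setNames(rep(1, 16), species),
    apis_only = setNames(as.numeric(species == "Apis mellifera"), species)
  )
  rep <- clade_report(tr, mat, clades)
  expect_equal(unname(unclass(rep)["everywhere", ]), rep(100, 7),
               tolerance = 1e-4)
  # a single presence deep inside the tree leaves distant clades near zero
  expect_lt(rep["apis_only", "Apidae sensu lato"], 10)
  expect_lt(rep["apis_only", "Meliponini"], 25)
  expect_false(attr(rep, "flags")["apis_only", "Apidae sensu lato"])
  expect_true(all(attr(rep, "flags")["everywhere", ]))

  bad <- mat[-1, , drop = FALSE]
  expect_error(clade_report(tr, bad, clades), "mismatch")
})

test_that("report cells are invariant to row/column order of the matrix", {
  tr <- set_unit_branch_lengths(simulate_yule_tree(8, seed = 91))
  set.seed(91)
  mat <- sapply(1:3, function(j) simulate_character(tr, 0.2)$tip_states)
  colnames(mat) <- c("c1", "c2", "c3")
  clades <- list(all = tr$tip.label, half = tr$tip.label[1:4])
  r1 <- clade_report(tr, mat, clades)
  r2 <- clade_report(tr, mat[sample(8), c(3, 1, 2)], clades)
  expect_equal(unclass(r2)[rownames(r1), colnames(r1)], unclass(r1),
               ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("report rounding is half-up to one decimal", {
  expect_equal(round_half_up(49.95, 1), 50.0)
  expect_equal(round_half_up(0.05, 1), 0.1)
  expect_equal(round_half_up(69.24, 1), 69.2)
})
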