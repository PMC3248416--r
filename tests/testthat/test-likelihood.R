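test_that("pruning equals exhaustive enumeration on small trees", {
  skip_if_not_installed("Matrix")
  set.seed(31)
  for (i in 1:6) {
    ntip <- sample(2:4, 1)
    tr <- if (ntip == 2) read_newick(text = sprintf("(t1:%.3f,t2:%.3f);",
                                                    runif(1, .05, .5),
                                                    runif(1, .05, .5)))
          else ape::unroot(random_tree(ntip))
    m <- random_mech_model()
    aln <- simulate_alignment(tr, m, 3, seed = 100 + i)
    ll <- tree_loglik(tr, aln, m)
    expect_equal(ll$lnL, oracle_loglik(tr, aln, m), tolerance = 1e-10)
  }
})

test_that("lnL is invariant to root placement and tip order", {
  set.seed(32)
  tr <- random_tree(6)
  m <- random_mech_model()
  aln <- simulate_alignment(tr, m, 20, seed = 33)
  ll <- tree_loglik(tr, aln, m)$lnL
  # reroot at a different internal node
  tr2 <- ape::root(ape::unroot(tr), node = 9, resolve.root = FALSE)
  expect_lt(abs(tree_loglik(tr2, aln, m)$lnL - ll), 1e-9)
  # permute alignment rows
  aln2 <- aln
  perm <- sample(nrow(aln$states))
  aln2$states <- aln$states[perm, , drop = FALSE]
  expect_lt(abs(tree_loglik(tr, aln2, m)$lnL - ll), 1e-12)
})

test_that("degenerate trees and boundary branch lengths behave", {
  m <- uniform_model()
  # identical single-codon sequences at branch length 0
  aln <- codon_alignment(c(a = "AAA", b = "AAA"), gc_uni)
  tr <- read_newick(text = "(a:0,b:0);")
  expect_equal(tree_loglik(tr, aln, m)$lnL, log(1 / 61))
  # single-tip tree: the prior alone
  aln1 <- codon_alignment(c(a = "AAACCCGGG"), gc_uni)
  tr1 <- read_newick(text = "(a:0.3);")
  expect_equal(tree_loglik(tr1, aln1, m)$lnL, 3 * log(1 / 61))
  # mismatched names and empty alignments error
  trx <- read_newick(text = "(a:0.1,zz:0.1);")
  expect_error(tree_loglik(trx, aln, m), "absent from alignment")
})

test_that("missing and ambiguous codons marginalize correctly", {
  m <- uniform_model()
  tr <- read_newick(text = "(a:0,b:0);")
  # fully missing tip leaves the prior
  aln <- codon_alignment(c(a = "NNN", b = "---"), gc_uni)
  expect_equal(tree_loglik(tr, aln, m)$lnL, 0)
  # AAR at t=0 against AAA pins the state
  aln2 <- codon_alignment(c(a = "AAR", b = "AAA"), gc_uni)
  expect_equal(tree_loglik(tr, aln2, m)$lnL, log(1 / 61))
  # AAR alone marginalizes over AAA + AAG
  aln3 <- codon_alignment(c(a = "AAR", b = "NNN"), gc_uni)
  expect_equal(tree_loglik(tr, aln3, m)$lnL, log(2 / 61))
})

test_that("mixture likelihood combines categories by their priors", {
  set.seed(34)
  tr <- random_tree(5)
  base <- random_mech_model()
  mix <- rate_categories(base, alpha = 0.8, m = 3)
  aln <- simulate_alignment(tr, mix, 15, seed = 35)
  ll <- tree_loglik(tr, aln, mix)
  # recompute from the per-category single-model likelihoods
  manual <- sapply(seq_len(3), function(k)
    tree_loglik(tr, aln, single_category(mix$models[[k]]))$site_lnL)
  expected <- log(rowSums(exp(manual) %*% diag(mix$priors)))
  expect_equal(ll$site_lnL, expected, tolerance = 1e-10)
  expect_equal(ll$lnL, sum(expected), tolerance = 1e-8)
})

test_that("AIC/BIC arithmetic and the LRT behave as defined", {
  expect_equal(aic(-1000, 62), 2124)
  expect_equal(bic(-1000, 62, 3000), 2000 + 62 * log(3000))
  expect_equal(aic(-500, 0), 1000)
  r <- lrt(list(lnL = -100, K = 1), list(lnL = -100, K = 2))
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  r2 <- lrt(list(lnL = -101.92, K = 1), list(lnL = -100, K = 2))
  expect_equal(r2$statistic, 3.84)
  expect_equal(r2$p, 0.05, tolerance = 0.01)
  r3 <- lrt(list(lnL = -100, K = 2), list(lnL = -100, K = 4))
  expect_equal(r3$df, 2)
  expect_equal(r3$p, 1)
  expect_error(lrt(list(lnL = -100, K = 3), list(lnL = -99, K = 3)),
               "more parameters")
})

test_that("parameter counting matches the model naming conventions", {
  expect_length(named_parameters("mechanistic"), 11)
  full <- c("exch", "sigma", "beta", "w0", "theta", "alpha")
  expect_equal(count_parameters("mechanistic", full, gc_uni,
                                frequencies_estimated = FALSE), 11L)
  expect_equal(count_parameters("mechanistic", setdiff(full, c("beta", "w0")),
                                gc_uni, frequencies_estimated = FALSE), 9L)
  expect_equal(count_parameters("mechanistic", setdiff(full, "theta"),
                                gc_uni, frequencies_estimated = FALSE), 10L)
  expect_equal(count_parameters("mechanistic", full, gc_uni), 11L + 60L)
  expect_equal(count_parameters("mechanistic", full, gc_mito), 11L + 59L)
  expect_error(count_parameters("mechanistic", "zeta", gc_uni), "unknown")
})

test_that("posterior site constraints are prior-weighted category means", {
  set.seed(36)
  f <- uniform_freqs()
  p <- mutation_params(c(1, 4, 1, 1, 4, 1), 0.05)
  mix <- constraint_categories(p, equal_constraint(), 1, -1, f, gc_uni,
                               alpha = 0.4, m = 4)
  tr <- random_tree(6, 0.2, 0.5)
  aln <- simulate_alignment(tr, mix, 60, seed = 37)
  # blank out one site entirely: its posterior is the prior mean
  aln$states[, 1] <- 0L
  fit <- codon_fit(aln, tr, site_variation = "constraint", categories = 4,
                   free = character(0), optimize_branches = FALSE,
                   start = list(exch = c(1, 4, 1, 1, 4, 1), sigma = 0.05,
                                beta = 1, w0 = -1, alpha = 0.4))
  post <- posterior_site_constraints(fit)
  prior_mean <- sum(mix$priors * mix$category_values)
  expect_equal(post[1], prior_mean, tolerance = 1e-10)
  expect_true(all(post >= min(mix$category_values) - 1e-12 &
                  post <= max(mix$category_values) + 1e-12))
  # conserved simulated sites get lower posterior acceptance than fast ones
  truth <- attr(aln, "truth")$categories[-1]
  expect_lt(mean(post[-1][truth == 1]), mean(post[-1][truth == 4]))
  # a rate mixture has no constraint posterior
  fit2 <- codon_fit(aln, tr, site_variation = "rate", categories = 2,
                    free = character(0), optimize_branches = FALSE)
  expect_error(posterior_site_constraints(fit2), "constraint")
})

test_that("a fit with nothing free returns the supplied configuration", {
  set.seed(38)
  tr <- random_tree(4)
  m <- uniform_model()
  aln <- simulate_alignment(tr, m, 25, seed = 39)
  fit <- codon_fit(aln, tr, free = character(0), optimize_branches = FALSE,
                   start = list(sigma = 1, beta = 0, w0 = 0),
                   frequencies = uniform_freqs())
  expect_equal(fit$lnL, tree_loglik(tr, aln, m)$lnL, tolerance = 1e-10)
  expect_equal(fit$tree$edge.length,
               stats::reorder(tr, "postorder")$edge.length)
  expect_true(fit$converged)
  expect_equal(fit$K, count_parameters("mechanistic", character(0), gc_uni,
                                       frequencies_estimated = FALSE))
})

test_that("conflict-free data drives branch lengths to the lower bound", {
  seqs <- c(a = "AAACCCGGGTTTACA", b = "AAACCCGGGTTTACA",
            c = "AAACCCGGGTTTACA")
  aln <- codon_alignment(seqs, gc_uni)
  tr <- read_newick(text = "(a:0.2,b:0.2,c:0.2);")
  fit <- codon_fit(aln, tr, free = character(0), optimize_branches = TRUE)
  expect_true(all(fit$tree$edge.length < 1e-4))
})

test_that("fit results serialize with AIC/BIC identities intact", {
  set.seed(40)
  tr <- random_tree(4)
  m <- uniform_model()
  aln <- simulate_alignment(tr, m, 30, seed = 41)
  fit <- codon_fit(aln, tr, free = "sigma",
                   control = list(max_cycles = 3, tol = 1e-4))
  expect_equal(fit$aic, -2 * fit$lnL + 2 * fit$K)
  expect_equal(fit$bic, -2 * fit$lnL + fit$K * log(fit$n_sites))
  ll <- logLik(fit)
  expect_equal(AIC(ll), fit$aic)
  expect_equal(BIC(ll), fit$bic)
  expect_equal(attr(ll, "df"), fit$K)
})
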