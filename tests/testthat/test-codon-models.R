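test_that("mutation exchangeability follows the sigma^(d-1) product rule", {
  p <- mutation_params(rep(1, 6), sigma = 0.5)
  C <- build_mutation_exchangeability(p, gc_uni)
  expect_equal(C["AAA", "AAG"], 1)
  expect_equal(C["AAA", "AGG"], 0.5)
  expect_equal(C["AAA", "GGG"], 0.25)
  expect_true(isSymmetric(C))
  expect_equal(sum(diag(C)), 0)

  # sigma = 0 kills every multi-nucleotide change
  C0 <- build_mutation_exchangeability(mutation_params(rep(1, 6), 0), gc_uni)
  expect_true(all(C0[gc_uni$ndiff >= 2] == 0))
  expect_true(all(C0[gc_uni$ndiff == 1] > 0))

  # per-position product rule (transversion mean kept at 1)
  p2 <- mutation_params(c(1, 4, 1, 1, 1, 1), sigma = 1)
  C2 <- build_mutation_exchangeability(p2, gc_uni)
  expect_equal(C2["AAA", "GAA"], 4 * p2$sigma^0)
  expect_equal(C2["AAA", "GGA"], 16 * p2$sigma)
  expect_equal(C2["AAA", "GGA"] / C2["AAA", "GAA"]^2, p2$sigma)
})

test_that("kappa is the mean transition/transversion exchangeability ratio", {
  expect_equal(kappa_of(mutation_params(c(1, 4, 1, 1, 4, 1), 0)), 4)
  expect_equal(kappa_of(mutation_params(c(1, 2, 1, 1, 6, 1), 0)), 4)
  expect_equal(kappa_of(mutation_params(rep(1, 6), 0)), 1)
  # normalization convention: transversion mean is 1, model unchanged
  p <- mutation_params(c(2, 8, 2, 2, 8, 2), sigma = 0.1)
  expect_equal(mean(p$exch[c(1, 3, 4, 6)]), 1)
  expect_equal(kappa_of(p), 4)
})

test_that("uniform equal-rates chain matches its closed forms", {
  m <- uniform_model()
  off <- m$Q[row(m$Q) != col(m$Q)]
  expect_equal(max(abs(off - 1 / 60)), 0, tolerance = 1e-12)
  expect_equal(m$scale_c, 61 / 60)
  P <- transition_probabilities(m, 1)
  expect_equal(P[1, 1], 1 / 61 + (60 / 61) * exp(-61 / 60),
               tolerance = 1e-10)
  expect_equal(transition_probabilities(m, 0),
               diag(61), ignore_attr = TRUE, tolerance = 1e-12)
  # ergodic limit
  Pinf <- transition_probabilities(m, 1e3)
  expect_lt(max(abs(sweep(Pinf, 2, m$freqs))), 1e-10)
})

test_that("all three families produce valid reversible generators", {
  set.seed(11)
  for (i in 1:12) {
    expect_valid_generator(random_mech_model())
    f <- random_freqs()
    expect_valid_generator(codon_model_aa(random_aa_exch(),
                                          runif(1, 0.2, 5), f, gc_uni))
    expect_valid_generator(codon_model_empirical(random_codon_exch(),
                                                 runif(1, 0.2, 5), f,
                                                 gc_uni))
    fm <- random_freqs(gc_mito)
    expect_valid_generator(codon_model_mechanistic(
      random_mutation_params(),
      linear_constraints(synthetic_what(), 1, -1), fm, gc_mito))
  }
})

test_that("sigma = 0 forbids multi-nucleotide changes; sigma > 0 connects all", {
  set.seed(12)
  f <- random_freqs()
  w <- linear_constraints(synthetic_what(), 1, -1)
  m0 <- codon_model_mechanistic(mutation_params(rgamma(6, 2) + 0.1, 0),
                                w, f, gc_uni)
  expect_true(all(m0$Q[gc_uni$ndiff >= 2] == 0))
  m1 <- codon_model_mechanistic(mutation_params(rgamma(6, 2) + 0.1, 0.05),
                                w, f, gc_uni)
  expect_true(all(transition_probabilities(m1, 0.5)[gc_uni$ndiff >= 1] > 0))
})

test_that("generator is invariant to the exch/sigma scale redundancy", {
  set.seed(13)
  e <- rgamma(6, 2) + 0.1
  f <- random_freqs()
  w <- linear_constraints(synthetic_what(), 1, -1)
  m1 <- codon_model_mechanistic(mutation_params(e, 0.2), w, f, gc_uni)
  m2 <- codon_model_mechanistic(mutation_params(5 * e, 0.2 / 5), w, f, gc_uni)
  expect_equal(m1$Q, m2$Q, tolerance = 1e-12)
})

test_that("without selection the model is blind to amino acid identity", {
  set.seed(14)
  p <- random_mutation_params()
  f <- random_freqs()
  w1 <- linear_constraints(synthetic_what(), 0, 0)
  w2 <- linear_constraints(equal_constraint(), 0, 0)
  m1 <- codon_model_mechanistic(p, w1, f, gc_uni)
  m2 <- codon_model_mechanistic(p, w2, f, gc_uni)
  expect_equal(m1$Q, m2$Q, tolerance = 1e-14)
})

test_that("Chapman-Kolmogorov holds and P(t) matches a matrix exponential", {
  skip_if_not_installed("Matrix")
  set.seed(15)
  for (i in 1:5) {
    m <- random_mech_model()
    s <- runif(1, 0, 5); t <- runif(1, 0, 5)
    expect_lt(max(abs(transition_probabilities(m, s + t) -
                      transition_probabilities(m, s) %*%
                      transition_probabilities(m, t))), 1e-8)
  }
  m <- random_mech_model()
  expect_lt(max(abs(transition_probabilities(m, 0.7) -
                    as.matrix(Matrix::expm(0.7 * m$Q)))), 1e-10)
})

test_that("codon frequency estimation follows the pseudocount rule", {
  S <- gc_uni$n_sense
  aln <- aln_from_states(matrix(rep(1:S, 2), nrow = 2, byrow = TRUE))
  f <- estimate_codon_frequencies(aln, pseudocount = 0)
  expect_equal(unname(f), rep(1 / S, S))
  # a single repeated codon with the default pseudocount
  aln2 <- aln_from_states(matrix(1L, 1, 10))
  f2 <- estimate_codon_frequencies(aln2, pseudocount = 0.5)
  expect_equal(unname(f2[1]), 10.5 / (10 + 0.5 * 61))
  expect_true(all(f2 > 0))
  expect_error(estimate_codon_frequencies(aln2, pseudocount = 0),
               "unobserved")
  expect_error(codon_alignment(character(0), gc_uni))
  expect_error(codon_alignment(c(a = "TAA"), gc_uni), "stop codon")
})

test_that("converted amino acid model scales synonymous rates by rho", {
  set.seed(16)
  ae <- random_aa_exch()
  f <- random_freqs()
  syn <- mechcodon:::.syn_mask(gc_uni)
  m1 <- codon_model_aa(ae, 1, f, gc_uni)
  # at rho = 1 every synonymous exchangeability equals max nonsyn
  C1 <- m1$exchangeability / m1$scale_c
  expect_equal(unname(range(C1[syn])), rep(max(ae), 2))
  # all-equal exchangeabilities, uniform f: all off-diagonal rates equal
  ones <- matrix(1, 20, 20); diag(ones) <- 0
  mu <- codon_model_aa(ones, 1, uniform_freqs(), gc_uni)
  off <- mu$Q[row(mu$Q) != col(mu$Q)]
  expect_lt(diff(range(off)), 1e-12)
  expect_error(codon_model_aa(matrix(0, 20, 20), 1, f, gc_uni),
               "degenerate")
})

test_that("extended empirical codon model balances syn/nonsyn maxima", {
  set.seed(17)
  ec <- random_codon_exch()
  f <- random_freqs()
  syn <- mechcodon:::.syn_mask(gc_uni)
  nonsyn <- !syn; diag(nonsyn) <- FALSE
  m1 <- codon_model_empirical(ec, 1, f, gc_uni)
  C1 <- m1$exchangeability
  expect_equal(max(C1[syn]), max(C1[nonsyn]))
  # rho = 2 doubles synonymous relative to nonsynonymous exchangeability
  m2 <- codon_model_empirical(ec, 2, f, gc_uni)
  C2 <- m2$exchangeability
  r1 <- C1[syn][1] / C1[nonsyn][1]
  r2 <- C2[syn][1] / C2[nonsyn][1]
  expect_equal(r2 / r1, 2, tolerance = 1e-10)
  # uniform exchangeabilities: rates constant within syn and nonsyn blocks
  ones <- matrix(1, 61, 61); diag(ones) <- 0
  dimnames(ones) <- list(gc_uni$sense_codons, gc_uni$sense_codons)
  mu <- codon_model_empirical(ones, 1, uniform_freqs(), gc_uni)
  expect_lt(diff(range(mu$Q[syn])), 1e-12)
  expect_lt(diff(range(mu$Q[nonsyn])), 1e-12)
  ec0 <- ones; ec0[syn] <- 0
  expect_error(codon_model_empirical(ec0, 1, f, gc_uni), "synonymous")
})
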