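# Shared builders for tests.  Everything is generated in code under
# fixed seeds; no fixture files are read from disk.

gc_uni <- genetic_code("universal")
gc_mito <- genetic_code("vertebrate-mito")

uniform_freqs <- function(code = gc_uni) rep(1 / code$n_sense, code$n_sense)

# the uniform equal-rates chain: all exchangeabilities 1, sigma = 1, no
# selection; every off-diagonal rate is 1/60 (universal code)
uniform_model <- function(code = gc_uni) {
  codon_model_mechanistic(mutation_params(rep(1, 6), 1),
                          linear_constraints(equal_constraint(), 0, 0),
                          uniform_freqs(code), code)
}

# random strictly positive frequencies over sense codons
random_freqs <- function(code = gc_uni) {
  f <- stats::rgamma(code$n_sense, shape = 5)
  f / sum(f)
}

random_mutation_params <- function() {
  mutation_params(stats::rgamma(6, shape = 2, rate = 2) + 0.05,
                  sigma = stats::runif(1, 0, 0.5))
}

# synthetic symmetric nonpositive constraint estimate
synthetic_what <- function() {
  w <- matrix(0, 20, 20, dimnames = list(AA_ORDER, AA_ORDER))
  w[upper.tri(w)] <- -stats::runif(190, 0.2, 3)
  w <- w + t(w)
  structure(w, source = "synthetic",
            class = c("constraint_matrix", "matrix"))
}

random_aa_exch <- function() {
  e <- matrix(0, 20, 20, dimnames = list(AA_ORDER, AA_ORDER))
  e[upper.tri(e)] <- stats::rgamma(190, shape = 0.8)
  e + t(e)
}

random_codon_exch <- function(code = gc_uni) {
  S <- code$n_sense
  e <- matrix(0, S, S,
              dimnames = list(code$sense_codons, code$sense_codons))
  e[upper.tri(e)] <- stats::rgamma(S * (S - 1) / 2, shape = 0.6)
  e + t(e)
}

random_mech_model <- function(code = gc_uni) {
  codon_model_mechanistic(
    random_mutation_params(),
    linear_constraints(synthetic_what(), stats::runif(1, 0.2, 1.5),
                       -stats::runif(1, 0.2, 2)),
    random_freqs(code), code)
}

random_tree <- function(ntip, min_bl = 0.05, max_bl = 0.5) {
  tr <- ape::rtree(ntip, br = NULL)
  tr$edge.length <- stats::runif(nrow(tr$edge), min_bl, max_bl)
  tr
}

# alignment straight from sense-codon state indices
aln_from_states <- function(states, code = gc_uni) {
  mechcodon:::.alignment_from_states(states, code)
}
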