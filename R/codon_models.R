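#' Nucleotide mutation parameters for the mechanistic codon model
#'
#' Six GTR-style nucleotide exchangeabilities, shared across the three
#' codon positions, together with the multiple-change ratio `sigma`
#' (exchangeability of a double change relative to a single change, and of
#' a triple relative to a double).  The one-dimensional redundancy between
#' the overall exchangeability scale and `sigma` is removed by rescaling
#' the exchangeabilities so that the mean of the four transversion types
#' (AC, AT, CG, GT) equals 1; `sigma` is rescaled jointly so the model is
#' unchanged.
#'
#' @param exch numeric vector of 6 positive exchangeabilities in the order
#'   `e_AC, e_AG, e_AT, e_CG, e_CT, e_GT` (names optional).
#' @param sigma nonnegative multiple-change ratio; 0 forbids multiple
#'   nucleotide changes in infinitesimal time.
#' @return An object of class `mutation_params` with normalized `exch`
#'   and `sigma`.
#' @examples
#' p <- mutation_params(c(1, 4, 1, 1, 4, 1), sigma = 0.1)
#' kappa_of(p)  # 4
#' @export
mutation_params <- function(exch = rep(1, 6), sigma = 0) {
  stopifnot(is.numeric(exch), length(exch) == 6, all(exch > 0),
            is.numeric(sigma), length(sigma) == 1, sigma >= 0, is.finite(sigma))
  exch <- as.numeric(exch)
  tv_mean <- mean(exch[c(1, 3, 4, 6)])
  exch <- exch / tv_mean
  sigma <- sigma * tv_mean
  names(exch) <- paste0("e_", NUC_PAIRS)
  structure(list(exch = exch, sigma = sigma), class = "mutation_params")
}

#' @export
print.mutation_params <- function(x, ...) {
  cat("Nucleotide mutation parameters (transversion mean = 1):\n")
  print(round(x$exch, 4))
  cat("sigma =", x$sigma, " kappa =", round(kappa_of(x), 4), "\n")
  invisible(x)
}

#' Transition/transversion exchangeability ratio
#'
#' `kappa = mean(e_AG, e_CT) / mean(e_AC, e_AT, e_CG, e_GT)`.
#'
#' @param p a [mutation_params()] object.
#' @export
kappa_of <- function(p) {
  stopifnot(inherits(p, "mutation_params"))
  mean(p$exch[c(2, 5)]) / mean(p$exch[c(1, 3, 4, 6)])
}

#' Equilibrium codon frequencies from observed counts
#'
#' The "F" convention: equilibrium frequencies equal observed codon
#' frequencies in the alignment, with an optional pseudocount per sense
#' codon so that every frequency is strictly positive.
#'
#' @param aln a [codon_alignment] object.
#' @param pseudocount nonnegative count added to every sense codon
#'   (default 0.5).
#' @return Named numeric vector over the sense codons, summing to 1.
#' @export
estimate_codon_frequencies <- function(aln, pseudocount = 0.5) {
  stopifnot(inherits(aln, "codon_alignment"), pseudocount >= 0)
  S <- aln$code$n_sense
  states <- aln$states[aln$states > 0]
  if (length(states) == 0 && pseudocount == 0)
    stop("no observed codons and pseudocount = 0: frequencies undefined")
  counts <- tabulate(states, nbins = S) + pseudocount
  if (any(counts == 0))
    stop("some sense codons unobserved with pseudocount = 0; ",
         "use a positive pseudocount")
  f <- counts / sum(counts)
  names(f) <- aln$code$sense_codons
  f
}

#' Codon mutation exchangeability matrix with multiple nucleotide changes
#'
#' For sense codons differing at `d >= 1` positions the mutational
#' exchangeability is `sigma^(d-1)` times the product of the per-position
#' nucleotide exchangeabilities; nucleotide mutations act independently at
#' each codon position, so a double change at positions 1 and 3 is as
#' frequent as one at adjacent positions.
#'
#' @param p a [mutation_params()] object.
#' @param code a [genetic_code()] object.
#' @return Symmetric sense x sense matrix with zero diagonal.
#' @export
build_mutation_exchangeability <- function(p, code) {
  stopifnot(inherits(p, "mutation_params"), inherits(code, "genetic_code"))
  S <- code$n_sense
  d <- code$ndiff
  M <- ifelse(d > 0, p$sigma^(d - 1), 0)  # sigma^0 = 1 covers single changes
  e1 <- c(1, p$exch)
  for (k in 1:3) M <- M * e1[code$pair_id[, , k] + 1L]
  dimnames(M) <- list(code$sense_codons, code$sense_codons)
  M
}

# Synonymous indicator over sense-codon pairs (diagonal FALSE)
.syn_mask <- function(code) {
  a <- code$aa_index
  same <- outer(a, a, "==")
  diag(same) <- FALSE
  same
}

# Finish a codon model: given an unscaled symmetric exchangeability C
# (zero diagonal) and frequencies f, build Q = scale * C * f_j, set the
# scale so the mean rate -sum f_i Q_ii = 1, and eigendecompose the
# similarity-symmetrized generator for reuse across branch lengths.
.finish_model <- function(C, f, code, family, params) {
  S <- code$n_sense
  stopifnot(length(f) == S, all(f > 0), abs(sum(f) - 1) < 1e-8)
  f <- f / sum(f)
  Q <- C * rep(f, each = S)      # Q_ij = C_ij * f_j
  diag(Q) <- 0
  rate <- sum(f * rowSums(Q))
  if (rate <= 0) stop("degenerate generator: all off-diagonal rates are zero")
  scale_c <- 1 / rate
  C <- C * scale_c
  Q <- Q * scale_c
  diag(Q) <- -rowSums(Q)
  m <- structure(list(code = code, freqs = f, exchangeability = C, Q = Q,
                      scale_c = scale_c, family = family, params = params),
                 class = "codon_model")
  m$eig <- .eig_decompose(m)
  m
}

.eig_decompose <- function(m) {
  sq <- sqrt(m$freqs)
  Sy <- m$Q * (sq / rep(sq, each = length(sq)))  # D Q D^-1, symmetric
  Sy <- (Sy + t(Sy)) / 2
  e <- eigen(Sy, symmetric = TRUE)
  list(values = e$values,
       U = e$vectors / sq,            # rows scaled by 1/sqrt(f)
       W = t(e$vectors * sq))         # columns recombined with sqrt(f)
}

# Rescale an existing model's generator by a scalar (used by mixtures).
.rescale_model <- function(m, s) {
  m$Q <- m$Q * s
  m$exchangeability <- m$exchangeability * s
  m$scale_c <- m$scale_c * s
  m$eig$values <- m$eig$values * s
  m
}

.mean_rate <- function(m) -sum(m$freqs * diag(m$Q))

#' Mechanistic codon substitution model
#'
#' Builds the reversible codon rate matrix whose exchangeability is the
#' product of a mutational term (GTR nucleotide exchangeabilities with
#' multiple changes damped by `sigma`, see
#' [build_mutation_exchangeability()]) and an acceptance term
#' `exp(w_ab)` for the encoded amino acid pair (`w_aa = 0`: synonymous
#' changes are neutral at the amino acid level).  Rates are
#' `Q_ij = C_ij * f_j` with the time unit normalized to one expected
#' substitution per codon site at equilibrium.
#'
#' @param p a [mutation_params()] object.
#' @param w 20x20 selective-constraint matrix with zero diagonal (e.g.
#'   from [linear_constraints()]).
#' @param f equilibrium frequencies over sense codons.
#' @param code a [genetic_code()] object.
#' @return A `codon_model` object.
#' @examples
#' gc <- genetic_code("universal")
#' f <- rep(1 / gc$n_sense, gc$n_sense)
#' m <- codon_model_mechanistic(mutation_params(sigma = 1),
#'                              linear_constraints(equal_constraint(), 0, 0),
#'                              f, gc)
#' @export
codon_model_mechanistic <- function(p, w, f, code) {
  stopifnot(identical(dim(w), c(20L, 20L)))
  if (any(diag(w) != 0)) stop("w must have zero diagonal")
  Cmut <- build_mutation_exchangeability(p, code)
  A <- exp(w)[code$aa_index, code$aa_index]
  diag(A) <- 0
  .finish_model(Cmut * A, f, code, "mechanistic",
                list(mutation = p, w = w))
}

#' Codon model converted from an empirical amino acid model
#'
#' Codon exchangeabilities for nonsynonymous pairs (including those
#' requiring multiple nucleotide changes) are proportional to the
#' empirical amino acid exchangeability of the encoded pair; synonymous
#' exchangeabilities are all equal, and at `rho = 1` equal to the maximum
#' nonsynonymous exchangeability.  As `rho -> Inf` the model becomes
#' equivalent to the underlying amino acid model.
#'
#' @param aa_exch symmetric nonnegative 20x20 amino acid exchangeability
#'   matrix with zero diagonal (e.g. from [read_paml_dat()]).
#' @param rho positive synonymous/nonsynonymous adjuster.
#' @param f equilibrium frequencies over sense codons.
#' @param code a [genetic_code()] object.
#' @return A `codon_model` object.
#' @export
codon_model_aa <- function(aa_exch, rho, f, code) {
  stopifnot(identical(dim(aa_exch), c(20L, 20L)), rho > 0)
  if (max(abs(aa_exch - t(aa_exch))) > 1e-8) stop("aa_exch must be symmetric")
  if (any(aa_exch < 0)) stop("aa_exch must be nonnegative")
  if (any(diag(aa_exch) != 0)) stop("aa_exch must have zero diagonal")
  emax <- max(aa_exch)
  if (emax == 0) stop("degenerate generator: all off-diagonal rates are zero")
  C <- aa_exch[code$aa_index, code$aa_index]
  C[.syn_mask(code)] <- rho * emax
  diag(C) <- 0
  .finish_model(C, f, code, "aa", list(aa_exch = aa_exch, rho = rho))
}

#' Extended empirical codon substitution model
#'
#' Starts from an empirical sense-codon exchangeability matrix and
#' rescales its synonymous block by `rho` and its nonsynonymous block so
#' that at `rho = 1` the maximum nonsynonymous exchangeability equals the
#' maximum synonymous one.
#'
#' @param codon_exch symmetric nonnegative sense x sense exchangeability
#'   matrix with zero diagonal, codon labels matching `code`.
#' @param rho positive synonymous/nonsynonymous adjuster.
#' @param f equilibrium frequencies over sense codons.
#' @param code a [genetic_code()] object.
#' @return A `codon_model` object.
#' @export
codon_model_empirical <- function(codon_exch, rho, f, code) {
  S <- code$n_sense
  stopifnot(identical(dim(codon_exch), c(S, S)), rho > 0)
  if (!is.null(rownames(codon_exch)) &&
      !identical(rownames(codon_exch), code$sense_codons))
    stop("codon_exch labels do not match the sense codons of '",
         code$name, "'")
  if (max(abs(codon_exch - t(codon_exch))) > 1e-8)
    stop("codon_exch must be symmetric")
  if (any(codon_exch < 0)) stop("codon_exch must be nonnegative")
  syn <- .syn_mask(code)
  nonsyn <- !syn; diag(nonsyn) <- FALSE
  max_syn <- max(codon_exch[syn])
  max_nonsyn <- max(codon_exch[nonsyn])
  if (max_syn == 0 || max_nonsyn == 0)
    stop("codon_exch needs nonzero synonymous and nonsynonymous entries")
  C <- codon_exch
  C[syn] <- rho * codon_exch[syn]
  C[nonsyn] <- codon_exch[nonsyn] * (max_syn / max_nonsyn)
  diag(C) <- 0
  .finish_model(C, f, code, "empirical",
                list(codon_exch = codon_exch, rho = rho))
}

#' Transition probability matrix P(t) = exp(tQ)
#'
#' Computed from the eigendecomposition of the similarity-symmetrized
#' generator (reversibility guarantees a real spectrum); one decomposition
#' stored in the model serves all branch lengths.  Tiny negative entries
#' (>= -1e-12) from roundoff are clipped to 0.
#'
#' @param m a `codon_model`.
#' @param t nonnegative time (expected substitutions per codon site).
#' @return Stochastic sense x sense matrix.
#' @export
transition_probabilities <- function(m, t) {
  stopifnot(inherits(m, "codon_model"), is.finite(t), t >= 0)
  .assemble_P(m, exp(t * m$eig$values))
}

# Assemble U diag(g(lambda)) W and clip roundoff negatives.
.assemble_P <- function(m, gvals) {
  P <- (m$eig$U * rep(gvals, each = nrow(m$eig$U))) %*% m$eig$W
  P[P < 0] <- 0
  dimnames(P) <- dimnames(m$Q)
  P
}

#' @export
print.codon_model <- function(x, ...) {
  cat("Reversible codon substitution model (", x$family, "), code: ",
      x$code$name, ", ", x$code$n_sense, " states\n", sep = "")
  cat("mean rate:", format(.mean_rate(x)), " scale_c:",
      format(x$scale_c), "\n")
  invisible(x)
}
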