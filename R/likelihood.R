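# IUPAC nucleotide ambiguity sets (T canonical; U mapped to T; gap-like
# characters match everything and make a codon fully missing)
.IUPAC <- list(A = "A", C = "C", G = "G", T = "T", U = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"), "-" = c("A", "C", "G", "T"),
               "." = c("A", "C", "G", "T"), "?" = c("A", "C", "G", "T"))

#' Codon alignment
#'
#' Builds a validated codon alignment from named nucleotide sequences.
#' Sequence lengths must be equal and divisible by 3.  In-frame stop
#' codons are a hard error.  Fully ambiguous or gap codons become missing
#' states; partially ambiguous codons (IUPAC letters) marginalize over
#' the compatible sense codons.
#'
#' @param seqs named character vector of nucleotide strings (or a named
#'   list of per-codon character vectors).
#' @param code a [genetic_code()] object.
#' @return An object of class `codon_alignment` with integer state matrix
#'   `states` (rows = sequences; positive = sense-codon index, 0 =
#'   missing, negative = index into the ambiguity mask table `amb`),
#'   `n_sites`, and `code`.
#' @export
codon_alignment <- function(seqs, code) {
  stopifnot(inherits(code, "genetic_code"))
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stop("sequences must be named")
  if (anyDuplicated(names(seqs))) stop("duplicate sequence names")
  if (is.list(seqs)) seqs <- vapply(seqs, paste0, "", collapse = "")
  if (length(seqs) == 0) stop("empty alignment")
  seqs <- toupper(seqs)
  len <- unique(nchar(seqs))
  if (length(len) != 1) stop("sequences have unequal lengths")
  if (len == 0) stop("empty sequences")
  if (len %% 3 != 0) stop("sequence length ", len, " is not divisible by 3")
  n_sites <- len %/% 3

  S <- code$n_sense
  amb_registry <- new.env(parent = emptyenv())
  amb_masks <- list()
  states <- matrix(0L, length(seqs), n_sites,
                   dimnames = list(names(seqs), NULL))
  sense_lookup <- match(code$codons, code$sense_codons)  # NA for stops

  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[i], "")[[1]]
    bad <- setdiff(unique(chars), names(.IUPAC))
    if (length(bad) > 0)
      stop("invalid character(s) ", paste(bad, collapse = ""),
           " in sequence '", names(seqs)[i], "'")
    cod <- matrix(chars, nrow = 3)
    for (s in seq_len(n_sites)) {
      tri <- cod[, s]
      if (all(tri %in% NUCS)) {
        codon <- paste0(tri, collapse = "")
        idx <- sense_lookup[match(codon, code$codons)]
        if (is.na(idx))
          stop("stop codon ", codon, " in sequence '", names(seqs)[i],
               "' at codon site ", s)
        states[i, s] <- idx
      } else {
        sets <- .IUPAC[tri]
        if (all(lengths(sets) == 4)) next  # fully missing, state 0
        compat <- as.vector(outer(outer(sets[[1]], sets[[2]], paste0),
                                  sets[[3]], paste0))
        idx <- sense_lookup[match(compat, code$codons)]
        idx <- sort(idx[!is.na(idx)])
        if (length(idx) == 0)
          stop("codon ", paste0(tri, collapse = ""), " in sequence '",
               names(seqs)[i], "' at codon site ", s,
               " is compatible only with stop codons")
        if (length(idx) == 1) { states[i, s] <- idx; next }
        key <- paste(idx, collapse = ",")
        k <- amb_registry[[key]]
        if (is.null(k)) {
          mask <- logical(S); mask[idx] <- TRUE
          amb_masks[[length(amb_masks) + 1]] <- mask
          k <- length(amb_masks)
          assign(key, k, envir = amb_registry)
        }
        states[i, s] <- -k
      }
    }
  }
  amb <- if (length(amb_masks) > 0)
    do.call(rbind, amb_masks) else matrix(FALSE, 0, S)
  structure(list(states = states, amb = amb, n_sites = n_sites,
                 code = code), class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("Codon alignment: ", nrow(x$states), " sequences, ", x$n_sites,
      " codon sites (", x$code$name, " code)\n", sep = "")
  invisible(x)
}

#' Codon strings of an alignment
#'
#' @param x a `codon_alignment`.
#' @param ... unused.
#' @return Named character vector of nucleotide strings ("NNN" for
#'   missing, IUPAC-ambiguous codons rendered as "NNN" as well).
#' @export
as.character.codon_alignment <- function(x, ...) {
  sc <- x$code$sense_codons
  apply(x$states, 1, function(row) {
    paste0(ifelse(row > 0, sc[pmax(row, 1)], "NNN"), collapse = "")
  })
}

# Collapse alignment columns to unique site patterns.
.compress_patterns <- function(aln) {
  keys <- apply(aln$states, 2, paste, collapse = ",")
  u <- !duplicated(keys)
  index <- match(keys, keys[u])
  list(states = aln$states[, u, drop = FALSE],
       weights = as.vector(table(factor(index, levels = seq_len(sum(u))))),
       index = index, npat = sum(u))
}

# Tip conditional-likelihood matrices (S x npat), one per sequence.
.tip_conditionals <- function(states, amb, S) {
  lapply(seq_len(nrow(states)), function(i) {
    Tm <- matrix(0, S, ncol(states))
    st <- states[i, ]
    full <- which(st > 0)
    Tm[cbind(st[full], full)] <- 1
    Tm[, st == 0] <- 1
    for (j in which(st < 0)) Tm[amb[-st[j], ], j] <- 1
    Tm
  })
}

# Validate tree/alignment pairing and precompute pruning inputs.
.prep_likelihood <- function(tree, aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths (see read_newick for defaults)")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels in tree")
  miss <- setdiff(tree$tip.label, rownames(aln$states))
  if (length(miss) > 0)
    stop("tip(s) absent from alignment: ", paste(miss, collapse = ", "))
  if (aln$n_sites == 0) stop("zero-length alignment")
  tree <- stats::reorder(tree, "postorder")
  ord <- match(tree$tip.label, rownames(aln$states))
  states <- aln$states[ord, , drop = FALSE]
  pat <- .compress_patterns(list(states = states))
  S <- aln$code$n_sense
  list(edge = tree$edge, edge_length = tree$edge.length,
       ntip = length(tree$tip.label), nnode = tree$Nnode,
       tipcond = .tip_conditionals(pat$states, aln$amb, S),
       weights = pat$weights, index = pat$index, npat = pat$npat,
       S = S, tree = tree)
}

# Per-edge transition matrix for one category under optional gamma
# time-variation of the mutation rate.
.edge_P <- function(model, t, theta) {
  if (theta > 0) expected_P_time_variation(model, t, theta)
  else transition_probabilities(model, t)
}

# Post-order partial likelihoods for one category.  Returns lower
# partials L and per-pattern log scalers for every node, plus the raw
# per-edge products Y_e = P_e %*% L_child.
.postorder <- function(prep, model, theta, edge_length) {
  edge <- prep$edge
  nn <- prep$ntip + prep$nnode
  L <- vector("list", nn); logsc <- vector("list", nn)
  Y <- vector("list", nrow(edge))
  Y_logsc <- vector("list", nrow(edge))
  zero <- numeric(prep$npat)
  for (e in seq_len(nrow(edge))) {
    par <- edge[e, 1]; ch <- edge[e, 2]
    P <- .edge_P(model, edge_length[e], theta)
    if (ch <= prep$ntip) {
      Lc <- prep$tipcond[[ch]]; lsc <- zero
    } else {
      # child is complete (postorder); rescale once before use
      cs <- colSums(L[[ch]])
      sc <- ifelse(cs > 0, cs, 1)
      L[[ch]] <- L[[ch]] / rep(sc, each = prep$S)
      logsc[[ch]] <- logsc[[ch]] + log(sc)
      Lc <- L[[ch]]; lsc <- logsc[[ch]]
    }
    Ye <- P %*% Lc
    Y[[e]] <- Ye
    Y_logsc[[e]] <- lsc
    if (is.null(L[[par]])) {
      L[[par]] <- Ye; logsc[[par]] <- lsc
    } else {
      L[[par]] <- L[[par]] * Ye
      logsc[[par]] <- logsc[[par]] + lsc
    }
  }
  list(L = L, logsc = logsc, Y = Y, Y_logsc = Y_logsc)
}

# log with non-positive values mapped to -Inf (no NaN warnings)
.safe_log <- function(v) {
  out <- rep(-Inf, length(v))
  pos <- v > 0
  out[pos] <- log(v[pos])
  out
}

# log per-pattern likelihood of one category from its postorder pass.
.root_site_loglik <- function(prep, model, post) {
  root <- prep$edge[nrow(prep$edge), 1]
  v <- colSums(model$freqs * post$L[[root]])
  .safe_log(v) + post$logsc[[root]]
}

.logsumexp_rows <- function(M) {
  mx <- apply(M, 2, max)
  mx0 <- ifelse(is.finite(mx), mx, 0)
  log(colSums(exp(M - rep(mx0, each = nrow(M))))) + mx0
}

#' Phylogenetic log-likelihood of a codon alignment
#'
#' Felsenstein pruning over a fixed topology under a category mixture of
#' reversible codon models, with optional gamma variation of the mutation
#' rate over time (`theta > 0` replaces `exp(tQ)` by the closed-form
#' expectation `(I - theta*Q)^(-t/theta)` on every branch).  Site
#' patterns are compressed; partial likelihoods are rescaled per node, so
#' large trees do not underflow.
#'
#' @param tree an ape `phylo` tree with branch lengths; tip labels must
#'   name sequences of `aln`.
#' @param aln a [codon_alignment].
#' @param mix a `codon_mixture` (or a single `codon_model`, which is
#'   wrapped via [single_category()]).
#' @param theta nonnegative scale of rate variation over time (0 = none).
#' @return Object of class `codon_loglik`: list with `lnL`, per-site
#'   `site_lnL`, the per-site per-category log-likelihood matrix
#'   `cat_loglik` (categories x sites), and the mixture `priors`.
#' @examples
#' gc <- genetic_code("universal")
#' aln <- codon_alignment(c(a = "AAAACA", b = "AAAACC"), gc)
#' m <- codon_model_mechanistic(mutation_params(sigma = 0.1),
#'                              linear_constraints(equal_constraint()),
#'                              estimate_codon_frequencies(aln), gc)
#' tr <- read_newick(text = "(a:0.1,b:0.1);")
#' tree_loglik(tr, aln, m)$lnL
#' @export
tree_loglik <- function(tree, aln, mix, theta = 0) {
  if (inherits(mix, "codon_model")) mix <- single_category(mix)
  stopifnot(inherits(mix, "codon_mixture"), theta >= 0)
  prep <- .prep_likelihood(tree, aln)
  .loglik_from_prep(prep, mix, theta, prep$edge_length)
}

.loglik_from_prep <- function(prep, mix, theta, edge_length) {
  m <- length(mix$models)
  cat_log <- matrix(NA_real_, m, prep$npat)
  for (k in seq_len(m)) {
    post <- .postorder(prep, mix$models[[k]], theta, edge_length)
    cat_log[k, ] <- .root_site_loglik(prep, mix$models[[k]], post)
  }
  pat_lnL <- .logsumexp_rows(cat_log + log(mix$priors))
  lnL <- sum(prep$weights * pat_lnL)
  structure(list(lnL = lnL,
                 site_lnL = pat_lnL[prep$index],
                 cat_loglik = cat_log[, prep$index, drop = FALSE],
                 priors = mix$priors),
            class = "codon_loglik")
}

#' @export
print.codon_loglik <- function(x, ...) {
  cat("log-likelihood:", format(x$lnL), "over",
      ncol(x$cat_loglik), "codon sites,", nrow(x$cat_loglik),
      "categories\n")
  invisible(x)
}
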