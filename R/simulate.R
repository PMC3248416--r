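# Build a codon_alignment directly from a matrix of sense-codon indices.
.alignment_from_states <- function(states, code) {
  structure(list(states = states,
                 amb = matrix(FALSE, 0, code$n_sense),
                 n_sites = ncol(states), code = code),
            class = "codon_alignment")
}

# Sample destination states given parent states and a stochastic matrix,
# grouped by parent state.
.sample_transitions <- function(parent_states, P) {
  out <- integer(length(parent_states))
  for (s in unique(parent_states)) {
    idx <- which(parent_states == s)
    pr <- pmax(P[s, ], 0)
    out[idx] <- sample.int(ncol(P), length(idx), replace = TRUE,
                           prob = pr)
  }
  out
}

# Gillespie simulation of the embedded jump chain for one site along one
# branch; returns final state and appends events to `log_env$events`.
.simulate_jumps <- function(s, Tlen, Q, log_env, site, edge) {
  t <- 0
  repeat {
    rate <- -Q[s, s]
    if (rate <= 0) return(s)
    t <- t + stats::rexp(1, rate)
    if (t >= Tlen) return(s)
    pr <- pmax(Q[s, ], 0)
    s2 <- sample.int(ncol(Q), 1, prob = pr)
    log_env$events[[length(log_env$events) + 1]] <-
      c(site = site, edge = edge, from = s, to = s2)
    s <- s2
  }
}

#' Simulate a codon alignment along a tree
#'
#' Evolves codon sites down a fixed tree under a category mixture of
#' reversible codon models.  Per site, a category is drawn from the
#' mixture priors and the root codon from the equilibrium frequencies;
#' along each branch of length `t` the site transitions with `exp(tQ_k)`,
#' or, when `theta > 0`, with `exp(rQ_k)` where `r` is drawn
#' per site and branch from a gamma law with shape `t/theta` and scale
#' `theta` (independent across sites and branches).  Tip states are drawn
#' from transition-probability rows; an optional event-logging mode
#' simulates the embedded jump chain instead so that individual
#' (possibly multi-nucleotide) substitution events can be inspected.
#'
#' @param tree an ape `phylo` tree with branch lengths.
#' @param mix a `codon_mixture` or single `codon_model`.
#' @param n_sites number of codon sites.
#' @param seed integer seed (mandatory; all randomness flows from it).
#' @param theta nonnegative time-variation scale (0 = constant rate).
#' @param record_events logical; use the (slower) jump-chain simulator
#'   and attach an event log.  Requires `theta = 0`.
#' @return A [codon_alignment] whose rows are the tip sequences, with a
#'   `truth` attribute: list of per-site `categories`, `root_states`,
#'   the mixture `category_values` and `priors`, `theta`, `seed`, and
#'   (if recorded) an `events` data frame with per-event codon indices
#'   and the number of nucleotides changed.
#' @export
simulate_alignment <- function(tree, mix, n_sites, seed, theta = 0,
                               record_events = FALSE) {
  if (inherits(mix, "codon_model")) mix <- single_category(mix)
  stopifnot(inherits(mix, "codon_mixture"), n_sites >= 1,
            is.numeric(seed), theta >= 0)
  if (record_events && theta > 0)
    stop("event logging is only available with theta = 0")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  set.seed(as.integer(seed))
  tree <- stats::reorder(tree, "postorder")
  edge <- tree$edge
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  root <- edge[nrow(edge), 1]
  code <- mix$models[[1]]$code
  S <- code$n_sense
  m <- length(mix$models)
  f <- mix$models[[1]]$freqs

  cat_of_site <- sample.int(m, n_sites, replace = TRUE, prob = mix$priors)
  states <- matrix(NA_integer_, nn, n_sites)
  states[root, ] <- sample.int(S, n_sites, replace = TRUE, prob = f)

  log_env <- new.env(parent = emptyenv())
  log_env$events <- list()

  for (e in rev(seq_len(nrow(edge)))) {
    par <- edge[e, 1]; ch <- edge[e, 2]
    tlen <- tree$edge.length[e]
    for (k in seq_len(m)) {
      sites <- which(cat_of_site == k)
      if (length(sites) == 0) next
      ps <- states[par, sites]
      md <- mix$models[[k]]
      if (record_events) {
        states[ch, sites] <- vapply(seq_along(sites), function(i)
          .simulate_jumps(ps[i], tlen, md$Q, log_env, sites[i], e), 0L)
      } else if (theta == 0) {
        P <- transition_probabilities(md, tlen)
        states[ch, sites] <- .sample_transitions(ps, P)
      } else {
        r <- stats::rgamma(length(sites), shape = tlen / theta,
                           scale = theta)
        E <- exp(outer(r, md$eig$values))
        probs <- (md$eig$U[ps, , drop = FALSE] * E) %*% md$eig$W
        probs[probs < 0] <- 0
        states[ch, sites] <- vapply(seq_along(sites), function(i)
          sample.int(S, 1, prob = probs[i, ]), 0L)
      }
    }
  }

  tipstates <- states[seq_len(ntip), , drop = FALSE]
  rownames(tipstates) <- tree$tip.label
  aln <- .alignment_from_states(tipstates, code)
  truth <- list(categories = cat_of_site,
                root_states = states[root, ],
                category_values = mix$category_values,
                priors = mix$priors, mode = mix$mode,
                theta = theta, seed = as.integer(seed))
  if (record_events) {
    ev <- do.call(rbind, log_env$events)
    ev <- as.data.frame(if (is.null(ev))
      matrix(integer(0), 0, 4, dimnames = list(NULL,
        c("site", "edge", "from", "to"))) else ev)
    ev$ndiff <- if (nrow(ev) > 0)
      code$ndiff[cbind(ev$from, ev$to)] else integer(0)
    truth$events <- ev
  }
  attr(aln, "truth") <- truth
  aln
}

#' Write a deterministic synthetic fixture suite
#'
#' Generates, under a single seed, the input files every other part of
#' the package consumes: a random symmetric nonpositive selective-
#' constraint CSV, a random amino acid exchangeability file in the
#' PAML-style lower-triangle layout, a random sense-codon exchangeability
#' CSV, random trees of 6, 8, and 16 taxa with branch lengths, and a
#' small simulated codon alignment (FASTA) with a JSON truth manifest.
#' All files are synthetic and labelled as such in their names.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed; the same seed reproduces identical files.
#' @param code genetic code name for the codon-level fixtures.
#' @return Invisibly, a named character vector of the written paths.
#' @export
make_fixtures <- function(dir, seed = 1, code = "universal") {
  if (!dir.exists(dir))
    if (!dir.create(dir, recursive = TRUE))
      stop("cannot create fixture directory: ", dir)
  set.seed(as.integer(seed))
  gc <- genetic_code(code)
  fmt <- function(x) formatC(x, digits = 6, format = "f")
  paths <- c()

  # selective-constraint matrix (symmetric, <= 0, zero diagonal)
  w <- matrix(0, 20, 20, dimnames = list(AA_ORDER, AA_ORDER))
  v <- -stats::runif(190, 0.2, 3)
  w[upper.tri(w)] <- v
  w <- w + t(w)
  p <- file.path(dir, "constraint_synthetic.csv")
  utils::write.csv(matrix(fmt(w), 20, 20,
                          dimnames = dimnames(w)), p, quote = FALSE)
  paths["constraint"] <- p

  # amino acid exchangeabilities, PAML-style lower triangle
  e <- stats::rgamma(190, shape = 0.8, rate = 1)
  p <- file.path(dir, "aa_exch_synthetic.dat")
  lines <- character(19)
  idx <- 1
  for (i in 2:20) {
    lines[i - 1] <- paste(fmt(e[idx:(idx + i - 2)]), collapse = " ")
    idx <- idx + i - 1
  }
  writeLines(lines, p)
  paths["aa_exch"] <- p

  # sense-codon exchangeabilities
  S <- gc$n_sense
  ec <- matrix(0, S, S, dimnames = list(gc$sense_codons, gc$sense_codons))
  ec[upper.tri(ec)] <- stats::rgamma(S * (S - 1) / 2, shape = 0.6, rate = 1)
  ec <- ec + t(ec)
  p <- file.path(dir, "codon_exch_synthetic.csv")
  utils::write.csv(matrix(fmt(ec), S, S, dimnames = dimnames(ec)),
                   p, quote = FALSE)
  paths["codon_exch"] <- p

  # random trees
  for (nt in c(6, 8, 16)) {
    tr <- ape::rtree(nt, br = NULL)
    tr$edge.length <- round(stats::runif(nrow(tr$edge), 0.05, 0.5), 4)
    p <- file.path(dir, paste0("tree_", nt, "taxa_synthetic.nwk"))
    ape::write.tree(tr, p)
    paths[paste0("tree", nt)] <- p
  }

  # small simulated alignment + truth manifest
  tr <- ape::read.tree(paths["tree8"])
  f <- rep(1 / S, S)
  mp <- mutation_params(c(1, 4, 1, 1, 4, 1), sigma = 0.1)
  mix <- constraint_categories(mp, equal_constraint(), 1, -1, f, gc,
                               alpha = 0.5, m = 4)
  aln <- simulate_alignment(tr, mix, n_sites = 200,
                            seed = as.integer(seed) + 1000)
  p <- file.path(dir, "alignment_synthetic.fasta")
  write_codon_fasta(aln, p)
  paths["alignment"] <- p
  truth <- attr(aln, "truth")
  p <- file.path(dir, "alignment_synthetic_truth.json")
  jsonlite::write_json(
    list(seed = truth$seed, theta = truth$theta, mode = truth$mode,
         priors = truth$priors, category_values = truth$category_values,
         categories = truth$categories,
         params = list(exch = mp$exch, sigma = mp$sigma,
                       beta = 1, w0 = -1, alpha = 0.5)),
    p, digits = 10, auto_unbox = TRUE)
  paths["manifest"] <- p
  invisible(paths)
}
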