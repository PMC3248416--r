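# ---- named parameter bookkeeping -------------------------------------

.EXCH_NAMES <- paste0("e_", c("AC", "AG", "AT", "CG", "CT", "GT"))

#' Named model parameters of a codon model family
#'
#' The adjustable parameters of the substitution rate matrix, excluding
#' equilibrium codon frequencies and branch lengths.  For the mechanistic
#' family these are the six nucleotide exchangeabilities, `sigma`,
#' `beta`, `w0`, `theta`, and `alpha` (11 in total).
#'
#' @param family `"mechanistic"`, `"aa"`, or `"empirical"`.
#' @return Character vector of parameter names.
#' @export
named_parameters <- function(family = c("mechanistic", "aa", "empirical")) {
  family <- match.arg(family)
  if (family == "mechanistic")
    c(.EXCH_NAMES, "sigma", "beta", "w0", "theta", "alpha")
  else c("rho", "theta", "alpha")
}

# parameter-block sizes used for K accounting ("exch" = 6 named values)
.block_size <- c(exch = 6, sigma = 1, beta = 1, w0 = 1, alpha = 1,
                 theta = 1, rho = 1)

#' Count adjustable parameters for AIC/BIC
#'
#' Counts the free named model parameters (the `exch` block counts as its
#' six exchangeabilities) plus, when equilibrium codon frequencies are
#' estimated from the data, their `n_sense - 1` degrees of freedom.
#' Branch lengths are excluded, matching the usual presentation of K for
#' substitution-model comparison on a fixed topology.
#'
#' @param family model family.
#' @param free character vector of free parameter blocks, a subset of
#'   `c("exch", "sigma", "beta", "w0", "alpha", "theta", "rho")`.
#' @param code a [genetic_code()] (needed for the frequency dof).
#' @param frequencies_estimated logical; add `n_sense - 1` when TRUE.
#' @return Integer K.
#' @examples
#' gc <- genetic_code("universal")
#' count_parameters("mechanistic",
#'                  c("exch", "sigma", "beta", "w0", "theta", "alpha"),
#'                  gc, frequencies_estimated = FALSE)  # 11
#' @export
count_parameters <- function(family, free, code,
                             frequencies_estimated = TRUE) {
  bad <- setdiff(free, names(.block_size))
  if (length(bad) > 0) stop("unknown parameter block(s): ",
                            paste(bad, collapse = ", "))
  k <- sum(.block_size[free])
  if (frequencies_estimated) {
    stopifnot(inherits(code, "genetic_code"))
    k <- k + code$n_sense - 1
  }
  as.integer(k)
}

#' Akaike and Bayesian information criteria
#'
#' `aic = -2 lnL + 2K`; `bic = -2 lnL + K ln(n)` with `n` the number of
#' codon sites.  The model with the minimum AIC or BIC is preferred.
#'
#' @param lnL maximum log-likelihood.
#' @param K number of adjustable parameters.
#' @param n number of codon sites.
#' @export
aic <- function(lnL, K) -2 * lnL + 2 * K

#' @rdname aic
#' @export
bic <- function(lnL, K, n) {
  stopifnot(n >= 1)
  -2 * lnL + K * log(n)
}

#' Likelihood ratio test between nested model fits
#'
#' @param nested,nesting `codon_fit` objects (or lists with `lnL` and
#'   `K`); the nested model must be a constrained case of the nesting
#'   model, which is the caller's responsibility to ensure.
#' @return List with the test `statistic` (`2 * delta lnL`, clipped at 0),
#'   degrees of freedom `df`, and the chi-square upper-tail `p` value.
#' @export
lrt <- function(nested, nesting) {
  df <- nesting$K - nested$K
  if (df <= 0) stop("nesting model must have more parameters (K difference ",
                    df, ")")
  stat <- max(0, 2 * (nesting$lnL - nested$lnL))
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

# ---- parameter transforms --------------------------------------------

.default_start <- function() {
  list(exch = stats::setNames(rep(1, 6), .EXCH_NAMES),
       sigma = 0.05, beta = 1, w0 = -1, alpha = 0.5, theta = 0, rho = 1)
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# pack free parameters onto unconstrained scales
.pack <- function(pars, free) {
  out <- numeric(0)
  for (nm in free) {
    out <- c(out, switch(nm,
      exch = log(pars$exch[2:6] / pars$exch[1]),
      sigma = log(max(pars$sigma, 1e-6)),
      beta = log(max(pars$beta, 1e-6)),
      w0 = log(max(-pars$w0, 1e-6)),
      alpha = log(pars$alpha),
      theta = log(max(pars$theta, 1e-3)),
      rho = log(pars$rho)))
  }
  out
}

.unpack <- function(x, pars, free) {
  i <- 0
  take <- function(n) { v <- x[(i + 1):(i + n)]; i <<- i + n; v }
  for (nm in free) {
    if (nm == "exch") {
      raw <- c(1, exp(.clamp(take(5), -12, 12)))
      pars$exch <- stats::setNames(raw / mean(raw[c(1, 3, 4, 6)]),
                                   .EXCH_NAMES)
    } else if (nm == "sigma") pars$sigma <- exp(.clamp(take(1), -20, 5))
    else if (nm == "beta") pars$beta <- exp(.clamp(take(1), -12, 5))
    else if (nm == "w0") pars$w0 <- -exp(.clamp(take(1), -12, log(30)))
    else if (nm == "alpha") pars$alpha <- exp(.clamp(take(1), -6, 6))
    else if (nm == "theta") pars$theta <- exp(.clamp(take(1), -12, 3))
    else if (nm == "rho") pars$rho <- exp(.clamp(take(1), -12, 12))
  }
  pars
}

# ---- mixture construction from a parameter list ----------------------

.make_mixture <- function(family, pars, spec) {
  sv <- spec$site_variation
  m <- spec$categories; priors <- spec$priors
  if (family == "mechanistic") {
    p <- mutation_params(pars$exch, pars$sigma)
    if (sv == "constraint")
      return(constraint_categories(p, spec$constraints, pars$beta, pars$w0,
                                   spec$f, spec$code, pars$alpha, m, priors))
    base <- codon_model_mechanistic(
      p, linear_constraints(spec$constraints, pars$beta, pars$w0),
      spec$f, spec$code)
  } else {
    exch <- if (family == "aa") spec$aa_exch else spec$codon_exch
    if (sv == "constraint")
      return(constraint_categories_nonmech(exch, pars$rho, spec$f, spec$code,
                                           pars$alpha, m, priors, family))
    base <- if (family == "aa")
      codon_model_aa(exch, pars$rho, spec$f, spec$code)
    else codon_model_empirical(exch, pars$rho, spec$f, spec$code)
  }
  if (sv == "rate") rate_categories(base, pars$alpha, m, priors)
  else single_category(base)
}

# ---- branch-length pass ----------------------------------------------

# One pass of per-edge Brent optimization against upper/lower partials.
# Partials are refreshed once per pass; within the pass each edge is
# optimized against the pass snapshot (a parallel coordinate update whose
# acceptance is decided at the cycle level on the exact likelihood).
.branch_pass <- function(prep, mix, theta, edge_length,
                         lower = 1e-8, upper = 50, tol = 2e-3) {
  m <- length(mix$models)
  S <- prep$S; npat <- prep$npat
  posts <- lapply(mix$models, function(md)
    .postorder(prep, md, theta, edge_length))
  edge <- prep$edge
  nE <- nrow(edge)
  root <- edge[nE, 1]
  nn <- prep$ntip + prep$nnode
  Upper <- lapply(seq_len(m), function(k) {
    u <- vector("list", nn)
    u[[root]] <- matrix(mix$models[[k]]$freqs, S, npat)
    u
  })
  Ulog <- lapply(seq_len(m), function(k) {
    u <- vector("list", nn); u[[root]] <- numeric(npat); u
  })
  kids <- split(seq_len(nE), edge[, 1])
  lp <- log(mix$priors)
  lam <- lapply(mix$models, function(md) md$eig$values)
  new_el <- edge_length

  for (e in rev(seq_len(nE))) {
    par <- edge[e, 1]; ch <- edge[e, 2]
    G <- vector("list", m)       # eigen-projected rest x lower products
    logoff <- vector("list", m)
    rest_k <- vector("list", m); rlog_k <- vector("list", m)
    for (k in seq_len(m)) {
      R <- Upper[[k]][[par]]; Rl <- Ulog[[k]][[par]]
      for (e2 in kids[[as.character(par)]]) if (e2 != e) {
        R <- R * posts[[k]]$Y[[e2]]
        Rl <- Rl + posts[[k]]$Y_logsc[[e2]]
      }
      cs <- colSums(R); sc <- ifelse(cs > 0, cs, 1)
      R <- R / rep(sc, each = S); Rl <- Rl + log(sc)
      rest_k[[k]] <- R; rlog_k[[k]] <- Rl
      if (ch <= prep$ntip) {
        Lc <- prep$tipcond[[ch]]; lsc <- numeric(npat)
      } else {
        Lc <- posts[[k]]$L[[ch]]; lsc <- posts[[k]]$logsc[[ch]]
      }
      eg <- mix$models[[k]]$eig
      G[[k]] <- (t(eg$U) %*% R) * (eg$W %*% Lc)
      logoff[[k]] <- Rl + lsc
    }
    obj <- function(u) {
      t <- exp(u)
      M <- matrix(NA_real_, m, npat)
      for (k in seq_len(m)) {
        E <- if (theta > 0) (1 - theta * lam[[k]])^(-t / theta)
             else exp(t * lam[[k]])
        v <- as.vector(crossprod(G[[k]], E))
        M[k, ] <- .safe_log(v) + logoff[[k]]
      }
      sum(prep$weights * .logsumexp_rows(M + lp))
    }
    opt <- stats::optimize(obj, c(log(lower), log(upper)),
                           maximum = TRUE, tol = tol)
    if (opt$objective >= obj(log(new_el[e]))) new_el[e] <- exp(opt$maximum)
    if (ch > prep$ntip) {
      for (k in seq_len(m)) {
        P <- .edge_P(mix$models[[k]], new_el[e], theta)
        U <- crossprod(P, rest_k[[k]])
        cs <- colSums(U); sc <- ifelse(cs > 0, cs, 1)
        Upper[[k]][[ch]] <- U / rep(sc, each = S)
        Ulog[[k]][[ch]] <- rlog_k[[k]] + log(sc)
      }
    }
  }
  new_el
}

# ---- the fitting function --------------------------------------------

#' Fit a codon substitution model by maximum likelihood
#'
#' Optimizes branch lengths and the free model parameters of a codon
#' substitution model on a fixed tree topology by coordinate cycles of
#' (i) per-branch Brent maximization and (ii) bounded derivative-free
#' maximization of the model parameters on transformed scales, stopping
#' when a full cycle improves the log-likelihood by less than
#' `control$tol` (default 1e-6) or after `control$max_cycles` cycles.
#' Optimization is deterministic given the starting point.
#'
#' Default starting values: branch lengths from the input tree (0.1 where
#' absent), all nucleotide exchangeabilities 1, `sigma = 0.05`,
#' `beta = 1`, `w0 = -1`, `alpha = 0.5`, `theta = 0`, `rho = 1`.
#'
#' @param aln a [codon_alignment].
#' @param tree an ape `phylo` tree; tip labels must name sequences.
#' @param family `"mechanistic"` (GTR mutation x selective constraints),
#'   `"aa"` (converted empirical amino acid model), or `"empirical"`
#'   (extended empirical codon model).
#' @param constraints a `constraint_matrix` estimate (mechanistic family).
#' @param aa_exch 20x20 amino acid exchangeabilities (`family = "aa"`).
#' @param codon_exch sense x sense codon exchangeabilities
#'   (`family = "empirical"`).
#' @param site_variation `"none"`, `"rate"` (dGmr), or `"constraint"`
#'   (dGms).
#' @param categories number of discrete-gamma categories (default 4).
#' @param priors category prior probabilities (default equal).
#' @param frequencies equilibrium codon frequencies; default estimated
#'   from the alignment with `pseudocount`.
#' @param pseudocount pseudocount per sense codon for frequency
#'   estimation (default 0.5).
#' @param free character vector of free parameter blocks among
#'   `"exch", "sigma", "beta", "w0", "alpha", "theta", "rho"`; defaults
#'   depend on the family (mechanistic: exch, sigma, beta, w0, plus
#'   alpha under site variation; aa: none; empirical: rho).  Everything
#'   not free is fixed at its `start` (or default) value.
#' @param start named list overriding starting/fixed parameter values.
#' @param optimize_branches logical; optimize branch lengths (default
#'   TRUE).
#' @param control list: `max_cycles` (200), `tol` (1e-6), `optim_maxit`
#'   (NM iterations per cycle, 150), `branch_tol` (2e-3 on log branch
#'   length), `trace` (0).
#' @return An object of class `codon_fit` with components `lnL`, `K`,
#'   `aic`, `bic`, `params`, `free`, `tree` (optimized branch lengths),
#'   `mixture`, `site_lnL`, `cat_loglik`, `site_posterior` (dGms fits),
#'   `n_sites`, `converged`, `cycles`.
#' @seealso [tree_loglik()], [lrt()], [posterior_site_constraints()]
#' @export
codon_fit <- function(aln, tree,
                      family = c("mechanistic", "aa", "empirical"),
                      constraints = equal_constraint(),
                      aa_exch = NULL, codon_exch = NULL,
                      site_variation = c("none", "rate", "constraint"),
                      categories = 4L, priors = NULL,
                      frequencies = NULL, pseudocount = 0.5,
                      free = NULL, start = list(),
                      optimize_branches = TRUE,
                      control = list()) {
  family <- match.arg(family)
  site_variation <- match.arg(site_variation)
  ctl <- utils::modifyList(list(max_cycles = 200, tol = 1e-6,
                                optim_maxit = 150, branch_tol = 2e-3,
                                trace = 0), control)
  categories <- if (site_variation == "none") 1L else as.integer(categories)
  if (is.null(priors)) priors <- rep(1 / categories, categories)
  if (family == "aa" && is.null(aa_exch)) stop("family 'aa' needs aa_exch")
  if (family == "empirical" && is.null(codon_exch))
    stop("family 'empirical' needs codon_exch")

  if (is.null(free)) {
    free <- switch(family,
      mechanistic = c("exch", "sigma", "beta", "w0"),
      aa = character(0),
      empirical = "rho")
    if (site_variation != "none") free <- c(free, "alpha")
  }
  if ("branches" %in% free) {
    optimize_branches <- TRUE
    free <- setdiff(free, "branches")
  }
  bad <- setdiff(free, names(.block_size))
  if (length(bad) > 0) stop("unknown free parameter(s): ",
                            paste(bad, collapse = ", "))
  if (family != "mechanistic")
    free <- setdiff(free, c("exch", "sigma", "beta", "w0"))

  pars <- utils::modifyList(.default_start(), start)
  if (!is.null(start$exch)) pars$exch <- stats::setNames(
    as.numeric(start$exch), .EXCH_NAMES)
  # free positive parameters sitting at 0 cannot start on the log scale
  if ("sigma" %in% free && pars$sigma <= 0) pars$sigma <- 0.05
  if ("theta" %in% free && pars$theta <= 0) pars$theta <- 0.05
  if ("beta" %in% free && pars$beta <= 0) pars$beta <- 0.5

  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; starting all at 0.1")
    tree$edge.length <- rep(0.1, nrow(tree$edge))
  }
  prep <- .prep_likelihood(tree, aln)
  tree <- prep$tree
  el <- pmin(pmax(prep$edge_length, 1e-8), 50)

  f <- if (is.null(frequencies))
    estimate_codon_frequencies(aln, pseudocount) else frequencies
  spec <- list(constraints = constraints, aa_exch = aa_exch,
               codon_exch = codon_exch, f = f, code = aln$code,
               site_variation = site_variation, categories = categories,
               priors = priors)

  mix <- .make_mixture(family, pars, spec)
  cur <- .loglik_from_prep(prep, mix, pars$theta, el)
  if (!is.finite(cur$lnL))
    stop("non-finite log-likelihood at starting parameters (",
         paste(names(pars), vapply(pars, function(p)
           paste(signif(unlist(p), 3), collapse = "/"), ""),
           sep = "=", collapse = ", "), ")")

  converged <- FALSE; cycle <- 0
  while (cycle < ctl$max_cycles &&
         (optimize_branches || length(free) > 0)) {
    cycle <- cycle + 1
    lnL_before <- cur$lnL

    if (optimize_branches) {
      el_new <- .branch_pass(prep, mix, pars$theta, el,
                             tol = ctl$branch_tol)
      val <- .loglik_from_prep(prep, mix, pars$theta, el_new)
      if (val$lnL >= cur$lnL) {
        el <- el_new; cur <- val
      } else {
        el_half <- (el + el_new) / 2
        val <- .loglik_from_prep(prep, mix, pars$theta, el_half)
        if (val$lnL >= cur$lnL) { el <- el_half; cur <- val }
      }
    }

    if (length(free) > 0) {
      x0 <- .pack(pars, free)
      negll <- function(x) {
        p2 <- .unpack(x, pars, free)
        v <- tryCatch(
          .loglik_from_prep(prep, .make_mixture(family, p2, spec),
                            p2$theta, el)$lnL,
          error = function(e) -Inf)
        if (!is.finite(v)) 1e10 else -v
      }
      if (length(x0) == 1) {
        opt <- stats::optimize(function(x) negll(x),
                               c(x0 - 8, x0 + 8), tol = 1e-5)
        best_x <- opt$minimum; best_v <- -opt$objective
      } else {
        opt <- stats::optim(x0, negll, method = "Nelder-Mead",
                            control = list(maxit = ctl$optim_maxit))
        best_x <- opt$par; best_v <- -opt$value
      }
      if (best_v > cur$lnL) {
        pars <- .unpack(best_x, pars, free)
        mix <- .make_mixture(family, pars, spec)
        cur <- .loglik_from_prep(prep, mix, pars$theta, el)
      }
    }

    if (ctl$trace > 0)
      message("cycle ", cycle, ": lnL = ", format(cur$lnL, digits = 12))
    if (cur$lnL - lnL_before < ctl$tol) { converged <- TRUE; break }
  }
  if (!optimize_branches && length(free) == 0) converged <- TRUE

  tree$edge.length <- el
  K <- count_parameters(family, free, aln$code,
                        frequencies_estimated = is.null(frequencies))
  fit <- structure(list(
    call = match.call(),
    family = family, site_variation = site_variation,
    categories = categories, priors = priors,
    lnL = cur$lnL, K = K, n_sites = aln$n_sites,
    aic = aic(cur$lnL, K), bic = bic(cur$lnL, K, aln$n_sites),
    params = pars, free = free,
    frequencies = f, constraints = constraints,
    tree = tree, mixture = mix,
    site_lnL = cur$site_lnL, cat_loglik = cur$cat_loglik,
    converged = converged, cycles = cycle,
    code = aln$code), class = "codon_fit")
  if (site_variation == "constraint")
    fit$site_posterior <- posterior_site_constraints(fit)
  fit
}

# ---- posterior site constraints --------------------------------------

#' Posterior mean selective constraint per site
#'
#' For a fit with discrete-gamma variation of selective constraint
#' (dGms), returns for every codon site the posterior mean of the
#' per-category mean acceptance rate,
#' `sum_k P(k | site) * abar_k` with `P(k | site)` proportional to
#' `prior_k * L(site | k)`.  Low values flag conserved sites.
#'
#' @param fit a `codon_fit` from a `site_variation = "constraint"` model
#'   (or any object with `cat_loglik`, `priors` and a constraint-mode
#'   `mixture`).
#' @return Numeric vector, one posterior mean acceptance per site.
#' @export
posterior_site_constraints <- function(fit) {
  mix <- fit$mixture
  if (!inherits(mix, "codon_mixture") || mix$mode != "constraint")
    stop("fit does not carry a constraint-mode (dGms) mixture")
  lw <- fit$cat_loglik + log(fit$priors)
  tot <- .logsumexp_rows(lw)
  post <- exp(lw - rep(tot, each = nrow(lw)))
  as.vector(crossprod(post, mix$category_values))
}

# ---- methods ----------------------------------------------------------

#' Model name following the field's naming convention
#'
#' Builds names like `Equal-Constraint-9-F-dG4s`: constraint source,
#' number of free named rate-matrix parameters, `F` for observed-
#' frequency equilibria, and the site-variation suffix `dG<m>r` / `dG<m>s`.
#'
#' @param fit a `codon_fit`.
#' @export
model_name <- function(fit) {
  stopifnot(inherits(fit, "codon_fit"))
  src <- switch(fit$family,
    mechanistic = {
      s <- attr(fit$constraints, "source")
      if (identical(s, "equal")) {
        w_used <- linear_constraints(fit$constraints,
                                     fit$params$beta, fit$params$w0)
        if (fit$params$beta == 0 && fit$params$w0 == 0 &&
            all(w_used == 0)) "No-Constraint" else "Equal-Constraint"
      } else if (is.null(s)) "Constraint" else
        tools::file_path_sans_ext(basename(s))
    },
    aa = "AA", empirical = "ECM")
  n <- sum(.block_size[fit$free])
  sv <- switch(fit$site_variation, none = "",
               rate = paste0("-dG", fit$categories, "r"),
               constraint = paste0("-dG", fit$categories, "s"))
  paste0(src, "-", n, "-F", sv)
}

#' @export
print.codon_fit <- function(x, ...) {
  cat("Codon substitution model fit: ", model_name(x), "\n", sep = "")
  cat("  lnL = ", format(x$lnL, digits = 10), ",  K = ", x$K,
      ",  n = ", x$n_sites, " codon sites\n", sep = "")
  cat("  AIC = ", format(x$aic, digits = 10), ",  BIC = ",
      format(x$bic, digits = 10), "\n", sep = "")
  cat("  converged: ", x$converged, " (", x$cycles, " cycles)\n", sep = "")
  invisible(x)
}

#' @export
summary.codon_fit <- function(object, ...) {
  x <- object
  print(x)
  cat("\nFree parameters:", if (length(x$free)) paste(x$free, collapse = ", ")
      else "(none)", "\n")
  cf <- coef(x)
  print(round(cf, 4))
  if (x$family == "mechanistic") {
    p <- mutation_params(x$params$exch, x$params$sigma)
    w <- linear_constraints(x$constraints, x$params$beta, x$params$w0)
    cat("kappa =", round(kappa_of(p), 4),
        " mean acceptance =", round(mean_acceptance(w), 4), "\n")
  }
  cat("tree length =", round(sum(x$tree$edge.length), 4), "\n")
  invisible(x)
}

#' @export
coef.codon_fit <- function(object, ...) {
  p <- object$params
  out <- c(p$exch, sigma = p$sigma, beta = p$beta, w0 = p$w0,
           alpha = p$alpha, theta = p$theta, rho = p$rho)
  if (object$family != "mechanistic")
    out <- out[c("rho", "theta", "alpha")]
  out
}

#' @export
logLik.codon_fit <- function(object, ...) {
  structure(object$lnL, df = object$K, nobs = object$n_sites,
            class = "logLik")
}

#' @export
plot.codon_fit <- function(x, ...) {
  if (!is.null(x$site_posterior)) {
    graphics::plot(x$site_posterior, type = "h", xlab = "codon site",
                   ylab = "posterior mean acceptance rate",
                   main = model_name(x), ...)
    graphics::abline(h = sum(x$priors * x$mixture$category_values),
                     lty = 2)
  } else {
    graphics::plot(x$site_lnL, type = "h", xlab = "codon site",
                   ylab = "site log-likelihood", main = model_name(x), ...)
  }
  invisible(x)
}

#' Simulate codon alignments from a fitted model
#'
#' @param object a `codon_fit`.
#' @param nsim number of alignments.
#' @param seed integer seed (required for reproducibility).
#' @param ... unused.
#' @return A list of [codon_alignment] objects (length `nsim`), each with
#'   a `truth` attribute; a single alignment if `nsim = 1`.
#' @export
simulate.codon_fit <- function(object, nsim = 1, seed = 1, ...) {
  sims <- lapply(seq_len(nsim), function(i)
    simulate_alignment(object$tree, object$mixture, object$n_sites,
                       seed = seed + i - 1, theta = object$params$theta))
  if (nsim == 1) sims[[1]] else sims
}
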