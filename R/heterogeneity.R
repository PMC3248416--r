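#' Discrete-gamma category values
#'
#' Discretizes a gamma distribution with shape `alpha` and mean 1 into `m`
#' categories with the given prior probabilities, each category
#' represented by the conditional mean of the gamma variate within its
#' probability segment (the standard discrete-gamma construction,
#' generalized to unequal priors via cumulative breakpoints).  The
#' prior-weighted mean of the returned values is 1.
#'
#' @param alpha positive shape parameter.
#' @param m number of categories.
#' @param priors prior probabilities (default equal), summing to 1.
#' @return Numeric vector of `m` nonnegative category values.
#' @examples
#' discrete_gamma_points(1, 2)  # ~ 0.3069, 1.6931
#' @export
discrete_gamma_points <- function(alpha, m, priors = rep(1 / m, m)) {
  stopifnot(is.numeric(alpha), length(alpha) == 1)
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be > 0")
  m <- as.integer(m)
  stopifnot(m >= 1, length(priors) == m, all(priors > 0))
  if (abs(sum(priors) - 1) > 1e-8) stop("priors must sum to 1")
  priors <- priors / sum(priors)
  if (m == 1) return(1)
  breaks <- c(0, stats::qgamma(cumsum(priors[-m]), shape = alpha,
                               rate = alpha), Inf)
  # E[X; a < X < b] for gamma(alpha, alpha) via the shape+1 identity
  upper <- stats::pgamma(breaks, shape = alpha + 1, rate = alpha)
  vals <- diff(upper) / priors
  vals / sum(priors * vals)  # pin the weighted mean at exactly 1
}

.new_mixture <- function(models, priors, values, mode) {
  structure(list(models = models, priors = priors,
                 category_values = values, mode = mode),
            class = "codon_mixture")
}

#' Single-category mixture wrapper
#'
#' Wraps one `codon_model` as a degenerate mixture so that the likelihood
#' machinery has a uniform interface.
#' @param model a `codon_model`.
#' @export
single_category <- function(model) {
  stopifnot(inherits(model, "codon_model"))
  .new_mixture(list(model), 1, 1, "none")
}

#' Discrete-gamma variation of mutation rate across sites (dGmr)
#'
#' Each category's generator is the base generator scaled by a
#' discrete-gamma point; the prior-weighted mean rate stays 1.
#'
#' @param base a normalized `codon_model`.
#' @param alpha positive shape parameter.
#' @param m number of categories.
#' @param priors prior probabilities (default equal).
#' @return A `codon_mixture` with mode `"rate"`.
#' @export
rate_categories <- function(base, alpha, m = 4, priors = rep(1 / m, m)) {
  stopifnot(inherits(base, "codon_model"))
  r <- discrete_gamma_points(alpha, m, priors)
  models <- lapply(r, function(rk) .rescale_model(base, rk))
  .new_mixture(models, priors, r, "rate")
}

#' Discrete-gamma variation of selective constraint across sites (dGms)
#'
#' The mean acceptance rate `abar` of the tailored constraints
#' `w = beta * what + w0` is assumed to vary across sites following a
#' discrete gamma distribution: category k has mean acceptance
#' `abar_k = abar * g_k` with `g_k` from [discrete_gamma_points()],
#' realized by the additive shift `w_k = w + ln(g_k)` on the off-diagonal
#' (so the equal-constraint case reduces exactly to acceptance rates at
#' the discrete-gamma points).  Category generators are built
#' mechanistically and rescaled by one common constant so the mixture
#' mean rate is 1.
#'
#' @param p a [mutation_params()] object.
#' @param what a `constraint_matrix` estimate.
#' @param beta,w0 selection parameters as in [linear_constraints()].
#' @param f equilibrium frequencies over sense codons.
#' @param code a [genetic_code()] object.
#' @param alpha positive shape parameter.
#' @param m number of categories.
#' @param priors prior probabilities (default equal).
#' @return A `codon_mixture` with mode `"constraint"`; `category_values`
#'   holds the per-category mean acceptance rates `abar_k`.
#' @export
constraint_categories <- function(p, what, beta, w0, f, code,
                                  alpha, m = 4, priors = rep(1 / m, m)) {
  w <- linear_constraints(what, beta, w0)
  abar <- mean_acceptance(w)
  g <- discrete_gamma_points(alpha, m, priors)
  models <- vector("list", m)
  rates <- numeric(m)
  for (k in seq_len(m)) {
    wk <- w + log(g[k])
    diag(wk) <- 0
    if (any(!is.finite(exp(wk))))
      stop("acceptance rates overflow in category ", k,
           "; reduce beta or the range of the constraint estimate")
    mk <- codon_model_mechanistic(p, wk, f, code)
    # undo the per-category normalization: keep the raw relative scale
    mk <- .rescale_model(mk, 1 / mk$scale_c)
    models[[k]] <- mk
    rates[k] <- .mean_rate(mk)
  }
  s <- 1 / sum(priors * rates)
  models <- lapply(models, .rescale_model, s = s)
  .new_mixture(models, priors, abar * g, "constraint")
}

#' Constraint variation across sites for converted/empirical models
#'
#' For codon models built from an empirical amino acid or codon
#' exchangeability matrix, the per-category constraint is realized by
#' multiplying the nonsynonymous exchangeability block of category k by
#' the discrete-gamma point `g_k`, leaving the synonymous block
#' unchanged; a common rescaling enforces mixture mean rate 1.
#'
#' @param exch 20x20 amino acid exchangeabilities (`family = "aa"`) or
#'   sense x sense codon exchangeabilities (`family = "empirical"`).
#' @param rho synonymous/nonsynonymous adjuster.
#' @param f equilibrium frequencies over sense codons.
#' @param code a [genetic_code()] object.
#' @param alpha positive shape parameter.
#' @param m number of categories.
#' @param priors prior probabilities (default equal).
#' @param family `"aa"` or `"empirical"`.
#' @return A `codon_mixture` with mode `"constraint"`.
#' @export
constraint_categories_nonmech <- function(exch, rho, f, code, alpha, m = 4,
                                          priors = rep(1 / m, m),
                                          family = c("aa", "empirical")) {
  family <- match.arg(family)
  g <- discrete_gamma_points(alpha, m, priors)
  build <- if (family == "aa") codon_model_aa else codon_model_empirical
  syn <- .syn_mask(code)
  models <- vector("list", m)
  rates <- numeric(m)
  for (k in seq_len(m)) {
    mk <- build(exch, rho, f, code)
    mk <- .rescale_model(mk, 1 / mk$scale_c)   # raw exchangeability scale
    C <- mk$exchangeability
    scale_ns <- matrix(g[k], nrow(C), ncol(C))
    scale_ns[syn] <- 1
    diag(scale_ns) <- 1
    C2 <- C * scale_ns
    mk2 <- .finish_model(C2, f, code, family, mk$params)
    mk2 <- .rescale_model(mk2, 1 / mk2$scale_c)
    models[[k]] <- mk2
    rates[k] <- .mean_rate(mk2)
  }
  s <- 1 / sum(priors * rates)
  models <- lapply(models, .rescale_model, s = s)
  .new_mixture(models, priors, g, "constraint")
}

#' Expected transition matrix under gamma rate variation over time
#'
#' If the total substitution rate accumulated along a branch of length `t`
#' is gamma distributed with shape `t/theta` and scale `theta` (mean `t`,
#' variance `theta * t`), the expectation of `exp(rQ)` has the closed
#' form `(I - theta * Q)^(-t/theta)`, evaluated here through the
#' eigendecomposition of `Q`.  `theta = 0` recovers a constant rate,
#' i.e. `exp(tQ)`.
#'
#' @param m a `codon_model`.
#' @param t nonnegative branch length.
#' @param theta nonnegative scale of the rate-variation gamma law.
#' @return Stochastic sense x sense matrix.
#' @export
expected_P_time_variation <- function(m, t, theta = 0) {
  stopifnot(inherits(m, "codon_model"), is.finite(t), t >= 0, theta >= 0)
  if (theta == 0) return(transition_probabilities(m, t))
  g <- (1 - theta * m$eig$values)^(-t / theta)
  .assemble_P(m, g)
}

#' @export
print.codon_mixture <- function(x, ...) {
  cat("Codon model mixture (", x$mode, "), ", length(x$models),
      " categories\n", sep = "")
  df <- data.frame(prior = x$priors, value = x$category_values,
                   mean_rate = vapply(x$models, .mean_rate, 0))
  print(df, digits = 4)
  invisible(x)
}
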