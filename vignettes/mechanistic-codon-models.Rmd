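---
title: "Mechanistic codon substitution models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanistic codon substitution models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mechcodon)
```

## The substitution model

mechcodon models the evolution of protein-coding sequences as a
time-reversible Markov process on the sense codons of a genetic code
(61 states for the universal code, 60 for the vertebrate-mitochondrial
code; stop codons carry zero equilibrium frequency and are excluded from
the state space).  Every rate matrix in the package is assembled from a
symmetric *exchangeability* matrix $C$ and equilibrium frequencies $f$:

$$R_{\mu\nu} = C_{\mu\nu}\, f_\nu, \qquad \mu \ne \nu,$$

which guarantees detailed balance $f_\mu R_{\mu\nu} = f_\nu R_{\nu\mu}$.
The time unit is fixed by the normalization
$-\sum_\mu f_\mu R_{\mu\mu} = 1$: branch lengths are expected
substitutions per codon site.  Only relative exchangeabilities are
meaningful; the scale constant enforcing the normalization is stored
with each model.  Equilibrium frequencies are taken equal to observed
codon frequencies in the alignment (the "F" convention), optionally
regularized by a pseudocount (default 0.5 per sense codon) so that all
frequencies are strictly positive.

### The mechanistic family

The core model factorizes each codon exchangeability into a *mutation*
term and a *selection* (average fixation) term:

$$C_{\mu\nu} \propto C^{\mathrm{mut}}_{\mu\nu}\,
  e^{w_{a_\mu a_\nu}},$$

where $a_\mu$ is the amino acid encoded by codon $\mu$.

**Mutation.**  Nucleotide mutations follow a single GTR exchangeability
set $e_{xy}$ shared by the three codon positions, and act independently
at each position.  For codons differing at the position set $D$ with
$d = |D| \ge 1$,

$$C^{\mathrm{mut}}_{\mu\nu} = \sigma^{\,d-1}
  \prod_{i \in D} e_{\mu_i \nu_i}.$$

$\sigma \ge 0$ is the ratio of double-to-single (and triple-to-double)
nucleotide-change exchangeability; $\sigma = 0$ forbids multi-nucleotide
codon changes in infinitesimal time, and position independence means a
double change at positions 1 and 3 is as frequent as one at adjacent
positions.  The product $\sigma^{d-1} \prod e$ leaves a one-dimensional
redundancy between the overall scale of $e$ and $\sigma$
($e \to \lambda e$, $\sigma \to \sigma/\lambda$ changes nothing after
normalization); `mutation_params()` removes it by rescaling so the mean
of the four transversion exchangeabilities is 1, under which
$\kappa = \bar e_{\mathrm{ts}} / \bar e_{\mathrm{tv}}$ reads directly as
the transition/transversion ratio.

**Selection.**  $w_{ab} \le 0$ is the log-scale acceptance penalty for
replacing amino acid $a$ by $b$; $w_{aa} = 0$ because synonymous
replacements are under no amino-acid-level selection.  Constraints are
tailored to a gene as a linear function of a given symmetric estimate
$\hat w$:

$$w_{ab} = \beta\,\hat w_{ab} + w_0, \qquad \beta \ge 0,\; w_0 \le 0.$$

$\beta$ scales the strength of the constraint *pattern*; $w_0$ shifts
all constraints and so directly controls the nonsynonymous/synonymous
exchangeability ratio.  The built-in `equal_constraint()` uses
$\hat w_{ab} = -1$ for all heterotypic pairs (so $\beta$ keeps its
"strength" meaning); with that estimate $\beta$ and $w_0$ are redundant
(only $-\beta + w_0$ matters) and the fitter should fix one of them.
$\beta = w_0 = 0$ gives the neutral No-Constraint model, which is
blind to amino acid identity and acts as a nucleotide-level model on
codons.  External estimates (e.g. ML estimates from empirical
substitution frequency matrices, or physico-chemical ones) are read
from CSV by `read_constraint_matrix()`; estimating $\hat w$ itself is
out of scope here — such matrices are inputs.

The summary statistic
$\bar a = \tfrac{1}{190}\sum_{a<b} e^{w_{ab}}$ (the *mean acceptance
rate*) averages over the 190 unordered heterotypic pairs, unweighted.
Whether that average should be ordered or frequency-weighted is not
decidable from the sources this design follows; the unweighted unordered
convention is applied everywhere, and at $\beta = 0$ it gives the exact
identity $\bar a = e^{w_0}$, which the tests assert.

### Converted amino acid and empirical codon families

Two comparison families reuse the same machinery.
`codon_model_aa()` converts an empirical amino acid exchangeability
matrix $\tilde e$ (PAML-style `.dat` input): nonsynonymous codon pairs —
including those needing several nucleotide changes — get
$C_{\mu\nu} \propto \tilde e_{a_\mu a_\nu}$, and all synonymous pairs
share $\rho \cdot \max_{a \ne b} \tilde e_{ab}$, so that at $\rho = 1$
the synonymous exchangeability equals the largest nonsynonymous one.
`codon_model_empirical()` extends an empirical sense-codon
exchangeability matrix with the same $\rho$ dial: the synonymous block
is multiplied by $\rho$ and the nonsynonymous block rescaled so their
maxima agree at $\rho = 1$.

As $\rho \to \infty$ the converted model becomes the amino acid model.
Because all synonymous exchangeabilities are equal and nonsynonymous
rates depend on codons only through their amino acids, the codon chain
is exactly *lumpable* to the 20-state amino acid chain; the equivalence
is exact at any $\rho$ once branch lengths are expressed in expected
amino-acid substitutions rather than codon substitutions (the unit-time
normalization otherwise absorbs the growing synonymous churn into the
time scale).  The test suite exploits this: codon-level likelihoods at
$\rho = 10^3$ and $10^4$ are compared on the amino-acid time scale
against an independent 20-state pruning oracle.

## Site heterogeneity

Either the mutation rate (suffix `dGmr`) or the selective constraint
(suffix `dGms`) may vary across sites — not both at once, a deliberate
restriction mirroring the cost of the joint mixture.  Both use the
standard discrete-gamma construction: a gamma law with shape $\alpha$
and mean 1 is cut at cumulative-probability breakpoints into $m$
segments (default $m = 4$, equal priors), each represented by its
conditional mean.  `discrete_gamma_points()` generalizes this to
arbitrary category priors via the cumulative breakpoints; unequal
priors are useful for constraint variation when $\bar a$ is small and
low categories would otherwise be numerically indistinguishable.  The
prior-weighted mean of the category values is exactly 1.

* **Rate variation** scales each category's generator:
  $R^{(k)} = r_k R$.
* **Constraint variation** makes the mean acceptance rate
  $\bar a_k = \bar a \, g_k$ follow the discrete gamma.  In the
  mechanistic family this is realized by the additive shift
  $w^{(k)}_{ab} = \beta \hat w_{ab} + w_0 + \ln g_k$, which satisfies
  the per-category mean-acceptance condition *exactly*, holds $\beta$
  fixed, and reduces, under the equal-constraint estimate, to
  per-category acceptance rates equal to the discrete-gamma points.
  (Rescaling $\beta$ per category instead would also match the
  category means; the additive shift was chosen because it preserves
  the constraint pattern and admits the closed-form identity.)
  In the converted/empirical families the nonsynonymous exchangeability
  block of category $k$ is multiplied by $g_k$, the synonymous block
  untouched.

Category generators are *not* normalized individually; a single common
constant rescales all of them so the mixture mean rate is 1, keeping
branch lengths interpretable as expected substitutions per site under
the mixture.

## Rate variation over time

The total substitution rate accumulated along a branch of length $t$ is
allowed to fluctuate: it is modeled as gamma distributed with shape
$t/\theta$ and scale $\theta$ (mean $t$, variance $\theta t$),
independent across sites and branches.  The expected transition matrix
then has the closed form

$$\tilde P(t) = \left(I - \theta Q\right)^{-t/\theta},$$

evaluated spectrally (the eigenvalue map
$\lambda \mapsto (1-\theta\lambda)^{-t/\theta}$), which costs nothing
beyond the eigendecomposition already needed for $e^{tQ}$.
$\theta = 0$ recovers the constant-rate matrix exponential, and the
implementation switches to it explicitly.  When site categories are
active, the map is applied to each category's generator.  A single
global $\theta$ applies to all branches.

## Likelihood, optimization, and model choice

`tree_loglik()` runs Felsenstein pruning over the fixed topology with
site-pattern compression and per-node rescaling of partial likelihoods
(so deep trees do not underflow).  Transition matrices come from one
symmetric eigendecomposition per model — reversibility guarantees a real
spectrum, and one decomposition serves every branch length; series-based
matrix exponentials are never used.  Tiny negative entries from
roundoff (bounded by about $10^{-12}$) are clipped to zero.  Gap or
fully ambiguous codons are missing states (partial likelihood 1 over
all sense codons); partially ambiguous IUPAC codons marginalize over
their compatible sense codons; in-frame stops are a hard error.

`codon_fit()` maximizes the likelihood by deterministic coordinate
cycles: each branch length is optimized by Brent's method on the log
scale within $[10^{-8}, 50]$ against upper/lower partial caches, then
the free model parameters are optimized together by Nelder–Mead on
transformed scales (logs for positive parameters;
$w_0 = -e^{x}$ keeps it nonpositive).  A cycle's branch proposals are
accepted only if the exact likelihood improves.  Iteration stops when a
full cycle gains less than `control$tol` (default $10^{-6}$) or after
`control$max_cycles` (default 200) cycles.  Default starting values:
branch lengths from the input tree (0.1 where absent), all
exchangeabilities 1, $\sigma = 0.05$, $\beta = 1$, $w_0 = -1$,
$\alpha = 0.5$, $\theta = 0$, $\rho = 1$.

Parameter counting for AIC/BIC (`count_parameters()`): the free named
rate-matrix parameters — for the full mechanistic model the vector
$(e_{AC}, e_{AG}, e_{AT}, e_{CG}, e_{CT}, e_{GT}, \sigma, \beta, w_0,
\theta, \alpha)$ of length 11 — plus the $n_{\mathrm{sense}} - 1$
degrees of freedom of equilibrium frequencies when they are estimated
from data.  Branch lengths are excluded, the usual presentation when
ranking substitution models on one fixed topology; since every compared
model shares the same branch-length dimension, rankings are unaffected.
`lrt()` uses the plain $\chi^2$ upper tail; for boundary hypotheses
($\sigma = 0$, $\theta = 0$) this is conservative, which the
documentation flags rather than applying a mixture correction.

For `dGms` fits, `posterior_site_constraints()` reports per site the
posterior mean of the category acceptance rates,
$\sum_k P(k \mid \text{site})\, \bar a_k$ — low values flag conserved
sites.

## The simulator and what passing tests show

`simulate_alignment()` draws, per site, a category from the mixture
priors and a root codon from $f$, then samples transitions down each
branch from the exact transition-probability rows ($e^{tQ_k}$, or
$e^{rQ_k}$ with per-site-and-branch gamma draws when $\theta > 0$).  An
optional event-logging mode simulates the embedded jump chain instead,
so individual substitution events — including multi-nucleotide ones —
can be inspected; it exists for validation (e.g. that $\sigma = 0$
produces no multi-nucleotide events), not for speed.
`make_fixtures()` writes a deterministic synthetic input suite
(constraint CSV, amino acid `.dat`, codon-exchangeability CSV, trees,
a small alignment with truth manifest) so everything is testable
without downloads; all randomness flows from one seed.

The simulator emulates exactly the model class it validates:
independent sites, a homogeneous process along the tree, no indels,
no recombination, no compensatory mechanisms beyond what an effective
$\sigma > 0$ captures.  Parameter-recovery results therefore
demonstrate the correctness and identifiability of the implementation
under its own assumptions — not robustness of the model on real
sequence data, where alignment error and among-site dependence exist.

Validation designs were chosen once at what a single-gene analysis
plausibly looks like: generator invariants over randomized
configurations of all three families; pruning against exhaustive
state-enumeration oracles on trees of up to 4 tips; recovery of
$(\kappa = 4, \sigma = 0.1, \beta = 1, w_0 = -1, \alpha = 0.5)$ from
3000 codon sites on an 8-taxon tree (branch lengths 0.05–0.5) under the
mechanistic dG4s model; and the $\sigma$ likelihood-ratio test's
rejection behavior on 300-site, 6-taxon simulations (10 seeds each with
and without multi-nucleotide changes).  The recovery refit uses a
convergence tolerance of $10^{-3}$ log-units — far finer than the
20–50 % recovery bands being asserted.

## Numerical choices and limitations

* Stop codons are excluded from the state space rather than carried
  with zero frequency: zero-frequency states would make the generator
  reducible and the symmetrized eigenproblem ill-conditioned, while the
  probability flow through stops is identically zero either way.
* Strictly positive frequencies are required (pseudocount default 0.5);
  a zero frequency breaks the detailed-balance factorization, and
  requesting `pseudocount = 0` with unobserved codons is an explicit
  error rather than a silent repair.
* `constraint_categories()` refuses parameter regions where
  per-category acceptance rates overflow `exp()`, suggesting a smaller
  $\beta\hat w$ range.
* Branch lengths are bounded in $[10^{-8}, 50]$ during optimization.
* Only one of site-rate / site-constraint variation can be active; the
  $\theta$ device is the only time-variation mechanism; topology search,
  positive-selection site tests beyond the posterior $\bar a$ report,
  and estimation of $\hat w$ from substitution frequency matrices are
  out of scope.
* The optimizer is single-start and deterministic; likelihood surfaces
  with strong $\beta$/$w_0$ trade-offs (notably under the
  equal-constraint estimate, where the pair is exactly redundant) should
  be fitted with one of the two fixed.

## A worked example

```{r example, eval = FALSE}
gc <- genetic_code("universal")
dir <- tempfile(); paths <- make_fixtures(dir, seed = 1)
aln <- read_codon_fasta(paths[["alignment"]], gc)
tree <- read_newick(paths[["tree8"]])
what <- read_constraint_matrix(paths[["constraint"]])

fit <- codon_fit(aln, tree, constraints = what,
                 site_variation = "constraint", categories = 4,
                 free = c("exch", "sigma", "beta", "w0", "alpha"))
summary(fit)
plot(fit)           # per-site posterior mean acceptance

fit0 <- codon_fit(aln, tree, constraints = what,
                  site_variation = "constraint", categories = 4,
                  free = c("exch", "beta", "w0", "alpha"),
                  start = list(sigma = 0))
lrt(fit0, fit)      # do multi-nucleotide changes matter here?
compare_fits(list(fit0, fit))
```
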