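#' Equal selective constraint on all amino acid replacements
#'
#' The simplest constraint estimate: every heterotypic amino acid pair gets
#' the same constraint, here fixed at -1 so that the strength multiplier
#' `beta` in [linear_constraints()] keeps its meaning; the diagonal is 0
#' because synonymous replacements are under no amino-acid-level selection.
#'
#' @return A `constraint_matrix`: symmetric 20x20 matrix with zero diagonal
#'   and -1 off-diagonal, rows/columns in [AA_ORDER].
#' @export
equal_constraint <- function() {
  m <- matrix(-1, 20, 20, dimnames = list(AA_ORDER, AA_ORDER))
  diag(m) <- 0
  structure(m, source = "equal", class = c("constraint_matrix", "matrix"))
}

.validate_constraint <- function(m, source, tol = 1e-8) {
  if (!is.numeric(m) || !identical(dim(m), c(20L, 20L)))
    stop("constraint matrix must be numeric 20x20")
  if (is.null(dimnames(m)) || !identical(rownames(m), AA_ORDER) ||
      !identical(colnames(m), AA_ORDER))
    stop("constraint matrix labels must be the 20 amino acids in ",
         paste(AA_ORDER, collapse = ""), " order")
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("non-finite constraint at (", rownames(m)[bad[1, 1]], ",",
         colnames(m)[bad[1, 2]], ")")
  asym <- abs(m - t(m))
  if (max(asym) > tol) {
    ij <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    stop("constraint matrix asymmetric beyond tolerance at (",
         AA_ORDER[ij[1]], ",", AA_ORDER[ij[2]], "): |diff| = ", max(asym))
  }
  m <- (m + t(m)) / 2
  if (any(diag(m) != 0)) {
    warning("nonzero diagonal in constraint matrix reset to 0 ",
            "(no constraint on synonymous replacements)")
    diag(m) <- 0
  }
  structure(m, source = source, class = c("constraint_matrix", "matrix"))
}

#' Read a 20x20 selective-constraint matrix from CSV
#'
#' Expects a header row and first column holding the one-letter amino acid
#' codes in ARNDCQEGHILKMFPSTWYV order and a numeric body; `#` lines are
#' comments.  The matrix is checked for symmetry (tolerance 1e-8), then
#' symmetrized as (M + t(M))/2; a nonzero diagonal is reset to 0 with a
#' warning.
#'
#' @param path CSV file.
#' @return A `constraint_matrix`.
#' @export
read_constraint_matrix <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                        row.names = 1)
  if (nrow(df) != 20 || ncol(df) != 20)
    stop("constraint CSV must be 20x20 with labels; got ",
         nrow(df), "x", ncol(df))
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(df, 2, as.numeric))),
                 arr.ind = TRUE)
    stop("non-numeric cell in constraint CSV at row ", bad[1, 1],
         ", column ", colnames(df)[bad[1, 2]])
  }
  if (!setequal(rownames(m), AA_ORDER) || !setequal(colnames(m), AA_ORDER))
    stop("constraint CSV labels must be the 20 one-letter amino acid codes")
  m <- m[AA_ORDER, AA_ORDER]
  .validate_constraint(m, source = path)
}

#' Tailor selective constraints linearly to a gene
#'
#' Given a constraint estimate `what` (a [equal_constraint()]-style matrix)
#' the gene-specific constraints are `w_ab = beta * what_ab + w0` for
#' `a != b`, with `w_aa = 0`.  `beta >= 0` scales the strength of the
#' constraint pattern; `w0 <= 0` shifts all constraints and thereby
#' directly controls the nonsynonymous/synonymous exchangeability ratio.
#' `beta = 0, w0 = 0` gives the neutral (No-Constraint) model.
#'
#' @param what a `constraint_matrix`.
#' @param beta nonnegative strength multiplier.
#' @param w0 nonpositive offset.
#' @return 20x20 matrix `w` with zero diagonal.
#' @export
linear_constraints <- function(what, beta = 1, w0 = -1) {
  stopifnot(is.numeric(beta), length(beta) == 1, beta >= 0,
            is.numeric(w0), length(w0) == 1, w0 <= 0)
  if (!inherits(what, "constraint_matrix"))
    what <- .validate_constraint(unclass(what), source = "ad hoc")
  w <- beta * unclass(what) + w0
  diag(w) <- 0
  w
}

#' Mean acceptance rate of a constraint matrix
#'
#' The average of `exp(w_ab)` over the 190 unordered heterotypic amino
#' acid pairs; 1 for neutral evolution, smaller under purifying selection.
#'
#' @param w 20x20 constraint matrix with zero diagonal.
#' @return The mean acceptance rate, a positive scalar.
#' @export
mean_acceptance <- function(w) {
  stopifnot(identical(dim(w), c(20L, 20L)))
  if (any(diag(w) != 0)) stop("w must have zero diagonal")
  mean(exp(w[upper.tri(w)]))
}
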