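#' @keywords internal
"_PACKAGE"

NUCS <- c("A", "C", "G", "T")

#' One-letter amino acid codes in the conventional ARND... order
#'
#' Order used for all 20x20 constraint and exchangeability matrices.
#' @export
AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# unordered nucleotide pair ids, matching the exchangeability vector
# c(e_AC, e_AG, e_AT, e_CG, e_CT, e_GT)
NUC_PAIRS <- c("AC", "AG", "AT", "CG", "CT", "GT")

# amino acids of the 64 codons in TCAG order (first base slowest), the
# layout in which the standard code is conventionally tabulated
.CODE_TCAG <- "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"

.code_registry <- local({
  tcag <- c("T", "C", "A", "G")
  # enumerate first base slowest, third fastest
  codons_tcag <- character(64)
  k <- 0
  for (a in tcag) for (b in tcag) for (d in tcag) {
    k <- k + 1
    codons_tcag[k] <- paste0(a, b, d)
  }
  universal <- strsplit(.CODE_TCAG, "")[[1]]
  names(universal) <- codons_tcag
  mito <- universal
  mito[c("AGA", "AGG")] <- "*"
  mito["ATA"] <- "M"
  mito["TGA"] <- "W"
  list("universal" = universal, "vertebrate-mito" = mito)
})

#' Genetic code tables
#'
#' Build the codon table for a named genetic code.  Codons are indexed in
#' fixed lexicographic order (AAA, AAC, ..., TTT) over the DNA alphabet;
#' all rate/exchangeability matrices in the package use the sense-codon
#' restriction of this order.
#'
#' @param name `"universal"` (61 sense codons; stops TAA, TAG, TGA) or
#'   `"vertebrate-mito"` (60 sense codons; stops TAA, TAG, AGA, AGG).
#' @return An object of class `genetic_code`: a list with the 64 `codons`,
#'   their amino acids `aa` (`"*"` for stops), the `sense_codons`, the
#'   encoded amino acids `sense_aa`, integer indices `aa_index` into
#'   [AA_ORDER], and precomputed codon-pair difference tables used by the
#'   rate-matrix builders.
#' @examples
#' gc <- genetic_code("universal")
#' length(gc$sense_codons)  # 61
#' @export
genetic_code <- function(name = c("universal", "vertebrate-mito")) {
  if (length(name) == 1 && !name %in% names(.code_registry))
    stop("unknown genetic code: '", name, "' (supported: ",
         paste(names(.code_registry), collapse = ", "), ")")
  name <- match.arg(name)
  tab <- .code_registry[[name]]

  codons <- character(64)
  k <- 0
  for (a in NUCS) for (b in NUCS) for (d in NUCS) {
    k <- k + 1
    codons[k] <- paste0(a, b, d)
  }
  aa <- unname(tab[codons])
  sense <- which(aa != "*")
  sense_codons <- codons[sense]
  sense_aa <- aa[sense]
  aa_index <- match(sense_aa, AA_ORDER)
  S <- length(sense)

  # per-position nucleotide of each sense codon
  pos_nuc <- sapply(1:3, function(p) substr(sense_codons, p, p))
  # pair id per position: 0 if equal, else 1..6 into NUC_PAIRS
  pair_id <- array(0L, dim = c(S, S, 3))
  for (p in 1:3) {
    xi <- match(pos_nuc[, p], NUCS)
    same <- outer(xi, xi, "==")
    lo <- outer(xi, xi, pmin)
    hi <- outer(xi, xi, pmax)
    id <- match(paste0(NUCS[lo], NUCS[hi]), NUC_PAIRS)
    id[same] <- 0L
    pair_id[, , p] <- id
  }
  ndiff <- (pair_id[, , 1] > 0) + (pair_id[, , 2] > 0) + (pair_id[, , 3] > 0)

  structure(list(
    name = name,
    codons = codons,
    aa = aa,
    sense = sense,
    sense_codons = sense_codons,
    sense_aa = sense_aa,
    aa_index = aa_index,
    stop_codons = codons[aa == "*"],
    n_sense = S,
    pair_id = pair_id,
    ndiff = ndiff
  ), class = "genetic_code")
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("Genetic code:", x$name, "-", x$n_sense, "sense codons, stops:",
      paste(x$stop_codons, collapse = " "), "\n")
  invisible(x)
}

.check_codon <- function(x) {
  if (!is.character(x) || length(x) != 1 || nchar(x) != 3 ||
      !all(strsplit(x, "")[[1]] %in% NUCS))
    stop("invalid codon: '", x, "' (expected a trinucleotide over A,C,G,T)")
  invisible(x)
}

#' Positions at which two codons differ
#'
#' @param c1,c2 trinucleotides over A,C,G,T.
#' @return Integer vector of differing positions, a subset of 1:3.
#' @examples
#' diff_positions("AAA", "AAG")  # 3
#' @export
diff_positions <- function(c1, c2) {
  .check_codon(c1); .check_codon(c2)
  which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
}

#' Classify a nucleotide change as transition or transversion
#'
#' A<->G and C<->T are transitions; the four other unordered pairs are
#' transversions.
#'
#' @param x,y distinct nucleotides.
#' @return `"transition"` or `"transversion"`.
#' @export
classify_change <- function(x, y) {
  if (!x %in% NUCS || !y %in% NUCS)
    stop("invalid nucleotide: ", x, ", ", y)
  if (x == y) stop("x and y must differ")
  pair <- paste0(min(x, y), max(x, y))
  if (pair %in% c("AG", "CT")) "transition" else "transversion"
}
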