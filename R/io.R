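#' Read a codon alignment from FASTA
#'
#' Sequences must have equal lengths divisible by 3.  Lowercase and `U`
#' are accepted; gap (`-`) and fully ambiguous triplets become missing
#' states; partially ambiguous IUPAC codons marginalize over compatible
#' sense codons; an in-frame stop codon is a hard error naming the
#' sequence and site.
#'
#' @param path FASTA file.
#' @param code a [genetic_code()] object or code name.
#' @return A [codon_alignment].
#' @export
read_codon_fasta <- function(path, code = genetic_code("universal")) {
  if (is.character(code)) code <- genetic_code(code)
  if (!file.exists(path)) stop("file not found: ", path)
  seqs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                             seqtype = "DNA")
  if (length(seqs) == 0) stop("empty FASTA file: ", path)
  v <- vapply(seqs, function(s) as.character(s)[1], "")
  names(v) <- names(seqs)
  codon_alignment(v, code)
}

#' Write a codon alignment (or named sequences) to FASTA
#'
#' @param x a [codon_alignment] or named character vector of sequences.
#' @param path output file.
#' @param width line width (default 60).
#' @export
write_codon_fasta <- function(x, path, width = 60) {
  seqs <- if (inherits(x, "codon_alignment")) as.character(x) else x
  if (is.null(names(seqs))) stop("sequences must be named")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[i]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))),
               con)
  }
  invisible(path)
}

#' Read a Newick tree
#'
#' A permissive single-tree Newick reader; branch lengths are optional
#' and default to 0.1 with a warning when absent.
#'
#' @param path file containing one Newick tree.
#' @param text alternatively, the Newick string itself.
#' @return An ape `phylo` object.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  tr <- if (is.null(text)) {
    if (!file.exists(path)) stop("file not found: ", path)
    tryCatch(ape::read.tree(path),
             error = function(e) stop("Newick parse error in ", path, ": ",
                                      conditionMessage(e)))
  } else ape::read.tree(text = text)
  if (is.null(tr)) stop("could not parse a tree")
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1) stop("expected a single tree, found ", length(tr))
    tr <- tr[[1]]
  }
  if (is.null(tr$edge.length)) {
    warning("tree has no branch lengths; defaulting all to 0.1")
    tr$edge.length <- rep(0.1, nrow(tr$edge))
  }
  if (anyNA(tr$edge.length)) {
    warning("missing branch lengths defaulted to 0.1")
    tr$edge.length[is.na(tr$edge.length)] <- 0.1
  }
  tr
}

#' Read amino acid exchangeabilities in PAML-style .dat layout
#'
#' Lower triangle of a 20x20 matrix in ARNDCQEGHILKMFPSTWYV order (190
#' values, whitespace separated across lines).  A trailing equilibrium-
#' frequency line (20 further values), if present, is ignored with a
#' message.
#'
#' @param path .dat file.
#' @return Symmetric nonnegative 20x20 matrix with zero diagonal.
#' @export
read_paml_dat <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  vals <- scan(path, what = numeric(), comment.char = "#", quiet = TRUE)
  if (length(vals) < 190)
    stop("expected at least 190 lower-triangle values, found ",
         length(vals))
  if (length(vals) > 190) {
    if (length(vals) >= 210)
      message("ignoring trailing frequency line (and ", length(vals) - 210,
              " further values) in ", path)
    else
      message("ignoring ", length(vals) - 190, " trailing values in ", path)
  }
  m <- matrix(0, 20, 20, dimnames = list(AA_ORDER, AA_ORDER))
  idx <- 1
  for (i in 2:20) {
    m[i, 1:(i - 1)] <- vals[idx:(idx + i - 2)]
    idx <- idx + i - 1
  }
  m <- m + t(m)
  if (any(m < 0)) stop("negative exchangeability in ", path)
  m
}

#' Read a sense-codon exchangeability matrix from CSV
#'
#' @param path CSV with sense-codon labels matching the genetic code.
#' @param code a [genetic_code()] object or code name.
#' @return Symmetric sense x sense matrix with zero diagonal.
#' @export
read_codon_exch_csv <- function(path, code = genetic_code("universal")) {
  if (is.character(code)) code <- genetic_code(code)
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                        row.names = 1)
  S <- code$n_sense
  if (nrow(df) != S || ncol(df) != S)
    stop("codon exchangeability CSV must be ", S, "x", S, " for the ",
         code$name, " code; got ", nrow(df), "x", ncol(df))
  m <- as.matrix(df)
  if (!setequal(rownames(m), code$sense_codons))
    stop("codon labels do not match the sense codons of '", code$name, "'")
  m <- m[code$sense_codons, code$sense_codons]
  if (max(abs(m - t(m))) > 1e-8) stop("codon exchangeability not symmetric")
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

# branch labels keyed by child node: tip label or node<i>
.branch_labels <- function(tree) {
  ntip <- length(tree$tip.label)
  ch <- tree$edge[, 2]
  ifelse(ch <= ntip, tree$tip.label[ch], paste0("node", ch))
}

#' Serialize a model fit to JSON
#'
#' @param fit a `codon_fit`.
#' @param path output file.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "codon_fit"))
  bl <- as.list(stats::setNames(fit$tree$edge.length,
                                .branch_labels(fit$tree)))
  out <- list(model = model_name(fit), family = fit$family,
              site_variation = fit$site_variation,
              categories = fit$categories, priors = fit$priors,
              params = fit$params[c("exch", "sigma", "beta", "w0",
                                    "alpha", "theta", "rho")],
              free = fit$free, lnL = fit$lnL, K = fit$K,
              n_sites = fit$n_sites, aic = fit$aic, bic = fit$bic,
              converged = fit$converged,
              newick = ape::write.tree(fit$tree),
              branch_lengths = bl)
  if (!is.null(fit$site_posterior))
    out$site_posteriors <- fit$site_posterior
  jsonlite::write_json(out, path, digits = 12, auto_unbox = TRUE)
  invisible(path)
}

#' Read a serialized model fit
#'
#' @param path JSON written by [write_fit_json()].
#' @return A list with the stored fields (not a refittable object).
#' @export
read_fit_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Compare model fits by AIC/BIC (and LRT where nested)
#'
#' Builds a comparison table over fits of the same alignment, sorted by
#' BIC.  Fits with differing numbers of codon sites are refused, since
#' their BICs are not comparable.  When a fit's free-parameter set is a
#' strict subset of the BIC-best model's (same family), the likelihood
#' ratio test of that nested pair is reported on its row.
#'
#' @param fits list of `codon_fit` objects or lists from
#'   [read_fit_json()].
#' @return A `data.frame` with columns model, K, lnL, dAIC, dBIC, AIC,
#'   BIC, and LRT columns versus the BIC-best model.
#' @export
compare_fits <- function(fits) {
  stopifnot(length(fits) >= 2)
  get <- function(f, k) if (inherits(f, "codon_fit")) f[[k]] else f[[k]]
  n <- vapply(fits, get, 0, k = "n_sites")
  if (length(unique(n)) != 1)
    stop("fits cover different numbers of codon sites (",
         paste(unique(n), collapse = ", "), "); BICs are not comparable")
  model <- vapply(fits, function(f)
    if (inherits(f, "codon_fit")) model_name(f) else f$model, "")
  lnL <- vapply(fits, get, 0, k = "lnL")
  K <- vapply(fits, get, 0, k = "K")
  AIC <- aic(lnL, K)
  BIC <- bic(lnL, K, n[1])
  tab <- data.frame(model = model, K = K, lnL = lnL,
                    dAIC = AIC - min(AIC), dBIC = BIC - min(BIC),
                    AIC = AIC, BIC = BIC)
  best <- which.min(BIC)
  freesets <- lapply(fits, function(f)
    unlist(if (inherits(f, "codon_fit")) f$free else f$free))
  fam <- vapply(fits, get, "", k = "family")
  tab$lrt_stat <- tab$lrt_df <- tab$lrt_p <- NA_real_
  for (i in seq_along(fits)) {
    if (i == best) next
    nested_in_best <- fam[i] == fam[best] && K[i] < K[best] &&
      all(freesets[[i]] %in% freesets[[best]])
    best_in_i <- fam[i] == fam[best] && K[best] < K[i] &&
      all(freesets[[best]] %in% freesets[[i]])
    if (nested_in_best) {
      r <- lrt(list(lnL = lnL[i], K = K[i]),
               list(lnL = lnL[best], K = K[best]))
    } else if (best_in_i) {
      r <- lrt(list(lnL = lnL[best], K = K[best]),
               list(lnL = lnL[i], K = K[i]))
    } else next
    tab$lrt_stat[i] <- r$statistic
    tab$lrt_df[i] <- r$df
    tab$lrt_p[i] <- r$p
  }
  tab[order(tab$BIC), ]
}

#' Write a model comparison table as TSV
#'
#' @param tab data frame from [compare_fits()].
#' @param path output file.
#' @export
write_comparison_tsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
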