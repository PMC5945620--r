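# Signature catalog container and exome rescaling.

#' Signature catalog
#'
#' A catalog of K mutational signatures, each a probability distribution
#' over the 96 substitution channels (rows sum to 1).
#'
#' @param probs K x 96 numeric matrix; columns in canonical channel
#'   order (colnames are set to the channel labels).
#' @param names character vector of K signature names.
#' @param aetiology optional character vector of K proposed aetiologies.
#' @param renormalise if TRUE, rows are rescaled to sum exactly to 1
#'   (they must already be within `tol` of 1).
#' @param tol row-sum validation tolerance.
#' @return object of class `sig_catalog`: list with `names`, `probs`,
#'   `aetiology`.
#' @export
sig_catalog <- function(probs, names = rownames(probs),
                        aetiology = NULL, renormalise = TRUE,
                        tol = 1e-6) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 96L) stop("catalog must have 96 channel columns")
  if (is.null(names)) names <- paste0("S", seq_len(nrow(probs)))
  if (length(names) != nrow(probs)) stop("one name per signature required")
  if (any(probs < 0)) stop("channel probabilities must be non-negative")
  rs <- rowSums(probs)
  if (any(abs(rs - 1) > tol)) {
    stop("signature rows must sum to 1 (max deviation ",
         format(max(abs(rs - 1))), ")")
  }
  if (renormalise) probs <- probs / rs
  dimnames(probs) <- list(names, sig_channels()$label)
  structure(list(names = names, probs = probs, aetiology = aetiology),
            class = "sig_catalog")
}

#' @export
print.sig_catalog <- function(x, ...) {
  cat(sprintf("sig_catalog: %d signatures x 96 channels\n",
              length(x$names)))
  cat("  ", paste(utils::head(x$names, 8), collapse = ", "),
      if (length(x$names) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Rescale a genome-derived catalog to exome trinucleotide frequencies
#'
#' Each channel probability is multiplied by the exome/genome frequency
#' ratio of its reference trinucleotide, then each signature is
#' renormalised to sum to 1. Used before fitting whole-exome samples
#' against a whole-genome signature catalog.
#'
#' @param catalog a [sig_catalog()].
#' @param freqs a `trinuc_freqs` object ([read_trinucleotide_freqs()]).
#' @return the rescaled `sig_catalog`.
#' @export
rescale_to_exome <- function(catalog, freqs) {
  stopifnot(inherits(catalog, "sig_catalog"),
            inherits(freqs, "trinuc_freqs"))
  tri <- sig_channels()$trinucleotide
  g <- freqs$genome[tri]
  e <- freqs$exome[tri]
  if (anyNA(g) || any(g <= 0)) {
    stop("genome frequency missing or zero for a needed trinucleotide")
  }
  probs <- sweep(catalog$probs, 2, e / g, `*`)
  probs <- probs / rowSums(probs)
  sig_catalog(probs, names = catalog$names,
              aetiology = catalog$aetiology)
}
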