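# 96-channel trinucleotide classification under the pyrimidine-strand
# convention. Channel ordering follows the canonical COSMIC layout:
# substitution classes C>A, C>G, C>T, T>A, T>C, T>G (major), 5' flank
# A,C,G,T (middle), 3' flank A,C,G,T (minor).

BASES <- c("A", "C", "G", "T")
SUB_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' Complement bases
#'
#' @param x character vector of base strings (any length).
#' @return the complemented string(s); `revcomp()` also reverses.
#' @keywords internal
comp_bases <- function(x) chartr("ACGT", "TGCA", x)

#' @rdname comp_bases
#' @keywords internal
revcomp <- function(x) {
  vapply(strsplit(comp_bases(x), ""), function(s) paste(rev(s), collapse = ""),
         character(1))
}

#' The 96 substitution channels in canonical order
#'
#' @return A data.frame with one row per channel: `index` (1-96), `ref`
#'   (pyrimidine), `alt`, `flank5`, `flank3`, `trinucleotide` (reference
#'   context), and `label` in COSMIC notation, e.g. `"A[C>A]A"`.
#' @examples
#' head(sig_channels())
#' @export
sig_channels <- function() {
  cached <- .channel_cache$tab
  if (!is.null(cached)) return(cached)
  grid <- expand.grid(flank3 = BASES, flank5 = BASES, sub = SUB_CLASSES,
                      stringsAsFactors = FALSE)
  grid <- grid[, c("sub", "flank5", "flank3")]
  ref <- substr(grid$sub, 1, 1)
  alt <- substr(grid$sub, 3, 3)
  tab <- data.frame(
    index = seq_len(96L),
    ref = ref,
    alt = alt,
    flank5 = grid$flank5,
    flank3 = grid$flank3,
    trinucleotide = paste0(grid$flank5, ref, grid$flank3),
    label = paste0(grid$flank5, "[", grid$sub, "]", grid$flank3),
    stringsAsFactors = FALSE
  )
  .channel_cache$tab <- tab
  tab
}

.channel_cache <- new.env(parent = emptyenv())

#' Convert between channel labels and canonical indices
#'
#' @param label character vector of COSMIC-style labels (`"A[C>A]A"`).
#' @param index integer vector in 1..96.
#' @return `channel_index()` returns integer indices; `channel_label()`
#'   returns labels.
#' @export
channel_index <- function(label) {
  idx <- match(label, sig_channels()$label)
  if (anyNA(idx)) {
    stop("unknown channel label(s): ",
         paste(unique(label[is.na(idx)]), collapse = ", "))
  }
  idx
}

#' @rdname channel_index
#' @export
channel_label <- function(index) {
  stopifnot(all(index >= 1L & index <= 96L))
  sig_channels()$label[index]
}

#' Classify substitutions into the 96 trinucleotide channels
#'
#' Purine-reference substitutions are mapped to their reverse-complement
#' representation so that the returned channel always has a pyrimidine
#' (C or T) reference base.
#'
#' @param ref,alt single-base reference and alternate alleles
#'   (vectorised).
#' @param context 3-base reference context, 5' to 3'; its middle base
#'   must equal `ref`.
#' @return Character vector of channel labels in COSMIC notation. Use
#'   [channel_index()] for numeric indices or [channel_fields()] for the
#'   parsed components.
#' @examples
#' classify_channel("C", "A", "ACA")  # "A[C>A]A"
#' classify_channel("A", "G", "TAC")  # "G[T>C]A" (reverse complemented)
#' @export
classify_channel <- function(ref, alt, context) {
  n <- length(ref)
  if (length(alt) != n || length(context) != n) {
    stop("ref, alt and context must have equal length")
  }
  bad_base <- !(ref %in% BASES) | !(alt %in% BASES)
  bad_ctx <- nchar(context) != 3L |
    !grepl("^[ACGT]{3}$", context) |
    substr(context, 2, 2) != ref
  same <- ref == alt
  if (any(bad_base | bad_ctx | same)) {
    i <- which(bad_base | bad_ctx | same)[1]
    stop(sprintf(
      "invalid substitution at record %d: ref=%s alt=%s context=%s",
      i, ref[i], alt[i], context[i]))
  }
  purine <- ref %in% c("A", "G")
  ref[purine] <- comp_bases(ref[purine])
  alt[purine] <- comp_bases(alt[purine])
  context[purine] <- revcomp(context[purine])
  paste0(substr(context, 1, 1), "[", ref, ">", alt, "]",
         substr(context, 3, 3))
}

#' @rdname classify_channel
#' @param label channel label(s) to parse.
#' @export
channel_fields <- function(label) {
  tab <- sig_channels()
  tab[channel_index(label), , drop = FALSE]
}
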