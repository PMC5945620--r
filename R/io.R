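# Readers and writers for mutation tables, signature catalogs, driver
# gene lists, trinucleotide frequencies and active-signature maps.
#
# Coordinates are 1-based inclusive (MAF convention). Chromosome names
# are normalised to the prefix-free form ("chr17" -> "17"); only the
# canonical nuclear chromosomes 1-22, X, Y are retained.

CANONICAL_CHROMS <- c(as.character(1:22), "X", "Y")
EFFECT_LEVELS <- c("nonsynonymous_SNV", "stopgain", "stoploss",
                   "synonymous", "other")

MUTATION_COLUMNS <- c("sample_id", "cancer_type", "chrom", "pos", "ref",
                      "alt", "context", "gene", "effect",
                      "variant_class_label", "protein_change")

# column name maps for the supported dialects; overridable via
# `column_map`. Only the columns the analysis needs are read.
.dialect_map <- function(dialect) {
  switch(dialect,
    generic = c(sample_id = "sample_id", cancer_type = "cancer_type",
                chrom = "chrom", pos = "pos", ref = "ref", alt = "alt",
                context = "context", gene = "gene", effect = "effect",
                variant_class_label = "variant_class_label",
                protein_change = "protein_change"),
    tcga = c(sample_id = "Tumor_Sample_Barcode",
             cancer_type = "cancer_type",
             chrom = "Chromosome", pos = "Start_Position",
             ref = "Reference_Allele", alt = "Tumor_Seq_Allele2",
             context = "context", gene = "Hugo_Symbol",
             effect = "effect", variant_class_label = "Variant_Type",
             protein_change = "HGVSp_Short"),
    icgc = c(sample_id = "icgc_sample_id", cancer_type = "cancer_type",
             chrom = "chromosome", pos = "chromosome_start",
             ref = "reference_genome_allele", alt = "mutated_to_allele",
             context = "context", gene = "gene_affected",
             effect = "effect", variant_class_label = "mutation_type",
             protein_change = "aa_mutation"),
    stop("unknown dialect: ", dialect)
  )
}

.normalise_effect <- function(x) {
  x <- trimws(x)
  canon <- c("nonsynonymous snv" = "nonsynonymous_SNV",
             "nonsynonymous_snv" = "nonsynonymous_SNV",
             "non-synonymous snv" = "nonsynonymous_SNV",
             "missense_mutation" = "nonsynonymous_SNV",
             "stopgain" = "stopgain", "nonsense_mutation" = "stopgain",
             "stoploss" = "stoploss", "nonstop_mutation" = "stoploss",
             "synonymous snv" = "synonymous",
             "synonymous_snv" = "synonymous",
             "silent" = "synonymous", "synonymous" = "synonymous")
  out <- canon[tolower(x)]
  out[is.na(out) | x == ""] <- "other"
  unname(out)
}

#' Read a somatic mutation table
#'
#' Reads a tab-separated mutation table in one of three dialects and
#' returns a validated data.frame of single-base substitutions. Per the
#' source conventions, only rows labelled `"single base substitution"`
#' (icgc) or `"SNP"` (tcga) are kept; the generic dialect keeps any row
#' that passes SNV validation. Rows on non-canonical chromosomes are
#' dropped; rows failing validation (multi-base alleles, ref == alt,
#' context middle base not matching ref) are skipped with a warning
#' giving the count. Duplicate records (same sample/position/alleles)
#' are kept and their count reported via a message.
#'
#' @param path path to a tab-separated file with a header.
#' @param dialect one of `"generic"`, `"tcga"`, `"icgc"`.
#' @param column_map optional named character vector overriding the
#'   dialect's column names (names are canonical fields, values are the
#'   file's column names).
#' @return A data.frame with columns `sample_id, cancer_type, chrom,
#'   pos, ref, alt, context, gene, effect, variant_class_label,
#'   protein_change`. Positions are 1-based inclusive.
#' @export
read_mutations <- function(path, dialect = c("generic", "tcga", "icgc"),
                           column_map = NULL) {
  dialect <- match.arg(dialect)
  map <- .dialect_map(dialect)
  if (!is.null(column_map)) map[names(column_map)] <- column_map
  raw <- data.table::fread(path, sep = "\t", header = TRUE,
                           colClasses = "character", data.table = FALSE)
  required <- map[c("sample_id", "chrom", "pos", "ref", "alt", "context")]
  missing <- setdiff(unname(required), names(raw))
  if (length(missing)) {
    stop("missing required column(s) for dialect '", dialect, "': ",
         paste(missing, collapse = ", "))
  }
  get_col <- function(field) {
    col <- map[[field]]
    if (col %in% names(raw)) raw[[col]] else rep("", nrow(raw))
  }
  rec <- data.frame(
    sample_id = get_col("sample_id"),
    cancer_type = get_col("cancer_type"),
    chrom = sub("^chr", "", get_col("chrom")),
    pos = suppressWarnings(as.integer(get_col("pos"))),
    ref = toupper(get_col("ref")),
    alt = toupper(get_col("alt")),
    context = toupper(get_col("context")),
    gene = get_col("gene"),
    effect = .normalise_effect(get_col("effect")),
    variant_class_label = get_col("variant_class_label"),
    protein_change = get_col("protein_change"),
    stringsAsFactors = FALSE
  )

  # dialect-specific SNV label filter
  keep <- switch(dialect,
    tcga = rec$variant_class_label == "SNP",
    icgc = grepl("single base substitution", rec$variant_class_label,
                 ignore.case = TRUE),
    generic = rep(TRUE, nrow(rec)))
  rec <- rec[keep, , drop = FALSE]

  rec <- rec[rec$chrom %in% CANONICAL_CHROMS, , drop = FALSE]

  valid <- !is.na(rec$pos) & rec$pos >= 1 &
    rec$ref %in% BASES & rec$alt %in% BASES & rec$ref != rec$alt &
    grepl("^[ACGT]{3}$", rec$context) &
    substr(rec$context, 2, 2) == rec$ref
  n_bad <- sum(!valid)
  if (n_bad > 0) {
    warning(sprintf("skipped %d unparseable row(s) in %s", n_bad, path))
  }
  rec <- rec[valid, , drop = FALSE]
  n_dup <- sum(duplicated(rec[, c("sample_id", "chrom", "pos", "ref",
                                  "alt")]))
  if (n_dup > 0) {
    message(sprintf("%d duplicate record(s) kept in %s", n_dup, path))
  }
  rownames(rec) <- NULL
  rec
}

#' Write mutation records in the generic dialect
#'
#' @param records a mutation record data.frame (see [read_mutations()]).
#' @param path output path (tab-separated, header).
#' @export
write_mutations <- function(records, path) {
  stopifnot(all(MUTATION_COLUMNS %in% names(records)))
  data.table::fwrite(records[, MUTATION_COLUMNS], path, sep = "\t")
  invisible(path)
}

#' Filter to non-silent mutations in driver genes
#'
#' Retains records whose gene is in `driver_genes` and whose effect is
#' nonsynonymous_SNV, stopgain or stoploss; input order is preserved.
#'
#' @param records mutation record data.frame.
#' @param driver_genes character vector of driver gene symbols.
#' @return the qualifying subset of `records`.
#' @export
filter_driver_nonsynonymous <- function(records, driver_genes) {
  keep <- records$gene %in% driver_genes &
    records$effect %in% c("nonsynonymous_SNV", "stopgain", "stoploss")
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.exclusion_key <- function(records) {
  paste(records$sample_id, records$chrom, records$pos, records$ref,
        records$alt, sep = "\r")
}

#' Per-sample channel count matrix
#'
#' Classifies every record into its trinucleotide channel and tabulates
#' counts per sample. Records in `exclude` (matched by sample,
#' chromosome, position and alleles; gene/effect ignored) are removed
#' first — used to exclude driver non-synonymous mutations from
#' signature fitting. Samples whose records are all excluded keep an
#' all-zero row.
#'
#' @param records mutation record data.frame.
#' @param exclude optional data.frame of records to remove.
#' @return An object of class `channel_counts`: list with `counts`
#'   (samples x 96 integer matrix, rownames = sample ids, colnames =
#'   channel labels) and `total` (row sums).
#' @export
count_channels <- function(records, exclude = NULL) {
  samples <- unique(records$sample_id)
  if (!is.null(exclude) && nrow(exclude) > 0) {
    drop <- .exclusion_key(records) %in% .exclusion_key(exclude)
    records <- records[!drop, , drop = FALSE]
  }
  counts <- matrix(0L, nrow = length(samples), ncol = 96L,
                   dimnames = list(samples, sig_channels()$label))
  if (nrow(records) > 0) {
    ch <- classify_channel(records$ref, records$alt, records$context)
    tab <- table(factor(records$sample_id, levels = samples),
                 factor(ch, levels = sig_channels()$label))
    counts[] <- as.integer(tab)
  }
  structure(list(counts = counts, total = rowSums(counts)),
            class = "channel_counts")
}

#' @export
print.channel_counts <- function(x, ...) {
  cat(sprintf("channel_counts: %d samples, %d mutations total\n",
              nrow(x$counts), sum(x$counts)))
  invisible(x)
}

#' Read a driver gene list (one symbol per line)
#'
#' @param path plain-text file; blank lines and `#` comments ignored.
#' @return character vector of gene symbols.
#' @export
read_driver_genes <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Read a signature catalog matrix
#'
#' Expects a tab-separated file whose first column holds channel labels
#' in COSMIC notation (`A[C>A]A`) and one column per signature. Rows
#' are reordered to the canonical channel order.
#'
#' @param path path to the TSV.
#' @return a [sig_catalog()] object.
#' @export
read_signature_catalog <- function(path) {
  raw <- data.table::fread(path, sep = "\t", header = TRUE,
                           data.table = FALSE)
  labels <- as.character(raw[[1]])
  idx <- channel_index(labels)
  if (length(unique(idx)) != 96L) {
    stop("signature catalog must cover all 96 channels exactly once")
  }
  probs <- t(as.matrix(raw[order(idx), -1, drop = FALSE]))
  colnames(probs) <- sig_channels()$label
  sig_catalog(probs, names = rownames(probs))
}

#' @rdname read_signature_catalog
#' @param catalog a `sig_catalog`.
#' @export
write_signature_catalog <- function(catalog, path) {
  out <- data.frame(channel = sig_channels()$label,
                    t(catalog$probs), check.names = FALSE)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read genome/exome trinucleotide frequencies
#'
#' @param path TSV with columns `trinucleotide` (32 pyrimidine-centred
#'   3-mers), `genome`, `exome`; each frequency column is renormalised
#'   to sum to 1.
#' @return object of class `trinuc_freqs`: list of two named numeric
#'   vectors `genome` and `exome`.
#' @export
read_trinucleotide_freqs <- function(path) {
  raw <- data.table::fread(path, sep = "\t", header = TRUE,
                           data.table = FALSE)
  stopifnot(all(c("trinucleotide", "genome", "exome") %in% names(raw)))
  tri <- toupper(raw$trinucleotide)
  expected <- sort(unique(sig_channels()$trinucleotide))
  if (!setequal(tri, expected) || anyDuplicated(tri)) {
    stop("trinucleotide frequency table must list the 32 ",
         "pyrimidine-centred trinucleotides exactly once")
  }
  mk <- function(v) {
    if (any(v <= 0)) stop("trinucleotide frequencies must be positive")
    stats::setNames(v / sum(v), tri)[expected]
  }
  structure(list(genome = mk(raw$genome), exome = mk(raw$exome)),
            class = "trinuc_freqs")
}

#' Read an active-signature map
#'
#' @param path JSON file mapping cancer type to a list of signature
#'   names active in that type.
#' @return named list of character vectors.
#' @export
read_active_signatures <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  lapply(x, as.character)
}
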