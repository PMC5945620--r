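# Synthetic cohort generation: signature catalogs, Dirichlet exposures,
# multinomial channel counts, and driver mutations planted under the
# cancer-initiation model with known relative risks. Every generated
# record passes the channels_io validation, so the whole pipeline can
# be tested against ground truth.

.rdirichlet <- function(n, alpha) {
  K <- length(alpha)
  g <- matrix(stats::rgamma(n * K, shape = alpha), nrow = n,
              byrow = TRUE)
  g / rowSums(g)
}

#' Generate a synthetic signature catalog
#'
#' K signatures drawn from a symmetric Dirichlet over the 96 channels.
#' Low concentrations give spiky, signature-like profiles; high
#' concentrations approach the uniform distribution 1/96.
#'
#' @param K number of signatures.
#' @param concentration symmetric Dirichlet concentration per channel.
#' @param seed integer seed (deterministic output).
#' @param names optional signature names (default `"S1"..."SK"`).
#' @return a [sig_catalog()].
#' @export
generate_signatures <- function(K, concentration = 0.2, seed = 1L,
                                names = paste0("S", seq_len(K))) {
  stopifnot(K >= 1, concentration > 0)
  restore <- .with_seed(seed)
  on.exit(restore(), add = TRUE)
  probs <- .rdirichlet(K, rep(concentration, 96L))
  rownames(probs) <- names
  sig_catalog(probs, names = names)
}

#' Cohort specification for the synthetic generator
#'
#' @param n_samples number of samples.
#' @param catalog a [sig_catalog()] (e.g. [generate_signatures()]).
#' @param cancer_type cohort label.
#' @param burden either a single number (fixed per-sample mutation
#'   count) or `list(mean =, dispersion =)` for a negative binomial
#'   burden (`dispersion` is the NB `size`; variance = mean +
#'   mean^2/size). Default NB(mean 200, dispersion 1) so the 20-
#'   mutation cutoff filter has work to do.
#' @param exposure_prior Dirichlet concentration per active signature
#'   (named, subset of the catalog; default 1 for every catalog
#'   signature).
#' @param driver_set optional data.frame defining drivers to plant:
#'   columns `label`, `gene`, `protein_change`, `channel` (causal
#'   channel label), `r` (relative risk).
#' @param drivers_per_sample drivers planted per sample (default 1).
#' @param seed integer seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples, catalog, cancer_type = "SYNTH",
                        burden = list(mean = 200, dispersion = 1),
                        exposure_prior = NULL, driver_set = NULL,
                        drivers_per_sample = 1L, seed = 1L) {
  stopifnot(n_samples >= 1, inherits(catalog, "sig_catalog"))
  if (is.null(exposure_prior)) {
    exposure_prior <- stats::setNames(rep(1, length(catalog$names)),
                                      catalog$names)
  }
  stopifnot(all(names(exposure_prior) %in% catalog$names),
            all(exposure_prior > 0))
  if (!is.null(driver_set)) {
    need <- c("label", "gene", "protein_change", "channel", "r")
    stopifnot(all(need %in% names(driver_set)), all(driver_set$r > 0))
    channel_index(driver_set$channel)  # validates labels
  }
  structure(list(n_samples = as.integer(n_samples), catalog = catalog,
                 cancer_type = cancer_type, burden = burden,
                 exposure_prior = exposure_prior,
                 driver_set = driver_set,
                 drivers_per_sample = as.integer(drivers_per_sample),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

.draw_burden <- function(burden, n) {
  if (is.numeric(burden) && length(burden) == 1) {
    rep(as.integer(burden), n)
  } else {
    stats::rnbinom(n, size = burden$dispersion, mu = burden$mean)
  }
}

# materialise channel counts as mutation records; position parity
# decides whether the pyrimidine- or purine-strand representation is
# emitted (both classify back to the same channel, and one genomic
# position always keeps one representation, as in a real MAF)
.records_from_channels <- function(sample_id, cancer_type, ch_idx,
                                   pos, gene = "", effect = "other",
                                   protein_change = "",
                                   variant_class_label = "SNP") {
  if (length(ch_idx) == 0) {
    return(data.frame(sample_id = character(), cancer_type = character(),
                      chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      context = character(), gene = character(),
                      effect = character(),
                      variant_class_label = character(),
                      protein_change = character(),
                      stringsAsFactors = FALSE))
  }
  tab <- sig_channels()[ch_idx, , drop = FALSE]
  ref <- tab$ref; alt <- tab$alt; ctx <- tab$trinucleotide
  flip <- pos %% 2L == 0L
  if (any(flip)) {
    ref[flip] <- comp_bases(ref[flip])
    alt[flip] <- comp_bases(alt[flip])
    ctx[flip] <- revcomp(ctx[flip])
  }
  data.frame(sample_id = sample_id, cancer_type = cancer_type,
             chrom = "1", pos = as.integer(pos), ref = ref, alt = alt,
             context = ctx, gene = gene, effect = effect,
             variant_class_label = variant_class_label,
             protein_change = protein_change, stringsAsFactors = FALSE)
}

#' Generate a synthetic passenger cohort
#'
#' Per sample: exposures are drawn from the Dirichlet prior, a mutation
#' burden is drawn from the burden model, and channel counts follow a
#' multinomial over the exposure-weighted signature mixture. Each count
#' is materialised as a mutation record with a context consistent with
#' its channel (half the records, chosen by a seeded coin, are emitted
#' in the purine-strand representation). Chromosome is fixed to "1" and
#' positions are synthetic identity keys; gene is empty for passengers.
#'
#' @param spec a [cohort_spec()].
#' @return list with `records` (mutation record data.frame) and `truth`
#'   (list: `exposures` samples x K matrix, `burden` vector, `spec`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  restore <- .with_seed(spec$seed)
  on.exit(restore(), add = TRUE)
  n <- spec$n_samples
  ids <- sprintf("SIM%04d", seq_len(n))
  K_active <- names(spec$exposure_prior)
  expo_act <- .rdirichlet(n, spec$exposure_prior)
  colnames(expo_act) <- K_active
  exposures <- matrix(0, n, length(spec$catalog$names),
                      dimnames = list(ids, spec$catalog$names))
  exposures[, K_active] <- expo_act
  burden <- .draw_burden(spec$burden, n)
  mix <- exposures %*% spec$catalog$probs   # n x 96
  recs <- vector("list", n)
  pos0 <- 0L
  for (i in seq_len(n)) {
    if (burden[i] == 0) next
    cnt <- drop(stats::rmultinom(1, burden[i], mix[i, ]))
    ch_idx <- rep.int(seq_len(96L), cnt)
    recs[[i]] <- .records_from_channels(
      ids[i], spec$cancer_type, ch_idx,
      pos = pos0 + seq_along(ch_idx))
    pos0 <- pos0 + length(ch_idx)
  }
  n_zero <- sum(burden == 0)
  if (n_zero > 0) {
    message(sprintf("%d sample(s) generated with zero mutations",
                    n_zero))
  }
  records <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
  if (is.null(records)) {
    records <- .records_from_channels(character(0), character(0),
                                      integer(0), integer(0))
  }
  rownames(records) <- NULL
  list(records = records,
       truth = list(exposures = exposures, burden = burden,
                    sample_ids = ids, spec = spec))
}

#' Plant driver mutations under the initiation model
#'
#' Each sample receives `drivers_per_sample` driver records. Driver j
#' is chosen with probability r_j * p_ij / sum_k r_k * p_ik, where
#' p_ij is the channel probability of driver j's causal channel under
#' the sample's true exposures — the multi-mutation generalisation of
#' the conditional occurrence probability under relative risk. Driver
#' records are appended on top of the passenger counts (the analysis
#' pipeline excludes driver non-synonymous mutations from signature
#' fitting, so passenger counts stay exactly multinomial). All records
#' of the same driver share one genomic position so recurrence counting
#' sees them as one DNA change.
#'
#' @param spec a [cohort_spec()] with a non-NULL `driver_set`.
#' @param cohort result of [generate_cohort()] for the same spec.
#' @return the cohort list with driver records appended to `records`
#'   and `truth$drivers` (data.frame sample_id, label) added.
#' @export
plant_drivers <- function(spec, cohort) {
  stopifnot(inherits(spec, "cohort_spec"), !is.null(spec$driver_set))
  restore <- .with_seed(.derive_seed(spec$seed, "plant_drivers"))
  on.exit(restore(), add = TRUE)
  ds <- spec$driver_set
  exposures <- cohort$truth$exposures
  ids <- cohort$truth$sample_ids
  ch_idx <- channel_index(ds$channel)
  # p_ij: samples x drivers channel probabilities under true exposures
  p <- exposures %*% spec$catalog$probs[, ch_idx, drop = FALSE]
  w <- sweep(p, 2, ds$r, `*`)
  drec <- vector("list", length(ids))
  planted <- character(length(ids))
  skipped <- 0L
  pos_map <- 10000000L + seq_len(nrow(ds))  # fixed position per driver
  for (i in seq_along(ids)) {
    if (sum(w[i, ]) == 0) { skipped <- skipped + 1L; next }
    js <- sample.int(nrow(ds), spec$drivers_per_sample,
                     replace = FALSE,
                     prob = w[i, ])
    planted[i] <- ds$label[js[1]]
    drec[[i]] <- .records_from_channels(
      ids[i], spec$cancer_type, ch_idx[js], pos = pos_map[js],
      gene = ds$gene[js], effect = "nonsynonymous_SNV",
      protein_change = ds$protein_change[js])
  }
  if (skipped > 0) {
    warning(sprintf(
      "%d sample(s) skipped: zero probability for every driver",
      skipped))
  }
  driver_records <- do.call(rbind,
                            drec[!vapply(drec, is.null, logical(1))])
  cohort$records <- rbind(cohort$records, driver_records)
  rownames(cohort$records) <- NULL
  cohort$truth$drivers <- data.frame(
    sample_id = ids[nzchar(planted)],
    label = planted[nzchar(planted)], stringsAsFactors = FALSE)
  cohort
}
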