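# Per-sample signature exposure fitting and calibration of the
# minimum-mutation cutoff.

#' Fit signature exposures by non-negative least squares
#'
#' For each sample, regresses the raw 96-channel count vector on the
#' active signatures' channel probabilities under a non-negativity
#' constraint. The fitted weights ("activity", on the mutation-count
#' scale) are normalised per sample to give exposures summing to 1.
#' Inactive signatures get activity and exposure 0. NNLS is run on raw
#' counts (not frequencies) so mutation-rich samples carry more weight;
#' normalisation happens after fitting.
#'
#' @param counts a `channel_counts` object ([count_channels()]) or a
#'   samples x 96 count matrix with sample rownames.
#' @param catalog a [sig_catalog()].
#' @param active character vector of active signature names (subset of
#'   the catalog); defaults to all.
#' @return object of class `exposure_fit`: list with `sample_ids`,
#'   `activity` and `exposure` (samples x K matrices over all catalog
#'   signatures), `total` (mutation counts), `flagged` (logical; TRUE
#'   for all-zero count rows whose exposure is undefined and set to 0),
#'   `active`.
#' @export
fit_exposures <- function(counts, catalog, active = catalog$names) {
  if (inherits(counts, "channel_counts")) counts <- counts$counts
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) == 96L)
  if (length(active) == 0) stop("'active' must be non-empty")
  missing <- setdiff(active, catalog$names)
  if (length(missing)) {
    stop("active signatures not in catalog: ",
         paste(missing, collapse = ", "))
  }
  K <- length(catalog$names)
  n <- nrow(counts)
  A <- t(catalog$probs[active, , drop = FALSE])   # 96 x |active|
  activity <- matrix(0, n, K,
                     dimnames = list(rownames(counts), catalog$names))
  flagged <- logical(n)
  for (i in seq_len(n)) {
    b <- counts[i, ]
    if (sum(b) == 0) { flagged[i] <- TRUE; next }
    activity[i, active] <- nnls_fit(A, b)$x
  }
  tot_act <- rowSums(activity)
  exposure <- activity
  pos <- tot_act > 0
  exposure[pos, ] <- activity[pos, , drop = FALSE] / tot_act[pos]
  flagged <- flagged | !pos
  structure(list(sample_ids = rownames(counts), activity = activity,
                 exposure = exposure, total = rowSums(counts),
                 flagged = flagged, active = active),
            class = "exposure_fit")
}

#' @export
print.exposure_fit <- function(x, ...) {
  cat(sprintf(
    "exposure_fit: %d samples, %d active signatures, %d flagged\n",
    length(x$sample_ids), length(x$active), sum(x$flagged)))
  invisible(x)
}

#' Exposure table for output
#'
#' @param fit an `exposure_fit`.
#' @param cancer_type optional cancer type label(s) to attach.
#' @param min_mutations cutoff used for the below-cutoff flag.
#' @return data.frame: sample_id, cancer_type, one exposure column per
#'   signature, total mutation count and `below_cutoff` flag.
#' @export
exposure_table <- function(fit, cancer_type = NA_character_,
                           min_mutations = 20L) {
  data.frame(sample_id = fit$sample_ids, cancer_type = cancer_type,
             fit$exposure, total = fit$total,
             below_cutoff = fit$total < min_mutations,
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' Calibrate the minimum-mutation cutoff by simulation
#'
#' Treats each signature as a multinomial distribution over the 96
#' channels, simulates count vectors with `n` total mutations, and
#' refits them by NNLS against the true signature plus `n_decoys`
#' randomly chosen other signatures. A replicate is a success when the
#' true signature receives more than `success_threshold` of the summed
#' regression weights. Decoys are redrawn fresh per replicate, uniformly
#' without replacement.
#'
#' @param catalog a [sig_catalog()].
#' @param n_grid integer vector of total mutation counts to test.
#' @param n_decoys number of decoy signatures per regression.
#' @param success_threshold fraction of summed weights the true
#'   signature must exceed.
#' @param reps replicates per (signature, n) cell.
#' @param seed integer seed controlling the whole procedure.
#' @return list with `success` (signatures x length(n_grid) matrix of
#'   success proportions), `mean_by_n` (named vector: mean proportion
#'   across signatures per n), `n_grid`.
#' @export
calibrate_min_mutations <- function(catalog, n_grid, n_decoys = 14L,
                                    success_threshold = 0.5,
                                    reps = 200L, seed = 1L) {
  K <- length(catalog$names)
  if (n_decoys >= K) stop("n_decoys must be smaller than the catalog size")
  if (reps < 1) stop("reps must be >= 1")
  stopifnot(all(n_grid >= 1), all(n_grid <= 96 * 1e6))
  withr_seed <- .with_seed(seed)
  on.exit(withr_seed(), add = TRUE)
  success <- matrix(NA_real_, K, length(n_grid),
                    dimnames = list(catalog$names,
                                    as.character(n_grid)))
  for (k in seq_len(K)) {
    p_true <- catalog$probs[k, ]
    for (ni in seq_along(n_grid)) {
      n <- n_grid[ni]
      ok <- logical(reps)
      for (r in seq_len(reps)) {
        b <- drop(stats::rmultinom(1, n, p_true))
        others <- if (n_decoys > 0) {
          sample(setdiff(seq_len(K), k), n_decoys)
        } else integer(0)
        A <- t(catalog$probs[c(k, others), , drop = FALSE])
        w <- nnls_fit(A, b)$x
        ok[r] <- sum(w) > 0 && w[1] / sum(w) > success_threshold
      }
      success[k, ni] <- mean(ok)
    }
  }
  list(success = success,
       mean_by_n = stats::setNames(colMeans(success),
                                   as.character(n_grid)),
       n_grid = n_grid)
}

# save/restore the global RNG state around seeded procedures so that
# package functions never clobber the caller's random stream
.with_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

# deterministic substream derivation: fold a label into the base seed
.derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}
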