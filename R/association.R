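# Associations between signature exposures and recurrent driver
# mutations: recurrence detection, causal-channel enrichment, one-sided
# rank-sum testing with BH FDR control, and simulation-based power.

#' Find recurrent driver mutations
#'
#' Counts identical DNA changes — keyed by (gene, chrom, pos, ref, alt)
#' — per cancer type and returns those occurring at least `min_count`
#' times, together with their causal channel (the trinucleotide channel
#' of the DNA change).
#'
#' @param driver_records mutation records already restricted to driver
#'   genes ([filter_driver_nonsynonymous()]).
#' @param min_count minimum per-cancer-type recurrence (default 4).
#' @return data.frame: cancer_type, gene, chrom, pos, ref, alt,
#'   protein_change, causal_channel (label), recurrence.
#' @export
find_recurrent <- function(driver_records, min_count = 4L) {
  empty <- data.frame(cancer_type = character(), gene = character(),
                      chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      protein_change = character(),
                      causal_channel = character(),
                      recurrence = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(driver_records) == 0) return(empty)
  dt <- data.table::as.data.table(driver_records)
  agg <- dt[, list(protein_change = protein_change[1],
                   context = context[1],
                   recurrence = .N),
            by = c("cancer_type", "gene", "chrom", "pos", "ref", "alt")]
  agg <- agg[agg$recurrence >= min_count, ]
  if (nrow(agg) == 0) return(empty)
  agg$causal_channel <- classify_channel(agg$ref, agg$alt, agg$context)
  out <- as.data.frame(agg[, c("cancer_type", "gene", "chrom", "pos",
                               "ref", "alt", "protein_change",
                               "causal_channel", "recurrence")])
  out[order(-out$recurrence, out$gene, out$pos), , drop = FALSE]
}

#' Signatures enriched for a channel
#'
#' Returns the active signatures whose probability on the given channel
#' is strictly above the (unweighted) mean of that channel's probability
#' across all active signatures. With `weights` supplied, the mean is
#' exposure-weighted instead.
#'
#' @param channel channel label or index.
#' @param catalog a [sig_catalog()].
#' @param active character vector of active signature names.
#' @param weights optional non-negative weights (one per active
#'   signature) for a weighted mean.
#' @return character vector of enriched signature names (may be empty).
#' @export
enriched_signatures <- function(channel, catalog, active,
                                weights = NULL) {
  stopifnot(length(active) > 0)
  if (is.character(channel)) channel <- channel_index(channel)
  p <- catalog$probs[active, channel]
  mu <- if (is.null(weights)) mean(p) else {
    stopifnot(length(weights) == length(active), all(weights >= 0))
    sum(p * weights) / sum(weights)
  }
  active[p > mu]
}

#' One-sided rank-sum test of exposure difference
#'
#' Tests whether carriers of a mutation have stochastically larger
#' exposure of a signature than non-carriers (Mann-Whitney U,
#' alternative: carrier-higher). The exact null distribution is used
#' when both groups have at most `exact_limit` samples and there are no
#' ties; otherwise the normal approximation with tie correction is used.
#' A fully tied comparison (null variance 0) returns p = 1.
#'
#' @param exposures numeric vector of one signature's exposure per
#'   sample.
#' @param carriers logical vector, TRUE for carriers.
#' @param alternative `"greater"` (carrier-higher, default) or
#'   `"less"`.
#' @param exact_limit group-size bound for the exact path.
#' @return list with `p_value`, `u` (Mann-Whitney U for the carrier
#'   group), `n_carriers`, `n_noncarriers`, `method`, `ok` (FALSE, with
#'   `p_value = NA`, when either group is empty).
#' @export
test_association <- function(exposures, carriers,
                             alternative = c("greater", "less"),
                             exact_limit = 20L) {
  alternative <- match.arg(alternative)
  stopifnot(length(exposures) == length(carriers))
  n1 <- sum(carriers); n2 <- sum(!carriers)
  if (n1 == 0 || n2 == 0) {
    return(list(p_value = NA_real_, u = NA_real_, n_carriers = n1,
                n_noncarriers = n2, method = "no-test", ok = FALSE))
  }
  x <- exposures[carriers]; y <- exposures[!carriers]
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  if (!ties && n1 <= exact_limit && n2 <= exact_limit) {
    # exact null distribution of U (tie-free)
    p <- if (alternative == "greater") {
      stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE)  # P(U >= u)
    } else {
      stats::pwilcox(u, n1, n2)                          # P(U <= u)
    }
    method <- "exact"
  } else {
    n <- n1 + n2
    mu <- n1 * n2 / 2
    tie_tab <- table(c(x, y))
    sig2 <- n1 * n2 / 12 *
      ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sig2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu - ifelse(alternative == "greater", 0.5, -0.5)) /
        sqrt(sig2)   # continuity correction
      p <- if (alternative == "greater") {
        stats::pnorm(z, lower.tail = FALSE)
      } else {
        stats::pnorm(z)
      }
    }
    method <- "normal"
  }
  list(p_value = min(max(p, 0), 1), u = u, n_carriers = n1,
       n_noncarriers = n2, method = method, ok = TRUE)
}

#' Benjamini-Hochberg FDR control
#'
#' @param p_values numeric vector of p-values in [0, 1] (NA allowed;
#'   propagated).
#' @param alpha FDR level for the significance flag.
#' @return list with `q` (BH step-up q-values) and `significant`
#'   (`q <= alpha`).
#' @export
bh_fdr <- function(p_values, alpha = 0.05) {
  stopifnot(all(is.na(p_values) | (p_values >= 0 & p_values <= 1)))
  q <- stats::p.adjust(p_values, method = "BH")
  list(q = q, significant = !is.na(q) & q <= alpha)
}

#' Simulation-based power for a mutation-signature association
#'
#' Implements a simple cancer-initiation power model: the mutation of
#' interest M is one of `n_set` mutations, one of which is required for
#' initiation. Per iteration, the other `n_set - 1` causal channels are
#' drawn uniformly without replacement from the 95 channels other than
#' M's; per-sample probabilities p_i that M occurred rather than any
#' decoy are computed from the exposure-weighted channel mixture; `m`
#' carriers are drawn without replacement with probability proportional
#' to p_i; and the one-sided rank-sum test on `signature` is applied.
#' Power is the fraction of iterations with p < alpha (p <= alpha only
#' at the boundary alpha = 1, so the degenerate case is exact).
#'
#' @param exposures samples x K exposure matrix (rows sum to 1), or an
#'   `exposure_fit`.
#' @param catalog a [sig_catalog()].
#' @param mutation_channel causal channel of M (label or index).
#' @param m number of carriers to plant.
#' @param signature signature name tested for association.
#' @param alpha significance level.
#' @param n_set size of the initiating mutation set (default 10).
#' @param iterations Monte Carlo iterations.
#' @param seed integer seed.
#' @return list with `power`, `alpha`, `m`, `n_set`, `iterations`,
#'   `n_skipped`.
#' @export
estimate_power <- function(exposures, catalog, mutation_channel, m,
                           signature, alpha = 0.05, n_set = 10L,
                           iterations = 1000L, seed = 1L) {
  if (inherits(exposures, "exposure_fit")) exposures <- exposures$exposure
  exposures <- as.matrix(exposures)
  stopifnot(m >= 1, m <= nrow(exposures), iterations >= 1, n_set >= 1)
  if (is.character(mutation_channel)) {
    mutation_channel <- channel_index(mutation_channel)
  }
  restore <- .with_seed(seed)
  on.exit(restore(), add = TRUE)
  # samples x 96 mixture probabilities
  mix <- exposures[, catalog$names, drop = FALSE] %*% catalog$probs
  sig_expo <- exposures[, signature]
  n <- nrow(exposures)
  hits <- 0L; skipped <- 0L
  for (it in seq_len(iterations)) {
    decoys <- sample(setdiff(seq_len(96L), mutation_channel),
                     n_set - 1L)
    denom <- rowSums(mix[, c(mutation_channel, decoys), drop = FALSE])
    p_i <- ifelse(denom > 0, mix[, mutation_channel] / denom, 0)
    if (sum(p_i) == 0) {
      warning("iteration skipped: all per-sample probabilities zero")
      skipped <- skipped + 1L
      next
    }
    carriers <- logical(n)
    carriers[sample.int(n, m, prob = p_i)] <- TRUE
    p <- test_association(sig_expo, carriers)$p_value
    reject <- if (alpha >= 1) p <= alpha else p < alpha
    if (isTRUE(reject)) hits <- hits + 1L
  }
  if (skipped == iterations) stop("all power iterations skipped")
  list(power = hits / (iterations - skipped), alpha = alpha, m = m,
       n_set = n_set, iterations = iterations, n_skipped = skipped)
}

#' Scan a cohort for mutation-signature associations
#'
#' For each cancer type, finds recurrent driver mutations, restricts to
#' signatures enriched for each mutation's causal channel (unless
#' `restrict_to_enriched = FALSE`, in which case all active signatures
#' are tested), tests carriers vs non-carriers among samples at or above
#' the mutation-count cutoff, and applies BH over all tests in the scan
#' (set `per_type_fdr = TRUE` to adjust within each cancer type).
#'
#' @param records all mutation records for the cohort.
#' @param driver_genes character vector of driver gene symbols.
#' @param catalog a [sig_catalog()].
#' @param active_by_type named list: cancer type -> active signature
#'   names.
#' @param min_recurrence recurrence threshold (default 4).
#' @param min_mutations per-sample mutation-count cutoff (default 20).
#' @param alpha FDR level (default 0.05).
#' @param restrict_to_enriched test only causal-channel-enriched
#'   signatures (default TRUE).
#' @param per_type_fdr apply BH within cancer type instead of globally.
#' @param exposures optional precomputed `exposure_fit` per cancer type
#'   (named list); fitted on the fly when NULL.
#' @return data.frame of class `association_scan`, one row per test,
#'   sorted by q-value: cancer_type, gene, protein_change, chrom, pos,
#'   ref, alt, causal_channel, signature, enriched, n_carriers,
#'   n_noncarriers, recurrence, direction, p, q, significant.
#' @export
run_association_scan <- function(records, driver_genes, catalog,
                                 active_by_type,
                                 min_recurrence = 4L,
                                 min_mutations = 20L, alpha = 0.05,
                                 restrict_to_enriched = TRUE,
                                 per_type_fdr = FALSE,
                                 exposures = NULL) {
  drivers <- filter_driver_nonsynonymous(records, driver_genes)
  rows <- list()
  for (ct in names(active_by_type)) {
    active <- active_by_type[[ct]]
    rec_ct <- records[records$cancer_type == ct, , drop = FALSE]
    if (nrow(rec_ct) == 0) next
    drv_ct <- drivers[drivers$cancer_type == ct, , drop = FALSE]
    counts <- count_channels(rec_ct, exclude = drv_ct)
    keep <- counts$total >= min_mutations
    n_excl <- sum(!keep)
    if (n_excl > 0) {
      message(sprintf(
        "%s: excluded %d sample(s) with fewer than %d mutations",
        ct, n_excl, min_mutations))
    }
    samples <- rownames(counts$counts)[keep]
    if (length(samples) < 2) next
    fit <- if (!is.null(exposures)) exposures[[ct]] else {
      fit_exposures(counts$counts[samples, , drop = FALSE], catalog,
                    active)
    }
    expo <- fit$exposure[match(samples, fit$sample_ids), , drop = FALSE]
    recur <- find_recurrent(drv_ct, min_count = min_recurrence)
    if (nrow(recur) == 0) next
    for (i in seq_len(nrow(recur))) {
      key <- recur[i, ]
      carrier_ids <- unique(drv_ct$sample_id[
        drv_ct$gene == key$gene & drv_ct$chrom == key$chrom &
        drv_ct$pos == key$pos & drv_ct$ref == key$ref &
        drv_ct$alt == key$alt])
      carriers <- samples %in% carrier_ids
      enr <- enriched_signatures(key$causal_channel, catalog, active)
      test_sigs <- if (restrict_to_enriched) enr else active
      for (s in test_sigs) {
        tst <- test_association(expo[, s], carriers)
        med_diff <- stats::median(expo[carriers, s]) -
          stats::median(expo[!carriers, s])
        rows[[length(rows) + 1L]] <- data.frame(
          cancer_type = ct, gene = key$gene,
          protein_change = key$protein_change, chrom = key$chrom,
          pos = key$pos, ref = key$ref, alt = key$alt,
          causal_channel = key$causal_channel, signature = s,
          enriched = s %in% enr, n_carriers = tst$n_carriers,
          n_noncarriers = tst$n_noncarriers,
          recurrence = key$recurrence,
          direction = ifelse(isTRUE(med_diff >= 0), "carrier_higher",
                             "carrier_lower"),
          p = tst$p_value, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    out <- data.frame(cancer_type = character(), gene = character(),
                      protein_change = character(), chrom = character(),
                      pos = integer(), ref = character(),
                      alt = character(), causal_channel = character(),
                      signature = character(), enriched = logical(),
                      n_carriers = integer(), n_noncarriers = integer(),
                      recurrence = integer(), direction = character(),
                      p = numeric(), q = numeric(),
                      significant = logical(), stringsAsFactors = FALSE)
    class(out) <- c("association_scan", class(out))
    return(out)
  }
  out <- do.call(rbind, rows)
  if (per_type_fdr) {
    out$q <- NA_real_; out$significant <- NA
    for (ct in unique(out$cancer_type)) {
      idx <- out$cancer_type == ct
      adj <- bh_fdr(out$p[idx], alpha)
      out$q[idx] <- adj$q; out$significant[idx] <- adj$significant
    }
  } else {
    adj <- bh_fdr(out$p, alpha)
    out$q <- adj$q; out$significant <- adj$significant
  }
  out <- out[order(out$q, out$p), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("association_scan", class(out))
  out
}

#' Enrichment contrast for an unrestricted scan
#'
#' Given an unrestricted association scan, tests whether significant
#' carrier-higher associations are enriched among signatures where the
#' causal channel is above average (Fisher's exact test on the 2 x 2
#' table of significance x enrichment).
#'
#' @param scan result of [run_association_scan()] with
#'   `restrict_to_enriched = FALSE`.
#' @return the `htest` object from [stats::fisher.test()], with the
#'   contingency table in `$table`.
#' @export
enrichment_contrast <- function(scan) {
  tab <- table(significant = factor(scan$significant, c(FALSE, TRUE)),
               enriched = factor(scan$enriched, c(FALSE, TRUE)))
  ht <- stats::fisher.test(tab)
  ht$table <- tab
  ht
}
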