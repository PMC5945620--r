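# Differential selection between driver mutations: the multistage
# cancer-initiation model, per-sample causal-channel probabilities, the
# exact Poisson binomial test, and maximum-likelihood relative-risk
# estimation with bootstrap confidence intervals.

#' Multistage cancer-initiation model
#'
#' Mutations occur at constant low per-year rates u_i (u_i << 1); after
#' a sequence S_j of n mutations has occurred, cancer follows at a
#' constant low rate lambda_j. Under these assumptions the incidence
#' probability at time t is
#'   I(t) = sum_j u_1(j) ... u_n(j) * lambda_j * t^n / n!
#'
#' @param sequences list of numeric vectors, one per mutation sequence,
#'   each holding the per-year rates u_1..u_n of its mutations; all
#'   sequences must have the same length n.
#' @param lambda numeric vector of per-year cancer rates, one per
#'   sequence.
#' @return object of class `cancer_initiation_model`.
#' @export
cancer_initiation_model <- function(sequences, lambda) {
  stopifnot(is.list(sequences), length(sequences) == length(lambda))
  n <- unique(vapply(sequences, length, integer(1)))
  if (length(n) != 1) stop("all sequences must have the same length")
  if (any(unlist(sequences) <= 0) || any(lambda <= 0)) {
    stop("all rates must be positive")
  }
  structure(list(sequences = sequences, lambda = lambda, n = n),
            class = "cancer_initiation_model")
}

#' Expected cancer incidence at time t
#'
#' @param model a [cancer_initiation_model()].
#' @param t time in years (non-negative). The formula is valid in the
#'   regime u_i * t << 1 and lambda * t << 1.
#' @return incidence probability I(t).
#' @export
expected_incidence <- function(model, t) {
  stopifnot(inherits(model, "cancer_initiation_model"), t >= 0)
  terms <- vapply(seq_along(model$lambda), function(j) {
    prod(model$sequences[[j]]) * model$lambda[j]
  }, numeric(1))
  sum(terms) * t^model$n / factorial(model$n)
}

#' Conditional occurrence probability under relative risk
#'
#' For two mutations with rates u1 and u2 that are "similar with
#' relative risk r" (substituting mutation 1 for mutation 2 in any
#' cancer-causing sequence multiplies the cancer rate by r), the
#' probability that mutation 1 occurred given that exactly one of the
#' two did is u1 * r / (u1 * r + u2).
#'
#' @param u1,u2 positive occurrence rates (or probabilities).
#' @param r positive relative risk of mutation 1 vs mutation 2.
#' @return probability in (0, 1), strictly increasing in r.
#' @export
conditional_probability <- function(u1, u2, r) {
  if (any(u1 <= 0) || any(u2 <= 0)) stop("rates must be positive")
  if (any(r <= 0)) stop("relative risk must be positive")
  u1 * r / (u1 * r + u2)
}

#' Per-sample channel probability under a signature mixture
#'
#' The probability that a mutation in a given sample falls in a given
#' channel, based on the sample's fitted exposures: the exposure-
#' weighted mixture sum_k exposure_k * probs[k, channel]. Over the 96
#' channels these probabilities sum to 1.
#'
#' @param exposure named numeric vector of normalised exposures (must
#'   sum to 1 within `tol`; names are catalog signature names), or a
#'   samples x K matrix for the vectorised form.
#' @param catalog a [sig_catalog()].
#' @param channel channel label or index (vectorised).
#' @param tol normalisation tolerance.
#' @return numeric: one probability per channel (or a samples x
#'   channels matrix when `exposure` is a matrix).
#' @export
channel_probability <- function(exposure, catalog, channel,
                                tol = 1e-6) {
  if (is.character(channel)) channel <- channel_index(channel)
  if (is.matrix(exposure)) {
    if (any(abs(rowSums(exposure) - 1) > tol)) {
      stop("exposure rows must be normalised to sum to 1")
    }
    mix <- exposure[, catalog$names, drop = FALSE] %*%
      catalog$probs[, channel, drop = FALSE]
    return(mix[, , drop = length(channel) == 1])
  }
  if (abs(sum(exposure) - 1) > tol) {
    stop("exposure must be normalised to sum to 1")
  }
  unname(drop(crossprod(exposure[catalog$names],
                        catalog$probs[, channel, drop = FALSE])))
}

#' Exact Poisson binomial probability mass function
#'
#' PMF of the number of successes in independent Bernoulli trials with
#' success probabilities q, computed by iterative convolution (dynamic
#' programme); exact up to floating point, sums to 1 within 1e-12.
#'
#' @param q numeric vector of probabilities in [0, 1].
#' @return numeric vector of length `length(q) + 1`: P(X = 0..n).
#' @export
poibin_pmf <- function(q) {
  stopifnot(all(q >= 0 & q <= 1))
  pmf <- 1
  for (qi in q) {
    pmf <- c(pmf * (1 - qi), 0) + c(0, pmf * qi)
  }
  pmf
}

#' Two-tailed Poisson binomial test
#'
#' Tests whether an observed success count m1 is consistent with
#' X ~ Poibin(q). The default minimum-likelihood rule sums the
#' probabilities of all outcomes no more likely than the observed one
#' (with a 1 + 1e-9 relative tolerance for floating-point ties); the
#' `"double"` method doubles the smaller tail probability (capped at
#' 1).
#'
#' @param q success probabilities.
#' @param m1 observed count, 0 <= m1 <= length(q).
#' @param method `"minlik"` (default) or `"double"`.
#' @return two-sided p-value in (0, 1].
#' @export
poibin_two_tailed_test <- function(q, m1,
                                   method = c("minlik", "double")) {
  method <- match.arg(method)
  stopifnot(m1 >= 0, m1 <= length(q), m1 == round(m1))
  pmf <- poibin_pmf(q)
  obs <- pmf[m1 + 1]
  p <- if (method == "minlik") {
    sum(pmf[pmf <= obs * (1 + 1e-9)])
  } else {
    lo <- sum(pmf[seq_len(m1 + 1)])        # P(X <= m1)
    hi <- sum(pmf[(m1 + 1):length(pmf)])   # P(X >= m1)
    2 * min(lo, hi)
  }
  min(max(p, obs), 1)
}

#' Select comparable samples for a mutation pair
#'
#' For mutations M1 and M2 drawn from a mutation set under
#' consideration, returns the samples carrying exactly one of M1, M2
#' and no other mutation in the set, with the per-sample causal-channel
#' probabilities p1 and p2 and the test probability
#' q = p1 / (p1 + p2). Samples with p1 + p2 = 0 are excluded with a
#' warning.
#'
#' @param carriers samples x mutations logical matrix (colnames are
#'   mutation labels) giving carrier status for every mutation in the
#'   set.
#' @param exposure samples x K normalised exposure matrix (rownames
#'   matching `carriers`).
#' @param catalog a [sig_catalog()].
#' @param channels named character vector: causal channel label per
#'   mutation label.
#' @param m1,m2 labels of the two mutations compared.
#' @return data.frame: sample_id, carrier_of (1 or 2), p1, p2, q; zero
#'   rows when no sample qualifies.
#' @export
select_comparable_samples <- function(carriers, exposure, catalog,
                                      channels, m1, m2) {
  stopifnot(m1 %in% colnames(carriers), m2 %in% colnames(carriers),
            m1 != m2, !is.null(rownames(carriers)))
  others <- setdiff(colnames(carriers), c(m1, m2))
  one_of_pair <- xor(carriers[, m1], carriers[, m2])
  no_other <- if (length(others)) {
    rowSums(carriers[, others, drop = FALSE]) == 0
  } else rep(TRUE, nrow(carriers))
  keep <- which(one_of_pair & no_other)
  ids <- rownames(carriers)[keep]
  expo <- exposure[match(ids, rownames(exposure)), , drop = FALSE]
  p1 <- as.numeric(channel_probability(expo, catalog, channels[[m1]]))
  p2 <- as.numeric(channel_probability(expo, catalog, channels[[m2]]))
  out <- data.frame(sample_id = ids,
                    carrier_of = ifelse(carriers[keep, m1], 1L, 2L),
                    p1 = p1, p2 = p2,
                    q = ifelse(p1 + p2 > 0, p1 / (p1 + p2), NA_real_),
                    stringsAsFactors = FALSE)
  if (any(is.na(out$q))) {
    warning(sprintf("%d sample(s) excluded with p1 + p2 = 0",
                    sum(is.na(out$q))))
    out <- out[!is.na(out$q), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

# negative log-likelihood of log r for the relative-risk model
# q_i(r) = r * p1 / (r * p1 + p2)
.rr_negll <- function(log_r, p1, p2, is_m1) {
  q <- exp(log_r) * p1 / (exp(log_r) * p1 + p2)
  -sum(log(q[is_m1])) - sum(log(1 - q[!is_m1]))
}

#' Maximum-likelihood relative risk with bootstrap CI
#'
#' Fits the relative risk r of M1 vs M2 by maximising
#' L = prod_{i in I1} q_i * prod_{i in I2} (1 - q_i) with
#' q_i = r * p_i1 / (r * p_i1 + p_i2), by bounded one-dimensional
#' optimisation of log r on [-12, 12] (natural-log scale). When one
#' carrier class is empty the likelihood is monotone; the estimate is
#' reported as censored at the boundary (infinite CI side) rather than
#' as a finite number. Percentile confidence intervals come from
#' resampling whole samples (carrier label and probability pair
#' jointly) with replacement.
#'
#' @param samples data.frame from [select_comparable_samples()]
#'   (columns p1, p2, carrier_of), or NULL if supplying vectors.
#' @param p1,p2,is_m1 alternative vector interface: channel
#'   probabilities and logical M1-carrier indicator.
#' @param bootstrap_iters bootstrap iterations (default 100).
#' @param seed integer seed for the bootstrap.
#' @param conf confidence level (default 0.95).
#' @param log_bound half-width of the log r search interval.
#' @return list of class `relative_risk`: `r` (MLE), `log_r`, `ci_low`,
#'   `ci_high` (Inf/0 when censored), `censored` ("none", "upper",
#'   "lower"), `n`, `m1`, `m2`, `boot` (bootstrap estimates of r).
#' @export
fit_relative_risk <- function(samples = NULL, p1 = samples$p1,
                              p2 = samples$p2,
                              is_m1 = samples$carrier_of == 1L,
                              bootstrap_iters = 100L, seed = 1L,
                              conf = 0.95, log_bound = 12) {
  stopifnot(length(p1) == length(p2), length(p1) == length(is_m1),
            length(p1) >= 1, all(p1 >= 0), all(p2 >= 0),
            all(p1 + p2 > 0))
  n1 <- sum(is_m1); n2 <- sum(!is_m1)
  point <- function(p1, p2, is_m1) {
    if (all(is_m1)) return(exp(log_bound))
    if (!any(is_m1)) return(exp(-log_bound))
    opt <- stats::optimize(.rr_negll, c(-log_bound, log_bound),
                           p1 = p1, p2 = p2, is_m1 = is_m1,
                           tol = 1e-8)
    exp(opt$minimum)
  }
  r_hat <- point(p1, p2, is_m1)
  censored <- if (n2 == 0) "upper" else if (n1 == 0) "lower" else "none"
  boot <- numeric(0)
  ci <- c(NA_real_, NA_real_)
  if (censored == "none" && bootstrap_iters > 0) {
    restore <- .with_seed(seed)
    on.exit(restore(), add = TRUE)
    n <- length(p1)
    boot <- vapply(seq_len(bootstrap_iters), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      point(p1[idx], p2[idx], is_m1[idx])
    }, numeric(1))
    ci <- unname(stats::quantile(boot, c((1 - conf) / 2,
                                         1 - (1 - conf) / 2)))
  } else if (censored == "upper") {
    ci <- c(NA_real_, Inf)
  } else if (censored == "lower") {
    ci <- c(0, NA_real_)
  }
  structure(list(r = if (censored == "none") r_hat else
                   switch(censored, upper = Inf, lower = 0),
                 log_r = if (censored == "none") log(r_hat) else
                   switch(censored, upper = Inf, lower = -Inf),
                 ci_low = ci[1], ci_high = ci[2], censored = censored,
                 n = length(p1), m1 = n1, m2 = n2, boot = boot),
            class = "relative_risk")
}

#' @export
print.relative_risk <- function(x, ...) {
  cat(sprintf(
    "relative risk: r = %s [%s, %s]%s (n = %d; m1 = %d, m2 = %d)\n",
    format(x$r, digits = 4), format(x$ci_low, digits = 4),
    format(x$ci_high, digits = 4),
    if (x$censored != "none") paste0(" censored: ", x$censored) else "",
    x$n, x$m1, x$m2))
  invisible(x)
}

#' Pairwise differential-selection scan
#'
#' Within one cancer type, identifies the common driver mutations in a
#' gene set (each accounting for more than `common_fraction` of the
#' set's non-silent driver mutations in that type, and jointly
#' occurring at least `min_occurrence` times), then for every unordered
#' pair runs the comparable-sample selection, the two-tailed Poisson
#' binomial test and the relative-risk MLE, applying BH over all
#' pairwise p-values.
#'
#' @param records all mutation records of the cohort.
#' @param genes character vector of driver genes forming the set.
#' @param cancer_type cancer type scanned.
#' @param exposure samples x K normalised exposure matrix with sample
#'   rownames (e.g. from [fit_exposures()]).
#' @param catalog a [sig_catalog()].
#' @param common_fraction recurrence fraction defining "common"
#'   (default 0.01).
#' @param min_occurrence minimum total count of the common mutations
#'   (default 10).
#' @param fdr FDR level (default 0.05).
#' @param bootstrap_iters,seed passed to [fit_relative_risk()].
#' @param two_sided_method passed to [poibin_two_tailed_test()].
#' @return data.frame of class `selection_scan`, one row per pair:
#'   cancer_type, mutation_1, mutation_2, n_included, m1, m2, p, q,
#'   r_mle, ci_low, ci_high, censored.
#' @export
pairwise_selection_scan <- function(records, genes, cancer_type,
                                    exposure, catalog,
                                    common_fraction = 0.01,
                                    min_occurrence = 10L, fdr = 0.05,
                                    bootstrap_iters = 100L, seed = 1L,
                                    two_sided_method = "minlik") {
  drv <- records[records$cancer_type == cancer_type &
                 records$gene %in% genes &
                 records$effect %in% c("nonsynonymous_SNV", "stopgain",
                                       "stoploss"), , drop = FALSE]
  empty <- data.frame(cancer_type = character(),
                      mutation_1 = character(),
                      mutation_2 = character(), n_included = integer(),
                      m1 = integer(), m2 = integer(), p = numeric(),
                      q = numeric(), r_mle = numeric(),
                      ci_low = numeric(), ci_high = numeric(),
                      censored = character(), stringsAsFactors = FALSE)
  class(empty) <- c("selection_scan", class(empty))
  if (nrow(drv) == 0) return(empty)
  keys <- find_recurrent(drv, min_count = 1L)
  keys$frac <- keys$recurrence / nrow(drv)
  common <- keys[keys$frac > common_fraction, , drop = FALSE]
  if (nrow(common) < 2 || sum(common$recurrence) < min_occurrence) {
    return(empty)
  }
  label <- ifelse(nzchar(common$protein_change) &
                    !is.na(common$protein_change),
                  paste(common$gene, common$protein_change),
                  paste0(common$gene, ":", common$chrom, ":",
                         common$pos, common$ref, ">", common$alt))
  common$label <- make.unique(label)
  samples <- rownames(exposure)
  carriers <- matrix(FALSE, length(samples), nrow(common),
                     dimnames = list(samples, common$label))
  for (i in seq_len(nrow(common))) {
    ids <- unique(drv$sample_id[
      drv$gene == common$gene[i] & drv$chrom == common$chrom[i] &
      drv$pos == common$pos[i] & drv$ref == common$ref[i] &
      drv$alt == common$alt[i]])
    carriers[samples %in% ids, i] <- TRUE
  }
  channels <- stats::setNames(common$causal_channel, common$label)
  pairs <- utils::combn(common$label, 2, simplify = FALSE)
  rows <- lapply(seq_along(pairs), function(k) {
    pr <- pairs[[k]]
    inc <- select_comparable_samples(carriers, exposure, catalog,
                                     channels, pr[1], pr[2])
    if (nrow(inc) < 1) return(NULL)
    m1 <- sum(inc$carrier_of == 1L); m2 <- sum(inc$carrier_of == 2L)
    pval <- poibin_two_tailed_test(inc$q, m1,
                                   method = two_sided_method)
    rr <- fit_relative_risk(inc, bootstrap_iters = bootstrap_iters,
                            seed = .derive_seed(seed, paste(pr,
                                                collapse = "|")))
    data.frame(cancer_type = cancer_type, mutation_1 = pr[1],
               mutation_2 = pr[2], n_included = nrow(inc), m1 = m1,
               m2 = m2, p = pval, q = NA_real_, r_mle = rr$r,
               ci_low = rr$ci_low, ci_high = rr$ci_high,
               censored = rr$censored, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  adj <- bh_fdr(out$p, fdr)
  out$q <- adj$q
  out$significant <- adj$significant
  out <- out[order(out$q, out$p), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("selection_scan", class(out))
  out
}

#' Variance in mutation frequency explained by mutation probability
#'
#' Ordinary least squares of observed mutation frequencies (counts per
#' mutation) on their mean per-sample occurrence probabilities; returns
#' the coefficient of determination and the slope sign.
#'
#' @param frequencies numeric vector of counts, one per mutation.
#' @param mean_probabilities numeric vector of mean per-sample channel
#'   probabilities, same length (unweighted mean across the cancer
#'   type's samples).
#' @return list with `r_squared`, `slope`, `positive_correlation`,
#'   `n`, `ok` (FALSE with NA results when fewer than 3 mutations or
#'   zero variance in the probabilities).
#' @export
variance_explained <- function(frequencies, mean_probabilities) {
  stopifnot(length(frequencies) == length(mean_probabilities))
  if (length(frequencies) < 3 ||
      stats::var(mean_probabilities) == 0) {
    return(list(r_squared = NA_real_, slope = NA_real_,
                positive_correlation = NA, n = length(frequencies),
                ok = FALSE))
  }
  slope <- stats::cov(frequencies, mean_probabilities) /
    stats::var(mean_probabilities)
  r2 <- if (stats::var(frequencies) == 0) 1 else
    stats::cor(frequencies, mean_probabilities)^2
  list(r_squared = r2, slope = slope,
       positive_correlation = slope > 0,
       n = length(frequencies), ok = TRUE)
}
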