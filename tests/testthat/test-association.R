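# recurrence detection, channel enrichment, rank-sum testing, FDR,
# power simulation and the association scan

test_that("find_recurrent applies the per-type threshold", {
  mk <- function(n, pos, ct = "CT1", gene = "KRAS") {
    do.call(rbind, lapply(seq_len(n), function(i) {
      mut_row(sample_id = paste0("S", i), cancer_type = ct,
              gene = gene, pos = pos, effect = "nonsynonymous_SNV",
              protein_change = "G12C")
    }))
  }
  recs <- rbind(mk(4, 100L), mk(3, 200L))
  out <- find_recurrent(recs, min_count = 4)
  expect_equal(nrow(out), 1L)
  expect_equal(out$pos, 100L)
  expect_equal(out$recurrence, 4L)
  expect_equal(out$causal_channel, "A[C>A]A")

  # min_count 1 returns every distinct change
  expect_equal(nrow(find_recurrent(recs, min_count = 1)), 2L)

  # per-type counting: 5 in one type, 2 in the other
  recs2 <- rbind(mk(5, 300L, ct = "CT1"), mk(2, 300L, ct = "CT2"))
  out2 <- find_recurrent(recs2, min_count = 4)
  expect_equal(out2$cancer_type, "CT1")
})

test_that("enriched_signatures uses a strict above-average rule", {
  ch <- 5L
  p5 <- c(0.1, 0.3, 0.2)
  # exact unit row sums: channel 1 equal across rows, channel 5 as
  # above, the rest spread uniformly
  probs <- matrix(0, 3, 96)
  probs[, 1] <- 0.05
  probs[, ch] <- p5
  probs[, setdiff(1:96, c(1L, ch))] <- (1 - 0.05 - p5) / 94
  catalog <- sig_catalog(probs, names = c("a", "b", "c"))
  expect_equal(enriched_signatures(ch, catalog, c("a", "b")), "b")
  # all equal: none strictly above the mean
  expect_equal(enriched_signatures(1L, catalog, c("a", "b", "c")),
               character(0))
  # a single active signature cannot exceed its own mean
  expect_equal(enriched_signatures(ch, catalog, "b"), character(0))
  # weighted variant shifts the mean
  expect_equal(
    enriched_signatures(ch, catalog, c("a", "b"), weights = c(1, 0)),
    "b")
})

test_that("test_association matches the exact enumeration oracle", {
  res <- test_association(c(0.9, 0.8, 0.1, 0.2),
                          c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(res$p_value, 1 / 6, tolerance = 1e-12)
  expect_equal(res$method, "exact")

  # fully tied comparison carries no evidence
  res2 <- test_association(rep(0.3, 10), rep(c(TRUE, FALSE), 5))
  expect_equal(res2$p_value, 1)

  # label swap: p_greater + p_less - P(U = u) = 1 on the exact null
  set.seed(41)
  for (i in 1:10) {
    x <- runif(7); carriers <- rep(c(TRUE, FALSE), c(3, 4))
    pg <- test_association(x, carriers)$p_value
    pl <- test_association(x, !carriers)$p_value
    u <- test_association(x, carriers)$u
    expect_equal(pg + pl - dwilcox(u, 3, 4), 1, tolerance = 1e-12)
  }

  # one empty group: flagged no-test
  res3 <- test_association(1:3, c(TRUE, TRUE, TRUE))
  expect_false(res3$ok)
  expect_true(is.na(res3$p_value))
})

test_that("test_association type-I error is calibrated at alpha 0.05", {
  set.seed(42)
  reps <- 5000
  p <- vapply(seq_len(reps), function(i) {
    x <- rnorm(40)
    carriers <- rep(c(TRUE, FALSE), each = 20)  # no exposure effect
    test_association(x, carriers)$p_value
  }, numeric(1))
  rate <- mean(p < 0.05)
  expect_lt(abs(rate - 0.05), 0.01)
})

test_that("bh_fdr reproduces the step-up examples", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.9))$q, c(0.03, 0.03, 0.9))
  expect_equal(bh_fdr(0.04)$q, 0.04)
  expect_equal(bh_fdr(rep(0.2, 5))$q, rep(0.2, 5))
  expect_true(all(bh_fdr(c(0.01, 0.5), alpha = 0.05)$significant ==
                    c(TRUE, FALSE)))
})

test_that("estimate_power: boundary, null calibration and direction", {
  # flat catalog: every signature has the same channel probabilities,
  # so carrier selection is independent of any signature's exposure
  flat <- sig_catalog(matrix(1 / 96, 4, 96),
                      names = paste0("S", 1:4))
  set.seed(51)
  expo <- matrix(rgamma(60 * 4, 1), 60, 4,
                 dimnames = list(sprintf("s%02d", 1:60),
                                 flat$names))
  expo <- expo / rowSums(expo)

  # alpha = 1 boundary: every iteration rejects
  pw1 <- estimate_power(expo, flat, "A[C>A]A", m = 10, signature = "S1",
                        alpha = 1, iterations = 20, seed = 1)
  expect_equal(pw1$power, 1)

  # null calibration: rejection rate near alpha
  pw0 <- estimate_power(expo, flat, "A[C>A]A", m = 15,
                        signature = "S1", alpha = 0.05,
                        iterations = 500, seed = 2)
  expect_lt(abs(pw0$power - 0.05), 0.03)

  # informative catalog: signature loaded on the causal channel plus
  # heterogeneous exposures beats the flat null at the same seed
  catalog <- generate_signatures(4, concentration = 0.1, seed = 52)
  ch <- channel_label(which.max(catalog$probs["S1", ]))
  pw_alt <- estimate_power(expo, catalog, ch, m = 15,
                           signature = "S1", alpha = 0.05,
                           iterations = 500, seed = 2)
  expect_gt(pw_alt$power, pw0$power)

  # power non-decreasing in m on average (3-point grid, shared seeds)
  pws <- vapply(c(5, 15, 40), function(m) {
    estimate_power(expo, catalog, ch, m = m, signature = "S1",
                   alpha = 0.05, iterations = 300, seed = 3)$power
  }, numeric(1))
  expect_true(all(diff(pws) >= -0.05))
})

test_that("association scan counts tests as sum of enriched signatures", {
  pa <- planted_association_cohort(n_samples = 120, seed = 61)
  records <- pa$cohort$records
  active <- list(SYNTH = pa$catalog$names)
  scan <- run_association_scan(
    records, c("KRAS", "TP53"), pa$catalog, active,
    min_recurrence = 4, min_mutations = 20)
  recur <- find_recurrent(
    filter_driver_nonsynonymous(records, c("KRAS", "TP53")),
    min_count = 4)
  expected_n <- sum(vapply(recur$causal_channel, function(ch) {
    length(enriched_signatures(ch, pa$catalog, pa$catalog$names))
  }, numeric(1)))
  expect_equal(nrow(scan), expected_n)
  expect_true(all(scan$q >= scan$p, na.rm = TRUE))

  # unrestricted scan tests every active signature per mutation
  scan_all <- run_association_scan(
    records, c("KRAS", "TP53"), pa$catalog, active,
    min_recurrence = 4, min_mutations = 20,
    restrict_to_enriched = FALSE)
  expect_equal(nrow(scan_all),
               nrow(recur) * length(pa$catalog$names))
  expect_s3_class(enrichment_contrast(scan_all), "htest")
})

test_that("planted association is recovered; single-signature edge case", {
  pa <- planted_association_cohort(n_samples = 300, seed = 62)
  scan <- run_association_scan(
    pa$cohort$records, c("KRAS", "TP53"), pa$catalog,
    list(SYNTH = pa$catalog$names))
  hit <- scan[scan$gene == "KRAS" & scan$signature == "S1", ]
  expect_equal(nrow(hit), 1L)
  expect_true(hit$significant)
  expect_equal(hit$direction, "carrier_higher")

  # one active signature: restricted scan has zero tests
  scan1 <- run_association_scan(
    pa$cohort$records, c("KRAS", "TP53"), pa$catalog,
    list(SYNTH = "S1"))
  expect_equal(nrow(scan1), 0L)
})
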