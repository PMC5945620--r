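# initiation model, channel probabilities, Poisson binomial test,
# relative-risk MLE, comparable-sample selection, variance explained

test_that("expected_incidence matches the closed form", {
  m1 <- cancer_initiation_model(list(0.01), lambda = 0.1)
  expect_equal(expected_incidence(m1, 10), 0.01)
  # two identical sequences double the incidence (linearity in j)
  m2 <- cancer_initiation_model(list(0.01, 0.01), lambda = c(0.1, 0.1))
  expect_equal(expected_incidence(m2, 10), 0.02)
  expect_equal(expected_incidence(m2, 0), 0)
  # n = 3 sequence: u1 u2 u3 lambda t^3 / 3!
  m3 <- cancer_initiation_model(list(c(1e-3, 2e-3, 5e-4)),
                                lambda = 0.05)
  expect_equal(expected_incidence(m3, 20),
               1e-3 * 2e-3 * 5e-4 * 0.05 * 20^3 / 6)
  expect_error(cancer_initiation_model(list(-0.1), 0.1), "positive")
})

test_that("conditional_probability follows u1 r / (u1 r + u2)", {
  expect_equal(conditional_probability(2e-6, 2e-6, 1), 0.5)
  expect_equal(conditional_probability(1e-6, 3e-6, 3), 0.5)
  expect_equal(conditional_probability(1e-6, 1e-6, 1e12), 1,
               tolerance = 1e-9)
  # strictly increasing in r
  rs <- c(0.1, 1, 10, 100)
  expect_true(all(diff(conditional_probability(1e-6, 2e-6, rs)) > 0))
  expect_error(conditional_probability(1e-6, 1e-6, 0), "positive")
})

test_that("channel_probability is the exposure-weighted mixture", {
  probs <- matrix(1 / 96, 2, 96)
  probs[1, 5] <- 0.1; probs[2, 5] <- 0.3
  probs <- probs / rowSums(probs)
  catalog <- sig_catalog(probs, names = c("a", "b"))
  # single active signature returns its own channel probability
  e1 <- c(a = 1, b = 0)
  expect_equal(channel_probability(e1, catalog, 5L),
               unname(catalog$probs[1, 5]))
  # uniform mixture of renormalised rows
  e <- c(a = 0.5, b = 0.5)
  expect_equal(channel_probability(e, catalog, 5L),
               unname(mean(catalog$probs[, 5])))
  # the 96 values sum to 1
  expect_equal(sum(channel_probability(e, catalog, 1:96)), 1,
               tolerance = 1e-9)
  expect_error(channel_probability(c(a = 0.5, b = 0.2), catalog, 5L),
               "normalised")
})

test_that("poibin_pmf matches enumeration and handles point masses", {
  expect_equal(poibin_pmf(c(0.5, 0.5)), c(0.25, 0.5, 0.25))
  expect_equal(poibin_pmf(c(1, 1)), c(0, 0, 1))
  expect_equal(poibin_pmf(c(0.2, 0.7)), c(0.24, 0.62, 0.14))
  set.seed(71)
  for (i in 1:8) {
    q <- runif(sample(1:10, 1))
    expect_equal(poibin_pmf(q), poibin_bruteforce(q),
                 tolerance = 1e-12)
    expect_equal(sum(poibin_pmf(q)), 1, tolerance = 1e-12)
  }
})

test_that("poibin two-tailed test follows the minimum-likelihood rule", {
  expect_equal(poibin_two_tailed_test(c(0.5, 0.5), 2), 0.5)
  expect_equal(poibin_two_tailed_test(c(0.5, 0.5), 1), 1)
  # p is bounded below by the observed outcome's probability
  set.seed(72)
  for (i in 1:10) {
    q <- runif(8)
    m1 <- sample(0:8, 1)
    p <- poibin_two_tailed_test(q, m1)
    expect_gte(p, poibin_pmf(q)[m1 + 1])
    expect_lte(p, 1)
  }
  # doubled-tail variant stays a valid p-value
  expect_lte(poibin_two_tailed_test(c(0.2, 0.7, 0.4), 3,
                                    method = "double"), 1)
})

test_that("select_comparable_samples applies the exactly-one rule", {
  catalog <- disjoint_catalog()
  expo <- matrix(c(1, 0,
                   0, 1,
                   0.5, 0.5,
                   0.25, 0.75), 4, 2, byrow = TRUE,
                 dimnames = list(paste0("s", 1:4), catalog$names))
  carriers <- matrix(FALSE, 4, 3,
                     dimnames = list(paste0("s", 1:4),
                                     c("M1", "M2", "M3")))
  carriers["s1", c("M1", "M2")] <- TRUE   # both: excluded
  carriers["s2", c("M1", "M3")] <- TRUE   # other set member: excluded
  carriers["s3", "M1"] <- TRUE            # included, carrier of 1
  carriers["s4", "M2"] <- TRUE            # included, carrier of 2
  ch <- c(M1 = "A[C>A]A", M2 = "A[T>A]A", M3 = "C[C>G]G")
  out <- select_comparable_samples(carriers, expo, catalog, ch,
                                   "M1", "M2")
  expect_equal(out$sample_id, c("s3", "s4"))
  expect_equal(out$carrier_of, c(1L, 2L))
  # q = p1 / (p1 + p2) with p from the exposure mixture
  p1 <- 0.5 / 48; p2 <- 0.5 / 48
  expect_equal(out$q[1], p1 / (p1 + p2))
  p1b <- 0.25 / 48; p2b <- 0.75 / 48
  expect_equal(out$q[2], p1b / (p1b + p2b))
})

test_that("fit_relative_risk matches the grid-search oracle", {
  # symmetry: one carrier each with equal probabilities
  rr1 <- fit_relative_risk(p1 = c(0.1, 0.1), p2 = c(0.1, 0.1),
                           is_m1 = c(TRUE, FALSE),
                           bootstrap_iters = 0)
  expect_equal(rr1$r, 1, tolerance = 1e-4)
  # 2 vs 1 with equal probabilities: q = r/(1+r), max of q^2(1-q) at 2/3
  rr2 <- fit_relative_risk(p1 = rep(0.2, 3), p2 = rep(0.2, 3),
                           is_m1 = c(TRUE, TRUE, FALSE),
                           bootstrap_iters = 0)
  expect_equal(rr2$r, 2, tolerance = 1e-4)
  # random instance against the independent grid oracle
  set.seed(81)
  p1 <- runif(40, 0.01, 0.2); p2 <- runif(40, 0.01, 0.2)
  is_m1 <- runif(40) < 0.6
  rr3 <- fit_relative_risk(p1 = p1, p2 = p2, is_m1 = is_m1,
                           bootstrap_iters = 50, seed = 9)
  expect_equal(log(rr3$r), log(rr_grid_oracle(p1, p2, is_m1)),
               tolerance = 2e-3)
  expect_length(rr3$boot, 50)
  expect_lte(rr3$ci_low, rr3$ci_high)
  # boundary cases are censored, never reported as finite estimates
  up <- fit_relative_risk(p1 = rep(0.1, 3), p2 = rep(0.1, 3),
                          is_m1 = rep(TRUE, 3))
  expect_equal(up$censored, "upper")
  expect_equal(up$r, Inf)
  expect_equal(up$ci_high, Inf)
  lo <- fit_relative_risk(p1 = rep(0.1, 3), p2 = rep(0.1, 3),
                          is_m1 = rep(FALSE, 3))
  expect_equal(lo$censored, "lower")
  expect_equal(lo$r, 0)
})

test_that("relative-risk bias shrinks as samples grow", {
  catalog <- generate_signatures(4, concentration = 0.2, seed = 82)
  ch1 <- which.max(catalog$probs["S1", ])
  ch2 <- which.max(catalog$probs["S2", ])
  r_true <- 2
  # shared randomness across n: each replicate draws one n = 800
  # dataset and the smaller sample sizes reuse its leading rows
  set.seed(83)
  est <- replicate(16, {
    n <- 800
    expo <- matrix(rgamma(n * 4, 0.5), n, 4,
                   dimnames = list(NULL, catalog$names))
    expo <- expo / rowSums(expo)
    p1 <- as.numeric(channel_probability(expo, catalog, ch1))
    p2 <- as.numeric(channel_probability(expo, catalog, ch2))
    q <- r_true * p1 / (r_true * p1 + p2)
    is_m1 <- runif(n) < q
    vapply(c(50, 200, 800), function(m) {
      log(fit_relative_risk(p1 = p1[1:m], p2 = p2[1:m],
                            is_m1 = is_m1[1:m],
                            bootstrap_iters = 0)$r)
    }, numeric(1))
  })
  bias <- abs(rowMeans(est) - log(r_true))
  expect_lt(bias[3], bias[1])
  expect_lt(bias[3], 0.15)
})

test_that("pairwise_selection_scan thresholds and planted-risk recovery", {
  catalog <- generate_signatures(4, concentration = 0.2, seed = 91)
  ch <- channel_label(order(colMeans(catalog$probs),
                            decreasing = TRUE)[1:2])
  drivers <- data.frame(
    label = c("A", "B"), gene = c("KRAS", "KRAS"),
    protein_change = c("G12C", "G12D"), channel = ch,
    r = c(4, 1), stringsAsFactors = FALSE)
  spec <- cohort_spec(250, catalog, burden = 150,
                      driver_set = drivers, seed = 92)
  cohort <- plant_drivers(spec, generate_cohort(spec))
  counts <- count_channels(
    cohort$records,
    exclude = filter_driver_nonsynonymous(cohort$records, "KRAS"))
  fit <- fit_exposures(counts, catalog)
  expo <- fit$exposure
  rownames(expo) <- fit$sample_ids
  scan <- pairwise_selection_scan(cohort$records, "KRAS", "SYNTH",
                                  expo, catalog, seed = 93)
  expect_equal(nrow(scan), 1L)
  lab_a <- scan$mutation_1 == "KRAS G12C"
  r_hat <- if (lab_a) scan$r_mle else 1 / scan$r_mle
  expect_lt(abs(log(r_hat) - log(4)), log(1.6))
  expect_true(scan$m1 + scan$m2 == scan$n_included)

  # a mutation below min_occurrence is excluded from the scan
  scan2 <- pairwise_selection_scan(cohort$records, "KRAS", "SYNTH",
                                   expo, catalog,
                                   min_occurrence = 10000L)
  expect_equal(nrow(scan2), 0L)
})

test_that("variance_explained matches the hand OLS oracle", {
  # exact proportionality
  expect_equal(variance_explained(c(2, 4, 6), c(0.1, 0.2, 0.3))$r_squared,
               1)
  # hand-computed: x = (1,2,3), y = (10,20,25) -> R^2 = 225/233.333
  out <- variance_explained(c(10, 20, 25), c(1, 2, 3))
  expect_equal(out$r_squared, 225 / (2 * 116.66667), tolerance = 1e-5)
  expect_true(out$positive_correlation)
  # degenerate: no variance in probabilities
  expect_false(variance_explained(c(1, 2, 3), c(0.1, 0.1, 0.1))$ok)
  expect_false(variance_explained(c(1, 2), c(0.1, 0.2))$ok)
})
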