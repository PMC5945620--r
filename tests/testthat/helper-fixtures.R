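# Shared fixtures and independent oracles, built in code at test time.

# two signatures with disjoint channel supports (NNLS decouples exactly)
disjoint_catalog <- function() {
  probs <- rbind(S1 = c(rep(1 / 48, 48), rep(0, 48)),
                 S2 = c(rep(0, 48), rep(1 / 48, 48)))
  sig_catalog(probs)
}

# write a mutation record data.frame to a temp generic-dialect TSV
tmp_mutation_file <- function(df) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  cols <- c("sample_id", "cancer_type", "chrom", "pos", "ref", "alt",
            "context", "gene", "effect", "variant_class_label",
            "protein_change")
  for (c in setdiff(cols, names(df))) df[[c]] <- ""
  write.table(df[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  path
}

# one valid generic mutation row, overridable field by field
mut_row <- function(...) {
  base <- list(sample_id = "S1", cancer_type = "CT", chrom = "1",
               pos = 100L, ref = "C", alt = "A", context = "ACA",
               gene = "", effect = "other",
               variant_class_label = "SNP", protein_change = "")
  over <- list(...)
  base[names(over)] <- over
  as.data.frame(base, stringsAsFactors = FALSE)
}

# independent Poisson binomial oracle: brute-force enumeration of all
# 2^n outcomes (n <= ~16)
poibin_bruteforce <- function(q) {
  n <- length(q)
  outcomes <- as.matrix(expand.grid(rep(list(0:1), n)))
  probs <- apply(outcomes, 1, function(o) prod(ifelse(o == 1, q, 1 - q)))
  pmf <- numeric(n + 1)
  for (k in 0:n) pmf[k + 1] <- sum(probs[rowSums(outcomes) == k])
  pmf
}

# independent relative-risk oracle: dense grid search on log r
rr_grid_oracle <- function(p1, p2, is_m1, lo = -8, hi = 8, by = 1e-3) {
  grid <- seq(lo, hi, by = by)
  ll <- vapply(grid, function(lr) {
    q <- exp(lr) * p1 / (exp(lr) * p1 + p2)
    sum(log(q[is_m1])) + sum(log(1 - q[!is_m1]))
  }, numeric(1))
  exp(grid[which.max(ll)])
}

# passenger cohort plus one planted driver whose m carriers are drawn
# without replacement from high-exposure samples: selection probability
# proportional to the true exposure of S1, the signature most loaded on
# the driver's causal channel
planted_signature_cohort <- function(n_samples = 300, m = 40,
                                     seed = 1) {
  catalog <- generate_signatures(5, concentration = 0.2, seed = 99)
  ch <- channel_label(which.max(catalog$probs["S1", ]))
  spec <- cohort_spec(n_samples, catalog,
                      burden = list(mean = 200, dispersion = 2),
                      exposure_prior = setNames(rep(0.5, 5),
                                                catalog$names),
                      seed = seed)
  cohort <- generate_cohort(spec)
  set.seed(seed + 7)
  carriers <- sample(cohort$truth$sample_ids, m,
                     prob = cohort$truth$exposures[, "S1"])
  cf <- channel_fields(ch)
  driver <- data.frame(sample_id = carriers, cancer_type = "SYNTH",
                       chrom = "1", pos = 10000001L, ref = cf$ref,
                       alt = cf$alt, context = cf$trinucleotide,
                       gene = "KRAS", effect = "nonsynonymous_SNV",
                       variant_class_label = "SNP",
                       protein_change = "G12C",
                       stringsAsFactors = FALSE)
  cohort$records <- rbind(cohort$records, driver)
  list(cohort = cohort, catalog = catalog, channel = ch,
       carriers = carriers)
}

# cohort with one signature sharply enriched for a planted driver's
# causal channel; used by association recovery tests
planted_association_cohort <- function(n_samples = 300, seed = 1) {
  catalog <- generate_signatures(5, concentration = 0.2, seed = 99)
  ch_a <- channel_label(which.max(catalog$probs["S1", ]))
  ch_b <- channel_label(which.max(catalog$probs["S2", ]))
  drivers <- data.frame(
    label = c("A", "B"), gene = c("KRAS", "TP53"),
    protein_change = c("G12C", "R175H"), channel = c(ch_a, ch_b),
    r = c(1, 1), stringsAsFactors = FALSE)
  spec <- cohort_spec(n_samples, catalog,
                      burden = list(mean = 200, dispersion = 2),
                      exposure_prior = setNames(rep(0.5, 5),
                                                catalog$names),
                      driver_set = drivers, seed = seed)
  cohort <- plant_drivers(spec, generate_cohort(spec))
  list(cohort = cohort, catalog = catalog, spec = spec,
       channels = c(A = ch_a, B = ch_b))
}
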