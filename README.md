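# sigselect

Joint analysis of **mutation** and **selection** in cancer cohorts.

The driver mutations found in a tumour reflect two forces: mutagenic
processes (smoking, APOBEC, mismatch-repair failure, ageing, ...) bias
*which* DNA changes arise, and selection decides which of them expand.
sigselect is for cancer genomicists who want to separate the two in a
cohort of somatic SNV calls:

1. **Exposures.** Each SNV is classified into one of the 96
   trinucleotide channels (pyrimidine-strand convention) and each
   sample's channel counts are decomposed over a signature catalog by
   non-negative least squares, giving per-sample signature exposures
   `e` with `Σ_k e_k = 1`.
2. **Mutation–process associations.** For each recurrent driver
   mutation, signatures enriched for its causal channel are tested for
   higher exposure in carriers vs non-carriers (one-sided Mann–Whitney
   U, Benjamini–Hochberg FDR), with simulation-based power estimates.
3. **Differential selection.** For two alternative driver mutations
   with per-sample causal-channel probabilities `p_i1, p_i2`, the
   carrier count of the first is modelled as `X ~ Poibin(q)` with
   `q_i = p_i1 / (p_i1 + p_i2)` under neutrality; an exact two-sided
   Poisson binomial test detects departures, and the relative risk
   `r` in `q_i(r) = r·p_i1 / (r·p_i1 + p_i2)` is estimated by maximum
   likelihood with bootstrap confidence intervals. Under the
   multistage initiation model, `r` is the factor by which swapping
   the two mutations multiplies the cancer rate.
4. **Synthetic cohorts.** A first-class generator (Dirichlet
   exposures, multinomial channel counts, drivers planted with known
   relative risks) provides ground truth for every stage.

## Worked example

Simulate a 300-sample cohort with two KRAS hotspot mutations planted
at relative risk 3, then recover the selection signal:

```r
library(sigselect)

catalog <- generate_signatures(5, concentration = 0.2, seed = 42)
drivers <- data.frame(
  label = c("A", "B"), gene = c("KRAS", "KRAS"),
  protein_change = c("G12C", "G12D"),
  channel = channel_label(order(colMeans(catalog$probs),
                                decreasing = TRUE)[1:2]),
  r = c(3, 1))                    # G12C three-fold more selected
spec <- cohort_spec(300, catalog, burden = 150, driver_set = drivers,
                    seed = 42)
cohort <- plant_drivers(spec, generate_cohort(spec))

counts <- count_channels(cohort$records,
  exclude = filter_driver_nonsynonymous(cohort$records, "KRAS"))
fit <- fit_exposures(counts, catalog)
expo <- fit$exposure; rownames(expo) <- fit$sample_ids

pairwise_selection_scan(cohort$records, "KRAS", "SYNTH", expo,
                        catalog, seed = 42)
#>   mutation_1 mutation_2 n_included  m1 m2            p    r_mle   ci_low  ci_high
#> 1  KRAS G12C  KRAS G12D        300 227 73 9.491425e-16 3.057742 2.339964 4.179189
```

227 of 300 informative samples carry G12C where the neutral Poisson
binomial expectation (driven only by each sample's mutational-process
exposures) would split the pair roughly evenly — the two-tailed
p = 9.5e-16 rejects neutrality, and the MLE relative risk 3.06
(95% bootstrap CI 2.34–4.18) recovers the planted value of 3.

The association scan on the same cohort links each planted mutation to
the signature loaded on its causal channel:

```r
run_association_scan(cohort$records, "KRAS", catalog,
                     list(SYNTH = catalog$names))
#>   gene protein_change causal_channel signature n_carriers            p            q significant
#> 1 KRAS           G12C        A[T>C]C        S4        227 4.442183e-06 7.252453e-06        TRUE
#> 2 KRAS           G12D        T[T>G]G        S2         73 4.834968e-06 7.252453e-06        TRUE
#> 3 KRAS           G12D        T[T>G]G        S4         73 9.999956e-01 9.999956e-01       FALSE
```

Carriers of each mutation have significantly higher exposure of the
signature that generates its causal channel (q < 1e-5); the third test
(G12D against the *other* mutation's signature) is correctly null.

## Command line

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","sigselect.R",package="sigselect"))')" \
    simulate --n-samples 200 --signatures 5 --seed 7 --out sim/
# further subcommands: exposures, associate, power, select, calibrate
```

Pipelines are configuration-driven (`run_pipeline()`, JSON config);
identical config and seed give byte-identical output tables.

## File formats

* Mutation tables: tab-separated, generic dialect columns
  `sample_id, cancer_type, chrom, pos, ref, alt, context, gene,
  effect, variant_class_label, protein_change` (1-based positions);
  TCGA-MAF and ICGC simple-somatic-mutation subsets supported via
  `dialect=`/`column_map=`.
* Signature catalogs: TSV, first column `A[C>A]A`-style channel
  labels in canonical COSMIC order, one column per signature.
* Driver gene list: one symbol per line
  (`inst/extdata/driver_genes.txt` ships an editable default).
* Genome/exome trinucleotide frequencies:
  `inst/extdata/trinucleotide_freqs_synthetic.tsv` (synthetic
  approximation — replace with real counts for production use).
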