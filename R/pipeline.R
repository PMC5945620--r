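# Configuration-driven pipeline orchestration. All randomness flows
# from the config seed through named substreams (one per stage);
# identical config + seed gives byte-identical output tables.

#' Read a pipeline run configuration
#'
#' The configuration is a JSON file with nested sections:
#' `paths` (mutations, signatures, driver_genes, active_signatures,
#' out_dir), `thresholds` (min_mutations = 20, min_recurrence = 4,
#' fdr = 0.05, min_occurrence = 10, common_fraction = 0.01), `seed`,
#' and `flags` (restrict_to_enriched = TRUE, two_sided_method =
#' "minlik", per_type_fdr = FALSE). Missing thresholds/flags take the
#' defaults above.
#'
#' @param path JSON config file.
#' @return object of class `run_config` (validated nested list).
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  defaults <- list(
    thresholds = list(min_mutations = 20L, min_recurrence = 4L,
                      fdr = 0.05, min_occurrence = 10L,
                      common_fraction = 0.01),
    flags = list(restrict_to_enriched = TRUE,
                 two_sided_method = "minlik", per_type_fdr = FALSE),
    seed = 1L)
  for (sec in names(defaults)) {
    if (is.list(defaults[[sec]])) {
      for (k in names(defaults[[sec]])) {
        if (is.null(cfg[[sec]][[k]])) cfg[[sec]][[k]] <-
            defaults[[sec]][[k]]
      }
    } else if (is.null(cfg[[sec]])) cfg[[sec]] <- defaults[[sec]]
  }
  th <- cfg$thresholds
  if (any(unlist(th) <= 0)) stop("thresholds must be positive")
  structure(cfg, class = "run_config")
}

.stage_outputs <- c(exposures = "exposures.tsv",
                    associate = "association.tsv",
                    power = "power.tsv",
                    select = "selection.tsv")

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order (`associate`,
#' `power` and `select` require `exposures`), writing one TSV per stage
#' plus a JSON run manifest (inputs, package version, seeds, row
#' counts, wall time) into the configured output directory.
#'
#' @param config a `run_config` ([read_run_config()]) or path to one.
#' @param stages subset of `c("exposures", "associate", "power",
#'   "select")`.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config,
                         stages = c("exposures", "associate")) {
  if (is.character(config)) config <- read_run_config(config)
  stages <- match.arg(stages, names(.stage_outputs),
                      several.ok = TRUE)
  out_dir <- config$paths$out_dir
  if (is.null(out_dir)) stop("config$paths$out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  needs_expo <- intersect(stages, c("associate", "power", "select"))
  if (length(needs_expo) &&
      !("exposures" %in% stages ||
        file.exists(file.path(out_dir, "exposures.tsv")))) {
    stop("stage '", needs_expo[1],
         "' requires the 'exposures' stage to run first")
  }
  t0 <- Sys.time()
  th <- config$thresholds
  records <- read_mutations(config$paths$mutations, dialect = "generic")
  catalog <- read_signature_catalog(config$paths$signatures)
  driver_genes <- read_driver_genes(config$paths$driver_genes)
  active_by_type <- if (!is.null(config$paths$active_signatures)) {
    read_active_signatures(config$paths$active_signatures)
  } else {
    types <- unique(records$cancer_type)
    stats::setNames(rep(list(catalog$names), length(types)), types)
  }
  drivers <- filter_driver_nonsynonymous(records, driver_genes)
  manifest <- list(
    package = "sigselect",
    version = as.character(utils::packageVersion("sigselect")),
    seed = config$seed, inputs = config$paths,
    thresholds = th, flags = config$flags, stages = stages,
    n_records = nrow(records), n_driver_records = nrow(drivers),
    rows = list())

  fits <- list()
  expo_rows <- list()
  for (ct in names(active_by_type)) {
    rec_ct <- records[records$cancer_type == ct, , drop = FALSE]
    if (nrow(rec_ct) == 0) next
    drv_ct <- drivers[drivers$cancer_type == ct, , drop = FALSE]
    counts <- count_channels(rec_ct, exclude = drv_ct)
    fit <- fit_exposures(counts, catalog, active_by_type[[ct]])
    fits[[ct]] <- fit
    expo_rows[[ct]] <- exposure_table(fit, cancer_type = ct,
                                      min_mutations = th$min_mutations)
  }
  if ("exposures" %in% stages) {
    tab <- do.call(rbind, expo_rows)
    data.table::fwrite(tab, file.path(out_dir, "exposures.tsv"),
                       sep = "\t")
    manifest$rows$exposures <- nrow(tab)
    message(sprintf("exposures: %d sample(s), %d below cutoff",
                    nrow(tab), sum(tab$below_cutoff)))
  }

  scan <- NULL
  if (any(c("associate", "power") %in% stages)) {
    scan <- run_association_scan(
      records, driver_genes, catalog, active_by_type,
      min_recurrence = th$min_recurrence,
      min_mutations = th$min_mutations, alpha = th$fdr,
      restrict_to_enriched = isTRUE(config$flags$restrict_to_enriched),
      per_type_fdr = isTRUE(config$flags$per_type_fdr))
  }
  if ("associate" %in% stages) {
    data.table::fwrite(scan, file.path(out_dir, "association.tsv"),
                       sep = "\t")
    manifest$rows$associate <- nrow(scan)
    message(sprintf("associate: %d test(s), %d significant at FDR %g",
                    nrow(scan), sum(scan$significant), th$fdr))
  }
  if ("power" %in% stages) {
    pw <- .power_stage(scan, fits, catalog, config)
    data.table::fwrite(pw, file.path(out_dir, "power.tsv"), sep = "\t")
    manifest$rows$power <- nrow(pw)
  }
  if ("select" %in% stages) {
    sel_rows <- list()
    sel_cfg <- config$selection
    genes <- if (!is.null(sel_cfg$genes)) sel_cfg$genes else
      driver_genes
    for (ct in names(fits)) {
      fit <- fits[[ct]]
      keep <- fit$total >= th$min_mutations & !fit$flagged
      expo <- fit$exposure[keep, , drop = FALSE]
      rownames(expo) <- fit$sample_ids[keep]
      res <- pairwise_selection_scan(
        records, genes, ct, expo, catalog,
        common_fraction = th$common_fraction,
        min_occurrence = th$min_occurrence, fdr = th$fdr,
        seed = .derive_seed(config$seed, paste0("select:", ct)),
        two_sided_method = config$flags$two_sided_method)
      if (nrow(res)) sel_rows[[ct]] <- res
    }
    sel <- if (length(sel_rows)) do.call(rbind, sel_rows) else
      pairwise_selection_scan(records[0, ], character(0), "none",
                              matrix(numeric(0), 0, 0), catalog)
    data.table::fwrite(sel, file.path(out_dir, "selection.tsv"),
                       sep = "\t")
    manifest$rows$select <- nrow(sel)
    message(sprintf("select: %d pair(s) tested", nrow(sel)))
  }
  manifest$wall_time_s <-
    as.numeric(difftime(Sys.time(), t0, units = "secs"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

# power estimates for every tested association, at the configured
# iteration budget
.power_stage <- function(scan, fits, catalog, config) {
  iters <- config$power$iterations
  if (is.null(iters)) iters <- 200L
  rows <- lapply(seq_len(nrow(scan)), function(i) {
    row <- scan[i, ]
    fit <- fits[[row$cancer_type]]
    keep <- fit$total >= config$thresholds$min_mutations &
      !fit$flagged
    expo <- fit$exposure[keep, , drop = FALSE]
    pw <- estimate_power(
      expo, catalog, row$causal_channel, m = row$recurrence,
      signature = row$signature, alpha = config$thresholds$fdr,
      iterations = iters,
      seed = .derive_seed(config$seed, paste0("power:", i)))
    data.frame(cancer_type = row$cancer_type, gene = row$gene,
               protein_change = row$protein_change,
               causal_channel = row$causal_channel,
               signature = row$signature, m = row$recurrence,
               alpha = config$thresholds$fdr, n_set = pw$n_set,
               iterations = iters, power = pw$power,
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0) {
    return(data.frame(cancer_type = character(), gene = character(),
                      protein_change = character(),
                      causal_channel = character(),
                      signature = character(), m = integer(),
                      alpha = numeric(), n_set = integer(),
                      iterations = integer(), power = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Write a synthetic cohort to disk
#'
#' Materialises a simulated cohort (and its ground truth) as the
#' plain-text artifacts the `simulate` CLI subcommand produces:
#' `mutations.tsv`, `truth_exposures.tsv`, `truth_drivers.tsv` and
#' `signatures.tsv`.
#'
#' @param spec a [cohort_spec()].
#' @param out_dir output directory (created if needed).
#' @return the cohort list, invisibly.
#' @export
simulate_to_dir <- function(spec, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(spec)
  if (!is.null(spec$driver_set)) cohort <- plant_drivers(spec, cohort)
  write_mutations(cohort$records, file.path(out_dir, "mutations.tsv"))
  truth <- data.frame(sample_id = cohort$truth$sample_ids,
                      cohort$truth$exposures, check.names = FALSE,
                      stringsAsFactors = FALSE)
  data.table::fwrite(truth, file.path(out_dir, "truth_exposures.tsv"),
                     sep = "\t")
  drv <- if (!is.null(cohort$truth$drivers)) cohort$truth$drivers else
    data.frame(sample_id = character(), label = character())
  data.table::fwrite(drv, file.path(out_dir, "truth_drivers.tsv"),
                     sep = "\t")
  write_signature_catalog(spec$catalog,
                          file.path(out_dir, "signatures.tsv"))
  invisible(cohort)
}
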