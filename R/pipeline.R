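#' Pipeline configuration
#'
#' Either all four input paths (`otu_table`, `tree`, `ffq`, `metadata`) or
#' a synthetic-cohort spec (`synthetic = TRUE`, with generator arguments in
#' `synthetic_args`) must be given. Thresholds, cluster counts,
#' permutation counts and seeds are recorded in the run manifest so a run
#' can be reproduced exactly.
#'
#' @param otu_table,tree,ffq,metadata input file paths (TSV / newick /
#'   CSV / CSV), or all `NULL` when `synthetic = TRUE`.
#' @param synthetic generate the inputs with [generate_cohort]?
#' @param synthetic_args list of arguments for [synthetic_config].
#' @param outdir output directory.
#' @param prevalence_min,min_abundance,fdr thresholds.
#' @param k_states,m_diet cluster counts or `"auto"`.
#' @param permutations permutation count for all permutation tests.
#' @param bootstrap_resamples resamples for median-regression inference.
#' @param seed master seed.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(otu_table = NULL, tree = NULL, ffq = NULL,
                            metadata = NULL, synthetic = is.null(otu_table),
                            synthetic_args = list(), outdir = "microstrat_out",
                            prevalence_min = 0.20, min_abundance = 0.001,
                            fdr = 0.05, k_states = "auto", m_diet = "auto",
                            permutations = 999, bootstrap_resamples = 2000,
                            seed = 1L) {
  paths <- list(otu_table = otu_table, tree = tree, ffq = ffq,
                metadata = metadata)
  have_paths <- !vapply(paths, is.null, logical(1))
  if (!synthetic) {
    if (!all(have_paths))
      stop_invalid("missing input paths: ",
                   paste(names(paths)[!have_paths], collapse = ", "),
                   " (or set synthetic = TRUE)")
    missing_files <- unlist(paths)[!file.exists(unlist(paths))]
    if (length(missing_files))
      stop_invalid("input files not found: ",
                   paste(missing_files, collapse = ", "))
  }
  structure(list(paths = paths, synthetic = synthetic,
                 synthetic_args = synthetic_args, outdir = outdir,
                 prevalence_min = prevalence_min,
                 min_abundance = min_abundance, fdr = fdr,
                 k_states = k_states, m_diet = m_diet,
                 permutations = permutations,
                 bootstrap_resamples = bootstrap_resamples,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file whose keys match the [pipeline_config] arguments.
#' @param ... overrides.
#' @export
read_pipeline_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  vals[names(list(...))] <- list(...)
  do.call(pipeline_config, vals)
}

stage <- function(report, name, expr) {
  t0 <- proc.time()[["elapsed"]]
  result <- tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  message(sprintf("[%s] done in %.1fs", name, proc.time()[["elapsed"]] - t0))
  result
}

#' Run the full stratification pipeline
#'
#' Executes load (or synthesis), normalization and genus aggregation,
#' alpha diversity, UniFrac, PCoA, steady-state identification with
#' verification, CAG detection and Wiggum over-abundance, FFQ-based diet
#' grouping (correspondence analysis), HFD and macronutrient summaries,
#' food vector fitting onto the microbiota ordination, age-adjusted median
#' regressions of the clinical markers on the leading PCoA axes, group
#' tests of genus abundances across steady states, and enrichment of the
#' lowest-diversity-state by least-diverse-diet combination in the obese
#' phenotype. Every intermediate is written to `config$outdir` with a
#' provenance header (config hash + seed).
#'
#' @param config a [pipeline_config].
#' @return a `run_report` list (also written as `report.json` /
#'   `report.md`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  # provenance: hash of the config echo; stamped into every output header
  config_path <- file.path(config$outdir, "config.yaml")
  yaml::write_yaml(config_echo(config), config_path)
  # hash the config without the output location, so identical analyses in
  # different directories share provenance
  canon <- tempfile(fileext = ".yaml")
  echo <- config_echo(config); echo$outdir <- NULL
  yaml::write_yaml(echo, canon)
  hash <- unname(tools::md5sum(canon))
  unlink(canon)
  prov <- c(paste0("config: ", hash), paste0("seed: ", config$seed))
  warnings_seen <- character()
  withCallingHandlers({
  inputs <- stage(NULL, "load", load_inputs(config))
  otus <- inputs$otu_table; tree <- inputs$tree
  ffq <- inputs$ffq; metadata <- inputs$metadata

  rel <- stage(NULL, "normalize", relative_abundance(otus))
  genus <- aggregate_taxonomy(otus, "genus")

  alpha <- stage(NULL, "alpha_diversity", data.frame(
    sample = sample_ids(otus),
    shannon = alpha_diversity(otus, "shannon"),
    observed = alpha_diversity(otus, "observed"),
    faith_pd = alpha_diversity(otus, "faith_pd", tree = tree)))
  write_labels_csv(alpha, file.path(config$outdir, "alpha_diversity.csv"),
                   comment = prov)

  uf_u <- stage(NULL, "unifrac_unweighted", unifrac(otus, tree, "unweighted"))
  uf_w <- stage(NULL, "unifrac_weighted",
                unifrac(otus, tree, "weighted_normalized"))
  write_distance_tsv(uf_u, file.path(config$outdir, "unweighted_unifrac.tsv"),
                     comment = prov)
  write_distance_tsv(uf_w, file.path(config$outdir, "weighted_unifrac.tsv"),
                     comment = prov)

  ord_u <- stage(NULL, "pcoa", pcoa(uf_u))
  ord_w <- pcoa(uf_w)
  write_ordination_tsv(ord_u, file.path(config$outdir, "pcoa_unweighted.tsv"),
                       comment = prov)
  write_ordination_tsv(ord_w, file.path(config$outdir, "pcoa_weighted.tsv"),
                       comment = prov)

  states <- stage(NULL, "steady_states", identify_steady_states(
    otus, prevalence_min = config$prevalence_min, k = config$k_states,
    permutations = config$permutations, seed = config$seed))
  cags <- stage(NULL, "cags", identify_cags(
    otus, min_abundance = config$min_abundance, fdr = config$fdr))
  wiggum <- wiggum_overabundance(otus, states, cags)
  write_edges_tsv(cags$edges, file.path(config$outdir, "cag_edges.tsv"),
                  comment = prov)
  write_labels_csv(wiggum$ratios, file.path(config$outdir, "wiggum.csv"),
                   comment = prov)

  diets <- stage(NULL, "diet_groups", identify_diet_groups(ffq, m = config$m_diet))
  write_ordination_tsv(diets$ca, file.path(config$outdir, "ffq_ca.tsv"),
                       comment = prov)
  labels_df <- data.frame(sample = names(states$labels),
                          state = unname(states$labels),
                          diet = unname(diets$labels[names(states$labels)]),
                          stringsAsFactors = FALSE)
  write_labels_csv(labels_df, file.path(config$outdir, "labels.csv"),
                   comment = prov)

  hfd <- stage(NULL, "hfd", hfd_index(ffq))
  macro <- macronutrient_summary(ffq)
  write_labels_csv(data.frame(sample = names(hfd), hfd = unname(hfd), macro),
                   file.path(config$outdir, "diet_summaries.csv"),
                   comment = prov)

  envfit_foods <- stage(NULL, "envfit", fit_env_vectors(
    ord_u, ffq_values(ffq)[rownames(ord_u$coordinates), , drop = FALSE],
    axes = 1:2, permutations = config$permutations, seed = config$seed))
  utils::write.csv(envfit_foods,
                   file.path(config$outdir, "envfit_foods.csv"),
                   row.names = FALSE)

  marker_cols <- intersect(marker_reference()$marker, names(metadata))
  med <- stage(NULL, "median_regression", median_regression_table(
    metadata[match(rownames(ord_u$coordinates), metadata$sample), marker_cols],
    ord_u, age = metadata$age[match(rownames(ord_u$coordinates),
                                    metadata$sample)],
    axes = 1:min(3, ncol(ord_u$coordinates)),
    resamples = config$bootstrap_resamples, seed = config$seed))
  utils::write.csv(med, file.path(config$outdir, "median_regression.csv"),
                   row.names = FALSE)

  gt <- stage(NULL, "group_tests", group_tests(
    genus, states$labels[sample_ids(otus)],
    prevalence_min = config$prevalence_min))
  utils::write.csv(gt, file.path(config$outdir, "group_tests.csv"),
                   row.names = FALSE)

  enrich <- stage(NULL, "enrichment", {
    shannon_by_state <- tapply(alpha$shannon, states$labels[alpha$sample], mean)
    low_states <- names(sort(shannon_by_state))[
      seq_len(min(2, length(shannon_by_state)))]
    hfd_by_diet <- tapply(hfd, diets$labels[names(hfd)], mean)
    low_diet <- names(which.min(hfd_by_diet))
    subject_map <- stats::setNames(metadata$subject, metadata$sample)
    obese <- tapply(metadata$weight_status == "obese", metadata$subject, any)
    res <- combination_enrichment(states$labels, diets$labels,
                                  stats::setNames(as.logical(obese),
                                                  names(obese)),
                                  subject_map, state_set = low_states,
                                  diet_set = low_diet)
    list(result = res, state_set = low_states, diet_set = low_diet)
  })

  report <- list(
    package_version = as.character(utils::packageVersion("microstrat")),
    config_hash = hash,
    config = config_echo(config),
    n_samples = nrow(otus$counts),
    n_otus = ncol(otus$counts),
    alpha_shannon_range = range(alpha$shannon),
    steady_states = list(k = states$k,
                         sizes = as.list(table(states$labels)),
                         permanova_pseudo_f = states$permanova_result$statistic,
                         permanova_p = states$permanova_result$p_value),
    cags = list(k = cags$k, dominant = as.list(cags$dominant),
                n_edges = nrow(cags$edges)),
    diet_groups = list(m = diets$m, sizes = as.list(table(diets$labels)),
                       ca_axis1_inertia = diets$ca$proportion_explained[1]),
    hfd = list(mean = mean(hfd), by_diet = as.list(
      tapply(hfd, diets$labels[names(hfd)], mean))),
    significant_envfit_foods = sum(envfit_foods$q <= config$fdr),
    significant_regressions = sum(med$p_value <= 0.05),
    significant_group_taxa = sum(gt$p_adjusted <= config$fdr, na.rm = TRUE),
    enrichment = list(state_set = enrich$state_set,
                      diet_set = enrich$diet_set,
                      table = unclass(enrich$result$table),
                      odds_ratio = enrich$result$odds_ratio,
                      p_one_sided = enrich$result$p_one_sided,
                      p_two_sided = enrich$result$p_two_sided),
    warnings = warnings_seen
  )
  jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(render_report_md(report), file.path(config$outdir, "report.md"))
  class(report) <- "run_report"
  report
  }, warning = function(w) {
    warnings_seen <<- c(warnings_seen, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
}

config_echo <- function(config) {
  e <- unclass(config)
  e$paths <- lapply(e$paths, function(p) if (is.null(p)) "" else p)
  e
}

load_inputs <- function(config) {
  if (config$synthetic) {
    args <- config$synthetic_args
    args$seed <- args$seed %||% config$seed
    cohort <- generate_cohort(do.call(synthetic_config, args))
    write_cohort(cohort, file.path(config$outdir, "cohort"))
    list(otu_table = cohort$otu_table, tree = cohort$tree, ffq = cohort$ffq,
         metadata = cohort$metadata, truth = cohort$truth)
  } else {
    list(otu_table = read_otu_tsv(config$paths$otu_table),
         tree = read_newick(config$paths$tree),
         ffq = read_ffq_csv(config$paths$ffq),
         metadata = read_metadata_csv(config$paths$metadata),
         truth = NULL)
  }
}

render_report_md <- function(r) {
  c("# microstrat run report",
    "",
    sprintf("- package version: %s", r$package_version),
    sprintf("- config hash: %s (seed %s)", r$config_hash, r$config$seed),
    sprintf("- samples: %d, OTUs: %d", r$n_samples, r$n_otus),
    sprintf("- Shannon diversity range: %.3f - %.3f",
            r$alpha_shannon_range[1], r$alpha_shannon_range[2]),
    "",
    "## Steady states",
    sprintf("- k = %d (%s)", r$steady_states$k,
            paste(sprintf("%s: %d", names(r$steady_states$sizes),
                          unlist(r$steady_states$sizes)), collapse = ", ")),
    sprintf("- PERMANOVA pseudo-F = %.3f, p = %.4g",
            r$steady_states$permanova_pseudo_f, r$steady_states$permanova_p),
    "",
    "## Co-abundance groups",
    sprintf("- %d CAGs, %d significant edges; dominant genera: %s",
            r$cags$k, r$cags$n_edges,
            paste(unlist(r$cags$dominant), collapse = ", ")),
    "",
    "## Diet",
    sprintf("- %d diet groups; CA axis 1 explains %.1f%% of inertia",
            r$diet_groups$m, 100 * r$diet_groups$ca_axis1_inertia),
    sprintf("- mean HFD %.3f (%s)", r$hfd$mean,
            paste(sprintf("%s: %.3f", names(r$hfd$by_diet),
                          unlist(r$hfd$by_diet)), collapse = ", ")),
    "",
    "## Associations",
    sprintf("- foods associated with the ordination (q <= fdr): %d",
            r$significant_envfit_foods),
    sprintf("- marker-axis median regressions with p <= 0.05: %d",
            r$significant_regressions),
    sprintf("- taxa different across steady states (BH <= fdr): %d",
            r$significant_group_taxa),
    sprintf("- enrichment of %s x %s in obesity: OR %.3g, one-sided p %.4g",
            paste(r$enrichment$state_set, collapse = "/"),
            paste(r$enrichment$diet_set, collapse = "/"),
            r$enrichment$odds_ratio, r$enrichment$p_one_sided),
    if (length(r$warnings)) c("", "## Warnings", paste0("- ", r$warnings))
    else character())
}

#' @export
print.run_report <- function(x, ...) {
  cat(paste(render_report_md(x), collapse = "\n"), "\n")
  invisible(x)
}

## entry point for the inst/scripts/microstrat CLI; returns an exit code
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: microstrat simulate|run [--config FILE] [--seed N] [--outdir DIR] [--quiet]"
  if (!length(args) || args[1] %in% c("-h", "--help")) {
    cat(usage, "\n"); return(0L)
  }
  cmd <- args[1]
  opts <- list(seed = 1L, outdir = "microstrat_out", config = NULL,
               quiet = FALSE)
  i <- 2
  while (i <= length(args)) {
    a <- args[i]
    if (a == "--quiet") { opts$quiet <- TRUE; i <- i + 1 }
    else if (a %in% c("--seed", "--outdir", "--config")) {
      if (i == length(args)) { message("missing value for ", a); return(2L) }
      opts[[sub("^--", "", a)]] <- args[i + 1]; i <- i + 2
    } else { message("unknown argument: ", a, "\n", usage); return(2L) }
  }
  run <- function(expr) {
    tryCatch({ expr; 0L },
      microstrat_invalid_argument = function(e) {
        message("validation error: ", conditionMessage(e)); 2L
      },
      error = function(e) { message("error: ", conditionMessage(e)); 1L })
  }
  seed <- as.integer(opts$seed)
  if (cmd == "simulate") {
    run({
      cohort <- generate_cohort(synthetic_config(seed = seed))
      write_cohort(cohort, opts$outdir)
      if (!opts$quiet) message("cohort written to ", opts$outdir)
    })
  } else if (cmd == "run") {
    run({
      config <- if (!is.null(opts$config))
        read_pipeline_config(opts$config, outdir = opts$outdir, seed = seed)
      else pipeline_config(outdir = opts$outdir, seed = seed)
      report <- if (opts$quiet) suppressMessages(run_pipeline(config))
                else run_pipeline(config)
      if (!opts$quiet) print(report)
    })
  } else {
    message("unknown command: ", cmd, "\n", usage)
    2L
  }
}
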