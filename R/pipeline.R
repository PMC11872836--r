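REPORT_VERSION <- "1.0"

#' Default pipeline configuration
#'
#' All thresholds live here, never hard-coded in stages: `alpha_primary`
#' (0.01) is the headline significance level, `alpha_secondary` (0.05) the
#' secondary one used for state classification. The `simulate` block holds
#' [simulation_design()] arguments; the `clock` block the elastic-net
#' settings and the group sizes of the independent training cohort. Set
#' `inputs` (paths `beta`, `sample_sheet`, `annotation`) to analyze real
#' files instead of simulating.
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(seed = 1L,
       alpha_primary = 0.01,
       alpha_secondary = 0.05,
       trim = 0.05,
       min_cpgs = 10,
       simulate = list(),
       clock = list(alpha = 0.5, nfolds = 5, transform = "identity",
                    train_group_sizes = c(young = 12, old_control = 12,
                                          old_treated = 2)),
       inputs = NULL)
}

read_config <- function(config) {
  if (is.null(config)) return(default_config())
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- default_config()
  modifyList(base, config)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    abort("stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full rejuvenation-quantification pipeline
#'
#' Orchestrates simulate (or load) -> clock -> EWAS -> chromatin states ->
#' enrichment, writing every stage table plus a machine-readable
#' `report.json` under `out_dir`. Identical configuration and seed produce a
#' byte-identical report. A stage failure aborts with the stage named;
#' earlier outputs are retained.
#'
#' @param config configuration list or YAML path (see [default_config()]).
#' @param out_dir output directory, created if needed.
#' @param seed overrides `config$seed` when given.
#' @return the report, invisibly.
#' @export
run_pipeline <- function(config = NULL, out_dir, seed = NULL) {
  cfg <- read_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  log_stage <- function(name) message(sprintf(
    "[%6.1fs] stage: %s (seed %d)", proc.time()[["elapsed"]] - t0, name,
    cfg$seed))

  # -- data ---------------------------------------------------------------
  log_stage("data")
  simulated <- is.null(cfg$inputs)
  cohort <- stage("data", {
    if (simulated) {
      design <- do.call(simulation_design,
                        c(cfg$simulate, list(seed = cfg$seed)))
      co <- simulate_cohort(design)
      write_beta_matrix(co$beta, file.path(out_dir, "beta.tsv"))
      write_sample_sheet(co$sample_sheet, file.path(out_dir, "samples.csv"))
      write_cpg_annotation(co$annotation, file.path(out_dir, "annotation.tsv"))
      write_table(co$truth, file.path(out_dir, "truth.tsv"))
      co$design <- design
      co
    } else {
      list(beta = read_beta_matrix(cfg$inputs$beta),
           sample_sheet = read_sample_sheet(cfg$inputs$sample_sheet),
           annotation = read_cpg_annotation(cfg$inputs$annotation))
    }
  })

  # -- clock --------------------------------------------------------------
  log_stage("clock")
  clock_res <- stage("clock", {
    cc <- cfg$clock
    if (simulated) {
      # independent animals from the same design (same CpG truth, new noise)
      tdesign <- cohort$design
      tdesign$group_sizes <- cc$train_group_sizes[GROUP_LEVELS]
      train <- simulate_cohort(tdesign, annotation = cohort$annotation,
                               cohort_seed = cohort$design$seed + 7919L)
      keep <- train$sample_sheet$group %in% c("young", "old_control")
      tb <- train$beta[, keep, drop = FALSE]
      tages <- train$sample_sheet$age_years[keep]
    } else {
      keep <- cohort$sample_sheet$group %in% c("young", "old_control")
      tb <- cohort$beta[, keep, drop = FALSE]
      tages <- cohort$sample_sheet$age_years[keep]
    }
    model <- fit_clock(tb, tages, transform = cc$transform,
                       max_lifespan_years =
                         cohort$sample_sheet$max_lifespan_years[1],
                       alpha = cc$alpha, nfolds = cc$nfolds, seed = cfg$seed)
    write_clock_coefficients(model, file.path(out_dir, "clock_coefficients.csv"))
    preds <- apply_clock(model, cohort$beta)
    write_table(data.frame(sample_id = names(preds), dnam_age = preds),
                file.path(out_dir, "dnam_age.tsv"))
    cmp <- compare_groups(preds, cohort$sample_sheet,
                          contrast = c("old_treated", "old_control"))
    list(model = model, predictions = preds, comparison = cmp)
  })

  # -- ewas ---------------------------------------------------------------
  log_stage("ewas")
  ewas_res <- stage("ewas", {
    tab <- ewas_table(cohort$beta, cohort$sample_sheet,
                      alpha = cfg$alpha_primary)
    write_table(as.data.frame(tab), file.path(out_dir, "ewas.tsv"))
    for (ctr in c("age", "treatment")) {
      scan <- if (ctr == "age")
        data.frame(cpg_id = tab$cpg_id, p = tab$p_age, z = tab$z_age)
      else data.frame(cpg_id = tab$cpg_id, p = tab$p_treat, z = tab$z_treat)
      idx <- match(scan$cpg_id, cohort$annotation$cpg_id)
      man <- data.frame(cpg_id = scan$cpg_id,
                        chrom = cohort$annotation$chrom[idx],
                        pos = cohort$annotation$start[idx],
                        z = scan$z, p = scan$p,
                        significant = scan$p < cfg$alpha_primary,
                        direction = ifelse(scan$z >= 0, "gain", "loss"))
      write_table(man, file.path(out_dir, sprintf("manhattan_%s.tsv", ctr)))
      write_table(top_hits(scan, cohort$annotation, k = 15),
                  file.path(out_dir, sprintf("top_hits_%s.tsv", ctr)))
    }
    counts <- overlap_summary(tab$label)
    rev <- reversal_correlation(tab$z_age, tab$z_treat, subset = "all")
    perm <- reversal_permutation_test(cohort$beta, cohort$sample_sheet,
                                      seed = cfg$seed)
    list(table = tab, counts = counts, reversal = rev, perm = perm)
  })

  # -- states -------------------------------------------------------------
  log_stage("states")
  state_res <- stage("states", {
    se <- state_effects(cohort$beta, cohort$annotation, cohort$sample_sheet,
                        trim = cfg$trim, min_cpgs = cfg$min_cpgs)
    write_table(se$summary, file.path(out_dir, "state_summary.tsv"))
    write_table(data.frame(state = rownames(se$means), se$means,
                           check.names = FALSE),
                file.path(out_dir, "state_means.tsv"))
    rev <- state_reversal(se, z_threshold = qnorm(1 - cfg$alpha_secondary / 2))
    write_table(rev$classification, file.path(out_dir, "state_reversal.tsv"))
    list(summary = se, reversal = rev)
  })

  # -- enrichment ---------------------------------------------------------
  log_stage("enrich")
  enrich_res <- stage("enrich", {
    tab <- ewas_res$table
    out <- list()
    for (ctr in c("age", "treatment")) {
      z <- if (ctr == "age") tab$z_age else tab$z_treat
      p <- if (ctr == "age") tab$p_age else tab$p_treat
      for (dirn in c("gain", "loss")) {
        hits <- tab$cpg_id[p < cfg$alpha_primary &
                             (if (dirn == "gain") z > 0 else z < 0)]
        key <- sprintf("%s_%s", ctr, dirn)
        if (length(hits) == 0) { out[[key]] <- NULL; next }
        tss <- tss_position_enrichment(hits, cohort$annotation)
        st <- state_enrichment(hits, cohort$annotation)
        write_table(tss, file.path(out_dir, sprintf("tss_enrichment_%s.tsv", key)))
        write_table(st, file.path(out_dir, sprintf("state_enrichment_%s.tsv", key)))
        out[[key]] <- list(
          n_hits = length(hits),
          tss_significant_bins = sum(tss$p < cfg$alpha_secondary),
          enriched_states = st$state[st$tail == "upper" &
                                       st$p < cfg$alpha_secondary])
      }
    }
    idx <- match(tab$cpg_id, cohort$annotation$cpg_id)
    isl <- island_status_comparison(tab$z_age, cohort$annotation$island[idx])
    out$island_age <- isl
    out
  })

  # -- report -------------------------------------------------------------
  log_stage("report")
  cmp <- clock_res$comparison
  report <- list(
    report_version = REPORT_VERSION,
    seed = cfg$seed,
    alpha_primary = cfg$alpha_primary,
    alpha_secondary = cfg$alpha_secondary,
    simulated = simulated,
    clock = list(groups = cmp$groups, n = cmp$n, means = cmp$means,
                 se = cmp$se, t = cmp$t, df = cmp$df,
                 two_sided_p = cmp$two_sided_p,
                 one_sided_p = cmp$one_sided_p,
                 n_coefficients = length(clock_res$model$coefficients)),
    ewas = list(reversal_r = ewas_res$reversal$r,
                reversal_p_naive = ewas_res$reversal$p,
                reversal_p = ewas_res$perm$p,
                reversal_null_mean = ewas_res$perm$null_mean,
                counts = as.list(ewas_res$counts)),
    states = list(r = state_res$reversal$r, p = state_res$reversal$p,
                  n_states = state_res$reversal$n_states,
                  classification = state_res$reversal$classification),
    enrichment = enrich_res)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(report)
}
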