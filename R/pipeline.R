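#' Default pipeline configuration
#'
#' Single structured configuration for [run_pipeline()]. The demo defaults
#' use a small cohort and short chains so the full pipeline runs in minutes;
#' the study-scale settings are documented per field.
#'
#' @param cohort A [cohort_design()].
#' @param models Which smoothness ladder models to fit (see
#'   [smoothness_model()]).
#' @param chains,iter MCMC configuration per fit.
#' @param clinical_n Patients per group in the simulated clinical table
#'   (`0` skips the clinical stage).
#' @param ephys A [coupling_design()] or `NULL` to skip the coherence stage.
#' @param n_perm Permutations for the coherence cluster test.
#' @param seed Master seed; stage seeds derive from it.
#' @param out_dir Output directory.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_design(n_treatment = 4,
                                                   n_control = 4,
                                                   n_sessions = 4,
                                                   task = task_spec(repetitions = 2)),
                            models = 1:5, chains = 2, iter = 800,
                            clinical_n = 0, ephys = NULL, n_perm = 500,
                            seed = 1, out_dir = tempfile("sonirehab_run_")) {
  structure(list(cohort = cohort, models = models, chains = chains,
                 iter = iter, clinical_n = clinical_n, ephys = ephys,
                 n_perm = n_perm, seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full analysis pipeline on simulated (or supplied) data
#'
#' Executes simulate -> smoothness -> model ladder -> comparison (and
#' optionally the clinical pre-difference stage and the coherence stage),
#' writing per-stage tables with provenance headers and a machine-readable
#' JSON manifest. Every output records the configuration hash and seed; a
#' stage failure aborts with the stage name while earlier outputs persist.
#'
#' @param config A [pipeline_config()].
#' @param records Optional pre-computed smoothness records; when given, the
#'   simulation and kinematics stages are skipped.
#' @param quiet Suppress progress messages.
#' @return Invisibly, the manifest list (also written to
#'   `<out_dir>/manifest.json`).
#' @export
run_pipeline <- function(config = pipeline_config(), records = NULL,
                         quiet = FALSE) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_for_hash <- config[setdiff(names(config), "out_dir")]
  cfg_hash <- rlang::hash(cfg_for_hash)
  prov <- list(config_hash = cfg_hash, seed = config$seed)
  say <- function(...) if (!quiet) message(sprintf(...))
  manifest <- list(config_hash = cfg_hash, seed = config$seed, stages = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  if (is.null(records)) {
    say("simulating cohort (%d + %d patients, %d sessions)",
        config$cohort$n_treatment, config$cohort$n_control,
        config$cohort$n_sessions)
    cohort <- stage("simulate", gen_cohort(config$cohort))
    say("scoring stroke smoothness")
    records <- stage("smoothness", cohort_records(cohort))
  }
  rec_path <- file.path(config$out_dir, "smoothness_records.csv")
  write_table_prov(records, rec_path,
                   c(prov, list(n_records = nrow(records))))
  say("records: %d rows, %d patients", nrow(records),
      length(unique(records$IDanon)))

  fits <- list()
  fit_rows <- list()
  for (m in config$models) {
    say("fitting smoothness model #%d", m)
    fit <- stage(sprintf("fit_model_%d", m),
                 fit_mlm(records, smoothness_model(m),
                         chains = config$chains, iter = config$iter,
                         seed = config$seed + m))
    fits[[sprintf("model%d", m)]] <- fit
    tab <- fit$summary[, c("term", "estimate", "std.error",
                           "conf.low", "conf.high")]
    write_table_prov(tab,
                     file.path(config$out_dir, sprintf("fit_model_%d.csv", m)),
                     c(prov, list(model = m, converged = fit$converged)))
    fit_rows[[length(fit_rows) + 1L]] <- list(
      model = m,
      group_estimate = tab$estimate[tab$term == "Group.c"],
      converged = fit$converged)
  }
  manifest$stages$fits <- fit_rows

  if (length(fits) >= 2) {
    say("comparing models by PSIS-LOO")
    cmp <- stage("compare", compare_models(fits))
    write_table_prov(cmp, file.path(config$out_dir, "model_comparison.csv"),
                     prov)
    manifest$stages$comparison <- list(best = cmp$model[1],
                                       elpd = cmp$elpd[1])
  }

  if (config$clinical_n >= 2) {
    say("clinical pre-intervention differences (%d/group)", config$clinical_n)
    tab <- stage("clinical",
                 gen_clinical_table(config$clinical_n, seed = config$seed))
    pre <- lapply(setdiff(clinical_scales(), character(0)), function(sc)
      stage(sprintf("pre_diff_%s", sc),
            fit_pre_difference(tab, sc, chains = config$chains,
                               iter = config$iter, seed = config$seed)))
    pre_tab <- do.call(rbind, lapply(pre, function(p)
      data.frame(scale = p$scale, estimate = p$median,
                 conf.low = p$conf.low, conf.high = p$conf.high,
                 tail_mass = p$tail_mass)))
    write_table_prov(pre_tab, file.path(config$out_dir, "pre_differences.csv"),
                     prov)
    manifest$stages$clinical <- list(n_scales = nrow(pre_tab))
  }

  if (!is.null(config$ephys)) {
    say("coherence stage (%d trials)", config$ephys$n_trials)
    pre_d <- config$ephys; pre_d$coupling_strength <- 0
    post_d <- config$ephys; post_d$seed <- post_d$seed + 1L
    res <- stage("coherence", {
      rec_pre <- preprocess(gen_ephys(pre_d))
      rec_post <- preprocess(gen_ephys(post_d))
      tr_pre <- epoch_recording(rec_pre)
      tr_post <- epoch_recording(rec_post)
      w_post <- wpli(tr_post)
      cl <- cluster_permutation(tr_pre, tr_post, n_perm = config$n_perm,
                                seed = config$seed)
      write_table_prov(as.data.frame(w_post),
                       file.path(config$out_dir, "wpli_post.csv"), prov)
      cl
    })
    manifest$stages$coherence <- list(
      n_clusters = length(res$clusters),
      min_p = if (length(res$clusters))
        min(vapply(res$clusters, function(c) c$p, 0)) else NA)
  }

  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("pipeline complete: %s", config$out_dir)
  invisible(manifest)
}
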