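# ---- end-to-end pipeline orchestration -------------------------------------

#' Pipeline configuration
#'
#' One object drives the whole run: simulate -> score -> classify ->
#' archetypes -> trends/groups -> survival. Accepts a YAML file path or
#' a list of overrides; unspecified fields take the documented defaults.
#'
#' @param config `NULL`, a named list of overrides, or a path to a YAML
#'   file with flat keys.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = NULL) {
  defaults <- list(
    outdir = "injuryarch-run",
    seed = 1L,
    n_biopsies = 600L,
    k = 6L,
    restarts = 10L,
    window = 400L,
    n_trees = 10000L,
    cv_folds = 10L,
    cortex_threshold = 10,
    rejection_filter = "all",
    horizon_days = 1095L
  )
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort(sprintf("Config file '%s' not found.", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.null(config)) {
    unknown <- setdiff(names(config), names(defaults))
    if (length(unknown) > 0) {
      abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")))
    }
    defaults[names(config)] <- config
  }
  structure(defaults, class = "pipeline_config")
}

#' Run the full injury-phenotyping pipeline on a synthetic cohort
#'
#' Executes all stages in dependency order, writing every artifact under
#' `config$outdir` and returning a manifest listing each file with its
#' stage and md5 checksum. Stage seeds are derived from `config$seed`, so
#' a rerun with the same config is bit-identical for deterministic
#' stages. A failing stage aborts with the stage named; artifacts already
#' written are preserved.
#'
#' @param config A [pipeline_config()] (or anything it accepts).
#' @param quiet Suppress per-stage progress messages.
#' @return A tibble manifest: `file`, `stage`, `md5`.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  say <- function(...) if (!quiet) message(sprintf(...))
  emit <- function(stage, file) {
    manifest[[length(manifest) + 1]] <<- tibble(
      file = file, stage = stage, md5 = unname(tools::md5sum(file)))
  }
  stage <- function(name, fn) {
    say("[%s] starting", name)
    t0 <- Sys.time()
    res <- tryCatch(fn(), error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
    say("[%s] done in %.1fs", name, as.numeric(Sys.time() - t0, units = "secs"))
    res
  }
  path <- function(f) file.path(outdir, f)

  # effective configuration is dumped alongside the outputs
  jsonlite::write_json(unclass(config), path("config.json"),
                       auto_unbox = TRUE, digits = NA)
  emit("config", path("config.json"))

  sim <- stage("simulate", function() {
    cfg <- simulation_config(n_biopsies = config$n_biopsies,
                             seed = config$seed)
    cohort <- simulate_cohort(cfg)
    write_expression(cohort$expr, path("expression.tsv"))
    write_gmt(cohort$gene_sets, path("gene_sets.gmt"))
    write_clinical(cohort$clinical, path("clinical.csv"))
    jsonlite::write_json(
      list(Z_true = unname(cohort$truth$Z_true),
           labels = cohort$truth$labels,
           cluster_true = cohort$truth$cluster_true,
           seed = config$seed),
      path("truth.json"), auto_unbox = TRUE, digits = NA)
    cohort
  })
  emit("simulate", path("expression.tsv"))
  emit("simulate", path("gene_sets.gmt"))
  emit("simulate", path("clinical.csv"))
  emit("simulate", path("truth.json"))

  pbt <- stage("score", function() {
    s <- score_pbts(sim$expr, sim$gene_sets)
    write_scores(s, path("pbt_scores.csv"))
    s
  })
  emit("score", path("pbt_scores.csv"))

  scores <- stage("classify", function() {
    targets <- binary_targets(sim$clinical)
    probs <- tibble(sample_id = pbt$sample_id)
    for (ep in classifier_features()) {
      ens <- oof_ensemble(
        pbt, tibble(sample_id = targets$sample_id, label = targets[[ep]]),
        k = config$cv_folds, seed = config$seed + match(ep, classifier_features()))
      probs[[ep]] <- ens$score[match(probs$sample_id, ens$sample_id)]
    }
    s <- assemble_score_table(pbt, probs)
    write_scores(s, path("scores.csv"))
    s
  })
  emit("classify", path("scores.csv"))

  kept <- stage("filter", function() {
    fl <- filter_low_cortex(sim$clinical, config$cortex_threshold)
    say("[filter] removed %d low-cortex biopsies", fl$n_removed)
    scores[scores$sample_id %in% fl$retained$sample_id, , drop = FALSE]
  })

  arch <- stage("archetypes", function() {
    model <- fit_archetypes(kept, k = config$k, restarts = config$restarts,
                            seed = config$seed)
    lab <- label_archetypes(model, scores = kept)
    asg <- assign_clusters(model, labels = lab$mapping$label)
    pca <- fit_pca(kept)
    write_archetype_model(model, path("model.json"))
    readr::write_csv(asg, path("assignments.csv"), progress = FALSE)
    readr::write_csv(pca$scores, path("pca_scores.csv"), progress = FALSE)
    list(model = model, assignments = asg, pca = pca)
  })
  emit("archetypes", path("model.json"))
  emit("archetypes", path("assignments.csv"))
  emit("archetypes", path("pca_scores.csv"))

  stage("trends", function() {
    clin <- sim$clinical
    days <- clin$days_post_transplant[match(rownames(arch$model$A),
                                            clin$sample_id)]
    w <- min(config$window, nrow(arch$model$A))
    lab <- assign_clusters(arch$model,
                           labels = NULL) # labels live in assignments
    tr <- standardized_trend(arch$model$A, days, w = w,
                             labels = label_archetypes(arch$model)$mapping$label)
    readr::write_csv(tr, path("trends.csv"), progress = FALSE)
  })
  emit("trends", path("trends.csv"))

  stage("groups", function() {
    gs <- group_summary(arch$assignments, sim$clinical,
                        rejection_filter = config$rejection_filter)
    readr::write_csv(gs, path("group_summary.csv"), progress = FALSE)
    ct <- contingency(arch$assignments, sim$clinical, "rejection_group")
    readr::write_csv(as_tibble(as.data.frame.table(as.table(ct$counts))),
                     path("rejection_contingency.csv"), progress = FALSE)
  })
  emit("groups", path("group_summary.csv"))
  emit("groups", path("rejection_contingency.csv"))

  stage("survival", function() {
    one <- select_one_biopsy_per_patient(sim$clinical, seed = config$seed)
    km <- km_by_group(one, arch$assignments,
                      horizon_days = config$horizon_days)
    readr::write_csv(km$curves, path("km_curves.csv"), progress = FALSE)
    ff <- purrr::map_dfr(km$groups$group, function(g) {
      ids <- arch$assignments$sample_id[
        (arch$assignments$label %||% arch$assignments$archetype_index) == g]
      dplyr::bind_cols(tibble(group = g),
                       failure_fraction(one[one$sample_id %in% ids, ],
                                        config$horizon_days))
    })
    readr::write_csv(ff, path("failure_fractions.csv"), progress = FALSE)
    feats <- dplyr::bind_cols(
      tibble(sample_id = rownames(arch$model$A)),
      as_tibble(setNames(as.data.frame(arch$model$A),
                         paste0("injury_", seq_len(config$k)))))
    lowgfr <- tibble(sample_id = sim$clinical$sample_id,
                     label = sim$clinical$egfr <= 30)
    imp <- variable_importance(feats, lowgfr, mode = "classification",
                               n_trees = config$n_trees, seed = config$seed)
    readr::write_csv(as_tibble(imp), path("importance_lowgfr.csv"),
                     progress = FALSE)
  })
  emit("survival", path("km_curves.csv"))
  emit("survival", path("failure_fractions.csv"))
  emit("survival", path("importance_lowgfr.csv"))

  dplyr::bind_rows(manifest)
}
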