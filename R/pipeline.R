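# End-to-end orchestration: generate -> segment -> metrics -> statistics ->
# clustering -> report bundle, reproducible from one config and one seed.

#' Pipeline configuration
#'
#' Assembles and validates the configuration consumed by [run_pipeline()].
#' `synth` holds [synth_config()] fields; the global seed drives cohort
#' generation and every stochastic downstream step.
#'
#' @param path Optional YAML or JSON file whose keys override the defaults
#'   (nested keys merge).
#' @param ... Further overrides applied after the file.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL, ...) {
  cfg <- list(
    n_subjects = 10L,
    seed = 1L,
    synth = list(),
    share_stage_effects = FALSE,
    band = c(0.3, 20),
    smooth_hz = 20,
    ldf_epoch_s = 10,
    ldf_band = c(0.6, 1.6),
    dv = list(),
    summary_params = c("dv", "ri_forehead", "a_mc"),
    nmi_bins = 16L,
    stable_sd = 0.15,
    clustering = list(min_samples_grid = 3:10, min_clusters = 2L,
                      max_noise_frac = 0.2),
    tsne_subjects = 1L,  # subject indices to embed; integer(0) disables
    tsne_perplexity = 30,
    write_recordings = FALSE
  )
  if (!is.null(path)) {
    if (!file.exists(path)) abort_rheo(sprintf("config file %s not found", path),
                                       "io_error")
    raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
           else yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, raw)
  }
  dots <- list(...)
  if (length(dots)) cfg <- utils::modifyList(cfg, dots)
  cfg$seed <- as.integer(cfg$seed)
  cfg$n_subjects <- as.integer(cfg$n_subjects)
  if (cfg$n_subjects < 1) abort_rheo("n_subjects must be >= 1", "config_error")
  structure(cfg, class = "pipeline_config")
}

write_table <- function(df, out_dir, name) {
  data.table::fwrite(data.table::as.data.table(df),
                     file.path(out_dir, name), na = "NA")
}

matrix_to_df <- function(m, params) {
  df <- as.data.frame(m)
  names(df) <- params
  cbind(data.frame(parameter = params), df)
}

#' Run the full analysis pipeline
#'
#' Generates (or loads) a cohort, segments every recording into cardiac
#' cycles, computes the per-cycle metric battery, derives stage summaries
#' with Mann-Whitney tests, within-stage and stage-averaged correlations,
#' cohort mean/std correlation heatmap matrices with the stability mask,
#' the NMI matrix, and per-subject DBSCAN clustering of the four functional
#' parameter groups with the cohort cluster summary and optional t-SNE
#' coordinates. All artifacts are written as delimited text plus a JSON run
#' manifest. Identical config and seed give identical numeric outputs.
#'
#' @param config A [pipeline_config()], a path to a YAML/JSON config, or
#'   `NULL` for the defaults.
#' @param out_dir Output directory (created, including parents, if absent).
#' @param seed Optional override of the config seed.
#' @param n_subjects Optional override of the cohort size.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the in-memory results (feature table,
#'   summaries, matrices, cluster results, manifest).
#' @export
run_pipeline <- function(config = NULL, out_dir, seed = NULL,
                         n_subjects = NULL, quiet = FALSE) {
  if (is.character(config)) config <- pipeline_config(config)
  if (is.null(config)) config <- pipeline_config()
  if (!inherits(config, "pipeline_config"))
    config <- do.call(pipeline_config, config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (!is.null(n_subjects)) config$n_subjects <- as.integer(n_subjects)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    abort_rheo(sprintf("cannot create output directory %s", out_dir), "io_error")
  say <- function(...) if (!quiet) message(sprintf(...))
  step <- function(name, expr) {
    tryCatch(expr, error = function(e)
      abort_rheo(sprintf("pipeline stage '%s' failed: %s", name,
                         conditionMessage(e)), "pipeline_error"))
  }

  say("simulate: generating %d synthetic subject(s), seed %d",
      config$n_subjects, config$seed)
  cohort <- step("simulate", {
    scfg <- do.call(synth_config, config$synth)
    generate_cohort(config$n_subjects, scfg, seed = config$seed,
                    share_stage_effects = isTRUE(config$share_stage_effects))
  })
  if (isTRUE(config$write_recordings))
    step("write-recordings", {
      rec_dir <- file.path(out_dir, "recordings")
      for (rec in cohort) write_recording(rec, rec_dir)
    })

  say("segment + metrics: extracting cycles and per-cycle parameters")
  tables <- step("metrics", lapply(cohort, function(rec) {
    tab <- compute_cycle_metrics(rec, dv_params = if (length(config$dv))
      do.call(dv_model_params, config$dv) else NULL,
      smooth_hz = config$smooth_hz, ldf_epoch_s = config$ldf_epoch_s,
      ldf_band = config$ldf_band)
    write_table(tab, out_dir, sprintf("cycle_metrics_%s.csv", rec$subject_id))
    tab
  }))
  feature_table <- step("feature-table", build_feature_table(tables))
  write_table(feature_table, out_dir, "feature_table.csv")

  say("stats: stage summaries, correlations, NMI")
  stage_summaries <- step("stage-summary", {
    out <- do.call(rbind, lapply(config$summary_params, function(p)
      cbind(parameter = p, stage_summary(feature_table, p))))
    write_table(out, out_dir, "stage_summary.csv")
    out
  })
  within_stage_r <- step("within-stage-correlation", {
    ps <- config$summary_params
    rows <- list()
    for (s in sort(unique(feature_table$stage_id))) {
      cm <- pearson_within_stage(feature_table, ps, stage_id = s)
      for (i in seq_along(ps)) for (j in seq_along(ps)) if (i < j)
        rows[[length(rows) + 1L]] <- data.frame(
          stage_id = s, param1 = ps[i], param2 = ps[j],
          r = cm$matrix[i, j], n = cm$n_pairs[i, j])
    }
    out <- do.call(rbind, rows)
    write_table(out, out_dir, "within_stage_correlations.csv")
    out
  })
  stage_avg <- step("stage-averaged-correlation", {
    cm <- pearson_stage_averaged(feature_table)
    write_table(matrix_to_df(cm$matrix, cm$params), out_dir,
                "stage_averaged_correlation.csv")
    cm
  })
  heatmaps <- step("cohort-heatmaps", {
    subj <- unique(feature_table$subject_id)
    mats <- lapply(subj, function(id)
      pearson_whole_record(feature_table, subject_id = id))
    hm <- cohort_heatmaps(mats, stable_sd = config$stable_sd)
    write_table(matrix_to_df(hm$mean, hm$params), out_dir,
                "correlation_mean.csv")
    write_table(matrix_to_df(hm$sd, hm$params), out_dir, "correlation_sd.csv")
    write_table(matrix_to_df(hm$stable, hm$params), out_dir,
                "correlation_stability.csv")
    hm
  })
  nmi <- step("nmi", {
    nm <- nmi_matrix(feature_table, n_bins = config$nmi_bins)
    write_table(matrix_to_df(nm$matrix, nm$params), out_dir, "nmi_matrix.csv")
    nm
  })

  say("cluster: DBSCAN over four functional groups per subject")
  clust <- step("clustering", {
    groups <- build_feature_groups(feature_table)
    subj <- unique(feature_table$subject_id)
    rows <- list(); results <- list()
    for (id in subj) {
      sub <- feature_table[feature_table$subject_id == id, , drop = FALSE]
      for (gname in names(groups)) {
        if (!length(groups[[gname]])) next
        x <- try(prepare_features(sub, groups[[gname]]), silent = TRUE)
        if (inherits(x, "try-error") || nrow(x) < 20L) next
        cr <- dbscan_auto(x,
                          min_samples_grid = config$clustering$min_samples_grid,
                          min_clusters = config$clustering$min_clusters,
                          max_noise_frac = config$clustering$max_noise_frac)
        results[[paste(id, gname, sep = ".")]] <- cr
        rows[[length(rows) + 1L]] <- data.frame(
          group = gname, subject_id = id, n_clusters = cr$n_clusters,
          silhouette = cr$silhouette, eps = cr$eps,
          min_samples = cr$min_samples, noise_frac = cr$noise_frac)
      }
    }
    tab <- do.call(rbind, rows)
    write_table(tab, out_dir, "cluster_results.csv")
    summ <- cluster_summary(tab)
    write_table(summ, out_dir, "cluster_summary.csv")
    list(results = results, table = tab, summary = summ, groups = groups)
  })
  tsne_files <- step("tsne", {
    idx <- config$tsne_subjects
    subj <- unique(feature_table$subject_id)
    files <- character(0)
    for (i in idx) {
      if (i < 1 || i > length(subj)) next
      id <- subj[i]
      sub <- feature_table[feature_table$subject_id == id, , drop = FALSE]
      for (gname in names(clust$groups)) {
        key <- paste(id, gname, sep = ".")
        if (is.null(clust$results[[key]])) next
        x <- suppressWarnings(prepare_features(sub, clust$groups[[gname]]))
        emb <- suppressWarnings(
          tsne_embed(x, seed = config$seed + 17L,
                     perplexity = config$tsne_perplexity))
        df <- data.frame(subject_id = id, group = gname,
                         row = attr(x, "rows"),
                         stage_id = sub$stage_id[attr(x, "rows")],
                         cluster = clust$results[[key]]$labels,
                         tsne1 = emb[, 1], tsne2 = emb[, 2])
        f <- sprintf("tsne_%s_%s.csv", id, gname)
        write_table(df, out_dir, f)
        files <- c(files, f)
      }
    }
    files
  })

  manifest <- list(
    package = "rheomicro",
    version = as.character(utils::packageVersion("rheomicro")),
    seed = config$seed,
    n_subjects = config$n_subjects,
    n_cycles = nrow(feature_table),
    config = unclass(config),
    artifacts = sort(setdiff(list.files(out_dir, recursive = TRUE),
                             "manifest.json")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = I(10), pretty = TRUE)
  say("done: %d cycles from %d subjects; artifacts in %s",
      nrow(feature_table), config$n_subjects, out_dir)
  invisible(list(feature_table = feature_table,
                 stage_summaries = stage_summaries,
                 within_stage_r = within_stage_r, stage_avg = stage_avg,
                 heatmaps = heatmaps, nmi = nmi, clustering = clust,
                 tsne_files = tsne_files, manifest = manifest))
}
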