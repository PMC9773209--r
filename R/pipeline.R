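# End-to-end orchestration: simulate -> generate stimuli -> score ->
# analyze -> power, driven by one config, with a checksummed run manifest.

#' Default pipeline configuration
#'
#' Returns the full configuration list with the study defaults: the 6 x 60
#' design, 2 Hz / 50% duty gating with 10 ms ramps, -10 dB SNR, pooled
#' keyword aggregation, 3 x IQR fencing, and the four-predictor model.
#' Supply overrides as a (possibly nested) list or a YAML file via
#' [read_run_config()].
#'
#' @param overrides named list merged over the defaults (nested lists are
#'   merged recursively).
#' @return configuration list.
#' @export
default_run_config <- function(overrides = list()) {
  config <- list(
    seed = 1,
    design = list(n_per_condition = 60),
    stimulus = list(rate_hz = 2, duty = 0.5, start_phase = "speech_first",
                    ramp_ms = 10, snr_db = -10, rms_target = 0.05,
                    rms_scope = "active_segments", fft_policy = "concat",
                    n_audio = 6, sample_rate = 16000, duration_s = 2),
    scoring = list(double_letter = TRUE, transposition = TRUE,
                   apostrophe = TRUE, collapse_double_space = TRUE,
                   aggregation = "pooled"),
    cohort = list(n = 63, residual_sd = 7.5, p_typo = 0.2),
    analysis = list(fence_k = 3, quantile_type = 7, levene_center = "mean",
                    p_stay = 0.25, delta_beta_max = 0.20,
                    literal_direction = FALSE,
                    predictors = c("rst_percent", "lextale_percent",
                                   "stroop_interference", "stroop_speed_ms")),
    power = list(f2 = 0.3, alpha = 0.05, power = 0.9, n_predictors = 4,
                 lambda_convention = "total_n")
  )
  merge_config(config, overrides)
}

merge_config <- function(base, overrides) {
  for (k in names(overrides)) {
    if (is.list(overrides[[k]]) && is.list(base[[k]])) {
      base[[k]] <- merge_config(base[[k]], overrides[[k]])
    } else {
      base[[k]] <- overrides[[k]]
    }
  }
  base
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file; keys override [default_run_config()].
#' @return configuration list.
#' @export
read_run_config <- function(path) {
  abort_if(!file.exists(path), sprintf("read_run_config: no such file '%s'", path))
  default_run_config(yaml::read_yaml(path))
}

require_keys <- function(config, keys) {
  for (k in keys) {
    parts <- strsplit(k, ".", fixed = TRUE)[[1]]
    node <- config
    for (p in parts) {
      node <- node[[p]]
      abort_if(is.null(node),
               sprintf("run_pipeline: configuration error: missing key '%s'", k))
    }
  }
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order — simulate (cohort, keywords,
#' transcripts, trial logs), generate-stimuli (example silent-gap /
#' noise-burst WAV pairs with segment-map sidecars), score-transcripts,
#' score-cognitive, analyze (fencing, descriptives, Levene + Welch omnibus,
#' BH pairwise, correlation screen, per-condition regressions with
#' diagnostics), and power — writing CSV/WAV outputs under `outdir` and a
#' manifest with an MD5 checksum per file. Reruns with the same config and
#' seed reproduce identical checksums.
#'
#' @param config configuration list from [default_run_config()] /
#'   [read_run_config()].
#' @param outdir output directory (created if needed).
#' @return the manifest tibble (columns `stage`, `file`, `md5`),
#'   invisibly; also written to `manifest.csv`. Attributes `n_sentences`
#'   and `conditions` record the instantiated design.
#' @export
run_pipeline <- function(config = default_run_config(), outdir) {
  require_keys(config, c(
    "seed", "design.n_per_condition",
    "stimulus.rate_hz", "stimulus.duty", "stimulus.ramp_ms",
    "stimulus.snr_db", "stimulus.rms_target", "stimulus.n_audio",
    "scoring.aggregation", "cohort.n", "analysis.fence_k",
    "analysis.predictors", "power.f2", "power.alpha", "power.power",
    "power.n_predictors"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  emit <- function(stage, name, writer) {
    path <- file.path(outdir, name)
    writer(path)
    files[[length(files) + 1]] <<- tibble::tibble(stage = stage, file = name)
    path
  }
  seed <- config$seed

  ## stage: simulate ----------------------------------------------------
  design <- study_design(config$design$n_per_condition)
  study <- simulate_study(
    design = design,
    cohort = cohort_spec(n = config$cohort$n,
                         residual_sd = config$cohort$residual_sd),
    seed = seed, p_typo = config$cohort$p_typo)
  kw_df <- dplyr::bind_rows(lapply(study$keywords, function(kl) {
    kws <- kl$keywords
    tibble::as_tibble(c(list(sentence_id = kl$sentence_id),
                        setNames(as.list(kws), paste0("keyword_", seq_along(kws)))))
  }))
  kw_df$condition <- design$condition[match(kw_df$sentence_id, design$sentence_id)]
  emit("simulate", "design.csv", function(p) write.csv(design, p, row.names = FALSE))
  emit("simulate", "keywords.csv", function(p) write.csv(kw_df, p, row.names = FALSE))
  emit("simulate", "transcripts.csv",
       function(p) write.csv(study$transcripts, p, row.names = FALSE))
  emit("simulate", "trial_log.csv",
       function(p) write.csv(study$trial_log, p, row.names = FALSE))
  emit("simulate", "dst_norms_synthetic.csv",
       function(p) write.csv(study$dst_norms, p, row.names = FALSE))
  truth <- cbind(participant_id = study$cohort$participant_id,
                 as.data.frame(attr(study$cohort, "abilities")))
  emit("simulate", "ground_truth_abilities.csv",
       function(p) write.csv(truth, p, row.names = FALSE))
  emit("simulate", "ground_truth_betas.csv", function(p)
    write.csv(cbind(condition = rownames(attr(study$cohort, "betas")),
                    as.data.frame(attr(study$cohort, "betas"))), p,
              row.names = FALSE))

  ## stage: generate-stimuli --------------------------------------------
  st <- config$stimulus
  gspec <- gating_spec(st$rate_hz, st$duty, st$start_phase, st$ramp_ms)
  n_audio <- min(st$n_audio, nrow(design))
  sent_ids <- design$sentence_id[seq_len(n_audio)]
  corpus <- lapply(sent_ids, function(sid) {
    synth_sentence(sentence_spec(duration_s = st$duration_s,
                                 sample_rate = st$sample_rate,
                                 seed = derive_seed(seed, paste0("audio/", sid))),
                   sentence_id = sid)$audio
  })
  model <- build_noise_model(corpus, st$fft_policy)
  for (i in seq_along(sent_ids)) {
    sid <- sent_ids[i]
    pair <- assemble_pair(corpus[[i]], gspec, model, snr_db = st$snr_db,
                          seed = derive_seed(seed, paste0("noise/", sid)),
                          rms_target = st$rms_target)
    emit("generate-stimuli", sprintf("%s_silent.wav", sid),
         function(p) write_wav(pair$silent_gap, p))
    emit("generate-stimuli", sprintf("%s_noise.wav", sid),
         function(p) write_wav(pair$noise_burst, p))
    emit("generate-stimuli", sprintf("%s_segments.csv", sid),
         function(p) write_segment_map(pair$segment_map, p))
  }

  ## stage: score-transcripts -------------------------------------------
  rules <- scoring_rules(config$scoring$double_letter,
                         config$scoring$transposition,
                         config$scoring$apostrophe,
                         config$scoring$collapse_double_space)
  scores <- score_transcripts(kw_df, study$transcripts, rules,
                              method = config$scoring$aggregation)
  emit("score-transcripts", "condition_scores.csv",
       function(p) write.csv(scores, p, row.names = FALSE))
  score_wide <- tidyr_pivot(scores)

  ## stage: score-cognitive ---------------------------------------------
  measures <- score_cognitive(study$trial_log, study$dst_norms)
  emit("score-cognitive", "cognitive_measures.csv",
       function(p) write.csv(measures, p, row.names = FALSE))

  ## stage: analyze -----------------------------------------------------
  an <- config$analysis
  demo_cols <- c("participant_id", "age", "education", "ssq_speech",
                 "ssq_spatial", "ssq_qualities")
  table <- dplyr::inner_join(study$cohort[, demo_cols], measures,
                             by = "participant_id")
  table <- dplyr::inner_join(table, score_wide, by = "participant_id")
  screened <- intersect(screened_measures(), names(table))
  fenced <- fence_adjust(table, k = an$fence_k, cols = screened,
                         quantile_type = an$quantile_type)
  emit("analyze", "fence_report.csv", function(p)
    write.csv(fenced$report$adjusted_cells, p, row.names = FALSE))
  emit("analyze", "descriptives.csv", function(p)
    write.csv(describe_table(fenced$table, screened), p, row.names = FALSE))

  conds <- names(default_condition_means())
  long <- tidyr_longer(fenced$table, conds)
  lev <- levene_test(long$score, long$condition, center = an$levene_center)
  wa <- welch_anova(long$score, long$condition)
  pw <- pairwise_welch_bh(long$score, long$condition)
  emit("analyze", "omnibus.csv", function(p) write.csv(tibble::tibble(
    test = c("levene", "welch_anova"), F = c(lev$F, wa$F),
    df1 = c(lev$df1, wa$df1), df2 = c(lev$df2, wa$df2),
    p = c(lev$p, wa$p)), p, row.names = FALSE))
  emit("analyze", "pairwise_bh.csv",
       function(p) write.csv(pw$pairs, p, row.names = FALSE))

  corr_cols <- c("rst_percent", "dst_percentile", "stroop_interference",
                 "stroop_speed_ms", "flanker_interference_ms",
                 "lextale_percent", "lextale_word_rt_ms", conds)
  cs <- correlation_screen(fenced$table, corr_cols)
  emit("analyze", "correlations_r.csv", function(p) write.csv(cs$r, p))
  emit("analyze", "correlations_p.csv", function(p) write.csv(cs$p, p))

  model_rows <- list()
  diag_rows <- list()
  for (cond in conds) {
    fit <- fit_model(fenced$table, cond, an$predictors)
    dg <- diagnostics(fit)
    model_rows[[cond]] <- dplyr::mutate(fit$coefficients, condition = cond,
                                        r_squared = fit$r_squared,
                                        adj_r_squared = fit$adj_r_squared,
                                        f_statistic = fit$f_statistic,
                                        f_p = fit$f_p)
    diag_rows[[cond]] <- tibble::tibble(
      condition = cond, max_vif = max(dg$vif), bp_statistic = dg$bp_statistic,
      bp_p = dg$bp_p, shapiro_statistic = dg$shapiro_statistic,
      shapiro_p = dg$shapiro_p)
  }
  emit("analyze", "models.csv", function(p)
    write.csv(dplyr::bind_rows(model_rows), p, row.names = FALSE))
  emit("analyze", "model_diagnostics.csv", function(p)
    write.csv(dplyr::bind_rows(diag_rows), p, row.names = FALSE))

  ## stage: power --------------------------------------------------------
  pw_cfg <- config$power
  n_req <- required_sample_size(pw_cfg$f2, pw_cfg$alpha, pw_cfg$power,
                                pw_cfg$n_predictors, pw_cfg$lambda_convention)
  emit("power", "power.csv", function(p) write.csv(tibble::tibble(
    f2 = pw_cfg$f2, alpha = pw_cfg$alpha, target_power = pw_cfg$power,
    n_predictors = pw_cfg$n_predictors, required_n = n_req),
    p, row.names = FALSE))

  manifest <- dplyr::bind_rows(files)
  manifest$md5 <- unname(tools::md5sum(file.path(outdir, manifest$file)))
  manifest$seed <- seed
  write.csv(manifest, file.path(outdir, "manifest.csv"), row.names = FALSE)
  attr(manifest, "n_sentences") <- nrow(design)
  attr(manifest, "conditions") <- unique(design$condition)
  invisible(manifest)
}

# wide participant x condition score table
tidyr_pivot <- function(scores) {
  out <- tibble::tibble(participant_id = unique(scores$participant_id))
  for (cond in unique(scores$condition)) {
    sub <- scores[scores$condition == cond, ]
    out[[cond]] <- sub$percent_correct[match(out$participant_id,
                                             sub$participant_id)]
  }
  out
}

# long condition-score table for the omnibus tests
tidyr_longer <- function(table, conds) {
  dplyr::bind_rows(lapply(conds, function(cond) {
    tibble::tibble(participant_id = table$participant_id, condition = cond,
                   score = table[[cond]])
  }))
}
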