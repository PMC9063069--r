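# Orchestration and file-format contracts tying the stages together.

#' Pipeline configuration
#'
#' Tunable parameters of the analysis stages (the simulation has its own
#' [sim_config()]).
#'
#' @param dixon_alpha Level of the triplicate Dixon outlier test.
#' @param concordance_threshold Duplicate concordance threshold (fraction).
#' @param reference_run_count Opening runs used for the batch reference.
#' @param embed_seed Seed of the network embedding.
#' @param perplexity t-SNE perplexity (NULL = default rule).
#' @param cv_folds,cv_n_perm Cross-validation folds and permutation count.
#' @param holm Add Holm-adjusted p-values to the timepoint comparisons.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(dixon_alpha = 0.05,
                            concordance_threshold = 0.07,
                            reference_run_count = 10,
                            embed_seed = 7L,
                            perplexity = NULL,
                            cv_folds = 10,
                            cv_n_perm = 100,
                            holm = FALSE) {
  if (concordance_threshold <= 0 || concordance_threshold >= 1) {
    abort("`concordance_threshold` must be in (0, 1).")
  }
  if (reference_run_count < 1) abort("`reference_run_count` must be >= 1.")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline on a synthetic study
#'
#' Executes simulate -> quantify -> batch-adjust -> resolve replicates
#' (simulating third runs for discordant duplicates) -> longitudinal cohort
#' statistics -> stress-profile screening, and returns every intermediate and
#' final result. Deterministic for a fixed configuration.
#'
#' @param config A [sim_config()] describing the synthetic study.
#' @param pipeline A [pipeline_config()].
#' @param out_dir Optional directory; when given, tables and results are
#'   written as CSV/JSON (see [write_results()]).
#' @return Object of class `telo_results`: list with the simulation bundle
#'   (`sim`), `curves`, `quants`, `ltl` (per-sample reported adjusted T/S
#'   with timepoints), `assay_qc`, `timepoint_comparisons`, `mode_rank_sum`,
#'   `mode_model`, `descriptives`, `completeness`, `associations_t1`,
#'   `associations_mean`, `network`, `cv_t1`, `cv_mean`, and `provenance`.
#' @export
run_pipeline <- function(config = sim_config(),
                         pipeline = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(pipeline, "pipeline_config"))
  sim <- simulate_study(config)

  quants <- quantify_plates(sim$plates, dixon_alpha = pipeline$dixon_alpha)
  adjusted <- adjust_batches(quants, n_reference_runs = pipeline$reference_run_count)
  resolved <- resolve_samples(filter(adjusted, .data$role == "unknown"),
                              value = "adjusted_ts",
                              threshold = pipeline$concordance_threshold)

  # Discordant duplicates are rerun on fresh plates and re-resolved.
  plates <- sim$plates
  needs <- resolved$sample_id[resolved$needs_third]
  if (length(needs) > 0) {
    extra_samples <- sim$truth$draws %>%
      filter(.data$sample_id %in% needs) %>%
      select("sample_id", "true_ts")
    groups <- split(extra_samples,
                    ceiling(seq_len(nrow(extra_samples)) / config$samples_per_run))
    idx <- sim$next_run_index
    for (grp in groups) {
      run <- simulate_plate_run(config, idx, grp)
      plates <- bind_rows(plates, run$plate)
      idx <- idx + 1L
    }
    quants <- quantify_plates(plates, dixon_alpha = pipeline$dixon_alpha)
    adjusted <- adjust_batches(quants,
                               n_reference_runs = pipeline$reference_run_count)
    resolved <- resolve_samples(filter(adjusted, .data$role == "unknown"),
                                value = "adjusted_ts",
                                threshold = pipeline$concordance_threshold)
  }
  unresolved <- sum(is.na(resolved$reported_ts))
  if (unresolved > 0) {
    warn(sprintf("%d sample(s) remain unresolved after a third run; dropped.",
                 unresolved))
  }

  ltl <- resolved %>%
    filter(!is.na(.data$reported_ts)) %>%
    inner_join(select(sim$draws, "sample_id", "subject_id", "timepoint",
                      "postpartum_days", "pseudo_ga"),
               by = "sample_id") %>%
    select("sample_id", "subject_id", "timepoint", "postpartum_days",
           "pseudo_ga", "reported_ts", "concordant", "n_measurements")

  qc <- assay_cv(filter(adjusted, .data$role == "control"))

  comparisons <- compare_timepoints(ltl, holm = pipeline$holm)

  postpartum <- ltl %>%
    filter(.data$timepoint == 3, !is.na(.data$postpartum_days)) %>%
    inner_join(select(sim$cohort, "subject_id", "delivery_mode", "age"),
               by = "subject_id")
  mode_rank_sum <- if (length(unique(postpartum$delivery_mode)) == 2) {
    rank_sum_by_mode(postpartum$reported_ts, postpartum$delivery_mode)
  } else NULL
  mode_model <- tryCatch(
    delivery_mode_model(postpartum),
    error = function(e) NULL
  )

  descriptives <- describe_cohort(
    select(sim$cohort, "age", "bmi", "race", "private_insurance", "college",
           "spontaneous_conception", "delivery_mode", "epds")
  )
  completeness <- completeness_range(
    select(sim$survey, -"subject_id")
  )

  # Screening outcomes: Timepoint 1 LTL and mean LTL across available draws.
  types <- attr(sim$survey, "feature_types")
  per_subject <- ltl %>%
    group_by(.data$subject_id) %>%
    summarise(
      t1 = if (any(.data$timepoint == 1))
        .data$reported_ts[.data$timepoint == 1][1] else NA_real_,
      mean_ltl = mean(.data$reported_ts), .groups = "drop"
    )
  svy <- sim$survey %>%
    inner_join(per_subject, by = "subject_id")
  feats <- setdiff(names(sim$survey), "subject_id")
  associations_t1 <- screen_features(svy[c("subject_id", feats)], svy$t1,
                                     types = types)
  associations_mean <- screen_features(svy[c("subject_id", feats)],
                                       svy$mean_ltl, types = types)
  imputed <- impute_median(svy[c("subject_id", feats)], types = types)
  network <- correlation_network(imputed, associations_t1,
                                 embed_seed = pipeline$embed_seed,
                                 perplexity = pipeline$perplexity)
  complete_rows <- !is.na(svy$t1) & !is.na(svy$mean_ltl)
  cv_t1 <- cv_predict(imputed[complete_rows, ], svy$t1[complete_rows],
                      folds = min(pipeline$cv_folds, sum(complete_rows)),
                      seed = child_seed(config$seed, 404L),
                      n_perm = pipeline$cv_n_perm)
  cv_mean <- cv_predict(imputed[complete_rows, ], svy$mean_ltl[complete_rows],
                        folds = min(pipeline$cv_folds, sum(complete_rows)),
                        seed = child_seed(config$seed, 505L),
                        n_perm = pipeline$cv_n_perm)

  res <- structure(
    list(
      sim = sim,
      curves = attr(quants, "curves"),
      quants = adjusted,
      ltl = ltl,
      assay_qc = qc,
      timepoint_comparisons = comparisons,
      mode_rank_sum = mode_rank_sum,
      mode_model = mode_model,
      descriptives = descriptives,
      completeness = completeness,
      associations_t1 = associations_t1,
      associations_mean = associations_mean,
      network = network,
      cv_t1 = cv_t1,
      cv_mean = cv_mean,
      provenance = list(
        seed = config$seed,
        sim_config = unclass(config),
        pipeline_config = unclass(pipeline),
        package_version = as.character(utils::packageVersion("telopipe"))
      )
    ),
    class = "telo_results"
  )
  if (!is.null(out_dir)) write_results(res, out_dir)
  res
}

#' @export
print.telo_results <- function(x, ...) {
  cat("Telomere pipeline results\n")
  cat(sprintf("  samples quantified: %d (%d subjects)\n",
              nrow(x$ltl), length(unique(x$ltl$subject_id))))
  cat(sprintf("  assay CV: %.2f%%\n", x$assay_qc$cv_percent))
  means <- x$ltl %>% group_by(.data$timepoint) %>%
    summarise(m = mean(.data$reported_ts), s = sd(.data$reported_ts),
              .groups = "drop")
  for (i in seq_len(nrow(means))) {
    cat(sprintf("  mean T/S at timepoint %d: %.2f +/- %.2f\n",
                means$timepoint[i], means$m[i], means$s[i]))
  }
  if (!is.null(x$mode_model)) {
    cat(sprintf("  cesarean effect on log T/S: %.3f (95%% CI %.3f to %.3f)\n",
                x$mode_model$estimate, x$mode_model$ci_low, x$mode_model$ci_high))
  }
  invisible(x)
}

# ---- file-format contracts -------------------------------------------------
# CSV dialect: UTF-8, comma-separated, header row, "." decimal, missing as
# empty cell. Gestational age always travels as two integer columns
# (weeks, days); pseudo-GA separately as decimal weeks.

#' Write / read a plate-well CSV
#'
#' Columns: `run_id`, `well`, `sample_id`, `target`, `role`, `quantity_ng`
#' (standards only), `cq`.
#'
#' @param plates Plate table.
#' @param path File path.
#' @return `path` (writer) or the plate tibble (reader).
#' @export
write_plate_csv <- function(plates, path) {
  readr::write_csv(
    select(plates, "run_id", "well", "sample_id", "target", "role",
           "quantity_ng", "cq"),
    path, na = ""
  )
  invisible(path)
}

#' @rdname write_plate_csv
#' @export
read_plate_csv <- function(path) {
  readr::read_csv(
    path, na = "",
    col_types = readr::cols(
      run_id = readr::col_character(), well = readr::col_character(),
      sample_id = readr::col_character(), target = readr::col_character(),
      role = readr::col_character(), quantity_ng = readr::col_double(),
      cq = readr::col_double()
    )
  )
}

#' Write all pipeline outputs to a directory
#'
#' Emits `plates.csv`, `cohort.csv`, `draws.csv`, `survey.csv`,
#' `quantified.csv` (per-run adjusted quantifications), `ltl.csv` (reported
#' per-sample T/S), `associations_t1.csv`, `associations_mean.csv`,
#' `descriptives.csv`, `network.json` and `results.json` (statistics +
#' provenance).
#'
#' @param results A [run_pipeline()] result.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_results <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(out_dir, f)
  write_plate_csv(results$sim$plates, fp("plates.csv"))
  readr::write_csv(results$sim$cohort, fp("cohort.csv"), na = "")
  readr::write_csv(results$sim$draws, fp("draws.csv"), na = "")
  readr::write_csv(results$sim$survey, fp("survey.csv"), na = "")
  readr::write_csv(
    select(results$quants, -dplyr::any_of(c("t_removed", "s_removed"))),
    fp("quantified.csv"), na = ""
  )
  readr::write_csv(
    mutate(results$ltl, runs_used = NULL),
    fp("ltl.csv"), na = ""
  )
  readr::write_csv(results$associations_t1, fp("associations_t1.csv"), na = "")
  readr::write_csv(results$associations_mean, fp("associations_mean.csv"), na = "")
  readr::write_csv(results$descriptives, fp("descriptives.csv"), na = "")
  write_network_json(results$network, fp("network.json"))
  jsonlite::write_json(
    list(
      assay_cv_percent = results$assay_qc$cv_percent,
      timepoint_comparisons = results$timepoint_comparisons,
      mode_rank_sum = results$mode_rank_sum,
      mode_model = results$mode_model,
      completeness = as.list(results$completeness),
      cv_t1 = tidy(results$cv_t1),
      cv_mean = tidy(results$cv_mean),
      provenance = results$provenance
    ),
    fp("results.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE,
    force = TRUE
  )
  invisible(out_dir)
}
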