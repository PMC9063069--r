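# Duplicate concordance, third-run resolution, control-DNA batch adjustment.

#' Check concordance of duplicate T/S measurements
#'
#' Two measurements are concordant when their absolute difference relative to
#' their mean is at most `threshold` (default 7%). The denominator convention
#' (mean of the two values) is symmetric in the pair; alternatives can be
#' selected with `denominator`.
#'
#' @param a,b Positive T/S ratios (vectorised).
#' @param threshold Relative-difference threshold as a fraction (default 0.07).
#' @param denominator One of "mean" (default), "first", "min".
#' @return Logical vector: `TRUE` where the pair is concordant.
#' @export
concordance_check <- function(a, b, threshold = 0.07,
                              denominator = c("mean", "first", "min")) {
  denominator <- match.arg(denominator)
  assert_positive(a, "a"); assert_positive(b, "b")
  base <- switch(denominator,
                 mean = (a + b) / 2,
                 first = a,
                 min = pmin(a, b))
  abs(a - b) / base <= threshold
}

#' Resolve 2--3 replicate T/S measurements to one reported value
#'
#' Each sample's T/S is measured twice; when the duplicates differ by more
#' than the concordance threshold the sample is run a third time and the two
#' closest values are reported (as their mean). With two concordant
#' measurements the reported value is their mean. Ties in closeness among the
#' three pairs are broken toward the pair containing the earliest run.
#'
#' @param measurements 2 or 3 positive T/S values, ordered by run.
#' @param run_ids Optional run identifiers aligned with `measurements`.
#' @param threshold Concordance threshold (fraction).
#' @return A one-row tibble: `reported_ts` (NA when a third run is needed),
#'   `concordant`, `needs_third`, `n_measurements`, and `runs_used`
#'   (list-column of the run ids behind the reported value).
#' @export
resolve_replicates <- function(measurements, run_ids = seq_along(measurements),
                               threshold = 0.07) {
  n <- length(measurements)
  if (!n %in% c(2L, 3L)) {
    abort("resolve_replicates() expects 2 or 3 measurements.")
  }
  assert_positive(measurements, "measurements")
  if (n == 2L) {
    ok <- concordance_check(measurements[1], measurements[2], threshold)
    return(tibble(
      reported_ts = if (ok) mean(measurements) else NA_real_,
      concordant = ok,
      needs_third = !ok,
      n_measurements = 2L,
      runs_used = list(if (ok) run_ids else run_ids[0])
    ))
  }
  # Three measurements: the first two were discordant; report the mean of the
  # closest pair. Pairs enumerated as (1,2), (1,3), (2,3); strict "<" keeps
  # the earlier pair on ties, i.e. the pair containing the earliest run.
  pairs <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  gaps <- map_dbl(pairs, ~ abs(diff(measurements[.x])))
  best <- pairs[[which.min(gaps)]]
  tibble(
    reported_ts = mean(measurements[best]),
    concordant = FALSE,
    needs_third = FALSE,
    n_measurements = 3L,
    runs_used = list(run_ids[best])
  )
}

#' Resolve replicates for every sample in a quantification table
#'
#' @param quants Per-run quantification table (e.g. from [quantify_plates()]
#'   after [adjust_batches()]) with columns `sample_id`, `run_id` and the
#'   value column named by `value`.
#' @param value Name of the T/S column to resolve (default `"adjusted_ts"`).
#' @param threshold Concordance threshold.
#' @return One row per sample: `sample_id`, `reported_ts`, `concordant`,
#'   `needs_third`, `n_measurements`, `runs_used`.
#' @export
resolve_samples <- function(quants, value = "adjusted_ts", threshold = 0.07) {
  quants %>%
    arrange(.data$sample_id, .data$run_id) %>%
    group_by(.data$sample_id) %>%
    group_modify(~ resolve_replicates(.x[[value]], .x$run_id, threshold)) %>%
    ungroup()
}

#' Build the per-control reference from the first runs of a batch
#'
#' The reference is the per-control arithmetic mean T/S across the first
#' `n_reference_runs` runs (default 10, matching the convention of anchoring
#' the batch to its opening runs). Fewer available runs are allowed with a
#' warning.
#'
#' @param controls Table of per-run control measurements: `run_id`,
#'   `sample_id` (control identity), and the column named by `value`.
#' @param n_reference_runs Number of opening runs to average (default 10).
#' @param value Value column name (default `"raw_ts"`).
#' @return Tibble `sample_id`, `reference_ts`, `n_runs`.
#' @export
build_reference <- function(controls, n_reference_runs = 10, value = "raw_ts") {
  run_order <- unique(controls$run_id)
  use_runs <- head(run_order, n_reference_runs)
  if (length(use_runs) < n_reference_runs) {
    warn(sprintf("Only %d run(s) available for the reference (requested %d).",
                 length(use_runs), n_reference_runs))
  }
  sub <- controls %>% filter(.data$run_id %in% use_runs)
  counts <- sub %>% count(.data$sample_id)
  if (any(counts$n < length(use_runs))) {
    abort("Every control must be present in every reference run.")
  }
  sub %>%
    group_by(.data$sample_id) %>%
    summarise(reference_ts = mean(.data[[value]]),
              n_runs = n(), .groups = "drop")
}

#' Build one run's batch adjustment from its control measurements
#'
#' Each control contributes a factor `reference / observed`; the run factor is
#' the arithmetic mean of the control factors. A run reading high is thereby
#' scaled down (verified by the drift-cancellation property on noiseless
#' synthetic data).
#'
#' @param run_controls One run's control table: `sample_id` and `value` column.
#' @param reference Output of [build_reference()].
#' @param value Value column name (default `"raw_ts"`).
#' @return An object of class `batch_adjustment`: list with `run_id`,
#'   `control_factors` (named), `run_factor`.
#' @export
build_adjustment <- function(run_controls, reference, value = "raw_ts") {
  joined <- run_controls %>%
    inner_join(reference, by = "sample_id")
  if (nrow(joined) < nrow(reference)) {
    abort("Run is missing one or more reference controls.")
  }
  factors <- setNames(joined$reference_ts / joined[[value]], joined$sample_id)
  if (any(!is.finite(factors)) || any(factors <= 0)) {
    abort("Adjustment factors must be positive and finite.")
  }
  structure(
    list(run_id = run_controls$run_id[1] %||% NA,
         control_factors = factors,
         run_factor = mean(factors)),
    class = "batch_adjustment"
  )
}

#' Apply a batch adjustment to one run's raw T/S values
#'
#' @param raw_ts Numeric vector of raw T/S ratios from the run.
#' @param adjustment A [build_adjustment()] result for the same run.
#' @return Adjusted T/S values: `raw_ts * run_factor`.
#' @export
adjust_run <- function(raw_ts, adjustment) {
  stopifnot(inherits(adjustment, "batch_adjustment"))
  raw_ts * adjustment$run_factor
}

#' Batch-adjust a full quantification table
#'
#' Builds the control reference from the opening runs, derives each run's
#' adjustment factor from its 8 control DNAs, and converts raw to adjusted
#' T/S ratios for every sample.
#'
#' @param quants Quantification table from [quantify_plates()] (must contain
#'   control rows with `role == "control"`).
#' @param n_reference_runs Runs used for the reference (default 10).
#' @return `quants` with `run_factor` and `adjusted_ts` columns added. The
#'   reference table and per-run adjustments are attached as attributes
#'   `"reference"` and `"adjustments"`.
#' @export
adjust_batches <- function(quants, n_reference_runs = 10) {
  controls <- quants %>% filter(.data$role == "control")
  if (nrow(controls) == 0) abort("No control rows found; cannot batch-adjust.")
  reference <- build_reference(controls, n_reference_runs)
  adjustments <- controls %>%
    group_by(.data$run_id) %>%
    group_map(~ build_adjustment(mutate(.x, run_id = .y$run_id), reference))
  names(adjustments) <- map_chr(adjustments, ~ as.character(.x$run_id))
  factors <- tibble(
    run_id = unname(map_chr(adjustments, ~ as.character(.x$run_id))),
    run_factor = unname(map_dbl(adjustments, "run_factor"))
  )
  out <- quants %>%
    mutate(.run_chr = as.character(.data$run_id)) %>%
    left_join(factors, by = c(".run_chr" = "run_id")) %>%
    select(-".run_chr") %>%
    mutate(adjusted_ts = .data$raw_ts * .data$run_factor)
  attr(out, "reference") <- reference
  attr(out, "adjustments") <- adjustments
  out
}

#' Assay precision from repeated control measurements
#'
#' Coefficient of variation of the LTL assay: per-control CV = SD/mean of its
#' repeated (adjusted) T/S values; the headline `cv_percent` is the mean of
#' the per-control CVs, in percent.
#'
#' @param control_history Table with `sample_id` (control identity) and the
#'   value column named by `value`, one row per repeated measurement.
#' @param value Value column (default `"adjusted_ts"`).
#' @return Object of class `assay_qc`: list with `per_control` tibble
#'   (`sample_id`, `n`, `mean`, `sd`, `cv`) and `cv_percent`.
#' @export
assay_cv <- function(control_history, value = "adjusted_ts") {
  per <- control_history %>%
    group_by(.data$sample_id) %>%
    summarise(n = n(),
              mean = mean(.data[[value]]),
              sd = sd(.data[[value]]),
              .groups = "drop") %>%
    filter(.data$n >= 2) %>%
    mutate(cv = .data$sd / .data$mean)
  if (nrow(per) == 0) {
    abort("assay_cv() needs at least one control with >= 2 measurements.")
  }
  structure(
    list(per_control = per, cv_percent = mean(per$cv) * 100),
    class = "assay_qc"
  )
}

#' @export
print.assay_qc <- function(x, ...) {
  cat(sprintf("Assay CV: %.2f%% (mean over %d controls)\n",
              x$cv_percent, nrow(x$per_control)))
  invisible(x)
}
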