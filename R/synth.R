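# Synthetic plate / cohort / survey generator with known ground truth.
#
# The generator emulates the full measurement chain of a longitudinal
# pregnancy LTL study: per-subject true T/S trajectories over three
# gestational draw windows, qPCR plates (standard dilution series, 8 repeated
# control DNAs, triplicate wells, between-run drift, gross outlier wells),
# and a mixed-type perceived-stress survey with a planted sleep-quality
# effect. Every emitted row has a ground-truth entry so downstream stages can
# be tested by parameter recovery.

#' The reference DNA dilution series (ng)
#'
#' The six-point reference dilution series included in every PCR run for
#' standard-curve quantification.
#' @return Numeric vector of input quantities in ng.
#' @export
reference_dilution_series <- function() c(26, 8.75, 2.9, 0.97, 0.324, 0.108)

#' Simulation configuration
#'
#' Defaults reproduce the study conditions of a healthy nulliparous pregnancy
#' cohort: baseline T/S 1.15 +/- 0.26, a total within-person drift of -0.07
#' T/S across pregnancy, a cesarean rate of 39.1% with a -0.18 log T/S effect
#' on postpartum draws, PCR efficiencies of 93.2% (T) and 94.0% (S), and a
#' 79-feature stress survey.
#'
#' @param n_subjects Number of subjects (default 46).
#' @param true_efficiency_T,true_efficiency_S Per-cycle amplification
#'   efficiencies as fractions in (0, 1.2].
#' @param cq_noise_sd Well-level Cq noise SD in cycles. The default 0.04 is
#'   calibrated so the pipeline's control-based CV lands near 2.2%.
#' @param outlier_rate Probability that a triplicate contains one gross
#'   outlier well (Cq displaced by 5--10 cycles, random sign).
#' @param batch_drift_sd Log-scale SD of the multiplicative per-run batch
#'   drift applied to true T quantities.
#' @param baseline_ts_mean,baseline_ts_sd Between-subject baseline T/S
#'   distribution.
#' @param within_person_drift Total true T/S change across pregnancy (from
#'   the mean Timepoint 1 draw, 12 weeks, to the mean Timepoint 3 draw,
#'   43 pseudo-GA weeks).
#' @param residual_log_sd Within-person log-scale residual SD per draw:
#'   biological fluctuation around the planted trajectory, part of each
#'   draw's true T/S.
#' @param cesarean_log_effect Planted log T/S shift on postpartum draws of
#'   cesarean subjects.
#' @param cesarean_rate Probability of cesarean birth.
#' @param sleep_effect Planted baseline T/S shift per SD of the latent
#'   sleep-quality score.
#' @param n_features Number of stress-survey features (default 79).
#' @param missing_rate Cell-level missingness rate of the survey.
#' @param samples_per_run Unknown samples per qPCR run (plates also carry the
#'   dilution series and 8 control DNAs).
#' @param wells_per_control Replicate wells per control DNA per target
#'   (default 3, i.e. 6 wells per control across the two targets).
#' @param intercept_T,intercept_S Standard-curve intercepts (Cq at 1 ng).
#' @param seed Integer seed; identical configurations give identical output.
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_subjects = 46,
                       true_efficiency_T = 0.932,
                       true_efficiency_S = 0.940,
                       cq_noise_sd = 0.04,
                       outlier_rate = 0.02,
                       batch_drift_sd = 0.06,
                       baseline_ts_mean = 1.15,
                       baseline_ts_sd = 0.26,
                       within_person_drift = -0.07,
                       residual_log_sd = 0.13,
                       cesarean_log_effect = -0.18,
                       cesarean_rate = 0.391,
                       sleep_effect = 0.16,
                       n_features = 79,
                       missing_rate = 0.05,
                       samples_per_run = 12,
                       wells_per_control = 3,
                       intercept_T = 21,
                       intercept_S = 28,
                       seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$n_subjects < 1) abort("`n_subjects` must be >= 1.")
  for (f in c("cesarean_rate", "outlier_rate", "missing_rate")) {
    assert_fraction(cfg[[f]], f)
  }
  for (f in c("true_efficiency_T", "true_efficiency_S")) {
    if (cfg[[f]] <= 0 || cfg[[f]] > 1.2) {
      abort(sprintf("`%s` must be in (0, 1.2].", f))
    }
  }
  for (f in c("cq_noise_sd", "batch_drift_sd", "baseline_ts_sd",
              "residual_log_sd")) {
    if (cfg[[f]] < 0) abort(sprintf("`%s` must be >= 0.", f))
  }
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

# Slope of a standard curve implied by a per-cycle efficiency.
efficiency_to_slope <- function(efficiency) -1 / log10(1 + efficiency)

#' Simulate a reference dilution series
#'
#' Standard wells with `Cq = intercept + slope * log10(quantity) + noise`.
#'
#' @param slope Cycles per log10(ng); negative for a valid assay.
#' @param intercept Cq at 1 ng.
#' @param quantities Input quantities in ng (default: the six-point reference
#'   series from [reference_dilution_series()]).
#' @param noise_sd Cq noise SD in cycles.
#' @param seed Integer seed.
#' @return Tibble `quantity_ng`, `cq`.
#' @export
simulate_dilution_series <- function(slope, intercept,
                                     quantities = reference_dilution_series(),
                                     noise_sd = 0, seed = 1L) {
  assert_positive(quantities, "quantities")
  if (length(unique(quantities)) < 2) {
    abort("Need at least 2 distinct quantities.")
  }
  withr::with_seed(seed, {
    tibble(
      quantity_ng = quantities,
      cq = intercept + slope * log10(quantities) +
        rnorm(length(quantities), 0, noise_sd)
    )
  })
}

# Fixed panel of 8 control DNAs, drawn once per configuration seed.
control_panel <- function(config) {
  withr::with_seed(child_seed(config$seed, 101L), {
    tibble(
      sample_id = sprintf("ctrl%02d", 1:8),
      true_ts = pmax(0.4, rnorm(8, config$baseline_ts_mean, config$baseline_ts_sd)),
      s_ng = 6.6
    )
  })
}

#' Simulate one qPCR run (both targets)
#'
#' Emits one run's plate wells: the reference dilution series (singlet wells
#' per target), the 8 control DNAs and each manifest sample in triplicate per
#' target. A log-normal run multiplier (SD `batch_drift_sd`) scales every true
#' T quantity, planting a between-run batch effect on the T/S scale; with
#' probability `outlier_rate` one well of a triplicate is displaced by 5--10
#' Cq cycles (random sign) and flagged in the ground truth.
#'
#' @param config A [sim_config()].
#' @param run_index Run number (1-based); also seeds the run.
#' @param samples Manifest tibble with `sample_id` and `true_ts` (one row per
#'   unknown on the run).
#' @return List: `plate` (tibble `run_id`, `well`, `sample_id`, `target`,
#'   `role`, `quantity_ng`, `cq`), `multiplier` (the true run batch factor),
#'   `outliers` (tibble of flagged wells).
#' @export
simulate_plate_run <- function(config, run_index, samples) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(samples) == 0) abort("`samples` manifest must be nonempty.")
  run_id <- sprintf("run%03d", run_index)
  slopes <- c(T = efficiency_to_slope(config$true_efficiency_T),
              S = efficiency_to_slope(config$true_efficiency_S))
  intercepts <- c(T = config$intercept_T, S = config$intercept_S)
  controls <- control_panel(config)

  withr::with_seed(child_seed(config$seed, 1000L + run_index), {
    multiplier <- exp(rnorm(1, 0, config$batch_drift_sd))
    # Per-sample DNA input varies around the nominal 6.6 ng per reaction.
    input_ng <- 6.6 * exp(rnorm(nrow(samples), 0, 0.15))
    specs <- bind_rows(
      tibble(sample_id = controls$sample_id, role = "control",
             s_ng = controls$s_ng, true_ts = controls$true_ts,
             n_wells = config$wells_per_control),
      tibble(sample_id = samples$sample_id, role = "unknown",
             s_ng = input_ng, true_ts = samples$true_ts, n_wells = 3L)
    )
    wells <- list()
    outliers <- list()
    for (tgt in c("T", "S")) {
      std <- tibble(
        sample_id = NA_character_, target = tgt, role = "standard",
        quantity_ng = reference_dilution_series(),
        true_q = reference_dilution_series()
      )
      smp <- specs %>%
        mutate(true_q = if (tgt == "T") .data$s_ng * .data$true_ts * multiplier
               else .data$s_ng) %>%
        tidyr::uncount(.data$n_wells) %>%
        transmute(.data$sample_id, target = tgt, .data$role,
                  quantity_ng = NA_real_, .data$true_q)
      wells[[tgt]] <- bind_rows(std, smp)
    }
    plate <- bind_rows(wells) %>%
      mutate(
        run_id = run_id,
        well = sprintf("W%03d", seq_len(n())),
        cq = intercepts[.data$target] + slopes[.data$target] * log10(.data$true_q) +
          rnorm(n(), 0, config$cq_noise_sd),
        outlier = FALSE
      )
    # Gross outliers: at most one displaced well per sample x target triplicate.
    trip <- plate %>%
      filter(.data$role != "standard") %>%
      distinct(.data$sample_id, .data$target)
    hit <- runif(nrow(trip)) < config$outlier_rate
    for (i in which(hit)) {
      idx <- which(plate$sample_id == trip$sample_id[i] &
                     plate$target == trip$target[i])
      w <- sample(idx, 1)
      plate$cq[w] <- plate$cq[w] + sample(c(-1, 1), 1) * runif(1, 5, 10)
      plate$outlier[w] <- TRUE
    }
    outliers <- plate %>%
      filter(.data$outlier) %>%
      select("run_id", "well", "sample_id", "target")
    plate <- plate %>%
      select("run_id", "well", "sample_id", "target", "role",
             "quantity_ng", "cq", "outlier")
    list(plate = plate, multiplier = multiplier, outliers = outliers)
  })
}

#' Simulate the full plate schedule for a set of samples
#'
#' Every sample is measured twice: replicate A runs fill the opening plates
#' (which also anchor the batch-adjustment reference) and replicate B runs
#' repeat the same groups on later plates.
#'
#' @param config A [sim_config()].
#' @param samples Tibble `sample_id`, `true_ts`.
#' @param start_run_index First run number to use (default 1).
#' @return List: `plates` (all wells), `runs` (tibble `run_id`,
#'   `multiplier`), `outliers`, `next_run_index`.
#' @export
simulate_plates <- function(config, samples, start_run_index = 1L) {
  groups <- split(samples, ceiling(seq_len(nrow(samples)) / config$samples_per_run))
  schedule <- c(groups, groups)  # replicate A then replicate B
  runs <- map(seq_along(schedule), function(i) {
    simulate_plate_run(config, start_run_index + i - 1L, schedule[[i]])
  })
  list(
    plates = list_rbind(map(runs, "plate")),
    runs = tibble(
      run_id = map_chr(runs, ~ .x$plate$run_id[1]),
      multiplier = map_dbl(runs, "multiplier")
    ),
    outliers = list_rbind(map(runs, "outliers")),
    next_run_index = start_run_index + length(schedule)
  )
}

#' Simulate the pregnancy cohort and draw manifest
#'
#' Each subject receives up to three blood draws inside the study's
#' gestational windows (draw probabilities mirror the observed per-timepoint
#' sample counts). The planted true T/S trajectory is
#' `baseline + within_person_drift * progress`, with progress 0 at 12
#' pseudo-GA weeks and 1 at 43 weeks; cesarean subjects' postpartum draws are
#' further shifted by `cesarean_log_effect` on the log scale. The latent
#' sleep-quality score shifts the baseline by `sleep_effect` per SD.
#'
#' @param config A [sim_config()].
#' @return List: `cohort` (one row per subject), `draws` (one row per draw,
#'   with GA as integer weeks + days, `postpartum_days`, `pseudo_ga`,
#'   `timepoint`, and `measured_ts`, the assay-free LTL equal to the per-draw
#'   truth, for analyses that skip the plate stage), and `truth` (list with
#'   `subjects` and `draws` ground-truth tibbles).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_subjects
  withr::with_seed(child_seed(config$seed, 202L), {
    sleep_z <- rnorm(n)
    resid_sd <- sqrt(max(0, config$baseline_ts_sd^2 - config$sleep_effect^2))
    baseline <- pmax(0.3, config$baseline_ts_mean +
                       config$sleep_effect * sleep_z + rnorm(n, 0, resid_sd))
    cesarean <- runif(n) < config$cesarean_rate
    deliv_days <- pmin(294L, pmax(259L, round(rnorm(n, 39.1, 1.3) * 7)))
    cohort <- tibble(
      subject_id = sprintf("S%03d", seq_len(n)),
      age = round(rnorm(n, 29.8, 3.8), 1),
      bmi = ifelse(runif(n) < 0.109, NA_real_, round(rnorm(n, 21.7, 2.8), 1)),
      race = ifelse(runif(n) < 0.022, NA_character_,
                    sample(c("White", "Asian", "Hispanic", "Indian", "Multi-race"),
                           n, replace = TRUE,
                           prob = c(0.578, 0.156, 0.133, 0.067, 0.066))),
      private_insurance = runif(n) < 0.913,
      college = ifelse(runif(n) < 0.109, NA,
                       runif(n) < 0.878),
      spontaneous_conception = runif(n) < 0.891,
      delivery_mode = ifelse(cesarean, "cesarean", "vaginal"),
      ga_delivery_weeks = deliv_days %/% 7L,
      ga_delivery_days = deliv_days %% 7L,
      epds = ifelse(runif(n) < 0.3, NA_real_, pmax(0, round(rnorm(n, 4.4, 3.3))))
    )

    has <- cbind(runif(n) < 41 / 46, runif(n) < 39 / 46, runif(n) < 35 / 46)
    none <- rowSums(has) == 0
    has[none, 1] <- TRUE
    draws <- map(seq_len(n), function(i) {
      out <- list()
      if (has[i, 1]) {
        d <- pmin(139L, pmax(35L, round(rnorm(1, 12.0, 2.6) * 7)))
        out$t1 <- tibble(ga_total_days = d, postpartum_days = NA_real_)
      }
      if (has[i, 2]) {
        d <- pmin(258L, pmax(141L, round(rnorm(1, 26.5, 1.8) * 7)))
        out$t2 <- tibble(ga_total_days = d, postpartum_days = NA_real_)
      }
      if (has[i, 3]) {
        if (runif(1) < 0.914) {
          pp <- pmin(63, pmax(1, round(rnorm(1, 26, 14))))
          out$t3 <- tibble(ga_total_days = deliv_days[i], postpartum_days = pp)
        } else {
          d <- if (deliv_days[i] > 259L) sample(259:deliv_days[i], 1) else 259L
          out$t3 <- tibble(ga_total_days = as.integer(d), postpartum_days = NA_real_)
        }
      }
      list_rbind(out) %>% mutate(subject_id = cohort$subject_id[i])
    }) %>% list_rbind()

    draws <- draws %>%
      mutate(
        ga_weeks = .data$ga_total_days %/% 7L,
        ga_days = .data$ga_total_days %% 7L,
        pseudo_ga = ifelse(
          is.na(.data$postpartum_days),
          .data$ga_total_days / 7,
          postpartum_to_pseudo_ga(.data$ga_weeks, .data$ga_days,
                                  .data$postpartum_days)
        ),
        timepoint = assign_timepoint(.data$ga_weeks, .data$ga_days,
                                     .data$postpartum_days),
        sample_id = sprintf("%s_T%d", .data$subject_id, .data$timepoint)
      ) %>%
      left_join(tibble(subject_id = cohort$subject_id,
                       .baseline = baseline, .cesarean = cesarean),
                by = "subject_id") %>%
      mutate(
        progress = (.data$pseudo_ga - 12) / 31,
        # Per-draw truth: planted trajectory, a cesarean log shift on
        # postpartum draws, and within-person biological fluctuation.
        true_ts = pmax(
          0.2,
          .data$.baseline + config$within_person_drift * .data$progress
        ) * exp(ifelse(.data$.cesarean & !is.na(.data$postpartum_days),
                       config$cesarean_log_effect, 0) +
                  rnorm(n(), 0, config$residual_log_sd)),
        measured_ts = .data$true_ts
      ) %>%
      select("subject_id", "sample_id", "timepoint", "ga_weeks", "ga_days",
             "postpartum_days", "pseudo_ga", "measured_ts", "true_ts") %>%
      arrange(.data$subject_id, .data$timepoint)

    truth <- list(
      subjects = tibble(subject_id = cohort$subject_id,
                        baseline_ts = baseline, sleep_z = sleep_z,
                        cesarean = cesarean),
      draws = draws %>% select("sample_id", "subject_id", "timepoint", "true_ts")
    )
    list(cohort = cohort,
         draws = draws %>% select(-"true_ts"),
         truth = truth)
  })
}

#' Simulate a block-correlated feature matrix
#'
#' Low-level helper: numeric features organised in equicorrelated blocks
#' (`x = sqrt(r) * factor + sqrt(1 - r) * noise`), so the within-block
#' pairwise correlation is `r_within` and between-block correlation is 0 in
#' expectation.
#'
#' @param n Number of rows (subjects).
#' @param block_sizes Integer vector of features per block.
#' @param r_within Common within-block correlation in [0, 1).
#' @param seed Integer seed.
#' @return Matrix `n x sum(block_sizes)` with a `block` attribute.
#' @export
simulate_correlated_features <- function(n, block_sizes, r_within, seed = 1L) {
  assert_fraction(r_within, "r_within")
  withr::with_seed(seed, {
    blocks <- rep(seq_along(block_sizes), block_sizes)
    f <- matrix(rnorm(n * length(block_sizes)), n)
    x <- sqrt(r_within) * f[, blocks, drop = FALSE] +
      sqrt(1 - r_within) * matrix(rnorm(n * length(blocks)), n)
    colnames(x) <- sprintf("F%02d", seq_along(blocks))
    attr(x, "block") <- blocks
    x
  })
}

#' Simulate the perceived-stress survey
#'
#' Emits `n_features` mixed-type features over the cohort's subjects. The
#' first feature, `sleep_quality`, is a monotone transform of the latent
#' sleep score that shifts true baseline T/S (the planted association). The
#' remaining features load on 8 latent factors (loadings drawn once per
#' seed), giving the correlated block structure a feature network needs, and
#' are rendered as numeric, binary (0/1) or small-integer categorical
#' columns. Cells are then masked missing-completely-at-random at
#' `missing_rate`.
#'
#' @param config A [sim_config()].
#' @param cohort Cohort table from [simulate_cohort()].
#' @param truth Ground truth from [simulate_cohort()] (supplies the latent
#'   sleep scores).
#' @return Tibble `subject_id` + features, with attribute `feature_types`
#'   (named character vector "numeric"/"binary"/"categorical") and attribute
#'   `planted_effects` (tibble `feature`, `effect`).
#' @export
simulate_stress_survey <- function(config, cohort, truth) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(cohort) == 0) abort("`cohort` must be nonempty.")
  n <- nrow(cohort)
  p <- config$n_features
  sleep_z <- truth$subjects$sleep_z[match(cohort$subject_id,
                                          truth$subjects$subject_id)]
  withr::with_seed(child_seed(config$seed, 303L), {
    n_factors <- 8L
    lambda <- runif(p - 1, 0.5, 0.85)
    fac_of <- rep_len(seq_len(n_factors), p - 1)
    latent <- matrix(rnorm(n * n_factors), n)
    raw <- latent[, fac_of, drop = FALSE] * rep(lambda, each = n) +
      matrix(rnorm(n * (p - 1)), n) * rep(sqrt(1 - lambda^2), each = n)

    # Type schedule: numeric / binary / categorical cycling over features.
    types <- rep_len(c("numeric", "binary", "numeric", "categorical", "binary"),
                     p - 1)
    cols <- map(seq_len(p - 1), function(j) {
      x <- raw[, j]
      switch(types[j],
             numeric = round(x, 3),
             binary = as.integer(x > stats::quantile(x, runif(1, 0.3, 0.7))),
             categorical = as.integer(cut(x, breaks = sample(3:5, 1))))
    })
    names(cols) <- sprintf("feat%02d", seq_len(p - 1) + 1L)
    survey <- tibble(
      subject_id = cohort$subject_id,
      sleep_quality = round(5 + 1.5 * sleep_z, 3),
      !!!cols
    )
    feature_types <- c(sleep_quality = "numeric", setNames(types, names(cols)))

    # MCAR missingness on feature cells.
    if (config$missing_rate > 0) {
      for (v in names(feature_types)) {
        miss <- runif(n) < config$missing_rate
        survey[[v]][miss] <- NA
      }
    }
    attr(survey, "feature_types") <- feature_types
    attr(survey, "planted_effects") <- tibble(
      feature = names(feature_types),
      effect = c(config$sleep_effect, rep(0, p - 1))
    )
    survey
  })
}

#' Simulate a complete study bundle
#'
#' Convenience wrapper: cohort + draws, stress survey, and the full two-
#' replicate plate schedule for every draw.
#'
#' @param config A [sim_config()].
#' @return List of class `telo_sim`: `config`, `cohort`, `draws`, `survey`,
#'   `plates`, `runs`, `outliers`, `truth`, `next_run_index`.
#' @export
simulate_study <- function(config = sim_config()) {
  sim <- simulate_cohort(config)
  survey <- simulate_stress_survey(config, sim$cohort, sim$truth)
  samples <- sim$truth$draws %>% select("sample_id", "true_ts")
  pl <- simulate_plates(config, samples)
  structure(
    list(config = config, cohort = sim$cohort, draws = sim$draws,
         survey = survey, plates = pl$plates, runs = pl$runs,
         outliers = pl$outliers, truth = sim$truth,
         next_run_index = pl$next_run_index),
    class = "telo_sim"
  )
}
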