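# Timepoint assignment and longitudinal cohort statistics.

# Draw windows in gestational days (week^day/7 notation):
# Timepoint 1 up to 20^0/7, Timepoint 2 from 20^1/7 to 36^6/7, Timepoint 3
# from 37^0/7 through 9 weeks postpartum.
.t1_max_days <- 20L * 7L        # 140: boundary day assigned to Timepoint 1
.t2_max_days <- 36L * 7L + 6L   # 258
.t3_min_days <- 37L * 7L        # 259
.pp_max_days <- 63L             # 9 weeks postpartum

#' Assign a blood draw to a gestational timepoint
#'
#' Timepoint 1: up to 20^0/7 weeks; Timepoint 2: 20^1/7 to 36^6/7 weeks;
#' Timepoint 3: 37^0/7 weeks or any postpartum draw within 9 weeks of
#' delivery. A draw at exactly 20^0/7 weeks sits on the boundary the window
#' definitions leave open; it is assigned to Timepoint 1 with a warning.
#'
#' @param ga_weeks Completed gestational weeks at draw (vectorised). For a
#'   postpartum draw, pass the GA at delivery (ignored for assignment).
#' @param ga_days Additional days (0--6), default 0.
#' @param postpartum_days Days since delivery, or NA for antepartum draws.
#' @return Integer vector of timepoints (1, 2 or 3). Postpartum draws beyond
#'   9 weeks (63 days) are out of window and raise an error.
#' @export
assign_timepoint <- function(ga_weeks, ga_days = 0L, postpartum_days = NA_real_) {
  n <- max(length(ga_weeks), length(ga_days), length(postpartum_days))
  ga_weeks <- rep_len(ga_weeks, n)
  ga_days <- rep_len(ga_days, n)
  postpartum_days <- rep_len(postpartum_days, n)
  if (any(ga_days < 0 | ga_days > 6, na.rm = TRUE)) {
    abort("`ga_days` must be in 0..6.")
  }
  pp <- !is.na(postpartum_days)
  if (any(postpartum_days[pp] < 0) || any(postpartum_days[pp] > .pp_max_days)) {
    abort(sprintf("Postpartum draw beyond %d days (9 weeks) is out of window.",
                  .pp_max_days))
  }
  total_days <- ga_weeks * 7L + ga_days
  if (any(total_days < 0 | !is.finite(total_days))) {
    abort("Invalid gestational age.")
  }
  tp <- rep(NA_integer_, n)
  tp[pp] <- 3L
  ante <- !pp
  tp[ante & total_days <= .t1_max_days] <- 1L
  tp[ante & total_days > .t1_max_days & total_days <= .t2_max_days] <- 2L
  tp[ante & total_days >= .t3_min_days] <- 3L
  if (any(ante & total_days == .t1_max_days)) {
    warn("Draw at exactly 20^0/7 weeks assigned to Timepoint 1 (window boundary).")
  }
  tp
}

#' Postpartum draw time on the pseudo-gestational-age scale
#'
#' Postpartum samples are recorded on a common time scale as gestational age
#' at delivery plus postpartum time, capped at 50 weeks.
#'
#' @param ga_weeks,ga_days Gestational age at delivery (completed weeks +
#'   0--6 days).
#' @param postpartum_days Days since delivery (0--63).
#' @return Pseudo-gestational age in decimal weeks, `<= 50`.
#' @export
postpartum_to_pseudo_ga <- function(ga_weeks, ga_days = 0L, postpartum_days = 0) {
  if (any(postpartum_days < 0 | postpartum_days > .pp_max_days, na.rm = TRUE)) {
    abort("`postpartum_days` must be in 0..63.")
  }
  pmin(ga_weeks + ga_days / 7 + postpartum_days / 7, 50)
}

# Wilcoxon conventions shared by both tests: exact distributions when the
# sample is small and untied, normal approximation with mid-rank tie
# correction otherwise.
.signed_rank <- function(diffs) {
  diffs <- diffs[diffs != 0]
  n <- length(diffs)
  if (n == 0) {
    warn("No informative pairs (all differences zero); p = 1.")
    return(list(statistic = NA_real_, p_value = 1, n_informative = 0L))
  }
  exact <- n <= 25 && !any(duplicated(abs(diffs)))
  ht <- suppressWarnings(wilcox.test(diffs, exact = exact, correct = !exact))
  list(statistic = unname(ht$statistic), p_value = ht$p.value, n_informative = n)
}

#' Paired within-person LTL comparison between two timepoints
#'
#' Computes per-subject differences (later minus earlier timepoint) for
#' subjects measured at both, summarises them as mean and SD, and tests the
#' null of no within-person change with the two-sided Wilcoxon signed-rank
#' test. Zero differences are dropped; the exact distribution is used when
#' the informative n is at most 25 with untied absolute differences, and the
#' normal approximation with tie correction otherwise.
#'
#' @param ltl Long table with columns `subject_id`, `timepoint`, and the LTL
#'   column named by `value`.
#' @param pair Length-2 vector of timepoints, earlier first (e.g. `c(1, 3)`).
#' @param value LTL column name (default `"reported_ts"`).
#' @return One-row tibble: `timepoint_a`, `timepoint_b`, `n_pairs`,
#'   `n_informative`, `mean_diff`, `sd_diff`, `statistic` (signed-rank V),
#'   `p_value`.
#' @export
paired_differences <- function(ltl, pair, value = "reported_ts") {
  stopifnot(length(pair) == 2)
  wide <- ltl %>%
    filter(.data$timepoint %in% pair) %>%
    select("subject_id", "timepoint", all_of(value)) %>%
    tidyr::pivot_wider(names_from = "timepoint", values_from = all_of(value),
                       names_prefix = "tp")
  for (cn in paste0("tp", pair)) {
    if (!cn %in% names(wide)) wide[[cn]] <- NA_real_
  }
  wide <- tidyr::drop_na(wide)
  if (nrow(wide) == 0) {
    warn("No subjects with both timepoints; empty result.")
    return(tibble(timepoint_a = pair[1], timepoint_b = pair[2], n_pairs = 0L,
                  n_informative = 0L, mean_diff = NA_real_, sd_diff = NA_real_,
                  statistic = NA_real_, p_value = NA_real_))
  }
  diffs <- wide[[paste0("tp", pair[2])]] - wide[[paste0("tp", pair[1])]]
  sr <- .signed_rank(diffs)
  tibble(
    timepoint_a = pair[1], timepoint_b = pair[2],
    n_pairs = length(diffs), n_informative = sr$n_informative,
    mean_diff = mean(diffs), sd_diff = sd(diffs),
    statistic = sr$statistic, p_value = sr$p_value
  )
}

#' All pairwise timepoint comparisons
#'
#' Runs [paired_differences()] for timepoint pairs (1,2), (2,3) and (1,3).
#' No multiplicity correction is applied by default; `holm = TRUE` adds a
#' Holm-adjusted column.
#'
#' @inheritParams paired_differences
#' @param holm Add Holm-adjusted p-values?
#' @return Tibble with one row per pair.
#' @export
compare_timepoints <- function(ltl, value = "reported_ts", holm = FALSE) {
  out <- list(c(1, 2), c(2, 3), c(1, 3)) %>%
    map(~ paired_differences(ltl, .x, value = value)) %>%
    list_rbind()
  if (holm) out <- mutate(out, p_holm = stats::p.adjust(.data$p_value, "holm"))
  out
}

#' Rank-sum comparison of postpartum LTL by delivery mode
#'
#' Two-sided Wilcoxon rank-sum test comparing LTL between two delivery-mode
#' groups. Exact p-value when the combined sample is at most 20 without ties,
#' normal approximation otherwise.
#'
#' @param ltl Numeric LTL values.
#' @param mode Group labels aligned with `ltl` (exactly 2 observed levels,
#'   e.g. "vaginal"/"cesarean").
#' @return One-row tibble: group ns and means, `statistic` (rank-sum W for the
#'   first sorted level), `p_value`.
#' @export
rank_sum_by_mode <- function(ltl, mode) {
  keep <- !is.na(ltl) & !is.na(mode)
  ltl <- ltl[keep]; mode <- as.character(mode[keep])
  lev <- sort(unique(mode))
  if (length(lev) != 2) abort("`mode` must have exactly 2 observed groups.")
  x <- ltl[mode == lev[1]]; y <- ltl[mode == lev[2]]
  if (length(x) == 0 || length(y) == 0) abort("Both groups must be nonempty.")
  exact <- (length(x) + length(y)) <= 20 && !any(duplicated(c(x, y)))
  ht <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = !exact))
  tibble(
    group_a = lev[1], group_b = lev[2],
    n_a = length(x), n_b = length(y),
    mean_a = mean(x), mean_b = mean(y),
    statistic = unname(ht$statistic), p_value = ht$p.value
  )
}

#' Age-adjusted delivery-mode regression on log LTL
#'
#' Ordinary least squares of log(LTL) on a cesarean indicator and maternal
#' age. The coefficient of interest is the cesarean effect on the log T/S
#' scale, with its 95% confidence interval.
#'
#' @param data Data frame with one row per subject.
#' @param ltl,mode,age Column names (strings) for postpartum LTL (> 0),
#'   delivery mode, and maternal age.
#' @param cesarean_level Level of `mode` coding cesarean (default "cesarean").
#' @return One-row tibble: `term`, `estimate`, `ci_low`, `ci_high`,
#'   `p_value`, `n`. The full `lm` fit is attached as attribute `"fit"`.
#' @export
delivery_mode_model <- function(data, ltl = "reported_ts",
                                mode = "delivery_mode", age = "age",
                                cesarean_level = "cesarean") {
  df <- tibble(
    ltl = data[[ltl]],
    cesarean = as.integer(data[[mode]] == cesarean_level),
    age = data[[age]]
  ) %>% tidyr::drop_na()
  assert_positive(df$ltl, ltl)
  if (min(table(df$cesarean)) < 3) {
    abort("Need at least 3 observations in each delivery-mode group.")
  }
  fit <- lm(log(ltl) ~ cesarean + age, data = df)
  if (any(!is.finite(coef(fit)))) abort("Singular design in delivery-mode model.")
  ci <- confint(fit, "cesarean", level = 0.95)
  out <- tibble(
    term = "cesarean",
    estimate = unname(coef(fit)["cesarean"]),
    ci_low = ci[1], ci_high = ci[2],
    p_value = summary(fit)$coefficients["cesarean", 4],
    n = nrow(df)
  )
  attr(out, "fit") <- fit
  out
}

#' Descriptive cohort table with missing-excluding percentages
#'
#' Continuous variables are summarised as mean ± SD; categorical variables as
#' n (percent), where each variable's percentage denominator excludes its own
#' missing values. Percentages are rounded half-up to 1 decimal, matching
#' printed clinical tables.
#'
#' @param data Cohort data frame, one row per subject.
#' @param variables Named character vector mapping column names to
#'   `"continuous"` or `"categorical"`. When NULL, numeric columns with more
#'   than 6 distinct values are treated as continuous, everything else as
#'   categorical.
#' @return Tibble: `variable`, `type`, `level` (NA for continuous),
#'   `n` (category count), `n_nonmissing`, `percent`, `mean`, `sd`, and a
#'   formatted `label` ("n (x.x%)" or "m ± sd").
#' @export
describe_cohort <- function(data, variables = NULL) {
  if (is.null(variables)) {
    variables <- map_chr(names(data), function(v) {
      x <- data[[v]]
      if (is.numeric(x) && length(unique(x[!is.na(x)])) > 6) "continuous"
      else "categorical"
    })
    names(variables) <- names(data)
  }
  imap(variables, function(type, var) {
    x <- data[[var]]
    obs <- x[!is.na(x)]
    if (type == "continuous") {
      tibble(variable = var, type = type, level = NA_character_,
             n = NA_integer_, n_nonmissing = length(obs),
             percent = NA_real_, mean = mean(obs), sd = sd(obs),
             label = sprintf("%.1f ± %.1f", mean(obs), sd(obs)))
    } else {
      tab <- table(obs)
      tibble(variable = var, type = type, level = names(tab),
             n = as.integer(tab), n_nonmissing = length(obs),
             percent = round_half_up(100 * as.integer(tab) / length(obs), 1),
             mean = NA_real_, sd = NA_real_) %>%
        mutate(label = sprintf("%d (%.1f%%)", .data$n, .data$percent))
    }
  }) %>% list_rbind()
}

#' Range of per-item survey completeness
#'
#' Completeness of an item is the number of respondents divided by the number
#' eligible to answer it, in percent (half-up, 1 decimal).
#'
#' @param survey Data frame of survey items (one column per item); a cell is
#'   a response, NA is missing.
#' @param eligible Eligible denominator per item: a single number applied to
#'   all items (default: number of rows) or a vector named by or aligned with
#'   the columns.
#' @return Named numeric vector `c(min = , max = )` of completeness percent.
#' @export
completeness_range <- function(survey, eligible = nrow(survey)) {
  if (length(eligible) == 1) eligible <- rep(eligible, ncol(survey))
  if (any(eligible <= 0)) abort("`eligible` denominators must be positive.")
  answered <- map_int(survey, ~ sum(!is.na(.x)))
  pct <- round_half_up(100 * answered / eligible, 1)
  c(min = min(pct), max = max(pct))
}
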