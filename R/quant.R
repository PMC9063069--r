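# Standard-curve quantification and triplicate QC: plate wells -> raw T/S.

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Cq on log10(input quantity) over a reference
#' dilution series. The slope determines the per-cycle amplification
#' efficiency, `E = (10^(-1/slope) - 1) * 100` percent (100% for perfect
#' doubling chemistry, slope -3.32).
#'
#' @param standards Data frame with columns `quantity_ng` (> 0) and `cq`,
#'   one row per standard well.
#' @param target Optional label ("T" or "S") carried into the result.
#'
#' @return An object of class `standard_curve`: a list with `target`,
#'   `slope` (cycles per log10 ng), `intercept` (Cq at 1 ng), `r_squared`,
#'   `efficiency` (percent), `n_wells`, and the quantity range of the series
#'   (`quantity_min`, `quantity_max`) used to flag extrapolation.
#'
#' A warning is emitted if the efficiency falls outside the conventional
#' 80--110% acceptance band; a non-negative slope is an error (no
#' amplification-dependent signal).
#'
#' @examples
#' std <- tibble::tibble(quantity_ng = c(10, 1, 0.1),
#'                       cq = c(26.678072, 30, 33.321928))
#' fit_standard_curve(std)
#' @export
fit_standard_curve <- function(standards, target = NA_character_) {
  stopifnot(is.data.frame(standards),
            all(c("quantity_ng", "cq") %in% names(standards)))
  q <- standards$quantity_ng
  cq <- standards$cq
  assert_positive(q, "quantity_ng")
  if (length(unique(q)) < 2) {
    abort("Standard-curve fit needs at least 2 distinct quantities.")
  }
  fit <- lm(cq ~ log10(q))
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope >= 0) {
    abort("Invalid assay: standard-curve slope must be negative (Cq falls as input rises).")
  }
  eff <- (10^(-1 / slope) - 1) * 100
  if (eff < 80 || eff > 110) {
    warn(sprintf("PCR efficiency %.1f%% outside the 80-110%% acceptance band.", eff))
  }
  structure(
    list(
      target = target,
      slope = slope,
      intercept = unname(coef(fit)[1]),
      r_squared = suppressWarnings(summary(fit)$r.squared),
      efficiency = eff,
      n_wells = length(cq),
      quantity_min = min(q),
      quantity_max = max(q)
    ),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "Standard curve%s: slope %.4f, intercept %.3f, E = %.1f%%, r2 = %.4f (%d wells)\n",
    if (is.na(x$target)) "" else paste0(" [", x$target, "]"),
    x$slope, x$intercept, x$efficiency, x$r_squared, x$n_wells
  ))
  invisible(x)
}

#' @export
tidy.standard_curve <- function(x, ...) {
  tibble(
    target = x$target, slope = x$slope, intercept = x$intercept,
    r_squared = x$r_squared, efficiency = x$efficiency, n_wells = x$n_wells
  )
}

#' Interpolate template quantity from a Cq value
#'
#' Inverts the standard curve: `quantity = 10^((cq - intercept) / slope)`.
#' Warns when the interpolated quantity falls outside the dilution-series
#' range (extrapolation beyond the calibrated region).
#'
#' @param cq Numeric vector of quantification cycles.
#' @param curve A [fit_standard_curve()] result.
#' @return Numeric vector of quantities (ng relative to the reference DNA).
#' @export
interpolate_quantity <- function(cq, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  q <- 10^((cq - curve$intercept) / curve$slope)
  # small relative tolerance so quantities at the series endpoints do not
  # trip the extrapolation warning through floating-point round-off
  out <- q < curve$quantity_min * (1 - 1e-9) |
    q > curve$quantity_max * (1 + 1e-9)
  if (any(out, na.rm = TRUE)) {
    warn(sprintf(
      "%d quantit%s outside the standard range [%.3g, %.3g] ng (extrapolated).",
      sum(out, na.rm = TRUE), if (sum(out, na.rm = TRUE) == 1) "y" else "ies",
      curve$quantity_min, curve$quantity_max
    ))
  }
  q
}

# Two-tailed Dixon r10 critical values for n = 3 (Rorabacher 1991).
.dixon_crit_n3 <- c("0.1" = 0.941, "0.05" = 0.970, "0.01" = 0.994)

#' Dixon's Q test on a qPCR triplicate
#'
#' Identifies at most one gross outlier among three replicate quantities.
#' The suspect is the extremum farther from the median;
#' `Q = |suspect - nearest neighbour| / range`, and the suspect is removed
#' when Q exceeds the two-tailed critical value for n = 3.
#'
#' @param values Exactly 3 finite quantities.
#' @param alpha Test level; one of 0.10, 0.05 (default), 0.01.
#' @return An object of class `triplicate_qc`: list with `values`,
#'   `q_statistic` (NA when the range is zero), `removed_index` (NA or 1--3),
#'   `kept` (retained values) and `kept_mean`.
#'
#' @examples
#' dixon_q_test(c(1.0, 1.02, 2.5))  # removes 2.5
#' @export
dixon_q_test <- function(values, alpha = 0.05) {
  if (length(values) != 3 || any(!is.finite(values))) {
    abort("dixon_q_test() requires exactly 3 finite values.")
  }
  key <- as.character(alpha)
  if (!key %in% names(.dixon_crit_n3)) {
    abort("`alpha` must be one of 0.10, 0.05, 0.01 for the n = 3 table.")
  }
  rng <- max(values) - min(values)
  if (rng == 0) {
    return(structure(
      list(values = values, q_statistic = NA_real_, removed_index = NA_integer_,
           kept = values, kept_mean = mean(values)),
      class = "triplicate_qc"
    ))
  }
  med <- median(values)
  # Suspect: extremum farther from the median (ties resolved toward the max;
  # a symmetric triple can never exceed Q = 0.5 so the choice is inert).
  suspect_idx <- if ((max(values) - med) >= (med - min(values))) {
    which.max(values)
  } else {
    which.min(values)
  }
  others <- values[-suspect_idx]
  gap <- min(abs(values[suspect_idx] - others))
  q_stat <- gap / rng
  removed <- if (q_stat > .dixon_crit_n3[[key]]) suspect_idx else NA_integer_
  kept <- if (is.na(removed)) values else values[-removed]
  structure(
    list(values = values, q_statistic = q_stat, removed_index = removed,
         kept = kept, kept_mean = mean(kept)),
    class = "triplicate_qc"
  )
}

#' @export
print.triplicate_qc <- function(x, ...) {
  cat(sprintf(
    "Triplicate QC: Q = %s; %s; kept mean %.4g\n",
    if (is.na(x$q_statistic)) "undefined (zero range)" else sprintf("%.4f", x$q_statistic),
    if (is.na(x$removed_index)) "no well removed"
    else sprintf("removed well %d (%.4g)", x$removed_index, x$values[x$removed_index]),
    x$kept_mean
  ))
  invisible(x)
}

#' Quantify one sample from its T and S triplicates
#'
#' Applies Dixon's Q to each target's triplicate on the Cq scale (where well
#' noise is approximately normal and the test is symmetric in the outlier's
#' direction), interpolates the retained wells to quantities, and reports
#' `raw_ts = mean(T quantities kept) / mean(S quantities kept)`. Averaging is
#' on the concentration scale (not mean-Cq-then-interpolate). On the quantity
#' scale a well displaced toward low quantity compresses Q toward the ratio
#' of the two good wells and gross outliers escape the test, which is why the
#' test runs on Cq.
#'
#' @param t_cq,s_cq Triplicate Cq values for the telomere (T) and single-copy
#'   gene (S) reactions.
#' @param curve_t,curve_s Standard curves for the two targets.
#' @param dixon_alpha Level for the triplicate outlier test.
#' @param sample_id Optional identifier carried into the result.
#' @return A one-row tibble: `sample_id`, `t_quantity`, `s_quantity`,
#'   `raw_ts`, `t_q`, `s_q` (Q statistics), `t_removed`, `s_removed`
#'   (1-based removed well index or NA).
#' @export
quantify_sample <- function(t_cq, s_cq, curve_t, curve_s,
                            dixon_alpha = 0.05, sample_id = NA_character_) {
  if (length(t_cq) != 3 || length(s_cq) != 3) {
    abort("quantify_sample() expects triplicate Cq values for both targets.")
  }
  t_qc <- dixon_q_test(t_cq, alpha = dixon_alpha)
  s_qc <- dixon_q_test(s_cq, alpha = dixon_alpha)
  keep_t <- if (is.na(t_qc$removed_index)) 1:3 else (1:3)[-t_qc$removed_index]
  keep_s <- if (is.na(s_qc$removed_index)) 1:3 else (1:3)[-s_qc$removed_index]
  t_mean <- mean(interpolate_quantity(t_cq[keep_t], curve_t))
  s_mean <- mean(interpolate_quantity(s_cq[keep_s], curve_s))
  if (!is.finite(t_mean) || !is.finite(s_mean) || t_mean <= 0 || s_mean <= 0) {
    abort("Quantification failed: non-positive mean quantity after QC.")
  }
  tibble(
    sample_id = sample_id,
    t_quantity = t_mean,
    s_quantity = s_mean,
    raw_ts = t_mean / s_mean,
    t_q = t_qc$q_statistic,
    s_q = s_qc$q_statistic,
    t_removed = t_qc$removed_index,
    s_removed = s_qc$removed_index
  )
}

#' Fit per-run, per-target standard curves from a plate table
#'
#' @param plates Plate-well table with columns `run_id`, `sample_id`,
#'   `target` ("T"/"S"), `role` ("standard"/"control"/"unknown"),
#'   `quantity_ng` (standards only) and `cq`.
#' @return A tibble with one row per (run, target): slope, intercept,
#'   r_squared, efficiency, plus a `curve` list-column of `standard_curve`
#'   objects. Curves are fit per run; no pooling across runs.
#' @export
fit_run_curves <- function(plates) {
  plates %>%
    filter(.data$role == "standard") %>%
    group_by(.data$run_id, .data$target) %>%
    group_modify(function(df, key) {
      cv <- fit_standard_curve(df, target = key$target)
      tidy(cv) %>% select(-"target") %>% mutate(curve = list(cv))
    }) %>%
    ungroup()
}

#' Quantify all samples on one or more plates
#'
#' For every run and target, fits the run's standard curve, then converts
#' each control/unknown triplicate to a quantity with Dixon QC and forms the
#' raw T/S ratio.
#'
#' @inheritParams fit_run_curves
#' @param dixon_alpha Level for the triplicate outlier test.
#' @return A tibble with one row per (run, sample): `run_id`, `sample_id`,
#'   `role`, `t_quantity`, `s_quantity`, `raw_ts`, Q statistics and removed
#'   well indices. The per-run curve table is attached as attribute
#'   `"curves"` (also available via [fit_run_curves()]).
#' @export
quantify_plates <- function(plates, dixon_alpha = 0.05) {
  stopifnot(all(c("run_id", "sample_id", "target", "role", "cq") %in% names(plates)))
  curves <- fit_run_curves(plates)
  curve_of <- function(run, tgt) {
    curves$curve[[which(curves$run_id == run & curves$target == tgt)[1]]]
  }
  res <- plates %>%
    filter(.data$role != "standard") %>%
    tidyr::pivot_wider(
      id_cols = c("run_id", "sample_id", "role"),
      names_from = "target", values_from = "cq", values_fn = list
    ) %>%
    pmap(function(run_id, sample_id, role, T, S) {
      quantify_sample(unlist(T), unlist(S),
                      curve_of(run_id, "T"), curve_of(run_id, "S"),
                      dixon_alpha = dixon_alpha, sample_id = sample_id) %>%
        mutate(run_id = run_id, role = role, .before = 1)
    }) %>%
    list_rbind() %>%
    relocate("sample_id", .after = "run_id")
  attr(res, "curves") <- curves
  res
}
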