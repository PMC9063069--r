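# Multivariate stress-profile screening against LTL.

#' Classify a survey feature by its observed values
#'
#' Rules: at most 2 observed distinct levels -> binary; non-numeric values or
#' integer-coded values with at most 6 distinct levels -> categorical;
#' otherwise numeric. Explicit declarations (e.g. for 7-level Likert items)
#' should override the inference via the `types` argument of the table-level
#' functions.
#'
#' @param values Vector of observed feature values (NA = missing).
#' @return One of `"numeric"`, `"categorical"`, `"binary"`.
#' @export
classify_feature <- function(values) {
  obs <- values[!is.na(values)]
  if (length(obs) == 0) abort("Cannot type an all-missing feature.")
  lev <- unique(obs)
  if (length(lev) <= 2) return("binary")
  if (!is.numeric(obs)) return("categorical")
  integer_coded <- all(abs(obs - round(obs)) < 1e-8)
  if (integer_coded && length(lev) <= 6) return("categorical")
  "numeric"
}

# Resolve declared + inferred types for a feature table.
feature_types <- function(table, types = NULL) {
  feats <- setdiff(names(table), "subject_id")
  inferred <- map_chr(table[feats], classify_feature)
  if (!is.null(types)) {
    bad <- setdiff(names(types), feats)
    if (length(bad)) abort(paste("Unknown features in `types`:", toString(bad)))
    inferred[names(types)] <- types
  }
  inferred
}

#' Univariate association between one feature and LTL
#'
#' Type-dispatched two-sided tests: Kendall's tau-b for numeric features,
#' Kruskal--Wallis across levels for categorical features, Wilcoxon rank-sum
#' for binary features. The direction is the sign of tau (numeric) or the
#' sign of the mean LTL difference between the higher- and lower-coded level
#' (binary); categorical tests are unsigned.
#'
#' @param feature Feature values (NA = missing).
#' @param ltl Per-subject LTL outcome aligned with `feature`.
#' @param type Feature type; inferred with [classify_feature()] when NULL.
#' @param feature_name Label carried into the result.
#' @return One-row tibble: `feature`, `type`, `test`, `statistic`, `p_value`,
#'   `direction`. A constant feature yields a degenerate result with p = 1.
#' @export
univariate_association <- function(feature, ltl, type = NULL,
                                   feature_name = NA_character_) {
  keep <- !is.na(feature) & !is.na(ltl)
  f <- feature[keep]; y <- ltl[keep]
  if (length(y) < 3) abort("Need at least 3 complete (feature, LTL) pairs.")
  type <- type %||% classify_feature(f)
  if (length(unique(f)) < 2) {
    return(tibble(feature = feature_name, type = type, test = "degenerate",
                  statistic = NA_real_, p_value = 1, direction = 0))
  }
  if (type == "numeric") {
    ht <- suppressWarnings(cor.test(as.numeric(f), y, method = "kendall"))
    tibble(feature = feature_name, type = type, test = "kendall_tau",
           statistic = unname(ht$estimate), p_value = ht$p.value,
           direction = sign(unname(ht$estimate)))
  } else if (type == "categorical") {
    ht <- kruskal.test(y, factor(f))
    tibble(feature = feature_name, type = type, test = "kruskal_wallis",
           statistic = unname(ht$statistic), p_value = ht$p.value,
           direction = 0)
  } else {
    lev <- sort(unique(f))
    lo <- y[f == lev[1]]; hi <- y[f == lev[2]]
    exact <- (length(lo) + length(hi)) <= 20 && !any(duplicated(c(lo, hi)))
    ht <- suppressWarnings(wilcox.test(hi, lo, exact = exact, correct = !exact))
    tibble(feature = feature_name, type = type, test = "rank_sum",
           statistic = unname(ht$statistic), p_value = ht$p.value,
           direction = sign(mean(hi) - mean(lo)))
  }
}

#' Screen every survey feature against LTL
#'
#' @param table Feature table (optionally with a `subject_id` column, which
#'   is ignored as a feature).
#' @param ltl LTL outcome aligned with the table's rows.
#' @param types Optional named character vector of declared feature types
#'   overriding inference.
#' @return Tibble with one [univariate_association()] row per feature.
#' @export
screen_features <- function(table, ltl, types = NULL) {
  ft <- feature_types(table, types)
  imap(ft, function(tp, v) {
    univariate_association(table[[v]], ltl, type = tp, feature_name = v)
  }) %>% list_rbind()
}

#' Median-impute a mixed-type feature table
#'
#' Numeric features: missing values replaced by the observed median. Binary
#' features: the median rounded to an observed level (nearest level, lower on
#' ties). Categorical features: the observed mode, ties broken toward the
#' lowest-coded level.
#'
#' @inheritParams screen_features
#' @return The table with no missing feature cells.
#' @export
impute_median <- function(table, types = NULL) {
  ft <- feature_types(table, types)
  for (v in names(ft)) {
    x <- table[[v]]
    miss <- is.na(x)
    if (!any(miss)) next
    obs <- x[!miss]
    if (length(obs) == 0) abort(sprintf("Feature `%s` is all-missing.", v))
    fill <- if (ft[v] == "numeric") {
      median(obs)
    } else if (ft[v] == "binary") {
      med <- median(as.numeric(obs))
      lev <- sort(unique(as.numeric(obs)))
      lev[which.min(abs(lev - med))]  # nearest observed level, lower on ties
    } else {
      tab <- sort(table(obs), decreasing = TRUE)
      modes <- names(tab)[tab == max(tab)]
      sort(modes)[1]
    }
    if (is.numeric(x)) fill <- as.numeric(fill)
    x[miss] <- fill
    table[[v]] <- x
  }
  table
}

# Encode a complete mixed-type table as a numeric matrix (factor/character
# columns become integer level codes in sorted level order).
encode_numeric <- function(table) {
  feats <- setdiff(names(table), "subject_id")
  m <- map(table[feats], function(x) {
    if (is.numeric(x)) as.numeric(x)
    else as.numeric(factor(x, levels = sort(unique(x))))
  })
  out <- do.call(cbind, m)
  rownames(out) <- NULL
  out
}

#' Correlation network of stress features with LTL association annotation
#'
#' Computes the Spearman correlation matrix of the (imputed, numerically
#' coded) feature table, embeds the rows of its absolute-value matrix in 2-D
#' with t-SNE (fixed seed and perplexity for determinism), and annotates each
#' node with its univariate LTL association: node size is -log10(p), nodes
#' are coloured when p < 0.1 (orange for positive, blue for negative
#' direction) and bold when p < 0.05. Edges connect feature pairs with
#' absolute correlation at least 0.3 (class "thin") or 0.7 (class "thick").
#'
#' @param table Complete (imputed) feature table.
#' @param associations Result of [screen_features()] covering all features.
#' @param embed_seed Seed for the embedding.
#' @param perplexity t-SNE perplexity; default `min(15, (p - 1) / 3)`.
#' @param thin,thick Absolute-correlation edge thresholds.
#' @return Object of class `ltl_network`: list with `nodes` (feature, x, y,
#'   p_value, direction, size, colored, color, bold), `edges` (undirected,
#'   one row per unordered pair: from, to, r, class), the correlation matrix
#'   `r`, and `params` (seed, perplexity, thresholds) recorded for
#'   reproducibility.
#' @export
correlation_network <- function(table, associations, embed_seed = 7L,
                                perplexity = NULL, thin = 0.3, thick = 0.7) {
  feats <- setdiff(names(table), "subject_id")
  if (anyNA(table[feats])) abort("Impute the table before building the network.")
  missing_assoc <- setdiff(feats, associations$feature)
  if (length(missing_assoc)) {
    abort(paste("Associations missing for:", toString(missing_assoc)))
  }
  m <- encode_numeric(table)
  r <- suppressWarnings(cor(m, method = "spearman"))
  if (anyNA(r)) {
    warn("Constant feature(s): correlation undefined, set to 0.")
    r[is.na(r)] <- 0
    diag(r) <- 1
  }
  a <- abs(r)
  p <- length(feats)
  perplexity <- perplexity %||% min(15, (p - 1) / 3)
  coords <- withr::with_seed(embed_seed, {
    Rtsne::Rtsne(a, dims = 2, perplexity = perplexity, theta = 0,
                 pca = FALSE, check_duplicates = FALSE, max_iter = 500)$Y
  })
  assoc <- associations[match(feats, associations$feature), ]
  nodes <- tibble(
    feature = feats,
    x = coords[, 1], y = coords[, 2],
    p_value = assoc$p_value,
    direction = assoc$direction,
    size = -log10(assoc$p_value),
    colored = assoc$p_value < 0.1,
    # unsigned tests (Kruskal-Wallis) have no direction to colour by
    color = ifelse(assoc$p_value >= 0.1 | assoc$direction == 0, "none",
                   ifelse(assoc$direction > 0, "orange", "blue")),
    bold = assoc$p_value < 0.05
  )
  pairs <- which(upper.tri(a), arr.ind = TRUE)
  rr <- r[pairs]
  keep <- abs(rr) >= thin
  edges <- tibble(
    from = feats[pairs[keep, 1]],
    to = feats[pairs[keep, 2]],
    r = rr[keep],
    class = ifelse(abs(rr[keep]) >= thick, "thick", "thin")
  )
  structure(
    list(nodes = nodes, edges = edges, r = r,
         params = list(embed_seed = embed_seed, perplexity = perplexity,
                       thin = thin, thick = thick)),
    class = "ltl_network"
  )
}

#' @export
print.ltl_network <- function(x, ...) {
  cat(sprintf(
    "LTL feature network: %d nodes, %d edges (%d thick), %d nodes at p < 0.1\n",
    nrow(x$nodes), nrow(x$edges), sum(x$edges$class == "thick"),
    sum(x$nodes$colored)
  ))
  invisible(x)
}

#' Write a network as node-link JSON
#'
#' @param network An `ltl_network`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_network_json <- function(network, path) {
  jsonlite::write_json(
    list(nodes = network$nodes, links = network$edges,
         params = network$params),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' Cross-validated multivariate prediction of LTL with a permutation null
#'
#' Trains a support-vector regression (radial kernel, default
#' hyperparameters) to predict LTL from the full stress profile, evaluated by
#' k-fold cross-validation (out-of-fold R-squared and MSE). Significance is
#' judged against a permutation null: the outcome is permuted `n_perm` times
#' and the CV metric recomputed with the same fold assignment; the observed
#' model is significant iff its R-squared exceeds the 95th percentile of the
#' null.
#'
#' @param table Complete (imputed) feature table.
#' @param ltl Outcome aligned with the table's rows.
#' @param folds Number of CV folds (default 10).
#' @param seed Seed for fold assignment and permutations.
#' @param n_perm Number of outcome permutations (default 100).
#' @return Object of class `cv_fit`: list with `r_squared`, `mse`,
#'   `null_r_squared` (vector), `null_q95`, `p_value` (permutation), and
#'   `significant`.
#' @export
cv_predict <- function(table, ltl, folds = 10, seed = 1L, n_perm = 100) {
  feats <- setdiff(names(table), "subject_id")
  if (anyNA(table[feats])) abort("Impute the table before cv_predict().")
  x <- encode_numeric(table)
  y <- as.numeric(ltl)
  n <- length(y)
  if (folds > n) abort("`folds` cannot exceed the number of subjects.")
  withr::with_seed(seed, {
    fold <- sample(rep_len(seq_len(folds), n))
    oof_r2 <- function(yy) {
      pred <- numeric(n)
      for (k in seq_len(folds)) {
        te <- fold == k
        fit <- e1071::svm(x[!te, , drop = FALSE], yy[!te])
        pred[te] <- predict(fit, x[te, , drop = FALSE])
      }
      c(r2 = 1 - sum((yy - pred)^2) / sum((yy - mean(yy))^2),
        mse = mean((yy - pred)^2))
    }
    obs <- oof_r2(y)
    null <- map_dbl(seq_len(n_perm), function(b) oof_r2(sample(y))[["r2"]])
  })
  q95 <- unname(quantile(null, 0.95))
  structure(
    list(r_squared = unname(obs[["r2"]]), mse = unname(obs[["mse"]]),
         null_r_squared = null, null_q95 = q95,
         p_value = (sum(null >= obs[["r2"]]) + 1) / (n_perm + 1),
         significant = obs[["r2"]] > q95,
         folds = folds, n_perm = n_perm, seed = seed),
    class = "cv_fit"
  )
}

#' @export
print.cv_fit <- function(x, ...) {
  cat(sprintf(
    "%d-fold CV SVR: out-of-fold R2 = %.3f (null 95th pct %.3f) -> %ssignificant (perm p = %.3f)\n",
    x$folds, x$r_squared, x$null_q95,
    if (x$significant) "" else "not ", x$p_value
  ))
  invisible(x)
}

#' @export
tidy.cv_fit <- function(x, ...) {
  tibble(r_squared = x$r_squared, mse = x$mse, null_q95 = x$null_q95,
         p_value = x$p_value, significant = x$significant)
}

#' @export
glance.cv_fit <- function(x, ...) {
  tibble(folds = x$folds, n_perm = x$n_perm, seed = x$seed,
         r_squared = x$r_squared, p_value = x$p_value)
}
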