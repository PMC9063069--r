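# Feature typing, type-dispatched associations, imputation, network, CV-SVR.

test_that("feature typing follows the level-count rules", {
  expect_equal(classify_feature(c(0, 1, 1, 0)), "binary")
  expect_equal(classify_feature(c("yes", "no", NA, "yes")), "binary")
  expect_equal(classify_feature(c(22.1, 25.3, 19.8)), "numeric")
  expect_equal(classify_feature(c(1, 2, 3, 4, 5, 1, 2)), "categorical")
  # a 7-level integer-coded item exceeds the 6-level rule -> numeric;
  # an explicit declaration overrides it at the table level
  likert <- sample(1:7, 30, replace = TRUE)
  expect_equal(classify_feature(likert), "numeric")
  tab <- tibble::tibble(q = likert)
  assoc <- screen_features(tab, rnorm(30), types = c(q = "categorical"))
  expect_equal(assoc$test, "kruskal_wallis")
  expect_error(classify_feature(c(NA, NA)), "all-missing")
})

test_that("association tests dispatch by type with signed directions", {
  y <- c(0.8, 0.9, 1.0, 1.1, 1.2, 1.3, 1.35, 1.5)
  # perfect concordance
  a <- univariate_association(seq_along(y), y, feature_name = "f")
  expect_equal(a$test, "kendall_tau")
  expect_equal(a$statistic, 1)
  expect_equal(a$direction, 1)
  expect_lt(a$p_value, 0.01)
  # binary enumeration oracle
  b <- univariate_association(c("A", "A", "B", "B"), c(1, 2, 3, 4))
  expect_equal(b$test, "rank_sum")
  expect_equal(b$p_value, 1 / 3, tolerance = 1e-12)
  expect_equal(b$direction, 1)  # higher-coded level B has larger LTL
  # constant feature degenerates to p = 1
  k <- univariate_association(rep(1, 8), y)
  expect_equal(k$p_value, 1)
  expect_equal(k$test, "degenerate")
  expect_error(univariate_association(c(1, 2), c(1, 2)), "at least 3")
})

test_that("Kruskal-Wallis with two groups agrees with the rank-sum decision", {
  set.seed(19)
  agree <- vapply(1:50, function(i) {
    f <- rep(c(1L, 2L), each = 25)
    y <- rnorm(50) + 0.4 * (f == 2)
    p_kw <- univariate_association(f, y, type = "categorical")$p_value
    p_rs <- univariate_association(f, y, type = "binary")$p_value
    abs(p_kw - p_rs) < 0.02 && ((p_kw < 0.05) == (p_rs < 0.05) ||
                                  min(abs(c(p_kw, p_rs) - 0.05)) < 0.01)
  }, logical(1))
  expect_gte(mean(agree), 0.95)
})

test_that("median imputation is type-aware and idempotent on complete data", {
  tab <- tibble::tibble(
    num = c(1, NA, 3, 10.5),
    bin = c(0, 0, 1, NA),
    cat = c("a", "b", NA, "b")
  )
  out <- impute_median(tab, types = c(num = "numeric", bin = "binary",
                                      cat = "categorical"))
  expect_equal(out$num[2], 3)          # median of {1, 3, 10.5}
  expect_equal(out$bin[4], 0)          # median of {0, 0, 1} is 0
  expect_equal(out$cat[3], "b")        # mode
  expect_false(anyNA(out))
  # binary median between levels rounds to an observed level (lower on ties)
  t2 <- impute_median(tibble::tibble(b = c(0, 0, 1, 1, NA)),
                      types = c(b = "binary"))
  expect_equal(t2$b[5], 0)
  # mode tie breaks toward the lowest-coded level
  t3 <- impute_median(tibble::tibble(c = c("b", "a", NA)),
                      types = c(c = "categorical"))
  expect_equal(t3$c[3], "a")
  # complete table passes through unchanged
  done <- tibble::tibble(x = 1:5, y = c(0, 1, 0, 1, 0))
  expect_identical(impute_median(done), done)
})

test_that("null sleep association has uniform p-values", {
  ps <- vapply(1:200, function(s) {
    cfg <- sim_config(n_subjects = 27, sleep_effect = 0, missing_rate = 0,
                      seed = 60000 + s)
    sim <- simulate_cohort(cfg)
    svy <- simulate_stress_survey(cfg, sim$cohort, sim$truth)
    t1 <- sim$draws$measured_ts[match(paste0(sim$cohort$subject_id, "_T1"),
                                      sim$draws$sample_id)]
    keep <- !is.na(t1)
    univariate_association(svy$sleep_quality[keep], t1[keep],
                           type = "numeric")$p_value
  }, numeric(1))
  # tau p-values at n = 27 are mildly discrete; ks.test's tie warning is inert
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

fixture_screen <- function(n = 30, seed = 5, p_extra = 8) {
  withr::with_seed(seed, {
    x <- simulate_correlated_features(n, c(p_extra / 2, p_extra / 2),
                                      r_within = 0.6, seed = seed)
    tab <- tibble::as_tibble(as.data.frame(x))
    y <- rnorm(n)
    list(tab = tab, y = y)
  })
}

test_that("network nodes and edges follow the figure conventions", {
  fx <- fixture_screen(n = 200, seed = 77)
  tab <- fx$tab
  tab$dup <- tab$F01  # a duplicated feature forces a thick r = 1 edge
  assoc <- screen_features(tab, fx$y)
  net <- correlation_network(tab, assoc, embed_seed = 3)
  dup_edge <- dplyr::filter(net$edges,
                            (from == "F01" & to == "dup") |
                              (from == "dup" & to == "F01"))
  expect_equal(nrow(dup_edge), 1)
  expect_equal(dup_edge$r, 1, tolerance = 1e-12)
  expect_equal(dup_edge$class, "thick")
  # no self-edges; thick edges all satisfy the thin threshold too
  expect_true(all(net$edges$from != net$edges$to))
  expect_true(all(abs(net$edges$r) >= 0.3))
  expect_true(all(abs(net$edges$r[net$edges$class == "thick"]) >= 0.7))
  # node annotation rules
  expect_equal(net$nodes$colored, net$nodes$p_value < 0.1)
  expect_equal(net$nodes$bold, net$nodes$p_value < 0.05)
  expect_equal(net$nodes$size, -log10(net$nodes$p_value))

  # determinism: identical table and seed give identical coordinates/edges
  net2 <- correlation_network(tab, assoc, embed_seed = 3)
  expect_identical(net$nodes, net2$nodes)
  expect_identical(net$edges, net2$edges)

  # edge classes match brute-force counts over the Spearman matrix
  brute <- oracle_edge_counts(net$r)
  expect_equal(sum(net$edges$class == "thin"), unname(brute["thin"]))
  expect_equal(sum(net$edges$class == "thick"), unname(brute["thick"]))
})

test_that("planted block structure shows up as within-block edges only", {
  x <- simulate_correlated_features(200, c(6, 6), r_within = 0.6, seed = 13)
  tab <- tibble::as_tibble(as.data.frame(x))
  blocks <- attr(x, "block")
  assoc <- screen_features(tab, rnorm(200))
  net <- correlation_network(tab, assoc, embed_seed = 1)
  block_of <- setNames(blocks, colnames(x))
  same_block <- block_of[net$edges$from] == block_of[net$edges$to]
  expect_true(all(same_block))                    # no cross-block edges
  expect_equal(nrow(net$edges), choose(6, 2) * 2) # all within-block pairs
})

test_that("independent features at n = 100 produce no thick edges", {
  x <- matrix(rnorm(100 * 20), 100)
  colnames(x) <- sprintf("V%02d", 1:20)
  tab <- tibble::as_tibble(as.data.frame(x))
  net <- correlation_network(tab, screen_features(tab, rnorm(100)),
                             embed_seed = 2)
  expect_equal(sum(net$edges$class == "thick"), 0)
})

test_that("cross-validated SVR finds strong signal and calibrates to its null", {
  withr::with_seed(11, {
    n <- 200
    tab <- tibble::as_tibble(as.data.frame(matrix(rnorm(n * 5), n)))
    y <- 2 * tab$V1  # exact linear function of one feature
  })
  fit <- cv_predict(tab, y, folds = 10, seed = 4, n_perm = 50)
  expect_gt(fit$r_squared, 0.9)
  expect_true(fit$significant)
  # a permuted outcome lands inside its own permutation band
  yperm <- withr::with_seed(21, sample(y))
  fit0 <- cv_predict(tab, yperm, folds = 10, seed = 4, n_perm = 50)
  expect_false(fit0$significant)
  expect_error(cv_predict(tab, y, folds = 201), "folds")
  expect_s3_class(tidy(fit), "tbl_df")
  expect_named(glance(fit), c("folds", "n_perm", "seed", "r_squared", "p_value"))
})
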