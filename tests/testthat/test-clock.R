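# Clock preprocessing, imputation, training, prediction, centering and
# group comparison.

make_cohort <- function(n = 120, n_genes = 400, n_age = 100,
                        slope_sd = 0.03, seed = 1) {
  cfg <- sim_count_config(n_genes = n_genes, samples_per_group = n,
                          groups = "quiescent",
                          n_senescence_genes_up = 0,
                          n_senescence_genes_down = 0,
                          n_age_genes = n_age, age_slope_sd = slope_sd,
                          age_range = c(20, 90), seed = seed)
  simulate_clock_cohort(cfg)
}

split_cohort <- function(cohort, frac = 0.25, seed = 1) {
  n <- ncol(cohort$counts)
  set.seed(seed)
  test <- sample.int(n, round(frac * n))
  list(train = count_matrix(cohort$counts[, -test, drop = FALSE],
                            cohort$sample_metadata[-test, , drop = FALSE]),
       test = count_matrix(cohort$counts[, test, drop = FALSE],
                           cohort$sample_metadata[test, , drop = FALSE]))
}

test_that("training-mode scaling standardizes and drops flat genes", {
  cohort <- make_cohort(n = 30, n_genes = 120, seed = 2)
  cm <- cohort
  cm$counts[5, ] <- 0          # all-zero gene: flat after transform
  z <- preprocess_expression(cm)
  expect_false(rownames(cm$counts)[5] %in% rownames(z))
  expect_true(rownames(cm$counts)[5] %in% attr(z, "dropped"))
  expect_equal(unname(rowMeans(z)), rep(0, nrow(z)), tolerance = 1e-12)
  expect_equal(unname(apply(z, 1, sd)), rep(1, nrow(z)), tolerance = 1e-12)
})

test_that("application-mode scaling reproduces a constant shift in z units", {
  cohort <- make_cohort(n = 40, n_genes = 150, seed = 3)
  z <- preprocess_expression(cohort)
  model <- train_clock(z, cohort$sample_metadata$age, seed = 1)
  # quadruple one gene in every sample: its log2 rises by ~2, so its
  # application-mode z rises by 2 / training SD
  g <- rownames(z)[10]
  shifted <- cohort
  shifted$counts[g, ] <- shifted$counts[g, ] * 4
  z2 <- preprocess_expression(shifted, model)
  expect_equal(mean(unclass(z2)[g, ] - unclass(z)[g, ]),
               2 / model$gene_sds[[g]], tolerance = 0.05)
  # doubling every count (all samples alike) leaves size factors unchanged
  # and shifts each gene's log2 by 1, i.e. its z by 1 / training SD
  doubled <- cohort
  doubled$counts <- cohort$counts * 2
  z3 <- preprocess_expression(doubled, model)
  shift <- rowMeans(unclass(z3)[rownames(z), ] - unclass(z)[rownames(z), ])
  expect_equal(shift, 1 / model$gene_sds[rownames(z)], tolerance = 0.05)
})

test_that("imputation fills missing clock genes with training means", {
  cohort <- make_cohort(n = 40, n_genes = 150, seed = 4)
  z <- preprocess_expression(cohort)
  model <- train_clock(z, cohort$sample_metadata$age, seed = 1)
  # drop 30 genes from the input entirely
  sub <- cohort
  drop_genes <- rownames(cohort$counts)[21:50]
  sub$counts <- cohort$counts[setdiff(rownames(cohort$counts), drop_genes), ]
  zs <- preprocess_expression(sub, model)
  expect_true(anyNA(zs))
  zi <- impute_missing(zs, model)
  expect_false(anyNA(zi))
  expect_true(all(unclass(zi)[drop_genes, ] == 0))
  expect_equal(attr(zi, "n_imputed"),
               length(drop_genes) * ncol(cohort$counts))
  # no missing genes: values unchanged, zero imputations recorded
  z_full <- preprocess_expression(cohort, model)
  z_imp <- impute_missing(z_full, model)
  expect_equal(attr(z_imp, "n_imputed"), 0L)
  expect_equal(unclass(z_imp), unclass(z_full), ignore_attr = "n_imputed")
})

test_that("all clock genes missing predicts the intercept", {
  cohort <- make_cohort(n = 40, n_genes = 150, seed = 5)
  z <- preprocess_expression(cohort)
  model <- train_clock(z, cohort$sample_metadata$age, seed = 1)
  blank <- matrix(0, length(model$gene_ids), 3,
                  dimnames = list(model$gene_ids, paste0("s", 1:3)))
  attr(blank, "preprocessed") <- TRUE
  pred <- predict_tage(model, blank)
  expect_equal(unname(pred), rep(model$intercept, 3))
})

test_that("training is deterministic and rejects degenerate input", {
  cohort <- make_cohort(n = 40, n_genes = 150, seed = 6)
  z <- preprocess_expression(cohort)
  m1 <- train_clock(z, cohort$sample_metadata$age, seed = 7)
  m2 <- train_clock(z, cohort$sample_metadata$age, seed = 7)
  expect_identical(m1$coefficients, m2$coefficients)
  expect_error(train_clock(z, rep(50, ncol(z)), seed = 1), "constant")
  raw <- matrix(rnorm(40 * ncol(z)), 40,
                dimnames = list(paste0("g", 1:40), colnames(z)))
  expect_error(train_clock(raw, cohort$sample_metadata$age),
               "preprocess_expression")
})

test_that("held-out age recovery exceeds r = 0.9 on an informative cohort", {
  cohort <- make_cohort(n = 160, n_genes = 500, n_age = 200,
                        slope_sd = 0.02, seed = 8)
  parts <- split_cohort(cohort, seed = 8)
  z <- preprocess_expression(parts$train)
  model <- train_clock(z, parts$train$sample_metadata$age, seed = 1)
  zt <- impute_missing(preprocess_expression(parts$test, model), model)
  pred <- predict_tage(model, zt)
  expect_gt(cor(pred, parts$test$sample_metadata$age), 0.9)
})

test_that("a zero-slope cohort trains to a near-intercept model", {
  cohort <- make_cohort(n = 80, n_genes = 200, slope_sd = 0, seed = 9)
  parts <- split_cohort(cohort, seed = 9)
  z <- preprocess_expression(parts$train)
  model <- train_clock(z, parts$train$sample_metadata$age, seed = 1)
  zt <- impute_missing(preprocess_expression(parts$test, model), model)
  pred <- predict_tage(model, zt)
  # cannot beat the intercept-only predictor: held-out residual variance
  # is no better than predicting the mean
  rss <- sum((pred - parts$test$sample_metadata$age)^2)
  tss <- sum((parts$test$sample_metadata$age -
                mean(parts$train$sample_metadata$age))^2)
  expect_gt(rss / tss, 0.8)
})

test_that("prediction is linear and order-invariant", {
  cohort <- make_cohort(n = 40, n_genes = 150, seed = 10)
  z <- preprocess_expression(cohort)
  model <- train_clock(z, cohort$sample_metadata$age, seed = 1)
  g <- names(model$coefficients)[1]
  z2 <- z
  z2[g, 1] <- z2[g, 1] + 1
  p1 <- predict_tage(model, z)
  p2 <- predict_tage(model, z2)
  expect_equal(unname(p2[1] - p1[1]), unname(model$coefficients[g]),
               tolerance = 1e-10)
  expect_equal(p2[-1], p1[-1])
  # permuting samples and genes permutes/preserves predictions
  set.seed(2)
  zp <- z[sample(nrow(z)), sample(ncol(z))]
  attr(zp, "preprocessed") <- TRUE
  expect_equal(predict_tage(model, zp)[names(p1)], p1)
})

test_that("centering on controls is exact, idempotent, shift-invariant", {
  t <- c(a = 10, b = 20, c = 30, d = 25)
  d1 <- center_tage(t, c("a", "b", "c"))
  expect_equal(unname(d1["d"]), 5)
  expect_equal(median(d1[c("a", "b", "c")]), 0)
  expect_equal(center_tage(d1, c("a", "b", "c")), d1)          # idempotent
  expect_equal(center_tage(t + 100, c("a", "b", "c")), d1)     # invariant
  expect_equal(unname(center_tage(c(x = 7), "x")), 0)          # lone control
  expect_error(center_tage(t, character(0)), "empty")
})

test_that("group comparisons match their analytic power and BH oracle", {
  # identical groups: t = 0, p = 1 (pooled form)
  t <- c(rep(1:3, 2))
  names(t) <- paste0("s", 1:6)
  g <- rep(c("quiescent", "senescent"), each = 3)
  cmp <- compare_tage_groups(t, g, reference = "senescent", var_equal = TRUE)
  expect_equal(cmp$statistic, 0)
  expect_equal(cmp$p, 1)
  # -3 year shift, SD 1, n = 3: rejection rate near closed-form power
  target <- power.t.test(n = 3, delta = 3, sd = 1, sig.level = 0.05)$power
  set.seed(17)
  rej <- mean(vapply(1:200, function(i) {
    v <- c(rnorm(3, 0), rnorm(3, -3))
    names(v) <- paste0("s", 1:6)
    compare_tage_groups(v, g, reference = "quiescent",
                        var_equal = TRUE)$p < 0.05
  }, logical(1)))
  expect_lt(abs(rej - target), 0.10)
  # BH across pairs equals the brute-force step-up
  set.seed(18)
  v <- rnorm(12)
  names(v) <- paste0("s", 1:12)
  g4 <- rep(c("quiescent", "senescent", "senescent+a", "senescent+b"),
            each = 3)
  cmp4 <- compare_tage_groups(v, g4, reference = "senescent")
  expect_equal(cmp4$p_adj, bh_brute_force(cmp4$p))
})

test_that("clock models survive a JSON round-trip", {
  cohort <- make_cohort(n = 30, n_genes = 100, seed = 11)
  z <- preprocess_expression(cohort)
  model <- train_clock(z, cohort$sample_metadata$age, seed = 1)
  path <- file.path(withr::local_tempdir(), "clock.json")
  write_clock(model, path)
  back <- read_clock(path)
  expect_equal(back$coefficients, model$coefficients)
  expect_equal(back$intercept, model$intercept)
  expect_equal(back$gene_means, model$gene_means)
  # round-tripped model predicts identically
  zt <- impute_missing(preprocess_expression(cohort, back), back)
  zo <- impute_missing(preprocess_expression(cohort, model), model)
  expect_equal(predict_tage(back, zt), predict_tage(model, zo))
})
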