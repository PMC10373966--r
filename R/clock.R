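# Penalized linear transcriptomic age clock: elastic-net training on
# scaled log expression, standalone application with training-statistics
# scaling and mean imputation, centering of predicted ages on a control
# group, and group-comparison statistics.

#' Preprocess counts for clock training or application
#'
#' Normalizes by median-of-ratios [size_factors()], transforms to
#' `log2(normalized + 1)` and z-scales per gene. In training mode
#' (`model = NULL`) the cohort's own per-gene means and SDs are used and
#' stored in the result (genes with zero SD are excluded from scaling and
#' reported); in application mode the supplied model's training statistics
#' are used over the model's gene set, and genes absent from the input are
#' returned as `NA` rows for [impute_missing()] to fill.
#'
#' @param counts A [count_matrix()].
#' @param model Optional `clock_model` whose training statistics to apply.
#' @return A genes-by-samples matrix of class `scaled_expression` with
#'   attributes `gene_means`, `gene_sds` (training mode), `dropped`
#'   (zero-SD genes) and `preprocessed = TRUE`.
#' @export
preprocess_expression <- function(counts, model = NULL) {
  stopifnot(inherits(counts, "count_matrix"))
  sf <- size_factors(counts)
  y <- log2(sweep(counts$counts, 2, sf, "/") + 1)
  if (is.null(model)) {
    mu <- rowMeans(y)
    sdv <- apply(y, 1, stats::sd)
    dropped <- rownames(y)[sdv == 0]
    keep <- sdv > 0
    z <- (y[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
    attr(z, "gene_means") <- mu[keep]
    attr(z, "gene_sds") <- sdv[keep]
  } else {
    stopifnot(inherits(model, "clock_model"))
    genes <- model$gene_ids
    z <- matrix(NA_real_, length(genes), ncol(y),
                dimnames = list(genes, colnames(y)))
    present <- intersect(genes, rownames(y))
    z[present, ] <- (y[present, , drop = FALSE] - model$gene_means[present]) /
      model$gene_sds[present]
    dropped <- character(0)
  }
  attr(z, "dropped") <- dropped
  attr(z, "preprocessed") <- TRUE
  class(z) <- c("scaled_expression", class(z))
  z
}

#' Impute missing clock genes with training means
#'
#' Clock genes not detected in the data are filled with their training
#' average, i.e. `z = 0` on the scaled scale, so they contribute nothing
#' beyond the intercept. The number of imputed entries is recorded in
#' `attr(, "n_imputed")`.
#'
#' @param matrix A [preprocess_expression()] result in application mode.
#' @param model The `clock_model` the matrix was preprocessed with.
#' @return The matrix with `NA` entries replaced by 0.
#' @export
impute_missing <- function(matrix, model) {
  stopifnot(inherits(model, "clock_model"))
  n_imp <- sum(is.na(matrix))
  matrix[is.na(matrix)] <- 0
  attr(matrix, "n_imputed") <- n_imp
  matrix
}

#' Train an elastic-net transcriptomic age clock
#'
#' Fits a penalized linear regression of chronological age on scaled log
#' expression with [glmnet::cv.glmnet()]; the penalty is chosen by
#' cross-validated mean squared error over a log-spaced grid. The returned
#' model stores everything needed for standalone application: gene ids,
#' coefficients, intercept, and per-gene training means/SDs for scaling and
#' imputation.
#'
#' @param matrix A training-mode [preprocess_expression()] result.
#' @param ages Numeric vector of chronological ages (years), one per sample.
#' @param l1_ratio Elastic-net mixing parameter alpha in `[0, 1]`
#'   (0 = ridge, 1 = lasso; default 0.5).
#' @param penalty_grid Lambda grid; default log-spaced over six decades,
#'   `10^seq(1, -5)`.
#' @param cv_folds Number of CV folds (default 5).
#' @param seed Integer seed controlling the fold assignment.
#' @return Object of class `clock_model`: `gene_ids`, `coefficients`
#'   (named, clock genes only), `intercept`, `gene_means`, `gene_sds`,
#'   `lambda`, `l1_ratio`, `cv_folds`, `seed`.
#' @export
train_clock <- function(matrix, ages, l1_ratio = 0.5, penalty_grid = NULL,
                        cv_folds = 5L, seed = 1L) {
  if (!isTRUE(attr(matrix, "preprocessed")))
    stop("'matrix' must come from preprocess_expression()", call. = FALSE)
  if (length(ages) != ncol(matrix) || any(!is.finite(ages)))
    stop("'ages' must be finite, one per sample", call. = FALSE)
  if (stats::sd(ages) == 0)
    stop("ages are constant; no signal to fit", call. = FALSE)
  check_number(cv_folds, "cv_folds", lower = 2, integer = TRUE)
  if (ncol(matrix) < cv_folds)
    stop("need at least as many samples as CV folds", call. = FALSE)
  check_number(l1_ratio, "l1_ratio", 0, 1)
  if (is.null(penalty_grid))
    penalty_grid <- 10^seq(1, -5, length.out = 60)
  x <- t(unclass(matrix))
  fold_id <- with_seed(seed,
                       sample(rep_len(seq_len(cv_folds), nrow(x))))
  cv <- glmnet::cv.glmnet(x, ages, alpha = l1_ratio, lambda = penalty_grid,
                          foldid = fold_id, family = "gaussian")
  beta <- as.numeric(stats::coef(cv, s = "lambda.min"))
  names(beta) <- c("(Intercept)", colnames(x))
  coefs <- beta[-1][beta[-1] != 0]
  structure(list(
    gene_ids = rownames(matrix),
    coefficients = coefs,
    intercept = unname(beta[1]),
    gene_means = attr(matrix, "gene_means"),
    gene_sds = attr(matrix, "gene_sds"),
    lambda = cv$lambda.min,
    l1_ratio = l1_ratio,
    cv_folds = as.integer(cv_folds),
    seed = as.integer(seed)
  ), class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf("clock_model: %d/%d genes with nonzero coefficients, intercept %.2f y, lambda %.4g\n",
              length(x$coefficients), length(x$gene_ids), x$intercept,
              x$lambda))
  invisible(x)
}

#' Predict transcriptomic ages
#'
#' `tAge = intercept + sum(coef * z)` over the model's coefficient genes.
#' The input must have been produced by [preprocess_expression()] (with
#' this model for standalone application) and imputed with
#' [impute_missing()] if genes are missing.
#'
#' @param model A `clock_model`.
#' @param matrix Scaled expression matrix (genes x samples).
#' @return Named numeric vector of predicted ages in years.
#' @export
predict_tage <- function(model, matrix) {
  stopifnot(inherits(model, "clock_model"))
  if (!isTRUE(attr(matrix, "preprocessed")))
    stop("'matrix' must come from preprocess_expression()", call. = FALSE)
  if (anyNA(matrix))
    stop("matrix contains missing clock genes; run impute_missing() first",
         call. = FALSE)
  genes <- names(model$coefficients)
  missing <- setdiff(genes, rownames(matrix))
  if (length(missing))
    stop("coefficient gene(s) absent from matrix: ",
         paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
  z <- unclass(matrix)[genes, , drop = FALSE]
  drop(model$intercept + crossprod(z, model$coefficients)[, 1])
}

#' Center predicted ages on a control group
#'
#' `delta_tAge = tAge - median(tAge over controls)`, so the control group's
#' median delta is exactly zero. Idempotent: centering twice equals once.
#'
#' @param tages Named numeric vector from [predict_tage()].
#' @param control_ids Sample names of the control (e.g. quiescent) group.
#' @return Named numeric vector of delta tAges (years).
#' @export
center_tage <- function(tages, control_ids) {
  if (!length(control_ids))
    stop("empty control set", call. = FALSE)
  if (!all(control_ids %in% names(tages)))
    stop("control id(s) absent from tAge vector", call. = FALSE)
  tages - stats::median(tages[control_ids])
}

#' Compare delta tAges between groups
#'
#' Two-sided independent t-tests of each test group against the reference
#' group, BH-adjusted across the pairs.
#'
#' @param tages Named numeric vector of (delta) tAges.
#' @param groups Character vector of group labels aligned with `tages`.
#' @param reference Reference group label.
#' @param test_groups Labels to compare against the reference (default: all
#'   other groups).
#' @param var_equal Pooled-variance t-tests instead of Welch.
#' @return Data frame with `comparison`, `mean_diff`, `statistic`, `p`,
#'   `p_adj`.
#' @export
compare_tage_groups <- function(tages, groups, reference,
                                test_groups = NULL, var_equal = FALSE) {
  stopifnot(length(tages) == length(groups))
  if (is.null(test_groups)) test_groups <- setdiff(unique(groups), reference)
  for (g in c(reference, test_groups)) {
    if (sum(groups == g) < 2)
      stop(sprintf("group '%s' needs >= 2 samples", g), call. = FALSE)
  }
  ref <- tages[groups == reference]
  rows <- lapply(test_groups, function(g) {
    v <- tages[groups == g]
    tt <- stats::t.test(v, ref, var.equal = var_equal)
    data.frame(comparison = sprintf("%s vs %s", g, reference),
               mean_diff = mean(v) - mean(ref),
               statistic = unname(tt$statistic), p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out
}

#' Serialize a clock model to JSON
#'
#' @param model A `clock_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clock <- function(model, path) {
  stopifnot(inherits(model, "clock_model"))
  obj <- list(
    gene_ids = model$gene_ids,
    coefficients = as.list(model$coefficients),
    intercept = model$intercept,
    gene_means = as.list(model$gene_means),
    gene_sds = as.list(model$gene_sds),
    lambda = model$lambda, l1_ratio = model$l1_ratio,
    cv_folds = model$cv_folds, seed = model$seed
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a clock model from JSON
#'
#' @param path Path written by [write_clock()].
#' @return A `clock_model`.
#' @export
read_clock <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    gene_ids = obj$gene_ids,
    coefficients = unlist(obj$coefficients),
    intercept = obj$intercept,
    gene_means = unlist(obj$gene_means),
    gene_sds = unlist(obj$gene_sds),
    lambda = obj$lambda, l1_ratio = obj$l1_ratio,
    cv_folds = obj$cv_folds, seed = obj$seed
  ), class = "clock_model")
}
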