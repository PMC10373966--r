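# Negative-binomial RNA-seq simulation with planted senescence, treatment
# reversal and age structure. Counts for gene g in sample s are drawn as
#   counts_gs ~ NB(mu = p_gs * L_s, size = 1/phi)
# where p_gs is the gene's expected expression proportion in the sample's
# group, L_s a log-uniform library size and phi the common dispersion, so
# Var = mu + phi * mu^2.

VALID_GROUP_PATTERN <- "^(quiescent|senescent(\\+.+)?)$"

#' Configuration for the count simulator
#'
#' Defines the statistical structure of a simulated bulk RNA-seq experiment:
#' a quiescent baseline, senescent groups in which a planted set of genes is
#' shifted by `senescence_log2fc`, treated senescent groups
#' (`"senescent+<label>"`) in which a fraction of those genes returns to the
#' quiescent mean, and optionally genes whose log expression drifts linearly
#' with chronological age (for clock training).
#'
#' @param n_genes Total number of genes.
#' @param samples_per_group Replicates per group.
#' @param groups Character vector of group labels; each must be
#'   `"quiescent"`, `"senescent"`, or `"senescent+<treatment>"`.
#' @param n_senescence_genes_up,n_senescence_genes_down Numbers of genes up-
#'   and down-regulated in senescent groups.
#' @param senescence_log2fc Magnitude of the planted senescence shift
#'   (log2 fold change, applied with sign per direction).
#' @param reversal_fraction_up,reversal_fraction_down Fractions of the up/down
#'   senescence genes whose expression a treatment returns to the quiescent
#'   mean, in `[0, 1]`.
#' @param n_age_genes Number of genes with age-linear log2 expression.
#' @param age_slope_sd SD of per-gene age slopes (log2 units per year).
#' @param dispersion Negative-binomial dispersion `phi` (> 0).
#' @param library_size_range Range for log-uniform library sizes (total
#'   expected counts per sample).
#' @param ages Optional numeric vector of sample ages in years (recycled to
#'   the number of samples), or `NULL` to sample from `age_range` when a
#'   cohort is requested.
#' @param age_range Range from which ages are drawn uniformly when `ages` is
#'   `NULL` and age structure is requested.
#' @param seed Integer seed; identical configurations give identical counts.
#' @return An object of class `sim_count_config`.
#' @export
#' @examples
#' cfg <- sim_count_config(n_genes = 500, samples_per_group = 3)
#' cm <- simulate_counts(cfg)
#' dim(cm$counts)
sim_count_config <- function(n_genes = 2000L,
                             samples_per_group = 6L,
                             groups = c("quiescent", "senescent",
                                        "senescent+treated"),
                             n_senescence_genes_up = 100L,
                             n_senescence_genes_down = 100L,
                             senescence_log2fc = 2,
                             reversal_fraction_up = 0.5,
                             reversal_fraction_down = 0.5,
                             n_age_genes = 0L,
                             age_slope_sd = 0.02,
                             dispersion = 0.1,
                             library_size_range = c(5e5, 2e6),
                             ages = NULL,
                             age_range = c(20, 90),
                             seed = 1L) {
  check_number(n_genes, "n_genes", lower = 1, integer = TRUE)
  check_number(samples_per_group, "samples_per_group", lower = 1,
               integer = TRUE)
  if (!is.character(groups) || length(groups) < 1L)
    stop("'groups' must be a non-empty character vector", call. = FALSE)
  bad <- groups[!grepl(VALID_GROUP_PATTERN, groups)]
  if (length(bad))
    stop("invalid group label(s): ", paste(bad, collapse = ", "),
         " (expected 'quiescent', 'senescent' or 'senescent+<treatment>')",
         call. = FALSE)
  check_number(n_senescence_genes_up, "n_senescence_genes_up", lower = 0,
               integer = TRUE)
  check_number(n_senescence_genes_down, "n_senescence_genes_down", lower = 0,
               integer = TRUE)
  check_number(senescence_log2fc, "senescence_log2fc")
  check_number(reversal_fraction_up, "reversal_fraction_up", 0, 1)
  check_number(reversal_fraction_down, "reversal_fraction_down", 0, 1)
  check_number(n_age_genes, "n_age_genes", lower = 0, integer = TRUE)
  check_number(age_slope_sd, "age_slope_sd", lower = 0)
  check_number(dispersion, "dispersion", lower = 1e-12)
  check_range(library_size_range, "library_size_range", lower = 1)
  check_range(age_range, "age_range", lower = 0)
  if (!is.null(ages)) {
    if (!is.numeric(ages) || any(!is.finite(ages)) || any(ages < 0))
      stop("'ages' must be finite non-negative years", call. = FALSE)
  }
  if (n_senescence_genes_up + n_senescence_genes_down + n_age_genes > n_genes)
    stop("planted gene classes exceed 'n_genes'", call. = FALSE)
  check_number(seed, "seed", integer = TRUE)
  structure(list(
    n_genes = as.integer(n_genes),
    samples_per_group = as.integer(samples_per_group),
    groups = groups,
    n_senescence_genes_up = as.integer(n_senescence_genes_up),
    n_senescence_genes_down = as.integer(n_senescence_genes_down),
    senescence_log2fc = senescence_log2fc,
    reversal_fraction_up = reversal_fraction_up,
    reversal_fraction_down = reversal_fraction_down,
    n_age_genes = as.integer(n_age_genes),
    age_slope_sd = age_slope_sd,
    dispersion = dispersion,
    library_size_range = library_size_range,
    ages = ages,
    age_range = age_range,
    seed = as.integer(seed)
  ), class = "sim_count_config")
}

#' Construct a count matrix container
#'
#' Bundles a non-negative integer gene-by-sample matrix with its sample
#' metadata; the substrate for all transcriptomic stages.
#'
#' @param counts Integer matrix, genes in rows, samples in columns; row and
#'   column names are taken as gene and sample identifiers.
#' @param sample_metadata Data frame with one row per sample and at least a
#'   `group` column; an `age` column (years, `NA` allowed) is optional.
#' @param truth Optional list of ground-truth annotations (simulators fill
#'   this in).
#' @return An object of class `count_matrix` with elements `counts`,
#'   `gene_ids`, `sample_metadata` and `truth`.
#' @export
count_matrix <- function(counts, sample_metadata, truth = NULL) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("'counts' must be a numeric matrix", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("'counts' must contain non-negative integers", call. = FALSE)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("'counts' must have gene row names and sample column names",
         call. = FALSE)
  if (!is.data.frame(sample_metadata) ||
      nrow(sample_metadata) != ncol(counts))
    stop("'sample_metadata' must have one row per sample", call. = FALSE)
  if (!"group" %in% names(sample_metadata))
    stop("'sample_metadata' must contain a 'group' column", call. = FALSE)
  bad <- setdiff(unique(sample_metadata$group),
                 grep(VALID_GROUP_PATTERN,
                      unique(sample_metadata$group), value = TRUE))
  if (length(bad))
    stop("invalid group label(s) in metadata: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (!"age" %in% names(sample_metadata)) sample_metadata$age <- NA_real_
  if (!"sample_id" %in% names(sample_metadata))
    sample_metadata$sample_id <- colnames(counts)
  structure(list(
    counts = counts,
    gene_ids = rownames(counts),
    sample_metadata = sample_metadata,
    truth = truth
  ), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  print(table(x$sample_metadata$group))
  invisible(x)
}

# Expected expression proportions per gene and group, plus the truth table.
build_group_means <- function(config) {
  n <- config$n_genes
  gene_ids <- sprintf("gene%05d", seq_len(n))
  # assign planted roles to a random subset of gene indices
  roles <- rep("null", n)
  planted <- sample.int(n, config$n_senescence_genes_up +
                          config$n_senescence_genes_down +
                          config$n_age_genes)
  i_up <- planted[seq_len(config$n_senescence_genes_up)]
  i_down <- planted[config$n_senescence_genes_up +
                      seq_len(config$n_senescence_genes_down)]
  i_age <- planted[config$n_senescence_genes_up +
                     config$n_senescence_genes_down +
                     seq_len(config$n_age_genes)]
  roles[i_up] <- "senescence_up"
  roles[i_down] <- "senescence_down"
  roles[i_age] <- "age"
  base_log2 <- stats::runif(n, 3, 9)

  sen_shift <- rep(0, n)
  sen_shift[i_up] <- config$senescence_log2fc
  sen_shift[i_down] <- -config$senescence_log2fc

  reversed <- rep(FALSE, n)
  if (length(i_up))
    reversed[sample(i_up, round(config$reversal_fraction_up *
                                  length(i_up)))] <- TRUE
  if (length(i_down))
    reversed[sample(i_down, round(config$reversal_fraction_down *
                                    length(i_down)))] <- TRUE

  age_slope <- rep(0, n)
  age_slope[i_age] <- stats::rnorm(length(i_age), 0, config$age_slope_sd)

  groups <- config$groups
  shift <- matrix(0, n, length(groups), dimnames = list(gene_ids, groups))
  for (g in groups) {
    if (g == "quiescent") next
    treated <- g != "senescent"         # "senescent+<treatment>"
    s <- sen_shift
    if (treated) s[reversed] <- 0       # treatment cancels the shift
    shift[, g] <- s
  }
  truth <- data.frame(
    gene_id = gene_ids,
    role = roles,
    senescence_log2fc = sen_shift,
    reversed_by_treatment = reversed,
    age_slope = age_slope,
    stringsAsFactors = FALSE
  )
  list(gene_ids = gene_ids, base_log2 = base_log2, shift = shift,
       age_slope = age_slope, truth = truth)
}

nb_draw <- function(mu, dispersion) {
  k <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                             size = 1 / dispersion),
              nrow = nrow(mu), dimnames = dimnames(mu))
  storage.mode(k) <- "double"
  k
}

simulate_counts_impl <- function(config, ages) {
  spec <- build_group_means(config)
  groups <- rep(config$groups, each = config$samples_per_group)
  n_samp <- length(groups)
  sample_ids <- sprintf("%s_rep%d", gsub("[^A-Za-z0-9]+", "_", groups),
                        sequence(rep(config$samples_per_group,
                                     length(config$groups))))
  lib <- exp(stats::runif(n_samp, log(config$library_size_range[1]),
                          log(config$library_size_range[2])))
  if (is.null(ages)) {
    age_vec <- rep(NA_real_, n_samp)
  } else {
    age_vec <- rep_len(ages, n_samp)
  }
  ref_age <- mean(config$age_range)
  log2mu <- matrix(spec$base_log2, config$n_genes, n_samp) +
    spec$shift[, groups, drop = FALSE]
  if (any(spec$age_slope != 0) && !all(is.na(age_vec))) {
    a <- ifelse(is.na(age_vec), ref_age, age_vec)
    log2mu <- log2mu + outer(spec$age_slope, a - ref_age)
  }
  rel <- 2^log2mu
  prop <- sweep(rel, 2, colSums(rel), "/")
  mu <- sweep(prop, 2, lib, "*")
  dimnames(mu) <- list(spec$gene_ids, sample_ids)
  counts <- nb_draw(mu, config$dispersion)
  meta <- data.frame(
    sample_id = sample_ids,
    group = groups,
    age = age_vec,
    library_size = lib,
    stringsAsFactors = FALSE
  )
  count_matrix(counts, meta,
               truth = list(genes = spec$truth, config = config))
}

#' Simulate a senescence / treatment RNA-seq experiment
#'
#' Draws negative-binomial counts whose group means encode the planted
#' senescence shift and its partial reversal by treatment (see
#' [sim_count_config()]). The returned `truth` element records which genes
#' are senescence-responsive and which the treatment reverses.
#'
#' @param config A [sim_count_config()].
#' @return A [count_matrix()] with ground-truth annotations.
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_count_config"))
  with_seed(config$seed, simulate_counts_impl(config, config$ages))
}

#' Simulate an age-annotated cohort for clock training
#'
#' Like [simulate_counts()], but every sample carries a chronological age
#' (supplied via `config$ages` or drawn uniformly from `config$age_range`)
#' and the `n_age_genes` planted genes have log2 expression linear in age
#' with slopes drawn from `Normal(0, age_slope_sd)`.
#'
#' @param config A [sim_count_config()] with `n_age_genes > 0` for a
#'   non-null cohort.
#' @return A [count_matrix()] whose metadata carries true ages.
#' @export
#' @examples
#' cfg <- sim_count_config(n_genes = 400, samples_per_group = 20,
#'                         groups = "quiescent", n_senescence_genes_up = 0,
#'                         n_senescence_genes_down = 0, n_age_genes = 50)
#' cohort <- simulate_clock_cohort(cfg)
#' range(cohort$sample_metadata$age)
simulate_clock_cohort <- function(config) {
  stopifnot(inherits(config, "sim_count_config"))
  n_samp <- config$samples_per_group * length(config$groups)
  with_seed(config$seed, {
    ages <- config$ages
    if (is.null(ages))
      ages <- stats::runif(n_samp, config$age_range[1], config$age_range[2])
    if (any(!is.finite(ages)) || any(ages < 0))
      stop("ages must be finite and non-negative", call. = FALSE)
    simulate_counts_impl(config, ages)
  })
}
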