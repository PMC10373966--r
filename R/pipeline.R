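# End-to-end orchestration of the synthetic study: simulate reporter
# fields and count matrices, quantify colocalization, run differential
# expression / signature / reversal, pre-ranked GSEA, the transcriptomic
# clock and signature association, from one config, with a machine-readable
# run report. All stage randomness derives from the single config seed via
# derive_seed(), so disabling one stage never changes another's numbers.

# stream indices for derive_seed(); fixed so results are stable across
# versions that add stages
.STREAMS <- c(image = 1L, counts = 2L, gsea = 3L, cohort = 4L, clock = 5L)

#' Default pipeline configuration
#'
#' A small, complete demo configuration exercising every stage: two imaging
#' conditions (quiescent-like low mislocalization vs senescent-like high
#' mislocalization), a three-group count experiment with planted senescence
#' genes half-reversed by treatment, a clock training cohort, GSEA over
#' truth-derived and random gene sets, and signature association across
#' contrasts.
#'
#' @param seed Master integer seed.
#' @return A nested list of class `pipeline_config`.
#' @export
demo_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    stages = list(ncc = TRUE, de = TRUE, gsea = TRUE, clock = TRUE,
                  assoc = TRUE),
    segmentation = "truth",
    image = list(
      base = list(height = 256L, width = 256L, n_cells = 15L,
                  noise_sd = 5, background_level = 50),
      conditions = list(quiescent = list(mislocalization_fraction = 0.0),
                        senescent = list(mislocalization_fraction = 0.8)),
      n_fields = 2L,
      positive = "senescent", negative = "quiescent"
    ),
    counts = list(n_genes = 2000L, samples_per_group = 6L,
                  groups = c("quiescent", "senescent", "senescent+c1",
                             "senescent+osk"),
                  n_senescence_genes_up = 100L,
                  n_senescence_genes_down = 100L,
                  senescence_log2fc = 2.5,
                  reversal_fraction_up = 0.5, reversal_fraction_down = 0.5),
    signature = list(p_adj_cutoff = 0.01, fc_cutoff = 2),
    reversal = list(p_adj_cutoff = 0.05),
    cohort = list(n_genes = 1000L, samples_per_group = 200L,
                  groups = "quiescent",
                  n_senescence_genes_up = 0L, n_senescence_genes_down = 0L,
                  n_age_genes = 300L, age_slope_sd = 0.02,
                  age_range = c(20, 90)),
    gsea = list(n_perm = 1000L, n_random_sets = 8L, random_set_size = 40L),
    assoc = list(top_n = 300L)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Values given in the file override the [demo_config()] defaults; anything
#' omitted keeps its default.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(unclass(demo_config()), user)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks the schema and inter-stage dependencies before any computation:
#' enabled stages must have their config blocks, and downstream stages
#' (GSEA, association) require the DE stage.
#'
#' @param config A `pipeline_config`.
#' @return `config`, invisibly; errors on violation.
#' @export
validate_pipeline_config <- function(config) {
  if (!is.list(config) || is.null(config$stages) || is.null(config$seed))
    stop("config must carry 'seed' and 'stages'", call. = FALSE)
  st <- config$stages
  need <- function(stage, block) {
    if (isTRUE(st[[stage]]) && is.null(config[[block]]))
      stop(sprintf("stage '%s' enabled but config block '%s' missing",
                   stage, block), call. = FALSE)
  }
  need("ncc", "image")
  need("de", "counts")
  need("clock", "cohort")
  need("gsea", "gsea")
  if ((isTRUE(st$gsea) || isTRUE(st$assoc) || isTRUE(st$clock)) &&
      !isTRUE(st$de))
    stop("stages gsea/assoc/clock require the de stage", call. = FALSE)
  if (!config$segmentation %in% c("truth", "computed"))
    stop("segmentation must be 'truth' or 'computed'", call. = FALSE)
  if (isTRUE(st$assoc)) {
    treated <- grep("^senescent\\+", config$counts$groups, value = TRUE)
    if (length(treated) + 1 < 2)
      stop("association stage needs >= 2 contrasts (add treated groups)",
           call. = FALSE)
  }
  invisible(config)
}

stage_ncc <- function(config, out, log) {
  img <- config$image
  conds <- names(img$conditions)
  tabs <- list()
  for (ci in seq_along(conds)) {
    for (fi in seq_len(img$n_fields)) {
      seed_i <- derive_seed(config$seed,
                            .STREAMS[["image"]] * 100L + ci * 10L + fi)
      args <- utils::modifyList(img$base, img$conditions[[ci]])
      args$seed <- seed_i
      field <- simulate_ncc_field(do.call(sim_image_config, args))
      seg <- if (config$segmentation == "truth") truth_segmentation(field)
             else segment_field(field$mcherry, field$egfp)
      tab <- pearson_colocalization(field$mcherry, field$egfp, seg,
                                    condition = conds[ci])
      tab$field <- fi
      tabs[[length(tabs) + 1L]] <- tab
    }
  }
  all_tab <- do.call(rbind, tabs)
  write_tsv(all_tab, file.path(out, "colocalization.tsv"))
  method <- if (length(conds) > 2) "anova_bonferroni" else "ttest"
  scr <- compare_conditions(all_tab, method = method,
                            positive = img$positive, negative = img$negative)
  write_tsv(scr$summary, file.path(out, "condition_summary.tsv"))
  write_tsv(scr$pairwise, file.path(out, "condition_tests.tsv"))
  log("ncc: %d cells across %d conditions, Z-factor %.3f",
      nrow(all_tab), length(conds), scr$z_factor)
  list(mean_r = stats::setNames(scr$summary$mean_r, scr$summary$condition),
       z_factor = scr$z_factor, pairwise = scr$pairwise)
}

stage_de <- function(config, out, log) {
  args <- config$counts
  args$seed <- derive_seed(config$seed, .STREAMS[["counts"]])
  cm <- simulate_counts(do.call(sim_count_config, args))
  de_sen <- de_test(cm, "quiescent", "senescent")
  sig <- extract_signature(de_sen, config$signature$p_adj_cutoff,
                           config$signature$fc_cutoff)
  treated <- grep("^senescent\\+", args$groups, value = TRUE)
  treat_de <- list()
  reversal <- list()
  for (g in treated) {
    d <- de_test(cm, "senescent", g)
    treat_de[[g]] <- d
    reversal[[g]] <- classify_reversal(sig, d, config$reversal$p_adj_cutoff)
    rv <- reversal[[g]]
    write_tsv(rv, file.path(out, sprintf("reversal_%s.tsv",
                                         gsub("[^A-Za-z0-9]+", "_", g))))
    log("de: %s reversed %.1f%% of up, %.1f%% of down genes", g,
        rv$reversed_pct[rv$direction == "up"],
        rv$reversed_pct[rv$direction == "down"])
  }
  write_tsv(de_sen, file.path(out, "de_senescent_vs_quiescent.tsv"))
  write_tsv(sig$up, file.path(out, "signature_up.tsv"))
  write_tsv(sig$down, file.path(out, "signature_down.tsv"))
  list(counts = cm, de_senescence = de_sen, signature = sig,
       treatment_de = treat_de, reversal = reversal)
}

stage_gsea <- function(config, de_stage, out, log) {
  gcfg <- config$gsea
  truth <- de_stage$counts$truth$genes
  sets <- list(
    senescence_up = truth$gene_id[truth$role == "senescence_up"],
    senescence_down = truth$gene_id[truth$role == "senescence_down"]
  )
  seed0 <- derive_seed(config$seed, .STREAMS[["gsea"]])
  universe <- truth$gene_id
  rand <- with_seed(seed0, lapply(seq_len(gcfg$n_random_sets), function(i)
    sample(universe, gcfg$random_set_size)))
  names(rand) <- sprintf("random_%02d", seq_along(rand))
  sets <- c(sets, rand)
  d <- de_stage$treatment_de[[1]]
  ranked <- rank_metric(d)
  et <- gsea_preranked(ranked, sets, n_perm = gcfg$n_perm,
                       seed = derive_seed(seed0, 1L))
  write_tsv(et, file.path(out, "enrichment.tsv"))
  log("gsea: %d/%d sets significant at p_adj < 0.1",
      sum(et$significant), nrow(et))
  et
}

stage_clock <- function(config, de_stage, out, log) {
  args <- config$cohort
  args$seed <- derive_seed(config$seed, .STREAMS[["cohort"]])
  cohort <- simulate_clock_cohort(do.call(sim_count_config, args))
  n <- ncol(cohort$counts)
  seed_split <- derive_seed(config$seed, .STREAMS[["clock"]])
  test_idx <- with_seed(seed_split, sample.int(n, round(0.25 * n)))
  train_cm <- subset_count_matrix(cohort, setdiff(seq_len(n), test_idx))
  test_cm <- subset_count_matrix(cohort, test_idx)
  ztrain <- preprocess_expression(train_cm)
  model <- train_clock(ztrain, train_cm$sample_metadata$age,
                       seed = derive_seed(seed_split, 1L))
  ztest <- impute_missing(preprocess_expression(test_cm, model), model)
  pred <- predict_tage(model, ztest)
  holdout_r <- stats::cor(pred, test_cm$sample_metadata$age)
  write_clock(model, file.path(out, "clock_model.json"))

  # apply the trained clock to the main experiment
  cm <- de_stage$counts
  z <- impute_missing(preprocess_expression(cm, model), model)
  tages <- predict_tage(model, z)
  qids <- cm$sample_metadata$sample_id[cm$sample_metadata$group == "quiescent"]
  delta <- center_tage(tages, qids)
  tab <- data.frame(sample_id = names(delta),
                    group = cm$sample_metadata$group[
                      match(names(delta), cm$sample_metadata$sample_id)],
                    tage = unname(tages), delta_tage = unname(delta),
                    stringsAsFactors = FALSE)
  cmp <- compare_tage_groups(delta, tab$group, reference = "senescent")
  write_tsv(tab, file.path(out, "tage_table.tsv"))
  write_tsv(cmp, file.path(out, "tage_comparisons.tsv"))
  log("clock: holdout r = %.3f (%d imputed entries on application)",
      holdout_r, attr(z, "n_imputed"))
  list(holdout_r = holdout_r, model = model, tage_table = tab,
       comparisons = cmp)
}

stage_assoc <- function(config, de_stage, out, log) {
  sigs <- c(list(senescence = de_stage$de_senescence),
            de_stage$treatment_de)
  sigs <- lapply(sigs, function(d) d[, c("gene_id", "log2fc", "p")])
  am <- association_matrix(signature_collection(sigs),
                           top_n = config$assoc$top_n)
  write_association_matrix(am, file.path(out, "association"))
  log("assoc: %d signatures, mean |rho| off-diagonal = %.3f",
      nrow(am$rho), mean(abs(am$rho[upper.tri(am$rho)]), na.rm = TRUE))
  am
}

subset_count_matrix <- function(cm, idx) {
  count_matrix(cm$counts[, idx, drop = FALSE],
               cm$sample_metadata[idx, , drop = FALSE], truth = cm$truth)
}

#' Run the full synthetic study pipeline
#'
#' Executes the enabled stages in dependency order (simulation + NCC
#' quantification, DE/signature/reversal, GSEA, clock, association),
#' writes one subdirectory of TSV/JSON outputs per stage under `out_dir`,
#' and returns (and writes) a machine-readable run report. Re-running with
#' an identical config and seed reproduces identical numeric outputs.
#'
#' @param config A `pipeline_config` (see [demo_config()],
#'   [read_pipeline_config()]).
#' @param out_dir Output directory (created if needed).
#' @param seed Optional override of `config$seed`.
#' @param quiet Suppress progress messages.
#' @return The run report, a list of class `run_report`, invisibly written
#'   to `out_dir/report.json`.
#' @export
run_pipeline <- function(config = demo_config(), out_dir = tempfile("run_"),
                         seed = NULL, quiet = FALSE) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  t0 <- Sys.time()
  report <- list(seed = config$seed, stages = list())
  mkout <- function(name) {
    d <- file.path(out_dir, name)
    dir.create(d, showWarnings = FALSE)
    d
  }
  ncc <- de <- NULL
  if (isTRUE(config$stages$ncc)) {
    ncc <- stage_ncc(config, mkout("ncc"), log)
    report$stages$ncc <- list(
      status = "ok",
      mean_r = as.list(ncc$mean_r),
      z_factor = ncc$z_factor)
  }
  if (isTRUE(config$stages$de)) {
    de <- stage_de(config, mkout("de"), log)
    report$stages$de <- list(
      status = "ok",
      n_signature_up = nrow(de$signature$up),
      n_signature_down = nrow(de$signature$down),
      reversal = lapply(de$reversal, function(rv)
        stats::setNames(as.list(rv$reversed_pct), rv$direction)))
  }
  if (isTRUE(config$stages$gsea)) {
    et <- stage_gsea(config, de, mkout("gsea"), log)
    report$stages$gsea <- list(
      status = "ok",
      n_sets = nrow(et),
      significant_sets = et$set[et$significant])
  }
  if (isTRUE(config$stages$clock)) {
    ck <- stage_clock(config, de, mkout("clock"), log)
    delta_by_group <- tapply(ck$tage_table$delta_tage, ck$tage_table$group,
                             mean)
    report$stages$clock <- list(
      status = "ok",
      holdout_r = ck$holdout_r,
      mean_delta_tage = as.list(delta_by_group))
  }
  if (isTRUE(config$stages$assoc)) {
    am <- stage_assoc(config, de, mkout("assoc"), log)
    report$stages$assoc <- list(
      status = "ok",
      rho = as.data.frame(am$rho))
  }
  report$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  class(report) <- "run_report"
  jsonlite::write_json(unclass(report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns")
  log("pipeline finished in %.1f s; report at %s", report$elapsed_s,
      file.path(out_dir, "report.json"))
  invisible(report)
}
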