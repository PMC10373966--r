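# Differential expression on normalized counts, senescence signature
# extraction and the treatment reversal statistic.
#
# The DE engine is deliberately simple and transparent: median-of-ratios
# size factors, log2(normalized + 1) transform, per-gene Welch t-test,
# Benjamini-Hochberg adjustment. It stands behind the same interface a
# heavier NB-GLM engine would, so one can be swapped in without touching
# the signature or reversal logic downstream.

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median, over reference
#' genes, of the ratio of the sample's count to the gene's geometric mean
#' across samples. Reference genes are those with no zero count in any
#' sample.
#'
#' @param counts A [count_matrix()] or a numeric gene-by-sample matrix.
#' @return Named numeric vector of positive factors, one per sample.
#' @export
#' @examples
#' m <- matrix(c(10, 30, 20, 60), 2, dimnames = list(c("g1", "g2"), c("a", "b")))
#' size_factors(m)  # c(1, 2) / sqrt(2)
size_factors <- function(counts) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else counts
  if (!is.matrix(m) || !is.numeric(m))
    stop("'counts' must be a count_matrix or numeric matrix", call. = FALSE)
  ref <- rowSums(m == 0) == 0
  if (!any(ref))
    stop("no zero-free gene rows available as normalization reference",
         call. = FALSE)
  logm <- log(m[ref, , drop = FALSE])
  loggeo <- rowMeans(logm)
  sf <- apply(logm, 2, function(x) exp(stats::median(x - loggeo)))
  names(sf) <- colnames(m)
  sf
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment, returned in input order:
#' with p-values sorted ascending, `adj_(i) = min over k >= i of
#' min(1, p_(k) * m / k)`. Implemented literally (the products are formed
#' as `p * m / k`) so results agree bit-for-bit with the step-up
#' definition; it matches [stats::p.adjust()] `method = "BH"` to
#' floating-point rounding.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` allowed and
#'   propagated).
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p))
    stop("'p' must be numeric", call. = FALSE)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  out <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m == 0) return(out)
  ord <- order(pv)
  stepped <- pmin(1, pv[ord] * m / seq_len(m))
  adj <- rev(cummin(rev(stepped)))
  out[ok][ord] <- adj
  out
}

row_welch_t <- function(ya, yb) {
  na <- ncol(ya); nb <- ncol(yb)
  ma <- rowMeans(ya); mb <- rowMeans(yb)
  va <- rowSums((ya - ma)^2) / (na - 1)
  vb <- rowSums((yb - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  tstat <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  # degenerate rows: both groups constant
  flat <- se2 == 0
  if (any(flat)) {
    same <- flat & (mb == ma)
    tstat[same] <- 0; p[same] <- 1
    diff <- flat & (mb != ma)
    tstat[diff] <- sign(mb - ma)[diff] * Inf; p[diff] <- 0
  }
  list(t = tstat, p = p, meanA = ma, meanB = mb)
}

#' Two-group differential expression test
#'
#' Normalizes counts by median-of-ratios [size_factors()], transforms to
#' `log2(normalized + 1)`, and tests each gene with a two-sided Welch
#' (unequal-variance) t-test between the two groups. Log2 fold change is
#' the difference of group means of the transformed values
#' (`groupB - groupA`). Genes with zero counts in every sample are dropped
#' before testing. P-values are BH-adjusted across the tested genes.
#'
#' @param counts A [count_matrix()].
#' @param groupA,groupB Group labels in the sample metadata; the contrast is
#'   `groupB` vs `groupA` (positive log2fc = higher in `groupB`).
#' @param var_equal If `TRUE` use the pooled-variance (Student) form instead
#'   of Welch.
#' @return A data frame of class `de_result` with columns `gene_id`,
#'   `log2fc`, `t`, `p`, `p_adj`, `mean_expr` (mean transformed expression
#'   across the tested samples); the contrast is stored in
#'   `attr(, "contrast")`.
#' @export
de_test <- function(counts, groupA, groupB, var_equal = FALSE) {
  stopifnot(inherits(counts, "count_matrix"))
  grp <- counts$sample_metadata$group
  for (g in c(groupA, groupB)) {
    if (sum(grp == g) < 2)
      stop(sprintf("group '%s' needs >= 2 samples", g), call. = FALSE)
  }
  sel <- grp %in% c(groupA, groupB)
  m <- counts$counts[, sel, drop = FALSE]
  grp <- grp[sel]
  keep <- rowSums(m) > 0
  m <- m[keep, , drop = FALSE]
  sf <- size_factors(counts)[sel]
  y <- log2(sweep(m, 2, sf, "/") + 1)
  ya <- y[, grp == groupA, drop = FALSE]
  yb <- y[, grp == groupB, drop = FALSE]
  if (var_equal) {
    res <- apply_pooled_t(ya, yb)
  } else {
    res <- row_welch_t(ya, yb)
  }
  out <- data.frame(
    gene_id = rownames(m),
    log2fc = res$meanB - res$meanA,
    t = res$t,
    p = res$p,
    p_adj = bh_adjust(res$p),
    mean_expr = rowMeans(y),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  attr(out, "contrast") <- sprintf("%s_vs_%s", groupB, groupA)
  class(out) <- c("de_result", class(out))
  out
}

apply_pooled_t <- function(ya, yb) {
  na <- ncol(ya); nb <- ncol(yb)
  ma <- rowMeans(ya); mb <- rowMeans(yb)
  va <- rowSums((ya - ma)^2) / (na - 1)
  vb <- rowSums((yb - mb)^2) / (nb - 1)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  se2 <- sp2 * (1 / na + 1 / nb)
  tstat <- (mb - ma) / sqrt(se2)
  p <- 2 * stats::pt(-abs(tstat), na + nb - 2)
  flat <- se2 == 0
  if (any(flat)) {
    same <- flat & (mb == ma)
    tstat[same] <- 0; p[same] <- 1
    diff <- flat & (mb != ma)
    tstat[diff] <- sign(mb - ma)[diff] * Inf; p[diff] <- 0
  }
  list(t = tstat, p = p, meanA = ma, meanB = mb)
}

#' Extract a senescence signature from a DE result
#'
#' Selects genes passing an adjusted-p cutoff and an absolute fold-change
#' cutoff, split by direction: up-genes satisfy `p_adj < p_adj_cutoff` and
#' `log2fc > log2(fc_cutoff)`, down-genes the mirror image.
#'
#' @param de A `de_result` from [de_test()].
#' @param p_adj_cutoff Adjusted-p threshold (default 0.01).
#' @param fc_cutoff Fold-change threshold on the natural scale (default 2,
#'   i.e. `|log2fc| > 1`).
#' @return An object of class `senescence_signature`: data frames `up` and
#'   `down` (gene_id, log2fc, p_adj) plus the thresholds used.
#' @export
extract_signature <- function(de, p_adj_cutoff = 0.01, fc_cutoff = 2) {
  stopifnot(inherits(de, "de_result"))
  check_number(p_adj_cutoff, "p_adj_cutoff", 0, 1)
  check_number(fc_cutoff, "fc_cutoff", lower = 1)
  lfc_cut <- log2(fc_cutoff)
  sel_up <- de$p_adj < p_adj_cutoff & de$log2fc > lfc_cut
  sel_down <- de$p_adj < p_adj_cutoff & de$log2fc < -lfc_cut
  cols <- c("gene_id", "log2fc", "p_adj")
  structure(list(
    up = de[sel_up, cols, drop = FALSE],
    down = de[sel_down, cols, drop = FALSE],
    p_adj_cutoff = p_adj_cutoff,
    fc_cutoff = fc_cutoff,
    contrast = attr(de, "contrast")
  ), class = "senescence_signature")
}

#' @export
print.senescence_signature <- function(x, ...) {
  cat(sprintf("senescence_signature (%s): %d up, %d down (p_adj < %g, FC > %g)\n",
              x$contrast %||% "?", nrow(x$up), nrow(x$down),
              x$p_adj_cutoff, x$fc_cutoff))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify treatment reversal of a senescence signature
#'
#' For each signature gene, asks how the treatment contrast (treated vs
#' senescent) moved it: a senescence-upregulated gene is *reversed* if the
#' treatment significantly decreased it (`p_adj < cutoff` and `log2fc < 0`),
#' *exacerbated* if significantly increased, *unchanged* otherwise; mirror
#' rules for senescence-downregulated genes. The percentage of reversed
#' genes is rounded to one decimal.
#'
#' @param sig A [extract_signature()] result, or a list with `up`/`down`
#'   data frames containing a `gene_id` column.
#' @param treatment_de A `de_result` for the treated-vs-senescent contrast
#'   on the same gene universe.
#' @param p_adj_cutoff Significance cutoff for calling a gene changed by the
#'   treatment (default 0.05).
#' @return Data frame of class `reversal_summary`, one row per direction,
#'   with counts `total`, `reversed`, `exacerbated`, `unchanged` and
#'   `reversed_pct`.
#' @export
#' @examples
#' # 82 of 190 senescence-upregulated genes significantly decreased:
#' de <- data.frame(gene_id = sprintf("g%03d", 1:190),
#'                  log2fc = c(rep(-1, 82), rep(0, 108)),
#'                  p = c(rep(.001, 82), rep(.9, 108)))
#' de$p_adj <- bh_adjust(de$p)
#' class(de) <- c("de_result", class(de))
#' sig <- list(up = de[, "gene_id", drop = FALSE],
#'             down = de[0, "gene_id", drop = FALSE])
#' classify_reversal(sig, de)$reversed_pct[1]  # 43.2
classify_reversal <- function(sig, treatment_de, p_adj_cutoff = 0.05) {
  stopifnot(inherits(treatment_de, "de_result") ||
              all(c("gene_id", "log2fc", "p_adj") %in% names(treatment_de)))
  check_number(p_adj_cutoff, "p_adj_cutoff", 0, 1)
  classify_dir <- function(genes, up) {
    idx <- match(genes, treatment_de$gene_id)
    if (anyNA(idx))
      stop("signature gene(s) missing from treatment DE result: ",
           paste(utils::head(genes[is.na(idx)], 3), collapse = ", "),
           call. = FALSE)
    lfc <- treatment_de$log2fc[idx]
    padj <- treatment_de$p_adj[idx]
    sig_chg <- padj < p_adj_cutoff
    toward <- if (up) lfc < 0 else lfc > 0   # back toward quiescent
    away <- if (up) lfc > 0 else lfc < 0
    total <- length(genes)
    reversed <- sum(sig_chg & toward)
    exacerbated <- sum(sig_chg & away)
    data.frame(
      direction = if (up) "up" else "down",
      total = total,
      reversed = reversed,
      exacerbated = exacerbated,
      unchanged = total - reversed - exacerbated,
      reversed_pct = if (total > 0) round(100 * reversed / total, 1) else NA_real_,
      stringsAsFactors = FALSE
    )
  }
  out <- rbind(classify_dir(sig$up$gene_id, up = TRUE),
               classify_dir(sig$down$gene_id, up = FALSE))
  class(out) <- c("reversal_summary", class(out))
  out
}
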