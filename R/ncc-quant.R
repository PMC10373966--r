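# Quantification of nucleocytoplasmic compartmentalization from paired
# fluorescence channels: segmentation into per-cell nucleus/cytoplasm
# regions, per-cell Pearson colocalization of the two channels, intensity
# line profiles, cytoplasmic mean intensities, puncta counting, the
# Z-factor screening-window statistic and condition-level comparisons.

as_ebimage <- function(m) EBImage::Image(m)

#' Construct a segmentation result
#'
#' @param nucleus_labels,cytoplasm_labels Integer label matrices of equal
#'   shape (0 = background); every cell id must appear in both.
#' @return Object of class `segmentation_result` with `nucleus_labels`,
#'   `cytoplasm_labels`, `cell_ids`.
#' @export
segmentation_result <- function(nucleus_labels, cytoplasm_labels) {
  if (!all(dim(nucleus_labels) == dim(cytoplasm_labels)))
    stop("label matrices must have identical shape", call. = FALSE)
  if (any(nucleus_labels > 0 & cytoplasm_labels > 0))
    stop("nucleus and cytoplasm regions must be disjoint", call. = FALSE)
  ids <- sort(intersect(unique(nucleus_labels[nucleus_labels > 0]),
                        unique(cytoplasm_labels[cytoplasm_labels > 0])))
  structure(list(nucleus_labels = nucleus_labels,
                 cytoplasm_labels = cytoplasm_labels,
                 cell_ids = as.integer(ids)),
            class = "segmentation_result")
}

#' Ground-truth segmentation of a simulated field
#'
#' Wraps the simulator's label matrices as a [segmentation_result()], for
#' quantification against known masks.
#'
#' @param field A [simulate_ncc_field()] result.
#' @return A `segmentation_result`.
#' @export
truth_segmentation <- function(field) {
  stopifnot(inherits(field, "simulated_field"))
  segmentation_result(field$nucleus_labels, field$cytoplasm_labels)
}

#' Segment a two-channel field into per-cell nucleus and cytoplasm regions
#'
#' Nuclei are detected from the smoothed mCherry channel (nuclear by
#' construction in non-senescent reporter cells) by Otsu thresholding and a
#' distance-transform watershed to split touching nuclei; per-cell
#' territories are then grown over the combined-channel foreground by
#' Voronoi-style propagation, and the cytoplasm is each territory minus its
#' nucleus. Deterministic for fixed input. An all-background image yields
#' zero cells (not an error).
#'
#' @param mcherry,egfp Numeric intensity matrices of identical shape.
#' @param blur_sigma Gaussian smoothing sigma in pixels before thresholding.
#' @param min_nucleus_area Minimum nucleus area in pixels; smaller detections
#'   are discarded.
#' @param watershed_tolerance Minimum object-height separation in the
#'   distance-transform watershed; higher values merge shallow splits.
#' @return A [segmentation_result()].
#' @export
segment_field <- function(mcherry, egfp, blur_sigma = 2,
                          min_nucleus_area = 50L, watershed_tolerance = 3) {
  if (!is.matrix(mcherry) || !is.matrix(egfp) ||
      !all(dim(mcherry) == dim(egfp)))
    stop("channels must be numeric matrices of identical shape",
         call. = FALSE)
  if (length(mcherry) == 0) stop("empty image", call. = FALSE)
  empty <- segmentation_result(
    matrix(0L, nrow(mcherry), ncol(mcherry)),
    matrix(0L, nrow(mcherry), ncol(mcherry)))
  comb <- mcherry + egfp
  if (max(comb) <= min(comb)) return(empty)

  norm01 <- function(m) (m - min(m)) / (max(m) - min(m))
  comb_s <- EBImage::gblur(as_ebimage(norm01(comb)), sigma = blur_sigma)
  fg <- matrix(as.numeric(comb_s) >
                 EBImage::otsu(comb_s, range = c(0, 1)), nrow(mcherry))

  if (max(mcherry) <= min(mcherry)) return(empty)
  mch_s <- EBImage::gblur(as_ebimage(norm01(mcherry)), sigma = blur_sigma)
  nmask <- matrix(as.numeric(mch_s) >
                    EBImage::otsu(mch_s, range = c(0, 1)), nrow(mcherry))
  nmask <- EBImage::fillHull(as_ebimage(nmask))
  if (sum(nmask) == 0) return(empty)
  nseg <- EBImage::watershed(EBImage::distmap(nmask),
                             tolerance = watershed_tolerance, ext = 1)
  nseg <- matrix(as.integer(nseg), nrow(mcherry))

  # drop undersized nuclei, relabel 1..n
  tab <- table(nseg[nseg > 0])
  if (!length(tab)) return(empty)
  keep <- as.integer(names(tab)[tab >= min_nucleus_area])
  if (!length(keep)) return(empty)
  relab <- integer(max(as.integer(names(tab))))
  relab[keep] <- seq_along(keep)
  nlab <- matrix(0L, nrow(mcherry), ncol(mcherry))
  pos <- nseg > 0
  nlab[pos] <- relab[nseg[pos]]

  terr <- EBImage::propagate(comb_s, seeds = as_ebimage(nlab),
                             mask = as_ebimage(fg | (nlab > 0)))
  terr <- matrix(as.integer(terr), nrow(mcherry))
  clab <- terr
  clab[nlab > 0] <- 0L
  # keep only cells with non-empty cytoplasm
  ok <- intersect(unique(nlab[nlab > 0]), unique(clab[clab > 0]))
  nlab[!(nlab %in% ok)] <- 0L
  clab[!(clab %in% ok)] <- 0L
  segmentation_result(nlab, clab)
}

cell_pixels <- function(segmentation, id, region = c("union", "nucleus",
                                                     "cytoplasm")) {
  region <- match.arg(region)
  nuc <- segmentation$nucleus_labels == id
  cyt <- segmentation$cytoplasm_labels == id
  switch(region, union = nuc | cyt, nucleus = nuc, cytoplasm = cyt)
}

#' Per-cell Pearson colocalization of two channels
#'
#' For each segmented cell, the Pearson correlation of the mCherry and eGFP
#' intensities over the union of that cell's nucleus and cytoplasm pixels.
#' Cells whose region has zero variance in either channel get `NA` with
#' `flag = "zero_variance"` and are excluded from aggregates. Optionally
#' also reports the cytoplasmic eGFP mean and, when `spot_threshold` is
#' given, the cytoplasmic mCherry puncta count.
#'
#' @param mcherry,egfp Intensity matrices aligned with the segmentation.
#' @param segmentation A [segmentation_result()].
#' @param condition Condition label attached to the table.
#' @param spot_threshold Optional intensity threshold for puncta counting
#'   (see [count_puncta()]); `NULL` skips it.
#' @param min_area Minimum punctum area, pixels.
#' @return Data frame of class `colocalization_table`: `cell_id`,
#'   `pearson_r`, `n_pixels`, `cytoplasmic_egfp_mean`,
#'   `cytoplasmic_mcherry_puncta`, `flag`, `condition`.
#' @export
pearson_colocalization <- function(mcherry, egfp, segmentation,
                                   condition = NA_character_,
                                   spot_threshold = NULL, min_area = 4L) {
  stopifnot(inherits(segmentation, "segmentation_result"))
  if (!all(dim(mcherry) == dim(segmentation$nucleus_labels)) ||
      !all(dim(egfp) == dim(mcherry)))
    stop("channels and segmentation must share one shape", call. = FALSE)
  ids <- segmentation$cell_ids
  rows <- lapply(ids, function(id) {
    px <- cell_pixels(segmentation, id, "union")
    a <- mcherry[px]; b <- egfp[px]
    flag <- ""
    r <- NA_real_
    if (length(a) >= 2 && stats::sd(a) > 0 && stats::sd(b) > 0) {
      r <- stats::cor(a, b)
    } else {
      flag <- "zero_variance"
    }
    cyt <- cell_pixels(segmentation, id, "cytoplasm")
    puncta <- if (is.null(spot_threshold)) NA_integer_ else
      count_puncta(mcherry, segmentation, id, spot_threshold, min_area)
    data.frame(cell_id = id, pearson_r = r, n_pixels = length(a),
               cytoplasmic_egfp_mean = mean(egfp[cyt]),
               cytoplasmic_mcherry_puncta = puncta,
               flag = flag, condition = condition,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(cell_id = integer(0), pearson_r = numeric(0),
                      n_pixels = integer(0),
                      cytoplasmic_egfp_mean = numeric(0),
                      cytoplasmic_mcherry_puncta = integer(0),
                      flag = character(0), condition = character(0),
                      stringsAsFactors = FALSE)
  class(out) <- c("colocalization_table", class(out))
  out
}

#' Intensity profile along a line segment
#'
#' Samples a channel by bilinear interpolation at `n_points` evenly spaced
#' positions along the segment from `start` to `end`. Coordinates are
#' 0-based `(row, col)` pixel positions; both endpoints must lie inside the
#' image.
#'
#' @param channel Numeric intensity matrix.
#' @param start,end Numeric pairs `(row, col)`, 0-based.
#' @param n_points Number of samples (>= 2).
#' @return Data frame with `position` (pixels along the segment) and
#'   `intensity`.
#' @export
line_profile <- function(channel, start, end, n_points = 100L) {
  stopifnot(is.matrix(channel), length(start) == 2, length(end) == 2)
  check_number(n_points, "n_points", lower = 2, integer = TRUE)
  lim <- c(nrow(channel), ncol(channel)) - 1
  for (pt in list(start, end)) {
    if (any(pt < 0) || any(pt > lim))
      stop("profile endpoint outside the image", call. = FALSE)
  }
  tt <- seq(0, 1, length.out = n_points)
  ry <- start[1] + tt * (end[1] - start[1])
  rx <- start[2] + tt * (end[2] - start[2])
  y0 <- pmin(floor(ry), lim[1] - 1); y1 <- y0 + 1
  x0 <- pmin(floor(rx), lim[2] - 1); x1 <- x0 + 1
  fy <- ry - y0; fx <- rx - x0
  # 0-based coords -> 1-based matrix indices
  v <- channel[cbind(y0 + 1, x0 + 1)] * (1 - fy) * (1 - fx) +
    channel[cbind(y1 + 1, x0 + 1)] * fy * (1 - fx) +
    channel[cbind(y0 + 1, x1 + 1)] * (1 - fy) * fx +
    channel[cbind(y1 + 1, x1 + 1)] * fy * fx
  data.frame(position = tt * sqrt(sum((end - start)^2)), intensity = v)
}

#' Mean channel intensity over a cell's cytoplasm
#'
#' @param channel Intensity matrix.
#' @param segmentation A [segmentation_result()].
#' @param cell_id Cell identifier present in the segmentation.
#' @return Arithmetic mean intensity over the cell's cytoplasm pixels.
#' @export
cytoplasmic_intensity <- function(channel, segmentation, cell_id) {
  stopifnot(inherits(segmentation, "segmentation_result"))
  if (!cell_id %in% segmentation$cell_ids)
    stop(sprintf("cell id %s not present in segmentation", cell_id),
         call. = FALSE)
  px <- cell_pixels(segmentation, cell_id, "cytoplasm")
  if (!any(px)) stop("empty cytoplasm mask", call. = FALSE)
  mean(channel[px])
}

#' Count puncta in a cell's cytoplasm
#'
#' Flattens the background with a white top-hat (disc brush), thresholds,
#' and counts connected components inside the cell's cytoplasm region whose
#' area is at least `min_area` pixels.
#'
#' @param channel Intensity matrix (typically mCherry).
#' @param segmentation A [segmentation_result()].
#' @param cell_id Cell identifier.
#' @param spot_threshold Intensity threshold on the top-hat image (> 0).
#' @param min_area Minimum component area in pixels (> 0).
#' @param brush_size Odd diameter of the top-hat disc brush, pixels.
#' @return Integer punctum count.
#' @export
count_puncta <- function(channel, segmentation, cell_id, spot_threshold,
                         min_area = 4L, brush_size = 9L) {
  stopifnot(inherits(segmentation, "segmentation_result"))
  check_number(spot_threshold, "spot_threshold", lower = 1e-12)
  check_number(min_area, "min_area", lower = 1)
  th <- EBImage::whiteTopHat(as_ebimage(channel),
                             EBImage::makeBrush(brush_size, shape = "disc"))
  spots <- matrix(as.numeric(th) > spot_threshold, nrow(channel))
  cyt <- cell_pixels(segmentation, cell_id, "cytoplasm")
  comp <- EBImage::bwlabel(as_ebimage(spots & cyt))
  if (max(comp) == 0) return(0L)
  sum(table(comp[comp > 0]) >= min_area)
}

#' Z-factor screening-window statistic
#'
#' `Z = 1 - 3 (sd_pos + sd_neg) / |mean_pos - mean_neg|` with sample SDs;
#' at most 1 by construction. Values near 1 indicate an assay whose control
#' separation is wide relative to its noise; negative values indicate
#' overlapping controls unsuitable for high-throughput screening.
#'
#' @param positive_control,negative_control Numeric vectors (>= 2 values
#'   each) of the assay readout under the two controls.
#' @return The Z-factor (unitless, <= 1).
#' @export
#' @examples
#' z_factor(rnorm(10, 10, 1), rnorm(10, 0, 1))  # ~ 0.4
z_factor <- function(positive_control, negative_control) {
  for (v in list(positive_control, negative_control)) {
    if (!is.numeric(v) || sum(is.finite(v)) < 2)
      stop("each control group needs >= 2 finite values", call. = FALSE)
  }
  mp <- mean(positive_control); mn <- mean(negative_control)
  if (mp == mn)
    stop("control means are equal; Z-factor undefined", call. = FALSE)
  1 - 3 * (stats::sd(positive_control) + stats::sd(negative_control)) /
    abs(mp - mn)
}

#' Compare colocalization across conditions
#'
#' Summarizes per-cell Pearson r by condition and tests pairwise
#' differences, either with two-sided two-sample t-tests over all pairs
#' (`method = "ttest"`) or with a one-way ANOVA F-test followed by pairwise
#' t-tests with Bonferroni correction over the pairs performed
#' (`method = "anova_bonferroni"`). Cells flagged by the colocalization
#' step are excluded. When `positive` and `negative` name two conditions,
#' their per-cell values also yield a [z_factor()].
#'
#' @param tables List of [pearson_colocalization()] tables (each with a
#'   `condition` label), or one combined data frame.
#' @param method `"ttest"` or `"anova_bonferroni"`.
#' @param var_equal Use pooled-variance t-tests instead of Welch.
#' @param positive,negative Optional condition labels used as screening
#'   controls for the Z-factor.
#' @return Object of class `screen_result`: `summary` (condition, mean_r,
#'   sd_r, n_cells), `pairwise` (comparison, statistic, p, p_corrected),
#'   `anova_p` (or `NA`), `z_factor` (or `NA`).
#' @export
compare_conditions <- function(tables,
                               method = c("ttest", "anova_bonferroni"),
                               var_equal = FALSE,
                               positive = NULL, negative = NULL) {
  method <- match.arg(method)
  tab <- if (is.data.frame(tables)) tables else do.call(rbind, tables)
  tab <- tab[is.finite(tab$pearson_r), , drop = FALSE]
  conds <- unique(tab$condition)
  if (length(conds) < 2)
    stop("need >= 2 conditions", call. = FALSE)
  vals <- split(tab$pearson_r, factor(tab$condition, levels = conds))
  small <- names(vals)[vapply(vals, length, integer(1)) < 2]
  if (length(small))
    stop("condition(s) with < 2 usable cells: ",
         paste(small, collapse = ", "), call. = FALSE)
  summary_df <- data.frame(
    condition = conds,
    mean_r = vapply(vals, mean, numeric(1)),
    sd_r = vapply(vals, stats::sd, numeric(1)),
    n_cells = vapply(vals, length, integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  anova_p <- NA_real_
  if (method == "anova_bonferroni") {
    df_long <- data.frame(r = tab$pearson_r, condition = factor(tab$condition))
    anova_p <- summary(stats::aov(r ~ condition, data = df_long))[[1]][
      "condition", "Pr(>F)"]
  }
  pairs <- utils::combn(conds, 2, simplify = FALSE)
  pw <- do.call(rbind, lapply(pairs, function(pr) {
    tt <- stats::t.test(vals[[pr[1]]], vals[[pr[2]]],
                        var.equal = var_equal)
    data.frame(comparison = paste(pr, collapse = " vs "),
               statistic = unname(tt$statistic), p = tt$p.value,
               stringsAsFactors = FALSE)
  }))
  pw$p_corrected <- if (method == "anova_bonferroni")
    stats::p.adjust(pw$p, method = "bonferroni") else pw$p
  zf <- NA_real_
  if (!is.null(positive) && !is.null(negative))
    zf <- z_factor(vals[[positive]], vals[[negative]])
  structure(list(summary = summary_df, pairwise = pw,
                 anova_p = anova_p, method = method, z_factor = zf),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("screen_result (%s)\n", x$method))
  print(x$summary)
  if (is.finite(x$z_factor)) cat(sprintf("Z-factor: %.3f\n", x$z_factor))
  invisible(x)
}
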