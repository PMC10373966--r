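# Pre-ranked gene-set enrichment with a signed log-p ranking metric, the
# classic weighted Kolmogorov-Smirnov running-sum score (weight exponent 1)
# and a gene-permutation null (size-matched random sets).

#' Signed log-p ranking metric
#'
#' Scores every gene as `-log10(p) * sgn(log2fc)` so that strongly
#' significant upregulated genes sit at the top of the ranking and strongly
#' significant downregulated genes at the bottom, and returns the list
#' sorted by descending score. `sgn(0) = 0`. Zero p-values are clamped to
#' the smallest positive double before the log, and a clamp count is
#' recorded in `attr(, "n_clamped")`. Ties in score are broken by gene id
#' (lexicographic) for determinism.
#'
#' @param de A `de_result` from [de_test()], or any data frame with
#'   `gene_id`, `log2fc` and `p` columns.
#' @param literal_sign If `TRUE`, use the literal form `log10(p) * sgn(lfc)`
#'   (which puts significant upregulated genes at the *bottom*); the default
#'   `FALSE` uses the conventional `-log10(p) * sgn(lfc)`.
#' @return A named numeric vector of class `ranked_list`: scores named by
#'   gene id, sorted descending.
#' @export
#' @examples
#' de <- data.frame(gene_id = c("a", "b", "c"),
#'                  log2fc = c(1.5, -1.5, 2), p = c(0.01, 0.01, 1))
#' rank_metric(de)  # a: 2, c: 0, b: -2
rank_metric <- function(de, literal_sign = FALSE) {
  stopifnot(all(c("gene_id", "log2fc", "p") %in% names(de)))
  if (anyDuplicated(de$gene_id))
    stop("duplicate gene ids in DE result", call. = FALSE)
  p <- de$p
  n_clamped <- sum(p == 0, na.rm = TRUE)
  p <- pmax(p, .Machine$double.xmin)
  score <- log10(p) * sign(de$log2fc)
  if (!literal_sign) score <- -score
  names(score) <- de$gene_id
  ord <- order(-score, de$gene_id)
  out <- score[ord]
  attr(out, "n_clamped") <- n_clamped
  class(out) <- "ranked_list"
  out
}

#' Weighted running-sum enrichment score
#'
#' Classic GSEA statistic with weight exponent 1: walking down the ranked
#' list, hitting a set member increments the running sum by
#' `|score| / sum(|score| over the set)` and missing decrements by
#' `1 / (N - K)`; the enrichment score is the signed maximal deviation of
#' the running sum from zero.
#'
#' @param ranked A [rank_metric()] result (named scores, sorted descending).
#' @param set Character vector of gene ids; must intersect the ranked
#'   universe and not cover it.
#' @return List with `es` (in `[-1, 1]`), `peak` (1-based rank position of
#'   the extreme) and `size` (set size after intersection).
#' @export
enrichment_score <- function(ranked, set) {
  ids <- names(ranked)
  n <- length(ids)
  hit <- sort(match(unique(set), ids))
  hit <- hit[!is.na(hit)]
  k <- length(hit)
  if (k == 0) stop("gene set does not intersect the ranked universe",
                   call. = FALSE)
  if (k == n) stop("gene set covers the entire ranked universe",
                   call. = FALSE)
  es_from_hits(as.numeric(ranked), hit, n)
}

# Core statistic given sorted hit indices; running sum is piecewise linear
# between hits, so its extremes occur at hit steps (just after a hit for
# positive peaks, just before for negative troughs).
es_from_hits <- function(scores, hit, n) {
  k <- length(hit)
  w <- abs(scores[hit])
  sw <- sum(w)
  if (sw == 0) w[] <- 1 / k else w <- w / sw
  miss_step <- 1 / (n - k)
  cw <- cumsum(w)
  after <- cw - (hit - seq_len(k)) * miss_step           # just after hit i
  before <- cw - w - (hit - seq_len(k)) * miss_step      # just before hit i
  i_max <- which.max(after)
  i_min <- which.min(before)
  top <- after[i_max]
  bottom <- before[i_min]
  if (top >= -bottom) {
    list(es = top, peak = hit[i_max], size = k)
  } else {
    list(es = bottom, peak = hit[i_min], size = k)
  }
}

#' Read gene sets from a GMT file
#'
#' @param path Path to a tab-separated GMT file (set name, description,
#'   member genes).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Description field written for every set.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, description, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Pre-ranked GSEA with a gene-permutation null
#'
#' For each gene set (intersected with the ranked universe; sets smaller
#' than `min_size` after intersection are dropped with a warning), computes
#' the observed [enrichment_score()] and a null distribution of scores of
#' size-matched random gene sets. Permutations are shared across sets of the
#' same size. The p-value uses the add-one estimator restricted to
#' permutation scores on the same sign side as the observed score:
#' `p = (1 + #\{|ES_perm| >= |ES_obs|, same sign\}) / (1 + n_same_sign)`,
#' and `NES = ES / mean(|ES_perm|, same sign)`. P-values are BH-adjusted
#' across the retained sets and flagged significant at `p_adj < 0.1`.
#'
#' @param ranked A [rank_metric()] result.
#' @param sets Named list of gene-id vectors (e.g. from [read_gmt()]).
#' @param n_perm Number of permutations (>= 100; default 5000).
#' @param seed Integer seed for the permutation draws.
#' @param min_size Minimum set size after intersection (default 2).
#' @return Data frame of class `enrichment_table`: `set`, `size`, `es`,
#'   `nes`, `peak`, `p`, `p_adj`, `significant`.
#' @export
gsea_preranked <- function(ranked, sets, n_perm = 5000L, seed = 1L,
                           min_size = 2L) {
  stopifnot(inherits(ranked, "ranked_list") || is.numeric(ranked))
  check_number(n_perm, "n_perm", lower = 100, integer = TRUE)
  ids <- names(ranked)
  n <- length(ids)
  scores <- as.numeric(ranked)
  keep <- list()
  for (nm in names(sets)) {
    hit <- sort(match(unique(sets[[nm]]), ids))
    hit <- hit[!is.na(hit)]
    if (length(hit) < min_size || length(hit) >= n) {
      warning(sprintf("dropping set '%s' (size %d after intersection)",
                      nm, length(hit)), call. = FALSE)
      next
    }
    keep[[nm]] <- hit
  }
  if (!length(keep))
    stop("no gene set survives intersection with the ranked universe",
         call. = FALSE)
  obs <- lapply(keep, function(h) es_from_hits(scores, h, n))
  sizes <- vapply(keep, length, integer(1))
  with_seed(seed, {
    null_by_size <- lapply(sort(unique(sizes)), function(k) {
      vapply(seq_len(n_perm), function(i)
        es_from_hits(scores, sort(sample.int(n, k)), n)$es, numeric(1))
    })
    names(null_by_size) <- as.character(sort(unique(sizes)))
  })
  rows <- lapply(names(keep), function(nm) {
    o <- obs[[nm]]
    perm <- null_by_size[[as.character(o$size)]]
    same <- if (o$es >= 0) perm[perm >= 0] else perm[perm < 0]
    p <- (1 + sum(abs(same) >= abs(o$es))) / (1 + length(same))
    nes <- if (length(same)) o$es / mean(abs(same)) else NA_real_
    data.frame(set = nm, size = o$size, es = o$es, nes = nes,
               peak = o$peak, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out$significant <- out$p_adj < 0.1
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", class(out))
  out
}
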