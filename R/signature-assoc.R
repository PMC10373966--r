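# Pairwise association between transcriptomic signatures (treatment
# effects, aging signatures, reprogramming signatures): Spearman rank
# correlation of log2 fold changes over the union of each pair's top-N
# most significant genes, BH-adjusted across pairs.

#' Assemble a signature collection
#'
#' @param signatures Named list of data frames, each with columns
#'   `gene_id`, `log2fc`, `p` over a (mostly) shared gene universe.
#' @return Object of class `signature_collection`.
#' @export
signature_collection <- function(signatures) {
  stopifnot(is.list(signatures), !is.null(names(signatures)),
            length(signatures) >= 1)
  for (nm in names(signatures)) {
    s <- signatures[[nm]]
    if (!all(c("gene_id", "log2fc", "p") %in% names(s)))
      stop(sprintf("signature '%s' lacks gene_id/log2fc/p columns", nm),
           call. = FALSE)
    if (any(s$p < 0 | s$p > 1, na.rm = TRUE))
      stop(sprintf("signature '%s' has p-values outside [0, 1]", nm),
           call. = FALSE)
    if (anyDuplicated(s$gene_id))
      stop(sprintf("signature '%s' has duplicate gene ids", nm),
           call. = FALSE)
  }
  structure(signatures, class = "signature_collection")
}

top_genes <- function(sig, top_n) {
  # ties in p broken by gene id for determinism
  ord <- order(sig$p, sig$gene_id)
  sig$gene_id[ord][seq_len(min(top_n, nrow(sig)))]
}

#' Spearman association of two signatures
#'
#' Takes the union of each signature's `top_n` lowest-p genes, keeps those
#' present in both signatures, and computes the Spearman rank correlation
#' of the two log2 fold-change vectors over that union (average ranks for
#' ties; p-value from the t-distribution approximation).
#'
#' @param sigA,sigB Data frames with `gene_id`, `log2fc`, `p`.
#' @param top_n Number of lowest-p genes taken from each signature
#'   (default 300).
#' @return List with `rho`, `p`, `n_used`.
#' @export
spearman_pair <- function(sigA, sigB, top_n = 300L) {
  check_number(top_n, "top_n", lower = 1, integer = TRUE)
  genes <- union(top_genes(sigA, top_n), top_genes(sigB, top_n))
  genes <- genes[genes %in% sigA$gene_id & genes %in% sigB$gene_id]
  if (length(genes) < 3)
    stop("fewer than 3 shared genes in the top union", call. = FALSE)
  a <- sigA$log2fc[match(genes, sigA$gene_id)]
  b <- sigB$log2fc[match(genes, sigB$gene_id)]
  ct <- suppressWarnings(
    stats::cor.test(a, b, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n_used = length(genes))
}

#' Pairwise association matrix of a signature collection
#'
#' [spearman_pair()] over all unordered pairs; BH adjustment across the
#' off-diagonal upper triangle; symmetric fill; the diagonal is `rho = 1`
#' with `p_adj = 0` by convention and is excluded from the adjustment.
#' Pairs that fail (too few shared genes) propagate as `NA` entries with a
#' warning.
#'
#' @param collection A [signature_collection()].
#' @param top_n Per-signature gene count for the top union (default 300).
#' @return Object of class `association_matrix`: matrices `rho`, `p`,
#'   `p_adj`, `n_used`.
#' @export
association_matrix <- function(collection, top_n = 300L) {
  stopifnot(inherits(collection, "signature_collection"))
  nms <- names(collection)
  k <- length(nms)
  if (k < 2) stop("need >= 2 signatures", call. = FALSE)
  rho <- p <- matrix(NA_real_, k, k, dimnames = list(nms, nms))
  n_used <- matrix(NA_integer_, k, k, dimnames = list(nms, nms))
  diag(rho) <- 1
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      res <- tryCatch(
        spearman_pair(collection[[i]], collection[[j]], top_n),
        error = function(e) {
          warning(sprintf("pair (%s, %s): %s", nms[i], nms[j],
                          conditionMessage(e)), call. = FALSE)
          NULL
        })
      if (!is.null(res)) {
        rho[i, j] <- rho[j, i] <- res$rho
        p[i, j] <- p[j, i] <- res$p
        n_used[i, j] <- n_used[j, i] <- res$n_used
      }
    }
  }
  upper <- upper.tri(p)
  p_adj <- matrix(NA_real_, k, k, dimnames = list(nms, nms))
  p_adj[upper] <- bh_adjust(p[upper])
  p_adj[lower.tri(p_adj)] <- t(p_adj)[lower.tri(p_adj)]
  diag(p_adj) <- 0
  structure(list(rho = rho, p = p, p_adj = p_adj, n_used = n_used,
                 top_n = as.integer(top_n)),
            class = "association_matrix")
}

#' @export
print.association_matrix <- function(x, ...) {
  cat(sprintf("association_matrix over %d signatures (top %d union)\n",
              nrow(x$rho), x$top_n))
  print(round(x$rho, 3))
  invisible(x)
}
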