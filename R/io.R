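# Plain-text and TIFF input/output for the package's containers: count
# matrices as TSV or MatrixMarket with sidecars, intensity channels and
# label masks as 16-bit TIFF, tables as TSV.

#' Write a table as TSV
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV table
#'
#' @param path Input path.
#' @return Data frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a count matrix to disk
#'
#' TSV format writes `<prefix>_counts.tsv` (genes in rows, header = sample
#' ids, first column `gene_id`) and `<prefix>_metadata.tsv`; MatrixMarket
#' format writes `<prefix>_counts.mtx` plus `<prefix>_genes.tsv`,
#' `<prefix>_samples.tsv` and the metadata sidecar.
#'
#' @param cm A [count_matrix()].
#' @param prefix Path prefix (directories must exist).
#' @param format `"tsv"` or `"mtx"`.
#' @return Character vector of the files written, invisibly.
#' @export
write_count_matrix <- function(cm, prefix, format = c("tsv", "mtx")) {
  stopifnot(inherits(cm, "count_matrix"))
  format <- match.arg(format)
  meta_path <- paste0(prefix, "_metadata.tsv")
  write_tsv(cm$sample_metadata, meta_path)
  if (format == "tsv") {
    cpath <- paste0(prefix, "_counts.tsv")
    df <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write_tsv(df, cpath)
    files <- c(cpath, meta_path)
  } else {
    cpath <- paste0(prefix, "_counts.mtx")
    Matrix::writeMM(Matrix::Matrix(cm$counts, sparse = TRUE), cpath)
    gpath <- paste0(prefix, "_genes.tsv")
    spath <- paste0(prefix, "_samples.tsv")
    writeLines(rownames(cm$counts), gpath)
    writeLines(colnames(cm$counts), spath)
    files <- c(cpath, gpath, spath, meta_path)
  }
  invisible(files)
}

#' Read a count matrix from disk
#'
#' Reverses [write_count_matrix()] for either format.
#'
#' @param prefix Path prefix used when writing.
#' @param format `"tsv"` or `"mtx"`.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(prefix, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  meta <- read_tsv(paste0(prefix, "_metadata.tsv"))
  if (format == "tsv") {
    df <- read_tsv(paste0(prefix, "_counts.tsv"))
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$gene_id
  } else {
    m <- as.matrix(Matrix::readMM(paste0(prefix, "_counts.mtx")))
    rownames(m) <- readLines(paste0(prefix, "_genes.tsv"))
    colnames(m) <- readLines(paste0(prefix, "_samples.tsv"))
  }
  storage.mode(m) <- "double"
  count_matrix(m, meta)
}

# 16-bit TIFF scaling: intensities are stored as value / scale with scale
# chosen so the maximum maps to 1; the scale is returned/accepted so
# round-trips are linear and invertible.

#' Write an intensity channel as 16-bit TIFF
#'
#' Linearly scales the matrix so its maximum maps to the top of the 16-bit
#' range and writes one-channel TIFF.
#'
#' @param channel Non-negative numeric matrix.
#' @param path Output path.
#' @return The scale factor (intensity units per TIFF unit), invisibly.
#' @export
write_channel_tiff <- function(channel, path) {
  stopifnot(is.matrix(channel), all(channel >= 0))
  scale <- max(channel, 1e-12)
  tiff::writeTIFF(channel / scale, path, bits.per.sample = 16L)
  invisible(scale)
}

#' Read a one-channel TIFF as an intensity matrix
#'
#' @param path Input path.
#' @param scale Intensity units per TIFF unit (default 1 returns values in
#'   `[0, 1]`).
#' @return Numeric matrix.
#' @export
read_channel_tiff <- function(path, scale = 1) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m * scale
}

#' Write a simulated field to a directory
#'
#' Writes both channels and both label masks as 16-bit TIFF plus the
#' per-cell truth table as TSV.
#'
#' @param field A [simulate_ncc_field()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_field <- function(field, dir) {
  stopifnot(inherits(field, "simulated_field"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s1 <- write_channel_tiff(field$mcherry, file.path(dir, "mcherry.tif"))
  s2 <- write_channel_tiff(field$egfp, file.path(dir, "egfp.tif"))
  tiff::writeTIFF(field$nucleus_labels / 65535,
                  file.path(dir, "nucleus_labels.tif"),
                  bits.per.sample = 16L)
  tiff::writeTIFF(field$cytoplasm_labels / 65535,
                  file.path(dir, "cytoplasm_labels.tif"),
                  bits.per.sample = 16L)
  write_tsv(field$per_cell_truth, file.path(dir, "per_cell_truth.tsv"))
  write_tsv(data.frame(file = c("mcherry.tif", "egfp.tif"),
                       scale = c(s1, s2)),
            file.path(dir, "tiff_scales.tsv"))
  invisible(dir)
}

#' Write an association matrix as a TSV trio
#'
#' @param am An [association_matrix()].
#' @param prefix Path prefix; writes `<prefix>_rho.tsv`, `<prefix>_p.tsv`,
#'   `<prefix>_p_adj.tsv`.
#' @return File paths, invisibly.
#' @export
write_association_matrix <- function(am, prefix) {
  stopifnot(inherits(am, "association_matrix"))
  files <- character(0)
  for (part in c("rho", "p", "p_adj")) {
    path <- sprintf("%s_%s.tsv", prefix, part)
    df <- data.frame(signature = rownames(am[[part]]), am[[part]],
                     check.names = FALSE)
    write_tsv(df, path)
    files <- c(files, path)
  }
  invisible(files)
}
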