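# Synthetic two-channel reporter fields. Each cell is a concentric
# disk/annulus pair: the nucleus carries the nuclear-localized mCherry
# signal, the cytoplasmic annulus the nuclear-export eGFP signal. A
# configurable fraction of each cell's total mCherry mass is relocated from
# the nucleus into Gaussian cytoplasmic puncta, emulating the senescent
# loss of nucleocytoplasmic compartmentalization: at fraction 0 the two
# channels are spatially separated (negative per-cell correlation), at high
# fractions mCherry appears where eGFP is, and the correlation rises.
#
# Intensity bookkeeping is exact: per-cell total mCherry is conserved
# across mislocalization settings (signal is moved, never created), so
# noiseless fields satisfy sharp conservation identities that the tests
# assert.

# total per-cell channel masses, arbitrary intensity units
.MCHERRY_MASS <- 5000
.EGFP_MASS <- 5000

#' Configuration for the reporter-field simulator
#'
#' @param height,width Canvas size in pixels.
#' @param n_cells Number of cells to place (non-overlapping; placement is
#'   rejection-sampled and errors out if the canvas cannot hold them).
#' @param nucleus_radius_range,cytoplasm_radius_range Sampling ranges for
#'   the nuclear disk and cytoplasmic outer radius, pixels.
#' @param mislocalization_fraction Fraction in `[0, 1]` of each cell's total
#'   mCherry intensity relocated from the nucleus into cytoplasmic puncta.
#' @param puncta_per_cell Number of puncta per cell (realized counts can be
#'   lower in crowded annuli; the truth table records them).
#' @param puncta_radius Gaussian sigma of a punctum, pixels (truncated at
#'   3 sigma and clipped to the cytoplasm).
#' @param egfp_nuclear_leak Fraction in `[0, 1]` of each cell's eGFP mass
#'   placed in the nucleus instead of the cytoplasm.
#' @param background_level Constant background intensity added everywhere.
#' @param noise_sd SD of additive Gaussian noise (clipped at zero).
#' @param seed Integer seed; identical configs give bit-identical fields.
#' @return An object of class `sim_image_config`.
#' @export
sim_image_config <- function(height = 512L, width = 512L, n_cells = 50L,
                             nucleus_radius_range = c(8, 12),
                             cytoplasm_radius_range = c(18, 26),
                             mislocalization_fraction = 0.3,
                             puncta_per_cell = 6L,
                             puncta_radius = 2,
                             egfp_nuclear_leak = 0.05,
                             background_level = 50,
                             noise_sd = 5,
                             seed = 1L) {
  check_number(height, "height", lower = 8, integer = TRUE)
  check_number(width, "width", lower = 8, integer = TRUE)
  check_number(n_cells, "n_cells", lower = 1, integer = TRUE)
  check_range(nucleus_radius_range, "nucleus_radius_range", lower = 1)
  check_range(cytoplasm_radius_range, "cytoplasm_radius_range", lower = 1)
  if (cytoplasm_radius_range[1] <= nucleus_radius_range[2])
    stop("cytoplasm radii must exceed nucleus radii", call. = FALSE)
  check_number(mislocalization_fraction, "mislocalization_fraction", 0, 1)
  check_number(puncta_per_cell, "puncta_per_cell", lower = 1, integer = TRUE)
  check_number(puncta_radius, "puncta_radius", lower = 0.5)
  check_number(egfp_nuclear_leak, "egfp_nuclear_leak", 0, 1)
  check_number(background_level, "background_level", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(seed, "seed", integer = TRUE)
  structure(list(
    height = as.integer(height), width = as.integer(width),
    n_cells = as.integer(n_cells),
    nucleus_radius_range = nucleus_radius_range,
    cytoplasm_radius_range = cytoplasm_radius_range,
    mislocalization_fraction = mislocalization_fraction,
    puncta_per_cell = as.integer(puncta_per_cell),
    puncta_radius = puncta_radius,
    egfp_nuclear_leak = egfp_nuclear_leak,
    background_level = background_level,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "sim_image_config")
}

disk_pixels <- function(cy, cx, r, height, width) {
  ys <- max(1L, floor(cy - r)):min(height, ceiling(cy + r))
  xs <- max(1L, floor(cx - r)):min(width, ceiling(cx + r))
  g <- expand.grid(y = ys, x = xs)
  d2 <- (g$y - cy)^2 + (g$x - cx)^2
  g[d2 <= r^2, , drop = FALSE]
}

#' Simulate a two-channel reporter field
#'
#' @param config A [sim_image_config()].
#' @return An object of class `simulated_field`: numeric intensity matrices
#'   `mcherry` and `egfp` (rows = y, columns = x), integer label matrices
#'   `nucleus_labels` and `cytoplasm_labels` (0 = background), and a
#'   `per_cell_truth` data frame (cell id, center, radii, true
#'   mislocalization fraction, realized puncta count).
#' @export
#' @examples
#' f <- simulate_ncc_field(sim_image_config(height = 128, width = 128,
#'                                          n_cells = 4, seed = 7))
#' f$per_cell_truth
simulate_ncc_field <- function(config) {
  stopifnot(inherits(config, "sim_image_config"))
  with_seed(config$seed, simulate_field_impl(config))
}

simulate_field_impl <- function(config) {
  h <- config$height; w <- config$width; n <- config$n_cells
  r_nuc <- stats::runif(n, config$nucleus_radius_range[1],
                        config$nucleus_radius_range[2])
  r_cyt <- stats::runif(n, config$cytoplasm_radius_range[1],
                        config$cytoplasm_radius_range[2])
  # rejection-sample non-overlapping centers fully inside the canvas
  cy <- numeric(n); cx <- numeric(n)
  max_attempts <- 2000L * n
  attempts <- 0L
  placed <- 0L
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop(sprintf("could not place %d cells on a %dx%d canvas", n, h, w),
           call. = FALSE)
    r <- r_cyt[placed + 1L]
    if (2 * r + 2 >= min(h, w))
      stop(sprintf("could not place %d cells on a %dx%d canvas", n, h, w),
           call. = FALSE)
    y <- stats::runif(1, r + 1, h - r)
    x <- stats::runif(1, r + 1, w - r)
    if (placed > 0L) {
      d <- sqrt((cy[seq_len(placed)] - y)^2 + (cx[seq_len(placed)] - x)^2)
      if (any(d < r_cyt[seq_len(placed)] + r + 1)) next
    }
    placed <- placed + 1L
    cy[placed] <- y; cx[placed] <- x
  }

  mch <- matrix(0, h, w)
  egfp <- matrix(0, h, w)
  nuc_lab <- matrix(0L, h, w)
  cyt_lab <- matrix(0L, h, w)
  f <- config$mislocalization_fraction
  leak <- config$egfp_nuclear_leak
  sigma <- config$puncta_radius
  puncta_n <- integer(n)

  for (i in seq_len(n)) {
    nuc <- disk_pixels(cy[i], cx[i], r_nuc[i], h, w)
    cyt_all <- disk_pixels(cy[i], cx[i], r_cyt[i], h, w)
    in_nuc <- (cyt_all$y - cy[i])^2 + (cyt_all$x - cx[i])^2 <= r_nuc[i]^2
    cyt <- cyt_all[!in_nuc, , drop = FALSE]
    nuc_idx <- cbind(nuc$y, nuc$x)
    cyt_idx <- cbind(cyt$y, cyt$x)
    nuc_lab[nuc_idx] <- i
    cyt_lab[cyt_idx] <- i

    # mCherry: (1 - f) of the mass uniform over the nucleus
    mch[nuc_idx] <- mch[nuc_idx] + (1 - f) * .MCHERRY_MASS / nrow(nuc)
    # remaining f goes into puncta placed in the annulus, mass-conserving
    if (f > 0) {
      centers <- place_puncta(cy[i], cx[i], r_nuc[i], r_cyt[i],
                              config$puncta_per_cell, sigma)
      puncta_n[i] <- nrow(centers)
      if (nrow(centers) > 0) {
        mass <- f * .MCHERRY_MASS / nrow(centers)
        for (j in seq_len(nrow(centers))) {
          d2 <- (cyt$y - centers$y[j])^2 + (cyt$x - centers$x[j])^2
          kern <- exp(-d2 / (2 * sigma^2))
          kern[d2 > (3 * sigma)^2] <- 0
          if (sum(kern) == 0) kern[which.min(d2)] <- 1
          mch[cyt_idx] <- mch[cyt_idx] + mass * kern / sum(kern)
        }
      } else {
        # annulus too tight for any punctum: keep the mass nuclear
        mch[nuc_idx] <- mch[nuc_idx] + f * .MCHERRY_MASS / nrow(nuc)
      }
    }
    # eGFP: (1 - leak) uniform over the annulus, leak uniform in the nucleus
    egfp[cyt_idx] <- egfp[cyt_idx] + (1 - leak) * .EGFP_MASS / nrow(cyt)
    egfp[nuc_idx] <- egfp[nuc_idx] + leak * .EGFP_MASS / nrow(nuc)
  }

  mch <- mch + config$background_level
  egfp <- egfp + config$background_level
  if (config$noise_sd > 0) {
    mch <- pmax(mch + matrix(stats::rnorm(h * w, 0, config$noise_sd), h, w), 0)
    egfp <- pmax(egfp + matrix(stats::rnorm(h * w, 0, config$noise_sd), h, w), 0)
  }
  realized_f <- ifelse(puncta_n > 0 | f == 0, f, 0)
  truth <- data.frame(
    cell_id = seq_len(n), center_y = cy, center_x = cx,
    nucleus_radius = r_nuc, cytoplasm_radius = r_cyt,
    mislocalization_fraction = realized_f,
    puncta_count = puncta_n
  )
  structure(list(
    mcherry = mch, egfp = egfp,
    nucleus_labels = nuc_lab, cytoplasm_labels = cyt_lab,
    per_cell_truth = truth, config = config
  ), class = "simulated_field")
}

# sample puncta centers in the annulus with their 3-sigma footprint inside
# the cytoplasm and pairwise separation >= 2 sigma + 2 px; bounded attempts,
# so crowded annuli yield fewer puncta (recorded in the truth table)
place_puncta <- function(cy, cx, r_nuc, r_cyt, k, sigma) {
  lo <- r_nuc + 3 * sigma
  hi <- r_cyt - 3 * sigma
  if (hi <= lo) {
    lo <- r_nuc + sigma
    hi <- max(lo, r_cyt - sigma)
  }
  if (hi < lo) return(data.frame(y = numeric(0), x = numeric(0)))
  ys <- numeric(0); xs <- numeric(0)
  attempts <- 0L
  while (length(ys) < k && attempts < 200L * k) {
    attempts <- attempts + 1L
    d <- sqrt(stats::runif(1, lo^2, hi^2))
    a <- stats::runif(1, 0, 2 * pi)
    y <- cy + d * sin(a); x <- cx + d * cos(a)
    if (length(ys) &&
        any((ys - y)^2 + (xs - x)^2 < (4 * sigma + 2)^2)) next
    ys <- c(ys, y); xs <- c(xs, x)
  }
  data.frame(y = ys, x = xs)
}

#' @export
print.simulated_field <- function(x, ...) {
  cat(sprintf("simulated_field: %dx%d px, %d cells, mislocalization %.2f\n",
              nrow(x$mcherry), ncol(x$mcherry), nrow(x$per_cell_truth),
              x$config$mislocalization_fraction))
  invisible(x)
}
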