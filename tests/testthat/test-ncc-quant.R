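# NCC quantification: segmentation against ground truth, per-cell Pearson
# colocalization, profiles, cytoplasmic intensities, puncta, Z-factor and
# condition-level statistics.

field_with <- function(..., seed = 1) {
  simulate_ncc_field(do.call(sim_image_config, c(list(...), seed = seed)))
}

test_that("blank fields give zero cells and shape mismatches error", {
  blank <- matrix(0, 64, 64)
  seg <- segment_field(blank, blank)
  expect_length(seg$cell_ids, 0)
  expect_error(segment_field(matrix(0, 10, 10), matrix(0, 10, 12)),
               "shape")
})

test_that("a single noiseless cell is found with nucleus IoU >= 0.8", {
  f <- field_with(height = 96, width = 96, n_cells = 1,
                  mislocalization_fraction = 0, noise_sd = 0, seed = 2)
  seg <- segment_field(f$mcherry, f$egfp)
  expect_length(seg$cell_ids, 1)
  a <- seg$nucleus_labels > 0
  b <- f$nucleus_labels > 0
  expect_gte(sum(a & b) / sum(a | b), 0.8)
})

test_that("detected cell count is within 10% of truth at default config", {
  hits <- vapply(1:3, function(s) {
    f <- field_with(height = 384, width = 384, n_cells = 25, seed = s)
    length(segment_field(f$mcherry, f$egfp)$cell_ids)
  }, numeric(1))
  expect_true(all(abs(hits - 25) <= 2.5))
})

test_that("Pearson colocalization hits the analytic anchors", {
  f <- field_with(height = 128, width = 128, n_cells = 3, seed = 3)
  seg <- truth_segmentation(f)
  # identical channels: r = 1 everywhere
  tab <- pearson_colocalization(f$mcherry, f$mcherry, seg)
  expect_equal(tab$pearson_r, rep(1, 3))
  # negative affine image: r = -1
  tab2 <- pearson_colocalization(f$mcherry, max(f$mcherry) - f$mcherry, seg)
  expect_equal(tab2$pearson_r, rep(-1, 3))
  # invariance under positive affine rescaling of either channel
  tab3 <- pearson_colocalization(f$mcherry, f$egfp, seg)
  tab4 <- pearson_colocalization(2.5 * f$mcherry + 7, 0.3 * f$egfp + 1, seg)
  expect_equal(tab4$pearson_r, tab3$pearson_r, tolerance = 1e-9)
})

test_that("zero-variance regions are flagged and excluded", {
  f <- field_with(height = 96, width = 96, n_cells = 1, noise_sd = 0,
                  seed = 4)
  seg <- truth_segmentation(f)
  flat <- matrix(5, nrow(f$mcherry), ncol(f$mcherry))
  tab <- pearson_colocalization(flat, f$egfp, seg)
  expect_true(is.na(tab$pearson_r[1]))
  expect_equal(tab$flag[1], "zero_variance")
})

test_that("colocalization rises with the mislocalization fraction", {
  mean_r <- function(f, s) {
    fl <- field_with(height = 256, width = 256, n_cells = 10,
                     mislocalization_fraction = f, seed = s)
    tab <- pearson_colocalization(fl$mcherry, fl$egfp,
                                  truth_segmentation(fl))
    mean(tab$pearson_r, na.rm = TRUE)
  }
  seeds <- 1:5
  r0 <- mean(vapply(seeds, function(s) mean_r(0.0, s), numeric(1)))
  r8 <- mean(vapply(seeds, function(s) mean_r(0.8, s), numeric(1)))
  expect_gt(r8, r0)
})

test_that("line profiles interpolate bilinearly", {
  m <- matrix(7, 32, 32)
  prof <- line_profile(m, c(2, 2), c(20, 25), n_points = 11)
  expect_equal(prof$intensity, rep(7, 11))
  # two points return exactly the endpoints
  m2 <- matrix(seq_len(64), 8, 8)
  prof2 <- line_profile(m2, c(0, 0), c(7, 7), n_points = 2)
  expect_equal(prof2$intensity, c(m2[1, 1], m2[8, 8]))
  # midpoint of a linear ramp is the average of the endpoints
  ramp <- outer(0:7, rep(1, 8))
  prof3 <- line_profile(ramp, c(0, 3), c(7, 3), n_points = 3)
  expect_equal(prof3$intensity[2], 3.5)
  expect_error(line_profile(m, c(-1, 0), c(5, 5)), "outside")
})

test_that("profile through a compartmentalized cell peaks in the nucleus", {
  f <- field_with(height = 96, width = 96, n_cells = 1,
                  mislocalization_fraction = 0, noise_sd = 0, seed = 5)
  tr <- f$per_cell_truth
  start <- c(tr$center_y - tr$cytoplasm_radius, tr$center_x) - c(2, 0)
  end <- c(tr$center_y + tr$cytoplasm_radius, tr$center_x) + c(2, 0)
  prof <- line_profile(f$mcherry, start, end, n_points = 101)
  peak_pos <- prof$position[which.max(prof$intensity)]
  # nucleus occupies the central band of the transect (1 px margin for
  # the pixelized disk boundary)
  nuc_lo <- tr$cytoplasm_radius + 2 - tr$nucleus_radius - 1
  nuc_hi <- tr$cytoplasm_radius + 2 + tr$nucleus_radius + 1
  expect_gte(peak_pos, nuc_lo)
  expect_lte(peak_pos, nuc_hi)
})

test_that("cytoplasmic intensity is the plain mean over the annulus", {
  f <- field_with(height = 96, width = 96, n_cells = 1, seed = 6)
  seg <- truth_segmentation(f)
  flat <- matrix(3.25, 96, 96)
  expect_equal(cytoplasmic_intensity(flat, seg, 1), 3.25)
  expect_equal(cytoplasmic_intensity(matrix(0, 96, 96), seg, 1), 0)
  expect_error(cytoplasmic_intensity(flat, seg, 99), "not present")
})

test_that("eGFP nuclear leak lowers the cytoplasmic eGFP mean", {
  base <- list(height = 128, width = 128, n_cells = 3, noise_sd = 0,
               background_level = 0, seed = 7)
  f_leak0 <- simulate_ncc_field(do.call(sim_image_config,
                                        c(base, egfp_nuclear_leak = 0)))
  f_leak5 <- simulate_ncc_field(do.call(sim_image_config,
                                        c(base, egfp_nuclear_leak = 0.5)))
  m0 <- cytoplasmic_intensity(f_leak0$egfp, truth_segmentation(f_leak0), 1)
  m5 <- cytoplasmic_intensity(f_leak5$egfp, truth_segmentation(f_leak5), 1)
  expect_lt(m5, m0)
})

test_that("puncta counting matches the simulated ground truth", {
  f <- field_with(height = 128, width = 128, n_cells = 1,
                  mislocalization_fraction = 0.8, puncta_per_cell = 5,
                  puncta_radius = 2, nucleus_radius_range = c(8, 8),
                  cytoplasm_radius_range = c(30, 30), noise_sd = 0,
                  background_level = 0, egfp_nuclear_leak = 0, seed = 4)
  seg <- truth_segmentation(f)
  peak <- max(f$mcherry[f$cytoplasm_labels > 0])
  expect_equal(count_puncta(f$mcherry, seg, 1, spot_threshold = peak / 10),
               f$per_cell_truth$puncta_count)
  # a mislocalization-free noiseless cell has zero puncta
  f0 <- field_with(height = 96, width = 96, n_cells = 1,
                   mislocalization_fraction = 0, noise_sd = 0,
                   background_level = 0, seed = 4)
  expect_equal(count_puncta(f0$mcherry, truth_segmentation(f0), 1,
                            spot_threshold = 1), 0L)
  # components below min_area are filtered out
  expect_equal(count_puncta(f$mcherry, seg, 1, spot_threshold = peak / 10,
                            min_area = 1e4), 0L)
})

test_that("Z-factor follows the screening-window formula", {
  # noiseless separated controls: exactly 1
  expect_equal(z_factor(c(10, 10, 10), c(0, 0, 0)), 1)
  # mu 10 vs 0 with unit sample SDs: 1 - 3*(1+1)/10 = 0.4
  unit_sd <- function(x, mu) mu + (x - mean(x)) / sd(x)
  pos <- unit_sd(rnorm(20), 10)
  neg <- unit_sd(rnorm(20), 0)
  expect_equal(z_factor(pos, neg), 0.4, tolerance = 1e-12)
  # symmetric in the two controls, invariant under common affine maps
  expect_equal(z_factor(neg, pos), z_factor(pos, neg))
  expect_equal(z_factor(3 * pos + 2, 3 * neg + 2), z_factor(pos, neg),
               tolerance = 1e-12)
  expect_error(z_factor(c(1, 1), c(1, 1)), "equal")
  expect_error(z_factor(1, c(0, 0)), ">= 2")
})

test_that("condition comparisons: degenerate and capped cases", {
  mk <- function(r, cond) data.frame(cell_id = seq_along(r), pearson_r = r,
                                     n_pixels = 100,
                                     cytoplasmic_egfp_mean = 1,
                                     cytoplasmic_mcherry_puncta = NA,
                                     flag = "", condition = cond)
  # identical groups: t = 0, p = 1 (pooled form; Welch is 0/0 here)
  a <- mk(c(0.1, 0.2, 0.3), "a")
  b <- mk(c(0.1, 0.2, 0.3), "b")
  res <- compare_conditions(list(a, b), method = "ttest", var_equal = TRUE)
  expect_equal(res$pairwise$statistic, 0)
  expect_equal(res$pairwise$p, 1)
  # Bonferroni over m pairs = min(1, m * p), capped at 1
  set.seed(1)
  tabs <- lapply(c("a", "b", "c"), function(cc) mk(rnorm(20, 0, 0.1), cc))
  res3 <- compare_conditions(tabs, method = "anova_bonferroni")
  expect_equal(res3$pairwise$p_corrected, pmin(1, 3 * res3$pairwise$p))
  expect_true(all(res3$pairwise$p_corrected >= res3$pairwise$p))
  expect_true(all(res3$pairwise$p_corrected <= 1))
  expect_error(compare_conditions(list(a)), ">= 2 conditions")
  expect_error(compare_conditions(list(a, mk(0.5, "c"))), "< 2 usable")
})

test_that("t-test rejection rate matches the closed-form power", {
  # per-cell r shifted by 1 SD, n = 100 cells per condition
  target <- power.t.test(n = 100, delta = 1, sd = 1,
                         sig.level = 0.05)$power
  set.seed(33)
  rej <- mean(vapply(1:200, function(i) {
    x <- rnorm(100); y <- rnorm(100, 1)
    tab <- rbind(
      data.frame(cell_id = 1:100, pearson_r = x, n_pixels = 1,
                 cytoplasmic_egfp_mean = 1, cytoplasmic_mcherry_puncta = NA,
                 flag = "", condition = "neg"),
      data.frame(cell_id = 1:100, pearson_r = y, n_pixels = 1,
                 cytoplasmic_egfp_mean = 1, cytoplasmic_mcherry_puncta = NA,
                 flag = "", condition = "pos"))
    compare_conditions(tab, method = "ttest")$pairwise$p < 0.05
  }, logical(1)))
  expect_lt(abs(rej - target), 0.05)
})
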