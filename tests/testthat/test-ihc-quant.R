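# IHC quantification: tissue masking, erosion, the three-step neuron
# detector, brown detection, cluster filtering, percent area and count
# calibration.

test_that("all-white image yields an empty tissue mask, not an error", {
  white <- array(255, c(64, 64, 3))
  qc <- quant_config()
  expect_warning(tis <- compute_tissue_mask(white, qc), "empty")
  expect_equal(tis$area_um2, 0)
})

test_that("tissue mask recovers the generated section (Jaccard >= 0.95)", {
  cfg <- small_scene(n_cells = 10, seed = 2)
  sec <- render_section(build_scene(cfg), cfg)
  qc <- quant_config()
  tis <- compute_tissue_mask(sec$rgb, qc)
  truth <- sec$truth$tissue_mask_true
  jac <- sum(tis$mask & truth) / sum(tis$mask | truth)
  expect_gte(jac, 0.95)
  # area definition: pixel count times the squared scale
  expect_equal(tis$area_um2, sum(tis$mask) * 0.65^2)
})

test_that("mask erosion is anti-extensive and matches the disk closed form", {
  qc <- quant_config()
  # a solid disk of radius 100 um eroded by 10 um leaves ~ pi * 90^2
  r_px <- 100 / qc$um_per_pixel
  n <- 2 * ceiling(r_px) + 21
  ctr <- (n + 1) / 2
  disk <- outer(seq_len(n), seq_len(n),
                function(i, j) (i - ctr)^2 + (j - ctr)^2 <= r_px^2)
  tis <- structure(list(mask = disk, area_um2 = sum(disk) * 0.65^2,
                        um_per_pixel = 0.65), class = "tissue_mask")
  same <- erode_tissue_mask(tis, 0)
  expect_identical(same$mask, tis$mask)
  er <- erode_tissue_mask(tis, 10)
  expect_lt(abs(er$area_um2 - pi * 90^2) / (pi * 90^2), 0.05)
  expect_true(all(tis$mask[er$mask]))         # subset of the input
  expect_lte(er$area_um2, tis$area_um2)
})

test_that("blank tissue has zero detected neurons", {
  cfg <- small_scene(n_cells = 0, seed = 4)
  sec <- render_section(build_scene(cfg), cfg)
  qc <- quant_config()
  tis <- compute_tissue_mask(sec$rgb, qc)
  det <- detect_motor_neurons(sec$rgb, tis, qc)
  expect_identical(det$count, 0L)
})

test_that("clean fixtures: exact count and centroids within 5 um", {
  cfg <- scene_config(canvas_px = c(512, 512), n_cells = 30,
                      n_touching_pairs = 0, seed = 2)
  truth <- build_scene(cfg)
  sec <- render_section(truth, cfg)
  qc <- quant_config()
  tis <- compute_tissue_mask(sec$rgb, qc)
  det <- detect_motor_neurons(sec$rgb, tis, qc)
  expect_identical(det$count, 30L)
  for (i in seq_len(30)) {
    dists <- sqrt(colSums((t(det$centroids) - truth$cell_centroids[i, ])^2))
    expect_lt(min(dists) * cfg$um_per_pixel, 5)
  }
  # areas respect the inclusive size filter
  expect_true(all(det$areas_um2 >= qc$min_cell_area_um2))
  expect_true(all(det$areas_um2 <= qc$max_cell_area_um2))
})

test_that("watershed splits abutting pairs: 6 cells from 3 pairs", {
  cfg <- scene_config(canvas_px = c(512, 512), n_cells = 6,
                      n_touching_pairs = 3, seed = 6)
  sec <- render_section(build_scene(cfg), cfg)
  qc <- quant_config()
  tis <- compute_tissue_mask(sec$rgb, qc)
  det <- detect_motor_neurons(sec$rgb, tis, qc)
  expect_identical(det$count, 6L)
})

test_that("brown rule separates stain from counterstain and guards zeros", {
  qc <- quant_config()
  img <- array(0, c(4, 4, 3))
  img[1:2, , 1] <- 130; img[1:2, , 2] <- 80; img[1:2, , 3] <- 40   # DAB brown
  img[3:4, , 1] <- 190; img[3:4, , 2] <- 190; img[3:4, , 3] <- 210 # tissue
  tis <- structure(list(mask = matrix(TRUE, 4, 4), area_um2 = 16 * 0.65^2,
                        um_per_pixel = 0.65), class = "tissue_mask")
  qc0 <- quant_config(brown_smooth_radius_um = 0)
  pos <- detect_brown_positive(img, tis, qc0)
  expect_true(all(pos[1:2, ]))
  expect_false(any(pos[3:4, ]))
  # all-black image: intensity passes but the zero-sum guard holds
  black <- array(0, c(4, 4, 3))
  expect_false(any(detect_brown_positive(black, tis, qc0)))
})

test_that("positive-pixel count is monotone in the blue-ratio threshold", {
  cfg <- small_scene(n_cells = 5, diffuse_fraction = 0.1, noise_sd = 5,
                     seed = 9)
  sec <- render_section(build_scene(cfg), cfg)
  tis <- compute_tissue_mask(sec$rgb, quant_config())
  counts <- vapply(c(0.1, 0.2, 0.25, 0.3, 0.4), function(thr) {
    qc <- quant_config(brown_rule = list(blue_ratio_max = thr,
                                         intensity_max = 220),
                       brown_smooth_radius_um = 0)
    sum(detect_brown_positive(sec$rgb, tis, qc))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("minimum-area filter drops small clusters and only removes", {
  px <- 0.65
  m <- matrix(FALSE, 60, 60)
  # component of ~100 um^2 (237 px -> use a 15x16 block = 240 px ~ 101 um^2)
  m[5:19, 5:20] <- TRUE
  # component of ~200 um^2 (474 px -> 21x23 = 483 px ~ 204 um^2)
  m[35:55, 30:52] <- TRUE
  out <- filter_by_min_area(m, 180, px)
  expect_false(any(out[5:19, 5:20]))
  expect_true(all(out[35:55, 30:52]))
  expect_identical(filter_by_min_area(m, 0, px), m)
  expect_lte(sum(out), sum(m))
})

test_that("percent area stained is exact arithmetic and bounded", {
  tis <- structure(list(mask = matrix(TRUE, 40, 40),
                        area_um2 = 1600 * 0.65^2, um_per_pixel = 0.65),
                   class = "tissue_mask")
  pos <- matrix(FALSE, 40, 40); pos[1:20, 1:20] <- TRUE
  q <- percent_area_stained(pos, tis)
  expect_equal(q$percent_area, 25)
  expect_equal(percent_area_stained(matrix(TRUE, 40, 40), tis)$percent_area,
               100)
  empty <- structure(list(mask = matrix(FALSE, 4, 4), area_um2 = 0,
                          um_per_pixel = 0.65), class = "tissue_mask")
  expect_error(percent_area_stained(pos[1:4, 1:4], empty), "undefined")
})

test_that("diffuse stain fraction is recovered within one percentage point", {
  cfg <- scene_config(canvas_px = c(512, 512), n_cells = 0,
                      diffuse_fraction = 0.12, seed = 5)
  truth <- build_scene(cfg)
  sec <- render_section(truth, cfg)
  q <- quantify_section(sec$rgb, quant_config(), mode = "area")
  expect_lt(abs(q$percent_area - 100 * truth$diffuse_area_fraction_true), 1)
})

test_that("count calibration: exact lines and noisy OLS recovery", {
  manual <- c(40, 55, 60, 75, 90)
  cal <- calibrate_automated_counts(manual, 0.75 * manual)
  expect_equal(cal$slope, 0.75)
  expect_equal(cal$r_squared, 1)
  expect_equal(cal$mean_bias_fraction, 0.25)
  ident <- calibrate_automated_counts(manual, manual)
  expect_equal(ident$slope, 1)
  expect_equal(ident$mean_bias_fraction, 0)
  set.seed(14)
  manual <- round(runif(20, 30, 90))
  auto <- 0.75 * manual + rnorm(20, 0, 2)
  noisy <- calibrate_automated_counts(manual, auto)
  expect_lt(abs(noisy$slope - 0.75), 0.1)
  expect_error(calibrate_automated_counts(rep(50, 4), rep(40, 4)),
               "degenerate")
})
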