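# Segmentation and morphometrics against generator ground truth and
# analytic fixtures.

test_that("nucleus segmentation recovers disjoint nuclei with high IoU", {
  p <- tiny_profile(cells_per_image = 5)
  g <- generate_cell_image(p, c(256, 256), seed = 2)
  nuc <- segment_nuclei(g$image)
  expect_equal(max(nuc), 5)
  m <- match_instances(nuc, g$truth$nuclei_mask)
  expect_true(all(m$iou >= 0.95))
})

test_that("blank or constant DNA channel raises a degenerate-input error", {
  img <- list(dna = matrix(0, 128, 128))
  expect_error(segment_nuclei(img), "degenerate")
})

test_that("watershed splits two nuclei fused by a thin bridge", {
  dna <- matrix(0, 128, 128)
  rg <- matrix(rep(1:128, 128), 128); cg <- t(rg)
  dna[(rg - 60)^2 + (cg - 50)^2 <= 14^2] <- 100
  dna[(rg - 60)^2 + (cg - 82)^2 <= 14^2] <- 100
  dna[59:60, 60:75] <- 100  # 2-px bridge
  nuc <- segment_nuclei(list(dna = dna))
  expect_equal(max(nuc), 2)
})

test_that("cell segmentation assigns one cell per nucleus and contains its seed", {
  p <- tiny_profile(cells_per_image = 4)
  g <- generate_cell_image(p, c(256, 256), seed = 9)
  nuc <- segment_nuclei(g$image)
  cells <- segment_cells(g$image, nuc)
  m <- match_instances(cells, g$truth$cell_mask)
  expect_true(all(m$iou >= 0.9))
  for (k in seq_len(max(nuc))) {
    under <- cells[nuc == k]
    expect_true(all(under == under[1]) && under[1] > 0)
  }
  expect_error(segment_cells(g$image, matrix(0L, 256, 256)), "no nuclei")
})

test_that("fiber segmentation recovers count and length, and stays empty without fibers", {
  p <- tiny_profile(cells_per_image = 1, fiber_count_mean = 0)
  g <- generate_cell_image(p, c(192, 192), seed = 1)
  nuc <- segment_nuclei(g$image)
  cells <- segment_cells(g$image, nuc)
  expect_false(any(segment_stress_fibers(g$image, cells)))

  # three fibers of known length, drawn directly into a flat cell body
  actin <- matrix(20, 192, 192)
  rg <- matrix(rep(1:192, 192), 192); cg <- t(rg)
  cell_truth <- (rg - 96)^2 + (cg - 96)^2 <= 80^2
  actin[cell_truth] <- 70
  for (off in c(-30, 0, 30)) {
    rows <- (96 + off - 1):(96 + off)
    actin[rows, 77:116] <- 170  # 40 px long, 2 px wide
  }
  cells_m <- matrix(0L, 192, 192); cells_m[cell_truth] <- 1L
  fib <- segment_stress_fibers(list(actin = actin), cells_m)
  lens <- hippoquant:::component_lengths(hippoquant:::label8(fib))
  expect_length(lens, 3)
  expect_true(all(abs(lens - 40) <= 3))

  # uniform actin: no ridges -> empty mask
  actin_u <- matrix(20, 192, 192); actin_u[cell_truth] <- 70
  expect_false(any(segment_stress_fibers(list(actin = actin_u), cells_m)))
})

test_that("moment ellipse of an analytic 40x20 ellipse has axis ratio 0.5", {
  rg <- matrix(rep(1:160, 160), 160); cg <- t(rg)
  lab <- matrix(0L, 160, 160)
  lab[((rg - 80) / 40)^2 + ((cg - 80) / 20)^2 <= 1] <- 1L
  props <- region_props(lab)
  expect_equal(props$eccentricity_ratio, 0.5, tolerance = 0.02)
  expect_equal(props$major_axis, 80, tolerance = 0.03 * 80)
  expect_equal(props$solidity, 1)
})

test_that("full pipeline matches ground truth within 5% on noise-free images", {
  # displacement fraction large enough that 5% of the truth displacement
  # exceeds the sub-pixel discretisation floor of the centroids
  p <- tiny_profile(cells_per_image = 5, fiber_count_mean = 2,
                    nucleus_displacement_frac_mean = 0.2)
  g <- generate_cell_image(p, c(256, 256), seed = 13)
  nuc <- segment_nuclei(g$image)
  cells <- segment_cells(g$image, nuc)
  fib <- segment_stress_fibers(g$image, cells)
  rec <- measure_cells(g$image, nuc, cells, fib)
  m <- match_instances(nuc, g$truth$nuclei_mask)
  tr <- g$truth$cells
  for (f in cell_metric_names()) {
    tv <- tr[[f]][match(m$truth_label, tr$cell_id)]
    pv <- rec[[f]][match(m$pred_label, rec$nucleus_id)]
    ok <- is.finite(tv) & is.finite(pv)
    expect_true(all(abs(pv[ok] - tv[ok]) <= 0.05 * pmax(abs(tv[ok]), 1e-9)),
                info = f)
  }
})

test_that("intensity invariance: adding a constant shifts means by that constant", {
  p <- tiny_profile(cells_per_image = 3)
  g <- generate_cell_image(p, c(256, 256), seed = 4)
  nuc <- segment_nuclei(g$image)
  cells <- segment_cells(g$image, nuc)
  r0 <- measure_cells(g$image, nuc, cells)
  img2 <- g$image; img2$protein <- img2$protein + 37.5
  r1 <- measure_cells(img2, nuc, cells)
  expect_equal(r1$mean_nuc_intensity, r0$mean_nuc_intensity + 37.5)
  expect_equal(r1$mean_cyto_intensity, r0$mean_cyto_intensity + 37.5)
})

test_that("scale covariance: 2x upsampling preserves ratios and doubles displacement", {
  # larger nuclei keep the blocky upsampled boundary a small fraction of
  # the region, as the covariance property is asymptotic in region size
  p <- tiny_profile(cells_per_image = 2, nucleus_displacement_frac_mean = 0.2,
                    nucleus_radius_mean = 20)
  g <- generate_cell_image(p, c(256, 256), seed = 6)
  up <- function(m) m[rep(seq_len(nrow(m)), each = 2),
                      rep(seq_len(ncol(m)), each = 2)]
  r0 <- measure_cells(g$image, g$truth$nuclei_mask, g$truth$cell_mask)
  img2 <- lapply(g$image, up)
  r1 <- measure_cells(img2, up(g$truth$nuclei_mask), up(g$truth$cell_mask))
  for (f in c("eccentricity_ratio", "solidity", "nc_area_ratio")) {
    expect_equal(r1[[f]], r0[[f]], tolerance = 0.02, info = f)
  }
  expect_equal(r1$nuclear_displacement, 2 * r0$nuclear_displacement,
               tolerance = 0.05)
})

test_that("shape metrics stay in their ranges across seeds", {
  for (s in 1:5) {
    g <- generate_cell_image(tiny_profile(noise_sd = 8), c(192, 192), seed = s)
    nuc <- segment_nuclei(g$image)
    cells <- segment_cells(g$image, nuc)
    fib <- segment_stress_fibers(g$image, cells)
    rec <- measure_cells(g$image, nuc, cells, fib)
    expect_true(all(rec$eccentricity_ratio > 0 & rec$eccentricity_ratio <= 1))
    expect_true(all(rec$solidity > 0 & rec$solidity <= 1))
    expect_true(all(rec$pct_fiber_area >= 0 & rec$pct_fiber_area <= 100))
    expect_true(all(rec$nuclear_displacement >= 0))
  }
})

test_that("estimate_effect reproduces the exact rank-sum p for {1,2,3} vs {4,5,6}", {
  mk <- function(v) {
    r <- do.call(rbind, lapply(seq_along(v), function(i)
      data.frame(cell_id = i, nucleus_id = i, nuclear_area = v[i], flag = "ok")))
    r
  }
  e <- estimate_effect(mk(1:3), mk(4:6), "nuclear_area")
  # all 3 alt values exceed all ref values: U = 0, exact two-sided p = 2/20
  expect_equal(e$p_value, 0.1)
  expect_equal(e$percent_change, 100 * (5 - 2) / 2)
  # identical groups: no change, p = 1
  e0 <- estimate_effect(mk(c(1, 2, 3, 4)), mk(c(1, 2, 3, 4)), "nuclear_area")
  expect_equal(e0$percent_change, 0)
  expect_gt(e0$p_value, 0.9)
  expect_error(estimate_effect(mk(1:3), mk(4:6), "no_such_metric"),
               "valid metrics")
})
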