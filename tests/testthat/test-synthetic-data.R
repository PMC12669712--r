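# Generators: determinism, ground-truth structure, closed-form examples.

test_that("image generator is a pure function of (profile, seed)", {
  p <- tiny_profile()
  g1 <- generate_cell_image(p, c(192, 192), seed = 42)
  g2 <- generate_cell_image(p, c(192, 192), seed = 42)
  expect_identical(g1$image, g2$image)
  expect_identical(g1$truth$nuclei_mask, g2$truth$nuclei_mask)
  g3 <- generate_cell_image(p, c(192, 192), seed = 43)
  expect_false(identical(g1$image$dna, g3$image$dna))
})

test_that("concentric-circles profile yields d = 0, axis ratio 1, solidity 1 exactly", {
  g <- generate_cell_image(concentric_profile(), c(128, 128), seed = 7)
  tc <- g$truth$cells
  expect_equal(tc$nuclear_displacement, 0)
  expect_equal(tc$eccentricity_ratio, 1)
  expect_equal(tc$solidity, 1)
})

test_that("noise-free single-cell protein channel has exactly three levels", {
  p <- tiny_profile(cells_per_image = 1, fiber_count_mean = 0, noise_sd = 0)
  g <- generate_cell_image(p, c(128, 128), seed = 3)
  expect_length(unique(as.vector(g$image$protein)), 3)
  expect_setequal(unique(as.vector(g$image$protein)),
                  c(p$background_level, p$yap_cyto_mean, p$yap_nuclear_mean))
})

test_that("ground truth is self-consistent: measuring truth masks reproduces truth records", {
  p <- tiny_profile(fiber_count_mean = 2)
  g <- generate_cell_image(p, c(192, 192), seed = 11)
  # re-measure on the noise-free reconstruction of the channels
  clean <- g$image  # noise_sd = 0 in tiny_profile, image is noise-free
  re <- measure_cells(clean, g$truth$nuclei_mask, g$truth$cell_mask,
                      g$truth$fiber_mask)
  for (f in cell_metric_names()) {
    expect_equal(re[[f]], g$truth$cells[[f]], tolerance = 1e-6, info = f)
  }
})

test_that("effect monotonicity: higher nuclear protein level raises truth nuclear intensity", {
  lo <- generate_cell_image(tiny_profile(yap_nuclear_mean = 100), c(192, 192), seed = 5)
  hi <- generate_cell_image(tiny_profile(yap_nuclear_mean = 200), c(192, 192), seed = 5)
  expect_lt(mean(lo$truth$cells$mean_nuc_intensity),
            mean(hi$truth$cells$mean_nuc_intensity))
})

test_that("too-small image shapes are rejected with a clear constraint", {
  expect_error(generate_cell_image(tiny_profile(), c(100, 100), seed = 1),
               "128")
  p <- tiny_profile(cells_per_image = 40, nucleus_radius_mean = 20,
                    nucleus_radius_sd = 0)
  expect_error(generate_cell_image(p, c(128, 128), seed = 1),
               "too small to place")
})

test_that("condition sets preserve labels, count images, reject empty requests", {
  profs <- list(tiny_profile("A"), tiny_profile("B"))
  set <- generate_condition_set(profs, n_images = 3,
                                image_shape = c(192, 192), seed = 1)
  expect_length(set, 6)
  expect_equal(sort(unique(vapply(set, `[[`, "", "condition"))), c("A", "B"))
  expect_error(generate_condition_set(profs, n_images = 0, seed = 1),
               "n_images")
  # identical profiles, different seeds: truth means agree within 3 SEM
  s1 <- generate_condition_set(list(tiny_profile(cells_per_image = 8)),
                               n_images = 3, image_shape = c(256, 256), seed = 1)
  s2 <- generate_condition_set(list(tiny_profile(cells_per_image = 8)),
                               n_images = 3, image_shape = c(256, 256), seed = 99)
  a1 <- unlist(lapply(s1, function(g) g$truth$cells$nuclear_area))
  a2 <- unlist(lapply(s2, function(g) g$truth$cells$nuclear_area))
  sem <- sqrt(sd(a1)^2 / length(a1) + sd(a2)^2 / length(a2))
  expect_lt(abs(mean(a1) - mean(a2)), 3 * sem)
})

test_that("CT generator follows the closed form CT = ref - log2(FC)", {
  d <- ct_design(genes = c("T1", "REF"), reference_gene = "REF",
                 conditions = c("ctl", "trt"), calibrator_condition = "ctl",
                 true_fold_change = list(T1 = list(ctl = 1, trt = 2),
                                         REF = list(ctl = 1, trt = 1)),
                 ct_noise_sd = 0)
  tab <- generate_ct_table(d, seed = 1)
  t_trt <- tab$ct[tab$gene == "T1" & tab$condition == "trt"]
  t_ctl <- tab$ct[tab$gene == "T1" & tab$condition == "ctl"]
  expect_equal(unique(t_ctl - t_trt), 1)  # FC 2 -> one cycle earlier
  ref <- tab$ct[tab$gene == "REF"]
  expect_equal(unique(ref), d$reference_ct_mean)  # condition-independent
  expect_equal(nrow(tab), 2 * 2 * 3 * 3)  # genes x conditions x reps x runs
})

test_that("CT design rejects non-positive fold changes and bad references", {
  expect_error(ct_design(genes = c("T1", "REF"), reference_gene = "REF",
                         conditions = c("a", "b"), calibrator_condition = "a",
                         true_fold_change = list(T1 = list(a = 1, b = -2),
                                                 REF = list(a = 1, b = 1))),
               "non-positive")
  expect_error(ct_design(genes = c("T1", "REF"), reference_gene = "REF",
                         conditions = c("a", "b"), calibrator_condition = "a",
                         true_fold_change = list(T1 = list(a = 1, b = 2),
                                                 REF = list(a = 1, b = 1.5))),
               "reference gene")
})

test_that("mass-event generator matches its closed-form mixture moments", {
  # degenerate: one species, zero spread
  d0 <- mass_design(data.frame(name = "A", mass = 150, fraction = 1),
                    n_events = 100, mass_sd = 0)
  ev0 <- generate_mass_events(d0, seed = 1)
  expect_true(all(ev0$events$mass_kda == 150))
  # 50/50 mixture: sample mean within 3 SE of the mixture mean
  d <- mass_design(data.frame(name = c("A", "B"), mass = c(100, 500),
                              fraction = c(0.5, 0.5)),
                   n_events = 10000, mass_sd = 8)
  ev <- generate_mass_events(d, seed = 2)
  mix_mean <- 0.5 * 100 + 0.5 * 500
  mix_var <- 0.5 * (100 - mix_mean)^2 + 0.5 * (500 - mix_mean)^2 + 8^2
  se <- sqrt(mix_var / 10000)
  expect_lt(abs(mean(ev$events$mass_kda) - mix_mean), 3 * se)
  # contrasts invert the calibration
  expect_equal(d$contrast_slope * ev$events$contrast + d$contrast_intercept,
               ev$events$mass_kda)
})

test_that("network generator plants route, plan and is seed-deterministic", {
  nd <- network_design(n_nodes = 20, edge_prob = 0,
                       ranked_overlap_plan = c(c1 = 2, c2 = 3, c3 = 1),
                       ranked_list_size = 10)
  net <- generate_ppi_network(nd, seed = 4)
  sc <- score_route(net$route, net$graph, net$ranked)
  expect_equal(c(sc$c1, sc$c2, sc$c3), c(2, 3, 1))
  net2 <- generate_ppi_network(nd, seed = 4)
  expect_identical(igraph::as_edgelist(net$graph),
                   igraph::as_edgelist(net2$graph))
  # disjoint ranked list scores (0,0,0)
  sc0 <- score_route(net$route, net$graph, c("NOPE1", "NOPE2"))
  expect_equal(sc0$total, 0)
  # infeasible plan
  expect_error(generate_ppi_network(
    network_design(n_nodes = 5, edge_prob = 0,
                   ranked_overlap_plan = c(c1 = 2, c2 = 3, c3 = 1),
                   ranked_list_size = 10), seed = 1),
    "infeasible")
})

test_that("RPPA generator plants recoverable effects and clean nulls", {
  rt <- generate_rppa_table(30, 3, planted = c(P001 = 2), noise_sd = 0.1,
                            seed = 1)
  expect_equal(dim(rt$values), c(30, 6))
  trt <- rowMeans(rt$values[, rt$groups == "treated"])
  ctl <- rowMeans(rt$values[, rt$groups == "control"])
  expect_gt(trt["P001"] - ctl["P001"], 1.5)
  expect_lt(max(abs(trt[-1] - ctl[-1])), 1)  # nulls stay near zero
  expect_error(generate_rppa_table(10, 1), "n_per_group")
})
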