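test_that("relative positions follow the signed centromere conventions", {
  cells <- make_cells(list(c(7)), sc_length_um = 10, centromere_um = 4)
  rel <- relative_positions(cells)
  expect_equal(rel$rel_pos_sc, 30)       # +30% of total SC length
  expect_equal(rel$rel_pos_arm, 50)      # half-way along the q arm
  expect_equal(rel$bin, 30)

  # q-arm telomere end: +100% of the arm extent
  telo <- relative_positions(make_cells(list(c(10))))
  expect_equal(telo$rel_pos_arm, 100)
  expect_equal(telo$rel_pos_sc, 60)
  # focus exactly at the centromere: q-arm, position 0
  cen <- relative_positions(make_cells(list(c(4))))
  expect_equal(cen$rel_pos_sc, 0)
  expect_equal(cen$rel_pos_arm, 0)
  expect_equal(cen$bin, 0)
  # p-arm focus is negative
  p <- relative_positions(make_cells(list(c(1))))
  expect_equal(p$rel_pos_sc, -30)
  expect_equal(p$rel_pos_arm, -75)
})

test_that("genetic length is 50 cM per mean crossover", {
  expect_equal(genetic_length(make_cells(list(1, 2, 3))), 50)
  expect_equal(genetic_length(make_cells(list(c(1, 2), c(3, 7)))), 100)
  expect_equal(genetic_length(make_cells(list(numeric()))), 0)
  # linearity in the mean count
  cells <- make_cells(list(c(1), c(1, 2), c(1, 2, 3)))
  expect_equal(genetic_length(cells), mean(c(1, 2, 3)) * 50)
})

test_that("densities conserve foci between inside and outside regions", {
  cells <- make_cells(list(c(1, 5, 9), c(2, 6), numeric()), sc_length_um = 10)
  whole <- co_density(cells, "sc1")
  expect_equal(whole$total_foci, 5L)
  expect_equal(whole$foci_per_um, 5 / 30)
  iv <- tibble::tibble(cell_id = 1:3, lo_um = 4, hi_um = 7)
  inside <- co_density(cells, "sc1", iv, label = "inside_inv")
  outside <- co_density(cells, "sc1", synrec:::anti_intervals(cells, iv),
                        label = "outside_inv")
  expect_equal(inside$total_foci + outside$total_foci, whole$total_foci)
  expect_equal(inside$total_um + outside$total_um, whole$total_um,
               tolerance = 1e-6)
  # boundary focus counted inside (closed-left)
  b <- co_density(make_cells(list(c(4))), "sc1", c(4, 7))
  expect_equal(b$total_foci, 1L)
  b2 <- co_density(make_cells(list(c(7))), "sc1", c(4, 7))
  expect_equal(b2$total_foci, 0L)
  # empty region foci give zero density; zero-length region errors
  expect_equal(co_density(make_cells(list(c(1))), "sc1",
                          c(8, 9))$foci_per_um, 0)
  expect_error(co_density(cells, "sc1", c(5, 5)), "zero")
})

test_that("marker-delimited inversions and listwise exclusion work", {
  cells <- make_cells(list(c(1, 5), c(2, 6)), sc_length_um = 10,
                      centromere_um = 4, bac = c(bacD = 7))
  iv <- delimit_inversion(cells, "sc1", "centromere", "bacD")
  expect_equal(iv$lo_um, c(4, 4))
  expect_equal(iv$hi_um, c(7, 7))
  expect_equal(attr(iv, "n_excluded"), 0L)
  # pericentric: two BACs spanning the centromere
  cells2 <- make_cells(list(c(5)), bac = c(b1 = 3, b2 = 6))
  iv2 <- delimit_inversion(cells2, "sc1", "b1", "b2")
  expect_equal(c(iv2$lo_um, iv2$hi_um), c(3, 6))
  # missing marker: cell excluded and counted
  cells3 <- dplyr::bind_rows(cells, cells2)
  iv3 <- delimit_inversion(cells3, "sc1", "centromere", "bacD")
  expect_equal(nrow(iv3), 2L)
  expect_equal(attr(iv3, "n_excluded"), 1L)
})

test_that("a whole-SC simulated inversion equals the whole-SC density", {
  cells <- make_cells(list(c(1, 5, 9), c(2, 6)), sc_length_um = 10)
  ctrl <- simulated_inversion_control(cells, "sc1", c(0, 1))
  whole <- co_density(cells, "sc1")
  expect_equal(ctrl$foci_per_um, whole$foci_per_um)
  expect_error(simulated_inversion_control(cells, "sc1", c(0.5, 1.2)),
               "within")
  # a 30% span under uniform placement is close to the whole-SC density
  cfg <- meiosis_config(n_cells = 2000, per_sc_expected_co = 2.5,
                        sc_length_um = 10, obligate_co = FALSE,
                        interference_min_spacing = 0, seed = 41)
  sim <- simulate_meiotic_cells(cfg)
  span <- simulated_inversion_control(sim, "sc1", c(0.35, 0.65))
  whole2 <- co_density(sim, "sc1")
  expect_lt(abs(span$foci_per_um / whole2$foci_per_um - 1), 0.1)
})

test_that("pericentromeric densities cover the configured arm fractions", {
  cells <- make_cells(list(c(3.5, 4.5, 9.5)), sc_length_um = 10,
                      centromere_um = 4)
  pc <- pericentromeric_density(cells, "sc1", fraction = 0.30)
  expect_equal(pc$p_arm$total_um, 1.2)   # 30% of the 4-um p arm
  expect_equal(pc$q_arm$total_um, 1.8)   # 30% of the 6-um q arm
  expect_equal(pc$p_arm$total_foci, 1L)
  expect_equal(pc$q_arm$total_foci, 1L)
  # fraction 1 recovers the whole arms
  pc1 <- pericentromeric_density(cells, "sc1", fraction = 1)
  expect_equal(pc1$p_arm$total_um + pc1$q_arm$total_um, 10)
  expect_equal(pc1$p_arm$total_foci + pc1$q_arm$total_foci, 3L)
  # outer-arm foci leave the pericentromeric region empty
  far <- make_cells(list(c(0.5, 9.5)), sc_length_um = 10, centromere_um = 4)
  pcf <- pericentromeric_density(far, "sc1", fraction = 0.30)
  expect_equal(pcf$p_arm$total_foci + pcf$q_arm$total_foci, 0L)
})

test_that("suppression inside an inversion is detected with >= 90% power at n = 85", {
  detect_once <- function(seed, s) {
    cfg <- meiosis_config(n_cells = 85, per_sc_expected_co = 2,
                          sc_length_um = 8, centromere_rel_pos = 0.35,
                          suppression_intervals = list(sc1 = c(0.45, 0.75)),
                          suppression_factor = s,
                          bac_markers = list(sc1 = c(bacP = 0.45,
                                                     bacD = 0.75)),
                          seed = seed)
    cells <- simulate_meiotic_cells(cfg)
    iv <- delimit_inversion(cells, "sc1", "bacP", "bacD")
    inside <- co_density(cells, "sc1", iv, label = "inside_inv")
    outside <- co_density(cells, "sc1", synrec:::anti_intervals(cells, iv),
                          label = "outside_inv")
    compare_densities(inside = inside, outside = outside)$p.value < 0.05
  }
  power <- mean(vapply(1:60, detect_once, logical(1), s = 0.1))
  expect_gte(power, 0.90)
})

test_that("the collinear control shows no suppression (specificity)", {
  reject_once <- function(seed) {
    cfg <- meiosis_config(n_cells = 86, per_sc_expected_co = 2,
                          sc_length_um = 8, centromere_rel_pos = 0.35,
                          seed = seed + 7000)
    cells <- simulate_meiotic_cells(cfg)
    ctrl <- simulated_inversion_control(cells, "sc1", c(0.45, 0.75))
    outside <- co_density(cells, "sc1",
                          synrec:::anti_intervals(
                            cells, ctrl$per_cell |>
                              dplyr::transmute(cell_id = .data$cell_id,
                                               lo_um = 0.45 * 8,
                                               hi_um = 0.75 * 8)),
                          label = "outside")
    compare_densities(inside = ctrl, outside = outside,
                      alternative = "less")$p.value < 0.05
  }
  rej <- mean(vapply(1:60, reject_once, logical(1)))
  expect_lte(rej, 0.15)
})

test_that("cumulative maps step correctly and mix over crossover classes", {
  # single focus: one step from 0 to 1 at its bin
  one <- make_cells(list(c(9)), sc_length_um = 10, centromere_um = 4)
  m <- cumulative_distribution(one, "sc1")
  expect_equal(max(m$cumulative), 1)
  expect_equal(m$cumulative[m$bin == 50], 1)
  expect_equal(m$cumulative[m$bin == 40], 0)
  # mirrored cells give a symmetric distribution around the centromere
  mir <- make_cells(list(c(2), c(6)), sc_length_um = 10, centromere_um = 4)
  mm <- cumulative_distribution(mir, "sc1")
  expect_equal(mm$frequency[mm$bin == -20], 0.5)
  expect_equal(mm$frequency[mm$bin == 20], 0.5)
  # all-class curve is the focus-count-weighted mix of the class curves
  cells <- make_cells(list(c(1, 5), c(2, 6), c(1, 4, 8)),
                      sc_length_um = 10, centromere_um = 4)
  all_map <- cumulative_distribution(cells, "sc1", "all")
  m2 <- cumulative_distribution(cells, "sc1", 2)
  m3 <- cumulative_distribution(cells, "sc1", 3)
  w2 <- 4 / 7; w3 <- 3 / 7
  expect_equal(all_map$frequency, w2 * m2$frequency + w3 * m3$frequency)
  # no qualifying cells: empty, flagged
  none <- cumulative_distribution(cells, "sc1", "9")
  expect_true(attr(none, "flagged"))
  expect_equal(sum(none$frequency), 0)
})

test_that("tidiers and plots expose the results", {
  cells <- make_cells(list(c(1, 5), c(2, 6)), sc_length_um = 10)
  d <- co_density(cells, "sc1")
  td <- tidy(d)
  expect_equal(td$total_foci, 4L)
  ht <- compare_densities(a = d$per_cell$density, b = d$per_cell$density + 0)
  expect_s3_class(tidy(ht), "tbl_df")
  expect_s3_class(glance(ht), "tbl_df")
  m <- cumulative_distribution(cells, "sc1")
  p <- autoplot(m)
  expect_s3_class(p, "ggplot")
  p2 <- plot_density_comparison(inside = d, outside = d)
  expect_s3_class(p2, "ggplot")
})
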