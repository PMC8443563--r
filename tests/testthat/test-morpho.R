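# ground-truth voxel tomograms (no reconstruction error) for mask tests
truth_spec <- phantom_spec(grid_shape = c(96, 96), pixel_size = 0.3,
                           nucleolus_center_offset = c(2, 1, 0),
                           angle_schedule = 0)
truth_tomo <- phantom_truth_volume(truth_spec)

test_that("nucleus segmentation recovers the phantom volume", {
  # half-contrast threshold is the unbiased edge criterion on a sharp object
  mask <- segment_nucleus_mask(truth_tomo, delta = truth_spec$nucleus_delta_n / 2)
  v_true <- 4 / 3 * pi * prod(truth_spec$nucleus_semi_axes)
  expect_equal(attr(mask, "volume"), v_true, tolerance = 0.03)
  # all-background tomogram errors
  flat <- tomogram(array(1.368, c(8, 8, 8)), 1, 1.368)
  expect_error(segment_nucleus_mask(flat), "not found")
})

test_that("3D labelling keeps the largest of disjoint components", {
  a <- array(FALSE, c(20, 20, 20))
  a[3:8, 3:8, 3:8] <- TRUE          # 216 voxels
  a[14:17, 14:17, 14:17] <- TRUE    # 64 voxels
  ri <- array(1.368, dim(a)); ri[a] <- 1.40
  tm <- tomogram(ri, 1, 1.368)
  mask <- segment_nucleus_mask(tm, delta = 0.01, closing_size = 0)
  expect_equal(sum(mask), 216)
  # label_volume separates the two components
  labs <- holotomo:::label_volume(a)
  expect_equal(max(labs), 2)
  expect_setequal(tabulate(labs[labs > 0]), c(216, 64))
})

test_that("nucleolus segmentation finds the high-RI interval", {
  nmask <- segment_nucleus_mask(truth_tomo,
                                delta = truth_spec$nucleus_delta_n / 2)
  smask <- segment_nucleolus(truth_tomo, nmask)
  v_true <- 4 / 3 * pi * prod(truth_spec$nucleolus_semi_axes)
  expect_equal(attr(smask, "volume"), v_true, tolerance = 0.10)
  expect_true(attr(smask, "valley_found"))
  expect_gt(attr(smask, "valley_depth"), 0.5)
  # segmented distribution sits above the threshold
  expect_true(all(truth_tomo$ri[smask] > attr(smask, "threshold")))
  # uniform nucleus: no high-RI mode -> fallback then error
  sp2 <- truth_spec; sp2$nucleolus_semi_axes <- NULL
  uni <- phantom_truth_volume(sp2)
  umask <- segment_nucleus_mask(uni, delta = 0.011)
  expect_error(segment_nucleolus(uni, umask, min_voxels = 1e5),
               "no nucleolus")
})

test_that("equivalent radius inverts the printed volumes", {
  expect_equal(equivalent_radius(4 * pi / 3), 1)
  expect_equal(equivalent_radius(1377.42), 6.90, tolerance = 0.01 / 6.90)
  expect_equal(equivalent_radius(50.25), 2.29, tolerance = 0.01 / 2.29)
  # exact inversion property
  for (v in c(0.7, 55.6, 1954.09)) {
    expect_equal(4 / 3 * pi * equivalent_radius(v)^3, v, tolerance = 1e-12)
  }
  expect_error(equivalent_radius(-1), "volume")
})

test_that("principal axes match the uniform-ellipsoid identity", {
  sp <- phantom_spec(nucleus_semi_axes = c(10, 7, 3.5),
                     nucleolus_semi_axes = NULL, grid_shape = c(96, 96),
                     pixel_size = 0.3, angle_schedule = 0)
  vol <- phantom_truth_volume(sp)
  mask <- vol$ri > 1.368 + 0.011
  expect_equal(principal_axes(mask, 0.3), c(20, 14, 7), tolerance = 0.03)
  # sphere: three equal axes
  sps <- phantom_spec(nucleus_semi_axes = c(5, 5, 5),
                      nucleolus_semi_axes = NULL, grid_shape = c(64, 64),
                      pixel_size = 0.3, angle_schedule = 0)
  ax <- principal_axes(phantom_truth_volume(sps)$ri > 1.3735, 0.3)
  expect_lt(diff(range(ax)) / mean(ax), 0.02)
  # single-plane mask is degenerate
  pl <- array(FALSE, c(10, 10, 10)); pl[, , 5] <- TRUE
  expect_error(principal_axes(pl, 1), "degenerate")
  expect_error(principal_axes(array(TRUE, c(2, 2, 2)), 1), "10 voxels")
})

test_that("RI statistics: hand case and brute-force agreement", {
  ri <- array(1.368, c(6, 6, 6))
  ri[1, 1, 1] <- 1.35; ri[2, 1, 1] <- 1.43
  tm <- tomogram(ri, 1, 1.368)
  mask <- array(FALSE, c(6, 6, 6)); mask[1:2, 1, 1] <- TRUE
  s <- ri_statistics(tm, mask)
  expect_equal(unname(s), c(1.39, 0.04, 1.35, 1.43))
  # brute force over the whole phantom
  all_mask <- array(TRUE, dim(truth_tomo$ri))
  s2 <- ri_statistics(truth_tomo, all_mask)
  v <- as.vector(truth_tomo$ri)
  expect_equal(unname(s2),
               c(mean(v), sqrt(mean((v - mean(v))^2)), min(v), max(v)))
  expect_error(ri_statistics(tm, array(FALSE, c(6, 6, 6))), "empty")
})

test_that("dry mass is the linear refraction-increment formula", {
  expect_equal(dry_mass(1.334, 1000), 0)
  expect_equal(dry_mass(1.39, 1377.42), (1.39 - 1.334) * 1377.42 / 0.2)
  # linear in volume and in RI excess
  expect_equal(dry_mass(1.39, 2000), 2 * dry_mass(1.39, 1000))
  expect_equal(dry_mass(1.334 + 0.06, 500), 2 * dry_mass(1.334 + 0.03, 500))
  expect_warning(dry_mass(1.30, 100), "negative")
  expect_error(dry_mass(1.39, -5), "volume")
  expect_error(dry_mass(1.39, 5, alpha = 0), "alpha")
})

test_that("volume ratio reproduces printed values and guards ordering", {
  expect_equal(volume_ratio(50.25, 1377.42), 3.65, tolerance = 0.01 / 3.65)
  expect_equal(volume_ratio(55.63, 1954.09), 2.85, tolerance = 0.01 / 2.85)
  expect_error(volume_ratio(10, 10), "smaller")
  expect_error(volume_ratio(-1, 10), "> 0")
})

test_that("report table summarises per-nucleus records", {
  m1 <- nuclear_metrics(truth_tomo, delta = truth_spec$nucleus_delta_n / 2)
  tab1 <- report_table(m1)
  expect_equal(tab1$mean, tab1$nucleus_1)
  expect_true(all(tab1$sd == 0))
  # two hand-built records
  m2 <- m1
  m2$nuclear_volume <- m1$nuclear_volume + 100
  tab2 <- report_table(list(m1, m2))
  i <- which(tab2$metric == "nuclear_volume")
  expect_equal(tab2$mean[i], m1$nuclear_volume + 50)
  expect_equal(tab2$sd[i], stats::sd(c(m1$nuclear_volume, m2$nuclear_volume)))
  expect_true(all(tab2$n == 2))
  # missing field summarised over available values with count
  m3 <- m2
  m3$nucleolar_volume <- NA_real_
  tab3 <- report_table(list(m1, m3))
  j <- which(tab3$metric == "nucleolar_volume")
  expect_equal(tab3$n[j], 1)
  expect_equal(tab3$mean[j], m1$nucleolar_volume)
})
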