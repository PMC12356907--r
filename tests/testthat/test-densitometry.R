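test_that("RI maps linearly to density and inverts exactly", {
  expect_equal(ri_to_density(1.333 + 0.019, 1.333), 100, tolerance = 1e-9)
  expect_identical(ri_to_density(1.333, 1.333), 0)
  # inverse evaluation at the measured 60-min nuclear density
  expect_equal(ri_to_density(1.333 + 0.017366, 1.333), 91.4,
               tolerance = 1e-9)
  set.seed(7)
  rho <- runif(50, -20, 300)
  expect_equal(ri_to_density(density_to_ri(rho, 1.337), 1.337), rho,
               tolerance = 1e-9)
})

test_that("otsu segmentation separates cell from medium", {
  ph <- make_cell_phantom(tiny_phantom())
  mask <- suppressMessages(segment_otsu(ph$tomogram))
  expect_identical(as.vector(mask), as.vector((ph$mask > 0) * 1L))
  expect_true(is.numeric(attr(mask, "threshold")))

  # with noise, disagreement stays on a 1-voxel shell around the boundary
  phn <- make_cell_phantom(tiny_phantom(noise_sd = 2e-4, seed = 5))
  mn <- suppressMessages(segment_otsu(phn$tomogram))
  truth <- (phn$mask > 0) * 1L
  wrong <- which(mn != truth, arr.ind = TRUE)
  if (nrow(wrong) > 0) {
    d <- dim(truth)
    near_boundary <- apply(wrong, 1, function(ix) {
      zz <- max(1, ix[1] - 1):min(d[1], ix[1] + 1)
      yy <- max(1, ix[2] - 1):min(d[2], ix[2] + 1)
      xx <- max(1, ix[3] - 1):min(d[3], ix[3] + 1)
      nb <- truth[zz, yy, xx]
      any(nb == 0) && any(nb == 1)
    })
    expect_true(all(near_boundary))
  }

  flat <- tomogram(array(1.35, dim = c(4, 4, 4)), 0.3, 1.333)
  expect_error(segment_otsu(flat), "degenerate histogram")
})

test_that("compartment quantification integrates volume, mass, density", {
  # analytic sphere oracle: (4/3) pi 5.105^3 * 0.0914 pg/um^3 = 50.93 pg
  sp <- phantom_spec(c(7, 7, 6), 5.105, density_nucleoplasm = 91.4,
                     density_cytoplasm = 100, voxel_size_um = 0.12,
                     noise_sd = 0, axial_blur_sigma_um = 0)
  ph <- make_cell_phantom(sp)
  q <- quantify_compartment(ph$tomogram, ph$mask, 2L)
  expect_lt(abs(q$dry_mass_pg - 50.93) / 50.93, 0.02)
  expect_lt(abs(q$volume_um3 - 4 / 3 * pi * 5.105^3) /
              (4 / 3 * pi * 5.105^3), 0.02)
  # internal identity to machine precision
  expect_equal(q$mean_density_mg_ml * q$volume_um3, 1000 * q$dry_mass_pg,
               tolerance = 1e-12)
  expect_error(quantify_compartment(ph$tomogram, ph$mask, 7L),
               "empty compartment")
})

test_that("nucleolus label is excluded from nucleoplasmic density", {
  ph <- make_cell_phantom(tiny_phantom(nucleolus = TRUE))
  q2 <- quantify_compartment(ph$tomogram, ph$mask, 2L)
  # exactly the generated nucleoplasmic density, untouched by the denser
  # nucleolus sitting inside the nucleus
  expect_equal(q2$mean_density_mg_ml, 80, tolerance = 1e-9)
  q3 <- quantify_compartment(ph$tomogram, ph$mask, 3L)
  expect_equal(q3$mean_density_mg_ml, 150, tolerance = 1e-9)
})

test_that("dry mass is additive over disjoint labels", {
  ph <- make_cell_phantom(tiny_phantom(nucleolus = TRUE))
  q1 <- quantify_compartment(ph$tomogram, ph$mask, 2L)
  q2 <- quantify_compartment(ph$tomogram, ph$mask, 3L)
  merged <- ph$mask
  merged[merged == 3L] <- 2L
  qu <- quantify_compartment(ph$tomogram, merged, 2L)
  expect_equal(qu$dry_mass_pg, q1$dry_mass_pg + q2$dry_mass_pg,
               tolerance = 1e-12)
  expect_equal(qu$volume_um3, q1$volume_um3 + q2$volume_um3,
               tolerance = 1e-12)
})

test_that("ROI sampling is uniform-exact, seeded and bounded", {
  ph <- make_cell_phantom(tiny_phantom())
  r <- roi_density_stats(ph$tomogram, ph$mask, 2L, roi_edge_um = 0.6,
                         n_roi = 5, seed = 3)
  # uniform region: every ROI mean equals the voxelwise mean exactly
  expect_equal(r$mean_density_mg_ml, 80, tolerance = 1e-9)
  r2 <- roi_density_stats(ph$tomogram, ph$mask, 2L, roi_edge_um = 0.6,
                          n_roi = 5, seed = 3)
  expect_identical(r$rois, r2$rois)
  expect_error(
    roi_density_stats(ph$tomogram, ph$mask, 2L, roi_edge_um = 10),
    "limiting dimension")
})

test_that("NC ratios follow their definitions", {
  nuc <- compartment_quant("nucleus", 558, 51)
  cyt <- compartment_quant("cytoplasm", 5000, 500)
  cell <- compartment_quant("cell", 5558, 551)
  nc <- nc_ratios(nuc, cyt, cell)
  expect_equal(nc$density_ratio, 91.4 / 100, tolerance = 1e-3)
  expect_equal(nc$volume_ratio, 558 / (5558 - 558), tolerance = 1e-12)
  expect_equal(nc$mass_ratio, 51 / 500, tolerance = 1e-12)
  # equal densities give ratio 1
  same <- nc_ratios(compartment_quant("n", 100, 10),
                    compartment_quant("c", 400, 40))
  expect_equal(same$density_ratio, 1, tolerance = 1e-12)
  # senescent inversion: 28 vs 22 mg/mL
  sen <- nc_ratios(compartment_quant("n", 100, 2.8),
                   compartment_quant("c", 400, 8.8))
  expect_equal(sen$density_ratio, 28 / 22, tolerance = 1e-12)
  expect_gt(sen$density_ratio, 1)
  expect_error(nc_ratios(nuc, cyt, compartment_quant("cell", 500, 50)),
               "cell volume")
})

test_that("group comparison: Mann-Whitney U, Cohen's d and bands", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  cg <- compare_groups(a, b)
  expect_equal(cg$U, oracle_U(a, b))   # brute-force over all 9 pairs: 0
  expect_equal(cg$U, 0)
  set.seed(11)
  x <- rnorm(12); y <- rnorm(15, 1)
  expect_equal(compare_groups(x, y)$U, oracle_U(x, y))

  same <- compare_groups(c(5, 6, 7, 8), c(5, 6, 7, 8))
  expect_equal(same$cohens_d, 0)
  expect_gt(same$p_value, 0.9)

  expect_identical(cohens_d_band(0.6), "medium")
  expect_identical(cohens_d_band(0.1), "negligible")
  expect_identical(cohens_d_band(-0.3), "small")
  expect_identical(cohens_d_band(0.95), "large")
  expect_error(compare_groups(1, c(1, 2)), "n >= 2")
})
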