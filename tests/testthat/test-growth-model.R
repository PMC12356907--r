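test_that("equilibrium volume matches the independent unit oracle", {
  p <- model_params(n_c = 0.6418485, N_chr = 0)
  # protein-only: 37.6 pg of 131.1 kDa complexes against 0.642 mM
  expect_equal(equilibrium_volume(37.616, p),
               oracle_volume_um3(37.616, 131.1, 0.6418485),
               tolerance = 1e-6)
  expect_equal(equilibrium_volume(37.616, p), 447.0, tolerance = 1e-3)
  # adding the chromatin particle count: + ~112 um^3
  pN <- model_params(n_c = 0.6418485, N_chr = 4.3e7)
  expect_equal(equilibrium_volume(37.616, pN),
               oracle_volume_um3(37.616, 131.1, 0.6418485, N_chr = 4.3e7),
               tolerance = 1e-6)
  expect_equal(equilibrium_volume(37.616, pN), 558.3, tolerance = 1e-3)
  expect_warning(equilibrium_volume(0, p), "degenerate")
})

test_that("equilibrium volume is linear and strictly increasing in mass", {
  p <- xen$params
  m <- seq(0, 60, by = 5)
  v <- equilibrium_volume(m, p)
  expect_true(all(diff(v) > 0))
  slopes <- diff(v) / diff(m)
  expect_equal(max(slopes), min(slopes), tolerance = 1e-12)
  # intercept is the chromatin term
  expect_equal(v[1], p$N_chr / (p$n_c * 6.02214076e5), tolerance = 1e-9)
})

test_that("nuclear density divides total mass by volume", {
  expect_equal(nuclear_density(37.616, xen$params, 558.0),
               1000 * (37.616 + xen$M_chr) / 558.0, tolerance = 1e-12)
  expect_lt(abs(nuclear_density(xen$M_p_60, xen$params, xen$V60) - 91.4),
            1e-6)
  expect_error(nuclear_density(1, xen$params, 0), "V")
})

test_that("import flux saturates, gates on t_dec and on the switch", {
  p <- xen$params
  expect_identical(import_flux(c(0, 30, 60), 10,
                               apply_scenario(p, "import_inhibition")),
                   c(0, 0, 0))
  expect_equal(import_flux(30, p$M_sat, p), 0)
  expect_equal(import_flux(2, 0, p), 0)     # decondensation still running
  expect_gt(import_flux(10, 0, p), 0)
  # beta = 0 removes the genome-size dependence
  p0 <- p; p0$beta <- 0; p0$genome_bp <- 1.7e9
  p1 <- p; p1$beta <- 0
  expect_equal(import_flux(10, 5, p0), import_flux(10, 5, p1),
               tolerance = 1e-12)
})

test_that("import-off simulation holds the cytoplasmic density", {
  p <- apply_scenario(xen$params, "import_inhibition")
  tr <- simulate_assembly(p, c(0, 5, 10, 30, 60))
  after <- tr$t_min >= p$t_dec
  expect_true(all(abs(tr$rho_mg_ml[after] - p$rho_c) / p$rho_c < 0.02))
  expect_equal(tr$rho_mg_ml[tr$t_min == 60], 100, tolerance = 1e-9)
  # condensed sperm start
  expect_equal(tr$rho_mg_ml[1], 183, tolerance = 1e-9)
})

test_that("calibrated trajectory grows and ends below cytoplasmic density", {
  tr <- simulate_assembly(xen$params, seq(0, 60, 5))
  expect_true(all(diff(tr$V_um3) >= 0))
  expect_true(all(diff(tr$V_um3[tr$t_min >= 5]) > 0))
  rho60 <- tr$rho_mg_ml[tr$t_min == 60]
  expect_lt(rho60, xen$params$rho_c)
  expect_lt(abs(rho60 - 91.4) / 91.4, 0.01)
  # density bounded by the condensed sperm state
  expect_true(all(tr$rho_mg_ml <= 183 + 1e-9))
  expect_true(all(tr$rho_mg_ml > 0))
})

test_that("the simulation reaches the closed-form steady state", {
  tr <- simulate_assembly(xen$params, c(0, 2000))
  expect_equal(tr$Mp_pg[2], xen$params$M_sat, tolerance = 1e-6)
  expect_equal(tr$V_um3[2], equilibrium_volume(xen$params$M_sat, xen$params),
               tolerance = 1e-6)
})

test_that("equal-concentration limit gives density ratio m_n/m_c", {
  p <- model_params(M_chr = 0, N_chr = 0, rho_sperm = 183, rho_dec = 100)
  tr <- simulate_assembly(p, c(0, 5000))
  ratio <- tr$rho_mg_ml[2] / p$rho_c
  expect_equal(ratio, p$m_n / p$m_c, tolerance = 1e-9)
})

test_that("euler stepping agrees with refined stepping and an rk4 oracle", {
  t_grid <- c(5, 15, 30, 60)
  coarse <- simulate_assembly(xen$params, t_grid, dt = 0.1)
  fine <- simulate_assembly(xen$params, t_grid, dt = 0.01)
  rel <- function(a, b) max(abs(a - b) / pmax(abs(b), 1e-12))
  expect_lt(rel(coarse$V_um3, fine$V_um3), 1e-3)
  expect_lt(rel(coarse$rho_mg_ml, fine$rho_mg_ml), 1e-3)
  skip_if_not_installed("deSolve")
  p <- xen$params
  rhs <- function(t, y, parms) list(import_flux(t, y, p))
  out <- deSolve::ode(c(M = 0), c(0, 60), rhs, NULL, method = "rk4",
                      hini = 0.01)
  expect_lt(abs(coarse$Mp_pg[4] - out[2, 2]) / out[2, 2], 1e-3)
})

test_that("a too-coarse step is refined automatically", {
  expect_message(simulate_assembly(xen$params, c(0, 60), dt = 10),
                 "refined")
})

test_that("chromatin contribution to final volume is ~20% when calibrated", {
  expect_identical(chromatin_contribution(model_params(N_chr = 0), 40), 0)
  frac <- chromatin_contribution(xen$params, xen$M_p_60)
  expect_equal(frac, 1 - 447.0 / 558.0, tolerance = 1e-2)
  big <- xen$params; big$N_chr <- 1e12
  expect_gt(chromatin_contribution(big, xen$M_p_60), 0.99)
})

test_that("scenario transforms encode the perturbations", {
  p <- xen$params
  expect_error(apply_scenario(p, "nonsense"), "unknown scenario")

  # import inhibition shrinks the final nucleus
  off <- simulate_assembly(apply_scenario(p, "import_inhibition"), c(0, 60))
  ctl <- simulate_assembly(p, c(0, 60))
  expect_lt(off$V_um3[2], ctl$V_um3[2])

  # ploidy swap: smaller nucleus, comparable density (within 3%)
  trop <- apply_scenario(p, "ploidy_swap", genome_bp = 1.7e9)
  expect_equal(trop$M_chr, p$M_chr * 1.7 / 3.1, tolerance = 1e-12)
  expect_equal(trop$N_chr, p$N_chr * 1.7 / 3.1, tolerance = 1e-12)
  ttr <- simulate_assembly(trop, c(0, 60))
  expect_lt(ttr$V_um3[2], ctl$V_um3[2])
  expect_lt(abs(ttr$rho_mg_ml[2] - ctl$rho_mg_ml[2]) / ctl$rho_mg_ml[2],
            0.03)
  # ~1.4-fold laevis/tropicalis dry-mass difference
  mass_ratio <- (ctl$Mp_pg[2] + p$M_chr) / (ttr$Mp_pg[2] + trop$M_chr)
  expect_lt(abs(mass_ratio - 1.4), 0.1)

  # HS extract: same import machinery, so same nuclear dry mass as control
  hs <- apply_scenario(p, "hs_extract")
  htr <- simulate_assembly(hs, c(0, 60))
  expect_equal(htr$Mp_pg[2], ctl$Mp_pg[2], tolerance = 1e-12)
  # nucleus now denser than the diluted cytoplasm
  expect_gt(htr$rho_mg_ml[2] / hs$rho_c, 1)
  # add-back restores the control prediction
  back <- apply_scenario(hs, "add_back", rho_c_restore = p$rho_c)
  btr <- simulate_assembly(back, c(0, 60))
  expect_equal(btr$rho_mg_ml[2] / back$rho_c, ctl$rho_mg_ml[2] / p$rho_c,
               tolerance = 1e-12)

  # senescence inverts the NC density ratio
  sen <- apply_scenario(p, "senescence")
  str_ <- simulate_assembly(sen, c(0, 60))
  expect_gt(str_$rho_mg_ml[2] / sen$rho_c, 1)

  # cleavage caps the per-cell saturating mass
  cl <- apply_scenario(p, "cleavage", cell_dry_mass_pg = 500, phi = 0.02)
  expect_equal(cl$M_sat, 10, tolerance = 1e-12)
  expect_error(apply_scenario(p, "cleavage"), "cell_dry_mass_pg")
})
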