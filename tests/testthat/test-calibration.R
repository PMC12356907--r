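test_that("closed-form calibration reproduces the bookkeeping chain", {
  cal <- calibrate_xenopus()
  expect_equal(cal$V60, 1000 * 51 / 91.4, tolerance = 1e-12)
  # independent oracle: N_chr = (V60 - V_protein_only) * n_c in particles
  v_prot <- oracle_volume_um3(cal$M_p_60, 131.1, cal$n_c)
  n_chr_oracle <- (cal$V60 - v_prot) * cal$n_c * 6.02214076e5
  expect_equal(cal$N_chr, n_chr_oracle, tolerance = 1e-6)
  expect_equal(cal$N_chr, 4.3e7, tolerance = 0.01)
  # the calibrated flux lands the pool on M_p at 60 min
  tr <- simulate_assembly(cal$params, c(0, 60), dt = 0.01)
  expect_equal(tr$Mp_pg[2], cal$M_p_60, tolerance = 1e-3)

  # lighter packaging: more protein mass, fewer chromatin particles
  cal2 <- calibrate_xenopus(chromatin = chromatin_spec(3.1e9, kappa = 2))
  expect_gt(cal2$M_p_60, cal$M_p_60)
  expect_lt(cal2$N_chr, cal$N_chr)
  expect_gt(cal2$N_chr, 0)
  # naked DNA alone cannot close the balance at the observed volume
  expect_error(calibrate_xenopus(chromatin = chromatin_spec(3.1e9,
                                                            kappa = 1)),
               "inconsistent anchors")
})

test_that("inconsistent anchors raise diagnostics", {
  # nucleus as dense as cytoplasm with little chromatin: the protein-only
  # volume already exceeds the observed volume
  expect_error(
    calibrate_xenopus(rho_n = 100, chromatin = chromatin_spec(3.1e9,
                                                              kappa = 1)),
    "inconsistent anchors")
  expect_error(calibrate_xenopus(M_sat = 30), "M_sat")
})

test_that("noise-free observations are recovered exactly", {
  obs <- make_assembly_timecourse(xen$params, n_nuclei = 5, noise_sd = 0,
                                  t_grid = c(5, 15, 30, 60))
  fs <- fit_spec(list(J0 = c(0.2, 4), M_sat = c(20, 150)), seed = 2,
                 dt = 0.1)
  ft <- fit_model(obs, fs, xen$params, n_boot = 0)
  expect_true(ft$converged)
  expect_lt(abs(ft$par[["J0"]] - xen$params$J0) / xen$params$J0, 1e-3)
  expect_lt(abs(ft$par[["M_sat"]] - xen$params$M_sat) / xen$params$M_sat,
            1e-3)
  expect_lt(ft$loss, 1e-3)

  # single free parameter goes through the 1-D bounded search
  fs1 <- fit_spec(list(J0 = c(0.2, 4)), seed = 2, dt = 0.1)
  ft1 <- fit_model(obs, fs1, xen$params, n_boot = 0)
  expect_lt(abs(ft1$par[["J0"]] - xen$params$J0) / xen$params$J0, 1e-4)
})

test_that("underdetermined fits are rejected", {
  obs <- make_assembly_timecourse(xen$params, n_nuclei = 2, noise_sd = 0,
                                  t_grid = 30)[, c("t_min", "V_mean",
                                                   "V_sem")]
  fs <- fit_spec(list(J0 = c(0.2, 4), M_sat = c(20, 150)))
  expect_error(fit_model(obs, fs, xen$params), "free parameters")
  expect_error(fit_spec(list()), "named list")
  expect_error(fit_spec(list(J0 = c(2, 1))), "lower < upper")
})

test_that("5%-noise time courses recover the generating parameters", {
  obs <- make_assembly_timecourse(xen$params, n_nuclei = 175,
                                  noise_sd = 0.05,
                                  t_grid = c(5, 15, 30, 60), seed = 11)
  fs <- fit_spec(list(J0 = c(0.2, 4), M_sat = c(20, 150),
                      N_chr = c(1e6, 2e8)), seed = 5, dt = 0.5)
  ft <- fit_model(obs, fs, xen$params, n_boot = 0)
  truth <- c(J0 = xen$params$J0, M_sat = xen$params$M_sat,
             N_chr = xen$params$N_chr)
  expect_true(all(abs(ft$par - truth) / truth < 0.10))
})

test_that("the loss is locally optimal at the truth for clean data", {
  obs <- make_assembly_timecourse(xen$params, n_nuclei = 5, noise_sd = 0,
                                  t_grid = c(5, 15, 30, 60))
  loss_at <- function(J0, M_sat) {
    p <- xen$params; p$J0 <- J0; p$M_sat <- M_sat
    tr <- simulate_assembly(p, obs$t_min, dt = 0.5)
    sum((tr$V_um3 - obs$V_mean)^2 + (tr$Mp_pg + p$M_chr - obs$M_mean)^2)
  }
  l0 <- loss_at(xen$params$J0, xen$params$M_sat)
  for (fj in c(0.9, 1.1)) for (fm in c(0.9, 1.1)) {
    expect_gt(loss_at(fj * xen$params$J0, fm * xen$params$M_sat), l0)
  }
})

test_that("bootstrap intervals cover the truth in repeated synthesis", {
  fs <- fit_spec(list(J0 = c(0.2, 4), N_chr = c(1e6, 2e8)), seed = 5,
                 dt = 1, n_starts = 3)
  truth <- c(J0 = xen$params$J0, N_chr = xen$params$N_chr)
  n_rep <- 50
  covered <- matrix(FALSE, n_rep, 2)
  for (r in seq_len(n_rep)) {
    obs <- make_assembly_timecourse(xen$params, n_nuclei = 30,
                                    noise_sd = 0.05,
                                    t_grid = c(5, 15, 30, 60),
                                    seed = 1000 + r)
    ft <- fit_model(obs, fs, xen$params, n_boot = 19)
    covered[r, ] <- truth >= ft$ci[1, ] & truth <= ft$ci[2, ]
  }
  expect_true(all(colMeans(covered) >= 0.8))
})
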