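# small in-code fixtures shared across test files

# coarse, noise-free, blur-free phantom: fast and exactly quantifiable
tiny_phantom <- function(nucleolus = FALSE, noise_sd = 0, blur = 0,
                         voxel = 0.3, seed = 1L) {
  phantom_spec(
    cell_semi_axes_um = c(4, 4, 3),
    nucleus_radius_um = 2,
    nucleolus_radii_um = if (nucleolus) 0.7 else numeric(0),
    density_cytoplasm = 100,
    density_nucleoplasm = 80,
    density_nucleolus = 150,
    voxel_size_um = voxel,
    noise_sd = noise_sd,
    axial_blur_sigma_um = blur,
    seed = seed
  )
}

# calibrated Xenopus parameter set (closed-form; cheap to recompute)
xen <- calibrate_xenopus()

# independent unit oracle for the equilibrium volume: particle counts via
# Avogadro, concentrations via litres; shares no code with the package
oracle_volume_um3 <- function(M_p_pg, m_n_kda, n_c_mM, N_chr = 0) {
  particles <- M_p_pg * 1e-12 / (m_n_kda * 1000 / 6.02214076e23) + N_chr
  conc_per_um3 <- n_c_mM * 1e-3 * 6.02214076e23 / 1e15
  particles / conc_per_um3
}

# brute-force Mann-Whitney U: count pairs (a > b) + half-ties
oracle_U <- function(a, b) {
  s <- 0
  for (x in a) for (y in b) s <- s + (x > y) + 0.5 * (x == y)
  s
}
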