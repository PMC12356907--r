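#' Molar concentration of a protein-complex pool
#'
#' The osmotically active units on either side of the nuclear envelope are
#' protein complexes, not monomers. Given the dry-mass density of a pool and
#' the mean complex mass, the number concentration follows directly:
#' `n[mM] = rho[mg/mL] / m[kDa]`.
#'
#' With the Xenopus egg-extract anchors (cytoplasm 100 mg/mL at a mean
#' complex mass of 155.8 kDa) this gives 0.642 mM.
#'
#' @param mass_density Dry-mass density of the pool, mg/mL. May be a vector.
#' @param mean_mass Mean complex mass, kDa. Must be > 0.
#' @return Molar concentration in mM.
#' @export
#' @examples
#' complex_concentration(100, 155.8)   # cytoplasmic complexes, ~0.642 mM
complex_concentration <- function(mass_density, mean_mass) {
  stopifnot_scalar(mean_mass, "mean_mass", positive = TRUE)
  if (any(!is.finite(mass_density)) || any(mass_density < 0)) {
    stop("`mass_density` must be finite and >= 0", call. = FALSE)
  }
  mass_density / mean_mass
}

#' Particle-reduction factor of complex assembly
#'
#' Assembling free macromolecules into one complex divides their osmotic
#' particle count: a ribosome built from 82 proteins and 4 RNAs reduces the
#' osmotic pressure of its constituents by a factor of 86.
#'
#' @param n_proteins Number of protein subunits per complex (>= 0).
#' @param n_rnas Number of RNA molecules per complex (>= 0).
#' @return Free osmotic units per assembled complex, `n_proteins + n_rnas`.
#' @export
#' @examples
#' particle_reduction_factor(82, 4)  # ribosome: 86
particle_reduction_factor <- function(n_proteins, n_rnas = 0) {
  stopifnot_scalar(n_proteins, "n_proteins", nonneg = TRUE)
  stopifnot_scalar(n_rnas, "n_rnas", nonneg = TRUE)
  total <- n_proteins + n_rnas
  if (total < 1) {
    stop("a complex needs at least one constituent (n_proteins + n_rnas >= 1)",
         call. = FALSE)
  }
  total
}

#' Ideal (van 't Hoff) osmotic pressure
#'
#' `pi = c R T` with the concentration converted from mM to mol/m^3. Ideality
#' is assumed throughout: the pressure balance reasons at the level of
#' particle counts, without virial corrections.
#'
#' @param concentration_mM Particle concentration, mM (may be a vector).
#' @param temperature_K Absolute temperature, K (default 293).
#' @return Pressure in Pa.
#' @export
#' @examples
#' vant_hoff_pressure(0.642)  # ~1.56e3 Pa for the cytoplasmic complex pool
vant_hoff_pressure <- function(concentration_mM,
                               temperature_K = nd_constants()$temperature_K) {
  stopifnot_scalar(temperature_K, "temperature_K", positive = TRUE)
  if (any(!is.finite(concentration_mM)) || any(concentration_mM < 0)) {
    stop("`concentration_mM` must be finite and >= 0", call. = FALSE)
  }
  # 1 mM = 1 mol/m^3
  concentration_mM * nd_constants()$gas_constant_J_per_mol_K * temperature_K
}

#' Chromatin specification
#'
#' Holds the genome size, per-base-pair mass and the packaging factor kappa
#' (total chromatin mass over naked DNA mass; DNA plus histones, chromatin
#' proteins and RNA). The default kappa = 4 is the reconstruction that makes
#' the printed nuclear bookkeeping (51 pg, 91.4 mg/mL, 0.51 mM at 131.1 kDa)
#' mutually consistent; it is a configurable parameter, not a measured
#' constant.
#'
#' @param genome_bp Genome size in base pairs (>= 0). The tetraploid
#'   X. laevis complement is 3.1e9 bp, diploid X. tropicalis 1.7e9 bp.
#' @param bp_mass_da Average mass per base pair, Da (default 650).
#' @param kappa Packaging factor, >= 1 (default 4).
#' @return Object of class `chromatin_spec`.
#' @export
#' @examples
#' chromatin_spec(3.1e9)
chromatin_spec <- function(genome_bp,
                           bp_mass_da = nd_constants()$da_per_bp,
                           kappa = nd_constants()$chromatin_packaging_factor) {
  stopifnot_scalar(genome_bp, "genome_bp", nonneg = TRUE)
  stopifnot_scalar(bp_mass_da, "bp_mass_da", positive = TRUE)
  stopifnot_scalar(kappa, "kappa")
  if (kappa < 1) stop("`kappa` must be >= 1", call. = FALSE)
  structure(list(genome_bp = genome_bp, bp_mass_da = bp_mass_da,
                 kappa = kappa),
            class = "chromatin_spec")
}

#' Chromatin dry mass
#'
#' Naked DNA mass is `genome_bp * bp_mass / N_A`; total chromatin mass
#' multiplies by the packaging factor kappa.
#'
#' @param spec A [chromatin_spec()].
#' @return Chromatin dry mass in pg.
#' @export
#' @examples
#' chromatin_mass(chromatin_spec(3.1e9))          # ~13.4 pg
#' chromatin_mass(chromatin_spec(3.1e9, kappa = 1)) # naked DNA, ~3.35 pg
chromatin_mass <- function(spec) {
  stopifnot(inherits(spec, "chromatin_spec"))
  grams <- spec$genome_bp * spec$bp_mass_da / nd_constants()$avogadro_per_mol
  spec$kappa * grams * 1e12  # g -> pg
}

#' Nuclear protein mass from total nuclear dry mass
#'
#' The imported-protein mass is what remains of the measured total nuclear
#' dry mass after subtracting chromatin: `M_n = M_tot - M_chr`.
#'
#' @param total_dry_mass_pg Total nuclear dry mass, pg.
#' @param chromatin_mass_pg Chromatin dry mass, pg.
#' @return Protein mass in pg. Errors if chromatin exceeds the total.
#' @export
nuclear_protein_mass <- function(total_dry_mass_pg, chromatin_mass_pg) {
  stopifnot_scalar(total_dry_mass_pg, "total_dry_mass_pg", nonneg = TRUE)
  stopifnot_scalar(chromatin_mass_pg, "chromatin_mass_pg", nonneg = TRUE)
  if (chromatin_mass_pg > total_dry_mass_pg) {
    stop("chromatin exceeds total mass (",
         format(chromatin_mass_pg), " > ", format(total_dry_mass_pg), " pg)",
         call. = FALSE)
  }
  total_dry_mass_pg - chromatin_mass_pg
}

#' Full osmotic bookkeeping table for a reconstituted nucleus
#'
#' Chains the measured anchors into the quantities the pressure balance
#' needs: nuclear volume from total dry mass and density, chromatin mass
#' from the genome, imported protein mass by subtraction, complex
#' concentrations on both sides of the envelope, and the ideal osmotic
#' pressures they exert.
#'
#' @param total_dry_mass_pg Total nuclear dry mass at the reference time, pg.
#' @param rho_n Nuclear mass density, mg/mL.
#' @param rho_c Cytoplasmic mass density, mg/mL.
#' @param m_n Mean nuclear complex mass, kDa.
#' @param m_c Mean cytoplasmic complex mass, kDa.
#' @param chromatin A [chromatin_spec()].
#' @param temperature_K Temperature for the pressure columns, K.
#' @return A one-row data.frame with columns `V_n_um3`, `M_chr_pg`,
#'   `M_p_pg`, `n_n_mM`, `n_c_mM`, `pi_n_Pa`, `pi_c_Pa`, `delta_pi_Pa`.
#' @export
#' @examples
#' osmotic_report(51, 91.4, 100, 131.1, 155.8, chromatin_spec(3.1e9))
osmotic_report <- function(total_dry_mass_pg, rho_n, rho_c,
                           m_n = 131.1, m_c = 155.8,
                           chromatin = chromatin_spec(3.1e9),
                           temperature_K = nd_constants()$temperature_K) {
  stopifnot_scalar(rho_n, "rho_n", positive = TRUE)
  stopifnot_scalar(rho_c, "rho_c", positive = TRUE)
  V_n <- 1000 * total_dry_mass_pg / rho_n      # um^3
  M_chr <- chromatin_mass(chromatin)
  M_p <- nuclear_protein_mass(total_dry_mass_pg, M_chr)
  # nuclear complex density = protein mass / volume, in mg/mL
  rho_p <- 1000 * M_p / V_n
  n_n <- complex_concentration(rho_p, m_n)
  n_c <- complex_concentration(rho_c, m_c)
  data.frame(
    V_n_um3 = V_n, M_chr_pg = M_chr, M_p_pg = M_p,
    n_n_mM = n_n, n_c_mM = n_c,
    pi_n_Pa = vant_hoff_pressure(n_n, temperature_K),
    pi_c_Pa = vant_hoff_pressure(n_c, temperature_K),
    delta_pi_Pa = vant_hoff_pressure(n_c, temperature_K) -
      vant_hoff_pressure(n_n, temperature_K)
  )
}
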