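#' Parameters of the pressure-balance growth model
#'
#' The model treats the nucleus as a quasi-static osmometer. Imported
#' protein complexes (mean mass `m_n`) and an effective chromatin particle
#' count `N_chr` exert an ideal osmotic pressure inward-balanced by the
#' cytoplasmic complex pool at concentration `n_c`; the envelope carries no
#' tension and water equilibrates instantly, so at every instant the volume
#' satisfies
#' \deqn{kT\,[n_n(V) + N_{chr}/V] = kT\,n_c}
#' which is closed-form linear in the imported mass (see
#' [equilibrium_volume()]). Import kinetics are a single saturating pool,
#' \deqn{J(t) = J_0\,(G/G_{ref})^{\beta}\,(1 - M_p/M_{sat}),}
#' zero before decondensation ends at `t_dec` and zero when import is
#' disabled. The genome-size exponent `beta` stands in for the chromatin ->
#' RanGTP -> import coupling; its default 0.56 maps the X. laevis /
#' X. tropicalis genome ratio onto the observed ~1.4-fold nuclear dry-mass
#' difference.
#'
#' Defaults are the calibrated Xenopus egg-extract bookkeeping (see
#' [calibrate_xenopus()] for the closed-form chain that produces them).
#'
#' @param m_n Mean nuclear complex mass, kDa (default 131.1).
#' @param m_c Mean cytoplasmic complex mass, kDa (default 155.8).
#' @param rho_c Cytoplasmic mass density, mg/mL (default 100).
#' @param n_c Cytoplasmic complex concentration, mM (default `rho_c / m_c`).
#' @param M_chr Chromatin dry mass, pg (default from a 3.1e9 bp genome at
#'   packaging factor 4, ~13.4 pg).
#' @param N_chr Effective osmotic particle count of confined chromatin
#'   (dimensionless; default 4.3e7, the value the printed 60-min volume and
#'   mass imply).
#' @param genome_bp Genome size, bp (default 3.1e9).
#' @param genome_ref_bp Reference genome size for the import scaling
#'   (default 3.1e9, i.e. X. laevis flux is unscaled).
#' @param J0 Import flux amplitude, pg/min (default 1.08, which carries the
#'   default pool to the calibrated 60-min mass).
#' @param M_sat Saturating imported mass, pg (default 60).
#' @param t_dec End of the decondensation phase, min (default 5).
#' @param beta Genome-size import exponent (default 0.56).
#' @param rho_sperm Density of condensed sperm chromatin, mg/mL
#'   (default 183).
#' @param rho_dec Density of fully decondensed, solvated chromatin, mg/mL;
#'   defaults to `rho_c` (decondensed chromatin is indistinguishable from
#'   cytoplasm in the densitometry), and sets the volume floor
#'   `V_dec = M_chr / rho_dec`.
#' @param temperature_K Temperature, K (default 293).
#' @param import_enabled Logical; `FALSE` models import inhibition.
#' @return Object of class `model_params`.
#' @export
model_params <- function(m_n = 131.1, m_c = 155.8,
                         rho_c = 100, n_c = rho_c / m_c,
                         M_chr = chromatin_mass(chromatin_spec(3.1e9)),
                         N_chr = 4.3e7,
                         genome_bp = 3.1e9, genome_ref_bp = 3.1e9,
                         J0 = 1.08, M_sat = 60, t_dec = 5, beta = 0.56,
                         rho_sperm = 183, rho_dec = rho_c,
                         temperature_K = nd_constants()$temperature_K,
                         import_enabled = TRUE) {
  for (nm in c("m_n", "m_c", "rho_c", "n_c", "J0", "M_sat", "rho_sperm",
               "temperature_K")) {
    stopifnot_scalar(get(nm), nm, positive = TRUE)
  }
  for (nm in c("M_chr", "N_chr", "genome_bp", "t_dec", "rho_dec")) {
    stopifnot_scalar(get(nm), nm, nonneg = TRUE)
  }
  stopifnot_scalar(beta, "beta")
  stopifnot(is.logical(import_enabled), length(import_enabled) == 1L)
  structure(list(
    m_n = m_n, m_c = m_c, rho_c = rho_c, n_c = n_c,
    M_chr = M_chr, N_chr = N_chr,
    genome_bp = genome_bp, genome_ref_bp = genome_ref_bp,
    J0 = J0, M_sat = M_sat, t_dec = t_dec, beta = beta,
    rho_sperm = rho_sperm, rho_dec = rho_dec,
    temperature_K = temperature_K, import_enabled = import_enabled
  ), class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Pressure-balance model parameters\n")
  cat(sprintf("  complexes: m_n %.1f kDa, m_c %.1f kDa, n_c %.4f mM\n",
              x$m_n, x$m_c, x$n_c))
  cat(sprintf("  cytoplasm: rho_c %.1f mg/mL at %g K\n",
              x$rho_c, x$temperature_K))
  cat(sprintf("  chromatin: M_chr %.2f pg, N_chr %.3g, genome %.3g bp\n",
              x$M_chr, x$N_chr, x$genome_bp))
  cat(sprintf("  import: %s, J0 %.3f pg/min, M_sat %.1f pg, beta %.2f, t_dec %g min\n",
              if (x$import_enabled) "on" else "off",
              x$J0, x$M_sat, x$beta, x$t_dec))
  invisible(x)
}

#' Quasi-static equilibrium nuclear volume
#'
#' Solves the pressure balance `kT (n_n(V) + N_chr/V) = kT n_c` for the
#' volume at a given imported complex mass. With the internal unit system
#' the solution is closed-form and linear in `M_p`:
#' \deqn{V = \frac{1000\,M_p/(m_n\,n_c)\; [\mu m^3]\; + \;N_{chr}/(n_c\,N_{mM})}{}}
#' where `N_mM = 6.022e5` particles per µm³ per mM. `V = 0` when both the
#' imported mass and the chromatin particle count are zero (degenerate; a
#' warning is raised).
#'
#' @param M_p Imported complex mass, pg (vectorised).
#' @param params A [model_params()].
#' @return Volume in µm³.
#' @export
#' @examples
#' p <- calibrate_xenopus()
#' equilibrium_volume(p$M_p_60, p$params)       # ~558 um^3
equilibrium_volume <- function(M_p, params) {
  stopifnot(inherits(params, "model_params"))
  if (params$n_c <= 0) stop("`n_c` must be > 0", call. = FALSE)
  if (any(!is.finite(M_p)) || any(M_p < 0)) {
    stop("`M_p` must be finite and >= 0", call. = FALSE)
  }
  v <- 1000 * M_p / (params$m_n * params$n_c) +
    params$N_chr / (params$n_c * nd_constants()$particles_per_um3_per_mM)
  if (any(v == 0)) {
    warning("degenerate equilibrium volume 0 (M_p = 0 and N_chr = 0)",
            call. = FALSE)
  }
  v
}

#' Nuclear mass density at a given state
#'
#' `rho_n = (M_p + M_chr) / V`, expressed in mg/mL.
#'
#' @param M_p Imported complex mass, pg.
#' @param params A [model_params()] (supplies `M_chr`).
#' @param V Nuclear volume, µm³ (> 0).
#' @return Density in mg/mL.
#' @export
nuclear_density <- function(M_p, params, V) {
  stopifnot(inherits(params, "model_params"))
  if (any(!is.finite(V)) || any(V <= 0)) {
    stop("`V` must be finite and > 0", call. = FALSE)
  }
  1000 * (M_p + params$M_chr) / V
}

#' Import flux of the saturating pool
#'
#' Zero before `t_dec` and whenever import is disabled; otherwise
#' `J0 (G/G_ref)^beta (1 - M_p/M_sat)`, floored at zero.
#'
#' @param t Time, min.
#' @param M_p Imported mass so far, pg.
#' @param params A [model_params()].
#' @return Flux in pg/min.
#' @export
import_flux <- function(t, M_p, params) {
  stopifnot(inherits(params, "model_params"))
  if (params$M_sat <= 0) stop("`M_sat` must be > 0", call. = FALSE)
  if (!params$import_enabled) return(rep(0, length(t)))
  scale <- (params$genome_bp / params$genome_ref_bp)^params$beta
  flux <- params$J0 * scale * pmax(0, 1 - M_p / params$M_sat)
  ifelse(t < params$t_dec, 0, flux)
}

#' Simulate nuclear assembly
#'
#' Integrates the imported mass with a fixed-step explicit Euler scheme and
#' evaluates the volume quasi-statically at each step. The run has two
#' phases:
#' \enumerate{
#'   \item Decondensation (`t < t_dec`): no import; the condensed sperm
#'     state (`rho_sperm`, volume `M_chr/rho_sperm`) ramps linearly to the
#'     solvated state `V_dec = M_chr/rho_dec`, at which chromatin matches
#'     the surrounding density (`rho_dec` defaults to `rho_c`).
#'   \item Growth (`t >= t_dec`): `dM_p/dt = ` [import_flux()]; the volume
#'     is `max(V_dec, ` [equilibrium_volume()] `)` — the decondensed
#'     chromatin volume is a floor, so with import disabled the nucleus
#'     holds `rho_n = rho_dec` (≈ cytoplasmic density) indefinitely.
#' }
#' The Euler step (default 0.1 min) is automatically halved until no single
#' step moves the pool by more than `M_sat/10`; a refinement is reported
#' with a message.
#'
#' @param params A [model_params()].
#' @param t_grid Strictly increasing times (min) at which to report the
#'   state. Must start at >= 0.
#' @param dt Internal Euler step, min (default 0.1).
#' @return A data.frame of class `nd_trajectory` with columns `t_min`,
#'   `Mp_pg`, `V_um3`, `rho_mg_ml`.
#' @export
#' @examples
#' traj <- simulate_assembly(calibrate_xenopus()$params, seq(0, 60, 5))
#' traj[traj$t_min == 60, ]
simulate_assembly <- function(params, t_grid = seq(0, 60, by = 1), dt = 0.1) {
  stopifnot(inherits(params, "model_params"))
  if (length(t_grid) < 1L || any(diff(t_grid) <= 0) || t_grid[1] < 0) {
    stop("`t_grid` must be non-empty, start at >= 0 and increase strictly",
         call. = FALSE)
  }
  stopifnot_scalar(dt, "dt", positive = TRUE)

  # refine the step until the fastest possible move is < M_sat/10
  jmax <- params$J0 * (params$genome_bp / params$genome_ref_bp)^params$beta
  while (params$import_enabled && jmax * dt > params$M_sat / 10) {
    dt <- dt / 2
    message(sprintf("euler step refined to %g min", dt))
  }

  Mp <- .euler_mass(params, t_grid, dt)
  st <- .predict_observables(params, t_grid, dt, Mp = Mp)
  traj <- data.frame(t_min = t_grid, Mp_pg = Mp,
                     V_um3 = st$V, rho_mg_ml = st$rho)
  class(traj) <- c("nd_trajectory", "data.frame")
  traj
}

#' Fraction of the final volume contributed by chromatin pressure
#'
#' Compares the full equilibrium volume at a final imported mass with the
#' protein-only volume (same mass, `N_chr = 0`):
#' `1 - V_protein_only / V_full`. With the calibrated Xenopus bookkeeping
#' this is ~0.20.
#'
#' @param params A [model_params()].
#' @param M_p_final Final imported mass, pg.
#' @return Dimensionless fraction in `[0, 1)`.
#' @export
chromatin_contribution <- function(params, M_p_final) {
  stopifnot(inherits(params, "model_params"))
  stopifnot_scalar(M_p_final, "M_p_final", nonneg = TRUE)
  if (params$N_chr == 0) return(0)
  p0 <- params
  p0$N_chr <- 0
  v_full <- suppressWarnings(equilibrium_volume(M_p_final, params))
  if (v_full == 0) return(0)
  v_prot <- suppressWarnings(equilibrium_volume(M_p_final, p0))
  1 - v_prot / v_full
}

#' Apply a named perturbation scenario to model parameters
#'
#' Encodes the experimental perturbations as parameter transforms:
#' \describe{
#'   \item{control}{no change.}
#'   \item{import_inhibition}{import disabled (ivermectin/pitstop
#'     treatment); the nucleus holds the decondensed-chromatin density.}
#'   \item{ploidy_swap}{assemble around a different genome
#'     (`genome_bp`, default 1.7e9 bp): chromatin mass and particle count
#'     scale with genome size; import scales through `beta`.}
#'   \item{hs_extract}{high-speed extract: heavy, osmotically inactive
#'     components (ribosomes, glycogen) removed, so `rho_c` drops by
#'     `rho_c_factor` (default 0.5) while `n_c` is unchanged — nuclear dry
#'     mass is predicted to match the untreated control.}
#'   \item{add_back}{heavy components restored: `rho_c` set back to
#'     `rho_c_restore` (default the current control value, 100).}
#'   \item{senescence}{cytoplasm diluted by `cyto_dilution` (default
#'     22/66, the measured senescent drop) through loss of heavy but
#'     osmotically minor components (`n_c` unchanged); the nucleoplasmic
#'     supply (`J0`, `M_sat`) scaled by `nuclear_supply` (default 28/56).
#'     The density ratio inverts.}
#'   \item{cleavage}{a cell of the stated dry mass can supply at most
#'     `phi` of its content: `M_sat <- min(M_sat, phi * cell_dry_mass_pg)`.}
#' }
#'
#' @param params A [model_params()].
#' @param scenario Scenario name (see Details).
#' @param genome_bp,rho_c_factor,rho_c_restore,cyto_dilution,nuclear_supply,cell_dry_mass_pg,phi
#'   Scenario knobs; only the ones the named scenario uses are consulted.
#' @return A transformed `model_params`.
#' @export
#' @examples
#' p <- calibrate_xenopus()$params
#' apply_scenario(p, "import_inhibition")$import_enabled
apply_scenario <- function(params, scenario,
                           genome_bp = 1.7e9,
                           rho_c_factor = 0.5,
                           rho_c_restore = 100,
                           cyto_dilution = 22 / 66,
                           nuclear_supply = 28 / 56,
                           cell_dry_mass_pg = NULL,
                           phi = 0.02) {
  stopifnot(inherits(params, "model_params"))
  known <- c("control", "import_inhibition", "ploidy_swap", "hs_extract",
             "add_back", "senescence", "cleavage")
  if (!is.character(scenario) || length(scenario) != 1L ||
      !(scenario %in% known)) {
    stop("unknown scenario; expected one of: ",
         paste(known, collapse = ", "), call. = FALSE)
  }
  p <- params
  switch(scenario,
    control = NULL,
    import_inhibition = {
      p$import_enabled <- FALSE
    },
    ploidy_swap = {
      ratio <- genome_bp / p$genome_bp
      p$genome_bp <- genome_bp
      p$M_chr <- p$M_chr * ratio
      p$N_chr <- p$N_chr * ratio
    },
    hs_extract = {
      p$rho_c <- p$rho_c * rho_c_factor
      p$rho_dec <- p$rho_dec * rho_c_factor
    },
    add_back = {
      p$rho_c <- rho_c_restore
      p$rho_dec <- rho_c_restore
    },
    senescence = {
      # dilution is loss of heavy, osmotically minor components: rho_c
      # drops while n_c stays (as for the ultracentrifuged extract)
      p$rho_c <- p$rho_c * cyto_dilution
      p$rho_dec <- p$rho_dec * cyto_dilution
      p$J0 <- p$J0 * nuclear_supply
      p$M_sat <- p$M_sat * nuclear_supply
    },
    cleavage = {
      if (is.null(cell_dry_mass_pg)) {
        stop("cleavage scenario needs `cell_dry_mass_pg`", call. = FALSE)
      }
      p$M_sat <- min(p$M_sat, phi * cell_dry_mass_pg)
    }
  )
  p
}
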