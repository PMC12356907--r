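#' Physical constants and unit conversions
#'
#' The package works in a fixed internal unit system: lengths in micrometres,
#' volumes in cubic micrometres, masses in picograms, mass densities in
#' mg/mL and molar concentrations in mM. `nd_constants()` returns the
#' registry of physical constants and conversion factors every module uses,
#' so that all unit handling lives in one place.
#'
#' Key identities:
#' \itemize{
#'   \item 1 mg/mL = 1e-3 pg/µm³ (so `V[µm³] = 1000 * M[pg] / rho[mg/mL]`).
#'   \item 1 mM of particles = `6.02214076e5` particles per µm³.
#'   \item `n[mM] = rho[mg/mL] / m[kDa]` for a pool of complexes of mean
#'     mass `m`.
#' }
#'
#' @return Named list with elements
#'   \describe{
#'     \item{alpha_ml_per_g}{default refractive-index increment for
#'       protein/nucleic-acid dry mass, 0.19 mL/g}
#'     \item{gas_constant_J_per_mol_K}{R = 8.31446 J/(mol K)}
#'     \item{avogadro_per_mol}{Avogadro constant, 1/mol}
#'     \item{pg_per_um3_per_mg_ml}{1e-3: pg/µm³ per mg/mL}
#'     \item{particles_per_um3_per_mM}{particles per µm³ in a 1 mM solution}
#'     \item{da_per_bp}{average mass of one DNA base pair, 650 Da}
#'     \item{temperature_K}{default temperature, 293 K (extract work at
#'       16-20 degrees C)}
#'     \item{chromatin_packaging_factor}{default total-chromatin to
#'       naked-DNA mass ratio, 4}
#'   }
#' @export
#' @examples
#' cst <- nd_constants()
#' # 100 mg/mL of 155.8 kDa complexes:
#' 100 / 155.8                       # mM
#' 100 * cst$pg_per_um3_per_mg_ml    # pg/um^3
nd_constants <- function() {
  list(
    alpha_ml_per_g            = 0.19,
    gas_constant_J_per_mol_K  = 8.31446,
    avogadro_per_mol          = 6.02214076e23,
    pg_per_um3_per_mg_ml      = 1e-3,
    particles_per_um3_per_mM  = 6.02214076e5,
    da_per_bp                 = 650,
    temperature_K             = 293,
    chromatin_packaging_factor = 4
  )
}

# internal shorthand
.nd <- nd_constants()

# run a block with a fixed RNG seed, restoring RNG state afterwards
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

stopifnot_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  }
  if (nonneg && x < 0) {
    stop(sprintf("`%s` must be >= 0", name), call. = FALSE)
  }
  invisible(x)
}
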