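#' Specification of a cleavage-stage embryo lineage
#'
#' The null model the lineage encodes: cleavage partitions a fixed pool of
#' maternal material into smaller cells without growth, nucleoplasmic and
#' cytoplasmic densities are constants, and each cell assembles a nucleus
#' whose imported mass is limited by the material the cell holds
#' (`M_p = min(M_sat, phi * cell dry mass)`). Because the equilibrium
#' volume carries a cell-size-independent chromatin term, the NC volume
#' ratio rises as cells shrink while the NC density ratio stays exactly
#' `density_nucleoplasm / density_cytoplasm`.
#'
#' @param n_divisions Number of divisions (>= 1).
#' @param initial_cell_volume_um3 One-cell material pool volume, µm³.
#' @param density_cytoplasm,density_nucleoplasm Constant densities, mg/mL.
#' @param phi Fraction of a cell's dry mass available for nuclear import
#'   (default 0.02, which leaves the 2-cell stage below saturation).
#' @param M_sat Saturating imported mass per nucleus, pg (default 40).
#' @param params A [model_params()] used for [equilibrium_volume()]
#'   (default: standard complex masses with a small chromatin particle
#'   count per embryo nucleus).
#' @param asymmetry_sd S.d. of the division fraction around 0.5 (default 0:
#'   symmetric cleavage). Fractions are clamped to `[0.2, 0.8]`.
#' @param seed Integer seed (used only when `asymmetry_sd > 0`).
#' @return Object of class `lineage_spec`.
#' @export
lineage_spec <- function(n_divisions = 4,
                         initial_cell_volume_um3 = 25000,
                         density_cytoplasm = 100,
                         density_nucleoplasm = 80,
                         phi = 0.02, M_sat = 40,
                         params = model_params(N_chr = 4.3e6,
                                               M_chr = 0.3,
                                               rho_c = density_cytoplasm),
                         asymmetry_sd = 0, seed = 1L) {
  if (!is.numeric(n_divisions) || length(n_divisions) != 1L ||
      n_divisions < 1 || n_divisions != round(n_divisions)) {
    stop("`n_divisions` must be an integer >= 1", call. = FALSE)
  }
  stopifnot_scalar(initial_cell_volume_um3, "initial_cell_volume_um3",
                   positive = TRUE)
  stopifnot_scalar(density_cytoplasm, "density_cytoplasm", positive = TRUE)
  stopifnot_scalar(density_nucleoplasm, "density_nucleoplasm",
                   positive = TRUE)
  stopifnot_scalar(phi, "phi", positive = TRUE)
  stopifnot_scalar(M_sat, "M_sat", positive = TRUE)
  stopifnot_scalar(asymmetry_sd, "asymmetry_sd", nonneg = TRUE)
  stopifnot(inherits(params, "model_params"))
  structure(list(
    n_divisions = as.integer(n_divisions),
    initial_cell_volume_um3 = initial_cell_volume_um3,
    density_cytoplasm = density_cytoplasm,
    density_nucleoplasm = density_nucleoplasm,
    phi = phi, M_sat = M_sat, params = params,
    asymmetry_sd = asymmetry_sd, seed = as.integer(seed)
  ), class = "lineage_spec")
}

#' Generate per-cell records of a cleavage-stage lineage
#'
#' Each division splits a cell's material pool (volume and dry mass)
#' exactly between the daughters, so the stage totals conserve the maternal
#' pool bit-for-bit. Within every cell, a nucleus condenses out of the
#' cytoplasm at the constant nucleoplasmic density: the imported mass is
#' `min(M_sat, phi * cell dry mass)`, the nuclear volume follows
#' [equilibrium_volume()], the nuclear dry mass is `rho_n * V_n`, and the
#' cytoplasm gives up that mass together with `M_n / rho_c` of volume so
#' its density stays exactly `rho_c`. The reported cell volume is the
#' cytoplasmic plus nuclear volume (the nucleus swells osmotically, so it
#' slightly exceeds the allocated pool volume).
#'
#' @param spec A [lineage_spec()].
#' @return data.frame with one row per cell and stage: `stage` (0 = one
#'   cell), `cell_id`, `V_pool_um3`, `M_pool_pg`, `V_nuc_um3`, `M_nuc_pg`,
#'   `V_cyt_um3`, `M_cyt_pg`, `V_cell_um3`, `M_cell_pg`, `rho_nuc_mg_ml`,
#'   `rho_cyt_mg_ml`, `density_ratio`, `volume_ratio`, `mass_ratio`.
#' @export
#' @examples
#' emb <- make_embryo_lineage(lineage_spec(n_divisions = 4))
#' aggregate(volume_ratio ~ stage, emb, mean)
make_embryo_lineage <- function(spec) {
  stopifnot(inherits(spec, "lineage_spec"))
  rho_c <- spec$density_cytoplasm
  rho_n <- spec$density_nucleoplasm
  pgf <- nd_constants()$pg_per_um3_per_mg_ml

  cell_row <- function(stage, cell_id, V_pool) {
    M_pool <- V_pool * rho_c * pgf
    M_p <- min(spec$M_sat, spec$phi * M_pool)
    V_n <- suppressWarnings(equilibrium_volume(M_p, spec$params))
    M_n <- V_n * rho_n * pgf
    if (M_n >= M_pool) {
      stop("nuclear mass exceeds the cell's material pool at stage ",
           stage, "; lower `phi` or `M_sat`", call. = FALSE)
    }
    V_cyt <- V_pool - M_n / (rho_c * pgf)
    M_cyt <- M_pool - M_n
    data.frame(
      stage = stage, cell_id = cell_id,
      V_pool_um3 = V_pool, M_pool_pg = M_pool,
      V_nuc_um3 = V_n, M_nuc_pg = M_n,
      V_cyt_um3 = V_cyt, M_cyt_pg = M_cyt,
      V_cell_um3 = V_cyt + V_n, M_cell_pg = M_cyt + M_n,
      rho_nuc_mg_ml = rho_n, rho_cyt_mg_ml = M_cyt / V_cyt / pgf,
      density_ratio = rho_n / rho_c,
      volume_ratio = V_n / V_cyt,
      mass_ratio = M_n / M_cyt
    )
  }

  fractions <- function(n_cells, stage) {
    if (spec$asymmetry_sd == 0) return(rep(0.5, n_cells))
    with_seed(spec$seed + stage, {
      pmin(0.8, pmax(0.2, stats::rnorm(n_cells, 0.5, spec$asymmetry_sd)))
    })
  }

  pools <- spec$initial_cell_volume_um3
  rows <- list(cell_row(0L, 1L, pools))
  for (s in seq_len(spec$n_divisions)) {
    f <- fractions(length(pools), s)
    pools <- as.vector(rbind(pools * f, pools * (1 - f)))
    rows[[s + 1L]] <- do.call(rbind, lapply(seq_along(pools), function(i) {
      cell_row(s, i, pools[i])
    }))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
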