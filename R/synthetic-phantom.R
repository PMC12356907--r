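#' Specification of a synthetic cell phantom
#'
#' Describes a cell as nested analytic solids — an ellipsoidal cell, a
#' spherical nucleus and optional spherical nucleoli — with a uniform
#' dry-mass density per compartment. The phantom emulates what an optical
#' diffraction tomography reconstruction of such a cell would look like:
#' voxel RI is `medium_ri + alpha * rho / 1000` plus additive Gaussian
#' noise, with a Gaussian blur along the optical (Z) axis standing in for
#' the anisotropic axial smearing of limited-angle tomography. Holograms
#' and the reconstruction itself are not simulated.
#'
#' @param cell_semi_axes_um Ellipsoid semi-axes `c(x, y, z)`, µm.
#' @param nucleus_radius_um Nuclear radius, µm; the nucleus (centred in the
#'   cell) must fit inside the cell.
#' @param nucleolus_radii_um Numeric vector of nucleolus radii, µm (may be
#'   empty).
#' @param nucleolus_centers_um Optional list of `c(x, y, z)` offsets of the
#'   nucleoli from the nucleus centre, µm. Defaults place them along the
#'   x-axis. Each nucleolus must fit inside the nucleus.
#' @param density_cytoplasm,density_nucleoplasm,density_nucleolus
#'   Compartment dry-mass densities, mg/mL (all >= 0).
#' @param medium_ri Medium refractive index (default 1.333).
#' @param ri_increment Refractive-index increment alpha, mL/g (default 0.19).
#' @param voxel_size_um Isotropic voxel size, µm (default 0.12, the
#'   resolution scale of the emulated instrument).
#' @param noise_sd Additive RI noise s.d. (default 2e-4, small against the
#'   0.019 RI contrast of 100 mg/mL).
#' @param axial_blur_sigma_um Gaussian sigma of the Z-axis blur, µm
#'   (default 0.4).
#' @param margin_um Padding of medium around the cell, µm (default 0.5).
#' @param seed Integer seed; identical specs with identical seeds produce
#'   bit-identical phantoms.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(cell_semi_axes_um,
                         nucleus_radius_um,
                         nucleolus_radii_um = numeric(0),
                         nucleolus_centers_um = NULL,
                         density_cytoplasm = 100,
                         density_nucleoplasm = 80,
                         density_nucleolus = 150,
                         medium_ri = 1.333,
                         ri_increment = nd_constants()$alpha_ml_per_g,
                         voxel_size_um = 0.12,
                         noise_sd = 2e-4,
                         axial_blur_sigma_um = 0.4,
                         margin_um = 0.5,
                         seed = 1L) {
  if (!is.numeric(cell_semi_axes_um) || length(cell_semi_axes_um) != 3L ||
      any(cell_semi_axes_um <= 0)) {
    stop("`cell_semi_axes_um` must be three positive semi-axes c(x, y, z)",
         call. = FALSE)
  }
  stopifnot_scalar(nucleus_radius_um, "nucleus_radius_um", positive = TRUE)
  if (nucleus_radius_um > min(cell_semi_axes_um)) {
    stop("geometry does not nest: nucleus (radius ",
         nucleus_radius_um, " um) does not fit inside the cell (min semi-axis ",
         min(cell_semi_axes_um), " um)", call. = FALSE)
  }
  for (nm in c("density_cytoplasm", "density_nucleoplasm",
               "density_nucleolus", "noise_sd", "axial_blur_sigma_um",
               "margin_um")) {
    stopifnot_scalar(get(nm), nm, nonneg = TRUE)
  }
  stopifnot_scalar(voxel_size_um, "voxel_size_um", positive = TRUE)
  stopifnot_scalar(medium_ri, "medium_ri", positive = TRUE)
  stopifnot_scalar(ri_increment, "ri_increment", positive = TRUE)

  k <- length(nucleolus_radii_um)
  if (k > 0) {
    if (any(nucleolus_radii_um <= 0)) {
      stop("nucleolus radii must be > 0", call. = FALSE)
    }
    if (is.null(nucleolus_centers_um)) {
      # default placement: spread along x within the nucleus
      off <- if (k == 1L) 0 else
        seq(-0.5, 0.5, length.out = k) * nucleus_radius_um
      nucleolus_centers_um <- lapply(off, function(o) c(o, 0, 0))
    }
    if (length(nucleolus_centers_um) != k) {
      stop("need one centre per nucleolus", call. = FALSE)
    }
    for (i in seq_len(k)) {
      ctr <- nucleolus_centers_um[[i]]
      if (length(ctr) != 3L) stop("nucleolus centres must be c(x, y, z)",
                                  call. = FALSE)
      if (sqrt(sum(ctr^2)) + nucleolus_radii_um[i] > nucleus_radius_um) {
        stop("geometry does not nest: nucleolus ", i,
             " does not fit inside the nucleus", call. = FALSE)
      }
    }
  } else {
    nucleolus_centers_um <- list()
  }

  structure(list(
    cell_semi_axes_um = cell_semi_axes_um,
    nucleus_radius_um = nucleus_radius_um,
    nucleolus_radii_um = nucleolus_radii_um,
    nucleolus_centers_um = nucleolus_centers_um,
    density_cytoplasm = density_cytoplasm,
    density_nucleoplasm = density_nucleoplasm,
    density_nucleolus = density_nucleolus,
    medium_ri = medium_ri, ri_increment = ri_increment,
    voxel_size_um = voxel_size_um, noise_sd = noise_sd,
    axial_blur_sigma_um = axial_blur_sigma_um,
    margin_um = margin_um, seed = as.integer(seed)
  ), class = "phantom_spec")
}

# Gaussian blur along the first (Z) dimension only, sigma in voxels;
# kernel rows renormalised so flat fields are preserved at the borders
.axial_blur <- function(arr, sigma_vox) {
  if (sigma_vox <= 0) return(arr)
  nz <- dim(arr)[1]
  half <- max(1L, ceiling(3 * sigma_vox))
  idx <- seq_len(nz)
  K <- outer(idx, idx, function(i, j) {
    d <- abs(i - j)
    ifelse(d <= half, exp(-d^2 / (2 * sigma_vox^2)), 0)
  })
  K <- K / rowSums(K)
  out <- K %*% matrix(arr, nrow = nz)
  array(out, dim = dim(arr))
}

#' Generate a cell phantom with ground truth
#'
#' Voxelises the phantom geometry on a (Z, Y, X) grid, assigns the label
#' mask (0 background, 1 cytoplasm, 2 nucleoplasm, 3 nucleolus), maps
#' compartment densities to RI, applies the axial blur and adds seeded
#' Gaussian noise. Alongside the tomogram it returns the analytic ground
#' truth — exact volumes and dry masses per compartment — against which
#' quantifications can be scored.
#'
#' @param spec A [phantom_spec()].
#' @return List of class `phantom` with elements `tomogram` (a
#'   [tomogram()]), `mask` (integer label array), `truth` (named list of
#'   [compartment_quant()]: `cytoplasm`, `nucleoplasm`, optionally
#'   `nucleolus`, plus `cell`), and `spec`.
#' @export
#' @examples
#' ph <- make_cell_phantom(phantom_spec(c(4, 4, 3), 2, voxel_size_um = 0.3))
#' ph$truth$nucleoplasm
make_cell_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  vox <- spec$voxel_size_um
  half_extent <- spec$cell_semi_axes_um + spec$margin_um
  n_xyz <- pmax(3L, as.integer(ceiling(2 * half_extent / vox)))
  # voxel-centre coordinates relative to the cell centre, per axis
  coord <- lapply(1:3, function(k) {
    (seq_len(n_xyz[k]) - (n_xyz[k] + 1) / 2) * vox
  })
  xs <- coord[[1]]; ys <- coord[[2]]; zs <- coord[[3]]
  nz <- length(zs); ny <- length(ys); nx <- length(xs)

  # (Z, Y, X) field of the ellipsoid quadratic form
  qf <- function(za, ya, xa) {
    outer(outer(za, ya, "+"), xa, "+")
  }
  a <- spec$cell_semi_axes_um
  in_cell <- qf((zs / a[3])^2, (ys / a[2])^2, (xs / a[1])^2) <= 1
  r2 <- qf(zs^2, ys^2, xs^2)
  in_nuc <- r2 <= spec$nucleus_radius_um^2

  mask <- array(0L, dim = c(nz, ny, nx))
  mask[in_cell] <- 1L
  mask[in_nuc] <- 2L
  for (i in seq_along(spec$nucleolus_radii_um)) {
    ctr <- spec$nucleolus_centers_um[[i]]
    d2 <- qf((zs - ctr[3])^2, (ys - ctr[2])^2, (xs - ctr[1])^2)
    mask[d2 <= spec$nucleolus_radii_um[i]^2] <- 3L
  }

  rho <- array(0, dim = dim(mask))
  rho[mask == 1L] <- spec$density_cytoplasm
  rho[mask == 2L] <- spec$density_nucleoplasm
  rho[mask == 3L] <- spec$density_nucleolus

  ri <- density_to_ri(rho, spec$medium_ri, spec$ri_increment)
  ri <- .axial_blur(ri, spec$axial_blur_sigma_um / vox)
  if (spec$noise_sd > 0) {
    ri <- ri + with_seed(spec$seed, {
      array(stats::rnorm(length(ri), sd = spec$noise_sd), dim = dim(ri))
    })
  }

  v_sphere <- function(r) 4 / 3 * pi * r^3
  v_nucleolus <- sum(v_sphere(spec$nucleolus_radii_um))
  v_nucleoplasm <- v_sphere(spec$nucleus_radius_um) - v_nucleolus
  v_cyto <- 4 / 3 * pi * prod(a) - v_sphere(spec$nucleus_radius_um)
  pgf <- nd_constants()$pg_per_um3_per_mg_ml
  truth <- list(
    cytoplasm = compartment_quant("cytoplasm", v_cyto,
                                  v_cyto * spec$density_cytoplasm * pgf),
    nucleoplasm = compartment_quant("nucleoplasm", v_nucleoplasm,
                                    v_nucleoplasm * spec$density_nucleoplasm * pgf)
  )
  if (v_nucleolus > 0) {
    truth$nucleolus <- compartment_quant(
      "nucleolus", v_nucleolus, v_nucleolus * spec$density_nucleolus * pgf)
  }
  v_cell <- 4 / 3 * pi * prod(a)
  m_cell <- sum(vapply(truth, function(q) q$dry_mass_pg, 0))
  truth$cell <- compartment_quant("cell", v_cell, m_cell)

  structure(list(
    tomogram = tomogram(ri, vox, spec$medium_ri),
    mask = mask,
    truth = truth,
    spec = spec
  ), class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat("Synthetic cell phantom\n")
  print(x$tomogram)
  for (q in x$truth) print(q)
  invisible(x)
}

#' Default cross-species panel table
#'
#' The absolute per-species densities are instrument data and not shipped
#' as constants; this editable table provides plausible defaults at the
#' conserved NC density ratio of 0.8 across a eukaryotic size range. Sizes
#' are cell ellipsoid semi-axes and nuclear radii in µm.
#'
#' @param n_cells Cells per species (default 15).
#' @return data.frame with columns `species`, `rho_n`, `rho_c`,
#'   `cell_x`, `cell_y`, `cell_z`, `nucleus_radius`, `roi_edge` (the
#'   species-specific ROI edge length, µm), `n_cells`.
#' @export
species_panel_table <- function(n_cells = 15) {
  data.frame(
    species = c("S. cerevisiae", "S. pombe", "C. reinhardtii",
                "C. elegans", "D. melanogaster", "D. rerio",
                "X. laevis", "M. musculus", "H. sapiens"),
    rho_n = c(152, 144, 120, 96, 104, 88, 80, 96, 88),
    rho_c = c(190, 180, 150, 120, 130, 110, 100, 120, 110),
    cell_x = c(2.5, 5, 5, 12, 6, 8, 10, 7, 8),
    cell_y = c(2.2, 2, 5, 10, 6, 8, 8, 7, 8),
    cell_z = c(2.2, 2, 4, 8, 5, 6, 7, 6, 6),
    nucleus_radius = c(1, 1.2, 2, 4, 2.5, 3, 4, 3, 3),
    roi_edge = c(0.5, 0.5, 1, 2.5, 1.5, 2, 2.5, 2, 2),
    n_cells = n_cells
  )
}

#' Generate a panel of phantoms from a per-species table
#'
#' One phantom per cell and species row, with per-cell seeds derived from
#' `seed`. Each phantom's ground-truth NC density ratio equals the row's
#' `rho_n / rho_c` by construction.
#'
#' @param table data.frame as returned by [species_panel_table()] (columns
#'   `species`, `rho_n`, `rho_c`, `cell_x`, `cell_y`, `cell_z`,
#'   `nucleus_radius`, `n_cells`; optional `voxel_size`, `noise_sd`).
#' @param seed Integer master seed.
#' @param voxel_size_um Default voxel size for rows without a
#'   `voxel_size` column (0.12 µm).
#' @param noise_sd Default RI noise for rows without a `noise_sd` column.
#' @return List of `phantom` objects; each carries `species` and
#'   `truth_density_ratio` attributes-like fields in its `spec`.
#' @export
make_species_panel <- function(table, seed = 1L, voxel_size_um = 0.12,
                               noise_sd = 2e-4) {
  req <- c("species", "rho_n", "rho_c", "cell_x", "cell_y", "cell_z",
           "nucleus_radius", "n_cells")
  if (!is.data.frame(table) || nrow(table) == 0L) {
    stop("`table` must be a non-empty data.frame", call. = FALSE)
  }
  missing_cols <- setdiff(req, names(table))
  if (length(missing_cols)) {
    stop("`table` lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- list()
  for (r in seq_len(nrow(table))) {
    row <- table[r, ]
    n <- as.integer(row$n_cells)
    if (n < 1L) next
    for (i in seq_len(n)) {
      sp <- phantom_spec(
        cell_semi_axes_um = c(row$cell_x, row$cell_y, row$cell_z),
        nucleus_radius_um = row$nucleus_radius,
        density_cytoplasm = row$rho_c,
        density_nucleoplasm = row$rho_n,
        voxel_size_um = if ("voxel_size" %in% names(table))
          row$voxel_size else voxel_size_um,
        noise_sd = if ("noise_sd" %in% names(table))
          row$noise_sd else noise_sd,
        seed = as.integer(seed) + 1000L * r + i
      )
      ph <- make_cell_phantom(sp)
      ph$species <- as.character(row$species)
      ph$truth_density_ratio <- row$rho_n / row$rho_c
      if ("roi_edge" %in% names(table)) ph$spec_roi_edge <- row$roi_edge
      out[[length(out) + 1L]] <- ph
    }
  }
  out
}
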