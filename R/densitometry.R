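#' Refractive-index tomogram container
#'
#' A 3D refractive-index stack in plane-major (Z, Y, X) order together with
#' the voxel size and the independently measured refractive index of the
#' surrounding medium. This is the raw-measurement surrogate every
#' quantification step starts from.
#'
#' @param ri 3D numeric array of refractive indices, dimension
#'   `(Z, Y, X)`; all values finite.
#' @param voxel_size_um Isotropic voxel edge length, µm (> 0).
#' @param medium_ri Refractive index of the surrounding medium/extract.
#' @return Object of class `tomogram`.
#' @export
tomogram <- function(ri, voxel_size_um, medium_ri) {
  if (!is.array(ri) || length(dim(ri)) != 3L) {
    stop("`ri` must be a 3D array in (Z, Y, X) order", call. = FALSE)
  }
  if (any(!is.finite(ri))) stop("all RI values must be finite", call. = FALSE)
  stopifnot_scalar(voxel_size_um, "voxel_size_um", positive = TRUE)
  stopifnot_scalar(medium_ri, "medium_ri", positive = TRUE)
  structure(list(ri = ri, voxel_size_um = voxel_size_um,
                 medium_ri = medium_ri),
            class = "tomogram")
}

#' @export
print.tomogram <- function(x, ...) {
  d <- dim(x$ri)
  cat(sprintf("RI tomogram %d x %d x %d (Z,Y,X) at %.3g um/voxel, medium RI %.4f\n",
              d[1], d[2], d[3], x$voxel_size_um, x$medium_ri))
  cat(sprintf("  RI range [%.5f, %.5f]\n", min(x$ri), max(x$ri)))
  invisible(x)
}

#' Convert refractive index to dry-mass density (and back)
#'
#' In biological material the refractive index is linear in the dry-mass
#' density of dissolved macromolecules: `n_sample = n_medium + alpha * rho`,
#' with `alpha` the refractive-index increment (0.19 mL/g for
#' protein/nucleic-acid mixtures). Inverting gives
#' `rho[mg/mL] = 1000 * (ri - medium_ri) / alpha`.
#'
#' Negative densities (noise below the background) are returned as-is, not
#' clipped: clipping would bias integrated masses.
#'
#' @param ri Refractive index value(s).
#' @param medium_ri Medium refractive index.
#' @param alpha Refractive-index increment, mL/g (default 0.19).
#' @return Density in mg/mL (`ri_to_density`) or RI (`density_to_ri`).
#' @export
#' @examples
#' ri_to_density(1.352, 1.333)   # 100 mg/mL
#' density_to_ri(100, 1.333)     # 1.352
ri_to_density <- function(ri, medium_ri,
                          alpha = nd_constants()$alpha_ml_per_g) {
  stopifnot_scalar(alpha, "alpha", positive = TRUE)
  1000 * (ri - medium_ri) / alpha
}

#' @rdname ri_to_density
#' @param density Dry-mass density in mg/mL.
#' @export
density_to_ri <- function(density, medium_ri,
                          alpha = nd_constants()$alpha_ml_per_g) {
  stopifnot_scalar(alpha, "alpha", positive = TRUE)
  medium_ri + alpha * density / 1000
}

#' Segment the cell from the surrounding medium by Otsu thresholding
#'
#' Computes one global Otsu threshold on the RI histogram of the full stack
#' (3D objects are thresholded as a whole, not per plane) and returns the
#' foreground mask. The chosen threshold is reported via `message()` and
#' attached as the `"threshold"` attribute.
#'
#' @param tom A [tomogram()].
#' @param levels Number of histogram levels for the threshold search
#'   (default 256).
#' @return Integer array of the tomogram's dimension: 1 foreground
#'   (cell), 0 background, with attribute `threshold`.
#' @export
segment_otsu <- function(tom, levels = 256) {
  stopifnot(inherits(tom, "tomogram"))
  rng <- range(tom$ri)
  if (rng[1] == rng[2]) {
    stop("degenerate histogram: tomogram is constant", call. = FALSE)
  }
  # one global threshold: flatten the stack into a single frame
  flat <- EBImage::Image(matrix(tom$ri, nrow = dim(tom$ri)[1]))
  thr <- EBImage::otsu(flat, range = rng, levels = levels)
  message(sprintf("otsu threshold: RI %.6f", thr))
  mask <- array(as.integer(tom$ri > thr), dim = dim(tom$ri))
  attr(mask, "threshold") <- thr
  mask
}

#' Per-compartment volume, dry mass and mean density
#'
#' Integrates a labelled region of a tomogram exactly as the densitometry
#' defines it: volume is the voxel count times the voxel volume, dry mass
#' is the voxel-wise density integrated over the region, and the mean
#' density is dry mass over volume. Sub-background (negative-density)
#' voxels are retained in the integration by default — dropping them would
#' bias the mass — and their count is reported for QC.
#'
#' @param tom A [tomogram()].
#' @param mask Integer label array matching `dim(tom$ri)`.
#' @param label Label value to quantify.
#' @param alpha Refractive-index increment, mL/g.
#' @param name Compartment name stored in the result (default the label).
#' @param include_negative Keep negative-density voxels in the integral
#'   (default `TRUE`); `FALSE` clips them to zero.
#' @return Object of class `compartment_quant`: a list with `label`,
#'   `volume_um3`, `dry_mass_pg`, `mean_density_mg_ml`, `n_voxels`,
#'   `n_negative_voxels`.
#' @export
quantify_compartment <- function(tom, mask, label,
                                 alpha = nd_constants()$alpha_ml_per_g,
                                 name = as.character(label),
                                 include_negative = TRUE) {
  stopifnot(inherits(tom, "tomogram"))
  if (!identical(dim(mask), dim(tom$ri))) {
    stop("`mask` dimensions must match the tomogram", call. = FALSE)
  }
  sel <- mask == label
  n_vox <- sum(sel)
  if (n_vox == 0L) {
    stop("empty compartment: no voxel carries label ", label, call. = FALSE)
  }
  vox_vol <- tom$voxel_size_um^3
  rho <- ri_to_density(tom$ri[sel], tom$medium_ri, alpha)
  n_neg <- sum(rho < 0)
  if (!include_negative) rho <- pmax(rho, 0)
  volume <- n_vox * vox_vol
  # mg/mL = 1e-3 pg/um^3
  dry_mass <- sum(rho) * vox_vol * nd_constants()$pg_per_um3_per_mg_ml
  compartment_quant(name, volume, dry_mass, n_voxels = n_vox,
                    n_negative_voxels = n_neg)
}

#' Construct a compartment quantification record
#'
#' Mean density is derived as `1000 * dry_mass / volume` so the identity
#' `mean_density * volume == 1000 * dry_mass` holds to machine precision.
#'
#' @param label Compartment name.
#' @param volume_um3 Volume, µm³ (> 0).
#' @param dry_mass_pg Dry mass, pg.
#' @param n_voxels,n_negative_voxels Optional QC counts.
#' @return Object of class `compartment_quant`.
#' @export
compartment_quant <- function(label, volume_um3, dry_mass_pg,
                              n_voxels = NA_integer_,
                              n_negative_voxels = NA_integer_) {
  stopifnot_scalar(volume_um3, "volume_um3", positive = TRUE)
  stopifnot_scalar(dry_mass_pg, "dry_mass_pg")
  structure(list(
    label = as.character(label),
    volume_um3 = volume_um3,
    dry_mass_pg = dry_mass_pg,
    mean_density_mg_ml = 1000 * dry_mass_pg / volume_um3,
    n_voxels = n_voxels,
    n_negative_voxels = n_negative_voxels
  ), class = "compartment_quant")
}

#' @export
print.compartment_quant <- function(x, ...) {
  cat(sprintf("%s: V %.1f um^3, M %.2f pg, rho %.1f mg/mL",
              x$label, x$volume_um3, x$dry_mass_pg, x$mean_density_mg_ml))
  if (!is.na(x$n_negative_voxels) && x$n_negative_voxels > 0) {
    cat(sprintf("  [%d sub-background voxels]", x$n_negative_voxels))
  }
  cat("\n")
  invisible(x)
}

#' Tabulate compartment quantifications
#'
#' @param quants List of [compartment_quant()] objects.
#' @param cell_id Identifier recycled into the first column.
#' @return data.frame with columns `cell_id`, `label`, `volume_um3`,
#'   `dry_mass_pg`, `mean_density_mg_ml`.
#' @export
quant_table <- function(quants, cell_id = 1L) {
  if (inherits(quants, "compartment_quant")) quants <- list(quants)
  do.call(rbind, lapply(quants, function(q) {
    data.frame(cell_id = cell_id, label = q$label,
               volume_um3 = q$volume_um3, dry_mass_pg = q$dry_mass_pg,
               mean_density_mg_ml = q$mean_density_mg_ml)
  }))
}

#' Mean density from randomly placed cubic ROIs
#'
#' Emulates the unbiased-ROI protocol: `n_roi` axis-aligned cubes of the
#' stated edge length are placed by seeded rejection sampling fully inside
#' the requested label (so nucleolar voxels, which carry their own label,
#' are excluded automatically), without mutual overlap, and the mean of the
#' ROI mean densities is returned. The species-specific edge length (0.5 µm
#' for yeasts up to 5 µm for C. elegans) is a caller-supplied parameter.
#'
#' @param tom A [tomogram()].
#' @param mask Integer label array matching the tomogram.
#' @param label Label to sample within.
#' @param roi_edge_um Cube edge length, µm.
#' @param n_roi Number of ROIs (default 5).
#' @param seed Integer seed for the placements.
#' @param alpha Refractive-index increment, mL/g.
#' @param z_standoff_um Extra clearance the cube must keep from other
#'   labels along the optical (Z) axis, µm (default 0). Set to about twice
#'   the axial blur sigma to keep ROIs clear of the axial partial-volume
#'   band that limited-angle reconstructions smear across boundaries.
#' @param max_attempts Rejection-sampling budget (default 1e4).
#' @return List with `mean_density_mg_ml` (mean of ROI means) and `rois`, a
#'   data.frame of 0-based corner indices `(z0, y0, x0)`, `edge_vox` and
#'   per-ROI `mean_density_mg_ml`.
#' @export
roi_density_stats <- function(tom, mask, label, roi_edge_um, n_roi = 5,
                              seed = 1,
                              alpha = nd_constants()$alpha_ml_per_g,
                              z_standoff_um = 0,
                              max_attempts = 1e4) {
  stopifnot_scalar(z_standoff_um, "z_standoff_um", nonneg = TRUE)
  s_vox <- as.integer(round(z_standoff_um / tom$voxel_size_um))
  stopifnot(inherits(tom, "tomogram"))
  if (!identical(dim(mask), dim(tom$ri))) {
    stop("`mask` dimensions must match the tomogram", call. = FALSE)
  }
  stopifnot_scalar(roi_edge_um, "roi_edge_um", positive = TRUE)
  edge <- max(1L, as.integer(round(roi_edge_um / tom$voxel_size_um)))
  d <- dim(mask)
  sel <- which(mask == label, arr.ind = TRUE)
  if (nrow(sel) == 0L) {
    stop("empty compartment: no voxel carries label ", label, call. = FALSE)
  }
  ext <- apply(sel, 2, function(i) diff(range(i)) + 1L)
  names(ext) <- c("z", "y", "x")
  if (any(ext < edge)) {
    lim <- names(ext)[which.min(ext)]
    stop(sprintf(
      "region too small for a %d-voxel ROI cube: limiting dimension `%s` spans only %d voxels",
      edge, lim, min(ext)), call. = FALSE)
  }
  lo <- apply(sel, 2, min)
  hi <- apply(sel, 2, max) - edge + 1L

  corners <- matrix(NA_integer_, nrow = 0, ncol = 3)
  with_seed(seed, {
    attempts <- 0L
    while (nrow(corners) < n_roi && attempts < max_attempts) {
      attempts <- attempts + 1L
      c0 <- vapply(1:3, function(k) sample(lo[k]:hi[k], 1L), integer(1))
      z_lo <- c0[1] - s_vox
      z_hi <- c0[1] + edge - 1L + s_vox
      if (z_lo < 1L || z_hi > d[1]) next
      idx_z <- z_lo:z_hi
      idx_y <- c0[2]:(c0[2] + edge - 1L)
      idx_x <- c0[3]:(c0[3] + edge - 1L)
      if (!all(mask[idx_z, idx_y, idx_x] == label)) next
      if (nrow(corners) > 0 &&
          any(apply(corners, 1, function(p) all(abs(p - c0) < edge)))) next
      corners <- rbind(corners, c0)
    }
  })
  if (nrow(corners) < n_roi) {
    stop(sprintf(
      "could not place %d non-overlapping %d-voxel ROIs inside label %s within %d attempts",
      n_roi, edge, as.character(label), as.integer(max_attempts)),
      call. = FALSE)
  }
  roi_mean <- apply(corners, 1, function(c0) {
    cube <- tom$ri[c0[1]:(c0[1] + edge - 1L),
                   c0[2]:(c0[2] + edge - 1L),
                   c0[3]:(c0[3] + edge - 1L)]
    mean(ri_to_density(cube, tom$medium_ri, alpha))
  })
  rois <- data.frame(z0 = corners[, 1] - 1L, y0 = corners[, 2] - 1L,
                     x0 = corners[, 3] - 1L, edge_vox = edge,
                     mean_density_mg_ml = roi_mean)
  list(mean_density_mg_ml = mean(roi_mean), rois = rois)
}

#' Nucleocytoplasmic ratios
#'
#' Computes the three NC ratios as defined by the densitometry:
#' the volume ratio is nuclear volume over cytoplasmic volume
#' (cell volume minus nuclear volume), the density ratio is mean
#' nucleoplasmic over mean cytoplasmic density (nucleoli excluded upstream
#' via the label mask), and the mass ratio is nuclear over cytoplasmic dry
#' mass.
#'
#' @param nuc [compartment_quant()] of the nucleus.
#' @param cyto [compartment_quant()] of the cytoplasm (density and mass).
#' @param cell [compartment_quant()] of the whole cell (volume); defaults
#'   to a synthetic cell combining `nuc` and `cyto`.
#' @return List of class `nc_ratios` with `density_ratio`, `volume_ratio`,
#'   `mass_ratio`.
#' @export
#' @examples
#' nuc <- compartment_quant("nucleus", 558, 51)
#' cyt <- compartment_quant("cytoplasm", 5000, 500)
#' nc_ratios(nuc, cyt)$density_ratio   # 91.4 / 100 = 0.914
nc_ratios <- function(nuc, cyto, cell = NULL) {
  stopifnot(inherits(nuc, "compartment_quant"),
            inherits(cyto, "compartment_quant"))
  if (is.null(cell)) {
    cell <- compartment_quant("cell", nuc$volume_um3 + cyto$volume_um3,
                              nuc$dry_mass_pg + cyto$dry_mass_pg)
  }
  stopifnot(inherits(cell, "compartment_quant"))
  if (cell$volume_um3 <= nuc$volume_um3) {
    stop("cell volume must exceed nuclear volume", call. = FALSE)
  }
  structure(list(
    density_ratio = nuc$mean_density_mg_ml / cyto$mean_density_mg_ml,
    volume_ratio = nuc$volume_um3 / (cell$volume_um3 - nuc$volume_um3),
    mass_ratio = nuc$dry_mass_pg / cyto$dry_mass_pg
  ), class = "nc_ratios")
}

#' Compare two measurement groups
#'
#' Two-sided Mann-Whitney U test (exact where `stats::wilcox.test` can,
#' normal approximation otherwise) plus Cohen's d with the conventional
#' effect-size bands: |d| in 0.20-0.50 small, 0.51-0.80 medium, > 0.80
#' large (below 0.20: negligible).
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2.
#' @return List with `U`, `p_value`, `cohens_d`, `effect_band`.
#' @export
#' @examples
#' compare_groups(c(1, 2, 3), c(4, 5, 6))$U   # 0
compare_groups <- function(values_a, values_b) {
  if (length(values_a) < 2 || length(values_b) < 2) {
    stop("each group needs n >= 2", call. = FALSE)
  }
  wt <- suppressWarnings(stats::wilcox.test(values_a, values_b,
                                            alternative = "two.sided"))
  na <- length(values_a); nb <- length(values_b)
  sp <- sqrt(((na - 1) * stats::var(values_a) +
                (nb - 1) * stats::var(values_b)) / (na + nb - 2))
  dm <- mean(values_a) - mean(values_b)
  d <- if (sp == 0) {
    if (dm == 0) 0 else sign(dm) * Inf
  } else {
    dm / sp
  }
  band <- cohens_d_band(d)
  list(U = unname(wt$statistic), p_value = wt$p.value,
       cohens_d = d, effect_band = band)
}

#' Effect-size band for a Cohen's d value
#'
#' @param d Cohen's d (sign ignored).
#' @return One of "negligible", "small", "medium", "large".
#' @export
cohens_d_band <- function(d) {
  a <- abs(d)
  if (a < 0.20) "negligible"
  else if (a <= 0.50) "small"
  else if (a <= 0.80) "medium"
  else "large"
}
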