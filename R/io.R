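# TIFF float samples are clamped to [0, 1] by the writer, so tomograms are
# stored affinely mapped (ri = offset + scale * stored); the map lives in
# the JSON sidecar and is inverted on read.
.RI_OFFSET <- 1.0
.RI_SCALE <- 0.5

.sidecar_path <- function(path) paste0(path, ".json")

#' Write and read tomograms as multi-page TIFF with a JSON sidecar
#'
#' Stacks are written plane-major: TIFF page `k` is the Z-plane `k`, a
#' `(Y, X)` matrix. Voxel size, medium RI, axis order and the affine
#' storage map of the 32-bit samples are recorded in a JSON sidecar at
#' `<path>.json`; `read_tomogram()` consumes both and reconstructs the
#' [tomogram()] exactly (up to float32 rounding of the RI values).
#'
#' @param tom A [tomogram()].
#' @param path Output TIFF path.
#' @return `write_tomogram()`: the path, invisibly. `read_tomogram()`: a
#'   [tomogram()].
#' @export
write_tomogram <- function(tom, path) {
  stopifnot(inherits(tom, "tomogram"))
  stored <- (tom$ri - .RI_OFFSET) / .RI_SCALE
  if (any(stored < 0) || any(stored > 1)) {
    stop("RI values outside the storable range [",
         .RI_OFFSET, ", ", .RI_OFFSET + .RI_SCALE, "]", call. = FALSE)
  }
  pages <- lapply(seq_len(dim(stored)[1]), function(z) stored[z, , ])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  meta <- list(
    axis_order = "ZYX",
    voxel_size_um = tom$voxel_size_um,
    medium_ri = tom$medium_ri,
    value_offset = .RI_OFFSET,
    value_scale = .RI_SCALE,
    n_planes = dim(tom$ri)[1]
  )
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_tomogram
#' @export
read_tomogram <- function(path) {
  meta <- jsonlite::read_json(.sidecar_path(path), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  stack <- array(0, dim = c(length(pages), nrow(pages[[1]]),
                            ncol(pages[[1]])))
  for (z in seq_along(pages)) stack[z, , ] <- pages[[z]]
  ri <- meta$value_offset + meta$value_scale * stack
  tomogram(ri, meta$voxel_size_um, meta$medium_ri)
}

#' Write and read integer label masks as multi-page TIFF
#'
#' Labels (0 background, 1 cytoplasm, 2 nucleoplasm, 3 nucleolus) are
#' stored as 8-bit samples.
#'
#' @param mask Integer 3D array in (Z, Y, X) order with values in 0..255.
#' @param path Output TIFF path.
#' @return `write_mask()`: the path, invisibly. `read_mask()`: an integer
#'   array.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  if (any(mask < 0) || any(mask > 255)) {
    stop("labels must lie in 0..255", call. = FALSE)
  }
  pages <- lapply(seq_len(dim(mask)[1]), function(z) mask[z, , ] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none")
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  out <- array(0L, dim = c(length(pages), nrow(pages[[1]]),
                           ncol(pages[[1]])))
  for (z in seq_along(pages)) out[z, , ] <- as.integer(round(pages[[z]] * 255))
  out
}
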