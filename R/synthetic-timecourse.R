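#' Generate a synthetic nuclear-assembly observation table
#'
#' Emulates a population time course of reconstituted nuclei: the
#' deterministic pressure-balance trajectory ([simulate_assembly()])
#' evaluated on the time grid, one multiplicative Gaussian perturbation per
#' nucleus, time point and observable (volume and total dry mass; density
#' is recomputed per nucleus as mass over volume), then summarised as mean
#' and SEM (`sd/sqrt(n)`) across nuclei.
#'
#' With `noise_sd = 0` the table equals the deterministic simulation
#' exactly and all SEMs are zero.
#'
#' @param params A [model_params()].
#' @param n_nuclei Number of nuclei (>= 1; the reference experiment pooled
#'   175 at the final time point).
#' @param noise_sd Relative (multiplicative) noise s.d., e.g. 0.05 for 5%
#'   (must be >= 0).
#' @param t_grid Observation times, min.
#' @param seed Integer seed.
#' @param dt Euler step of the underlying simulation, min.
#' @return data.frame with columns `t_min`, `n_nuclei`, `V_mean`, `V_sem`,
#'   `M_mean`, `M_sem`, `rho_mean`, `rho_sem`. `M` is total nuclear dry
#'   mass (imported complexes plus chromatin), pg.
#' @export
#' @examples
#' obs <- make_assembly_timecourse(calibrate_xenopus()$params,
#'                                 n_nuclei = 20, noise_sd = 0.05,
#'                                 t_grid = c(5, 15, 30, 60), seed = 7)
make_assembly_timecourse <- function(params, n_nuclei = 175,
                                     noise_sd = 0.05,
                                     t_grid = c(0, 5, 15, 30, 60),
                                     seed = 1L, dt = 0.1) {
  stopifnot(inherits(params, "model_params"))
  if (!is.numeric(n_nuclei) || length(n_nuclei) != 1L || n_nuclei < 1) {
    stop("`n_nuclei` must be >= 1", call. = FALSE)
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0) {
    stop("`noise_sd` must be >= 0", call. = FALSE)
  }
  traj <- simulate_assembly(params, t_grid, dt = dt)
  nt <- nrow(traj)
  M_tot <- traj$Mp_pg + params$M_chr
  if (noise_sd == 0 || n_nuclei == 1) {
    fV <- matrix(1, n_nuclei, nt)
    fM <- matrix(1, n_nuclei, nt)
  }
  if (noise_sd > 0) {
    fac <- with_seed(seed, stats::rnorm(2 * n_nuclei * nt, 1, noise_sd))
    fV <- matrix(fac[seq_len(n_nuclei * nt)], n_nuclei, nt)
    fM <- matrix(fac[-seq_len(n_nuclei * nt)], n_nuclei, nt)
  }
  V <- sweep(fV, 2, traj$V_um3, `*`)
  M <- sweep(fM, 2, M_tot, `*`)
  rho <- ifelse(V > 0, 1000 * M / V, NA_real_)
  sem <- function(x) {
    if (length(x) < 2) return(0)
    stats::sd(x) / sqrt(length(x))
  }
  data.frame(
    t_min = t_grid,
    n_nuclei = n_nuclei,
    V_mean = colMeans(V), V_sem = apply(V, 2, sem),
    M_mean = colMeans(M), M_sem = apply(M, 2, sem),
    rho_mean = colMeans(rho), rho_sem = apply(rho, 2, sem)
  )
}
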