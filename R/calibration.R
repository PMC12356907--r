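# imported-mass Euler integration shared by simulate_assembly() and the
# fitting loss; returns M_p at the requested times only
.euler_mass <- function(params, t_out, dt) {
  t_end <- max(t_out)
  if (t_end <= 0) return(rep(0, length(t_out)))
  steps <- seq(0, t_end, by = dt)
  if (steps[length(steps)] < t_end) steps <- c(steps, t_end)
  M <- numeric(length(steps))
  if (params$import_enabled) {
    jmax <- params$J0 * (params$genome_bp / params$genome_ref_bp)^params$beta
    for (i in seq_along(steps)[-1]) {
      h <- steps[i] - steps[i - 1]
      if (steps[i - 1] >= params$t_dec) {
        M[i] <- M[i - 1] + h * jmax * max(0, 1 - M[i - 1] / params$M_sat)
      } else {
        M[i] <- M[i - 1]
      }
    }
  }
  stats::approx(steps, M, xout = t_out, rule = 2)$y
}

# model prediction of the observable columns at given times (no data.frame
# overhead; used inside optimisation loops)
.predict_observables <- function(params, t_out, dt = 0.5,
                                 Mp = .euler_mass(params, t_out, dt)) {
  V_dec <- if (params$rho_dec > 0) 1000 * params$M_chr / params$rho_dec else 0
  V_sperm <- if (params$rho_sperm > 0) 1000 * params$M_chr / params$rho_sperm else 0
  cst <- 1 / (params$n_c * 6.02214076e5)
  V_eq <- 1000 * Mp / (params$m_n * params$n_c) + params$N_chr * cst
  V <- pmax(V_dec, V_eq)
  ramp <- t_out < params$t_dec & params$t_dec > 0
  if (any(ramp)) {
    V[ramp] <- V_sperm + (V_dec - V_sperm) * t_out[ramp] / params$t_dec
  }
  M_tot <- Mp + params$M_chr
  rho <- ifelse(V > 0, 1000 * M_tot / V, NA_real_)
  list(V = V, M = M_tot, rho = rho)
}

#' Specify a model fit
#'
#' Describes which parameters of [model_params()] are free (with finite box
#' bounds), which observables enter the loss, and how the optimiser runs.
#' The loss is the sum of SEM-weighted squared residuals over the selected
#' observables; rows with a zero or missing SEM are weighted with the
#' median SEM of their observable.
#'
#' @param free Named list; each element a length-2 numeric `c(lower, upper)`
#'   bound for a free parameter (e.g. `list(J0 = c(0.1, 5))`).
#' @param observables Character subset of `c("V", "M", "rho")` to fit.
#' @param n_starts Number of seeded multi-starts (default 5).
#' @param reltol Optimiser relative tolerance (default 1e-8).
#' @param dt Euler step used inside the loss, min (default 0.5).
#' @param seed Integer seed for the multi-start draws.
#' @return Object of class `fit_spec`.
#' @export
fit_spec <- function(free, observables = c("V", "M", "rho"),
                     n_starts = 5, reltol = 1e-8, dt = 0.5, seed = 1) {
  if (!is.list(free) || length(free) == 0L || is.null(names(free)) ||
      any(names(free) == "")) {
    stop("`free` must be a non-empty named list of c(lower, upper) bounds",
         call. = FALSE)
  }
  for (nm in names(free)) {
    b <- free[[nm]]
    if (!is.numeric(b) || length(b) != 2L || any(!is.finite(b)) ||
        b[1] >= b[2]) {
      stop("bounds for `", nm, "` must be finite with lower < upper",
           call. = FALSE)
    }
  }
  observables <- match.arg(observables, c("V", "M", "rho"),
                           several.ok = TRUE)
  structure(list(free = free, observables = observables,
                 n_starts = n_starts, reltol = reltol, dt = dt,
                 seed = seed),
            class = "fit_spec")
}

.obs_columns <- list(V = c("V_mean", "V_sem"),
                     M = c("M_mean", "M_sem"),
                     rho = c("rho_mean", "rho_sem"))

# SEM weights with the zero/NA -> median-SEM rule
.sem_weights <- function(sem) {
  bad <- !is.finite(sem) | sem <= 0
  if (all(bad)) return(rep(1, length(sem)))
  sem[bad] <- stats::median(sem[!bad])
  sem
}

#' Fit model parameters to an observation table
#'
#' Weighted least squares over a nuclear-assembly observation table (as
#' produced by [make_assembly_timecourse()]): residuals are
#' `(model - observed) / SEM` for each selected observable, the optimiser
#' is a derivative-free Nelder-Mead local search restarted from seeded
#' uniform draws within the bounds, and per-parameter uncertainty comes
#' from a residual bootstrap (refit to data with resampled residuals).
#' Non-convergence is reported in the result, not thrown.
#'
#' @param observations Data.frame with column `t_min` and, per fitted
#'   observable, `<obs>_mean` and `<obs>_sem` columns (`V` in µm³,
#'   `M` total nuclear dry mass in pg, `rho` in mg/mL).
#' @param spec A [fit_spec()].
#' @param params Baseline [model_params()]; free parameters are overridden
#'   during the search, the rest stay fixed.
#' @param n_boot Number of residual-bootstrap refits (default 30; 0 skips
#'   the bootstrap).
#' @return List of class `nd_fit` with elements `par` (named fitted
#'   values), `loss`, `converged`, `boot` (matrix of bootstrap estimates or
#'   `NULL`), `se`, `ci` (2.5/97.5% bootstrap percentiles), `residuals`.
#' @export
fit_model <- function(observations, spec, params = model_params(),
                      n_boot = 30) {
  stopifnot(inherits(spec, "fit_spec"), inherits(params, "model_params"))
  if (!is.data.frame(observations) || !("t_min" %in% names(observations))) {
    stop("`observations` must be a data.frame with a `t_min` column",
         call. = FALSE)
  }
  used <- spec$observables[vapply(spec$observables, function(o) {
    all(.obs_columns[[o]] %in% names(observations))
  }, logical(1))]
  if (length(used) == 0L) {
    stop("no fitted observable has its columns in `observations`",
         call. = FALSE)
  }
  n_info <- nrow(observations) * length(used)
  if (n_info < length(spec$free)) {
    stop("need at least as many informative observations (", n_info,
         ") as free parameters (", length(spec$free), ")", call. = FALSE)
  }

  t_out <- observations$t_min
  y <- unlist(lapply(used, function(o) observations[[.obs_columns[[o]][1]]]))
  w <- unlist(lapply(used, function(o) {
    .sem_weights(observations[[.obs_columns[[o]][2]]])
  }))

  nms <- names(spec$free)
  lower <- vapply(spec$free, `[`, 0, 1)
  upper <- vapply(spec$free, `[`, 0, 2)

  predict_vec <- function(theta) {
    p <- params
    p[nms] <- as.list(theta)
    pr <- .predict_observables(p, t_out, dt = spec$dt)
    unlist(pr[used], use.names = FALSE)
  }
  make_loss <- function(target) {
    function(theta) {
      if (any(theta < lower) || any(theta > upper)) {
        return(1e10 * (1 + sum(pmax(0, lower - theta) + pmax(0, theta - upper))))
      }
      sum(((predict_vec(theta) - target) / w)^2)
    }
  }

  run_search <- function(target, starts) {
    loss <- make_loss(target)
    best <- NULL
    conv <- FALSE
    for (s in seq_len(nrow(starts))) {
      res <- if (length(nms) == 1L) {
        o <- stats::optimize(function(x) loss(x), lower = lower, upper = upper,
                             tol = max(spec$reltol, 1e-10) * (upper - lower))
        list(par = o$minimum, value = o$objective, convergence = 0L)
      } else {
        stats::optim(starts[s, ], loss, method = "Nelder-Mead",
                     control = list(reltol = spec$reltol, maxit = 2000))
      }
      if (is.null(best) || res$value < best$value) best <- res
      if (res$convergence == 0L) conv <- TRUE
    }
    list(par = stats::setNames(best$par, nms), value = best$value,
         converged = conv)
  }

  starts <- with_seed(spec$seed, {
    matrix(stats::runif(spec$n_starts * length(nms), rep(lower, each = spec$n_starts),
                        rep(upper, each = spec$n_starts)),
           nrow = spec$n_starts)
  })
  main <- run_search(y, starts)
  fitted_y <- predict_vec(main$par)
  resid <- y - fitted_y

  boot <- NULL
  if (n_boot > 0) {
    boot <- with_seed(spec$seed + 1L, {
      t(vapply(seq_len(n_boot), function(b) {
        ystar <- fitted_y + sample(resid, replace = TRUE)
        run_search(ystar, matrix(main$par, nrow = 1))$par
      }, stats::setNames(numeric(length(nms)), nms)))
    })
  }

  structure(list(
    par = main$par,
    loss = main$value,
    converged = main$converged,
    boot = boot,
    se = if (!is.null(boot)) apply(boot, 2, stats::sd) else NULL,
    ci = if (!is.null(boot)) {
      apply(boot, 2, stats::quantile, probs = c(0.025, 0.975))
    } else NULL,
    residuals = resid,
    observables = used
  ), class = "nd_fit")
}

#' @export
print.nd_fit <- function(x, ...) {
  cat("Pressure-balance model fit (",
      if (x$converged) "converged" else "NOT converged", ")\n", sep = "")
  est <- x$par
  if (!is.null(x$se)) {
    for (nm in names(est)) {
      cat(sprintf("  %-8s %.4g +/- %.3g\n", nm, est[[nm]], x$se[[nm]]))
    }
  } else {
    print(est)
  }
  cat(sprintf("  loss %.4g over %s\n", x$loss,
              paste(x$observables, collapse = ", ")))
  invisible(x)
}

#' Closed-form Xenopus calibration from printed anchors
#'
#' Chains the measured 60-min anchors into a fully determined parameter
#' set:
#' \enumerate{
#'   \item `V60 = 1000 * M_tot / rho_n` (µm³);
#'   \item `M_chr` from the genome via [chromatin_mass()];
#'   \item `M_p = M_tot - M_chr`;
#'   \item `n_c = rho_c / m_c`;
#'   \item `N_chr = (V60 - 1000 M_p/(m_n n_c)) * n_c * 6.022e5` — the
#'     chromatin particle count that closes the pressure balance at the
#'     observed volume;
#'   \item `J0 = -M_sat/(t_ref - t_dec) * log(1 - M_p/M_sat)` — the flux
#'     that carries the saturating pool to `M_p` by `t_ref`.
#' }
#' Inconsistent anchors (a negative implied `N_chr`, or `M_p >= M_sat`)
#' raise an error with a diagnostic.
#'
#' @param M_tot Total nuclear dry mass at `t_ref`, pg (default 51).
#' @param rho_n Nuclear density at `t_ref`, mg/mL (default 91.4).
#' @param rho_c Cytoplasmic density, mg/mL (default 100).
#' @param m_n,m_c Mean complex masses, kDa (defaults 131.1 and 155.8).
#' @param chromatin A [chromatin_spec()] (default 3.1e9 bp, kappa 4).
#' @param M_sat Saturating imported mass, pg (default 60).
#' @param t_ref Reference time of the anchors, min (default 60).
#' @param t_dec Decondensation end, min (default 5).
#' @param beta Genome-size import exponent (default 0.56).
#' @return List with `params` (a [model_params()]), the intermediate
#'   quantities `V60`, `M_chr`, `M_p_60`, `N_chr`, `n_c`, and `bookkeeping`
#'   (the [osmotic_report()] row).
#' @export
#' @examples
#' cal <- calibrate_xenopus()
#' cal$V60      # ~558 um^3
#' cal$N_chr    # ~4.3e7
calibrate_xenopus <- function(M_tot = 51, rho_n = 91.4, rho_c = 100,
                              m_n = 131.1, m_c = 155.8,
                              chromatin = chromatin_spec(3.1e9),
                              M_sat = 60, t_ref = 60, t_dec = 5,
                              beta = 0.56) {
  stopifnot_scalar(M_tot, "M_tot", positive = TRUE)
  stopifnot_scalar(rho_n, "rho_n", positive = TRUE)
  V60 <- 1000 * M_tot / rho_n
  M_chr <- chromatin_mass(chromatin)
  M_p <- nuclear_protein_mass(M_tot, M_chr)
  n_c <- complex_concentration(rho_c, m_c)
  N_chr <- (V60 - 1000 * M_p / (m_n * n_c)) * n_c *
    nd_constants()$particles_per_um3_per_mM
  if (N_chr < 0) {
    stop(sprintf(paste0(
      "inconsistent anchors: implied chromatin particle count is negative ",
      "(N_chr = %.3g). The protein-only volume %.1f um^3 already exceeds ",
      "the observed V60 = %.1f um^3; check rho_n vs rho_c or kappa."),
      N_chr, 1000 * M_p / (m_n * n_c), V60), call. = FALSE)
  }
  if (M_p >= M_sat) {
    stop(sprintf("anchors need M_p (%.1f pg) < M_sat (%.1f pg) for a %s",
                 M_p, M_sat, "saturating import pool"), call. = FALSE)
  }
  J0 <- -M_sat / (t_ref - t_dec) * log(1 - M_p / M_sat)
  params <- model_params(
    m_n = m_n, m_c = m_c, rho_c = rho_c, n_c = n_c,
    M_chr = M_chr, N_chr = N_chr,
    genome_bp = chromatin$genome_bp, genome_ref_bp = chromatin$genome_bp,
    J0 = J0, M_sat = M_sat, t_dec = t_dec, beta = beta
  )
  list(params = params, V60 = V60, M_chr = M_chr, M_p_60 = M_p,
       N_chr = N_chr, n_c = n_c,
       bookkeeping = osmotic_report(M_tot, rho_n, rho_c, m_n, m_c,
                                    chromatin))
}
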