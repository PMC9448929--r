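#' Draw oscillator natural frequencies
#'
#' Frequencies are sampled from a normal distribution in Hz (default mean
#' 60 Hz, sd 1 Hz) and returned as angular frequencies in rad/s.
#'
#' @param n number of oscillators.
#' @param mean_hz,sd_hz normal distribution parameters in Hz.
#' @return Numeric vector `omega` (rad/s).
#' @export
draw_frequencies <- function(n, mean_hz = 60, sd_hz = 1) {
  stopifnot(n >= 1)
  2 * pi * stats::rnorm(n, mean = mean_hz, sd = sd_hz)
}

#' Draw initial oscillator phases
#'
#' @param n number of oscillators.
#' @return Phases uniform on `[0, 2*pi)` (radians).
#' @export
draw_initial_phases <- function(n) {
  stopifnot(n >= 1)
  stats::runif(n, 0, 2 * pi)
}

#' Instantaneous order parameter
#'
#' Magnitude and angle of the mean unit phasor
#' `r e^{i phi} = (1/N) sum_j e^{i theta_j}`.
#'
#' @param phases numeric vector of phases (radians).
#' @return List with `r` in `[0, 1]` and mean phase `phi`.
#' @export
order_parameter <- function(phases) {
  stopifnot(length(phases) >= 1)
  z <- mean(exp(1i * phases))
  list(r = Mod(z), phi = Arg(z))
}

#' Simulate the Kuramoto model on a coupling matrix
#'
#' Integrates `dtheta_j/dt = omega_j + K * sum_h C_jh sin(theta_h - theta_j)`
#' with classical 4th-order Runge-Kutta, recording the order parameter at
#' fixed intervals.
#'
#' @param C symmetric nonnegative coupling matrix, zero diagonal (see
#'   [normalize_for_km()]).
#' @param omega angular frequencies (rad/s).
#' @param theta0 initial phases (radians).
#' @param K global coupling strength.
#' @param T total simulated time (s).
#' @param dt integration step (s); an error is raised if the step is too
#'   large for the fastest phase velocity (`dt * max|dtheta/dt| > 0.1` rad).
#' @param record_every sampling interval for `r(t)` (s).
#' @param burn_in transient interval excluded by [summarize_trace()] (s);
#'   defaults to the first fifth of the simulation (20 s of the default
#'   100 s).
#' @return A `km_trace`: list with `t`, `r`, `phi`, `dt`, `burn_in`,
#'   `theta_final`.
#' @export
simulate_km <- function(C, omega, theta0, K, T = 100, dt = 1e-4,
                        record_every = 1e-3, burn_in = T / 5) {
  n <- length(omega)
  stopifnot(is.matrix(C), nrow(C) == n, ncol(C) == n, length(theta0) == n,
            K >= 0, T > 0, dt > 0, record_every >= dt, T >= burn_in)
  max_rate <- max(abs(omega)) + K * max(rowSums(C))
  if (dt * max_rate > 0.1)
    stop(sprintf(
      "stability error: dt = %.3g too large (dt * max|dtheta/dt| = %.3g > 0.1 rad)",
      dt, dt * max_rate))
  n_steps <- round(T / dt)
  stride <- max(1L, as.integer(round(record_every / dt)))
  res <- km_integrate(C, omega, theta0, K, as.integer(n_steps), dt, stride)
  structure(list(t = as.numeric(res$t), r = as.numeric(res$r),
                 phi = as.numeric(res$phi), dt = dt, burn_in = burn_in,
                 theta_final = as.numeric(res$theta_final)),
            class = "km_trace")
}

#' Synchrony and metastability of a trace
#'
#' Synchrony is the time-mean of the order parameter `r(t)` after burn-in;
#' metastability is its standard deviation (population form) over the same
#' window.
#'
#' @param trace a `km_trace` from [simulate_km()].
#' @param burn_in override of the trace's burn-in (s).
#' @return List with `synchrony` and `metastability`.
#' @export
summarize_trace <- function(trace, burn_in = trace$burn_in) {
  stopifnot(inherits(trace, "km_trace"))
  keep <- trace$t > burn_in
  if (!any(keep)) stop("validation error: empty post-burn-in window")
  r <- trace$r[keep]
  list(synchrony = mean(r),
       metastability = sqrt(mean((r - mean(r))^2)))
}

#' Critical couplings from a synchrony/metastability grid
#'
#' @param K_grid ascending coupling grid.
#' @param synchrony,metastability per-K values.
#' @return List with `Kcrit_syn` (first K whose synchrony is within 10% of
#'   the grid maximum), `Kcrit_mts` (K of maximum metastability, first on
#'   ties) and `auc_synchrony` (trapezoidal area of synchrony over K).
#' @export
critical_couplings <- function(K_grid, synchrony, metastability) {
  stopifnot(length(K_grid) == length(synchrony),
            length(K_grid) == length(metastability),
            all(diff(K_grid) > 0))
  list(Kcrit_syn = K_grid[which(synchrony >= 0.9 * max(synchrony))[1L]],
       Kcrit_mts = K_grid[which.max(metastability)],
       auc_synchrony = trapezoid(K_grid, synchrony))
}

#' Sweep coupling strength for one subject
#'
#' Normalizes the subject's SC into a coupling matrix (mean off-diagonal 1),
#' draws frequencies and initial phases once per replicate (held fixed across
#' the whole K grid), simulates at every K, and averages synchrony and
#' metastability over replicates before locating the critical couplings.
#'
#' @param cm a [connectome] (or a precomputed coupling matrix via `C`).
#' @param K_grid ascending coupling grid (default 0 to 2 by 0.05).
#' @param T,dt,record_every,burn_in simulation settings, see [simulate_km()].
#' @param seed integer seed; replicate draws derive from it.
#' @param n_reps replicates with independent frequency/phase draws.
#' @param C optional coupling matrix overriding `normalize_for_km(cm)`
#'   (used for lesioned matrices that must keep their pre-lesion scale).
#' @param mean_hz,sd_hz frequency distribution (Hz).
#' @return A `coupling_sweep`: list with `subject_id`, `K_grid`, `synchrony`,
#'   `metastability`, `Kcrit_syn`, `Kcrit_mts`, `auc_synchrony`, `n_reps`.
#' @export
coupling_sweep <- function(cm, K_grid = seq(0, 2, by = 0.05), T = 100,
                           dt = 1e-4, record_every = 1e-3, burn_in = T / 5,
                           seed = 1L, n_reps = 3L, C = NULL,
                           mean_hz = 60, sd_hz = 1) {
  stopifnot(all(diff(K_grid) > 0), n_reps >= 1)
  if (is.null(C)) C <- normalize_for_km(cm)
  n <- nrow(C)
  syn <- mts <- matrix(NA_real_, n_reps, length(K_grid))
  for (rep in seq_len(n_reps)) {
    pars <- with_seed(derive_seed(seed, rep, salt = 101L), {
      list(omega = draw_frequencies(n, mean_hz, sd_hz),
           theta0 = draw_initial_phases(n))
    })
    for (ki in seq_along(K_grid)) {
      tr <- simulate_km(C, pars$omega, pars$theta0, K_grid[ki], T = T,
                        dt = dt, record_every = record_every,
                        burn_in = burn_in)
      sm <- summarize_trace(tr)
      syn[rep, ki] <- sm$synchrony
      mts[rep, ki] <- sm$metastability
    }
  }
  synchrony <- colMeans(syn)
  metastability <- colMeans(mts)
  crit <- critical_couplings(K_grid, synchrony, metastability)
  structure(c(list(subject_id = if (inherits(cm, "connectome")) cm$subject_id
                   else "matrix",
                   K_grid = K_grid, synchrony = synchrony,
                   metastability = metastability, n_reps = n_reps),
              crit),
            class = "coupling_sweep")
}

#' @export
print.coupling_sweep <- function(x, ...) {
  cat(sprintf(
    "<coupling_sweep> %s: K in [%g, %g] (%d points), Kcrit_syn = %g, Kcrit_mts = %g, AUC = %.3f\n",
    x$subject_id, min(x$K_grid), max(x$K_grid), length(x$K_grid),
    x$Kcrit_syn, x$Kcrit_mts, x$auc_synchrony))
  invisible(x)
}

#' Sweep coupling for a population
#'
#' @param population list of [connectome] objects.
#' @param ... passed to [coupling_sweep()]; per-subject seeds derive from
#'   `seed` and the subject position.
#' @param seed master seed.
#' @return Data frame with one row per subject: subject_id, Kcrit_syn,
#'   Kcrit_mts, auc_synchrony, plus a `sweeps` attribute holding the full
#'   `coupling_sweep` objects.
#' @export
population_sweeps <- function(population, seed = 1L, ...) {
  sweeps <- lapply(seq_along(population), function(i)
    coupling_sweep(population[[i]], seed = derive_seed(seed, i, salt = 7L), ...))
  out <- data.frame(
    subject_id = vapply(sweeps, `[[`, character(1), "subject_id"),
    Kcrit_syn = vapply(sweeps, `[[`, numeric(1), "Kcrit_syn"),
    Kcrit_mts = vapply(sweeps, `[[`, numeric(1), "Kcrit_mts"),
    auc_synchrony = vapply(sweeps, `[[`, numeric(1), "auc_synchrony"))
  attr(out, "sweeps") <- sweeps
  out
}
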