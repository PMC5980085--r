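# Persistent random deformation (PRD) model simulator.
#
# Shape modes evolve under restoring forces, motion-shape couplings and
# red-noise (Ornstein-Uhlenbeck) force multipoles:
#   dC2/dt = -kappa2 C2 - alpha2 conj(v1) C3 + F2
#   dC3/dt = -K3 C3 - alpha3 v1 C2 + beta3 conj(C3) F6 + F3,
#     K3 = kappa3 + gamma3 |C3|^2
#   dF_i/dt = kappa_f (-F_i + sigma_i xi_i)          (red noise, i = 2, 3, 6)
#   Gamma_v v1 = alpha_v conj(v1) C2
#                + beta1 conj(dC2/dt) C3 - beta2 conj(C2) dC3/dt,
#     Gamma_v = 1 + gamma_v |C2|^2.
# Because dC2/dt and dC3/dt themselves contain v1, the velocity equation is a
# conjugate-linear 2x2 system in (v1, conj(v1)); solve_velocity() uses its
# closed-form solution. Integration is Euler / Euler-Maruyama at dt = 0.5 min,
# sampled every 5 min with additive Gaussian observation noise, then smoothed
# and differenced exactly like the experimental pipeline.

#' PRD model parameters
#'
#' Constructor for the full parameter set of the PRD model. Units: mobilities
#' `beta1`, `beta2` and couplings `alpha_v`, `alpha2`, `alpha3`, `beta3` in
#' per micrometre; relaxation rates `kappa2`, `kappa3`, `kappa_f` in per
#' hour; nonlinear dampings `gamma_v` in per micrometre squared and `gamma3`
#' in per micrometre squared per hour; noise scales `sigma2`, `sigma3`,
#' `sigma6` in micrometres per hour; mean radius `r0` in micrometres.
#'
#' @param beta1,beta2 Mobility coefficients of the migration law.
#' @param kappa2,kappa3 Shape relaxation rates of modes 2 and 3.
#' @param sigma2,sigma3,sigma6 Red-noise force scales for F2, F3, F6.
#' @param kappa_f Cut-off rate of the red-noise forces.
#' @param alpha_v Velocity-elongation coupling (moves cells along the long
#'   axis for `alpha_v > 0`).
#' @param gamma_v Nonlinear damping bounding the velocity amplification.
#' @param alpha2,alpha3 Shape change due to motion.
#' @param gamma3 Nonlinear damping of the triangular mode.
#' @param beta3 Multiplicative coupling of C3 to the force hexapole F6
#'   (source of the exponential tail of the C3 distribution).
#' @param r0 Mean cell radius.
#' @return A list of class `prd_params`.
#' @seealso [prd_preset()] for the calibrated per-substrate parameter sets.
#' @export
prd_params <- function(beta1, beta2, kappa2, kappa3, sigma2, sigma3,
                       sigma6 = 0.25 * sigma3, kappa_f = 0.75,
                       alpha_v = 0.5, gamma_v = 0.0669,
                       alpha2 = 0.01, alpha3 = 0.01,
                       gamma3 = 0.3, beta3 = 0.3, r0 = 23.9) {
  p <- list(
    beta1 = beta1, beta2 = beta2, kappa2 = kappa2, kappa3 = kappa3,
    sigma2 = sigma2, sigma3 = sigma3, sigma6 = sigma6, kappa_f = kappa_f,
    alpha_v = alpha_v, gamma_v = gamma_v, alpha2 = alpha2, alpha3 = alpha3,
    gamma3 = gamma3, beta3 = beta3, r0 = r0
  )
  if (any(!vapply(p, is.numeric, TRUE))) abort("all parameters must be numeric.")
  if (kappa2 <= 0 || kappa3 <= 0 || kappa_f <= 0) {
    abort("`kappa2`, `kappa3`, `kappa_f` must be positive.")
  }
  if (gamma_v < 0 || gamma3 < 0 || sigma2 < 0 || sigma3 < 0 || sigma6 < 0) {
    abort("dampings and noise scales must be non-negative.")
  }
  structure(p, class = "prd_params")
}

#' @export
print.prd_params <- function(x, ...) {
  cat("<prd_params>\n")
  cat(sprintf(
    "  law:    beta1 = %.3g, beta2 = %.3g um^-1\n", x$beta1, x$beta2
  ))
  cat(sprintf(
    "  shape:  kappa2 = %.3g, kappa3 = %.3g h^-1; gamma3 = %.3g; beta3 = %.3g\n",
    x$kappa2, x$kappa3, x$gamma3, x$beta3
  ))
  cat(sprintf(
    "  force:  sigma2 = %.3g, sigma3 = %.3g, sigma6 = %.3g um/h; kappa_f = %.3g h^-1\n",
    x$sigma2, x$sigma3, x$sigma6, x$kappa_f
  ))
  cat(sprintf(
    "  motion: alpha_v = %.3g, gamma_v = %.3g, alpha2 = %.3g, alpha3 = %.3g; R0 = %.3g um\n",
    x$alpha_v, x$gamma_v, x$alpha2, x$alpha3, x$r0
  ))
  invisible(x)
}

#' Calibrated PRD parameter presets
#'
#' Parameter sets for the three gel stiffnesses. The mobility, relaxation and
#' non-dimensional force values are the published per-substrate estimates
#' (`sigma_n` back-computed from `sigma_n / (R0 kappa_n)` with the printed
#' mean radius); the remaining coefficients (`alpha_v`, `gamma_v`, `alpha2`,
#' `alpha3`, `gamma3`, `beta3`, `kappa_f`, `sigma6`) are this package's
#' calibrated defaults, chosen once so that the simulated ensembles
#' reproduce the qualitative statistics of crawling fibroblasts
#' (exponential-tailed velocity distribution, shape-autocorrelation times of
#' a few hours, back-and-forth motion). See the methods vignette.
#'
#' @param name One of `"table2_35kPa"`, `"table2_120kPa"`, `"table2_410kPa"`.
#' @param ... Named overrides passed to [prd_params()].
#' @return A `prd_params` object.
#' @export
prd_preset <- function(name = c("table2_35kPa", "table2_120kPa", "table2_410kPa"),
                       ...) {
  name <- match.arg(name)
  base <- switch(name,
    table2_35kPa = list(
      beta1 = 1.21, beta2 = 0.24, kappa2 = 0.38, kappa3 = 1.55,
      r0 = 23.9, nd2 = 0.66, nd3 = 0.026
    ),
    table2_120kPa = list(
      beta1 = 0.83, beta2 = 0.15, kappa2 = 0.40, kappa3 = 1.11,
      r0 = 26.6, nd2 = 0.64, nd3 = 0.036
    ),
    table2_410kPa = list(
      beta1 = 0.59, beta2 = 0.07, kappa2 = 0.40, kappa3 = 0.51,
      r0 = 27.2, nd2 = 0.67, nd3 = 0.076
    )
  )
  args <- list(
    beta1 = base$beta1, beta2 = base$beta2,
    kappa2 = base$kappa2, kappa3 = base$kappa3,
    sigma2 = base$nd2 * base$r0 * base$kappa2,
    sigma3 = base$nd3 * base$r0 * base$kappa3,
    r0 = base$r0
  )
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(prd_params, args)
}

#' Simulation configuration
#'
#' @param dt_min Integration step in minutes (default 0.5).
#' @param sample_min Observation sampling interval in minutes (default 5);
#'   must be a multiple of `dt_min`.
#' @param duration_h Recorded duration per cell in hours; scalar or one value
#'   per cell. Must be at least `min_duration_h` (the analysis inclusion
#'   filter).
#' @param n_cells Number of independent cells.
#' @param sigma0_um Observation-noise standard deviation added to positions
#'   and to the real and imaginary part of each sampled mode (micrometres).
#' @param burnin_h Burn-in integrated from the zero state and discarded
#'   before recording (default 5 h), so recorded series are stationary.
#' @param seed Master seed; each cell uses an independent substream derived
#'   from it.
#' @param velocity_scheme `"self-consistent"` (exact conjugate-linear solve
#'   each step) or `"lagged"` (previous step's velocity in the couplings).
#' @param min_duration_h Minimum analysable duration (default 8.3 h).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(dt_min = 0.5, sample_min = 5, duration_h = 16,
                       n_cells = 1, sigma0_um = 1, burnin_h = 5, seed = 1,
                       velocity_scheme = c("self-consistent", "lagged"),
                       min_duration_h = 8.3) {
  velocity_scheme <- match.arg(velocity_scheme)
  if (dt_min <= 0 || sample_min < dt_min) {
    abort("need 0 < dt_min <= sample_min.")
  }
  if (abs(sample_min / dt_min - round(sample_min / dt_min)) > 1e-9) {
    abort("`sample_min` must be a multiple of `dt_min`.")
  }
  if (any(duration_h < min_duration_h)) {
    abort(sprintf(
      "`duration_h` below the minimum analysable duration (%g h).",
      min_duration_h
    ))
  }
  if (n_cells < 1) abort("`n_cells` must be >= 1.")
  if (!(length(duration_h) %in% c(1L, n_cells))) {
    abort("`duration_h` must be scalar or length `n_cells`.")
  }
  structure(
    list(
      dt_min = dt_min, sample_min = sample_min, duration_h = duration_h,
      n_cells = as.integer(n_cells), sigma0_um = sigma0_um,
      burnin_h = burnin_h, seed = as.integer(seed),
      velocity_scheme = velocity_scheme, min_duration_h = min_duration_h
    ),
    class = "sim_config"
  )
}

#' One Euler-Maruyama step of a red-noise force multipole
#'
#' `F' = F - kappa_f * F * dt + kappa_f * sigma * xi * sqrt(dt)` with
#' `xi = xi_x + i xi_y` built from independent standard normal draws. The
#' stationary per-component standard deviation is `sigma * sqrt(kappa_f / 2)`.
#'
#' @param f Complex force value(s).
#' @param kappa_f Cut-off rate (per hour).
#' @param sigma Noise scale (micrometres per hour).
#' @param dt_h Step in hours.
#' @param xi Complex standard-normal draw(s) (`rnorm() + 1i * rnorm()`).
#' @return Updated complex force.
#' @export
step_force <- function(f, kappa_f, sigma, dt_h, xi) {
  f - kappa_f * f * dt_h + kappa_f * sigma * xi * sqrt(dt_h)
}

#' Self-consistent velocity solve
#'
#' The velocity equation contains `dC2/dt` and `dC3/dt`, which themselves
#' contain `v1`; substituting the evolution equations yields the
#' conjugate-linear system `A v1 - alpha_v C2 conj(v1) = b` with
#' `A = Gamma_v + beta1 alpha2 |C3|^2 - beta2 alpha3 |C2|^2` and
#' `b = beta1 (-kappa2 conj(C2) + conj(F2)) C3
#'      - beta2 conj(C2) (-K3 C3 + beta3 conj(C3) F6 + F3)`,
#' solved in closed form as
#' `v1 = (A b + alpha_v C2 conj(b)) / (A^2 - alpha_v^2 |C2|^2)`.
#'
#' @param state List with complex components `C2`, `C3`, `F2`, `F3`, `F6`
#'   (vectors are accepted and treated element-wise).
#' @param params A [prd_params()] object.
#' @return Complex velocity `v1` (micrometres per hour).
#' @export
solve_velocity <- function(state, params) {
  .solve_v(state$C2, state$C3, state$F2, state$F3, state$F6, params)
}

.solve_v <- function(C2, C3, F2, F3, F6, p) {
  m2 <- Mod(C2)^2
  m3 <- Mod(C3)^2
  K3 <- p$kappa3 + p$gamma3 * m3
  A <- 1 + p$gamma_v * m2 + p$beta1 * p$alpha2 * m3 - p$beta2 * p$alpha3 * m2
  b <- p$beta1 * (-p$kappa2 * Conj(C2) + Conj(F2)) * C3 -
    p$beta2 * Conj(C2) * (-K3 * C3 + p$beta3 * Conj(C3) * F6 + F3)
  den <- A^2 - p$alpha_v^2 * m2
  if (any(abs(den) < 1e-10)) {
    i <- which(abs(den) < 1e-10)[1L]
    abort(sprintf(
      "Singular velocity solve (|A^2 - alpha_v^2 |C2|^2| < 1e-10) at |C2| = %.3f, |C3| = %.3f: unstable parameters.",
      sqrt(m2[i]), sqrt(m3[i])
    ))
  }
  (A * b + p$alpha_v * C2 * Conj(b)) / den
}

.lagged_v <- function(C2, C3, F2, F3, F6, v_prev, p) {
  K3 <- p$kappa3 + p$gamma3 * Mod(C3)^2
  dC2 <- -p$kappa2 * C2 - p$alpha2 * Conj(v_prev) * C3 + F2
  dC3 <- -K3 * C3 - p$alpha3 * v_prev * C2 + p$beta3 * Conj(C3) * F6 + F3
  gv <- 1 + p$gamma_v * Mod(C2)^2
  (p$alpha_v * Conj(v_prev) * C2 +
    p$beta1 * Conj(dC2) * C3 - p$beta2 * Conj(C2) * dC3) / gv
}

#' One integration step of the PRD model
#'
#' Per step: (1) advance the three force multipoles by [step_force()];
#' (2) obtain `v1` (self-consistent solve, or the lagged scheme which uses
#' the previous step's velocity in the couplings); (3) evaluate the mode
#' evolution equations; (4) Euler-update `C2`, `C3` and the position.
#'
#' @param state List with complex components `x` (position `x + i y`), `C2`,
#'   `C3`, `F2`, `F3`, `F6`, `v1` and numeric `t_h`; components may be
#'   vectors (one entry per cell).
#' @param params A [prd_params()] object.
#' @param dt_h Step in hours.
#' @param xi Complex standard-normal draws for (F2, F3, F6): a length-3
#'   vector, or an `n_cells x 3` matrix.
#' @param scheme `"self-consistent"` or `"lagged"`.
#' @return The updated state list.
#' @export
step_cell <- function(state, params, dt_h, xi,
                      scheme = c("self-consistent", "lagged")) {
  scheme <- match.arg(scheme)
  if (is.null(dim(xi))) xi <- matrix(xi, nrow = 1L)
  st <- .prd_step(state, params, dt_h, xi[, 1L], xi[, 2L], xi[, 3L], scheme)
  if (any(!is.finite(c(Re(st$C2), Re(st$C3), Re(st$v1))))) {
    abort(sprintf(
      "Divergent PRD state at t = %.3f h; check parameter stability.", st$t_h
    ))
  }
  st
}

.prd_step <- function(st, p, dt_h, xi2, xi3, xi6, scheme) {
  F2 <- step_force(st$F2, p$kappa_f, p$sigma2, dt_h, xi2)
  F3 <- step_force(st$F3, p$kappa_f, p$sigma3, dt_h, xi3)
  F6 <- step_force(st$F6, p$kappa_f, p$sigma6, dt_h, xi6)
  C2 <- st$C2
  C3 <- st$C3
  if (scheme == "self-consistent") {
    v <- .solve_v(C2, C3, F2, F3, F6, p)
    vc <- v
  } else {
    v <- .lagged_v(C2, C3, F2, F3, F6, st$v1, p)
    vc <- st$v1 # couplings reuse the previous velocity
  }
  K3 <- p$kappa3 + p$gamma3 * Mod(C3)^2
  dC2 <- -p$kappa2 * C2 - p$alpha2 * Conj(vc) * C3 + F2
  dC3 <- -K3 * C3 - p$alpha3 * vc * C2 + p$beta3 * Conj(C3) * F6 + F3
  list(
    t_h = st$t_h + dt_h,
    x = st$x + v * dt_h,
    C2 = C2 + dC2 * dt_h,
    C3 = C3 + dC3 * dt_h,
    F2 = F2, F3 = F3, F6 = F6,
    v1 = v
  )
}

#' Low-level PRD integration with a supplied noise path
#'
#' Integrates the PRD equations for a fixed array of standard-normal draws,
#' recording every `record_every` steps (the initial state included). Used
#' by [simulate_cells()] and directly useful for frozen-noise experiments
#' (step-size refinement, rotational-equivariance checks).
#'
#' @param params A [prd_params()] object.
#' @param xi Complex array of dimension `(n_steps, n_cells, 3)` holding the
#'   standard-normal draws for F2, F3, F6.
#' @param dt_h Step in hours.
#' @param init Optional initial state as in [step_cell()] (default zeros).
#' @param scheme Velocity scheme.
#' @param record_every Record interval in steps.
#' @return A list of complex matrices `x`, `C2`, `C3`, `v1` (rows = recorded
#'   times, columns = cells) plus the numeric vector `t_h` of recorded times
#'   and the final `state`.
#' @export
prd_integrate <- function(params, xi, dt_h, init = NULL,
                          scheme = c("self-consistent", "lagged"),
                          record_every = 1L) {
  scheme <- match.arg(scheme)
  if (length(dim(xi)) != 3L || dim(xi)[3L] != 3L) {
    abort("`xi` must be a complex array (n_steps, n_cells, 3).")
  }
  n_steps <- dim(xi)[1L]
  nc <- dim(xi)[2L]
  zero <- complex(nc)
  st <- list(
    t_h = 0, x = zero, C2 = zero, C3 = zero,
    F2 = zero, F3 = zero, F6 = zero, v1 = zero
  )
  if (!is.null(init)) st[names(init)] <- init
  n_rec <- n_steps %/% record_every + 1L
  rec <- list(
    x = matrix(NA_complex_, n_rec, nc), C2 = matrix(NA_complex_, n_rec, nc),
    C3 = matrix(NA_complex_, n_rec, nc), v1 = matrix(NA_complex_, n_rec, nc)
  )
  t_h <- numeric(n_rec)
  rec$x[1L, ] <- st$x
  rec$C2[1L, ] <- st$C2
  rec$C3[1L, ] <- st$C3
  rec$v1[1L, ] <- st$v1
  r <- 1L
  for (k in seq_len(n_steps)) {
    st <- .prd_step(st, params, dt_h, xi[k, , 1L], xi[k, , 2L], xi[k, , 3L], scheme)
    if (k %% record_every == 0L) {
      r <- r + 1L
      rec$x[r, ] <- st$x
      rec$C2[r, ] <- st$C2
      rec$C3[r, ] <- st$C3
      rec$v1[r, ] <- st$v1
      t_h[r] <- st$t_h
      if (any(!is.finite(Re(st$C2))) || any(!is.finite(Re(st$C3)))) {
        abort(sprintf(
          "Divergent PRD trajectory at t = %.3f h; check parameter stability.",
          st$t_h
        ))
      }
    }
  }
  c(rec, list(t_h = t_h, state = st))
}

.cell_seed <- function(master, cell) {
  as.integer((as.numeric(master) + 104729 * cell) %% 2147483629)
}

#' Simulate an ensemble of PRD cells
#'
#' Integrates `n_cells` independent cells at `dt_min`, discards the burn-in,
#' samples every `sample_min`, adds Gaussian observation noise to positions
#' and mode components, and applies the observation pipeline
#' ([smooth_and_differentiate()]: 3-point moving average, forward
#' differences) to produce velocity and mode-derivative series. Each cell
#' draws its noise from an independent substream of the master seed, in a
#' fixed order (F2, F3, F6 per step, then observation noise), so ensembles
#' are reproducible and cell `k` is identical whatever `n_cells >= k` is.
#'
#' @param params A [prd_params()] object.
#' @param config A [sim_config()] object.
#' @return An object of class `prd_sim`: a list with tibbles `tracks`
#'   (`cell_id`, `time_min`, `x_um`, `y_um`; observation noise included),
#'   `modes` (`cell_id`, `time_min`, complex `c2`, `c3`), `derived`
#'   (smoothed positions/modes, complex `v1`, `dc2`, `dc3`; derivative
#'   columns are `NA` in each cell's final row), `truth` (noise-free sampled
#'   states) and the `params`/`config` used.
#' @export
simulate_cells <- function(params, config = sim_config()) {
  if (!inherits(params, "prd_params")) abort("`params` must be a prd_params object.")
  if (!inherits(config, "sim_config")) abort("`config` must be a sim_config object.")
  dt_h <- config$dt_min / 60
  durations <- rep(config$duration_h, length.out = config$n_cells)
  rec_every <- as.integer(round(config$sample_min / config$dt_min))
  steps_per_cell <- as.integer(round((config$burnin_h + durations) / dt_h))
  n_steps <- max(steps_per_cell)
  nc <- config$n_cells
  n_samp_max <- n_steps %/% rec_every + 1L

  xi <- array(NA_complex_, c(n_steps, nc, 3L))
  obs <- vector("list", nc)
  for (cell in seq_len(nc)) {
    set.seed(.cell_seed(config$seed, cell))
    z <- matrix(rnorm(n_steps * 6L), ncol = 6L)
    xi[, cell, 1L] <- complex(real = z[, 1L], imaginary = z[, 2L])
    xi[, cell, 2L] <- complex(real = z[, 3L], imaginary = z[, 4L])
    xi[, cell, 3L] <- complex(real = z[, 5L], imaginary = z[, 6L])
    obs[[cell]] <- matrix(rnorm(n_samp_max * 6L, sd = config$sigma0_um), ncol = 6L)
  }

  sim <- prd_integrate(params, xi, dt_h,
    scheme = config$velocity_scheme, record_every = rec_every
  )

  keep0 <- which(sim$t_h >= config$burnin_h - 1e-9)
  per_cell <- purrr::map(seq_len(nc), function(cell) {
    n_keep <- as.integer(round(durations[cell] * 60 / config$sample_min)) + 1L
    idx <- keep0[seq_len(n_keep)]
    time_min <- round((sim$t_h[idx] - sim$t_h[keep0[1L]]) * 60, 6)
    x <- sim$x[idx, cell] - sim$x[keep0[1L], cell]
    c2 <- sim$C2[idx, cell]
    c3 <- sim$C3[idx, cell]
    ob <- obs[[cell]][seq_len(n_keep), , drop = FALSE]
    tibble::tibble(
      cell_id = cell, time_min = time_min,
      x_true = Re(x), y_true = Im(x), c2_true = c2, c3_true = c3,
      v1_true = sim$v1[idx, cell],
      x_um = Re(x) + ob[, 1L], y_um = Im(x) + ob[, 2L],
      c2 = c2 + complex(real = ob[, 3L], imaginary = ob[, 4L]),
      c3 = c3 + complex(real = ob[, 5L], imaginary = ob[, 6L])
    )
  })
  all <- dplyr::bind_rows(per_cell)

  derived <- all |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_modify(function(df, key) {
      sm <- smooth_and_differentiate(
        df[c("time_min", "x_um", "y_um", "c2", "c3")],
        tau_min = config$sample_min
      )
      tibble::tibble(
        time_min = sm$time_min,
        x_um = sm$x_um_s, y_um = sm$y_um_s,
        v1 = complex(real = sm$d_x_um, imaginary = sm$d_y_um),
        c2 = sm$c2_s, c3 = sm$c3_s, dc2 = sm$d_c2, dc3 = sm$d_c3
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::relocate("cell_id")

  structure(
    list(
      tracks = all[c("cell_id", "time_min", "x_um", "y_um")],
      modes = all[c("cell_id", "time_min", "c2", "c3")],
      derived = derived,
      truth = all[c(
        "cell_id", "time_min", "x_true", "y_true",
        "c2_true", "c3_true", "v1_true"
      )],
      params = params, config = config
    ),
    class = "prd_sim"
  )
}

#' Simulate a single PRD cell
#'
#' Convenience wrapper for [simulate_cells()] with `n_cells = 1`.
#'
#' @inheritParams simulate_cells
#' @return A `prd_sim` object with a single cell.
#' @export
simulate_cell <- function(params, config = sim_config()) {
  config$n_cells <- 1L
  config$duration_h <- config$duration_h[1L]
  simulate_cells(params, config)
}

#' @export
print.prd_sim <- function(x, ...) {
  cat(sprintf(
    "<prd_sim> %d cell(s), %g-%g h at %g-min sampling (seed %d)\n",
    x$config$n_cells, min(x$config$duration_h), max(x$config$duration_h),
    x$config$sample_min, x$config$seed
  ))
  invisible(x)
}

#' Rotational-symmetry check for model coupling terms
#'
#' A coupling term entering the evolution equation of mode `n` must transform
#' like `C_n` under a global rotation: each factor of order `l` picks up
#' `exp(i l theta0)` (the velocity has order 1; complex conjugation negates
#' the order), so the term is admissible iff the factor orders sum to `n`.
#'
#' @param target_mode Integer order of the equation's left-hand side.
#' @param factor_orders Integer orders of the factors in the candidate term
#'   (conjugated factors as negative integers).
#' @return `TRUE` if the term is rotationally admissible, else `FALSE`.
#' @examples
#' validate_coupling_term(1, c(-2, 3)) # conj(C2) C3 in the velocity equation
#' @export
validate_coupling_term <- function(target_mode, factor_orders) {
  if (any(factor_orders == 0) || any(factor_orders != round(factor_orders))) {
    abort("`factor_orders` must be nonzero integers.")
  }
  sum(factor_orders) == target_mode
}
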