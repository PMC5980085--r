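# Summary-statistic fitting of the PRD model (ERR objective, multistart
# Nelder-Mead with common random numbers) and the persistent-random-walk
# (PRW) baseline fitted to the MSD.

#' Quantile-quantile R-squared between two samples
#'
#' Matches quantiles of both samples on a common probability grid and scores
#' the agreement as the coefficient of determination of the `b` quantiles
#' about the identity line `y = x` (1 means distributionally identical).
#'
#' @param a,b Numeric samples (`a` is the reference).
#' @param probs Probability grid (default 99 interior percentiles).
#' @return R-squared value (can be negative for badly mismatched samples).
#' @export
qq_r2 <- function(a, b, probs = seq(0.01, 0.99, by = 0.01)) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (!length(a) || !length(b)) abort("empty sample.")
  qa <- quantile(a, probs, names = FALSE, type = 7)
  qb <- quantile(b, probs, names = FALSE, type = 7)
  ss <- sum((qa - mean(qa))^2)
  if (ss < 1e-300) abort("degenerate (constant) reference sample.")
  1 - sum((qb - qa)^2) / ss
}

.wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y
}

#' Summary statistics entering the ERR objective
#'
#' Collects, from a derived series table, the distributional samples
#' (symmetrized velocity and mode components, two velocity-deformation phase
#' differences) and the autocorrelation curves of `v1`, `C2`, `C3` that the
#' ERR objective compares.
#'
#' @param derived Tibble with `cell_id`, `time_min` and complex columns
#'   `v1`, `c2`, `c3`, `dc2`, `dc3` (e.g. the `derived` table of
#'   [simulate_cells()], or experimental tables built with
#'   [track_velocities()] and [smooth_and_differentiate()]).
#' @param max_lag_min Longest autocorrelation lag in minutes.
#' @return A list of class `prd_summaries` with elements `samples` (named
#'   list of numeric vectors: `v`, `c2`, `c3`, `dphi1`, `dphi2`) and `acf`
#'   (named list of tibbles: `v1`, `c2`, `c3`).
#' @export
prd_summaries <- function(derived, max_lag_min = 120) {
  need <- c("cell_id", "time_min", "v1", "c2", "c3", "dc2", "dc3")
  miss <- setdiff(need, names(derived))
  if (length(miss)) {
    abort(paste0("`derived` is missing column(s): ", paste(miss, collapse = ", ")))
  }
  ok <- !is.na(derived$v1) & !is.na(derived$dc2) & !is.na(derived$dc3)
  d <- derived[ok, ]
  structure(
    list(
      samples = list(
        v = c(Re(d$v1), Im(d$v1)),
        c2 = c(Re(d$c2), Im(d$c2)),
        c3 = c(Re(d$c3), Im(d$c3)),
        dphi1 = .wrap_pi(Arg(d$v1) - Arg(Conj(d$dc2) * d$c3)),
        dphi2 = .wrap_pi(Arg(d$v1) - Arg(Conj(d$c2) * d$dc3))
      ),
      acf = list(
        v1 = autocorr(derived, v1, max_lag_min),
        c2 = autocorr(derived, c2, max_lag_min),
        c3 = autocorr(derived, c3, max_lag_min)
      )
    ),
    class = "prd_summaries"
  )
}

.acf_r2 <- function(obs, sim) {
  j <- dplyr::inner_join(obs, sim, by = "lag_min", suffix = c("_o", "_s"))
  ss <- sum((j$acf_o - mean(j$acf_o))^2)
  1 - sum((j$acf_s - j$acf_o)^2) / ss
}

#' ERR objective between observed and simulated summaries
#'
#' `ERR = sum_i (1 - R_i^2)` over the distributional components (velocity,
#' elongation, triangular deformation, two phase differences; compared by
#' [qq_r2()]) and the autocorrelation curves of `v1`, `C2`, `C3` (curve
#' R-squared on the common lag grid). Components are itemized so a mismatch
#' can be attributed.
#'
#' @param observed,simulated `prd_summaries` objects.
#' @return A list with `err` (total) and `components`
#'   (tibble `component`, `r2`, `one_minus_r2`).
#' @export
error_function <- function(observed, simulated) {
  for (side in list(observed, simulated)) {
    if (!inherits(side, "prd_summaries")) {
      abort("inputs must be `prd_summaries` objects.")
    }
  }
  s_names <- c("v", "c2", "c3", "dphi1", "dphi2")
  a_names <- c("v1", "c2", "c3")
  for (nm in s_names) {
    if (is.null(observed$samples[[nm]]) || is.null(simulated$samples[[nm]])) {
      abort(sprintf("missing distributional component `%s`.", nm))
    }
  }
  for (nm in a_names) {
    if (is.null(observed$acf[[nm]]) || is.null(simulated$acf[[nm]])) {
      abort(sprintf("missing autocorrelation component `%s`.", nm))
    }
  }
  r2 <- c(
    vapply(
      s_names,
      function(nm) qq_r2(observed$samples[[nm]], simulated$samples[[nm]]),
      0
    ),
    vapply(
      a_names,
      function(nm) .acf_r2(observed$acf[[nm]], simulated$acf[[nm]]),
      0
    )
  )
  comp <- tibble::tibble(
    component = c(
      paste0("pdf_", s_names),
      paste0("acf_", a_names)
    ),
    r2 = unname(r2),
    one_minus_r2 = 1 - unname(r2)
  )
  list(err = sum(comp$one_minus_r2), components = comp)
}

#' Multistart PRD model fit on summary statistics
#'
#' Minimizes the ERR objective over a chosen subset of PRD parameters.
#' Stage 1 scans `n_coarse` random multiplicative perturbations (within
#' `scan_range` of the initial values) and recentres on the best. Stage 2
#' runs `n_restarts` Nelder-Mead searches in log-parameter space from
#' jittered starts; each restart evaluates every candidate with its own
#' fixed simulation seed (common random numbers), so the objective seen by
#' the optimizer is deterministic and repeated calls reproduce the fit.
#'
#' @param observed A [prd_summaries()] object (the data being fitted).
#' @param init A [prd_params()] object: starting values; also supplies the
#'   fixed (non-free) parameters.
#' @param free Character vector of parameter names to optimize (all must be
#'   positive-valued parameters, e.g. `c("kappa2", "sigma2")`).
#' @param config [sim_config()] controlling the simulation budget per
#'   objective evaluation.
#' @param n_restarts Number of local searches (default 20).
#' @param n_coarse Stage-1 scan size (default 16).
#' @param scan_range Multiplicative half-range of the stage-1 scan
#'   (default 0.5, i.e. factors in `[0.5, 1.5]`).
#' @param jitter Log-scale half-width of the restart jitter (default 0.25).
#' @param maxit Nelder-Mead iteration cap per restart (default 40).
#' @param seed Master seed for scan, jitter and per-restart simulation seeds.
#' @param max_lag_min Autocorrelation lag range used in the objective.
#' @return An object of class `prd_fit`: `estimate` (mean over restarts),
#'   `sd` (across restarts), `best` (parameter set with the lowest ERR),
#'   `best_err`, `components` at the best fit, `restarts` (per-restart
#'   tibble) and the call settings. Supports [tidy()] and [glance()].
#' @export
fit_prd <- function(observed, init, free, config,
                    n_restarts = 20, n_coarse = 16, scan_range = 0.5,
                    jitter = 0.25, maxit = 40, seed = 1, max_lag_min = 120) {
  if (!inherits(init, "prd_params")) abort("`init` must be a prd_params object.")
  bad <- setdiff(free, names(init))
  if (length(bad)) {
    abort(paste0("unknown parameter(s) in `free`: ", paste(bad, collapse = ", ")))
  }
  objective <- function(log_theta, sim_seed) {
    p <- init
    p[free] <- as.list(exp(log_theta))
    cfg <- config
    cfg$seed <- sim_seed
    err <- tryCatch(
      {
        sim <- simulate_cells(p, cfg)
        error_function(observed, prd_summaries(sim$derived, max_lag_min))$err
      },
      error = function(e) Inf # unstable parameter proposals score worst
    )
    err
  }
  if (!length(free)) {
    e0 <- objective(numeric(0), seed)
    fit <- structure(
      list(
        estimate = numeric(0), sd = numeric(0), best = init, best_err = e0,
        components = NULL, restarts = tibble::tibble(), free = free, seed = seed
      ),
      class = "prd_fit"
    )
    return(fit)
  }
  theta0 <- log(unlist(init[free]))

  set.seed(seed)
  scan_seeds <- sample.int(2^30, n_coarse + n_restarts)
  # stage 1: coarse multiplicative scan around the initial values
  center <- theta0
  if (n_coarse > 0) {
    cand <- rbind(
      rep(0, length(free)),
      matrix(
        log(runif(n_coarse * length(free), 1 - scan_range, 1 + scan_range)),
        ncol = length(free)
      )
    )
    errs <- apply(cand, 1L, function(d) objective(theta0 + d, scan_seeds[1L]))
    center <- theta0 + cand[which.min(errs), ]
  }
  # stage 2: jittered Nelder-Mead restarts with common random numbers
  starts <- matrix(
    runif(n_restarts * length(free), -jitter, jitter),
    ncol = length(free)
  )
  restarts <- purrr::map_dfr(seq_len(n_restarts), function(r) {
    sim_seed <- scan_seeds[n_coarse + r]
    opt <- optim(
      center + starts[r, ],
      function(th) objective(th, sim_seed),
      method = "Nelder-Mead", control = list(maxit = maxit)
    )
    out <- tibble::as_tibble(as.list(exp(opt$par)))
    names(out) <- free
    out$err <- opt$value
    out$converged <- opt$convergence == 0
    out
  })
  est <- vapply(free, function(nm) mean(restarts[[nm]]), 0)
  sds <- vapply(free, function(nm) sd(restarts[[nm]]), 0)
  best_row <- which.min(restarts$err)
  best <- init
  best[free] <- as.list(unlist(restarts[best_row, free]))
  init_err <- objective(theta0, scan_seeds[1L])
  if (min(restarts$err) >= init_err) {
    warn(sprintf(
      "No restart improved on the initial ERR (%.4f); flat or noisy objective.",
      init_err
    ))
  }
  # itemized components at the best parameter set
  cfg <- config
  cfg$seed <- scan_seeds[n_coarse + best_row]
  comp <- error_function(
    observed,
    prd_summaries(simulate_cells(best, cfg)$derived, max_lag_min)
  )$components
  structure(
    list(
      estimate = est, sd = sds, best = best, best_err = min(restarts$err),
      components = comp, restarts = restarts, free = free, seed = seed
    ),
    class = "prd_fit"
  )
}

#' @export
print.prd_fit <- function(x, ...) {
  cat(sprintf(
    "<prd_fit> %d restart(s), best ERR = %.4f\n",
    nrow(x$restarts), x$best_err
  ))
  for (nm in x$free) {
    cat(sprintf(
      "  %-8s = %.4g +/- %.3g (restart sd)\n", nm, x$estimate[[nm]], x$sd[[nm]]
    ))
  }
  invisible(x)
}

#' @export
tidy.prd_fit <- function(x, ...) {
  tibble::tibble(
    term = x$free,
    estimate = unname(x$estimate[x$free]),
    std.error = unname(x$sd[x$free]),
    best = vapply(x$free, function(nm) x$best[[nm]], 0)
  )
}

#' @export
glance.prd_fit <- function(x, ...) {
  tibble::tibble(
    best_err = x$best_err,
    n_restarts = nrow(x$restarts),
    n_free = length(x$free)
  )
}

#' Analytic MSD of the persistent random walk
#'
#' Two-dimensional Fuerth form with an additive observation-noise offset:
#' `MSD(t) = 4 D (t - P (1 - exp(-t / P))) + 4 sigma0^2`, ballistic
#' (`(2 D / P) t^2`) for `t << P` and diffusive (`4 D t`) for `t >> P`.
#'
#' @param lag_h Positive lags in hours.
#' @param d Diffusivity (micrometres squared per hour).
#' @param p Persistence time (hours).
#' @param sigma0 Observation-noise standard deviation (micrometres).
#' @return MSD values in micrometres squared.
#' @export
prw_msd <- function(lag_h, d, p, sigma0 = 0) {
  if (any(lag_h <= 0)) abort("lags must be positive.")
  if (d <= 0 || p <= 0) abort("`d` and `p` must be positive.")
  4 * d * (lag_h - p * (1 - exp(-lag_h / p))) + 4 * sigma0^2
}

#' Fit the PRW baseline to an empirical MSD
#'
#' Minimizes the weighted residual sum of squares between [prw_msd()] and
#' the measured MSD, with weights `1 / n_pairs` per lag by default.
#' Optimization is Nelder-Mead in `(log D, log P, sigma0)` from a small set
#' of deterministic starts.
#'
#' @param msd_tbl Output of [msd()] (`lag_min`, `msd`, `n_pairs`).
#' @param weights Optional per-lag weights (default `1 / n_pairs`).
#' @return An object of class `prw_fit` with elements `d`, `p_h`, `sigma0`,
#'   `rss`, `n_lags` and `fitted` (tibble). Supports [tidy()]/[glance()].
#' @export
fit_prw <- function(msd_tbl, weights = NULL) {
  lag_h <- msd_tbl$lag_min / 60
  y <- msd_tbl$msd
  w <- weights %||% (1 / msd_tbl$n_pairs)
  obj <- function(th) {
    m <- prw_msd(lag_h, exp(th[1L]), exp(th[2L]), abs(th[3L]))
    sum(w * (y - m)^2)
  }
  d0 <- max(y) / (4 * max(lag_h))
  starts <- list(
    c(log(d0), log(max(lag_h) / 10), 0),
    c(log(d0), log(max(min(lag_h), max(lag_h) / 50)), 1),
    c(log(d0 * 5), log(max(lag_h) / 4), 0)
  )
  fits <- lapply(starts, function(s) {
    optim(s, obj, method = "Nelder-Mead", control = list(maxit = 500, reltol = 1e-12))
  })
  best <- fits[[which.min(vapply(fits, function(f) f$value, 0))]]
  vals <- vapply(fits, function(f) f$value, 0)
  if (diff(range(vals)) < 1e-12 * (1 + min(vals)) &&
    max(vapply(fits, function(f) max(abs(f$par - best$par)), 0)) > 1) {
    warn("PRW fit looks non-identifiable: distant starts reach the same RSS.")
  }
  d <- exp(best$par[1L])
  p <- exp(best$par[2L])
  s0 <- abs(best$par[3L])
  structure(
    list(
      d = d, p_h = p, sigma0 = s0, rss = best$value, n_lags = length(y),
      fitted = tibble::tibble(
        lag_min = msd_tbl$lag_min, msd = y,
        fitted = prw_msd(lag_h, d, p, s0)
      )
    ),
    class = "prw_fit"
  )
}

#' @export
print.prw_fit <- function(x, ...) {
  cat(sprintf(
    "<prw_fit> D = %.4g um^2/h, P = %.4g h, sigma0 = %.3g um (weighted RSS %.4g)\n",
    x$d, x$p_h, x$sigma0, x$rss
  ))
  invisible(x)
}

#' @export
tidy.prw_fit <- function(x, ...) {
  tibble::tibble(
    term = c("D", "P", "sigma0"),
    estimate = c(x$d, x$p_h, x$sigma0)
  )
}

#' @export
glance.prw_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, n_lags = x$n_lags)
}

#' Gaussian-residual AIC from a residual sum of squares
#'
#' `AIC = n ln(RSS / n) + 2 k`; lower is better. Used to compare candidate
#' migration laws fitted to the same stacked residual vector.
#'
#' @param rss Residual sum of squares (positive).
#' @param n_obs Number of residuals.
#' @param k_params Number of fitted parameters (`< n_obs`).
#' @return The AIC value.
#' @export
aic_rss <- function(rss, n_obs, k_params) {
  if (rss <= 0) abort("`rss` must be positive.")
  if (n_obs <= k_params) abort("need `n_obs > k_params`.")
  n_obs * log(rss / n_obs) + 2 * k_params
}

#' Non-dimensional internal force
#'
#' `sigma_n / (R0 * kappa_n)`: the red-noise force scale relative to cell
#' size and shape-relaxation rate.
#'
#' @param sigma Force noise scale (micrometres per hour).
#' @param r0 Mean cell radius (micrometres, positive).
#' @param kappa Shape relaxation rate (per hour, positive).
#' @return Dimensionless force magnitude.
#' @export
nondimensional_force <- function(sigma, r0, kappa) {
  if (any(r0 <= 0) || any(kappa <= 0)) abort("`r0` and `kappa` must be positive.")
  if (any(sigma < 0)) abort("`sigma` must be non-negative.")
  sigma / (r0 * kappa)
}
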