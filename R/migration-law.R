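# Deformation-based migration law.
#
# The cell velocity, written as the complex number v1 = vx + i vy, is coupled
# to the elongation mode C2 and triangular mode C3 through
#   v1 = beta1 * conj(dC2/dt) * C3 - beta2 * conj(C2) * dC3/dt,
# a bilinear, time-reverse-symmetric law: a shape change retraced backwards
# moves the centroid back along its path. The general form adds a
# shape-determined term betac * conj(C2) * C3 (keratocyte-type motion).

#' Predicted velocity from the deformation law
#'
#' Evaluates `v1 = beta1 * Conj(dc2) * c3 - beta2 * Conj(c2) * dc3`
#' (micrometres per hour). All complex arguments are vectorized.
#'
#' @param c2,c3 Complex mode amplitudes (micrometres).
#' @param dc2,dc3 Complex mode time derivatives (micrometres per hour).
#' @param beta1,beta2 Mobility coefficients (per micrometre).
#' @return Complex velocity `vx + i vy` in micrometres per hour.
#' @examples
#' predict_velocity(1 + 1i, 2 + 0i, 1i, 1 - 1i, beta1 = 0.29, beta2 = 0.11)
#' @export
predict_velocity <- function(c2, c3, dc2, dc3, beta1, beta2) {
  beta1 * Conj(dc2) * c3 - beta2 * Conj(c2) * dc3
}

#' General migration law including the shape-determined term
#'
#' Adds `betac * Conj(c2) * c3` to [predict_velocity()]. `betac = 0` recovers
#' the deformation-rate law; `beta1 = beta2 = 0` gives a purely
#' shape-determined (keratocyte-type) law.
#'
#' @inheritParams predict_velocity
#' @param betac Shape-determined mobility (per micrometre per hour scale).
#' @return Complex velocity in micrometres per hour.
#' @export
predict_velocity_general <- function(c2, c3, dc2, dc3, beta1, beta2, betac) {
  predict_velocity(c2, c3, dc2, dc3, beta1, beta2) + betac * Conj(c2) * c3
}

#' Least-squares estimation of the mobility coefficients
#'
#' Minimizes `S = sum(|V - v|^2)` between observed velocities and the
#' migration law by solving the real normal equations obtained from stacking
#' real and imaginary parts. Samples whose regressors all vanish carry no
#' information and are dropped (with a message). The fit pools all supplied
#' samples, i.e. it is a population-level estimate.
#'
#' @param data Data frame with complex columns `v1` (observed velocity,
#'   micrometres per hour), `c2`, `c3`, `dc2`, `dc3`. Rows with `NA` in any of
#'   these are dropped.
#' @param include_general If `TRUE`, also estimate the shape-determined
#'   coefficient `betac` of [predict_velocity_general()].
#'
#' @return An object of class `mobility_fit`: coefficients, standard errors
#'   and 95% confidence half-widths, the residual sum `S`, number of samples,
#'   `R^2`, and an AIC value (`n ln(RSS/n) + 2k` on the stacked residuals).
#'   Supports [tidy()], [glance()] and [autoplot()].
#' @export
fit_mobility <- function(data, include_general = FALSE) {
  need <- c("v1", "c2", "c3", "dc2", "dc3")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    abort(paste0("`data` is missing column(s): ", paste(miss, collapse = ", ")))
  }
  d <- data[need]
  keep <- !Reduce(`|`, lapply(d, is.na))
  d <- d[keep, , drop = FALSE]
  x1 <- Conj(d$dc2) * d$c3
  x2 <- -Conj(d$c2) * d$dc3
  x3 <- if (include_general) Conj(d$c2) * d$c3 else NULL
  info <- Mod(x1) > 0 | Mod(x2) > 0 | (include_general & Mod(x3 %||% 0) > 0)
  if (any(!info)) {
    inform(sprintf("Dropping %d sample(s) with all-zero regressors.", sum(!info)))
  }
  x1 <- x1[info]
  x2 <- x2[info]
  if (include_general) x3 <- x3[info]
  v <- d$v1[info]
  n_obs <- length(v)
  if (n_obs < 3L) abort("Need at least 3 informative samples to fit.")

  X <- cbind(c(Re(x1), Im(x1)), c(Re(x2), Im(x2)))
  terms <- c("beta1", "beta2")
  if (include_general) {
    X <- cbind(X, c(Re(x3), Im(x3)))
    terms <- c(terms, "betac")
  }
  y <- c(Re(v), Im(v))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    abort("Rank-deficient normal equations: regressors are collinear or zero.")
  }
  beta <- qr.coef(qrX, y)
  res <- y - X %*% beta
  S <- sum(res^2)
  k <- ncol(X)
  sigma2 <- S / (2 * n_obs - k)
  covb <- sigma2 * chol2inv(qr.R(qrX))
  se <- sqrt(diag(covb))
  names(beta) <- names(se) <- terms
  tss <- sum((y - mean(y))^2)
  structure(
    list(
      coefficients = beta, se = se, ci95 = stats::qnorm(0.975) * se,
      residual_s = S, n_obs = n_obs, r_squared = 1 - S / tss,
      aic = aic_rss(S, 2 * n_obs, k), include_general = include_general
    ),
    class = "mobility_fit"
  )
}

#' @export
print.mobility_fit <- function(x, ...) {
  cat("<mobility_fit> pooled least-squares fit of the migration law\n")
  for (nm in names(x$coefficients)) {
    cat(sprintf(
      "  %-6s = %8.4f +/- %.4f (95%% CI) um^-1\n",
      nm, x$coefficients[[nm]], x$ci95[[nm]]
    ))
  }
  cat(sprintf(
    "  n = %d, S = %.4g um^2 h^-2, R^2 = %.3f, AIC = %.4g\n",
    x$n_obs, x$residual_s, x$r_squared, x$aic
  ))
  invisible(x)
}

#' @export
tidy.mobility_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$se),
    conf.low = unname(x$coefficients - x$ci95),
    conf.high = unname(x$coefficients + x$ci95)
  )
}

#' @export
glance.mobility_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared, residual_s = x$residual_s,
    n_obs = x$n_obs, AIC = x$aic
  )
}

#' Joint phase distribution of two complex series
#'
#' Normalized 2D histogram of `(Arg(a), Arg(b))` on `[-pi, pi)^2`, the
#' diagnostic used to identify which bilinear couplings carry the velocity
#' phase. Also reports the circular concentration of the phase difference
#' (mean resultant length of `exp(i * (Arg(a) - Arg(b)))`).
#'
#' @param a,b Aligned complex series.
#' @param n_bins Number of bins per axis (default 24).
#' @param floor Magnitude floor; samples with `Mod(a) <= floor` or
#'   `Mod(b) <= floor` are excluded (default 0: only exact zeros, whose phase
#'   is undefined, are dropped).
#'
#' @return A list with `density` (tibble `arg_a`, `arg_b`, `prob` at bin
#'   centres), `phase_diff_concentration` in `[0, 1]` and `phase_diff_mean`
#'   (radians).
#' @export
phase_joint_distribution <- function(a, b, n_bins = 24, floor = 0) {
  if (length(a) != length(b)) abort("`a` and `b` must have equal length.")
  keep <- Mod(a) > floor & Mod(b) > floor & !is.na(a) & !is.na(b)
  a <- a[keep]
  b <- b[keep]
  if (!length(a)) abort("No samples above the magnitude floor.")
  edges <- seq(-pi, pi, length.out = n_bins + 1L)
  mids <- (edges[-1L] + edges[-length(edges)]) / 2
  ia <- findInterval(Arg(a), edges, rightmost.closed = TRUE)
  ib <- findInterval(Arg(b), edges, rightmost.closed = TRUE)
  ia <- pmin(pmax(ia, 1L), n_bins)
  ib <- pmin(pmax(ib, 1L), n_bins)
  tab <- unclass(table(
    factor(ia, levels = seq_len(n_bins)),
    factor(ib, levels = seq_len(n_bins))
  ))
  # expand_grid varies arg_b fastest; t(tab) stacked by column matches that
  dens <- tidyr::expand_grid(arg_a = mids, arg_b = mids)
  dens$prob <- as.vector(t(tab)) / length(a)
  z <- mean(exp(1i * (Arg(a) - Arg(b))))
  list(
    density = tibble::as_tibble(dens),
    phase_diff_concentration = Mod(z),
    phase_diff_mean = Arg(z)
  )
}

#' Binned agreement between predicted and observed velocity
#'
#' Bins each Cartesian component of the observed velocity by the predicted
#' component into intervals of width `gamma` centred at integer multiples of
#' `gamma`, reporting the mean, standard deviation and count per non-empty
#' bin. Points on the identity line indicate that the law captures the
#' velocity on average.
#'
#' @param v_pred,v_obs Aligned complex velocity series (micrometres per hour).
#' @param gamma Bin width in micrometres per hour (default 12).
#'
#' @return A tibble with columns `component` (`"x"`/`"y"`), `center`,
#'   `mean_obs`, `sd_obs`, `n`; attribute `range99` holds the central 99%
#'   range of the predicted values per component.
#' @export
binned_velocity_agreement <- function(v_pred, v_obs, gamma = 12) {
  if (length(v_pred) != length(v_obs)) abort("series must have equal length.")
  keep <- !is.na(v_pred) & !is.na(v_obs)
  v_pred <- v_pred[keep]
  v_obs <- v_obs[keep]
  comp <- function(vp, vo, label) {
    tibble::tibble(
      component = label,
      center = round(vp / gamma) * gamma,
      obs = vo
    ) |>
      dplyr::group_by(.data$component, .data$center) |>
      dplyr::summarise(
        mean_obs = mean(.data$obs),
        sd_obs = stats::sd(.data$obs),
        n = dplyr::n(),
        .groups = "drop"
      )
  }
  out <- dplyr::bind_rows(
    comp(Re(v_pred), Re(v_obs), "x"),
    comp(Im(v_pred), Im(v_obs), "y")
  )
  attr(out, "range99") <- tibble::tibble(
    component = c("x", "y"),
    lo = c(quantile(Re(v_pred), 0.005), quantile(Im(v_pred), 0.005)),
    hi = c(quantile(Re(v_pred), 0.995), quantile(Im(v_pred), 0.995))
  )
  out
}

#' Archetype motions of the migration law
#'
#' Integrates the velocity law over a linear amplitude ramp for the three
#' canonical deformation programs: `"elongation"` (one pseudopod extends;
#' `arg(C2) = arg(C3) = 0`, elongation rate dominant), `"bipolar"` (two
#' pseudopodia extend; `arg(C2) = 0`, `arg(C3) = pi`, triangular rate
#' dominant) and `"repolarize"` (an elongated cell extends a new pseudopod;
#' `arg(C2) = pi`, `arg(C3) = 0`, triangular rate dominant). The law is
#' time-reverse symmetric: running a ramp backwards exactly negates the
#' displacement (the integrator evaluates modes at interval midpoints so this
#' holds to machine precision).
#'
#' @param case One of `"elongation"`, `"bipolar"`, `"repolarize"`.
#' @param beta1,beta2 Mobility coefficients (per micrometre).
#' @param c2_range,c3_range Length-2 numeric: start and end magnitude of
#'   `|C2|` and `|C3|` (micrometres); defaults encode the dominant-rate
#'   pattern of each case.
#' @param delta_t_h Ramp duration in hours.
#' @param n_steps Integration steps.
#' @param r0 Mean radius used for the reconstructed outlines (micrometres).
#'
#' @return A list with `displacement` (complex, micrometres), `shapes`
#'   (tibble `theta`, `r_initial`, `r_final`) and `path` (tibble of midpoint
#'   times and velocities).
#' @export
archetype_motion <- function(case = c("elongation", "bipolar", "repolarize"),
                             beta1 = 1.21, beta2 = 0.24,
                             c2_range = NULL, c3_range = NULL,
                             delta_t_h = 1, n_steps = 200, r0 = 20) {
  case <- match.arg(case)
  ph <- switch(case,
    elongation = list(a2 = 0, a3 = 0, c2 = c(0.5, 5), c3 = c(0.8, 1.0)),
    bipolar = list(a2 = 0, a3 = pi, c2 = c(2, 2.2), c3 = c(0.2, 2.5)),
    repolarize = list(a2 = pi, a3 = 0, c2 = c(2, 2.2), c3 = c(0.2, 2.5))
  )
  c2_range <- c2_range %||% ph$c2
  c3_range <- c3_range %||% ph$c3
  tt <- seq(0, 1, length.out = n_steps + 1L)
  m2 <- c2_range[1] + (c2_range[2] - c2_range[1]) * tt
  m3 <- c3_range[1] + (c3_range[2] - c3_range[1]) * tt
  c2 <- m2 * exp(1i * ph$a2)
  c3 <- m3 * exp(1i * ph$a3)
  dt <- delta_t_h / n_steps
  dc2 <- diff(c2) / dt
  dc3 <- diff(c3) / dt
  mid2 <- (c2[-1L] + c2[-length(c2)]) / 2
  mid3 <- (c3[-1L] + c3[-length(c3)]) / 2
  v <- predict_velocity(mid2, mid3, dc2, dc3, beta1, beta2)
  theta <- 2 * pi * (0:199) / 200
  shapes <- tibble::tibble(
    theta = theta,
    r_initial = reconstruct_profile(r0, c("2" = c2[1L], "3" = c3[1L]), theta),
    r_final = reconstruct_profile(
      r0, c("2" = c2[length(c2)], "3" = c3[length(c3)]), theta
    )
  )
  list(
    case = case,
    displacement = sum(v) * dt,
    shapes = shapes,
    path = tibble::tibble(t_h = (tt[-1L] - dt / 2) * delta_t_h, v1 = v)
  )
}
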