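# Fourier shape-mode representation of cell contours.
#
# A cell outline is reduced to the radial profile R(theta), the distance from
# the area centroid to the rim as a function of the polar angle, and then to
# complex Fourier coefficients C_n = mean(R(theta) e^{i n theta}), so that
#   R(theta) = R0 + sum_{n>=2} ( C_n e^{-i n theta} + conj(C_n) e^{i n theta} ).
# n = 2 is elongation, n = 3 triangular deformation; the phase
# phi_n = arg(C_n)/n is the direction of maximum deformation. With this
# kernel a rigid rotation of the contour by theta0 multiplies C_n by
# e^{i n theta0}, so the bilinear migration law transforms like a velocity.

#' Radial profile of a cell contour
#'
#' Computes the distance `R(theta)` from the area centroid of a closed polygon
#' to its rim on a uniform angular grid, followed by a circular moving average
#' over `theta +/- smooth_halfwidth` degrees. For non-star-convex outlines the
#' outermost ray crossing is used, which preserves protrusion signal.
#'
#' @param boundary Data frame with vertex columns `x` and `y` (or `x_um`,
#'   `y_um`) in micrometres, ordered along the outline. The closing edge is
#'   implicit; a repeated final vertex is tolerated.
#' @param n_theta Number of uniform angular samples over `[0, 2*pi)`.
#' @param smooth_halfwidth Half-width of the angular smoothing window in
#'   degrees; samples within `theta +/- smooth_halfwidth` are averaged.
#'   Use `0` to disable smoothing.
#' @param time_min Optional frame time in minutes, stored as an attribute.
#'
#' @return A tibble of class `contour_frame` with columns `theta` (radians)
#'   and `r` (micrometres), and attributes `centroid` (length-2 numeric),
#'   `r_raw` (profile before smoothing) and `time_min`.
#' @examples
#' sq <- data.frame(x = c(-1, 1, 1, -1) / 2, y = c(-1, -1, 1, 1) / 2)
#' prof <- radial_profile(sq, n_theta = 360, smooth_halfwidth = 0)
#' prof$r[1] # 0.5 along the +x ray
#' @export
radial_profile <- function(boundary, n_theta = 360, smooth_halfwidth = 6,
                           time_min = NA_real_) {
  xy <- .boundary_xy(boundary)
  x <- xy$x
  y <- xy$y
  n <- length(x)
  if (n < 3L) abort("`boundary` needs at least 3 vertices.")
  if (n_theta < 8L) abort("`n_theta` is too small for a stable profile.")

  ii <- seq_len(n)
  jj <- c(ii[-1L], 1L)
  cr <- x[ii] * y[jj] - x[jj] * y[ii]
  area <- sum(cr) / 2
  if (abs(area) < 1e-12) {
    abort("Degenerate polygon: zero enclosed area (collinear vertices?).")
  }
  cx <- sum((x[ii] + x[jj]) * cr) / (6 * area)
  cy <- sum((y[ii] + y[jj]) * cr) / (6 * area)

  theta <- 2 * pi * (seq_len(n_theta) - 1L) / n_theta
  r <- .ray_crossings(theta, x, y, cx, cy, time_min = time_min)

  r_s <- .circular_smooth(r, theta, smooth_halfwidth)
  out <- tibble::tibble(theta = theta, r = r_s)
  class(out) <- c("contour_frame", class(out))
  attr(out, "centroid") <- c(x = cx, y = cy)
  attr(out, "r_raw") <- r
  attr(out, "time_min") <- time_min
  out
}

.boundary_xy <- function(boundary) {
  if (is.data.frame(boundary)) {
    xn <- intersect(c("x", "x_um"), names(boundary))[1]
    yn <- intersect(c("y", "y_um"), names(boundary))[1]
    if (is.na(xn) || is.na(yn)) {
      abort("`boundary` must have columns x/y (or x_um/y_um).")
    }
    x <- boundary[[xn]]
    y <- boundary[[yn]]
  } else if (is.matrix(boundary) && ncol(boundary) == 2L) {
    x <- boundary[, 1L]
    y <- boundary[, 2L]
  } else {
    abort("`boundary` must be a data frame or a 2-column matrix.")
  }
  if (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y))) {
    abort("`boundary` contains non-finite vertices.")
  }
  # drop an explicitly repeated closing vertex
  n <- length(x)
  if (n > 3L && x[1L] == x[n] && y[1L] == y[n]) {
    x <- x[-n]
    y <- y[-n]
  }
  list(x = x, y = y)
}

# Outermost intersection of rays from (cx, cy) with the polygon, one radius
# per angle. Vectorized over angles x edges.
.ray_crossings <- function(theta, x, y, cx, cy, time_min = NA_real_) {
  n <- length(x)
  jj <- c(seq_len(n)[-1L], 1L)
  ex <- x[jj] - x
  ey <- y[jj] - y
  wx <- x - cx
  wy <- y - cy
  dx <- cos(theta)
  dy <- sin(theta)
  # t = cross(w, e) / cross(d, e); s = cross(w, d) / cross(d, e)
  we <- wx * ey - wy * ex # per edge
  cde <- outer(dx, ey) - outer(dy, ex) # angle x edge
  tt <- rep(we, each = length(theta)) / cde
  dim(tt) <- dim(cde)
  ss <- (outer(dy, wx) - outer(dx, wy)) / cde
  # s-tolerance keeps rays that pass exactly through a vertex
  ok <- is.finite(tt) & is.finite(ss) & tt > 1e-9 & ss >= -1e-9 & ss <= 1 + 1e-9
  tt[!ok] <- -Inf
  r <- apply(tt, 1L, max)
  if (any(!is.finite(r)) || any(r <= 0)) {
    bad <- which(!is.finite(r) | r <= 0)[1L]
    abort(sprintf(
      paste0(
        "No boundary crossing along theta = %.3f rad",
        "%s: centroid lies outside the outline (non-star-convex frame)."
      ),
      theta[bad],
      if (is.na(time_min)) "" else sprintf(" (frame t = %g min)", time_min)
    ))
  }
  r
}

.circular_smooth <- function(r, theta, halfwidth_deg) {
  if (halfwidth_deg <= 0) {
    return(r)
  }
  n <- length(r)
  dtheta_deg <- 360 / n
  k <- floor(halfwidth_deg / dtheta_deg + 1e-9)
  if (k == 0L) {
    return(r)
  }
  acc <- r
  for (s in seq_len(k)) {
    acc <- acc + r[.wrap_idx(seq_len(n) + s, n)] + r[.wrap_idx(seq_len(n) - s, n)]
  }
  acc / (2 * k + 1)
}

.wrap_idx <- function(i, n) ((i - 1L) %% n) + 1L

#' Complex Fourier shape modes of a radial profile
#'
#' Projects `R(theta)` on circular harmonics:
#' `C_n = mean(R(theta) * exp(1i * n * theta))` over the uniform grid, so the
#' truncated series `R0 + sum(C_n e^{-i n theta} + conj(C_n) e^{i n theta})`
#' reproduces the profile, the phase `arg(C_n) / n` points at the maximum
#' deformation, and rotating the contour by `theta0` multiplies `C_n` by
#' `exp(1i * n * theta0)`. Mode `n = 1` reflects residual centroid offset; it
#' is returned separately as a quality diagnostic and excluded from `modes`.
#'
#' @param frame A `contour_frame` from [radial_profile()], or any list/data
#'   frame with components `theta` and `r` on a uniform grid over `[0, 2*pi)`.
#' @param m_max Highest retained mode index (must satisfy
#'   `m_max < length(theta) / 2` to avoid aliasing).
#'
#' @return A list of class `shape_modes`: `r0` (mean radius, micrometres),
#'   `modes` (named complex vector `C_2 .. C_m`), `c1` (diagnostic mode-1
#'   amplitude), `m_max`, `n_theta`.
#' @examples
#' th <- 2 * pi * (0:359) / 360
#' fm <- fourier_modes(list(theta = th, r = 20 + 3 * cos(2 * th)), m_max = 3)
#' fm$modes[["2"]] # 1.5 + 0i
#' @export
fourier_modes <- function(frame, m_max = 3) {
  theta <- frame$theta
  r <- frame$r
  n_theta <- length(theta)
  if (m_max < 2L) abort("`m_max` must be at least 2.")
  if (m_max >= n_theta / 2) {
    abort(sprintf(
      "Aliasing: m_max = %d needs more than %d angular samples.",
      m_max, n_theta
    ))
  }
  ns <- seq_len(m_max)
  cn <- vapply(
    ns,
    function(n) mean(r * exp(1i * n * theta)),
    complex(1)
  )
  modes <- cn[ns >= 2L]
  names(modes) <- as.character(ns[ns >= 2L])
  structure(
    list(
      r0 = mean(r), modes = modes, c1 = cn[1L],
      m_max = as.integer(m_max), n_theta = n_theta
    ),
    class = "shape_modes"
  )
}

#' @export
print.shape_modes <- function(x, ...) {
  cat(sprintf(
    "<shape_modes> R0 = %.3f um, modes n = 2..%d (|C2| = %.3f, |C1| = %.2g)\n",
    x$r0, x$m_max, Mod(x$modes[["2"]]), Mod(x$c1)
  ))
  invisible(x)
}

#' Reconstruct a radial profile from shape modes
#'
#' Evaluates the truncated Fourier series
#' `R(theta) = R0 + sum_n (C_n e^{-i n theta} + conj(C_n) e^{i n theta})`.
#'
#' @param r0 Mean radius in micrometres.
#' @param modes Named complex vector of mode amplitudes; names are the mode
#'   indices (e.g. `"2"`, `"3"`), as produced by [fourier_modes()].
#' @param theta Angles (radians) at which to evaluate.
#' @param m_used Highest mode to include (default: all supplied modes).
#'
#' @return Numeric vector of radii, same length as `theta`.
#' @export
reconstruct_profile <- function(r0, modes, theta, m_used = NULL) {
  if (length(modes)) {
    ns <- as.integer(names(modes))
    if (anyNA(ns)) abort("`modes` must be named by integer mode index.")
  } else {
    ns <- integer(0)
  }
  if (!is.null(m_used)) {
    if (length(ns) && m_used > max(ns)) {
      abort("`m_used` exceeds the highest available mode.")
    }
    keep <- ns <= m_used
    modes <- modes[keep]
    ns <- ns[keep]
  }
  r <- rep(as.numeric(r0), length(theta))
  for (k in seq_along(ns)) {
    r <- r + 2 * Re(modes[[k]] * exp(-1i * ns[k] * theta))
  }
  r
}

#' Magnitude and deformation direction of a shape mode
#'
#' Splits `C_n = |C_n| exp(i n phi_n)`: the magnitude is the deformation
#' amplitude and `phi_n = arg(C_n) / n`, reduced to `[0, 2*pi/n)`, is the
#' direction of maximum deformation. A vanishing amplitude has no direction:
#' the phase is returned as `NA` with `defined = FALSE`, never as an
#' arbitrary angle.
#'
#' @param c_n Complex mode amplitude(s).
#' @param n Mode index (`>= 2`).
#'
#' @return A tibble with columns `magnitude` (micrometres), `phi` (radians in
#'   `[0, 2*pi/n)`) and `defined` (logical).
#' @export
phase_decomposition <- function(c_n, n) {
  if (n < 2L) abort("`n` must be >= 2 (mode 1 is centroid motion).")
  mag <- Mod(c_n)
  phi <- (Arg(c_n) / n) %% (2 * pi / n)
  defined <- mag > 0
  phi[!defined] <- NA_real_
  tibble::tibble(magnitude = mag, phi = phi, defined = defined)
}

#' Moving-average smoothing and forward differencing of sampled series
#'
#' Applies the observation pipeline used for both experimental and simulated
#' series: a centred moving average over `window` consecutive samples
#' (shrinking symmetrically at the ends), then the forward difference
#' `(s[k + 1] - s[k]) / tau` converted to per-hour units. The derivative
#' series is aligned to the left sample time and is one sample shorter.
#'
#' @param series Either a numeric/complex vector sampled every `tau_min`
#'   minutes, or a data frame with a `time_min` column plus value columns.
#' @param tau_min Sampling interval in minutes.
#' @param window Odd moving-average length (default 3).
#'
#' @return For a vector: a list with `smoothed` (length `n`) and `derivative`
#'   (length `n - 1`, units value per hour). For a data frame: a tibble with
#'   `time_min`, smoothed columns `<col>_s`, and derivative columns `d_<col>`
#'   (`NA` in the final row).
#' @examples
#' smooth_and_differentiate(2 * (0:10) * 5, tau_min = 5)$derivative[1] # 120/h
#' @export
smooth_and_differentiate <- function(series, tau_min = 5, window = 3) {
  if (window %% 2 != 1 || window < 1) abort("`window` must be odd and >= 1.")
  if (is.data.frame(series)) {
    if (!"time_min" %in% names(series)) {
      abort("data-frame input needs a `time_min` column.")
    }
    tt <- series$time_min
    .check_uniform_grid(tt, tau_min)
    vals <- series[setdiff(names(series), c("time_min", "cell_id"))]
    vals <- vals[vapply(vals, function(v) is.numeric(v) || is.complex(v), TRUE)]
    out <- tibble::tibble(time_min = tt)
    if ("cell_id" %in% names(series)) out$cell_id <- series$cell_id
    for (nm in names(vals)) {
      sm <- .movavg_shrink(vals[[nm]], window)
      out[[paste0(nm, "_s")]] <- sm
      dv <- diff(sm) / (tau_min / 60)
      out[[paste0("d_", nm)]] <- c(dv, NA)
    }
    return(out)
  }
  if (length(series) < window + 1L) {
    abort("`series` must have at least `window + 1` samples.")
  }
  sm <- .movavg_shrink(series, window)
  list(smoothed = sm, derivative = diff(sm) / (tau_min / 60))
}

.check_uniform_grid <- function(tt, tau_min) {
  if (length(tt) < 2L) abort("time series too short.")
  gaps <- diff(tt)
  bad <- which(abs(gaps - tau_min) > 1e-6)
  if (length(bad)) {
    abort(sprintf(
      "Non-uniform time grid: gap of %g min between t = %g and t = %g (expected %g).",
      gaps[bad[1L]], tt[bad[1L]], tt[bad[1L] + 1L], tau_min
    ))
  }
  invisible(TRUE)
}

.movavg_shrink <- function(v, window) {
  n <- length(v)
  half <- (window - 1L) %/% 2L
  out <- v
  for (i in seq_len(n)) {
    h <- min(half, i - 1L, n - i)
    out[i] <- mean(v[(i - h):(i + h)])
  }
  out
}

#' Shape modes for a table of contour frames
#'
#' Tidy pipeline from a long contour-vertex table to a per-frame mode table:
#' each `(cell_id, time_min)` group is run through [radial_profile()] and
#' [fourier_modes()].
#'
#' @param contours Data frame with columns `cell_id`, `time_min`, `x_um`,
#'   `y_um` and optionally `vertex_index` (used for ordering).
#' @inheritParams radial_profile
#' @inheritParams fourier_modes
#'
#' @return A tibble with one row per frame: `cell_id`, `time_min`, `r0_um`,
#'   diagnostic `c1`, and complex mode columns `c2 .. c<m_max>`.
#' @export
contours_to_modes <- function(contours, n_theta = 360, smooth_halfwidth = 6,
                              m_max = 3) {
  need <- c("cell_id", "time_min", "x_um", "y_um")
  miss <- setdiff(need, names(contours))
  if (length(miss)) {
    abort(paste0("`contours` is missing column(s): ", paste(miss, collapse = ", ")))
  }
  contours |>
    dplyr::group_by(.data$cell_id, .data$time_min) |>
    dplyr::group_modify(function(df, key) {
      if ("vertex_index" %in% names(df)) df <- dplyr::arrange(df, .data$vertex_index)
      fr <- radial_profile(df,
        n_theta = n_theta, smooth_halfwidth = smooth_halfwidth,
        time_min = key$time_min
      )
      fm <- fourier_modes(fr, m_max = m_max)
      row <- tibble::tibble(r0_um = fm$r0, c1 = fm$c1)
      for (nm in names(fm$modes)) row[[paste0("c", nm)]] <- fm$modes[[nm]]
      row
    }) |>
    dplyr::ungroup()
}
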