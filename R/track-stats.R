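# Trajectory and shape statistics: MSD, autocorrelations, symmetrized
# densities, velocity-correlation persistence segmentation, rotation angles.

#' Minimum-duration inclusion filter
#'
#' Drops cells whose track spans less than `min_h` hours, reporting which.
#'
#' @param tracks Tibble with `cell_id` and `time_min`.
#' @param min_h Minimum duration in hours (default 8.3).
#' @return The filtered tibble.
#' @export
filter_min_duration <- function(tracks, min_h = 8.3) {
  span <- tracks |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(
      dur_h = (max(.data$time_min) - min(.data$time_min)) / 60,
      .groups = "drop"
    )
  drop <- span$cell_id[span$dur_h < min_h]
  if (length(drop)) {
    inform(sprintf(
      "Excluding %d track(s) shorter than %g h: %s",
      length(drop), min_h, paste(drop, collapse = ", ")
    ))
  }
  dplyr::filter(tracks, !(.data$cell_id %in% drop))
}

#' Observation-pipeline velocities for a track table
#'
#' Applies [smooth_and_differentiate()] per cell to the positions: 3-point
#' centred moving average, forward difference over the sampling interval.
#'
#' @param tracks Tibble with `cell_id`, `time_min`, `x_um`, `y_um` on a
#'   uniform grid.
#' @param tau_min Sampling interval in minutes.
#' @param window Moving-average window (odd).
#' @return Tibble `cell_id`, `time_min`, smoothed `x_um`, `y_um`, and complex
#'   `v1` (micrometres per hour; `NA` in each cell's final row).
#' @export
track_velocities <- function(tracks, tau_min = 5, window = 3) {
  tracks |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_modify(function(df, key) {
      sm <- smooth_and_differentiate(
        df[c("time_min", "x_um", "y_um")],
        tau_min = tau_min, window = window
      )
      tibble::tibble(
        time_min = sm$time_min, x_um = sm$x_um_s, y_um = sm$y_um_s,
        v1 = complex(real = sm$d_x_um, imaginary = sm$d_y_um)
      )
    }) |>
    dplyr::ungroup()
}

#' Ensemble mean squared displacement
#'
#' Time-averaged MSD per track over all start points, then an unweighted
#' ensemble mean across tracks, on the sampling-lag grid.
#'
#' @param tracks Tibble with `cell_id`, `time_min`, `x_um`, `y_um`.
#' @param max_lag_min Largest lag in minutes (default: longest usable lag of
#'   the longest track).
#' @return Tibble `lag_min`, `msd` (micrometres squared), `n_pairs` (total
#'   displacement pairs entering the lag) and `n_tracks`.
#' @export
msd <- function(tracks, max_lag_min = NULL) {
  per <- tracks |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_modify(function(df, key) {
      df <- dplyr::arrange(df, .data$time_min)
      n <- nrow(df)
      tau <- diff(df$time_min[1:2])
      lags <- seq_len(n - 1L)
      tibble::tibble(
        lag_min = lags * tau,
        msd_track = vapply(lags, function(k) {
          dx <- df$x_um[(k + 1L):n] - df$x_um[1:(n - k)]
          dy <- df$y_um[(k + 1L):n] - df$y_um[1:(n - k)]
          mean(dx^2 + dy^2)
        }, 0),
        n_pairs = n - lags
      )
    }) |>
    dplyr::ungroup()
  if (!is.null(max_lag_min)) {
    per <- dplyr::filter(per, .data$lag_min <= max_lag_min)
    if (!nrow(per)) abort("`max_lag_min` exceeds every track duration.")
  }
  per |>
    dplyr::group_by(.data$lag_min) |>
    dplyr::summarise(
      msd = mean(.data$msd_track),
      n_pairs = sum(.data$n_pairs),
      n_tracks = dplyr::n(),
      .groups = "drop"
    )
}

#' Log-log slope of the MSD over a lag window
#'
#' Least-squares slope of `log(msd)` against `log(lag)` within the window;
#' 2 is ballistic, 1 diffusive, 1.6-1.7 the superdiffusive short-time range
#' typical of persistent crawling.
#'
#' @param msd_tbl Output of [msd()].
#' @param lag_window Length-2 numeric window in minutes (default 10-60).
#' @return The fitted slope (dimensionless).
#' @export
msd_exponent <- function(msd_tbl, lag_window = c(10, 60)) {
  d <- dplyr::filter(
    msd_tbl,
    .data$lag_min >= lag_window[1], .data$lag_min <= lag_window[2]
  )
  if (nrow(d) < 3L) abort("Fewer than 3 lags inside `lag_window`.")
  if (any(d$msd <= 0)) abort("Non-positive MSD values inside `lag_window`.")
  unname(coef(lm(log(msd) ~ log(lag_min), data = d))[2L])
}

#' Ensemble autocorrelation function
#'
#' Per-track autocorrelation after per-track mean subtraction, normalized to
#' one at lag zero, then an equal-weight average across tracks. For complex
#' series the real part of `<a(t + tau) * Conj(a(t))>` is used.
#'
#' @param data Tibble with `cell_id`, `time_min` and the series column.
#' @param col Column to correlate (tidy-select, e.g. `v1`).
#' @param max_lag_min Largest lag in minutes (default 120).
#' @return Tibble `lag_min`, `acf`, `n_tracks`.
#' @export
autocorr <- function(data, col, max_lag_min = 120) {
  per <- data |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_modify(function(df, key) {
      df <- dplyr::arrange(df, .data$time_min)
      a <- dplyr::pull(df, {{ col }})
      a <- a[!is.na(a)]
      a <- a - mean(a)
      v0 <- mean(Mod(a)^2)
      if (v0 < 1e-300) {
        abort("Zero-variance series: autocorrelation undefined.")
      }
      tau <- diff(df$time_min[1:2])
      kmax <- min(length(a) - 1L, floor(max_lag_min / tau))
      tibble::tibble(
        lag_min = (0:kmax) * tau,
        acf_track = vapply(0:kmax, function(k) {
          n <- length(a)
          Re(mean(a[(k + 1L):n] * Conj(a[1:(n - k)])))
        }, 0) / v0
      )
    }) |>
    dplyr::ungroup()
  per |>
    dplyr::group_by(.data$lag_min) |>
    dplyr::summarise(
      acf = mean(.data$acf_track), n_tracks = dplyr::n(), .groups = "drop"
    )
}

#' Symmetrized component density of a complex series
#'
#' By spatial symmetry the real and imaginary parts of velocity and modes
#' share one distribution; this pools both components into a single
#' density-normalized histogram with bin edges symmetric about zero.
#'
#' @param z Complex (or numeric) sample; for numeric input the values are
#'   used as-is.
#' @param binwidth Bin width in the series' units; default uses the
#'   Freedman-Diaconis rule on the pooled sample.
#' @return Tibble `mid`, `density`, `n` (count per bin).
#' @export
pdf_symmetrized <- function(z, binwidth = NULL) {
  if (!length(z)) abort("empty sample.")
  v <- if (is.complex(z)) c(Re(z), Im(z)) else as.numeric(z)
  v <- v[!is.na(v)]
  if (is.null(binwidth)) {
    binwidth <- 2 * stats::IQR(v) / length(v)^(1 / 3)
    if (binwidth <= 0) binwidth <- 1
  }
  m <- ceiling(max(abs(v)) / binwidth + 0.5)
  edges <- (seq(-m, m) - 0.5) * binwidth # bins centred at multiples of binwidth
  h <- hist(v, breaks = edges, plot = FALSE)
  keep <- h$counts > 0
  tibble::tibble(
    mid = h$mids[keep],
    density = h$counts[keep] / (length(v) * binwidth),
    n = h$counts[keep]
  )
}

#' Short-lag velocity correlation series
#'
#' `CV(t) = vx(t + dt) vx(t) + vy(t + dt) vy(t)`: small when the cell turns
#' sharply or stalls, large during persistent motion.
#'
#' @param velocities Tibble with `cell_id`, `time_min` and complex `v1`
#'   (from [track_velocities()] or a simulation's `derived` table).
#' @param dt_min Correlation interval in minutes (default 10); must be a
#'   multiple of the sampling interval.
#' @return Tibble `cell_id`, `time_min`, `cv` (micrometres squared per hour
#'   squared).
#' @export
velocity_correlation <- function(velocities, dt_min = 10) {
  velocities |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_modify(function(df, key) {
      df <- dplyr::arrange(df, .data$time_min)
      tau <- diff(df$time_min[1:2])
      k <- dt_min / tau
      if (abs(k - round(k)) > 1e-9) {
        abort("`dt_min` must be a multiple of the sampling interval.")
      }
      k <- as.integer(round(k))
      v <- df$v1
      n <- sum(!is.na(v))
      if (n <= k) abort(sprintf("track %s shorter than `dt_min`.", key$cell_id))
      idx <- seq_len(n - k)
      tibble::tibble(
        time_min = df$time_min[idx],
        cv = Re(v[idx + k] * Conj(v[idx]))
      )
    }) |>
    dplyr::ungroup()
}

#' Persistence segmentation of tracks
#'
#' A sample is persistent when its velocity correlation `CV(t)` exceeds
#' `threshold_fraction` of the per-track median of `CV`; maximal runs of
#' persistent samples form segments. Each segment's span includes the step
#' of its last persistent velocity sample, its path length is the summed
#' step length along the (smoothed) positions, and the net displacement is
#' the vector between its endpoints.
#'
#' @param tracks Tibble with `cell_id`, `time_min`, `x_um`, `y_um` on a
#'   uniform grid.
#' @param dt_min `CV` interval in minutes (default 10).
#' @param threshold_fraction Fraction of the per-track median (default 2/3).
#' @param tau_min,window Passed to [track_velocities()].
#' @return Tibble with one row per segment: `cell_id`, `segment`,
#'   `t_start_min`, `t_end_min`, `n_samples`, `path_length_um`, `net_dx_um`,
#'   `net_dy_um`; attribute `cv` holds the per-sample `CV` table with its
#'   persistence flag.
#' @export
persistent_segments <- function(tracks, dt_min = 10, threshold_fraction = 2 / 3,
                                tau_min = 5, window = 3) {
  vel <- track_velocities(tracks, tau_min = tau_min, window = window)
  cv <- velocity_correlation(vel, dt_min = dt_min)
  cv <- cv |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::mutate(persistent = .data$cv > threshold_fraction * median(.data$cv)) |>
    dplyr::ungroup()
  segs <- cv |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_modify(function(df, key) {
      r <- rle(df$persistent)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      runs <- which(r$values)
      if (!length(runs)) {
        return(tibble::tibble(
          segment = integer(0), t_start_min = numeric(0),
          t_end_min = numeric(0), n_samples = integer(0),
          path_length_um = numeric(0), net_dx_um = numeric(0),
          net_dy_um = numeric(0)
        ))
      }
      pos <- vel[vel$cell_id == key$cell_id, ]
      purrr::map_dfr(seq_along(runs), function(j) {
        i0 <- starts[runs[j]]
        i1 <- ends[runs[j]]
        t0 <- df$time_min[i0]
        t1 <- df$time_min[i1] + tau_min # include the last velocity step
        seg <- pos[pos$time_min >= t0 & pos$time_min <= t1, ]
        tibble::tibble(
          segment = j, t_start_min = t0, t_end_min = t1,
          n_samples = i1 - i0 + 1L,
          path_length_um = sum(sqrt(diff(seg$x_um)^2 + diff(seg$y_um)^2)),
          net_dx_um = seg$x_um[nrow(seg)] - seg$x_um[1L],
          net_dy_um = seg$y_um[nrow(seg)] - seg$y_um[1L]
        )
      })
    }) |>
    dplyr::ungroup()
  attr(segs, "cv") <- cv
  segs
}

#' Rotation angles between successive persistent segments
#'
#' The unsigned angle between the net-displacement vectors of consecutive
#' segments of a track, in degrees in `[0, 180]`; 180 marks motion reversal.
#' Pairs involving a zero net displacement are skipped (with a message).
#'
#' @param segments Output of [persistent_segments()].
#' @return Tibble `cell_id`, `angle_deg`.
#' @export
rotation_angles <- function(segments) {
  skipped <- 0L
  out <- segments |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < 2L) {
        return(tibble::tibble(angle_deg = numeric(0)))
      }
      df <- dplyr::arrange(df, .data$segment)
      z <- complex(real = df$net_dx_um, imaginary = df$net_dy_um)
      ok <- Mod(z[-length(z)]) > 0 & Mod(z[-1L]) > 0
      skipped <<- skipped + sum(!ok)
      dphi <- Arg(z[-1L][ok] / z[-length(z)][ok])
      tibble::tibble(angle_deg = abs(dphi) * 180 / pi)
    }) |>
    dplyr::ungroup()
  if (skipped > 0L) {
    inform(sprintf("Skipped %d segment pair(s) with zero net displacement.", skipped))
  }
  out
}

#' Modal rotation-angle bin
#'
#' Centre of the highest-density bin of a rotation-angle histogram with bins
#' centred at multiples of `binwidth` degrees. Because angles are unsigned
#' magnitudes on `[0, 180]`, the end bins at 0 and 180 cover half the width
#' of interior bins and are density-corrected, which is equivalent to
#' binning the symmetric full-circle distribution on `[0, 360)`.
#'
#' @param angles Output of [rotation_angles()], or a numeric vector of
#'   angles in degrees.
#' @param binwidth Bin width in degrees (default 20; must divide 180).
#' @return Centre of the modal bin in degrees.
#' @export
modal_rotation_bin <- function(angles, binwidth = 20) {
  a <- if (is.data.frame(angles)) angles$angle_deg else angles
  a <- a[!is.na(a)]
  if (!length(a)) abort("no angles supplied.")
  if (abs(180 / binwidth - round(180 / binwidth)) > 1e-9) {
    abort("`binwidth` must divide 180.")
  }
  centers <- seq(0, 180, by = binwidth)
  ctr <- pmin(round(a / binwidth) * binwidth, 180)
  cnt <- as.numeric(table(factor(ctr, levels = centers)))
  width <- c(binwidth / 2, rep(binwidth, length(centers) - 2L), binwidth / 2)
  centers[which.max(cnt / width)]
}

#' Empirical complementary cumulative distribution
#'
#' `P(X > x)` evaluated at the sorted sample points.
#'
#' @param values Numeric sample.
#' @return Tibble `value`, `ccdf`.
#' @export
ccdf <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) abort("empty sample.")
  x <- sort(values)
  n <- length(x)
  tibble::tibble(value = x, ccdf = (n - seq_len(n)) / n)
}
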