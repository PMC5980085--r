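# Shared fixtures, all generated in code.

# smooth band-limited complex mode series on the 5-min grid
make_mode_series <- function(n = 500, seed = 1, amp = 2, tau_min = 5) {
  set.seed(seed)
  tt <- seq(0, by = tau_min, length.out = n)
  one <- function() {
    per <- runif(3, 150, 700) # periods in minutes
    ph <- runif(3, 0, 2 * pi)
    a <- amp * runif(3, 0.3, 1)
    re <- rowSums(sapply(1:3, function(k) a[k] * sin(2 * pi * tt / per[k] + ph[k])))
    per <- runif(3, 150, 700)
    ph <- runif(3, 0, 2 * pi)
    im <- rowSums(sapply(1:3, function(k) a[k] * cos(2 * pi * tt / per[k] + ph[k])))
    complex(real = re, imaginary = im)
  }
  tibble::tibble(time_min = tt, c2 = one(), c3 = one())
}

# smoothed/differenced law table with v generated by the migration law
make_law_table <- function(n = 500, seed = 1, beta1 = 1.21, beta2 = 0.24,
                           noise_sd = 0) {
  ms <- make_mode_series(n, seed)
  sm <- smooth_and_differentiate(ms, tau_min = 5)
  k <- nrow(sm) - 1L
  d <- tibble::tibble(
    time_min = sm$time_min[1:k],
    c2 = sm$c2_s[1:k], c3 = sm$c3_s[1:k],
    dc2 = sm$d_c2[1:k], dc3 = sm$d_c3[1:k]
  )
  d$v1 <- predict_velocity(d$c2, d$c3, d$dc2, d$dc3, beta1, beta2)
  if (noise_sd > 0) {
    d$v1 <- d$v1 + complex(
      real = rnorm(k, sd = noise_sd), imaginary = rnorm(k, sd = noise_sd)
    )
  }
  d
}

# polygon from a band-limited shape, optionally rotated/translated
make_contour_polygon <- function(r0 = 20, modes = c("2" = 1.5 + 0.5i, "3" = 0.6 - 0.2i),
                                 n_vertices = 240, rotate = 0, shift = c(0, 0)) {
  th <- 2 * pi * (seq_len(n_vertices) - 1L) / n_vertices
  rot_modes <- modes * exp(1i * as.integer(names(modes)) * rotate)
  r <- reconstruct_profile(r0, rot_modes, th)
  data.frame(
    x = shift[1] + r * cos(th),
    y = shift[2] + r * sin(th)
  )
}

# one shared 35 kPa acceptance-scale ensemble, built lazily and cached for
# the session so several tests can reuse it
.ensemble_cache <- new.env(parent = emptyenv())
acceptance_ensemble <- function(seed = 1, n_cells = 100, duration_h = 16) {
  key <- paste(seed, n_cells, duration_h, sep = "_")
  if (is.null(.ensemble_cache[[key]])) {
    .ensemble_cache[[key]] <- simulate_cells(
      prd_preset("table2_35kPa"),
      sim_config(n_cells = n_cells, duration_h = duration_h, seed = seed)
    )
  }
  .ensemble_cache[[key]]
}
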