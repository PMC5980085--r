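test_that("red-noise force steps and stationary spread are exact", {
  # deterministic decay: sigma = 0
  expect_equal(
    step_force(1 + 0i, kappa_f = 1, sigma = 0, dt_h = 1 / 120, xi = 0),
    1 - 1 / 120 + 0i
  )
  expect_equal(step_force(0i, 1, 0, 1 / 120, 0), 0i)

  # long-run per-component sd -> sigma * sqrt(kappa_f / 2)
  set.seed(5)
  kf <- 2
  dt <- 1 / 120
  n <- 240000 # 2000 h
  f <- complex(1)
  out <- numeric(n)
  xi <- complex(real = rnorm(n), imaginary = rnorm(n))
  for (k in seq_len(n)) {
    f <- step_force(f, kf, 1, dt, xi[k])
    out[k] <- Re(f)
  }
  expect_equal(sd(out[-(1:2000)]), sqrt(kf / 2), tolerance = 0.05)
})

test_that("velocity solve matches a brute-force real 2x2 solve", {
  p <- prd_preset("table2_35kPa")
  set.seed(6)
  for (i in 1:10) {
    st <- list(
      C2 = complex(real = rnorm(1, sd = 6), imaginary = rnorm(1, sd = 6)),
      C3 = complex(real = rnorm(1, sd = 0.8), imaginary = rnorm(1, sd = 0.8)),
      F2 = complex(real = rnorm(1, sd = 4), imaginary = rnorm(1, sd = 4)),
      F3 = complex(real = rnorm(1), imaginary = rnorm(1)),
      F6 = complex(real = rnorm(1, sd = 0.3), imaginary = rnorm(1, sd = 0.3))
    )
    v <- solve_velocity(st, p)
    # oracle: write A v - alpha_v C2 conj(v) = b as a real linear system
    m2 <- Mod(st$C2)^2
    m3 <- Mod(st$C3)^2
    K3 <- p$kappa3 + p$gamma3 * m3
    A <- 1 + p$gamma_v * m2 + p$beta1 * p$alpha2 * m3 - p$beta2 * p$alpha3 * m2
    b <- p$beta1 * (-p$kappa2 * Conj(st$C2) + Conj(st$F2)) * st$C3 -
      p$beta2 * Conj(st$C2) *
        (-K3 * st$C3 + p$beta3 * Conj(st$C3) * st$F6 + st$F3)
    cr <- Re(st$C2)
    ci <- Im(st$C2)
    M <- matrix(
      c(
        A - p$alpha_v * cr, -p$alpha_v * ci,
        -p$alpha_v * ci, A + p$alpha_v * cr
      ),
      2, 2,
      byrow = TRUE
    )
    pq <- solve(M, c(Re(b), Im(b)))
    expect_equal(v, complex(real = pq[1], imaginary = pq[2]), tolerance = 1e-12)
  }

  # decoupled reduction: alpha_v = couplings = 0 gives the bare law on dC/dt
  p0 <- prd_preset("table2_35kPa",
    alpha_v = 0, gamma_v = 0, alpha2 = 0, alpha3 = 0
  )
  st <- list(C2 = 2 - 1i, C3 = 0.5 + 0.2i, F2 = 1 + 2i, F3 = 0.3i, F6 = 0.1)
  K3 <- p0$kappa3 + p0$gamma3 * Mod(st$C3)^2
  expect_equal(
    solve_velocity(st, p0),
    p0$beta1 * (-p0$kappa2 * Conj(st$C2) + Conj(st$F2)) * st$C3 -
      p0$beta2 * Conj(st$C2) *
        (-K3 * st$C3 + p0$beta3 * Conj(st$C3) * st$F6 + st$F3),
    tolerance = 1e-12
  )

  # vanished modes: both law terms carry a mode factor
  st0 <- list(C2 = 0i, C3 = 0i, F2 = 3 + 1i, F3 = 1 - 2i, F6 = 0.5 + 0i)
  expect_equal(solve_velocity(st0, p), 0 + 0i)

  # singular denominator flags parameter instability
  psing <- prd_preset("table2_35kPa",
    alpha_v = 1, gamma_v = 0, alpha2 = 0, alpha3 = 0
  )
  expect_error(
    solve_velocity(list(C2 = 1 + 0i, C3 = 0i, F2 = 0i, F3 = 0i, F6 = 0i), psing),
    "Singular velocity"
  )
})

test_that("zero state with zero noise is a fixed point", {
  p <- prd_preset("table2_35kPa")
  st <- list(
    t_h = 0, x = 0i, C2 = 0i, C3 = 0i, F2 = 0i, F3 = 0i, F6 = 0i, v1 = 0i
  )
  for (k in 1:20) st <- step_cell(st, p, 1 / 120, c(0i, 0i, 0i))
  expect_equal(st$C2, 0i)
  expect_equal(st$C3, 0i)
  expect_equal(st$x, 0i)
  expect_equal(st$t_h, 20 / 120)
})

test_that("linear-limit stationary variance of C2 matches the closed form", {
  p <- prd_preset("table2_35kPa",
    alpha_v = 0, gamma_v = 0, alpha2 = 0, alpha3 = 0, gamma3 = 0, beta3 = 0
  )
  dt <- 1 / 120
  n <- 120000 # 1000 h
  set.seed(8)
  xi <- array(complex(real = rnorm(3 * n), imaginary = rnorm(3 * n)), c(n, 1, 3))
  sim <- prd_integrate(p, xi, dt, record_every = 10L)
  c2 <- sim$C2[sim$t_h > 30, 1] # discard transient
  target <- (p$kappa_f * p$sigma2^2 / 2) / (p$kappa2 * (p$kappa2 + p$kappa_f))
  expect_equal(var(Re(c2)), target, tolerance = 0.3)
  expect_equal(var(Im(c2)), target, tolerance = 0.3)

  # no-noise decay from a nonzero state is monotone when couplings are off
  init <- list(C2 = 5 + 2i, C3 = 1 - 1i)
  xi0 <- array(0i, c(600, 1, 3))
  dec <- prd_integrate(p, xi0, dt, init = init, record_every = 10L)
  expect_true(all(diff(Mod(dec$C2[, 1])) < 0))
  expect_true(all(diff(Mod(dec$C3[, 1])) < 0))
})

test_that("integration converges at first order on frozen noise paths", {
  p <- prd_preset("table2_35kPa")
  set.seed(12)
  n4 <- 4800 # 10 h at dt/4
  z <- array(complex(real = rnorm(3 * n4), imaginary = rnorm(3 * n4)), c(n4, 1, 3))
  agg <- function(x, fac) {
    # sum consecutive draws / sqrt(fac): same Brownian path, coarser grid
    n <- dim(x)[1] / fac
    out <- array(0i, c(n, 1, 3))
    for (j in 1:3) {
      out[, 1, j] <- colSums(matrix(x[, 1, j], nrow = fac)) / sqrt(fac)
    }
    out
  }
  dt4 <- 1 / 480
  end <- function(xi, dt) {
    s <- prd_integrate(p, xi, dt, record_every = dim(xi)[1])
    s$state$C2
  }
  e_coarse <- end(agg(z, 4), 4 * dt4)
  e_mid <- end(agg(z, 2), 2 * dt4)
  e_fine <- end(z, dt4)
  d1 <- Mod(e_coarse - e_mid)
  d2 <- Mod(e_mid - e_fine)
  expect_gt(d1 / d2, 1.3) # halving dt roughly halves the error
  expect_lt(d1 / d2, 4)
})

test_that("simulator is rotation-equivariant on frozen noise", {
  p <- prd_preset("table2_35kPa")
  set.seed(13)
  n <- 1200
  xi <- array(complex(real = rnorm(3 * n), imaginary = rnorm(3 * n)), c(n, 1, 3))
  th0 <- 0.83
  rot <- xi
  rot[, , 1] <- xi[, , 1] * exp(2i * th0)
  rot[, , 2] <- xi[, , 2] * exp(3i * th0)
  rot[, , 3] <- xi[, , 3] * exp(6i * th0)
  base <- prd_integrate(p, xi, 1 / 120, record_every = 60L)
  turned <- prd_integrate(p, rot, 1 / 120, record_every = 60L)
  expect_equal(turned$C2, base$C2 * exp(2i * th0), tolerance = 1e-9)
  expect_equal(turned$C3, base$C3 * exp(3i * th0), tolerance = 1e-9)
  expect_equal(turned$x, base$x * exp(1i * th0), tolerance = 1e-9)
  expect_equal(turned$v1, base$v1 * exp(1i * th0), tolerance = 1e-9)
})

test_that("velocity schemes agree in the small-step limit", {
  p <- prd_preset("table2_35kPa")
  set.seed(14)
  n <- 2400 # 5 h at dt/2
  z <- array(complex(real = rnorm(3 * n), imaginary = rnorm(3 * n)), c(n, 1, 3))
  coarse <- array(0i, c(n / 2, 1, 3))
  for (j in 1:3) coarse[, 1, j] <- colSums(matrix(z[, 1, j], nrow = 2)) / sqrt(2)
  gap <- function(xi, dt) {
    a <- prd_integrate(p, xi, dt, scheme = "self-consistent", record_every = dim(xi)[1])
    b <- prd_integrate(p, xi, dt, scheme = "lagged", record_every = dim(xi)[1])
    Mod(a$state$C2 - b$state$C2) + Mod(a$state$x - b$state$x)
  }
  expect_lt(gap(z, 1 / 240), gap(coarse, 1 / 120))
})

test_that("sampled simulations are reproducible and well-formed", {
  p <- prd_preset("table2_35kPa")
  cfg <- sim_config(n_cells = 3, duration_h = 9, burnin_h = 1, seed = 7)
  s1 <- simulate_cells(p, cfg)
  s2 <- simulate_cells(p, cfg)
  expect_identical(s1$tracks, s2$tracks)
  expect_identical(s1$modes, s2$modes)

  # cell 1 of an ensemble equals a single-cell run with the same master seed
  single <- simulate_cell(p, sim_config(duration_h = 9, burnin_h = 1, seed = 7))
  expect_equal(
    dplyr::filter(s1$tracks, cell_id == 1),
    single$tracks
  )

  # 5-min grid, duration, burn-in reset
  tt <- dplyr::filter(s1$tracks, cell_id == 2)$time_min
  expect_equal(diff(tt), rep(5, length(tt) - 1))
  expect_equal(max(tt), 9 * 60)

  # observation noise has the configured spread about the true positions
  pf <- prd_preset("table2_35kPa", sigma2 = 0, sigma3 = 0, sigma6 = 0)
  cf <- sim_config(n_cells = 20, duration_h = 10, burnin_h = 0, seed = 3)
  sf <- simulate_cells(pf, cf)
  expect_equal(sf$truth$x_true, rep(0, nrow(sf$truth)))
  err <- sf$tracks$x_um
  expect_equal(sd(err), 1, tolerance = 0.05)

  expect_error(sim_config(duration_h = 4), "minimum analysable")
  expect_error(sim_config(dt_min = 3, sample_min = 5), "multiple")
})

test_that("preset noise scales reproduce the published non-dimensional forces", {
  p <- prd_preset("table2_35kPa")
  expect_equal(nondimensional_force(p$sigma2, p$r0, p$kappa2), 0.66)
  expect_equal(nondimensional_force(p$sigma3, p$r0, p$kappa3), 0.026)
  p4 <- prd_preset("table2_410kPa")
  expect_equal(p4$beta1, 0.59)
  expect_equal(nondimensional_force(p4$sigma3, p4$r0, p4$kappa3), 0.076)
})

test_that("coupling terms must conserve the rotation order", {
  expect_true(validate_coupling_term(1, c(-2, 3))) # conj(C2) C3 -> v1
  expect_true(validate_coupling_term(1, c(-1, 2))) # conj(v1) C2 -> v1
  expect_false(validate_coupling_term(1, c(2, 3)))
  expect_true(validate_coupling_term(3, c(-3, 6))) # conj(C3) F6 -> C3
  expect_true(validate_coupling_term(2, c(-1, 3))) # conj(v1) C3 -> C2
  expect_false(validate_coupling_term(2, c(1, 3)))
  expect_error(validate_coupling_term(2, c(0, 2)), "nonzero integers")
})
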