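test_that("velocity law evaluates its defining products", {
  expect_equal(predict_velocity(1 + 1i, 2, 0, 0, 1.21, 0.24), 0 + 0i)
  expect_equal(predict_velocity(0, 1 + 0i, 1 + 0i, 0, 1, 0), 1 + 0i)
  # direct complex-arithmetic case
  expect_equal(
    predict_velocity(1 + 1i, 2 + 0i, 1i, 1 - 1i, 0.29, 0.11),
    -0.36i,
    tolerance = 1e-12
  )
  # general law: betac = 0 reduces exactly; single-term case; all zero
  z <- list(c2 = 1.2 - 0.3i, c3 = -0.5 + 2i, dc2 = 0.1 + 1i, dc3 = -1 + 0.4i)
  expect_equal(
    predict_velocity_general(z$c2, z$c3, z$dc2, z$dc3, 0.29, 0.11, 0),
    predict_velocity(z$c2, z$c3, z$dc2, z$dc3, 0.29, 0.11)
  )
  expect_equal(predict_velocity_general(1, 1i, 5, 5, 0, 0, 1), 1i)
  expect_equal(predict_velocity_general(z$c2, z$c3, z$dc2, z$dc3, 0, 0, 0), 0 + 0i)
})

test_that("mobility fit recovers generating coefficients", {
  d <- make_law_table(500, seed = 2, beta1 = 1.21, beta2 = 0.24)
  f <- fit_mobility(d)
  expect_equal(unname(f$coefficients[["beta1"]]), 1.21, tolerance = 1e-10)
  expect_equal(unname(f$coefficients[["beta2"]]), 0.24, tolerance = 1e-10)
  expect_lt(f$residual_s, 1e-16)
  expect_lt(f$coefficients[["beta2"]], f$coefficients[["beta1"]])

  # general-law recovery including the shape-determined term
  d2 <- make_law_table(400, seed = 3)
  d2$v1 <- predict_velocity_general(d2$c2, d2$c3, d2$dc2, d2$dc3, 0.8, 0.2, 0.05)
  f2 <- fit_mobility(d2, include_general = TRUE)
  expect_equal(
    unname(f2$coefficients), c(0.8, 0.2, 0.05),
    tolerance = 1e-8
  )

  # broom-style accessors
  td <- tidy(f)
  expect_named(td, c("term", "estimate", "std.error", "conf.low", "conf.high"))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  expect_equal(glance(f)$n_obs, f$n_obs)
})

test_that("mobility fit handles orthogonal, noisy and degenerate inputs", {
  # regressors purely real, observed velocity purely imaginary: beta = 0
  tt <- seq_len(50)
  d <- tibble::tibble(
    c2 = complex(real = sin(tt)), c3 = complex(real = cos(tt / 3)),
    dc2 = complex(real = cos(tt / 2)), dc3 = complex(real = sin(tt / 5)),
    v1 = complex(imaginary = rnorm(50))
  )
  f <- fit_mobility(d)
  expect_equal(unname(f$coefficients), c(0, 0), tolerance = 1e-10)

  # unbiased under isotropic noise (within 3 standard errors)
  set.seed(9)
  dn <- make_law_table(10000, seed = 11, beta1 = 1.21, beta2 = 0.24, noise_sd = 4)
  fn <- fit_mobility(dn)
  expect_lt(abs(fn$coefficients[["beta1"]] - 1.21) / fn$se[["beta1"]], 3)
  expect_lt(abs(fn$coefficients[["beta2"]] - 0.24) / fn$se[["beta2"]], 3)

  # collinear regressors: conj(dc2) c3 proportional to -conj(c2) dc3
  ones <- rep(1 + 0i, 20)
  dc <- tibble::tibble(
    c2 = ones, c3 = complex(real = rnorm(20)),
    dc2 = -2 * Conj(complex(real = Re(ones))) * 0 + 1 + 0i, dc3 = ones * 0,
    v1 = complex(real = rnorm(20))
  )
  dc$dc3 <- -2 * Conj(dc$dc2) * dc$c3 / Conj(dc$c2) # x2 = 2 x1
  expect_error(fit_mobility(dc), "Rank-deficient")

  # all-zero regressors are dropped with a message, then too few remain
  dz <- tibble::tibble(
    c2 = complex(4), c3 = complex(4), dc2 = complex(4), dc3 = complex(4),
    v1 = complex(real = rnorm(4))
  )
  expect_error(suppressMessages(fit_mobility(dz)), "at least 3")
  expect_error(fit_mobility(dz[, -1]), "missing column")
})

test_that("law is rotation-equivariant and time-reverse antisymmetric", {
  set.seed(21)
  for (i in 1:5) {
    z <- complex(real = rnorm(4), imaginary = rnorm(4))
    th0 <- runif(1, 0, 2 * pi)
    v <- predict_velocity(z[1], z[2], z[3], z[4], 1.21, 0.24)
    vr <- predict_velocity(
      z[1] * exp(2i * th0), z[2] * exp(3i * th0),
      z[3] * exp(2i * th0), z[4] * exp(3i * th0), 1.21, 0.24
    )
    expect_equal(vr, v * exp(1i * th0), tolerance = 1e-12)
  }

  # reversing a mode trajectory negates the velocity at matched midpoints
  ms <- make_mode_series(80, seed = 5)
  tau_h <- 5 / 60
  mid <- function(z) (z[-1] + z[-length(z)]) / 2
  dz <- function(z) diff(z) / tau_h
  v_fwd <- predict_velocity(mid(ms$c2), mid(ms$c3), dz(ms$c2), dz(ms$c3), 1.21, 0.24)
  r2 <- rev(ms$c2)
  r3 <- rev(ms$c3)
  v_rev <- predict_velocity(mid(r2), mid(r3), dz(r2), dz(r3), 1.21, 0.24)
  expect_equal(v_rev, -rev(v_fwd), tolerance = 1e-12)

  # speed grows with either deformation rate (direction-only property)
  set.seed(22)
  n <- 4000
  dc2 <- complex(real = rnorm(n), imaginary = rnorm(n))
  dc3 <- complex(real = rnorm(n), imaginary = rnorm(n))
  c2 <- complex(real = rnorm(n), imaginary = rnorm(n))
  c3 <- complex(real = rnorm(n), imaginary = rnorm(n))
  sp <- Mod(predict_velocity(c2, c3, dc2, dc3, 1.21, 0.24))
  expect_gt(cor(sp, Mod(dc2)), 0)
  expect_gt(cor(sp, Mod(dc3)), 0)
})

test_that("joint phase distribution localizes correlated phases", {
  set.seed(31)
  a <- complex(real = rnorm(5000), imaginary = rnorm(5000))

  # identical phases: all mass within the diagonal band
  jd <- phase_joint_distribution(a, a, n_bins = 24)
  on_diag <- sum(jd$density$prob[jd$density$arg_a == jd$density$arg_b])
  expect_equal(on_diag, 1, tolerance = 1e-12)
  expect_equal(jd$phase_diff_concentration, 1, tolerance = 1e-12)

  # conjugate: mass on the anti-diagonal
  jc <- phase_joint_distribution(a, Conj(a), n_bins = 24)
  anti <- sum(jc$density$prob[
    abs(jc$density$arg_a + jc$density$arg_b) < 1e-9
  ])
  expect_equal(anti, 1, tolerance = 1e-12)

  # independent uniform phases: chi-square does not reject uniformity
  b <- complex(real = rnorm(10000), imaginary = rnorm(10000))
  a2 <- complex(real = rnorm(10000), imaginary = rnorm(10000))
  ju <- phase_joint_distribution(a2, b, n_bins = 12)
  counts <- ju$density$prob * 10000
  chi <- sum((counts - mean(counts))^2 / mean(counts))
  expect_lt(chi, qchisq(0.999, df = 144 - 1))
  expect_lt(ju$phase_diff_concentration, 0.05)

  expect_error(phase_joint_distribution(complex(0), complex(0)), "No samples")
})

test_that("binned velocity agreement lies on the identity for exact data", {
  set.seed(41)
  v <- complex(real = rnorm(2000, sd = 15), imaginary = rnorm(2000, sd = 15))
  b <- binned_velocity_agreement(v, v, gamma = 12)
  expect_true(all(abs(b$mean_obs - b$center) <= 6)) # within half a bin
  expect_equal(sum(b$n[b$component == "x"]), 2000)

  # predictions exactly at bin centres: identity means with zero spread
  vd <- complex(real = 12 * sample(-2:2, 500, TRUE), imaginary = 0)
  bd <- binned_velocity_agreement(vd, vd, gamma = 12)
  bx <- dplyr::filter(bd, component == "x")
  expect_equal(bx$mean_obs, bx$center)
  expect_true(all(bx$sd_obs[bx$n > 1] == 0))

  # one bin only
  b1 <- binned_velocity_agreement(rep(1 + 1i, 7), rep(2 + 2i, 7), gamma = 12)
  expect_equal(nrow(b1), 2) # one bin per component
  expect_true(all(b1$n == 7))

  # noisy observations: per-bin means near identity within standard error
  vn <- v + complex(real = rnorm(2000, sd = 4), imaginary = rnorm(2000, sd = 4))
  bn <- binned_velocity_agreement(v, vn, gamma = 12)
  big <- dplyr::filter(bn, n >= 30)
  expect_true(all(abs(big$mean_obs - big$center) <
    6 + 3 * big$sd_obs / sqrt(big$n)))
  expect_s3_class(attr(bn, "range99"), "tbl_df")
})

test_that("archetype motions displace as the law predicts", {
  # elongation case: centroid moves along the extended pseudopod (+x)
  a <- archetype_motion("elongation", beta1 = 1.21, beta2 = 0.24)
  expect_gt(Re(a$displacement), 0)
  expect_lt(abs(Im(a$displacement)), 1e-10 * Mod(a$displacement))

  # zero ramp: no displacement
  z <- archetype_motion("elongation", c2_range = c(2, 2), c3_range = c(1, 1))
  expect_equal(Mod(z$displacement), 0, tolerance = 1e-12)

  # time-reversed ramp exactly negates the displacement
  for (case in c("elongation", "bipolar", "repolarize")) {
    fwd <- archetype_motion(case, c2_range = c(0.5, 3), c3_range = c(0.4, 1.8))
    bwd <- archetype_motion(case, c2_range = c(3, 0.5), c3_range = c(1.8, 0.4))
    expect_equal(bwd$displacement, -fwd$displacement, tolerance = 1e-12)
  }
  expect_error(archetype_motion("sideways"), "arg")
})
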