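test_that("rectangle dimensions follow the closed form and conserve area", {
  d0 <- rect_dims(100, 0)
  expect_equal(d0$L, 10, tolerance = 1e-12)
  expect_equal(d0$h, 10, tolerance = 1e-12)
  d <- rect_dims(100, 0.5)
  expect_equal(d$L, 16.487, tolerance = 1e-4)
  expect_equal(d$h, 6.0653, tolerance = 1e-4)
  expect_equal(d$L * d$h, 100, tolerance = 1e-10)
  ## aspect ratio convention ar = exp(2 Q_xx)
  expect_equal(d$L / d$h, exp(2 * 0.5), tolerance = 1e-12)
  expect_error(rect_dims(-1, 0), "positive")
})

test_that("the rearrangement step matches limits and the ODE oracle", {
  ## algebraic no-delay limit: R = Q/tau_r + lambda instantly
  expect_equal(step_rearrangement(0.5, 0.18, 0.18, 1.8, 0, 0, 1 / 12),
               0.10, tolerance = 1e-12)
  ## step response approaches the drive with time constant tau_d
  tau_d <- 2; tau_r <- 1.5; lam <- -0.08; q <- 0.3
  r <- 0
  dt <- 0.01
  for (i in 1:200) r <- step_rearrangement(r, q, q, tau_r, tau_d, lam, dt)
  target <- q / tau_r + lam
  analytic <- target * (1 - exp(-2 / tau_d))
  expect_equal(r, analytic, tolerance = 1e-10)
  ## against the adaptive ODE oracle for a time-varying Q
  tt <- seq(0, 10, by = 0.25)
  qq <- 0.2 * sin(tt / 2)
  sim <- simulate_eq5(tt, qq, tau_r, tau_d, lam, r0 = 0.02)
  r2 <- 0.02
  for (i in seq_len(length(tt) - 1))
    r2 <- step_rearrangement(r2, qq[i], qq[i + 1], tau_r, tau_d, lam, 0.25)
  expect_equal(r2, sim$r[length(tt)], tolerance = 1e-7)
})

test_that("the delayed law has fixed point Q = -tau_r * lambda", {
  tau_r <- 1.8; lam <- -0.10
  q_star <- -tau_r * lam
  sim <- simulate_eq5(seq(0, 80, by = 0.5), rep(q_star, 161), tau_r, 3.7, lam,
                      r0 = 0.3)
  expect_equal(sim$r[161], 0, tolerance = 1e-9)
})

test_that("noise-free trajectories return the generating coefficients", {
  tt <- seq(0, 16, by = 1 / 12)
  qq <- ifelse(tt < 6, 0.2 * (3 * (tt / 6)^2 - 2 * (tt / 6)^3),
               0.18 + 0.02 * exp(-(tt - 6) / 2))
  sim <- simulate_eq5(tt, qq, tau_r = 1.8, tau_d = 3.7, lambda = -0.10)
  fit <- fit_eq5(sim)
  expect_equal(fit$tau_r, 1.8, tolerance = 1e-3)
  expect_equal(fit$tau_d, 3.7, tolerance = 1e-3)
  expect_equal(fit$lambda, -0.10, tolerance = 1e-3)
  expect_false(fit$weak_delay)
  ## no-delay data: fitted tau_d collapses to zero, (Q, R) collinear
  sim0 <- simulate_eq5(tt, qq, 1.8, 0, -0.10)
  fit0 <- fit_eq5(sim0)
  expect_lt(fit0$tau_d, 1e-4)
  expect_gt(suppressWarnings(summary(lm(sim0$r ~ sim0$q)))$r.squared,
            1 - 1e-10)
})

test_that("joint fits share time scales and separate the per-wing drives", {
  tt <- seq(0, 16, by = 1 / 6)
  qq <- 0.2 * pmin(tt / 6, 1) * exp(-pmax(tt - 8, 0) / 40)
  wings <- lapply(c(-0.11, -0.09, -0.068), function(lam)
    simulate_eq5(tt, qq, tau_r = 1.7, tau_d = 4.2, lambda = lam))
  jf <- fit_eq5(wings)
  expect_equal(jf$tau_r, 1.7, tolerance = 1e-3)
  expect_equal(jf$tau_d, 4.2, tolerance = 1e-3)
  expect_equal(jf$lambda, c(-0.11, -0.09, -0.068), tolerance = 1e-3)
})

test_that("noisy refits are unbiased with near-nominal uncertainty", {
  set.seed(84)
  tt <- seq(0, 16, by = 1 / 6)
  qq <- ifelse(tt < 6, 0.2 * (3 * (tt / 6)^2 - 2 * (tt / 6)^3),
               0.18 + 0.02 * exp(-(tt - 6) / 2))
  clean <- simulate_eq5(tt, qq, 1.8, 3.7, -0.10)
  sd_noise <- 0.05 * diff(range(clean$r))
  est <- t(replicate(30, {
    noisy <- clean
    noisy$r <- clean$r + rnorm(nrow(clean), 0, sd_noise)
    coef(fit_eq5(noisy))[c("tau_r", "tau_d")]
  }))
  expect_equal(mean(est[, "tau_r"]), 1.8, tolerance = 0.15)
  expect_equal(mean(est[, "tau_d"]), 3.7, tolerance = 0.15)
  ## RMSE stays moderate at this noise level
  expect_lt(sqrt(mean((est[, "tau_d"] - 3.7)^2)), 1.5)
})

test_that("the fitted transient spirals toward the fixed point without crossing", {
  tt <- seq(0, 30, by = 0.1)
  qq <- ifelse(tt < 6, 0.25 * (3 * (tt / 6)^2 - 2 * (tt / 6)^3),
               0.18 + 0.07 * exp(-(tt - 6) / 3))
  sim <- simulate_eq5(tt, qq, 1.8, 3.7, -0.10)
  expect_false(path_self_intersects(sim$q, sim$r))
  ## end point approaches (Q*, 0)
  expect_equal(sim$q[length(tt)], 0.18, tolerance = 1e-3)
  expect_lt(abs(sim$r[length(tt)]), 0.01)
})

test_that("the two-rectangle model holds its geometric identities and statics", {
  par <- rect_params(tau_d = 1, tau_r = 2, lambda_xx = -0.05, zeta_xx = 0.2,
                     lambda_xx_h = -0.02, etabar = 5)
  bnd <- rect_boundary()
  init <- list(blade_area = 0.75, hinge_area = 0.25, qt_b = 0.1, qt_h = -0.1,
               q_b = 0.05, r_b = -0.02, q_h = 0, r_h = 0, a_cell = 1, a0 = 1)
  ## all drives off from an isotropic initial state: static forever
  par0 <- rect_params(zeta_xx = 0, lambda_xx = 0, lambda_xx_h = 0,
                      zetabar = 0, tau_d = 1, tau_d_h = 1)
  init0 <- list(blade_area = 0.75, hinge_area = 0.25, qt_b = 0, qt_h = 0,
                q_b = 0, r_b = 0, q_h = 0, r_h = 0, a_cell = 1, a0 = 1)
  tr0 <- simulate_rectangle_model(par0, bnd,
                                  list(hinge_area = 0.25, kd = 0, ke = 0),
                                  init0, t_span = c(0, 5), dt = 0.5)
  expect_lt(max(abs(tr0$q_b)), 1e-10)
  expect_lt(max(abs(tr0$blade_area - 0.75)), 1e-9)
  ## imposed hinge area is tracked and h*L = A holds at every step
  inputs <- list(hinge_area = function(t) 0.25 - 0.05 * pmin(t / 8, 1),
                 kd = 0.02, ke = 0.005)
  tr <- simulate_rectangle_model(par, bnd, inputs, init,
                                 t_span = c(0, 16), dt = 0.1)
  expect_lt(max(abs(tr$hinge_area - inputs$hinge_area(tr$time))), 1e-5)
  expect_lt(max(abs(tr$L_b * tr$h_b - tr$blade_area)), 1e-10)
  ## constant inputs: converges to the steady state R = 0, Q = -tau_r*lambda
  tr2 <- simulate_rectangle_model(par, bnd,
                                  list(hinge_area = 0.25, kd = 0, ke = 0),
                                  init, t_span = c(0, 250), dt = 1)
  n <- nrow(tr2)
  expect_equal(tr2$q_b[n], -par$tau_r * par$lambda_xx, tolerance = 1e-6)
  expect_lt(abs(tr2$r_b[n]), 1e-7)
  expect_equal(tr2$q_h[n], -par$tau_r_h * par$lambda_xx_h, tolerance = 1e-5)
  ## step-halving convergence of the output discretization
  tr_c <- simulate_rectangle_model(par, bnd, inputs, init,
                                   t_span = c(0, 8), dt = 0.2)
  tr_f <- simulate_rectangle_model(par, bnd, inputs, init,
                                   t_span = c(0, 8), dt = 0.1)
  expect_equal(tr_c$q_b[nrow(tr_c)], tr_f$q_b[nrow(tr_f)], tolerance = 1e-6)
})

test_that("hinge contraction with a fixed distal end gives the wild-type signature", {
  ## phase I/II: Q_xx rises then falls while cumulative shear keeps rising
  par <- rect_params()
  bnd <- rect_boundary(distal_attachment = "fixed")
  inputs <- list(hinge_area = function(t) 0.25 - 0.10 * pmin((t - 16) / 16, 1),
                 kd = 0.03, ke = 0.005)
  init <- list(blade_area = 0.75, hinge_area = 0.25, qt_b = 0.1, qt_h = -0.1,
               q_b = 0.17, r_b = -0.05, q_h = 0, r_h = 0, a_cell = 1, a0 = 1)
  tr <- simulate_rectangle_model(par, bnd, inputs, init,
                                 t_span = c(16, 32), dt = 0.1)
  ipk <- which.max(tr$q_b)
  expect_gt(tr$q_b[ipk], tr$q_b[1] + 0.05)      # rises markedly
  expect_lt(tr$q_b[nrow(tr)], tr$q_b[ipk] - 0.05) # then falls
  expect_gt(ipk, 10); expect_lt(ipk, nrow(tr) - 10) # interior peak
  ## cumulative shear keeps rising once past the initial transient in
  ## which the rearrangement rate adjusts to the flow
  cum <- cumsum(tr$shear_b) * 0.1
  late <- tr$time > 17
  expect_gt(min(diff(cum[late])), 0)
  ## removing the distal attachment reverses the net shear direction
  bnd_free <- rect_boundary(k_pd = 0.005, distal_attachment = "free")
  trf <- simulate_rectangle_model(par, bnd_free, inputs, init,
                                  t_span = c(16, 32), dt = 0.1)
  expect_gt(sum(tr$shear_b), 0)   # PD-oriented in the attached wing
  expect_lt(sum(trf$shear_b), 0)  # AP-oriented when detached
})

test_that("simulate-then-fit recovers free parameters; frozen masks only evaluate", {
  par <- rect_params()
  bnd <- rect_boundary()
  inputs <- list(hinge_area = function(t) 0.25 - 0.08 * pmin((t - 16) / 8, 1),
                 kd = 0.03, ke = 0.005)
  init <- list(blade_area = 0.75, hinge_area = 0.25, qt_b = 0.1, qt_h = -0.1,
               q_b = 0.17, r_b = -0.05, q_h = 0, r_h = 0, a_cell = 1, a0 = 1)
  tr <- simulate_rectangle_model(par, bnd, inputs, init,
                                 t_span = c(16, 32), dt = 0.2)
  ds <- list(list(observed = tr[, c("time", "shear_b", "q_b", "blade_area")],
                  inputs = inputs, init = init, boundary = bnd))
  fit <- fit_rectangle_model(ds, params = rect_params(etabar = 30),
                             free = "etabar", dt = 0.2)
  expect_equal(fit$params$etabar, 49, tolerance = 0.01)
  expect_lt(fit$value, 1e-6)
  ## all-frozen mask: no optimization, residual equals forward simulation
  frozen <- fit_rectangle_model(ds, params = par, free = character(0),
                                dt = 0.2)
  expect_lt(frozen$value, 1e-12)
  expect_error(fit_rectangle_model(ds, free = "not_a_parameter"),
               "unknown free parameters")
})
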