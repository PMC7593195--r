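test_that("latent-to-data conversion handles both links", {
  st <- latent_state(c(sdl = 20, mat = 0), extra_var = c(sdl = 0, mat = 0))
  m <- latent_to_data_mean(st)
  expect_equal(m[["sdl"]], 20)      # identity link
  expect_equal(m[["mat"]], 0.5)     # probit symmetry

  # marginalization over extra latent variance vs Monte-Carlo integration
  set.seed(2)
  st2 <- latent_state(c(sdl = 20, mat = 1), extra_var = c(sdl = 0, mat = 1))
  p_analytic <- latent_to_data_mean(st2)[["mat"]]
  expect_equal(p_analytic, pnorm(1 / sqrt(2)))
  n_mc <- 1e6
  liab <- 1 + rnorm(n_mc, 0, sqrt(1)) + rnorm(n_mc, 0, 1) # extra var + residual
  p_mc <- mean(liab > 0)
  se <- sqrt(p_mc * (1 - p_mc) / n_mc)
  expect_lt(abs(p_analytic - p_mc), 3 * se)
})

test_that("gradient back-transformation equals the probit Jacobian", {
  st <- latent_state(c(sdl = 20, mat = 0), extra_var = c(sdl = 0, mat = 0))
  expect_equal(data_gradient_to_latent(c(sdl = 0, mat = 0), st), c(sdl = 0, mat = 0))
  bl <- data_gradient_to_latent(c(sdl = 0.7, mat = 1), st)
  expect_equal(bl[["sdl"]], 0.7)               # identity link untouched
  expect_equal(bl[["mat"]], dnorm(0), tolerance = 1e-12)

  # central-difference oracle on the data-scale mean
  st3 <- latent_state(c(sdl = 20, mat = 0.8), extra_var = c(sdl = 0, mat = 1.7))
  h <- 1e-5
  up <- latent_state(c(sdl = 20, mat = 0.8 + h), extra_var = st3$extra_var)
  dn <- latent_state(c(sdl = 20, mat = 0.8 - h), extra_var = st3$extra_var)
  deriv <- (latent_to_data_mean(up)[["mat"]] - latent_to_data_mean(dn)[["mat"]]) / (2 * h)
  expect_equal(data_gradient_to_latent(c(sdl = 0, mat = 1), st3)[["mat"]],
               deriv, tolerance = 1e-7)
})

test_that("response recursion obeys the Lande-Arnold update", {
  g <- matrix(c(1, 0.6, 0.6, 1), 2)
  st <- latent_state(c(sdl = 0, mat = 0), extra_var = c(sdl = 0, mat = 0))

  # one generation, no drift: delta mu = G beta (Jacobian 1 for sdl; for mat
  # supply the latent gradient via a data gradient that converts to -1)
  beta_lat <- c(sdl = 1, mat = -1)
  beta_dat <- c(sdl = 1, mat = -1 / (dnorm(0) / 1)) # converts back to -1 at mu = 0
  pr <- predict_response(g, beta_dat, st, n_generations = 1, drift = FALSE,
                         refresh_jacobian = FALSE)
  lat <- pr[pr$scale == "latent" & pr$generation == 1, ]
  expect_equal(lat$median[lat$trait == "sdl"], 0.4, tolerance = 1e-10)
  expect_equal(lat$median[lat$trait == "mat"], -0.4, tolerance = 1e-10)

  # beta = 0 without drift: stasis, deterministic, seed-invariant
  st1 <- latent_state(c(sdl = 3, mat = 1), extra_var = c(sdl = 0, mat = 0))
  p1 <- predict_response(g, c(sdl = 0, mat = 0), st1, n_generations = 5,
                         drift = FALSE, seed = 1)
  p2 <- predict_response(g, c(sdl = 0, mat = 0), st1, n_generations = 5,
                         drift = FALSE, seed = 999)
  expect_identical(p1$median, p2$median)
  expect_true(all(p1$median[p1$scale == "latent" & p1$trait == "sdl"] == 3))
  expect_equal(p1$lo, p1$hi) # deterministic: degenerate intervals

  # zero generations returns the starting state
  p0 <- predict_response(g, beta_dat, st1, n_generations = 0, drift = FALSE)
  expect_equal(p0$median[p0$scale == "latent" & p0$trait == "sdl"], 3)

  # breeder's-equation equivalence for the Gaussian trait: with beta on sdl
  # only and no drift, per-generation response = V_G * beta = h2 * S when
  # beta = S / V_P and V_P = V_G / h2
  v_g <- 1; h2 <- 0.4; s_diff <- 0.8
  v_p <- v_g / h2
  pr2 <- predict_response(g, c(sdl = s_diff / v_p, mat = 0), st,
                          n_generations = 3, drift = FALSE)
  sdl_path <- pr2$median[pr2$scale == "latent" & pr2$trait == "sdl"]
  expect_equal(diff(sdl_path), rep(h2 * s_diff, 3), tolerance = 1e-10)
})

test_that("data-scale maturity means stay in (0,1) and are monotone in the latent mean", {
  g <- matrix(c(1, 0.3, 0.3, 0.5), 2)
  st <- latent_state(c(sdl = 0, mat = -2), extra_var = c(sdl = 0, mat = NA))
  pr <- predict_response(g, c(sdl = 2, mat = 2), st, n_generations = 8,
                         drift = FALSE)
  dat <- pr[pr$scale == "data" & pr$trait == "mat", ]
  lat <- pr[pr$scale == "latent" & pr$trait == "mat", ]
  expect_true(all(dat$median > 0 & dat$median < 1))
  expect_equal(order(lat$median), order(dat$median))
})

test_that("drift-only trajectories accumulate variance g * G / Ne", {
  g <- matrix(c(1, 0.5, 0.5, 2), 2)
  ne <- 20
  st <- latent_state(c(sdl = 0, mat = 0), extra_var = c(sdl = 0, mat = 0))
  pr <- predict_response(g, c(sdl = 0, mat = 0), st, n_generations = 6,
                         ne = ne, drift = TRUE, n_rep = 4000, seed = 3)
  traj <- attr(pr, "trajectories")$latent
  for (gen in c(3, 6)) {
    cv <- cov(t(traj[gen + 1, , ]))
    expect_equal(cv, gen * g / ne, tolerance = 0.12)
  }
})
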