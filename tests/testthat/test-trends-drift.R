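# handmade bivariate fit with controllable breeding-value and aquarium-effect
# draws, on a 3-aquarium pedigree with identified dams
fake_bv_fit <- function(bv_draws, u_draws, meta, aq_levels) {
  k <- dim(bv_draws)[3]
  d <- dim(bv_draws)[2]
  chains <- list(list(
    G = array(diag(d), c(d, d, k)), E = array(diag(d), c(d, d, k)),
    AQ = array(diag(d), c(d, d, k)), FG = array(diag(d), c(d, d, k)),
    B = array(0, c(1, d, k)), BV = bv_draws, U = u_draws,
    n_stored = k, n_diverged = 0
  ))
  out <- list(chains = chains,
              traits = setNames(c("sdl_mm", "mature")[seq_len(d)],
                                c("sdl", "mat")[seq_len(d)]),
              trait_types = c("gaussian", "binary")[seq_len(d)],
              ped_ids = meta$id, ped_meta = meta, aq_levels = aq_levels,
              fixed_names = "intercept", use_aq = TRUE, use_gen = FALSE,
              n = nrow(meta),
              spec = model_spec(iterations = 10, burnin = 0, thin = 1))
  class(out) <- "qgsel_fit"
  out
}

toy_meta <- function() {
  tibble::tibble(
    id = c("d1", "d2", "d3", "o1", "o2", "o3", "o4", "o5", "o6"),
    line = c(rep("Founder", 3), rep("L", 6)),
    generation = c(0L, 0L, 0L, rep(1L, 6)),
    aquarium = c("t0", "t0", "t0", "a", "a", "b", "b", "c", "c"),
    dam = c(NA, NA, NA, "d1", "d1", "d2", "d2", "d3", "d3"),
    f = 0
  )
}

test_that("genetic trends are per-draw cell means with honest intervals", {
  meta <- toy_meta()
  n <- nrow(meta)
  # constant zero breeding values: flat trend, zero-width interval
  fit0 <- fake_bv_fit(array(0, c(n, 2, 5)), array(0, c(4, 2, 5)), meta,
                      c("t0", "a", "b", "c"))
  tr0 <- genetic_trends(fit0)
  expect_true(all(tr0$median == 0 & tr0$lo == 0 & tr0$hi == 0))

  # single draw: median equals that draw's means, degenerate interval
  set.seed(8)
  bv <- array(rnorm(n * 2), c(n, 2, 1))
  fit1 <- fake_bv_fit(bv, array(0, c(4, 2, 1)), meta, c("t0", "a", "b", "c"))
  tr1 <- genetic_trends(fit1)
  row <- tr1[tr1$line == "L" & tr1$trait == "sdl", ]
  expect_equal(row$median, mean(bv[4:9, 1, 1]))
  expect_equal(row$lo, row$hi)

  # several draws: medians/quantiles match direct recomputation
  bv5 <- array(rnorm(n * 2 * 200), c(n, 2, 200))
  fit5 <- fake_bv_fit(bv5, array(0, c(4, 2, 200)), meta, c("t0", "a", "b", "c"))
  tr5 <- genetic_trends(fit5)
  cellmeans <- apply(bv5[4:9, 2, ], 2, mean)
  row5 <- tr5[tr5$line == "L" & tr5$trait == "mat", ]
  expect_equal(row5$median, median(cellmeans))
  expect_equal(row5$lo, unname(quantile(cellmeans, 0.025)))
})

test_that("maternal effect equals a per-draw least-squares oracle", {
  meta <- toy_meta()
  n <- nrow(meta)
  k <- 50
  set.seed(10)
  bv <- array(rnorm(n * 2 * k), c(n, 2, k))
  aq_levels <- c("a", "b", "c", "t0")
  # aquarium effects built as exactly 0.3 x dam breeding value
  u <- array(0, c(4, 2, k))
  dam_idx <- c(1, 2, 3) # d1, d2, d3 in ped_ids
  for (kk in 1:k) for (t in 1:2) {
    u[1:3, t, kk] <- 0.3 * bv[dam_idx, t, kk]
    u[4, t, kk] <- rnorm(1) # founder tank has no identified dam
  }
  fit <- fake_bv_fit(bv, u, meta, aq_levels)
  me <- maternal_effect(fit)
  expect_equal(unique(round(me$draws$m, 10)), 0.3)
  expect_equal(me$summary$median, c(0.3, 0.3), tolerance = 1e-12)

  # independent lm() oracle on noisy draws
  u2 <- u
  set.seed(11)
  for (kk in 1:k) for (t in 1:2) u2[1:3, t, kk] <- rnorm(3)
  fit2 <- fake_bv_fit(bv, u2, meta, aq_levels)
  me2 <- maternal_effect(fit2)
  oracle <- unname(coef(lm(u2[1:3, 1, 7] ~ bv[dam_idx, 1, 7]))[2])
  got <- me2$draws$m[me2$draws$draw == 7 & me2$draws$trait == "sdl"]
  expect_equal(got, oracle, tolerance = 1e-10)
})

test_that("drift simulation reproduces founder covariance and degenerate cases", {
  # founders only: sample covariance of simulated values ~ G
  ped <- tibble::tibble(id = sprintf("f%05d", 1:10000), sire = NA_character_,
                        dam = NA_character_)
  pc <- qgsel:::ped_compile(ped)
  g <- matrix(c(1, 0.5, 0.5, 2), 2)
  set.seed(5)
  a <- qgsel:::simulate_bv(pc, g)
  expect_equal(cov(a), g, tolerance = 0.06)

  # G = 0: every simulated value is 0
  dr0 <- simulate_drift_null(ped[1:50, ], matrix(0, 2, 2), n_per_draw = 3,
                             seed = 1)
  expect_true(all(dr0$replicates$mean_bv == 0))
  expect_true(all(dr0$envelope$lo == 0 & dr0$envelope$hi == 0))
})

test_that("drift envelopes are centered on zero and widen with generations", {
  exp <- small_experiment(seed = 91)
  g <- matrix(c(1, 0.3, 0.3, 0.6), 2)
  dr <- simulate_drift_null(exp$pedigree, g, n_per_draw = 600, seed = 2)
  env <- dr$envelope
  for (l in c("Large", "Control")) {
    sub <- env[env$line == l & env$trait == "t1", ]
    sub <- sub[order(sub$generation), ]
    # envelope approximately symmetric: median near 0 relative to width
    expect_true(all(abs(sub$median) < 0.35 * (sub$hi - sub$lo)))
    # monotone widening in expectation: last wider than first
    expect_gt(sub$hi[nrow(sub)] - sub$lo[nrow(sub)], sub$hi[1] - sub$lo[1])
  }
  # per-cell replicate means are centered on 0 within 3 standard errors
  reps <- dr$replicates
  last <- reps[reps$line == "Large" & reps$trait == "t1" &
                 reps$generation == max(reps$generation), ]
  expect_lt(abs(mean(last$mean_bv)), 3 * sd(last$mean_bv) / sqrt(nrow(last)))
})

test_that("genetic trends of drift-simulated data sit inside the drift envelope", {
  # calibration of the null: simulate neutral BVs on the pedigree, treat them
  # as estimated trends, and check envelope coverage across cells
  exp <- small_experiment(seed = 101)
  pc <- qgsel:::ped_compile(exp$pedigree)
  g <- matrix(c(0.9, 0.2, 0.2, 0.5), 2)
  dr <- simulate_drift_null(exp$pedigree, g, n_per_draw = 1000, seed = 3)
  meta <- pc$ped
  set.seed(4)
  inside <- replicate(150, {
    a <- qgsel:::simulate_bv(pc, g)
    means <- tapply(a[, 1], paste(meta$line, meta$generation), mean)
    env <- dr$envelope[dr$envelope$trait == "t1", ]
    key <- paste(env$line, env$generation)
    m <- means[key]
    mean(m >= env$lo & m <= env$hi)
  })
  expect_gt(mean(inside), 0.88)
  expect_lt(mean(inside), 1.0)
})
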