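# minimal handmade fit object (univariate, no aquarium/generation) whose
# "posterior draws" are supplied directly; used to unit-test summaries and
# diagnostics against closed forms
fake_fit <- function(draw_chains, e_draws = NULL) {
  chains <- lapply(draw_chains, function(v) {
    k <- length(v)
    list(G = array(v, c(1, 1, k)),
         E = array(e_draws %||% rep(1, k), c(1, 1, k)),
         AQ = array(0, c(1, 1, k)), FG = array(0, c(1, 1, k)),
         B = array(0, c(1, 1, k)), n_stored = k, n_diverged = 0)
  })
  out <- list(chains = chains, traits = c(sdl = "sdl_mm"),
              trait_types = "gaussian", ped_ids = "x",
              fixed_names = "intercept", use_aq = FALSE, use_gen = FALSE,
              n = 1, spec = model_spec(iterations = 10, burnin = 0, thin = 1))
  class(out) <- "qgsel_fit"
  out
}

test_that("posterior summaries are order statistics of the pooled draws", {
  fit <- fake_fit(list(rep(7, 100)))
  ps <- posterior_summary(fit)
  row <- ps[ps$parameter == "v_g_sdl", ]
  expect_equal(c(row$q2.5, row$median, row$q97.5), c(7, 7, 7))

  fit2 <- fake_fit(list(1:1000))
  expect_equal(posterior_summary(fit2)$median[1], 500.5)
})

test_that("effective sample size matches closed forms", {
  set.seed(3)
  # independent draws: ESS close to the draw count
  fit <- fake_fit(list(rnorm(2000), rnorm(2000)))
  d <- convergence_diagnostics(fit)
  expect_gt(d$ess[d$parameter == "v_g_sdl"], 0.8 * 4000)
  expect_lt(d$ess[d$parameter == "v_g_sdl"], 1.25 * 4000)

  # AR(1) with rho = 0.9: ESS ~ n (1 - rho) / (1 + rho)
  rho <- 0.9
  n <- 20000
  ar <- as.numeric(arima.sim(list(ar = rho), n))
  fit_ar <- fake_fit(list(ar))
  ess <- convergence_diagnostics(fit_ar)$ess[1]
  expect_equal(ess, n * (1 - rho) / (1 + rho), tolerance = 0.25)
})

test_that("shifted chains are flagged by the split scale reduction", {
  set.seed(4)
  fit <- fake_fit(list(rnorm(500), rnorm(500) + 4))
  d <- convergence_diagnostics(fit)
  expect_gt(d$rhat[d$parameter == "v_g_sdl"], 1.1)
  expect_true(d$flagged[d$parameter == "v_g_sdl"])
  # single chain: scale reduction unavailable
  d1 <- convergence_diagnostics(fake_fit(list(rnorm(500))))
  expect_true(is.na(d1$rhat[1]))
})

test_that("a binary-only model with true latent mean 0 predicts 50% maturity", {
  set.seed(9)
  n <- 1200
  ped <- tibble::tibble(id = sprintf("b%04d", 1:n), sire = NA_character_,
                        dam = NA_character_)
  pheno <- tibble::tibble(id = ped$id, mature = rbinom(n, 1, 0.5))
  spec <- model_spec("full", include_inbreeding = FALSE, iterations = 4000,
                     burnin = 1000, thin = 5, n_chains = 1, seed = 1,
                     use_aquarium = FALSE, use_generation = FALSE,
                     store_bv = FALSE, store_ranef = FALSE)
  fit <- fit_animal_model(ped, pheno, spec, traits = c(mat = "mature"),
                          trait_types = "binary")
  ps <- posterior_summary(fit)
  mu <- ps$median[ps$parameter == "intercept_mat"]
  v <- ps$median[ps$parameter == "v_g_mat"]
  # posterior-predictive maturity frequency on the data scale
  p_hat <- pnorm(mu / sqrt(1 + v))
  expect_lt(abs(p_hat - 0.5), 0.05)
  # every stored residual draw has the binary variance fixed at exactly 1
  expect_true(all(fit$chains[[1]]$E[1, 1, ] == 1))
})

test_that("variance components match an lme4 oracle on grouped Gaussian data", {
  skip_if_not_installed("lme4")
  set.seed(11)
  n_fam <- 120; per <- 8
  fam <- rep(sprintf("q%03d", 1:n_fam), each = per)
  u <- rnorm(n_fam, 0, sqrt(2))
  y <- 5 + u[match(fam, unique(fam))] + rnorm(n_fam * per, 0, sqrt(3))
  ped <- tibble::tibble(id = sprintf("u%04d", seq_along(y)),
                        sire = NA_character_, dam = NA_character_,
                        aquarium = fam)
  pheno <- tibble::tibble(id = ped$id, sdl_mm = y)
  spec <- model_spec("full", include_inbreeding = FALSE, iterations = 6000,
                     burnin = 1500, thin = 5, n_chains = 1, seed = 2,
                     use_aquarium = TRUE, use_generation = FALSE,
                     store_bv = FALSE, store_ranef = FALSE)
  fit <- fit_animal_model(ped, pheno, spec, traits = c(sdl = "sdl_mm"),
                          trait_types = "gaussian")
  ps <- posterior_summary(fit)
  lfit <- lme4::lmer(y ~ 1 + (1 | fam))
  vc <- as.data.frame(lme4::VarCorr(lfit))
  v_fam <- vc$vcov[vc$grp == "fam"]
  v_res <- vc$vcov[vc$grp == "Residual"]
  # the A = I additive term is unidentified against the residual here, so
  # compare the aquarium variance and the total non-family variance
  expect_equal(ps$median[ps$parameter == "v_aq_sdl"], v_fam, tolerance = 0.25)
  tot <- ps$median[ps$parameter == "v_g_sdl"] + ps$median[ps$parameter == "v_e_sdl"]
  expect_equal(tot, v_res, tolerance = 0.15)
})

test_that("censoring the binary trait leaves the Gaussian marginals intact", {
  exp <- small_experiment(seed = 61)
  spec <- model_spec("full", iterations = 6000, burnin = 1500, thin = 5,
                     n_chains = 1, seed = 3, store_bv = FALSE,
                     store_ranef = FALSE)
  fit_uni <- fit_animal_model(exp$pedigree, exp$phenotypes, spec,
                              traits = c(sdl = "sdl_mm"),
                              trait_types = "gaussian")
  ph_cens <- exp$phenotypes
  ph_cens$mature <- NA_integer_
  fit_biv <- fit_animal_model(exp$pedigree, ph_cens, spec)
  ps_u <- posterior_summary(fit_uni)
  ps_b <- posterior_summary(fit_biv)
  for (par in c("v_g_sdl", "v_e_sdl", "v_aq_sdl", "intercept_sdl")) {
    m_u <- ps_u$median[ps_u$parameter == par]
    m_b <- ps_b$median[ps_b$parameter == par]
    expect_equal(m_b, m_u, tolerance = 0.25)
  }
})

test_that("derived posterior quantities are recomputed per draw, not from summaries", {
  exp <- small_experiment(seed = 71)
  spec <- model_spec("full", iterations = 1500, burnin = 500, thin = 10,
                     n_chains = 2, seed = 4, store_bv = FALSE,
                     store_ranef = FALSE)
  fit <- fit_animal_model(exp$pedigree, exp$phenotypes, spec)
  k <- fit$chains[[1]]$n_stored
  r_g <- unlist(lapply(fit$chains, function(ch) {
    ch$G[1, 2, 1:k] / sqrt(ch$G[1, 1, 1:k] * ch$G[2, 2, 1:k])
  }))
  ps <- posterior_summary(fit)
  expect_equal(ps$median[ps$parameter == "r_g"], median(r_g), tolerance = 1e-12)
  h2 <- unlist(lapply(fit$chains, function(ch) {
    ch$G[1, 1, 1:k] / (ch$G[1, 1, 1:k] + ch$AQ[1, 1, 1:k] + ch$E[1, 1, 1:k])
  }))
  expect_equal(ps$q97.5[ps$parameter == "h2_sdl"],
               unname(quantile(h2, 0.975)), tolerance = 1e-12)
})

test_that("the predictive scope keeps pre-split generations plus the control line", {
  exp <- small_experiment(seed = 81)
  spec <- model_spec("predictive", iterations = 400, burnin = 100, thin = 10,
                     n_chains = 1, seed = 5, store_bv = FALSE,
                     store_ranef = FALSE)
  fit <- fit_animal_model(exp$pedigree, exp$phenotypes, spec)
  joined <- phenotypes_with_pedigree(exp$phenotypes, exp$pedigree)
  keep <- qgsel:::predictive_rows(joined, "Control")
  expect_equal(fit$n, sum(keep))
  split_gen <- min(joined$generation[joined$line != "Founder"])
  expect_true(all(joined$line[keep] %in% c("Founder", "Control") |
                    joined$generation[keep] <= split_gen))
  expect_error(model_spec("predictive", include_inbreeding = TRUE),
               class = "qgsel_input_error")
})
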