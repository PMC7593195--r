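#' Settings for the Bayesian animal model
#'
#' Bundles dataset scope, prior and chain settings for [fit_animal_model()].
#' The `"full"` scope uses every record and (by default) the inbreeding
#' covariate; the `"predictive"` scope restricts the data to the generations
#' before the lines diverged plus the control line afterwards, and drops the
#' inbreeding covariate, so that predicted and realized selection responses
#' are independent.
#'
#' Default chain settings are desk-scale (`iterations = 50000`,
#' `burnin = 5000`, `thin = 25`, 4 chains); production-scale runs simply pass
#' larger values.
#'
#' @param scope `"full"` or `"predictive"`.
#' @param include_inbreeding Use the inbreeding coefficient as a covariate
#'   for both traits? Forced to `FALSE` for the predictive scope.
#' @param iterations,burnin,thin,n_chains MCMC settings per chain.
#' @param seed Root seed; chain `c` uses a deterministic sub-seed.
#' @param nu Inverse-Wishart prior degrees of freedom for every covariance
#'   component (default 2: proper and weakly informative for 2 traits, denser
#'   near zero than `nu = 3`).
#' @param psi Optional named list of prior scale matrices (`g`, `e`, `aq`,
#'   `gen`); defaults to `diag(phenotypic variance / 3)` per trait (1 for the
#'   latent scale of a binary trait).
#' @param use_aquarium,use_generation Include the aquarium / generation
#'   random effects?
#' @param store_bv,store_ranef Store per-draw breeding values / aquarium
#'   effects (needed for genetic trends, drift nulls and maternal effects)?
#' @param liability_bound Absolute bound beyond which a liability draw is
#'   treated as divergent (reset to its conditional mean and counted).
#' @param control_line Name of the control line (predictive scope).
#' @return A list of class `qgsel_model_spec`.
#' @export
model_spec <- function(scope = c("full", "predictive"),
                       include_inbreeding = NULL,
                       iterations = 50000, burnin = 5000, thin = 25,
                       n_chains = 4, seed = 1, nu = 2, psi = NULL,
                       use_aquarium = TRUE, use_generation = TRUE,
                       store_bv = TRUE, store_ranef = TRUE,
                       liability_bound = 12, control_line = "Control") {
  scope <- match.arg(scope)
  if (is.null(include_inbreeding)) include_inbreeding <- scope == "full"
  if (scope == "predictive" && include_inbreeding) {
    abort("the predictive scope excludes the inbreeding covariate",
          class = "qgsel_input_error")
  }
  check_number(iterations, "iterations", lower = 2)
  check_number(burnin, "burnin", lower = 0, upper = iterations - 1)
  check_number(thin, "thin", lower = 1)
  check_number(n_chains, "n_chains", lower = 1)
  out <- list(scope = scope, include_inbreeding = include_inbreeding,
              iterations = as.integer(iterations), burnin = as.integer(burnin),
              thin = as.integer(thin), n_chains = as.integer(n_chains),
              seed = as.integer(seed), nu = nu, psi = psi,
              use_aquarium = use_aquarium, use_generation = use_generation,
              store_bv = store_bv, store_ranef = store_ranef,
              liability_bound = liability_bound, control_line = control_line)
  class(out) <- "qgsel_model_spec"
  out
}

# rows retained under the predictive scope: common generations (before the
# line split) plus the control line afterwards
predictive_rows <- function(meta, control_line) {
  non_founder <- meta$line[!meta$line %in% "Founder"]
  lines <- unique(non_founder)
  if (length(lines) <= 1) return(rep(TRUE, nrow(meta)))
  g_split <- min(meta$generation[!meta$line %in% "Founder"], na.rm = TRUE)
  meta$generation <= g_split | meta$line == control_line
}

#' Fit the Bayesian bivariate Gaussian-probit animal model
#'
#' Fits, by Gibbs sampling with data augmentation, the infinitesimal-model
#' mixed model \eqn{y_{ti} = \mu_t + f_t F_i + a_{ti} + u_{t,aq(i)} +
#' g_{t,gen(i)} + e_{ti}} for a Gaussian trait and a binary threshold trait
#' observed as \eqn{1(y > 0)}. Breeding values have covariance
#' \eqn{G \otimes A} (A = pedigree relationship matrix, handled through its
#' sparse inverse); aquarium and generation effects have their own 2x2
#' covariances; residuals are bivariate with the binary trait's residual
#' variance fixed to 1 (enforced exactly in every stored draw by parameter
#' expansion). All covariance components carry inverse-Wishart priors.
#' Breeding values are sampled for every pedigree member, phenotyped or not.
#'
#' @param ped Pedigree table.
#' @param pheno Phenotype table (one row per phenotyped individual).
#' @param spec A [model_spec()].
#' @param traits Trait columns, in order.
#' @param trait_types `"gaussian"` or `"binary"` per trait.
#' @return An object of class `qgsel_fit` holding per-chain posterior draws
#'   of all variance components, fixed effects, and (optionally) breeding
#'   values and aquarium effects, plus the pedigree metadata needed by
#'   [genetic_trends()], [maternal_effect()] and [simulate_drift_null()].
#' @export
fit_animal_model <- function(ped, pheno, spec = model_spec(),
                             traits = c(sdl = "sdl_mm", mat = "mature"),
                             trait_types = c("gaussian", "binary")) {
  stopifnot(inherits(spec, "qgsel_model_spec"))
  if (length(traits) != length(trait_types) || !length(traits) %in% 1:2) {
    abort("1 or 2 traits with matching types are supported",
          class = "qgsel_input_error")
  }
  pc <- ped_compile(ped)
  ainv <- ped_ainverse(pc)
  meta <- pc$ped
  if (!"line" %in% names(meta)) meta$line <- "all"
  if (!"generation" %in% names(meta)) meta$generation <- 0L

  data <- phenotypes_with_pedigree(pheno, ped)
  if (anyDuplicated(data$id) > 0) {
    abort("phenotype table has duplicated ids", class = "qgsel_input_error")
  }
  if (spec$scope == "predictive") {
    keep <- predictive_rows(data, spec$control_line)
    data <- data[keep, , drop = FALSE]
  }

  d <- length(traits)
  type_code <- as.integer(trait_types == "binary")
  y <- as.matrix(data[, unname(traits), drop = FALSE])
  storage.mode(y) <- "double"

  ped_index <- match(data$id, pc$ids) - 1L
  f_all <- ped_inbreeding_cpp(pc$sire0, pc$dam0)$F
  x <- cbind(intercept = rep(1, nrow(data)))
  if (spec$include_inbreeding) x <- cbind(x, f = f_all[ped_index + 1L])

  use_aq <- spec$use_aquarium && !is.null(data$aquarium)
  if (use_aq && anyNA(data$aquarium)) {
    abort("phenotyped individuals without an aquarium; disable `use_aquarium` or fix the pedigree",
          class = "qgsel_input_error")
  }
  aq_levels <- if (use_aq) sort(unique(data$aquarium)) else character(0)
  aq_idx <- if (use_aq) match(data$aquarium, aq_levels) - 1L else rep(-1L, nrow(data))
  use_gen <- spec$use_generation && !is.null(data$generation)
  gen_levels <- if (use_gen) sort(unique(data$generation)) else integer(0)
  gen_idx <- if (use_gen) match(data$generation, gen_levels) - 1L else rep(-1L, nrow(data))

  # default prior scales from the observed phenotypic variance
  vp <- purrr::map_dbl(seq_len(d), function(t) {
    if (type_code[t] == 1) 1 else var(y[, t], na.rm = TRUE)
  })
  default_psi <- diag(vp / 3, nrow = d)
  psi <- spec$psi %||% list()
  psi_g <- psi$g %||% default_psi
  psi_e <- psi$e %||% {
    m <- default_psi
    for (t in which(type_code == 1)) m[t, t] <- 1
    m
  }
  psi_aq <- psi$aq %||% default_psi
  psi_gen <- psi$gen %||% default_psi

  g0 <- diag(vp / 3, nrow = d)
  e0 <- diag(vp / 3, nrow = d)
  for (t in which(type_code == 1)) e0[t, t] <- 1
  aq0 <- diag(vp / 6, nrow = d)
  f0 <- diag(vp / 6, nrow = d)

  chains <- purrr::map(seq_len(spec$n_chains), function(ch) {
    chain_seed <- substream_seed(spec$seed, paste0("chain", ch))
    with_seed(chain_seed, {
      res <- animal_gibbs_cpp(
        Y = y, trait_type = type_code, X = x, ped_index = ped_index,
        n_ped = length(pc$ids),
        ai_p = ainv$ainv@p, ai_i = ainv$ainv@i, ai_x = ainv$ainv@x,
        aq = aq_idx, n_aq = length(aq_levels),
        gen = gen_idx, n_gen = length(gen_levels),
        nu = spec$nu, psi_g = psi_g, psi_e = psi_e,
        psi_aq = psi_aq, psi_gen = psi_gen,
        G0 = g0, E0 = e0, AQ0 = aq0, F0 = f0,
        n_iter = spec$iterations, burnin = spec$burnin, thin = spec$thin,
        store_bv = spec$store_bv, store_ranef = spec$store_ranef,
        liability_bound = spec$liability_bound)
      res$seed <- chain_seed
      res
    })
  })

  out <- list(
    chains = chains, spec = spec, traits = traits, trait_types = trait_types,
    ped_ids = pc$ids,
    ped_meta = tibble::tibble(id = pc$ids, line = meta$line,
                              generation = meta$generation,
                              aquarium = col_or(meta, "aquarium", NA_character_),
                              dam = meta$dam, f = f_all),
    aq_levels = aq_levels, gen_levels = gen_levels,
    use_aq = use_aq, use_gen = use_gen,
    fixed_names = colnames(x), n = nrow(data),
    prior = list(nu = spec$nu, psi_g = psi_g, psi_e = psi_e,
                 psi_aq = psi_aq, psi_gen = psi_gen)
  )
  class(out) <- "qgsel_fit"
  out
}

#' @export
print.qgsel_fit <- function(x, ...) {
  cat(sprintf("<qgsel_fit> %s scope, %d trait(s), n = %d phenotypes, %d pedigree members\n",
              x$spec$scope, length(x$traits), x$n, length(x$ped_ids)))
  cat(sprintf("  %d chain(s) x %d stored draws (iterations %d, burn-in %d, thin %d)\n",
              length(x$chains), x$chains[[1]]$n_stored, x$spec$iterations,
              x$spec$burnin, x$spec$thin))
  invisible(x)
}

# per-draw scalar parameters, pooled or per chain:
# returns a named list of matrices draws x chains
fit_scalar_draws <- function(fit, derived = TRUE) {
  d <- length(fit$traits)
  tn <- names(fit$traits) %||% paste0("t", seq_len(d))
  comp_names <- c("g", "e", "aq", "f_gen")
  comp_keys <- c("G", "E", "AQ", "FG")
  used <- c(TRUE, TRUE, isTRUE(fit$use_aq), isTRUE(fit$use_gen))
  comp_names <- comp_names[used]
  comp_keys <- comp_keys[used]
  out <- list()
  k <- fit$chains[[1]]$n_stored
  nc <- length(fit$chains)
  grab <- function(key, i, j) {
    vapply(fit$chains, function(ch) ch[[key]][i, j, seq_len(k)], numeric(k))
  }
  for (ci in seq_along(comp_keys)) {
    for (i in seq_len(d)) for (j in i:d) {
      nm <- if (i == j) paste0("v_", comp_names[ci], "_", tn[i])
            else paste0("c_", comp_names[ci], "_", tn[i], tn[j])
      out[[nm]] <- grab(comp_keys[ci], i, j)
    }
  }
  p <- length(fit$fixed_names)
  for (pi in seq_len(p)) for (t in seq_len(d)) {
    out[[paste0(fit$fixed_names[pi], "_", tn[t])]] <-
      vapply(fit$chains, function(ch) ch$B[pi, t, seq_len(k)], numeric(k))
  }
  if (derived) {
    for (t in seq_len(d)) {
      g <- out[[paste0("v_g_", tn[t])]]
      aq <- out[[paste0("v_aq_", tn[t])]] %||% 0
      e <- out[[paste0("v_e_", tn[t])]]
      out[[paste0("h2_", tn[t])]] <- g / (g + aq + e)
    }
    if (d == 2) {
      for (ci in seq_along(comp_names)) {
        v1 <- out[[paste0("v_", comp_names[ci], "_", tn[1])]]
        v2 <- out[[paste0("v_", comp_names[ci], "_", tn[2])]]
        cc <- out[[paste0("c_", comp_names[ci], "_", tn[1], tn[2])]]
        if (!is.null(v1) && !is.null(cc)) {
          out[[paste0("r_", comp_names[ci])]] <- cc / sqrt(v1 * v2)
        }
      }
    }
  }
  lapply(out, function(m) matrix(m, nrow = k, ncol = nc))
}

#' Posterior summaries of variance components and derived quantities
#'
#' Reports the 2.5%, 50% and 97.5% posterior quantiles of every variance
#' component, fixed effect, and derived quantity (heritabilities
#' \eqn{h^2_t = G_{tt} / (G_{tt} + AQ_{tt} + E_{tt})} and component
#' correlations). Derived quantities are computed draw by draw, never from
#' summarized components, and chains are pooled after burn-in.
#'
#' @param fit A [fit_animal_model()] result.
#' @return A tibble: `parameter`, `q2.5`, `median`, `q97.5`.
#' @export
posterior_summary <- function(fit) {
  stopifnot(inherits(fit, "qgsel_fit"))
  if (fit$chains[[1]]$n_stored < 1) {
    abort("no stored draws", class = "qgsel_input_error")
  }
  draws <- fit_scalar_draws(fit)
  purrr::map_dfr(names(draws), function(nm) {
    v <- as.numeric(draws[[nm]])
    q <- quantile(v, c(0.025, 0.5, 0.975), names = FALSE)
    tibble::tibble(parameter = nm, q2.5 = q[1], median = q[2], q97.5 = q[3])
  })
}

#' @rdname posterior_summary
#' @param x A `qgsel_fit` object.
#' @param ... Unused.
#' @export
tidy.qgsel_fit <- function(x, ...) posterior_summary(x)

#' @rdname posterior_summary
#' @export
glance.qgsel_fit <- function(x, ...) {
  diag <- convergence_diagnostics(x)
  tibble::tibble(
    n = x$n, n_pedigree = length(x$ped_ids), n_chains = length(x$chains),
    draws_per_chain = x$chains[[1]]$n_stored,
    min_ess = min(diag$ess, na.rm = TRUE),
    max_rhat = if (all(is.na(diag$rhat))) NA_real_ else max(diag$rhat, na.rm = TRUE),
    n_diverged = sum(vapply(x$chains, function(ch) ch$n_diverged, numeric(1)))
  )
}

# effective sample size via Geyer's initial monotone positive sequence,
# averaged autocorrelations across chains
ess_geyer <- function(mat) {
  n <- nrow(mat)
  nc <- ncol(mat)
  if (var(as.numeric(mat)) == 0) return(NA_real_)
  max_lag <- min(n - 1, 400)
  rho <- rowMeans(vapply(seq_len(nc), function(c) {
    ac <- stats::acf(mat[, c], lag.max = max_lag, plot = FALSE,
                     demean = TRUE)$acf[, 1, 1]
    ac
  }, numeric(max_lag + 1)))
  # Geyer: sum of adjacent pairs must stay positive (and monotone)
  s <- 0
  prev <- Inf
  k <- 1
  while (k + 1 <= length(rho) - 1) {
    pair <- rho[k + 1] + rho[k + 2]
    if (pair < 0) break
    pair <- min(pair, prev)
    s <- s + pair
    prev <- pair
    k <- k + 2
  }
  n * nc / (1 + 2 * s)
}

# split-chain potential scale reduction
rhat_split <- function(mat) {
  n <- nrow(mat)
  if (ncol(mat) < 2 || n < 4) return(NA_real_)
  half <- floor(n / 2)
  sub <- do.call(cbind, lapply(seq_len(ncol(mat)), function(c) {
    cbind(mat[seq_len(half), c], mat[(n - half + 1):n, c])
  }))
  m <- ncol(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, var)
  w <- mean(vars)
  b <- half * var(means)
  if (w == 0) return(NA_real_)
  sqrt(((half - 1) / half * w + b / half) / w)
}

#' MCMC convergence diagnostics
#'
#' Effective sample size (Geyer initial monotone sequence estimator, chains
#' pooled) and split-chain potential scale reduction per scalar parameter.
#' With a single chain the scale reduction is reported as `NA`. Parameters
#' with a scale reduction above 1.1 are flagged.
#'
#' @param fit A [fit_animal_model()] result.
#' @return A tibble: `parameter`, `ess`, `rhat`, `flagged`.
#' @export
convergence_diagnostics <- function(fit) {
  draws <- fit_scalar_draws(fit)
  multi <- length(fit$chains) >= 2
  purrr::map_dfr(names(draws), function(nm) {
    m <- draws[[nm]]
    r <- if (multi) rhat_split(m) else NA_real_
    tibble::tibble(parameter = nm, ess = ess_geyer(m), rhat = r,
                   flagged = isTRUE(r > 1.1))
  })
}

# pooled G draws as a d x d x K array
g_draws <- function(fit) {
  k <- fit$chains[[1]]$n_stored
  arrs <- lapply(fit$chains, function(ch) ch$G[, , seq_len(k), drop = FALSE])
  out <- array(unlist(arrs), dim = c(dim(arrs[[1]])[1:2], k * length(arrs)))
  dimnames(out) <- list(names(fit$traits), names(fit$traits), NULL)
  out
}
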