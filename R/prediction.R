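#' Latent-scale population state for response prediction
#'
#' The multivariate response prediction operates on the scale where the
#' infinitesimal model is most defensible: the trait scale for the Gaussian
#' trait and the latent (probit liability) scale for the binary trait. A
#' latent state holds the latent means plus the extra (non-genetic-mean)
#' latent variance used when converting the binary trait between scales; the
#' binary trait's total latent variance is `extra_var + 1` because the
#' residual liability variance is fixed at 1.
#'
#' @param mu Named length-2 numeric: latent means (`sdl` in mm, `mat` in
#'   probits).
#' @param extra_var Named length-2 numeric: extra latent variance per trait
#'   (`NA` for the binary trait means "use the current `G` draw's genetic
#'   variance", the default conversion variance).
#' @param generation Generation index of the state.
#' @return A list of class `qgsel_latent_state`.
#' @export
latent_state <- function(mu, extra_var = c(sdl = 0, mat = NA), generation = 0) {
  if (length(mu) != 2) abort("`mu` must have 2 entries", class = "qgsel_input_error")
  if (any(!is.na(extra_var) & extra_var < 0)) {
    abort("`extra_var` must be non-negative", class = "qgsel_input_error")
  }
  out <- list(mu = mu, extra_var = extra_var, generation = generation)
  class(out) <- "qgsel_latent_state"
  out
}

#' Convert latent means to data-scale means
#'
#' The Gaussian trait uses an identity link, so its mean is unchanged. The
#' binary trait's data-scale mean marginalizes the probit over the extra
#' latent variance \eqn{v}: \eqn{p = \Phi(\mu / \sqrt{1 + v})} (the residual
#' liability variance contributes the 1).
#'
#' @param state A [latent_state()].
#' @param extra_var_mat Override for the binary trait's extra latent
#'   variance (used internally when it tracks a posterior `G` draw).
#' @return Named numeric: data-scale means (`mat` as a probability).
#' @export
latent_to_data_mean <- function(state, extra_var_mat = NULL) {
  v <- extra_var_mat %||% state$extra_var[2]
  if (is.na(v)) {
    abort("binary-trait extra latent variance is unset", class = "qgsel_input_error")
  }
  c(sdl = unname(state$mu[1]),
    mat = unname(pnorm(state$mu[2] / sqrt(1 + v))))
}

#' Convert data-scale selection gradients to the latent scale
#'
#' Gradients estimated on the data scale (probability scale for the binary
#' trait) are mapped to the latent scale by the chain rule: the Gaussian
#' entry is unchanged, and the binary entry is multiplied by the derivative
#' of the data-scale mean with respect to the latent mean,
#' \eqn{\phi(\mu/\sqrt{1+v}) / \sqrt{1+v}}.
#'
#' @param beta_data Named length-2 gradient on the data scale.
#' @param state A [latent_state()].
#' @inheritParams latent_to_data_mean
#' @return Named numeric latent-scale gradient.
#' @export
data_gradient_to_latent <- function(beta_data, state, extra_var_mat = NULL) {
  v <- extra_var_mat %||% state$extra_var[2]
  if (is.na(v)) {
    abort("binary-trait extra latent variance is unset", class = "qgsel_input_error")
  }
  s <- sqrt(1 + v)
  c(sdl = unname(beta_data[1]),
    mat = unname(beta_data[2] * dnorm(state$mu[2] / s) / s))
}

#' Recursive multivariate selection-response prediction
#'
#' Iterates the Lande-Arnold equation \eqn{\Delta\mu = G\beta} on the latent
#' scale over generations, once per posterior `G` draw (and per drift
#' replicate), adding a genetic-drift deviation \eqn{N(0, G/N_e)} each
#' generation. Data-scale gradients are converted to the latent scale at the
#' current mean each generation (the probit Jacobian moves with the mean;
#' set `refresh_jacobian = FALSE` to freeze it at the starting state for
#' sensitivity analysis). Trajectories are reported on both scales with
#' medians and 95% support intervals across draws and replicates.
#'
#' @param g A `qgsel_fit`, a `2 x 2 x K` array of posterior `G` draws or a
#'   single matrix.
#' @param beta_data Named length-2 data-scale gradient, held constant across
#'   generations.
#' @param start A [latent_state()] for generation 0 of the forecast.
#' @param n_generations Number of generations to predict.
#' @param ne Effective population size used for the drift deviations
#'   (default 25, the typical drift-based estimate for this design).
#' @param drift Add drift deviations? `FALSE` gives the deterministic
#'   recursion.
#' @param n_rep Drift replicates per posterior draw.
#' @param seed Optional seed.
#' @param refresh_jacobian Re-evaluate the probit Jacobian at the current
#'   mean each generation?
#' @return A tibble of class `qgsel_prediction`: `generation`, `trait`,
#'   `scale` (`"latent"`/`"data"`), `lo`, `median`, `hi`. Trajectory draws
#'   are attached as attribute `"trajectories"`.
#' @export
predict_response <- function(g, beta_data, start, n_generations = 6, ne = 25,
                             drift = TRUE, n_rep = 1, seed = NULL,
                             refresh_jacobian = TRUE) {
  stopifnot(inherits(start, "qgsel_latent_state"))
  if (inherits(g, "qgsel_fit")) g <- g_draws(g)
  if (is.matrix(g)) g <- array(g, dim = c(dim(g), 1))
  check_number(n_generations, "n_generations", lower = 0)
  check_number(ne, "ne", lower = 1e-12)
  k <- dim(g)[3]
  n_skipped <- 0

  traj <- with_seed(seed, {
    res <- vector("list", k * n_rep)
    ri <- 0
    for (di in seq_len(k)) {
      gm <- symm(g[, , di])
      if (!is_psd(gm)) {
        n_skipped <- n_skipped + 1
        next
      }
      v_mat <- if (is.na(start$extra_var[2])) gm[2, 2] else start$extra_var[2]
      cd <- if (drift) mat_sqrt(gm / ne) else NULL
      jac_state <- start
      for (rr in seq_len(n_rep)) {
        mu <- start$mu
        path <- matrix(NA_real_, n_generations + 1, 2)
        path[1, ] <- mu
        st <- start
        for (gen in seq_len(n_generations)) {
          st$mu <- mu
          bl <- data_gradient_to_latent(
            beta_data, if (refresh_jacobian) st else jac_state, v_mat)
          mu <- mu + drop(gm %*% bl)
          if (drift) mu <- mu + drop(rnorm(2) %*% cd)
          path[gen + 1, ] <- mu
        }
        ri <- ri + 1
        res[[ri]] <- list(path = path, v_mat = v_mat)
      }
    }
    res[seq_len(ri)]
  })
  if (n_skipped > 0) {
    inform(sprintf("skipped %d non-positive-semidefinite G draw(s)", n_skipped))
  }
  if (length(traj) == 0) {
    abort("no usable G draws", class = "qgsel_input_error")
  }

  n_traj <- length(traj)
  lat <- array(unlist(lapply(traj, `[[`, "path")),
               dim = c(n_generations + 1, 2, n_traj))
  vmats <- vapply(traj, `[[`, numeric(1), "v_mat")
  dat <- lat
  dat[, 2, ] <- pnorm(sweep(lat[, 2, , drop = FALSE], 3,
                            sqrt(1 + vmats), "/"))[, 1, ]

  summarize_scale <- function(arr, scale) {
    purrr::map_dfr(1:2, function(t) {
      m <- matrix(arr[, t, ], nrow = n_generations + 1)
      q <- apply(m, 1, quantile, c(0.025, 0.5, 0.975), names = FALSE)
      tibble::tibble(generation = start$generation + 0:n_generations,
                     trait = c("sdl", "mat")[t], scale = scale,
                     lo = q[1, ], median = q[2, ], hi = q[3, ])
    })
  }
  out <- dplyr::bind_rows(summarize_scale(lat, "latent"),
                          summarize_scale(dat, "data"))
  class(out) <- c("qgsel_prediction", class(out))
  attr(out, "trajectories") <- list(latent = lat, data = dat)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Starting latent state from a fitted predictive model
#'
#' Uses the posterior mean intercepts of a (typically predictive-scope)
#' animal-model fit as the latent starting means, with the binary trait's
#' conversion variance left to track each posterior `G` draw.
#'
#' @param fit A [fit_animal_model()] result.
#' @param generation Generation index assigned to the starting state.
#' @return A [latent_state()].
#' @export
prediction_start <- function(fit, generation = 1) {
  stopifnot(inherits(fit, "qgsel_fit"))
  k <- fit$chains[[1]]$n_stored
  b <- rowMeans(vapply(fit$chains,
                       function(ch) apply(ch$B[1, , seq_len(k), drop = FALSE], 2, mean),
                       numeric(length(fit$traits))))
  latent_state(setNames(b, c("sdl", "mat")[seq_along(b)]),
               generation = generation)
}
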