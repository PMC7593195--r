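#' Effective among- and within-family selection differentials
#'
#' Selection in a two-stage family design acts first among families (a subset
#' of families is preselected on their mean phenotype) and then within
#' families (breeders are picked inside preselected families). The effective
#' differentials weight each breeder by its realized number of surviving
#' offspring:
#' \itemize{
#'   \item among-family: \eqn{S_a} = offspring-weighted mean of the
#'     preselected family means, minus the population mean over *all*
#'     phenotyped individuals (non-preselected families included);
#'   \item within-family: \eqn{S_w} = offspring-weighted mean over breeders
#'     of the deviation of each breeder from its own family mean.
#' }
#'
#' @param data A phenotype table joined with its pedigree annotations (see
#'   [phenotypes_with_pedigree()]); must contain `aquarium` (the family
#'   identifier), `is_breeder`, `n_offspring`, `family_preselected` and the
#'   trait columns.
#' @param traits Named character vector mapping trait labels to columns;
#'   the binary trait is used on its observed 0/1 scale.
#' @return A tibble with one row per trait: `trait`, `s_a`, `s_w`.
#' @export
effective_differentials <- function(data,
                                    traits = c(sdl = "sdl_mm", mat = "mature")) {
  data <- tibble::as_tibble(data)
  br <- data[data$is_breeder %in% TRUE, , drop = FALSE]
  if (nrow(br) == 0) {
    abort("no breeders in this group", class = "qgsel_empty_selection")
  }
  w <- br$n_offspring
  if (sum(w, na.rm = TRUE) <= 0) {
    abort("total offspring weight is zero", class = "qgsel_degenerate_weights")
  }
  fam_presel <- unique(data$aquarium[data$family_preselected %in% TRUE])
  if (length(unique(data$aquarium)) < 2) {
    abort("need at least two families", class = "qgsel_input_error")
  }
  purrr::map_dfr(names(traits), function(tr) {
    x <- data[[traits[[tr]]]]
    pop_mean <- mean(x, na.rm = TRUE)
    fam_means <- tapply(x, data$aquarium, mean, na.rm = TRUE)
    # family weights: total surviving offspring of the family's breeders
    fam_w <- tapply(br$n_offspring, br$aquarium, sum)
    presel <- intersect(fam_presel, names(fam_w)[fam_w > 0])
    if (length(presel) == 0) {
      abort("no preselected family has breeding offspring",
            class = "qgsel_degenerate_weights")
    }
    s_a <- weighted.mean(fam_means[presel], fam_w[presel]) - pop_mean
    xb <- br[[traits[[tr]]]]
    s_w <- weighted.mean(xb - fam_means[br$aquarium], w)
    tibble::tibble(trait = tr, s_a = s_a, s_w = s_w)
  })
}

#' Phenotypic correlation between sibs
#'
#' The full-sib phenotypic correlation `t` (the fraction of phenotypic
#' variance attributable to family structure) computed as the Pearson
#' correlation over all ordered pairs of individuals belonging to the same
#' family -- the pairwise estimator of the intraclass correlation.
#'
#' @inheritParams effective_differentials
#' @param trait Column name of the trait.
#' @return A single correlation in \eqn{[-1, 1]}.
#' @export
sib_correlation <- function(data, trait = "sdl_mm") {
  data <- tibble::as_tibble(data)
  x <- data[[trait]]
  fam <- data$aquarium
  ok <- !is.na(x) & !is.na(fam)
  x <- x[ok]; fam <- fam[ok]
  sizes <- table(fam)
  if (sum(sizes >= 2) < 2) {
    abort("need at least two families with two or more phenotyped sibs",
          class = "qgsel_input_error")
  }
  if (var(x) == 0) {
    abort("trait has zero variance", class = "qgsel_zero_variance")
  }
  pairs <- purrr::map(split(x, fam), function(v) {
    n <- length(v)
    if (n < 2) return(NULL)
    idx <- expand.grid(i = seq_len(n), j = seq_len(n))
    idx <- idx[idx$i != idx$j, ]
    cbind(v[idx$i], v[idx$j])
  })
  pp <- do.call(rbind, pairs)
  if (var(pp[, 1]) == 0) {
    abort("within-family pairs have zero variance", class = "qgsel_zero_variance")
  }
  cor(pp[, 1], pp[, 2])
}

#' Composite selection differential for two-stage family selection
#'
#' Among- and within-family differentials predict different responses per
#' unit of differential: among-family selection responds as
#' \eqn{h^2 S_a / (2t)} and within-family selection as
#' \eqn{h^2 S_w / (2(1 - t))}, where `t` is the sib phenotypic correlation.
#' The composite differential \eqn{S = S_a/(2t) + S_w/(2(1-t))} is the
#' quantity whose product with \eqn{h^2} predicts the total response.
#'
#' @param s_a,s_w Among- and within-family differentials (trait units).
#' @param t Sib phenotypic correlation, strictly inside (0, 1).
#' @return The composite differential (vectorized).
#' @export
composite_differential <- function(s_a, s_w, t) {
  if (any(!is.finite(t)) || any(t <= 0) || any(t >= 1)) {
    abort("sib correlation `t` must lie strictly inside (0, 1)",
          class = "qgsel_out_of_domain")
  }
  s_a / (2 * t) + s_w / (2 * (1 - t))
}

#' Selection gradients from differentials
#'
#' Direct (partial) selection per trait after removing indirect selection via
#' phenotypically correlated traits: \eqn{\beta = P^{-1} S}, with `P` the
#' phenotypic covariance matrix. The standardized gradient
#' \eqn{\beta_\sigma = \beta \sqrt{P_{kk}}} is unitless.
#'
#' @param s Differential vector (one entry per trait).
#' @param p Phenotypic covariance matrix (same trait order).
#' @param max_condition Largest acceptable condition number of `p`.
#' @return A tibble with `beta` and `beta_sigma` per trait.
#' @export
selection_gradients <- function(s, p, max_condition = 1e10) {
  p <- as.matrix(p)
  if (!isTRUE(all.equal(p, t(p), tolerance = 1e-8))) {
    abort("`p` must be symmetric", class = "qgsel_input_error")
  }
  if (kappa(p, exact = TRUE) > max_condition) {
    abort("phenotypic covariance matrix is singular or near-singular",
          class = "qgsel_ill_conditioned")
  }
  beta <- drop(solve(p, s))
  tibble::tibble(trait = names(s) %||% paste0("trait", seq_along(s)),
                 beta = beta, beta_sigma = beta * sqrt(diag(p)))
}

#' Per line-and-generation selection summary
#'
#' Computes, for every line-by-generation group in which breeders exist, the
#' effective among/within-family differentials, the sib correlation, the
#' composite differential, the phenotypic (co)variances and the selection
#' gradients for both traits (the binary trait on its observed 0/1 scale).
#'
#' Sib correlations very close to (or outside) the boundaries of (0, 1) make
#' the composite differential ill-defined; they are clamped to
#' `[t_floor, 1 - t_floor]` with a warning (this happens for a binary trait
#' whose frequency is near 0 or 1 in a group).
#'
#' @param pheno Phenotype table.
#' @param ped Pedigree table.
#' @param traits Named character vector of trait columns.
#' @param t_floor Clamp bound for degenerate sib correlations.
#' @return A tibble of class `qgsel_selection`, one row per
#'   line-generation-trait: `line`, `generation`, `trait`, `n`, `s_a`, `s_w`,
#'   `t` (raw sib correlation), `s`, `v_p`, `c_p`, `beta`, `beta_sigma`.
#' @export
selection_summary <- function(pheno, ped,
                              traits = c(sdl = "sdl_mm", mat = "mature"),
                              t_floor = 0.02) {
  data <- phenotypes_with_pedigree(pheno, ped)
  groups <- dplyr::distinct(
    dplyr::filter(data, .data$is_breeder %in% TRUE),
    .data$line, .data$generation
  )
  out <- purrr::pmap_dfr(groups, function(line, generation) {
    g <- data[data$line == line & data$generation == generation, , drop = FALSE]
    dif <- effective_differentials(g, traits)
    tv <- purrr::map_dbl(traits, function(col) {
      tryCatch(sib_correlation(g, col),
               qgsel_zero_variance = function(e) NA_real_)
    })
    tc <- pmin(pmax(tv, t_floor), 1 - t_floor)
    if (any(is.na(tc)) || any(tc != tv, na.rm = TRUE)) {
      warn(sprintf("sib correlation clamped to [%g, %g] for %s generation %s",
                   t_floor, 1 - t_floor, line, generation))
      tc[is.na(tc)] <- t_floor
    }
    s <- composite_differential(dif$s_a, dif$s_w, tc)
    xm <- as.matrix(g[, unname(traits)])
    p <- cov(xm, use = "complete.obs")
    grad <- tryCatch(
      selection_gradients(setNames(s, names(traits)), p),
      error = function(e) {
        # degenerate P (e.g. a binary trait fixed in this group): fall back
        # to per-trait univariate gradients where defined
        warn(sprintf("near-singular phenotypic covariance for %s generation %s; univariate gradients used",
                     line, generation))
        vd <- diag(p)
        beta <- ifelse(vd > 0, s / vd, NA_real_)
        tibble::tibble(trait = names(traits), beta = beta,
                       beta_sigma = beta * sqrt(vd))
      })
    tibble::tibble(
      line = line, generation = generation, trait = names(traits),
      n = nrow(g), s_a = dif$s_a, s_w = dif$s_w, t = unname(tv), s = s,
      v_p = diag(p), c_p = p[1, 2],
      beta = grad$beta, beta_sigma = grad$beta_sigma
    )
  })
  class(out) <- c("qgsel_selection", class(out))
  out
}

#' Mean gradients per line
#'
#' Averages per-generation selection gradients with equal weights and reports
#' the across-generation standard deviation.
#'
#' @param summary A [selection_summary()] result.
#' @return A tibble per line and trait: `beta_mean`, `beta_sd`,
#'   `beta_sigma_mean`, `n_generations`.
#' @export
mean_gradients <- function(summary) {
  dplyr::summarise(
    dplyr::group_by(summary, .data$line, .data$trait),
    beta_mean = mean(.data$beta, na.rm = TRUE),
    beta_sd = sd(.data$beta, na.rm = TRUE),
    beta_sigma_mean = mean(.data$beta_sigma, na.rm = TRUE),
    n_generations = sum(is.finite(.data$beta)),
    .groups = "drop"
  )
}
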