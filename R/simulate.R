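# symmetric PSD square root (tolerates singular and zero matrices)
mat_sqrt <- function(m) {
  e <- eigen(symm(m), symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

# n draws from N(0, sigma), as an n x d matrix
rmvn <- function(n, sigma) {
  d <- nrow(sigma)
  matrix(rnorm(n * d), n, d) %*% mat_sqrt(sigma)
}

#' Configuration of a synthetic two-stage selection experiment
#'
#' Defines the ground truth and design of a simulated selection experiment on
#' body length (`sdl`, mm) and maturity (`mat`, probit threshold trait):
#' three lines selected for large, small and random size, two-stage selection
#' (among-family preselection on mean length, then within-family truncation
#' among mature fish), inbreeding-minimizing pair assignment, and aquarium,
#' generation and inbreeding effects entering both traits.
#'
#' Default variance components, intercepts and inbreeding-depression
#' coefficients are realistic for a small laboratory fish (medaka-like):
#' additive variance 0.86 mm^2 for length with genetic correlation 0.6 to the
#' maturity liability, residual covariance giving a residual correlation of
#' about 0.94, tank (aquarium) variance larger than the additive variance,
#' substantial generation-to-generation environmental variance, a 20 mm
#' length intercept and a liability intercept placing about 90% of fish
#' mature at 75 days.
#'
#' @param g,e,aq,f_gen True 2x2 covariance components (additive, residual,
#'   aquarium, generation). `e[2,2]` must be 1 (probit residual scale).
#' @param mu Intercepts: `sdl` in mm, `mat` in probits.
#' @param f_coef Inbreeding-depression coefficients per unit inbreeding
#'   (mm for `sdl`, probits for `mat`).
#' @param lines Named character vector: line name -> selection mode
#'   (`"large"`, `"small"`, `"random"`).
#' @param families_per_line Pairs formed (= families) per line and episode.
#' @param fish_per_family Mean family size.
#' @param family_size_sd,family_size_min Family-size variability (rounded
#'   normal with a floor); set `family_size_sd = 0` for fixed sizes.
#' @param preselected_families Families kept at the among-family stage.
#' @param breeders_per_family_per_sex Within-family truncation count.
#' @param n_selection_episodes Episodes of selection after the line split.
#' @param n_random_mating_generations Random-mating generations before the
#'   split (the founder generation counts as the first).
#' @param founder_families,random_pairs Founder family count and pair count
#'   of the pre-split random matings.
#' @param min_density Families below this size are discarded at
#'   preselection (the low-density criterion).
#' @param pairing_resamples Patterns scored by the pair-assignment
#'   optimizer at each episode.
#' @param quiet_environment Zero out the generation effect (clean
#'   parameter-recovery setting)?
#' @param seed Default seed used by [simulate_experiment()].
#' @return A list of class `qgsel_config`.
#' @export
experiment_config <- function(
    g = matrix(c(0.86, 0.6 * sqrt(0.86 * 0.51), 0.6 * sqrt(0.86 * 0.51), 0.51), 2),
    e = matrix(c(3.34, 1.72, 1.72, 1), 2),
    aq = matrix(c(1.40, 0.54, 0.54, 0.50), 2),
    f_gen = matrix(c(1.05, 0.50, 0.50, 1.53), 2),
    mu = c(sdl = 20, mat = 2.4),
    f_coef = c(sdl = -6.78, mat = -10.21),
    lines = c(Large = "large", Small = "small", Control = "random"),
    families_per_line = 15,
    fish_per_family = 15,
    family_size_sd = 5.8,
    family_size_min = 4,
    preselected_families = 10,
    breeders_per_family_per_sex = 2,
    n_selection_episodes = 6,
    n_random_mating_generations = 2,
    founder_families = 54,
    random_pairs = 56,
    min_density = 5,
    pairing_resamples = 200,
    quiet_environment = FALSE,
    seed = 1) {
  for (m in list(g, e, aq, f_gen)) {
    if (!is_psd(m)) abort("covariance components must be PSD",
                          class = "qgsel_input_error")
  }
  if (abs(e[2, 2] - 1) > 1e-12) {
    abort("e[2,2] (maturity residual liability variance) must be 1",
          class = "qgsel_input_error")
  }
  if (quiet_environment) f_gen <- matrix(0, 2, 2)
  if (preselected_families > families_per_line * 1.4) {
    warn("preselecting more families than typically available")
  }
  out <- list(
    g = g, e = e, aq = aq, f_gen = f_gen, mu = mu, f_coef = f_coef,
    lines = lines, families_per_line = families_per_line,
    fish_per_family = fish_per_family, family_size_sd = family_size_sd,
    family_size_min = family_size_min,
    preselected_families = preselected_families,
    breeders_per_family_per_sex = breeders_per_family_per_sex,
    n_selection_episodes = n_selection_episodes,
    n_random_mating_generations = n_random_mating_generations,
    founder_families = founder_families, random_pairs = random_pairs,
    min_density = min_density, pairing_resamples = pairing_resamples,
    seed = seed
  )
  class(out) <- "qgsel_config"
  out
}

#' Within-family truncation selection
#'
#' Selects, among the mature fish of each sex in one family, the `k` largest
#' (`"large"`), `k` smallest (`"small"`) or `k` random (`"random"`)
#' individuals. Ties at the cutoff are resolved by stable id order. When a
#' sex has fewer than `k` mature fish, all available are returned and the
#' shortfall is flagged in the `"shortfall"` attribute.
#'
#' @param family Data frame with columns `id`, `sex`, `sdl` (or `sdl_mm`)
#'   and `mature`.
#' @param mode `"large"`, `"small"` or `"random"`.
#' @param k_per_sex Number to keep per sex.
#' @param seed Optional seed (only consulted for `mode = "random"`).
#' @return Character ids of the selected fish (attribute `"shortfall"`
#'   TRUE/FALSE).
#' @export
truncation_select <- function(family, mode = c("large", "small", "random"),
                              k_per_sex = 2, seed = NULL) {
  mode <- match.arg(mode)
  family <- tibble::as_tibble(family)
  if (nrow(family) == 0) abort("empty family", class = "qgsel_input_error")
  sdl <- if ("sdl" %in% names(family)) family$sdl else family$sdl_mm
  pool <- family[family$mature %in% c(1, TRUE), , drop = FALSE]
  sdl <- sdl[family$mature %in% c(1, TRUE)]
  pick <- with_seed(seed, {
    unlist(lapply(c("M", "F"), function(sx) {
      rows <- which(pool$sex == sx)
      if (length(rows) == 0) return(character(0))
      k <- min(k_per_sex, length(rows))
      ord <- switch(mode,
        large = rows[order(-sdl[rows], pool$id[rows])],
        small = rows[order(sdl[rows], pool$id[rows])],
        random = sample(rows)
      )
      pool$id[ord[seq_len(k)]]
    }))
  })
  shortfall <- length(pick) < 2 * k_per_sex
  attr(pick, "shortfall") <- shortfall
  pick
}

#' Among-family preselection
#'
#' Applies the two among-family criteria of the design: families below the
#' density threshold are discarded, and the remainder are ranked by mean
#' length (descending for `"large"`, ascending for `"small"`, random for
#' `"random"`); the top `n_keep` are preselected. If fewer than `n_keep`
#' families survive the density filter, all survivors are returned with a
#' flag.
#'
#' @param family_means Named numeric vector of family mean lengths.
#' @param densities Named numeric vector of family sizes (same names).
#' @param n_keep Families to preselect.
#' @param mode Selection mode.
#' @param min_density Density threshold.
#' @param seed Optional seed (only consulted for `mode = "random"`).
#' @return Character family ids (attribute `"shortfall"`).
#' @export
preselect_families <- function(family_means, densities, n_keep,
                               mode = c("large", "small", "random"),
                               min_density = 5, seed = NULL) {
  mode <- match.arg(mode)
  keep <- names(family_means)[densities[names(family_means)] >= min_density]
  shortfall <- length(keep) < n_keep
  out <- with_seed(seed, {
    ord <- switch(mode,
      large = keep[order(-family_means[keep], keep)],
      small = keep[order(family_means[keep], keep)],
      random = sample(keep)
    )
    ord[seq_len(min(n_keep, length(ord)))]
  })
  attr(out, "shortfall") <- shortfall
  out
}

# internal growing state for the simulator
new_sim_state <- function() {
  env <- new.env(parent = emptyenv())
  env$rows <- list()
  env$counter <- 0L
  env$aq_effects <- list()
  env$gen_effects <- list()
  env
}

#' Simulate a full two-stage selection experiment
#'
#' Generates a pedigree and phenotype table under a known ground truth: a
#' founder generation of unrelated families, pre-split random-mating
#' generations, allocation of families to the selected lines, and the
#' configured number of selection episodes with among-family preselection on
#' mean length, within-family truncation among mature fish, and
#' inbreeding-minimizing pair assignment. Breeding values follow the
#' infinitesimal model (founders `N(0, G)`, offspring centered on the
#' midparent with segregation covariance `G/2`); maturity is the indicator
#' of a latent liability, sharing its residual, aquarium, generation and
#' inbreeding structure with length.
#'
#' @param config An [experiment_config()].
#' @param seed Seed (defaults to `config$seed`).
#' @return An object of class `qgsel_experiment`: list with `pedigree`,
#'   `phenotypes`, `truth` (per-individual components whose sum reproduces
#'   the phenotypes exactly, plus the true parameters) and `config`.
#' @export
simulate_experiment <- function(config = experiment_config(),
                                seed = config$seed) {
  stopifnot(inherits(config, "qgsel_config"))
  with_seed(seed, simulate_experiment_impl(config, seed))
}

simulate_experiment_impl <- function(config, seed) {
  st <- new_sim_state()
  n_rm <- config$n_random_mating_generations
  n_gens <- n_rm + config$n_selection_episodes
  # generation environmental effects, shared across lines
  gen_eff <- rmvn(n_gens, config$f_gen)

  new_family <- function(sire_id, dam_id, f_child, mid_bv, line, gen, aq_id,
                         size) {
    bv <- matrix(rep(mid_bv, each = size), size, 2) + rmvn(size, config$g / 2)
    add_fish(bv, f_child, line, gen, aq_id, size, sire_id, dam_id)
  }

  add_fish <- function(bv, f, line, gen, aq_id, size, sire_id = NA_character_,
                       dam_id = NA_character_) {
    aq_eff <- rmvn(1, config$aq)
    e <- rmvn(size, config$e)
    ids <- sprintf("I%06d", st$counter + seq_len(size))
    st$counter <- st$counter + size
    latent <- matrix(rep(config$mu, each = size), size, 2) +
      matrix(rep(config$f_coef * f, each = size), size, 2) +
      bv +
      matrix(rep(aq_eff, each = size), size, 2) +
      matrix(rep(gen_eff[gen + 1, ], each = size), size, 2) +
      e
    # plain list chunks; assembled into one tibble at the end (fast path)
    st$rows[[length(st$rows) + 1L]] <- list(
      id = ids, sire = rep(sire_id, size), dam = rep(dam_id, size),
      sex = sample(c("M", "F"), size, replace = TRUE),
      line = rep(line, size), generation = rep(as.integer(gen), size),
      aquarium = rep(aq_id, size), f = rep(f, size),
      bv_sdl = bv[, 1], bv_mat = bv[, 2],
      aq_sdl = rep(aq_eff[1], size), aq_mat = rep(aq_eff[2], size),
      gen_sdl = rep(gen_eff[gen + 1, 1], size),
      gen_mat = rep(gen_eff[gen + 1, 2], size),
      resid_sdl = e[, 1], resid_mat = e[, 2],
      sdl_mm = latent[, 1], liability = latent[, 2],
      mature = as.integer(latent[, 2] > 0),
      is_breeder = rep(FALSE, size), n_offspring = rep(0L, size),
      family_preselected = rep(FALSE, size)
    )
    ids
  }

  fam_size <- function(n) {
    if (config$family_size_sd == 0) return(rep(as.integer(config$fish_per_family), n))
    pmax(as.integer(round(rnorm(n, config$fish_per_family, config$family_size_sd))),
         as.integer(config$family_size_min))
  }

  current <- function() {
    flds <- names(st$rows[[1]])
    tibble::as_tibble(lapply(setNames(flds, flds), function(fl) {
      unlist(lapply(st$rows, `[[`, fl), use.names = FALSE)
    }))
  }

  mark <- function(ids, col, value = TRUE) {
    for (i in seq_along(st$rows)) {
      hit <- st$rows[[i]]$id %in% ids
      if (any(hit)) st$rows[[i]][[col]][hit] <- value
    }
  }

  # --- founder generation: unrelated families -------------------------------
  sizes <- fam_size(config$founder_families)
  for (fam in seq_len(config$founder_families)) {
    bv <- rmvn(sizes[fam], config$g)
    add_fish(bv, 0, "Founder", 0L, sprintf("T_g0_%03d", fam), sizes[fam])
  }

  # one selection-or-random episode: pick breeders in `fish`, form pairs,
  # create the next generation
  episode <- function(fish, mode, n_keep, n_pairs, line_next, gen_next,
                      select_size = TRUE) {
    fams <- split(fish, fish$aquarium)
    densities <- vapply(fams, nrow, integer(1))
    means <- vapply(fams, function(f) mean(f$sdl_mm), numeric(1))
    presel <- preselect_families(means, densities, n_keep,
                                 mode = if (select_size) mode else "random",
                                 min_density = config$min_density)
    if (length(presel) == 0) {
      abort(sprintf("line '%s' lost all families", line_next),
            class = "qgsel_line_extinct")
    }
    mark(fish$id[fish$aquarium %in% presel], "family_preselected")

    k <- config$breeders_per_family_per_sex
    pick_candidates <- function(strict) {
      cand <- purrr::map(presel, function(fa) {
        f <- fams[[fa]]
        n_mat <- table(factor(f$sex[f$mature == 1], levels = c("M", "F")))
        if (strict && any(n_mat < k)) {
          inform(sprintf("family %s skipped: fewer than %d mature fish of a sex",
                         fa, k))
          return(NULL)
        }
        ids <- truncation_select(
          f[, c("id", "sex", "sdl_mm", "mature")], mode = mode, k_per_sex = k)
        f[f$id %in% ids, c("id", "sex")]
      })
      dplyr::bind_rows(cand)
    }
    cand <- pick_candidates(strict = TRUE)
    n_m <- sum(cand$sex == "M"); n_f <- sum(cand$sex == "F")
    # strong maturity attrition: re-admit shortfall families rather than lose
    # the line (the breeding protocol uses whatever mature fish are available)
    if (min(n_m, n_f) < max(2, floor(n_pairs / 3))) {
      cand <- pick_candidates(strict = FALSE)
      n_m <- sum(cand$sex == "M"); n_f <- sum(cand$sex == "F")
    }
    pairs_here <- min(n_pairs, n_m, n_f)
    if (pairs_here == 0) {
      abort(sprintf("line '%s' has no breeding pairs left", line_next),
            class = "qgsel_line_extinct")
    }
    bv_lookup <- current()
    pat <- optimize_pairing(bv_lookup[, c("id", "sire", "dam")], cand,
                            pairs_here,
                            n_resamples = config$pairing_resamples)
    sizes <- fam_size(pairs_here)
    for (p in seq_len(pairs_here)) {
      srow <- bv_lookup[bv_lookup$id == pat$sire[p], ]
      drow <- bv_lookup[bv_lookup$id == pat$dam[p], ]
      mid <- c((srow$bv_sdl + drow$bv_sdl) / 2, (srow$bv_mat + drow$bv_mat) / 2)
      new_family(pat$sire[p], pat$dam[p], pat$f[p], mid, line_next, gen_next,
                 sprintf("T_%s_g%d_%03d", line_next, gen_next, p), sizes[p])
    }
    mark(pat$sire, "is_breeder")
    mark(pat$dam, "is_breeder")
    for (p in seq_len(pairs_here)) {
      mark(c(pat$sire[p], pat$dam[p]), "n_offspring", sizes[p])
    }
    invisible(NULL)
  }

  # --- pre-split random matings ---------------------------------------------
  for (g in seq_len(n_rm - 1)) {
    fish <- current()
    fish <- fish[fish$generation == g - 1, ]
    episode(fish, mode = "random", n_keep = length(unique(fish$aquarium)),
            n_pairs = config$random_pairs, line_next = "Founder",
            gen_next = g, select_size = FALSE)
  }

  # --- allocate families of the last pre-split generation to lines ----------
  split_gen <- n_rm - 1
  fish <- current()
  fish <- fish[fish$generation == split_gen, ]
  fam_ids <- sample(unique(fish$aquarium))
  alloc <- split(fam_ids, rep(names(config$lines),
                              length.out = length(fam_ids)))
  for (ln in names(config$lines)) {
    mark(fish$id[fish$aquarium %in% alloc[[ln]]], "line", ln)
  }

  # --- selection episodes ----------------------------------------------------
  for (ep in seq_len(config$n_selection_episodes)) {
    gen_now <- split_gen + ep - 1
    all_fish <- current()
    for (ln in names(config$lines)) {
      fish <- all_fish[all_fish$generation == gen_now & all_fish$line == ln, ]
      episode(fish, mode = config$lines[[ln]],
              n_keep = config$preselected_families,
              n_pairs = config$families_per_line,
              line_next = ln, gen_next = gen_now + 1)
    }
  }

  full <- current()
  pedigree <- full[, c("id", "sire", "dam", "sex", "line", "generation",
                       "aquarium")]
  phenotypes <- full[, c("id", "sdl_mm", "mature", "is_breeder",
                         "n_offspring", "family_preselected")]
  truth <- full[, c("id", "f", "bv_sdl", "bv_mat", "aq_sdl", "aq_mat",
                    "gen_sdl", "gen_mat", "resid_sdl", "resid_mat",
                    "liability")]
  out <- list(pedigree = pedigree, phenotypes = phenotypes, truth = truth,
              params = list(g = config$g, e = config$e, aq = config$aq,
                            f_gen = config$f_gen, mu = config$mu,
                            f_coef = config$f_coef),
              config = config, seed = seed)
  class(out) <- "qgsel_experiment"
  out
}

#' @export
print.qgsel_experiment <- function(x, ...) {
  cat(sprintf("<qgsel_experiment> %d fish, %d generations, lines: %s (seed %s)\n",
              nrow(x$pedigree), max(x$pedigree$generation) + 1,
              paste(names(x$config$lines), collapse = ", "),
              format(x$seed)))
  invisible(x)
}

#' Recombine stored truth components into phenotypes
#'
#' Reconstructs `sdl_mm` and `mature` from the stored per-individual truth
#' components (intercept + inbreeding term + breeding value + aquarium +
#' generation + residual). Used to verify that the generator's bookkeeping is
#' exact.
#'
#' @param experiment A [simulate_experiment()] result.
#' @return Tibble `id`, `sdl_mm`, `mature`.
#' @export
recombine_truth <- function(experiment) {
  tr <- experiment$truth
  p <- experiment$params
  sdl <- p$mu[1] + p$f_coef[1] * tr$f + tr$bv_sdl + tr$aq_sdl + tr$gen_sdl +
    tr$resid_sdl
  liab <- p$mu[2] + p$f_coef[2] * tr$f + tr$bv_mat + tr$aq_mat + tr$gen_mat +
    tr$resid_mat
  tibble::tibble(id = tr$id, sdl_mm = sdl, mature = as.integer(liab > 0))
}
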