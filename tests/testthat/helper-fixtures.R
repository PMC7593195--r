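# shared in-code fixtures

# founders a,b + full sibs c,d + their inbred offspring e (F = 0.25)
ped_sib_mating <- function() {
  tibble::tibble(
    id = c("a", "b", "c", "d", "e"),
    sire = c(NA, NA, "a", "a", "c"),
    dam = c(NA, NA, "b", "b", "d")
  )
}

# random pedigree: n0 founders, then g generations of random mating
random_pedigree <- function(n0 = 10, g = 3, per_gen = 10, seed = 1) {
  withr::with_seed(seed, {
    id <- sprintf("f%02d", seq_len(n0))
    sire <- rep(NA_character_, n0)
    dam <- rep(NA_character_, n0)
    sex <- rep(c("M", "F"), length.out = n0)
    prev <- tibble::tibble(id = id, sex = sex)
    for (gen in seq_len(g)) {
      males <- prev$id[prev$sex == "M"]
      females <- prev$id[prev$sex == "F"]
      nid <- sprintf("g%d_%02d", gen, seq_len(per_gen))
      nsire <- sample(males, per_gen, replace = TRUE)
      ndam <- sample(females, per_gen, replace = TRUE)
      nsex <- sample(c("M", "F"), per_gen, replace = TRUE)
      id <- c(id, nid); sire <- c(sire, nsire); dam <- c(dam, ndam)
      sex <- c(sex, nsex)
      prev <- tibble::tibble(id = nid, sex = nsex)
    }
    tibble::tibble(id = id, sire = sire, dam = dam, sex = sex)
  })
}

# minimal two-family phenotype table with explicit family structure
toy_phenotypes <- function() {
  tibble::tibble(
    id = sprintf("i%02d", 1:8),
    aquarium = rep(c("fam1", "fam2"), each = 4),
    line = "L", generation = 1L,
    sdl_mm = c(2, 4, 3, 5, 6, 8, 7, 9),
    mature = c(1, 1, 1, 0, 1, 1, 1, 1),
    is_breeder = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    n_offspring = c(3L, 1L, 0L, 0L, 0L, 0L, 0L, 0L),
    family_preselected = rep(c(TRUE, FALSE), each = 4)
  )
}

# small, fast synthetic experiment (reduced counts, quiet environment);
# ... overrides the reduced defaults
small_experiment <- function(seed = 11, ...) {
  args <- utils::modifyList(
    list(families_per_line = 6, fish_per_family = 10, family_size_sd = 0,
         preselected_families = 4, n_selection_episodes = 3,
         founder_families = 12, random_pairs = 12, min_density = 2,
         pairing_resamples = 50, quiet_environment = TRUE, seed = seed),
    list(...))
  cfg <- do.call(experiment_config, args)
  suppressMessages(suppressWarnings(simulate_experiment(cfg)))
}
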