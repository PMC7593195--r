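test_that("tabular relationship matrix reproduces textbook cases", {
  # two unrelated founders
  ped <- tibble::tibble(id = c("x", "y"), sire = c(NA, NA), dam = c(NA, NA))
  expect_equal(unname(build_relationship_matrix(ped)$a_matrix), diag(2))

  # parent-offspring relatedness 0.5, no inbreeding
  ped <- tibble::tibble(id = c("s", "d", "o"), sire = c(NA, NA, "s"),
                        dam = c(NA, NA, "d"))
  a <- build_relationship_matrix(ped)$a_matrix
  expect_equal(a["o", "s"], 0.5)
  expect_equal(a["o", "d"], 0.5)
  expect_equal(a["o", "o"], 1.0)

  # full-sib mating: offspring F = 0.25, diagonal 1.25
  rel <- build_relationship_matrix(ped_sib_mating())
  expect_equal(rel$a_matrix["e", "e"], 1.25)
  expect_equal(rel$inbreeding$f[rel$inbreeding$id == "e"], 0.25)
  expect_equal(rel$coancestry, rel$a_matrix / 2)
})

test_that("gene-dropping oracle agrees with the tabular method", {
  set.seed(7)
  n_rep <- 1e5
  for (seed in 1:3) {
    ped <- random_pedigree(n0 = 8, g = 3, per_gen = 7, seed = seed)
    a_tab <- build_relationship_matrix(ped)$a_matrix
    theta <- gene_drop_kinship(ped, n_rep = n_rep, seed = seed + 100)
    a_mc <- 2 * theta
    diag(a_mc) <- 2 * diag(theta) # A_ii = 2 * theta_ii
    # binomial-ish Monte-Carlo standard error per entry
    se <- pmax(sqrt(a_mc * (2 - a_mc) / n_rep), 1e-4)
    expect_true(all(abs(a_tab - a_mc) <= 3.5 * se))
  }
})

test_that("Meuwissen-Luo inbreeding matches the dense diagonal and is order-invariant", {
  ped <- random_pedigree(n0 = 10, g = 4, per_gen = 12, seed = 3)
  a <- build_relationship_matrix(ped)
  f1 <- ped_inbreeding(ped)
  expect_equal(f1$f[match(rownames(a$a_matrix), f1$id)],
               unname(diag(a$a_matrix) - 1), tolerance = 1e-12)
  # shuffle record order (still a valid pedigree, just unsorted)
  perm <- withr::with_seed(1, sample(nrow(ped)))
  f2 <- ped_inbreeding(ped[perm, ])
  expect_equal(f2$f[match(f1$id, f2$id)], f1$f, tolerance = 1e-12)
})

test_that("A is symmetric PSD and A-inverse actually inverts A", {
  for (seed in 1:4) {
    ped <- random_pedigree(n0 = 6, g = 3, per_gen = 8, seed = seed)
    a <- build_relationship_matrix(ped)$a_matrix
    expect_equal(a, t(a))
    ev <- eigen(a, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8)
    pc <- qgsel:::ped_compile(ped)
    ainv <- as.matrix(qgsel:::ped_ainverse(pc)$ainv)
    ids <- pc$ids
    expect_equal(ainv %*% a[ids, ids], diag(nrow(a)), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("structural errors are caught", {
  expect_error(build_relationship_matrix(
    tibble::tibble(id = c("a", "a"), sire = c(NA, NA), dam = c(NA, NA))),
    class = "qgsel_structure_error")
  expect_error(build_relationship_matrix(
    tibble::tibble(id = "a", sire = "ghost", dam = NA)),
    class = "qgsel_structure_error")
  # cycle
  expect_error(build_relationship_matrix(
    tibble::tibble(id = c("a", "b"), sire = c("b", "a"), dam = c(NA, NA))),
    class = "qgsel_structure_error")
})

test_that("prospective inbreeding equals parental coancestry", {
  ped <- ped_sib_mating()
  pairs <- tibble::tibble(sire = c("a", "c", "c"), dam = c("b", "d", "b"))
  f <- prospective_inbreeding(ped, pairs)$f
  expect_equal(f[1], 0)      # unrelated founders
  expect_equal(f[2], 0.25)   # full sibs
  expect_equal(f[3], 0.25)   # parent-offspring theta
  # half sibs -> 0.125
  hs <- tibble::tibble(id = c("s", "d1", "d2", "o1", "o2"),
                       sire = c(NA, NA, NA, "s", "s"),
                       dam = c(NA, NA, NA, "d1", "d2"))
  expect_equal(prospective_inbreeding(hs, tibble::tibble(sire = "o1", dam = "o2"))$f,
               0.125)
  expect_error(prospective_inbreeding(ped, tibble::tibble(sire = "zz", dam = "a")),
               class = "qgsel_structure_error")
})

test_that("optimize_pairing avoids sib matings when it can and warns when it cannot", {
  # 2 families x (2M + 2F): cross-family pairing gives median F = 0
  ped <- tibble::tibble(
    id = c("s1", "d1", "s2", "d2", paste0("A", 1:4), paste0("B", 1:4)),
    sire = c(rep(NA, 4), rep("s1", 4), rep("s2", 4)),
    dam = c(rep(NA, 4), rep("d1", 4), rep("d2", 4))
  )
  cand <- tibble::tibble(id = c(paste0("A", 1:4), paste0("B", 1:4)),
                         sex = rep(c("M", "M", "F", "F"), 2))
  pat <- optimize_pairing(ped, cand, n_pairs = 4, n_resamples = 2000, seed = 1)
  expect_equal(attr(pat, "median_f"), 0)
  # exhaustive check: a fully cross-family pattern exists, so the optimum is 0
  expect_true(all(pat$f == 0))
  expect_equal(anyDuplicated(pat$sire), 0)
  expect_equal(anyDuplicated(pat$dam), 0)

  # single family: forced sib mating, median 0.25 with a warning
  cand1 <- tibble::tibble(id = paste0("A", 1:4), sex = c("M", "M", "F", "F"))
  expect_warning(
    pat1 <- optimize_pairing(ped, cand1, n_pairs = 2, n_resamples = 50, seed = 1),
    "full-sib")
  expect_equal(attr(pat1, "median_f"), 0.25)

  # unrelated founders: any pattern has median 0
  cand0 <- tibble::tibble(id = c("s1", "s2", "d1", "d2"),
                          sex = c("M", "M", "F", "F"))
  pat0 <- optimize_pairing(ped, cand0, n_pairs = 2, n_resamples = 10, seed = 2)
  expect_equal(attr(pat0, "median_f"), 0)

  # determinism under a fixed seed
  p1 <- optimize_pairing(ped, cand, n_pairs = 4, n_resamples = 200, seed = 9)
  p2 <- optimize_pairing(ped, cand, n_pairs = 4, n_resamples = 200, seed = 9)
  expect_identical(p1, p2)

  expect_error(optimize_pairing(ped, cand1, n_pairs = 3, n_resamples = 10),
               class = "qgsel_capacity_error")
})

test_that("optimized pairing is never beaten by random patterns", {
  ped <- small_experiment(seed = 21)$pedigree
  last <- ped[ped$generation == max(ped$generation) & ped$line == "Large", ]
  cand <- tibble::tibble(id = last$id, sex = last$sex)
  cand <- dplyr::slice_head(dplyr::group_by(cand, sex), n = 8)
  pat <- optimize_pairing(ped, cand, n_pairs = 5, n_resamples = 300, seed = 5)
  best <- attr(pat, "median_f")
  theta <- build_relationship_matrix(qgsel:::prune_pedigree(ped, cand$id))$coancestry
  males <- cand$id[cand$sex == "M"]; females <- cand$id[cand$sex == "F"]
  set.seed(99)
  rand_meds <- replicate(1000, {
    median(theta[cbind(sample(males, 5), sample(females, 5))])
  })
  expect_true(all(best <= rand_meds + 1e-12))
})

test_that("inbreeding-based Ne uses the linear increment and rounds as reported", {
  expect_identical(ne_from_inbreeding(0.11, 6), 27)
  expect_identical(ne_from_inbreeding(0.091, 6), 33)
  expect_identical(ne_from_inbreeding(0.085, 6), 35)
  expect_equal(ne_from_inbreeding(0.11, 6, rounded = FALSE), 6 / 0.22)
  # the compound form 1-(1-1/2Ne)^g would disagree for the strongest case:
  ne_compound <- 1 / (2 * (1 - (1 - 0.11)^(1 / 6)))
  expect_identical(round(ne_compound), 26)
  expect_error(ne_from_inbreeding(0, 6), class = "qgsel_unbounded_ne")
  expect_error(ne_from_inbreeding(1.2, 6), class = "qgsel_input_error")
})
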