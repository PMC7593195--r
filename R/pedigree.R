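#' Pedigree tables
#'
#' A pedigree is an ordinary data frame with one row per individual and
#' columns `id`, `sire`, `dam` (character; `NA` or `""` for an unknown
#' parent), plus optional annotation columns `sex` (`"M"`, `"F"`, `"U"`),
#' `line`, `generation` (integer, founders at 0) and `aquarium` (the rearing
#' tank, which doubles as the full-sib family identifier). All relatedness
#' functions in the package accept the rows in any order; internally the
#' pedigree is sorted so that parents precede their offspring, and a cycle or
#' a parent id without a matching record is a structural error.
#'
#' @name pedigree-format
NULL

# normalize columns and types; does not reorder
ped_normalize <- function(ped) {
  ped <- tibble::as_tibble(ped)
  need <- c("id", "sire", "dam")
  miss <- setdiff(need, names(ped))
  if (length(miss) > 0) {
    abort(paste0("pedigree is missing column(s): ", paste(miss, collapse = ", ")),
          class = "qgsel_structure_error")
  }
  for (col in need) {
    v <- as.character(ped[[col]])
    v[!is.na(v) & v == ""] <- NA_character_
    ped[[col]] <- v
  }
  if (anyNA(ped$id)) {
    abort("pedigree contains missing ids", class = "qgsel_structure_error")
  }
  ped
}

# validate and topologically sort; returns the sorted tibble plus 0-based
# parent indices into the sorted order
ped_compile <- function(ped) {
  ped <- ped_normalize(ped)
  n <- nrow(ped)
  if (anyDuplicated(ped$id) > 0) {
    dup <- unique(ped$id[duplicated(ped$id)])
    abort(paste0("duplicated pedigree ids: ", paste(head(dup, 5), collapse = ", ")),
          class = "qgsel_structure_error")
  }
  idx <- setNames(seq_len(n), ped$id)
  sire <- unname(idx[ped$sire])
  dam <- unname(idx[ped$dam])
  bad <- c(ped$sire[!is.na(ped$sire) & is.na(sire)],
           ped$dam[!is.na(ped$dam) & is.na(dam)])
  if (length(bad) > 0) {
    abort(paste0("parent id(s) absent from the pedigree: ",
                 paste(head(unique(bad), 5), collapse = ", ")),
          class = "qgsel_structure_error")
  }
  if (any(sire == seq_len(n), na.rm = TRUE) || any(dam == seq_len(n), na.rm = TRUE)) {
    abort("an individual is recorded as its own parent",
          class = "qgsel_structure_error")
  }

  # Kahn's algorithm
  indeg <- (!is.na(sire)) + (!is.na(dam))
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(sire[i], dam[i])) {
      if (!is.na(p)) kids[[p]] <- c(kids[[p]], i)
    }
  }
  queue <- which(indeg == 0L)
  order <- integer(0)
  while (length(queue) > 0) {
    v <- queue[[1]]
    queue <- queue[-1]
    order <- c(order, v)
    for (k in kids[[v]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(order) != n) {
    cyc <- ped$id[indeg > 0L]
    abort(paste0("pedigree contains a cycle involving: ",
                 paste(head(cyc, 5), collapse = ", ")),
          class = "qgsel_structure_error")
  }
  sorted <- ped[order, , drop = FALSE]
  idx2 <- setNames(seq_len(n), sorted$id)
  s0 <- unname(idx2[sorted$sire]); s0[is.na(s0)] <- 0L
  d0 <- unname(idx2[sorted$dam]); d0[is.na(d0)] <- 0L
  list(ped = sorted, sire0 = as.integer(s0 - 1L), dam0 = as.integer(d0 - 1L),
       ids = sorted$id)
}

# ancestors closure of a set of ids, as a sub-pedigree
prune_pedigree <- function(ped, ids) {
  ped <- ped_normalize(ped)
  keep <- unique(ids)
  missing <- setdiff(keep, ped$id)
  if (length(missing) > 0) {
    abort(paste0("id(s) absent from the pedigree: ",
                 paste(head(missing, 5), collapse = ", ")),
          class = "qgsel_structure_error")
  }
  frontier <- keep
  repeat {
    rows <- ped[ped$id %in% frontier, , drop = FALSE]
    parents <- setdiff(stats::na.omit(c(rows$sire, rows$dam)), keep)
    if (length(parents) == 0) break
    keep <- c(keep, parents)
    frontier <- parents
  }
  ped[ped$id %in% keep, , drop = FALSE]
}

#' Additive relationship matrix, inbreeding and coancestry from a pedigree
#'
#' Builds the (dense) additive relationship matrix **A** by the recursive
#' tabular method, along with per-individual inbreeding coefficients
#' \eqn{F_i} and the pairwise coancestry (kinship) matrix
#' \eqn{\theta = A / 2}. The diagonal of **A** is \eqn{1 + F_i}, and
#' off-diagonal entries are twice the coancestry of the pair. Founders
#' (individuals with both parents unknown) are treated as unrelated and
#' non-inbred.
#'
#' The dense matrix grows with the square of the pedigree size; for large
#' pedigrees the model-fitting code uses the sparse inverse of **A** directly
#' and never forms this matrix.
#'
#' @param ped A pedigree data frame (see [pedigree-format]).
#' @return An object of class `qgsel_relatedness`: a list with elements
#'   `a_matrix` (dense, dimnames = ids), `coancestry` (`a_matrix / 2`), and
#'   `inbreeding` (tibble with `id` and `f`).
#' @examples
#' ped <- tibble::tibble(id = c("s", "d", "o"), sire = c(NA, NA, "s"),
#'                       dam = c(NA, NA, "d"))
#' rel <- build_relationship_matrix(ped)
#' rel$a_matrix["o", "s"] # 0.5
#' @export
build_relationship_matrix <- function(ped) {
  pc <- ped_compile(ped)
  a <- ped_tabular_a_cpp(pc$sire0, pc$dam0)
  dimnames(a) <- list(pc$ids, pc$ids)
  f <- diag(a) - 1
  out <- list(
    a_matrix = a,
    coancestry = a / 2,
    inbreeding = tibble::tibble(id = pc$ids, f = unname(f))
  )
  class(out) <- "qgsel_relatedness"
  out
}

#' @export
print.qgsel_relatedness <- function(x, ...) {
  cat("<qgsel_relatedness> ", nrow(x$a_matrix), " individuals, mean F = ",
      signif(mean(x$inbreeding$f), 3), "\n", sep = "")
  invisible(x)
}

#' Inbreeding coefficients for every pedigree member
#'
#' Computes \eqn{F_i} for all individuals with the Meuwissen-Luo algorithm,
#' which scales to large pedigrees without forming the dense relationship
#' matrix.
#'
#' @inheritParams build_relationship_matrix
#' @return A tibble with columns `id` and `f`, in the input row order.
#' @export
ped_inbreeding <- function(ped) {
  pc <- ped_compile(ped)
  res <- ped_inbreeding_cpp(pc$sire0, pc$dam0)
  out <- tibble::tibble(id = pc$ids, f = res$F)
  out[match(ped_normalize(ped)$id, out$id), ]
}

# sparse inverse of A (dgCMatrix) + inbreeding, for the animal model
ped_ainverse <- function(pc) {
  res <- ped_inbreeding_cpp(pc$sire0, pc$dam0)
  tri <- ped_ainverse_cpp(pc$sire0, pc$dam0, res$D)
  ainv <- Matrix::sparseMatrix(i = tri$i + 1L, j = tri$j + 1L, x = tri$x,
                               dims = c(length(pc$ids), length(pc$ids)))
  list(ainv = methods::as(ainv, "CsparseMatrix"), f = res$F)
}

#' Monte-Carlo gene-dropping estimate of the kinship matrix
#'
#' Drops two distinct alleles per founder down the pedigree under Mendelian
#' transmission and estimates the coancestry \eqn{\theta_{ij}} as the
#' probability that one allele drawn at random from each individual is
#' identical by descent. This sampler is independent of the tabular and
#' Henderson code paths and is intended as a cross-check on small pedigrees.
#'
#' @inheritParams build_relationship_matrix
#' @param n_rep Number of allele-transmission replicates.
#' @param seed Optional seed for reproducibility.
#' @return A kinship matrix estimate with dimnames = ids (note
#'   \eqn{A = 2\theta} off-diagonal and \eqn{A_{ii} = 2\theta_{ii}}).
#' @export
gene_drop_kinship <- function(ped, n_rep = 1e5, seed = NULL) {
  pc <- ped_compile(ped)
  theta <- with_seed(seed, ped_gene_drop_cpp(pc$sire0, pc$dam0, as.integer(n_rep)))
  dimnames(theta) <- list(pc$ids, pc$ids)
  theta
}

#' Inbreeding coefficient of the offspring of candidate pairs
#'
#' The inbreeding coefficient of a prospective offspring equals the
#' coancestry of its parents, so this evaluates \eqn{\theta(sire, dam)} for
#' each candidate pair without modifying the pedigree.
#'
#' @inheritParams build_relationship_matrix
#' @param pairs A data frame with columns `sire` and `dam` (ids present in
#'   the pedigree).
#' @return `pairs` as a tibble with an added column `f`.
#' @export
prospective_inbreeding <- function(ped, pairs) {
  pairs <- tibble::as_tibble(pairs)
  if (!all(c("sire", "dam") %in% names(pairs))) {
    abort("`pairs` needs columns `sire` and `dam`", class = "qgsel_input_error")
  }
  ids <- unique(c(pairs$sire, pairs$dam))
  sub <- prune_pedigree(ped, ids)
  rel <- build_relationship_matrix(sub)
  pairs$f <- rel$coancestry[cbind(pairs$sire, pairs$dam)]
  pairs
}

#' Pairing pattern minimizing the median prospective inbreeding
#'
#' Emulates the resampling procedure used to assign breeding pairs in
#' pedigree-managed selection lines: candidate patterns (each candidate used
#' at most once, one male and one female per pair) are sampled at random, the
#' median inbreeding coefficient of the prospective offspring is computed for
#' each, and the pattern with the smallest median is returned. Ties on the
#' median are broken by the smaller mean, then by sampling order, so the
#' result is deterministic under a fixed seed.
#'
#' @inheritParams build_relationship_matrix
#' @param candidates Data frame with columns `id` and `sex` (`"M"`/`"F"`),
#'   typically the within-family selected breeders.
#' @param n_pairs Number of pairs to form.
#' @param n_resamples Number of random patterns to score.
#' @param seed Optional seed.
#' @param forbid_sibs If `TRUE`, patterns containing a full-sib or more
#'   closely related pair (coancestry >= 0.25) are rejected outright; an
#'   error is raised if no sampled pattern is feasible.
#' @return A tibble of `n_pairs` rows with columns `sire`, `dam`, `f`, with
#'   attributes `median_f` and `mean_f`. A warning is emitted when the best
#'   pattern still contains full-sib matings.
#' @export
optimize_pairing <- function(ped, candidates, n_pairs, n_resamples = 10000,
                             seed = NULL, forbid_sibs = FALSE) {
  candidates <- tibble::as_tibble(candidates)
  if (!all(c("id", "sex") %in% names(candidates))) {
    abort("`candidates` needs columns `id` and `sex`", class = "qgsel_input_error")
  }
  check_number(n_pairs, "n_pairs", lower = 1)
  check_number(n_resamples, "n_resamples", lower = 1)
  males <- candidates$id[candidates$sex == "M"]
  females <- candidates$id[candidates$sex == "F"]
  if (length(males) < n_pairs || length(females) < n_pairs) {
    abort(sprintf("need at least %d candidates of each sex (have %d M, %d F)",
                  n_pairs, length(males), length(females)),
          class = "qgsel_capacity_error")
  }
  sub <- prune_pedigree(ped, candidates$id)
  theta <- build_relationship_matrix(sub)$coancestry

  with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_resamples)) {
      m <- sample(males, n_pairs)
      f <- sample(females, n_pairs)
      fv <- theta[cbind(m, f)]
      if (forbid_sibs && any(fv >= 0.25 - 1e-12)) next
      cand <- list(median = median(fv), mean = mean(fv), m = m, f = f, fv = fv)
      if (is.null(best) ||
          cand$median < best$median - 1e-15 ||
          (abs(cand$median - best$median) <= 1e-15 && cand$mean < best$mean - 1e-15)) {
        best <- cand
      }
    }
    if (is.null(best)) {
      abort("no feasible pairing pattern found with `forbid_sibs = TRUE`",
            class = "qgsel_capacity_error")
    }
    if (any(best$fv >= 0.25 - 1e-12)) {
      warn("optimal pairing pattern still contains full-sib (or closer) matings")
    }
    out <- tibble::tibble(sire = best$m, dam = best$f, f = unname(best$fv))
    attr(out, "median_f") <- best$median
    attr(out, "mean_f") <- best$mean
    out
  })
}

#' Inbreeding effective population size
#'
#' Under an idealized population of effective size \eqn{N_e}, inbreeding
#' accumulates by about \eqn{1/(2N_e)} per generation, so a mean inbreeding
#' coefficient \eqn{\bar F} reached after \eqn{g} generations implies
#' \eqn{N_e = g / (2 \bar F)}. This linear-increment form is used (rather
#' than compounding \eqn{1 - (1 - 1/2N_e)^g}) because it is the conventional
#' report for short breeding experiments; the two agree closely at small
#' \eqn{\bar F}.
#'
#' @param mean_f Mean inbreeding coefficient reached, in (0, 1).
#' @param n_generations Number of generations over which it accumulated.
#' @param rounded Round to the nearest integer (the conventional report)?
#' @return The effective size estimate (integer-rounded by default).
#' @examples
#' ne_from_inbreeding(0.11, 6) # 27
#' @export
ne_from_inbreeding <- function(mean_f, n_generations, rounded = TRUE) {
  check_number(n_generations, "n_generations", lower = 1)
  if (!is.numeric(mean_f) || length(mean_f) != 1L || !is.finite(mean_f)) {
    abort("`mean_f` must be a single finite number", class = "qgsel_input_error")
  }
  if (mean_f == 0) {
    abort("mean inbreeding is exactly 0: the inbreeding effective size is unbounded",
          class = "qgsel_unbounded_ne")
  }
  if (mean_f < 0 || mean_f >= 1) {
    abort("`mean_f` must lie in (0, 1)", class = "qgsel_input_error")
  }
  ne <- n_generations / (2 * mean_f)
  if (rounded) round(ne) else ne
}
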