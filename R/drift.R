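# simulate breeding values down a compiled pedigree for one G matrix;
# returns n_ped x d matrix. Founders ~ N(0, G); offspring ~ N(midparent,
# G/2); a missing parent contributes a fresh founder value. The optional
# inbreeding correction shrinks the segregation variance by
# (1 - (F_s + F_d)/2).
simulate_bv <- function(pc, g, inbreeding_correction = FALSE, f = NULL) {
  n <- length(pc$ids)
  d <- nrow(g)
  cg <- mat_sqrt(g)
  cg2 <- mat_sqrt(g / 2)
  a <- matrix(0, n, d)
  s <- pc$sire0 + 1L
  dm <- pc$dam0 + 1L
  founder <- s == 0L & dm == 0L
  nf <- sum(founder)
  a[founder, ] <- matrix(rnorm(nf * d), nf, d) %*% cg
  # process by pedigree depth so whole levels vectorize
  depth <- integer(n)
  for (i in seq_len(n)) {
    depth[i] <- 1L + max(if (s[i] > 0) depth[s[i]] else 0L,
                         if (dm[i] > 0) depth[dm[i]] else 0L)
  }
  for (lev in sort(unique(depth[!founder]))) {
    idx <- which(depth == lev & !founder)
    m <- length(idx)
    si <- s[idx]; di <- dm[idx]
    pa <- matrix(0, m, d); pb <- matrix(0, m, d)
    pa[si > 0, ] <- a[si[si > 0], , drop = FALSE]
    pb[di > 0, ] <- a[di[di > 0], , drop = FALSE]
    # phantom founder for a missing parent
    if (any(si == 0)) pa[si == 0, ] <- matrix(rnorm(sum(si == 0) * d), ncol = d) %*% cg
    if (any(di == 0)) pb[di == 0, ] <- matrix(rnorm(sum(di == 0) * d), ncol = d) %*% cg
    seg <- matrix(rnorm(m * d), m, d) %*% cg2
    if (inbreeding_correction && !is.null(f)) {
      fs <- ifelse(si > 0, f[si], 0)
      fd <- ifelse(di > 0, f[di], 0)
      seg <- seg * sqrt(pmax(1 - (fs + fd) / 2, 0))
    }
    a[idx, ] <- (pa + pb) / 2 + seg
  }
  a
}

#' Drift-null envelope of line-mean breeding values
#'
#' Simulates neutral breeding values down the observed pedigree: founder
#' values are drawn from \eqn{N(0, G)} with `G` sampled from its posterior
#' (one simulation per retained draw, subsampled if needed), and each
#' offspring from a normal centered on the mean parental value with
#' segregation covariance `G/2`. Per-replicate line-by-generation means give
#' the 95% envelope of genetic trends reachable by drift alone.
#'
#' @param ped Pedigree table.
#' @param g A [fit_animal_model()] result, a `d x d x K` array of posterior
#'   `G` draws, or a single `d x d` matrix.
#' @param n_per_draw Replicates per posterior draw.
#' @param max_replicates Upper bound on total replicates (posterior draws are
#'   subsampled evenly beyond it).
#' @param seed Optional seed.
#' @param inbreeding_correction Shrink segregation variance by
#'   \eqn{1 - (F_s + F_d)/2}? Off by default: the uncorrected `G/2` form is
#'   the conventional gene-dropping null for this design.
#' @param traits Trait labels.
#' @return An object of class `qgsel_drift`: list with `envelope` (tibble
#'   `line`, `generation`, `trait`, `lo`, `median`, `hi`), `replicates`
#'   (tibble `rep`, `line`, `generation`, `trait`, `mean_bv`) and
#'   `n_replicates`.
#' @export
simulate_drift_null <- function(ped, g, n_per_draw = 1, max_replicates = 5000,
                                seed = NULL, inbreeding_correction = FALSE,
                                traits = NULL) {
  pc <- ped_compile(ped)
  if (inherits(g, "qgsel_fit")) {
    traits <- traits %||% names(g$traits)
    g <- g_draws(g)
  }
  if (is.matrix(g)) g <- array(g, dim = c(dim(g), 1))
  d <- dim(g)[1]
  traits <- traits %||% dimnames(g)[[1]] %||% paste0("t", seq_len(d))
  k <- dim(g)[3]
  n_rep <- k * n_per_draw
  draw_ids <- rep(seq_len(k), each = n_per_draw)
  if (n_rep > max_replicates) {
    draw_ids <- draw_ids[round(seq(1, n_rep, length.out = max_replicates))]
    n_rep <- max_replicates
  }

  meta <- pc$ped
  line <- col_or(meta, "line", "all")
  generation <- col_or(meta, "generation", 0L)
  cell <- paste(line, generation, sep = "\r")
  cells <- sort(unique(cell))
  cell_index <- match(cell, cells)
  counts <- as.integer(table(factor(cell, levels = cells)))
  fvec <- if (inbreeding_correction) ped_inbreeding_cpp(pc$sire0, pc$dam0)$F else NULL

  n_skipped <- 0
  res <- with_seed(seed, {
    purrr::map(draw_ids, function(di) {
      gm <- symm(g[, , di])
      if (!is_psd(gm)) {
        n_skipped <<- n_skipped + 1
        return(NULL)
      }
      a <- simulate_bv(pc, gm, inbreeding_correction, fvec)
      rowsum(a, cell_index, reorder = TRUE) / counts
    })
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (n_skipped > 0) {
    inform(sprintf("skipped %d non-positive-semidefinite G draw(s)", n_skipped))
  }
  arr <- array(unlist(res), dim = c(length(cells), d, length(res)))

  parts <- strsplit(cells, "\r", fixed = TRUE)
  cl <- vapply(parts, `[`, "", 1)
  cg <- as.integer(vapply(parts, `[`, "", 2))
  envelope <- purrr::map_dfr(seq_len(d), function(t) {
    q <- apply(arr[, t, , drop = FALSE], 1, quantile, c(0.025, 0.5, 0.975),
               names = FALSE)
    tibble::tibble(line = cl, generation = cg, trait = traits[t],
                   lo = unname(q[1, ]), median = unname(q[2, ]),
                   hi = unname(q[3, ]))
  })
  replicates <- purrr::map_dfr(seq_len(d), function(t) {
    m <- matrix(arr[, t, ], nrow = length(cells))
    tibble::tibble(
      rep = rep(seq_len(ncol(m)), each = length(cells)),
      line = rep(cl, ncol(m)), generation = rep(cg, ncol(m)),
      trait = traits[t], mean_bv = as.numeric(m)
    )
  })
  out <- list(envelope = envelope, replicates = replicates,
              n_replicates = length(res), traits = traits, seed = seed)
  class(out) <- "qgsel_drift"
  out
}

#' @export
print.qgsel_drift <- function(x, ...) {
  cat(sprintf("<qgsel_drift> %d replicates, %d traits, %d line x generation cells\n",
              x$n_replicates, length(x$traits),
              nrow(x$envelope) / length(x$traits)))
  invisible(x)
}

#' Drift effective size from replicate variance growth
#'
#' Under pure drift the across-replicate variance of the line-mean breeding
#' value grows by about \eqn{V_G / N_e} per generation. For each line, the
#' variance of the replicate means is regressed on generation (through the
#' origin, counting from the line's first generation), and
#' \eqn{N_e = V_G / slope} is averaged over traits.
#'
#' @param drift A [simulate_drift_null()] result.
#' @param v_g True or estimated additive genetic variance per trait (named
#'   vector in trait order, or a `G` matrix whose diagonal is used).
#' @return A tibble per line: `line`, `ne`, plus per-trait slopes.
#' @export
drift_ne <- function(drift, v_g) {
  stopifnot(inherits(drift, "qgsel_drift"))
  if (is.matrix(v_g)) v_g <- diag(v_g)
  if (drift$n_replicates < 100) {
    abort("need at least 100 drift replicates", class = "qgsel_input_error")
  }
  reps <- drift$replicates
  purrr::map_dfr(setdiff(unique(reps$line), "Founder"), function(l) {
    ne_t <- purrr::map_dbl(seq_along(drift$traits), function(t) {
      sub <- reps[reps$line == l & reps$trait == drift$traits[t], ]
      vg_gen <- tapply(sub$mean_bv, sub$generation, var)
      gens <- as.numeric(names(vg_gen))
      if (length(gens) < 3) {
        abort("need at least 3 generations per line", class = "qgsel_input_error")
      }
      g0 <- min(gens)
      x <- gens - g0
      y <- vg_gen - vg_gen[which.min(gens)]
      slope <- sum(x * y) / sum(x^2)
      if (slope <= 0) {
        abort(sprintf("drift variance does not grow for line '%s'", l),
              class = "qgsel_degenerate_drift")
      }
      v_g[t] / slope
    })
    tibble::tibble(line = l, ne = mean(ne_t),
                   !!!setNames(as.list(ne_t), paste0("ne_", drift$traits)))
  })
}
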