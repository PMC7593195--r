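#' Generalized least-squares slope through the origin
#'
#' Fits \eqn{R = h^2 S + \epsilon} with a known error covariance `V`:
#' \eqn{\hat h^2 = (S^T V^{-1} S)^{-1} S^T V^{-1} R}, with sampling variance
#' \eqn{(S^T V^{-1} S)^{-1}}. With `V` proportional to the identity this is
#' ordinary least squares through the origin.
#'
#' @param s,r Predictor and response series (equal length).
#' @param v Error covariance matrix of `r`.
#' @return A list with `slope` and `se`.
#' @export
gls_origin_fit <- function(s, r, v) {
  if (length(s) != length(r) || length(s) != nrow(v)) {
    abort("`s`, `r` and `v` must be conformable", class = "qgsel_input_error")
  }
  ch <- tryCatch(chol(v), error = function(e) NULL)
  if (is.null(ch)) {
    abort("error covariance `V` is not positive definite; consider larger N or Ne",
          class = "qgsel_v_not_pd")
  }
  vs <- backsolve(ch, forwardsolve(t(ch), s))
  xtvx <- sum(s * vs)
  slope <- sum(r * vs) / xtvx
  list(slope = slope, se = sqrt(1 / xtvx))
}

# drift + sampling covariance of cumulative response at generations i, j
# (1-based episode counts since the start of selection)
response_vcov <- function(h2, v_p, n, ne, g) {
  n <- rep_len(n, g)
  ij <- outer(seq_len(g), seq_len(g), pmin)
  # the drift term is a variance contribution: a (legitimately) negative h2
  # estimate enters the point estimate, but V is built with h2 floored at 0
  # so it stays a covariance matrix
  v <- max(h2, 0) * v_p * (1 / n[1] + ij / ne)
  diag(v) <- diag(v) + v_p / n
  v
}

#' Realized heritability by iterated GLS on cumulative series
#'
#' Regresses the cumulative selection response (measured relative to an
#' unselected control line) on the cumulative selection differential, through
#' the origin, with an error covariance that accounts for genetic drift and
#' sampling: \eqn{V_{ij} = h^2 V_P (1/N + \min(i,j)/N_e) + [i=j] V_P/N}.
#' Because `V` depends on \eqn{h^2}, the regression is iterated to
#' convergence. The \eqn{\min(i,j)} form is the covariance of cumulated drift
#' (the printed diagonal form \eqn{i/N_e} extended off-diagonal by symmetry).
#'
#' The estimate may legitimately be negative when the response runs against
#' the differential.
#'
#' @param cum_s Cumulative composite selection differentials (trait units),
#'   one value per generation of selection.
#' @param cum_r Cumulative control-centered responses, same length.
#' @param v_p Phenotypic variance of the trait.
#' @param n Phenotyped count per generation (scalar or vector; the drift term
#'   uses the first generation's count).
#' @param ne Assumed effective population size (default 30, the typical
#'   inbreeding-based estimate for this design).
#' @param tol Convergence tolerance on \eqn{h^2}.
#' @param max_iter Maximum number of GLS iterations.
#' @return An object of class `qgsel_h2` with elements `h2`, `se`, `v`
#'   (converged error covariance), `cum_s`, `cum_r`, `n`, `ne`, `v_p`,
#'   `iterations`, `converged`.
#' @export
realized_heritability <- function(cum_s, cum_r, v_p, n, ne = 30,
                                  tol = 1e-8, max_iter = 50) {
  g <- length(cum_s)
  if (g < 2 || length(cum_r) != g) {
    abort("need cumulative series of equal length >= 2", class = "qgsel_input_error")
  }
  check_number(v_p, "v_p", lower = 0)
  check_number(ne, "ne", lower = 1e-8)
  h2 <- sum(cum_s * cum_r) / sum(cum_s^2) # OLS start
  converged <- FALSE
  it <- 0
  fit <- NULL
  while (it < max_iter) {
    it <- it + 1
    v <- response_vcov(h2, v_p, n, ne, g)
    fit <- gls_origin_fit(cum_s, cum_r, v)
    if (abs(fit$slope - h2) < tol) {
      h2 <- fit$slope
      converged <- TRUE
      break
    }
    h2 <- fit$slope
  }
  if (!converged) {
    warn(sprintf("realized heritability GLS did not converge in %d iterations; returning last iterate", max_iter))
  }
  out <- list(h2 = h2, se = fit$se, v = response_vcov(h2, v_p, n, ne, g),
              cum_s = cum_s, cum_r = cum_r, n = n, ne = ne, v_p = v_p,
              iterations = it, converged = converged)
  class(out) <- "qgsel_h2"
  out
}

#' @export
print.qgsel_h2 <- function(x, ...) {
  cat(sprintf("<qgsel_h2> realized h2 = %.4f (se %.4f), %d generations, %d GLS iterations%s\n",
              x$h2, x$se, length(x$cum_s), x$iterations,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' @rdname realized_heritability
#' @param x A `qgsel_h2` object.
#' @param ... Unused.
#' @export
tidy.qgsel_h2 <- function(x, ...) {
  tibble::tibble(term = "h2_realized", estimate = x$h2, std.error = x$se)
}

#' @rdname realized_heritability
#' @export
glance.qgsel_h2 <- function(x, ...) {
  tibble::tibble(n_generations = length(x$cum_s), ne = x$ne, v_p = x$v_p,
                 iterations = x$iterations, converged = x$converged)
}

#' Cumulative differential and control-centered response series
#'
#' Builds, for one selected line, the per-generation cumulative composite
#' selection differential and the cumulative response relative to the control
#' line: \eqn{R_g = (\bar z_{line,g} - \bar z_{ctrl,g}) - (\bar z_{line,g_0} -
#' \bar z_{ctrl,g_0})}, where \eqn{g_0} is the first generation in which the
#' line exists. The differential applied between generations `g-1` and `g` is
#' accumulated into the value reported at `g`.
#'
#' @param pheno,ped Phenotype and pedigree tables.
#' @param line Focal selected line.
#' @param control Name of the control line.
#' @param trait Trait column (continuous trait).
#' @param summary Optional precomputed [selection_summary()].
#' @return A tibble per post-selection generation: `generation`, `cum_s`,
#'   `cum_r`, `n` (phenotyped count of the focal line), plus the pooled
#'   phenotypic variance `v_p` as an attribute.
#' @export
cumulative_selection_series <- function(pheno, ped, line, control = "Control",
                                        trait = "sdl_mm", summary = NULL) {
  data <- phenotypes_with_pedigree(pheno, ped)
  if (is.null(summary)) summary <- selection_summary(pheno, ped)
  tr_label <- names(which(c(sdl = "sdl_mm", mat = "mature") == trait))
  if (length(tr_label) == 0) tr_label <- trait
  sums <- summary[summary$line == line & summary$trait == tr_label, , drop = FALSE]
  sums <- sums[order(sums$generation), ]
  if (nrow(sums) == 0) {
    abort(sprintf("no selection episodes found for line '%s'", line),
          class = "qgsel_input_error")
  }
  gens <- sort(unique(sums$generation))
  g0 <- min(gens)
  target <- c(gens[-1], max(gens) + 1) # generations at which response is read

  line_mean <- function(l, g) {
    x <- data[[trait]][data$line == l & data$generation == g]
    mean(x, na.rm = TRUE)
  }
  base <- line_mean(line, g0) - line_mean(control, g0)
  cum_s <- cumsum(sums$s)
  cum_r <- purrr::map_dbl(target, function(g) {
    (line_mean(line, g) - line_mean(control, g)) - base
  })
  nvec <- purrr::map_int(target, function(g) {
    sum(data$line == line & data$generation == g & !is.na(data[[trait]]))
  })
  out <- tibble::tibble(generation = target, cum_s = cum_s, cum_r = cum_r, n = nvec)
  attr(out, "v_p") <- mean(sums$v_p)
  out
}

#' Realized heritability of a selected line relative to a control
#'
#' Convenience wrapper chaining [selection_summary()],
#' [cumulative_selection_series()] and [realized_heritability()].
#'
#' @inheritParams cumulative_selection_series
#' @inheritParams realized_heritability
#' @return A `qgsel_h2` object (see [realized_heritability()]).
#' @export
realized_heritability_line <- function(pheno, ped, line, control = "Control",
                                       trait = "sdl_mm", ne = 30,
                                       tol = 1e-8, max_iter = 50,
                                       summary = NULL) {
  ser <- cumulative_selection_series(pheno, ped, line, control, trait, summary)
  realized_heritability(ser$cum_s, ser$cum_r, attr(ser, "v_p"),
                        n = ser$n, ne = ne, tol = tol, max_iter = max_iter)
}
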