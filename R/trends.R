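# line x generation cell means of a pedigree-indexed matrix of draws
cell_means_by_draw <- function(bv, cells, cell_index) {
  # bv: n_ped x K matrix; returns cells x K
  agg <- rowsum(bv, cell_index, reorder = TRUE)
  counts <- as.integer(table(cell_index))
  agg / counts
}

#' Posterior genetic trends per line and generation
#'
#' For every stored posterior draw, averages the breeding values over the
#' individuals of each line-by-generation cell, then summarizes the draws by
#' their median and 95% support interval. Averaging per draw (rather than
#' averaging posterior-mean breeding values) keeps the uncertainty of the
#' genetic trend honest.
#'
#' @param fit A [fit_animal_model()] result with stored breeding values.
#' @return A tibble of class `qgsel_trend`: `line`, `generation`, `trait`,
#'   `n_ind`, `lo`, `median`, `hi`. The full per-draw cell means are attached
#'   as attribute `"draws"` (list per trait of cells x draws matrices).
#' @export
genetic_trends <- function(fit) {
  stopifnot(inherits(fit, "qgsel_fit"))
  if (is.null(fit$chains[[1]]$BV)) {
    abort("fit does not store breeding values (set store_bv = TRUE)",
          class = "qgsel_input_error")
  }
  meta <- fit$ped_meta
  cell <- paste(meta$line, meta$generation, sep = "\r")
  cells <- sort(unique(cell))
  cell_index <- match(cell, cells)
  k <- fit$chains[[1]]$n_stored
  d <- length(fit$traits)
  tn <- names(fit$traits) %||% paste0("t", seq_len(d))

  draws_by_trait <- lapply(seq_len(d), function(t) {
    mats <- lapply(fit$chains, function(ch) {
      bv <- matrix(ch$BV[, t, seq_len(k)], nrow = length(fit$ped_ids))
      cell_means_by_draw(bv, cells, cell_index)
    })
    do.call(cbind, mats)
  })
  names(draws_by_trait) <- tn

  counts <- as.integer(table(factor(cell, levels = cells)))
  parts <- strsplit(cells, "\r", fixed = TRUE)
  out <- purrr::map_dfr(seq_len(d), function(t) {
    q <- apply(draws_by_trait[[t]], 1, quantile, c(0.025, 0.5, 0.975),
               names = FALSE)
    tibble::tibble(
      line = vapply(parts, `[`, "", 1),
      generation = as.integer(vapply(parts, `[`, "", 2)),
      trait = tn[t], n_ind = counts,
      lo = unname(q[1, ]), median = unname(q[2, ]), hi = unname(q[3, ])
    )
  })
  out <- dplyr::arrange(out, .data$trait, .data$line, .data$generation)
  class(out) <- c("qgsel_trend", class(out))
  attr(out, "draws") <- draws_by_trait
  attr(out, "cells") <- tibble::tibble(
    line = vapply(parts, `[`, "", 1),
    generation = as.integer(vapply(parts, `[`, "", 2))
  )
  out
}

#' Heritable maternal effect from aquarium effects
#'
#' Full sibs share both their parents and their rearing aquarium, so the
#' aquarium random effect can absorb heritable maternal contributions. The
#' maternal-effect coefficient `m` is estimated per posterior draw as the
#' least-squares slope of the aquarium effect on the dam's breeding value
#' across aquaria, and the slope draws are summarized as a posterior.
#'
#' @param fit A [fit_animal_model()] result with stored breeding values and
#'   aquarium effects.
#' @return An object of class `qgsel_maternal`: list with `draws` (tibble
#'   `chain`, `draw`, `trait`, `m`) and `summary` (tibble `trait`, `lo`,
#'   `median`, `hi`).
#' @export
maternal_effect <- function(fit) {
  stopifnot(inherits(fit, "qgsel_fit"))
  if (is.null(fit$chains[[1]]$BV) || is.null(fit$chains[[1]]$U)) {
    abort("fit must store breeding values and aquarium effects",
          class = "qgsel_input_error")
  }
  meta <- fit$ped_meta
  # one dam per aquarium; aquaria with no identified dam are dropped
  dam_of_aq <- tapply(meta$dam, meta$aquarium, function(d) {
    u <- unique(stats::na.omit(d))
    if (length(u) == 1) u else NA_character_
  })
  dam_of_aq <- dam_of_aq[fit$aq_levels]
  usable <- which(!is.na(dam_of_aq))
  if (length(usable) < 3) {
    abort("fewer than 3 aquaria with an identified dam",
          class = "qgsel_insufficient_data")
  }
  dam_idx <- match(dam_of_aq[usable], fit$ped_ids)
  k <- fit$chains[[1]]$n_stored
  d <- length(fit$traits)
  tn <- names(fit$traits) %||% paste0("t", seq_len(d))

  draws <- purrr::map_dfr(seq_along(fit$chains), function(ci) {
    ch <- fit$chains[[ci]]
    purrr::map_dfr(seq_len(d), function(t) {
      u <- matrix(ch$U[, t, seq_len(k)], nrow = length(fit$aq_levels))[usable, , drop = FALSE]
      a <- matrix(ch$BV[, t, seq_len(k)], nrow = length(fit$ped_ids))[dam_idx, , drop = FALSE]
      # per-draw OLS slope with intercept
      am <- colMeans(a); um <- colMeans(u)
      sxy <- colSums((a - rep(am, each = nrow(a))) * (u - rep(um, each = nrow(u))))
      sxx <- colSums((a - rep(am, each = nrow(a)))^2)
      tibble::tibble(chain = ci, draw = seq_len(k), trait = tn[t],
                     m = sxy / sxx)
    })
  })
  summ <- dplyr::summarise(
    dplyr::group_by(draws, .data$trait),
    lo = quantile(.data$m, 0.025), median = median(.data$m),
    hi = quantile(.data$m, 0.975), .groups = "drop"
  )
  out <- list(draws = draws, summary = summ)
  class(out) <- "qgsel_maternal"
  out
}

#' @export
print.qgsel_maternal <- function(x, ...) {
  cat("<qgsel_maternal> posterior of the maternal-effect slope m:\n")
  print(x$summary)
  invisible(x)
}

#' @rdname maternal_effect
#' @param x A `qgsel_maternal` object.
#' @param ... Unused.
#' @export
tidy.qgsel_maternal <- function(x, ...) x$summary
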