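#' Run configuration for the end-to-end analyses
#'
#' Bundles the inputs (either file paths or a synthetic preset), model and
#' prediction settings, output directory and root seed for
#' [run_full_analysis()] and [run_prediction()]. Exactly one of
#' `pedigree_path`/`phenotype_path` or `synthetic` must be given. All
#' randomness flows from the root seed through named per-stage sub-seeds, so
#' stages are independently reproducible.
#'
#' @param pedigree_path,phenotype_path CSV inputs (see [qgsel-io]).
#' @param synthetic An [experiment_config()] to simulate instead of reading
#'   files.
#' @param outdir Output directory (created if needed); `NULL` disables file
#'   output.
#' @param seed Root seed.
#' @param iterations,burnin,thin,n_chains Chain settings passed to
#'   [model_spec()].
#' @param prediction_ne,prediction_generations Drift effective size and
#'   horizon for [predict_response()].
#' @param drift_max_replicates Cap on drift-null replicates.
#' @param control_line Control-line name.
#' @param verbose Emit progress messages?
#' @return A list of class `qgsel_run_config`.
#' @export
run_config <- function(pedigree_path = NULL, phenotype_path = NULL,
                       synthetic = NULL, outdir = NULL, seed = 1,
                       iterations = 20000, burnin = 2000, thin = 20,
                       n_chains = 2, prediction_ne = 25,
                       prediction_generations = 6,
                       drift_max_replicates = 2000,
                       control_line = "Control", verbose = TRUE) {
  files <- !is.null(pedigree_path) || !is.null(phenotype_path)
  if (files == !is.null(synthetic)) {
    abort("give either input paths or a synthetic preset (exactly one)",
          class = "qgsel_input_error")
  }
  if (files && (is.null(pedigree_path) || is.null(phenotype_path))) {
    abort("both `pedigree_path` and `phenotype_path` are required",
          class = "qgsel_input_error")
  }
  out <- list(pedigree_path = pedigree_path, phenotype_path = phenotype_path,
              synthetic = synthetic, outdir = outdir, seed = seed,
              iterations = iterations, burnin = burnin, thin = thin,
              n_chains = n_chains, prediction_ne = prediction_ne,
              prediction_generations = prediction_generations,
              drift_max_replicates = drift_max_replicates,
              control_line = control_line, verbose = verbose)
  class(out) <- "qgsel_run_config"
  out
}

load_inputs <- function(cfg) {
  if (!is.null(cfg$synthetic)) {
    exp <- simulate_experiment(cfg$synthetic,
                               seed = substream_seed(cfg$seed, "simulate"))
    list(ped = exp$pedigree, pheno = exp$phenotypes, experiment = exp)
  } else {
    for (p in c(cfg$pedigree_path, cfg$phenotype_path)) {
      if (!file.exists(p)) {
        abort(paste0("input file not found: ", p), class = "qgsel_input_error")
      }
    }
    list(ped = read_pedigree(cfg$pedigree_path),
         pheno = read_phenotypes(cfg$phenotype_path), experiment = NULL)
  }
}

say <- function(cfg, ...) if (isTRUE(cfg$verbose)) inform(paste0(...))

write_output <- function(cfg, name, obj) {
  if (is.null(cfg$outdir)) return(NULL)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(cfg$outdir, name)
  if (is.data.frame(obj)) {
    write.csv(as.data.frame(obj), path, row.names = FALSE)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
  }
  path
}

finish_manifest <- function(cfg, paths, stage) {
  if (is.null(cfg$outdir)) return(invisible(NULL))
  paths <- paths[!vapply(paths, is.null, logical(1))]
  manifest <- list(
    stage = stage, seed = cfg$seed,
    config = cfg[setdiff(names(cfg), c("synthetic", "verbose"))],
    outputs = lapply(paths, function(p) {
      list(file = basename(p), md5 = unname(tools::md5sum(p)))
    })
  )
  write_output(cfg, paste0(stage, "_manifest.json"), manifest)
}

#' Validate pedigree and phenotype inputs
#'
#' Report-only pre-flight checks: duplicated ids, unknown or cyclic parents,
#' phenotype rows that do not join to the pedigree, phenotype-invariant
#' violations, and counts per line and generation.
#'
#' @param ped,pheno Tables (or paths to their CSV files).
#' @return A list with `issues` (tibble `check`, `detail`) and `counts`
#'   (tibble per line and generation).
#' @export
validate_inputs <- function(ped, pheno) {
  if (is.character(ped)) ped <- read_pedigree(ped)
  if (is.character(pheno)) pheno <- read_phenotypes(pheno)
  issues <- list()
  note <- function(check, detail) {
    issues[[length(issues) + 1]] <<- tibble::tibble(check = check,
                                                    detail = detail)
  }
  ped <- tryCatch(ped_normalize(ped), error = function(e) {
    note("pedigree", conditionMessage(e)); NULL
  })
  if (!is.null(ped)) {
    tryCatch(ped_compile(ped), error = function(e) {
      note("pedigree_structure", conditionMessage(e))
    })
    if (!is.null(ped$generation)) {
      founders_bad <- ped$id[ped$generation == 0 &
                               (!is.na(ped$sire) | !is.na(ped$dam))]
      if (length(founders_bad) > 0) {
        note("founders", paste0("generation-0 individuals with parents: ",
                                paste(head(founders_bad, 5), collapse = ", ")))
      }
    }
  }
  pheno <- tibble::as_tibble(pheno)
  if (anyDuplicated(pheno$id) > 0) note("phenotypes", "duplicated ids")
  if (!is.null(ped)) {
    unknown <- setdiff(pheno$id, ped$id)
    if (length(unknown) > 0) {
      note("join", paste0("phenotyped ids missing from pedigree: ",
                          paste(head(unknown, 5), collapse = ", ")))
    }
  }
  if (any(pheno$sdl_mm <= 0, na.rm = TRUE)) note("phenotypes", "non-positive sdl_mm")
  if (any(pheno$n_offspring > 0 & !pheno$is_breeder, na.rm = TRUE)) {
    note("phenotypes", "n_offspring > 0 for non-breeders")
  }
  counts <- NULL
  if (!is.null(ped) && length(issues) == 0) {
    joined <- phenotypes_with_pedigree(pheno, ped)
    counts <- dplyr::count(joined, .data$line, .data$generation)
  }
  list(issues = if (length(issues) > 0) dplyr::bind_rows(issues)
                else tibble::tibble(check = character(), detail = character()),
       counts = counts)
}

#' End-to-end descriptive analysis
#'
#' Runs the full-scope analysis: input validation, selection differentials
#' and gradients, realized heritability per selected line, the full-scope
#' animal model, posterior summaries and diagnostics, genetic trends, the
#' drift-null envelope and the drift-based effective size. Results are
#' returned as a bundle and, when `outdir` is set, written as tidy CSV/JSON
#' with an md5 manifest.
#'
#' @param cfg A [run_config()].
#' @return A list of class `qgsel_run` with elements `validation`,
#'   `selection`, `realized_h2`, `fit`, `posterior`, `diagnostics`, `trends`,
#'   `maternal`, `drift`, `drift_ne`, `inputs`.
#' @export
run_full_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "qgsel_run_config"))
  inputs <- load_inputs(cfg)
  say(cfg, "validating inputs")
  validation <- validate_inputs(inputs$ped, inputs$pheno)
  if (nrow(validation$issues) > 0) {
    abort(paste0("input validation failed: ",
                 paste(validation$issues$detail, collapse = "; ")),
          class = "qgsel_stage_error")
  }
  say(cfg, "selection differentials and gradients")
  selection <- selection_summary(inputs$pheno, inputs$ped)
  lines <- setdiff(unique(selection$line), c(cfg$control_line, "Founder"))
  realized <- purrr::map(setNames(lines, lines), function(l) {
    tryCatch(
      realized_heritability_line(inputs$pheno, inputs$ped, l,
                                 control = cfg$control_line,
                                 summary = selection),
      error = function(e) NULL)
  })

  say(cfg, "fitting the full animal model")
  spec <- model_spec("full", iterations = cfg$iterations, burnin = cfg$burnin,
                     thin = cfg$thin, n_chains = cfg$n_chains,
                     seed = substream_seed(cfg$seed, "fit_full"),
                     control_line = cfg$control_line)
  fit <- fit_animal_model(inputs$ped, inputs$pheno, spec)
  posterior <- posterior_summary(fit)
  diagnostics <- convergence_diagnostics(fit)
  say(cfg, "genetic trends, maternal effects and drift null")
  trends <- genetic_trends(fit)
  maternal <- maternal_effect(fit)
  drift <- simulate_drift_null(inputs$ped, fit,
                               max_replicates = cfg$drift_max_replicates,
                               seed = substream_seed(cfg$seed, "drift"))
  g_med <- apply(g_draws(fit), 1:2, median)
  dne <- tryCatch(drift_ne(drift, g_med), error = function(e) NULL)

  paths <- list(
    write_output(cfg, "selection_summary.csv", selection),
    write_output(cfg, "posterior_summary.csv", posterior),
    write_output(cfg, "diagnostics.csv", diagnostics),
    write_output(cfg, "genetic_trends.csv",
                 tibble::as_tibble(unclass_tbl(trends))),
    write_output(cfg, "drift_envelope.csv", drift$envelope),
    write_output(cfg, "maternal_effect.csv", maternal$summary),
    write_output(cfg, "realized_h2.json",
                 lapply(realized, function(x) {
                   if (is.null(x)) NULL
                   else list(h2 = x$h2, se = x$se, ne = x$ne,
                             converged = x$converged)
                 }))
  )
  if (!is.null(dne)) paths <- c(paths, list(write_output(cfg, "drift_ne.csv", dne)))
  finish_manifest(cfg, paths, "full")

  out <- list(validation = validation, selection = selection,
              realized_h2 = realized, fit = fit, posterior = posterior,
              diagnostics = diagnostics, trends = trends, maternal = maternal,
              drift = drift, drift_ne = dne, inputs = inputs)
  class(out) <- "qgsel_run"
  out
}

unclass_tbl <- function(x) {
  class(x) <- setdiff(class(x), c("qgsel_trend", "qgsel_selection",
                                  "qgsel_prediction"))
  attr(x, "draws") <- NULL
  attr(x, "cells") <- NULL
  attr(x, "trajectories") <- NULL
  x
}

#' Predictive analysis: forecast versus observed response
#'
#' Fits the predictive-scope animal model (pre-split generations plus the
#' control line, no inbreeding covariate), converts the mean realized
#' data-scale gradients of each selected line to the latent scale, predicts
#' the selection response recursively with drift, and tabulates the forecast
#' against the observed phenotypic means.
#'
#' @param cfg A [run_config()].
#' @param beta_data Optional named list of data-scale gradients per line
#'   (each `c(sdl = ..., mat = ...)`); computed from the realized selection
#'   summary when omitted.
#' @return A list of class `qgsel_run_prediction` with elements `fit`,
#'   `gradients`, `predictions` (per line), `observed`, `inputs`.
#' @export
run_prediction <- function(cfg, beta_data = NULL) {
  stopifnot(inherits(cfg, "qgsel_run_config"))
  inputs <- load_inputs(cfg)
  say(cfg, "fitting the predictive animal model")
  spec <- model_spec("predictive", iterations = cfg$iterations,
                     burnin = cfg$burnin, thin = cfg$thin,
                     n_chains = cfg$n_chains,
                     seed = substream_seed(cfg$seed, "fit_predictive"),
                     control_line = cfg$control_line,
                     store_bv = FALSE, store_ranef = FALSE)
  fit <- fit_animal_model(inputs$ped, inputs$pheno, spec)

  if (is.null(beta_data)) {
    selection <- selection_summary(inputs$pheno, inputs$ped)
    mg <- mean_gradients(selection)
    lines <- setdiff(unique(mg$line), c(cfg$control_line, "Founder"))
    beta_data <- purrr::map(setNames(lines, lines), function(l) {
      b <- mg[mg$line == l, ]
      bv <- setNames(b$beta_mean[match(c("sdl", "mat"), b$trait)],
                     c("sdl", "mat"))
      if (any(!is.finite(bv))) {
        warn(sprintf("non-finite mean gradient for line '%s' set to 0", l))
        bv[!is.finite(bv)] <- 0
      }
      bv
    })
  }

  start <- prediction_start(fit)
  say(cfg, "predicting selection response")
  predictions <- purrr::imap(beta_data, function(b, l) {
    predict_response(fit, b, start,
                     n_generations = cfg$prediction_generations,
                     ne = cfg$prediction_ne,
                     seed = substream_seed(cfg$seed, paste0("predict_", l)))
  })

  joined <- phenotypes_with_pedigree(inputs$pheno, inputs$ped)
  observed <- dplyr::summarise(
    dplyr::group_by(joined, .data$line, .data$generation),
    sdl = mean(.data$sdl_mm, na.rm = TRUE),
    mat = mean(.data$mature, na.rm = TRUE), .groups = "drop"
  )

  paths <- purrr::imap(predictions, function(p, l) {
    write_output(cfg, paste0("prediction_", l, ".csv"),
                 tibble::as_tibble(unclass_tbl(p)))
  })
  paths <- c(paths, list(write_output(cfg, "observed_means.csv", observed)))
  finish_manifest(cfg, paths, "prediction")

  out <- list(fit = fit, gradients = beta_data, predictions = predictions,
              observed = observed, inputs = inputs)
  class(out) <- "qgsel_run_prediction"
  out
}
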