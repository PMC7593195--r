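#' Read and write the package's delimited formats
#'
#' Pedigrees are stored as CSV with header
#' `id,sire,dam,sex,line,generation,aquarium` (missing parents as empty
#' fields or `NA`); phenotypes as CSV with header
#' `id,sdl_mm,mature,is_breeder,n_offspring,family_preselected`. Identifiers
#' are opaque strings.
#'
#' @param path File path.
#' @return A tibble.
#' @name qgsel-io
NULL

#' @rdname qgsel-io
#' @export
read_pedigree <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(id = "character", sire = "character",
                                dam = "character"))
  ped_normalize(df)
}

#' @rdname qgsel-io
#' @export
read_phenotypes <- function(path) {
  df <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE,
                                   colClasses = c(id = "character")))
  for (col in c("is_breeder", "family_preselected")) {
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  }
  df
}

#' @rdname qgsel-io
#' @param x Table to write.
#' @export
write_pedigree <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname qgsel-io
#' @export
write_phenotypes <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a relationship matrix as dense CSV or coordinate triplets
#'
#' @param rel A [build_relationship_matrix()] result (or a plain matrix).
#' @param path Output path.
#' @param format `"dense"` (square CSV with id row/column labels) or
#'   `"triplets"` (`id_row,id_col,value`, upper triangle incl. diagonal).
#' @export
write_relationship <- function(rel, path, format = c("dense", "triplets")) {
  format <- match.arg(format)
  a <- if (inherits(rel, "qgsel_relatedness")) rel$a_matrix else as.matrix(rel)
  if (format == "dense") {
    write.csv(as.data.frame(a), path, row.names = TRUE)
  } else {
    ut <- which(upper.tri(a, diag = TRUE), arr.ind = TRUE)
    df <- data.frame(id_row = rownames(a)[ut[, 1]],
                     id_col = colnames(a)[ut[, 2]],
                     value = a[ut])
    df <- df[df$value != 0, ]
    write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Join phenotypes with pedigree annotations
#'
#' Adds `sex`, `line`, `generation` and `aquarium` (the full-sib family
#' identifier) from the pedigree to a phenotype table. Every phenotyped id
#' must exist in the pedigree.
#'
#' @param pheno Phenotype table (see [qgsel-io]).
#' @param ped Pedigree table (see [pedigree-format]).
#' @return The joined tibble.
#' @export
phenotypes_with_pedigree <- function(pheno, ped) {
  ped <- ped_normalize(ped)
  pheno <- tibble::as_tibble(pheno)
  unknown <- setdiff(pheno$id, ped$id)
  if (length(unknown) > 0) {
    abort(paste0("phenotyped id(s) absent from the pedigree: ",
                 paste(head(unknown, 5), collapse = ", ")),
          class = "qgsel_structure_error")
  }
  keep <- intersect(c("id", "sex", "line", "generation", "aquarium"), names(ped))
  dplyr::left_join(pheno, ped[keep], by = "id")
}
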