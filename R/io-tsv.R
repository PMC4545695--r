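## Plain-text TSV model format: a long-format stoichiometry file of
## (metabolite, reaction, coefficient) triples and a bounds file of
## (reaction, lb, ub, objective). External species are flagged either by
## an `external` column (TRUE/FALSE) in the stoichiometry file or by the
## ID convention of a `_ext` suffix; the column, when present, wins.

#' Read a metabolic model from TSV files
#'
#' @param stoich_path TSV with columns `metabolite`, `reaction`,
#'   `coefficient` and optionally `external` (logical).
#' @param bounds_path TSV with columns `reaction`, `lb`, `ub` and
#'   optionally `objective`. `Inf`/`-Inf` are accepted.
#' @return a `metabolic_model`.
#' @export
read_tsv_model <- function(stoich_path, bounds_path) {
  for (p in c(stoich_path, bounds_path)) {
    if (!file.exists(p)) stop("no such file: ", p)
  }
  stoich <- utils::read.delim(stoich_path, stringsAsFactors = FALSE)
  bounds <- utils::read.delim(bounds_path, stringsAsFactors = FALSE)
  if (nrow(stoich) == 0L) {
    stop("empty stoichiometry file: ", stoich_path)
  }
  if (!is.numeric(stoich$coefficient)) {
    stop("column 'coefficient' of ", stoich_path, " is not numeric")
  }
  for (cn in c("lb", "ub")) {
    if (!is.numeric(bounds[[cn]])) {
      bounds[[cn]] <- suppressWarnings(as.numeric(bounds[[cn]]))
      if (anyNA(bounds[[cn]])) stop("column '", cn, "' of ", bounds_path,
                                    " contains non-numeric values")
    }
  }
  externals <- character()
  if ("external" %in% names(stoich)) {
    externals <- unique(stoich$metabolite[as.logical(stoich$external)])
    stoich$external <- NULL
  }
  metabolic_model(stoich, bounds, externals = externals)
}

#' Write a metabolic model to TSV files
#'
#' Inverse of [read_tsv_model()]: the stoichiometry file carries an
#' explicit `external` column so the round trip does not rely on the ID
#' convention.
#'
#' @param model a `metabolic_model`.
#' @param stoich_path,bounds_path output files.
#' @return `stoich_path`, invisibly.
#' @export
write_tsv_model <- function(model, stoich_path, bounds_path) {
  stoich <- tidy(model)
  utils::write.table(stoich, stoich_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  bounds <- tibble::tibble(reaction = model$rxn_ids,
                           lb = unname(model$lb), ub = unname(model$ub),
                           objective = unname(model$obj))
  utils::write.table(bounds, bounds_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(stoich_path)
}
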