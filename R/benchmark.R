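#' Reduce an externally supplied genome-scale model and report statistics
#'
#' Benchmark harness for user-downloaded genome-scale models (e.g. an
#' E. coli or cyanobacterial reconstruction in SBML): runs the full
#' prune + compress pipeline under a YAML protection specification and
#' emits a summary table of network statistics per stage (reaction and
#' metabolite counts, degrees of freedom, conservation relations,
#' enzyme-subset counts, and the per-scenario FBA optimum of the model
#' objective), plus the condensed biomass-reaction report when a biomass
#' reaction is named. Genome-scale inputs are deliberately not shipped
#' with the package and are never downloaded; reduction outcomes on such
#' models are order-dependent, so sizes are indicative while optima must
#' be preserved to the protected fraction.
#'
#' @param model_path SBML model file supplied by the user.
#' @param spec_path YAML protection specification.
#' @param biomass_reaction optional biomass reaction ID for the report.
#' @param seed tie-breaking seed passed to [prune()].
#' @param compress_model also run loss-free compression (default TRUE).
#' @return a list with `report` (tibble: `statistic`, one column per
#'   stage), `bsr` (condensed-biomass tibble or `NULL`), `prune_result`,
#'   `compressed`.
#' @export
run_benchmark <- function(model_path, spec_path, biomass_reaction = NULL,
                          seed = 0L, compress_model = TRUE) {
  if (!file.exists(model_path)) {
    stop("benchmark model not found: '", model_path, "'.\n",
         "Genome-scale models are not shipped with this package and are ",
         "never downloaded automatically. Obtain the SBML file from its ",
         "published source (e.g. the supplementary material or model ",
         "repository of the original reconstruction) and pass its local path.")
  }
  if (!file.exists(spec_path)) {
    stop("protection specification not found: '", spec_path, "'")
  }
  model <- read_sbml(model_path)
  spec <- read_protection_spec(spec_path, model)
  pr <- prune(model, spec, seed = seed)
  cmp <- if (compress_model) compress(pr$model, spec) else NULL
  stages <- list(full = model, pruned = pr$model)
  if (!is.null(cmp)) stages$compressed <- cmp$model

  stat_rows <- c("# reactions", "# int. metabolites", "# ext. metabolites",
                 "degrees of freedom", "# conservation relations",
                 "# enzyme subsets (# containing reactions)")
  report <- tibble::tibble(statistic = stat_rows)
  for (nm in names(stages)) {
    m <- stages[[nm]]
    sub <- detect_subsets(m, spec)
    multi <- table(sub$lumped_id)
    vals <- c(length(m$rxn_ids), length(m$met_ids), length(m$ext_ids),
              dof(m), conservation_relations(m)$count, NA)
    col <- as.character(vals)
    col[6] <- sprintf("%d (%d)", sum(multi > 1), sum(multi[multi > 1]))
    report[[nm]] <- col
  }
  for (sc in spec$scenarios) {
    lbl <- sprintf("mu_max (%s)", sc$name)
    row <- stats::setNames(as.list(c(lbl, rep(NA_character_, length(stages)))),
                           c("statistic", names(stages)))
    for (nm in names(stages)) {
      m <- stages[[nm]]  # pruning/compression carry the objective through
      sc_m <- if (nm == "compressed") translate_scenario(sc, cmp) else sc
      res <- if (all(m$obj == 0)) NULL else fba(m, scenario = sc_m)
      row[[nm]] <- if (!is.null(res) && res$status == "optimal") {
        sprintf("%.4f", res$objval)
      } else NA_character_
    }
    report <- dplyr::bind_rows(report, tibble::as_tibble(row))
  }
  bsr <- NULL
  if (!is.null(biomass_reaction)) {
    bsr <- condensed_bsr_report(if (!is.null(cmp)) cmp else pr$model,
                                biomass_reaction)
  }
  list(report = report, bsr = bsr, prune_result = pr, compressed = cmp)
}
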