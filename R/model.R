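#' Construct a stoichiometric metabolic model
#'
#' The central container of the package: an `m x n` stoichiometric matrix
#' over *internal* (balanced) metabolites, per-reaction flux bounds
#' \eqn{\alpha_i \le r_i \le \beta_i}, and a linear objective
#' \eqn{z = c^T r}. External (boundary) species are not rows of the
#' balanced matrix but are carried alongside so that exchange
#' stoichiometry survives reduction and shows up in condensed reports.
#'
#' The data-frame constructor takes long-format stoichiometry, one row
#' per nonzero coefficient, and a bounds table, and is pipe-friendly:
#' `stoich |> metabolic_model(bounds)`.
#'
#' @param stoich data frame with columns `metabolite`, `reaction`,
#'   `coefficient` (negative = consumed, positive = produced).
#' @param bounds data frame with columns `reaction`, `lb`, `ub` and
#'   optionally `objective` (default 0). Every reaction in `stoich` must
#'   appear exactly once.
#' @param externals character vector of metabolite IDs to treat as
#'   external/boundary species. Additionally, any metabolite ID ending in
#'   `"_ext"` is treated as external (the TSV format's ID convention).
#' @param compartments optional named character vector, metabolite ->
#'   compartment tag.
#'
#' @return An object of class `metabolic_model` with fields `S` (internal
#'   stoichiometric matrix, dimnames set), `S_ext` (external-species
#'   rows), `lb`, `ub`, `obj` (named numeric), `met_ids`, `rxn_ids`,
#'   `ext_ids`, `compartments`.
#' @examples
#' stoich <- tibble::tribble(
#'   ~metabolite, ~reaction, ~coefficient,
#'   "A", "R_up",  1,
#'   "A", "R_conv", -1,
#'   "B", "R_conv", 1,
#'   "B", "R_out", -1)
#' bounds <- tibble::tribble(
#'   ~reaction, ~lb, ~ub, ~objective,
#'   "R_up", 0, 10, 0,
#'   "R_conv", 0, Inf, 0,
#'   "R_out", 0, Inf, 1)
#' m <- metabolic_model(stoich, bounds)
#' m
#' @export
metabolic_model <- function(stoich, bounds, externals = character(),
                            compartments = NULL) {
  stoich <- as.data.frame(stoich)
  bounds <- as.data.frame(bounds)
  need <- c("metabolite", "reaction", "coefficient")
  if (!all(need %in% names(stoich))) {
    stop("`stoich` must have columns metabolite, reaction, coefficient")
  }
  if (nrow(stoich) == 0L) {
    stop("empty stoichiometry: a model must contain at least one coefficient")
  }
  if (!is.numeric(stoich$coefficient)) {
    stop("stoichiometric coefficients must be numeric")
  }
  if (anyDuplicated(stoich[c("metabolite", "reaction")])) {
    dup <- stoich[duplicated(stoich[c("metabolite", "reaction")]), , drop = FALSE]
    stop("duplicate stoichiometric entry for (",
         dup$metabolite[1], ", ", dup$reaction[1], ")")
  }
  if (!all(c("reaction", "lb", "ub") %in% names(bounds))) {
    stop("`bounds` must have columns reaction, lb, ub (and optionally objective)")
  }
  if (is.null(bounds$objective)) bounds$objective <- 0
  unknown <- setdiff(bounds$reaction, stoich$reaction)
  if (length(unknown)) {
    stop("bounds given for unknown reaction(s): ", paste(unknown, collapse = ", "))
  }
  if (anyDuplicated(bounds$reaction)) {
    stop("duplicate bounds row for reaction ",
         bounds$reaction[duplicated(bounds$reaction)][1])
  }
  rxn_ids <- unique(stoich$reaction)
  missing_b <- setdiff(rxn_ids, bounds$reaction)
  if (length(missing_b)) {
    stop("no bounds for reaction(s): ", paste(missing_b, collapse = ", "))
  }
  mets <- unique(stoich$metabolite)
  is_ext <- mets %in% externals | endsWith(mets, "_ext")
  met_ids <- mets[!is_ext]
  ext_ids <- mets[is_ext]

  n <- length(rxn_ids)
  S <- matrix(0, length(met_ids), n, dimnames = list(met_ids, rxn_ids))
  S_ext <- matrix(0, length(ext_ids), n, dimnames = list(ext_ids, rxn_ids))
  int_rows <- stoich$metabolite %in% met_ids
  S[cbind(stoich$metabolite[int_rows], stoich$reaction[int_rows])] <-
    stoich$coefficient[int_rows]
  if (any(!int_rows)) {
    S_ext[cbind(stoich$metabolite[!int_rows], stoich$reaction[!int_rows])] <-
      stoich$coefficient[!int_rows]
  }
  idx <- match(rxn_ids, bounds$reaction)
  new_metabolic_model(S, S_ext,
                      lb = as.numeric(bounds$lb[idx]),
                      ub = as.numeric(bounds$ub[idx]),
                      obj = as.numeric(bounds$objective[idx]),
                      compartments = compartments)
}

## low-level constructor from matrices (dimnames required)
new_metabolic_model <- function(S, S_ext = NULL, lb, ub, obj = NULL,
                                compartments = NULL) {
  if (is.null(S_ext)) {
    S_ext <- matrix(0, 0L, ncol(S), dimnames = list(NULL, colnames(S)))
  }
  if (is.null(obj)) obj <- rep(0, ncol(S))
  m <- structure(list(
    S = S, S_ext = S_ext,
    lb = stats::setNames(lb, colnames(S)),
    ub = stats::setNames(ub, colnames(S)),
    obj = stats::setNames(obj, colnames(S)),
    met_ids = rownames(S), rxn_ids = colnames(S),
    ext_ids = rownames(S_ext),
    compartments = compartments
  ), class = "metabolic_model")
  validate_model(m)
}

#' Validate a metabolic model's invariants
#'
#' Checks ID uniqueness, dimension agreement, bound ordering
#' (\eqn{\alpha_i \le \beta_i}) and that every reaction touches at least
#' one internal or external species. Called by all constructors; exported
#' because readers of foreign files may want to re-validate after manual
#' surgery.
#'
#' @param model a `metabolic_model`.
#' @return `model`, invisibly usable, or an error describing the violated
#'   invariant.
#' @export
validate_model <- function(model) {
  with(model, {
    if (anyDuplicated(met_ids)) stop("duplicate metabolite IDs")
    if (anyDuplicated(rxn_ids)) stop("duplicate reaction IDs")
    if (length(intersect(met_ids, ext_ids))) {
      stop("metabolite(s) both internal and external: ",
           paste(intersect(met_ids, ext_ids), collapse = ", "))
    }
    n <- ncol(S)
    if (nrow(S) != length(met_ids) || ncol(S_ext) != n ||
        length(lb) != n || length(ub) != n || length(obj) != n) {
      stop("dimension mismatch between S, bounds and objective")
    }
    bad <- which(lb > ub)
    if (length(bad)) {
      stop("lower bound exceeds upper bound for reaction ", rxn_ids[bad[1]])
    }
    empty <- colSums(S != 0) == 0 & colSums(S_ext != 0) == 0
    if (any(empty)) {
      stop("reaction with no stoichiometry: ", rxn_ids[which(empty)[1]])
    }
  })
  model
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", length(x$rxn_ids), " reactions, ",
      length(x$met_ids), " internal metabolites, ",
      length(x$ext_ids), " external species\n", sep = "")
  nrev <- sum(x$lb < 0)
  cat("  reversible (lb < 0): ", nrev, "; objective on: ",
      paste(x$rxn_ids[x$obj != 0], collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Drop reactions from a model
#'
#' Removes the named reaction columns; optionally also removes internal
#' metabolites left without any reaction (all-zero rows), which is the
#' clean-up the pruning loop applies on termination.
#'
#' @param model a `metabolic_model`.
#' @param reactions character vector of reaction IDs to remove.
#' @param drop_unconnected also drop internal metabolites whose row
#'   becomes all zero (default `FALSE`).
#' @return the reduced `metabolic_model`.
#' @export
remove_reactions <- function(model, reactions, drop_unconnected = FALSE) {
  unknown <- setdiff(reactions, model$rxn_ids)
  if (length(unknown)) stop("unknown reaction(s): ", paste(unknown, collapse = ", "))
  keep <- setdiff(model$rxn_ids, reactions)
  S <- model$S[, keep, drop = FALSE]
  S_ext <- model$S_ext[, keep, drop = FALSE]
  if (drop_unconnected) {
    S <- S[rowSums(S != 0) > 0, , drop = FALSE]
  }
  new_metabolic_model(S, S_ext, model$lb[keep], model$ub[keep],
                      model$obj[keep], model$compartments)
}

#' Add a biomass tracker species and export reaction
#'
#' A common modelling convention when reducing networks: introduce a
#' pseudo-metabolite `biomass` produced with coefficient 1 by the biomass
#' synthesis reaction, plus an export reaction for it. Protecting the
#' export reaction (and the tracker species) then preserves growth
#' capability while leaving the biomass synthesis reaction itself free to
#' be lumped during compression, so a condensed biomass reaction can be
#' derived. The transform is never applied implicitly.
#'
#' @param model a `metabolic_model`.
#' @param biomass_reaction_id ID of the biomass synthesis reaction.
#' @param tracker_id ID for the new species (default `"biomass"`).
#' @param export_id ID for the new export reaction
#'   (default `paste0(biomass_reaction_id, "_export")`).
#' @return the extended `metabolic_model`.
#' @export
add_biomass_tracker <- function(model, biomass_reaction_id,
                                tracker_id = "biomass",
                                export_id = paste0(biomass_reaction_id, "_export")) {
  if (!biomass_reaction_id %in% model$rxn_ids) {
    stop("unknown biomass reaction: ", biomass_reaction_id)
  }
  if (tracker_id %in% c(model$met_ids, model$ext_ids)) {
    stop("tracker species ID already in use: ", tracker_id)
  }
  S <- rbind(model$S, 0)
  rownames(S)[nrow(S)] <- tracker_id
  S[tracker_id, biomass_reaction_id] <- 1
  S <- cbind(S, 0)
  colnames(S)[ncol(S)] <- export_id
  S[tracker_id, export_id] <- -1
  S_ext <- cbind(model$S_ext, matrix(0, nrow(model$S_ext), 1))
  colnames(S_ext)[ncol(S_ext)] <- export_id
  new_metabolic_model(S, S_ext,
                      c(model$lb, 0), c(model$ub, Inf), c(model$obj, 0),
                      model$compartments)
}

#' Tidy view of a model's stoichiometry
#'
#' @param x a `metabolic_model`.
#' @param ... unused.
#' @return a tibble with columns `metabolite`, `reaction`, `coefficient`,
#'   `external` (one row per nonzero entry).
#' @export
tidy.metabolic_model <- function(x, ...) {
  long <- function(M, ext) {
    nz <- which(M != 0, arr.ind = TRUE)
    tibble::tibble(metabolite = rownames(M)[nz[, 1]],
                   reaction = colnames(M)[nz[, 2]],
                   coefficient = M[nz],
                   external = ext)
  }
  dplyr::arrange(dplyr::bind_rows(long(x$S, FALSE), long(x$S_ext, TRUE)),
                 .data$reaction, .data$external, .data$metabolite)
}

#' One-row summary of a model
#'
#' @param x a `metabolic_model`.
#' @param ... unused.
#' @return a tibble with reaction/metabolite counts, degrees of freedom
#'   and number of conservation relations.
#' @export
glance.metabolic_model <- function(x, ...) {
  rk <- stoich_rank(x$S)
  tibble::tibble(
    n_reactions = length(x$rxn_ids),
    n_metabolites = length(x$met_ids),
    n_external = length(x$ext_ids),
    dof = length(x$rxn_ids) - rk,
    n_conservation = length(x$met_ids) - rk
  )
}
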