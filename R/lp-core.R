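## Constraint-based analysis primitives: FBA, FVA, blocked reactions,
## degrees of freedom, conservation relations.

## default numerical tolerances (all overridable per call)
EPS_FLUX <- 1e-9   # zero / sign classification of fluxes
EPS_FEAS <- 1e-7   # constraint satisfaction
FLUX_CAP <- 1e5    # clip for unbounded FVA directions

## Assemble the LP data (A, sense, rhs, lb, ub) for a model under an
## optional scenario: steady-state rows S r = 0, scenario rows D r <= d,
## bounds merged with the scenario's overrides.
scenario_lp_data <- function(model, scenario = NULL) {
  n <- length(model$rxn_ids)
  A <- model$S
  sense <- rep("=", nrow(A))
  rhs <- rep(0, nrow(A))
  lb <- model$lb
  ub <- model$ub
  if (!is.null(scenario)) {
    for (cons in scenario$constraints) {
      row <- stats::setNames(rep(0, n), model$rxn_ids)
      bad <- setdiff(names(cons$coef), model$rxn_ids)
      if (length(bad)) {
        stop("scenario '", scenario$name, "' references unknown reaction(s): ",
             paste(bad, collapse = ", "))
      }
      row[names(cons$coef)] <- cons$coef
      A <- rbind(A, row)
      sense <- c(sense, "<=")
      rhs <- c(rhs, cons$rhs)
    }
    for (rid in names(scenario$bound_overrides)) {
      if (!rid %in% model$rxn_ids) {
        stop("scenario '", scenario$name, "' overrides bounds of unknown reaction: ", rid)
      }
      ov <- scenario$bound_overrides[[rid]]
      lb[rid] <- ov[1]
      ub[rid] <- ov[2]
    }
  }
  list(A = A, sense = sense, rhs = rhs, lb = lb, ub = ub)
}

#' Flux balance analysis
#'
#' Maximises a linear objective \eqn{z = c^T r} over the steady-state
#' flux polyhedron \eqn{\{r : N r = 0,\; \alpha \le r \le \beta\}},
#' optionally intersected with a scenario's linear constraints
#' \eqn{D r \le d} and bound overrides.
#'
#' @param model a `metabolic_model`.
#' @param objective named numeric vector of objective coefficients, a
#'   single reaction ID (maximise that flux), or `NULL` to use the
#'   model's own objective.
#' @param scenario a [scenario()] or `NULL`.
#' @param maximize maximise (default) or minimise.
#' @return a list with `status` (`"optimal"`, `"infeasible"`,
#'   `"unbounded"`), `objval`, and `flux` (named vector, one optimal flux
#'   distribution; `NA` unless optimal).
#' @export
fba <- function(model, objective = NULL, scenario = NULL, maximize = TRUE) {
  n <- length(model$rxn_ids)
  cvec <- stats::setNames(rep(0, n), model$rxn_ids)
  if (is.null(objective)) {
    cvec[] <- model$obj
  } else if (is.character(objective) && length(objective) == 1L) {
    if (!objective %in% model$rxn_ids) stop("unknown objective reaction: ", objective)
    cvec[objective] <- 1
  } else {
    bad <- setdiff(names(objective), model$rxn_ids)
    if (length(bad)) stop("unknown reaction(s) in objective: ", paste(bad, collapse = ", "))
    cvec[names(objective)] <- objective
  }
  if (all(cvec == 0)) stop("objective is identically zero")
  dat <- scenario_lp_data(model, scenario)
  res <- lp_solve(cvec, dat$A, dat$rhs, dat$sense, dat$lb, dat$ub,
                  maximize = maximize)
  list(status = res$status, objval = res$objval,
       flux = stats::setNames(res$x, model$rxn_ids))
}

#' Flux variability analysis
#'
#' For each requested reaction, minimises and maximises its rate under
#' the steady-state, bound and scenario constraints, giving the feasible
#' flux range. Directions in which the LP is unbounded are clipped at
#' `flux_cap` and flagged, so that downstream ranking can still compare
#' unbounded ranges honestly.
#'
#' @inheritParams fba
#' @param reactions reaction IDs to analyse (default: all).
#' @param flux_cap clip value for unbounded directions.
#' @return a tibble with columns `reaction`, `lo`, `hi`, `capped_lo`,
#'   `capped_hi`, `status`. An infeasible scenario yields
#'   `status = "infeasible"` and `NA` ranges for every reaction (never
#'   silently empty ranges).
#' @export
fva <- function(model, reactions = model$rxn_ids, scenario = NULL,
                flux_cap = FLUX_CAP) {
  bad <- setdiff(reactions, model$rxn_ids)
  if (length(bad)) stop("unknown reaction(s): ", paste(bad, collapse = ", "))
  dat <- scenario_lp_data(model, scenario)
  ## cap all variables so every LP is bounded; remember which bounds are real
  lb_real <- dat$lb
  ub_real <- dat$ub
  lb <- pmax(lb_real, -flux_cap)
  ub <- pmin(ub_real, flux_cap)
  if (any(lb > ub)) {
    ## a bound override can produce an empty box
    return(tibble::tibble(reaction = reactions, lo = NA_real_, hi = NA_real_,
                          capped_lo = FALSE, capped_hi = FALSE,
                          status = "infeasible"))
  }
  n <- length(model$rxn_ids)
  ## one feasibility probe: minimise 0 is not allowed, use first reaction
  probe <- lp_solve(stats::setNames(c(1, rep(0, n - 1)), model$rxn_ids),
                    dat$A, dat$rhs, dat$sense, lb, ub)
  if (probe$status == "infeasible") {
    return(tibble::tibble(reaction = reactions, lo = NA_real_, hi = NA_real_,
                          capped_lo = FALSE, capped_hi = FALSE,
                          status = "infeasible"))
  }
  out <- lapply(reactions, function(rid) {
    cvec <- stats::setNames(rep(0, n), model$rxn_ids)
    cvec[rid] <- 1
    lo_res <- lp_solve(cvec, dat$A, dat$rhs, dat$sense, lb, ub, maximize = FALSE)
    hi_res <- lp_solve(cvec, dat$A, dat$rhs, dat$sense, lb, ub, maximize = TRUE)
    if (lo_res$status != "optimal" || hi_res$status != "optimal") {
      return(tibble::tibble(reaction = rid, lo = NA_real_, hi = NA_real_,
                            capped_lo = FALSE, capped_hi = FALSE,
                            status = "solver_error"))
    }
    lo <- lo_res$objval
    hi <- hi_res$objval
    capped_lo <- lb_real[rid] < -flux_cap + 1e-6 && lo <= -flux_cap + 1e-6 * flux_cap
    capped_hi <- ub_real[rid] > flux_cap - 1e-6 && hi >= flux_cap - 1e-6 * flux_cap
    tibble::tibble(reaction = rid, lo = lo, hi = hi,
                   capped_lo = capped_lo, capped_hi = capped_hi,
                   status = "optimal")
  })
  res <- dplyr::bind_rows(out)
  ## numerical guard: lo <= hi always
  swap <- !is.na(res$lo) & res$lo > res$hi
  if (any(swap)) {
    mid <- (res$lo[swap] + res$hi[swap]) / 2
    res$lo[swap] <- mid
    res$hi[swap] <- mid
  }
  res
}

#' Per-scenario flux ranges and their union
#'
#' Runs [fva()] once per scenario of a protection specification and
#' stacks the results. With no scenarios, the base flux range of the
#' model is used as the single "scenario" (the documented fallback when
#' no protected function is specified).
#'
#' @param model a `metabolic_model`.
#' @param spec a [protection_spec()] (its `scenarios` are used) or a list
#'   of [scenario()] objects.
#' @param reactions reaction IDs to analyse (default: all).
#' @param flux_cap clip for unbounded directions.
#' @return a tibble with columns `reaction`, `scenario`, `lo`, `hi`,
#'   `capped_lo`, `capped_hi`, `status`.
#' @export
flux_range_table <- function(model, spec, reactions = model$rxn_ids,
                             flux_cap = FLUX_CAP) {
  scens <- if (inherits(spec, "protection_spec")) spec$scenarios else spec
  if (length(scens) == 0L) {
    scens <- list(scenario("base"))
  }
  dplyr::bind_rows(lapply(scens, function(sc) {
    dplyr::mutate(fva(model, reactions, sc, flux_cap = flux_cap),
                  scenario = sc$name, .after = "reaction")
  }))
}

#' Union of per-scenario flux ranges
#'
#' Collapses a [flux_range_table()] to one row per reaction: the union
#' \eqn{F_i = \cup_k F_i^k} of the per-scenario intervals as a sorted
#' list of disjoint intervals, its total width, and whether any
#' contributing end was capped. The union's width is the candidate
#' ranking key of the pruning loop (smallest overall range first).
#'
#' @param table tibble as returned by [flux_range_table()].
#' @return a tibble with columns `reaction`, `intervals` (list column of
#'   2-column matrices), `width`, `n_capped` (number of capped interval
#'   ends), `sign_definite` (entirely positive or entirely negative in at
#'   least one scenario).
#' @export
union_ranges <- function(table) {
  stopifnot(all(c("reaction", "lo", "hi") %in% names(table)))
  table |>
    dplyr::filter(!is.na(.data$lo)) |>
    dplyr::group_by(.data$reaction) |>
    dplyr::summarise(
      intervals = list(merge_intervals(.data$lo, .data$hi)),
      width = sum(intervals[[1]][, 2] - intervals[[1]][, 1]),
      n_capped = sum(.data$capped_lo) + sum(.data$capped_hi),
      sign_definite = any(.data$lo > EPS_FLUX | .data$hi < -EPS_FLUX),
      .groups = "drop"
    )
}

## merge a set of intervals [lo_i, hi_i] into sorted disjoint intervals
merge_intervals <- function(lo, hi) {
  o <- order(lo)
  lo <- lo[o]
  hi <- hi[o]
  out_lo <- lo[1]
  out_hi <- hi[1]
  if (length(lo) > 1L) {
    for (i in 2:length(lo)) {
      k <- length(out_lo)
      if (lo[i] <= out_hi[k] + 1e-12) {
        out_hi[k] <- max(out_hi[k], hi[i])
      } else {
        out_lo <- c(out_lo, lo[i])
        out_hi <- c(out_hi, hi[i])
      }
    }
  }
  cbind(lo = out_lo, hi = out_hi)
}

#' Blocked reactions
#'
#' A reaction is blocked when its flux range under the model's base
#' bounds (no scenario) is `[0, 0]` to within `eps`: it can never carry
#' flux at steady state.
#'
#' @param model a `metabolic_model`.
#' @param eps zero tolerance.
#' @return character vector of blocked reaction IDs.
#' @export
find_blocked <- function(model, eps = EPS_FLUX) {
  rng <- fva(model)
  if (any(rng$status == "infeasible")) {
    stop("model is infeasible under its base bounds")
  }
  rng$reaction[abs(rng$lo) <= eps & abs(rng$hi) <= eps]
}

## numerical rank of the internal stoichiometric matrix
stoich_rank <- function(S, eps_rank = 1e-9) {
  if (nrow(S) == 0L || ncol(S) == 0L) return(0L)
  d <- svd(S, nu = 0, nv = 0)$d
  sum(d > eps_rank * d[1])
}

#' Degrees of freedom of the steady-state flux space
#'
#' `dof = n - rank(N)`: the dimension of the null space of the internal
#' stoichiometric matrix. A model with no internal metabolites (e.g. a
#' single transfer between two external species) has `rank 0`, hence
#' `dof = n`.
#'
#' @param model a `metabolic_model`.
#' @param eps_rank relative singular-value tolerance for the rank.
#' @return integer degrees of freedom.
#' @export
dof <- function(model, eps_rank = 1e-9) {
  ncol(model$S) - stoich_rank(model$S, eps_rank)
}

#' Conservation relations
#'
#' Left-null vectors of the internal stoichiometric matrix: combinations
#' \eqn{y^T N = 0} of metabolite balances that are conserved (moiety
#' conservation). Their count is `m - rank(N)`.
#'
#' @inheritParams dof
#' @return a list with `count` and `basis` (an `m x count` matrix of
#'   left-null vectors; columns orthonormal).
#' @export
conservation_relations <- function(model, eps_rank = 1e-9) {
  S <- model$S
  m <- nrow(S)
  if (m == 0L) return(list(count = 0L, basis = matrix(0, 0L, 0L)))
  sv <- svd(S, nu = m)
  rk <- sum(sv$d > eps_rank * max(sv$d, 0))
  count <- m - rk
  basis <- if (count > 0L) sv$u[, (rk + 1L):m, drop = FALSE] else matrix(0, m, 0L)
  rownames(basis) <- rownames(S)
  list(count = count, basis = basis)
}

## orthonormal kernel (right null space) basis of S
kernel_basis <- function(S, eps_rank = 1e-9) {
  n <- ncol(S)
  if (nrow(S) == 0L) return(diag(n))
  sv <- svd(S, nv = n)
  rk <- sum(sv$d > eps_rank * max(sv$d, 0))
  if (rk == n) return(matrix(0, n, 0L))
  K <- sv$v[, (rk + 1L):n, drop = FALSE]
  rownames(K) <- colnames(S)
  K
}
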