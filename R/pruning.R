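## Iterative FVA-guided network pruning.
##
## The loop deletes non-protected reactions one at a time, smallest
## overall flux range first, and rejects (reinserts) any deletion that
## breaks a protected metabolite, reaction, phenotype, the dof floor or
## the reaction-count floor. The result is always a proper subnetwork of
## the input.

#' Preprocess a model for pruning
#'
#' Checks that every protected scenario is feasible on the full model,
#' removes blocked reactions that are not protected, and drops internal
#' metabolites left unconnected. Errors early when a protected reaction
#' is blocked while feasibility of protected reactions is enforced, or
#' when a protected metabolite only touches blocked reactions.
#'
#' @param model a `metabolic_model`.
#' @param spec a [protection_spec()]; validated (and FBA_MAX-resolved)
#'   against `model` if not already.
#' @return a list with `model` (the cleaned model), `spec` (validated)
#'   and `log` (tibble of blocked-reaction removals).
#' @export
preprocess <- function(model, spec) {
  spec <- validate_spec(spec, model)
  for (sc in spec$scenarios) {
    dat <- scenario_lp_data(model, sc)
    probe <- lp_solve(stats::setNames(c(1, rep(0, ncol(model$S) - 1)), model$rxn_ids),
                      dat$A, dat$rhs, dat$sense,
                      pmax(dat$lb, -FLUX_CAP), pmin(dat$ub, FLUX_CAP))
    if (probe$status != "optimal") {
      stop("protected function '", sc$name, "' is infeasible on the full model ",
           "(its constraints admit no steady-state flux vector; review the ",
           "scenario's inequalities and bound overrides)")
    }
  }
  blocked <- find_blocked(model)
  if (spec$enforce_protected_feasibility) {
    bad <- intersect(blocked, spec$protected_reactions)
    if (length(bad)) {
      stop("protected reaction(s) can never carry flux: ",
           paste(bad, collapse = ", "))
    }
  }
  for (p in spec$protected_metabolites) {
    touching <- met_reactions(model, p)
    if (length(touching) && all(touching %in% blocked)) {
      stop("protected metabolite '", p, "' only touches blocked reactions")
    }
  }
  drop <- setdiff(blocked, spec$protected_reactions)
  log <- tibble::tibble(iteration = 0L, reaction = drop,
                        action = "blocked", width = 0,
                        scenario_widths = NA_character_)
  if (length(drop)) {
    model <- remove_reactions(model, drop, drop_unconnected = TRUE)
  }
  list(model = model, spec = spec, log = log)
}

## reactions whose column touches metabolite id (internal or external)
met_reactions <- function(model, met) {
  if (met %in% model$met_ids) {
    model$rxn_ids[model$S[met, ] != 0]
  } else if (met %in% model$ext_ids) {
    model$rxn_ids[model$S_ext[met, ] != 0]
  } else character()
}

#' Essential reactions from a flux-range table
#'
#' A reaction whose flux range under *some* protected scenario is
#' entirely positive or entirely negative must carry flux whenever that
#' phenotype is realised, so it can never be deleted. Such reactions
#' leave the removable set permanently.
#'
#' @param range_table tibble from [flux_range_table()].
#' @param eps sign-classification tolerance.
#' @return character vector of essential reaction IDs.
#' @export
classify_essential <- function(range_table, eps = EPS_FLUX) {
  sd <- range_table |>
    dplyr::filter(!is.na(.data$lo)) |>
    dplyr::group_by(.data$reaction) |>
    dplyr::summarise(sig = any(.data$lo > eps | .data$hi < -eps), .groups = "drop")
  sd$reaction[sd$sig]
}

#' Next deletion candidate
#'
#' Returns the removable reaction with the smallest overall (union)
#' flux-range width. Capped (unbounded, clipped) ranges compare by their
#' capped width first and then by the number of capped ends, fewer
#' first. Ties are broken by the configured rule: a seeded uniform
#' random choice (the default, matching the non-unique nature of
#' pruning) or deterministically by lowest index.
#'
#' @param union_table tibble from [union_ranges()].
#' @param removable character vector of candidate reaction IDs.
#' @param tie_rule `"random"` or `"lowest_index"`.
#' @return a single reaction ID, or `NULL` when `removable` is empty.
#' @export
select_candidate <- function(union_table, removable,
                             tie_rule = c("random", "lowest_index")) {
  ord <- candidate_order(union_table, removable, match.arg(tie_rule))
  if (length(ord) == 0L) NULL else ord[1]
}

## full candidate ordering (ascending width, then n_capped, then tie rule);
## assumes the caller has seeded the RNG when tie_rule == "random"
candidate_order <- function(union_table, removable, tie_rule) {
  tbl <- union_table[union_table$reaction %in% removable, , drop = FALSE]
  if (nrow(tbl) == 0L) return(character())
  key <- order(tbl$width, tbl$n_capped)
  tbl <- tbl[key, , drop = FALSE]
  ## break ties within groups of (numerically) equal width and n_capped
  grp <- cumsum(c(TRUE, abs(diff(tbl$width)) > 1e-9 * (1 + abs(tbl$width[-1])) |
                    diff(tbl$n_capped) != 0))
  out <- character(0)
  for (g in unique(grp)) {
    ids <- tbl$reaction[grp == g]
    if (length(ids) > 1L) {
      ids <- if (tie_rule == "random") sample(ids) else sort(ids)
    }
    out <- c(out, ids)
  }
  out
}

## Trial deletion of `rxn`: fix its bounds to zero, test specifications
## (a)-(e); on rejection the caller's model is untouched (we only ever
## work on a bounds-modified copy). Returns list(accepted, reason).
try_delete_check <- function(model, spec, rxn, n_current, flux_cap = FLUX_CAP,
                             eps = EPS_FLUX) {
  if (n_current - 1L < spec$n_min) {
    return(list(accepted = FALSE, reason = "n_min"))
  }
  trial <- model
  trial$lb[rxn] <- 0
  trial$ub[rxn] <- 0
  scens <- if (length(spec$scenarios)) spec$scenarios else list(scenario("base"))
  ## (c) every protected function still feasible
  lps <- lapply(scens, function(sc) {
    dat <- scenario_lp_data(trial, sc)
    dat$lb <- pmax(dat$lb, -flux_cap)
    dat$ub <- pmin(dat$ub, flux_cap)
    dat
  })
  zero_obj <- stats::setNames(rep(0, length(trial$rxn_ids)), trial$rxn_ids)
  for (i in seq_along(lps)) {
    dat <- lps[[i]]
    cvec <- zero_obj
    cvec[1] <- 1
    probe <- lp_solve(cvec, dat$A, dat$rhs, dat$sense, dat$lb, dat$ub)
    if (probe$status != "optimal") {
      return(list(accepted = FALSE,
                  reason = paste0("scenario:", scens[[i]]$name)))
    }
  }
  can_flux <- function(rid) {
    for (dat in lps) {
      cvec <- zero_obj
      cvec[rid] <- 1
      hi <- lp_solve(cvec, dat$A, dat$rhs, dat$sense, dat$lb, dat$ub, maximize = TRUE)
      if (hi$status == "optimal" && hi$objval > eps) return(TRUE)
      lo <- lp_solve(cvec, dat$A, dat$rhs, dat$sense, dat$lb, dat$ub, maximize = FALSE)
      if (lo$status == "optimal" && lo$objval < -eps) return(TRUE)
    }
    FALSE
  }
  ## (b) protected reactions stay feasible (carry nonzero flux somewhere)
  if (spec$enforce_protected_feasibility) {
    for (p in spec$protected_reactions) {
      if (!can_flux(p)) {
        return(list(accepted = FALSE, reason = paste0("protected_reaction:", p)))
      }
    }
  }
  ## (a) each protected metabolite participates in >=1 feasible reaction
  for (pm in spec$protected_metabolites) {
    touching <- setdiff(met_reactions(trial, pm), rxn)
    ok <- FALSE
    for (rid in touching) {
      if (can_flux(rid)) { ok <- TRUE; break }
    }
    if (!ok) {
      return(list(accepted = FALSE, reason = paste0("protected_metabolite:", pm)))
    }
  }
  ## (d) dof on the tentative network (column actually absent)
  if (spec$dof_min > 0L) {
    keep <- setdiff(trial$rxn_ids, rxn)
    dtent <- length(keep) - stoich_rank(trial$S[, keep, drop = FALSE])
    if (dtent < spec$dof_min) {
      return(list(accepted = FALSE, reason = "dof_min"))
    }
  }
  list(accepted = TRUE, reason = "ok")
}

#' Attempt deletion of a single reaction
#'
#' Tests whether removing `rxn` from `model` preserves every protected
#' specification: protected-phenotype feasibility, protected-reaction
#' feasibility (when enforced), protected-metabolite participation, the
#' dof floor and the reaction-count floor. The trial fixes the
#' reaction's bounds to zero, so rejection leaves the model untouched;
#' acceptance returns the model with the column truly removed. Rejection
#' is a normal outcome, not an error.
#'
#' @param model a `metabolic_model`.
#' @param spec a validated [protection_spec()].
#' @param rxn a non-protected reaction ID.
#' @return a list with `accepted` (logical), `reason` (which
#'   specification blocked the deletion, or `"ok"`), and `model` (the
#'   reduced model if accepted, else the input).
#' @export
try_delete <- function(model, spec, rxn) {
  if (!rxn %in% model$rxn_ids) stop("unknown reaction: ", rxn)
  if (rxn %in% spec$protected_reactions) stop("reaction is protected: ", rxn)
  chk <- try_delete_check(model, spec, rxn, n_current = length(model$rxn_ids))
  if (chk$accepted) {
    list(accepted = TRUE, reason = "ok",
         model = remove_reactions(model, rxn))
  } else {
    list(accepted = FALSE, reason = chk$reason, model = model)
  }
}

#' Prune a metabolic network
#'
#' The main reduction loop. Starting from the preprocessed model, each
#' iteration computes flux variability for all removable reactions under
#' every protected scenario, moves sign-definite reactions to the
#' essential (non-removable) set, and then attempts to delete the
#' removable reaction with the smallest union flux-range width. A
#' rejected deletion is reinserted, marked non-removable, and the next
#' smallest candidate from the same table is tried; after an accepted
#' deletion the ranges are recomputed. The loop stops when no removable
#' reaction is left, and unconnected internal metabolites are dropped.
#'
#' @param model a `metabolic_model`.
#' @param spec a [protection_spec()].
#' @param seed integer seed for random tie-breaking (written to the log;
#'   the caller's RNG state is preserved).
#' @param tie_rule `"random"` (default) or `"lowest_index"`.
#' @param flux_cap clip for unbounded FVA directions.
#' @param lazy_fva reuse the flux-range table across accepted deletions
#'   until a rejection occurs, instead of recomputing every iteration.
#'   Cheaper, and may change (but never invalidate) the trajectory.
#' @return an object of class `prune_result`: `model` (the pruned
#'   network), `log` (removal log tibble with columns `iteration`,
#'   `reaction`, `action`, `width`, `scenario_widths`), `essential`,
#'   `removed`, `stats` (before/after sizes and dof), `scenario_optima`,
#'   `spec`, `seed`.
#' @export
prune <- function(model, spec, seed = 0L, tie_rule = c("random", "lowest_index"),
                  flux_cap = FLUX_CAP, lazy_fva = FALSE) {
  tie_rule <- match.arg(tie_rule)
  prep <- preprocess(model, spec)
  full <- model
  model <- prep$model
  spec <- prep$spec
  log <- prep$log

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)

  removable <- setdiff(model$rxn_ids, spec$protected_reactions)
  iteration <- 0L
  table_fresh <- FALSE
  tab <- NULL

  repeat {
    iteration <- iteration + 1L
    if (length(removable) == 0L) break
    if (is.null(tab) || !table_fresh) {
      tab <- flux_range_table(model, spec, reactions = removable,
                              flux_cap = flux_cap)
      table_fresh <- TRUE
    }
    ur <- union_ranges(tab[tab$reaction %in% removable, , drop = FALSE])
    ess <- ur$reaction[ur$sign_definite]
    if (length(ess)) {
      log <- dplyr::bind_rows(log, tibble::tibble(
        iteration = iteration, reaction = ess, action = "essential",
        width = ur$width[match(ess, ur$reaction)],
        scenario_widths = scen_widths(tab, ess)))
      removable <- setdiff(removable, ess)
      ur <- ur[!ur$reaction %in% ess, , drop = FALSE]
    }
    if (length(removable) == 0L) break
    cands <- candidate_order(ur, removable, tie_rule)
    accepted_one <- FALSE
    for (cand in cands) {
      chk <- try_delete_check(model, spec, cand,
                              n_current = length(model$rxn_ids),
                              flux_cap = flux_cap)
      w <- ur$width[ur$reaction == cand]
      sw <- scen_widths(tab, cand)
      if (chk$accepted) {
        model <- remove_reactions(model, cand)
        removable <- setdiff(removable, cand)
        log <- dplyr::bind_rows(log, tibble::tibble(
          iteration = iteration, reaction = cand, action = "removed",
          width = w, scenario_widths = sw))
        tab <- tab[tab$reaction != cand, , drop = FALSE]
        table_fresh <- lazy_fva   # stale unless lazily reused
        accepted_one <- TRUE
        break
      } else {
        removable <- setdiff(removable, cand)
        log <- dplyr::bind_rows(log, tibble::tibble(
          iteration = iteration, reaction = cand, action = "reinserted",
          width = w, scenario_widths = sw))
        table_fresh <- FALSE      # a rejection ends any lazy reuse
        if (lazy_fva) break       # recompute before further candidates
      }
    }
    if (!accepted_one && !lazy_fva) break
  }

  pruned <- remove_reactions(model, character(), drop_unconnected = TRUE)
  stats <- tibble::tibble(
    stage = c("full", "pruned"),
    n_reactions = c(length(full$rxn_ids), length(pruned$rxn_ids)),
    n_metabolites = c(length(full$met_ids), length(pruned$met_ids)),
    dof = c(dof(full), dof(pruned))
  )
  optima <- scenario_optima(full, pruned, spec)
  structure(list(model = pruned, log = log,
                 essential = log$reaction[log$action == "essential"],
                 removed = log$reaction[log$action %in% c("removed", "blocked")],
                 stats = stats, scenario_optima = optima,
                 spec = spec, seed = seed),
            class = "prune_result")
}

## per-scenario width summary string for the log, e.g. "aerobic=0.01;anaerobic=0"
scen_widths <- function(tab, rxns) {
  vapply(rxns, function(r) {
    rows <- tab[tab$reaction == r, , drop = FALSE]
    paste0(rows$scenario, "=", signif(rows$hi - rows$lo, 6), collapse = ";")
  }, character(1))
}

## FBA optimum of the model objective under each scenario, full vs reduced
scenario_optima <- function(full, reduced, spec) {
  if (all(full$obj == 0) || length(spec$scenarios) == 0L) {
    return(tibble::tibble(scenario = character(), full = numeric(),
                          reduced = numeric()))
  }
  get_opt <- function(m, sc) {
    res <- fba(m, scenario = sc)
    if (res$status == "optimal") res$objval else NA_real_
  }
  obj_red <- full$obj[reduced$rxn_ids]
  red <- reduced
  red$obj <- obj_red
  tibble::tibble(
    scenario = vapply(spec$scenarios, `[[`, character(1), "name"),
    full = vapply(spec$scenarios, function(sc) get_opt(full, sc), numeric(1)),
    reduced = vapply(spec$scenarios, function(sc) get_opt(red, sc), numeric(1))
  )
}

#' @export
print.prune_result <- function(x, ...) {
  s <- x$stats
  cat("<prune_result> ", s$n_reactions[1], " -> ", s$n_reactions[2],
      " reactions; ", s$n_metabolites[1], " -> ", s$n_metabolites[2],
      " internal metabolites; dof ", s$dof[1], " -> ", s$dof[2], "\n",
      "  removed ", sum(x$log$action == "removed"), ", reinserted ",
      sum(x$log$action == "reinserted"), ", essential ",
      sum(x$log$action == "essential"), ", blocked ",
      sum(x$log$action == "blocked"), " (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.prune_result <- function(x, ...) x$log

#' @export
glance.prune_result <- function(x, ...) {
  s <- x$stats
  tibble::tibble(
    n_reactions_full = s$n_reactions[1], n_reactions_pruned = s$n_reactions[2],
    n_metabolites_full = s$n_metabolites[1], n_metabolites_pruned = s$n_metabolites[2],
    dof_full = s$dof[1], dof_pruned = s$dof[2],
    n_removed = sum(x$log$action == "removed"),
    n_reinserted = sum(x$log$action == "reinserted"),
    n_essential = sum(x$log$action == "essential"),
    seed = x$seed
  )
}
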