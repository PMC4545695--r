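#' Define a protected phenotype (scenario)
#'
#' A scenario is one protected function: a set of linear inequality
#' constraints \eqn{D_k r \le d_k} over named reactions, optionally with
#' per-reaction bound overrides that apply only within the scenario
#' (e.g. shutting off oxygen uptake for an anaerobic phenotype). The
#' reduced network must retain at least one steady-state flux vector
#' satisfying every scenario.
#'
#' Constraints may be given as strings (`"R_glc_up <= 10"`,
#' `"-mu <= -0.999 * FBA_MAX(mu)"`) or as prebuilt lists
#' `list(coef = c(mu = -1), rhs = -0.9)`. Relations are normalised to
#' `<=`: a `>=` is stored negated and an `=` becomes a pair of `<=`. The
#' `FBA_MAX(rxn)` token denotes the maximum of `rxn`'s flux on the *full*
#' model under the scenario's other constraints; it is resolved to a
#' number by [resolve_scenario()] (called automatically by
#' [read_protection_spec()]).
#'
#' @param name scenario name.
#' @param constraints list/vector of constraint strings or coef/rhs lists.
#' @param bound_overrides named list `reaction -> c(lb, ub)`.
#' @return an object of class `scenario`.
#' @examples
#' scenario("aerobic", c("R_glc_up <= 10", "-mu <= -0.999 * FBA_MAX(mu)"))
#' @export
scenario <- function(name, constraints = list(), bound_overrides = list()) {
  parsed <- list()
  for (cons in constraints) {
    if (is.character(cons)) {
      parsed <- c(parsed, parse_constraint(cons))
    } else {
      stopifnot(is.list(cons), !is.null(cons$coef), !is.null(cons$rhs))
      parsed <- c(parsed, list(list(coef = cons$coef, rhs = cons$rhs,
                                    fba_max = NULL)))
    }
  }
  structure(list(name = name, constraints = parsed,
                 bound_overrides = bound_overrides),
            class = "scenario")
}

## Parse one linear constraint string into >= 1 normalised `<=` rows.
## Grammar: linear expr (terms `c`, `c*ID`, `ID`, `c*FBA_MAX(ID)`,
## `FBA_MAX(ID)`) REL linear expr, REL in {<=, >=, =, ==}. No general
## expression language on purpose.
parse_constraint <- function(s) {
  s0 <- s
  rel <- regmatches(s, regexpr("<=|>=|==|=", s))
  if (length(rel) != 1L) stop("constraint must contain one relation (<=, >=, =): ", s0)
  sides <- strsplit(s, "<=|>=|==|=", perl = TRUE)[[1]]
  if (length(sides) != 2L) stop("malformed constraint: ", s0)
  lhs <- parse_linexpr(sides[1], s0)
  rhs <- parse_linexpr(sides[2], s0)
  ## move variables left, constants right: (lhs - rhs) REL 0
  coef <- lhs$coef
  for (v in names(rhs$coef)) {
    coef[v] <- (if (v %in% names(coef)) coef[v] else 0) - rhs$coef[[v]]
  }
  coef <- coef[coef != 0]
  if (length(coef) == 0L) stop("constraint has no reaction term: ", s0)
  const <- rhs$const - lhs$const
  ## FBA_MAX terms end up on the right-hand side; lhs occurrences negate
  fm <- c(lapply(lhs$fba_max, function(t) list(coef = -t$coef, rxn = t$rxn)),
          rhs$fba_max)
  row <- list(coef = coef, rhs = const, fba_max = if (length(fm)) fm else NULL)
  switch(rel,
    "<=" = list(row),
    ">=" = list(negate_row(row)),
    list(row, negate_row(row))  # "=" / "=="
  )
}

negate_row <- function(row) {
  list(coef = -row$coef, rhs = -row$rhs,
       fba_max = lapply(row$fba_max, function(t) list(coef = -t$coef, rxn = t$rxn)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## parse one side of a constraint into coef map + constant + FBA_MAX terms
parse_linexpr <- function(s, ctx) {
  s <- gsub("\\s+", "", s)
  if (s == "") stop("empty expression in constraint: ", ctx)
  ## split into signed terms
  toks <- regmatches(s, gregexpr("[+-]?[^+-]+(\\([^)]*\\))?", s))[[1]]
  ## the regex above can split inside FBA_MAX(...); re-join fragments
  terms <- character()
  for (t in toks) {
    if (length(terms) && grepl("FBA_MAX\\([^)]*$", terms[length(terms)])) {
      terms[length(terms)] <- paste0(terms[length(terms)], t)
    } else terms <- c(terms, t)
  }
  coef <- numeric()
  const <- 0
  fba_max <- list()
  num_re <- "^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$"
  for (t in terms) {
    sign <- 1
    if (startsWith(t, "-")) { sign <- -1; t <- substring(t, 2) }
    else if (startsWith(t, "+")) t <- substring(t, 2)
    parts <- strsplit(t, "*", fixed = TRUE)[[1]]
    if (length(parts) == 1L) {
      cval <- 1
      sym <- parts[1]
    } else if (length(parts) == 2L) {
      if (!grepl(num_re, parts[1])) stop("coefficient must be a number literal in: ", ctx)
      cval <- as.numeric(parts[1])
      sym <- parts[2]
    } else stop("malformed term '", t, "' in constraint: ", ctx)
    if (grepl("^FBA_MAX\\(.+\\)$", sym)) {
      rxn <- sub("^FBA_MAX\\((.+)\\)$", "\\1", sym)
      fba_max <- c(fba_max, list(list(coef = sign * cval, rxn = rxn)))
    } else if (grepl(num_re, sym)) {
      if (length(parts) == 2L) stop("number*number term in constraint: ", ctx)
      const <- const + sign * as.numeric(sym)
    } else {
      if (!grepl("^[A-Za-z_][A-Za-z0-9_]*$", sym)) {
        stop("invalid identifier '", sym, "' in constraint: ", ctx)
      }
      coef[sym] <- (if (sym %in% names(coef)) coef[sym] else 0) + sign * cval
    }
  }
  list(coef = coef, const = const, fba_max = fba_max)
}

#' Resolve FBA_MAX tokens of a scenario against the full model
#'
#' Each `FBA_MAX(rxn)` token is replaced by the optimal value of an FBA
#' maximising `rxn` on the full model, under the scenario's bound
#' overrides and all of its constraints that carry no token themselves
#' (so an anaerobic scenario's maximal growth is computed with oxygen
#' uptake already shut off). The resolved values are recorded in the
#' `"resolutions"` attribute of the returned scenario.
#'
#' @param scen a [scenario()].
#' @param model the full `metabolic_model`.
#' @return the scenario with all constraint rows fully numeric.
#' @export
resolve_scenario <- function(scen, model) {
  has_token <- vapply(scen$constraints, function(r) !is.null(r$fba_max), logical(1))
  if (!any(has_token)) return(scen)
  plain <- scen$constraints[!has_token]
  base <- structure(list(name = paste0(scen$name, "[resolve]"),
                         constraints = plain,
                         bound_overrides = scen$bound_overrides),
                    class = "scenario")
  resolutions <- list()
  for (i in which(has_token)) {
    row <- scen$constraints[[i]]
    extra <- 0
    for (t in row$fba_max) {
      if (!t$rxn %in% model$rxn_ids) {
        stop("FBA_MAX references unknown reaction: ", t$rxn)
      }
      key <- paste0(scen$name, ":", t$rxn)
      if (is.null(resolutions[[key]])) {
        res <- fba(model, objective = t$rxn, scenario = base, maximize = TRUE)
        if (res$status != "optimal") {
          stop("FBA_MAX(", t$rxn, ") in scenario '", scen$name,
               "' is ", res$status, " on the full model")
        }
        resolutions[[key]] <- res$objval
      }
      extra <- extra + t$coef * resolutions[[key]]
    }
    row$rhs <- row$rhs + extra
    row$fba_max <- NULL
    scen$constraints[[i]] <- row
  }
  attr(scen, "resolutions") <- resolutions
  scen
}

#' Build a protection specification
#'
#' The full statement of what a reduction must preserve: (a) protected
#' metabolites, (b) protected reactions (optionally required to stay
#' feasible, i.e. able to carry nonzero flux), (c) protected phenotypes
#' as scenarios, (d) a minimum number of degrees of freedom and (e) a
#' minimum number of reactions.
#'
#' @param protected_metabolites character vector of metabolite IDs.
#' @param protected_reactions character vector of reaction IDs.
#' @param enforce_protected_feasibility must each protected reaction be
#'   able to carry nonzero flux in at least one scenario?
#' @param scenarios list of [scenario()] objects.
#' @param dof_min non-negative integer; `0` disables the constraint.
#' @param n_min positive integer.
#' @param model optional `metabolic_model`; when given, all referenced
#'   IDs are validated and FBA_MAX tokens resolved against it.
#' @return an object of class `protection_spec`.
#' @export
protection_spec <- function(protected_metabolites = character(),
                            protected_reactions = character(),
                            enforce_protected_feasibility = FALSE,
                            scenarios = list(),
                            dof_min = 0L, n_min = 1L,
                            model = NULL) {
  if (dof_min < 0) stop("dof_min must be >= 0")
  if (n_min < 1) stop("n_min must be >= 1")
  if (inherits(scenarios, "scenario")) scenarios <- list(scenarios)
  spec <- structure(list(
    protected_metabolites = unique(as.character(protected_metabolites)),
    protected_reactions = unique(as.character(protected_reactions)),
    enforce_protected_feasibility = isTRUE(enforce_protected_feasibility),
    scenarios = scenarios,
    dof_min = as.integer(dof_min),
    n_min = as.integer(n_min)
  ), class = "protection_spec")
  if (!is.null(model)) spec <- validate_spec(spec, model)
  spec
}

## validate IDs against a model and resolve FBA_MAX tokens
validate_spec <- function(spec, model) {
  bad_m <- setdiff(spec$protected_metabolites, c(model$met_ids, model$ext_ids))
  if (length(bad_m)) stop("unknown protected metabolite(s): ", paste(bad_m, collapse = ", "))
  bad_r <- setdiff(spec$protected_reactions, model$rxn_ids)
  if (length(bad_r)) stop("unknown protected reaction(s): ", paste(bad_r, collapse = ", "))
  spec$scenarios <- lapply(spec$scenarios, function(sc) {
    for (row in sc$constraints) {
      bad <- setdiff(names(row$coef), model$rxn_ids)
      if (length(bad)) {
        stop("scenario '", sc$name, "' references unknown reaction(s): ",
             paste(bad, collapse = ", "))
      }
    }
    resolve_scenario(sc, model)
  })
  spec
}

#' Read a protection specification from YAML
#'
#' The YAML schema (also shipped as a JSON-schema file under
#' `inst/extdata/protection-spec.schema.json`) has top-level keys
#' `protected_metabolites`, `protected_reactions`,
#' `enforce_protected_feasibility`, `dof_min`, `n_min` and `scenarios`;
#' each scenario has `name`, `constraints` (strings) and optional
#' `bound_overrides` (`reaction: [lb, ub]`). All IDs are validated
#' against `model` and `FBA_MAX` tokens are resolved on it.
#'
#' @param path YAML file path.
#' @param model the full `metabolic_model`.
#' @return a validated `protection_spec`.
#' @export
read_protection_spec <- function(path, model) {
  if (!file.exists(path)) stop("no such file: ", path)
  y <- yaml::read_yaml(path)
  scens <- lapply(y$scenarios %||% list(), function(sy) {
    ov <- lapply(sy$bound_overrides %||% list(), function(v) {
      v <- as.numeric(v)
      if (length(v) != 2L) stop("bound_overrides entries must be [lb, ub]")
      v
    })
    scenario(sy$name %||% "scenario",
             constraints = unlist(sy$constraints %||% list()),
             bound_overrides = ov)
  })
  protection_spec(
    protected_metabolites = unlist(y$protected_metabolites %||% character()),
    protected_reactions = unlist(y$protected_reactions %||% character()),
    enforce_protected_feasibility = isTRUE(y$enforce_protected_feasibility),
    scenarios = scens,
    dof_min = y$dof_min %||% 0L,
    n_min = y$n_min %||% 1L,
    model = model
  )
}

#' @export
print.protection_spec <- function(x, ...) {
  cat("<protection_spec> ", length(x$protected_reactions), " protected reactions, ",
      length(x$protected_metabolites), " protected metabolites, ",
      length(x$scenarios), " scenario(s); dof_min=", x$dof_min,
      ", n_min=", x$n_min,
      if (x$enforce_protected_feasibility) ", feasibility enforced" else "",
      "\n", sep = "")
  invisible(x)
}
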