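## Packaged toy networks with documented expected reduction outcomes,
## plus a seeded random-network generator for property testing.

#' Build a packaged toy network
#'
#' Each toy returns a model, a matching protection specification and a
#' descriptor of the expected reduction outcome, asserted end-to-end in
#' the test suite.
#'
#' * `worked_example` — a protected core supplying precursor P plus the
#'   three-step amino-acid synthesis chain `2 P -> D`, `D + NADPH -> F`,
#'   `F + ATP -> A` feeding a biomass reaction consuming `2 A` (and two
#'   further core precursors, so the biomass column has the largest
#'   support and survives lumping as the subset representative), a
#'   suboptimal alternative route that pruning removes, and a protected
#'   biomass export via the tracker species. After prune + compress the
#'   condensed biomass reaction consumes 4 P, 2 ATP and 2 NADPH and the
#'   intermediates D, F, A are gone.
#' * `diamond` — two parallel two-step paths between a protected source
#'   and sink; with a maximal-export phenotype exactly one path
#'   survives (4 reactions), for every tie-breaking seed.
#' * `oxidase_pair` — a respiratory chain with two ubiquinol oxidases
#'   differing only in proton translocation (2 vs 4 protons per 0.5 O2);
#'   under a maximal-growth phenotype the 4-proton oxidase is essential
#'   and the 2-proton one is pruned.
#' * `trace_element` — uptake and biomass consumption of a trace element
#'   collapse into one step during compression, so the external species
#'   appears directly in the condensed biomass reaction.
#' * `cycle_unbounded` — a feasible linear chain next to an isolated
#'   reversible two-cycle whose internal flux is unbounded: FVA must
#'   report capped, flagged ranges.
#'
#' @param name one of `"worked_example"`, `"diamond"`, `"oxidase_pair"`,
#'   `"trace_element"`, `"cycle_unbounded"`.
#' @return a list with `model`, `spec` and `expected` (a named list of
#'   expected outcome facts used by the tests).
#' @examples
#' toy <- build_toy("diamond")
#' toy$model
#' @export
build_toy <- function(name) {
  builders <- list(
    worked_example = toy_worked_example,
    diamond = toy_diamond,
    oxidase_pair = toy_oxidase_pair,
    trace_element = toy_trace_element,
    cycle_unbounded = toy_cycle_unbounded
  )
  if (!name %in% names(builders)) {
    stop("unknown toy '", name, "'; available: ",
         paste(names(builders), collapse = ", "))
  }
  builders[[name]]()
}

toy_worked_example <- function() {
  stoich <- tibble::tribble(
    ~metabolite, ~reaction, ~coefficient,
    "P",       "R_P_up",     1,
    "P2",      "R_P2_up",    1,
    "P3",      "R_P3_up",    1,
    "NADPH",   "R_NADPH_up", 1,
    "ATP",     "R_ATP_up",   1,
    "P",       "R1",        -2,   # 2 P -> D
    "D",       "R1",         1,
    "D",       "R2",        -1,   # D + NADPH -> F
    "NADPH",   "R2",        -1,
    "F",       "R2",         1,
    "F",       "R3",        -1,   # F + ATP -> A
    "ATP",     "R3",        -1,
    "A",       "R3",         1,
    "P",       "R_alt",     -3,   # wasteful alternative route to A
    "ATP",     "R_alt",     -1,
    "A",       "R_alt",      1,
    "A",       "BSR",       -2,   # 2 A + core precursors -> biomass
    "P2",      "BSR",       -0.2,
    "P3",      "BSR",       -0.1,
    "Biomass", "BSR",        1,
    "Biomass", "R_bio_exp", -1
  )
  bounds <- tibble::tibble(
    reaction = c("R_P_up", "R_P2_up", "R_P3_up", "R_NADPH_up", "R_ATP_up",
                 "R1", "R2", "R3", "R_alt", "BSR", "R_bio_exp"),
    lb = 0,
    ub = c(10, 1000, 1000, 1000, 1000, Inf, Inf, Inf, Inf, Inf, Inf),
    objective = c(rep(0, 10), 1))
  model <- metabolic_model(stoich, bounds)
  spec <- protection_spec(
    protected_metabolites = c("P", "Biomass"),
    protected_reactions = c("R_P_up", "R_P2_up", "R_P3_up", "R_NADPH_up",
                            "R_ATP_up", "R_bio_exp"),
    enforce_protected_feasibility = TRUE,
    scenarios = list(scenario("max_growth",
                              "-R_bio_exp <= -0.999 * FBA_MAX(R_bio_exp)")),
    dof_min = 1, n_min = 1, model = model)
  list(model = model, spec = spec,
       expected = list(
         pruned_removed = "R_alt",
         n_pruned = 10L,
         bsr_coefficients = c(P = -4, ATP = -2, NADPH = -2,
                              P2 = -0.2, P3 = -0.1, Biomass = 1),
         eliminated = c("D", "F", "A"),
         biomass_reaction = "BSR"))
}

toy_diamond <- function() {
  stoich <- tibble::tribble(
    ~metabolite, ~reaction, ~coefficient,
    "A", "R_in", 1,
    "A", "R_a1", -1, "B1", "R_a1", 1, "B1", "R_b1", -1, "Z", "R_b1", 1,
    "A", "R_a2", -1, "B2", "R_a2", 1, "B2", "R_b2", -1, "Z", "R_b2", 1,
    "Z", "R_out", -1)
  bounds <- tibble::tibble(
    reaction = c("R_in", "R_a1", "R_b1", "R_a2", "R_b2", "R_out"),
    lb = 0, ub = c(10, Inf, Inf, Inf, Inf, Inf),
    objective = c(0, 0, 0, 0, 0, 1))
  model <- metabolic_model(stoich, bounds)
  spec <- protection_spec(
    protected_reactions = c("R_in", "R_out"),
    scenarios = list(scenario("max_export",
                              "-R_out <= -0.999 * FBA_MAX(R_out)")),
    dof_min = 1, n_min = 1, model = model)
  list(model = model, spec = spec,
       expected = list(n_pruned = 4L, n_efms_full = 2L, n_efms_pruned = 1L))
}

toy_oxidase_pair <- function() {
  stoich <- tibble::tribble(
    ~metabolite, ~reaction, ~coefficient,
    "O2",   "R_O2_up", 1,
    "Sub",  "R_S_up",  1,
    "Sub",  "R_dh",   -1, "Q8", "R_dh", -1, "Q8H2", "R_dh", 1,
    ## cytochrome bd oxidase: 2 H+ + 0.5 O2 + Q8H2 -> H2O + 2 H+_p + Q8
    "H_c",  "CYO_2H", -2, "O2", "CYO_2H", -0.5, "Q8H2", "CYO_2H", -1,
    "H2O",  "CYO_2H",  1, "H_p", "CYO_2H", 2,  "Q8",   "CYO_2H",  1,
    ## cytochrome bo3 oxidase: 4 H+ + 0.5 O2 + Q8H2 -> H2O + 4 H+_p + Q8
    "H_c",  "CYO_4H", -4, "O2", "CYO_4H", -0.5, "Q8H2", "CYO_4H", -1,
    "H2O",  "CYO_4H",  1, "H_p", "CYO_4H", 4,  "Q8",   "CYO_4H",  1,
    "H_p",  "R_atps", -3, "H_c", "R_atps", 3, "ATP", "R_atps", 1,
    "H2O",  "R_h2o_ex", -1,
    "ATP",  "MU", -1, "Biomass", "MU", 1,
    "Biomass", "R_bio_exp", -1)
  rxns <- c("R_O2_up", "R_S_up", "R_dh", "CYO_2H", "CYO_4H", "R_atps",
            "R_h2o_ex", "MU", "R_bio_exp")
  bounds <- tibble::tibble(
    reaction = rxns, lb = 0,
    ub = c(10, 1000, Inf, Inf, Inf, Inf, Inf, Inf, Inf),
    objective = as.numeric(rxns == "R_bio_exp"))
  model <- metabolic_model(stoich, bounds)
  spec <- protection_spec(
    protected_metabolites = "Biomass",
    protected_reactions = c("R_O2_up", "R_S_up", "R_h2o_ex", "R_bio_exp"),
    enforce_protected_feasibility = TRUE,
    scenarios = list(scenario("max_growth",
                              "-R_bio_exp <= -0.999 * FBA_MAX(R_bio_exp)")),
    dof_min = 1, n_min = 1, model = model)
  list(model = model, spec = spec,
       expected = list(retained = "CYO_4H", removed = "CYO_2H",
                       mu_max_4H = 80 / 3, mu_max_2H_only = 40 / 3))
}

toy_trace_element <- function() {
  stoich <- tibble::tribble(
    ~metabolite, ~reaction, ~coefficient,
    "A",       "R_A_up",   1,
    "TE_ext",  "R_TE_up", -1,
    "TE",      "R_TE_up",  1,
    "A",       "BSR",     -1,
    "TE",      "BSR",     -0.01,
    "Biomass", "BSR",      1,
    "Biomass", "R_bio_exp", -1)
  bounds <- tibble::tibble(
    reaction = c("R_A_up", "R_TE_up", "BSR", "R_bio_exp"),
    lb = 0, ub = c(10, Inf, Inf, Inf), objective = c(0, 0, 0, 1))
  model <- metabolic_model(stoich, bounds)
  spec <- protection_spec(
    protected_metabolites = "Biomass",
    protected_reactions = c("R_A_up", "R_bio_exp"),
    scenarios = list(scenario("max_growth",
                              "-R_bio_exp <= -0.999 * FBA_MAX(R_bio_exp)")),
    dof_min = 1, n_min = 1, model = model)
  list(model = model, spec = spec,
       expected = list(condensed_external = "TE_ext",
                       te_coefficient = -0.01,
                       biomass_reaction = "BSR"))
}

toy_cycle_unbounded <- function() {
  stoich <- tibble::tribble(
    ~metabolite, ~reaction, ~coefficient,
    "A", "R_in", 1, "A", "R_ab", -1, "B", "R_ab", 1, "B", "R_out", -1,
    "C", "R_cyc1", -1, "D", "R_cyc1", 1,
    "D", "R_cyc2", -1, "C", "R_cyc2", 1)
  bounds <- tibble::tibble(
    reaction = c("R_in", "R_ab", "R_out", "R_cyc1", "R_cyc2"),
    lb = c(0, 0, 0, -Inf, -Inf), ub = c(5, Inf, Inf, Inf, Inf),
    objective = c(0, 0, 1, 0, 0))
  model <- metabolic_model(stoich, bounds)
  spec <- protection_spec(protected_reactions = c("R_in", "R_out"),
                          dof_min = 1, n_min = 1, model = model)
  list(model = model, spec = spec,
       expected = list(capped = c("R_cyc1", "R_cyc2")))
}

#' Generate a random mass-connected metabolic network
#'
#' Rejection-sampling generator used by the property tests: draws sparse
#' random stoichiometry plus exchange reactions, and accepts a draw only
#' if every internal metabolite is reachable from an exchange (mass
#' connectivity) and the network admits a nonzero feasible steady-state
#' flux. Reproducible for a fixed seed; the caller's RNG state is left
#' untouched.
#'
#' @param n_metabolites number of internal metabolites.
#' @param n_reactions number of internal (non-exchange) reactions.
#' @param density probability that a metabolite participates in a given
#'   internal reaction (draws with fewer than two participants are
#'   redrawn; `density = 0` therefore never yields a valid model and
#'   errors once the rejection budget is spent).
#' @param fraction_reversible probability that an internal reaction is
#'   reversible (`lb = -10` instead of `0`; all finite so that oracle
#'   LPs stay bounded).
#' @param n_exchanges number of exchange reactions (at least one uptake
#'   and one export).
#' @param seed integer seed.
#' @param max_tries rejection budget.
#' @return a `metabolic_model`.
#' @export
random_network <- function(n_metabolites = 8, n_reactions = 10,
                           density = 0.25, fraction_reversible = 0.3,
                           n_exchanges = 4, seed = 1L, max_tries = 200L) {
  stopifnot(n_exchanges >= 2, n_metabolites >= 2, n_reactions >= 1)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)

  mets <- sprintf("M%02d", seq_len(n_metabolites))
  for (try_i in seq_len(max_tries)) {
    rows <- list()
    ok <- TRUE
    for (j in seq_len(n_reactions)) {
      part <- NULL
      for (draw in 1:20) {
        part <- mets[stats::runif(n_metabolites) < density]
        if (length(part) >= 2) break
      }
      if (length(part) < 2) { ok <- FALSE; break }
      ns <- sample(seq_len(length(part) - 1L), 1)
      subs <- part[seq_len(ns)]
      prods <- part[-seq_len(ns)]
      co <- sample(c(1, 2), length(part), replace = TRUE, prob = c(.8, .2))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        metabolite = c(subs, prods),
        reaction = sprintf("R%02d", j),
        coefficient = c(-co[seq_along(subs)], co[length(subs) + seq_along(prods)]))
    }
    if (!ok) next
    ## exchanges: first half uptakes, rest exports, on random metabolites
    ex_mets <- sample(mets, n_exchanges, replace = n_exchanges > n_metabolites)
    n_up <- max(1L, n_exchanges %/% 2L)
    ex <- tibble::tibble(
      metabolite = ex_mets,
      reaction = sprintf("EX%02d", seq_len(n_exchanges)),
      coefficient = c(rep(1, n_up), rep(-1, n_exchanges - n_up)))
    stoich <- dplyr::bind_rows(c(rows, list(ex)))
    stoich <- dplyr::distinct(stoich, .data$metabolite, .data$reaction,
                              .keep_all = TRUE)
    rev <- stats::runif(n_reactions) < fraction_reversible
    bounds <- tibble::tibble(
      reaction = c(sprintf("R%02d", seq_len(n_reactions)),
                   sprintf("EX%02d", seq_len(n_exchanges))),
      lb = c(ifelse(rev, -10, 0), rep(0, n_exchanges)),
      ub = 10,
      objective = 0)
    model <- tryCatch(metabolic_model(stoich, bounds), error = function(e) NULL)
    if (is.null(model)) next
    if (!mass_connected(model)) next
    rng <- tryCatch(fva(model), error = function(e) NULL)
    if (is.null(rng) || any(rng$status != "optimal")) next
    if (all(abs(rng$lo) <= 1e-7 & abs(rng$hi) <= 1e-7)) next  # fully blocked
    return(model)
  }
  stop("random_network: rejection budget exceeded (", max_tries,
       " tries); the configuration admits no feasible connected network")
}

## every internal metabolite reachable from an exchanged metabolite via
## shared reactions (undirected bipartite BFS)
mass_connected <- function(model) {
  S <- model$S
  ex <- colSums(S != 0) == 1
  seen <- rowSums(abs(S[, ex, drop = FALSE])) > 0
  if (!any(seen)) return(FALSE)
  repeat {
    touched <- colSums(abs(S[seen, , drop = FALSE])) > 0
    new_seen <- rowSums(abs(S[, touched, drop = FALSE])) > 0
    if (all(new_seen == seen)) break
    seen <- new_seen
  }
  all(seen)
}

#' Count elementary flux modes of a small network
#'
#' Validation-only enumeration by support search: a flux vector is an
#' elementary mode iff the kernel of the stoichiometric matrix
#' restricted to its support is one-dimensional, has full support there,
#' and admits an orientation respecting all irreversibilities. A fully
#' reversible mode and its negative are counted once. Exhaustive over
#' supports, hence limited to small networks.
#'
#' @param model a `metabolic_model` with at most `max_reactions`
#'   reactions.
#' @param max_reactions hard guard (default 20).
#' @return integer count of elementary flux modes.
#' @export
count_efms <- function(model, max_reactions = 20L) {
  n <- ncol(model$S)
  if (n > max_reactions) {
    stop("count_efms is an exhaustive validation oracle; refusing n = ", n,
         " > ", max_reactions, " reactions")
  }
  irrev <- model$lb >= 0
  S <- model$S
  count <- 0L
  for (mask in seq_len(2^n - 1L)) {
    T_idx <- which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1L))) != 0L)
    k <- length(T_idx)
    St <- S[, T_idx, drop = FALSE]
    if (qr(St)$rank != k - 1L) next        # kernel dim must be exactly 1
    K <- kernel_basis(St)
    if (ncol(K) != 1L) next
    v <- K[, 1]
    if (any(abs(v) < 1e-9)) next           # must have full support on T
    ok_pos <- all(v[irrev[T_idx]] >= -1e-12)
    ok_neg <- all(-v[irrev[T_idx]] >= -1e-12)
    if (ok_pos || ok_neg) count <- count + 1L
  }
  count
}
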