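# Shared fixtures and independent oracles for the test suite.

# linear chain  -> A -> B -> C ->  with uptake capped at `cap`
chain_model <- function(cap = 10) {
  stoich <- tibble::tribble(
    ~metabolite, ~reaction, ~coefficient,
    "A", "R_up", 1,
    "A", "R_ab", -1, "B", "R_ab", 1,
    "B", "R_bc", -1, "C", "R_bc", 1,
    "C", "R_out", -1)
  bounds <- tibble::tibble(reaction = c("R_up", "R_ab", "R_bc", "R_out"),
                           lb = 0, ub = c(cap, Inf, Inf, Inf),
                           objective = c(0, 0, 0, 1))
  metabolic_model(stoich, bounds)
}

# carrier cycle with one conserved moiety (X + B pool):
# -> A ; A + X -> B ; B -> C + X ; C ->
moiety_model <- function() {
  stoich <- tibble::tribble(
    ~metabolite, ~reaction, ~coefficient,
    "A", "R_a_up", 1,
    "A", "R1", -1, "X", "R1", -1, "B", "R1", 1,
    "B", "R2", -1, "X", "R2", 1, "C", "R2", 1,
    "C", "R_c_out", -1)
  bounds <- tibble::tibble(reaction = c("R_a_up", "R1", "R2", "R_c_out"),
                           lb = 0, ub = 10, objective = 0)
  metabolic_model(stoich, bounds)
}

# Independent LP reference via boot::simplex on the split-variable
# standard form (x = p - q, p,q >= 0; bounds as extra rows; rhs made
# non-negative as boot requires). Used to cross-check the built-in
# bounded-variable simplex.
boot_lp <- function(obj, A, rhs, sense, lb, ub, maximize = FALSE) {
  n <- length(obj)
  A1 <- NULL; b1 <- NULL; A2 <- NULL; b2 <- NULL; A3 <- NULL; b3 <- NULL
  add_row <- function(a, b, s) {
    if (b < 0) { a <- -a; b <- -b; s <- switch(s, "<=" = ">=", ">=" = "<=", "=" = "=") }
    if (s == "<=") { A1 <<- rbind(A1, a); b1 <<- c(b1, b) }
    else if (s == ">=") { A2 <<- rbind(A2, a); b2 <<- c(b2, b) }
    else { A3 <<- rbind(A3, a); b3 <<- c(b3, b) }
  }
  for (i in seq_along(rhs)) add_row(c(A[i, ], -A[i, ]), rhs[i], sense[i])
  for (j in seq_len(n)) {
    e <- rep(0, 2 * n); e[j] <- 1; e[n + j] <- -1
    if (is.finite(ub[j])) add_row(e, ub[j], "<=")
    if (is.finite(lb[j])) add_row(e, lb[j], ">=")
  }
  out <- tryCatch(
    boot::simplex(a = c(obj, -obj), A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                  A3 = A3, b3 = b3, maxi = maximize, n.iter = 1000),
    error = function(e) NULL)
  if (is.null(out)) return(list(status = "error"))
  if (out$solved == 1) {
    list(status = "optimal", objval = unname(out$value),
         x = out$soln[seq_len(n)] - out$soln[n + seq_len(n)])
  } else if (out$solved == -1) {
    list(status = "infeasible")
  } else list(status = "other")
}

# brute-force blocked set: for each reaction, maximise and minimise its
# flux with two direct LPs over the raw constraint data
oracle_blocked <- function(model, eps = 1e-7) {
  n <- length(model$rxn_ids)
  sense <- rep("=", nrow(model$S))
  rhs <- rep(0, nrow(model$S))
  blocked <- character()
  for (rid in model$rxn_ids) {
    cvec <- stats::setNames(rep(0, n), model$rxn_ids)
    cvec[rid] <- 1
    hi <- lp_solve(cvec, model$S, rhs, sense, model$lb, model$ub, maximize = TRUE)
    lo <- lp_solve(cvec, model$S, rhs, sense, model$lb, model$ub, maximize = FALSE)
    if (hi$status == "optimal" && lo$status == "optimal" &&
        abs(hi$objval) <= eps && abs(lo$objval) <= eps) {
      blocked <- c(blocked, rid)
    }
  }
  blocked
}

# deletion oracle: is every scenario still feasible with reaction fixed to 0?
oracle_deletion_feasible <- function(model, spec, rxn) {
  trial <- model
  trial$lb[rxn] <- 0
  trial$ub[rxn] <- 0
  scens <- if (length(spec$scenarios)) spec$scenarios else list(scenario("base"))
  for (sc in scens) {
    r <- fva(trial, reactions = model$rxn_ids[1], scenario = sc)
    if (any(r$status != "optimal")) return(FALSE)
  }
  TRUE
}

# pairwise FVA-fixing subset oracle: reactions i, j are coupled with
# ratio rho iff fixing r_i = s (s = +1 or -1, whichever is feasible)
# collapses r_j's range to the single point s * rho
oracle_subset_partner <- function(model, i, j, eps = 1e-6) {
  for (s in c(1, -1)) {
    trial <- model
    trial$lb[i] <- s
    trial$ub[i] <- s
    rng <- fva(trial, reactions = j)
    if (any(rng$status != "optimal")) next
    if (rng$hi - rng$lo > eps) return(NA_real_)  # feasible but not coupled
    return(s * (rng$hi + rng$lo) / 2)
  }
  NA_real_
}

# random protection spec for a random network: protect one uptake and
# one export exchange, demand near-maximal flux through the export
random_spec <- function(model, frac = 0.999) {
  ex <- model$rxn_ids[startsWith(model$rxn_ids, "EX")]
  upt <- ex[colSums(model$S[, ex, drop = FALSE]) > 0]
  exp <- ex[colSums(model$S[, ex, drop = FALSE]) < 0]
  # pick the export with the largest attainable flux
  best <- NULL; best_v <- 0
  for (e in exp) {
    v <- fba(model, objective = e)$objval
    if (!is.na(v) && v > best_v) { best <- e; best_v <- v }
  }
  if (is.null(best) || best_v < 1e-6) return(NULL)
  protection_spec(
    protected_reactions = c(upt[1], best),
    scenarios = list(scenario("max_product",
      sprintf("-%s <= -%.17g", best, frac * best_v))),
    dof_min = 1, n_min = 1, model = model)
}
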