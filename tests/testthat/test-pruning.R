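# The pruning loop and its specification checks.

test_that("preprocess validates protected functions and strips blocked reactions", {
  # chain plus an unprotected dead end
  st <- tibble::tibble(
    metabolite = c("A", "A", "B", "B", "A", "X"),
    reaction = c("R_up", "R_ab", "R_ab", "R_out", "R_dead", "R_dead"),
    coefficient = c(1, -1, 1, -1, -1, 1))
  bd <- tibble::tibble(reaction = unique(st$reaction), lb = 0, ub = 10)
  m <- metabolic_model(st, bd)

  spec <- protection_spec(protected_reactions = c("R_up", "R_out"), model = m)
  prep <- preprocess(m, spec)
  expect_false("R_dead" %in% prep$model$rxn_ids)
  expect_false("X" %in% prep$model$met_ids)     # unconnected metabolite gone
  expect_equal(prep$log$action, "blocked")

  # infeasible protected function errors, naming the scenario
  bad <- protection_spec(
    scenarios = list(scenario("impossible", "R_out >= 99")), model = m)
  expect_error(preprocess(m, bad), "impossible")

  # protected-but-blocked reaction with enforcement errors
  bad2 <- protection_spec(protected_reactions = "R_dead",
                          enforce_protected_feasibility = TRUE, model = m)
  expect_error(preprocess(m, bad2), "can never carry flux")
})

test_that("sign-definite ranges mark reactions essential and imply deletion infeasibility", {
  # direct contract
  tab <- tibble::tibble(
    reaction = c("a", "a", "b", "b"), scenario = rep(c("s1", "s2"), 2),
    lo = c(0.2, -1, -1, -2), hi = c(5, 3, 3, 2),
    capped_lo = FALSE, capped_hi = FALSE, status = "optimal")
  expect_equal(classify_essential(tab), "a")

  # random networks: essential => deleting the reaction breaks a scenario
  set.seed(41)
  n_essential <- 0
  for (s in 1:10) {
    m <- random_network(n_metabolites = 6, n_reactions = 8, n_exchanges = 4,
                        seed = 3000 + s)
    spec <- random_spec(m)
    if (is.null(spec)) next
    tab <- flux_range_table(m, spec)
    for (rid in classify_essential(tab)) {
      n_essential <- n_essential + 1
      expect_false(oracle_deletion_feasible(m, spec, rid),
                   info = sprintf("seed %d reaction %s", 3000 + s, rid))
    }
  }
  expect_gt(n_essential, 5)
})

test_that("candidate selection takes the smallest union width with configurable ties", {
  ut <- tibble::tibble(reaction = c("R1", "R2"), width = c(0, 3.2),
                       n_capped = 0L)
  expect_equal(select_candidate(ut, c("R1", "R2")), "R1")
  expect_null(select_candidate(ut, character()))

  # capped ranges lose against equal finite width with fewer capped ends
  ut2 <- tibble::tibble(reaction = c("Ra", "Rb"), width = c(2, 2),
                        n_capped = c(2L, 0L))
  expect_equal(select_candidate(ut2, c("Ra", "Rb")), "Rb")

  # ties: lowest-index rule is deterministic, random rule covers both
  ut3 <- tibble::tibble(reaction = c("Rz", "Ra"), width = 1, n_capped = 0L)
  expect_equal(select_candidate(ut3, ut3$reaction, tie_rule = "lowest_index"),
               "Ra")
  picks <- vapply(1:20, function(i) {
    set.seed(i)
    select_candidate(ut3, ut3$reaction, tie_rule = "random")
  }, "")
  expect_setequal(unique(picks), c("Ra", "Rz"))
})

test_that("try_delete accepts redundant paths and rejects protected lifelines", {
  toy <- build_toy("diamond")
  # one of two parallel paths is redundant
  td <- try_delete(toy$model, toy$spec, "R_a1")
  expect_true(td$accepted)
  expect_false("R_a1" %in% td$model$rxn_ids)
  # the input model is untouched on acceptance and rejection alike
  expect_true("R_a1" %in% toy$model$rxn_ids)

  # deleting the only oxygen supply of an aerobic phenotype is rejected
  ox <- build_toy("oxidase_pair")
  spec_o2 <- protection_spec(
    protected_reactions = "R_bio_exp",
    scenarios = ox$spec$scenarios, dof_min = 1, n_min = 1, model = ox$model)
  td2 <- try_delete(ox$model, spec_o2, "R_O2_up")
  expect_false(td2$accepted)
  expect_match(td2$reason, "scenario")

  # a deletion that would push n below n_min is rejected
  m <- chain_model()
  spec_n <- protection_spec(protected_reactions = c("R_up", "R_out"),
                            n_min = 4, model = m)
  expect_false(try_delete(m, spec_n, "R_ab")$accepted)
  expect_error(try_delete(m, spec_n, "R_up"), "protected")
})

test_that("diamond pruning reaches the 4-reaction fixed point for every seed", {
  toy <- build_toy("diamond")
  # independent oracle: exhaustive search over all deletion orders
  terminal_sizes <- local({
    seen <- new.env()
    sizes <- integer()
    explore <- function(model) {
      key <- paste(sort(model$rxn_ids), collapse = ",")
      if (!is.null(seen[[key]])) return(invisible())
      assign(key, TRUE, envir = seen)
      removable <- setdiff(model$rxn_ids, toy$spec$protected_reactions)
      any_accepted <- FALSE
      for (r in removable) {
        td <- try_delete(model, toy$spec, r)
        if (td$accepted) {
          any_accepted <- TRUE
          explore(td$model)
        }
      }
      if (!any_accepted) sizes <<- c(sizes, length(model$rxn_ids))
      invisible()
    }
    explore(toy$model)
    sizes
  })
  expect_true(all(terminal_sizes == 4L))

  for (s in 0:6) {
    pr <- prune(toy$model, toy$spec, seed = s)
    expect_equal(length(pr$model$rxn_ids), 4L, info = sprintf("seed %d", s))
    expect_true(all(c("R_in", "R_out") %in% pr$model$rxn_ids))
  }
})

test_that("pruning is idempotent on a network equal to its protected core", {
  toy <- build_toy("diamond")
  pr <- prune(toy$model, toy$spec, seed = 0)
  spec2 <- protection_spec(
    protected_reactions = toy$spec$protected_reactions,
    scenarios = list(scenario("max_export",
                              "-R_out <= -0.999 * FBA_MAX(R_out)")),
    dof_min = 1, n_min = 1, model = pr$model)
  pr2 <- prune(pr$model, spec2, seed = 0)
  expect_equal(pr2$model$rxn_ids, pr$model$rxn_ids)
  expect_equal(pr2$model$S, pr$model$S)
  expect_equal(sum(pr2$log$action == "removed"), 0)
})

test_that("identical inputs and seed give identical removal logs", {
  toy <- build_toy("worked_example")
  a <- prune(toy$model, toy$spec, seed = 3)
  b <- prune(toy$model, toy$spec, seed = 3)
  expect_identical(a$log, b$log)
  expect_identical(a$model$rxn_ids, b$model$rxn_ids)
})

test_that("pruned models are proper subnetworks preserving scenario optima", {
  set.seed(61)
  n_done <- 0
  for (s in 1:8) {
    m <- random_network(n_metabolites = 6, n_reactions = 8, n_exchanges = 4,
                        seed = 4000 + s)
    spec <- random_spec(m)
    if (is.null(spec)) next
    pr <- tryCatch(prune(m, spec, seed = s), error = function(e) NULL)
    if (is.null(pr)) next
    n_done <- n_done + 1
    p <- pr$model
    # subnetwork: columns are copies of the full model's columns
    expect_true(all(p$rxn_ids %in% m$rxn_ids))
    expect_equal(p$S, m$S[rownames(p$S), p$rxn_ids, drop = FALSE])
    expect_true(all(spec$protected_reactions %in% p$rxn_ids))
    # sizes and dof never increase
    expect_lte(length(p$rxn_ids), length(m$rxn_ids))
    expect_lte(dof(p), dof(m))
    # zero-padded pruned flux vectors satisfy the full model
    sc <- spec$scenarios[[1]]
    for (rid in sample(p$rxn_ids, min(3, length(p$rxn_ids)))) {
      opt <- fba(p, objective = rid, scenario = sc)
      if (opt$status != "optimal") next
      r_full <- stats::setNames(rep(0, length(m$rxn_ids)), m$rxn_ids)
      r_full[names(opt$flux)] <- opt$flux
      expect_lt(max(abs(m$S %*% r_full)), 1e-6)
      expect_true(all(r_full >= m$lb - 1e-6 & r_full <= m$ub + 1e-6))
    }
    # the protected near-maximal product flux is still attainable
    prod_rxn <- spec$protected_reactions[2]
    full_opt <- fba(m, objective = prod_rxn)$objval
    pruned_opt <- fba(p, objective = prod_rxn)$objval
    expect_gte(pruned_opt, 0.999 * full_opt - 1e-6)
  }
  expect_gte(n_done, 5)
})
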