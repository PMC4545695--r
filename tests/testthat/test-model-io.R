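# Model container, TSV and SBML I/O, protection specifications.

test_that("data-frame constructor builds and validates a model", {
  m <- chain_model()
  expect_s3_class(m, "metabolic_model")
  expect_equal(dim(m$S), c(3L, 4L))
  expect_equal(unname(m$ub["R_up"]), 10)

  # duplicate (metabolite, reaction) entries are ambiguous -> error
  st <- tibble::tibble(metabolite = c("A", "A"), reaction = c("R1", "R1"),
                       coefficient = c(-1, 1))
  bd <- tibble::tibble(reaction = "R1", lb = 0, ub = 1)
  expect_error(metabolic_model(st, bd), "duplicate")

  # empty stoichiometry is an error, not an empty model
  expect_error(metabolic_model(st[0, ], bd), "empty")

  # bounds for an unknown reaction
  st2 <- tibble::tibble(metabolite = c("A", "B"), reaction = "R1",
                        coefficient = c(-1, 1))
  bd2 <- tibble::tibble(reaction = c("R1", "R9"), lb = 0, ub = 1)
  expect_error(metabolic_model(st2, bd2), "unknown reaction")

  # lb > ub rejected
  expect_error(metabolic_model(st2, tibble::tibble(reaction = "R1", lb = 2, ub = 1)),
               "lower bound")

  # minimal 2x1 model from triples
  m2 <- metabolic_model(st2, tibble::tibble(reaction = "R1", lb = 0, ub = 5))
  expect_equal(dim(m2$S), c(2L, 1L))
})

test_that("TSV round trip preserves stoichiometry, bounds and objective", {
  m <- build_toy("trace_element")$model
  sp <- withr::local_tempfile(fileext = ".tsv")
  bp <- withr::local_tempfile(fileext = ".tsv")
  write_tsv_model(m, sp, bp)
  m2 <- read_tsv_model(sp, bp)
  expect_setequal(m2$rxn_ids, m$rxn_ids)
  expect_setequal(m2$met_ids, m$met_ids)
  expect_equal(m2$ext_ids, m$ext_ids)  # TE_ext preserved as external
  expect_equal(m2$S[m$met_ids, m$rxn_ids], m$S)
  expect_equal(m2$lb[m$rxn_ids], m$lb)
  expect_equal(m2$ub[m$rxn_ids], m$ub)
  expect_equal(m2$obj[m$rxn_ids], m$obj)
})

test_that("SBML write/read round trip is the identity", {
  for (toy in c("worked_example", "oxidase_pair", "trace_element",
                "cycle_unbounded")) {
    m <- build_toy(toy)$model
    f <- withr::local_tempfile(fileext = ".xml")
    write_sbml(m, f)
    m2 <- read_sbml(f)
    expect_equal(m2$rxn_ids, m$rxn_ids, info = toy)
    expect_equal(m2$S[m$met_ids, ], m$S, info = toy)
    expect_equal(m2$S_ext[m$ext_ids, , drop = FALSE], m$S_ext, info = toy)
    expect_equal(m2$lb, m$lb, info = toy)
    expect_equal(m2$ub, m$ub, info = toy)   # includes Inf round trip
    expect_equal(m2$obj, m$obj, info = toy)
  }
})

test_that("SBML reader enforces the boundary and bounds conventions", {
  # fixture: 3 internal metabolites, 4 reactions, one boundary species
  m <- chain_model()
  # mark C as boundary by writing it external
  st <- tidy(m)
  st$metabolite[st$metabolite == "C"] <- "C_b"
  m_ext <- metabolic_model(st[, 1:3],
                           tibble::tibble(reaction = m$rxn_ids,
                                          lb = unname(m$lb), ub = unname(m$ub),
                                          objective = unname(m$obj)),
                           externals = "C_b")
  f <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m_ext, f)
  m2 <- read_sbml(f)
  expect_equal(sort(m2$met_ids), c("A", "B"))
  expect_equal(m2$ext_ids, "C_b")  # boundary species not a row of S

  # a reaction without flux bounds must error, never default silently
  txt <- readLines(f)
  txt <- gsub(' fbc:lowerFluxBound="[^"]*"', "", txt)
  txt <- gsub(' fbc:upperFluxBound="[^"]*"', "", txt)
  f2 <- withr::local_tempfile(fileext = ".xml")
  writeLines(txt, f2)
  expect_error(read_sbml(f2), "no flux bounds")

  # parse failure names the file
  f3 <- withr::local_tempfile(fileext = ".xml")
  writeLines("<sbml><model></sbml>", f3)
  expect_error(read_sbml(f3), "parse failure")
})

test_that("constraint strings parse to normalised <= rows", {
  sc <- scenario("s", c("R1 <= 10", "2*R2 - R1 >= 4", "R3 = 1"))
  expect_length(sc$constraints, 4L)  # equality expands to two rows
  expect_equal(sc$constraints[[1]]$coef, c(R1 = 1))
  expect_equal(sc$constraints[[1]]$rhs, 10)
  expect_equal(sc$constraints[[2]]$coef, c(R2 = -2, R1 = 1))
  expect_equal(sc$constraints[[2]]$rhs, -4)
  expect_equal(sc$constraints[[3]]$coef, c(R3 = 1))
  expect_equal(sc$constraints[[4]]$coef, c(R3 = -1))

  expect_error(scenario("s", "R1 + 2"), "relation")
  expect_error(scenario("s", "R1 * R2 <= 1"), "coefficient|identifier")
})

test_that("protection specs validate, resolve FBA_MAX, and read from YAML", {
  m <- chain_model()
  # FBA_MAX resolved against the full model: max export = 10
  spec <- protection_spec(
    protected_reactions = c("R_up", "R_out"),
    scenarios = list(scenario("opt", "-R_out <= -0.5 * FBA_MAX(R_out)")),
    dof_min = 1, n_min = 1, model = m)
  row <- spec$scenarios[[1]]$constraints[[1]]
  expect_equal(row$rhs, -5)  # -0.5 * 10
  expect_named(attr(spec$scenarios[[1]], "resolutions"), "opt:R_out")

  # unknown IDs are rejected at load time
  expect_error(protection_spec(protected_reactions = "nope", model = m),
               "unknown protected reaction")
  expect_error(protection_spec(protected_metabolites = "nope", model = m),
               "unknown protected metabolite")
  expect_error(
    protection_spec(scenarios = list(scenario("s", "ghost <= 1")), model = m),
    "unknown reaction")

  # boundary values: dof_min = 0 is the documented no-op, negatives rejected
  expect_silent(protection_spec(dof_min = 0, model = m))
  expect_error(protection_spec(dof_min = -1), "dof_min")
  expect_error(protection_spec(n_min = 0), "n_min")

  # empty spec is valid (pruning then subject only to dof_min/n_min)
  empty <- protection_spec(model = m)
  expect_length(empty$scenarios, 0L)

  # YAML round trip with bound overrides and two scenarios
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "protected_reactions: [R_up, R_out]",
    "enforce_protected_feasibility: true",
    "dof_min: 1",
    "n_min: 1",
    "scenarios:",
    "  - name: aerobic",
    "    constraints:",
    "      - 'R_up <= 10'",
    "      - '-R_out <= -0.999 * FBA_MAX(R_out)'",
    "  - name: capped",
    "    constraints: ['R_out <= 3']",
    "    bound_overrides:",
    "      R_up: [0, 3]"), f)
  spec2 <- read_protection_spec(f, m)
  expect_length(spec2$scenarios, 2L)
  expect_true(spec2$enforce_protected_feasibility)
  expect_equal(spec2$scenarios[[2]]$bound_overrides$R_up, c(0, 3))
  expect_equal(spec2$scenarios[[1]]$constraints[[2]]$rhs, -0.999 * 10)
})

test_that("biomass tracker transform adds species and export explicitly", {
  m <- chain_model()
  m2 <- add_biomass_tracker(m, "R_bc", tracker_id = "bm")
  expect_true("bm" %in% m2$met_ids)
  expect_true("R_bc_export" %in% m2$rxn_ids)
  expect_equal(unname(m2$S["bm", "R_bc"]), 1)
  expect_equal(unname(m2$S["bm", "R_bc_export"]), -1)
  # original model untouched, transform is explicit
  expect_false("bm" %in% m$met_ids)
  expect_error(add_biomass_tracker(m, "nope"), "unknown biomass reaction")
})
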