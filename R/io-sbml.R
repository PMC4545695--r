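## SBML read/write. Level 3 Version 1 with the fbc (version 2) package
## is the primary dialect: flux bounds are fbc parameter references and
## the objective is the active fbc objective. A Level 2 fallback reads
## the older COBRA convention (kineticLaw parameters LOWER_BOUND /
## UPPER_BOUND / OBJECTIVE_COEFFICIENT). Species with
## boundaryCondition="true" become external; everything else is a
## balanced row of the stoichiometric matrix.

SBML_CORE_NS <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

#' Read a metabolic model from SBML
#'
#' @param path SBML file (Level 3 + fbc v2, or Level 2 with COBRA-style
#'   kineticLaw bound parameters).
#' @return a `metabolic_model`. Boundary-condition species are recorded
#'   as external and are not rows of the balanced matrix. Missing flux
#'   bounds are an error, never a silent default.
#' @export
read_sbml <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse failure in '", path,
                                           "': ", conditionMessage(e)))
  root <- xml2::xml_name(doc)
  if (root != "sbml") stop("not an SBML document (root element <", root, ">)")
  level <- xml2::xml_attr(doc, "level")
  model_node <- xml_child_ln(doc, "model")
  if (is.na(level) || is.null(model_node)) stop("SBML document has no <model>")

  species <- xml_all_ln(model_node, "listOfSpecies", "species")
  if (length(species) == 0L) stop("SBML model contains no species")
  sp_id <- vapply(species, xml2::xml_attr, "", attr = "id")
  sp_bc <- vapply(species, xml2::xml_attr, "", attr = "boundaryCondition")
  sp_comp <- vapply(species, xml2::xml_attr, "", attr = "compartment")
  is_ext <- !is.na(sp_bc) & sp_bc == "true"

  params <- xml_all_ln(model_node, "listOfParameters", "parameter")
  par_val <- stats::setNames(
    vapply(params, function(p) parse_sbml_double(xml2::xml_attr(p, "value")), 0),
    vapply(params, xml2::xml_attr, "", attr = "id"))

  reactions <- xml_all_ln(model_node, "listOfReactions", "reaction")
  if (length(reactions) == 0L) stop("SBML model contains no reactions")
  rx_id <- vapply(reactions, xml2::xml_attr, "", attr = "id")

  triples <- list()
  lb <- ub <- obj <- stats::setNames(rep(NA_real_, length(rx_id)), rx_id)
  for (i in seq_along(reactions)) {
    rxn <- reactions[[i]]
    for (ref in xml_all_ln(rxn, "listOfReactants", "speciesReference")) {
      triples[[length(triples) + 1L]] <- tibble::tibble(
        metabolite = xml2::xml_attr(ref, "species"), reaction = rx_id[i],
        coefficient = -parse_sbml_double(xml2::xml_attr(ref, "stoichiometry") %||% "1"))
    }
    for (ref in xml_all_ln(rxn, "listOfProducts", "speciesReference")) {
      triples[[length(triples) + 1L]] <- tibble::tibble(
        metabolite = xml2::xml_attr(ref, "species"), reaction = rx_id[i],
        coefficient = parse_sbml_double(xml2::xml_attr(ref, "stoichiometry") %||% "1"))
    }
    at <- xml2::xml_attrs(rxn)
    lb_ref <- attr_get(at, "lowerFluxBound")
    ub_ref <- attr_get(at, "upperFluxBound")
    if (!is.na(lb_ref) && !is.na(ub_ref)) {
      if (!lb_ref %in% names(par_val) || !ub_ref %in% names(par_val)) {
        stop("reaction '", rx_id[i], "' references undefined bound parameter '",
             if (lb_ref %in% names(par_val)) ub_ref else lb_ref, "'")
      }
      lb[i] <- par_val[[lb_ref]]
      ub[i] <- par_val[[ub_ref]]
    } else {
      ## Level 2 fallback: kineticLaw parameters
      kl <- xml_all_ln(rxn, "kineticLaw", "listOfParameters", "parameter")
      if (length(kl)) {
        kl_id <- vapply(kl, xml2::xml_attr, "", attr = "id")
        kl_v <- vapply(kl, function(p) parse_sbml_double(xml2::xml_attr(p, "value")), 0)
        if ("LOWER_BOUND" %in% kl_id) lb[i] <- kl_v[kl_id == "LOWER_BOUND"][1]
        if ("UPPER_BOUND" %in% kl_id) ub[i] <- kl_v[kl_id == "UPPER_BOUND"][1]
        if ("OBJECTIVE_COEFFICIENT" %in% kl_id) {
          obj[i] <- kl_v[kl_id == "OBJECTIVE_COEFFICIENT"][1]
        }
      }
    }
    if (is.na(lb[i]) || is.na(ub[i])) {
      stop("reaction '", rx_id[i], "' has no flux bounds ",
           "(fbc attributes or kineticLaw parameters required; ",
           "refusing to guess defaults)")
    }
  }

  ## fbc objective (overrides any L2 objective coefficients)
  fbc_obj <- xml2::xml_find_all(
    model_node, ".//*[local-name() = 'fluxObjective']")
  if (length(fbc_obj)) {
    obj[] <- 0
    for (fo in fbc_obj) {
      at <- xml2::xml_attrs(fo)
      rid <- attr_get(at, "reaction")
      co <- parse_sbml_double(attr_get(at, "coefficient", default = "1"))
      if (!rid %in% rx_id) stop("fluxObjective references unknown reaction '", rid, "'")
      obj[rid] <- co
    }
  }
  obj[is.na(obj)] <- 0

  stoich <- dplyr::bind_rows(triples)
  if (anyDuplicated(stoich[c("metabolite", "reaction")])) {
    ## same species both reactant and product: sum to a net coefficient
    stoich <- stoich |>
      dplyr::group_by(.data$metabolite, .data$reaction) |>
      dplyr::summarise(coefficient = sum(.data$coefficient), .groups = "drop") |>
      dplyr::filter(.data$coefficient != 0)
  }
  comp <- stats::setNames(sp_comp, sp_id)
  metabolic_model(stoich,
                  tibble::tibble(reaction = rx_id, lb = as.numeric(lb),
                                 ub = as.numeric(ub), objective = as.numeric(obj)),
                  externals = sp_id[is_ext],
                  compartments = comp)
}

## attribute lookup tolerant of namespace prefixes (xml2 strips known
## prefixes from attribute names; tolerate both forms)
attr_get <- function(at, name, default = NA_character_) {
  for (k in c(name, paste0("fbc:", name))) {
    if (k %in% names(at)) return(at[[k]])
  }
  default
}

## namespace-agnostic child lookup helpers
xml_child_ln <- function(node, name) {
  hit <- xml2::xml_find_first(node, paste0("./*[local-name() = '", name, "']"))
  if (inherits(hit, "xml_missing")) NULL else hit
}
xml_all_ln <- function(node, ...) {
  path <- paste(vapply(list(...), function(nm)
    paste0("*[local-name() = '", nm, "']"), ""), collapse = "/")
  xml2::xml_find_all(node, paste0("./", path))
}

parse_sbml_double <- function(s) {
  if (is.null(s) || is.na(s)) return(NA_real_)
  if (s %in% c("INF", "inf", "Inf")) return(Inf)
  if (s %in% c("-INF", "-inf", "-Inf")) return(-Inf)
  v <- suppressWarnings(as.numeric(s))
  if (is.na(v)) stop("non-numeric value in SBML: '", s, "'")
  v
}

#' Write a metabolic model to SBML (Level 3 + fbc v2)
#'
#' Bounds become shared fbc parameters (infinities written as
#' `INF`/`-INF`), external species get `boundaryCondition="true"`, and a
#' nonzero objective becomes the active fbc objective. `read_sbml()` of
#' the output reproduces the model exactly.
#'
#' @param model a `metabolic_model`.
#' @param path output file.
#' @param model_id SBML model id.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path, model_id = "model") {
  fmt_num <- function(x) {
    if (x == Inf) "INF" else if (x == -Inf) "-INF"
    else format(x, digits = 17, scientific = FALSE, trim = TRUE)
  }
  comp_of <- function(met) {
    cp <- model$compartments
    if (!is.null(cp) && met %in% names(cp) && !is.na(cp[[met]]) && nzchar(cp[[met]])) {
      cp[[met]]
    } else "c"
  }
  all_comps <- unique(vapply(c(model$met_ids, model$ext_ids), comp_of, ""))

  ## shared bound parameters, deduplicated by value
  vals <- sort(unique(c(model$lb, model$ub)))
  pid <- stats::setNames(sprintf("bnd_%d", seq_along(vals) - 1L), vapply(vals, fmt_num, ""))

  doc <- xml2::xml_new_root("sbml",
    xmlns = SBML_CORE_NS, "xmlns:fbc" = SBML_FBC_NS,
    level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = model_id, "fbc:strict" = "true")

  lc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cp in all_comps) {
    xml2::xml_add_child(lc, "compartment", id = cp, constant = "true")
  }
  ls <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (met in model$met_ids) {
    xml2::xml_add_child(ls, "species", id = met, compartment = comp_of(met),
                        boundaryCondition = "false",
                        hasOnlySubstanceUnits = "false", constant = "false")
  }
  for (met in model$ext_ids) {
    xml2::xml_add_child(ls, "species", id = met, compartment = comp_of(met),
                        boundaryCondition = "true",
                        hasOnlySubstanceUnits = "false", constant = "false")
  }
  lp <- xml2::xml_add_child(mdl, "listOfParameters")
  for (k in seq_along(vals)) {
    xml2::xml_add_child(lp, "parameter", id = pid[[k]],
                        value = fmt_num(vals[k]), constant = "true")
  }
  lr <- xml2::xml_add_child(mdl, "listOfReactions")
  for (rid in model$rxn_ids) {
    col <- c(stats::setNames(model$S[, rid], rownames(model$S)),
             stats::setNames(model$S_ext[, rid], rownames(model$S_ext)))
    rxn <- xml2::xml_add_child(lr, "reaction", id = rid,
      reversible = if (model$lb[rid] < 0) "true" else "false",
      fast = "false",
      "fbc:lowerFluxBound" = pid[[fmt_num(model$lb[rid])]],
      "fbc:upperFluxBound" = pid[[fmt_num(model$ub[rid])]])
    subs <- col[col < 0]
    prods <- col[col > 0]
    if (length(subs)) {
      lref <- xml2::xml_add_child(rxn, "listOfReactants")
      for (met in names(subs)) {
        xml2::xml_add_child(lref, "speciesReference", species = met,
                            stoichiometry = fmt_num(-subs[[met]]),
                            constant = "true")
      }
    }
    if (length(prods)) {
      lref <- xml2::xml_add_child(rxn, "listOfProducts")
      for (met in names(prods)) {
        xml2::xml_add_child(lref, "speciesReference", species = met,
                            stoichiometry = fmt_num(prods[[met]]),
                            constant = "true")
      }
    }
  }
  if (any(model$obj != 0)) {
    lo <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                              "fbc:activeObjective" = "obj")
    ob <- xml2::xml_add_child(lo, "fbc:objective", "fbc:id" = "obj",
                              "fbc:type" = "maximize")
    lf <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
    for (rid in model$rxn_ids[model$obj != 0]) {
      xml2::xml_add_child(lf, "fbc:fluxObjective", "fbc:reaction" = rid,
                          "fbc:coefficient" = fmt_num(model$obj[rid]))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
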