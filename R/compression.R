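## Loss-free network compression: lump enzyme subsets (reactions whose
## steady-state fluxes are always proportional) into single overall
## reactions, excluding protected elements, and derive the condensed
## biomass synthesis reaction.

#' Detect enzyme subsets
#'
#' Two reactions belong to one enzyme subset when their rows in a kernel
#' (null-space) basis of the stoichiometric matrix are proportional:
#' their steady-state fluxes are then coupled by a fixed ratio in every
#' feasible flux distribution. Detection is a single null-space
#' computation (SVD) followed by row clustering; protected reactions are
#' never members of a multi-reaction subset, reactions with an all-zero
#' kernel row (blocked) stay singletons, and a candidate subset whose
#' member flux ratios are incompatible with the member bounds (an
#' irreversible reaction forced backward, with no nonzero common flux)
#' is split back into singletons.
#'
#' @param model a `metabolic_model`.
#' @param spec a [protection_spec()] or `NULL` (nothing protected).
#' @param eps_rank relative tolerance for the null-space computation and
#'   for row proportionality.
#' @return a tibble (the subset map) with columns `lumped_id`,
#'   `member_id`, `ratio` (flux of the member per unit flux of the
#'   representative) and `representative` (logical). Singleton reactions
#'   map to themselves with ratio 1.
#' @export
detect_subsets <- function(model, spec = NULL, eps_rank = 1e-9) {
  n <- length(model$rxn_ids)
  prot <- if (is.null(spec)) character() else spec$protected_reactions
  K <- kernel_basis(model$S, eps_rank)
  groups <- rep(NA_integer_, n)
  scale <- rep(1, n)
  if (ncol(K) > 0L) {
    norms <- sqrt(rowSums(K^2))
    nz <- which(norms > eps_rank * max(norms, 1))
    ## normalise each row to unit length with the first significant
    ## component positive; equal rows = proportional fluxes
    sig <- matrix(0, length(nz), ncol(K))
    sgn <- rep(1, length(nz))
    for (ii in seq_along(nz)) {
      v <- K[nz[ii], ] / norms[nz[ii]]
      lead <- which(abs(v) > 1e-7)[1]
      if (!is.na(lead) && v[lead] < 0) { v <- -v; sgn[ii] <- -1 }
      sig[ii, ] <- v
    }
    ## cluster by proximity of signature rows
    gid <- rep(NA_integer_, length(nz))
    next_g <- 0L
    for (ii in seq_along(nz)) {
      if (!is.na(gid[ii])) next
      next_g <- next_g + 1L
      gid[ii] <- next_g
      if (ii < length(nz)) {
        rest <- (ii + 1L):length(nz)
        d <- sqrt(rowSums((sig[rest, , drop = FALSE] -
                             matrix(sig[ii, ], length(rest), ncol(sig),
                                    byrow = TRUE))^2))
        hit <- rest[is.na(gid[rest]) & d < 1e-6]
        gid[hit] <- next_g
      }
    }
    groups[nz] <- gid
    scale[nz] <- sgn * norms[nz]
  }
  ## protected reactions and kernel-zero reactions are singletons
  out <- vector("list", 0L)
  used <- rep(FALSE, n)
  for (g in stats::na.omit(unique(groups))) {
    mem <- which(groups == g & !(model$rxn_ids %in% prot))
    if (length(mem) < 2L) next
    ## representative: largest stoichiometric support, ties lowest index
    supp <- colSums(model$S[, mem, drop = FALSE] != 0) +
      colSums(model$S_ext[, mem, drop = FALSE] != 0)
    rep_i <- mem[order(-supp, mem)[1]]
    ratio <- snap_rational(scale[mem] / scale[rep_i])
    ## sign/bound compatibility: the lump must admit some nonzero flux,
    ## otherwise the implied ratios force an irreversible member backward
    ## and the subset is split (members stay singletons)
    iv <- lump_interval(model$lb[mem], model$ub[mem], ratio)
    if (is.null(iv) || (abs(iv[1]) < 1e-12 && abs(iv[2]) < 1e-12)) next
    lump_id <- lump_name(model$rxn_ids[mem])
    out[[length(out) + 1L]] <- tibble::tibble(
      lumped_id = lump_id,
      member_id = model$rxn_ids[mem],
      ratio = ratio,
      representative = mem == rep_i)
    used[mem] <- TRUE
  }
  singles <- which(!used)
  map <- dplyr::bind_rows(c(out, list(tibble::tibble(
    lumped_id = model$rxn_ids[singles],
    member_id = model$rxn_ids[singles],
    ratio = rep(1, length(singles)),
    representative = rep(TRUE, length(singles))))))
  ## preserve model reaction order for singletons, subsets appended stably
  map[order(match(map$member_id, model$rxn_ids)), ]
}

## Stoichiometries are rational, so exact flux-coupling ratios are
## rational too; the SVD-derived estimates carry float dust. Snap each
## ratio to the nearest small-denominator rational (continued fractions)
## when it is within tolerance, else keep the float.
snap_rational <- function(x, tol = 1e-7, max_den = 1000L) {
  vapply(x, function(v) {
    if (!is.finite(v)) return(v)
    s <- sign(v)
    a <- abs(v)
    ## continued-fraction convergents
    p0 <- 0; q0 <- 1; p1 <- 1; q1 <- 0; r <- a
    for (it in 1:30) {
      ai <- floor(r)
      p2 <- ai * p1 + p0; q2 <- ai * q1 + q0
      if (q2 > max_den) break
      p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
      if (abs(a - p1 / q1) < tol * max(1, a)) return(s * p1 / q1)
      frac <- r - ai
      if (frac < 1e-12) break
      r <- 1 / frac
    }
    v
  }, numeric(1))
}

## feasible interval of the lump flux t given member bounds and ratios
## (member flux = ratio * t); NULL when empty
lump_interval <- function(lb, ub, ratio) {
  lo <- -Inf
  hi <- Inf
  for (j in seq_along(ratio)) {
    if (ratio[j] > 0) {
      lo <- max(lo, lb[j] / ratio[j])
      hi <- min(hi, ub[j] / ratio[j])
    } else {
      lo <- max(lo, ub[j] / ratio[j])
      hi <- min(hi, lb[j] / ratio[j])
    }
  }
  if (lo > hi + 1e-12) NULL else c(lo, hi)
}

## lumped reaction ID: members joined by "*", capped at 60 chars with a
## short deterministic hash suffix (full membership lives in the map)
lump_name <- function(members) {
  nm <- paste(members, collapse = "*")
  if (nchar(nm) <= 60L) return(nm)
  h <- 5381
  for (cp in utf8ToInt(nm)) h <- (h * 33 + cp) %% 2147483647
  paste0(substr(nm, 1L, 53L), "~", sprintf("%06x", h %% 16777216))
}

#' Loss-free compression of a metabolic network
#'
#' Replaces every detected enzyme subset by one lumped overall reaction
#' whose stoichiometric column is the ratio-weighted sum of the member
#' columns (\eqn{S_c = S\,T}), removes internal metabolites whose rows
#' become all-zero (they were interior to a lumped chain), and carries
#' external-species stoichiometry through the same transformation so
#' that e.g. a trace-element uptake collapsed into the biomass reaction
#' stays visible. Bounds of a lumped reaction are the tightest implied
#' by the member bounds scaled by their ratios; the objective transforms
#' as \eqn{c_c = T^T c}, so every FBA optimum is preserved exactly.
#' Protected reactions are never lumped and protected metabolites are
#' never deleted, even when their row becomes zero. Compression changes
#' neither the degrees of freedom nor the feasible flux space.
#'
#' @param model a `metabolic_model` (typically pruned first).
#' @param spec a [protection_spec()] or `NULL`.
#' @param eps zero tolerance for row elimination.
#' @return an object of class `compressed_model`: `model` (the
#'   compressed `metabolic_model`), `subsets` (the subset-map tibble of
#'   [detect_subsets()]), `T` (the `n_in x n_out` transformation matrix
#'   with `S_out = S_in T` before zero-row deletion), and
#'   `eliminated_metabolites`.
#' @export
compress <- function(model, spec = NULL, eps = 1e-10) {
  map <- detect_subsets(model, spec)
  lump_ids <- unique(map$lumped_id)
  n <- length(model$rxn_ids)
  TT <- matrix(0, n, length(lump_ids),
               dimnames = list(model$rxn_ids, lump_ids))
  TT[cbind(map$member_id, map$lumped_id)] <- map$ratio
  S_c <- model$S %*% TT
  S_ext_c <- model$S_ext %*% TT
  S_c[abs(S_c) < eps] <- 0
  S_ext_c[abs(S_ext_c) < eps] <- 0

  lb_c <- ub_c <- stats::setNames(numeric(length(lump_ids)), lump_ids)
  for (lid in lump_ids) {
    rows <- map[map$lumped_id == lid, , drop = FALSE]
    iv <- lump_interval(model$lb[rows$member_id], model$ub[rows$member_id],
                        rows$ratio)
    if (is.null(iv)) {
      stop("bounds of subset '", lid, "' are incompatible after scaling")
    }
    lb_c[lid] <- iv[1]
    ub_c[lid] <- iv[2]
  }
  obj_c <- as.vector(crossprod(TT, model$obj))

  prot_m <- if (is.null(spec)) character() else spec$protected_metabolites
  zero_row <- rowSums(S_c != 0) == 0
  drop_rows <- rownames(S_c)[zero_row & !rownames(S_c) %in% prot_m]
  S_keep <- S_c[!rownames(S_c) %in% drop_rows, , drop = FALSE]

  cmp <- new_metabolic_model(S_keep, S_ext_c, lb_c, ub_c, obj_c,
                             model$compartments)
  structure(list(model = cmp, subsets = map, T = TT,
                 eliminated_metabolites = drop_rows,
                 input_rxn_ids = model$rxn_ids),
            class = "compressed_model")
}

#' Expand a compressed-model flux vector to the input network
#'
#' Maps a flux vector of the compressed model back through the lumping
#' transformation: `r_full = T v`. The result is a steady-state flux
#' vector of the input (pruned) model satisfying its bounds whenever `v`
#' is feasible for the compressed model.
#'
#' @param compressed a `compressed_model`.
#' @param v named (or positionally ordered) flux vector of the
#'   compressed model.
#' @return named flux vector over the input model's reactions.
#' @export
expand_flux <- function(compressed, v) {
  ids <- colnames(compressed$T)
  if (!is.null(names(v))) v <- v[ids]
  stats::setNames(as.vector(compressed$T %*% v), rownames(compressed$T))
}

#' Translate a scenario onto a compressed model
#'
#' Rewrites a scenario's constraint coefficients and bound overrides
#' from the input model's reaction IDs to the compressed model's: a
#' coefficient `a` on a member with ratio `rho` becomes `a * rho` on its
#' lumped reaction (member flux = ratio times lump flux), so the
#' feasible phenotype set is identical on both sides.
#'
#' @param scen a (resolved) [scenario()].
#' @param compressed a `compressed_model`.
#' @return the translated scenario.
#' @export
translate_scenario <- function(scen, compressed) {
  map <- compressed$subsets
  to_lump <- stats::setNames(map$lumped_id, map$member_id)
  ratio <- stats::setNames(map$ratio, map$member_id)
  scen$constraints <- lapply(scen$constraints, function(row) {
    coef <- stats::setNames(numeric(0), character(0))
    for (rid in names(row$coef)) {
      lid <- to_lump[[rid]]
      coef[lid] <- (if (lid %in% names(coef)) coef[lid] else 0) +
        row$coef[[rid]] * ratio[[rid]]
    }
    list(coef = coef, rhs = row$rhs, fba_max = row$fba_max)
  })
  if (length(scen$bound_overrides)) {
    ov <- list()
    for (rid in names(scen$bound_overrides)) {
      lid <- to_lump[[rid]]
      b <- scen$bound_overrides[[rid]] / ratio[[rid]]
      if (ratio[[rid]] < 0) b <- rev(b)
      if (!is.null(ov[[lid]])) {
        b <- c(max(b[1], ov[[lid]][1]), min(b[2], ov[[lid]][2]))
      }
      ov[[lid]] <- b
    }
    scen$bound_overrides <- ov
  }
  scen
}

#' Condensed biomass synthesis reaction report
#'
#' Signed stoichiometric coefficient table of the (possibly lumped)
#' biomass synthesis reaction: negative values are consumed, positive
#' produced. The reaction is found by its ID; if that ID was lumped into
#' a subset, the lumped reaction containing it is reported (coefficients
#' rescaled so the original biomass reaction runs at unit flux). The
#' biomass-tracker convention is supported as a fallback: when the ID is
#' not found, the reaction producing the `biomass` species is used.
#'
#' @param x a `compressed_model`, `prune_result` or `metabolic_model`.
#' @param biomass_reaction reaction ID of the biomass synthesis reaction.
#' @param tracker_id species ID of the biomass tracker (fallback lookup).
#' @return a tibble with columns `metabolite`, `coefficient`, `external`,
#'   sorted by metabolite ID.
#' @export
condensed_bsr_report <- function(x, biomass_reaction, tracker_id = "biomass") {
  scale <- 1
  if (inherits(x, "compressed_model")) {
    model <- x$model
    if (!biomass_reaction %in% model$rxn_ids) {
      hit <- x$subsets[x$subsets$member_id == biomass_reaction, , drop = FALSE]
      if (nrow(hit) == 1L) {
        scale <- 1 / hit$ratio   # report per unit flux of the original BSR
        biomass_reaction <- hit$lumped_id
      }
    }
  } else if (inherits(x, "prune_result")) {
    model <- x$model
  } else {
    model <- x
  }
  if (!biomass_reaction %in% model$rxn_ids) {
    if (tracker_id %in% model$met_ids) {
      prod <- model$rxn_ids[model$S[tracker_id, ] > 0]
      if (length(prod) == 1L) biomass_reaction <- prod
      else stop("biomass reaction '", biomass_reaction,
                "' not found and tracker lookup is ambiguous")
    } else {
      stop("biomass reaction not present: ", biomass_reaction)
    }
  }
  col <- c(stats::setNames(model$S[, biomass_reaction], rownames(model$S)),
           stats::setNames(model$S_ext[, biomass_reaction], rownames(model$S_ext)))
  ext <- c(rep(FALSE, nrow(model$S)), rep(TRUE, nrow(model$S_ext)))
  keep <- col != 0
  tibble::tibble(metabolite = names(col)[keep],
                 coefficient = as.numeric(col[keep]) * scale,
                 external = ext[keep]) |>
    dplyr::arrange(.data$metabolite)
}

#' Diff two biomass-reaction reports
#'
#' Aligns two [condensed_bsr_report()] tables on the union of their
#' metabolites, with `NA` where a metabolite is absent from one model —
#' the side-by-side comparison used to contrast a condensed biomass
#' reaction with a manually curated one.
#'
#' @param a,b tibbles from [condensed_bsr_report()].
#' @param names length-2 labels for the coefficient columns.
#' @return a tibble `metabolite`, `<names[1]>`, `<names[2]>`.
#' @export
bsr_diff <- function(a, b, names = c("model_a", "model_b")) {
  out <- dplyr::full_join(
    dplyr::select(a, "metabolite", !!names[1] := "coefficient"),
    dplyr::select(b, "metabolite", !!names[2] := "coefficient"),
    by = "metabolite")
  dplyr::arrange(out, .data$metabolite)
}

#' @export
print.compressed_model <- function(x, ...) {
  multi <- table(x$subsets$lumped_id)
  cat("<compressed_model> ", length(x$input_rxn_ids), " -> ",
      length(x$model$rxn_ids), " reactions (",
      sum(multi > 1), " lumped subset(s), ",
      length(x$eliminated_metabolites), " metabolite(s) eliminated)\n",
      sep = "")
  invisible(x)
}

#' @export
tidy.compressed_model <- function(x, ...) x$subsets

#' @export
glance.compressed_model <- function(x, ...) {
  tibble::tibble(
    n_reactions_in = length(x$input_rxn_ids),
    n_reactions_out = length(x$model$rxn_ids),
    n_subsets = length(unique(x$subsets$lumped_id[duplicated(x$subsets$lumped_id)])),
    n_metabolites_eliminated = length(x$eliminated_metabolites),
    dof = dof(x$model)
  )
}
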