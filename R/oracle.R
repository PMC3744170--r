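# Independent LP-based semantics of drug inhibition ("the oracle").
#
# A reaction is blocked under a drug set when its maximal flux over the
# steady-state polytope (with every target of every used drug forced to
# zero) stays below the activity threshold epsilon. All reported side
# effects are computed here, independently of the MILP, which makes this
# module the verification standard for the duality reformulation.

FEAS_TOL <- 1e-6

# union of split target reactions of a drug set
drug_targets_off <- function(catalog, drug_set) {
  if (!length(drug_set)) return(character())
  unknown <- setdiff(drug_set, names(catalog$targets))
  if (length(unknown)) stop("unknown drug id: ", paste(unknown, collapse = ", "))
  unique(unlist(catalog$targets[drug_set], use.names = FALSE))
}

# maximize a linear functional of the flux vector with some reactions off;
# `zero` additionally pins reactions to zero (used to exclude the futile
# self-loop of a reverse pair when maximizing one direction, so that the
# maximum measures net directional flux)
flux_lp_max <- function(model, off, coef_idx, zero = integer()) {
  ub <- model$ub
  ub[off] <- 0
  ub[zero] <- 0
  obj <- numeric(length(ub))
  obj[coef_idx] <- 1
  lp_solve(obj, A_eq = model$S, b_eq = rep(0, length(model$metabolites)),
           lb = 0, ub = ub, maximize = TRUE)
}

# index of the reverse twin (NA when unpaired)
twin_idx <- function(model, j) {
  id <- model$reactions[j]
  if (id %in% names(model$rev_pair)) {
    match(model$rev_pair[[id]], model$reactions)
  } else {
    NA_integer_
  }
}

#' Maximal attainable flux of a reaction under a drug set
#'
#' Solves `max v_j` over `Sv = 0`, `0 <= v <= U`, with every target
#' reaction of every used drug constrained to zero. For a reversible
#' (split) reaction the larger of the two directional maxima is returned.
#'
#' @param model a `metabolic_model`.
#' @param catalog a `drug_catalog` resolved against `model`.
#' @param drug_set character vector of drug ids (may be empty).
#' @param reaction a reaction id (parent or split direction).
#' @return the LP maximum (non-negative scalar).
#' @export
max_flux <- function(model, catalog, drug_set, reaction) {
  off <- drug_targets_off(catalog, drug_set)
  dirs <- if (reaction %in% model$reactions && reaction %in% names(model$parent) &&
              model$parent[[reaction]] != reaction) {
    reaction
  } else {
    directions_of(model, reaction)
  }
  if (!length(dirs)) stop("unknown reaction: ", reaction)
  best <- 0
  for (d in dirs) {
    if (d %in% off || model$ub[[d]] <= 0) next
    j <- match(d, model$reactions)
    tw <- twin_idx(model, j)
    r <- flux_lp_max(model, off, j, zero = tw[!is.na(tw)])
    if (r$status != "optimal") stop("LP failure for reaction ", d)
    best <- max(best, r$value)
  }
  best
}

# per-direction maxima for all split reactions, with a certification trick:
# one LP maximizing sum(min(v_j, eps)) certifies many reactions active at
# once; only the remainder needs individual LPs.
split_max_flux_all <- function(model, off, epsilon) {
  n_r <- length(model$reactions)
  ub <- model$ub
  ub[off] <- 0
  mx <- rep(NA_real_, n_r)
  names(mx) <- model$reactions
  mx[ub <= 0] <- 0
  rem <- which(is.na(mx))
  n_m <- length(model$metabolites)
  Sd <- as.matrix(model$S)
  repeat {
    if (!length(rem)) break
    k <- length(rem)
    # vars: v (n_r), t (k); maximize sum t with t_j <= eps and
    # t_j <= v_j (unpaired) or t_j <= v_j - v_twin (net flux, so a futile
    # self-loop of a reverse pair cannot certify activity)
    A_eq <- cbind(Sd, matrix(0, n_m, k))
    A_ub <- cbind(matrix(0, k, n_r), diag(k))
    for (i in seq_len(k)) {
      A_ub[i, rem[i]] <- -1
      tw <- twin_idx(model, rem[i])
      if (!is.na(tw)) A_ub[i, tw] <- 1
    }
    r <- lp_solve(c(rep(0, n_r), rep(1, k)),
                  A_eq = A_eq, b_eq = rep(0, n_m),
                  A_ub = A_ub, b_ub = rep(0, k),
                  lb = 0, ub = c(ub, rep(epsilon, k)), maximize = TRUE)
    if (r$status != "optimal") stop("LP failure in blocked-reaction scan")
    tt <- r$x[n_r + seq_len(k)]
    cert <- tt >= epsilon - 1e-9
    if (!any(cert)) break
    mx[rem[cert]] <- Inf  # certified able to reach eps; exact max not needed
    rem <- rem[!cert]
  }
  for (j in rem) {
    tw <- twin_idx(model, j)
    r <- flux_lp_max(model, off, j, zero = tw[!is.na(tw)])
    if (r$status != "optimal") stop("LP failure for reaction ", model$reactions[j])
    mx[j] <- r$value
  }
  mx
}

#' Reactions blocked by a drug set
#'
#' A split direction is blocked when its maximal flux (minus the LP
#' feasibility tolerance) is below `epsilon`; a (collapsed) reaction is
#' blocked when every one of its directions is.
#'
#' @inheritParams max_flux
#' @param epsilon activity threshold (flux units), default 0.1.
#' @return character vector of blocked parent reaction ids.
#' @export
blocked_reactions <- function(model, catalog, drug_set, epsilon = 0.1) {
  stopifnot(epsilon > 0)
  off <- drug_targets_off(catalog, drug_set)
  mx <- split_max_flux_all(model, off, epsilon)
  blocked_dir <- (mx - FEAS_TOL) < epsilon
  parents <- collapse_ids(model, model$reactions)
  blk <- vapply(parents, function(p) {
    all(blocked_dir[directions_of(model, p)])
  }, logical(1))
  parents[blk]
}

#' Side effect of a drug set
#'
#' The side-effect score sigma(D) = number of newly stopped reactions
#' (reverse pairs collapsed; the objective reaction and reactions already
#' blocked with no drugs excluded) plus the beta-weighted penalty for the
#' non-metabolic targets of the used drugs.
#'
#' @inheritParams blocked_reactions
#' @param objective objective reaction id to exclude from the count, or
#'   `NULL` to count every stopped reaction.
#' @return a `side_effect_report`: list with `sigma`, `stopped_reactions`
#'   (newly stopped, objective excluded), `beta_term` and `drug_set`.
#' @export
side_effect <- function(model, catalog, drug_set, objective = NULL,
                        epsilon = 0.1) {
  baseline <- blocked_reactions(model, catalog, character(), epsilon)
  blocked <- if (length(drug_set)) {
    blocked_reactions(model, catalog, drug_set, epsilon)
  } else {
    baseline
  }
  stopped <- setdiff(blocked, baseline)
  if (!is.null(objective)) {
    stopped <- setdiff(stopped, collapse_ids(model, objective))
  }
  beta_term <- if (length(drug_set)) sum(catalog$beta[drug_set]) else 0
  structure(list(sigma = length(stopped) + beta_term,
                 stopped_reactions = stopped,
                 beta_term = beta_term,
                 drug_set = sort(drug_set)),
            class = "side_effect_report")
}

#' @export
print.side_effect_report <- function(x, ...) {
  cat("side effect sigma =", format(x$sigma),
      "(", length(x$stopped_reactions), "stopped reactions + beta term",
      format(x$beta_term), ")\n")
  if (length(x$drug_set)) cat("drugs:", paste(x$drug_set, collapse = ", "), "\n")
  invisible(x)
}

#' Synergy profile of a drug combination
#'
#' The synergy set Y holds the reactions that none of the single drugs of
#' the combination blocks but that the full combination does; the binary
#' vector `s` over the (collapsed) reaction universe is its indicator.
#'
#' @inheritParams blocked_reactions
#' @param combination character vector of at least two drug ids.
#' @return a `synergy_profile`: list with `combination`, `Y`, `s` and the
#'   reaction universe `reactions`.
#' @export
synergy_profile <- function(model, catalog, combination, epsilon = 0.1) {
  if (length(combination) < 2) {
    stop("a synergy profile needs a combination of at least two drugs")
  }
  comb_blocked <- blocked_reactions(model, catalog, combination, epsilon)
  single_blocked <- unique(unlist(lapply(combination, function(k) {
    blocked_reactions(model, catalog, k, epsilon)
  })))
  Y <- setdiff(comb_blocked, single_blocked)
  universe <- collapse_ids(model, model$reactions)
  s <- stats::setNames(as.integer(universe %in% Y), universe)
  structure(list(combination = sort(combination), Y = Y, s = s,
                 reactions = universe),
            class = "synergy_profile")
}

#' @export
print.synergy_profile <- function(x, ...) {
  cat("synergy of {", paste(x$combination, collapse = ", "), "}: |Y| =",
      length(x$Y), "\n")
  invisible(x)
}

# does drug set D block every direction of the objective?
blocks_objective <- function(model, catalog, drug_set, objective, epsilon) {
  off <- drug_targets_off(catalog, drug_set)
  dirs <- directions_of(model, collapse_ids(model, objective))
  for (d in dirs) {
    if (d %in% off || model$ub[[d]] <= 0) next
    j <- match(d, model$reactions)
    tw <- twin_idx(model, j)
    r <- flux_lp_max(model, off, j, zero = tw[!is.na(tw)])
    if (r$status != "optimal") stop("LP failure")
    if ((r$value - FEAS_TOL) >= epsilon) return(FALSE)
  }
  TRUE
}

#' Exhaustive-search optimum (test oracle)
#'
#' Enumerates drug subsets (up to `max_cardinality`) and returns one that
#' blocks the objective with minimal sigma, tie-broken by fewer drugs and
#' then lexicographically. Supersets of known blocking sets are pruned
#' (sigma is monotone under adding drugs), as are supersets of any
#' `forbidden_cuts` entry, mirroring the exclusion-cut semantics of the
#' MILP enumeration. Only usable at small catalog sizes.
#'
#' @inheritParams blocked_reactions
#' @param objective objective reaction id.
#' @param max_cardinality largest subset size to consider.
#' @param forbidden_cuts list of previously returned drug sets; any superset
#'   of an entry is excluded.
#' @return list with `status` (`"optimal"` or `"infeasible"`), `used_drugs`
#'   and `sigma` (oracle side effect).
#' @export
brute_force_optimum <- function(model, catalog, objective, epsilon = 0.1,
                                max_cardinality = Inf,
                                forbidden_cuts = list()) {
  drugs <- names(catalog$targets)
  n_d <- length(drugs)
  cap <- min(max_cardinality, n_d)
  hits <- list()  # inclusion-minimal blocking subsets respecting the cuts
  is_superset <- function(D, sets) {
    for (s in sets) if (all(s %in% D)) return(TRUE)
    FALSE
  }
  for (size in 0:cap) {
    subsets <- if (size == 0) list(character()) else
      utils::combn(drugs, size, simplify = FALSE)
    for (D in subsets) {
      if (is_superset(D, forbidden_cuts)) next
      if (is_superset(D, hits)) next
      if (blocks_objective(model, catalog, D, objective, epsilon)) {
        hits[[length(hits) + 1]] <- D
      }
    }
  }
  if (!length(hits)) {
    return(list(status = "infeasible", used_drugs = NULL, sigma = NA_real_))
  }
  sig <- vapply(hits, function(D) {
    side_effect(model, catalog, D, objective, epsilon)$sigma
  }, numeric(1))
  ord <- order(sig, lengths(hits),
               vapply(hits, function(D) paste(sort(D), collapse = "|"), ""))
  best <- hits[[ord[1]]]
  list(status = "optimal", used_drugs = sort(best), sigma = sig[ord[1]])
}
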