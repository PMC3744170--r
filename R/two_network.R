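# Two-network selectivity: block an objective reaction of a target network
# (e.g. a cancer cell's biomass) while minimizing the side effect on a
# reference network (e.g. regular human metabolism). One shared drug
# binary d_k couples the two networks: the same compound hits its targets
# in both cell types. The target network carries the full primal + dual +
# strong-duality machinery forcing its objective to zero; the reference
# network contributes only a primal flux block and stopped-reaction
# indicators, whose count (soft, minimized, not constrained) is the outer
# objective together with the beta drug penalties.

#' Pair two networks under a shared drug catalog
#'
#' Resolves the same drug records against both models separately, groups
#' drugs by their joint (target-model, reference-model) target sets, and
#' estimates beta-bar on the reference network.
#'
#' @param target_model `metabolic_model` whose objective must be blocked.
#' @param reference_model `metabolic_model` whose metabolism is preserved.
#' @param records drug records (see [read_drug_table()]).
#' @param correspondence optional data.frame with columns `target_id`,
#'   `reference_id` mapping reactions between the models; defaults to
#'   matching shared reaction ids.
#' @param beta_bar optional fixed beta-bar (estimated on the reference
#'   network when `NULL`).
#' @param epsilon activity threshold for the beta-bar estimate.
#' @return a `network_pair`.
#' @export
network_pair <- function(target_model, reference_model, records,
                         correspondence = NULL, beta_bar = NULL,
                         epsilon = 0.1) {
  if (is.null(correspondence)) {
    shared <- intersect(collapse_ids(target_model, target_model$reactions),
                        collapse_ids(reference_model,
                                     reference_model$reactions))
    correspondence <- stats::setNames(shared, shared)
  } else {
    stopifnot(all(c("target_id", "reference_id") %in% names(correspondence)))
    bad_t <- setdiff(correspondence$target_id,
                     collapse_ids(target_model, target_model$reactions))
    bad_r <- setdiff(correspondence$reference_id,
                     collapse_ids(reference_model,
                                  reference_model$reactions))
    if (length(bad_t) || length(bad_r)) {
      stop("correspondence names unknown reactions: ",
           paste(c(bad_t, bad_r), collapse = ", "))
    }
    correspondence <- stats::setNames(correspondence$reference_id,
                                      correspondence$target_id)
  }
  flt <- filter_records(records)
  tg_t <- suppressWarnings(map_targets(flt, target_model))
  tg_r <- suppressWarnings(map_targets(flt, reference_model))
  keep <- flt$drug_id[flt$drug_id %in% union(names(tg_t), names(tg_r))]
  if (!length(keep)) stop("no drug resolves to a target in either network")
  flt <- flt[flt$drug_id %in% keep, , drop = FALSE]
  key <- vapply(flt$drug_id, function(d) {
    paste(paste(tg_t[[d]], collapse = "|"), "::",
          paste(tg_r[[d]], collapse = "|"))
  }, "")
  reps <- character(); members <- list()
  for (g in split(flt$drug_id, key)) {
    nn <- flt$n_nonmetabolic[match(g, flt$drug_id)]
    rep_id <- g[order(nn, g)][1]
    reps <- c(reps, rep_id); members[[rep_id]] <- sort(g)
  }
  reps <- sort(reps)
  drugs_df <- flt[match(reps, flt$drug_id), , drop = FALSE]
  empty_chr <- stats::setNames(rep(list(character()), length(reps)), reps)
  t_t <- empty_chr; t_r <- empty_chr
  for (d in reps) {
    if (!is.null(tg_t[[d]])) t_t[[d]] <- tg_t[[d]]
    if (!is.null(tg_r[[d]])) t_r[[d]] <- tg_r[[d]]
  }
  if (is.null(beta_bar)) {
    with_ref <- t_r[lengths(t_r) > 0]
    beta_bar <- if (length(with_ref)) {
      estimate_beta_bar(reference_model, with_ref, epsilon)
    } else 0
  }
  beta <- stats::setNames(beta_bar * drugs_df$n_nonmetabolic, reps)
  mk_cat <- function(tg) {
    structure(list(drugs = drugs_df, targets = tg, beta = beta,
                   beta_bar = beta_bar, group_members = members[reps]),
              class = "drug_catalog")
  }
  structure(list(target_model = target_model,
                 reference_model = reference_model,
                 correspondence = correspondence,
                 catalog_target = mk_cat(t_t),
                 catalog_reference = mk_cat(t_r),
                 beta_bar = beta_bar),
            class = "network_pair")
}

#' @export
print.network_pair <- function(x, ...) {
  cat("network pair: target", length(x$target_model$reactions),
      "reactions vs reference", length(x$reference_model$reactions),
      "reactions;", nrow(x$catalog_target$drugs), "drug groups\n")
  invisible(x)
}

#' Read a network-pair specification file
#'
#' JSON with fields `target_model`, `reference_model` (tabular dialect
#' paths), `drug_table` and optionally `correspondence` (TSV path with
#' columns `target_id`, `reference_id`) and `default_cap`. Paths are
#' resolved relative to the JSON file.
#'
#' @param path JSON file.
#' @param beta_bar optional fixed beta-bar.
#' @return a `network_pair`.
#' @export
read_network_pair <- function(path, beta_bar = NULL) {
  spec <- jsonlite::fromJSON(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) if (file.exists(p)) p else file.path(base, p)
  cap <- spec$default_cap %||% 1000
  tm <- split_reversible(load_model(rel(spec$target_model)), cap)
  rm_ <- split_reversible(load_model(rel(spec$reference_model)), cap)
  records <- read_drug_table(rel(spec$drug_table))
  corr <- if (!is.null(spec$correspondence)) {
    utils::read.delim(rel(spec$correspondence), stringsAsFactors = FALSE)
  }
  network_pair(tm, rm_, records, correspondence = corr, beta_bar = beta_bar)
}

# assemble the coupled two-network MILP
build_selective_milp <- function(pair, objective, config,
                                 forbidden_cuts = list(), min_drugs = 0) {
  tm <- pair$target_model; rm_ <- pair$reference_model
  cat_t <- pair$catalog_target; cat_r <- pair$catalog_reference
  drugs <- cat_t$drugs$drug_id
  n_rt <- length(tm$reactions); n_mt <- length(tm$metabolites)
  n_rr <- length(rm_$reactions); n_mr <- length(rm_$metabolites)
  n_d <- length(drugs)
  obj_parent <- collapse_ids(tm, objective)
  obj_dirs <- directions_of(tm, obj_parent)
  if (!length(obj_dirs)) stop("unknown objective reaction: ", objective)
  pjt <- integer(); pkt <- integer()
  for (k in seq_len(n_d)) {
    tj <- match(cat_t$targets[[drugs[k]]], tm$reactions)
    pjt <- c(pjt, tj); pkt <- c(pkt, rep(k, length(tj)))
  }
  n_tt <- length(pjt)
  pjr <- integer(); pkr <- integer()
  for (k in seq_len(n_d)) {
    tj <- match(cat_r$targets[[drugs[k]]], rm_$reactions)
    pjr <- c(pjr, tj); pkr <- c(pkr, rep(k, length(tj)))
  }
  n_tr <- length(pjr)
  U_t <- unname(tm$ub); U_r <- unname(rm_$ub)
  dmax <- config$delta_max; eps <- config$epsilon
  alpha <- rep_len(unname(config$alpha), n_rr)
  beta <- stats::setNames(rep(0, n_d), drugs)
  if (length(cat_t$beta)) beta[names(cat_t$beta)] <- cat_t$beta
  # one dual certificate block per objective direction (net flux for a
  # reverse pair, see build_milp)
  n_b <- length(obj_dirs)
  cvecs <- lapply(obj_dirs, function(d) {
    cv <- as.numeric(tm$reactions == d)
    if (d %in% names(tm$rev_pair)) {
      cv[match(tm$rev_pair[[d]], tm$reactions)] <- -1
    }
    cv
  })
  # layout: v_t | v_r, y_r (reference) | d | per block: mu, lam, delta, z
  i_vt <- seq_len(n_rt)
  i_vr <- n_rt + seq_len(n_rr)
  i_yr <- n_rt + n_rr + seq_len(n_rr)
  i_d <- n_rt + 2 * n_rr + seq_len(n_d)
  blk_len <- n_mt + n_rt + 2 * n_tt
  blk0 <- n_rt + 2 * n_rr + n_d
  i_mu <- lapply(seq_len(n_b), function(i) blk0 + (i - 1) * blk_len + seq_len(n_mt))
  i_lam <- lapply(seq_len(n_b), function(i) {
    blk0 + (i - 1) * blk_len + n_mt + seq_len(n_rt)
  })
  i_delta <- lapply(seq_len(n_b), function(i) {
    blk0 + (i - 1) * blk_len + n_mt + n_rt + seq_len(n_tt)
  })
  i_z <- lapply(seq_len(n_b), function(i) {
    blk0 + (i - 1) * blk_len + n_mt + n_rt + n_tt + seq_len(n_tt)
  })
  nv <- blk0 + n_b * blk_len
  rp <- rm_$rev_pair
  nmp <- names(rp)[names(rp) < rp]
  rev_once <- cbind(match(nmp, rm_$reactions), match(rp[nmp], rm_$reactions))
  n_rows <- n_mt + n_tt + n_b * (n_rt + 1 + 3 * n_tt) +
    n_mr + n_tr + 2 * n_rr + (if (length(rev_once)) nrow(rev_once) else 0) +
    length(forbidden_cuts) + (min_drugs > 0)
  A <- matrix(0, n_rows, nv)
  lhs <- numeric(n_rows); rhs <- numeric(n_rows)
  r <- 0
  St <- as.matrix(tm$S); Sr <- as.matrix(rm_$S)
  A[r + seq_len(n_mt), i_vt] <- St
  r <- r + n_mt
  for (p in seq_len(n_tt)) {
    A[r + p, i_vt[pjt[p]]] <- 1; A[r + p, i_d[pkt[p]]] <- -U_t[pjt[p]]
    lhs[r + p] <- -Inf
  }
  r <- r + n_tt
  for (i in seq_len(n_b)) {
    A[r + seq_len(n_rt), i_mu[[i]]] <- t(St)
    for (j in seq_len(n_rt)) A[r + j, i_lam[[i]][j]] <- 1
    for (p in seq_len(n_tt)) A[r + pjt[p], i_delta[[i]][p]] <- 1
    lhs[r + seq_len(n_rt)] <- cvecs[[i]]
    rhs[r + seq_len(n_rt)] <- Inf
    r <- r + n_rt
    A[r + 1, i_vt] <- cvecs[[i]]
    A[r + 1, i_lam[[i]]] <- -U_t
    for (p in seq_len(n_tt)) A[r + 1, i_z[[i]][p]] <- -U_t[pjt[p]]
    r <- r + 1
    for (p in seq_len(n_tt)) {
      A[r + 1, i_z[[i]][p]] <- 1; A[r + 1, i_d[pkt[p]]] <- -dmax
      lhs[r + 1] <- -Inf
      A[r + 2, i_z[[i]][p]] <- 1; A[r + 2, i_delta[[i]][p]] <- -1
      lhs[r + 2] <- -Inf
      A[r + 3, i_delta[[i]][p]] <- 1; A[r + 3, i_z[[i]][p]] <- -1
      A[r + 3, i_d[pkt[p]]] <- dmax
      lhs[r + 3] <- -Inf; rhs[r + 3] <- dmax
      r <- r + 3
    }
  }
  A[r + seq_len(n_mr), i_vr] <- Sr
  r <- r + n_mr
  for (p in seq_len(n_tr)) {
    A[r + p, i_vr[pjr[p]]] <- 1; A[r + p, i_d[pkr[p]]] <- -U_r[pjr[p]]
    lhs[r + p] <- -Inf
  }
  r <- r + n_tr
  for (j in seq_len(n_rr)) {
    A[r + j, i_yr[j]] <- eps; A[r + j, i_vr[j]] <- -1
    lhs[r + j] <- -Inf
  }
  r <- r + n_rr
  for (j in seq_len(n_rr)) {
    A[r + j, i_vr[j]] <- 1; A[r + j, i_yr[j]] <- -U_r[j]
    lhs[r + j] <- -Inf
  }
  r <- r + n_rr
  if (length(rev_once)) {
    for (q in seq_len(nrow(rev_once))) {
      A[r + q, i_yr[rev_once[q, ]]] <- 1
      lhs[r + q] <- -Inf; rhs[r + q] <- 1
    }
    r <- r + nrow(rev_once)
  }
  for (cut in forbidden_cuts) {
    kk <- match(cut, drugs)
    r <- r + 1
    A[r, i_d[kk]] <- 1
    lhs[r] <- 1; rhs[r] <- Inf
  }
  if (min_drugs > 0) {
    r <- r + 1
    A[r, i_d] <- 1
    lhs[r] <- -Inf; rhs[r] <- n_d - min_drugs
  }
  stopifnot(r == n_rows)
  lb <- rep(0, nv); ub <- rep(Inf, nv)
  ub[i_vt] <- U_t
  ub[i_vt[match(obj_dirs, tm$reactions)]] <- 0
  lb[unlist(i_mu)] <- -Inf
  ub[unlist(i_delta)] <- dmax; ub[unlist(i_z)] <- dmax
  ub[i_vr] <- U_r
  ub[i_yr] <- 1; ub[i_d] <- 1
  integer <- rep(FALSE, nv); integer[c(i_yr, i_d)] <- TRUE
  obj <- numeric(nv)
  obj[i_yr] <- -alpha
  obj[i_d] <- -(unname(beta) + config$b)
  list(A = A, lhs = lhs, rhs = rhs, lb = lb, ub = ub, integer = integer,
       obj = obj, const = sum(alpha) + sum(beta),
       idx = list(yr = i_yr, d = i_d, delta = unlist(i_delta)),
       pairs_k = rep(pkt, n_b), drugs = drugs, obj_parent = obj_parent)
}

#' Solve the selective (two-network) problem
#'
#' Finds the drug combination blocking the objective reaction of the
#' target network while minimizing the side effect counted on the
#' reference network (soft preservation). The reported `sigma_oracle` is
#' recomputed on the reference network by the LP blocking oracle; the
#' objective's corresponding reference reaction (when the correspondence
#' contains one) is excluded from the count.
#'
#' @param pair a `network_pair`.
#' @param objective objective reaction id in the target model.
#' @param config a [milp_config()].
#' @param forbidden_cuts list of drug sets to exclude (with supersets).
#' @param min_drugs require at least this many used drugs.
#' @return a `synergy_solution` (side effects refer to the reference
#'   network).
#' @export
solve_selective <- function(pair, objective, config = milp_config(),
                            forbidden_cuts = list(), min_drugs = 0) {
  tm <- pair$target_model
  cat_t <- pair$catalog_target; cat_r <- pair$catalog_reference
  obj_parent <- collapse_ids(tm, objective)
  ref_obj <- if (obj_parent %in% names(pair$correspondence)) {
    pair$correspondence[[obj_parent]]
  }
  baseline_t <- blocked_reactions(tm, cat_t, character(), config$epsilon)
  if (obj_parent %in% baseline_t) {
    sol <- empty_solution(tm, cat_t, obj_parent, config, "optimal",
                          sigma_oracle = 0)
    sol$reference_sigma <- 0
    return(sol)
  }
  inst <- build_selective_milp(pair, objective, config, forbidden_cuts,
                               min_drugs)
  res <- milp_solve(inst$obj, inst$A, inst$lhs, inst$rhs, inst$lb, inst$ub,
                    inst$integer, time_limit = config$time_limit)
  if (res$status != "optimal" || is.null(res$x)) {
    status <- if (res$status %in% c("infeasible", "unbounded", "failed"))
      "infeasible" else res$status
    return(empty_solution(tm, cat_t, obj_parent, config, status))
  }
  dval <- res$x[inst$idx$d]
  used <- sort(inst$drugs[dval < 0.5])
  objective_value <- res$value + inst$const
  sigma_milp <- objective_value + config$b * sum(dval > 0.5)
  inner_ok <- blocks_objective(tm, cat_t, used, obj_parent, config$epsilon)
  if (!inner_ok) {
    warning("duality certificate failed on the target network", call. = FALSE)
  }
  se <- side_effect(pair$reference_model, cat_r, used, ref_obj,
                    config$epsilon)
  yval <- res$x[inst$idx$yr]
  structure(list(used_drugs = used,
                 objective_value = objective_value,
                 sigma_milp = sigma_milp,
                 sigma_oracle = se$sigma,
                 status = res$status,
                 blocked_flags = stats::setNames(yval < 0.5,
                                                 pair$reference_model$reactions),
                 stopped_oracle = se$stopped_reactions,
                 objective = obj_parent,
                 config = config,
                 inner_ok = inner_ok,
                 delta_tight = any(res$x[inst$idx$delta][
                   dval[inst$pairs_k] > 0.5] >= 0.99 * config$delta_max)),
            class = "synergy_solution")
}

#' Enumerate selective solutions
#'
#' Iterates [solve_selective()] with exclusion cuts until infeasibility,
#' mirroring the single-network enumeration; reference-network side
#' effects come out non-decreasing.
#'
#' @inheritParams solve_selective
#' @param max_solutions stop after this many solutions.
#' @return list of `synergy_solution` objects.
#' @export
enumerate_selective <- function(pair, objective, config = milp_config(),
                                max_solutions = Inf, min_drugs = 0) {
  out <- list(); cuts <- list()
  tm <- pair$target_model
  obj_parent <- collapse_ids(tm, objective)
  baseline_t <- blocked_reactions(tm, pair$catalog_target, character(),
                                  config$epsilon)
  if (obj_parent %in% baseline_t) return(list())
  while (length(out) < max_solutions) {
    sol <- solve_selective(pair, objective, config, forbidden_cuts = cuts,
                           min_drugs = min_drugs)
    if (sol$status != "optimal") break
    out[[length(out) + 1]] <- sol
    cuts[[length(cuts) + 1]] <- sol$used_drugs
  }
  out
}

#' Screen candidate additional targets
#'
#' For each candidate reaction, deletes it from the target network (and,
#' through the correspondence, from the reference network), re-solves the
#' selective problem, and flags how the deletion changes the outcome:
#' `deletion_lethal` (the deletion alone blocks the objective),
#' `new_inhibition` (a drug solution exists only after the deletion),
#' `improved` (lower reference side effect than the no-deletion baseline),
#' or `unchanged`. Candidates with no reference correspondence are deleted
#' from the target network only and flagged.
#'
#' @inheritParams solve_selective
#' @param candidate_reactions parent reaction ids of the target model.
#' @return data.frame with one row per candidate and the baseline solution
#'   as attribute `"baseline"`.
#' @export
additional_target_screen <- function(pair, objective,
                                     config = milp_config(),
                                     candidate_reactions) {
  tm <- pair$target_model
  missing <- setdiff(candidate_reactions,
                     collapse_ids(tm, tm$reactions))
  if (length(missing)) {
    stop("candidates not in target model: ", paste(missing, collapse = ", "))
  }
  base_sol <- solve_selective(pair, objective, config)
  rows <- vector("list", length(candidate_reactions))
  for (i in seq_along(candidate_reactions)) {
    cand <- candidate_reactions[i]
    mod_pair <- pair
    mod_pair$target_model <- with_reactions_off(tm, cand)
    no_corr <- !(cand %in% names(pair$correspondence))
    if (!no_corr) {
      mod_pair$reference_model <-
        with_reactions_off(pair$reference_model,
                           pair$correspondence[[cand]])
    }
    sol <- solve_selective(mod_pair, objective, config)
    flag <-
      if (sol$status == "optimal" && !length(sol$used_drugs)) "deletion_lethal"
      else if (sol$status == "optimal" && base_sol$status != "optimal") "new_inhibition"
      else if (sol$status == "optimal" && base_sol$status == "optimal" &&
               sol$sigma_oracle < base_sol$sigma_oracle) "improved"
      else "unchanged"
    rows[[i]] <- data.frame(
      candidate = cand,
      status = sol$status,
      drugs = paste(sol$used_drugs, collapse = "+"),
      sigma = sol$sigma_oracle,
      flag = flag,
      no_reference_correspondence = no_corr,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "baseline") <- base_sol
  out
}
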