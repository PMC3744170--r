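# The single-level MILP for optimal drug combinations.
#
# The underlying program is bilevel: an outer problem picks the drug set D
# minimizing the side effect sigma(D), subject to the inner flux-balance LP
# (maximize the objective flux over the drug-restricted steady-state
# polytope) attaining zero. Appending the inner LP's dual feasibility
# conditions and equating primal and dual objectives (strong duality)
# collapses the two levels into one minimization; the only nonlinearities,
# products delta*d of a dual variable and a drug binary, are exactly
# linearized with big-M bounds (z variables).

#' MILP configuration
#'
#' @param epsilon activity threshold below which a flux counts as stopped
#'   (default 0.1; must be below the smallest positive capacity).
#' @param b small bonus per unused drug excluding redundant inhibitions
#'   from optimal combinations (default 0.001).
#' @param delta_max big-M upper bound for the dual variables of the
#'   drug-target coupling constraints (default 1000).
#' @param alpha per-reaction weight of a stopped reaction in the outer
#'   objective; scalar or named vector (default 1).
#' @param time_limit optional solver wall-clock limit in seconds.
#' @return a `milp_config` list.
#' @export
milp_config <- function(epsilon = 0.1, b = 0.001, delta_max = 1000,
                        alpha = 1, time_limit = NULL) {
  stopifnot(epsilon > 0, b > 0, delta_max > 0)
  structure(list(epsilon = epsilon, b = b, delta_max = delta_max,
                 alpha = alpha, time_limit = time_limit),
            class = "milp_config")
}

#' Assemble the duality-reformulated MILP
#'
#' Builds the full single-level instance: primal flux block (steady state,
#' capacities, drug-target coupling), dual feasibility, the strong-duality
#' equality with linearized `z = delta * d` products, the zero constraint
#' on the objective flux, the epsilon/capacity indicator rows defining the
#' stopped-reaction binaries `y`, the reverse-pair double-count exclusion,
#' one exclusion cut per forbidden drug set, and the outer objective.
#'
#' @param model a `metabolic_model`.
#' @param catalog a `drug_catalog` resolved against `model`.
#' @param objective objective reaction id (parent or split direction).
#' @param config a [milp_config()].
#' @param forbidden_cuts list of drug-id sets; each adds a cut requiring at
#'   least one member to stay unused (forbidding the set and its supersets).
#' @param min_drugs require at least this many used drugs.
#' @param baseline optional precomputed baseline blocked set (parent ids);
#'   computed from the oracle when `NULL`.
#' @return a `milp_instance`.
#' @export
build_milp <- function(model, catalog, objective, config = milp_config(),
                       forbidden_cuts = list(), min_drugs = 0,
                       baseline = NULL) {
  drugs <- catalog$drugs$drug_id
  n_r <- length(model$reactions)
  n_m <- length(model$metabolites)
  n_d <- length(drugs)
  missing_t <- setdiff(unlist(catalog$targets, use.names = FALSE),
                       model$reactions)
  if (length(missing_t)) {
    stop("catalog targets not in model: ", paste(missing_t, collapse = ", "))
  }
  obj_parent <- collapse_ids(model, objective)
  obj_dirs <- directions_of(model, obj_parent)
  if (!length(obj_dirs)) stop("unknown objective reaction: ", objective)
  if (is.null(baseline)) {
    baseline <- blocked_reactions(model, catalog, character(), config$epsilon)
  }
  if (obj_parent %in% baseline) {
    stop("degenerate instance: objective '", obj_parent,
         "' carries no flux even with no drugs; report the empty solution")
  }
  # (target reaction, drug) pairs indexing delta and z
  pj <- integer(); pk <- integer()
  for (k in seq_len(n_d)) {
    tj <- match(catalog$targets[[drugs[k]]], model$reactions)
    pj <- c(pj, tj); pk <- c(pk, rep(k, length(tj)))
  }
  n_t <- length(pj)
  alpha <- rep_len(unname(config$alpha), n_r)
  beta <- stats::setNames(rep(0, n_d), drugs)
  if (length(catalog$beta)) beta[names(catalog$beta)] <- catalog$beta
  U <- unname(model$ub)
  dmax <- config$delta_max
  eps <- config$epsilon
  pos_u <- U[U > 0]
  if (length(pos_u) && eps > min(pos_u)) {
    warning("epsilon exceeds the smallest positive capacity; reactions ",
            "with U < epsilon can never count as active")
  }
  # one dual certificate block per objective direction: blocking direction
  # j of a reverse pair means its net flux (v_j - v_twin) cannot be
  # positive, so the inner objective is e_j - e_twin (a futile self-loop
  # of the pair must not count as objective flux); an irreversible
  # objective keeps the plain e_obj objective
  n_b <- length(obj_dirs)
  cvecs <- lapply(obj_dirs, function(d) {
    cv <- as.numeric(model$reactions == d)
    tw <- model$rev_pair[d]
    if (d %in% names(model$rev_pair)) cv[match(tw, model$reactions)] <- -1
    cv
  })
  # variable layout: v, y, d shared; mu/lam/delta/z per certificate block
  i_v <- seq_len(n_r)
  i_y <- n_r + seq_len(n_r)
  i_d <- 2 * n_r + seq_len(n_d)
  blk_len <- n_m + n_r + 2 * n_t
  blk0 <- 2 * n_r + n_d
  i_mu <- lapply(seq_len(n_b), function(i) blk0 + (i - 1) * blk_len + seq_len(n_m))
  i_lam <- lapply(seq_len(n_b), function(i) blk0 + (i - 1) * blk_len + n_m + seq_len(n_r))
  i_delta <- lapply(seq_len(n_b), function(i) {
    blk0 + (i - 1) * blk_len + n_m + n_r + seq_len(n_t)
  })
  i_z <- lapply(seq_len(n_b), function(i) {
    blk0 + (i - 1) * blk_len + n_m + n_r + n_t + seq_len(n_t)
  })
  nv <- blk0 + n_b * blk_len
  rev_once <- {
    rp <- model$rev_pair
    nm <- names(rp)[names(rp) < rp]
    cbind(match(nm, model$reactions), match(rp[nm], model$reactions))
  }
  n_rows <- n_m + n_t + 2 * n_r +
    (if (length(rev_once)) nrow(rev_once) else 0) +
    n_b * (n_r + 1 + 3 * n_t) +
    length(forbidden_cuts) + (min_drugs > 0)
  A <- matrix(0, n_rows, nv)
  lhs <- numeric(n_rows); rhs <- numeric(n_rows)
  Sd <- as.matrix(model$S)
  r <- 0
  # steady state
  A[r + seq_len(n_m), i_v] <- Sd
  lhs[r + seq_len(n_m)] <- 0; rhs[r + seq_len(n_m)] <- 0
  r <- r + n_m
  # drug-target coupling v_j <= U_j d_k
  for (p in seq_len(n_t)) {
    A[r + p, i_v[pj[p]]] <- 1
    A[r + p, i_d[pk[p]]] <- -U[pj[p]]
    lhs[r + p] <- -Inf; rhs[r + p] <- 0
  }
  r <- r + n_t
  for (i in seq_len(n_b)) {
    # dual feasibility: S^T mu + lam + sum_k delta_jk >= c_j
    A[r + seq_len(n_r), i_mu[[i]]] <- t(Sd)
    for (j in seq_len(n_r)) A[r + j, i_lam[[i]][j]] <- 1
    for (p in seq_len(n_t)) A[r + pj[p], i_delta[[i]][p]] <- 1
    lhs[r + seq_len(n_r)] <- cvecs[[i]]; rhs[r + seq_len(n_r)] <- Inf
    r <- r + n_r
    # strong duality: c^T v - sum U_j lam_j - sum U_j z_jk = 0
    A[r + 1, i_v] <- cvecs[[i]]
    A[r + 1, i_lam[[i]]] <- -U
    for (p in seq_len(n_t)) A[r + 1, i_z[[i]][p]] <- -U[pj[p]]
    lhs[r + 1] <- 0; rhs[r + 1] <- 0
    r <- r + 1
    # exact linearization of z = delta * d
    for (p in seq_len(n_t)) {
      A[r + 1, i_z[[i]][p]] <- 1; A[r + 1, i_d[pk[p]]] <- -dmax
      lhs[r + 1] <- -Inf; rhs[r + 1] <- 0
      A[r + 2, i_z[[i]][p]] <- 1; A[r + 2, i_delta[[i]][p]] <- -1
      lhs[r + 2] <- -Inf; rhs[r + 2] <- 0
      A[r + 3, i_delta[[i]][p]] <- 1; A[r + 3, i_z[[i]][p]] <- -1
      A[r + 3, i_d[pk[p]]] <- dmax
      lhs[r + 3] <- -Inf; rhs[r + 3] <- dmax
      r <- r + 3
    }
  }
  # y indicators: eps*y_j <= v_j and v_j <= U_j y_j
  for (j in seq_len(n_r)) {
    A[r + j, i_y[j]] <- eps; A[r + j, i_v[j]] <- -1
    lhs[r + j] <- -Inf; rhs[r + j] <- 0
  }
  r <- r + n_r
  for (j in seq_len(n_r)) {
    A[r + j, i_v[j]] <- 1; A[r + j, i_y[j]] <- -U[j]
    lhs[r + j] <- -Inf; rhs[r + j] <- 0
  }
  r <- r + n_r
  # reverse pairs counted once: y_j + y_l <= 1
  if (length(rev_once)) {
    for (q in seq_len(nrow(rev_once))) {
      A[r + q, i_y[rev_once[q, ]]] <- 1
      lhs[r + q] <- -Inf; rhs[r + q] <- 1
    }
    r <- r + nrow(rev_once)
  }
  # exclusion cuts: at least one drug of each forbidden set stays unused
  for (cut in forbidden_cuts) {
    kk <- match(cut, drugs)
    if (anyNA(kk)) stop("cut names unknown drug: ",
                        paste(cut[is.na(kk)], collapse = ", "))
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
  ub[i_v] <- U
  ub[i_v[match(obj_dirs, model$reactions)]] <- 0  # v_obj = 0
  lb[unlist(i_mu)] <- -Inf
  ub[unlist(i_delta)] <- dmax; ub[unlist(i_z)] <- dmax
  ub[i_y] <- 1; ub[i_d] <- 1
  integer <- rep(FALSE, nv)
  integer[c(i_y, i_d)] <- TRUE
  obj <- numeric(nv)
  obj[i_y] <- -alpha
  obj[i_d] <- -(unname(beta) + config$b)
  const <- sum(alpha) + sum(beta)
  structure(list(A = A, lhs = lhs, rhs = rhs, lb = lb, ub = ub,
                 integer = integer, obj = obj, const = const,
                 idx = list(v = i_v, mu = unlist(i_mu), lam = unlist(i_lam),
                            delta = unlist(i_delta), z = unlist(i_z),
                            y = i_y, d = i_d),
                 pairs = cbind(j = pj, k = pk),
                 pairs_k_all = rep(pk, n_b),
                 drugs = drugs, beta = beta, alpha = alpha,
                 objective = obj_parent, obj_dirs = obj_dirs,
                 baseline = baseline, config = config),
            class = "milp_instance")
}

#' @export
print.milp_instance <- function(x, ...) {
  cat("MILP instance:", length(x$obj), "variables (",
      sum(x$integer), "binary ),", nrow(x$A), "constraint rows,",
      length(x$idx$z), "linearized dual products\n")
  invisible(x)
}

empty_solution <- function(model, catalog, objective, config, status,
                           sigma_oracle = NA_real_) {
  structure(list(used_drugs = character(), objective_value = NA_real_,
                 sigma_milp = NA_real_, sigma_oracle = sigma_oracle,
                 status = status,
                 blocked_flags = NULL, objective = objective,
                 config = config, inner_ok = NA, delta_tight = FALSE),
            class = "synergy_solution")
}

#' Solve for the optimal drug combination
#'
#' Solves the strong-duality MILP and post-verifies the returned
#' combination: an independent inner LP re-checks that the objective flux
#' cannot reach `epsilon` under the used drugs (weak-duality certificate),
#' and the reported side effect `sigma_oracle` is recomputed with the
#' LP blocking oracle. If the objective is already blocked with no drugs,
#' the empty combination is reported.
#'
#' @inheritParams build_milp
#' @return a `synergy_solution` with `used_drugs`, `sigma_milp` (the outer
#'   objective without the `-b` drug bonus), `sigma_oracle`, `status`
#'   (`"optimal"`, `"infeasible"` or `"time_limit"`) and per-reaction
#'   activity flags.
#' @export
solve_optimal_combination <- function(model, catalog, objective,
                                      config = milp_config(),
                                      forbidden_cuts = list(),
                                      min_drugs = 0, baseline = NULL) {
  if (is.null(baseline)) {
    baseline <- blocked_reactions(model, catalog, character(), config$epsilon)
  }
  obj_parent <- collapse_ids(model, objective)
  if (obj_parent %in% baseline) {
    return(empty_solution(model, catalog, obj_parent, config, "optimal",
                          sigma_oracle = 0))
  }
  inst <- build_milp(model, catalog, objective, config, forbidden_cuts,
                     min_drugs, baseline = baseline)
  res <- milp_solve(inst$obj, inst$A, inst$lhs, inst$rhs, inst$lb, inst$ub,
                    inst$integer, time_limit = config$time_limit)
  if (res$status %in% c("infeasible", "unbounded", "failed")) {
    return(empty_solution(model, catalog, obj_parent, config, "infeasible"))
  }
  if (res$status == "time_limit" && is.null(res$x)) {
    return(empty_solution(model, catalog, obj_parent, config, "time_limit"))
  }
  dval <- res$x[inst$idx$d]
  yval <- res$x[inst$idx$y]
  used <- sort(inst$drugs[dval < 0.5])
  objective_value <- res$value + inst$const
  sigma_milp <- objective_value + config$b * sum(dval > 0.5)
  # delta of a used drug (d = 0) is decoupled slack; only pairs with the
  # drug unused have z = delta forced, so only there big-M tightness means
  # anything
  unused_pair <- dval[inst$pairs_k_all] > 0.5
  delta_tight <- any(res$x[inst$idx$delta][unused_pair] >=
                       0.99 * config$delta_max)
  if (delta_tight) {
    warning("a dual variable is within 1% of delta_max; ",
            "consider increasing delta_max", call. = FALSE)
  }
  inner_ok <- blocks_objective(model, catalog, used, obj_parent,
                               config$epsilon)
  if (!inner_ok) {
    warning("duality certificate failed: inner LP sustains the objective ",
            "flux under the returned drugs", call. = FALSE)
  }
  se <- side_effect(model, catalog, used, obj_parent, config$epsilon)
  structure(list(used_drugs = used,
                 objective_value = objective_value,
                 sigma_milp = sigma_milp,
                 sigma_oracle = se$sigma,
                 status = res$status,
                 blocked_flags = stats::setNames(yval < 0.5, model$reactions),
                 stopped_oracle = se$stopped_reactions,
                 objective = obj_parent,
                 config = config,
                 inner_ok = inner_ok,
                 delta_tight = delta_tight),
            class = "synergy_solution")
}

#' @export
print.synergy_solution <- function(x, ...) {
  cat("synergy solution [", x$status, "] objective:", x$objective, "\n")
  if (x$status != "infeasible") {
    cat("  drugs used:",
        if (length(x$used_drugs)) paste(x$used_drugs, collapse = " + ")
        else "(none needed)", "\n")
    cat("  sigma (oracle):", format(x$sigma_oracle),
        " sigma (MILP):", format(x$sigma_milp), "\n")
  }
  invisible(x)
}

#' Hierarchical enumeration of suboptimal combinations
#'
#' Repeatedly solves the MILP, after each optimum `D*` adding the exclusion
#' cut `sum_{k in D*} d_k >= 1` (at least one of its drugs must stay
#' unused), which forbids `D*` and all its supersets; iteration stops when
#' the problem becomes infeasible or `max_solutions` is reached. Solutions
#' come out in non-decreasing order of the outer objective.
#'
#' @inheritParams solve_optimal_combination
#' @param max_solutions stop after this many solutions.
#' @return list of `synergy_solution` objects (empty when the objective is
#'   unblockable or blocked at baseline).
#' @export
enumerate_solutions <- function(model, catalog, objective,
                                config = milp_config(), max_solutions = Inf,
                                min_drugs = 0) {
  baseline <- blocked_reactions(model, catalog, character(), config$epsilon)
  obj_parent <- collapse_ids(model, objective)
  if (obj_parent %in% baseline) return(list())
  out <- list()
  cuts <- list()
  while (length(out) < max_solutions) {
    sol <- solve_optimal_combination(model, catalog, objective, config,
                                     forbidden_cuts = cuts,
                                     min_drugs = min_drugs,
                                     baseline = baseline)
    if (sol$status != "optimal") break
    out[[length(out) + 1]] <- sol
    cuts[[length(cuts) + 1]] <- sol$used_drugs
  }
  out
}

#' Verify a solution against the blocking oracle
#'
#' Re-checks (a) that an independent inner LP cannot push the objective
#' flux to `epsilon` under the used drugs, and (b) that the stopped
#' reactions implied by the MILP's `y` variables (collapsed, baseline and
#' objective excluded) agree with the per-reaction blocking oracle. A
#' disagreement localizes the simultaneity gap: reactions each
#' individually able to carry flux that cannot all be active in one flux
#' vector.
#'
#' @inheritParams solve_optimal_combination
#' @param solution an optimal `synergy_solution`.
#' @param slack tolerated number of per-reaction discrepancies (default 0).
#' @return a `verification_report` with `inner_max`, `inner_ok`,
#'   `discrepancies` (reaction ids), `sigma_oracle`, `milp_stopped_count`
#'   and overall `ok`.
#' @export
verify_solution <- function(model, catalog, solution,
                            config = milp_config(), slack = 0) {
  stopifnot(inherits(solution, "synergy_solution"),
            solution$status == "optimal")
  obj_parent <- solution$objective
  used <- solution$used_drugs
  off <- drug_targets_off(catalog, used)
  dirs <- directions_of(model, obj_parent)
  inner_max <- 0
  for (d in dirs) {
    if (d %in% off || model$ub[[d]] <= 0) next
    j <- match(d, model$reactions)
    tw <- twin_idx(model, j)
    r <- flux_lp_max(model, off, j, zero = tw[!is.na(tw)])
    inner_max <- max(inner_max, r$value)
  }
  inner_ok <- (inner_max - FEAS_TOL) < config$epsilon
  baseline <- blocked_reactions(model, catalog, character(), config$epsilon)
  if (is.null(solution$blocked_flags)) {
    milp_stopped <- character()
  } else {
    flags <- solution$blocked_flags
    parents <- collapse_ids(model, model$reactions)
    milp_stopped <- parents[vapply(parents, function(p) {
      all(flags[directions_of(model, p)])
    }, logical(1))]
    milp_stopped <- setdiff(milp_stopped, c(baseline, obj_parent))
  }
  se <- side_effect(model, catalog, used, obj_parent, config$epsilon)
  discrepancies <- sort(union(setdiff(milp_stopped, se$stopped_reactions),
                              setdiff(se$stopped_reactions, milp_stopped)))
  structure(list(inner_max = inner_max, inner_ok = inner_ok,
                 milp_stopped = sort(milp_stopped),
                 oracle_stopped = sort(se$stopped_reactions),
                 discrepancies = discrepancies,
                 sigma_oracle = se$sigma,
                 milp_stopped_count = length(milp_stopped),
                 ok = inner_ok && length(discrepancies) <= slack),
            class = "verification_report")
}

#' @export
print.verification_report <- function(x, ...) {
  cat("verification:", if (x$ok) "PASS" else "FAIL", "\n")
  cat("  inner LP max objective flux:", format(x$inner_max),
      if (x$inner_ok) "(blocked)" else "(NOT blocked)", "\n")
  cat("  stopped count MILP/oracle:", x$milp_stopped_count, "/",
      length(x$oracle_stopped), "\n")
  if (length(x$discrepancies)) {
    cat("  discrepant reactions:", paste(x$discrepancies, collapse = ", "),
        "\n")
  }
  invisible(x)
}
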