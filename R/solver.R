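# LP/MILP backend. All optimization goes through scipy.optimize (HiGHS);
# reticulate auto-discovery does not find the conda python on this image,
# so we bind the python on PATH explicitly before first import.

.solver <- new.env(parent = emptyenv())

scipy_opt <- function() {
  if (is.null(.solver$sp)) {
    if (!reticulate::py_available(initialize = FALSE)) {
      py <- Sys.getenv("RETICULATE_PYTHON")
      if (!nzchar(py)) py <- Sys.which("python3")
      if (!nzchar(py)) py <- Sys.which("python")
      if (nzchar(py)) {
        tryCatch(reticulate::use_python(py, required = TRUE),
                 error = function(e) NULL)
      }
    }
    .solver$sp <- reticulate::import("scipy.optimize", delay_load = FALSE)
    .solver$np <- reticulate::import("numpy", delay_load = FALSE)
  }
  .solver$sp
}

#' Solve a linear program
#'
#' Thin wrapper around the HiGHS LP solver. Maximizes (or minimizes)
#' `obj %*% x` subject to `A_eq %*% x == b_eq`, `A_ub %*% x <= b_ub` and
#' box bounds.
#'
#' @param obj objective coefficient vector.
#' @param A_eq,b_eq equality constraints (may be `NULL`).
#' @param A_ub,b_ub inequality (`<=`) constraints (may be `NULL`).
#' @param lb,ub variable bounds, recycled to the number of variables.
#' @param maximize if `TRUE` (default) maximize the objective.
#' @return list with `status` (one of `"optimal"`, `"infeasible"`,
#'   `"unbounded"`, `"failed"`), `value` and the primal point `x`.
#' @keywords internal
lp_solve <- function(obj, A_eq = NULL, b_eq = NULL, A_ub = NULL, b_ub = NULL,
                     lb = 0, ub = Inf, maximize = TRUE) {
  sp <- scipy_opt()
  n <- length(obj)
  bounds <- cbind(rep_len(lb, n), rep_len(ub, n))
  cc <- if (maximize) -obj else obj
  args <- list(c = cc, bounds = bounds, method = "highs")
  if (!is.null(A_eq)) {
    args$A_eq <- as.matrix(A_eq)
    args$b_eq <- as.numeric(b_eq)
  }
  if (!is.null(A_ub)) {
    args$A_ub <- as.matrix(A_ub)
    args$b_ub <- as.numeric(b_ub)
  }
  res <- do.call(sp$linprog, args)
  status <- switch(as.character(res$status),
                   "0" = "optimal", "2" = "infeasible", "3" = "unbounded",
                   "failed")
  list(status = status,
       value = if (status == "optimal") (if (maximize) -res$fun else res$fun) else NA_real_,
       x = if (status == "optimal") as.numeric(res$x) else NULL)
}

#' Solve a mixed-integer linear program
#'
#' Minimizes `obj %*% x` subject to `lhs <= A %*% x <= rhs`, box bounds and
#' integrality on the flagged variables, via HiGHS.
#'
#' @param obj objective coefficients (minimized).
#' @param A constraint matrix.
#' @param lhs,rhs constraint row bounds (`-Inf`/`Inf` for one-sided rows).
#' @param lb,ub variable bounds.
#' @param integer logical vector flagging integer variables.
#' @param time_limit optional wall-clock limit in seconds.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"time_limit"`,
#'   `"failed"`), `value` and `x`.
#' @keywords internal
milp_solve <- function(obj, A, lhs, rhs, lb, ub, integer,
                       time_limit = NULL) {
  sp <- scipy_opt()
  np <- .solver$np
  opts <- list(mip_rel_gap = 0, presolve = TRUE)
  if (!is.null(time_limit)) opts$time_limit <- as.numeric(time_limit)
  res <- sp$milp(
    c = as.numeric(obj),
    constraints = sp$LinearConstraint(as.matrix(A), as.numeric(lhs),
                                      as.numeric(rhs)),
    integrality = np$array(as.integer(integer)),
    bounds = sp$Bounds(as.numeric(lb), as.numeric(ub)),
    options = opts)
  status <- switch(as.character(res$status),
                   "0" = "optimal", "1" = "time_limit", "2" = "infeasible",
                   "3" = "unbounded", "failed")
  list(status = status,
       value = if (!is.null(res$x)) res$fun else NA_real_,
       x = if (!is.null(res$x)) as.numeric(res$x) else NULL)
}
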