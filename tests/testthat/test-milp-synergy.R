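toy <- figure1_toy()

test_that("the assembled instance has the prescribed variable structure", {
  inst <- build_milp(toy$model, toy$catalog, "v10")
  expect_equal(sum(inst$integer), 13)            # 10 y + 3 d binaries
  expect_length(inst$idx$z, 3)                   # one z per (target, drug)
  expect_length(inst$idx$delta, 3)
  expect_length(inst$idx$mu, 7)
  # v fixed to zero for the objective column
  expect_equal(inst$ub[inst$idx$v[match("v10", toy$model$reactions)]], 0)
  # a drug with two targets contributes two dual products
  m <- tmp_model(c("a1\t -> A\t0\t10\t\t", "a2\tA -> B\t0\t10\t\t",
                   "a3\tB -> \t0\t10\t\t"))
  cat2 <- build_catalog(mk_records("dd", list(c("a1", "a2"))), m,
                        beta_bar = 0)
  inst2 <- build_milp(m, cat2, "a3")
  expect_length(inst2$idx$z, 2)
  # degenerate instance: objective already blocked with no drugs
  m0 <- tmp_model(c("z1\t -> A\t0\t10\t\t", "z2\tA -> \t0\t0\t\t"))
  cat0 <- build_catalog(mk_records("dz", list("z1")), m0, beta_bar = 0)
  expect_error(build_milp(m0, cat0, "z1"), "degenerate")
})

test_that("the MILP reproduces the worked example and its single-drug facts", {
  sol <- solve_optimal_combination(toy$model, toy$catalog, "v10")
  expect_identical(sol$status, "optimal")
  expect_identical(sol$used_drugs, c("drug_v4", "drug_v7"))
  expect_equal(sol$sigma_oracle, 4)
  expect_true(sol$inner_ok)
  # neither valve alone stops the objective; the gateway drug stops all
  expect_gte(max_flux(toy$model, toy$catalog, "drug_v4", "v10"), 0.1)
  expect_gte(max_flux(toy$model, toy$catalog, "drug_v7", "v10"), 0.1)
  expect_setequal(blocked_reactions(toy$model, toy$catalog, "drug_v2"),
                  collapse_ids(toy$model, toy$model$reactions))
})

test_that("an unreachable objective is reported infeasible", {
  cat9 <- build_catalog(mk_records("d9", list("v9")), toy$model,
                        beta_bar = 0)
  sol <- solve_optimal_combination(toy$model, cat9, "v10")
  expect_identical(sol$status, "infeasible")
  expect_length(enumerate_solutions(toy$model, cat9, "v10"), 0)
})

test_that("a baseline-blocked objective needs no drugs", {
  m0 <- tmp_model(c("z1\t -> A\t0\t10\t\t", "z2\tA -> \t0\t0\t\t"))
  cat0 <- build_catalog(mk_records("dz", list("z1")), m0, beta_bar = 0)
  sol <- solve_optimal_combination(m0, cat0, "z1")
  expect_identical(sol$status, "optimal")
  expect_length(sol$used_drugs, 0)
  expect_equal(sol$sigma_oracle, 0)
})

test_that("enumeration walks suboptimal solutions until infeasibility", {
  sols <- enumerate_solutions(toy$model, toy$catalog, "v10")
  expect_length(sols, 2)
  expect_identical(sols[[1]]$used_drugs, c("drug_v4", "drug_v7"))
  expect_identical(sols[[2]]$used_drugs, "drug_v2")
  expect_true(sols[[1]]$sigma_milp <= sols[[2]]$sigma_milp)
  expect_length(enumerate_solutions(toy$model, toy$catalog, "v10",
                                    max_solutions = 1), 1)
  # no enumerated solution is a superset of an earlier one
  for (a in seq_along(sols)) {
    for (b in seq_len(a - 1)) {
      expect_false(all(sols[[b]]$used_drugs %in% sols[[a]]$used_drugs))
    }
  }
})

test_that("MILP optima match exhaustive search on random instances", {
  for (s in c(5, 23, 41)) {
    inst <- random_instance(random_instance_spec(seed = s))
    sol <- solve_optimal_combination(inst$model, inst$catalog,
                                     inst$objective)
    bf <- brute_force_optimum(inst$model, inst$catalog, inst$objective)
    expect_identical(sol$status == "optimal", bf$status == "optimal",
                     label = paste("feasibility, seed", s))
    if (bf$status == "optimal") {
      expect_equal(sol$sigma_oracle, bf$sigma, tolerance = 1e-9,
                   label = paste("sigma, seed", s))
    }
  }
})

test_that("no drug in an optimal set is redundant", {
  for (s in c(5, 23)) {
    inst <- random_instance(random_instance_spec(seed = s))
    sol <- solve_optimal_combination(inst$model, inst$catalog,
                                     inst$objective)
    if (sol$status != "optimal" || length(sol$used_drugs) < 2) next
    for (k in sol$used_drugs) {
      reduced <- setdiff(sol$used_drugs, k)
      still_blocks <- synflux:::blocks_objective(
        inst$model, inst$catalog, reduced, inst$objective, 0.1)
      if (still_blocks) {
        sig <- side_effect(inst$model, inst$catalog, reduced,
                           inst$objective)$sigma
        expect_gt(sig, sol$sigma_oracle - 1e-9)
      } else {
        succeed()
      }
    }
  }
  # the toy pair is irredundant outright
  sol <- solve_optimal_combination(toy$model, toy$catalog, "v10")
  for (k in sol$used_drugs) {
    expect_false(synflux:::blocks_objective(
      toy$model, toy$catalog, setdiff(sol$used_drugs, k), "v10", 0.1))
  }
})

test_that("verification certifies good solutions and exposes bad ones", {
  sol <- solve_optimal_combination(toy$model, toy$catalog, "v10")
  v <- verify_solution(toy$model, toy$catalog, sol)
  expect_true(v$ok)
  expect_length(v$discrepancies, 0)
  expect_lt(v$inner_max, 0.1)
  # a hand-built "solution" missing a required drug fails the inner check
  fake <- sol
  fake$used_drugs <- "drug_v4"
  vf <- verify_solution(toy$model, toy$catalog, fake)
  expect_false(vf$inner_ok)
  expect_false(vf$ok)
})

test_that("a reversible objective requires both net directions blocked", {
  m <- tmp_model(c(
    "x1\t -> A\t0\t10\t\t",
    "x2\tA -> B\t-8\t8\t\t",
    "x3\tB -> \t0\t10\t\t",
    "x4\t -> B\t0\t10\t\t",
    "x5\tA -> \t0\t10\t\t"))
  # x2 can run forward (A from x1) and backward (B from x4)
  cat1 <- build_catalog(mk_records(c("dA", "dB"), list("x1", "x4")), m,
                        beta_bar = 0)
  sol <- solve_optimal_combination(m, cat1, "x2")
  expect_identical(sol$status, "optimal")
  expect_setequal(sol$used_drugs, c("dA", "dB"))
  expect_true(sol$inner_ok)
  bf <- brute_force_optimum(m, cat1, "x2")
  expect_equal(sol$sigma_oracle, bf$sigma)
})
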