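toy <- figure1_toy()

test_that("a degenerate pair reproduces the single-network optimum", {
  pair <- network_pair(toy$model, toy$model, toy$records, beta_bar = 0)
  sel <- solve_selective(pair, "v10")
  sol <- solve_optimal_combination(toy$model, toy$catalog, "v10")
  expect_identical(sel$used_drugs, sol$used_drugs)
  expect_equal(sel$sigma_oracle, sol$sigma_oracle)
  for (s in c(11, 12, 13)) {
    inst <- random_instance(random_instance_spec(seed = s))
    p <- network_pair(inst$model, inst$model, inst$records,
                      beta_bar = inst$catalog$beta_bar)
    a <- solve_selective(p, inst$objective)
    b <- solve_optimal_combination(inst$model, inst$catalog,
                                   inst$objective)
    expect_identical(a$status, b$status, label = paste("seed", s))
    if (b$status == "optimal") {
      expect_equal(a$sigma_oracle, b$sigma_oracle, tolerance = 1e-9,
                   label = paste("seed", s))
    }
  }
})

test_that("a target-only pathway is hit with reference cost = beta only", {
  target <- tmp_model(c(
    "e1\t -> A\t0\t10\t\t",
    "t1\tA -> B\t0\t10\t\t",
    "t2\tB -> \t0\t10\t\t"))
  reference <- tmp_model(c(
    "h1\t -> C\t0\t10\t\t",
    "h2\tC -> \t0\t10\t\t"))
  rec <- mk_records("donly", list("t1"), n_nonmetabolic = 2)
  pair <- network_pair(target, reference, rec, beta_bar = 1)
  sel <- solve_selective(pair, "t2")
  expect_identical(sel$used_drugs, "donly")
  expect_equal(sel$sigma_oracle, 2)  # beta only; no reference reaction stops
  expect_length(sel$stopped_oracle, 0)
})

test_that("an uncorresponded objective is counted in the reference cost", {
  # identical networks, but the correspondence omits the objective, so the
  # stopped reference copy of it is charged to the side effect
  ids <- collapse_ids(toy$model, toy$model$reactions)
  corr <- data.frame(target_id = setdiff(ids, "v10"),
                     reference_id = setdiff(ids, "v10"))
  pair <- network_pair(toy$model, toy$model, toy$records,
                       correspondence = corr, beta_bar = 0)
  sel <- solve_selective(pair, "v10")
  expect_identical(sel$used_drugs, c("drug_v4", "drug_v7"))
  expect_equal(sel$sigma_oracle, 5)  # v3, v4, v7, v8 plus the v10 copy
})

test_that("selective enumeration yields non-decreasing reference cost", {
  pair <- network_pair(toy$model, toy$model, toy$records, beta_bar = 0)
  sols <- enumerate_selective(pair, "v10")
  expect_length(sols, 2)
  sig <- vapply(sols, function(s) s$sigma_oracle, 0)
  expect_true(!is.unsorted(sig))
  expect_length(enumerate_selective(pair, "v10", max_solutions = 0), 0)
})

test_that("additional-target deletions are screened and flagged", {
  pair <- network_pair(toy$model, toy$model, toy$records, beta_bar = 0)
  scr <- additional_target_screen(pair, "v10", milp_config(),
                                  c("v8", "v9", "v3"))
  expect_identical(scr$flag[scr$candidate == "v8"], "deletion_lethal")
  expect_identical(scr$drugs[scr$candidate == "v8"], "")
  # deleting the side branch leaves the optimum no better than baseline
  expect_identical(scr$flag[scr$candidate == "v9"], "unchanged")
  # deleting one parallel route lets a single drug finish the job
  expect_identical(scr$flag[scr$candidate == "v3"], "improved")
  expect_identical(scr$drugs[scr$candidate == "v3"], "drug_v7")
  expect_error(additional_target_screen(pair, "v10", milp_config(),
                                        "nope"), "not in target model")
})

test_that("a deletion can unlock an otherwise impossible inhibition", {
  # two parallel routes, only one druggable: no drug set blocks the
  # objective until the undruggable route is deleted
  target <- tmp_model(c(
    "e1\t -> A\t0\t10\t\t",
    "ra\tA -> B\t0\t10\t\t",
    "rb\tA -> B\t0\t10\t\t",
    "rout\tB -> \t0\t10\t\t"))
  rec <- mk_records("da", list("ra"))
  pair <- network_pair(target, target, rec, beta_bar = 0)
  base <- solve_selective(pair, "rout")
  expect_identical(base$status, "infeasible")
  scr <- additional_target_screen(pair, "rout", milp_config(), "rb")
  expect_identical(scr$flag, "new_inhibition")
  expect_identical(scr$drugs, "da")
})

test_that("candidates missing from the correspondence are flagged", {
  target <- tmp_model(c(
    "e1\t -> A\t0\t10\t\t",
    "ra\tA -> B\t0\t10\t\t",
    "rb\tA -> B\t0\t10\t\t",
    "rout\tB -> \t0\t10\t\t"))
  reference <- tmp_model(c(
    "e1\t -> A\t0\t10\t\t",
    "ra\tA -> B\t0\t10\t\t",
    "rout\tB -> \t0\t10\t\t"))
  rec <- mk_records("da", list("ra"))
  pair <- network_pair(target, reference, rec, beta_bar = 0)
  scr <- additional_target_screen(pair, "rout", milp_config(), "rb")
  expect_true(scr$no_reference_correspondence)
  expect_identical(scr$flag, "new_inhibition")
})

test_that("deleting a reaction never shrinks the blocked set", {
  inst <- random_instance(random_instance_spec(seed = 17))
  drugs <- names(inst$catalog$targets)[1]
  before <- blocked_reactions(inst$model, inst$catalog, drugs)
  victims <- setdiff(collapse_ids(inst$model, inst$model$reactions),
                     before)[1:3]
  for (v in victims) {
    m2 <- synflux:::with_reactions_off(inst$model, v)
    after <- blocked_reactions(m2, inst$catalog, drugs)
    expect_true(all(before %in% after), label = v)
  }
})

test_that("pair specifications load from JSON", {
  dir <- withr::local_tempdir()
  write_model_tsv(toy$model, file.path(dir, "target.tsv"))
  write_model_tsv(toy$model, file.path(dir, "reference.tsv"))
  write_drug_tsv(toy$records, file.path(dir, "drugs.tsv"))
  jsonlite::write_json(list(target_model = "target.tsv",
                            reference_model = "reference.tsv",
                            drug_table = "drugs.tsv"),
                       file.path(dir, "pair.json"), auto_unbox = TRUE)
  pair <- read_network_pair(file.path(dir, "pair.json"), beta_bar = 0)
  sel <- solve_selective(pair, "v10")
  expect_identical(sel$used_drugs, c("drug_v4", "drug_v7"))
})
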