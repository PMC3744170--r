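test_that("tabular loader reports counts and catches malformed input", {
  raw <- tmp_raw_model(c(
    "t1\t -> A\t0\t10\t\t",
    "t2\tA -> B\t0\t5\t\t",
    "t3\tB -> C\t-2\t5\t\t",
    "t4\tC -> \t0\t10\t\t"))
  expect_s3_class(raw, "raw_model")
  expect_length(raw$metabolites, 3)
  expect_length(raw$reactions, 4)
  expect_equal(unname(raw$lb[["t3"]]), -2)

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tequation\tlower\tupper", "a\t -> X\t0\t1", "a\tX -> \t0\t1"),
             dup)
  expect_error(load_model(dup, "tabular"), "duplicate reaction id")

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tequation\tlower\tupper", "a\tX -> -> Y\t0\t1"), bad)
  expect_error(load_model(bad, "tabular"), "equation")
})

test_that("a reaction referencing an undeclared metabolite is rejected", {
  rx <- withr::local_tempfile(fileext = ".tsv")
  mt <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tequation\tlower\tupper", "a\t -> X\t0\t1",
               "b\tX -> Z\t0\t1"), rx)
  writeLines(c("id\tcompartment", "X\tc"), mt)
  expect_error(load_model(rx, "tabular", metabolites_path = mt),
               "undeclared metabolite.*Z")
})

test_that("split_reversible decomposes, caps, and registers twins", {
  raw <- tmp_raw_model(c(
    "f1\t -> A\t0\t10\t\t",
    "f2\tA -> B\t-5\t10\t\t",
    "f3\tB -> \t-Inf\tInf\t\t"))
  m <- split_reversible(raw, default_cap = 1000)
  expect_setequal(m$reactions, c("f1", "f2", "f3", "f2_rev", "f3_rev"))
  expect_equal(unname(m$ub[c("f2", "f2_rev")]), c(10, 5))
  expect_equal(unname(m$ub[c("f3", "f3_rev")]), c(1000, 1000))
  expect_equal(unname(m$rev_pair[["f2"]]), "f2_rev")
  expect_equal(unname(m$rev_pair[["f2_rev"]]), "f2")
  expect_equal(as.numeric(m$S[, "f2"] + m$S[, "f2_rev"]), c(0, 0))
  # already-irreversible model passes through unchanged
  raw2 <- tmp_raw_model(c("g1\t -> A\t0\t10\t\t", "g2\tA -> \t0\t10\t\t"))
  m2 <- split_reversible(raw2)
  expect_identical(m2$reactions, c("g1", "g2"))
  expect_length(m2$rev_pair, 0)
  # idempotent on the canonical form
  expect_identical(split_reversible(m), m)
})

test_that("splitting preserves attainable net fluxes in both directions", {
  raw <- tmp_raw_model(c(
    "e_in\t -> A\t0\t8\t\t",
    "c1\tA -> B\t-6\t9\t\t",
    "c2\tB -> C\t-3\t7\t\t",
    "e_b\t -> B\t0\t2\t\t",
    "e_out\tC -> \t0\t10\t\t"))
  m <- split_reversible(raw)
  # oracle: raw-model LP with signed bounds vs split-model net maximum
  raw_net_max <- function(j, sign) {
    obj <- numeric(length(raw$reactions)); obj[j] <- sign
    r <- synflux:::lp_solve(obj, A_eq = raw$S,
                            b_eq = rep(0, length(raw$metabolites)),
                            lb = raw$lb, ub = raw$ub, maximize = TRUE)
    r$value
  }
  dummy <- structure(list(targets = list(), beta = numeric()),
                     class = "drug_catalog")
  for (j in seq_along(raw$reactions)) {
    id <- raw$reactions[j]
    expect_equal(max_flux(m, dummy, character(), id),
                 max(0, raw_net_max(j, 1)), tolerance = 1e-7, label = id)
    if (raw$lb[j] < 0) {
      expect_equal(max_flux(m, dummy, character(), paste0(id, "_rev")),
                   max(0, raw_net_max(j, -1)), tolerance = 1e-7,
                   label = paste0(id, "_rev"))
    }
  }
})

test_that("validate_model reports broken invariants and passes clean models", {
  toy <- figure1_toy()
  expect_length(validate_model(toy$model), 0)

  m <- tmp_model(c("h1\t -> A\t-4\t10\t\t", "h2\tA -> \t0\t10\t\t"))
  expect_length(validate_model(m), 0)
  bad <- m
  bad$S[1, "h1_rev"] <- -2  # twin no longer an exact negation
  rep <- validate_model(bad)
  expect_true(any(grepl("h1", rep) & grepl("negation", rep)))
  bad2 <- m
  bad2$ub[["h2"]] <- -1
  expect_true(any(grepl("h2", validate_model(bad2))))
})

test_that("JSON and tabular serializations round-trip the canonical model", {
  m <- tmp_model(c(
    "j1\t -> A\t0\t10\tupt\t1.2.3.4",
    "j2\tA -> B\t-5\t10\tcore\t",
    "j3\tB -> \t0\t10\tout\t"))
  m2 <- model_from_json(model_to_json(m))
  expect_identical(m2$reactions, m$reactions)
  expect_equal(unname(m2$ub), unname(m$ub))
  expect_identical(unname(m2$rev_pair["j2"]), "j2_rev")
  expect_equal(as.matrix(m2$S), as.matrix(m$S), ignore_attr = TRUE)
  expect_identical(m2$ec[["j1"]], "1.2.3.4")

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_model_tsv(m, tsv)
  m3 <- split_reversible(load_model(tsv, "tabular"))
  expect_identical(sort(m3$reactions), sort(m$reactions))
  expect_equal(m3$ub[m$reactions], m$ub)
})

test_that("SBML writer/reader round-trips models including reversibility", {
  toy <- figure1_toy()
  f <- withr::local_tempfile(fileext = ".xml")
  write_sbml(toy$model, f)
  raw <- read_sbml(f)
  expect_length(raw$reactions, 10)
  expect_length(raw$metabolites, 7)
  m2 <- split_reversible(raw)
  expect_equal(m2$ub[toy$model$reactions], toy$model$ub)
  expect_identical(unname(m2$ec[["v2"]]), "1.1.1.1")
  expect_identical(unname(m2$pathway[["v3"]]), "branch1")

  raw0 <- tmp_raw_model(c("k1\t -> A\t-5\t10\t\t", "k2\tA -> \t0\tInf\t\t"))
  f2 <- withr::local_tempfile(fileext = ".xml")
  write_sbml(raw0, f2)
  rt <- read_sbml(f2)
  expect_equal(unname(rt$lb[["k1"]]), -5)
  expect_equal(unname(rt$ub[["k2"]]), Inf)
})

test_that("Level 3 fbc bounds and boundary species are understood", {
  sbml <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    '<model id="m">',
    '<listOfCompartments><compartment id="c"/></listOfCompartments>',
    '<listOfSpecies>',
    '<species id="A" compartment="c"/>',
    '<species id="Xb" compartment="c" boundaryCondition="true"/>',
    '</listOfSpecies>',
    '<listOfParameters>',
    '<parameter id="lbm" value="-12"/><parameter id="ubm" value="34"/>',
    '</listOfParameters>',
    '<listOfReactions>',
    '<reaction id="q1" reversible="true" lowerFluxBound="lbm" upperFluxBound="ubm">',
    '<listOfReactants><speciesReference species="Xb" stoichiometry="1"/></listOfReactants>',
    '<listOfProducts><speciesReference species="A" stoichiometry="1"/></listOfProducts>',
    '</reaction>',
    '<reaction id="q2" reversible="false">',
    '<listOfReactants><speciesReference species="A" stoichiometry="2"/></listOfReactants>',
    '</reaction>',
    '</listOfReactions>',
    '</model></sbml>')
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines(sbml, f)
  raw <- read_sbml(f)
  expect_identical(raw$metabolites, "A")  # boundary species dropped
  expect_equal(unname(raw$lb[["q1"]]), -12)
  expect_equal(unname(raw$ub[["q1"]]), 34)
  expect_equal(unname(raw$lb[["q2"]]), 0)
  expect_equal(as.numeric(raw$S["A", ]), c(1, -2))
})
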