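toy <- figure1_toy()

test_that("single-drug effects are computed once per drug", {
  eff <- single_drug_effects(toy$model, toy$catalog)
  expect_setequal(eff$drug_v2,
                  collapse_ids(toy$model, toy$model$reactions))
  expect_setequal(eff$drug_v7, "v7")
  eff2 <- single_drug_effects(toy$model, toy$catalog)
  expect_identical(eff, eff2)
  # a drug with no targets leaves only the baseline blocked
  cat0 <- toy$catalog
  cat0$targets$inert <- character()
  cat0$beta <- c(cat0$beta, inert = 0)
  expect_length(single_drug_effects(toy$model, cat0)$inert, 0)
})

test_that("the whole-network screen classifies every reaction", {
  scr <- screen_all_objectives(toy$model, toy$catalog)
  expect_equal(nrow(scr), 10)
  expect_false(anyNA(scr$outcome))
  classes <- c("single_only", "new_inhibition", "more_selective",
               "less_selective", "unblockable", "baseline_blocked")
  expect_true(all(scr$outcome %in% classes))
  # the objective of the worked example is a more-selective case: the
  # two-drug valve pair beats the broad gateway drug
  expect_identical(scr$outcome[scr$objective == "v10"], "more_selective")
  expect_identical(scr$multi_drugs[scr$objective == "v10"],
                   "drug_v4+drug_v7")
  expect_equal(scr$ratio[scr$objective == "v10"], 50)
  # classification agrees with a direct oracle recomputation
  for (i in which(scr$outcome %in% c("more_selective", "less_selective"))) {
    expect_identical(scr$outcome[i],
                     if (scr$multi_sigma[i] < scr$best_single_sigma[i])
                       "more_selective" else "less_selective")
  }
  # a reaction blocked at baseline is flagged and not classified
  m0 <- tmp_model(c("c1\t -> A\t0\t10\t\t", "c2\tA -> \t0\t0\t\t",
                    "c3\tA -> \t0\t10\t\t"))
  cat0 <- build_catalog(mk_records("dc", list("c1")), m0, beta_bar = 0)
  scr0 <- screen_all_objectives(m0, cat0)
  expect_identical(scr0$outcome[scr0$objective == "c2"], "baseline_blocked")
})

test_that("new inhibitions are recognized when no single drug suffices", {
  # drop the broad gateway drug: only the valve pair can stop v10
  rec <- toy$records[toy$records$drug_id != "drug_v2", , drop = FALSE]
  cat2 <- build_catalog(rec, toy$model, beta_bar = 0)
  scr <- screen_all_objectives(toy$model, cat2)
  expect_identical(scr$outcome[scr$objective == "v10"], "new_inhibition")
  expect_identical(scr$outcome[scr$objective == "v1"], "unblockable")
  # a blocking single plus any second drug still blocks, so with several
  # drugs available the multi arm exists and the single is just better
  expect_identical(scr$outcome[scr$objective == "v4"], "less_selective")
  # with a one-drug catalog no multi-drug arm can exist at all
  rec1 <- toy$records[toy$records$drug_id == "drug_v2", , drop = FALSE]
  cat1 <- build_catalog(rec1, toy$model, beta_bar = 0)
  scr1 <- screen_all_objectives(toy$model, cat1)
  expect_true(all(scr1$outcome == "single_only"))
})

test_that("synergy ratios are truncated percentages", {
  expect_equal(synergy_ratio(11.0, 5), 45.4)
  expect_equal(synergy_ratio(363.8, 91), 25.0)
  expect_equal(synergy_ratio(298.9, 52), 17.3)
  expect_equal(synergy_ratio(116.0, 6), 5.1)
  expect_equal(synergy_ratio(7, 0), 0)
  expect_error(synergy_ratio(0, 3), "undefined")
})

test_that("profile distances satisfy the metric axioms", {
  mk_prof <- function(Y, universe) {
    structure(list(combination = paste0("c", paste(Y, collapse = "")),
                   Y = Y, s = stats::setNames(as.integer(universe %in% Y),
                                              universe),
                   reactions = universe), class = "synergy_profile")
  }
  u <- paste0("r", 1:6)
  pa <- mk_prof(c("r1", "r2"), u)
  pb <- mk_prof(c("r2", "r3"), u)
  pc <- mk_prof(character(), u)
  D <- distance_matrix(list(pa, pb, pa, pc), metric = "jaccard")
  expect_equal(D[1, 3], 0)
  expect_equal(D[1, 2], 2 / 3)
  expect_equal(D[1, 4], 1)       # empty vs non-empty
  expect_equal(D[4, 4], 0)
  expect_true(isSymmetric(D))
  H <- distance_matrix(list(pa, pb), metric = "hamming")
  expect_equal(H[1, 2], 2)
  # triangle inequality on random profiles under a fixed seed
  set.seed(42)
  profs <- lapply(1:6, function(i) mk_prof(sample(u, sample(0:4, 1)), u))
  DJ <- distance_matrix(profs, "jaccard")
  for (a in 1:6) for (b in 1:6) for (cc in 1:6) {
    expect_lte(DJ[a, b], DJ[a, cc] + DJ[cc, b] + 1e-12)
  }
  expect_error(distance_matrix(list(pa)), "at least two")
})

test_that("cluster trees group identical profiles as sisters", {
  D <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1, 0), 3, 3,
              dimnames = list(c("p1", "p2", "p3"), c("p1", "p2", "p3")))
  tr <- cluster_tree(D)
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("p1", "p2", "p3"))
  coph <- ape::cophenetic.phylo(tr)
  expect_lt(coph["p1", "p2"], coph["p1", "p3"])
  expect_equal(unname(cut_synergy_classes(D, h = 0.5)),
               c(1, 1, 2), ignore_attr = TRUE)
  # newick serialization round-trips through ape
  f <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(tr, f)
  expect_setequal(ape::read.tree(f)$tip.label, tr$tip.label)
  expect_error(cluster_tree(D[1, 1, drop = FALSE]), "at least two")
  expect_s3_class(cluster_tree(D, "nj"), "phylo")
})

test_that("the drug proximity network links co-members as cliques", {
  prof_pair <- synergy_profile(toy$model, toy$catalog,
                               c("drug_v4", "drug_v7"))
  g1 <- drug_proximity_network(list(prof_pair), toy$catalog, toy$model)
  expect_equal(igraph::gorder(g1), 2)
  expect_equal(igraph::gsize(g1), 1)
  expect_equal(igraph::E(g1)$weight, 2)  # |Y| of the pair
  expect_equal(unname(igraph::V(g1)$n_targets), c(1, 1))
  # a triple contributes a triangle; sharing a drug joins components
  fake3 <- structure(list(combination = c("drug_v2", "drug_v4", "drug_v7"),
                          Y = c("v8"), s = NULL,
                          reactions = NULL), class = "synergy_profile")
  g2 <- drug_proximity_network(list(fake3), toy$catalog, toy$model)
  expect_equal(igraph::gsize(g2), 3)
  g3 <- drug_proximity_network(list(prof_pair, fake3), toy$catalog,
                               toy$model)
  comp <- igraph::components(g3)
  expect_equal(comp$no, 1)
  expect_gte(comp$csize[1], 3)
})

test_that("screen and graph tables are written as readable TSV", {
  scr <- screen_all_objectives(toy$model, toy$catalog)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_screen_tsv(scr, f)
  back <- utils::read.delim(f)
  expect_equal(nrow(back), nrow(scr))
  expect_true("outcome" %in% names(back))
  prof <- synergy_profile(toy$model, toy$catalog, c("drug_v4", "drug_v7"))
  g <- drug_proximity_network(list(prof), toy$catalog, toy$model)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_graph_tsv(g, f2)
  expect_equal(nrow(utils::read.delim(f2)), 1)
})
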