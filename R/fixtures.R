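# Synthetic instances: a small hand-built branched network with three
# drug-controllable valves (the canonical worked example), seeded random
# branched-pathway instances for property and equivalence suites, and a
# capacity-bottleneck construction exposing the simultaneity gap between
# per-reaction and single-flux-vector blocking counts.

local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

model_from_table <- function(lines, default_cap = 1000) {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  split_reversible(load_model(tmp, "tabular"), default_cap)
}

records_df <- function(drug_id, targets, n_nonmetabolic = 0,
                       approved = TRUE, name = drug_id) {
  data.frame(drug_id = drug_id, name = name,
             approved = rep_len(approved, length(drug_id)),
             ec = I(rep(list(character()), length(drug_id))),
             direct_targets = I(targets),
             n_nonmetabolic = rep_len(as.integer(n_nonmetabolic),
                                      length(drug_id)),
             stringsAsFactors = FALSE)
}

#' The ten-reaction worked example
#'
#' A branched pathway with an uptake `v1`, a gateway `v2`, two parallel
#' routes to the precursor of the objective (`v3`/`v4` and `v5`/`v7`), a
#' side branch (`v6`, `v9`) and the objective export `v10`. Drugs sit at
#' `v2`, `v4` and `v7`; all beta weights are zero. By construction: a drug
#' at `v4` or `v7` alone leaves the objective running, the drug at `v2`
#' stops every reaction of the network, and the pair `{drug_v4, drug_v7}`
#' blocks the objective with minimal side effect.
#'
#' @return list with `model`, `catalog`, `objective` (`"v10"`) and the
#'   drug `records`.
#' @export
figure1_toy <- function() {
  lines <- c(
    "id\tequation\tlower\tupper\tpathway\tec",
    "v1\t -> A\t0\t10\tuptake\t",
    "v2\tA -> B\t0\t10\tcore\t1.1.1.1",
    "v3\tB -> C\t0\t10\tbranch1\t",
    "v4\tC -> E\t0\t10\tbranch1\t2.2.2.2",
    "v5\tB -> D\t0\t10\tbranch2\t",
    "v6\tD -> F\t0\t10\tside\t",
    "v7\tD -> E\t0\t10\tbranch2\t3.3.3.3",
    "v8\tE -> G\t0\t10\tcore\t",
    "v9\tF -> \t0\t10\tside\t",
    "v10\tG -> \t0\t10\tobjective\t")
  model <- model_from_table(lines)
  records <- records_df(c("drug_v2", "drug_v4", "drug_v7"),
                        list("v2", "v4", "v7"))
  catalog <- build_catalog(records, model, beta_bar = 0)
  list(model = model, catalog = catalog, objective = "v10",
       records = records)
}

#' Specification of a random instance
#'
#' @param n_metabolites number of metabolites in the backbone.
#' @param n_internal number of internal conversion reactions.
#' @param n_exchange number of uptake/export reactions beyond those needed
#'   to make every metabolite producible and consumable.
#' @param reversible_fraction fraction of internal reactions made
#'   reversible before canonicalization.
#' @param n_drugs catalog size.
#' @param targets_per_drug integer range `c(min, max)` of targets per drug.
#' @param nonmetabolic_range integer range of non-metabolic target counts.
#' @param seed RNG seed; the instance is a deterministic function of the
#'   spec.
#' @return a `random_instance_spec`.
#' @export
random_instance_spec <- function(n_metabolites = 12, n_internal = 16,
                                 n_exchange = 4, reversible_fraction = 0.15,
                                 n_drugs = 6, targets_per_drug = c(1, 3),
                                 nonmetabolic_range = c(0, 2), seed = 1) {
  stopifnot(n_metabolites >= 3, n_internal >= 3, n_exchange >= 0,
            reversible_fraction >= 0, reversible_fraction <= 1,
            n_drugs >= 0, targets_per_drug[1] >= 1,
            targets_per_drug[2] >= targets_per_drug[1])
  structure(list(n_metabolites = n_metabolites, n_internal = n_internal,
                 n_exchange = n_exchange,
                 reversible_fraction = reversible_fraction,
                 n_drugs = n_drugs, targets_per_drug = targets_per_drug,
                 nonmetabolic_range = nonmetabolic_range, seed = seed),
            class = "random_instance_spec")
}

#' Generate a seeded random instance
#'
#' Builds a random branched pathway DAG (metabolites ordered, reactions
#' convert earlier to later metabolites, uptakes feed the head and every
#' dead-end metabolite gets an export) so that steady-state flux from
#' uptake to export exists, picks an internal objective reaction carrying
#' comfortable baseline flux, and assigns each drug a random set of
#' internal target reactions. The full catalog pipeline (including the
#' oracle beta-bar estimate) is run on the generated records.
#'
#' @param spec a [random_instance_spec()].
#' @return list with `model`, `catalog`, `objective`, `records`, `spec`.
#' @export
random_instance <- function(spec = random_instance_spec()) {
  stopifnot(inherits(spec, "random_instance_spec"))
  local_seed(spec$seed, {
    for (attempt in seq_len(100)) {
      inst <- try(generate_instance_once(spec), silent = TRUE)
      if (!inherits(inst, "try-error") && !is.null(inst)) return(inst)
    }
    stop("could not generate a flux-carrying objective in 100 attempts")
  })
}

# sample() that never interprets a scalar as 1:n
resample <- function(x, size = 1, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

generate_instance_once <- function(spec) {
  n_m <- spec$n_metabolites
  mets <- sprintf("M%02d", seq_len(n_m))
  eqs <- character(); ids <- character(); lo <- numeric(); up <- numeric()
  pw <- character()
  add <- function(id, eq, l, u, p) {
    ids <<- c(ids, id); eqs <<- c(eqs, eq); lo <<- c(lo, l); up <<- c(up, u)
    pw <<- c(pw, p)
  }
  # uptakes into the head of the ordering
  head_pool <- max(2, floor(n_m / 3))
  n_in <- min(max(1, ceiling(spec$n_exchange / 2)), head_pool)
  heads <- sort(sample.int(head_pool, n_in, replace = FALSE))
  for (i in seq_along(heads)) {
    add(sprintf("EX_in%d", i), paste("->", mets[heads[i]]), 0, 10, "exchange")
  }
  internal_ids <- character()
  for (i in seq_len(spec$n_internal)) {
    n_sub <- if (stats::runif(1) < 0.8) 1 else 2
    subs <- sort(sample.int(n_m - 1, n_sub))
    prod <- resample((max(subs) + 1):n_m)
    coef <- function() if (stats::runif(1) < 0.85) "" else "2 "
    lhs <- paste(paste0(vapply(subs, function(s) coef(), ""), mets[subs]),
                 collapse = " + ")
    eq <- paste(lhs, "->", paste0(coef(), mets[prod]))
    u <- round(stats::runif(1, 5, 15), 1)
    rev <- stats::runif(1) < spec$reversible_fraction
    id <- sprintf("R%02d", i)
    internal_ids <- c(internal_ids, id)
    add(id, eq, if (rev) -u else 0, u, sprintf("pw%d", 1 + (i %% 4)))
  }
  # exports for metabolites nothing consumes; uptakes for unproduced ones
  produced <- heads; consumed <- integer()
  for (e in eqs[-seq_along(heads)]) {
    sides <- parse_equation(e)
    consumed <- c(consumed, match(names(sides$substrates), mets))
    produced <- c(produced, match(names(sides$products), mets))
  }
  n_out <- 0
  for (k in setdiff(seq_len(n_m), unique(consumed))) {
    n_out <- n_out + 1
    add(sprintf("EX_out%d", n_out), paste(mets[k], "-> "), 0, 10, "exchange")
  }
  for (k in setdiff(seq_len(n_m), unique(produced))) {
    n_in <- n_in + 1
    add(sprintf("EX_in%d", n_in), paste("->", mets[k]), 0, 10, "exchange")
  }
  # a few extra exports from the tail for redundancy
  extra <- spec$n_exchange - n_in - n_out
  if (extra > 0) {
    for (k in resample(seq_len(n_m), min(extra, n_m))) {
      n_out <- n_out + 1
      add(sprintf("EX_out%d", n_out), paste(mets[k], "-> "), 0, 10, "exchange")
    }
  }
  tab <- c("id\tequation\tlower\tupper\tpathway\tec",
           paste(ids, eqs, lo, up, pw, "", sep = "\t"))
  model <- model_from_table(tab)
  dummy <- structure(list(drugs = data.frame(), targets = list(),
                          beta = numeric()), class = "drug_catalog")
  # objective: a late internal reaction with comfortable baseline flux
  cand <- rev(internal_ids)
  objective <- NULL
  for (p in cand) {
    if (max_flux(model, dummy, character(), p) >= 0.5) {
      objective <- p
      break
    }
  }
  if (is.null(objective)) return(NULL)
  if (spec$n_drugs == 0) {
    catalog <- structure(list(drugs = records_df(character(), list()),
                              targets = stats::setNames(list(), character()),
                              beta = stats::setNames(numeric(), character()),
                              beta_bar = 0, group_members = list()),
                         class = "drug_catalog")
    return(list(model = model, catalog = catalog, objective = objective,
                records = records_df(character(), list()), spec = spec))
  }
  tg <- lapply(seq_len(spec$n_drugs), function(i) {
    k <- resample(seq.int(spec$targets_per_drug[1],
                          spec$targets_per_drug[2]))
    resample(internal_ids, min(k, length(internal_ids)))
  })
  nn <- resample(seq.int(spec$nonmetabolic_range[1],
                         spec$nonmetabolic_range[2]),
                 spec$n_drugs, replace = TRUE)
  records <- records_df(sprintf("D%02d", seq_len(spec$n_drugs)), tg,
                        n_nonmetabolic = nn)
  catalog <- build_catalog(records, model)
  if (!nrow(catalog$drugs)) return(NULL)
  list(model = model, catalog = catalog, objective = objective,
       records = records, spec = spec)
}

#' Capacity-bottleneck fixture exposing the simultaneity gap
#'
#' A shared uptake of capacity 0.15 feeds two branches that can each
#' individually sustain the activity threshold (0.1) but not both at
#' once; a separate drug-controllable pathway carries the objective.
#' The per-reaction blocking oracle leaves both branches unblocked, while
#' any single steady-state flux vector must starve one of them, so the
#' MILP's simultaneous stopped-reaction count exceeds the oracle count and
#' [verify_solution()] reports the discrepancy.
#'
#' @return list with `model`, `catalog`, `objective` (`"b7"`) and the
#'   branch reaction ids (`"b2"`,`"b3"`,`"b4"`,`"b5"`).
#' @export
bottleneck_fixture <- function() {
  lines <- c(
    "id\tequation\tlower\tupper\tpathway\tec",
    "b1\t -> A\t0\t0.15\tbottleneck\t",
    "b2\tA -> B\t0\t10\tbranch\t",
    "b3\tA -> C\t0\t10\tbranch\t",
    "b4\tB -> \t0\t10\tbranch\t",
    "b5\tC -> \t0\t10\tbranch\t",
    "b6\t -> E\t0\t10\tdruggable\t",
    "b7\tE -> \t0\t10\tobjective\t")
  model <- model_from_table(lines)
  records <- records_df("drug_b6", list("b6"))
  catalog <- build_catalog(records, model, beta_bar = 0)
  list(model = model, catalog = catalog, objective = "b7",
       branches = c("b2", "b3", "b4", "b5"))
}
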