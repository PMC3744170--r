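# Results-stage procedures: screen every reaction as a potential objective,
# classify the outcome against the precomputed single-drug effects, and
# characterize the synergisms (synergy ratio, distances, cluster tree,
# drug proximity network).

#' Blocked set of every single drug
#'
#' Evaluates the inhibitory effect of each drug alone on the whole network
#' once, for reuse across the screen.
#'
#' @inheritParams blocked_reactions
#' @return named list: drug id -> blocked parent reaction ids.
#' @export
single_drug_effects <- function(model, catalog, epsilon = 0.1) {
  drugs <- names(catalog$targets)
  stats::setNames(lapply(drugs, function(k) {
    blocked_reactions(model, catalog, k, epsilon)
  }), drugs)
}

#' Screen every reaction as a potential objective
#'
#' For each (collapsed) reaction that carries flux at baseline, searches
#' the most selective blocking drug combination and classifies the
#' outcome: `single_only` (only single drugs block it), `new_inhibition`
#' (no single drug blocks it but a combination does), `more_selective`
#' (the best multi-drug combination has a smaller side effect than the
#' best single drug), `less_selective` (it has a larger or equal one), or
#' `unblockable`. Reactions blocked at baseline are flagged
#' `baseline_blocked` and not screened. The multi-drug arm is the MILP
#' optimum restricted to at least two used drugs; all side effects are
#' oracle-recomputed.
#'
#' @inheritParams solve_optimal_combination
#' @return a data.frame (class `synergy_screen`) with one row per
#'   reaction: `objective`, `pathway`, `outcome`, `best_single_sigma`,
#'   `multi_drugs`, `multi_sigma`, `n_synergy`, `ratio`. Multi-drug
#'   synergy profiles are attached as attribute `"profiles"`.
#' @export
screen_all_objectives <- function(model, catalog, config = milp_config()) {
  eps <- config$epsilon
  baseline <- blocked_reactions(model, catalog, character(), eps)
  singles <- single_drug_effects(model, catalog, eps)
  parents <- collapse_ids(model, model$reactions)
  rows <- vector("list", length(parents))
  profiles <- list()
  for (i in seq_along(parents)) {
    p <- parents[i]
    pw <- unname(model$pathway[[match(p, model$reactions)]])
    row <- data.frame(objective = p, pathway = pw %||% NA_character_,
                      outcome = NA_character_,
                      best_single_sigma = NA_real_,
                      multi_drugs = NA_character_, multi_sigma = NA_real_,
                      n_synergy = NA_integer_, ratio = NA_real_,
                      stringsAsFactors = FALSE)
    if (p %in% baseline) {
      row$outcome <- "baseline_blocked"
      rows[[i]] <- row
      next
    }
    blockers <- names(singles)[vapply(singles, function(b) p %in% b,
                                      logical(1))]
    best_single <- NA_real_
    if (length(blockers)) {
      sig <- vapply(blockers, function(k) {
        side_effect(model, catalog, k, p, eps)$sigma
      }, numeric(1))
      best_single <- min(sig)
    }
    multi <- tryCatch(
      solve_optimal_combination(model, catalog, p, config, min_drugs = 2,
                                baseline = baseline),
      error = function(e) {
        warning("solver failure for objective ", p, ": ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
    has_multi <- !is.null(multi) && multi$status == "optimal" &&
      length(multi$used_drugs) >= 2
    if (has_multi) {
      row$multi_drugs <- paste(multi$used_drugs, collapse = "+")
      row$multi_sigma <- multi$sigma_oracle
      prof <- synergy_profile(model, catalog, multi$used_drugs, eps)
      profiles[[p]] <- prof
      row$n_synergy <- length(prof$Y)
      row$ratio <- if (multi$sigma_oracle > 0) {
        synergy_ratio(multi$sigma_oracle, length(prof$Y))
      } else NA_real_
    }
    row$best_single_sigma <- best_single
    row$outcome <-
      if (!length(blockers) && !has_multi) "unblockable"
      else if (length(blockers) && !has_multi) "single_only"
      else if (!length(blockers)) "new_inhibition"
      else if (row$multi_sigma < best_single) "more_selective"
      else "less_selective"
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  class(out) <- c("synergy_screen", "data.frame")
  attr(out, "profiles") <- profiles
  attr(out, "baseline_blocked") <- intersect(parents, baseline)
  out
}

#' Synergy ratio of a combination
#'
#' 100 * |Y| / sigma, truncated (not rounded) to one decimal, matching the
#' convention of the reported synergism tables.
#'
#' @param sigma side effect of the combination (> 0).
#' @param n_synergy size of the synergy set Y.
#' @return percentage with one decimal.
#' @export
synergy_ratio <- function(sigma, n_synergy) {
  if (sigma <= 0) stop("synergy ratio undefined for sigma <= 0")
  floor(1000 * n_synergy / sigma) / 10
}

#' Distance matrix between synergy profiles
#'
#' Jaccard (default) or Hamming distances between the synergy sets Y of a
#' list of profiles over a common reaction universe. Two empty sets are at
#' distance 0; an empty and a non-empty set at Jaccard distance 1.
#'
#' @param profiles list of `synergy_profile` objects.
#' @param metric `"jaccard"` or `"hamming"` (count of differing reactions).
#' @return symmetric matrix with zero diagonal, labeled by the
#'   combinations.
#' @export
distance_matrix <- function(profiles, metric = c("jaccard", "hamming")) {
  metric <- match.arg(metric)
  if (length(profiles) < 2) stop("need at least two profiles")
  universe <- profiles[[1]]$reactions
  for (p in profiles) {
    if (!identical(p$reactions, universe)) {
      stop("profiles are not over the same reaction universe")
    }
  }
  labs <- vapply(profiles, function(p) paste(p$combination, collapse = "+"),
                 "")
  n <- length(profiles)
  D <- matrix(0, n, n, dimnames = list(labs, labs))
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      Ya <- profiles[[a]]$Y; Yb <- profiles[[b]]$Y
      d <- if (metric == "jaccard") {
        u <- length(union(Ya, Yb))
        if (u == 0) 0 else 1 - length(intersect(Ya, Yb)) / u
      } else {
        length(setdiff(Ya, Yb)) + length(setdiff(Yb, Ya))
      }
      D[a, b] <- d; D[b, a] <- d
    }
  }
  D
}

#' Cluster tree of synergy profiles
#'
#' Hierarchical distance-based tree over the synergisms (the layout used
#' for phylogenetic trees): average-linkage by default, neighbor-joining
#' optionally. The returned `phylo` object carries the underlying
#' `hclust` (average linkage only) as attribute for flat class cuts, and
#' can be serialized with [ape::write.tree()].
#'
#' @param D distance matrix from [distance_matrix()].
#' @param method `"average"` (UPGMA) or `"nj"` (neighbor joining).
#' @return an `ape` `phylo` tree with the profiles at the leaves.
#' @export
cluster_tree <- function(D, method = c("average", "nj")) {
  method <- match.arg(method)
  if (nrow(D) < 2) stop("need at least two leaves")
  if (method == "nj") {
    if (nrow(D) < 3) stop("neighbor joining needs at least three leaves")
    return(ape::nj(stats::as.dist(D)))
  }
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  tr <- ape::as.phylo(hc)
  attr(tr, "hclust") <- hc
  tr
}

#' Flat synergy classes from the cluster tree
#'
#' Cuts the average-linkage tree at a distance threshold to label classes
#' of synergisms sharing a mechanism.
#'
#' @param D distance matrix.
#' @param h cut height (distance threshold).
#' @return named integer vector of class labels.
#' @export
cut_synergy_classes <- function(D, h) {
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  stats::cutree(hc, h = h)
}

#' Drug proximity network
#'
#' Nodes are drugs; each multi-drug solution contributes a clique linking
#' the drugs belonging to the same synergistic interaction. Node attribute
#' `n_targets` is the drug's number of direct (collapsed) targets; edge
#' attributes carry the synergy size `|Y|` as `weight` and the originating
#' combination.
#'
#' @param profiles list of `synergy_profile` objects.
#' @param catalog the `drug_catalog`.
#' @param model the `metabolic_model` (for target collapsing).
#' @return an `igraph` graph.
#' @export
drug_proximity_network <- function(profiles, catalog, model) {
  edges <- list()
  drugs <- character()
  for (p in profiles) {
    comb <- p$combination
    drugs <- union(drugs, comb)
    if (length(comb) < 2) next
    prs <- utils::combn(sort(comb), 2)
    for (q in seq_len(ncol(prs))) {
      edges[[length(edges) + 1]] <-
        data.frame(from = prs[1, q], to = prs[2, q],
                   weight = length(p$Y),
                   combination = paste(comb, collapse = "+"),
                   stringsAsFactors = FALSE)
    }
  }
  ed <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(), to = character(), weight = numeric(),
               combination = character())
  vt <- data.frame(name = drugs,
                   n_targets = vapply(drugs, function(d) {
                     length(collapse_ids(model, catalog$targets[[d]]))
                   }, integer(1)),
                   stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(ed, directed = FALSE, vertices = vt)
}

#' Write a screen table as TSV
#' @param screen a `synergy_screen`.
#' @param path output file.
#' @export
write_screen_tsv <- function(screen, path) {
  utils::write.table(as.data.frame(screen), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a drug proximity network as an edge-list TSV
#' @param graph an `igraph` graph from [drug_proximity_network()].
#' @param path output file.
#' @export
write_graph_tsv <- function(graph, path) {
  ed <- igraph::as_data_frame(graph, what = "edges")
  utils::write.table(ed, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
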