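# Drug catalog: turn a drug-annotation table into the optimization's drug
# set. Pipeline mirrors the curation applied to an approved-drug database
# export: keep approved drugs with experimentally proven inhibition of at
# least one metabolic enzyme, resolve EC numbers to (possibly many) model
# reactions, group drugs with identical metabolic target sets, and weight
# each drug's non-metabolic targets by the network-wide mean blocking
# impact of a single metabolic inhibition (beta-bar).

#' Read a drug annotation table
#'
#' Tab-separated with header columns `drug_id`, `name`, `approved`,
#' `ec_list` (semicolon-separated EC numbers), `direct_targets`
#' (semicolon-separated reaction ids) and `n_nonmetabolic`.
#'
#' @param path file path.
#' @return data.frame of drug records with list-columns `ec` and
#'   `direct_targets`.
#' @export
read_drug_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("drug_id", "name", "approved", "ec_list", "direct_targets",
            "n_nonmetabolic")
  if (!all(need %in% names(tab))) {
    stop("drug table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(tab$drug_id)) stop("duplicate drug_id in drug table")
  split_semi <- function(v) {
    lapply(v, function(s) {
      if (is.na(s) || !nzchar(s)) character() else
        trimws(strsplit(as.character(s), ";", fixed = TRUE)[[1]])
    })
  }
  data.frame(drug_id = tab$drug_id, name = tab$name,
             approved = as.logical(tab$approved),
             ec = I(split_semi(tab$ec_list)),
             direct_targets = I(split_semi(tab$direct_targets)),
             n_nonmetabolic = as.integer(tab$n_nonmetabolic),
             stringsAsFactors = FALSE)
}

#' Filter drug records to the usable set
#'
#' Keeps approved drugs carrying at least one metabolic target annotation
#' (an inhibited EC number or a directly targeted reaction), preserving
#' input order.
#'
#' @param records drug record data.frame (see [read_drug_table()]).
#' @return the filtered data.frame.
#' @export
filter_records <- function(records) {
  has_target <- lengths(records$ec) > 0 | lengths(records$direct_targets) > 0
  records[records$approved & has_target, , drop = FALSE]
}

#' Resolve drug records to model target reactions
#'
#' Each drug maps to the union of the model reactions whose EC annotation
#' intersects the drug's inhibited EC set (one EC number may expand to many
#' reactions) plus any directly targeted reactions. Targets are stored at
#' the split-reaction level: inhibiting an enzyme stops both directions of
#' a reversible reaction. Drugs whose annotations resolve to no model
#' reaction are dropped with a warning.
#'
#' @param records filtered drug records.
#' @param model a `metabolic_model`.
#' @return named list: drug id -> character vector of split reaction ids.
#' @export
map_targets <- function(records, model) {
  ec_index <- list()
  for (j in seq_along(model$reactions)) {
    for (e in model$ec[[j]]) {
      ec_index[[e]] <- c(ec_index[[e]], model$reactions[j])
    }
  }
  out <- list()
  for (i in seq_len(nrow(records))) {
    via_ec <- unique(unlist(ec_index[records$ec[[i]]], use.names = FALSE))
    direct <- records$direct_targets[[i]]
    bad <- setdiff(direct, c(model$reactions, unname(model$parent)))
    direct <- setdiff(direct, bad)
    via_direct <- if (length(direct)) directions_of(model, collapse_ids(model, direct))
    tg <- unique(c(via_ec, via_direct))
    if (!length(tg)) {
      warning("drug ", records$drug_id[i],
              " has no target in the model; dropped", call. = FALSE)
      next
    }
    out[[records$drug_id[i]]] <- sort(tg)
  }
  out
}

#' Group drugs with identical metabolic target sets
#'
#' Drugs whose resolved target sets coincide exactly are merged into one
#' group; the representative is the member with the minimal number of
#' non-metabolic targets (ties broken by lexicographic drug id).
#'
#' @param records filtered drug records.
#' @param targets named list from [map_targets()].
#' @return list with `representatives` (record rows of the kept drugs),
#'   `targets` (restricted to representatives) and `group_members`.
#' @export
group_by_target_set <- function(records, targets) {
  records <- records[records$drug_id %in% names(targets), , drop = FALSE]
  if (!nrow(records)) {
    return(list(representatives = records, targets = list(),
                group_members = list()))
  }
  key <- vapply(records$drug_id, function(d) {
    paste(targets[[d]], collapse = "|")
  }, "")
  groups <- split(records$drug_id, key)
  reps <- character(); members <- list()
  for (g in groups) {
    nn <- records$n_nonmetabolic[match(g, records$drug_id)]
    rep_id <- g[order(nn, g)][1]
    reps <- c(reps, rep_id)
    members[[rep_id]] <- sort(g)
  }
  reps <- sort(reps)
  list(representatives = records[match(reps, records$drug_id), , drop = FALSE],
       targets = targets[reps],
       group_members = members[reps])
}

#' Estimate the mean blocking impact of a single inhibition (beta-bar)
#'
#' For every (drug, target reaction) pair in the catalog, inhibit only that
#' reaction and count the newly blocked reactions (the inhibited reaction
#' included, reactions blocked with no drugs excluded); beta-bar is the
#' arithmetic mean of these counts over all pairs.
#'
#' @param model a `metabolic_model`.
#' @param targets named list drug -> split target reactions.
#' @param epsilon activity threshold.
#' @return non-negative scalar beta-bar.
#' @export
estimate_beta_bar <- function(model, targets, epsilon = 0.1) {
  if (!length(targets)) stop("cannot estimate beta-bar from an empty catalog")
  dummy <- list(targets = list(), beta = numeric())
  baseline <- blocked_reactions(model, dummy, character(), epsilon)
  counts <- numeric()
  seen <- new.env(parent = emptyenv())
  for (d in names(targets)) {
    for (p in collapse_ids(model, targets[[d]])) {
      cnt <- get0(p, envir = seen, ifnotfound = NA_real_)
      if (is.na(cnt)) {
        off <- directions_of(model, p)
        mx <- split_max_flux_all(model, off, epsilon)
        blocked_dir <- (mx - FEAS_TOL) < epsilon
        parents <- collapse_ids(model, model$reactions)
        blk <- parents[vapply(parents, function(q) {
          all(blocked_dir[directions_of(model, q)])
        }, logical(1))]
        cnt <- length(setdiff(blk, baseline))
        assign(p, cnt, envir = seen)
      }
      counts <- c(counts, cnt)
    }
  }
  mean(counts)
}

#' Attach beta weights to a catalog
#'
#' beta_k = beta-bar times the representative's number of non-metabolic
#' targets.
#'
#' @param catalog a `drug_catalog`.
#' @param beta_bar non-negative scalar.
#' @return the catalog with `beta` and `beta_bar` filled in.
#' @export
compute_beta_weights <- function(catalog, beta_bar) {
  stopifnot(beta_bar >= 0)
  nn <- catalog$drugs$n_nonmetabolic
  catalog$beta <- stats::setNames(beta_bar * nn, catalog$drugs$drug_id)
  catalog$beta_bar <- beta_bar
  catalog
}

#' Build a drug catalog against a model
#'
#' Convenience pipeline: [filter_records()] -> [map_targets()] ->
#' [group_by_target_set()] -> beta weights (estimating beta-bar from the
#' blocking oracle unless supplied).
#'
#' @param records drug records (see [read_drug_table()]).
#' @param model a `metabolic_model`.
#' @param beta_bar optional fixed beta-bar; estimated when `NULL`.
#' @param epsilon activity threshold used in the beta-bar estimate.
#' @return a `drug_catalog`: list with `drugs` (representative records),
#'   `targets`, `beta`, `beta_bar`, `group_members`.
#' @export
build_catalog <- function(records, model, beta_bar = NULL, epsilon = 0.1) {
  flt <- filter_records(records)
  tg <- map_targets(flt, model)
  grp <- group_by_target_set(flt, tg)
  cat <- structure(list(drugs = grp$representatives,
                        targets = grp$targets,
                        beta = numeric(),
                        beta_bar = NA_real_,
                        group_members = grp$group_members),
                   class = "drug_catalog")
  if (!nrow(grp$representatives)) {
    cat$beta <- stats::setNames(numeric(), character())
    cat$beta_bar <- if (is.null(beta_bar)) 0 else beta_bar
    return(cat)
  }
  if (is.null(beta_bar)) {
    beta_bar <- estimate_beta_bar(model, cat$targets, epsilon)
  }
  compute_beta_weights(cat, beta_bar)
}

#' @export
print.drug_catalog <- function(x, ...) {
  cat("drug catalog:", nrow(x$drugs), "drug groups, beta-bar =",
      format(x$beta_bar), "\n")
  invisible(x)
}
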