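# Metabolic network containers and canonicalization.
#
# Two containers: `raw_model` as read from disk (bounds may be negative or
# infinite, i.e. reversible/unbounded reactions) and `metabolic_model`, the
# canonical non-negative-flux form the optimization works on, where every
# reversible reaction has been decomposed into a forward/reverse pair of
# irreversible reactions registered in `rev_pair`.

REV_SUFFIX <- "_rev"

new_raw_model <- function(metabolites, reactions, S, lb, ub,
                          pathway = NULL, ec = NULL, compartment = NULL) {
  n_r <- length(reactions)
  if (is.null(pathway)) pathway <- rep(NA_character_, n_r)
  if (is.null(ec)) ec <- rep(list(character()), n_r)
  if (is.null(compartment)) compartment <- rep(NA_character_, length(metabolites))
  S <- methods::as(methods::as(S, "CsparseMatrix"), "generalMatrix")
  dimnames(S) <- list(metabolites, reactions)
  structure(list(metabolites = metabolites, reactions = reactions, S = S,
                 lb = stats::setNames(as.numeric(lb), reactions),
                 ub = stats::setNames(as.numeric(ub), reactions),
                 pathway = stats::setNames(as.character(pathway), reactions),
                 ec = stats::setNames(ec, reactions),
                 compartment = stats::setNames(as.character(compartment),
                                               metabolites)),
            class = "raw_model")
}

#' Parse a reaction equation string
#'
#' Equations use the form `"2 A + B -> C"`; either side may be empty
#' (exchange reactions), coefficients default to 1.
#'
#' @param eq equation string.
#' @return list with named numeric vectors `substrates` and `products`.
#' @keywords internal
parse_equation <- function(eq) {
  parts <- strsplit(eq, "->", fixed = TRUE)[[1]]
  if (length(parts) > 2 || !grepl("->", eq, fixed = TRUE)) {
    stop("malformed equation (need exactly one '->'): ", eq)
  }
  side <- function(s) {
    s <- trimws(s)
    if (!nzchar(s)) return(stats::setNames(numeric(), character()))
    terms <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
    out <- numeric(0)
    for (tm in terms) {
      toks <- strsplit(tm, "[[:space:]]+")[[1]]
      if (length(toks) == 1) {
        out[toks] <- (if (toks %in% names(out)) out[toks] else 0) + 1
      } else if (length(toks) == 2 && !is.na(suppressWarnings(as.numeric(toks[1])))) {
        out[toks[2]] <- (if (toks[2] %in% names(out)) out[toks[2]] else 0) +
          as.numeric(toks[1])
      } else {
        stop("malformed term '", tm, "' in equation: ", eq)
      }
    }
    out
  }
  lhs <- side(parts[1])
  rhs <- side(if (length(parts) == 2) parts[2] else "")
  list(substrates = lhs, products = rhs)
}

#' Load a metabolic network
#'
#' Reads a network in either the tab-separated dialect (a reactions table
#' with columns `id`, `equation`, `lower`, `upper` and optional `pathway`,
#' `ec`; plus an optional metabolites table with columns `id`,
#' `compartment`) or SBML (Level 2 COBRA-style or Level 3 with fbc bounds).
#'
#' @param path path to the reactions table or SBML file.
#' @param dialect `"tabular"` or `"sbml"`.
#' @param metabolites_path optional metabolites table (tabular dialect only);
#'   when given, reactions referencing undeclared metabolites are an error.
#' @return a `raw_model`; pass through [split_reversible()] before
#'   optimization.
#' @export
load_model <- function(path, dialect = c("tabular", "sbml"),
                       metabolites_path = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "sbml") return(read_sbml(path))
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE, comment.char = "#")
  need <- c("id", "equation", "lower", "upper")
  if (!all(need %in% names(tab))) {
    stop("reactions table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(tab$id)) {
    stop("duplicate reaction id: ",
         paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "))
  }
  declared <- NULL
  compartment <- NULL
  if (!is.null(metabolites_path)) {
    mt <- utils::read.delim(metabolites_path, stringsAsFactors = FALSE)
    if (anyDuplicated(mt$id)) stop("duplicate metabolite id in metabolites table")
    declared <- mt$id
    compartment <- if ("compartment" %in% names(mt)) mt$compartment
  }
  eqs <- lapply(tab$equation, function(e) {
    tryCatch(parse_equation(e),
             error = function(err) stop("record '", conditionMessage(err),
                                        "'", call. = FALSE))
  })
  mets <- unique(unlist(lapply(eqs, function(e) {
    c(names(e$substrates), names(e$products))
  })))
  if (!is.null(declared)) {
    undecl <- setdiff(mets, declared)
    if (length(undecl)) {
      stop("reaction references undeclared metabolite(s): ",
           paste(undecl, collapse = ", "))
    }
    mets <- declared
  }
  ii <- integer(); jj <- integer(); xx <- numeric()
  for (j in seq_along(eqs)) {
    e <- eqs[[j]]
    for (m in names(e$substrates)) {
      ii <- c(ii, match(m, mets)); jj <- c(jj, j); xx <- c(xx, -e$substrates[[m]])
    }
    for (m in names(e$products)) {
      ii <- c(ii, match(m, mets)); jj <- c(jj, j); xx <- c(xx, e$products[[m]])
    }
  }
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(length(mets), nrow(tab)))
  lb <- as.numeric(tab$lower); ub <- as.numeric(tab$upper)
  if (any(lb > ub, na.rm = TRUE)) {
    stop("lower > upper for reaction(s): ",
         paste(tab$id[lb > ub], collapse = ", "))
  }
  ec <- if ("ec" %in% names(tab)) {
    lapply(tab$ec, function(s) {
      if (is.na(s) || !nzchar(s)) character() else strsplit(s, ";", fixed = TRUE)[[1]]
    })
  }
  pw <- if ("pathway" %in% names(tab)) tab$pathway
  new_raw_model(mets, tab$id, S, lb, ub, pathway = pw, ec = ec,
                compartment = compartment)
}

#' Decompose reversible reactions into irreversible pairs
#'
#' Every reaction with a negative lower bound becomes a forward reaction
#' (upper bound = original upper) and a reverse twin (upper bound =
#' `-lower`), with exactly negated stoichiometric columns, so that all
#' fluxes are non-negative. Infinite bounds are replaced by `default_cap`
#' (LP duality requires finite capacities). Positive lower bounds are
#' relaxed to zero.
#'
#' @param raw a `raw_model` (a `metabolic_model` is returned unchanged).
#' @param default_cap finite replacement for infinite bounds.
#' @return a `metabolic_model` with `rev_pair` registering the twins.
#' @export
split_reversible <- function(raw, default_cap = 1000) {
  if (inherits(raw, "metabolic_model")) return(raw)
  stopifnot(inherits(raw, "raw_model"), default_cap > 0, is.finite(default_cap))
  ub <- ifelse(is.finite(raw$ub), raw$ub, default_cap)
  lb <- ifelse(is.finite(raw$lb), raw$lb, -default_cap)
  rev_idx <- which(lb < 0)
  ids <- raw$reactions
  rev_ids <- if (length(rev_idx)) paste0(ids[rev_idx], REV_SUFFIX) else character(0)
  if (any(rev_ids %in% ids)) {
    stop("reaction id collides with reverse-twin naming: ",
         paste(intersect(rev_ids, ids), collapse = ", "))
  }
  S <- methods::as(raw$S, "CsparseMatrix")
  S2 <- cbind(S, -S[, rev_idx, drop = FALSE])
  all_ids <- c(ids, rev_ids)
  ub2 <- c(pmax(ub, 0), -lb[rev_idx])
  rev_pair <- character(0)
  if (length(rev_idx)) {
    rev_pair <- stats::setNames(c(rev_ids, ids[rev_idx]),
                                c(ids[rev_idx], rev_ids))
  }
  parent <- stats::setNames(c(ids, ids[rev_idx]), all_ids)
  m <- structure(list(
    metabolites = raw$metabolites,
    reactions = all_ids,
    S = S2,
    ub = stats::setNames(as.numeric(ub2), all_ids),
    pathway = stats::setNames(unname(raw$pathway[c(ids, ids[rev_idx])]), all_ids),
    ec = stats::setNames(raw$ec[c(ids, ids[rev_idx])], all_ids),
    rev_pair = rev_pair,
    parent = parent,
    compartment = raw$compartment), class = "metabolic_model")
  dimnames(m$S) <- list(m$metabolites, m$reactions)
  m
}

#' Validate a canonical metabolic model
#'
#' Checks the container invariants: finite non-negative bounds, unique
#' reaction ids, `rev_pair` an involution with exactly negated columns, no
#' all-zero stoichiometric column unless the reaction is an exchange
#' (single-sided) reaction.
#'
#' @param model a `metabolic_model`.
#' @return character vector of violations; empty when the model is valid.
#' @export
validate_model <- function(model) {
  rep <- character()
  if (anyDuplicated(model$reactions)) {
    rep <- c(rep, paste("duplicate reaction id:",
                        paste(unique(model$reactions[duplicated(model$reactions)]),
                              collapse = ", ")))
  }
  bad <- model$reactions[!is.finite(model$ub) | model$ub < 0]
  if (length(bad)) {
    rep <- c(rep, paste("non-finite or negative upper bound:",
                        paste(bad, collapse = ", ")))
  }
  rp <- model$rev_pair
  if (length(rp)) {
    for (j in names(rp)) {
      l <- rp[[j]]
      if (!(l %in% names(rp)) || rp[[l]] != j) {
        rep <- c(rep, paste0("rev_pair is not an involution at: ", j))
        next
      }
      if (j < l) {  # check each pair once
        dj <- model$S[, j] + model$S[, l]
        if (any(abs(dj) > 1e-12)) {
          rep <- c(rep, paste0("reverse pair (", j, ", ", l,
                               ") columns are not exact negations"))
        }
      }
    }
  }
  zero_col <- Matrix::colSums(model$S != 0) == 0
  exch <- is_exchange(model)
  bad0 <- model$reactions[zero_col & !exch]
  if (length(bad0)) {
    rep <- c(rep, paste("all-zero stoichiometric column (not exchange):",
                        paste(bad0, collapse = ", ")))
  }
  rep
}

# exchange = reaction touching a single metabolite side (or none)
is_exchange <- function(model) {
  n_sub <- Matrix::colSums(model$S < 0)
  n_pro <- Matrix::colSums(model$S > 0)
  (n_sub == 0) | (n_pro == 0)
}

#' Collapse split-reaction ids to their parent reactions
#'
#' @param model a `metabolic_model`.
#' @param ids reaction ids (possibly reverse twins).
#' @return unique parent ids, in first-appearance order.
#' @export
collapse_ids <- function(model, ids) {
  unique(unname(model$parent[ids]))
}

#' All split directions of a set of parent reactions
#' @param model a `metabolic_model`.
#' @param parents parent reaction ids.
#' @return split reaction ids covering every direction of the parents.
#' @export
directions_of <- function(model, parents) {
  model$reactions[model$parent[model$reactions] %in% parents]
}

#' @export
print.raw_model <- function(x, ...) {
  cat("raw metabolic model:", length(x$metabolites), "metabolites,",
      length(x$reactions), "reactions (",
      sum(x$lb < 0), "reversible )\n")
  invisible(x)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("metabolic model:", length(x$metabolites), "metabolites,",
      length(x$reactions), "irreversible reactions (",
      length(x$rev_pair) / 2, "reverse pairs )\n")
  invisible(x)
}

#' Serialize a canonical model to JSON
#' @param model a `metabolic_model`.
#' @param path optional file; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
model_to_json <- function(model, path = NULL) {
  trip <- Matrix::mat2triplet(model$S)
  obj <- list(metabolites = model$metabolites,
              reactions = model$reactions,
              S = list(i = trip$i, j = trip$j, x = trip$x),
              ub = unname(model$ub),
              pathway = unname(model$pathway),
              ec = unname(model$ec),
              rev_pair = as.list(model$rev_pair),
              parent = as.list(model$parent),
              compartment = unname(model$compartment))
  js <- jsonlite::toJSON(obj, auto_unbox = FALSE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Deserialize a canonical model from JSON
#' @param path file path or JSON string produced by [model_to_json()].
#' @return a `metabolic_model`.
#' @export
model_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  S <- Matrix::sparseMatrix(i = obj$S$i, j = obj$S$j, x = obj$S$x,
                            dims = c(length(obj$metabolites),
                                     length(obj$reactions)))
  ec <- obj$ec
  if (is.null(ec)) ec <- rep(list(character()), length(obj$reactions))
  ec <- lapply(ec, function(e) if (is.null(e)) character() else as.character(e))
  m <- structure(list(
    metabolites = obj$metabolites,
    reactions = obj$reactions,
    S = methods::as(S, "generalMatrix"),
    ub = stats::setNames(obj$ub, obj$reactions),
    pathway = stats::setNames(as.character(obj$pathway), obj$reactions),
    ec = stats::setNames(ec, obj$reactions),
    rev_pair = unlist(obj$rev_pair) %||% character(0),
    parent = unlist(obj$parent),
    compartment = stats::setNames(as.character(obj$compartment),
                                  obj$metabolites)),
    class = "metabolic_model")
  dimnames(m$S) <- list(m$metabolites, m$reactions)
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a model in the tabular dialect
#'
#' Writes the reactions table (and optionally a metabolites table) readable
#' by [load_model()]. A `metabolic_model` is written with reverse pairs
#' recombined into single reversible rows.
#'
#' @param model a `raw_model` or `metabolic_model`.
#' @param path output path for the reactions table.
#' @param metabolites_path optional output path for the metabolites table.
#' @export
write_model_tsv <- function(model, path, metabolites_path = NULL) {
  if (inherits(model, "metabolic_model")) {
    keep <- model$reactions[model$parent[model$reactions] == model$reactions]
    lb <- stats::setNames(rep(0, length(keep)), keep)
    twins <- model$rev_pair[keep[keep %in% names(model$rev_pair)]]
    lb[names(twins)] <- -model$ub[twins]
    S <- model$S[, keep, drop = FALSE]
    ub <- model$ub[keep]
    pw <- model$pathway[keep]; ec <- model$ec[keep]
  } else {
    keep <- model$reactions
    S <- model$S; lb <- model$lb; ub <- model$ub
    pw <- model$pathway; ec <- model$ec
  }
  eq <- vapply(seq_along(keep), function(j) {
    col <- S[, j]
    subs <- which(col < 0); pros <- which(col > 0)
    term <- function(i) {
      co <- abs(col[i])
      if (co == 1) model$metabolites[i] else paste(format(co), model$metabolites[i])
    }
    paste(paste(vapply(subs, term, ""), collapse = " + "), "->",
          paste(vapply(pros, term, ""), collapse = " + "))
  }, "")
  tab <- data.frame(id = keep, equation = eq, lower = unname(lb),
                    upper = unname(ub),
                    pathway = unname(pw),
                    ec = vapply(ec, paste, "", collapse = ";"),
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metabolites_path)) {
    mt <- data.frame(id = model$metabolites,
                     compartment = unname(model$compartment))
    utils::write.table(mt, metabolites_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

# force one or more reactions off (ub = 0); used for deletions
with_reactions_off <- function(model, parents) {
  off <- directions_of(model, parents)
  model$ub[off] <- 0
  model
}
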