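# SBML reader/writer built on xml2. The writer emits COBRA-style Level 2
# Version 4 (bounds as kineticLaw parameters, pathway/EC in the notes body);
# the reader additionally understands Level 3 fbc flux bounds. Annotations
# are optional everywhere downstream, so anything unrecognized is skipped.

#' Read an SBML network
#'
#' Accepts Level 2 (COBRA-style `LOWER_BOUND`/`UPPER_BOUND` kineticLaw
#' parameters) and Level 3 (`fbc:lowerFluxBound`/`fbc:upperFluxBound`
#' attributes resolving to model parameters). When no bounds are present,
#' `reversible` determines the lower bound and the upper bound is infinite.
#' EC numbers and pathway labels are read from notes lines of the form
#' `EC Number: ...` and `SUBSYSTEM: ...` when present.
#'
#' @param path SBML file path.
#' @return a `raw_model`.
#' @export
read_sbml <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  mets <- xml2::xml_attr(sp_nodes, "id")
  if (anyDuplicated(mets)) stop("duplicate species id in SBML")
  comp <- xml2::xml_attr(sp_nodes, "compartment")
  boundary <- xml2::xml_attr(sp_nodes, "boundaryCondition") %in% "true"
  # model-level parameters (L3 fbc bound values)
  par_nodes <- xml2::xml_find_all(doc, ".//model/listOfParameters/parameter")
  par_val <- stats::setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                             xml2::xml_attr(par_nodes, "id"))
  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  ids <- xml2::xml_attr(rx_nodes, "id")
  if (anyDuplicated(ids)) {
    stop("duplicate reaction id in SBML: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  n_r <- length(ids)
  lb <- numeric(n_r); ub <- numeric(n_r)
  pw <- rep(NA_character_, n_r); ec <- rep(list(character()), n_r)
  ii <- integer(); jj <- integer(); xx <- numeric()
  keep_met <- !boundary
  for (j in seq_len(n_r)) {
    rx <- rx_nodes[[j]]
    add_side <- function(xpath, sign) {
      refs <- xml2::xml_find_all(rx, xpath)
      for (r in refs) {
        m <- xml2::xml_attr(r, "species")
        k <- match(m, mets)
        if (is.na(k)) stop("reaction ", ids[j],
                           " references undeclared species: ", m)
        if (boundary[k]) next  # boundary species do not constrain steady state
        st <- xml2::xml_attr(r, "stoichiometry")
        st <- if (is.na(st)) 1 else as.numeric(st)
        ii <<- c(ii, k); jj <<- c(jj, j); xx <<- c(xx, sign * st)
      }
    }
    add_side("./listOfReactants/speciesReference", -1)
    add_side("./listOfProducts/speciesReference", +1)
    rev <- !(xml2::xml_attr(rx, "reversible") %in% "false")
    lo <- xml2::xml_attr(rx, "lowerFluxBound")
    hi <- xml2::xml_attr(rx, "upperFluxBound")
    if (!is.na(lo) || !is.na(hi)) {
      lb[j] <- if (!is.na(lo) && lo %in% names(par_val)) par_val[[lo]] else -Inf
      ub[j] <- if (!is.na(hi) && hi %in% names(par_val)) par_val[[hi]] else Inf
    } else {
      kl <- xml2::xml_find_all(rx, ".//kineticLaw//parameter")
      kid <- xml2::xml_attr(kl, "id")
      kvl <- as.numeric(xml2::xml_attr(kl, "value"))
      lb[j] <- if ("LOWER_BOUND" %in% kid) kvl[match("LOWER_BOUND", kid)] else
        if (rev) -Inf else 0
      ub[j] <- if ("UPPER_BOUND" %in% kid) kvl[match("UPPER_BOUND", kid)] else Inf
    }
    notes <- xml2::xml_text(xml2::xml_find_all(rx, "./notes//p"))
    for (ln in notes) {
      if (grepl("^\\s*SUBSYSTEM:", ln)) {
        pw[j] <- trimws(sub("^\\s*SUBSYSTEM:", "", ln))
      } else if (grepl("^\\s*EC Number:", ln)) {
        v <- trimws(sub("^\\s*EC Number:", "", ln))
        if (nzchar(v)) ec[[j]] <- trimws(strsplit(v, "[;,]")[[1]])
      }
    }
  }
  # drop boundary species rows entirely
  sel <- which(keep_met)
  remap <- match(ii, sel)
  ok <- !is.na(remap)
  S <- Matrix::sparseMatrix(i = remap[ok], j = jj[ok], x = xx[ok],
                            dims = c(length(sel), n_r))
  new_raw_model(mets[sel], ids, S, lb, ub, pathway = pw, ec = ec,
                compartment = comp[sel])
}

#' Write a network as COBRA-style SBML Level 2
#'
#' @param model a `raw_model` or `metabolic_model` (the latter is written
#'   with reverse pairs recombined into reversible reactions).
#' @param path output file.
#' @export
write_sbml <- function(model, path) {
  if (inherits(model, "metabolic_model")) {
    tmp <- tempfile(fileext = ".tsv")
    on.exit(unlink(tmp))
    write_model_tsv(model, tmp)
    model <- load_model(tmp, "tabular")
  }
  esc <- function(s) {
    s <- gsub("&", "&amp;", s, fixed = TRUE)
    s <- gsub("<", "&lt;", s, fixed = TRUE)
    gsub(">", "&gt;", s, fixed = TRUE)
  }
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  w <- function(...) writeLines(paste0(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">')
  w('  <model id="synflux_model">')
  comps <- unique(stats::na.omit(model$compartment))
  if (!length(comps)) comps <- "c"
  w('    <listOfCompartments>')
  for (cm in comps) w('      <compartment id="', esc(cm), '"/>')
  w('    </listOfCompartments>')
  w('    <listOfSpecies>')
  for (k in seq_along(model$metabolites)) {
    cm <- model$compartment[[k]]
    if (is.na(cm)) cm <- comps[1]
    w('      <species id="', esc(model$metabolites[k]), '" compartment="',
      esc(cm), '"/>')
  }
  w('    </listOfSpecies>')
  w('    <listOfReactions>')
  for (j in seq_along(model$reactions)) {
    col <- model$S[, j]
    rev <- model$lb[j] < 0
    w('      <reaction id="', esc(model$reactions[j]), '" reversible="',
      if (rev) "true" else "false", '">')
    pwj <- model$pathway[[j]]; ecj <- model$ec[[j]]
    if (!is.na(pwj) || length(ecj)) {
      w('        <notes><body xmlns="http://www.w3.org/1999/xhtml">')
      if (!is.na(pwj)) w('          <p>SUBSYSTEM: ', esc(pwj), '</p>')
      if (length(ecj)) w('          <p>EC Number: ',
                         esc(paste(ecj, collapse = ";")), '</p>')
      w('        </body></notes>')
    }
    side <- function(idx, tag) {
      if (!length(idx)) return()
      w('        <', tag, '>')
      for (k in idx) {
        w('          <speciesReference species="', esc(model$metabolites[k]),
          '" stoichiometry="', format(abs(col[k])), '"/>')
      }
      w('        </', tag, '>')
    }
    side(which(col < 0), "listOfReactants")
    side(which(col > 0), "listOfProducts")
    w('        <kineticLaw>')
    w('          <math xmlns="http://www.w3.org/1998/Math/MathML"><ci> FLUX_VALUE </ci></math>')
    w('          <listOfParameters>')
    w('            <parameter id="LOWER_BOUND" value="', format(model$lb[j]), '"/>')
    w('            <parameter id="UPPER_BOUND" value="', format(model$ub[j]), '"/>')
    w('          </listOfParameters>')
    w('        </kineticLaw>')
    w('      </reaction>')
  }
  w('    </listOfReactions>')
  w('  </model>')
  w('</sbml>')
  invisible(path)
}
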