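# shared test helpers: tiny models written to temp files in the tabular
# dialect, and a catalog constructor that bypasses the beta-bar estimate

tmp_model <- function(lines, default_cap = 1000) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(c("id\tequation\tlower\tupper\tpathway\tec", lines), path)
  split_reversible(load_model(path, "tabular"), default_cap)
}

tmp_raw_model <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(c("id\tequation\tlower\tupper\tpathway\tec", lines), path)
  load_model(path, "tabular")
}

mk_records <- function(drug_id, targets, n_nonmetabolic = 0,
                       approved = TRUE, ec = NULL) {
  if (is.null(ec)) ec <- rep(list(character()), length(drug_id))
  data.frame(drug_id = drug_id, name = drug_id,
             approved = rep_len(approved, length(drug_id)),
             ec = I(ec), direct_targets = I(targets),
             n_nonmetabolic = rep_len(as.integer(n_nonmetabolic),
                                      length(drug_id)),
             stringsAsFactors = FALSE)
}

# a linear chain with a branch point, used across catalog/oracle tests:
#   e1 -> N (consumed by r1 and r4, so removing r1 strands nothing)
#   e2 -> M1 -> M2 -> out (a chain that dies entirely when r2 is removed)
chain_model <- function() {
  tmp_model(c(
    "e1\t -> N\t0\t10\t\t",
    "r1\tN -> \t0\t10\t\t1.1.1.1",
    "r4\tN -> \t0\t10\t\t",
    "e2\t -> M1\t0\t10\t\t",
    "r2\tM1 -> M2\t0\t10\t\t2.2.2.2",
    "r3\tM2 -> \t0\t10\t\t"))
}

write_drug_tsv <- function(records, path) {
  tab <- data.frame(drug_id = records$drug_id, name = records$name,
                    approved = records$approved,
                    ec_list = vapply(records$ec, paste, "", collapse = ";"),
                    direct_targets = vapply(records$direct_targets, paste,
                                            "", collapse = ";"),
                    n_nonmetabolic = records$n_nonmetabolic)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
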