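# Shared helpers for the suite: tiny record-table builders and an external
# python/RDKit oracle used to cross-check scaffold and fragment chemistry.

records_df <- function(assay, compound, outcome,
                       ac50 = NA_real_, source = "hts") {
  if (length(assay) == 0L) {
    ac50 <- numeric()
    source <- character()
  }
  data.frame(assay_id = assay, compound_id = compound,
             outcome = factor(outcome,
                              levels = c("active", "inactive",
                                         "unspecified", "inconclusive")),
             ac50_uM = ac50,
             source = factor(source, levels = c("hts", "literature")),
             stringsAsFactors = FALSE)
}

categories_df <- function(assay, cluster, type = "t1", target = NA) {
  data.frame(assay_id = assay, cluster_id = cluster, type_id = type,
             target_id = target, stringsAsFactors = FALSE)
}

# Run a python snippet (RDKit lives there) and capture stdout lines.
run_python <- function(code) {
  f <- tempfile(fileext = ".py")
  on.exit(unlink(f))
  writeLines(code, f)
  out <- suppressWarnings(system2("python", f, stdout = TRUE, stderr = FALSE))
  out
}

cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# Co-membership matrix of a label vector (for permutation-invariance checks).
comembership <- function(labels) {
  outer(labels, labels, "==")
}
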