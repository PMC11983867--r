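#!/usr/bin/env Rscript
# Optional replication check against an externally obtained curated-inactive
# compound list (a .smi file downloaded separately; nothing is fetched here):
#
#   Rscript scripts/replication-check.R --cics path/to/cics.smi
#
# Reports the Ro5-compliance and PAINS rates of the list, the two summary
# statistics this package computes for any compound set. Note the bundled
# PAINS catalog is a representative subset of the published families, so the
# PAINS rate reported here is a lower bound relative to a full-catalog
# screen (pass --pains-catalog FILE to use one).

suppressMessages(library(inertforge))

args <- commandArgs(trailingOnly = TRUE)
arg_val <- function(flag, default = NULL) {
  i <- match(flag, args)
  if (is.na(i) || i == length(args)) default else args[[i + 1L]]
}
path <- arg_val("--cics")
if (is.null(path)) stop("usage: replication-check.R --cics FILE.smi")
catalog <- arg_val("--pains-catalog")

smis <- read_smi(path)
valid <- is_valid_smiles(smis)
message(sprintf("%d molecules read; %.1f%% valid", length(smis),
                100 * mean(valid)))
smis <- smis[valid]
props <- compute_properties(smis)
cat(sprintf("Ro5 compliance: %.1f%%\n", 100 * mean(ro5_compliant(props))))
catal <- if (is.null(catalog)) pains_catalog() else pains_catalog(catalog)
cat(sprintf("PAINS rate (%d-pattern catalog): %.1f%%\n", nrow(catal),
            100 * mean(pains_flag(smis, catal))))
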