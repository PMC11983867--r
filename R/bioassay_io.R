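# Reading bioassay outcome tables and resolving them to one active/inactive
# label per (assay, compound) pair, following conservative curation rules:
# within-assay conflicts resolve to active, and literature records annotated
# unspecified/inconclusive are classified by their AC50.

.outcome_levels <- c("active", "inactive", "unspecified", "inconclusive")
.source_levels <- c("hts", "literature")

#' Read a bioassay results table
#'
#' Reads a delimited table of per-(assay, compound) outcomes. Column names are
#' mapped through `columns`, so any dump dialect can be adapted without
#' rewriting the file. Outcome strings are matched case-insensitively against
#' `active`, `inactive`, `unspecified`, `inconclusive`; anything else is
#' rejected. Gzip-compressed files are read transparently.
#'
#' @param path Path to a TSV/CSV file (optionally gzipped).
#' @param columns Named list mapping the required fields (`assay_id`,
#'   `compound_id`, `outcome`, and optionally `ac50_uM`, `source`) to header
#'   names in the file.
#' @param sep Field separator; guessed from the file extension by default.
#' @return A `data.frame` of assay records with columns `assay_id`,
#'   `compound_id`, `outcome` (factor), `ac50_uM` (numeric, `NA` when absent)
#'   and `source` (factor), one row per input data row, in file order.
#' @export
read_assay_results <- function(path,
                               columns = list(assay_id = "assay_id",
                                              compound_id = "compound_id",
                                              outcome = "outcome",
                                              ac50_uM = "ac50_uM",
                                              source = "source"),
                               sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    base <- sub("\\.gz$", "", path)
    sep <- if (grepl("\\.csv$", base, ignore.case = TRUE)) "," else "\t"
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", quote = "\"",
                           comment.char = "", check.names = FALSE,
                           stringsAsFactors = FALSE)
  required <- c("assay_id", "compound_id", "outcome")
  for (field in required) {
    cn <- columns[[field]]
    if (is.null(cn) || !cn %in% names(raw)) {
      stop("required column missing from ", path, ": ", field,
           " (mapped to '", if (is.null(cn)) "?" else cn, "')")
    }
  }
  out <- data.frame(assay_id = raw[[columns$assay_id]],
                    compound_id = raw[[columns$compound_id]],
                    stringsAsFactors = FALSE)
  oc <- tolower(trimws(raw[[columns$outcome]]))
  bad <- !oc %in% .outcome_levels
  if (any(bad)) {
    stop("unknown outcome value(s): ",
         paste(unique(raw[[columns$outcome]][bad]), collapse = ", "),
         "; allowed values are: ", paste(.outcome_levels, collapse = ", "))
  }
  out$outcome <- factor(oc, levels = .outcome_levels)
  ac_col <- columns$ac50_uM
  if (!is.null(ac_col) && ac_col %in% names(raw)) {
    txt <- trimws(raw[[ac_col]])
    empty <- is.na(txt) | txt == "" | toupper(txt) == "NA"
    val <- suppressWarnings(as.numeric(txt))
    bad <- !empty & is.na(val)
    if (any(bad)) {
      stop("unparseable AC50 value at data line(s) ",
           paste(which(bad), collapse = ", "), ": ",
           paste(unique(txt[bad]), collapse = ", "))
    }
    if (any(val[!empty] < 0, na.rm = TRUE)) {
      stop("negative AC50 value at data line(s) ",
           paste(which(!empty & val < 0), collapse = ", "))
    }
    out$ac50_uM <- val
  } else {
    out$ac50_uM <- NA_real_
  }
  src_col <- columns$source
  if (!is.null(src_col) && src_col %in% names(raw)) {
    sc <- tolower(trimws(raw[[src_col]]))
    bad <- !sc %in% .source_levels
    if (any(bad)) {
      stop("unknown source value(s): ",
           paste(unique(raw[[src_col]][bad]), collapse = ", "),
           "; allowed values are: ", paste(.source_levels, collapse = ", "))
    }
    out$source <- factor(sc, levels = .source_levels)
  } else {
    out$source <- factor("hts", levels = .source_levels)
  }
  out
}

#' Classify literature records by their AC50
#'
#' Literature-derived records annotated `unspecified` or `inconclusive` are
#' assigned a definite label from the reported AC50: active when
#' AC50 <= 1000 uM, inactive otherwise (including when no AC50 is reported).
#'
#' @param records Assay-record `data.frame` (see [read_assay_results()]);
#'   every row must be a literature record with outcome `unspecified` or
#'   `inconclusive`.
#' @param threshold_uM Activity concentration cutoff in micromolar.
#' @return The records with `outcome` replaced by `active`/`inactive`.
#' @export
classify_literature_outcome <- function(records, threshold_uM = 1000) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) return(records)
  if (any(records$source != "literature")) {
    stop("classify_literature_outcome applies to literature records only")
  }
  if (any(records$outcome %in% c("active", "inactive"))) {
    stop("records already labeled active/inactive must not be reclassified")
  }
  act <- !is.na(records$ac50_uM) & records$ac50_uM <= threshold_uM
  records$outcome <- factor(ifelse(act, "active", "inactive"),
                            levels = .outcome_levels)
  records
}

#' Prepare raw records for harmonization
#'
#' Applies the full outcome-resolution policy: literature records annotated
#' `unspecified`/`inconclusive` are classified from AC50
#' ([classify_literature_outcome()]); HTS records with those annotations have
#' no curation path and are dropped (with a message reporting the count).
#'
#' @param records Assay-record `data.frame`.
#' @inheritParams classify_literature_outcome
#' @return Records in which every outcome is `active` or `inactive`.
#' @export
resolve_ambiguous_outcomes <- function(records, threshold_uM = 1000) {
  stopifnot(is.data.frame(records))
  amb <- records$outcome %in% c("unspecified", "inconclusive")
  lit <- amb & records$source == "literature"
  hts <- amb & records$source == "hts"
  if (any(hts)) {
    message("dropping ", sum(hts),
            " hts record(s) with unspecified/inconclusive outcome")
  }
  if (any(lit)) {
    records[lit, ] <- classify_literature_outcome(records[lit, , drop = FALSE],
                                                  threshold_uM)
  }
  records[!hts, , drop = FALSE]
}

#' Harmonize outcomes to one label per assay-compound pair
#'
#' Collapses duplicate depositions and resolves within-assay conflicts
#' conservatively: a compound annotated both active and inactive in the same
#' bioassay is classified active.
#'
#' @param records Assay-record `data.frame` in which every outcome is already
#'   `active` or `inactive` (see [resolve_ambiguous_outcomes()]).
#' @return A `data.frame` with columns `assay_id`, `compound_id`, `label`
#'   (factor `active`/`inactive`), one row per distinct pair, ordered by
#'   assay then compound.
#' @export
harmonize_outcomes <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) {
    return(data.frame(assay_id = character(), compound_id = character(),
                      label = factor(character(),
                                     levels = c("active", "inactive")),
                      stringsAsFactors = FALSE))
  }
  if (any(records$outcome %in% c("unspecified", "inconclusive"))) {
    stop("unresolved unspecified/inconclusive outcomes present; ",
         "run resolve_ambiguous_outcomes() first")
  }
  key <- paste(records$assay_id, records$compound_id, sep = "\r")
  any_active <- tapply(records$outcome == "active", key, any)
  keys <- names(any_active)
  parts <- regmatches(keys, regexpr("\r", keys), invert = TRUE)
  out <- data.frame(
    assay_id = vapply(parts, `[[`, "", 1L),
    compound_id = vapply(parts, `[[`, "", 2L),
    label = factor(ifelse(unname(any_active), "active", "inactive"),
                   levels = c("active", "inactive")),
    stringsAsFactors = FALSE)
  out <- out[order(out$assay_id, out$compound_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build per-compound assay profiles
#'
#' Counts, for every compound, how many distinct assays it has an outcome in
#' and how those assays distribute over the three category axes (name-cluster,
#' assay type, target), plus whether any outcome is active. These profiles are
#' the input of the assay-diversity score.
#'
#' @param outcomes Resolved outcome `data.frame` from [harmonize_outcomes()].
#' @param categories Category assignment from [assign_categories()] (a
#'   `data.frame` with columns `assay_id`, `cluster_id`, `type_id`,
#'   `target_id`; `target_id` may be `NA`).
#' @return An object of class `compound_profiles`: a named list, one entry per
#'   compound, each with elements `n_assay`, `any_active`, and `counts` (a
#'   list of named integer count vectors for the `cluster`, `type` and
#'   `target` axes).
#' @export
build_compound_profiles <- function(outcomes, categories) {
  stopifnot(is.data.frame(outcomes), is.data.frame(categories))
  if (nrow(outcomes) == 0L) {
    return(structure(list(), class = "compound_profiles"))
  }
  orphan <- setdiff(unique(outcomes$assay_id), categories$assay_id)
  if (length(orphan)) {
    stop("assay id(s) missing from the category assignment: ",
         paste(orphan, collapse = ", "))
  }
  if (anyDuplicated(categories$assay_id)) {
    stop("duplicated assay_id in category assignment")
  }
  idx <- match(outcomes$assay_id, categories$assay_id)
  ax <- list(cluster = as.character(categories$cluster_id)[idx],
             type = as.character(categories$type_id)[idx],
             target = as.character(categories$target_id)[idx])
  split_rows <- split(seq_len(nrow(outcomes)), outcomes$compound_id)
  profiles <- lapply(split_rows, function(rows) {
    counts <- lapply(ax, function(v) {
      vals <- v[rows]
      vals <- vals[!is.na(vals) & vals != "NA"]
      if (length(vals) == 0L) {
        stats::setNames(integer(), character())
      } else {
        tab <- table(vals)
        stats::setNames(as.integer(tab), names(tab))
      }
    })
    list(n_assay = length(unique(outcomes$assay_id[rows])),
         any_active = any(outcomes$label[rows] == "active"),
         counts = counts)
  })
  structure(profiles, class = "compound_profiles")
}

#' @export
print.compound_profiles <- function(x, ...) {
  cat("compound assay profiles:", length(x), "compound(s)\n")
  if (length(x)) {
    n <- vapply(x, `[[`, 0, "n_assay")
    cat("  N_assay range:", min(n), "-", max(n), "\n")
    cat("  compounds with any active outcome:",
        sum(vapply(x, `[[`, TRUE, "any_active")), "\n")
  }
  invisible(x)
}

#' Write / read resolved outcomes
#'
#' Plain TSV serialization of the resolved outcome table.
#'
#' @param outcomes Resolved outcome `data.frame`.
#' @param path Destination file.
#' @return `path`, invisibly (writer); the outcome `data.frame` (reader).
#' @export
write_resolved_outcomes <- function(outcomes, path) {
  utils::write.table(outcomes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_resolved_outcomes
#' @export
read_resolved_outcomes <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", stringsAsFactors = FALSE)
  out$label <- factor(out$label, levels = c("active", "inactive"))
  out
}
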