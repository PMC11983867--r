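# Assay-diversity scoring and inactive-compound selection. A compound tested
# many times in one assay family tells us little; the diversity score rewards
# testing history spread over distinct assay categories. Each category axis
# (name-cluster, assay type, target) is scored by a normalized Shannon
# entropy, and the three are averaged.

#' Normalized Shannon entropy of category counts
#'
#' Computes `H / log2(n)` where `H = -sum(p * log2(p))` over category
#' proportions `p = f / N` and `n` is the number of distinct categories
#' observed. The result lies in `[0, 1]`: 0 when all observations fall in a
#' single category (no diversity), 1 when they are spread uniformly over the
#' observed categories. By convention the entropy of zero or one category is 0.
#'
#' @param counts Named or unnamed vector of positive integer category counts.
#' @return A number in `[0, 1]`.
#' @examples
#' normalized_entropy(c(x = 5, y = 5))  # 1
#' normalized_entropy(c(x = 7))         # 0
#' normalized_entropy(c(3, 1))          # 0.8113
#' @export
normalized_entropy <- function(counts) {
  if (length(counts) == 0L) return(0)
  counts <- as.numeric(counts)
  if (any(!is.finite(counts)) || any(counts <= 0)) {
    stop("category counts must be positive")
  }
  n <- length(counts)
  if (n <= 1L) return(0)
  p <- counts / sum(counts)
  h <- -sum(p * log2(p))
  min(max(h / log2(n), 0), 1)
}

#' Assay-diversity scores for compound profiles
#'
#' Scores each compound profile on the three category axes and averages the
#' normalized entropies into the assay-diversity score. An axis with no
#' annotated assays (for example missing targets) contributes 0.
#'
#' @param profiles A `compound_profiles` object from
#'   [build_compound_profiles()].
#' @return A `data.frame` with one row per compound: `compound_id`,
#'   `h_cluster`, `h_type`, `h_target`, `d_assay`, `n_assay`, `any_active`.
#' @export
compute_d_assay <- function(profiles) {
  stopifnot(inherits(profiles, "compound_profiles"))
  if (length(profiles) == 0L) {
    return(data.frame(compound_id = character(), h_cluster = numeric(),
                      h_type = numeric(), h_target = numeric(),
                      d_assay = numeric(), n_assay = integer(),
                      any_active = logical(), stringsAsFactors = FALSE))
  }
  h <- t(vapply(profiles, function(p) {
    c(cluster = normalized_entropy(p$counts$cluster),
      type = normalized_entropy(p$counts$type),
      target = normalized_entropy(p$counts$target))
  }, numeric(3)))
  data.frame(
    compound_id = names(profiles),
    h_cluster = unname(h[, "cluster"]),
    h_type = unname(h[, "type"]),
    h_target = unname(h[, "target"]),
    d_assay = unname(rowMeans(h)),
    n_assay = vapply(profiles, function(p) as.integer(p$n_assay), integer(1)),
    any_active = vapply(profiles, function(p) isTRUE(p$any_active),
                        logical(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Derive curation thresholds from score distributions
#'
#' The testing-depth cutoff is a (nearest-rank) percentile of the `n_assay`
#' distribution and the diversity cutoff a quantile of `d_assay` (the median
#' by default). For multimodal testing-depth distributions an optional
#' KDE-based detector reports the rightmost local maximum of the log-scale
#' density instead of the plain percentile. Both cutoffs act as *strict* lower
#' bounds in [select_cics()]. Manual overrides are supported.
#'
#' @param scores Score `data.frame` from [compute_d_assay()].
#' @param n_assay_percentile Percentile (0-100, exclusive) of `n_assay` used
#'   as the testing-depth cutoff.
#' @param d_assay_quantile Quantile (0-1) of `d_assay` used as the diversity
#'   cutoff.
#' @param method `"percentile"` (nearest-rank, the default) or `"kde"`
#'   (rightmost local maximum of a log-scale kernel density of `n_assay`).
#' @param n_assay_cutoff,d_assay_cutoff Optional manual overrides; when given
#'   the corresponding distribution-derived value is ignored.
#' @return An object of class `curation_thresholds`: a list with
#'   `n_assay_cutoff`, `d_assay_cutoff` and a `provenance` record.
#' @export
derive_thresholds <- function(scores, n_assay_percentile = 93,
                              d_assay_quantile = 0.5,
                              method = c("percentile", "kde"),
                              n_assay_cutoff = NULL, d_assay_cutoff = NULL) {
  stopifnot(is.data.frame(scores), nrow(scores) >= 1L)
  method <- match.arg(method)
  if (is.null(n_assay_cutoff)) {
    if (n_assay_percentile <= 0 || n_assay_percentile >= 100) {
      stop("n_assay_percentile must lie strictly between 0 and 100")
    }
    if (method == "kde" && length(unique(scores$n_assay)) > 2L) {
      d <- stats::density(log(scores$n_assay + 1))
      peaks <- which(diff(sign(diff(d$y))) == -2) + 1L
      if (length(peaks) == 0L) peaks <- which.max(d$y)
      n_cut <- exp(d$x[max(peaks)]) - 1
      n_prov <- "kde rightmost local maximum (log scale)"
    } else {
      n_cut <- unname(stats::quantile(scores$n_assay,
                                      n_assay_percentile / 100, type = 1))
      n_prov <- sprintf("nearest-rank percentile %g of n_assay",
                        n_assay_percentile)
    }
  } else {
    n_cut <- n_assay_cutoff
    n_prov <- "manual"
  }
  if (is.null(d_assay_cutoff)) {
    if (d_assay_quantile < 0 || d_assay_quantile > 1) {
      stop("d_assay_quantile must lie in [0, 1]")
    }
    d_cut <- unname(stats::quantile(scores$d_assay, d_assay_quantile,
                                    type = 1))
    d_prov <- sprintf("quantile %g of d_assay", d_assay_quantile)
  } else {
    d_cut <- d_assay_cutoff
    d_prov <- "manual"
  }
  structure(list(n_assay_cutoff = n_cut, d_assay_cutoff = d_cut,
                 provenance = list(n_assay = n_prov, d_assay = d_prov)),
            class = "curation_thresholds")
}

#' @export
print.curation_thresholds <- function(x, ...) {
  cat("curation thresholds (strict lower bounds):\n")
  cat(sprintf("  N_assay  > %g   [%s]\n", x$n_assay_cutoff,
              x$provenance$n_assay))
  cat(sprintf("  D_assay  > %g   [%s]\n", x$d_assay_cutoff,
              x$provenance$d_assay))
  invisible(x)
}

#' Select curated inactive compounds
#'
#' A compound qualifies when it was tested in strictly more than
#' `n_assay_cutoff` assays, with assay diversity strictly above
#' `d_assay_cutoff`, and was inactive in every tested bioassay.
#'
#' @param scores Score `data.frame` from [compute_d_assay()].
#' @param thresholds A `curation_thresholds` object (or list with
#'   `n_assay_cutoff`/`d_assay_cutoff`).
#' @return Character vector of selected compound ids.
#' @export
select_cics <- function(scores, thresholds) {
  stopifnot(is.data.frame(scores))
  need <- c("compound_id", "n_assay", "d_assay", "any_active")
  missing_col <- setdiff(need, names(scores))
  if (length(missing_col)) {
    stop("scores lack column(s): ", paste(missing_col, collapse = ", "))
  }
  if (any(is.na(scores$d_assay)) || any(is.na(scores$n_assay))) {
    stop("scores contain missing values")
  }
  sel <- scores$n_assay > thresholds$n_assay_cutoff &
    scores$d_assay > thresholds$d_assay_cutoff &
    !scores$any_active
  scores$compound_id[sel]
}

#' Write diversity scores as TSV
#'
#' @param scores Score `data.frame` from [compute_d_assay()].
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_diversity_scores <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
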