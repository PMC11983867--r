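# Generator evaluation metrics on a sample of generated strings against the
# reference set: validity, uniqueness, novelty, and cosine similarity of
# Murcko-scaffold and BRICS-fragment frequency profiles. Uniqueness and
# novelty are computed at the level of canonical structures.

#' Fraction of syntactically valid SMILES
#'
#' @param generated Character vector of generated strings.
#' @return Share of strings that parse into a molecule.
#' @export
fraction_valid <- function(generated) {
  if (length(generated) == 0L) stop("no generated strings")
  mean(is_valid_smiles(generated))
}

#' Fraction of unique structures among valid strings
#'
#' @param generated Character vector of generated strings.
#' @return Number of distinct canonical structures divided by the number of
#'   valid strings.
#' @export
fraction_unique <- function(generated) {
  can <- canonicalize_smiles(generated)
  can <- can[!is.na(can)]
  if (length(can) == 0L) stop("no valid strings to assess")
  length(unique(can)) / length(can)
}

#' Fraction of novel structures
#'
#' @param generated Character vector of generated strings.
#' @param reference Character vector of reference SMILES (canonicalized
#'   internally).
#' @return Share of distinct canonical structures absent from the reference
#'   set.
#' @export
fraction_novel <- function(generated, reference) {
  can <- unique(canonicalize_smiles(generated))
  can <- can[!is.na(can)]
  if (length(can) == 0L) stop("no valid strings to assess")
  ref <- if (length(reference)) {
    can_ref <- canonicalize_smiles(reference)
    can_ref[!is.na(can_ref)]
  } else {
    character()
  }
  mean(!can %in% ref)
}

# Cosine similarity between two named frequency vectors after normalizing
# each to sum 1 over the union of keys.
.freq_cosine <- function(fa, fb) {
  keys <- union(names(fa), names(fb))
  # positional assignment: "" (the no-scaffold key) defeats name indexing
  a <- rep(0, length(keys))
  b <- rep(0, length(keys))
  a[match(names(fa), keys)] <- as.numeric(fa)
  b[match(names(fb), keys)] <- as.numeric(fb)
  a <- a / sum(a)
  b <- b / sum(b)
  den <- sqrt(sum(a^2)) * sqrt(sum(b^2))
  if (den == 0) return(0)
  sum(a * b) / den
}

#' Scaffold-profile similarity of two molecule sets
#'
#' Builds Murcko-scaffold frequency vectors for the generated and reference
#' sets over the union of scaffold keys, normalizes each to sum 1, and
#' returns their cosine similarity. Acyclic molecules map to an explicit
#' no-scaffold key so the vectors stay comparable.
#'
#' @param generated,reference Character vectors of valid SMILES.
#' @return Cosine similarity in `[0, 1]`.
#' @export
scaffold_similarity <- function(generated, reference) {
  if (length(generated) == 0L || length(reference) == 0L) {
    stop("both molecule sets must be non-empty")
  }
  fa <- table(murcko_scaffold(generated))
  fb <- table(murcko_scaffold(reference))
  .freq_cosine(fa, fb)
}

#' Fragment-profile similarity of two molecule sets
#'
#' Same construction as [scaffold_similarity()] over BRICS-fragment
#' frequency vectors (see [brics_fragments()]).
#'
#' @param generated,reference Character vectors of valid SMILES.
#' @return Cosine similarity in `[0, 1]`.
#' @export
fragment_similarity <- function(generated, reference) {
  if (length(generated) == 0L || length(reference) == 0L) {
    stop("both molecule sets must be non-empty")
  }
  fa <- table(unlist(brics_fragments(generated), use.names = FALSE))
  fb <- table(unlist(brics_fragments(reference), use.names = FALSE))
  if (length(fa) == 0L || length(fb) == 0L) return(0)
  .freq_cosine(fa, fb)
}

#' Full generator evaluation report
#'
#' Computes the five quantitative metrics on a sample of generated strings.
#'
#' @param generated Character vector of generated strings (typically a
#'   10,000-string sample).
#' @param reference Character vector of reference SMILES.
#' @return A `gen_metrics` object: list with `fraction_valid`,
#'   `fraction_unique`, `fraction_novel`, `scaffold_similarity`,
#'   `fragment_similarity` and `sample_size`.
#' @export
generation_metrics <- function(generated, reference) {
  if (length(generated) == 0L) stop("no generated strings")
  can <- canonicalize_smiles(generated)
  valid <- can[!is.na(can)]
  out <- list(fraction_valid = mean(!is.na(can)),
              fraction_unique = if (length(valid)) {
                length(unique(valid)) / length(valid)
              } else {
                NA_real_
              },
              fraction_novel = if (length(valid)) {
                fraction_novel(valid, reference)
              } else {
                NA_real_
              },
              scaffold_similarity = if (length(valid)) {
                scaffold_similarity(unique(valid), reference)
              } else {
                NA_real_
              },
              fragment_similarity = if (length(valid)) {
                fragment_similarity(unique(valid), reference)
              } else {
                NA_real_
              },
              sample_size = length(generated))
  structure(out, class = "gen_metrics")
}

#' @export
print.gen_metrics <- function(x, ...) {
  cat("generator evaluation on", x$sample_size, "sampled string(s):\n")
  for (nm in c("fraction_valid", "fraction_unique", "fraction_novel",
               "scaffold_similarity", "fragment_similarity")) {
    cat(sprintf("  %-20s %.4f\n", nm, x[[nm]]))
  }
  invisible(x)
}
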