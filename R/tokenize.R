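# SMILES tokenization for the recurrent generator. Default mode is atom-wise:
# bracket atoms, two-letter organic-subset elements (Cl, Br) and two-digit
# ring closures (%nn) are single tokens, so detokenization is simple
# concatenation and round-trips exactly. A pure character mode is available.

.smiles_token_regex <- "\\[[^]]+\\]|Br|Cl|%[0-9]{2}|."

#' Tokenize SMILES strings
#'
#' @param smiles Character vector of SMILES strings.
#' @param mode `"atom"` (default): multi-character units (bracket atoms,
#'   `Cl`/`Br`, `%nn` ring closures) are single tokens; `"char"`: every
#'   character is its own token.
#' @return List of character vectors, one per input string.
#' @examples
#' tokenize_smiles("C[NH3+]Cl")[[1]]  # "C" "[NH3+]" "Cl"
#' @export
tokenize_smiles <- function(smiles, mode = c("atom", "char")) {
  mode <- match.arg(mode)
  stopifnot(is.character(smiles))
  if (mode == "char") {
    return(strsplit(smiles, "", fixed = TRUE))
  }
  regmatches(smiles, gregexpr(.smiles_token_regex, smiles))
}

#' Reassemble tokens into a SMILES string
#'
#' Inverse of [tokenize_smiles()]: concatenation.
#'
#' @param tokens Character vector of tokens (or list of such vectors).
#' @return Character scalar (or vector, for a list input).
#' @export
detokenize_smiles <- function(tokens) {
  if (is.list(tokens)) {
    return(vapply(tokens, paste0, "", collapse = ""))
  }
  paste0(tokens, collapse = "")
}

# Reserved marker indices: 1 = pad, 2 = begin, 3 = end; content from 4 on.
.PAD <- 1L
.BOS <- 2L
.EOS <- 3L

#' Token vocabulary for the generator
#'
#' Collects the distinct tokens of a corpus and prepends the reserved
#' pad/begin/end markers.
#'
#' @param token_lists List of token vectors (from [tokenize_smiles()]).
#' @return A `smiles_vocab` object.
#' @export
build_vocab <- function(token_lists) {
  toks <- sort(unique(unlist(token_lists)))
  if (length(toks) == 0L) stop("cannot build a vocabulary from no tokens")
  vocab <- c("<pad>", "<bos>", "<eos>", toks)
  structure(list(tokens = vocab,
                 index = stats::setNames(seq_along(vocab), vocab)),
            class = "smiles_vocab")
}

#' @export
print.smiles_vocab <- function(x, ...) {
  cat("SMILES token vocabulary:", length(x$tokens) - 3L,
      "content tokens (+ pad/begin/end)\n")
  invisible(x)
}

#' Encode token lists as padded index sequences
#'
#' Rows are begin-prefixed, end-suffixed, pad-filled index vectors; tokens
#' outside the vocabulary raise an error.
#'
#' @param token_lists List of token vectors.
#' @param vocab A `smiles_vocab` from [build_vocab()].
#' @param max_len Optional cap on the content length.
#' @return Integer matrix, one row per sequence.
#' @export
encode_tokens <- function(token_lists, vocab, max_len = NULL) {
  ids <- lapply(token_lists, function(tk) {
    v <- vocab$index[tk]
    if (anyNA(v)) {
      stop("token(s) outside vocabulary: ",
           paste(unique(tk[is.na(v)]), collapse = " "))
    }
    c(.BOS, unname(v), .EOS)
  })
  len <- lengths(ids)
  width <- if (is.null(max_len)) max(len) else max_len + 2L
  if (any(len > width)) stop("sequence longer than maximum length")
  mat <- matrix(.PAD, nrow = length(ids), ncol = width)
  for (i in seq_along(ids)) mat[i, seq_len(len[i])] <- ids[[i]]
  mat
}

decode_ids <- function(ids, vocab) {
  ids <- ids[ids > .EOS]
  paste0(vocab$tokens[ids], collapse = "")
}
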