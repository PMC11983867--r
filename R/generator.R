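# The inactive-compound SMILES generator: randomized-SMILES augmentation of a
# reference set, an LSTM language model over SMILES tokens, temperature
# sampling into a generation run (canonical structure -> generation count),
# and the post-generation quality filters.

#' Generator configuration
#'
#' Collects the hyperparameters of the recurrent SMILES generator. Training
#' uses Adam with early stopping monitored on held-out augmented strings.
#'
#' @param n_layers Number of LSTM layers (1 or 3 in the reference sweeps; any
#'   positive integer is accepted).
#' @param augmentation_factor Randomized SMILES written per reference
#'   molecule (1 disables augmentation).
#' @param hidden_size Hidden units per LSTM layer.
#' @param embed_size Dimension of the learned token embeddings.
#' @param max_epochs Training epoch cap.
#' @param learning_rate,beta1,beta2 Adam hyperparameters.
#' @param min_delta,patience Early stopping: smallest improvement of the
#'   held-out cross-entropy that counts, and epochs to wait for it.
#' @param val_fraction Fraction of augmented strings held out for the early
#'   stopping monitor.
#' @param batch_size Minibatch size.
#' @param max_len Maximum sampled sequence length in tokens.
#' @param temperature Default sampling temperature.
#' @param tokenizer `"atom"` or `"char"` tokenization (see
#'   [tokenize_smiles()]).
#' @param seed Integer seed controlling initialization, augmentation,
#'   shuffling and the validation split.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_layers = 1L, augmentation_factor = 10L,
                             hidden_size = 256L, embed_size = 128L,
                             max_epochs = 300L, learning_rate = 0.001,
                             beta1 = 0.9, beta2 = 0.999, min_delta = 0.001,
                             patience = 10L, val_fraction = 0.1,
                             batch_size = 128L, max_len = 120L,
                             temperature = 1.0,
                             tokenizer = c("atom", "char"), seed = 1L) {
  tokenizer <- match.arg(tokenizer)
  if (n_layers < 1L) stop("n_layers must be a positive integer")
  if (augmentation_factor < 1L) stop("augmentation_factor must be >= 1")
  stopifnot(hidden_size >= 1L, embed_size >= 1L, max_epochs >= 1L,
            learning_rate > 0, beta1 > 0, beta1 < 1, beta2 > 0, beta2 < 1,
            min_delta >= 0, patience >= 1L, val_fraction >= 0,
            val_fraction < 1, batch_size >= 1L, max_len >= 2L,
            temperature >= 0)
  structure(list(n_layers = as.integer(n_layers),
                 augmentation_factor = as.integer(augmentation_factor),
                 hidden_size = as.integer(hidden_size),
                 embed_size = as.integer(embed_size),
                 max_epochs = as.integer(max_epochs),
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 min_delta = min_delta, patience = as.integer(patience),
                 val_fraction = val_fraction,
                 batch_size = as.integer(batch_size),
                 max_len = as.integer(max_len), temperature = temperature,
                 tokenizer = tokenizer, seed = as.integer(seed)),
            class = "generator_config")
}

#' Randomized SMILES augmentation
#'
#' Writes `factor` SMILES strings for one molecule by permuting the atom
#' order before serialization. Every returned string canonicalizes back to
#' the input's canonical form; duplicates are permitted (small molecules
#' admit few distinct orderings).
#'
#' @param smiles A single valid SMILES string.
#' @param factor Number of strings to produce.
#' @param seed Integer seed.
#' @return Character vector of `factor` SMILES strings.
#' @export
augment_smiles <- function(smiles, factor, seed = 1L) {
  stopifnot(length(smiles) == 1L, factor >= 1L)
  if (!is_valid_smiles(smiles)) stop("invalid SMILES: ", smiles)
  sdf <- parse_smiles(smiles)[[1]]
  n <- nrow(ChemmineR::atomblock(sdf))
  set.seed(seed)
  out <- character(factor)
  for (k in seq_len(factor)) {
    perm <- if (n == 1L) 1L else sample.int(n)
    s <- sdf_to_smiles(sdf_reindex_atoms(sdf, perm))
    # very rare writer hiccups fall back to the input ordering
    out[k] <- if (is.na(s)) smiles else s
  }
  out
}

# Corpus-level augmentation used by train_generator: one randomized pass per
# molecule per round, seeded per molecule for reproducibility.
.augment_corpus <- function(smiles, factor, seed) {
  if (factor == 1L) return(smiles)
  unlist(lapply(seq_along(smiles), function(i) {
    augment_smiles(smiles[i], factor, seed = seed * 1000L + i)
  }), use.names = FALSE)
}

#' Train the SMILES generator
#'
#' Augments the reference set, builds the token vocabulary from the augmented
#' corpus, and trains the LSTM language model with teacher forcing on
#' begin-prefixed, end-suffixed sequences. Early stopping monitors the
#' cross-entropy of a held-out slice of the augmented strings; the weights of
#' the best epoch are kept.
#'
#' @param reference Character vector of valid SMILES (the curated inactive
#'   set in the intended workflow).
#' @param config A [generator_config()].
#' @return An object of class `smiles_lstm` holding the weights, vocabulary,
#'   configuration, loss history and the canonical reference set.
#' @export
train_generator <- function(reference, config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  if (length(reference) == 0L) stop("reference set is empty")
  can <- canonicalize_smiles(reference)
  if (anyNA(can)) {
    stop("reference contains invalid SMILES: ",
         paste(utils::head(reference[is.na(can)], 5L), collapse = ", "))
  }
  corpus <- .augment_corpus(can, config$augmentation_factor, config$seed)
  toks <- tokenize_smiles(corpus, mode = config$tokenizer)
  too_long <- lengths(toks) > config$max_len - 2L
  if (any(too_long)) {
    corpus <- corpus[!too_long]
    toks <- toks[!too_long]
    if (length(toks) == 0L) stop("all training strings exceed max_len")
  }
  vocab <- build_vocab(toks)
  ids <- encode_tokens(toks, vocab)
  set.seed(config$seed + 7L)
  n <- nrow(ids)
  n_val <- floor(n * config$val_fraction)
  if (n_val >= 1L && n - n_val >= 1L) {
    val_idx <- sample.int(n, n_val)
    ids_val <- ids[val_idx, , drop = FALSE]
    ids_train <- ids[-val_idx, , drop = FALSE]
  } else {
    ids_val <- NULL
    ids_train <- ids
  }
  fit <- .lstm_train(ids_train, ids_val, length(vocab$tokens), config)
  structure(list(params = fit$params, vocab = vocab, config = config,
                 history = fit$history, best_epoch = fit$best_epoch,
                 reference = unique(can)),
            class = "smiles_lstm")
}

#' @export
print.smiles_lstm <- function(x, ...) {
  cat("SMILES LSTM generator\n")
  cat(sprintf("  layers: %d, hidden: %d, embedding: %d, vocabulary: %d\n",
              x$config$n_layers, x$config$hidden_size, x$config$embed_size,
              length(x$vocab$tokens)))
  cat(sprintf("  reference molecules: %d, augmentation: %dx\n",
              length(x$reference), x$config$augmentation_factor))
  cat(sprintf("  trained %d epoch(s); best held-out loss %.4f at epoch %d\n",
              nrow(x$history),
              if (all(is.na(x$history$val_loss))) min(x$history$train_loss)
              else min(x$history$val_loss, na.rm = TRUE),
              x$best_epoch))
  invisible(x)
}

#' @export
summary.smiles_lstm <- function(object, ...) {
  print(object)
  cat("\nloss history (last 5 epochs):\n")
  print(utils::tail(object$history, 5L), row.names = FALSE)
  invisible(object$history)
}

#' Sample SMILES strings from a trained generator
#'
#' Draws strings token by token until the end marker or the length cap, then
#' aggregates them into a generation run: the total number of raw samples and
#' a frequency map keyed by canonical structure. Strings that do not parse
#' count toward `raw_count` but not toward the map.
#'
#' @param model A `smiles_lstm` from [train_generator()].
#' @param count Number of strings to sample.
#' @param seed Integer seed.
#' @param temperature Sampling temperature; defaults to the model
#'   configuration. Near zero reduces to greedy decoding.
#' @return An object of class `generation_run` with fields `raw_count`,
#'   `frequencies` (named integer vector, canonical SMILES -> count),
#'   `n_valid`, and `provenance`.
#' @export
sample_generator <- function(model, count, seed = 1L,
                             temperature = model$config$temperature) {
  stopifnot(inherits(model, "smiles_lstm"), count >= 1L)
  raw <- .lstm_sample(model$params, model$vocab, count,
                      model$config$max_len, temperature, seed)
  can <- canonicalize_smiles(raw)
  valid <- !is.na(can)
  freq <- if (any(valid)) {
    tab <- table(can[valid])
    stats::setNames(as.integer(tab), names(tab))
  } else {
    stats::setNames(integer(), character())
  }
  structure(list(raw_count = length(raw), frequencies = freq,
                 n_valid = sum(valid),
                 provenance = list(seed = seed, temperature = temperature,
                                   n_layers = model$config$n_layers,
                                   augmentation_factor =
                                     model$config$augmentation_factor)),
            class = "generation_run")
}

#' @export
#' @method simulate smiles_lstm
simulate.smiles_lstm <- function(object, nsim = 1L, seed = NULL, ...) {
  if (is.null(seed)) seed <- 1L
  run <- sample_generator(object, count = nsim, seed = seed, ...)
  run
}

#' @export
print.generation_run <- function(x, ...) {
  cat("generation run:", x$raw_count, "sampled string(s)\n")
  cat(sprintf("  valid: %d (%.1f%%), distinct structures: %d\n",
              x$n_valid, 100 * x$n_valid / max(x$raw_count, 1L),
              length(x$frequencies)))
  if (length(x$frequencies)) {
    top <- sort(x$frequencies, decreasing = TRUE)
    cat("  most frequent:", names(top)[1L], "x", top[[1L]], "\n")
  }
  invisible(x)
}

# Organic-subset filter: at least one carbon, and only elements commonly seen
# in drug-like organic molecules.
.organic_elements <- c("H", "B", "C", "N", "O", "F", "P", "S", "Cl", "Se",
                       "Br", "I")

.smiles_elements <- function(smiles) {
  toks <- tokenize_smiles(smiles)[[1]]
  els <- character(0)
  for (tk in toks) {
    if (startsWith(tk, "[")) {
      m <- regmatches(tk, regexpr("[A-Za-z][a-z]?", tk))
      if (length(m)) {
        el <- m[[1]]
        els <- c(els, paste0(toupper(substr(el, 1, 1)), substring(el, 2)))
      }
    } else if (grepl("^[A-Za-z]", tk)) {
      els <- c(els, paste0(toupper(substr(tk, 1, 1)), substring(tk, 2)))
    }
  }
  els
}

.is_organic_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    els <- .smiles_elements(s)
    any(els == "C") && all(els %in% .organic_elements)
  }, logical(1), USE.NAMES = FALSE)
}

#' Filter a generation run
#'
#' Applies the post-generation quality rules: canonical strings shorter than
#' `min_chars` characters are removed, as are structures failing the organic
#' filter (no carbon, or elements outside H/B/C/N/O/F/P/S/Cl/Se/Br/I -- which
#' discards inorganic species such as azides and halide salts) and structures
#' already present in the reference set. Frequencies of survivors are
#' untouched.
#'
#' @param run A `generation_run`.
#' @param reference Character vector of canonical SMILES to exclude.
#' @param min_chars Minimum character length of the canonical SMILES.
#' @return A filtered `generation_run`.
#' @export
filter_generated <- function(run, reference = character(), min_chars = 15L) {
  stopifnot(inherits(run, "generation_run"))
  keys <- names(run$frequencies)
  if (length(keys)) {
    keep <- nchar(keys) >= min_chars &
      .is_organic_smiles(keys) &
      !(keys %in% reference)
    run$frequencies <- run$frequencies[keep]
  }
  run
}

#' Generation-frequency subset
#'
#' Structures generated strictly more often than a bound. The preliminary
#' sets at bounds 100, 30, 10, 3 and 1 are nested by construction.
#'
#' @param run A `generation_run`.
#' @param min_frequency_exclusive Strict lower bound on generation count.
#' @return Character vector of canonical SMILES.
#' @export
frequency_subset <- function(run, min_frequency_exclusive) {
  stopifnot(inherits(run, "generation_run"), min_frequency_exclusive >= 0)
  names(run$frequencies)[run$frequencies > min_frequency_exclusive]
}

#' Persist and restore generation runs
#'
#' Runs are stored as a TSV of (canonical_smiles, frequency) plus a JSON
#' provenance sidecar.
#'
#' @param run A `generation_run`.
#' @param path Path of the TSV file; provenance goes to `<path>.json`.
#' @return `path` invisibly (writer); a `generation_run` (reader).
#' @export
write_generation_run <- function(run, path) {
  utils::write.table(
    data.frame(canonical_smiles = names(run$frequencies),
               frequency = as.integer(run$frequencies)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    c(run$provenance, list(raw_count = run$raw_count,
                           n_valid = run$n_valid)),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_generation_run
#' @export
read_generation_run <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(raw_count = meta$raw_count,
                 frequencies = stats::setNames(as.integer(tab$frequency),
                                               tab$canonical_smiles),
                 n_valid = meta$n_valid,
                 provenance = meta[setdiff(names(meta),
                                           c("raw_count", "n_valid"))]),
            class = "generation_run")
}

#' Read and write .smi molecule lists
#'
#' Minimal SMILES-file helpers: one molecule per line, optional title after
#' whitespace.
#'
#' @param path File path.
#' @param smiles Character vector of SMILES.
#' @param names Optional titles.
#' @return Character vector of SMILES (reader), `path` invisibly (writer).
#' @export
read_smi <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sub("[ \t].*", "", lines)
}

#' @rdname read_smi
#' @export
write_smi <- function(smiles, path, names = NULL) {
  out <- if (is.null(names)) smiles else paste(smiles, names)
  writeLines(out, path)
  invisible(path)
}
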