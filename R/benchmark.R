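# Negative-set benchmarking harness. For each benchmark endpoint (verified
# actives and inactives) and each negative-sourcing strategy, a fingerprint
# random-forest classifier is trained on a strategy-specific training set and
# scored on a hold-out test set of verified compounds that is identical
# across strategies, over repeated splits. Comparative statistics relate
# performance to the chemical similarity of the negative pool.

#' Define a benchmark endpoint
#'
#' @param id Endpoint identifier.
#' @param actives Character vector of verified active SMILES.
#' @param inactives Character vector of verified inactive SMILES.
#' @return An `endpoint` object.
#' @export
endpoint <- function(id, actives, inactives) {
  stopifnot(length(actives) >= 1L, length(inactives) >= 1L)
  if (length(intersect(actives, inactives))) {
    stop("actives and inactives overlap")
  }
  structure(list(id = id, actives = actives, inactives = inactives),
            class = "endpoint")
}

#' Define a negative-sourcing strategy
#'
#' Three families are supported: `baseline` trains on the endpoint's own
#' verified inactives; `sampled_negatives` samples training negatives from an
#' external pool (curated set, generated set, or a database sample);
#' `decoy_negatives` reads a decoy list (semantically identical to sampling
#' from the decoy pool; kept distinct for reporting).
#'
#' @param name One of `baseline`, `sampled_negatives`, `decoy_negatives`.
#' @param negative_pool Character vector of SMILES used as the training
#'   negative source (ignored for `baseline`).
#' @param label Display label (defaults to `name`).
#' @param ratio_cap Maximum training/test negatives per positive.
#' @return A `strategy_spec` object.
#' @export
strategy_spec <- function(name = c("baseline", "sampled_negatives",
                                   "decoy_negatives"),
                          negative_pool = NULL, label = NULL,
                          ratio_cap = 2.0) {
  name <- match.arg(name)
  if (ratio_cap <= 0) stop("ratio_cap must be positive")
  if (name != "baseline" &&
      (is.null(negative_pool) || length(negative_pool) == 0L)) {
    stop("strategy '", name, "' needs a non-empty negative pool")
  }
  structure(list(name = name, negative_pool = negative_pool,
                 label = if (is.null(label)) name else label,
                 ratio_cap = ratio_cap),
            class = "strategy_spec")
}

# Deterministic child seeds: master seed plus a labelled counter, kept well
# inside the 32-bit integer range so strategy arms stay paired.
.child_seed <- function(master, endpoint_idx, repeat_idx, purpose) {
  p <- c(split = 0L, negatives = 1L, model = 2L)[[purpose]]
  (master * 7919L + endpoint_idx * 104729L + repeat_idx * 131L + p) %%
    2147483562L
}

#' Assemble one train/test split
#'
#' The hold-out test set is always drawn from the endpoint's verified
#' actives and inactives and depends only on the split seed, so all
#' strategies see the identical test set. Training negatives come from the
#' strategy's source and both train and test negatives are undersampled to
#' at most `ratio_cap` times the positives.
#'
#' @param ep An [endpoint()].
#' @param strategy A [strategy_spec()].
#' @param holdout_fraction Fraction of verified compounds held out.
#' @param split_seed Seed for the hold-out split and test undersampling
#'   (shared across strategies).
#' @param negative_seed Seed for sampling training negatives from the pool.
#' @param fp_cache Optional precomputed fingerprint lookup (named list of
#'   fingerprint rows) to avoid recomputation; built on the fly when `NULL`.
#' @return List with elements `x_train`, `y_train`, `x_test`, `y_test`
#'   (fingerprint matrices and 0/1 labels) and `test_smiles`.
#' @export
assemble_training_set <- function(ep, strategy, holdout_fraction = 0.2,
                                  split_seed = 1L, negative_seed = 2L,
                                  fp_cache = NULL) {
  stopifnot(inherits(ep, "endpoint"), inherits(strategy, "strategy_spec"))
  n_act <- length(ep$actives)
  n_inact <- length(ep$inactives)
  n_act_test <- max(1L, round(holdout_fraction * n_act))
  n_inact_test <- max(1L, round(holdout_fraction * n_inact))
  if (n_act_test >= n_act) stop("too few actives for a hold-out split")
  set.seed(split_seed)
  act_test <- sample.int(n_act, n_act_test)
  inact_test <- sample.int(n_inact, n_inact_test)
  test_act <- ep$actives[act_test]
  test_inact <- ep$inactives[inact_test]
  # test undersampling: negatives capped at ratio_cap x positives
  cap_test <- floor(strategy$ratio_cap * length(test_act))
  if (length(test_inact) > cap_test) {
    test_inact <- sample(test_inact, cap_test)
  }
  train_act <- ep$actives[-act_test]
  pool <- if (strategy$name == "baseline") {
    ep$inactives[-inact_test]
  } else {
    setdiff(strategy$negative_pool, c(test_act, test_inact))
  }
  if (length(pool) == 0L) stop("empty negative pool after exclusions")
  cap_train <- floor(strategy$ratio_cap * length(train_act))
  set.seed(negative_seed)
  train_neg <- if (length(pool) > cap_train) sample(pool, cap_train) else pool
  fp <- function(smiles) {
    if (is.null(fp_cache)) {
      ecfp(smiles)
    } else {
      out <- do.call(rbind, fp_cache[smiles])
      out
    }
  }
  list(x_train = fp(c(train_act, train_neg)),
       y_train = c(rep(1L, length(train_act)), rep(0L, length(train_neg))),
       x_test = fp(c(test_act, test_inact)),
       y_test = c(rep(1L, length(test_act)), rep(0L, length(test_inact))),
       test_smiles = c(test_act, test_inact))
}

#' Train the fingerprint random-forest classifier
#'
#' @param x Binary fingerprint matrix.
#' @param y 0/1 labels (both classes must be present).
#' @param seed Integer seed.
#' @param num_trees Forest size.
#' @return A fitted model usable with [score_classifier()].
#' @export
train_classifier <- function(x, y, seed = 1L, num_trees = 500L) {
  if (length(unique(y)) < 2L) stop("training labels contain a single class")
  x <- matrix(as.numeric(x), nrow = nrow(x))
  colnames(x) <- paste0("b", seq_len(ncol(x)))
  ranger::ranger(x = x, y = factor(y, levels = c(0L, 1L)),
                 num.trees = num_trees, probability = TRUE, seed = seed,
                 num.threads = 1L)
}

#' Score molecules with a trained classifier
#'
#' @param model Fitted model from [train_classifier()].
#' @param x Fingerprint matrix.
#' @return Numeric vector of positive-class scores.
#' @export
score_classifier <- function(model, x) {
  x <- matrix(as.numeric(x), nrow = nrow(x))
  colnames(x) <- paste0("b", seq_len(ncol(x)))
  pr <- stats::predict(model, data = x, num.threads = 1L)$predictions
  pr[, "1"]
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random positive outscores
#' a random negative, ties counted one half.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 (or logical) labels; both classes must be present.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Run the full benchmark factorial
#'
#' Every endpoint x strategy x repeat cell trains a classifier on a
#' strategy-specific training set and evaluates AUROC, MCC and balanced
#' accuracy on the shared hold-out test set; the split seed depends only on
#' (endpoint, repeat), so strategies are paired. Training negatives are
#' resampled every repeat. Per-endpoint mean nearest-neighbor similarity of
#' each strategy's negative pool to the verified actives and inactives is
#' recorded alongside.
#'
#' @param endpoints List of [endpoint()] objects.
#' @param strategies List of [strategy_spec()] objects.
#' @param repeats Number of repeated splits.
#' @param holdout_fraction Hold-out fraction.
#' @param seed Master seed.
#' @param num_trees Forest size per classifier.
#' @param class_threshold Score cut for the confusion-based metrics.
#' @return A `benchmark_result`: list with `results` (one row per cell:
#'   endpoint, strategy, repeat, auroc, mcc, ba) and `similarity` (one row
#'   per endpoint x strategy: mean nn-Tc of the negative pool to verified
#'   actives and inactives).
#' @export
run_benchmark <- function(endpoints, strategies, repeats = 100L,
                          holdout_fraction = 0.2, seed = 1L,
                          num_trees = 500L, class_threshold = 0.5) {
  stopifnot(length(endpoints) >= 1L, length(strategies) >= 1L,
            repeats >= 1L)
  if (inherits(endpoints, "endpoint")) endpoints <- list(endpoints)
  if (inherits(strategies, "strategy_spec")) strategies <- list(strategies)
  all_smiles <- unique(c(
    unlist(lapply(endpoints, function(e) c(e$actives, e$inactives))),
    unlist(lapply(strategies, function(s) s$negative_pool))))
  fpm <- ecfp(all_smiles)
  fp_cache <- stats::setNames(
    lapply(seq_len(nrow(fpm)), function(i) fpm[i, , drop = FALSE]),
    all_smiles)
  rows <- list()
  sim_rows <- list()
  for (ei in seq_along(endpoints)) {
    ep <- endpoints[[ei]]
    act_fp <- do.call(rbind, fp_cache[ep$actives])
    inact_fp <- do.call(rbind, fp_cache[ep$inactives])
    for (si in seq_along(strategies)) {
      st <- strategies[[si]]
      pool <- if (st$name == "baseline") ep$inactives else st$negative_pool
      pool_fp <- do.call(rbind, fp_cache[pool])
      sim_rows[[length(sim_rows) + 1L]] <- data.frame(
        endpoint = ep$id, strategy = st$label,
        nn_tc_to_actives = mean(nearest_neighbor_tc(pool_fp, act_fp)),
        nn_tc_to_inactives = mean(nearest_neighbor_tc(pool_fp, inact_fp)),
        stringsAsFactors = FALSE)
      for (r in seq_len(repeats)) {
        split <- assemble_training_set(
          ep, st, holdout_fraction,
          split_seed = .child_seed(seed, ei, r, "split"),
          negative_seed = .child_seed(seed, ei, r, "negatives") + si,
          fp_cache = fp_cache)
        model <- train_classifier(split$x_train, split$y_train,
                                  seed = .child_seed(seed, ei, r, "model"),
                                  num_trees = num_trees)
        sc <- score_classifier(model, split$x_test)
        cm <- confusion_from_labels(split$y_test, sc >= class_threshold)
        rows[[length(rows) + 1L]] <- data.frame(
          endpoint = ep$id, strategy = st$label, rep = r,
          auroc = auroc(sc, split$y_test),
          mcc = mcc(cm), ba = balanced_accuracy(cm),
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(results = do.call(rbind, rows),
                 similarity = do.call(rbind, sim_rows),
                 repeats = repeats, seed = seed),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("benchmark:", length(unique(x$results$endpoint)), "endpoint(s) x",
      length(unique(x$results$strategy)), "strateg(ies) x", x$repeats,
      "repeat(s)\n")
  print(summary_benchmark(x), row.names = FALSE)
  invisible(x)
}

#' Per-endpoint mean performance
#'
#' @param x A `benchmark_result`.
#' @return A `data.frame`: endpoint, strategy, mean AUROC/MCC/BA over
#'   repeats.
#' @export
summary_benchmark <- function(x) {
  stopifnot(inherits(x, "benchmark_result"))
  agg <- stats::aggregate(cbind(auroc, mcc, ba) ~ endpoint + strategy,
                          data = x$results, FUN = mean)
  agg[order(agg$endpoint, agg$strategy), ]
}

#' Paired Wilcoxon test of two performance vectors
#'
#' Two-sided signed-rank test on per-endpoint means, paired by endpoint.
#' Exact null distribution up to n = 25 (when free of ties and zeros),
#' normal approximation with continuity correction beyond. All-zero
#' differences give p = 1 with a warning.
#'
#' @param perf_a,perf_b Equal-length numeric vectors (n >= 5), paired by
#'   endpoint.
#' @return Two-sided p-value.
#' @export
paired_wilcoxon <- function(perf_a, perf_b) {
  if (length(perf_a) != length(perf_b)) stop("vectors must have equal length")
  if (length(perf_a) < 5L) stop("need at least 5 paired endpoints")
  d <- perf_a - perf_b
  if (all(d == 0)) {
    warning("all paired differences are zero; p = 1")
    return(1)
  }
  exact <- length(d) <= 25L && !any(d == 0) && !anyDuplicated(abs(d))
  res <- suppressWarnings(stats::wilcox.test(perf_a, perf_b, paired = TRUE,
                                             exact = exact, correct = TRUE))
  res$p.value
}

#' Correlation between performance and negative-pool similarity
#'
#' Spearman rank correlation (two-sided) between per-(endpoint, source)
#' performance means and the matched mean nearest-neighbor Tanimoto
#' similarity of the negative pool.
#'
#' @param perf Numeric vector of performance means.
#' @param nn_tc Matched numeric vector of mean nearest-neighbor Tc values.
#' @return List with `rho` and `p`.
#' @export
similarity_performance_correlation <- function(perf, nn_tc) {
  if (length(perf) != length(nn_tc)) stop("vectors must have equal length")
  if (length(perf) < 5L) stop("need at least 5 matched pairs")
  if (length(unique(perf)) == 1L || length(unique(nn_tc)) == 1L) {
    stop("constant vector: rank correlation undefined")
  }
  ct <- suppressWarnings(stats::cor.test(perf, nn_tc, method = "spearman",
                                         alternative = "two.sided"))
  list(rho = unname(ct$estimate), p = ct$p.value)
}
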