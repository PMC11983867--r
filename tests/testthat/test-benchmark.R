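# The negative-set validation harness.

test_that("endpoint and strategy constructors validate their inputs", {
  expect_error(endpoint("e", c("CCO"), c("CCO", "CCN")), "overlap")
  expect_error(strategy_spec("sampled_negatives"), "negative pool")
  expect_error(strategy_spec("baseline", ratio_cap = 0), "positive")
  expect_s3_class(strategy_spec("baseline"), "strategy_spec")
})

test_that("auroc agrees with the exhaustive pairwise oracle", {
  expect_equal(auroc(c(.9, .8, .4, .3), c(1, 0, 1, 0)), 0.75)
  expect_equal(auroc(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  expect_equal(auroc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(auroc(c(1, 2), c(1, 1)), "both classes")

  pair_oracle <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (p in pos) for (q in neg) {
      tot <- tot + (p > q) + 0.5 * (p == q)
    }
    tot / (length(pos) * length(neg))
  }
  set.seed(21)
  for (k in 1:30) {
    n <- sample(5:50, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- round(stats::runif(n), 2)  # rounded scores force ties
    expect_equal(auroc(s, y), pair_oracle(s, y))
  }
})

test_that("auroc matches an independent ROC implementation", {
  set.seed(31)
  y <- rbinom(60, 1, 0.4)
  y[1:2] <- c(0, 1)
  s <- stats::rnorm(60) + y
  expect_equal(auroc(s, y),
               as.numeric(suppressMessages(pROC::auc(y, s))))
})

test_that("training sets are paired, capped and strategy-specific", {
  ep <- endpoint("e1",
                 actives = sprintf("A%02d", 1:20),
                 inactives = sprintf("I%02d", 1:50))
  pool <- sprintf("P%03d", 1:100)
  fpc <- lapply(c(ep$actives, ep$inactives, pool), function(s) {
    set.seed(sum(utf8ToInt(s)))
    matrix(rbinom(64, 1, .3), 1)
  })
  names(fpc) <- c(ep$actives, ep$inactives, pool)
  base <- strategy_spec("baseline")
  samp <- strategy_spec("sampled_negatives", pool)

  s1 <- assemble_training_set(ep, base, split_seed = 9, negative_seed = 1,
                              fp_cache = fpc)
  s2 <- assemble_training_set(ep, samp, split_seed = 9, negative_seed = 2,
                              fp_cache = fpc)
  # identical hold-out test set across strategies for a given split seed
  expect_identical(s1$test_smiles, s2$test_smiles)
  expect_identical(s1$x_test, s2$x_test)
  # undersampling caps negatives at twice the positives, never drops positives
  expect_equal(sum(s1$y_train == 1), 16)  # 20 actives - 20% holdout
  expect_lte(sum(s1$y_train == 0), 2 * sum(s1$y_train == 1))
  expect_lte(sum(s1$y_test == 0), 2 * sum(s1$y_test == 1))
  expect_lte(sum(s2$y_train == 0), 2 * sum(s2$y_train == 1))

  # a small pool is kept whole
  small <- strategy_spec("sampled_negatives", pool[1:5])
  s3 <- assemble_training_set(ep, small, split_seed = 9, negative_seed = 3,
                              fp_cache = fpc)
  expect_equal(sum(s3$y_train == 0), 5)
})

test_that("classifier is seeded and separates separable data", {
  set.seed(33)
  x <- rbind(matrix(rbinom(20 * 64, 1, 0.8), 20),
             matrix(rbinom(20 * 64, 1, 0.1), 20))
  y <- rep(c(1, 0), each = 20)
  m1 <- train_classifier(x, y, seed = 5, num_trees = 100)
  m2 <- train_classifier(x, y, seed = 5, num_trees = 100)
  s1 <- score_classifier(m1, x)
  expect_equal(s1, score_classifier(m2, x))
  expect_equal(auroc(s1, y), 1)
  expect_error(train_classifier(x, rep(1, 40)), "single class")
})

test_that("run_benchmark fills the factorial and reproduces itself", {
  se <- synth_endpoint(synth_endpoint_config(n_actives = 15,
                                             n_inactives = 30,
                                             pool_size = 30, seed = 51))
  eps <- list(se$endpoint,
              synth_endpoint(synth_endpoint_config(n_actives = 15,
                                                   n_inactives = 30,
                                                   pool_size = 30,
                                                   seed = 52))$endpoint)
  strategies <- list(strategy_spec("baseline"),
                     strategy_spec("sampled_negatives", se$negative_pool,
                                   label = "pool"))
  b1 <- run_benchmark(eps, strategies, repeats = 2, seed = 3,
                      num_trees = 60)
  expect_equal(nrow(b1$results), 2 * 2 * 2)
  expect_true(all(b1$results$auroc >= 0 & b1$results$auroc <= 1))
  b2 <- run_benchmark(eps, strategies, repeats = 2, seed = 3,
                      num_trees = 60)
  expect_equal(b1$results, b2$results)
  # a sampled strategy whose pool is the verified inactives mirrors baseline
  mirror <- strategy_spec("sampled_negatives", se$endpoint$inactives,
                          label = "mirror")
  b3 <- run_benchmark(list(se$endpoint),
                      list(strategy_spec("baseline"), mirror),
                      repeats = 2, seed = 3, num_trees = 60)
  s3 <- summary_benchmark(b3)
  expect_equal(s3$auroc[s3$strategy == "baseline"],
               s3$auroc[s3$strategy == "mirror"], tolerance = 0.15)
})

test_that("paired wilcoxon matches the signed-rank distribution", {
  a <- seq(0.5, 0.64, by = 0.01)
  expect_lt(paired_wilcoxon(a + 0.1, a), 0.05)
  # n = 15, distinct all-positive differences: exact two-sided p = 2 * 2^-15
  b <- a + seq(0.01, 0.15, by = 0.01)
  expect_equal(paired_wilcoxon(b, a), 2 / 2^15, tolerance = 1e-10)
  expect_warning(p <- paired_wilcoxon(a, a), "zero")
  expect_equal(p, 1)
  expect_error(paired_wilcoxon(a, a[1:3]), "equal length")
  expect_error(paired_wilcoxon(a[1:3], a[1:3]), "at least 5")
})

test_that("spearman correlation handles the rank examples", {
  r <- similarity_performance_correlation(c(1, 2, 3, 4, 5),
                                          c(2, 1, 4, 3, 5))
  expect_equal(r$rho, 1 - 6 * 4 / (5 * 24))  # 0.8 by the rank formula
  mono <- similarity_performance_correlation(1:6, c(2, 4, 5, 7, 8, 11))
  expect_equal(mono$rho, 1)
  rev_ <- similarity_performance_correlation(1:6, 6:1)
  expect_equal(rev_$rho, -1)
  expect_error(similarity_performance_correlation(1:6, rep(1, 6)),
               "constant")
  expect_error(similarity_performance_correlation(1:3, 3:1), "at least 5")
})
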