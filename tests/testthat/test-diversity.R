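# The assay-diversity score: normalized entropies, thresholds, selection.

test_that("normalized entropy matches hand-computed values", {
  expect_equal(normalized_entropy(c(x = 5, y = 5)), 1)
  expect_equal(normalized_entropy(c(x = 7)), 0)
  oracle <- -(0.75 * log2(0.75) + 0.25 * log2(0.25))  # n = 2: H_max = 1
  expect_equal(normalized_entropy(c(x = 3, y = 1)), oracle, tolerance = 1e-12)
  expect_equal(round(normalized_entropy(c(3, 1)), 4), 0.8113)
  expect_equal(normalized_entropy(integer()), 0)
  expect_error(normalized_entropy(c(2, 0)), "positive")
  expect_error(normalized_entropy(c(2, -1)), "positive")
})

test_that("entropy merge/split monotonicity holds", {
  set.seed(4)
  for (k in 1:25) {
    counts <- stats::rpois(sample(3:6, 1), 4) + 1
    h <- normalized_entropy(counts)
    # merging two categories (unnormalized H drops; compare unnormalized)
    hraw <- function(cc) {
      p <- cc / sum(cc)
      -sum(p * log2(p))
    }
    merged <- c(counts[1] + counts[2], counts[-(1:2)])
    expect_lte(hraw(merged), hraw(counts) + 1e-12)
    # splitting a category (first into two halves) never decreases H
    split <- c(ceiling(counts[1] / 2), floor(counts[1] / 2 + 0.6),
               counts[-1])
    split <- split[split > 0]
    expect_gte(hraw(split), hraw(counts) - 1e-12)
  }
})

test_that("d_assay averages the three axis entropies", {
  out <- harmonize_outcomes(records_df(paste0("A", 1:4), "C1", "inactive"))
  cats <- categories_df(paste0("A", 1:4), c("k1", "k1", "k1", "k2"),
                        type = c("t1", "t2", "t1", "t2"),
                        target = NA)
  sc <- compute_d_assay(build_compound_profiles(out, cats))
  expect_equal(sc$h_cluster, normalized_entropy(c(3, 1)))
  expect_equal(sc$h_type, 1)
  expect_equal(sc$h_target, 0)  # unannotated axis contributes zero
  expect_equal(sc$d_assay, (sc$h_cluster + sc$h_type + sc$h_target) / 3,
               tolerance = 1e-12)
  expect_equal(round(mean(c(0.8113, 1, 0)), 4), 0.6038)

  # all axes single-category -> no diversity
  cats0 <- categories_df(paste0("A", 1:4), "k1", type = "t1", target = "T1")
  sc0 <- compute_d_assay(build_compound_profiles(out, cats0))
  expect_equal(sc0$d_assay, 0)
})

test_that("d_assay is invariant to category relabeling and row order", {
  set.seed(7)
  out <- harmonize_outcomes(records_df(paste0("A", 1:12),
                                       rep(c("C1", "C2"), 6), "inactive"))
  cats <- categories_df(paste0("A", 1:12),
                        sample(c("k1", "k2", "k3"), 12, TRUE),
                        type = sample(c("t1", "t2"), 12, TRUE),
                        target = sample(c("T1", "T2", NA), 12, TRUE))
  base <- compute_d_assay(build_compound_profiles(out, cats))
  relab <- cats
  relab$cluster_id <- paste0("XX_", relab$cluster_id)
  perm <- out[sample.int(nrow(out)), ]
  alt <- compute_d_assay(build_compound_profiles(perm, relab))
  expect_equal(alt[order(alt$compound_id), ], base[order(base$compound_id), ])
})

test_that("thresholds follow the nearest-rank convention", {
  sc <- data.frame(compound_id = paste0("C", 1:100), n_assay = 1:100,
                   d_assay = seq(0.005, 1, by = 0.01) - 0.004,
                   any_active = FALSE)
  th <- derive_thresholds(sc, n_assay_percentile = 93)
  expect_equal(th$n_assay_cutoff, 93)

  sc3 <- data.frame(compound_id = c("a", "b", "c"), n_assay = c(2, 9, 4),
                    d_assay = c(0.2, 0.5, 0.8), any_active = FALSE)
  expect_equal(derive_thresholds(sc3)$d_assay_cutoff, 0.5)

  one <- derive_thresholds(sc3[2, ])
  expect_equal(one$n_assay_cutoff, 9)
  expect_equal(one$d_assay_cutoff, 0.5)

  expect_error(derive_thresholds(sc3, n_assay_percentile = 0), "between")
  expect_error(derive_thresholds(sc3, n_assay_percentile = 100), "between")

  man <- derive_thresholds(sc3, n_assay_cutoff = 394, d_assay_cutoff = 0.568)
  expect_equal(man$n_assay_cutoff, 394)
  expect_equal(man$provenance$n_assay, "manual")
})

test_that("kde threshold detector finds the rightmost mode", {
  set.seed(11)
  n_assay <- c(stats::rpois(400, 3), stats::rpois(100, 150))
  sc <- data.frame(compound_id = seq_along(n_assay), n_assay = n_assay,
                   d_assay = 0.5, any_active = FALSE)
  th <- derive_thresholds(sc, method = "kde")
  # the rightmost density mode sits near the heavy component's mean
  expect_gt(th$n_assay_cutoff, 50)
  expect_lt(th$n_assay_cutoff, 400)
})

test_that("selection applies strict bounds and the all-inactive rule", {
  sc <- data.frame(
    compound_id = c("in", "act", "low_n", "low_d", "edge_n", "edge_d"),
    n_assay = c(10, 10, 5, 10, 5, 10),
    d_assay = c(0.7, 0.7, 0.9, 0.4, 0.9, 0.5),
    any_active = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE))
  th <- list(n_assay_cutoff = 5, d_assay_cutoff = 0.5)
  expect_equal(select_cics(sc, th), "in")

  # monotone non-increasing in either cutoff
  set.seed(2)
  pop <- data.frame(compound_id = 1:200,
                    n_assay = sample(1:50, 200, TRUE),
                    d_assay = stats::runif(200),
                    any_active = stats::runif(200) < 0.3)
  sel_size <- function(nc, dc) {
    length(select_cics(pop, list(n_assay_cutoff = nc, d_assay_cutoff = dc)))
  }
  for (nc in c(0, 10, 20, 40)) {
    expect_true(all(diff(vapply(c(0, .25, .5, .75),
                                function(dc) sel_size(nc, dc), 0)) <= 0))
  }
  for (dc in c(0, 0.5)) {
    expect_true(all(diff(vapply(c(0, 10, 25, 45),
                                function(nc) sel_size(nc, dc), 0)) <= 0))
  }

  expect_error(select_cics(pop[, 1:3], th), "any_active")
})
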