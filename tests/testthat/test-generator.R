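# Tokenizer, augmentation, generator training/sampling, filters, subsets.

test_that("tokenizer round-trips SMILES including multi-character tokens", {
  smis <- c("C[NH3+]Cl", "BrCC(=O)N", "C%12CCCCC%12",
            "c1ccc(cc1)[C@@H](N)C(=O)O", "FC(F)(F)c1ccc(Cl)cc1")
  toks <- tokenize_smiles(smis)
  expect_equal(detokenize_smiles(toks), smis)
  expect_equal(toks[[1]], c("C", "[NH3+]", "Cl"))
  expect_true("%12" %in% toks[[3]])
  # char mode splits everything
  expect_equal(tokenize_smiles("Cl", mode = "char")[[1]], c("C", "l"))
  # fixture corpus round-trips
  corp <- synth_smiles_corpus(60, seed = 3)
  expect_equal(detokenize_smiles(tokenize_smiles(corp)), corp)
})

test_that("vocabulary encodes and rejects unknown tokens", {
  toks <- tokenize_smiles(c("CCO", "CCN"))
  v <- build_vocab(toks)
  ids <- encode_tokens(toks, v)
  expect_equal(dim(ids), c(2L, 5L))  # bos + 3 tokens + eos
  expect_equal(ids[1, 1], 2L)
  expect_equal(ids[1, 5], 3L)
  expect_error(encode_tokens(tokenize_smiles("CCS"), v), "outside vocabulary")
})

test_that("augmentation preserves structure and is seeded", {
  out <- augment_smiles("CCO", 5, seed = 1)
  expect_length(out, 5L)
  expect_true(all(canonicalize_smiles(out) == canonicalize_smiles("CCO")))
  expect_equal(augment_smiles("CCO", 5, seed = 1), out)
  expect_length(augment_smiles("CCO", 1, seed = 1), 1L)
  expect_error(augment_smiles("C1CC", 3), "invalid")
})

test_that("generator config validates hyperparameters", {
  expect_error(generator_config(n_layers = 0), "n_layers")
  expect_error(generator_config(augmentation_factor = 0), "augmentation")
  expect_s3_class(generator_config(n_layers = 3), "generator_config")
})

test_that("training reduces the loss and the model samples deterministically", {
  ref <- synth_smiles_corpus(12, seed = 19)
  cfg <- generator_config(n_layers = 1, augmentation_factor = 4,
                          hidden_size = 24, embed_size = 12,
                          max_epochs = 6, batch_size = 16, seed = 3)
  m <- train_generator(ref, cfg)
  expect_s3_class(m, "smiles_lstm")
  expect_lt(m$history$train_loss[6], m$history$train_loss[1])

  r1 <- sample_generator(m, 40, seed = 5)
  r2 <- sample_generator(m, 40, seed = 5)
  expect_equal(r1$frequencies, r2$frequencies)
  expect_equal(r1$raw_count, 40L)
  expect_lte(sum(r1$frequencies), r1$raw_count)

  s <- simulate(m, nsim = 10, seed = 2)
  expect_s3_class(s, "generation_run")
  expect_equal(s$raw_count, 10L)

  expect_error(train_generator(character(), cfg), "empty")
  expect_error(train_generator("C1CC", cfg), "invalid")
})

test_that("post-generation filters match hand-computed survivors", {
  freq <- c("CCO" = 9L,                                   # too short
            "CCCCCCCCCCCCCCCC" = 5L,                      # survives
            "[N-]=[N+]=[N-]" = 4L,                        # no carbon
            "ClCCCCCCCCCCCCCCCl" = 3L,                    # survives (organic)
            "CCCCCCCCCCCCCCCCO" = 2L,                     # in reference
            "[Se]=[Se]" = 1L)                             # no carbon
  run <- structure(list(raw_count = 30L, frequencies = freq,
                        n_valid = sum(freq), provenance = list()),
                   class = "generation_run")
  out <- filter_generated(run, reference = "CCCCCCCCCCCCCCCCO")
  expect_equal(sort(names(out$frequencies)),
               sort(c("CCCCCCCCCCCCCCCC", "ClCCCCCCCCCCCCCCCl")))
  expect_equal(out$frequencies[["CCCCCCCCCCCCCCCC"]], 5L)
  # filtering never adds keys or increases frequencies
  expect_true(all(names(out$frequencies) %in% names(freq)))
  expect_true(all(out$frequencies <= freq[names(out$frequencies)]))
})

test_that("frequency subsets are strict and nested", {
  freq <- c(A = 150L, B = 40L, C = 12L, D = 5L, E = 2L, F = 1L)
  run <- structure(list(raw_count = 210L, frequencies = freq,
                        n_valid = 210L, provenance = list()),
                   class = "generation_run")
  expect_equal(sort(frequency_subset(run, 10)), c("A", "B", "C"))
  expect_equal(sort(frequency_subset(run, 0)), sort(names(freq)))
  tiers <- lapply(c(100, 30, 10, 3, 1), frequency_subset, run = run)
  for (k in 1:4) {
    expect_true(all(tiers[[k]] %in% tiers[[k + 1]]))
  }
  # "more than once" tier excludes frequency-1 structures
  expect_false("F" %in% frequency_subset(run, 1))
  expect_true("E" %in% frequency_subset(run, 1))
})

test_that("generation runs persist to TSV + JSON and back", {
  freq <- c("CCO" = 3L, "CCN" = 1L)
  run <- structure(list(raw_count = 10L, frequencies = freq, n_valid = 4L,
                        provenance = list(seed = 7, temperature = 1)),
                   class = "generation_run")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_generation_run(run, f)
  back <- read_generation_run(f)
  expect_equal(back$frequencies, freq)
  expect_equal(back$raw_count, 10L)
  expect_equal(back$provenance$seed, 7L)
})
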