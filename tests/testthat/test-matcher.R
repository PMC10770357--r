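# A 3-class toy corpus is enough to exercise training, memorization and
# determinism without a heavyweight fit.
make_toy_fit <- function(seed = 11L) {
  lex <- make_test_lexicon()
  corpus <- make_corpus(
    c("tee pee five three", "tp five three", "tee p fifty three",
      "pick three see ay", "pik three c a", "pick 3 c a",
      "kay ras", "k ras", "kay rass"),
    rep(c("TP53", "PIK3CA", "KRAS"), each = 3),
    rep("GENE", 9))
  # duplicate records so that, after the seeded 0.95 split, every distinct
  # transcription is still represented in the training partition
  doubled <- rbind(corpus, corpus)
  list(lex = lex, corpus = corpus,
       fit = train_matcher(doubled, train_fraction = 0.95, seed = seed))
}

test_that("split arithmetic is floor(f * N) for arbitrary N and f", {
  for (n in c(10L, 24093L, 7L, 101L)) {
    for (f in c(0.9, 0.5, 0.33, 0.75)) {
      corpus <- data.frame(transcription = paste0("t", seq_len(n)),
                           target_value = "x", attribute_type = "GENE",
                           norm = paste0("t", seq_len(n)))
      parts <- split_corpus(corpus, f, seed = 3L)
      expect_equal(nrow(parts$train), floor(f * n),
                   label = sprintf("N=%d f=%g", n, f))
      expect_equal(nrow(parts$test), n - floor(f * n))
      expect_equal(sort(c(parts$train$transcription,
                          parts$test$transcription)),
                   sort(corpus$transcription))
    }
  }
})

test_that("same corpus and seed give identical splits; seeds differ", {
  corpus <- make_corpus(paste0("utt ", 1:50), rep("TP53", 50),
                        rep("GENE", 50))
  a <- split_corpus(corpus, 0.9, seed = 5L)
  b <- split_corpus(corpus, 0.9, seed = 5L)
  expect_identical(rownames(a$train), rownames(b$train))
  c_ <- split_corpus(corpus, 0.9, seed = 6L)
  expect_false(identical(rownames(a$train), rownames(c_$train)))
})

test_that("featurization is deterministic and zeroes unseen n-grams", {
  state <- fit_featurizer(c("tee pee five three", "kay ras"))
  f1 <- featurize("kay ras", state)
  f2 <- featurize("kay ras", state)
  expect_identical(f1, f2)
  expect_identical(f1$phonetic_codes, phonetic_code("kay ras"))
  # a string sharing no n-grams with training contributes all-zero tf-idf
  f3 <- featurize("zzqq", state)
  expect_true(all(f3$char_ngram_tfidf == 0))
  # token structure shows up in the length features
  fa <- featurize("tp53", state)
  fb <- featurize("tp 53", state)
  expect_false(identical(fa$length_features, fb$length_features))
  # degenerate input flagged with zero syllables
  fd <- featurize(NA_character_, state)
  expect_true(fd$degenerate)
  expect_equal(fd$syllable_count, 0L)
})

test_that("the forest memorizes a small training corpus", {
  toy <- make_toy_fit()
  model <- toy$fit$model
  for (i in seq_len(nrow(toy$corpus))) {
    res <- predict_match(model, toy$corpus$norm[i], seed = 1L)
    expect_equal(res$stage, "PREDICTED")
    expect_equal(res$value, toy$corpus$target_value[i],
                 label = toy$corpus$norm[i])
    expect_gt(res$confidence, 0.5)
  }
})

test_that("prediction is reproducible for identical input, model and seed", {
  toy <- make_toy_fit()
  r1 <- predict_match(toy$fit$model, "kay rasss", seed = 9L)
  r2 <- predict_match(toy$fit$model, "kay rasss", seed = 9L)
  expect_identical(r1, r2)
  expect_equal(predict_match(toy$fit$model, NA_character_)$stage,
               "UNRESOLVED")
})

test_that("model artifacts round-trip and version mismatches error", {
  toy <- make_toy_fit()
  path <- withr::local_tempfile(fileext = ".rds")
  save_matcher(toy$fit$model, path)
  model2 <- load_matcher(path)
  expect_identical(predict_match(model2, "kay ras", seed = 2L),
                   predict_match(toy$fit$model, "kay ras", seed = 2L))
  broken <- toy$fit$model
  broken$version <- 999L
  saveRDS(broken, path)
  expect_error(load_matcher(path), "version mismatch")
})

test_that("held-out evaluation reports chain and baseline accuracy", {
  lex <- make_test_lexicon()
  # held-out records whose transcriptions equal their targets -> accuracy 1
  heldout <- make_corpus(c("TP53", "breast cancer", "mutations"),
                         c("TP53", "breast cancer", "mutations"),
                         c("GENE", "CANCER_TYPE", "DATA_TYPE"))
  toy <- make_toy_fit()
  rep <- evaluate_matcher(toy$fit$model, heldout, lex, toy$corpus)
  expect_equal(rep$accuracy, 1)
  expect_equal(rep$baseline_accuracy, 1)
  expect_equal(sum(rep$by_type$n), 3L)
  expect_error(evaluate_matcher(toy$fit$model, heldout[0, ], lex, toy$corpus),
               "empty held-out")
})

test_that("the chain never underperforms the exact-only baseline", {
  lexs <- generate_lexicon(12, 4, 3, seed = 21)
  for (noise in c(0, 0.4)) {
    corpus <- generate_utterance_corpus(lexs,
                                        perturbation_spec(noise, 4, seed = 21))
    fit <- train_matcher(corpus, 0.8, seed = 21)
    parts <- split_corpus(corpus, 0.8, seed = 21)
    rep <- evaluate_matcher(fit$model, parts$test, lexs, parts$train)
    expect_gte(rep$accuracy, rep$baseline_accuracy)
  }
})
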