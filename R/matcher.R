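# Predicted matching: a random forest over character n-gram TF-IDF,
# phonetic-code n-gram, syllable and length features of the normalized
# transcription. The forest's per-tree votes are tallied here so that the
# majority vote — with ties split by a seeded random draw — is explicit.

MODEL_FORMAT_VERSION <- 1L

# run expr under a seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# character n-grams (n in 2:4) over the normalized string with boundary
# markers; spaces become "_" so cross-token boundaries are features too
char_ngrams <- function(text, ns = 2:4) {
  if (is.na(text) || !nzchar(text)) return(character(0))
  s <- paste0("^", gsub(" ", "_", text, fixed = TRUE), "$")
  L <- nchar(s)
  out <- character(0)
  for (n in ns) {
    if (L < n) next
    out <- c(out, substring(s, seq_len(L - n + 1L), seq_len(L - n + 1L) + n - 1L))
  }
  out
}

#' Fit the featurizer on a set of transcriptions
#'
#' Learns the character n-gram vocabulary and IDF weights, and the
#' phonetic-code n-gram vocabulary, from training transcriptions only.
#'
#' @param texts Character vector of normalized transcriptions.
#' @return A `featurizer_state` used by [featurize()].
#' @export
fit_featurizer <- function(texts) {
  texts <- texts[!is.na(texts)]
  if (length(texts) == 0L) stop("no usable training transcriptions")
  n_docs <- length(texts)
  grams <- lapply(texts, char_ngrams)
  df_counts <- table(unlist(lapply(grams, unique)))
  vocab <- names(df_counts)
  idf <- log((1 + n_docs) / (1 + as.numeric(df_counts))) + 1
  names(idf) <- vocab

  phon <- phonetic_code(texts)
  pgrams <- lapply(phon, char_ngrams, ns = 1:3)
  pvocab <- sort(unique(unlist(pgrams)))

  structure(list(vocab = vocab, idf = idf, pvocab = pvocab, n_docs = n_docs),
            class = "featurizer_state")
}

#' Featurize a normalized transcription
#'
#' Deterministic function of the normalized text given a fitted featurizer:
#' TF-IDF weighted character n-gram counts, phonetic-code n-gram counts,
#' syllable count and length features. Unseen n-grams contribute zero.
#'
#' @param normalized Normalized text (single string).
#' @param state A `featurizer_state` from [fit_featurizer()].
#' @return Named list with the feature blocks plus `degenerate` flag; use
#'   [featurize_matrix()] for the flat numeric form the classifier consumes.
#' @export
featurize <- function(normalized, state) {
  stopifnot(inherits(state, "featurizer_state"))
  degenerate <- is.na(normalized) || !nzchar(normalized)
  grams <- if (degenerate) character(0) else char_ngrams(normalized)
  tf <- table(grams)
  tfidf <- numeric(length(state$vocab))
  names(tfidf) <- state$vocab
  hit <- intersect(names(tf), state$vocab)
  tfidf[hit] <- as.numeric(tf[hit]) * state$idf[hit]

  pc <- if (degenerate) "" else phonetic_code(normalized)
  ptf <- table(char_ngrams(pc, ns = 1:3))
  pcounts <- numeric(length(state$pvocab))
  names(pcounts) <- state$pvocab
  phit <- intersect(names(ptf), state$pvocab)
  pcounts[phit] <- as.numeric(ptf[phit])

  toks <- if (degenerate) character(0) else strsplit(normalized, " ", fixed = TRUE)[[1]]
  list(
    char_ngram_tfidf = tfidf,
    phonetic_ngrams = pcounts,
    phonetic_codes = pc,
    syllable_count = if (degenerate) 0L else syllable_count(normalized),
    length_features = c(n_char = if (degenerate) 0L else nchar(normalized),
                        n_tokens = length(toks),
                        n_digits = if (degenerate) 0L else
                          nchar(gsub("[^0-9]", "", normalized))),
    degenerate = degenerate
  )
}

#' Feature matrix for a vector of normalized transcriptions
#' @param texts Character vector of normalized texts.
#' @param state A `featurizer_state`.
#' @return Numeric matrix, one row per text.
#' @export
featurize_matrix <- function(texts, state) {
  rows <- lapply(texts, function(x) {
    f <- featurize(x, state)
    c(f$char_ngram_tfidf, f$phonetic_ngrams,
      syl = as.numeric(f$syllable_count), f$length_features)
  })
  m <- do.call(rbind, rows)
  colnames(m) <- paste0("f", seq_len(ncol(m)))
  m
}

#' Seeded train/held-out split of an utterance corpus
#'
#' The training partition size is `floor(train_fraction * nrow(corpus))`;
#' the shuffle is a deterministic function of `seed`.
#'
#' @param corpus Utterance data frame.
#' @param train_fraction Fraction in (0, 1).
#' @param seed Integer seed.
#' @return List with `train` and `test` data frames.
#' @export
split_corpus <- function(corpus, train_fraction = 0.9, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1, nrow(corpus) > 0)
  n <- nrow(corpus)
  n_train <- floor(train_fraction * n)
  ord <- with_seed(seed, sample.int(n))
  list(train = corpus[ord[seq_len(n_train)], , drop = FALSE],
       test = corpus[ord[setdiff(seq_len(n), seq_len(n_train))], , drop = FALSE])
}

#' Train the predicted-matching model
#'
#' Splits the corpus by a seeded shuffle, fits the featurizer on the
#' training partition only, and trains a 200-tree random forest whose class
#' is the (attribute type, canonical term) pair.
#'
#' @param corpus Utterance data frame from [read_utterance_corpus()].
#' @param train_fraction Training fraction (default 0.9).
#' @param seed Integer seed controlling split and forest.
#' @param num_trees Number of trees (default 200).
#' @return List with `model` (a `matcher_model`) and `heldout` (the held-out
#'   records, disjoint from training).
#' @export
train_matcher <- function(corpus, train_fraction = 0.9, seed = 1L,
                          num_trees = 200L) {
  parts <- split_corpus(corpus, train_fraction, seed)
  train <- parts$train
  if (nrow(train) == 0L) stop("empty training partition")
  state <- fit_featurizer(train$norm)
  labels <- paste(train$attribute_type, train$target_value, sep = "\t")
  x <- featurize_matrix(train$norm, state)
  y <- factor(labels)
  fit <- ranger::ranger(x = x, y = y, num.trees = num_trees, seed = seed,
                        classification = TRUE)
  label_index <- unique(data.frame(
    label = labels,
    value = train$target_value,
    attribute_type = train$attribute_type,
    stringsAsFactors = FALSE))
  model <- structure(list(
    version = MODEL_FORMAT_VERSION,
    fit = fit,
    featurizer = state,
    label_index = label_index,
    num_trees = num_trees,
    training_seed = seed,
    n_train = nrow(train)
  ), class = "matcher_model")
  list(model = model, heldout = parts$test)
}

#' Predict a match with majority voting over forest trees
#'
#' Tallies the per-tree class votes; the class with the most votes wins and
#' exact ties are split by a uniform draw seeded by `seed`, so identical
#' (input, model, seed) always reproduce the same result. Confidence is the
#' winning class's vote fraction.
#'
#' @param model A `matcher_model`.
#' @param normalized Normalized query text.
#' @param seed Integer seed for tie-breaking.
#' @return A `match_result` with stage PREDICTED, or UNRESOLVED for
#'   degenerate (empty) input.
#' @export
predict_match <- function(model, normalized, seed = 1L) {
  stopifnot(inherits(model, "matcher_model"))
  if (length(normalized) != 1L || is.na(normalized) || !nzchar(normalized)) {
    return(match_result())
  }
  x <- featurize_matrix(normalized, model$featurizer)
  pred <- stats::predict(model$fit, data = x, predict.all = TRUE)
  votes_idx <- as.integer(pred$predictions[1, ])
  lev <- model$fit$forest$levels
  tally <- tabulate(votes_idx, nbins = length(lev))
  top <- which(tally == max(tally))
  winner <- if (length(top) == 1L) top else with_seed(seed, sample(top, 1L))
  label <- lev[winner]
  row <- model$label_index[model$label_index$label == label, , drop = FALSE]
  match_result(row$value[1], row$attribute_type[1], "PREDICTED",
               confidence = tally[winner] / length(votes_idx))
}

#' Save / load a matcher model artifact
#'
#' A single serialized file carrying a format version; loading a mismatched
#' version errors cleanly.
#'
#' @param model A `matcher_model`.
#' @param path Artifact path.
#' @return `path` (save) or the model (load).
#' @export
save_matcher <- function(model, path) {
  stopifnot(inherits(model, "matcher_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_matcher
#' @export
load_matcher <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "matcher_model") ||
      !identical(model$version, MODEL_FORMAT_VERSION)) {
    stop("model artifact version mismatch (expected ",
         MODEL_FORMAT_VERSION, ")")
  }
  model
}

#' Evaluate the full resolution chain on held-out utterances
#'
#' Reports the fraction of held-out records resolved to their true target by
#' the full chain (exact, crowdsourced over the training partition, then
#' prediction), the exact-only baseline, and a per-attribute-type breakdown.
#'
#' @param model A `matcher_model`.
#' @param heldout Held-out utterance records (disjoint from training).
#' @param lexicon A `term_lexicon`.
#' @param corpus The training-partition records backing crowdsourced lookup.
#' @param seed Seed for prediction tie-breaks.
#' @return A list: `accuracy`, `baseline_accuracy`, `by_type` data frame,
#'   `n`.
#' @export
evaluate_matcher <- function(model, heldout, lexicon, corpus, seed = 1L) {
  if (is.null(heldout) || nrow(heldout) == 0L) stop("empty held-out set")
  chain_ok <- logical(nrow(heldout))
  exact_ok <- logical(nrow(heldout))
  for (i in seq_len(nrow(heldout))) {
    truth_v <- heldout$target_value[i]
    truth_t <- heldout$attribute_type[i]
    ex <- exact_match(heldout$norm[i], lexicon)
    exact_ok[i] <- is_resolved(ex) &&
      ex$value == truth_v && ex$attribute_type == truth_t
    res <- map_utterance(heldout$transcription[i], lexicon, corpus, model,
                         seed = seed)
    chain_ok[i] <- is_resolved(res) &&
      res$value == truth_v && res$attribute_type == truth_t
  }
  by_type <- do.call(rbind, lapply(split(seq_len(nrow(heldout)),
                                         heldout$attribute_type),
                                   function(idx) {
    data.frame(n = length(idx),
               accuracy = mean(chain_ok[idx]),
               baseline_accuracy = mean(exact_ok[idx]))
  }))
  by_type$attribute_type <- rownames(by_type)
  rownames(by_type) <- NULL
  list(accuracy = mean(chain_ok),
       baseline_accuracy = mean(exact_ok),
       by_type = by_type[, c("attribute_type", "n", "accuracy",
                             "baseline_accuracy")],
       n = nrow(heldout))
}
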