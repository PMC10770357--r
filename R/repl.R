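# Conversational REPL over the knowledge base: typed utterances stand in
# for speech-to-text output. Each turn runs the mapper chain, intent
# parsing, state update and response dispatch, then executes the analytics
# the response requests.

# carrier phrases around the attribute value ("tell me about mutations",
# "show me breast cancer", "how about pik3ca") are stripped before the
# mapper sees the utterance — the stand-in for a voice platform's slot
# extraction
CARRIER_PATTERNS <- c(
  "^(please )?(tell me about|show me|what about|how about|switch to|go to|let's look at|lets look at|look at|give me|explore|i want|what is|whats) ",
  " please$")

strip_carrier_phrases <- function(raw) {
  x <- trimws(tolower(raw))
  for (p in CARRIER_PATTERNS) x <- sub(p, "", x)
  trimws(x)
}

DATA_TYPE_LABELS <- c(mutations = "mutations",
                      cna = "copy number alterations",
                      expression = "gene expression")

# execute the analysis a response payload describes; returns speech + table
execute_payload <- function(resp, state, cohorts) {
  pl <- resp$payload
  get_cohort <- function(label) {
    if (is.null(cohorts[[label]])) stop("cohort not loaded: ", label)
    cohorts[[label]]
  }
  if (is.null(pl$analysis)) return(list(speech = resp$speech_text, table = NULL))
  ds <- get_cohort(state$cancer_type)
  if (pl$analysis == "gene_summary") {
    if (pl$data_type == "mutations") {
      gs <- mutation_frequency(ds, pl$gene)
      return(list(speech = sprintf(
        "%s is mutated in %.1f%% of %s samples (%d of %d).",
        gs$gene, 100 * gs$frequency, ds$cancer_type,
        gs$altered_sample_count, gs$cohort_size),
        table = data.frame(gene = gs$gene, cancer_type = gs$cancer_type,
                           altered = gs$altered_sample_count,
                           cohort = gs$cohort_size,
                           frequency = gs$frequency),
        result = gs))
    }
    if (pl$data_type == "copy number alterations") {
      cf <- cna_frequency(ds, pl$gene)
      return(list(speech = sprintf(
        "%s is amplified in %.1f%% and deleted in %.1f%% of %s samples.",
        pl$gene, 100 * cf$amplification$frequency,
        100 * cf$deletion$frequency, ds$cancer_type),
        table = data.frame(gene = pl$gene,
                           category = c("amplification", "deletion"),
                           frequency = c(cf$amplification$frequency,
                                         cf$deletion$frequency)),
        result = cf$amplification))
    }
    es <- expression_summary(ds, pl$gene)
    return(list(speech = sprintf(
      "%s expression in %s: mean %.2f, median %.2f over %d samples.",
      pl$gene, ds$cancer_type, es$mean, es$median, es$n),
      table = as.data.frame(es), result = es))
  }
  if (pl$analysis == "overview") {
    top <- top_mutated_genes(ds, k = 5L)
    speech <- if (nrow(top)) sprintf(
      "Most frequently mutated genes in %s: %s.", ds$cancer_type,
      paste(sprintf("%s (%.0f%%)", top$gene, 100 * top$frequency),
            collapse = ", ")) else
      sprintf("No mutated genes on record for %s.", ds$cancer_type)
    return(list(speech = speech, table = top, result = top))
  }
  if (pl$analysis == "compare") {
    cr <- compare_attributes(ds, state, pl$attribute_type, pl$value_b)
    speech <- if (!is.null(cr$contingency)) sprintf(
      "%s in %s: %d samples mutated only, %d copy-number altered only, %d both, %d neither.",
      cr$gene, ds$cancer_type, cr$contingency[["a_only"]],
      cr$contingency[["b_only"]], cr$contingency[["both"]],
      cr$contingency[["neither"]]) else sprintf(
      "%s: %.1f%% versus %s: %.1f%%.", cr$value_a, 100 * cr$freq_a,
      cr$value_b, 100 * cr$freq_b)
    return(list(speech = speech, table = NULL, result = cr))
  }
  if (pl$analysis == "split_by") {
    sb <- split_by(ds, pl$quant_gene, pl$partition_gene)
    return(list(speech = sprintf(
      "%s expression by %s status: mutant mean %.2f (n=%d), wild-type mean %.2f (n=%d), p = %.3g.",
      sb$quant_gene, sb$partition_gene, sb$group_mutant$mean,
      sb$group_mutant$n, sb$group_wildtype$mean, sb$group_wildtype$n,
      sb$p_value), table = NULL, result = sb))
  }
  list(speech = resp$speech_text, table = NULL)
}

#' Process one conversational turn
#'
#' Runs the full pipeline for a single typed utterance: term resolution,
#' intent parsing, state update, response dispatch and analytics execution.
#'
#' @param raw The typed utterance.
#' @param state Current `nav_state`.
#' @param lexicon A `term_lexicon`.
#' @param cohorts Named list of loaded `cohort_dataset`s keyed by cancer
#'   type (may be empty; analytics then fall back to dispatch text only).
#' @param corpus,model,store,user_id,seed Passed to [map_utterance()].
#' @return List: updated `state`, the `match_result`, the `response_spec`,
#'   and `speech` (final text for the user).
#' @export
process_turn <- function(raw, state, lexicon, cohorts = list(),
                         corpus = NULL, model = NULL, store = NULL,
                         user_id = NULL, seed = 1L) {
  stripped <- strip_carrier_phrases(raw)
  match <- map_utterance(stripped, lexicon, corpus, model, store, user_id,
                         seed)
  it <- parse_intent(match, state, stripped, lexicon)
  if (it$kind == "RESET") {
    state <- new_session(state$session_id)
  } else if (it$kind == "NAVIGATE") {
    state <- apply_attribute(state, it$payload$attribute_type,
                             it$payload$value)
  }
  resp <- resolve_response(state, it)
  speech <- resp$speech_text
  result <- NULL
  if (resp$response_class %in% c("GENE_SUMMARY", "OVERVIEW_LIST",
                                 "COMPARE_VIEW", "SPLITBY_VIEW") &&
      !is.na(state$cancer_type) && !is.null(cohorts[[state$cancer_type]])) {
    exec <- tryCatch(execute_payload(resp, state, cohorts),
                     error = function(e) list(speech = paste(
                       "I could not complete that analysis:",
                       conditionMessage(e)), table = NULL))
    speech <- exec$speech
    result <- exec$result
  }
  if (match$stage == "UNRESOLVED" && it$kind == "HELP") {
    speech <- paste("I did not recognize that term.", speech)
  }
  list(state = state, match = match, response = resp, speech = speech,
       result = result)
}

#' Run the conversational REPL
#'
#' Feeds each input line through [process_turn()], printing the speech text.
#' `input` may be a character vector of scripted utterances (for batch use
#' and tests) or a connection; interactively it defaults to standard input.
#' Feeding a saved transcript's user lines back reproduces the same final
#' state.
#'
#' @param kb_dir Knowledge-base root from [build_knowledge_base()].
#' @param lexicon A `term_lexicon`.
#' @param input Character vector of utterances, or a connection.
#' @param corpus,model,store,user_id,seed Passed to the mapper chain.
#' @param session_file Optional JSON path; the session state is loaded from
#'   it at startup (if present) and saved after every turn.
#' @param transcript_file Optional JSON path receiving the full transcript.
#' @param quiet Suppress per-turn printing.
#' @return Invisibly, a list with the final `state` and the `transcript`
#'   (one entry per turn: text, stage, value, response class, speech).
#' @export
run_repl <- function(kb_dir, lexicon, input = stdin(), corpus = NULL,
                     model = NULL, store = NULL, user_id = NULL, seed = 1L,
                     session_file = NULL, transcript_file = NULL,
                     quiet = FALSE) {
  if (!dir.exists(kb_dir)) {
    stop("knowledge base not found at ", kb_dir,
         "; build it first with build_knowledge_base() or the ingest subcommand")
  }
  cohorts <- list()
  for (d in list.dirs(kb_dir, recursive = FALSE)) {
    ds <- tryCatch(load_cohort(kb_dir, basename(d)), error = function(e) NULL)
    if (!is.null(ds)) cohorts[[ds$cancer_type]] <- ds
  }
  state <- if (!is.null(session_file) && file.exists(session_file)) {
    load_session(session_file)
  } else {
    new_session()
  }
  lines <- if (is.character(input)) input else readLines(input, warn = FALSE)
  transcript <- list()
  for (raw in lines) {
    raw <- trimws(raw)
    if (!nzchar(raw)) next
    if (tolower(raw) %in% c("exit", "quit", "bye")) break
    turn <- process_turn(raw, state, lexicon, cohorts, corpus, model,
                         store, user_id, seed)
    state <- turn$state
    if (!quiet) cat(turn$speech, "\n")
    transcript[[length(transcript) + 1L]] <- list(
      text = raw, stage = turn$match$stage,
      value = turn$match$value,
      response_class = turn$response$response_class,
      speech = turn$speech,
      state = list(gene = state$gene, cancer_type = state$cancer_type,
                   data_type = state$data_type))
    if (!is.null(session_file)) save_session(state, session_file)
  }
  if (!is.null(transcript_file)) {
    jsonlite::write_json(transcript, transcript_file, auto_unbox = TRUE,
                         na = "null", pretty = TRUE)
  }
  invisible(list(state = state, transcript = transcript))
}

#' Train the matcher from corpus and lexicon files
#'
#' File-level wrapper used by the command-line `train-oov` subcommand:
#' reads the lexicon and corpus, trains the matcher, writes the versioned
#' model artifact and reports the partition sizes.
#'
#' @param corpus_path Utterance corpus TSV.
#' @param lexicon_path Lexicon TSV.
#' @param model_out Output artifact path.
#' @param train_fraction Training fraction (default 0.9).
#' @param seed Integer seed.
#' @return Invisibly, a list with `model_path`, `n_train`, `n_test`.
#' @export
cmd_train <- function(corpus_path, lexicon_path, model_out,
                      train_fraction = 0.9, seed = 1L) {
  lexicon <- read_lexicon(lexicon_path)
  corpus <- read_utterance_corpus(corpus_path, lexicon)
  fit <- train_matcher(corpus, train_fraction, seed)
  save_matcher(fit$model, model_out)
  cat(sprintf("trained on %d utterances, held out %d; model written to %s\n",
              fit$model$n_train, nrow(fit$heldout), model_out))
  invisible(list(model_path = model_out, n_train = fit$model$n_train,
                 n_test = nrow(fit$heldout)))
}

#' Evaluate the matcher chain from corpus and lexicon files
#'
#' Re-creates the seeded split, evaluates the full chain on the held-out
#' partition and prints full-chain and exact-only accuracy with the
#' partition sizes.
#'
#' @inheritParams cmd_train
#' @param model_path Optional pre-trained artifact; when absent the model
#'   is trained in place with the same split.
#' @return Invisibly, the [evaluate_matcher()] report plus partition sizes.
#' @export
cmd_eval <- function(corpus_path, lexicon_path, model_path = NULL,
                     train_fraction = 0.9, seed = 1L) {
  lexicon <- read_lexicon(lexicon_path)
  corpus <- read_utterance_corpus(corpus_path, lexicon)
  fit <- train_matcher(corpus, train_fraction, seed)
  model <- if (!is.null(model_path)) load_matcher(model_path) else fit$model
  parts <- split_corpus(corpus, train_fraction, seed)
  rep <- evaluate_matcher(model, parts$test, lexicon, parts$train, seed)
  cat(sprintf("train %d / test %d\n", nrow(parts$train), nrow(parts$test)))
  cat(sprintf("full-chain accuracy: %.3f\nexact-only baseline: %.3f\n",
              rep$accuracy, rep$baseline_accuracy))
  print(rep$by_type)
  invisible(c(rep, list(n_train = nrow(parts$train),
                        n_test = nrow(parts$test))))
}
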