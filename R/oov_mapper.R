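# Out-of-vocabulary mapper: resolves a noisy transcription to a canonical
# attribute value through a chain of stages — personal pronunciations, exact
# matching, crowdsourced-utterance lookup, then random-forest prediction.
# The first stage that resolves wins.

MATCH_STAGES <- c("PERSONAL", "EXACT", "CROWDSOURCED", "PREDICTED", "UNRESOLVED")

#' Construct a match result
#'
#' @param value Canonical term, or `NA` when unresolved.
#' @param attribute_type Attribute type, or `NA` when unresolved.
#' @param stage One of PERSONAL, EXACT, CROWDSOURCED, PREDICTED, UNRESOLVED.
#' @param confidence Fraction in `[0, 1]`; the lookup stages always report 1.
#' @return A `match_result`.
#' @export
match_result <- function(value = NA_character_, attribute_type = NA_character_,
                         stage = "UNRESOLVED", confidence = 0) {
  stage <- match.arg(stage, MATCH_STAGES)
  if (stage == "UNRESOLVED" && !is.na(value)) {
    stop("UNRESOLVED result cannot carry a value")
  }
  if (stage != "UNRESOLVED" && is.na(value)) {
    stop("resolved result requires a value")
  }
  if (stage %in% c("PERSONAL", "EXACT", "CROWDSOURCED")) confidence <- 1
  stopifnot(confidence >= 0, confidence <= 1)
  structure(list(value = value, attribute_type = attribute_type,
                 stage = stage, confidence = confidence),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  if (x$stage == "UNRESOLVED") {
    cat("<match_result> UNRESOLVED\n")
  } else {
    cat(sprintf("<match_result> %s [%s] via %s (confidence %.3f)\n",
                x$value, x$attribute_type, x$stage, x$confidence))
  }
  invisible(x)
}

is_resolved <- function(x) x$stage != "UNRESOLVED"

#' Exact matching against the lexicon
#'
#' @param normalized Normalized query text (see [normalize_text()]).
#' @param lexicon A `term_lexicon`.
#' @return A `match_result` with stage EXACT, or UNRESOLVED.
#' @export
exact_match <- function(normalized, lexicon) {
  stopifnot(inherits(lexicon, "term_lexicon"))
  if (is.na(normalized)) return(match_result())
  hit <- .lexicon_lookup(lexicon, normalized)
  if (is.na(hit$value[1])) return(match_result())
  match_result(hit$value[1], hit$attribute_type[1], "EXACT", 1)
}

#' Read an utterance corpus TSV
#'
#' Columns: `transcription`, `target_value`, `attribute_type`, optional
#' `speaker_id`. Every `target_value` must exist in the lexicon.
#'
#' @param path Path to the TSV.
#' @param lexicon A `term_lexicon` used to validate targets.
#' @return Data frame of utterance records with a `norm` column (normalized
#'   transcription).
#' @export
read_utterance_corpus <- function(path, lexicon) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", na.strings = NULL,
                          quote = "", fileEncoding = "UTF-8")
  need <- c("transcription", "target_value", "attribute_type")
  if (!all(need %in% names(df))) {
    stop("utterance corpus requires columns: ", paste(need, collapse = ", "))
  }
  if (!"speaker_id" %in% names(df)) df$speaker_id <- NA_character_
  if (any(!nzchar(df$transcription))) stop("empty transcription in corpus")
  known <- paste(lexicon$entries$attribute_type, lexicon$entries$value)
  got <- paste(df$attribute_type, df$target_value)
  if (any(!got %in% known)) {
    stop("corpus target(s) absent from lexicon: ",
         paste(utils::head(unique(df$target_value[!got %in% known]), 5),
               collapse = ", "))
  }
  df$norm <- normalize_text(df$transcription)
  df
}

#' Crowdsourced-utterance matching
#'
#' Resolves only when every corpus record whose normalized transcription
#' equals the query points at one single target; zero hits or ambiguous hits
#' fall through (UNRESOLVED) so the prediction stage can take over.
#'
#' @param normalized Normalized query text.
#' @param corpus Utterance data frame from [read_utterance_corpus()] (or any
#'   data frame with `norm`, `target_value`, `attribute_type`).
#' @return A `match_result` with stage CROWDSOURCED, or UNRESOLVED.
#' @export
crowdsourced_match <- function(normalized, corpus) {
  if (is.na(normalized) || is.null(corpus) || nrow(corpus) == 0L) {
    return(match_result())
  }
  hits <- corpus[!is.na(corpus$norm) & corpus$norm == normalized, , drop = FALSE]
  if (nrow(hits) == 0L) return(match_result())
  targets <- unique(paste(hits$attribute_type, hits$target_value))
  if (length(targets) != 1L) return(match_result())
  match_result(hits$target_value[1], hits$attribute_type[1], "CROWDSOURCED", 1)
}

# ---- personal pronunciation store -----------------------------------------

#' Create an empty personal pronunciation store
#' @return A `personal_store` (named list keyed by user id).
#' @export
personal_store <- function() {
  structure(list(users = list()), class = "personal_store")
}

#' Add (upsert) a personal pronunciation
#'
#' Records are keyed by `(user_id, normalized transcription)`; re-adding the
#' same key overwrites the target. Personal pronunciations are consulted
#' before every other matching stage for the owning user only.
#'
#' @param store A `personal_store`.
#' @param user_id Opaque account label.
#' @param transcription Raw transcription text (non-empty).
#' @param target_value Canonical term; must be in `lexicon` unless
#'   `custom = TRUE`.
#' @param attribute_type Attribute type of the target.
#' @param lexicon A `term_lexicon` for validation (optional when `custom`).
#' @param custom Flag a target that is outside the supported lexicon.
#' @return The updated store.
#' @export
add_personal_pronunciation <- function(store, user_id, transcription,
                                       target_value, attribute_type,
                                       lexicon = NULL, custom = FALSE) {
  stopifnot(inherits(store, "personal_store"))
  key <- normalize_text(transcription)
  if (is.na(key)) stop("empty transcription rejected")
  if (!custom) {
    if (is.null(lexicon)) stop("lexicon required unless custom = TRUE")
    known <- paste(lexicon$entries$attribute_type, lexicon$entries$value)
    if (!paste(attribute_type, target_value) %in% known) {
      stop("target not in lexicon (pass custom = TRUE to override): ",
           target_value)
    }
  }
  u <- store$users[[user_id]]
  if (is.null(u)) u <- list()
  u[[key]] <- list(target_value = target_value,
                   attribute_type = attribute_type, custom = custom)
  store$users[[user_id]] <- u
  store
}

#' Remove a personal pronunciation
#' @inheritParams add_personal_pronunciation
#' @return The updated store.
#' @export
remove_personal_pronunciation <- function(store, user_id, transcription) {
  key <- normalize_text(transcription)
  if (!is.null(store$users[[user_id]]) && !is.na(key)) {
    store$users[[user_id]][[key]] <- NULL
  }
  store
}

#' List a user's personal pronunciations
#' @inheritParams add_personal_pronunciation
#' @return Data frame with transcription key, target and attribute type.
#' @export
list_personal_pronunciations <- function(store, user_id) {
  u <- store$users[[user_id]]
  if (is.null(u) || length(u) == 0L) {
    return(data.frame(transcription = character(0), target_value = character(0),
                      attribute_type = character(0)))
  }
  data.frame(
    transcription = names(u),
    target_value = vapply(u, `[[`, character(1), "target_value"),
    attribute_type = vapply(u, `[[`, character(1), "attribute_type"),
    row.names = NULL)
}

#' Save / load a personal store as JSON
#' @param store A `personal_store`.
#' @param path JSON file path.
#' @return `path` (save) or the store (load).
#' @export
save_personal_store <- function(store, path) {
  jsonlite::write_json(store$users, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname save_personal_store
#' @export
load_personal_store <- function(path) {
  users <- jsonlite::read_json(path)
  structure(list(users = users), class = "personal_store")
}

personal_match <- function(normalized, store, user_id) {
  if (is.null(store) || is.null(user_id) || is.na(normalized)) {
    return(match_result())
  }
  rec <- store$users[[user_id]][[normalized]]
  if (is.null(rec)) return(match_result())
  match_result(rec$target_value, rec$attribute_type, "PERSONAL", 1)
}

# ---- full chain -----------------------------------------------------------

#' Map a raw utterance through the full resolution chain
#'
#' Stages run in order: personal pronunciations for `user_id`, exact
#' matching, crowdsourced matching, then model prediction; the first stage
#' that resolves short-circuits the rest. With no model loaded the chain
#' stops after crowdsourced matching.
#'
#' @param raw Raw transcription text.
#' @param lexicon A `term_lexicon`.
#' @param corpus Utterance corpus data frame, or `NULL`.
#' @param model A trained matcher from [train_matcher()], or `NULL`.
#' @param store A `personal_store`, or `NULL`.
#' @param user_id User whose personal pronunciations apply, or `NULL`.
#' @param seed Seed for the prediction stage's tie-breaking.
#' @return A `match_result`; stage UNRESOLVED when no stage resolves.
#' @export
map_utterance <- function(raw, lexicon, corpus = NULL, model = NULL,
                          store = NULL, user_id = NULL, seed = 1L) {
  normalized <- normalize_text(raw)
  res <- personal_match(normalized, store, user_id)
  if (is_resolved(res)) return(res)
  res <- exact_match(normalized, lexicon)
  if (is_resolved(res)) return(res)
  res <- crowdsourced_match(normalized, corpus)
  if (is_resolved(res)) return(res)
  if (!is.null(model)) {
    res <- predict_match(model, normalized, seed = seed)
    if (is_resolved(res)) return(res)
  }
  match_result()
}
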