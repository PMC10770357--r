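# Three-slot conversational navigation state (GENE, CANCER_TYPE, DATA_TYPE),
# intent parsing from typed utterances, and response-class dispatch.

INTENT_KINDS <- c("NAVIGATE", "COMPARE", "SPLIT_BY", "RESET", "HELP")
RESPONSE_CLASSES <- c("PROMPT_MISSING", "OVERVIEW_LIST", "GENE_SUMMARY",
                      "COMPARE_VIEW", "SPLITBY_VIEW", "ERROR_TEXT")
QUANTITATIVE_DATA_TYPES <- c("gene expression")

#' Start a fresh navigation session
#'
#' A fresh session has all three attribute slots empty; the state is a pure
#' function of the sequence of accepted updates.
#'
#' @param session_id Opaque session label.
#' @return A `nav_state` with empty gene, cancer type and data type slots.
#' @export
new_session <- function(session_id = "default") {
  structure(list(gene = NA_character_, cancer_type = NA_character_,
                 data_type = NA_character_, session_id = session_id),
            class = "nav_state")
}

#' @export
print.nav_state <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "<empty>" else v
  cat(sprintf("<nav_state %s> gene=%s cancer_type=%s data_type=%s\n",
              x$session_id, fmt(x$gene), fmt(x$cancer_type), fmt(x$data_type)))
  invisible(x)
}

slot_for_attribute <- function(attribute_type) {
  switch(attribute_type,
         GENE = "gene", CANCER_TYPE = "cancer_type", DATA_TYPE = "data_type",
         stop("unknown attribute_type: ", attribute_type))
}

#' Update one attribute slot
#'
#' Attributes arrive incrementally and in any order; an incoming value
#' replaces its own slot and never touches the other two (context
#' retention), so "How about PIK3CA?" after a full query switches only the
#' gene.
#'
#' @param state A `nav_state`.
#' @param attribute_type One of GENE, CANCER_TYPE, DATA_TYPE.
#' @param value Canonical term (already resolved by the mapper).
#' @return The updated `nav_state`.
#' @export
apply_attribute <- function(state, attribute_type, value) {
  stopifnot(inherits(state, "nav_state"))
  state[[slot_for_attribute(attribute_type)]] <- value
  state
}

#' Construct an intent
#' @param kind One of NAVIGATE, COMPARE, SPLIT_BY, RESET, HELP.
#' @param payload Kind-specific payload list.
#' @return An `intent`.
#' @export
intent <- function(kind, payload = list()) {
  kind <- match.arg(kind, INTENT_KINDS)
  structure(list(kind = kind, payload = payload), class = "intent")
}

#' Parse an intent from a typed utterance
#'
#' Fixed keyword triggers stand in for a voice platform's intent model:
#' "reset" / "start over" resets, "help" asks for guidance, "split by
#' <gene>" requests a stratified view, and "compare ... with <value>"
#' requests a comparison against a second value of the same attribute type.
#' Anything else is a NAVIGATE carrying the mapper's resolution.
#'
#' @param match A `match_result` for the utterance (used for NAVIGATE).
#' @param state Current `nav_state`.
#' @param raw_text The raw utterance, scanned for trigger phrases.
#' @param lexicon A `term_lexicon`, needed to resolve the second operand of
#'   compare / split-by triggers.
#' @return An `intent`. An unresolved match with no trigger yields HELP.
#' @export
parse_intent <- function(match, state, raw_text, lexicon = NULL) {
  norm <- normalize_text(raw_text)
  if (!is.na(norm)) {
    if (norm %in% c("reset", "start over", "clear")) return(intent("RESET"))
    if (norm %in% c("help", "what can i say")) return(intent("HELP"))
    m <- regmatches(norm, regexec("^split by (.+)$", norm))[[1]]
    if (length(m) == 2L && !is.null(lexicon)) {
      hit <- exact_match(normalize_text(m[2]), lexicon)
      if (is_resolved(hit) && hit$attribute_type == "GENE") {
        return(intent("SPLIT_BY", list(partition_gene = hit$value)))
      }
      return(intent("HELP", list(reason = "split-by needs a known gene")))
    }
    m <- regmatches(norm, regexec("^compare .*with (.+)$", norm))[[1]]
    if (length(m) == 2L && !is.null(lexicon)) {
      hit <- exact_match(normalize_text(m[2]), lexicon)
      if (is_resolved(hit)) {
        return(intent("COMPARE", list(attribute_type = hit$attribute_type,
                                      value_b = hit$value)))
      }
      return(intent("HELP", list(reason = "compare needs a known value")))
    }
  }
  if (is_resolved(match)) {
    return(intent("NAVIGATE", list(attribute_type = match$attribute_type,
                                   value = match$value)))
  }
  intent("HELP", list(reason = "unresolved utterance"))
}

filled <- function(state) {
  c(GENE = !is.na(state$gene), CANCER_TYPE = !is.na(state$cancer_type),
    DATA_TYPE = !is.na(state$data_type))
}

# fixed prompting order: DATA_TYPE then CANCER_TYPE then GENE
first_missing <- function(state) {
  order <- c("DATA_TYPE", "CANCER_TYPE", "GENE")
  f <- filled(state)
  order[!f[order]][1]
}

#' Select the response class for a state and intent
#'
#' Dispatch is a pure function of the slot fill pattern and the intent kind:
#' all three slots filled on NAVIGATE gives a gene summary; data type and
#' cancer type with no gene gives a cohort overview (e.g. most frequently
#' mutated genes); anything less prompts for the first missing attribute
#' (data type, then cancer type, then gene). COMPARE and SPLIT_BY dispatch
#' to their views when their requirements hold, otherwise to explanatory
#' error text. The payload describes the analysis the explorer should run.
#'
#' @param state A `nav_state`.
#' @param intent An `intent` (default NAVIGATE with no payload).
#' @return A `response_spec`: `response_class`, `speech_text`, `payload`.
#' @export
resolve_response <- function(state, intent = NULL) {
  stopifnot(inherits(state, "nav_state"))
  if (is.null(intent)) intent <- intent("NAVIGATE")
  f <- filled(state)
  spec <- function(class, speech, payload = list()) {
    structure(list(response_class = class, speech_text = speech,
                   payload = payload), class = "response_spec")
  }
  if (intent$kind == "RESET") {
    return(spec("PROMPT_MISSING",
                "Starting over. Which data type would you like to explore?",
                list(ask = "DATA_TYPE")))
  }
  if (intent$kind == "HELP") {
    return(spec("PROMPT_MISSING",
                paste("You can name a gene, a cancer type, or a data type;",
                      "or say 'compare ... with ...', 'split by <gene>',",
                      "or 'reset'."),
                list(ask = first_missing(state))))
  }
  if (intent$kind == "COMPARE") {
    at <- intent$payload$attribute_type
    slot_a <- tryCatch(state[[slot_for_attribute(at)]], error = function(e) NA)
    if (is.na(slot_a)) {
      return(spec("ERROR_TEXT",
                  sprintf("To compare, first set a %s to compare against.",
                          tolower(gsub("_", " ", at)))))
    }
    need <- switch(at,
      DATA_TYPE = !f[["GENE"]] || !f[["CANCER_TYPE"]],
      GENE = !f[["CANCER_TYPE"]] || !f[["DATA_TYPE"]],
      CANCER_TYPE = !f[["GENE"]] || !f[["DATA_TYPE"]])
    if (isTRUE(need)) {
      return(spec("ERROR_TEXT",
                  "Comparison needs the other two attributes to be set."))
    }
    return(spec("COMPARE_VIEW",
                sprintf("Comparing %s with %s.", slot_a, intent$payload$value_b),
                list(analysis = "compare", attribute_type = at,
                     value_a = slot_a, value_b = intent$payload$value_b)))
  }
  if (intent$kind == "SPLIT_BY") {
    if (!all(f)) {
      return(spec("ERROR_TEXT",
                  "Split-by needs a gene, a cancer type, and a quantitative data type."))
    }
    if (!state$data_type %in% QUANTITATIVE_DATA_TYPES) {
      return(spec("ERROR_TEXT",
                  sprintf("Split-by requires a quantitative data type such as gene expression; '%s' is categorical.",
                          state$data_type)))
    }
    return(spec("SPLITBY_VIEW",
                sprintf("%s expression split by %s mutation status.",
                        state$gene, intent$payload$partition_gene),
                list(analysis = "split_by", quant_gene = state$gene,
                     partition_gene = intent$payload$partition_gene)))
  }
  # NAVIGATE dispatch on fill pattern
  if (all(f)) {
    return(spec("GENE_SUMMARY",
                sprintf("Here is the %s %s summary for %s.",
                        state$gene, state$data_type, state$cancer_type),
                list(analysis = "gene_summary", gene = state$gene,
                     cancer_type = state$cancer_type,
                     data_type = state$data_type)))
  }
  if (f[["DATA_TYPE"]] && f[["CANCER_TYPE"]]) {
    return(spec("OVERVIEW_LIST",
                sprintf("Here are the top genes by %s in %s.",
                        state$data_type, state$cancer_type),
                list(analysis = "overview", cancer_type = state$cancer_type,
                     data_type = state$data_type)))
  }
  miss <- first_missing(state)
  spec("PROMPT_MISSING",
       sprintf("Which %s would you like to explore?",
               tolower(gsub("_", " ", miss))),
       list(ask = miss))
}

#' Save / load a session as JSON
#' @param state A `nav_state`.
#' @param path JSON file path.
#' @return `path` (save) or the restored `nav_state` (load).
#' @export
save_session <- function(state, path) {
  stopifnot(inherits(state, "nav_state"))
  jsonlite::write_json(unclass(state), path, auto_unbox = TRUE, null = "null",
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname save_session
#' @export
load_session <- function(path) {
  x <- jsonlite::read_json(path)
  as_chr <- function(v) if (is.null(v)) NA_character_ else as.character(v)
  structure(list(gene = as_chr(x$gene), cancer_type = as_chr(x$cancer_type),
                 data_type = as_chr(x$data_type),
                 session_id = as.character(x$session_id)),
            class = "nav_state")
}
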