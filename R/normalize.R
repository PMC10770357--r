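# Text normalization shared by every matching stage: queries and stored
# transcriptions must go through the identical transform so lookup keys agree.

#' Normalize a raw transcription
#'
#' Lowercases, strips punctuation, collapses whitespace and lemmatizes each
#' token. Tokens that look like gene symbols (letters mixed with digits) are
#' exempt from lemmatization so that e.g. "TP53" is never stemmed. The
#' function is idempotent: `normalize_text(normalize_text(x))` equals
#' `normalize_text(x)`.
#'
#' @param raw Character vector of raw utterance text.
#' @return Character vector of normalized text. Input that is empty after
#'   cleaning yields `NA_character_` (the empty-normalization signal).
#' @export
#' @examples
#' normalize_text("Tp53.")       # "tp53"
#' normalize_text("Mutations")   # "mutation"
normalize_text <- function(raw) {
  if (length(raw) == 0L) return(character(0))
  vapply(raw, function(x) {
    if (is.na(x)) return(NA_character_)
    x <- tolower(x)
    x <- gsub("[^a-z0-9 ]+", " ", x)
    x <- gsub("[[:space:]]+", " ", x)
    x <- trimws(x)
    if (!nzchar(x)) return(NA_character_)
    toks <- strsplit(x, " ", fixed = TRUE)[[1]]
    paste(vapply(toks, lemmatize_token, character(1)), collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}

# Rule-based English lemmatizer for the handful of inflections that occur in
# attribute vocabulary ("mutations", "deletions", "copies", ...). Tokens
# containing digits are gene-symbol-like and returned untouched.
lemmatize_token <- function(tok) {
  if (grepl("[0-9]", tok) || nchar(tok) <= 3L) return(tok)
  exceptions <- c(
    "this" = "this", "analysis" = "analysis", "status" = "status",
    "series" = "series", "species" = "species", "atlas" = "atlas",
    "census" = "census", "various" = "various", "pancreas" = "pancreas",
    "uterus" = "uterus", "esophagus" = "esophagus"
  )
  if (tok %in% names(exceptions)) return(unname(exceptions[[tok]]))
  if (grepl("ies$", tok)) return(sub("ies$", "y", tok))
  if (grepl("(ches|shes|xes|sses|zes)$", tok)) return(sub("es$", "", tok))
  if (grepl("s$", tok) && !grepl("(ss|us|is)$", tok)) return(sub("s$", "", tok))
  tok
}

#' Phonetic code of a transcription
#'
#' Encodes each whitespace token with a compact consonant-class keyer
#' (Soundex-style classes with digraph handling for ph/gh/ck/kn/wr) and
#' concatenates the per-token codes with spaces. Tokens made of digits are
#' passed through unchanged. Used as a noise-tolerant feature channel for the
#' matcher: transcriptions that sound alike collide on the same code.
#'
#' @param text Normalized text (see [normalize_text()]).
#' @return Character vector of phonetic code strings; `NA` maps to `NA`.
#' @export
#' @examples
#' phonetic_code("kay rass")
phonetic_code <- function(text) {
  vapply(text, function(x) {
    if (is.na(x)) return(NA_character_)
    toks <- strsplit(x, " ", fixed = TRUE)[[1]]
    paste(vapply(toks, .phonetic_token, character(1)), collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}

.phonetic_token <- function(tok) {
  if (!nzchar(tok)) return("")
  if (grepl("^[0-9]+$", tok)) return(tok)
  # digraph folding before classing
  tok <- gsub("ph", "f", tok)
  tok <- gsub("gh", "g", tok)
  tok <- gsub("ck", "k", tok)
  tok <- gsub("^kn", "n", tok)
  tok <- gsub("^wr", "r", tok)
  tok <- gsub("^x", "z", tok)
  chars <- strsplit(tok, "")[[1]]
  classes <- c(
    b = "1", f = "1", p = "1", v = "1",
    c = "2", g = "2", j = "2", k = "2", q = "2", s = "2", x = "2", z = "2",
    d = "3", t = "3",
    l = "4",
    m = "5", n = "5",
    r = "6"
  )
  coded <- vapply(chars, function(ch) {
    if (ch %in% names(classes)) classes[[ch]]
    else if (grepl("[0-9]", ch)) ch
    else "" # vowels, h, w, y drop
  }, character(1))
  # collapse runs of the same class
  keep <- coded[nzchar(coded)]
  if (length(keep) == 0L) return(substr(tok, 1L, 1L))
  runs <- keep[c(TRUE, keep[-1] != keep[-length(keep)])]
  paste0(substr(tok, 1L, 1L), paste(runs, collapse = ""))
}

#' Count syllables with a vowel-group heuristic
#'
#' Counts maximal vowel groups per token, with a minimum of one syllable per
#' alphabetic token; digit-only tokens count one syllable per digit (they are
#' spoken digit by digit). Returns 0 for the empty-normalization signal.
#'
#' @param text Normalized text.
#' @return Integer vector of syllable counts.
#' @export
syllable_count <- function(text) {
  vapply(text, function(x) {
    if (is.na(x) || !nzchar(x)) return(0L)
    toks <- strsplit(x, " ", fixed = TRUE)[[1]]
    sum(vapply(toks, function(tok) {
      nd <- nchar(gsub("[^0-9]", "", tok))
      letters_part <- gsub("[0-9]", "", tok)
      vg <- if (nzchar(letters_part))
        lengths(regmatches(letters_part, gregexpr("[aeiouy]+", letters_part)))
      else 0L
      max(as.integer(vg) + nd, 1L)
    }, integer(1)))
  }, integer(1), USE.NAMES = FALSE)
}
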