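# Shared low-level helpers: tokenization, seeded RNG scoping, validation.

#' Default English stop-word list
#'
#' A deliberately small list used by [contextualize()]; prepositions are kept
#' out of it because the noun-phrase pattern of the profiling stage needs them
#' (profiling tokenizes separately and never removes stop words anyway).
#'
#' @return Character vector of stop words.
#' @export
default_stopwords <- function() {
  c("a", "an", "the", "and", "or", "but", "is", "are", "was", "were", "be",
    "been", "am", "do", "does", "did", "have", "has", "had", "i", "you", "he",
    "she", "it", "we", "they", "my", "your", "his", "her", "its", "our",
    "their", "this", "that", "these", "those", "what", "which", "who", "whom",
    "can", "could", "should", "would", "will", "shall", "may", "might", "must",
    "not", "no", "so", "if", "then", "than", "too", "very", "just", "there",
    "here", "when", "how", "why", "me", "him", "them", "us")
}

#' Tokenize free text
#'
#' Lowercases, splits on any run of characters outside `[a-z0-9']`, and
#' optionally drops stop words. This is the normalizer used throughout the
#' retrieval-side pipeline; the profiling stage uses `stopwords = character(0)`
#' so that prepositions survive for the noun-phrase pattern.
#'
#' @param text Character scalar (or vector, concatenated with spaces).
#' @param stopwords Character vector of tokens to drop after lowercasing.
#' @return Character vector of tokens (possibly empty).
#' @export
tokenize <- function(text, stopwords = default_stopwords()) {
  if (length(text) == 0L) return(character(0))
  text <- tolower(paste(text, collapse = " "))
  toks <- strsplit(text, "[^a-z0-9']+")[[1L]]
  toks <- toks[nzchar(toks)]
  if (length(stopwords)) toks <- toks[!(toks %in% stopwords)]
  toks
}

# Evaluate `expr` under a local, seeded RNG state without disturbing the
# caller's stream.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Deterministically derive a sub-seed for a named pipeline stage from a global
# seed. Keeps every derived seed a valid 32-bit R integer.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 48271 + h) %% 2147483587) + 1L
}

stop_qa <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == floor(x)
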