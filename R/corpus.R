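# QA records and corpora: construction, JSONL I/O, contextualization,
# hold-out splitting.

#' Construct a QA record
#'
#' One community QA item: a question, zero or more answers, zero or more tags.
#' `tokens` is filled by [contextualize()].
#'
#' @param id Unique record id (coerced to character).
#' @param question Question text (nonempty string).
#' @param answers Character vector of answer texts.
#' @param tags Character vector of short tags.
#' @return An object of class `qa_record`.
#' @export
qa_record <- function(id, question, answers = character(0), tags = character(0)) {
  if (length(id) != 1L || !nzchar(as.character(id))) {
    stop_qa("record id must be a nonempty scalar")
  }
  if (length(question) != 1L || is.na(question)) {
    stop_qa("record %s: question must be a single string", id)
  }
  structure(list(id = as.character(id),
                 question = as.character(question),
                 answers = as.character(answers),
                 tags = as.character(tags),
                 tokens = NULL,
                 length = 0L),
            class = "qa_record")
}

#' Construct a corpus of QA records
#'
#' @param records List of [qa_record()] objects with unique ids.
#' @param holdout_ids Record ids reserved for held-out perplexity evaluation.
#' @return An object of class `qa_corpus`.
#' @export
qa_corpus <- function(records, holdout_ids = character(0)) {
  ids <- vapply(records, function(r) r$id, character(1))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop_qa("duplicate record id(s): %s", paste(unique(dup), collapse = ", "))
  if (!all(holdout_ids %in% ids)) stop_qa("holdout_ids must be a subset of record ids")
  structure(list(records = stats::setNames(records, ids),
                 holdout_ids = as.character(holdout_ids)),
            class = "qa_corpus")
}

#' @export
print.qa_corpus <- function(x, ...) {
  cat(sprintf("<qa_corpus> %d records (%d held out)\n",
              length(x$records), length(x$holdout_ids)))
  invisible(x)
}

#' Number of records in a corpus
#' @param x A `qa_corpus`.
#' @export
length.qa_corpus <- function(x) length(x$records)

#' Record ids of a corpus, in input order
#' @param corpus A `qa_corpus`.
#' @return Character vector of record ids.
#' @export
corpus_ids <- function(corpus) names(corpus$records)

#' Read a corpus from JSON-lines
#'
#' One JSON object per line with keys `id`, `question` and optionally
#' `answers` (array) and `tags` (array). Input order is preserved.
#'
#' @param path Path to a JSONL file.
#' @return A `qa_corpus`.
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) stop_qa("corpus file not found: %s", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  records <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    obj <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
                    error = function(e) NULL)
    if (is.null(obj) || is.null(obj$id) || is.null(obj$question)) {
      stop_qa("corpus parse error at line %d: %s", i,
              if (is.null(obj)) "malformed JSON" else "missing id or question")
    }
    records[[i]] <- qa_record(obj$id, obj$question,
                              answers = if (is.null(obj$answers)) character(0) else unlist(obj$answers),
                              tags = if (is.null(obj$tags)) character(0) else unlist(obj$tags))
  }
  qa_corpus(records)
}

#' Write a corpus to JSON-lines
#'
#' @param corpus A `qa_corpus`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  lines <- vapply(corpus$records, function(r) {
    jsonlite::toJSON(list(id = r$id, question = r$question,
                          answers = r$answers, tags = r$tags),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Contextualize a record
#'
#' Health questions are short; following the corpus-construction practice of
#' contextualizing questions with their answers and tags, the record's token
#' sequence is the normalized question tokens followed by answer tokens
#' followed by tag tokens. Updates `tokens` and `length`.
#'
#' @param record A `qa_record` with a nonempty question.
#' @param stopwords Stop-word list passed to [tokenize()].
#' @param answers `"all"` keeps every answer, `"first"` only the top answer.
#' @return The record with `tokens` and `length` filled.
#' @export
contextualize <- function(record, stopwords = default_stopwords(),
                          answers = c("all", "first")) {
  answers <- match.arg(answers)
  if (!nzchar(trimws(record$question))) {
    stop_qa("record %s: cannot contextualize an empty question", record$id)
  }
  ans <- record$answers
  if (answers == "first" && length(ans) > 1L) ans <- ans[1L]
  toks <- c(tokenize(record$question, stopwords),
            unlist(lapply(ans, tokenize, stopwords = stopwords)),
            unlist(lapply(record$tags, tokenize, stopwords = stopwords)))
  record$tokens <- as.character(toks)
  record$length <- length(toks)
  record
}

#' Contextualize every record of a corpus
#'
#' @inheritParams contextualize
#' @param corpus A `qa_corpus`.
#' @return The corpus with all records contextualized.
#' @export
contextualize_corpus <- function(corpus, stopwords = default_stopwords(),
                                 answers = c("all", "first")) {
  answers <- match.arg(answers)
  corpus$records <- lapply(corpus$records, contextualize,
                           stopwords = stopwords, answers = answers)
  corpus
}

#' Mark a seeded hold-out split
#'
#' Marks `ceiling(fraction * n)` record ids as held out, chosen by seeded
#' uniform sampling without replacement. The same seed reproduces the split.
#'
#' @param corpus A `qa_corpus` with at least 2 records.
#' @param fraction Hold-out proportion in (0, 1).
#' @param seed Integer seed.
#' @return The corpus with `holdout_ids` set.
#' @export
split_holdout <- function(corpus, fraction = 0.1, seed = 1L) {
  if (!(is.numeric(fraction) && fraction > 0 && fraction < 1)) {
    stop_qa("holdout fraction must lie strictly in (0, 1)")
  }
  n <- length(corpus$records)
  if (n < 2L) stop_qa("corpus must hold at least 2 records to split")
  m <- ceiling(fraction * n)
  if (m >= n) m <- n - 1L
  ids <- corpus_ids(corpus)
  corpus$holdout_ids <- with_seed(seed, sort(sample(ids, m)))
  corpus
}

# Token lists of a set of records (must be contextualized).
record_tokens <- function(corpus, ids = corpus_ids(corpus)) {
  lapply(corpus$records[ids], function(r) {
    if (is.null(r$tokens)) stop_qa("record %s has not been contextualized", r$id)
    r$tokens
  })
}
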