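# Concept lexicon: surface phrase -> standard terminology with semantic group.
# A file-based stand-in for a concept-mapping service over a terminology
# metathesaurus; lookup is exact match after lowercasing and singularization.

#' Construct a concept lexicon
#'
#' @param phrase Character vector of surface phrases.
#' @param term_id Terminology id each phrase normalizes to.
#' @param term_name Canonical terminology name.
#' @param group Semantic group of the terminology (used for kernel boosting).
#' @return An object of class `concept_lexicon`.
#' @export
concept_lexicon <- function(phrase, term_id, term_name, group) {
  n <- length(phrase)
  if (!all(lengths(list(term_id, term_name, group)) == n)) {
    stop_qa("lexicon columns must have equal length")
  }
  key <- normalize_phrase(phrase)
  if (anyDuplicated(key)) {
    keep <- !duplicated(key)
    phrase <- phrase[keep]; term_id <- term_id[keep]
    term_name <- term_name[keep]; group <- group[keep]; key <- key[keep]
  }
  tab <- data.frame(phrase = as.character(phrase), key = key,
                    term_id = as.character(term_id),
                    term_name = as.character(term_name),
                    group = as.character(group),
                    stringsAsFactors = FALSE)
  structure(list(table = tab,
                 index = stats::setNames(seq_len(nrow(tab)), tab$key)),
            class = "concept_lexicon")
}

#' Read a lexicon from TSV
#'
#' Columns (no header): phrase, terminology id, terminology name, semantic
#' group.
#'
#' @param path Path to a tab-separated file.
#' @return A `concept_lexicon`.
#' @export
read_lexicon <- function(path) {
  if (!file.exists(path)) stop_qa("lexicon file not found: %s", path)
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           quote = "", comment.char = "",
                           col.names = c("phrase", "term_id", "term_name", "group"))
  concept_lexicon(tab$phrase, tab$term_id, tab$term_name, tab$group)
}

#' Write a lexicon to TSV
#' @param lexicon A `concept_lexicon`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lexicon, path) {
  utils::write.table(lexicon$table[, c("phrase", "term_id", "term_name", "group")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Singularize a token
#'
#' Rule-table plural stripping (no full lemmatizer): `-ies -> -y`;
#' `-(sh|x|ss|z)es -> drop es`; otherwise a trailing `-s` (not `-ss`) is
#' dropped, so "headaches" singularizes to "headache".
#'
#' @param token Character vector of lowercase tokens.
#' @return Singularized tokens.
#' @export
singularize <- function(token) {
  out <- token
  ies <- grepl("ies$", out) & nchar(out) > 4L
  out[ies] <- sub("ies$", "y", out[ies])
  es <- !ies & grepl("(sh|x|ss|z)es$", out)
  out[es] <- sub("es$", "", out[es])
  s <- !ies & !es & grepl("[^s']s$", out)
  out[s] <- sub("s$", "", out[s])
  out
}

# Canonical lookup key: lowercase, tokenwise singularization, single spaces.
normalize_phrase <- function(phrase) {
  vapply(phrase, function(p) {
    toks <- tokenize(p, stopwords = character(0))
    paste(singularize(toks), collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}

#' Look up phrases in a lexicon
#'
#' @param lexicon A `concept_lexicon`.
#' @param phrases Character vector of surface phrases.
#' @return Data frame with one row per *mapped* phrase: `phrase`, `term_id`,
#'   `term_name`, `group`. Unmapped phrases are absent.
#' @export
lexicon_lookup <- function(lexicon, phrases) {
  key <- normalize_phrase(phrases)
  hit <- lexicon$index[key]
  ok <- !is.na(hit)
  out <- lexicon$table[hit[ok], c("term_id", "term_name", "group")]
  out <- cbind(data.frame(phrase = phrases[ok], stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}

# Singularized single-word surface forms that belong to a boosted semantic
# group; used by the weighted term kernel.
boosted_tokens <- function(lexicon, groups) {
  if (is.null(lexicon)) return(character(0))
  tab <- lexicon$table
  one_word <- !grepl(" ", tab$key)
  tab$key[one_word & tolower(tab$group) %in% tolower(groups)]
}
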