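# Node profiling: extract frequent noun phrases from a node's member texts by
# a POS tag pattern, normalize them into standard terminologies through the
# concept lexicon, and rank terminologies by binary voting.

#' Dictionary-based POS tagger
#'
#' Maps each token through a word -> tag table; unknown tokens get
#' `default`. Tags are the coarse classes used by the noun-phrase pattern:
#' `"N"` noun, `"A"` adjective, `"P"` preposition, `"O"` other. A real tagger
#' plugs into the same interface (`function(tokens) -> character`).
#'
#' @param dict Named character vector `word -> tag`.
#' @param default Tag for unknown tokens, default `"N"`.
#' @return A tagger function.
#' @export
dictionary_tagger <- function(dict = character(0), default = "N") {
  function(tokens) {
    tags <- unname(dict[tokens])
    tags[is.na(tags)] <- default
    tags
  }
}

#' Default heuristic POS tagger
#'
#' A small offline stand-in: common English prepositions tag `"P"`, a short
#' verb/function-word list tags `"O"`, tokens with typical adjectival
#' suffixes (-ive, -al, -ful, -ous, -ic, -able, -less, -ing) tag `"A"`, and
#' everything else tags `"N"`. Sufficient for exercising the phrase pattern;
#' substitute a real tagger for natural text.
#'
#' @return A tagger function (token vector in, tag vector out).
#' @export
default_tagger <- function() {
  preps <- c("of", "in", "on", "for", "with", "to", "from", "at", "by",
             "about", "into", "over", "under", "during", "after", "before")
  others <- c("is", "are", "was", "were", "be", "been", "am", "have", "has",
              "had", "do", "does", "did", "get", "got", "take", "took",
              "make", "made", "cause", "caused", "feel", "felt", "and", "or",
              "but", "the", "a", "an", "what", "how", "why", "can", "could",
              "should", "would", "my", "your", "i", "you", "it", "this",
              "that", "not", "no", "very")
  function(tokens) {
    tags <- rep("N", length(tokens))
    tags[tokens %in% others] <- "O"
    tags[tokens %in% preps] <- "P"
    adj <- grepl("(ive|al|ful|ous|ic|able|less|ing)$", tokens) &
      nchar(tokens) > 4L & tags == "N"
    tags[adj] <- "A"
    tags
  }
}

# The noun-phrase tag pattern: (Adj|Noun)* (Noun Prep)? (Adj|Noun)* Noun,
# applied greedily left to right on the tag string of one text.
NP_PATTERN <- "[AN]*(NP)?[AN]*N"

#' Extract frequent noun phrases from texts
#'
#' Splits each text into sentences (terminal punctuation), tags the tokens,
#' and collects the maximal within-sentence token spans whose tag sequences
#' match `(Adj|Noun)* (Noun Prep)? (Adj|Noun)* Noun` (matched greedily left
#' to right). Plural variants are singularized tokenwise and merged.
#' Tokenization here keeps stop words: the pattern needs prepositions.
#'
#' @param texts Character vector of raw texts.
#' @param tagger A tagger function; one tag per token.
#' @param min_tokens Drop phrases shorter than this many tokens (default 1).
#' @return Data frame `phrase`, `count`, sorted by decreasing count then
#'   phrase.
#' @export
extract_noun_phrases <- function(texts, tagger = default_tagger(),
                                 min_tokens = 1L) {
  counts <- new.env(parent = emptyenv())
  sentences <- unlist(lapply(texts, function(t) strsplit(t, "[.?!;]+")[[1L]]))
  for (text in sentences) {
    toks <- tokenize(text, stopwords = character(0))
    if (!length(toks)) next
    tags <- tryCatch(tagger(toks), error = function(e) NULL)
    if (is.null(tags) || length(tags) != length(toks)) {
      warning("tagger failed on a text; skipped")
      next
    }
    tagstr <- paste(tags, collapse = "")
    m <- gregexpr(NP_PATTERN, tagstr, perl = TRUE)[[1L]]
    if (m[1L] == -1L) next
    lens <- attr(m, "match.length")
    for (i in seq_along(m)) {
      if (lens[i] < min_tokens) next
      span <- singularize(toks[m[i]:(m[i] + lens[i] - 1L)])
      phrase <- paste(span, collapse = " ")
      counts[[phrase]] <- (counts[[phrase]] %||% 0L) + 1L
    }
  }
  phrases <- ls(counts)
  if (!length(phrases)) {
    return(data.frame(phrase = character(0), count = integer(0)))
  }
  out <- data.frame(phrase = phrases,
                    count = vapply(phrases, function(p) counts[[p]], integer(1)),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$count, out$phrase), , drop = FALSE]
}

#' Vote candidate phrases into terminologies
#'
#' Normalizes each candidate phrase through the lexicon and scores each
#' terminology by the number of distinct candidate phrases mapping to it
#' (binary votes: one vote per phrase per terminology). Phrases without a
#' lexicon entry cast no vote. Ranking: score descending, ties by summed
#' phrase frequency descending, then terminology id.
#'
#' @param candidates Data frame `phrase`, `count` (as from
#'   [extract_noun_phrases()]), typically the top-k frequent phrases.
#' @param lexicon A `concept_lexicon`.
#' @return Data frame `term_id`, `term_name`, `score`, `freq`, ranked.
#' @export
vote_terminologies <- function(candidates, lexicon) {
  if (!nrow(candidates)) stop_qa("no candidate phrases to vote")
  hits <- lexicon_lookup(lexicon, candidates$phrase)
  if (!nrow(hits)) {
    warning("no candidate phrase maps to any terminology")
    return(data.frame(term_id = character(0), term_name = character(0),
                      score = integer(0), freq = integer(0)))
  }
  hits$freq <- candidates$count[match(hits$phrase, candidates$phrase)]
  score <- tapply(hits$phrase, hits$term_id, function(p) length(unique(p)))
  freq <- tapply(hits$freq, hits$term_id, sum)
  name <- tapply(hits$term_name, hits$term_id, `[`, 1L)
  out <- data.frame(term_id = names(score),
                    term_name = as.character(name[names(score)]),
                    score = as.integer(score),
                    freq = as.integer(freq[names(score)]),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$score, -out$freq, out$term_id), , drop = FALSE]
}

#' Label one hierarchy node with terminologies
#'
#' Runs noun-phrase extraction over the node members' raw texts (question,
#' answers, tags), takes the top `k` frequent phrases, votes them into
#' terminologies and keeps the `top_n` ranked ones as the node's labels.
#'
#' @param node A hierarchy node (list with `members`).
#' @param corpus The `qa_corpus` the hierarchy was built on.
#' @param lexicon A `concept_lexicon`.
#' @param tagger A POS tagger function.
#' @param k Number of candidate phrases entering the vote.
#' @param top_n Number of labels kept.
#' @return The node with `labels` set (data frame `term_id`, `term_name`,
#'   `score`; zero rows when nothing maps).
#' @export
label_node <- function(node, corpus, lexicon, tagger = default_tagger(),
                       k = 20L, top_n = 5L) {
  if (!length(node$members)) stop_qa("cannot label an empty node")
  texts <- unlist(lapply(corpus$records[node$members], function(r) {
    c(r$question, r$answers, r$tags)
  }))
  phrases <- extract_noun_phrases(texts, tagger)
  if (!nrow(phrases)) {
    node$labels <- data.frame(term_id = character(0),
                              term_name = character(0), score = integer(0))
    return(node)
  }
  cand <- utils::head(phrases, k)
  ranked <- suppressWarnings(vote_terminologies(cand, lexicon))
  node$labels <- utils::head(ranked[, c("term_id", "term_name", "score")], top_n)
  rownames(node$labels) <- NULL
  node
}

#' Label every node of a hierarchy
#'
#' @param hierarchy A `qa_hierarchy`.
#' @inheritParams label_node
#' @param k,top_n Defaults taken from the hierarchy's config.
#' @return The hierarchy with labeled nodes.
#' @export
label_hierarchy <- function(hierarchy, corpus, lexicon,
                            tagger = default_tagger(), k = NULL,
                            top_n = NULL) {
  k <- k %||% hierarchy$config$profile_k
  top_n <- top_n %||% hierarchy$config$profile_top_n
  hierarchy$nodes <- lapply(hierarchy$nodes, label_node, corpus = corpus,
                            lexicon = lexicon, tagger = tagger, k = k,
                            top_n = top_n)
  hierarchy
}
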